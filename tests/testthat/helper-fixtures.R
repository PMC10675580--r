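# Shared fixtures and independent oracles for the test suite.

# Independent PLS2 oracle: per component, the X-weight is the dominant left
# singular vector of t(X) %*% Y (X auto-scaled, Y centred one-hot), scores
# follow by projection and X is deflated by regression on the score. This
# is a direct eigen/SVD route, independent of the package's NIPALS loop.
pls2Oracle <- function(X, y, ncomp) {
    Xs <- scale(X)
    Y <- stats::model.matrix(~ y - 1)
    Y <- scale(Y, scale = FALSE)
    W <- NULL; Tm <- NULL
    for (h in seq_len(ncomp)) {
        sv <- svd(crossprod(Xs, Y), nu = 1, nv = 0)
        w <- sv$u[, 1]
        i <- which.max(abs(w))
        if (w[i] < 0) w <- -w
        tt <- Xs %*% w
        p <- crossprod(Xs, tt) / sum(tt^2)
        Xs <- Xs - tt %*% t(p)
        W <- cbind(W, w); Tm <- cbind(Tm, tt)
    }
    list(weights = W, scores = Tm)
}

# Tiny hand-assembled element table (values chosen for easy arithmetic).
smallEggTable <- function() {
    conc <- rbind(
        Na = c(10000, 600, 650, 12000, 700, 600),
        K  = c(4000, 600, 150, 4500, 550, 160),
        Ca = c(450, 1200, 75000, 500, 1300, 70000),
        Pb = c(1, 2, 0.1, 0.5, 1.5, 0.2)
    )
    ElementExperiment(conc,
        eggPart = rep(c("white", "yolk", "shell"), 2),
        system = rep(c("home", "commercial"), each = 3),
        sampleId = rep(c("e1", "e2"), each = 3))
}

# Small generated dataset reused across tests (fixed seed, fast size).
smallSynthetic <- function(seed = 11, home = 12, commercial = 6) {
    generateEggData(syntheticConfig(
        nEggs = c(home = home, commercial = commercial), seed = seed))
}

# CSV text written to a temp file.
writeCsvText <- function(lines) {
    f <- tempfile(fileext = ".csv")
    writeLines(lines, f)
    f
}
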