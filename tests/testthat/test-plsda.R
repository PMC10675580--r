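test_that("keepX soft-thresholding matches the hand-computed rule", {
    w <- ovorisk:::.keepXThreshold(c(0.9, 0.5, 0.1), 2)
    expect_equal(w, c(0.8, 0.4, 0) / sqrt(0.8^2 + 0.4^2), tolerance = 1e-12)
    # keepX = p leaves the direction unchanged (only normalises)
    v <- c(3, -1, 2)
    expect_equal(ovorisk:::.keepXThreshold(v, 3), v / sqrt(sum(v^2)))
})

test_that("full-keepX fits equal an independent PLS2 oracle", {
    set.seed(10)
    for (i in 1:8) {
        n <- sample(15:40, 1); p <- sample(3:8, 1)
        K <- sample(2:3, 1)
        y <- factor(sample(letters[1:K], n, replace = TRUE))
        while (nlevels(droplevels(y)) < K || min(table(y)) < 3)
            y <- factor(sample(letters[1:K], n, replace = TRUE))
        X <- matrix(rnorm(n * p), n, p)
        X[, 1] <- X[, 1] + 2 * (y == "a")
        nc <- min(3, p, n - 1)
        fit <- plsdaFit(X, y, ncomp = nc)
        or <- pls2Oracle(X, y, nc)
        expect_lt(max(abs(fit@weights - or$weights)), 1e-6)
        expect_lt(max(abs(fit@scoresX - or$scores)), 1e-6)
    }
})

test_that("fitted models satisfy sparsity and orthogonality invariants", {
    set.seed(11)
    for (i in 1:6) {
        n <- 30; p <- 8
        y <- factor(rep(c("a", "b", "c"), each = 10))
        X <- matrix(rnorm(n * p), n, p)
        X[, 2] <- X[, 2] + 1.5 * (y == "b")
        kx <- sample(1:p, 2, replace = TRUE)
        fit <- plsdaFit(X, y, ncomp = 2, keepX = kx)
        # nonzero weights per component bounded by keepX
        nz <- colSums(abs(fit@weights) > 0)
        expect_true(all(nz <= kx))
        # unit-norm weight columns
        expect_equal(unname(sqrt(colSums(fit@weights^2))), c(1, 1),
                     tolerance = 1e-10)
        # mutually orthogonal scores
        g <- crossprod(fit@scoresX)
        expect_lt(max(abs(g - diag(diag(g)))), 1e-8)
    }
})

test_that("the unpenalised route agrees with the mixOmics reference", {
    skip_if_not_installed("mixOmics")
    set.seed(42)
    X <- matrix(rnorm(40 * 8), 40, 8,
                dimnames = list(NULL, paste0("v", 1:8)))
    y <- factor(rep(c("a", "b", "c"), length.out = 40))  # balanced
    X[, 1] <- X[, 1] + 2 * (y == "a")
    X[, 5] <- X[, 5] - 1.5 * (y == "c")
    fit <- plsdaFit(X, y, ncomp = 3)
    mo <- mixOmics::plsda(X, y, ncomp = 3)
    expect_true(all(diag(abs(cor(fit@scoresX, mo$variates$X))) > 0.999))
    mine <- plsdaPredict(fit, X, distance = "max")$class
    theirs <- predict(mo, X)$class$max.dist[, 3]
    expect_equal(as.character(mine), unname(theirs))
    # sparse selection agrees on a clear two-signal fixture
    sf <- plsdaFit(X, y, ncomp = 2, keepX = c(2, 2))
    ms <- mixOmics::splsda(X, y, ncomp = 2, keepX = c(2, 2))
    moSel <- unique(unlist(lapply(1:2, function(h)
        mixOmics::selectVar(ms, comp = h)$name)))
    expect_setequal(selectedVariables(sf), moSel)
})

test_that("a single separating variable is selected at keepX = 1", {
    set.seed(12)
    y <- factor(rep(c("a", "b"), each = 15))
    X <- matrix(rnorm(30 * 3, sd = 0.3), 30, 3,
                dimnames = list(NULL, c("u", "v", "w")))
    X[, 2] <- ifelse(y == "a", 2, -2) + rnorm(30, sd = 0.1)
    fit <- plsdaFit(X, y, ncomp = 1, keepX = 1)
    expect_equal(selectedVariables(fit), "v")
    pr <- plsdaPredict(fit, X, distance = "centroid")
    expect_equal(as.character(pr$class), as.character(y))
})

test_that("prediction distance rules classify separable data and break ties", {
    set.seed(13)
    y <- factor(rep(c("a", "b", "c"), each = 12))
    X <- matrix(rnorm(36 * 4, sd = 0.2), 36, 4)
    X[, 1] <- X[, 1] + 3 * (y == "a")
    X[, 2] <- X[, 2] + 3 * (y == "b")
    fit <- plsdaFit(X, y, ncomp = 2)
    for (d in c("max", "centroid", "mahalanobis")) {
        pr <- plsdaPredict(fit, X, distance = d)
        expect_equal(as.character(pr$class), as.character(y), info = d)
    }
    # symmetric midpoint -> deterministic tie-break with a warning
    Xt <- matrix(c(-1, -1.5, 1, 1.5, 0.5, -0.5, 0.5, -0.5), 4, 2)
    yt <- factor(c("a", "a", "b", "b"))
    ft <- plsdaFit(Xt, yt, ncomp = 1)
    expect_warning(prt <- plsdaPredict(ft, matrix(0, 1, 2),
                                       distance = "centroid"), "tie")
    expect_equal(as.character(prt$class), "a")  # first class in level order
    # column mismatch is reported with the offending names
    Xn <- matrix(rnorm(8), 2, 4,
                 dimnames = list(NULL, c("p", "q", "r", "s")))
    fn <- plsdaFit(Xn, factor(c("a", "b")), ncomp = 1)
    expect_error(plsdaPredict(fn, Xn[, 1:3, drop = FALSE]), "missing.*s")
})

test_that("fit validates its preconditions", {
    X <- matrix(rnorm(20), 10, 2)
    y <- factor(rep(c("a", "b"), 5), levels = c("a", "b", "c"))
    expect_error(plsdaFit(X, y, ncomp = 1), "absent")
    expect_error(plsdaFit(X, droplevels(y), ncomp = 5), "ncomp")
    expect_error(plsdaFit(X, droplevels(y), ncomp = 1, keepX = 9), "keepX")
})

test_that("error-rate definitions and invariances hold", {
    truth <- factor(rep(c("a", "b", "c"), each = 10))
    pred <- as.character(truth)
    pred[c(1, 2, 11, 12, 21, 22)] <- c("b", "b", "a", "a", "a", "b")
    # per-class error rates all 0.2 -> BER 0.2
    expect_equal(balancedErrorRate(truth, pred), 0.2)
    expect_equal(overallErrorRate(truth, pred), 0.2)
    # duplicating one class leaves BER unchanged
    idx <- c(seq_along(truth), which(truth == "a"))
    expect_equal(balancedErrorRate(truth[idx], pred[idx]), 0.2)
    expect_gt(overallErrorRate(truth[idx], pred[idx]) - 0.2, -0.2) # OER shifts
})

test_that("classification reports match hand-computed metrics", {
    rep <- classificationReport(confusion = matrix(c(8, 3, 2, 17), 2))
    expect_equal(rep@accuracy, 25 / 30, tolerance = 1e-10)
    expect_equal(rep@sensitivity, 0.80)
    expect_equal(rep@specificity, 0.85)
    # perfect predictions
    y <- factor(rep(c("a", "b"), each = 5))
    perf <- classificationReport(y, y)
    expect_equal(perf@accuracy, 1)
    expect_equal(unname(diag(perf@confusion)), c(5, 5))
    # confusion row sums equal class counts
    expect_equal(unname(rowSums(perf@confusion)), c(5, 5))
})

test_that("cross-validation is leakage-free, reproducible and well-behaved", {
    set.seed(14)
    y <- factor(rep(c("a", "b", "c"), each = 15))
    X <- matrix(rnorm(45 * 6, sd = 0.2), 45, 6)
    X[, 1] <- X[, 1] + 4 * (y == "a")
    X[, 2] <- X[, 2] + 4 * (y == "b")
    cv <- crossValidate(X, y, ncompGrid = 1:2, keepXGrid = c(2, 6),
                        folds = 5, repeats = 2, seed = 3)
    # separable at the sufficient configuration
    sub <- cv@grid[cv@grid$ncomp == 2, ]
    expect_true(any(sub$BER < 0.05))
    expect_true(all(cv@grid$BER >= 0 & cv@grid$BER <= 1))
    expect_true(all(cv@grid$OER >= 0 & cv@grid$OER <= 1))
    # the chosen configuration attains the grid-minimum BER
    expect_equal(cv@best$BER, min(cv@grid$BER))
    # bit-reproducible under a fixed seed
    cv2 <- crossValidate(X, y, ncompGrid = 1:2, keepXGrid = c(2, 6),
                         folds = 5, repeats = 2, seed = 3)
    expect_identical(cv@grid, cv2@grid)
    # class smaller than the fold count is refused with advice
    ySmall <- factor(c(rep("a", 3), rep("b", 20)))
    expect_error(crossValidate(matrix(rnorm(46), 23, 2), ySmall,
                               folds = 5), "fewer folds")
})

test_that("BER is near 0.5 under permuted balanced labels", {
    bers <- vapply(1:20, function(s) {
        set.seed(s)
        X <- matrix(rnorm(40 * 6), 40, 6)
        y <- factor(sample(rep(c("a", "b"), 20)))
        cv <- crossValidate(X, y, ncompGrid = 1, keepXGrid = 6,
                            folds = 4, repeats = 1, seed = s,
                            distances = "centroid")
        cv@grid$BER
    }, numeric(1))
    expect_gt(mean(bers), 0.4)
    expect_lt(mean(bers), 0.6)
})

test_that("holdout evaluation splits stratified 70/30 and refuses bad splits", {
    set.seed(15)
    y <- factor(rep(c("a", "b", "c"), each = 20))
    X <- matrix(rnorm(60 * 5, sd = 0.3), 60, 5)
    X[, 1] <- X[, 1] + 3 * (y == "a")
    X[, 2] <- X[, 2] + 3 * (y == "b")
    ev <- evaluateHoldout(X, y, ncomp = 2, seed = 2)
    expect_length(ev$testIndex, 18)  # 30% of each class
    expect_equal(unname(rowSums(ev$report@confusion)), c(6, 6, 6))
    expect_gt(ev$report@accuracy, 0.9)
    yBad <- factor(c("a", rep("b", 19)), levels = c("a", "b"))
    expect_error(evaluateHoldout(matrix(rnorm(40), 20, 2), yBad),
                 "split|absent")
})

test_that("sparse tuning recovers the informative rearing-system markers", {
    info <- informativeElements()
    hits <- vapply(1:20, function(s) {
        ee <- substituteNondetects(generateEggData(syntheticConfig(
            nEggs = c(home = 25, commercial = 12), seed = 100 + s)))
        fit <- plsdaFit(ee, "system", ncomp = 3, keepX = c(6, 6, 6))
        sel <- selectedVariables(fit)
        mean(sel %in% info) >= 0.5
    }, logical(1))
    expect_gte(sum(hits), 10)  # at least half the runs
})
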