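#' Fit a (sparse) PLS-DA model
#'
#' Partial least squares discriminant analysis regresses the auto-scaled
#' predictor matrix X on the centred one-hot class indicator matrix Y,
#' extracting latent components that maximise covariance with the class
#' structure (NIPALS). The sparse variant restricts each component's
#' X-weight vector to its `keepX` largest-magnitude entries by
#' soft-thresholding at the (keepX+1)-th largest absolute weight, then
#' renormalising — e.g. weights (0.9, 0.5, 0.1) with keepX = 2 become
#' (0.8, 0.4, 0) before unit-norm scaling. After each component, X is
#' deflated by regression on the component score; Y is not deflated
#' (prediction uses the accumulated regression coefficients, which is
#' algebraically equivalent).
#'
#' @param x numeric samples x variables matrix, or an
#'   [ElementExperiment-class] (then `y` may name a metadata column).
#' @param y factor of class labels (>= 2 classes, all levels present), or
#'   `"egg_part"` / `"system"` when `x` is an `ElementExperiment`.
#' @param ncomp number of latent components, at most `min(n - 1, p)`.
#' @param keepX integer vector of per-component selection budgets in
#'   `[1, p]`, recycled to length `ncomp`; `NULL` keeps all variables
#'   (ordinary PLS-DA).
#' @param maxIter,tol NIPALS iteration controls.
#' @return A [PLSDAModel-class]. Score columns are mutually orthogonal and
#'   each weight column has unit norm and at most `keepX` nonzero entries.
#' @examples
#' X <- matrix(rnorm(60 * 5), 60, 5)
#' y <- factor(rep(c("a", "b", "c"), each = 20))
#' X[, 1] <- X[, 1] + 3 * (y == "a")
#' fit <- plsdaFit(X, y, ncomp = 2, keepX = c(2, 2))
#' selectedVariables(fit)
#' @export
plsdaFit <- function(x, y, ncomp = 2, keepX = NULL,
                     maxIter = 500, tol = 1e-09) {
    prep <- .plsdaInputs(x, y)
    X <- prep$X; y <- prep$y
    n <- nrow(X); p <- ncol(X)
    ncomp <- as.integer(ncomp)
    if (nlevels(y) < 2) stop("need at least 2 classes")
    if (!all(levels(y) %in% y))
        stop("class(es) absent from y: ",
             paste(setdiff(levels(y), unique(y)), collapse = ", "))
    if (ncomp > min(n - 1L, p))
        stop("ncomp = ", ncomp, " exceeds min(n - 1, p) = ", min(n - 1L, p))
    if (is.null(keepX)) keepX <- rep(p, ncomp)
    keepX <- as.integer(rep(keepX, length.out = ncomp))
    if (any(keepX < 1L | keepX > p))
        stop("keepX entries must lie in [1, ", p, "]")

    sc <- .scaleTrain(X)
    E <- sc$X
    Y <- .classDummy(y)
    yCenter <- colMeans(Y)
    Yc <- sweep(Y, 2, yCenter)
    K <- ncol(Yc)

    W <- matrix(0, p, ncomp, dimnames = list(colnames(X), NULL))
    P <- matrix(0, p, ncomp, dimnames = list(colnames(X), NULL))
    Tm <- matrix(0, n, ncomp, dimnames = list(rownames(X), NULL))
    C <- matrix(0, K, ncomp, dimnames = list(colnames(Yc), NULL))
    for (h in seq_len(ncomp)) {
        u <- Yc[, which.max(colSums(Yc^2))]
        w <- rep(0, p)
        for (it in seq_len(maxIter)) {
            wOld <- w
            w <- crossprod(E, u)[, 1]
            w <- .keepXThreshold(w, keepX[h])
            tt <- E %*% w
            cc <- crossprod(Yc, tt)[, 1] / sum(tt^2)
            u <- (Yc %*% cc)[, 1] / sum(cc^2)
            if (sqrt(sum((w - wOld)^2)) < tol) break
        }
        # deterministic sign: largest-|w| entry positive
        i <- which.max(abs(w))
        if (w[i] < 0) { w <- -w; tt <- -tt; cc <- -cc }
        ph <- crossprod(E, tt)[, 1] / sum(tt^2)
        E <- E - tcrossprod(tt[, 1], ph)
        W[, h] <- w; P[, h] <- ph; Tm[, h] <- tt; C[, h] <- cc
    }
    cent <- .classCentroids(Tm, y)
    new("PLSDAModel", ncomp = ncomp, keepX = keepX,
        weights = W, loadingsX = P, scoresX = Tm, coeffY = C,
        centroids = cent$centroids, withinCov = cent$withinCov,
        classes = levels(y), y = y,
        xCenter = sc$center, xScale = sc$scale, yCenter = yCenter)
}

# soft-threshold w at the (keepX+1)-th largest |w|, unit-normalise
.keepXThreshold <- function(w, keepX) {
    p <- length(w)
    if (keepX < p) {
        ord <- order(abs(w), decreasing = TRUE)
        drop <- ord[(keepX + 1):p]
        lambda <- max(abs(w[drop]))
        w <- sign(w) * pmax(abs(w) - lambda, 0)
    }
    nrm <- sqrt(sum(w^2))
    if (nrm < .Machine$double.eps)
        stop("degenerate weight vector (all-zero after thresholding)")
    w / nrm
}

.scaleTrain <- function(X) {
    ctr <- colMeans(X)
    Xc <- sweep(X, 2, ctr)
    sds <- apply(Xc, 2, sd)
    if (any(sds == 0))
        stop("zero-variance column(s): ",
             paste(colnames(X)[sds == 0], collapse = ", "))
    list(X = sweep(Xc, 2, sds, "/"), center = ctr, scale = sds)
}

.classDummy <- function(y) {
    Y <- matrix(0, length(y), nlevels(y),
                dimnames = list(NULL, levels(y)))
    Y[cbind(seq_along(y), as.integer(y))] <- 1
    Y
}

.classCentroids <- function(Tm, y) {
    K <- nlevels(y); H <- ncol(Tm)
    cent <- matrix(0, K, H, dimnames = list(levels(y), colnames(Tm)))
    Sw <- matrix(0, H, H)
    for (g in levels(y)) {
        Tg <- Tm[y == g, , drop = FALSE]
        cent[g, ] <- colMeans(Tg)
        Sw <- Sw + crossprod(sweep(Tg, 2, cent[g, ]))
    }
    Sw <- Sw / (nrow(Tm) - K)
    list(centroids = cent, withinCov = Sw)
}

.plsdaInputs <- function(x, y) {
    if (is(x, "ElementExperiment")) {
        if (is.character(y) && length(y) == 1) {
            y <- switch(y, egg_part = eggPart(x), system = rearingSystem(x),
                        stop("unknown target '", y,
                             "'; use 'egg_part' or 'system'"))
        }
        x <- concentrations(x, samplesInRows = TRUE)
    }
    X <- as.matrix(x)
    if (is.null(colnames(X))) colnames(X) <- paste0("v", seq_len(ncol(X)))
    if (is.null(rownames(X))) rownames(X) <- paste0("s", seq_len(nrow(X)))
    if (anyNA(X)) stop("predictor matrix contains NA")
    y <- as.factor(y)
    if (length(y) != nrow(X)) stop("length(y) must equal nrow(x)")
    list(X = X, y = y)
}

#' Predict classes from a fitted PLS-DA model
#'
#' Projects new samples into the latent score space (using the accumulated
#' weight/loading transformation `W (P'W)^-1`) and assigns classes by one
#' of three rules: `"max"`, the argmax of the predicted class-indicator
#' response; `"centroid"`, the nearest training-class centroid in score
#' space (Euclidean); `"mahalanobis"`, the nearest centroid under the
#' pooled within-class score covariance. Exact ties are broken toward the
#' first class in level order, with a warning.
#'
#' @param model a [PLSDAModel-class].
#' @param xnew numeric matrix (samples x variables) or
#'   [ElementExperiment-class]; columns must match the training variables.
#' @param distance `"max"`, `"centroid"` or `"mahalanobis"`.
#' @param comps number of leading components to use (default: all fitted).
#' @return A list with `class` (factor of predictions), `scores` (latent
#'   projections) and `response` (predicted dummy values).
#' @export
plsdaPredict <- function(model, xnew,
                         distance = c("max", "centroid", "mahalanobis"),
                         comps = model@ncomp) {
    distance <- match.arg(distance)
    if (is(xnew, "ElementExperiment"))
        xnew <- concentrations(xnew, samplesInRows = TRUE)
    xnew <- as.matrix(xnew)
    vars <- rownames(model@weights)
    if (!is.null(colnames(xnew))) {
        missing <- setdiff(vars, colnames(xnew))
        extra <- setdiff(colnames(xnew), vars)
        if (length(missing) || length(extra))
            stop("variable mismatch; missing: ",
                 paste(missing, collapse = ", "), "; extra: ",
                 paste(extra, collapse = ", "))
        xnew <- xnew[, vars, drop = FALSE]
    } else if (ncol(xnew) != length(vars))
        stop("xnew has ", ncol(xnew), " columns; model expects ",
             length(vars))
    comps <- as.integer(comps)
    stopifnot(comps >= 1, comps <= model@ncomp)
    h <- seq_len(comps)
    Xs <- sweep(sweep(xnew, 2, model@xCenter), 2, model@xScale, "/")
    R <- model@weights[, h, drop = FALSE] %*%
        solve(crossprod(model@loadingsX[, h, drop = FALSE],
                        model@weights[, h, drop = FALSE]))
    Tn <- Xs %*% R
    Yhat <- Tn %*% t(model@coeffY[, h, drop = FALSE])
    Yhat <- sweep(Yhat, 2, model@yCenter, "+")
    colnames(Yhat) <- model@classes

    distMat <- switch(distance,
        max = -Yhat,
        centroid = {
            ctr <- model@centroids[, h, drop = FALSE]
            t(apply(Tn, 1, function(t0)
                colSums((t(ctr) - t0)^2)))
        },
        mahalanobis = {
            ctr <- model@centroids[, h, drop = FALSE]
            Swi <- solve(model@withinCov[h, h, drop = FALSE])
            t(apply(Tn, 1, function(t0) {
                d <- sweep(ctr, 2, t0)
                rowSums((d %*% Swi) * d)
            }))
        })
    distMat <- matrix(distMat, nrow = nrow(Tn),
                      dimnames = list(rownames(xnew), model@classes))
    idx <- integer(nrow(distMat)); tie <- FALSE
    for (i in seq_len(nrow(distMat))) {
        v <- distMat[i, ]
        j <- which(v <= min(v) + 1e-12 * max(1, abs(min(v))))
        if (length(j) > 1) tie <- TRUE
        idx[i] <- j[1]
    }
    if (tie)
        warning("tied class distances; broke tie(s) by class order")
    list(class = factor(model@classes[idx], levels = model@classes),
         scores = Tn, response = Yhat)
}
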