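#' Principal component analysis of an element matrix
#'
#' Fits a PCA by singular value decomposition of the column-centred (and,
#' by default, unit-variance scaled) sample x element matrix — the usual
#' auto-scaling for mixed-magnitude element data. Eigenvalues are the
#' score variances (divisor n - 1); loadings are unit-norm; the sign of
#' each component is fixed so its largest-magnitude loading is positive,
#' making outputs deterministic. Variable contributions to dimension k are
#' `100 * coord_jk^2 / sum_j coord_jk^2` (equivalently `100 * loading^2`),
#' and variable coordinates are the loadings scaled by the component
#' standard deviation — correlations of variable and component when the
#' input is standardised.
#'
#' @param x an [ElementExperiment-class] (must have no remaining non-detect
#'   flags) or a numeric samples x variables matrix.
#' @param center,scale logical; centre and/or auto-scale columns. A
#'   zero-variance column with `scale = TRUE` is an error naming the
#'   column.
#' @param ncomp number of dimensions to keep (default: all).
#' @return A [PCAModel-class].
#' @examples
#' X <- matrix(rnorm(200), 40, 5)
#' fit <- pcaFit(X)
#' varExplained(fit)
#' @export
pcaFit <- function(x, center = TRUE, scale = TRUE, ncomp = NULL) {
    X <- .asSampleMatrix(x)
    if (nrow(X) < 2 || ncol(X) < 2)
        stop("PCA needs at least 2 samples and 2 variables")
    if (anyNA(X))
        stop("matrix contains NA; resolve non-detects first ",
             "(see substituteNondetects)")
    ctr <- if (center) colMeans(X) else rep(0, ncol(X))
    Xc <- sweep(X, 2, ctr)
    if (scale) {
        sds <- apply(Xc, 2, sd)
        if (any(sds == 0))
            stop("zero-variance column(s) cannot be scaled: ",
                 paste(colnames(X)[sds == 0], collapse = ", "))
    } else sds <- rep(1, ncol(X))
    Xs <- sweep(Xc, 2, sds, "/")
    k <- min(nrow(X) - 1L, ncol(X))
    if (!is.null(ncomp)) k <- min(k, as.integer(ncomp))
    sv <- svd(Xs, nu = k, nv = k)
    d <- sv$d[seq_len(k)]
    load <- sv$v
    # sign convention: largest-|loading| entry per component positive
    flip <- vapply(seq_len(k), function(j) {
        i <- which.max(abs(load[, j]))
        if (load[i, j] < 0) -1 else 1
    }, numeric(1))
    load <- sweep(load, 2, flip, "*")
    scoresM <- sweep(sv$u, 2, d * flip, "*")
    eig <- sv$d^2 / (nrow(X) - 1)
    totVar <- sum(apply(Xs, 2, var))
    dn <- paste0("Dim", seq_len(k))
    dimnames(load) <- list(colnames(X), dn)
    dimnames(scoresM) <- list(rownames(X), dn)
    contrib <- 100 * load^2
    contrib <- sweep(contrib, 2, colSums(contrib), "/") * 100
    coords <- sweep(load, 2, sqrt(eig[seq_len(k)]), "*")
    new("PCAModel",
        eigenvalues = eig[seq_len(k)],
        scores = scoresM, loadings = load,
        varExplained = 100 * eig[seq_len(k)] / totVar,
        contributions = contrib, varCoords = coords,
        center = ctr, scale = sds)
}

.asSampleMatrix <- function(x) {
    if (is(x, "ElementExperiment")) {
        if (any(isNonDetect(x)))
            stop("table still carries non-detect flags; apply ",
                 "substituteNondetects() first")
        concentrations(x, samplesInRows = TRUE)
    } else {
        m <- as.matrix(x)
        if (is.null(rownames(m)))
            rownames(m) <- paste0("s", seq_len(nrow(m)))
        if (is.null(colnames(m)))
            colnames(m) <- paste0("v", seq_len(ncol(m)))
        m
    }
}

#' Variable contributions to principal components
#'
#' Percent contribution of every variable to each dimension; each column
#' sums to 100. `topContributions()` returns the ranked top-N table for one
#' dimension together with the expected-average reference value `100 / p`
#' (the contribution every variable would have if all contributed equally).
#'
#' @param model a [PCAModel-class].
#' @return `variableContributions()`: variables x dimensions matrix of
#'   percentages. `topContributions()`: data.frame `variable`,
#'   `contribution`, with attribute `reference`.
#' @export
variableContributions <- function(model) model@contributions

#' @rdname variableContributions
#' @param dim dimension index.
#' @param n number of top variables to keep.
#' @export
topContributions <- function(model, dim = 1, n = 20) {
    con <- model@contributions[, dim]
    ord <- order(con, decreasing = TRUE)[seq_len(min(n, length(con)))]
    out <- data.frame(variable = names(con)[ord],
                      contribution = unname(con[ord]),
                      stringsAsFactors = FALSE)
    attr(out, "reference") <- 100 / nrow(model@contributions)
    out
}

#' Flag outliers by Mahalanobis distance in score space
#'
#' Computes the squared Mahalanobis distance of each sample on the first
#' `dims` score dimensions (score columns are uncorrelated with variance
#' equal to the eigenvalue, so the statistic is the sum of squared
#' standardised scores) and flags samples beyond the chi-square(`dims`)
#' quantile. This makes the visual trimming step of exploratory PCA
#' explicit, automatic and deterministic.
#'
#' @param model a [PCAModel-class].
#' @param dims number of leading dimensions to use (default 2).
#' @param quantile chi-square probability cutoff in (0, 1), default 0.999.
#' @return An [OutlierReport-class].
#' @export
flagOutliers <- function(model, dims = 2, quantile = 0.999) {
    if (quantile <= 0 || quantile >= 1)
        stop("'quantile' must lie strictly inside (0, 1)")
    dims <- as.integer(dims)
    if (dims > ncol(model@scores))
        stop("'dims' exceeds the number of fitted dimensions")
    sc <- model@scores[, seq_len(dims), drop = FALSE]
    d2 <- rowSums(sweep(sc, 2, sqrt(model@eigenvalues[seq_len(dims)]),
                        "/")^2)
    cutoff <- qchisq(quantile, df = dims)
    flagged <- names(d2)[d2 > cutoff]
    if (is.null(flagged)) flagged <- as.character(which(d2 > cutoff))
    new("OutlierReport", flagged = flagged, statistic = d2,
        cutoff = cutoff, dims = dims, quantile = quantile)
}

#' Remove flagged samples from an ElementExperiment
#'
#' Convenience subset dropping the samples named in an outlier report, for
#' the trim-and-refit pattern.
#'
#' @param x an [ElementExperiment-class] or matrix with rownames.
#' @param report an [OutlierReport-class].
#' @return `x` without the flagged samples.
#' @export
removeOutliers <- function(x, report) {
    if (is(x, "ElementExperiment")) x[, !colnames(x) %in% report@flagged]
    else x[!rownames(x) %in% report@flagged, , drop = FALSE]
}
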