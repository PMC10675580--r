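#' Classification error rates
#'
#' `overallErrorRate()` is the plain misclassification fraction;
#' `balancedErrorRate()` is the unweighted mean of the per-class error
#' rates, insensitive to class imbalance.
#'
#' @param truth,pred factors (or vectors coercible to factor) of true and
#'   predicted labels.
#' @return A number in `[0, 1]`.
#' @export
balancedErrorRate <- function(truth, pred) {
    truth <- as.factor(truth)
    perClass <- vapply(levels(truth), function(g)
        mean(pred[truth == g] != g), numeric(1))
    mean(perClass)
}

#' @rdname balancedErrorRate
#' @export
overallErrorRate <- function(truth, pred) mean(as.character(pred) != as.character(truth))

#' Build a classification report from labels or a confusion matrix
#'
#' Accuracy is `trace / total`. For two classes, sensitivity and
#' specificity are the recalls of the first and second class respectively;
#' for more classes both are macro-averaged (sensitivity: mean per-class
#' recall; specificity: mean per-class true-negative rate).
#'
#' @param truth,pred label vectors (rows of the confusion matrix are
#'   truth), or
#' @param confusion a square confusion matrix (rows = truth) given instead
#'   of labels.
#' @return A [ClassificationReport-class].
#' @examples
#' classificationReport(confusion = matrix(c(8, 3, 2, 17), 2))
#' @export
classificationReport <- function(truth = NULL, pred = NULL,
                                 confusion = NULL) {
    if (is.null(confusion)) {
        truth <- as.factor(truth)
        pred <- factor(as.character(pred), levels = levels(truth))
        confusion <- table(truth = truth, pred = pred)
        confusion <- matrix(confusion, nrow = nlevels(truth),
                            dimnames = dimnames(confusion))
    }
    confusion <- as.matrix(confusion)
    if (is.null(rownames(confusion)))
        dimnames(confusion) <- list(paste0("c", seq_len(nrow(confusion))),
                                    paste0("c", seq_len(nrow(confusion))))
    total <- sum(confusion)
    acc <- sum(diag(confusion)) / total
    rowS <- rowSums(confusion); colS <- colSums(confusion)
    recall <- diag(confusion) / rowS
    tn <- total - rowS - colS + diag(confusion)
    fp <- colS - diag(confusion)
    specPer <- tn / (tn + fp)
    K <- nrow(confusion)
    if (K == 2) { sens <- recall[1]; spec <- recall[2] }
    else { sens <- mean(recall); spec <- mean(specPer) }
    perClass <- data.frame(class = rownames(confusion), n = as.numeric(rowS),
                           recall = as.numeric(recall),
                           specificity = as.numeric(specPer),
                           row.names = NULL, stringsAsFactors = FALSE)
    new("ClassificationReport", confusion = confusion,
        accuracy = acc, sensitivity = unname(sens),
        specificity = unname(spec), perClass = perClass)
}

# stratified fold labels, one draw from the current RNG stream
.stratifiedFolds <- function(y, folds) {
    f <- integer(length(y))
    for (g in levels(y)) {
        idx <- sample(which(y == g))
        f[idx] <- rep(seq_len(folds), length.out = length(idx))
    }
    f
}

#' Repeated stratified cross-validation of sparse PLS-DA
#'
#' Tunes (ncomp, keepX, distance) on a grid by stratified k-fold
#' cross-validation repeated several times. Scaling and variable selection
#' are refitted inside every training fold, so no information leaks from
#' the held-out fold. OER and BER are computed per repeat (each sample
#' predicted exactly once per repeat) and averaged over repeats. The chosen
#' configuration attains the grid-minimum mean BER; ties are broken toward
#' fewer components, then smaller keepX, then distance order — the most
#' parsimonious of the equally good models.
#'
#' @param x,y as in [plsdaFit()].
#' @param ncompGrid integer vector of component counts to evaluate.
#' @param keepXGrid integer vector of per-component selection budgets
#'   (applied to all components of a model).
#' @param folds,repeats cross-validation design; every class must have at
#'   least `folds` members.
#' @param seed integer seed making the fold draws reproducible.
#' @param distances subset of `c("max", "centroid", "mahalanobis")`.
#' @return A [CVResult-class].
#' @export
crossValidate <- function(x, y, ncompGrid = 1:3,
                          keepXGrid = c(1:10, 15, 17, 20, 30, 50),
                          folds = 5, repeats = 10, seed = 1,
                          distances = c("max", "centroid", "mahalanobis")) {
    prep <- .plsdaInputs(x, y)
    X <- prep$X; y <- prep$y
    folds <- as.integer(folds); repeats <- as.integer(repeats)
    if (folds < 2) stop("folds must be >= 2")
    small <- table(y) < folds
    if (any(small))
        stop("class(es) smaller than the fold count: ",
             paste(names(which(small)), collapse = ", "),
             "; use fewer folds")
    p <- ncol(X)
    keepXGrid <- sort(unique(pmin(as.integer(keepXGrid), p)))
    ncompGrid <- sort(unique(as.integer(ncompGrid)))
    hmax <- max(ncompGrid)
    distances <- match.arg(distances, several.ok = TRUE)

    dims <- c(length(ncompGrid), length(keepXGrid), length(distances),
              repeats)
    oer <- array(NA_real_, dims)
    ber <- array(NA_real_, dims)
    set.seed(seed)
    for (r in seq_len(repeats)) {
        foldId <- .stratifiedFolds(y, folds)
        predArr <- array(NA_integer_,
                         c(length(y), dims[1], dims[2], dims[3]))
        for (f in seq_len(folds)) {
            test <- foldId == f
            for (ki in seq_along(keepXGrid)) {
                fit <- plsdaFit(X[!test, , drop = FALSE], y[!test],
                                ncomp = hmax, keepX = keepXGrid[ki])
                for (hi in seq_along(ncompGrid)) for (di in seq_along(distances)) {
                    pr <- suppressWarnings(plsdaPredict(
                        fit, X[test, , drop = FALSE],
                        distance = distances[di], comps = ncompGrid[hi]))
                    predArr[test, hi, ki, di] <- as.integer(pr$class)
                }
            }
        }
        for (hi in seq_along(ncompGrid))
            for (ki in seq_along(keepXGrid))
                for (di in seq_along(distances)) {
                    pred <- factor(levels(y)[predArr[, hi, ki, di]],
                                   levels = levels(y))
                    oer[hi, ki, di, r] <- overallErrorRate(y, pred)
                    ber[hi, ki, di, r] <- balancedErrorRate(y, pred)
                }
    }
    grid <- expand.grid(ncomp = ncompGrid, keepX = keepXGrid,
                        distance = distances, stringsAsFactors = FALSE)
    grid$OER <- as.vector(apply(oer, 1:3, mean))
    grid$BER <- as.vector(apply(ber, 1:3, mean))
    grid$BER_sd <- as.vector(apply(ber, 1:3, sd))
    ord <- order(grid$BER, grid$ncomp, grid$keepX,
                 match(grid$distance, distances))
    best <- as.list(grid[ord[1], c("ncomp", "keepX", "distance",
                                   "OER", "BER")])
    new("CVResult", grid = grid, best = best, folds = folds,
        repeats = repeats, seed = as.integer(seed))
}

# stratified train indices for a train_frac split
.stratifiedSplit <- function(y, trainFrac) {
    train <- integer(0)
    for (g in levels(y)) {
        idx <- sample(which(y == g))
        nTr <- floor(trainFrac * length(idx))
        if (nTr < 1 || nTr >= length(idx))
            stop("class '", g, "' cannot be split at trainFrac = ",
                 trainFrac)
        train <- c(train, idx[seq_len(nTr)])
    }
    sort(train)
}

#' Held-out evaluation of a tuned sparse PLS-DA configuration
#'
#' Shuffles and splits the data into stratified training and test
#' fractions, fits the model configuration on the training part only, and
#' reports test-set performance.
#'
#' @param x,y as in [plsdaFit()].
#' @param ncomp,keepX model configuration (see [plsdaFit()]).
#' @param distance prediction rule (see [plsdaPredict()]).
#' @param trainFrac training fraction (default 0.7, i.e. a 70/30 split).
#' @param seed integer seed for the shuffle.
#' @return A list with `report` (a [ClassificationReport-class]), `model`
#'   (the training fit), `testIndex`, and `predictions`.
#' @export
evaluateHoldout <- function(x, y, ncomp = 2, keepX = NULL,
                            distance = c("centroid", "max", "mahalanobis"),
                            trainFrac = 0.7, seed = 1) {
    distance <- match.arg(distance)
    prep <- .plsdaInputs(x, y)
    X <- prep$X; y <- prep$y
    set.seed(seed)
    train <- .stratifiedSplit(y, trainFrac)
    test <- setdiff(seq_along(y), train)
    if (!all(levels(y) %in% y[train]) || !all(levels(y) %in% y[test]))
        stop("a class is absent from the train or test split")
    fit <- plsdaFit(X[train, , drop = FALSE], y[train], ncomp = ncomp,
                    keepX = keepX)
    pr <- plsdaPredict(fit, X[test, , drop = FALSE], distance = distance)
    list(report = classificationReport(y[test], pr$class), model = fit,
         testIndex = test, predictions = pr$class)
}
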