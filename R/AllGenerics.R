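#' Accessors for ovorisk objects
#'
#' `concentrations()` returns the element x sample concentration matrix,
#' `isNonDetect()` the logical non-detect mask, `eggPart()`,
#' `rearingSystem()` and `sampleIds()` the sample metadata. `scores()`,
#' `loadingWeights()`, `eigenvalues()`, `varExplained()` and
#' `selectedVariables()` access fitted latent-variable models.
#'
#' @param x an object of the documented class.
#' @param ... further arguments for methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("concentrations", function(x, ...) standardGeneric("concentrations"))

#' @rdname accessors
#' @export
setGeneric("isNonDetect", function(x) standardGeneric("isNonDetect"))

#' @rdname accessors
#' @export
setGeneric("eggPart", function(x) standardGeneric("eggPart"))

#' @rdname accessors
#' @export
setGeneric("rearingSystem", function(x) standardGeneric("rearingSystem"))

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setGeneric("scores", function(x, ...) standardGeneric("scores"))

#' @rdname accessors
#' @export
setGeneric("loadingWeights", function(x, ...) standardGeneric("loadingWeights"))

#' @rdname accessors
#' @export
setGeneric("eigenvalues", function(x) standardGeneric("eigenvalues"))

#' @rdname accessors
#' @export
setGeneric("varExplained", function(x) standardGeneric("varExplained"))

#' @rdname accessors
#' @export
setGeneric("selectedVariables", function(x, ...) standardGeneric("selectedVariables"))

# ---- ElementExperiment methods ------------------------------------------

#' @describeIn accessors concentration matrix (elements x samples); set
#'   `samplesInRows = TRUE` for the transposed samples x elements layout used
#'   by the chemometric fits.
#' @param samplesInRows logical; transpose to samples x elements.
#' @export
setMethod("concentrations", "ElementExperiment",
    function(x, samplesInRows = FALSE) {
        m <- assay(x, "conc")
        if (samplesInRows) t(m) else m
    })

#' @describeIn accessors logical non-detect mask, elements x samples.
#' @export
setMethod("isNonDetect", "ElementExperiment",
    function(x) assay(x, "nd"))

#' @describeIn accessors factor of egg parts per sample.
#' @export
setMethod("eggPart", "ElementExperiment",
    function(x) colData(x)$egg_part)

#' @describeIn accessors factor of rearing systems per sample.
#' @export
setMethod("rearingSystem", "ElementExperiment",
    function(x) colData(x)$system)

#' @describeIn accessors character vector of egg identifiers per sample.
#' @export
setMethod("sampleIds", "ElementExperiment",
    function(x) colData(x)$sample_id)

setMethod("show", "ElementExperiment", function(object) {
    cat("ElementExperiment:", nrow(object), "elements x", ncol(object),
        "samples\n")
    cat("  parts:  ", paste(sprintf("%s=%d", levels(eggPart(object)),
        table(eggPart(object))), collapse = " "), "\n")
    cat("  systems:", paste(sprintf("%s=%d", levels(rearingSystem(object)),
        table(rearingSystem(object))), collapse = " "), "\n")
    nd <- sum(isNonDetect(object))
    cat("  non-detect cells:", nd,
        sprintf("(%.2f%%)\n", 100 * nd / length(isNonDetect(object))))
})

# ---- model accessors ----------------------------------------------------

#' @describeIn accessors sample scores of a fitted PCA.
#' @export
setMethod("scores", "PCAModel", function(x, ...) x@scores)

#' @describeIn accessors unit-norm loadings of a fitted PCA.
#' @export
setMethod("loadingWeights", "PCAModel", function(x, ...) x@loadings)

#' @describeIn accessors eigenvalues (score variances) of a fitted PCA.
#' @export
setMethod("eigenvalues", "PCAModel", function(x) x@eigenvalues)

#' @describeIn accessors percent variance explained per PCA dimension.
#' @export
setMethod("varExplained", "PCAModel", function(x) x@varExplained)

#' @describeIn accessors latent-component sample scores of a PLS-DA fit.
#' @export
setMethod("scores", "PLSDAModel", function(x, ...) x@scoresX)

#' @describeIn accessors X-weight vectors of a PLS-DA fit (variables x
#'   components; zero rows were dropped by keepX selection).
#' @export
setMethod("loadingWeights", "PLSDAModel", function(x, ...) x@weights)

#' @describeIn accessors variables with a nonzero weight on any (or a given)
#'   component of a sparse PLS-DA fit.
#' @param comp optional component index.
#' @export
setMethod("selectedVariables", "PLSDAModel", function(x, comp = NULL) {
    w <- x@weights
    if (!is.null(comp)) w <- w[, comp, drop = FALSE]
    rownames(w)[rowSums(abs(w) > 0) > 0]
})

setMethod("show", "PCAModel", function(object) {
    k <- min(5L, length(object@eigenvalues))
    cat("PCAModel:", nrow(object@scores), "samples,",
        nrow(object@loadings), "variables\n")
    cat("  variance explained (%):",
        paste(sprintf("%.1f", object@varExplained[seq_len(k)]),
              collapse = ", "),
        if (length(object@eigenvalues) > k) "...\n" else "\n")
})

setMethod("show", "OutlierReport", function(object) {
    cat("OutlierReport:", length(object@flagged), "of",
        length(object@statistic), "samples flagged",
        sprintf("(Mahalanobis on %d dims, chi-square cutoff %.2f)\n",
                object@dims, object@cutoff))
    if (length(object@flagged))
        cat("  flagged:", paste(object@flagged, collapse = ", "), "\n")
})

setMethod("show", "PLSDAModel", function(object) {
    cat("PLSDAModel:", object@ncomp, "components,",
        length(object@classes), "classes (",
        paste(object@classes, collapse = ", "), ")\n")
    cat("  keepX:", paste(object@keepX, collapse = ", "),
        "| selected:", paste(selectedVariables(object), collapse = ", "),
        "\n")
})

setMethod("show", "CVResult", function(object) {
    cat("CVResult:", nrow(object@grid), "grid points,",
        object@folds, "folds x", object@repeats, "repeats\n")
    b <- object@best
    cat(sprintf("  best: ncomp=%d keepX=%d distance=%s BER=%.4f OER=%.4f\n",
                b$ncomp, b$keepX, b$distance, b$BER, b$OER))
})

setMethod("show", "ClassificationReport", function(object) {
    cat("ClassificationReport\n")
    print(object@confusion)
    cat(sprintf("  accuracy %.4f | sensitivity %.4f | specificity %.4f\n",
                object@accuracy, object@sensitivity, object@specificity))
})

setMethod("show", "THQReport", function(object) {
    cat("THQReport:", nrow(object@perEgg), "eggs,",
        length(object@metals), "metals (",
        paste(object@metals, collapse = ", "), ")\n")
    print(object@bySystem, row.names = FALSE)
    if (any(object@perEgg$risk))
        cat("  ", sum(object@perEgg$risk), "egg(s) exceed TTHQ = 1\n")
    else cat("  no egg exceeds TTHQ = 1\n")
})

setMethod("show", "SyntheticConfig", function(object) {
    cat("SyntheticConfig:",
        sprintf("%d home + %d commercial eggs (x3 parts), %d calibrated cells\n",
                object@nEggs[["home"]], object@nEggs[["commercial"]],
                nrow(object@calibration)))
    cat("  blocks:", length(object@blocks),
        "| marker shift:", object@markerShift, "SD | outliers:",
        object@outliers$n, "\n")
})
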