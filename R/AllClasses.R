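#' ElementExperiment: element concentrations for egg component samples
#'
#' An S4 container extending [SummarizedExperiment] for wide element
#' concentration data. Rows are elements of the 64-element panel
#' ([panelElements()]), columns are samples (one egg component each). Two
#' assays are carried: `"conc"`, concentrations in mg/kg dry weight (`NA`
#' where censored), and `"nd"`, a logical non-detect mask. Column metadata
#' holds `sample_id` (the egg), `egg_part` (`white`, `yolk` or `shell`) and
#' `system` (`home` or `commercial` rearing).
#'
#' @slot .. inherited from `SummarizedExperiment`.
#' @seealso [ElementExperiment()] for construction, [readElementTable()] for
#'   CSV import.
#' @export
setClass("ElementExperiment", contains = "SummarizedExperiment")

.EGG_PARTS <- c("white", "yolk", "shell")
.SYSTEMS <- c("home", "commercial")

setValidity("ElementExperiment", function(object) {
    msg <- character()
    cd <- colData(object)
    need <- c("sample_id", "egg_part", "system")
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
        return(paste("missing column metadata:", paste(miss, collapse = ", ")))
    if (!all(c("conc", "nd") %in% names(assays(object))))
        return("assays 'conc' and 'nd' are required")
    conc <- assay(object, "conc")
    nd <- assay(object, "nd")
    if (!is.logical(nd))
        msg <- c(msg, "'nd' assay must be logical")
    if (any(conc < 0, na.rm = TRUE))
        msg <- c(msg, "negative concentrations are not allowed")
    if (anyNA(cd$egg_part) || !all(cd$egg_part %in% .EGG_PARTS))
        msg <- c(msg, "egg_part must be one of white/yolk/shell, non-missing")
    if (anyNA(cd$system) || !all(cd$system %in% .SYSTEMS))
        msg <- c(msg, "system must be one of home/commercial, non-missing")
    if (anyDuplicated(paste(cd$sample_id, cd$egg_part)))
        msg <- c(msg, "duplicated (sample_id, egg_part) pair")
    unknown <- setdiff(rownames(object), panelElements())
    if (length(unknown))
        msg <- c(msg, paste("elements outside the declared panel:",
                            paste(unknown, collapse = ", ")))
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct an ElementExperiment
#'
#' @param conc numeric matrix of concentrations (mg/kg dry weight), elements
#'   in rows and samples in columns; `NA` entries are taken as non-detects
#'   unless `nd` is supplied.
#' @param eggPart character/factor of egg parts per sample
#'   (`white`/`yolk`/`shell`).
#' @param system character/factor of rearing systems per sample
#'   (`home`/`commercial`).
#' @param sampleId egg identifiers per sample; the pair (`sampleId`,
#'   `eggPart`) must be unique.
#' @param nd optional logical matrix flagging non-detect cells (same
#'   dimensions as `conc`).
#' @return An [ElementExperiment-class] object.
#' @examples
#' conc <- matrix(c(10266, 639, 3.8, 629, 176, 33.2), nrow = 3,
#'                dimnames = list(c("Na", "Mg", "Zn"), NULL))
#' ee <- ElementExperiment(conc, eggPart = c("white", "yolk"),
#'                         system = c("home", "home"),
#'                         sampleId = c("egg1", "egg1"))
#' ee
#' @export
ElementExperiment <- function(conc, eggPart, system, sampleId, nd = NULL) {
    conc <- as.matrix(conc)
    if (is.null(nd)) nd <- is.na(conc)
    storage.mode(conc) <- "double"
    if (is.null(colnames(conc)))
        colnames(conc) <- paste(sampleId, eggPart, sep = "_")
    dimnames(nd) <- dimnames(conc)
    cd <- DataFrame(
        sample_id = as.character(sampleId),
        egg_part = factor(as.character(eggPart), levels = .EGG_PARTS),
        system = factor(as.character(system), levels = .SYSTEMS),
        row.names = colnames(conc)
    )
    rd <- DataFrame(group = elementGroup(rownames(conc)),
                    row.names = rownames(conc))
    se <- SummarizedExperiment(assays = list(conc = conc, nd = nd),
                               colData = cd, rowData = rd)
    new("ElementExperiment", se)
}

# ---- downstream model classes -------------------------------------------

#' Fitted principal component model
#'
#' Holds the results of [pcaFit()]: eigenvalues (score variances), sample
#' scores, unit-norm variable loadings, percent variance explained, percent
#' variable contributions per dimension, and variable coordinates
#' (correlation-circle coordinates when the input was standardised).
#'
#' @export
setClass("PCAModel", representation(
    eigenvalues = "numeric", scores = "matrix", loadings = "matrix",
    varExplained = "numeric", contributions = "matrix", varCoords = "matrix",
    center = "numeric", scale = "numeric"
))

#' Outlier report from PCA score distances
#'
#' Result of [flagOutliers()]: squared Mahalanobis score distances per
#' sample, the chi-square cutoff used, and the flagged sample names.
#'
#' @export
setClass("OutlierReport", representation(
    flagged = "character", statistic = "numeric", cutoff = "numeric",
    dims = "integer", quantile = "numeric"
))

#' Fitted (sparse) PLS-DA model
#'
#' Result of [plsdaFit()]: NIPALS latent components of the auto-scaled
#' predictor matrix against the centred one-hot class matrix, with per
#' component keepX soft-threshold variable selection. Carries everything
#' needed for the three prediction distance rules: X-weights, X-loadings,
#' training scores, class-dummy regression coefficients, class centroids in
#' score space and the pooled within-class score covariance.
#'
#' @export
setClass("PLSDAModel", representation(
    ncomp = "integer", keepX = "integer",
    weights = "matrix", loadingsX = "matrix", scoresX = "matrix",
    coeffY = "matrix", centroids = "matrix", withinCov = "matrix",
    classes = "character", y = "factor",
    xCenter = "numeric", xScale = "numeric", yCenter = "numeric"
))

#' Cross-validation result grid
#'
#' Result of [crossValidate()]: overall (OER) and balanced (BER) error rates
#' for every (ncomp, keepX, distance) grid point, plus the chosen
#' configuration (grid-minimum BER; ties broken toward fewer components,
#' then smaller keepX, then distance order).
#'
#' @export
setClass("CVResult", representation(
    grid = "data.frame", best = "list",
    folds = "integer", repeats = "integer", seed = "integer"
))

#' Held-out classification report
#'
#' Result of [evaluateHoldout()] (or [classificationReport()]): confusion
#' matrix (rows = truth), accuracy, macro-averaged sensitivity and
#' specificity, and per-class rates.
#'
#' @export
setClass("ClassificationReport", representation(
    confusion = "matrix", accuracy = "numeric",
    sensitivity = "numeric", specificity = "numeric",
    perClass = "data.frame"
))

#' Per-sample and per-group THQ risk report
#'
#' Result of [riskByGroup()]: per-egg per-metal Target Hazard Quotients on
#' the edible fraction, the summed TTHQ with its `TTHQ > 1` risk flag, and
#' min/mean/max TTHQ summaries per rearing system.
#'
#' @export
setClass("THQReport", representation(
    perEgg = "data.frame", thq = "data.frame", bySystem = "data.frame",
    metals = "character", params = "list"
))

setValidity("THQReport", function(object) {
    pe <- object@perEgg
    if (nrow(pe)) {
        if (any(object@thq$THQ < 0)) return("negative THQ")
        if (!isTRUE(all.equal(pe$risk, pe$TTHQ > 1)))
            return("risk flag must equal TTHQ > 1")
    }
    TRUE
})

#' Synthetic egg-composition generator configuration
#'
#' See [syntheticConfig()] for construction and slot semantics.
#'
#' @export
setClass("SyntheticConfig", representation(
    nEggs = "integer", calibration = "data.frame", blocks = "list",
    markers = "data.frame", markerShift = "numeric",
    ndRate = "numeric", outliers = "list", seed = "integer"
))

setValidity("SyntheticConfig", function(object) {
    msg <- character()
    if (any(object@nEggs < 1)) msg <- c(msg, "nEggs must be >= 1 per system")
    if (!all(c("home", "commercial") %in% names(object@nEggs)))
        msg <- c(msg, "nEggs needs 'home' and 'commercial' entries")
    for (b in object@blocks) {
        if (abs(b$loading) > 1) msg <- c(msg, "|block loading| must be <= 1")
    }
    blockEls <- unlist(lapply(object@blocks, `[[`, "elements"))
    if (anyDuplicated(blockEls))
        msg <- c(msg, "an element may belong to at most one correlation block")
    if (any(object@ndRate < 0 | object@ndRate >= 1))
        msg <- c(msg, "ndRate must lie in [0, 1)")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})
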