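#' Convert acid-digest solution measurements to tissue concentrations
#'
#' An acid-digested sample measured at solution concentration \eqn{C_s}
#' (ug/L) in a digest volume \eqn{V_s} (L), prepared from a dry sample mass
#' \eqn{W_t} (g), corresponds to a tissue concentration
#' \deqn{C_t = C_s V_s / W_t}
#' in ug/g dry weight (numerically equal to mg/kg dry weight). Non-detect
#' measurements (`NA` in `solutionConc` or flagged in `nonDetect`) stay
#' non-detect (`NA`) after conversion.
#'
#' @param solutionConc numeric, solution concentration in ug/L; `NA` means
#'   non-detect.
#' @param volume numeric, digest solution volume in L (must be > 0).
#' @param dryMass numeric, dry sample mass in g (must be > 0).
#' @param nonDetect optional logical vector flagging non-detects.
#' @return Numeric vector of tissue concentrations in ug/g dry weight, `NA`
#'   where the input was non-detect.
#' @examples
#' convertConcentration(500, 0.05, 0.5)   # 50 ug/g
#' convertConcentration(1000, 0.05, 0.5)  # 100 ug/g (50 mL digest, 0.5 g)
#' @export
convertConcentration <- function(solutionConc, volume, dryMass,
                                 nonDetect = NULL) {
    if (any(!is.finite(volume)) || any(volume <= 0))
        stop("'volume' must be a positive digest volume in L")
    if (any(!is.finite(dryMass)) || any(dryMass <= 0))
        stop("'dryMass' must be a positive dry sample mass in g")
    if (any(solutionConc < 0, na.rm = TRUE))
        stop("'solutionConc' must be non-negative (NA marks non-detects)")
    out <- solutionConc * volume / dryMass
    if (!is.null(nonDetect)) out[nonDetect] <- NA_real_
    out
}

#' Read digestion records from CSV
#'
#' Expects columns `sample_id`, `solution_conc` (ug/L), `volume` (L) and
#' `dry_mass` (g); `ND` or empty `solution_conc` cells are parsed as
#' non-detects. `convertDigestion()` appends the converted `tissue_conc`
#' column (ug/g dry weight).
#'
#' @param path CSV file path.
#' @return A data.frame of validated digestion records.
#' @export
readDigestionRecords <- function(path) {
    df <- read.csv(path, stringsAsFactors = FALSE,
                   colClasses = "character", check.names = FALSE)
    need <- c("sample_id", "solution_conc", "volume", "dry_mass")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop("digestion records lack column(s): ", paste(miss, collapse = ", "))
    parsed <- .parseConcCells(df$solution_conc, "solution_conc")
    data.frame(
        sample_id = df$sample_id,
        solution_conc = parsed$value,
        non_detect = parsed$nd,
        volume = .parseNumeric(df$volume, "volume"),
        dry_mass = .parseNumeric(df$dry_mass, "dry_mass"),
        stringsAsFactors = FALSE
    )
}

#' @rdname readDigestionRecords
#' @param records data.frame as returned by [readDigestionRecords()].
#' @export
convertDigestion <- function(records) {
    records$tissue_conc <- convertConcentration(
        records$solution_conc, records$volume, records$dry_mass,
        nonDetect = records$non_detect)
    records
}

# Parse numeric cells strictly: "." decimal separator, no thousands
# separators (a cell like "15,373.56" is rejected, not silently mangled).
.parseNumeric <- function(x, what) {
    x <- trimws(x)
    if (any(grepl(",", x, fixed = TRUE)))
        stop("column '", what, "' contains ',' ",
             "(thousands separators are not supported; use plain numbers)")
    ok <- grepl("^-?[0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?$", x)
    if (!all(ok))
        stop("column '", what, "' has non-numeric cell(s): ",
             paste(unique(x[!ok])[1:min(3, sum(!ok))], collapse = ", "))
    as.numeric(x)
}

.parseConcCells <- function(x, what) {
    x <- trimws(x)
    nd <- x %in% c("ND", "nd", "", "NA")
    val <- rep(NA_real_, length(x))
    if (any(!nd)) val[!nd] <- .parseNumeric(x[!nd], what)
    if (any(val < 0, na.rm = TRUE))
        stop("column '", what, "' has negative concentration(s)")
    list(value = val, nd = nd)
}

#' Read a wide element table from CSV
#'
#' The expected layout has one row per sample with metadata columns
#' `sample_id`, `egg_part`, `system` followed by one column per panel
#' element, concentrations in mg/kg dry weight. Cells `ND` or empty are
#' parsed as non-detect flags; columns not in the 64-element panel are
#' dropped with a warning; missing metadata columns are an error. The
#' decimal separator is `"."` and thousands separators are rejected.
#'
#' @param path CSV file path.
#' @return An [ElementExperiment-class].
#' @seealso [writeElementTable()] for the inverse; the round trip preserves
#'   numeric values exactly.
#' @export
readElementTable <- function(path) {
    df <- read.csv(path, stringsAsFactors = FALSE,
                   colClasses = "character", check.names = FALSE)
    meta <- c("sample_id", "egg_part", "system")
    miss <- setdiff(meta, colnames(df))
    if (length(miss))
        stop("element table lacks metadata column(s): ",
             paste(miss, collapse = ", "))
    elemCols <- setdiff(colnames(df), meta)
    unknown <- setdiff(elemCols, panelElements())
    if (length(unknown)) {
        warning("ignoring column(s) outside the element panel: ",
                paste(unknown, collapse = ", "))
        elemCols <- setdiff(elemCols, unknown)
    }
    if (!length(elemCols)) stop("no element columns found")
    n <- nrow(df)
    conc <- matrix(NA_real_, length(elemCols), n,
                   dimnames = list(elemCols, NULL))
    nd <- matrix(FALSE, length(elemCols), n, dimnames = dimnames(conc))
    for (el in elemCols) {
        parsed <- .parseConcCells(df[[el]], el)
        conc[el, ] <- parsed$value
        nd[el, ] <- parsed$nd
    }
    ElementExperiment(conc, eggPart = df$egg_part, system = df$system,
                      sampleId = df$sample_id, nd = nd)
}

#' Write an ElementExperiment as a wide CSV
#'
#' Non-detect cells are written as `ND`; numeric cells use full (17
#' significant digit) precision so that a read/write/read round trip is
#' value-exact.
#'
#' @param x an [ElementExperiment-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeElementTable <- function(x, path) {
    conc <- concentrations(x)
    nd <- isNonDetect(x)
    cells <- matrix("", nrow(conc), ncol(conc))
    cells[!is.na(conc)] <- sprintf("%.17g", conc[!is.na(conc)])
    cells[nd] <- "ND"
    df <- data.frame(
        sample_id = sampleIds(x),
        egg_part = as.character(eggPart(x)),
        system = as.character(rearingSystem(x)),
        t(cells), check.names = FALSE, stringsAsFactors = FALSE
    )
    colnames(df)[-(1:3)] <- rownames(conc)
    write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Substitute non-detect cells
#'
#' Left-censored (non-detect) cells must be resolved before numeric
#' analysis. Policies: `"zero"` substitutes 0 (conservative under-count for
#' risk scoring, the package default there), `"half_lod"` substitutes half
#' the element's limit of detection, `"drop"` leaves the cell `NA` so it is
#' excluded from downstream summaries. All policies clear the non-detect
#' mask; the number of substituted cells per element is recorded in
#' `metadata(x)$nd_substitutions`.
#'
#' @param x an [ElementExperiment-class].
#' @param policy one of `"zero"`, `"half_lod"`, `"drop"`.
#' @param lod named numeric vector of per-element limits of detection
#'   (mg/kg dw); required for `policy = "half_lod"`.
#' @return An [ElementExperiment-class] with no non-detect flags.
#' @export
substituteNondetects <- function(x, policy = c("zero", "half_lod", "drop"),
                                 lod = NULL) {
    policy <- match.arg(policy)
    conc <- concentrations(x)
    nd <- isNonDetect(x)
    if (policy == "half_lod") {
        if (is.null(lod))
            stop("policy 'half_lod' requires a named 'lod' map")
        els <- rownames(conc)[rowSums(nd) > 0]
        miss <- setdiff(els, names(lod))
        if (length(miss))
            stop("no LOD supplied for element(s): ",
                 paste(miss, collapse = ", "))
    }
    conc[nd] <- switch(policy,
        zero = 0,
        half_lod = (lod[rownames(conc)] / 2)[row(conc)][nd],
        drop = NA_real_)
    out <- ElementExperiment(conc, eggPart = eggPart(x),
                             system = rearingSystem(x),
                             sampleId = sampleIds(x),
                             nd = matrix(FALSE, nrow(conc), ncol(conc)))
    metadata(out) <- metadata(x)
    metadata(out)$nd_substitutions <-
        list(policy = policy, n_per_element = rowSums(nd)[rowSums(nd) > 0])
    out
}

#' Per-element summary statistics by group
#'
#' Computes n, minimum, mean and maximum concentration per element within
#' groups defined by sample metadata (default: per egg part). Non-detect /
#' dropped cells (`NA`) are excluded from the statistics; an empty
#' (element, group) cell is reported as `NA`, not zero.
#'
#' @param x an [ElementExperiment-class].
#' @param by character vector of grouping variables among `"egg_part"`,
#'   `"system"`; use `character(0)` for a single overall group.
#' @return A data.frame with columns `element`, the grouping variables,
#'   `n`, `min`, `mean`, `max` (mg/kg dry weight).
#' @examples
#' ee <- generateEggData(syntheticConfig(nEggs = c(home = 5, commercial = 2)))
#' head(summarizeElements(ee, by = "egg_part"))
#' @export
summarizeElements <- function(x, by = "egg_part") {
    stopifnot(all(by %in% c("egg_part", "system")))
    conc <- concentrations(x)
    cd <- as.data.frame(colData(x))
    grp <- if (length(by)) interaction(cd[by], drop = FALSE, sep = ".")
           else factor(rep("all", ncol(conc)))
    levs <- levels(grp)
    out <- do.call(rbind, lapply(levs, function(g) {
        cols <- grp == g
        vals <- conc[, cols, drop = FALSE]
        n <- rowSums(!is.na(vals))
        mn <- suppressWarnings(apply(vals, 1, min, na.rm = TRUE))
        mx <- suppressWarnings(apply(vals, 1, max, na.rm = TRUE))
        av <- rowMeans(vals, na.rm = TRUE)
        mn[n == 0] <- NA_real_; mx[n == 0] <- NA_real_; av[n == 0] <- NA_real_
        res <- data.frame(element = rownames(conc), n = n, min = mn,
                          mean = av, max = mx, row.names = NULL)
        if (length(by)) {
            gparts <- strsplit(g, ".", fixed = TRUE)[[1]]
            for (i in seq_along(by)) res[[by[i]]] <- gparts[i]
            res <- res[c("element", by, "n", "min", "mean", "max")]
        }
        res
    }))
    rownames(out) <- NULL
    out
}
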