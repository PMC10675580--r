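#' Chronic dietary exposure parameters
#'
#' Parameters of the Target Hazard Quotient model for lifetime adult egg
#' consumption: exposure frequency `EF` (days/year), exposure duration `ED`
#' (years, the average adult lifetime), daily egg intake rate `IR`
#' (kg/person/day), body weight `BW` (kg) and averaging time `AT` (days).
#' With the defaults, `EF * ED / AT = 1` exactly, so the THQ reduces to
#' `C * IR / (BW * RfD)`.
#'
#' @param EF,ED,IR,BW,AT numeric scalars, all strictly positive.
#' @return An `ExposureParams` object.
#' @export
exposureParams <- function(EF = 365, ED = 75.88, IR = 0.0328, BW = 70,
                           AT = 365 * 75.88) {
    vals <- c(EF = EF, ED = ED, IR = IR, BW = BW, AT = AT)
    if (any(!is.finite(vals)) || any(vals <= 0))
        stop("all exposure parameters must be positive: ",
             paste(names(vals)[!is.finite(vals) | vals <= 0], collapse = ", "))
    new("ExposureParams", EF = EF, ED = ED, IR = IR, BW = BW, AT = AT)
}

#' @rdname exposureParams
#' @export
setClass("ExposureParams", representation(
    EF = "numeric", ED = "numeric", IR = "numeric",
    BW = "numeric", AT = "numeric"))

setMethod("show", "ExposureParams", function(object) {
    cat(sprintf(paste0("ExposureParams: EF=%g d/yr, ED=%g yr, ",
                       "IR=%g kg/d, BW=%g kg, AT=%g d\n"),
                object@EF, object@ED, object@IR, object@BW, object@AT))
})

#' Oral reference doses (RfD)
#'
#' The default registry holds the twelve metals with tabulated oral
#' reference doses, in ug/kg body weight/day: Al 1000, Cr 1500, Mn 140,
#' Co 43, Ni 20, Cu 40, Zn 300, As 0.304, Cd 1, Sn 0.3, Hg 0.571, Pb 3.57.
#' Values are stored in ug/kg/day exactly as tabulated; the single
#' conversion to mg/kg/day happens inside [computeTHQ()].
#'
#' @return Named numeric vector of RfD values in ug/kg/day.
#' @export
defaultRfD <- function() {
    c(Al = 1000, Cr = 1500, Mn = 140, Co = 43, Ni = 20, Cu = 40,
      Zn = 300, As = 0.304, Cd = 1, Sn = 0.3, Hg = 0.571, Pb = 3.57)
}

#' Target Hazard Quotient for one metal
#'
#' The non-carcinogenic hazard of chronic dietary exposure to a metal at
#' concentration \eqn{C} (mg/kg) in the consumed food is
#' \deqn{THQ = \frac{EF \cdot ED \cdot IR \cdot C}{BW \cdot AT \cdot RfD}}
#' with RfD in mg/kg/day. A THQ (or summed TTHQ) at or below 1 indicates no
#' expected risk; above 1, a probability of adverse effects.
#'
#' @param conc metal concentration in the food, mg/kg (vectorised).
#' @param metal metal symbol(s), must be present in `rfd`.
#' @param params an [exposureParams()] object.
#' @param rfd named RfD vector in ug/kg/day (see [defaultRfD()]).
#' @return Numeric THQ, dimensionless.
#' @examples
#' computeTHQ(0.016, "Cd")  # home-grown mean cadmium
#' computeTHQ(0.086, "Hg")  # commercial mean mercury
#' @export
computeTHQ <- function(conc, metal, params = exposureParams(),
                       rfd = defaultRfD()) {
    bad <- setdiff(unique(metal), names(rfd))
    if (length(bad))
        stop("no oral reference dose for: ", paste(bad, collapse = ", "),
             "; known metals: ", paste(names(rfd), collapse = ", "))
    if (any(conc < 0, na.rm = TRUE)) stop("'conc' must be non-negative")
    if (any(rfd <= 0)) stop("RfD values must be positive")
    rfdMg <- rfd[metal] / 1000  # ug/kg/day -> mg/kg/day, once
    unname(params@EF * params@ED * params@IR * conc /
               (params@BW * params@AT * rfdMg))
}

#' Total Target Hazard Quotient
#'
#' Sums per-metal THQs into the cumulative mixture score TTHQ and applies
#' the `TTHQ > 1` risk rule.
#'
#' @param thq named numeric vector of per-metal THQs; metal names must be
#'   unique (a duplicate would double-count a metal).
#' @return A list with `tthq` (the arithmetic sum) and `risk` (logical,
#'   `TRUE` iff `tthq > 1`).
#' @examples
#' computeTTHQ(c(Cd = 0.3, Hg = 0.3, Pb = 0.5))  # 1.1, risk TRUE
#' @export
computeTTHQ <- function(thq) {
    if (!length(thq)) stop("'thq' must be non-empty")
    if (!is.null(names(thq)) && anyDuplicated(names(thq)))
        stop("duplicated metal(s) in THQ vector: ",
             paste(unique(names(thq)[duplicated(names(thq))]), collapse = ", "))
    s <- sum(thq)
    list(tthq = s, risk = s > 1)
}

#' Bundled reference mean concentrations for the edible fraction
#'
#' Mean concentrations (mg/kg dry weight, egg white + yolk) of the risk
#' metals reported for Romanian home-grown and commercial eggs, used both
#' as a worked risk-scoring example and to calibrate the synthetic
#' generator. Pb is the average of the reported egg-white and yolk means
#' (no per-system Pb means are available); Ni has a single overall mean.
#'
#' @param system `"home"` or `"commercial"`.
#' @return Named numeric vector of concentrations in mg/kg dw.
#' @export
referenceEdibleConcentrations <- function(system = c("home", "commercial")) {
    system <- match.arg(system)
    pb <- (0.957 + 1.186) / 2
    switch(system,
        home = c(Al = 4.783, Cu = 2.147, Mn = 1.059, Zn = 18.264,
                 Ni = 2.400, Cr = 12.389, Cd = 0.016, Hg = 0.065, Pb = pb),
        commercial = c(Al = 6.927, Cu = 2.344, Mn = 1.647, Zn = 19.335,
                       Ni = 2.400, Cr = 17.306, Cd = 0.007, Hg = 0.086,
                       Pb = pb))
}

#' Per-egg THQ/TTHQ risk assessment with group summaries
#'
#' For every egg, combines the white and yolk concentrations into an edible
#' fraction (the shell is not eaten and is excluded by default), computes
#' the per-metal THQ via [computeTHQ()] and the summed TTHQ, and summarises
#' TTHQ (min, mean, max) per rearing system. Only metals present both in
#' the RfD registry and in the table are scored; absent metals are skipped
#' with a warning, never imputed. Non-detect cells are substituted with the
#' given policy first (default `"zero"`, a conservative under-count).
#'
#' @param x an [ElementExperiment-class] containing white and yolk rows.
#' @param params an [exposureParams()] object.
#' @param rfd named RfD vector, ug/kg/day.
#' @param edibleRule `"mean"` (unweighted mean of white and yolk, the
#'   default) or `"mass_weighted"`.
#' @param whiteMassFrac dry-mass fraction of white in the edible part, used
#'   when `edibleRule = "mass_weighted"`.
#' @param ndPolicy,lod passed to [substituteNondetects()].
#' @return A [THQReport-class].
#' @export
riskByGroup <- function(x, params = exposureParams(), rfd = defaultRfD(),
                        edibleRule = c("mean", "mass_weighted"),
                        whiteMassFrac = 0.3, ndPolicy = "zero", lod = NULL) {
    edibleRule <- match.arg(edibleRule)
    if (any(isNonDetect(x)))
        x <- substituteNondetects(x, policy = ndPolicy, lod = lod)
    metals <- intersect(names(rfd), rownames(x))
    skipped <- setdiff(names(rfd), metals)
    if (length(skipped))
        warning("no concentration data for metal(s): ",
                paste(skipped, collapse = ", "), "; skipped, not imputed")
    if (!length(metals)) stop("no RfD metal has concentration data")
    conc <- concentrations(x)[metals, , drop = FALSE]
    part <- as.character(eggPart(x))
    sid <- sampleIds(x)
    sys <- as.character(rearingSystem(x))
    wWhite <- if (edibleRule == "mean") 0.5 else whiteMassFrac

    eggs <- unique(sid)
    rows <- list(); thqLong <- list()
    for (egg in eggs) {
        iw <- which(sid == egg & part == "white")
        iy <- which(sid == egg & part == "yolk")
        if (!length(iw) && !length(iy)) {
            warning("egg '", egg, "' lacks both edible parts; skipped")
            next
        }
        edible <- if (length(iw) && length(iy))
            wWhite * conc[, iw] + (1 - wWhite) * conc[, iy]
        else if (length(iw)) conc[, iw] else conc[, iy]
        thq <- setNames(computeTHQ(edible, metals, params, rfd), metals)
        tot <- computeTTHQ(thq)
        sysEgg <- sys[c(iw, iy)][1]
        rows[[egg]] <- data.frame(
            sample_id = egg, system = sysEgg, t(thq),
            TTHQ = tot$tthq, risk = tot$risk,
            check.names = FALSE, stringsAsFactors = FALSE)
        thqLong[[egg]] <- data.frame(
            sample_id = egg, system = sysEgg, metal = metals,
            concentration = unname(edible), THQ = unname(thq),
            stringsAsFactors = FALSE)
    }
    perEgg <- do.call(rbind, rows); rownames(perEgg) <- NULL
    thqLong <- do.call(rbind, thqLong); rownames(thqLong) <- NULL
    bySystem <- do.call(rbind, lapply(split(perEgg, perEgg$system), function(d)
        data.frame(system = d$system[1], n = nrow(d), min = min(d$TTHQ),
                   mean = mean(d$TTHQ), max = max(d$TTHQ),
                   stringsAsFactors = FALSE)))
    rownames(bySystem) <- NULL
    new("THQReport", perEgg = perEgg, thq = thqLong, bySystem = bySystem,
        metals = metals,
        params = list(EF = params@EF, ED = params@ED, IR = params@IR,
                      BW = params@BW, AT = params@AT, rfd = rfd[metals],
                      edibleRule = edibleRule, whiteMassFrac = wWhite))
}
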