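#' Calibration table for the synthetic egg-composition generator
#'
#' One row per calibrated cell: `element`, optional `part`
#' (white/yolk/shell) and `system` (home/commercial) — `NA` acts as a
#' wildcard — with the target `mean` (mg/kg dry weight) and, where a
#' min-max envelope is available, `min` and `max`. The default table
#' encodes the reported composition of Romanian eggs: full min/max/mean
#' rows for the five macro-minerals per component; component means for Zn,
#' Pb, Cd and Hg; component ranges for Cu and Mn; rearing-system specific
#' means for Al and Cr; a single overall mean for Ni; and group-level
#' means for the alkaline/alkaline-earth metals, REEs (0.010 mg/kg each),
#' TCEs (0.006), PGEs (0.004), transition and post-transition metals
#' (0.513) and Th (0.023). Cells with no reported value (shell levels of
#' some trace metals; Fe, Se, Ag, As, Sn, Co) carry synthetic assumed
#' means, marked in the `source` column.
#'
#' The lognormal scale parameter of a cell is derived from the min-max
#' envelope where present (about 99% of the mass inside the printed
#' range), otherwise from a default geometric standard deviation of 1.8;
#' the location parameter is always solved so the distribution mean equals
#' the target mean exactly.
#'
#' @return A data.frame with columns `element`, `part`, `system`, `mean`,
#'   `min`, `max`, `source`.
#' @export
defaultCalibration <- function() {
    r <- function(element, part = NA, system = NA, mean, min = NA, max = NA,
                  source = "reported")
        data.frame(element = element, part = part, system = system,
                   mean = mean, min = min, max = max, source = source,
                   stringsAsFactors = FALSE)
    macro <- rbind(
        r("Na", "white", mean = 10266.37, min = 5900.00, max = 15373.56),
        r("Na", "yolk",  mean = 629.06,  min = 156.75,  max = 1200.11),
        r("Na", "shell", mean = 653.64,  min = 300.22,  max = 1183.84),
        r("Mg", "white", mean = 639.20,  min = 290.55,  max = 965.85),
        r("Mg", "yolk",  mean = 176.03,  min = 53.10,   max = 230.45),
        r("Mg", "shell", mean = 1488.01, min = 738.57,  max = 3000.70),
        r("P",  "white", mean = 665.93,  min = 220.38,  max = 1400.02),
        r("P",  "yolk",  mean = 3856.23, min = 1331.11, max = 5000.44),
        r("P",  "shell", mean = 521.04,  min = 230.29,  max = 873.81),
        r("K",  "white", mean = 4151.84, min = 526.95,  max = 6977.12),
        r("K",  "yolk",  mean = 593.43,  min = 280.72,  max = 921.95),
        r("K",  "shell", mean = 156.72,  min = 85.56,   max = 346.10),
        r("Ca", "white", mean = 453.49,  min = 130.11,  max = 2928.81),
        r("Ca", "yolk",  mean = 1225.18, min = 438.15,  max = 1843.34),
        r("Ca", "shell", mean = 74643.56, min = 40813.66, max = 139519.80))
    trace <- rbind(
        r("Zn", "white", mean = 3.830),
        r("Zn", "yolk",  mean = 33.158),
        r("Zn", "shell", mean = 2.0, source = "synthetic"),
        r("Cu", "white", mean = 1.971, min = 0.496, max = 7.828,
          source = "range; geometric-midpoint mean"),
        r("Cu", "yolk",  mean = 2.947, min = 1.430, max = 6.074,
          source = "range; geometric-midpoint mean"),
        r("Cu", "shell", mean = 0.649, min = 0.233, max = 1.808,
          source = "range; geometric-midpoint mean"),
        r("Mn", "white", mean = 1.1,   min = 0.05,  max = 25.105,
          source = "range; synthetic mean"),
        r("Mn", "yolk",  mean = 1.907, min = 0.580, max = 6.27,
          source = "range; geometric-midpoint mean"),
        r("Mn", "shell", mean = 0.3,   min = 0.02,  max = 1.772,
          source = "range; synthetic mean"),
        r("Pb", "white", mean = 0.957),
        r("Pb", "yolk",  mean = 1.186),
        r("Pb", "shell", mean = 0.103),
        r("Cd", "white", mean = 0.023),
        r("Cd", "yolk",  mean = 0.004),
        r("Cd", "shell", mean = 0.004),
        r("Hg", "white", mean = 0.121),
        r("Hg", "yolk",  mean = 0.019),
        r("Hg", "shell", mean = 0.0007),
        r("Al", "white", "home",       mean = 4.783),
        r("Al", "white", "commercial", mean = 6.927),
        r("Al", "yolk",  "home",       mean = 4.783),
        r("Al", "yolk",  "commercial", mean = 6.927),
        r("Al", "shell", mean = 1.0, source = "synthetic"),
        r("Cr", "white", "home",       mean = 12.389, min = 0.05,
          max = 160.167),
        r("Cr", "white", "commercial", mean = 17.306, min = 0.05,
          max = 160.167),
        r("Cr", "yolk",  "home",       mean = 12.389, min = 0.05,
          max = 33.86),
        r("Cr", "yolk",  "commercial", mean = 17.306, min = 0.05,
          max = 33.86),
        r("Cr", "shell", mean = 1.0, source = "synthetic"),
        r("Ni", mean = 2.400),
        r("Fe", mean = 60,   source = "synthetic"),
        r("Se", mean = 0.3,  source = "synthetic"),
        r("Ag", mean = 0.01, source = "synthetic"),
        r("As", mean = 0.02, source = "synthetic"),
        r("Sn", mean = 0.01, source = "synthetic"),
        r("Co", mean = 0.01, source = "synthetic"))
    alkaline <- rbind(
        r("Li", mean = 0.477), r("Cs", mean = 0.013), r("Rb", mean = 3.8),
        r("Be", mean = 0.012), r("Ba", mean = 6.242), r("Sr", mean = 1.945))
    panel <- elementPanel()
    groupMeans <- rbind(
        do.call(rbind, lapply(panel$ree, function(e)
            r(e, mean = 0.010, source = "group mean"))),
        do.call(rbind, lapply(panel$tce, function(e)
            r(e, mean = 0.006, source = "group mean"))),
        do.call(rbind, lapply(panel$pge, function(e)
            r(e, mean = 0.004, source = "group mean"))),
        do.call(rbind, lapply(panel$transition, function(e)
            r(e, mean = 0.513, source = "group mean"))),
        r("Th", mean = 0.023))
    out <- rbind(macro, trace, alkaline, groupMeans)
    rownames(out) <- NULL
    out
}

# lognormal parameters for one calibration row: sdlog from the min-max
# envelope (99% of mass inside) or the default geometric SD; meanlog solved
# so E[X] equals the target mean exactly.
.lognormParams <- function(mean, min = NA, max = NA, defaultGsd = 1.8) {
    sdlog <- if (!is.na(min) && !is.na(max) && min > 0 && max > min)
        (log(max) - log(min)) / (2 * qnorm(0.995))
    else log(defaultGsd)
    list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# most specific calibration row for (element, part, system); specificity
# order: (e,p,s) > (e,p) > (e,s) > (e)
.resolveCalibration <- function(cal, element, part, system) {
    cand <- cal[cal$element == element, , drop = FALSE]
    if (!nrow(cand))
        stop("no calibration entry for element '", element, "'")
    spec <- 2L * (!is.na(cand$part) & cand$part == part) +
        1L * (!is.na(cand$system) & cand$system == system)
    spec[!is.na(cand$part) & cand$part != part] <- -1L
    spec[!is.na(cand$system) & cand$system != system] <- -1L
    ok <- spec >= 0
    if (!any(ok))
        stop("no calibration entry for (", element, ", ", part, ", ",
             system, ")")
    cand[which(ok)[which.max(spec[ok])], , drop = FALSE]
}
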