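test_that("generation is deterministic given config and seed", {
    cfg <- syntheticConfig(nEggs = c(home = 3, commercial = 1), seed = 9)
    a <- generateEggData(cfg)
    b <- generateEggData(cfg)
    expect_identical(concentrations(a), concentrations(b))
    expect_identical(isNonDetect(a), isNonDetect(b))
    c <- generateEggData(syntheticConfig(nEggs = c(home = 3, commercial = 1),
                                         seed = 10))
    expect_false(identical(concentrations(a), concentrations(c)))
})

test_that("the default design yields 70 eggs x 3 parts x 64 elements", {
    ee <- generateEggData(syntheticConfig(seed = 1))
    expect_equal(dim(ee), c(64L, 210L))
    expect_equal(length(unique(sampleIds(ee))), 70)
    expect_equal(unname(table(eggPart(ee))), rep(70L, 3), ignore_attr = TRUE)
    expect_equal(sum(rearingSystem(ee) == "home"), 165)  # 55 eggs x 3
    expect_equal(sum(rearingSystem(ee) == "commercial"), 45)
})

test_that("marginal means converge to the calibration targets", {
    cfg <- syntheticConfig(nEggs = c(home = 3929, commercial = 1071),
                           seed = 5)
    ee <- generateEggData(cfg)
    conc <- concentrations(ee)
    white <- eggPart(ee) == "white"
    expect_equal(mean(conc["Zn", white], na.rm = TRUE), 3.830,
                 tolerance = 0.02)
    expect_equal(mean(conc["Na", white], na.rm = TRUE), 10266.37,
                 tolerance = 0.02)
    yolk <- eggPart(ee) == "yolk"
    expect_equal(mean(conc["Zn", yolk], na.rm = TRUE), 33.158,
                 tolerance = 0.02)
    # non-detect fraction converges to the configured rate
    expect_lt(abs(mean(isNonDetect(ee)["Mn", ]) - 0.05), 0.01)
    expect_lt(abs(mean(isNonDetect(ee)["Cr", ]) - 0.05), 0.01)
    expect_equal(sum(isNonDetect(ee)["Zn", ]), 0)
})

test_that("part separation makes the egg-part task solvable from macros", {
    ee <- generateEggData(syntheticConfig(seed = 2))
    s <- summarizeElements(ee, by = "egg_part")
    m <- function(el, pt) s$mean[s$element == el & s$egg_part == pt]
    expect_gt(m("Na", "white"), 5 * m("Na", "yolk"))
    expect_gt(m("Na", "white"), 5 * m("Na", "shell"))
    expect_gt(m("K", "white"), 3 * m("K", "yolk"))
    expect_gt(m("Ca", "shell"), 20 * m("Ca", "white"))
    expect_gt(m("Ca", "shell"), 20 * m("Ca", "yolk"))
})

test_that("copula blocks realise the configured correlations", {
    cfg <- syntheticConfig(nEggs = c(home = 150, commercial = 50), seed = 3)
    ee <- generateEggData(cfg)
    conc <- concentrations(ee)
    white <- eggPart(ee) == "white"
    # Cu-Mg near-perfect negative block (loading 0.95 -> latent corr -0.9)
    expect_lte(cor(log(conc["Cu", white]), log(conc["Mg", white])), -0.85)
    # positive light-REE block
    expect_gt(cor(log(conc["Tb", white]), log(conc["Ce", white])), 0.4)
    # an element outside any block stays roughly uncorrelated
    expect_lt(abs(cor(log(conc["Zn", white]), log(conc["Pb", white]))), 0.25)
})

test_that("marker shifts create the requested standardised difference", {
    base <- syntheticConfig(nEggs = c(home = 300, commercial = 300),
                            markerShift = 0, outliers = list(n = 0),
                            seed = 4)
    ee <- generateEggData(base)
    w <- ee[, eggPart(ee) == "white"]
    smd <- function(x, el) {
        v <- log(concentrations(x)[el, ])
        sys <- rearingSystem(x)
        (mean(v[sys == "home"]) - mean(v[sys == "commercial"])) / sd(v)
    }
    # null case: no shift -> standardised difference near zero
    expect_lt(abs(smd(w, "Li")), 0.25)
    # injecting a 2 SD shift on Li yields a difference near 2
    sh <- injectStructure(ee, markers = data.frame(element = "Li", sign = 1),
                          shift = 2)
    shw <- sh[, eggPart(sh) == "white"]
    v <- log(concentrations(shw)["Li", ])
    sys <- rearingSystem(shw)
    pooled <- sqrt((var(v[sys == "home"]) + var(v[sys == "commercial"])) / 2)
    expect_equal((mean(v[sys == "home"]) - mean(v[sys == "commercial"])) /
                     pooled, 2, tolerance = 0.2)
    # unknown element in the marker spec is refused
    expect_error(injectStructure(ee, data.frame(element = "Xx", sign = 1)),
                 "Xx")
})

test_that("outlier injection records its spikes and respects the magnitude", {
    cfg <- syntheticConfig(outliers = list(n = 3, magnitude = 10,
                                           nElements = 5, part = "yolk"),
                           seed = 6)
    ee <- generateEggData(cfg)
    meta <- metadata(ee)$outliers
    expect_length(meta$samples, 3)
    expect_length(meta$elements, 5)
    expect_true(all(meta$samples %in% colnames(ee)))
    expect_true(all(eggPart(ee)[meta$rows] == "yolk"))
    conc <- concentrations(ee)
    for (el in meta$elements) {
        v <- conc[el, ]
        clean <- v[-meta$rows]
        # all three spikes share one extreme value, far out in the
        # uncontaminated column's distribution
        expect_length(unique(v[meta$rows]), 1)
        expect_true(all(v[meta$rows] >
                            mean(clean, na.rm = TRUE) +
                                9 * sd(clean, na.rm = TRUE)))
    }
})

test_that("config validity rules reject impossible setups", {
    expect_error(syntheticConfig(nEggs = c(home = 0, commercial = 5)),
                 "nEggs")
    expect_error(syntheticConfig(ndRate = c(Mn = 1.2)), "ndRate")
    badBlocks <- c(defaultBlocks(),
                   list(list(elements = c("Cu", "Zn"), loading = 0.5,
                             signs = c(1, 1))))
    expect_error(syntheticConfig(blocks = badBlocks), "one correlation block")
})
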