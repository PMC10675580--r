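test_that("digest conversion follows Ct = Cs*Vs/Wt and propagates non-detects", {
    expect_equal(convertConcentration(500, 0.05, 0.5), 50)
    expect_equal(convertConcentration(0, 0.05, 0.5), 0)
    expect_equal(convertConcentration(1000, 0.05, 0.5), 100)
    # non-detect in -> non-detect out
    expect_true(is.na(convertConcentration(NA, 0.05, 0.5)))
    expect_true(is.na(convertConcentration(500, 0.05, 0.5,
                                           nonDetect = TRUE)))
    # validation errors name the offending field
    expect_error(convertConcentration(500, 0, 0.5), "volume")
    expect_error(convertConcentration(500, 0.05, -1), "dryMass")
    expect_error(convertConcentration(-5, 0.05, 0.5), "solutionConc")
    # linear in Cs, inversely proportional to Wt
    set.seed(1)
    for (i in 1:25) {
        cs <- runif(1, 0, 2000); vs <- runif(1, 0.01, 0.1)
        wt <- runif(1, 0.1, 2); a <- runif(1, 0.1, 5)
        expect_equal(convertConcentration(a * cs, vs, wt),
                     a * convertConcentration(cs, vs, wt))
        expect_equal(convertConcentration(cs, vs, 2 * wt),
                     convertConcentration(cs, vs, wt) / 2)
    }
})

test_that("digestion records read, validate and convert", {
    f <- writeCsvText(c("sample_id,solution_conc,volume,dry_mass",
                        "s1,500,0.05,0.5", "s2,ND,0.05,0.5"))
    rec <- readDigestionRecords(f)
    expect_equal(rec$non_detect, c(FALSE, TRUE))
    out <- convertDigestion(rec)
    expect_equal(out$tissue_conc, c(50, NA))
    f2 <- writeCsvText(c("sample_id,solution_conc", "s1,5"))
    expect_error(readDigestionRecords(f2), "volume")
})

test_that("element table CSV round trip preserves values and flags exactly", {
    ee <- smallSynthetic()
    f <- tempfile(fileext = ".csv")
    writeElementTable(ee, f)
    ee2 <- readElementTable(f)
    expect_identical(concentrations(ee2), concentrations(ee))
    expect_identical(unname(isNonDetect(ee2)), unname(isNonDetect(ee)))
    expect_equal(as.character(eggPart(ee2)), as.character(eggPart(ee)))
    # second pass is idempotent
    f2 <- tempfile(fileext = ".csv")
    writeElementTable(ee2, f2)
    expect_identical(readLines(f), readLines(f2))
})

test_that("table parsing flags NDs, rejects bad input, drops unknown columns", {
    f <- writeCsvText(c("sample_id,egg_part,system,Na,Zn",
                        "e1,white,home,10,ND",
                        "e1,yolk,home,5,2",
                        "e2,white,home,12,4"))
    ee <- readElementTable(f)
    expect_true(isNonDetect(ee)["Zn", 1])
    # the ND cell is excluded from group means
    s <- summarizeElements(ee, by = "egg_part")
    znWhite <- s[s$element == "Zn" & s$egg_part == "white", ]
    expect_equal(znWhite$n, 1)
    expect_equal(znWhite$mean, 4)  # not (0 + 4)/2

    # unknown element column -> warning + exclusion
    fu <- writeCsvText(c("sample_id,egg_part,system,Na,Xx",
                         "e1,white,home,10,1"))
    expect_warning(eeu <- readElementTable(fu), "Xx")
    expect_false("Xx" %in% rownames(eeu))

    # missing metadata -> error
    fm <- writeCsvText(c("sample_id,Na", "e1,10"))
    expect_error(readElementTable(fm), "egg_part")

    # duplicated (sample_id, egg_part) -> rejection
    fd <- writeCsvText(c("sample_id,egg_part,system,Na",
                         "e1,white,home,10", "e1,white,home,11"))
    expect_error(readElementTable(fd), "duplicated")

    # thousands separators are rejected, not silently mangled
    ft <- writeCsvText(c("sample_id,egg_part,system,Na",
                         "e1,white,home,\"15,373.56\""))
    expect_error(readElementTable(ft), "separator")
})

test_that("non-detect substitution policies behave as defined", {
    conc <- rbind(Zn = c(NA, 4, 6), Pb = c(1, NA, 2))
    ee <- ElementExperiment(conc, eggPart = c("white", "white", "white"),
                            system = rep("home", 3),
                            sampleId = c("a", "b", "c"))
    z <- substituteNondetects(ee, "zero")
    expect_equal(unname(concentrations(z)["Zn", 1]), 0)
    expect_false(any(isNonDetect(z)))
    h <- substituteNondetects(ee, "half_lod", lod = c(Zn = 0.01, Pb = 0.2))
    expect_equal(unname(concentrations(h)["Zn", 1]), 0.005)
    expect_equal(unname(concentrations(h)["Pb", 2]), 0.1)
    expect_error(substituteNondetects(ee, "half_lod"), "LOD|lod")
    d <- substituteNondetects(ee, "drop")
    s <- summarizeElements(d, by = character(0))
    expect_equal(s$n[s$element == "Zn"], 2)  # n decreases by the ND count
    expect_equal(s$mean[s$element == "Zn"], 5)
    # substitution provenance is logged
    expect_equal(metadata(z)$nd_substitutions$policy, "zero")
    expect_equal(unname(metadata(z)$nd_substitutions$n_per_element["Zn"]), 1)
})

test_that("summaries satisfy min <= mean <= max and handle edge groups", {
    conc <- rbind(Na = c(1, 2, 3), K = c(5, 5, 5))
    ee <- ElementExperiment(conc, eggPart = rep("white", 3),
                            system = rep("home", 3),
                            sampleId = c("a", "b", "c"))
    s <- summarizeElements(ee, by = character(0))
    expect_equal(unlist(s[s$element == "Na", c("min", "max", "mean")]),
                 c(min = 1, max = 3, mean = 2))
    # single-value group: min = max = mean
    one <- ee[, 1]
    s1 <- summarizeElements(one, by = character(0))
    expect_true(all(s1$min == s1$mean & s1$mean == s1$max))
    # generated table: min <= mean <= max everywhere
    sg <- summarizeElements(smallSynthetic(), by = c("egg_part", "system"))
    ok <- !is.na(sg$mean)
    expect_true(all(sg$min[ok] <= sg$mean[ok] + 1e-12))
    expect_true(all(sg$mean[ok] <= sg$max[ok] + 1e-12))
    # group with no data is NA, not zero
    dd <- substituteNondetects(
        ElementExperiment(rbind(Zn = c(NA, 2)),
                          eggPart = c("white", "yolk"),
                          system = c("home", "home"),
                          sampleId = c("a", "a")), "drop")
    sd2 <- summarizeElements(dd, by = "egg_part")
    expect_true(is.na(sd2$mean[sd2$egg_part == "white"]))
})

test_that("container invariants are enforced", {
    conc <- rbind(Na = c(1, 2))
    expect_error(ElementExperiment(conc, eggPart = c("white", "white"),
                                   system = c("home", "home"),
                                   sampleId = c("a", "a")),
                 "duplicated")
    expect_error(ElementExperiment(rbind(Na = c(-1, 2)),
                                   eggPart = c("white", "yolk"),
                                   system = c("home", "home"),
                                   sampleId = c("a", "a")),
                 "negative")
    # panel definition: 64 unique symbols in disjoint groups
    panel <- elementPanel()
    expect_length(unique(unlist(panel)), 64)
    expect_equal(sum(lengths(panel)), 64)
    f <- tempfile(fileext = ".json")
    writeElementPanel(f)
    expect_equal(readElementPanel(f), panel)
})
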