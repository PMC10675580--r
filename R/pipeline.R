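#' Reproduce the full analysis pipeline on one dataset
#'
#' Runs the end-to-end workflow — data acquisition (synthetic generation
#' or CSV input), per-element summaries, full-data PCA, Mahalanobis
#' score-distance outlier flagging, PCA refit on the trimmed data,
#' THQ/TTHQ risk scoring, and the two held-out sparse PLS-DA tasks (egg
#' part; rearing system) — writing every stage output into `outDir` as
#' CSV/JSON plus a `manifest.json` with package version, seed, per-stage
#' files and their MD5 hashes. Stage outputs are pure functions of (input,
#' config, seed): rerunning with the same arguments reproduces identical
#' hashes. A failing stage halts with an error naming the stage; outputs
#' of completed stages are preserved.
#'
#' @param outDir output directory (created if needed).
#' @param seed integer master seed; the PLS-DA splits use `seed + 1` and
#'   `seed + 2`.
#' @param config a [syntheticConfig()] used when `input` is `NULL`; its
#'   seed is set to `seed`.
#' @param input optional CSV path of a measured element table (see
#'   [readElementTable()]); overrides synthetic generation.
#' @param stages subset of `c("data", "summary", "pca_full", "outliers",
#'   "pca_trimmed", "risk", "plsda_part", "plsda_system")`; the data are
#'   always acquired in memory, but only requested stages write outputs
#'   (and later stages implied by the request are computed as needed).
#' @param ndPolicy non-detect substitution policy for the numeric stages.
#' @param outlierDims,outlierQuantile parameters of [flagOutliers()].
#' @param partConfig,systemConfig lists with `ncomp`, `keepX`, `distance`
#'   for the two classification tasks.
#' @param trainFrac held-out training fraction.
#' @return Invisibly, a list with the manifest and the fitted objects.
#' @export
reproduceStudy <- function(outDir, seed = 1,
                           config = syntheticConfig(seed = seed),
                           input = NULL,
                           stages = c("data", "summary", "pca_full",
                                      "outliers", "pca_trimmed", "risk",
                                      "plsda_part", "plsda_system"),
                           ndPolicy = "zero",
                           outlierDims = 2, outlierQuantile = 0.999,
                           partConfig = list(ncomp = 2, keepX = c(2, 1),
                                             distance = "centroid"),
                           systemConfig = list(ncomp = 3, keepX = 17,
                                               distance = "centroid"),
                           trainFrac = 0.7) {
    allStages <- c("data", "summary", "pca_full", "outliers", "pca_trimmed",
                   "risk", "plsda_part", "plsda_system")
    stages <- match.arg(stages, allStages, several.ok = TRUE)
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    manifest <- list(package = "ovorisk",
                     version = as.character(utils::packageVersion("ovorisk")),
                     seed = seed, nd_policy = ndPolicy, stages = list())
    objects <- list()
    emit <- function(stage, files) {
        manifest$stages[[stage]] <<- list(
            files = basename(files),
            md5 = unname(tools::md5sum(files)))
    }
    run <- function(stage, expr) {
        tryCatch(expr, error = function(e)
            stop("stage '", stage, "': ", conditionMessage(e),
                 call. = FALSE))
    }

    x <- run("data", {
        if (!is.null(input)) readElementTable(input)
        else generateEggData(`slot<-`(config, "seed", value = as.integer(seed)))
    })
    objects$data <- x
    if ("data" %in% stages) {
        f <- file.path(outDir, "element_table.csv")
        writeElementTable(x, f)
        emit("data", f)
    }
    xsub <- substituteNondetects(x, policy = ndPolicy)

    if ("summary" %in% stages) run("summary", {
        f <- file.path(outDir, "summary_by_part.csv")
        write.csv(summarizeElements(xsub, by = c("egg_part")), f,
                  row.names = FALSE)
        emit("summary", f)
    })

    needPCA <- any(c("pca_full", "outliers", "pca_trimmed", "plsda_part",
                     "plsda_system") %in% stages)
    fitFull <- NULL; outRep <- NULL; xTrim <- xsub
    if (needPCA) {
        fitFull <- run("pca_full", pcaFit(xsub))
        objects$pca_full <- fitFull
        if ("pca_full" %in% stages) {
            fs <- file.path(outDir, c("pca_scores.csv", "pca_loadings.csv",
                                      "pca_contributions.csv"))
            write.csv(scores(fitFull), fs[1])
            write.csv(loadingWeights(fitFull), fs[2])
            write.csv(variableContributions(fitFull), fs[3])
            emit("pca_full", fs)
        }
        outRep <- run("outliers",
                      flagOutliers(fitFull, dims = outlierDims,
                                   quantile = outlierQuantile))
        objects$outliers <- outRep
        if ("outliers" %in% stages) {
            f <- file.path(outDir, "outliers.json")
            jsonlite::write_json(
                list(flagged = outRep@flagged, cutoff = outRep@cutoff,
                     dims = outRep@dims, quantile = outRep@quantile,
                     statistic = as.list(outRep@statistic)),
                f, auto_unbox = TRUE, digits = NA)
            emit("outliers", f)
        }
        xTrim <- removeOutliers(xsub, outRep)
    }

    if ("pca_trimmed" %in% stages) run("pca_trimmed", {
        fitTrim <- pcaFit(xTrim)
        objects$pca_trimmed <- fitTrim
        fs <- file.path(outDir, c("pca_trimmed_scores.csv",
                                  "pca_trimmed_variance.csv"))
        write.csv(scores(fitTrim), fs[1])
        write.csv(data.frame(dim = seq_along(varExplained(fitTrim)),
                             var_explained = varExplained(fitTrim)),
                  fs[2], row.names = FALSE)
        emit("pca_trimmed", fs)
    })

    if ("risk" %in% stages) run("risk", {
        rep <- riskByGroup(xsub)
        objects$risk <- rep
        fs <- file.path(outDir, c("risk_per_egg.csv", "risk_by_system.csv",
                                  "risk_thq_long.csv"))
        write.csv(rep@perEgg, fs[1], row.names = FALSE)
        write.csv(rep@bySystem, fs[2], row.names = FALSE)
        write.csv(rep@thq, fs[3], row.names = FALSE)
        emit("risk", fs)
    })

    writeTask <- function(stage, target, cfg, taskSeed) {
        ev <- evaluateHoldout(xTrim, target, ncomp = cfg$ncomp,
                              keepX = cfg$keepX, distance = cfg$distance,
                              trainFrac = trainFrac, seed = taskSeed)
        objects[[stage]] <<- ev
        rep <- ev$report
        fs <- file.path(outDir, paste0(stage, c("_report.json",
                                                "_scores.csv")))
        jsonlite::write_json(list(
            target = target, ncomp = cfg$ncomp, keepX = cfg$keepX,
            distance = cfg$distance, seed = taskSeed,
            selected = selectedVariables(ev$model),
            confusion = as.data.frame.matrix(rep@confusion),
            accuracy = rep@accuracy, sensitivity = rep@sensitivity,
            specificity = rep@specificity),
            fs[1], auto_unbox = TRUE, digits = NA)
        write.csv(data.frame(scores(ev$model),
                             class = as.character(ev$model@y)),
                  fs[2])
        emit(stage, fs)
    }
    if ("plsda_part" %in% stages)
        run("plsda_part",
            writeTask("plsda_part", "egg_part", partConfig, seed + 1))
    if ("plsda_system" %in% stages)
        run("plsda_system",
            writeTask("plsda_system", "system", systemConfig, seed + 2))

    mf <- file.path(outDir, "manifest.json")
    jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA)
    invisible(list(manifest = manifest, objects = objects,
                   manifestPath = mf))
}
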