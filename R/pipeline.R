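#' Write a synthetic study to disk
#'
#' Generates the peptide table, emPAI and probability matrices, label table
#' and a ground-truth marker manifest for a synthetic study, and writes them
#' under `dir` (created if missing). With defaults this reproduces the
#' explant-study layout: 24 samples over four treatments and two subjects,
#' one anomalously sparse sample.
#'
#' @param dir output directory.
#' @param design a [StudyDesign-class].
#' @param config a [generatorConfig()].
#' @return named character vector of written paths, invisibly.
#' @export
simulateStudy <- function(dir, design = generateDesign(),
                          config = generatorConfig(seed = 1)) {
    if (!dir.exists(dir)) {
        dir.create(dir, recursive = TRUE)
        message("created output directory ", dir)
    }
    tab <- generatePeptideTable(design, config)
    samples <- designSamples(design)
    paths <- c(peptides = file.path(dir, "peptides.tsv"),
               labels = file.path(dir, "labels.tsv"),
               empai = file.path(dir, "matrix_empai.tsv"),
               probability = file.path(dir, "matrix_probability.tsv"),
               markers = file.path(dir, "markers.json"))
    writeTable(tab, paths[["peptides"]])
    writeTable(samples, paths[["labels"]])
    writeQuantMatrix(generateQuantMatrix(design, config, "empai"),
                     paths[["empai"]])
    writeQuantMatrix(generateQuantMatrix(design, config, "probability"),
                     paths[["probability"]])
    jsonlite::write_json(lapply(config$markers, unclass), paths[["markers"]],
                         auto_unbox = TRUE, null = "null")
    invisible(paths)
}

#' Run the full pipeline end-to-end
#'
#' Quantify (or simulate) a score matrix, filter anomalous samples, evaluate
#' by LOOCV with permutation significance, mine an ensemble of learner runs
#' into per-class protein rankings and a top-k pair network, and write every
#' artefact plus a single JSON run report. All randomness derives from
#' `seed`.
#'
#' @param outDir output directory (created if missing).
#' @param x a [QuantMatrix-class]; if `NULL`, one is simulated from `design`
#'   and `generatorCfg`.
#' @param design,generatorCfg synthetic inputs used when `x` is `NULL`.
#' @param scoreType `"empai"`, `"probability"` or `"combined"` (simulated
#'   input only).
#' @param seed base seed for every stage.
#' @param anomalyThreshold fraction-of-median cutoff for
#'   [filterAnomalousSamples()].
#' @param learnerCfg a [learnerConfig()] (seed overridden by `seed`).
#' @param nPermutations label permutations for [permutationTest()]
#'   (0 skips the test).
#' @param nRuns ensemble size for [runEnsemble()].
#' @param pairsK top pairs per class for [buildNetwork()].
#' @param verbose emit stage-by-stage log messages.
#' @return the run report, a list (also written to `<outDir>/report.json`).
#' @examples
#' \donttest{
#' rep <- runPipeline(tempfile(), seed = 1, nPermutations = 0, nRuns = 5,
#'                    learnerCfg = learnerConfig(seed = 1, generations = 5,
#'                                               populationSize = 10))
#' rep$loocv$accuracy_percent
#' }
#' @export
runPipeline <- function(outDir, x = NULL, design = generateDesign(),
                        generatorCfg = NULL,
                        scoreType = c("empai", "probability", "combined"),
                        seed = 1, anomalyThreshold = 0.25,
                        learnerCfg = learnerConfig(seed = seed),
                        nPermutations = 50, nRuns = 10000, pairsK = 100,
                        verbose = TRUE) {
    scoreType <- match.arg(scoreType)
    say <- function(stage, fmt, ...) {
        if (verbose) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
    }
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    if (is.null(x)) {
        if (is.null(generatorCfg)) generatorCfg <- generatorConfig(seed = seed)
        x <- if (scoreType == "combined")
            combineMatrices(generateQuantMatrix(design, generatorCfg, "empai"),
                            generateQuantMatrix(design, generatorCfg,
                                                "probability"))
        else generateQuantMatrix(design, generatorCfg, scoreType)
        say("simulate", "%d features x %d samples (%s)", nrow(x), ncol(x),
            scoreType)
    }
    flt <- filterAnomalousSamples(x, anomalyThreshold)
    say("filter", "%d of %d samples retained (%d removed)",
        ncol(flt$matrix), ncol(x), length(flt$removed))
    m <- flt$matrix
    learnerCfg$seed <- as.integer(seed)
    loocv <- runLoocv(m, learnerCfg)
    say("loocv", "%d splits, accuracy %s", ncol(m),
        formatAccuracy(loocv$accuracy))
    permRes <- NULL
    if (nPermutations > 0) {
        permRes <- permutationTest(m, learnerCfg, nPermutations, seed = seed)
        say("permute", "%d permutations, p_empirical = %.4g", nPermutations,
            permRes$p_empirical)
    }
    ensemble <- runEnsemble(m, learnerCfg, nRuns = nRuns,
                            baseSeed = deriveSeed(seed, 1L),
                            progressEvery = if (verbose) max(1, nRuns %/% 10)
                                            else 0)
    say("mine", "%d rule sets, %d rules total", length(ensemble),
        sum(vapply(ensemble, function(rs) length(rs@rules), integer(1))))
    ranking <- rankProteins(ensemble)
    pairs <- extractPairs(ensemble)
    net <- buildNetwork(pairs, k = pairsK)
    say("network", "%d nodes, %d edges (k = %d per class)",
        length(net$nodes), nrow(net$edges), pairsK)
    # artefacts
    writeQuantMatrix(m, file.path(outDir, "matrix_filtered.tsv"))
    writeTable(data.frame(confusionToLong(loocv$confusion)),
               file.path(outDir, "confusion.tsv"))
    writeRankingTSV(ranking, outDir)
    writeSIF(net, file.path(outDir, "network.sif"))
    writeGraphML(net, file.path(outDir, "network.graphml"))
    rsPath <- file.path(outDir, "rulesets.txt")
    writeLines(vapply(ensemble, serializeRuleSet, character(1)), rsPath)
    report <- list(
        seed = as.integer(seed),
        score_type = scoreType,
        n_input_samples = ncol(x),
        filter = list(threshold = anomalyThreshold,
                      removed = as.list(flt$removed),
                      n_retained = ncol(m)),
        learner = unclass(learnerCfg),
        loocv = list(n_splits = ncol(m),
                     accuracy = loocv$accuracy,
                     accuracy_percent = formatAccuracy(loocv$accuracy),
                     confusion = apply(loocv$confusion, 1, as.list),
                     predictions = loocv$predictions),
        permutation = if (!is.null(permRes)) list(
            n_permutations = permRes$n_permutations,
            observed_accuracy = permRes$observed_accuracy,
            p_empirical = permRes$p_empirical,
            p_gaussian = permRes$p_gaussian,
            permuted_accuracies = permRes$permuted_accuracies),
        ensemble = list(n_runs = nRuns, base_seed = deriveSeed(seed, 1L),
                        pairs_k = pairsK,
                        n_network_edges = nrow(net$edges)),
        files = as.list(list.files(outDir)))
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
    invisible(report)
}

# long form of a confusion matrix for TSV export
confusionToLong <- function(cm) {
    data.frame(true = rep(rownames(cm), times = ncol(cm)),
               predicted = rep(colnames(cm), each = nrow(cm)),
               count = as.integer(cm))
}
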