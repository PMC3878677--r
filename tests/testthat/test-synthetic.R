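test_that("study designs reproduce the explant layout and reject degenerates", {
    d <- generateDesign()
    expect_equal(length(d@classes), 4)
    expect_equal(sum(d@replicatesPerClass), 24)
    expect_equal(d@defaultClass, "control")
    expect_equal(d@subjects, 2L)
    s <- designSamples(d)
    expect_equal(nrow(s), 24)
    expect_equal(as.integer(table(s$class)[d@classes]), rep(6L, 4))
    expect_equal(sort(unique(s$subject)), c("1", "2"))

    d2 <- generateDesign(FALSE, classes = c("a", "b"), replicates = c(3, 5))
    expect_equal(nrow(designSamples(d2)), 8)
    expect_error(generateDesign(FALSE, classes = "only"), "2 classes")
})

test_that("peptide tables are seed-reproducible and config-validated", {
    d <- generateDesign()
    cfg <- testGeneratorConfig(seed = 7)
    t1 <- generatePeptideTable(d, cfg)
    t2 <- generatePeptideTable(d, cfg)
    expect_identical(t1, t2)
    expect_true(all(t1$observed_peptides >= 0))
    expect_true(all(t1$observable_peptides >= 1))
    # one row per (protein, sample)
    expect_equal(nrow(t1), (20 + 4) * 24)
    # invalid config fields named
    expect_error(generatorConfig(seed = 1, dropoutProb = 1), "dropoutProb")
    expect_error(generatorConfig(seed = 1, noiseCV = -1), "noiseCV")
    expect_error(generatorConfig(), "seed")
    expect_error(generatorConfig(seed = 1,
                                 anomalousSample = list(class = "x",
                                                        fraction = 0.5)),
                 "fraction")
})

test_that("empty generator configuration yields zero protein rows", {
    d <- generateDesign()
    cfg <- generatorConfig(seed = 1, nBackgroundProteins = 0,
                           markers = list(), anomalousSample = NULL)
    expect_equal(nrow(generatePeptideTable(d, cfg)), 0)
})

test_that("planted markers have elevated observed counts (Monte Carlo)", {
    # noise-free: one marker at multiplier 10, >= 1000 draws per group
    d <- generateDesign(FALSE, classes = c("control", "treated"),
                        replicates = 1000)
    cfg <- generatorConfig(seed = 99, nBackgroundProteins = 0,
                           markers = list(markerSpec("MK", "treated",
                                                     presenceOther = 1)),
                           dropoutProb = 0, noiseCV = 0, subjectCV = 0,
                           anomalousSample = NULL)
    tab <- generatePeptideTable(d, cfg)
    cls <- sub("_s\\d+_r\\d+$", "", tab$sample_id)
    mTreated <- mean(tab$observed_peptides[cls == "treated"])
    mControl <- mean(tab$observed_peptides[cls == "control"])
    expect_gte(mTreated, 5 * mControl)
})

test_that("quant matrices respect score ranges and the anomalous sample", {
    d <- generateDesign()
    cfg <- generatorConfig(seed = 3)   # full-scale world for the filter
    qp <- generateQuantMatrix(d, cfg, "probability")
    expect_lte(max(scoreMatrix(qp)), 1)
    expect_gte(min(scoreMatrix(qp)), 0)
    qe <- generateQuantMatrix(d, cfg, "empai")
    nz <- colSums(scoreMatrix(qe) > 0)
    anom <- S4Vectors::metadata(qe)$anomalousSample
    expect_equal(sub("_s\\d+_r\\d+$", "", anom), "IL1b_carprofen")
    expect_lte(nz[anom], 0.05 * stats::median(nz))
    expect_equal(sum(nz <= 0.05 * stats::median(nz)), 1)
    # labels attached per design
    expect_equal(as.integer(sort(table(sampleClasses(qe)))), rep(6L, 4))
    # determinism
    expect_identical(scoreMatrix(qe),
                     scoreMatrix(generateQuantMatrix(d, cfg, "empai")))
})

test_that("marker class means exceed control means across seeds", {
    # multiplier 10, dropout 0.1: holds in >= 95% of seeds
    d <- generateDesign()
    hits <- vapply(1:100, function(s) {
        cfg <- generatorConfig(seed = s, nBackgroundProteins = 2,
                               markers = list(
                                   markerSpec("MMP3",
                                              c("IL1b", "IL1b_carprofen"))),
                               dropoutProb = 0.1, anomalousSample = NULL)
        qm <- generateQuantMatrix(d, cfg, "probability")
        y <- sampleClasses(qm)
        v <- scoreMatrix(qm)["MMP3|probability", ]
        all(mean(v[y == "IL1b"]) > mean(v[y == "control"]),
            mean(v[y == "IL1b_carprofen"]) > mean(v[y == "control"]))
    }, logical(1))
    expect_gte(mean(hits), 0.95)
})
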