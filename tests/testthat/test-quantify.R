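test_that("PAI is observed over observable peptides, with guarded inputs", {
    expect_equal(computePAI(4, 8), 0.5)
    expect_equal(computePAI(0, 10), 0)
    expect_equal(computePAI(10, 10), 1)
    expect_equal(computePAI(c(1, 2), c(4, 4)), c(0.25, 0.5))
    expect_error(computePAI(1, 0, accession = "P12345"), "P12345")
    expect_error(computePAI(-1, 5), ">= 0")
})

test_that("emPAI is 10^PAI - 1", {
    expect_equal(computeEmpai(0), 0)
    expect_equal(computeEmpai(1), 9)
    expect_equal(round(computeEmpai(0.5), 4), 2.1623)
    expect_error(computeEmpai(-0.1), "nonnegative")
    # exhaustive check of the composition against independent arithmetic
    for (O in 1:50) {
        o <- 0:O
        expect_equal(computeEmpai(computePAI(o, O)), 10^(o / O) - 1)
    }
    # strictly increasing
    p <- seq(0, 3, by = 0.1)
    expect_true(all(diff(computeEmpai(p)) > 0))
})

test_that("protein probability combines independent peptide evidence", {
    expect_equal(proteinProbability(c(0.5, 0.5)), 0.75)
    expect_equal(proteinProbability(c(1, 0.2)), 1)
    expect_equal(proteinProbability(c(0.9, 0.9, 0.9)), 0.999)
    expect_error(proteinProbability(numeric()), "nonempty")
    expect_error(proteinProbability(c(0.5, 1.2)), "\\[0, 1\\]")
    # monotone nondecreasing in each component
    base <- proteinProbability(c(0.3, 0.4))
    expect_gte(proteinProbability(c(0.5, 0.4)), base)
    expect_gte(proteinProbability(c(0.3, 0.6)), base)
})

test_that("matrix assembly fills the protein-sample union with zeros", {
    rec <- data.frame(protein_id = c("A", "B", "C", "A"),
                      sample_id = c("s1", "s1", "s1", "s2"),
                      score = c(1, 2, 3, 4))
    qm <- assembleMatrix(rec, c(s1 = "control", s2 = "IL1b"), "empai")
    expect_equal(dim(qm), c(3L, 2L))
    expect_equal(sum(scoreMatrix(qm) == 0), 2)  # B, C absent from s2
    expect_equal(unname(scoreMatrix(qm)["A|empai", ]), c(1, 4))
    # order independence
    qm2 <- assembleMatrix(rec[c(4, 2, 1, 3), ],
                          c(s2 = "IL1b", s1 = "control"), "empai")
    expect_identical(scoreMatrix(qm), scoreMatrix(qm2))
    expect_identical(sampleClasses(qm), sampleClasses(qm2))
})

test_that("matrix assembly rejects degenerate input", {
    expect_error(assembleMatrix(data.frame(), c(s1 = "control")), "empty")
    rec <- data.frame(protein_id = "A", sample_id = "s1", score = 1)
    expect_error(assembleMatrix(rec, c(other = "control")), "s1")
    dup <- rbind(rec, rec)
    expect_error(assembleMatrix(dup, c(s1 = "control")), "duplicate")
})

test_that("peptide tables assemble to element-wise emPAI", {
    tab <- expand.grid(protein_id = c("A", "B"),
                       sample_id = c("s1", "s2", "s3"),
                       stringsAsFactors = FALSE)
    set.seed(11)
    tab$observable_peptides <- rep(c(10L, 20L), 3)
    tab$observed_peptides <- sample(0:15, 6)
    qm <- assembleMatrix(tab, c(s1 = "a", s2 = "a", s3 = "b"), "empai")
    for (i in seq_len(nrow(tab))) {
        fid <- paste0(tab$protein_id[i], "|empai")
        expect_equal(scoreMatrix(qm)[fid, tab$sample_id[i]],
                     10^(tab$observed_peptides[i] /
                         tab$observable_peptides[i]) - 1)
    }
})

test_that("combining matrices forms score-type-tagged feature unions", {
    m1 <- matrix(1:6, 3, 2, dimnames = list(c("A", "B", "C"), c("s1", "s2")))
    m2 <- matrix(seq(0.1, 0.4, 0.1), 2, 2,
                 dimnames = list(c("A", "D"), c("s1", "s2")))
    labs <- c(s1 = "control", s2 = "IL1b")
    a <- QuantMatrix(m1, "empai", labs)
    b <- QuantMatrix(m2, "probability", labs)
    ab <- combineMatrices(a, b)
    expect_equal(nrow(ab), 5)
    expect_equal(ncol(ab), 2)
    # same accession twice, tagged by score type
    expect_true(all(c("A|empai", "A|probability") %in% featureIds(ab)))
    # symmetric up to feature ordering
    ba <- combineMatrices(b, a)
    expect_identical(scoreMatrix(ab)[sort(featureIds(ab)), ],
                     scoreMatrix(ba)[sort(featureIds(ba)), ])
    # same score type twice duplicates feature ids
    expect_error(combineMatrices(a, a), "overlap")
    # mismatched samples
    c2 <- QuantMatrix(m1[, 1, drop = FALSE], "empai", c(s1 = "control"))
    expect_error(combineMatrices(a, c2), "differ")
})

test_that("anomalous-sample filter drops low-identification samples", {
    set.seed(42)
    m <- matrix(rpois(30 * 8, 3), 30, 8,
                dimnames = list(sprintf("P%02d", 1:30),
                                sprintf("s%d", 1:8)))
    m[m > 0] <- m[m > 0] + 0.5
    m[3:30, "s8"] <- 0  # s8 keeps ~2 of ~28 nonzero proteins
    qm <- QuantMatrix(m, "empai",
                      stats::setNames(rep(c("a", "b"), 4), colnames(m)))
    res <- suppressMessages(filterAnomalousSamples(qm, 0.25))
    expect_equal(res$removed, "s8")
    expect_equal(ncol(res$matrix), 7)
    # idempotent
    res2 <- filterAnomalousSamples(res$matrix, 0.25)
    expect_length(res2$removed, 0)
    expect_identical(scoreMatrix(res2$matrix), scoreMatrix(res$matrix))
    # uniform matrix: nothing removed at any threshold < 1
    u <- QuantMatrix(matrix(1, 4, 4, dimnames = list(letters[1:4],
                                                     LETTERS[1:4])),
                     "empai", stats::setNames(rep(c("a", "b"), 2),
                                              LETTERS[1:4]))
    expect_length(filterAnomalousSamples(u, 0.99)$removed, 0)
    expect_error(filterAnomalousSamples(qm, 1.2), "minFraction")
})

test_that("QuantMatrix validity catches bad objects", {
    m <- matrix(1, 1, 1, dimnames = list("A", "s1"))
    expect_error(QuantMatrix(m, "empai", c(s2 = "x")), "unlabeled")
    expect_error(QuantMatrix(matrix(2, 1, 1, dimnames = list("A", "s1")),
                             "probability", c(s1 = "x")), "exceed 1")
    expect_error(QuantMatrix(-m, "empai", c(s1 = "x")), "nonnegative")
})
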