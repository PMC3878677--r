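test_that("rule matching uses strict inequalities with zero for absences", {
    r1 <- Rule("TPIS", ">", 0.01, "IL1b")
    expect_true(ruleMatches(r1, c(TPIS = 0.02)))
    expect_false(ruleMatches(r1, c(TPIS = 0.01)))   # strict
    expect_false(ruleMatches(r1, c(OTHER = 5)))     # absent feature is 0
    r3 <- Rule(c("MMP3", "UBIB"), c(">", "<"), c(0, 0.2), "IL1b")
    expect_false(ruleMatches(r3, c(MMP3 = 0, UBIB = 0)))  # boundary fails
    expect_true(ruleMatches(r3, c(MMP3 = 1e-9, UBIB = 0.19)))
    # constructed satisfying assignment for an arbitrary rule
    r <- Rule(c("a", "b"), c(">", "<"), c(3, 7), "X")
    expect_true(ruleMatches(r, c(a = 4, b = 6)))
})

test_that("the printed example rule set classifies by first match", {
    rs <- printedRuleSet()
    expect_equal(unname(predict(rs, printedSample(TPIS = 0.02))), "IL1b")
    expect_equal(unname(predict(rs, printedSample())), "control")
    # both rule 1 and rule 2 match; the first wins
    expect_equal(unname(predict(rs, printedSample(TPIS = 0.02, IL8 = 0.03))),
                 "IL1b")
    expect_equal(unname(predict(rs, printedSample(IL8 = 0.03))),
                 "IL1b_carprofen")
    expect_equal(unname(predict(rs, printedSample(MGP = 0.5, A1AT = 0.1))),
                 "carprofen")
})

test_that("prediction agrees with brute-force rule evaluation", {
    set.seed(5)
    for (s in 1:25) {
        rs <- randomRuleSet(s)
        samp <- stats::setNames(round(stats::runif(12), 3),
                                sprintf("P%02d", 1:12))
        expect_equal(unname(predict(rs, samp)), oraclePredict(rs, samp))
    }
})

test_that("a separable toy admits a maximal one-condition rule and is learned", {
    qm <- toySeparableMatrix()
    X <- scoreMatrix(qm); y <- sampleClasses(qm)
    # exhaustive oracle: enumerate every 1-condition '>' rule over value
    # midpoints; the best achievable fitness is accuracy 1 with full class
    # coverage, and only protein A attains it
    bestByFeat <- vapply(rownames(X), function(f) {
        v <- sort(unique(X[f, ]))
        thr <- (v[-1] + v[-length(v)]) / 2
        best <- 0
        for (t in thr) {
            cov <- X[f, ] > t
            if (sum(cov) == 0) next
            acc <- max(mean(y[cov] == "X"), mean(y[cov] == "control"))
            best <- max(best, acc * min(1, sum(cov) / (0.15 * length(y))))
        }
        best
    }, numeric(1))
    expect_equal(unname(which.max(bestByFeat)), 1L)  # A|empai
    expect_equal(max(bestByFeat), 1)

    rs <- learnRuleSet(qm, learnerConfig(seed = 2))
    expect_equal(unname(predict(rs, qm)), unname(y))  # 100% training accuracy
    expect_true(all(vapply(rules(rs), predictedClass, "") != "control"))
})

test_that("constant data with strict accuracy yields a default-only set", {
    m <- matrix(1, 4, 8, dimnames = list(letters[1:4], sprintf("s%d", 1:8)))
    qm <- QuantMatrix(m, "empai",
                      stats::setNames(rep(c("control", "X"), 4),
                                      colnames(m)))
    rs <- learnRuleSet(qm, learnerConfig(seed = 1, minRuleAccuracy = 1))
    expect_length(rules(rs), 0)
    expect_equal(defaultClass(rs), "control")
})

test_that("the learner is deterministic under its seed and stochastic across", {
    qm <- generateQuantMatrix(generateDesign(), testGeneratorConfig(seed = 2))
    rs1 <- learnRuleSet(qm, fastLearner(seed = 11))
    rs2 <- learnRuleSet(qm, fastLearner(seed = 11))
    expect_identical(serializeRuleSet(rs1), serializeRuleSet(rs2))
    rs3 <- learnRuleSet(qm, fastLearner(seed = 12))
    expect_s4_class(rs3, "RuleSet")   # different seed: valid, possibly different
    expect_true(validObject(rs3))
})

test_that("learned thresholds fall strictly between observed feature values", {
    qm <- generateQuantMatrix(generateDesign(), testGeneratorConfig(seed = 4))
    X <- scoreMatrix(qm)
    for (s in 1:3) {
        rs <- learnRuleSet(qm, fastLearner(seed = s))
        for (r in rules(rs)) {
            cd <- ruleConditions(r)
            for (i in seq_len(nrow(cd))) {
                v <- X[cd$feature[i], ]
                expect_gt(cd$threshold[i], min(v))
                expect_lt(cd$threshold[i], max(v))
                expect_false(cd$threshold[i] %in% v)
            }
        }
        expect_false("control" %in% vapply(rules(rs), predictedClass, ""))
    }
})

test_that("learner rejects degenerate training input", {
    m <- matrix(1:4, 2, 2, dimnames = list(c("A", "B"), c("s1", "s2")))
    one <- QuantMatrix(m, "empai", c(s1 = "x", s2 = "x"))
    expect_error(learnRuleSet(one, learnerConfig(seed = 1)), "single class")
    expect_error(learnerConfig(seed = 1, generations = 0), "generations")
    expect_error(learnerConfig(), "seed")
})

test_that("rule sets serialize to text and parse back identically", {
    rs <- printedRuleSet()
    txt <- serializeRuleSet(rs)
    rs2 <- parseRuleSet(txt)
    expect_identical(serializeRuleSet(rs2), txt)
    expect_equal(length(rules(rs2)), 5)
    expect_identical(ruleConditions(rules(rs2)[[3]]),
                     data.frame(feature = c("MMP3", "UBIB"),
                                op = c(">", "<"), threshold = c(0, 0.2)))
    # empty rule set
    empty <- RuleSet(list(), "control", classes = c("control", "IL1b"))
    expect_equal(serializeRuleSet(empty), "DEFAULT control\n")
    expect_length(rules(parseRuleSet("DEFAULT control")), 0)
    # corrupted operator carries a line number
    expect_error(parseRuleSet("IF TPIS >= 0.1 THEN IL1b\nDEFAULT control"),
                 "line 1")
    expect_error(parseRuleSet("DEFAULT control\nIF A > 1 THEN B"), "final")
    # round-trip of learned rule sets, thresholds bit-exact
    qm <- toySeparableMatrix()
    for (s in 1:5) {
        rs <- learnRuleSet(qm, fastLearner(seed = s))
        back <- parseRuleSet(serializeRuleSet(rs))
        expect_equal(length(rules(back)), length(rules(rs)))
        for (i in seq_along(rules(rs)))
            expect_identical(ruleConditions(rules(back)[[i]]),
                             ruleConditions(rules(rs)[[i]]))
    }
})

test_that("rule and rule-set validity is enforced", {
    expect_error(Rule(character(), character(), numeric(), "X"),
                 "at least one")
    expect_error(Rule(c("A", "A"), c(">", ">"), c(1, 2), "X"), "duplicate")
    expect_error(Rule("A", ">", Inf, "X"), "finite")
    r <- Rule("A", ">", 1, "control")
    expect_error(RuleSet(list(r), "control"), "default")
})
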