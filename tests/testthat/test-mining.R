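test_that("ensembles are reproducible with consecutive seeds", {
    qm <- toySeparableMatrix()
    ens <- runEnsemble(qm, fastLearner(seed = 1), nRuns = 3, baseSeed = 500)
    expect_length(ens, 3)
    expect_equal(vapply(ens, function(rs) rs@seed, integer(1)), 500:502)
    ens2 <- runEnsemble(qm, fastLearner(seed = 99), nRuns = 3, baseSeed = 500)
    expect_identical(lapply(ens, serializeRuleSet),
                     lapply(ens2, serializeRuleSet))
})

test_that("every run on a separable toy uses the unique separator", {
    qm <- toySeparableMatrix()
    ens <- runEnsemble(qm, fastLearner(seed = 1), nRuns = 100, baseSeed = 1)
    usesA <- vapply(ens, function(rs)
        any(vapply(rules(rs), function(r) "A|empai" %in% r@features,
                   logical(1))), logical(1))
    expect_true(all(usesA))
})

test_that("protein ranking counts rule appearances per class", {
    rs <- printedRuleSet()
    rk <- rankProteins(list(rs))
    il1b <- rk$perClass$IL1b
    expect_setequal(il1b$feature, c("TPIS", "MMP3", "UBIB"))
    expect_true(all(il1b$count == 1))
    expect_equal(sum(il1b$share), 100)
    expect_false("control" %in% names(rk$perClass))
    # a feature in two conditions of one rule counts once
    dbl <- RuleSet(list(Rule(c("A", "A"), c(">", "<"), c(0, 9), "X")),
                   "control")
    expect_equal(rankProteins(list(dbl))$perClass$X$count, 1)
    # duplication doubles counts, leaves shares unchanged
    rk2 <- rankProteins(list(rs, rs))
    expect_equal(rk2$perClass$IL1b$count, 2 * il1b$count)
    expect_equal(rk2$perClass$IL1b$share, il1b$share)
    # zero-rule sets rank nothing
    expect_length(rankProteins(list(RuleSet(list(), "control")))$perClass, 0)
})

test_that("pair extraction enumerates 2-subsets of multi-feature rules", {
    rs <- printedRuleSet()
    pc <- extractPairs(list(rs))
    expect_equal(nrow(pc), 2)
    expect_true(any(pc$a == "MMP3" & pc$b == "UBIB" & pc$class == "IL1b"))
    expect_true(any(pc$a == "A1AT" & pc$b == "MGP" &
                    pc$class == "carprofen"))
    expect_true(all(pc$a < pc$b))
    # three features give all three pairs
    tri <- RuleSet(list(Rule(c("C", "A", "B"), rep(">", 3), 1:3, "X")),
                   "control")
    ptri <- extractPairs(list(tri))
    expect_equal(nrow(ptri), 3)
    expect_setequal(paste(ptri$a, ptri$b), c("A B", "A C", "B C"))
    # single-feature rules contribute nothing
    single <- RuleSet(list(Rule("A", ">", 1, "X")), "control")
    expect_equal(nrow(extractPairs(list(single))), 0)
})

test_that("ranking and pairs match brute-force oracles on random sets", {
    rulesets <- lapply(1:120, randomRuleSet)
    rk <- rankProteins(rulesets)
    oracle <- oracleRankCounts(rulesets)
    expect_setequal(names(rk$perClass), names(oracle))
    for (cls in names(oracle)) {
        got <- stats::setNames(rk$perClass[[cls]]$count,
                               rk$perClass[[cls]]$feature)
        expect_equal(got[sort(names(got))],
                     oracle[[cls]][sort(names(oracle[[cls]]))])
        # sorted by decreasing count
        expect_true(all(diff(rk$perClass[[cls]]$count) <= 0))
    }
    pc <- extractPairs(rulesets)
    opc <- oraclePairCounts(rulesets)
    key <- function(d) paste(d$a, d$b, d$class)
    expect_setequal(key(pc), key(opc))
    expect_equal(pc$count[match(key(opc), key(pc))], opc$count)
})

test_that("ranking counts grow monotonically with more runs", {
    rulesets <- lapply(1:40, randomRuleSet)
    rkSmall <- rankProteins(rulesets[1:20])
    rkFull <- rankProteins(rulesets)
    for (cls in names(rkSmall$perClass)) {
        small <- rkSmall$perClass[[cls]]
        full <- rkFull$perClass[[cls]]
        expect_true(all(small$feature %in% full$feature))
        expect_true(all(full$count[match(small$feature, full$feature)] >=
                        small$count))
    }
})

test_that("networks retain the top-k pairs per class deterministically", {
    rulesets <- lapply(1:120, randomRuleSet)
    pc <- extractPairs(rulesets)
    net <- buildNetwork(pc, k = 5)
    perClass <- table(net$edges$class)
    expect_true(all(perClass <= 5))
    expect_lte(nrow(net$edges), 5 * length(unique(pc$class)))
    expect_true(all(net$edges$a < net$edges$b))  # no self-loops, ordered
    expect_false("control" %in% net$edges$class)
    # truncation floor: a class with fewer pairs keeps them all
    few <- pc[pc$class == pc$class[1], ][1:3, ]
    expect_equal(nrow(buildNetwork(few, k = 100)$edges), 3)
    # k = 1 keeps exactly one edge per class, ties broken deterministically
    n1a <- buildNetwork(pc, k = 1)
    n1b <- buildNetwork(pc[sample(nrow(pc)), ], k = 1)
    expect_equal(n1a$edges[order(n1a$edges$class), ],
                 n1b$edges[order(n1b$edges$class), ],
                 ignore_attr = TRUE)
})

test_that("most connected proteins are ranked by distinct neighbours", {
    hub <- do.call(rbind, lapply(letters[2:6], function(l)
        data.frame(a = "H", b = l, class = "IL1b", count = 2)))
    hub$a <- pmin(hub$a, hub$b); hub$b <- pmax("H", hub$b)
    net <- buildNetwork(data.frame(a = "H", b = letters[2:6],
                                   class = "IL1b", count = 5:1), k = 100)
    mc <- mostConnected(net, 3)
    expect_equal(mc$feature[1], "H")
    expect_equal(mc$degree[1], 5)
    # topN larger than the node count returns everything
    expect_equal(nrow(mostConnected(net, 50)), 6)
    expect_error(mostConnected(buildNetwork(
        data.frame(a = character(), b = character(), class = character(),
                   count = integer()), 1), 3), "empty")
    # independent cross-check with igraph on a random network
    skip_if_not_installed("igraph")
    pc <- extractPairs(lapply(1:80, randomRuleSet))
    net2 <- buildNetwork(pc, k = 20)
    g <- igraph::graph_from_data_frame(unique(net2$edges[c("a", "b")]),
                                       directed = FALSE)
    degs <- igraph::degree(g)
    mc2 <- mostConnected(net2, length(net2$nodes))
    expect_equal(stats::setNames(mc2$degree, mc2$feature)[names(degs)],
                 degs)
})
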