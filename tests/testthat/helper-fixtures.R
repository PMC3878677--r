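# Shared fixtures: the published example rule set, toy matrices, random
# rule-set generators, and independent brute-force oracles.

# The six-line example rule set (ASCII class ids), as serialized text. Rule
# order matters: first match wins, control is the default.
printedRuleSetText <- function() {
    paste(
        "IF TPIS > 0.01 THEN IL1b",
        "IF IL8 > 0.02 THEN IL1b_carprofen",
        "IF MMP3 > 0 AND UBIB < 0.2 THEN IL1b",
        "IF MGP > 0 AND A1AT < 0.9 THEN carprofen",
        "IF ALBU > 0.01 THEN IL1b_carprofen",
        "DEFAULT control",
        sep = "\n")
}

printedRuleSet <- function() parseRuleSet(printedRuleSetText())

# a sample over the printed rule set's features; unspecified features are 0
printedSample <- function(...) {
    v <- stats::setNames(rep(0, 6),
                         c("TPIS", "IL8", "MMP3", "UBIB", "MGP", "A1AT"))
    over <- c(...)
    v[names(over)] <- over
    v
}

# perfectly separable toy: protein A scores > 0 exactly in class X
toySeparableMatrix <- function(nPerClass = 4) {
    n <- 2 * nPerClass
    ids <- sprintf("t%02d", seq_len(n))
    m <- matrix(0, 3, n, dimnames = list(c("A", "B", "C"), ids))
    cls <- rep(c("X", "control"), each = nPerClass)
    m["A", cls == "X"] <- seq(0.5, 1.5, length.out = nPerClass)
    m["B", ] <- rep(c(0.3, 0.4), length.out = n)   # uninformative
    m["C", ] <- seq(0.1, 0.9, length.out = n)      # uninformative gradient
    QuantMatrix(m, "empai", classes = stats::setNames(cls, ids))
}

# random rule sets for oracle-equivalence fixtures
randomRuleSet <- function(seed, features = sprintf("P%02d", 1:12),
                          classes = c("IL1b", "carprofen", "IL1b_carprofen")) {
    withr::with_seed(seed, {
        nr <- sample(0:5, 1)
        rules <- lapply(seq_len(nr), function(i) {
            k <- sample(1:3, 1)
            f <- sample(features, k)
            Rule(f, sample(c(">", "<"), k, replace = TRUE),
                 round(stats::runif(k), 3), sample(classes, 1))
        })
        RuleSet(rules, "control", classes = c("control", classes))
    })
}

# ---- independent oracles (work from serialized text, not from Rule objects)

# parse serialized lines into a data.frame of (class, features-string)
.oracleRuleLines <- function(rulesets) {
    txt <- unlist(lapply(rulesets, serializeRuleSet))
    lines <- unlist(strsplit(txt, "\n"))
    lines[grepl("^IF ", lines)]
}

# per-class feature counts, counting a feature once per rule it appears in
oracleRankCounts <- function(rulesets) {
    lines <- .oracleRuleLines(rulesets)
    out <- list()
    for (ln in lines) {
        cls <- sub("^.* THEN ", "", ln)
        body <- sub(" THEN .*$", "", sub("^IF ", "", ln))
        conds <- strsplit(body, " AND ", fixed = TRUE)[[1]]
        feats <- unique(vapply(strsplit(conds, " "), `[[`, "", 1))
        for (f in feats)
            out[[cls]][f] <- (if (is.null(out[[cls]][f]) ||
                                  is.na(out[[cls]][f])) 0
                              else out[[cls]][f]) + 1
    }
    out
}

# per-class unordered pair counts from multi-feature rules
oraclePairCounts <- function(rulesets) {
    lines <- .oracleRuleLines(rulesets)
    out <- new.env()
    for (ln in lines) {
        cls <- sub("^.* THEN ", "", ln)
        body <- sub(" THEN .*$", "", sub("^IF ", "", ln))
        conds <- strsplit(body, " AND ", fixed = TRUE)[[1]]
        feats <- sort(unique(vapply(strsplit(conds, " "), `[[`, "", 1)))
        if (length(feats) < 2) next
        for (i in seq_len(length(feats) - 1))
            for (j in seq(i + 1, length(feats))) {
                key <- paste(feats[i], feats[j], cls, sep = "\r")
                cur <- mget(key, out, ifnotfound = 0)[[1]]
                assign(key, cur + 1, out)
            }
    }
    keys <- ls(out)
    if (!length(keys))
        return(data.frame(a = character(), b = character(),
                          class = character(), count = integer()))
    parts <- strsplit(keys, "\r", fixed = TRUE)
    data.frame(a = vapply(parts, `[[`, "", 1),
               b = vapply(parts, `[[`, "", 2),
               class = vapply(parts, `[[`, "", 3),
               count = as.integer(unlist(mget(keys, out))),
               stringsAsFactors = FALSE)
}

# brute-force first-match prediction of one sample (named vector)
oraclePredict <- function(rs, sample) {
    for (r in rules(rs)) {
        cd <- ruleConditions(r)
        v <- sample[cd$feature]
        v[is.na(v)] <- 0
        ok <- all(ifelse(cd$op == ">", v > cd$threshold, v < cd$threshold))
        if (ok) return(predictedClass(r))
    }
    defaultClass(rs)
}

# small generator config used across tests (fewer background proteins for
# speed; the full default world is exercised in the acceptance tests)
testGeneratorConfig <- function(seed, ...) {
    generatorConfig(seed = seed, nBackgroundProteins = 20, ...)
}

fastLearner <- function(seed, ...) {
    learnerConfig(seed = seed, generations = 6, populationSize = 12, ...)
}
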