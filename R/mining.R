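#' Train an ensemble of rule sets
#'
#' Runs the stochastic learner `nRuns` times on the full matrix with seeds
#' `baseSeed, baseSeed + 1, ...`; because the learner is stochastic, distinct
#' seeds yield different rule sets whose recurrent structure the mining
#' functions extract. The study ran its learner 10,000 times.
#'
#' @param x a [QuantMatrix-class].
#' @param config a [learnerConfig()] (its seed is ignored in favour of the
#'   per-run seeds).
#' @param nRuns number of runs (>= 1).
#' @param baseSeed seed of the first run.
#' @param progressEvery log a progress message every this many runs (0 to
#'   silence).
#' @return list of [RuleSet-class] objects, one per run.
#' @examples
#' \donttest{
#' qm <- generateQuantMatrix(generateDesign(), generatorConfig(seed = 1))
#' ens <- runEnsemble(qm, learnerConfig(seed = 1, generations = 5,
#'                                      populationSize = 10), nRuns = 3,
#'                    baseSeed = 100)
#' length(ens)
#' }
#' @export
runEnsemble <- function(x, config, nRuns = 10000, baseSeed = config$seed,
                        progressEvery = 0) {
    stopifnot(nRuns >= 1)
    out <- vector("list", nRuns)
    for (i in seq_len(nRuns)) {
        cfg <- config
        cfg$seed <- as.integer((as.double(baseSeed) + i - 1) %% 2147483647)
        out[[i]] <- tryCatch(learnRuleSet(x, cfg),
                             error = function(e)
                                 stop("ensemble run ", i, ": ",
                                      conditionMessage(e)))
        if (progressEvery > 0 && i %% progressEvery == 0)
            message(sprintf("ensemble: %d/%d runs", i, nRuns))
    }
    out
}

#' Rank proteins by how often they appear in rules
#'
#' For every non-default class, counts how many rules predicting that class
#' use each feature; a feature occurring in several conditions of one rule is
#' counted once for that rule. `share` expresses the count as a percentage of
#' all feature-appearances in that class's rules. There is no ranking for the
#' default class, which by construction has no rules.
#'
#' @param rulesets nonempty list of [RuleSet-class] objects.
#' @return object of class `ProteinRanking`: list with `perClass` (named
#'   list of data.frames `feature`, `count`, `share`, sorted by decreasing
#'   count, ties broken by feature id), `nRuns`, and `nRulesPerClass`.
#' @examples
#' rs <- RuleSet(list(Rule(c("MMP3", "UBIB"), c(">", "<"), c(0, 0.2),
#'                         "IL1b")), "control")
#' rankProteins(list(rs))$perClass$IL1b
#' @export
rankProteins <- function(rulesets) {
    stopifnot(length(rulesets) >= 1)
    counts <- list()   # class -> named numeric vector of feature counts
    nRules <- integer()
    for (rs in rulesets) {
        for (r in rs@rules) {
            cls <- r@predictedClass
            feats <- unique(r@features)
            if (is.null(counts[[cls]])) counts[[cls]] <- numeric()
            cur <- counts[[cls]]
            hit <- feats %in% names(cur)
            cur[feats[hit]] <- cur[feats[hit]] + 1
            cur[feats[!hit]] <- 1
            counts[[cls]] <- cur
            nRules[cls] <- (if (is.na(nRules[cls])) 0L
                            else nRules[cls]) + 1L
        }
    }
    perClass <- lapply(counts, function(cnt) {
        total <- sum(cnt)
        ord <- order(-cnt, names(cnt))
        data.frame(feature = names(cnt)[ord], count = unname(cnt[ord]),
                   share = unname(100 * cnt[ord] / total),
                   stringsAsFactors = FALSE, row.names = NULL)
    })
    if (length(perClass)) perClass <- perClass[order(names(perClass))]
    if (length(nRules)) nRules <- nRules[order(names(nRules))]
    structure(list(perClass = perClass, nRuns = length(rulesets),
                   nRulesPerClass = nRules),
              class = "ProteinRanking")
}

#' @export
print.ProteinRanking <- function(x, ...) {
    cat(sprintf("ProteinRanking over %d run(s)\n", x$nRuns))
    for (cls in names(x$perClass)) {
        top <- utils::head(x$perClass[[cls]], 5)
        cat(sprintf("  %s (%d rules): %s\n", cls, x$nRulesPerClass[[cls]],
                    paste(sprintf("%s (%.1f)", top$feature, top$share),
                          collapse = ", ")))
    }
    invisible(x)
}

#' Extract per-class protein-pair counts from rule sets
#'
#' Every rule using two or more distinct features contributes one count for
#' each unordered feature pair within it, attributed to the rule's predicted
#' class; single-feature rules contribute nothing.
#'
#' @param rulesets nonempty list of [RuleSet-class] objects.
#' @return data.frame with columns `a`, `b` (feature ids, `a < b`
#'   lexicographically), `class`, `count`, sorted by class, decreasing
#'   count, then pair.
#' @examples
#' rs <- RuleSet(list(Rule(c("MGP", "A1AT"), c(">", "<"), c(0, 0.9),
#'                         "carprofen")), "control")
#' extractPairs(list(rs))
#' @export
extractPairs <- function(rulesets) {
    stopifnot(length(rulesets) >= 1)
    rows <- list()
    for (rs in rulesets) {
        for (r in rs@rules) {
            feats <- sort(unique(r@features))
            if (length(feats) < 2L) next
            idx <- utils::combn(length(feats), 2L)
            rows[[length(rows) + 1L]] <-
                data.frame(a = feats[idx[1L, ]], b = feats[idx[2L, ]],
                           class = r@predictedClass,
                           stringsAsFactors = FALSE)
        }
    }
    if (length(rows) == 0L)
        return(data.frame(a = character(), b = character(),
                          class = character(), count = integer()))
    all <- do.call(rbind, rows)
    agg <- stats::aggregate(list(count = rep(1L, nrow(all))),
                            all[c("a", "b", "class")], FUN = sum)
    agg <- agg[order(agg$class, -agg$count, agg$a, agg$b), ]
    rownames(agg) <- NULL
    agg[c("a", "b", "class", "count")]
}

#' Build a per-class top-k protein-pair network
#'
#' For each class, retains the `k` most frequent pairs (ties broken
#' lexicographically by pair) and unions them into one weighted graph whose
#' edges carry the class and count; a class with fewer than `k` distinct
#' pairs keeps them all. The study retained the top 100 pairs per treatment
#' class.
#'
#' @param pairCounts data.frame from [extractPairs()].
#' @param k pairs retained per class (>= 1), default 100.
#' @return object of class `PairNetwork`: list with `edges` (data.frame `a`,
#'   `b`, `class`, `count`), `nodes` (character), `k`.
#' @export
buildNetwork <- function(pairCounts, k = 100) {
    stopifnot(k >= 1)
    edges <- do.call(rbind, lapply(split(pairCounts, pairCounts$class),
        function(d) {
            d <- d[order(-d$count, d$a, d$b), ]
            utils::head(d, k)
        }))
    if (is.null(edges))
        edges <- data.frame(a = character(), b = character(),
                            class = character(), count = integer())
    rownames(edges) <- NULL
    structure(list(edges = edges,
                   nodes = sort(unique(c(edges$a, edges$b))),
                   k = as.integer(k)),
              class = "PairNetwork")
}

#' @export
print.PairNetwork <- function(x, ...) {
    cat(sprintf("PairNetwork: %d node(s), %d edge(s), k = %d per class\n",
                length(x$nodes), nrow(x$edges), x$k))
    if (nrow(x$edges)) {
        tab <- table(x$edges$class)
        cat("  edges per class:",
            paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
            "\n")
    }
    invisible(x)
}

#' Most connected proteins of a pair network
#'
#' Degree is the number of distinct neighbours a node has across all classes
#' (parallel edges of different classes between the same pair count once).
#'
#' @param net a [buildNetwork()] result with at least one edge.
#' @param topN number of nodes to return (all nodes if larger than the node
#'   count).
#' @return data.frame with columns `feature`, `degree`, sorted by decreasing
#'   degree, ties by feature id.
#' @export
mostConnected <- function(net, topN = 10) {
    stopifnot(inherits(net, "PairNetwork"))
    if (nrow(net$edges) == 0L) stop("empty network")
    pairs <- unique(net$edges[c("a", "b")])
    deg <- table(c(pairs$a, pairs$b))
    out <- data.frame(feature = names(deg), degree = as.integer(deg),
                      stringsAsFactors = FALSE)
    out <- out[order(-out$degree, out$feature), ]
    rownames(out) <- NULL
    utils::head(out, topN)
}
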