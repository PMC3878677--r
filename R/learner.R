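#' Learner configuration
#'
#' Settings for the seeded evolutionary rule search. One rule at a time is
#' evolved by a generational genetic algorithm over candidate threshold
#' conditions; sequential covering then removes the samples the accepted rule
#' matches and repeats.
#'
#' @param seed integer RNG seed (required; same seed + same data gives an
#'   identical rule set).
#' @param generations GA generations per rule.
#' @param populationSize GA population per rule.
#' @param maxConditions maximum conditions per rule (default 3; observed
#'   rule sets use 1–2 conditions, 3 leaves headroom).
#' @param coverageBreakpoint fraction of the remaining training samples a
#'   rule should cover before its fitness stops being penalised, in (0, 1].
#'   The default 0.15 suits a four-class design: a rule covering most of one
#'   class escapes the penalty, so a genuinely discriminating rule that
#'   misses a dropped-out sample is not outcompeted by broader but impurer
#'   chance rules.
#' @param minRuleAccuracy minimum accuracy (on the samples a rule matches)
#'   for the rule to be accepted.
#' @param maxRules cap on rules per set.
#' @param minRuleCoverage minimum number of correctly classified training
#'   samples a rule must cover to be accepted (default 2): rules fitted to a
#'   single straggler sample generalise at chance and poison first-match
#'   prediction for default-class samples, so under-covering is preferred.
#' @param ruleChoiceSlack stochastic rule choice: after the search, the
#'   appended rule is drawn (rank-weighted, P(rank r) ~ 0.25^r) from the
#'   distinct admissible rule families (class + feature/op set) whose
#'   accuracy-times-coverage score, before the parsimony penalty, is within
#'   this relative slack of the best. This is what makes repeated runs produce different
#'   rule sets — the ensemble-mining stage depends on that diversity — while
#'   single-run quality stays close to the deterministic optimum. Set to 0
#'   to restrict the draw to exact fitness ties.
#' @param conditionPenalty parsimony pressure: fitness is multiplied by
#'   `1 - conditionPenalty * (conditions - 1)`, so a multi-condition rule
#'   must beat a simpler one by a margin. With few samples and many protein
#'   features, spuriously perfect conjunctions over noise features are
#'   common; this biases the search towards simple, generalising rules.
#' @return a validated `LearnerConfig` list.
#' @examples
#' learnerConfig(seed = 1)
#' @export
learnerConfig <- function(seed, generations = 16, populationSize = 24,
                          maxConditions = 3, coverageBreakpoint = 0.15,
                          minRuleAccuracy = 0.75, maxRules = 10,
                          minRuleCoverage = 2, conditionPenalty = 0.15,
                          ruleChoiceSlack = 0.1) {
    if (missing(seed) || length(seed) != 1L || is.na(seed))
        stop("invalid 'seed': a single integer is required")
    counts <- c(generations = generations, populationSize = populationSize,
                maxConditions = maxConditions, maxRules = maxRules,
                minRuleCoverage = minRuleCoverage)
    bad <- names(counts)[counts < 1]
    if (length(bad)) stop("invalid (must be >= 1): ",
                          paste(bad, collapse = ", "))
    if (coverageBreakpoint <= 0 || coverageBreakpoint > 1)
        stop("invalid 'coverageBreakpoint': must be in (0, 1]")
    if (minRuleAccuracy < 0 || minRuleAccuracy > 1)
        stop("invalid 'minRuleAccuracy': must be in [0, 1]")
    if (conditionPenalty < 0 || conditionPenalty > 0.5)
        stop("invalid 'conditionPenalty': must be in [0, 0.5]")
    if (ruleChoiceSlack < 0 || ruleChoiceSlack > 0.5)
        stop("invalid 'ruleChoiceSlack': must be in [0, 0.5]")
    structure(list(seed = as.integer(seed),
                   generations = as.integer(generations),
                   populationSize = as.integer(populationSize),
                   maxConditions = as.integer(maxConditions),
                   coverageBreakpoint = coverageBreakpoint,
                   minRuleAccuracy = minRuleAccuracy,
                   maxRules = as.integer(maxRules),
                   minRuleCoverage = as.integer(minRuleCoverage),
                   conditionPenalty = conditionPenalty,
                   ruleChoiceSlack = ruleChoiceSlack),
              class = "LearnerConfig")
}

#' Does a rule match a sample?
#'
#' A rule matches iff every one of its conditions holds under strict
#' inequality. A feature absent from the sample scores 0 (a protein not
#' identified in a sample), so `feature > 0` fails for absent proteins.
#'
#' @param rule a [Rule-class].
#' @param sample named numeric vector of feature scores.
#' @return logical.
#' @examples
#' r <- Rule(c("MMP3", "UBIB"), c(">", "<"), c(0, 0.2), "IL1b")
#' ruleMatches(r, c(MMP3 = 0, UBIB = 0))    # FALSE: strict inequality at 0
#' ruleMatches(r, c(MMP3 = 0.5, UBIB = 0))  # TRUE
#' @export
ruleMatches <- function(rule, sample) {
    stopifnot(is(rule, "Rule"))
    v <- sample[rule@features]
    v[is.na(v)] <- 0
    all(ifelse(rule@ops == ">", v > rule@thresholds, v < rule@thresholds))
}

# vectorised matching of one rule against a features x samples matrix;
# features absent from the matrix score 0 for every sample
.ruleMatchesMatrix <- function(features, ops, thresholds, X) {
    matched <- rep(TRUE, ncol(X))
    for (j in seq_along(features)) {
        row <- match(features[j], rownames(X))
        v <- if (is.na(row)) numeric(ncol(X)) else X[row, ]
        matched <- matched & (if (ops[j] == ">") v > thresholds[j]
                              else v < thresholds[j])
    }
    matched
}

#' Predict classes with a rule set
#'
#' First-match semantics: a sample is assigned the predicted class of the
#' first rule (in order) whose conditions it satisfies; a sample matching no
#' rule is assigned the default class.
#'
#' @param object a [RuleSet-class].
#' @param newdata a named numeric vector (one sample), a features-by-samples
#'   numeric matrix, or a [QuantMatrix-class].
#' @param ... ignored.
#' @return character vector of predicted classes, one per sample.
#' @examples
#' rs <- RuleSet(list(Rule("TPIS", ">", 0.01, "IL1b")), "control")
#' predict(rs, c(TPIS = 0.02))   # "IL1b"
#' predict(rs, c(TPIS = 0))      # "control"
#' @export
setMethod("predict", "RuleSet", function(object, newdata, ...) {
    if (is(newdata, "QuantMatrix")) newdata <- scoreMatrix(newdata)
    if (is.null(dim(newdata)))
        newdata <- matrix(newdata, ncol = 1,
                          dimnames = list(names(newdata), "sample"))
    pred <- rep(object@defaultClass, ncol(newdata))
    unassigned <- rep(TRUE, ncol(newdata))
    for (r in object@rules) {
        if (!any(unassigned)) break
        hit <- .ruleMatchesMatrix(r@features, r@ops, r@thresholds, newdata)
        take <- unassigned & hit
        pred[take] <- r@predictedClass
        unassigned <- unassigned & !hit
    }
    stats::setNames(pred, colnames(newdata))
})

# ---- evolutionary search for one rule ---------------------------------------

# candidate: list(cls, feat (int), op (+1 / -1), thrIdx (int))
.candFitness <- function(cand, X, y, thrList, gapList, breakpoint,
                         condPenalty) {
    matched <- rep(TRUE, ncol(X))
    gaps <- numeric(length(cand$feat))
    for (j in seq_along(cand$feat)) {
        v <- X[cand$feat[j], ]
        thr <- thrList[[cand$feat[j]]][cand$thrIdx[j]]
        gaps[j] <- gapList[[cand$feat[j]]][cand$thrIdx[j]]
        matched <- matched & (if (cand$op[j] > 0) v > thr else v < thr)
    }
    cov <- sum(matched)
    corr <- if (cov) sum(y[matched] == cand$cls) else 0L
    acc <- if (cov) corr / cov else 0
    rawFit <- acc * min(1, cov / (breakpoint * ncol(X)))
    fit <- rawFit * (1 - condPenalty * (length(cand$feat) - 1L))
    # a rule must assert the presence/elevation of at least one protein;
    # pure-absence rules (all '<') match any all-zero sample and cannot be
    # biomarker evidence
    if (all(cand$op < 0L)) fit <- rawFit <- 0
    list(fit = fit, rawFit = rawFit, cov = cov, acc = acc, corr = corr,
         matched = matched, gap = mean(gaps))
}

# deterministic scan of every single-condition rule; returns the strongest
# stumps (one per feature/op, best threshold and class) used to seed the GA
.bestStumps <- function(X, y, thrList, gapList, usable, classes, breakpoint,
                        topM) {
    out <- list()
    n <- ncol(X)
    for (f in usable) {
        v <- X[f, ]
        thr <- thrList[[f]]
        for (op in 1L) {  # single-condition rules must assert presence
            # matched matrix: thresholds x samples
            M <- if (op > 0) outer(thr, v, function(t, s) s > t)
                 else outer(thr, v, function(t, s) s < t)
            cov <- rowSums(M)
            covPen <- pmin(1, cov / (breakpoint * n))
            bestFit <- -1; bestT <- NA_integer_; bestC <- NA_character_
            for (cls in classes) {
                corr <- as.vector(M %*% (y == cls))
                acc <- ifelse(cov > 0, corr / cov, 0)
                fit <- acc * covPen
                fit[corr < 1] <- -1
                # equal fitness: prefer correct coverage plus margin
                # (single which.max over a composite avoids a full sort)
                t <- which.max(fit * 1e6 + corr + 3 * gapList[[f]])
                if (length(t) && fit[t] > bestFit) {
                    bestFit <- fit[t]; bestT <- t; bestC <- cls
                }
            }
            if (bestFit > 0)
                out[[length(out) + 1L]] <-
                    list(fit = bestFit, gap = gapList[[f]][bestT],
                         cand = list(cls = bestC, feat = f, op = op,
                                     thrIdx = bestT))
        }
    }
    if (!length(out)) return(list())
    ord <- order(-vapply(out, `[[`, numeric(1), "fit"),
                 -vapply(out, `[[`, numeric(1), "gap"))
    lapply(out[utils::head(ord, topM)], `[[`, "cand")
}

.dedupeCand <- function(cand, maxConditions) {
    key <- cand$feat * 2L + (cand$op > 0L)
    keep <- !duplicated(key)
    cand$feat <- cand$feat[keep]; cand$op <- cand$op[keep]
    cand$thrIdx <- cand$thrIdx[keep]
    if (length(cand$feat) > maxConditions) {
        cand$feat <- cand$feat[seq_len(maxConditions)]
        cand$op <- cand$op[seq_len(maxConditions)]
        cand$thrIdx <- cand$thrIdx[seq_len(maxConditions)]
    }
    cand
}

.randomCand <- function(classes, usable, nThr, maxConditions) {
    n <- sample.int(min(2L, maxConditions), 1L)
    feat <- usable[sample.int(length(usable), n, replace = TRUE)]
    cand <- list(cls = classes[sample.int(length(classes), 1L)],
                 feat = feat,
                 op = 1L - 2L * (stats::runif(n) < 0.5),
                 thrIdx = 1L + as.integer(stats::runif(n) * nThr[feat]))
    .dedupeCand(cand, maxConditions)
}

.mutateCand <- function(cand, classes, usable, nThr, maxConditions) {
    u <- stats::runif(4)
    if (u[1] < 0.4) {  # perturb one threshold
        j <- sample.int(length(cand$feat), 1L)
        nthr <- nThr[cand$feat[j]]
        step <- if (stats::runif(1) < 0.5) -1L else 1L
        cand$thrIdx[j] <- min(nthr, max(1L, cand$thrIdx[j] + step))
    }
    if (u[2] < 0.2 && length(cand$feat) < maxConditions) {  # add condition
        f <- usable[sample.int(length(usable), 1L)]
        cand$feat <- c(cand$feat, f)
        cand$op <- c(cand$op, if (stats::runif(1) < 0.5) 1L else -1L)
        cand$thrIdx <- c(cand$thrIdx, 1L + as.integer(stats::runif(1) * nThr[f]))
    }
    if (u[3] < 0.2 && length(cand$feat) > 1L) {  # drop condition
        j <- sample.int(length(cand$feat), 1L)
        cand$feat <- cand$feat[-j]; cand$op <- cand$op[-j]
        cand$thrIdx <- cand$thrIdx[-j]
    }
    if (u[4] < 0.1)  # reassign class
        cand$cls <- classes[sample.int(length(classes), 1L)]
    .dedupeCand(cand, maxConditions)
}

.crossoverCand <- function(a, b, maxConditions) {
    feat <- c(a$feat, b$feat); op <- c(a$op, b$op)
    thrIdx <- c(a$thrIdx, b$thrIdx)
    keep <- stats::runif(length(feat)) < 0.5
    if (!any(keep)) keep[1] <- TRUE
    .dedupeCand(list(cls = a$cls, feat = feat[keep], op = op[keep],
                     thrIdx = thrIdx[keep]), maxConditions)
}

# canonical serialisation of a candidate, for deterministic tie-breaking
.candKey <- function(cand, featNames, thrList) {
    ord <- order(featNames[cand$feat], cand$op)
    paste(sprintf("%s %s %.17g", featNames[cand$feat[ord]],
                  ifelse(cand$op[ord] > 0, ">", "<"),
                  vapply(seq_along(ord), function(k) {
                      j <- ord[k]
                      thrList[[cand$feat[j]]][cand$thrIdx[j]]
                  }, numeric(1))),
          collapse = " AND ")
}

# a is strictly preferred to b? higher fitness first; fitness ties are then
# resolved by a generality-plus-margin score, corr + 3 * gap: coverage beyond
# the breakpoint is free under the fitness, so among equally fitting rules
# the one correctly covering more samples AND cutting through a wide value
# gap (mean relative log1p threshold gap) generalises best — with only a few
# samples and many protein features, many rules fit the training data
# perfectly, and neither generality nor margin alone separates genuine
# markers from chance splits; then fewer conditions; finally lexicographic
# serialisation for determinism
.candBetter <- function(a, b, featNames, thrList) {
    if (is.null(b)) return(TRUE)
    if (a$fit != b$fit) return(a$fit > b$fit)
    sa <- a$eval$corr + 3 * a$eval$gap
    sb <- b$eval$corr + 3 * b$eval$gap
    if (sa != sb) return(sa > sb)
    if (length(a$cand$feat) != length(b$cand$feat))
        return(length(a$cand$feat) < length(b$cand$feat))
    .candKey(a$cand, featNames, thrList) < .candKey(b$cand, featNames, thrList)
}

.searchRule <- function(X, y, thrList, gapList, usable, classes, config) {
    popN <- config$populationSize
    # informed initialisation: seed up to half the population with the best
    # deterministic single-condition stumps, the rest random for diversity
    nThr <- integer(length(thrList)); nThr[] <- lengths(thrList)
    stumps <- .bestStumps(X, y, thrList, gapList, usable, classes,
                          config$coverageBreakpoint, popN %/% 3L)
    # pair the strongest stumps so that informative conjunctions (one marker
    # qualified by another, e.g. shared-marker rules) are in the initial
    # population rather than awaiting a lucky crossover
    pairs <- list()
    if (length(stumps) >= 2L && config$maxConditions >= 2L) {
        top <- utils::head(stumps, 6L)
        for (i in seq_len(length(top) - 1L))
            for (j in seq(i + 1L, length(top))) {
                if (top[[i]]$feat == top[[j]]$feat) next
                pairs[[length(pairs) + 1L]] <- .dedupeCand(
                    list(cls = top[[i]]$cls,
                         feat = c(top[[i]]$feat, top[[j]]$feat),
                         op = c(top[[i]]$op, top[[j]]$op),
                         thrIdx = c(top[[i]]$thrIdx, top[[j]]$thrIdx)),
                    config$maxConditions)
                # the complementary direction of the second condition
                pairs[[length(pairs) + 1L]] <- .dedupeCand(
                    list(cls = top[[i]]$cls,
                         feat = c(top[[i]]$feat, top[[j]]$feat),
                         op = c(top[[i]]$op, -top[[j]]$op),
                         thrIdx = c(top[[i]]$thrIdx, top[[j]]$thrIdx)),
                    config$maxConditions)
            }
        pairs <- utils::head(pairs, popN %/% 3L)
    }
    seedCands <- c(stumps, pairs)
    pop <- c(seedCands,
             lapply(seq_len(max(0L, popN - length(seedCands))), function(i)
                 .randomCand(classes, usable, nThr, config$maxConditions)))
    popN <- length(pop)
    evalPop <- function(pop) lapply(pop, function(cand)
        .candFitness(cand, X, y, thrList, gapList,
                     config$coverageBreakpoint, config$conditionPenalty))
    evals <- evalPop(pop)
    # pool of distinct admissible candidates encountered during the search;
    # the final rule is drawn stochastically from its near-best entries, so
    # repeated runs with different seeds produce different (all defensible)
    # rule sets — the behaviour ensemble mining relies on
    pool <- list()
    best <- NULL
    updatePool <- function(pop, evals) {
        for (i in seq_along(pop)) {
            e <- evals[[i]]
            if (e$fit > 0 && e$cov >= 1 &&
                e$corr >= config$minRuleCoverage &&
                e$acc >= config$minRuleAccuracy) {
                # one pool entry per rule family (class + feature/op set),
                # keeping the best-scoring threshold variant
                ordf <- order(pop[[i]]$feat, pop[[i]]$op)
                key <- paste(pop[[i]]$cls,
                             paste(pop[[i]]$feat[ordf], pop[[i]]$op[ordf],
                                   collapse = "|"))
                cur <- list(fit = e$fit, cand = pop[[i]], eval = e)
                if (is.null(pool[[key]]) ||
                    .candBetter(cur, pool[[key]], rownames(X), thrList))
                    pool[[key]] <<- cur
                if (.candBetter(cur, best, rownames(X), thrList))
                    best <<- cur
            }
        }
    }
    updatePool(pop, evals)
    fits <- vapply(evals, `[[`, numeric(1), "fit")
    stagnant <- 0L
    for (g in seq_len(config$generations)) {
        newPop <- vector("list", popN)
        # elitism: carry the current population's best forward unchanged
        newPop[[1L]] <- pop[[which.max(fits)]]
        tidx <- matrix(sample.int(popN, 6L * (popN - 1L), replace = TRUE),
                       nrow = 6L)
        for (i in seq_len(popN)[-1L]) {
            t1 <- tidx[1:3, i - 1L]
            p1 <- pop[[t1[which.max(fits[t1])]]]
            if (stats::runif(1) < 0.6) {
                t2 <- tidx[4:6, i - 1L]
                p2 <- pop[[t2[which.max(fits[t2])]]]
                child <- .crossoverCand(p1, p2, config$maxConditions)
            } else child <- p1
            newPop[[i]] <- .mutateCand(child, classes, usable, nThr,
                                       config$maxConditions)
        }
        pop <- newPop
        evals <- evalPop(pop)
        fits <- vapply(evals, `[[`, numeric(1), "fit")
        prevBest <- best
        updatePool(pop, evals)
        stagnant <- if (identical(prevBest, best)) stagnant + 1L else 0L
        if (stagnant >= 6L) break  # converged: best unchanged for 6 gens
    }
    if (length(pool) == 0L) return(NULL)
    # eligible: within ruleChoiceSlack of the best raw (parsimony-free)
    # fitness, so an equally accurate conjunction stays in the draw while a
    # less accurate chance rule falls out; ordered by the deterministic
    # preference, then pick rank r with P(r) ~ 0.5^r
    maxFit <- max(vapply(pool, function(p) p$eval$rawFit, numeric(1)))
    elig <- Filter(function(p)
        p$eval$rawFit >= (1 - config$ruleChoiceSlack) * maxFit, pool)
    # within the eligible set, order by raw fitness, then parsimony (a
    # conjunction never outranks an equally fitting simpler rule — extra
    # conditions on top of a perfect stump are almost always chance), then
    # the generality-plus-margin composite
    ord <- order(vapply(elig, function(p) -p$eval$rawFit, numeric(1)),
                 vapply(elig, function(p) length(p$cand$feat), numeric(1)),
                 vapply(elig, function(p)
                     -(p$eval$corr + 3 * p$eval$gap), numeric(1)),
                 names(elig))
    elig <- elig[ord]
    r <- 1L
    while (r < length(elig) && stats::runif(1) < 0.25) r <- r + 1L
    elig[[r]]
}

#' Learn an ordered rule set by sequential covering with an evolutionary
#' rule search
#'
#' Repeatedly evolves one conjunctive threshold rule over the remaining
#' training samples — candidates are scored by accuracy penalised for
#' covering less than `coverageBreakpoint` of the remaining samples — then
#' appends the best admissible rule and removes the samples it matches. The
#' search stops when the remaining samples all belong to the default class,
#' `maxRules` is reached, or no candidate attains `minRuleAccuracy`. Rules
#' never predict the default class; candidate thresholds are midpoints
#' between consecutive distinct observed values of each feature, so learned
#' thresholds generalise beyond exact training scores. Identical seed and
#' data give an identical rule set.
#'
#' @param train a [QuantMatrix-class] with >= 2 classes present.
#' @param config a [learnerConfig()].
#' @return a [RuleSet-class] (its `seed` slot records `config$seed`).
#' @examples
#' qm <- generateQuantMatrix(generateDesign(), generatorConfig(seed = 3))
#' rs <- learnRuleSet(qm, learnerConfig(seed = 42))
#' rs
#' @export
learnRuleSet <- function(train, config) {
    stopifnot(is(train, "QuantMatrix"), inherits(config, "LearnerConfig"))
    if (nrow(train) == 0L || ncol(train) == 0L)
        stop("empty training matrix")
    X <- scoreMatrix(train)
    y <- sampleClasses(train)
    classes <- unique(y)
    if (length(classes) < 2L)
        stop("training data contains a single class; need >= 2")
    default <- if ("control" %in% classes) "control"
               else names(sort(table(y), decreasing = TRUE))[1L]
    if (all(y == default))
        stop("no non-default-class samples to learn from")
    # candidate thresholds: midpoints between consecutive sorted distinct
    # observed values, computed once on the full training matrix
    # candidate thresholds sit strictly between consecutive sorted distinct
    # observed values of each feature, at the log1p-space midpoint: protein
    # abundance scores are multiplicative (emPAI is exponential in PAI), so
    # the geometric middle of a gap generalises better than the arithmetic
    # one, which lands far above the low tail of an elevated class
    thrList <- lapply(seq_len(nrow(X)), function(i) {
        v <- sort(unique(X[i, ]))
        if (length(v) < 2L) return(numeric())
        lv <- log1p(v)
        expm1(lv[-length(lv)] + 0.35 * (lv[-1] - lv[-length(lv)]))
    })
    # margin of each threshold: width of its log1p gap relative to the
    # feature's log1p range; used as a tie-break between equally fitting
    # rules (wide multiplicative gaps generalise best)
    gapList <- lapply(seq_len(nrow(X)), function(i) {
        v <- sort(unique(X[i, ]))
        if (length(v) < 2L) return(numeric())
        lv <- log1p(v)
        (lv[-1] - lv[-length(lv)]) / (lv[length(lv)] - lv[1])
    })
    usable <- which(lengths(thrList) > 0L)
    ruleList <- list()
    if (length(usable)) withSeed(config$seed, {
        Xrem <- X; yrem <- y
        repeat {
            targets <- setdiff(unique(yrem), default)
            if (length(targets) == 0L || length(ruleList) >= config$maxRules)
                break
            best <- .searchRule(Xrem, yrem, thrList, gapList, usable,
                                targets, config)
            if (is.null(best)) break
            cand <- best$cand
            ord <- order(rownames(X)[cand$feat], cand$op)
            rule <- Rule(rownames(X)[cand$feat[ord]],
                         ifelse(cand$op[ord] > 0, ">", "<"),
                         vapply(ord, function(j)
                             thrList[[cand$feat[j]]][cand$thrIdx[j]],
                             numeric(1)),
                         cand$cls)
            ruleList[[length(ruleList) + 1L]] <- rule
            keep <- !best$eval$matched
            Xrem <- Xrem[, keep, drop = FALSE]
            yrem <- yrem[keep]
            if (ncol(Xrem) == 0L) break
        }
    })
    RuleSet(ruleList, default, classes = classes, seed = config$seed)
}

# ---- serialisation ----------------------------------------------------------

# shortest decimal representation that round-trips to the same double
.numToStr <- function(x) {
    for (d in 1:17) {
        s <- sprintf("%.*g", d, x)
        if (as.numeric(s) == x) return(s)
    }
    sprintf("%.17g", x)
}

.formatRule <- function(rule) {
    conds <- sprintf("%s %s %s", rule@features, rule@ops,
                     vapply(rule@thresholds, .numToStr, character(1)))
    sprintf("IF %s THEN %s", paste(conds, collapse = " AND "),
            rule@predictedClass)
}

#' Serialize / parse rule sets as human-readable text
#'
#' One rule per line, `IF <feature> > <x> [AND ...] THEN <class>`, followed
#' by a final `DEFAULT <class>` line. `parseRuleSet()` inverts
#' `serializeRuleSet()` exactly (round-trip identity); malformed input raises
#' an error naming the offending line.
#'
#' @param rs a [RuleSet-class].
#' @param text character scalar or vector of lines.
#' @return `serializeRuleSet()`: a single string; `parseRuleSet()`: a
#'   [RuleSet-class].
#' @examples
#' rs <- RuleSet(list(Rule("TPIS", ">", 0.01, "IL1b")), "control")
#' cat(serializeRuleSet(rs))
#' identical(parseRuleSet(serializeRuleSet(rs))@rules[[1]]@thresholds, 0.01)
#' @export
serializeRuleSet <- function(rs) {
    stopifnot(is(rs, "RuleSet"))
    lines <- c(vapply(rs@rules, .formatRule, character(1)),
               paste("DEFAULT", rs@defaultClass))
    paste0(paste(lines, collapse = "\n"), "\n")
}

#' @rdname serializeRuleSet
#' @export
parseRuleSet <- function(text) {
    lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n",
                             fixed = TRUE))
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) stop("empty rule-set text")
    ruleList <- list()
    default <- NULL
    for (i in seq_along(lines)) {
        ln <- trimws(lines[i])
        if (grepl("^DEFAULT\\s+\\S+$", ln)) {
            if (i != length(lines))
                stop("parse error at line ", i,
                     ": DEFAULT must be the final line")
            default <- sub("^DEFAULT\\s+", "", ln)
        } else if (grepl("^IF\\s+.+\\s+THEN\\s+\\S+$", ln)) {
            body <- sub("^IF\\s+", "", ln)
            cls <- sub("^.*\\s+THEN\\s+", "", body)
            condStr <- sub("\\s+THEN\\s+\\S+$", "", body)
            parts <- strsplit(condStr, "\\s+AND\\s+")[[1]]
            m <- regmatches(parts,
                            regexec("^(\\S+)\\s+([<>])\\s+(\\S+)$", parts))
            if (any(lengths(m) != 4L))
                stop("parse error at line ", i, ": bad condition in '", ln,
                     "'")
            thr <- suppressWarnings(
                as.numeric(vapply(m, `[[`, character(1), 4L)))
            if (any(is.na(thr)))
                stop("parse error at line ", i, ": bad threshold in '", ln,
                     "'")
            ruleList[[length(ruleList) + 1L]] <-
                Rule(vapply(m, `[[`, character(1), 2L),
                     vapply(m, `[[`, character(1), 3L), thr, cls)
        } else {
            stop("parse error at line ", i, ": '", ln, "'")
        }
    }
    if (is.null(default))
        stop("parse error: missing final DEFAULT line")
    RuleSet(ruleList, default)
}
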