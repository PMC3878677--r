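#' Leave-one-out cross-validation splits
#'
#' One split per sample: the test set is that single sample, the training set
#' is every other sample. The test ids over all splits partition the sample
#' set.
#'
#' @param x a [QuantMatrix-class] with >= 2 samples.
#' @return list of `list(train = character ids, test = character id)`.
#' @examples
#' \donttest{
#' qm <- generateQuantMatrix(generateDesign(), generatorConfig(seed = 1))
#' length(loocvSplits(qm))  # one split per sample
#' }
#' @export
loocvSplits <- function(x) {
    stopifnot(is(x, "QuantMatrix"))
    ids <- colnames(x)
    if (length(ids) < 2L) stop("LOOCV needs at least 2 samples")
    lapply(seq_along(ids), function(i)
        list(train = ids[-i], test = ids[i]))
}

#' Cross-tabulate true versus predicted classes
#'
#' @param true,predicted character vectors of class labels.
#' @param classes ordered class set for the matrix dimensions; defaults to
#'   the sorted union of observed labels.
#' @return integer matrix, rows = true class, columns = predicted class.
#' @export
confusionMatrix <- function(true, predicted, classes = NULL) {
    if (is.null(classes)) classes <- sort(unique(c(true, predicted)))
    cm <- table(factor(true, levels = classes),
                factor(predicted, levels = classes))
    m <- matrix(as.integer(cm), nrow = length(classes),
                dimnames = list(true = classes, predicted = classes))
    m
}

#' Classification accuracy of a confusion matrix
#'
#' @param cm square confusion matrix from [confusionMatrix()].
#' @return fraction of evaluated samples on the diagonal.
#' @export
confusionAccuracy <- function(cm) {
    sum(diag(cm)) / sum(cm)
}

#' Evaluate a learner by leave-one-out cross-validation
#'
#' For every sample, a rule set is learned on the other samples (each split
#' gets its own seed derived from `config$seed` and the split index, see
#' [deriveSeed()]) and the held-out sample is predicted with first-match
#' semantics. Accuracy is the fraction of held-out samples predicted
#' correctly.
#'
#' @param x a [QuantMatrix-class] with >= 2 classes.
#' @param config a [learnerConfig()]; its seed is the base seed for all
#'   splits.
#' @return list with `confusion` (matrix), `accuracy` (fraction),
#'   `predictions` (data.frame: sample_id, true, predicted, seed).
#' @examples
#' \donttest{
#' qm <- generateQuantMatrix(generateDesign(), generatorConfig(seed = 1))
#' res <- runLoocv(qm, learnerConfig(seed = 9, generations = 5,
#'                                   populationSize = 10))
#' formatAccuracy(res$accuracy)
#' }
#' @export
runLoocv <- function(x, config) {
    stopifnot(is(x, "QuantMatrix"), inherits(config, "LearnerConfig"))
    splits <- loocvSplits(x)
    y <- sampleClasses(x)
    preds <- character(length(splits))
    seeds <- integer(length(splits))
    for (i in seq_along(splits)) {
        sp <- splits[[i]]
        seeds[i] <- deriveSeed(config$seed, i)
        foldCfg <- config; foldCfg$seed <- seeds[i]
        rs <- tryCatch(learnRuleSet(x[, sp$train], foldCfg),
                       error = function(e)
                           stop("LOOCV split ", i, " (test sample ", sp$test,
                                "): ", conditionMessage(e)))
        preds[i] <- predict(rs, x[, sp$test, drop = FALSE])[[1L]]
    }
    testIds <- vapply(splits, `[[`, character(1), "test")
    classes <- sort(unique(y))
    cm <- confusionMatrix(y[testIds], preds, classes)
    list(confusion = cm, accuracy = mean(preds == y[testIds]),
         predictions = data.frame(sample_id = testIds, true = y[testIds],
                                  predicted = preds, seed = seeds,
                                  row.names = NULL))
}

#' Permute class labels, preserving class sizes
#'
#' Returns a copy of the matrix whose class labels have been reassigned
#' uniformly at random among the samples; the multiset of class sizes and the
#' score matrix itself are untouched.
#'
#' @param x a [QuantMatrix-class].
#' @param seed integer seed; the same seed reproduces the same labelling.
#' @return a [QuantMatrix-class] with permuted labels.
#' @export
permuteLabels <- function(x, seed) {
    stopifnot(is(x, "QuantMatrix"))
    y <- sampleClasses(x)
    perm <- withSeed(seed, sample(length(y)))
    out <- x
    colData(out)$class <- unname(y[perm])
    out
}

#' One-tailed permutation test of LOOCV accuracy
#'
#' The observed accuracy is [runLoocv()] on the true labels; each of
#' `nPermutations` permuted datasets (labels reassigned, class sizes
#' preserved) is evaluated the same way. The primary significance measure is
#' the empirical one-tailed p-value `(r + 1) / (nPermutations + 1)`, where
#' `r` counts permuted accuracies at least as large as the observed one; it
#' can never be 0. A Gaussian-tail p-value (upper-tail normal probability of
#' the observed accuracy under the permuted accuracies' mean and sd) is
#' reported alongside for comparison with sub-resolution p-values, but the
#' empirical value is the defensible one.
#'
#' @param x a [QuantMatrix-class].
#' @param config a [learnerConfig()].
#' @param nPermutations number of label permutations (>= 1; the study used
#'   50).
#' @param seed base seed for the permutations (defaults to `config$seed`).
#' @return object of class `PermutationResult`: list with
#'   `observed_accuracy`, `permuted_accuracies`, `p_empirical`,
#'   `p_gaussian`, `n_permutations`, plus the observed `confusion` matrix.
#' @export
permutationTest <- function(x, config, nPermutations = 50,
                            seed = config$seed) {
    stopifnot(nPermutations >= 1)
    obs <- runLoocv(x, config)
    perm <- numeric(nPermutations)
    for (k in seq_len(nPermutations)) {
        permSeed <- deriveSeed(seed, 10000L + k)
        xk <- permuteLabels(x, permSeed)
        cfgk <- config; cfgk$seed <- deriveSeed(seed, 20000L + k)
        perm[k] <- runLoocv(xk, cfgk)$accuracy
    }
    r <- sum(perm >= obs$accuracy)
    pEmp <- (r + 1) / (nPermutations + 1)
    sdp <- stats::sd(perm)
    if (nPermutations < 2 || is.na(sdp) || sdp == 0) {
        warning("zero variance in permuted accuracies; ",
                "p_gaussian degenerates to 0 or 1")
        pGauss <- if (obs$accuracy > mean(perm)) 0 else 1
    } else {
        pGauss <- stats::pnorm(obs$accuracy, mean(perm), sdp,
                               lower.tail = FALSE)
    }
    structure(list(observed_accuracy = obs$accuracy,
                   permuted_accuracies = perm,
                   p_empirical = pEmp, p_gaussian = pGauss,
                   n_permutations = as.integer(nPermutations),
                   confusion = obs$confusion),
              class = "PermutationResult")
}

#' @export
print.PermutationResult <- function(x, ...) {
    cat(sprintf(
        "Permutation test: observed accuracy %s over %d permutations\n",
        formatAccuracy(x$observed_accuracy), x$n_permutations))
    cat(sprintf("  p (empirical) = %.4g, p (Gaussian tail) = %.4g\n",
                x$p_empirical, x$p_gaussian))
    invisible(x)
}
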