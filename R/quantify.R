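#' Protein abundance index (PAI)
#'
#' The PAI of a protein in a sample is the number of peptides identified
#' divided by the number of theoretically observable tryptic peptides for that
#' protein. Vectorised over proteins.
#'
#' @param observed integer count(s) of identified peptides, >= 0.
#' @param observable integer count(s) of theoretically observable tryptic
#'   peptides, >= 1.
#' @param accession optional accession(s) used in error messages.
#' @return numeric PAI value(s), `observed / observable`.
#' @examples
#' computePAI(4, 8)   # 0.5
#' computePAI(0, 10)  # absent protein -> 0
#' @export
computePAI <- function(observed, observable, accession = NULL) {
    if (any(observed < 0)) stop("'observed' must be >= 0")
    bad <- observable < 1
    if (any(bad)) {
        who <- if (is.null(accession)) which(bad) else accession[bad]
        stop("observable peptide count must be >= 1; undefined for: ",
             paste(who, collapse = ", "))
    }
    observed / observable
}

#' Exponentially modified PAI (emPAI)
#'
#' emPAI = 10^PAI - 1, an estimate proportional to the absolute amount of a
#' protein in a sample. Strictly increasing in PAI and 0 at PAI = 0.
#'
#' @param pai nonnegative PAI value(s), see [computePAI()].
#' @return numeric emPAI value(s).
#' @examples
#' computeEmpai(0)            # 0
#' computeEmpai(1)            # 9
#' computeEmpai(computePAI(4, 8))
#' @export
computeEmpai <- function(pai) {
    if (any(pai < 0)) stop("'pai' must be nonnegative")
    10^pai - 1
}

#' Combine peptide-level probabilities into a protein probability
#'
#' A simplified stand-in for full Bayesian protein-identification scoring:
#' assuming independent peptide evidence, the probability that at least one
#' peptide identification is correct is `1 - prod(1 - p)`. The result lies in
#' [0, 1] and is monotone nondecreasing in every peptide probability.
#'
#' @param peptideProbs nonempty numeric vector of peptide-level
#'   probabilities, each in [0, 1].
#' @return a single probability.
#' @examples
#' proteinProbability(c(0.5, 0.5))       # 0.75
#' proteinProbability(c(1, 0.2))         # 1
#' @export
proteinProbability <- function(peptideProbs) {
    if (length(peptideProbs) == 0L)
        stop("'peptideProbs' must be nonempty")
    if (any(peptideProbs < 0 | peptideProbs > 1))
        stop("peptide probabilities must be in [0, 1]")
    1 - prod(1 - peptideProbs)
}

#' Assemble a QuantMatrix from a long score or peptide table
#'
#' Builds the features-by-samples matrix over the union of proteins seen in
#' any sample; a (protein, sample) pair absent from `records` is an explicit
#' zero (a protein not identified in a sample scored 0, so rule conditions
#' such as "greater than 0" are well defined). Protein and sample order is
#' lexicographic, so assembly is independent of input row order.
#'
#' `records` is either a score table with columns `protein_id`, `sample_id`,
#' `score`, or a peptide table with columns `protein_id`, `sample_id`,
#' `observed_peptides`, `observable_peptides`; the latter is converted to the
#' requested `scoreType` (emPAI via 10^(obs/observable) - 1; probability via
#' a saturating transform of the observed count, see
#' [peptideCountToProbability()]).
#'
#' @param records data.frame, long format, one row per (protein, sample).
#' @param labels named character vector or data.frame (`sample_id`, `class`,
#'   optional `subject`) mapping every sample to its treatment class.
#' @param scoreType `"empai"` or `"probability"`.
#' @param provenance free-text origin note.
#' @return a [QuantMatrix-class].
#' @examples
#' rec <- data.frame(protein_id = c("A", "B", "A"),
#'                   sample_id = c("s1", "s1", "s2"), score = c(1, 2, 3))
#' assembleMatrix(rec, c(s1 = "control", s2 = "IL1b"), "empai")
#' @export
assembleMatrix <- function(records, labels, scoreType = c("empai", "probability"),
                           provenance = "assembled") {
    scoreType <- match.arg(scoreType)
    records <- as.data.frame(records)
    if (nrow(records) == 0L)
        stop("no records to assemble (empty input)")
    need <- c("protein_id", "sample_id")
    if (!all(need %in% names(records)))
        stop("records need columns: ", paste(need, collapse = ", "))
    if (!"score" %in% names(records)) {
        if (!all(c("observed_peptides", "observable_peptides") %in%
                 names(records)))
            stop("records need either 'score' or peptide-count columns")
        records$score <- switch(scoreType,
            empai = computeEmpai(computePAI(records$observed_peptides,
                                            records$observable_peptides,
                                            records$protein_id)),
            probability = peptideCountToProbability(records$observed_peptides))
    }
    subjects <- NULL
    if (is.data.frame(labels)) {
        if ("subject" %in% names(labels))
            subjects <- stats::setNames(as.character(labels$subject),
                                        labels$sample_id)
        labels <- stats::setNames(as.character(labels$class), labels$sample_id)
    }
    samples <- sort(unique(as.character(records$sample_id)))
    missing <- setdiff(samples, names(labels))
    if (length(missing))
        stop("unlabeled sample(s): ", paste(missing, collapse = ", "))
    key <- paste(records$protein_id, records$sample_id)
    if (anyDuplicated(key))
        stop("duplicate (protein, sample) rows: ",
             paste(unique(key[duplicated(key)]), collapse = "; "))
    proteins <- sort(unique(as.character(records$protein_id)))
    m <- matrix(0, length(proteins), length(samples),
                dimnames = list(proteins, samples))
    m[cbind(match(records$protein_id, proteins),
            match(records$sample_id, samples))] <- records$score
    QuantMatrix(m, scoreType, classes = labels[samples],
                subjects = subjects, provenance = provenance)
}

#' Saturating probability transform of an observed-peptide count
#'
#' Maps an observed-peptide count to a pseudo identification probability
#' `1 - exp(-count / 2)`: 0 for an absent protein, saturating towards 1 as
#' peptide evidence accumulates. Used when a probability-type matrix is
#' assembled from peptide counts rather than from an external
#' protein-inference tool.
#'
#' @param count nonnegative observed-peptide count(s).
#' @return probabilities in [0, 1).
#' @export
peptideCountToProbability <- function(count) {
    if (any(count < 0)) stop("'count' must be nonnegative")
    1 - exp(-count / 2)
}

#' Combine two QuantMatrix objects into a mixed-score-type matrix
#'
#' Stacks the feature blocks of two matrices over the same samples; features
#' remain tagged by score type, so the same accession may appear once per
#' block (as in a combined emPAI + probability dataset).
#'
#' @param a,b [QuantMatrix-class] objects over identical sample sets with
#'   identical class labels.
#' @return a [QuantMatrix-class] with the disjoint union of features.
#' @export
combineMatrices <- function(a, b) {
    stopifnot(is(a, "QuantMatrix"), is(b, "QuantMatrix"))
    if (!setequal(colnames(a), colnames(b))) {
        onlyA <- setdiff(colnames(a), colnames(b))
        onlyB <- setdiff(colnames(b), colnames(a))
        stop("sample sets differ; only in first: [",
             paste(onlyA, collapse = ", "), "], only in second: [",
             paste(onlyB, collapse = ", "), "]")
    }
    b <- b[, colnames(a)]
    la <- sampleClasses(a); lb <- sampleClasses(b)
    if (!identical(la, lb[names(la)]))
        stop("class labels disagree between the two matrices")
    if (length(intersect(rownames(a), rownames(b))))
        stop("feature ids overlap (same accession and score type): ",
             paste(utils::head(intersect(rownames(a), rownames(b)), 5),
                   collapse = ", "))
    sc <- rbind(scoreMatrix(a), scoreMatrix(b))
    rownames(sc) <- c(accessions(a), accessions(b))
    subj <- if ("subject" %in% colnames(colData(a)))
        stats::setNames(colData(a)$subject, colnames(a)) else NULL
    QuantMatrix(sc, c(unname(scoreTypes(a)), unname(scoreTypes(b))),
                classes = la, subjects = subj,
                provenance = paste0("combined(",
                                    metadata(a)$provenance, " + ",
                                    metadata(b)$provenance, ")"))
}

#' Remove samples with anomalously few identified proteins
#'
#' Operationalises the by-inspection removal of a sample with a very small
#' number of identified proteins as a reproducible rule: a sample is dropped
#' when its count of nonzero features is below `minFraction` times the median
#' nonzero-feature count over all samples. The filter is idempotent.
#'
#' @param x a [QuantMatrix-class].
#' @param minFraction fraction of the median nonzero-protein count below
#'   which a sample is considered anomalous; in (0, 1), default 0.25.
#' @return a list with `matrix` (the filtered [QuantMatrix-class]), `removed`
#'   (character vector of removed sample ids) and `counts` (named
#'   nonzero-feature counts of all input samples).
#' @examples
#' \donttest{
#' qm <- generateQuantMatrix(generateDesign(), generatorConfig(seed = 1))
#' filterAnomalousSamples(qm)$removed
#' }
#' @export
filterAnomalousSamples <- function(x, minFraction = 0.25) {
    stopifnot(is(x, "QuantMatrix"), ncol(x) >= 1)
    if (minFraction <= 0 || minFraction >= 1)
        stop("'minFraction' must be in (0, 1)")
    counts <- colSums(scoreMatrix(x) > 0)
    cutoff <- minFraction * stats::median(counts)
    drop <- counts < cutoff
    if (all(drop))
        stop("threshold removes every sample; choose a smaller 'minFraction'")
    kept <- x[, !drop]
    if (any(drop))
        message(sprintf(
            "removed %d anomalous sample(s): %s (nonzero counts %s; cutoff %.1f)",
            sum(drop), paste(colnames(x)[drop], collapse = ", "),
            paste(counts[drop], collapse = ", "), cutoff))
    list(matrix = kept, removed = colnames(x)[drop], counts = counts)
}
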