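#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData colData<-
NULL

.SCORE_TYPES <- c("empai", "probability")

#' QuantMatrix: protein-by-sample score matrix with treatment labels
#'
#' A \code{QuantMatrix} holds nonnegative label-free quantification scores
#' (emPAI values or protein-identification probabilities) for a set of protein
#' features across labelled samples. It extends
#' \linkS4class{SummarizedExperiment}: the single \code{"scores"} assay is a
#' features-by-samples matrix, \code{rowData} carries the protein accession and
#' score type of every feature, and \code{colData} carries the treatment class
#' and (optionally) the biological subject of every sample. Feature ids
#' (rownames) are \code{"accession|score_type"}, so a combined matrix may carry
#' the same accession once per score type.
#'
#' Validity requires: all scores finite and nonnegative, probability-type
#' scores at most 1, unique feature ids, and a non-missing class label for
#' every sample.
#'
#' @slot .Data see \linkS4class{SummarizedExperiment}
#' @seealso [QuantMatrix()] the constructor, [assembleMatrix()],
#'   [combineMatrices()], [filterAnomalousSamples()]
#' @export
setClass("QuantMatrix", contains = "SummarizedExperiment")

.validQuantMatrix <- function(object) {
    msg <- character()
    if (!"scores" %in% SummarizedExperiment::assayNames(object))
        return("assay 'scores' is missing")
    sc <- assay(object, "scores")
    if (!is.numeric(sc) || any(!is.finite(sc)))
        msg <- c(msg, "scores must be finite numbers")
    else if (any(sc < 0))
        msg <- c(msg, "scores must be nonnegative")
    rd <- rowData(object)
    if (!all(c("accession", "scoreType") %in% colnames(rd)))
        msg <- c(msg, "rowData must have 'accession' and 'scoreType'")
    else {
        if (!all(rd$scoreType %in% .SCORE_TYPES))
            msg <- c(msg, sprintf("scoreType must be one of: %s",
                                  paste(.SCORE_TYPES, collapse = ", ")))
        prob <- rd$scoreType == "probability"
        if (any(prob) && is.numeric(sc) && nrow(sc) > 0 &&
            any(sc[prob, , drop = FALSE] > 1 + 1e-12))
            msg <- c(msg, "probability-type scores must not exceed 1")
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "feature ids must be unique")
    cd <- colData(object)
    if (!"class" %in% colnames(cd))
        msg <- c(msg, "colData must have a 'class' column")
    else if (any(is.na(cd$class)) || any(cd$class == ""))
        msg <- c(msg, "every sample needs a non-missing class label")
    if (length(msg)) msg else TRUE
}
setValidity("QuantMatrix", .validQuantMatrix)

#' Construct a QuantMatrix
#'
#' @param scores numeric matrix of nonnegative scores, proteins in rows
#'   (rownames = accessions), samples in columns (colnames = sample ids).
#' @param scoreType `"empai"` or `"probability"`; either a single value for
#'   the whole matrix or one value per row.
#' @param classes character vector of treatment class labels, one per sample
#'   (recycled names from `colnames(scores)` if named).
#' @param subjects optional character/integer vector of biological subject ids,
#'   one per sample.
#' @param provenance free-text origin note stored in `metadata()`.
#' @return a [QuantMatrix-class] object whose feature ids are
#'   `"accession|score_type"`.
#' @examples
#' m <- matrix(c(0, 1.5, 2, 0), 2, 2,
#'             dimnames = list(c("MMP3", "TPIS"), c("s1", "s2")))
#' qm <- QuantMatrix(m, "empai", classes = c(s1 = "control", s2 = "IL1b"))
#' featureIds(qm)
#' @export
QuantMatrix <- function(scores, scoreType, classes, subjects = NULL,
                        provenance = "") {
    scores <- as.matrix(scores)
    if (is.null(rownames(scores)) || is.null(colnames(scores)))
        stop("'scores' needs accession rownames and sample-id colnames")
    if (length(scoreType) == 1L)
        scoreType <- rep(scoreType, nrow(scores))
    stopifnot(length(scoreType) == nrow(scores))
    if (!all(scoreType %in% .SCORE_TYPES))
        stop("scoreType must be 'empai' or 'probability'")
    if (!is.null(names(classes)))
        classes <- classes[colnames(scores)]
    if (length(classes) != ncol(scores))
        stop("need one class label per sample")
    if (any(is.na(classes)))
        stop("unlabeled sample(s): ",
             paste(colnames(scores)[is.na(classes)], collapse = ", "))
    rd <- DataFrame(accession = rownames(scores), scoreType = scoreType)
    cd <- DataFrame(class = as.character(classes), row.names = colnames(scores))
    if (!is.null(subjects)) {
        if (!is.null(names(subjects))) subjects <- subjects[colnames(scores)]
        cd$subject <- as.character(subjects)
    }
    fid <- paste(rownames(scores), scoreType, sep = "|")
    rownames(scores) <- fid
    se <- SummarizedExperiment(assays = list(scores = scores),
                               rowData = rd, colData = cd,
                               metadata = list(provenance = provenance))
    new("QuantMatrix", se)
}

#' Rule: a conjunctive threshold rule over protein features
#'
#' A rule is a conjunction of strict threshold conditions
#' (`feature > x` or `feature < x`) plus the treatment class it predicts.
#' Conditions are stored as parallel vectors. A sample matches the rule iff
#' every condition holds under strict inequality; a feature absent from the
#' sample scores 0.
#'
#' @slot features character vector of feature ids.
#' @slot ops character vector, each `">"` or `"<"`.
#' @slot thresholds numeric vector of finite thresholds.
#' @slot predictedClass class assigned when the rule matches.
#' @seealso [Rule()], [ruleMatches()], [RuleSet-class]
#' @export
setClass("Rule", representation(features = "character", ops = "character",
                                thresholds = "numeric",
                                predictedClass = "character"))

setValidity("Rule", function(object) {
    msg <- character()
    n <- length(object@features)
    if (n < 1L) msg <- c(msg, "a rule needs at least one condition")
    if (length(object@ops) != n || length(object@thresholds) != n)
        msg <- c(msg, "features, ops and thresholds must have equal length")
    if (!all(object@ops %in% c(">", "<")))
        msg <- c(msg, "ops must be '>' or '<'")
    if (any(!is.finite(object@thresholds)))
        msg <- c(msg, "thresholds must be finite")
    if (length(object@predictedClass) != 1L || object@predictedClass == "")
        msg <- c(msg, "predictedClass must be a single non-empty class name")
    if (anyDuplicated(paste(object@features, object@ops)))
        msg <- c(msg, "duplicate (feature, op) condition")
    if (length(msg)) msg else TRUE
})

#' Construct a Rule
#'
#' @param features feature ids, one per condition.
#' @param ops `">"` or `"<"`, one per condition.
#' @param thresholds numeric thresholds, one per condition.
#' @param predictedClass the class the rule assigns.
#' @return a [Rule-class] object.
#' @examples
#' Rule(c("MMP3", "UBIB"), c(">", "<"), c(0, 0.2), "IL1b")
#' @export
Rule <- function(features, ops, thresholds, predictedClass) {
    new("Rule", features = as.character(features), ops = as.character(ops),
        thresholds = as.numeric(thresholds),
        predictedClass = as.character(predictedClass))
}

#' RuleSet: an ordered rule list with an explicit default class
#'
#' A rule set classifies a sample as the predicted class of the first rule it
#' matches, in order; a sample matching no rule takes the default class. The
#' default class never appears as a rule's predicted class (in the explant
#' study the untreated control is the default: "there are no rules for the
#' control").
#'
#' @slot rules list of [Rule-class] objects (order is significant).
#' @slot defaultClass class assigned when no rule matches.
#' @slot classes the full set of class names the set was trained over.
#' @slot seed integer seed the learner used (NA for hand-built sets).
#' @seealso [RuleSet()], [learnRuleSet()], [predict,RuleSet-method]
#' @export
setClass("RuleSet", representation(rules = "list", defaultClass = "character",
                                   classes = "character", seed = "integer"))

setValidity("RuleSet", function(object) {
    msg <- character()
    if (!all(vapply(object@rules, is, logical(1), "Rule")))
        msg <- c(msg, "rules must all be Rule objects")
    if (length(object@defaultClass) != 1L)
        msg <- c(msg, "defaultClass must be a single class name")
    if (length(object@classes) &&
        !object@defaultClass %in% object@classes)
        msg <- c(msg, "defaultClass must be among classes")
    preds <- vapply(object@rules, function(r) r@predictedClass, character(1))
    if (any(preds == object@defaultClass))
        msg <- c(msg, "no rule may predict the default class")
    if (length(object@classes) && length(preds) &&
        !all(preds %in% object@classes))
        msg <- c(msg, "rule classes must be among classes")
    if (length(msg)) msg else TRUE
})

#' Construct a RuleSet
#'
#' @param rules list of [Rule-class] objects, applied in order.
#' @param defaultClass class assigned when no rule matches.
#' @param classes full class set; defaults to the union of rule classes and
#'   the default class.
#' @param seed integer training seed (NA for hand-built sets).
#' @return a [RuleSet-class] object.
#' @examples
#' rs <- RuleSet(list(Rule("TPIS", ">", 0.01, "IL1b")), "control")
#' predict(rs, c(TPIS = 0.02))
#' @export
RuleSet <- function(rules, defaultClass, classes = NULL, seed = NA_integer_) {
    if (is.null(classes)) {
        preds <- vapply(rules, function(r) r@predictedClass, character(1))
        classes <- unique(c(defaultClass, preds))
    }
    new("RuleSet", rules = rules, defaultClass = as.character(defaultClass),
        classes = as.character(classes), seed = as.integer(seed))
}
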