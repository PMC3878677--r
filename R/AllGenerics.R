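#' Accessors for QuantMatrix
#'
#' `scoreMatrix()` returns the features-by-samples score matrix,
#' `sampleClasses()` the named vector of treatment labels, `scoreTypes()` the
#' per-feature score-type tags, `featureIds()` the `"accession|score_type"`
#' feature ids, and `accessions()` the bare protein accessions.
#'
#' @param x a [QuantMatrix-class]
#' @return see individual descriptions above.
#' @name quantmatrix-accessors
#' @aliases scoreMatrix sampleClasses scoreTypes featureIds accessions
#' @examples
#' qm <- QuantMatrix(matrix(1, 1, 1, dimnames = list("A", "s1")),
#'                   "empai", c(s1 = "control"))
#' scoreMatrix(qm); sampleClasses(qm)
NULL

#' @rdname quantmatrix-accessors
#' @export
setGeneric("scoreMatrix", function(x) standardGeneric("scoreMatrix"))
#' @rdname quantmatrix-accessors
#' @export
setGeneric("sampleClasses", function(x) standardGeneric("sampleClasses"))
#' @rdname quantmatrix-accessors
#' @export
setGeneric("scoreTypes", function(x) standardGeneric("scoreTypes"))
#' @rdname quantmatrix-accessors
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))
#' @rdname quantmatrix-accessors
#' @export
setGeneric("accessions", function(x) standardGeneric("accessions"))

#' @rdname quantmatrix-accessors
setMethod("scoreMatrix", "QuantMatrix", function(x) assay(x, "scores"))

#' @rdname quantmatrix-accessors
setMethod("sampleClasses", "QuantMatrix", function(x) {
    stats::setNames(as.character(colData(x)$class), colnames(x))
})

#' @rdname quantmatrix-accessors
setMethod("scoreTypes", "QuantMatrix", function(x) {
    stats::setNames(as.character(rowData(x)$scoreType), rownames(x))
})

#' @rdname quantmatrix-accessors
setMethod("featureIds", "QuantMatrix", function(x) rownames(x))

#' @rdname quantmatrix-accessors
setMethod("accessions", "QuantMatrix", function(x) {
    as.character(rowData(x)$accession)
})

#' Rule accessors
#'
#' `ruleConditions()` returns a rule's conditions as a data.frame with columns
#' `feature`, `op`, `threshold`; `predictedClass()` the class a rule assigns;
#' `rules()` the ordered rule list of a rule set and `defaultClass()` its
#' default class.
#'
#' @param x a [Rule-class] or [RuleSet-class]
#' @name rule-accessors
#' @aliases ruleConditions predictedClass rules defaultClass
#' @examples
#' r <- Rule("TPIS", ">", 0.01, "IL1b")
#' ruleConditions(r)
NULL

#' @rdname rule-accessors
#' @export
setGeneric("ruleConditions", function(x) standardGeneric("ruleConditions"))
#' @rdname rule-accessors
#' @export
setGeneric("predictedClass", function(x) standardGeneric("predictedClass"))
#' @rdname rule-accessors
#' @export
setGeneric("rules", function(x) standardGeneric("rules"))
#' @rdname rule-accessors
#' @export
setGeneric("defaultClass", function(x) standardGeneric("defaultClass"))

#' @rdname rule-accessors
setMethod("ruleConditions", "Rule", function(x) {
    data.frame(feature = x@features, op = x@ops, threshold = x@thresholds,
               stringsAsFactors = FALSE)
})
#' @rdname rule-accessors
setMethod("predictedClass", "Rule", function(x) x@predictedClass)
#' @rdname rule-accessors
setMethod("rules", "RuleSet", function(x) x@rules)
#' @rdname rule-accessors
setMethod("defaultClass", "RuleSet", function(x) x@defaultClass)

setMethod("show", "QuantMatrix", function(object) {
    st <- table(rowData(object)$scoreType)
    cl <- table(colData(object)$class)
    cat(sprintf("QuantMatrix: %d features x %d samples\n",
                nrow(object), ncol(object)))
    cat("  score types:",
        paste(sprintf("%s (%d)", names(st), st), collapse = ", "), "\n")
    cat("  classes:",
        paste(sprintf("%s (%d)", names(cl), cl), collapse = ", "), "\n")
    prov <- metadata(object)$provenance
    if (!is.null(prov) && nzchar(prov)) cat("  provenance:", prov, "\n")
})

setMethod("show", "Rule", function(object) {
    cat(.formatRule(object), "\n")
})

setMethod("show", "RuleSet", function(object) {
    cat(sprintf("RuleSet with %d rule(s), default class '%s'\n",
                length(object@rules), object@defaultClass))
    for (r in object@rules) cat(" ", .formatRule(r), "\n")
    cat("  DEFAULT", object@defaultClass, "\n")
})
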