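#' StudyDesign: treatment classes, replication and subjects
#'
#' Describes the layout of a multi-treatment secretome experiment: the ordered
#' treatment classes, replicates per class, the number of biological subjects
#' the replicates are spread over, and the default (untreated) class that the
#' rule learner falls back to.
#'
#' @slot classes ordered character vector of unique class names (>= 2).
#' @slot replicatesPerClass named integer vector, one count (>= 1) per class.
#' @slot subjects number of biological subjects.
#' @slot defaultClass one of `classes`.
#' @seealso [generateDesign()]
#' @export
setClass("StudyDesign", representation(classes = "character",
                                       replicatesPerClass = "integer",
                                       subjects = "integer",
                                       defaultClass = "character"))

setValidity("StudyDesign", function(object) {
    msg <- character()
    if (length(object@classes) < 2L)
        msg <- c(msg, "classification needs at least 2 classes")
    if (anyDuplicated(object@classes))
        msg <- c(msg, "class names must be unique")
    if (!identical(sort(names(object@replicatesPerClass)),
                   sort(object@classes)))
        msg <- c(msg, "replicatesPerClass must be named by the classes")
    if (any(object@replicatesPerClass < 1L))
        msg <- c(msg, "all replicate counts must be >= 1")
    if (!object@defaultClass %in% object@classes)
        msg <- c(msg, "defaultClass must be one of the classes")
    if (object@subjects < 1L) msg <- c(msg, "subjects must be >= 1")
    if (length(msg)) msg else TRUE
})

setMethod("show", "StudyDesign", function(object) {
    cat(sprintf("StudyDesign: %d classes, %d samples, %d subject(s)\n",
                length(object@classes), sum(object@replicatesPerClass),
                object@subjects))
    cat("  classes:", paste(sprintf("%s (n=%d)", object@classes,
        object@replicatesPerClass[object@classes]), collapse = ", "), "\n")
    cat("  default class:", object@defaultClass, "\n")
})

#' Create a study design
#'
#' With `paperDefaults = TRUE` (the default) this reproduces the cartilage
#' explant study layout: four treatment classes — untreated control, IL-1β,
#' carprofen, and IL-1β plus carprofen — with six replicates per class spread
#' over two subjects (dogs), 24 samples in all, and control as the default
#' class.
#'
#' @param paperDefaults use the explant-study layout.
#' @param classes,replicates,subjects,defaultClass custom layout
#'   (`replicates` is a single count or one count per class), used when
#'   `paperDefaults = FALSE`.
#' @return a [StudyDesign-class].
#' @examples
#' generateDesign()
#' generateDesign(FALSE, classes = c("control", "treated"),
#'                replicates = c(3, 5))
#' @export
generateDesign <- function(paperDefaults = TRUE, classes = NULL,
                           replicates = NULL, subjects = 1L,
                           defaultClass = NULL) {
    if (paperDefaults) {
        classes <- c("control", "IL1b", "carprofen", "IL1b_carprofen")
        replicates <- rep(6L, 4L)
        subjects <- 2L
        defaultClass <- "control"
    }
    if (is.null(classes) || length(classes) < 2L)
        stop("classification needs at least 2 classes")
    if (length(replicates) == 1L)
        replicates <- rep(replicates, length(classes))
    if (is.null(defaultClass))
        defaultClass <- classes[1L]
    new("StudyDesign", classes = as.character(classes),
        replicatesPerClass = stats::setNames(as.integer(replicates),
                                             classes),
        subjects = as.integer(subjects),
        defaultClass = as.character(defaultClass))
}

#' Sample sheet of a design
#'
#' Expands a design into one row per sample with deterministic sample ids
#' (`<class>_s<subject>_r<replicate>`); replicates are dealt round-robin
#' across subjects, mirroring equal per-subject replication.
#'
#' @param design a [StudyDesign-class].
#' @return data.frame with columns `sample_id`, `class`, `subject`.
#' @export
designSamples <- function(design) {
    stopifnot(is(design, "StudyDesign"))
    out <- do.call(rbind, lapply(design@classes, function(cl) {
        n <- design@replicatesPerClass[[cl]]
        subj <- ((seq_len(n) - 1L) %% design@subjects) + 1L
        within <- stats::ave(subj, subj, FUN = seq_along)
        data.frame(sample_id = sprintf("%s_s%d_r%d", cl, subj, within),
                   class = cl, subject = as.character(subj),
                   stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
}

#' Specify a planted marker protein
#'
#' A marker is a protein whose observed-peptide abundance is multiplied by
#' `effectMultiplier` in the classes it is elevated in, and whose chance of
#' being detected at all can differ per class (`presenceProb`), emulating
#' study patterns such as a protein detected in all treatment groups except
#' one.
#'
#' @param proteinId accession-like id.
#' @param elevatedIn character vector of class names with elevated abundance.
#' @param baselineScore baseline mean observed-peptide count (> 0).
#' @param effectMultiplier abundance multiplier in elevated classes (> 1).
#' @param presenceElevated,presenceOther detection probability in elevated /
#'   other classes. Elevated-class detection defaults to certain so that the
#'   global dropout probability is the single source of marker missingness;
#'   per-class patterns (a protein undetectable under one treatment) are
#'   expressed through `presenceProb`.
#' @param presenceProb optional named per-class override of the detection
#'   probability.
#' @return a `MarkerSpec` list.
#' @examples
#' markerSpec("MMP3", c("IL1b", "IL1b_carprofen"))
#' @export
markerSpec <- function(proteinId, elevatedIn, baselineScore = 3,
                       effectMultiplier = 10, presenceElevated = 1,
                       presenceOther = 0.7, presenceProb = NULL) {
    if (effectMultiplier <= 1) stop("'effectMultiplier' must be > 1")
    if (baselineScore < 0) stop("'baselineScore' must be nonnegative")
    probs <- c(presenceElevated, presenceOther, presenceProb)
    if (any(probs < 0 | probs > 1))
        stop("presence probabilities must be in [0, 1]")
    structure(list(proteinId = as.character(proteinId),
                   elevatedIn = as.character(elevatedIn),
                   baselineScore = baselineScore,
                   effectMultiplier = effectMultiplier,
                   presenceElevated = presenceElevated,
                   presenceOther = presenceOther,
                   presenceProb = presenceProb),
              class = "MarkerSpec")
}

.markerPresence <- function(marker, class) {
    if (!is.null(marker$presenceProb) && class %in% names(marker$presenceProb))
        return(marker$presenceProb[[class]])
    if (class %in% marker$elevatedIn) marker$presenceElevated
    else marker$presenceOther
}

#' Default planted markers emulating the explant study narrative
#'
#' One dominant marker per treated class plus one marker shared by the two
#' IL-1β-containing classes: TPIS elevated under IL-1β, MGP elevated under
#' carprofen (and rarely detected under IL-1β + carprofen), IL-8 elevated
#' under IL-1β + carprofen, and MMP-3 elevated under both IL-1β-containing
#' treatments.
#'
#' @param effectMultiplier abundance multiplier applied to every marker.
#' @return list of [markerSpec()] objects.
#' @export
paperDefaultMarkers <- function(effectMultiplier = 10) {
    list(
        markerSpec("TPIS", "IL1b", effectMultiplier = effectMultiplier),
        markerSpec("MGP", "carprofen", effectMultiplier = effectMultiplier,
                   presenceProb = c(IL1b_carprofen = 0.1)),
        markerSpec("IL8", "IL1b_carprofen",
                   effectMultiplier = effectMultiplier),
        markerSpec("MMP3", c("IL1b", "IL1b_carprofen"),
                   effectMultiplier = effectMultiplier))
}

#' Generator configuration
#'
#' Bundles everything the synthetic-data generator needs. Defaults state the
#' package's model of the explant study: 60 background proteins, the
#' [paperDefaultMarkers()] at effect multiplier 10, a 10% dropout
#' probability, 30% multiplicative noise (a typical label-free CV), moderate
#' negative-binomial overdispersion, a mild per-subject offset, and one
#' anomalous IL-1β + carprofen sample retaining 5% of the median protein
#' count.
#'
#' @param seed integer RNG seed (required).
#' @param nBackgroundProteins number of non-marker background proteins.
#' @param markers list of [markerSpec()] objects (possibly empty).
#' @param dropoutProb probability, in [0, 1), that a detected protein is
#'   lost from a sample.
#' @param noiseCV coefficient of variation of per-cell multiplicative
#'   lognormal noise (>= 0).
#' @param anomalousSample `NULL`, or `list(class =, fraction =)` with
#'   fraction in (0, 0.25]: one sample of that class keeps only this
#'   fraction of the median nonzero-protein count.
#' @param nbDispersion negative-binomial size parameter of peptide counts.
#' @param subjectCV coefficient of variation of the per-subject
#'   multiplicative offset.
#' @return a validated `GeneratorConfig` list.
#' @export
generatorConfig <- function(seed, nBackgroundProteins = 60,
                            markers = paperDefaultMarkers(),
                            dropoutProb = 0.1, noiseCV = 0.3,
                            anomalousSample = list(class = "IL1b_carprofen",
                                                   fraction = 0.05),
                            nbDispersion = 10, subjectCV = 0.15) {
    if (missing(seed) || length(seed) != 1L || is.na(seed))
        stop("invalid 'seed': a single integer is required")
    if (nBackgroundProteins < 0)
        stop("invalid 'nBackgroundProteins': must be >= 0")
    if (dropoutProb < 0 || dropoutProb >= 1)
        stop("invalid 'dropoutProb': must be in [0, 1)")
    if (noiseCV < 0) stop("invalid 'noiseCV': must be >= 0")
    if (!is.null(anomalousSample)) {
        if (!all(c("class", "fraction") %in% names(anomalousSample)))
            stop("invalid 'anomalousSample': needs 'class' and 'fraction'")
        f <- anomalousSample$fraction
        if (f <= 0 || f > 0.25)
            stop("invalid 'anomalousSample': fraction must be in (0, 0.25]")
    }
    if (!all(vapply(markers, inherits, logical(1), "MarkerSpec")))
        stop("invalid 'markers': use markerSpec()")
    if (nbDispersion <= 0) stop("invalid 'nbDispersion': must be > 0")
    if (subjectCV < 0) stop("invalid 'subjectCV': must be >= 0")
    structure(list(seed = as.integer(seed),
                   nBackgroundProteins = as.integer(nBackgroundProteins),
                   markers = markers, dropoutProb = dropoutProb,
                   noiseCV = noiseCV, anomalousSample = anomalousSample,
                   nbDispersion = nbDispersion, subjectCV = subjectCV),
              class = "GeneratorConfig")
}

# lognormal with mean 1 and coefficient of variation cv
.rlnormCV <- function(n, cv) {
    if (cv == 0) return(rep(1, n))
    s2 <- log(1 + cv^2)
    stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

#' Generate a synthetic peptide-identification table
#'
#' Draws one row per (protein, sample): a fixed per-protein count of
#' theoretically observable tryptic peptides, and an observed-peptide count
#' drawn from a negative binomial whose mean is the protein's baseline
#' abundance times the marker effect multiplier in elevated classes, a shared
#' per-subject offset, and per-cell lognormal noise; detection is thinned by
#' the marker's per-class presence probability and the global dropout
#' probability. Identical seeds give identical tables.
#'
#' @param design a [StudyDesign-class].
#' @param config a [generatorConfig()].
#' @return data.frame with columns `protein_id`, `sample_id`,
#'   `observed_peptides`, `observable_peptides`.
#' @examples
#' d <- generateDesign()
#' head(generatePeptideTable(d, generatorConfig(seed = 7)))
#' @export
generatePeptideTable <- function(design, config) {
    stopifnot(is(design, "StudyDesign"), inherits(config, "GeneratorConfig"))
    samples <- designSamples(design)
    markerIds <- vapply(config$markers, `[[`, character(1), "proteinId")
    if (anyDuplicated(markerIds)) stop("duplicate marker protein ids")
    bgIds <- if (config$nBackgroundProteins > 0)
        sprintf("BG%03d", seq_len(config$nBackgroundProteins)) else character()
    proteins <- c(markerIds, bgIds)
    if (length(proteins) == 0L)
        return(data.frame(protein_id = character(), sample_id = character(),
                          observed_peptides = integer(),
                          observable_peptides = integer()))
    nP <- length(proteins); nS <- nrow(samples)
    withSeed(config$seed, {
        observable <- sample(10:40, nP, replace = TRUE)
        baseline <- c(vapply(config$markers, `[[`, numeric(1),
                             "baselineScore"),
                      pmax(0.5, stats::rlnorm(length(bgIds), log(3), 0.5)))
        subjOffset <- stats::setNames(.rlnormCV(design@subjects,
                                                config$subjectCV),
                                      as.character(seq_len(design@subjects)))
        # mean matrix proteins x samples
        mult <- matrix(1, nP, nS)
        pres <- matrix(1, nP, nS)
        for (k in seq_along(config$markers)) {
            m <- config$markers[[k]]
            elev <- samples$class %in% m$elevatedIn
            mult[k, elev] <- m$effectMultiplier
            pres[k, ] <- vapply(samples$class, function(cl)
                .markerPresence(m, cl), numeric(1))
        }
        mu <- (baseline * mult) *
            rep(subjOffset[samples$subject], each = nP)
        noise <- matrix(.rlnormCV(nP * nS, config$noiseCV), nP, nS)
        counts <- matrix(stats::rnbinom(nP * nS, mu = as.vector(mu * noise),
                                        size = config$nbDispersion), nP, nS)
        detected <- matrix(stats::runif(nP * nS) < as.vector(pres), nP, nS)
        kept <- matrix(stats::runif(nP * nS) >= config$dropoutProb, nP, nS)
        counts <- counts * detected * kept
        data.frame(protein_id = rep(proteins, times = nS),
                   sample_id = rep(samples$sample_id, each = nP),
                   observed_peptides = as.integer(counts),
                   observable_peptides = rep(as.integer(observable),
                                             times = nS),
                   stringsAsFactors = FALSE)
    })
}

#' Generate a synthetic QuantMatrix
#'
#' Runs [generatePeptideTable()] and converts the counts into per-sample
#' protein scores: emPAI (`10^(observed/observable) - 1`) or saturating
#' identification probabilities (see [peptideCountToProbability()]). If the
#' configuration plants an anomalous sample, one sample of the configured
#' class (the last replicate, chosen deterministically) is masked down to
#' `fraction` of the median nonzero-protein count, keeping a seeded random
#' subset of its detectable proteins.
#'
#' @param design a [StudyDesign-class].
#' @param config a [generatorConfig()].
#' @param scoreType `"empai"` or `"probability"`.
#' @return a [QuantMatrix-class] with class and subject labels attached.
#' @examples
#' qm <- generateQuantMatrix(generateDesign(), generatorConfig(seed = 7))
#' qm
#' @export
generateQuantMatrix <- function(design, config,
                                scoreType = c("empai", "probability")) {
    scoreType <- match.arg(scoreType)
    tab <- generatePeptideTable(design, config)
    if (nrow(tab) == 0L) stop("generator produced no proteins")
    samples <- designSamples(design)
    labels <- data.frame(sample_id = samples$sample_id,
                         class = samples$class, subject = samples$subject)
    qm <- assembleMatrix(tab, labels, scoreType,
                         provenance = sprintf("synthetic(seed=%d, %s)",
                                              config$seed, scoreType))
    if (!is.null(config$anomalousSample)) {
        cls <- config$anomalousSample$class
        if (!cls %in% design@classes)
            stop("anomalousSample class not in design: ", cls)
        target <- utils::tail(samples$sample_id[samples$class == cls], 1L)
        sc <- scoreMatrix(qm)
        nz <- colSums(sc > 0)
        keepN <- max(1L, floor(config$anomalousSample$fraction *
                               stats::median(nz)))
        nzIdx <- which(sc[, target] > 0)
        if (length(nzIdx) > keepN) {
            dropIdx <- withSeed(deriveSeed(config$seed, 104729L),
                sample(nzIdx, length(nzIdx) - keepN))
            sc[dropIdx, target] <- 0
            SummarizedExperiment::assay(qm, "scores") <- sc
        }
        metadata(qm)$anomalousSample <- target
    }
    metadata(qm)$markers <- config$markers
    qm
}
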