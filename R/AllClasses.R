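#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame metadata "metadata<-"
NULL

#' OtuSet: an OTU count table with per-sample body-site and study labels
#'
#' `OtuSet` extends [SummarizedExperiment::SummarizedExperiment] with a single
#' `"counts"` assay (integer, OTUs in rows, samples in columns) and mandatory
#' `body_site` and `study_id` columns in `colData`. It is the universal
#' exchange object of the package: preprocessing, mixture simulation,
#' classification and biomarker discovery all consume it.
#'
#' @param counts integer matrix of non-negative counts, OTUs x samples, with
#'   unique row and column names.
#' @param body_site character vector of body-site labels, one per sample.
#' @param study_id character vector of study labels, one per sample. Defaults
#'   to a single study.
#' @param ground_truth optional [GroundTruth] carried in `metadata()` for
#'   synthetic datasets.
#'
#' @return An `OtuSet`.
#' @examples
#' cts <- matrix(c(5L, 0L, 2L, 7L), 2, 2,
#'               dimnames = list(c("otu1", "otu2"), c("s1", "s2")))
#' ose <- OtuSet(cts, body_site = c("skin", "feces"))
#' otuCounts(ose)
#' @export
OtuSet <- function(counts, body_site, study_id = NULL, ground_truth = NULL) {
  counts <- as.matrix(counts)
  if (is.null(study_id)) study_id <- rep("study1", ncol(counts))
  storage.mode(counts) <- "integer"
  se <- SummarizedExperiment(
    assays = list(counts = counts),
    colData = DataFrame(body_site = as.character(body_site),
                        study_id = as.character(study_id),
                        row.names = colnames(counts))
  )
  md <- list()
  if (!is.null(ground_truth)) md$ground_truth <- ground_truth
  obj <- new("OtuSet", se)
  metadata(obj) <- md
  obj
}

#' @rdname OtuSet
#' @export
setClass("OtuSet", contains = "SummarizedExperiment")

setValidity("OtuSet", function(object) {
  msg <- character(0)
  if (!"counts" %in% assayNames(object))
    msg <- c(msg, "OtuSet must carry a 'counts' assay")
  else {
    cts <- assay(object, "counts")
    if (anyNA(cts) || any(cts < 0))
      msg <- c(msg, "counts must be non-negative and non-missing")
    if (is.null(rownames(cts)) || anyDuplicated(rownames(cts)))
      msg <- c(msg, "OTU ids (rownames) must be present and unique")
    if (is.null(colnames(cts)) || anyDuplicated(colnames(cts)))
      msg <- c(msg, "sample ids (colnames) must be present and unique")
  }
  if (!all(c("body_site", "study_id") %in% colnames(colData(object))))
    msg <- c(msg, "colData must contain 'body_site' and 'study_id'")
  if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("otuCounts", "OtuSet", function(x) assay(x, "counts"))

#' @rdname accessors
#' @export
setMethod("bodySite", "OtuSet", function(x) as.character(colData(x)$body_site))

#' @rdname accessors
#' @export
setMethod("studyId", "OtuSet", function(x) as.character(colData(x)$study_id))

#' @rdname accessors
#' @export
setMethod("groundTruth", "OtuSet", function(x) metadata(x)$ground_truth)

#' GroundTruth: planted structure of a synthetic dataset
#'
#' Records which OTUs were planted as direct positively associated (PA) or
#' negatively associated (NA) markers per site, the parent -> child dependency
#' edges of indirectly associated OTUs, the background noise OTUs, and the
#' per-study detection-dropout matrix actually drawn by the generator (kept so
#' tests can compute exact expected presence frequencies).
#'
#' The four OTU categories (PA, NA, indirect, noise) are pairwise disjoint and
#' every indirect parent is a direct marker.
#'
#' @slot direct_pa named list, site -> character vector of OTU ids.
#' @slot direct_na named list, site -> character vector of OTU ids.
#' @slot indirect_edges data.frame with columns `parent`, `child`, `q1`, `q0`.
#' @slot noise_otus character vector of OTU ids.
#' @slot dropout numeric matrix, studies x OTUs, per-study extra nondetection
#'   probability.
#' @export
setClass("GroundTruth",
         representation(direct_pa = "list", direct_na = "list",
                        indirect_edges = "data.frame", noise_otus = "character",
                        dropout = "matrix"))

setValidity("GroundTruth", function(object) {
  pa <- unlist(object@direct_pa, use.names = FALSE)
  na <- unlist(object@direct_na, use.names = FALSE)
  ind <- object@indirect_edges$child
  cats <- list(pa, na, ind, object@noise_otus)
  all_ids <- unlist(cats)
  if (anyDuplicated(all_ids))
    return("PA, NA, indirect and noise OTU categories must be pairwise disjoint")
  if (nrow(object@indirect_edges) &&
      !all(object@indirect_edges$parent %in% c(pa, na)))
    return("every indirect parent must be a planted direct marker")
  TRUE
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:",
      length(unlist(object@direct_pa)), "direct PA,",
      length(unlist(object@direct_na)), "direct NA,",
      nrow(object@indirect_edges), "indirect,",
      length(object@noise_otus), "noise OTUs\n")
  invisible(object)
})

#' @param gt a [GroundTruth].
#' @return `directMarkers` returns the character vector of all planted direct
#'   marker ids (PA and NA pooled over sites).
#' @rdname GroundTruth-class
#' @export
directMarkers <- function(gt) {
  unique(c(unlist(gt@direct_pa, use.names = FALSE),
           unlist(gt@direct_na, use.names = FALSE)))
}

#' @return `indirectOtus` returns the character vector of planted indirect
#'   (child) OTU ids.
#' @rdname GroundTruth-class
#' @export
indirectOtus <- function(gt) unique(gt@indirect_edges$child)

#' BiomarkerSet: per-site marker records from local causal discovery
#'
#' Holds one row per (OTU, site) marker with association sign (+1 presence
#' raises the site probability, -1 lowers it, NA indeterminate), strength as
#' normalized mutual information with the one-vs-rest site indicator,
#' prevalence (number of samples carrying the OTU) and, when a trained model
#' was supplied, the percentile of Random-Forest feature importance among the
#' site's markers. The full audit trail of independence tests is kept in
#' `@tests` (one data.frame per site).
#'
#' @slot markers data.frame with columns `otu_id`, `site`, `sign`,
#'   `strength_nmi`, `prevalence`, `importance_percentile`.
#' @slot tests named list of data.frames of independence-test records.
#' @slot config the [gllConfig] list used for discovery.
#' @export
setClass("BiomarkerSet",
         representation(markers = "data.frame", tests = "list", config = "list"))

setValidity("BiomarkerSet", function(object) {
  m <- object@markers
  need <- c("otu_id", "site", "sign", "strength_nmi", "prevalence",
            "importance_percentile")
  if (!all(need %in% colnames(m)))
    return(paste("markers must have columns:", paste(need, collapse = ", ")))
  if (nrow(m) && anyDuplicated(m[, c("otu_id", "site")]))
    return("an OTU may appear at most once per site")
  TRUE
})

setMethod("show", "BiomarkerSet", function(object) {
  m <- object@markers
  cat("BiomarkerSet with", nrow(m), "marker records across",
      length(unique(m$site)), "sites\n")
  if (nrow(m)) {
    tab <- table(m$site, factor(ifelse(is.na(m$sign), "indet",
                                       ifelse(m$sign > 0, "PA", "NA")),
                                levels = c("PA", "NA", "indet")))
    print(tab)
  }
  invisible(object)
})

#' @rdname accessors
#' @export
setMethod("markers", "BiomarkerSet", function(x) x@markers)

#' TrainedModel: calibrated Random-Forest body-site classifier
#'
#' Wraps a fitted probability forest together with the per-class isotonic
#' calibrators fitted on out-of-fold scores, the feature universe, the chosen
#' hyperparameters, and impurity-based feature importances normalized to sum
#' to one.
#'
#' @slot forest the fitted `ranger` object.
#' @slot calibrators named list (one per class) of isotonic calibration
#'   functions mapping raw scores to calibrated probabilities.
#' @slot features character vector of feature (OTU) ids, in training order.
#' @slot classes character vector of class labels.
#' @slot hyper list with elements `n_trees` and `mtry_mult` (the selected grid
#'   point) and `inner_f1` (its inner-CV macro-F1).
#' @slot importance named numeric vector of normalized impurity importances.
#' @export
setClass("TrainedModel",
         representation(forest = "ANY", calibrators = "list",
                        features = "character", classes = "character",
                        hyper = "list", importance = "numeric"))

setMethod("show", "TrainedModel", function(object) {
  cat("TrainedModel:", length(object@classes), "classes,",
      length(object@features), "features; n_trees =",
      object@hyper$n_trees, ", mtry multiplier =", object@hyper$mtry_mult,
      sprintf("(inner-CV macro-F1 %.3f)\n", object@hyper$inner_f1))
  invisible(object)
})

#' @param model a [TrainedModel].
#' @return `featureImportance` returns the named numeric vector of normalized
#'   impurity importances (sums to 1 over the model's features).
#' @rdname TrainedModel-class
#' @export
featureImportance <- function(model) model@importance
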