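#' @import methods
NULL

#' Accessors for siteMarkers objects
#'
#' Small family of generics giving read access to the core containers:
#' the count assay and metadata columns of an [OtuSet], the planted truth
#' of a synthetic dataset, and the marker table of a [BiomarkerSet].
#'
#' @param x an object of the appropriate class.
#' @return `otuCounts` the integer count matrix (OTUs x samples);
#'   `bodySite` / `studyId` character vectors, one entry per sample;
#'   `groundTruth` a [GroundTruth] or `NULL`; `markers` a `data.frame`
#'   with one row per (OTU, site) marker record.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("otuCounts", function(x) standardGeneric("otuCounts"))

#' @rdname accessors
#' @export
setGeneric("bodySite", function(x) standardGeneric("bodySite"))

#' @rdname accessors
#' @export
setGeneric("studyId", function(x) standardGeneric("studyId"))

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname accessors
#' @export
setGeneric("markers", function(x) standardGeneric("markers"))
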