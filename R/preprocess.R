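#' Read and write OTU count tables and sample metadata as TSV
#'
#' The TSV dialect is tab-separated UTF-8 without quoting, header row
#' mandatory. Count tables carry `otu_id` as first column and one integer
#' column per sample; metadata tables carry `sample_id`, `body_site`,
#' `study_id`. `readOtuSet` combines both files into an [OtuSet];
#' write-then-read round-trips are lossless.
#'
#' @param path file path.
#' @param x an [OtuSet].
#' @return `readOtuTable` an integer matrix (OTUs x samples);
#'   `readSampleMeta` a data.frame; `readOtuSet` an [OtuSet].
#' @name otu-io
NULL

#' @rdname otu-io
#' @export
readOtuTable <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 1 || colnames(df)[1] != "otu_id")
    stop("malformed header in ", path, ": first column must be 'otu_id'")
  ids <- as.character(df[[1]])
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate otu_id in ", path, ": ", paste(unique(dup), collapse = ", "))
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (anyDuplicated(colnames(mat)))
    stop("duplicate sample id in header of ", path)
  num <- suppressWarnings(matrix(as.numeric(mat), nrow = nrow(mat),
                                 ncol = ncol(mat)))
  bad <- which(is.na(num) | num != floor(num) | num < 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("non-integer cell in ", path, " at otu '", ids[bad[1, 1]],
         "', sample '", colnames(mat)[bad[1, 2]], "'")
  storage.mode(num) <- "integer"
  dimnames(num) <- list(ids, colnames(mat))
  num
}

#' @rdname otu-io
#' @export
writeOtuTable <- function(x, path) {
  cts <- if (is(x, "OtuSet")) otuCounts(x) else as.matrix(x)
  ids <- if (is.null(rownames(cts))) character(nrow(cts)) else rownames(cts)
  df <- data.frame(otu_id = ids, cts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname otu-io
#' @export
readSampleMeta <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "body_site", "study_id")
  if (!all(need %in% colnames(df)))
    stop("malformed metadata header in ", path, ": need columns ",
         paste(need, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in ", path)
  df
}

#' @rdname otu-io
#' @export
writeSampleMeta <- function(x, path) {
  df <- data.frame(sample_id = colnames(otuCounts(x)),
                   body_site = bodySite(x), study_id = studyId(x),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' @param counts_path,meta_path paths to the two TSV files.
#' @rdname otu-io
#' @export
readOtuSet <- function(counts_path, meta_path) {
  cts <- readOtuTable(counts_path)
  meta <- readSampleMeta(meta_path)
  missing <- setdiff(colnames(cts), meta$sample_id)
  if (length(missing))
    stop("samples without metadata record: ", paste(missing, collapse = ", "))
  meta <- meta[match(colnames(cts), meta$sample_id), ]
  OtuSet(cts, body_site = meta$body_site, study_id = meta$study_id)
}

#' Drop low-richness samples
#'
#' Samples detecting fewer than `min_unique` distinct OTUs tend to be noisy
#' and are excluded; the default threshold is 20 unique OTUs. Idempotent: OTU
#' rows are never touched.
#'
#' @param x an [OtuSet] or count matrix.
#' @param min_unique minimum number of OTUs with count >= 1 a sample must
#'   have to be retained.
#' @return object of the same class as `x` with offending samples removed.
#' @export
filterLowRichness <- function(x, min_unique = 20) {
  cts <- if (is(x, "OtuSet")) otuCounts(x) else as.matrix(x)
  keep <- colSums(cts >= 1) >= min_unique
  if (is(x, "OtuSet")) x[, keep] else cts[, keep, drop = FALSE]
}

#' Convert counts to relative abundances
#'
#' Divides each sample column by its total read count. Zero-depth samples are
#' rejected by name (filter them out first).
#'
#' @param x an [OtuSet] or count matrix.
#' @return numeric matrix of the same shape; each column sums to 1.
#' @export
relativeAbundance <- function(x) {
  cts <- if (is(x, "OtuSet")) otuCounts(x) else as.matrix(x)
  depth <- colSums(cts)
  zero <- colnames(cts)[depth == 0]
  if (length(zero))
    stop("zero-depth sample(s): ", paste(zero, collapse = ", "))
  sweep(cts, 2, depth, "/")
}

#' Binarize counts to presence/absence
#'
#' An OTU is scored 1 in a sample iff at least one read mapped to it.
#' Binarized tables feed the discretized independence tests of the biomarker
#' discovery stage and reduce sequencing-depth bias.
#'
#' @param x an [OtuSet] or count matrix.
#' @return integer 0/1 matrix of the same shape and dimnames.
#' @export
binarizeCounts <- function(x) {
  cts <- if (is(x, "OtuSet")) otuCounts(x) else as.matrix(x)
  out <- (cts >= 1) * 1L
  storage.mode(out) <- "integer"
  out
}

#' Normalized mutual information of two discrete vectors
#'
#' Plug-in mutual information in natural-log units, normalized to \[0, 1\].
#' The default normalization divides by the geometric mean of the marginal
#' entropies, `I(X;Y) / sqrt(H(X) H(Y))`; arithmetic-mean and minimum-entropy
#' variants are selectable. Returns 0 when either variable is constant.
#'
#' @param x,y equal-length vectors (any discrete coding; typically 0/1).
#' @param normalization one of `"sqrt"`, `"mean"`, `"min"`.
#' @return NMI in \[0, 1\].
#' @examples
#' nmi(c(0, 0, 1, 1), c(0, 0, 1, 1))  # 1
#' nmi(c(0, 0, 1, 1), c(0, 1, 0, 1))  # 0
#' @export
nmi <- function(x, y, normalization = c("sqrt", "mean", "min")) {
  if (length(x) != length(y)) stop("nmi: length mismatch")
  normalization <- match.arg(normalization)
  hx <- plugin_entropy(x)
  hy <- plugin_entropy(y)
  if (hx == 0 || hy == 0) return(0)
  mi <- plugin_mi(x, y)
  denom <- switch(normalization,
                  sqrt = sqrt(hx * hy),
                  mean = (hx + hy) / 2,
                  min = min(hx, hy))
  min(1, max(0, mi / denom))
}

# Vectorized pairwise NMI for a 0/1 matrix (OTUs in rows) via 2x2 cell counts
# from cross-products; used by the redundancy clustering.
nmiMatrix <- function(bin, normalization = c("sqrt", "mean", "min")) {
  normalization <- match.arg(normalization)
  bin <- as.matrix(bin)
  n <- ncol(bin)
  n11 <- tcrossprod(bin)
  r <- rowSums(bin)
  n10 <- outer(r, r, function(a, b) a) - n11
  n01 <- outer(r, r, function(a, b) b) - n11
  n00 <- n - n11 - n10 - n01
  ent <- function(p) ifelse(p > 0 & p < 1,
                            -(p * log(p) + (1 - p) * log1p(-p)), 0)
  h <- ent(r / n)
  term <- function(nab, pa, pb) {
    p <- nab / n
    out <- p * log(p / (pa * pb))
    out[nab == 0] <- 0
    out
  }
  px <- r / n
  pA <- matrix(px, nrow(bin), nrow(bin))  # P(row var = 1), constant per row
  pB <- t(pA)
  mi <- term(n11, pA, pB) + term(n10, pA, 1 - pB) +
        term(n01, 1 - pA, pB) + term(n00, 1 - pA, 1 - pB)
  denom <- switch(normalization,
                  sqrt = sqrt(outer(h, h)),
                  mean = outer(h, h, "+") / 2,
                  min = outer(h, h, pmin))
  out <- ifelse(denom > 0, mi / denom, 0)
  out[out < 0] <- 0
  out[out > 1] <- 1
  diag(out) <- ifelse(h > 0, 1, 0)
  dimnames(out) <- list(rownames(bin), rownames(bin))
  out
}

#' Group redundant OTUs by normalized mutual information
#'
#' Nearly identical presence/absence profiles are indistinguishable to the
#' conditional-independence machinery of biomarker discovery, so OTU pairs
#' with NMI above a threshold (0.9 by default) are collapsed. The default
#' mode clusters on the dissimilarity `d = 1 - NMI` with complete-linkage
#' agglomeration and cuts the tree at `1 - threshold`, which guarantees every
#' within-group pair has NMI >= threshold. A literal alternative mode
#' (`metric = "euclidean"`) clusters Euclidean distances between rows of the
#' NMI matrix and cuts at the largest height that still keeps all
#' within-group pairwise NMI at or above the threshold. One representative
#' per group is chosen uniformly at random with the given seed.
#'
#' @param bin 0/1 matrix, OTUs in rows (see [binarizeCounts()]).
#' @param threshold NMI threshold in (0, 1].
#' @param seed integer seed for representative choice.
#' @param metric `"nmi"` (default) or `"euclidean"` (see above).
#' @param normalization passed to the NMI computation.
#' @return list with `groups` (list of OTU-id vectors), `representative`
#'   (named character vector, one per group), `keep` (representative ids in
#'   input order) and `reduced` (the input rows for the representatives).
#' @export
redundancyGroups <- function(bin, threshold = 0.9, seed = 1,
                             metric = c("nmi", "euclidean"),
                             normalization = "sqrt") {
  if (threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  metric <- match.arg(metric)
  bin <- as.matrix(bin)
  if (nrow(bin) < 1) stop("redundancyGroups needs at least one OTU")
  if (nrow(bin) == 1) {
    groups <- list(rownames(bin))
  } else {
    nm <- nmiMatrix(bin, normalization = normalization)
    if (metric == "nmi") {
      hc <- hclust(as.dist(1 - nm), method = "complete")
      cl <- cutree(hc, h = 1 - threshold)
    } else {
      hc <- hclust(dist(nm), method = "complete")
      heights <- sort(unique(c(0, hc$height)))
      cl <- rep(seq_len(nrow(bin)))
      for (h in rev(heights)) {  # largest admissible cut
        cand <- cutree(hc, h = h)
        ok <- all(vapply(split(seq_len(nrow(bin)), cand), function(idx) {
          length(idx) < 2 || min(nm[idx, idx]) >= threshold
        }, logical(1)))
        if (ok) { cl <- cand; break }
      }
    }
    groups <- split(rownames(bin), cl)
    names(groups) <- NULL
  }
  reps <- withr::with_seed(seed, vapply(groups, function(g)
    g[sample.int(length(g), 1)], character(1)))
  names(reps) <- paste0("group", seq_along(groups))
  keep <- rownames(bin)[rownames(bin) %in% reps]
  list(groups = groups, representative = reps, keep = keep,
       reduced = bin[keep, , drop = FALSE], nmi_threshold = threshold)
}
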