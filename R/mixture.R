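#' In silico two-source mixture of one sample pair
#'
#' Mixes one target-site sample with one background-site sample: the OTU
#' relative frequencies of the two parents are combined as
#' `p = (1 - F) p_target + F p_background`, where `F` is the mixture fraction
#' (the proportion of the mixed community contributed by the background
#' source); `n` reads are then drawn multinomially from `p`, with `n` the
#' weighted average of the two parents' depths under the same weights,
#' rounded to the nearest integer and at least 1. The mixed counts therefore
#' sum to `n` exactly and are supported only on the union of the parents'
#' supports.
#'
#' @param target_counts,background_counts integer count vectors over the same
#'   OTU universe, each with positive depth.
#' @param fraction mixture fraction `F` in \[0, 1\]; `F = 0` reproduces the
#'   target composition, `F = 1` the background composition.
#' @return integer vector of mixed counts with attributes `n` (depth) and
#'   `fraction`. Uses the current RNG state; seed externally for
#'   reproducibility.
#' @export
mixPair <- function(target_counts, background_counts, fraction) {
  if (fraction < 0 || fraction > 1) stop("fraction must lie in [0, 1]")
  nt <- sum(target_counts)
  nb <- sum(background_counts)
  if (nt == 0 || nb == 0) stop("mixPair: zero-depth parent sample")
  p <- (1 - fraction) * target_counts / nt + fraction * background_counts / nb
  n <- max(1L, as.integer(round((1 - fraction) * nt + fraction * nb)))
  out <- as.integer(rmultinom(1, n, p))
  names(out) <- names(target_counts)
  attr(out, "n") <- n
  attr(out, "fraction") <- fraction
  out
}

#' Build mixed evaluation sets along a mixture-fraction grid
#'
#' For each requested (target site, background site, fraction) combination,
#' every target-site sample in the validation table is mixed with one
#' background-site sample drawn uniformly with replacement; the negatives of
#' the evaluation set are all unmixed background-site samples. Specs whose
#' site stratum is empty are skipped with a warning.
#'
#' @param counts count matrix (OTUs x samples) of the validation split.
#' @param body_site per-sample site labels.
#' @param specs data.frame with columns `target`, `background`, `fraction`.
#' @param seed integer seed.
#' @return list of evaluation sets, each a list with `spec`, `positives`
#'   (mixed count matrix), `provenance` (data.frame of parent ids and
#'   fraction) and `negatives` (count matrix of unmixed background samples).
#' @export
buildMixtureGrid <- function(counts, body_site, specs, seed = 1) {
  counts <- as.matrix(counts)
  body_site <- as.character(body_site)
  out <- list()
  withr::with_seed(seed, {
    for (i in seq_len(nrow(specs))) {
      sp <- specs[i, ]
      if (sp$target == sp$background)
        stop("target and background site must differ")
      tgt <- which(body_site == sp$target)
      bgd <- which(body_site == sp$background)
      if (!length(tgt) || !length(bgd)) {
        warning("spec skipped, empty site stratum: ", sp$target, " vs ",
                sp$background)
        next
      }
      partners <- bgd[sample.int(length(bgd), length(tgt), replace = TRUE)]
      pos <- vapply(seq_along(tgt), function(k)
        mixPair(counts[, tgt[k]], counts[, partners[k]], sp$fraction),
        integer(nrow(counts)))
      rownames(pos) <- rownames(counts)
      colnames(pos) <- sprintf("mix_%s_%s_%03d_%04d", sp$target,
                               sp$background, round(100 * sp$fraction),
                               seq_along(tgt))
      out[[length(out) + 1]] <- list(
        spec = list(target = sp$target, background = sp$background,
                    fraction = sp$fraction),
        positives = pos,
        provenance = data.frame(
          target_sample = colnames(counts)[tgt],
          background_sample = colnames(counts)[partners],
          fraction = sp$fraction, stringsAsFactors = FALSE),
        negatives = counts[, bgd, drop = FALSE])
    }
  })
  out
}

#' Contaminate a training table with a background source
#'
#' Replaces a uniformly chosen fraction of training samples by their mixture
#' with a randomly drawn background-pool sample (e.g., soil) at a fixed
#' mixture fraction, leaving all labels unchanged. The defaults reproduce the
#' contaminated-training regime: half of all training samples mixed with 30%
#' background.
#'
#' @param counts training count matrix (OTUs x samples).
#' @param background_pool count matrix of background samples over the same
#'   OTU universe.
#' @param sample_fraction fraction of training samples to contaminate.
#' @param mix_fraction mixture fraction applied to each contaminated sample.
#' @param seed integer seed.
#' @return count matrix of the same shape and column names.
#' @export
contaminateTraining <- function(counts, background_pool, sample_fraction = 0.5,
                                mix_fraction = 0.3, seed = 1) {
  if (sample_fraction < 0 || sample_fraction > 1 ||
      mix_fraction < 0 || mix_fraction > 1)
    stop("fractions must lie in [0, 1]")
  counts <- as.matrix(counts)
  background_pool <- as.matrix(background_pool)
  if (!ncol(background_pool)) stop("background pool is empty")
  n <- ncol(counts)
  n_mix <- round(sample_fraction * n)
  if (n_mix == 0) return(counts)
  withr::with_seed(seed, {
    chosen <- sample.int(n, n_mix)
    for (j in chosen) {
      b <- sample.int(ncol(background_pool), 1)
      counts[, j] <- mixPair(counts[, j], background_pool[, b], mix_fraction)
    }
  })
  counts
}
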