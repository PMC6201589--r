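#' @importFrom stats p.adjust pchisq phyper rbinom rlnorm rmultinom runif
#'   fisher.test hclust cutree as.dist dist isoreg approx cor predict sd
#'   qnorm
#' @importFrom utils head read.delim write.table combn
NULL

# Deterministic derived seeds: every stochastic stage of the package draws its
# own seed from the user's master seed so stages can be re-run independently.
# Kept strictly below .Machine$integer.max.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(offset)) %% 2147483629L)
}

# Plug-in (maximum-likelihood) entropy of a discrete vector, natural logs.
plugin_entropy <- function(x) {
  p <- as.numeric(table(x)) / length(x)
  p <- p[p > 0]
  -sum(p * log(p))
}

# Plug-in mutual information of two discrete vectors, natural logs.
plugin_mi <- function(x, y) {
  n <- length(x)
  tab <- table(x, y)
  px <- rowSums(tab) / n
  py <- colSums(tab) / n
  p <- tab / n
  e <- outer(px, py)
  ok <- p > 0
  sum(p[ok] * log(p[ok] / e[ok]))
}

# Stratified fold assignment: members of each class are shuffled and dealt to
# folds cyclically, so per-fold class counts differ by at most one.
stratified_folds <- function(labels, k, seed) {
  labels <- as.character(labels)
  small <- names(which(table(labels) < k))
  if (length(small))
    stop("class(es) with fewer than ", k, " samples: ",
         paste(small, collapse = ", "))
  folds <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- sample(idx)
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Area under the ROC curve from two score vectors
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a random positive
#' outscores a random negative, with ties counted as one half.
#'
#' @param pos numeric scores of positive samples.
#' @param neg numeric scores of negative samples.
#' @return AUC in \[0, 1\].
#' @examples
#' rocAuc(c(0.9, 0.8), c(0.1, 0.2))  # 1
#' rocAuc(c(0.5, 0.5), c(0.5, 0.5))  # 0.5
#' @export
rocAuc <- function(pos, neg) {
  if (!length(pos) || !length(neg))
    stop("rocAuc needs at least one positive and one negative score")
  r <- rank(c(pos, neg))
  np <- length(pos)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * length(neg))
}
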