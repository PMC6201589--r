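#' Hyperparameter grid for the Random-Forest classifier
#'
#' The grid searched by the inner cross-validation loop: number of trees and
#' multipliers applied to `sqrt(number of features)` to obtain `mtry`
#' (rounded to the nearest integer, floor 1, capped at the feature count).
#'
#' @param n_trees candidate forest sizes.
#' @param mtry_mult candidate multipliers of `sqrt(p)`.
#' @return list of class `"HyperGrid"`.
#' @export
hyperGrid <- function(n_trees = c(500, 1000, 2000), mtry_mult = c(0.5, 1, 2)) {
  if (!length(n_trees) || !length(mtry_mult) || any(mtry_mult <= 0))
    stop("hyperGrid: non-empty sets required, multipliers > 0")
  structure(list(n_trees = as.integer(n_trees), mtry_mult = mtry_mult),
            class = "HyperGrid")
}

#' Stratified outer cross-validation plan
#'
#' Partitions samples into `outer_k` folds, retaining the body-site
#' proportions of the full dataset within each fold (per-fold class counts
#' differ by at most one). Deterministic for a fixed seed.
#'
#' @param body_site per-sample site labels; names (if any) are carried to the
#'   fold assignment.
#' @param outer_k number of folds (default 5).
#' @param seed integer seed.
#' @return list of class `"CvPlan"` with `assignments` (integer fold index
#'   per sample) and `k`.
#' @export
makeCvPlan <- function(body_site, outer_k = 5, seed = 1) {
  folds <- stratified_folds(body_site, outer_k, derive_seed(seed, 21))
  names(folds) <- names(body_site)
  structure(list(assignments = folds, k = as.integer(outer_k)),
            class = "CvPlan")
}

macro_f1 <- function(pred, truth, classes = NULL, weights = NULL) {
  if (is.null(classes)) classes <- sort(unique(as.character(truth)))
  if (is.null(weights)) weights <- rep(1, length(truth))
  per <- vapply(classes, function(cl) {
    tp <- sum(weights[pred == cl & truth == cl])
    fp <- sum(weights[pred == cl & truth != cl])
    fn <- sum(weights[pred != cl & truth == cl])
    if (tp + fp == 0 || tp + fn == 0) return(0)
    p <- tp / (tp + fp)
    r <- tp / (tp + fn)
    if (p + r == 0) 0 else 2 * p * r / (p + r)
  }, numeric(1))
  list(per_class = per, macro = mean(per))
}

fit_forest <- function(X, y, n_trees, mtry_mult, seed, importance = "none") {
  mtry <- min(ncol(X), max(1L, as.integer(round(mtry_mult * sqrt(ncol(X))))))
  cw <- as.numeric(length(y) / (nlevels(y) * table(y)))
  ranger::ranger(x = X, y = y, num.trees = n_trees, mtry = mtry,
                 probability = TRUE, class.weights = cw,
                 importance = importance, seed = seed, num.threads = 1)
}

# Isotonic calibrator from out-of-fold (score, indicator) pairs. Fitted with
# stats::isoreg in score order; fitted values are pooled (averaged) over tied
# scores, then linearly interpolated. A vanishing linear term keeps the map
# strictly increasing so sample rankings -- and hence AUC -- are unchanged.
fit_isotonic <- function(scores, indicator) {
  ord <- order(scores)
  yf <- isoreg(seq_along(scores), indicator[ord])$yf
  xs <- scores[ord]
  ux <- unique(xs)
  uy <- as.numeric(tapply(yf, match(xs, ux), mean))
  eps <- 1e-6
  function(s) {
    base <- if (length(ux) == 1) rep(uy, length(s)) else
      approx(ux, uy, xout = s, rule = 2)$y
    pmin(1, pmax(0, base)) * (1 - eps) + eps * s
  }
}

#' Train a calibrated Random-Forest body-site classifier
#'
#' Grid-searches the forest hyperparameters over a stratified inner
#' cross-validation (macro-F1 objective), refits the best grid point on all
#' training data with class weights inversely proportional to class
#' frequency, and fits one isotonic calibrator per class on the inner
#' out-of-fold scores of the selected grid point. Feature importances are
#' impurity-based and normalized to sum to one.
#'
#' @param relab relative-abundance matrix, OTUs in rows, samples in columns
#'   (see [relativeAbundance()]).
#' @param labels per-sample body-site labels.
#' @param grid a [hyperGrid()].
#' @param inner_k number of inner folds (default 4).
#' @param seed integer seed driving fold assignment and forest randomness.
#' @return A [TrainedModel].
#' @export
trainModel <- function(relab, labels, grid = hyperGrid(), inner_k = 4,
                       seed = 1) {
  X <- t(as.matrix(relab))
  y <- factor(as.character(labels))
  if (nlevels(y) < 2)
    stop("trainModel: training set has a single class")
  folds <- stratified_folds(y, inner_k, derive_seed(seed, 31))
  gridpts <- expand.grid(n_trees = grid$n_trees, mtry_mult = grid$mtry_mult,
                         KEEP.OUT.ATTRS = FALSE)
  inner_fits <- vector("list", inner_k)  # refits for the winning point
  scores <- numeric(nrow(gridpts))
  for (g in seq_len(nrow(gridpts))) {
    f1s <- numeric(inner_k)
    fits <- vector("list", inner_k)
    for (f in seq_len(inner_k)) {
      tr <- folds != f
      fit <- fit_forest(X[tr, , drop = FALSE], droplevels(y[tr]),
                        gridpts$n_trees[g], gridpts$mtry_mult[g],
                        derive_seed(seed, 100 * g + f))
      pr <- predict(fit, data = X[!tr, , drop = FALSE],
                    num.threads = 1)$predictions
      pred <- colnames(pr)[max.col(pr, ties.method = "first")]
      f1s[f] <- macro_f1(pred, y[!tr], classes = levels(y))$macro
      fits[[f]] <- fit
    }
    scores[g] <- mean(f1s)
    if (g == which.max(replace(scores, seq_len(nrow(gridpts)) > g, -Inf)))
      inner_fits <- fits
  }
  best <- which.max(scores)  # ties resolved toward the first grid point

  # out-of-fold calibration scores under the selected hyperparameters
  oof <- matrix(NA_real_, nrow = length(y), ncol = nlevels(y),
                dimnames = list(NULL, levels(y)))
  for (f in seq_len(inner_k)) {
    pr <- predict(inner_fits[[f]], data = X[folds == f, , drop = FALSE],
                  num.threads = 1)$predictions
    oof[folds == f, colnames(pr)] <- pr
  }
  oof[is.na(oof)] <- 0
  calibrators <- lapply(levels(y), function(cl)
    fit_isotonic(oof[, cl], as.numeric(y == cl)))
  names(calibrators) <- levels(y)

  final <- fit_forest(X, y, gridpts$n_trees[best], gridpts$mtry_mult[best],
                      derive_seed(seed, 41), importance = "impurity")
  imp <- final$variable.importance
  imp[imp < 0] <- 0
  imp <- if (sum(imp) > 0) imp / sum(imp) else
    rep(1 / length(imp), length(imp))
  names(imp) <- colnames(X)
  new("TrainedModel", forest = final, calibrators = calibrators,
      features = colnames(X), classes = levels(y),
      hyper = list(n_trees = gridpts$n_trees[best],
                   mtry_mult = gridpts$mtry_mult[best],
                   inner_f1 = scores[best]),
      importance = imp)
}

#' Calibrated class probabilities for new samples
#'
#' Aligns the input table to the model's feature universe (absent features
#' are imputed as 0, extra features dropped with a warning), applies the
#' forest, passes each class score through its isotonic calibrator, and (by
#' default) renormalizes each sample's probabilities to sum to one. The
#' calibrators are strictly monotone, so with `renormalize = FALSE` sample
#' rankings per class -- and therefore AUC -- are identical before and after
#' calibration.
#'
#' @param model a [TrainedModel].
#' @param relab relative-abundance matrix, OTUs x samples.
#' @param renormalize renormalize rows to sum to 1 (default TRUE).
#' @param calibrate apply the isotonic calibrators (default TRUE).
#' @return numeric matrix, samples x classes.
#' @export
predictProba <- function(model, relab, renormalize = TRUE, calibrate = TRUE) {
  relab <- as.matrix(relab)
  common <- intersect(model@features, rownames(relab))
  if (!length(common))
    stop("predictProba: no overlap between table OTUs and model features")
  extra <- setdiff(rownames(relab), model@features)
  if (length(extra))
    warning(length(extra), " feature(s) absent from the model were dropped")
  X <- matrix(0, nrow = ncol(relab), ncol = length(model@features),
              dimnames = list(colnames(relab), model@features))
  X[, common] <- t(relab[common, , drop = FALSE])
  pr <- predict(model@forest, data = X, num.threads = 1)$predictions
  pr <- pr[, model@classes, drop = FALSE]
  if (calibrate)
    for (cl in model@classes) pr[, cl] <- model@calibrators[[cl]](pr[, cl])
  if (renormalize) {
    rs <- rowSums(pr)
    rs[rs == 0] <- 1
    pr <- pr / rs
  }
  rownames(pr) <- colnames(relab)
  pr
}

#' Predicted body-site labels
#'
#' Argmax of [predictProba()], ties broken toward the first class.
#'
#' @inheritParams predictProba
#' @return character vector of predicted labels.
#' @export
predictSite <- function(model, relab) {
  pr <- predictProba(model, relab)
  model@classes[max.col(pr, ties.method = "first")]
}

#' Per-class and macro F1 report
#'
#' Per-class F1 as the harmonic mean of precision and recall computed from
#' (optionally weighted) true/false positive counts; the mean F1 is the
#' unweighted average over classes (macro-F1). Supplying
#' [studyWeights()] yields the study-weighted variant that rewards correct
#' prediction of samples from small studies.
#'
#' @param pred,truth equal-length label vectors.
#' @param sample_weights optional per-sample weights.
#' @return list with `per_class` (named numeric) and `macro_f1`.
#' @export
f1Report <- function(pred, truth, sample_weights = NULL) {
  pred <- as.character(pred)
  truth <- as.character(truth)
  if (length(pred) != length(truth)) stop("f1Report: length mismatch")
  classes <- sort(unique(truth))
  out <- macro_f1(pred, truth, classes = classes, weights = sample_weights)
  list(per_class = out$per_class, macro_f1 = out$macro)
}

#' Study-inverse sample weights
#'
#' Each sample is weighted by the inverse of the number of samples in its
#' study, so the total weight equals the number of studies and small studies
#' count as much as large ones.
#'
#' @param study_id per-sample study labels.
#' @return numeric weight vector.
#' @export
studyWeights <- function(study_id) {
  study_id <- as.character(study_id)
  tab <- table(study_id)
  as.numeric(1 / tab[study_id])
}

#' Row-normalized confusion matrix
#'
#' Rows are true classes, columns predicted classes; each row with at least
#' one true sample sums to one.
#'
#' @param pred,truth equal-length label vectors.
#' @return numeric matrix.
#' @export
confusionMatrix <- function(pred, truth) {
  classes <- sort(unique(c(as.character(pred), as.character(truth))))
  tab <- table(factor(truth, classes), factor(pred, classes))
  rs <- rowSums(tab)
  rs[rs == 0] <- 1
  out <- as.matrix(tab / rs)
  dimnames(out) <- list(true = classes, predicted = classes)
  out
}

#' AUC of a mixed evaluation set
#'
#' Scores the mixed positives and the unmixed background negatives of one
#' evaluation set (see [buildMixtureGrid()]) with the calibrated target-class
#' probability (un-renormalized, so the monotone calibration cannot alter the
#' ranking) and returns the Mann-Whitney AUC with ties counted one half.
#'
#' @param model a [TrainedModel].
#' @param eval_set one element of the [buildMixtureGrid()] output.
#' @return AUC in \[0, 1\].
#' @export
mixtureAuc <- function(model, eval_set) {
  if (!ncol(eval_set$positives) || !ncol(eval_set$negatives))
    stop("mixtureAuc: empty positive or negative side")
  target <- eval_set$spec$target
  score <- function(cts)
    predictProba(model, relativeAbundance(cts),
                 renormalize = FALSE)[, target]
  rocAuc(score(eval_set$positives), score(eval_set$negatives))
}

#' F1-optimal decision thresholds over a mixture grid
#'
#' For every (target site, background site, fraction) combination, mixes the
#' training samples in silico, scores mixed positives and unmixed background
#' negatives with the calibrated target-class probability, and picks the
#' threshold maximizing binary F1 along the precision-recall curve (candidate
#' cut points are the observed scores; a sample is called positive when its
#' score is at or above the threshold; ties are broken toward the higher
#' threshold). Only thresholds are tuned here -- the forest and calibrators
#' never see mixed samples.
#'
#' @param model a [TrainedModel] fitted on the (unmixed) training split.
#' @param counts training count matrix (OTUs x samples).
#' @param body_site per-sample site labels of the training split.
#' @param sites sites to cross (default: all observed sites).
#' @param fractions mixture-fraction grid (default 10 steps of 10%).
#' @param seed integer seed.
#' @return data.frame with one row per grid entry: `target`, `background`,
#'   `fraction`, `threshold`, `f1`.
#' @export
optimizeThresholds <- function(model, counts, body_site, sites = NULL,
                               fractions = seq(0.1, 1, by = 0.1), seed = 1) {
  body_site <- as.character(body_site)
  if (is.null(sites)) sites <- sort(unique(body_site))
  specs <- expand.grid(target = sites, background = sites,
                       fraction = fractions, stringsAsFactors = FALSE)
  specs <- specs[specs$target != specs$background, ]
  specs <- specs[order(specs$target, specs$background, specs$fraction), ]
  rows <- vector("list", nrow(specs))
  for (i in seq_len(nrow(specs))) {
    sp <- specs[i, ]
    es <- buildMixtureGrid(counts, body_site, sp,
                           seed = derive_seed(seed, i))[[1]]
    pos <- predictProba(model, relativeAbundance(es$positives),
                        renormalize = FALSE)[, sp$target]
    neg <- predictProba(model, relativeAbundance(es$negatives),
                        renormalize = FALSE)[, sp$target]
    cut <- bestF1Threshold(pos, neg)
    rows[[i]] <- data.frame(target = sp$target, background = sp$background,
                            fraction = sp$fraction, threshold = cut$threshold,
                            f1 = cut$f1, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' F1-optimal threshold for one score set
#'
#' Enumerates all distinct observed scores as cut points (classification rule
#' `score >= threshold`; intermediate cut points between consecutive distinct
#' scores induce identical confusion counts, so observed scores exhaust the
#' attainable F1 values) and returns the highest threshold attaining the
#' maximal binary F1.
#'
#' @param pos,neg scores of positives and negatives.
#' @return list with `threshold` and `f1`.
#' @export
bestF1Threshold <- function(pos, neg) {
  if (!length(pos)) stop("bestF1Threshold: no positives")
  s <- c(pos, neg)
  lab <- c(rep(1, length(pos)), rep(0, length(neg)))
  ord <- order(-s)
  s <- s[ord]
  lab <- lab[ord]
  # cumulative counts at each cut "score >= s[i]", evaluated at the last
  # occurrence of each distinct score
  tp <- cumsum(lab)
  n_called <- seq_along(s)
  idx <- which(rev(!duplicated(rev(s))))  # last index per distinct score
  precision <- tp[idx] / n_called[idx]
  recall <- tp[idx] / length(pos)
  f1 <- ifelse(precision + recall == 0, 0,
               2 * precision * recall / (precision + recall))
  best <- max(f1)
  at <- idx[f1 == best]
  list(threshold = max(s[at]), f1 = best)
}

#' Biased sample subset
#'
#' Keeps all samples from one body site and down-samples every other site
#' (without replacement, seeded) to `round(ratio * n_bias)` samples; sites
#' smaller than the quota are kept whole with a warning.
#'
#' @param sample_ids sample identifiers.
#' @param body_site per-sample site labels.
#' @param bias_site site kept in full.
#' @param ratio quota for other sites relative to the bias site (default 0.1).
#' @param seed integer seed.
#' @return character vector of retained sample ids.
#' @export
biasedSubset <- function(sample_ids, body_site, bias_site, ratio = 0.1,
                         seed = 1) {
  body_site <- as.character(body_site)
  if (!bias_site %in% body_site)
    stop("bias site not present: ", bias_site)
  quota <- round(ratio * sum(body_site == bias_site))
  keep <- sample_ids[body_site == bias_site]
  withr::with_seed(seed, {
    for (s in setdiff(unique(body_site), bias_site)) {
      ids <- sample_ids[body_site == s]
      if (length(ids) <= quota) {
        if (length(ids) < quota)
          warning("site ", s, " smaller than quota; kept whole")
        keep <- c(keep, ids)
      } else {
        keep <- c(keep, sample(ids, quota))
      }
    }
  })
  keep
}

#' Learning curve over cumulative studies
#'
#' Evaluates classification performance for increasing numbers of studies:
#' studies are ordered largest first (then seeded random order of the rest),
#' a model is trained on the cumulative sample set at each step, and both
#' unweighted and study-weighted macro-F1 are measured on a fixed stratified
#' held-out split.
#'
#' @param counts count matrix (OTUs x samples).
#' @param body_site,study_id per-sample labels.
#' @param grid a [hyperGrid()] (a reduced grid keeps the curve cheap).
#' @param inner_k inner folds for each trained model.
#' @param holdout_k the held-out split is fold 1 of a stratified `holdout_k`
#'   fold plan (default 4, i.e. 25% held out).
#' @param seed integer seed.
#' @return data.frame with one row per cumulative study set: `n_studies`,
#'   `n_samples`, `macro_f1`, `weighted_f1`.
#' @export
learningCurveByStudy <- function(counts, body_site, study_id,
                                 grid = hyperGrid(1000, 1), inner_k = 4,
                                 holdout_k = 4, seed = 1) {
  body_site <- as.character(body_site)
  study_id <- as.character(study_id)
  if (length(unique(study_id)) < 2)
    stop("learning curve needs at least 2 studies")
  folds <- stratified_folds(body_site, holdout_k, derive_seed(seed, 51))
  heldout <- folds == 1
  sizes <- sort(table(study_id), decreasing = TRUE)
  rest <- names(sizes)[-1]
  order_rest <- withr::with_seed(derive_seed(seed, 52), sample(rest))
  study_order <- c(names(sizes)[1], order_rest)
  relab <- relativeAbundance(counts)
  w_all <- studyWeights(study_id)
  rows <- vector("list", length(study_order))
  for (i in seq_along(study_order)) {
    in_set <- study_id %in% study_order[seq_len(i)]
    tr <- in_set & !heldout
    model <- tryCatch(
      trainModel(relab[, tr, drop = FALSE], body_site[tr], grid = grid,
                 inner_k = inner_k, seed = derive_seed(seed, 60 + i)),
      error = function(e) NULL)
    if (is.null(model)) {
      rows[[i]] <- data.frame(n_studies = i, n_samples = sum(tr),
                              macro_f1 = NA_real_, weighted_f1 = NA_real_)
      next
    }
    pred <- predictSite(model, relab[, heldout, drop = FALSE])
    truth <- body_site[heldout]
    rows[[i]] <- data.frame(
      n_studies = i, n_samples = sum(tr),
      macro_f1 = f1Report(pred, truth)$macro_f1,
      weighted_f1 = f1Report(pred, truth,
                             sample_weights = w_all[heldout])$macro_f1)
  }
  do.call(rbind, rows)
}

#' Overlap and rank agreement of two models' feature importances
#'
#' Counts predictive features (importance strictly positive) shared and
#' exclusive to each model and computes the Spearman rank correlation of the
#' importances over the shared predictive set (undefined and reported as `NA`
#' when the intersection has fewer than two members or zero variance).
#'
#' @param a,b [TrainedModel]s or named importance vectors.
#' @return list with `shared`, `a_only`, `b_only` (counts),
#'   `fraction_a_supported` (share of a's predictive features also predictive
#'   in b) and `rho`.
#' @export
featureImportanceOverlap <- function(a, b) {
  imp <- function(x) if (is(x, "TrainedModel")) featureImportance(x) else x
  ia <- imp(a)
  ib <- imp(b)
  pa <- names(ia)[ia > 0]
  pb <- names(ib)[ib > 0]
  shared <- intersect(pa, pb)
  rho <- if (length(shared) >= 2 && sd(ia[shared]) > 0 && sd(ib[shared]) > 0)
    cor(ia[shared], ib[shared], method = "spearman") else NA_real_
  list(shared = length(shared), a_only = length(setdiff(pa, pb)),
       b_only = length(setdiff(pb, pa)),
       fraction_a_supported = if (length(pa)) length(shared) / length(pa)
                              else NA_real_,
       rho = rho)
}
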