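test_that("cross-validation plans are stratified, balanced and seeded", {
  bs <- rep(paste0("s", 1:5), each = 20)
  plan <- makeCvPlan(bs, 5, seed = 1)
  tab <- table(plan$assignments, bs)
  expect_true(all(tab == 4))  # exact divisibility: 4 of each class per fold
  plan2 <- makeCvPlan(bs, 5, seed = 1)
  expect_identical(plan$assignments, plan2$assignments)

  odd <- rep(paste0("s", 1:5), each = 7)
  tab2 <- table(makeCvPlan(odd, 5, seed = 2)$assignments, odd)
  expect_true(all(apply(tab2, 2, function(col) diff(range(col)) <= 1)))

  expect_error(makeCvPlan(c(rep("a", 10), rep("b", 3)), 5), "b")
})

test_that("F1 reports match hand-computed precision/recall arithmetic", {
  truth <- c("a", "a", "b", "b")
  pred <- c("a", "b", "b", "b")
  rep_ <- f1Report(pred, truth)
  expect_equal(rep_$per_class[["a"]], 2 / 3)
  expect_equal(rep_$per_class[["b"]], 0.8)
  expect_equal(rep_$macro_f1, (2 / 3 + 0.8) / 2)
  perfect <- f1Report(truth, truth)
  expect_equal(perfect$macro_f1, 1)
  expect_equal(f1Report(pred, truth, sample_weights = rep(2, 4))$macro_f1,
               rep_$macro_f1)  # uniform weights change nothing
})

test_that("study weights invert study sizes and sum to the study count", {
  w <- studyWeights(c("x", "x", "y"))
  expect_equal(w, c(0.5, 0.5, 1))
  withr::with_seed(9, {
    st <- sample(paste0("st", 1:7), 100, replace = TRUE)
    expect_equal(sum(studyWeights(st)), length(unique(st)))
  })
})

test_that("confusion matrices are row-normalized pair tallies", {
  truth <- rep("A", 9)
  pred <- c(rep("A", 6), rep("B", 3))
  cm <- confusionMatrix(pred, truth)
  expect_equal(cm["A", "A"], 2 / 3)
  expect_equal(cm["A", "B"], 1 / 3)
  expect_equal(confusionMatrix(truth, truth)["A", "A"], 1)
  # brute-force tally oracle on random labels
  withr::with_seed(10, {
    t2 <- sample(c("a", "b", "c"), 60, replace = TRUE)
    p2 <- sample(c("a", "b", "c"), 60, replace = TRUE)
  })
  cm2 <- confusionMatrix(p2, t2)
  for (i in c("a", "b", "c")) for (j in c("a", "b", "c"))
    expect_equal(cm2[i, j], sum(t2 == i & p2 == j) / sum(t2 == i))
  expect_true(all(abs(rowSums(cm2) - 1) < 1e-12))
})

test_that("rank-based AUC follows the Mann-Whitney tie convention", {
  expect_equal(rocAuc(c(0.9, 0.8), c(0.1, 0.2)), 1)
  expect_equal(rocAuc(c(0.5, 0.5), c(0.5, 0.5)), 0.5)
  # exhaustive pair comparison: 3 wins + 1 loss out of 4 pairs
  expect_equal(rocAuc(c(0.9, 0.4), c(0.5, 0.1)), 0.75)
  expect_error(rocAuc(numeric(0), 1), "at least one")
})

test_that("F1-optimal thresholds maximize over enumerated cut points", {
  # perfectly separated: the lowest positive score attains F1 = 1
  sep <- bestF1Threshold(c(0.8, 0.9), c(0.1, 0.2))
  expect_equal(sep$f1, 1)
  expect_equal(sep$threshold, 0.8)
  # frozen case checked against brute-force enumeration over all cut points
  pos <- c(0.9, 0.6)
  neg <- c(0.7, 0.2)
  brute <- vapply(sort(unique(c(pos, neg))), function(thr) {
    tp <- sum(pos >= thr); fp <- sum(neg >= thr)
    p <- if (tp + fp) tp / (tp + fp) else 0
    r <- tp / length(pos)
    if (p + r) 2 * p * r / (p + r) else 0
  }, numeric(1))
  got <- bestF1Threshold(pos, neg)
  expect_equal(got$f1, max(brute))
  expect_equal(got$f1, 0.8)        # threshold 0.6: P = 2/3, R = 1
  expect_equal(got$threshold, 0.6)
})

test_that("separable classes are learned perfectly and probabilities are calibrated", {
  # two classes with disjoint OTU support
  withr::with_seed(12, {
    n <- 60
    cts <- rbind(
      matrix(rpois(5 * n, ifelse(rep(rep(c(1, 0), each = n / 2), each = 5),
                                 50, 0)), nrow = 5),
      matrix(rpois(5 * n, ifelse(rep(rep(c(0, 1), each = n / 2), each = 5),
                                 50, 0)), nrow = 5))
  })
  dimnames(cts) <- list(paste0("o", 1:10), paste0("s", 1:60))
  cts["o1", cts["o1", ] == 0] <- 1L  # avoid zero-depth columns
  bs <- rep(c("gut", "skin"), each = 30)
  relab <- relativeAbundance(cts)
  model <- trainModel(relab, bs, grid = hyperGrid(100, 1), seed = 3)
  expect_equal(f1Report(predictSite(model, relab), bs)$macro_f1, 1)

  pp <- predictProba(model, relab)
  expect_true(all(abs(rowSums(pp) - 1) < 1e-9))
  expect_true(all(pp >= 0 & pp <= 1))
  # monotone calibration leaves the AUC of each class score unchanged
  raw <- predictProba(model, relab, renormalize = FALSE, calibrate = FALSE)
  cal <- predictProba(model, relab, renormalize = FALSE, calibrate = TRUE)
  for (cl in model@classes) {
    is_pos <- bs == cl
    expect_equal(rocAuc(raw[is_pos, cl], raw[!is_pos, cl]),
                 rocAuc(cal[is_pos, cl], cal[!is_pos, cl]))
  }
  # feature importances are normalized
  expect_equal(sum(featureImportance(model)), 1)
  # prediction aligns by feature id: missing OTUs imputed as absent
  sub <- relab[1:8, , drop = FALSE]
  expect_identical(dim(predictProba(model, sub)), c(60L, 2L))
  expect_error(predictProba(model,
                            matrix(0.5, 1, 2,
                                   dimnames = list("other", c("x", "y")))),
               "no overlap")
})

test_that("a 3x3 grid evaluates exactly nine inner-CV points", {
  withr::with_seed(14, {
    cts <- matrix(rpois(20 * 40, 20), nrow = 20,
                  dimnames = list(paste0("o", 1:20), paste0("s", 1:40)))
    cts[1:5, 1:20] <- cts[1:5, 1:20] + 60L
  })
  bs <- rep(c("a", "b"), each = 20)
  grid <- hyperGrid(n_trees = c(50, 100, 150), mtry_mult = c(0.5, 1, 2))
  model <- trainModel(relativeAbundance(cts), bs, grid = grid, seed = 2)
  expect_true(model@hyper$n_trees %in% grid$n_trees)
  expect_true(model@hyper$mtry_mult %in% grid$mtry_mult)
  expect_identical(nrow(expand.grid(grid$n_trees, grid$mtry_mult)), 9L)
})

test_that("mixture AUC separates mixed positives from background negatives", {
  cfg <- generatorConfig(n_sites = 2, samples_per_site = c(30L, 30L),
                         n_noise = 40, n_indirect = 0)
  ose <- generateDataset(cfg, seed = 15)
  cts <- otuCounts(ose)
  bs <- bodySite(ose)
  model <- trainModel(relativeAbundance(cts), bs, grid = hyperGrid(200, 1),
                      seed = 4)
  es <- buildMixtureGrid(cts, bs, data.frame(target = "site1",
                                             background = "site2",
                                             fraction = 0.3), seed = 5)[[1]]
  auc <- mixtureAuc(model, es)
  expect_gt(auc, 0.9)  # 70% target content is easily detected
  expect_true(auc <= 1)
})

test_that("biased subsets keep the bias site whole and down-sample the rest", {
  ids <- sprintf("s%03d", 1:130)
  bs <- c(rep("big", 100), rep("mid", 20), rep("small", 10))
  keep <- biasedSubset(ids, bs, "big", ratio = 0.1, seed = 1)
  expect_identical(sum(keep %in% ids[bs == "big"]), 100L)
  expect_identical(sum(keep %in% ids[bs == "mid"]), 10L)
  expect_identical(sum(keep %in% ids[bs == "small"]), 10L)  # exactly at quota
  expect_identical(biasedSubset(ids, bs, "big", ratio = 0.1, seed = 1), keep)
  expect_warning(biasedSubset(ids, bs, "big", ratio = 0.15, seed = 1),
                 "smaller than quota")
  even <- biasedSubset(ids[1:40], rep(c("a", "b"), each = 20), "a", ratio = 1,
                       seed = 2)
  expect_identical(sort(even), ids[1:40])
  expect_error(biasedSubset(ids, bs, "missing"), "missing")
})

test_that("feature-importance overlap is reflexive and handles disjoint sets", {
  a <- c(o1 = 0.5, o2 = 0.3, o3 = 0.2, o4 = 0)
  self <- featureImportanceOverlap(a, a)
  expect_identical(self$shared, 3L)
  expect_equal(self$fraction_a_supported, 1)
  expect_equal(self$rho, 1)
  b <- c(o1 = 0, o2 = 0, o3 = 0, o4 = 1)
  dis <- featureImportanceOverlap(a, b)
  expect_identical(dis$shared, 0L)
  expect_true(is.na(dis$rho))
  expect_identical(dis$a_only, 3L)
  expect_identical(dis$b_only, 1L)
})

test_that("the study learning curve has one point per cumulative study set", {
  cfg <- generatorConfig(n_sites = 2, samples_per_site = c(60L, 60L),
                         n_studies = 3, n_noise = 30, n_indirect = 0)
  ose <- generateDataset(cfg, seed = 16)
  lc <- learningCurveByStudy(otuCounts(ose), bodySite(ose), studyId(ose),
                             grid = hyperGrid(100, 1), inner_k = 2,
                             seed = 2)
  expect_identical(nrow(lc), 3L)
  sizes <- table(studyId(ose))
  expect_identical(lc$n_studies, 1:3)
  # first point trains only on the largest study (minus the held-out split)
  expect_lte(lc$n_samples[1], max(sizes))
  expect_true(all(diff(lc$n_samples) > 0))
  expect_true(all(is.na(lc$macro_f1) | (lc$macro_f1 >= 0 & lc$macro_f1 <= 1)))
})
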