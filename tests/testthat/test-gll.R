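test_that("unconditional G-tests reproduce the closed-form boundary cases", {
  # exact independence in a balanced 2x2
  r <- gTest(c(0, 0, 1, 1), c(0, 1, 0, 1))
  expect_equal(r$G, 0)
  expect_identical(r$df, 1L)
  expect_equal(r$p, 1)
  # perfect dependence: G = 2 N ln 2 at N = 6
  v <- c(0, 0, 0, 1, 1, 1)
  r2 <- gTest(v, v)
  expect_equal(r2$G, 12 * log(2), tolerance = 1e-12)
  expect_equal(r2$p, pchisq(12 * log(2), 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_lt(abs(r2$p - 0.00393), 5e-5)
  # constant margin: df = 0 forces p = 1
  r3 <- gTest(v, rep(1, 6))
  expect_equal(r3$G, 0)
  expect_identical(r3$df, 0L)
  expect_equal(r3$p, 1)
  expect_error(gTest(v, c(0, 1)), "length")
})

test_that("conditional G equals 2N times plug-in conditional MI on random tables", {
  withr::with_seed(11, {
    for (r in 1:200) {
      n <- sample(20:60, 1)
      x <- rbinom(n, 1, runif(1, 0.2, 0.8))
      y <- rbinom(n, 1, runif(1, 0.2, 0.8))
      nz <- sample(0:2, 1)
      z <- replicate(nz, rbinom(n, 1, runif(1, 0.3, 0.7)), simplify = FALSE)
      got <- gTest(x, y, conditioning = z)
      strata <- if (nz) do.call(paste, z) else NULL
      want <- 2 * n * oracle_cmi(x, y, strata = strata)
      if (want < 1e-8) want <- 0  # shared zero convention (roundoff guard)
      expect_lt(abs(got$G - want), 1e-9)
      want_p <- if (got$df == 0) 1 else
        pchisq(want, got$df, lower.tail = FALSE)
      expect_lt(abs(got$p - want_p), 1e-10)
    }
  })
})

test_that("the univariate screen ranks, adjusts and filters candidates", {
  withr::with_seed(3, {
    target <- rep(c(0L, 1L), each = 40)
    bin <- rbind(hit = target,                          # identical to target
                 near = ifelse(runif(80) < 0.9, target, 1L - target),
                 flat = rbinom(80, 1, 0.5),
                 const = rep(1L, 80))
  })
  scr <- univariateScreen(bin, target)
  expect_identical(scr$otu_id[1], "hit")
  expect_true(scr$candidate[scr$otu_id == "hit"])
  expect_false(scr$candidate[scr$otu_id == "const"])
  expect_equal(scr$p[scr$otu_id == "const"], 1)
  expect_true(all(scr$p_adj >= scr$p))
  # monotonicity: raising alpha never shrinks the candidate set
  lo <- univariateScreen(bin, target, gllConfig(alpha = 0.01))
  hi <- univariateScreen(bin, target, gllConfig(alpha = 0.1))
  expect_true(all(lo$otu_id[lo$candidate] %in% hi$otu_id[hi$candidate]))
})

test_that("HITON-PC removes variables that a parent explains away", {
  # T -> A -> B: B depends on the site only through A
  withr::with_seed(5, {
    t_ <- rep(c(0L, 1L), each = 400)
    a <- rbinom(800, 1, ifelse(t_ == 1, 0.9, 0.1))
    b <- rbinom(800, 1, ifelse(a == 1, 0.9, 0.1))
    noise <- rbinom(800, 1, 0.5)
    bin <- rbind(A = a, B = b, Z = noise)
  })
  hp <- hitonPC(bin, t_)
  expect_true("A" %in% hp$pc)
  expect_false("B" %in% hp$pc)
  # output is always a subset of the screened candidates
  expect_true(all(hp$pc %in% hp$screen$otu_id[hp$screen$candidate]))
})

test_that("a single screened candidate is returned unconditionally", {
  withr::with_seed(6, {
    t_ <- rep(c(0L, 1L), each = 30)
    bin <- rbind(only = ifelse(runif(60) < 0.95, t_, 1L - t_))
  })
  hp <- hitonPC(bin, t_)
  expect_identical(hp$pc, "only")
})

test_that("symmetry-corrected HITON-PC is exact on a spouse-of-child graph", {
  # T -> C, S -> C, S -> X, C -> X: the plain forward/backward passes cannot
  # separate X from T (its separator contains S, outside PC(T)); the
  # symmetry correction removes it.
  adj <- matrix(0, 4, 4, dimnames = list(c("T", "C", "S", "X"),
                                         c("T", "C", "S", "X")))
  adj["T", "C"] <- adj["S", "C"] <- adj["S", "X"] <- adj["C", "X"] <- 1
  got <- hiton_on_dag(adj, "T")
  expect_identical(got, "C")
})

test_that("association signs follow the 2x2 determinant", {
  y <- rep(c(1L, 0L), each = 20)
  expect_identical(associationSign(y, y), 1L)
  expect_identical(associationSign(1L - y, y), -1L)
  # a=30 b=10 c=10 d=30: determinant positive, odds ratio > 1
  x <- c(rep(1, 30), rep(0, 10), rep(1, 10), rep(0, 30))
  t_ <- c(rep(1, 40), rep(0, 40))
  expect_identical(associationSign(x, t_), 1L)
  expect_gt((30 * 30) / (10 * 10), 1)
  expect_identical(associationSign(rep(1L, 40), rep(c(0L, 1L), 20)),
                   NA_integer_)
  # balanced table: determinant exactly zero -> indeterminate
  xb <- c(1, 1, 0, 0)
  yb <- c(1, 0, 1, 0)
  expect_identical(associationSign(xb, yb), NA_integer_)
})

test_that("discovered markers carry the planted signs", {
  cfg <- generatorConfig(n_sites = 3, samples_per_site = rep(100L, 3),
                         n_indirect = 0, n_noise = 30,
                         study_dropout_range = c(0, 0))
  ose <- generateDataset(cfg, seed = 17)
  gt <- groundTruth(ose)
  bset <- discoverMarkers(binarizeCounts(ose), bodySite(ose))
  m <- markers(bset)
  expect_false(anyDuplicated(m[, c("otu_id", "site")]) > 0)
  for (s in names(gt@direct_pa)) {
    pa_found <- m[m$site == s & m$otu_id %in% gt@direct_pa[[s]], ]
    na_found <- m[m$site == s & m$otu_id %in% gt@direct_na[[s]], ]
    expect_true(all(pa_found$sign == 1L))
    expect_true(all(na_found$sign == -1L))
    expect_gt(nrow(pa_found), 0)
  }
  expect_true(all(m$strength_nmi >= 0 & m$strength_nmi <= 1))
  expect_true(all(m$prevalence <= ncol(otuCounts(ose))))
})

test_that("marker summaries compute Jaccard overlap and type counts", {
  m <- data.frame(
    otu_id = c("a", "b", "c", "b", "c", "d"),
    site = rep(c("s1", "s2"), each = 3),
    sign = c(1L, 1L, -1L, 1L, -1L, NA),
    strength_nmi = 0.5, prevalence = 3, importance_percentile = NA_real_)
  bset <- new("BiomarkerSet", markers = m, tests = list(), config = list())
  sm <- markerSummaries(bset)
  expect_equal(sm$jaccard["s1", "s2"], 0.5)  # {a,b,c} vs {b,c,d}
  expect_equal(sm$jaccard["s1", "s1"], 1)
  expect_identical(sm$counts$pa[sm$counts$site == "s1"], 2L)
  expect_identical(sm$counts$na[sm$counts$site == "s2"], 1L)
  expect_identical(sm$counts$indeterminate[sm$counts$site == "s2"], 1L)

  m2 <- m
  m2$otu_id <- c("a", "b", "c", "x", "y", "z")
  sm2 <- markerSummaries(new("BiomarkerSet", markers = m2, tests = list(),
                             config = list()))
  expect_equal(sm2$jaccard["s1", "s2"], 0)
})
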