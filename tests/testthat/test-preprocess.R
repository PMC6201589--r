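test_that("count table and metadata TSVs round-trip losslessly", {
  ose <- tiny_otuset()
  cdir <- withr::local_tempdir()
  cpath <- file.path(cdir, "counts.tsv")
  mpath <- file.path(cdir, "meta.tsv")
  writeOtuTable(ose, cpath)
  writeSampleMeta(ose, mpath)
  back <- readOtuSet(cpath, mpath)
  expect_identical(otuCounts(back), otuCounts(ose))
  expect_identical(bodySite(back), bodySite(ose))
  expect_identical(studyId(back), studyId(ose))
})

test_that("malformed tables are rejected with row/column context", {
  cdir <- withr::local_tempdir()
  p <- file.path(cdir, "bad.tsv")
  writeLines(c("otu_id\ts1\ts2", "otuA\t1\t2", "otuA\t3\t4"), p)
  expect_error(readOtuTable(p), "otuA")
  writeLines(c("otu_id\ts1", "otuA\t1.5"), p)
  expect_error(readOtuTable(p), "otuA")
  writeLines(c("wrong\ts1", "otuA\t1"), p)
  expect_error(readOtuTable(p), "otu_id")
})

test_that("empty tables survive the round trip", {
  cdir <- withr::local_tempdir()
  p <- file.path(cdir, "empty.tsv")
  m <- matrix(integer(0), nrow = 0, ncol = 2,
              dimnames = list(NULL, c("s1", "s2")))
  writeOtuTable(m, p)
  back <- readOtuTable(p)
  expect_identical(nrow(back), 0L)
  expect_identical(colnames(back), c("s1", "s2"))
})

test_that("low-richness filtering is a strict, idempotent sample filter", {
  # three samples with richness 19, 20, 21
  m <- matrix(0L, nrow = 25, ncol = 3,
              dimnames = list(sprintf("o%02d", 1:25), c("r19", "r20", "r21")))
  m[1:19, 1] <- 1L
  m[1:20, 2] <- 1L
  m[1:21, 3] <- 1L
  kept <- filterLowRichness(m)
  expect_identical(colnames(kept), c("r20", "r21"))
  expect_identical(filterLowRichness(kept), kept)  # idempotent
  expect_identical(nrow(kept), 25L)                # OTU rows untouched

  z <- cbind(m, allzero = rep(0L, 25))
  expect_false("allzero" %in% colnames(filterLowRichness(z, min_unique = 1)))
})

test_that("relative abundances normalize per sample and are scale-invariant", {
  m <- matrix(c(2L, 3L), 2, 1, dimnames = list(c("a", "b"), "s1"))
  expect_equal(as.numeric(relativeAbundance(m)), c(0.4, 0.6))
  single <- matrix(7L, 1, 1, dimnames = list("a", "s1"))
  expect_equal(as.numeric(relativeAbundance(single)), 1)
  scaled <- m * 13L
  expect_equal(relativeAbundance(m), relativeAbundance(scaled))
  bad <- cbind(m, empty = c(0L, 0L))
  expect_error(relativeAbundance(bad), "empty")
})

test_that("binarization thresholds at one read and is idempotent", {
  m <- matrix(c(0L, 1L, 999L, 0L), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  b <- binarizeCounts(m)
  expect_identical(as.integer(b), c(0L, 1L, 1L, 0L))
  expect_identical(binarizeCounts(b), b)
  e <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("s1", "s2")))
  expect_identical(dim(binarizeCounts(e)), c(0L, 2L))
})

test_that("nmi matches the plug-in oracle and its boundary values", {
  x <- c(0, 0, 1, 1)
  expect_equal(nmi(x, x), 1)
  expect_equal(nmi(x, c(0, 1, 0, 1)), 0)
  # frozen oracle value for the 6-sample overlapping pair
  a <- c(0, 0, 1, 1, 1, 1)
  b <- c(0, 0, 0, 1, 1, 1)
  expect_equal(nmi(a, b), oracle_nmi(a, b), tolerance = 1e-12)
  expect_equal(oracle_nmi(a, b), 0.4791388, tolerance = 1e-6)
  expect_equal(nmi(a, rep(1, 6)), 0)  # constant partner
  expect_error(nmi(a, c(0, 1)), "length")
})

test_that("nmi is symmetric and nmiMatrix agrees with pairwise calls", {
  withr::with_seed(42, {
    for (r in 1:20) {
      x <- rbinom(30, 1, 0.4)
      y <- rbinom(30, 1, 0.6)
      expect_equal(nmi(x, y), nmi(y, x), tolerance = 1e-12)
    }
    bin <- matrix(rbinom(8 * 40, 1, 0.3), nrow = 8,
                  dimnames = list(paste0("o", 1:8), NULL))
    nm <- siteMarkers:::nmiMatrix(bin)
    for (i in 1:8) for (j in 1:8)
      expect_equal(nm[i, j], nmi(bin[i, ], bin[j, ]), tolerance = 1e-10)
  })
})

test_that("redundancy grouping collapses exactly the high-NMI pairs", {
  base <- c(rep(0, 10), rep(1, 10))
  half <- c(rep(0, 5), rep(1, 5), rep(0, 5), rep(1, 5))
  bin <- rbind(A = base, B = base, C = half)
  rg <- redundancyGroups(bin, threshold = 0.9, seed = 1)
  got <- lapply(rg$groups, sort)
  expect_true(any(vapply(got, identical, logical(1), c("A", "B"))))
  expect_true(any(vapply(got, identical, logical(1), "C")))
  expect_identical(length(rg$groups), 2L)
  # representative belongs to its group, reduced rows unchanged from source
  for (g in seq_along(rg$groups))
    expect_true(rg$representative[g] %in% rg$groups[[g]])
  for (id in rg$keep)
    expect_identical(rg$reduced[id, ], bin[id, ])

  # brute-force oracle: pairwise NMI thresholding gives the same partition
  nm <- siteMarkers:::nmiMatrix(bin)
  expect_true(nm["A", "B"] >= 0.9)
  expect_true(nm["A", "C"] < 0.9 && nm["B", "C"] < 0.9)
})

test_that("independent rows stay singletons and high thresholds split everything", {
  withr::with_seed(7, {
    bin <- matrix(rbinom(6 * 200, 1, 0.5), nrow = 6,
                  dimnames = list(paste0("o", 1:6), NULL))
  })
  rg <- redundancyGroups(bin, threshold = 0.9, seed = 2)
  expect_identical(length(rg$groups), 6L)
  nm <- siteMarkers:::nmiMatrix(bin)
  thr <- min(1, max(nm[upper.tri(nm)]) + 1e-6)
  rg2 <- redundancyGroups(bin, threshold = thr, seed = 2)
  expect_identical(length(rg2$groups), 6L)
  expect_error(redundancyGroups(bin, threshold = 0), "threshold")
})
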