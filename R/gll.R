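#' Configuration for local causal biomarker discovery
#'
#' Parameters of the Generalized Local Learning run: the maximum
#' conditioning-set size `max_k`, the `h_ps` cap on the pool of conditioning
#' variables enumerated per candidate, the significance level `alpha`, and
#' the multiple-testing method applied to the univariate screen before any
#' conditioning.
#'
#' @param max_k maximum conditioning-set size (default 3).
#' @param h_ps size of the conditioning pool per candidate (default 5);
#'   subsets are enumerated only from the `h_ps` admitted variables most
#'   strongly associated with the candidate under test (see
#'   `pool_rank = "candidate"`), or with the target when
#'   `pool_rank = "target"`.
#' @param alpha significance level for all independence tests (default 0.05).
#' @param fdr_method adjustment method for the univariate screen, passed to
#'   [stats::p.adjust()] (default Benjamini-Hochberg `"BH"`).
#' @param pool_rank how the `h_ps` pool is ranked: by association with the
#'   candidate being tested (default) or with the target.
#' @return list of class `"GllConfig"`.
#' @export
gllConfig <- function(max_k = 3, h_ps = 5, alpha = 0.05, fdr_method = "BH",
                      pool_rank = c("candidate", "target")) {
  if (max_k < 0) stop("max_k must be >= 0")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (h_ps < 1) stop("h_ps must be >= 1")
  structure(list(max_k = as.integer(max_k), h_ps = as.integer(h_ps),
                 alpha = alpha, fdr_method = fdr_method,
                 pool_rank = match.arg(pool_rank)),
            class = "GllConfig")
}

#' Conditional G-test of independence for discrete vectors
#'
#' Likelihood-ratio (G) test of X independent of Y given a conditioning set
#' Z, with `G = 2 N MI(X; Y | Z)` in natural-log units. The statistic is
#' accumulated over the strata defined by the joint assignment of the
#' conditioning vectors; cells with zero count contribute nothing and empty
#' strata are skipped. Degrees of freedom are
#' `(levels(X)-1) (levels(Y)-1) (number of non-empty strata)` and the p-value
#' comes from the upper chi-square tail; `df = 0` (a constant margin) yields
#' `p = 1`.
#'
#' @param x,y equal-length discrete vectors (typically 0/1).
#' @param conditioning list of equal-length discrete vectors (possibly
#'   empty/NULL) defining the strata.
#' @return list with `G`, `df`, `p`, `n_strata`.
#' @examples
#' gTest(c(0, 0, 1, 1), c(0, 1, 0, 1))$p          # 1 (exact independence)
#' gTest(c(0, 0, 0, 1, 1, 1), c(0, 0, 0, 1, 1, 1))$G  # 12 log(2)
#' @export
gTest <- function(x, y, conditioning = NULL) {
  if (length(x) != length(y)) stop("gTest: length mismatch")
  if (!is.null(conditioning) && length(conditioning)) {
    lens <- vapply(conditioning, length, integer(1))
    if (any(lens != length(x))) stop("gTest: conditioning length mismatch")
    strata <- do.call(paste, c(conditioning, sep = "\r"))
  } else {
    strata <- NULL
  }
  lx <- length(unique(x))
  ly <- length(unique(y))
  G <- 0
  n_strata <- 0L
  if (is.null(strata)) {
    groups <- list(seq_along(x))
  } else {
    groups <- split(seq_along(x), strata)
  }
  for (idx in groups) {
    ns <- length(idx)
    if (ns == 0) next
    n_strata <- n_strata + 1L
    tab <- table(x[idx], y[idx])
    if (nrow(tab) < 2 || ncol(tab) < 2) next  # constant margin: G_s = 0
    e <- outer(rowSums(tab), colSums(tab)) / ns
    ok <- tab > 0
    G <- G + 2 * sum(tab[ok] * log(tab[ok] / e[ok]))
  }
  df <- (lx - 1L) * (ly - 1L) * n_strata
  # roundoff guard: an exactly independent table accumulates G at machine
  # epsilon; genuine nonzero statistics from discrete tables are orders of
  # magnitude larger, and the chi-square tail is sqrt-sensitive at 0
  G <- max(0, G)
  if (G < 1e-8) G <- 0
  p <- if (df == 0) 1 else pchisq(G, df, lower.tail = FALSE)
  list(G = G, df = as.integer(df), p = p, n_strata = n_strata)
}

#' Univariate screen of OTUs against a site indicator
#'
#' Runs an unconditional G-test of each OTU row against the binary target,
#' adjusts p-values across all OTUs (Benjamini-Hochberg by default), and
#' flags candidates with adjusted p at or below `alpha`. Candidates are
#' ordered by decreasing G statistic, ties broken by OTU id ascending; this
#' ordering is the admission priority of [hitonPC()].
#'
#' @param bin 0/1 matrix, OTUs in rows.
#' @param target binary (0/1) site-indicator vector over samples.
#' @param config a [gllConfig()].
#' @return data.frame with columns `otu_id`, `G`, `df`, `p`, `p_adj`,
#'   `candidate`, ordered by the admission priority.
#' @export
univariateScreen <- function(bin, target, config = gllConfig()) {
  bin <- as.matrix(bin)
  if (length(unique(target)) < 2)
    stop("univariateScreen: target indicator is constant")
  res <- lapply(seq_len(nrow(bin)), function(i) gTest(bin[i, ], target))
  out <- data.frame(otu_id = rownames(bin),
                    G = vapply(res, `[[`, numeric(1), "G"),
                    df = vapply(res, `[[`, integer(1), "df"),
                    p = vapply(res, `[[`, numeric(1), "p"),
                    stringsAsFactors = FALSE)
  out$p_adj <- p.adjust(out$p, method = config$fdr_method)
  out$candidate <- out$p_adj <= config$alpha
  out[order(-out$G, out$otu_id), , drop = FALSE]
}

# Enumerate subsets of `pool` of size 1..max_k in increasing size,
# lexicographic within size; deterministic.
enumerate_subsets <- function(pool, max_k) {
  out <- list()
  for (k in seq_len(min(max_k, length(pool)))) {
    cmb <- combn(pool, k, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

#' Semi-interleaved HITON-PC over an abstract independence test
#'
#' The engine behind [hitonPC()], usable with any conditional-independence
#' oracle. Candidates are admitted in priority order into a tentative
#' parents-and-children set (TPC); a candidate is discarded permanently as
#' soon as some conditioning subset (size at most `max_k`, drawn from the
#' `h_ps`-capped pool of current TPC members) renders it independent of the
#' target at level `alpha`. After all candidates are processed, backward
#' passes re-test each TPC member against subsets of the remaining TPC until
#' stable.
#'
#' @param candidates character vector of candidate ids in admission priority
#'   order (strongest first).
#' @param indep_test function `(id, cond_ids) -> p-value` testing the
#'   candidate against the target given the conditioning ids.
#' @param assoc function `(id_a, id_b) -> numeric` association strength used
#'   to rank the conditioning pool when `pool_rank = "candidate"`; ignored
#'   otherwise. May be `NULL` when the pool is never capped.
#' @param config a [gllConfig()].
#' @param target_strength named numeric vector of association strengths with
#'   the target (used for `pool_rank = "target"`).
#' @return list with `pc` (retained ids, admission order) and `tests`
#'   (data.frame audit of every conditional test performed).
#' @export
hitonPCEngine <- function(candidates, indep_test, assoc = NULL,
                          config = gllConfig(), target_strength = NULL) {
  tpc <- character(0)
  audit <- list()
  record <- function(id, z, p) {
    audit[[length(audit) + 1]] <<- data.frame(
      otu_id = id, conditioning = paste(z, collapse = ","), p = p,
      stringsAsFactors = FALSE)
  }
  pool_for <- function(id, members) {
    if (length(members) <= config$h_ps) return(members)
    if (config$pool_rank == "candidate" && !is.null(assoc)) {
      s <- vapply(members, function(m) assoc(m, id), numeric(1))
    } else if (!is.null(target_strength)) {
      s <- target_strength[members]
    } else {
      return(members[seq_len(config$h_ps)])
    }
    members[order(-s, members)][seq_len(config$h_ps)]
  }
  separated <- function(id, members) {
    pool <- pool_for(id, members)
    for (z in enumerate_subsets(pool, config$max_k)) {
      p <- indep_test(id, z)
      record(id, z, p)
      if (p > config$alpha) return(TRUE)
    }
    FALSE
  }
  # forward (semi-interleaved): eliminate against current TPC at admission
  for (id in candidates) {
    if (!length(tpc) || !separated(id, tpc)) tpc <- c(tpc, id)
  }
  # backward passes until stable
  repeat {
    removed <- FALSE
    for (id in tpc) {
      others <- setdiff(tpc, id)
      if (length(others) && separated(id, others)) {
        tpc <- others
        removed <- TRUE
      }
    }
    if (!removed) break
  }
  tests <- if (length(audit)) do.call(rbind, audit) else
    data.frame(otu_id = character(0), conditioning = character(0),
               p = numeric(0))
  list(pc = tpc, tests = tests)
}

#' Symmetry-corrected HITON-PC over an abstract independence test
#'
#' Runs [hitonPCEngine()] for the target and then applies the symmetry
#' correction of the Generalized Local Learning family: a variable X is kept
#' in the parents-and-children set of T only if T is in turn recovered in
#' the parents-and-children set of X. The plain semi-interleaved algorithm
#' can retain false members whose separating set lies outside the target's
#' neighbourhood (e.g. a spouse's child); under a faithful exact
#' independence oracle the corrected output equals the true
#' parents-and-children set, provided `max_k` is at least the maximum
#' in-degree and the conditioning pool is not capped below the
#' neighbourhood size.
#'
#' @param target id of the target variable.
#' @param vars character vector of all variable ids (including the target).
#' @param indep_test function `(x, y, cond_ids) -> p-value`.
#' @param assoc optional pairwise association function for pool ranking and
#'   admission priority; when `NULL`, candidates are admitted in
#'   lexicographic order.
#' @param config a [gllConfig()].
#' @return character vector: the corrected parents-and-children set.
#' @export
hitonPCSymmetric <- function(target, vars, indep_test, assoc = NULL,
                             config = gllConfig()) {
  run <- function(tgt) {
    others <- setdiff(vars, tgt)
    dep <- vapply(others, function(v)
      indep_test(v, tgt, character(0)) <= config$alpha, logical(1))
    cand <- others[dep]
    if (!is.null(assoc)) {
      s <- vapply(cand, function(v) assoc(v, tgt), numeric(1))
      cand <- cand[order(-s, cand)]
    } else {
      cand <- sort(cand)
    }
    hitonPCEngine(cand, function(id, z) indep_test(id, tgt, z),
                  assoc = assoc, config = config)$pc
  }
  pc <- run(target)
  pc[vapply(pc, function(v) target %in% run(v), logical(1))]
}

#' Semi-interleaved HITON-PC on a binarized OTU table
#'
#' Identifies the OTUs whose association with a binary site indicator cannot
#' be explained away by conditioning on other admitted OTUs: the univariate
#' screen (FDR-adjusted) supplies the prioritized candidate list, and the
#' engine eliminates every candidate that some conditioning subset of
#' already-admitted OTUs (at most `max_k` of them, drawn from the
#' `h_ps`-capped pool) renders independent of the target by conditional
#' G-test.
#'
#' @param bin 0/1 matrix, OTUs in rows; ideally redundancy-reduced (see
#'   [redundancyGroups()]) since near-duplicate OTUs can explain each other
#'   away.
#' @param target binary site-indicator vector.
#' @param config a [gllConfig()].
#' @param screen optional precomputed result of [univariateScreen()].
#' @return list with `pc` (retained OTU ids), `screen` (the univariate screen
#'   table) and `tests` (audit of conditional tests).
#' @export
hitonPC <- function(bin, target, config = gllConfig(), screen = NULL) {
  bin <- as.matrix(bin)
  if (is.null(screen)) screen <- univariateScreen(bin, target, config)
  cand <- screen$otu_id[screen$candidate]
  strengths <- structure(screen$G, names = screen$otu_id)
  indep_test <- function(id, z)
    gTest(bin[id, ], target,
          conditioning = lapply(z, function(zz) bin[zz, ]))$p
  assoc <- function(a, b) nmi(bin[a, ], bin[b, ])
  eng <- hitonPCEngine(cand, indep_test, assoc = assoc, config = config,
                       target_strength = strengths)
  list(pc = eng$pc, screen = screen, tests = eng$tests)
}

#' Association sign of a binary OTU with a binary site indicator
#'
#' The sign of the Spearman rank correlation between two binary vectors,
#' which reduces to the sign of `ad - bc` in their 2x2 contingency table
#' (equivalently, whether the odds ratio exceeds 1). `+1` marks a positively
#' associated (PA) OTU, `-1` a negatively associated (NA) OTU; an exactly
#' zero determinant or a constant input is indeterminate (`NA`).
#'
#' @param x binary OTU presence vector.
#' @param y binary site indicator.
#' @return `+1`, `-1`, or `NA` (indeterminate).
#' @export
associationSign <- function(x, y) {
  if (length(x) != length(y)) stop("associationSign: length mismatch")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) return(NA_integer_)
  a <- sum(x == 1 & y == 1)
  b <- sum(x == 1 & y == 0)
  c_ <- sum(x == 0 & y == 1)
  d <- sum(x == 0 & y == 0)
  det <- as.numeric(a) * d - as.numeric(b) * c_
  if (det > 0) 1L else if (det < 0) -1L else NA_integer_
}

#' Discover biomarkers for every body site
#'
#' Runs the full per-site pipeline on a (redundancy-reduced) binarized OTU
#' table: one-vs-rest site indicator, FDR-screened univariate candidates,
#' semi-interleaved HITON-PC elimination, association-sign assignment, NMI
#' marker strength, prevalence, and (when a [TrainedModel] is supplied) the
#' percentile of Random-Forest feature importance among the site's markers.
#'
#' @param bin 0/1 matrix, OTUs in rows (see [binarizeCounts()]).
#' @param body_site character vector of per-sample site labels.
#' @param config a [gllConfig()].
#' @param model optional [TrainedModel] providing feature importances.
#' @return A [BiomarkerSet].
#' @export
discoverMarkers <- function(bin, body_site, config = gllConfig(),
                            model = NULL) {
  bin <- as.matrix(bin)
  body_site <- as.character(body_site)
  if (ncol(bin) != length(body_site))
    stop("discoverMarkers: one body-site label per sample required")
  sites <- sort(unique(body_site))
  rows <- list()
  tests <- list()
  for (s in sites) {
    if (sum(body_site == s) < 2) {
      warning("site skipped (fewer than 2 samples): ", s)
      next
    }
    target <- as.integer(body_site == s)
    hp <- hitonPC(bin, target, config)
    tests[[s]] <- hp$tests
    if (!length(hp$pc)) next
    sign <- vapply(hp$pc, function(o) associationSign(bin[o, ], target),
                   integer(1))
    strength <- vapply(hp$pc, function(o) nmi(bin[o, ], target), numeric(1))
    prevalence <- rowSums(bin[hp$pc, , drop = FALSE])
    imp_pct <- rep(NA_real_, length(hp$pc))
    if (!is.null(model)) {
      imp <- featureImportance(model)[hp$pc]
      imp[is.na(imp)] <- 0
      imp_pct <- 100 * (rank(imp, ties.method = "average") - 1) /
        max(1, length(imp) - 1)
    }
    rows[[s]] <- data.frame(otu_id = hp$pc, site = s, sign = sign,
                            strength_nmi = strength, prevalence = prevalence,
                            importance_percentile = imp_pct,
                            stringsAsFactors = FALSE, row.names = NULL)
  }
  m <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE)) else
    data.frame(otu_id = character(0), site = character(0), sign = integer(0),
               strength_nmi = numeric(0), prevalence = numeric(0),
               importance_percentile = numeric(0))
  new("BiomarkerSet", markers = m, tests = tests, config = unclass(config))
}

#' Summaries of a biomarker set
#'
#' Pairwise Jaccard similarity of marker OTU sets between sites, PA/NA counts
#' per site, and the per-marker prevalence table.
#'
#' @param bset a [BiomarkerSet].
#' @return list with `jaccard` (site x site matrix), `counts` (data.frame of
#'   PA / NA / indeterminate counts per site) and `prevalence` (data.frame of
#'   per-marker prevalences).
#' @export
markerSummaries <- function(bset) {
  m <- markers(bset)
  sites <- sort(unique(m$site))
  sets <- lapply(sites, function(s) unique(m$otu_id[m$site == s]))
  names(sets) <- sites
  jac <- matrix(1, length(sites), length(sites),
                dimnames = list(sites, sites))
  for (i in seq_along(sites)) for (j in seq_along(sites)) {
    u <- union(sets[[i]], sets[[j]])
    jac[i, j] <- if (length(u)) length(intersect(sets[[i]], sets[[j]])) /
      length(u) else 1
  }
  counts <- data.frame(
    site = sites,
    pa = vapply(sites, function(s) sum(m$site == s & !is.na(m$sign) &
                                         m$sign > 0), integer(1)),
    na = vapply(sites, function(s) sum(m$site == s & !is.na(m$sign) &
                                         m$sign < 0), integer(1)),
    indeterminate = vapply(sites, function(s) sum(m$site == s &
                                                    is.na(m$sign)),
                           integer(1)),
    row.names = NULL)
  list(jaccard = jac, counts = counts,
       prevalence = m[, c("otu_id", "site", "prevalence")])
}

#' Parameter-recovery metrics against planted ground truth
#'
#' Compares a discovered [BiomarkerSet] with the [GroundTruth] of a synthetic
#' dataset. Direct-marker precision and recall are computed on the pooled
#' (OTU-level) discovered set versus the planted direct markers. For each
#' indirect child the relevant site is its parent's site (the site it is
#' indirectly associated with): `indirect_excluded` is the fraction of
#' children absent from that site's marker list, and
#' `indirect_screen_flagged` the fraction the univariate screen alone flags
#' for that site.
#'
#' @param bset a [BiomarkerSet] from [discoverMarkers()].
#' @param gt the [GroundTruth].
#' @param screens optional named list (site -> screen data.frame) to compute
#'   the univariate flag rate; see [univariateScreen()].
#' @return list of numeric metrics.
#' @export
recoveryMetrics <- function(bset, gt, screens = NULL) {
  m <- markers(bset)
  discovered <- unique(m$otu_id)
  direct <- directMarkers(gt)
  prec <- if (length(discovered))
    length(intersect(discovered, direct)) / length(discovered) else NA_real_
  rec <- if (length(direct))
    length(intersect(discovered, direct)) / length(direct) else NA_real_
  out <- list(direct_precision = prec, direct_recall = rec)
  edges <- gt@indirect_edges
  if (nrow(edges)) {
    parent_site <- vapply(edges$parent, function(p) {
      hits <- names(gt@direct_pa)[vapply(gt@direct_pa, function(v)
        p %in% v, logical(1))]
      if (!length(hits))
        hits <- names(gt@direct_na)[vapply(gt@direct_na, function(v)
          p %in% v, logical(1))]
      hits[1]
    }, character(1))
    excl <- mapply(function(child, s)
      !any(m$otu_id == child & m$site == s), edges$child, parent_site)
    out$indirect_excluded <- mean(excl)
    if (!is.null(screens)) {
      flagged <- mapply(function(child, s) {
        sc <- screens[[s]]
        any(sc$otu_id == child & sc$candidate)
      }, edges$child, parent_site)
      out$indirect_screen_flagged <- mean(flagged)
    }
  }
  out
}
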