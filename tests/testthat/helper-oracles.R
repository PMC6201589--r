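# Independent oracles used to freeze expected values. These deliberately
# avoid the package's own code paths.

# Plug-in conditional mutual information MI(X;Y|Z), natural logs, computed
# stratum by stratum from raw probabilities.
oracle_cmi <- function(x, y, strata = NULL) {
  if (is.null(strata)) strata <- rep(1L, length(x))
  n <- length(x)
  out <- 0
  for (s in unique(strata)) {
    idx <- strata == s
    ns <- sum(idx)
    for (xv in unique(x[idx])) for (yv in unique(y[idx])) {
      pxy <- sum(x[idx] == xv & y[idx] == yv) / ns
      if (pxy == 0) next
      px <- sum(x[idx] == xv) / ns
      py <- sum(y[idx] == yv) / ns
      out <- out + (ns / n) * pxy * log(pxy / (px * py))
    }
  }
  out
}

# Plug-in NMI oracle over the 2x2 table (geometric-mean normalization).
oracle_nmi <- function(x, y) {
  ent <- function(v) {
    p <- as.numeric(table(v)) / length(v)
    -sum(p * log(p))
  }
  hx <- ent(x); hy <- ent(y)
  if (hx == 0 || hy == 0) return(0)
  oracle_cmi(x, y) / sqrt(hx * hy)
}

# Exact d-separation by moralized ancestral graph (requires igraph).
oracle_dsep <- function(adj, x, y, z) {
  nodes <- rownames(adj)
  anc <- unique(c(x, y, z))
  repeat {
    pa <- nodes[rowSums(adj[, anc, drop = FALSE]) > 0]
    new <- union(anc, pa)
    if (length(new) == length(anc)) break
    anc <- new
  }
  sub <- adj[anc, anc, drop = FALSE]
  und <- (sub | t(sub))
  for (ch in anc) {
    ps <- anc[sub[, ch] > 0]
    if (length(ps) > 1) und[ps, ps] <- TRUE
  }
  diag(und) <- FALSE
  keep <- setdiff(anc, z)
  if (!(x %in% keep) || !(y %in% keep)) return(TRUE)
  g <- igraph::graph_from_adjacency_matrix(und[keep, keep, drop = FALSE],
                                           mode = "undirected")
  !is.finite(igraph::distances(g, v = x, to = y)[1, 1])
}

# Random DAG over n nodes with max in/out-degree bounded.
random_dag <- function(n, maxdeg = 3, p_edge = 0.35) {
  adj <- matrix(0, n, n, dimnames = list(paste0("v", seq_len(n)),
                                         paste0("v", seq_len(n))))
  ord <- sample(n)
  for (i in 2:n) for (j in seq_len(i - 1)) {
    a <- ord[j]; b <- ord[i]
    if (runif(1) < p_edge && sum(adj[a, ]) < maxdeg && sum(adj[, b]) < maxdeg)
      adj[a, b] <- 1
  }
  adj
}

dag_pc_truth <- function(adj, target) {
  sort(unique(c(rownames(adj)[adj[, target] > 0],
                rownames(adj)[adj[target, ] > 0])))
}

# Run the package's symmetry-corrected HITON-PC with the exact d-separation
# oracle as independence test.
hiton_on_dag <- function(adj, target, max_k = 3) {
  cfg <- gllConfig(max_k = max_k, h_ps = nrow(adj))
  it <- function(x, y, z) if (oracle_dsep(adj, x, y, z)) 1 else 0
  sort(hitonPCSymmetric(target, rownames(adj), it, config = cfg))
}

# One-tailed (greater) Fisher p-value by exhaustive hypergeometric
# enumeration over all tables at least as extreme in the a-cell.
oracle_fisher_greater <- function(a, b, c, d) {
  m <- a + b; n_ <- c + d; k <- a + c
  amax <- min(m, k)
  sum(vapply(a:amax, function(x)
    choose(m, x) * choose(n_, k - x) / choose(m + n_, k), numeric(1)))
}

# Small deterministic OtuSet fixture.
tiny_otuset <- function() {
  cts <- matrix(c(5L, 0L, 2L,
                  0L, 3L, 1L,
                  4L, 4L, 0L), nrow = 3, byrow = TRUE,
                dimnames = list(c("otuA", "otuB", "otuC"),
                                c("s1", "s2", "s3")))
  OtuSet(cts, body_site = c("skin", "feces", "skin"),
         study_id = c("st1", "st1", "st2"))
}
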