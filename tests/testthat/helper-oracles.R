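# Independent oracles used to cross-check the implementation. Each one
# deliberately takes a different route than the code under test.

# site-by-site loop, no vectorization shared with p_distance()
naive_p_distance <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  ncomp <- 0L
  ndiff <- 0L
  for (i in seq_along(ca)) {
    x <- ca[i]; y <- cb[i]
    if (x %in% c("A", "C", "G", "T") && y %in% c("A", "C", "G", "T")) {
      ncomp <- ncomp + 1L
      if (x != y) ndiff <- ndiff + 1L
    }
  }
  if (ncomp == 0L) stop("no comparable sites")
  ndiff / ncomp
}

# closed-form two-sequence JC log-likelihood (single rate)
jc_pair_loglik <- function(n_same, n_diff, t) {
  p_same <- 0.25 + 0.75 * exp(-4 * t / 3)   # P(x -> x)
  p_diff <- 0.25 - 0.25 * exp(-4 * t / 3)   # P(x -> one specific y != x)
  n_same * log(0.25 * p_same) + n_diff * log(0.25 * p_diff)
}

jc_closed_form_t <- function(p) -0.75 * log(1 - 4 * p / 3)

# monophyly via ape's bipartition machinery (independent C code path)
oracle_monophyletic <- function(phy, tips) {
  idx <- sort(match(tips, phy$tip.label))
  ntip <- length(phy$tip.label)
  if (length(idx) <= 1L || length(idx) == ntip) return(TRUE)
  comp <- sort(setdiff(seq_len(ntip), idx))
  parts <- ape::prop.part(phy)
  for (s in parts) {
    s <- sort(s)
    if (identical(s, idx) || identical(s, comp)) return(TRUE)
  }
  FALSE
}

# threshold-graph connected components via igraph
oracle_threshold_components <- function(mat, threshold) {
  n <- nrow(mat)
  adj <- (mat <= threshold)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  ids <- rownames(mat)
  vapply(seq_len(n), function(i) min(ids[comp == comp[i]]), character(1))
}

# gamma category means by numerical quadrature
quadrature_gamma_rates <- function(alpha, C) {
  cuts <- qgamma(seq(0, 1, length.out = C + 1), shape = alpha, rate = alpha)
  vapply(seq_len(C), function(k) {
    C * integrate(function(x) x * dgamma(x, shape = alpha, rate = alpha),
                  cuts[k], cuts[k + 1], rel.tol = 1e-12)$value
  }, numeric(1))
}

# random valid GTR model
random_gtr <- function(gamma_shape = NULL) {
  ex <- stats::setNames(runif(6, 0.3, 4), c("AC", "AG", "AT", "CG", "CT", "GT"))
  f <- runif(4, 0.5, 2)
  f <- f / sum(f)
  substitution_model("GTR", exchangeabilities = ex,
                     base_frequencies = stats::setNames(f, c("A", "C", "G", "T")),
                     gamma_shape = gamma_shape)
}

random_symmetric_pmat <- function(n, max_d = 0.05) {
  ids <- sprintf("s%02d", seq_len(n))
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  v <- runif(n * (n - 1) / 2, 0, max_d)
  m[upper.tri(m)] <- v
  m <- m + t(m)
  attr(m, "method") <- "p"
  m
}
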