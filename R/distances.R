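# Pairwise genetic distances on a partitioned alignment: uncorrected
# p-distances and maximum-likelihood distances under fixed GTR-family
# models, one shared branch length per pair across partitions.

#' Uncorrected p-distance between two aligned rows
#'
#' Proportion of differing sites among comparable positions. Under pairwise
#' deletion a site is comparable when both rows carry an unambiguous base
#' (A/C/G/T); gaps and IUPAC ambiguity codes are excluded. (For a single
#' pair, complete-set deletion coincides with pairwise deletion; the
#' distinction matters at the matrix level, see [p_distance_matrix()].)
#'
#' @param a,b Aligned sequences of equal length.
#' @param deletion `"pairwise"` (default) or `"complete-set"`.
#' @return The distance, with attributes `n_compared` and `n_differences`.
#'   Zero comparable sites is an error, not a zero distance.
#' @examples
#' p_distance("ACGT", "ACGA")  # 0.25
#' @export
p_distance <- function(a, b, deletion = c("pairwise", "complete-set")) {
  deletion <- match.arg(deletion)
  ca <- seq_chars(toupper(a)); cb <- seq_chars(toupper(b))
  if (length(ca) != length(cb)) stop("sequences must have equal length")
  ok <- is_acgt(ca) & is_acgt(cb)
  n <- sum(ok)
  if (n == 0L) stop("no comparable sites between the two sequences")
  diff <- sum(ca[ok] != cb[ok])
  structure(diff / n, n_compared = n, n_differences = diff)
}

# 4x4 site-pattern count table over comparable sites of one column range.
pair_site_counts <- function(ca, cb, start, end) {
  i <- seq.int(start, end)
  x <- ca[i]; y <- cb[i]
  ok <- is_acgt(x) & is_acgt(y)
  table(factor(x[ok], DNA_BASES), factor(y[ok], DNA_BASES))
}

mixture_matrix <- function(eig, rates, t) {
  M <- matrix(0, 4L, 4L)
  for (r in rates) M <- M + transition_probability(eig, t * r)
  M / length(rates)
}

#' Partitioned two-sequence log-likelihood
#'
#' `l(t) = sum_partitions sum_xy n_xy log sum_c (1/C) pi_x P_xy(t r_c)`,
#' with one shared branch length `t` across partitions, each partition
#' using its own model's rate matrix and gamma categories.
#'
#' @param counts A 4x4 site-pattern count matrix, or a list of them (one
#'   per partition).
#' @param t Branch length (>= 0).
#' @param models A [substitution_model()] or list matching `counts`.
#' @return The log-likelihood (scalar).
#' @export
pair_loglik <- function(counts, t, models) {
  if (is.matrix(counts) || is.table(counts)) counts <- list(counts)
  if (inherits(models, "substitution_model")) models <- list(models)
  if (length(counts) != length(models))
    stop("counts and models must have the same length")
  if (sum(vapply(counts, sum, numeric(1L))) == 0)
    stop("all-zero site-pattern counts")
  assert_scalar_number(t, "t", lower = 0)
  ll <- 0
  for (i in seq_along(counts)) {
    n <- unclass(counts[[i]])
    if (sum(n) == 0) next
    m <- models[[i]]
    eig <- if (inherits(m, "substitution_model")) model_eigen(m) else m$eig
    rates <- if (inherits(m, "substitution_model")) model_rates(m) else m$rates
    pi <- if (inherits(m, "substitution_model")) m$base_frequencies else m$pi
    J <- pi * mixture_matrix(eig, rates, t)   # joint prob, rows scaled by pi
    J[J < 1e-300] <- 1e-300
    ll <- ll + sum(n * log(J))
  }
  ll
}

# Precompute per-partition likelihood ingredients for repeated t evaluation.
model_cache <- function(models) {
  lapply(models, function(m) {
    stopifnot(inherits(m, "substitution_model"))
    list(eig = model_eigen(m), rates = model_rates(m),
         pi = m$base_frequencies)
  })
}

ml_from_counts <- function(counts, cache, lower = 1e-6, upper = 10,
                           tol = 1e-8) {
  nonempty <- vapply(counts, sum, numeric(1L)) > 0
  if (!any(nonempty)) stop("no comparable sites in any partition")
  counts <- counts[nonempty]
  cache <- cache[nonempty]
  negll <- function(t) {
    ll <- 0
    for (i in seq_along(counts)) {
      J <- cache[[i]]$pi * mixture_matrix(cache[[i]]$eig, cache[[i]]$rates, t)
      J[J < 1e-300] <- 1e-300
      ll <- ll + sum(unclass(counts[[i]]) * log(J))
    }
    -ll
  }
  opt <- stats::optimize(negll, interval = c(lower, upper), tol = tol)
  t_hat <- opt$minimum
  # snap to the bounds when the optimum sits against them
  if (t_hat - lower < 10 * tol && negll(lower) <= opt$objective) t_hat <- lower
  saturated <- upper - t_hat < 1e-3
  if (saturated) t_hat <- upper
  structure(t_hat, loglik = -negll(t_hat), saturated = saturated,
            n_compared = vapply(counts, sum, numeric(1L)))
}

#' Maximum-likelihood distance between two aligned rows
#'
#' Maximizes the partitioned two-sequence log-likelihood over a single
#' shared branch length by bounded scalar optimization on
#' `[1e-6, 10]` (tolerance 1e-8). Sites with a gap or ambiguity in either
#' row are excluded per partition. Saturated pairs return the upper bound
#' with attribute `saturated = TRUE`.
#'
#' @param a,b Aligned sequences of equal length.
#' @param models A [substitution_model()] (single partition) or named list,
#'   one per partition.
#' @param partitions Optional data frame (`name`, `start`, `end`); default
#'   one partition spanning the whole alignment.
#' @return Estimated distance in substitutions/site with attributes
#'   `loglik`, `saturated`, `n_compared`.
#' @examples
#' jc <- substitution_model("JC", n_categories = 1)
#' ml_distance("ACGTACGT", "ACGTACGA", jc)
#' @export
ml_distance <- function(a, b, models, partitions = NULL) {
  ca <- seq_chars(toupper(a)); cb <- seq_chars(toupper(b))
  if (length(ca) != length(cb)) stop("sequences must have equal length")
  if (inherits(models, "substitution_model")) models <- list(models)
  if (is.null(partitions))
    partitions <- data.frame(name = names(models) %||% "all",
                             start = 1L, end = length(ca))
  stopifnot(nrow(partitions) == length(models))
  counts <- lapply(seq_len(nrow(partitions)), function(i)
    pair_site_counts(ca, cb, partitions$start[i], partitions$end[i]))
  ml_from_counts(counts, model_cache(models))
}

new_dist_matrix <- function(ids, method, deletion = NULL) {
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  attr(m, "method") <- method
  if (!is.null(deletion)) attr(m, "deletion") <- deletion
  m
}

#' Pairwise p-distance matrix
#'
#' @param aln A [partitioned_alignment()] or named character vector of
#'   aligned sequences.
#' @param deletion `"pairwise"` excludes gap/ambiguous sites per pair;
#'   `"complete-set"` first drops every column with any gap/ambiguity in
#'   any row.
#' @return Symmetric matrix with zero diagonal and attribute
#'   `method = "p"`.
#' @export
p_distance_matrix <- function(aln, deletion = c("pairwise", "complete-set")) {
  deletion <- match.arg(deletion)
  seqs <- if (inherits(aln, "partitioned_alignment")) aln$seqs else toupper(aln)
  ids <- names(seqs)
  rows <- lapply(seqs, seq_chars)
  if (deletion == "complete-set") {
    keep <- Reduce(`&`, lapply(rows, is_acgt))
    if (!any(keep)) stop("no columns survive complete-set deletion")
    rows <- lapply(rows, `[`, keep)
  }
  m <- new_dist_matrix(ids, "p", deletion)
  n <- length(rows)
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    ok <- is_acgt(rows[[i]]) & is_acgt(rows[[j]])
    nc <- sum(ok)
    if (nc == 0L)
      stop(sprintf("no comparable sites between '%s' and '%s'", ids[i], ids[j]))
    m[i, j] <- m[j, i] <- sum(rows[[i]][ok] != rows[[j]][ok]) / nc
  }
  m
}

#' Pairwise maximum-likelihood distance matrix
#'
#' Computes [ml_distance()] for every pair under the alignment's attached
#' per-partition models (attach them via [partitioned_alignment()] or
#' [fit_partition_models()]).
#'
#' @param aln A [partitioned_alignment()] with models attached.
#' @return Symmetric matrix with attribute `method = "ml"`; saturated
#'   pairs are listed in attribute `saturated_pairs`.
#' @export
ml_distance_matrix <- function(aln) {
  stopifnot(inherits(aln, "partitioned_alignment"))
  if (is.null(aln$models))
    stop("alignment has no models attached; see fit_partition_models()")
  ids <- names(aln$seqs)
  rows <- lapply(aln$seqs, seq_chars)
  parts <- aln$partitions
  cache <- model_cache(aln$models[parts$name])
  m <- new_dist_matrix(ids, "ml", "pairwise")
  sat <- character(0L)
  n <- length(rows)
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    counts <- lapply(seq_len(nrow(parts)), function(k)
      pair_site_counts(rows[[i]], rows[[j]], parts$start[k], parts$end[k]))
    d <- ml_from_counts(counts, cache)
    if (isTRUE(attr(d, "saturated")))
      sat <- c(sat, paste(ids[i], ids[j], sep = "|"))
    m[i, j] <- m[j, i] <- as.numeric(d)
  }
  attr(m, "saturated_pairs") <- sat
  m
}
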