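# Per-partition model parameter estimation by composite (pairwise)
# likelihood: exchangeabilities and the gamma shape maximize the sum of
# all two-sequence log-likelihoods, alternating with per-pair branch
# length updates. Base frequencies are observed column frequencies (+F
# models) or fixed uniform (SYM/JC).

free_param_template <- function(kind, with_alpha) {
  ex_names <- switch(kind,
                     GTR = c("AC", "AG", "AT", "CG", "CT"),
                     SYM = c("AC", "AG", "AT", "CG", "CT"),
                     TVM = c("AC", "AG", "AT", "CG"),   # AG == CT, GT = 1
                     JC = character(0L))
  c(ex_names, if (with_alpha) "alpha")
}

theta_to_model <- function(theta, kind, freqs, n_categories, with_alpha) {
  ex <- stats::setNames(rep(1, 6L), EXCH_NAMES)
  nm <- setdiff(names(theta), "alpha")
  ex[nm] <- exp(theta[nm])
  if (kind == "TVM") ex["CT"] <- ex["AG"]
  alpha <- if (with_alpha) exp(theta[["alpha"]]) else NULL
  substitution_model(kind, exchangeabilities = ex,
                     base_frequencies = if (kind %in% c("SYM", "JC")) NULL else freqs,
                     gamma_shape = alpha, n_categories = n_categories)
}

observed_base_frequencies <- function(rows) {
  pooled <- unlist(rows, use.names = FALSE)
  pooled <- pooled[is_acgt(pooled)]
  tab <- table(factor(pooled, DNA_BASES))
  f <- as.numeric(tab) / sum(tab)
  names(f) <- DNA_BASES
  if (any(f == 0)) {             # guard degenerate compositions
    f <- (as.numeric(tab) + 0.5) / (sum(tab) + 2)
    names(f) <- DNA_BASES
  }
  f / sum(f)
}

jc_initial_t <- function(p) {
  p <- min(p, 0.70)
  t0 <- -0.75 * log(1 - 4 * p / 3)
  min(max(t0, 1e-4), 5)
}

#' Estimate substitution-model parameters for one partition
#'
#' Maximizes the sum of all pairwise two-sequence log-likelihoods over the
#' model's free exchangeabilities and gamma shape, alternating
#' (coordinate-wise) with per-pair branch-length updates until parameter
#' changes fall below `tol`. Initialization is deterministic (all
#' exchangeabilities 1, alpha = 1, branch lengths from the JC formula), so
#' the result does not depend on input order. `+F` base frequencies are
#' the observed frequencies of the partition.
#'
#' @param aln A [partitioned_alignment()] or named character vector of
#'   aligned sequences (>= 3 rows).
#' @param partition Partition name (or index) when `aln` is partitioned;
#'   ignored otherwise.
#' @param kind Model family; defaults to the partition's attached model
#'   kind, else `"GTR"`.
#' @param n_categories Discrete-gamma categories (1 disables the gamma
#'   component).
#' @param tol Convergence tolerance on the free parameters (default 1e-6).
#' @param max_outer Maximum alternation rounds.
#' @return A fitted [substitution_model()]. Degenerate partitions (fewer
#'   than two distinct rows) return JC defaults with a warning.
#' @export
estimate_model_params <- function(aln, partition = NULL, kind = NULL,
                                  n_categories = 4L, tol = 1e-6,
                                  max_outer = 8L) {
  if (inherits(aln, "partitioned_alignment")) {
    parts <- aln$partitions
    i <- if (is.null(partition)) 1L
    else if (is.character(partition)) match(partition, parts$name)
    else as.integer(partition)
    if (is.na(i) || i < 1L || i > nrow(parts)) stop("unknown partition")
    if (is.null(kind) && !is.null(aln$models))
      kind <- aln$models[[parts$name[i]]]$kind
    seqs <- substr(aln$seqs, parts$start[i], parts$end[i])
  } else {
    seqs <- toupper(aln)
  }
  kind <- kind %||% "GTR"
  kind <- match.arg(kind, c("GTR", "TVM", "SYM", "JC"))
  if (length(seqs) < 3L) stop("partition must have >= 3 sequences")
  rows <- lapply(seqs, seq_chars)

  if (length(unique(seqs)) <= 1L) {
    warning("degenerate partition (a single distinct row); returning JC defaults")
    return(substitution_model("JC", n_categories = n_categories))
  }

  freqs <- if (kind %in% c("TVM", "GTR")) observed_base_frequencies(rows)
  else stats::setNames(rep(0.25, 4L), DNA_BASES)

  n <- length(rows)
  pairs <- utils::combn(n, 2L)
  counts <- lapply(seq_len(ncol(pairs)), function(k)
    pair_site_counts(rows[[pairs[1L, k]]], rows[[pairs[2L, k]]],
                     1L, length(rows[[1L]])))
  usable <- vapply(counts, sum, numeric(1L)) > 0
  counts <- counts[usable]
  if (!length(counts)) stop("no comparable sites in the partition")

  t_hat <- vapply(counts, function(nct) {
    tot <- sum(nct)
    jc_initial_t((tot - sum(diag(unclass(nct)))) / tot)
  }, numeric(1L))

  with_alpha <- n_categories > 1L
  par_names <- free_param_template(kind, with_alpha)
  theta <- stats::setNames(rep(0, length(par_names)), par_names)

  objective <- function(th, tv) {
    model <- tryCatch(
      theta_to_model(th, kind, freqs, n_categories, with_alpha),
      error = function(e) NULL)
    if (is.null(model)) return(1e10)
    cache <- model_cache(list(model))[[1L]]
    ll <- 0
    for (k in seq_along(counts)) {
      J <- cache$pi * mixture_matrix(cache$eig, cache$rates, tv[k])
      J[J < 1e-300] <- 1e-300
      ll <- ll + sum(unclass(counts[[k]]) * log(J))
    }
    -ll
  }

  update_t <- function(th) {
    model <- theta_to_model(th, kind, freqs, n_categories, with_alpha)
    cache <- model_cache(list(model))
    vapply(counts, function(nct)
      as.numeric(ml_from_counts(list(nct), cache, tol = 1e-8)), numeric(1L))
  }
  # fully profiled objective: branch lengths are re-optimized inside every
  # evaluation. Alternating t-updates with fixed-t parameter moves crawls
  # along the ridge shared by t, the transition exchangeabilities and
  # alpha; profiling removes the ridge at modest cost (the per-pair inner
  # optimizations are 1-D and cheap).
  objective_profiled <- function(th) {
    model <- tryCatch(
      theta_to_model(th, kind, freqs, n_categories, with_alpha),
      error = function(e) NULL)
    if (is.null(model)) return(1e10)
    cache <- model_cache(list(model))
    -sum(vapply(counts, function(nct)
      attr(ml_from_counts(list(nct), cache, tol = 1e-6), "loglik"),
      numeric(1L)))
  }

  if (length(theta)) {
    # coordinate-style warm-up with t fixed, then profiled refinement
    warm <- stats::optim(theta, objective, tv = t_hat,
                         method = if (length(theta) == 1L) "Brent" else "Nelder-Mead",
                         lower = if (length(theta) == 1L) -10 else -Inf,
                         upper = if (length(theta) == 1L) 10 else Inf,
                         control = list(maxit = 300, reltol = 1e-8))
    theta <- stats::setNames(warm$par, par_names)
    for (outer in seq_len(max_outer)) {
      theta_old <- theta
      opt <- stats::optim(theta, objective_profiled,
                          method = if (length(theta) == 1L) "Brent" else "Nelder-Mead",
                          lower = if (length(theta) == 1L) -10 else -Inf,
                          upper = if (length(theta) == 1L) 10 else Inf,
                          control = list(maxit = 500, reltol = 1e-10))
      theta <- stats::setNames(opt$par, par_names)
      if (max(abs(theta - theta_old)) < tol) break
    }
  }
  t_hat <- update_t(theta)
  theta_to_model(theta, kind, freqs, n_categories, with_alpha)
}

#' Fit and attach models for every partition of an alignment
#'
#' @param aln A [partitioned_alignment()].
#' @param kinds Named character vector of model kinds per partition
#'   (default: `SYM` for the 5.8S partition, `TVM` otherwise, mirroring
#'   the marker's standard partitioned models).
#' @param n_categories Gamma categories per partition model.
#' @param ... Passed to [estimate_model_params()].
#' @return The alignment with fitted models attached.
#' @export
fit_partition_models <- function(aln, kinds = NULL, n_categories = 4L, ...) {
  stopifnot(inherits(aln, "partitioned_alignment"))
  nms <- aln$partitions$name
  if (is.null(kinds))
    kinds <- stats::setNames(
      ifelse(grepl("5\\.?8", nms), "SYM", "TVM"), nms)
  models <- lapply(nms, function(nm)
    estimate_model_params(aln, nm, kind = kinds[[nm]],
                          n_categories = n_categories, ...))
  names(models) <- nms
  aln$models <- models
  aln
}
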