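# GTR-family nucleotide substitution models with discrete-gamma rate
# heterogeneity. The model objects feed both the likelihood machinery
# (pairwise ML distances) and the sequence simulator, so the two always
# share one rate-matrix construction and one gamma discretization.

EXCH_NAMES <- c("AC", "AG", "AT", "CG", "CT", "GT")

#' Construct a nucleotide substitution model
#'
#' Builds a reversible GTR-family model. Supported kinds:
#' * `"GTR"`: six free exchangeabilities, free base frequencies.
#' * `"TVM"`: transversion model; the two transition exchangeabilities are
#'   constrained equal (`AG == CT`), base frequencies free (`+F`).
#' * `"SYM"`: six free exchangeabilities, base frequencies fixed at 1/4.
#' * `"JC"`: all exchangeabilities equal, frequencies 1/4.
#'
#' Among-site rate heterogeneity is modelled as a discrete gamma
#' distribution with `n_categories` equal-probability categories
#' (`gamma_shape = NULL` turns rate heterogeneity off).
#'
#' @param kind Model family, one of `"GTR"`, `"TVM"`, `"SYM"`, `"JC"`.
#' @param exchangeabilities Named positive numeric vector with names
#'   `AC, AG, AT, CG, CT, GT`. Defaults to all 1 (within the kind's
#'   constraints).
#' @param base_frequencies Named numeric vector (`A, C, G, T`) summing to 1.
#'   Ignored (forced uniform) for SYM and JC.
#' @param gamma_shape Gamma shape parameter alpha (> 0), or `NULL` for a
#'   single rate.
#' @param n_categories Number of discrete gamma categories (default 4).
#' @return An object of class `substitution_model`.
#' @examples
#' substitution_model("JC")
#' substitution_model("TVM",
#'   exchangeabilities = c(AC = 1.2, AG = 3, AT = 0.8, CG = 0.9, CT = 3, GT = 1),
#'   base_frequencies = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3),
#'   gamma_shape = 0.7)
#' @export
substitution_model <- function(kind = c("GTR", "TVM", "SYM", "JC"),
                               exchangeabilities = NULL,
                               base_frequencies = NULL,
                               gamma_shape = NULL,
                               n_categories = 4L) {
  kind <- match.arg(kind)
  ex <- stats::setNames(rep(1, 6L), EXCH_NAMES)
  if (!is.null(exchangeabilities)) {
    if (is.null(names(exchangeabilities)) ||
        !all(names(exchangeabilities) %in% EXCH_NAMES))
      stop("exchangeabilities must be named with ", paste(EXCH_NAMES, collapse = ", "))
    ex[names(exchangeabilities)] <- exchangeabilities
  }
  if (any(!is.finite(ex)) || any(ex <= 0))
    stop("exchangeabilities must be positive")
  if (kind == "TVM") {
    if (!is.null(exchangeabilities) &&
        all(c("AG", "CT") %in% names(exchangeabilities)) &&
        abs(ex["AG"] - ex["CT"]) > 1e-12)
      stop("TVM requires equal transition exchangeabilities (AG == CT)")
    ex["CT"] <- ex["AG"]
  }
  if (kind == "JC") {
    if (!is.null(exchangeabilities) && length(unique(round(ex, 12))) != 1L)
      stop("JC requires all exchangeabilities equal")
    ex[] <- 1
  }

  if (kind %in% c("SYM", "JC")) {
    pi <- stats::setNames(rep(0.25, 4L), DNA_BASES)
  } else {
    pi <- base_frequencies %||% stats::setNames(rep(0.25, 4L), DNA_BASES)
    if (is.null(names(pi)) || !setequal(names(pi), DNA_BASES))
      stop("base_frequencies must be named A, C, G, T")
    pi <- pi[DNA_BASES]
    if (any(pi <= 0)) stop("base frequencies must be positive")
    if (abs(sum(pi) - 1) > 1e-12)
      stop("base frequencies must sum to 1 (within 1e-12)")
  }

  if (!is.null(gamma_shape)) {
    assert_scalar_number(gamma_shape, "gamma_shape", lower = 1e-12)
    if (gamma_shape <= 0) stop("gamma_shape must be > 0")
  }
  n_categories <- as.integer(n_categories)
  if (n_categories < 1L) stop("n_categories must be >= 1")

  structure(list(kind = kind,
                 exchangeabilities = ex,
                 base_frequencies = pi,
                 gamma_shape = gamma_shape,
                 n_categories = n_categories),
            class = "substitution_model")
}

#' @export
print.substitution_model <- function(x, ...) {
  g <- if (is.null(x$gamma_shape)) "uniform rates" else
    sprintf("+G%d (alpha = %.4g)", x$n_categories, x$gamma_shape)
  cat(sprintf("substitution model %s, %s\n", x$kind, g))
  cat("  exchangeabilities:",
      paste(sprintf("%s=%.4g", EXCH_NAMES, x$exchangeabilities), collapse = " "), "\n")
  cat("  base frequencies: ",
      paste(sprintf("%s=%.4g", DNA_BASES, x$base_frequencies), collapse = " "), "\n")
  invisible(x)
}

#' Build the normalized instantaneous rate matrix Q
#'
#' Off-diagonal entries are `q_ij = s_ij * pi_j`; rows sum to zero and the
#' matrix is rescaled so the expected substitution rate at stationarity,
#' `-sum_i pi_i q_ii`, equals 1. Branch lengths are then in expected
#' substitutions per site. The construction satisfies detailed balance
#' `pi_i q_ij == pi_j q_ji`.
#'
#' @param model A [substitution_model()].
#' @return A 4x4 numeric matrix with dimnames A, C, G, T.
#' @examples
#' build_rate_matrix(substitution_model("JC"))
#' @export
build_rate_matrix <- function(model) {
  stopifnot(inherits(model, "substitution_model"))
  ex <- model$exchangeabilities
  pi <- model$base_frequencies
  if (any(ex <= 0) || any(pi <= 0))
    stop("exchangeabilities and frequencies must be positive")
  S <- matrix(0, 4L, 4L, dimnames = list(DNA_BASES, DNA_BASES))
  S["A", "C"] <- S["C", "A"] <- ex["AC"]
  S["A", "G"] <- S["G", "A"] <- ex["AG"]
  S["A", "T"] <- S["T", "A"] <- ex["AT"]
  S["C", "G"] <- S["G", "C"] <- ex["CG"]
  S["C", "T"] <- S["T", "C"] <- ex["CT"]
  S["G", "T"] <- S["T", "G"] <- ex["GT"]
  Q <- S * rep(pi, each = 4L)        # q_ij = s_ij * pi_j
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q / mu
}

#' Discrete-gamma rate categories
#'
#' Rates for `C` equal-probability categories of a gamma(alpha, alpha)
#' distribution (mean 1). Each category rate is the exact conditional mean
#' of the density over its quantile slice, so the discretized rates average
#' to 1.
#'
#' @param alpha Gamma shape parameter (> 0).
#' @param n_categories Number of categories `C` (>= 1).
#' @return Numeric vector of `C` rates, increasing, mean 1.
#' @examples
#' gamma_rates(0.5, 4)
#' @export
gamma_rates <- function(alpha, n_categories = 4L) {
  assert_scalar_number(alpha, "alpha", lower = 1e-300)
  C <- as.integer(n_categories)
  if (C < 1L) stop("n_categories must be >= 1")
  if (C == 1L) return(1)
  cuts <- stats::qgamma(seq(0, 1, length.out = C + 1L), shape = alpha, rate = alpha)
  # E[X; a < X < b] for gamma(shape, rate) = (shape/rate) * (F_{shape+1}(b) - F_{shape+1}(a))
  upper <- stats::pgamma(cuts[-1L], shape = alpha + 1, rate = alpha)
  lower <- stats::pgamma(cuts[-(C + 1L)], shape = alpha + 1, rate = alpha)
  rates <- C * (upper - lower)
  rates / mean(rates) * 1  # guard rounding; mean is already 1 to ~1e-15
}

#' Rates used by a model (1 if no gamma component)
#' @noRd
model_rates <- function(model) {
  if (is.null(model$gamma_shape)) return(1)
  gamma_rates(model$gamma_shape, model$n_categories)
}

#' Eigen-decomposition of Q exploiting reversibility
#'
#' Returns a closure-friendly list so P(t) = L diag(exp(lambda t)) R can be
#' evaluated cheaply for many t.
#' @noRd
model_eigen <- function(model) {
  Q <- build_rate_matrix(model)
  pi <- model$base_frequencies
  d <- sqrt(pi)
  A <- Q * outer(d, 1 / d)              # D^{1/2} Q D^{-1/2}, symmetric
  A <- (A + t(A)) / 2
  e <- eigen(A, symmetric = TRUE)
  list(values = e$values,
       L = e$vectors / d,               # row i scaled by 1/sqrt(pi_i)
       R = t(e$vectors * d),            # t(U) pre-scaled by sqrt(pi)
       pi = pi)
}

#' Transition-probability matrix P(t) = exp(Qt)
#'
#' @param model A [substitution_model()] (or the result of the internal
#'   eigen cache).
#' @param t Branch length in expected substitutions per site (>= 0).
#' @return 4x4 stochastic matrix.
#' @examples
#' transition_probability(substitution_model("JC"), 0.1)
#' @export
transition_probability <- function(model, t) {
  eig <- if (inherits(model, "substitution_model")) model_eigen(model) else model
  assert_scalar_number(t, "t", lower = 0)
  P <- eig$L %*% (exp(eig$values * t) * eig$R)
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(DNA_BASES, DNA_BASES)
  P
}
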