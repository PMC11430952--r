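# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

DNA_BASES <- c("A", "C", "G", "T")

#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so that seeded generator calls
#' never perturb the global random stream.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

chars_seq <- function(x) paste(x, collapse = "")

#' Sample n bases i.i.d. from a base-frequency vector
#' @noRd
random_bases <- function(n, freqs = NULL) {
  if (n <= 0L) return(character(0L))
  freqs <- freqs %||% stats::setNames(rep(0.25, 4L), DNA_BASES)
  sample(DNA_BASES, n, replace = TRUE, prob = freqs[DNA_BASES])
}

is_acgt <- function(x) x %in% DNA_BASES

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stop(sprintf("'%s' must be a single number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  invisible(x)
}
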