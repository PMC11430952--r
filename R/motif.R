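# Conserved boundary motifs of the gyrodactylid ITS rDNA region and the
# mismatch-tolerant search used to anchor region boundaries:
#   M18S    ATCATTA  3' end of the 18S gene (end of the 5' flank)
#   M58S_5p CAACTC   5' end of the 5.8S gene
#   M58S_3p GTCGGCT  3' end of the 5.8S gene
#   M28S    CCTGACC  5' end of the 28S gene (start of the 3' flank)

MOTIF_NAMES <- c("M18S", "M58S_5p", "M58S_3p", "M28S")

CANONICAL_MOTIFS <- c(M18S = "ATCATTA",
                      M58S_5p = "CAACTC",
                      M58S_3p = "GTCGGCT",
                      M28S = "CCTGACC")

MOTIF_SEARCH_END <- c(M18S = "head", M58S_5p = "interior",
                      M58S_3p = "interior", M28S = "tail")

#' Expected length of the gyrodactylid 5.8S rRNA gene
#' @export
LEN_58S <- 157L

#' Motif search specification
#'
#' @param name One of `"M18S"`, `"M58S_5p"`, `"M58S_3p"`, `"M28S"`.
#' @param canonical Canonical motif string; defaults to the family-conserved
#'   motif for `name`.
#' @param max_mismatches Substitution tolerance, 0 or 1 (default 1).
#' @param search_end Where to search: `"head"` (first window), `"tail"`
#'   (last window) or `"interior"` (whole sequence).
#' @return Object of class `motif_spec`.
#' @export
motif_spec <- function(name, canonical = NULL, max_mismatches = 1L,
                       search_end = NULL) {
  name <- match.arg(name, MOTIF_NAMES)
  canonical <- toupper(canonical %||% CANONICAL_MOTIFS[[name]])
  if (!nchar(canonical) %in% c(6L, 7L))
    stop("canonical motif must be 6 or 7 nt")
  max_mismatches <- as.integer(max_mismatches)
  if (!max_mismatches %in% c(0L, 1L))
    stop("max_mismatches must be 0 or 1")
  search_end <- search_end %||% MOTIF_SEARCH_END[[name]]
  search_end <- match.arg(search_end, c("head", "tail", "interior"))
  structure(list(name = name, canonical = canonical,
                 max_mismatches = max_mismatches, search_end = search_end),
            class = "motif_spec")
}

default_motif_specs <- function(max_mismatches = 1L) {
  lapply(stats::setNames(MOTIF_NAMES, MOTIF_NAMES),
         motif_spec, max_mismatches = max_mismatches)
}

#' Classify a base substitution
#'
#' @param a,b Single unambiguous bases (A, C, G or T).
#' @return `"identity"` if equal, `"transition"` for purine-purine or
#'   pyrimidine-pyrimidine changes, else `"transversion"`.
#' @examples
#' classify_mismatch("C", "T")  # transition
#' classify_mismatch("T", "A")  # transversion
#' @export
classify_mismatch <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  if (!is_acgt(a) || !is_acgt(b))
    stop("classify_mismatch() requires unambiguous bases A/C/G/T, got '",
         a, "', '", b, "'")
  if (a == b) return("identity")
  purine <- c("A", "G")
  if ((a %in% purine) == (b %in% purine)) "transition" else "transversion"
}

# All candidate placements of a motif within seq[from:to] whose effective
# mismatch count is within tolerance. IUPAC codes that include the canonical
# base count as matches (recorded in ambiguous_matches); other codes count
# as mismatches.
motif_candidates <- function(chars, spec, from, to) {
  m <- nchar(spec$canonical)
  can <- seq_chars(spec$canonical)
  out <- list()
  if (to - from + 1L < m) return(out)
  for (start in from:(to - m + 1L)) {
    obs <- chars[start:(start + m - 1L)]
    mism <- list()
    eff <- 0L
    amb <- 0L
    ok <- TRUE
    for (j in seq_len(m)) {
      b <- obs[j]
      if (b == can[j]) next
      code <- Biostrings::IUPAC_CODE_MAP[b]
      if (!is.na(code) && !is_acgt(b) && grepl(can[j], code, fixed = TRUE)) {
        amb <- amb + 1L
        next
      }
      eff <- eff + 1L
      if (eff > spec$max_mismatches) { ok <- FALSE; break }
      cls <- if (is_acgt(b)) classify_mismatch(can[j], b) else "ambiguous"
      mism[[length(mism) + 1L]] <-
        list(position_in_motif = j, canonical_base = can[j],
             observed_base = b, class = cls)
    }
    if (ok)
      out[[length(out) + 1L]] <-
        list(spec = spec, start = start, end = start + m - 1L,
             observed = chars_seq(obs), mismatches = mism,
             n_mismatches = eff, ambiguous_matches = amb)
  }
  out
}

#' Locate a boundary motif with mismatch tolerance
#'
#' Searches the first `window` nt (`search_end = "head"`), the last `window`
#' nt (`"tail"`) or the whole sequence (`"interior"`) for the motif,
#' tolerating up to `max_mismatches` substitutions. The hit with fewest
#' mismatches wins; ties are broken by proximity to the bounded flank
#' (head: rightmost; tail or interior: leftmost), because the motifs bound
#' the excisable flanks.
#'
#' @param seq Nucleotide sequence (character scalar).
#' @param spec A [motif_spec()] or a motif name.
#' @param window Search window in nt from the relevant end (default 120).
#'   `NULL` searches the whole sequence.
#' @return A `motif_hit` list (`start`, `end`, `observed`, `mismatches`,
#'   `n_mismatches`, `ambiguous_matches`) with 1-based inclusive
#'   coordinates, or `NULL` if no hit is within tolerance.
#' @examples
#' find_motif("GGGATCATTACCC", "M18S", window = NULL)
#' @export
find_motif <- function(seq, spec, window = 120L) {
  if (is.character(spec)) spec <- motif_spec(spec)
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n == 0L) stop("empty sequence")
  m <- nchar(spec$canonical)
  if (!is.null(window) && window < m) stop("window must be >= motif length")
  w <- if (is.null(window)) n else min(window, n)
  range <- switch(spec$search_end,
                  head = c(1L, w),
                  tail = c(n - w + 1L, n),
                  interior = c(1L, n))
  chars <- seq_chars(seq)
  cand <- motif_candidates(chars, spec, range[1L], range[2L])
  pick_motif_hit(cand, spec$search_end)
}

pick_motif_hit <- function(cand, search_end) {
  if (!length(cand)) return(NULL)
  mm <- vapply(cand, `[[`, integer(1L), "n_mismatches")
  cand <- cand[mm == min(mm)]
  starts <- vapply(cand, `[[`, integer(1L), "start")
  idx <- if (search_end == "head") which.max(starts) else which.min(starts)
  cand[[idx]]
}
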