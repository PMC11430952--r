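# Motif-anchored annotation of ITS rDNA records: locate the four boundary
# motifs, excise the 18S/28S flanks, partition into ITS1 / 5.8S / ITS2,
# check the 157-bp 5.8S rule and raise quality flags.

VALID_SEQ_CHARS <- names(Biostrings::IUPAC_CODE_MAP)  # A/C/G/T plus ambiguity

validate_seq <- function(seq) {
  if (length(seq) != 1L || !is.character(seq)) stop("sequence must be a character scalar")
  seq <- toupper(seq)
  if (nchar(seq) == 0L) stop("empty sequence")
  bad <- setdiff(unique(seq_chars(seq)), VALID_SEQ_CHARS)
  if (length(bad))
    stop("invalid characters in sequence: ", paste(bad, collapse = ", "))
  seq
}

region_substr <- function(chars, start, end) {
  if (is.na(start) || is.na(end) || end < start) return(NA_character_)
  chars_seq(chars[start:end])
}

# Assemble a region annotation from the four motif hits (any may be NULL).
# Shared by the annotator and the synthetic generator so that ground truth
# and recovered annotations have identical shape.
build_annotation <- function(record_id, chars, h18, h5p, h3p, h28) {
  n <- length(chars)
  its1_start <- if (!is.null(h18)) h18$end + 1L else 1L
  its1_end   <- if (!is.null(h5p)) h5p$start - 1L else NA_integer_
  s58        <- if (!is.null(h5p)) h5p$start else NA_integer_
  e58        <- if (!is.null(h3p)) h3p$end else NA_integer_
  its2_start <- if (!is.null(h3p)) h3p$end + 1L else NA_integer_
  its2_end   <- if (!is.null(h28)) h28$start - 1L else n

  starts <- c(its1_start, s58, its2_start)
  ends <- c(its1_end, e58, its2_end)
  lens <- ifelse(is.na(starts) | is.na(ends), NA_integer_,
                 as.integer(ends - starts + 1L))
  comp <- c(ITS1 = !is.null(h18) && !is.null(h5p),
            `5.8S` = !is.null(h5p) && !is.null(h3p),
            ITS2 = !is.null(h3p) && !is.null(h28))
  first7 <- vapply(seq_along(starts), function(i) {
    s <- starts[i]
    if (is.na(s) || s + 6L > n) NA_character_ else region_substr(chars, s, s + 6L)
  }, character(1L))
  last7 <- vapply(seq_along(ends), function(i) {
    e <- ends[i]
    if (is.na(e) || e < 7L) NA_character_ else region_substr(chars, e - 6L, e)
  }, character(1L))

  regions <- data.frame(
    region = c("ITS1", "5.8S", "ITS2"),
    start = as.integer(starts), end = as.integer(ends), length = lens,
    first7 = first7, last7 = last7,
    completeness = ifelse(comp, "complete", "incomplete"),
    stringsAsFactors = FALSE)
  total <- if (anyNA(lens)) NA_integer_ else sum(lens)
  structure(list(record_id = record_id,
                 seq_length = n,
                 regions = regions,
                 motifs = list(M18S = h18, M58S_5p = h5p,
                               M58S_3p = h3p, M28S = h28),
                 total_trimmed_length = total),
            class = "its_annotation")
}

#' @export
print.its_annotation <- function(x, ...) {
  cat(sprintf("ITS annotation for '%s' (%d nt, trimmed total %s bp)\n",
              x$record_id, x$seq_length,
              if (is.na(x$total_trimmed_length)) "ND" else x$total_trimmed_length))
  print(x$regions, row.names = FALSE)
  invisible(x)
}

variant_flag <- function(hit, name) {
  cls <- hit$mismatches[[1L]]$class
  sprintf("motif_variant_%s(%s)", cls, name)
}

# QC flags from the located motifs and the implied 5.8S length.
derive_qc <- function(chars, hits) {
  flags <- character(0L)
  h18 <- hits$M18S; h5p <- hits$M58S_5p; h3p <- hits$M58S_3p; h28 <- hits$M28S
  interior_found <- !is.null(h5p) || !is.null(h3p)

  if (is.null(h18)) {
    flags <- c(flags, "motif_missing(M18S)", "truncated_5p")
    if (interior_found) flags <- c(flags, "aberrant_18S_end")
  } else if (h18$n_mismatches >= 1L) {
    flags <- c(flags, "aberrant_18S_end", variant_flag(h18, "M18S"))
  }

  if (is.null(h28)) {
    flags <- c(flags, "motif_missing(M28S)", "truncated_3p")
  } else if (h28$n_mismatches >= 1L) {
    ext <- min(h28$end + 2L, length(chars))
    nine <- chars_seq(chars[h28$start:ext])
    flags <- c(flags, sprintf("nonstandard_28S_motif(%s)", nine),
               variant_flag(h28, "M28S"))
  }

  for (nm in c("M58S_5p", "M58S_3p")) {
    h <- hits[[nm]]
    if (is.null(h)) flags <- c(flags, sprintf("motif_missing(%s)", nm))
    else if (h$n_mismatches >= 1L) flags <- c(flags, variant_flag(h, nm))
  }

  if (!is.null(h5p) && !is.null(h3p)) {
    len58 <- h3p$end - h5p$start + 1L
    if (len58 != LEN_58S)
      flags <- c(flags,
                 sprintf("fivepointeight_length_deviation(%+d)", len58 - LEN_58S))
  }
  qc_report(flags)
}

qc_report <- function(flags) {
  flags <- sort(unique(flags))
  disposition <- if (any(grepl("^motif_missing", flags))) "review"
  else if (length(flags)) "pass_with_warnings"
  else "pass"
  structure(list(flags = flags, disposition = disposition), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC disposition:", x$disposition, "\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

# Choose the best 5.8S motif pair. The 157-bp rule is the strongest prior:
# among candidate (5', 3') pairs prefer the pair whose implied 5.8S length
# is closest to 157, then fewest total mismatches, then leftmost.
pair_58s_hits <- function(c5p, c3p) {
  if (length(c5p) && length(c3p)) {
    best <- NULL
    for (a in c5p) for (b in c3p) {
      if (b$start < a$end + 1L) next
      len <- b$end - a$start + 1L
      key <- c(abs(len - LEN_58S), a$n_mismatches + b$n_mismatches,
               a$start, b$start)
      if (is.null(best) || isTRUE(vector_less(key, best$key)))
        best <- list(a = a, b = b, key = key)
    }
    if (!is.null(best)) return(list(h5p = best$a, h3p = best$b))
  }
  list(h5p = pick_motif_hit(c5p, "interior"),
       h3p = pick_motif_hit(c3p, "interior"))
}

vector_less <- function(x, y) {
  for (i in seq_along(x)) {
    if (x[i] < y[i]) return(TRUE)
    if (x[i] > y[i]) return(FALSE)
  }
  FALSE
}

#' Annotate an ITS rDNA record
#'
#' Locates the conserved boundary motifs (with single-substitution
#' tolerance), excises the 18S/28S flanks and partitions the record into
#' ITS1, 5.8S and ITS2 with 1-based inclusive coordinates. A missing 18S
#' motif leaves ITS1 incomplete starting at position 1; a missing 28S motif
#' leaves ITS2 incomplete ending at the last position. The implied 5.8S
#' length is checked against the conserved 157 bp.
#'
#' @param seq Nucleotide sequence (character scalar; IUPAC codes allowed).
#' @param record_id Identifier used in reports.
#' @param window Search window (nt) at each end for the 18S/28S motifs
#'   (default 120); the 5.8S motifs are searched in the interior between
#'   them.
#' @param max_mismatches Substitution tolerance per motif (0 or 1).
#' @return A list with components `annotation` (class `its_annotation`) and
#'   `qc` (class `qc_report`).
#' @examples
#' ref <- make_reference_its(its_template(seed = 1))
#' ann <- annotate_its(ref$record, "demo")
#' ann$annotation$regions
#' @export
annotate_its <- function(seq, record_id = "record", window = 120L,
                         max_mismatches = 1L) {
  seq <- validate_seq(seq)
  chars <- seq_chars(seq)
  n <- length(chars)
  specs <- default_motif_specs(max_mismatches)

  h18 <- find_motif(seq, specs$M18S, window = window)
  h28 <- find_motif(seq, specs$M28S, window = window)

  from <- if (!is.null(h18)) h18$end + 1L else 1L
  to <- if (!is.null(h28)) h28$start - 1L else n
  c5p <- c3p <- list()
  if (to - from + 1L >= 6L) {
    c5p <- motif_candidates(chars, specs$M58S_5p, from, to)
    c3p <- motif_candidates(chars, specs$M58S_3p, from, to)
  }
  pair <- pair_58s_hits(c5p, c3p)

  hits <- list(M18S = h18, M58S_5p = pair$h5p, M58S_3p = pair$h3p, M28S = h28)
  annotation <- build_annotation(record_id, chars, h18, pair$h5p, pair$h3p, h28)
  list(annotation = annotation, qc = derive_qc(chars, hits))
}

#' Hologenotype-style diagnosis string
#'
#' Formats an annotation as the one-line molecular diagnosis used for
#' reference (hologenotype) ITS sequences:
#' `ITS rDNA (<id>) <total> bp: ITS1 <completeness> <first7> to <last7>
#' <len> bp, 5.8S ..., ITS2 ...`. The total is always the arithmetic sum of
#' the region lengths; if `reported_total` is supplied and disagrees, the
#' discrepancy is logged via [message()] and the computed sum is used.
#'
#' @param annotation An `its_annotation` (from [annotate_its()] or the
#'   generator truth).
#' @param record_id Identifier; defaults to the annotation's.
#' @param reported_total Optional externally reported total length to check
#'   against the sum of parts.
#' @return The diagnosis string (invisibly also printed fields via the
#'   annotation).
#' @export
diagnose <- function(annotation, record_id = NULL, reported_total = NULL) {
  stopifnot(inherits(annotation, "its_annotation"))
  id <- record_id %||% annotation$record_id
  r <- annotation$regions
  total <- annotation$total_trimmed_length
  total_str <- if (is.na(total)) "ND" else as.integer(total)
  if (!is.null(reported_total) && !is.na(total) && reported_total != total)
    message(sprintf(
      "diagnosis for %s: sum of region lengths is %d bp but reported total is %d bp",
      id, total, reported_total))
  fmt <- function(i) {
    len <- if (is.na(r$length[i])) "ND" else r$length[i]
    sprintf("%s %s %s to %s %s bp", r$region[i], r$completeness[i],
            r$first7[i] %|na|% "ND", r$last7[i] %|na|% "ND", len)
  }
  sprintf("ITS rDNA (%s) %s bp: %s, %s, %s",
          id, total_str, fmt(1L), fmt(2L), fmt(3L))
}

`%|na|%` <- function(a, b) if (length(a) == 1L && is.na(a)) b else a

#' Extract trimmed regions from an annotated record
#'
#' @param seq The original record sequence.
#' @param annotation Its `its_annotation`.
#' @return Named list of region sequences (`ITS1`, `5.8S`, `ITS2`) and the
#'   concatenated trimmed record `ITS`; indeterminate regions are `NA`.
#' @export
extract_regions <- function(seq, annotation) {
  stopifnot(inherits(annotation, "its_annotation"))
  chars <- seq_chars(toupper(seq))
  r <- annotation$regions
  out <- lapply(seq_len(3L), function(i) region_substr(chars, r$start[i], r$end[i]))
  names(out) <- r$region
  out$ITS <- if (anyNA(unlist(out[1:3]))) NA_character_ else
    paste(unlist(out[1:3]), collapse = "")
  out
}

#' Batch quality control of ITS records
#'
#' Annotates every record, collecting one row per record with region
#' lengths, flags and disposition. Per-record failures are recorded with
#' disposition `review` and never abort the batch. The summary names the
#' shortest and longest trimmed records among those passing (with or
#' without warnings).
#'
#' @param records Named character vector of sequences.
#' @param window,max_mismatches Passed to [annotate_its()].
#' @return Object of class `its_qc_batch`: list with `table` (data frame),
#'   `shortest`, `longest` and `annotations` (named list).
#' @export
batch_qc <- function(records, window = 120L, max_mismatches = 1L) {
  if (!length(records)) stop("at least one record is required")
  if (is.null(names(records)) || any(!nzchar(names(records))))
    stop("records must be named")
  anns <- vector("list", length(records))
  names(anns) <- names(records)
  rows <- lapply(names(records), function(id) {
    res <- tryCatch(annotate_its(records[[id]], id, window, max_mismatches),
                    error = function(e)
                      list(error = conditionMessage(e)))
    if (!is.null(res$error))
      return(data.frame(id = id, its1_length = NA_integer_,
                        fivepointeight_length = NA_integer_,
                        its2_length = NA_integer_, total = NA_integer_,
                        flags = sprintf("error(%s)", res$error),
                        disposition = "review", stringsAsFactors = FALSE))
    anns[[id]] <<- res
    r <- res$annotation$regions
    data.frame(id = id,
               its1_length = r$length[1L],
               fivepointeight_length = r$length[2L],
               its2_length = r$length[3L],
               total = res$annotation$total_trimmed_length,
               flags = paste(res$qc$flags, collapse = ";"),
               disposition = res$qc$disposition, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  ok <- tab$disposition %in% c("pass", "pass_with_warnings") & !is.na(tab$total)
  pick <- function(which_fun) {
    if (!any(ok)) return(NULL)
    i <- which(ok)[which_fun(tab$total[ok])]
    list(id = tab$id[i], total = tab$total[i])
  }
  structure(list(table = tab, shortest = pick(which.min),
                 longest = pick(which.max), annotations = anns),
            class = "its_qc_batch")
}

#' @export
print.its_qc_batch <- function(x, ...) {
  print(x$table, row.names = FALSE)
  if (!is.null(x$shortest))
    cat(sprintf("shortest trimmed record: %s (%d bp); longest: %s (%d bp)\n",
                x$shortest$id, x$shortest$total, x$longest$id, x$longest$total))
  invisible(x)
}
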