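# Synthetic ITS record generator with exact ground truth. Emits the
# pre-excision form of a gyrodactylid ITS rDNA submission: an 18S tail
# ending in ATCATTA, ITS1, an exactly 157-nt 5.8S gene bounded by CAACTC
# and GTCGGCT, ITS2, and a 28S head starting with CCTGACC. Background
# composition is i.i.d. from a configurable base-frequency vector and is
# guaranteed free of confusable motif matches (no placement of any
# canonical motif within one substitution outside the true sites), so the
# truth coordinates are unambiguous for a single-mismatch-tolerant search.

#' Template for a synthetic ITS record
#'
#' @param flank18_len Length of the retained 18S tail (>= 7; its last 7 nt
#'   are the ATCATTA motif).
#' @param its1_len,its2_len Spacer lengths in nt (>= 7 so the boundary
#'   heptamers exist).
#' @param flank28_len Length of the retained 28S head (>= 7; starts with
#'   CCTGACC).
#' @param base_freqs Background base frequencies (named A, C, G, T; default
#'   uniform).
#' @param seed Integer seed governing all randomness of the record.
#' @return Object of class `its_template`.
#' @export
its_template <- function(flank18_len = 100L, its1_len = 343L,
                         its2_len = 289L, flank28_len = 100L,
                         base_freqs = NULL, seed = 1L) {
  flank18_len <- as.integer(flank18_len); its1_len <- as.integer(its1_len)
  its2_len <- as.integer(its2_len); flank28_len <- as.integer(flank28_len)
  if (its1_len < 7L || its2_len < 7L)
    stop("its1_len and its2_len must be >= 7 (regions carry boundary heptamers)")
  if (flank18_len < 7L || flank28_len < 7L)
    stop("flank lengths must be >= 7 (they carry the boundary motifs)")
  freqs <- base_freqs %||% stats::setNames(rep(0.25, 4L), DNA_BASES)
  if (is.null(names(freqs)) || !setequal(names(freqs), DNA_BASES) ||
      any(freqs <= 0) || abs(sum(freqs) - 1) > 1e-9)
    stop("base_freqs must be named A, C, G, T, positive, summing to 1")
  structure(list(flank18_len = flank18_len, its1_len = its1_len,
                 its2_len = its2_len, flank28_len = flank28_len,
                 base_freqs = freqs[DNA_BASES], seed = as.integer(seed)),
            class = "its_template")
}

# Candidate windows (<= 1 mismatch) of every canonical motif over the whole
# sequence that could confuse the annotator: anything other than the true
# placement, unless it has strictly more mismatches than the true hit of
# the same motif (such windows always lose the fewest-mismatches rule and
# are harmless). For an absent motif every candidate is harmful.
spurious_motif_windows <- function(chars, expected, true_mm) {
  out <- list()
  for (nm in MOTIF_NAMES) {
    spec <- motif_spec(nm)
    cand <- motif_candidates(chars, spec, 1L, length(chars))
    exp_start <- expected[[nm]]
    present <- !is.null(exp_start) && !is.na(exp_start)
    for (h in cand) {
      if (present && h$start == exp_start) next
      # head/tail searches pick fewest mismatches first, so a worse window
      # can never win there; the interior 5.8S pairing scores implied
      # length before mismatches, so any stray interior candidate is kept
      if (present && spec$search_end != "interior" &&
          h$n_mismatches > true_mm[[nm]]) next
      out[[length(out) + 1L]] <- c(h$start, h$end)
    }
  }
  out
}

# Redraw background positions inside spurious windows until the sequence is
# clean. `protected` marks positions whose content is fixed (true motifs,
# pinned heptamers).
scrub_motif_background <- function(chars, expected, protected, freqs,
                                   true_mm = NULL, max_iter = 100L) {
  true_mm <- true_mm %||% stats::setNames(rep(0L, 4L), MOTIF_NAMES)
  for (iter in seq_len(max_iter)) {
    windows <- spurious_motif_windows(chars, expected, true_mm)
    if (!length(windows)) return(chars)
    changed <- FALSE
    for (w in windows) {
      idx <- setdiff(seq.int(w[1L], w[2L]), protected)
      if (!length(idx)) next
      chars[idx] <- random_bases(length(idx), freqs)
      changed <- TRUE
    }
    if (!changed)
      stop("cannot scrub a spurious motif match made entirely of protected positions")
  }
  stop("failed to remove spurious motif matches after ", max_iter, " redraws")
}

pin_heptamer <- function(chars, start, value, what) {
  if (is.null(value)) return(list(chars = chars, idx = integer(0L)))
  value <- toupper(value)
  if (nchar(value) != 7L) stop(what, " must be a 7-mer")
  idx <- seq.int(start, start + 6L)
  chars[idx] <- seq_chars(value)
  list(chars = chars, idx = idx)
}

#' Generate a reference ITS record with known truth
#'
#' Builds the pre-excision record described by `template` and the exact
#' region/motif coordinates as a truth annotation. Optional `heptamers`
#' pins the first/last 7 nt of regions (to reconstruct published diagnosis
#' strings); pinned heptamers must be consistent with the conserved motifs
#' they overlap (the 5.8S first7 must start with CAACTC and its last7 is
#' always GTCGGCT).
#'
#' @param template An [its_template()].
#' @param heptamers Optional list with any of `its1_first7`, `its1_last7`,
#'   `fives_first7`, `its2_first7`, `its2_last7`.
#' @return Object of class `its_reference`: list with `record` (sequence),
#'   `truth` (class `its_annotation`) and `template`.
#' @examples
#' ref <- make_reference_its(its_template(its1_len = 345, its2_len = 332))
#' ref$truth$total_trimmed_length  # 834
#' @export
make_reference_its <- function(template, heptamers = NULL) {
  stopifnot(inherits(template, "its_template"))
  tp <- template
  freqs <- tp$base_freqs
  with_seed(tp$seed, {
    f18 <- c(random_bases(tp$flank18_len - 7L, freqs), seq_chars("ATCATTA"))
    its1 <- random_bases(tp$its1_len, freqs)
    fives <- c(seq_chars("CAACTC"), random_bases(LEN_58S - 13L, freqs),
               seq_chars("GTCGGCT"))
    its2 <- random_bases(tp$its2_len, freqs)
    f28 <- c(seq_chars("CCTGACC"), random_bases(tp$flank28_len - 7L, freqs))
    chars <- c(f18, its1, fives, its2, f28)

    m18 <- tp$flank18_len - 6L
    its1_start <- tp$flank18_len + 1L
    s58 <- its1_start + tp$its1_len
    e58 <- s58 + LEN_58S - 1L
    its2_start <- e58 + 1L
    m28 <- its2_start + tp$its2_len
    n <- length(chars)

    protected <- c(seq.int(m18, m18 + 6L), seq.int(s58, s58 + 5L),
                   seq.int(e58 - 6L, e58), seq.int(m28, m28 + 6L))
    if (!is.null(heptamers)) {
      hp <- heptamers
      if (!is.null(hp$fives_first7) &&
          substr(toupper(hp$fives_first7), 1L, 6L) != "CAACTC")
        stop("fives_first7 must start with the CAACTC motif")
      p <- pin_heptamer(chars, its1_start, hp$its1_first7, "its1_first7")
      chars <- p$chars; protected <- c(protected, p$idx)
      p <- pin_heptamer(chars, its1_start + tp$its1_len - 7L, hp$its1_last7, "its1_last7")
      chars <- p$chars; protected <- c(protected, p$idx)
      p <- pin_heptamer(chars, s58, hp$fives_first7, "fives_first7")
      chars <- p$chars; protected <- c(protected, p$idx)
      p <- pin_heptamer(chars, its2_start, hp$its2_first7, "its2_first7")
      chars <- p$chars; protected <- c(protected, p$idx)
      p <- pin_heptamer(chars, its2_start + tp$its2_len - 7L, hp$its2_last7, "its2_last7")
      chars <- p$chars; protected <- c(protected, p$idx)
    }
    protected <- sort(unique(protected))

    expected <- list(M18S = m18, M58S_5p = s58, M58S_3p = e58 - 6L, M28S = m28)
    chars <- scrub_motif_background(chars, expected, protected, freqs)

    mk_hit <- function(nm, start) {
      spec <- motif_spec(nm)
      m <- nchar(spec$canonical)
      list(spec = spec, start = start, end = start + m - 1L,
           observed = chars_seq(chars[start:(start + m - 1L)]),
           mismatches = list(), n_mismatches = 0L, ambiguous_matches = 0L)
    }
    truth <- build_annotation("synthetic", chars,
                              mk_hit("M18S", m18), mk_hit("M58S_5p", s58),
                              mk_hit("M58S_3p", e58 - 6L), mk_hit("M28S", m28))
    structure(list(record = chars_seq(chars), truth = truth,
                   template = tp),
              class = "its_reference")
  })
}

#' Synthetic reconstructions of published hologenotype diagnoses
#'
#' Builds a small panel of synthetic ITS records whose region lengths,
#' boundary heptamers and motif variants reproduce published hologenotype
#' diagnoses of reference gyrodactylid sequences. The interior background
#' is random, so these are explicitly *synthetic stand-ins* (ids carry a
#' `_syn` suffix) for the real GenBank records; they exercise the
#' annotator against the printed region structure without network access.
#'
#' Panel (ITS1 / 5.8S / ITS2, trimmed total):
#' * `ol413105_syn` 343/157/289 = 789 bp (printed as 788 bp; the parts sum
#'   to 789 — see [diagnose()]'s `reported_total`).
#' * `or773087_syn` 345/157/332 = 834 bp.
#' * `mh667459_syn` 359/157/322 = 838 bp.
#' * `kj461316_syn` 367/157/384 = 908 bp.
#' * `aj001843_syn` 297/157/297 = 751 bp, with the CAACTT 5.8S variant and
#'   the CCCGACC 28S variant (single transitions); the published diagnosis
#'   gives only the 751 bp total, so the ITS1/ITS2 split is a synthetic
#'   choice.
#' * `kf680221_syn` 500/157/438 = 1095 bp with a single-transition 18S
#'   motif end (retained with a warning); only the total is published.
#'
#' @param seed Integer seed for the random backgrounds.
#' @return List with `records` (named character vector) and `expected`
#'   (data frame `id`, `exp_its1`, `exp_its2`, `exp_total`).
#' @export
synthetic_hologenotypes <- function(seed = 2024L) {
  mk <- function(i, its1, its2, hept = NULL, specs = list()) {
    ref <- make_reference_its(
      its_template(its1_len = its1, its2_len = its2, seed = seed + i),
      heptamers = hept)
    if (length(specs))
      apply_mutations(ref, specs, seed = seed + 100L + i)$record
    else ref$record
  }
  records <- c(
    ol413105_syn = mk(1L, 343L, 289L,
      list(its1_first7 = "TTAAATT", its1_last7 = "AATTATA",
           fives_first7 = "CAACTCT",
           its2_first7 = "TTAACCT", its2_last7 = "TACTATT")),
    or773087_syn = mk(2L, 345L, 332L,
      list(its1_first7 = "TGTATTG", its1_last7 = "TAATTTT",
           fives_first7 = "CAACTCC",
           its2_first7 = "TTTACCT", its2_last7 = "TTAGCCT")),
    mh667459_syn = mk(3L, 359L, 322L,
      list(its1_first7 = "TGTATTT", its1_last7 = "ATATGTA",
           fives_first7 = "CAACTCC",
           its2_first7 = "TTTACCT", its2_last7 = "ATTACTT")),
    kj461316_syn = mk(4L, 367L, 384L,
      list(its1_first7 = "CGTATTG", its1_last7 = "ATTTGTA",
           fives_first7 = "CAACTCC",
           its2_first7 = "TTTACCT", its2_last7 = "AAACCTT")),
    aj001843_syn = mk(5L, 297L, 297L, NULL,
      list(mutation_spec("M58S_5p", "transition", 6),    # CAACTT
           mutation_spec("M28S", "transition", 3))),     # CCCGACC
    kf680221_syn = mk(6L, 500L, 438L, NULL,
      list(mutation_spec("M18S", "transition", 5))))     # ATCACTA-style end
  expected <- data.frame(
    id = c("ol413105_syn", "or773087_syn", "mh667459_syn", "kj461316_syn",
           "aj001843_syn", "kf680221_syn"),
    exp_its1 = c(343L, 345L, 359L, 367L, 297L, 500L),
    exp_its2 = c(289L, 332L, 322L, 384L, 297L, 438L),
    stringsAsFactors = FALSE)
  expected$exp_total <- expected$exp_its1 + 157L + expected$exp_its2
  list(records = records, expected = expected)
}

#' Mutation specification for the synthetic generator
#'
#' @param target_motif One of `"M18S"`, `"M58S_5p"`, `"M58S_3p"`, `"M28S"`.
#' @param kind `"transition"` or `"transversion"` (single-base motif
#'   substitutions), `"insertion"`/`"deletion"` (length changes of
#'   `count` nt next to the targeted motif: inside the 5.8S gene for the
#'   5.8S motifs, inside the flank for the 18S/28S motifs), or
#'   `"truncate_5p"`/`"truncate_3p"` (remove the motif plus `count`
#'   adjacent spacer bases, emulating submissions whose flanking motifs
#'   were trimmed off).
#' @param position_in_motif 1-based position for substitutions.
#' @param count Length change / extra truncation in nt (default 1; 0
#'   allowed for truncations).
#' @return Object of class `mutation_spec`.
#' @export
mutation_spec <- function(target_motif, kind, position_in_motif = NA_integer_,
                          count = 1L) {
  target_motif <- match.arg(target_motif, MOTIF_NAMES)
  kind <- match.arg(kind, c("transition", "transversion", "insertion",
                            "deletion", "truncate_5p", "truncate_3p"))
  count <- as.integer(count)
  if (kind %in% c("transition", "transversion")) {
    m <- nchar(CANONICAL_MOTIFS[[target_motif]])
    if (is.na(position_in_motif) || position_in_motif < 1L ||
        position_in_motif > m)
      stop("position_in_motif must be in 1..", m, " for ", target_motif)
  }
  if (kind %in% c("insertion", "deletion") && count < 1L)
    stop("count must be >= 1 for indels")
  if (kind == "truncate_5p" && target_motif != "M18S")
    stop("truncate_5p applies to M18S")
  if (kind == "truncate_3p" && target_motif != "M28S")
    stop("truncate_3p applies to M28S")
  if (kind %in% c("truncate_5p", "truncate_3p") && count < 0L)
    stop("count must be >= 0 for truncations")
  structure(list(target_motif = target_motif, kind = kind,
                 position_in_motif = as.integer(position_in_motif),
                 count = count),
            class = "mutation_spec")
}

TRANSITION_MAP <- c(A = "G", G = "A", C = "T", T = "C")
TRANSVERSION_MAP <- c(A = "T", T = "A", C = "G", G = "C")

#' Apply motif mutations to a synthetic reference record
#'
#' Applies the given [mutation_spec()]s and returns the mutated record
#' together with the QC findings a single-mismatch-tolerant annotator must
#' raise and the region lengths it must report (NA where a boundary becomes
#' indeterminate). At most one destructive (indel/truncation) spec per
#' motif is allowed.
#'
#' @param ref An `its_reference` from [make_reference_its()].
#' @param specs List of [mutation_spec()]s (empty list leaves the record
#'   untouched and expects no flags).
#' @param seed Seed for inserted-base content.
#' @return List with `record`, `expected_flags`, `expected_lengths` (named
#'   `ITS1`, `5.8S`, `ITS2`), `expected_completeness`,
#'   `expected_disposition` and `specs`.
#' @export
apply_mutations <- function(ref, specs = list(), seed = 1L) {
  stopifnot(inherits(ref, "its_reference"))
  if (inherits(specs, "mutation_spec")) specs <- list(specs)
  lapply(specs, function(s) stopifnot(inherits(s, "mutation_spec")))
  tp <- ref$template
  destructive <- vapply(specs, function(s)
    s$kind %in% c("insertion", "deletion", "truncate_5p", "truncate_3p"),
    logical(1L))
  dmot <- vapply(specs[destructive], `[[`, character(1L), "target_motif")
  if (anyDuplicated(dmot))
    stop("overlapping destructive mutation specs on motif ",
         dmot[duplicated(dmot)][1L])

  chars <- seq_chars(ref$record)
  motif_start <- vapply(ref$truth$motifs, `[[`, integer(1L), "start")
  motif_len <- vapply(MOTIF_NAMES, function(nm)
    nchar(CANONICAL_MOTIFS[[nm]]), integer(1L))

  sub_count <- stats::setNames(integer(4L), MOTIF_NAMES)
  sub_class <- stats::setNames(rep(NA_character_, 4L), MOTIF_NAMES)
  for (s in specs[!destructive]) {
    nm <- s$target_motif
    idx <- motif_start[[nm]] + s$position_in_motif - 1L
    map <- if (s$kind == "transition") TRANSITION_MAP else TRANSVERSION_MAP
    chars[idx] <- map[[chars[idx]]]
    sub_count[[nm]] <- sub_count[[nm]] + 1L
    sub_class[[nm]] <- s$kind
  }

  flank18 <- tp$flank18_len
  flank28 <- tp$flank28_len
  len58_delta <- 0L
  trunc5 <- trunc3 <- 0L
  truncated <- stats::setNames(rep(FALSE, 4L), MOTIF_NAMES)

  ops <- specs[destructive]
  # apply right-to-left so earlier coordinates stay valid
  anchor <- vapply(ops, function(s) motif_start[[s$target_motif]], integer(1L))
  ops <- ops[order(anchor, decreasing = TRUE)]
  ins_points <- integer(0L)
  with_seed(seed, {
    for (s in ops) {
      nm <- s$target_motif
      st <- motif_start[[nm]]; en <- st + motif_len[[nm]] - 1L
      if (s$kind == "insertion") {
        at <- if (nm %in% c("M58S_5p", "M58S_3p")) {
          if (nm == "M58S_5p") motif_start[["M58S_5p"]] + 6L
          else motif_start[["M58S_3p"]] - 1L
        } else if (nm == "M18S") st - 1L else en
        ins <- random_bases(s$count, tp$base_freqs)
        chars <- append(chars, ins, after = at)
        ins_points <- c(ins_points, at)
        if (nm %in% c("M58S_5p", "M58S_3p")) len58_delta <- len58_delta + s$count
        else if (nm == "M18S") flank18 <- flank18 + s$count
        else flank28 <- flank28 + s$count
        shift <- motif_start > at
        motif_start[shift] <- motif_start[shift] + s$count
      } else if (s$kind == "deletion") {
        if (nm %in% c("M58S_5p", "M58S_3p")) {
          if (s$count > LEN_58S - 13L) stop("deletion would eat a 5.8S motif")
          from <- motif_start[["M58S_5p"]] + 6L + 1L
          len58_delta <- len58_delta - s$count
        } else if (nm == "M18S") {
          if (s$count > flank18 - 7L) stop("deletion would eat the 18S motif")
          from <- 1L
          flank18 <- flank18 - s$count
        } else {
          if (s$count > flank28 - 7L) stop("deletion would eat the 28S motif")
          from <- en + 1L
          flank28 <- flank28 - s$count
        }
        drop <- seq.int(from, from + s$count - 1L)
        chars <- chars[-drop]
        shift <- motif_start > from
        motif_start[shift] <- motif_start[shift] - s$count
      } else if (s$kind == "truncate_5p") {
        cut <- en + s$count
        chars <- chars[-seq_len(cut)]
        trunc5 <- s$count
        truncated[["M18S"]] <- TRUE
        motif_start <- motif_start - cut
        motif_start[["M18S"]] <- NA_integer_
      } else { # truncate_3p
        cut_from <- st - s$count
        chars <- chars[-seq.int(cut_from, length(chars))]
        trunc3 <- s$count
        truncated[["M28S"]] <- TRUE
        motif_start[["M28S"]] <- NA_integer_
      }
    }

    present <- !truncated & sub_count <= 1L
    expected_pos <- as.list(ifelse(present, motif_start, NA_integer_))
    names(expected_pos) <- MOTIF_NAMES
    protected <- integer(0L)
    for (nm in MOTIF_NAMES)
      if (isTRUE(present[[nm]]))
        protected <- c(protected,
                       seq.int(motif_start[[nm]],
                               motif_start[[nm]] + motif_len[[nm]] - 1L))
    chars <- scrub_motif_background(chars, expected_pos, protected,
                                    tp$base_freqs, true_mm = sub_count)
  })

  present <- !truncated & sub_count <= 1L
  flags <- character(0L)
  for (nm in MOTIF_NAMES) {
    if (!present[[nm]]) {
      flags <- c(flags, sprintf("motif_missing(%s)", nm))
      if (nm == "M18S") flags <- c(flags, "aberrant_18S_end", "truncated_5p")
      if (nm == "M28S") flags <- c(flags, "truncated_3p")
    } else if (sub_count[[nm]] == 1L) {
      flags <- c(flags, sprintf("motif_variant_%s(%s)", sub_class[[nm]], nm))
      if (nm == "M18S") flags <- c(flags, "aberrant_18S_end")
      if (nm == "M28S") {
        st <- motif_start[["M28S"]]
        ext <- min(st + 8L, length(chars))
        flags <- c(flags, sprintf("nonstandard_28S_motif(%s)",
                                  chars_seq(chars[st:ext])))
      }
    }
  }
  if (present[["M58S_5p"]] && present[["M58S_3p"]] && len58_delta != 0L)
    flags <- c(flags, sprintf("fivepointeight_length_deviation(%+d)", len58_delta))

  its1 <- tp$its1_len
  if (truncated[["M18S"]]) its1 <- its1 - trunc5
  else if (!present[["M18S"]]) its1 <- its1 + flank18
  its2 <- tp$its2_len
  if (truncated[["M28S"]]) its2 <- its2 - trunc3
  else if (!present[["M28S"]]) its2 <- its2 + flank28
  if (!present[["M58S_5p"]]) its1 <- NA_integer_
  if (!present[["M58S_3p"]]) its2 <- NA_integer_
  len58 <- if (present[["M58S_5p"]] && present[["M58S_3p"]])
    LEN_58S + len58_delta else NA_integer_

  qc <- qc_report(flags)
  list(record = chars_seq(chars),
       expected_flags = qc$flags,
       expected_lengths = c(ITS1 = as.integer(its1), `5.8S` = as.integer(len58),
                            ITS2 = as.integer(its2)),
       expected_completeness = c(
         ITS1 = if (present[["M18S"]] && present[["M58S_5p"]]) "complete" else "incomplete",
         `5.8S` = if (present[["M58S_5p"]] && present[["M58S_3p"]]) "complete" else "incomplete",
         ITS2 = if (present[["M58S_3p"]] && present[["M28S"]]) "complete" else "incomplete"),
       expected_disposition = qc$disposition,
       specs = specs)
}
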