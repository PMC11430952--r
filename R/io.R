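# Readers and writers for the formats the pipeline touches: FASTA,
# RAxML-style or tabular partition files, Newick trees, group maps and the
# tabular/JSON report mirrors.

#' Read a FASTA file
#'
#' @param path FASTA file (multi-record). Duplicate ids and empty files are
#'   errors; lowercase bases are uppercased with a notice.
#' @return Named character vector of sequences (full header line as name).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) stop("empty FASTA file: ", path)
  ids <- names(x)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate FASTA id(s): ", paste(dup, collapse = ", "))
  seqs <- as.character(x)
  if (any(grepl("[a-z]", seqs))) {
    message("lowercase bases uppercased on input")
    seqs <- toupper(seqs)
  }
  stats::setNames(seqs, ids)
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line wrap (default 80 columns).
#' @export
write_fasta <- function(seqs, path, width = 80L) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("sequences must be named")
  if (anyDuplicated(names(seqs)))
    stop("duplicate ids: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = width)
  invisible(path)
}

#' Read a partition table
#'
#' Accepts RAxML-style lines (`DNA, ITS1 = 1-826`) or a TSV with header
#' columns `name`, `start`, `end` and optional `model`.
#'
#' @param path Partition file.
#' @return Data frame with columns `name`, `start`, `end`, `model`.
#' @export
read_partition_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("empty partition file: ", path)
  raxml <- grepl("^[^\t]+,.*=\\s*\\d+\\s*-\\s*\\d+\\s*$", lines[1L])
  if (raxml) {
    m <- regmatches(lines, regexec(
      "^\\s*(\\S+)\\s*,\\s*(\\S+)\\s*=\\s*(\\d+)\\s*-\\s*(\\d+)\\s*$", lines))
    bad <- vapply(m, length, integer(1L)) != 5L
    if (any(bad)) stop("malformed partition line: ", lines[bad][1L])
    out <- data.frame(
      name = vapply(m, `[`, character(1L), 3L),
      start = as.integer(vapply(m, `[`, character(1L), 4L)),
      end = as.integer(vapply(m, `[`, character(1L), 5L)),
      model = NA_character_, stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.delim(textConnection(lines), stringsAsFactors = FALSE)
    stopifnot(all(c("name", "start", "end") %in% names(tab)))
    if (is.null(tab$model)) tab$model <- NA_character_
    out <- tab[, c("name", "start", "end", "model")]
    out$start <- as.integer(out$start); out$end <- as.integer(out$end)
  }
  if (anyDuplicated(out$name)) stop("duplicate partition names")
  out
}

#' Read a Newick tree with support annotations
#'
#' @param path File path, or a Newick string via `text`.
#' @param text Newick string (alternative to `path`).
#' @param ... Passed to [tree_view()] (e.g. `outgroup`, `label_format`).
#' @return A [tree_view()].
#' @export
read_newick <- function(path = NULL, text = NULL, ...) {
  phy <- if (!is.null(text)) ape::read.tree(text = text) else {
    if (!file.exists(path)) stop("no such file: ", path)
    ape::read.tree(path)
  }
  if (is.null(phy)) stop("could not parse Newick input")
  tree_view(phy, ...)
}

#' Write a distance matrix
#'
#' @param mat Symmetric distance matrix with id dimnames.
#' @param path Output path.
#' @param format `"tsv"` (header row + id column) or `"phylip"`
#'   (lower-triangular PHYLIP-style square matrix).
#' @export
write_distance_matrix <- function(mat, path, format = c("tsv", "phylip")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(id = rownames(mat), as.data.frame(unclass(mat)[, , drop = FALSE]),
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(sprintf("%5d", nrow(mat)), con)
    for (i in seq_len(nrow(mat)))
      writeLines(paste(c(sprintf("%-10s", rownames(mat)[i]),
                         sprintf("%.6f", mat[i, ])), collapse = " "), con)
  }
  invisible(path)
}

#' Long-format (heatmap-ready) distance table
#'
#' One row per ordered pair with the method recorded per cell, mirroring
#' heatmaps that carry p-distances in one triangle and ML distances in the
#' other.
#'
#' @param ... Named distance matrices (e.g. `p = pmat, ml = mlmat`); with
#'   two matrices the first fills the upper triangle, the second the lower.
#' @return Data frame (`id_a`, `id_b`, `method`, `distance`).
#' @export
distance_long_format <- function(...) {
  mats <- list(...)
  stopifnot(length(mats) >= 1L, !is.null(names(mats)))
  ids <- rownames(mats[[1L]])
  rows <- list()
  for (k in seq_along(mats)) {
    m <- mats[[k]]
    tri <- if (length(mats) == 2L && k == 2L) lower.tri(m) else upper.tri(m)
    w <- which(tri, arr.ind = TRUE)
    rows[[k]] <- data.frame(id_a = ids[w[, 1L]], id_b = ids[w[, 2L]],
                            method = names(mats)[k],
                            distance = m[tri], stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Read a tip-to-group map
#'
#' Two-column TSV (`tip_id`, `group`), with or without a header line.
#'
#' @param path File path.
#' @return Named character vector (`tip -> group`).
#' @export
read_group_map <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("group map must have two columns (tip_id, group)")
  if (identical(tolower(tab[1L, 1L]), "tip_id")) tab <- tab[-1L, , drop = FALSE]
  normalize_group_map(stats::setNames(as.character(tab[[2L]]),
                                      as.character(tab[[1L]])))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a QC batch as TSV and JSON
#'
#' @param batch An `its_qc_batch` from [batch_qc()].
#' @param prefix Output path prefix (writes `<prefix>_qc.tsv` and
#'   `<prefix>_qc.json`).
#' @return Character vector of the two paths.
#' @export
write_qc_table <- function(batch, prefix) {
  stopifnot(inherits(batch, "its_qc_batch"))
  tsv <- paste0(prefix, "_qc.tsv")
  json <- paste0(prefix, "_qc.json")
  write_tsv(batch$table, tsv)
  jsonlite::write_json(list(table = batch$table, shortest = batch$shortest,
                            longest = batch$longest),
                       json, auto_unbox = TRUE, digits = NA, na = "null")
  c(tsv, json)
}

#' Write a lineage report as TSV and JSON
#'
#' @param report A [lineage_report()].
#' @param prefix Output path prefix.
#' @return Character vector of written paths.
#' @export
write_lineage_report <- function(report, prefix) {
  stopifnot(inherits(report, "lineage_report"))
  paths <- c(paste0(prefix, "_groups.tsv"), paste0(prefix, "_group_pairs.tsv"),
             paste0(prefix, "_report.json"))
  write_tsv(report$groups, paths[1L])
  write_tsv(report$group_pairs, paths[2L])
  jsonlite::write_json(list(groups = report$groups,
                            group_pairs = report$group_pairs),
                       paths[3L], auto_unbox = TRUE, digits = NA, na = "null")
  paths
}
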