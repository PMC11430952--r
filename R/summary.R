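# Group-level distance summaries: mean intra-group and inter-group
# pairwise distances, the quantities reported for genus-level comparisons.

normalize_group_map <- function(groups) {
  if (is.data.frame(groups)) {
    stopifnot(ncol(groups) >= 2L)
    out <- stats::setNames(as.character(groups[[2L]]),
                           as.character(groups[[1L]]))
  } else {
    out <- groups
  }
  if (is.null(names(out)) || any(!nzchar(names(out))))
    stop("group map must be named by sequence/tip id")
  if (any(is.na(out) | !nzchar(out))) stop("group labels must be non-empty")
  out
}

#' Mean intra- and inter-group distances
#'
#' Intra-group mean: average over all unordered within-group pairs (groups
#' with fewer than two members yield no intra mean). Inter-group mean:
#' average over all cross pairs of the two groups. Full precision is
#' retained; the print method rounds to 2 decimals as in published tables.
#'
#' @param mat Symmetric distance matrix with id dimnames (from
#'   [p_distance_matrix()] or [ml_distance_matrix()]).
#' @param groups Named character vector (`id -> group`) or two-column data
#'   frame (id, group). Every matrix id must be mapped.
#' @return Object of class `group_distance_summary`: list with data frames
#'   `intra` (`group`, `n_members`, `n_pairs`, `mean_distance`) and
#'   `inter` (`group_a`, `group_b`, `n_pairs`, `mean_distance`).
#' @export
group_distance_summary <- function(mat, groups) {
  groups <- normalize_group_map(groups)
  ids <- rownames(mat)
  if (is.null(ids)) stop("distance matrix must have id dimnames")
  unmapped <- setdiff(ids, names(groups))
  if (length(unmapped))
    stop("unmapped ids in distance matrix: ", paste(unmapped, collapse = ", "))
  g <- groups[ids]
  labels <- sort(unique(g))

  intra <- do.call(rbind, lapply(labels, function(lab) {
    members <- ids[g == lab]
    if (length(members) < 2L)
      return(data.frame(group = lab, n_members = length(members),
                        n_pairs = 0L, mean_distance = NA_real_,
                        stringsAsFactors = FALSE))
    sub <- mat[members, members, drop = FALSE]
    vals <- sub[upper.tri(sub)]
    data.frame(group = lab, n_members = length(members),
               n_pairs = length(vals), mean_distance = mean(vals),
               stringsAsFactors = FALSE)
  }))

  inter <- if (length(labels) < 2L) {
    data.frame(group_a = character(0L), group_b = character(0L),
               n_pairs = integer(0L), mean_distance = numeric(0L))
  } else {
    pairs <- utils::combn(labels, 2L)
    do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
      a <- ids[g == pairs[1L, k]]; b <- ids[g == pairs[2L, k]]
      vals <- as.vector(mat[a, b, drop = FALSE])
      data.frame(group_a = pairs[1L, k], group_b = pairs[2L, k],
                 n_pairs = length(vals), mean_distance = mean(vals),
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(intra = intra, inter = inter,
                 method = attr(mat, "method")),
            class = "group_distance_summary")
}

#' @export
print.group_distance_summary <- function(x, digits = 2, ...) {
  cat("Mean intra-group distances",
      if (!is.null(x$method)) sprintf(" (%s)", x$method), ":\n", sep = "")
  i <- x$intra; i$mean_distance <- round(i$mean_distance, digits)
  print(i, row.names = FALSE)
  cat("Mean inter-group distances:\n")
  j <- x$inter; j$mean_distance <- round(j$mean_distance, digits)
  print(j, row.names = FALSE)
  invisible(x)
}
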