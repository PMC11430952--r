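# Monophyly evaluation on support-annotated trees (trees are consumed,
# never inferred) and threshold-based species delimitation.

#' Support-annotated tree view
#'
#' Wraps a `phylo` tree with parsed edge-support annotations. Compound
#' node labels of the form `"99/1.0"` are split into bootstrap percentage
#' (bp) and posterior probability (pp); single-valued labels are assigned
#' by `label_format` (`"auto"` treats labels entirely within \[0, 1\] as pp,
#' otherwise bp).
#'
#' @param tree `phylo` object, Newick string or file path.
#' @param bp,pp Optional numeric vectors (one per internal node) overriding
#'   label parsing; bp in \[0, 100\], pp in \[0, 1\].
#' @param outgroup Optional outgroup tip label(s); monophyly is then
#'   assessed on the side excluding the outgroup.
#' @param label_format `"auto"`, `"bp/pp"`, `"bp"` or `"pp"`.
#' @return Object of class `tree_view`.
#' @export
tree_view <- function(tree, bp = NULL, pp = NULL, outgroup = NULL,
                      label_format = c("auto", "bp/pp", "bp", "pp")) {
  label_format <- match.arg(label_format)
  phy <- as_phylo(tree)
  if (anyDuplicated(phy$tip.label))
    stop("duplicate tip labels")
  nnode <- phy$Nnode
  if (is.null(bp) && is.null(pp) && !is.null(phy$node.label)) {
    lab <- phy$node.label
    if (label_format == "bp/pp" || (label_format == "auto" && any(grepl("/", lab)))) {
      parts <- strsplit(lab, "/", fixed = TRUE)
      bp <- suppressWarnings(as.numeric(vapply(parts, function(p)
        if (length(p) >= 1L) p[1L] else NA_character_, character(1L))))
      pp <- suppressWarnings(as.numeric(vapply(parts, function(p)
        if (length(p) >= 2L) p[2L] else NA_character_, character(1L))))
    } else {
      vals <- suppressWarnings(as.numeric(lab))
      fmt <- label_format
      if (fmt == "auto")
        fmt <- if (all(is.na(vals) | vals <= 1)) "pp" else "bp"
      if (fmt == "pp") pp <- vals else bp <- vals
    }
  }
  if (!is.null(bp)) {
    if (length(bp) != nnode) stop("bp must have one value per internal node")
    if (any(bp < 0 | bp > 100, na.rm = TRUE)) stop("bp values must lie in [0, 100]")
  }
  if (!is.null(pp)) {
    if (length(pp) != nnode) stop("pp must have one value per internal node")
    if (any(pp < 0 | pp > 1, na.rm = TRUE)) stop("pp values must lie in [0, 1]")
  }
  if (!is.null(outgroup)) {
    missing <- setdiff(outgroup, phy$tip.label)
    if (length(missing))
      stop("outgroup tip(s) not in tree: ", paste(missing, collapse = ", "))
  }
  structure(list(tree = phy, bp = bp, pp = pp, outgroup = outgroup),
            class = "tree_view")
}

#' @export
print.tree_view <- function(x, ...) {
  cat(sprintf("tree view: %d tips, %d internal nodes; bp %s, pp %s%s\n",
              length(x$tree$tip.label), x$tree$Nnode,
              if (is.null(x$bp)) "absent" else "parsed",
              if (is.null(x$pp)) "absent" else "parsed",
              if (is.null(x$outgroup)) "" else
                paste0("; outgroup ", paste(x$outgroup, collapse = ","))))
  invisible(x)
}

# Tip index sets below every node, via one postorder sweep of the edge
# matrix (children are complete before their parent is visited).
clade_tip_sets <- function(phy) {
  ntip <- length(phy$tip.label)
  po <- ape::reorder.phylo(phy, "postorder")
  sets <- vector("list", ntip + phy$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- i
  e <- po$edge
  for (k in seq_len(nrow(e)))
    sets[[e[k, 1L]]] <- c(sets[[e[k, 1L]]], sets[[e[k, 2L]]])
  sets
}

#' Test a tip set for monophyly
#'
#' Unrooted bipartition semantics: the set is monophyletic iff some edge of
#' the tree splits the tips exactly into the set versus its complement.
#' When the view designates an outgroup, the group must lie on the side
#' excluding the outgroup (and a group containing the outgroup is never
#' monophyletic).
#'
#' @param tv A [tree_view()] or `phylo` object.
#' @param tips Character vector of tip labels.
#' @return List with `monophyletic` (logical), `node` (the node subtending
#'   the defining edge, or `NA`) and `side` (`"clade"` or `"complement"`,
#'   describing which side of the defining split equals the tip set).
#' @examples
#' tv <- tree_view("((a,b),(c,d));")
#' is_monophyletic(tv, c("a", "b"))$monophyletic  # TRUE
#' is_monophyletic(tv, c("a", "c"))$monophyletic  # FALSE
#' @export
is_monophyletic <- function(tv, tips) {
  phy <- if (inherits(tv, "tree_view")) tv$tree else as_phylo(tv)
  outgroup <- if (inherits(tv, "tree_view")) tv$outgroup else NULL
  unknown <- setdiff(tips, phy$tip.label)
  if (length(unknown))
    stop("unknown tip ids: ", paste(unknown, collapse = ", "))
  ntip <- length(phy$tip.label)
  idx <- sort(match(unique(tips), phy$tip.label))
  og <- if (is.null(outgroup)) integer(0L) else match(outgroup, phy$tip.label)
  if (length(og) && any(og %in% idx))
    return(list(monophyletic = FALSE, node = NA_integer_, side = NA_character_))
  if (length(idx) == ntip)
    return(list(monophyletic = TRUE, node = ntip + 1L, side = "clade"))
  if (length(idx) == 1L)
    return(list(monophyletic = TRUE, node = idx, side = "clade"))
  comp <- setdiff(seq_len(ntip), idx)
  # pendant edge: the complement of a single tip is always one side of a
  # split (relevant for outgroup-rooted "everything but the outgroup")
  fallback <- if (length(comp) == 1L)
    list(monophyletic = TRUE, node = comp, side = "complement") else NULL
  sets <- clade_tip_sets(phy)
  for (node in seq.int(ntip + 1L, ntip + phy$Nnode)) {
    s <- sort(sets[[node]])
    if (length(s) == length(idx) && all(s == idx))
      return(list(monophyletic = TRUE, node = node, side = "clade"))
    if (is.null(fallback) && length(s) == length(comp) && all(s == comp))
      fallback <- list(monophyletic = TRUE, node = node, side = "complement")
  }
  # a clade-side match is preferred so that reported support belongs to the
  # edge subtending the group itself
  fallback %||% list(monophyletic = FALSE, node = NA_integer_,
                     side = NA_character_)
}

node_support <- function(tv, node) {
  ntip <- length(tv$tree$tip.label)
  i <- node - ntip
  list(bp = if (!is.null(tv$bp) && i >= 1L) tv$bp[i] else NA_real_,
       pp = if (!is.null(tv$pp) && i >= 1L) tv$pp[i] else NA_real_)
}

#' Evaluate monophyly and support of mapped groups
#'
#' One result per group: status (`monophyletic`,
#' `paraphyletic/polyphyletic`, `singleton`), the defining-edge support
#' where monophyletic, and the intruding tips otherwise. A group is "well
#' supported" when monophyletic and the defining edge meets every
#' available support threshold; a support type absent from the tree is
#' ignored with a warning. The group spanning all tips is monophyletic
#' trivially and flagged uninformative.
#'
#' @param tv A [tree_view()].
#' @param groups Named character vector (`tip -> group`) or two-column
#'   data frame.
#' @param bp_min,pp_min Support thresholds (defaults 75 and 0.95, the
#'   customary display cutoffs).
#' @return Data frame with one row per group.
#' @export
evaluate_groups <- function(tv, groups, bp_min = 75, pp_min = 0.95) {
  stopifnot(inherits(tv, "tree_view"))
  groups <- normalize_group_map(groups)
  phy <- tv$tree
  missing <- setdiff(names(groups), phy$tip.label)
  if (length(missing))
    stop("mapped tips not present in tree: ", paste(missing, collapse = ", "))
  labels <- sort(unique(groups))
  if (is.null(tv$bp) && !is.null(tv$pp) || !is.null(tv$bp) && is.null(tv$pp))
    warning("only one support type available; the missing one is ignored")
  ntip <- length(phy$tip.label)
  rows <- lapply(labels, function(lab) {
    tips <- names(groups)[groups == lab]
    if (!length(tips)) stop("group with zero tips in tree: ", lab)
    if (length(tips) == 1L)
      return(data.frame(group = lab, n_tips = 1L, status = "singleton",
                        bp = NA_real_, pp = NA_real_, well_supported = NA,
                        uninformative = FALSE, offending_tips = "",
                        stringsAsFactors = FALSE))
    res <- is_monophyletic(tv, tips)
    if (res$monophyletic) {
      sup <- node_support(tv, res$node)
      checks <- c(if (!is.null(tv$bp)) !is.na(sup$bp) && sup$bp >= bp_min,
                  if (!is.null(tv$pp)) !is.na(sup$pp) && sup$pp >= pp_min)
      data.frame(group = lab, n_tips = length(tips), status = "monophyletic",
                 bp = sup$bp, pp = sup$pp,
                 well_supported = length(checks) > 0 && all(checks),
                 uninformative = length(tips) == ntip, offending_tips = "",
                 stringsAsFactors = FALSE)
    } else {
      mrca <- ape::getMRCA(phy, tips)
      clade <- phy$tip.label[clade_tip_sets(phy)[[mrca]]]
      data.frame(group = lab, n_tips = length(tips),
                 status = "paraphyletic/polyphyletic",
                 bp = NA_real_, pp = NA_real_, well_supported = FALSE,
                 uninformative = FALSE,
                 offending_tips = paste(sort(setdiff(clade, tips)),
                                        collapse = ","),
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Delimit candidate species by distance threshold
#'
#' Single-linkage clustering at a p-distance threshold: two sequences fall
#' in one cluster iff they are connected by a chain of pairwise distances
#' `<= threshold` (the split is strictly greater-than: a pair just above
#' the threshold separates). The default 1.3% is the customary
#' species-level cutoff for this marker. Cluster labels are the
#' lexicographically smallest member id, so output is deterministic and
#' permutation-invariant.
#'
#' @param mat Symmetric p-distance matrix (proportion scale) with id
#'   dimnames.
#' @param threshold Splitting threshold (default 0.013).
#' @param linkage Only `"single"` is implemented.
#' @param force Set `TRUE` to accept a matrix not on the p-distance scale
#'   (e.g. ML distances); by default such matrices are rejected.
#' @return Data frame (`id`, `cluster`), one row per id, sorted by id, with
#'   attribute `threshold`.
#' @examples
#' m <- matrix(c(0, 0.014, 0.014, 0), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
#' attr(m, "method") <- "p"
#' delimit_species(m)  # two clusters
#' @export
delimit_species <- function(mat, threshold = 0.013, linkage = "single",
                            force = FALSE) {
  linkage <- match.arg(linkage, "single")
  ids <- rownames(mat)
  if (is.null(ids)) stop("distance matrix must have id dimnames")
  if (!force) {
    meth <- attr(mat, "method")
    if (identical(meth, "ml"))
      stop("matrix is on the ML (substitutions/site) scale; ",
           "the threshold applies to p-distances (use force = TRUE to override)")
    if (is.null(meth) && any(mat > 1))
      stop("distances exceed 1; not a p-distance matrix (use force = TRUE)")
  }
  n <- length(ids)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (n > 1L) for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    if (mat[i, j] <= threshold) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  comp <- vapply(seq_len(n), find, integer(1L))
  cluster <- vapply(seq_len(n), function(i)
    min(ids[comp == comp[i]]), character(1L))
  out <- data.frame(id = ids, cluster = cluster, stringsAsFactors = FALSE)
  out <- out[order(out$id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  out
}

#' Combined lineage report
#'
#' Joins monophyly/support evaluation with group-level distance
#' summaries: per group the monophyly status, defining-edge support and
#' intra-group mean distance; per group pair the inter-group mean.
#'
#' @param tv A [tree_view()].
#' @param groups Tip-to-group mapping (named vector or data frame).
#' @param mat Distance matrix over the same ids.
#' @param bp_min,pp_min Support thresholds.
#' @return Object of class `lineage_report`: list with data frames
#'   `groups` and `group_pairs`.
#' @export
lineage_report <- function(tv, groups, mat, bp_min = 75, pp_min = 0.95) {
  ev <- evaluate_groups(tv, groups, bp_min, pp_min)
  gs <- group_distance_summary(mat, groups)
  g <- merge(ev, gs$intra[, c("group", "mean_distance")], by = "group",
             all.x = TRUE, sort = TRUE)
  names(g)[names(g) == "mean_distance"] <- "intra_mean_distance"
  g <- g[order(g$group), , drop = FALSE]
  rownames(g) <- NULL
  structure(list(groups = g, group_pairs = gs$inter), class = "lineage_report")
}

#' @export
print.lineage_report <- function(x, ...) {
  cat("Lineage report\n")
  print(x$groups, row.names = FALSE)
  cat("Group pairs:\n")
  print(x$group_pairs, row.names = FALSE)
  invisible(x)
}
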