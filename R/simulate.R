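# Substitution-only sequence simulation under GTR-family models with
# discrete-gamma rate heterogeneity: aligned pairs at a known distance and
# alignments evolved along a tree with known clades. Rates use the same
# category-mean discretization as the likelihood machinery.

evolve_chars <- function(parent, t, rates, cat_idx, eig) {
  child <- parent
  if (t == 0) return(child)
  for (c in seq_along(rates)) {
    P <- transition_probability(eig, t * rates[c])
    for (b in DNA_BASES) {
      idx <- which(cat_idx == c & parent == b)
      if (length(idx))
        child[idx] <- sample(DNA_BASES, length(idx), replace = TRUE,
                             prob = P[b, ])
    }
  }
  child
}

#' Simulate an aligned sequence pair at a known distance
#'
#' Sites are i.i.d.: the ancestral base is drawn from the model's
#' stationary frequencies, each site is assigned one of the discrete-gamma
#' categories uniformly, and the descendant base is drawn from the
#' transition probabilities at `t * rate`. The simulation is
#' substitution-only (no gaps).
#'
#' @param model A [substitution_model()].
#' @param t True distance in expected substitutions per site (>= 0).
#' @param n_sites Number of sites.
#' @param seed Integer seed; identical seeds give identical pairs.
#' @return Object of class `simulated_pair`: list with `seq_a`, `seq_b`,
#'   `true_distance`, `model`, `seed`.
#' @examples
#' p <- simulate_pair(substitution_model("JC", n_categories = 1), 0.1, 1000, 7)
#' @export
simulate_pair <- function(model, t, n_sites, seed = 1L) {
  stopifnot(inherits(model, "substitution_model"))
  assert_scalar_number(t, "t", lower = 0)
  n_sites <- as.integer(n_sites)
  stopifnot(n_sites >= 1L)
  with_seed(seed, {
    pi <- model$base_frequencies
    anc <- sample(DNA_BASES, n_sites, replace = TRUE, prob = pi)
    rates <- model_rates(model)
    cat_idx <- sample.int(length(rates), n_sites, replace = TRUE)
    eig <- model_eigen(model)
    child <- evolve_chars(anc, t, rates, cat_idx, eig)
    structure(list(seq_a = chars_seq(anc), seq_b = chars_seq(child),
                   true_distance = t, model = model, seed = seed),
              class = "simulated_pair")
  })
}

#' Partitioned alignment container
#'
#' @param seqs Named character vector of equal-length aligned sequences
#'   (A/C/G/T, gap `-`, IUPAC ambiguity).
#' @param partitions Data frame with columns `name`, `start`, `end`
#'   (1-based inclusive, non-overlapping, within the alignment width).
#' @param models Optional named list of [substitution_model()]s, one per
#'   partition name.
#' @return Object of class `partitioned_alignment`.
#' @export
partitioned_alignment <- function(seqs, partitions = NULL, models = NULL) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("sequences must be named")
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence ids: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  w <- unique(nchar(seqs))
  if (length(w) != 1L) stop("all rows must have equal length")
  if (is.null(partitions))
    partitions <- data.frame(name = "all", start = 1L, end = w,
                             stringsAsFactors = FALSE)
  stopifnot(all(c("name", "start", "end") %in% names(partitions)))
  partitions$start <- as.integer(partitions$start)
  partitions$end <- as.integer(partitions$end)
  if (anyDuplicated(partitions$name)) stop("duplicate partition names")
  if (any(partitions$start < 1L) || any(partitions$end > w) ||
      any(partitions$end < partitions$start))
    stop("partition ranges must lie within the alignment width")
  o <- order(partitions$start)
  po <- partitions[o, ]
  if (nrow(po) > 1L && any(po$start[-1L] <= po$end[-nrow(po)]))
    stop("partitions overlap")
  if (!is.null(models)) {
    if (is.null(names(models)) || !all(partitions$name %in% names(models)))
      stop("models must be a named list covering every partition")
    lapply(models, function(m) stopifnot(inherits(m, "substitution_model")))
  }
  structure(list(seqs = toupper(seqs), partitions = partitions,
                 models = models, width = w),
            class = "partitioned_alignment")
}

#' @export
print.partitioned_alignment <- function(x, ...) {
  cat(sprintf("partitioned alignment: %d sequences x %d columns\n",
              length(x$seqs), x$width))
  p <- x$partitions
  p$model <- if (is.null(x$models)) NA_character_ else
    vapply(p$name, function(nm) x$models[[nm]]$kind, character(1L))
  print(p, row.names = FALSE)
  invisible(x)
}

as_phylo <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  if (is.character(tree) && length(tree) == 1L) {
    if (file.exists(tree)) return(ape::read.tree(tree))
    return(ape::read.tree(text = tree))
  }
  stop("tree must be a phylo object, a Newick string or a file path")
}

#' Simulate a partitioned alignment along a tree
#'
#' Each partition evolves independently under its own model along the same
#' tree (branch lengths in expected substitutions per site). Per-site rate
#' categories are drawn once per site and shared across the whole tree, as
#' in standard discrete-gamma models. The output is gap-free and the
#' partition columns are contiguous in the declared order.
#'
#' @param tree A `phylo` object, Newick string or file path; must have
#'   branch lengths and unique non-empty tip labels.
#' @param partitions List of partitions, each a list with `name`, `length`
#'   (nt) and `model` (a [substitution_model()]).
#' @param seed Integer seed.
#' @return List with `alignment` (a [partitioned_alignment()]) and `tree`
#'   (the `phylo` used, i.e. the truth tree).
#' @examples
#' tr <- ape::read.tree(text = "((a:0.1,b:0.1):0.2,(c:0.1,d:0.1):0.2);")
#' sim <- simulate_alignment_on_tree(tr,
#'   list(list(name = "ITS1", length = 200,
#'             model = substitution_model("JC", n_categories = 1))), seed = 1)
#' @export
simulate_alignment_on_tree <- function(tree, partitions, seed = 1L) {
  phy <- as_phylo(tree)
  if (is.null(phy$edge.length)) stop("tree must have branch lengths")
  tips <- phy$tip.label
  if (any(is.na(tips)) || any(!nzchar(tips)))
    stop("tree tips must be named")
  if (anyDuplicated(tips))
    stop("duplicate tip labels: ",
         paste(unique(tips[duplicated(tips)]), collapse = ", "))
  stopifnot(is.list(partitions), length(partitions) >= 1L)
  lens <- vapply(partitions, function(p) as.integer(p$length), integer(1L))
  if (any(lens < 1L)) stop("partition lengths must be > 0")

  ntip <- length(tips)
  po <- ape::reorder.phylo(phy, "postorder")
  edge <- po$edge
  elen <- po$edge.length
  root <- ntip + 1L

  blocks <- with_seed(seed, lapply(partitions, function(p) {
    model <- p$model
    stopifnot(inherits(model, "substitution_model"))
    n_sites <- as.integer(p$length)
    rates <- model_rates(model)
    cat_idx <- sample.int(length(rates), n_sites, replace = TRUE)
    eig <- model_eigen(model)
    node_seq <- vector("list", ntip + phy$Nnode)
    node_seq[[root]] <- sample(DNA_BASES, n_sites, replace = TRUE,
                               prob = model$base_frequencies)
    for (k in rev(seq_len(nrow(edge)))) {
      par <- edge[k, 1L]; ch <- edge[k, 2L]
      node_seq[[ch]] <- evolve_chars(node_seq[[par]], elen[k], rates,
                                     cat_idx, eig)
    }
    vapply(seq_len(ntip), function(i) chars_seq(node_seq[[i]]), character(1L))
  }))

  seqs <- do.call(paste0, blocks)
  names(seqs) <- tips
  ends <- cumsum(lens)
  parts <- data.frame(name = vapply(partitions, `[[`, character(1L), "name"),
                      start = c(1L, utils::head(ends, -1L) + 1L),
                      end = ends, stringsAsFactors = FALSE)
  models <- stats::setNames(lapply(partitions, `[[`, "model"), parts$name)
  list(alignment = partitioned_alignment(seqs, parts, models), tree = phy)
}
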