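# Monophyly evaluation, support parsing, species delimitation and the
# combined lineage report.

test_that("monophyly agrees with worked examples", {
  tv <- tree_view("((a,b),(c,d));")
  expect_true(is_monophyletic(tv, c("a", "b"))$monophyletic)
  expect_false(is_monophyletic(tree_view("((a,c),(b,d));"),
                               c("a", "b"))$monophyletic)
  expect_error(is_monophyletic(tv, c("a", "zz")), "unknown tip")
})

test_that("monophyly agrees with the bipartition oracle on random trees", {
  set.seed(21)
  for (rep in 1:20) {
    phy <- ape::rtree(8)
    tv <- tree_view(phy)
    for (k in 2:4) {
      subsets <- utils::combn(phy$tip.label, k)
      for (j in seq_len(ncol(subsets))) {
        tips <- subsets[, j]
        expect_identical(is_monophyletic(tv, tips)$monophyletic,
                         oracle_monophyletic(phy, tips),
                         info = paste(rep, paste(tips, collapse = ",")))
      }
    }
  }
})

test_that("monophyly status is invariant under re-rooting", {
  set.seed(33)
  for (rep in 1:5) {
    phy <- ape::rtree(8)
    groups <- list(phy$tip.label[1:3], phy$tip.label[c(2, 5)],
                   phy$tip.label[4:7])
    base <- lapply(groups, function(g) is_monophyletic(phy, g)$monophyletic)
    for (root_tip in phy$tip.label[c(1, 4, 8)]) {
      re <- ape::root(phy, outgroup = root_tip, resolve.root = TRUE)
      for (i in seq_along(groups))
        expect_identical(is_monophyletic(re, groups[[i]])$monophyletic,
                         base[[i]])
    }
  }
})

test_that("group evaluation reports status, support and offenders", {
  tv <- read_newick(text = "(((a:1,b:1)100/1.0:1,(c:1,d:1)74/0.99:1)90/1.0:1,(e:1,f:1)99/0.2:1);")
  map <- c(a = "AB", b = "AB", c = "CD", d = "CD", e = "EF", f = "EF")
  ev <- evaluate_groups(tv, map)
  expect_equal(ev$status, rep("monophyletic", 3))
  expect_equal(ev$bp[ev$group == "AB"], 100)
  expect_true(ev$well_supported[ev$group == "AB"])
  expect_false(ev$well_supported[ev$group == "CD"])   # bp 74 < 75
  expect_false(ev$well_supported[ev$group == "EF"])   # pp 0.2 < 0.95

  # split group lists intruding tips
  ev2 <- evaluate_groups(tv, c(a = "X", c = "X", b = "Y", d = "Y",
                               e = "Z", f = "Z"))
  bad <- ev2[ev2$group == "X", ]
  expect_identical(bad$status, "paraphyletic/polyphyletic")
  expect_match(bad$offending_tips, "b")

  # all-tips group is trivially monophyletic but uninformative
  ev3 <- evaluate_groups(tv, stats::setNames(rep("ALL", 6), letters[1:6]))
  expect_identical(ev3$status, "monophyletic")
  expect_true(ev3$uninformative)

  ev4 <- evaluate_groups(tv, c(a = "S", b = "AB2", c = "AB2", d = "AB2",
                               e = "E", f = "F"))
  expect_identical(ev4$status[ev4$group == "S"], "singleton")
  expect_error(evaluate_groups(tv, c(zz = "Q")), "not present")
})

test_that("outgroup-aware monophyly excludes the outgroup side", {
  tv <- tree_view("((a,b),(c,(d,e)));", outgroup = "a")
  expect_true(is_monophyletic(tv, c("d", "e"))$monophyletic)
  expect_false(is_monophyletic(tv, c("a", "b"))$monophyletic)  # contains outgroup
  # b+c+d+e is the complement of the outgroup-containing side
  expect_true(is_monophyletic(tv, c("b", "c", "d", "e"))$monophyletic)
})

test_that("species delimitation follows the threshold semantics", {
  ids <- c("u", "v")
  m <- matrix(c(0, 0.014, 0.014, 0), 2, 2, dimnames = list(ids, ids))
  attr(m, "method") <- "p"
  expect_equal(length(unique(delimit_species(m)$cluster)), 2L)  # just above 1.3%
  m2 <- m; m2[1, 2] <- m2[2, 1] <- 0
  expect_equal(length(unique(delimit_species(m2)$cluster)), 1L)
  m3 <- m; m3[1, 2] <- m3[2, 1] <- 0.013
  expect_equal(length(unique(delimit_species(m3)$cluster)), 1L)  # <= stays together

  mlm <- m; attr(mlm, "method") <- "ml"
  expect_error(delimit_species(mlm), "ML")
  expect_silent(delimit_species(mlm, force = TRUE))
})

test_that("delimitation equals the graph-component oracle and is permutation-invariant", {
  set.seed(55)
  for (rep in 1:20) {
    m <- random_symmetric_pmat(20, max_d = 0.04)
    got <- delimit_species(m, threshold = 0.013)
    want <- oracle_threshold_components(m, 0.013)
    names(want) <- rownames(m)
    expect_identical(got$cluster, unname(want[got$id]))

    perm <- sample(nrow(m))
    mp <- m[perm, perm]
    attr(mp, "method") <- "p"
    got_p <- delimit_species(mp, threshold = 0.013)
    expect_identical(got_p, got, ignore_attr = TRUE)
  }
})

test_that("cluster count is monotone non-increasing in the threshold", {
  set.seed(77)
  m <- random_symmetric_pmat(15, max_d = 0.03)
  counts <- vapply(c(0, 0.005, 0.01, 0.013, 0.02, 0.05), function(th)
    length(unique(delimit_species(m, threshold = th)$cluster)), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("the lineage report combines monophyly and distances deterministically", {
  # eleven groups, each a true clade of two tips
  clades <- paste0("(", sprintf("t%02da:0.01,t%02db:0.01", 1:11, 1:11), ")")
  nwk <- paste0("(", paste(vapply(seq_along(clades), function(i)
    paste0(clades[i], ":", 0.1 + 0.01 * i), character(1)), collapse = ","), ");")
  tv <- read_newick(text = nwk)
  tips <- tv$tree$tip.label
  groups <- stats::setNames(sub("[ab]$", "", tips), tips)
  d <- ape::cophenetic.phylo(tv$tree) / 10
  attr(d, "method") <- "p"
  rep1 <- lineage_report(tv, groups, d)
  expect_equal(nrow(rep1$groups), 11L)
  expect_true(all(rep1$groups$status == "monophyletic"))
  expect_equal(nrow(rep1$group_pairs), choose(11, 2))

  # invariance to tip input order
  perm <- sample(length(tips))
  rep2 <- lineage_report(tv, groups[perm], d)
  expect_identical(rep1$groups, rep2$groups)
})
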