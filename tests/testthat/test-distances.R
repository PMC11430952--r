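# p-distances, pairwise likelihoods, ML distances, model estimation and
# group summaries.

test_that("p-distance matches worked examples and excludes non-comparable sites", {
  expect_equal(as.numeric(p_distance("ACGT", "ACGA")), 0.25)
  d <- p_distance("AC-T", "ACGT")
  expect_equal(as.numeric(d), 0)
  expect_equal(attr(d, "n_compared"), 3L)
  expect_error(p_distance("----", "ACGT"), "comparable")
  expect_error(p_distance("ACG", "ACGT"), "equal length")
})

test_that("p-distance equals the per-site loop oracle on random pairs", {
  set.seed(11)
  alphabet <- c("A", "C", "G", "T", "-", "N")
  for (i in 1:200) {
    a <- paste(sample(alphabet, 200, TRUE, prob = c(rep(0.23, 4), 0.05, 0.03)),
               collapse = "")
    b <- paste(sample(alphabet, 200, TRUE, prob = c(rep(0.23, 4), 0.05, 0.03)),
               collapse = "")
    expect_equal(as.numeric(p_distance(a, b)), naive_p_distance(a, b))
  }
})

test_that("pair log-likelihood is additive over partitions and peaks at 0 for identical data", {
  jc <- substitution_model("JC", n_categories = 1)
  counts <- matrix(0, 4, 4, dimnames = list(c("A","C","G","T"), c("A","C","G","T")))
  diag(counts) <- c(30, 20, 25, 25)
  l0 <- pair_loglik(counts, 0, jc)
  for (t in c(0.01, 0.1, 1)) expect_lt(pair_loglik(counts, t, jc), l0)
  expect_equal(l0, sum(diag(counts) * log(0.25)), tolerance = 1e-9)

  counts2 <- counts; counts2["A", "G"] <- 7; counts2["C", "T"] <- 3
  both <- pair_loglik(list(counts, counts2), 0.2, list(jc, jc))
  expect_equal(both,
               pair_loglik(counts, 0.2, jc) + pair_loglik(counts2, 0.2, jc),
               tolerance = 1e-10)
  expect_error(pair_loglik(matrix(0, 4, 4), 0.1, jc), "zero")
})

test_that("pair log-likelihood matches the closed-form JC pair likelihood", {
  jc <- substitution_model("JC", n_categories = 1)
  counts <- matrix(2, 4, 4); diag(counts) <- c(100, 110, 95, 105)
  n_same <- sum(diag(counts)); n_diff <- sum(counts) - n_same
  for (t in c(0.01, 0.1, 0.5, 2)) {
    # closed form assumes differences spread evenly; rescale the off-diagonal
    expect_equal(pair_loglik(counts, t, jc),
                 jc_pair_loglik(n_same, n_diff, t), tolerance = 1e-8)
  }
})

test_that("ML distance reduces to the JC closed form and hits the bounds", {
  jc <- substitution_model("JC", n_categories = 1)
  same <- strrep("ACGT", 50)
  expect_equal(as.numeric(ml_distance(same, same, jc)), 1e-6)

  # pair with exactly p = 941/10000 differences
  n <- 10000; ndiff <- 941
  a <- paste(rep(c("A", "C", "G", "T"), length.out = n), collapse = "")
  b_chars <- strsplit(a, "")[[1]]
  flip <- seq_len(ndiff)
  b_chars[flip] <- c(G = "A", A = "G", T = "C", C = "T")[b_chars[flip]]
  b <- paste(b_chars, collapse = "")
  t_hat <- ml_distance(a, b, jc)
  expect_equal(as.numeric(t_hat), jc_closed_form_t(ndiff / n), tolerance = 1e-6)

  # saturation is flagged, not silently truncated
  sat <- ml_distance(strrep("A", 300), strrep("C", 300), jc)
  expect_true(attr(sat, "saturated"))
  expect_equal(as.numeric(sat), 10)
})

test_that("JC ML distance is monotone in the observed p-distance", {
  jc <- substitution_model("JC", n_categories = 1)
  n <- 2000
  base <- strsplit(strrep("ACGT", n / 4), "")[[1]]
  prev <- -1
  for (ndiff in c(0, 50, 200, 500, 900)) {
    b <- base
    if (ndiff > 0) b[seq_len(ndiff)] <- c(A = "C", C = "A", G = "T", T = "G")[b[seq_len(ndiff)]]
    t_hat <- as.numeric(ml_distance(paste(base, collapse = ""),
                                    paste(b, collapse = ""), jc))
    expect_gt(t_hat, prev)
    prev <- t_hat
  }
})

test_that("ML distance recovers the simulating distance under TVM+F+G4", {
  tvm <- substitution_model("TVM",
    exchangeabilities = c(AC = 1.3, AG = 3.5, AT = 0.6, CG = 0.9, CT = 3.5, GT = 1),
    base_frequencies = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3),
    gamma_shape = 0.8)
  p <- simulate_pair(tvm, 0.5, 50000, seed = 71)
  t_hat <- as.numeric(ml_distance(p$seq_a, p$seq_b, tvm))
  expect_lt(abs(t_hat - 0.5), 0.03)
})

test_that("distance matrices are symmetric with zero diagonal under both methods", {
  sim <- small_study_alignment(seed = 5)
  aln <- sim$alignment
  pm <- p_distance_matrix(aln)
  mm <- ml_distance_matrix(aln)
  for (m in list(pm, mm)) {
    expect_equal(m, t(m), ignore_attr = TRUE)
    expect_equal(unname(diag(m)), rep(0, nrow(m)))
    expect_true(all(m >= 0))
  }
  expect_true(all(pm <= 1))
  expect_identical(attr(pm, "method"), "p")
  expect_identical(attr(mm, "method"), "ml")
})

test_that("complete-set deletion removes columns with any gap or ambiguity", {
  seqs <- c(a = "ACGTAC", b = "AC-TAC", c = "ACGTNC")
  pm <- p_distance_matrix(seqs, deletion = "complete-set")
  # columns 3 and 5 drop for every pair
  expect_equal(pm["a", "b"], 0)
  expect_equal(pm["a", "c"], 0)
})

test_that("+F frequencies equal hand-counted proportions and uniform data give 0.25", {
  seqs <- c(x = "AACCGGTTAACC", y = "AACCGGTTGGTT", z = "AACCGGTTACGT")
  fit <- estimate_model_params(seqs, kind = "TVM", n_categories = 1)
  pooled <- table(factor(strsplit(paste(seqs, collapse = ""), "")[[1]],
                         c("A", "C", "G", "T")))
  expect_equal(unname(fit$base_frequencies),
               as.numeric(pooled) / sum(pooled), tolerance = 1e-12)

  set.seed(3)
  unif <- vapply(1:4, function(i)
    paste(sample(c("A", "C", "G", "T"), 4000, TRUE), collapse = ""),
    character(1))
  names(unif) <- paste0("u", 1:4)
  fit2 <- estimate_model_params(unif, kind = "TVM", n_categories = 1)
  expect_equal(unname(fit2$base_frequencies), rep(0.25, 4), tolerance = 0.02)
})

test_that("degenerate partitions fall back to JC defaults with a warning", {
  seqs <- c(a = "ACGTACGT", b = "ACGTACGT", c = "ACGTACGT")
  expect_warning(fit <- estimate_model_params(seqs), "degenerate")
  expect_identical(fit$kind, "JC")
})

test_that("SYM+G4 simulation recovers the gamma shape", {
  tr <- ape::read.tree(
    text = "(((s1:0.08,s2:0.08):0.15,(s3:0.08,s4:0.08):0.15):0.1,(s5:0.08,s6:0.08):0.25);")
  sym <- substitution_model("SYM",
    exchangeabilities = c(AC = 1.5, AG = 4, AT = 0.7, CG = 1.1, CT = 5, GT = 1),
    gamma_shape = 0.8)
  sim <- simulate_alignment_on_tree(tr, list(list(name = "p1", length = 20000,
                                                  model = sym)), seed = 99)
  fit <- estimate_model_params(sim$alignment, "p1", kind = "SYM")
  expect_gt(fit$gamma_shape, 0.6)
  expect_lt(fit$gamma_shape, 1.0)
})

test_that("group distance summaries average the right pairs and keep orderings", {
  ids <- c("a1", "a2", "b1", "b2")
  m <- matrix(0.1, 4, 4, dimnames = list(ids, ids)); diag(m) <- 0
  gs <- group_distance_summary(m, c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"))
  expect_equal(gs$intra$mean_distance, c(0.1, 0.1))
  expect_equal(gs$inter$mean_distance, 0.1)

  ids2 <- c("g1", "g2", "g3")
  m2 <- matrix(0, 3, 3, dimnames = list(ids2, ids2))
  m2["g1", "g2"] <- m2["g2", "g1"] <- 0.08
  m2["g1", "g3"] <- m2["g3", "g1"] <- 0.10
  m2["g2", "g3"] <- m2["g3", "g2"] <- 0.06
  gs2 <- group_distance_summary(m2, c(g1 = "G", g2 = "G", g3 = "G"))
  expect_equal(gs2$intra$mean_distance, 0.08)

  # inter > intra structure is preserved by the summary
  ids3 <- c("x1", "x2", "y1", "y2")
  m3 <- matrix(0.3, 4, 4, dimnames = list(ids3, ids3))
  m3[1:2, 1:2] <- 0.02; m3[3:4, 3:4] <- 0.03; diag(m3) <- 0
  gs3 <- group_distance_summary(m3, c(x1 = "X", x2 = "X", y1 = "Y", y2 = "Y"))
  expect_true(all(gs3$inter$mean_distance > max(gs3$intra$mean_distance)))

  expect_error(group_distance_summary(m, c(a1 = "A", a2 = "A", b1 = "B")),
               "unmapped.*b2")
})
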