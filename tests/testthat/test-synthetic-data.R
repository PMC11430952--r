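# The generator: reference records with exact truth, motif mutations with
# expected QC findings, pair and tree simulation.

test_that("reference records have the declared geometry and motifs", {
  ref <- make_reference_its(its_template(its1_len = 343, its2_len = 289, seed = 3))
  r <- ref$truth$regions
  expect_equal(r$length, c(343L, 157L, 289L))
  expect_equal(ref$truth$total_trimmed_length, 789L)
  expect_equal(substr(r$first7[2], 1, 6), "CAACTC")
  expect_equal(r$last7[2], "GTCGGCT")
  seq <- ref$record
  f18 <- ref$template$flank18_len
  expect_equal(substr(seq, f18 - 6, f18), "ATCATTA")
  expect_equal(substr(seq, r$end[3] + 1, r$end[3] + 7), "CCTGACC")

  # a geometry mirroring a published 345/157/332 diagnosis
  ref2 <- make_reference_its(its_template(its1_len = 345, its2_len = 332, seed = 4))
  expect_equal(ref2$truth$total_trimmed_length, 834L)
})

test_that("generation is deterministic in the seed and coordinates do not depend on it", {
  t1 <- its_template(seed = 11)
  a <- make_reference_its(t1)
  b <- make_reference_its(t1)
  expect_identical(a$record, b$record)
  c <- make_reference_its(its_template(seed = 12))
  expect_identical(a$truth$regions$start, c$truth$regions$start)
  expect_false(identical(a$record, c$record))
})

test_that("templates that cannot carry boundary heptamers are rejected", {
  expect_error(its_template(its1_len = 5), ">= 7")
  expect_error(its_template(its2_len = 3), ">= 7")
  expect_error(its_template(flank18_len = 4), "flank")
})

test_that("motif mutations report the expected QC findings", {
  ref <- default_reference(7)
  mut <- apply_mutations(ref, list(mutation_spec("M58S_5p", "transition", 6)))
  expect_true(any(grepl("motif_variant_transition", mut$expected_flags)))
  s58 <- ref$truth$motifs$M58S_5p$start
  expect_equal(substr(mut$record, s58, s58 + 5), "CAACTT")

  ins <- apply_mutations(ref, list(mutation_spec("M58S_5p", "insertion", count = 1)))
  expect_equal(unname(ins$expected_lengths["5.8S"]), 158L)
  expect_true("fivepointeight_length_deviation(+1)" %in% ins$expected_flags)

  id <- apply_mutations(ref, list())
  expect_identical(id$record, ref$record)
  expect_length(id$expected_flags, 0)
  expect_identical(id$expected_disposition, "pass")

  expect_error(apply_mutations(ref, list(
    mutation_spec("M58S_5p", "insertion", count = 1),
    mutation_spec("M58S_5p", "deletion", count = 1))), "overlapping")
})

test_that("simulated pairs honour the distance and the seed", {
  jc <- substitution_model("JC", n_categories = 1)
  p0 <- simulate_pair(jc, 0, 500, seed = 5)
  expect_identical(p0$seq_a, p0$seq_b)

  p <- simulate_pair(jc, 0.1, 100000, seed = 6)
  obs <- as.numeric(p_distance(p$seq_a, p$seq_b))
  expected <- 0.75 * (1 - exp(-4 * 0.1 / 3))     # 0.0941
  sd3 <- 3 * sqrt(expected * (1 - expected) / 100000)
  expect_lt(abs(obs - expected), sd3)

  p2 <- simulate_pair(jc, 0.1, 100000, seed = 6)
  expect_identical(p$seq_b, p2$seq_b)
})

test_that("tree simulation respects partitions, clades and degenerate trees", {
  star <- ape::read.tree(text = "(a:0,b:0,c:0,d:0);")
  sim0 <- simulate_alignment_on_tree(star, list(
    list(name = "x", length = 100,
         model = substitution_model("JC", n_categories = 1))), seed = 2)
  expect_length(unique(sim0$alignment$seqs), 1L)

  sim <- simulate_alignment_on_tree(
    "((a:0.02,b:0.02):0.5,(c:0.02,d:0.02):0.5);",
    list(list(name = "ITS1", length = 826,
              model = substitution_model("TVM", gamma_shape = 1)),
         list(name = "5.8S", length = 160,
              model = substitution_model("SYM", gamma_shape = 1))), seed = 3)
  expect_equal(sim$alignment$width, 986L)
  expect_equal(sim$alignment$partitions$end, c(826L, 986L))
  ev <- evaluate_groups(tree_view(sim$tree),
                        c(a = "G1", b = "G1", c = "G2", d = "G2"))
  expect_true(all(ev$status == "monophyletic"))

  bad <- ape::read.tree(text = "((a:1,a:1):1,b:2);")
  expect_error(simulate_alignment_on_tree(bad, list(
    list(name = "x", length = 10,
         model = substitution_model("JC"))), seed = 1), "duplicate")
})

test_that("generator truth round-trips through the annotator exactly", {
  for (seed in c(1, 2, 3)) {
    ref <- make_reference_its(its_template(
      its1_len = 300 + 20 * seed, its2_len = 250 + 30 * seed, seed = seed))
    ann <- annotate_its(ref$record, "rt")
    expect_identical(ann$annotation$regions$start, ref$truth$regions$start)
    expect_identical(ann$annotation$regions$end, ref$truth$regions$end)
    expect_identical(ann$annotation$regions$first7, ref$truth$regions$first7)
    expect_identical(ann$qc$disposition, "pass")
  }
})
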