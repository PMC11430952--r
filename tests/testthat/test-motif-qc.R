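# Mismatch classification, motif search, annotation, diagnosis strings
# and batch QC.

test_that("mismatch classification matches the purine/pyrimidine table on all 16 pairs", {
  bases <- c("A", "C", "G", "T")
  purine <- c("A", "G")
  tally <- c(identity = 0, transition = 0, transversion = 0)
  for (a in bases) for (b in bases) {
    got <- classify_mismatch(a, b)
    want <- if (a == b) "identity"
    else if ((a %in% purine) == (b %in% purine)) "transition"
    else "transversion"
    expect_identical(got, want)
    tally[got] <- tally[got] + 1
  }
  expect_equal(unname(tally), c(4, 4, 8))
  expect_identical(classify_mismatch("C", "T"), "transition")
  expect_identical(classify_mismatch("T", "A"), "transversion")
  expect_error(classify_mismatch("N", "A"), "unambiguous")
})

test_that("motif search tolerates one substitution and reports its class", {
  # outgroup-style 18S end with a C/T transition at motif position 5
  seq <- paste0("GGCGGTGGATCACTA", strrep("T", 30))
  hit <- find_motif(seq, "M18S", window = NULL)
  expect_equal(hit$n_mismatches, 1L)
  expect_equal(hit$mismatches[[1]]$position_in_motif, 5L)
  expect_identical(hit$mismatches[[1]]$class, "transition")

  exact <- find_motif(paste0("GGGG", "ATCATTA", "CCCC"), "M18S", window = NULL)
  expect_equal(exact$n_mismatches, 0L)
  expect_equal(exact$start, 5L)

  # two substitutions exceed the tolerance
  expect_null(find_motif(paste0("GGGG", "TTCATTG", "CCCC"), "M18S", window = NULL))
})

test_that("motif search is position-equivariant", {
  ref <- default_reference(31)
  base_hit <- find_motif(ref$record, "M18S", window = NULL)
  for (k in c(3L, 17L)) {
    shifted <- paste0(strrep("G", k), ref$record)
    hit <- find_motif(shifted, "M18S", window = NULL)
    expect_equal(hit$start, base_hit$start + k)
  }
})

test_that("annotation reproduces known geometries and flags deviations", {
  ref <- make_reference_its(its_template(its1_len = 345, its2_len = 332, seed = 13))
  ann <- annotate_its(ref$record, "g")
  expect_equal(ann$annotation$regions$length, c(345L, 157L, 332L))
  expect_equal(ann$annotation$total_trimmed_length, 834L)

  ins <- apply_mutations(ref, list(mutation_spec("M58S_3p", "insertion", count = 1)))
  ann2 <- annotate_its(ins$record, "i")
  expect_equal(ann2$annotation$regions$length[2], 158L)
  expect_true("fivepointeight_length_deviation(+1)" %in% ann2$qc$flags)
  expect_identical(ann2$qc$disposition, "pass_with_warnings")

  tr <- apply_mutations(ref, list(mutation_spec("M18S", "truncate_5p", count = 0)))
  ann3 <- annotate_its(tr$record, "t")
  expect_identical(ann3$annotation$regions$completeness[1], "incomplete")
  expect_identical(ann3$qc$disposition, "review")
  expect_error(annotate_its("", "x"), "empty")
})

test_that("diagnosis strings have the published format and round-trip the truth", {
  ref <- make_reference_its(
    its_template(its1_len = 359, its2_len = 322, seed = 17),
    heptamers = list(its1_first7 = "TGTATTT", its1_last7 = "ATATGTA",
                     fives_first7 = "CAACTCC",
                     its2_first7 = "TTTACCT", its2_last7 = "ATTACTT"))
  d <- diagnose(ref$truth, "SYN1")
  expect_match(d, "^ITS rDNA \\(SYN1\\) 838 bp: ", fixed = FALSE)
  expect_match(d, "ITS1 complete TGTATTT to ATATGTA 359 bp", fixed = TRUE)
  expect_match(d, "5.8S complete CAACTCC to GTCGGCT 157 bp", fixed = TRUE)
  expect_match(d, "ITS2 complete TTTACCT to ATTACTT 322 bp", fixed = TRUE)

  # a parser extracting the lengths recovers the truth
  lens <- as.integer(regmatches(d, gregexpr("[0-9]+(?= bp)", d, perl = TRUE))[[1]])
  expect_equal(lens, c(838L, 359L, 157L, 322L))

  # arithmetic identity of a 367/157/384 record
  ref2 <- make_reference_its(its_template(its1_len = 367, its2_len = 384, seed = 18))
  expect_equal(ref2$truth$total_trimmed_length, 908L)
  expect_match(diagnose(ref2$truth, "SYN2"), "908 bp:", fixed = TRUE)
})

test_that("diagnose logs a discrepancy with an externally reported total", {
  ref <- make_reference_its(its_template(its1_len = 343, its2_len = 289, seed = 19))
  expect_message(diagnose(ref$truth, "SYN3", reported_total = 788),
                 "789 bp but reported total is 788")
  expect_silent(d <- diagnose(ref$truth, "SYN3", reported_total = 789))
  expect_match(d, "789 bp:", fixed = TRUE)
})

test_that("batch QC summarizes extremes and isolates bad records", {
  refs <- list(
    a = make_reference_its(its_template(its1_len = 297, its2_len = 297, seed = 21)),
    b = make_reference_its(its_template(its1_len = 345, its2_len = 332, seed = 22)),
    c = make_reference_its(its_template(its1_len = 500, its2_len = 438, seed = 23)))
  records <- vapply(refs, `[[`, character(1), "record")
  bad <- apply_mutations(refs$b, list(mutation_spec("M18S", "transition", 2),
                                      mutation_spec("M18S", "transversion", 5)))
  records <- c(records, d = bad$record)

  batch <- batch_qc(records)
  expect_equal(nrow(batch$table), 4L)
  expect_equal(batch$shortest$total, 751L)
  expect_equal(batch$longest$total, 1095L)
  expect_identical(batch$table$disposition[batch$table$id == "d"], "review")
  expect_identical(batch$table$disposition[batch$table$id == "a"], "pass")
  expect_true(all(batch$table$disposition[batch$table$id %in% c("b", "c")] == "pass"))
})

test_that("region lengths are consistent for every fully motif-anchored record", {
  set.seed(99)
  for (i in 1:5) {
    ref <- make_reference_its(its_template(
      its1_len = sample(250:450, 1), its2_len = sample(250:450, 1),
      seed = 1000 + i))
    ann <- annotate_its(ref$record, "p")
    r <- ann$annotation$regions
    expect_true(all(r$length >= 0))
    expect_equal(sum(r$length), ann$annotation$total_trimmed_length)
    expect_equal(r$length[2], 157L)
  }
})
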