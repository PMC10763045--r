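test_that("default parameters carry the documented values", {
  p <- default_parameters()
  expect_equal(p$edge_clip_window, 25L)
  expect_equal(p$min_clip_reads, 3L)
  expect_equal(p$clip_support_pct, 75)
  expect_equal(p$realign_edge_mult, 2L)
  expect_equal(p$min_orphan_reads, 3L)
  expect_equal(p$max_orphan_clip_pct, 25)
  expect_equal(p$min_orphan_extension_pct, 50)
  expect_equal(p$n_join, 5L)
  expect_equal(p$seed_len, 25L)
  expect_equal(p$seed_identity_pct, 100)
  expect_equal(p$extend_identity_pct, 90)
  expect_equal(p$max_gaps, 0L)
  expect_equal(p$min_island_reads, 5L)
  expect_equal(p$min_island_overlap, 10L)
  expect_equal(p$island_overlap_score, 90)
  expect_equal(p$island_edge_slack_pct, 5)
  expect_equal(p$min_internal_consensus, 10L)
  expect_equal(p$internal_identity_pct, 90)
  expect_equal(p$min_new_contig_len, 200L)
  expect_equal(p$abrupt_cov_pct, 80)
  expect_equal(p$gradual_window, 100L)
  expect_equal(p$gradual_cov_pct, 80)
  expect_equal(p$min_mapq, 20L)
  expect_equal(p$redundancy_identity, 0.95)
  expect_equal(p$inner_max, 30L)
  expect_equal(p$outer_max, 100L)
  expect_equal(p$error_threshold, 0L)
  expect_false(p$gradual_check)
  expect_true(p$dedup_check)
})

test_that("invalid parameters are rejected at construction", {
  expect_error(default_parameters(clip_support_pct = 140), "percentage")
  expect_error(default_parameters(abrupt_cov_pct = -5), "percentage")
  expect_error(default_parameters(min_clip_reads = -1), "count")
  expect_error(default_parameters(inner_max = 2.5), "count")
  expect_error(default_parameters(redundancy_identity = 1.5), "fraction")
  expect_error(default_parameters(nonsense_knob = 1), "unknown")
})

test_that("assembly construction enforces its invariants", {
  expect_silent(new_assembly(c(a = "ACGT", b = "GGNRY")))
  expect_error(new_assembly(c(a = "ACGT", a = "GG")), "duplicate")
  expect_error(new_assembly(c(a = "")), "empty")
  expect_error(new_assembly(c(a = "ACXGT")), "non-IUPAC")
  expect_error(new_assembly(stats::setNames("ACGT", "")), "id")
  asm <- new_assembly(c(x = "acgt"))
  expect_equal(asm$seq[["x"]], "ACGT")   # uppercased
})

test_that("IUPAC-aware sequence comparison treats codes as base sets", {
  expect_true(roast:::cpp_iupac_eq("ACGT", "ACGT"))
  expect_true(roast:::cpp_iupac_eq("AMGT", "ACGT"))   # M = A|C covers C
  expect_false(roast:::cpp_iupac_eq("AKGT", "ACGT"))  # K = G|T misses C
  expect_false(roast:::cpp_iupac_eq("ACG", "ACGT"))
  expect_equal(roast:::cpp_revcomp("ACGTM"), "KACGT") # comp(M)=K, reversed
})
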