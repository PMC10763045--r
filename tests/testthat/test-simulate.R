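test_that("supertranscriptome generation is deterministic and in-range", {
  asm <- generate_supertranscriptome(30, c(800L, 1600L), seed = 7)
  expect_length(asm, 30)
  lens <- nchar(asm$seq)
  expect_true(all(lens >= 800 & lens <= 1600))
  asm2 <- generate_supertranscriptome(30, c(800L, 1600L), seed = 7)
  expect_identical(asm$seq, asm2$seq)
  expect_error(generate_supertranscriptome(5, c(200L, 400L)), "500")
  # mutual dissimilarity: no long high-identity cross-contig overlap
  hits <- roast:::find_local_overlap_multi(unname(asm$seq), asm$seq,
                                           default_parameters())
  hits$query <- names(asm$seq)[hits$query]
  cross <- hits[hits$subject_id != hits$query]
  expect_true(all(cross$length < 0.5 * 800 | cross$identity_pct < 95))
})

test_that("error injection honors the documented size rules", {
  asm <- generate_supertranscriptome(40, c(1000L, 3000L), seed = 9)
  inj <- inject_errors(asm, c(incomplete = 3L, fragmented = 3L, chimera = 3L,
                              missing_seq = 3L, unsupported_insertion = 3L,
                              translocation = 3L, inversion = 3L),
                       read_len = 100L, seed = 10)
  tr <- inj$truth
  expect_equal(nrow(tr), 21L)
  # 3 chimeras: -2 contigs +1 each; 3 fragmentations: -1 +2 each -> net 40
  expect_equal(length(inj$assembly$seq), 40L)
  for (i in which(tr$type == "incomplete")) {
    n <- nchar(tr$orig_seq[i])
    dtot <- tr$pos[i] + tr$pos2[i]
    expect_gte(dtot / n, 0.09)
    expect_lte(dtot / n, 0.31)
    err_len <- nchar(inj$assembly$seq[[tr$err_id[i]]])
    expect_equal(err_len, n - dtot)
  }
  for (i in which(tr$type == "fragmented")) {
    ids <- strsplit(tr$err_id[i], ";")[[1]]
    joined <- paste0(inj$assembly$seq[[ids[1]]], inj$assembly$seq[[ids[2]]])
    expect_equal(joined, tr$orig_seq[i])             # conservation
    expect_gte(tr$pos[i] / nchar(tr$orig_seq[i]), 0.4)
    expect_lte(tr$pos[i] / nchar(tr$orig_seq[i]), 0.6)
  }
  for (i in which(tr$type %in% c("missing_seq", "unsupported_insertion"))) {
    L <- max(nchar(tr$removed_seq[i]), nchar(tr$added_seq[i]))
    expect_gte(L, 30L); expect_lte(L, 70L)
  }
  for (i in which(tr$type %in% c("translocation", "inversion"))) {
    n <- nchar(tr$orig_seq[i])
    L <- nchar(tr$removed_seq[i])
    expect_gte(L / n, 0.19); expect_lte(L / n, 0.31)
    # length conserved; inversions record the reverse-complemented copy
    expect_equal(nchar(inj$assembly$seq[[tr$err_id[i]]]), n)
    if (tr$type[i] == "inversion")
      expect_equal(tr$added_seq[i], roast:::cpp_revcomp(tr$removed_seq[i]))
    else
      expect_equal(tr$added_seq[i], tr$removed_seq[i])
  }
  expect_error(inject_errors(asm, c(incomplete = 500L)), "eligible")
})

test_that("simulated reads are exact substrings at zero substitution rate", {
  asm <- toy_assembly(n = 3, len = 1200, seed = 15)
  rp <- simulate_read_pairs(asm, 400, read_len = 100L, subst_rate = 0,
                            seed = 3)
  all_ctg <- paste(unlist(asm$seq), collapse = "\r")
  hit1 <- vapply(rp$s1[1:50], function(s) roast:::cpp_find_exact(all_ctg, s) >= 0,
                 logical(1))
  hit2 <- vapply(rp$s2[1:50], function(s)
    roast:::cpp_find_exact(all_ctg, roast:::cpp_revcomp(s)) >= 0, logical(1))
  expect_true(all(hit1))
  expect_true(all(hit2))
})

test_that("fragment sizes stay in range and substitutions match the rate", {
  asm <- toy_assembly(n = 2, len = 2000, seed = 16)
  rp <- simulate_read_pairs(asm, 3000, read_len = 100L, subst_rate = 0.005,
                            seed = 4)
  # implied fragment span: align both mates, measure outer distance
  rec <- align_read_pairs(rp, asm)
  fr <- rec[rec$orientation == "FR" & rec$strand == 1L &
              rec$lclip + rec$rclip == 0L]
  span <- fr$mate_start + 100L - fr$start
  expect_gte(min(span), 245)
  expect_lte(max(span), 505)
  # empirical substitution rate within +-20% at ~600k bases
  rp0 <- simulate_read_pairs(asm, 3000, read_len = 100L, subst_rate = 0,
                             seed = 4)
  diffs <- sum(vapply(seq_len(3000), function(i) {
    (100 - roast:::cpp_match_count(rp$s1[i], rp0$s1[i], 0L, 0L, 100L)) +
      (100 - roast:::cpp_match_count(rp$s2[i], rp0$s2[i], 0L, 0L, 100L))
  }, numeric(1)))
  rate <- diffs / (3000 * 200)
  expect_gte(rate, 0.004); expect_lte(rate, 0.006)
  # determinism
  rp2 <- simulate_read_pairs(asm, 3000, read_len = 100L, subst_rate = 0.005,
                             seed = 4)
  expect_identical(rp$s1, rp2$s1)
})

test_that("recovery scorer is calibrated: 0% unrepaired, 100% identity map", {
  bench <- mini_bench()
  idmap <- data.table::data.table(initial_id = names(bench$erroneous$seq),
                                  final_id = names(bench$erroneous$seq),
                                  relation = "unchanged")
  sc0 <- score_recovery(bench$truth, bench$erroneous, idmap)
  expect_true(all(sc0$pct == 0))
  # ceiling: pre-error assembly under an identity-style map
  ref <- bench$reference
  mp <- data.table::rbindlist(lapply(seq_len(nrow(bench$truth)), function(i) {
    tr <- as.list(bench$truth[i])
    err_ids <- strsplit(tr$err_id, ";")[[1]]
    orig_ids <- strsplit(tr$orig_id, ";")[[1]]
    data.table::data.table(initial_id = err_ids,
                           final_id = orig_ids[pmin(seq_along(err_ids),
                                                    length(orig_ids))],
                           relation = "unchanged")
  }))
  # chimera initials must reach both constituents
  ch <- bench$truth[bench$truth$type == "chimera"]
  extra <- data.table::rbindlist(lapply(seq_len(nrow(ch)), function(i) {
    data.table::data.table(initial_id = ch$err_id[i],
                           final_id = strsplit(ch$orig_id[i], ";")[[1]],
                           relation = "split-into")
  }))
  sc1 <- score_recovery(bench$truth, ref, rbind(mp, extra))
  expect_true(all(sc1$pct == 100))
  # unknown contig in the truth -> error
  bad <- data.table::copy(bench$truth)[1, err_id := "nope"]
  expect_error(score_recovery(bad, ref, mp), "absent")
})
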