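test_that("clip extension grows the contig by the consensus length", {
  ctg <- rand_dna(500, seed = 1)
  left <- list(direction = "left", position = 0L)
  cons <- list(seq = "TTGCA", depth = rep(5L, 5), origin = -5L)
  res <- extend_with_clips(ctg, left, cons)
  expect_equal(res$seq, paste0("TTGCA", ctg))
  expect_equal(res$gain, 5L)
  expect_equal(res$prov[1:5], rep(1L, 5))
  right <- list(direction = "right", position = 500L)
  cons2 <- list(seq = rand_dna(30, seed = 2), depth = rep(4L, 30), origin = 0L)
  res2 <- extend_with_clips(ctg, right, cons2)
  expect_equal(nchar(res2$seq), 530L)
  expect_equal(res2$gain, 30L)
})

test_that("orphan extension enforces the minimum length gain", {
  src <- rand_dna(700, seed = 3)
  ctg <- substr(src, 1, 400)
  # mates tile the region just past the contig end, overlapping it
  starts <- seq(350, 580, by = 10)
  mates <- vapply(starts, function(s) substr(src, s + 1, s + 100), character(1))
  cl <- list(edge = "right")
  p <- default_parameters()
  res <- extend_with_orphans(ctg, cl, mates, p, 100L)
  expect_equal(res$action, "stitched")
  expect_gte(res$gain, 50L)                 # >= 50% of read length
  expect_true(startsWith(res$seq, ctg))
  expect_equal(res$seq, substr(src, 1, nchar(res$seq)))
  # a block whose overlap yields a tiny gain is rejected
  starts2 <- seq(300, 340, by = 5)
  mates2 <- vapply(starts2, function(s) substr(src, s + 1, s + 100), character(1))
  res2 <- extend_with_orphans(ctg, cl, mates2, p, 100L)
  expect_equal(res2$action, "none")
})

test_that("clip merge requires a perfect full-length seed hit", {
  src <- rand_dna(900, seed = 4)
  a <- substr(src, 1, 500); b <- substr(src, 451, 900)  # 50-base true overlap
  asm <- new_assembly(c(a = a, b = b), read_length = 100L)
  p <- default_parameters()
  out <- merge_fragments_by_clip(asm, "a", "right", p)
  expect_false(is.null(out$merge))
  expect_equal(out$merge$order, c("a", "b"))
  expect_equal(out$merge$overlap_len, 50L)
  expect_equal(out$assembly$seq[["a+b"]], src)
  # mutate one base of the seed region of b: no 100% seed, no merge
  v <- strsplit(b, "")[[1]]
  v[30] <- chartr("ACGT", "TGCA", v[30])
  asm2 <- new_assembly(c(a = a, b = paste(v, collapse = "")),
                       read_length = 100L)
  out2 <- merge_fragments_by_clip(asm2, "a", "right", p)
  expect_null(out2$merge)
})

test_that("island merges respect overlap length, score and edge slack", {
  src <- rand_dna(900, seed = 5)
  a <- substr(src, 1, 500); b <- substr(src, 476, 900)   # 25-base overlap
  asm <- new_assembly(c(a = a, b = b), read_length = 100L)
  p <- default_parameters()
  isl <- list(contig = "a", edge = "right", outer = 475L,
              partner = "b", partner_edge = "left", partner_outer = 25L,
              n_reads = 6L)
  out <- merge_fragments_by_islands(asm, isl, p, 100L)
  expect_false(is.null(out$merge))
  expect_equal(out$assembly$seq[["a+b"]], src)
  # 8-base overlap -> below min_island_overlap
  b2 <- substr(src, 493, 900)
  asm2 <- new_assembly(c(a = a, b = b2), read_length = 100L)
  isl2 <- isl; isl2$outer <- 492L
  expect_null(merge_fragments_by_islands(asm2, isl2, p, 100L)$merge)
  # qualifying overlap but far from the island's outer edge -> rejected
  isl3 <- isl; isl3$outer <- 430L                        # 45 > 5% of read len
  expect_null(merge_fragments_by_islands(asm, isl3, p, 100L)$merge)
})

test_that("chimera splitting routes the smaller piece by length and self-hits", {
  p <- default_parameters()
  big <- rand_dna(900, seed = 6); small <- rand_dna(350, seed = 7)
  site <- list(kind = "one_sided_right", pos_right = 900L,
               pos_left = NA_integer_,
               right_consensus = list(seq = substr(small, 1, 40),
                                      depth = rep(5L, 40), origin = 0L),
               left_consensus = NULL)
  act <- split_chimera_at_clip(paste0(big, small), site, p)
  expect_equal(act$mode, "split")
  expect_equal(act$big, big)
  expect_equal(act$small, small)
  expect_equal(act$small_disposition, "new_contig")
  # a 150-base piece is discarded (< 200)
  small2 <- rand_dna(150, seed = 8)
  site2 <- site
  site2$right_consensus$seq <- substr(small2, 1, 40)
  act2 <- split_chimera_at_clip(paste0(big, small2), site2, p)
  expect_equal(act2$small_disposition, "discarded")
  # a duplicated block: the consensus hits its other copy, so the region
  # between the hit and the clip point is excised and the flanks rejoined
  dup <- substr(big, 101, 400)
  site3 <- list(kind = "one_sided_right", pos_right = 900L,
                pos_left = NA_integer_,
                right_consensus = list(seq = substr(dup, 1, 40),
                                       depth = rep(5L, 40), origin = 0L),
                left_consensus = NULL)
  act3 <- split_chimera_at_clip(paste0(big, dup), site3, p)
  expect_equal(act3$mode, "excised")
  expect_gt(nchar(act3$removed), 0L)
})

test_that("coverage-break splitting delegates to the same routing", {
  p <- default_parameters()
  a <- rand_dna(800, seed = 9); b <- rand_dna(700, seed = 10)
  act <- split_chimera_at_coverage(paste0(a, b),
                                   list(position = 800L), p)
  expect_equal(act$mode, "split")
  expect_equal(act$big, a)
  expect_equal(act$small, b)
  expect_equal(act$small_disposition, "new_contig")
})

test_that("unsupported insertions are removed exactly via facing consensi", {
  p <- default_parameters()
  orig <- rand_dna(1200, seed = 11)
  U <- rand_dna(60, seed = 12)
  pos <- 600L
  mut <- paste0(substr(orig, 1, pos), U, substr(orig, pos + 1, 1200))
  site <- list(kind = "facing", pos_right = pos, pos_left = pos + 60L,
               right_consensus = list(seq = substr(orig, pos + 1, pos + 40),
                                      depth = rep(8L, 40), origin = 0L),
               left_consensus = list(seq = substr(orig, pos - 39, pos),
                                     depth = rep(8L, 40), origin = -40L))
  fx <- remove_unsupported_insertion(mut, site, p)
  expect_equal(fx$seq, orig)
  expect_equal(fx$removed, U)
  expect_equal(nchar(fx$removed), fx$coords[2] - fx$coords[1])
  # consensi that do not cross-map leave the contig unchanged
  site2 <- site
  site2$right_consensus$seq <- rand_dna(40, seed = 13)
  expect_null(remove_unsupported_insertion(mut, site2, p))
})

test_that("translocated and inverted fragments are re-placed exactly", {
  p <- default_parameters()
  orig <- rand_dna(2000, seed = 14)
  blk <- substr(orig, 501, 900)                       # 400-base block
  rest <- paste0(substr(orig, 1, 500), substr(orig, 901, 2000))
  mut <- paste0(substr(rest, 1, 1200), blk, substr(rest, 1201, 1600))
  # crisscross at the removal junction (500); block now at [1200, 1600)
  site <- list(kind = "crisscross", pos_right = 500L, pos_left = 500L,
               right_consensus = list(seq = substr(blk, 1, 35)),
               left_consensus = list(seq = substr(blk, 366, 400)))
  h1 <- roast:::cons_self_hit(substr(blk, 1, 35), mut, p)
  h2 <- roast:::cons_self_hit(substr(blk, 366, 400), mut, p)
  fx <- fix_translocation_inversion(mut, site,
                                    list(right = h1, left = h2,
                                         right_seq = substr(blk, 1, 35),
                                         left_seq = substr(blk, 366, 400)),
                                    p)
  expect_false(is.null(fx))
  expect_equal(nchar(fx$seq), nchar(mut))             # length preserved
  expect_equal(fx$seq, orig)
  # inversion: block reinserted reverse-complemented elsewhere
  rblk <- roast:::cpp_revcomp(blk)
  mut2 <- paste0(substr(rest, 1, 1200), rblk, substr(rest, 1201, 1600))
  cr <- substr(blk, 1, 35); cl <- substr(blk, 366, 400)
  h1i <- roast:::cons_self_hit(cr, mut2, p)
  h2i <- roast:::cons_self_hit(cl, mut2, p)
  expect_equal(h1i$strand, "-")
  fxi <- fix_translocation_inversion(mut2, site,
                                     list(right = h1i, left = h2i,
                                          right_seq = cr, left_seq = cl),
                                     p)
  expect_false(is.null(fxi))
  expect_equal(fxi$seq, orig)
})
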