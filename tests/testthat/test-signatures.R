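# Fixture builder: hand-crafted alignment records on one contig.
rec_row <- function(rid, start, mlen, lclip = 0L, rclip = 0L, strand = 1L,
                    oseq = NULL, contig = "c01", mate = 1L, mapq = 60L,
                    mate_mapped = TRUE, mate_contig = contig,
                    mate_start = start + 150L, orientation = "FR",
                    read_len = NULL) {
  rl <- if (is.null(read_len)) lclip + mlen + rclip else read_len
  if (is.null(oseq)) oseq <- rand_dna(rl)
  data.table::data.table(
    rid = rid, read_id = paste0("r", rid), mate = mate, contig = contig,
    start = as.integer(start), mlen = as.integer(mlen),
    lclip = as.integer(lclip), rclip = as.integer(rclip),
    strand = as.integer(strand), mapq = mapq, score = mlen,
    read_len = as.integer(rl), oseq = oseq, mate_mapped = mate_mapped,
    mate_contig = mate_contig, mate_start = as.integer(mate_start),
    orientation = orientation)
}

test_that("edge clip clusters require 3 reads and 75% support", {
  p <- default_parameters()
  clip <- rand_dna(30, seed = 1)
  mkclip <- function(rid) rec_row(rid, 0, 70, lclip = 30,
                                  oseq = paste0(clip, rand_dna(70)))
  # 4 left-clipped reads, nothing else spanning -> support 1.0
  recs <- data.table::rbindlist(lapply(1:4, mkclip))
  cl <- find_edge_clip_clusters(recs, "c01", 2000L, p)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$direction, "left")
  expect_equal(cl[[1]]$position, 0L)
  expect_equal(cl[[1]]$n_reads, 4L)
  expect_equal(cl[[1]]$support_fraction, 1.0)
  # 2 clipped reads only -> below min_clip_reads
  recs2 <- data.table::rbindlist(lapply(1:2, mkclip))
  expect_length(find_edge_clip_clusters(recs2, "c01", 2000L, p), 0)
  # 3 clipped + 3 unclipped spanning -> support 50% < 75%
  span <- lapply(4:6, function(i) rec_row(i, 0, 100))
  recs3 <- data.table::rbindlist(c(lapply(1:3, mkclip), span))
  expect_length(find_edge_clip_clusters(recs3, "c01", 2000L, p), 0)
})

test_that("orphan clusters require outward orientation and low clipping", {
  p <- default_parameters()
  mk <- function(rid, strand = 1L, rclip = 0L, lclip = 0L)
    rec_row(rid, 1900 - 100, 100 - rclip - lclip, lclip = lclip,
            rclip = rclip, strand = strand, mate_mapped = FALSE,
            mate_contig = NA_character_, mate_start = NA_integer_,
            orientation = "mate_unmapped", read_len = 100L)
  # 3 outward (+ strand at right edge) unclipped reads with unmapped mates
  recs <- data.table::rbindlist(lapply(1:3, mk))
  cl <- find_orphan_mate_clusters(recs, "c01", 2000L, p, 100L)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$edge, "right")
  # same reads but 30% clipped -> rejected (max 25%)
  recs2 <- data.table::rbindlist(lapply(1:3, function(i) mk(i, rclip = 30L)))
  expect_length(find_orphan_mate_clusters(recs2, "c01", 2000L, p, 100L), 0)
  # pointing inward (reverse strand at right edge) -> rejected
  recs3 <- data.table::rbindlist(lapply(1:3, function(i) mk(i, strand = -1L)))
  expect_length(find_orphan_mate_clusters(recs3, "c01", 2000L, p, 100L), 0)
})

test_that("internal one-sided sites respect junctions and consensus length", {
  p <- default_parameters()
  cons <- rand_dna(40, seed = 5)
  mk <- function(rid, rclip) rec_row(rid, 500 - (100 - rclip), 100 - rclip,
                                     rclip = rclip,
                                     oseq = paste0(rand_dna(100 - rclip),
                                                   substr(cons, 1, rclip)))
  recs <- data.table::rbindlist(lapply(1:10, function(i) mk(i, 20 + i)))
  sites <- find_internal_clip_sites(recs, "c01", 2000L, integer(), p, 100L)
  expect_length(sites, 1)
  expect_equal(sites[[1]]$kind, "one_sided_right")
  expect_equal(sites[[1]]$pos_right, 500L)
  # clip point at a splice junction -> ignored
  expect_length(
    find_internal_clip_sites(recs, "c01", 2000L, c(500L), p, 100L), 0)
  # consensus of 8 bases -> below the 10-base minimum
  recs2 <- data.table::rbindlist(lapply(1:10, function(i) mk(i, 8L)))
  expect_length(
    find_internal_clip_sites(recs2, "c01", 2000L, integer(), p, 100L), 0)
})

test_that("facing and crisscross sites are classified by clip-point order", {
  p <- default_parameters()
  consA <- rand_dna(30, seed = 6); consB <- rand_dna(30, seed = 7)
  right_at <- function(rid, pos, cons)
    rec_row(rid, pos - 70, 70, rclip = 30,
            oseq = paste0(rand_dna(70), cons))
  left_at <- function(rid, pos, cons)
    rec_row(rid, pos, 70, lclip = 30, oseq = paste0(cons, rand_dna(70)))
  # right-pointing at 500, left-pointing at 550: facing (insertion of 50)
  recs <- data.table::rbindlist(c(
    lapply(1:5, function(i) right_at(i, 500, consA)),
    lapply(6:10, function(i) left_at(i, 550, consB))))
  sites <- find_internal_clip_sites(recs, "c01", 2000L, integer(), p, 100L)
  expect_length(sites, 1)
  expect_equal(sites[[1]]$kind, "facing")
  # both at the same point: crisscross
  recs2 <- data.table::rbindlist(c(
    lapply(1:5, function(i) right_at(i, 500, consA)),
    lapply(6:10, function(i) left_at(i, 500, consB))))
  sites2 <- find_internal_clip_sites(recs2, "c01", 2000L, integer(), p, 100L)
  expect_length(sites2, 1)
  expect_equal(sites2[[1]]$kind, "crisscross")
})

test_that("mate islands require 5 reads on a single partner contig", {
  p <- default_parameters()
  asm <- toy_assembly(n = 3, len = 2000)
  mk <- function(rid, partner, mstart = 100L)
    rec_row(rid, 1950 - 100, 100, strand = 1L, mate_contig = partner,
            mate_start = mstart, orientation = "diff_contig")
  recs <- data.table::rbindlist(lapply(1:5, function(i) mk(i, "c02")))
  isl <- find_mate_islands(recs, asm, p, 100L)
  expect_length(isl, 1)
  expect_equal(isl[[1]]$contig, "c01")
  expect_equal(isl[[1]]$partner, "c02")
  expect_equal(isl[[1]]$edge, "right")
  expect_equal(isl[[1]]$partner_edge, "left")
  # 4 reads -> below threshold
  recs2 <- data.table::rbindlist(lapply(1:4, function(i) mk(i, "c02")))
  expect_length(find_mate_islands(recs2, asm, p, 100L), 0)
  # mates scattered over two partners, 3+2 -> no island
  recs3 <- data.table::rbindlist(c(lapply(1:3, function(i) mk(i, "c02")),
                                   lapply(4:5, function(i) mk(i, "c03"))))
  expect_length(find_mate_islands(recs3, asm, p, 100L), 0)
})

test_that("abrupt coverage breaks use relative differences and end-ignore", {
  p <- default_parameters()
  # 84% drop mid-contig: (50-8)/50 = 84% >= 80%
  d <- c(rep(50L, 300), rep(8L, 300))
  br <- find_abrupt_breaks(d, "c01", p, 100L)
  expect_equal(nrow(br), 1L)
  expect_equal(br$position, 300L)
  expect_equal(br$left_depth, 50L)
  expect_equal(br$right_depth, 8L)
  # 10% change: no break
  d2 <- c(rep(50L, 300), rep(45L, 300))
  expect_equal(nrow(find_abrupt_breaks(d2, "c01", p, 100L)), 0L)
  # same 84% drop at position 30: inside the end-ignore zone
  d3 <- c(rep(50L, 30), rep(8L, 570))
  expect_equal(nrow(find_abrupt_breaks(d3, "c01", p, 100L)), 0L)
  # invariance under uniform scaling of the depth vector
  br4 <- find_abrupt_breaks(d * 7L, "c01", p, 100L)
  expect_equal(br4$position, br$position)
  # a zero-coverage run is flagged at both ends
  d5 <- c(rep(40L, 250), rep(0L, 100), rep(40L, 250))
  br5 <- find_abrupt_breaks(d5, "c01", p, 100L)
  expect_setequal(br5$position, c(250L, 350L))
})

test_that("gradual breaks are window-based and off by default", {
  p <- default_parameters()
  # ramp from 50 down to 5 over 20 bases: no single step >= 80%
  d <- c(rep(50L, 300), as.integer(round(seq(50, 5, length.out = 20))),
         rep(5L, 300))
  expect_equal(nrow(find_abrupt_breaks(d, "c01", p, 100L)), 0L)
  expect_equal(nrow(find_gradual_breaks(d, "c01", p, 100L)), 0L)  # off
  p2 <- default_parameters(gradual_check = TRUE)
  br <- find_gradual_breaks(d, "c01", p2, 100L)
  expect_gte(nrow(br), 1L)
  expect_lt(abs(br$position[1] - 310L), 25L)
  # flat profile: nothing
  expect_equal(nrow(find_gradual_breaks(rep(30L, 600), "c01", p2, 100L)), 0L)
})

test_that("signature support is auditable from the reported read ids", {
  bench <- mini_bench()
  p <- default_parameters(dedup_check = FALSE)
  asm <- bench$erroneous
  rec <- filter_alignments(align_read_pairs(bench$reads, asm, p), p)
  clens <- nchar(asm$seq)
  found <- 0L
  for (id in names(asm$seq)) {
    for (cl in find_edge_clip_clusters(rec, id, clens[[id]], p)) {
      found <- found + 1L
      expect_equal(length(cl$read_ids), cl$n_reads)
      keys <- paste0(rec$rid, "/", rec$mate)
      expect_true(all(cl$read_ids %in% keys))
    }
  }
  expect_gt(found, 0L)
})

test_that("clean alignments of error-free reads yield no signatures", {
  asm <- toy_assembly(n = 4, len = 1800, seed = 31)
  reads <- toy_reads(asm, n_pairs = 3500, seed = 8, subst_rate = 0.005)
  p <- default_parameters()
  rec <- filter_alignments(align_read_pairs(reads, asm, p), p)
  clens <- nchar(asm$seq)
  for (id in names(asm$seq)) {
    expect_length(find_edge_clip_clusters(rec, id, clens[[id]], p), 0)
    expect_length(find_orphan_mate_clusters(rec, id, clens[[id]], p, 100L), 0)
    expect_length(
      find_internal_clip_sites(rec, id, clens[[id]], integer(), p, 100L), 0)
    d <- compute_coverage(rec, id, clens[[id]])
    expect_equal(nrow(find_abrupt_breaks(d, id, p, 100L)), 0L)
  }
  expect_length(find_mate_islands(rec, asm, p, 100L), 0)
})
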