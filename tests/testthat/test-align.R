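test_that("exact substrings align full-length with no clips", {
  asm <- toy_assembly(n = 2, len = 2000)
  ctg <- asm$seq[[1]]
  pairs <- list(ids = "r1", s1 = substr(ctg, 501, 600),
                s2 = roast:::cpp_revcomp(substr(ctg, 801, 900)),
                read_len = 100L)
  rec <- align_read_pairs(pairs, asm)
  expect_equal(rec$contig, c("c01", "c01"))
  expect_equal(rec$start, c(500L, 800L))
  expect_equal(rec$mlen, c(100L, 100L))
  expect_equal(rec$lclip + rec$rclip, c(0L, 0L))
  expect_equal(rec$strand, c(1L, -1L))
  expect_equal(rec$orientation, c("FR", "FR"))
})

test_that("a read spanning a deleted prefix is soft-clipped", {
  asm <- toy_assembly(n = 1, len = 2000)
  ctg <- asm$seq[[1]]
  # first 20 bases of the read come from a region deleted from the contig
  junk <- rand_dna(20, seed = 9)
  read <- paste0(junk, substr(ctg, 1, 80))
  pairs <- list(ids = "r1", s1 = read,
                s2 = roast:::cpp_revcomp(substr(ctg, 301, 400)),
                read_len = 100L)
  rec <- align_read_pairs(pairs, asm)
  r1 <- rec[rec$mate == 1L]
  expect_equal(r1$start, 0L)
  expect_equal(r1$lclip, 20L)
  expect_equal(r1$mlen, 80L)
  # agreement with the Smith-Waterman oracle
  expect_equal(unname(sw_clip_lengths(read, ctg)), c(20L, 0L))
})

test_that("a read matching two identical contigs is ambiguous (low mapq)", {
  seqs <- c(a = rand_dna(1000, seed = 2))
  seqs["b"] <- seqs[["a"]]
  asm <- new_assembly(seqs, read_length = 100L)
  pairs <- list(ids = "r1", s1 = substr(seqs[[1]], 101, 200),
                s2 = roast:::cpp_revcomp(substr(seqs[[1]], 401, 500)),
                read_len = 100L)
  rec <- align_read_pairs(pairs, asm)
  expect_true(all(rec$mapq < default_parameters()$min_mapq))
  expect_equal(nrow(filter_alignments(rec)), 0L)
})

test_that("internal aligner matches the Smith-Waterman oracle on small instances", {
  set.seed(101)
  n_agree <- 0L
  n_cases <- 40L
  for (i in seq_len(n_cases)) {
    ctg <- rand_dna(300)
    s <- sample(240, 1)
    read <- substr(ctg, s, s + 59)
    # mutate a few bases
    v <- strsplit(read, "")[[1]]
    k <- sample(0:3, 1)
    if (k > 0) {
      pos <- sample(60, k)
      v[pos] <- sample(c("A", "C", "G", "T"), k, replace = TRUE)
    }
    # half the cases: replace a tail with junk to force a clip
    if (i %% 2 == 0) {
      cl <- sample(5:25, 1)
      v[(60 - cl + 1):60] <- strsplit(rand_dna(cl), "")[[1]]
    }
    read <- paste(v, collapse = "")
    al <- roast:::cpp_align_reads(ctg, read)
    ora <- sw_clip_lengths(read, ctg)
    sw_score <- Biostrings::score(sw_local(read, ctg))
    # equal-score placements are equally optimal (ties at clip boundaries)
    if (!is.na(al$contig[1]) &&
        ((al$lclip[1] == ora[1] && al$rclip[1] == ora[2]) ||
           al$score[1] == sw_score))
      n_agree <- n_agree + 1L
  }
  expect_gte(n_agree / n_cases, 0.95)
})

test_that("orientation filtering removes improper pairs and is idempotent", {
  asm <- toy_assembly(n = 1, len = 2000)
  ctg <- asm$seq[[1]]
  # p1: proper FR; p2: F1F2 (both forward); p3: R1R2; p4: RF tail-to-tail
  pairs <- list(
    ids = c("p1", "p2", "p3", "p4"),
    s1 = c(substr(ctg, 101, 200), substr(ctg, 101, 200),
           roast:::cpp_revcomp(substr(ctg, 101, 200)),
           roast:::cpp_revcomp(substr(ctg, 101, 200))),
    s2 = c(roast:::cpp_revcomp(substr(ctg, 401, 500)), substr(ctg, 401, 500),
           roast:::cpp_revcomp(substr(ctg, 401, 500)),
           substr(ctg, 401, 500)),
    read_len = 100L)
  rec <- align_read_pairs(pairs, asm)
  expect_equal(rec[rec$read_id == "p1"]$orientation, c("FR", "FR"))
  expect_equal(rec[rec$read_id == "p2"]$orientation, c("F1F2", "F1F2"))
  expect_equal(rec[rec$read_id == "p3"]$orientation, c("R1R2", "R1R2"))
  expect_equal(rec[rec$read_id == "p4"]$orientation, c("RF", "RF"))
  kept <- filter_alignments(rec)
  expect_setequal(unique(kept$read_id), "p1")
  expect_identical(filter_alignments(kept), kept)
})

test_that("coverage equals a brute-force per-base recount", {
  asm <- toy_assembly(n = 1, len = 1200)
  reads <- toy_reads(asm, n_pairs = 300, seed = 11)
  rec <- filter_alignments(align_read_pairs(reads, asm))
  d <- compute_coverage(rec, "c01", 1200L)
  # oracle: count interval membership per base directly
  r <- rec[rec$contig == "c01"]
  oracle <- integer(1200)
  for (i in seq_len(nrow(r))) {
    idx <- (r$start[i] + 1L):(r$start[i] + r$mlen[i])
    oracle[idx] <- oracle[idx] + 1L
  }
  expect_identical(d, oracle)
  expect_equal(sum(d), sum(r$mlen))
})

test_that("edge-read selection honors the 2x read-length window", {
  asm <- toy_assembly(n = 1, len = 5000)
  ctg <- asm$seq[[1]]
  mk <- function(from) substr(ctg, from + 1, from + 100)
  pairs <- list(ids = c("e", "m"), s1 = c(mk(150), mk(2500)),
                s2 = c(roast:::cpp_revcomp(mk(400)),
                       roast:::cpp_revcomp(mk(2800))),
                read_len = 100L)
  rec <- align_read_pairs(pairs, asm)
  sel <- select_edge_reads(rec, "c01", 5000L, default_parameters(), 100L)
  expect_true("e" %in% sel$read_id)     # start 150 < 200
  expect_false("m" %in% sel$read_id)    # mid-contig
  # short contig (< 2 windows): everything is within the edge zones
  asm2 <- toy_assembly(n = 1, len = 380, seed = 77)
  reads2 <- toy_reads(asm2, n_pairs = 40, seed = 3)
  rec2 <- align_read_pairs(reads2, asm2)
  sel2 <- select_edge_reads(rec2, "c01", 380L, default_parameters(), 100L)
  expect_equal(nrow(sel2), nrow(rec2[!is.na(rec2$contig)]))
})

test_that("error-free reads from the assembly itself align almost perfectly", {
  asm <- toy_assembly(n = 3, len = 1500, seed = 12)
  reads <- toy_reads(asm, n_pairs = 1500, seed = 4, subst_rate = 0)
  rec <- align_read_pairs(reads, asm)
  proper <- rec$orientation == "FR" & rec$lclip == 0 & rec$rclip == 0
  expect_gte(mean(proper), 0.99)
})
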