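test_that("clip consensus takes per-column majority with IUPAC ties", {
  # unanimous columns
  cons <- consensus_from_clips(c("ACG", "ACG", "ACG"))
  expect_equal(cons$seq, "ACG")
  expect_equal(cons$depth, c(3L, 3L, 3L))
  # {A,A,C,C} at one column -> M
  cons2 <- consensus_from_clips(c("AAG", "AAG", "CAG", "CAG"))
  expect_equal(substr(cons2$seq, 1, 1), "M")
  expect_equal(substr(cons2$seq, 2, 3), "AG")
  expect_error(consensus_from_clips(character()), "empty")
})

test_that("staggered error-free fragments reconstruct their source exactly", {
  src <- rand_dna(60, seed = 21)
  frags <- data.table::data.table(
    seq = c(substr(src, 1, 30), substr(src, 11, 45), substr(src, 21, 60)),
    offset = c(0L, 10L, 20L))
  cons <- consensus_from_clips(frags)
  expect_equal(cons$seq, src)
  expect_equal(cons$origin, 0L)
  # independent overlap-layout oracle: exhaustive merge order at 0 mismatch
  expect_equal(exhaustive_assemble_len(frags$seq, min_ov = 10, min_id = 100),
               60L)
})

test_that("greedy assembly merges overlaps and leaves disjoint reads apart", {
  src <- rand_dna(150, seed = 22)
  a <- substr(src, 1, 100); b <- substr(src, 51, 150)
  out <- greedy_assemble(c(a, b), min_overlap = 16, min_identity_pct = 95)
  expect_length(out, 1)
  expect_equal(out[1], src)
  expect_equal(nchar(out[1]), 150L)     # 100 + 100 - 50
  # disjoint reads stay unmerged
  out2 <- greedy_assemble(c(rand_dna(80, seed = 1), rand_dna(80, seed = 2)))
  expect_length(out2, 2)
  # result never shorter than the longest input
  expect_gte(max(nchar(out2)), 80L)
})

test_that("greedy assembly matches the exhaustive merge-order oracle", {
  set.seed(33)
  agree <- 0L
  for (i in 1:25) {
    src <- rand_dna(240)
    starts <- sort(sample(0:140, sample(3:5, 1)))
    frags <- vapply(starts, function(s) substr(src, s + 1, s + 100),
                    character(1))
    frags <- c(substr(src, 1, 100), frags)
    out <- greedy_assemble(frags, min_overlap = 16, min_identity_pct = 95)
    if (sum(nchar(out)) == exhaustive_assemble_len(frags)) agree <- agree + 1L
  }
  expect_gte(agree / 25, 0.95)
})

test_that("overlap search finds exact substrings and rejects absent queries", {
  asm <- toy_assembly(n = 3, len = 1000)
  q <- substr(asm$seq[[2]], 301, 325)
  hits <- find_local_overlap(q, asm)
  expect_gte(nrow(hits), 1)
  expect_equal(hits$subject_id[1], "c02")
  expect_equal(hits$ss[1], 300L)
  expect_equal(hits$identity_pct[1], 100)
  expect_equal(hits$n_gaps[1], 0L)
  expect_equal(hits$score[1], 100)
  # absent query -> no hits
  expect_equal(nrow(find_local_overlap(rand_dna(50, seed = 99), asm)), 0L)
  # self-hit sanity: a full contig finds itself at identity 100
  h2 <- find_local_overlap(asm$seq[[1]], asm)
  expect_equal(h2$subject_id[1], "c01")
  expect_equal(h2$identity_pct[1], 100)
  expect_equal(h2$length[1], 1000L)
})

test_that("overlap search matches a Smith-Waterman oracle on mutated pairs", {
  set.seed(44)
  ok <- 0L
  for (i in 1:20) {
    subj <- rand_dna(1000)
    s <- sample(700, 1)
    q <- substr(subj, s, s + 199)
    v <- strsplit(q, "")[[1]]
    pos <- sample(200, 10)                       # 5% mutation
    v[pos] <- sample(c("A", "C", "G", "T"), 10, replace = TRUE)
    q <- paste(v, collapse = "")
    hits <- find_local_overlap(q, c(s1 = subj))
    al <- sw_local(q, subj)
    sw_start <- Biostrings::start(Biostrings::subject(al)) - 1L
    if (nrow(hits) && abs(hits$ss[1] - sw_start) <= 2) ok <- ok + 1L
  }
  expect_gte(ok / 20, 0.9)
})

test_that("overlap extension honors the running-identity threshold", {
  set.seed(55)
  ovl <- rand_dna(140)                    # true terminal overlap
  tail_a <- rand_dna(100); head_b <- rand_dna(100)
  a <- paste0(tail_a, ovl)
  b <- paste0(ovl, head_b)
  # seed in the middle of the overlap, extended to its full extent
  seed <- list(qs = 150L, qe = 189L, ss = 50L, se = 89L)
  ov <- extend_overlap(a, b, seed)
  expect_equal(ov$a_range, c(100, 240))
  expect_equal(ov$b_range, c(0, 140))
  # 8 scattered mismatches outside the seed (94% overall) retained at 90%
  v <- strsplit(ovl, "")[[1]]
  flip <- function(ch) chartr("ACGT", "TGCA", ch)
  mpos <- c(5, 15, 25, 35, 95, 105, 115, 125)
  v[mpos] <- flip(v[mpos])
  b2 <- paste0(paste(v, collapse = ""), head_b)
  ov2 <- extend_overlap(a, b2, seed)
  expect_equal(ov2$b_range, c(0, 140))
  # overlap degrading to random sequence stops near the seed
  b3 <- paste0(substr(ovl, 1, 90), rand_dna(150))
  ov3 <- extend_overlap(a, b3, seed)
  expect_lt(ov3$b_range[2], 110)
})

test_that("terminal merge arithmetic and preconditions hold", {
  m <- merge_by_overlap("TTTTAC", "ACGGGG",
                        list(a_range = c(4, 6), b_range = c(0, 2)))
  expect_equal(m$seq, "TTTTACGGGG")           # 6 + 6 - 2
  expect_error(merge_by_overlap("AAAA", "TTTT",
                                list(a_range = c(4, 4), b_range = c(0, 0))),
               "zero-length")
  expect_error(merge_by_overlap("AAAA", "TTTT",
                                list(a_range = c(1, 3), b_range = c(0, 2))),
               "terminal")
  # provenance-aware resolution: original base beats read-derived
  m2 <- merge_by_overlap("AAC", "GTT", list(a_range = c(2, 3), b_range = c(0, 1)),
                         prov_a = c(0L, 0L, 1L), prov_b = c(0L, 0L, 0L))
  expect_equal(m2$seq, "AAGTT")              # b's original G beats a's derived C
  # equal provenance, disagreeing bases -> IUPAC union
  m3 <- merge_by_overlap("AAC", "GTT", list(a_range = c(2, 3), b_range = c(0, 1)))
  expect_equal(substr(m3$seq, 3, 3), "S")    # C|G
})

test_that("fragmenting and re-merging a contig restores it exactly", {
  src <- rand_dna(800, seed = 66)
  a <- substr(src, 1, 450); b <- substr(src, 401, 800)   # 50-base overlap
  seed_q <- substr(a, 426, 450)
  hits <- find_local_overlap(seed_q, c(b = b))
  expect_equal(hits$ss[1], 25L)
  ov <- extend_overlap(a, b, list(qs = 425L, qe = 449L,
                                  ss = hits$ss[1], se = hits$se[1]))
  m <- merge_by_overlap(a, b, ov)
  expect_equal(m$seq, src)
})
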