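# Shared fixtures, all built in code.

rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# small assembly of dissimilar random contigs
toy_assembly <- function(n = 3, len = 1500, seed = 42) {
  set.seed(seed)
  seqs <- vapply(seq_len(n), function(i) rand_dna(len), character(1))
  names(seqs) <- sprintf("c%02d", seq_len(n))
  new_assembly(seqs, read_length = 100L)
}

# error-free reads straight from an assembly
toy_reads <- function(asm, n_pairs = 2000, seed = 7, subst_rate = 0) {
  simulate_read_pairs(asm, n_pairs, read_len = 100L,
                      frag_range = c(250L, 500L),
                      subst_rate = subst_rate, seed = seed)
}

# memoized mini benchmark: one error of each type, run to convergence.
# Several test files share this single (moderately expensive) run.
.mini_cache <- new.env(parent = emptyenv())
mini_bench <- function() {
  if (is.null(.mini_cache$bench)) {
    .mini_cache$bench <- roast_simulate(n_contigs = 14, errors_per_type = 1,
                                        n_pairs = 10000, seed = 5)
  }
  .mini_cache$bench
}
mini_run <- function() {
  if (is.null(.mini_cache$run)) {
    b <- mini_bench()
    .mini_cache$run <- roast_run(b$erroneous, b$reads,
                                 default_parameters(dedup_check = FALSE))
  }
  .mini_cache$run
}

# Smith-Waterman oracle via Biostrings::pairwiseAlignment with the same
# scoring scheme as the internal aligner (gaps effectively discouraged)
sw_local <- function(read, contig) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  Biostrings::pairwiseAlignment(read, contig, type = "local",
                                substitutionMatrix = mat,
                                gapOpening = 3, gapExtension = 3)
}

sw_clip_lengths <- function(read, contig) {
  al <- sw_local(read, contig)
  pr <- Biostrings::pattern(al)
  c(Biostrings::start(pr) - 1L, nchar(read) - Biostrings::end(pr))
}

# exhaustive merge-order oracle for greedy assembly of few fragments:
# best (longest-sequence-minimising) reconstruction over all merge orders
exhaustive_assemble_len <- function(seqs, min_ov = 16, min_id = 95) {
  best <- new.env(parent = emptyenv())
  best$len <- sum(nchar(seqs))      # no merge at all
  merge2 <- function(a, b) {
    ov <- roast:::cpp_sp_overlap(a, b, as.integer(min_ov), min_id)
    if (ov[1] == 0) return(NULL)
    paste0(a, substr(b, ov[1] + 1L, nchar(b)))
  }
  recur <- function(ss) {
    n <- length(ss)
    merged_any <- FALSE
    if (n >= 2) {
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i == j) next
        m <- merge2(ss[i], ss[j])
        if (!is.null(m)) {
          merged_any <- TRUE
          recur(c(m, ss[-c(i, j)]))
        }
      }
    }
    if (!merged_any) {
      tot <- sum(nchar(ss))
      if (tot < best$len) best$len <- tot
    }
  }
  recur(seqs)
  best$len
}

# write a minimal SAM file for parse_sam tests
write_toy_sam <- function(path, asm, rows) {
  con <- file(path, "w")
  for (id in contig_ids(asm))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", id, nchar(asm$seq[[id]])), con)
  for (r in rows) writeLines(paste(r, collapse = "\t"), con)
  close(con)
  path
}
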