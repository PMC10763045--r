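# Benchmark harness: synthetic supertranscriptome generation, injection of
# the seven canonical assembly-error types, paired-end read simulation, and
# the per-type recovery scorer.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

rand_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Generate a synthetic supertranscriptome
#'
#' Contigs are i.i.d. random nucleotide sequences at the requested GC
#' content, with lengths uniform over `length_range`.  Mutual dissimilarity
#' (pairwise identity below 95 percent) is enforced by rejection: any
#' contig sharing a long high-identity overlap with another is resampled.
#' Deterministic per seed.
#'
#' @param n_contigs number of contigs.
#' @param length_range integer length range (min, max); lengths must exceed
#'   500 so every contig is eligible for error injection.
#' @param gc GC fraction.
#' @param seed RNG seed.
#' @return a `roast_assembly` with ids `st0001`, `st0002`, ...
#' @export
generate_supertranscriptome <- function(n_contigs, length_range = c(1000L, 3000L),
                                        gc = 0.5, seed = 1L) {
  if (length_range[1] <= 500L)
    stop("contig lengths must exceed 500 bases")
  if (n_contigs < 1) stop("n_contigs must be positive")
  with_seed(seed, {
    lens <- sample(seq.int(length_range[1], length_range[2]), n_contigs,
                   replace = TRUE)
    seqs <- vapply(lens, rand_seq, character(1), gc = gc)
    names(seqs) <- sprintf("st%04d", seq_len(n_contigs))
    p <- default_parameters()
    for (round in 1:10) {
      hits <- find_local_overlap_multi(unname(seqs), seqs, p)
      hits[, query := names(seqs)[query]]
      hits <- hits[subject_id != query]
      shorter <- pmin(nchar(seqs)[hits$query], nchar(seqs)[hits$subject_id])
      bad <- unique(hits$query[hits$identity_pct >= 95 &
                                 hits$length >= 0.5 * shorter])
      if (!length(bad)) break
      for (b in bad) seqs[[b]] <- rand_seq(nchar(seqs[[b]]), gc)
    }
    new_assembly(seqs)
  })
}

runif_int <- function(n, lo, hi) lo + floor(stats::runif(n) * (hi - lo + 1L))

#' Inject assembly errors and record the ground truth
#'
#' Injects, on distinct randomly chosen contigs (each longer than 500
#' bases):
#' * `incomplete`: 10-30 percent of the contig deleted from one or both
#'   ends;
#' * `fragmented`: a cut at a uniform position within 40-60 percent of the
#'   length;
#' * `chimera`: two contigs broken (40-60 percent) and fused
#'   (prefix of one + suffix of the other), consuming two contigs;
#' * `missing_seq` / `unsupported_insertion`: an internal fragment of
#'   30-70 percent of the read length deleted / inserted;
#' * `translocation` / `inversion`: a fragment of 20-30 percent of the
#'   contig length moved to a new position in the same / reverse
#'   orientation.
#'
#' Internal error positions keep a margin of 1.5 read lengths from the
#' contig ends, and translocation/inversion destinations stay at least two
#' read lengths away from the excision site, so that each error presents
#' its own distinct internal signature.
#'
#' @param assembly the error-free reference assembly.
#' @param counts named integer vector of error counts per type (defaults
#'   to 50 of each of the seven types).
#' @param read_len read length used to size local mis-assemblies.
#' @param seed RNG seed.
#' @return list with `assembly` (the erroneous assembly) and `truth`
#'   (a `data.table`, one row per error).
#' @export
inject_errors <- function(assembly,
                          counts = c(incomplete = 50L, fragmented = 50L,
                                     chimera = 50L, missing_seq = 50L,
                                     unsupported_insertion = 50L,
                                     translocation = 50L, inversion = 50L),
                          read_len = 100L, seed = 1L) {
  types <- c("incomplete", "fragmented", "chimera", "missing_seq",
             "unsupported_insertion", "translocation", "inversion")
  counts <- counts[intersect(names(counts), types)]
  need <- sum(counts) + sum(counts[names(counts) == "chimera"])
  elig <- contig_ids(assembly)[contig_lengths(assembly) > 500L]
  if (need > length(elig))
    stop("requested ", need, " contigs but only ", length(elig),
         " are eligible")
  margin <- as.integer(round(1.5 * read_len))
  with_seed(seed, {
    pool <- sample(elig)
    take <- function(k) { out <- pool[seq_len(k)]; pool <<- pool[-seq_len(k)]; out }
    rows <- list()
    out_seqs <- assembly$seq
    add_row <- function(...) rows[[length(rows) + 1L]] <<- data.table::data.table(...)

    for (type in names(counts)) {
      for (i in seq_len(counts[[type]])) {
        if (type == "chimera") {
          ids <- take(2L)
          a <- out_seqs[[ids[1]]]; b <- out_seqs[[ids[2]]]
          ca <- runif_int(1, round(0.4 * nchar(a)), round(0.6 * nchar(a)))
          cb <- runif_int(1, round(0.4 * nchar(b)), round(0.6 * nchar(b)))
          chim <- paste0(substr(a, 1, ca), substr(b, cb + 1L, nchar(b)))
          cid <- paste0(ids[1], "_", ids[2], "_chim")
          out_seqs <- out_seqs[setdiff(names(out_seqs), ids)]
          out_seqs[[cid]] <- chim
          add_row(type = type, err_id = cid,
                  orig_id = paste(ids, collapse = ";"),
                  orig_seq = paste(a, b, sep = ";"),
                  pos = ca, pos2 = cb, removed_seq = "", added_seq = "")
          next
        }
        id <- take(1L)
        s <- out_seqs[[id]]
        n <- nchar(s)
        if (type == "incomplete") {
          f <- stats::runif(1, 0.10, 0.30)
          dtot <- max(1L, as.integer(round(f * n)))
          side <- sample(c("left", "right", "both"), 1)
          if (side == "left") { dl <- dtot; dr <- 0L }
          else if (side == "right") { dl <- 0L; dr <- dtot }
          else {
            dl <- max(1L, as.integer(round(dtot * stats::runif(1, 0.3, 0.7))))
            dr <- dtot - dl
          }
          out_seqs[[id]] <- substr(s, dl + 1L, n - dr)
          add_row(type = type, err_id = id, orig_id = id, orig_seq = s,
                  pos = dl, pos2 = dr,
                  removed_seq = paste(substr(s, 1, dl),
                                      substr(s, n - dr + 1L, n), sep = ";"),
                  added_seq = "")
        } else if (type == "fragmented") {
          cut <- runif_int(1, round(0.4 * n), round(0.6 * n))
          p1 <- paste0(id, ".a"); p2 <- paste0(id, ".b")
          out_seqs <- out_seqs[setdiff(names(out_seqs), id)]
          out_seqs[[p1]] <- substr(s, 1L, cut)
          out_seqs[[p2]] <- substr(s, cut + 1L, n)
          add_row(type = type, err_id = paste(p1, p2, sep = ";"),
                  orig_id = id, orig_seq = s, pos = cut, pos2 = NA_integer_,
                  removed_seq = "", added_seq = "")
        } else if (type == "missing_seq") {
          L <- runif_int(1, round(0.3 * read_len), round(0.7 * read_len))
          pos <- runif_int(1, margin, n - margin - L)
          out_seqs[[id]] <- paste0(substr(s, 1L, pos),
                                   substr(s, pos + L + 1L, n))
          add_row(type = type, err_id = id, orig_id = id, orig_seq = s,
                  pos = pos, pos2 = NA_integer_,
                  removed_seq = substr(s, pos + 1L, pos + L), added_seq = "")
        } else if (type == "unsupported_insertion") {
          L <- runif_int(1, round(0.3 * read_len), round(0.7 * read_len))
          pos <- runif_int(1, margin, n - margin)
          ins <- rand_seq(L)
          out_seqs[[id]] <- paste0(substr(s, 1L, pos), ins,
                                   substr(s, pos + 1L, n))
          add_row(type = type, err_id = id, orig_id = id, orig_seq = s,
                  pos = pos, pos2 = NA_integer_, removed_seq = "",
                  added_seq = ins)
        } else {  # translocation / inversion
          L <- runif_int(1, round(0.2 * n), round(0.3 * n))
          src <- runif_int(1, margin, n - margin - L)
          frag <- substr(s, src + 1L, src + L)
          rest <- paste0(substr(s, 1L, src), substr(s, src + L + 1L, n))
          # destination in `rest` coordinates, >= 2 read lengths from the cut
          lo_ok <- seq2(margin, max(margin, src - 2L * read_len))
          hi_ok <- seq2(min(src + 2L * read_len, nchar(rest) - margin),
                        nchar(rest) - margin)
          cand <- c(lo_ok, hi_ok)
          if (!length(cand)) cand <- c(margin, nchar(rest) - margin)
          dst <- cand[runif_int(1, 1L, length(cand))]
          ins <- if (type == "inversion") cpp_revcomp(frag) else frag
          out_seqs[[id]] <- paste0(substr(rest, 1L, dst), ins,
                                   substr(rest, dst + 1L, nchar(rest)))
          add_row(type = type, err_id = id, orig_id = id, orig_seq = s,
                  pos = src, pos2 = dst, removed_seq = frag, added_seq = ins)
        }
      }
    }
    truth <- data.table::rbindlist(rows)
    list(assembly = new_assembly(out_seqs), truth = truth)
  })
}

#' Simulate paired-end reads from an assembly
#'
#' Fragments are sampled from contigs weighted by length (uniform
#' expression) or by `abundance * length`; fragment lengths are uniform
#' over `frag_range` (clamped to the contig), mates are read FR from the
#' fragment ends, and bases are substituted independently at `subst_rate`.
#' Qualities are constant Q30.  Deterministic per seed.
#'
#' @param assembly source assembly (normally the error-free reference).
#' @param n_pairs number of read pairs.
#' @param read_len read length.
#' @param frag_range fragment length range (min, max).
#' @param subst_rate per-base substitution probability.
#' @param seed RNG seed.
#' @param abundance optional named per-contig relative abundance.
#' @param out1,out2 optional FASTQ paths to write.
#' @return list with `ids`, `s1`, `s2`, `read_len` (same layout as
#'   [read_fastq_pair()]).
#' @export
simulate_read_pairs <- function(assembly, n_pairs, read_len = 100L,
                                frag_range = c(250L, 500L),
                                subst_rate = 0.005, seed = 1L,
                                abundance = NULL, out1 = NULL, out2 = NULL) {
  seqs <- assembly$seq
  lens <- nchar(seqs)
  if (any(lens < frag_range[1]))
    stop("every contig must be at least the minimum fragment size")
  w <- as.numeric(lens)
  if (!is.null(abundance)) w <- w * abundance[names(seqs)]
  with_seed(seed, {
    ci <- sample.int(length(seqs), n_pairs, replace = TRUE, prob = w)
    flen <- runif_int(n_pairs, frag_range[1], frag_range[2])
    flen <- pmin(flen, lens[ci])
    s0 <- floor(stats::runif(n_pairs) * (lens[ci] - flen + 1L))  # 0-based
    s1 <- substring(seqs[ci], s0 + 1L, s0 + read_len)
    r2 <- substring(seqs[ci], s0 + flen - read_len + 1L, s0 + flen)
    s2 <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(r2)))
    # substitution errors, positions drawn in R for determinism
    nerr <- stats::rbinom(2L * n_pairs, read_len, subst_rate)
    ev_read <- rep.int(seq_len(2L * n_pairs), nerr)
    if (length(ev_read)) {
      ev_pos <- runif_int(length(ev_read), 1L, read_len)
      allr <- c(s1, s2)
      orig <- substring(allr[ev_read], ev_pos, ev_pos)
      shift <- runif_int(length(ev_read), 1L, 3L)
      bases <- c("A", "C", "G", "T")
      newb <- bases[(match(orig, bases) - 1L + shift) %% 4L + 1L]
      newb[is.na(newb)] <- "A"
      allr <- cpp_apply_substitutions(allr, ev_read, ev_pos, newb)
      s1 <- allr[seq_len(n_pairs)]
      s2 <- allr[n_pairs + seq_len(n_pairs)]
    }
    ids <- sprintf("r%07d", seq_len(n_pairs))
    if (!is.null(out1)) {
      q <- strrep("?", read_len)  # Phred+33 Q30
      w1 <- Biostrings::BStringSet(stats::setNames(s1, paste0(ids, "/1")))
      w2 <- Biostrings::BStringSet(stats::setNames(s2, paste0(ids, "/2")))
      Biostrings::writeXStringSet(w1, out1, format = "fastq",
                                  qualities = Biostrings::BStringSet(rep(q, n_pairs)))
      Biostrings::writeXStringSet(w2, out2, format = "fastq",
                                  qualities = Biostrings::BStringSet(rep(q, n_pairs)))
    }
    list(ids = ids, s1 = s1, s2 = s2, read_len = as.integer(read_len))
  })
}

#' Generate a complete synthetic benchmark
#'
#' Generates a reference supertranscriptome, injects errors, simulates
#' reads from the error-free reference, and (optionally) writes
#' `reference.fasta`, `erroneous.fasta`, `truth.tsv` and the FASTQ pair to
#' a directory.
#'
#' @param out_dir optional output directory.
#' @param n_contigs,len_range,gc passed to [generate_supertranscriptome()].
#' @param errors_per_type scalar count per error type.
#' @param n_pairs,read_len,frag_range,subst_rate passed to
#'   [simulate_read_pairs()].
#' @param seed master seed (sub-seeds are derived from it).
#' @return list with `reference`, `erroneous`, `truth`, `reads`.
#' @export
roast_simulate <- function(out_dir = NULL, n_contigs = 400L,
                           len_range = c(1000L, 3000L), gc = 0.5,
                           errors_per_type = 50L, n_pairs = 200000L,
                           read_len = 100L, frag_range = c(250L, 500L),
                           subst_rate = 0.005, seed = 1L) {
  ref <- generate_supertranscriptome(n_contigs, len_range, gc, seed = seed)
  counts <- stats::setNames(rep(as.integer(errors_per_type), 7),
                            c("incomplete", "fragmented", "chimera",
                              "missing_seq", "unsupported_insertion",
                              "translocation", "inversion"))
  counts <- counts[counts > 0]
  inj <- inject_errors(ref, counts, read_len = read_len, seed = seed + 1L)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    o1 <- file.path(out_dir, "reads_1.fastq")
    o2 <- file.path(out_dir, "reads_2.fastq")
  } else o1 <- o2 <- NULL
  reads <- simulate_read_pairs(ref, n_pairs, read_len, frag_range,
                               subst_rate, seed = seed + 2L,
                               out1 = o1, out2 = o2)
  if (!is.null(out_dir)) {
    write_fasta(ref, file.path(out_dir, "reference.fasta"))
    write_fasta(inj$assembly, file.path(out_dir, "erroneous.fasta"))
    data.table::fwrite(inj$truth, file.path(out_dir, "truth.tsv"), sep = "\t")
  }
  list(reference = ref, erroneous = inj$assembly, truth = inj$truth,
       reads = reads)
}
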