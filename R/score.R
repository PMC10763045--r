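# Recovery scoring against the injected ground truth.
#
# Fixed-if rules per error type:
#   incomplete, missing_seq     >= 90% of the deleted bases recovered, in
#                               place, in the mapped final contig
#   fragmented, translocation,  final sequence identical to the original
#   inversion                   (IUPAC codes covering the original base
#                               count as recovered)
#   unsupported_insertion       all inserted bases removed (the final
#                               contig equals the original)
#   chimera                     both constituent sequences fully restored
#                               as separate contigs

# final contigs an initial (erroneous) contig maps to
finals_of <- function(map, init_id) {
  f <- map$final_id[map$initial_id == init_id]
  setdiff(unique(f), "-")
}

# iupac-compatible full equality
seq_restored <- function(final, orig) cpp_iupac_eq(final, orig)

# locate the (unmodified) erroneous sequence inside a final contig;
# returns the 0-based offset or NA
locate_core <- function(final, core) {
  off <- cpp_find_exact(final, core)
  if (off >= 0) return(off)
  n <- nchar(core)
  if (n < 60L) return(NA_integer_)
  mid <- n %/% 2L
  probe <- substr(core, mid - 19L, mid + 20L)
  o2 <- cpp_find_exact(final, probe)
  if (o2 < 0) return(NA_integer_)
  o2 - (mid - 20L)
}

score_incomplete <- function(tr, finals, asm_seqs) {
  orig <- tr$orig_seq
  n <- nchar(orig)
  dl <- tr$pos; dr <- tr$pos2
  err <- substr(orig, dl + 1L, n - dr)
  best <- 0
  for (f in finals) {
    fseq <- asm_seqs[[f]]
    if (is.null(fseq)) next
    off <- locate_core(fseq, err)
    if (is.na(off)) next
    kl <- min(off, dl)
    rl <- if (kl > 0) cpp_match_count(fseq, orig, off - kl, dl - kl, kl) else 0L
    tr_len <- nchar(fseq) - (off + nchar(err))
    kr <- min(tr_len, dr)
    rr <- if (kr > 0) cpp_match_count(fseq, orig, off + nchar(err), n - dr, kr) else 0L
    best <- max(best, (rl + rr) / max(1L, dl + dr))
  }
  best >= 0.9
}

score_missing <- function(tr, finals, asm_seqs) {
  orig <- tr$orig_seq
  p <- tr$pos
  M <- nchar(tr$removed_seq)
  for (f in finals) {
    fseq <- asm_seqs[[f]]
    if (is.null(fseq)) next
    if (seq_restored(fseq, orig)) return(TRUE)
    flank <- substr(orig, p - 39L, p)
    off <- cpp_find_exact(fseq, flank)
    if (off < 0) next
    q <- off + 40L
    if (q + M > nchar(fseq)) next
    m <- cpp_match_count(fseq, orig, q, p, M)
    if (m >= 0.9 * M) return(TRUE)
  }
  FALSE
}

score_identical <- function(tr, finals, asm_seqs) {
  for (f in finals) {
    fseq <- asm_seqs[[f]]
    if (!is.null(fseq) && seq_restored(fseq, tr$orig_seq)) return(TRUE)
  }
  FALSE
}

# a sequence is fully recovered inside a final contig when every base of
# it matches, in order and in one block, at some offset
seq_contained <- function(piece, final) {
  if (cpp_find_exact(final, piece) >= 0) return(TRUE)
  off <- locate_core(final, piece)
  if (is.na(off) || off < 0) return(FALSE)
  n <- nchar(piece)
  off + n <= nchar(final) && cpp_match_count(final, piece, off, 0L, n) == n
}

score_chimera <- function(tr, finals, asm_seqs) {
  origs <- strsplit(tr$orig_seq, ";", fixed = TRUE)[[1]]
  pieces <- c(substr(origs[1], 1L, tr$pos),
              substr(origs[2], tr$pos2 + 1L, nchar(origs[2])))
  hit <- lapply(pieces, function(o)
    Filter(function(f) !is.null(asm_seqs[[f]]) && seq_contained(o, asm_seqs[[f]]),
           finals))
  # both producing sequences restored, on separate contigs
  length(hit[[1]]) > 0 && length(hit[[2]]) > 0 &&
    length(union(hit[[1]], hit[[2]])) >= 2 &&
    (length(setdiff(hit[[1]], hit[[2]])) > 0 ||
       length(setdiff(hit[[2]], hit[[1]])) > 0 ||
       length(intersect(hit[[1]], hit[[2]])) >= 2)
}

#' Score error recovery against the injected ground truth
#'
#' @param truths the `truth` table from [inject_errors()] (or a path to a
#'   `truth.tsv` written by [roast_simulate()]).
#' @param improved the improved `roast_assembly` (or FASTA path).
#' @param map the contig map returned by [roast_run()] (columns
#'   `initial_id`, `final_id`), or a path to its TSV.
#' @return a `data.table` with one row per error type: `type`, `n_total`,
#'   `n_fixed`, `pct`.
#' @export
score_recovery <- function(truths, improved, map) {
  if (is.character(truths)) truths <- data.table::fread(truths, sep = "\t")
  if (is.character(improved)) improved <- read_fasta(improved)
  if (is.character(map)) map <- data.table::fread(map, sep = "\t")
  truths <- data.table::as.data.table(truths)
  map <- data.table::as.data.table(map)
  asm_seqs <- as.list(improved$seq)
  known <- unique(map$initial_id)
  res <- vector("list", nrow(truths))
  for (i in seq_len(nrow(truths))) {
    tr <- as.list(truths[i])
    err_ids <- strsplit(tr$err_id, ";", fixed = TRUE)[[1]]
    missing <- setdiff(err_ids, known)
    if (length(missing))
      stop("truth references contig '", missing[1], "' absent from the map")
    finals <- unique(unlist(lapply(err_ids, finals_of, map = map)))
    fixed <- switch(tr$type,
      incomplete = score_incomplete(tr, finals, asm_seqs),
      missing_seq = score_missing(tr, finals, asm_seqs),
      fragmented = ,
      translocation = ,
      inversion = ,
      unsupported_insertion = score_identical(tr, finals, asm_seqs),
      chimera = score_chimera(tr, finals, asm_seqs),
      stop("unknown error type: ", tr$type))
    res[[i]] <- data.table::data.table(type = tr$type, fixed = fixed)
  }
  res <- data.table::rbindlist(res)
  out <- res[, .(n_total = .N, n_fixed = sum(fixed)), by = type]
  out[, pct := 100 * n_fixed / n_total]
  out[]
}

utils::globalVariables(c("pct", "n_fixed", "n_total", "type", "final_id"))
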