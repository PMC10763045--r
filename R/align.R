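# Read alignment: the built-in seed-and-extend aligner, orientation
# classification, filtering, coverage, junctions, and edge-read selection.
#
# The internal aligner is ungapped: each mate is seeded with exact k-mers
# (k = 15), the best diagonals are extended with X-drop scoring
# (match +1 / mismatch -2), and unextendable read ends are soft-clipped.
# Supertranscripts carry no introns, so reads from them need no gapped or
# spliced alignment; small indels would surface as clipped tails and be
# handled by the same signature machinery.  mapq = 40 * (1 - second/best),
# capped at 60, so a read placing equally well twice gets mapq 0.

#' Align mate pairs against an assembly with the built-in aligner
#'
#' Each mate is placed independently at its best location; a mate with no
#' seed match anywhere is reported unmapped (a row with `NA` placement).
#'
#' @param pairs read pairs from [read_fastq_pair()].
#' @param assembly a `roast_assembly`.
#' @param params a `roast_params` object.
#' @return a `data.table` with one row per mate (2 rows per pair), columns
#'   `rid`, `read_id`, `mate`, `contig`, `start` (0-based), `mlen`, `lclip`,
#'   `rclip`, `strand`, `mapq`, `score`, `read_len`, `oseq` (the read in
#'   reference orientation), mate placement columns, and `orientation`.
#' @export
align_read_pairs <- function(pairs, assembly, params = default_parameters()) {
  n <- length(pairs$ids)
  reads <- c(pairs$s1, pairs$s2)
  res <- cpp_align_reads(unname(assembly$seq), reads,
                         k = params$aligner_k,
                         min_score = params$aligner_min_score)
  dt <- data.table::data.table(
    rid = rep(seq_len(n), 2L),
    read_id = rep(pairs$ids, 2L),
    mate = rep(c(1L, 2L), each = n),
    contig = contig_ids(assembly)[res$contig],
    start = res$start, mlen = res$mlen,
    lclip = res$lclip, rclip = res$rclip,
    strand = res$strand, mapq = res$mapq, score = res$score,
    read_len = nchar(reads))
  oseq <- reads
  neg <- which(!is.na(dt$strand) & dt$strand == -1L)
  if (length(neg))
    oseq[neg] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(reads[neg])))
  dt[, oseq := oseq]
  # mate linkage: rows are (mate1 block, mate2 block) in pair order
  other <- c(seq_len(n) + n, seq_len(n))
  dt[, mate_mapped := !is.na(dt$contig[other])]
  dt[, mate_contig := dt$contig[other]]
  dt[, mate_start := dt$start[other]]
  derive_orientation(dt)
}

# orientation classes:
#   FR       proper pair (mates on one contig pointing toward each other)
#   F1F2     both mates forward on one contig
#   R1R2     both mates reverse on one contig
#   RF       tail-to-tail pair on one contig (reverse upstream of forward)
#   diff_contig   both mates mapped, different contigs (kept: island signal)
#   mate_unmapped mapped read whose mate is unmapped (kept: orphan signal)
#   unmapped      this mate did not align
derive_orientation <- function(dt) {
  n2 <- nrow(dt)
  ori <- rep("unmapped", n2)
  mapped <- !is.na(dt$contig)
  ori[mapped & !dt$mate_mapped] <- "mate_unmapped"
  both <- mapped & dt$mate_mapped
  same <- both & dt$contig == dt$mate_contig
  ori[both & !same] <- "diff_contig"
  # same-contig pairs: need the mate's strand
  idx <- which(same)
  if (length(idx)) {
    # mate strand via rid+mate join
    key <- paste0(dt$rid, "_", 3L - dt$mate)
    self_key <- paste0(dt$rid, "_", dt$mate)
    strand_by_key <- stats::setNames(dt$strand, self_key)
    ms <- strand_by_key[key[idx]]
    s <- dt$strand[idx]
    both_f <- s == 1L & ms == 1L
    both_r <- s == -1L & ms == -1L
    opp <- !(both_f | both_r)
    start_plus <- ifelse(s == 1L, dt$start[idx], dt$mate_start[idx])
    start_minus <- ifelse(s == 1L, dt$mate_start[idx], dt$start[idx])
    cls <- character(length(idx))
    cls[both_f] <- "F1F2"
    cls[both_r] <- "R1R2"
    cls[opp] <- ifelse(start_plus[opp] <= start_minus[opp], "FR", "RF")
    ori[idx] <- cls
  }
  dt[, orientation := ori]
  dt[]
}

#' Filter alignment records
#'
#' Drops unmapped rows, records with `mapq` below `min_mapq`, and both mates
#' of same-contig pairs in the removable orientation classes (`F1F2`,
#' `R1R2`, tail-to-tail `RF`).  Proper pairs, pairs split across contigs,
#' and reads with unmapped mates are kept (the latter two are needed later
#' as error signatures).  Filtering is idempotent.
#'
#' @param records alignment `data.table`.
#' @param params a `roast_params`.
#' @return the filtered `data.table`.
#' @export
filter_alignments <- function(records, params = default_parameters()) {
  records[!is.na(contig) & mapq >= params$min_mapq &
            !orientation %in% c("F1F2", "R1R2", "RF")]
}

#' Per-base coverage of one contig
#'
#' `depth[i]` counts retained records whose aligned (M) span covers base i;
#' soft-clipped and inserted bases contribute nothing, and spliced (`N`)
#' spans from ingested SAM records are subtracted.
#'
#' @param records filtered alignment records (any contig mix; subset is
#'   taken internally).
#' @param contig contig id.
#' @param contig_len contig length in bases.
#' @return integer vector of per-base depth.
#' @export
compute_coverage <- function(records, contig, contig_len) {
  cid_ <- contig
  r <- records[records$contig == cid_]
  if (nrow(r) == 0) return(integer(contig_len))
  d <- cpp_coverage(r$start, r$mlen, as.integer(contig_len))
  if ("junc" %in% names(r)) {
    for (j in r$junc) {
      if (length(j) >= 2) {
        for (g in seq(1, length(j), by = 2)) {
          gs <- j[g] + 1L; ge <- j[g + 1L]
          if (ge >= gs) d[gs:ge] <- d[gs:ge] - 1L
        }
      }
    }
  }
  d
}

#' Splice-junction positions inferred from spliced alignments
#'
#' Both the donor and acceptor reference positions of every `N` CIGAR
#' operation are collected per contig.  Records produced by the built-in
#' aligner are never spliced, so the set is empty unless alignments were
#' ingested from a splice-aware external aligner via [parse_sam()].
#'
#' @param records alignment records.
#' @return named list: contig id -> sorted integer positions (0-based).
#' @export
detect_junctions <- function(records) {
  if (!"junc" %in% names(records)) return(list())
  r <- records[!is.na(contig) & lengths(records$junc) > 0]
  if (nrow(r) == 0) return(list())
  out <- split(r$junc, r$contig)
  lapply(out, function(v) sort(unique(unlist(v))))
}

#' Select records aligned near the contig boundaries
#'
#' Keeps records whose alignment start or end lies within
#' `realign_edge_mult * read_length` of either boundary of their contig.
#' Contigs shorter than two windows keep all their records.
#'
#' @param records alignment records.
#' @param contig contig id.
#' @param contig_len contig length.
#' @param params a `roast_params`.
#' @param read_len read length in bases.
#' @return the selected records.
#' @export
select_edge_reads <- function(records, contig, contig_len, params, read_len) {
  w <- edge_window_bases(params, read_len)
  cid_ <- contig
  r <- records[records$contig == cid_]
  r[r$start < w | (r$start + r$mlen) > contig_len - w]
}

# oriented sequence for a subset of raw rows (used to pull clip fragments)
oriented_subseq <- function(rows) rows$oseq
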