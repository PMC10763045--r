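# Sequence-building primitives: clip-anchored consensus, greedy
# overlap-layout assembly, word-seeded overlap search, overlap extension,
# and overlap-based contig merging.

# R-side IUPAC tables (mirror of the C++ ones)
iupac_mask_table <- local({
  m <- integer(256)
  set <- function(ch, v) {
    m[utf8ToInt(ch)] <<- v
    m[utf8ToInt(tolower(ch))] <<- v
  }
  set("A", 1L); set("C", 2L); set("G", 4L); set("T", 8L); set("U", 8L)
  set("M", 3L); set("R", 5L); set("W", 9L); set("S", 6L); set("Y", 10L)
  set("K", 12L); set("V", 7L); set("H", 11L); set("D", 13L); set("B", 14L)
  set("N", 15L)
  m
})
iupac_char_table <- c("N", "A", "C", "M", "G", "R", "S", "V",
                      "T", "W", "Y", "H", "K", "D", "B", "N")

char_masks <- function(chars) iupac_mask_table[utf8ToInt(paste(chars, collapse = ""))]

#' Consensus sequence from anchored soft-clip fragments
#'
#' Fragments are anchored to a shared clip point by their offsets (the
#' column of each fragment's first base relative to the clip point), so
#' their mutual layout is known; the consensus is the per-column majority
#' base over the anchored stack.  Columns with tied maxima emit the IUPAC
#' code covering the tied bases; the consensus spans the maximal column
#' extent.
#'
#' @param fragments a data.frame/data.table with columns `seq` and
#'   `offset`, or a character vector (offsets then default to 0).
#' @param params a `roast_params` (currently unused; reserved).
#' @return list with `seq`, per-column `depth`, and `origin` (the offset of
#'   the first consensus column relative to the clip point).
#' @export
consensus_from_clips <- function(fragments, params = default_parameters()) {
  if (is.character(fragments))
    fragments <- data.table::data.table(seq = fragments,
                                        offset = integer(length(fragments)))
  if (nrow(fragments) == 0) stop("empty fragment list")
  if (any(nchar(fragments$seq) == 0)) stop("empty fragment")
  cpp_consensus(fragments$seq, as.integer(fragments$offset))
}

#' Greedy overlap assembly of unanchored sequences
#'
#' Repeatedly merges the pair of sequences (or growing layouts) with the
#' longest qualifying suffix-prefix overlap (at least `min_overlap` bases
#' at `min_identity_pct` identity, optionally on either strand) until no
#' pair qualifies.  Each returned sequence is the per-column majority
#' consensus of its layout, longest first; per-column depths are attached
#' as the `"layouts"` attribute.
#'
#' @param seqs character vector of input sequences.
#' @param min_overlap minimum overlap in bases.
#' @param min_identity_pct minimum overlap identity (percent).
#' @param both_strands consider reverse-complement overlaps as well.
#' @return character vector of assembled sequences, longest first.
#' @export
greedy_assemble <- function(seqs, min_overlap = 16L, min_identity_pct = 95,
                            both_strands = FALSE) {
  stopifnot(length(seqs) > 0)
  res <- cpp_greedy_assemble(seqs, as.integer(min_overlap),
                             min_identity_pct, both_strands)
  out <- vapply(res, function(x) x$seq, character(1))
  attr(out, "layouts") <- lapply(res, function(x)
    list(depth = x$depth, n_seqs = x$n_seqs))
  out
}

#' Word-seeded overlap search (ungapped)
#'
#' Finds local overlaps of a query within a set of target sequences using
#' exact 11-base word seeding and X-drop extension on the seed diagonal.
#' Hits are ungapped (`n_gaps` is always 0); reverse-strand hits are
#' reported with query coordinates on the forward query.  Hits are ranked
#' by `score = matches / query length * 100`, then leftmost subject
#' position.
#'
#' @param query query sequence (single string).
#' @param targets a `roast_assembly`, or a named character vector of target
#'   sequences.
#' @param params a `roast_params`.
#' @param both_strands search the reverse strand too.
#' @return data.table with `subject_id`, `qs`, `qe`, `ss`, `se` (0-based,
#'   inclusive), `strand`, `matches`, `length`, `identity_pct`, `n_gaps`,
#'   `score`.
#' @export
find_local_overlap <- function(query, targets, params = default_parameters(),
                               both_strands = TRUE) {
  hits <- find_local_overlap_multi(query, targets, params, both_strands)
  hits[, query := NULL]
  hits[]
}

# batch version: `queries` may be a character vector; returns a `query`
# index column.
find_local_overlap_multi <- function(queries, targets,
                                     params = default_parameters(),
                                     both_strands = TRUE) {
  tseq <- if (inherits(targets, "roast_assembly")) targets$seq else targets
  ids <- names(tseq)
  if (is.null(ids)) ids <- as.character(seq_along(tseq))
  h <- data.table::as.data.table(
    cpp_overlap_hits(queries, unname(tseq), both_strands = both_strands))
  if (nrow(h) == 0)
    return(data.table::data.table(query = integer(), subject_id = character(),
                                  qs = integer(), qe = integer(),
                                  ss = integer(), se = integer(),
                                  strand = character(), matches = integer(),
                                  length = integer(), identity_pct = numeric(),
                                  n_gaps = integer(), score = numeric()))
  qlen <- nchar(queries)[h$query]
  out <- data.table::data.table(
    query = h$query, subject_id = ids[h$subject],
    qs = h$qs, qe = h$qe, ss = h$ss, se = h$se,
    strand = ifelse(h$strand == 1L, "+", "-"),
    matches = h$matches, length = h$length,
    identity_pct = h$matches / h$length * 100,
    n_gaps = 0L,
    score = h$matches / qlen * 100)
  out <- out[n_gaps <= params$max_gaps]
  data.table::setorder(out, query, -score, subject_id, ss)
  out
}

#' Extend a seeded overlap between two contigs at relaxed identity
#'
#' Starting from the matched seed region, the overlap is grown base by base
#' in both directions while the running identity (measured from the seed
#' edge) stays at or above `extend_identity_pct`.  The seed must be a
#' forward-strand pairing; reverse-complement the second contig first for
#' minus-strand seeds.
#'
#' @param a,b contig sequences (strings).
#' @param seed list/row with `qs`, `qe` (on `a`) and `ss`, `se` (on `b`),
#'   0-based inclusive.
#' @param params a `roast_params`.
#' @return list with `a_range` and `b_range` (0-based half-open intervals)
#'   covering the maximal extended overlap.
#' @export
extend_overlap <- function(a, b, seed, params = default_parameters()) {
  idp <- params$extend_identity_pct
  lft <- cpp_extend_identity(a, b, seed$qs - 1L, seed$ss - 1L, -1L, idp)
  rgt <- cpp_extend_identity(a, b, seed$qe + 1L, seed$se + 1L, +1L, idp)
  list(a_range = c(seed$qs - lft[1], seed$qe + rgt[1] + 1L),
       b_range = c(seed$ss - lft[1], seed$se + rgt[1] + 1L))
}

# resolve two aligned sequence segments column-wise.
# Provenance 0 (assembler-original) beats 1 (read-derived); equal-provenance
# disagreements emit the IUPAC union code.
resolve_columns <- function(xa, xb, pa, pb) {
  ca <- strsplit(xa, "", fixed = TRUE)[[1]]
  cb <- strsplit(xb, "", fixed = TRUE)[[1]]
  ma <- char_masks(ca); mb <- char_masks(cb)
  pick_a <- pa < pb | (pa == pb & ma == mb)
  pick_b <- pb < pa
  un <- !(pick_a | pick_b)
  outm <- ifelse(pick_a, ma, ifelse(pick_b, mb, bitwOr(ma, mb)))
  chars <- iupac_char_table[outm + 1L]
  list(seq = paste(chars, collapse = ""), prov = pmin(pa, pb))
}

#' Merge two contigs across a terminal overlap
#'
#' The overlap must be terminal: it ends at the 3' end of `a` and starts at
#' the 5' end of `b`.  Overlapping column disagreements are resolved in
#' favour of the base with assembler-original provenance (a proxy for read
#' support); ties emit the IUPAC union code.  Merged length is
#' `|a| + |b| - overlap`.
#'
#' @param a,b sequences.
#' @param overlap result of [extend_overlap()].
#' @param prov_a,prov_b per-base provenance vectors (default all-original).
#' @return list with `seq` and `prov` of the merged contig.
#' @export
merge_by_overlap <- function(a, b, overlap,
                             prov_a = integer(nchar(a)),
                             prov_b = integer(nchar(b))) {
  ar <- overlap$a_range; br <- overlap$b_range
  if (ar[2] - ar[1] <= 0) stop("zero-length overlap")
  if (ar[2] != nchar(a) || br[1] != 0L)
    stop("overlap is not terminal (must end at 3' of a, start at 5' of b)")
  ov <- resolve_columns(substr(a, ar[1] + 1L, ar[2]),
                        substr(b, br[1] + 1L, br[2]),
                        prov_a[(ar[1] + 1L):ar[2]],
                        prov_b[(br[1] + 1L):br[2]])
  list(seq = paste0(substr(a, 1L, ar[1]), ov$seq,
                    substr(b, br[2] + 1L, nchar(b))),
       prov = c(prov_a[seq_len(ar[1])], ov$prov,
                prov_b[seq2(br[2] + 1L, nchar(b))]))
}

# safe ascending-only seq
seq2 <- function(from, to) if (from > to) integer() else seq.int(from, to)
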