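# Repair operations, one per detected signature class.
#
# Each fixer is a pure function of sequences, signatures and parameters;
# the pipeline driver applies the result to the assembly and emits the
# corresponding change events.  Length accounting per fix:
#   clip/orphan extension   adds  |consensus| - |replaced unsupported tail|
#   overlap merge           loses exactly the overlap length
#   translocation/inversion preserves total length
#   insertion removal       deletes exactly the clip-point distance

#' Extend a contig with an edge-clip consensus
#'
#' Prepends (left cluster) or appends (right cluster) the consensus built
#' from outward clipped fragments.  Contig bases between the pooled clip
#' point and the boundary are unsupported and are replaced by the
#' consensus columns covering them.
#'
#' @param contig contig sequence.
#' @param cluster an edge cluster from [find_edge_clip_clusters()].
#' @param consensus a (possibly depth-trimmed) consensus list with `seq`
#'   and `origin` relative to the clip point.
#' @param prov per-base provenance of `contig`.
#' @return list with `seq`, `prov`, `gain` (signed length change),
#'   `replaced` (bases overwritten), or `NULL` when the consensus gains
#'   nothing.
#' @export
extend_with_clips <- function(contig, cluster, consensus,
                              prov = integer(nchar(contig))) {
  n <- nchar(contig)
  len <- nchar(consensus$seq)
  if (len == 0) return(NULL)
  if (cluster$direction == "left") {
    # consensus columns span [origin, origin+len) relative to clip point
    keep_from <- cluster$position + consensus$origin + len  # 0-based
    if (keep_from < 0 || keep_from >= n) return(NULL)
    gain <- len - keep_from
    if (gain <= 0) return(NULL)
    seq <- paste0(consensus$seq, substr(contig, keep_from + 1L, n))
    prov2 <- c(rep(1L, len), prov[seq2(keep_from + 1L, n)])
  } else {
    repl_from <- cluster$position + consensus$origin     # 0-based
    if (repl_from <= 0 || repl_from > n) return(NULL)
    gain <- len - (n - repl_from)
    if (gain <= 0) return(NULL)
    seq <- paste0(substr(contig, 1L, repl_from), consensus$seq)
    prov2 <- c(prov[seq2(1L, repl_from)], rep(1L, len))
  }
  list(seq = seq, prov = prov2, gain = gain,
       replaced = nchar(contig) + gain - len, side = cluster$direction)
}

#' Assemble orphan mates and stitch the block to the contig edge
#'
#' The unmapped mates (already reverse-complemented into contig
#' orientation by the caller) are assembled with [greedy_assemble()]; the
#' longest block is depth-trimmed and stitched to the contig end across
#' the best suffix-prefix overlap.  An extension is accepted only when it
#' grows the contig by at least `min_orphan_extension_pct` percent of the
#' read length; with no overlap the block is returned for addition as a
#' separate (pending) contig.
#'
#' @param contig contig sequence.
#' @param cluster an orphan cluster from [find_orphan_mate_clusters()].
#' @param orphan_mates character vector of oriented mate sequences.
#' @param params a `roast_params`.
#' @param read_len read length.
#' @param prov contig provenance.
#' @return list with `action` (`"stitched"`, `"new_contig"` or `"none"`),
#'   and for stitches `seq`/`prov`/`gain`, for new contigs `block`.
#' @export
extend_with_orphans <- function(contig, cluster, orphan_mates, params,
                                read_len, prov = integer(nchar(contig))) {
  blocks <- greedy_assemble(orphan_mates, min_overlap = 16L,
                            min_identity_pct = 95)
  lay <- attr(blocks, "layouts")
  block <- NULL
  for (i in seq_along(blocks)) {
    d <- lay[[i]]$depth
    keep <- which(d >= 2L)
    cand <- if (length(keep)) substr(blocks[i], min(keep), max(keep)) else blocks[i]
    if (nchar(cand) >= read_len) { block <- cand; break }
  }
  if (is.null(block)) return(list(action = "none"))
  n <- nchar(contig)
  min_gain <- params$min_orphan_extension_pct / 100 * read_len
  if (cluster$edge == "right") {
    ov <- cpp_sp_overlap(contig, block, params$min_island_overlap,
                         params$extend_identity_pct)
    if (ov[1] > 0) {
      gain <- nchar(block) - ov[1]
      if (gain < min_gain) return(list(action = "none"))
      m <- merge_by_overlap(contig, block,
                            list(a_range = c(n - ov[1], n),
                                 b_range = c(0L, ov[1])),
                            prov, rep(1L, nchar(block)))
      return(list(action = "stitched", seq = m$seq, prov = m$prov, gain = gain))
    }
  } else {
    ov <- cpp_sp_overlap(block, contig, params$min_island_overlap,
                         params$extend_identity_pct)
    if (ov[1] > 0) {
      gain <- nchar(block) - ov[1]
      if (gain < min_gain) return(list(action = "none"))
      m <- merge_by_overlap(block, contig,
                            list(a_range = c(nchar(block) - ov[1], nchar(block)),
                                 b_range = c(0L, ov[1])),
                            rep(1L, nchar(block)), prov)
      return(list(action = "stitched", seq = m$seq, prov = m$prov, gain = gain))
    }
  }
  list(action = "new_contig", block = block)
}

# ---- terminal merge machinery ----------------------------------------------

# Try to merge contig `ida` (at `side`) with a partner found by searching
# its terminal seed across the assembly.  Returns NULL or a description of
# the merge: list(id_a, id_b, order, seq, prov, overlap_len).
attempt_clip_merge <- function(asm, ida, side, params) {
  a <- asm$seq[[ida]]
  na <- nchar(a)
  sl <- params$seed_len
  if (na < sl) return(NULL)
  qseq <- if (side == "right") substr(a, na - sl + 1L, na) else substr(a, 1L, sl)
  others <- setdiff(contig_ids(asm), ida)
  if (!length(others)) return(NULL)
  hits <- find_local_overlap(qseq, asm$seq[others], params)
  hits <- hits[identity_pct >= params$seed_identity_pct & length == sl]
  if (nrow(hits) == 0) return(NULL)
  hit <- hits[1]   # max score, then leftmost
  idb <- hit$subject_id
  b <- asm$seq[[idb]]
  pb <- asm$prov[[idb]]
  if (hit$strand == "-") {
    rb <- revcomp_with_prov(b, pb)
    b <- rb$seq; pb <- rb$prov
    nb <- nchar(b)
    s0 <- nb - 1L - hit$se; e0 <- nb - 1L - hit$ss
    hit$ss <- s0; hit$se <- e0
  }
  pa <- asm$prov[[ida]]
  if (side == "right") {
    seed <- list(qs = na - sl + hit$qs, qe = na - sl + hit$qe,
                 ss = hit$ss, se = hit$se)
    ov <- extend_overlap(a, b, seed, params)
    if (ov$a_range[2] != na || ov$b_range[1] != 0L) return(NULL)
    m <- merge_by_overlap(a, b, ov, pa, pb)
    list(id_a = ida, id_b = idb, order = c(ida, idb), seq = m$seq,
         prov = m$prov, overlap_len = ov$a_range[2] - ov$a_range[1],
         strand = hit$strand)
  } else {
    seed_a <- list(qs = hit$qs, qe = hit$qe, ss = hit$ss, se = hit$se)
    ov <- extend_overlap(a, b, seed_a, params)
    if (ov$a_range[1] != 0L || ov$b_range[2] != nchar(b)) return(NULL)
    m <- merge_by_overlap(b, a,
                          list(a_range = ov$b_range, b_range = ov$a_range),
                          pb, pa)
    list(id_a = ida, id_b = idb, order = c(idb, ida), seq = m$seq,
         prov = m$prov, overlap_len = ov$a_range[2] - ov$a_range[1],
         strand = hit$strand)
  }
}

# Try to merge a linked island pair across a terminal overlap at the
# island edges.  `isl` comes from find_mate_islands().
attempt_island_merge <- function(asm, isl, params, read_len) {
  ida <- isl$contig; idb <- isl$partner
  if (!ida %in% contig_ids(asm) || !idb %in% contig_ids(asm)) return(NULL)
  a <- asm$seq[[ida]]; b <- asm$seq[[idb]]
  na <- nchar(a)
  w <- min(edge_window_bases(params, read_len), na)
  qseq <- if (isl$edge == "right") substr(a, na - w + 1L, na) else substr(a, 1L, w)
  hits <- find_local_overlap(qseq, asm$seq[idb], params)
  if (nrow(hits) == 0) return(NULL)
  slack <- params$island_edge_slack_pct / 100 * read_len
  pa <- asm$prov[[ida]]
  for (hi in seq_len(min(nrow(hits), 5L))) {
    hit <- hits[hi]
    bb <- b; pbb <- asm$prov[[idb]]
    if (hit$strand == "-") {
      rb <- revcomp_with_prov(bb, pbb)
      bb <- rb$seq; pbb <- rb$prov
      nb <- nchar(bb)
      s0 <- nb - 1L - hit$se; e0 <- nb - 1L - hit$ss
      hit$ss <- s0; hit$se <- e0
    }
    off <- if (isl$edge == "right") na - w else 0L
    seed <- list(qs = off + hit$qs, qe = off + hit$qe, ss = hit$ss, se = hit$se)
    ov <- extend_overlap(a, bb, seed, params)
    ov_len <- ov$a_range[2] - ov$a_range[1]
    if (ov_len < params$min_island_overlap) next
    m_cnt <- cpp_match_count(a, bb, ov$a_range[1], ov$b_range[1], ov_len)
    if (m_cnt / ov_len * 100 < params$island_overlap_score) next
    if (isl$edge == "right") {
      if (ov$a_range[2] != na || ov$b_range[1] != 0L) next
      if (abs(ov$a_range[1] - isl$outer) > slack) next
      m <- merge_by_overlap(a, bb, ov, pa, pbb)
      return(list(id_a = ida, id_b = idb, order = c(ida, idb), seq = m$seq,
                  prov = m$prov, overlap_len = ov_len, strand = hit$strand))
    } else {
      if (ov$a_range[1] != 0L || ov$b_range[2] != nchar(bb)) next
      if (abs(ov$a_range[2] - isl$outer) > slack) next
      m <- merge_by_overlap(bb, a,
                            list(a_range = ov$b_range, b_range = ov$a_range),
                            pbb, pa)
      return(list(id_a = ida, id_b = idb, order = c(idb, ida), seq = m$seq,
                  prov = m$prov, overlap_len = ov_len, strand = hit$strand))
    }
  }
  NULL
}

#' Merge a clip-extended contig with its overlap partner
#'
#' The terminal `seed_len` bases of the freshly extended end are used as a
#' query across the whole assembly; a full-length hit at
#' `seed_identity_pct` identity is required, the best-scoring hit is
#' extended at `extend_identity_pct`, and the contigs are merged when the
#' extended overlap is terminal on both.
#'
#' @param assembly a `roast_assembly`.
#' @param extended_contig id of the contig extended in the inner loop.
#' @param side which end was extended (`"left"` or `"right"`).
#' @param params a `roast_params`.
#' @return list with the updated `assembly` and a `merge` description (or
#'   `NULL` when no qualifying partner exists).
#' @export
merge_fragments_by_clip <- function(assembly, extended_contig,
                                    side = "right",
                                    params = default_parameters()) {
  m <- attempt_clip_merge(assembly, extended_contig, side, params)
  if (is.null(m)) return(list(assembly = assembly, merge = NULL))
  list(assembly = apply_merge(assembly, m), merge = m)
}

#' Merge the two contigs of a linked read/mate island pair
#'
#' A merge requires a terminal overlap of at least `min_island_overlap`
#' bases scoring at least `island_overlap_score`, starting within
#' `island_edge_slack_pct` percent of the read length from the island's
#' outer edge.
#'
#' @param assembly a `roast_assembly`.
#' @param island_pair a linked island from [find_mate_islands()].
#' @param params a `roast_params`.
#' @param read_len read length.
#' @return list with the updated `assembly` and a `merge` description.
#' @export
merge_fragments_by_islands <- function(assembly, island_pair,
                                       params = default_parameters(),
                                       read_len = 100L) {
  m <- attempt_island_merge(assembly, island_pair, params, read_len)
  if (is.null(m)) return(list(assembly = assembly, merge = NULL))
  list(assembly = apply_merge(assembly, m), merge = m)
}

merged_id <- function(order) paste(order, collapse = "+")

apply_merge <- function(asm, m) {
  newid <- merged_id(m$order)
  asm <- asm_drop(asm, c(m$id_a, m$id_b))
  asm_add(asm, newid, m$seq, m$prov)
}

# ---- chimera splitting ------------------------------------------------------

# Split `contig` at 0-based position p; the smaller piece is searched
# against the larger: a hit scoring >= internal_identity_pct marks it a
# self-chimera duplicate (removed); otherwise it becomes a new contig when
# >= min_new_contig_len, or is discarded.
split_at_position <- function(contig, p, params, prov = integer(nchar(contig))) {
  n <- nchar(contig)
  if (p <= 0 || p >= n) return(NULL)
  left <- substr(contig, 1L, p); right <- substr(contig, p + 1L, n)
  pl <- prov[seq_len(p)]; pr <- prov[seq2(p + 1L, n)]
  if (nchar(left) >= nchar(right)) {
    big <- left; pbig <- pl; small <- right; psmall <- pr; small_side <- "right"
  } else {
    big <- right; pbig <- pr; small <- left; psmall <- pl; small_side <- "left"
  }
  disp <- "new_contig"
  if (nchar(small) >= 12L) {
    hits <- find_local_overlap(small, c(big = big), params)
    if (nrow(hits) && hits$score[1] >= params$internal_identity_pct)
      disp <- "self_chimera"
  }
  if (disp == "new_contig" && nchar(small) < params$min_new_contig_len)
    disp <- "discarded"
  list(position = p, big = big, prov_big = pbig, small = small,
       prov_small = psmall, small_side = small_side, small_disposition = disp)
}

#' Split a contig at an internal clip site
#'
#' If the site consensus occurs elsewhere in the contig at
#' `internal_identity_pct` or better, the region between the hit and the
#' clip point is excised and the flanks rejoined across their maximal
#' exact overlap (self-chimera repeat removal).  Otherwise the contig is
#' split at the clip point and the smaller piece is classified: a
#' self-chimera duplicate (removed), a new contig (length at least
#' `min_new_contig_len`), or discarded.
#'
#' @param contig contig sequence.
#' @param site a one-sided site from [find_internal_clip_sites()] (or a
#'   crisscross site routed here when its consensi neither hit elsewhere
#'   nor merge into a missing fragment).
#' @param params a `roast_params`.
#' @param prov contig provenance.
#' @return an action list: either `mode = "excised"` with the repaired
#'   `seq`/`prov` and the `removed` segment, or `mode = "split"` with the
#'   result of the split and smaller-piece disposition; `NULL` when the
#'   site is unusable.
#' @export
split_chimera_at_clip <- function(contig, site, params = default_parameters(),
                                  prov = integer(nchar(contig))) {
  p <- if (!is.na(site$pos_right)) site$pos_right else site$pos_left
  cons <- if (!is.na(site$pos_right)) site$right_consensus else site$left_consensus
  n <- nchar(contig)
  if (!is.null(cons) && nchar(cons$seq) >= params$min_internal_consensus) {
    hits <- find_local_overlap(cons$seq, c(self = contig), params)
    hits <- hits[score >= params$internal_identity_pct &
                   identity_pct >= params$internal_identity_pct]
    if (nrow(hits)) {
      hit <- hits[1]
      if (hit$ss >= p) { from <- p; to <- hit$ss }          # region [from, to)
      else if (hit$se < p) { from <- hit$se + 1L; to <- p }
      else { from <- NA }
      if (!is.na(from) && to > from) {
        lf <- substr(contig, 1L, from); rf <- substr(contig, to + 1L, n)
        ovl <- cpp_sp_overlap(lf, rf, 1L, 100)[1]
        seq <- paste0(lf, substr(rf, ovl + 1L, nchar(rf)))
        prov2 <- c(prov[seq2(1L, from)], prov[seq2(to + 1L + ovl, n)])
        return(list(mode = "excised", seq = seq, prov = prov2,
                    removed = substr(contig, from + 1L, to),
                    coords = c(from, to)))
      }
    }
  }
  sp <- split_at_position(contig, p, params, prov)
  if (is.null(sp)) return(NULL)
  c(list(mode = "split"), sp)
}

#' Split a contig at a coverage break
#'
#' @param contig contig sequence.
#' @param brk one row of [find_abrupt_breaks()] / [find_gradual_breaks()].
#' @param params a `roast_params`.
#' @param prov contig provenance.
#' @return a `mode = "split"` action list as in [split_chimera_at_clip()].
#' @export
split_chimera_at_coverage <- function(contig, brk,
                                      params = default_parameters(),
                                      prov = integer(nchar(contig))) {
  sp <- split_at_position(contig, brk$position, params, prov)
  if (is.null(sp)) return(NULL)
  c(list(mode = "split"), sp)
}

# ---- local mis-assemblies ---------------------------------------------------

# Trim flank contamination from a crisscross consensus.  The right-dir
# consensus is anchored at p and may end with bases that simply continue
# the contig at p; the left-dir consensus may begin with bases that
# precede p.  The longest positionally matching flank (>= min_keep bases
# at >= min_id identity) is removed.
trim_flank_right_cons <- function(cons_seq, contig, p, min_id = 90, min_keep = 8L) {
  len <- nchar(cons_seq)
  for (j in seq2(0L, len - min_keep)) {
    sl <- len - j
    m <- cpp_match_count(cons_seq, contig, j, p, sl)
    eff <- min(sl, nchar(contig) - p)
    if (eff >= min_keep && m / eff * 100 >= min_id)
      return(substr(cons_seq, 1L, j))
  }
  cons_seq
}
trim_flank_left_cons <- function(cons_seq, contig, p, min_id = 90, min_keep = 8L) {
  len <- nchar(cons_seq)
  for (j in rev(seq2(min_keep, len))) {   # j = prefix length to test
    if (p - j < 0) next
    m <- cpp_match_count(cons_seq, contig, 0L, p - j, j)
    if (m / j * 100 >= min_id)
      return(substr(cons_seq, j + 1L, len))
  }
  cons_seq
}

#' Reconstruct sequence missing at a crisscross clip site
#'
#' Both consensi are trimmed of flank contamination; the trimmed
#' right-direction consensus (the start of the missing fragment) and the
#' trimmed left-direction consensus (its end) are merged across their
#' overlap and the result is inserted at the clip point.  When no overlap
#' of at least `min_island_overlap` bases exists the site is not treated
#' as missing sequence (the caller then routes it to chimera splitting).
#'
#' @param contig contig sequence.
#' @param site a crisscross site whose consensi have no hit elsewhere in
#'   the contig.
#' @param params a `roast_params`.
#' @param prov contig provenance.
#' @param verify optional predicate run on each candidate fix; the first
#'   accepted candidate is returned.
#' @return list with `seq`, `prov`, `inserted` and `position`, or `NULL`
#'   when the consensi do not overlap.
#' @export
fix_missing_sequence <- function(contig, site, params = default_parameters(),
                                 prov = integer(nchar(contig)),
                                 verify = NULL) {
  pr <- site$pos_right; pl <- site$pos_left
  crt <- trim_flank_right_cons(site$right_consensus$seq, contig, pr)
  clt <- trim_flank_left_cons(site$left_consensus$seq, contig, pl)
  if (nchar(crt) == 0 || nchar(clt) == 0) return(NULL)
  n <- nchar(contig)
  # the left block ends with the missing fragment, the right block starts
  # with it; merging the two across their overlap re-anchors the junction
  # exactly even when the two clip points jitter by a base or two
  lblock <- paste0(substr(contig, 1L, pl), clt)
  rblock <- paste0(crt, substr(contig, pr + 1L, n))
  ov <- cpp_sp_overlap(lblock, rblock, params$min_island_overlap,
                       params$internal_identity_pct)
  if (ov[1] == 0) return(NULL)
  if (ov[1] > nchar(clt) + nchar(crt) + 2L * POOL_TOL) return(NULL)
  seq <- paste0(lblock, substr(rblock, ov[1] + 1L, nchar(rblock)))
  delta <- nchar(seq) - n
  if (delta <= 0) return(NULL)
  ins <- substr(seq, pl + 1L, pl + delta)
  # consensus noise can leave a few junk bases at either end of the
  # reconstructed fragment; candidate head/tail trims are arbitrated by
  # the caller's read-support verifier
  grid <- expand.grid(ht = 0:4, tt = 0:4)
  grid <- grid[order(grid$ht + grid$tt), ]
  for (g in seq_len(nrow(grid))) {
    ins2 <- substr(ins, grid$ht[g] + 1L, nchar(ins) - grid$tt[g])
    if (nchar(ins2) < params$min_internal_consensus) next
    fx <- list(seq = paste0(substr(contig, 1L, pl), ins2,
                            substr(contig, pl + 1L, n)),
               prov = c(prov[seq2(1L, pl)], rep(1L, nchar(ins2)),
                        prov[seq2(pl + 1L, n)]),
               inserted = ins2, position = pl)
    if (is.null(verify) || verify(fx)) return(fx)
  }
  NULL
}

#' Re-place a translocated or inverted fragment at its clip site
#'
#' The two consensus hits locate the displaced fragment (the
#' right-direction consensus matches its start, the left-direction
#' consensus its end; for minus-strand hits the roles reverse).  The
#' combined span is excised and re-inserted at the clip point,
#' reverse-complemented for minus-strand hits.  Total length is preserved.
#'
#' @param contig contig sequence.
#' @param site a crisscross site.
#' @param hits named list with `right` and `left` hit rows (from
#'   [find_local_overlap()] of the trimmed consensi against the contig)
#'   and, optionally, `right_seq`/`left_seq`, the trimmed consensi used
#'   to refine the fragment boundaries.
#' @param params a `roast_params`.
#' @param prov contig provenance.
#' @param verify optional predicate run on each candidate fix; the first
#'   accepted candidate is returned.
#' @return list with `seq`, `prov`, `span`, `strand`, or `NULL` for
#'   inconsistent hit geometry.
#' @export
fix_translocation_inversion <- function(contig, site, hits,
                                        params = default_parameters(),
                                        prov = integer(nchar(contig)),
                                        verify = NULL) {
  hr <- hits$right; hl <- hits$left
  if (is.null(hr) || is.null(hl)) return(NULL)
  n <- nchar(contig)
  idp <- params$internal_identity_pct
  refine <- function(q, pos0, end_side) {
    lq <- nchar(q)
    best <- pos0; bfrac <- -1
    for (d in -8L:8L) {
      a0 <- if (end_side) pos0 + d - lq else pos0 + d
      if (a0 < 0 || a0 + lq > n) next
      fr <- cpp_match_count(q, contig, 0L, a0, lq) / lq
      if (fr > bfrac) { bfrac <- fr; best <- pos0 + d }
    }
    if (bfrac * 100 >= idp) best else NA_integer_
  }
  if (hr$strand != hl$strand)
    return(fix_inversion_mixed(contig, site, hits, params, prov, verify,
                               refine, n))
  # geometry: the two hits must bracket the displaced fragment consistently
  if (hr$strand == "+") {
    if (!(hr$ss <= hl$ss && hr$se <= hl$se)) return(NULL)
  } else {
    if (!(hl$ss <= hr$ss && hl$se <= hr$se)) return(NULL)
  }
  p <- site$pos_right
  from <- min(hr$ss, hl$ss); to <- max(hr$se, hl$se) + 1L  # [from, to)
  # hit extension can stop a base or two short of the true fragment
  # boundary; refine both ends by positional best-offset matching of the
  # consensus that anchors each boundary
  if (!is.null(hits$right_seq) && !is.null(hits$left_seq)) {
    if (hr$strand == "+") {
      from <- refine(hits$right_seq, from, end_side = FALSE)
      to <- refine(hits$left_seq, to, end_side = TRUE)
    } else {
      from <- refine(cpp_revcomp(hits$left_seq), from, end_side = FALSE)
      to <- refine(cpp_revcomp(hits$right_seq), to, end_side = TRUE)
    }
    if (is.na(from) || is.na(to)) return(NULL)
  }
  # Chance-matched junction bases are invisible to consensus evidence:
  # when the first bases of the displaced fragment happen to equal the
  # sequence that follows the clip point, every read extends over them,
  # shifting the clip point and the measured fragment boundary inward by
  # the same run.  The run length cannot be recovered from the sequence
  # alone (the same chance process governs both), so candidate slide
  # amounts along each IUPAC-equal run are enumerated and the caller's
  # read-support verifier arbitrates; candidates whose two slid junction
  # estimates agree are tried first.
  pr0 <- site$pos_right; pl0 <- site$pos_left
  cc <- strsplit(contig, "", fixed = TRUE)[[1]]
  eq <- function(i, j) i >= 1 && j >= 1 && i <= n && j <= n &&
    bitwAnd(iupac_mask_table[utf8ToInt(cc[i])],
            iupac_mask_table[utf8ToInt(cc[j])]) > 0
  comp_eq <- function(i, j) {
    if (i < 1 || j < 1 || i > n || j > n) return(FALSE)
    mi <- iupac_mask_table[utf8ToInt(cc[i])]
    mj <- iupac_mask_table[utf8ToInt(cc[j])]
    rj <- bitwOr(bitwOr(ifelse(bitwAnd(mj, 1L) > 0, 8L, 0L),
                        ifelse(bitwAnd(mj, 2L) > 0, 4L, 0L)),
                 bitwOr(ifelse(bitwAnd(mj, 4L) > 0, 2L, 0L),
                        ifelse(bitwAnd(mj, 8L) > 0, 1L, 0L)))
    bitwAnd(mi, rj) > 0
  }
  cap <- 12L
  run_len <- function(step_ok) {
    j <- 0L
    while (j < cap && step_ok(j)) j <- j + 1L
    j
  }
  if (hr$strand == "+") {
    r1 <- run_len(function(j) eq(pr0 - j, from - j))
    r2 <- run_len(function(j) eq(pl0 + 1L + j, to + 1L + j))
  } else {
    r1 <- run_len(function(j) comp_eq(pr0 - j, to + 1L + j))
    r2 <- run_len(function(j) comp_eq(pl0 + 1L + j, from - j))
  }
  from0 <- from; to0 <- to
  cand <- expand.grid(j1 = seq2(max(0L, r1 - 4L), r1),
                      j2 = seq2(max(0L, r2 - 4L), r2))
  if (hr$strand == "+") {
    cand$pr <- pr0 - cand$j1; cand$from <- from0 - cand$j1
    cand$pl <- pl0 + cand$j2; cand$to <- to0 + cand$j2
  } else {
    cand$pr <- pr0 - cand$j1; cand$to <- to0 + cand$j1
    cand$pl <- pl0 + cand$j2; cand$from <- from0 - cand$j2
  }
  cand <- cand[abs(cand$pr - cand$pl) <= 2L, ]
  if (nrow(cand) == 0) return(NULL)
  cand <- cand[order(abs(cand$pr - cand$pl), -(cand$j1 + cand$j2)), ]
  for (ci in seq_len(nrow(cand))) {
    fx <- build_ti_fix(contig, prov, cand$from[ci], cand$to[ci],
                       cand$pr[ci], hr$strand, n)
    if (is.null(fx)) next
    if (is.null(verify) || verify(fx)) return(fx)
  }
  return(NULL)
}

# assemble the repaired sequence for a translocation/inversion candidate:
# excise [from, to), reverse-complement for minus-strand hits, re-insert
# at clip point p; total length is preserved
build_ti_fix <- function(contig, prov, from, to, p, strand, n) {
  if (from < 0L || to > n) return(NULL)
  if (from >= to || to - from > n - (to - from)) return(NULL)
  if (p > from && p < to) return(NULL)                     # span contains site
  frag <- substr(contig, from + 1L, to)
  pf <- prov[seq2(from + 1L, to)]
  if (strand == "-") {
    rf <- revcomp_with_prov(frag, pf)
    frag <- rf$seq; pf <- rf$prov
  }
  rest <- paste0(substr(contig, 1L, from), substr(contig, to + 1L, n))
  prest <- c(prov[seq2(1L, from)], prov[seq2(to + 1L, n)])
  p2 <- if (from < p) p - (to - from) else p
  if (p2 < 0L || p2 > nchar(rest)) return(NULL)
  # position, in the repaired sequence, of the junction created by the
  # excision (used by the caller to verify the fix against the reads)
  exc_junction <- if (from < p) from else to
  list(seq = paste0(substr(rest, 1L, p2), frag,
                    substr(rest, p2 + 1L, nchar(rest))),
       prov = c(prest[seq2(1L, p2)], pf, prest[seq2(p2 + 1L, nchar(rest))]),
       span = c(from, to), strand = strand, insert_at = p2,
       insert_pre = p, exc_junction = exc_junction)
}

# Mixed-strand crisscross at an inverted block's junction: the
# forward-strand consensus hit locates where the displaced original
# continuation resumes (the far end of the reverse-complemented block),
# the reverse-strand hit locates the removal junction.  Candidate
# boundary jitters are arbitrated by the caller's read-support verifier.
fix_inversion_mixed <- function(contig, site, hits, params, prov, verify,
                                refine, n) {
  hr <- hits$right; hl <- hits$left
  if (is.null(hits$right_seq) || is.null(hits$left_seq)) return(NULL)
  q <- site$pos_right
  if (hr$strand == "+") {
    # block extends right from the site; CL (reverse) marks the insert
    to0 <- refine(hits$right_seq, hr$ss, end_side = FALSE)
    p0 <- refine(cpp_revcomp(hits$left_seq), hl$ss, end_side = FALSE)
    from0 <- q
  } else {
    # block ends at the site; CR (reverse) marks the insert point
    from0 <- refine(hits$left_seq, hl$se + 1L, end_side = TRUE)
    p0 <- refine(cpp_revcomp(hits$right_seq), hr$se + 1L, end_side = TRUE)
    to0 <- q
  }
  if (is.na(from0) || is.na(to0) || is.na(p0)) return(NULL)
  grid <- expand.grid(df = -2:2, dt = -2:2, dp = -2:2)
  grid <- grid[order(abs(grid$df) + abs(grid$dt) + abs(grid$dp)), ]
  for (g in seq_len(nrow(grid))) {
    fx <- build_ti_fix(contig, prov, from0 + grid$df[g], to0 + grid$dt[g],
                       p0 + grid$dp[g], "-", n)
    if (is.null(fx)) next
    if (is.null(verify) || verify(fx)) return(fx)
  }
  NULL
}

#' Remove an unsupported insertion flagged by facing clips
#'
#' The right-direction consensus (at the upstream clip point) must map
#' immediately after the downstream clip point and the left-direction
#' consensus immediately before the upstream one (cross-mapping); the
#' between-clip segment, whose length equals the clip-point distance, is
#' then removed.
#'
#' @param contig contig sequence.
#' @param site a facing site from [find_internal_clip_sites()].
#' @param params a `roast_params`.
#' @param prov contig provenance.
#' @param verify optional predicate run on each candidate fix (best match
#'   first); the first candidate it accepts is returned.
#' @return list with `seq`, `prov`, `removed` and `coords`, or `NULL` when
#'   the cross-mapping precondition fails.
#' @export
remove_unsupported_insertion <- function(contig, site,
                                         params = default_parameters(),
                                         prov = integer(nchar(contig)),
                                         verify = NULL) {
  p1 <- site$pos_right; p2 <- site$pos_left
  if (is.na(p1) || is.na(p2) || p2 <= p1) return(NULL)
  n <- nchar(contig)
  cr <- site$right_consensus$seq; cl <- site$left_consensus$seq
  idp <- params$internal_identity_pct
  lr <- min(nchar(cr), n - p2)
  ll <- min(nchar(cl), p1)
  if (lr < 8L || ll < 8L) return(NULL)
  # clip points jitter inward when the inserted segment's boundary bases
  # happen to match the true continuation; search a small offset window
  # for the positions where the consensi really map.  The right consensus
  # locates the removal end (where the true continuation resumes), the
  # left consensus end locates the removal start.
  cand_off <- function(score_fn) {
    d <- -8L:8L
    fr <- vapply(d, score_fn, numeric(1))
    ok <- !is.na(fr) & fr * 100 >= idp
    data.frame(d = d[ok], fr = fr[ok])
  }
  crs <- cand_off(function(d) {
    if (p2 + d < 0 || p2 + d + lr > n) return(NA_real_)
    cpp_match_count(cr, contig, 0L, p2 + d, lr) / lr
  })
  cls <- cand_off(function(d) {
    if (p1 + d - ll < 0 || p1 + d > n) return(NA_real_)
    cpp_match_count(cl, contig, nchar(cl) - ll, p1 + d - ll, ll) / ll
  })
  if (nrow(crs) == 0 || nrow(cls) == 0) return(NULL)
  # candidate removal intervals, best-matching first; the caller-supplied
  # verifier (read support across the healed junction) arbitrates ties
  cand <- expand.grid(il = seq_len(nrow(cls)), ir = seq_len(nrow(crs)))
  cand$a <- p1 + cls$d[cand$il]
  cand$b <- p2 + crs$d[cand$ir]
  cand$fr <- cls$fr[cand$il] + crs$fr[cand$ir]
  # chance-runs at either anchor consume the first bases of the true
  # continuation, displacing one measured boundary outward; offer the
  # corresponding slid-in variants as well and let the read-support
  # verifier arbitrate
  base <- cand[, c("a", "b", "fr")]
  grid <- expand.grid(i = 0:4, j = 0:4)
  cand <- do.call(rbind, lapply(seq_len(nrow(grid)), function(g) {
    data.frame(a = base$a + grid$i[g], b = base$b - grid$j[g],
               fr = base$fr - (grid$i[g] + grid$j[g]) / 100)
  }))
  cand <- cand[cand$b > cand$a & cand$b - cand$a <= 2L * (p2 - p1) + 16L, ]
  cand <- cand[!duplicated(cand[, c("a", "b")]), ]
  if (nrow(cand) == 0) return(NULL)
  # the clip modal points are usually within a few bases of the truth;
  # try near candidates first and let the read-support verifier decide
  cand <- cand[order(abs(cand$a - p1) + abs(cand$b - p2), -cand$fr), ]
  for (ci in seq_len(min(nrow(cand), 30L))) {
    a <- cand$a[ci]; b <- cand$b[ci]
    fx <- list(seq = paste0(substr(contig, 1L, a), substr(contig, b + 1L, n)),
               prov = c(prov[seq2(1L, a)], prov[seq2(b + 1L, n)]),
               removed = substr(contig, a + 1L, b), coords = c(a, b))
    if (is.null(verify) || verify(fx)) return(fx)
  }
  NULL
}
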