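# Error-signature detection on filtered alignments: outward edge clips,
# orphan-mate clusters, internal clip sites (one-sided / crisscross /
# facing), read/mate islands, and coverage breaks.
#
# Clip points within 5 bases of each other are pooled into one cluster at
# the modal point (aligner jitter).  Soft-clipped tails shorter than
# `min_clip_len` (3) are ignored everywhere as alignment noise.

POOL_TOL <- 5L

# modal position and members within tolerance
pool_modal <- function(pos, tol = POOL_TOL) {
  tab <- sort(table(pos), decreasing = TRUE)
  modal <- as.integer(names(tab)[1])
  # deterministic tie-break: smallest position among maximal counts
  mx <- tab == tab[1]
  if (sum(mx) > 1) modal <- min(as.integer(names(tab)[mx]))
  list(position = modal, members = which(abs(pos - modal) <= tol))
}

# iteratively pool a position vector into clusters
pool_all <- function(pos, tol = POOL_TOL) {
  idx <- seq_along(pos)
  out <- list()
  while (length(idx)) {
    pm <- pool_modal(pos[idx], tol)
    out[[length(out) + 1]] <- list(position = pm$position,
                                   members = idx[pm$members])
    idx <- idx[-pm$members]
  }
  out
}

read_keys <- function(rows) paste0(rows$rid, "/", rows$mate)

#' Find outward soft-clip clusters at contig edges
#'
#' Clusters of reads whose soft-clipped bases point outward and whose clip
#' point lies within `edge_clip_window` of a boundary.  A cluster must have
#' at least `min_clip_reads` reads and be supported by at least
#' `clip_support_pct` percent of the reads covering (or abutting) the clip
#' point.
#'
#' @param records filtered alignment records.
#' @param contig contig id.
#' @param contig_len contig length.
#' @param params a `roast_params`.
#' @return list of clusters, each with `contig`, `position` (0-based clip
#'   point), `direction` (`"left"`/`"right"`, the direction the clipped
#'   bases extend), `n_reads`, `support_fraction`, `read_ids` and a
#'   `fragments` data.table (`seq`, `offset` relative to the clip point).
#' @export
find_edge_clip_clusters <- function(records, contig, contig_len, params) {
  cid_ <- contig
  r <- records[records$contig == cid_]
  out <- list()
  if (nrow(r) == 0) return(out)
  w <- params$edge_clip_window
  # left edge: left-pointing clips anchored near position 0.
  # Edge clusters accept even 1-base clips: near a true terminus the only
  # remaining evidence is short overhangs, and the read-count and support
  # thresholds already exclude jitter.
  cand <- r[lclip >= 1L & start <= w]
  if (nrow(cand) >= params$min_clip_reads) {
    pm <- pool_modal(cand$start)
    mem <- cand[pm$members]
    p <- pm$position
    cov <- r[(start <= p & start + mlen > p) | start == p]
    sup <- nrow(mem) / max(1L, nrow(cov))
    if (nrow(mem) >= params$min_clip_reads &&
        sup >= params$clip_support_pct / 100) {
      frags <- data.table::data.table(
        seq = substr(mem$oseq, 1L, mem$lclip),
        offset = mem$start - mem$lclip - p)
      out[[length(out) + 1]] <- list(
        contig = contig, position = p, direction = "left",
        n_reads = nrow(mem), support_fraction = sup,
        read_ids = read_keys(mem), fragments = frags)
    }
  }
  # right edge: right-pointing clips anchored near the end
  cand <- r[rclip >= 1L & start + mlen >= contig_len - w]
  if (nrow(cand) >= params$min_clip_reads) {
    ends <- cand$start + cand$mlen
    pm <- pool_modal(ends)
    mem <- cand[pm$members]
    p <- pm$position
    cov <- r[start < p & start + mlen >= p]
    sup <- nrow(mem) / max(1L, nrow(cov))
    if (nrow(mem) >= params$min_clip_reads &&
        sup >= params$clip_support_pct / 100) {
      frags <- data.table::data.table(
        seq = substr(mem$oseq, mem$read_len - mem$rclip + 1L, mem$read_len),
        offset = (mem$start + mem$mlen) - p)
      out[[length(out) + 1]] <- list(
        contig = contig, position = p, direction = "right",
        n_reads = nrow(mem), support_fraction = sup,
        read_ids = read_keys(mem), fragments = frags)
    }
  }
  out
}

#' Find clusters of outward edge reads with unmapped mates
#'
#' At least `min_orphan_reads` reads must be mapped near an edge, oriented
#' outward, with unmapped mates, and each anchor read must carry less than
#' `max_orphan_clip_pct` percent soft-clipped bases.
#'
#' @inheritParams find_edge_clip_clusters
#' @param read_len read length in bases.
#' @return list of clusters with `contig`, `edge` (`"left"`/`"right"`),
#'   `n_reads`, `read_ids`, and `rids`/`mates` identifying the anchor rows.
#' @export
find_orphan_mate_clusters <- function(records, contig, contig_len, params,
                                      read_len) {
  cid_ <- contig
  r <- records[records$contig == cid_ & records$orientation == "mate_unmapped"]
  out <- list()
  if (nrow(r) == 0) return(out)
  w <- edge_window_bases(params, read_len)
  r <- r[(lclip + rclip) / read_len < params$max_orphan_clip_pct / 100]
  left <- r[strand == -1L & start < w]
  if (nrow(left) >= params$min_orphan_reads)
    out[[length(out) + 1]] <- list(contig = contig, edge = "left",
                                   n_reads = nrow(left),
                                   read_ids = read_keys(left),
                                   rids = left$rid, mates = left$mate)
  right <- r[strand == 1L & start + mlen > contig_len - w]
  if (nrow(right) >= params$min_orphan_reads)
    out[[length(out) + 1]] <- list(contig = contig, edge = "right",
                                   n_reads = nrow(right),
                                   read_ids = read_keys(right),
                                   rids = right$rid, mates = right$mate)
  out
}

# restrict an internal-site consensus to the clipped side of its clip
# point: offsets >= 0 for right-pointing clips, < 0 for left-pointing
clamp_consensus <- function(cons, dir) {
  n <- nchar(cons$seq)
  if (dir == "right") {
    if (cons$origin >= 0L) return(cons)
    drop <- -cons$origin
    if (drop >= n) return(NULL)
    list(seq = substr(cons$seq, drop + 1L, n), depth = cons$depth[(drop + 1L):n],
         origin = 0L)
  } else {
    over <- cons$origin + n      # columns extending past the clip point
    if (over <= 0L) return(cons)
    if (over >= n) return(NULL)
    keep <- n - over
    list(seq = substr(cons$seq, 1L, keep), depth = cons$depth[seq_len(keep)],
         origin = cons$origin)
  }
}

# trim a consensus so that only columns with depth >= min_depth survive at
# the far (outward) end; anchor_side "left" keeps the right end intact.
trim_consensus <- function(cons, min_depth = 2L, anchor_side = c("left", "right")) {
  anchor_side <- match.arg(anchor_side)
  d <- cons$depth
  keep <- d >= min_depth
  if (!any(keep)) return(NULL)
  if (anchor_side == "left") {
    last <- max(which(keep))
    list(seq = substr(cons$seq, 1L, last), depth = d[seq_len(last)],
         origin = cons$origin)
  } else {
    first <- min(which(keep))
    n <- nchar(cons$seq)
    list(seq = substr(cons$seq, first, n), depth = d[first:n],
         origin = cons$origin + first - 1L)
  }
}

#' Find internal soft-clip sites (one-sided, crisscross, facing)
#'
#' Internal clip points (outside the edge windows, not at splice-junction
#' positions) are pooled per direction, given a consensus, and paired:
#' a left-pointing and right-pointing cluster at the same position form a
#' crisscross site (signature of missing sequence, translocation or
#' inversion, or of a chimeric junction); a right-pointing cluster upstream
#' of a left-pointing one within `2 * read_len` forms a facing site
#' (unsupported insertion).  Remaining clusters are one-sided.  Site
#' support is the fraction of reads touching the site that carry a clip,
#' counting both directions of a paired site together.
#'
#' @inheritParams find_orphan_mate_clusters
#' @param junctions integer vector of junction positions for this contig
#'   (from [detect_junctions()]).
#' @return list of sites with `contig`, `kind`, `pos_right`/`pos_left`
#'   (0-based clip points; `NA` where absent), `right_consensus` /
#'   `left_consensus` (with depths), `n_reads`, `support_fraction`,
#'   `read_ids`.
#' @export
find_internal_clip_sites <- function(records, contig, contig_len, junctions,
                                     params, read_len) {
  cid_ <- contig
  r <- records[records$contig == cid_]
  if (nrow(r) == 0) return(list())
  w <- params$edge_clip_window
  near_junc <- function(p)
    length(junctions) > 0 && any(abs(junctions - p) <= POOL_TOL)

  build <- function(cand, dir) {
    pos <- if (dir == "right") cand$start + cand$mlen else cand$start
    cl <- pool_all(pos)
    res <- list()
    for (c0 in cl) {
      if (length(c0$members) < params$min_clip_reads) next
      p <- c0$position
      if (near_junc(p)) next
      mem <- cand[c0$members]
      if (dir == "right") {
        frs <- data.table::data.table(
          seq = substr(mem$oseq, mem$read_len - mem$rclip + 1L, mem$read_len),
          offset = (mem$start + mem$mlen) - p)
      } else {
        frs <- data.table::data.table(
          seq = substr(mem$oseq, 1L, mem$lclip),
          offset = mem$start - mem$lclip - p)
      }
      cons <- cpp_consensus(frs$seq, frs$offset)
      cons <- trim_consensus(cons, 2L,
                             anchor_side = if (dir == "right") "left" else "right")
      if (is.null(cons)) next
      # clamp to columns strictly beyond the clip point: columns on the
      # anchored side merely duplicate flank sequence (chance-match
      # overhangs) and would mis-anchor every downstream comparison
      cons <- clamp_consensus(cons, dir)
      if (is.null(cons) || nchar(cons$seq) < params$min_internal_consensus) next
      res[[length(res) + 1]] <- list(position = p, n = nrow(mem),
                                     consensus = cons, keys = read_keys(mem))
    }
    res
  }
  rc <- build(r[rclip >= params$min_clip_len &
                  (start + mlen) > w & (start + mlen) < contig_len - w], "right")
  lc <- build(r[lclip >= params$min_clip_len &
                  start > w & start < contig_len - w], "left")

  cover_n <- function(lo, hi)
    nrow(r[start <= hi & start + mlen >= lo])

  sites <- list()
  used_l <- rep(FALSE, length(lc))
  for (i in seq_along(rc)) {
    pr <- rc[[i]]$position
    # prefer a crisscross partner (same point), then a facing partner
    jx <- 0L; kind <- NA_character_
    # crisscross: the left-pointing cluster sits at (or, with pooling
    # jitter, just left of) the right-pointing one -- both clips emanate
    # from one junction.  facing: the right-pointing cluster lies strictly
    # upstream of the left-pointing one; the gap is an unsupported
    # insertion of exactly that size (chance-matched junction bases can
    # shrink the apparent gap, so any positive gap counts as facing).
    for (j in seq_along(lc)) {
      if (used_l[j]) next
      pl <- lc[[j]]$position
      if (pl <= pr && pr - pl <= 2L * POOL_TOL) {
        jx <- j; kind <- "crisscross"; break
      }
    }
    if (jx == 0L) {
      for (j in seq_along(lc)) {
        if (used_l[j]) next
        pl <- lc[[j]]$position
        if (pl > pr && pl - pr <= 2L * read_len) { jx <- j; kind <- "facing"; break }
      }
    }
    if (jx > 0L) {
      used_l[jx] <- TRUE
      pl <- lc[[jx]]$position
      n <- rc[[i]]$n + lc[[jx]]$n
      sup <- n / max(1L, cover_n(min(pr, pl), max(pr, pl)))
      sites[[length(sites) + 1]] <- list(
        contig = contig, kind = kind, pos_right = pr, pos_left = pl,
        right_consensus = rc[[i]]$consensus, left_consensus = lc[[jx]]$consensus,
        n_reads = n, support_fraction = sup,
        read_ids = c(rc[[i]]$keys, lc[[jx]]$keys))
    } else {
      sup <- rc[[i]]$n / max(1L, cover_n(pr, pr))
      sites[[length(sites) + 1]] <- list(
        contig = contig, kind = "one_sided_right", pos_right = pr,
        pos_left = NA_integer_, right_consensus = rc[[i]]$consensus,
        left_consensus = NULL, n_reads = rc[[i]]$n, support_fraction = sup,
        read_ids = rc[[i]]$keys)
    }
  }
  for (j in seq_along(lc)) {
    if (used_l[j]) next
    pl <- lc[[j]]$position
    sup <- lc[[j]]$n / max(1L, cover_n(pl, pl))
    sites[[length(sites) + 1]] <- list(
      contig = contig, kind = "one_sided_left", pos_right = NA_integer_,
      pos_left = pl, right_consensus = NULL,
      left_consensus = lc[[j]]$consensus, n_reads = lc[[j]]$n,
      support_fraction = sup, read_ids = lc[[j]]$keys)
  }
  Filter(function(s) s$support_fraction >= params$clip_support_pct / 100, sites)
}

#' Find linked read/mate islands across contig pairs
#'
#' Clusters of at least `min_island_reads` outward edge reads on one contig
#' whose mates all map to a single other contig, linked with the implied
#' mate island on the partner.
#'
#' @param records filtered alignment records.
#' @param assembly the current assembly.
#' @param params a `roast_params`.
#' @param read_len read length.
#' @return list of linked island pairs with contig/edge/outer-edge position
#'   for both sides, `n_reads` and `read_ids`.
#' @export
find_mate_islands <- function(records, assembly, params, read_len) {
  r <- records[records$orientation == "diff_contig"]
  if (nrow(r) == 0) return(list())
  clens <- contig_lengths(assembly)
  w <- edge_window_bases(params, read_len)
  clen <- clens[r$contig]
  left <- r$strand == -1L & r$start < w
  right <- r$strand == 1L & (r$start + r$mlen) > clen - w
  r <- r[left | right]
  if (nrow(r) == 0) return(list())
  r[, edge := ifelse(strand == -1L, "left", "right")]
  grp <- r[, .N, by = .(contig, edge, partner = mate_contig)]
  grp <- grp[grp$N >= params$min_island_reads]
  out <- list()
  if (nrow(grp) == 0) return(out)
  seen <- character()
  for (g in seq_len(nrow(grp))) {
    c1 <- grp$contig[g]; e1 <- grp$edge[g]; c2 <- grp$partner[g]
    key <- paste(sort(c(c1, c2)), collapse = "\r")
    if (key %in% seen) next
    mem <- r[contig == c1 & edge == e1 & mate_contig == c2]
    outer1 <- if (e1 == "left") min(mem$start) else max(mem$start + mem$mlen)
    ms <- mem$mate_start
    p2len <- clens[[c2]]
    e2 <- if (stats::median(ms) < p2len / 2) "left" else "right"
    outer2 <- if (e2 == "left") min(ms) else max(ms) + read_len
    seen <- c(seen, key)
    out[[length(out) + 1]] <- list(
      contig = c1, edge = e1, outer = outer1,
      partner = c2, partner_edge = e2, partner_outer = min(outer2, p2len),
      n_reads = nrow(mem), read_ids = read_keys(mem))
  }
  out
}

#' Find abrupt coverage breaks
#'
#' Positions where consecutive per-base depths differ by at least
#' `abrupt_cov_pct` percent of the larger value.  Positions within
#' `read_len` (the end-ignore zone) of either contig end are never
#' reported.  The reported position is 0-based: the first base of the
#' right-hand segment.
#'
#' @param profile integer depth vector from [compute_coverage()].
#' @param contig contig id.
#' @param params a `roast_params`.
#' @param read_len read length (end-ignore zone size).
#' @return data.table with `contig`, `position`, `left_depth`,
#'   `right_depth`, `mode`.
#' @export
find_abrupt_breaks <- function(profile, contig, params, read_len) {
  L <- length(profile)
  ig <- end_ignore_bases(params, read_len)
  empty <- data.table::data.table(contig = character(), position = integer(),
                                  left_depth = integer(),
                                  right_depth = integer(), mode = character())
  if (L < 2 * ig + 2) return(empty)
  i <- seq.int(ig + 1L, L - ig - 1L)   # 1-based left index of each pair
  a <- profile[i]; b <- profile[i + 1L]
  mx <- pmax(a, b)
  diffpct <- ifelse(mx == 0, 0, abs(a - b) / mx * 100)
  hit <- which(diffpct >= params$abrupt_cov_pct)
  if (!length(hit)) return(empty)
  data.table::data.table(contig = contig, position = i[hit],  # 0-based = i
                         left_depth = a[hit], right_depth = b[hit],
                         mode = "abrupt")
}

#' Find gradual coverage breaks with a sliding-window scan
#'
#' Compares the mean depth of the two `gradual_window`-sized windows
#' flanking each position; off unless `gradual_check` is enabled.
#' Consecutive qualifying positions are collapsed to the largest-difference
#' position of each run.
#'
#' @inheritParams find_abrupt_breaks
#' @return data.table in the layout of [find_abrupt_breaks()].
#' @export
find_gradual_breaks <- function(profile, contig, params, read_len) {
  empty <- data.table::data.table(contig = character(), position = integer(),
                                  left_depth = integer(),
                                  right_depth = integer(), mode = character())
  if (!params$gradual_check) return(empty)
  L <- length(profile)
  w <- params$gradual_window
  ig <- max(end_ignore_bases(params, read_len), w)
  if (L < 2 * ig + 2) return(empty)
  cs <- cumsum(c(0, profile))
  i <- seq.int(ig + 1L, L - ig)        # boundary after position i (1-based)
  ml <- (cs[i + 1L] - cs[i + 1L - w]) / w
  mr <- (cs[pmin(i + 1L + w, L + 1L)] - cs[i + 1L]) / w
  mx <- pmax(ml, mr)
  diffpct <- ifelse(mx == 0, 0, abs(ml - mr) / mx * 100)
  hit <- which(diffpct >= params$gradual_cov_pct)
  if (!length(hit)) return(empty)
  runs <- split(hit, cumsum(c(1L, diff(hit) != 1L)))
  best <- vapply(runs, function(h) h[which.max(diffpct[h])], integer(1))
  data.table::data.table(contig = contig, position = i[best],
                         left_depth = as.integer(round(ml[best])),
                         right_depth = as.integer(round(mr[best])),
                         mode = "gradual")
}
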