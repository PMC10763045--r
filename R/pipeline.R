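# Pipeline driver: redundancy removal and the nested inner/outer
# iteration that detects and repairs assembly errors.
#
# One outer pass runs, in order:
#   1. the inner iteration (clip-based edge extension, edge-zone
#      re-alignment only),
#   2. overlap merging of contigs extended by the inner loop,
#   3. a fresh full re-alignment,
#   4. orphan-mate extension and read/mate-island merging,
#   5. a fresh full re-alignment,
#   6. chimera splitting and local mis-assembly fixes (at most one
#      structural fix per contig per pass, crisscross sites first).
# The outer loop stops when a pass touches no more contigs than
# `error_threshold`, or after `outer_max` passes.

# ---- run state --------------------------------------------------------------

new_state <- function(assembly, reads, params) {
  st <- new.env(parent = emptyenv())
  st$asm <- assembly
  st$reads <- reads
  st$params <- params
  st$read_len <- if (!is.null(reads)) reads$read_len else assembly$read_length
  st$asm$read_length <- st$read_len
  st$events <- list()
  st$outer_iter <- 0L
  st$inner_iter <- NA_integer_
  st$lineage <- data.table::data.table(initial_id = contig_ids(assembly),
                                       current_id = contig_ids(assembly),
                                       relation = "unchanged")
  st$pending <- list()    # orphan blocks: list(block, partner, edge)
  st$raw <- NULL
  st$rec <- NULL
  st
}

REL_RANK <- c(unchanged = 0L, extended = 1L, `merged-into` = 2L,
              `split-into` = 2L, removed = 3L)

add_event <- function(st, kind, contigs_in, contigs_out = contigs_in,
                      coords = "", seq_delta_len = 0L, seq_delta = "") {
  st$events[[length(st$events) + 1L]] <- data.table::data.table(
    outer_iter = st$outer_iter, inner_iter = st$inner_iter, kind = kind,
    contigs_in = paste(contigs_in, collapse = ";"),
    contigs_out = paste(contigs_out, collapse = ";"),
    coords = coords, seq_delta_len = as.integer(seq_delta_len),
    seq_delta = seq_delta)
  invisible(st)
}

events_table <- function(st) {
  if (!length(st$events)) {
    return(data.table::data.table(
      outer_iter = integer(), inner_iter = integer(), kind = character(),
      contigs_in = character(), contigs_out = character(),
      coords = character(), seq_delta_len = integer(),
      seq_delta = character()))
  }
  data.table::rbindlist(st$events)
}

lineage_update <- function(st, old_ids, new_ids, relation) {
  ln <- st$lineage
  sel <- which(ln$current_id %in% old_ids)
  if (!length(sel)) return(invisible(st))
  keep <- ln[-sel]
  upd <- ln[sel]
  pieces <- lapply(seq_len(nrow(upd)), function(i) {
    rel <- if (REL_RANK[[relation]] >= REL_RANK[[upd$relation[i]]])
      relation else upd$relation[i]
    data.table::data.table(initial_id = upd$initial_id[i],
                           current_id = new_ids,
                           relation = rel)
  })
  st$lineage <- data.table::rbindlist(c(list(keep), pieces))
  invisible(st)
}

rename_pending <- function(st, old, new) {
  for (i in seq_along(st$pending))
    if (st$pending[[i]]$partner %in% old) st$pending[[i]]$partner <- new[1]
  invisible(st)
}

# ---- alignment management ---------------------------------------------------

full_align <- function(st) {
  st$raw <- align_read_pairs(st$reads, st$asm, st$params)
  st$rec <- filter_alignments(st$raw, st$params)
  invisible(st)
}

# realign only the pairs in `rids` against the current assembly
partial_align <- function(st, rids) {
  if (!length(rids)) return(invisible(st))
  sub <- list(ids = st$reads$ids[rids], s1 = st$reads$s1[rids],
              s2 = st$reads$s2[rids], read_len = st$reads$read_len)
  nr <- align_read_pairs(sub, st$asm, st$params)
  nr[, rid := rids[rid]]
  st$raw <- rbind(st$raw[!rid %in% rids], nr)
  data.table::setorder(st$raw, rid, mate)
  st$rec <- filter_alignments(st$raw, st$params)
  invisible(st)
}

# pairs worth re-aligning inside the inner loop: anything unmapped or
# ambiguous, plus reads in the edge zones of recently extended contigs
inner_realign_rids <- function(st, touched) {
  raw <- st$raw
  clens <- contig_lengths(st$asm)
  w <- edge_window_bases(st$params, st$read_len)
  sel <- is.na(raw$contig) | raw$mapq < st$params$min_mapq
  if (length(touched)) {
    on_t <- !is.na(raw$contig) & raw$contig %in% touched
    cl <- clens[raw$contig]
    edge <- on_t & (raw$start < w | raw$start + raw$mlen > cl - w)
    sel <- sel | edge
  }
  sort(unique(raw$rid[sel]))
}

# shift stored coordinates on `id` after its left end moved by `shift`
shift_records <- function(st, id, shift) {
  if (shift == 0L) return(invisible(st))
  st$raw[contig == id, start := start + shift]
  st$raw[mate_contig == id, mate_start := mate_start + shift]
  # the filtered view holds the same rows; shift it in place rather than
  # re-filtering the full table
  st$rec[contig == id, start := start + shift]
  st$rec[mate_contig == id, mate_start := mate_start + shift]
  invisible(st)
}

# ---- redundancy removal -----------------------------------------------------

#' Remove redundant contigs by greedy identity clustering
#'
#' Contigs are visited longest-first; a contig is removed when it aligns
#' to an earlier surviving contig with identity at or above
#' `redundancy_identity` over at least 90 percent of the shorter
#' sequence.
#'
#' @param assembly a `roast_assembly`.
#' @param params a `roast_params`.
#' @return list with the deduplicated `assembly` and a character vector
#'   `removed` naming the dropped contigs (with their representatives as
#'   names).
#' @export
remove_redundant <- function(assembly, params = default_parameters()) {
  ids <- contig_ids(assembly)
  lens <- contig_lengths(assembly)
  ord <- ids[order(-lens, ids)]
  if (length(ids) < 2) return(list(assembly = assembly, removed = character()))
  hits <- find_local_overlap_multi(unname(assembly$seq[ord]), assembly$seq,
                                   params, both_strands = TRUE)
  hits[, query := ord[query]]
  hits <- hits[subject_id != query]
  removed <- character(); reps <- character()
  min_id <- params$redundancy_identity * 100
  for (id in ord) {
    h <- hits[query == id & subject_id %in% reps]
    if (nrow(h)) {
      shorter <- pmin(lens[[id]], lens[h$subject_id])
      h <- h[h$length >= 0.9 * shorter & h$identity_pct >= min_id]
    }
    if (nrow(h)) removed[[id]] <- h$subject_id[1] else reps <- c(reps, id)
  }
  list(assembly = asm_drop(assembly, names(removed)), removed = removed)
}

# ---- inner iteration --------------------------------------------------------

#' Run the inner (clip-extension) iteration
#'
#' Repeats align / filter / edge-cluster detection / consensus / extension
#' until no contig is extended in a pass or `inner_max` passes have run.
#' Only reads that are unmapped, ambiguous, or in the edge zones of
#' contigs extended in the previous pass are re-aligned between passes.
#'
#' @param st a run-state environment (internal); see [roast_run()].
#' @return the state, with `st$extended_inner` recording which contig ends
#'   grew.
#' @export
run_inner <- function(st) {
  p <- st$params
  extended <- list()
  touched_last <- character()
  for (inner in seq_len(p$inner_max)) {
    st$inner_iter <- inner
    if (inner > 1L) partial_align(st, inner_realign_rids(st, touched_last))
    clens <- contig_lengths(st$asm)
    rec <- st$rec
    cl <- clens[rec$contig]
    cand <- rec[(lclip >= 1L & start <= p$edge_clip_window) |
                  (rclip >= 1L & start + mlen >= cl - p$edge_clip_window)]
    cand_ids <- sort(unique(cand$contig))
    touched_last <- character()
    for (id in cand_ids) {
      clusters <- find_edge_clip_clusters(st$rec, id, clens[[id]], p)
      # apply right-side first so left-side coordinates stay valid
      dirs <- vapply(clusters, `[[`, "", "direction")
      for (cluster in clusters[order(dirs != "right")]) {
        # clamp to the outward side of the clip point: overhang columns
        # would overwrite supported contig bases at depth 1
        cons0 <- clamp_consensus(consensus_from_clips(cluster$fragments, p),
                                 cluster$direction)
        if (is.null(cons0)) next
        cons <- trim_consensus(cons0, 2L,
                               anchor_side = if (cluster$direction == "left")
                                 "right" else "left")
        # near a true terminus only 1-2 short overhangs remain; a short
        # consensus may keep its depth-1 columns (bounded error exposure)
        if (nchar(cons0$seq) <= 8L) cons <- cons0
        if (is.null(cons)) next
        ok_anchor <- if (cluster$direction == "left")
          cons$origin + nchar(cons$seq) == 0L else cons$origin == 0L
        if (!ok_anchor) next
        res <- extend_with_clips(st$asm$seq[[id]], cluster, cons,
                                 st$asm$prov[[id]])
        if (is.null(res) || res$gain < 1L) next
        old_len <- nchar(st$asm$seq[[id]])
        st$asm <- asm_replace(st$asm, id, res$seq, res$prov)
        if (cluster$direction == "left")
          shift_records(st, id, nchar(res$seq) - old_len)
        add_event(st, "clip-extended", id, id,
                  coords = sprintf("%s:%d:%s", id, cluster$position,
                                   cluster$direction),
                  seq_delta_len = res$gain)
        lineage_update(st, id, id, "extended")
        extended[[id]] <- union(extended[[id]], cluster$direction)
        touched_last <- union(touched_last, id)
      }
    }
    if (!length(touched_last)) break
  }
  st$inner_iter <- NA_integer_
  st$extended_inner <- extended
  invisible(st)
}

# ---- outer stages -----------------------------------------------------------

stage_merge_by_clip <- function(st) {
  p <- st$params
  for (id in sort(names(st$extended_inner))) {
    for (side in sort(st$extended_inner[[id]], decreasing = TRUE)) {
      if (!id %in% contig_ids(st$asm)) next
      m <- attempt_clip_merge(st$asm, id, side, p)
      if (is.null(m)) next
      st$asm <- apply_merge(st$asm, m)
      newid <- merged_id(m$order)
      add_event(st, "merged-clip", m$order, newid,
                coords = sprintf("overlap=%d;strand=%s", m$overlap_len, m$strand),
                seq_delta_len = -m$overlap_len)
      lineage_update(st, c(m$id_a, m$id_b), newid, "merged-into")
      rename_pending(st, c(m$id_a, m$id_b), newid)
    }
  }
  invisible(st)
}

stage_orphans_islands <- function(st) {
  p <- st$params
  rl <- st$read_len
  edited <- character()

  # re-check pending orphan blocks for a stitchable overlap
  for (i in rev(seq_along(st$pending))) {
    pb <- st$pending[[i]]
    if (!pb$block %in% contig_ids(st$asm) ||
        !pb$partner %in% contig_ids(st$asm)) {
      st$pending[[i]] <- NULL; next
    }
    ctg <- st$asm$seq[[pb$partner]]; blk <- st$asm$seq[[pb$block]]
    if (pb$edge == "right") {
      ov <- cpp_sp_overlap(ctg, blk, p$min_island_overlap, p$extend_identity_pct)
      if (ov[1] == 0) next
      m <- merge_by_overlap(ctg, blk,
                            list(a_range = c(nchar(ctg) - ov[1], nchar(ctg)),
                                 b_range = c(0L, ov[1])),
                            st$asm$prov[[pb$partner]], st$asm$prov[[pb$block]])
    } else {
      ov <- cpp_sp_overlap(blk, ctg, p$min_island_overlap, p$extend_identity_pct)
      if (ov[1] == 0) next
      m <- merge_by_overlap(blk, ctg,
                            list(a_range = c(nchar(blk) - ov[1], nchar(blk)),
                                 b_range = c(0L, ov[1])),
                            st$asm$prov[[pb$block]], st$asm$prov[[pb$partner]])
    }
    st$asm <- asm_drop(st$asm, pb$block)
    st$asm <- asm_replace(st$asm, pb$partner, m$seq, m$prov)
    add_event(st, "orphan-extended", c(pb$partner, pb$block), pb$partner,
              coords = sprintf("edge=%s;overlap=%d", pb$edge, ov[1]),
              seq_delta_len = nchar(m$seq) - nchar(ctg))
    lineage_update(st, pb$partner, pb$partner, "extended")
    edited <- union(edited, pb$partner)
    st$pending[[i]] <- NULL
  }

  # orphan-mate clusters
  clens <- contig_lengths(st$asm)
  orph <- st$rec[orientation == "mate_unmapped"]
  cand_ids <- sort(intersect(unique(orph$contig), contig_ids(st$asm)))
  nblk <- 0L
  for (id in cand_ids) {
    clusters <- find_orphan_mate_clusters(st$rec, id, clens[[id]], p, rl)
    dirs <- vapply(clusters, `[[`, "", "edge")
    for (cluster in clusters[order(dirs != "right")]) {
      mates <- mate_seqs(st, cluster)
      if (length(mates) < p$min_orphan_reads) next
      res <- extend_with_orphans(st$asm$seq[[id]], cluster, mates, p, rl,
                                 st$asm$prov[[id]])
      if (res$action == "stitched") {
        old_len <- nchar(st$asm$seq[[id]])
        st$asm <- asm_replace(st$asm, id, res$seq, res$prov)
        if (cluster$edge == "left")
          shift_records(st, id, nchar(res$seq) - old_len)
        add_event(st, "orphan-extended", id, id,
                  coords = sprintf("edge=%s", cluster$edge),
                  seq_delta_len = res$gain)
        lineage_update(st, id, id, "extended")
        edited <- union(edited, id)
      } else if (res$action == "new_contig") {
        nblk <- nblk + 1L
        bid <- sprintf("%s.orph%d", id, nblk)
        if (bid %in% contig_ids(st$asm)) next
        st$asm <- asm_add(st$asm, bid, res$block,
                          prov = rep(1L, nchar(res$block)),
                          tags = "orphan-derived")
        st$pending[[length(st$pending) + 1L]] <-
          list(block = bid, partner = id, edge = cluster$edge)
        add_event(st, "new-contig", id, bid,
                  coords = sprintf("edge=%s", cluster$edge),
                  seq_delta_len = nchar(res$block))
      }
    }
  }

  # read/mate islands
  islands <- find_mate_islands(st$rec, st$asm, p, rl)
  for (isl in islands) {
    if (isl$contig %in% edited || isl$partner %in% edited) next
    if (!isl$contig %in% contig_ids(st$asm) ||
        !isl$partner %in% contig_ids(st$asm)) next
    m <- attempt_island_merge(st$asm, isl, p, rl)
    if (is.null(m)) next
    st$asm <- apply_merge(st$asm, m)
    newid <- merged_id(m$order)
    add_event(st, "merged-island", m$order, newid,
              coords = sprintf("overlap=%d;strand=%s", m$overlap_len, m$strand),
              seq_delta_len = -m$overlap_len)
    lineage_update(st, c(m$id_a, m$id_b), newid, "merged-into")
    rename_pending(st, c(m$id_a, m$id_b), newid)
    edited <- union(edited, newid)
  }
  invisible(st)
}

# oriented (contig-forward) sequences of a cluster's unmapped mates
mate_seqs <- function(st, cluster) {
  out <- character(length(cluster$rids))
  for (i in seq_along(cluster$rids)) {
    rid <- cluster$rids[i]
    om <- 3L - cluster$mates[i]
    s <- if (om == 1L) st$reads$s1[rid] else st$reads$s2[rid]
    out[i] <- if (cluster$edge == "right") cpp_revcomp(s) else s
  }
  out
}

# route a removed piece after a split/excision: self-duplicate pieces are
# dropped, long novel pieces become new contigs, short ones are discarded
route_small_piece <- function(st, id, piece, prov_piece, disposition,
                              side, kind) {
  if (disposition == "new_contig") {
    nid <- paste0(id, if (side == "left") ".1" else ".2")
    while (nid %in% contig_ids(st$asm)) nid <- paste0(nid, "b")
    st$asm <- asm_add(st$asm, nid, piece, prov = prov_piece,
                      tags = "split-product")
    return(nid)
  }
  add_event(st, if (disposition == "self_chimera") "self-chimera-removed"
            else "discarded", id, character(0),
            seq_delta_len = -nchar(piece), seq_delta = piece)
  NULL
}

apply_split <- function(st, id, sp, kind) {
  small_first <- sp$small_side == "left"
  big_id <- paste0(id, if (small_first) ".2" else ".1")
  st$asm <- asm_drop(st$asm, id)
  st$asm <- asm_add(st$asm, big_id, sp$big, prov = sp$prov_big)
  small_id <- route_small_piece(st, id, sp$small, sp$prov_small,
                                sp$small_disposition, sp$small_side, kind)
  outs <- c(if (small_first) small_id else NULL, big_id,
            if (!small_first) small_id else NULL)
  add_event(st, kind, id, outs,
            coords = sprintf("%s:%d", id, sp$position),
            seq_delta_len = if (is.null(small_id)) -nchar(sp$small) else 0L)
  lineage_update(st, id, outs, "split-into")
  rename_pending(st, id, big_id)
  invisible(st)
}

stage_chimera_local <- function(st) {
  p <- st$params
  rl <- st$read_len
  juncs <- detect_junctions(st$rec)
  clens <- contig_lengths(st$asm)
  # candidate contigs: any internal clips at all, else coverage scan
  for (id in sort(contig_ids(st$asm))) {
    contig <- st$asm$seq[[id]]
    prov <- st$asm$prov[[id]]
    jn <- if (id %in% names(juncs)) juncs[[id]] else integer()
    sites <- find_internal_clip_sites(st$rec, id, clens[[id]], jn, p, rl)
    kinds <- vapply(sites, `[[`, "", "kind")
    sup <- vapply(sites, `[[`, 0, "support_fraction")
    # a crisscross whose two clip points coincide exactly carries no
    # chance-matched boundary bases; prefer it over shifted ones
    skew <- vapply(sites, function(s) {
      if (s$kind == "crisscross") abs(s$pos_right - s$pos_left) else 0L
    }, 0L)
    ord <- order(match(kinds, c("crisscross", "facing", "one_sided_right",
                                "one_sided_left")), skew, -sup)
    sites <- sites[ord]; kinds <- kinds[ord]
    has_crisscross <- any(kinds == "crisscross")
    acted <- FALSE
    for (site in sites) {
      if (acted) break
      if (site$kind == "crisscross") {
        pr <- site$pos_right; pl <- site$pos_left
        crt <- trim_flank_right_cons(site$right_consensus$seq, contig, pr)
        clt <- trim_flank_left_cons(site$left_consensus$seq, contig, pl)
        hit1 <- cons_self_hit(crt, contig, p)
        hit2 <- cons_self_hit(clt, contig, p)
        if (!is.null(hit1) && !is.null(hit2)) {
          # the excision junction of a correct fix is read-supported; an
          # off-by-a-few span leaves an unsupported junction, so candidate
          # spans are arbitrated by read support
          # all three junctions a fix creates must be read-supported.
          # Each junction's local context depends on only two of the
          # candidate offsets, so results are memoized across candidates.
          jcache <- new.env(parent = emptyenv())
          ver_ti <- function(fx) {
            lf <- fx$span[2] - fx$span[1]
            pre <- list(c(fx$span[1] - 110L, fx$span[1] + 110L),
                        c(fx$span[2] - 110L, fx$span[2] + 110L),
                        c(site$pos_right - 110L, site$pos_right + 110L),
                        c(fx$insert_pre - 110L, fx$insert_pre + 110L))
            chk <- function(tag, key, jpos) {
              k <- paste(tag, paste(key, collapse = ","))
              if (is.null(jcache[[k]]))
                jcache[[k]] <- junction_read_support(st, id, fx$seq, jpos, pre)
              jcache[[k]]
            }
            if (fx$strand == "+") {
              kl <- c(fx$insert_pre, fx$span[1]); kr <- c(fx$insert_pre, fx$span[2])
            } else {
              kl <- c(fx$insert_pre, fx$span[2]); kr <- c(fx$insert_pre, fx$span[1])
            }
            chk("e", fx$span, fx$exc_junction) &&
              chk("l", kl, fx$insert_at) &&
              chk("r", kr, fx$insert_at + lf)
          }
          fx <- fix_translocation_inversion(contig, site,
                                            list(right = hit1, left = hit2,
                                                 right_seq = crt,
                                                 left_seq = clt),
                                            p, prov, verify = ver_ti)
          if (!is.null(fx)) {
            st$asm <- asm_replace(st$asm, id, fx$seq, fx$prov)
            add_event(st, if (fx$strand == "-") "inversion-fixed"
                      else "translocation-fixed", id, id,
                      coords = sprintf("%s:%d-%d->%d", id, fx$span[1],
                                       fx$span[2], fx$insert_at),
                      seq_delta_len = 0L)
            lineage_update(st, id, id, "extended")
            acted <- TRUE
          }
        } else if (is.null(hit1) && is.null(hit2)) {
          site2 <- site
          site2$right_consensus <- list(seq = crt, depth = NULL, origin = 0L)
          site2$left_consensus <- list(seq = clt, depth = NULL,
                                       origin = -nchar(clt))
          ver_ms <- function(fx) {
            li <- nchar(fx$inserted)
            pre <- list(c(fx$position - 110L, fx$position),
                        c(fx$position, fx$position + 110L))
            junction_read_support(st, id, fx$seq, fx$position, pre) &&
              junction_read_support(st, id, fx$seq, fx$position + li, pre)
          }
          fx <- fix_missing_sequence(contig, site2, p, prov, verify = ver_ms)
          if (!is.null(fx)) {
            st$asm <- asm_replace(st$asm, id, fx$seq, fx$prov)
            add_event(st, "missing-inserted", id, id,
                      coords = sprintf("%s:%d", id, fx$position),
                      seq_delta_len = nchar(fx$inserted),
                      seq_delta = fx$inserted)
            lineage_update(st, id, id, "extended")
            acted <- TRUE
          } else if (nchar(crt) >= p$min_internal_consensus ||
                       nchar(clt) >= p$min_internal_consensus) {
            # consensi are unrelated sequences: a chimeric junction.
            # (When both trim away almost completely the site is a
            # base-scale local defect, not a junction; leave it alone.)
            act <- split_chimera_at_clip(contig, site, p, prov)
            if (!is.null(act) && act$mode == "split") {
              apply_split(st, id, act, "chimera-split-clip")
              acted <- TRUE
            }
          }
        }
        # exactly one hit: ambiguous evidence; wait for the next pass
      } else if (site$kind == "facing") {
        ver <- function(fx) {
          a <- fx$coords[1]; b <- fx$coords[2]
          junction_read_support(st, id, fx$seq, a,
                                list(c(a - 110L, a), c(b, b + 110L)))
        }
        fx <- remove_unsupported_insertion(contig, site, p, prov,
                                           verify = ver)
        if (!is.null(fx)) {
          removed_len <- nchar(fx$removed)
          st$asm <- asm_replace(st$asm, id, fx$seq, fx$prov)
          add_event(st, "insertion-removed", id, id,
                    coords = sprintf("%s:%d-%d", id, fx$coords[1], fx$coords[2]),
                    seq_delta_len = -removed_len, seq_delta = fx$removed)
          lineage_update(st, id, id, "extended")
          if (removed_len >= p$min_new_contig_len) {
            hits <- find_local_overlap(fx$removed,
                                       stats::setNames(fx$seq, id), p)
            if (!nrow(hits) || hits$score[1] < p$internal_identity_pct) {
              nid <- paste0(id, ".ins")
              st$asm <- asm_add(st$asm, nid, fx$removed,
                                prov = rep(0L, removed_len),
                                tags = "split-product")
              add_event(st, "new-contig", id, nid,
                        seq_delta_len = removed_len)
            }
          }
          acted <- TRUE
        }
      } else if (!has_crisscross) {   # one-sided
        # a clip consensus explained by the adjacent contig sequence (up to
        # a couple of bases of slippage) marks a tiny local defect, not a
        # chimeric junction; splitting there would discard true sequence
        if (one_sided_explained(site, contig, p)) next
        act <- split_chimera_at_clip(contig, site, p, prov)
        if (is.null(act)) next
        if (act$mode == "excised") {
          st$asm <- asm_replace(st$asm, id, act$seq, act$prov)
          add_event(st, "self-chimera-removed", id, id,
                    coords = sprintf("%s:%d-%d", id, act$coords[1],
                                     act$coords[2]),
                    seq_delta_len = -nchar(act$removed),
                    seq_delta = act$removed)
          lineage_update(st, id, id, "extended")
          acted <- TRUE
        } else {
          apply_split(st, id, act, "chimera-split-clip")
          acted <- TRUE
        }
      }
    }
    if (acted || length(sites) > 0) next
    # coverage-based chimera scan (only for contigs with no clip-derived
    # signature at all: a junction with clip evidence belongs to the clip
    # fixers, and splitting it on coverage would pre-empt them)
    d <- compute_coverage(st$rec, id, clens[[id]])
    brks <- find_abrupt_breaks(d, id, p, rl)
    if (p$gradual_check)
      brks <- rbind(brks, find_gradual_breaks(d, id, p, rl))
    if (nrow(brks)) {
      mx <- pmax(brks$left_depth, brks$right_depth)
      brks <- brks[order(-abs(brks$left_depth - brks$right_depth) /
                           pmax(mx, 1L))]
      act <- split_chimera_at_coverage(contig, brks[1], p, prov)
      if (!is.null(act))
        apply_split(st, id, act, "chimera-split-coverage")
    }
  }
  invisible(st)
}

# Verify a candidate repair junction against the reads: a window around
# the junction in the repaired sequence must be crossed, essentially
# unclipped, by at least min_clip_reads of the reads currently mapped
# near the sequence that became adjacent.  A junction produced by an
# off-by-a-few excision has no such support.
junction_read_support <- function(st, id, fixed_seq, jpos,
                                  pre_regions, win = NULL) {
  p <- st$params
  # the window must comfortably contain whole reads on either side of the
  # junction, or every crossing read would be clipped at the window edge
  if (is.null(win)) win <- st$read_len + 40L
  n <- nchar(fixed_seq)
  lo <- max(0L, jpos - win); hi <- min(n, jpos + win)
  if (jpos - lo < 20L || hi - jpos < 20L) return(TRUE)  # too close to an end
  W <- substr(fixed_seq, lo + 1L, hi)
  # gather from the unfiltered records: reads crossing a junction under
  # repair are often mapq-ambiguous in the pre-fix contig (their clipped
  # content has a second placement) and would be missed in the filtered set
  r <- st$raw[!is.na(st$raw$contig) & st$raw$contig == id]
  keep <- rep(FALSE, nrow(r))
  for (rg in pre_regions)
    keep <- keep | (r$start < rg[2] & r$start + r$mlen > rg[1])
  seqs <- utils::head(r$oseq[keep], 500L)
  if (length(seqs) < p$min_clip_reads) return(FALSE)
  al <- cpp_align_reads(W, seqs, k = p$aligner_k,
                        min_score = p$aligner_min_score, max_cand = 4L)
  jrel <- jpos - lo
  cross <- !is.na(al$contig) &
    (al$lclip + al$rclip) <= 3L &
    al$start <= jrel - 12L &
    (al$start + al$mlen) >= jrel + 12L
  # a single-base junction error never clips a crossing read, but it does
  # break every crossing read's perfect match (IUPAC-aware; sequencing
  # errors only thin the count), so base-scale junk shows up as crossing
  # reads that almost never match perfectly
  perfect <- cross & al$matches == al$mlen
  np <- sum(perfect, na.rm = TRUE)
  nc <- sum(cross, na.rm = TRUE)
  np >= p$min_clip_reads ||
    (np >= 2L && nc >= 3L && np >= 0.5 * nc)
}

# TRUE when a one-sided site's consensus is positionally explained by the
# contig just beyond (or before) its clip point, allowing 1-3 bases of
# slippage: the signature then reflects a tiny indel-scale defect rather
# than a chimeric junction
one_sided_explained <- function(site, contig, params) {
  n <- nchar(contig)
  minc <- params$min_internal_consensus
  if (site$kind == "one_sided_right") {
    cs <- site$right_consensus$seq
    p <- site$pos_right
    for (d in -3L:3L) {
      for (j in 0L:3L) {
        sl <- nchar(cs) - j
        if (sl < minc || p + d + j < 0 || p + d + j + sl > n) next
        m <- cpp_match_count(cs, contig, j, p + d + j, sl)
        if (m / sl * 100 >= params$internal_identity_pct) return(TRUE)
      }
    }
  } else if (site$kind == "one_sided_left") {
    cs <- site$left_consensus$seq
    p <- site$pos_left
    lc <- nchar(cs)
    for (d in -3L:3L) {
      for (j in 0L:3L) {
        sl <- lc - j
        a0 <- p + d - j - sl
        if (sl < minc || a0 < 0 || a0 + sl > n) next
        m <- cpp_match_count(cs, contig, 0L, a0, sl)
        if (m / sl * 100 >= params$internal_identity_pct) return(TRUE)
      }
    }
  }
  FALSE
}

# best self-hit of a consensus within its contig (score and identity both
# at internal_identity_pct or better); NULL when absent or too short
cons_self_hit <- function(cons_seq, contig, params) {
  if (nchar(cons_seq) < params$min_internal_consensus) return(NULL)
  hits <- find_local_overlap(cons_seq, c(self = contig), params)
  hits <- hits[score >= params$internal_identity_pct &
                 identity_pct >= params$internal_identity_pct]
  if (!nrow(hits)) return(NULL)
  hits[1]
}

#' Run one outer iteration
#'
#' @param st a run-state environment; see [roast_run()].
#' @return the state, with `st$contigs_with_errors` set to the number of
#'   distinct contigs touched by this pass.
#' @export
run_outer <- function(st) {
  st$outer_iter <- st$outer_iter + 1L
  n_before <- length(st$events)
  run_inner(st)
  stage_merge_by_clip(st)
  full_align(st)
  stage_orphans_islands(st)
  full_align(st)
  stage_chimera_local(st)
  evs <- st$events[seq2(n_before + 1L, length(st$events))]
  touched <- unique(unlist(lapply(evs, function(e)
    strsplit(e$contigs_in, ";", fixed = TRUE)[[1]])))
  st$contigs_with_errors <- length(touched)
  invisible(st)
}

# join still-pending orphan blocks to their contigs with n_join Ns
finalize_pending <- function(st) {
  p <- st$params
  ns <- strrep("N", p$n_join)
  for (pb in st$pending) {
    if (!pb$block %in% contig_ids(st$asm) ||
        !pb$partner %in% contig_ids(st$asm)) next
    ctg <- st$asm$seq[[pb$partner]]; blk <- st$asm$seq[[pb$block]]
    if (pb$edge == "right") {
      seq <- paste0(ctg, ns, blk)
      prov <- c(st$asm$prov[[pb$partner]], rep(1L, p$n_join),
                st$asm$prov[[pb$block]])
    } else {
      seq <- paste0(blk, ns, ctg)
      prov <- c(st$asm$prov[[pb$block]], rep(1L, p$n_join),
                st$asm$prov[[pb$partner]])
    }
    st$asm <- asm_drop(st$asm, pb$block)
    st$asm <- asm_replace(st$asm, pb$partner, seq, prov)
    add_event(st, "N-joined", c(pb$partner, pb$block), pb$partner,
              coords = sprintf("edge=%s", pb$edge),
              seq_delta_len = nchar(blk) + p$n_join)
    lineage_update(st, pb$partner, pb$partner, "extended")
  }
  st$pending <- list()
  invisible(st)
}

contig_map_table <- function(st) {
  mp <- data.table::copy(st$lineage)
  data.table::setnames(mp, "current_id", "final_id")
  mp[is.na(final_id) | !final_id %in% contig_ids(st$asm),
     `:=`(final_id = "-", relation = "removed")]
  data.table::setorder(mp, initial_id, final_id)
  unique(mp)
}

#' Run the full iterative improvement pipeline
#'
#' Optionally removes redundant contigs, then repeats outer iterations
#' until convergence (`contigs_with_errors <= error_threshold`) or
#' `outer_max` passes, N-joins any leftover orphan blocks, and returns (and
#' optionally writes) the improved assembly, contig map and change log.
#'
#' @param assembly a `roast_assembly` (or FASTA path).
#' @param reads read pairs from [read_fastq_pair()] (or a length-2
#'   character vector of FASTQ paths).
#' @param params a `roast_params`.
#' @param out_dir optional output directory for
#'   `improved.fasta` / `contig_map.tsv` / `change_log.tsv` and
#'   per-iteration intermediate assemblies.
#' @param sam optional SAM file used for the first alignment pass instead
#'   of the built-in aligner (later passes re-align internally).
#' @return list with `assembly`, `contig_map`, `events`, `iterations`,
#'   and `converged`.
#' @export
roast_run <- function(assembly, reads, params = default_parameters(),
                      out_dir = NULL, sam = NULL) {
  if (is.character(assembly)) assembly <- read_fasta(assembly)
  if (is.character(reads) && length(reads) == 2)
    reads <- read_fastq_pair(reads[1], reads[2])
  if (length(assembly) == 0) stop("empty assembly")
  if (is.null(reads) || length(reads$ids) == 0) stop("empty read set")
  st <- new_state(assembly, reads, params)
  if (params$dedup_check) {
    dd <- remove_redundant(st$asm, params)
    for (rid in names(dd$removed)) {
      add_event(st, "redundancy-removed", rid, character(0))
      lineage_update(st, rid, NA_character_, "removed")
    }
    st$asm <- dd$assembly
  }
  if (!is.null(sam)) {
    st$raw <- parse_sam(sam, st$asm)
    st$rec <- filter_alignments(st$raw, params)
  } else {
    full_align(st)
  }
  converged <- FALSE
  while (st$outer_iter < params$outer_max) {
    run_outer(st)
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write_fasta(st$asm, file.path(out_dir,
                                    sprintf("iter_%03d.fasta", st$outer_iter)))
    }
    if (st$contigs_with_errors <= params$error_threshold) {
      converged <- TRUE
      break
    }
    full_align(st)
  }
  finalize_pending(st)
  ev <- events_table(st)
  mp <- contig_map_table(st)
  if (!is.null(out_dir))
    write_reports(ev, mp, out_dir, assembly = st$asm)
  list(assembly = st$asm, contig_map = mp, events = ev,
       iterations = st$outer_iter, converged = converged)
}
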