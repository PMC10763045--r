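#' Pipeline parameters and their defaults
#'
#' Returns the full parameter set controlling signature detection and error
#' fixing, with every field at its default value.  Units are bases unless
#' noted.  The fields are:
#'
#' * `edge_clip_window` (25): outward soft-clips must occur within this many
#'   bases of a contig boundary to count as edge clips.
#' * `min_clip_reads` (3): minimum reads sharing a soft-clip point.
#' * `clip_support_pct` (75): minimum percentage of the reads covering a clip
#'   point that must carry the clip.
#' * `realign_edge_window` (`2 * read_length`, stored as the multiplier `NA`
#'   and resolved at run time): reads whose alignment touches this edge zone
#'   are the only ones re-aligned inside the inner iteration.
#' * `min_orphan_reads` (3): minimum edge reads with unmapped mates required
#'   to trigger orphan-mate assembly.
#' * `max_orphan_clip_pct` (25): an orphan-cluster anchor read may have at
#'   most this percentage of its length soft-clipped.
#' * `min_orphan_extension_pct` (50): an orphan-mate extension is kept only
#'   if it grows the contig by at least this percentage of the read length.
#' * `n_join` (5): number of Ns used to join a still-unmerged orphan block to
#'   its contig at the end of the run.
#' * `seed_len` (25): length of the terminal query used when searching for a
#'   merge partner after clip extension.
#' * `seed_identity_pct` (100): identity required of that seed hit.
#' * `extend_identity_pct` (90): running identity used when growing an
#'   overlap beyond its seed.
#' * `max_gaps` (0): overlap hits containing more gaps are ignored (the
#'   built-in overlap search is ungapped, so hits always carry 0 gaps).
#' * `min_island_reads` (5): minimum reads in a read/mate island.
#' * `min_island_overlap` (10): minimum overlap length for an island merge.
#' * `island_overlap_score` (90): minimum overlap score
#'   (`matches / query length * 100`) for an island merge.
#' * `island_edge_slack_pct` (5): the overlap must start within this
#'   percentage of the read length from the island's outer edge.
#' * `min_internal_consensus` (10): minimum internal clip consensus length.
#' * `internal_identity_pct` (90): identity/score threshold for searching an
#'   internal clip consensus within its contig.
#' * `min_new_contig_len` (200): split-off pieces shorter than this are
#'   discarded rather than added as new contigs.
#' * `abrupt_cov_pct` (80): relative coverage difference between consecutive
#'   positions flagging an abrupt break.
#' * `gradual_window` (100): window size for the optional gradual-change scan.
#' * `gradual_cov_pct` (80): window-mean difference flagging a gradual break.
#' * `end_ignore` (`read_length`, resolved at run time): coverage changes
#'   this close to a contig end are ignored.
#' * `min_mapq` (20): records below this mapping quality are removed.
#' * `redundancy_identity` (0.95): identity cut-off for redundancy removal.
#' * `inner_max` (30), `outer_max` (100): iteration caps.
#' * `error_threshold` (0): outer iteration stops once the number of contigs
#'   with errors is at or below this.
#' * `gradual_check` (`FALSE`), `dedup_check` (`TRUE`): optional stages.
#'
#' @param ... named overrides of any default.
#' @return an object of class `roast_params` (a validated named list).
#' @export
#' @examples
#' p <- default_parameters()
#' p$edge_clip_window
#' default_parameters(inner_max = 5)$inner_max
default_parameters <- function(...) {
  p <- list(
    edge_clip_window = 25L,
    min_clip_reads = 3L,
    clip_support_pct = 75,
    realign_edge_mult = 2L,     # realign window = mult * read_length
    min_orphan_reads = 3L,
    max_orphan_clip_pct = 25,
    min_orphan_extension_pct = 50,
    n_join = 5L,
    seed_len = 25L,
    seed_identity_pct = 100,
    extend_identity_pct = 90,
    max_gaps = 0L,
    min_island_reads = 5L,
    min_island_overlap = 10L,
    island_overlap_score = 90,
    island_edge_slack_pct = 5,
    min_internal_consensus = 10L,
    internal_identity_pct = 90,
    min_new_contig_len = 200L,
    abrupt_cov_pct = 80,
    gradual_window = 100L,
    gradual_cov_pct = 80,
    min_mapq = 20L,
    redundancy_identity = 0.95,
    inner_max = 30L,
    outer_max = 100L,
    error_threshold = 0L,
    gradual_check = FALSE,
    dedup_check = TRUE,
    # internal aligner knobs
    aligner_k = 15L,
    aligner_min_score = 20L,
    min_clip_len = 3L           # clipped tails shorter than this are jitter
  )
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  p[names(over)] <- over
  validate_parameters(p)
}

validate_parameters <- function(p) {
  pct <- c("clip_support_pct", "max_orphan_clip_pct", "min_orphan_extension_pct",
           "seed_identity_pct", "extend_identity_pct", "island_overlap_score",
           "island_edge_slack_pct", "internal_identity_pct", "abrupt_cov_pct",
           "gradual_cov_pct")
  for (f in pct) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 100)
      stop("parameter '", f, "' must be a percentage in [0, 100]")
  }
  cnt <- c("edge_clip_window", "min_clip_reads", "realign_edge_mult",
           "min_orphan_reads", "n_join", "seed_len", "max_gaps",
           "min_island_reads", "min_island_overlap", "min_internal_consensus",
           "min_new_contig_len", "gradual_window", "min_mapq", "inner_max",
           "outer_max", "error_threshold", "aligner_k", "aligner_min_score",
           "min_clip_len")
  for (f in cnt) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v != round(v))
      stop("parameter '", f, "' must be a non-negative integer count")
    p[[f]] <- as.integer(v)
  }
  if (!is.numeric(p$redundancy_identity) || p$redundancy_identity < 0 ||
      p$redundancy_identity > 1)
    stop("'redundancy_identity' must be a fraction in [0, 1]")
  for (f in c("gradual_check", "dedup_check"))
    if (!is.logical(p[[f]]) || length(p[[f]]) != 1 || is.na(p[[f]]))
      stop("parameter '", f, "' must be TRUE or FALSE")
  structure(p, class = "roast_params")
}

#' @export
print.roast_params <- function(x, ...) {
  cat("roast parameters:\n")
  for (n in names(x)) cat(sprintf("  %-26s %s\n", n, format(x[[n]])))
  invisible(x)
}

# resolve read-length dependent windows
edge_window_bases <- function(params, read_len) params$realign_edge_mult * read_len
end_ignore_bases <- function(params, read_len) read_len
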