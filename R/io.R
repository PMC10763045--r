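# FASTA / FASTQ / SAM readers and the TSV report writers.

#' Read an assembly from a FASTA file
#'
#' The header token before the first whitespace becomes the contig id;
#' sequences are uppercased.  Duplicate ids and empty sequences are errors.
#'
#' @param path FASTA file (optionally gzipped).
#' @param read_length optional read length to record on the assembly.
#' @return a `roast_assembly`.
#' @export
read_fasta <- function(path, read_length = NA_integer_) {
  x <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  seqs <- stats::setNames(toupper(as.character(x)), ids)
  if (anyDuplicated(ids))
    stop("duplicate id '", ids[duplicated(ids)][1], "' in ", path)
  empt <- nchar(seqs) == 0L
  if (any(empt))
    stop("empty sequence for record '", ids[empt][1], "' in ", path)
  new_assembly(seqs, read_length = read_length)
}

#' Write an assembly to a FASTA file (80-column wrapped)
#' @param asm a `roast_assembly`.
#' @param path output path.
#' @export
write_fasta <- function(asm, path) {
  x <- Biostrings::BStringSet(asm$seq)
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Read a pair of FASTQ files as mate-paired reads
#'
#' Ids are paired after stripping a trailing `/1` or `/2` (or whitespace
#' suffix); a record-count or id mismatch is an error.
#'
#' @param path1,path2 FASTQ files for mate 1 and mate 2.
#' @return a list with `ids`, `s1`, `s2` (character vectors) and `read_len`
#'   (modal read length).
#' @export
read_fastq_pair <- function(path1, path2) {
  r1 <- Biostrings::readBStringSet(path1, format = "fastq")
  r2 <- Biostrings::readBStringSet(path2, format = "fastq")
  if (length(r1) != length(r2))
    stop("read count mismatch: ", length(r1), " vs ", length(r2))
  strip <- function(n) sub("/[12]$", "", sub("\\s.*$", "", n))
  id1 <- strip(names(r1)); id2 <- strip(names(r2))
  bad <- which(id1 != id2)
  if (length(bad))
    stop("read id mismatch at record ", bad[1], ": '", id1[bad[1]],
         "' vs '", id2[bad[1]], "'")
  s1 <- toupper(as.character(r1)); s2 <- toupper(as.character(r2))
  names(s1) <- names(s2) <- NULL
  list(ids = id1, s1 = s1, s2 = s2,
       read_len = as.integer(stats::median(nchar(c(s1, s2)))))
}

#' Ingest externally produced alignments from a SAM file
#'
#' Reference names must all exist in the assembly.  CIGARs are parsed into
#' per-record soft-clip lengths, aligned (reference-consuming) spans, and
#' splice-junction (`N`) boundaries; the orientation class is derived from
#' the FLAG and mate fields.  Coordinates are converted to the 0-based
#' convention used internally.
#'
#' @param path SAM file.
#' @param assembly the `roast_assembly` the alignments refer to.
#' @return an alignment `data.table` in the same layout produced by
#'   [align_read_pairs()].
#' @export
parse_sam <- function(path, assembly) {
  # validate reference names against the assembly before conversion
  ln <- readLines(path, warn = FALSE)
  body_refs <- vapply(strsplit(ln[!startsWith(ln, "@")], "\t"),
                      function(x) if (length(x) >= 3) x[3] else "*",
                      character(1))
  unknown <- setdiff(setdiff(unique(body_refs), "*"), contig_ids(assembly))
  if (length(unknown))
    stop("unknown reference '", unknown[1], "' in ", path)
  bam <- Rsamtools::asBam(path,
                          destination = tempfile(fileext = ""),
                          overwrite = TRUE, indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  par <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq",
             "mrnm", "mpos"))
  b <- Rsamtools::scanBam(bam, param = par)[[1]]
  n <- length(b$qname)
  if (n == 0) return(empty_records())
  refs <- as.character(b$rname)
  unknown <- setdiff(stats::na.omit(unique(refs)), contig_ids(assembly))
  if (length(unknown))
    stop("unknown reference '", unknown[1], "' in ", path)
  flag <- b$flag
  mapped <- !bitwAnd(flag, 4L)
  paired <- bitwAnd(flag, 1L) > 0
  mate1 <- ifelse(paired & bitwAnd(flag, 128L) > 0, 2L, 1L)
  rev <- bitwAnd(flag, 16L) > 0
  mate_unmapped <- bitwAnd(flag, 8L) > 0

  ops <- GenomicAlignments::explodeCigarOps(ifelse(mapped, b$cigar, "1M"))
  lens <- GenomicAlignments::explodeCigarOpLengths(ifelse(mapped, b$cigar, "1M"))
  lclip <- vapply(seq_len(n), function(i) {
    o <- ops[[i]]; l <- lens[[i]]
    if (length(o) && o[1] == "S") l[1] else 0L
  }, integer(1))
  rclip <- vapply(seq_len(n), function(i) {
    o <- ops[[i]]; l <- lens[[i]]
    if (length(o) && o[length(o)] == "S") l[length(o)] else 0L
  }, integer(1))
  reflen <- vapply(seq_len(n), function(i) {
    o <- ops[[i]]; l <- lens[[i]]
    sum(l[o %in% c("M", "D", "N")])
  }, integer(1))
  junc <- lapply(seq_len(n), function(i) {
    o <- ops[[i]]; l <- lens[[i]]
    w <- which(o == "N")
    if (!length(w) || !mapped[i]) return(integer())
    cum <- cumsum(ifelse(o %in% c("M", "D", "N"), l, 0L))
    st <- b$pos[i] - 1L
    # interleaved (gap start, gap end) pairs, 0-based half-open
    as.integer(rbind(st + cum[w] - l[w], st + cum[w]))
  })
  qlen <- vapply(seq_len(n), function(i) {
    o <- ops[[i]]; l <- lens[[i]]
    sum(l[o %in% c("M", "S", "I")])
  }, integer(1))
  seqs <- as.character(b$seq)
  qlen <- ifelse(nchar(seqs) > 0, nchar(seqs), qlen)

  dt <- data.table::data.table(
    rid = match(b$qname, unique(b$qname)),
    read_id = b$qname,
    mate = mate1,
    contig = ifelse(mapped, refs, NA_character_),
    start = ifelse(mapped, b$pos - 1L, NA_integer_),
    mlen = ifelse(mapped, reflen, NA_integer_),
    lclip = ifelse(mapped, lclip, NA_integer_),
    rclip = ifelse(mapped, rclip, NA_integer_),
    strand = ifelse(mapped, ifelse(rev, -1L, 1L), NA_integer_),
    mapq = ifelse(mapped, as.integer(b$mapq), NA_integer_),
    score = NA_integer_,
    read_len = qlen,
    oseq = seqs,   # as stored in SAM: already reverse-complemented for '-'
    mate_mapped = !mate_unmapped,
    mate_contig = ifelse(!mate_unmapped, as.character(b$mrnm), NA_character_),
    mate_start = ifelse(!mate_unmapped, b$mpos - 1L, NA_integer_),
    junc = junc
  )
  # basic record invariants
  over <- dt[!is.na(contig)]
  clens <- contig_lengths(assembly)
  if (nrow(over) && any(over$start + over$mlen > clens[over$contig]))
    stop("alignment extends past contig end in ", path)
  derive_orientation(dt)
}

empty_records <- function() {
  data.table::data.table(
    rid = integer(), read_id = character(), mate = integer(),
    contig = character(), start = integer(), mlen = integer(),
    lclip = integer(), rclip = integer(), strand = integer(),
    mapq = integer(), score = integer(), read_len = integer(),
    oseq = character(), mate_mapped = logical(), mate_contig = character(),
    mate_start = integer(), orientation = character())
}

#' Write the improved assembly, change log and contig map
#'
#' Deterministic given the same inputs: rows are written in event order and
#' the contig map in initial-id order.
#'
#' @param events change-event `data.table` (see [roast_run()]).
#' @param map contig-map `data.table` with columns `initial_id`, `final_id`,
#'   `relation`.
#' @param out_dir output directory (created if needed).
#' @param assembly optional final assembly to write as `improved.fasta`.
#' @return invisibly, the paths written.
#' @export
write_reports <- function(events, map, out_dir, assembly = NULL) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) stop("cannot create directory ", out_dir)
  }
  paths <- character()
  ev <- data.table::as.data.table(events)
  keep <- c("outer_iter", "inner_iter", "kind", "contigs_in", "contigs_out",
            "coords", "seq_delta_len")
  for (k in setdiff(keep, names(ev))) ev[[k]] <- if (k == "kind") character() else NA
  p1 <- file.path(out_dir, "change_log.tsv")
  utils::write.table(ev[, keep, with = FALSE], p1, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  p2 <- file.path(out_dir, "contig_map.tsv")
  mp <- data.table::as.data.table(map)
  data.table::setorder(mp, initial_id)
  utils::write.table(mp, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(p1, p2)
  if (!is.null(assembly)) {
    p3 <- file.path(out_dir, "improved.fasta")
    write_fasta(assembly, p3)
    paths <- c(paths, p3)
  }
  invisible(paths)
}
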