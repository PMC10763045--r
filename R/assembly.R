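# Assembly container.
#
# An assembly is a plain list with class "roast_assembly":
#   seq  - named character vector of contig sequences (names are contig ids)
#   tags - named list of character tag vectors, one entry per contig
#   prov - named list of integer vectors (one per base): 0 = base inherited
#          from an input contig, 1 = base derived from read consensus.
#          Provenance lets overlap merges prefer assembler-original bases
#          over read-derived ones when the two disagree.
#   read_length - integer, inferred from the input reads (NA until known)

IUPAC_CHARS <- "ACGTUMRWSYKVHDBN"

#' Construct an assembly from contig sequences
#'
#' @param seqs named character vector of nucleotide sequences.
#' @param read_length integer read length, if known.
#' @param tags optional named list of character tag vectors.
#' @param prov optional named list of per-base provenance vectors
#'   (0 = original, 1 = read-derived); defaults to all-original.
#' @return a `roast_assembly` object.
#' @export
new_assembly <- function(seqs, read_length = NA_integer_, tags = NULL,
                         prov = NULL) {
  ids <- names(seqs)
  if (is.null(ids) || any(is.na(ids)) || any(ids == ""))
    stop("every contig must have a non-empty id")
  if (anyDuplicated(ids))
    stop("duplicate id: ", seqs_dup <- ids[duplicated(ids)][1])
  seqs <- toupper(seqs)
  if (any(nchar(seqs) == 0L))
    stop("empty sequence for contig '", ids[nchar(seqs) == 0L][1], "'")
  bad <- grepl(sprintf("[^%s]", IUPAC_CHARS), seqs)
  if (any(bad))
    stop("contig '", ids[bad][1], "' contains non-IUPAC characters")
  if (is.null(tags)) tags <- stats::setNames(vector("list", length(ids)), ids)
  if (is.null(prov))
    prov <- stats::setNames(lapply(nchar(seqs), function(n) integer(n)), ids)
  structure(list(seq = seqs, tags = tags, prov = prov,
                 read_length = as.integer(read_length)),
            class = "roast_assembly")
}

#' @export
print.roast_assembly <- function(x, ...) {
  cat(sprintf("roast_assembly: %d contigs, %d bases (read_length %s)\n",
              length(x$seq), sum(nchar(x$seq)),
              ifelse(is.na(x$read_length), "?", x$read_length)))
  invisible(x)
}

#' @export
length.roast_assembly <- function(x) length(x$seq)

contig_ids <- function(asm) names(asm$seq)
contig_lengths <- function(asm) stats::setNames(nchar(asm$seq), names(asm$seq))

asm_add <- function(asm, id, seq, prov = NULL, tags = character()) {
  if (id %in% names(asm$seq)) stop("duplicate id: ", id)
  asm$seq[[id]] <- seq
  asm$prov[[id]] <- if (is.null(prov)) integer(nchar(seq)) else prov
  asm$tags[[id]] <- tags
  asm
}

asm_drop <- function(asm, ids) {
  keep <- setdiff(names(asm$seq), ids)
  asm$seq <- asm$seq[keep]
  asm$prov <- asm$prov[keep]
  asm$tags <- asm$tags[keep]
  asm
}

asm_replace <- function(asm, id, seq, prov) {
  stopifnot(id %in% names(asm$seq), nchar(seq) == length(prov))
  asm$seq[[id]] <- seq
  asm$prov[[id]] <- prov
  asm
}

# reverse-complement sequence together with its provenance
revcomp_with_prov <- function(seq, prov) {
  list(seq = cpp_revcomp(seq), prov = rev(prov))
}
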