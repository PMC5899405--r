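#' Read / write FASTA
#'
#' Thin wrappers around Biostrings keeping names to the first whitespace
#' token (the convention aligners use for contig names).
#'
#' @param path File path.
#' @return `read_fasta()`: a `DNAStringSet`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' @rdname read_fasta
#' @param x A `DNAStringSet` or named character vector.
#' @export
write_fasta <- function(x, path) {
  if (!inherits(x, "DNAStringSet")) x <- Biostrings::DNAStringSet(as_seq_chr(x))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write alignments as SAM
#'
#' Writes a read tibble as a headered SAM file: FLAG carries strand (0x10),
#' duplicate (0x400) and unmapped (0x4) bits; sequences are stored in
#' reference orientation per the SAM convention. Converted reads carry the
#' bisulphite strand in an `XG` tag (`CT` top / `GA` bottom); the simulated
#' haplotype of origin, when present, goes in a `ZH` tag so truth survives a
#' round trip.
#'
#' @param reads Read tibble (see [simulate_reads()]).
#' @param reference Reference the reads are placed on (for `@SQ` lines);
#'   include the control genome when control reads are present.
#' @param path Output path.
#' @export
write_sam <- function(reads, reference, path) {
  ref <- as_seq_chr(reference)
  header <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", names(ref), nchar(ref))
  )
  unmapped <- is.na(reads$contig)
  flag <- ifelse(unmapped, 4L, 0L) +
    ifelse(!unmapped & reads$strand == "-", 16L, 0L) +
    ifelse(reads$duplicate, 1024L, 0L)
  lines <- paste(
    reads$name, flag,
    ifelse(unmapped, "*", reads$contig),
    ifelse(unmapped, 0L, reads$pos),
    reads$mapq,
    ifelse(unmapped, "*", paste0(nchar(reads$seq), "M")),
    "*", 0L, 0L,
    reads$seq,
    strrep("I", nchar(reads$seq)),
    sep = "\t"
  )
  tags <- ifelse(is.na(reads$bs_tag), "", paste0("\tXG:Z:", reads$bs_tag))
  if ("haplotype" %in% names(reads)) {
    tags <- paste0(tags, ifelse(is.na(reads$haplotype), "",
      paste0("\tZH:Z:", reads$haplotype)
    ))
  }
  writeLines(c(header, paste0(lines, tags)), path)
  invisible(path)
}

#' Read a SAM file into a read tibble
#'
#' Parses via Rsamtools (SAM is converted to BAM in a temporary location and
#' scanned). Matches-only CIGARs are assumed downstream; alignments with
#' indel or clip operations are rejected by the pileup engine with a clear
#' error rather than silently mis-stacked.
#'
#' @param path SAM file path.
#' @return Tibble with columns `name`, `contig` (`NA` if unmapped), `pos`,
#'   `strand`, `mapq`, `seq`, `cigar`, `duplicate`, `converted`, `bs_tag`,
#'   `haplotype` (from the `ZH` tag when present, else `NA`).
#' @export
read_sam <- function(path) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
  on.exit(unlink(bam), add = TRUE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq"),
    tag = c("XG", "ZH")
  )
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(x$qname)
  bs_tag <- x$tag$XG %||% rep(NA_character_, n)
  hap <- x$tag$ZH %||% rep(NA_character_, n)
  tibble::tibble(
    name = x$qname,
    contig = as.character(x$rname),
    pos = x$pos,
    strand = ifelse(bitwAnd(x$flag, 16L) > 0L, "-", "+"),
    mapq = as.integer(x$mapq),
    seq = as.character(x$seq),
    cigar = x$cigar,
    duplicate = bitwAnd(x$flag, 1024L) > 0L,
    converted = !is.na(bs_tag),
    bs_tag = bs_tag,
    haplotype = hap
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write reads as FASTQ
#'
#' Minus-strand records are reverse-complemented back to read orientation;
#' base qualities are uniform (quality simulation is out of scope).
#'
#' @param reads Read tibble.
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  s <- reads$seq
  neg <- !is.na(reads$strand) & reads$strand == "-"
  s[neg] <- revcomp(s[neg])
  writeLines(
    paste0("@", reads$name, "\n", s, "\n+\n", strrep("I", nchar(s))),
    path
  )
  invisible(path)
}

#' Read / write BED intervals
#'
#' BED is 0-based half-open; tibbles carry `contig`, `start`, `end` and an
#' optional `name` column.
#'
#' @param path File path.
#' @export
read_bed <- function(path) {
  x <- readr::read_tsv(path,
    col_names = FALSE, show_col_types = FALSE,
    col_types = readr::cols(.default = readr::col_guess())
  )
  names(x)[1:3] <- c("contig", "start", "end")
  if (ncol(x) >= 4) names(x)[4] <- "name"
  tibble::as_tibble(x)
}

#' @rdname read_bed
#' @param x Tibble with columns `contig`, `start`, `end` (0-based half-open)
#'   and optionally `name`.
#' @export
write_bed <- function(x, path) {
  cols <- intersect(c("contig", "start", "end", "name"), names(x))
  readr::write_tsv(x[, cols], path, col_names = FALSE)
  invisible(path)
}
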