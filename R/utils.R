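#' @importFrom rlang .data
#' @importFrom dplyr %>%
NULL

DNA_BASES <- c("A", "C", "G", "T")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Derive a deterministic sub-stream seed
#'
#' One top-level seed governs all stochastic stages; each named operation
#' draws from its own sub-stream so that, e.g., adding reads to a simulation
#' does not perturb the genome it was built on.
#'
#' @param seed Integer top-level seed.
#' @param stream Character stream name.
#' @return An integer seed in `[0, 2^31)`.
#' @keywords internal
substream_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}

with_substream <- function(seed, stream, code) {
  withr::with_seed(substream_seed(seed, stream), code)
}

#' Reverse-complement a character vector of DNA sequences
#' @param x Character vector of sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Coerce a reference to a named character vector of sequences.
as_seq_chr <- function(reference) {
  if (inherits(reference, "DNAStringSet")) {
    out <- as.character(reference)
  } else if (inherits(reference, "DNAString")) {
    out <- stats::setNames(as.character(reference), "seq")
  } else if (is.character(reference)) {
    out <- reference
  } else {
    stop("reference must be a DNAStringSet or a named character vector")
  }
  if (is.null(names(out)) || any(!nzchar(names(out)))) {
    stop("reference sequences must be named")
  }
  out
}

#' Classify cytosine context (CpG / CHG / CHH)
#'
#' Plant methylomes are profiled in three sequence contexts. For a
#' forward-strand cytosine at `pos`, the context is read from the reference as
#' `C,G,.` = CpG, `C,H,G` = CHG and `C,H,H` = CHH with H one of A/C/T; for a
#' reverse-strand cytosine (reference G) the same rule is applied to the
#' reverse complement. Sites within two bases of a contig end cannot be
#' classified and are labelled `"truncated"`.
#'
#' @param reference Named character vector or `DNAStringSet` of contigs.
#' @param contig,pos,strand Parallel vectors locating the cytosines
#'   (1-based positions; strand `"+"` means reference base C, `"-"` reference
#'   base G).
#' @return Character vector: `"CpG"`, `"CHG"`, `"CHH"` or `"truncated"`.
#' @export
classify_context <- function(reference, contig, pos, strand) {
  ref <- as_seq_chr(reference)
  lens <- stats::setNames(nchar(ref), names(ref))
  seqs <- ref[contig]
  L <- lens[contig]
  out <- rep("truncated", length(pos))
  fwd <- strand == "+"
  ok_f <- fwd & pos + 2 <= L
  ok_r <- !fwd & pos - 2 >= 1
  tri <- character(length(pos))
  tri[ok_f] <- stringr::str_sub(seqs[ok_f], pos[ok_f], pos[ok_f] + 2)
  tri[ok_r] <- revcomp(stringr::str_sub(seqs[ok_r], pos[ok_r] - 2, pos[ok_r]))
  ok <- ok_f | ok_r
  b2 <- substr(tri[ok], 2, 2)
  b3 <- substr(tri[ok], 3, 3)
  ctx <- ifelse(b2 == "G", "CpG", ifelse(b3 == "G", "CHG", "CHH"))
  out[ok] <- ctx
  out
}

#' Enumerate cytosine sites of a reference
#'
#' Returns every position carrying a cytosine on either strand: reference C
#' on `"+"`, reference G on `"-"`, together with its context.
#'
#' @inheritParams classify_context
#' @param mask Optional tibble of sites (`contig`, `pos`, `strand`) to
#'   exclude, e.g. C/T SNP positions masked by [correct_reference()].
#' @return Tibble with columns `contig`, `pos`, `strand`, `context`.
#' @export
cytosine_sites <- function(reference, mask = NULL) {
  ref <- as_seq_chr(reference)
  per_contig <- purrr::imap(ref, function(s, nm) {
    b <- strsplit(s, "", fixed = TRUE)[[1]]
    fwd <- which(b == "C")
    rev <- which(b == "G")
    tibble::tibble(
      contig = nm,
      pos = c(fwd, rev),
      strand = rep(c("+", "-"), c(length(fwd), length(rev)))
    )
  })
  sites <- dplyr::bind_rows(per_contig) %>%
    dplyr::arrange(.data$contig, .data$pos, .data$strand)
  sites$context <- classify_context(ref, sites$contig, sites$pos, sites$strand)
  if (!is.null(mask) && nrow(mask) > 0) {
    sites <- dplyr::anti_join(sites, mask, by = c("contig", "pos", "strand"))
  }
  sites
}

# Apply single-base substitutions at several positions of one sequence.
substitute_bases <- function(seq, pos, base) {
  if (length(pos) == 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  ch[pos] <- base
  paste(ch, collapse = "")
}

# Split fixed-length read sequences into a base matrix (reads x position).
seq_matrix <- function(seqs, read_length) {
  stopifnot(all(nchar(seqs) == read_length))
  matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
    nrow = length(seqs), ncol = read_length, byrow = TRUE
  )
}

collapse_seq_matrix <- function(m) {
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}
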