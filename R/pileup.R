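#' Filter alignments before pileup
#'
#' Standard post-mapping cleanup: unmapped records, reads below the mapping
#' quality floor (default keeps MAPQ >= 10, i.e. removes "poor quality"
#' reads under 10), duplicate-flagged reads and non-uniquely mapped reads
#' are removed. Input order is preserved.
#'
#' Uniqueness uses the `unique` column when present; otherwise the usual
#' aligner convention that MAPQ 0 marks a multi-mapper is applied.
#'
#' @param reads Read tibble ([read_sam()] / [simulate_reads()]).
#' @param min_mapq Minimum MAPQ retained (inclusive).
#' @param drop_duplicates Remove duplicate-flagged reads.
#' @param unique_only Remove non-uniquely mapped reads.
#' @return Filtered read tibble.
#' @export
filter_alignments <- function(reads, min_mapq = 10, drop_duplicates = TRUE,
                              unique_only = TRUE) {
  keep <- !is.na(reads$contig) & reads$mapq >= min_mapq
  if (drop_duplicates) keep <- keep & !reads$duplicate
  if (unique_only) {
    uniq <- if ("unique" %in% names(reads)) reads$unique else reads$mapq > 0
    keep <- keep & uniq
  }
  reads[keep, , drop = FALSE]
}

#' Build a base-level pileup from aligned reads
#'
#' Stacks matches-only alignments into per-position base counts in reference
#' orientation (SAM sequences are already reference-oriented, so no
#' re-complementing is needed for minus-strand reads). Columns with zero
#' depth are omitted. `mean_mapq` is the arithmetic mean MAPQ of the reads
#' contributing to the column.
#'
#' @param reads Filtered read tibble; alignments must fit their contig.
#' @param reference Reference sequences (for contig bounds checking).
#' @return Tibble with `contig`, `pos`, `n_A`, `n_C`, `n_G`, `n_T`, `depth`,
#'   `mean_mapq`, sorted by contig then position.
#' @export
pileup <- function(reads, reference) {
  ref <- as_seq_chr(reference)
  reads <- reads[!is.na(reads$contig), , drop = FALSE]
  if (nrow(reads) == 0) {
    return(tibble::tibble(
      contig = character(), pos = integer(),
      n_A = integer(), n_C = integer(), n_G = integer(), n_T = integer(),
      depth = integer(), mean_mapq = numeric()
    ))
  }
  if ("cigar" %in% names(reads)) {
    bad <- !is.na(reads$cigar) & !grepl("^[0-9]+M$", reads$cigar)
    if (any(bad)) {
      stop(
        "unsupported CIGAR (only matches-only alignments are handled): read ",
        reads$name[which(bad)[1]]
      )
    }
  }
  unknown <- !(reads$contig %in% names(ref))
  if (any(unknown)) {
    stop("read aligned to unknown contig: ", reads$name[which(unknown)[1]])
  }
  len <- nchar(reads$seq)
  over <- reads$pos + len - 1L > nchar(ref)[match(reads$contig, names(ref))]
  if (any(over)) {
    stop("read overhangs contig end: ", reads$name[which(over)[1]])
  }

  per_len <- split(seq_len(nrow(reads)), len)
  obs <- purrr::map_dfr(per_len, function(idx) {
    r <- reads[idx, , drop = FALSE]
    w <- nchar(r$seq[1])
    m <- seq_matrix(r$seq, w)
    n <- nrow(r)
    tibble::tibble(
      contig = rep(r$contig, w),
      pos = rep(r$pos, w) + rep(0:(w - 1L), each = n),
      base = as.vector(m),
      mapq = rep(r$mapq, w)
    )
  })
  cols <- obs %>%
    dplyr::group_by(.data$contig, .data$pos) %>%
    dplyr::summarise(
      n_A = sum(.data$base == "A"),
      n_C = sum(.data$base == "C"),
      n_G = sum(.data$base == "G"),
      n_T = sum(.data$base == "T"),
      depth = dplyr::n(),
      mean_mapq = mean(.data$mapq),
      .groups = "drop"
    ) %>%
    dplyr::arrange(.data$contig, .data$pos)
  cols$pos <- as.integer(cols$pos)
  cols
}

#' Call SNPs in a polyploid pileup
#'
#' Emits an alternate-allele call at every column passing the polyploid
#' thresholds: coverage of at least `min_cov`, column mean mapping quality
#' strictly above `min_mean_mapq`, and some non-reference base at a
#' frequency strictly above `min_maf` (frequencies are counts over the
#' post-filter column depth). Positions whose reference base is not A/C/G/T
#' are skipped and tallied in the `n_skipped` attribute.
#'
#' @param columns Pileup tibble from [pileup()].
#' @param reference Reference sequences.
#' @param min_cov Minimum column depth (default 5).
#' @param min_mean_mapq Column mean MAPQ must exceed this (default 15).
#' @param min_maf Alternate allele frequency must exceed this (default 0.1).
#' @return Tibble with one row per qualifying alternate allele: `contig`,
#'   `pos`, `ref_allele`, `alt_allele`, `alt_freq`, `depth`, `mean_mapq`.
#' @export
call_polyploid_snps <- function(columns, reference, min_cov = 5,
                                min_mean_mapq = 15, min_maf = 0.1) {
  ref <- as_seq_chr(reference)
  if (nrow(columns) == 0) {
    out <- tibble::tibble(
      contig = character(), pos = integer(), ref_allele = character(),
      alt_allele = character(), alt_freq = numeric(), depth = integer(),
      mean_mapq = numeric()
    )
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  ref_base <- stringr::str_sub(ref[columns$contig], columns$pos, columns$pos)
  skip <- !(ref_base %in% DNA_BASES)
  n_skipped <- sum(skip)
  keep <- !skip & columns$depth >= min_cov & columns$mean_mapq > min_mean_mapq
  cand <- columns[keep, , drop = FALSE]
  cand$ref_allele <- ref_base[keep]
  long <- cand %>%
    tidyr::pivot_longer(
      dplyr::all_of(c("n_A", "n_C", "n_G", "n_T")),
      names_to = "alt_allele", values_to = "count", names_prefix = "n_"
    ) %>%
    dplyr::filter(.data$alt_allele != .data$ref_allele, .data$count > 0) %>%
    dplyr::mutate(alt_freq = .data$count / .data$depth) %>%
    dplyr::filter(.data$alt_freq > min_maf) %>%
    dplyr::select(
      "contig", "pos", "ref_allele", "alt_allele",
      "alt_freq", "depth", "mean_mapq"
    ) %>%
    dplyr::arrange(.data$contig, .data$pos, .data$alt_allele)
  attr(long, "n_skipped") <- n_skipped
  long
}

#' Keep one primary alternate allele per SNP position
#'
#' The highest-frequency alternate wins; frequency ties break
#' alphabetically.
#'
#' @param snps SNP call tibble from [call_polyploid_snps()].
#' @return One row per (`contig`, `pos`).
#' @export
primary_alt <- function(snps) {
  snps %>%
    dplyr::arrange(
      .data$contig, .data$pos, dplyr::desc(.data$alt_freq), .data$alt_allele
    ) %>%
    dplyr::distinct(.data$contig, .data$pos, .keep_all = TRUE)
}
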