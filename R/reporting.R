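# Per-contig coverage Rle list from matches-only alignments.
coverage_rle <- function(reads, ref) {
  lapply(stats::setNames(names(ref), names(ref)), function(nm) {
    r <- reads[reads$contig == nm, , drop = FALSE]
    ir <- IRanges::IRanges(start = r$pos, width = nchar(r$seq))
    IRanges::coverage(ir, width = nchar(ref[[nm]]))
  })
}

#' Capture-efficiency coverage statistics
#'
#' Per-contig and aggregate mapping summaries of a capture experiment:
#' percentage of reads aligned (against a supplied pre-filter total, which
#' counts individual read records), per-contig percentage covered and mean
#' depth, how many contigs received any read, and total base-space mapped
#' (reference positions with depth >= 1). "Mean depth" is averaged over
#' covered positions by default; set `depth_over_covered = FALSE` to divide
#' by contig length instead.
#'
#' @param reads Filtered alignment tibble.
#' @param reference Reference sequences.
#' @param n_total_reads Pre-filter read count for the percent-aligned
#'   figure; defaults to `nrow(reads)`.
#' @param depth_over_covered Average depth over covered positions (default)
#'   or over all positions.
#' @return Object of class `coverage_report`: list with `per_contig`
#'   (tibble `contig`, `length`, `covered_bases`, `pct_covered`,
#'   `mean_depth`, `mapped`) and `aggregate` (one-row tibble).
#' @export
coverage_stats <- function(reads, reference, n_total_reads = NULL,
                           depth_over_covered = TRUE) {
  if (length(reference) == 0) stop("empty reference")
  ref <- as_seq_chr(reference)
  reads <- reads[!is.na(reads$contig) & reads$contig %in% names(ref), ,
    drop = FALSE
  ]
  n_total_reads <- n_total_reads %||% nrow(reads)
  cov <- coverage_rle(reads, ref)
  per_contig <- purrr::imap_dfr(cov, function(rle, nm) {
    v <- as.integer(rle)
    covered <- sum(v > 0)
    tibble::tibble(
      contig = nm,
      length = length(v),
      covered_bases = covered,
      pct_covered = 100 * covered / length(v),
      mean_depth = if (depth_over_covered) {
        if (covered > 0) mean(v[v > 0]) else 0
      } else {
        mean(v)
      },
      mapped = covered > 0
    )
  })
  aggregate <- tibble::tibble(
    n_reads_aligned = nrow(reads),
    pct_reads_aligned =
      if (n_total_reads > 0) 100 * nrow(reads) / n_total_reads else NA_real_,
    mean_pct_covered = mean(per_contig$pct_covered),
    mean_depth = mean(per_contig$mean_depth),
    n_contigs = nrow(per_contig),
    n_contigs_mapped = sum(per_contig$mapped),
    pct_contigs_mapped = 100 * mean(per_contig$mapped),
    base_space_mapped = sum(per_contig$covered_bases)
  )
  structure(
    list(per_contig = per_contig, aggregate = aggregate),
    class = "coverage_report"
  )
}

#' @export
print.coverage_report <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf(
    paste0(
      "<coverage_report> %d read(s) aligned (%.1f%%); %d/%d contig(s) ",
      "mapped\n  mean %% covered per contig %.1f; mean depth %.1fx; ",
      "base-space mapped %d bp\n"
    ),
    a$n_reads_aligned, a$pct_reads_aligned, a$n_contigs_mapped,
    a$n_contigs, a$mean_pct_covered, a$mean_depth, a$base_space_mapped
  ))
  invisible(x)
}

#' Mean depth per bait interval
#'
#' @param reads Filtered alignment tibble.
#' @param reference Reference sequences.
#' @param baits Tibble `contig`, `start` (0-based), `end` of bait
#'   intervals (e.g. from [read_bed()]).
#' @return The baits tibble with a `mean_depth` column (averaged over every
#'   position of the bait, covered or not).
#' @export
bait_depths <- function(reads, reference, baits) {
  ref <- as_seq_chr(reference)
  cov <- coverage_rle(
    reads[!is.na(reads$contig) & reads$contig %in% names(ref), ,
      drop = FALSE
    ],
    ref
  )
  baits$mean_depth <- purrr::pmap_dbl(
    baits[, c("contig", "start", "end")],
    function(contig, start, end) {
      v <- as.integer(cov[[contig]])
      mean(v[(start + 1L):end])
    }
  )
  baits
}

#' Bait depth-evenness profile
#'
#' Summarises how even the capture was across baits: the fraction of baits
#' whose mean depth exceeds twice the overall mean (over-captured) and the
#' fraction below an absolute floor (under-captured, default 5x).
#'
#' @param bait_mean_depths Numeric vector of per-bait mean depths (e.g.
#'   `bait_depths()$mean_depth`).
#' @param low_depth Absolute low-coverage threshold (default 5).
#' @return Tibble `n_baits`, `mean_depth`, `frac_high` (> 2x mean),
#'   `frac_low` (< `low_depth`), `defined`.
#' @export
bait_depth_profile <- function(bait_mean_depths, low_depth = 5) {
  if (length(bait_mean_depths) == 0) {
    return(tibble::tibble(
      n_baits = 0L, mean_depth = NA_real_, frac_high = NA_real_,
      frac_low = NA_real_, defined = FALSE
    ))
  }
  m <- mean(bait_mean_depths)
  tibble::tibble(
    n_baits = length(bait_mean_depths),
    mean_depth = m,
    frac_high = mean(bait_mean_depths > 2 * m),
    frac_low = mean(bait_mean_depths < low_depth),
    defined = TRUE
  )
}

#' Windowed feature frequencies, min-max normalised
#'
#' Counts placed features (SNPs, informative cytosines) per half-open
#' window `[k*w, (k+1)*w)` along each chromosome and normalises the counts
#' to `[0, 1]` by the track-wide minimum and maximum, the scale used for
#' genome-wide frequency plots. When every window has the same count the
#' normalised track is all zeros. Normalisation is idempotent on the
#' normalised values' ordering and invariant to scaling the raw counts.
#'
#' @param positions Tibble `chromosome`, `pos` (1-based placed coordinates).
#' @param chromosome_lengths Named numeric vector of chromosome lengths.
#' @param window_size Window width in bp (default 1 Mb).
#' @return Tibble of class `capmeth_windows`: `chromosome`, `window_start`
#'   (0-based), `raw`, `normalized`.
#' @export
window_frequencies <- function(positions, chromosome_lengths,
                               window_size = 1e6) {
  stopifnot(window_size >= 1, !is.null(names(chromosome_lengths)))
  bad <- !(positions$chromosome %in% names(chromosome_lengths))
  if (any(bad)) {
    stop("feature on unknown chromosome: row ", which(bad)[1])
  }
  over <- positions$pos >
    chromosome_lengths[positions$chromosome]
  if (any(over)) {
    stop(
      "feature beyond chromosome length: ", positions$chromosome[which(over)[1]],
      ":", positions$pos[which(over)[1]]
    )
  }
  grid <- purrr::imap_dfr(chromosome_lengths, function(L, nm) {
    tibble::tibble(
      chromosome = nm,
      window_start = seq(0, L - 1, by = window_size)
    )
  })
  counts <- positions %>%
    dplyr::mutate(
      window_start = floor((.data$pos - 1) / window_size) * window_size
    ) %>%
    dplyr::count(.data$chromosome, .data$window_start, name = "raw")
  track <- dplyr::left_join(
    grid, counts,
    by = c("chromosome", "window_start")
  ) %>%
    dplyr::mutate(raw = dplyr::coalesce(.data$raw, 0L))
  rng <- range(track$raw)
  track$normalized <- if (rng[2] > rng[1]) {
    (track$raw - rng[1]) / (rng[2] - rng[1])
  } else {
    rep(0, nrow(track))
  }
  structure(track, class = c("capmeth_windows", class(track)))
}
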