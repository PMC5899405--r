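#' Tile probe candidates across design-space contigs
#'
#' Emits fixed-length candidate probes at a regular step (the capture design
#' tiles 120-mers every 40 bp): a contig of length `L >= probe_length`
#' yields `floor((L - probe_length) / step) + 1` candidates at 0-based
#' offsets `0, step, 2*step, ...`; shorter contigs yield none.
#'
#' @param contigs Design-space sequences (`DNAStringSet` or named character
#'   vector).
#' @param probe_length Probe length in bp (default 120).
#' @param step Tiling interval in bp (default 40).
#' @return Tibble `contig`, `offset` (0-based), `length`, `seq`,
#'   `gc_content`.
#' @export
tile_candidates <- function(contigs, probe_length = 120, step = 40) {
  stopifnot(probe_length >= 1, step >= 1)
  ref <- as_seq_chr(contigs)
  out <- purrr::imap_dfr(ref, function(s, nm) {
    L <- nchar(s)
    if (L < probe_length) {
      return(tibble::tibble(
        contig = character(), offset = integer(), length = integer(),
        seq = character()
      ))
    }
    offs <- seq(0L, L - probe_length, by = step)
    tibble::tibble(
      contig = nm, offset = as.integer(offs),
      length = as.integer(probe_length),
      seq = stringr::str_sub(s, offs + 1L, offs + probe_length)
    )
  })
  out$gc_content <- gc_fraction(out$seq)
  out
}

gc_fraction <- function(seq) {
  if (length(seq) == 0) return(numeric())
  stringr::str_count(seq, "[GC]") / nchar(seq)
}

#' Annotate probe candidates for ranking
#'
#' Fills the three ranking annotations the design uses: percentage
#' alignment to an external reference (identity), counts of homoeologous
#' and varietal SNPs overlapping the probe, and prior mean depth of
#' coverage from earlier capture experiments. Candidates without an
#' alignment record get identity 0; a missing depth track leaves
#' `prior_mean_depth` as `NA`, which ranking treats as neutral.
#'
#' @param candidates Tibble from [tile_candidates()].
#' @param alignments Optional tibble `contig`, `offset`, `identity`
#'   (fraction in `[0, 1]`) keyed per candidate.
#' @param homoeo_snps,varietal_snps Optional SNP tables with `contig`,
#'   `pos` (1-based).
#' @param depth_track Optional per-position depth tibble `contig`, `pos`,
#'   `depth`.
#' @return Candidates with `alignment_identity`, `homoeo_snp_count`,
#'   `varietal_snp_count`, `prior_mean_depth` filled.
#' @export
annotate_candidates <- function(candidates, alignments = NULL,
                                homoeo_snps = NULL, varietal_snps = NULL,
                                depth_track = NULL) {
  count_overlaps <- function(snps) {
    if (is.null(snps) || nrow(snps) == 0) {
      return(rep(0L, nrow(candidates)))
    }
    n <- integer(nrow(candidates))
    for (nm in unique(candidates$contig)) {
      ci <- which(candidates$contig == nm)
      sp <- snps$pos[snps$contig == nm]
      if (length(sp) == 0) next
      ir <- IRanges::IRanges(
        start = candidates$offset[ci] + 1L,
        width = candidates$length[ci]
      )
      n[ci] <- IRanges::countOverlaps(ir, IRanges::IRanges(sp, width = 1L))
    }
    n
  }
  candidates$alignment_identity <- if (is.null(alignments)) {
    0
  } else {
    al <- dplyr::left_join(
      candidates[, c("contig", "offset")],
      alignments[, c("contig", "offset", "identity")],
      by = c("contig", "offset")
    )
    dplyr::coalesce(al$identity, 0)
  }
  candidates$homoeo_snp_count <- count_overlaps(homoeo_snps)
  candidates$varietal_snp_count <- count_overlaps(varietal_snps)
  candidates$prior_mean_depth <- if (is.null(depth_track)) {
    NA_real_
  } else {
    md <- numeric(nrow(candidates))
    for (nm in unique(candidates$contig)) {
      ci <- which(candidates$contig == nm)
      dt <- depth_track[depth_track$contig == nm, , drop = FALSE]
      depth_vec <- numeric(max(
        candidates$offset[ci] + candidates$length[ci], dt$pos, 0
      ))
      depth_vec[dt$pos] <- dt$depth
      md[ci] <- vapply(ci, function(i) {
        mean(depth_vec[(candidates$offset[i] + 1L):(
          candidates$offset[i] + candidates$length[i])])
      }, numeric(1))
    }
    md
  }
  candidates
}

#' Rank candidates and select the probe set
#'
#' The rank score is a configurable weighted sum, monotone in each design
#' criterion: alignment identity, normalised homoeologous SNP count,
#' normalised varietal SNP count, and closeness of the prior mean depth to
#' the median prior depth (probes from regions that captured at a typical
#' depth before are preferred over both dead and runaway regions); missing
#' depth is neutral (0.5). Selection order: probes forced by priority
#' intervals (tiled end-to-end, step = probe length) come first; with the
#' even-tiling bias, the best candidate of each not-yet-represented contig
#' is taken before any contig receives a second probe; remaining slots fill
#' by descending score. Ties break lexicographically (contig, offset) so
#' selection is a deterministic, permutation-invariant function of the
#' candidate set.
#'
#' @param candidates Annotated candidate tibble.
#' @param target_count Number of probes to select.
#' @param weights Numeric length-4 vector: identity, homoeologous SNPs,
#'   varietal SNPs, depth closeness.
#' @param one_per_contig_bias Prefer spreading probes across contigs.
#' @param priority_intervals Optional tibble `contig`, `start` (0-based),
#'   `end` of regions tiled end-to-end and force-included.
#' @param contigs Sequences, required to build forced probes not already in
#'   `candidates`.
#' @return List of class `probe_set`: `selected` (tibble with `rank_score`
#'   and `forced` flag), `boosted` (empty until [boost()]), `target_count`.
#' @export
rank_and_select <- function(candidates, target_count,
                            weights = c(1, 1, 1, 1),
                            one_per_contig_bias = TRUE,
                            priority_intervals = NULL,
                            contigs = NULL) {
  stopifnot(length(weights) == 4, target_count >= 0)
  probe_length <- if (nrow(candidates) > 0) candidates$length[1] else 120L

  forced <- tibble::tibble(
    contig = character(), offset = integer(), length = integer(),
    seq = character()
  )
  if (!is.null(priority_intervals) && nrow(priority_intervals) > 0) {
    forced <- purrr::pmap_dfr(priority_intervals, function(contig, start, end, ...) {
      offs <- seq(start, end - probe_length, by = probe_length)
      tibble::tibble(
        contig = contig, offset = as.integer(offs),
        length = as.integer(probe_length)
      )
    })
    forced$seq <- if (!is.null(contigs)) {
      ref <- as_seq_chr(contigs)
      stringr::str_sub(
        ref[forced$contig], forced$offset + 1L, forced$offset + forced$length
      )
    } else {
      NA_character_
    }
    forced <- dplyr::distinct(forced, .data$contig, .data$offset,
      .keep_all = TRUE
    )
    if (nrow(forced) > target_count) {
      stop(
        "target_count (", target_count, ") smaller than the ",
        nrow(forced), " probes forced by priority intervals (deficit ",
        nrow(forced) - target_count, ")"
      )
    }
  }

  norm01 <- function(x) if (max(x, 0) > 0) x / max(x) else rep(0, length(x))
  cand <- candidates
  if (nrow(cand) > 0) {
    dev <- abs(cand$prior_mean_depth -
      stats::median(cand$prior_mean_depth, na.rm = TRUE))
    closeness <- if (all(is.na(dev)) || max(dev, na.rm = TRUE) == 0) {
      ifelse(is.na(dev), 0.5, 1)
    } else {
      ifelse(is.na(dev), 0.5, 1 - dev / max(dev, na.rm = TRUE))
    }
    cand$rank_score <- weights[1] * cand$alignment_identity +
      weights[2] * norm01(cand$homoeo_snp_count) +
      weights[3] * norm01(cand$varietal_snp_count) +
      weights[4] * closeness
    cand <- cand %>%
      dplyr::arrange(
        dplyr::desc(.data$rank_score), .data$contig, .data$offset
      ) %>%
      dplyr::anti_join(forced, by = c("contig", "offset"))
  } else {
    cand$rank_score <- numeric()
  }

  selected <- forced
  if (nrow(selected) > 0) selected$rank_score <- NA_real_
  slots <- target_count - nrow(selected)
  if (slots > 0 && nrow(cand) > 0) {
    if (one_per_contig_bias) {
      first <- cand %>%
        dplyr::filter(!(.data$contig %in% selected$contig)) %>%
        dplyr::distinct(.data$contig, .keep_all = TRUE) %>%
        utils::head(slots)
      selected <- dplyr::bind_rows(selected, first)
      cand <- dplyr::anti_join(cand, first, by = c("contig", "offset"))
      slots <- target_count - nrow(selected)
    }
    if (slots > 0) {
      selected <- dplyr::bind_rows(selected, utils::head(cand, slots))
    }
  }
  selected$forced <- seq_len(nrow(selected)) <= nrow(forced)
  selected <- dplyr::arrange(selected, .data$contig, .data$offset)
  structure(
    list(
      selected = selected,
      boosted = selected[0, , drop = FALSE],
      target_count = target_count
    ),
    class = "probe_set"
  )
}

#' @export
print.probe_set <- function(x, ...) {
  cat(
    "<probe_set> ", nrow(x$selected), " of ", x$target_count,
    " probe(s) selected (", sum(x$selected$forced), " forced), ",
    nrow(x$boosted), " boosted cop(ies)\n",
    sep = ""
  )
  invisible(x)
}

#' Boost high-GC probes into spare design capacity
#'
#' Probes predicted to perform poorly in hybridisation — those with GC
#' content strictly above the selected set's mean (or an explicit
#' threshold) — are duplicated, highest GC first in round-robin order,
#' until the extra capacity is exhausted, evening out depth of coverage.
#'
#' @param probe_set A [rank_and_select()] result.
#' @param capacity Number of extra probe slots available.
#' @param gc_threshold GC fraction above which a probe is boosted; defaults
#'   to the mean GC of the selected set.
#' @return The probe set with `boosted` filled (repeated probe records,
#'   one row per extra copy).
#' @export
boost <- function(probe_set, capacity, gc_threshold = NULL) {
  stopifnot(inherits(probe_set, "probe_set"), capacity >= 0)
  sel <- probe_set$selected
  if (capacity == 0 || nrow(sel) == 0) return(probe_set)
  gc <- sel$gc_content %||% gc_fraction(sel$seq)
  thr <- gc_threshold %||% mean(gc, na.rm = TRUE)
  eligible <- which(!is.na(gc) & gc > thr)
  if (length(eligible) == 0) return(probe_set)
  eligible <- eligible[order(-gc[eligible], sel$contig[eligible],
    sel$offset[eligible]
  )]
  copies <- eligible[(seq_len(capacity) - 1L) %% length(eligible) + 1L]
  probe_set$boosted <- sel[copies, , drop = FALSE]
  probe_set
}

#' Write a probe set as BED (+ optional FASTA)
#'
#' Boosted probes appear as repeated records, the convention used when
#' submitting boosted bait designs.
#'
#' @param probe_set A [rank_and_select()] / [boost()] result.
#' @param bed_path Output BED path (0-based half-open).
#' @param fasta_path Optional FASTA of probe sequences.
#' @export
write_probe_set <- function(probe_set, bed_path, fasta_path = NULL) {
  all_probes <- dplyr::bind_rows(probe_set$selected, probe_set$boosted)
  bed <- tibble::tibble(
    contig = all_probes$contig,
    start = all_probes$offset,
    end = all_probes$offset + all_probes$length,
    name = sprintf(
      "probe_%s_%d", all_probes$contig, all_probes$offset
    )
  )
  write_bed(bed, bed_path)
  if (!is.null(fasta_path)) {
    seqs <- stats::setNames(all_probes$seq, make.unique(bed$name))
    write_fasta(seqs[!is.na(seqs)], fasta_path)
  }
  invisible(bed_path)
}
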