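#' Extract per-cytosine methylation calls from bisulphite alignments
#'
#' For top-strand (`bs_tag == "CT"`) reads, a reference-C position covered
#' by the read is called methylated when the read shows C and unmethylated
#' when it shows T; bottom-strand (`"GA"`) reads are scored symmetrically at
#' reference-G positions (G methylated, A unmethylated). Any other read base
#' at a scoreable position is ignored and tallied (`n_other` attribute).
#' Context (CpG / CHG / CHH) is computed from the reference; sites within
#' two bases of a contig end are labelled `"truncated"` so they can be
#' excluded from context-specific summaries. Records are aggregated per
#' (contig, position, strand); CpG sites are *not* merged across strands —
#' only one strand of DNA is profiled per site.
#'
#' @param reads Bisulphite read tibble; every mapped read must carry a
#'   `bs_tag` (`"CT"`/`"GA"`), or an error naming the first offender is
#'   raised.
#' @param reference Reference sequences (optionally the corrected reference
#'   from [correct_reference()]).
#' @param mask Optional tibble of sites (`contig`, `pos`, `strand`) excluded
#'   from the cytosine analysis set (genotype-masked C/T SNP positions).
#' @return List of class `methylation_extract` with `calls` (one row per
#'   read x site: `name`, `contig`, `pos`, `strand`, `status`) and `records`
#'   (per-site tibble: `contig`, `pos`, `strand`, `context`, `meth_count`,
#'   `unmeth_count`).
#' @export
extract_methylation <- function(reads, reference, mask = NULL) {
  ref <- as_seq_chr(reference)
  reads <- reads[!is.na(reads$contig) & reads$contig %in% names(ref), ,
    drop = FALSE
  ]
  no_tag <- is.na(reads$bs_tag)
  if (any(no_tag)) {
    stop(
      "bisulphite read without strand tag: ", reads$name[which(no_tag)[1]]
    )
  }
  sites <- cytosine_sites(ref, mask = mask)
  if (nrow(reads) == 0) {
    out <- list(
      calls = tibble::tibble(
        name = character(), contig = character(), pos = integer(),
        strand = character(), status = character()
      ),
      records = tibble::tibble(
        contig = character(), pos = integer(), strand = character(),
        context = character(), meth_count = integer(),
        unmeth_count = integer()
      )
    )
    class(out) <- "methylation_extract"
    attr(out, "n_other") <- 0L
    return(out)
  }

  w <- unique(nchar(reads$seq))
  stopifnot(length(w) == 1)
  m <- seq_matrix(reads$seq, w)
  n <- nrow(reads)
  obs <- tibble::tibble(
    name = rep(reads$name, w),
    contig = rep(reads$contig, w),
    pos = rep(reads$pos, w) + rep(0:(w - 1L), each = n),
    base = as.vector(m),
    bs_tag = rep(reads$bs_tag, w)
  )
  # A CT read scores + strand sites, a GA read - strand sites.
  obs$strand <- ifelse(obs$bs_tag == "CT", "+", "-")
  obs <- dplyr::inner_join(obs, sites, by = c("contig", "pos", "strand"))
  meth_base <- ifelse(obs$strand == "+", "C", "G")
  unmeth_base <- ifelse(obs$strand == "+", "T", "A")
  obs$status <- dplyr::case_when(
    obs$base == meth_base ~ "methylated",
    obs$base == unmeth_base ~ "unmethylated",
    TRUE ~ "other"
  )
  n_other <- sum(obs$status == "other")
  calls <- obs %>%
    dplyr::filter(.data$status != "other") %>%
    dplyr::select("name", "contig", "pos", "strand", "status")
  records <- obs %>%
    dplyr::filter(.data$status != "other") %>%
    dplyr::group_by(.data$contig, .data$pos, .data$strand, .data$context) %>%
    dplyr::summarise(
      meth_count = sum(.data$status == "methylated"),
      unmeth_count = sum(.data$status == "unmethylated"),
      .groups = "drop"
    ) %>%
    dplyr::arrange(.data$contig, .data$pos, .data$strand)
  records$pos <- as.integer(records$pos)
  calls$pos <- as.integer(calls$pos)
  out <- list(calls = calls, records = records)
  class(out) <- "methylation_extract"
  attr(out, "n_other") <- n_other
  out
}

#' @export
print.methylation_extract <- function(x, ...) {
  lvl <- if (nrow(x$records) > 0) {
    100 * sum(x$records$meth_count) /
      sum(x$records$meth_count + x$records$unmeth_count)
  } else {
    NA_real_
  }
  cat(
    "<methylation_extract> ", nrow(x$records), " cytosine site(s), ",
    nrow(x$calls), " read-level call(s), overall methylation ",
    sprintf("%.1f%%", lvl), "\n",
    sep = ""
  )
  invisible(x)
}

# Collapse an allele map under bisulphite aliasing: on a top-strand (CT)
# read C and T are indistinguishable for an unmethylated cytosine; on a
# bottom-strand (GA) read G and A alias. Returns the collapsed base.
collapse_bs_allele <- function(base, bs_tag) {
  dplyr::case_when(
    bs_tag == "CT" & base == "C" ~ "T",
    bs_tag == "GA" & base == "G" ~ "A",
    TRUE ~ base
  )
}

#' Assign methylation calls to sub-genomes via homoeologous SNP alleles
#'
#' A bisulphite read with mapping quality strictly above `min_mapq` that
#' covers a homoeologous SNP whose observed allele identifies exactly one
#' sub-genome has all of its cytosine calls credited to that sub-genome.
#' Because bisulphite conversion aliases C with T (top strand) and G with A
#' (bottom strand), allele maps are collapsed per read strand before
#' matching, and a SNP is only used when the collapsed observed base still
#' maps to a single sub-genome. Reads whose diagnostic alleles disagree are
#' discarded and tallied (`n_conflicting` attribute); by default only
#' singleton allele-to-genome sets assign (multi-genome diagnostic alleles
#' such as `"B,D"` are skipped).
#'
#' @param extract A [extract_methylation()] result.
#' @param reads The bisulphite read tibble the calls came from.
#' @param homoeolog_list Long allele map (`contig`, `pos`, `allele`,
#'   `genomes`) from either homoeolog-list route.
#' @param min_mapq Reads must have MAPQ strictly greater than this
#'   (default 20).
#' @return Per-site record tibble as in [extract_methylation()] plus
#'   per-sub-genome count columns `meth_A`, `unmeth_A`, ..., with an
#'   `assignments` attribute (tibble `name`, `genome`) recording the
#'   per-read assignment.
#' @export
assign_subgenome_methylation <- function(extract, reads, homoeolog_list,
                                         min_mapq = 20) {
  stopifnot(inherits(extract, "methylation_extract"))
  records <- extract$records
  genomes <- c("A", "B", "D")
  for (g in genomes) {
    records[[paste0("meth_", g)]] <- 0L
    records[[paste0("unmeth_", g)]] <- 0L
  }
  eligible <- reads[!is.na(reads$contig) & reads$mapq > min_mapq, ,
    drop = FALSE
  ]
  empty_attr <- function(rec, n_conflict = 0L) {
    attr(rec, "assignments") <-
      tibble::tibble(name = character(), genome = character())
    attr(rec, "n_conflicting") <- n_conflict
    rec
  }
  if (nrow(eligible) == 0 || nrow(homoeolog_list) == 0) {
    return(empty_attr(records))
  }

  w <- unique(nchar(eligible$seq))
  stopifnot(length(w) == 1)
  # Observed read base at each homoeologous SNP the read covers.
  cover <- dplyr::inner_join(
    dplyr::select(eligible, "name", "contig",
      read_pos = "pos", "bs_tag"
    ),
    dplyr::distinct(homoeolog_list, .data$contig, .data$pos),
    by = "contig", relationship = "many-to-many"
  ) %>%
    dplyr::filter(
      .data$pos >= .data$read_pos, .data$pos < .data$read_pos + w
    )
  if (nrow(cover) == 0) return(empty_attr(records))
  seq_by_name <- stats::setNames(eligible$seq, eligible$name)
  off <- cover$pos - cover$read_pos + 1L
  cover$base <- stringr::str_sub(seq_by_name[cover$name], off, off)

  # Collapse the allele map per bisulphite strand and keep only alleles
  # that remain diagnostic for a single sub-genome after collapsing.
  votes <- purrr::map_dfr(c("CT", "GA"), function(tag) {
    amap <- homoeolog_list %>%
      dplyr::mutate(allele = collapse_bs_allele(.data$allele, tag)) %>%
      dplyr::group_by(.data$contig, .data$pos, .data$allele) %>%
      dplyr::summarise(
        genomes = paste(
          sort(unique(unlist(strsplit(.data$genomes, ",", fixed = TRUE)))),
          collapse = ","
        ),
        .groups = "drop"
      ) %>%
      dplyr::filter(!grepl(",", .data$genomes))
    cover %>%
      dplyr::filter(.data$bs_tag == tag) %>%
      dplyr::mutate(allele = collapse_bs_allele(.data$base, tag)) %>%
      dplyr::inner_join(amap, by = c("contig", "pos", "allele"))
  })
  if (nrow(votes) == 0) return(empty_attr(records))

  per_read <- votes %>%
    dplyr::group_by(.data$name) %>%
    dplyr::summarise(
      n_distinct_genomes = dplyr::n_distinct(.data$genomes),
      genome = .data$genomes[1],
      .groups = "drop"
    )
  n_conflicting <- sum(per_read$n_distinct_genomes > 1)
  assignments <- per_read %>%
    dplyr::filter(.data$n_distinct_genomes == 1) %>%
    dplyr::select("name", "genome")

  assigned_calls <- dplyr::inner_join(
    extract$calls, assignments, by = "name"
  )
  if (nrow(assigned_calls) > 0) {
    per_site <- assigned_calls %>%
      dplyr::group_by(
        .data$contig, .data$pos, .data$strand, .data$genome
      ) %>%
      dplyr::summarise(
        meth = sum(.data$status == "methylated"),
        unmeth = sum(.data$status == "unmethylated"),
        .groups = "drop"
      )
    for (g in genomes) {
      gg <- per_site[per_site$genome == g, , drop = FALSE]
      i <- match(
        paste(gg$contig, gg$pos, gg$strand),
        paste(records$contig, records$pos, records$strand)
      )
      records[[paste0("meth_", g)]][i] <- gg$meth
      records[[paste0("unmeth_", g)]][i] <- gg$unmeth
    }
  }
  attr(records, "assignments") <- assignments
  attr(records, "n_conflicting") <- n_conflicting
  records
}

#' Split sub-genome-assigned records into per-genome record tables
#'
#' Reshapes the output of [assign_subgenome_methylation()] into one
#' per-cytosine record table per sub-genome (counts from the reads assigned
#' to that genome), the inputs the pairwise differential methylation
#' comparisons (A-A, B-B, D-D between two samples) expect.
#'
#' @param records Record tibble with `meth_A`/`unmeth_A` ... columns.
#' @return Named list (`A`, `B`, `D`) of record tibbles with `meth_count`
#'   and `unmeth_count` taken from that genome's assigned reads.
#' @export
subgenome_records <- function(records) {
  lapply(c(A = "A", B = "B", D = "D"), function(g) {
    out <- records[, c("contig", "pos", "strand", "context")]
    out$meth_count <- records[[paste0("meth_", g)]]
    out$unmeth_count <- records[[paste0("unmeth_", g)]]
    out[out$meth_count + out$unmeth_count > 0, , drop = FALSE]
  })
}

#' Estimate bisulphite conversion efficiency on a control genome
#'
#' On a genome assumed unmethylated (a chloroplast in practice), every
#' cytosine observation should read T; the efficiency is the percentage of
#' converted observations, `100 * T / (C + T)`, over both strands
#' (strand-appropriate bases). Also reports mean depth over the control
#' genome and the percentage of it covered at depth >= 1.
#'
#' @param reads Bisulphite read tibble (the full set; the function subsets
#'   to reads mapped on the control contigs).
#' @param control_reference Control genome sequences.
#' @return Object of class `conversion_efficiency`: a list with
#'   `efficiency_pct` (`NA` with `defined = FALSE` when there are no
#'   observations), `n_converted`, `n_unconverted`, `mean_depth`,
#'   `pct_covered`, `base_space_mapped`.
#' @export
conversion_efficiency <- function(reads, control_reference) {
  ctrl <- as_seq_chr(control_reference)
  sub <- reads[!is.na(reads$contig) & reads$contig %in% names(ctrl), ,
    drop = FALSE
  ]
  ext <- extract_methylation(sub, ctrl)
  n_c <- sum(ext$records$meth_count)
  n_t <- sum(ext$records$unmeth_count)
  cov <- if (nrow(sub) > 0) {
    cols <- pileup(sub, ctrl)
    list(
      mean_depth = sum(cols$depth) / sum(nchar(ctrl)),
      pct_covered = 100 * nrow(cols) / sum(nchar(ctrl)),
      base_space = nrow(cols)
    )
  } else {
    list(mean_depth = 0, pct_covered = 0, base_space = 0L)
  }
  out <- list(
    efficiency_pct = if (n_c + n_t > 0) 100 * n_t / (n_c + n_t) else NA_real_,
    defined = n_c + n_t > 0,
    n_converted = n_t,
    n_unconverted = n_c,
    n_observations = n_c + n_t,
    mean_depth = cov$mean_depth,
    pct_covered = cov$pct_covered,
    base_space_mapped = cov$base_space
  )
  class(out) <- "conversion_efficiency"
  out
}

#' @export
print.conversion_efficiency <- function(x, ...) {
  if (x$defined) {
    cat(sprintf(
      "<conversion_efficiency> %.2f%% (%d of %d cytosine observations converted)\n",
      x$efficiency_pct, x$n_converted, x$n_observations
    ))
    cat(sprintf(
      "  control genome: mean depth %.1fx, %.2f%% covered (%d bp)\n",
      x$mean_depth, x$pct_covered, x$base_space_mapped
    ))
  } else {
    cat("<conversion_efficiency> undefined (no cytosine observations)\n")
  }
  invisible(x)
}

#' Pairwise differential methylation by Fisher's exact test
#'
#' Tests every site with depth at least `min_depth` in *both* groups using
#' the two-sided Fisher exact test on the 2x2 table of methylated /
#' unmethylated counts. A site is significant when `p < alpha` and the
#' absolute methylation difference (percentage points) is at least
#' `min_diff`. No multiple-testing correction is applied: with pairwise
#' per-base comparisons the raw-p Fisher convention is used.
#'
#' The difference threshold is a required, explicit choice: 25 percentage
#' points is the default used for the headline comparisons this package
#' reproduces, while 50 is the stricter alternative in circulation; both are
#' legitimate, so the parameter is surfaced rather than buried.
#'
#' @param records_a,records_b Per-site record tibbles (`contig`, `pos`,
#'   `strand`, `meth_count`, `unmeth_count`).
#' @param min_depth Minimum depth per group (default 5); must be >= 1.
#' @param alpha Significance level on the raw p-value (default 0.01).
#' @param min_diff Minimum absolute methylation difference in percentage
#'   points (default 25).
#' @return Tibble of class `capmeth_dm`, one row per tested site: counts for
#'   both groups, `p_value`, `meth_difference` (group a minus group b,
#'   percentage points) and `significant`; attributes `n_tested`,
#'   `n_significant`, `frac_significant`.
#' @export
differential_methylation <- function(records_a, records_b, min_depth = 5,
                                     alpha = 0.01, min_diff = 25) {
  if (min_depth < 1) stop("min_depth must be >= 1")
  keys <- c("contig", "pos", "strand")
  ab <- dplyr::inner_join(
    dplyr::select(
      records_a, dplyr::all_of(keys),
      meth_a = "meth_count", unmeth_a = "unmeth_count"
    ),
    dplyr::select(
      records_b, dplyr::all_of(keys),
      meth_b = "meth_count", unmeth_b = "unmeth_count"
    ),
    by = keys
  ) %>%
    dplyr::mutate(
      depth_a = .data$meth_a + .data$unmeth_a,
      depth_b = .data$meth_b + .data$unmeth_b
    ) %>%
    dplyr::filter(.data$depth_a >= min_depth, .data$depth_b >= min_depth)
  if (nrow(ab) > 0) {
    ab$p_value <- fisher_exact_2x2(
      ab$meth_a, ab$unmeth_a, ab$meth_b, ab$unmeth_b
    )
    ab$meth_difference <-
      100 * ab$meth_a / ab$depth_a - 100 * ab$meth_b / ab$depth_b
    ab$significant <- ab$p_value < alpha &
      abs(ab$meth_difference) >= min_diff
  } else {
    ab$p_value <- numeric()
    ab$meth_difference <- numeric()
    ab$significant <- logical()
  }
  out <- structure(ab, class = c("capmeth_dm", class(ab)))
  attr(out, "n_tested") <- nrow(ab)
  attr(out, "n_significant") <- sum(ab$significant)
  attr(out, "frac_significant") <-
    if (nrow(ab) > 0) sum(ab$significant) / nrow(ab) else NA_real_
  attr(out, "params") <-
    list(min_depth = min_depth, alpha = alpha, min_diff = min_diff)
  out
}

#' Write a per-cytosine record table compatible with methylKit-style input
#'
#' Columns follow the coverage / numCs / numTs semantics of per-base
#' methylation tables: `contig`, `pos` (1-based), `strand`, `context`,
#' `coverage`, `numCs`, `numTs`, followed by any per-sub-genome count
#' columns present.
#'
#' @param records Per-site record tibble.
#' @param path Output TSV path.
#' @export
write_methylation_tsv <- function(records, path) {
  out <- records %>%
    dplyr::mutate(
      coverage = .data$meth_count + .data$unmeth_count,
      numCs = .data$meth_count,
      numTs = .data$unmeth_count
    ) %>%
    dplyr::select(
      "contig", "pos", "strand", "context", "coverage", "numCs", "numTs",
      dplyr::starts_with("meth_"), dplyr::starts_with("unmeth_"),
      -"meth_count", -"unmeth_count"
    )
  readr::write_tsv(out, path)
  invisible(path)
}
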