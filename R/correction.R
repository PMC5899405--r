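#' Classify SNP calls by their effect on methylation analysis
#'
#' One primary alternate allele per position (highest frequency, ties
#' alphabetical) is classified by its reference/alternate bases:
#'
#' * `CT_GA` — reference C read as T, or G as A: exactly the signature
#'   bisulphite conversion produces, so an unidentified SNP of this class is
#'   miscalled as an unmethylated cytosine;
#' * `AT_CG` — an A/T reference base replaced by C or G in the sample: a
#'   cytosine the accession carries but the reference does not, invisible
#'   until the reference is corrected;
#' * `CG_SWAP` — C to G or G to C: the cytosine changes strand;
#' * `OTHER` — everything else.
#'
#' @param snps SNP call tibble ([call_polyploid_snps()] output; positions
#'   with several alternates are reduced with [primary_alt()]).
#' @return The input (one row per position) with a `category` column.
#' @export
classify_snps <- function(snps) {
  snps <- primary_alt(snps)
  if (any(snps$ref_allele == snps$alt_allele)) {
    stop("SNP with identical reference and alternate allele")
  }
  snps$category <- dplyr::case_when(
    snps$ref_allele == "C" & snps$alt_allele == "T" ~ "CT_GA",
    snps$ref_allele == "G" & snps$alt_allele == "A" ~ "CT_GA",
    snps$ref_allele %in% c("A", "T") &
      snps$alt_allele %in% c("C", "G") ~ "AT_CG",
    snps$ref_allele == "C" & snps$alt_allele == "G" ~ "CG_SWAP",
    snps$ref_allele == "G" & snps$alt_allele == "C" ~ "CG_SWAP",
    TRUE ~ "OTHER"
  )
  snps
}

#' Correct the reference for genotype-aware methylation calling
#'
#' Applies homozygous-in-sample SNPs (alternate frequency at least
#' `hom_freq`) to the cytosine analysis set:
#'
#' * `CT_GA` positions are *masked* out of the cytosine set (the sample has
#'   no cytosine there; an apparent T is genotype, not conversion);
#' * `AT_CG` positions substitute the sample allele into the reference,
#'   adding new cytosine positions whose context is read from the corrected
#'   sequence;
#' * `CG_SWAP` positions substitute the allele, masking the lost strand and
#'   adding the gained strand.
#'
#' The corrected reference keeps its length. Contradictory edits at one
#' position raise an error.
#'
#' @param reference Reference sequences.
#' @param snp_classes Output of [classify_snps()].
#' @param hom_freq Minimum alternate frequency for an edit (default 0.9).
#' @return List of class `reference_correction`: `reference` (corrected
#'   `DNAStringSet`), `masked` (tibble `contig`, `pos`, `strand` of sites
#'   removed from the cytosine set), `added` (sites gained), `edits` (the
#'   SNPs applied).
#' @export
correct_reference <- function(reference, snp_classes, hom_freq = 0.9) {
  ref <- as_seq_chr(reference)
  ed <- snp_classes[snp_classes$alt_freq >= hom_freq, , drop = FALSE]
  dup <- duplicated(ed[, c("contig", "pos")])
  if (any(dup)) stop("contradictory edits at one position")

  site <- function(df, strand) {
    tibble::tibble(contig = df$contig, pos = df$pos, strand = strand)
  }
  ct <- ed[ed$category == "CT_GA", , drop = FALSE]
  at <- ed[ed$category == "AT_CG", , drop = FALSE]
  sw <- ed[ed$category == "CG_SWAP", , drop = FALSE]

  masked <- dplyr::bind_rows(
    site(ct[ct$ref_allele == "C", ], "+"),
    site(ct[ct$ref_allele == "G", ], "-"),
    site(sw[sw$ref_allele == "C", ], "+"),
    site(sw[sw$ref_allele == "G", ], "-")
  )
  added <- dplyr::bind_rows(
    site(at[at$alt_allele == "C", ], "+"),
    site(at[at$alt_allele == "G", ], "-"),
    site(sw[sw$alt_allele == "C", ], "+"),
    site(sw[sw$alt_allele == "G", ], "-")
  )

  # Substitute sample alleles where the edit gains or moves a cytosine;
  # masked-only (CT_GA) positions keep the reference base and are excluded
  # via the mask.
  subst <- dplyr::bind_rows(at, sw)
  corrected <- ref
  if (nrow(subst) > 0) {
    for (nm in unique(subst$contig)) {
      idx <- subst$contig == nm
      corrected[nm] <- substitute_bases(
        corrected[nm], subst$pos[idx], subst$alt_allele[idx]
      )
    }
  }
  structure(
    list(
      reference = Biostrings::DNAStringSet(corrected),
      masked = dplyr::arrange(masked, .data$contig, .data$pos),
      added = dplyr::arrange(added, .data$contig, .data$pos),
      edits = ed
    ),
    class = "reference_correction"
  )
}

#' @export
print.reference_correction <- function(x, ...) {
  cat(
    "<reference_correction> ", nrow(x$edits), " homozygous edit(s): ",
    nrow(x$masked), " cytosine site(s) masked, ",
    nrow(x$added), " added\n",
    sep = ""
  )
  invisible(x)
}

#' False-positive-elimination and cytosine-recovery accounting
#'
#' The headline accounting of the dual-purpose design: among cytosines with
#' analyzable coverage (depth at least `min_depth`), what percentage of
#' methylation calls could a genotype correction eliminate (C/T and G/A
#' SNPs masquerading as unmethylated cytosines), and what percentage of new
#' cytosines does it add (A/T to C/G SNPs)? The eliminated percentage is
#' `100 * n_ct_ga / n_analyzable`, an "up to" figure: not every such SNP
#' position necessarily reaches analyzable depth.
#'
#' @param snp_classes Output of [classify_snps()], or `NULL` when `counts`
#'   is given.
#' @param cytosine_records Per-site record tibble with `meth_count` /
#'   `unmeth_count` (depth is their sum), or `NULL` when `counts` is given.
#' @param min_depth Analyzable-coverage threshold (default 10).
#' @param counts Optional precomputed counts, a list with `n_ct_ga`,
#'   `n_at_cg`, `n_analyzable` and optionally `n_snps_total`, for running
#'   the accounting on externally obtained tallies.
#' @return Object of class `correction_report` with fields `n_snps_total`,
#'   `n_ct_ga`, `n_at_cg`, `n_analyzable_cytosines`, `pct_calls_eliminated`
#'   (one-decimal), `n_cytosines_added`, `pct_cytosines_added`, `defined`.
#' @export
correction_report <- function(snp_classes = NULL, cytosine_records = NULL,
                              min_depth = 10, counts = NULL) {
  if (is.null(counts)) {
    stopifnot(!is.null(snp_classes), !is.null(cytosine_records))
    depth <- cytosine_records$meth_count + cytosine_records$unmeth_count
    counts <- list(
      n_snps_total = nrow(snp_classes),
      n_ct_ga = sum(snp_classes$category == "CT_GA"),
      n_at_cg = sum(snp_classes$category == "AT_CG"),
      n_analyzable = sum(depth >= min_depth)
    )
  }
  n_an <- counts$n_analyzable
  defined <- n_an > 0
  out <- list(
    n_snps_total = counts$n_snps_total %||% NA_integer_,
    n_ct_ga = counts$n_ct_ga,
    n_at_cg = counts$n_at_cg,
    n_analyzable_cytosines = n_an,
    min_depth = min_depth,
    pct_calls_eliminated =
      if (defined) round(100 * counts$n_ct_ga / n_an, 1) else NA_real_,
    n_cytosines_added = counts$n_at_cg,
    pct_cytosines_added =
      if (defined) round(100 * counts$n_at_cg / n_an, 1) else NA_real_,
    defined = defined
  )
  class(out) <- "correction_report"
  out
}

#' @export
print.correction_report <- function(x, ...) {
  cat("<correction_report>\n")
  cat("  SNPs total:            ", x$n_snps_total, "\n")
  cat("  C/G -> T/A SNPs:       ", x$n_ct_ga, "\n")
  cat("  A/T -> C/G SNPs:       ", x$n_at_cg, "\n")
  cat(
    "  analyzable cytosines (>= ", x$min_depth, "x): ",
    x$n_analyzable_cytosines, "\n",
    sep = ""
  )
  if (x$defined) {
    cat(sprintf(
      "  calls eliminated: up to %.1f%%; cytosines added: %.1f%%\n",
      x$pct_calls_eliminated, x$pct_cytosines_added
    ))
  } else {
    cat("  percentages undefined (no analyzable cytosines)\n")
  }
  invisible(x)
}
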