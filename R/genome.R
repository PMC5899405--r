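#' Configuration for the synthetic polyploid genome
#'
#' Defaults describe the desk-scale study system the package is tested
#' against: a collapsed capture reference of a few contigs from which three
#' coordinate-matched sub-genome haplotypes (A/B/D) diverge by diagnostic
#' homoeologous SNPs, an accession that additionally differs from the
#' reference variety by varietal SNPs shared across sub-genomes, per-context
#' methylation states, and a small unmethylated control genome standing in
#' for the chloroplast.
#'
#' @param n_contigs Number of reference contigs.
#' @param contig_length Length of each contig in bp (recycled).
#' @param homoeo_rate Per-base probability that a position is a homoeologous
#'   SNP (positions where the three sub-genome copies disagree).
#' @param varietal_rate Per-base probability of an accession (varietal) SNP
#'   relative to the reference variety; applied to all three haplotypes.
#' @param meth_rates Named numeric: probability that a cytosine in each
#'   context is methylated. Defaults reflect a heavily methylated plant
#'   genome (high CpG/CHG, low CHH).
#' @param gc GC content of the simulated sequences.
#' @param control_length Length of the unmethylated control genome in bp.
#' @return A list of class `genome_config`.
#' @export
genome_config <- function(n_contigs = 3,
                          contig_length = 10000,
                          homoeo_rate = 0.01,
                          varietal_rate = 0.002,
                          meth_rates = c(CpG = 0.8, CHG = 0.6, CHH = 0.1),
                          gc = 0.46,
                          control_length = 10000) {
  stopifnot(
    n_contigs >= 1, all(contig_length >= 1),
    homoeo_rate >= 0, homoeo_rate <= 1,
    varietal_rate >= 0, varietal_rate <= 1,
    all(meth_rates >= 0), all(meth_rates <= 1),
    all(c("CpG", "CHG", "CHH") %in% names(meth_rates)),
    gc > 0, gc < 1, control_length >= 1
  )
  structure(
    list(
      n_contigs = n_contigs,
      contig_length = rep_len(contig_length, n_contigs),
      homoeo_rate = homoeo_rate,
      varietal_rate = varietal_rate,
      meth_rates = meth_rates,
      gc = gc,
      control_length = control_length
    ),
    class = "genome_config"
  )
}

random_dna <- function(n, gc) {
  paste(sample(DNA_BASES, n,
    replace = TRUE,
    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  ), collapse = "")
}

#' Build a synthetic polyploid genome model
#'
#' Generates the collapsed reference, three coordinate-matched sub-genome
#' haplotypes, truth tables (homoeologous SNPs, varietal SNPs, per-site
#' methylation states) and an unmethylated control genome. Deterministic for
#' a fixed seed; the truth tables exactly describe the emitted haplotypes.
#'
#' At each homoeologous position either one sub-genome carries a non-reference
#' base (common) or all three sub-genomes carry distinct bases (rare).
#' Varietal SNPs are placed at non-homoeologous positions and applied to all
#' three haplotypes, emulating an accession sequenced against the reference
#' variety's assembly. Methylation states are binary per
#' (haplotype, contig, pos, strand) site, drawn with the context-specific
#' rates; sites too close to a contig end for context classification are left
#' unmethylated.
#'
#' @param config A [genome_config()].
#' @param seed Integer seed (all randomness flows from it via named
#'   sub-streams).
#' @param min_contig_length Reject configs whose contigs are shorter than
#'   this (reads must fit on a contig).
#' @return A list of class `genome_model` with elements `reference`
#'   (`DNAStringSet`), `haplotypes` (named list A/B/D of `DNAStringSet`),
#'   `homoeo_truth`, `varietal_truth`, `methylation_truth` (tibbles),
#'   `control` (`DNAStringSet`) and `config`.
#' @export
build_genome <- function(config = genome_config(), seed = 1,
                         min_contig_length = 200) {
  stopifnot(inherits(config, "genome_config"))
  if (any(config$contig_length < min_contig_length)) {
    stop("contig_length must be >= ", min_contig_length, " (the read length)")
  }
  contig_names <- sprintf("contig%02d", seq_len(config$n_contigs))

  ref_chr <- with_substream(seed, "reference", {
    stats::setNames(
      vapply(config$contig_length, random_dna, "", gc = config$gc),
      contig_names
    )
  })

  homoeo <- with_substream(seed, "homoeologous", {
    purrr::imap_dfr(ref_chr, function(s, nm) {
      L <- nchar(s)
      pos <- which(stats::runif(L) < config$homoeo_rate)
      if (length(pos) == 0) {
        return(tibble::tibble(
          contig = character(), pos = integer(),
          allele_A = character(), allele_B = character(),
          allele_D = character()
        ))
      }
      ref_base <- stringr::str_sub(s, pos, pos)
      all_distinct <- stats::runif(length(pos)) < 0.1
      variant_genome <- sample(c("A", "B", "D"), length(pos), replace = TRUE)
      alleles <- matrix(rep(ref_base, 3), ncol = 3,
        dimnames = list(NULL, c("A", "B", "D"))
      )
      for (i in seq_along(pos)) {
        others <- setdiff(DNA_BASES, ref_base[i])
        if (all_distinct[i]) {
          alleles[i, ] <- c(ref_base[i], sample(others, 2))
          alleles[i, ] <- sample(alleles[i, ])
        } else {
          alleles[i, variant_genome[i]] <- sample(others, 1)
        }
      }
      tibble::tibble(
        contig = nm, pos = as.integer(pos),
        allele_A = alleles[, "A"], allele_B = alleles[, "B"],
        allele_D = alleles[, "D"]
      )
    })
  })

  varietal <- with_substream(seed, "varietal", {
    purrr::imap_dfr(ref_chr, function(s, nm) {
      L <- nchar(s)
      pos <- which(stats::runif(L) < config$varietal_rate)
      pos <- setdiff(pos, homoeo$pos[homoeo$contig == nm])
      if (length(pos) == 0) {
        return(tibble::tibble(
          contig = character(), pos = integer(),
          ref_allele = character(), alt_allele = character()
        ))
      }
      ref_base <- stringr::str_sub(s, pos, pos)
      alt <- vapply(ref_base, function(b) sample(setdiff(DNA_BASES, b), 1), "")
      tibble::tibble(
        contig = nm, pos = as.integer(pos),
        ref_allele = ref_base, alt_allele = unname(alt)
      )
    })
  })

  # Apply homoeologous + varietal substitutions to build each haplotype.
  hap_chr <- lapply(c(A = "A", B = "B", D = "D"), function(g) {
    out <- ref_chr
    if (nrow(homoeo) > 0) {
      al <- homoeo[[paste0("allele_", g)]]
      for (nm in unique(homoeo$contig)) {
        idx <- homoeo$contig == nm
        out[nm] <- substitute_bases(out[nm], homoeo$pos[idx], al[idx])
      }
    }
    if (nrow(varietal) > 0) {
      for (nm in unique(varietal$contig)) {
        idx <- varietal$contig == nm
        out[nm] <- substitute_bases(
          out[nm], varietal$pos[idx], varietal$alt_allele[idx]
        )
      }
    }
    out
  })

  meth <- with_substream(seed, "methylation", {
    purrr::imap_dfr(hap_chr, function(seqs, g) {
      sites <- cytosine_sites(seqs)
      p <- dplyr::case_when(
        sites$context == "CpG" ~ config$meth_rates[["CpG"]],
        sites$context == "CHG" ~ config$meth_rates[["CHG"]],
        sites$context == "CHH" ~ config$meth_rates[["CHH"]],
        TRUE ~ 0
      )
      sites$prob <- as.numeric(stats::runif(nrow(sites)) < p)
      sites$haplotype <- g
      sites[, c("haplotype", "contig", "pos", "strand", "context", "prob")]
    })
  })

  control_chr <- with_substream(seed, "control", {
    c(control = random_dna(config$control_length, config$gc))
  })

  structure(
    list(
      reference = Biostrings::DNAStringSet(ref_chr),
      haplotypes = lapply(hap_chr, Biostrings::DNAStringSet),
      homoeo_truth = homoeo,
      varietal_truth = varietal,
      methylation_truth = meth,
      control = Biostrings::DNAStringSet(control_chr),
      config = config,
      seed = seed
    ),
    class = "genome_model"
  )
}

#' @export
print.genome_model <- function(x, ...) {
  cat(
    "<genome_model> ", length(x$reference), " contig(s), ",
    sum(Biostrings::width(x$reference)), " bp collapsed reference\n",
    "  homoeologous SNPs: ", nrow(x$homoeo_truth),
    "; varietal SNPs: ", nrow(x$varietal_truth), "\n",
    "  methylation truth sites: ", nrow(x$methylation_truth),
    "; control genome: ", Biostrings::width(x$control), " bp\n",
    sep = ""
  )
  invisible(x)
}

#' Long (allele, sub-genome set) view of a wide homoeologous SNP table
#'
#' Converts the wide per-genome allele table (`allele_A`, `allele_B`,
#' `allele_D`) into the canonical long allele map used throughout: one row
#' per observed base with the comma-joined set of sub-genomes carrying it.
#'
#' @param truth Tibble with columns `contig`, `pos`, `allele_A`, `allele_B`,
#'   `allele_D`.
#' @return Tibble `contig`, `pos`, `allele`, `genomes` (e.g. `"B,D"`).
#' @export
homoeolog_alleles <- function(truth) {
  truth %>%
    tidyr::pivot_longer(
      dplyr::starts_with("allele_"),
      names_to = "genome", values_to = "allele",
      names_prefix = "allele_"
    ) %>%
    dplyr::group_by(.data$contig, .data$pos, .data$allele) %>%
    dplyr::summarise(
      genomes = paste(sort(.data$genome), collapse = ","),
      .groups = "drop"
    ) %>%
    dplyr::arrange(.data$contig, .data$pos, .data$allele)
}
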