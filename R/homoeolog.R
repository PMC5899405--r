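#' Assign untreated reads to sub-genomes by exact matching
#'
#' A read is assigned the set of sub-genomes in whose haplotype sequences it
#' has at least one exact full-length match (either strand). Only perfect
#' hits to one or two genomes are informative for discriminating
#' homoeologous alleles; reads matching zero genomes (errors, off-target) or
#' all three (no diagnostic site covered) are discarded and tallied in the
#' `n_discarded_none` / `n_discarded_all` attributes.
#'
#' @param reads Read tibble (untreated); all sequences must share one
#'   length.
#' @param haplotypes Named list (`A`, `B`, `D`) of `DNAStringSet` haplotype
#'   contigs (e.g. `model$haplotypes`).
#' @return Tibble `name`, `genomes` (comma-joined sorted labels, e.g.
#'   `"A"` or `"B,D"`), `n_genomes` for retained reads.
#' @export
assign_reads_to_genomes <- function(reads, haplotypes) {
  stopifnot(all(c("A", "B", "D") %in% names(haplotypes)))
  if (nrow(reads) == 0) {
    out <- tibble::tibble(
      name = character(), genomes = character(), n_genomes = integer()
    )
    attr(out, "n_discarded_none") <- 0L
    attr(out, "n_discarded_all") <- 0L
    return(out)
  }
  pats <- Biostrings::DNAStringSet(reads$seq)
  pd <- Biostrings::PDict(pats)
  pd_rc <- Biostrings::PDict(Biostrings::reverseComplement(pats))
  hit <- do.call(cbind, lapply(c(A = "A", B = "B", D = "D"), function(g) {
    subj <- haplotypes[[g]]
    h <- rep(FALSE, nrow(reads))
    for (i in seq_along(subj)) {
      h[Biostrings::whichPDict(pd, subj[[i]])] <- TRUE
      h[Biostrings::whichPDict(pd_rc, subj[[i]])] <- TRUE
    }
    h
  }))
  n_hit <- rowSums(hit)
  keep <- n_hit %in% c(1L, 2L)
  genomes <- apply(hit[keep, , drop = FALSE], 1, function(z) {
    paste(c("A", "B", "D")[z], collapse = ",")
  })
  out <- tibble::tibble(
    name = reads$name[keep],
    genomes = genomes,
    n_genomes = as.integer(n_hit[keep])
  )
  attr(out, "n_discarded_none") <- sum(n_hit == 0L)
  attr(out, "n_discarded_all") <- sum(n_hit == 3L)
  out
}

#' Homoeologous SNP list from coordinate-matched haplotypes
#'
#' The direct route: align-free comparison of the three sub-genome
#' haplotypes against each other at every reference position. Any position
#' where the three copies are not identical yields one record mapping each
#' observed base to the set of sub-genomes carrying it.
#'
#' @param reference Reference sequences (contig names and lengths).
#' @param haplotypes Named list (`A`, `B`, `D`) of coordinate-matched
#'   haplotype sequences.
#' @return Long allele-map tibble `contig`, `pos`, `allele`, `genomes`.
#' @export
build_homoeolog_list_from_haplotypes <- function(reference, haplotypes) {
  ref <- as_seq_chr(reference)
  hap <- lapply(haplotypes[c("A", "B", "D")], as_seq_chr)
  for (g in names(hap)) {
    if (!identical(nchar(hap[[g]])[names(ref)], nchar(ref))) {
      stop("haplotype ", g, " is not coordinate-matched to the reference")
    }
  }
  per_contig <- purrr::map_dfr(names(ref), function(nm) {
    a <- strsplit(hap$A[[nm]], "", fixed = TRUE)[[1]]
    b <- strsplit(hap$B[[nm]], "", fixed = TRUE)[[1]]
    d <- strsplit(hap$D[[nm]], "", fixed = TRUE)[[1]]
    pos <- which(a != b | a != d)
    if (length(pos) == 0) {
      return(tibble::tibble(
        contig = character(), pos = integer(),
        allele_A = character(), allele_B = character(), allele_D = character()
      ))
    }
    tibble::tibble(
      contig = nm, pos = pos,
      allele_A = a[pos], allele_B = b[pos], allele_D = d[pos]
    )
  })
  homoeolog_alleles(per_contig)
}

#' Homoeologous SNP list from genome-assigned reads
#'
#' The read route: polyploid SNP calls are made on the genome-assigned read
#' set, then each allele at a called position (the called alternates plus
#' the reference base) is attributed to the union of the genome sets of the
#' reads carrying it. Positions whose alleles resolve to at least two
#' distinct non-empty genome groups become homoeologous SNP records.
#'
#' @param reads Untreated read tibble (filtered alignments).
#' @param assignments Output of [assign_reads_to_genomes()].
#' @param reference Reference sequences.
#' @inheritParams call_polyploid_snps
#' @return Long allele-map tibble `contig`, `pos`, `allele`, `genomes`.
#' @export
build_homoeolog_list_from_reads <- function(reads, assignments, reference,
                                            min_cov = 5, min_mean_mapq = 15,
                                            min_maf = 0.1) {
  assigned <- dplyr::inner_join(reads, assignments, by = "name")
  empty <- tibble::tibble(
    contig = character(), pos = integer(),
    allele = character(), genomes = character()
  )
  if (nrow(assigned) == 0) return(empty)
  cols <- pileup(assigned, reference)
  snps <- call_polyploid_snps(cols, reference,
    min_cov = min_cov, min_mean_mapq = min_mean_mapq, min_maf = min_maf
  )
  if (nrow(snps) == 0) return(empty)

  sites <- dplyr::distinct(snps, .data$contig, .data$pos, .data$ref_allele)
  alleles <- dplyr::bind_rows(
    dplyr::select(snps, "contig", "pos", allele = "alt_allele"),
    dplyr::select(sites, "contig", "pos", allele = "ref_allele")
  ) %>% dplyr::distinct()

  # Per-read base observations restricted to called positions.
  w <- nchar(assigned$seq)
  obs <- tibble::tibble(
    contig = rep(assigned$contig, w[1]),
    pos = rep(assigned$pos, w[1]) + rep(0:(w[1] - 1L), each = nrow(assigned)),
    allele = as.vector(seq_matrix(assigned$seq, w[1])),
    genomes = rep(assigned$genomes, w[1])
  ) %>%
    dplyr::semi_join(alleles, by = c("contig", "pos", "allele"))

  attrib <- obs %>%
    dplyr::group_by(.data$contig, .data$pos, .data$allele) %>%
    dplyr::summarise(
      genomes = paste(
        sort(unique(unlist(strsplit(.data$genomes, ",", fixed = TRUE)))),
        collapse = ","
      ),
      .groups = "drop"
    )
  attrib %>%
    dplyr::group_by(.data$contig, .data$pos) %>%
    dplyr::filter(dplyr::n_distinct(.data$genomes) >= 2) %>%
    dplyr::ungroup() %>%
    dplyr::arrange(.data$contig, .data$pos, .data$allele)
}
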