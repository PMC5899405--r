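#' Simulate captured sequencing reads from a genome model
#'
#' Emits single-end fragment reads (the package maps and processes reads as
#' fragments throughout) from the three sub-genome haplotypes, plus
#' off-target reads drawn from the unmethylated control genome and from
#' random background sequence. Sequences are stored in reference orientation
#' (as in SAM); minus-strand fragments carry `strand == "-"`. MAPQ is drawn
#' from a configurable discrete distribution so that downstream mapping
#' quality filters are exercised.
#'
#' @param model A [build_genome()] result.
#' @param depth Requested mean on-target depth (reads per position).
#' @param read_length Read length in bp (the study design sequences 125 bp
#'   reads).
#' @param on_target_fraction Fraction of emitted reads that come from the
#'   captured reference space; the remainder are off-target.
#' @param control_fraction Fraction of off-target reads drawn from the
#'   control genome (the rest are unmappable random background).
#' @param error_rate Per-base uniform substitution error rate.
#' @param duplicate_rate Probability a read is flagged as a PCR/optical
#'   duplicate (FLAG 0x400 in SAM output).
#' @param mapq_values,mapq_probs Discrete MAPQ distribution.
#' @param seed Integer seed.
#' @return Tibble of reads with columns `name`, `haplotype` (A/B/D/control/
#'   background), `contig`, `pos` (1-based; `NA` for background), `strand`,
#'   `mapq`, `seq`, `duplicate`, `converted`, `bs_tag`, `bs_origin`.
#' @export
simulate_reads <- function(model,
                           depth = 30,
                           read_length = 125,
                           on_target_fraction = 0.5,
                           control_fraction = 0.5,
                           error_rate = 0,
                           duplicate_rate = 0,
                           mapq_values = c(60L, 35L, 12L, 3L),
                           mapq_probs = c(0.85, 0.07, 0.05, 0.03),
                           seed = 1) {
  stopifnot(inherits(model, "genome_model"))
  if (depth <= 0) stop("depth must be > 0")
  stopifnot(
    read_length >= 1,
    on_target_fraction > 0, on_target_fraction <= 1,
    control_fraction >= 0, control_fraction <= 1,
    error_rate >= 0, error_rate < 1,
    duplicate_rate >= 0, duplicate_rate <= 1,
    length(mapq_values) == length(mapq_probs)
  )
  ref_len <- Biostrings::width(model$reference)
  if (any(ref_len < read_length)) stop("contig shorter than read length")
  contig_names <- names(model$reference)

  with_substream(seed, "reads", {
    n_on <- max(1L, round(depth * sum(ref_len) / read_length))
    n_off <- round(n_on * (1 - on_target_fraction) / on_target_fraction)
    n_ctrl <- round(n_off * control_fraction)
    n_bg <- n_off - n_ctrl

    hap_chr <- lapply(model$haplotypes, as.character)
    ctrl_chr <- as.character(model$control)
    ctrl_len <- nchar(ctrl_chr)
    if (ctrl_len < read_length && n_ctrl > 0) {
      stop("control genome shorter than read length")
    }

    contig <- sample(contig_names, n_on, replace = TRUE, prob = ref_len)
    L <- ref_len[match(contig, contig_names)]
    pos <- as.integer(floor(stats::runif(n_on) * (L - read_length + 1)) + 1)
    hap <- sample(c("A", "B", "D"), n_on, replace = TRUE)
    seqs <- character(n_on)
    for (g in c("A", "B", "D")) {
      for (nm in contig_names) {
        idx <- hap == g & contig == nm
        if (any(idx)) {
          seqs[idx] <- stringr::str_sub(
            hap_chr[[g]][nm], pos[idx], pos[idx] + read_length - 1L
          )
        }
      }
    }

    if (n_ctrl > 0) {
      cpos <- as.integer(floor(stats::runif(n_ctrl) * (ctrl_len - read_length + 1)) + 1)
      cseq <- stringr::str_sub(ctrl_chr, cpos, cpos + read_length - 1L)
    } else {
      cpos <- integer()
      cseq <- character()
    }
    bseq <- if (n_bg > 0) {
      vapply(seq_len(n_bg), function(i) random_dna(read_length, 0.5), "")
    } else {
      character()
    }

    n <- n_on + n_ctrl + n_bg
    reads <- tibble::tibble(
      name = sprintf("read%06d", seq_len(n)),
      haplotype = c(hap, rep("control", n_ctrl), rep("background", n_bg)),
      contig = c(contig, rep(names(ctrl_chr), n_ctrl), rep(NA_character_, n_bg)),
      pos = c(pos, cpos, rep(NA_integer_, n_bg)),
      strand = sample(c("+", "-"), n, replace = TRUE),
      mapq = sample(as.integer(mapq_values), n, replace = TRUE, prob = mapq_probs),
      seq = c(seqs, cseq, bseq),
      duplicate = stats::runif(n) < duplicate_rate,
      converted = FALSE,
      bs_tag = NA_character_,
      bs_origin = NA_character_
    )

    if (error_rate > 0) {
      m <- seq_matrix(reads$seq, read_length)
      hit <- which(stats::runif(length(m)) < error_rate)
      if (length(hit) > 0) {
        shift <- sample(1:3, length(hit), replace = TRUE)
        m[hit] <- DNA_BASES[(match(m[hit], DNA_BASES) - 1L + shift) %% 4L + 1L]
        reads$seq <- collapse_seq_matrix(m)
      }
    }
    reads
  })
}

#' Apply in-silico bisulphite conversion to simulated reads
#'
#' Bisulphite treatment deaminates unmethylated cytosines to uracil, read as
#' thymine; methylated cytosines are protected. Conversion is applied on the
#' genomic strand the fragment derives from: in reference-orientation read
#' coordinates, plus-strand fragments have C changed to T and minus-strand
#' fragments have G changed to A, each with probability
#' `conversion_efficiency` when the underlying site is unmethylated
#' (methylation states come from the model's truth table; control-genome and
#' background cytosines are always unmethylated). In non-directional mode
#' half of the fragments are emitted as the PCR complement of the converted
#' strand (CTOT/CTOB): their reference-orientation base pattern is unchanged
#' but the alignment orientation flips.
#'
#' Converted reads carry `bs_tag` `"CT"` (top-strand cytosine pattern,
#' informative at reference C positions) or `"GA"` (bottom strand,
#' informative at reference G positions), the convention Bismark writes in
#' its `XG` tag.
#'
#' @param reads Tibble from [simulate_reads()]; must not already be
#'   converted.
#' @param model The [build_genome()] model the reads were simulated from.
#' @param conversion_efficiency Probability an unmethylated cytosine is
#'   converted; the default is the efficiency reported for the full
#'   bisulphite-treated capture sample in the study system this package
#'   models.
#' @param directional If `FALSE` (default, matching the non-directional
#'   libraries this design uses), all four bisulphite strand types are
#'   emitted.
#' @param seed Integer seed.
#' @return The reads tibble with converted sequences, `converted = TRUE`,
#'   `bs_tag`, `bs_origin` (OT/OB/CTOT/CTOB) and possibly flipped `strand`.
#' @export
bisulphite_convert <- function(reads, model,
                               conversion_efficiency = 0.9873,
                               directional = FALSE,
                               seed = 1) {
  stopifnot(inherits(model, "genome_model"))
  if (any(reads$converted)) stop("reads are already bisulphite-converted")
  if (conversion_efficiency < 0 || conversion_efficiency > 1) {
    stop("conversion_efficiency must be in [0, 1]")
  }
  if (nrow(reads) == 0) return(reads)
  read_length <- unique(nchar(reads$seq))
  stopifnot(length(read_length) == 1)

  mt <- model$methylation_truth
  meth_key <- paste(mt$haplotype, mt$contig, mt$pos, mt$strand)

  with_substream(seed, "bisulphite", {
    m <- seq_matrix(reads$seq, read_length)
    conv_strand <- reads$strand
    target_base <- ifelse(conv_strand == "+", "C", "G")
    converted_base <- ifelse(conv_strand == "+", "T", "A")

    hits <- which(m == matrix(target_base,
      nrow = nrow(m), ncol = ncol(m)
    ), arr.ind = TRUE)
    if (nrow(hits) > 0) {
      ri <- hits[, 1]
      gpos <- reads$pos[ri] + hits[, 2] - 1L
      key <- paste(
        reads$haplotype[ri], reads$contig[ri], gpos, conv_strand[ri]
      )
      p_meth <- mt$prob[match(key, meth_key)]
      p_meth[is.na(p_meth)] <- 0
      unmeth <- stats::runif(nrow(hits)) >= p_meth
      convert <- unmeth & stats::runif(nrow(hits)) < conversion_efficiency
      m[hits[convert, , drop = FALSE]] <- converted_base[ri[convert]]
    }

    reads$seq <- collapse_seq_matrix(m)
    reads$converted <- TRUE
    reads$bs_tag <- ifelse(conv_strand == "+", "CT", "GA")
    if (directional) {
      reads$bs_origin <- ifelse(conv_strand == "+", "OT", "OB")
      reads$strand <- conv_strand
    } else {
      complement <- stats::runif(nrow(reads)) < 0.5
      reads$bs_origin <- ifelse(conv_strand == "+",
        ifelse(complement, "CTOT", "OT"),
        ifelse(complement, "CTOB", "OB")
      )
      reads$strand <- ifelse(complement,
        ifelse(conv_strand == "+", "-", "+"),
        conv_strand
      )
    }
    reads
  })
}
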