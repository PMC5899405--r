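# Shared fixtures, built once per test run and memoised; everything is
# generated in code from fixed seeds.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Small polyploid model shared by most unit tests.
tiny_model <- function() {
  fixture("tiny_model", build_genome(
    genome_config(
      n_contigs = 2, contig_length = 4000, homoeo_rate = 0.01,
      varietal_rate = 0.003, control_length = 4000
    ),
    seed = 42
  ))
}

# Error-free untreated reads over the tiny model, filtered for pileup.
tiny_untreated <- function() {
  fixture("tiny_untreated", {
    m <- tiny_model()
    r <- filter_alignments(simulate_reads(m, depth = 30, seed = 42))
    r[r$haplotype %in% c("A", "B", "D"), , drop = FALSE]
  })
}

# Error-free bisulphite reads (efficiency 1 so truth maps cleanly).
tiny_bisulphite <- function() {
  fixture("tiny_bisulphite", {
    m <- tiny_model()
    bisulphite_convert(
      simulate_reads(m, depth = 30, seed = 43), m,
      conversion_efficiency = 1, seed = 43
    )
  })
}

# Hand-built read tibble for pileup / extraction unit cases.
make_reads <- function(contig, pos, seq, strand = "+", mapq = 60L,
                       duplicate = FALSE, bs_tag = NA_character_,
                       name = NULL) {
  n <- max(length(contig), length(pos), length(seq))
  tibble::tibble(
    name = name %||% sprintf("r%03d", seq_len(n)),
    haplotype = NA_character_,
    contig = rep_len(contig, n),
    pos = as.integer(rep_len(pos, n)),
    strand = rep_len(strand, n),
    mapq = as.integer(rep_len(mapq, n)),
    seq = rep_len(seq, n),
    duplicate = rep_len(duplicate, n),
    converted = !is.na(rep_len(bs_tag, n)),
    bs_tag = rep_len(bs_tag, n),
    bs_origin = NA_character_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force SNP-caller oracle: literal threshold evaluation
# per column, written without reference to the package implementation.
oracle_calls <- function(columns, ref_chr, min_cov = 5, min_mean_mapq = 15,
                         min_maf = 0.1) {
  out <- list()
  for (i in seq_len(nrow(columns))) {
    row <- columns[i, ]
    rb <- substr(ref_chr[[row$contig]], row$pos, row$pos)
    if (!rb %in% c("A", "C", "G", "T")) next
    if (row$depth < min_cov) next
    if (!(row$mean_mapq > min_mean_mapq)) next
    for (base in c("A", "C", "G", "T")) {
      if (base == rb) next
      cnt <- row[[paste0("n_", base)]]
      freq <- cnt / row$depth
      if (freq > min_maf) {
        out[[length(out) + 1]] <- data.frame(
          contig = row$contig, pos = row$pos, ref_allele = rb,
          alt_allele = base, alt_freq = freq, depth = row$depth,
          mean_mapq = row$mean_mapq
        )
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(
      contig = character(), pos = integer(), ref_allele = character(),
      alt_allele = character(), alt_freq = numeric(), depth = integer(),
      mean_mapq = numeric()
    ))
  }
  res <- dplyr::bind_rows(out)
  res <- res[order(res$contig, res$pos, res$alt_allele), ]
  tibble::as_tibble(res)
}

# Exhaustive two-sided Fisher oracle by direct hypergeometric enumeration
# with choose() arithmetic (no dhyper), for a single 2x2 table.
oracle_fisher <- function(a, b, c, d) {
  m1 <- a + b
  m2 <- c + d
  k <- a + c
  total <- choose(m1 + m2, k)
  support <- max(0, k - m2):min(k, m1)
  probs <- choose(m1, support) * choose(m2, k - support) / total
  p_obs <- probs[match(a, support)]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
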