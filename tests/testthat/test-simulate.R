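test_that("error-free reads substring-match their haplotype of origin", {
  m <- tiny_model()
  reads <- simulate_reads(m,
    depth = 5, error_rate = 0, duplicate_rate = 0, seed = 1
  )
  on <- reads[reads$haplotype %in% c("A", "B", "D"), ]
  hap_chr <- lapply(m$haplotypes, as.character)
  got <- mapply(
    function(g, ct, p, s) {
      substr(hap_chr[[g]][[ct]], p, p + nchar(s) - 1) == s
    },
    on$haplotype, on$contig, on$pos, on$seq
  )
  expect_true(all(got))
  ctrl <- reads[reads$haplotype == "control", ]
  ctrl_ok <- substring(
    as.character(m$control)[[1]], ctrl$pos, ctrl$pos + 124
  ) == ctrl$seq
  expect_true(all(ctrl_ok))
})

test_that("duplicate flagging is binomially consistent with the rate", {
  m <- tiny_model()
  reads <- simulate_reads(m, depth = 10, duplicate_rate = 0.5, seed = 2)
  n <- nrow(reads)
  expect_lt(abs(sum(reads$duplicate) - 0.5 * n), 4 * sqrt(n * 0.25))
})

test_that("on_target_fraction 1 emits no control or background reads", {
  m <- tiny_model()
  reads <- simulate_reads(m, depth = 3, on_target_fraction = 1, seed = 3)
  expect_true(all(reads$haplotype %in% c("A", "B", "D")))
})

test_that("mean on-target depth lands within 10% of the request", {
  m <- tiny_model()
  reads <- simulate_reads(m, depth = 30, seed = 4)
  on <- reads[reads$haplotype %in% c("A", "B", "D"), ]
  total_len <- sum(Biostrings::width(m$reference))
  mean_depth <- sum(nchar(on$seq)) / total_len
  expect_lt(abs(mean_depth - 30) / 30, 0.1)
})

test_that("invalid simulation parameters are rejected", {
  m <- tiny_model()
  expect_error(simulate_reads(m, depth = 0), "depth")
  expect_error(simulate_reads(m, depth = -3), "depth")
  expect_error(
    simulate_reads(m, depth = 5, read_length = 5000),
    "shorter than read length"
  )
  expect_error(
    bisulphite_convert(
      simulate_reads(m, depth = 1, seed = 1), m,
      conversion_efficiency = 1.2
    ),
    "conversion_efficiency"
  )
})

test_that("conversion at efficiency 0 is the identity", {
  m <- tiny_model()
  reads <- simulate_reads(m, depth = 2, seed = 5)
  conv <- bisulphite_convert(reads, m,
    conversion_efficiency = 0, directional = TRUE, seed = 5
  )
  expect_identical(conv$seq, reads$seq)
  expect_true(all(conv$converted))
  expect_error(bisulphite_convert(conv, m), "already")
})

test_that("full conversion of an unmethylated genome leaves no top-strand C", {
  m0 <- build_genome(
    genome_config(
      n_contigs = 1, contig_length = 2000,
      meth_rates = c(CpG = 0, CHG = 0, CHH = 0)
    ),
    seed = 6
  )
  reads <- simulate_reads(m0,
    depth = 5, on_target_fraction = 1, seed = 6
  )
  conv <- bisulphite_convert(reads, m0,
    conversion_efficiency = 1, directional = TRUE, seed = 6
  )
  top <- conv[conv$bs_tag == "CT", ]
  expect_gt(nrow(top), 0)
  expect_false(any(grepl("C", top$seq, fixed = TRUE)))
  bottom <- conv[conv$bs_tag == "GA", ]
  expect_false(any(grepl("G", bottom$seq, fixed = TRUE)))
})

test_that("conversion only rewrites the fragment strand's cytosine base", {
  m <- tiny_model()
  reads <- simulate_reads(m, depth = 3, seed = 7)
  conv <- bisulphite_convert(reads, m, directional = TRUE, seed = 7)
  expect_identical(nchar(conv$seq), nchar(reads$seq))
  for (i in seq_len(nrow(reads))) {
    before <- strsplit(reads$seq[i], "")[[1]]
    after <- strsplit(conv$seq[i], "")[[1]]
    changed <- which(before != after)
    if (reads$strand[i] == "+") {
      expect_true(all(before[changed] == "C" & after[changed] == "T"))
    } else {
      expect_true(all(before[changed] == "G" & after[changed] == "A"))
    }
  }
})

test_that("simulated conversion recovers the configured efficiency rate", {
  # all-unmethylated single contig: every C observation is convertible
  m0 <- build_genome(
    genome_config(
      n_contigs = 1, contig_length = 20000,
      meth_rates = c(CpG = 0, CHG = 0, CHH = 0), homoeo_rate = 0,
      varietal_rate = 0
    ),
    seed = 8
  )
  reads <- simulate_reads(m0, depth = 30, on_target_fraction = 1, seed = 8)
  eff <- 0.9873
  conv <- bisulphite_convert(reads, m0,
    conversion_efficiency = eff, directional = TRUE, seed = 8
  )
  target <- ifelse(conv$bs_tag == "CT", "C", "G")
  n_before <- stringr::str_count(reads$seq, stringr::fixed(target))
  n_after <- stringr::str_count(conv$seq, stringr::fixed(target))
  n_sites <- sum(n_before)
  n_conv <- sum(n_before - n_after)
  expect_gt(n_sites, 100000)
  sd <- sqrt(n_sites * eff * (1 - eff))
  expect_lt(abs(n_conv - eff * n_sites), 3 * sd)
})

test_that("identical seeds reproduce identical FASTQ and SAM bytes", {
  m <- tiny_model()
  combined <- c(
    setNames(as.character(m$reference), names(m$reference)),
    setNames(as.character(m$control), names(m$control))
  )
  files <- replicate(2, {
    r <- bisulphite_convert(
      simulate_reads(m, depth = 2, seed = 21), m,
      seed = 21
    )
    sam <- tempfile(fileext = ".sam")
    fq <- tempfile(fileext = ".fastq")
    write_sam(r, combined, sam)
    write_fastq(r, fq)
    c(sam = unname(tools::md5sum(sam)), fq = unname(tools::md5sum(fq)))
  })
  expect_identical(files[, 1], files[, 2])
})
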