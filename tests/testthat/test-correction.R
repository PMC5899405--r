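snp_row <- function(ref, alt, pos = 1L, freq = 1, contig = "c") {
  tibble::tibble(
    contig = contig, pos = as.integer(pos), ref_allele = ref,
    alt_allele = alt, alt_freq = freq, depth = 20L, mean_mapq = 40
  )
}

test_that("SNP classification follows the base-change categories", {
  cls <- classify_snps(dplyr::bind_rows(
    snp_row("C", "T", 1),
    snp_row("G", "A", 2),
    snp_row("A", "G", 3), # creates a minus-strand cytosine
    snp_row("T", "C", 4),
    snp_row("C", "G", 5),
    snp_row("A", "T", 6)
  ))
  expect_equal(
    cls$category,
    c("CT_GA", "CT_GA", "AT_CG", "AT_CG", "CG_SWAP", "OTHER")
  )
  expect_error(classify_snps(snp_row("C", "C")), "identical")
})

test_that("classification recovers simulated varietal categories exactly", {
  m <- tiny_model()
  snps <- classify_snps(call_polyploid_snps(
    pileup(tiny_untreated(), m$reference), m$reference
  ))
  vrec <- dplyr::inner_join(
    snps, m$varietal_truth,
    by = c("contig", "pos")
  )
  expect_gt(nrow(vrec), 5)
  expect_identical(vrec$alt_allele.x, vrec$alt_allele.y)
  truth_cat <- dplyr::case_when(
    vrec$ref_allele.y == "C" & vrec$alt_allele.y == "T" ~ "CT_GA",
    vrec$ref_allele.y == "G" & vrec$alt_allele.y == "A" ~ "CT_GA",
    vrec$ref_allele.y %in% c("A", "T") &
      vrec$alt_allele.y %in% c("C", "G") ~ "AT_CG",
    vrec$ref_allele.y %in% c("C", "G") &
      vrec$alt_allele.y %in% c("C", "G") ~ "CG_SWAP",
    TRUE ~ "OTHER"
  )
  expect_identical(vrec$category, truth_cat)
})

test_that("reference correction masks, substitutes and reports sites", {
  ref <- c(c = "ACGTAG")
  cls <- classify_snps(dplyr::bind_rows(
    snp_row("C", "T", 2), # masked + site
    snp_row("A", "C", 5) # added + site, substituted
  ))
  corr <- correct_reference(ref, cls)
  expect_equal(as.character(corr$reference)[["c"]], "ACGTCG")
  expect_equal(corr$masked$pos, 2L)
  expect_equal(corr$masked$strand, "+")
  expect_equal(corr$added$pos, 5L)
  # masked site absent from the corrected cytosine set
  cyt <- cytosine_sites(corr$reference, mask = corr$masked)
  expect_false(any(cyt$pos == 2 & cyt$strand == "+"))
  expect_true(any(cyt$pos == 5 & cyt$strand == "+"))
  # the added cytosine's context comes from the corrected sequence ("CG.")
  expect_equal(cyt$context[cyt$pos == 5 & cyt$strand == "+"], "truncated")
  corr2 <- correct_reference(
    c(c = "ACGTAGAA"), classify_snps(snp_row("A", "C", 5))
  )
  sites2 <- cytosine_sites(corr2$reference)
  expect_equal(sites2$context[sites2$pos == 5 & sites2$strand == "+"], "CpG")
})

test_that("heterozygous calls and contradictions are handled", {
  ref <- c(c = "ACGTAG")
  het <- classify_snps(snp_row("C", "T", 2, freq = 0.4))
  corr <- correct_reference(ref, het)
  expect_equal(nrow(corr$edits), 0)
  expect_equal(nrow(corr$masked), 0)
  dup <- dplyr::bind_rows(snp_row("C", "T", 2), snp_row("C", "G", 2))
  dup$category <- c("CT_GA", "CG_SWAP")
  expect_error(correct_reference(ref, dup), "contradictory")
})

test_that("CG swaps move the cytosine to the other strand", {
  ref <- c(c = "AACGTTAA")
  corr <- correct_reference(ref, classify_snps(snp_row("C", "G", 3)))
  expect_equal(as.character(corr$reference)[["c"]], "AAGGTTAA")
  expect_equal(corr$masked$strand, "+")
  expect_equal(corr$added$strand, "-")
  expect_equal(corr$added$pos, 3L)
})

test_that("correction-report arithmetic matches its definition", {
  # 3 C/T SNPs over 30 analyzable cytosines -> 10.0%
  cls <- classify_snps(dplyr::bind_rows(
    snp_row("C", "T", 1), snp_row("G", "A", 2), snp_row("C", "T", 3),
    snp_row("A", "C", 4)
  ))
  rec <- tibble::tibble(
    contig = "c", pos = 1:40, strand = "+", context = "CpG",
    meth_count = c(rep(10L, 30), rep(2L, 10)), unmeth_count = 0L
  )
  rep <- correction_report(cls, rec, min_depth = 10)
  expect_equal(rep$n_analyzable_cytosines, 30)
  expect_equal(rep$pct_calls_eliminated, 10.0)
  expect_equal(rep$n_ct_ga, 3)
  expect_equal(rep$n_at_cg, 1)
  # no C/T SNPs -> 0.0%
  none <- correction_report(
    classify_snps(snp_row("A", "C", 4)), rec,
    min_depth = 10
  )
  expect_equal(none$pct_calls_eliminated, 0.0)
  # zero analyzable cytosines -> undefined, flagged
  undef <- correction_report(cls, rec[0, ], min_depth = 10)
  expect_false(undef$defined)
  expect_true(is.na(undef$pct_calls_eliminated))
})

test_that("simulated C->T varietal SNPs stop producing false unmethylated calls after correction", {
  m <- fixture("corr_model", build_genome(
    genome_config(
      n_contigs = 2, contig_length = 5000, varietal_rate = 0.004
    ),
    seed = 11
  ))
  vt <- m$varietal_truth
  ct_sites <- dplyr::bind_rows(
    dplyr::mutate(
      dplyr::filter(vt, ref_allele == "C", alt_allele == "T"), strand = "+"
    ),
    dplyr::mutate(
      dplyr::filter(vt, ref_allele == "G", alt_allele == "A"), strand = "-"
    )
  )[, c("contig", "pos", "strand")]
  skip_if(nrow(ct_sites) == 0, "no C->T varietal SNPs drawn")

  un <- filter_alignments(simulate_reads(m, depth = 30, seed = 11))
  un <- un[un$haplotype %in% c("A", "B", "D"), ]
  snps <- classify_snps(
    call_polyploid_snps(pileup(un, m$reference), m$reference)
  )
  corr <- correct_reference(m$reference, snps)

  bs <- filter_alignments(bisulphite_convert(
    simulate_reads(m, depth = 30, seed = 12), m,
    seed = 12
  ))
  bs <- bs[!is.na(bs$contig) & bs$contig %in% names(m$reference), ]
  before <- extract_methylation(bs, m$reference)$records
  false_before <- dplyr::semi_join(
    before, ct_sites,
    by = c("contig", "pos", "strand")
  )
  expect_gt(sum(false_before$unmeth_count), 0)
  after <- extract_methylation(bs, corr$reference, mask = corr$masked)$records
  false_after <- dplyr::semi_join(
    after, ct_sites,
    by = c("contig", "pos", "strand")
  )
  expect_equal(sum(false_after$unmeth_count) + sum(false_after$meth_count), 0)

  # corrected cytosine set = (original - masked) + added, exactly
  orig <- cytosine_sites(m$reference)[, c("contig", "pos", "strand")]
  got <- cytosine_sites(corr$reference, mask = corr$masked)[
    , c("contig", "pos", "strand")
  ]
  want <- dplyr::arrange(dplyr::distinct(dplyr::bind_rows(
    dplyr::anti_join(orig, corr$masked, by = c("contig", "pos", "strand")),
    corr$added
  )), contig, pos, strand)
  expect_equal(as.data.frame(got), as.data.frame(want))
})
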