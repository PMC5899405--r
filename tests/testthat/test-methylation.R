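test_that("extraction follows the hand-traced conversion rules", {
  ref <- c(c = "TACGT")
  # top-strand read with the C converted: unmethylated CpG at pos 3
  un <- extract_methylation(
    make_reads("c", 1, "TATGT", bs_tag = "CT"), ref
  )
  expect_equal(un$records$pos, 3L)
  expect_equal(un$records$strand, "+")
  expect_equal(un$records$context, "CpG")
  expect_equal(un$records$unmeth_count, 1L)
  expect_equal(un$records$meth_count, 0L)
  # unconverted C: methylated
  me <- extract_methylation(
    make_reads("c", 1, "TACGT", bs_tag = "CT"), ref
  )
  expect_equal(me$records$meth_count[me$records$pos == 3], 1L)
  # the same read on the bottom strand scores the reference G at pos 4
  bo <- extract_methylation(
    make_reads("c", 1, "TACGT", bs_tag = "GA"), ref
  )
  expect_equal(bo$records$pos, 4L)
  expect_equal(bo$records$strand, "-")
  expect_equal(bo$records$meth_count, 1L)
  ba <- extract_methylation(
    make_reads("c", 1, "TACAT", bs_tag = "GA"), ref
  )
  expect_equal(ba$records$unmeth_count[ba$records$pos == 4], 1L)
})

test_that("reads without a bisulphite strand tag are rejected by name", {
  ref <- c(c = "TACGT")
  expect_error(
    extract_methylation(make_reads("c", 1, "TACGT", name = "naked"), ref),
    "naked"
  )
})

test_that("context classification covers CpG, CHG, CHH and truncation", {
  ref <- c(k = "ACGCTGCATAA")
  #         123456789..
  expect_equal(
    classify_context(ref, rep("k", 3), c(2L, 4L, 7L), rep("+", 3)),
    c("CpG", "CHG", "CHH")
  )
  # reverse strand: context reads leftwards on the complement
  expect_equal(
    classify_context(ref, c("k", "k"), c(3L, 6L), c("-", "-")),
    c("CpG", "CHG")
  )
  # within two bases of the contig end
  expect_equal(classify_context(ref, "k", 11L, "+"), "truncated")
  expect_equal(classify_context(ref, "k", 1L, "-"), "truncated")
  sites <- cytosine_sites(ref)
  expect_true(all(c("+", "-") %in% sites$strand))
  # masking removes sites from the set
  masked <- cytosine_sites(
    ref,
    mask = tibble::tibble(contig = "k", pos = 2L, strand = "+")
  )
  expect_false(any(masked$pos == 2 & masked$strand == "+"))
})

test_that("fully methylated genome at full efficiency yields no unmethylated calls", {
  m1 <- build_genome(
    genome_config(
      n_contigs = 1, contig_length = 2000,
      meth_rates = c(CpG = 1, CHG = 1, CHH = 1),
      homoeo_rate = 0, varietal_rate = 0
    ),
    seed = 31
  )
  bs <- bisulphite_convert(
    simulate_reads(m1, depth = 5, on_target_fraction = 1, seed = 31),
    m1,
    conversion_efficiency = 1, seed = 31
  )
  ext <- extract_methylation(bs, m1$reference)
  # truncated edge sites are simulated unmethylated; all classified
  # contexts must be fully methylated
  ctx <- ext$records[ext$records$context != "truncated", ]
  expect_equal(sum(ctx$unmeth_count), 0)
  expect_gt(sum(ctx$meth_count), 0)
})

test_that("pooled CpG methylation recovers the simulated rate", {
  m <- tiny_model()
  bs <- filter_alignments(tiny_bisulphite())
  bs <- bs[bs$contig %in% names(m$reference), ]
  rec <- extract_methylation(bs, m$reference)$records
  cpg <- rec[rec$context == "CpG", ]
  n <- sum(cpg$meth_count + cpg$unmeth_count)
  level <- sum(cpg$meth_count) / n
  # homoeologous/varietal divergence makes a few reference-CpG sites
  # non-cytosine in some haplotype; allow 3 binomial SD around 0.8
  expect_lt(abs(level - 0.8), 3 * sqrt(0.8 * 0.2 / n) + 0.02)
})

test_that("sub-genome assignment requires MAPQ strictly over 20", {
  ref <- c(c = strrep("A", 30))
  hl <- tibble::tibble(
    contig = "c", pos = c(5L, 5L), allele = c("G", "T"),
    genomes = c("D", "A")
  )
  mk <- function(mapq) {
    r <- make_reads("c", 1,
      paste0("AAAAG", "CG", strrep("A", 23)),
      mapq = mapq, bs_tag = "CT", name = "probe"
    )
    ext <- extract_methylation(r, c(c = paste0(
      "AAAAA", "CG", strrep("A", 23)
    )))
    assign_subgenome_methylation(ext, r, hl, min_mapq = 20)
  }
  at20 <- mk(20L)
  expect_equal(nrow(attr(at20, "assignments")), 0)
  at21 <- mk(21L)
  expect_equal(attr(at21, "assignments")$genome, "D")
  # the read's methylated C at pos 6 is credited to D
  expect_equal(at21$meth_D[at21$pos == 6], 1L)
  expect_equal(at21$meth_count[at21$pos == 6], 1L)
})

test_that("bisulphite-aliased diagnostic alleles are not used for assignment", {
  # C(A) vs T(B,D) SNP: a top-strand read showing T is ambiguous because an
  # unmethylated C also reads T; a bottom-strand (GA) read keeps C/T apart
  ref <- c(c = strrep("A", 30))
  hl <- tibble::tibble(
    contig = "c", pos = c(5L, 5L), allele = c("C", "T"),
    genomes = c("A", "B,D")
  )
  seqv <- paste0("AAAAT", strrep("A", 25))
  top <- make_reads("c", 1, seqv, mapq = 60L, bs_tag = "CT")
  ext_top <- extract_methylation(top, ref)
  got_top <- assign_subgenome_methylation(ext_top, top, hl)
  expect_equal(nrow(attr(got_top, "assignments")), 0)
})

test_that("error-free simulation assigns every diagnostic read to its true sub-genome", {
  m <- tiny_model()
  bs <- tiny_bisulphite()
  bs <- bs[!is.na(bs$contig) & bs$contig %in% names(m$reference), ]
  ext <- extract_methylation(bs, m$reference)
  hl <- build_homoeolog_list_from_haplotypes(m$reference, m$haplotypes)
  rec <- assign_subgenome_methylation(ext, bs, hl)
  asg <- attr(rec, "assignments")
  truth <- dplyr::inner_join(
    asg, bs[, c("name", "haplotype")],
    by = "name"
  )
  expect_gt(nrow(truth), 100)
  expect_equal(mean(truth$genome == truth$haplotype), 1)
  # per-sub-genome counts never exceed totals
  expect_true(all(
    rec$meth_A + rec$meth_B + rec$meth_D <= rec$meth_count &
      rec$unmeth_A + rec$unmeth_B + rec$unmeth_D <= rec$unmeth_count
  ))
})

test_that("conversion-efficiency arithmetic matches its definition", {
  ref <- c(ctl = strrep("AC", 200))
  n_t <- 99
  n_c <- 1
  reads <- make_reads(
    contig = "ctl", pos = seq(1, by = 2, length.out = 100),
    seq = c(rep("ATA", n_t), rep("ACA", n_c)), bs_tag = "CT",
    name = sprintf("cv%03d", 1:100)
  )
  ce <- conversion_efficiency(reads, ref)
  expect_equal(ce$efficiency_pct, 99)
  all_t <- conversion_efficiency(reads[1:n_t, ], ref)
  expect_equal(all_t$efficiency_pct, 100)
  none <- conversion_efficiency(reads[0, ], ref)
  expect_false(none$defined)
  expect_true(is.na(none$efficiency_pct))
})

test_that("differential methylation matches the enumeration oracle and thresholds", {
  rec <- function(meth, unmeth, pos = 1L) {
    tibble::tibble(
      contig = "c", pos = pos, strand = "+", context = "CpG",
      meth_count = meth, unmeth_count = unmeth
    )
  }
  # (5,0) vs (0,5): p = 2/252, difference 100 points
  dm <- differential_methylation(rec(5L, 0L), rec(0L, 5L))
  expect_equal(dm$p_value, 2 / 252, tolerance = 1e-12)
  expect_equal(dm$meth_difference, 100)
  expect_true(dm$significant)
  expect_true(
    differential_methylation(rec(5L, 0L), rec(0L, 5L), min_diff = 50)$significant
  )
  # identical groups: p = 1, not significant
  same <- differential_methylation(rec(3L, 3L), rec(3L, 3L))
  expect_equal(same$p_value, 1)
  expect_false(same$significant)
  # depth 4 in one group -> excluded from testing
  thin <- differential_methylation(rec(4L, 0L), rec(0L, 5L))
  expect_equal(attr(thin, "n_tested"), 0)
  expect_error(differential_methylation(rec(1L, 1L), rec(1L, 1L), min_depth = 0))
})

test_that("two-sided Fisher p equals exhaustive enumeration over small margins", {
  tables <- expand.grid(a = 0:6, b = 0:6, c = 0:6, d = 0:6)
  tables <- tables[tables$a + tables$b >= 1 & tables$c + tables$d >= 1, ]
  got <- fisher_exact_2x2(tables$a, tables$b, tables$c, tables$d)
  want <- mapply(oracle_fisher, tables$a, tables$b, tables$c, tables$d)
  expect_lt(max(abs(got - want) / want), 1e-7)
})

test_that("Fisher p agrees with the reference implementation", {
  set.seed(7)
  a <- rbinom(100, 15, 0.6)
  c <- rbinom(100, 11, 0.3)
  got <- fisher_exact_2x2(a, 15 - a, c, 11 - c)
  want <- mapply(
    function(a, b, c, d) {
      stats::fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))$p.value
    },
    a, 15 - a, c, 11 - c
  )
  expect_equal(got, want, tolerance = 1e-10)
})
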