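test_that("chi2_homogeneity matches hand evaluation and the chisq.test oracle", {
  t0 <- chi2_homogeneity(10, 100, 10, 100)
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)
  # worked table: 250 * (40*100 - 100*10)^2 / (140*110*50*200)
  t1 <- chi2_homogeneity(40, 100, 10, 100)
  expect_equal(t1$statistic, 250 * 3000^2 / (140 * 110 * 50 * 200))
  expect_equal(t1$statistic, 14.61, tolerance = 1e-4)
  expect_equal(t1$p_value, 1.3e-4, tolerance = 0.02)
  # zero margin
  t2 <- chi2_homogeneity(0, 0, 5, 50)
  expect_equal(t2$statistic, 0)
  expect_equal(t2$p_value, 1)
  set.seed(7)
  for (i in 1:25) {
    tb <- matrix(rpois(4, 40) + 1, 2)
    ours <- chi2_homogeneity(tb[1, 1], tb[1, 2], tb[2, 1], tb[2, 2])
    ref <- suppressWarnings(stats::chisq.test(tb, correct = FALSE))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("fisher2x2 matches enumeration, fisher.test, and the stated examples", {
  expect_equal(fisher2x2(5, 0, 0, 5), 2 / 252)
  expect_equal(fisher2x2(3, 3, 3, 3), 1)
  expect_equal(fisher2x2(0, 0, 7, 9), 1)  # zero row
  expect_equal(fisher2x2(0, 4, 0, 9), 1)  # zero column
  set.seed(11)
  for (i in 1:50) {
    x <- rpois(4, sample(c(3, 20, 80), 1))
    expect_equal(fisher2x2(x[1], x[2], x[3], x[4]),
                 oracle_fisher(x[1], x[2], x[3], x[4]), tolerance = 1e-12)
    expect_equal(fisher2x2(x[1], x[2], x[3], x[4]),
                 stats::fisher.test(matrix(x, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-9)
  }
  # fractional entries are rounded half-up
  expect_equal(fisher2x2(4.5, 0.4, 0.2, 4.5), fisher2x2(5, 0, 0, 5))
})

test_that("intron-retention scan calls IR/MES with the all-replicates rule", {
  # ratio 0.40 (mutant) vs 0.10 (wt) at exon depth 100: the worked chi2
  # table per pair, p ~ 1.3e-4 < 0.01 in all 5 pairs -> significant IR
  fx <- ir_fixture(wt_intron = 10, mut_intron = 40)
  ir <- scan_intron_retention(fx$wt, fx$mut, fx$models)
  expect_equal(nrow(ir), 1L)
  expect_true(ir$significant)
  expect_equal(ir$event_type, "IR")
  expect_equal(ir$p_values[[1]], rep(1.3e-4, 5), tolerance = 0.02)
  expect_equal(ir$ratio_mut[[1]], rep(0.4, 5))
  # reversed magnitudes -> MES; genotype swap maps IR <-> MES exactly
  mes <- scan_intron_retention(fx$mut, fx$wt, fx$models)
  expect_true(mes$significant)
  expect_equal(mes$event_type, "MES")
  expect_equal(mes$p_values[[1]], ir$p_values[[1]])
  # identical genotypes -> nothing significant
  null <- scan_intron_retention(fx$wt, fx$wt, fx$models)
  expect_false(any(null$significant))
})

test_that("one failing replicate or a discordant direction blocks the call", {
  fx <- ir_fixture(wt_intron = 10, mut_intron = 40)
  # replicate 3 shows no difference -> p ~ 1 there -> not significant
  fx$mut[[3]] <- fx$wt[[3]]
  ir <- scan_intron_retention(fx$wt, fx$mut, fx$models)
  expect_false(any(ir$significant))
  # direction flip in one replicate (strong both ways): all p < alpha but
  # the per-pair directions disagree -> no call
  fx2 <- ir_fixture(wt_intron = 10, mut_intron = 40)
  tmp <- fx2$mut[[2]]
  fx2$mut[[2]] <- fx2$wt[[2]]
  fx2$wt[[2]] <- tmp
  ir2 <- scan_intron_retention(fx2$wt, fx2$mut, fx2$models)
  expect_true(all(ir2$p_values[[1]] < 0.01))
  expect_true(is.na(ir2$event_type))
  expect_false(any(ir2$significant))
})

test_that("zero background skips the intron with a diagnostic", {
  fx <- ir_fixture(wt_intron = 10, mut_intron = 40)
  fx$wt[[2]]$exon_depth$depth <- c(0, 0)
  ir <- scan_intron_retention(fx$wt, fx$mut, fx$models)
  expect_equal(nrow(ir), 0L)
  expect_equal(attr(ir, "skipped")$gene_id, "g1")
})

test_that("exon-skipping scan follows the skip/inclusion contingency", {
  models <- gene_model_set(list(three_exon_model()))
  mk <- function(skip, incl, id) {
    j <- data.table::data.table(
      gene_id = "g1", chrom = "chr1",
      donor_end = c(100, 300, 100), acceptor_start = c(201, 401, 401),
      count = c(incl / 2, incl / 2, skip),
      annotated = c(TRUE, TRUE, FALSE),
      intron_index = c(1L, 2L, NA))
    manual_sc(models, id, junctions = j[j$count > 0])
  }
  wt <- lapply(1:5, function(i) mk(2, 100, paste0("wt_", i)))
  mut <- lapply(1:5, function(i) mk(20, 100, paste0("mut_", i)))
  es <- scan_exon_skipping(wt, mut, models)
  expect_equal(nrow(es), 1L)
  expect_true(es$significant)
  expect_equal(es$event_type, "ES_enhanced")
  expect_equal(es$exon_index, 2L)
  expect_equal(es$junction, "100-401")
  # per-pair table (20,100,2,100) by hand: 222*1800^2/(120*102*22*200)
  expect_equal(es$p_values[[1]],
               rep(stats::pchisq(222 * 1800^2 / (120 * 102 * 22 * 200), 1,
                                 lower.tail = FALSE), 5))
  # equal usage -> p = 1, no call; skip never observed -> no test at all
  eq <- scan_exon_skipping(wt, wt, models)
  expect_false(any(eq$significant))
  expect_true(all(unlist(eq$p_values) == 1))
  none <- lapply(1:5, function(i) mk(0, 100, paste0("n_", i)))
  expect_equal(nrow(scan_exon_skipping(none, none, models)), 0L)
  # genotype swap flips the direction label
  es_rev <- scan_exon_skipping(mut, wt, models)
  expect_equal(es_rev$event_type, "ES_reduced")
})

test_that("alt splice-site scan needs both Fisher tests in every replicate", {
  models <- gene_model_set(list(two_exon_model()))
  mk <- function(variant, annotated, id, uniq = 1000) {
    j <- data.table::data.table(
      gene_id = "g1", chrom = "chr1",
      donor_end = c(100, 100), acceptor_start = c(201, 189),
      count = c(annotated, variant), annotated = c(TRUE, FALSE),
      intron_index = c(1L, 1L))
    manual_sc(models, id, junctions = j[j$count > 0],
              gene_reads = c(g1 = uniq))
  }
  wt <- lapply(1:5, function(i) mk(5, 35, paste0("wt_", i)))
  mut <- lapply(1:5, function(i) mk(30, 10, paste0("mut_", i)))
  alt <- scan_alt_splice_sites(wt, mut, models)
  expect_equal(nrow(alt), 1L)
  expect_true(alt$significant)
  # acceptor changed on a plus-strand gene -> alternative 3' splice site;
  # 30/1000 > 5/1000 -> enhanced
  expect_equal(alt$event_type, "A3SS_enhanced")
  expect_equal(alt$p_values[[1]],
               rep(stats::fisher.test(matrix(c(30, 10, 5, 35), 2,
                                             byrow = TRUE))$p.value, 5),
               tolerance = 1e-9)
  expect_equal(alt$p_values_gene[[1]],
               rep(stats::fisher.test(matrix(c(30, 1000, 5, 1000), 2,
                                             byrow = TRUE))$p.value, 5),
               tolerance = 1e-9)
  # identical relative usage -> p = 1, no call
  eq <- scan_alt_splice_sites(wt, wt, models)
  expect_false(any(eq$significant))
  # swap -> reduced
  red <- scan_alt_splice_sites(mut, wt, models)
  expect_equal(red$event_type, "A3SS_reduced")
})

test_that("alt-SS side label is strand-aware", {
  mkset <- function(strand) gene_model_set(list(two_exon_model(strand = strand)))
  mk <- function(models, donor_side, variant, annotated, id) {
    de <- if (donor_side) c(100, 112) else c(100, 100)
    as_ <- if (donor_side) c(201, 201) else c(201, 189)
    j <- data.table::data.table(
      gene_id = "g1", chrom = "chr1", donor_end = de, acceptor_start = as_,
      count = c(annotated, variant), annotated = c(TRUE, FALSE),
      intron_index = c(1L, 1L))
    manual_sc(models, id, gene_reads = c(g1 = 1000), junctions = j)
  }
  for (strand in c("+", "-")) for (donor_side in c(TRUE, FALSE)) {
    models <- mkset(strand)
    wt <- lapply(1:3, function(i) mk(models, donor_side, 5, 45, paste0("w", i)))
    mut <- lapply(1:3, function(i) mk(models, donor_side, 40, 10, paste0("m", i)))
    alt <- scan_alt_splice_sites(wt, mut, models)
    expected <- if (donor_side == (strand == "+")) "A5SS" else "A3SS"
    expect_equal(alt$event_type, paste0(expected, "_enhanced"),
                 info = paste(strand, donor_side))
  }
})

test_that("zero unique gene count skips the variant with a diagnostic", {
  models <- gene_model_set(list(two_exon_model()))
  j <- data.table::data.table(gene_id = "g1", chrom = "chr1",
                              donor_end = c(100, 100),
                              acceptor_start = c(201, 189),
                              count = c(30, 10), annotated = c(TRUE, FALSE),
                              intron_index = c(1L, 1L))
  zero <- lapply(1:2, function(i)
    manual_sc(models, paste0("z", i), junctions = j,
              gene_reads = c(g1 = 0), library_size = 1))
  ok <- lapply(1:2, function(i)
    manual_sc(models, paste0("k", i), junctions = j, gene_reads = c(g1 = 100)))
  alt <- scan_alt_splice_sites(zero, ok, models)
  expect_equal(nrow(alt), 0L)
  expect_equal(attr(alt, "skipped")$gene_id, "g1")
})

test_that("event summary counts events, genes and multi-event genes", {
  fx <- ir_fixture(10, 40)
  ir <- scan_intron_retention(fx$wt, fx$mut, fx$models)
  sm <- summarize_events(ir = ir)
  expect_equal(sm$event_type, "IR")
  expect_equal(sm$n_events, 1L)
  expect_equal(sm$n_multi_event_genes, 0L)
  sh <- shared_events(ir, ir)
  expect_equal(nrow(sh), 1L)
  expect_equal(nrow(shared_events(ir, ir[0, ])), 0L)
})
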