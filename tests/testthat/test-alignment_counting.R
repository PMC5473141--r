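test_that("identity filter keeps >= min_identity and drops below", {
  # 40M reads with NM:i:2 -> identity 0.95; NM:i:8 -> 0.80
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(sam, data.frame(
    qname = c("keep", "drop"), chrom = "chr1", pos = c(10, 10),
    cigar = "40M", extra = c("NM:i:2", "NM:i:8")))
  kept <- stream_alignments(sam, min_identity = 0.90)
  expect_equal(unique(kept$blocks$qname), "keep")
  expect_equal(kept$n_low_identity, 1L)
  all_kept <- stream_alignments(sam, min_identity = 0)
  expect_setequal(unique(all_kept$blocks$qname), c("keep", "drop"))
})

test_that("missing @SQ header is fatal; bad records are skipped with a counter", {
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(sam, data.frame(qname = "r", chrom = "chr1", pos = 10,
                            cigar = "10M"), header = FALSE)
  expect_error(stream_alignments(sam), "@SQ")
  sam2 <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6", "@SQ\tSN:chr1\tLN:10000",
               "ok\t0\tchr1\t10\t255\t10M\t*\t0\t0\tAAAAAAAAAA\t*\tNM:i:0",
               "broken\t0\tchr1\tnotanumber\t255\t10M\t*\t0\t0\tAAAA\t*",
               "short\t0\tchr1"), sam2)
  ar <- stream_alignments(sam2)
  expect_equal(ar$n_skipped, 2L)
  expect_equal(unique(ar$blocks$qname), "ok")
})

test_that("mapq-0 records are excluded as non-unique", {
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(sam, data.frame(qname = c("multi", "uni"), chrom = "chr1",
                            pos = c(10, 10), cigar = "10M",
                            mapq = c(0L, 40L)))
  ar <- stream_alignments(sam)
  expect_equal(unique(ar$blocks$qname), "uni")
  expect_equal(ar$n_nonunique, 1L)
})

test_that("depth, junction and boundary arithmetic match hand evaluation", {
  models <- gene_model_set(list(two_exon_model()))
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(sam, data.frame(
    qname = c("in_exon", "spliced", "retained"),
    chrom = "chr1",
    pos = c(11, 81, 91),
    cigar = c("50M", "20M100N20M", "30M")))
  sc <- count_sample(stream_alignments(sam), models, anchor = 8L)
  # 50-base read inside the 100-nt exon 1: depth 0.5; spliced read adds
  # 20/100; retained read adds 10/100 (positions 91-100)
  expect_equal(sc$exon_depth$depth[sc$exon_depth$index == 1], 0.8)
  # spliced gap (101,200) matches the intron exactly
  jx <- sc$junction_reads
  ann <- jx[jx$annotated == TRUE, ]
  expect_equal(nrow(ann), 1L)
  expect_equal(ann$count, 1)
  expect_equal(c(ann$donor_end, ann$acceptor_start), c(100, 201))
  # intron depth: only the retained read's 20 bases (101-120) overlap
  expect_equal(sc$intron_depth$depth, 20 / 100)
  # the retained read (91-120) covers the 5' boundary window [93, 108]
  b <- sc$boundary_reads
  expect_equal(b$count[b$side == "5p"], 1)
  # anchor 11 needs [90, 111], which the read does not cover
  sc11 <- count_sample(stream_alignments(sam), models, anchor = 11L)
  expect_equal(nrow(sc11$boundary_reads[sc11$boundary_reads$side == "5p", ]), 0L)
})

test_that("junction match is exact: a 1-nt perturbed gap never counts", {
  models <- gene_model_set(list(two_exon_model()))
  # acceptor 1 nt early (gap 101-199, donor shared); donor 1 nt late
  # (gap 102-200, acceptor shared); whole read shifted (gap 100-199,
  # neither end shared)
  cases <- data.frame(pos = c(81, 82, 80),
                      cigar = c("20M99N21M", "20M99N20M", "20M100N20M"),
                      attached = c(TRUE, TRUE, FALSE))
  for (i in seq_len(nrow(cases))) {
    sam <- withr::local_tempfile(fileext = ".sam")
    write_sam(sam, data.frame(qname = "r", chrom = "chr1",
                              pos = cases$pos[i], cigar = cases$cigar[i]))
    sc <- count_sample(stream_alignments(sam), models)
    expect_equal(sum(sc$junction_reads$count[sc$junction_reads$annotated]), 0,
                 info = cases$cigar[i])
    # near-misses sharing one end are attached to the intron as observed
    # alternative junctions; sharing neither end stays unattached
    alt <- sc$junction_reads[!sc$junction_reads$annotated, ]
    expect_equal(alt$count, 1)
    if (cases$attached[i]) expect_equal(alt$intron_index, 1L)
    else expect_true(is.na(alt$intron_index))
  }
})

test_that("counting is order-independent and paired mates count once", {
  models <- gene_model_set(list(two_exon_model(), gene_model(
    "g2", "chr1", "+", rbind(c(1001, 1100), c(1201, 1300)))))
  recs <- data.frame(
    qname = c("frag1", "frag1", "x", "y"),
    flag = c(99L, 147L, 0L, 0L),
    chrom = "chr1", pos = c(11, 231, 41, 1011),
    cigar = c("40M", "40M", "30M", "30M"))
  sam1 <- withr::local_tempfile(fileext = ".sam")
  sam2 <- withr::local_tempfile(fileext = ".sam")
  write_sam(sam1, recs)
  write_sam(sam2, recs[c(3, 1, 4, 2), ])
  sc1 <- count_sample(stream_alignments(sam1), models, "s")
  sc2 <- count_sample(stream_alignments(sam2), models, "s")
  expect_equal(sc1$gene_reads, sc2$gene_reads)
  expect_equal(sc1$exon_depth, sc2$exon_depth)
  expect_equal(sc1$junction_reads, sc2$junction_reads)
  # both mates of frag1 hit g1, yet it counts once
  expect_equal(sc1$gene_reads[["g1"]], 2) # frag1 + x
  expect_equal(sc1$library_size, 3)
})

test_that("a read overlapping two genes counts for both but is not 'unique'", {
  models <- gene_model_set(list(
    gene_model("a", "chr1", "+", cbind(1, 200)),
    gene_model("b", "chr1", "-", cbind(150, 400))))
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(sam, data.frame(qname = c("both", "only_a"), chrom = "chr1",
                            pos = c(141, 11), cigar = "20M"))
  sc <- count_sample(stream_alignments(sam), models)
  expect_equal(sc$gene_reads[["a"]], 2)
  expect_equal(sc$gene_reads[["b"]], 1)
  expect_equal(sc$unique_gene_reads[["a"]], 1)
  expect_equal(sc$unique_gene_reads[["b"]], 0)
})

test_that("depth conservation: sum(depth x length) equals aligned bases in features", {
  models <- gen_models(8, seed = 31)
  sam <- withr::local_tempfile(fileext = ".sam")
  reads <- simulate_sam(models, sam)
  sc <- count_sample(stream_alignments(sam), models)
  got <- sum(sc$exon_depth$depth * feature_table(models, "exons")$width) +
    sum(sc$intron_depth$depth * feature_table(models, "introns")$width)
  # oracle: expand each read's blocks from its CIGAR and intersect with
  # feature intervals by plain interval arithmetic
  feat <- rbind(feature_table(models, "exons"), feature_table(models, "introns"))
  expected <- 0
  for (i in seq_len(nrow(reads))) {
    ops <- regmatches(reads$cigar[i], gregexpr("[0-9]+[A-Z]", reads$cigar[i]))[[1L]]
    pos <- reads$pos[i]
    for (op in ops) {
      w <- as.integer(sub("[A-Z]", "", op))
      if (grepl("M", op)) {
        f <- feat[feat$chrom == reads$chrom[i], ]
        expected <- expected +
          sum(pmax(0, pmin(f$end, pos + w - 1) - pmax(f$start, pos) + 1))
      }
      pos <- pos + w
    }
  }
  expect_equal(got, expected)
})

test_that("TSV round trip reproduces sample counts", {
  models <- gen_models(6, seed = 9)
  sim <- simulate_counts(models, simulation_design(n_replicates = 1, seed = 5))
  sc <- sim$wt[[1]]
  dir <- withr::local_tempdir()
  write_sample_counts(sc, dir)
  back <- read_sample_counts(dir)
  expect_equal(back$gene_reads[names(sc$gene_reads)], sc$gene_reads)
  expect_equal(back$library_size, sc$library_size)
  expect_equal(data.frame(back$intron_depth), data.frame(sc$intron_depth))
  o <- function(j) data.frame(j[order(j$gene_id, j$donor_end, j$acceptor_start), ])
  expect_equal(o(back$junction_reads), o(sc$junction_reads),
               ignore_attr = TRUE)
})
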