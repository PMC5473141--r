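# In-code fixtures: no data files, everything constructed at test time.

# A minimal two-exon plus-strand gene: intron (101, 200), junction (100, 201).
two_exon_model <- function(id = "g1", strand = "+") {
  gene_model(id, "chr1", strand, rbind(c(1, 100), c(201, 300)))
}

# Three exons: introns (101,200) and (301,400); skip junction (100, 401).
three_exon_model <- function(id = "g1", strand = "+") {
  gene_model(id, "chr1", strand, rbind(c(1, 100), c(201, 300), c(401, 500)))
}

# Hand-assembled sample_counts against a model set.
manual_sc <- function(models, sample_id = "s",
                      exon_depth = NULL, intron_depth = NULL,
                      junctions = NULL, boundaries = NULL,
                      gene_reads = NULL, unique_gene_reads = NULL,
                      library_size = NULL) {
  ids <- names(models$models)
  if (is.null(gene_reads)) gene_reads <- stats::setNames(rep(1000, length(ids)), ids)
  if (is.null(unique_gene_reads)) unique_gene_reads <- gene_reads
  empty_d <- data.table::data.table(gene_id = character(0), index = integer(0),
                                    depth = numeric(0))
  empty_j <- data.table::data.table(gene_id = character(0), chrom = character(0),
                                    donor_end = numeric(0), acceptor_start = numeric(0),
                                    count = numeric(0), annotated = logical(0),
                                    intron_index = integer(0))
  empty_b <- data.table::data.table(gene_id = character(0), intron_index = integer(0),
                                    side = character(0), count = numeric(0))
  sample_counts(sample_id = sample_id, gene_reads = gene_reads,
                unique_gene_reads = unique_gene_reads,
                exon_depth = exon_depth %||% empty_d,
                intron_depth = intron_depth %||% empty_d,
                junction_reads = junctions %||% empty_j,
                boundary_reads = boundaries %||% empty_b,
                library_size = library_size %||% max(gene_reads))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Replicated intron-retention fixture: one two-exon gene, exon depth
# `exon_d`, intron depths per genotype. Returns list(wt=, mut=, models=).
ir_fixture <- function(wt_intron, mut_intron, exon_d = 100, n_rep = 5) {
  models <- gene_model_set(list(two_exon_model()))
  mk <- function(intron_d, id) manual_sc(
    models, id,
    exon_depth = data.table::data.table(gene_id = "g1", index = 1:2,
                                        depth = rep(exon_d, 2)),
    intron_depth = data.table::data.table(gene_id = "g1", index = 1L,
                                          depth = intron_d))
  list(models = models,
       wt = lapply(seq_len(n_rep), function(i) mk(wt_intron, paste0("wt_", i))),
       mut = lapply(seq_len(n_rep), function(i) mk(mut_intron, paste0("mut_", i))))
}

# Independent hypergeometric-enumeration oracle for the two-sided Fisher
# test, written from choose() ratios (no dhyper), used to check fisher2x2.
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; c2 <- b + d; n <- a + b + c + d
  if (r1 == 0 || c1 == 0 || c2 == 0 || c + d == 0) return(1)
  lo <- max(0, r1 - c2); hi <- min(r1, c1)
  x <- lo:hi
  probs <- choose(c1, x) * choose(c2, r1 - x) / choose(n, r1)
  min(1, sum(probs[probs <= probs[a - lo + 1] * (1 + 1e-7)]))
}

# Write a SAM file from a record table (qname, chrom, pos, cigar [, extra]).
write_sam <- function(path, records, sq = c(chr1 = 10000),
                      header = TRUE) {
  lines <- character(0)
  if (header)
    lines <- c("@HD\tVN:1.6", sprintf("@SQ\tSN:%s\tLN:%d", names(sq),
                                      as.integer(sq)))
  qlen <- vapply(records$cigar, function(cg) {
    ops <- regmatches(cg, gregexpr("[0-9]+[A-Z]", cg))[[1L]]
    sum(as.integer(sub("[A-Z]", "", ops[grepl("M|I|S|=|X", ops)])))
  }, numeric(1))
  extra <- records$extra %||% rep("NM:i:0", nrow(records))
  flag <- records$flag %||% rep(0L, nrow(records))
  mapq <- records$mapq %||% rep(255L, nrow(records))
  lines <- c(lines, sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*\t%s",
                            records$qname, flag, records$chrom,
                            as.integer(records$pos), mapq, records$cigar,
                            strrep("A", qlen), extra))
  writeLines(lines, path)
  path
}
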