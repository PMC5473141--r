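#' Read and filter spliced alignments from SAM
#'
#' Parses a SAM file, applies the alignment-identity filter and a
#' uniqueness criterion, and returns the per-record aligned blocks and
#' inter-block gaps that all downstream counting consumes.
#'
#' Identity is computed from the `NM` tag as
#' `(aligned_bases - NM) / aligned_bases` over M/=/X CIGAR operations; when
#' `NM` is absent the record is treated as identity 1.0 (a warning is issued
#' once per file). Records flagged secondary or supplementary, and records
#' with mapping quality 0 (ambiguous best alignment), are excluded.
#' Unparseable records are skipped and counted; a SAM file without an `@SQ`
#' header line is a hard error. Paired-end mates share a query name and are
#' treated as blocks of one fragment.
#'
#' @param sam_path Path to a SAM file (text; coordinate sorting not
#'   required).
#' @param min_identity Minimum accepted alignment identity in `[0, 1]`
#'   (default 0.90).
#' @return An `aligned_reads` object: list with `blocks` (data.table:
#'   `record_id`, `qname`, `chrom`, `start`, `end`), `gaps` (data.table:
#'   `record_id`, `qname`, `chrom`, `gap_start`, `gap_end` — one row per
#'   alignment gap, i.e. candidate intron), `n_fragments` (distinct kept
#'   query names), and skip counters (`n_skipped`, `n_low_identity`,
#'   `n_nonunique`).
#' @export
stream_alignments <- function(sam_path, min_identity = 0.90) {
  stopifnot(min_identity >= 0, min_identity <= 1)
  lines <- readLines(sam_path)
  hdr <- lines[startsWith(lines, "@")]
  if (!any(startsWith(hdr, "@SQ")))
    stop("SAM file '", sam_path, "' has no @SQ header line")
  rec <- lines[!startsWith(lines, "@")]
  rec <- rec[nzchar(rec)]
  cigar_re <- "^(\\*|([0-9]+[MIDNSHP=X])+)$"
  ok <- vapply(strsplit(rec, "\t", fixed = TRUE), function(f) {
    length(f) >= 11L && !is.na(suppressWarnings(as.integer(f[4L]))) &&
      grepl(cigar_re, f[6L])
  }, logical(1))
  n_skipped <- sum(!ok)
  tmp_sam <- tempfile(fileext = ".sam")
  writeLines(c(hdr, rec[ok]), tmp_sam)
  tmp_bam <- suppressMessages(Rsamtools::asBam(
    tmp_sam, tempfile(), overwrite = TRUE, indexDestination = FALSE))
  on.exit(unlink(c(tmp_sam, tmp_bam)), add = TRUE)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "mapq"), tag = "NM",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE))
  gal <- GenomicAlignments::readGAlignments(tmp_bam, param = param)
  mc <- S4Vectors::mcols(gal)
  nm <- mc$NM
  if (is.null(nm)) nm <- rep(NA_integer_, length(gal))
  if (length(gal) && anyNA(nm))
    warning("NM tag missing for ", sum(is.na(nm)),
            " record(s); treating identity as 1.0")
  aligned <- GenomicAlignments::cigarWidthAlongQuerySpace(
    GenomicAlignments::cigar(gal), after.soft.clipping = TRUE)
  identity <- ifelse(is.na(nm), 1, pmax(0, (aligned - nm) / aligned))
  unique_ok <- is.na(mc$mapq) | mc$mapq > 0L
  n_nonunique <- sum(!unique_ok)
  keep <- identity >= min_identity & unique_ok
  n_low_identity <- sum(!keep & unique_ok)
  gal <- gal[keep]
  mc <- S4Vectors::mcols(gal)
  blk <- GenomicAlignments::grglist(gal) # blocks split at N gaps
  nb <- S4Vectors::elementNROWS(blk)
  fblk <- unlist(blk, use.names = FALSE)
  blocks <- data.table::data.table(
    record_id = rep(seq_along(gal), nb),
    qname = rep(mc$qname, nb),
    chrom = as.character(GenomicRanges::seqnames(fblk)),
    start = GenomicRanges::start(fblk),
    end = GenomicRanges::end(fblk))
  gaps <- blocks[, if (.N > 1L)
    list(qname = qname[1L], chrom = chrom[1L],
         gap_start = end[-.N] + 1L, gap_end = start[-1L] - 1L),
    by = "record_id"]
  if (!nrow(gaps))
    gaps <- data.table::data.table(record_id = integer(0), qname = character(0),
                                   chrom = character(0), gap_start = integer(0),
                                   gap_end = integer(0))
  structure(list(blocks = blocks, gaps = gaps,
                 n_fragments = length(unique(blocks$qname)),
                 n_skipped = n_skipped, n_low_identity = n_low_identity,
                 n_nonunique = n_nonunique),
            class = "aligned_reads")
}

#' @export
print.aligned_reads <- function(x, ...) {
  cat(sprintf(paste0("<aligned_reads> %d fragment(s), %d block(s), %d gap(s);",
                     " skipped %d unparseable, %d low-identity, %d non-unique\n"),
              x$n_fragments, nrow(x$blocks), nrow(x$gaps),
              x$n_skipped, x$n_low_identity, x$n_nonunique))
  invisible(x)
}

#' Flat table of exon or intron features across a model set
#'
#' @param set A `gene_model_set`.
#' @param what `"exons"` or `"introns"`.
#' @return data.table: `gene_id`, `chrom`, `index` (genomic order),
#'   `start`, `end`, `width`.
#' @export
feature_table <- function(set, what = c("exons", "introns")) {
  what <- match.arg(what)
  data.table::rbindlist(lapply(set$models, function(m) {
    f <- m[[what]]
    if (!nrow(f)) return(NULL)
    data.table::data.table(gene_id = m$gene_id, chrom = m$chrom,
                           index = seq_len(nrow(f)),
                           start = f[, 1L], end = f[, 2L],
                           width = f[, 2L] - f[, 1L] + 1)
  }))
}

.depth_by_feature <- function(blocks, feat) {
  if (!nrow(feat))
    return(data.table::data.table(gene_id = character(0), index = integer(0),
                                  depth = numeric(0)))
  bgr <- GenomicRanges::GRanges(blocks$chrom, IRanges::IRanges(blocks$start, blocks$end))
  fgr <- GenomicRanges::GRanges(feat$chrom, IRanges::IRanges(feat$start, feat$end))
  hits <- GenomicRanges::findOverlaps(fgr, bgr, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  ov <- pmin(feat$end[qh], blocks$end[sh]) - pmax(feat$start[qh], blocks$start[sh]) + 1
  bases <- rep(0, nrow(feat))
  if (length(qh)) {
    agg <- rowsum(ov, qh)
    bases[as.integer(rownames(agg))] <- agg[, 1L]
  }
  data.table::data.table(gene_id = feat$gene_id, index = feat$index,
                         depth = bases / feat$width)
}

#' Build per-sample count structures from aligned reads
#'
#' Computes, against a set of gene models: per-gene fragment counts and
#' unique (single-gene) fragment counts; average read depth of every exon
#' and intron (aligned bases overlapping the feature divided by feature
#' length); splice-junction read counts, where a fragment supports a
#' junction iff one of its alignment gaps matches the intron coordinates
#' exactly (observed non-annotated gaps are retained and, when they share a
#' donor or acceptor with an annotated intron, attached to it for
#' alternative splice-site testing); and exon–intron boundary-spanning
#' counts (a single aligned block contiguously covering `anchor` bases on
#' each side of the boundary), the evidence used for unspliced transcripts.
#'
#' @param reads An `aligned_reads` object from [stream_alignments()].
#' @param models A `gene_model_set`.
#' @param sample_id Sample label stored in the result.
#' @param anchor Boundary anchor width in nt on each side (default 8).
#' @return A `sample_counts` object; see [sample_counts()].
#' @export
count_sample <- function(reads, models, sample_id = "sample", anchor = 8L) {
  blocks <- reads$blocks
  exf <- feature_table(models, "exons")
  inf <- feature_table(models, "introns")
  # gene (fragment) counts: any block overlapping the gene span
  bgr <- GenomicRanges::GRanges(blocks$chrom, IRanges::IRanges(blocks$start, blocks$end))
  hits <- GenomicRanges::findOverlaps(bgr, models$ranges, ignore.strand = TRUE)
  gene_of_hit <- models$ranges$gene_id[S4Vectors::subjectHits(hits)]
  qn <- blocks$qname[S4Vectors::queryHits(hits)]
  fg <- unique(data.table::data.table(qname = qn, gene_id = gene_of_hit))
  gene_id <- qname <- NULL # data.table NSE
  gene_reads <- fg[, list(count = .N), by = "gene_id"]
  ngenes <- fg[, list(n = data.table::uniqueN(gene_id)), by = "qname"]
  uni <- fg[fg$qname %in% ngenes$qname[ngenes$n == 1L]][, list(count = .N), by = "gene_id"]
  all_ids <- names(models$models)
  gr_vec <- stats::setNames(rep(0, length(all_ids)), all_ids)
  gr_vec[gene_reads$gene_id] <- gene_reads$count
  ur_vec <- stats::setNames(rep(0, length(all_ids)), all_ids)
  ur_vec[uni$gene_id] <- uni$count
  # depths
  exon_depth <- .depth_by_feature(blocks, exf)
  intron_depth <- .depth_by_feature(blocks, inf)
  # junctions: aggregate observed gaps per fragment (a fragment counts once)
  gaps <- unique(reads$gaps[, c("qname", "chrom", "gap_start", "gap_end")])
  obs <- gaps[, list(count = .N), by = c("chrom", "gap_start", "gap_end")]
  ann <- if (nrow(inf))
    data.table::data.table(chrom = inf$chrom, gap_start = inf$start,
                           gap_end = inf$end, ann_gene = inf$gene_id,
                           ann_index = inf$index)
  else data.table::data.table(chrom = character(0), gap_start = numeric(0),
                              gap_end = numeric(0), ann_gene = character(0),
                              ann_index = integer(0))
  jx <- merge(obs, ann, by = c("chrom", "gap_start", "gap_end"), all.x = TRUE)
  jx$annotated <- !is.na(jx$ann_gene)
  # attach non-annotated gaps sharing a donor or an acceptor with an intron
  if (any(!jx$annotated) && nrow(ann)) {
    un <- which(!jx$annotated)
    key_d <- paste(jx$chrom[un], jx$gap_start[un])
    map_d <- ann[!duplicated(paste(ann$chrom, ann$gap_start))]
    md <- match(key_d, paste(map_d$chrom, map_d$gap_start))
    key_a <- paste(jx$chrom[un], jx$gap_end[un])
    map_a <- ann[!duplicated(paste(ann$chrom, ann$gap_end))]
    ma <- match(key_a, paste(map_a$chrom, map_a$gap_end))
    jx$ann_gene[un] <- ifelse(!is.na(md), map_d$ann_gene[md],
                              ifelse(!is.na(ma), map_a$ann_gene[ma], NA))
    jx$ann_index[un] <- ifelse(!is.na(md), map_d$ann_index[md],
                               ifelse(!is.na(ma), map_a$ann_index[ma], NA))
  }
  junction_reads <- data.table::data.table(
    gene_id = jx$ann_gene, chrom = jx$chrom,
    donor_end = jx$gap_start - 1, acceptor_start = jx$gap_end + 1,
    count = jx$count, annotated = jx$annotated, intron_index = jx$ann_index)
  # boundary-spanning fragments: one block covering [b-a+1, b+a] (5p) or
  # [b-a, b+a-1] (3p), b = donor_end / acceptor_start
  boundary_reads <- data.table::data.table(
    gene_id = character(0), intron_index = integer(0), side = character(0),
    count = numeric(0))
  if (nrow(inf)) {
    win <- data.table::rbindlist(list(
      data.table::data.table(gene_id = inf$gene_id, intron_index = inf$index,
                             side = "5p", chrom = inf$chrom,
                             start = inf$start - anchor, end = inf$start + anchor - 1),
      data.table::data.table(gene_id = inf$gene_id, intron_index = inf$index,
                             side = "3p", chrom = inf$chrom,
                             start = inf$end - anchor + 1, end = inf$end + anchor)))
    wgr <- GenomicRanges::GRanges(win$chrom, IRanges::IRanges(win$start, win$end))
    wh <- GenomicRanges::findOverlaps(wgr, bgr, type = "within", ignore.strand = TRUE)
    cnt <- rep(0, nrow(win))
    if (length(wh)) {
      dt <- unique(data.table::data.table(
        w = S4Vectors::queryHits(wh),
        qname = blocks$qname[S4Vectors::subjectHits(wh)]))
      agg <- dt[, list(n = .N), by = "w"]
      cnt[agg$w] <- agg$n
    }
    win$count <- cnt
    boundary_reads <- win[win$count > 0,
                          c("gene_id", "intron_index", "side", "count")]
  }
  sample_counts(sample_id = sample_id, gene_reads = gr_vec,
                unique_gene_reads = ur_vec, exon_depth = exon_depth,
                intron_depth = intron_depth, junction_reads = junction_reads,
                boundary_reads = boundary_reads,
                library_size = reads$n_fragments)
}

#' Per-sample count container
#'
#' The structure every statistic in the pipeline consumes, whether produced
#' from spliced alignments ([count_sample()]), loaded from TSV tables
#' ([read_sample_counts()]) or simulated ([simulate_counts()]).
#'
#' @param sample_id Sample label.
#' @param gene_reads Named numeric: fragments per gene (a fragment counts
#'   toward every gene it overlaps).
#' @param unique_gene_reads Named numeric: fragments attributable to exactly
#'   one gene — the gene-level denominator in the Fisher confirmation test.
#' @param exon_depth,intron_depth data.tables (`gene_id`, `index`, `depth`)
#'   of average feature depths.
#' @param junction_reads data.table (`gene_id`, `chrom`, `donor_end`,
#'   `acceptor_start`, `count`, `annotated`, `intron_index`).
#' @param boundary_reads data.table (`gene_id`, `intron_index`, `side`
#'   `("5p"/"3p")`, `count`) of exon–intron boundary-spanning fragments.
#' @param library_size Total counted fragments.
#' @return A `sample_counts` object.
#' @export
sample_counts <- function(sample_id, gene_reads, unique_gene_reads = gene_reads,
                          exon_depth, intron_depth, junction_reads,
                          boundary_reads, library_size) {
  stopifnot(all(gene_reads >= 0), all(exon_depth$depth >= 0),
            all(intron_depth$depth >= 0), all(junction_reads$count >= 0),
            library_size >= if (length(gene_reads)) max(gene_reads) else 0)
  if (is.null(junction_reads$chrom)) junction_reads$chrom <- NA_character_
  structure(list(sample_id = sample_id, gene_reads = gene_reads,
                 unique_gene_reads = unique_gene_reads,
                 exon_depth = data.table::as.data.table(exon_depth),
                 intron_depth = data.table::as.data.table(intron_depth),
                 junction_reads = data.table::as.data.table(junction_reads),
                 boundary_reads = data.table::as.data.table(boundary_reads),
                 library_size = library_size),
            class = "sample_counts")
}

#' @export
print.sample_counts <- function(x, ...) {
  cat(sprintf("<sample_counts> %s: %d gene(s), library size %.0f, %d junction record(s)\n",
              x$sample_id, length(x$gene_reads), x$library_size,
              nrow(x$junction_reads)))
  invisible(x)
}

#' Write / read the TSV form of sample counts
#'
#' Five flat tables per sample under `dir`: `genes.tsv` (gene_id, reads,
#' unique_reads), `exon_depth.tsv`, `intron_depth.tsv`, `junctions.tsv`,
#' `boundaries.tsv`, plus `library.tsv`. These files are also a direct input
#' path into the pipeline, bypassing SAM entirely.
#'
#' @param sc A `sample_counts`.
#' @param dir Output directory (created if needed).
#' @return `dir` invisibly (write) / a `sample_counts` (read).
#' @export
write_sample_counts <- function(sc, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fw <- function(x, f) data.table::fwrite(x, file.path(dir, f), sep = "\t")
  fw(data.table::data.table(gene_id = names(sc$gene_reads),
                            reads = as.numeric(sc$gene_reads),
                            unique_reads = as.numeric(
                              sc$unique_gene_reads[names(sc$gene_reads)])),
     "genes.tsv")
  fw(sc$exon_depth, "exon_depth.tsv")
  fw(sc$intron_depth, "intron_depth.tsv")
  fw(sc$junction_reads, "junctions.tsv")
  fw(sc$boundary_reads, "boundaries.tsv")
  fw(data.table::data.table(sample_id = sc$sample_id,
                            library_size = sc$library_size), "library.tsv")
  invisible(dir)
}

#' @rdname write_sample_counts
#' @param sample_id Optional override of the stored sample id.
#' @export
read_sample_counts <- function(dir, sample_id = NULL) {
  fr <- function(f) data.table::fread(file.path(dir, f), sep = "\t")
  g <- fr("genes.tsv")
  lib <- fr("library.tsv")
  jx <- fr("junctions.tsv")
  if (nrow(jx)) {
    jx$gene_id <- as.character(jx$gene_id)
    jx$gene_id[jx$gene_id == ""] <- NA_character_
  }
  sample_counts(
    sample_id = if (is.null(sample_id)) lib$sample_id[1L] else sample_id,
    gene_reads = stats::setNames(g$reads, g$gene_id),
    unique_gene_reads = stats::setNames(g$unique_reads, g$gene_id),
    exon_depth = fr("exon_depth.tsv"), intron_depth = fr("intron_depth.tsv"),
    junction_reads = jx, boundary_reads = fr("boundaries.tsv"),
    library_size = lib$library_size[1L])
}
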