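#' Gene model: one exon/intron chain per gene
#'
#' A `gene_model` holds a single representative exon chain for one gene,
#' with introns derived as the gaps between consecutive exons. All
#' coordinates are 1-based inclusive genomic positions (GFF3 convention).
#'
#' @param gene_id Gene identifier (unique within a set).
#' @param chrom Chromosome / sequence name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix or data.frame of exon `(start, end)`
#'   intervals; may be unsorted, duplicates are merged.
#' @return An object of class `gene_model` with fields `gene_id`, `chrom`,
#'   `strand`, `exons` (sorted matrix), `introns` (matrix, 0 rows for
#'   single-exon genes) and `length_nt` (sum of exon widths).
#' @examples
#' gm <- gene_model("g1", "chr1", "+", rbind(c(1, 100), c(201, 300)))
#' gm$introns  # one intron (101, 200)
#' @export
gene_model <- function(gene_id, chrom, strand, exons) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L,
            strand %in% c("+", "-"))
  ex <- as.matrix(exons)
  storage.mode(ex) <- "double"
  if (ncol(ex) != 2L || nrow(ex) < 1L)
    stop("exons must be a non-empty 2-column (start, end) table")
  if (any(ex[, 2L] < ex[, 1L]))
    stop("malformed exon coordinates (end < start) in gene ", gene_id)
  ex <- unique(ex)
  ex <- ex[order(ex[, 1L], ex[, 2L]), , drop = FALSE]
  if (nrow(ex) > 1L && any(ex[-1L, 1L] <= ex[-nrow(ex), 2L]))
    stop("overlapping exons in gene ", gene_id)
  dimnames(ex) <- list(NULL, c("start", "end"))
  n <- nrow(ex)
  if (n > 1L) {
    introns <- cbind(start = ex[-n, 2L] + 1, end = ex[-1L, 1L] - 1)
  } else {
    introns <- matrix(numeric(0), 0L, 2L, dimnames = list(NULL, c("start", "end")))
  }
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 exons = ex, introns = introns,
                 length_nt = sum(ex[, 2L] - ex[, 1L] + 1)),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%d-%d (%s), %d exon(s), %d intron(s), %d nt\n",
              x$gene_id, x$chrom, x$exons[1L, 1L], x$exons[nrow(x$exons), 2L],
              x$strand, nrow(x$exons), nrow(x$introns), x$length_nt))
  invisible(x)
}

#' Number of exons / introns of a gene model
#' @param model A `gene_model`.
#' @return Integer count.
#' @export
n_exons <- function(model) nrow(model$exons)

#' @rdname n_exons
#' @export
n_introns <- function(model) nrow(model$introns)

#' Map between genomic and transcription-order feature indices
#'
#' Exon and intron indices are stored in genomic order (left to right).
#' Reporting uses transcription order: identical on `+` genes, reversed on
#' `-` genes.
#'
#' @param model A `gene_model`.
#' @param genomic_index Index in genomic order.
#' @param type `"intron"` or `"exon"`.
#' @return The index in transcription order.
#' @export
tx_order_index <- function(model, genomic_index, type = c("intron", "exon")) {
  type <- match.arg(type)
  n <- if (type == "intron") n_introns(model) else n_exons(model)
  stopifnot(all(genomic_index >= 1L), all(genomic_index <= n))
  if (model$strand == "+") genomic_index else n + 1L - genomic_index
}

#' Collection of gene models with an interval index
#'
#' @param models List of `gene_model` objects (gene_ids must be unique).
#' @return A `gene_model_set`: list with `models` (named list) and `ranges`
#'   (a [GenomicRanges::GRanges] of gene spans used for overlap queries).
#' @export
gene_model_set <- function(models) {
  ids <- vapply(models, function(m) m$gene_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate gene_ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(models) <- ids
  ranges <- GenomicRanges::GRanges(
    seqnames = vapply(models, function(m) m$chrom, character(1)),
    ranges = IRanges::IRanges(
      start = vapply(models, function(m) m$exons[1L, 1L], numeric(1)),
      end = vapply(models, function(m) m$exons[nrow(m$exons), 2L], numeric(1))),
    strand = vapply(models, function(m) m$strand, character(1)),
    gene_id = ids)
  structure(list(models = models, ranges = ranges), class = "gene_model_set")
}

#' @export
print.gene_model_set <- function(x, ...) {
  cat(sprintf("<gene_model_set> %d gene model(s) on %d sequence(s)\n",
              length(x$models),
              length(unique(as.character(GenomicRanges::seqnames(x$ranges))))))
  invisible(x)
}

#' @export
`[[.gene_model_set` <- function(x, i) x$models[[i]]

#' @export
length.gene_model_set <- function(x) length(x$models)

#' Gene models overlapping a genomic interval
#'
#' @param set A `gene_model_set`.
#' @param chrom Sequence name.
#' @param start,end Query interval (1-based inclusive).
#' @return Named list of overlapping `gene_model`s (possibly empty).
#' @export
models_overlapping <- function(set, chrom, start, end) {
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  hits <- GenomicRanges::findOverlaps(q, set$ranges, ignore.strand = TRUE)
  set$models[S4Vectors::subjectHits(hits)]
}

#' Parse a GFF3 annotation into gene models
#'
#' Reads `gene`, `mRNA`/`transcript` and `exon` features. When a gene has
#' several transcripts, one representative exon chain is chosen
#' (`transcript_choice`): the per-intron depth statistics downstream
#' presuppose a single exon/intron chain per gene. Exons parented directly
#' to a gene are accepted too. Genes whose chosen exon chain contains
#' overlapping exons are rejected with a diagnostic (kept in
#' `attr(, "rejected_genes")`); exon records without a resolvable parent are
#' dropped (counted in `attr(, "rejected_records")`); `end < start` anywhere
#' is a hard error.
#'
#' @param path Path to a GFF3 file.
#' @param transcript_choice `"longest"` (default; maximal summed exon
#'   length, ties broken by transcript id) or `"first"` (lexicographically
#'   first transcript id).
#' @return A `gene_model_set`.
#' @export
parse_gene_models <- function(path, transcript_choice = c("longest", "first")) {
  transcript_choice <- match.arg(transcript_choice)
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("malformed GFF3 '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  typ <- tolower(as.character(gr$type))
  genes <- gr[typ == "gene"]
  gene_ids <- as.character(genes$ID)
  tx <- gr[typ %in% c("mrna", "transcript")]
  tx_parent <- vapply(tx$Parent, function(p) if (length(p)) p[[1L]] else NA_character_,
                      character(1))
  tx2gene <- stats::setNames(tx_parent, as.character(tx$ID))
  ex <- gr[typ == "exon"]
  n_bad_records <- 0L
  rows <- vector("list", length(ex))
  if (length(ex)) {
    ex_parent <- vapply(ex$Parent, function(p) if (length(p)) p[[1L]] else NA_character_,
                        character(1))
    for (i in seq_along(ex)) {
      p <- ex_parent[i]
      if (is.na(p)) { n_bad_records <- n_bad_records + 1L; next }
      if (p %in% names(tx2gene)) {
        g <- tx2gene[[p]]; t <- p
      } else if (p %in% gene_ids) {
        g <- p; t <- paste0(p, ".chain")
      } else { n_bad_records <- n_bad_records + 1L; next }
      rows[[i]] <- data.table::data.table(
        gene = g, tx = t,
        chrom = as.character(GenomicRanges::seqnames(ex)[i]),
        strand = as.character(GenomicRanges::strand(ex)[i]),
        start = GenomicRanges::start(ex)[i], end = GenomicRanges::end(ex)[i])
    }
  }
  extab <- data.table::rbindlist(rows)
  models <- list()
  rejected <- character(0)
  if (nrow(extab)) {
    start <- end <- tx <- NULL # data.table NSE
    for (g in unique(extab$gene)) {
      sub <- extab[extab$gene == g]
      len <- sub[, list(L = sum(end - start + 1)), by = tx]
      pick <- if (transcript_choice == "longest")
        len$tx[order(-len$L, len$tx)][1L] else sort(len$tx)[1L]
      chain <- sub[sub$tx == pick]
      m <- tryCatch(
        gene_model(g, chain$chrom[1L],
                   if (chain$strand[1L] %in% c("+", "-")) chain$strand[1L] else "+",
                   cbind(chain$start, chain$end)),
        error = function(e) e)
      if (inherits(m, "error")) {
        if (grepl("end < start", conditionMessage(m)))
          stop(conditionMessage(m), call. = FALSE)
        message("rejecting gene ", g, ": ", conditionMessage(m))
        rejected <- c(rejected, g)
      } else models[[g]] <- m
    }
  }
  set <- gene_model_set(models)
  attr(set, "rejected_genes") <- rejected
  attr(set, "rejected_records") <- n_bad_records
  set
}

#' Write gene models as GFF3
#'
#' Emits one `gene`, one `mRNA` and its `exon` features per model, in a form
#' that [parse_gene_models()] reads back to identical models (round-trip).
#'
#' @param set A `gene_model_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gene_models_gff3 <- function(set, path) {
  rows <- lapply(set$models, function(m) {
    n <- nrow(m$exons)
    data.frame(
      chrom = m$chrom,
      start = c(m$exons[1L, 1L], m$exons[1L, 1L], m$exons[, 1L]),
      end = c(m$exons[n, 2L], m$exons[n, 2L], m$exons[, 2L]),
      strand = m$strand,
      type = c("gene", "mRNA", rep("exon", n)),
      ID = c(m$gene_id, paste0(m$gene_id, ".1"),
             paste0(m$gene_id, ".1.exon", seq_len(n))),
      Parent = c(NA_character_, m$gene_id, rep(paste0(m$gene_id, ".1"), n)))
  })
  tab <- do.call(rbind, unname(rows))
  gr <- GenomicRanges::GRanges(
    seqnames = tab$chrom, ranges = IRanges::IRanges(tab$start, tab$end),
    strand = tab$strand, type = tab$type, ID = tab$ID, Parent = tab$Parent)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write a flat audit table of gene models
#'
#' @param set A `gene_model_set`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_gene_models_tsv <- function(set, path) {
  fmt <- function(m) paste(sprintf("%d-%d", as.integer(m[, 1L]), as.integer(m[, 2L])),
                           collapse = ";")
  dt <- data.table::rbindlist(lapply(set$models, function(m)
    data.table::data.table(gene_id = m$gene_id, chrom = m$chrom, strand = m$strand,
                           length_nt = m$length_nt,
                           exons = fmt(m$exons),
                           introns = if (nrow(m$introns)) fmt(m$introns) else "")))
  data.table::fwrite(dt[order(dt$gene_id)], path, sep = "\t")
  invisible(path)
}

#' Canonical (and optionally skip) junction keys of a gene model
#'
#' A junction key is `(donor_end, acceptor_start)`: the last base of the
#' upstream exon and the first base of the downstream exon. With
#' `include_skip = TRUE`, the exon-skipping junction of every internal exon
#' (upstream flanking exon's donor joined to the downstream flanking exon's
#' acceptor) is appended with `kind = "skip"`.
#'
#' @param model A `gene_model`.
#' @param include_skip Also enumerate skip junctions for internal exons.
#' @return A [data.table::data.table] with columns `gene_id`, `donor_end`,
#'   `acceptor_start`, `kind` (`"intron"` / `"skip"`), `index` (genomic
#'   intron index, or the skipped exon's genomic index for skip keys).
#' @export
derive_junctions <- function(model, include_skip = FALSE) {
  ni <- n_introns(model)
  out <- list()
  if (ni > 0L)
    out$intron <- data.table::data.table(
      gene_id = model$gene_id,
      donor_end = model$introns[, 1L] - 1,
      acceptor_start = model$introns[, 2L] + 1,
      kind = "intron", index = seq_len(ni))
  if (include_skip && n_exons(model) >= 3L) {
    idx <- 2:(n_exons(model) - 1L)
    out$skip <- data.table::data.table(
      gene_id = model$gene_id,
      donor_end = model$exons[idx - 1L, 2L],
      acceptor_start = model$exons[idx + 1L, 1L],
      kind = "skip", index = idx)
  }
  if (!length(out))
    return(data.table::data.table(gene_id = character(0), donor_end = numeric(0),
                                  acceptor_start = numeric(0), kind = character(0),
                                  index = integer(0)))
  data.table::rbindlist(out)
}

#' Junction keys for every model in a set
#' @param set A `gene_model_set`.
#' @inheritParams derive_junctions
#' @return Row-bound [derive_junctions()] output over all models.
#' @export
all_junctions <- function(set, include_skip = FALSE) {
  data.table::rbindlist(lapply(set$models, derive_junctions,
                               include_skip = include_skip))
}
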