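#' Model of the three-variant reporter locus
#'
#' The reporter carries a canonical GT–AG intron nested strictly inside a
#' noncanonical (U2-type) AT–AC intron. The two introns' 3' splice sites
#' are separated by exactly 3 nt, with the AC acceptor on the outside, so a
#' spliced read can support at most one of the two junctions. Three major
#' transcripts result: unspliced (long), GT–AG-spliced (middle), and
#' AT–AC-spliced (short, the only translatable one).
#'
#' @param chrom Sequence name.
#' @param outer `(start, end)` of the AT–AC intron (1-based inclusive).
#' @param inner `(start, end)` of the GT–AG intron; must lie strictly
#'   inside `outer` with `outer[2] == inner[2] + 3`.
#' @param gene_id Identifier used for the reporter's junction records.
#' @return A `reporter_model`.
#' @export
reporter_model <- function(chrom, outer, inner, gene_id = "reporter") {
  stopifnot(length(outer) == 2L, length(inner) == 2L,
            outer[1L] < outer[2L], inner[1L] < inner[2L])
  if (!(inner[1L] > outer[1L] && inner[2L] < outer[2L]))
    stop("inner (GT-AG) intron must lie strictly inside the outer (AT-AC) intron")
  if (outer[2L] - inner[2L] != 3L)
    stop("the two 3' splice sites must be exactly 3 nt apart (AC outside)")
  structure(list(gene_id = gene_id, chrom = chrom,
                 outer = as.numeric(outer), inner = as.numeric(inner)),
            class = "reporter_model")
}

#' @export
print.reporter_model <- function(x, ...) {
  cat(sprintf("<reporter_model> %s %s: AT-AC intron %d-%d, nested GT-AG intron %d-%d\n",
              x$gene_id, x$chrom, x$outer[1L], x$outer[2L],
              x$inner[1L], x$inner[2L]))
  invisible(x)
}

#' Quantify the three reporter splice variants in one sample
#'
#' Junction reads whose gap matches the outer AT–AC intron exactly count
#' the translatable short variant; reads matching the inner GT–AG intron
#' count the middle variant; reads contiguously spanning the shared 5'
#' exon–intron boundary of the outer intron count the unspliced variant
#' (one boundary only, so long reads are not double-counted;
#' `use_both_boundaries = TRUE` averages the 5' and 3' boundary counts
#' instead). Because the 3' splice sites differ by 3 nt, the two junction
#' classes are disjoint. No length normalization is applied: junction and
#' boundary anchors have the same width, so raw counts are comparable.
#'
#' @param counts A `sample_counts` whose junction/boundary tables cover the
#'   reporter (zero counts are allowed, an entirely uncovered reporter is an
#'   error).
#' @param model A `reporter_model`.
#' @param use_both_boundaries Average the two outer-intron boundaries for
#'   the unspliced count instead of using the 5' boundary only.
#' @return A `reporter_quant`: list with `sample_id`, `counts` (named:
#'   `unspliced`, `gtag`, `atac`) and `proportions` (summing to 1).
#' @export
quantify_reporter <- function(counts, model, use_both_boundaries = FALSE) {
  jx <- counts$junction_reads
  pick <- function(iv) {
    hit <- jx$donor_end == iv[1L] - 1 & jx$acceptor_start == iv[2L] + 1 &
      (is.na(jx$gene_id) | jx$gene_id == model$gene_id)
    if (!is.null(jx$chrom)) hit <- hit & (is.na(jx$chrom) | jx$chrom == model$chrom)
    sum(jx$count[hit])
  }
  n_atac <- pick(model$outer)
  n_gtag <- pick(model$inner)
  bx <- counts$boundary_reads
  bnd <- function(side) {
    hit <- bx$gene_id == model$gene_id & bx$intron_index == 1L & bx$side == side
    sum(bx$count[hit])
  }
  n_unspliced <- if (use_both_boundaries) (bnd("5p") + bnd("3p")) / 2 else bnd("5p")
  tot <- n_unspliced + n_gtag + n_atac
  if (tot == 0) stop("reporter not covered in sample ", counts$sample_id)
  cnt <- c(unspliced = n_unspliced, gtag = n_gtag, atac = n_atac)
  structure(list(sample_id = counts$sample_id, counts = cnt,
                 proportions = cnt / tot),
            class = "reporter_quant")
}

#' @export
print.reporter_quant <- function(x, ...) {
  cat(sprintf("<reporter_quant> %s: unspliced %.1f%%, GT-AG %.1f%%, AT-AC %.1f%%\n",
              x$sample_id, 100 * x$proportions[1L], 100 * x$proportions[2L],
              100 * x$proportions[3L]))
  invisible(x)
}

#' Reporter quantification table for many samples
#'
#' @param quants List of `reporter_quant` objects.
#' @param path Optional TSV output path.
#' @return data.table (`sample_id`, counts and proportions per variant).
#' @export
reporter_table <- function(quants, path = NULL) {
  dt <- data.table::rbindlist(lapply(quants, function(q)
    data.table::data.table(
      sample_id = q$sample_id,
      n_unspliced = q$counts[["unspliced"]], n_gtag = q$counts[["gtag"]],
      n_atac = q$counts[["atac"]],
      p_unspliced = q$proportions[["unspliced"]],
      p_gtag = q$proportions[["gtag"]], p_atac = q$proportions[["atac"]])))
  if (!is.null(path)) data.table::fwrite(dt, path, sep = "\t")
  dt
}
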