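#' Gene-by-sample count matrix
#'
#' @param counts Non-negative integer-like matrix, genes in rows (rownames =
#'   gene ids), samples in columns.
#' @param lib_sizes Optional explicit library sizes; defaults to column
#'   sums.
#' @param gene_lengths Optional named numeric of gene lengths (nt), used by
#'   [adjusted_rpkm()].
#' @return A `count_matrix` object.
#' @export
count_matrix <- function(counts, lib_sizes = NULL, gene_lengths = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts")
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  stopifnot(length(lib_sizes) == ncol(counts))
  structure(list(counts = counts, lib_sizes = lib_sizes,
                 gene_lengths = gene_lengths),
            class = "count_matrix")
}

#' Assemble a count matrix from per-sample counts
#'
#' @param samples List of `sample_counts`.
#' @param models Optional `gene_model_set` supplying gene lengths.
#' @return A `count_matrix` (columns in the order of `samples`).
#' @export
count_matrix_from_samples <- function(samples, models = NULL) {
  ids <- names(samples[[1L]]$gene_reads)
  m <- vapply(samples, function(s) as.numeric(s$gene_reads[ids]),
              numeric(length(ids)))
  m <- matrix(m, nrow = length(ids),
              dimnames = list(ids, vapply(samples, `[[`, "", "sample_id")))
  lens <- if (!is.null(models))
    vapply(models$models[ids], function(x) x$length_nt, numeric(1))
  count_matrix(m, gene_lengths = lens)
}

# edgeR-style f75 reference selection: quantile of count/libsize
.factor_quantile <- function(counts, lib_sizes, p = 0.75) {
  apply(sweep(counts, 2L, lib_sizes, "/"), 2L, stats::quantile, probs = p)
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values (Robinson & Oshlack): per sample, the weighted
#' mean of library-size-scaled log2 ratios against a reference sample,
#' after a double trim — `trim_m` on each tail of the M-values (log
#' ratios) and `trim_a` on each tail of the A-values (average log
#' abundance) — with inverse asymptotic-variance weights. Factors are
#' rescaled to a geometric mean of 1. The reference sample is the column
#' whose 75th count-fraction percentile is closest to the mean, as in
#' standard implementations.
#'
#' @param counts A `count_matrix` (or plain matrix).
#' @param trim_m M-value trim fraction per tail (default 0.30).
#' @param trim_a A-value trim fraction per tail (default 0.05).
#' @return Numeric vector of per-sample factors, geometric mean 1.
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  cm <- if (inherits(counts, "count_matrix")) counts else count_matrix(counts)
  x <- cm$counts
  lib <- cm$lib_sizes
  if (ncol(x) < 2L) stop("TMM needs at least two samples")
  zero <- which(colSums(x) == 0)
  if (length(zero))
    stop("all-zero sample(s): ",
         paste(colnames(x)[zero] %||% zero, collapse = ", "))
  f75 <- .factor_quantile(x, lib)
  ref <- if (min(f75) < 1e-20) which.max(colSums(sqrt(x)))
         else which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(x)), function(k)
    .tmm_pair(x[, k], x[, ref], lib[k], lib[ref], trim_m, trim_a),
    numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(x)
  f
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.tmm_pair <- function(obs, ref, n_obs, n_ref, trim_m, trim_a) {
  logR <- log2((obs / n_obs) / (ref / n_ref))
  absE <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  v <- (n_obs - obs) / n_obs / obs + (n_ref - ref) / n_ref / ref
  fin <- is.finite(logR) & is.finite(absE)
  logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
  if (!length(logR) || max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * trim_m) + 1; hiL <- n + 1 - loL
  loS <- floor(n * trim_a) + 1; hiS <- n + 1 - loS
  keep <- (rank(logR) >= loL & rank(logR) <= hiL) &
          (rank(absE) >= loS & rank(absE) <= hiS)
  f <- sum(logR[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
  if (!is.finite(f)) f <- 0
  2^f
}

#' logCPM transform
#'
#' `log2((count + 0.5) / (lib_size * factor + 1) * 1e6)` — the
#' offset-stabilized log counts-per-million used ahead of linear-model
#' testing (no precision weights are computed here; only the transform).
#'
#' @param counts A `count_matrix` or plain matrix.
#' @param factors Per-sample normalization factors (default: TMM).
#' @return Real matrix of logCPM values, same dimensions as the counts.
#' @export
logcpm <- function(counts, factors = NULL) {
  cm <- if (inherits(counts, "count_matrix")) counts else count_matrix(counts)
  if (is.null(factors)) factors <- tmm_factors(cm)
  eff <- cm$lib_sizes * factors
  log2(sweep(cm$counts + 0.5, 2L, eff + 1, "/") * 1e6)
}

#' Length-adjusted logCPM (log-scale RPKM)
#'
#' Subtracts `log2(length_nt / 1000)` from each gene's logCPM, yielding a
#' log2 reads-per-kilobase-per-million scale suitable for per-gene t-tests.
#' Genes without a length are dropped with a diagnostic message.
#'
#' @param logcpm_matrix Matrix from [logcpm()] (genes in rows, rownames =
#'   gene ids).
#' @param gene_lengths Named numeric of gene lengths in nt (> 0).
#' @return Real matrix over the genes that have lengths.
#' @export
adjusted_rpkm <- function(logcpm_matrix, gene_lengths) {
  ids <- rownames(logcpm_matrix)
  len <- gene_lengths[ids]
  miss <- is.na(len) | len <= 0
  if (any(miss)) {
    message("dropping ", sum(miss), " gene(s) without a valid length")
    logcpm_matrix <- logcpm_matrix[!miss, , drop = FALSE]
    len <- len[!miss]
  }
  sweep(logcpm_matrix, 1L, log2(len / 1000), "-")
}

#' The differential-expression call rule
#'
#' A gene is called iff its t-test p-value is strictly below `alpha` AND its
#' absolute log2 fold-change is at least `min_abs_lfc` (inclusive
#' boundary).
#'
#' @param p_value,log_fc Numeric vectors.
#' @param alpha P-value threshold (default 0.01, strict).
#' @param min_abs_lfc Log2 fold-change threshold (default 0.6, inclusive).
#' @return Logical vector.
#' @export
deg_called <- function(p_value, log_fc, alpha = 0.01, min_abs_lfc = 0.6) {
  p_value < alpha & abs(log_fc) >= min_abs_lfc
}

#' Two-group differential expression by per-gene t-test
#'
#' Per gene, a two-sided t-test (Welch by default) on length-adjusted
#' logCPM values; `log_fc` is `mean(group B) - mean(group A)` on the log2
#' scale. No multiple-testing correction is applied: the call rule is the
#' raw `p < alpha` together with `|log_fc| >= min_abs_lfc`. Genes with zero
#' variance in both groups and equal means get `p = 1`.
#'
#' @param rpkm_a,rpkm_b Matrices of adjusted RPKM values (genes x
#'   replicates), same row order; `a` is the baseline (e.g. wild type).
#' @param alpha,min_abs_lfc Call thresholds (see [deg_called()]).
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @return data.table: `gene_id`, `log_fc`, `p_value`, `called`.
#' @export
call_deg <- function(rpkm_a, rpkm_b, alpha = 0.01, min_abs_lfc = 0.6,
                     var_equal = FALSE) {
  stopifnot(nrow(rpkm_a) == nrow(rpkm_b),
            ncol(rpkm_a) >= 2L, ncol(rpkm_b) >= 2L)
  p <- vapply(seq_len(nrow(rpkm_a)), function(i) {
    a <- rpkm_a[i, ]; b <- rpkm_b[i, ]
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      if (mean(a) == mean(b)) return(1)
      return(0)
    }
    stats::t.test(b, a, var.equal = var_equal)$p.value
  }, numeric(1))
  lfc <- rowMeans(rpkm_b) - rowMeans(rpkm_a)
  data.table::data.table(
    gene_id = rownames(rpkm_a) %||% as.character(seq_len(nrow(rpkm_a))),
    log_fc = lfc, p_value = p,
    called = deg_called(p, lfc, alpha, min_abs_lfc))
}

#' Count-matrix to DEG table in one step
#'
#' TMM factors, logCPM, length adjustment, then [call_deg()] between the
#' two sample groups.
#'
#' @param cm A `count_matrix` with `gene_lengths`.
#' @param group Factor/character of length `ncol`, exactly two levels; the
#'   first level is the baseline.
#' @inheritParams call_deg
#' @return data.table as in [call_deg()].
#' @export
deg_pipeline <- function(cm, group, alpha = 0.01, min_abs_lfc = 0.6,
                         var_equal = FALSE) {
  group <- as.factor(group)
  stopifnot(nlevels(group) == 2L)
  lc <- logcpm(cm, tmm_factors(cm))
  ar <- adjusted_rpkm(lc, cm$gene_lengths)
  call_deg(ar[, group == levels(group)[1L], drop = FALSE],
           ar[, group == levels(group)[2L], drop = FALSE],
           alpha = alpha, min_abs_lfc = min_abs_lfc, var_equal = var_equal)
}
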