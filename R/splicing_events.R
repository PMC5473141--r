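#' Chi-square homogeneity test on a 2x2 table
#'
#' Pearson statistic with expected values from the margins, one degree of
#' freedom, no continuity correction. Entries may be fractional (average
#' depths enter unrounded). The null is that the focal/background ratio is
#' the same in the two samples. Any zero margin means the table carries no
#' evidence either way: statistic 0, p 1.
#'
#' @param a,b,c,d Table entries (vectorized): `a` = focal evidence in the
#'   mutant, `b` = background in the mutant, `c` = focal in the wild type,
#'   `d` = background in the wild type.
#' @return List with `statistic` and `p_value` (vectors).
#' @examples
#' chi2_homogeneity(40, 100, 10, 100)  # statistic ~ 14.61, p ~ 1.3e-4
#' @export
chi2_homogeneity <- function(a, b, c, d) {
  stopifnot(all(a >= 0), all(b >= 0), all(c >= 0), all(d >= 0))
  n <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  denom <- r1 * r2 * c1 * c2
  stat <- ifelse(denom > 0, n * (a * d - b * c)^2 / denom, 0)
  stat[!is.finite(stat)] <- 0
  p <- ifelse(denom > 0, stats::pchisq(stat, df = 1, lower.tail = FALSE), 1)
  list(statistic = stat, p_value = p)
}

#' Fisher exact test on a 2x2 table (two-sided)
#'
#' Entries are rounded half-up to integers, margins are conditioned on, and
#' the two-sided p-value is the sum of hypergeometric probabilities no
#' larger than that of the observed table (with the customary `1 + 1e-7`
#' tie tolerance). A zero margin gives p 1.
#'
#' @inheritParams chi2_homogeneity
#' @return Vector of p-values.
#' @examples
#' fisher2x2(5, 0, 0, 5)  # 2/252
#' @export
fisher2x2 <- function(a, b, c, d) {
  stopifnot(all(a >= 0), all(b >= 0), all(c >= 0), all(d >= 0))
  a <- floor(a + 0.5); b <- floor(b + 0.5)
  c <- floor(c + 0.5); d <- floor(d + 0.5)
  vapply(seq_along(a), function(i) {
    .fisher1(a[i], b[i], c[i], d[i])
  }, numeric(1))
}

.fisher1 <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(1)
  k <- r1                       # row-1 total, drawn from col-1 (m) vs col-2 (n)
  lo <- max(0, k - c2); hi <- min(k, c1)
  probs <- stats::dhyper(lo:hi, m = c1, n = c2, k = k)
  p_obs <- probs[a - lo + 1L]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

.get_pairs <- function(n_wt, n_mut, pairing) {
  if (pairing == "index") {
    if (n_wt != n_mut)
      stop("index pairing needs equal replicate numbers (", n_wt, " vs ", n_mut, ")")
    cbind(wt = seq_len(n_wt), mut = seq_len(n_mut))
  } else {
    cbind(wt = rep(NA_integer_, n_mut), mut = seq_len(n_mut)) # NA = pooled wt
  }
}

.depth_matrix <- function(samples, feat, what) {
  m <- matrix(0, nrow(feat), length(samples))
  key <- paste(feat$gene_id, feat$index)
  for (j in seq_along(samples)) {
    d <- samples[[j]][[what]]
    idx <- match(paste(d$gene_id, d$index), key)
    ok <- !is.na(idx)
    m[idx[ok], j] <- d$depth[ok]
  }
  m
}

.consistent <- function(per_pair_labels) {
  # one label per replicate pair; a call needs all pairs to agree
  u <- unique(per_pair_labels)
  if (length(u) == 1L && !is.na(u)) u else NA_character_
}

#' Scan annotated introns for retention shifts (IR / MES)
#'
#' Per intron and replicate pair, the intron's average depth is compared to
#' the background (unweighted mean depth of the two flanking exons) across
#' genotypes with [chi2_homogeneity()]. An intron is significant iff the
#' p-value is below `alpha` in every replicate pair; it is labeled `MES`
#' (more efficiently spliced) if the intron/background depth ratio in the
#' mutant is smaller than in the wild type in every pair, `IR` (increased
#' retention) if greater in every pair, and is not called when pairs
#' disagree on direction. Introns with a zero background in any replicate
#' are skipped (recorded in `attr(, "skipped")`).
#'
#' @param wt,mut Lists of `sample_counts` (wild type / mutant replicates).
#' @param models A `gene_model_set`.
#' @param alpha Per-test significance threshold (default 0.01).
#' @param pairing `"index"` (mutant i vs wild type i) or `"pooled"` (each
#'   mutant replicate vs the sum of all wild-type replicates).
#' @return data.table of tested introns: `gene_id`, `intron_index`
#'   (genomic), `feature_tx` (transcription order), `event_type`,
#'   list-columns `p_values`, `ratio_mut`, `ratio_wt`, plus `max_p` and
#'   `significant`.
#' @export
scan_intron_retention <- function(wt, mut, models, alpha = 0.01,
                                  pairing = c("index", "pooled")) {
  pairing <- match.arg(pairing)
  pairs <- .get_pairs(length(wt), length(mut), pairing)
  inf <- feature_table(models, "introns")
  empty <- data.table::data.table(
    gene_id = character(0), intron_index = integer(0), feature_tx = integer(0),
    event_type = character(0), p_values = list(), ratio_mut = list(),
    ratio_wt = list(), max_p = numeric(0), significant = logical(0))
  if (!nrow(inf)) return(empty)
  exf <- feature_table(models, "exons")
  I_wt <- .depth_matrix(wt, inf, "intron_depth")
  I_mut <- .depth_matrix(mut, inf, "intron_depth")
  E_wt <- .depth_matrix(wt, exf, "exon_depth")
  E_mut <- .depth_matrix(mut, exf, "exon_depth")
  exkey <- paste(exf$gene_id, exf$index)
  up <- match(paste(inf$gene_id, inf$index), exkey)
  dn <- match(paste(inf$gene_id, inf$index + 1L), exkey)
  B_wt <- (E_wt[up, , drop = FALSE] + E_wt[dn, , drop = FALSE]) / 2
  B_mut <- (E_mut[up, , drop = FALSE] + E_mut[dn, , drop = FALSE]) / 2
  if (pairing == "pooled") {
    I_wt <- matrix(rowSums(I_wt), nrow(inf), nrow(pairs))
    B_wt <- matrix(rowSums(B_wt), nrow(inf), nrow(pairs))
  } else {
    I_wt <- I_wt[, pairs[, "wt"], drop = FALSE]
    B_wt <- B_wt[, pairs[, "wt"], drop = FALSE]
  }
  I_mut <- I_mut[, pairs[, "mut"], drop = FALSE]
  B_mut <- B_mut[, pairs[, "mut"], drop = FALSE]
  bad <- rowSums(B_wt == 0 | B_mut == 0) > 0
  res_rows <- which(!bad)
  P <- matrix(NA_real_, nrow(inf), nrow(pairs))
  for (j in seq_len(nrow(pairs)))
    P[res_rows, j] <- chi2_homogeneity(I_mut[res_rows, j], B_mut[res_rows, j],
                                       I_wt[res_rows, j], B_wt[res_rows, j])$p_value
  R_mut <- I_mut / B_mut
  R_wt <- I_wt / B_wt
  out <- data.table::rbindlist(lapply(res_rows, function(i) {
    m <- models[[inf$gene_id[i]]]
    data.table::data.table(
      gene_id = inf$gene_id[i], intron_index = inf$index[i],
      feature_tx = tx_order_index(m, inf$index[i], "intron"),
      # more efficiently spliced if the mutant ratio is smaller; otherwise IR
      event_type = .consistent(ifelse(R_mut[i, ] < R_wt[i, ], "MES", "IR")),
      p_values = list(P[i, ]), ratio_mut = list(R_mut[i, ]),
      ratio_wt = list(R_wt[i, ]), max_p = max(P[i, ]))
  }))
  if (!nrow(out)) out <- empty
  else out$significant <- out$max_p < alpha & !is.na(out$event_type)
  attr(out, "skipped") <- inf[bad, c("gene_id", "index")]
  out
}

.junction_count_matrix <- function(samples, keys) {
  # keys: data.table(gene_id, donor_end, acceptor_start)
  m <- matrix(0, nrow(keys), length(samples))
  kk <- paste(keys$gene_id, keys$donor_end, keys$acceptor_start)
  for (j in seq_along(samples)) {
    jx <- samples[[j]]$junction_reads
    idx <- match(paste(jx$gene_id, jx$donor_end, jx$acceptor_start), kk)
    ok <- !is.na(idx)
    if (any(ok)) m[idx[ok], j] <- m[idx[ok], j] + jx$count[ok]
  }
  m
}

#' Scan internal exons for skipping shifts (ES)
#'
#' For each internal exon whose skip junction (upstream flanking exon's
#' donor joined to the downstream flanking exon's acceptor) is observed in
#' at least one sample, the skip-junction read count is compared to the sum
#' of the two inclusion-junction read counts across genotypes with
#' [chi2_homogeneity()], per replicate pair. Direction (`ES_enhanced` /
#' `ES_reduced`) follows the skip/inclusion ratio, required to agree in all
#' pairs; significant iff all p-values are below `alpha`.
#'
#' @inheritParams scan_intron_retention
#' @return data.table: `gene_id`, `exon_index` (genomic), `feature_tx`,
#'   `junction` ("donor-acceptor"), `event_type`, list-columns as in
#'   [scan_intron_retention()], `max_p`, `significant`.
#' @export
scan_exon_skipping <- function(wt, mut, models, alpha = 0.01,
                               pairing = c("index", "pooled")) {
  pairing <- match.arg(pairing)
  pairs <- .get_pairs(length(wt), length(mut), pairing)
  jk <- all_junctions(models, include_skip = TRUE)
  empty <- data.table::data.table(
    gene_id = character(0), exon_index = integer(0), feature_tx = integer(0),
    junction = character(0), event_type = character(0), p_values = list(),
    ratio_mut = list(), ratio_wt = list(), max_p = numeric(0),
    significant = logical(0))
  if (!nrow(jk) || !any(jk$kind == "skip")) return(empty)
  skip <- jk[jk$kind == "skip"]
  S_wt <- .junction_count_matrix(wt, skip)
  S_mut <- .junction_count_matrix(mut, skip)
  tested <- which(rowSums(S_wt) + rowSums(S_mut) > 0)
  if (!length(tested)) return(empty)
  ann <- jk[jk$kind == "intron"]
  A_wt <- .junction_count_matrix(wt, ann)
  A_mut <- .junction_count_matrix(mut, ann)
  annkey <- paste(ann$gene_id, ann$index)
  out <- data.table::rbindlist(lapply(tested, function(i) {
    e <- skip$index[i]; g <- skip$gene_id[i]
    iu <- match(paste(g, e - 1L), annkey)   # inclusion junction upstream
    id <- match(paste(g, e), annkey)        # inclusion junction downstream
    incl_wt <- A_wt[iu, ] + A_wt[id, ]
    incl_mut <- A_mut[iu, ] + A_mut[id, ]
    if (pairing == "pooled") {
      s_wt <- rep(sum(S_wt[i, ]), nrow(pairs))
      b_wt <- rep(sum(incl_wt), nrow(pairs))
    } else {
      s_wt <- S_wt[i, pairs[, "wt"]]; b_wt <- incl_wt[pairs[, "wt"]]
    }
    s_mut <- S_mut[i, pairs[, "mut"]]; b_mut <- incl_mut[pairs[, "mut"]]
    tst <- chi2_homogeneity(s_mut, b_mut, s_wt, b_wt)
    r_mut <- ifelse(b_mut > 0, s_mut / b_mut, NA_real_)
    r_wt <- ifelse(b_wt > 0, s_wt / b_wt, NA_real_)
    dir <- if (anyNA(r_mut) || anyNA(r_wt)) NA_character_
           else .consistent(ifelse(r_mut > r_wt, "ES_enhanced", "ES_reduced"))
    m <- models[[g]]
    data.table::data.table(
      gene_id = g, exon_index = e, feature_tx = tx_order_index(m, e, "exon"),
      junction = sprintf("%d-%d", as.integer(skip$donor_end[i]),
                         as.integer(skip$acceptor_start[i])),
      event_type = dir, p_values = list(tst$p_value),
      ratio_mut = list(r_mut), ratio_wt = list(r_wt),
      max_p = max(tst$p_value))
  }))
  out$significant <- out$max_p < alpha & !is.na(out$event_type)
  out
}

#' Scan alternative 5'/3' splice-site usage (A5SS / A3SS)
#'
#' Observed non-annotated junctions that share exactly one end (donor or
#' acceptor) with an annotated intron are its splice-site variants. For
#' each variant and replicate pair two Fisher exact tests are run: (i)
#' variant reads vs reads of the intron's other junctions, and (ii) variant
#' reads vs the gene's unique read count (confirmation). A variant is
#' significant iff both p-values are below `alpha` in every pair, and its
#' direction (enhanced/reduced) follows the variant-to-unique-gene-reads
#' ratio, required to agree across pairs. The side label is strand-aware:
#' a changed donor is A5SS, a changed acceptor is A3SS. Variants whose
#' coordinates coincide with an exon-skipping junction are excluded (they
#' are ES evidence); variants in genes with a zero unique read count in any
#' replicate are skipped (recorded in `attr(, "skipped")`).
#'
#' @inheritParams scan_intron_retention
#' @return data.table: `gene_id`, `intron_index`, `feature_tx`, `junction`,
#'   `event_type` (`A5SS_enhanced`, `A5SS_reduced`, `A3SS_enhanced`,
#'   `A3SS_reduced`), list-columns `p_values` (junction-vs-junction),
#'   `p_values_gene` (confirmation), `ratio_mut`, `ratio_wt`, `max_p`
#'   (over both tests), `significant`.
#' @export
scan_alt_splice_sites <- function(wt, mut, models, alpha = 0.01,
                                  pairing = c("index", "pooled")) {
  pairing <- match.arg(pairing)
  pairs <- .get_pairs(length(wt), length(mut), pairing)
  all_sc <- c(wt, mut)
  jk <- all_junctions(models, include_skip = TRUE)
  skipkey <- if (nrow(jk)) with(jk[jk$kind == "skip"],
                                paste(gene_id, donor_end, acceptor_start))
             else character(0)
  annkey <- if (nrow(jk)) with(jk[jk$kind == "intron"],
                               paste(gene_id, donor_end, acceptor_start))
            else character(0)
  # variant universe: attached, non-annotated, not a skip junction
  vars <- data.table::rbindlist(lapply(all_sc, function(s) {
    j <- s$junction_reads
    j[!j$annotated & !is.na(j$gene_id) & !is.na(j$intron_index),
      c("gene_id", "intron_index", "donor_end", "acceptor_start")]
  }))
  empty <- data.table::data.table(
    gene_id = character(0), intron_index = integer(0), feature_tx = integer(0),
    junction = character(0), event_type = character(0), p_values = list(),
    p_values_gene = list(), ratio_mut = list(), ratio_wt = list(),
    max_p = numeric(0), significant = logical(0))
  if (!nrow(vars)) return(empty)
  vars <- unique(vars)
  vars <- vars[!paste(vars$gene_id, vars$donor_end, vars$acceptor_start) %in%
                 c(skipkey, annkey)]
  if (!nrow(vars)) return(empty)
  # per-intron totals need all variants incl. the annotated junction
  ann <- jk[jk$kind == "intron"]
  fam <- data.table::rbindlist(list(
    vars,
    data.table::data.table(gene_id = ann$gene_id, intron_index = ann$index,
                           donor_end = ann$donor_end,
                           acceptor_start = ann$acceptor_start)))
  fam <- unique(fam)
  C_wt <- .junction_count_matrix(wt, fam)
  C_mut <- .junction_count_matrix(mut, fam)
  famkey <- paste(fam$gene_id, fam$intron_index)
  U_wt <- vapply(wt, function(s) as.numeric(s$unique_gene_reads),
                 numeric(length(wt[[1L]]$unique_gene_reads)))
  U_wt <- matrix(U_wt, ncol = length(wt),
                 dimnames = list(names(wt[[1L]]$unique_gene_reads), NULL))
  U_mut <- vapply(mut, function(s) as.numeric(s$unique_gene_reads),
                  numeric(length(mut[[1L]]$unique_gene_reads)))
  U_mut <- matrix(U_mut, ncol = length(mut),
                  dimnames = list(names(mut[[1L]]$unique_gene_reads), NULL))
  skipped <- list()
  out <- data.table::rbindlist(lapply(seq_len(nrow(vars)), function(v) {
    g <- vars$gene_id[v]; ii <- vars$intron_index[v]
    vrow <- which(famkey == paste(g, ii))
    self <- vrow[fam$donor_end[vrow] == vars$donor_end[v] &
                   fam$acceptor_start[vrow] == vars$acceptor_start[v]]
    ug_wt <- U_wt[g, ]; ug_mut <- U_mut[g, ]
    if (any(ug_wt == 0) || any(ug_mut == 0)) {
      skipped[[length(skipped) + 1L]] <<- vars[v]
      return(NULL)
    }
    v_wt <- C_wt[self, ]; v_mut <- C_mut[self, ]
    o_wt <- colSums(C_wt[vrow, , drop = FALSE]) - v_wt
    o_mut <- colSums(C_mut[vrow, , drop = FALSE]) - v_mut
    if (pairing == "pooled") {
      pv_wt <- rep(sum(v_wt), nrow(pairs)); po_wt <- rep(sum(o_wt), nrow(pairs))
      pu_wt <- rep(sum(ug_wt), nrow(pairs))
    } else {
      pv_wt <- v_wt[pairs[, "wt"]]; po_wt <- o_wt[pairs[, "wt"]]
      pu_wt <- ug_wt[pairs[, "wt"]]
    }
    pv_mut <- v_mut[pairs[, "mut"]]; po_mut <- o_mut[pairs[, "mut"]]
    pu_mut <- ug_mut[pairs[, "mut"]]
    p1 <- fisher2x2(pv_mut, po_mut, pv_wt, po_wt)
    p2 <- fisher2x2(pv_mut, pu_mut, pv_wt, pu_wt)
    r_mut <- pv_mut / pu_mut; r_wt <- pv_wt / pu_wt
    m <- models[[g]]
    ann_row <- ann[ann$gene_id == g & ann$index == ii]
    side <- if (vars$donor_end[v] != ann_row$donor_end) "donor" else "acceptor"
    ss <- if ((side == "donor") == (m$strand == "+")) "A5SS" else "A3SS"
    dir <- .consistent(ifelse(r_mut > r_wt, "_enhanced", "_reduced"))
    data.table::data.table(
      gene_id = g, intron_index = ii,
      feature_tx = tx_order_index(m, ii, "intron"),
      junction = sprintf("%d-%d", as.integer(vars$donor_end[v]),
                         as.integer(vars$acceptor_start[v])),
      event_type = if (is.na(dir)) NA_character_ else paste0(ss, dir),
      p_values = list(p1), p_values_gene = list(p2),
      ratio_mut = list(r_mut), ratio_wt = list(r_wt),
      max_p = max(c(p1, p2)))
  }))
  if (!nrow(out)) out <- empty
  else out$significant <- out$max_p < alpha & !is.na(out$event_type)
  attr(out, "skipped") <- data.table::rbindlist(skipped)
  out
}

#' Flatten an event table for TSV output
#'
#' List-columns (per-replicate p-values and ratios) are joined with commas.
#'
#' @param events Output of one of the scan functions.
#' @param path Optional file; when given the table is written as TSV.
#' @return The flat data.table, invisibly when `path` is given.
#' @export
events_to_tsv <- function(events, path = NULL) {
  flat <- data.table::copy(events)
  for (col in c("p_values", "p_values_gene", "ratio_mut", "ratio_wt")) {
    if (col %in% names(flat))
      data.table::set(flat, j = col, value = vapply(
        flat[[col]], function(x) paste(signif(x, 6), collapse = ","), ""))
  }
  if (!is.null(path)) {
    data.table::fwrite(flat, path, sep = "\t")
    return(invisible(flat))
  }
  flat
}

#' Summarize significant events per type (Table-2 style)
#'
#' @param ir,es,alt Scan outputs for one mutant-vs-wild-type contrast (any
#'   may be NULL).
#' @return data.table with `event_type`, `n_events`, `n_genes`, and
#'   `n_multi_event_genes` (genes contributing more than one event of the
#'   type, e.g. multiple retained introns in one pre-mRNA).
#' @export
summarize_events <- function(ir = NULL, es = NULL, alt = NULL) {
  sig <- data.table::rbindlist(lapply(list(ir, es, alt), function(x) {
    if (is.null(x) || !nrow(x)) return(NULL)
    x[x$significant, c("gene_id", "event_type")]
  }))
  if (!nrow(sig))
    return(data.table::data.table(event_type = character(0),
                                  n_events = integer(0), n_genes = integer(0),
                                  n_multi_event_genes = integer(0)))
  gene_id <- NULL
  sig[, list(n_events = .N, n_genes = data.table::uniqueN(gene_id),
             n_multi_event_genes = sum(table(gene_id) > 1L)),
      by = "event_type"]
}

#' Events shared between two contrasts
#'
#' @param ev_a,ev_b Scan outputs of the same type for two contrasts.
#' @return data.table of significant events (matched on gene, feature and
#'   event type) present in both.
#' @export
shared_events <- function(ev_a, ev_b) {
  fcol <- intersect(c("intron_index", "exon_index"), names(ev_a))[1L]
  key <- function(x) paste(x$gene_id, x[[fcol]], x$event_type,
                           if ("junction" %in% names(x)) x$junction else "")
  a <- ev_a[ev_a$significant]
  b <- ev_b[ev_b$significant]
  a[key(a) %in% key(b)]
}
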