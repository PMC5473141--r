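#' Generate random gene models
#'
#' Multi-exon genes with exon lengths uniform in 50–500 nt and intron
#' lengths uniform in 60–1,000 nt, laid out without overlap over five
#' chromosomes, strands assigned at random. The exon count per gene is
#' `1 + Poisson(exon_lambda)` (default mean 6, matching compact plant
#' genes). Fully deterministic under `seed`.
#'
#' @param n_genes Number of genes (>= 1).
#' @param seed Integer seed.
#' @param exon_lambda Poisson mean of (exons per gene - 1).
#' @return A `gene_model_set`.
#' @export
gen_models <- function(n_genes, seed = 1L, exon_lambda = 5) {
  stopifnot(n_genes >= 1)
  set.seed(seed)
  chroms <- paste0("chr", 1:5)
  cursor <- stats::setNames(rep(1000, length(chroms)), chroms)
  models <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    k <- 1L + stats::rpois(1L, exon_lambda)
    exon_w <- round(stats::runif(k, 50, 500))
    intron_w <- if (k > 1L) round(stats::runif(k - 1L, 60, 1000)) else numeric(0)
    chrom <- chroms[(g - 1L) %% length(chroms) + 1L]
    pos <- cursor[[chrom]]
    starts <- ends <- numeric(k)
    for (e in seq_len(k)) {
      starts[e] <- pos
      ends[e] <- pos + exon_w[e] - 1
      pos <- ends[e] + 1 + if (e < k) intron_w[e] else 0
    }
    cursor[[chrom]] <- pos + 2000
    models[[g]] <- gene_model(sprintf("SYNG%04d", g), chrom,
                              sample(c("+", "-"), 1L), cbind(starts, ends))
  }
  gene_model_set(models)
}

#' Simulation design
#'
#' The stated world the generator draws from: two genotypes in biological
#' quintuplicates; per-gene expression negative-binomial with
#' `variance = mean + dispersion * mean^2`; per-intron splicing
#' efficiencies (fraction of transcripts spliced); Poisson feature depths
#' around the gene's replicate coverage; binomial junction reads; and
#' injected mutant-side perturbations expressed as odds folds.
#'
#' @param n_replicates Replicates per genotype (default 5).
#' @param mean_depth Mean exonic read depth per gene (default 400; chosen
#'   so the all-replicates p < 0.01 rule has >= 95% power on 4-fold
#'   retention-odds changes — see the package vignette).
#' @param dispersion NB dispersion (default 0.05; typical biological
#'   replicates).
#' @param read_length Read length in nt used to convert depth to read
#'   counts (default 100).
#' @param splicing_efficiency Baseline per-intron fraction spliced, scalar
#'   in \[0, 1\] (default 0.8, i.e. 20% baseline retention).
#' @param skip_rate Baseline exon-skipping junction rate (default 0.05).
#' @param altss_rate Baseline alternative splice-site usage fraction
#'   (default 0.05).
#' @param altss_offset Offset (nt) of simulated alternative donor/acceptor
#'   sites from the annotated site (default 12).
#' @param events data.table of injected events: columns `type`
#'   (`IR`, `MES`, `ES`, `A5SS`, `A3SS`), `gene_id`, `feature_index`
#'   (genomic intron index, or exon index for ES), `fold` (odds fold
#'   applied on the mutant side). NULL for a null design.
#' @param seed Integer seed fixing all randomness.
#' @return A `simulation_design`.
#' @export
simulation_design <- function(n_replicates = 5L, mean_depth = 400,
                              dispersion = 0.05, read_length = 100,
                              splicing_efficiency = 0.8, skip_rate = 0.05,
                              altss_rate = 0.05, altss_offset = 12L,
                              events = NULL, seed = 1L) {
  stopifnot(n_replicates >= 1, mean_depth > 0, dispersion >= 0,
            splicing_efficiency >= 0, splicing_efficiency <= 1,
            skip_rate >= 0, skip_rate < 1, altss_rate >= 0, altss_rate < 1)
  structure(list(n_replicates = as.integer(n_replicates),
                 mean_depth = mean_depth, dispersion = dispersion,
                 read_length = read_length,
                 splicing_efficiency = splicing_efficiency,
                 skip_rate = skip_rate, altss_rate = altss_rate,
                 altss_offset = as.integer(altss_offset),
                 events = events, seed = as.integer(seed)),
            class = "simulation_design")
}

#' Draw a random set of events to inject
#'
#' Samples distinct features from the models: introns for IR/MES/A5SS/A3SS,
#' internal exons for ES. Odds folds default to the detectability regime
#' used throughout the tests (4-fold retention odds, 6-fold junction odds).
#'
#' @param models A `gene_model_set`.
#' @param n_ir,n_mes,n_es,n_a5ss,n_a3ss Number of events per type.
#' @param fold_ir,fold_junction Odds folds (MES uses `1/fold_ir`).
#' @param seed Integer seed.
#' @return Events data.table for [simulation_design()].
#' @export
sample_events <- function(models, n_ir = 0L, n_mes = 0L, n_es = 0L,
                          n_a5ss = 0L, n_a3ss = 0L, fold_ir = 4,
                          fold_junction = 6, seed = 1L) {
  set.seed(seed)
  inf <- feature_table(models, "introns")
  exf <- feature_table(models, "exons")
  internal <- do.call(rbind, lapply(models$models, function(m) {
    if (n_exons(m) < 3L) return(NULL)
    data.frame(gene_id = m$gene_id, index = 2:(n_exons(m) - 1L))
  }))
  n_intron_ev <- n_ir + n_mes + n_a5ss + n_a3ss
  stopifnot(n_intron_ev <= nrow(inf), n_es <= NROW(internal))
  pick_i <- sample(nrow(inf), n_intron_ev)
  types <- rep(c("IR", "MES", "A5SS", "A3SS"), c(n_ir, n_mes, n_a5ss, n_a3ss))
  ev <- data.table::data.table(
    type = types, gene_id = inf$gene_id[pick_i],
    feature_index = inf$index[pick_i],
    fold = ifelse(types == "IR", fold_ir,
                  ifelse(types == "MES", 1 / fold_ir, fold_junction)))
  if (n_es > 0L) {
    pick_e <- sample(NROW(internal), n_es)
    ev <- rbind(ev, data.table::data.table(
      type = "ES", gene_id = internal$gene_id[pick_e],
      feature_index = internal$index[pick_e], fold = fold_junction))
  }
  ev
}

.odds_fold <- function(p, fold) {
  # multiply the odds p/(1-p) by `fold`, clamped to [0, 1]
  o <- fold * p / (1 - p)
  out <- o / (1 + o)
  out[!is.finite(o)] <- 1 # p = 1 (infinite odds) stays 1
  pmin(1, pmax(0, out))
}

#' Simulate per-replicate sample counts with known truth
#'
#' For gene g in replicate r, the read count is
#' `X ~ NB(mean_depth * length / read_length, dispersion)` and the
#' replicate coverage is `d = X * read_length / length`. Each exon's depth
#' is `Poisson(d)`; intron i's depth is `Poisson(d * (1 - efficiency_i))`;
#' junction reads are `Binomial(round(d), efficiency_i)`, of which a
#' `Binomial(., altss_rate)` subset uses a simulated alternative
#' donor/acceptor; each internal exon gets `Binomial(round(d), skip_rate)`
#' skip-junction reads; boundary-spanning counts are Poisson at the
#' retention level scaled by the anchor fraction. Injected events multiply
#' the corresponding odds (retention, skip, or variant usage) by their
#' `fold` on the mutant side; a perturbed probability falling outside
#' \[0, 1\] is clamped and flagged in the truth table.
#'
#' @param models A `gene_model_set`.
#' @param design A `simulation_design`.
#' @return List with `wt` and `mut` (lists of `sample_counts`, length
#'   `n_replicates`), `truth` (the injected events with realized
#'   probabilities and a `clamped` flag) and `efficiency` (per-intron
#'   baseline efficiencies).
#' @export
simulate_counts <- function(models, design) {
  stopifnot(inherits(design, "simulation_design"))
  set.seed(design$seed)
  exf <- feature_table(models, "exons")
  inf <- feature_table(models, "introns")
  ids <- names(models$models)
  lens <- vapply(models$models, function(m) m$length_nt, numeric(1))
  strands <- vapply(models$models, function(m) m$strand, character(1))
  eff <- rep(design$splicing_efficiency, nrow(inf))
  ikey <- paste(inf$gene_id, inf$index)
  # internal exons (candidate ES features) and their skip keys
  jk <- all_junctions(models, include_skip = TRUE)
  skipj <- jk[jk$kind == "skip"]
  skey <- paste(skipj$gene_id, skipj$index)
  # per-intron alternative junction: shift the transcription-3' end inward
  alt_left <- (strands[inf$gene_id] == "-") # A5SS on '-' genes changes right end
  # two candidate variants per intron: donor-side and acceptor-side shifts
  # (used only when an A5SS/A3SS event or baseline variant usage applies)
  alt_donor_end <- inf$start - 1 + design$altss_offset
  alt_acceptor_start <- inf$end + 1 - design$altss_offset
  ev <- design$events
  ir_fold <- rep(1, nrow(inf))
  altss_fold <- rep(1, nrow(inf))
  alt_side_left <- rep(NA, nrow(inf)) # TRUE = variant changes left end
  es_fold <- rep(1, nrow(skipj))
  truth <- data.table::data.table()
  if (!is.null(ev) && nrow(ev)) {
    truth <- data.table::copy(data.table::as.data.table(ev))
    truth$clamped <- FALSE
    for (r in seq_len(nrow(ev))) {
      g <- ev$gene_id[r]; fi <- ev$feature_index[r]; fold <- ev$fold[r]
      if (ev$type[r] %in% c("IR", "MES")) {
        ir_fold[ikey == paste(g, fi)] <- fold
      } else if (ev$type[r] == "ES") {
        es_fold[skey == paste(g, fi)] <- fold
      } else {
        i <- which(ikey == paste(g, fi))
        altss_fold[i] <- fold
        # A5SS changes the transcription-5' (donor) side
        alt_side_left[i] <- (ev$type[r] == "A5SS") == (strands[g] == "+")
      }
    }
  }
  # baseline variants use the acceptor-side shift unless an event says otherwise
  alt_side_left[is.na(alt_side_left)] <- FALSE
  rho0 <- 1 - eff
  chrom_of <- vapply(models$models, function(m) m$chrom, character(1))
  anchor_frac <- 16 / design$read_length
  gen_sample <- function(genotype, rep_i) {
    mu_reads <- design$mean_depth * lens / design$read_length
    size <- if (design$dispersion > 0) 1 / design$dispersion else Inf
    X <- if (is.finite(size)) stats::rnbinom(length(ids), mu = mu_reads, size = size)
         else stats::rpois(length(ids), mu_reads)
    names(X) <- ids
    d <- X * design$read_length / lens         # replicate coverage per gene
    d_ex <- d[exf$gene_id]
    exon_depth <- data.table::data.table(
      gene_id = exf$gene_id, index = exf$index,
      depth = stats::rpois(nrow(exf), d_ex))
    d_in <- d[inf$gene_id]
    rho <- if (genotype == "mut") .odds_fold(rho0, ir_fold) else rho0
    intron_depth <- data.table::data.table(
      gene_id = inf$gene_id, index = inf$index,
      depth = stats::rpois(nrow(inf), d_in * rho))
    # junction reads, split between annotated and variant usage
    trials <- stats::rbinom(nrow(inf), round(d_in), eff)
    q <- rep(design$altss_rate, nrow(inf))
    if (genotype == "mut") q <- .odds_fold(q, altss_fold)
    n_var <- stats::rbinom(nrow(inf), trials, q)
    n_ann <- trials - n_var
    jx_ann <- data.table::data.table(
      gene_id = inf$gene_id, chrom = inf$chrom,
      donor_end = inf$start - 1, acceptor_start = inf$end + 1,
      count = n_ann, annotated = TRUE, intron_index = inf$index)
    jx_var <- data.table::data.table(
      gene_id = inf$gene_id, chrom = inf$chrom,
      donor_end = ifelse(alt_side_left, alt_donor_end, inf$start - 1),
      acceptor_start = ifelse(alt_side_left, inf$end + 1, alt_acceptor_start),
      count = n_var, annotated = FALSE, intron_index = inf$index)
    jx_var <- jx_var[jx_var$count > 0]
    s <- rep(design$skip_rate, nrow(skipj))
    if (genotype == "mut") s <- .odds_fold(s, es_fold)
    d_sk <- d[skipj$gene_id]
    n_skip <- stats::rbinom(nrow(skipj), round(d_sk), s)
    jx_skip <- data.table::data.table(
      gene_id = skipj$gene_id, chrom = chrom_of[skipj$gene_id],
      donor_end = skipj$donor_end, acceptor_start = skipj$acceptor_start,
      count = n_skip, annotated = FALSE, intron_index = NA_integer_)
    jx_skip <- jx_skip[jx_skip$count > 0]
    boundary <- data.table::data.table(
      gene_id = rep(inf$gene_id, 2L),
      intron_index = rep(inf$index, 2L),
      side = rep(c("5p", "3p"), each = nrow(inf)),
      count = stats::rpois(2L * nrow(inf), rep(d_in * rho * anchor_frac, 2L)))
    boundary <- boundary[boundary$count > 0]
    sample_counts(sample_id = sprintf("%s_%d", genotype, rep_i),
                  gene_reads = X, unique_gene_reads = X,
                  exon_depth = exon_depth, intron_depth = intron_depth,
                  junction_reads = data.table::rbindlist(
                    list(jx_ann, jx_var, jx_skip)),
                  boundary_reads = boundary, library_size = sum(X))
  }
  wt <- lapply(seq_len(design$n_replicates), function(r) gen_sample("wt", r))
  mut <- lapply(seq_len(design$n_replicates), function(r) gen_sample("mut", r))
  if (nrow(truth)) {
    truth$clamped <- vapply(seq_len(nrow(truth)), function(r) {
      if (truth$type[r] %in% c("IR", "MES")) {
        o <- truth$fold[r] * rho0[1L] / (1 - rho0[1L])
        o / (1 + o) > 1 || o / (1 + o) < 0
      } else FALSE
    }, logical(1))
  }
  list(wt = wt, mut = mut, truth = truth,
       efficiency = data.table::data.table(gene_id = inf$gene_id,
                                           index = inf$index, efficiency = eff))
}

#' Simulate reporter-locus counts from a known variant mixture
#'
#' Draws `Multinomial(depth, mixture)` read counts for the three variants
#' (unspliced, GT–AG-spliced, AT–AC-spliced) and packages them as a
#' `sample_counts` fragment that [quantify_reporter()] consumes.
#'
#' @param mixture Numeric length 3 (unspliced, gtag, atac), summing to 1,
#'   no negative entries.
#' @param depth Total reporter read count.
#' @param model A `reporter_model`.
#' @param seed Optional integer seed.
#' @param sample_id Sample label.
#' @return A `sample_counts` covering only the reporter.
#' @export
simulate_reporter <- function(mixture, depth, model, seed = NULL,
                              sample_id = "reporter_sim") {
  if (any(mixture < 0)) stop("negative mixture fractions")
  if (abs(sum(mixture) - 1) > 1e-8) stop("mixture must sum to 1")
  if (!is.null(seed)) set.seed(seed)
  n <- if (depth > 0) as.vector(stats::rmultinom(1L, depth, mixture))
       else c(0, 0, 0)
  jx <- data.table::data.table(
    gene_id = model$gene_id, chrom = model$chrom,
    donor_end = c(model$inner[1L] - 1, model$outer[1L] - 1),
    acceptor_start = c(model$inner[2L] + 1, model$outer[2L] + 1),
    count = c(n[2L], n[3L]), annotated = c(TRUE, FALSE),
    intron_index = c(1L, NA_integer_))
  bnd <- data.table::data.table(gene_id = model$gene_id, intron_index = 1L,
                                side = "5p", count = n[1L])
  sample_counts(sample_id = sample_id,
                gene_reads = stats::setNames(depth, model$gene_id),
                exon_depth = data.table::data.table(
                  gene_id = character(0), index = integer(0), depth = numeric(0)),
                intron_depth = data.table::data.table(
                  gene_id = character(0), index = integer(0), depth = numeric(0)),
                junction_reads = jx, boundary_reads = bnd,
                library_size = depth)
}

#' Emit concrete spliced reads as SAM (end-to-end testing)
#'
#' Writes deterministic single-end reads for every model: `per_exon` reads
#' tiled inside each exon, `per_junction` spliced reads whose alignment gap
#' is exactly each intron, and `per_intron` retention reads spanning each
#' 5' exon–intron boundary. The emitted reads are also returned as a table
#' so tests can compute expected counts independently.
#'
#' @param models A `gene_model_set`.
#' @param path Output SAM path.
#' @param per_exon,per_junction,per_intron Reads per feature.
#' @param read_length Read length (nt); exonic features shorter than this
#'   get shorter reads.
#' @return data.table of emitted reads (`qname`, `chrom`, `pos`, `cigar`),
#'   invisibly; the SAM file is written to `path`.
#' @export
simulate_sam <- function(models, path, per_exon = 4L, per_junction = 3L,
                         per_intron = 2L, read_length = 50L) {
  chrom_len <- tapply(
    vapply(models$models, function(m) m$exons[nrow(m$exons), 2L], numeric(1)),
    vapply(models$models, function(m) m$chrom, character(1)), max)
  recs <- list()
  add <- function(qname, chrom, pos, cigar) {
    recs[[length(recs) + 1L]] <<- data.table::data.table(
      qname = qname, chrom = chrom, pos = as.integer(pos), cigar = cigar)
  }
  half <- as.integer(read_length / 2)
  for (m in models$models) {
    for (e in seq_len(n_exons(m))) {
      w <- min(read_length, m$exons[e, 2L] - m$exons[e, 1L] + 1)
      span <- m$exons[e, 2L] - m$exons[e, 1L] + 1 - w
      for (r in seq_len(per_exon))
        add(sprintf("%s_ex%d_%d", m$gene_id, e, r), m$chrom,
            m$exons[e, 1L] + round(span * (r - 1) / max(1, per_exon - 1)),
            sprintf("%dM", w))
    }
    for (i in seq_len(n_introns(m))) {
      gap <- m$introns[i, 2L] - m$introns[i, 1L] + 1
      for (r in seq_len(per_junction))
        add(sprintf("%s_jx%d_%d", m$gene_id, i, r), m$chrom,
            m$introns[i, 1L] - half,
            sprintf("%dM%dN%dM", half, gap, half))
      for (r in seq_len(per_intron))
        add(sprintf("%s_ir%d_%d", m$gene_id, i, r), m$chrom,
            m$introns[i, 1L] - half, sprintf("%dM", read_length))
    }
  }
  reads <- data.table::rbindlist(recs)
  qlen <- vapply(reads$cigar, function(cg) {
    ops <- regmatches(cg, gregexpr("[0-9]+[A-Z]", cg))[[1L]]
    sum(as.integer(sub("[A-Z]", "", ops[grepl("M", ops)])))
  }, numeric(1))
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_len),
                   as.integer(chrom_len + 1000)))
  body <- sprintf("%s\t0\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t*\tNM:i:0",
                  reads$qname, reads$chrom, reads$pos, reads$cigar,
                  strrep("A", qlen))
  writeLines(c(hdr, body), path)
  invisible(reads)
}
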