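#' Simulation configuration
#'
#' Defines the generative model for a synthetic retention time course.
#' Each gene carries one retention class and one retention-fraction
#' trajectory rho_t shared by its introns (coordinated regulation), so the
#' steady-state closed forms hold exactly per intron: with transcription
#' rate T and decay factor gamma (intron-retained transcripts degrade
#' gamma-fold faster than spliced ones), spliced abundance is
#' S_t = T (1 - rho_t), retained abundance R_t = T rho_t / gamma, and the
#' expected retention index IRI_t = R_t / (S_t + R_t). Exonic read depth is
#' proportional to S_t + R_t and intronic depth to R_t, so rising retention
#' depresses exonic signal whenever gamma > 1 -- the coupling the
#' association stage must detect.
#'
#' Default trajectory amplitudes keep intronic depth detectable: below
#' rho ~ 0.12 (at depth 30, gamma 5) the mean intronic depth drops under
#' ln 2 reads/base and the 50% coverage-completeness filter would remove
#' the intron, so "up" runs 0.18 -> 0.75, "down" is its mirror, "stable"
#' is constant in [0.45, 0.75], "none" constant in [0.18, 0.30] (expected
#' IRI < 0.08), and "irregular" alternates between the up-range extremes
#' (its correlation with the monotone reference is 0 by symmetry).
#'
#' @param n_genes Number of genes.
#' @param introns_per_gene Integer range (min, max), uniform per gene.
#' @param exon_length,intron_length_change,intron_length_other Length
#'   ranges in bp; regulated (up/down) introns are drawn shorter, as
#'   observed for dynamically regulated introns.
#' @param gc_change,gc_stable,gc_other GC-content ranges per intron class
#'   (regulated introns GC-richer).
#' @param skip_fraction Fraction of genes (with >= 3 exons) given a second
#'   isoform skipping one internal exon, to exercise shared-region
#'   reduction.
#' @param minus_fraction Fraction of genes on the minus strand.
#' @param n_timepoints,replicates Design dimensions (defaults 5 x 3).
#' @param depth Target mean exonic read depth at rho = 0.
#' @param read_length Nominal read length for FPKM/total-read bookkeeping.
#' @param class_props Mixture over classes none/stable/up/down/irregular
#'   (must sum to 1).
#' @param rho_up,rho_stable,rho_none Retention-fraction amplitude ranges.
#' @param gamma Decay factor of intron-retained transcripts (>= 1).
#' @param gene_scale_sdlog Log-SD of the per-gene baseline transcription
#'   rate.
#' @param t_drift_sdlog Log-SD of the stationary per-time-point drift of
#'   each gene's transcription rate T_t around its baseline (default 0.05,
#'   i.e. ~5\% CV): genes have expression variation of their own,
#'   independent of the retention machinery, as real time courses do.
#' @param rbp List of RBP roster settings: \code{n_decoys},
#'   \code{background_rate} (sites per kb), \code{site_width},
#'   \code{planted} (name), \code{enrichment} (site-rate fold in changed
#'   introns), \code{models}, \code{drop_models} (how many models show the
#'   expression drop), \code{expr_replicates}, \code{planted_rpkm},
#'   \code{decoy_rpkm}, \code{expr_cv}, \code{planted_fold}.
#' @param retention_cutoff Retention cutoff used for the feasibility check.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(n_genes = 100,
                       introns_per_gene = c(2, 4),
                       exon_length = c(150, 300),
                       intron_length_change = c(250, 500),
                       intron_length_other = c(500, 900),
                       gc_change = c(0.52, 0.62),
                       gc_stable = c(0.40, 0.50),
                       gc_other = c(0.38, 0.48),
                       skip_fraction = 0.3,
                       minus_fraction = 0.3,
                       n_timepoints = 5,
                       replicates = 3,
                       depth = 30,
                       read_length = 100,
                       class_props = c(none = 0.4, stable = 0.2, up = 0.15,
                                       down = 0.15, irregular = 0.1),
                       rho_up = c(0.18, 0.75),
                       rho_stable = c(0.45, 0.75),
                       rho_none = c(0.18, 0.30),
                       gamma = 5,
                       gene_scale_sdlog = 0.2,
                       t_drift_sdlog = 0.05,
                       rbp = list(),
                       retention_cutoff = 0.1) {
  rbp_defaults <- list(
    n_decoys = 10, background_rate = 0.5, site_width = 20,
    planted = "RBP_REG", enrichment = 5,
    models = c("HFF", "MRC5", "DF", "BJ", "IMR90", "WI38"),
    drop_models = 3, expr_replicates = 3, planted_rpkm = 30,
    decoy_rpkm = 20, expr_cv = 0.05, planted_fold = 2
  )
  rbp <- utils::modifyList(rbp_defaults, rbp)
  cfg <- list(
    n_genes = n_genes, introns_per_gene = introns_per_gene,
    exon_length = exon_length,
    intron_length_change = intron_length_change,
    intron_length_other = intron_length_other,
    gc_change = gc_change, gc_stable = gc_stable, gc_other = gc_other,
    skip_fraction = skip_fraction, minus_fraction = minus_fraction,
    n_timepoints = n_timepoints, replicates = replicates,
    depth = depth, read_length = read_length,
    class_props = class_props, rho_up = rho_up, rho_stable = rho_stable,
    rho_none = rho_none, gamma = gamma,
    gene_scale_sdlog = gene_scale_sdlog, t_drift_sdlog = t_drift_sdlog,
    rbp = rbp,
    retention_cutoff = retention_cutoff
  )
  if (abs(sum(class_props) - 1) > 1e-8) {
    stop("class_props must sum to 1")
  }
  if (gamma < 1) stop("gamma must be >= 1")
  if (depth <= 0) stop("depth must be > 0")
  if (any(c(rho_up, rho_stable, rho_none) < 0) ||
      any(c(rho_up, rho_stable, rho_none) >= 1)) {
    stop("rho ranges must lie in [0, 1)")
  }
  if (diff(introns_per_gene) < 0 || introns_per_gene[1L] < 1L) {
    stop("infeasible introns_per_gene range")
  }
  if (any(c(diff(exon_length), diff(intron_length_change),
            diff(intron_length_other)) < 0)) {
    stop("infeasible length ranges")
  }
  c0 <- retention_cutoff
  rho_needed <- c0 * gamma / (1 + c0 * (gamma - 1))
  if (expected_iri(max(rho_up), gamma) < c0 ||
      expected_iri(min(rho_stable), gamma) < c0) {
    stop("amplitude incompatible with gamma: retained classes need rho >= ",
         format(rho_needed, digits = 4), " to reach IRI >= ", c0)
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Expected IRI under the degradation model
#'
#' Closed form: with retention fraction rho and decay factor gamma,
#' IRI = (rho / gamma) / (1 - rho + rho / gamma). At gamma = 1 this
#' reduces to rho.
#'
#' @param rho Retention fraction(s) in [0, 1).
#' @param gamma Decay factor (>= 1).
#' @return Expected IRI value(s).
#' @export
expected_iri <- function(rho, gamma) {
  (rho / gamma) / (1 - rho + rho / gamma)
}

.class_labels <- c(none = "no_IR", stable = "stable_IR", up = "up_IR",
                   down = "down_IR", irregular = "discarded")

#' True intron labels implied by simulated classes
#'
#' @param truth An \code{ir_truth} object (or its \code{introns} table).
#' @return data.frame: \code{intron_id}, \code{label}.
#' @export
truth_labels <- function(truth) {
  introns <- if (is.data.frame(truth)) truth else truth$introns
  data.frame(intron_id = introns$intron_id,
             label = unname(.class_labels[introns$class]),
             stringsAsFactors = FALSE)
}

.draw_seq <- function(n, gc) {
  sample(c("G", "C", "A", "T"), n, replace = TRUE,
         prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2))
}

.gc_range_for <- function(config, class) {
  switch(class,
         up = config$gc_change, down = config$gc_change,
         stable = config$gc_stable, config$gc_other)
}

.len_range_for <- function(config, class) {
  if (class %in% c("up", "down")) config$intron_length_change
  else config$intron_length_other
}

#' Simulate gene models, genome sequence and intron records
#'
#' Lays out \code{n_genes} genes on one chromosome with per-gene retention
#' classes from the configured mixture. A fraction of multi-exon genes get
#' an exon-skipping second isoform; shared regions and intron records are
#' then derived through the annotation stage itself, guaranteeing that the
#' simulator and the pipeline agree on intron identity. Intron sequence GC
#' is drawn from the class-conditional range.
#'
#' @param config A \code{\link{sim_config}}.
#' @param seed Integer seed (this stage uses its own stream).
#' @return List of class \code{sim_genome}: \code{models} (GeneModel
#'   list), \code{genome} (\code{DNAStringSet}), \code{shared_list},
#'   \code{records} (intron records with \code{gc} and true \code{class}),
#'   \code{genes} (gene table with class and transcription scale),
#'   \code{chrom_length}.
#' @export
simulate_genome <- function(config, seed) {
  set.seed(seed)
  chrom <- "chrS"
  gap <- 300L
  classes <- names(config$class_props)
  gene_class <- sample(classes, config$n_genes, replace = TRUE,
                       prob = config$class_props)
  scale <- exp(stats::rnorm(config$n_genes, 0, config$gene_scale_sdlog))
  strand <- ifelse(stats::runif(config$n_genes) < config$minus_fraction,
                   "-", "+")
  models <- list()
  seq_parts <- list()
  pos <- 1L
  gene_rows <- vector("list", config$n_genes)
  for (g in seq_len(config$n_genes)) {
    gid <- sprintf("G%03d", g)
    n_int <- sample(seq(config$introns_per_gene[1L],
                        config$introns_per_gene[2L]), 1L)
    n_ex <- n_int + 1L
    ex_len <- sample(seq(config$exon_length[1L], config$exon_length[2L]),
                     n_ex, replace = TRUE)
    lr <- .len_range_for(config, gene_class[g])
    in_len <- sample(seq(lr[1L], lr[2L]), n_int, replace = TRUE)
    # leading gap
    seq_parts[[length(seq_parts) + 1L]] <- .draw_seq(gap, 0.40)
    pos <- pos + gap
    ex_start <- integer(n_ex)
    ex_end <- integer(n_ex)
    gc_rng <- .gc_range_for(config, gene_class[g])
    for (k in seq_len(n_ex)) {
      ex_start[k] <- pos
      ex_end[k] <- pos + ex_len[k] - 1L
      seq_parts[[length(seq_parts) + 1L]] <- .draw_seq(ex_len[k], 0.50)
      pos <- pos + ex_len[k]
      if (k <= n_int) {
        gc <- stats::runif(1, gc_rng[1L], gc_rng[2L])
        seq_parts[[length(seq_parts) + 1L]] <- .draw_seq(in_len[k], gc)
        pos <- pos + in_len[k]
      }
    }
    exons <- IRanges::IRanges(start = ex_start, end = ex_end)
    txs <- list(t1 = exons)
    if (n_ex >= 3L && stats::runif(1) < config$skip_fraction) {
      k_skip <- sample(2:(n_ex - 1L), 1L)
      txs$t2 <- exons[-k_skip]
    }
    names(txs) <- paste0(gid, ".", seq_along(txs))
    models[[gid]] <- gene_model(gid, chrom, strand[g], txs)
    gene_rows[[g]] <- data.frame(
      gene_id = gid, class = gene_class[g], scale = scale[g],
      strand = strand[g], n_introns = n_int, stringsAsFactors = FALSE
    )
  }
  seq_parts[[length(seq_parts) + 1L]] <- .draw_seq(gap, 0.40)
  genome_seq <- paste(unlist(seq_parts), collapse = "")
  genome <- Biostrings::DNAStringSet(genome_seq)
  names(genome) <- chrom
  shared_list <- lapply(models, compute_shared_regions)
  records <- do.call(rbind, lapply(shared_list, build_intron_records))
  rownames(records) <- NULL
  records <- annotate_features(records, genome)
  genes <- do.call(rbind, gene_rows)
  records$class <- genes$class[match(records$gene_id, genes$gene_id)]
  structure(
    list(models = models, genome = genome, shared_list = shared_list,
         records = records, genes = genes, chrom = chrom,
         chrom_length = nchar(genome_seq)),
    class = "sim_genome"
  )
}

#' Simulate retention-fraction trajectories and expected IRI
#'
#' Draws one rho_t trajectory per gene according to its class: strictly
#' increasing ("up"), strictly decreasing ("down"), constant retained
#' ("stable"), constant low ("none"), or alternating between the up-range
#' extremes ("irregular"). Expected IRI per time point follows the closed
#' form of \code{\link{expected_iri}}.
#'
#' @param config A \code{\link{sim_config}}.
#' @param genome A \code{sim_genome}.
#' @param seed Integer seed (own stream).
#' @return List of class \code{ir_truth}: \code{genes}, \code{introns}
#'   (with class labels), \code{rho} (genes x timepoints), \code{iri}
#'   (expected, genes x timepoints), \code{gamma}, \code{timepoints}.
#' @export
simulate_ir_trajectories <- function(config, genome, seed) {
  set.seed(seed)
  n_t <- config$n_timepoints
  genes <- genome$genes
  rho <- base::matrix(0, nrow(genes), n_t,
                      dimnames = list(genes$gene_id,
                                      paste0("T", seq_len(n_t))))
  jit <- function(r, w = 0.07) stats::runif(1, r[1L], r[1L] + w)
  for (g in seq_len(nrow(genes))) {
    cls <- genes$class[g]
    if (cls == "up" || cls == "down") {
      lo <- jit(config$rho_up)
      hi <- stats::runif(1, config$rho_up[2L] - 0.07, config$rho_up[2L])
      tr <- seq(lo, hi, length.out = n_t)
      if (cls == "down") tr <- rev(tr)
      rho[g, ] <- tr
    } else if (cls == "stable") {
      rho[g, ] <- stats::runif(1, config$rho_stable[1L],
                               config$rho_stable[2L])
    } else if (cls == "none") {
      rho[g, ] <- stats::runif(1, config$rho_none[1L], config$rho_none[2L])
    } else { # irregular: alternate amplitude extremes
      hi <- config$rho_up[2L]
      lo <- config$rho_up[1L]
      rho[g, ] <- rep(c(hi, lo), length.out = n_t)
    }
  }
  iri <- expected_iri(rho, config$gamma)
  # per-gene transcription rate T_t: baseline scale times a stationary
  # lognormal drift per time point (independent of the retention state)
  T_t <- genes$scale * exp(base::matrix(
    stats::rnorm(nrow(genes) * n_t, 0, config$t_drift_sdlog),
    nrow(genes), n_t))
  dimnames(T_t) <- dimnames(rho)
  structure(
    list(genes = genes, introns = genome$records, rho = rho, iri = iri,
         T_t = T_t, gamma = config$gamma, timepoints = colnames(rho)),
    class = "ir_truth"
  )
}

# per-base Poisson rate vector for one time point
.lambda_vector <- function(config, genome, truth, t_idx) {
  lam <- numeric(genome$chrom_length)
  for (g in seq_len(nrow(genome$genes))) {
    gid <- genome$genes$gene_id[g]
    rho_t <- truth$rho[gid, t_idx]
    T_gt <- truth$T_t[gid, t_idx]
    gene_signal <- config$depth * T_gt * (1 - rho_t * (1 - 1 / config$gamma))
    intr_signal <- config$depth * T_gt * rho_t / config$gamma
    model <- genome$models[[gid]]
    ex_union <- IRanges::reduce(do.call(c, unname(model$transcripts)))
    for (i in seq_along(ex_union)) {
      lam[IRanges::start(ex_union)[i]:IRanges::end(ex_union)[i]] <-
        gene_signal
    }
    intr <- IRanges::setdiff(range(ex_union), ex_union)
    for (i in seq_along(intr)) {
      lam[IRanges::start(intr)[i]:IRanges::end(intr)[i]] <- intr_signal
    }
  }
  lam
}

#' Simulate per-base coverage tracks and the sample design
#'
#' Per sample, per-base depths are independent Poisson draws: exonic bases
#' with mean proportional to S_t + R_t, intronic bases to R_t. Because
#' S_t + R_t = T (1 - rho_t (1 - 1/gamma)) falls as rho_t rises whenever
#' gamma > 1, expression and retention are anti-correlated by
#' construction.
#'
#' @param config A \code{\link{sim_config}}.
#' @param genome A \code{sim_genome}.
#' @param truth An \code{ir_truth}.
#' @param seed Integer seed (own stream).
#' @return List: \code{tracks} (CoverageTrack list) and \code{design}
#'   (sample design data.frame; \code{group} is an ordered-level factor).
#' @export
simulate_coverage <- function(config, genome, truth, seed) {
  set.seed(seed)
  n_t <- config$n_timepoints
  tps <- paste0("T", seq_len(n_t))
  tracks <- list()
  design_rows <- list()
  for (t_idx in seq_len(n_t)) {
    lam <- .lambda_vector(config, genome, truth, t_idx)
    for (r in seq_len(config$replicates)) {
      depth <- stats::rpois(length(lam), lam)
      sid <- sprintf("%s_r%d", tps[t_idx], r)
      total <- max(1, round(sum(as.numeric(depth)) / config$read_length))
      tr <- coverage_track(stats::setNames(list(S4Vectors::Rle(depth)),
                                           genome$chrom), sid, total)
      tracks[[sid]] <- tr
      design_rows[[length(design_rows) + 1L]] <- data.frame(
        sample_id = sid, group = tps[t_idx], replicate = r,
        total_mapped = total, stringsAsFactors = FALSE
      )
    }
  }
  design <- do.call(rbind, design_rows)
  design$group <- factor(design$group, levels = tps)
  list(tracks = tracks, design = design)
}

#' Simulate RBP binding sites with one planted regulator
#'
#' Background RBPs place sites uniformly at \code{background_rate} per kb
#' of intron; the planted regulator's rate is multiplied by
#' \code{enrichment} inside changed (up/down) introns. Site placement is
#' uniform within the intron.
#'
#' @param config A \code{\link{sim_config}}.
#' @param genome A \code{sim_genome}.
#' @param seed Integer seed (own stream).
#' @return List: \code{sites} (\code{GRanges} with \code{rbp}) and
#'   \code{manifest} (data.frame of true per-RBP rates).
#' @export
simulate_rbp_sites <- function(config, genome, seed) {
  set.seed(seed)
  rb <- config$rbp
  rbps <- c(rb$planted,
            if (rb$n_decoys > 0) sprintf("RBP_D%02d", seq_len(rb$n_decoys)))
  records <- genome$records
  rows <- list()
  manifest <- list()
  for (r in rbps) {
    planted <- identical(r, rb$planted)
    for (i in seq_len(nrow(records))) {
      len_kb <- records$length[i] / 1e3
      rate <- rb$background_rate *
        if (planted && records$class[i] %in% c("up", "down"))
          rb$enrichment else 1
      n <- stats::rpois(1L, rate * len_kb)
      if (n == 0L) next
      w <- min(rb$site_width, records$length[i])
      s <- sort(sample(seq(records$start[i], records$end[i] - w + 1L), n,
                       replace = TRUE))
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = records$chrom[i], start = s, end = s + w - 1L, rbp = r,
        stringsAsFactors = FALSE
      )
    }
    manifest[[length(manifest) + 1L]] <- data.frame(
      rbp = r, planted = planted,
      base_rate = rb$background_rate,
      enrichment = if (planted) rb$enrichment else 1,
      stringsAsFactors = FALSE
    )
  }
  sites <- if (length(rows)) {
    d <- do.call(rbind, rows)
    GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$start, d$end),
                           rbp = d$rbp, source = "simulated")
  } else {
    GenomicRanges::GRanges(rbp = character(0), source = character(0))
  }
  list(sites = sites, manifest = do.call(rbind, manifest))
}

#' Simulate RBP expression across senescence models
#'
#' Per model and RBP, replicate RPKM values for an early and a late
#' passage. The planted regulator drops \code{planted_fold}-fold in the
#' first \code{drop_models} models; decoys stay flat. Noise is Gaussian
#' with coefficient of variation \code{expr_cv}.
#'
#' @param config A \code{\link{sim_config}}.
#' @param seed Integer seed (own stream).
#' @return Named list (one data.frame per model) with columns \code{rbp},
#'   \code{passage}, \code{replicate}, \code{rpkm}.
#' @export
simulate_rbp_expression <- function(config, seed) {
  set.seed(seed)
  rb <- config$rbp
  rbps <- c(rb$planted,
            if (rb$n_decoys > 0) sprintf("RBP_D%02d", seq_len(rb$n_decoys)))
  out <- list()
  for (m_idx in seq_along(rb$models)) {
    m <- rb$models[m_idx]
    rows <- list()
    for (r in rbps) {
      planted <- identical(r, rb$planted)
      base <- if (planted) rb$planted_rpkm else
        rb$decoy_rpkm * exp(stats::rnorm(1, 0, 0.2))
      late_level <- if (planted && m_idx <= rb$drop_models)
        base / rb$planted_fold else base
      for (p in c("early", "late")) {
        level <- if (p == "early") base else late_level
        vals <- pmax(0, stats::rnorm(rb$expr_replicates, level,
                                     rb$expr_cv * level))
        rows[[length(rows) + 1L]] <- data.frame(
          rbp = r, passage = p, replicate = seq_len(rb$expr_replicates),
          rpkm = vals, stringsAsFactors = FALSE
        )
      }
    }
    out[[m]] <- do.call(rbind, rows)
  }
  out
}

#' Simulate a complete dataset
#'
#' Orchestrates genome, trajectories, coverage, binding sites and RBP
#' expression. Each stage draws from its own RNG stream seeded at a fixed
#' offset from the master seed, so adding an RBP cannot perturb coverage.
#'
#' @param config A \code{\link{sim_config}}.
#' @param seed Master integer seed (keep below 2^31 - 5).
#' @return List of class \code{sim_dataset} with components
#'   \code{config}, \code{seed}, \code{genome}, \code{truth},
#'   \code{tracks}, \code{design}, \code{sites}, \code{site_manifest},
#'   \code{rbp_expression}.
#' @export
simulate_dataset <- function(config = sim_config(), seed = 1) {
  genome <- simulate_genome(config, seed)
  truth <- simulate_ir_trajectories(config, genome, seed + 1L)
  cov <- simulate_coverage(config, genome, truth, seed + 2L)
  sites <- simulate_rbp_sites(config, genome, seed + 3L)
  expr <- simulate_rbp_expression(config, seed + 4L)
  structure(
    list(config = config, seed = seed, genome = genome, truth = truth,
         tracks = cov$tracks, design = cov$design, sites = sites$sites,
         site_manifest = sites$manifest, rbp_expression = expr),
    class = "sim_dataset"
  )
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("sim_dataset:", nrow(x$genome$genes), "genes,",
      nrow(x$genome$records), "introns,",
      length(x$tracks), "samples, gamma =", x$config$gamma,
      ", seed =", x$seed, "\n")
  invisible(x)
}
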