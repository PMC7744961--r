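#' Load RBP binding sites from a BED file
#'
#' Expects BED with at least 4 columns; column 4 names the RBP. BED
#' coordinates (0-based half-open) are converted to 1-based closed.
#' Records with start >= end are dropped with a warning; non-numeric
#' coordinates raise an error naming the line.
#'
#' @param path BED file path.
#' @param source Optional source tag stored with every site (e.g.
#'   \code{"eCLIP"}).
#' @return A \code{GenomicRanges::GRanges} with metadata columns
#'   \code{rbp} and \code{source}.
#' @export
load_binding_sites <- function(path, source = NA_character_) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (!length(lines)) {
    return(GenomicRanges::GRanges(rbp = character(0),
                                  source = character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_bad <- 0L
  rows <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 4L) {
      stop("malformed BED record at line ", i, ": expected >= 4 columns")
    }
    s <- suppressWarnings(as.integer(f[2L]))
    e <- suppressWarnings(as.integer(f[3L]))
    if (is.na(s) || is.na(e)) {
      stop("malformed BED record at line ", i, ": non-numeric coordinates")
    }
    if (s >= e) {
      n_bad <- n_bad + 1L
      next
    }
    rows[[i]] <- data.frame(
      chrom = f[1L], start = s + 1L, end = e, rbp = f[4L],
      strand = if (length(f) >= 6L && f[6L] %in% c("+", "-")) f[6L] else "*",
      stringsAsFactors = FALSE
    )
  }
  if (n_bad > 0L) {
    warning("rejected ", n_bad, " BED record(s) with start >= end")
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(GenomicRanges::GRanges(rbp = character(0),
                                  source = character(0)))
  }
  d <- do.call(rbind, rows)
  GenomicRanges::GRanges(
    seqnames = d$chrom,
    ranges = IRanges::IRanges(start = d$start, end = d$end),
    strand = d$strand, rbp = d$rbp, source = source
  )
}

.records_granges <- function(records, which = c("intron", "flanks")) {
  which <- match.arg(which)
  if (which == "intron") {
    GenomicRanges::GRanges(records$chrom,
                           IRanges::IRanges(records$start, records$end))
  } else {
    GenomicRanges::GRanges(
      rep(records$chrom, 2L),
      IRanges::IRanges(c(records$flank_up_start, records$flank_down_start),
                       c(records$flank_up_end, records$flank_down_end))
    )
  }
}

#' Binding-site density over introns
#'
#' Counts sites overlapping each intron by at least 1 bp (strand-blind)
#' and reports the density per kilobase of intron length.
#'
#' @param sites \code{GRanges} from \code{\link{load_binding_sites}}.
#' @param records Intron record data.frame.
#' @param rbp One RBP name, or \code{"all"} to pool every site.
#' @return data.frame: \code{rbp}, \code{intron_id}, \code{n_sites},
#'   \code{density} (sites per kb).
#' @export
binding_density <- function(sites, records, rbp = "all") {
  if (!nrow(records)) {
    return(data.frame(rbp = character(0), intron_id = character(0),
                      n_sites = integer(0), density = numeric(0)))
  }
  gr <- .records_granges(records, "intron")
  rbps <- if (identical(rbp, "all")) "all" else rbp
  out <- lapply(rbps, function(r) {
    sub <- if (identical(r, "all")) sites else sites[sites$rbp == r]
    n <- GenomicRanges::countOverlaps(gr, sub, ignore.strand = TRUE)
    data.frame(rbp = r, intron_id = records$intron_id, n_sites = n,
               density = n / (records$length / 1e3),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Screening thresholds for the RBP candidate screen
#'
#' @param alpha Binding-density Wilcoxon significance level (default
#'   0.05; one-sided greater).
#' @param expr_alpha Expression-difference t-test level (default 0.05).
#' @param min_models Minimum number of senescence models with a
#'   significant early/late expression difference (default 2).
#' @param expr_floor Expression floor in RPKM (default 10; strict
#'   inequality, tested in the designated model's passages).
#' @param retained_labels Intron labels counted as "retained" for the
#'   density contrast (default change_IR plus stable_IR).
#' @return A list of class \code{screen_config}.
#' @export
screen_config <- function(alpha = 0.05, expr_alpha = 0.05, min_models = 2,
                          expr_floor = 10,
                          retained_labels = c("up_IR", "down_IR",
                                              "stable_IR")) {
  stopifnot(alpha > 0, alpha < 1, expr_alpha > 0, expr_alpha < 1)
  structure(list(alpha = alpha, expr_alpha = expr_alpha,
                 min_models = min_models, expr_floor = expr_floor,
                 retained_labels = retained_labels),
            class = "screen_config")
}

#' Screen for candidate IR-regulating RBPs
#'
#' An RBP is a candidate iff it meets all three criteria:
#' \enumerate{
#'   \item its binding density is significantly higher in retained introns
#'     (labels in \code{config$retained_labels}) than in spliced (no_IR)
#'     introns, one-sided Wilcoxon rank-sum p < alpha, in \emph{every}
#'     supplied dataset;
#'   \item its expression differs significantly between earlier and later
#'     passages (two-sided t-test on replicates) in at least
#'     \code{min_models} of the supplied senescence models;
#'   \item its expression exceeds \code{expr_floor} RPKM in at least one
#'     passage of the designated floor model.
#' }
#'
#' @param datasets Named list; each element is a list with
#'   \code{densities} (data.frame \code{rbp}, \code{intron_id},
#'   \code{density}) and \code{labels} (data.frame \code{intron_id},
#'   \code{label}).
#' @param expression Named list of senescence models; each a data.frame
#'   with columns \code{rbp}, \code{passage} (\code{"early"} or
#'   \code{"late"}), \code{replicate}, \code{rpkm}.
#' @param config A \code{\link{screen_config}}.
#' @param floor_model Name of the model used for criterion 3 (default:
#'   first model).
#' @return data.frame with one row per RBP: per-criterion pass flags and
#'   statistics, and \code{candidate} (all three).
#' @export
rbp_candidate_screen <- function(datasets, expression,
                                 config = screen_config(),
                                 floor_model = NULL) {
  stopifnot(length(datasets) >= 1L, length(expression) >= 2L)
  if (is.null(floor_model)) floor_model <- names(expression)[1L]
  if (!floor_model %in% names(expression)) {
    stop("missing expression table for model: ", floor_model)
  }
  rbps <- sort(unique(unlist(lapply(datasets,
                                    function(d) unique(d$densities$rbp)))))
  res <- vector("list", length(rbps))
  for (j in seq_along(rbps)) {
    r <- rbps[j]
    # criterion 1: density contrast in every dataset
    p1 <- vapply(datasets, function(d) {
      den <- d$densities[d$densities$rbp == r, ]
      lab <- d$labels$label[match(den$intron_id, d$labels$intron_id)]
      a <- den$density[lab %in% config$retained_labels]
      b <- den$density[lab == "no_IR"]
      if (length(a) < 3L || length(b) < 3L) return(NA_real_)
      suppressWarnings(
        stats::wilcox.test(a, b, alternative = "greater")$p.value)
    }, numeric(1))
    crit1 <- length(p1) > 0L && !anyNA(p1) && all(p1 < config$alpha)
    # criterion 2: expression shift in >= min_models models
    p2 <- vapply(expression, function(tab) {
      sub <- tab[tab$rbp == r, ]
      a <- sub$rpkm[sub$passage == "early"]
      b <- sub$rpkm[sub$passage == "late"]
      if (length(a) < 2L || length(b) < 2L) return(NA_real_)
      if (stats::sd(c(a, b)) == 0) return(1)
      stats::t.test(a, b, var.equal = TRUE)$p.value
    }, numeric(1))
    n_sig <- sum(p2 < config$expr_alpha, na.rm = TRUE)
    crit2 <- n_sig >= config$min_models
    # criterion 3: expression floor in the designated model
    ftab <- expression[[floor_model]]
    fsub <- ftab[ftab$rbp == r, ]
    pass_means <- if (nrow(fsub)) tapply(fsub$rpkm, fsub$passage, mean)
      else numeric(0)
    crit3 <- length(pass_means) > 0L && any(pass_means > config$expr_floor)
    res[[j]] <- data.frame(
      rbp = r, crit1_pass = crit1, crit1_max_p = suppressWarnings(max(p1)),
      crit2_pass = crit2, crit2_n_models = n_sig,
      crit3_pass = crit3,
      crit3_max_rpkm = if (length(pass_means)) max(pass_means) else NA_real_,
      candidate = crit1 && crit2 && crit3,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Screen for candidate target introns of one RBP
#'
#' An intron passes iff (1) it has a changed-IR label (up_IR or down_IR)
#' in both the replicative-senescence and the knockdown classification;
#' (2) its gene's expression log2FC in the knockdown comparison has the
#' opposite sign to its knockdown delta IRI; and (3) at least one binding
#' peak overlaps the intron or either flanking exon (>= 1 bp).
#'
#' @param class_replicative \code{classification_table} from the
#'   time-series (replicative senescence) design.
#' @param class_kd \code{classification_table} from the two-condition
#'   (knockdown) design; must carry \code{delta_iri}.
#' @param fc_kd Named expression log2 fold-change vector for the knockdown
#'   comparison.
#' @param peaks \code{GRanges} of the RBP's binding peaks.
#' @param records Intron record data.frame (for flank coordinates).
#' @return data.frame of passing introns sorted by |delta IRI| descending:
#'   \code{intron_id}, \code{gene_id}, \code{label_replicative},
#'   \code{label_kd}, \code{delta_iri}, \code{expr_log2fc},
#'   \code{n_peaks}.
#' @export
target_gene_screen <- function(class_replicative, class_kd, fc_kd, peaks,
                               records) {
  a <- as.data.frame(class_replicative)
  b <- as.data.frame(class_kd)
  mism <- c(setdiff(a$intron_id, b$intron_id),
            setdiff(b$intron_id, a$intron_id))
  if (length(mism)) {
    stop("intron universes disagree between classifications: ",
         paste(utils::head(mism, 5L), collapse = ", "),
         if (length(mism) > 5L) " ..." else "")
  }
  changed <- c("up_IR", "down_IR")
  d <- merge(a[, c("intron_id", "gene_id", "label")],
             b[, c("intron_id", "label", "delta_iri")],
             by = "intron_id", suffixes = c("_replicative", "_kd"))
  d <- d[d$label_replicative %in% changed & d$label_kd %in% changed, ,
         drop = FALSE]
  if (!nrow(d)) return(.empty_target_table())
  d$expr_log2fc <- unname(fc_kd[d$gene_id])
  d <- d[!is.na(d$expr_log2fc) &
           sign(d$expr_log2fc) == -sign(d$delta_iri) &
           d$expr_log2fc != 0, , drop = FALSE]
  if (!nrow(d)) return(.empty_target_table())
  rec <- records[match(d$intron_id, records$intron_id), , drop = FALSE]
  region <- GenomicRanges::GRanges(
    rep(rec$chrom, 3L),
    IRanges::IRanges(
      c(rec$start, rec$flank_up_start, rec$flank_down_start),
      c(rec$end, rec$flank_up_end, rec$flank_down_end))
  )
  hits <- GenomicRanges::countOverlaps(region, peaks, ignore.strand = TRUE)
  n <- nrow(d)
  d$n_peaks <- hits[seq_len(n)] + hits[n + seq_len(n)] +
    hits[2L * n + seq_len(n)]
  d <- d[d$n_peaks >= 1L, , drop = FALSE]
  d <- d[order(-abs(d$delta_iri), d$intron_id), ]
  rownames(d) <- NULL
  d[, c("intron_id", "gene_id", "label_replicative", "label_kd",
        "delta_iri", "expr_log2fc", "n_peaks")]
}

.empty_target_table <- function() {
  data.frame(intron_id = character(0), gene_id = character(0),
             label_replicative = character(0), label_kd = character(0),
             delta_iri = numeric(0), expr_log2fc = numeric(0),
             n_peaks = integer(0), stringsAsFactors = FALSE)
}
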