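#' Classifier thresholds
#'
#' @param retention_cutoff IRI at or above which an intron counts as
#'   retained (default 0.1).
#' @param change_cutoff Minimum IRI range (time series) or |delta IRI|
#'   (two conditions) for a change call (default 0.1).
#' @param corr_cutoff Pearson correlation magnitude against the monotone
#'   reference required for an up/down call (default 0.7).
#' @param alpha Two-condition t-test significance level (default 0.05).
#' @return A list of class \code{classifier_config}.
#' @export
classifier_config <- function(retention_cutoff = 0.1, change_cutoff = 0.1,
                              corr_cutoff = 0.7, alpha = 0.05) {
  cfg <- list(retention_cutoff = retention_cutoff,
              change_cutoff = change_cutoff,
              corr_cutoff = corr_cutoff, alpha = alpha)
  if (any(unlist(cfg) <= 0) || any(unlist(cfg) >= 1)) {
    stop("all classifier thresholds must lie in (0, 1)")
  }
  class(cfg) <- "classifier_config"
  cfg
}

#' Monotone reference sequence
#'
#' The reference vector L against which a time-series IRI vector is
#' correlated: length n, first value 0, last value 1, constant step
#' 1/(n-1). A trajectory rising steadily across the time course correlates
#' near +1 with L; a steadily falling one near -1.
#'
#' @param n Number of time points (>= 2).
#' @return Numeric vector of length \code{n}.
#' @export
monotone_reference <- function(n) {
  if (n < 2) stop("monotone reference needs n >= 2 time points")
  seq(0, 1, length.out = n)
}

#' Classify one time-series IRI trajectory
#'
#' Rules, applied strictly in order:
#' \enumerate{
#'   \item max(X) < retention_cutoff: never retained, \code{no_IR};
#'   \item max(X) - min(X) < change_cutoff: retained but unchanging,
#'     \code{stable_IR};
#'   \item Pearson Cor(X, L) > corr_cutoff: \code{up_IR};
#'   \item Cor(X, L) < -corr_cutoff: \code{down_IR};
#'   \item otherwise irregular, \code{discarded}.
#' }
#'
#' @param X Complete numeric IRI vector (one value per time point, group
#'   means when replicates exist), all values in [0, 1].
#' @param config A \code{\link{classifier_config}}.
#' @return List: \code{label}, \code{max_minus_min}, \code{cor_with_L}.
#' @export
classify_timeseries <- function(X, config = classifier_config()) {
  if (anyNA(X)) stop("IRI vector contains missing values; filter first")
  if (any(X < 0 | X > 1)) stop("IRI values must lie in [0, 1]")
  rng <- max(X) - min(X)
  if (max(X) < config$retention_cutoff) {
    return(list(label = "no_IR", max_minus_min = rng, cor_with_L = NA_real_))
  }
  if (rng < config$change_cutoff) {
    return(list(label = "stable_IR", max_minus_min = rng,
                cor_with_L = NA_real_))
  }
  if (stats::sd(X) == 0) { # unreachable after rule 2; guard anyway
    return(list(label = "discarded", max_minus_min = rng,
                cor_with_L = NA_real_))
  }
  r <- stats::cor(X, monotone_reference(length(X)))
  label <- if (r > config$corr_cutoff) "up_IR"
    else if (r < -config$corr_cutoff) "down_IR"
    else "discarded"
  list(label = label, max_minus_min = rng, cor_with_L = r)
}

#' Classify one intron between two conditions
#'
#' delta IRI is mean(repsB) - mean(repsA); the p-value comes from a
#' two-sided pooled-variance (Student) two-sample t-test on the replicate
#' values. Rules in order: \code{no_IR} if both condition means fall below
#' the retention cutoff; \code{stable_IR} if |delta| < change_cutoff;
#' \code{up_IR}/\code{down_IR} if delta >= change_cutoff (resp. <=
#' -change_cutoff) with p < alpha; otherwise \code{discarded}.
#'
#' @param repsA,repsB Replicate IRI values for the reference and contrast
#'   condition (>= 2 each, values in [0, 1]).
#' @param config A \code{\link{classifier_config}}.
#' @return List: \code{label}, \code{delta_iri}, \code{p_value},
#'   \code{mean_a}, \code{mean_b}.
#' @export
classify_two_condition <- function(repsA, repsB,
                                   config = classifier_config()) {
  if (length(repsA) < 2L || length(repsB) < 2L) {
    stop("need >= 2 replicates per condition for the t-test")
  }
  if (any(c(repsA, repsB) < 0 | c(repsA, repsB) > 1)) {
    stop("IRI values must lie in [0, 1]")
  }
  ma <- mean(repsA)
  mb <- mean(repsB)
  delta <- mb - ma
  # degenerate replicates: no within-group variance, so the t statistic is
  # undefined (0/0) or infinite; treat identical means as p=1, else p=0
  p <- if (stats::var(repsA) == 0 && stats::var(repsB) == 0) {
    if (delta == 0) 1 else 0
  } else {
    stats::t.test(repsB, repsA, var.equal = TRUE)$p.value
  }
  label <- if (ma < config$retention_cutoff && mb < config$retention_cutoff) {
    "no_IR"
  } else if (abs(delta) < config$change_cutoff) {
    "stable_IR"
  } else if (delta >= config$change_cutoff && p < config$alpha) {
    "up_IR"
  } else if (delta <= -config$change_cutoff && p < config$alpha) {
    "down_IR"
  } else {
    "discarded"
  }
  list(label = label, delta_iri = delta, p_value = p,
       mean_a = ma, mean_b = mb)
}

# ordered group levels for a time-series design
.design_group_levels <- function(design) {
  g <- design$group
  if (is.factor(g)) return(levels(g)[levels(g) %in% as.character(g)])
  u <- unique(as.character(g))
  num <- suppressWarnings(as.numeric(gsub("[^0-9.]", "", u)))
  if (anyNA(num) || anyDuplicated(num)) {
    stop("time-series design groups must be an ordered factor or carry a ",
         "unique numeric time component (e.g. PD16, PD26, ...)")
  }
  u[order(num)]
}

#' Classify every intron of a filtered IRI matrix
#'
#' In \code{"timeseries"} mode, replicate IRI values are averaged per time
#' point (design groups in factor-level or numeric order) and each intron's
#' trajectory goes through \code{\link{classify_timeseries}}. In
#' \code{"two_condition"} mode the design must have exactly two groups and
#' each intron goes through \code{\link{classify_two_condition}} (group A =
#' first level = reference).
#'
#' @param matrix A filtered \code{iri_matrix} (see
#'   \code{\link{apply_iri_filters}}).
#' @param mode \code{"timeseries"} or \code{"two_condition"}.
#' @param config A \code{\link{classifier_config}}.
#' @return A \code{classification_table} data.frame with one row per
#'   intron: \code{intron_id}, \code{gene_id}, \code{label}, per-time-point
#'   means (\code{X1..Xn}) or condition means, and the supporting
#'   statistics. Label counts are attached as attribute \code{counts}.
#' @export
classify_all <- function(matrix, mode = c("timeseries", "two_condition"),
                         config = classifier_config()) {
  mode <- match.arg(mode)
  design <- matrix$design
  wide <- iri_wide(matrix)
  gene_of <- matrix$records$gene_id[match(rownames(wide),
                                          matrix$records$intron_id)]
  if (mode == "timeseries") {
    lev <- .design_group_levels(design)
    res <- vector("list", nrow(wide))
    for (i in seq_len(nrow(wide))) {
      X <- vapply(lev, function(g) {
        mean(wide[i, design$sample_id[as.character(design$group) == g]])
      }, numeric(1))
      cl <- classify_timeseries(X, config)
      row <- data.frame(intron_id = rownames(wide)[i], gene_id = gene_of[i],
                        label = cl$label, stringsAsFactors = FALSE)
      for (k in seq_along(X)) row[[paste0("X", k)]] <- X[[k]]
      row$max_minus_min <- cl$max_minus_min
      row$cor_with_L <- cl$cor_with_L
      res[[i]] <- row
    }
  } else {
    lev <- if (is.factor(design$group)) {
      levels(design$group)[levels(design$group) %in%
                             as.character(design$group)]
    } else unique(as.character(design$group))
    if (length(lev) != 2L) {
      stop("two-condition mode needs exactly 2 design groups, got ",
           length(lev))
    }
    res <- vector("list", nrow(wide))
    for (i in seq_len(nrow(wide))) {
      a <- wide[i, design$sample_id[as.character(design$group) == lev[1L]]]
      b <- wide[i, design$sample_id[as.character(design$group) == lev[2L]]]
      cl <- classify_two_condition(a, b, config)
      res[[i]] <- data.frame(
        intron_id = rownames(wide)[i], gene_id = gene_of[i],
        label = cl$label, mean_a = cl$mean_a, mean_b = cl$mean_b,
        delta_iri = cl$delta_iri, p_value = cl$p_value,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(intron_id = character(0), gene_id = character(0),
               label = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  labs <- c("no_IR", "stable_IR", "up_IR", "down_IR", "discarded")
  attr(out, "counts") <- vapply(labs, function(l) sum(out$label == l),
                                integer(1))
  attr(out, "mode") <- mode
  attr(out, "test") <- if (mode == "two_condition")
    "two-sided pooled-variance t-test" else "pearson-vs-monotone-reference"
  class(out) <- c("classification_table", "data.frame")
  out
}
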