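#' Run the retention pipeline end to end
#'
#' Annotation reduction -> IRI quantification and filtering ->
#' trajectory classification -> gene-level expression association
#' (-> binding-density contrast when sites are supplied). Accepts either a
#' fixture-bundle directory or in-memory components. Writes stage TSVs and
#' a JSON run report with per-stage counts when \code{out_dir} is given.
#'
#' @param bundle_dir Fixture bundle directory
#'   (\code{\link{write_fixture_bundle}}); alternative to passing
#'   components.
#' @param models,tracks,design,sites In-memory inputs (used when
#'   \code{bundle_dir} is \code{NULL}).
#' @param mode \code{"timeseries"} or \code{"two_condition"}.
#' @param config A \code{\link{classifier_config}}.
#' @param read_length Read length for FPKM conversion.
#' @param pseudocount_fpkm,pseudocount_iri Fold-change pseudocounts.
#' @param out_dir Optional output directory for stage TSVs and
#'   \code{run_report.json}.
#' @return List of class \code{pipeline_result}: \code{records},
#'   \code{iri} (filtered \code{iri_matrix}), \code{filter_report},
#'   \code{classification}, \code{gene_classes}, \code{expression},
#'   \code{fc}, \code{bins} (\code{NULL} when fewer than 8 genes
#'   qualify), \code{binding} (when sites given), \code{report}.
#' @export
run_pipeline <- function(bundle_dir = NULL, models = NULL, tracks = NULL,
                         design = NULL, sites = NULL,
                         mode = c("timeseries", "two_condition"),
                         config = classifier_config(), read_length = 100,
                         pseudocount_fpkm = 0.1, pseudocount_iri = 0.01,
                         out_dir = NULL) {
  mode <- match.arg(mode)
  if (!is.null(bundle_dir)) {
    if (!dir.exists(bundle_dir)) stop("bundle directory not found: ",
                                      bundle_dir)
    bundle <- read_fixture_bundle(bundle_dir)
    models <- bundle$models
    tracks <- bundle$tracks
    design <- bundle$design
    if (is.null(sites) && length(bundle$sites)) sites <- bundle$sites
  }
  if (is.null(models) || is.null(tracks) || is.null(design)) {
    stop("run_pipeline needs models, tracks and design ",
         "(or a bundle_dir providing them)")
  }
  shared_list <- lapply(models, compute_shared_regions)
  records <- do.call(rbind, lapply(shared_list, build_intron_records))
  rownames(records) <- NULL
  im <- build_iri_matrix(tracks, records, design,
                         retention_cutoff = config$retention_cutoff,
                         change_cutoff = config$change_cutoff)
  filt <- apply_iri_filters(im)
  classification <- classify_all(filt$matrix, mode = mode, config = config)
  gene_classes <- gene_level_classes(classification)
  expr <- expression_table(tracks, shared_list, read_length)
  lev <- if (is.factor(design$group)) levels(design$group) else
    unique(as.character(design$group))
  groupA <- lev[1L]
  groupB <- lev[length(lev)]
  fc <- expression_change(expr, design, groupA, groupB,
                          pseudocount = pseudocount_fpkm)
  bins <- tryCatch(
    iri_fc_binning(filt$matrix, fc, groupA, groupB,
                   delta = pseudocount_iri),
    error = function(e) NULL
  )
  binding <- if (!is.null(sites) && length(sites)) {
    den <- do.call(rbind, lapply(unique(sites$rbp), function(r)
      binding_density(sites, filt$matrix$records, r)))
    labels <- data.frame(intron_id = classification$intron_id,
                         label = classification$label,
                         stringsAsFactors = FALSE)
    list(densities = den, labels = labels)
  } else NULL
  counts <- attr(classification, "counts")
  report <- list(
    mode = mode,
    thresholds = unclass(config),
    n_introns_annotated = nrow(records),
    n_flankless_dropped = sum(vapply(
      lapply(shared_list, build_intron_records),
      function(r) attr(r, "n_dropped"), integer(1))),
    filter = as.list(filt$report),
    labels = as.list(counts),
    n_genes_expressed = length(filter_expressed(expr, design)),
    contrast = list(groupA = groupA, groupB = groupB),
    bin_trend_rho = if (!is.null(bins)) bins$rho else NA_real_
  )
  result <- structure(
    list(records = records, iri = filt$matrix,
         filter_report = filt$report, classification = classification,
         gene_classes = gene_classes, expression = expr, fc = fc,
         bins = bins, binding = binding, report = report),
    class = "pipeline_result"
  )
  if (!is.null(out_dir)) .write_pipeline_outputs(result, out_dir)
  result
}

.write_pipeline_outputs <- function(result, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  w <- function(d, name) {
    utils::write.table(d, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  w(result$iri$cells, "iri_matrix.tsv")
  w(as.data.frame(result$classification), "classification.tsv")
  w(result$expression, "expression_fpkm.tsv")
  w(data.frame(gene_id = names(result$fc), log2fc = unname(result$fc)),
    "expression_log2fc.tsv")
  if (!is.null(result$bins)) w(result$bins$bins, "iri_fc_bins.tsv")
  if (!is.null(result$binding)) w(result$binding$densities,
                                  "binding_density.tsv")
  jsonlite::write_json(result$report,
                       file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result (", x$report$mode, ")\n", sep = "")
  cat("  introns annotated:", x$report$n_introns_annotated, "\n")
  cat("  filter:", paste(names(x$filter_report), x$filter_report,
                         sep = "=", collapse = ", "), "\n")
  cat("  labels:", paste(names(x$report$labels), unlist(x$report$labels),
                         sep = "=", collapse = ", "), "\n")
  if (!is.null(x$bins)) {
    cat("  8-bin trend rho:", format(x$bins$rho, digits = 3), "\n")
  }
  invisible(x)
}
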