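#' Lift intron labels to gene-level class sets
#'
#' A gene belongs to \code{up_IR} if at least one of its introns is
#' up_IR (likewise down_IR and stable_IR); it belongs to \code{no_IR}
#' only if every one of its classified introns is no_IR.
#' \code{change_IR} is the union of up_IR and down_IR genes (a gene with
#' one up and one down intron is counted once).
#'
#' @param classification A \code{classification_table}.
#' @return A list of character vectors: \code{up_IR}, \code{down_IR},
#'   \code{stable_IR}, \code{no_IR}, \code{change_IR}.
#' @export
gene_level_classes <- function(classification) {
  d <- as.data.frame(classification)
  one <- function(lab) sort(unique(d$gene_id[d$label == lab]))
  up <- one("up_IR")
  down <- one("down_IR")
  stable <- one("stable_IR")
  all_no <- vapply(split(d$label, d$gene_id),
                   function(l) all(l == "no_IR"), logical(1))
  list(up_IR = up, down_IR = down, stable_IR = stable,
       no_IR = sort(names(all_no)[all_no]),
       change_IR = sort(union(up, down)))
}

#' Per-gene expression log2 fold change between two groups
#'
#' log2((mean_B + pseudocount) / (mean_A + pseudocount)) of group-mean
#' FPKM, for the genes passing \code{\link{filter_expressed}} (or an
#' explicit gene set).
#'
#' @param expr Expression table (\code{gene_id}, \code{sample_id},
#'   \code{fpkm}).
#' @param design Sample design data.frame.
#' @param groupA,groupB Reference and contrast group labels.
#' @param pseudocount FPKM pseudocount (default 0.1).
#' @param genes Optional character vector restricting the gene universe;
#'   default = expression-filtered genes.
#' @return Named numeric vector of log2 fold changes (names = gene ids).
#' @export
expression_change <- function(expr, design, groupA, groupB,
                              pseudocount = 0.1, genes = NULL) {
  groups <- unique(as.character(design$group))
  if (!all(c(groupA, groupB) %in% groups)) {
    stop("unknown group(s): ",
         paste(setdiff(c(groupA, groupB), groups), collapse = ", "))
  }
  if (is.null(genes)) genes <- filter_expressed(expr, design)
  expr$group <- as.character(design$group[match(expr$sample_id,
                                                design$sample_id)])
  gm <- function(g) {
    sub <- expr[expr$group == g & expr$gene_id %in% genes, ]
    tapply(sub$fpkm, sub$gene_id, mean)
  }
  ma <- gm(groupA)
  mb <- gm(groupB)
  genes <- intersect(names(ma), names(mb))
  fc <- log2((mb[genes] + pseudocount) / (ma[genes] + pseudocount))
  fc[order(names(fc))]
}

#' Expression fold-change contrast between IR gene classes
#'
#' Summarises the expression fold-change distribution per gene class and
#' tests the coupling predicted by faster decay of intron-retained
#' transcripts: genes gaining retention (up_IR) should shift down in
#' expression relative to no_IR genes (one-sided Wilcoxon rank-sum,
#' alternative "less"), and genes losing retention (down_IR) should shift
#' up (alternative "greater"). Classes with fewer than 3 genes in the fold
#' change table are summarised but not tested.
#'
#' @param classes Output of \code{\link{gene_level_classes}}.
#' @param fc Named log2 fold-change vector
#'   (\code{\link{expression_change}}).
#' @return List: \code{summary} (per-class n and median log2FC) and
#'   \code{tests} (data.frame: contrast, alternative, p_value, note).
#' @export
class_expression_contrast <- function(classes, fc) {
  vals <- lapply(classes, function(g) unname(fc[intersect(g, names(fc))]))
  summary <- data.frame(
    class = names(vals),
    n = vapply(vals, length, integer(1)),
    median_log2fc = vapply(vals, function(v)
      if (length(v)) stats::median(v) else NA_real_, numeric(1)),
    row.names = NULL
  )
  test_one <- function(a, b, alternative, label) {
    if (length(vals[[a]]) < 3L || length(vals[[b]]) < 3L) {
      return(data.frame(contrast = label, alternative = alternative,
                        p_value = NA_real_,
                        note = "skipped: <3 genes in a class"))
    }
    p <- stats::wilcox.test(vals[[a]], vals[[b]],
                            alternative = alternative, exact = FALSE)$p.value
    data.frame(contrast = label, alternative = alternative, p_value = p,
               note = "")
  }
  tests <- rbind(
    test_one("up_IR", "no_IR", "less", "up_IR vs no_IR"),
    test_one("down_IR", "no_IR", "greater", "down_IR vs no_IR")
  )
  list(summary = summary, tests = tests)
}

#' Gene-level IRI fold change between two groups
#'
#' Per gene, the classified intron with the largest |mean IRI_B - mean
#' IRI_A| represents the gene; its IRI fold change is
#' (mean_B + delta) / (mean_A + delta).
#'
#' @param matrix A filtered \code{iri_matrix}.
#' @param groupA,groupB Group labels in the matrix design.
#' @param delta IRI pseudocount (default 0.01).
#' @return data.frame: \code{gene_id}, \code{intron_id}, \code{iri_a},
#'   \code{iri_b}, \code{iri_fc}.
#' @export
gene_iri_fold_change <- function(matrix, groupA, groupB, delta = 0.01) {
  design <- matrix$design
  wide <- iri_wide(matrix)
  sa <- design$sample_id[as.character(design$group) == groupA]
  sb <- design$sample_id[as.character(design$group) == groupB]
  if (!length(sa) || !length(sb)) stop("unknown group(s) for IRI fold change")
  ma <- rowMeans(wide[, sa, drop = FALSE])
  mb <- rowMeans(wide[, sb, drop = FALSE])
  d <- data.frame(
    intron_id = rownames(wide),
    gene_id = matrix$records$gene_id[match(rownames(wide),
                                           matrix$records$intron_id)],
    iri_a = ma, iri_b = mb, adiff = abs(mb - ma),
    stringsAsFactors = FALSE
  )
  d <- d[order(d$gene_id, -d$adiff, d$intron_id), ]
  d <- d[!duplicated(d$gene_id), ]
  d$iri_fc <- (d$iri_b + delta) / (d$iri_a + delta)
  rownames(d) <- NULL
  d[, c("gene_id", "intron_id", "iri_a", "iri_b", "iri_fc")]
}

#' Bin genes by IRI fold change and trace median expression change
#'
#' Genes carrying both an IRI fold change and an expression fold change
#' are ranked by IRI fold change (ties broken by gene id, so binning is
#' deterministic) and split into \code{n_bins} equal-count bins. The trend
#' statistic is the Spearman correlation of bin index with per-bin median
#' expression log2FC; under degradation-coupled retention it is strongly
#' negative.
#'
#' @param matrix A filtered \code{iri_matrix}.
#' @param fc Named expression log2 fold-change vector.
#' @param groupA,groupB Group labels for the IRI fold change.
#' @param n_bins Number of bins (default 8).
#' @param delta IRI pseudocount (default 0.01).
#' @return List of class \code{bin_trend}: \code{bins} (data.frame with
#'   bin, n, iri_fc range, median log2FC), \code{rho}, \code{genes}
#'   (per-gene table with bin assignment).
#' @export
iri_fc_binning <- function(matrix, fc, groupA, groupB, n_bins = 8,
                           delta = 0.01) {
  gfc <- gene_iri_fold_change(matrix, groupA, groupB, delta)
  gfc <- gfc[gfc$gene_id %in% names(fc), ]
  n <- nrow(gfc)
  if (n < n_bins) {
    stop("only ", n, " genes with both fold changes; choose n_bins <= ", n)
  }
  gfc$expr_log2fc <- unname(fc[gfc$gene_id])
  gfc <- gfc[order(gfc$iri_fc, gfc$gene_id), ]
  gfc$bin <- ceiling(seq_len(n) * n_bins / n)
  bins <- do.call(rbind, lapply(split(gfc, gfc$bin), function(d) {
    data.frame(bin = d$bin[1L], n = nrow(d),
               iri_fc_min = min(d$iri_fc), iri_fc_max = max(d$iri_fc),
               median_log2fc = stats::median(d$expr_log2fc))
  }))
  rownames(bins) <- NULL
  rho <- stats::cor(bins$bin, bins$median_log2fc, method = "spearman")
  structure(list(bins = bins, rho = rho, genes = gfc), class = "bin_trend")
}

#' @export
print.bin_trend <- function(x, ...) {
  cat("bin_trend:", nrow(x$bins), "bins,", nrow(x$genes),
      "genes, Spearman rho =", format(x$rho, digits = 3), "\n")
  invisible(x)
}

#' Wilcoxon contrast of an intron feature between two classes
#'
#' Rank-sum test of a per-intron feature (GC content, length, binding
#' density, ...) between two label classes, with the requested sidedness.
#' \code{"change_IR"} means the union of up_IR and down_IR introns.
#'
#' @param feature_table data.frame with columns \code{label} and the named
#'   feature.
#' @param classA,classB Class labels to compare (classA is the first
#'   sample, so \code{alternative = "greater"} tests classA > classB).
#' @param feature Feature column name.
#' @param alternative \code{"greater"}, \code{"less"} or
#'   \code{"two.sided"}.
#' @return List: \code{p_value}, \code{n_a}, \code{n_b},
#'   \code{median_a}, \code{median_b}.
#' @export
feature_contrast <- function(feature_table, classA, classB, feature,
                             alternative = c("greater", "less",
                                             "two.sided")) {
  alternative <- match.arg(alternative)
  if (!feature %in% names(feature_table)) {
    stop("unknown feature: ", feature)
  }
  pick <- function(cl) {
    lab <- if (cl == "change_IR") c("up_IR", "down_IR") else cl
    feature_table[[feature]][feature_table$label %in% lab]
  }
  a <- pick(classA)
  b <- pick(classB)
  if (length(a) < 3L || length(b) < 3L) {
    stop("need >= 3 introns per class for the contrast")
  }
  # exact for small untied samples; normal approximation with tie
  # correction otherwise (ties are expected for discrete features)
  p <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = alternative)$p.value)
  list(p_value = p, n_a = length(a), n_b = length(b),
       median_a = stats::median(a), median_b = stats::median(b))
}

#' Overlap fraction of two gene sets
#'
#' Percentage of the reference set A found in B:
#' 100 * |A intersect B| / |A|, together with the overlap and A-only
#' counts.
#'
#' @param setA Reference set (character vector; nonempty).
#' @param setB Comparison set.
#' @return List: \code{n_overlap}, \code{n_A_only}, \code{percentage}.
#' @export
overlap_fraction <- function(setA, setB) {
  setA <- unique(setA)
  setB <- unique(setB)
  if (!length(setA)) stop("reference set A is empty")
  n_overlap <- length(intersect(setA, setB))
  list(n_overlap = n_overlap,
       n_A_only = length(setA) - n_overlap,
       percentage = 100 * n_overlap / length(setA))
}
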