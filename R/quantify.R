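#' Construct a coverage track
#'
#' A coverage track is the per-base read depth of one sample, stored as one
#' integer \code{Rle} per chromosome, plus the sample's total mapped read
#' count (used for FPKM scaling). Positions beyond the stored run length are
#' treated as depth 0.
#'
#' @param cov A named list (or \code{RleList}) of integer \code{Rle}
#'   vectors, one per chromosome.
#' @param sample_id Sample identifier.
#' @param total_mapped Total aligned reads in the sample (> 0).
#' @return An object of class \code{CoverageTrack}.
#' @export
coverage_track <- function(cov, sample_id, total_mapped) {
  stopifnot(total_mapped > 0)
  cov <- lapply(cov, function(x) {
    if (!methods::is(x, "Rle")) x <- S4Vectors::Rle(as.integer(x))
    if (any(S4Vectors::runValue(x) < 0L)) stop("negative depth in track")
    x
  })
  structure(list(sample_id = sample_id, cov = cov,
                 total_mapped = total_mapped),
            class = "CoverageTrack")
}

#' @export
print.CoverageTrack <- function(x, ...) {
  cat("CoverageTrack", x$sample_id, "-", length(x$cov), "chromosome(s),",
      format(x$total_mapped, big.mark = ","), "mapped reads\n")
  invisible(x)
}

#' Read a bedGraph file into a coverage track
#'
#' bedGraph intervals are 0-based half-open with a depth score; they are
#' expanded to a per-base run-length encoding. When \code{total_mapped} is
#' not given it is estimated as total base coverage divided by
#' \code{read_length}.
#'
#' @param path bedGraph file path.
#' @param sample_id Sample identifier (default: file base name).
#' @param total_mapped Total mapped reads, or \code{NULL} to estimate.
#' @param read_length Read length used for the estimate.
#' @return A \code{CoverageTrack}.
#' @export
read_bedgraph_track <- function(path, sample_id = NULL, total_mapped = NULL,
                                read_length = 100) {
  if (is.null(sample_id)) {
    sample_id <- sub("\\.bedgraph$", "", basename(path), ignore.case = TRUE)
  }
  gr <- suppressWarnings(rtracklayer::import(path, format = "bedGraph"))
  cov <- GenomicRanges::coverage(gr, weight = "score")
  cov <- lapply(as.list(cov), function(x) {
    S4Vectors::Rle(as.integer(round(S4Vectors::runValue(x))),
                   S4Vectors::runLength(x))
  })
  if (is.null(total_mapped)) {
    total_mapped <- max(1, round(sum(vapply(cov, function(x)
      sum(as.numeric(S4Vectors::runValue(x)) * S4Vectors::runLength(x)),
      numeric(1))) / read_length))
  }
  coverage_track(cov, sample_id, total_mapped)
}

#' Write a coverage track as bedGraph
#'
#' Zero-depth runs are omitted; output is 0-based half-open and
#' deterministic for a given track.
#'
#' @param track A \code{CoverageTrack}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_bedgraph_track <- function(track, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (chrom in names(track$cov)) {
    x <- track$cov[[chrom]]
    rl <- S4Vectors::runLength(x)
    rv <- S4Vectors::runValue(x)
    ends <- cumsum(as.numeric(rl))
    starts <- ends - rl # 0-based
    keep <- rv > 0L
    if (!any(keep)) next
    writeLines(sprintf("%s\t%d\t%d\t%d", chrom,
                       as.integer(starts[keep]), as.integer(ends[keep]),
                       as.integer(rv[keep])), con)
  }
  invisible(path)
}

# depth vector over a 1-based closed interval, padding beyond track with 0
.interval_depths <- function(track, chrom, start, end) {
  if (!chrom %in% names(track$cov)) {
    stop("chromosome '", chrom, "' absent from coverage track ",
         track$sample_id)
  }
  x <- track$cov[[chrom]]
  n <- length(x)
  if (start > n) return(integer(end - start + 1L))
  upper <- min(end, n)
  d <- if (is.integer(x)) x[start:upper] else
    as.integer(S4Vectors::window(x, start, upper))
  if (end > n) d <- c(d, integer(end - n))
  d
}

# decode the Rle runs to plain integer vectors for fast repeated slicing
.decode_track <- function(track) {
  track$cov <- lapply(track$cov, function(x) {
    if (is.integer(x)) x else as.integer(x)
  })
  track
}

#' Mean read depth over an interval
#'
#' "Read density" of a region: the sum of per-base depths divided by the
#' region length, in reads per base.
#'
#' @param track A \code{CoverageTrack}.
#' @param chrom Chromosome name.
#' @param start,end 1-based closed interval bounds.
#' @return Mean depth (numeric scalar).
#' @export
region_density <- function(track, chrom, start, end) {
  stopifnot(end >= start)
  sum(as.numeric(.interval_depths(track, chrom, start, end))) /
    (end - start + 1)
}

#' Fraction of interval bases with non-zero depth
#'
#' Used for the coverage-completeness filter: introns whose covered
#' fraction falls below 0.5 in a sample are not quantifiable there.
#'
#' @inheritParams region_density
#' @return Fraction in [0, 1].
#' @export
covered_fraction <- function(track, chrom, start, end) {
  stopifnot(end >= start)
  d <- .interval_depths(track, chrom, start, end)
  sum(d >= 1L) / length(d)
}

#' Intron retention index of one intron in one sample
#'
#' IRI is the ratio of the intron's read density to the pooled read density
#' of its two flanking shared exonic segments (one denominator: summed
#' depths over both flanks divided by their summed length). The value is
#' missing when the pooled flank density is zero (\code{zero_flank}) or the
#' intron's covered fraction is below \code{min_covered}
#' (\code{low_coverage}). Values above 1 are computed and flagged
#' \code{iri_gt1}; row-level discarding happens in
#' \code{\link{apply_iri_filters}}.
#'
#' @param track A \code{CoverageTrack}.
#' @param record One intron record row (from
#'   \code{\link{build_intron_records}}).
#' @param min_covered Minimum covered fraction of the intron (default 0.5).
#' @return A one-row data.frame: \code{intron_id}, \code{sample_id},
#'   \code{intron_density}, \code{flank_density}, \code{covered_fraction},
#'   \code{iri}, and logical flags \code{low_coverage}, \code{zero_flank},
#'   \code{iri_gt1}.
#' @export
compute_iri <- function(track, record, min_covered = 0.5) {
  stopifnot(nrow(record) == 1L)
  chrom <- record$chrom
  idep <- .interval_depths(track, chrom, record$start, record$end)
  intron_density <- sum(as.numeric(idep)) / length(idep)
  covfrac <- sum(idep >= 1L) / length(idep)
  f1 <- .interval_depths(track, chrom, record$flank_up_start,
                         record$flank_up_end)
  f2 <- .interval_depths(track, chrom, record$flank_down_start,
                         record$flank_down_end)
  flank_density <- (sum(as.numeric(f1)) + sum(as.numeric(f2))) /
    (length(f1) + length(f2))
  zero_flank <- flank_density == 0
  low_coverage <- covfrac < min_covered
  iri <- if (zero_flank || low_coverage) NA_real_ else
    intron_density / flank_density
  data.frame(
    intron_id = record$intron_id, sample_id = track$sample_id,
    intron_density = intron_density, flank_density = flank_density,
    covered_fraction = covfrac, iri = iri,
    low_coverage = low_coverage, zero_flank = zero_flank,
    iri_gt1 = !is.na(iri) && iri > 1,
    stringsAsFactors = FALSE
  )
}

#' Quantify IRI for all introns across all samples
#'
#' @param tracks List of \code{CoverageTrack} objects.
#' @param records Intron record data.frame.
#' @param design Sample design data.frame with columns \code{sample_id},
#'   \code{group}, \code{replicate} (and optionally \code{total_mapped});
#'   (group, replicate) pairs must be unique.
#' @param retention_cutoff IRI at or above which an intron counts as
#'   retained (default 0.1).
#' @param change_cutoff Minimum IRI range/difference for a change call
#'   (default 0.1).
#' @param min_covered Coverage-completeness threshold passed to
#'   \code{\link{compute_iri}}.
#' @return An object of class \code{iri_matrix}: list with \code{cells}
#'   (long data.frame of per intron x sample records), \code{records},
#'   \code{design} and the cutoffs.
#' @export
build_iri_matrix <- function(tracks, records, design,
                             retention_cutoff = 0.1, change_cutoff = 0.1,
                             min_covered = 0.5) {
  stopifnot(retention_cutoff > 0, retention_cutoff < 1,
            change_cutoff > 0, change_cutoff < 1)
  if (anyDuplicated(design[, c("group", "replicate")])) {
    stop("design has duplicated (group, replicate) pairs")
  }
  ids <- vapply(tracks, function(t) t$sample_id, character(1))
  missing <- setdiff(design$sample_id, ids)
  if (length(missing)) {
    stop("no coverage track for sample(s): ", paste(missing, collapse = ", "))
  }
  tracks <- tracks[match(design$sample_id, ids)]
  n_rec <- nrow(records)
  n_tr <- length(tracks)
  n <- n_rec * n_tr
  intron_id <- character(n)
  sample_id <- character(n)
  intron_density <- numeric(n)
  flank_density <- numeric(n)
  covfrac <- numeric(n)
  iri <- numeric(n)
  low_coverage <- logical(n)
  zero_flank <- logical(n)
  for (k in seq_len(n_tr)) {
    tr <- .decode_track(tracks[[k]])
    off <- (k - 1L) * n_rec
    for (i in seq_len(n_rec)) {
      idep <- .interval_depths(tr, records$chrom[i], records$start[i],
                               records$end[i])
      f1 <- .interval_depths(tr, records$chrom[i],
                             records$flank_up_start[i],
                             records$flank_up_end[i])
      f2 <- .interval_depths(tr, records$chrom[i],
                             records$flank_down_start[i],
                             records$flank_down_end[i])
      j <- off + i
      intron_density[j] <- sum(as.numeric(idep)) / length(idep)
      flank_density[j] <- (sum(as.numeric(f1)) + sum(as.numeric(f2))) /
        (length(f1) + length(f2))
      covfrac[j] <- sum(idep >= 1L) / length(idep)
      intron_id[j] <- records$intron_id[i]
      sample_id[j] <- tr$sample_id
    }
  }
  zero_flank <- flank_density == 0
  low_coverage <- covfrac < min_covered
  iri <- ifelse(zero_flank | low_coverage, NA_real_,
                intron_density / flank_density)
  cells <- data.frame(
    intron_id = intron_id, sample_id = sample_id,
    intron_density = intron_density, flank_density = flank_density,
    covered_fraction = covfrac, iri = iri,
    low_coverage = low_coverage, zero_flank = zero_flank,
    iri_gt1 = !is.na(iri) & iri > 1, stringsAsFactors = FALSE
  )
  structure(
    list(cells = cells, records = records, design = design,
         retention_cutoff = retention_cutoff, change_cutoff = change_cutoff),
    class = "iri_matrix"
  )
}

#' @export
print.iri_matrix <- function(x, ...) {
  cat("iri_matrix:", length(unique(x$cells$intron_id)), "introns x",
      length(unique(x$cells$sample_id)), "samples\n")
  invisible(x)
}

#' Apply the IRI row filters
#'
#' Removes every intron having an IRI above 1 in any sample (likely a
#' missing annotation) or a missing IRI in any sample (not quantifiable
#' everywhere, so no complete trajectory exists). Surviving IRI values all
#' lie in [0, 1].
#'
#' @param matrix An \code{iri_matrix}.
#' @return A list: \code{matrix} (filtered \code{iri_matrix}) and
#'   \code{report}, a named integer vector with counts \code{kept},
#'   \code{dropped_iri_gt1} and \code{dropped_missing}.
#' @export
apply_iri_filters <- function(matrix) {
  cells <- matrix$cells
  by_intron <- split(cells, cells$intron_id)
  gt1 <- vapply(by_intron, function(d) any(d$iri_gt1), logical(1))
  miss <- vapply(by_intron, function(d) anyNA(d$iri), logical(1))
  drop_gt1 <- gt1
  drop_missing <- miss & !gt1 # one reason per row; gt1 takes precedence
  keep_ids <- names(by_intron)[!gt1 & !miss]
  out <- matrix
  out$cells <- cells[cells$intron_id %in% keep_ids, , drop = FALSE]
  out$records <- matrix$records[matrix$records$intron_id %in% keep_ids, ,
                                drop = FALSE]
  rownames(out$cells) <- NULL
  rownames(out$records) <- NULL
  list(
    matrix = out,
    report = c(kept = length(keep_ids),
               dropped_iri_gt1 = sum(drop_gt1),
               dropped_missing = sum(drop_missing))
  )
}

#' Wide IRI matrix (introns x samples)
#'
#' @param matrix An \code{iri_matrix}.
#' @return A numeric matrix, rows = introns, columns = samples in design
#'   order.
#' @export
iri_wide <- function(matrix) {
  cells <- matrix$cells
  introns <- unique(cells$intron_id)
  samples <- matrix$design$sample_id
  m <- base::matrix(NA_real_, length(introns), length(samples),
                    dimnames = list(introns, samples))
  m[cbind(match(cells$intron_id, introns),
          match(cells$sample_id, samples))] <- cells$iri
  m
}

#' Gene expression as FPKM over shared exons
#'
#' A coverage-based stand-in for fragment counting: the fragment count over
#' a gene's shared exonic regions is approximated by total base coverage
#' divided by the read length, then scaled per kilobase of shared-exon
#' length and per million mapped reads. Invariant to jointly scaling
#' coverage and total_mapped.
#'
#' @param track A \code{CoverageTrack}.
#' @param shared Shared-region list for one gene
#'   (\code{\link{compute_shared_regions}}).
#' @param read_length Read length used to convert base coverage to
#'   fragments (default 100).
#' @return FPKM (numeric scalar).
#' @export
gene_fpkm <- function(track, shared, read_length = 100) {
  ex <- shared$shared_exonic
  len <- sum(IRanges::width(ex))
  if (len == 0L) stop("gene ", shared$gene_id, " has no shared exonic bases")
  bases <- 0
  for (i in seq_along(ex)) {
    bases <- bases + sum(as.numeric(.interval_depths(
      track, shared$chrom, IRanges::start(ex)[i], IRanges::end(ex)[i])))
  }
  fragments <- bases / read_length
  fragments / (len / 1e3) / (track$total_mapped / 1e6)
}

#' FPKM table for all genes and samples
#'
#' @param tracks List of \code{CoverageTrack} objects.
#' @param shared_list Named list of shared-region lists, one per gene.
#' @param read_length Passed to \code{\link{gene_fpkm}}.
#' @return Long data.frame: \code{gene_id}, \code{sample_id}, \code{fpkm}.
#' @export
expression_table <- function(tracks, shared_list, read_length = 100) {
  rows <- list()
  for (tr in tracks) {
    tr <- .decode_track(tr)
    for (sh in shared_list) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = sh$gene_id, sample_id = tr$sample_id,
        fpkm = gene_fpkm(tr, sh, read_length), stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Keep genes expressed above a threshold in at least one group
#'
#' Genes with low expression are more susceptible to statistical error in
#' retention estimates; only genes whose group-mean FPKM strictly exceeds
#' \code{threshold} in at least one design group are kept.
#'
#' @param expr Expression table (\code{gene_id}, \code{sample_id},
#'   \code{fpkm}).
#' @param design Sample design data.frame.
#' @param threshold FPKM threshold (default 1; strict inequality).
#' @return Character vector of gene ids.
#' @export
filter_expressed <- function(expr, design, threshold = 1) {
  expr$group <- design$group[match(expr$sample_id, design$sample_id)]
  gm <- stats::aggregate(fpkm ~ gene_id + group, data = expr, FUN = mean)
  keep <- stats::aggregate(fpkm ~ gene_id, data = gm, FUN = max)
  sort(keep$gene_id[keep$fpkm > threshold])
}
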