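#' Parse a gene annotation into gene models
#'
#' Reads exon records from a GTF file or a refFlat-style table and groups
#' them into one gene model per gene. A gene model holds, per transcript,
#' the sorted and merged exon intervals (1-based closed, Bioconductor
#' convention; GTF input is already 1-based inclusive, refFlat starts are
#' 0-based and shifted on read).
#'
#' Transcripts of a gene must share one chromosome and strand; genes
#' violating this are dropped with a warning (trans-spliced and
#' multi-chromosome genes are out of scope).
#'
#' @param path Path to the annotation file.
#' @param dialect Either \code{"gtf"} or \code{"refflat"}.
#' @return A named list of \code{GeneModel} objects (see
#'   \code{\link{gene_model}}).
#' @export
parse_annotation <- function(path, dialect = c("gtf", "refflat")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop("annotation file not found: ", path)
  }
  exons <- switch(dialect,
    gtf = .read_gtf_exons(path),
    refflat = .read_refflat_exons(path)
  )
  models <- list()
  dropped <- character(0)
  for (gid in unique(exons$gene_id)) {
    g <- exons[exons$gene_id == gid, , drop = FALSE]
    if (length(unique(g$chrom)) > 1L || length(unique(g$strand)) > 1L) {
      dropped <- c(dropped, gid)
      next
    }
    txs <- lapply(split(g, g$transcript_id), function(tx) {
      IRanges::reduce(IRanges::IRanges(start = tx$start, end = tx$end))
    })
    models[[gid]] <- gene_model(gid, g$chrom[1L], g$strand[1L], txs)
  }
  if (length(dropped)) {
    warning("dropped ", length(dropped),
            " gene(s) spanning multiple chromosomes/strands: ",
            paste(utils::head(dropped, 5L), collapse = ", "))
  }
  models
}

.read_gtf_exons <- function(path) {
  gr <- tryCatch(
    suppressWarnings(rtracklayer::import(path, format = "gtf")),
    error = function(e) stop("failed to parse GTF '", path, "': ",
                             conditionMessage(e))
  )
  gr <- gr[gr$type == "exon"]
  if (!length(gr)) stop("no exon records in ", path)
  md <- S4Vectors::mcols(gr)
  if (is.null(md$gene_id) || is.null(md$transcript_id) ||
      anyNA(md$gene_id) || anyNA(md$transcript_id)) {
    stop("GTF exon records must carry gene_id and transcript_id: ", path)
  }
  data.frame(
    gene_id = as.character(md$gene_id),
    transcript_id = as.character(md$transcript_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

# refFlat: geneName, name, chrom, strand, txStart, txEnd, cdsStart, cdsEnd,
# exonCount, exonStarts, exonEnds -- starts 0-based, ends exclusive.
.read_refflat_exons <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("no records in ", path)
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 11L) {
      stop("malformed refFlat record at line ", i, ": expected 11 fields")
    }
    n <- suppressWarnings(as.integer(f[9L]))
    starts <- suppressWarnings(as.integer(
      strsplit(sub(",$", "", f[10L]), ",", fixed = TRUE)[[1L]]))
    ends <- suppressWarnings(as.integer(
      strsplit(sub(",$", "", f[11L]), ",", fixed = TRUE)[[1L]]))
    if (is.na(n) || anyNA(starts) || anyNA(ends) ||
        length(starts) != n || length(ends) != n) {
      stop("malformed refFlat record at line ", i,
           ": exon lists do not match exonCount")
    }
    out[[i]] <- data.frame(
      gene_id = f[1L], transcript_id = f[2L], chrom = f[3L], strand = f[4L],
      start = starts + 1L, end = ends, stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Construct a gene model
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome name.
#' @param strand \code{"+"}, \code{"-"} or \code{"."}.
#' @param transcripts Named list of \code{IRanges} exon sets (one per
#'   transcript). Each is sorted and merged on construction.
#' @return An object of class \code{GeneModel}.
#' @export
gene_model <- function(gene_id, chrom, strand, transcripts) {
  stopifnot(length(transcripts) >= 1L)
  transcripts <- lapply(transcripts, function(x) {
    x <- IRanges::reduce(x)
    if (!length(x)) stop("transcript with no exons in gene ", gene_id)
    x
  })
  structure(
    list(gene_id = gene_id, chrom = chrom, strand = strand,
         transcripts = transcripts),
    class = "GeneModel"
  )
}

#' @export
print.GeneModel <- function(x, ...) {
  cat("GeneModel", x$gene_id, sprintf("(%s%s)", x$chrom, x$strand),
      length(x$transcripts), "transcript(s)\n")
  invisible(x)
}

#' Reduce a gene model to regions shared by every isoform
#'
#' A base is shared exonic iff it is exonic in every transcript of the
#' gene; it is shared intronic iff, in every transcript, it lies strictly
#' between that transcript's first and last exon and is exonic in none.
#' Bases outside any transcript's span belong to neither set. Quantifying
#' retention only on these shared regions avoids interference from
#' alternative exons of multiple isoforms.
#'
#' @param gene A \code{GeneModel}.
#' @return A list with \code{gene_id}, \code{chrom}, \code{strand},
#'   \code{shared_exonic} and \code{shared_intronic} (\code{IRanges},
#'   sorted and merged, mutually disjoint).
#' @export
compute_shared_regions <- function(gene) {
  stopifnot(inherits(gene, "GeneModel"))
  exonic <- lapply(gene$transcripts, IRanges::reduce)
  intronic <- lapply(exonic, function(ex) {
    IRanges::setdiff(range(ex), ex)
  })
  shared_ex <- Reduce(IRanges::intersect, exonic)
  shared_in <- Reduce(IRanges::intersect, intronic)
  list(gene_id = gene$gene_id, chrom = gene$chrom, strand = gene$strand,
       shared_exonic = IRanges::reduce(shared_ex),
       shared_intronic = IRanges::reduce(shared_in))
}

#' Build intron records with flanking shared exons
#'
#' One record per shared intronic segment that has a shared exonic segment
#' on both sides; edge segments lacking a flank are dropped (their count is
#' attached as attribute \code{n_dropped}). \code{flank_up}/\code{flank_down}
#' are the nearest shared exonic segments on the left/right of the forward
#' coordinate axis; the ordinal index in \code{intron_id} follows
#' transcription order, so on the minus strand the leftmost intron gets the
#' highest index.
#'
#' @param shared Output of \code{\link{compute_shared_regions}}.
#' @return A data.frame with one row per intron: \code{intron_id},
#'   \code{gene_id}, \code{chrom}, \code{strand}, \code{start}, \code{end}
#'   (1-based closed), flank coordinates, \code{length}, \code{gc}
#'   (\code{NA} until \code{\link{annotate_features}}).
#' @export
build_intron_records <- function(shared) {
  si <- shared$shared_intronic
  se <- shared$shared_exonic
  empty <- data.frame(
    intron_id = character(0), gene_id = character(0), chrom = character(0),
    strand = character(0), start = integer(0), end = integer(0),
    flank_up_start = integer(0), flank_up_end = integer(0),
    flank_down_start = integer(0), flank_down_end = integer(0),
    length = integer(0), gc = numeric(0), stringsAsFactors = FALSE
  )
  if (!length(si)) {
    attr(empty, "n_dropped") <- 0L
    return(empty)
  }
  ex_start <- IRanges::start(se)
  ex_end <- IRanges::end(se)
  rows <- list()
  n_dropped <- 0L
  for (i in seq_along(si)) {
    s <- IRanges::start(si)[i]
    e <- IRanges::end(si)[i]
    left <- which(ex_end < s)
    right <- which(ex_start > e)
    if (!length(left) || !length(right)) {
      n_dropped <- n_dropped + 1L
      next
    }
    li <- left[which.max(ex_end[left])]
    ri <- right[which.min(ex_start[right])]
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = shared$gene_id, chrom = shared$chrom,
      strand = shared$strand, start = s, end = e,
      flank_up_start = ex_start[li], flank_up_end = ex_end[li],
      flank_down_start = ex_start[ri], flank_down_end = ex_end[ri],
      length = e - s + 1L, gc = NA_real_, stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) {
    attr(empty, "n_dropped") <- n_dropped
    return(empty)
  }
  rec <- do.call(rbind, rows)
  ord <- seq_len(nrow(rec))
  if (identical(shared$strand, "-")) ord <- rev(ord)
  rec$intron_id <- paste0(rec$gene_id, ":I", ord)
  rec <- rec[, c("intron_id", setdiff(names(rec), "intron_id"))]
  rownames(rec) <- NULL
  attr(rec, "n_dropped") <- n_dropped
  rec
}

#' Attach GC content to intron records
#'
#' GC content is (#G + #C) / (#A + #C + #G + #T) over the intron sequence,
#' case-insensitive; N bases are excluded from both numerator and
#' denominator so assembly gaps do not bias the estimate.
#'
#' @param records Intron record data.frame.
#' @param genome A \code{Biostrings::DNAStringSet} (or object subsettable
#'   by chromosome name yielding one) covering the records' chromosomes.
#' @return \code{records} with \code{gc} filled; records on chromosomes
#'   absent from \code{genome} keep \code{NA} with a warning.
#' @export
annotate_features <- function(records, genome) {
  if (!nrow(records)) return(records)
  missing_chrom <- setdiff(unique(records$chrom), names(genome))
  if (length(missing_chrom)) {
    warning("chromosome(s) absent from genome, gc left missing: ",
            paste(missing_chrom, collapse = ", "))
  }
  for (i in seq_len(nrow(records))) {
    chrom <- records$chrom[i]
    if (!chrom %in% names(genome)) next
    seq <- Biostrings::subseq(genome[[chrom]],
                              start = records$start[i],
                              end = records$end[i])
    records$gc[i] <- gc_fraction(as.character(seq))
  }
  records
}

#' GC fraction of a sequence, excluding N
#'
#' @param seq A character scalar DNA sequence.
#' @return Fraction of G+C among non-N bases (NA if all N or empty).
#' @export
gc_fraction <- function(seq) {
  dna <- Biostrings::DNAString(toupper(seq))
  counts <- Biostrings::letterFrequency(dna, letters = c("A", "C", "G", "T"))
  denom <- sum(counts)
  if (denom == 0L) return(NA_real_)
  unname((counts[["C"]] + counts[["G"]]) / denom)
}

#' Export intron records as BED6+
#'
#' Coordinates are converted to BED's 0-based half-open convention;
#' extra columns carry intron length and GC content.
#'
#' @param records Intron record data.frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
export_intron_bed <- function(records, path) {
  bed <- data.frame(
    chrom = records$chrom,
    start = records$start - 1L,
    end = records$end,
    name = records$intron_id,
    score = 0L,
    strand = records$strand,
    length = records$length,
    gc = ifelse(is.na(records$gc), ".", format(records$gc, digits = 6))
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
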