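#' Write a simulated dataset as a self-describing fixture bundle
#'
#' Emits exactly the formats the pipeline reads back: GTF annotation,
#' FASTA genome, one bedGraph per sample, design TSV, binding-site BED,
#' RBP expression TSV, ground-truth TSV and a JSON manifest (config, seed,
#' per-file md5 checksums). Re-running with the same config and seed
#' reproduces every file byte for byte.
#'
#' @param sim A \code{sim_dataset}.
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
write_fixture_bundle <- function(sim, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) {
      stop("cannot create output directory: ", out_dir)
    }
  }
  files <- character(0)
  # annotation
  gtf <- file.path(out_dir, "genes.gtf")
  lines <- character(0)
  for (m in sim$genome$models) {
    for (tx in names(m$transcripts)) {
      ex <- m$transcripts[[tx]]
      lines <- c(lines, sprintf(
        "%s\tiridyn_sim\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
        m$chrom, IRanges::start(ex), IRanges::end(ex), m$strand,
        m$gene_id, tx))
    }
  }
  writeLines(lines, gtf)
  files <- c(files, gtf)
  # genome
  fa <- file.path(out_dir, "genome.fa")
  Biostrings::writeXStringSet(sim$genome$genome, fa)
  files <- c(files, fa)
  # coverage
  cov_dir <- file.path(out_dir, "coverage")
  dir.create(cov_dir, showWarnings = FALSE)
  for (tr in sim$tracks) {
    p <- file.path(cov_dir, paste0(tr$sample_id, ".bedGraph"))
    write_bedgraph_track(tr, p)
    files <- c(files, p)
  }
  # design
  design_path <- file.path(out_dir, "design.tsv")
  utils::write.table(sim$design, design_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, design_path)
  # binding sites (BED: 0-based half-open)
  bed <- file.path(out_dir, "rbp_sites.bed")
  s <- sim$sites
  if (length(s)) {
    writeLines(sprintf("%s\t%d\t%d\t%s\t0\t.",
                       as.character(GenomicRanges::seqnames(s)),
                       GenomicRanges::start(s) - 1L,
                       GenomicRanges::end(s), s$rbp), bed)
  } else {
    file.create(bed)
  }
  files <- c(files, bed)
  # RBP expression
  expr_path <- file.path(out_dir, "rbp_expression.tsv")
  expr <- do.call(rbind, lapply(names(sim$rbp_expression), function(m) {
    cbind(model = m, sim$rbp_expression[[m]])
  }))
  utils::write.table(expr, expr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, expr_path)
  # ground truth
  truth_path <- file.path(out_dir, "ground_truth.tsv")
  tr <- sim$truth
  introns <- tr$introns
  g_idx <- match(introns$gene_id, rownames(tr$rho))
  truth_tab <- data.frame(
    intron_id = introns$intron_id, gene_id = introns$gene_id,
    class = introns$class, label = truth_labels(tr)$label,
    scale = tr$genes$scale[match(introns$gene_id, tr$genes$gene_id)],
    stringsAsFactors = FALSE
  )
  for (k in seq_along(tr$timepoints)) {
    truth_tab[[paste0("rho_", tr$timepoints[k])]] <- tr$rho[g_idx, k]
    truth_tab[[paste0("iri_", tr$timepoints[k])]] <- tr$iri[g_idx, k]
    truth_tab[[paste0("T_", tr$timepoints[k])]] <- tr$T_t[g_idx, k]
  }
  utils::write.table(truth_tab, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, truth_path)
  manifest <- list(
    seed = sim$seed,
    gamma = sim$config$gamma,
    n_genes = sim$config$n_genes,
    n_timepoints = sim$config$n_timepoints,
    replicates = sim$config$replicates,
    depth = sim$config$depth,
    read_length = sim$config$read_length,
    files = data.frame(path = substring(files, nchar(out_dir) + 2L),
                       md5 = unname(tools::md5sum(files)),
                       stringsAsFactors = FALSE)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a fixture bundle back into pipeline inputs
#'
#' Uses the package's own readers (GTF parser, bedGraph reader, BED
#' loader), so a round trip exercises every external interface.
#'
#' @param dir Bundle directory written by
#'   \code{\link{write_fixture_bundle}}.
#' @return List: \code{models}, \code{genome}, \code{design},
#'   \code{tracks}, \code{sites}, \code{rbp_expression}, \code{truth}
#'   (data.frame), \code{manifest}.
#' @export
read_fixture_bundle <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  design <- utils::read.delim(file.path(dir, "design.tsv"),
                              stringsAsFactors = FALSE)
  design$group <- factor(design$group, levels = unique(design$group))
  tracks <- lapply(seq_len(nrow(design)), function(i) {
    read_bedgraph_track(
      file.path(dir, "coverage", paste0(design$sample_id[i], ".bedGraph")),
      sample_id = design$sample_id[i],
      total_mapped = design$total_mapped[i]
    )
  })
  names(tracks) <- design$sample_id
  list(
    models = parse_annotation(file.path(dir, "genes.gtf"), "gtf"),
    genome = Biostrings::readDNAStringSet(file.path(dir, "genome.fa")),
    design = design,
    tracks = tracks,
    sites = load_binding_sites(file.path(dir, "rbp_sites.bed"),
                               source = "simulated"),
    rbp_expression = split(
      utils::read.delim(file.path(dir, "rbp_expression.tsv"),
                        stringsAsFactors = FALSE)[, -1L],
      utils::read.delim(file.path(dir, "rbp_expression.tsv"),
                        stringsAsFactors = FALSE)$model),
    truth = utils::read.delim(file.path(dir, "ground_truth.tsv"),
                              stringsAsFactors = FALSE),
    manifest = manifest
  )
}
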