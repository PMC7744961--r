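# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (per-base loops, enumeration) so they cannot share a
# bug with the interval/rank machinery they check.

# -- shared-region oracle: label every base of 1..max_pos ---------------

brute_shared_regions <- function(gene, max_pos) {
  txs <- gene$transcripts
  exonic <- matrix(FALSE, max_pos, length(txs))
  spanned <- matrix(FALSE, max_pos, length(txs))
  for (j in seq_along(txs)) {
    ex <- txs[[j]]
    for (i in seq_along(ex)) {
      exonic[IRanges::start(ex)[i]:IRanges::end(ex)[i], j] <- TRUE
    }
    spanned[min(IRanges::start(ex)):max(IRanges::end(ex)), j] <- TRUE
  }
  ex_all <- apply(exonic, 1L, all)
  in_all <- apply(spanned, 1L, all) & !apply(exonic, 1L, any)
  pos_to_ranges <- function(keep) {
    IRanges::reduce(IRanges::IRanges(start = which(keep), width = 1L))
  }
  list(shared_exonic = pos_to_ranges(ex_all),
       shared_intronic = pos_to_ranges(in_all))
}

# random multi-isoform gene on a small span: isoforms share an exon grid
# but may skip exons or trim the span
random_gene_model <- function(gene_id = "g", max_span = 2000L) {
  n_ex <- sample(2:6, 1L)
  bounds <- sort(sample(seq_len(max_span), 2L * n_ex))
  starts <- bounds[seq(1L, 2L * n_ex, by = 2L)]
  ends <- bounds[seq(2L, 2L * n_ex, by = 2L)]
  base <- IRanges::IRanges(starts, ends)
  n_iso <- sample(1:3, 1L)
  txs <- lapply(seq_len(n_iso), function(i) {
    keep <- sort(sample(seq_len(n_ex), sample(seq_len(n_ex), 1L)))
    base[keep]
  })
  names(txs) <- paste0(gene_id, ".t", seq_len(n_iso))
  gene_model(gene_id, "chr1", sample(c("+", "-"), 1L), txs)
}

# -- coverage fixtures --------------------------------------------------

make_track <- function(depths, sample_id = "s1", total_mapped = 1e6,
                       chrom = "chr1") {
  coverage_track(stats::setNames(list(as.integer(depths)), chrom),
                 sample_id, total_mapped)
}

# one intron record row from explicit coordinates (1-based closed)
make_record <- function(intron = c(101L, 200L), flank_up = c(51L, 100L),
                        flank_down = c(201L, 250L), intron_id = "g:I1",
                        gene_id = "g", chrom = "chr1", strand = "+") {
  data.frame(
    intron_id = intron_id, gene_id = gene_id, chrom = chrom,
    strand = strand, start = intron[1L], end = intron[2L],
    flank_up_start = flank_up[1L], flank_up_end = flank_up[2L],
    flank_down_start = flank_down[1L], flank_down_end = flank_down[2L],
    length = intron[2L] - intron[1L] + 1L, gc = NA_real_,
    stringsAsFactors = FALSE
  )
}

# naive per-base IRI recount straight from the depth vectors
naive_iri <- function(depths, record) {
  intron <- depths[record$start:record$end]
  flank <- c(depths[record$flank_up_start:record$flank_up_end],
             depths[record$flank_down_start:record$flank_down_end])
  fd <- sum(flank) / length(flank)
  covfrac <- mean(intron >= 1)
  if (fd == 0 || covfrac < 0.5) return(NA_real_)
  (sum(intron) / length(intron)) / fd
}

# assemble an iri_matrix object directly from a wide value matrix
manual_iri_matrix <- function(values, gene_ids = NULL) {
  introns <- rownames(values)
  samples <- colnames(values)
  if (is.null(gene_ids)) gene_ids <- sub(":.*$", "", introns)
  cells <- expand.grid(intron_id = introns, sample_id = samples,
                       stringsAsFactors = FALSE)
  cells$iri <- values[cbind(match(cells$intron_id, introns),
                            match(cells$sample_id, samples))]
  cells$iri_gt1 <- !is.na(cells$iri) & cells$iri > 1
  design <- data.frame(
    sample_id = samples,
    group = factor(sub("_r[0-9]+$", "", samples),
                   levels = unique(sub("_r[0-9]+$", "", samples))),
    replicate = as.integer(sub("^.*_r", "", samples)),
    stringsAsFactors = FALSE
  )
  records <- data.frame(intron_id = introns, gene_id = gene_ids,
                        stringsAsFactors = FALSE)
  structure(list(cells = cells, records = records, design = design,
                 retention_cutoff = 0.1, change_cutoff = 0.1),
            class = "iri_matrix")
}

# -- statistics oracles -------------------------------------------------

pearson_direct <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}

# exact one-sided ("greater") rank-sum p by full enumeration (no ties)
wilcox_enum_greater <- function(a, b) {
  n <- length(a)
  pooled <- c(a, b)
  obs <- sum(rank(pooled)[seq_len(n)])
  combs <- utils::combn(length(pooled), n)
  stats <- apply(combs, 2L, function(idx) sum(rank(pooled)[idx]))
  mean(stats >= obs)
}

pooled_t_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
    (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  2 * stats::pt(-abs(t), na + nb - 2)
}

# tiny sim config to keep unit tests fast
small_sim_config <- function(n_genes = 12, ...) {
  sim_config(n_genes = n_genes, introns_per_gene = c(2, 3),
             exon_length = c(80, 150),
             intron_length_change = c(150, 300),
             intron_length_other = c(250, 450), ...)
}
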