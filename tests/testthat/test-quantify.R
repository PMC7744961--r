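test_that("region density and covered fraction are per-base means", {
  tr <- make_track(c(rep(0L, 100L), rep(2L, 100L)))
  expect_equal(region_density(tr, "chr1", 101, 200), 2.0)
  expect_equal(region_density(tr, "chr1", 1, 100), 0.0)
  tr2 <- make_track(c(0L, 0L, 3L, 3L))
  expect_equal(region_density(tr2, "chr1", 1, 4), 1.5)

  tr3 <- make_track(c(rep(1L, 40L), rep(0L, 60L)))
  expect_equal(covered_fraction(tr3, "chr1", 1, 100), 0.4)
  expect_equal(covered_fraction(make_track(rep(3L, 10L)), "chr1", 1, 10), 1.0)
  expect_equal(covered_fraction(make_track(rep(0L, 10L)), "chr1", 1, 10), 0.0)
  # positions beyond the stored run length count as zero depth
  expect_equal(region_density(tr2, "chr1", 3, 6), 1.5)
  expect_error(region_density(tr2, "chrZ", 1, 4), "chrZ")
})

test_that("compute_iri pools both flanks and applies the coverage guard", {
  # flanks at depth 6, intron 10 bp with 6 covered bases at depth 1:
  # intron density 0.6, flank density 6.0, IRI 0.1 (the retention cutoff)
  depths <- c(rep(6L, 50L), rep(c(1L, 0L), c(6L, 4L)), rep(6L, 50L))
  tr <- make_track(depths)
  rec <- make_record(intron = c(51L, 60L), flank_up = c(1L, 50L),
                     flank_down = c(61L, 110L))
  out <- compute_iri(tr, rec)
  expect_equal(out$iri, 0.1)
  expect_equal(out$covered_fraction, 0.6)
  expect_false(out$low_coverage || out$zero_flank || out$iri_gt1)

  # covered fraction below 0.5: value withheld, low_coverage flagged
  depths2 <- c(rep(6L, 50L), rep(c(1L, 0L), c(4L, 6L)), rep(6L, 50L))
  out2 <- compute_iri(make_track(depths2), rec)
  expect_true(is.na(out2$iri))
  expect_true(out2$low_coverage)

  # zero flank density: division guard
  depths3 <- c(rep(0L, 50L), rep(1L, 10L), rep(0L, 50L))
  out3 <- compute_iri(make_track(depths3), rec)
  expect_true(is.na(out3$iri))
  expect_true(out3$zero_flank)

  # IRI above 1 is computed but flagged
  depths4 <- c(rep(1L, 50L), rep(5L, 10L), rep(1L, 50L))
  out4 <- compute_iri(make_track(depths4), rec)
  expect_equal(out4$iri, 5)
  expect_true(out4$iri_gt1)
})

test_that("IRI is invariant under uniform coverage scaling", {
  set.seed(7)
  for (k in c(2L, 5L, 17L)) {
    depths <- rpois(200L, 4)
    rec <- make_record(intron = c(81L, 140L), flank_up = c(31L, 80L),
                       flank_down = c(141L, 190L))
    a <- compute_iri(make_track(depths), rec)
    b <- compute_iri(make_track(depths * k), rec)
    expect_equal(a$iri, b$iri, tolerance = 1e-12)
    expect_equal(a$covered_fraction, b$covered_fraction)
  }
})

test_that("compute_iri equals a naive per-base recount on random fixtures", {
  set.seed(11)
  for (i in 1:25) {
    depths <- rpois(300L, sample(c(0.4, 2, 8), 1L))
    rec <- make_record(intron = c(101L, 200L), flank_up = c(41L, 100L),
                       flank_down = c(201L, 260L))
    got <- compute_iri(make_track(depths), rec)$iri
    want <- naive_iri(depths, rec)
    if (is.na(want)) expect_true(is.na(got)) else
      expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("row filters drop IRI>1 and incomplete introns with a reason count", {
  vals <- rbind(
    "gA:I1" = c(0.2, 0.3, 1.2),
    "gB:I1" = c(0.1, 0.4, 0.9),
    "gC:I1" = c(0.2, NA, 0.3)
  )
  colnames(vals) <- c("T1_r1", "T2_r1", "T3_r1")
  im <- manual_iri_matrix(vals)
  out <- apply_iri_filters(im)
  expect_equal(unique(out$matrix$cells$intron_id), "gB:I1")
  expect_true(all(out$matrix$cells$iri >= 0 & out$matrix$cells$iri <= 1))
  expect_equal(out$report[["kept"]], 1L)
  expect_equal(out$report[["dropped_iri_gt1"]], 1L)
  expect_equal(out$report[["dropped_missing"]], 1L)
})

test_that("gene FPKM follows the coverage-to-fragments conversion", {
  shared <- list(gene_id = "g", chrom = "chr1", strand = "+",
                 shared_exonic = IRanges::IRanges(1L, 1000L),
                 shared_intronic = IRanges::IRanges())
  tr <- make_track(rep(10L, 1000L), total_mapped = 1e6)
  # 10x coverage over 1 kb / 100 bp reads = 100 fragments -> FPKM 100
  expect_equal(gene_fpkm(tr, shared, read_length = 100), 100)
  expect_equal(gene_fpkm(make_track(rep(0L, 1000L)), shared), 0)
  # jointly doubling coverage and library size leaves FPKM unchanged
  tr2 <- make_track(rep(20L, 1000L), total_mapped = 2e6)
  expect_equal(gene_fpkm(tr2, shared), gene_fpkm(tr, shared))
  shared0 <- shared
  shared0$shared_exonic <- IRanges::IRanges()
  expect_error(gene_fpkm(tr, shared0), "shared exonic")
})

test_that("expression filter keeps genes above threshold in >= 1 group", {
  design <- data.frame(sample_id = c("a1", "a2", "b1", "b2"),
                       group = c("A", "A", "B", "B"),
                       replicate = c(1L, 2L, 1L, 2L))
  expr <- data.frame(
    gene_id = rep(c("g1", "g2", "g3"), each = 4L),
    sample_id = rep(design$sample_id, 3L),
    fpkm = c(0.4, 0.6, 1.1, 1.3,   # g1: means 0.5 / 1.2 -> kept
             0.1, 0.3, 0.8, 1.0,   # g2: means 0.2 / 0.9 -> dropped
             1.0, 1.0, 1.0, 1.0)   # g3: exactly 1 -> dropped (strict)
  )
  expect_equal(filter_expressed(expr, design), "g1")
})

test_that("bedGraph round trip preserves depths and total_mapped estimate", {
  set.seed(3)
  depths <- rpois(500L, 2)
  tr <- make_track(depths, sample_id = "s7", total_mapped = 4321)
  path <- tempfile(fileext = ".bedGraph")
  write_bedgraph_track(tr, path)
  back <- read_bedgraph_track(path, sample_id = "s7", total_mapped = 4321)
  # trailing zero runs are not representable in bedGraph; compare to the
  # last covered base
  n <- max(which(depths > 0))
  expect_equal(as.integer(back$cov$chr1)[seq_len(n)], depths[seq_len(n)])
  expect_equal(back$total_mapped, 4321)
  est <- read_bedgraph_track(path, read_length = 100)
  expect_equal(est$total_mapped, max(1, round(sum(depths) / 100)))
})

test_that("the matrix builder agrees with per-record compute_iri", {
  set.seed(13)
  recs <- rbind(
    make_record(intron = c(101L, 200L), flank_up = c(41L, 100L),
                flank_down = c(201L, 260L), intron_id = "g1:I1",
                gene_id = "g1"),
    make_record(intron = c(311L, 380L), flank_up = c(261L, 310L),
                flank_down = c(381L, 430L), intron_id = "g1:I2",
                gene_id = "g1")
  )
  tracks <- lapply(1:3, function(k)
    make_track(rpois(430L, 3), sample_id = paste0("T1_r", k)))
  design <- data.frame(sample_id = paste0("T1_r", 1:3), group = "T1",
                       replicate = 1:3)
  im <- build_iri_matrix(tracks, recs, design)
  for (k in 1:3) {
    for (i in 1:2) {
      ref <- compute_iri(tracks[[k]], recs[i, , drop = FALSE])
      cell <- im$cells[im$cells$sample_id == paste0("T1_r", k) &
                         im$cells$intron_id == recs$intron_id[i], ]
      expect_equal(cell$iri, ref$iri, tolerance = 1e-12)
      expect_equal(cell$flank_density, ref$flank_density)
      expect_equal(cell$covered_fraction, ref$covered_fraction)
    }
  }
})
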