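test_that("expected IRI closed form behaves at its anchors", {
  # with no differential decay the index equals the retention fraction
  rho <- seq(0, 0.9, by = 0.1)
  expect_equal(expected_iri(rho, 1), rho)
  # rho = 0.2, gamma = 5: (0.04)/(0.8 + 0.04)
  expect_equal(expected_iri(0.2, 5), 0.04 / 0.84, tolerance = 1e-12)
  expect_true(all(expected_iri(rho, 5) < expected_iri(rho, 1)[-1][9] + 1))
})

test_that("config validation rejects infeasible settings", {
  expect_error(sim_config(class_props = c(none = 0.5, stable = 0.5,
                                          up = 0.2, down = 0, irregular = 0)),
               "sum to 1")
  expect_error(sim_config(gamma = 0.5), "gamma")
  expect_error(sim_config(depth = 0), "depth")
  # amplitudes that cannot reach the retention cutoff under gamma
  expect_error(sim_config(rho_up = c(0.02, 0.3), gamma = 5),
               "amplitude incompatible")
})

test_that("simulated genome is deterministic and structurally sound", {
  cfg <- small_sim_config()
  g1 <- simulate_genome(cfg, seed = 5)
  g2 <- simulate_genome(cfg, seed = 5)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(g1$records, g2$records)
  g3 <- simulate_genome(cfg, seed = 6)
  expect_false(identical(as.character(g1$genome), as.character(g3$genome)))

  # single-isoform genes: shared regions equal the isoform's own introns
  one_iso <- names(Filter(function(m) length(m$transcripts) == 1L,
                          g1$models))
  for (gid in utils::head(one_iso, 3L)) {
    sh <- compute_shared_regions(g1$models[[gid]])
    ex <- g1$models[[gid]]$transcripts[[1L]]
    expect_identical(sh$shared_exonic, IRanges::reduce(ex))
    expect_identical(sh$shared_intronic,
                     IRanges::setdiff(range(ex), ex))
  }
  # exon-skipping pair: the skipped exon sits in neither shared set
  skip <- names(Filter(function(m) length(m$transcripts) == 2L, g1$models))
  if (length(skip)) {
    m <- g1$models[[skip[1L]]]
    skipped <- IRanges::setdiff(m$transcripts[[1L]], m$transcripts[[2L]])
    sh <- compute_shared_regions(m)
    oracle <- brute_shared_regions(m, g1$chrom_length)
    expect_identical(sh$shared_exonic, oracle$shared_exonic)
    expect_identical(sh$shared_intronic, oracle$shared_intronic)
    expect_length(IRanges::intersect(sh$shared_exonic, skipped), 0L)
    expect_length(IRanges::intersect(sh$shared_intronic, skipped), 0L)
  }
})

test_that("trajectories honour their class shapes", {
  cfg <- small_sim_config(n_genes = 40)
  genome <- simulate_genome(cfg, seed = 9)
  truth <- simulate_ir_trajectories(cfg, genome, seed = 10)
  for (g in seq_len(nrow(truth$genes))) {
    rho <- truth$rho[g, ]
    cls <- truth$genes$class[g]
    if (cls == "up") expect_true(all(diff(rho) > 0))
    if (cls == "down") expect_true(all(diff(rho) < 0))
    if (cls %in% c("stable", "none")) expect_equal(diff(range(rho)), 0)
    if (cls == "none") {
      expect_true(all(expected_iri(rho, cfg$gamma) < 0.1))
    }
    if (cls == "stable") {
      expect_true(all(expected_iri(rho, cfg$gamma) >= 0.1))
    }
    if (cls == "irregular") {
      r <- stats::cor(expected_iri(rho, cfg$gamma),
                      monotone_reference(length(rho)))
      expect_lt(abs(r), 0.7)
    }
  }
})

test_that("simulated coverage matches the degradation closed forms", {
  cfg <- sim_config(n_genes = 60, gene_scale_sdlog = 0,
                    t_drift_sdlog = 0,
                    class_props = c(none = 0, stable = 0, up = 1,
                                    down = 0, irregular = 0))
  genome <- simulate_genome(cfg, seed = 21)
  truth <- simulate_ir_trajectories(cfg, genome, seed = 22)
  cov <- simulate_coverage(cfg, genome, truth, seed = 23)

  # exonic signal falls by T(1 - rho(1-1/gamma)) from first to last
  # time point when gamma > 1
  shared_list <- genome$shared_list
  first <- cov$tracks[["T1_r1"]]
  last <- cov$tracks[["T5_r1"]]
  dens <- function(track, gid) {
    sh <- shared_list[[gid]]
    ex <- sh$shared_exonic
    num <- 0; den <- 0
    for (i in seq_along(ex)) {
      num <- num + region_density(track, sh$chrom,
                                  IRanges::start(ex)[i],
                                  IRanges::end(ex)[i]) *
        IRanges::width(ex)[i]
      den <- den + IRanges::width(ex)[i]
    }
    num / den
  }
  gids <- names(shared_list)
  obs_ratio <- mean(vapply(gids, function(g)
    dens(last, g) / dens(first, g), numeric(1)))
  k <- 1 - 1 / cfg$gamma
  exp_ratio <- mean(
    (1 - truth$rho[gids, 5] * k) / (1 - truth$rho[gids, 1] * k))
  expect_equal(obs_ratio, exp_ratio, tolerance = 0.05)

  # empirical IRI tracks the expected closed form
  records <- genome$records
  design <- cov$design
  im <- build_iri_matrix(cov$tracks, records, design)
  filt <- apply_iri_filters(im)
  wide <- iri_wide(filt$matrix)
  t3 <- design$sample_id[design$group == "T3"]
  emp <- rowMeans(wide[, t3, drop = FALSE])
  expct <- truth$iri[records$gene_id[match(rownames(wide),
                                           records$intron_id)], 3]
  expect_gte(length(emp), 50L)
  expect_lt(mean(abs(emp - expct)), 0.02)
})

test_that("gamma = 1 removes the retention-expression coupling", {
  cfg <- sim_config(n_genes = 30, gamma = 1, gene_scale_sdlog = 0,
                    t_drift_sdlog = 0,
                    class_props = c(none = 0, stable = 0, up = 1, down = 0,
                                    irregular = 0))
  genome <- simulate_genome(cfg, seed = 31)
  truth <- simulate_ir_trajectories(cfg, genome, seed = 32)
  # S_t + R_t = T: exonic lambda is flat across time points
  lam1 <- iridyn:::.lambda_vector(cfg, genome, truth, 1L)
  lam5 <- iridyn:::.lambda_vector(cfg, genome, truth, 5L)
  sh <- genome$shared_list[[1L]]
  ex <- sh$shared_exonic
  idx <- unlist(lapply(seq_along(ex), function(i)
    IRanges::start(ex)[i]:IRanges::end(ex)[i]))
  expect_equal(lam1[idx], lam5[idx], tolerance = 1e-12)
})

test_that("planted RBP sites are enriched in changed introns", {
  cfg <- sim_config(n_genes = 80,
                    rbp = list(n_decoys = 2, enrichment = 5,
                               background_rate = 1))
  genome <- simulate_genome(cfg, seed = 41)
  out <- simulate_rbp_sites(cfg, genome, seed = 42)
  man <- out$manifest
  expect_true(man$planted[man$rbp == "RBP_REG"])
  expect_equal(man$enrichment[man$rbp == "RBP_REG"], 5)
  den <- binding_density(out$sites, genome$records, "RBP_REG")
  cls <- genome$records$class[match(den$intron_id,
                                    genome$records$intron_id)]
  changed <- den$density[cls %in% c("up", "down")]
  spliced <- den$density[cls == "none"]
  p <- suppressWarnings(
    stats::wilcox.test(changed, spliced, alternative = "greater")$p.value)
  expect_lt(p, 0.01)
  # sites are deterministic under the seed
  out2 <- simulate_rbp_sites(cfg, genome, seed = 42)
  expect_identical(as.data.frame(out$sites), as.data.frame(out2$sites))
})

test_that("RBP expression drops only for the planted regulator", {
  cfg <- sim_config(rbp = list(n_decoys = 3, drop_models = 3,
                               planted_fold = 2))
  expr <- simulate_rbp_expression(cfg, seed = 51)
  expect_length(expr, 6L)
  m1 <- expr[[1L]]
  reg_early <- mean(m1$rpkm[m1$rbp == "RBP_REG" & m1$passage == "early"])
  reg_late <- mean(m1$rpkm[m1$rbp == "RBP_REG" & m1$passage == "late"])
  expect_equal(reg_early / reg_late, 2, tolerance = 0.2)
  m6 <- expr[[6L]]
  reg6 <- tapply(m6$rpkm[m6$rbp == "RBP_REG"],
                 m6$passage[m6$rbp == "RBP_REG"], mean)
  expect_equal(unname(reg6["early"] / reg6["late"]), 1, tolerance = 0.2)
})

test_that("fixture bundles are byte-reproducible and round-trip", {
  cfg <- small_sim_config(n_timepoints = 3, replicates = 2)
  sim <- simulate_dataset(cfg, seed = 61)
  d1 <- file.path(tempdir(), "bundle1")
  d2 <- file.path(tempdir(), "bundle2")
  unlink(c(d1, d2), recursive = TRUE)
  write_fixture_bundle(sim, d1)
  write_fixture_bundle(simulate_dataset(cfg, seed = 61), d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
  # manifest checksums describe the files on disk
  man <- jsonlite::read_json(file.path(d1, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(nrow(man$files), length(f1) - 1L) # manifest excludes itself
  # ground truth covers every intron
  truth_tab <- utils::read.delim(file.path(d1, "ground_truth.tsv"))
  expect_equal(nrow(truth_tab), nrow(sim$genome$records))

  back <- read_fixture_bundle(d1)
  expect_equal(sort(names(back$models)),
               sort(names(sim$genome$models)))
  rec_back <- do.call(rbind, lapply(
    lapply(back$models, compute_shared_regions), build_intron_records))
  rownames(rec_back) <- NULL
  expect_equal(rec_back$intron_id, sim$genome$records$intron_id)
  expect_equal(rec_back$start, sim$genome$records$start)
  expect_identical(as.character(back$genome), as.character(sim$genome$genome))
  expect_equal(back$design$sample_id, sim$design$sample_id)
  expect_length(back$tracks, length(sim$tracks))
})
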