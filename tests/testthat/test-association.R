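make_ct <- function(intron_id, gene_id, label) {
  d <- data.frame(intron_id = intron_id, gene_id = gene_id, label = label,
                  stringsAsFactors = FALSE)
  class(d) <- c("classification_table", "data.frame")
  d
}

test_that("gene classes lift intron labels with union semantics", {
  ct <- make_ct(
    c("g1:I1", "g1:I2", "g2:I1", "g2:I2", "g3:I1", "g3:I2", "g4:I1"),
    c("g1", "g1", "g2", "g2", "g3", "g3", "g4"),
    c("up_IR", "no_IR", "up_IR", "down_IR", "no_IR", "no_IR", "stable_IR")
  )
  cl <- gene_level_classes(ct)
  expect_equal(cl$up_IR, c("g1", "g2"))
  expect_equal(cl$down_IR, "g2")
  expect_equal(cl$stable_IR, "g4")
  # no_IR requires every classified intron to be no_IR
  expect_equal(cl$no_IR, "g3")
  # g2 carries both directions but counts once in change_IR
  expect_equal(cl$change_IR, c("g1", "g2"))
})

test_that("expression change is a pseudocounted log2 ratio of group means", {
  design <- data.frame(sample_id = c("a1", "a2", "b1", "b2"),
                       group = c("A", "A", "B", "B"),
                       replicate = c(1L, 2L, 1L, 2L))
  expr <- data.frame(
    gene_id = rep(c("g1", "g2", "g3"), each = 4L),
    sample_id = rep(design$sample_id, 3L),
    fpkm = c(2, 2, 4, 4,  3, 3, 3, 3,  0, 0, 1, 1)
  )
  fc <- expression_change(expr, design, "A", "B", pseudocount = 0,
                          genes = c("g1", "g2"))
  expect_equal(unname(fc["g1"]), 1)
  expect_equal(unname(fc["g2"]), 0)
  fc3 <- expression_change(expr, design, "A", "B", pseudocount = 0.1,
                           genes = "g3")
  expect_equal(unname(fc3["g3"]), log2(1.1 / 0.1), tolerance = 1e-12)
  expect_error(expression_change(expr, design, "A", "Z"), "unknown group")
})

test_that("class expression contrasts detect the decay-coupled shifts", {
  classes <- list(up_IR = paste0("u", 1:8), down_IR = paste0("d", 1:8),
                  stable_IR = paste0("s", 1:8), no_IR = paste0("n", 1:8),
                  change_IR = c(paste0("u", 1:8), paste0("d", 1:8)))
  fc <- c(stats::setNames(rep(-1, 8), paste0("u", 1:8)),
          stats::setNames(rep(1, 8), paste0("d", 1:8)),
          stats::setNames(rep(0, 8), paste0("s", 1:8)),
          stats::setNames(rep(0, 8), paste0("n", 1:8)))
  out <- class_expression_contrast(classes, fc)
  expect_lt(out$tests$p_value[out$tests$contrast == "up_IR vs no_IR"], 0.01)
  expect_lt(out$tests$p_value[out$tests$contrast == "down_IR vs no_IR"],
            0.01)
  expect_equal(
    out$summary$median_log2fc[out$summary$class == "up_IR"], -1)

  # identical distributions: nothing significant
  fc_null <- stats::setNames(rep(c(-0.5, 0.5), 16),
                             c(paste0("u", 1:8), paste0("d", 1:8),
                               paste0("s", 1:8), paste0("n", 1:8)))
  out_null <- class_expression_contrast(classes, fc_null)
  expect_true(all(out_null$tests$p_value > 0.3))

  # tiny classes are skipped with a notice, not tested
  small <- list(up_IR = "u1", down_IR = paste0("d", 1:8),
                stable_IR = character(0), no_IR = paste0("n", 1:8),
                change_IR = "u1")
  out_small <- class_expression_contrast(small, fc)
  expect_true(is.na(
    out_small$tests$p_value[out_small$tests$contrast == "up_IR vs no_IR"]))
})

test_that("IRI fold-change binning recovers a perfect anti-correlation", {
  n <- 80
  ids <- sprintf("g%02d:I1", 1:n)
  iri_a <- rep(0.2, n)
  iri_b <- seq(0.05, 0.75, length.out = n)
  wide <- cbind(A_r1 = iri_a, A_r2 = iri_a, B_r1 = iri_b, B_r2 = iri_b)
  rownames(wide) <- ids
  im <- manual_iri_matrix(wide)
  # expression FC strictly decreasing as IRI FC increases
  fc <- stats::setNames(seq(2, -2, length.out = n), sub(":.*", "", ids))
  bt <- iri_fc_binning(im, fc, "A", "B", n_bins = 8)
  expect_equal(bt$rho, -1)
  expect_equal(sum(bt$bins$n), n)
  expect_equal(nrow(bt$bins), 8L)
  expect_true(all(diff(bt$bins$iri_fc_min) > 0))

  # deterministic: same input, same binning
  bt2 <- iri_fc_binning(im, fc, "A", "B", n_bins = 8)
  expect_identical(bt$genes, bt2$genes)
  expect_error(iri_fc_binning(im, fc[1:5], "A", "B", n_bins = 8), "n_bins")
})

test_that("random gene pairing gives a null bin trend (permutation check)", {
  set.seed(31)
  n <- 80
  ids <- sprintf("g%02d:I1", 1:n)
  wide <- cbind(A_r1 = rep(0.2, n), B_r1 = runif(n, 0.05, 0.8))
  rownames(wide) <- ids
  im <- manual_iri_matrix(wide)
  fc_vals <- rnorm(n)
  fc <- stats::setNames(fc_vals, sub(":.*", "", ids))
  obs <- iri_fc_binning(im, fc, "A", "B")$rho
  perm <- replicate(300, {
    iri_fc_binning(im, stats::setNames(sample(fc_vals), names(fc)),
                   "A", "B")$rho
  })
  # observed rho sits inside the permutation null's central region
  expect_gte(obs, quantile(perm, 0.005))
  expect_lte(obs, quantile(perm, 0.995))
})

test_that("gene-level IRI fold change picks the largest-shift intron", {
  wide <- rbind("gA:I1" = c(0.2, 0.25), "gA:I2" = c(0.2, 0.6),
                "gB:I1" = c(0.5, 0.1))
  colnames(wide) <- c("A_r1", "B_r1")
  gfc <- gene_iri_fold_change(manual_iri_matrix(wide), "A", "B",
                              delta = 0.01)
  expect_equal(gfc$intron_id[gfc$gene_id == "gA"], "gA:I2")
  expect_equal(gfc$iri_fc[gfc$gene_id == "gA"], 0.61 / 0.21)
})

test_that("feature contrasts honour sidedness and the rank-sum identity", {
  tab <- data.frame(
    label = rep(c("up_IR", "down_IR", "stable_IR"), each = 6),
    gc = c(rep(0.6, 12), rep(0.4, 6)),
    len = c(300, 320, 280, 310, 305, 295, 290, 315, 300, 285, 310, 305,
            800, 850, 900, 820, 870, 910)
  )
  hi <- feature_contrast(tab, "change_IR", "stable_IR", "gc", "greater")
  expect_lt(hi$p_value, 0.05)
  expect_equal(hi$n_a, 12L)
  lo <- feature_contrast(tab, "change_IR", "stable_IR", "len", "less")
  expect_lt(lo$p_value, 0.01)
  # identical samples: no signal
  same <- data.frame(label = rep(c("up_IR", "stable_IR"), each = 5),
                     gc = rep(c(0.5, 0.52, 0.48, 0.51, 0.49), 2))
  expect_gt(feature_contrast(same, "up_IR", "stable_IR", "gc",
                             "greater")$p_value, 0.3)
  # swapping groups under a one-sided test mirrors the alternative
  a <- tab$len[tab$label %in% c("up_IR", "down_IR")]
  b <- tab$len[tab$label == "stable_IR"]
  p1 <- feature_contrast(tab, "change_IR", "stable_IR", "len",
                         "less")$p_value
  p2 <- feature_contrast(tab, "stable_IR", "change_IR", "len",
                         "greater")$p_value
  expect_equal(p1, p2, tolerance = 1e-12)
  expect_error(feature_contrast(tab, "up_IR", "stable_IR", "nope"),
               "unknown feature")
})

test_that("wilcox.test matches a brute-force enumeration oracle", {
  set.seed(37)
  for (i in 1:12) {
    a <- round(runif(sample(3:5, 1)), 6)
    b <- round(runif(sample(3:5, 1)), 6)
    p_pkg <- stats::wilcox.test(a, b, alternative = "greater",
                                exact = TRUE)$p.value
    expect_equal(p_pkg, wilcox_enum_greater(a, b), tolerance = 1e-12)
  }
})

test_that("overlap fraction reproduces the reported ratio arithmetic", {
  a <- paste0("g", 1:685)
  b <- c(paste0("g", 1:112), paste0("x", 1:200))
  out <- overlap_fraction(a, b)
  expect_equal(out$n_overlap, 112L)
  expect_equal(out$n_A_only, 573L)
  expect_equal(round(out$percentage, 1), 16.4)
  expect_equal(overlap_fraction(c("a", "b"), c("c"))$percentage, 0)
  expect_equal(overlap_fraction(c("a", "b"), c("a", "b", "c"))$percentage,
               100)
  expect_error(overlap_fraction(character(0), "a"), "empty")
})
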