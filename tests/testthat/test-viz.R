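toy_cmp <- function() {
  quant <- quantify(make_replicates(toy_counts()))
  part <- build_stringency_partition(quant)
  list(quant = quant, part = part,
       cmp = compare_states(quant, part, "control", "treatment"))
}

test_that("venn counts are the three disjoint high-stringency classes", {
  x <- toy_cmp()
  v <- venn_counts(x$part, "control", "treatment")
  # control high {A,D}, treatment high {A,B,C}
  expect_equal(v$unique_control, 1)
  expect_equal(v$shared, 1)
  expect_equal(v$unique_treatment, 2)
  hc <- high_stringency_ids(x$part, "control")
  ht <- high_stringency_ids(x$part, "treatment")
  expect_equal(v$unique_control + v$shared + v$unique_treatment,
               length(union(hc, ht)))
  expect_s3_class(plot_venn(v, "control", "treatment"), "ggplot")
})

test_that("venn layout solves the lens area for proportional circles", {
  v <- tibble::tibble(unique_control = 0, shared = 50, unique_treatment = 0)
  expect_s3_class(plot_venn(v), "ggplot")  # identical sets degenerate layout
  # half-overlap case: solved distance reproduces the requested lens area
  r <- sqrt(10 / pi)
  d <- speccount:::venn_circle_distance(r, r, 5)
  lens <- 2 * r^2 * acos(d / (2 * r)) - d / 2 * sqrt(4 * r^2 - d^2)
  expect_equal(lens, 5, tolerance = 1e-6)
})

test_that("volcano points are (log2 fc, -log10 p)", {
  x <- toy_cmp()
  pts <- volcano_points(x$cmp)
  tbl <- tidy(x$cmp) |> dplyr::filter(!is.na(p_value))
  expect_equal(nrow(pts), nrow(tbl))
  expect_equal(pts$x, tbl$log2_fold_change)
  expect_equal(pts$y, -log10(tbl$p_value))
  expect_s3_class(plot_volcano(x$cmp), "ggplot")
  expect_s3_class(autoplot(x$cmp), "ggplot")
})

test_that("heatmap selection ranks by p, |fc|, identifier and truncates", {
  set.seed(21)
  sim <- simulate_dataset(spc_design(
    n_proteins = 60, states = c(control = 3, treatment = 3),
    de_fraction = 0.3, dropout_rate = 0, seed = 21
  ))
  quant <- quantify(dplyr::filter(sim$data, spectral_count > 0))
  part <- build_stringency_partition(quant)
  cmp <- compare_states(quant, part, "control", "treatment")
  sel <- heatmap_selection(cmp, quant, k = 20)
  expect_equal(dplyr::n_distinct(sel$protein), 20)
  expect_equal(dplyr::n_distinct(sel$rank), 20)
  # rank order agrees with a full sort oracle
  tbl <- tidy(cmp) |> dplyr::filter(!is.na(p_value))
  oracle <- tbl[order(tbl$p_value, -abs(tbl$log2_fold_change),
                      tbl$protein), ]$protein[1:20]
  expect_equal(unique(sel$protein), oracle)
  # truncation below k
  small <- toy_cmp()
  sel_small <- heatmap_selection(small$cmp, small$quant, k = 20)
  n_tested <- sum(!is.na(tidy(small$cmp)$p_value))
  expect_equal(dplyr::n_distinct(sel_small$protein), n_tested)
  expect_s3_class(plot_heatmap(cmp, quant), "ggplot")
})

test_that("p-value histogram uses fixed 0.05 bins with the first highlighted", {
  h <- pvalue_histogram(c(0.01, 0.04, 0.2, 0.97, 1))
  expect_equal(nrow(h), 20)
  expect_equal(sum(h$count), 5)
  expect_equal(h$count[1], 2)
  expect_true(h$highlight[1] && !any(h$highlight[-1]))
  expect_equal(h$count[20], 2)  # 0.97 and 1 fall in the closed last bin
  all_small <- pvalue_histogram(rep(0.01, 7))
  expect_equal(all_small$count[1], 7)
  expect_error(pvalue_histogram(c(0.5, 1.5)), "0, 1")
  expect_s3_class(plot_pvalue_histogram(runif(50)), "ggplot")
})

test_that("PCA scores match a direct eigendecomposition on a toy matrix", {
  set.seed(8)
  m <- matrix(rnorm(20), nrow = 4)  # 4 replicates x 5 proteins
  quant <- tibble::tibble(
    state = "s",
    replicate = rep(1:4, times = 5),
    protein = rep(sprintf("P%d", 1:5), each = 4),
    ln_nsaf = as.vector(m),
    spectral_count = 1
  )
  scores <- pca_scores(quant, on = "ln_nsaf")
  centred <- scale(m, center = TRUE, scale = FALSE)
  eig <- eigen(stats::cov(centred))
  proj <- centred %*% eig$vectors[, 1:2]
  # scores match up to per-component sign
  for (j in 1:2) {
    got <- scores[[paste0("PC", j)]]
    expect_true(
      isTRUE(all.equal(got, proj[, j], tolerance = 1e-8)) ||
        isTRUE(all.equal(got, -proj[, j], tolerance = 1e-8))
    )
  }
  ev <- attr(scores, "explained")
  expect_lte(sum(ev), 1 + 1e-12)
  # identical replicates coincide in score space
  m2 <- m; m2[2, ] <- m2[1, ]
  quant2 <- dplyr::mutate(quant, ln_nsaf = as.vector(m2))
  s2 <- pca_scores(quant2)
  expect_equal(s2$PC1[1], s2$PC1[2], tolerance = 1e-9)
  expect_equal(s2$PC2[1], s2$PC2[2], tolerance = 1e-9)
  expect_s3_class(plot_pca(quant), "ggplot")
  expect_s3_class(
    plot_pca(quant, groups = list(A = c(1, 2), B = c(3, 4))), "ggplot"
  )
})
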