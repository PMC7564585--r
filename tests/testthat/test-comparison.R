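test_that("shared/unique sets follow the low-stringency presence rule", {
  # high sets {A,B} / {B,C}; all sets equal high sets -> plain set algebra
  part <- tibble::tibble(
    state = rep(c("x", "y"), each = 2),
    protein = c("A", "B", "B", "C"),
    summed_count = 10,
    high_stringency = TRUE
  )
  class(part) <- c("spc_partition", class(part))
  s <- shared_and_unique(part, "x", "y")
  expect_equal(s$shared, "B")
  expect_equal(s$unique_control, "A")
  expect_equal(s$unique_treatment, "C")

  # A high in control but present at low stringency in treatment:
  # tested as shared, not unique
  part2 <- tibble::tibble(
    state = c("x", "y"),
    protein = c("A", "A"),
    summed_count = c(10, 2),
    high_stringency = c(TRUE, FALSE)
  )
  class(part2) <- c("spc_partition", class(part2))
  s2 <- shared_and_unique(part2, "x", "y")
  expect_equal(s2$tested, "A")
  expect_equal(s2$unique_control, character(0))

  # identical states: no uniques
  s3 <- shared_and_unique(part, "x", "x")
  expect_equal(s3$unique_control, character(0))
  expect_equal(s3$unique_treatment, character(0))
})

test_that("pooled t-test matches the textbook computation", {
  x <- c(1.0, 1.1, 0.9)
  y <- c(1.2, 1.3, 1.1)
  # hand pooled-variance t with 4 df
  sp2 <- (2 * var(x) + 2 * var(y)) / 4
  t_stat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  p_hand <- 2 * pt(-abs(t_stat), df = 4)
  expect_equal(ttest_lnnsaf(x, y), p_hand, tolerance = 1e-12)

  expect_equal(ttest_lnnsaf(c(1, 1, 1), c(1, 1, 1)), 1)
  expect_equal(ttest_lnnsaf(c(0, 0, 0), c(10, 10, 10)), 0)
  jit <- c(-1e-9, 0, 1e-9)
  expect_lt(ttest_lnnsaf(0 + jit, 10 + jit), 1e-10)
  expect_error(ttest_lnnsaf(1, c(1, 2)), "2 replicates")
})

test_that("classification gates on significance and fold-change sign", {
  quant <- quantify(make_replicates(toy_counts()))
  part <- build_stringency_partition(quant)
  cmp <- compare_states(quant, part, "control", "treatment")
  tbl <- tidy(cmp)
  expect_equal(tbl$category[tbl$protein == "C"], "UP")     # 1,1,1 -> 9,9,9
  expect_equal(tbl$category[tbl$protein == "A"], "UNCHANGED")  # jittered null
  expect_equal(tbl$category[tbl$protein == "D"], "UNIQUE_CONTROL")
  # B fails control presence but is present there at low stringency
  expect_true(tbl$protein[tbl$category == "UNCHANGED" |
                            tbl$category == "UP" |
                            tbl$category == "DOWN"] |> length() >= 3)
  # categories partition the stream inventory
  g <- glance(cmp)
  expect_equal(
    g$n_up + g$n_down + g$n_unchanged + g$n_unique_control +
      g$n_unique_treatment,
    nrow(tbl)
  )
  # UP implies positive fold change and significance
  sig <- dplyr::filter(tbl, category == "UP")
  expect_true(all(sig$log2_fold_change > 0 & sig$p_value < 0.05))
})

test_that("swapping state labels mirrors categories and keeps p-values", {
  quant <- quantify(make_replicates(toy_counts()))
  part <- build_stringency_partition(quant)
  fwd <- tidy(compare_states(quant, part, "control", "treatment"))
  rev <- tidy(compare_states(quant, part, "treatment", "control"))
  j <- dplyr::inner_join(fwd, rev, by = "protein",
                         suffix = c("_f", "_r")) |>
    dplyr::filter(!is.na(p_value_f))
  expect_equal(j$p_value_f, j$p_value_r, tolerance = 1e-12)
  expect_equal(j$log2_fold_change_f, -j$log2_fold_change_r,
               tolerance = 1e-12)
  map <- c(UP = "DOWN", DOWN = "UP", UNCHANGED = "UNCHANGED")
  expect_equal(unname(map[j$category_f]), j$category_r)
  expect_equal(sum(fwd$category == "UNIQUE_CONTROL"),
               sum(rev$category == "UNIQUE_TREATMENT"))
})

test_that("a BH q threshold replaces the alpha rule when supplied", {
  quant <- quantify(make_replicates(toy_counts()))
  part <- build_stringency_partition(quant)
  strict <- tidy(compare_states(quant, part, "control", "treatment",
                                q_threshold = 1e-9))
  expect_true(all(strict$category %in%
                    c("UNCHANGED", "UNIQUE_CONTROL", "UNIQUE_TREATMENT")))
  loose <- tidy(compare_states(quant, part, "control", "treatment",
                               q_threshold = 1))
  tested <- dplyr::filter(loose, !is.na(p_value))
  expect_true(all(tested$category %in% c("UP", "DOWN")))
})

test_that("null data flags about 5% of shared proteins at p < 0.05", {
  p_all <- c()
  for (seed in 1:10) {
    sim <- simulate_dataset(spc_design(
      n_proteins = 150, states = c(a = 3, b = 3), de_fraction = 0,
      dropout_rate = 0, seed = seed
    ))
    quant <- quantify(dplyr::filter(sim$data, spectral_count > 0))
    part <- build_stringency_partition(quant)
    cmp <- tidy(compare_states(quant, part, "a", "b"))
    p_all <- c(p_all, cmp$p_value[!is.na(cmp$p_value)])
  }
  frac <- mean(p_all < 0.05)
  # binomial error around 0.05 at n > 1000
  expect_gt(frac, 0.02)
  expect_lt(frac, 0.09)
})
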