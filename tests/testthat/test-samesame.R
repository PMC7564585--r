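# brute-force oracle: all ordered k-subsets, deduplicated as unordered splits
brute_force_splits <- function(reps) {
  k <- length(reps) / 2
  combos <- utils::combn(sort(reps), k, simplify = FALSE)
  seen <- character(0)
  out <- list()
  for (a in combos) {
    b <- setdiff(reps, a)
    key <- paste(
      sort(c(paste(a, collapse = ","), paste(b, collapse = ","))),
      collapse = "|"
    )
    if (!key %in% seen) {
      seen <- c(seen, key)
      out[[length(out) + 1]] <- list(a = a, b = b)
    }
  }
  out
}

# independent BH step-up oracle
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, m * p[o[i]] / i)
    q[o[i]] <- min(running, 1)
  }
  q
}

test_that("six replicates yield exactly the ten non-redundant splits", {
  parts <- enumerate_triplet_partitions(1:6)
  expect_equal(nrow(parts), 10)
  oracle <- brute_force_splits(1:6)
  expect_equal(length(oracle), 10)
  canon <- function(a, b) paste(sort(c(paste(sort(a), collapse = ","),
                                       paste(sort(b), collapse = ","))),
                                collapse = "|")
  got <- purrr::map2_chr(parts$group_a, parts$group_b, canon)
  want <- purrr::map_chr(oracle, ~ canon(.x$a, .x$b))
  expect_setequal(got, want)
  # disjoint and covering
  for (i in seq_len(nrow(parts))) {
    expect_length(intersect(parts$group_a[[i]], parts$group_b[[i]]), 0)
    expect_setequal(c(parts$group_a[[i]], parts$group_b[[i]]), 1:6)
  }
  expect_error(enumerate_triplet_partitions(1:5), "even number")
})

test_that("split count is C(2k, k) / 2 for k up to 4", {
  for (k in 1:4) {
    reps <- seq_len(2 * k)
    expect_equal(nrow(enumerate_triplet_partitions(reps)),
                 choose(2 * k, k) / 2)
    expect_equal(length(brute_force_splits(reps)), choose(2 * k, k) / 2)
  }
})

test_that("BH adjustment matches an independent step-up oracle", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(99)
  for (i in 1:25) {
    p <- runif(sample(1:100, 1))^sample(1:3, 1)
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    # monotone in p
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

six_rep_quant <- function(seed = 3, n = 60) {
  sim <- simulate_dataset(spc_design(
    n_proteins = n, states = c(control = 6), de_fraction = 0,
    dropout_rate = 0, seed = seed
  ))
  quantify(dplyr::filter(sim$data, spectral_count > 0))
}

test_that("PQ-FDR curves are monotone, bounded, and pinned at the ends", {
  quant <- six_rep_quant()
  part <- build_stringency_partition(quant)
  high <- high_stringency_ids(part, "control")
  parts <- enumerate_triplet_partitions(1:6)
  for (i in seq_len(nrow(parts))) {
    cv <- pqfdr_for_partition(quant, parts$group_a[[i]], parts$group_b[[i]],
                              proteins = high)
    expect_equal(cv$pqfdr[cv$q == 0], 0)
    expect_equal(cv$pqfdr[cv$q == 1], 100)
    expect_true(all(diff(cv$pqfdr) >= 0))
    expect_true(all(cv$pqfdr >= 0 & cv$pqfdr <= 100))
    expect_equal(attr(cv, "n_proteins_tested"), length(high))
  }
  expect_error(
    pqfdr_for_partition(quant, 1:3, 3:6, proteins = high), "overlap"
  )
  expect_error(
    pqfdr_for_partition(quant, 1:3, 4:6, proteins = character(0)), "empty"
  )
})

test_that("curve averaging is pointwise and preserves monotonicity", {
  g <- seq(0, 1, by = 0.01)
  c0 <- tibble::tibble(q = g, pqfdr = rep(0, length(g)))
  c2 <- tibble::tibble(q = g, pqfdr = rep(2, length(g)))
  avg <- average_pqfdr_curves(list(c0, c2))
  expect_equal(avg$pqfdr, rep(1, length(g)))
  expect_equal(average_pqfdr_curves(list(c2, c2))$pqfdr, c2$pqfdr)
  inc <- tibble::tibble(q = g, pqfdr = 100 * g)
  avg2 <- average_pqfdr_curves(list(c0, inc))
  expect_true(all(diff(avg2$pqfdr) >= 0))
  expect_error(
    average_pqfdr_curves(list(c0, tibble::tibble(q = g[-1],
                                                 pqfdr = g[-1]))),
    "grids"
  )
})

test_that("threshold derivation interpolates to the target crossing", {
  g <- seq(0, 1, by = 0.01)
  flat <- tibble::tibble(q = g, pqfdr = rep(0, length(g)))
  expect_equal(derive_q_threshold(flat, target = 1)$q_star, 1)
  linear <- tibble::tibble(q = g, pqfdr = 100 * g)
  expect_equal(derive_q_threshold(linear, target = 1)$q_star, 0.01)
  # sub-grid refinement: crossing between grid points
  curve <- tibble::tibble(q = g, pqfdr = 100 * g^2)  # crosses 1% at q = 0.1
  thr <- derive_q_threshold(curve, target = 1)
  expect_gte(thr$q_star, 0.1 - 0.01)
  expect_lte(thr$q_star, 0.1)
  expect_lte(thr$pqfdr_at_q_star, 1)
  steep <- tibble::tibble(q = g, pqfdr = c(0, rep(50, length(g) - 1)))
  expect_warning(thr0 <- derive_q_threshold(steep, target = 1), "q_star = 0")
  expect_equal(thr0$q_star, 0)
})

test_that("relabelling replicates leaves the state average curve unchanged", {
  quant <- six_rep_quant(seed = 5)
  part <- build_stringency_partition(quant)
  ss1 <- samesame_analysis(quant, part)
  relabel <- c(4L, 6L, 1L, 3L, 2L, 5L)
  quant2 <- dplyr::mutate(quant, replicate = relabel[replicate])
  ss2 <- samesame_analysis(quant2, part)
  expect_equal(ss1$state_averages$pqfdr, ss2$state_averages$pqfdr,
               tolerance = 1e-9)
  expect_equal(ss1$threshold$q_star, ss2$threshold$q_star, tolerance = 1e-9)
})

test_that("same-same runs per six-replicate state and averages across them", {
  sim <- simulate_dataset(spc_design(
    n_proteins = 60, states = c(control = 6, treatment = 6),
    de_fraction = 0, dropout_rate = 0, seed = 13
  ))
  quant <- quantify(dplyr::filter(sim$data, spectral_count > 0))
  part <- build_stringency_partition(quant)
  ss <- samesame_analysis(quant, part)
  expect_setequal(ss$states, c("control", "treatment"))
  expect_equal(nrow(ss$curves), 2 * 10 * 101)
  manual <- average_pqfdr_curves(
    ss$state_averages |>
      dplyr::group_split(state) |>
      purrr::map(~ dplyr::select(.x, q, pqfdr))
  )
  expect_equal(ss$grand_average$pqfdr, manual$pqfdr)
  expect_lte(
    ss$grand_average$pqfdr[
      max(which(ss$grand_average$q <= ss$threshold$q_star))
    ],
    ss$threshold$target
  )
  # a state without six replicates is rejected by name
  expect_error(samesame_analysis(quant, part, states = "nope"),
               "six replicates")
})
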