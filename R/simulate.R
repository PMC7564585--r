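#' Design for a synthetic spectral-count dataset
#'
#' Describes the generative model for search-engine-style replicate CSVs
#' with known ground truth. Per-protein baseline abundance is log-normal
#' across the inventory; per-replicate counts are negative binomial around
#' the (possibly fold-changed) mean, or Poisson for a clean null; dropout
#' zeroes a (protein, replicate) cell after sampling, and zero-count rows
#' are omitted from the written CSV the way a search engine simply does not
#' report an unidentified protein. Differential expression is planted on a
#' fraction of proteins in every non-control state, direction split evenly.
#'
#' @param n_proteins Inventory size (default 300).
#' @param states Named integer vector of replicates per state, first state
#'   is the control (default `c(control = 3, treatment = 3)`).
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of the
#'   per-protein mean spectral count (defaults `log(30)`, 0.8), emulating
#'   the abundance range of reproducibly identified proteins.
#' @param de_fraction Fraction of proteins with a planted fold change in
#'   non-control states (default 0.2).
#' @param de_fold_change Multiplicative effect size (default 4).
#' @param dropout_rate Probability a sampled cell is zeroed (default 0.05).
#' @param noise_model `"nbinom"` (default; spectral counts are
#'   over-dispersed in practice) or `"poisson"`.
#' @param dispersion Negative binomial size parameter (default 25, i.e.
#'   replicate coefficients of variation around 25-35% on top of counting
#'   noise).
#' @param mw_range Molecular-weight sampling bounds in kDa (default 10-250).
#' @param seed Integer RNG seed (default 1).
#' @return An `spc_design` list.
#' @export
spc_design <- function(n_proteins = 300,
                       states = c(control = 3, treatment = 3),
                       baseline_meanlog = log(30), baseline_sdlog = 0.8,
                       de_fraction = 0.2, de_fold_change = 4,
                       dropout_rate = 0.05,
                       noise_model = c("nbinom", "poisson"),
                       dispersion = 25, mw_range = c(10, 250), seed = 1) {
  noise_model <- match.arg(noise_model)
  if (is.null(names(states)) || any(!nzchar(names(states)))) {
    abort("states must be a named vector of replicate counts")
  }
  if (de_fraction < 0 || de_fraction > 1) abort("de_fraction must be in [0,1]")
  structure(
    list(
      n_proteins = n_proteins, states = states,
      baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
      de_fraction = de_fraction, de_fold_change = de_fold_change,
      dropout_rate = dropout_rate, noise_model = noise_model,
      dispersion = dispersion, mw_range = mw_range, seed = seed
    ),
    class = "spc_design"
  )
}

#' Read a dataset design from YAML
#'
#' @param path YAML file whose keys mirror the [spc_design()] arguments
#'   (`states` as a label-to-replicates mapping).
#' @return An `spc_design`.
#' @export
read_design_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$states)) y$states <- unlist(y$states)
  do.call(spc_design, y)
}

#' Simulate a spectral-count dataset with known ground truth
#'
#' Draws counts per the design and, when `dir` is given, writes one
#' dialect-conformant `{state}-{R#}.csv` per replicate (zero-count proteins
#' omitted from that file). Generation is fully seeded: the same design
#' yields byte-identical files.
#'
#' @param design An [spc_design()].
#' @param dir Output directory for the CSV files; `NULL` to skip writing.
#' @param dialect Output dialect name (default `"gpm_xtandem"`).
#' @return List with `data` (long tibble of all sampled cells, including
#'   zeros), `truth` (per protein: `protein`, `molecular_weight`,
#'   `baseline_mean`, `is_de`, `direction`, `fold_change`), and `files`
#'   (paths written, or `NULL`).
#' @export
simulate_dataset <- function(design, dir = NULL, dialect = "gpm_xtandem") {
  stopifnot(inherits(design, "spc_design"))
  set.seed(design$seed)
  n <- design$n_proteins
  protein <- sprintf("SYN%04d", seq_len(n))
  mw <- runif(n, design$mw_range[1], design$mw_range[2])
  base_mean <- rlnorm(n, design$baseline_meanlog, design$baseline_sdlog)
  n_de <- round(design$de_fraction * n)
  is_de <- seq_len(n) <= n_de
  direction <- rep("none", n)
  if (n_de > 0) {
    direction[is_de] <- sample(c("up", "down"), n_de, replace = TRUE)
  }
  fold <- ifelse(direction == "up", design$de_fold_change,
                 ifelse(direction == "down", 1 / design$de_fold_change, 1))
  truth <- tibble(
    protein = protein, molecular_weight = mw, baseline_mean = base_mean,
    is_de = is_de, direction = direction, fold_change = fold
  )
  draw <- function(mu) {
    if (design$noise_model == "poisson") rpois(n, mu)
    else rnbinom(n, size = design$dispersion, mu = mu)
  }
  cells <- purrr::imap(design$states, function(n_rep, st) {
    mu <- if (st == names(design$states)[1]) base_mean else base_mean * fold
    purrr::map(seq_len(n_rep), function(r) {
      counts <- draw(mu)
      dropped <- runif(n) < design$dropout_rate
      counts[dropped] <- 0L
      tibble(
        state = st, replicate = r, protein = protein,
        spectral_count = as.numeric(counts),
        score = round(-runif(n, 3, 120), 1),
        molecular_weight = mw
      )
    }) |> bind_rows()
  }) |> bind_rows()
  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- cells |>
      filter(.data$spectral_count > 0) |>
      dplyr::group_split(.data$state, .data$replicate) |>
      purrr::map_chr(function(tbl) {
        path <- file.path(dir, paste0(tbl$state[1], "-", tbl$replicate[1],
                                      ".csv"))
        write_replicate_csv(tbl, path, dialect = dialect)
        path
      })
  }
  list(data = cells, truth = truth, files = files)
}

#' Write a canonical replicate table as a dialect-conformant CSV
#'
#' @param data Tibble with `protein`, `spectral_count`, `score`,
#'   `molecular_weight` columns (zero-count rows are dropped: an
#'   unidentified protein has no row in a search-engine export).
#' @param path Output CSV path.
#' @param dialect Dialect name from the registry.
#' @param registry Dialect registry.
#' @return `path`, invisibly.
#' @export
write_replicate_csv <- function(data, path, dialect = "gpm_xtandem",
                                registry = dialect_registry()) {
  if (!dialect %in% names(registry)) abort(paste0("unknown dialect: ", dialect))
  cols <- registry[[dialect]]$columns
  out <- data |>
    filter(.data$spectral_count > 0) |>
    arrange(.data$protein)
  out <- tibble(
    !!cols$protein := out$protein,
    !!cols$spectral_count := out$spectral_count,
    !!cols$score := out$score,
    !!cols$molecular_weight := out$molecular_weight
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

# fixed hand-sized two-state dataset: counts chosen to exercise every MSC
# and uniqueness pathway (presence failures, sum failures, true uniques,
# planted up/down changes, singleton noise)
worked_example_counts <- function() {
  tibble::tribble(
    ~protein, ~molecular_weight, ~c1, ~c2, ~c3, ~t1, ~t2, ~t3,
    "P01",  50, 10, 12, 11, 11, 10, 12,
    "P02",  30, 20, 22, 18,  5,  6,  5,
    "P03",  80,  3,  4,  3, 12, 14, 13,
    "P04",  25,  2,  2,  1,  2,  2,  2,
    "P05",  60,  1,  1,  1,  1,  2,  1,
    "P06",  45,  5,  0,  6,  4,  5,  6,
    "P07",  70,  8,  9,  7,  0,  0,  0,
    "P08",  55,  0,  0,  0,  7,  8,  9,
    "P09",  40,  0,  0,  4,  0,  0,  0,
    "P10",  90, 15, 14, 16, 30, 29, 31,
    "P11", 100,  9,  8, 10,  9, 10,  8,
    "P12",  20,  6,  7,  6,  7,  6,  7,
    "P13",  35, 12, 11, 13, 12, 13, 11,
    "P14",  65,  4,  5,  4,  5,  4,  5,
    "P15", 110, 25, 24, 26, 25, 26, 24,
    "P16",  15,  3,  3,  3,  3,  3,  4,
    "P17",  75,  7,  6,  8,  7,  8,  6,
    "P18",  85, 18, 19, 17, 18, 17, 19,
    "P19",  95,  2,  3,  2,  2,  2,  3,
    "P20", 120, 40, 38, 42, 39, 41, 40
  )
}

#' Write the fixed worked-example dataset
#'
#' A hand-sized two-state (control, treatment) x 3-replicate dataset of 20
#' proteins whose MSC survivors, NSAF values and t-test p-values are known
#' and shipped as expected-output files under
#' `system.file("extdata", "worked_example", package = "speccount")`.
#'
#' @param dir Output directory.
#' @param dialect Output dialect (default `"gpm_xtandem"`).
#' @return Character vector of the six file paths written.
#' @export
worked_example <- function(dir, dialect = "gpm_xtandem") {
  wide <- worked_example_counts()
  long <- wide |>
    tidyr::pivot_longer(c1:t3, names_to = "rep", values_to = "spectral_count") |>
    mutate(
      state = ifelse(substr(.data$rep, 1, 1) == "c", "control", "treatment"),
      replicate = as.integer(substr(.data$rep, 2, 2)),
      score = -10
    )
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  long |>
    dplyr::group_split(.data$state, .data$replicate) |>
    purrr::map_chr(function(tbl) {
      path <- file.path(dir, paste0(tbl$state[1], "-", tbl$replicate[1],
                                    ".csv"))
      write_replicate_csv(tbl, path, dialect = dialect)
      path
    })
}
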