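# shared fixtures, all built in code

# long replicate tibble from a wide count spec: one row per protein,
# one count column per (state initial, replicate), e.g. c1, c2, t1 ...
make_replicates <- function(wide, states = c(c = "control", t = "treatment"),
                            score = -10) {
  wide |>
    tidyr::pivot_longer(-c(protein, molecular_weight),
                        names_to = "rep", values_to = "spectral_count") |>
    dplyr::mutate(
      state = unname(states[substr(rep, 1, 1)]),
      replicate = as.integer(substring(rep, 2)),
      score = score
    ) |>
    dplyr::select(state, replicate, protein, spectral_count, score,
                  molecular_weight) |>
    dplyr::filter(spectral_count > 0)
}

quantify <- function(long, pseudocount = 0.5) {
  long |>
    dplyr::group_split(state) |>
    purrr::map(collate_state) |>
    dplyr::bind_rows() |>
    add_nsaf(pseudocount = pseudocount)
}

# the small three-state count table used across stringency/comparison tests
toy_counts <- function() {
  tibble::tribble(
    ~protein, ~molecular_weight, ~c1, ~c2, ~c3, ~t1, ~t2, ~t3,
    "A", 50, 2, 3, 2, 2, 2, 3,
    "B", 40, 5, 0, 5, 4, 4, 4,
    "C", 60, 1, 1, 1, 9, 9, 9,
    "D", 30, 8, 9, 7, 0, 0, 0
  )
}

worked_example_dir <- function() {
  d <- withr::local_tempdir(.local_envir = parent.frame())
  worked_example(d)
  d
}

expected_path <- function(file) {
  system.file("extdata", "worked_example", file, package = "speccount")
}
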