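#' Collate replicates of one state into a complete protein x replicate grid
#'
#' Takes the union of protein identifiers over the replicates of a single
#' state ("All Proteins") and fills absent (protein, replicate) cells with a
#' spectral count of zero, so every protein has one row per replicate.
#' Molecular weight must agree across replicates for the same identifier;
#' conflicting values trigger a warning and the first (lowest replicate) is
#' kept.
#'
#' @param data Long replicate tibble (columns `state`, `replicate`,
#'   `protein`, `spectral_count`, `score`, `molecular_weight`), one state
#'   only.
#' @return A tibble on the complete grid, ordered by protein then replicate.
#' @export
collate_state <- function(data) {
  if (nrow(data) == 0) abort("no replicate rows to collate")
  if (n_distinct(data$state) != 1) {
    abort(paste0("mixed state labels in one collation: ",
                 paste(unique(data$state), collapse = ", ")))
  }
  dup <- data |>
    dplyr::count(.data$replicate, .data$protein) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort("duplicate (replicate, protein) rows; merge duplicates at parse time")
  }
  per_rep <- data |> distinct(.data$replicate, .data$protein)
  if (nrow(distinct(per_rep, .data$replicate)) !=
      n_distinct(data$replicate)) {
    abort("duplicate replicate numbers within one state")
  }
  mw <- data |>
    arrange(.data$replicate) |>
    group_by(.data$protein) |>
    summarise(
      n_mw = n_distinct(.data$molecular_weight),
      molecular_weight = first(.data$molecular_weight),
      .groups = "drop"
    )
  if (any(mw$n_mw > 1)) {
    warn(paste0("inconsistent molecular weight for ", sum(mw$n_mw > 1),
                " protein(s); keeping the first replicate's value"))
  }
  grid <- tidyr::expand_grid(
    state = unique(data$state),
    protein = sort(unique(data$protein)),
    replicate = sort(unique(data$replicate))
  )
  grid |>
    left_join(select(data, "replicate", "protein", "spectral_count", "score"),
              by = c("replicate", "protein")) |>
    left_join(select(mw, "protein", "molecular_weight"), by = "protein") |>
    mutate(spectral_count = tidyr::replace_na(.data$spectral_count, 0)) |>
    arrange(.data$protein, .data$replicate)
}

#' Minimum-spectral-count qualification for one protein
#'
#' A protein passes MSC in a state when it is identified (count > 0) in
#' every replicate of that state and its replicate-summed spectral count
#' reaches the threshold.
#'
#' @param counts Numeric vector of per-replicate spectral counts within one
#'   state.
#' @param min_summed_count Summed-count threshold (default 5).
#' @return Logical scalar.
#' @export
#' @examples
#' msc_qualify(c(2, 2, 1), 5)  # TRUE: present everywhere, sum 5
#' msc_qualify(c(2, 2, 0), 4)  # FALSE: absent from one replicate
msc_qualify <- function(counts, min_summed_count = 5) {
  all(counts > 0) && sum(counts) >= min_summed_count
}

#' Partition each state's proteins into high-stringency and All Proteins
#'
#' Applies the MSC rules per state over the collated grid: the
#' high-stringency set holds proteins present in every replicate of that
#' state with summed counts at or above the threshold; the All Proteins set
#' is everything observed at least once. The experiment-wide high-stringency
#' inventory is the union over states of the per-state qualifying sets.
#'
#' @param collated Collated tibble for one or more states (rows on the
#'   complete per-state grid, see [collate_state()]).
#' @param min_summed_count Summed-count threshold (default 5).
#' @return A tibble of class `spc_partition` with one row per (state,
#'   protein): columns `state`, `protein`, `summed_count`,
#'   `high_stringency`; attribute `min_summed_count`.
#' @export
build_stringency_partition <- function(collated, min_summed_count = 5) {
  if (min_summed_count < 1) abort("min_summed_count must be >= 1")
  n_reps <- collated |>
    group_by(.data$state) |>
    summarise(n = n_distinct(.data$replicate), .groups = "drop")
  if (any(n_reps$n < 3)) {
    warn(paste0(
      "state(s) with fewer than 3 replicates: ",
      paste(n_reps$state[n_reps$n < 3], collapse = ", "),
      "; MSC rules still apply but reproducibility filtering is weak"
    ))
  }
  out <- collated |>
    group_by(.data$state, .data$protein) |>
    summarise(
      summed_count = sum(.data$spectral_count),
      high_stringency = all(.data$spectral_count > 0) &&
        sum(.data$spectral_count) >= min_summed_count,
      .groups = "drop"
    ) |>
    filter(.data$summed_count > 0) |>
    arrange(.data$state, .data$protein)
  attr(out, "min_summed_count") <- min_summed_count
  class(out) <- c("spc_partition", class(out))
  out
}

#' Extract protein sets from a stringency partition
#'
#' @param partition An `spc_partition` from [build_stringency_partition()].
#' @param state State label; `NULL` for the experiment-wide union.
#' @return Character vector of protein identifiers.
#' @export
high_stringency_ids <- function(partition, state = NULL) {
  x <- filter(partition, .data$high_stringency)
  if (!is.null(state)) x <- filter(x, .data$state == !!state)
  sort(unique(x$protein))
}

#' @rdname high_stringency_ids
#' @export
all_protein_ids <- function(partition, state = NULL) {
  x <- partition
  if (!is.null(state)) x <- filter(x, .data$state == !!state)
  sort(unique(x$protein))
}
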