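#' Non-redundant equal-split partitions of a replicate set
#'
#' For six replicates there are C(6,3) = 20 ordered triplets collapsing to
#' 10 unordered triplet-vs-triplet splits. The canonical form puts the
#' lowest replicate number in `group_a`, which both deduplicates A-vs-B
#' against B-vs-A and fixes a deterministic order. The helper generalises to
#' any even number of replicates (C(2k, k) / 2 splits); the analysis
#' pipeline only ever uses 3-vs-3.
#'
#' @param replicates Vector of distinct replicate numbers, even length.
#' @return A tibble with `partition` id and list-columns `group_a`,
#'   `group_b`.
#' @export
#' @examples
#' enumerate_triplet_partitions(1:6)  # 10 rows
enumerate_triplet_partitions <- function(replicates) {
  replicates <- sort(unique(replicates))
  n <- length(replicates)
  if (n < 2 || n %% 2 != 0) {
    abort("need an even number (>= 2) of distinct replicate numbers")
  }
  k <- n %/% 2
  combos <- utils::combn(replicates, k, simplify = FALSE)
  # keeping only subsets that contain the smallest replicate halves the
  # C(2k, k) ordered subsets into unordered splits
  keep <- purrr::keep(combos, ~ replicates[1] %in% .x)
  tibble(
    partition = seq_along(keep),
    group_a = keep,
    group_b = purrr::map(keep, ~ setdiff(replicates, .x))
  )
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Adjusted value for the i-th smallest p is `min over j >= i of
#' m * p_(j) / j`, clipped at 1; a protein is significant at BH threshold Q
#' when its adjusted value is <= Q.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' PQ-FDR curve for one triplet-vs-triplet partition
#'
#' Splits one state's six replicates per the partition, t-tests every
#' high-stringency protein's lnNSAF between the two halves, BH-adjusts, and
#' for each grid threshold Q reports the percentage of proteins with
#' adjusted value <= Q. Since the halves are biologically identical, any
#' protein called significant is a false discovery at the protein
#' quantitation level: the curve is an empirical false-discovery-rate read
#' on the BH threshold.
#'
#' @param quant NSAF-quantified collated tibble for the state.
#' @param group_a,group_b Disjoint replicate-number vectors covering the
#'   state's replicates.
#' @param proteins Protein identifiers to test (the state's high-stringency
#'   set).
#' @param q_grid BH threshold grid (default 0, 0.01, ..., 1).
#' @param var_equal Pooled-variance t-test (default) or Welch.
#' @return A tibble with columns `q`, `pqfdr` (percent) and attribute
#'   `n_proteins_tested`.
#' @export
pqfdr_for_partition <- function(quant, group_a, group_b, proteins,
                                q_grid = seq(0, 1, by = 0.01),
                                var_equal = TRUE) {
  if (length(intersect(group_a, group_b)) > 0) {
    abort("partition groups overlap")
  }
  if (length(proteins) == 0) {
    abort("empty high-stringency set: nothing to test in same-same analysis")
  }
  sub <- quant |>
    filter(.data$protein %in% proteins,
           .data$replicate %in% c(group_a, group_b))
  pvals <- sub |>
    group_by(.data$protein) |>
    summarise(
      p_value = ttest_lnnsaf(
        .data$ln_nsaf[.data$replicate %in% group_a],
        .data$ln_nsaf[.data$replicate %in% group_b],
        var_equal = var_equal
      ),
      .groups = "drop"
    )
  qv <- bh_adjust(pvals$p_value)
  out <- tibble(
    q = q_grid,
    pqfdr = vapply(q_grid, function(q) 100 * mean(qv <= q), numeric(1))
  )
  attr(out, "n_proteins_tested") <- nrow(pvals)
  out
}

#' Pointwise average of PQ-FDR curves
#'
#' Applied twice in the workflow: over a state's ten partitions, then across
#' states' averages.
#'
#' @param curves List of curve tibbles on identical `q` grids.
#' @return One curve tibble, the arithmetic mean per grid point.
#' @export
average_pqfdr_curves <- function(curves) {
  if (length(curves) == 0) abort("no curves to average")
  grids <- purrr::map(curves, "q")
  if (!all(purrr::map_lgl(grids, ~ isTRUE(all.equal(.x, grids[[1]]))))) {
    abort("PQ-FDR curves are on different q grids")
  }
  tibble(
    q = grids[[1]],
    pqfdr = rowMeans(do.call(cbind, purrr::map(curves, "pqfdr")))
  )
}

#' Derive the BH threshold reaching a target PQ-FDR
#'
#' Picks the largest grid Q whose grand-average PQ-FDR is at or below the
#' target, then refines by linear interpolation between that point and the
#' next grid point where the curve crosses the target, giving a sub-grid
#' threshold. If the curve exceeds the target already at the first non-zero
#' grid point, no permissive threshold exists and 0 is returned with a
#' warning; a curve never exceeding the target returns 1.
#'
#' @param curve Grand-average PQ-FDR curve tibble (`q`, `pqfdr`).
#' @param target Target PQ-FDR percentage (default 1).
#' @return List with `q_star`, `target`, and `pqfdr_at_q_star` (the curve
#'   value at the last grid point at or below `q_star`).
#' @export
derive_q_threshold <- function(curve, target = 1) {
  if (is.unsorted(curve$q)) abort("q grid must be increasing")
  ok <- which(curve$pqfdr <= target)
  if (length(ok) == 0 || max(curve$q[ok]) == 0) {
    warn("PQ-FDR exceeds the target at every positive threshold; q_star = 0")
    return(list(q_star = 0, target = target, pqfdr_at_q_star = curve$pqfdr[1]))
  }
  i <- max(ok)
  if (i == nrow(curve)) {
    return(list(q_star = curve$q[i], target = target,
                pqfdr_at_q_star = curve$pqfdr[i]))
  }
  q_lo <- curve$q[i]; f_lo <- curve$pqfdr[i]
  q_hi <- curve$q[i + 1]; f_hi <- curve$pqfdr[i + 1]
  q_star <- if (f_hi > f_lo) {
    q_lo + (target - f_lo) * (q_hi - q_lo) / (f_hi - f_lo)
  } else {
    q_lo
  }
  list(q_star = q_star, target = target, pqfdr_at_q_star = f_lo)
}

#' Same-same permutation analysis of six-replicate states
#'
#' For every supplied state holding exactly six replicates: enumerate the
#' ten non-redundant 3-vs-3 splits, compute each split's PQ-FDR curve over
#' the high-stringency proteins (MSC applied across all six replicates),
#' average the ten curves, then average the per-state curves into a grand
#' average and derive the BH threshold at the target PQ-FDR. The derived
#' threshold replaces the flat 0.05 cut-off when the two-state comparison is
#' re-run.
#'
#' @param quant NSAF-quantified collated tibble covering the states.
#' @param partition Stringency partition over the same data.
#' @param states State labels to permute; defaults to every state in `quant`
#'   with exactly six replicates.
#' @param target_pqfdr Target PQ-FDR percentage (default 1).
#' @param q_grid BH threshold grid (default 0 to 1 step 0.01).
#' @param var_equal Pooled-variance t-test (default) or Welch.
#' @return An `spc_samesame` object: list with `partitions` (per-state
#'   partition tables), `curves` (per-partition curves, long tibble),
#'   `state_averages`, `grand_average`, `threshold` (from
#'   [derive_q_threshold()]) and `n_proteins` per state.
#' @export
samesame_analysis <- function(quant, partition, states = NULL,
                              target_pqfdr = 1,
                              q_grid = seq(0, 1, by = 0.01),
                              var_equal = TRUE) {
  reps <- quant |>
    distinct(.data$state, .data$replicate) |>
    dplyr::count(.data$state)
  if (is.null(states)) states <- reps$state[reps$n == 6]
  if (length(states) == 0) {
    abort("same-same analysis needs at least one state with six replicates")
  }
  bad <- setdiff(states, reps$state[reps$n == 6])
  if (length(bad) > 0) {
    abort(paste0("state(s) without exactly six replicates: ",
                 paste(bad, collapse = ", ")))
  }
  per_state <- purrr::map(setNames(states, states), function(st) {
    st_quant <- filter(quant, .data$state == st)
    high <- high_stringency_ids(partition, st)
    if (length(high) == 0) {
      abort(paste0("state ", st, " has an empty high-stringency set"))
    }
    parts <- enumerate_triplet_partitions(unique(st_quant$replicate))
    curves <- purrr::pmap(parts, function(partition, group_a, group_b) {
      pqfdr_for_partition(st_quant, group_a, group_b, proteins = high,
                          q_grid = q_grid, var_equal = var_equal)
    })
    list(
      partitions = parts,
      curves = curves,
      average = average_pqfdr_curves(curves),
      n_proteins = length(high)
    )
  })
  grand <- average_pqfdr_curves(purrr::map(per_state, "average"))
  thr <- derive_q_threshold(grand, target = target_pqfdr)
  curves_long <- purrr::imap(per_state, function(ps, st) {
    purrr::imap(ps$curves, function(cv, i) {
      mutate(cv, state = st, partition = i, .before = 1)
    }) |> bind_rows()
  }) |> bind_rows()
  out <- list(
    states = states,
    partitions = purrr::map(per_state, "partitions"),
    curves = curves_long,
    state_averages = purrr::imap(
      purrr::map(per_state, "average"),
      ~ mutate(.x, state = .y, .before = 1)
    ) |> bind_rows(),
    grand_average = grand,
    threshold = thr,
    n_proteins = purrr::map_int(per_state, "n_proteins")
  )
  class(out) <- "spc_samesame"
  out
}

#' @exportS3Method generics::tidy
tidy.spc_samesame <- function(x, ...) x$grand_average

#' @exportS3Method generics::glance
glance.spc_samesame <- function(x, ...) {
  tibble(
    n_states = length(x$states),
    n_partitions = sum(purrr::map_int(x$partitions, nrow)),
    q_star = x$threshold$q_star,
    target_pqfdr = x$threshold$target,
    pqfdr_at_q_star = x$threshold$pqfdr_at_q_star
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.spc_samesame <- function(object, ...) {
  plot_pqfdr(object, ...)
}

#' @export
print.spc_samesame <- function(x, ...) {
  cat("Same-same permutation analysis over state(s): ",
      paste(x$states, collapse = ", "), "\n",
      "Derived BH threshold q* = ", format(x$threshold$q_star, digits = 4),
      " at target PQ-FDR ", x$threshold$target, "%\n", sep = "")
  invisible(x)
}
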