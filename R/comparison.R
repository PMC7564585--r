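#' Shared and unique high-stringency proteins between two states
#'
#' Shared proteins are those in both states' high-stringency sets. A protein
#' counts as unique to a state only when its high-stringency identification
#' there has no trace at all in the other state's All Proteins list: a
#' low-stringency sighting in the other state means the protein is tested as
#' shared rather than declared unique, so borderline proteins still get a
#' p-value and users can see why they fell out of the high-stringency list.
#'
#' @param partition An `spc_partition` (see [build_stringency_partition()]).
#' @param control,treatment State labels.
#' @return A list with character vectors `shared` (intersection of the two
#'   high-stringency sets), `tested` (shared plus high-stringency proteins
#'   seen at low stringency in the other state), `unique_control`,
#'   `unique_treatment`.
#' @export
shared_and_unique <- function(partition, control, treatment) {
  hc <- high_stringency_ids(partition, control)
  ht <- high_stringency_ids(partition, treatment)
  ac <- all_protein_ids(partition, control)
  at <- all_protein_ids(partition, treatment)
  list(
    shared = intersect(hc, ht),
    tested = sort(union(intersect(hc, at), intersect(ht, ac))),
    unique_control = setdiff(hc, at),
    unique_treatment = setdiff(ht, ac)
  )
}

#' Two-sample Student's t-test on lnNSAF replicate vectors
#'
#' Two-sided, pooled-variance by default (`var_equal = FALSE` gives Welch).
#' Degenerate inputs with zero pooled variance return p = 1 when the group
#' means are equal (no evidence) and the p = 0 limit when they differ.
#'
#' @param x,y Numeric replicate vectors (>= 2 values each).
#' @param var_equal Pooled-variance Student's test when `TRUE` (default).
#' @return p-value in `[0, 1]`.
#' @export
ttest_lnnsaf <- function(x, y, var_equal = TRUE) {
  if (length(x) < 2 || length(y) < 2) abort("need >= 2 replicates per group")
  if (any(!is.finite(c(x, y)))) abort("non-finite lnNSAF values")
  if (sd(x) == 0 && sd(y) == 0) {
    return(if (mean(x) == mean(y)) 1 else 0)
  }
  stats::t.test(x, y, var.equal = var_equal)$p.value
}

#' Two-state differential expression on shared proteins
#'
#' Runs the control-vs-treatment comparison on one stringency stream:
#' per-protein Student's t-test on lnNSAF across replicates, log2 fold
#' change of mean NSAF (treatment over control), BH-adjusted q-values, and
#' classification into `UP` / `DOWN` / `UNCHANGED` (plus `UNIQUE_CONTROL` /
#' `UNIQUE_TREATMENT` rows in the high-stringency stream). Without a BH
#' threshold, significance is `p < alpha`; with `q_threshold` set (e.g. the
#' same-same derived value), significance is `q <= q_threshold`.
#'
#' @param quant NSAF-quantified collated tibble covering both states (see
#'   [add_nsaf()]).
#' @param partition Stringency partition over the same data.
#' @param control,treatment State labels; comparisons are relative to
#'   control.
#' @param stream `"high_stringency"` (MSC-filtered, with unique classes) or
#'   `"all_proteins"` (unfiltered, shared identifiers only).
#' @param alpha Per-test significance cut-off when no BH threshold is used
#'   (default 0.05).
#' @param q_threshold Optional BH q-value threshold replacing the alpha rule.
#' @param var_equal Pooled-variance t-test (default) or Welch.
#' @return An `spc_comparison` object: a tibble with one row per classified
#'   protein (`protein`, `mean_ln_nsaf_control`, `mean_ln_nsaf_treatment`,
#'   `log2_fold_change`, `p_value`, `q_value`, `category`, `stream`) and
#'   attributes recording the states and thresholds.
#' @export
compare_states <- function(quant, partition, control, treatment,
                           stream = c("high_stringency", "all_proteins"),
                           alpha = 0.05, q_threshold = NULL,
                           var_equal = TRUE) {
  stream <- match.arg(stream)
  sets <- shared_and_unique(partition, control, treatment)
  if (stream == "high_stringency") {
    tested <- sets$tested
    uniques <- tibble(
      protein = c(sets$unique_control, sets$unique_treatment),
      category = rep(c("UNIQUE_CONTROL", "UNIQUE_TREATMENT"),
                     c(length(sets$unique_control),
                       length(sets$unique_treatment)))
    )
  } else {
    tested <- intersect(all_protein_ids(partition, control),
                        all_protein_ids(partition, treatment))
    uniques <- tibble(protein = character(), category = character())
  }
  stats_tbl <- quant |>
    filter(.data$state %in% c(control, treatment),
           .data$protein %in% tested) |>
    group_by(.data$protein) |>
    summarise(
      mean_ln_nsaf_control = mean(.data$ln_nsaf[.data$state == control]),
      mean_ln_nsaf_treatment = mean(.data$ln_nsaf[.data$state == treatment]),
      log2_fold_change = log2_fold_change(
        mean(.data$nsaf[.data$state == control]),
        mean(.data$nsaf[.data$state == treatment])
      ),
      p_value = ttest_lnnsaf(.data$ln_nsaf[.data$state == control],
                             .data$ln_nsaf[.data$state == treatment],
                             var_equal = var_equal),
      .groups = "drop"
    ) |>
    mutate(q_value = bh_adjust(.data$p_value))
  significant <- if (is.null(q_threshold)) {
    stats_tbl$p_value < alpha
  } else {
    stats_tbl$q_value <= q_threshold
  }
  stats_tbl <- stats_tbl |>
    mutate(category = dplyr::case_when(
      significant & .data$log2_fold_change > 0 ~ "UP",
      significant & .data$log2_fold_change < 0 ~ "DOWN",
      .default = "UNCHANGED"
    ))
  out <- bind_rows(stats_tbl, uniques) |>
    mutate(stream = stream) |>
    arrange(.data$protein)
  attr(out, "control") <- control
  attr(out, "treatment") <- treatment
  attr(out, "alpha") <- alpha
  attr(out, "q_threshold") <- q_threshold
  class(out) <- c("spc_comparison", class(out))
  out
}

#' @exportS3Method generics::tidy
tidy.spc_comparison <- function(x, ...) {
  class(x) <- setdiff(class(x), "spc_comparison")
  as_tibble(x)
}

#' @exportS3Method generics::glance
glance.spc_comparison <- function(x, ...) {
  tibble(
    control = attr(x, "control"),
    treatment = attr(x, "treatment"),
    stream = x$stream[1] %||% NA_character_,
    n_tested = sum(!is.na(x$p_value)),
    n_up = sum(x$category == "UP"),
    n_down = sum(x$category == "DOWN"),
    n_unchanged = sum(x$category == "UNCHANGED"),
    n_unique_control = sum(x$category == "UNIQUE_CONTROL"),
    n_unique_treatment = sum(x$category == "UNIQUE_TREATMENT"),
    alpha = attr(x, "alpha"),
    q_threshold = attr(x, "q_threshold") %||% NA_real_
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.spc_comparison <- function(object, ...) {
  plot_volcano(object, ...)
}

#' @export
print.spc_comparison <- function(x, ...) {
  cat("Two-state comparison (", attr(x, "control"), " vs ",
      attr(x, "treatment"), "), stream: ", x$stream[1] %||% "?", "\n",
      sep = "")
  print(glance(x))
  NextMethod()
}
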