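#' Normalised spectral abundance factors for one replicate
#'
#' NSAF for protein k is (SpC_k / L_k) / sum_j (SpC_j / L_j), with the sum
#' running over the replicate's full protein basis, so NSAF is the fraction
#' of length-corrected spectral evidence a protein carries within that run.
#' Molecular weight stands in for length: the ratio is invariant to any
#' global unit factor (Da vs kDa), so no conversion is attempted.
#'
#' Zero counts receive `pseudocount` in the numerator only; the denominator
#' is built from the raw counts, so NSAF over the basis sums to exactly 1
#' before pseudocount adjustment and log-NSAF stays defined for proteins
#' missing from some replicates.
#'
#' @param counts Non-negative spectral counts, one per basis protein.
#' @param lengths Positive molecular weights (length proxy), same order.
#' @param pseudocount Count substituted for zeros in the numerator
#'   (default 0).
#' @return Numeric vector of NSAF values.
#' @export
#' @examples
#' compute_nsaf(c(10, 10, 5), c(100, 50, 50))  # 0.25 0.50 0.25
compute_nsaf <- function(counts, lengths, pseudocount = 0) {
  if (any(lengths <= 0) || any(is.na(lengths))) {
    abort("molecular weights must be positive")
  }
  if (any(counts < 0)) abort("spectral counts must be non-negative")
  if (all(counts == 0)) abort("all spectral counts are zero in this replicate")
  denom <- sum(counts / lengths)
  num <- ifelse(counts > 0, counts, pseudocount)
  (num / lengths) / denom
}

#' Add NSAF and lnNSAF columns to a collated state grid
#'
#' NSAF is computed per replicate over that state's full All Proteins basis
#' (the collated grid), so values stay comparable between the
#' high-stringency and All Proteins output streams.
#'
#' @param collated Collated tibble (see [collate_state()]); may hold several
#'   states.
#' @param pseudocount Numerator substitute for zero counts (default 0.5
#'   spectral counts), so lnNSAF is defined everywhere.
#' @return The input with `nsaf` and `ln_nsaf` columns appended.
#' @export
add_nsaf <- function(collated, pseudocount = 0.5) {
  if (pseudocount < 0) abort("pseudocount must be non-negative")
  out <- collated |>
    group_by(.data$state, .data$replicate) |>
    mutate(nsaf = compute_nsaf(.data$spectral_count, .data$molecular_weight,
                               pseudocount = pseudocount)) |>
    ungroup()
  if (any(out$nsaf <= 0)) {
    abort("zero NSAF values; set a positive pseudocount to take logs")
  }
  out |> mutate(ln_nsaf = log(.data$nsaf))
}

#' Log2 fold change of treatment over control
#'
#' Comparisons are made relative to the control group: positive values mean
#' higher abundance in the treatment.
#'
#' @param control_mean,treatment_mean Positive per-protein mean NSAF values.
#' @return `log2(treatment_mean / control_mean)`.
#' @export
log2_fold_change <- function(control_mean, treatment_mean) {
  if (any(control_mean <= 0) || any(treatment_mean <= 0)) {
    abort("group mean NSAF must be positive to form a fold change")
  }
  log2(treatment_mean / control_mean)
}
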