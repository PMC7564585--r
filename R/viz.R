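#' Venn counts for a two-state high-stringency comparison
#'
#' @param partition An `spc_partition`.
#' @param control,treatment State labels.
#' @return A tibble with `unique_control`, `shared`, `unique_treatment`
#'   counts of high-stringency proteins (here "unique" is relative to the
#'   other state's high-stringency set, the quantity the Venn displays).
#' @export
venn_counts <- function(partition, control, treatment) {
  hc <- high_stringency_ids(partition, control)
  ht <- high_stringency_ids(partition, treatment)
  tibble(
    unique_control = length(setdiff(hc, ht)),
    shared = length(intersect(hc, ht)),
    unique_treatment = length(setdiff(ht, hc))
  )
}

# distance between two circle centres such that the lens area equals
# `overlap`, solved numerically (area-proportional two-set Venn layout)
venn_circle_distance <- function(r1, r2, overlap) {
  if (overlap <= 0) return(r1 + r2)
  max_overlap <- pi * min(r1, r2)^2
  if (overlap >= max_overlap) return(abs(r1 - r2))
  lens <- function(d) {
    a1 <- r1^2 * acos(pmin(pmax((d^2 + r1^2 - r2^2) / (2 * d * r1), -1), 1))
    a2 <- r2^2 * acos(pmin(pmax((d^2 + r2^2 - r1^2) / (2 * d * r2), -1), 1))
    tri <- 0.5 * sqrt(pmax(
      (-d + r1 + r2) * (d + r1 - r2) * (d - r1 + r2) * (d + r1 + r2), 0
    ))
    a1 + a2 - tri
  }
  uniroot(function(d) lens(d) - overlap,
          lower = abs(r1 - r2) + 1e-9, upper = r1 + r2 - 1e-9,
          tol = 1e-10)$root
}

#' Proportional two-set Venn diagram
#'
#' Circle areas are proportional to each state's high-stringency set size
#' and the centre distance is solved so the lens area matches the shared
#' count.
#'
#' @param counts Tibble from [venn_counts()].
#' @param control,treatment Labels for the two circles.
#' @return A ggplot object.
#' @export
plot_venn <- function(counts, control = "control", treatment = "treatment") {
  n1 <- counts$unique_control + counts$shared
  n2 <- counts$unique_treatment + counts$shared
  r1 <- sqrt(n1 / pi); r2 <- sqrt(n2 / pi)
  d <- venn_circle_distance(r1, r2, counts$shared)
  th <- seq(0, 2 * pi, length.out = 256)
  circles <- bind_rows(
    tibble(set = control, x = r1 * cos(th), y = r1 * sin(th)),
    tibble(set = treatment, x = d + r2 * cos(th), y = r2 * sin(th))
  )
  labels <- tibble(
    x = c(-r1 / 2, d / 2, d + r2 / 2),
    y = 0,
    text = c(counts$unique_control, counts$shared, counts$unique_treatment)
  )
  ggplot2::ggplot(circles, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_polygon(ggplot2::aes(fill = .data$set), alpha = 0.4,
                          colour = "grey30") +
    ggplot2::geom_text(data = labels,
                       ggplot2::aes(.data$x, .data$y,
                                    label = .data$text),
                       inherit.aes = FALSE, size = 5) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(fill = NULL,
                  title = "High-stringency proteins per state")
}

#' Volcano plot coordinates
#'
#' One point per tested protein: x = log2 fold change, y = -log10 p. The
#' p-value is floored at machine epsilon before the log so zero-variance
#' limits stay plottable.
#'
#' @param comparison An `spc_comparison`.
#' @return Tibble with `protein`, `x`, `y`, `category`.
#' @export
volcano_points <- function(comparison) {
  comparison |>
    tidy() |>
    filter(!is.na(.data$p_value)) |>
    mutate(
      x = .data$log2_fold_change,
      y = -log10(pmax(.data$p_value, .Machine$double.eps))
    ) |>
    select("protein", "x", "y", "category")
}

#' Volcano plot of a two-state comparison
#'
#' @param comparison An `spc_comparison`.
#' @param alpha Significance reference line (horizontal, at -log10 alpha);
#'   defaults to the comparison's active threshold.
#' @return A ggplot object.
#' @export
plot_volcano <- function(comparison, alpha = NULL) {
  alpha <- alpha %||% attr(comparison, "alpha") %||% 0.05
  pts <- volcano_points(comparison)
  ggplot2::ggplot(pts, ggplot2::aes(.data$x, .data$y,
                                    colour = .data$category)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::scale_colour_manual(values = c(
      UP = "#c0392b", DOWN = "#2471a3", UNCHANGED = "grey60"
    )) +
    ggplot2::labs(x = "log2 fold-change (treatment / control)",
                  y = "-log10 p-value (Student's t-test)",
                  colour = NULL)
}

#' Select the top differentially expressed proteins for the heatmap
#'
#' Ranks tested proteins by ascending p-value, breaking ties by descending
#' absolute log2 fold change, then identifier, and returns the top
#' `min(k, n)` with their per-replicate lnNSAF values across both states.
#'
#' @param comparison An `spc_comparison`.
#' @param quant NSAF-quantified collated tibble covering both states.
#' @param k Number of proteins to keep (default 20).
#' @return Tibble of lnNSAF values (`protein`, `state`, `replicate`,
#'   `ln_nsaf`, `rank`), proteins ordered by rank.
#' @export
heatmap_selection <- function(comparison, quant, k = 20) {
  ranked <- comparison |>
    tidy() |>
    filter(!is.na(.data$p_value)) |>
    arrange(.data$p_value, desc(abs(.data$log2_fold_change)),
            .data$protein) |>
    mutate(rank = row_number()) |>
    head(k)
  quant |>
    filter(.data$state %in% c(attr(comparison, "control"),
                              attr(comparison, "treatment"))) |>
    inner_join(select(ranked, "protein", "rank"), by = "protein") |>
    select("protein", "state", "replicate", "ln_nsaf", "rank") |>
    arrange(.data$rank, .data$state, .data$replicate)
}

#' Heatmap of the top differentially expressed proteins
#'
#' Tile map of per-replicate lnNSAF for the top-k proteins, row-standardised
#' (z-score per protein) by default for visual comparability; set
#' `scale_rows = FALSE` for raw lnNSAF.
#'
#' @param comparison An `spc_comparison`.
#' @param quant NSAF-quantified collated tibble.
#' @param k Number of proteins (default 20).
#' @param scale_rows Row-standardise per protein (default `TRUE`).
#' @return A ggplot object.
#' @export
plot_heatmap <- function(comparison, quant, k = 20, scale_rows = TRUE) {
  sel <- heatmap_selection(comparison, quant, k = k)
  if (scale_rows) {
    sel <- sel |>
      group_by(.data$protein) |>
      mutate(value = as.numeric(scale(.data$ln_nsaf))) |>
      ungroup()
  } else {
    sel <- mutate(sel, value = .data$ln_nsaf)
  }
  sel <- mutate(sel,
                column = paste0(.data$state, "-R", .data$replicate),
                protein = stats::reorder(.data$protein, -.data$rank))
  ggplot2::ggplot(sel, ggplot2::aes(.data$column, .data$protein,
                                    fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2471a3", mid = "white",
                                  high = "#c0392b") +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = if (scale_rows) "z(lnNSAF)" else "lnNSAF",
                  title = paste0("Top ", min(k, dplyr::n_distinct(sel$protein)),
                                 " differentially expressed proteins")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Fixed-width p-value histogram counts
#'
#' Bins of width `bin_width` on `[0, 1]`; the first bin (p < 0.05 at the
#' default width) is the highlighted one.
#'
#' @param p Numeric p-values in `[0, 1]`.
#' @param bin_width Bin width (default 0.05).
#' @return Tibble with `bin_low`, `bin_high`, `count`, `highlight`.
#' @export
pvalue_histogram <- function(p, bin_width = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  breaks <- seq(0, 1, by = bin_width)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  idx <- pmin(findInterval(p, breaks, rightmost.closed = TRUE),
              length(breaks) - 1)
  tibble(
    bin_low = breaks[-length(breaks)],
    bin_high = breaks[-1],
    count = vapply(seq_len(length(breaks) - 1),
                   function(i) sum(idx == i, na.rm = TRUE), numeric(1)),
    highlight = seq_len(length(breaks) - 1) == 1
  )
}

#' P-value distribution histogram
#'
#' @param p Numeric p-values.
#' @param bin_width Bin width (default 0.05).
#' @param title Plot title (e.g. the stream name).
#' @return A ggplot object with the sub-0.05 bin highlighted.
#' @export
plot_pvalue_histogram <- function(p, bin_width = 0.05, title = NULL) {
  bins <- pvalue_histogram(p, bin_width)
  ggplot2::ggplot(bins, ggplot2::aes(x = .data$bin_low + bin_width / 2,
                                     y = .data$count,
                                     fill = .data$highlight)) +
    ggplot2::geom_col(width = bin_width, colour = "grey30",
                      show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#145a32",
                                          `FALSE` = "#a9dfbf")) +
    ggplot2::labs(x = "p-value", y = "proteins", title = title)
}

#' PQ-FDR curve plot
#'
#' Grand-average PQ-FDR against the BH threshold grid, with the target line
#' and the derived threshold marked.
#'
#' @param samesame An `spc_samesame` object.
#' @return A ggplot object.
#' @export
plot_pqfdr <- function(samesame) {
  ggplot2::ggplot(samesame$grand_average,
                  ggplot2::aes(.data$q, .data$pqfdr)) +
    ggplot2::geom_line(colour = "#2471a3") +
    ggplot2::geom_hline(yintercept = samesame$threshold$target,
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = samesame$threshold$q_star,
                        linetype = "dotted") +
    ggplot2::labs(x = "BH Q value threshold", y = "PQ-FDR (%)",
                  title = paste0("Same-same PQ-FDR; q* = ",
                                 format(samesame$threshold$q_star,
                                        digits = 3)))
}

#' Replicate-level PCA scores
#'
#' Principal component analysis with replicates as observations and proteins
#' as variables (replicate-level quality control); values are protein-centred
#' and unscaled before decomposition.
#'
#' @param quant NSAF-quantified collated tibble (one or more states).
#' @param on `"ln_nsaf"` (default) or `"spectral_count"`.
#' @return Tibble with `state`, `replicate`, `PC1`, `PC2`; attribute
#'   `explained` holds the two explained-variance fractions.
#' @export
pca_scores <- function(quant, on = c("ln_nsaf", "spectral_count")) {
  on <- match.arg(on)
  wide <- quant |>
    mutate(sample = paste0(.data$state, "-R", .data$replicate)) |>
    select("sample", "protein", dplyr::all_of(on)) |>
    tidyr::pivot_wider(names_from = "protein", values_from = dplyr::all_of(on),
                       values_fill = 0)
  if (nrow(wide) < 3) abort("PCA needs at least 3 replicate columns")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$sample
  fit <- prcomp(m, center = TRUE, scale. = FALSE)
  if (ncol(fit$x) < 2) abort("fewer than 2 non-degenerate components")
  ev <- fit$sdev^2 / sum(fit$sdev^2)
  meta <- quant |>
    distinct(.data$state, .data$replicate) |>
    mutate(sample = paste0(.data$state, "-R", .data$replicate))
  out <- tibble(
    sample = rownames(fit$x),
    PC1 = unname(fit$x[, 1]),
    PC2 = unname(fit$x[, 2])
  ) |>
    left_join(meta, by = "sample") |>
    select("state", "replicate", "PC1", "PC2")
  attr(out, "explained") <- ev[1:2]
  out
}

#' PCA scatter plot of replicates
#'
#' @param quant NSAF-quantified collated tibble.
#' @param on `"ln_nsaf"` (default) or `"spectral_count"`.
#' @param groups Optional named list mapping a group label to replicate
#'   numbers (same-same variant: colour by partition group instead of
#'   state).
#' @return A ggplot object.
#' @export
plot_pca <- function(quant, on = c("ln_nsaf", "spectral_count"),
                     groups = NULL) {
  on <- match.arg(on)
  scores <- pca_scores(quant, on = on)
  ev <- attr(scores, "explained")
  if (!is.null(groups)) {
    lookup <- tibble(
      group = rep(names(groups), lengths(groups)),
      replicate = unlist(groups, use.names = FALSE)
    )
    scores <- left_join(scores, lookup, by = "replicate")
  } else {
    scores <- mutate(scores, group = .data$state)
  }
  ggplot2::ggplot(scores, ggplot2::aes(.data$PC1, .data$PC2,
                                       colour = .data$group)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * ev[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * ev[2]),
      colour = NULL,
      title = paste0("Replicate PCA on ", on)
    )
}
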