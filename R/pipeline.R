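#' Plan a run from an input file inventory
#'
#' Routes the workflow from the uploaded file set alone: a single state
#' yields data-quality outputs only; two or more states add the full
#' comparison outputs; and when every state carries exactly six replicates
#' the same-same permutation outputs (PQ-FDR curve and plot, combinatorial
#' PCAs, BH-refined classification files) are enabled on top.
#'
#' @param files Character vector of `{state}-{R#}.csv` file names/paths.
#' @param control Control state label; defaults to the first state
#'   encountered in the sorted file list. All comparisons are relative to
#'   the control.
#' @return An `spc_plan`: list with `files` (parsed tibble), `states`
#'   (control first), `replicates` (named counts), `workflow` and `outputs`
#'   (enabled output classes).
#' @export
plan_run <- function(files, control = NULL) {
  if (length(files) == 0) abort("no input files")
  parsed <- parse_spc_filename(files) |> arrange(.data$state, .data$replicate)
  dup <- parsed |>
    dplyr::count(.data$state, .data$replicate) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("duplicate replicate numbers: ",
                 paste(dup$state, dup$replicate, sep = "-", collapse = ", ")))
  }
  gaps <- parsed |>
    group_by(.data$state) |>
    summarise(ok = identical(sort(.data$replicate),
                             seq_len(max(.data$replicate))),
              .groups = "drop")
  if (any(!gaps$ok)) {
    abort(paste0("replicate numbering has gaps in state(s): ",
                 paste(gaps$state[!gaps$ok], collapse = ", ")))
  }
  states <- unique(parsed$state)
  control <- control %||% states[1]
  if (!control %in% states) {
    abort(paste0("control state '", control, "' not among inputs"))
  }
  states <- c(control, setdiff(states, control))
  reps <- vapply(states, function(s) sum(parsed$state == s), integer(1))
  samesame <- all(reps == 6)
  outputs <- c("all_proteins_list", "high_stringency_list")
  if (length(states) >= 2) {
    outputs <- c(outputs, "upregulated", "downregulated", "unchanged",
                 "unique", "venn", "volcano", "heatmap",
                 "pvalue_histograms", "interstate_pca")
  }
  if (samesame) {
    outputs <- c(outputs, "samesame_pca", "pqfdr_plot")
    if (length(states) >= 2) outputs <- c(outputs, "refined_classification")
  }
  workflow <- if (length(states) == 1) {
    if (samesame) "quality_samesame" else "quality"
  } else {
    if (samesame) "comparison_samesame" else "comparison"
  }
  structure(
    list(files = parsed, states = states, replicates = reps,
         workflow = workflow, outputs = outputs),
    class = "spc_plan"
  )
}

#' @export
print.spc_plan <- function(x, ...) {
  cat("Run plan (", x$workflow, "): ",
      paste0(x$states, " x", x$replicates, collapse = ", "),
      "\noutputs: ", paste(x$outputs, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Run the full analysis pipeline on a directory of replicate CSVs
#'
#' Executes the planned workflow: parse and collate every state, apply MSC
#' stringency filtering, NSAF-quantify, run the two-state comparison on the
#' high-stringency and All Proteins streams in parallel for each
#' treatment-vs-control pair, run the same-same permutation analysis when
#' every state has six replicates (re-classifying each comparison at the
#' derived BH threshold), and build every enabled figure.
#'
#' @param input Directory containing `{state}-{R#}.csv` files, or a
#'   character vector of file paths.
#' @param min_spc MSC summed-count threshold (default 5).
#' @param alpha Per-test significance threshold (default 0.05).
#' @param pseudocount Zero-count substitute for NSAF numerators
#'   (default 0.5).
#' @param target_pqfdr Same-same target PQ-FDR percent (default 1).
#' @param control Control state label (default: first state).
#' @param var_equal Pooled-variance t-tests (default) or Welch.
#' @param out Optional path for a zip archive of the written bundle.
#' @return An `spc_bundle`: list with `plan`, `params`, `quant`,
#'   `partition`, `comparisons` (named list per pair and stream),
#'   `samesame` (or `NULL`), `refined` (BH-thresholded comparisons, or
#'   `NULL`), and `figures` (named list of ggplot objects).
#' @export
run_pipeline <- function(input, min_spc = 5, alpha = 0.05, pseudocount = 0.5,
                         target_pqfdr = 1, control = NULL, var_equal = TRUE,
                         out = NULL) {
  files <- if (length(input) == 1 && dir.exists(input)) {
    list.files(input, pattern = "\\.csv$", full.names = TRUE)
  } else {
    input
  }
  plan <- plan_run(files, control = control)
  params <- list(min_spc = min_spc, alpha = alpha, pseudocount = pseudocount,
                 target_pqfdr = target_pqfdr, control = plan$states[1],
                 var_equal = var_equal)
  raw <- purrr::pmap(plan$files, function(file, state, replicate) {
    read_replicate_csv(file, state = state, replicate = replicate)
  }) |> bind_rows()
  quant <- raw |>
    dplyr::group_split(.data$state) |>
    purrr::map(collate_state) |>
    bind_rows() |>
    add_nsaf(pseudocount = pseudocount)
  partition <- build_stringency_partition(quant, min_summed_count = min_spc)
  ctrl <- plan$states[1]
  pairs <- setdiff(plan$states, ctrl)
  comparisons <- list()
  figures <- list()
  for (tr in pairs) {
    for (stream in c("high_stringency", "all_proteins")) {
      key <- paste0(tr, "_vs_", ctrl, ".", stream)
      comparisons[[key]] <- compare_states(
        quant, partition, ctrl, tr, stream = stream,
        alpha = alpha, var_equal = var_equal
      )
      figures[[paste0("volcano.", key)]] <- plot_volcano(comparisons[[key]])
      figures[[paste0("pvalue_hist.", key)]] <- plot_pvalue_histogram(
        tidy(comparisons[[key]])$p_value |> stats::na.omit(),
        title = paste0(tr, " vs ", ctrl, " (", stream, ")")
      )
    }
    hs_key <- paste0(tr, "_vs_", ctrl, ".high_stringency")
    figures[[paste0("venn.", tr, "_vs_", ctrl)]] <-
      plot_venn(venn_counts(partition, ctrl, tr), ctrl, tr)
    figures[[paste0("heatmap.", tr, "_vs_", ctrl)]] <-
      plot_heatmap(comparisons[[hs_key]],
                   filter(quant, .data$state %in% c(ctrl, tr)))
  }
  if (length(pairs) > 0) {
    figures$pca_lnnsaf <- plot_pca(quant, on = "ln_nsaf")
    figures$pca_spc <- plot_pca(quant, on = "spectral_count")
  }
  samesame <- NULL
  refined <- NULL
  if (all(plan$replicates == 6)) {
    samesame <- samesame_analysis(quant, partition,
                                  target_pqfdr = target_pqfdr,
                                  var_equal = var_equal)
    figures$pqfdr_plot <- plot_pqfdr(samesame)
    for (st in samesame$states) {
      parts <- samesame$partitions[[st]]
      grp <- list(A = parts$group_a[[1]], B = parts$group_b[[1]])
      figures[[paste0("samesame_pca.", st)]] <-
        plot_pca(filter(quant, .data$state == st), on = "ln_nsaf",
                 groups = grp) +
        ggplot2::labs(title = paste0("Same-same PCA, ", st,
                                     " (first 3-vs-3 split)"))
    }
    refined <- list()
    for (tr in pairs) {
      key <- paste0(tr, "_vs_", ctrl, ".high_stringency")
      refined[[key]] <- compare_states(
        quant, partition, ctrl, tr, stream = "high_stringency",
        alpha = alpha, q_threshold = samesame$threshold$q_star,
        var_equal = var_equal
      )
    }
  }
  bundle <- structure(
    list(plan = plan, params = params, quant = quant, partition = partition,
         comparisons = comparisons, samesame = samesame, refined = refined,
         figures = figures),
    class = "spc_bundle"
  )
  if (!is.null(out)) {
    staging <- file.path(tempfile("speccount_bundle_"))
    write_bundle(bundle, staging)
    bundle_outputs(staging, out)
    unlink(staging, recursive = TRUE)
  }
  bundle
}

write_comparison_files <- function(cmp, quant, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tbl <- tidy(cmp)
  per_replicate <- function(ids) {
    quant |>
      filter(.data$protein %in% ids,
             .data$state %in% c(attr(cmp, "control"), attr(cmp, "treatment")))
  }
  groups <- list(
    upregulated = tbl$protein[tbl$category == "UP"],
    downregulated = tbl$protein[tbl$category == "DOWN"],
    unchanged = tbl$protein[tbl$category == "UNCHANGED"],
    combined = tbl$protein
  )
  if (cmp$stream[1] == "high_stringency") {
    groups$unique_control <- tbl$protein[tbl$category == "UNIQUE_CONTROL"]
    groups$unique_treatment <- tbl$protein[tbl$category == "UNIQUE_TREATMENT"]
  }
  for (nm in names(groups)) {
    readr::write_csv(
      tbl |> filter(.data$protein %in% groups[[nm]]),
      file.path(dir, paste0(nm, ".csv")), progress = FALSE
    )
  }
  write_protein_table(per_replicate(groups$combined),
                      file.path(dir, "combined_per_replicate.csv"))
  invisible(dir)
}

#' Write an analysis bundle to a directory tree
#'
#' Materialises every enabled output of the run as CSV tables and PNG
#' figures under subfolders grouped by result class, plus a machine-readable
#' `run_log.yaml` recording all parameters and any derived threshold. Use
#' [bundle_outputs()] to zip the directory.
#'
#' @param bundle An `spc_bundle` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  qdir <- file.path(dir, "data_quality")
  dir.create(qdir, showWarnings = FALSE)
  for (st in bundle$plan$states) {
    stq <- filter(bundle$quant, .data$state == st)
    write_protein_table(stq, file.path(qdir, paste0(st, "_all_proteins.csv")))
    high <- high_stringency_ids(bundle$partition, st)
    write_protein_table(filter(stq, .data$protein %in% high),
                        file.path(qdir, paste0(st, "_high_stringency.csv")))
  }
  for (key in names(bundle$comparisons)) {
    write_comparison_files(bundle$comparisons[[key]], bundle$quant,
                           file.path(dir, "comparison", key))
  }
  if (!is.null(bundle$samesame)) {
    ssdir <- file.path(dir, "samesame")
    dir.create(ssdir, showWarnings = FALSE)
    readr::write_csv(bundle$samesame$curves,
                     file.path(ssdir, "per_partition_curves.csv"),
                     progress = FALSE)
    readr::write_csv(bundle$samesame$state_averages,
                     file.path(ssdir, "state_average_curves.csv"),
                     progress = FALSE)
    readr::write_csv(bundle$samesame$grand_average,
                     file.path(ssdir, "grand_average_curve.csv"),
                     progress = FALSE)
    for (key in names(bundle$refined)) {
      write_comparison_files(bundle$refined[[key]], bundle$quant,
                             file.path(ssdir, "refined", key))
    }
  }
  if (length(bundle$figures) > 0) {
    fdir <- file.path(dir, "figures")
    dir.create(fdir, showWarnings = FALSE)
    for (nm in names(bundle$figures)) {
      ggplot2::ggsave(file.path(fdir, paste0(nm, ".png")),
                      bundle$figures[[nm]], width = 7, height = 5, dpi = 120)
    }
  }
  log <- bundle$params
  log$workflow <- bundle$plan$workflow
  log$states <- as.list(setNames(as.integer(bundle$plan$replicates),
                                 bundle$plan$states))
  if (!is.null(bundle$samesame)) {
    log$derived_q_threshold <- bundle$samesame$threshold$q_star
    log$pqfdr_at_threshold <- bundle$samesame$threshold$pqfdr_at_q_star
  }
  yaml::write_yaml(log, file.path(dir, "run_log.yaml"))
  invisible(dir)
}

#' @export
print.spc_bundle <- function(x, ...) {
  cat("speccount run (", x$plan$workflow, "): ",
      paste0(x$plan$states, " x", x$plan$replicates, collapse = ", "),
      "\n", sep = "")
  if (!is.null(x$samesame)) {
    cat("derived BH threshold q* =",
        format(x$samesame$threshold$q_star, digits = 4), "\n")
  }
  cat(length(x$comparisons), "comparison table(s),",
      length(x$figures), "figure(s)\n")
  invisible(x)
}
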