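#' Parse `{state}-{R#}.csv` filenames
#'
#' Replicate files follow the naming template `{state}-{R#}.csv`, where the
#' token after the final hyphen is the replicate number. The state label may
#' itself contain hyphens (`"IAC1131-drought-3.csv"` parses to state
#' `"IAC1131-drought"`, replicate 3).
#'
#' @param names Character vector of file names (paths allowed; only the base
#'   name is interpreted).
#' @return A tibble with columns `file`, `state` and `replicate` (integer).
#' @export
#' @examples
#' parse_spc_filename(c("control-1.csv", "IAC1131-drought-3.csv"))
parse_spc_filename <- function(names) {
  base <- basename(names)
  ok_ext <- grepl("\\.csv$", base, ignore.case = TRUE)
  if (any(!ok_ext)) {
    abort(paste0("not a .csv file: ", paste(base[!ok_ext], collapse = ", ")))
  }
  stem <- sub("\\.csv$", "", base, ignore.case = TRUE)
  m <- regmatches(stem, regexec("^(.+)-([0-9]+)$", stem))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) {
    abort(paste0(
      "file name does not match '{state}-{R#}.csv': ",
      paste(base[bad], collapse = ", ")
    ))
  }
  tibble(
    file = names,
    state = vapply(m, `[`, character(1), 2L),
    replicate = as.integer(vapply(m, `[`, character(1), 3L))
  )
}

#' Load the search-engine dialect registry
#'
#' The registry is a YAML file mapping each supported search engine's export
#' columns onto the four canonical fields (`protein`, `spectral_count`,
#' `score`, `molecular_weight`). The packaged registry covers GPM/X!Tandem,
#' MetaMorpheus and Proteome Discoverer exports; pass your own file to add or
#' adjust signatures without touching code.
#'
#' @param path Path to a registry YAML file; default is the packaged one.
#' @return Named list of dialect definitions.
#' @export
dialect_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "dialects.yaml", package = "speccount")
  }
  reg <- yaml::read_yaml(path)
  for (d in names(reg)) {
    cols <- reg[[d]]$columns
    stopifnot(all(c("protein", "spectral_count", "score",
                    "molecular_weight") %in% names(cols)))
    reg[[d]]$columns <- lapply(cols, tolower)
  }
  reg
}

#' Detect the search-engine dialect of a header row
#'
#' A dialect matches when every one of its registered column names is present
#' in the header (case-insensitive, surrounding whitespace ignored).
#'
#' @param header Character vector of column names.
#' @param registry Dialect registry, see [dialect_registry()].
#' @return The dialect name (e.g. `"gpm_xtandem"`).
#' @export
detect_dialect <- function(header, registry = dialect_registry()) {
  if (length(header) == 0) abort("empty header row")
  h <- tolower(trimws(header))
  for (d in names(registry)) {
    if (all(unlist(registry[[d]]$columns) %in% h)) return(d)
  }
  sigs <- vapply(
    names(registry),
    function(d) paste0(d, ": [", paste(unlist(registry[[d]]$columns),
                                       collapse = ", "), "]"),
    character(1)
  )
  abort(paste0(
    "header matches no supported search-engine dialect.\nExpected one of:\n",
    paste(" ", sigs, collapse = "\n")
  ))
}

#' Read one replicate CSV into a canonical protein table
#'
#' Parses a protein-level search-engine export. Duplicate identifiers within
#' the file are merged by summing spectral counts and keeping the best score
#' (direction per dialect); rows with missing or non-positive molecular
#' weight are dropped with a warning. State and replicate default to the
#' values parsed from the file name.
#'
#' @param path CSV file path.
#' @param dialect Dialect name; auto-detected from the header when `NULL`.
#' @param state,replicate State label and replicate number; parsed from the
#'   file name when `NULL`.
#' @param registry Dialect registry.
#' @return A tibble with columns `state`, `replicate`, `protein`,
#'   `spectral_count`, `score`, `molecular_weight`, plus a `dialect`
#'   attribute.
#' @export
read_replicate_csv <- function(path, dialect = NULL, state = NULL,
                               replicate = NULL,
                               registry = dialect_registry()) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         progress = FALSE, name_repair = "minimal")
  if (is.null(dialect)) dialect <- detect_dialect(names(raw), registry)
  if (!dialect %in% names(registry)) {
    abort(paste0("unknown dialect: ", dialect))
  }
  spec <- registry[[dialect]]
  h <- tolower(trimws(names(raw)))
  idx <- vapply(unlist(spec$columns), function(col) {
    i <- which(h == col)
    if (length(i) == 0) {
      abort(paste0("file ", basename(path), " lacks required column '", col,
                   "' for dialect ", dialect))
    }
    i[1]
  }, integer(1))
  tbl <- tibble(
    protein = as.character(raw[[idx[["protein"]]]]),
    spectral_count = as.numeric(raw[[idx[["spectral_count"]]]]),
    score = as.numeric(raw[[idx[["score"]]]]),
    molecular_weight = as.numeric(raw[[idx[["molecular_weight"]]]])
  )
  if (is.null(state) || is.null(replicate)) {
    parsed <- parse_spc_filename(basename(path))
    state <- state %||% parsed$state
    replicate <- replicate %||% parsed$replicate
  }
  bad_mw <- is.na(tbl$molecular_weight) | tbl$molecular_weight <= 0
  if (any(bad_mw)) {
    warn(paste0(basename(path), ": dropped ", sum(bad_mw),
                " row(s) with missing or non-positive molecular weight"))
    tbl <- tbl[!bad_mw, ]
  }
  if (any(is.na(tbl$spectral_count)) || any(tbl$spectral_count < 0)) {
    abort(paste0(basename(path), ": spectral counts must be non-negative"))
  }
  if (any(!nzchar(tbl$protein) | is.na(tbl$protein))) {
    abort(paste0(basename(path), ": empty protein identifier"))
  }
  best <- if (identical(spec$score_best, "min")) min else max
  out <- tbl |>
    group_by(.data$protein) |>
    summarise(
      spectral_count = sum(.data$spectral_count),
      score = best(.data$score),
      molecular_weight = first(.data$molecular_weight),
      .groups = "drop"
    ) |>
    mutate(state = state, replicate = as.integer(replicate),
           .before = "protein") |>
    arrange(.data$protein)
  attr(out, "dialect") <- dialect
  out
}

#' Read every replicate CSV in a directory
#'
#' @param dir Directory containing `{state}-{R#}.csv` files.
#' @param registry Dialect registry.
#' @return One long tibble of all replicates (see [read_replicate_csv()]).
#' @export
read_replicate_dir <- function(dir, registry = dialect_registry()) {
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  if (length(files) == 0) abort(paste0("no .csv files in ", dir))
  meta <- parse_spc_filename(files)
  purrr::pmap(meta, function(file, state, replicate) {
    read_replicate_csv(file, state = state, replicate = replicate,
                       registry = registry)
  }) |>
    bind_rows()
}

#' Write a protein-level table with per-replicate columns
#'
#' One row per protein, one column triple (spectral count, NSAF, score) per
#' replicate, replicates in ascending order and proteins in ascending
#' identifier order, so archives built from the same inputs are
#' byte-identical.
#'
#' @param data Long tibble with columns `protein`, `replicate`,
#'   `spectral_count`, `molecular_weight` and optionally `nsaf`, `score`.
#' @param path Output CSV path.
#' @return The wide tibble, invisibly.
#' @export
write_protein_table <- function(data, path) {
  value_cols <- intersect(c("spectral_count", "nsaf", "score"), names(data))
  if (nrow(data) == 0) {
    wide <- tibble(protein = character(), molecular_weight = numeric())
  } else {
    multi_state <- "state" %in% names(data) && n_distinct(data$state) > 1
    key_cols <- if (multi_state) c("state", "replicate") else "replicate"
    wide <- data |>
      select("protein", "molecular_weight", dplyr::all_of(key_cols),
             dplyr::all_of(value_cols)) |>
      arrange(dplyr::pick(dplyr::all_of(key_cols))) |>
      tidyr::pivot_wider(
        id_cols = c("protein", "molecular_weight"),
        names_from = dplyr::all_of(key_cols),
        values_from = dplyr::all_of(value_cols),
        names_glue = if (multi_state) "{.value}_{state}_R{replicate}"
                     else "{.value}_R{replicate}"
      ) |>
      arrange(.data$protein)
  }
  readr::write_csv(wide, path, progress = FALSE)
  invisible(wide)
}

#' Zip a written output bundle
#'
#' Archives every file under `dir` at its relative path, in sorted order, so
#' identical inputs produce an archive with identical member listing.
#'
#' @param dir Directory holding the bundle files (subfolders preserved).
#' @param zipfile Output `.zip` path.
#' @return `zipfile`, invisibly.
#' @export
bundle_outputs <- function(dir, zipfile) {
  files <- sort(list.files(dir, recursive = TRUE))
  if (length(files) == 0) abort("empty output bundle")
  zipfile <- file.path(normalizePath(dirname(zipfile)), basename(zipfile))
  zip::zip(zipfile = zipfile, files = files, root = dir,
           mode = "mirror", include_directories = FALSE)
  invisible(zipfile)
}
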