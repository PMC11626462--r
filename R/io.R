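#' Read and write cohort files
#'
#' CSV dialect is fixed, not sniffed: comma-separated, UTF-8, `.` decimal,
#' mandatory header. Occupation and sector codes are always read as
#' character so codes like `"4310"` keep leading structure.
#'
#' @param path File path.
#' @param data Cohort tibble.
#' @return `read_cohort()` returns a tibble; `write_cohort()` returns
#'   `path` invisibly.
#' @export
read_cohort <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      pcs = readr::col_character(),
      naf = readr::col_character(),
      .default = readr::col_guess()
    ),
    progress = FALSE
  )
}

#' @rdname read_cohort
#' @export
write_cohort <- function(data, path) {
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

#' Read an exposure specification file
#'
#' A CSV with columns `exposure`, `scale`, `cutoff` (and optionally
#' `prevalence`, `missingness`, `domain`); the shipped default equals
#' [exposure_specs()].
#'
#' @param path File path; `NULL` returns the default specification.
#' @return A specification tibble.
#' @export
read_exposure_specs <- function(path = NULL) {
  if (is.null(path)) return(exposure_specs())
  specs <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  stopifnot(all(c("exposure", "scale") %in% names(specs)))
  if (!"cutoff" %in% names(specs)) specs$cutoff <- NA_real_
  as_tibble(specs)
}

#' Write / read a JEM table
#'
#' The export holds one row per occupational group x exposure with the
#' group's complete-case size, its exposure frequency (3 decimal places),
#' the selected dichotomization threshold, and the binary assignment
#' (frequency strictly above threshold). `write_jem()` also writes a JSON
#' sidecar (`<path>.json`) echoing variant, seed, split fraction and cohort
#' size for provenance.
#'
#' @param jem A `jem` object from [build_jem()].
#' @param path Output CSV path.
#' @return `write_jem()` returns `path` invisibly; `read_jem()` the tibble.
#' @export
write_jem <- function(jem, path) {
  stopifnot(inherits(jem, "jem"))
  out <- jem$table
  out$frequency <- round(out$frequency, 3)
  out$group_key <- NULL
  out <- rename(out, exposed_binary = "exposed")
  readr::write_csv(out, path, progress = FALSE)
  jsonlite::write_json(
    list(variant = jem$variant, seed = jem$seed,
         learning_fraction = jem$learning_fraction,
         min_group_size = jem$min_group_size,
         n_records = jem$n_records, built = jem$built),
    paste0(path, ".json"), auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_jem
#' @export
read_jem <- function(path) {
  hdr <- names(readr::read_csv(path, n_max = 0,
                               col_types = readr::cols(.default = readr::col_character()),
                               progress = FALSE))
  spec <- readr::cols(.default = readr::col_guess())
  for (cc in intersect(c("pcs", "naf"), hdr)) {
    spec$cols[[cc]] <- readr::col_character()
  }
  out <- readr::read_csv(path, col_types = spec, progress = FALSE)
  if ("exposed_binary" %in% names(out)) {
    out <- rename(out, exposed = "exposed_binary")
  }
  out
}

#' Assign JEM exposures to new individuals
#'
#' The deployment step: given a built JEM and a table of individuals with
#' occupation/sector codes, returns each individual's group frequency and
#' binary assignment per exposure. Sector codes that do not match a JEM row
#' exactly are retried at successively shallower truncations (5 down to 1
#' character) before the individual is flagged unmatched; unknown
#' occupation codes are flagged, never an error.
#'
#' @param jem A `jem` object or a tibble as returned by [read_jem()].
#' @param data Tibble of individuals with `pcs` (and `naf` unless the JEM
#'   is occupation-only; plus `public`/`large` for the alternative
#'   variant). An `id` column is carried through (row number otherwise).
#' @return A long tibble: `id`, `exposure`, `frequency`, `exposed`,
#'   `matched_depth` (`NA` when unmatched).
#' @export
assign_exposures <- function(jem, data) {
  table <- if (inherits(jem, "jem")) jem$table else as_tibble(jem)
  has_naf <- "naf" %in% names(table)
  has_stratum <- "sector_type" %in% names(table)
  data <- normalize_cohort_codes(data)
  if (!"id" %in% names(data)) data$id <- seq_len(nrow(data))

  make_key <- function(pcs, naf, stratum) {
    key <- pcs
    if (has_naf) key <- paste(key, naf, sep = "|")
    if (has_stratum) key <- paste(key, stratum, sep = "|")
    key
  }
  tab_stratum <- if (has_stratum) {
    paste(table$sector_type, table$size_class, sep = ".")
  } else NULL
  dat_stratum <- if (has_stratum) {
    paste(ifelse(data$public, "public", "private"),
          ifelse(data$large, "large", "small"), sep = ".")
  } else NULL

  purrr::map_dfr(unique(table$exposure), function(e) {
    sub <- table[table$exposure == e, ]
    lookup <- setNames(seq_len(nrow(sub)),
                       make_key(sub$pcs, if (has_naf) sub$naf else NULL,
                                if (has_stratum) tab_stratum[table$exposure == e] else NULL))
    hit <- rep(NA_integer_, nrow(data))
    depth <- rep(NA_integer_, nrow(data))
    depths <- if (has_naf) 5:1 else 0L
    for (d in depths) {
      todo <- is.na(hit)
      if (!any(todo)) break
      naf_d <- if (has_naf) naf_level(data$naf[todo], max(d, 1L)) else NULL
      keys <- make_key(data$pcs[todo], naf_d, dat_stratum[todo])
      m <- lookup[keys]
      hit[todo] <- unname(m)
      depth[todo][!is.na(m)] <- d
    }
    tibble(
      id = data$id, exposure = e,
      frequency = sub$frequency[hit],
      exposed = sub$exposed[hit],
      matched_depth = depth
    )
  })
}

#' Pipeline commands
#'
#' Thin file-in/file-out wrappers binding the package into shell-style
#' workflows; the command-line driver in `inst/cli/jembuild.R` calls these.
#' Every command is deterministic given its inputs and seed, and writes
#' plain CSV (plus JSON sidecars for provenance).
#'
#' @param out Output directory (created if absent).
#' @param n,seed Generator size and seed.
#' @param config Optional [cohort_config()] overriding `n`/`seed`.
#' @return Invisibly, the paths written.
#' @name commands
NULL

#' @describeIn commands Generate a synthetic cohort: writes `cohort.csv`,
#'   `truth.csv` and `config.json`.
#' @export
run_simulate <- function(out, n = 12489L, seed = 1L, config = NULL) {
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  config <- config %||% cohort_config(n = n, seed = seed)
  sim <- generate_cohort(config)
  write_cohort(sim$records, file.path(out, "cohort.csv"))
  readr::write_csv(sim$truth, file.path(out, "truth.csv"), progress = FALSE)
  cfg <- unclass(config)
  cfg$specs <- NULL
  jsonlite::write_json(cfg, file.path(out, "config.json"), auto_unbox = TRUE)
  invisible(file.path(out, c("cohort.csv", "truth.csv", "config.json")))
}

#' @describeIn commands Build and validate a JEM from a cohort file: writes
#'   `jem.csv` (+ sidecar), `performance.csv`, `threshold_scans.csv`,
#'   `groups.csv`.
#' @param input Cohort CSV path.
#' @param exposures Optional exposure-specification CSV path.
#' @param variant `"standard"`, `"simplified"` or `"alternative"`.
#' @param learning_fraction Learning-set fraction (default 0.7).
#' @export
run_build <- function(input, out, exposures = NULL, variant = "standard",
                      learning_fraction = 0.7, seed = 1L) {
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  cohort <- read_cohort(input)
  specs <- read_exposure_specs(exposures)
  missing_cols <- setdiff(specs$exposure, names(cohort))
  if (length(missing_cols) == length(specs$exposure)) {
    abort(sprintf("No exposure column found in '%s'; expected one of: %s.",
                  input, paste(specs$exposure, collapse = ", ")),
          class = "jembuild_no_exposures")
  }
  jem <- build_jem(cohort, specs, variant = variant,
                   learning_fraction = learning_fraction, seed = seed)
  write_jem(jem, file.path(out, "jem.csv"))
  perf <- jem$performance
  readr::write_csv(perf, file.path(out, "performance.csv"), progress = FALSE)
  readr::write_csv(jem$scans, file.path(out, "threshold_scans.csv"),
                   progress = FALSE)
  readr::write_csv(jem$groups, file.path(out, "groups.csv"), progress = FALSE)
  invisible(file.path(out, c("jem.csv", "performance.csv",
                             "threshold_scans.csv", "groups.csv")))
}

#' @describeIn commands Compare methods on a cohort file: writes
#'   `comparison.csv` and optionally a forest plot.
#' @param methods Methods to compare.
#' @param plot Optional path for a forest-plot file (pdf).
#' @param ... Passed to [compare_methods()] (e.g. `sets`, `grids`,
#'   `n_boot`, `folds`).
#' @export
run_compare <- function(input, out, exposures = NULL,
                        methods = c("frequency", "tree", "forest", "boosted"),
                        seed = 1L, plot = NULL, ...) {
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  cohort <- read_cohort(input)
  specs <- read_exposure_specs(exposures)
  expo <- intersect(specs$exposure, names(cohort))
  cmp <- compare_methods(cohort, expo, methods = methods, specs = specs,
                         seed = seed, ...)
  readr::write_csv(as_tibble(cmp), file.path(out, "comparison.csv"),
                   progress = FALSE)
  if (!is.null(plot)) {
    p <- autoplot(cmp)
    ggplot2::ggsave(plot, p, width = 7,
                    height = 1 + 0.6 * length(unique(cmp$exposure)),
                    device = "pdf")
  }
  invisible(file.path(out, "comparison.csv"))
}

#' @describeIn commands Apply a built JEM file to a cohort file: writes
#'   `assignments.csv`.
#' @param jem_path Path to a JEM CSV written by [write_jem()].
#' @export
run_apply <- function(jem_path, input, out) {
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  jem <- read_jem(jem_path)
  cohort <- read_cohort(input)
  assignments <- assign_exposures(jem, cohort)
  readr::write_csv(assignments, file.path(out, "assignments.csv"),
                   progress = FALSE)
  invisible(file.path(out, "assignments.csv"))
}
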