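#' Parse hierarchical occupation (PCS-style) codes
#'
#' Occupation codes follow the three-level nested layout of the French
#' PCS-2003 classification: a 1-character socio-professional group, a
#' 2-character category, and the full 4-character occupation code. Parsing
#' normalizes case and whitespace and exposes the nested prefixes.
#'
#' @param code Character vector of raw occupation codes (e.g. `"431f"`).
#'
#' @return A tibble with one row per input code and columns `pcs` (the
#'   normalized 4-character code), `pcs1`, `pcs2` (its 1- and 2-character
#'   prefixes).
#'
#' @examples
#' parse_occupation(c("431f", "  431F "))
#' @export
parse_occupation <- function(code) {
  if (length(code) == 0 || any(is.na(code))) {
    abort("`code` must be a non-missing character vector.",
          class = "jembuild_malformed_code")
  }
  raw <- tolower(trimws(as.character(code)))
  bad <- nchar(raw) != 4L
  if (any(bad)) {
    abort(
      sprintf("Malformed occupation code(s): %s (must be 4 characters after normalization).",
              paste(unique(raw[bad]), collapse = ", ")),
      class = "jembuild_malformed_code"
    )
  }
  tibble(pcs = raw, pcs1 = substr(raw, 1, 1), pcs2 = substr(raw, 1, 2))
}

#' Parse hierarchical activity-sector (NAF-style) codes
#'
#' Sector codes are nested from a 1-character section down to a 5-character
#' full code; a record carries the deepest level available to it, so codes of
#' heterogeneous depth coexist in one cohort. Dots (as in `"86.10Z"`) are
#' removed before the declared depth is computed; a record is never up-coded
#' to a depth it did not declare.
#'
#' @param code Character vector of raw sector codes, 1--5 characters after
#'   dot removal.
#'
#' @return A tibble with columns `naf` (normalized code) and `naf_depth`
#'   (its declared depth, 1--5).
#'
#' @examples
#' parse_sector(c("Q", "86.10Z"))
#' @export
parse_sector <- function(code) {
  if (length(code) == 0 || any(is.na(code))) {
    abort("`code` must be a non-missing character vector.",
          class = "jembuild_malformed_code")
  }
  raw <- tolower(gsub("[. ]", "", as.character(code)))
  bad <- nchar(raw) < 1L | nchar(raw) > 5L
  if (any(bad)) {
    abort(
      sprintf("Malformed sector code(s): %s (must be 1-5 characters after normalization).",
              paste(unique(raw[bad]), collapse = ", ")),
      class = "jembuild_malformed_code"
    )
  }
  tibble(naf = raw, naf_depth = nchar(raw))
}

#' Truncate codes to a nested level
#'
#' `pcs_level()` truncates occupation codes to 1, 2 or 4 characters;
#' `naf_level()` truncates sector codes to depths 1--5. A code shallower than
#' the requested depth is returned at its own declared depth (never up-coded).
#'
#' @param code Character vector of normalized codes.
#' @param depth Truncation depth: one of 1, 2, 4 for `pcs_level()`; 1--5 for
#'   `naf_level()`.
#' @return Character vector of truncated codes.
#' @examples
#' pcs_level("431f", 2)
#' naf_level(c("8610z", "86"), 4)
#' @export
pcs_level <- function(code, depth) {
  stopifnot(length(depth) == 1, depth %in% c(1L, 2L, 4L))
  substr(code, 1, depth)
}

#' @rdname pcs_level
#' @export
naf_level <- function(code, depth) {
  stopifnot(length(depth) == 1, depth %in% 1:5)
  substr(code, 1, pmin(depth, nchar(code)))
}

#' Assign occupational group keys to cohort records
#'
#' An occupational group is the unit a JEM row describes. Three keying
#' variants are supported: `"standard"` (occupation x sector), `"simplified"`
#' (occupation only, for use when sector information is unavailable), and
#' `"alternative"` (occupation x sector x establishment stratum, the stratum
#' crossing public/private with size below/at-or-above 200 employees).
#' Records missing a component the variant requires are flagged rather than
#' dropped, so callers can log them.
#'
#' @param data A cohort tibble with columns `pcs`, `naf` (normalized codes;
#'   `NA` allowed) and, for the alternative variant, logical `public` and
#'   `large`.
#' @param variant One of `"standard"`, `"simplified"`, `"alternative"`.
#'
#' @return `data` with two added columns: `group_key` (character; `NA` when
#'   ungroupable) and `groupable` (logical).
#'
#' @export
add_group_key <- function(data, variant = c("standard", "simplified", "alternative")) {
  variant <- match.arg(variant)
  stopifnot(is.data.frame(data), "pcs" %in% names(data))
  pcs <- data$pcs
  key <- switch(
    variant,
    simplified = pcs,
    standard = {
      stopifnot("naf" %in% names(data))
      ifelse(is.na(pcs) | is.na(data$naf), NA_character_,
             paste(pcs, data$naf, sep = "|"))
    },
    alternative = {
      stopifnot(all(c("naf", "public", "large") %in% names(data)))
      stratum <- paste(ifelse(data$public, "public", "private"),
                       ifelse(data$large, "large", "small"), sep = ".")
      ok <- !is.na(pcs) & !is.na(data$naf) & !is.na(data$public) & !is.na(data$large)
      ifelse(ok, paste(pcs, data$naf, stratum, sep = "|"), NA_character_)
    }
  )
  data$group_key <- key
  data$groupable <- !is.na(key)
  as_tibble(data)
}

#' Enumerate the occupational-variable sets for model selection
#'
#' Tree-based comparators are fitted on dummy-encoded occupation and sector
#' codes truncated to every informative combination of depths: occupation
#' depth in \{none, 1, 2, 4\} crossed with sector depth in \{none, 1, ..., 5\},
#' excluding the pair that carries no information at all. This yields
#' 4 x 6 - 1 = 23 candidate variable sets.
#'
#' @return A 23-row tibble with integer columns `pcs_depth` and `naf_depth`;
#'   `NA` means the classification is left out of that set.
#' @examples
#' enumerate_variable_sets()
#' @export
enumerate_variable_sets <- function() {
  sets <- tidyr::expand_grid(
    pcs_depth = c(NA_integer_, 1L, 2L, 4L),
    naf_depth = c(NA_integer_, 1L, 2L, 3L, 4L, 5L)
  )
  filter(sets, !(is.na(.data$pcs_depth) & is.na(.data$naf_depth)))
}

#' Dummy-encode truncated occupation/sector codes
#'
#' Builds the indicator design matrix for one variable set: one column per
#' distinct truncated code value observed in the data at the requested
#' depths. Columns constant across all records (a unique response modality)
#' carry no information and are dropped.
#'
#' @param data Cohort tibble with `pcs` and (if `naf_depth` is used) `naf`.
#' @param pcs_depth,naf_depth Truncation depths as in
#'   [enumerate_variable_sets()]; `NA` omits the classification.
#'
#' @return A numeric 0/1 matrix with one row per record (row order
#'   preserved). Column names are `pcs<depth>_<value>` / `naf<depth>_<value>`.
#'   Errors with class `jembuild_empty_design` when every column is constant.
#' @export
dummy_encode <- function(data, pcs_depth = NA, naf_depth = NA) {
  stopifnot(is.data.frame(data))
  if (is.na(pcs_depth) && is.na(naf_depth)) {
    abort("At least one of `pcs_depth`, `naf_depth` must be set.",
          class = "jembuild_empty_design")
  }
  blocks <- list()
  if (!is.na(pcs_depth)) {
    v <- pcs_level(data$pcs, as.integer(pcs_depth))
    blocks[[paste0("pcs", pcs_depth)]] <- v
  }
  if (!is.na(naf_depth)) {
    v <- naf_level(data$naf, as.integer(naf_depth))
    blocks[[paste0("naf", naf_depth)]] <- v
  }
  cols <- purrr::imap(blocks, function(v, nm) {
    lev <- sort(unique(v))
    m <- matrix(0, nrow = length(v), ncol = length(lev),
                dimnames = list(NULL, paste0(nm, "_", lev)))
    m[cbind(seq_along(v), match(v, lev))] <- 1
    m
  })
  design <- do.call(cbind, unname(cols))
  keep <- apply(design, 2, function(x) length(unique(x)) > 1L)
  if (!any(keep)) {
    abort("All indicator columns are constant: empty design.",
          class = "jembuild_empty_design")
  }
  design[, keep, drop = FALSE]
}
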