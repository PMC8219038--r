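# canonical schema: field -> canonical unit and known conversion factors
CANONICAL_FIELDS <- list(
  curve_id = list(unit = NA_character_, required = TRUE),
  A        = list(unit = "umol m-2 s-1", required = TRUE),
  gs_w     = list(unit = "mol m-2 s-1",  required = TRUE),
  ci       = list(unit = "umol mol-1",   required = TRUE),
  ca       = list(unit = "umol mol-1",   required = TRUE),
  PAR      = list(unit = "umol m-2 s-1", required = TRUE),
  Tleaf    = list(unit = "degC",         required = FALSE),
  VPD      = list(unit = "kPa",          required = FALSE),
  flow     = list(unit = "umol s-1",     required = FALSE),
  phi_PSII = list(unit = "1",            required = FALSE),
  Patm     = list(unit = "kPa",          required = FALSE)
)

# magnitude of each unit relative to its dimension's base unit
UNIT_FACTORS <- c(
  "mol m-2 s-1" = 1, "mmol m-2 s-1" = 1e-3, "umol m-2 s-1" = 1e-6,
  "mol mol-1" = 1, "mmol mol-1" = 1e-3, "umol mol-1" = 1e-6,
  "ppm" = 1e-6,
  "kPa" = 1, "Pa" = 1e-3, "degC" = 1,
  "mol s-1" = 1, "mmol s-1" = 1e-3, "umol s-1" = 1e-6, "1" = 1
)

# factor that converts a declared unit into the canonical unit of a field
unit_factor <- function(field, unit) {
  canonical <- CANONICAL_FIELDS[[field]]$unit
  if (is.na(canonical) || is.null(unit) || identical(unit, canonical)) {
    return(1)
  }
  if (!unit %in% names(UNIT_FACTORS) ||
      !canonical %in% names(UNIT_FACTORS)) {
    stop("unknown unit '", unit, "' for field ", field, call. = FALSE)
  }
  # factors are expressed relative to a common base per dimension
  UNIT_FACTORS[[unit]] / UNIT_FACTORS[[canonical]]
}

#' Declare how source columns map onto the canonical gas-exchange schema
#'
#' Each argument names a canonical field and gives either the source
#' column header (string) or `list(col = , unit = )` when the source is
#' not in canonical units. Canonical fields and units: `curve_id`, `A`
#' (umol m-2 s-1), `gs_w` (mol m-2 s-1), `ci`, `ca` (umol mol-1), `PAR`
#' (umol m-2 s-1), and optional `Tleaf` (degC), `VPD` (kPa), `flow`
#' (umol s-1), `phi_PSII`, `Patm` (kPa).
#'
#' @param ... Named mappings, e.g.
#'   `A = "Photo"`, `gs_w = list(col = "Cond_mmol", unit = "mmol m-2 s-1")`.
#' @return An object of class `column_mapping`.
#' @examples
#' column_mapping(curve_id = "curve", A = "Photo", gs_w = "Cond",
#'                ci = "Ci", ca = "CO2R", PAR = "PARi")
#' @export
column_mapping <- function(...) {
  raw <- list(...)
  bad <- setdiff(names(raw), names(CANONICAL_FIELDS))
  if (length(bad)) {
    stop("unknown canonical field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(names(raw))) {
    stop("each canonical field may be mapped only once", call. = FALSE)
  }
  entries <- purrr::imap(raw, function(v, nm) {
    if (is.character(v)) list(col = v, unit = CANONICAL_FIELDS[[nm]]$unit)
    else list(col = v$col, unit = v$unit %||% CANONICAL_FIELDS[[nm]]$unit)
  })
  structure(entries, class = "column_mapping")
}

# identity mapping over the canonical headers themselves
default_mapping <- function() {
  do.call(column_mapping,
          stats::setNames(as.list(names(CANONICAL_FIELDS)),
                          names(CANONICAL_FIELDS)))
}

#' Read a gas-exchange log into response curves
#'
#' Reads a comma-separated, header-first gas-exchange table, applies a
#' [column_mapping()] (renaming and unit conversion at the I/O boundary),
#' groups records into curves by the curve-id column, and collects
#' malformed rows into an error report attached as the `"errors"`
#' attribute - rows are flagged (`qc_row = FALSE`), never silently
#' dropped.
#'
#' @param path CSV file path.
#' @param mapping A [column_mapping()]; defaults to the canonical
#'   headers.
#' @return A named list of `response_curve` tibbles, one per curve id,
#'   with attribute `errors` (tibble of row, field, problem).
#' @export
read_gas_exchange_table <- function(path, mapping = default_mapping()) {
  stopifnot(inherits(mapping, "column_mapping"))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         progress = FALSE)
  if (nrow(raw) == 0 && ncol(raw) == 0) {
    stop("schema error: empty file", call. = FALSE)
  }
  required <- names(CANONICAL_FIELDS)[
    purrr::map_lgl(CANONICAL_FIELDS, "required")]
  missing_map <- setdiff(required, names(mapping))
  if (length(missing_map)) {
    stop("schema error: unmapped required field(s): ",
         paste(missing_map, collapse = ", "), call. = FALSE)
  }
  missing_cols <- purrr::keep(names(mapping), function(nm) {
    !mapping[[nm]]$col %in% names(raw)
  })
  if (length(intersect(missing_cols, required))) {
    stop("schema error: source column(s) not found for: ",
         paste(intersect(missing_cols, required), collapse = ", "),
         call. = FALSE)
  }
  mapping <- mapping[setdiff(names(mapping), missing_cols)]

  out <- tibble::tibble(.rows = nrow(raw))
  errors <- list()
  for (nm in names(mapping)) {
    src <- raw[[mapping[[nm]]$col]]
    if (nm == "curve_id") {
      out[[nm]] <- as.character(src)
      next
    }
    val <- suppressWarnings(as.numeric(src))
    bad <- which(is.na(val) & !is.na(src))
    if (length(bad)) {
      errors[[nm]] <- tibble::tibble(row = bad, field = nm,
                                     problem = "not numeric",
                                     value = as.character(src[bad]))
    }
    out[[nm]] <- val * unit_factor(nm, mapping[[nm]]$unit)
  }
  errors <- dplyr::bind_rows(errors)
  out$qc_row <- TRUE
  if (nrow(errors)) out$qc_row[unique(errors$row)] <- FALSE
  # physically inconsistent records are flagged, not dropped
  susp <- which(out$A > 0 & out$ci > out$ca)
  if (length(susp)) {
    errors <- dplyr::bind_rows(errors, tibble::tibble(
      row = susp, field = "ci", problem = "ci > ca while A > 0",
      value = as.character(out$ci[susp])))
  }
  curves <- split(out, out$curve_id)
  curves <- purrr::imap(curves, function(d, id) {
    new_response_curve(dplyr::select(d, -"curve_id"), "unknown", NULL,
                       curve_id = id)
  })
  attr(curves, "errors") <- errors
  curves
}

#' Write response curves to the canonical CSV schema
#'
#' The inverse of [read_gas_exchange_table()] under the default mapping:
#' canonical headers, canonical units, one row per record, curves
#' concatenated with their `curve_id`.
#'
#' @param curves A `response_curve` tibble or a (possibly named) list of
#'   them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_gas_exchange_table <- function(curves, path) {
  if (is.data.frame(curves)) curves <- list(curves)
  df <- dplyr::bind_rows(purrr::map(curves, tibble::as_tibble))
  cols <- intersect(names(CANONICAL_FIELDS), names(df))
  readr::write_csv(df[, cols], path, progress = FALSE)
  invisible(path)
}
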