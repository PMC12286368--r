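#' Read a long-format concentration table
#'
#' Reads one row per region x bakery x stage x element, mg/kg dry weight.
#' Expected columns: `region`, `bakery_id`, `stage`, `bread_type`,
#' `element`, `value`, `censored`, `lod`. Censored cells may be encoded
#' either as `censored = TRUE` with an empty value, or as a `"<LOD"` string
#' in the value column (e.g. `"<0.01"`), from which the LOD is taken.
#'
#' @param path CSV file path.
#' @return A validated data frame of concentration records (see
#'   [validate_concentrations()]).
#' @export
read_concentrations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  needed <- c("region", "bakery_id", "stage", "element", "value")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(raw$bread_type)) raw$bread_type <- "unknown"
  if (is.null(raw$censored)) raw$censored <- ""
  if (is.null(raw$lod)) raw$lod <- ""

  val_chr <- trimws(raw$value)
  censored <- tolower(trimws(raw$censored)) %in% c("true", "t", "1", "yes")
  lod <- suppressWarnings(as.numeric(raw$lod))

  # "<0.01" style entries imply censoring and carry the LOD inline
  lt <- grepl("^<", val_chr)
  censored <- censored | lt
  lod[lt] <- suppressWarnings(as.numeric(sub("^<\\s*", "", val_chr[lt])))
  val_chr[lt] <- ""
  value <- suppressWarnings(as.numeric(val_chr))
  value[censored] <- NA_real_

  rec <- data.frame(
    region = trimws(raw$region),
    bakery_id = trimws(raw$bakery_id),
    stage = tolower(trimws(raw$stage)),
    bread_type = tolower(trimws(raw$bread_type)),
    element = trimws(raw$element),
    value = value,
    censored = censored,
    lod = lod,
    stringsAsFactors = FALSE
  )
  validate_concentrations(rec)
}

#' Validate concentration records
#'
#' Enforces the record invariants: element symbols from [bread_elements()],
#' stage from [bread_stages()], non-negative values for uncensored rows,
#' absent value plus a positive LOD for censored rows.
#'
#' @param records data frame with the concentration-record columns.
#' @return The records, invisibly unchanged, or an error naming the first
#'   offending row.
#' @export
validate_concentrations <- function(records) {
  stopifnot(is.data.frame(records))
  needed <- c("region", "bakery_id", "stage", "element", "value", "censored", "lod")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(records$bread_type)) records$bread_type <- "unknown"

  fail <- function(i, msg) {
    stop(sprintf("row %d: %s", i, msg), call. = FALSE)
  }
  bad <- which(!records$element %in% bread_elements())
  if (length(bad)) {
    fail(bad[1], sprintf("unknown element '%s'; allowed symbols: %s",
                         records$element[bad[1]],
                         paste(bread_elements(), collapse = ", ")))
  }
  bad <- which(!records$stage %in% bread_stages())
  if (length(bad)) {
    fail(bad[1], sprintf("missing or unknown stage '%s' (expected %s)",
                         records$stage[bad[1]],
                         paste(bread_stages(), collapse = "/")))
  }
  cens <- records$censored
  bad <- which(cens & !is.na(records$value))
  if (length(bad)) fail(bad[1], "censored row must not carry a value")
  bad <- which(cens & (is.na(records$lod) | records$lod <= 0))
  if (length(bad)) fail(bad[1], "censored row requires a positive LOD")
  bad <- which(!cens & is.na(records$value))
  if (length(bad)) fail(bad[1], "uncensored row requires a numeric value")
  bad <- which(!cens & records$value < 0)
  if (length(bad)) fail(bad[1], "negative concentration")
  invisible(records)
}

#' Write a concentration table to CSV
#'
#' Inverse of [read_concentrations()]; round-trips losslessly.
#'
#' @param records validated concentration records.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_concentrations <- function(records, path) {
  validate_concentrations(records)
  out <- records[, c("region", "bakery_id", "stage", "bread_type",
                     "element", "value", "censored", "lod")]
  out$value <- num_chr(out$value)
  out$lod <- num_chr(out$lod)
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# full-precision numeric -> character for lossless CSV round-trips
num_chr <- function(x) {
  out <- character(length(x))
  ok <- !is.na(x)
  out[ok] <- sprintf("%.17g", x[ok])
  out[!ok] <- NA_character_
  out
}

#' Read a regulatory limit table
#'
#' @param path CSV with columns `element`, `authority`, `limit_mg_kg`.
#' @return Data frame of limit entries (limits must be positive, elements
#'   from the closed vocabulary).
#' @export
read_limits <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lim <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("element", "authority", "limit_mg_kg")
  missing_cols <- setdiff(needed, names(lim))
  if (length(missing_cols)) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(lim$element, bread_elements())
  if (length(bad)) stop("unknown element(s) in limit table: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  if (any(!is.finite(lim$limit_mg_kg) | lim$limit_mg_kg <= 0)) {
    stop("limits must be positive", call. = FALSE)
  }
  lim
}

#' Bundled example regulatory limits
#'
#' An editable example limit table (WHO/FAO-style slots) shipped with the
#' package for demonstration and testing; users supply their own CSV via
#' [read_limits()] for real screening work.
#'
#' @return Data frame with columns `element`, `authority`, `limit_mg_kg`.
#' @export
example_limits <- function() {
  read_limits(system.file("extdata", "example_limits.csv",
                          package = "breadrisk", mustWork = TRUE))
}
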