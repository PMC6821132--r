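#' Read a typed CSV table with schema validation
#'
#' Reads a comma-separated, header-bearing UTF-8 table and validates it
#' against a declared schema: required columns must be present and
#' coercible to their declared types. Unknown extra columns are accepted
#' with a warning (tolerant reader); missing required columns, empty
#' files and uncoercible values are structured errors.
#'
#' @param path Path to a CSV file.
#' @param schema Named character vector mapping required column names to
#'   types (`"numeric"`, `"integer"` or `"character"`).
#' @return A tibble with at least the schema's columns.
#' @examples
#' p <- tempfile(fileext = ".csv")
#' readr::write_csv(tibble::tibble(region = "central", density = 1000), p)
#' read_table_checked(p, c(region = "character", density = "numeric"))
#' @export
read_table_checked <- function(path, schema) {
  if (!file.exists(path)) {
    stop("Input file does not exist: ", path, call. = FALSE)
  }
  if (file.size(path) == 0) {
    stop("Input file is empty: ", path, call. = FALSE)
  }
  df <- readr::read_csv(path, show_col_types = FALSE,
                        progress = FALSE)
  if (nrow(df) == 0) {
    stop("Input table has no data rows: ", path, call. = FALSE)
  }
  missing <- setdiff(names(schema), names(df))
  if (length(missing)) {
    stop("Schema error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "), ".", call. = FALSE)
  }
  extra <- setdiff(names(df), names(schema))
  if (length(extra)) {
    warning("Ignoring unknown column(s) in ", path, ": ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  for (col in names(schema)) {
    coerced <- switch(schema[[col]],
      numeric = suppressWarnings(as.numeric(df[[col]])),
      integer = suppressWarnings(as.integer(df[[col]])),
      character = as.character(df[[col]]),
      stop("Unknown schema type: ", schema[[col]], call. = FALSE)
    )
    bad <- which(is.na(coerced) & !is.na(df[[col]]))
    if (length(bad)) {
      stop("Schema error in ", path, ": column '", col, "' row ", bad[1],
           " is not coercible to ", schema[[col]], ".", call. = FALSE)
    }
    df[[col]] <- coerced
  }
  df
}

#' Write a table as CSV with a provenance sidecar
#'
#' Writes the table at full double precision and an adjacent
#' `<path>.provenance.json` recording the package version, timestamp,
#' seed, free-form parameters and the MD5 digest of the CSV, so any
#' output can be traced back to the exact invocation that produced it.
#'
#' @param data A data frame.
#' @param path Output CSV path.
#' @param seed The RNG seed used to produce `data`, if any.
#' @param params Named list of run parameters to record.
#' @return `path`, invisibly.
#' @export
write_table_with_provenance <- function(data, path, seed = NULL,
                                        params = list()) {
  readr::write_csv(data, path, progress = FALSE)
  sidecar <- list(
    tool = "clearkin",
    version = as.character(utils::packageVersion("clearkin")),
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    params = params,
    output = basename(path),
    md5 = unname(tools::md5sum(path))
  )
  jsonlite::write_json(sidecar, paste0(path, ".provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a snapshot-series table
#'
#' Schema: `day`, `live`, `visible`, `cleared`, `observed_fraction`.
#'
#' @param path Path to a CSV written by [write_table_with_provenance()]
#'   or any conforming table.
#' @return A `snapshot_series` tibble.
#' @export
read_snapshot_series <- function(path) {
  df <- read_table_checked(path, c(
    day = "numeric", live = "numeric", visible = "numeric",
    cleared = "numeric", observed_fraction = "numeric"
  ))
  structure(df, class = c("snapshot_series", class(df)))
}

#' Read a per-field density table
#'
#' Schema: `region` (central/middle/peripheral), `fov_id`, and either
#' `density` directly or `count` plus `fov_area` (from which density is
#' derived).
#'
#' @param path Path to a CSV file.
#' @return A tibble with columns `region`, `fov_id`, `density`.
#' @export
read_density_table <- function(path) {
  probe <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                           n_max = 0)
  if ("density" %in% names(probe)) {
    df <- read_table_checked(path, c(
      region = "character", fov_id = "integer", density = "numeric"
    ))
  } else {
    df <- read_table_checked(path, c(
      region = "character", fov_id = "integer", count = "numeric",
      fov_area = "numeric"
    ))
    df <- dplyr::mutate(df, density = .data$count / .data$fov_area)
  }
  bad <- setdiff(unique(df$region),
                 c("central", "middle", "peripheral"))
  if (length(bad)) {
    stop("Schema error in ", path, ": unknown region(s) ",
         paste(bad, collapse = ", "), ".", call. = FALSE)
  }
  df
}

#' Read a planar point table
#'
#' Schema: `x_mm`, `y_mm` (or plain `x`, `y`).
#'
#' @param path Path to a CSV file.
#' @return A tibble with columns `x`, `y`.
#' @export
read_points <- function(path) {
  probe <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                           n_max = 0)
  if (all(c("x_mm", "y_mm") %in% names(probe))) {
    df <- read_table_checked(path, c(x_mm = "numeric", y_mm = "numeric"))
    tibble::tibble(x = df$x_mm, y = df$y_mm)
  } else {
    read_table_checked(path, c(x = "numeric", y = "numeric"))
  }
}
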