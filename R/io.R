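#' Read a landing-observation table from CSV
#'
#' Loads and validates the per-attempt schema (`colony`, `day`, `species`,
#' `ledge`, `height`, `wind`, `turbulence`, `success`). Files with different
#' headers — such as deposited supplementary tables — can be adapted with a
#' column mapping; missing columns and malformed rows are reported by name
#' and row number.
#'
#' @param path Path to a CSV file.
#' @param column_map Optional named character vector: names are the package
#'   column names, values the file's column names
#'   (e.g. `c(success = "Landed", ledge = "LedgeType")`).
#' @return A validated observation data frame.
#' @export
read_observations <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("observation file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    for (pkg_name in names(column_map)) {
      file_name <- column_map[[pkg_name]]
      if (!file_name %in% names(tab))
        stop("mapped column `", file_name, "` not present in ", path)
      names(tab)[names(tab) == file_name] <- pkg_name
    }
  }
  validate_observations(tab)
}

#' Write a landing-observation table to CSV
#'
#' @param table An observation table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(table, path) {
  table <- validate_observations(table)
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gridded wind field from CSV
#'
#' Expects at least columns `U` (mean wind speed, m s^-1) and `k`
#' (turbulent kinetic energy); coordinate columns are passed through.
#'
#' @param path Path to a CSV file.
#' @return Data frame of wind samples.
#' @export
read_wind_grid <- function(path) {
  if (!file.exists(path)) stop("wind grid file not found: ", path)
  grid <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- setdiff(c("U", "k"), names(grid))
  if (length(need))
    stop("wind grid is missing column(s): ", paste(need, collapse = ", "))
  if (any(grid$U < 0) || any(grid$k < 0))
    stop("wind grid requires U >= 0 and k >= 0 everywhere")
  grid
}

#' Read colony bearings from CSV
#'
#' Expects columns `colony` and `bearing` (degrees); bearings are wrapped
#' into `[0, 360)`.
#'
#' @param path Path to a CSV file.
#' @return Data frame with `colony` and `bearing`.
#' @export
read_bearings <- function(path) {
  if (!file.exists(path)) stop("bearings file not found: ", path)
  b <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- setdiff(c("colony", "bearing"), names(b))
  if (length(need))
    stop("bearings file is missing column(s): ", paste(need, collapse = ", "))
  if (!is.numeric(b$bearing) || any(!is.finite(b$bearing)))
    stop("bearings must be finite numbers (degrees)")
  b$bearing <- b$bearing %% 360
  b
}
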