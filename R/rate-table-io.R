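#' Path to a bundled example/fixture file
#'
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return A file path (or a character vector of file names).
#' @examples
#' nadtherm_example()
#' @export
nadtherm_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "nadtherm")))
  }
  path <- system.file("extdata", file, package = "nadtherm")
  if (path == "") abort(paste0("no bundled file ", file), class = "nadtherm_config_error")
  path
}

.RATE_TABLE_COLS <- c("compound", "temperature_C", "rate_pct_per_min", "sd_pct_per_min")
.COMPOUNDS <- c("NR", "NMN", "NAD", "NAR", "NAMN", "NAAD")

#' Read a thermolysis rate table
#'
#' Reads the tab-separated measurement schema (columns `compound`,
#' `temperature_C`, `rate_pct_per_min`, `sd_pct_per_min`) used for the
#' bundled in vitro hydrolysis measurements. Parsing is strict: the header
#' must match exactly, unknown columns are rejected, and malformed or
#' negative values are reported with their line number.
#'
#' @param path Path to a TSV file.
#' @return A tibble with the four schema columns plus `temperature_K`.
#' @examples
#' read_rate_table(nadtherm_example("table1_thermolysis.tsv"))
#' @export
read_rate_table <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path), class = "nadtherm_config_error")
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    abort(paste0("empty rate table; expected header: ", paste(.RATE_TABLE_COLS, collapse = "\t")),
          class = "nadtherm_schema_error")
  }
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (!identical(header, .RATE_TABLE_COLS)) {
    missing <- setdiff(.RATE_TABLE_COLS, header)
    extra <- setdiff(header, .RATE_TABLE_COLS)
    abort(paste0(
      "rate table header mismatch",
      if (length(missing)) paste0("; missing: ", paste(missing, collapse = ", ")),
      if (length(extra)) paste0("; unknown: ", paste(extra, collapse = ", "))
    ), class = "nadtherm_schema_error")
  }
  rows <- lapply(seq_along(lines)[-1], function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) != 4) {
      abort(sprintf("line %d: expected 4 tab-separated fields, got %d", i, length(f)),
            class = "nadtherm_schema_error")
    }
    num <- suppressWarnings(as.numeric(f[2:4]))
    if (any(is.na(num))) {
      abort(sprintf("line %d: non-numeric value in %s", i,
                    .RATE_TABLE_COLS[1 + which(is.na(num))[1]]), class = "nadtherm_schema_error")
    }
    if (num[2] < 0 || num[3] < 0) {
      abort(sprintf("line %d: negative rate or sd", i), class = "nadtherm_invalid_measurement")
    }
    tibble(compound = f[1], temperature_C = num[1],
           rate_pct_per_min = num[2], sd_pct_per_min = num[3])
  })
  out <- list_rbind(rows)
  bad <- setdiff(unique(out$compound), .COMPOUNDS)
  if (length(bad)) {
    abort(paste0("unknown compound(s): ", paste(bad, collapse = ", ")), class = "nadtherm_schema_error")
  }
  out$temperature_K <- out$temperature_C + 273.15
  out
}

#' Write a thermolysis rate table
#'
#' Inverse of [read_rate_table()]; round-trips bit-identically for tables
#' produced by the package (numbers are written with full precision).
#'
#' @param data Data frame with the rate-table schema columns.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_rate_table <- function(data, path) {
  stopifnot(all(.RATE_TABLE_COLS %in% names(data)))
  fmt <- function(x) {
    vapply(x, function(v) format(v, digits = 17, scientific = FALSE, trim = TRUE), character(1))
  }
  lines <- c(
    paste(.RATE_TABLE_COLS, collapse = "\t"),
    paste(data$compound, fmt(data$temperature_C), fmt(data$rate_pct_per_min),
          fmt(data$sd_pct_per_min), sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}
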