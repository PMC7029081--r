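#' Read and write prevalence time series as tidy CSV
#'
#' The on-disk dialect is fixed: comma separated, UTF-8, mandatory header
#' `replicate,time,class,count,n_assayed`, decimal points, no thousands
#' separators. Reading validates every record (counts within
#' `[0, n_assayed]`, no duplicate `(replicate, time, class)` keys, class
#' counts at one time summing to at most `n_assayed`); writing then reading
#' reproduces the records exactly.
#'
#' @param path File path.
#' @return `read_prevalence_csv()` returns a `prevalence_series`;
#'   an empty data section yields an empty series, not an error.
#' @export
read_prevalence_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  needed <- c("replicate", "time", "class", "count", "n_assayed")
  if (!all(needed %in% names(df)))
    stop("header must contain columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  df <- df[, needed]
  if (nrow(df) > 0) {
    for (col in c("time", "count", "n_assayed")) {
      bad <- which(!is.finite(suppressWarnings(as.numeric(df[[col]]))))
      if (length(bad))
        stop(sprintf("malformed value in column '%s' at data line %d",
                     col, bad[1]), call. = FALSE)
      df[[col]] <- as.numeric(df[[col]])
    }
    df$count <- as.integer(df$count)
    df$n_assayed <- as.integer(df$n_assayed)
    bad <- which(df$count > df$n_assayed | df$count < 0)
    if (length(bad))
      stop(sprintf("count outside [0, n_assayed] at data line %d", bad[1]),
           call. = FALSE)
  }
  validate_prevalence_series(df)
  new_prevalence_series(df)
}

#' @rdname read_prevalence_csv
#' @param series A `prevalence_series` (or compatible data frame).
#' @export
write_prevalence_csv <- function(series, path) {
  validate_prevalence_series(series)
  df <- as.data.frame(series)[, c("replicate", "time", "class", "count",
                                  "n_assayed")]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
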