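#' Read time series from a delimited text file
#'
#' Reads CSV, TSV or whitespace-delimited plain text with one column per
#' channel. A header row is auto-detected (a first line with any
#' non-numeric field is taken as channel labels). Non-numeric data cells
#' raise an error naming the offending row and column; ragged rows fail in
#' parsing.
#'
#' @param path file path.
#' @param format `"csv"`, `"tsv"` or `"plain"`; `NULL` guesses from the
#'   file extension.
#' @param fs sampling rate attached to every channel (optional).
#' @param channels channel selection by index or name; `NULL` keeps all.
#' @return A named list of [nlts] objects, one per channel.
#' @export
read_timeseries <- function(path, format = NULL, fs = NULL, channels = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", tsv = "tsv", "plain")
  }
  sep <- switch(format, csv = ",", tsv = "\t", plain = "")
  first <- strsplit(readLines(path, n = 1L),
                    if (sep == "") "[[:space:]]+" else sep)[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(first))))
  df <- read.table(path, sep = sep, header = has_header,
                   colClasses = "character", stringsAsFactors = FALSE)
  labels <- if (has_header) colnames(df) else paste0("ch", seq_len(ncol(df)))
  num <- lapply(seq_len(ncol(df)), function(j) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v) & !is.na(df[[j]]))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at data row %d, column %d (%s)",
                   df[[j]][bad[1]], bad[1], j, labels[j]))
    v
  })
  out <- lapply(seq_along(num), function(j) nlts(num[[j]], fs = fs,
                                                 label = labels[j]))
  names(out) <- labels
  if (!is.null(channels)) out <- out[channels]
  out
}

#' Write time series to a delimited text file
#'
#' One column per channel with a header row of channel labels; values are
#' written at full precision so a write/read round trip is bit-identical.
#'
#' @param tslist a single [nlts] or a list of them (equal lengths).
#' @param path output path.
#' @param format `"csv"` or `"tsv"`.
#' @export
write_timeseries <- function(tslist, path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  if (inherits(tslist, "nlts")) tslist <- list(tslist)
  m <- do.call(cbind, lapply(tslist, ts_values))
  colnames(m) <- vapply(seq_along(tslist), function(i) {
    lbl <- tslist[[i]]$label
    if (is.null(lbl) || !nzchar(lbl)) paste0("ch", i) else lbl
  }, character(1))
  df <- as.data.frame(m)
  df[] <- lapply(df, function(v) sprintf("%.17g", v))
  write.table(df, path, sep = if (format == "csv") "," else "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write analysis results as JSON
#'
#' Serializes a (possibly nested) list of scalars, vectors and matrices to
#' JSON at full precision, with a provenance record (package version,
#' timestamp, and any parameters passed in `provenance`).
#'
#' @param results named list.
#' @param path output path.
#' @param provenance optional named list recorded under `$provenance`
#'   (e.g. inputs, config, seed).
#' @export
write_results <- function(results, path, provenance = NULL) {
  payload <- list(
    provenance = c(list(package = "nltsa",
                        version = as.character(utils::packageVersion("nltsa")),
                        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
                   provenance),
    results = results)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Write a recurrence spectrum as long-format TSV
#'
#' Columns `T`, `scale` (radius in percent of SD for SREPS, window start
#' sample for TRAS), `P` and `amplitude`.
#'
#' @param spectrum a `recurrence_spectrum`.
#' @param path output path.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "recurrence_spectrum"))
  df <- data.frame(
    T = rep(spectrum$T, times = length(spectrum$scale)),
    scale = rep(spectrum$scale, each = length(spectrum$T)),
    P = as.vector(spectrum$P),
    amplitude = as.vector(spectrum$amplitude))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
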