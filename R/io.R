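#' Read and write height traces
#'
#' Two formats are supported. `"csv"` is a plain text file: commented
#' metadata header lines (`# key: value`, at minimum `sampling_rate_hz`),
#' then a `time_s,height_nm` table written at full double precision.
#' `"feather"` is a chunked binary Arrow/Feather container that
#' round-trips the trace (including attributes such as ground truth)
#' bit-identically; it requires the `arrow` package.
#'
#' @param trace An `afm_trace`.
#' @param path File path.
#' @param format `"csv"` or `"feather"` (default from the file
#'   extension).
#' @return `write_trace()` returns `path` invisibly; `read_trace()`
#'   returns an `afm_trace`.
#' @export
write_trace <- function(trace, path, format = NULL) {
  format <- format %||% guess_format(path)
  sr <- trace_sampling_rate(trace)
  if (format == "feather") {
    rlang::check_installed("arrow")
    arrow::write_feather(trace, path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# sampling_rate_hz: %s", format(sr, digits = 17)),
               con)
    writeLines("time_s,height_nm", con)
    writeLines(paste(format(trace$time_s, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     format(trace$height_nm, digits = 17, trim = TRUE),
                     sep = ","), con)
  }
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path, format = NULL) {
  format <- format %||% guess_format(path)
  if (format == "feather") {
    rlang::check_installed("arrow")
    df <- as.data.frame(arrow::read_feather(path))
    sr <- attr(df, "sampling_rate")
    if (is.null(sr)) {
      rlang::abort("Container lacks sampling_rate metadata.",
                   class = "heightspec_format_error")
    }
    return(new_afm_trace(df$height_nm, sr, t0 = df$time_s[1],
                         ground_truth = attr(df, "ground_truth")))
  }
  lines <- readLines(path, n = 50)
  meta_lines <- grep("^#", lines, value = TRUE)
  m <- regmatches(meta_lines,
                  regexec("^#\\s*sampling_rate_hz:\\s*([0-9eE+.-]+)",
                          meta_lines))
  sr <- suppressWarnings(as.numeric(
    unlist(lapply(m, function(z) if (length(z) == 2) z[2]))))
  header_at <- grep("^time_s,height_nm$", lines)
  if (length(header_at) != 1) {
    rlang::abort("CSV trace lacks the `time_s,height_nm` header.",
                 class = "heightspec_format_error")
  }
  df <- utils::read.csv(path, comment.char = "#")
  if (length(sr) == 0 || is.na(sr[1])) {
    if (nrow(df) < 2) {
      rlang::abort("CSV trace lacks sampling_rate_hz metadata.",
                   class = "heightspec_format_error")
    }
    dt <- diff(df$time_s)
    if (max(dt) - min(dt) > 1e-6 * stats::median(dt)) {
      rlang::abort("Non-uniform timestamps in CSV trace.",
                   class = "heightspec_format_error")
    }
    sr <- 1 / stats::median(dt)
  }
  new_afm_trace(df$height_nm, sr[1], t0 = df$time_s[1])
}

guess_format <- function(path) {
  if (grepl("\\.(feather|arrow)$", path)) "feather" else "csv"
}

#' Read and write kymographs as CSV matrices
#'
#' A commented metadata header (`line_period_ms`, `x_step_nm`), then one
#' row per x-position: the x coordinate followed by the heights of
#' successive lines.
#'
#' @param kym An `afm_kymograph`.
#' @param path File path.
#' @return `write_kymograph()` returns `path` invisibly;
#'   `read_kymograph()` returns an `afm_kymograph`.
#' @export
write_kymograph <- function(kym, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# line_period_ms: %s",
                       format(attr(kym, "line_period_s") * 1e3,
                              digits = 17)),
               sprintf("# x_step_nm: %s",
                       format(attr(kym, "x_step_nm"), digits = 17)),
               if (!is.null(attr(kym, "delta_nm")))
                 sprintf("# delta_nm: %s",
                         format(attr(kym, "delta_nm"), digits = 17))),
             con)
  utils::write.table(
    cbind(x_nm = attr(kym, "x_nm"), unclass(kym)), con, sep = ",",
    row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_kymograph
#' @export
read_kymograph <- function(path) {
  lines <- readLines(path, n = 10)
  get_meta <- function(key) {
    m <- regmatches(lines, regexec(paste0("^#\\s*", key,
                                          ":\\s*([0-9eE+.-]+)"), lines))
    v <- unlist(lapply(m, function(z) if (length(z) == 2) z[2]))
    if (length(v)) as.numeric(v[1]) else NULL
  }
  lp_ms <- get_meta("line_period_ms")
  if (is.null(lp_ms)) {
    rlang::abort("Kymograph CSV lacks line_period_ms metadata.",
                 class = "heightspec_format_error")
  }
  df <- utils::read.csv(path, comment.char = "#", header = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  dimnames(mat) <- NULL
  structure(mat, x_nm = df[[1]], line_period_s = lp_ms * 1e-3,
            x_step_nm = get_meta("x_step_nm"),
            delta_nm = get_meta("delta_nm"),
            class = c("afm_kymograph", "matrix", "array"))
}

#' Read and write a Kd matrix as labelled CSV
#'
#' @param kd A square numeric matrix with species dimnames.
#' @param path File path.
#' @return `write_kd_matrix()` returns `path`; `read_kd_matrix()` a
#'   matrix shaped like [a5_kd_matrix()].
#' @export
write_kd_matrix <- function(kd, path) {
  utils::write.csv(as.data.frame(unclass(kd)), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_kd_matrix
#' @export
read_kd_matrix <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}
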