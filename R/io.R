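#' Write a trace set to disk
#'
#' Two dialects are supported. CSV: a header row `time,<id1>,<id2>,...`
#' followed by one row per frame, time in seconds. Legacy binary
#' (little-endian): an int32 frame count F, an int16 trace count T, then
#' F x T int16 intensities in trace-major order (all frames of trace 1,
#' then trace 2, ...). Binary intensities are rounded to the nearest
#' integer and must fit in int16.
#'
#' @param traces A `trace_set` (see [simulate_traces()]).
#' @param path Output file path.
#' @param format `"auto"` (by extension: `.csv` vs anything else binary),
#'   `"csv"`, or `"binary"`.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path, format = c("auto", "csv", "binary")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else
      "binary"
  mat <- traces$intensities
  if (format == "csv") {
    df <- data.frame(time = traces$time, mat, check.names = FALSE)
    names(df) <- c("time", traces$ids)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    v <- round(as.vector(mat))           # trace-major: column by column
    if (any(v < -32768 | v > 32767))
      stop("intensities out of int16 range for the binary dialect",
           call. = FALSE)
    if (ncol(mat) > 32767)
      stop("binary dialect holds at most 32767 traces", call. = FALSE)
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.integer(nrow(mat)), con, size = 4L, endian = "little")
    writeBin(as.integer(ncol(mat)), con, size = 2L, endian = "little")
    writeBin(as.integer(v), con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read a trace set from disk
#'
#' Counterpart of [write_traces()]. With `format = "auto"` the dialect is
#' chosen by extension (`.csv`) or by sniffing the first bytes for a
#' plausible CSV header. The binary dialect carries no ids or time base, so
#' ids are synthesized and `frame_interval` is taken from the argument.
#'
#' @param path Input file path.
#' @param format `"auto"`, `"csv"`, or `"binary"`.
#' @param frame_interval Seconds per frame for the binary dialect (for CSV
#'   it is inferred from the time column). Default 0.1.
#' @return A `trace_set`.
#' @export
read_traces <- function(path, format = c("auto", "csv", "binary"),
                        frame_interval = 0.1) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0)
    stop("empty trace file: ", path, call. = FALSE)
  if (format == "auto") {
    if (grepl("\\.csv$", path, ignore.case = TRUE)) {
      format <- "csv"
    } else {
      head_bytes <- readBin(path, "raw", n = 5L)
      format <- if (identical(head_bytes, charToRaw("time,"))) "csv" else
        "binary"
    }
  }
  if (format == "csv") {
    df <- utils::read.csv(path, check.names = FALSE)
    if (names(df)[1] != "time")
      stop("malformed trace CSV header in ", path,
           ": first column must be `time` (line 1)", call. = FALSE)
    if (ncol(df) < 2L)
      stop("trace CSV has no trace columns: ", path, call. = FALSE)
    tm <- df[[1]]
    fi <- if (length(tm) > 1L) stats::median(diff(tm)) else frame_interval
    mat <- as.matrix(df[, -1, drop = FALSE])
    structure(list(time = tm, intensities = mat, ids = colnames(mat),
                   frame_interval = fi),
              class = "trace_set")
  } else {
    sz <- file.size(path)
    con <- file(path, "rb")
    on.exit(close(con))
    if (sz < 6L)
      stop("truncated binary trace file ", path, ": ", sz,
           " bytes, need at least 6 for the header", call. = FALSE)
    nf <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    nt <- readBin(con, "integer", 1L, size = 2L, endian = "little")
    if (nf < 1L || nt < 1L)
      stop("malformed binary trace header in ", path,
           " (frames = ", nf, ", traces = ", nt, ")", call. = FALSE)
    need <- 6 + 2 * as.numeric(nf) * nt
    if (sz < need)
      stop("truncated binary trace file ", path, ": expected ", need,
           " bytes, got ", sz, " (truncation at byte offset ", sz, ")",
           call. = FALSE)
    v <- readBin(con, "integer", nf * nt, size = 2L, endian = "little")
    mat <- matrix(as.numeric(v), nrow = nf, ncol = nt)
    ids <- paste0("trace_", seq_len(nt))
    colnames(mat) <- ids
    structure(list(time = (seq_len(nf) - 1L) * frame_interval,
                   intensities = mat, ids = ids,
                   frame_interval = frame_interval),
              class = "trace_set")
  }
}

#' Write step calls as TSV
#'
#' Columns: `trace_id`, `n_steps`, `status`, `changepoints`
#' (semicolon-joined frame indices).
#'
#' @param calls Data frame from [call_steps()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_step_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_step_calls
#' @export
read_step_calls <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, colClasses = c("character", "integer",
                                               "character", "character"))
  need <- c("trace_id", "n_steps", "status", "changepoints")
  if (!all(need %in% names(df)))
    stop("malformed step TSV ", path, ": need columns ",
         paste(need, collapse = ", "), call. = FALSE)
  df
}

#' Write a fitted model as a JSON report
#'
#' The comparable payload (input counts, settings, posterior summaries,
#' predictive diagnostics) is kept separate from the timestamp so that runs
#' with the same seed produce byte-identical payloads.
#'
#' @param fit An [oligo_fit()] object.
#' @param path Output file path.
#' @param samples_path Optional path; when given, the retained posterior
#'   draws are also written as a tab-separated table with columns
#'   `q1`, `q2`, `q3`.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path, samples_path = NULL) {
  stopifnot(inherits(fit, "oligo_fit"))
  ppc <- posterior_predictive_check(fit)
  payload <- list(
    input = list(counts = as.list(fit$counts), N = fit$N),
    config = list(r = fit$r, prior = fit$prior,
                  iterations = fit$iterations, burn_in = fit$burn_in,
                  thin = fit$thin, seed = fit$seed),
    posterior = list(mean = as.list(fit$mean), sd = as.list(fit$sd),
                     ess = as.list(fit$ess)),
    predictive = list(predicted = as.list(ppc$predicted),
                      empirical = as.list(ppc$empirical),
                      max_discrepancy = ppc$max_discrepancy)
  )
  jsonlite::write_json(list(payload = payload,
                            timestamp = format(Sys.time(), usetz = TRUE)),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(samples_path)) {
    df <- as.data.frame(fit$samples)
    names(df) <- c("q1", "q2", "q3")
    utils::write.table(df, samples_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}
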