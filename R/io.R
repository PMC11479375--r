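# On-disk artifacts are plain CSV (comma separator, '.' decimal, one header
# row) plus a key=value sidecar ("<path>.meta") carrying recording metadata.
# Floats are written with 17 significant digits so write -> read round-trips
# reproduce doubles bitwise.

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.17g", v)
  }, character(1))
  out
}

write_csv_raw <- function(d, path) {
  con <- tryCatch(file(path, "w"), error = function(e)
    stop_mear(sprintf("cannot open '%s' for writing", path), "mear_io_error"))
  on.exit(close(con))
  cols <- lapply(d, function(col) if (is.numeric(col)) fmt_num(col)
                 else as.character(col))
  writeLines(paste(names(d), collapse = ","), con)
  if (nrow(d))
    writeLines(do.call(paste, c(cols, sep = ",")), con)
  invisible(path)
}

read_csv_raw <- function(path, columns, numeric_cols) {
  if (!file.exists(path))
    stop_mear(sprintf("file not found: '%s'", path), "mear_io_error")
  lines <- readLines(path)
  if (!length(lines))
    stop_mear(sprintf("%s: empty file", path), "mear_format_error")
  header <- strsplit(lines[[1]], ",", fixed = TRUE)[[1]]
  missing <- setdiff(columns, header)
  if (length(missing))
    stop_mear(sprintf("%s: missing column(s): %s", path,
                      paste(missing, collapse = ", ")), "mear_format_error")
  body <- lines[-1]
  body <- body[nzchar(body)]
  cells <- strsplit(body, ",", fixed = TRUE)
  ncol_exp <- length(header)
  d <- as.data.frame(matrix(NA_character_, nrow = length(body),
                            ncol = ncol_exp, dimnames = list(NULL, header)),
                     stringsAsFactors = FALSE)
  for (i in seq_along(cells)) {
    row <- cells[[i]]
    if (length(row) < ncol_exp) row <- c(row, rep("", ncol_exp - length(row)))
    if (length(row) != ncol_exp)
      stop_mear(sprintf("%s: line %d has %d fields, expected %d",
                        path, i + 1L, length(row), ncol_exp),
                "mear_format_error")
    d[i, ] <- row
  }
  for (col in numeric_cols) {
    v <- d[[col]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & nzchar(v))
    if (length(bad))
      stop_mear(sprintf("%s: non-numeric value '%s' in column '%s' at line %d",
                        path, v[bad[1]], col, bad[1] + 1L),
                "mear_format_error")
    d[[col]] <- num
  }
  d[, columns, drop = FALSE]
}

write_sidecar <- function(path, fields) {
  writeLines(paste0(names(fields), "=", unlist(fields)), paste0(path, ".meta"))
}

read_sidecar <- function(path) {
  meta_path <- paste0(path, ".meta")
  if (!file.exists(meta_path)) return(list())
  lines <- readLines(meta_path)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  out <- lapply(kv, `[`, 2)
  names(out) <- vapply(kv, `[`, character(1), 1)
  out
}

#' Write / read an acceleration recording
#'
#' The recording CSV has columns `t,acc_ml,acc_ap,acc_is`; subject id,
#' ear side and sample rate travel in a `<path>.meta` key=value sidecar.
#' The round-trip is lossless at full double precision.
#'
#' @param recording an [accel_recording()].
#' @param path CSV file path.
#' @return `path` (write) / an `accel_recording` (read).
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "accel_recording"))
  d <- data.frame(t = recording_times(recording), recording$samples)
  write_csv_raw(d, path)
  write_sidecar(path, list(subject_id = recording$subject_id,
                           ear_side = recording$ear_side,
                           sample_rate = recording$sample_rate))
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  d <- read_csv_raw(path, c("t", ACC_CHANNELS), c("t", ACC_CHANNELS))
  if (!nrow(d))
    stop_mear(sprintf("%s: recording has no samples", path),
              "mear_format_error")
  meta <- read_sidecar(path)
  fs <- if (!is.null(meta$sample_rate)) as.numeric(meta$sample_rate) else 100
  if (nrow(d) > 1) {
    dt <- diff(d$t)
    if (max(abs(dt - 1 / fs)) > 1e-6)
      stop_mear(sprintf("%s: sample spacing inconsistent with %g Hz (line %d)",
                        path, fs, which.max(abs(dt - 1 / fs)) + 2L),
                "mear_format_error")
  }
  accel_recording(as.matrix(d[, ACC_CHANNELS]),
                  subject_id = meta$subject_id %||% "unknown",
                  ear_side = meta$ear_side %||% "left",
                  t0 = d$t[1], sample_rate = fs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

FOOT_CODE <- c(left = "L", right = "R", unknown = "U")

#' Write / read gait-event tables
#'
#' Events CSV has columns `time,kind,foot` with foot coded `L`/`R`/`U`.
#' Events are written (and therefore read back) sorted by time.
#'
#' @param events a [gait_events()] table.
#' @param path CSV file path.
#' @return `path` (write) / event table (read).
#' @export
write_events <- function(events, path) {
  events <- gait_events(events$time, events$kind, events$foot)  # validates + sorts
  d <- data.frame(time = events$time, kind = events$kind,
                  foot = unname(FOOT_CODE[events$foot]))
  write_csv_raw(d, path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  d <- read_csv_raw(path, c("time", "kind", "foot"), "time")
  code <- c(L = "left", R = "right", U = "unknown")
  if (nrow(d) && !all(d$foot %in% names(code)))
    stop_mear(sprintf("%s: foot codes must be L/R/U", path),
              "mear_format_error")
  gait_events(d$time, d$kind, if (nrow(d)) unname(code[d$foot]) else character())
}

#' Write / read stride tables
#'
#' Strides CSV has columns `foot,ic_time,stride_time,swing_time,dsupp_time,
#' stride_length_cm,stride_width_cm`; missing values are empty cells.
#'
#' @param strides a [stride_table()].
#' @param path CSV file path.
#' @return `path` (write) / stride table (read).
#' @export
write_strides <- function(strides, path) {
  d <- strides[, STRIDE_COLUMNS, drop = FALSE]
  d$foot <- unname(FOOT_CODE[d$foot])
  write_csv_raw(d, path)
  invisible(path)
}

#' @rdname write_strides
#' @export
read_strides <- function(path) {
  num_cols <- setdiff(STRIDE_COLUMNS, "foot")
  d <- read_csv_raw(path, STRIDE_COLUMNS, num_cols)
  code <- c(L = "left", R = "right")
  if (nrow(d) && !all(d$foot %in% names(code)))
    stop_mear(sprintf("%s: stride foot codes must be L/R", path),
              "mear_format_error")
  do.call(stride_table,
          c(list(foot = if (nrow(d)) unname(code[d$foot]) else character()),
            d[num_cols]))
}
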