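#' Read and write the JINS MEME ES_R CSV dialect
#'
#' Files carry leading acquisition-parameter rows (serialized as `#`-prefixed
#' `key,value` lines so they are unambiguous to strip), one header row, then
#' comma-separated data rows in the fixed column order
#' `sample_number, date, ACCX, ACCY, ACCZ, EOGL, EOGR, EOGH, EOGV`
#' (optionally followed by `GYROX, GYROY, GYROZ`, which the pipeline
#' ignores).  Dates use the format `dd.mm.rrrr:hh:mm:ss` with `rrrr` the
#' 4-digit year.  One row is written per EOG sample; the slower accelerometer
#' stream is sample-and-hold replicated to the EOG grid, and decimated back
#' on read, so write-then-read is an identity.
#'
#' @param recording A [raw_recording()].
#' @param path File path.
#' @return `write_jins_csv()` returns `path` invisibly; `read_jins_csv()`
#'   returns a [raw_recording()].
#' @export
write_jins_csv <- function(recording, path) {
  stopifnot(inherits(recording, "raw_recording"))
  rec <- recording
  factor <- rec$eog_rate / rec$acc_rate
  if (factor != round(factor)) {
    stop("eog_rate must be an integer multiple of acc_rate", call. = FALSE)
  }
  params <- c(
    sprintf("# Device,JINS MEME ES_R"),
    sprintf("# EOG_RATE,%g", rec$eog_rate),
    sprintf("# ACC_RATE,%g", rec$acc_rate),
    sprintf("# ACC_RANGE_G,2"),
    sprintf("# LABEL,%d", rec$label$code),
    sprintf("# LABEL_NAME,%s", rec$label$name)
  )
  n <- length(rec$eog_l)
  up <- function(a) if (n == 0L) numeric(0) else rep(a, each = factor)[1:n]
  df <- data.frame(
    sample_number = rec$sample_index,
    date = rec$timestamps,
    ACCX = up(rec$acc_x), ACCY = up(rec$acc_y), ACCZ = up(rec$acc_z),
    EOGL = rec$eog_l, EOGR = rec$eog_r, EOGH = rec$eog_h, EOGV = rec$eog_v,
    stringsAsFactors = FALSE
  )
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot open '", path, "' for writing: ", conditionMessage(e),
         call. = FALSE)
  })
  on.exit(close(con))
  writeLines(params, con)
  writeLines(paste(JINS_COLUMNS, collapse = ","), con)
  if (n > 0L) {
    utils::write.table(df, con, sep = ",", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

JINS_COLUMNS <- c("sample_number", "date", "ACCX", "ACCY", "ACCZ",
                  "EOGL", "EOGR", "EOGH", "EOGV")
JINS_GYRO_COLUMNS <- c("GYROX", "GYROY", "GYROZ")
JINS_DATE_RE <- "^[0-3][0-9]\\.[0-1][0-9]\\.[0-9]{4}:[0-2][0-9]:[0-5][0-9]:[0-5][0-9]$"

#' @rdname write_jins_csv
#' @export
read_jins_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  is_param <- startsWith(lines, "#")
  params <- parse_param_rows(lines[is_param])
  body <- lines[!is_param]
  if (length(body) < 1L) stop("no header row in ", path, call. = FALSE)
  header <- strsplit(body[1], ",", fixed = TRUE)[[1]]
  has_gyro <- length(header) == length(JINS_COLUMNS) + 3L &&
    identical(header, c(JINS_COLUMNS, JINS_GYRO_COLUMNS))
  if (!has_gyro && !identical(header, JINS_COLUMNS)) {
    stop("format error: expected columns [", paste(JINS_COLUMNS, collapse = ", "),
         "] but found [", paste(header, collapse = ", "), "]", call. = FALSE)
  }
  eog_rate <- as.numeric(params[["EOG_RATE"]] %||% EOG_RATE)
  acc_rate <- as.numeric(params[["ACC_RATE"]] %||% ACC_RATE)
  code <- as.integer(params[["LABEL"]] %||% 0L)
  label <- label_map(code)

  if (length(body) == 1L) {
    return(raw_recording(label, numeric(0), numeric(0), numeric(0), numeric(0),
                         numeric(0), numeric(0), numeric(0),
                         eog_rate = eog_rate, acc_rate = acc_rate))
  }
  df <- utils::read.csv(text = body, header = TRUE, stringsAsFactors = FALSE,
                        colClasses = c(date = "character"))
  bad <- which(!grepl(JINS_DATE_RE, df$date))
  if (length(bad)) {
    stop(sprintf("format error: unparseable date '%s' in data row %d of %s",
                 df$date[bad[1]], bad[1], path), call. = FALSE)
  }
  factor <- eog_rate / acc_rate
  if (factor != round(factor)) {
    stop("EOG_RATE must be an integer multiple of ACC_RATE", call. = FALSE)
  }
  pick <- seq(1L, nrow(df), by = factor)
  dev <- max(abs(df$EOGH - (df$EOGL - df$EOGR)))
  if (dev > 1e-6) {
    warning(sprintf(
      "channel identity EOGH = EOGL - EOGR deviates by up to %.3g in %s",
      dev, path), call. = FALSE)
  }
  raw_recording(label,
                df$EOGL, df$EOGR, df$EOGH, df$EOGV,
                df$ACCX[pick], df$ACCY[pick], df$ACCZ[pick],
                eog_rate = eog_rate, acc_rate = acc_rate,
                timestamps = df$date)
}

parse_param_rows <- function(lines) {
  out <- list()
  for (ln in lines) {
    kv <- strsplit(sub("^#\\s*", "", ln), ",", fixed = TRUE)[[1]]
    if (length(kv) >= 2L) out[[kv[1]]] <- paste(kv[-1], collapse = ",")
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
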