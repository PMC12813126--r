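#' Read a three-lead VCG from a WFDB header/data pair
#'
#' Parses a WFDB `.hea` header and its 16-bit little-endian `.dat` signal
#' file (format 16, the PTB convention) and returns the three named leads
#' converted to millivolts using each channel's gain and baseline.
#'
#' @param path Path to the record, with or without the `.hea` extension.
#' @param lead_names Names (header signal descriptions) of the three
#'   orthogonal leads, in the order X, Y, Z. PTB headers call them
#'   `vx`, `vy`, `vz`.
#' @param label Optional class tag attached to the returned record.
#' @return A [vcg_record].
#' @export
read_wfdb_record <- function(path, lead_names = c("vx", "vy", "vz"),
                             label = "unknown") {
  if (length(lead_names) != 3L) stopf("lead_names must name exactly 3 leads")
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) stopf("WFDB header not found: %s", hea)
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  record_name <- sub("/.*", "", top[1])
  nsig <- as.integer(top[2])
  fs <- if (length(top) >= 3) as.numeric(sub("/.*", "", top[3])) else 250
  nsamp <- if (length(top) >= 4) as.integer(top[4]) else NA_integer_
  sig <- lines[2:(1 + nsig)]
  parse_sig <- function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    gain_field <- if (length(f) >= 3) f[3] else "200"
    gain_num <- sub("\\(.*", "", sub("/.*", "", gain_field))
    gain <- suppressWarnings(as.numeric(gain_num))
    if (is.na(gain) || gain == 0) gain <- 200
    baseline <- if (grepl("\\(", gain_field))
      as.numeric(sub(".*\\((-?[0-9]+)\\).*", "\\1", gain_field))
    else if (length(f) >= 5) suppressWarnings(as.numeric(f[5])) else 0
    if (is.na(baseline)) baseline <- 0
    fmt <- if (length(f) >= 2) sub("x.*|:.*|\\+.*", "", f[2]) else "16"
    # description = everything after the 9 numeric fields (may contain spaces)
    desc <- if (length(f) >= 9) paste(f[9:length(f)], collapse = " ") else ""
    list(file = f[1], fmt = fmt, gain = gain, baseline = baseline, desc = desc)
  }
  sigs <- lapply(sig, parse_sig)
  fmts <- unique(vapply(sigs, `[[`, "", "fmt"))
  if (!identical(fmts, "16"))
    stopf("only WFDB signal format 16 is supported (got %s)",
          paste(fmts, collapse = ","))
  descs <- vapply(sigs, `[[`, "", "desc")
  sel <- match(lead_names, descs)
  if (anyNA(sel))
    stopf("lead not found in %s: %s (available: %s)", hea,
          paste(lead_names[is.na(sel)], collapse = ", "),
          paste(descs, collapse = ", "))
  datfile <- file.path(dirname(hea), sigs[[1]]$file)
  if (!file.exists(datfile)) stopf("WFDB data file not found: %s", datfile)
  raw <- readBin(datfile, what = "integer", size = 2L, signed = TRUE,
                 endian = "little", n = file.size(datfile) / 2L)
  if (length(raw) %% nsig != 0L)
    stopf("data file length is not a multiple of the %d channels", nsig)
  adu <- matrix(raw, ncol = nsig, byrow = TRUE)
  if (!is.na(nsamp) && nrow(adu) != nsamp)
    stopf("header declares %d samples but data file holds %d", nsamp, nrow(adu))
  mv <- function(j) (adu[, sel[j]] - sigs[[sel[j]]]$baseline) / sigs[[sel[j]]]$gain
  vcg_record(mv(1), mv(2), mv(3), fs = fs, record_id = record_name,
             label = label)
}

#' Read a three-lead VCG from CSV
#'
#' Expects header columns `x`, `y`, `z` (voltages in mV) and optionally
#' `time` (seconds); when a time column is present its spacing must be
#' uniform and consistent with `fs` within 1%.
#'
#' @param path CSV file path.
#' @param fs Sampling rate in Hz.
#' @param record_id,label Metadata for the returned record; `record_id`
#'   defaults to the file name.
#' @return A [vcg_record].
#' @export
read_csv_record <- function(path, fs, record_id = NULL, label = "unknown") {
  if (!file.exists(path)) stopf("CSV record not found: %s", path)
  df <- utils::read.csv(path, check.names = TRUE)
  need <- c("x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("CSV %s lacks required column(s): %s", path, paste(miss, collapse = ", "))
  for (cn in intersect(c("time", need), names(df))) {
    v <- df[[cn]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))[1]
      stopf("non-numeric value in column '%s' of %s at data row %d",
            cn, path, if (is.na(bad)) 1L else bad)
    }
    if (anyNA(v)) stopf("missing value in column '%s' of %s at data row %d",
                        cn, path, which(is.na(v))[1])
  }
  if ("time" %in% names(df) && nrow(df) > 1) {
    dt <- diff(df$time)
    if (any(abs(dt - 1 / fs) > 0.01 / fs))
      stopf("time column of %s is not uniformly spaced at fs=%g Hz (max step %g s)",
            path, fs, max(dt))
  }
  if (is.null(record_id)) record_id <- sub("\\.csv$", "", basename(path))
  vcg_record(df$x, df$y, df$z, fs = fs, record_id = record_id, label = label)
}

#' Write a VCG record as CSV (time, x, y, z)
#' @param record A [vcg_record].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_csv_record <- function(record, path) {
  n <- length(record$x)
  df <- data.frame(time = (seq_len(n) - 1) / record$fs,
                   x = record$x, y = record$y, z = record$z)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write / read the per-record feature table
#'
#' The table has columns `record_id`, `label`, then the 12 features in the
#' canonical order of [feature_names()]. `read_feature_table()` inverts
#' `write_feature_table()` exactly.
#'
#' @param features Data frame (or matrix) with one row per record and the 12
#'   feature columns, plus `record_id` and `label` columns (or supplied via
#'   the arguments of the same name).
#' @param path Output CSV path.
#' @param record_id,label Optional vectors overriding columns of `features`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path, record_id = NULL, label = NULL) {
  features <- as.data.frame(features)
  if (!is.null(record_id)) features$record_id <- record_id
  if (!is.null(label)) features$label <- label
  miss <- setdiff(c("record_id", "label", feature_names()), names(features))
  if (length(miss))
    stopf("feature table lacks column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(features$record_id))
    stopf("duplicate record_id in feature table: %s",
          features$record_id[anyDuplicated(features$record_id)])
  out <- features[, c("record_id", "label", feature_names())]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stopf("feature table not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(record_id = "character"))
  miss <- setdiff(c("record_id", "label", feature_names()), names(df))
  if (length(miss))
    stopf("feature table %s lacks column(s): %s", path, paste(miss, collapse = ", "))
  df[, c("record_id", "label", feature_names())]
}
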