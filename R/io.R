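# Delimited-text round-tripping for every data type. Files are plain CSV
# with optional leading `# key=value` metadata comment lines; both LF and
# CRLF line endings are accepted, and malformed rows are reported with
# their line number.

.read_kin_file <- function(path, columns) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  meta <- list()
  i <- 1L
  while (i <= length(lines) &&
         (grepl("^\\s*#", lines[i]) || !nzchar(trimws(lines[i])))) {
    m <- regmatches(lines[i],
                    regexec("^\\s*#\\s*([A-Za-z0-9_.]+)\\s*=\\s*(.*)\\s*$",
                            lines[i]))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- m[3]
    i <- i + 1L
  }
  if (i > length(lines)) {
    stop("parse error in ", path, ": no header line found", call. = FALSE)
  }
  header <- trimws(strsplit(lines[i], ",", fixed = TRUE)[[1]])
  if (!identical(header, columns)) {
    stop("parse error in ", path, " line ", i, ": expected header `",
         paste(columns, collapse = ","), "`, got `", lines[i], "`",
         call. = FALSE)
  }
  rows <- vector("list", length(lines) - i)
  n <- 0L
  for (j in seq(i + 1L, length.out = length(lines) - i)) {
    ln <- lines[j]
    if (!nzchar(trimws(ln))) next
    parts <- trimws(strsplit(ln, ",", fixed = TRUE)[[1]])
    if (length(parts) != length(columns)) {
      stop("parse error in ", path, " line ", j, ": expected ",
           length(columns), " columns, got ", length(parts), call. = FALSE)
    }
    n <- n + 1L
    rows[[n]] <- parts
  }
  if (n == 0L) stop("parse error in ", path, ": no data rows", call. = FALSE)
  mat <- do.call(rbind, rows[seq_len(n)])
  out <- stats::setNames(as.data.frame(mat, stringsAsFactors = FALSE),
                         columns)
  list(data = tibble::as_tibble(out), meta = meta,
       data_start = i + 1L)
}

.numeric_cols <- function(parsed, path, cols) {
  d <- parsed$data
  for (cn in cols) {
    v <- suppressWarnings(as.numeric(d[[cn]]))
    bad <- which(is.na(v) & nzchar(d[[cn]]))
    if (any(is.na(v))) {
      ln <- parsed$data_start + (if (length(bad)) bad[1] else
        which(is.na(v))[1]) - 1L
      stop("parse error in ", path, " line ", ln,
           ": non-numeric value in column `", cn, "`", call. = FALSE)
    }
    d[[cn]] <- v
  }
  d
}

.check_time_monotone <- function(tv, path, data_start, colname) {
  if (is.unsorted(tv, strictly = TRUE)) {
    bad <- which(diff(tv) <= 0)[1] + 1L
    stop("parse error in ", path, " line ", data_start + bad - 1L,
         ": `", colname, "` is not strictly increasing", call. = FALSE)
  }
}

.fmt_num <- function(x) sprintf("%.15g", x)

#' Read / write a CD kinetic trace
#'
#' Format: `time_min,signal` CSV with a `# wavelength_nm=` metadata
#' comment. Round trips to numeric precision 1e-12.
#'
#' @param path File path.
#' @return `read_cd_trace()`: a `quadkin_cd_trace`.
#' @export
read_cd_trace <- function(path) {
  p <- .read_kin_file(path, c("time_min", "signal"))
  d <- .numeric_cols(p, path, c("time_min", "signal"))
  .check_time_monotone(d$time_min, path, p$data_start, "time_min")
  w <- if (!is.null(p$meta$wavelength_nm)) as.numeric(p$meta$wavelength_nm)
       else NA_real_
  cd_trace(d$time_min, d$signal, w)
}

#' @rdname read_cd_trace
#' @param x Object to write.
#' @export
write_cd_trace <- function(x, path) {
  lines <- c(paste0("# wavelength_nm=", cd_wavelength(x)),
             "time_min,signal",
             paste(.fmt_num(x$time_min), .fmt_num(x$signal), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a CD melting curve
#'
#' Format: `temp_C,signal` CSV with a `# wavelength_nm=` comment.
#' @param path File path.
#' @return `read_melting_curve()`: a `quadkin_melting_curve`.
#' @export
read_melting_curve <- function(path) {
  p <- .read_kin_file(path, c("temp_C", "signal"))
  d <- .numeric_cols(p, path, c("temp_C", "signal"))
  .check_time_monotone(d$temp_C, path, p$data_start, "temp_C")
  w <- if (!is.null(p$meta$wavelength_nm)) as.numeric(p$meta$wavelength_nm)
       else NA_real_
  melting_curve(d$temp_C, d$signal, w)
}

#' @rdname read_melting_curve
#' @param x Object to write.
#' @export
write_melting_curve <- function(x, path) {
  lines <- c(paste0("# wavelength_nm=", cd_wavelength(x)),
             "temp_C,signal",
             paste(.fmt_num(x$temp_C), .fmt_num(x$signal), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write an HDX peak-volume series
#'
#' Format: `time_min,volume` CSV with a `# residue=` comment.
#' @param path File path.
#' @return `read_hdx_series()`: a `quadkin_hdx_series` tibble.
#' @export
read_hdx_series <- function(path) {
  p <- .read_kin_file(path, c("time_min", "volume"))
  d <- .numeric_cols(p, path, c("time_min", "volume"))
  .check_time_monotone(d$time_min, path, p$data_start, "time_min")
  out <- tibble::tibble(time_min = d$time_min, volume = d$volume)
  attr(out, "residue") <- p$meta$residue
  class(out) <- c("quadkin_hdx_series", class(out))
  out
}

#' @rdname read_hdx_series
#' @param x Object to write.
#' @export
write_hdx_series <- function(x, path) {
  res <- attr(x, "residue")
  lines <- c(if (!is.null(res)) paste0("# residue=", res),
             "time_min,volume",
             paste(.fmt_num(x$time_min), .fmt_num(x$volume), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write an imino-proton peak-volume table
#'
#' Format: `residue,vol_g4i,vol_g4ii` CSV.
#' @param path File path.
#' @return `read_peak_table()`: a tibble.
#' @export
read_peak_table <- function(path) {
  p <- .read_kin_file(path, c("residue", "vol_g4i", "vol_g4ii"))
  d <- .numeric_cols(p, path, c("vol_g4i", "vol_g4ii"))
  tibble::tibble(residue = d$residue, vol_g4i = d$vol_g4i,
                 vol_g4ii = d$vol_g4ii)
}

#' @rdname read_peak_table
#' @param x Object to write.
#' @export
write_peak_table <- function(x, path) {
  lines <- c("residue,vol_g4i,vol_g4ii",
             paste(x$residue, .fmt_num(x$vol_g4i), .fmt_num(x$vol_g4ii),
                   sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a state trajectory
#'
#' Format: `time_min,A_hp,B_g4i,D_u,C_g4ii` CSV in the package's fixed
#' state order (Hp, G4(I), U, G4(II)).
#' @param path File path.
#' @return `read_trajectory()`: a `quadkin_trajectory` tibble.
#' @export
read_trajectory <- function(path) {
  cols <- c("time_min", "A_hp", "B_g4i", "D_u", "C_g4ii")
  p <- .read_kin_file(path, cols)
  d <- .numeric_cols(p, path, cols)
  .check_time_monotone(d$time_min, path, p$data_start, "time_min")
  out <- tibble::as_tibble(d)
  class(out) <- c("quadkin_trajectory", class(out))
  out
}

#' @rdname read_trajectory
#' @param x Object to write.
#' @export
write_trajectory <- function(x, path) {
  lines <- c("time_min,A_hp,B_g4i,D_u,C_g4ii",
             paste(.fmt_num(x$time_min), .fmt_num(x$A_hp),
                   .fmt_num(x$B_g4i), .fmt_num(x$D_u), .fmt_num(x$C_g4ii),
                   sep = ","))
  writeLines(lines, path)
  invisible(path)
}
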