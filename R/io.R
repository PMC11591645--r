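#' Read a Raman spectrum from disk
#'
#' Supports two-column delimited text (comma or tab, optional header) and a
#' subset of JCAMP-DX: `##XYDATA=(X++(Y..Y))` and `##XYPOINTS=(XY..XY)`
#' blocks. The axis is canonicalized to ascending; the file's original
#' direction is kept in the metadata.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"csv"` or `"jcamp"`.
#' @return a [raman_spectrum].
#' @export
read_spectrum <- function(path, format = c("auto", "csv", "jcamp")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(jdx|dx|jcamp)$", tolower(path))) "jcamp" else "csv"
  }
  if (format == "csv") read_spectrum_csv(path) else read_spectrum_jcamp(path)
}

read_spectrum_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("parse error in ", path, ": empty file")
  split_row <- function(l) strsplit(trimws(l), "[,\t;]+|[[:space:]]+")[[1]]
  first <- suppressWarnings(as.numeric(split_row(lines[1])))
  start <- if (anyNA(first)) 2L else 1L   # header line present
  if (start > length(lines)) stop("parse error in ", path, ": no data rows")
  xs <- ys <- numeric(length(lines) - start + 1L)
  for (i in seq.int(start, length(lines))) {
    vals <- suppressWarnings(as.numeric(split_row(lines[i])))
    if (length(vals) < 2L || anyNA(vals[1:2]))
      stop(sprintf("parse error in %s at line %d: expected two numeric columns",
                   path, i))
    xs[i - start + 1L] <- vals[1]; ys[i - start + 1L] <- vals[2]
  }
  if (length(xs) < 2L) stop("validation error: a spectrum needs at least 2 points")
  raman_spectrum(xs, ys, metadata = list(source_file = basename(path)))
}

jcamp_headers <- function(lines) {
  hdr <- grep("^##", lines, value = TRUE)
  keys <- toupper(sub("^##\\$?([^=]*)=.*$", "\\1", hdr))
  vals <- trimws(sub("^##\\$?[^=]*=", "", hdr))
  stats::setNames(as.list(vals), trimws(keys))
}

read_spectrum_jcamp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  h <- jcamp_headers(lines)
  num <- function(key) {
    v <- h[[key]]
    if (is.null(v) || !length(v)) return(NA_real_)
    suppressWarnings(as.numeric(v))
  }
  xfac <- if (!is.na(num("XFACTOR"))) num("XFACTOR") else 1
  yfac <- if (!is.na(num("YFACTOR"))) num("YFACTOR") else 1

  ixy <- grep("^##XYDATA=", lines)
  ixp <- grep("^##XYPOINTS=", lines)
  iend <- grep("^##END", lines)
  stop_at <- if (length(iend)) iend[1] else length(lines) + 1L
  if (length(ixy)) {
    body <- lines[seq.int(ixy[1] + 1L, stop_at - 1L)]
    body <- body[nzchar(trimws(body)) & !grepl("^##", body)]
    deltax <- num("DELTAX")
    if (is.na(deltax)) {
      np <- num("NPOINTS")
      if (is.na(np) || np < 2) stop("parse error in ", path,
                                    ": XYDATA needs DELTAX or NPOINTS/FIRSTX/LASTX")
      deltax <- (num("LASTX") - num("FIRSTX")) / (np - 1)
    }
    xs <- ys <- list()
    for (i in seq_along(body)) {
      vals <- suppressWarnings(as.numeric(strsplit(trimws(body[i]),
                                                   "[,;[:space:]]+")[[1]]))
      if (length(vals) < 2L || anyNA(vals))
        stop(sprintf("parse error in %s at XYDATA line %d", path, i))
      x0 <- vals[1]; yv <- vals[-1]
      xs[[i]] <- x0 + deltax * (seq_along(yv) - 1L)
      ys[[i]] <- yv
    }
    x <- unlist(xs) * xfac; y <- unlist(ys) * yfac
  } else if (length(ixp)) {
    body <- lines[seq.int(ixp[1] + 1L, stop_at - 1L)]
    body <- body[nzchar(trimws(body)) & !grepl("^##", body)]
    toks <- unlist(strsplit(trimws(body), ";"))
    toks <- toks[nzchar(trimws(toks))]
    pairs <- lapply(seq_along(toks), function(i) {
      vals <- suppressWarnings(as.numeric(strsplit(trimws(toks[i]),
                                                   "[,[:space:]]+")[[1]]))
      if (length(vals) != 2L || anyNA(vals))
        stop(sprintf("parse error in %s at XYPOINTS entry %d", path, i))
      vals
    })
    m <- do.call(rbind, pairs)
    x <- m[, 1] * xfac; y <- m[, 2] * yfac
  } else {
    stop("parse error in ", path, ": no XYDATA or XYPOINTS block")
  }
  md <- list(source_file = basename(path))
  if (!is.null(h[["INSTRUMENT"]])) md$instrument_name <- h[["INSTRUMENT"]]
  if (!is.na(num("RESOLUTION"))) md$resolution <- num("RESOLUTION")
  s <- raman_spectrum(x, y, metadata = md)
  if (!is.null(md$instrument_name)) s$instrument <- md$instrument_name
  s
}

#' Write a Raman spectrum to disk
#'
#' Values are written with 15 significant digits so a write/read round trip
#' preserves them to better than 1e-9. JCAMP output uses the XYPOINTS dialect
#' and carries the instrument name and (when known) resolution in the header.
#'
#' @param s a [raman_spectrum].
#' @param path output path.
#' @param format `"csv"` or `"jcamp"`.
#' @export
write_spectrum <- function(s, path, format = c("csv", "jcamp")) {
  format <- match.arg(format)
  stopifnot(inherits(s, "raman_spectrum"))
  if (!length(s$intensities)) stop("validation error: empty spectrum")
  fmt <- function(v) sprintf("%.15g", v)
  if (format == "csv") {
    lines <- c("wavenumber,intensity",
               paste(fmt(s$wavenumbers), fmt(s$intensities), sep = ","))
  } else {
    res <- s$metadata$resolution
    lines <- c(
      sprintf("##TITLE=%s replicate %s", s$sample_id, s$replicate_id),
      "##JCAMP-DX=4.24",
      "##DATA TYPE=RAMAN SPECTRUM",
      "##XUNITS=1/CM",
      "##YUNITS=ARBITRARY UNITS",
      sprintf("##$INSTRUMENT=%s", s$instrument),
      if (!is.null(res)) sprintf("##$RESOLUTION=%g", res),
      sprintf("##FIRSTX=%s", fmt(s$wavenumbers[1])),
      sprintf("##LASTX=%s", fmt(s$wavenumbers[length(s$wavenumbers)])),
      sprintf("##NPOINTS=%d", length(s$wavenumbers)),
      "##XYPOINTS=(XY..XY)",
      paste0(fmt(s$wavenumbers), ", ", fmt(s$intensities), ";"),
      "##END=")
  }
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) stop("I/O error writing ", path, ": ",
                                          conditionMessage(e)))
  invisible(ok)
}

#' Read / write a sample table
#'
#' A sample table holds one row per physical sample:
#' `sample_id, pmi_class, sex, instrument, n_replicates`.
#'
#' @param path CSV path.
#' @return data.frame with validated columns.
#' @export
read_sample_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_sample_table(df)
  df
}

#' @rdname read_sample_table
#' @param df sample table data.frame.
#' @export
write_sample_table <- function(df, path) {
  validate_sample_table(df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

validate_sample_table <- function(df) {
  need <- c("sample_id", "pmi_class", "instrument", "n_replicates")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sample table missing columns: ",
                         paste(miss, collapse = ", "))
  if (!all(df$pmi_class %in% 1:5)) stop("pmi_class must be in 1..5")
  if (anyDuplicated(df[c("sample_id", "instrument")]))
    stop("sample_id must be unique within instrument")
  invisible(TRUE)
}
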