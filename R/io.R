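## Delimited-text column contracts (exact names):
##   spectrum : wavelength_nm, intensity
##   titration: ligand_total_nM, signal, replicate
##   decay    : time_ps, counts [, irf]

table_schema <- list(
  spectrum = c("wavelength_nm", "intensity"),
  titration = c("ligand_total_nM", "signal", "replicate"),
  decay = c("time_ps", "counts")
)

detect_sep <- function(path) {
  header <- readLines(path, n = 1)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a delimited data table into a typed record
#'
#' Reads comma- or tab-separated text (delimiter auto-detected from the
#' header row) with the fixed column contract for each kind:
#' `spectrum` (`wavelength_nm,intensity`), `titration`
#' (`ligand_total_nM,signal,replicate`), `decay`
#' (`time_ps,counts[,irf]`). Missing mandatory columns raise a schema
#' error naming the column; non-numeric cells raise a parse error with
#' the offending row index.
#'
#' @param path file path.
#' @param kind `"spectrum"`, `"titration"` or `"decay"`.
#' @return a [spectrum], [binding_dataset] or [decay_trace].
#' @export
read_table <- function(path, kind = c("spectrum", "titration", "decay")) {
  kind <- match.arg(kind)
  check_that(file.exists(path), "io",
             sprintf("file not found: %s", path))
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character",
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- table_schema[[kind]]
  for (col in need) {
    check_that(col %in% names(df), "schema",
               sprintf("missing mandatory column '%s' in %s table",
                       col, kind), column = col)
  }
  num_cols <- intersect(c(need, "irf"), names(df))
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !(trimws(df[[col]]) %in% c("NA", "")))
    check_that(length(bad) == 0, "parse",
               sprintf("non-numeric value in column '%s' at row %s",
                       col, paste(bad, collapse = ", ")),
               column = col, rows = bad)
    df[[col]] <- v
  }
  switch(kind,
    spectrum = spectrum(df$wavelength_nm, df$intensity,
                        meta = list(source = path)),
    decay = decay_trace(df$time_ps, df$counts,
                        irf = if ("irf" %in% names(df)) df$irf,
                        meta = list(source = path)),
    titration = {
      conc <- sort(unique(df$ligand_total_nM))
      reps <- sort(unique(df$replicate))
      sig <- matrix(NA_real_, length(conc), length(reps))
      for (i in seq_len(nrow(df))) {
        sig[match(df$ligand_total_nM[i], conc),
            match(df$replicate[i], reps)] <- df$signal[i]
      }
      check_that(!anyNA(sig), "schema",
                 "titration table is not rectangular across replicates")
      binding_dataset(conc, sig)
    })
}

#' Write a typed record as a delimited table
#'
#' Inverse of [read_table]; the same column contracts apply.
#'
#' @param x a [spectrum], [binding_dataset] or [decay_trace].
#' @param path output path.
#' @param sep `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, sep = ",") {
  df <- if (inherits(x, "spectrum")) {
    data.frame(wavelength_nm = x$wavelength, intensity = x$intensity)
  } else if (inherits(x, "decay_trace")) {
    d <- data.frame(time_ps = x$time, counts = x$counts)
    if (!is.null(x$irf)) d$irf <- x$irf
    d
  } else if (inherits(x, "binding_dataset")) {
    data.frame(
      ligand_total_nM = rep(x$total_ligand, times = ncol(x$signal)),
      signal = as.vector(x$signal),
      replicate = rep(seq_len(ncol(x$signal)), each = length(x$total_ligand)))
  } else {
    lcophys_abort("invalid_parameter",
                  "write_table supports spectrum, decay_trace and binding_dataset")
  }
  utils::write.table(format(df, digits = 17, scientific = NA,
                            trim = TRUE),
                     path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---- structured result files --------------------------------------------

flatten_record <- function(x, prefix = "") {
  out <- list()
  for (nm in names(x)) {
    v <- x[[nm]]
    key <- if (prefix == "") nm else paste0(prefix, ".", nm)
    if (is.list(v) && !is.null(names(v))) {
      out <- c(out, flatten_record(v, key))
    } else if (is.numeric(v) || is.logical(v) || is.character(v)) {
      if (length(v) > 1 && is.null(names(v))) names(v) <- seq_along(v)
      if (length(v) > 1) {
        for (i in seq_along(v)) out[[paste0(key, ".", names(v)[i])]] <- v[[i]]
      } else if (length(v) == 1) {
        out[[key]] <- v
      }
    }
  }
  out
}

#' Write a fit/summary record to a structured text file
#'
#' Serializes any of the package's result objects (decay fits, Gaussian
#' fits, quantum-yield results, binding fits, ...) as deterministic
#' `key: value` lines — human-readable, machine-parseable, byte-identical
#' across identical runs. Numeric values are written with 17 significant
#' digits so a re-read reproduces them exactly; the record class and
#' package version are always included.
#'
#' @param record a (possibly nested) named list or fit object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_result <- function(record, path) {
  check_that(is.list(record), "invalid_parameter",
             "`record` must be a (named) list or fit object")
  flat <- flatten_record(unclass(record))
  flat <- flat[order(names(flat))]
  lines <- c(
    paste0("record_class: ", paste(class(record), collapse = ",")),
    paste0("software: lcophys ",
           as.character(utils::packageVersion("lcophys"))),
    vapply(names(flat), function(k) {
      v <- flat[[k]]
      vs <- if (is.numeric(v)) fmt_num(v) else as.character(v)
      paste0(k, ": ", vs)
    }, character(1))
  )
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE,
                 warning = function(w) FALSE)
  check_that(ok, "io", sprintf("cannot write result file: %s", path))
  invisible(path)
}

#' Read a structured result file back into a named list
#'
#' @param path a file written by [write_result].
#' @return named list; numeric-looking values are converted to numeric.
#' @export
read_result <- function(path) {
  check_that(file.exists(path), "io", sprintf("file not found: %s", path))
  lines <- readLines(path)
  out <- list()
  for (ln in lines) {
    i <- regexpr(": ", ln, fixed = TRUE)
    if (i < 0) next
    key <- substr(ln, 1, i - 1)
    val <- substr(ln, i + 2, nchar(ln))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num
                  else if (val %in% c("TRUE", "FALSE")) as.logical(val)
                  else val
  }
  out
}

## ---- FLIM rasters --------------------------------------------------------

TIFF_SCALE <- 65535

#' Write a FLIM image as a multi-frame TIFF plus YAML sidecar
#'
#' Each TIFF frame is one time channel. Frames are stored 16-bit with
#' counts scaled by 1/65535, so integer photon counts up to 65535 per
#' channel round-trip exactly; the channel grid, scale and IRF live in a
#' YAML sidecar at `<path>.yaml`.
#'
#' @param img a [flim_image].
#' @param path TIFF output path.
#' @return `path`, invisibly.
#' @export
write_flim_tiff <- function(img, path) {
  check_that(inherits(img, "flim_image"), "invalid_parameter",
             "`img` must be a flim_image")
  check_that(max(img$counts) <= TIFF_SCALE, "invalid_parameter",
             "per-channel counts exceed the 16-bit storage range")
  d <- dim(img$counts)
  frames <- lapply(seq_len(d[3]),
                   function(k) img$counts[, , k] / TIFF_SCALE)
  tiff::writeTIFF(frames, path, bits.per.sample = 16L, reduce = FALSE)
  irf_out <- NULL
  if (!is.null(img$irf)) {
    ## flush the far Gaussian tail: denormal doubles do not survive YAML
    irf_out <- img$irf
    irf_out[irf_out < 1e-12 * max(irf_out)] <- 0
  }
  meta <- list(n_channels = d[3], channel_width_ps = img$channel_width,
               height = d[1], width = d[2], scale = TIFF_SCALE,
               irf = irf_out)
  yaml::write_yaml(meta, paste0(path, ".yaml"), precision = 15L)
  invisible(path)
}

#' Read a FLIM image written by [write_flim_tiff]
#'
#' @param path TIFF path; the `<path>.yaml` sidecar must be present.
#' @return a [flim_image].
#' @export
read_flim_tiff <- function(path) {
  side <- paste0(path, ".yaml")
  check_that(file.exists(path) && file.exists(side), "io",
             "FLIM TIFF or its .yaml sidecar is missing")
  meta <- yaml::read_yaml(side)
  frames <- tiff::readTIFF(path, all = TRUE)
  counts <- array(0, dim = c(meta$height, meta$width, meta$n_channels))
  for (k in seq_len(meta$n_channels)) {
    counts[, , k] <- round(frames[[k]] * meta$scale)
  }
  flim_image(counts, meta$channel_width_ps,
             irf = if (!is.null(meta$irf)) {
               v <- suppressWarnings(as.numeric(unlist(meta$irf)))
               v[is.na(v)] <- 0
               v
             })
}

#' Write / read a binary ROI mask as single-frame TIFF
#'
#' @param mask logical (or 0/1) matrix.
#' @param path TIFF path.
#' @return `path` (write) or a logical matrix (read).
#' @export
write_roi_mask <- function(mask, path) {
  m <- matrix(as.numeric(as.logical(mask)), nrow(mask), ncol(mask))
  tiff::writeTIFF(m, path, bits.per.sample = 8L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_roi_mask
#' @export
read_roi_mask <- function(path) {
  check_that(file.exists(path), "io", sprintf("file not found: %s", path))
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  m > 0.5
}
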