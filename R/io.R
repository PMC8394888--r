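# Readers and writers: cohort CSV schema, JSON/CSV reports, lossless PNG
# image I/O (JPEG is rejected for analysis inputs because chroma subsampling
# corrupts the a* plane).

cohort_schema <- c("animal_id", "group", "week", "eta_collagen",
                   "eta_porphyrins", "status")

#' Read a cohort table from CSV
#'
#' Schema: `animal_id,group,week,eta_collagen,eta_porphyrins,status`.
#' Censored rows (status `withdrawn`/`dead`, `NA` values) are preserved.
#'
#' @param path CSV path.
#' @return typed cohort data.frame.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("read_cohort_csv: no such file: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(cohort_schema, names(df))
  if (length(missing) > 0)
    stop(sprintf("read_cohort_csv: missing column(s): %s",
                 paste(missing, collapse = ", ")))
  for (col in c("week", "eta_collagen", "eta_porphyrins")) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      if (any(!is.na(v) & v != "" & is.na(num)))
        stop(sprintf("read_cohort_csv: non-numeric values in column '%s'", col))
      df[[col]] <- num
    }
  }
  key <- paste(df$animal_id, df$week)
  if (anyDuplicated(key))
    stop(sprintf("read_cohort_csv: duplicate (animal_id, week) key: %s",
                 key[which(duplicated(key))[1]]))
  df[, cohort_schema]
}

#' Write a cohort table to CSV
#'
#' @param cohort cohort data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  missing <- setdiff(cohort_schema, names(cohort))
  if (length(missing) > 0)
    stop(sprintf("write_cohort_csv: missing column(s): %s",
                 paste(missing, collapse = ", ")))
  utils::write.csv(cohort[, cohort_schema], path, row.names = FALSE)
  invisible(path)
}

#' Write an analysis report
#'
#' JSON (default) keeps the input's key order and unboxes scalars; numbers
#' are written at a fixed 10 significant digits so repeated runs diff
#' cleanly. CSV requires a data.frame.
#'
#' @param results named list (JSON) or data.frame (CSV).
#' @param path output path.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(results, path, auto_unbox = TRUE, digits = I(10),
                         pretty = TRUE, null = "null")
  } else {
    if (!is.data.frame(results))
      stop("write_report: CSV format requires a data.frame")
    utils::write.csv(results, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read an 8-bit RGB image from PNG
#'
#' Returns a numeric array \[rows, cols, 3\] on the 0..255 scale. Non-PNG
#' files (notably JPEG) are rejected: lossy chroma subsampling corrupts the
#' a* plane the erythema index is computed from.
#'
#' @param path PNG path.
#' @return 8-bit RGB image array.
#' @export
read_image_png <- function(path) {
  magic <- readBin(path, "raw", n = 8)
  png_magic <- as.raw(c(0x89, 0x50, 0x4E, 0x47, 0x0D, 0x0A, 0x1A, 0x0A))
  if (length(magic) < 8 || !identical(magic, png_magic)) {
    if (length(magic) >= 2 && identical(magic[1:2], as.raw(c(0xFF, 0xD8))))
      stop("read_image_png: JPEG input rejected; chroma subsampling corrupts a*. Use lossless PNG.")
    stop("read_image_png: not a PNG file")
  }
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] == 4) img <- img[, , 1:3, drop = FALSE]
  round(img * 255)
}

#' Write an 8-bit RGB image to PNG
#'
#' @param img 8-bit RGB image array (0..255).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(img, path) {
  check_image8(img)
  png::writePNG(img / 255, path)
  invisible(path)
}
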