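#' Read a feature table from CSV/TSV
#'
#' Delimiter follows the file extension (`.tsv`/`.tab` are tab-separated,
#' anything else comma-separated). Duplicate header names and empty tables
#' are rejected with informative errors; column types are inferred.
#'
#' @param path Path to the table.
#' @return A tibble.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  delim <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  hdr <- strsplit(readLines(path, n = 1L), delim, fixed = TRUE)[[1]]
  hdr <- gsub('^"|"$', "", hdr)
  dup <- unique(hdr[duplicated(hdr)])
  if (length(dup)) {
    stop("Duplicate column name(s) in ", path, ": ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  out <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (nrow(out) == 0) stop("Table is empty: ", path, call. = FALSE)
  out
}

#' Write a feature table to CSV/TSV
#'
#' @param data Data frame.
#' @param path Output path; extension chooses the delimiter as in
#'   [read_feature_table()].
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(data, path) {
  if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) {
    readr::write_tsv(data, path)
  } else {
    readr::write_csv(data, path)
  }
  invisible(path)
}

#' Read a single-channel image
#'
#' TIFF or PNG via EBImage; multi-frame images are reduced to their first
#' frame, colour images to the luminance mean.
#'
#' @param path Image path.
#' @return Numeric intensity matrix (rows = image rows).
#' @export
read_channel <- function(path) {
  if (!file.exists(path)) stop("Image not found: ", path, call. = FALSE)
  img <- EBImage::readImage(path)
  d <- dim(img)
  if (length(d) == 3) img <- img[, , 1]
  # EBImage stores x (columns) in dim 1; transpose to rows x cols
  t(as_img_matrix(img))
}

#' Write a single-channel image
#'
#' @param mat Numeric matrix (rows = image rows); values are rescaled to
#'   \[0,1\] for storage.
#' @param path Output path (`.tif` or `.png`).
#' @return `path`, invisibly.
#' @export
write_channel <- function(mat, path) {
  mat <- as_img_matrix(mat)
  rng <- range(mat)
  if (diff(rng) > 0) mat <- (mat - rng[1]) / diff(rng)
  EBImage::writeImage(EBImage::Image(t(mat)), path)
  invisible(path)
}
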