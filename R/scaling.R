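#' Jointly scale dimensional features to the 0.1-1 interval
#'
#' Lengths and widths of the plotted ellipses are scaled *together*: the
#' minimum over all pooled dimensional values maps to 0.1 and the maximum to
#' 1, via `v' = (v - min) / range * 0.9 + 0.1`. Pooling preserves aspect
#' ratios between dimensions (a cell twice as long as it is wide stays so
#' after scaling, up to the affine map), and the 0.1 floor keeps the smallest
#' object visible. All other bound features are scaled per column to \[0,1\]
#' by [scale_unit()].
#'
#' If all pooled values are equal the affine map is undefined; every value is
#' then mapped to the interval midpoint 0.55.
#'
#' @param data A data frame of raw features.
#' @param cols Character vector of dimensional column names (lengths/widths).
#' @return `data` with the dimensional columns replaced by their scaled
#'   values, as a tibble.
#' @examples
#' scale_dimensional(data.frame(l = c(2, 10), w = c(4, 5)), c("l", "w"))
#' @export
scale_dimensional <- function(data, cols) {
  stopifnot(is.data.frame(data), length(cols) >= 1)
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    stop("Dimensional column(s) not in data: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  pooled <- unlist(data[cols], use.names = FALSE)
  if (!is.numeric(pooled) || any(!is.finite(pooled))) {
    stop("Dimensional columns must be finite numeric.", call. = FALSE)
  }
  lo <- min(pooled); rng <- max(pooled) - lo
  out <- tibble::as_tibble(data)
  for (cl in cols) {
    out[[cl]] <- if (rng == 0) rep(0.55, nrow(out))
                 else (out[[cl]] - lo) / rng * 0.9 + 0.1
  }
  out
}

#' Min-max scale a vector to the unit interval
#'
#' @param x Finite numeric vector.
#' @return `(x - min) / range`; if all values are equal, all 0.5.
#' @examples
#' scale_unit(c(0, 5, 10))
#' @export
scale_unit <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("Input must be finite numeric.", call. = FALSE)
  }
  lo <- min(x); rng <- max(x) - lo
  if (rng == 0) rep(0.5, length(x)) else (x - lo) / rng
}

#' Scale a feature table for plotting
#'
#' Applies the two plotting normalizations: dimensional features (the
#' length/width columns bound to ellipse-dimension elements) are jointly
#' scaled to \[0.1, 1\] with [scale_dimensional()]; every other bound feature
#' is min-max scaled to \[0, 1\] with [scale_unit()]. Count-bound columns
#' (sub-circle counts) are left on their integer scale. Values supplied
#' already outside \[0,1\] in a table marked pre-scaled are clipped with a
#' warning rather than rejected.
#'
#' @param data A data frame of raw features (one row per glyph).
#' @param spec A `glyph_spec`; only bound columns are scaled.
#' @return A tibble with scaled bound columns and attribute
#'   `scaling = "scaled"`. Re-scaling an already scaled table is an error.
#' @export
scale_features <- function(data, spec) {
  stopifnot(is.data.frame(data), inherits(spec, "glyph_spec"))
  if (identical(attr(data, "scaling"), "scaled")) {
    stop("Table is already scaled; refusing to scale twice.", call. = FALSE)
  }
  bound <- spec$bindings$feature
  missing <- setdiff(bound, names(data))
  if (length(missing)) {
    stop("Bound feature(s) missing from data: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (cl in bound) {
    if (!is.numeric(data[[cl]])) {
      stop("Bound column is not numeric: ", cl, call. = FALSE)
    }
    if (anyNA(data[[cl]])) {
      stop("Bound column contains missing values: ", cl, call. = FALSE)
    }
  }
  out <- tibble::as_tibble(data)
  dims <- dimensional_features(spec)
  if (length(dims)) out <- scale_dimensional(out, dims)
  unit_cols <- setdiff(bound[spec$registry$domain == "unit"], dims)
  for (cl in unit_cols) out[[cl]] <- scale_unit(out[[cl]])
  count_cols <- bound[spec$registry$domain == "count"]
  for (cl in count_cols) out[[cl]] <- as.integer(round(out[[cl]]))
  attr(out, "scaling") <- "scaled"
  out
}

# Clip a scaled value into [lo, hi], warning once if anything was outside.
clip_unit <- function(x, lo = 0, hi = 1, what = "value") {
  if (any(x < lo - 1e-12 | x > hi + 1e-12)) {
    warning("Clipping ", what, " outside [", lo, ", ", hi, "].", call. = FALSE)
  }
  pmin(pmax(x, lo), hi)
}
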