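# Brightness normalization: per-nucleus modal-intensity (BI) correction and
# between-group median offsets.

#' Brightness index of a nucleus
#'
#' The brightness index (BI) is the modal intensity of the inside-mask pixels:
#' the grey level with the highest pixel count. Ties are broken toward the
#' lower intensity. The full 256-bin histogram is returned alongside.
#'
#' @param nucleus a [nucleus_image()].
#' @return object of class `"chp_brightness"`: list with `bi` (integer in
#'   0..255) and `histogram` (integer vector of 256 counts named `"0"`..
#'   `"255"`, summing to the number of inside-mask pixels).
#' @export
brightness_index <- function(nucleus) {
  assert_nucleus(nucleus)
  v <- nucleus$intensity[nucleus$mask]
  counts <- tabulate(v + 1L, nbins = 256L)
  names(counts) <- 0:255
  structure(list(
    bi = as.integer(which.max(counts) - 1L),  # which.max takes the first tie
    histogram = counts
  ), class = "chp_brightness")
}

#' @export
print.chp_brightness <- function(x, ...) {
  cat(sprintf("brightness index (modal intensity): %d (%d of %d pixels)\n",
              x$bi, x$histogram[x$bi + 1L], sum(x$histogram)))
  invisible(x)
}

#' Adjust a nucleus to a target brightness index
#'
#' Shifts every inside-mask intensity by `target - BI` so the modal intensity
#' becomes `target` (127 by default, the midpoint grey level used as the
#' common reference). The shift is additive with clamping to 0..255;
#' outside-mask pixels are untouched. When no pixel clamps, the operation is
#' idempotent and removes any global additive brightness difference between
#' nuclei.
#'
#' @param nucleus a [nucleus_image()].
#' @param target target brightness index, integer in 0..255; default 127.
#' @return a new [nucleus_image()] with shifted intensities.
#' @export
bi_correct <- function(nucleus, target = 127) {
  assert_nucleus(nucleus)
  if (length(target) != 1L || is.na(target) || target < 0 || target > 255 ||
      target != round(target)) {
    stop("`target` must be a single integer in 0..255", call. = FALSE)
  }
  shift <- as.integer(target) - brightness_index(nucleus)$bi
  out <- nucleus$intensity
  inside <- nucleus$mask
  out[inside] <- pmin(255L, pmax(0L, out[inside] + shift))
  nucleus_image(out, nucleus$mask)
}

#' Median offset between two groups of values
#'
#' The additive constant that aligns the median of `target_values` with that
#' of `reference_values`: `median(reference) - median(target)`. Used to
#' normalize a feature (HV, b1MAX) measured under darker imaging conditions
#' onto the scale of a reference group; the caller adds the returned offset to
#' every target value. The median of an even-sized group is the mean of its
#' two central values.
#'
#' @param reference_values,target_values non-empty numeric vectors.
#' @return single number; antisymmetric in its arguments.
#' @examples
#' median_offset(c(40, 50, 60), c(31, 41, 51))  # 9
#' @export
median_offset <- function(reference_values, target_values) {
  if (length(reference_values) == 0L || length(target_values) == 0L) {
    stop("both value vectors must be non-empty", call. = FALSE)
  }
  if (anyNA(reference_values) || anyNA(target_values)) {
    stop("value vectors must not contain NA", call. = FALSE)
  }
  median(reference_values) - median(target_values)
}
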