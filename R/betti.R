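# Digital-topology primitives on 2D binary images.
#
# Fixed convention (Jordan-curve consistent, not configurable for Betti
# numbers): foreground is 8-connected, background is 4-connected. A hole is a
# background component with no 4-connected path to the image border, i.e. a
# background region fully enclosed by foreground.

#' Coerce to a binary image matrix
#'
#' Accepts a logical matrix, or a numeric/integer matrix whose entries are 0/1
#' (nonzero = foreground). Used by all binary-image operations.
#'
#' @param img matrix-like binary image; `TRUE`/nonzero = foreground.
#' @return logical matrix.
#' @keywords internal
as_binary <- function(img) {
  if (!is.matrix(img)) stop("`img` must be a matrix", call. = FALSE)
  if (nrow(img) < 1L || ncol(img) < 1L) {
    stop("`img` must have at least one row and one column", call. = FALSE)
  }
  if (is.logical(img)) {
    if (anyNA(img)) stop("`img` must not contain NA", call. = FALSE)
    return(img)
  }
  if (is.numeric(img)) {
    if (anyNA(img)) stop("`img` must not contain NA", call. = FALSE)
    return(img != 0)
  }
  stop("`img` must be a logical or numeric matrix", call. = FALSE)
}

#' Count connected components of a binary image
#'
#' Counts maximal connected sets of pixels of the requested phase under 4- or
#' 8-connectivity.
#'
#' @param img binary image (logical or 0/1 matrix); `TRUE` = foreground.
#' @param which phase to count, `"foreground"` or `"background"`.
#' @param connectivity `4` (edge-adjacent) or `8` (edge- or corner-adjacent).
#' @return non-negative integer count.
#' @examples
#' m <- matrix(FALSE, 5, 5); m[2, 2] <- m[3, 3] <- TRUE
#' count_components(m, connectivity = 8)  # diagonal pixels touch: 1
#' count_components(m, connectivity = 4)  # they do not: 2
#' @export
count_components <- function(img, which = c("foreground", "background"),
                             connectivity = 8) {
  img <- as_binary(img)
  which <- match.arg(which)
  if (!connectivity %in% c(4, 8)) {
    stop("`connectivity` must be 4 or 8", call. = FALSE)
  }
  if (which == "background") img <- !img
  .cpp_count_components(img, as.integer(connectivity))
}

#' Betti numbers of a binary image
#'
#' Computes `b0`, the number of 8-connected foreground components, and `b1`,
#' the number of holes: 4-connected background components fully enclosed by
#' foreground (no path to the image border). The complementary 8/4
#' connectivity pairing avoids the checkerboard paradox, so every hole is
#' counted exactly once.
#'
#' @inheritParams count_components
#' @return named integer vector `c(b0 = , b1 = )`.
#' @examples
#' ring <- matrix(FALSE, 5, 5); ring[1, ] <- ring[5, ] <- ring[, 1] <- ring[, 5] <- TRUE
#' betti_numbers(ring)  # annulus: b0 = 1, b1 = 1
#' @export
betti_numbers <- function(img) {
  .cpp_betti(as_binary(img))
}

#' Euler characteristic of a binary image by bit-quad counting
#'
#' Euler number of the 8-connected foreground computed from local 2-by-2 pixel
#' patterns (Gray's bit-quad formula), an implementation independent of
#' component counting. Satisfies `euler_number(img) == b0 - b1` from
#' [betti_numbers()] on every image.
#'
#' @inheritParams count_components
#' @return integer Euler characteristic (may be negative).
#' @export
euler_number <- function(img) {
  img <- as_binary(img)
  # pad with one background ring so every foreground pixel sits in 4 quads
  p <- matrix(FALSE, nrow(img) + 2L, ncol(img) + 2L)
  p[2:(nrow(img) + 1L), 2:(ncol(img) + 1L)] <- img
  nr <- nrow(p); nc <- ncol(p)
  a <- p[-nr, -nc]; b <- p[-nr, -1]; cc <- p[-1, -nc]; d <- p[-1, -1]
  s <- a + b + cc + d
  q1 <- sum(s == 1L)
  q3 <- sum(s == 3L)
  qd <- sum(s == 2L & ((a & d) | (b & cc)))
  as.integer((q1 - q3 - 2L * qd) / 4L)
}
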