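# Image and table IO, and run configuration.

FEATURE_COLUMNS <- c("nucleus_id", "label", "b1max", "hv", "bi", "ns", "ns2",
                     "density", "predicted")

#' Run configuration
#'
#' Collects the knobs of the pipeline with their defaults: hole threshold 5
#' (HV definition), BI target 127, b1MAX cutoff 25, density cutoff 0.05, no
#' HV cutoff, luma (ITU-R BT.601) grayscale conversion, no physical pixel
#' calibration. A flat `key = value` config file can override any of them;
#' command-line flags override the file.
#'
#' @param hole_threshold hole count defining HV.
#' @param bi_target brightness-index target for [bi_correct()].
#' @param b1max_cutoff,density_cutoff,hv_cutoff see [chp_rule()].
#' @param rgb_to_gray `"luma601"`, `"mean"`, `"channel:r"`, `"channel:g"` or
#'   `"channel:b"`.
#' @param um_per_pixel optional physical calibration; when set, `ns` is also
#'   reported in micrometres by the CLI.
#' @param seed default RNG seed for simulation commands.
#' @return list of class `"chp_config"`.
#' @export
chp_config <- function(hole_threshold = 5, bi_target = 127,
                       b1max_cutoff = 25, density_cutoff = 0.05,
                       hv_cutoff = NULL, rgb_to_gray = "luma601",
                       um_per_pixel = NULL, seed = 1) {
  ok_gray <- c("luma601", "mean", "channel:r", "channel:g", "channel:b")
  if (!rgb_to_gray %in% ok_gray) {
    stop("`rgb_to_gray` must be one of ", paste(ok_gray, collapse = ", "),
         call. = FALSE)
  }
  structure(list(hole_threshold = hole_threshold, bi_target = bi_target,
                 b1max_cutoff = b1max_cutoff, density_cutoff = density_cutoff,
                 hv_cutoff = hv_cutoff, rgb_to_gray = rgb_to_gray,
                 um_per_pixel = um_per_pixel, seed = seed),
            class = "chp_config")
}

#' Read a flat key = value configuration file
#'
#' INI-style flat keys, one `key = value` per line; `#` starts a comment.
#' Unknown keys are rejected. Values are parsed as numbers where the
#' corresponding default is numeric.
#'
#' @param path file path.
#' @param base configuration to override; default [chp_config()].
#' @return a `"chp_config"`.
#' @export
read_config <- function(path, base = chp_config()) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  numeric_keys <- c("hole_threshold", "bi_target", "b1max_cutoff",
                    "density_cutoff", "hv_cutoff", "um_per_pixel", "seed")
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      stop("config line is not `key = value`: ", ln, call. = FALSE)
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (!key %in% names(base)) stop("unknown config key: ", key, call. = FALSE)
    base[[key]] <- if (key %in% numeric_keys) as.numeric(val) else val
  }
  base
}

# round half away from zero, the conventional luma rounding
round_half_up <- function(x) floor(x + 0.5)

rgb_to_gray_matrix <- function(arr, mode) {
  r <- arr[, , 1]; g <- arr[, , 2]; b <- arr[, , 3]
  gray01 <- switch(sub(":.*$", "", mode),
    luma601 = 0.299 * r + 0.587 * g + 0.114 * b,
    mean = (r + g + b) / 3,
    channel = switch(sub("^channel:", "", mode), r = r, g = g, b = b)
  )
  matrix(as.integer(round_half_up(gray01 * 255)), nrow(r), ncol(r))
}

read_image_8bit <- function(path, mode) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    arr <- png::readPNG(path, info = TRUE)
    depth <- attr(arr, "info")$bit.depth
  } else if (ext %in% c("tif", "tiff")) {
    arr <- tiff::readTIFF(path, info = TRUE)
    depth <- attr(arr, "bits.per.sample")
    if (is.null(depth)) depth <- 8L
  } else {
    stop("unsupported image format: ", path, " (use PNG or TIFF)",
         call. = FALSE)
  }
  if (!is.null(depth) && length(depth) && max(depth) > 8) {
    warning("16-bit image rescaled to 8-bit: ", path, call. = FALSE)
  }
  if (length(dim(arr)) == 3L) {
    if (dim(arr)[3] == 2L) {          # gray + alpha: drop alpha
      arr <- arr[, , 1]
    } else {
      return(rgb_to_gray_matrix(arr[, , 1:3, drop = FALSE], mode))
    }
  }
  matrix(as.integer(round_half_up(arr * 255)), nrow(arr), ncol(arr))
}

#' Read a nucleus image and its mask
#'
#' Reads a PNG or TIFF photomicrograph plus a mask image of identical
#' dimensions (any nonzero mask pixel = inside the nucleus). RGB images are
#' converted to 8-bit grey per `config$rgb_to_gray` (default ITU-R BT.601
#' luma with round-half-up); 16-bit inputs are rescaled to 8-bit with a
#' warning.
#'
#' @param image_path,mask_path file paths.
#' @param config a [chp_config()].
#' @return a [nucleus_image()].
#' @export
read_nucleus <- function(image_path, mask_path, config = chp_config()) {
  intensity <- read_image_8bit(image_path, config$rgb_to_gray)
  mask <- read_image_8bit(mask_path, config$rgb_to_gray)
  if (!identical(dim(mask), dim(intensity))) {
    stop(sprintf("dimension mismatch: image is %dx%d but mask is %dx%d",
                 nrow(intensity), ncol(intensity), nrow(mask), ncol(mask)),
         call. = FALSE)
  }
  if (!any(mask != 0)) stop("mask has no inside pixel", call. = FALSE)
  nucleus_image(intensity, mask != 0)
}

#' Write a nucleus image (and mask) as PNG
#'
#' @param nucleus a [nucleus_image()].
#' @param image_path output PNG for the intensities.
#' @param mask_path optional output PNG for the mask (white = inside).
#' @return `image_path`, invisibly.
#' @export
write_nucleus <- function(nucleus, image_path, mask_path = NULL) {
  assert_nucleus(nucleus)
  png::writePNG(nucleus$intensity / 255, image_path)
  if (!is.null(mask_path)) {
    png::writePNG(matrix(as.numeric(nucleus$mask), nrow(nucleus$mask)),
                  mask_path)
  }
  invisible(image_path)
}

#' Write and read feature tables
#'
#' CSV with the fixed header
#' `nucleus_id,label,b1max,hv,bi,ns,ns2,density,predicted`. An absent HV (and
#' an absent label or prediction) is written as an empty field, never as text
#' `NA`/`NaN`. `read_features(write_features(x))` restores `x`.
#'
#' @param records feature `data.frame` (columns as from [nucleus_features()];
#'   a missing `predicted` column is written empty).
#' @param path CSV path.
#' @return `path` invisibly for the writer; a `data.frame` for the reader.
#' @export
write_features <- function(records, path) {
  if (NROW(records) == 0L) stop("`records` must be non-empty", call. = FALSE)
  records <- as.data.frame(records)
  if (!"predicted" %in% names(records)) records$predicted <- NA_character_
  missing_cols <- setdiff(FEATURE_COLUMNS, names(records))
  if (length(missing_cols)) {
    stop("records lack columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- records[, FEATURE_COLUMNS]
  write.table(out, path, sep = ",", na = "", row.names = FALSE,
              col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""),
                 colClasses = c(nucleus_id = "character", label = "character",
                                predicted = "character"))
  if (!identical(names(df), FEATURE_COLUMNS)) {
    stop("unexpected feature CSV header in ", path, call. = FALSE)
  }
  for (col in c("label", "predicted")) {
    bad <- !is.na(df[[col]]) & !df[[col]] %in% CHP_LABELS
    if (any(bad)) {
      stop("unknown label value(s) in ", col, ": ",
           paste(unique(df[[col]][bad]), collapse = ", "), call. = FALSE)
    }
  }
  df$hv <- as.integer(df$hv)
  df$b1max <- as.integer(df$b1max)
  df$bi <- as.integer(df$bi)
  df
}

#' Read a labels CSV
#'
#' Two columns `nucleus_id,label`; returns a named character vector mapping
#' id to label. Unknown label values are rejected.
#'
#' @param path CSV path.
#' @return named character vector.
#' @export
read_labels <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("nucleus_id", "label") %in% names(df))) {
    stop("labels CSV needs columns nucleus_id,label", call. = FALSE)
  }
  bad <- !df$label %in% CHP_LABELS
  if (any(bad)) {
    stop("unknown label value(s): ", paste(unique(df$label[bad]), collapse = ", "),
         call. = FALSE)
  }
  stats::setNames(df$label, df$nucleus_id)
}

#' Dump a homology profile as CSV
#'
#' Writes the 256-row table `t,b1` for audit or plotting.
#'
#' @param profile a `"chp"` object.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  if (!inherits(profile, "chp")) stop("`profile` must be a chp object", call. = FALSE)
  write.table(data.frame(t = 0:255, b1 = as.integer(profile$b1)), path,
              sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
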