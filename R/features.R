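# Per-nucleus geometric features, the cutoff classifier, and cutoff
# evaluation.

CHP_LABELS <- c("squamous", "adeno", "small_cell", "non_cancerous")

#' Nucleus diagonal length (ns)
#'
#' Length of the diagonal of the tight bounding box of the mask, in pixels:
#' `sqrt(w^2 + h^2)` where `w` and `h` are the pixel counts of the bounding
#' box. Its square, ns², serves as an approximate nucleus area. A single
#' pixel (1 x 1 box) gives `sqrt(2)`.
#'
#' @param mask logical matrix (`TRUE` = inside the nucleus), or a
#'   [nucleus_image()].
#' @return positive number, pixels.
#' @examples
#' m <- matrix(FALSE, 10, 10); m[3:5, 2:5] <- TRUE  # 3 x 4 box
#' ns_diagonal(m)  # 5
#' @export
ns_diagonal <- function(mask) {
  if (is_nucleus_image(mask)) mask <- mask$mask
  mask <- as_binary(mask)
  if (!any(mask)) stop("`mask` has no inside pixel", call. = FALSE)
  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  h <- rows[2] - rows[1] + 1
  w <- cols[2] - cols[1] + 1
  sqrt(w^2 + h^2)
}

#' Chromatin density
#'
#' Holes per squared pixel: `b1max / ns^2`. Higher in adenocarcinoma (fine
#' granular chromatin, many small holes) than in squamous cell carcinoma.
#' Note the value scales with image resolution: upsampling a nucleus by a
#' factor k leaves b1MAX unchanged but divides the density by k², so a cutoff
#' is only meaningful at a fixed magnification and camera resolution.
#'
#' @param b1max non-negative hole-count maximum (see [b1max()]).
#' @param ns positive diagonal length in pixels (see [ns_diagonal()]).
#' @return non-negative number, holes per pixel².
#' @export
chromatin_density <- function(b1max, ns) {
  if (any(ns <= 0)) stop("`ns` must be positive", call. = FALSE)
  if (any(b1max < 0)) stop("`b1max` must be non-negative", call. = FALSE)
  b1max / ns^2
}

#' Per-nucleus feature record
#'
#' Runs the full single-nucleus pipeline — homology profile, brightness
#' index, bounding-box diagonal — and assembles one feature row.
#'
#' @param nucleus a [nucleus_image()].
#' @param nucleus_id identifier string.
#' @param label optional class label, one of `"squamous"`, `"adeno"`,
#'   `"small_cell"`, `"non_cancerous"`; `NA` when unknown.
#' @param hole_threshold hole count defining HV; default 5.
#' @param bi_target when non-`NULL`, apply [bi_correct()] to this target
#'   before profiling (the intensities feeding the BI itself are always the
#'   raw ones).
#' @return one-row `data.frame` with columns `nucleus_id`, `label`, `b1max`,
#'   `hv`, `bi`, `ns`, `ns2`, `density`.
#' @export
nucleus_features <- function(nucleus, nucleus_id = "nucleus",
                             label = NA_character_, hole_threshold = 5,
                             bi_target = NULL) {
  assert_nucleus(nucleus)
  if (!is.na(label) && !label %in% CHP_LABELS) {
    stop(sprintf("unknown label %s; expected one of %s", dQuote(label),
                 paste(CHP_LABELS, collapse = ", ")), call. = FALSE)
  }
  bi <- brightness_index(nucleus)$bi
  profiled <- if (is.null(bi_target)) nucleus else bi_correct(nucleus, bi_target)
  prof <- chp(profiled, hole_threshold = hole_threshold)
  ns <- ns_diagonal(nucleus$mask)
  data.frame(
    nucleus_id = as.character(nucleus_id),
    label = label,
    b1max = prof$b1max,
    hv = prof$hv,
    bi = bi,
    ns = ns,
    ns2 = ns^2,
    density = chromatin_density(prof$b1max, ns),
    stringsAsFactors = FALSE
  )
}

#' Histotype classification rule
#'
#' The cutoff hierarchy applied per nucleus:
#' \enumerate{
#'   \item optionally, `hv >= hv_cutoff` calls the nucleus `non_cancerous`
#'     (cancer nuclei have lower HV); this stage is off by default because no
#'     validated HV cutoff is established;
#'   \item `b1max < b1max_cutoff` calls it `small_cell`;
#'   \item otherwise `density >= density_cutoff` calls it `adeno`, else
#'     `squamous`.
#' }
#' Values equal to a cutoff fall on the `>=` side (non-small-cell, adeno).
#' The default cutoffs 25 (b1MAX) and 0.05 (density) are tied to the imaging
#' scale at which they were established; see [chromatin_density()].
#'
#' @param b1max_cutoff small-cell vs non-small-cell cutoff on b1MAX;
#'   default 25.
#' @param density_cutoff adeno vs squamous cutoff on b1MAX/ns²; default 0.05.
#' @param hv_cutoff optional cancer vs non-cancer cutoff on HV; `NULL`
#'   disables the stage.
#' @return object of class `"chp_rule"`.
#' @export
chp_rule <- function(b1max_cutoff = 25, density_cutoff = 0.05,
                     hv_cutoff = NULL) {
  if (b1max_cutoff <= 0 || density_cutoff <= 0) {
    stop("cutoffs must be strictly positive", call. = FALSE)
  }
  if (!is.null(hv_cutoff) && hv_cutoff <= 0) {
    stop("`hv_cutoff` must be strictly positive when set", call. = FALSE)
  }
  structure(list(b1max_cutoff = b1max_cutoff, density_cutoff = density_cutoff,
                 hv_cutoff = hv_cutoff), class = "chp_rule")
}

#' @export
print.chp_rule <- function(x, ...) {
  cat("Histotype cutoff rule:\n")
  if (!is.null(x$hv_cutoff)) {
    cat(sprintf("  HV >= %g                -> non_cancerous\n", x$hv_cutoff))
  }
  cat(sprintf("  b1MAX < %g              -> small_cell\n", x$b1max_cutoff))
  cat(sprintf("  density >= %g           -> adeno, else squamous\n",
              x$density_cutoff))
  invisible(x)
}

#' Classify nuclei by the cutoff hierarchy
#'
#' @param records `data.frame` of feature records (rows as produced by
#'   [nucleus_features()]; must contain `b1max` and `density`, plus `hv` when
#'   the rule's HV stage is enabled).
#' @param rule a [chp_rule()].
#' @return character vector of predicted classes, one per row.
#' @examples
#' classify_histotype(data.frame(b1max = c(20, 40, 40),
#'                               density = c(0.01, 0.08, 0.02)))
#' @export
classify_histotype <- function(records, rule = chp_rule()) {
  if (!inherits(rule, "chp_rule")) stop("`rule` must be a chp_rule", call. = FALSE)
  records <- as.data.frame(records)
  needed <- c("b1max", "density", if (!is.null(rule$hv_cutoff)) "hv")
  for (f in needed) {
    if (!f %in% names(records) || anyNA(records[[f]])) {
      stop(sprintf("classification requires complete field `%s`", f),
           call. = FALSE)
    }
  }
  out <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    out[i] <- if (!is.null(rule$hv_cutoff) && r$hv >= rule$hv_cutoff) {
      "non_cancerous"
    } else if (r$b1max < rule$b1max_cutoff) {
      "small_cell"
    } else if (r$density >= rule$density_cutoff) {
      "adeno"
    } else {
      "squamous"
    }
  }
  out
}

#' Sensitivity and specificity of a single cutoff
#'
#' Evaluates a univariate cutoff against binary truth labels.
#' `positive_direction` states on which side of the cutoff the positive class
#' lies: `"high"` predicts positive when `value >= cutoff`, `"low"` when
#' `value < cutoff` (matching the rule convention that ties fall on the high
#' side).
#'
#' @param values numeric vector of feature values.
#' @param labels logical (or 0/1) vector of the same length; `TRUE` =
#'   positive class. Both classes must be present.
#' @param cutoff single number.
#' @param positive_direction `"high"` or `"low"`.
#' @return named list: `sensitivity` = TP/(TP+FN), `specificity` =
#'   TN/(TN+FP), `n_pos`, `n_neg`.
#' @export
evaluate_cutoff <- function(values, labels, cutoff,
                            positive_direction = c("high", "low")) {
  positive_direction <- match.arg(positive_direction)
  if (length(values) == 0L || length(values) != length(labels)) {
    stop("`values` and `labels` must be non-empty and of equal length",
         call. = FALSE)
  }
  labels <- as.logical(labels)
  if (anyNA(values) || anyNA(labels)) stop("NA in values or labels", call. = FALSE)
  if (all(labels) || !any(labels)) {
    stop("both label classes must be present", call. = FALSE)
  }
  pred <- if (positive_direction == "high") values >= cutoff else values < cutoff
  list(
    sensitivity = sum(pred & labels) / sum(labels),
    specificity = sum(!pred & !labels) / sum(!labels),
    n_pos = sum(labels),
    n_neg = sum(!labels)
  )
}
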