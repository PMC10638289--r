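# Synthetic nuclei: ring phantoms with analytically known homology profiles,
# and seeded class-parameterized chromatin textures.

# run expr under a temporary RNG state so generators are pure in `seed`
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Ring phantom with exact expected homology profile
#'
#' Draws dark annuli ("rings") on a bright elliptical nucleus so the homology
#' profile is known in closed form: at threshold `t < background_intensity`
#' the holes are exactly the interiors of the rings whose intensity is
#' `<= t`, so `b1(t)` equals the number of such rings; at
#' `t >= background_intensity` the whole mask is foreground and every hole
#' fills in. The expected b1MAX equals the number of rings.
#'
#' Rings are Euclidean annuli `r_inner <= d <= r_outer`. Validity demands
#' widths of at least 2 pixels (guaranteeing closed loops), pairwise-disjoint
#' annuli (not nested, not touching), ring intensities below the background,
#' and a non-empty interior for each ring.
#'
#' @param size side length of the square canvas, pixels.
#' @param rings `data.frame` with columns `cx`, `cy` (center, 1-based pixel
#'   coordinates: `cx` = column, `cy` = row), `r_inner`, `r_outer`,
#'   `intensity`. Zero rows give a flat phantom.
#' @param background_intensity grey level of the unstained nucleus interior;
#'   default 200.
#' @param hole_threshold passed through to the expected profile; default 5.
#' @return list with components `nucleus` (a [nucleus_image()] whose mask is
#'   the inscribed ellipse) and `expected` (a `"chp"` object holding the
#'   analytic profile).
#' @examples
#' ph <- ring_phantom(48, rings = data.frame(
#'   cx = c(16, 33), cy = c(24, 24), r_inner = 4, r_outer = 6,
#'   intensity = c(50, 80)))
#' ph$expected$b1max  # 2
#' @export
ring_phantom <- function(size, rings = NULL, background_intensity = 200,
                         hole_threshold = 5) {
  if (size < 8) stop("`size` must be at least 8 pixels", call. = FALSE)
  if (is.null(rings)) {
    rings <- data.frame(cx = numeric(), cy = numeric(), r_inner = numeric(),
                        r_outer = numeric(), intensity = numeric())
  }
  need <- c("cx", "cy", "r_inner", "r_outer", "intensity")
  if (!all(need %in% names(rings))) {
    stop("`rings` needs columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (nrow(rings) > 0) {
    if (any(rings$intensity < 0 | rings$intensity > 255 |
            rings$intensity != round(rings$intensity))) {
      stop("ring intensities must be integers in 0..255", call. = FALSE)
    }
    if (any(rings$intensity >= background_intensity)) {
      stop("ring intensities must be below `background_intensity` ",
           "(dark chromatin on a bright nucleus)", call. = FALSE)
    }
    if (any(rings$r_outer - rings$r_inner < 2)) {
      stop("ring widths must be at least 2 pixels", call. = FALSE)
    }
    if (any(rings$r_inner < 1.5)) {
      stop("`r_inner` must be at least 1.5 pixels", call. = FALSE)
    }
    if (nrow(rings) > 1) {
      for (i in seq_len(nrow(rings) - 1)) {
        for (j in (i + 1):nrow(rings)) {
          d <- sqrt((rings$cx[i] - rings$cx[j])^2 +
                    (rings$cy[i] - rings$cy[j])^2)
          if (d <= rings$r_outer[i] + rings$r_outer[j] + 1) {
            stop(sprintf("rings %d and %d overlap or touch", i, j),
                 call. = FALSE)
          }
        }
      }
    }
  }

  ctr <- (size + 1) / 2
  semi <- size / 2 - 1.5
  row_c <- matrix(seq_len(size), size, size)         # y
  col_c <- matrix(seq_len(size), size, size, byrow = TRUE)  # x
  mask <- ((row_c - ctr) / semi)^2 + ((col_c - ctr) / semi)^2 <= 1

  intensity <- matrix(as.integer(background_intensity), size, size)
  for (i in seq_len(nrow(rings))) {
    d <- sqrt((row_c - rings$cy[i])^2 + (col_c - rings$cx[i])^2)
    ann <- d >= rings$r_inner[i] & d <= rings$r_outer[i]
    if (any(ann & !mask)) {
      stop(sprintf("ring %d extends outside the elliptical mask", i),
           call. = FALSE)
    }
    if (!any(d < rings$r_inner[i])) {
      stop(sprintf("ring %d has an empty interior", i), call. = FALSE)
    }
    intensity[ann] <- as.integer(rings$intensity[i])
  }

  curve <- integer(256)
  for (t in 0:255) {
    curve[t + 1] <- if (t >= background_intensity) 0L else
      sum(rings$intensity <= t)
  }
  names(curve) <- 0:255
  expected <- structure(list(
    b1 = curve,
    b1max = max(curve),
    hv = first_reaching(curve, hole_threshold),
    hole_threshold = hole_threshold,
    n_inside = sum(mask)
  ), class = "chp")

  list(nucleus = nucleus_image(intensity, mask), expected = expected)
}

#' Texture class parameters
#'
#' Parameter bundle for [textured_nucleus()]. The three shipped presets (see
#' [chp_presets()]) caricature the chromatin patterns that distinguish lung
#' cancer histotypes: fine granular chromatin (adenocarcinoma-like), coarse
#' clumped chromatin (squamous-like) and densely packed hyperchromatic
#' chromatin (small-cell-like, where merging granules erase holes).
#'
#' @param class_name one of `"fine_granular"`, `"coarse"`, `"dense_packed"`,
#'   or any custom tag.
#' @param label histotype label attached to generated nuclei.
#' @param granule_count number of chromatin granules.
#' @param granule_radius length-2 range of granule radii, pixels.
#' @param granule_intensity length-2 range of granule grey levels.
#' @param background_intensity grey level of unstained nucleoplasm.
#' @param nucleus_radius semi-major axis of the elliptical nucleus, pixels
#'   (semi-minor axis is 0.85 of it).
#' @param noise_sd standard deviation of additive Gaussian intensity noise.
#' @param seed integer RNG seed.
#' @return list of class `"chp_texture_params"`.
#' @export
texture_params <- function(class_name, label = NA_character_,
                           granule_count, granule_radius, granule_intensity,
                           background_intensity, nucleus_radius,
                           noise_sd = 0, seed = 1) {
  p <- list(class_name = class_name, label = label,
            granule_count = as.integer(granule_count),
            granule_radius = as.numeric(granule_radius),
            granule_intensity = as.numeric(granule_intensity),
            background_intensity = as.numeric(background_intensity),
            nucleus_radius = as.numeric(nucleus_radius),
            noise_sd = as.numeric(noise_sd), seed = as.integer(seed))
  if (p$granule_count < 1) stop("`granule_count` must be positive", call. = FALSE)
  if (length(p$granule_radius) != 2 || any(p$granule_radius <= 0)) {
    stop("`granule_radius` must be a positive length-2 range", call. = FALSE)
  }
  if (length(p$granule_intensity) != 2 ||
      any(p$granule_intensity < 0 | p$granule_intensity > 255)) {
    stop("`granule_intensity` must be a length-2 range in 0..255", call. = FALSE)
  }
  if (p$background_intensity < 0 || p$background_intensity > 255) {
    stop("`background_intensity` must be in 0..255", call. = FALSE)
  }
  if (max(p$granule_radius) >= p$nucleus_radius) {
    stop("granule radius must be smaller than the nucleus radius", call. = FALSE)
  }
  if (p$noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  class(p) <- "chp_texture_params"
  p
}

#' Generate a textured synthetic nucleus
#'
#' Places dark chromatin granules (filled disks, darkest-wins on overlap) at
#' seeded uniform positions inside an elliptical nucleus, adds rounded and
#' clamped Gaussian noise (before masking), and returns the masked nucleus.
#' Holes arise from granule contact, as they do in stained chromatin, not
#' from explicit rings; use [ring_phantom()] when exact ground truth is
#' needed. Identical parameters and seed give a bit-identical image.
#'
#' @param params a [texture_params()] bundle.
#' @param seed optional seed overriding `params$seed`.
#' @return a [nucleus_image()].
#' @export
textured_nucleus <- function(params, seed = NULL) {
  if (!inherits(params, "chp_texture_params")) {
    stop("`params` must come from `texture_params()`", call. = FALSE)
  }
  if (!is.null(seed)) params$seed <- as.integer(seed)
  a <- params$nucleus_radius          # semi-axis along columns (x)
  b <- 0.85 * params$nucleus_radius   # semi-axis along rows (y)
  size <- 2L * as.integer(ceiling(a) + 4L)
  ctr <- (size + 1) / 2
  row_c <- matrix(seq_len(size), size, size)
  col_c <- matrix(seq_len(size), size, size, byrow = TRUE)
  mask <- ((row_c - ctr) / b)^2 + ((col_c - ctr) / a)^2 <= 1

  with_seed(params$seed, {
    img <- matrix(params$background_intensity, size, size)
    # uniform positions inside the ellipse, kept clear of the rim
    k <- params$granule_count
    theta <- runif(k, 0, 2 * pi)
    rad <- sqrt(runif(k))
    gx <- ctr + 0.95 * a * rad * cos(theta)
    gy <- ctr + 0.95 * b * rad * sin(theta)
    gr <- runif(k, params$granule_radius[1], params$granule_radius[2])
    gi <- round(runif(k, params$granule_intensity[1],
                      params$granule_intensity[2]))
    for (g in seq_len(k)) {
      i0 <- max(1L, floor(gy[g] - gr[g])); i1 <- min(size, ceiling(gy[g] + gr[g]))
      j0 <- max(1L, floor(gx[g] - gr[g])); j1 <- min(size, ceiling(gx[g] + gr[g]))
      ii <- i0:i1; jj <- j0:j1
      d2 <- outer((ii - gy[g])^2, (jj - gx[g])^2, "+")
      hit <- d2 <= gr[g]^2
      sub <- img[ii, jj, drop = FALSE]
      sub[hit] <- pmin(sub[hit], gi[g])
      img[ii, jj] <- sub
    }
    if (params$noise_sd > 0) {
      img <- img + round(rnorm(length(img), 0, params$noise_sd))
    }
    img <- pmin(255, pmax(0, round(img)))
    nucleus_image(matrix(as.integer(img), size, size), mask)
  })
}

#' Shipped texture presets and frozen cohort cutoffs
#'
#' Three illustrative parameter sets — not biological ground truth — chosen so
#' the generated classes reproduce the orderings seen in lung cytology:
#' small-cell-like nuclei have the lowest b1MAX (merging granules erase
#' holes), and adenocarcinoma-like fine granular chromatin has a higher
#' chromatin density than squamous-like coarse chromatin.
#'
#' `cohort_cutoffs` are the classification cutoffs for cohorts generated at
#' these presets, tuned once on an independent seed and then frozen; they
#' differ from the clinical defaults in [chp_rule()] because cutoff values
#' are specific to an imaging scale.
#'
#' @return named list with one [texture_params()] per class and an element
#'   `cohort_cutoffs` (a [chp_rule()]).
#' @export
chp_presets <- function() {
  list(
    fine_granular = texture_params(
      class_name = "fine_granular", label = "adeno",
      granule_count = 700, granule_radius = c(0.9, 1.4),
      granule_intensity = c(60, 90), background_intensity = 190,
      nucleus_radius = 22, noise_sd = 0),
    coarse = texture_params(
      class_name = "coarse", label = "squamous",
      granule_count = 200, granule_radius = c(2.2, 3.5),
      granule_intensity = c(30, 100), background_intensity = 190,
      nucleus_radius = 34, noise_sd = 0),
    dense_packed = texture_params(
      class_name = "dense_packed", label = "small_cell",
      granule_count = 180, granule_radius = c(2, 4),
      granule_intensity = c(20, 70), background_intensity = 90,
      nucleus_radius = 11, noise_sd = 0),
    cohort_cutoffs = chp_rule(b1max_cutoff = 13, density_cutoff = 0.0085)
  )
}

#' Generate a labeled synthetic cohort
#'
#' Draws `n` nuclei per class with per-nucleus seeds derived reproducibly
#' from `master_seed`.
#'
#' @param class_specs list of `list(params = <texture_params>, n = <count>)`.
#' @param master_seed integer seed for the whole cohort.
#' @return list with one element per nucleus: `list(nucleus, label, class_name,
#'   id, seed)`.
#' @export
generate_cohort <- function(class_specs, master_seed = 1) {
  if (length(class_specs) == 0L) return(list())
  ns <- vapply(class_specs, function(s) as.integer(s$n), integer(1))
  if (any(ns < 1)) stop("each class needs n >= 1", call. = FALSE)
  total <- sum(ns)
  seeds <- with_seed(master_seed, sample.int(.Machine$integer.max - 1L, total))
  out <- vector("list", total)
  k <- 0L
  for (spec in class_specs) {
    for (i in seq_len(spec$n)) {
      k <- k + 1L
      out[[k]] <- list(
        nucleus = textured_nucleus(spec$params, seed = seeds[k]),
        label = spec$params$label,
        class_name = spec$params$class_name,
        id = sprintf("%s_%03d", spec$params$class_name, i),
        seed = seeds[k]
      )
    }
  }
  out
}

#' Feature table for a generated cohort
#'
#' Convenience wrapper running [nucleus_features()] over [generate_cohort()]
#' output.
#'
#' @param cohort list from [generate_cohort()].
#' @param ... passed to [nucleus_features()].
#' @return `data.frame` with one feature row per nucleus.
#' @export
cohort_features <- function(cohort, ...) {
  rows <- lapply(cohort, function(x) {
    nucleus_features(x$nucleus, nucleus_id = x$id, label = x$label, ...)
  })
  do.call(rbind, rows)
}
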