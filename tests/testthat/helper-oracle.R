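# Independent pure-R flood-fill oracle for component and hole counting.
# Deliberately written against the raw definitions (breadth-first frontier
# expansion over pixel indices), sharing no code with the package internals.

neighbour_offsets <- function(connectivity) {
  four <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  if (connectivity == 4) return(four)
  c(four, list(c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L)))
}

# flood fill from `starts` (linear indices) across TRUE pixels of `px`;
# returns the logical membership vector of everything reached
oracle_flood <- function(px, nr, nc, starts, connectivity) {
  reached <- rep(FALSE, nr * nc)
  frontier <- starts[px[starts]]
  reached[frontier] <- TRUE
  offs <- neighbour_offsets(connectivity)
  while (length(frontier)) {
    i <- ((frontier - 1L) %% nr) + 1L
    j <- ((frontier - 1L) %/% nr) + 1L
    cand <- integer(0)
    for (o in offs) {
      ni <- i + o[1]; nj <- j + o[2]
      ok <- ni >= 1L & ni <= nr & nj >= 1L & nj <= nc
      cand <- c(cand, (nj[ok] - 1L) * nr + ni[ok])
    }
    cand <- unique(cand)
    cand <- cand[px[cand] & !reached[cand]]
    reached[cand] <- TRUE
    frontier <- cand
  }
  reached
}

oracle_count_components <- function(img, connectivity) {
  px <- as.vector(img)
  nr <- nrow(img); nc <- ncol(img)
  seen <- rep(FALSE, nr * nc)
  count <- 0L
  repeat {
    start <- which(px & !seen)[1]
    if (is.na(start)) break
    count <- count + 1L
    seen <- seen | oracle_flood(px, nr, nc, start, connectivity)
  }
  count
}

# b0 by foreground flood fill; b1 by border-seeded background flood fill:
# holes are the background pixels a border flood never reaches
oracle_betti <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  b0 <- oracle_count_components(img, 8)
  bg <- as.vector(!img)
  border <- unique(c(seq_len(nr), (nc - 1L) * nr + seq_len(nr),
                     (seq_len(nc) - 1L) * nr + 1L, (seq_len(nc) - 1L) * nr + nr))
  outside <- oracle_flood(bg, nr, nc, border, 4)
  holes <- bg & !outside
  b1 <- oracle_count_components(matrix(holes, nr, nc), 4)
  c(b0 = b0, b1 = b1)
}

random_binary <- function(nr, nc, p = 0.5) {
  matrix(runif(nr * nc) < p, nr, nc)
}

# small random textured nucleus for property tests
random_test_nucleus <- function(seed, radius = 9, intensity = c(60, 140),
                                background = 200) {
  p <- texture_params("test", granule_count = 25,
                      granule_radius = c(1, 2.5),
                      granule_intensity = intensity,
                      background_intensity = background,
                      nucleus_radius = radius, noise_sd = 0, seed = seed)
  textured_nucleus(p)
}

# random valid ring phantom specification
random_phantom <- function(seed, size = 96, background = 200) {
  set.seed(seed)
  rings <- data.frame(cx = numeric(), cy = numeric(), r_inner = numeric(),
                      r_outer = numeric(), intensity = numeric())
  n_target <- sample(0:7, 1)
  guard <- 0
  while (nrow(rings) < n_target && guard < 200) {
    guard <- guard + 1
    r_in <- runif(1, 1.5, 4)
    r_out <- r_in + runif(1, 2, 3.5)
    ctr <- (size + 1) / 2
    cx <- runif(1, 1 + r_out, size - r_out)
    cy <- runif(1, 1 + r_out, size - r_out)
    # stay inside the elliptical mask with margin
    semi <- size / 2 - 1.5
    if (((cy - ctr)^2 + (cx - ctr)^2) > (semi - r_out - 2)^2) next
    ok <- TRUE
    if (nrow(rings) > 0) {
      d <- sqrt((rings$cx - cx)^2 + (rings$cy - cy)^2)
      if (any(d <= rings$r_outer + r_out + 2)) ok <- FALSE
    }
    if (ok) {
      rings <- rbind(rings, data.frame(
        cx = cx, cy = cy, r_inner = r_in, r_outer = r_out,
        intensity = sample(0:(background - 1), 1)))
    }
  }
  ring_phantom(size, rings = rings, background_intensity = background)
}
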