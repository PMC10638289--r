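test_that("binarization follows the <= threshold, mask-restricted convention", {
  intens <- matrix(c(0L, 105L, 106L, 255L), 2, 2)
  mask <- matrix(TRUE, 2, 2)
  nuc <- nucleus_image(intens, mask)

  expect_equal(binarize(nuc, 255), mask)                 # everything inside
  expect_equal(binarize(nuc, 0), intens == 0L)           # only exact zeros
  expect_false(binarize(nuc, 105)[1, 2])                 # 106 still background
  expect_true(binarize(nuc, 106)[1, 2])                  # 106 now foreground

  half <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2)
  expect_equal(binarize(nucleus_image(intens, half), 255), half)
  expect_error(binarize(nuc, 256), "0..255")
  expect_error(binarize(nuc, -1), "0..255")
})

test_that("foreground grows monotonically with the threshold", {
  for (seed in 1:10) {
    nuc <- random_test_nucleus(seed)
    prev <- binarize(nuc, 0)
    for (t in seq(5, 255, by = 10)) {
      cur <- binarize(nuc, t)
      expect_true(all(cur[prev]))   # nesting: fg(t) subset of fg(t')
      prev <- cur
    }
    expect_true(all(!binarize(nuc, 255)[!nuc$mask]))
  }
})

test_that("profile of a constant nucleus is flat with absent HV", {
  nuc <- nucleus_image(matrix(80L, 16, 16))
  p <- chp(nuc)
  expect_equal(unname(p$b1), rep(0L, 256))
  expect_equal(p$b1max, 0L)
  expect_true(is.na(p$hv))
})

test_that("single-ring phantom yields the hand-computed box profile", {
  ph <- ring_phantom(40, rings = data.frame(cx = 20.5, cy = 20.5,
                                            r_inner = 5, r_outer = 8,
                                            intensity = 50),
                     background_intensity = 200)
  p <- chp(ph$nucleus)
  expect_equal(unname(p$b1[1:50]), rep(0L, 50))          # t < 50
  expect_equal(unname(p$b1[51:200]), rep(1L, 150))       # 50 <= t < 200
  expect_equal(unname(p$b1[201:256]), rep(0L, 56))       # t >= 200: filled
  expect_equal(p$b1max, 1L)
})

test_that("five disjoint rings give b1max 5 and HV at the fifth intensity", {
  ph <- ring_phantom(96, rings = data.frame(
    cx = c(20, 48, 76, 30, 62), cy = c(28, 18, 28, 66, 70),
    r_inner = 4, r_outer = 6.5, intensity = c(10, 20, 30, 40, 50)))
  p <- chp(ph$nucleus)
  expect_equal(p$b1max, 5L)
  expect_equal(p$hv, 50L)
  expect_equal(as.integer(p$b1), as.integer(ph$expected$b1))
})

test_that("profile accessors agree with a linear scan of the curve", {
  curve <- c(0L, 2L, 7L, 7L, 3L, rep(0L, 251))
  expect_equal(b1max(curve), 7L)
  expect_equal(homology_value(curve, hole_threshold = 5), 2L)
  expect_equal(homology_value(rep(0L, 256)), NA_integer_)

  late <- rep(0L, 256); late[43] <- 5L                   # index 43 = t 42
  expect_equal(homology_value(late), 42L)

  set.seed(7)
  for (k in 1:20) {
    nuc <- random_test_nucleus(k + 100)
    p <- chp(nuc)
    expect_equal(p$b1max, max(p$b1))
    scan <- which(p$b1 >= p$hole_threshold)
    expect_equal(p$hv, if (length(scan)) as.integer(scan[1] - 1) else NA_integer_)
    # curve at t = 255 is the b1 of the mask itself (simply connected: 0)
    expect_equal(unname(p$b1[256]), 0L)
  }
})

test_that("adding a constant to intensities shifts HV and keeps b1max", {
  for (seed in 1:6) {
    nuc <- random_test_nucleus(seed, intensity = c(60, 140), background = 200)
    shift <- 17L
    shifted <- nucleus_image(nuc$intensity + shift, nuc$mask)
    p0 <- chp(nuc); p1 <- chp(shifted)
    expect_equal(p1$b1max, p0$b1max)
    expect_equal(p1$hv, p0$hv + shift)
  }
})

test_that("shrinking the mask never creates foreground outside it", {
  nuc <- random_test_nucleus(5)
  small_mask <- nuc$mask
  small_mask[1:(nrow(small_mask) / 2), ] <- FALSE
  shrunk <- nucleus_image(nuc$intensity, small_mask)
  for (t in c(0, 64, 128, 255)) {
    expect_true(all(!binarize(shrunk, t)[!small_mask]))
  }
})

test_that("nucleus container validates its inputs", {
  expect_error(nucleus_image(matrix(300L, 3, 3)), "0..255")
  expect_error(nucleus_image(matrix(1.5, 3, 3)), "integers")
  expect_error(nucleus_image(matrix(1L, 3, 3), matrix(FALSE, 3, 3)),
               "no inside pixel")
  expect_error(nucleus_image(matrix(1L, 3, 3), matrix(TRUE, 2, 2)),
               "dimensions differ")
})

test_that("print, summary and plot run on a profile", {
  p <- chp(random_test_nucleus(1))
  expect_output(print(p), "b1MAX")
  expect_output(print(summary(p)), "nonzero b1")
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_invisible(plot(p))
})
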