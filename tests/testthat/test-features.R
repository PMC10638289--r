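test_that("ns is the bounding-box diagonal in pixel counts", {
  m <- matrix(FALSE, 10, 10); m[3:5, 2:5] <- TRUE       # 3 x 4 box
  expect_equal(ns_diagonal(m), 5)

  single <- matrix(FALSE, 4, 4); single[2, 3] <- TRUE   # 1 x 1 box
  expect_equal(ns_diagonal(single), sqrt(2))

  box10 <- matrix(FALSE, 12, 12); box10[2:11, 2:11] <- TRUE
  expect_equal(ns_diagonal(box10), sqrt(200), tolerance = 1e-12)

  # scattered pixels: the box spans the extremes
  sc <- matrix(FALSE, 20, 20); sc[4, 6] <- sc[9, 15] <- TRUE
  expect_equal(ns_diagonal(sc), sqrt(6^2 + 10^2))
  expect_error(ns_diagonal(matrix(FALSE, 3, 3)), "no inside pixel")
})

test_that("chromatin density is b1max / ns^2 with its scaling law", {
  expect_equal(chromatin_density(50, sqrt(1000)), 0.05)
  expect_equal(chromatin_density(0, 10), 0)
  expect_equal(chromatin_density(40, 20), 4 * chromatin_density(40, 40))
  expect_error(chromatin_density(10, 0), "positive")
})

test_that("upsampling a nucleus keeps b1max and divides density by k^2", {
  for (seed in c(2, 5)) {
    nuc <- random_test_nucleus(seed, radius = 8)
    f1 <- nucleus_features(nuc, "orig")
    for (k in c(2L, 3L)) {
      idx_r <- rep(seq_len(nrow(nuc$intensity)), each = k)
      idx_c <- rep(seq_len(ncol(nuc$intensity)), each = k)
      up <- nucleus_image(nuc$intensity[idx_r, idx_c], nuc$mask[idx_r, idx_c])
      fk <- nucleus_features(up, "up")
      expect_equal(fk$b1max, f1$b1max)
      expect_equal(fk$density, f1$density / k^2, tolerance = 1e-12)
    }
  }
})

test_that("feature records are internally consistent", {
  nuc <- random_test_nucleus(3)
  f <- nucleus_features(nuc, "n1", label = "adeno")
  expect_equal(f$ns2, f$ns^2)
  expect_equal(f$density, f$b1max / f$ns2)
  expect_equal(f$b1max, chp(nuc)$b1max)
  expect_equal(f$bi, brightness_index(nuc)$bi)
  expect_error(nucleus_features(nuc, "n1", label = "carcinoid"), "unknown label")
})

test_that("the cutoff hierarchy classifies and breaks ties on the >= side", {
  recs <- data.frame(
    b1max = c(20, 40, 40, 25, 40),
    density = c(0.01, 0.08, 0.02, 0.01, 0.05),
    hv = c(10, 20, 30, 40, 50)
  )
  expect_equal(classify_histotype(recs),
               c("small_cell", "adeno", "squamous",
                 "squamous",   # b1max exactly 25: non-small-cell branch
                 "adeno"))     # density exactly 0.05: adeno branch

  # optional HV stage: high HV is non-cancerous, cancer has low HV
  rule <- chp_rule(hv_cutoff = 45)
  expect_equal(classify_histotype(recs, rule)[c(1, 5)],
               c("small_cell", "non_cancerous"))

  expect_error(classify_histotype(data.frame(b1max = 10), chp_rule()),
               "density")
  expect_error(
    classify_histotype(data.frame(b1max = 10, density = 0.1,
                                  hv = NA_integer_),
                       chp_rule(hv_cutoff = 45)),
    "hv")
})

test_that("classification is deterministic and order-independent", {
  set.seed(13)
  recs <- data.frame(b1max = sample(5:80, 40, replace = TRUE),
                     density = runif(40, 0, 0.1))
  pred <- classify_histotype(recs)
  perm <- sample(40)
  expect_equal(classify_histotype(recs[perm, ]), pred[perm])
})

test_that("sensitivity and specificity follow the confusion table", {
  # perfectly separated groups
  res <- evaluate_cutoff(c(1, 2, 3, 10, 11, 12), rep(c(FALSE, TRUE), each = 3),
                         cutoff = 5, positive_direction = "high")
  expect_equal(res$sensitivity, 1)
  expect_equal(res$specificity, 1)

  # cutoff below all values, positives on the high side: everything positive
  res <- evaluate_cutoff(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE),
                         cutoff = 0, positive_direction = "high")
  expect_equal(res$sensitivity, 1)
  expect_equal(res$specificity, 0)

  # six points, one misclassified per class:
  # positives (high): 7, 8, 2 ; negatives: 1, 3, 9 ; cutoff 5
  res <- evaluate_cutoff(c(7, 8, 2, 1, 3, 9),
                         c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                         cutoff = 5, positive_direction = "high")
  expect_equal(res$sensitivity, 2 / 3)
  expect_equal(res$specificity, 2 / 3)
  expect_equal(res$n_pos, 3)
  expect_equal(res$n_neg, 3)

  # degenerate cutoffs
  res <- evaluate_cutoff(1:6, rep(c(TRUE, FALSE), 3), -Inf, "high")
  expect_equal(c(res$sensitivity, res$specificity), c(1, 0))
  res <- evaluate_cutoff(1:6, rep(c(TRUE, FALSE), 3), Inf, "high")
  expect_equal(c(res$sensitivity, res$specificity), c(0, 1))

  # low direction: positives below the cutoff
  res <- evaluate_cutoff(c(1, 2, 9, 10), c(TRUE, TRUE, FALSE, FALSE),
                         cutoff = 5, positive_direction = "low")
  expect_equal(c(res$sensitivity, res$specificity), c(1, 1))

  expect_error(evaluate_cutoff(1:3, c(TRUE, TRUE, TRUE), 2), "both label")
})
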