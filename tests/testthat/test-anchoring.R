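test_that("step ring defaults match the expanded-sample convention", {
  f <- formals(step_rings)
  expect_equal(eval(f$k_min), -40)
  expect_equal(eval(f$k_max), 20)
})

test_that("single-pixel object rings follow the dilation/erosion formulae", {
  m <- matrix(0L, 9, 9); m[5, 5] <- 1L
  rg <- step_rings(label_mask(m), 1, k_min = -2, k_max = 2, se = "square")
  expect_length(rg$steps[["1"]], 8)
  expect_length(rg$steps[["2"]], 16)
  # ring(-1) = object \ erosion = the pixel itself; deeper rings are empty
  expect_identical(rg$steps[["-1"]], which(m == 1L))
  expect_length(rg$steps[["-2"]], 0)
})

test_that("rings match the chessboard distance-transform oracle on an 11x11 square", {
  m <- matrix(0L, 31, 31)
  m[11:21, 11:21] <- 1L
  rg <- step_rings(label_mask(m), 1, k_min = -5, k_max = 3, se = "square")
  dout <- oracle_cheb_outside(m == 1L)
  din <- oracle_cheb_inside(m == 1L)
  for (k in 1:3)
    expect_identical(rg$steps[[as.character(k)]],
                     sort(which(m == 0L & dout == k)))
  for (k in 1:5)
    expect_identical(rg$steps[[as.character(-k)]],
                     sort(which(m == 1L & din == k)))
})

test_that("ring algebra holds for random blobs against the oracle", {
  for (seed in 1:6) {
    blob <- random_blob(36, seed)
    mask <- label_mask(matrix(as.integer(blob), 36, 36))
    rg <- step_rings(mask, 1, k_min = -4, k_max = 5, se = "square")
    all_rings <- unlist(rg$steps)
    expect_identical(anyDuplicated(all_rings), 0L) # pairwise disjoint
    obj <- which(blob)
    for (k in 1:5) {
      pos <- unname(unlist(rg$steps[as.character(1:k)]))
      dil <- blob
      for (i in seq_len(k)) dil <- binary_dilate(dil, "square")
      expect_identical(sort(pos), setdiff(which(dil), obj))
      expect_length(intersect(pos, obj), 0)
    }
    for (k in 1:4) {
      neg <- unname(unlist(rg$steps[as.character(-(1:k))]))
      ero <- blob
      for (i in seq_len(k)) ero <- binary_erode(ero, "square")
      expect_identical(sort(neg), setdiff(obj, which(ero)))
    }
    # oracle agreement
    dout <- oracle_cheb_outside(blob)
    din <- oracle_cheb_inside(blob)
    for (k in 1:5)
      expect_identical(rg$steps[[as.character(k)]],
                       sort(which(!blob & dout == k)))
    for (k in 1:4)
      expect_identical(rg$steps[[as.character(-k)]],
                       sort(which(blob & din == k)))
  }
})

test_that("convex objects have nondecreasing outer ring sizes until clipping", {
  m <- matrix(0L, 61, 61)
  m[26:36, 26:36] <- 1L
  rg <- step_rings(label_mask(m), 1, k_min = -1, k_max = 20, se = "square")
  sizes <- vapply(as.character(1:20), function(k)
    length(rg$steps[[k]]), integer(1))
  clipped <- 26 # dilation reaches the border after 25 steps; none here <= 20
  expect_true(all(diff(sizes) >= 0))
})

test_that("overlap exclusion removes exactly the other-object pixels", {
  m <- matrix(0L, 30, 40)
  m[10:20, 5:10] <- 1L
  m[10:20, 15:20] <- 2L # 4 px gap
  mask <- label_mask(m)
  rg <- step_rings(mask, 1, k_min = -1, k_max = 6, se = "square")
  pruned <- exclude_overlaps(rg, mask)
  other <- which(m == 2L)
  for (k in names(rg$steps)) {
    expect_identical(pruned$steps[[k]], setdiff(rg$steps[[k]], other))
    expect_length(intersect(pruned$steps[[k]], other), 0)
  }
  # an isolated object is untouched
  m2 <- matrix(0L, 30, 30); m2[10:15, 10:15] <- 1L
  rg2 <- step_rings(label_mask(m2), 1, k_min = -2, k_max = 4)
  expect_identical(exclude_overlaps(rg2, label_mask(m2))$steps, rg2$steps)
})

test_that("profiles report constant channels, class fractions and NA for empty rings", {
  m <- matrix(0L, 20, 20); m[9:11, 9:11] <- 1L
  mask <- label_mask(m)
  img <- multiplex_image(list(a = matrix(7, 20, 20)), 1)
  cm <- class_map(matrix(1L, 20, 20), c(astrocyte = 1, microglia = 2))
  rg <- step_rings(mask, 1, k_min = -3, k_max = 3)
  prof <- profile_object(img, rg, list(cm))
  nonempty <- prof$n_pixels > 0
  expect_true(all(prof$a[nonempty] == 7))
  expect_true(all(prof$frac_astrocyte[nonempty] == 1))
  expect_true(all(prof$frac_microglia[nonempty] == 0))
  # erosion exhausts a 3x3 object after 2 steps: step -3 is empty -> NA
  expect_true(is.na(prof$a[prof$step == -3]))
  expect_true(all(prof$frac_astrocyte[nonempty] +
                    prof$frac_microglia[nonempty] <= 1 + 1e-12))
})

test_that("per-step means peak at the generative offset (radial-histogram oracle)", {
  sp <- phantom_spec(90, 90,
    vessels = list(list(center = c(44.3, 45.1), lumen_radius_px = 12,
                        wall_thickness_px = 4)),
    layers = list(list(marker = "GlnSyn", offset_px = 8, thickness_px = 2,
                       amplitude = 50)), background_rate = 0)
  ph <- make_vessel_phantom(sp)
  rg <- step_rings(ph$mask, 1, k_min = -14, k_max = 14, se = "disc")
  prof <- profile_object(ph$image, rg)
  peak_k <- prof$step[which.max(prof$GlnSyn)]
  expect_equal(peak_k, 8)
  # independent radial histogram from brute-force signed distances
  s <- oracle_signed_euclid(unclass(ph$mask) > 0)
  ch <- get_channel(ph$image, "GlnSyn")
  oracle_means <- vapply(prof$step, function(k) {
    px <- if (k > 0) s > k - 1 & s <= k & unclass(ph$mask) == 0
      else -s > -k - 1 & -s <= -k & unclass(ph$mask) == 1
    if (any(px)) mean(ch[px]) else NA_real_
  }, numeric(1))
  expect_equal(prof$GlnSyn, oracle_means)
})

test_that("aggregation applies sqrt before averaging and handles n = 1", {
  rec <- data.frame(step = c(-1, 1), n_pixels = c(4, 4), a = c(4, 9))
  ap <- aggregate_profiles(list(rec), transform = "sqrt")
  expect_equal(ap$mean[ap$step == -1], 2)
  expect_equal(ap$mean[ap$step == 1], 3)
  expect_true(all(is.na(ap$ci_lo))) # single object: no CI
  ap2 <- aggregate_profiles(list(rec, rec), transform = "none")
  expect_equal(ap2$mean, c(4, 9))
  expect_equal(ap2$sd, c(0, 0))
  expect_error(aggregate_profiles(list()), "1")
})

test_that("confidence intervals reach nominal coverage across replicates", {
  # 30 objects, Gaussian per-object noise around a known per-step truth
  steps <- c(-20:-1, 1:10)
  truth <- 5 + 0.1 * steps
  n_obj <- 30
  hits <- 0; total <- 0
  set.seed(42)
  for (rep in 1:200) {
    records <- lapply(seq_len(n_obj), function(i) {
      df <- data.frame(step = steps, n_pixels = 10)
      df$a <- truth + rnorm(length(steps), 0, 2)
      df
    })
    ap <- aggregate_profiles(records, transform = "none", ci = "normal")
    hits <- hits + sum(ap$ci_lo <= truth & truth <= ap$ci_hi)
    total <- total + length(steps)
  }
  expect_gte(hits / total, 0.93)
})

test_that("z-normalisation and peak localisation follow the documented contract", {
  steps <- c(-5:-1, 1:5)
  rec <- data.frame(step = steps, n_pixels = 1)
  rec$rising <- seq_along(steps)        # monotone: peak at k_max
  rec$flat <- 1                          # constant: excluded
  ap <- aggregate_profiles(list(rec, rec), transform = "none")
  hp <- heatmap_and_peaks(ap)
  expect_equal(hp$peaks$peak_step[hp$peaks$variable == "rising"], 5)
  expect_true("flat" %in% hp$excluded)
  z <- hp$z["rising", ]
  expect_lt(abs(mean(z)), 1e-9)
  expect_lt(abs(sqrt(mean((z - mean(z))^2)) - 1), 1e-9)
  # exact tie between -2 and +2 resolves toward the smaller |k|... and the
  # lumen between -2 and +2
  rec2 <- data.frame(step = steps, n_pixels = 1,
                     a = c(0, 0, 0, 9, 0, 0, 9, 0, 0, 0))
  hp2 <- heatmap_and_peaks(aggregate_profiles(list(rec2, rec2),
                                              transform = "none"))
  expect_equal(hp2$peaks$peak_step, -2)
})

test_that("peak ordering of a multi-vessel phantom is recovered (Kendall tau = 1)", {
  sp <- phantom_spec(300, 300, vessels = grid_vessels(3, 72, seed = 2),
                     layers = demo_layers(50), background_rate = 1, seed = 3)
  ph <- make_vessel_phantom(sp)
  pv <- profile_vessels(ph$image, ph$mask, k_min = -14, k_max = 14,
                        se = "disc")
  hp <- heatmap_and_peaks(aggregate_profiles(pv))
  truth <- ph$truth[hp$peaks$variable]
  expect_equal(cor(truth, hp$peaks$peak_step, method = "kendall"), 1)
})
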