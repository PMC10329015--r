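test_that("vessel phantom paints layers at the stated signed distances", {
  sp <- phantom_spec(64, 64,
    vessels = list(list(center = c(31, 31), lumen_radius_px = 10,
                        wall_thickness_px = 3)),
    layers = list(list(marker = "GLUT1", offset_px = 0, thickness_px = 2,
                       amplitude = 100)),
    background_rate = 0)
  ph <- make_vessel_phantom(sp)
  s <- oracle_signed_euclid(unclass(ph$mask) > 0)
  g <- get_channel(ph$image, "GLUT1")
  expect_true(all((g == 100) == (s >= -1 & s <= 1)))
  expect_true(all(g[s < -1 | s > 1] == 0))
  # vessel object = lumen disc dilated by the wall: radius 13 disc
  expect_equal(sum(ph$mask > 0),
               sum(outer(0:63, 0:63,
                         function(r, c) (r - 31)^2 + (c - 31)^2 <= 13^2)))
  expect_identical(ph$truth, c(GLUT1 = 0))
})

test_that("empty vessel list yields pure background and an empty mask", {
  sp <- phantom_spec(16, 16, layers = list(
    list(marker = "GLUT1", offset_px = 0, thickness_px = 2, amplitude = 9)),
    background_rate = 2)
  ph <- make_vessel_phantom(sp)
  expect_true(all(get_channel(ph$image, "GLUT1") == 2))
  expect_length(mask_labels(ph$mask), 0)
})

test_that("border_safe violations name the offending vessel", {
  sp <- phantom_spec(32, 32, vessels = list(
    list(center = c(16, 16), lumen_radius_px = 5, wall_thickness_px = 2),
    list(center = c(3, 3), lumen_radius_px = 5, wall_thickness_px = 2)))
  expect_error(make_vessel_phantom(sp), "vessel 2")
})

test_that("Poisson phantom counts match the brute-force expectation", {
  sp <- phantom_spec(96, 96,
    vessels = list(list(center = c(47, 47), lumen_radius_px = 12,
                        wall_thickness_px = 4)),
    layers = list(list(marker = "GLUT1", offset_px = 3, thickness_px = 2,
                       amplitude = 80)),
    background_rate = 0.5, seed = 7)
  ph <- make_vessel_phantom(sp, poisson = TRUE)
  s <- oracle_signed_euclid(unclass(ph$mask) > 0)
  n_annulus <- sum(s >= 2 & s <= 4)
  expected <- 80 * n_annulus + 0.5 * (96 * 96 - n_annulus)
  total <- sum(get_channel(ph$image, "GLUT1"))
  expect_lt(abs(total - expected), 4 * sqrt(expected))
  # determinism
  ph2 <- make_vessel_phantom(sp, poisson = TRUE)
  expect_identical(ph$image$channels, ph2$image$channels)
})

test_that("cell fields honour count, area and determinism contracts", {
  expect_length(mask_labels(make_cell_field(0, c(40, 40), 50)$mask), 0)
  cf <- make_cell_field(50, c(260, 260), mean_area_px = 100, area_cv = 0,
                        seed = 3)
  areas <- tabulate(cf$mask[cf$mask > 0])
  expect_length(areas, 50)
  # zero-variance areas agree with 100 px up to disc discretisation
  expect_true(all(abs(areas - 100) <= 0.5 * 2 * pi * sqrt(100 / pi)))
  # nuclear channels positive exactly on cell pixels
  expect_true(all((get_channel(cf$image, "dsDNA") > 0) ==
                    (unclass(cf$mask) > 0)))
  cf2 <- make_cell_field(50, c(260, 260), mean_area_px = 100, area_cv = 0,
                         seed = 3)
  expect_identical(cf$image$channels, cf2$image$channels)
  expect_identical(unclass(cf$mask), unclass(cf2$mask))
  expect_error(make_cell_field(100, c(30, 30), 100), "packing")
})

test_that("apply_scale shape, area and composition contracts hold", {
  img <- multiplex_image(list(a = matrix(runif(100 * 100), 100, 100)), 1)
  expect_identical(apply_scale(img, 1), img)
  expect_equal(dim(apply_scale(img, 3.7)), c(370, 370))
  expect_equal(apply_scale(img, 2)$expansion_fold, 2)
  # disc area quadruples under fold 2 within 2%
  disc <- label_mask(matrix(as.integer(
    outer(0:99, 0:99, function(r, c) (r - 49)^2 + (c - 49)^2 <= 30^2)),
    100, 100))
  sc <- apply_scale(disc, 2, "nearest")
  expect_lt(abs(sum(sc > 0) / (4 * sum(disc > 0)) - 1), 0.02)
  expect_error(apply_scale(disc, 2, "linear"), "nearest")
  # composition: shapes within 1 px
  s1 <- apply_scale(apply_scale(img, 1.5), 2.1)
  s2 <- apply_scale(img, 1.5 * 2.1)
  expect_true(all(abs(dim(s1) - dim(s2)) <= 1))
})

test_that("smooth warps are bounded, reproducible and match a spline oracle", {
  wf0 <- make_smooth_warp(c(40, 40), 8, 0, seed = 5)
  expect_true(all(wf0$drow == 0) && all(wf0$dcol == 0))
  img <- matrix(runif(1600), 40, 40)
  expect_identical(apply_warp(img, wf0), img)
  for (seed in 1:5) {
    wf <- make_smooth_warp(c(40, 40), 8, 3, seed = seed)
    expect_lte(max(sqrt(wf$drow^2 + wf$dcol^2)), 3 + 1e-9)
  }
  # oracle: same control draws, transposed interpolation order, same clamp
  seed <- 9; amp <- 2.5; sp <- 10; h <- 35; w <- 42
  wf <- make_smooth_warp(c(h, w), sp, amp, seed = seed)
  set.seed(seed)
  ctrl_r <- seq(-sp, h - 1 + sp, by = sp)
  ctrl_c <- seq(-sp, w - 1 + sp, by = sp)
  dense <- lapply(1:2, function(k) {
    off <- matrix(runif(length(ctrl_r) * length(ctrl_c), -amp, amp),
                  length(ctrl_r), length(ctrl_c))
    # columns first, then rows (reverse of the implementation's order)
    tmp <- apply(off, 2, function(col)
      splinefun(ctrl_r, col, method = "natural")(0:(h - 1)))
    t(apply(tmp, 1, function(row)
      splinefun(ctrl_c, row, method = "natural")(0:(w - 1))))
  })
  mx <- max(sqrt(dense[[1]]^2 + dense[[2]]^2))
  if (mx > amp) dense <- lapply(dense, function(m) m * amp / mx)
  expect_lt(max(abs(wf$drow - dense[[1]])), 1e-6)
  expect_lt(max(abs(wf$dcol - dense[[2]])), 1e-6)
})

test_that("Poisson noise is mean-preserving, deterministic and guarded", {
  z <- matrix(0, 20, 20)
  expect_true(all(add_poisson_noise(z, 1) == 0))
  lam <- matrix(50, 100, 100)
  n1 <- add_poisson_noise(lam, seed = 2)
  expect_lt(abs(mean(n1) - 50), 4 * sqrt(50 / 1e4))
  expect_identical(n1, add_poisson_noise(lam, seed = 2))
  expect_error(add_poisson_noise(matrix(-1, 2, 2), 1), "non-negative")
})

test_that("noise-free phantom channel mass equals the geometric integral", {
  sp <- phantom_spec(80, 80,
    vessels = list(list(center = c(39.5, 40.2), lumen_radius_px = 9,
                        wall_thickness_px = 3)),
    layers = demo_layers(amplitude = 60)[3:4], background_rate = 0.25)
  ph <- make_vessel_phantom(sp)
  s <- oracle_signed_euclid(unclass(ph$mask) > 0)
  for (l in sp$layers) {
    inside <- s >= l$offset_px - 1 & s <= l$offset_px + 1
    expect_equal(sum(get_channel(ph$image, l$marker)),
                 60 * sum(inside) + 0.25 * sum(!inside))
  }
})
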