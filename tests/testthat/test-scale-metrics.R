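test_that("linear fold recovers exact and jittered scalings (pairwise oracle)", {
  set.seed(10)
  pre <- cbind(runif(20, 0, 200), runif(20, 0, 200))
  expect_equal(fold_linear(landmark_pairs(pre, pre))$fold, 1)
  expect_equal(fold_linear(landmark_pairs(pre, pre))$dispersion, 0)
  exact <- fold_linear(landmark_pairs(pre, pre * 3.7))
  expect_equal(exact$fold, 3.7)
  expect_lt(exact$dispersion, 1e-12)
  # jittered scaling s = 2.5, sigma = 0.5 px
  post <- pre * 2.5 + matrix(rnorm(40, 0, 0.5), 20, 2)
  est <- fold_linear(landmark_pairs(pre, post))
  expect_lt(abs(est$fold / 2.5 - 1), 0.02)
  # brute-force all-pairs oracle
  rats <- c()
  for (i in 1:19) for (j in (i + 1):20) {
    dp <- sqrt(sum((pre[i, ] - pre[j, ])^2))
    dq <- sqrt(sum((post[i, ] - post[j, ])^2))
    rats <- c(rats, dq / dp)
  }
  expect_equal(est$fold, mean(rats))
  expect_equal(est$dispersion, sd(rats))
  expect_equal(est$n, length(rats))
  # coincident pre-landmarks are skipped with a warning
  pre2 <- rbind(pre, pre[1, ])
  post2 <- rbind(post, post[1, ] + 1)
  expect_warning(fold_linear(landmark_pairs(pre2, post2)), "coincident")
})

test_that("area fold takes the square root of the physical area ratio", {
  disc <- outer(0:99, 0:99, function(r, c) (r - 49)^2 + (c - 49)^2 <= 25^2)
  expect_equal(fold_area(disc, disc)$fold, 1)
  sc <- apply_scale(label_mask(matrix(as.integer(disc), 100, 100)), 2,
                    "nearest")
  expect_lt(abs(fold_area(disc, unclass(sc) > 0)$fold - 2), 0.02 * 2)
  # area ratio 13.69 -> linear fold 3.7
  m1 <- matrix(TRUE, 10, 10)
  m2 <- matrix(TRUE, 37, 37)
  expect_equal(fold_area(m1, m2)$fold, 3.7)
  expect_error(fold_area(matrix(FALSE, 5, 5), m1), "empty")
})

test_that("segmentation fold recovers a 3x rescaling end-to-end", {
  cf <- make_cell_field(40, c(240, 240), mean_area_px = 110, area_cv = 0.25,
                        seed = 14)
  pre_img <- add_poisson_noise(cf$image, seed = 1)
  post_img <- add_poisson_noise(apply_scale(cf$image, 3, "linear"), seed = 2)
  seg_pre <- segment_features(composite(pre_img, "HistoneH3"),
                              segmentation_params(blur_sigma_px = 2,
                                                  min_size_px = 30))
  seg_post <- segment_features(composite(post_img, "HistoneH3"),
                               segmentation_params(blur_sigma_px = 6,
                                                   min_size_px = 30))
  est <- fold_segmentation(quantify_cells(pre_img, seg_pre),
                           quantify_cells(post_img, seg_post))
  expect_lt(abs(est$fold / 3 - 1), 0.05)
  # identical tables give 1; median and mean agree on symmetric areas
  tab <- quantify_cells(pre_img, seg_pre)
  expect_equal(fold_segmentation(tab, tab)$fold, 1)
  f_med <- fold_segmentation(tab, quantify_cells(post_img, seg_post),
                             "median")$fold
  f_mean <- fold_segmentation(tab, quantify_cells(post_img, seg_post),
                              "mean")$fold
  expect_lt(abs(f_med / f_mean - 1), 0.03)
  expect_error(fold_segmentation(tab[1:5, ], tab), "20")
})

test_that("line profiles sample rows exactly and interpolate bilinearly", {
  ch <- matrix(seq_len(50) + 0, 5, 10)
  img <- multiplex_image(list(a = ch), pixel_size_um = 2,
                         expansion_fold = 1)
  lp <- line_profile(img, "a", c(2, 0), c(2, 9))
  expect_equal(lp$intensity, ch[3, ])
  expect_length(lp$intensity, floor(9) + 1)
  expect_equal(lp$position_um, (0:9) * 2)
  # midpoint of a 2x2 block [[0,0],[2,2]] between rows is 1
  img2 <- multiplex_image(list(a = matrix(c(0, 2, 0, 2), 2, 2)), 1)
  lp2 <- line_profile(img2, "a", c(0.5, 0), c(0.5, 1))
  expect_equal(lp2$intensity, c(1, 1))
  expect_error(line_profile(img, "a", c(0, 0), c(10, 3)), "outside")
  # positions halve when expansion_fold doubles (pure metadata)
  img3 <- img; img3$expansion_fold <- 2
  expect_equal(line_profile(img3, "a", c(2, 0), c(2, 9))$position_um,
               lp$position_um / 2)
})

test_that("16-84% distances match step, ramp and Gaussian-edge oracles", {
  # ideal step edge: sharpest measurable distance <= 1 px
  step_v <- c(rep(0, 30), rep(10, 30))
  expect_lte(resolution_16_84(as_line_profile(0:59, step_v)), 1)
  # linear ramp over L px between plateaus: (0.84 - 0.16) L
  L <- 40
  ramp <- c(rep(0, 25), seq(0, 1, length.out = L + 1), rep(1, 25))
  d <- resolution_16_84(as_line_profile(seq_along(ramp) - 1, ramp))
  expect_lt(abs(d - 0.68 * L), 0.1)
  # Gaussian edge, sigma = 2 px: numeric error-function oracle gives
  # sigma * (qnorm(.84) - qnorm(.16)), approximately 2 sigma
  x <- 0:120
  edge <- pnorm((x - 60) / 2)
  d2 <- resolution_16_84(as_line_profile(x, edge))
  expect_lt(abs(d2 - 2 * (qnorm(0.84) - qnorm(0.16))),
            0.05 * 4)
  expect_lt(abs(d2 / 4 - 1), 0.05)
  # affine intensity invariance
  d3 <- resolution_16_84(as_line_profile(x, 3.2 * edge + 17))
  expect_equal(d3, d2, tolerance = 1e-9)
  # falling edges are handled by reversal
  d4 <- resolution_16_84(as_line_profile(x, rev(edge)))
  expect_equal(d4, d2, tolerance = 1e-9)
  # guards: flat and non-monotone profiles
  expect_error(resolution_16_84(as_line_profile(0:20, rep(1, 21))),
               "plateau")
  wiggly <- c(rep(0, 10), 1, 0, rep(1, 10))
  expect_error(resolution_16_84(as_line_profile(seq_along(wiggly) - 1,
                                                wiggly)), "monotonicity")
  # summary across scans
  sm <- summarize_resolution(c(3.9, 4.1, 4.0))
  expect_equal(sm$mean, 4)
  expect_equal(sm$n_scans, 3)
})

test_that("channel sums are exact", {
  z <- multiplex_image(list(a = matrix(0, 4, 4)), 1, fov_id = "z")
  cst <- multiplex_image(list(a = matrix(3, 5, 6)), 1, fov_id = "c")
  set.seed(3)
  rnd <- multiplex_image(list(a = matrix(rpois(30, 4) + 0, 5, 6)), 1,
                         fov_id = "r")
  tab <- sum_channels(list(z, cst, rnd), "a")
  expect_equal(tab$a, c(0, 3 * 30, sum(rnd$channels$a)))
  expect_error(sum_channels(list(z), "b"), "b")
})

test_that("fold estimators are concordant on one scaled tissue", {
  # one synthetic tissue, known folds; all three strategies agree with the
  # truth and each other within 5%
  cf <- make_cell_field(55, c(280, 280), mean_area_px = 120, area_cv = 0.25,
                        seed = 42)
  pre_img <- add_poisson_noise(cf$image, seed = 7)
  cells_pre <- quantify_cells(pre_img, cf$mask)
  for (s in c(2.0, 3.7, 4.5)) {
    post_mask <- apply_scale(cf$mask, s, "nearest")
    post_img <- add_poisson_noise(apply_scale(cf$image, s, "linear"),
                                  seed = 8)
    cells_post <- quantify_cells(post_img, post_mask)
    common <- intersect(cells_pre$label, cells_post$label)
    lp <- landmark_pairs(
      as.matrix(cells_pre[match(common, cells_pre$label),
                          c("centroid_row", "centroid_col")]),
      as.matrix(cells_post[match(common, cells_post$label),
                           c("centroid_row", "centroid_col")]))
    folds <- c(linear = fold_linear(lp)$fold,
               area = fold_area(unclass(cf$mask) > 0,
                                unclass(post_mask) > 0)$fold,
               segmentation = fold_segmentation(cells_pre, cells_post)$fold)
    expect_true(all(abs(folds / s - 1) < 0.05))
    expect_lt(max(folds) / min(folds) - 1, 0.05)
  }
})
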