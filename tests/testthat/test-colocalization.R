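test_that("make_mask applies a strict threshold and Otsu separates modes", {
  z <- matrix(0, 10, 10)
  expect_false(any(make_mask(z, 10)))
  flat <- matrix(7, 10, 10)
  expect_false(any(make_mask(flat, 7)))      # strict inequality
  expect_error(make_mask(flat, 100, strict = TRUE), "empty mask")
  set.seed(1)
  img <- matrix(rnorm(10000, 20, 5), 100, 100)
  bright <- sample(10000, 3000)
  img[bright] <- rnorm(3000, 200, 10)
  img <- pmax(img, 0)
  mask <- make_mask(img, "otsu")
  expect_equal(mean(mask), 0.3, tolerance = 0.033)  # within 1% of pixels
})

test_that("a contaminated control image triggers the empty-mask warning", {
  img <- matrix(100, 20, 20)
  ctrl_clean <- matrix(1, 20, 20)
  expect_silent(make_mask(img, 50, control = ctrl_clean))
  ctrl_bad <- ctrl_clean
  ctrl_bad[1:3, 1] <- 200
  expect_warning(make_mask(img, 50, control = ctrl_bad),
                 "control image")
})

test_that("mask_product is a pixelwise AND", {
  set.seed(2)
  a <- matrix(runif(400) > 0.5, 20, 20)
  b <- matrix(runif(400) > 0.5, 20, 20)
  expect_equal(mask_product(a, a), a, ignore_attr = TRUE)
  expect_equal(mask_product(a, b), mask_product(b, a))
  disjoint <- !a
  expect_false(any(mask_product(a, disjoint)))
  expect_error(mask_product(a, matrix(TRUE, 5, 5)), "dimensions differ")
})

test_that("count-based Manders coefficients are direct count ratios", {
  a <- matrix(FALSE, 3, 3); a[1, 1:2] <- TRUE; a[2, 1:2] <- TRUE  # 4 px
  b <- matrix(FALSE, 3, 3); b[1, 1] <- TRUE; b[3, 3] <- TRUE      # 2 px
  m <- manders_overlap(a, b)                                      # overlap 1
  expect_equal(unname(m), c(0.25, 0.5))
  expect_equal(unname(manders_overlap(a, a)), c(1, 1))
  expect_equal(unname(manders_overlap(a, !a)), c(0, 0))
  expect_error(manders_overlap(matrix(FALSE, 3, 3), b), "M1 undefined")
  expect_error(manders_overlap(a, matrix(FALSE, 3, 3)), "M2 undefined")
})

test_that("intensity-weighted Manders variant weights by signal", {
  a <- matrix(FALSE, 2, 2); a[1, ] <- TRUE
  b <- matrix(FALSE, 2, 2); b[1, 1] <- TRUE
  img_a <- matrix(c(10, 0, 30, 0), 2, 2)   # a-positive px: 10 and 30
  img_b <- matrix(c(5, 0, 0, 0), 2, 2)
  m <- manders_overlap(a, b, weighted = TRUE, img_a = img_a, img_b = img_b)
  expect_equal(unname(m["m1"]), 10 / 40)
  expect_equal(unname(m["m2"]), 1)
})

test_that("pearson_r reproduces the degenerate identities and the null", {
  set.seed(3)
  a <- matrix(runif(2500, 0, 100), 50, 50)
  expect_equal(pearson_r(a, a), 1)
  expect_equal(pearson_r(a, max(a) - a), -1)
  b <- matrix(runif(10000, 0, 100), 100, 100)
  b2 <- matrix(runif(10000, 0, 100), 100, 100)
  expect_lt(abs(pearson_r(b, b2)), 0.05)
  expect_error(pearson_r(a, matrix(5, 50, 50)), "constant channel")
})

test_that("pearson_r is invariant under positive affine rescaling", {
  set.seed(4)
  a <- matrix(runif(900), 30, 30)
  b <- matrix(a + rnorm(900, 0, 0.2), 30, 30)
  r0 <- pearson_r(a, b)
  expect_equal(pearson_r(2.5 * a + 7, b), r0, tolerance = 1e-12)
  expect_equal(pearson_r(a, 0.1 * b + 100), r0, tolerance = 1e-12)
})

test_that("Li's ICQ hits its bounds, its null and its invariances", {
  set.seed(5)
  a <- matrix(runif(2500, 0, 100), 50, 50)
  ica <- li_ica(a, a)
  expect_equal(ica$icq, 0.5)
  expect_equal(li_ica(a, max(a) - a)$icq, -0.5)
  n1 <- matrix(runif(10000), 100, 100)
  n2 <- matrix(runif(10000), 100, 100)
  expect_lt(abs(li_ica(n1, n2)$icq), 0.02)
  # increasing affine maps leave ICQ unchanged
  b <- matrix(a + rnorm(2500, 0, 10), 50, 50)
  expect_equal(li_ica(3 * a + 2, b)$icq, li_ica(a, b)$icq)
  # ++PDM pixels are a subset of positive-PDM pixels
  ica <- li_ica(a, b)
  expect_true(all(ica$pdm[ica$pdm_pp_mask] > 0))
  expect_error(li_ica(matrix(1, 4, 4), matrix(2, 4, 4)), "all PDMs are zero")
})

test_that("polygon ROIs select pixel centres inside the polygon", {
  img_a <- matrix(seq_len(100), 10, 10)
  set.seed(6)
  img_b <- matrix(runif(100), 10, 10)
  roi <- cbind(c(1.5, 7.5, 7.5, 1.5), c(1.5, 1.5, 7.5, 7.5))  # x, y square
  sel_r <- pearson_r(img_a, img_b, roi = roi)
  inside <- matrix(FALSE, 10, 10)
  inside[3:8, 3:8] <- TRUE   # rows y=2..7, cols x=2..7 (0-based centres)
  expect_equal(sel_r, stats::cor(img_a[inside], img_b[inside]))
  # logical-mask ROI takes the same path
  expect_equal(pearson_r(img_a, img_b, roi = inside), sel_r)
})

test_that("swapping channels swaps M1/M2 and fixes r and ICQ", {
  bp <- make_belt_pair(belt_pair_spec(rho = 0.55, seed = 9,
                                      b_off_frac = 0.1))
  r1 <- coloc_report(bp$channel_a, bp$channel_b, 110, 110)
  r2 <- coloc_report(bp$channel_b, bp$channel_a, 110, 110)
  expect_equal(r1$m1, r2$m2)
  expect_equal(r1$m2, r2$m1)
  expect_equal(r1$n_a, r2$n_b)
  expect_equal(r1$pearson_r, r2$pearson_r)
  expect_equal(r1$li_icq, r2$li_icq)
  expect_true(r1$m1 >= 0 && r1$m1 <= 1 && r1$m2 >= 0 && r1$m2 <= 1)
})

test_that("coloc_report bundles the suite and flags empty channels", {
  set.seed(7)
  a <- matrix(runif(400, 0, 100), 20, 20)
  r <- coloc_report(a, a, 50, 50)
  expect_equal(r$m1, 1)
  expect_equal(r$m2, 1)
  expect_equal(r$pearson_r, 1)
  expect_equal(r$li_icq, 0.5)
  expect_equal(r$n_overlap, r$n_a)
  noise <- matrix(runif(400, 0, 10), 20, 20)
  expect_error(coloc_report(a, noise, 50, 50), "mask is empty")
  f <- withr::local_tempfile(fileext = ".csv")
  write_coloc_csv(r, f)
  back <- read.csv(f)
  expect_equal(back$m1, 1)
  expect_equal(back$li_icq, 0.5)
})

test_that("the mask-product and ++PDM routes agree on belt images", {
  jacc <- function(a, b) sum(a & b) / sum(a | b)
  for (seed in 1:5) {
    bp <- make_belt_pair(belt_pair_spec(seed = seed))
    r <- coloc_report(bp$channel_a, bp$channel_b, 110, 110)
    expect_gte(jacc(r$overlap_mask, r$pdm_pp_mask), 0.5)
  }
})
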