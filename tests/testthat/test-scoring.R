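test_that("compartment masks obey their set algebra by construction", {
  set.seed(21)
  for (k in 1:5) {
    roi <- matrix(runif(900) > 0.3, 30, 30)
    dab <- matrix(runif(900) > 0.6, 30, 30)
    comp <- build_compartments(roi, dab)
    expect_true(all(comp$roi[comp$tumor]))
    expect_identical(comp$stroma, comp$roi & !comp$tumor)
    expect_false(any(comp$tumor & comp$stroma))
    expect_identical(comp$tumor | comp$stroma, comp$roi)
  }
  roi <- matrix(TRUE, 10, 10)
  empty <- matrix(FALSE, 10, 10)
  expect_identical(build_compartments(roi, empty)$stroma, roi)
  expect_identical(build_compartments(roi, roi)$tumor, roi)
  expect_false(any(build_compartments(roi, roi)$stroma))
  expect_error(build_compartments(empty, empty), "empty ROI")
  expect_error(build_compartments(roi, matrix(FALSE, 5, 5)), "shape")
})

test_that("score panel matches hand arithmetic", {
  roi <- matrix(TRUE, 10, 10)
  tumor <- matrix(FALSE, 10, 10); tumor[1:3, ] <- TRUE      # 30 px tumor
  comp <- build_compartments(roi, tumor)
  od <- matrix(0, 10, 10)
  mask <- matrix(FALSE, 10, 10)
  mask[5, 1:10] <- TRUE                                     # 10 stromal px
  od[5, 1:10] <- 0.5
  s <- compute_scores(od, mask, comp)
  expect_identical(s$blue_area_stroma, 10L)
  expect_equal(s$mean_blue_od_stroma, 0.5)
  expect_equal(s$tbs, 5.0)
  expect_identical(s$tsa, 70L)
  expect_identical(s$negative_stroma_area, 60L)
  expect_equal(s$tbt, 0)
  expect_equal(s$blue_area_tumor, 0L)
})

test_that("empty positive set yields zero scores, full stroma area retained", {
  roi <- matrix(TRUE, 8, 8)
  comp <- build_compartments(roi, matrix(FALSE, 8, 8))
  s <- compute_scores(matrix(0.7, 8, 8), matrix(FALSE, 8, 8), comp)
  expect_equal(s$tbs, 0)
  expect_equal(s$tbt, 0)
  expect_identical(s$tsa, 64L)
})

test_that("TBS identity: area x mean equals the integrated OD, exactly", {
  set.seed(77)
  for (k in 1:10) {
    roi <- matrix(runif(400) > 0.2, 20, 20)
    if (!any(roi)) next
    comp <- build_compartments(roi, matrix(runif(400) > 0.7, 20, 20))
    od <- matrix(rexp(400, 3), 20, 20)
    mask <- matrix(runif(400) > 0.5, 20, 20)
    s <- compute_scores(od, mask, comp)
    expect_equal(s$tbs, sum(od[mask & comp$stroma]), tolerance = 1e-12)
    expect_equal(s$tbt, sum(od[mask & comp$tumor]), tolerance = 1e-12)
    # area conservation, exact
    expect_identical(s$blue_area_stroma + s$negative_stroma_area, s$tsa)
    expect_true(s$blue_area_stroma <= s$tsa)
  }
})

test_that("adding a positive stromal pixel with positive OD increases TBS", {
  roi <- matrix(TRUE, 6, 6)
  comp <- build_compartments(roi, matrix(FALSE, 6, 6))
  od <- matrix(0.3, 6, 6)
  mask <- matrix(FALSE, 6, 6); mask[1, 1:3] <- TRUE
  base <- compute_scores(od, mask, comp)$tbs
  mask2 <- mask; mask2[2, 2] <- TRUE
  expect_gt(compute_scores(od, mask2, comp)$tbs, base)
})

test_that("mask overlap follows the Dice conventions", {
  a <- matrix(FALSE, 10, 10); a[1:5, 1:4] <- TRUE
  expect_equal(mask_overlap(a, a)$dice, 1)
  b <- matrix(FALSE, 10, 10); b[6:10, 6:9] <- TRUE
  expect_equal(mask_overlap(a, b)$dice, 0)
  # equal-area half-overlapping rectangles: 20 px each, 10 shared
  c2 <- matrix(FALSE, 10, 10); c2[1:5, 3:6] <- TRUE
  ov <- mask_overlap(a, c2)
  expect_equal(ov$dice, 2 * 10 / (20 + 20))
  expect_equal(ov$a_in_b, 0.5)
  empty <- matrix(FALSE, 10, 10)
  expect_equal(mask_overlap(empty, empty)$dice, 0)
  expect_error(mask_overlap(a, matrix(FALSE, 3, 3)), "shape")
})

test_that("registered compartments match ground truth on a synthetic pair", {
  p <- simulate_image_pair(image_sim_config(seed = 41))
  s <- score_sample(p$ihc_image, p$ish_image, roi = p$roi_mask)
  tum_true <- warp_mask(p$tumor_mask_true, p$misalignment_true,
                        dim(p$tumor_mask_true))
  expect_gte(mask_overlap(s$masks$tumor, tum_true)$dice, 0.9)
})
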