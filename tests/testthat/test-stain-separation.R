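test_that("optical density follows the offset Beer-Lambert convention", {
  # white background carries (essentially) no optical density
  white <- array(255, c(1, 1, 3))
  expect_lt(max(rgb_to_od(white)), 0.002)
  # fully black pixel: closed form -log10(1/256) per channel
  black <- array(0, c(1, 1, 3))
  expect_equal(as.numeric(rgb_to_od(black)), rep(-log10(1 / 256), 3),
               tolerance = 1e-12)
  expect_equal(-log10(1 / 256), 2.40824, tolerance = 1e-5)
  # monotone decreasing in intensity
  ramp <- array(0:255, c(256, 1, 3))
  expect_true(all(diff(rgb_to_od(ramp)[, 1, 1]) < 0))
})

test_that("od_to_rgb inverts rgb_to_od on all 256 gray levels", {
  g <- array(0:255, c(256, 1, 3))
  expect_true(all(od_to_rgb(rgb_to_od(g)) == g))
})

test_that("stain matrices validate their vectors", {
  m <- default_stain_matrix("ihc")
  expect_equal(colnames(m), c("dab", "hematoxylin"))
  expect_equal(colSums(unclass(m)^2), c(dab = 1, hematoxylin = 1),
               tolerance = 1e-12)
  expect_error(stain_matrix(a = c(1, 0, 0), b = c(2, 0, 0)), "collinear")
  expect_error(stain_matrix(a = c(-1, 1, 0)), "non-negative")
  expect_error(stain_matrix(c(1, 0, 0)), "named")
})

test_that("stain matrix JSON round trip preserves the vectors", {
  m <- default_stain_matrix("ish")
  path <- withr::local_tempfile(fileext = ".json")
  write_stain_matrix(m, path)
  expect_equal(unclass(read_stain_matrix(path)), unclass(m), tolerance = 1e-15)
})

test_that("unmixing is exact on unquantized mixtures and clamps negatives", {
  set.seed(4)
  m <- default_stain_matrix("ihc")
  conc <- list(dab = matrix(runif(400, 0, 1.2), 20),
               hematoxylin = matrix(runif(400, 0, 0.8), 20))
  od <- array(0, c(20, 20, 3))
  for (ch in 1:3) od[, , ch] <- m[ch, 1] * conc$dab + m[ch, 2] * conc$hematoxylin
  rec <- unmix(od, m)
  expect_equal(rec$dab, conc$dab, tolerance = 1e-9)
  expect_equal(rec$hematoxylin, conc$hematoxylin, tolerance = 1e-9)

  # pure white image: all maps ~ 0
  white <- array(255, c(8, 8, 3))
  rec_w <- unmix(rgb_to_od(white), m)
  expect_lt(max(rec_w$dab, rec_w$hematoxylin), 0.01)

  # single-stain image with OD 0.8: that map is 0.8, the other 0
  od1 <- array(0, c(5, 5, 3))
  for (ch in 1:3) od1[, , ch] <- m[ch, 1] * 0.8
  rec1 <- unmix(od1, m)
  expect_equal(rec1$dab, matrix(0.8, 5, 5), tolerance = 1e-9)
  expect_equal(rec1$hematoxylin, matrix(0, 5, 5), tolerance = 1e-9)
  expect_true(all(unlist(rec1) >= 0))
})

test_that("rendered-then-unmixed images reproduce the source within quantization", {
  # quantization to 8 bits is the only loss: re-rendering the recovered
  # concentrations must reproduce the original image to within one level
  set.seed(9)
  m <- default_stain_matrix("ish")
  # keep every channel OD below the 8-bit black limit (~2.4) so rounding,
  # not clipping, is the only loss
  conc <- list(blue = matrix(pmin(rexp(900, 2), 1.5), 30),
               nuclear_fast_red = matrix(runif(900, 0, 0.9), 30))
  od <- array(0, c(30, 30, 3))
  for (ch in 1:3) od[, , ch] <- m[ch, 1] * conc$blue +
    m[ch, 2] * conc$nuclear_fast_red
  img <- od_to_rgb(od)
  rec <- unmix(rgb_to_od(img), m)
  od_rec <- array(0, c(30, 30, 3))
  for (ch in 1:3) od_rec[, , ch] <- m[ch, 1] * rec$blue +
    m[ch, 2] * rec$nuclear_fast_red
  expect_lte(max(abs(od_to_rgb(od_rec) - img)), 1)
})

test_that("thresholding matches an exhaustive two-level oracle and is monotone", {
  # two-level map: any threshold strictly between the levels separates them;
  # Otsu must pick exactly the high-level pixels
  set.seed(2)
  map <- matrix(0.05, 16, 16)
  hi <- sample(length(map), 60)
  map[hi] <- 0.9
  bm <- threshold_stain(map, "otsu")
  expect_identical(which(bm), sort(hi))
  expect_gt(attr(bm, "threshold"), 0.05)
  expect_lte(attr(bm, "threshold"), 0.9)

  # fixed thresholds: monotone (raising the threshold never adds pixels)
  map2 <- matrix(runif(256, 0, 1), 16)
  t1 <- threshold_stain(map2, "fixed", fixed_value = 0.3)
  t2 <- threshold_stain(map2, "fixed", fixed_value = 0.5)
  expect_true(all(which(t2) %in% which(t1)))

  expect_identical(sum(threshold_stain(matrix(0, 4, 4) + 0, "fixed",
                                       fixed_value = 0.15)), 0L)
  expect_error(threshold_stain(matrix(0.2, 4, 4), "otsu"), "fixed")
  expect_error(threshold_stain(matrix(1, 2, 2), "fixed", fixed_value = -1),
               "positive")
})

test_that("thresholding the synthetic ISH blue map recovers the drawn positives", {
  pair <- simulate_image_pair(image_sim_config(
    seed = 201, misalignment = identity_transform()))
  maps <- unmix(rgb_to_od(pair$ish_image), default_stain_matrix("ish"))
  bm <- threshold_stain(maps$blue, "otsu")
  expect_gte(mask_overlap(bm, pair$blue_mask_true)$dice, 0.95)
})
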