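test_that("median filter matches the exhaustive neighbourhood-sort oracle", {
  flat <- matrix(50L, 6, 6)
  expect_equal(median_filter(flat, 3), flat)

  salt <- matrix(0L, 7, 7); salt[4, 4] <- 255L
  expect_true(all(median_filter(salt, 3) == 0))

  set.seed(11)
  img <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
  expect_equal(median_filter(img, 3), oracle_median_filter(img, 3))
  expect_equal(median_filter(img, 5), oracle_median_filter(img, 5))

  expect_error(median_filter(img, 4), "odd")
})

test_that("histogram equalization follows the cdf remap", {
  expect_true(all(histogram_equalize(matrix(7L, 5, 5)) == 255))

  two <- matrix(c(rep(10L, 8), rep(200L, 8)), 4, 4)
  out <- histogram_equalize(two)
  expect_setequal(unique(as.vector(out)), c(128, 255))
  expect_true(all(out[two == 10] == 128))

  ramp <- matrix(0:255, 16, 16)
  expect_true(all(abs(histogram_equalize(ramp) - ramp) <= 1))

  # monotone non-decreasing in input grey level
  set.seed(3)
  img <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
  eq <- histogram_equalize(img)
  o <- order(as.vector(img))
  expect_true(all(diff(as.vector(eq)[o]) >= 0))
})

test_that("growing condition reproduces its two-branch truth table", {
  # branch (a): zero gradient, below threshold
  expect_true(growing_condition(100, 100, beta = 150, xbar = 0, sigma = 0))
  # both branches fail: extreme gradient, grey below running mean - sd
  expect_false(growing_condition(0, 255, beta = 150, xbar = 150, sigma = 10))

  set.seed(12)
  n <- 10000
  gl <- sample(0:255, n, TRUE); ge <- sample(0:255, n, TRUE)
  beta <- sample(0:255, n, TRUE)
  xb <- runif(n, 0, 255); sg <- runif(n, 0, 60)
  got <- mapply(growing_condition, gl, ge, beta, xb, sg)
  # independent restatement of the rule
  want <- mapply(function(gl, ge, beta, xb, sg) {
    grad <- abs(ge - gl) / 255 * 100
    if (grad < 95) gl <= beta else gl >= xb - sg
  }, gl, ge, beta, xb, sg)
  expect_identical(got, want)
})

test_that("region growing matches the flood-fill and boundary oracles", {
  cell <- generate_cell_image(cell_spec(width = 64L, height = 48L,
                                        centre = c(32, 24),
                                        nucleus_radius = 8,
                                        cytoplasm_radius = 20,
                                        noise_sd = 0))
  img <- cell$image
  eq <- histogram_equalize(median_filter(img, 3))
  grown <- region_grow(img, eq, c(x = 32, y = 24), beta = 171)
  truth_nuc <- cell$truth$mask == 0L
  expect_identical(grown$member, truth_nuc)
  expect_equal(grown$size, sum(truth_nuc))
  expect_equal(grown$border_count, oracle_boundary_count(truth_nuc))
  expect_equal(grown$grey_sum, sum(img[grown$member]))
  expect_equal(grown$mean, 153)
})

test_that("region growing handles a 1x1 image and conserves its sums", {
  one <- matrix(90L, 1, 1)
  g <- region_grow(one, one, c(x = 0, y = 0), beta = 10)  # seed always accepted
  expect_equal(g$size, 1L)
  expect_equal(g$border_count, 1L)
  expect_equal(g$mean, 90)
  expect_equal(g$sd, 0)

  set.seed(9)
  img <- matrix(sample(80:200, 32 * 24, TRUE), 24, 32)
  g <- region_grow(img, img, c(x = 10, y = 10), beta = 150)
  expect_equal(g$size, sum(g$member))
  expect_equal(g$grey_sum, sum(img[g$member]))
  expect_equal(g$border_count, oracle_boundary_count(g$member))
})

test_that("growth with a pixel-local condition equals connected-component flood fill", {
  # with eq == img the gradient is 0, so acceptance reduces to g <= beta:
  # the visit-once breadth-first growth must equal the set-fixpoint flood
  set.seed(14)
  for (i in 1:5) {
    img <- matrix(sample(0:255, 32 * 24, TRUE), 24, 32)
    seed <- c(x = sample(0:31, 1), y = sample(0:23, 1))
    beta <- sample(60:200, 1)
    g <- region_grow(img, img, seed, beta)
    cond <- img <= beta
    cond[seed[["y"]] + 1, seed[["x"]] + 1] <- TRUE  # seed force-accepted
    want <- oracle_flood(cond, rc_to_idx_helper(seed, nrow(img)))
    expect_identical(g$member, want)
  }
})

test_that("segmentation recovers exact features on zero-noise cells", {
  cell <- generate_cell_image(cell_spec(noise_sd = 0, nucleus_radius = 10,
                                        cytoplasm_radius = 30))
  seg <- segment_and_extract(cell$image,
                             c(beta_NC = 171, beta_CB = 208),
                             cell$truth$centroid)
  f <- seg$features
  expect_equal(unname(f["nucleus_size"]), cell$truth$nucleus_size)
  expect_equal(unname(f["cytoplasm_size"]), cell$truth$cytoplasm_size)
  expect_equal(unname(f["nucleus_grey"]), 153)
  expect_equal(unname(f["cytoplasm_grey"]), 190)
  expect_identical(seg$mask, cell$truth$mask)

  # label conservation and Eq-(3) style pixel accounting
  expect_equal(sum(seg$mask == 0) + sum(seg$mask == 127) + sum(seg$mask == 255),
               length(cell$image))
  expect_equal(f[["nucleus_size"]] + f[["cytoplasm_size"]],
               seg$cytoplasm$size)
  # nucleus members are a subset of the cytoplasm-pass members
  expect_true(all(seg$cytoplasm$member[seg$nucleus$member]))
  # grey-sum conservation across the two passes
  expect_equal(f[["nucleus_grey"]] * f[["nucleus_size"]] +
                 f[["cytoplasm_grey"]] * f[["cytoplasm_size"]],
               seg$cytoplasm$grey_sum)
})

test_that("degenerate cytoplasm growth errors", {
  img <- matrix(100L, 10, 10)
  expect_error(segment_and_extract(img, c(beta_NC = 50, beta_CB = 50),
                                   c(x = 5, y = 5)),
               "degenerate cytoplasm")
})

test_that("noisy segmentation stays within 5% of ground truth sizes", {
  cell <- generate_cell_image(cell_spec(noise_sd = 5, seed = 31))
  res <- run_afe_pipeline(cell$image)
  expect_lt(abs(res$features[["nucleus_size"]] - cell$truth$nucleus_size) /
              cell$truth$nucleus_size, 0.05)
  expect_lt(abs(res$features[["cytoplasm_size"]] - cell$truth$cytoplasm_size) /
              cell$truth$cytoplasm_size, 0.05)
})

test_that("normal and HSIL presets reproduce the expected morphology contrast", {
  nrm <- run_afe_pipeline(generate_cell_image(
    cell_spec_preset("normal", noise_sd = 3, seed = 41))$image)
  hsil <- run_afe_pipeline(generate_cell_image(
    cell_spec_preset("HSIL", noise_sd = 3, seed = 41))$image)
  expect_lt(nrm$features[["nucleus_size"]], hsil$features[["nucleus_size"]])
  expect_gt(nrm$features[["cytoplasm_size"]], hsil$features[["cytoplasm_size"]])
})
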