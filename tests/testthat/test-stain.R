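test_that("optical density transform: closed forms and round trip", {
  img <- array(255, c(2, 2, 3))
  expect_equal(rgb_to_od(img)$od, array(0, c(2, 2, 3)))
  img[1, 1, 2] <- 25.5
  expect_equal(rgb_to_od(img)$od[1, 1, 2], 1.0)
  expect_error(rgb_to_od(matrix(1, 3, 3)), "RGB")
  expect_error(rgb_to_od(img, io = 0), "positive")
  set.seed(2)
  for (i in 1:3) {
    r <- array(sample(0:255, 300, TRUE), c(10, 10, 3))
    back <- od_to_rgb(rgb_to_od(r))
    expect_true(max(abs(back - pmax(r, 1))) <= 1)
  }
})

test_that("stain-vector estimation recovers the generating matrix", {
  truth <- default_stain_model()
  cfg <- sim_config(seed = 7, field_width_um = 300, field_height_um = 300)
  lay <- sample_cell_layout(cfg)
  set.seed(8)
  tile <- render_tile(lay, noise_sd = 0)
  m <- estimate_stain_vectors(rgb_to_od(tile$image))
  for (j in 1:2)
    expect_lt(tilquant:::vector_angle_deg(m$vectors[, j],
                                          truth$vectors[, j]), 2)
  # pure background tile
  blank <- array(255, c(50, 50, 3))
  expect_error(estimate_stain_vectors(rgb_to_od(blank)), "beta")
})

test_that("estimation error grows with OD noise but stays bounded
           on dense two-stain phantoms", {
  truth <- default_stain_model()
  err <- sapply(c(0, 0.02, 0.05), function(ns) {
    mean(sapply(1:3, function(s) {
      set.seed(s)
      ph <- render_stain_phantom(150, 150, noise_sd = ns)
      m <- estimate_stain_vectors(rgb_to_od(ph$image))
      mean(c(tilquant:::vector_angle_deg(m$vectors[, 1], truth$vectors[, 1]),
             tilquant:::vector_angle_deg(m$vectors[, 2], truth$vectors[, 2])))
    }))
  })
  expect_lt(err[1], 2)
  expect_lt(err[3], 5)
  # error grows with noise once it dominates 8-bit quantization (tiny
  # noise dithers the quantizer, so the curve is not monotone near zero)
  expect_gt(err[3], err[2])
})

test_that("estimation is a pixel-population statistic: invariant to
           rotation and pixel shuffling", {
  cfg <- sim_config(seed = 13, field_width_um = 200, field_height_um = 200)
  set.seed(14)
  tile <- render_tile(sample_cell_layout(cfg), noise_sd = 0.01)
  m0 <- estimate_stain_vectors(rgb_to_od(tile$image))
  rot <- aperm(tile$image, c(2, 1, 3))[dim(tile$image)[2]:1, , ]
  m1 <- estimate_stain_vectors(rgb_to_od(rot))
  set.seed(15)
  idx <- sample(prod(dim(tile$image)[1:2]))
  shuf <- array(apply(tile$image, 3, function(ch) ch[idx]),
                dim = dim(tile$image))
  m2 <- estimate_stain_vectors(rgb_to_od(shuf))
  expect_equal(m0$vectors, m1$vectors, tolerance = 1e-9)
  expect_equal(m0$vectors, m2$vectors, tolerance = 1e-9)
})

test_that("concentration inversion: closed forms and linear-algebra
           round trip", {
  model <- default_stain_model()
  S <- model$vectors
  expect_equal(as.numeric(compute_concentrations(rbind(S[, 1]), model)),
               c(1, 0), tolerance = 1e-10)
  expect_equal(as.numeric(compute_concentrations(rbind(c(0, 0, 0)), model)),
               c(0, 0), tolerance = 1e-12)
  set.seed(5)
  cc <- matrix(runif(200, 0, 2), 100, 2)
  od <- cc %*% t(S)
  expect_equal(unname(compute_concentrations(od, model)), unname(cc),
               tolerance = 1e-6)
  bad <- stain_model(cbind(c(0.6, 0.7, 0.3), c(0.07, 0.99, 0.11)))
  bad$vectors[, 2] <- bad$vectors[, 1]
  expect_error(compute_concentrations(od, bad), "collinear")
})

test_that("normalization: self-idempotence, convergence of different
           stains, background preservation", {
  cfg <- sim_config(seed = 17, field_width_um = 250, field_height_um = 250)
  lay <- sample_cell_layout(cfg)
  set.seed(18)
  tile <- render_tile(lay, noise_sd = 0)
  m <- estimate_stain_vectors(rgb_to_od(tile$image))
  self <- normalize_image(tile$image, m, m)
  expect_lt(mean(abs(self - tile$image)), 2)
  twice <- normalize_image(self, m, m)
  expect_lt(mean(abs(twice - self)), 2)

  # same concentration field through two different stain matrices
  alt <- stain_model(cbind(c(0.55, 0.75, 0.37), c(0.15, 0.95, 0.27)))
  set.seed(18)
  tile_alt <- render_tile(lay, stain = alt, noise_sd = 0)
  m_alt <- estimate_stain_vectors(rgb_to_od(tile_alt$image))
  ref <- m
  n1 <- normalize_image(tile$image, m, ref)
  n2 <- normalize_image(tile_alt$image, m_alt, ref)
  expect_lt(mean(abs(n1 - n2)), 3)

  bg <- tile$concentration[, , 1] == 0 & tile$concentration[, , 2] == 0
  for (ch in 1:3)
    expect_true(all(abs(n1[, , ch][bg] - 255) <= 2))

  m0 <- m; m0$scale <- c(0, 0)
  expect_error(normalize_image(tile$image, m0, ref), "scale")
})

test_that("fit_reference composes estimation and persists the model", {
  set.seed(3)
  ph <- render_stain_phantom(120, 120)
  path <- tempfile(fileext = ".json")
  m <- fit_reference(ph$image, path = path)
  expect_true(file.exists(path))
  m2 <- read_stain_model(path)
  expect_equal(m$vectors, m2$vectors, tolerance = 1e-9)
  expect_equal(m$scale, m2$scale, tolerance = 1e-9)
})
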