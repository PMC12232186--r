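test_that("detection: blank tile, missing pixel size, exact grid count", {
  blank <- matrix(0, 100, 100)
  expect_equal(max(detect_nuclei(blank, pixel_size_um = 0.5)), 0L)
  expect_error(detect_nuclei(blank, pixel_size_um = NA), "pixel size")

  tile <- render_tile(grid_layout(50), noise_sd = 0)
  nuc <- detect_nuclei(tile$concentration[, , 1],
                       pixel_size_um = tile$pixel_size_um)
  expect_equal(max(nuc), 50L)
  f <- extract_features(nuc, conc = tile$concentration,
                        pixel_size_um = tile$pixel_size_um)
  rep_ <- evaluate_classification(
    data.frame(x_um = f$x_um, y_um = f$y_um, class = "tumor"),
    tile$truth[, c("x_um", "y_um", "class")], match_radius = 2)
  expect_equal(nrow(attr(rep_, "matching")), 50L)
})

test_that("watershed splits touching nuclei at a smoothing scale below
           their separation", {
  cells <- data.frame(class = "immune", x_um = c(47.5, 52.5), y_um = 50,
                      r_major_um = 3.5, r_minor_um = 3.5, theta = 0)
  tile <- render_tile(cell_layout(cells, 100, 100), noise_sd = 0)
  nuc <- detect_nuclei(tile$concentration[, , 1],
                       pixel_size_um = tile$pixel_size_um, sigma_um = 0.5)
  expect_equal(max(nuc), 2L)
})

test_that("detection count is conserved under translation and rotation", {
  tile <- render_tile(grid_layout(20), noise_sd = 0)
  n0 <- max(detect_nuclei(tile$concentration[, , 1],
                          pixel_size_um = tile$pixel_size_um))
  lay_t <- grid_layout(20)
  lay_t$cells$x_um <- lay_t$cells$x_um + 7
  lay_t$cells$y_um <- lay_t$cells$y_um + 13
  lay_t$width_um <- lay_t$width_um + 20
  lay_t$height_um <- lay_t$height_um + 20
  tile_t <- render_tile(lay_t, noise_sd = 0)
  expect_equal(max(detect_nuclei(tile_t$concentration[, , 1],
                                 pixel_size_um = tile_t$pixel_size_um)), n0)
  rot <- t(tile$concentration[, , 1])[, seq_len(nrow(tile$concentration))]
  rot <- t(tile$concentration[, , 1])
  expect_equal(max(detect_nuclei(rot[, ncol(rot):1],
                                 pixel_size_um = tile$pixel_size_um)), n0)
})

test_that("cell expansion: zero radius is identity, growth matches
           brute-force dilation, adjacent cells partition", {
  tile <- render_tile(grid_layout(1, radius = 4, spacing = 50,
                                  width = 100, height = 100), noise_sd = 0)
  nuc <- detect_nuclei(tile$concentration[, , 1],
                       pixel_size_um = tile$pixel_size_um)
  expect_identical(expand_cells(nuc, 0), nuc)
  r_um <- 5
  cel <- expand_cells(nuc, r_um)
  # brute force: pixel belongs to the cell iff within r of a nucleus pixel
  ps <- tile$pixel_size_um
  idx_n <- which(nuc > 0, arr.ind = TRUE)
  idx_all <- which(cel >= 0, arr.ind = TRUE)
  d2 <- outer(idx_all[, 1], idx_n[, 1], `-`)^2 +
    outer(idx_all[, 2], idx_n[, 2], `-`)^2
  brute <- matrix(FALSE, nrow(nuc), ncol(nuc))
  brute[idx_all[sqrt(apply(d2, 1, min)) * ps <= r_um, ]] <- TRUE
  agree <- mean((cel > 0) == brute)
  expect_gt(agree, 0.995)  # only boundary-pixel discretization differs
  expect_true(all(cel[nuc > 0] == nuc[nuc > 0]))

  cells2 <- data.frame(class = "immune", x_um = c(44, 56), y_um = 50,
                       r_major_um = 3, r_minor_um = 3, theta = 0)
  tile2 <- render_tile(cell_layout(cells2, 100, 100), noise_sd = 0)
  nuc2 <- detect_nuclei(tile2$concentration[, , 1],
                        pixel_size_um = tile2$pixel_size_um,
                        sigma_um = 0.5)
  cel2 <- expand_cells(nuc2, 6)
  expect_equal(max(nuc2), 2L)
  a <- tabulate(cel2[cel2 > 0], 2)
  n <- tabulate(nuc2[nuc2 > 0], 2)
  expect_true(all(a >= n))       # cell area >= nucleus area
  expect_equal(max(cel2), 2L)    # labels partition, no merge
})

test_that("features: disk circularity, analytic ellipse eccentricity,
           fixed schema, degenerate flag", {
  conc <- array(0.5, c(100, 100, 2))
  disk <- ellipse_mask(25, 25, 6, 6)
  f <- extract_features(disk, conc = conc, pixel_size_um = 0.5)
  expect_true(f$circularity >= 0.9 && f$circularity <= 1)
  ell <- ellipse_mask(25, 25, 9, 3, theta = 0.7)
  f2 <- extract_features(ell, conc = conc, pixel_size_um = 0.5)
  expect_equal(f2$eccentricity, sqrt(1 - (1 / 3)^2), tolerance = 0.02)
  expect_equal(names(f)[4:22], til_feature_names())
  expect_identical(names(f), names(f2))
  one <- matrix(0L, 20, 20); one[10, 10] <- 1L
  f3 <- extract_features(one, conc = array(0.5, c(20, 20, 2)),
                         pixel_size_um = 0.5)
  expect_true(f3$degenerate)
  expect_gt(f3$nucleus_perimeter, 0)
})

test_that("classifier: separable data, determinism, validation", {
  set.seed(6)
  n <- 40
  base <- as.data.frame(matrix(runif(2 * n * 19), 2 * n, 19))
  names(base) <- til_feature_names()
  base$nucleus_area <- c(rnorm(n, 10, 1), rnorm(n, 100, 5))
  labs <- rep(c("immune", "tumor"), each = n)
  clf <- train_classifier(base, labs, hidden = 4, seed = 2)
  pred <- classify_cells(clf, base)
  expect_equal(mean(as.character(pred$class) == labs), 1.0)
  expect_equal(unname(rowSums(pred$posteriors)), rep(1, 2 * n),
               tolerance = 1e-6)
  clf2 <- train_classifier(base, labs, hidden = 4, seed = 2)
  expect_identical(classify_cells(clf2, base)$class, pred$class)
  expect_error(train_classifier(base, rep("immune", 2 * n)), "2 classes")
  expect_error(train_classifier(base[, -1], labs), "nucleus_area")
  expect_error(classify_cells(clf, base[, -3]), "circularity")
})

test_that("evaluation: perfect agreement, empty predictions, brute-force
           confusion equivalence", {
  truth <- data.frame(x_um = runif(30, 0, 100), y_um = runif(30, 0, 100),
                      class = sample(c("tumor", "immune", "stromal"), 30,
                                     TRUE))
  r <- evaluate_classification(truth, truth, match_radius = 1)
  expect_true(all(r$precision == 1 & r$recall == 1 & r$f1 == 1))
  r0 <- evaluate_classification(truth[0, ], truth, match_radius = 5)
  expect_true(all(r0$recall == 0 & r0$f1 == 0))
  expect_error(evaluate_classification(truth, truth, match_radius = 0),
               "positive")
  set.seed(8)
  for (i in 1:25) {
    tr <- sample(c("a", "b", "c", "d"), 60, TRUE)
    pr <- sample(c("a", "b", "c", "d"), 60, TRUE)
    rep_ <- classification_report(tr, pr)
    expect_equal(rep_$f1, unname(brute_f1(tr, pr)), tolerance = 1e-12)
  }
})
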