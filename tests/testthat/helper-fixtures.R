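# Fixture builders and independent brute-force oracles used across tests.

# Regular grid of identical nuclei, guaranteed non-touching.
grid_layout <- function(n = 50, class = "tumor", radius = 5,
                        spacing = 20, width = 200, height = 200) {
  pos <- expand.grid(x = seq(spacing, width - spacing, by = spacing),
                     y = seq(spacing, height - spacing, by = spacing))
  pos <- pos[seq_len(n), ]
  cell_layout(data.frame(class = class, x_um = pos$x, y_um = pos$y,
                         r_major_um = radius, r_minor_um = radius,
                         theta = 0),
              width, height)
}

# Exact rasterized ellipse mask (no smoothing, no detection).
ellipse_mask <- function(cx, cy, a, b, theta = 0, nx = 100, ny = 100,
                         ps = 0.5) {
  xs <- ((1:nx) - 0.5) * ps
  ys <- ((1:ny) - 0.5) * ps
  dx <- outer(rep(1, ny), xs - cx)
  dy <- outer(ys - cy, rep(1, nx))
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  lab <- matrix(0L, ny, nx)
  lab[(u / a)^2 + (v / b)^2 <= 1] <- 1L
  attr(lab, "pixel_size_um") <- ps
  lab
}

# Winding-number point-in-polygon with explicit boundary test; an
# algorithm independent of the ray-casting implementation.
brute_pip <- function(px, py, poly) {
  n <- nrow(poly)
  on_boundary <- function(x, y) {
    for (i in seq_len(n)) {
      j <- if (i == 1) n else i - 1
      x1 <- poly[j, 1]; y1 <- poly[j, 2]
      x2 <- poly[i, 1]; y2 <- poly[i, 2]
      L2 <- (x2 - x1)^2 + (y2 - y1)^2
      t <- if (L2 == 0) 0 else ((x - x1) * (x2 - x1) + (y - y1) * (y2 - y1)) / L2
      t <- min(max(t, 0), 1)
      if ((x - (x1 + t * (x2 - x1)))^2 + (y - (y1 + t * (y2 - y1)))^2 < 1e-18)
        return(TRUE)
    }
    FALSE
  }
  vapply(seq_along(px), function(i) {
    if (on_boundary(px[i], py[i])) return(TRUE)
    ang <- 0
    for (k in seq_len(n)) {
      j <- if (k == 1) n else k - 1
      a1 <- atan2(poly[j, 2] - py[i], poly[j, 1] - px[i])
      a2 <- atan2(poly[k, 2] - py[i], poly[k, 1] - px[i])
      d <- a2 - a1
      if (d > pi) d <- d - 2 * pi
      if (d < -pi) d <- d + 2 * pi
      ang <- ang + d
    }
    abs(ang) > pi
  }, logical(1))
}

# ICC(2,1) straight from aov() sums of squares.
brute_icc21 <- function(m) {
  df <- data.frame(v = as.vector(m),
                   case = factor(rep(seq_len(nrow(m)), ncol(m))),
                   rater = factor(rep(seq_len(ncol(m)), each = nrow(m))))
  tab <- summary(stats::aov(v ~ case + rater, data = df))[[1]]
  msr <- tab["case", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  n <- nrow(m); k <- ncol(m)
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# Kendall W written directly from the tied-rank definition.
brute_kendall_w <- function(m) {
  n <- nrow(m); k <- ncol(m)
  r <- apply(m, 2, rank)
  s <- sum((rowSums(r) - k * (n + 1) / 2)^2)
  tt <- sum(apply(m, 2, function(x) {
    tab <- table(x); sum(tab^3 - tab)
  }))
  12 * s / (k^2 * (n^3 - n) - k * tt)
}

# Per-class confusion-matrix F1, loop form.
brute_f1 <- function(truth, pred) {
  classes <- sort(unique(c(truth, pred)))
  sapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    if (p + r == 0) 0 else 2 * p * r / (p + r)
  })
}

# Two-group log-rank chi-square from first principles (risk tables).
brute_logrank <- function(time, event, group) {
  g <- as.integer(factor(group))
  stopifnot(max(g) == 2)
  times <- sort(unique(time[event == 1]))
  o_minus_e <- 0; v <- 0
  for (t in times) {
    at_risk <- time >= t
    n1 <- sum(at_risk & g == 1); n2 <- sum(at_risk & g == 2)
    d1 <- sum(time == t & event == 1 & g == 1)
    d2 <- sum(time == t & event == 1 & g == 2)
    d <- d1 + d2; nn <- n1 + n2
    if (nn < 2) next
    o_minus_e <- o_minus_e + d1 - d * n1 / nn
    v <- v + d * (n1 / nn) * (n2 / nn) * (nn - d) / (nn - 1)
  }
  o_minus_e^2 / v
}

# Survival data with an effect whose sign flips at t_flip (violates
# proportional hazards by construction).
sim_flip_cohort <- function(n, beta = 1, t_flip = 10, h0 = 0.02,
                            cmax = 120) {
  g <- rep(0:1, length.out = n)
  u <- runif(n)
  h1 <- h0 * exp(beta * g)   # hazard before the flip
  h2 <- h0 * exp(-beta * g)  # hazard after
  tt <- ifelse(-log(u) < h1 * t_flip,
               -log(u) / h1,
               t_flip + (-log(u) - h1 * t_flip) / h2)
  cc <- runif(n, 0, cmax)
  data.frame(time_months = pmin(tt, cc), event = as.integer(tt <= cc),
             group = factor(ifelse(g == 1, "high", "low"),
                            levels = c("low", "high")))
}

# Collect labeled feature sets from rendered tiles by running the full
# detect -> features -> match-to-truth path.
harvest_labeled_cells <- function(seeds, field = 650, noise = 0.01) {
  feats <- NULL; labs <- NULL
  for (s in seeds) {
    cfg <- sim_config(seed = s, field_width_um = field,
                      field_height_um = field)
    lay <- sample_cell_layout(cfg)
    set.seed(s + 5000L)
    tile <- render_tile(lay, noise_sd = noise)
    od <- rgb_to_od(tile$image)
    model <- estimate_stain_vectors(od)
    conc <- compute_concentrations(od, model)
    nuc <- detect_nuclei(conc[, , 1], pixel_size_um = tile$pixel_size_um)
    cel <- expand_cells(nuc, 5)
    f <- extract_features(nuc, cel, conc,
                          pixel_size_um = tile$pixel_size_um)
    rep_ <- evaluate_classification(
      data.frame(x_um = f$x_um, y_um = f$y_um, class = "u"),
      tile$truth[, c("x_um", "y_um", "class")], match_radius = 5)
    pairs <- attr(rep_, "matching")
    ll <- rep(NA_character_, nrow(f))
    if (!is.null(pairs) && nrow(pairs))
      ll[pairs[, 1]] <- as.character(tile$truth$class)[pairs[, 2]]
    ok <- !is.na(ll)
    feats <- rbind(feats, f[ok, , drop = FALSE])
    labs <- c(labs, ll[ok])
  }
  list(features = feats, labels = labs)
}
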