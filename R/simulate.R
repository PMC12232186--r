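#' Simulation configuration
#'
#' Bundles every parameter the synthetic-data generators use: cell densities
#' and per-class nuclear morphology for tile generation, stain concentrations
#' per class, optical-density noise, the geometry of the operator study
#' (cases x raters) with a target intraclass correlation, the ordinal Clark
#' grading model, and the survival cohort (sample size, true hazard ratio,
#' baseline hazard, censoring window).
#'
#' Defaults mirror the design of a multi-operator melanoma TIL study:
#' 60 cases scored by 38 AI-arm operators (29 in the manual arm), a target
#' ICC of 0.94 for the machine-derived score, a testing cohort of 111
#' subjects with a true hazard ratio of 0.45 for the high-TIL group, and a
#' scanner pixel size of 0.4986 um.
#'
#' @param seed integer seed; all generator randomness flows from it.
#' @param field_width_um,field_height_um tile dimensions in micrometers.
#' @param pixel_size_um micrometers per pixel (default 0.4986).
#' @param densities named vector, cells per mm^2 for classes
#'   \code{tumor, stromal, immune, other}.
#' @param morphology per-class list with \code{radius_um} (semi-major axis
#'   range), \code{axis_ratio} (major/minor range), \code{cyto_scale}
#'   (cytoplasm ellipse scale factor) and stain concentrations
#'   \code{nucleus_h, nucleus_e, cyto_e} in OD units at unit stain vector.
#' @param noise_sd Gaussian optical-density noise (OD units, base 10).
#' @param n_cases,n_raters,n_raters_manual operator-study geometry.
#' @param target_icc case-variance share of total score variance, i.e. the
#'   population ICC(2,1) of simulated score matrices; in [0, 1).
#' @param rater_share fraction of the non-case variance assigned to the
#'   systematic rater effect (the rest is residual).
#' @param score_mean,score_var marginal mean and total variance of scores.
#' @param clark_latent_icc latent-scale ICC controlling ordinal agreement.
#' @param clark_breaks latent marginal quantiles separating sparse/nonbrisk
#'   and nonbrisk/brisk grades.
#' @param n_subjects survival cohort size.
#' @param hazard_ratio true hazard ratio of the high-TIL group vs low.
#' @param baseline_hazard events per month in the low group (exponential).
#' @param censor_max upper bound of the independent uniform censoring time
#'   (months).
#' @param beta_sex,beta_age,beta_stage log-hazard effects of the covariates
#'   (age effect per year, centered at 60; stage effects vs stage I).
#' @return an object of class \code{til_sim_config} (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       field_width_um = 500,
                       field_height_um = 500,
                       pixel_size_um = 0.4986,
                       densities = c(tumor = 400, stromal = 400,
                                     immune = 600, other = 200),
                       morphology = default_morphology(),
                       noise_sd = 0.01,
                       n_cases = 60L,
                       n_raters = 38L,
                       n_raters_manual = 29L,
                       target_icc = 0.94,
                       rater_share = 0.3,
                       score_mean = 20,
                       score_var = 25,
                       clark_latent_icc = 0.5,
                       clark_breaks = c(1 / 3, 2 / 3),
                       n_subjects = 111L,
                       hazard_ratio = 0.45,
                       baseline_hazard = 0.015,
                       censor_max = 150,
                       beta_sex = 0,
                       beta_age = 0,
                       beta_stage = c(II = 0, III = 0, IV = 0)) {
  classes <- c("tumor", "stromal", "immune", "other")
  if (field_width_um <= 0 || field_height_um <= 0)
    stop("field dimensions must be positive")
  if (pixel_size_um <= 0) stop("pixel_size_um must be positive")
  if (!all(classes %in% names(densities)))
    stop("densities must name all of: ", paste(classes, collapse = ", "))
  if (any(densities < 0)) stop("densities must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (target_icc < 0 || target_icc >= 1)
    stop("target_icc must lie in [0, 1)")
  if (clark_latent_icc < 0 || clark_latent_icc >= 1)
    stop("clark_latent_icc must lie in [0, 1)")
  if (rater_share < 0 || rater_share > 1) stop("rater_share must be in [0, 1]")
  if (score_var < 0) stop("score_var must be >= 0")
  if (baseline_hazard <= 0) stop("baseline_hazard must be positive")
  if (censor_max < 0) stop("censoring window must be non-negative")
  cfg <- list(seed = as.integer(seed),
              field_width_um = field_width_um,
              field_height_um = field_height_um,
              pixel_size_um = pixel_size_um,
              densities = densities[classes],
              morphology = morphology,
              noise_sd = noise_sd,
              n_cases = as.integer(n_cases),
              n_raters = as.integer(n_raters),
              n_raters_manual = as.integer(n_raters_manual),
              target_icc = target_icc,
              rater_share = rater_share,
              score_mean = score_mean,
              score_var = score_var,
              clark_latent_icc = clark_latent_icc,
              clark_breaks = clark_breaks,
              n_subjects = as.integer(n_subjects),
              hazard_ratio = hazard_ratio,
              baseline_hazard = baseline_hazard,
              censor_max = censor_max,
              beta_sex = beta_sex,
              beta_age = beta_age,
              beta_stage = beta_stage)
  class(cfg) <- "til_sim_config"
  cfg
}

#' Default per-class nuclear morphology and staining
#'
#' Immune nuclei are small, near-circular and strongly hematoxylin-dense;
#' tumor nuclei large with a wide eosinophilic cytoplasm; stromal nuclei
#' elongated (axis ratio >= 2.5) in eosin-rich tissue; "other" covers
#' weakly-stained debris blobs. Cytoplasm carries eosin only and nuclei
#' hematoxylin (plus a trace of eosin for debris), so tiles contain
#' near-pure pixels of both stains.
#'
#' @return named list of per-class parameter lists.
#' @export
default_morphology <- function() {
  list(
    tumor   = list(radius_um = c(5, 10),    axis_ratio = c(1, 1.5),
                   cyto_scale = 1.8, nucleus_h = 0.65, nucleus_e = 0,
                   cyto_e = 0.40),
    stromal = list(radius_um = c(6, 12),    axis_ratio = c(2.5, 4),
                   cyto_scale = 1.5, nucleus_h = 0.55, nucleus_e = 0,
                   cyto_e = 0.55),
    immune  = list(radius_um = c(2.5, 4),   axis_ratio = c(1, 1.2),
                   cyto_scale = 1.15, nucleus_h = 1.10, nucleus_e = 0,
                   cyto_e = 0.15),
    other   = list(radius_um = c(1.5, 3.5), axis_ratio = c(1, 2),
                   cyto_scale = 1.3, nucleus_h = 0.35, nucleus_e = 0.10,
                   cyto_e = 0.20)
  )
}

#' Sample a ground-truth cell layout
#'
#' Cell counts per class are Poisson with mean density x field area; cell
#' centers are uniform over the field; nuclear semi-axes and orientations
#' are drawn from the per-class morphology ranges. Deterministic given
#' \code{config$seed}.
#'
#' @param config a \code{\link{sim_config}} object.
#' @return object of class \code{cell_layout}: a list with a \code{cells}
#'   data frame (class, centroid in um, semi-axes in um, orientation in
#'   radians), field dimensions and pixel size.
#' @export
sample_cell_layout <- function(config) {
  stopifnot(inherits(config, "til_sim_config"))
  set.seed(config$seed)
  area_mm2 <- config$field_width_um * config$field_height_um / 1e6
  out <- lapply(names(config$densities), function(cl) {
    n <- stats::rpois(1L, config$densities[[cl]] * area_mm2)
    if (n == 0L) return(NULL)
    m <- config$morphology[[cl]]
    a <- stats::runif(n, m$radius_um[1], m$radius_um[2])
    ratio <- stats::runif(n, m$axis_ratio[1], m$axis_ratio[2])
    data.frame(class = cl,
               x_um = stats::runif(n, 0, config$field_width_um),
               y_um = stats::runif(n, 0, config$field_height_um),
               r_major_um = a,
               r_minor_um = a / ratio,
               theta = stats::runif(n, 0, pi),
               stringsAsFactors = FALSE)
  })
  cells <- do.call(rbind, out)
  if (is.null(cells))
    cells <- data.frame(class = character(), x_um = numeric(),
                        y_um = numeric(), r_major_um = numeric(),
                        r_minor_um = numeric(), theta = numeric(),
                        stringsAsFactors = FALSE)
  if (nrow(cells)) {
    cells <- cells[sample.int(nrow(cells)), , drop = FALSE]
    cells$id <- seq_len(nrow(cells))
    rownames(cells) <- NULL
  } else {
    cells$id <- integer()
  }
  structure(list(cells = cells,
                 width_um = config$field_width_um,
                 height_um = config$field_height_um,
                 pixel_size_um = config$pixel_size_um,
                 morphology = config$morphology),
            class = "cell_layout")
}

#' Render a layout into an H&E-like RGB tile
#'
#' Builds per-pixel hematoxylin and eosin concentration maps from the
#' layout (nucleus ellipse carries the class's hematoxylin concentration,
#' the surrounding cytoplasm ellipse its eosin concentration; overlaps take
#' the maximum), converts to optical density through the stain matrix, adds
#' Gaussian OD noise, and maps to transmitted light as
#' \code{Io * 10^(-OD)} quantized to 8 bits. Background (no cell) has zero
#' concentration and renders at intensity Io.
#'
#' Uses the current RNG stream for noise; seed upstream for reproducibility.
#'
#' @param layout a \code{cell_layout}.
#' @param stain a \code{\link{stain_model}} providing the stain matrix.
#' @param noise_sd Gaussian OD noise standard deviation (>= 0).
#' @param io intensity ceiling (default 255).
#' @return object of class \code{rendered_tile}: list with \code{image}
#'   (numeric array [y, x, 3], 0..io integers), \code{truth} (data frame:
#'   id, class, x_um, y_um, nucleus_area_um2), \code{concentration}
#'   (array [y, x, 2], ground-truth H and E maps) and \code{pixel_size_um}.
#' @export
render_tile <- function(layout, stain = default_stain_model(),
                        noise_sd = 0, io = 255) {
  stopifnot(inherits(layout, "cell_layout"))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  validate_stain_model(stain)
  ps <- layout$pixel_size_um
  nx <- max(1L, as.integer(round(layout$width_um / ps)))
  ny <- max(1L, as.integer(round(layout$height_um / ps)))
  ch <- matrix(0, ny, nx)
  ce <- matrix(0, ny, nx)
  cells <- layout$cells
  for (i in seq_len(nrow(cells))) {
    m <- layout$morphology[[cells$class[i]]]
    a <- cells$r_major_um[i]; b <- cells$r_minor_um[i]
    s <- m$cyto_scale
    th <- cells$theta[i]
    ext <- a * s
    x0 <- cells$x_um[i]; y0 <- cells$y_um[i]
    ix <- max(1L, floor((x0 - ext) / ps)):min(nx, ceiling((x0 + ext) / ps))
    iy <- max(1L, floor((y0 - ext) / ps)):min(ny, ceiling((y0 + ext) / ps))
    if (!length(ix) || !length(iy)) next
    px <- (ix - 0.5) * ps - x0
    py <- (iy - 0.5) * ps - y0
    dx <- matrix(px, length(iy), length(ix), byrow = TRUE)
    dy <- matrix(py, length(iy), length(ix))
    u <- dx * cos(th) + dy * sin(th)
    v <- -dx * sin(th) + dy * cos(th)
    q <- (u / a)^2 + (v / b)^2
    nuc <- q <= 1
    cyto <- (q <= s^2) & !nuc
    sub_h <- ch[iy, ix, drop = FALSE]
    sub_e <- ce[iy, ix, drop = FALSE]
    sub_h[nuc] <- pmax(sub_h[nuc], m$nucleus_h)
    sub_e[nuc] <- pmax(sub_e[nuc], m$nucleus_e)
    sub_e[cyto] <- pmax(sub_e[cyto], m$cyto_e)
    ch[iy, ix] <- sub_h
    ce[iy, ix] <- sub_e
  }
  S <- stain$vectors
  img <- array(0, dim = c(ny, nx, 3L))
  for (c3 in 1:3) {
    od <- S[c3, 1L] * ch + S[c3, 2L] * ce
    if (noise_sd > 0)
      od <- od + matrix(stats::rnorm(ny * nx, 0, noise_sd), ny, nx)
    od <- pmax(od, 0)
    img[, , c3] <- clamp(round(io * 10^(-od)), 0, io)
  }
  truth <- data.frame(id = cells$id, class = cells$class,
                      x_um = cells$x_um, y_um = cells$y_um,
                      nucleus_area_um2 = pi * cells$r_major_um *
                        cells$r_minor_um,
                      stringsAsFactors = FALSE)
  structure(list(image = img, truth = truth,
                 concentration = array(c(ch, ce), dim = c(ny, nx, 2L),
                                       dimnames = list(NULL, NULL,
                                                       c("h", "e"))),
                 pixel_size_um = ps, io = io),
            class = "rendered_tile")
}

#' Simulate an operator score matrix with a target ICC
#'
#' Generates \code{x_ij = mu + b_i + r_j + e_ij} with case effects
#' \code{b_i ~ N(0, s_b^2)}, rater effects \code{r_j ~ N(0, s_r^2)} and
#' residuals \code{e_ij ~ N(0, s_e^2)}, where the variance components are
#' chosen so that \code{s_b^2 / (s_b^2 + s_r^2 + s_e^2)} equals
#' \code{config$target_icc} (the population ICC(2,1)). Deterministic given
#' \code{config$seed}.
#'
#' @param config a \code{\link{sim_config}}; uses \code{n_cases},
#'   \code{n_raters}, \code{target_icc}, \code{rater_share},
#'   \code{score_mean}, \code{score_var}.
#' @param n_raters optional override of the rater count.
#' @param target_icc optional override of the target ICC.
#' @param components optional explicit variance components
#'   \code{c(case, rater, residual)}; overrides the target-ICC
#'   parameterization (e.g. \code{c(1, 0, 0)} makes raters identical and
#'   the ICC exactly 1).
#' @return numeric matrix, cases in rows, raters in columns.
#' @export
simulate_score_matrix <- function(config, n_raters = config$n_raters,
                                  target_icc = config$target_icc,
                                  components = NULL) {
  stopifnot(inherits(config, "til_sim_config"))
  if (config$n_cases < 2L || n_raters < 2L)
    stop("need at least 2 cases and 2 raters")
  set.seed(config$seed)
  n <- config$n_cases; k <- as.integer(n_raters)
  if (is.null(components)) {
    if (target_icc < 0 || target_icc >= 1)
      stop("target_icc must lie in [0, 1)")
    s2b <- target_icc * config$score_var
    s2r <- config$rater_share * (1 - target_icc) * config$score_var
    s2e <- (1 - config$rater_share) * (1 - target_icc) * config$score_var
  } else {
    if (length(components) != 3L || any(components < 0))
      stop("components must be 3 non-negative variances")
    s2b <- components[1L]; s2r <- components[2L]; s2e <- components[3L]
  }
  b <- stats::rnorm(n, 0, sqrt(s2b))
  r <- stats::rnorm(k, 0, sqrt(s2r))
  e <- matrix(stats::rnorm(n * k, 0, sqrt(s2e)), n, k)
  m <- config$score_mean + outer(b, rep(1, k)) + outer(rep(1, n), r) + e
  dimnames(m) <- list(paste0("case_", seq_len(n)),
                      paste0("rater_", seq_len(k)))
  attr(m, "variance_components") <- c(case = s2b, rater = s2r, residual = s2e)
  m
}

#' Simulate an ordinal Clark-grade score matrix
#'
#' A latent continuous operator matrix (same two-way random-effects model
#' as \code{\link{simulate_score_matrix}}, agreement set by
#' \code{clark_latent_icc}) is thresholded at fixed marginal quantiles into
#' grades sparse = 1, nonbrisk = 2, brisk = 3.
#'
#' @param config a \code{\link{sim_config}}; uses \code{n_cases},
#'   \code{n_raters_manual}, \code{clark_latent_icc}, \code{clark_breaks}.
#' @param latent_icc optional override of the latent agreement level.
#' @return integer matrix with values in \{1, 2, 3\}.
#' @export
simulate_clark_matrix <- function(config,
                                  latent_icc = config$clark_latent_icc) {
  stopifnot(inherits(config, "til_sim_config"))
  if (config$n_cases < 2L) stop("need at least 2 cases")
  if (latent_icc < 0 || latent_icc >= 1)
    stop("latent agreement must lie in [0, 1)")
  set.seed(config$seed)
  n <- config$n_cases; k <- config$n_raters_manual
  b <- stats::rnorm(n, 0, sqrt(latent_icc))
  s2rest <- 1 - latent_icc
  r <- stats::rnorm(k, 0, sqrt(config$rater_share * s2rest))
  e <- matrix(stats::rnorm(n * k, 0,
                           sqrt((1 - config$rater_share) * s2rest)), n, k)
  latent <- outer(b, rep(1, k)) + outer(rep(1, n), r) + e
  cuts <- stats::qnorm(config$clark_breaks)  # latent marginal is N(0, 1)
  m <- matrix(1L + (latent > cuts[1]) + (latent > cuts[2]), n, k)
  dimnames(m) <- list(paste0("case_", seq_len(n)),
                      paste0("rater_", seq_len(k)))
  m
}

#' Simulate a survival cohort with a known hazard ratio
#'
#' Event times are exponential with hazard
#' \code{lambda0 * exp(beta * high + covariate effects)}; censoring is
#' independent Uniform(0, censor_max). Sex, age (Normal(61, 12) truncated
#' to 25..87) and stage (I..IV, stage-I-heavy) mimic a melanoma testing
#' cohort. Half the subjects are in the high-TIL group. Deterministic given
#' \code{config$seed}.
#'
#' @param config a \code{\link{sim_config}}.
#' @return data frame with columns \code{time_months}, \code{event},
#'   \code{sex}, \code{age}, \code{stage}, \code{group}.
#' @export
simulate_survival_cohort <- function(config) {
  stopifnot(inherits(config, "til_sim_config"))
  if (config$censor_max < 0) stop("censoring window must be non-negative")
  set.seed(config$seed)
  n <- config$n_subjects
  group <- factor(sample(rep(c("low", "high"), length.out = n)),
                  levels = c("low", "high"))
  sex <- factor(sample(c("F", "M"), n, replace = TRUE),
                levels = c("F", "M"))
  age <- round(clamp(stats::rnorm(n, 61, 12), 25, 87))
  stage <- factor(sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                         prob = c(0.5, 0.25, 0.15, 0.10)),
                  levels = c("I", "II", "III", "IV"))
  lp <- log(config$hazard_ratio) * (group == "high") +
    config$beta_sex * (sex == "M") +
    config$beta_age * (age - 60) +
    ifelse(stage == "I", 0, config$beta_stage[as.character(stage)])
  tt <- stats::rexp(n, rate = config$baseline_hazard * exp(lp))
  cc <- stats::runif(n, 0, config$censor_max)
  data.frame(time_months = pmin(tt, cc),
             event = as.integer(tt <= cc),
             sex = sex, age = age, stage = stage, group = group,
             stringsAsFactors = FALSE)
}

#' Render a two-stain Beer-Lambert phantom
#'
#' A dense random concentration field: each pixel draws independent
#' hematoxylin and eosin concentrations uniform on [0, conc_max], mixed
#' through the stain matrix with optional Gaussian OD noise and quantized
#' to 8 bits. Unlike \code{\link{render_tile}} (sparse cells on a blank
#' background), the phantom satisfies the coverage assumption of
#' Macenko-style estimation -- a continuum of stain mixtures with
#' near-pure pixels of both stains -- and is the appropriate fixture for
#' stain-vector recovery experiments.
#'
#' Uses the current RNG stream.
#'
#' @param width_px,height_px phantom dimensions in pixels.
#' @param stain a \code{\link{stain_model}}.
#' @param noise_sd Gaussian OD noise (>= 0).
#' @param conc_max upper bound of the uniform concentrations.
#' @param io intensity ceiling.
#' @return list with \code{image} (RGB array [y, x, 3]) and
#'   \code{concentration} (array [y, x, 2]).
#' @export
render_stain_phantom <- function(width_px = 200L, height_px = 200L,
                                 stain = default_stain_model(),
                                 noise_sd = 0, conc_max = 1.2, io = 255) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  validate_stain_model(stain)
  n <- as.integer(width_px) * as.integer(height_px)
  cc <- cbind(stats::runif(n, 0, conc_max), stats::runif(n, 0, conc_max))
  od <- cc %*% t(stain$vectors)
  if (noise_sd > 0) od <- od + matrix(stats::rnorm(3L * n, 0, noise_sd), n, 3L)
  od <- pmax(od, 0)
  img <- array(clamp(round(io * 10^(-od)), 0, io),
               c(height_px, width_px, 3L))
  list(image = img,
       concentration = array(cc, c(height_px, width_px, 2L),
                             dimnames = list(NULL, NULL, c("h", "e"))))
}

#' Construct a cell layout by hand
#'
#' Builds the same object \code{\link{sample_cell_layout}} returns, for
#' deterministic fixtures (e.g. a grid of non-touching nuclei or two
#' overlapping ones).
#'
#' @param cells data frame with columns \code{class, x_um, y_um,
#'   r_major_um, r_minor_um, theta} (an \code{id} column is added if
#'   absent).
#' @param width_um,height_um field dimensions (> 0).
#' @param pixel_size_um micrometers per pixel (> 0).
#' @param morphology per-class staining parameters (defaults to
#'   \code{\link{default_morphology}}).
#' @return an object of class \code{cell_layout}.
#' @export
cell_layout <- function(cells, width_um, height_um,
                        pixel_size_um = 0.4986,
                        morphology = default_morphology()) {
  if (width_um <= 0 || height_um <= 0) stop("field size must be positive")
  if (pixel_size_um <= 0) stop("pixel size must be positive")
  need <- c("class", "x_um", "y_um", "r_major_um", "r_minor_um", "theta")
  miss <- setdiff(need, names(cells))
  if (length(miss)) stop("cells lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(cells)) {
    if (any(cells$r_major_um <= 0) || any(cells$r_minor_um <= 0))
      stop("nucleus radii must be positive")
    if (any(cells$x_um < 0 | cells$x_um > width_um |
            cells$y_um < 0 | cells$y_um > height_um))
      stop("centroids must lie inside the field")
  }
  if (is.null(cells$id)) cells$id <- seq_len(nrow(cells))
  structure(list(cells = cells, width_um = width_um, height_um = height_um,
                 pixel_size_um = pixel_size_um, morphology = morphology),
            class = "cell_layout")
}
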