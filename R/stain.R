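#' Stain model
#'
#' Two unit stain vectors (hematoxylin, eosin) in base-10 optical-density
#' space together with per-stain concentration scales (99th-percentile
#' concentrations of the image the model was fitted to) and the estimation
#' parameters.
#'
#' @param vectors 3 x 2 matrix of non-negative OD components, columns
#'   hematoxylin then eosin; columns are normalized to unit length.
#' @param scale length-2 positive concentration scales (hematoxylin, eosin).
#' @param beta background OD-magnitude threshold used at estimation.
#' @param alpha angle percentile used at estimation.
#' @param io intensity ceiling of the source image.
#' @return an object of class \code{stain_model}.
#' @export
stain_model <- function(vectors, scale = c(1, 1), beta = 0.15, alpha = 1,
                        io = 255) {
  vectors <- apply(as.matrix(vectors), 2L, function(v) v / sqrt(sum(v^2)))
  colnames(vectors) <- c("hematoxylin", "eosin")
  m <- structure(list(vectors = vectors, scale = as.numeric(scale),
                      beta = beta, alpha = alpha, io = io),
                 class = "stain_model")
  validate_stain_model(m)
  m
}

#' @rdname stain_model
#' @param x object to validate.
#' @export
validate_stain_model <- function(x) {
  if (!inherits(x, "stain_model")) stop("not a stain_model")
  v <- x$vectors
  if (!is.matrix(v) || any(dim(v) != c(3L, 2L)))
    stop("stain vectors must form a 3 x 2 matrix")
  if (any(v < -1e-9)) stop("stain vector components must be non-negative")
  if (any(abs(colSums(v^2) - 1) > 1e-6))
    stop("stain vectors must have unit norm")
  if (vector_angle_deg(v[, 1L], v[, 2L]) <= 1)
    stop("stain vectors are collinear (angle <= 1 degree)")
  invisible(x)
}

#' Reference stain matrix
#'
#' Standard hematoxylin (0.65, 0.70, 0.29) and eosin (0.07, 0.99, 0.11)
#' OD vectors from the stain-deconvolution literature, unit-normalized.
#'
#' @param io intensity ceiling.
#' @return a \code{\link{stain_model}} with unit concentration scales.
#' @export
default_stain_model <- function(io = 255) {
  stain_model(cbind(c(0.65, 0.70, 0.29), c(0.07, 0.99, 0.11)), io = io)
}

#' RGB to optical density
#'
#' Beer-Lambert transform: \code{OD_c = -log10(max(pixel_c, 1) / Io)} per
#' channel. Zero pixels are mapped to 1 before the logarithm so the
#' transform stays finite; it is invertible up to 8-bit quantization.
#'
#' @param image numeric array [y, x, 3] with values in [0, Io].
#' @param io intensity ceiling (> 0), default 255.
#' @return object of class \code{od_image}: list with \code{od} (array
#'   [y, x, 3] of non-negative OD values) and \code{io}.
#' @export
rgb_to_od <- function(image, io = 255) {
  if (io <= 0) stop("io must be positive")
  if (length(dim(image)) != 3L || dim(image)[3L] != 3L)
    stop("input must be an RGB array [y, x, 3]")
  if (max(image) > io || min(image) < 0)
    stop("pixel values must lie in [0, io]")
  od <- -log10(pmax(image, 1) / io)
  structure(list(od = od, io = io), class = "od_image")
}

#' Optical density back to 8-bit RGB
#'
#' @param od an \code{od_image} or a bare OD array.
#' @param io intensity ceiling; defaults to the one stored in \code{od}.
#' @return numeric array [y, x, 3] of integers in [0, io].
#' @export
od_to_rgb <- function(od, io = NULL) {
  if (inherits(od, "od_image")) {
    io <- io %||% od$io
    od <- od$od
  }
  io <- io %||% 255
  clamp(round(io * 10^(-od)), 0, io)
}

# Flatten an od_image (or bare array) into an n x 3 pixel matrix.
od_pixels <- function(od) {
  a <- if (inherits(od, "od_image")) od$od else od
  dm <- dim(a)
  matrix(a, nrow = dm[1L] * dm[2L], ncol = 3L)
}

#' Estimate stain vectors from an optical-density image
#'
#' Macenko-style estimation: pixels with OD magnitude above \code{beta}
#' form the foreground; the top-2 eigenvectors of their OD covariance span
#' the stain plane; directions at the \code{alpha} and \code{100 - alpha}
#' angle percentiles within that plane are mapped back to OD space,
#' clamped to the non-negative orthant and unit-normalized. The vector with
#' the larger red:blue OD ratio is labeled hematoxylin (hematoxylin
#' absorbs red light most strongly). Per-stain 99th-percentile foreground
#' concentrations are recorded as the model's scales.
#'
#' Foreground pixels beyond \code{max_pixels} are subsampled with a fixed
#' stride, so the estimate is deterministic.
#'
#' @param od an \code{od_image} (see \code{\link{rgb_to_od}}).
#' @param beta background OD-magnitude threshold (default 0.15).
#' @param alpha extreme-angle percentile (default 1, i.e. 1st/99th).
#' @param max_pixels foreground subsample ceiling (default 200000).
#' @return a \code{\link{stain_model}}.
#' @export
estimate_stain_vectors <- function(od, beta = 0.15, alpha = 1,
                                   max_pixels = 200000L) {
  p <- od_pixels(od)
  io <- if (inherits(od, "od_image")) od$io else 255
  fg <- p[sqrt(rowSums(p^2)) > beta, , drop = FALSE]
  if (nrow(fg) < 100L)
    stop("fewer than 100 foreground pixels above the beta = ", beta,
         " OD threshold")
  if (nrow(fg) > max_pixels) {
    idx <- seq(1L, nrow(fg), length.out = max_pixels)
    fg <- fg[unique(as.integer(idx)), , drop = FALSE]
  }
  ev <- eigen(stats::cov(fg), symmetric = TRUE)
  if (ev$values[2L] < 1e-12 * max(ev$values[1L], 1e-300))
    stop("foreground OD covariance is rank-deficient; ",
         "cannot span a stain plane")
  basis <- ev$vectors[, 1:2, drop = FALSE]
  # orient the basis so projections are predominantly positive
  for (j in 1:2) if (sum(fg %*% basis[, j]) < 0) basis[, j] <- -basis[, j]
  proj <- fg %*% basis
  phi <- atan2(proj[, 2L], proj[, 1L])
  qs <- stats::quantile(phi, c(alpha, 100 - alpha) / 100, names = FALSE)
  vecs <- sapply(qs, function(a) {
    v <- basis %*% c(cos(a), sin(a))
    v <- pmax(as.numeric(v), 0)
    v / sqrt(sum(v^2))
  })
  # hematoxylin absorbs red more than blue; eosin the reverse
  rb <- (vecs[1L, ] + 1e-12) / (vecs[3L, ] + 1e-12)
  vecs <- vecs[, order(rb, decreasing = TRUE)]
  model <- stain_model(vecs, beta = beta, alpha = alpha, io = io)
  conc <- concentration_matrix(fg, model)
  model$scale <- as.numeric(apply(conc, 2L, stats::quantile, probs = 0.99,
                                  names = FALSE))
  model
}

# Least-squares concentrations for an n x 3 OD pixel matrix: solves
# OD = S C per pixel, negatives clamped to zero. Returns n x 2.
concentration_matrix <- function(pixels, model) {
  S <- model$vectors
  if (vector_angle_deg(S[, 1L], S[, 2L]) <= 1)
    stop("stain vectors are collinear; concentrations are not identifiable")
  cc <- t(solve(crossprod(S), t(S) %*% t(pixels)))
  cc[cc < 0] <- 0
  colnames(cc) <- c("hematoxylin", "eosin")
  cc
}

#' Per-pixel stain concentrations
#'
#' Least-squares inversion of the Beer-Lambert mixing model
#' \code{OD = S C} under a given stain model; negative solutions are
#' clamped to zero.
#'
#' @param od an \code{od_image}, a bare [y, x, 3] OD array, or an n x 3
#'   OD pixel matrix.
#' @param model a \code{\link{stain_model}}.
#' @return for image input, an array [y, x, 2] (hematoxylin, eosin); for
#'   matrix input, an n x 2 matrix.
#' @export
compute_concentrations <- function(od, model) {
  validate_stain_model(model)
  if (is.matrix(od)) return(concentration_matrix(od, model))
  a <- if (inherits(od, "od_image")) od$od else od
  dm <- dim(a)
  cc <- concentration_matrix(matrix(a, dm[1L] * dm[2L], 3L), model)
  array(cc, dim = c(dm[1L], dm[2L], 2L),
        dimnames = list(NULL, NULL, c("hematoxylin", "eosin")))
}

#' Normalize an image to a reference stain model
#'
#' Concentrations are computed under the source model, rescaled so each
#' stain's 99th-percentile concentration matches the reference scale, and
#' re-rendered through the reference stain matrix.
#'
#' @param image RGB array [y, x, 3].
#' @param source \code{stain_model} fitted to this image (or its batch).
#' @param reference \code{stain_model} of the reference image.
#' @param io intensity ceiling (default 255).
#' @return normalized 8-bit RGB array of the same dimensions.
#' @export
normalize_image <- function(image, source, reference, io = 255) {
  validate_stain_model(source)
  validate_stain_model(reference)
  if (any(source$scale <= 0))
    stop("source model has a zero 99th-percentile concentration scale")
  od <- rgb_to_od(image, io = io)
  dm <- dim(od$od)
  cc <- concentration_matrix(matrix(od$od, dm[1L] * dm[2L], 3L), source)
  cc <- sweep(cc, 2L, reference$scale / source$scale, `*`)
  od_new <- cc %*% t(reference$vectors)
  od_to_rgb(array(od_new, dim = dm), io = io)
}

#' Fit a reference stain model from an RGB image
#'
#' Composition of \code{\link{rgb_to_od}} and
#' \code{\link{estimate_stain_vectors}}; optionally persists the model as
#' JSON (see \code{\link{write_stain_model}}).
#'
#' @param image RGB array [y, x, 3].
#' @param beta,alpha estimation parameters.
#' @param io intensity ceiling.
#' @param path optional JSON output path.
#' @return a \code{\link{stain_model}}.
#' @export
fit_reference <- function(image, beta = 0.15, alpha = 1, io = 255,
                          path = NULL) {
  model <- estimate_stain_vectors(rgb_to_od(image, io = io),
                                  beta = beta, alpha = alpha)
  if (!is.null(path)) write_stain_model(model, path)
  model
}

#' @export
print.stain_model <- function(x, ...) {
  cat("Stain model (OD space, base 10)\n")
  v <- round(x$vectors, 4)
  cat("  hematoxylin: (", paste(v[, 1L], collapse = ", "), ")\n", sep = "")
  cat("  eosin:       (", paste(v[, 2L], collapse = ", "), ")\n", sep = "")
  cat("  concentration scales:", paste(round(x$scale, 4), collapse = ", "),
      "\n")
  cat("  beta =", x$beta, " alpha =", x$alpha, " Io =", x$io, "\n")
  invisible(x)
}
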