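# Nucleus detection, cell expansion, morphometric/chromatic features,
# MLP classification and evaluation.

# Fixed feature schema; order matters for the classifier.
til_feature_names <- function() {
  c("nucleus_area", "nucleus_perimeter", "circularity", "eccentricity",
    "max_caliper", "cell_area", "nucleus_cell_ratio",
    "h_mean_nuc", "h_min_nuc", "h_max_nuc",
    "e_mean_nuc", "e_min_nuc", "e_max_nuc",
    "h_mean_cyto", "h_min_cyto", "h_max_cyto",
    "e_mean_cyto", "e_min_cyto", "e_max_cyto")
}

#' Detect nuclei on the hematoxylin channel
#'
#' Gaussian smoothing (sigma in micrometers), threshold on the smoothed
#' hematoxylin signal, hole filling, distance-transform watershed to split
#' touching nuclei, then an area filter. Deterministic.
#'
#' @param hmap matrix [y, x] of hematoxylin concentration (or OD).
#' @param pixel_size_um micrometers per pixel; required.
#' @param sigma_um Gaussian smoothing sigma (default 1.5 um).
#' @param threshold foreground threshold on the smoothed signal
#'   (default 0.10).
#' @param min_area_um2,max_area_um2 nucleus area bounds (default 5..400).
#' @return integer label matrix [y, x]; labels 1..n, 0 = background, with
#'   attribute \code{pixel_size_um}.
#' @export
detect_nuclei <- function(hmap, pixel_size_um, sigma_um = 1.5,
                          threshold = 0.10, min_area_um2 = 5,
                          max_area_um2 = 400) {
  if (missing(pixel_size_um) || is.null(pixel_size_um) ||
      is.na(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel size (um/pixel) must be known and positive")
  stopifnot(is.matrix(hmap))
  img <- as_ebimage(hmap)
  sigma_px <- sigma_um / pixel_size_um
  sm <- EBImage::gblur(img, sigma = sigma_px)
  mask <- sm > threshold
  mask <- EBImage::fillHull(mask)
  if (sum(mask) == 0) {
    lab <- matrix(0L, nrow(hmap), ncol(hmap))
    attr(lab, "pixel_size_um") <- pixel_size_um
    return(lab)
  }
  dm <- EBImage::distmap(mask)
  ws <- EBImage::watershed(dm, tolerance = 1, ext = 1)
  lab <- from_ebimage(ws)
  # area filter in um^2
  px_area <- pixel_size_um^2
  tab <- tabulate(lab[lab > 0])
  keep <- which(tab * px_area >= min_area_um2 & tab * px_area <= max_area_um2)
  relab <- integer(length(tab))
  relab[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(lab), ncol(lab))
  nz <- lab > 0
  out[nz] <- relab[lab[nz]]
  attr(out, "pixel_size_um") <- pixel_size_um
  out
}

#' Expand nuclei into cell masks
#'
#' Distance-limited Voronoi expansion: each background pixel within
#' \code{radius_um} of a nucleus is assigned to its nearest nucleus
#' (geodesic label propagation), so cell masks partition the expanded
#' territory and never overlap.
#'
#' @param nuclei label matrix from \code{\link{detect_nuclei}}.
#' @param radius_um expansion radius (>= 0; 0 returns the nuclei).
#' @param pixel_size_um defaults to the attribute stored on \code{nuclei}.
#' @return integer label matrix of cell masks (same labels as nuclei).
#' @export
expand_cells <- function(nuclei, radius_um = 5,
                         pixel_size_um = attr(nuclei, "pixel_size_um")) {
  if (radius_um < 0) stop("radius_um must be >= 0")
  if (is.null(pixel_size_um)) stop("pixel size unknown")
  if (radius_um == 0 || !any(nuclei > 0)) return(nuclei)
  seeds <- as_ebimage(nuclei)
  dist_bg <- EBImage::distmap(as_ebimage(1 * (nuclei == 0)))
  mask <- (dist_bg <= radius_um / pixel_size_um) | (seeds > 0)
  cells <- EBImage::propagate(x = seeds * 0, seeds = seeds, mask = mask)
  out <- from_ebimage(cells)
  storage.mode(out) <- "integer"
  attr(out, "pixel_size_um") <- pixel_size_um
  out
}

#' Extract per-cell morphometric and chromatic features
#'
#' For each labeled nucleus/cell pair: nucleus area, perimeter, circularity
#' (4 pi A / P^2), eccentricity, max-caliper length (major axis), cell
#' area, nucleus/cell area ratio, and mean/min/max hematoxylin and eosin
#' concentrations inside the nucleus and in the cytoplasm ring (cell minus
#' nucleus). Areas are in um^2, lengths in um. One-pixel masks get a
#' one-pixel perimeter floor and are flagged \code{degenerate}.
#'
#' @param nuclei,cells label matrices (same label space).
#' @param conc concentration array [y, x, 2] (hematoxylin, eosin), e.g.
#'   from \code{\link{compute_concentrations}}.
#' @param pixel_size_um micrometers per pixel.
#' @return data frame: id, x_um, y_um, the feature columns of
#'   \code{til_feature_names()}, and a logical \code{degenerate} flag.
#' @export
extract_features <- function(nuclei, cells = nuclei, conc,
                             pixel_size_um = attr(nuclei, "pixel_size_um")) {
  if (is.null(pixel_size_um)) stop("pixel size unknown")
  nlab <- max(nuclei)
  feats <- til_feature_names()
  empty <- as.data.frame(matrix(numeric(), 0, length(feats) + 3L))
  names(empty) <- c("id", "x_um", "y_um", feats)
  if (nlab == 0) { empty$degenerate <- logical(); return(empty) }
  ps <- pixel_size_um
  nimg <- as_ebimage(nuclei)
  shape <- EBImage::computeFeatures.shape(nimg)
  mom <- EBImage::computeFeatures.moment(nimg)
  area_px <- shape[, "s.area"]
  perim_px <- pmax(shape[, "s.perimeter"], 1)  # perimeter floor
  degenerate <- area_px <= 1
  nucleus_area <- area_px * ps^2
  nucleus_perimeter <- perim_px * ps
  circularity <- pmin(4 * pi * area_px / perim_px^2, 1)
  cell_px <- tabulate(cells[cells > 0], nbins = nlab)
  cell_area <- pmax(cell_px, area_px) * ps^2
  # intensity stats by label
  nvec <- as.integer(nuclei); cvec <- as.integer(cells)
  h <- as.numeric(conc[, , 1L]); e <- as.numeric(conc[, , 2L])
  stat3 <- function(vals, labs) {
    f <- factor(labs, levels = seq_len(nlab))
    cbind(mean = tapply(vals, f, mean),
          min = tapply(vals, f, min),
          max = tapply(vals, f, max))
  }
  in_nuc <- nvec > 0
  nuc_h <- stat3(h[in_nuc], nvec[in_nuc])
  nuc_e <- stat3(e[in_nuc], nvec[in_nuc])
  ring <- cvec > 0 & nvec == 0
  if (any(ring)) {
    cy_h <- stat3(h[ring], cvec[ring])
    cy_e <- stat3(e[ring], cvec[ring])
  } else {
    cy_h <- cy_e <- matrix(NA_real_, nlab, 3L,
                           dimnames = list(NULL, c("mean", "min", "max")))
  }
  # cells with no ring (radius 0): zero cytoplasm signal
  cy_h[is.na(cy_h)] <- 0; cy_e[is.na(cy_e)] <- 0
  out <- data.frame(
    id = seq_len(nlab),
    x_um = (mom[, "m.cx"] - 0.5) * ps,
    y_um = (mom[, "m.cy"] - 0.5) * ps,
    nucleus_area = nucleus_area,
    nucleus_perimeter = nucleus_perimeter,
    circularity = circularity,
    eccentricity = mom[, "m.eccentricity"],
    max_caliper = mom[, "m.majoraxis"] * ps,
    cell_area = cell_area,
    nucleus_cell_ratio = nucleus_area / cell_area,
    h_mean_nuc = nuc_h[, "mean"], h_min_nuc = nuc_h[, "min"],
    h_max_nuc = nuc_h[, "max"],
    e_mean_nuc = nuc_e[, "mean"], e_min_nuc = nuc_e[, "min"],
    e_max_nuc = nuc_e[, "max"],
    h_mean_cyto = cy_h[, "mean"], h_min_cyto = cy_h[, "min"],
    h_max_cyto = cy_h[, "max"],
    e_mean_cyto = cy_e[, "mean"], e_min_cyto = cy_e[, "min"],
    e_max_cyto = cy_e[, "max"],
    row.names = NULL)
  out$degenerate <- as.logical(degenerate)
  out
}

#' Train the cell-type classifier
#'
#' One-hidden-layer multilayer perceptron (softmax output) over the fixed
#' feature schema. Features are z-scored with training-set statistics,
#' which are stored with the model. Seeded, so training is reproducible.
#'
#' @param features data frame containing the columns of
#'   \code{til_feature_names()}.
#' @param labels factor or character vector of classes (tumor, stromal,
#'   immune, other); at least 2 classes with >= 10 examples each.
#' @param hidden hidden-layer width (default 32).
#' @param maxit maximum training epochs (default 500).
#' @param decay L2 weight decay (default 1e-4).
#' @param seed RNG seed for weight initialization.
#' @return object of class \code{til_classifier}.
#' @export
train_classifier <- function(features, labels, hidden = 32L, maxit = 500L,
                             decay = 1e-4, seed = 1L) {
  feats <- til_feature_names()
  missing_cols <- setdiff(feats, names(features))
  if (length(missing_cols))
    stop("missing feature columns: ", paste(missing_cols, collapse = ", "))
  labels <- factor(labels)
  labels <- droplevels(labels)
  if (nlevels(labels) < 2L) stop("need at least 2 classes to train")
  if (any(table(labels) < 10L))
    stop("need at least 10 examples per class")
  x <- as.matrix(features[, feats])
  center <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  xs <- scale(x, center = center, scale = scl)
  y <- nnet::class.ind(labels)
  set.seed(seed)
  net <- nnet::nnet(xs, y, size = hidden, softmax = TRUE, maxit = maxit,
                    decay = decay, MaxNWts = 50000L, trace = FALSE)
  pred <- levels(labels)[max.col(predict(net, xs))]
  structure(list(net = net, center = center, scale = scl,
                 features = feats, levels = levels(labels),
                 training = list(n = nrow(x),
                                 class_counts = as.list(table(labels)),
                                 accuracy = mean(pred == as.character(labels)),
                                 converged = net$convergence == 0,
                                 seed = seed)),
            class = "til_classifier")
}

#' Classify cells with a trained classifier
#'
#' @param classifier a \code{til_classifier}.
#' @param features data frame with the training feature schema.
#' @return list with \code{class} (factor) and \code{posteriors}
#'   (matrix, rows summing to 1).
#' @export
classify_cells <- function(classifier, features) {
  stopifnot(inherits(classifier, "til_classifier"))
  missing_cols <- setdiff(classifier$features, names(features))
  if (length(missing_cols))
    stop("feature schema mismatch; missing: ",
         paste(missing_cols, collapse = ", "))
  x <- as.matrix(features[, classifier$features, drop = FALSE])
  xs <- scale(x, center = classifier$center, scale = classifier$scale)
  post <- predict(classifier$net, xs)
  if (is.null(dim(post))) post <- matrix(post, nrow = nrow(xs))
  colnames(post) <- classifier$levels
  post <- post / rowSums(post)
  cls <- factor(classifier$levels[max.col(post, ties.method = "first")],
                levels = classifier$levels)
  list(class = cls, posteriors = post)
}

# Per-class precision/recall/F1 from confusion counts.
report_from_counts <- function(tp, fp, fn, classes) {
  precision <- ifelse(tp + fp == 0, 0, tp / (tp + fp))
  recall <- ifelse(tp + fn == 0, 0, tp / (tp + fn))
  f1 <- ifelse(precision + recall == 0, 0,
               2 * precision * recall / (precision + recall))
  rep <- data.frame(class = classes, precision = precision, recall = recall,
                    f1 = f1, support = tp + fn, row.names = NULL,
                    stringsAsFactors = FALSE)
  structure(rep, class = c("classification_report", "data.frame"),
            macro = c(precision = mean(precision), recall = mean(recall),
                      f1 = mean(f1)))
}

#' Label-agreement classification report
#'
#' Per-class precision, recall and F1 (harmonic mean) from aligned label
#' vectors, plus macro averages in the \code{macro} attribute.
#'
#' @param truth,predicted equal-length label vectors.
#' @return a \code{classification_report} data frame.
#' @export
classification_report <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  truth <- as.character(truth); predicted <- as.character(predicted)
  classes <- sort(union(truth, predicted))
  tp <- sapply(classes, function(cl) sum(truth == cl & predicted == cl))
  fp <- sapply(classes, function(cl) sum(truth != cl & predicted == cl))
  fn <- sapply(classes, function(cl) sum(truth == cl & predicted != cl))
  report_from_counts(tp, fp, fn, classes)
}

#' Detection-aware evaluation against ground truth
#'
#' Greedy nearest-centroid matching within \code{match_radius}: predicted
#' and true cells are paired closest-first; a matched pair is correct iff
#' the labels agree, an unmatched true cell is a false negative of its
#' class, an unmatched prediction a false positive of its class.
#'
#' @param predicted data frame with \code{x_um, y_um, class}.
#' @param truth data frame with \code{x_um, y_um, class}.
#' @param match_radius maximum centroid distance (um), > 0.
#' @return a \code{classification_report}; attribute \code{matching} holds
#'   the matched index pairs.
#' @export
evaluate_classification <- function(predicted, truth, match_radius = 5) {
  if (match_radius <= 0) stop("match_radius must be positive")
  np <- nrow(predicted); nt <- nrow(truth)
  classes <- sort(union(as.character(truth$class),
                        as.character(predicted$class)))
  pairs <- NULL
  if (np > 0 && nt > 0) {
    d <- sqrt(outer(predicted$x_um, truth$x_um, `-`)^2 +
                outer(predicted$y_um, truth$y_um, `-`)^2)
    cand <- which(d <= match_radius, arr.ind = TRUE)
    if (nrow(cand)) {
      ord <- order(d[cand])
      cand <- cand[ord, , drop = FALSE]
      used_p <- logical(np); used_t <- logical(nt)
      keep <- logical(nrow(cand))
      for (i in seq_len(nrow(cand))) {
        pi <- cand[i, 1L]; ti <- cand[i, 2L]
        if (!used_p[pi] && !used_t[ti]) {
          used_p[pi] <- TRUE; used_t[ti] <- TRUE; keep[i] <- TRUE
        }
      }
      pairs <- cand[keep, , drop = FALSE]
    }
  }
  tp <- stats::setNames(numeric(length(classes)), classes)
  fp <- tp; fn <- tp
  matched_p <- matched_t <- integer()
  if (!is.null(pairs) && nrow(pairs)) {
    matched_p <- pairs[, 1L]; matched_t <- pairs[, 2L]
    pc <- as.character(predicted$class)[matched_p]
    tc <- as.character(truth$class)[matched_t]
    for (i in seq_along(pc)) {
      if (pc[i] == tc[i]) tp[pc[i]] <- tp[pc[i]] + 1
      else { fp[pc[i]] <- fp[pc[i]] + 1; fn[tc[i]] <- fn[tc[i]] + 1 }
    }
  }
  if (np > 0) {
    un <- setdiff(seq_len(np), matched_p)
    for (cl in as.character(predicted$class)[un]) fp[cl] <- fp[cl] + 1
  }
  if (nt > 0) {
    un <- setdiff(seq_len(nt), matched_t)
    for (cl in as.character(truth$class)[un]) fn[cl] <- fn[cl] + 1
  }
  rep <- report_from_counts(tp, fp, fn, classes)
  attr(rep, "matching") <- pairs
  rep
}

#' @export
print.classification_report <- function(x, ...) {
  cat("Classification report\n")
  print.data.frame(cbind(x[, "class", drop = FALSE],
                         round(x[, c("precision", "recall", "f1")], 3),
                         support = x$support), row.names = FALSE)
  m <- attr(x, "macro")
  cat(sprintf("macro: precision %.3f  recall %.3f  F1 %.3f\n",
              m["precision"], m["recall"], m["f1"]))
  invisible(x)
}
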