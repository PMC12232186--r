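# Region handling, the five electronic TIL variables, cohort QC and
# cutoff dichotomization.

#' Region annotation
#'
#' A set of simple polygons in micrometer coordinates (origin top-left,
#' y increasing downward) delimiting the analyzed tumor region.
#'
#' @param polygons a single n x 2 matrix or a list of them (columns x, y
#'   in um; vertices need not repeat the first point).
#' @return object of class \code{region_annotation} with the summed
#'   polygon area (mm^2) precomputed.
#' @export
region_annotation <- function(polygons) {
  if (is.matrix(polygons)) polygons <- list(polygons)
  if (!length(polygons)) stop("region is empty")
  polygons <- lapply(polygons, function(p) {
    p <- as.matrix(p)
    if (ncol(p) != 2L || nrow(p) < 3L)
      stop("each polygon needs an n x 2 matrix with n >= 3")
    storage.mode(p) <- "double"
    p
  })
  area <- sum(vapply(polygons, polygon_area, numeric(1))) / 1e6
  if (area <= 0) stop("region area must be positive")
  structure(list(polygons = polygons, area_mm2 = area),
            class = "region_annotation")
}

#' Rectangular region covering a whole tile
#'
#' @param width_um,height_um tile dimensions.
#' @return a \code{\link{region_annotation}}.
#' @export
tile_region <- function(width_um, height_um) {
  region_annotation(rbind(c(0, 0), c(width_um, 0),
                          c(width_um, height_um), c(0, height_um)))
}

#' Keep cells whose centroid falls inside the region
#'
#' Membership is centroid-in-polygon, boundary inclusive (a cell sitting
#' exactly on an edge or vertex is kept).
#'
#' @param cells data frame with \code{x_um, y_um}.
#' @param region a \code{\link{region_annotation}}.
#' @return the subset of \code{cells} inside the region.
#' @export
filter_cells_to_region <- function(cells, region) {
  stopifnot(inherits(region, "region_annotation"))
  if (!nrow(cells)) return(cells)
  pts <- cbind(cells$x_um, cells$y_um)
  inside <- rep(FALSE, nrow(pts))
  for (poly in region$polygons)
    inside <- inside | point_in_polygon(pts, poly)
  cells[inside, , drop = FALSE]
}

#' Compute the five electronic TIL variables
#'
#' From classified cells inside an annotated region:
#' \itemize{
#'   \item eTILs\%  = 100 n_immune / (n_immune + n_tumor)
#'   \item etTILs\% = 100 n_immune / (n_immune + n_tumor + n_stromal +
#'     n_other)
#'   \item esTILs\% = 100 n_immune / (n_immune + n_stromal)
#'   \item eaTILs   = immune cell area / region area (mm^2 per mm^2
#'     analyzed)
#'   \item easTILs\% = 100 immune cell area / (region area - tumor cell
#'     area), the stromal-area proxy
#' }
#' A score whose denominator is zero (or negative for easTILs) is returned
#' as \code{NA} and listed in the \code{undefined} field, never as 0.
#'
#' @param cells data frame with \code{class} in tumor/stromal/immune/other,
#'   \code{x_um, y_um}, and \code{cell_area_um2} (falls back to
#'   \code{nucleus_area_um2}, then \code{nucleus_area}, for area scores).
#' @param region a \code{\link{region_annotation}}; cells are filtered to
#'   it first.
#' @return object of class \code{til_panel}: counts, areas (mm^2), region
#'   area and the five scores.
#' @export
compute_til_panel <- function(cells, region) {
  stopifnot(inherits(region, "region_annotation"))
  cells <- filter_cells_to_region(cells, region)
  cls <- as.character(cells$class)
  n <- sapply(c("tumor", "stromal", "immune", "other"),
              function(k) sum(cls == k))
  area_col <- intersect(c("cell_area_um2", "nucleus_area_um2",
                          "nucleus_area", "cell_area"), names(cells))
  if (length(area_col)) {
    av <- cells[[area_col[1L]]]
    a <- sapply(c("tumor", "stromal", "immune"),
                function(k) sum(av[cls == k])) / 1e6
  } else {
    a <- c(tumor = NA_real_, stromal = NA_real_, immune = NA_real_)
  }
  ra <- region$area_mm2
  ratio <- function(num, den) {
    if (is.na(den) || den <= 0) NA_real_ else num / den
  }
  etils <- ratio(100 * n[["immune"]], n[["immune"]] + n[["tumor"]])
  ettils <- ratio(100 * n[["immune"]], sum(n))
  estils <- ratio(100 * n[["immune"]], n[["immune"]] + n[["stromal"]])
  eatils <- ratio(a[["immune"]], ra)
  eastils <- ratio(100 * a[["immune"]], ra - a[["tumor"]])
  scores <- c(eTILs_pct = etils, etTILs_pct = ettils, esTILs_pct = estils,
              eaTILs = eatils, easTILs_pct = eastils)
  structure(list(n_tumor = n[["tumor"]], n_stromal = n[["stromal"]],
                 n_immune = n[["immune"]], n_other = n[["other"]],
                 a_tumor_mm2 = a[["tumor"]], a_stromal_mm2 = a[["stromal"]],
                 a_immune_mm2 = a[["immune"]], region_area_mm2 = ra,
                 eTILs_pct = etils, etTILs_pct = ettils,
                 esTILs_pct = estils, eaTILs = eatils,
                 easTILs_pct = eastils,
                 undefined = names(scores)[is.na(scores)]),
            class = "til_panel")
}

#' @export
print.til_panel <- function(x, ...) {
  cat("Electronic TIL panel\n")
  cat(sprintf("  counts: tumor %d  stromal %d  immune %d  other %d\n",
              x$n_tumor, x$n_stromal, x$n_immune, x$n_other))
  cat(sprintf("  region %.4f mm^2  immune area %.5f mm^2\n",
              x$region_area_mm2,
              if (is.na(x$a_immune_mm2)) NA else x$a_immune_mm2))
  cat(sprintf(
    "  eTILs %.2f%%  etTILs %.2f%%  esTILs %.2f%%  eaTILs %.4f  easTILs %.2f%%\n",
    x$eTILs_pct, x$etTILs_pct, x$esTILs_pct, x$eaTILs, x$easTILs_pct))
  if (length(x$undefined))
    cat("  undefined:", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' Cohort quality-control filter
#'
#' A slide is excluded iff its analyzed area is less than 0.5 mm^2 or its
#' tumor-cell fraction is less than 0.50; slides exactly at either
#' boundary are included.
#'
#' @param area_mm2 numeric vector of analyzed areas (>= 0).
#' @param tumor_fraction numeric vector in [0, 1].
#' @return data frame with \code{include} (logical) and \code{reason}
#'   ("" when included).
#' @export
qc_filter <- function(area_mm2, tumor_fraction) {
  if (any(area_mm2 < 0)) stop("area must be non-negative")
  if (any(tumor_fraction < 0 | tumor_fraction > 1))
    stop("tumor_fraction must lie in [0, 1]")
  small <- area_mm2 < 0.5
  low_tumor <- tumor_fraction < 0.50
  reason <- character(length(area_mm2))
  reason[low_tumor] <- "tumor fraction < 50%"
  reason[small] <- "area < 0.5 mm^2"
  reason[small & low_tumor] <- "area < 0.5 mm^2; tumor fraction < 50%"
  data.frame(include = !(small | low_tumor), reason = reason,
             stringsAsFactors = FALSE)
}

#' Dichotomize scores at a cutoff
#'
#' Labels each case high iff its score is greater than or equal to the
#' cutoff (inclusive). The cutoff is either the median of the non-missing
#' scores or an absolute value (e.g. 16.6 for eTILs\%, 10 or 30 for manual
#' sTILs\%).
#'
#' @param scores numeric vector, missing values allowed.
#' @param cutoff \code{"median"} or a single numeric value.
#' @return list with \code{labels} (factor low/high, NA preserved) and
#'   \code{cutoff} (the numeric cutoff used).
#' @export
dichotomize <- function(scores, cutoff = "median") {
  if (all(is.na(scores))) stop("all scores are missing")
  cut_val <- if (identical(cutoff, "median"))
    stats::median(scores, na.rm = TRUE) else as.numeric(cutoff)
  if (is.na(cut_val)) stop("invalid cutoff")
  labels <- factor(ifelse(scores >= cut_val, "high", "low"),
                   levels = c("low", "high"))
  list(labels = labels, cutoff = cut_val)
}
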