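# Readers and writers: RGB tiles (PNG/TIFF), region annotations (GeoJSON),
# cell tables / score matrices / survival tables (CSV), stain models (JSON).

#' Read and write 8-bit RGB tiles
#'
#' Format is chosen by extension (.png, .tif/.tiff). Images are numeric
#' arrays [y, x, 3] with values 0..255.
#'
#' @param path file path.
#' @return \code{read_tile}: the image array.
#' @export
read_tile <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop("unsupported tile format: .", ext))
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3L] > 3L) img <- img[, , 1:3, drop = FALSE]
  round(img * 255)
}

#' @rdname read_tile
#' @param image numeric array [y, x, 3], values 0..255.
#' @export
write_tile <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  img <- clamp(image, 0, 255) / 255
  switch(ext,
         png = png::writePNG(img, path),
         tif = ,
         tiff = tiff::writeTIFF(img, path, bits.per.sample = 8L),
         stop("unsupported tile format: .", ext))
  invisible(path)
}

#' Read and write region annotations as GeoJSON
#'
#' One Polygon feature per region polygon; coordinates in micrometers
#' (origin top-left, y down). The pixel size is carried in each feature's
#' properties.
#'
#' @param path file path.
#' @return \code{read_region_geojson}: a \code{\link{region_annotation}}.
#' @export
read_region_geojson <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$features) || !length(gj$features))
    stop("GeoJSON has no features: ", path)
  polys <- lapply(seq_along(gj$features), function(i) {
    f <- gj$features[[i]]
    if (is.null(f$geometry) || !identical(f$geometry$type, "Polygon"))
      stop("feature ", i, " is not a Polygon in ", path)
    ring <- f$geometry$coordinates[[1L]]
    m <- do.call(rbind, lapply(ring, function(pt) {
      if (length(pt) < 2L) stop("feature ", i, ": malformed coordinate")
      as.numeric(pt[1:2])
    }))
    # drop the closing vertex GeoJSON repeats
    if (nrow(m) > 1L && all(m[1L, ] == m[nrow(m), ]))
      m <- m[-nrow(m), , drop = FALSE]
    m
  })
  region_annotation(polys)
}

#' @rdname read_region_geojson
#' @param region a \code{\link{region_annotation}}.
#' @param pixel_size_um pixel size stored in feature properties.
#' @export
write_region_geojson <- function(region, path, pixel_size_um = 0.4986) {
  stopifnot(inherits(region, "region_annotation"))
  features <- lapply(region$polygons, function(p) {
    ring <- lapply(seq_len(nrow(p)), function(i) c(p[i, 1L], p[i, 2L]))
    ring[[length(ring) + 1L]] <- ring[[1L]]  # close the ring
    list(type = "Feature",
         properties = list(object_type = "annotation",
                           unit = "um",
                           pixel_size_um = pixel_size_um),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write cell tables as CSV
#'
#' Schema: id, x_um, y_um, nucleus_area_um2, cell_area_um2, class,
#' p_tumor, p_stromal, p_immune, p_other, then feature columns. Column
#' order and row order are preserved on round trip.
#'
#' @param path file path.
#' @return \code{read_cell_table}: a data frame.
#' @export
read_cell_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname read_cell_table
#' @param cells data frame.
#' @export
write_cell_table <- function(cells, path) {
  utils::write.csv(cells, path, row.names = FALSE)
  invisible(path)
}

#' Read and write score matrices as CSV
#'
#' Rows are cases, columns raters; the first column holds case ids.
#'
#' @param path file path.
#' @return \code{read_score_matrix}: numeric matrix with dimnames.
#' @export
read_score_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric score entries in ", path)
  rownames(m) <- as.character(df[[1L]])
  m
}

#' @rdname read_score_matrix
#' @param m score matrix.
#' @export
write_score_matrix <- function(m, path) {
  df <- data.frame(case = rownames(m) %||% seq_len(nrow(m)),
                   m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read and write survival tables as CSV
#'
#' Columns: time_months, event, sex, age, stage, group.
#'
#' @param path file path.
#' @return \code{read_survival_table}: a data frame with stage and group
#'   as factors (levels I-IV and low/high).
#' @export
read_survival_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_months", "event")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("survival table ", path, " lacks columns: ",
         paste(miss, collapse = ", "))
  if ("stage" %in% names(df))
    df$stage <- factor(df$stage, levels = c("I", "II", "III", "IV"))
  if ("group" %in% names(df))
    df$group <- factor(df$group, levels = c("low", "high"))
  df
}

#' @rdname read_survival_table
#' @param records data frame.
#' @export
write_survival_table <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Read and write stain models as JSON
#'
#' Serializes the six stain-vector components, the two concentration
#' scales and the estimation parameters.
#'
#' @param path file path.
#' @return \code{read_stain_model}: a \code{\link{stain_model}}.
#' @export
read_stain_model <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  j <- jsonlite::fromJSON(path)
  stain_model(cbind(j$hematoxylin, j$eosin),
              scale = j$scale, beta = j$beta, alpha = j$alpha, io = j$io)
}

#' @rdname read_stain_model
#' @param model a \code{\link{stain_model}}.
#' @export
write_stain_model <- function(model, path) {
  validate_stain_model(model)
  jsonlite::write_json(list(hematoxylin = model$vectors[, 1L],
                            eosin = model$vectors[, 2L],
                            scale = model$scale, beta = model$beta,
                            alpha = model$alpha, io = model$io),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
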