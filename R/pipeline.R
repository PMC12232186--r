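# End-to-end pipeline: simulate -> normalize -> detect -> classify ->
# score, with per-stage artifacts on disk.

#' Pipeline configuration
#'
#' Collects every knob of the end-to-end run. The resolved configuration
#' is written next to the outputs of each run.
#'
#' @param seed master seed; every stage derives its stream from it.
#' @param sim a \code{\link{sim_config}} describing tile generation.
#' @param n_cases number of cases (tiles) to score.
#' @param n_train_tiles tiles used to train the classifier.
#' @param io,beta,alpha stain-normalization parameters.
#' @param sigma_um,threshold,min_area_um2,max_area_um2 detection
#'   parameters.
#' @param expansion_um cell expansion radius.
#' @param hidden,maxit,decay classifier parameters.
#' @param match_radius_um truth-matching radius for training labels and
#'   evaluation.
#' @param cutoff dichotomization cutoff rule (\code{"median"} or numeric).
#' @param icc_form ICC form for concordance summaries.
#' @param ties Cox tie-handling method.
#' @return object of class \code{til_pipeline_config}.
#' @export
pipeline_config <- function(seed = 1L, sim = sim_config(seed = seed),
                            n_cases = 2L, n_train_tiles = 2L,
                            io = 255, beta = 0.15, alpha = 1,
                            sigma_um = 1.5, threshold = 0.10,
                            min_area_um2 = 5, max_area_um2 = 400,
                            expansion_um = 5, hidden = 32L, maxit = 500L,
                            decay = 1e-4, match_radius_um = 5,
                            cutoff = "median", icc_form = "ICC2",
                            ties = "efron") {
  stopifnot(inherits(sim, "til_sim_config"))
  if (n_cases < 1L) stop("need at least 1 case")
  structure(list(seed = as.integer(seed), sim = sim,
                 n_cases = as.integer(n_cases),
                 n_train_tiles = as.integer(n_train_tiles),
                 io = io, beta = beta, alpha = alpha,
                 sigma_um = sigma_um, threshold = threshold,
                 min_area_um2 = min_area_um2, max_area_um2 = max_area_um2,
                 expansion_um = expansion_um, hidden = as.integer(hidden),
                 maxit = as.integer(maxit), decay = decay,
                 match_radius_um = match_radius_um, cutoff = cutoff,
                 icc_form = icc_form, ties = ties),
            class = "til_pipeline_config")
}

# Run one stage with context added to any error.
run_stage <- function(name, expr, log) {
  log(paste0("stage ", name, ": start"))
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

# Render one tile at a derived seed, normalize it against the reference,
# and return its detected, feature-extracted cells plus ground truth.
process_tile <- function(cfg, tile_seed, reference, stain_truth) {
  sim <- cfg$sim
  sim$seed <- as.integer(tile_seed)
  layout <- sample_cell_layout(sim)
  set.seed(tile_seed + 1L)
  tile <- render_tile(layout, stain = stain_truth,
                      noise_sd = sim$noise_sd, io = cfg$io)
  source_model <- estimate_stain_vectors(rgb_to_od(tile$image, io = cfg$io),
                                         beta = cfg$beta, alpha = cfg$alpha)
  norm <- normalize_image(tile$image, source_model, reference, io = cfg$io)
  conc <- compute_concentrations(rgb_to_od(norm, io = cfg$io), reference)
  nuclei <- detect_nuclei(conc[, , 1L], pixel_size_um = tile$pixel_size_um,
                          sigma_um = cfg$sigma_um,
                          threshold = cfg$threshold,
                          min_area_um2 = cfg$min_area_um2,
                          max_area_um2 = cfg$max_area_um2)
  cells <- expand_cells(nuclei, radius_um = cfg$expansion_um)
  feats <- extract_features(nuclei, cells, conc,
                            pixel_size_um = tile$pixel_size_um)
  feats$cell_area_um2 <- feats$cell_area
  feats$nucleus_area_um2 <- feats$nucleus_area
  list(layout = layout, tile = tile, image = norm, features = feats,
       truth = tile$truth)
}

# Assign ground-truth labels to detections by nearest-centroid matching.
truth_labels <- function(features, truth, radius) {
  if (!nrow(features)) return(character(0))
  report <- evaluate_classification(
    data.frame(x_um = features$x_um, y_um = features$y_um,
               class = "unlabeled", stringsAsFactors = FALSE),
    truth[, c("x_um", "y_um", "class")], match_radius = radius)
  pairs <- attr(report, "matching")
  labels <- rep(NA_character_, nrow(features))
  if (!is.null(pairs) && nrow(pairs))
    labels[pairs[, 1L]] <- as.character(truth$class)[pairs[, 2L]]
  labels
}

#' Run the full scoring pipeline on synthetic cases
#'
#' Stages, in order: fit a reference stain model on a dedicated reference
#' tile; render training tiles, normalize them, detect and feature-extract
#' cells, label them against ground truth and train the classifier; then
#' for each case render, normalize, detect, classify and compute the
#' five-variable TIL panel over the whole-tile region. When
#' \code{out_dir} is given, per-stage artifacts (reference model JSON,
#' per-case cell CSVs, panel CSV, resolved configuration, run log) are
#' written there. Idempotent given identical configuration and seed.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param out_dir optional output directory (created if missing).
#' @return list with \code{panels} (one row per case), \code{classifier},
#'   \code{reference} stain model, \code{cases} (per-case details) and
#'   \code{training_report}.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "til_pipeline_config"))
  log_lines <- character()
  log <- function(msg) {
    log_lines <<- c(log_lines, paste0(format(Sys.time(), "%H:%M:%S "), msg))
  }
  stain_truth <- default_stain_model(io = config$io)
  seed0 <- config$seed

  reference <- run_stage("fit-reference", {
    sim_ref <- config$sim
    sim_ref$seed <- seed0 + 900L
    layout <- sample_cell_layout(sim_ref)
    set.seed(seed0 + 901L)
    ref_tile <- render_tile(layout, stain = stain_truth,
                            noise_sd = config$sim$noise_sd, io = config$io)
    fit_reference(ref_tile$image, beta = config$beta, alpha = config$alpha,
                  io = config$io)
  }, log)

  classifier <- run_stage("train", {
    train_feats <- NULL; train_labs <- NULL
    for (t in seq_len(config$n_train_tiles)) {
      pt <- process_tile(config, seed0 + 700L + t, reference, stain_truth)
      labs <- truth_labels(pt$features, pt$truth, config$match_radius_um)
      ok <- !is.na(labs)
      train_feats <- rbind(train_feats, pt$features[ok, , drop = FALSE])
      train_labs <- c(train_labs, labs[ok])
    }
    train_classifier(train_feats, train_labs, hidden = config$hidden,
                     maxit = config$maxit, decay = config$decay,
                     seed = seed0)
  }, log)

  cases <- vector("list", config$n_cases)
  panels <- NULL
  for (i in seq_len(config$n_cases)) {
    res <- run_stage(paste0("score-case-", i), {
      pt <- process_tile(config, seed0 + 100L * i, reference, stain_truth)
      pred <- classify_cells(classifier, pt$features)
      cells <- pt$features
      cells$class <- as.character(pred$class)
      post <- pred$posteriors
      for (cl in colnames(post)) cells[[paste0("p_", cl)]] <- post[, cl]
      region <- tile_region(pt$layout$width_um, pt$layout$height_um)
      panel <- compute_til_panel(cells, region)
      list(cells = cells, truth = pt$truth, region = region, panel = panel)
    }, log)
    cases[[i]] <- res
    p <- res$panel
    panels <- rbind(panels, data.frame(
      case = i, n_tumor = p$n_tumor, n_stromal = p$n_stromal,
      n_immune = p$n_immune, n_other = p$n_other,
      a_tumor_mm2 = p$a_tumor_mm2, a_stromal_mm2 = p$a_stromal_mm2,
      a_immune_mm2 = p$a_immune_mm2, region_area_mm2 = p$region_area_mm2,
      eTILs_pct = p$eTILs_pct, etTILs_pct = p$etTILs_pct,
      esTILs_pct = p$esTILs_pct, eaTILs = p$eaTILs,
      easTILs_pct = p$easTILs_pct))
    log(paste0("case ", i, ": ", nrow(res$cells), " cells"))
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_stain_model(reference, file.path(out_dir, "reference_stain.json"))
    for (i in seq_len(config$n_cases))
      write_cell_table(cases[[i]]$cells,
                       file.path(out_dir, sprintf("case_%02d_cells.csv", i)))
    utils::write.csv(panels, file.path(out_dir, "til_panels.csv"),
                     row.names = FALSE)
    cfg_flat <- config
    cfg_flat$sim <- unclass(cfg_flat$sim)
    jsonlite::write_json(unclass(cfg_flat),
                         file.path(out_dir, "pipeline_config.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  list(panels = panels, classifier = classifier, reference = reference,
       cases = cases, training_report = classifier$training,
       log = log_lines)
}
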