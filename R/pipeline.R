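# Run configuration and the pipeline driver behind the command-line
# interface. One flat configuration object with per-stage sections; the
# defaults equal the protocol's standard thresholds, so a bare run is the
# reference quantification pipeline on a synthetic scene.

#' Run configuration for the pipeline driver
#'
#' @param scene a [scene_config()].
#' @param growth a [growth_config()].
#' @param thresholds named list overriding any of: `binarize` (number or
#'   `"auto"`), `classify_method`, `classify_param`, `circ_min`, `circ_max`,
#'   `overlap_frac`, `assign_frac`, `clone_small_max`,
#'   `clone_intermediate_max`, `membrane_width`, `erode_rule`.
#' @param seed top-level integer seed; all stage randomness derives from it.
#' @param output_dir directory for artifacts.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(scene = scene_config(), growth = growth_config(),
                       thresholds = list(), seed = 1L,
                       output_dir = "clonefish-out") {
  def <- list(binarize = "auto", classify_method = "threshold",
              classify_param = 0.25, circ_min = 0.4, circ_max = 1.0,
              overlap_frac = 0.2, assign_frac = 0.5, clone_small_max = 2L,
              clone_intermediate_max = 5L, membrane_width = 2L,
              erode_rule = "any_neighbour")
  unknown <- setdiff(names(thresholds), names(def))
  if (length(unknown))
    stop("unknown threshold field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  def[names(thresholds)] <- thresholds
  cfg <- structure(list(scene = scene, growth = growth, thresholds = def,
                        seed = as.integer(seed), output_dir = output_dir),
                   class = "run_config")
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  validate_scene_config(cfg$scene)
  th <- cfg$thresholds
  stopifnot_scalar_number(th$overlap_frac, "overlap_frac", min = 0, max = 1)
  if (th$assign_frac <= 0 || th$assign_frac >= 1)
    stop("'assign_frac' must lie strictly inside (0, 1)", call. = FALSE)
  stopifnot_scalar_number(th$circ_min, "circ_min", min = 0, max = 1)
  stopifnot_scalar_number(th$circ_max, "circ_max", min = 0, max = 1)
  if (th$circ_min > th$circ_max)
    stop("'circ_min' must not exceed 'circ_max'", call. = FALSE)
  stopifnot_scalar_number(th$clone_small_max, "clone_small_max", min = 1,
                          integer = TRUE)
  stopifnot_scalar_number(th$clone_intermediate_max, "clone_intermediate_max",
                          min = 2, integer = TRUE)
  if (th$clone_small_max >= th$clone_intermediate_max)
    stop("'clone_small_max' must be below 'clone_intermediate_max'",
         call. = FALSE)
  stopifnot_scalar_number(cfg$seed, "seed", integer = TRUE)
  invisible(cfg)
}

#' Load a run configuration from JSON
#'
#' Reads a flat JSON file with optional sections `scene`, `growth`,
#' `thresholds` plus `seed` and `output_dir`; omitted fields take the
#' package defaults.
#'
#' @param path JSON file path.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("missing input file: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  scene <- do.call(scene_config, as.list(raw$scene %||% list()))
  growth <- do.call(growth_config, as.list(raw$growth %||% list()))
  run_config(scene = scene, growth = growth,
             thresholds = as.list(raw$thresholds %||% list()),
             seed = raw$seed %||% 1L,
             output_dir = raw$output_dir %||% "clonefish-out")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_config_json <- function(cfg, path) {
  x <- list(scene = unclass(cfg$scene), growth = unclass(cfg$growth),
            thresholds = cfg$thresholds, seed = cfg$seed,
            output_dir = cfg$output_dir)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

log_line <- function(log_path, ..., echo = TRUE) {
  msg <- paste0(...)
  cat(msg, "\n", file = log_path, append = TRUE, sep = "")
  if (echo) message(msg)
  invisible(NULL)
}

#' Run the quantification pipeline
#'
#' Drives the package stages and writes their CSV/JSON/TIFF artifacts plus a
#' run log (configuration echo, seed, package version, per-stage record
#' counts) into `config$output_dir`. Commands:
#' `simulate` (synthetic scene + ground truth + growth series),
#' `clonal-area` (areas.csv from the reporter channels),
#' `clone-sizes` (clones.csv + clone_distribution.csv),
#' `fit-growth` (fit.json + fitted_curve.csv from growth.csv),
#' `fish-count` (dots.csv + ratios.csv),
#' `ddct` (relative expression from ddct.csv), and
#' `all` (simulate, then every analysis stage on the synthetic scene).
#' Identical configuration (including seed) gives byte-identical outputs.
#'
#' @param config a [run_config()].
#' @param command one of the commands above.
#' @param quiet suppress console logging.
#' @return Invisibly, a named list of the artifact paths written.
#' @export
run_pipeline <- function(config, command = c("all", "simulate", "clonal-area",
                                             "clone-sizes", "fit-growth",
                                             "fish-count", "ddct"),
                         quiet = FALSE) {
  command <- match.arg(command)
  validate_run_config(config)
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out, "run.log")
  if (file.exists(log_path)) unlink(log_path)
  p <- function(f) file.path(out, f)
  th <- config$thresholds
  written <- list()
  log_line(log_path, "clonefish ", as.character(packageVersion("clonefish")),
           " | command: ", command, " | seed: ", config$seed, echo = !quiet)
  write_config_json(config, p("config.json"))
  log_line(log_path, "config echoed to config.json", echo = !quiet)

  # the top-level seed overrides the per-section seeds so one integer
  # reproduces the full run
  scene_cfg <- config$scene
  scene_cfg$seed <- config$seed
  growth_cfg <- config$growth
  growth_cfg$seed <- config$seed

  if (command %in% c("simulate", "all")) {
    scene <- simulate_tissue(scene_cfg)
    fish <- simulate_fish_channels(scene_cfg, scene$truth)
    truth <- fish$truth
    write_channel(scene$tomato, p("tomato.tif"))
    write_channel(scene$gfp, p("gfp.tif"))
    write_channel(fish$green, p("fish_green.tif"))
    write_channel(fish$farred, p("fish_farred.tif"))
    write_label_map(truth$cell_label_map, p("cell_labels.tif"))
    write.csv(truth$cells[c("cell_id", "centroid_x", "centroid_y", "gfp")],
              p("cells.csv"), row.names = FALSE)
    write.csv(truth$dots_per_cell, p("dots_truth.csv"), row.names = FALSE)
    write.csv(truth$speckle_positions, p("speckles_truth.csv"),
              row.names = FALSE)
    gs <- simulate_growth_series(growth_cfg)
    write.csv(gs, p("growth.csv"), row.names = FALSE)
    log_line(log_path, sprintf(
      "simulate: %d cells (%d GFP+), %d true dots, %d speckles, %d growth obs",
      scene_cfg$n_cells, length(truth$gfp_cell_ids),
      sum(truth$dots_per_cell$count), nrow(truth$speckle_positions),
      nrow(gs)), echo = !quiet)
    written <- c(written, list(
      tomato = p("tomato.tif"), gfp = p("gfp.tif"),
      fish_green = p("fish_green.tif"), fish_farred = p("fish_farred.tif"),
      cell_labels = p("cell_labels.tif"), cells = p("cells.csv"),
      dots_truth = p("dots_truth.csv"), growth = p("growth.csv")))
  }

  if (command %in% c("clonal-area", "all")) {
    tom <- read_channel(p("tomato.tif"))
    gf <- read_channel(p("gfp.tif"))
    aq <- quantify_gfp_area(binarize_channel(tom, th$binarize),
                            binarize_channel(gf, th$binarize))
    if (aq$B > 0.8 * aq$A)
      log_line(log_path,
               "warning: B approaches A; GFP% denominator is small",
               echo = !quiet)
    df <- data.frame(sample = sprintf("seed_%d", config$seed),
                     time_days = NA_real_,
                     A = aq$A, B = aq$B, gfp_percent = aq$gfp_percent)
    write.csv(df, p("areas.csv"), row.names = FALSE)
    log_line(log_path, sprintf("clonal-area: A=%d B=%d GFP%%=%.4f",
                               aq$A, aq$B, aq$gfp_percent), echo = !quiet)
    written$areas <- p("areas.csv")
  }

  if (command %in% c("clone-sizes", "all")) {
    gf <- read_channel(p("gfp.tif"))
    labels <- read_label_map(p("cell_labels.tif"))
    clones <- detect_clones(binarize_channel(gf, th$binarize), labels,
                            time_days = NA_real_,
                            membrane_width = th$membrane_width,
                            small_max = th$clone_small_max,
                            intermediate_max = th$clone_intermediate_max)
    write.csv(as.data.frame(clones), p("clones.csv"), row.names = FALSE)
    if (nrow(clones)) {
      write.csv(clone_size_distribution(clones), p("clone_distribution.csv"),
                row.names = FALSE)
      written$clone_distribution <- p("clone_distribution.csv")
    }
    log_line(log_path, sprintf("clone-sizes: %d clones detected",
                               nrow(clones)), echo = !quiet)
    written$clones <- p("clones.csv")
  }

  if (command %in% c("fit-growth", "all")) {
    if (!file.exists(p("growth.csv")))
      stop("missing input file: ", p("growth.csv"), call. = FALSE)
    gs <- read.csv(p("growth.csv"))
    fit_log <- fit_log_growth(gs)
    res <- list(model_tag = fit_log$model_tag,
                coefficients = as.list(fit_log$coefficients),
                r_squared = fit_log$r_squared,
                residual_rms = sqrt(mean(fit_log$residuals^2)),
                n_obs = nrow(gs))
    cmp <- tryCatch({
      fit_exp <- fit_exp_decay_alternative(gs)
      compare_models(list(fit_log, fit_exp))
    }, error = function(e) NULL)
    if (!is.null(cmp)) res$model_comparison <- cmp
    jsonlite::write_json(res, p("fit.json"), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, dataframe = "rows")
    tt <- seq(min(gs$time_days), max(gs$time_days), length.out = 100)
    write.csv(data.frame(time_days = tt, gfp_percent = predict(fit_log, tt)),
              p("fitted_curve.csv"), row.names = FALSE)
    log_line(log_path, sprintf("fit-growth: a=%.6g R2=%.4f",
                               fit_log$coefficients[["a"]],
                               fit_log$r_squared), echo = !quiet)
    written$fit <- p("fit.json")
  }

  if (command %in% c("fish-count", "all")) {
    for (f in c("fish_green.tif", "fish_farred.tif", "cell_labels.tif",
                "cells.csv"))
      if (!file.exists(p(f)))
        stop("missing input file: ", p(f), call. = FALSE)
    labels <- read_label_map(p("cell_labels.tif"))
    cells_df <- read.csv(p("cells.csv"))
    status <- ifelse(as.logical(cells_df$gfp[order(cells_df$cell_id)]),
                     "gfp_pos", "gfp_neg")
    cells <- cell_rois(labels, status)
    fc <- fish_count(read_channel(p("fish_green.tif")),
                     read_channel(p("fish_farred.tif")), cells,
                     classify_method = th$classify_method,
                     classify_param = th$classify_param,
                     circ_min = th$circ_min, circ_max = th$circ_max,
                     overlap_frac = th$overlap_frac,
                     assign_frac = th$assign_frac,
                     erode_rule = th$erode_rule)
    dots_df <- rbind(as.data.frame(fc$dots$green),
                     as.data.frame(fc$dots$farred))
    write.csv(dots_df, p("dots.csv"), row.names = FALSE)
    ratios <- do.call(rbind, lapply(fc$ratios[!vapply(fc$ratios, is.null,
                                                      TRUE)],
                                    function(r)
      data.frame(channel = r$channel, mean_gfp_pos = r$mean_dots_gfp_pos,
                 mean_gfp_neg = r$mean_dots_gfp_neg, ratio = r$ratio)))
    write.csv(ratios, p("ratios.csv"), row.names = FALSE)
    log_line(log_path, sprintf(
      "fish-count: %d dot records (%d surviving assigned)", nrow(dots_df),
      sum(dots_df$eliminated_by == "none")), echo = !quiet)
    written$dots <- p("dots.csv")
    written$ratios <- p("ratios.csv")
  }

  if (command == "ddct") {
    if (!file.exists(p("ddct.csv")))
      stop("missing input file: ", p("ddct.csv"), call. = FALSE)
    d <- read.csv(p("ddct.csv"))
    d$fold_change <- relative_expression_ddct(
      d$ct_target_sample, d$ct_housekeeping_sample,
      d$ct_target_reference, d$ct_housekeeping_reference)
    write.csv(d, p("ddct_out.csv"), row.names = FALSE)
    log_line(log_path, sprintf("ddct: %d rows", nrow(d)), echo = !quiet)
    written$ddct <- p("ddct_out.csv")
  }

  invisible(written)
}
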