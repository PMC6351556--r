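# Synthetic dual-reporter tissue scenes with ground truth.
#
# The generator emulates a tumour section from an mT/mG lineage-tracing
# experiment: a tessellated epithelial sheet in which every cell carries
# membrane Tomato, a recombined subpopulation additionally carries membrane
# GFP, and two smFISH channels show diffraction-limited dots with
# population-specific Poisson rates plus occasional coincident speckles that
# appear in both channels (the non-specific background the cross-channel
# filter is designed to remove).

MEMBRANE_AMP <- 0.8
DOT_AMP <- 0.9

#' Scene configuration for the synthetic tissue generator
#'
#' Bundles and validates all knobs of [simulate_tissue()] and
#' [simulate_fish_channels()]. Defaults emulate a high-magnification field of
#' view centred on a traced clone: ~95 px cell diameter (a ~10 micron
#' epithelial cell at smFISH imaging resolution), half the cells recombined
#' (GFP+), a lower far-red dot rate in GFP+ cells than in their GFP-
#' neighbours, and a handful of coincident background speckles per image.
#'
#' @param width_px,height_px raster size in pixels.
#' @param n_cells number of cells in the tessellation.
#' @param recombined_fraction fraction of cells that are GFP+ at labelling.
#' @param membrane_width_px width (px) of the membrane band rendered along
#'   each cell wall, on the cell's own side.
#' @param dot_rate_green expected smFISH dots per cell in the green channel
#'   (all cells).
#' @param dot_rate_red_gfp_pos,dot_rate_red_gfp_neg expected far-red dots per
#'   cell for GFP+ and GFP- cells.
#' @param dot_sigma_px Gaussian width (px) of a rendered dot.
#' @param dot_min_sep_px minimum centre separation (px) between true dots of
#'   the same cell, across both channels. Dots closer than the optical
#'   resolution limit are not resolvable as distinct particles, so the
#'   ground-truth count is defined over resolvable dots and positions follow
#'   a hard-core process at this radius (about the diffraction limit at the
#'   emulated pixel scale).
#' @param noise_sd additive Gaussian noise SD on the [0, 1] intensity scale.
#' @param coincident_speckle_rate expected number of spurious dots per image
#'   rendered at identical coordinates in both FISH channels.
#' @param seed integer seed; identical configuration implies bit-identical
#'   scenes.
#' @return A validated list of class `scene_config`.
#' @export
scene_config <- function(width_px = 600L, height_px = 600L, n_cells = 40L,
                         recombined_fraction = 0.5, membrane_width_px = 2L,
                         dot_rate_green = 2, dot_rate_red_gfp_pos = 2,
                         dot_rate_red_gfp_neg = 4, dot_sigma_px = 1.6,
                         dot_min_sep_px = 6, noise_sd = 0.02,
                         coincident_speckle_rate = 5, seed = 1L) {
  cfg <- list(width_px = as.integer(width_px),
              height_px = as.integer(height_px),
              n_cells = as.integer(n_cells),
              recombined_fraction = recombined_fraction,
              membrane_width_px = as.integer(membrane_width_px),
              dot_rate_green = dot_rate_green,
              dot_rate_red_gfp_pos = dot_rate_red_gfp_pos,
              dot_rate_red_gfp_neg = dot_rate_red_gfp_neg,
              dot_sigma_px = dot_sigma_px,
              dot_min_sep_px = dot_min_sep_px,
              noise_sd = noise_sd,
              coincident_speckle_rate = coincident_speckle_rate,
              seed = as.integer(seed))
  class(cfg) <- "scene_config"
  validate_scene_config(cfg)
  cfg
}

validate_scene_config <- function(cfg) {
  stopifnot_scalar_number(cfg$width_px, "width_px", min = 1, integer = TRUE)
  stopifnot_scalar_number(cfg$height_px, "height_px", min = 1, integer = TRUE)
  stopifnot_scalar_number(cfg$n_cells, "n_cells", min = 1, integer = TRUE)
  stopifnot_scalar_number(cfg$recombined_fraction, "recombined_fraction",
                          min = 0, max = 1)
  stopifnot_scalar_number(cfg$membrane_width_px, "membrane_width_px",
                          min = 1, integer = TRUE)
  for (nm in c("dot_rate_green", "dot_rate_red_gfp_pos",
               "dot_rate_red_gfp_neg", "noise_sd",
               "coincident_speckle_rate"))
    stopifnot_scalar_number(cfg[[nm]], nm, min = 0)
  stopifnot_scalar_number(cfg$dot_sigma_px, "dot_sigma_px", min = 1e-6)
  stopifnot_scalar_number(cfg$dot_min_sep_px, "dot_min_sep_px", min = 0)
  stopifnot_scalar_number(cfg$seed, "seed", integer = TRUE)
  if (as.numeric(cfg$width_px) * cfg$height_px < cfg$n_cells)
    stop("raster must have at least as many pixels as cells", call. = FALSE)
  invisible(cfg)
}

# nearest-seed (Voronoi) partition of the raster; ties go to the lowest
# seed index. Chunked so the distance matrix never exceeds ~25 MB.
voronoi_label_map <- function(height, width, seed_rc) {
  n <- nrow(seed_rc)
  npx <- height * width
  lab <- integer(npx)
  s2 <- rowSums(seed_rc^2)
  chunk <- max(1L, floor(3e6 / n))
  px <- 0L
  while (px < npx) {
    take <- seq.int(px + 1L, min(npx, px + chunk))
    r <- ((take - 1L) %% height) + 1L
    c <- ((take - 1L) %/% height) + 1L
    # squared distance via |p|^2 + |s|^2 - 2 p.s ; argmin over seeds
    cross <- cbind(r, c) %*% t(seed_rc)
    d2 <- matrix(s2, nrow = length(take), ncol = n, byrow = TRUE) - 2 * cross
    lab[take] <- max.col(-d2, ties.method = "first")
    px <- px + chunk
  }
  matrix(lab, height, width)
}

#' Simulate a dual-reporter epithelial sheet
#'
#' Renders the two membrane-reporter channels of a synthetic tumour section.
#' Cell territories form a Voronoi tessellation of the raster; the Tomato
#' channel carries a membrane band along every cell wall, while the GFP
#' channel carries the same band only for the recombined (GFP+) cells. The
#' number of GFP+ cells is the nearest integer to
#' `recombined_fraction * n_cells`.
#'
#' @param config a [scene_config()].
#' @return A list with elements `tomato` and `gfp` (numeric intensity
#'   matrices on [0, 1]) and `truth`, a `scene_truth` list carrying
#'   `cell_label_map`, `gfp_cell_ids`, per-cell centroids and the
#'   configuration.
#' @seealso [simulate_fish_channels()] to add the smFISH channels.
#' @export
simulate_tissue <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  validate_scene_config(config)
  set.seed(config$seed)
  h <- config$height_px
  w <- config$width_px

  seed_px <- sample.int(h * w, config$n_cells)
  seed_rc <- cbind(((seed_px - 1L) %% h) + 1L, ((seed_px - 1L) %/% h) + 1L)
  labels <- voronoi_label_map(h, w, seed_rc)

  n_gfp <- round(config$recombined_fraction * config$n_cells)
  gfp_ids <- if (n_gfp > 0) sort(sample.int(config$n_cells, n_gfp)) else integer(0)

  band <- boundary_band(labels, config$membrane_width_px)
  tomato <- matrix(0, h, w)
  tomato[band] <- MEMBRANE_AMP
  gfp <- matrix(0, h, w)
  gfp[band & matrix(labels %in% gfp_ids, h, w)] <- MEMBRANE_AMP

  if (config$noise_sd > 0) {
    tomato <- tomato + rnorm(h * w, 0, config$noise_sd)
    gfp <- gfp + rnorm(h * w, 0, config$noise_sd)
  }
  tomato <- pmin(pmax(tomato, 0), 1)
  gfp <- pmin(pmax(gfp, 0), 1)

  # centroids: mean row/col per label
  rr <- ((seq_len(h * w) - 1L) %% h) + 1L
  cc <- ((seq_len(h * w) - 1L) %/% h) + 1L
  npix <- tabulate(labels, nbins = config$n_cells)
  cent_y <- as.numeric(rowsum(as.numeric(rr), as.vector(labels))) / npix
  cent_x <- as.numeric(rowsum(as.numeric(cc), as.vector(labels))) / npix

  truth <- structure(list(
    cell_label_map = labels,
    gfp_cell_ids = gfp_ids,
    cells = data.frame(cell_id = seq_len(config$n_cells),
                       centroid_x = cent_x, centroid_y = cent_y,
                       gfp = seq_len(config$n_cells) %in% gfp_ids,
                       n_pixels = npix),
    dots_per_cell = NULL,
    dot_positions = NULL,
    speckle_positions = NULL,
    config = config), class = "scene_truth")

  list(tomato = tomato, gfp = gfp, truth = truth)
}

# add isotropic Gaussian spots at (ys, xs) into img
render_spots <- function(img, ys, xs, sigma, amp = DOT_AMP) {
  if (!length(ys)) return(img)
  h <- nrow(img)
  w <- ncol(img)
  rad <- ceiling(4 * sigma)
  for (i in seq_along(ys)) {
    r0 <- max(1L, floor(ys[i] - rad)); r1 <- min(h, ceiling(ys[i] + rad))
    c0 <- max(1L, floor(xs[i] - rad)); c1 <- min(w, ceiling(xs[i] + rad))
    if (r0 > r1 || c0 > c1) next
    dr <- (r0:r1) - ys[i]
    dc <- (c0:c1) - xs[i]
    g <- amp * exp(-outer(dr^2, dc^2, "+") / (2 * sigma^2))
    img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] + g
  }
  img
}

#' Simulate the two smFISH channels of a scene
#'
#' Draws per-cell dot counts from Poisson laws (green rate uniform across
#' cells; far-red rate depending on GFP status), renders each dot as an
#' isotropic Gaussian spot at a uniform position in the cell's cytoplasmic
#' interior (clear of the membrane band), and injects coincident speckles --
#' spurious dots rendered at identical coordinates in both channels -- at an
#' expected rate of `coincident_speckle_rate` per image. True counts and all
#' coordinates are recorded in the returned ground truth.
#'
#' @param config the [scene_config()] used for the tissue.
#' @param truth the `scene_truth` returned by [simulate_tissue()].
#' @return A list with `green` and `farred` intensity matrices and the
#'   augmented `truth` (fields `dots_per_cell`, `dot_positions`,
#'   `speckle_positions`).
#' @export
simulate_fish_channels <- function(config, truth) {
  stopifnot(inherits(config, "scene_config"))
  if (!inherits(truth, "scene_truth") || is.null(truth$cell_label_map))
    stop("'truth' must come from simulate_tissue() and carry a cell_label_map",
         call. = FALSE)
  validate_scene_config(config)
  set.seed(config$seed + 1L)
  labels <- truth$cell_label_map
  h <- nrow(labels)
  w <- ncol(labels)
  n <- config$n_cells
  gfp <- seq_len(n) %in% truth$gfp_cell_ids

  # cytoplasmic interior: cell pixels clear of the membrane zone and of the
  # field-of-view border (a border-clipped dot is not a countable particle)
  margin <- as.integer(ceiling(2 * config$dot_sigma_px)) + 1L
  interior <- !boundary_band(labels, margin)
  edge <- matrix(FALSE, h, w)
  edge[c(seq_len(min(margin, h)), seq.int(max(1L, h - margin + 1L), h)), ] <- TRUE
  edge[, c(seq_len(min(margin, w)), seq.int(max(1L, w - margin + 1L), w))] <- TRUE
  interior <- interior & !edge
  pix_all <- split(seq_len(h * w), as.vector(labels))
  pix_int <- split(which(interior), as.vector(labels)[which(interior)])
  pick_from <- lapply(as.character(seq_len(n)), function(id) {
    p <- pix_int[[id]]
    if (is.null(p) || !length(p)) pix_all[[id]] else p
  })

  counts_green <- rpois(n, config$dot_rate_green)
  counts_red <- rpois(n, ifelse(gfp, config$dot_rate_red_gfp_pos,
                                config$dot_rate_red_gfp_neg))

  # joint hard-core placement: dots of one cell (both channels) keep at
  # least dot_min_sep_px between centres -- closer pairs would not be
  # resolvable as distinct dots, so true counts are over resolvable dots
  d2min <- config$dot_min_sep_px^2
  place_cell <- function(i, k) {
    p <- pick_from[[i]]
    ys <- numeric(k)
    xs <- numeric(k)
    for (j in seq_len(k)) {
      for (attempt in seq_len(200L)) {
        px <- p[sample.int(length(p), 1L)]
        y <- ((px - 1L) %% h) + 1L + runif(1L, -0.5, 0.5)
        x <- ((px - 1L) %/% h) + 1L + runif(1L, -0.5, 0.5)
        if (j == 1L || all((ys[seq_len(j - 1L)] - y)^2 +
                           (xs[seq_len(j - 1L)] - x)^2 >= d2min)) break
      }
      ys[j] <- y
      xs[j] <- x
    }
    cbind(ys, xs)
  }
  dots_g <- dots_r <- vector("list", n)
  for (i in seq_len(n)) {
    kg <- counts_green[i]
    kr <- counts_red[i]
    if (kg + kr == 0L) next
    pos <- place_cell(i, kg + kr)
    if (kg > 0L)
      dots_g[[i]] <- data.frame(cell_id = i, channel = "green",
                                y = pos[seq_len(kg), 1L],
                                x = pos[seq_len(kg), 2L])
    if (kr > 0L)
      dots_r[[i]] <- data.frame(cell_id = i, channel = "farred",
                                y = pos[kg + seq_len(kr), 1L],
                                x = pos[kg + seq_len(kr), 2L])
  }
  empty_dots <- data.frame(cell_id = integer(0), channel = character(0),
                           y = numeric(0), x = numeric(0))
  dots_g <- do.call(rbind, c(list(empty_dots), dots_g))
  dots_r <- do.call(rbind, c(list(empty_dots), dots_r))

  n_sp <- rpois(1L, config$coincident_speckle_rate)
  speckles <- data.frame(y = runif(n_sp, 0.5, h + 0.5),
                         x = runif(n_sp, 0.5, w + 0.5))

  green <- render_spots(matrix(0, h, w), dots_g$y, dots_g$x,
                        config$dot_sigma_px)
  green <- render_spots(green, speckles$y, speckles$x, config$dot_sigma_px)
  farred <- render_spots(matrix(0, h, w), dots_r$y, dots_r$x,
                         config$dot_sigma_px)
  farred <- render_spots(farred, speckles$y, speckles$x, config$dot_sigma_px)
  if (config$noise_sd > 0) {
    green <- green + rnorm(h * w, 0, config$noise_sd)
    farred <- farred + rnorm(h * w, 0, config$noise_sd)
  }
  green <- pmin(pmax(green, 0), 1)
  farred <- pmin(pmax(farred, 0), 1)

  truth$dots_per_cell <- rbind(
    data.frame(cell_id = seq_len(n), channel = "green", count = counts_green),
    data.frame(cell_id = seq_len(n), channel = "farred", count = counts_red))
  truth$dot_positions <- rbind(dots_g, dots_r)
  truth$speckle_positions <- speckles

  list(green = green, farred = farred, truth = truth)
}

#' Audit cross-channel speckle rejection on a synthetic scene
#'
#' Matches detected dots against the injected coincident speckles of a
#' synthetic scene (a dot "is" a speckle when its pixel set contains a
#' speckle centre) and reports how many speckle dots were eliminated by the
#' cross-channel overlap filter, together with the collateral loss of true
#' dots to that filter.
#'
#' @param green_dots,farred_dots `fish_dots` objects after
#'   [cross_channel_filter()] (and possibly assignment).
#' @param speckle_positions data frame with `y`, `x` speckle centres (from
#'   the scene truth).
#' @return A list: `n_speckle_dots` (detected dots containing a speckle
#'   centre), `n_speckle_rejected` (those flagged `overlap_filter`),
#'   `n_true_dots`, `n_true_lost` (non-speckle dots flagged
#'   `overlap_filter`), and the rates `speckle_rejection_rate`,
#'   `true_dot_loss_rate`.
#' @export
speckle_rejection_stats <- function(green_dots, farred_dots,
                                    speckle_positions) {
  stopifnot(inherits(green_dots, "fish_dots"),
            inherits(farred_dots, "fish_dots"))
  h <- green_dots$dim[1]
  sp_px <- (round(speckle_positions$x) - 1L) * h + round(speckle_positions$y)
  tally <- function(dots) {
    considered <- dots$info$eliminated_by != "circularity_filter"
    is_sp <- vapply(dots$pixels, function(p) any(p %in% sp_px), TRUE)
    by_overlap <- dots$info$eliminated_by == "overlap_filter"
    c(sp = sum(is_sp & considered),
      sp_rej = sum(is_sp & by_overlap),
      tr = sum(!is_sp & considered),
      tr_lost = sum(!is_sp & by_overlap))
  }
  tot <- tally(green_dots) + tally(farred_dots)
  list(n_speckle_dots = unname(tot["sp"]),
       n_speckle_rejected = unname(tot["sp_rej"]),
       n_true_dots = unname(tot["tr"]),
       n_true_lost = unname(tot["tr_lost"]),
       speckle_rejection_rate = unname(tot["sp_rej"] / tot["sp"]),
       true_dot_loss_rate = unname(tot["tr_lost"] / tot["tr"]))
}

#' Growth-series configuration
#'
#' Parameters of the saturating clonal-expansion law
#' `y = a * ln(t + b)` used to simulate (chase time, GFP%) observations.
#' Defaults describe the reference expansion law of the traced GFP+
#' population: coefficient 1.4, unit offset, chase points spanning 24 h
#' (day 1) to 90 days. Times are expressed in days (24 h = 1.0,
#' 36 h = 1.5).
#'
#' @param time_points_days chase times (days), strictly positive.
#' @param growth_coeff multiplier `a` of the log term.
#' @param growth_offset offset `b` inside the log, positive.
#' @param obs_noise_sd SD of additive Gaussian observation noise on GFP%.
#' @param replicates_per_time biological replicates per chase point.
#' @param seed integer seed.
#' @return A validated list of class `growth_config`.
#' @export
growth_config <- function(time_points_days = c(1, 1.5, 4, 10, 30, 60, 90),
                          growth_coeff = 1.4, growth_offset = 1,
                          obs_noise_sd = 0.5, replicates_per_time = 3L,
                          seed = 1L) {
  cfg <- list(time_points_days = as.numeric(time_points_days),
              growth_coeff = growth_coeff, growth_offset = growth_offset,
              obs_noise_sd = obs_noise_sd,
              replicates_per_time = as.integer(replicates_per_time),
              seed = as.integer(seed))
  class(cfg) <- "growth_config"
  if (!length(cfg$time_points_days) || any(cfg$time_points_days <= 0) ||
      any(!is.finite(cfg$time_points_days)))
    stop("time_points_days must be strictly positive", call. = FALSE)
  stopifnot_scalar_number(cfg$growth_coeff, "growth_coeff", min = 1e-12)
  stopifnot_scalar_number(cfg$growth_offset, "growth_offset", min = 1e-12)
  stopifnot_scalar_number(cfg$obs_noise_sd, "obs_noise_sd", min = 0)
  stopifnot_scalar_number(cfg$replicates_per_time, "replicates_per_time",
                          min = 1, integer = TRUE)
  stopifnot_scalar_number(cfg$seed, "seed", integer = TRUE)
  cfg
}

#' Simulate a clonal-expansion growth series
#'
#' Emits `y = a * ln(t + b) + e`, `e ~ N(0, obs_noise_sd^2)` for every chase
#' point and replicate. With `obs_noise_sd = 0` the output is exact.
#' Replicates are tagged alternately `facs` / `surface`, emulating the dual
#' quantification methodology whose observations are pooled for fitting.
#'
#' @param config a [growth_config()].
#' @return A `growth_series` data frame with columns `time_days`,
#'   `gfp_percent` and `method_tag`.
#' @export
simulate_growth_series <- function(config) {
  stopifnot(inherits(config, "growth_config"))
  if (any(config$time_points_days + config$growth_offset <= 0))
    stop("t + growth_offset must be positive for all time points",
         call. = FALSE)
  set.seed(config$seed)
  t <- rep(config$time_points_days, each = config$replicates_per_time)
  y <- config$growth_coeff * log(t + config$growth_offset)
  if (config$obs_noise_sd > 0)
    y <- y + rnorm(length(t), 0, config$obs_noise_sd)
  tag <- rep_len(c("facs", "surface"), config$replicates_per_time)
  out <- data.frame(time_days = t,
                    gfp_percent = y,
                    method_tag = rep(tag, times = length(config$time_points_days)))
  class(out) <- c("growth_series", "data.frame")
  out
}
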