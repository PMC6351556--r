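# smFISH (RNAscope) dot counting per cell.
#
# Fixed pipeline order: classify_pixels -> erode_segmentation ->
# particle_analysis -> cross_channel_filter -> assign_dots_to_cells ->
# dot_ratio. Stages never delete dot records or mutate pixel sets; they only
# set the `eliminated_by` flag, so the full audit trail of every candidate
# dot survives to the output tables.

#' Cell regions of interest
#'
#' Builds the cell-ROI container used for dot assignment: an integer label
#' map (0 = outside any cell) plus each cell's GFP status. Use
#' [cell_rois_from_pixels()] to build one from explicit pixel sets.
#'
#' @param label_map integer matrix; pixels of cell `i` carry value `i`.
#' @param gfp_status character vector over cell ids 1..max(label_map), each
#'   `"gfp_pos"` or `"gfp_neg"`.
#' @return An object of class `cell_rois`.
#' @export
cell_rois <- function(label_map, gfp_status) {
  if (!is.matrix(label_map) || any(label_map < 0))
    stop("'label_map' must be a matrix of nonnegative integer labels",
         call. = FALSE)
  n <- max(label_map)
  if (n < 1L) stop("label map contains no cells", call. = FALSE)
  if (length(gfp_status) != n ||
      !all(gfp_status %in% c("gfp_pos", "gfp_neg")))
    stop("'gfp_status' must give 'gfp_pos'/'gfp_neg' for each of the ",
         n, " cells", call. = FALSE)
  if (any(tabulate(label_map[label_map > 0L], nbins = n) == 0L))
    stop("every cell id must own at least one pixel", call. = FALSE)
  structure(list(labels = matrix(as.integer(label_map), nrow(label_map)),
                 info = data.frame(cell_id = seq_len(n),
                                   gfp_status = as.character(gfp_status))),
            class = "cell_rois")
}

#' @rdname cell_rois
#' @param pixel_sets list of integer vectors of linear pixel indices, one per
#'   cell; sets must be disjoint and nonempty.
#' @param dim raster dimensions `c(rows, cols)`.
#' @export
cell_rois_from_pixels <- function(pixel_sets, dim, gfp_status) {
  all_px <- unlist(pixel_sets, use.names = FALSE)
  if (anyDuplicated(all_px))
    stop("cell pixel sets overlap", call. = FALSE)
  lab <- matrix(0L, dim[1], dim[2])
  for (i in seq_along(pixel_sets)) {
    if (!length(pixel_sets[[i]]))
      stop("cell pixel sets must be nonempty", call. = FALSE)
    lab[pixel_sets[[i]]] <- i
  }
  cell_rois(lab, gfp_status)
}

#' Classify pixels of a FISH channel into dots vs background
#'
#' Deterministic intensity classifier standing in for a trained pixel
#' classifier: foreground is every pixel at or above a fixed intensity
#' (`method = "threshold"`), or exactly the top `(1 - param)` fraction of
#' pixels (`method = "quantile"`, ties broken by intensity then raster
#' order).
#'
#' @param img numeric intensity matrix.
#' @param method `"threshold"` or `"quantile"`.
#' @param param the intensity threshold, or the quantile in (0, 1).
#' @return A logical mask.
#' @export
classify_pixels <- function(img, method = c("threshold", "quantile"),
                            param) {
  method <- match.arg(method)
  if (!is.matrix(img) || !is.numeric(img) || length(img) == 0L)
    stop("'img' must be a nonempty numeric matrix", call. = FALSE)
  if (method == "threshold") {
    stopifnot_scalar_number(param, "param")
    return(img >= param)
  }
  if (!is.numeric(param) || length(param) != 1L || param <= 0 || param >= 1)
    stop("quantile must lie strictly inside (0, 1)", call. = FALSE)
  k <- round((1 - param) * length(img))
  mask <- matrix(FALSE, nrow(img), ncol(img))
  if (k >= 1L) {
    ord <- order(-as.vector(img), seq_along(img))
    mask[ord[seq_len(k)]] <- TRUE
  }
  mask
}

#' One-pass 3x3 erosion of a dot segmentation
#'
#' Applied exactly once. Under the default `"any_neighbour"` rule a
#' foreground pixel is eliminated when at least one of its 8 neighbours
#' (3x3 neighbourhood, out-of-raster treated as background) is background --
#' standard morphological erosion, which both separates touching dot
#' aggregates and suppresses small low-intensity dots. The stricter
#' `"isolated"` rule eliminates only pixels whose entire 3x3 neighbourhood is
#' background.
#'
#' @param mask logical matrix.
#' @param rule `"any_neighbour"` (default) or `"isolated"`.
#' @return A logical mask, always a subset of the input.
#' @export
erode_segmentation <- function(mask, rule = c("any_neighbour", "isolated")) {
  rule <- match.arg(rule)
  if (!is.matrix(mask) || !is.logical(mask))
    stop("'mask' must be a logical matrix", call. = FALSE)
  if (rule == "any_neighbour") {
    out <- mask
    for (k in seq_len(nrow(.OFF8)))
      out <- out & shift_mat(mask, .OFF8[k, 1L], .OFF8[k, 2L], FALSE)
  } else {
    any_nb <- matrix(FALSE, nrow(mask), ncol(mask))
    for (k in seq_len(nrow(.OFF8)))
      any_nb <- any_nb | shift_mat(mask, .OFF8[k, 1L], .OFF8[k, 2L], FALSE)
    out <- mask & any_nb
  }
  out
}

#' Particle analysis of a dot mask
#'
#' Enumerates 8-connected foreground components with no size limit, numbered
#' by their top-left-most pixel (raster order). Circularity is
#' `4 * pi * area / perimeter^2`, clamped to at most 1; single-pixel
#' particles take circularity 1 by convention. The default perimeter
#' estimator is the boundary-crack count (exposed pixel edges) scaled by
#' pi/4, which is exact for discs; `perimeter = "crack"` gives the raw
#' count. Components with circularity outside `[circ_min, circ_max]` are
#' flagged `eliminated_by = "circularity_filter"`.
#'
#' @param mask logical matrix (typically from [erode_segmentation()]).
#' @param circ_min,circ_max circularity bounds for single-dot acceptance.
#' @param channel optional channel name stored on the records
#'   (`"green"`/`"farred"`).
#' @param perimeter `"crack_corrected"` (default) or `"crack"`.
#' @return An object of class `fish_dots`: a record table (`dot_id`,
#'   `channel`, `area_px`, `circularity`, `assigned_cell`, `eliminated_by`)
#'   plus the pixel set of every dot.
#' @export
particle_analysis <- function(mask, circ_min = 0.4, circ_max = 1.0,
                              channel = NA_character_,
                              perimeter = c("crack_corrected", "crack")) {
  perimeter <- match.arg(perimeter)
  if (circ_min > circ_max)
    stop("circ_min must not exceed circ_max", call. = FALSE)
  lab <- label_components8(mask)
  k <- max(lab)
  if (k == 0L) {
    return(new_fish_dots(data.frame(dot_id = integer(0),
                                    channel = character(0),
                                    area_px = integer(0),
                                    circularity = numeric(0),
                                    assigned_cell = integer(0),
                                    eliminated_by = character(0)),
                         list(), dim(mask)))
  }
  area <- tabulate(lab[lab > 0L], nbins = k)
  crack <- crack_edges_by_label(lab)
  per <- if (perimeter == "crack_corrected") crack * (pi / 4) else crack
  circ <- pmin(1, 4 * pi * area / per^2)
  circ[area == 1L] <- 1
  pixels <- split(which(lab > 0L), lab[lab > 0L])
  names(pixels) <- NULL
  info <- data.frame(dot_id = seq_len(k),
                     channel = channel,
                     area_px = area,
                     circularity = circ,
                     assigned_cell = NA_integer_,
                     eliminated_by = ifelse(circ >= circ_min & circ <= circ_max,
                                            "none", "circularity_filter"))
  new_fish_dots(info, pixels, dim(mask))
}

new_fish_dots <- function(info, pixels, dim) {
  structure(list(info = info, pixels = pixels, dim = dim),
            class = "fish_dots")
}

#' @export
print.fish_dots <- function(x, ...) {
  n <- nrow(x$info)
  cat(sprintf("fish_dots: %d candidate dots on a %dx%d raster\n",
              n, x$dim[1], x$dim[2]))
  if (n) print(table(x$info$eliminated_by))
  invisible(x)
}

#' @export
as.data.frame.fish_dots <- function(x, ...) x$info

surviving <- function(dots) which(dots$info$eliminated_by == "none")

# integer raster with each pixel carrying the id of the surviving dot that
# owns it (dot pixel sets are disjoint by construction)
dot_owner_raster <- function(dots, idx = surviving(dots)) {
  own <- integer(prod(dots$dim))
  for (i in idx) own[dots$pixels[[i]]] <- i
  own
}

#' Cross-channel coincidence filter
#'
#' Challenges every surviving dot against the surviving dots of the other
#' fluorescent channel: a dot is eliminated when more than `overlap_frac`
#' (default 20%) of its own surface overlaps some dot of the other channel.
#' The rule is applied symmetrically and simultaneously in both channels, so
#' coincident background speckles (present at the same coordinates in both
#' channels) are removed from both. Eliminated dots are flagged
#' `eliminated_by = "overlap_filter"`, never deleted.
#'
#' @param green,farred `fish_dots` objects on a common raster.
#' @param overlap_frac overlap fraction (of the dot's own area) above which
#'   it is eliminated.
#' @return A list with the updated `green` and `farred` objects.
#' @export
cross_channel_filter <- function(green, farred, overlap_frac = 0.2) {
  stopifnot(inherits(green, "fish_dots"), inherits(farred, "fish_dots"))
  if (!identical(green$dim, farred$dim))
    stop("dot sets live on different rasters", call. = FALSE)
  stopifnot_scalar_number(overlap_frac, "overlap_frac", min = 0, max = 1)
  own_g <- dot_owner_raster(green)
  own_f <- dot_owner_raster(farred)
  flag <- function(dots, other_owner) {
    idx <- surviving(dots)
    out <- dots
    for (i in idx) {
      partners <- other_owner[dots$pixels[[i]]]
      partners <- partners[partners > 0L]
      if (!length(partners)) next
      if (max(tabulate(partners)) > overlap_frac * dots$info$area_px[i])
        out$info$eliminated_by[i] <- "overlap_filter"
    }
    out
  }
  list(green = flag(green, own_f), farred = flag(farred, own_g))
}

#' Assign surviving dots to cells by majority surface
#'
#' A dot is assigned to the unique cell containing strictly more than
#' `assign_frac` (default 50%) of its pixels; with disjoint cells and a
#' strict majority the assignment is unique by construction. Dots with no
#' majority cell -- including an exact 50/50 split across two cells -- stay
#' unassigned and are flagged `eliminated_by = "assignment"`.
#'
#' @param dots a `fish_dots` object.
#' @param cells a [cell_rois()] object on the same raster.
#' @param assign_frac strict-majority fraction.
#' @return The updated `fish_dots` with `assigned_cell` filled in.
#' @export
assign_dots_to_cells <- function(dots, cells, assign_frac = 0.5) {
  stopifnot(inherits(dots, "fish_dots"), inherits(cells, "cell_rois"))
  if (!identical(as.integer(dots$dim), as.integer(dim(cells$labels))))
    stop("dots and cells live on different rasters", call. = FALSE)
  if (assign_frac <= 0 || assign_frac >= 1)
    stop("'assign_frac' must lie strictly inside (0, 1)", call. = FALSE)
  lab <- cells$labels
  out <- dots
  for (i in surviving(dots)) {
    owners <- lab[dots$pixels[[i]]]
    owners <- owners[owners > 0L]
    assigned <- NA_integer_
    if (length(owners)) {
      counts <- tabulate(owners)
      best <- which.max(counts)
      if (counts[best] > assign_frac * dots$info$area_px[i])
        assigned <- best
    }
    if (is.na(assigned)) {
      out$info$eliminated_by[i] <- "assignment"
    } else {
      out$info$assigned_cell[i] <- assigned
    }
  }
  out
}

#' Per-cell counts of surviving assigned dots
#'
#' @param dots a `fish_dots` object after [assign_dots_to_cells()].
#' @param cells the matching [cell_rois()].
#' @return Integer vector of dot counts indexed by cell id (cells with no
#'   dots count 0).
#' @export
count_dots_per_cell <- function(dots, cells) {
  stopifnot(inherits(dots, "fish_dots"), inherits(cells, "cell_rois"))
  keep <- dots$info$eliminated_by == "none" & !is.na(dots$info$assigned_cell)
  tabulate(dots$info$assigned_cell[keep], nbins = nrow(cells$info))
}

#' Dot ratio between GFP+ and GFP- cell populations
#'
#' Mean number of surviving assigned dots per cell, computed over all cells
#' of each GFP population (cells with zero dots included), and their ratio
#' GFP+ / GFP-.
#'
#' @param dots a `fish_dots` object after assignment.
#' @param cells the matching [cell_rois()].
#' @param channel restrict to this channel (`"green"` or `"farred"`);
#'   default uses the channel stored on the records.
#' @return A list of class `dot_ratio_result`: `channel`,
#'   `mean_dots_gfp_pos`, `mean_dots_gfp_neg`, `ratio`, `n_gfp_pos`,
#'   `n_gfp_neg`.
#' @export
dot_ratio <- function(dots, cells, channel = NULL) {
  stopifnot(inherits(dots, "fish_dots"), inherits(cells, "cell_rois"))
  if (is.null(channel)) channel <- unique(dots$info$channel)
  if (length(channel) != 1L)
    stop("specify a single channel", call. = FALSE)
  sub <- dots
  sub$info$eliminated_by[!(sub$info$channel %in% channel)] <- "other_channel"
  counts <- count_dots_per_cell(sub, cells)
  pos <- cells$info$gfp_status == "gfp_pos"
  if (!any(pos) || all(pos))
    stop("both GFP populations must be represented among the cells",
         call. = FALSE)
  m_pos <- mean(counts[pos])
  m_neg <- mean(counts[!pos])
  if (m_neg == 0)
    stop("ratio undefined: GFP- population has zero mean dot count",
         call. = FALSE)
  structure(list(channel = channel,
                 mean_dots_gfp_pos = m_pos,
                 mean_dots_gfp_neg = m_neg,
                 ratio = m_pos / m_neg,
                 n_gfp_pos = sum(pos),
                 n_gfp_neg = sum(!pos)),
            class = "dot_ratio_result")
}

#' @export
print.dot_ratio_result <- function(x, ...) {
  cat(sprintf(
    "Dot ratio [%s]: mean GFP+ = %.3f (n=%d), mean GFP- = %.3f (n=%d), ratio = %.3f\n",
    x$channel, x$mean_dots_gfp_pos, x$n_gfp_pos, x$mean_dots_gfp_neg,
    x$n_gfp_neg, x$ratio))
  invisible(x)
}

#' Run the full smFISH dot-counting pipeline on two channels
#'
#' Convenience wrapper chaining the fixed pipeline order on both FISH
#' channels and computing per-cell counts and the GFP+/GFP- ratio per
#' channel.
#'
#' @param green_img,farred_img intensity matrices.
#' @param cells a [cell_rois()] object.
#' @param classify_method,classify_param see [classify_pixels()].
#' @param circ_min,circ_max see [particle_analysis()].
#' @param overlap_frac see [cross_channel_filter()].
#' @param assign_frac see [assign_dots_to_cells()].
#' @param erode_rule see [erode_segmentation()].
#' @return A list with `dots` (list of `fish_dots` per channel), `counts`
#'   (per-cell count matrix, one column per channel) and `ratios` (list of
#'   `dot_ratio_result`, `NULL` for a channel whose ratio is undefined).
#' @export
fish_count <- function(green_img, farred_img, cells,
                       classify_method = "threshold", classify_param = 0.25,
                       circ_min = 0.4, circ_max = 1.0, overlap_frac = 0.2,
                       assign_frac = 0.5, erode_rule = "any_neighbour") {
  seg <- function(img, channel) {
    mask <- classify_pixels(img, classify_method, classify_param)
    mask <- erode_segmentation(mask, erode_rule)
    particle_analysis(mask, circ_min, circ_max, channel = channel)
  }
  g <- seg(green_img, "green")
  f <- seg(farred_img, "farred")
  filt <- cross_channel_filter(g, f, overlap_frac)
  g <- assign_dots_to_cells(filt$green, cells, assign_frac)
  f <- assign_dots_to_cells(filt$farred, cells, assign_frac)
  counts <- cbind(green = count_dots_per_cell(g, cells),
                  farred = count_dots_per_cell(f, cells))
  ratio_or_null <- function(d, ch) tryCatch(dot_ratio(d, cells, ch),
                                            error = function(e) NULL)
  list(dots = list(green = g, farred = f),
       counts = counts,
       ratios = list(green = ratio_or_null(g, "green"),
                     farred = ratio_or_null(f, "farred")))
}
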