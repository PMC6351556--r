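# Clonal-area quantification from two-channel (Tomato/GFP) images and clone
# detection/size statistics on a cell tessellation.

#' Threshold a fluorescence channel into a binary mask
#'
#' Foreground is every pixel with intensity greater than or equal to the
#' threshold. In `"auto"` mode an Otsu threshold is computed from the image
#' histogram, a reproducible stand-in for per-channel manual threshold
#' adjustment.
#'
#' @param img numeric intensity matrix on [0, 1].
#' @param threshold a number, or `"auto"` for Otsu.
#' @return A logical mask of the same shape.
#' @export
binarize_channel <- function(img, threshold = "auto") {
  if (!is.matrix(img) || !is.numeric(img) || length(img) == 0L)
    stop("'img' must be a nonempty numeric matrix", call. = FALSE)
  if (identical(threshold, "auto")) {
    rng <- range(img)
    if (rng[1] == rng[2])
      stop("auto threshold is undefined on a constant image", call. = FALSE)
    threshold <- EBImage::otsu(img, range = c(0, 1), levels = 256)
  } else {
    stopifnot_scalar_number(threshold, "threshold")
  }
  img >= threshold
}

#' Quantify GFP+ clonal area on one tumour section
#'
#' Computes the pixel sums `A` (Tomato foreground, total tumour area) and `B`
#' (GFP foreground, recombined area) and the clonal-area statistic
#' `GFP% = 100 * B / (A - B)`. Because the reporter is homozygous, GFP+ cells
#' are also Tomato+, so the GFP area is subtracted from the total before it
#' is set to 100%; the statistic can therefore reach or exceed 100%.
#' `B = 0` returns 0% regardless of `A`.
#'
#' @param tomato_mask,gfp_mask logical masks of equal shape (see
#'   [binarize_channel()]).
#' @return A list of class `area_quantification` with fields `A`, `B`,
#'   `gfp_percent`.
#' @export
quantify_gfp_area <- function(tomato_mask, gfp_mask) {
  if (!identical(dim(tomato_mask), dim(gfp_mask)))
    stop("mask shapes differ", call. = FALSE)
  A <- sum(tomato_mask)
  B <- sum(gfp_mask)
  if (B == 0) {
    pct <- 0
  } else {
    if (A - B <= 0)
      stop("GFP% undefined: A - B <= 0 with B > 0", call. = FALSE)
    pct <- 100 * B / (A - B)
  }
  structure(list(A = as.integer(A), B = as.integer(B), gfp_percent = pct),
            class = "area_quantification")
}

#' @export
print.area_quantification <- function(x, ...) {
  cat(sprintf("Area quantification: A (Tomato px) = %d, B (GFP px) = %d, GFP%% = %.4g\n",
              x$A, x$B, x$gfp_percent))
  invisible(x)
}

# size class for clone cell counts given (small_max, intermediate_max)
clone_size_class <- function(n_cells, small_max = 2L, intermediate_max = 5L) {
  if (small_max >= intermediate_max)
    stop("clone size thresholds must satisfy small_max < intermediate_max",
         call. = FALSE)
  cut(n_cells, breaks = c(0, small_max, intermediate_max, Inf),
      labels = c("small", "intermediate", "large"))
}

# adjacency pairs (8-connectivity) between labelled cell territories
label_adjacency_pairs <- function(labels) {
  pairs <- vector("list", 4L)
  dirs <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  for (k in seq_along(dirs)) {
    nb <- shift_mat(labels, dirs[[k]][1L], dirs[[k]][2L], 0L)
    touch <- labels > 0L & nb > 0L & nb != labels
    if (any(touch)) pairs[[k]] <- cbind(labels[touch], nb[touch])
  }
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs)) return(matrix(integer(0), 0, 2))
  unique(cbind(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2])))
}

#' Detect GFP+ clones on a cell tessellation
#'
#' A cell is called GFP+ when more than `gfp_frac` (default 50%) of its
#' membrane-adjacent pixels (its own pixels within `membrane_width` px of a
#' wall with another cell) fall in the GFP foreground mask. A clone is a
#' maximal set of GFP+ cells whose territories touch (8-connectivity on the
#' label adjacency graph). Each clone is sized by cell count and classified
#' as small (<= `small_max` cells), intermediate or large
#' (> `intermediate_max` cells).
#'
#' @param gfp_mask logical GFP foreground mask.
#' @param cell_label_map integer label map of cell territories (same shape).
#' @param time_days chase time attached to the returned records.
#' @param membrane_width width of the membrane-adjacent band, px.
#' @param gfp_frac overlap fraction above which a cell is called GFP+.
#' @param small_max,intermediate_max upper cell counts of the small and
#'   intermediate classes.
#' @return A data frame of class `clone_records` with columns `clone_id`,
#'   `time_days`, `n_cells`, `size_class`, plus attribute `gfp_cells` (the
#'   ids of cells called GFP+). Zero rows when no cell is GFP+.
#' @export
detect_clones <- function(gfp_mask, cell_label_map, time_days = NA_real_,
                          membrane_width = 2L, gfp_frac = 0.5,
                          small_max = 2L, intermediate_max = 5L) {
  if (!identical(dim(gfp_mask), dim(cell_label_map)))
    stop("mask and label map shapes differ", call. = FALSE)
  band <- boundary_band(cell_label_map, membrane_width)
  n <- max(cell_label_map)
  in_band <- band & cell_label_map > 0L
  band_n <- tabulate(cell_label_map[in_band], nbins = n)
  band_gfp <- tabulate(cell_label_map[in_band & gfp_mask], nbins = n)
  gfp_cells <- which(band_n > 0L & band_gfp > gfp_frac * band_n)

  empty <- data.frame(clone_id = integer(0), time_days = numeric(0),
                      n_cells = integer(0),
                      size_class = factor(character(0),
                                          levels = c("small", "intermediate",
                                                     "large")))
  if (!length(gfp_cells)) {
    attr(empty, "gfp_cells") <- integer(0)
    class(empty) <- c("clone_records", "data.frame")
    return(empty)
  }

  adj <- label_adjacency_pairs(cell_label_map)
  keep <- adj[, 1] %in% gfp_cells & adj[, 2] %in% gfp_cells
  adj <- adj[keep, , drop = FALSE]
  vid <- match(seq_len(n), gfp_cells)  # cell id -> vertex id
  g <- igraph::make_graph(as.vector(t(matrix(vid[adj], ncol = 2))),
                          n = length(gfp_cells), directed = FALSE)
  memb <- igraph::components(g)$membership
  sizes <- tabulate(memb)
  # number clones by their lowest member cell id
  first_cell <- vapply(seq_along(sizes),
                       function(k) min(gfp_cells[memb == k]), numeric(1))
  ord <- order(first_cell)
  out <- data.frame(clone_id = seq_along(ord),
                    time_days = time_days,
                    n_cells = sizes[ord],
                    size_class = clone_size_class(sizes[ord], small_max,
                                                  intermediate_max))
  attr(out, "gfp_cells") <- gfp_cells
  class(out) <- c("clone_records", "data.frame")
  out
}

#' Clone size-class distribution per chase time
#'
#' Percentage of clones in each size class, per time point; percentages sum
#' to 100 within each time point.
#'
#' @param clones a `clone_records` data frame (rows from one or more calls to
#'   [detect_clones()], possibly at several chase times).
#' @return A data frame with columns `time_days`, `size_class`, `n_clones`,
#'   `percent`.
#' @export
clone_size_distribution <- function(clones) {
  if (!is.data.frame(clones) || nrow(clones) == 0L)
    stop("no clones to summarize", call. = FALSE)
  times <- sort(unique(clones$time_days))
  out <- do.call(rbind, lapply(times, function(t) {
    cl <- clones[clones$time_days == t | (is.na(t) & is.na(clones$time_days)), ]
    n <- table(factor(cl$size_class,
                      levels = c("small", "intermediate", "large")))
    data.frame(time_days = t, size_class = names(n),
               n_clones = as.integer(n),
               percent = 100 * as.integer(n) / nrow(cl))
  }))
  rownames(out) <- NULL
  out
}
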