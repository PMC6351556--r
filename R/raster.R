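# Internal raster primitives shared by the scene generator and both
# quantification pipelines. Images are numeric matrices (rows = y, cols = x,
# intensities on [0, 1]); masks are logical matrices; label maps are integer
# matrices with 0 = background. Linear (column-major) index order is the
# package's deterministic "raster order" for tie-breaks and dot enumeration.

# offsets of the 8-neighbourhood
.OFF8 <- cbind(dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
               dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))
.OFF4 <- cbind(dr = c(-1L, 1L, 0L, 0L), dc = c(0L, 0L, -1L, 1L))

# content of m shifted by (dr, dc); vacated cells take `fill`
shift_mat <- function(m, dr, dc, fill) {
  nr <- nrow(m)
  nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  r_dst <- seq_len(nr)[seq_len(nr) - dr >= 1L & seq_len(nr) - dr <= nr]
  c_dst <- seq_len(nc)[seq_len(nc) - dc >= 1L & seq_len(nc) - dc <= nc]
  if (length(r_dst) && length(c_dst))
    out[r_dst, c_dst] <- m[r_dst - dr, c_dst - dc]
  out
}

# 3x3 box dilation, repeated `times`
dilate_box <- function(mask, times = 1L) {
  out <- mask
  for (i in seq_len(times)) {
    acc <- out
    for (k in seq_len(nrow(.OFF8)))
      acc <- acc | shift_mat(out, .OFF8[k, 1L], .OFF8[k, 2L], FALSE)
    out <- acc
  }
  out
}

# pixels whose label differs from at least one 8-neighbour (raster edge is
# not treated as a wall: a cell truncated by the field of view has no
# membrane rendered along the image border)
wall_pixels <- function(labels) {
  wall <- matrix(FALSE, nrow(labels), ncol(labels))
  for (k in seq_len(nrow(.OFF8))) {
    nb <- shift_mat(labels, .OFF8[k, 1L], .OFF8[k, 2L], NA_integer_)
    wall <- wall | (!is.na(nb) & nb != labels)
  }
  wall
}

# pixels within Chebyshev distance `width` of a cell wall
boundary_band <- function(labels, width = 1L) {
  wall <- wall_pixels(labels)
  if (width > 1L) wall <- dilate_box(wall, width - 1L)
  wall
}

# 8-connected component labelling of a logical mask; components are numbered
# by their top-left-most (lowest linear index) pixel for determinism
label_components8 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  fg <- which(mask)
  if (!length(fg)) return(lab)
  idx <- matrix(0L, nrow(mask), ncol(mask))
  idx[fg] <- seq_along(fg)
  edges <- vector("list", 4L)
  dirs <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  for (k in seq_along(dirs)) {
    sh <- shift_mat(idx, dirs[[k]][1L], dirs[[k]][2L], 0L)
    both <- mask & sh > 0L
    if (any(both)) edges[[k]] <- cbind(idx[both], sh[both])
  }
  edges <- do.call(rbind, edges)
  if (is.null(edges)) {
    memb <- seq_along(fg)
  } else {
    g <- igraph::make_graph(as.vector(t(edges)), n = length(fg),
                            directed = FALSE)
    memb <- igraph::components(g)$membership
  }
  k <- max(memb)
  o <- order(memb, fg)
  keep <- !duplicated(memb[o])
  firsts <- fg[o][keep]       # lowest pixel index per component
  ids <- memb[o][keep]        # component ids, ascending
  newlab <- integer(k)
  newlab[ids[order(firsts)]] <- seq_len(k)
  lab[fg] <- newlab[memb]
  lab
}

# exposed 4-edge count per label (boundary-crack length in pixel edges)
crack_edges_by_label <- function(lab) {
  exposed <- matrix(0L, nrow(lab), ncol(lab))
  for (k in seq_len(nrow(.OFF4))) {
    nb <- shift_mat(lab, .OFF4[k, 1L], .OFF4[k, 2L], 0L)
    exposed <- exposed + (lab > 0L & nb != lab)
  }
  fg <- lab > 0L
  as.integer(rowsum(as.numeric(exposed[fg]), lab[fg],
                    reorder = TRUE))
}

stopifnot_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                    integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (integer && x != round(x))
    stop(sprintf("'%s' must be an integer", name), call. = FALSE)
  if (x < min || x > max)
    stop(sprintf("'%s' must be in [%s, %s]", name, min, max), call. = FALSE)
  invisible(x)
}
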