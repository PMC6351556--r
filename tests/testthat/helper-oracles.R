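# Independent brute-force oracles and small fixture builders. Oracles use
# plain per-pixel loops and R set arithmetic so they share no code path with
# the package implementations they check.

# per-pixel 3x3 scan: a foreground pixel survives only if every neighbour in
# its 3x3 window (out-of-raster = background) is foreground
oracle_erode <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  out <- mask
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c]) next
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr
      cc <- c + dc
      if (rr < 1 || rr > nr || cc < 1 || cc > nc || !mask[rr, cc])
        out[r, c] <- FALSE
    }
  }
  out
}

# set-arithmetic oracle for the cross-channel rule: a surviving dot is
# eliminated iff some surviving dot of the other channel overlaps it by more
# than frac of its own area
oracle_overlap_flags <- function(pix_a, pix_b, area_a, frac) {
  vapply(seq_along(pix_a), function(i) {
    any(vapply(pix_b, function(q)
      length(intersect(pix_a[[i]], q)) > frac * area_a[i], TRUE))
  }, TRUE)
}

# set-arithmetic oracle for majority-surface assignment
oracle_assign <- function(pix, lab, frac) {
  vapply(pix, function(p) {
    owners <- lab[p]
    owners <- owners[owners > 0]
    if (!length(owners)) return(NA_integer_)
    tab <- table(owners)
    best <- as.integer(names(tab)[which.max(tab)])
    if (max(tab) > frac * length(p)) best else NA_integer_
  }, integer(1))
}

# flood fill on the cell adjacency graph: partition of gfp_ids into clones,
# with adjacency decided by brute-force pixel scanning
oracle_clones <- function(label_map, gfp_ids) {
  nr <- nrow(label_map)
  nc <- ncol(label_map)
  adjacent <- function(a, b) {
    pa <- which(label_map == a)
    for (p in pa) {
      r <- ((p - 1) %% nr) + 1
      c <- ((p - 1) %/% nr) + 1
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr
        cc <- c + dc
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
            label_map[rr, cc] == b) return(TRUE)
      }
    }
    FALSE
  }
  unassigned <- gfp_ids
  clones <- list()
  while (length(unassigned)) {
    queue <- unassigned[1]
    clone <- integer(0)
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      if (v %in% clone) next
      clone <- c(clone, v)
      nbs <- Filter(function(u) !(u %in% clone) && adjacent(v, u),
                    unassigned)
      queue <- c(queue, nbs)
    }
    clones <- c(clones, list(sort(clone)))
    unassigned <- setdiff(unassigned, clone)
  }
  clones[order(vapply(clones, min, numeric(1)))]
}

# rectangular grid tessellation: nrow_cells x ncol_cells cells, each
# cell_h x cell_w pixels
grid_label_map <- function(nrow_cells, ncol_cells, cell_h = 3L, cell_w = 3L) {
  lab <- matrix(0L, nrow_cells * cell_h, ncol_cells * cell_w)
  id <- 0L
  for (cc in seq_len(ncol_cells)) for (rc in seq_len(nrow_cells)) {
    id <- id + 1L
    lab[(rc - 1L) * cell_h + seq_len(cell_h),
        (cc - 1L) * cell_w + seq_len(cell_w)] <- id
  }
  lab
}

# GFP mask that fully paints the territories of the given cells
gfp_mask_for <- function(label_map, gfp_ids) {
  matrix(label_map %in% gfp_ids, nrow(label_map), ncol(label_map))
}

# all 65536 4x4 binary masks as a logical matrix (rows = masks)
all_4x4_masks <- function() {
  b <- intToBits(0:65535)
  matrix(as.logical(b)[seq_len(16) + rep((0:65535) * 32, each = 16)],
         ncol = 16, byrow = TRUE)
}

# a small synthetic scene plus its cell_rois, shared by recovery tests
make_scene <- function(seed, ...) {
  cfg <- scene_config(seed = seed, ...)
  sc <- simulate_tissue(cfg)
  fish <- simulate_fish_channels(cfg, sc$truth)
  status <- ifelse(seq_len(cfg$n_cells) %in% sc$truth$gfp_cell_ids,
                   "gfp_pos", "gfp_neg")
  list(cfg = cfg, tissue = sc, fish = fish,
       cells = cell_rois(sc$truth$cell_label_map, status),
       truth_counts = xtabs(count ~ cell_id + channel,
                            fish$truth$dots_per_cell))
}

# delta-method standard error of the ratio of two population means
ratio_se <- function(counts, is_pos) {
  m_pos <- mean(counts[is_pos])
  m_neg <- mean(counts[!is_pos])
  r <- m_pos / m_neg
  r * sqrt(var(counts[is_pos]) / sum(is_pos) / m_pos^2 +
           var(counts[!is_pos]) / sum(!is_pos) / m_neg^2)
}

# disc mask of radius r centred in a (2r+4)^2 raster
disc_mask <- function(r) {
  n <- 2L * r + 5L
  ctr <- (n + 1) / 2
  m <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if ((i - ctr)^2 + (j - ctr)^2 <= r^2) m[i, j] <- TRUE
  m
}
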