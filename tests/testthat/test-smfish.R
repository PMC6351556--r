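# The smFISH dot-counting pipeline: pixel classification, one-pass erosion,
# particle analysis with circularity, cross-channel filtering, per-cell
# assignment and population ratios.

dots_from_pixels <- function(pixel_sets, dim, channel = "green") {
  info <- data.frame(dot_id = seq_along(pixel_sets),
                     channel = rep_len(channel, length(pixel_sets)),
                     area_px = lengths(pixel_sets),
                     circularity = rep_len(1, length(pixel_sets)),
                     assigned_cell = rep_len(NA_integer_, length(pixel_sets)),
                     eliminated_by = rep_len("none", length(pixel_sets)))
  clonefish:::new_fish_dots(info, pixel_sets, as.integer(dim))
}

test_that("pixel classification thresholds and takes exact quantile fractions", {
  img <- matrix(0.3, 10, 10)
  expect_false(any(classify_pixels(img, "threshold", 0.5)))
  expect_true(all(classify_pixels(img, "threshold", 0.3)))
  # five Gaussian spots on a dark background give five components
  set.seed(2)
  sp <- matrix(0, 120, 120)
  sp <- clonefish:::render_spots(sp, c(20, 20, 60, 100, 90),
                                 c(20, 100, 60, 30, 105), sigma = 1.6,
                                 amp = 0.9)
  mask <- classify_pixels(sp, "threshold", 0.45)
  expect_identical(max(clonefish:::label_components8(mask)), 5L)
  # quantile mode returns exactly the top (1 - q) fraction of pixels
  img2 <- matrix(runif(10000), 100, 100)
  expect_identical(sum(classify_pixels(img2, "quantile", 0.99)), 100L)
  img3 <- matrix(1, 100, 100)  # all tied: raster order breaks ties
  m3 <- classify_pixels(img3, "quantile", 0.99)
  expect_identical(which(m3), 1:100)
  expect_error(classify_pixels(img, "quantile", 1), "quantile")
  expect_error(classify_pixels(img, "quantile", 0), "quantile")
})

test_that("one-pass erosion follows the 3x3 any-neighbour rule", {
  # isolated pixel is eliminated
  m <- matrix(FALSE, 5, 5)
  m[3, 3] <- TRUE
  expect_false(any(erode_segmentation(m)))
  # solid 3x3 block: only the centre survives
  b <- matrix(FALSE, 5, 5)
  b[2:4, 2:4] <- TRUE
  eb <- erode_segmentation(b)
  expect_identical(which(eb), which(matrix(seq_len(25), 5, 5) == 13))
  # two 3x3 blocks joined by a 1-px bridge: bridge removed, centres split
  br <- matrix(FALSE, 5, 9)
  br[2:4, 2:4] <- TRUE
  br[2:4, 6:8] <- TRUE
  br[3, 5] <- TRUE
  ebr <- erode_segmentation(br)
  expect_identical(sum(ebr), 2L)
  expect_identical(max(clonefish:::label_components8(ebr)), 2L)
  # the alternative reading removes only fully isolated pixels
  iso <- erode_segmentation(m, rule = "isolated")
  expect_false(any(iso))
  expect_identical(erode_segmentation(b, rule = "isolated"), b)
  # output is always a subset of the input
  set.seed(3)
  rm <- matrix(runif(400) < 0.4, 20, 20)
  expect_true(all(erode_segmentation(rm) <= rm))
})

test_that("erosion matches the brute-force 3x3 scan on random masks", {
  set.seed(11)
  for (rep in 1:50) {
    nr <- sample(6:9, 1)
    nc <- sample(6:9, 1)
    m <- matrix(runif(nr * nc) < runif(1, 0.2, 0.8), nr, nc)
    expect_identical(erode_segmentation(m), oracle_erode(m))
  }
})

test_that("particle analysis measures area and circularity as specified", {
  # filled disc of radius 10: circularity >= 0.9, retained
  d <- particle_analysis(disc_mask(10))
  expect_identical(nrow(d$info), 1L)
  expect_gte(d$info$circularity, 0.9)
  expect_identical(d$info$eliminated_by, "none")
  # 1x20 line: circularity < 0.4, eliminated at the default bounds
  ln <- matrix(FALSE, 5, 24)
  ln[3, 3:22] <- TRUE
  dl <- particle_analysis(ln)
  expect_lt(dl$info$circularity, 0.4)
  expect_identical(dl$info$eliminated_by, "circularity_filter")
  expect_identical(dl$info$area_px, 20L)
  # single pixel: circularity clamped to 1, retained
  px <- matrix(FALSE, 3, 3)
  px[2, 2] <- TRUE
  expect_identical(particle_analysis(px)$info$circularity, 1)
  # components are enumerated in raster order of their top-left pixel
  two <- matrix(FALSE, 10, 10)
  two[8:9, 1:2] <- TRUE
  two[1:2, 8:9] <- TRUE
  dt <- particle_analysis(two)
  expect_identical(dt$info$dot_id, 1:2)
  expect_lt(min(dt$pixels[[1]]), min(dt$pixels[[2]]))
  expect_error(particle_analysis(px, circ_min = 0.8, circ_max = 0.4),
               "circ_min")
  # raw crack perimeter remains available and is larger for a disc
  draw <- particle_analysis(disc_mask(10), perimeter = "crack")
  expect_lt(draw$info$circularity, d$info$circularity)
})

test_that("cross-channel filter eliminates dots by fractional overlap, symmetrically", {
  dim <- c(10, 10)
  g <- dots_from_pixels(list(1:10), dim, "green")
  f3 <- dots_from_pixels(list(8:17), dim, "farred")   # 3 px overlap: 30%
  r <- cross_channel_filter(g, f3)
  expect_identical(r$green$info$eliminated_by, "overlap_filter")
  expect_identical(r$farred$info$eliminated_by, "overlap_filter")
  f1 <- dots_from_pixels(list(10:19), dim, "farred")  # 1 px overlap: 10%
  r1 <- cross_channel_filter(g, f1)
  expect_identical(r1$green$info$eliminated_by, "none")
  expect_identical(r1$farred$info$eliminated_by, "none")
  # no partner channel dots: everything retained
  r0 <- cross_channel_filter(g, dots_from_pixels(list(), dim, "farred"))
  expect_identical(r0$green$info$eliminated_by, "none")
  # asymmetric areas: only the dot whose own-area fraction exceeds 20% goes
  big <- dots_from_pixels(list(1:40), dim, "green")
  small <- dots_from_pixels(list(36:40), dim, "farred")  # 5 px: 12.5% vs 100%
  ra <- cross_channel_filter(big, small)
  expect_identical(ra$green$info$eliminated_by, "none")
  expect_identical(ra$farred$info$eliminated_by, "overlap_filter")
})

test_that("dot assignment requires a strict majority inside one cell", {
  lab <- matrix(0L, 6, 6)
  lab[, 1:3] <- 1L
  lab[, 4:6] <- 2L
  cells <- cell_rois(lab, c("gfp_pos", "gfp_neg"))
  # 4 of 6 px in cell 1
  d <- dots_from_pixels(list(c(13:16, 19:20)), c(6, 6))
  expect_identical(assign_dots_to_cells(d, cells)$info$assigned_cell, 1L)
  # exact 50/50 split stays unassigned
  split_dot <- dots_from_pixels(list(c(16:18, 19:21)), c(6, 6))
  r2 <- assign_dots_to_cells(split_dot, cells)
  expect_true(is.na(r2$info$assigned_cell))
  expect_identical(r2$info$eliminated_by, "assignment")
  # fully inside one cell
  d3 <- dots_from_pixels(list(25:28), c(6, 6))
  expect_identical(assign_dots_to_cells(d3, cells)$info$assigned_cell, 2L)
  expect_error(cell_rois_from_pixels(list(1:5, 5:9), c(6, 6),
                                     c("gfp_pos", "gfp_neg")), "overlap")
})

test_that("filters and assignment match set-arithmetic oracles on random scenes", {
  set.seed(77)
  lab <- grid_label_map(2, 2, 6L, 6L)
  cells <- cell_rois(lab, c("gfp_pos", "gfp_neg", "gfp_neg", "gfp_pos"))
  for (rep in 1:60) {
    mg <- matrix(runif(144) < 0.25, 12, 12)
    mf <- matrix(runif(144) < 0.25, 12, 12)
    g <- particle_analysis(mg, circ_min = 0, circ_max = 1)
    f <- particle_analysis(mf, circ_min = 0, circ_max = 1)
    r <- cross_channel_filter(g, f, overlap_frac = 0.2)
    exp_g <- oracle_overlap_flags(g$pixels, f$pixels, g$info$area_px, 0.2)
    exp_f <- oracle_overlap_flags(f$pixels, g$pixels, f$info$area_px, 0.2)
    expect_identical(r$green$info$eliminated_by == "overlap_filter", exp_g)
    expect_identical(r$farred$info$eliminated_by == "overlap_filter", exp_f)
    a <- assign_dots_to_cells(g, cells)
    expect_identical(a$info$assigned_cell,
                     oracle_assign(g$pixels, lab, 0.5))
  }
})

test_that("population dot ratios follow the configured count asymmetry", {
  lab <- grid_label_map(2, 2, 4L, 4L)
  mk <- function(counts) {
    # place `counts[i]` single-pixel dots inside cell i, well separated
    px <- list()
    for (i in seq_len(4)) {
      cpix <- which(lab == i)
      if (counts[i] > 0)
        px <- c(px, as.list(cpix[seq.int(1, by = 2,
                                         length.out = counts[i])]))
    }
    dots_from_pixels(px, dim(lab), "farred")
  }
  cells <- cell_rois(lab, c("gfp_pos", "gfp_pos", "gfp_neg", "gfp_neg"))
  r <- dot_ratio(assign_dots_to_cells(mk(c(2, 2, 4, 4)), cells), cells)
  expect_equal(r$ratio, 0.5)
  expect_equal(r$mean_dots_gfp_pos, 2)
  r2 <- dot_ratio(assign_dots_to_cells(mk(c(4, 4, 2, 2)), cells), cells)
  expect_equal(r2$ratio, 2)
  r1 <- dot_ratio(assign_dots_to_cells(mk(c(3, 3, 3, 3)), cells), cells)
  expect_equal(r1$ratio, 1)
  expect_error(dot_ratio(assign_dots_to_cells(mk(c(1, 1, 0, 0)), cells),
                         cells), "GFP-")
})

test_that("stages only flag dots, never drop records or alter pixel sets", {
  sc <- make_scene(6)
  mask_g <- classify_pixels(sc$fish$green, "threshold", 0.25)
  g0 <- particle_analysis(erode_segmentation(mask_g), channel = "green")
  f0 <- particle_analysis(erode_segmentation(
    classify_pixels(sc$fish$farred, "threshold", 0.25)), channel = "farred")
  r <- cross_channel_filter(g0, f0)
  g1 <- assign_dots_to_cells(r$green, sc$cells)
  expect_identical(nrow(g1$info), nrow(g0$info))
  expect_identical(g1$pixels, g0$pixels)
  # flags move only away from "none"
  changed <- g1$info$eliminated_by != g0$info$eliminated_by
  expect_true(all(g0$info$eliminated_by[changed] == "none"))
})

test_that("per-cell counts match ground truth on clean scenes", {
  ok <- total <- 0
  for (s in 1:4) {
    sc <- make_scene(s, coincident_speckle_rate = 0)
    fc <- fish_count(sc$fish$green, sc$fish$farred, sc$cells)
    ok <- ok + sum(fc$counts[, "green"] == sc$truth_counts[, "green"]) +
      sum(fc$counts[, "farred"] == sc$truth_counts[, "farred"])
    total <- total + 2 * nrow(sc$cells$info)
  }
  expect_gte(ok / total, 0.95)
})

test_that("coincident speckles are removed with minimal true-dot loss", {
  sc <- make_scene(8, coincident_speckle_rate = 12)
  fc <- fish_count(sc$fish$green, sc$fish$farred, sc$cells)
  st <- speckle_rejection_stats(fc$dots$green, fc$dots$farred,
                                sc$fish$truth$speckle_positions)
  expect_gte(st$speckle_rejection_rate, 0.9)
  expect_lt(st$true_dot_loss_rate, 0.05)
})

test_that("estimated population ratio converges to the configured ratio", {
  # consistency of the full-pipeline estimator: the error band shrinks as
  # 1/sqrt(n_cells); scene area scales with cell count
  sizes <- c(50, 200, 800)
  errs <- ses <- numeric(length(sizes))
  for (k in seq_along(sizes)) {
    n <- sizes[k]
    side <- round(sqrt(n * 2850))
    sc <- make_scene(31, width_px = side, height_px = side, n_cells = n,
                     coincident_speckle_rate = 0)
    fc <- fish_count(sc$fish$green, sc$fish$farred, sc$cells)
    pos <- sc$cells$info$gfp_status == "gfp_pos"
    errs[k] <- abs(fc$ratios$farred$ratio - 0.5)
    ses[k] <- ratio_se(fc$counts[, "farred"], pos)
  }
  expect_true(all(errs < 3 * ses))
  expect_lt(errs[3], errs[1])
})
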