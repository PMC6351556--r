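# The scene generator: tessellation, reporter rendering, dot statistics,
# determinism and conservation of ground truth.

small_cfg <- function(...) {
  scene_config(width_px = 240L, height_px = 240L, n_cells = 8L, seed = 11L,
               ...)
}

test_that("recombination fraction maps to the nearest integer cell count", {
  cfg <- scene_config(width_px = 400, height_px = 400, n_cells = 100,
                      recombined_fraction = 0.012, seed = 3)
  sc <- simulate_tissue(cfg)
  expect_length(sc$truth$gfp_cell_ids, 1L)

  sc0 <- simulate_tissue(small_cfg(recombined_fraction = 0, noise_sd = 0))
  expect_length(sc0$truth$gfp_cell_ids, 0L)
  expect_true(all(sc0$gfp == 0))

  sc1 <- simulate_tissue(small_cfg(recombined_fraction = 1, noise_sd = 0))
  expect_identical(sc1$gfp, sc1$tomato)
})

test_that("tessellation covers the raster and GFP membrane is a subset of Tomato", {
  sc <- simulate_tissue(small_cfg(noise_sd = 0))
  labels <- sc$truth$cell_label_map
  expect_true(all(labels >= 1 & labels <= 8))
  expect_setequal(unique(as.vector(labels)), 1:8)
  # every GFP-positive pixel is also Tomato-positive (partial recombination)
  expect_true(all(sc$tomato[sc$gfp > 0] > 0))
  expect_lte(sum(sc$gfp > 0), sum(sc$tomato > 0))
})

test_that("scene generation is bit-identical under a fixed seed", {
  a <- simulate_tissue(small_cfg())
  b <- simulate_tissue(small_cfg())
  expect_identical(a$tomato, b$tomato)
  expect_identical(a$truth$cell_label_map, b$truth$cell_label_map)
  fa <- simulate_fish_channels(small_cfg(), a$truth)
  fb <- simulate_fish_channels(small_cfg(), b$truth)
  expect_identical(fa$green, fb$green)
  expect_identical(fa$truth$dot_positions, fb$truth$dot_positions)
})

test_that("invalid scene configurations are rejected", {
  expect_error(scene_config(n_cells = 0), "n_cells")
  expect_error(scene_config(width_px = -5), "width_px")
  expect_error(scene_config(recombined_fraction = 1.2), "recombined_fraction")
  expect_error(scene_config(dot_rate_green = -1), "dot_rate_green")
  expect_error(scene_config(width_px = 3, height_px = 3, n_cells = 10),
               "at least as many pixels")
  sc <- simulate_tissue(small_cfg())
  bad_truth <- sc$truth
  bad_truth$cell_label_map <- NULL
  expect_error(simulate_fish_channels(small_cfg(), bad_truth),
               "cell_label_map")
})

test_that("zero rates give pure-noise FISH channels and zero truth counts", {
  cfg <- small_cfg(dot_rate_green = 0, dot_rate_red_gfp_pos = 0,
                   dot_rate_red_gfp_neg = 0, coincident_speckle_rate = 0,
                   noise_sd = 0)
  sc <- simulate_tissue(cfg)
  fish <- simulate_fish_channels(cfg, sc$truth)
  expect_true(all(fish$green == 0))
  expect_true(all(fish$farred == 0))
  expect_true(all(fish$truth$dots_per_cell$count == 0))
})

test_that("true dot counts are conserved between tables and rendered dots", {
  sc <- make_scene(5)
  expect_identical(nrow(sc$fish$truth$dot_positions),
                   sum(sc$fish$truth$dots_per_cell$count))
  # every dot position lies inside its own cell's territory
  dp <- sc$fish$truth$dot_positions
  lab <- sc$tissue$truth$cell_label_map
  owner <- lab[cbind(round(dp$y), round(dp$x))]
  expect_identical(owner, dp$cell_id)
  # hard-core separation within a cell, across channels
  for (cell in unique(dp$cell_id)) {
    pts <- dp[dp$cell_id == cell, c("y", "x")]
    if (nrow(pts) > 1) {
      d <- dist(pts)
      expect_gte(min(d), sc$cfg$dot_min_sep_px - 1e-9)
    }
  }
})

test_that("per-population dot counts follow the configured Poisson rates", {
  # >= 200 cells accumulated over five default scenes
  counts_pos <- counts_neg <- counts_green <- numeric(0)
  for (s in 1:5) {
    sc <- make_scene(s)
    pos <- sc$cells$info$gfp_status == "gfp_pos"
    counts_pos <- c(counts_pos, sc$truth_counts[pos, "farred"])
    counts_neg <- c(counts_neg, sc$truth_counts[!pos, "farred"])
    counts_green <- c(counts_green, sc$truth_counts[, "green"])
  }
  expect_gte(length(counts_green), 200L)
  for (chk in list(list(x = counts_pos, rate = 2),
                   list(x = counts_neg, rate = 4),
                   list(x = counts_green, rate = 2))) {
    se <- sqrt(chk$rate / length(chk$x))
    expect_lt(abs(mean(chk$x) - chk$rate), 3 * se)
  }
  # configured far-red rate ratio GFP+/GFP- = 0.5 shows in the truth means
  expect_lt(abs(mean(counts_pos) / mean(counts_neg) - 0.5), 0.15)
})

test_that("the growth series reproduces the saturating law exactly without noise", {
  cfg <- growth_config(obs_noise_sd = 0, replicates_per_time = 1)
  s <- simulate_growth_series(cfg)
  expect_equal(s$time_days, c(1, 1.5, 4, 10, 30, 60, 90))
  expect_equal(s$gfp_percent, 1.4 * log(s$time_days + 1), tolerance = 1e-12)
  # t = 0 is outside the default grid but the law passes through 0 there
  s0 <- simulate_growth_series(growth_config(time_points_days = 1e-12,
                                             obs_noise_sd = 0,
                                             replicates_per_time = 1))
  expect_equal(s0$gfp_percent, 0, tolerance = 1e-9)
})

test_that("noisy growth replicates centre on the law (CLT check)", {
  cfg <- growth_config(obs_noise_sd = 0.1, replicates_per_time = 100,
                       seed = 21)
  s <- simulate_growth_series(cfg)
  # global check over the seven chase points: the sum of squared z-scores of
  # the per-time sample means is chi-square(7) if the means follow the law
  z2 <- vapply(unique(s$time_days), function(t) {
    y <- s$gfp_percent[s$time_days == t]
    ((mean(y) - 1.4 * log(t + 1)) / (0.1 / sqrt(length(y))))^2
  }, numeric(1))
  expect_lt(sum(z2), qchisq(1 - 1e-4, df = length(z2)))
})

test_that("growth configuration rejects non-positive times", {
  expect_error(growth_config(time_points_days = c(1, 0)), "positive")
  expect_error(growth_config(growth_offset = -1), "growth_offset")
})
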