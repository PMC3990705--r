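make_single_cell_regions <- function(size = 80, radius_um = 5) {
  img <- matrix(600L, size, size)
  img <- draw_disk(img, size / 2, size / 2, radius_um / PX, 5000L)
  nl <- segment_nuclei(img, seg_params(), PX)
  make_measurement_regions(nl)
}

test_that("uniform reporter images give unit ratios; forced two-level case gives 2", {
  reg <- make_single_cell_regions()
  uni <- matrix(850, 80, 80)
  cm <- measure_cells(uni, reg, background = 100)
  expect_equal(cm$ratio, 1)
  expect_equal(cm$nuclear_mean, 750)
  # nucleus at 200, ring at 100 above background
  img <- matrix(100, 80, 80)
  img[reg$inner == 1L] <- 300
  img[reg$ring == 1L] <- 200
  cm2 <- measure_cells(img, reg, background = 100)
  expect_equal(cm2$ratio, 2)
})

test_that("ratios match a brute-force per-pixel recomputation exactly on small fields", {
  f <- simulate_field(cell_geometry(cell_density = 900), 0.8, noise_model(),
                      seed = 41, dim = c(64, 64))
  nl <- segment_nuclei(f$dapi, seg_params(), PX)
  reg <- make_measurement_regions(nl)
  expect_gt(nrow(reg$counts), 0)
  bg <- estimate_background(f$fitc)
  cm <- measure_cells(f$fitc, reg, background = bg)
  oracle <- brute_force_cell_means(f$fitc, reg, background = bg)
  m <- merge(cm, oracle, by = "label", suffixes = c("", ".oracle"))
  expect_equal(m$nuclear_mean, m$nuclear_mean.oracle, tolerance = 1e-12)
  expect_equal(m$ring_mean, m$ring_mean.oracle, tolerance = 1e-12)
  expect_equal(m$ratio, m$nuclear_mean.oracle / m$ring_mean.oracle,
               tolerance = 1e-12)
})

test_that("ratios are invariant under rescaling of the background-subtracted image", {
  f <- simulate_field(cell_geometry(), 0.65,
                      noise_model(background_level = 0, background_sd = 0),
                      seed = 43, dim = c(200, 200))
  nl <- segment_nuclei(f$dapi, seg_params(), PX)
  reg <- make_measurement_regions(nl)
  base <- measure_cells(f$fitc, reg, background = 0)
  for (g in c(0.5, 3, 17.3)) {
    scaled <- measure_cells(f$fitc * g, reg, background = 0)
    expect_equal(scaled$ratio, base$ratio, tolerance = 1e-12)
  }
})

test_that("simulated contrast is recovered through the full measurement chain", {
  f <- simulate_field(cell_geometry(), 0.65, noise_model(), seed = 7,
                      dim = c(400, 400))
  nl <- segment_nuclei(f$dapi, seg_params(), PX)
  reg <- make_measurement_regions(nl)
  cm <- measure_cells(f$fitc, reg, background = estimate_background(f$fitc))
  expect_lt(abs(median(cm$ratio) - 0.65), 0.05)
})

test_that("well aggregation averages ratios and enforces the cell floor", {
  cells <- data.frame(ratio = c(1, 1, 1), border = FALSE)
  w <- aggregate_well(cells, min_cells = 3)
  expect_equal(w$mean_ratio, 1)
  expect_identical(w$n_cells, 3L)
  expect_true(w$valid)
  w2 <- aggregate_well(data.frame(ratio = c(0.5, 1.5), border = FALSE),
                       min_cells = 2)
  expect_equal(w2$mean_ratio, 1)
  # below the floor: invalid, no NaN propagation
  w3 <- aggregate_well(data.frame(ratio = numeric(), border = logical()),
                       min_cells = 1)
  expect_false(w3$valid)
  expect_true(is.na(w3$activated))
  # border cells excluded from the mean by default
  cells4 <- data.frame(ratio = c(0.6, 0.6, 5), border = c(FALSE, FALSE, TRUE))
  expect_equal(aggregate_well(cells4, min_cells = 1)$mean_ratio, 0.6)
})

test_that("activation is called strictly below the 0.7 threshold", {
  expect_true(classify_activation(0.65))     # activated DMSO reference
  expect_false(classify_activation(0.70))    # boundary: not activated
  expect_false(classify_activation(1.1851))  # strong inhibition phenotype
  expect_identical(classify_activation(c(0.69, 0.71)), c(TRUE, FALSE))
})

test_that("nuclear-intensity endpoint matches the FITC operator and recovers truth", {
  reg <- make_single_cell_regions()
  uni <- matrix(720, 80, 80)
  r <- measure_nuclear_intensity(uni, reg, background = 120)
  expect_equal(r$cells$nuclear_mean, 600)
  expect_equal(r$well_mean, 600)
  # same operator as measure_cells on the same channel
  f <- simulate_field(cell_geometry(), 0.9, noise_model(), seed = 47,
                      dim = c(160, 160))
  nl <- segment_nuclei(f$dapi, seg_params(), PX)
  regs <- make_measurement_regions(nl)
  cm <- measure_cells(f$fitc, regs, background = 600)
  ni <- measure_nuclear_intensity(f$fitc, regs, background = 600)
  m <- merge(cm, ni$cells, by = "label")
  expect_equal(m$nuclear_mean.x, m$nuclear_mean.y)
  # simulated nuclear-only stain recovered at the well level
  stain <- matrix(0L, 160, 160)
  stain[f$ownership$nucleus > 0L] <- 1000L
  r2 <- measure_nuclear_intensity(stain, regs, background = 0)
  expect_lt(abs(r2$well_mean - 1000), 30)
})

test_that("monotone contrast series is recovered in strictly increasing order", {
  contrasts <- c(0.5, 0.8, 1.2)
  means <- vapply(seq_along(contrasts), function(i) {
    f <- simulate_field(cell_geometry(), contrasts[i], noise_model(),
                        seed = 50 + i, dim = c(220, 220))
    nl <- segment_nuclei(f$dapi, seg_params(), PX)
    reg <- make_measurement_regions(nl)
    cm <- measure_cells(f$fitc, reg, background = estimate_background(f$fitc))
    mean(cm$ratio)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
  expect_true(all(abs(means - contrasts) < 0.05))
})
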