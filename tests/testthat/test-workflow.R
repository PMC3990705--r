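test_that("run configuration round-trips losslessly through YAML", {
  cfg <- run_config(pixel_size = 0.5,
                    seg = seg_params(min_area = 80, separate_touching = FALSE),
                    ring = ring_params(outer_region_width = 3),
                    min_cells = 20, n_sites = 2, seed = 99)
  path <- withr::local_tempfile(fileext = ".yaml")
  save_config(cfg, path)
  cfg2 <- load_config(path)
  expect_equal(cfg2, cfg)
})

test_that("simulated images round-trip through 16-bit TIFF unchanged", {
  f <- simulate_field(cell_geometry(cell_density = 500), 0.65, noise_model(),
                      seed = 61, dim = c(96, 96))
  dir <- withr::local_tempdir()
  paths <- write_field_tiffs(f, dir, "P1", "A01", 1)
  expect_identical(read_image_tiff(paths[1]), f$dapi)
  expect_identical(read_image_tiff(paths[2]), f$fitc)
})

test_that("non-16-bit images are rejected with a descriptive error", {
  dir <- withr::local_tempdir()
  p8 <- file.path(dir, "P1_A01_1_DAPI.tif")
  tiff::writeTIFF(matrix(0.5, 8, 8), p8, bits.per.sample = 8L)
  expect_error(read_image_tiff(p8), "16-bit")
})

test_that("plate maps validate well ids and roles with row numbers", {
  dir <- withr::local_tempdir()
  map <- plate_map("P1", c("A01", "B07"), c("neg_ctrl", "pos_ctrl"))
  path <- file.path(dir, "map.csv")
  write_plate_map(map, path)
  expect_equal(read_plate_map(path), map)
  bad <- map; bad$well[2] <- "7B"
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_plate_map(path), "row\\(s\\) 2")
})

test_that("loading resolves mapped wells and reports missing sites per well", {
  map <- plate_map("P1", c("A01", "A02"), c("neg_ctrl", "pos_ctrl"))
  p <- simulate_plate(map, geom = cell_geometry(cell_density = 500),
                      seed = 62, n_sites = 2, dim = c(96, 96))
  dir <- withr::local_tempdir()
  write_plate_images(p, dir)
  pl <- load_plate_images(dir, map, n_sites = 2)
  expect_identical(pl$wells$site_count, c(2L, 2L))
  expect_identical(pl$images[["A01"]][[1]]$dapi, p$images[[1]][[1]]$dapi)
  # drop one site -> warning, reduced site_count, well still loads
  file.remove(file.path(dir, "P1_A02_2_DAPI.tif"))
  expect_warning(pl2 <- load_plate_images(dir, map, n_sites = 2),
                 "missing site")
  expect_identical(pl2$wells$site_count[pl2$wells$well == "A02"], 1L)
})

test_that("end-to-end screen run reports QC, well table and hits deterministically", {
  map <- plate_map("P1",
                   c("A01", "A02", "B01", "B02", "C01", "C02"),
                   c("neg_ctrl", "neg_ctrl", "pos_ctrl", "pos_ctrl",
                     "compound", "compound"),
                   compound_id = c(NA, NA, NA, NA, "CPD1", "CPD2"),
                   concentration_nM = c(NA, NA, NA, NA, 1e6, 0.001))
  cfg <- run_config(min_cells = 20, n_sites = 2, seed = 77)
  p <- simulate_plate(map, geom = cell_geometry(cell_density = 900),
                      noise = noise_model(well_to_well_sd = 0.01),
                      seed = cfg$seed, n_sites = 2, dim = c(200, 200))
  out1 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
  run1 <- run_screen(cfg, plate = p, output_dir = out1)
  run2 <- run_screen(cfg, plate = p, output_dir = out2)

  expect_identical(run1$status, 0L)
  expect_gt(run1$zprime, 0.5)
  expect_identical(nrow(run1$wells), 6L)
  expect_true(all(run1$wells$valid))
  # saturating compound scores as a hit; homeopathic dose does not
  expect_identical(run1$hits$compound_id, "CPD1")
  # activation calls: negative controls activated, positives not
  expect_true(all(run1$wells$activated[run1$wells$role == "neg_ctrl"]))
  expect_true(all(!run1$wells$activated[run1$wells$role == "pos_ctrl"]))
  # reruns byte-identical
  for (fn in c("cells.csv", "wells.csv", "summary.json"))
    expect_identical(readLines(file.path(out1, fn)),
                     readLines(file.path(out2, fn)))
  # summary report contains the QC and hit content
  js <- jsonlite::read_json(file.path(out1, "summary.json"))
  expect_equal(js$zprime, run1$zprime, tolerance = 1e-9)
  expect_identical(unlist(js$hits), "CPD1")
})

test_that("overlapping control phenotypes fail QC with a sentinel status", {
  map <- plate_map("P1", c("A01", "A02", "B01", "B02"),
                   c("neg_ctrl", "neg_ctrl", "pos_ctrl", "pos_ctrl"))
  # positive control phenotype indistinguishable from negative
  p <- simulate_plate(map, geom = cell_geometry(cell_density = 900),
                      dose = dose_model(r_active = 0.65, r_inhibited = 0.6501),
                      noise = noise_model(well_to_well_sd = 0.02),
                      seed = 78, n_sites = 1, dim = c(200, 200))
  run <- run_screen(run_config(min_cells = 10, n_sites = 1, seed = 78), plate = p)
  expect_identical(run$status, 1L)
})
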