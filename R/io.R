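#' Write a simulated field's channels as 16-bit TIFFs
#'
#' Files follow the naming pattern `{plate}_{well}_{site}_{channel}.tif`
#' with channels `DAPI` and `FITC`.
#'
#' @param field A [simulate_field()] result.
#' @param dir Output directory (created if needed).
#' @param plate,well,site Identifiers for the filename.
#' @return Invisibly, the two file paths written.
#' @export
write_field_tiffs <- function(field, dir, plate, well, site) {
  stopifnot(inherits(field, "sim_field"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, sprintf("%s_%s_%d_%s.tif", plate, well, site,
                                  c("DAPI", "FITC")))
  tiff::writeTIFF(field$dapi / 65535, paths[1], bits.per.sample = 16L)
  tiff::writeTIFF(field$fitc / 65535, paths[2], bits.per.sample = 16L)
  invisible(paths)
}

#' Write all site images of a simulated plate
#'
#' @param plate_sim A [simulate_plate()] result with images.
#' @param dir Output directory.
#' @return Invisibly, the vector of file paths written.
#' @export
write_plate_images <- function(plate_sim, dir) {
  stopifnot(inherits(plate_sim, "sim_plate"))
  if (is.null(plate_sim$images))
    stop("plate was simulated with images = FALSE; nothing to write")
  paths <- character()
  for (i in seq_len(nrow(plate_sim$wells))) {
    wellid <- plate_sim$wells$well[i]
    plateid <- plate_sim$wells$plate[i]
    sites <- plate_sim$images[[i]]
    for (s in seq_along(sites))
      paths <- c(paths, write_field_tiffs(sites[[s]], dir, plateid, wellid, s))
  }
  invisible(paths)
}

#' Read a single-channel 16-bit grayscale TIFF
#'
#' @param path File path.
#' @return Integer matrix of gray-levels (0-65535).
#' @export
read_image_tiff <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  img <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
  bps <- attr(img, "bits.per.sample")
  if (!is.null(bps) && bps != 16L)
    stop("expected a 16-bit grayscale image, got ", bps, "-bit: ", path)
  if (length(dim(img)) != 2L)
    stop("expected a single-channel grayscale image: ", path)
  m <- matrix(as.integer(img), nrow(img), ncol(img))
  m
}

#' Read and validate a plate map CSV
#'
#' Expected columns: `plate`, `well`, `compound_id`, `concentration_nM`,
#' `role` (one of compound/pos_ctrl/neg_ctrl/empty). Malformed well ids
#' or unknown roles are rejected with their row numbers.
#'
#' @param path CSV file path.
#' @return Validated plate map data frame.
#' @export
read_plate_map <- function(path) {
  map <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(plate = "character", well = "character",
                                        compound_id = "character",
                                        concentration_nM = "numeric",
                                        role = "character"))
  validate_plate_map(map)
  map
}

#' @rdname read_plate_map
#' @param map Plate map data frame.
#' @export
write_plate_map <- function(map, path) {
  validate_plate_map(map)
  utils::write.csv(map, path, row.names = FALSE)
  invisible(path)
}

#' Load plate images from disk according to a plate map
#'
#' Resolves every mapped (non-empty) well's sites and channels under the
#' `{plate}_{well}_{site}_{channel}.tif` naming pattern. Missing sites
#' are reported per well with a warning and the well's `site_count`
#' reduced; a well with no sites at all is an error.
#'
#' @param root Directory holding the TIFFs.
#' @param map Plate map data frame (see [read_plate_map()]).
#' @param n_sites Number of sites expected per well.
#' @return An object of class `plate_images`: named list `well ->` list
#'   of sites, each `list(dapi, fitc)`, with per-well `site_count` in
#'   the accompanying `wells` data frame.
#' @export
load_plate_images <- function(root, map, n_sites = 4) {
  validate_plate_map(map)
  used <- map[map$role != "empty", , drop = FALSE]
  wells <- used
  wells$site_count <- 0L
  imgs <- stats::setNames(vector("list", nrow(used)), used$well)
  for (i in seq_len(nrow(used))) {
    sites <- list()
    miss <- integer()
    for (s in seq_len(n_sites)) {
      pd <- file.path(root, sprintf("%s_%s_%d_DAPI.tif", used$plate[i],
                                    used$well[i], s))
      pf <- file.path(root, sprintf("%s_%s_%d_FITC.tif", used$plate[i],
                                    used$well[i], s))
      if (!file.exists(pd) || !file.exists(pf)) { miss <- c(miss, s); next }
      sites[[length(sites) + 1L]] <- list(dapi = read_image_tiff(pd),
                                          fitc = read_image_tiff(pf))
    }
    if (length(miss))
      warning("well ", used$well[i], ": missing site(s) ",
              paste(miss, collapse = ", "))
    if (!length(sites))
      stop("well ", used$well[i], ": no complete site images found under ", root)
    wells$site_count[i] <- length(sites)
    imgs[[i]] <- sites
  }
  structure(list(images = imgs, wells = wells, root = root),
            class = "plate_images")
}

#' Pipeline run configuration
#'
#' Bundles the tunable constants of the pipeline: pixel size,
#' segmentation and ring parameters, the activation (0.7), hit (1.0)
#' and validation (0.95) thresholds, the per-well cell floor and the
#' assay-quality floor on Z'. Round-trips losslessly through YAML via
#' [save_config()]/[load_config()].
#'
#' @param pixel_size um/pixel.
#' @param seg A [seg_params()].
#' @param ring A [ring_params()].
#' @param activation_threshold Well-activation threshold (strict `<`).
#' @param hit_threshold Primary-hit threshold (strict `>`).
#' @param validation_threshold Cascade pass threshold (strict `>`).
#' @param zprime_floor Minimum acceptable plate Z'.
#' @param min_cells Minimum valid cells per well.
#' @param n_sites Sites per well.
#' @param subtract_fitc_background Subtract the reporter-channel
#'   auto-constant background before ratios?
#' @param exclude_border Exclude border-flagged cells from well means?
#' @param seed Integer seed for simulation-backed runs.
#' @return An object of class `run_config`.
#' @export
run_config <- function(pixel_size = 0.65, seg = seg_params(),
                       ring = ring_params(), activation_threshold = 0.7,
                       hit_threshold = 1.0, validation_threshold = 0.95,
                       zprime_floor = 0.5, min_cells = 50, n_sites = 4,
                       subtract_fitc_background = TRUE, exclude_border = TRUE,
                       seed = 1L) {
  stopifnot(pixel_size > 0, activation_threshold > 0, hit_threshold > 0,
            validation_threshold > 0, min_cells >= 0, n_sites >= 1,
            inherits(seg, "seg_params"), inherits(ring, "ring_params"))
  structure(list(pixel_size = pixel_size, seg = seg, ring = ring,
                 activation_threshold = activation_threshold,
                 hit_threshold = hit_threshold,
                 validation_threshold = validation_threshold,
                 zprime_floor = zprime_floor, min_cells = min_cells,
                 n_sites = n_sites,
                 subtract_fitc_background = isTRUE(subtract_fitc_background),
                 exclude_border = isTRUE(exclude_border),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path YAML file path.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  plain <- rapply(unclass(config), identity, how = "list")
  plain$seg <- unclass(config$seg)
  plain$ring <- unclass(config$ring)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname run_config
#' @export
load_config <- function(path) {
  x <- yaml::read_yaml(path)
  seg_args <- x$seg
  run_config(pixel_size = x$pixel_size,
             seg = do.call(seg_params, seg_args),
             ring = do.call(ring_params, x$ring),
             activation_threshold = x$activation_threshold,
             hit_threshold = x$hit_threshold,
             validation_threshold = x$validation_threshold,
             zprime_floor = x$zprime_floor,
             min_cells = x$min_cells, n_sites = x$n_sites,
             subtract_fitc_background = x$subtract_fitc_background,
             exclude_border = x$exclude_border,
             seed = x$seed)
}
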