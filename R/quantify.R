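#' Measure per-cell nucleocytoplasmic reporter ratios
#'
#' Subtracts the constant background from the reporter (FITC/EGFP)
#' channel (floored at zero), then computes for each surviving object
#' the mean intensity over its inner nuclear region and over its
#' perinuclear ring, and their ratio `nuclear_mean / ring_mean`. Cells
#' whose ring is empty after collision exclusion, or whose ring mean is
#' zero (undefined ratio), are dropped and counted -- never silently
#' zeroed.
#'
#' @param fitc_image Reporter-channel matrix, co-registered with the
#'   DAPI image the regions were derived from.
#' @param regions A [make_measurement_regions()] result.
#' @param background Constant background gray-level to subtract (e.g.
#'   from [estimate_background()] on the reporter channel). Use 0 to
#'   disable subtraction.
#' @return A data frame of class `cell_measurements`, one row per
#'   measured cell: `label`, `nuclear_mean`, `ring_mean`, `ratio`,
#'   `border`, `n_inner`, `n_ring`. The number of cells dropped for an
#'   undefined ratio is in `attr(, "n_dropped")`.
#' @export
measure_cells <- function(fitc_image, regions, background = 0) {
  stopifnot(is.matrix(fitc_image), inherits(regions, "measurement_regions"),
            all(dim(fitc_image) == dim(regions$inner)),
            length(background) == 1L, is.finite(background))
  fb <- fitc_image - background
  fb[fb < 0] <- 0

  labs <- regions$counts$label
  n <- length(labs)
  out <- data.frame(label = labs,
                    nuclear_mean = NA_real_, ring_mean = NA_real_,
                    ratio = NA_real_,
                    border = regions$objects$border[match(labs, regions$objects$label)],
                    n_inner = regions$counts$n_inner,
                    n_ring = regions$counts$n_ring)
  if (n) {
    inner_v <- regions$inner[regions$inner > 0L]
    out$nuclear_mean <- as.numeric(
      tapply(fb[regions$inner > 0L], inner_v, mean)[as.character(labs)])
    ring_pos <- regions$ring > 0L
    ring_means <- tapply(fb[ring_pos], regions$ring[ring_pos], mean)
    out$ring_mean <- as.numeric(ring_means[as.character(labs)])
  }
  ok <- !is.na(out$ring_mean) & out$ring_mean > 0 & !is.na(out$nuclear_mean)
  dropped <- sum(!ok)
  if (dropped)
    message(dropped, " cell(s) dropped: empty ring or undefined ratio")
  out$ratio[ok] <- out$nuclear_mean[ok] / out$ring_mean[ok]
  res <- out[ok, , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("cell_measurements", "data.frame")
  attr(res, "n_dropped") <- dropped
  res
}

empty_cell_measurements <- function() {
  res <- data.frame(label = integer(), nuclear_mean = numeric(),
                    ring_mean = numeric(), ratio = numeric(),
                    border = logical(), n_inner = integer(),
                    n_ring = integer(), plate = character(),
                    well = character(), site = integer(),
                    stringsAsFactors = FALSE)
  class(res) <- c("cell_measurements", "data.frame")
  res
}

#' Aggregate per-cell ratios to a well result
#'
#' The well statistic is the arithmetic mean of the per-cell
#' nucleocytoplasmic ratios pooled over all imaged sites of the well
#' (mean of ratios, not ratio of means). Border-flagged cells are
#' excluded by default. A well with fewer than `min_cells` valid cells
#' is marked invalid rather than propagating an unstable mean.
#'
#' @param cells A [measure_cells()] result (rows from all sites of one
#'   well, concatenated).
#' @param min_cells Minimum valid cells for a reliable well mean.
#' @param exclude_border Drop border-flagged cells before averaging?
#' @param plate,well Identifiers carried into the result.
#' @param site_count Number of sites contributing.
#' @param activation_threshold Threshold for [classify_activation()].
#' @return One-row data frame of class `well_result`: `plate`, `well`,
#'   `n_cells`, `site_count`, `mean_ratio`, `activated`, `valid`.
#' @export
aggregate_well <- function(cells, min_cells = 50, exclude_border = TRUE,
                           plate = NA_character_, well = NA_character_,
                           site_count = NA_integer_,
                           activation_threshold = 0.7) {
  stopifnot(is.data.frame(cells), min_cells >= 0)
  use <- cells[is.finite(cells$ratio), , drop = FALSE]
  if (exclude_border && "border" %in% names(use))
    use <- use[!use$border %in% TRUE, , drop = FALSE]
  n <- nrow(use)
  mean_ratio <- if (n > 0) mean(use$ratio) else NA_real_
  valid <- n >= min_cells && is.finite(mean_ratio)
  res <- data.frame(plate = plate, well = well,
                    n_cells = n, site_count = site_count,
                    mean_ratio = mean_ratio,
                    activated = if (valid)
                      classify_activation(mean_ratio, activation_threshold)
                    else NA,
                    valid = valid, stringsAsFactors = FALSE)
  class(res) <- c("well_result", "data.frame")
  res
}

#' Classify pathway activation from a well-mean ratio
#'
#' Pathway activation is called when the well-mean nucleocytoplasmic
#' reporter ratio falls strictly below the threshold (default 0.7): an
#' activated pathway exports the reporter to the cytoplasm, depressing
#' the nuclear:cytoplasmic ratio, while inhibition retains it in the
#' nucleus (ratios near or above 1).
#'
#' @param mean_ratio Well-mean nucleocytoplasmic ratio(s).
#' @param threshold Activation threshold (default 0.7; strict `<`).
#' @return Logical vector: `TRUE` = activated.
#' @export
#' @examples
#' classify_activation(c(0.65, 0.7, 1.19))
classify_activation <- function(mean_ratio, threshold = 0.7) {
  stopifnot(is.numeric(mean_ratio), threshold > 0)
  mean_ratio < threshold
}

#' Per-cell nuclear intensity of an arbitrary co-registered channel
#'
#' Reuses the segmentation-derived inner nuclear regions to quantify a
#' nuclear endpoint in any co-registered channel -- e.g. a
#' phospho-epitope immunofluorescence stain read out as nuclear signal
#' -- and summarizes it as a well-level mean.
#'
#' @param channel_image Channel matrix (same frame as the DAPI image).
#' @param regions A [make_measurement_regions()] result.
#' @param background Constant background to subtract (floored at 0).
#' @param exclude_border Exclude border-flagged cells from the well mean?
#' @return List with `cells` (data frame: `label`, `nuclear_mean`,
#'   `border`) and `well_mean`.
#' @export
measure_nuclear_intensity <- function(channel_image, regions, background = 0,
                                      exclude_border = TRUE) {
  stopifnot(is.matrix(channel_image), inherits(regions, "measurement_regions"),
            all(dim(channel_image) == dim(regions$inner)))
  fb <- channel_image - background
  fb[fb < 0] <- 0
  labs <- regions$counts$label
  cells <- data.frame(label = labs, nuclear_mean = NA_real_,
                      border = regions$objects$border[match(labs, regions$objects$label)])
  if (length(labs)) {
    pos <- regions$inner > 0L
    means <- tapply(fb[pos], regions$inner[pos], mean)
    cells$nuclear_mean <- as.numeric(means[as.character(labs)])
  }
  cells <- cells[is.finite(cells$nuclear_mean), , drop = FALSE]
  use <- if (exclude_border) cells[!cells$border %in% TRUE, , drop = FALSE] else cells
  list(cells = cells,
       well_mean = if (nrow(use)) mean(use$nuclear_mean) else NA_real_)
}
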