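#' Nuclear segmentation parameters
#'
#' Parameters of the DAPI nuclear mask used to seed the translocation
#' measurement. Defaults follow the high-content application-module
#' settings of the assay: characteristic object width 13 um, threshold
#' 656 gray-levels above the estimated background up to the 16-bit
#' maximum, and an object area window of 60-355 um^2 with automatic
#' separation of touching objects.
#'
#' @param approximate_width Characteristic nucleus width in um; sets the
#'   scale of the touching-object separation.
#' @param intensity_above_background Threshold offset above the
#'   estimated background, in gray-levels.
#' @param max_gray Upper intensity bound (16-bit default 65535).
#' @param min_area,max_area Object area window. Interpreted in um^2 by
#'   default (`area_units = "um2"`) and converted with `pixel_size^2`;
#'   set `area_units = "px"` for pixel counts.
#' @param separate_touching Split touching nuclei by distance-transform
#'   watershed?
#' @param background_method `"auto_constant"` (histogram mode of the
#'   image) or `"fixed"` (use `background_value`).
#' @param background_value Fixed background gray-level when
#'   `background_method = "fixed"`.
#' @param area_units `"um2"` or `"px"`.
#' @return An object of class `seg_params`.
#' @export
seg_params <- function(approximate_width = 13, intensity_above_background = 656,
                       max_gray = 65535, min_area = 60, max_area = 355,
                       separate_touching = TRUE,
                       background_method = c("auto_constant", "fixed"),
                       background_value = NULL, area_units = c("um2", "px")) {
  background_method <- match.arg(background_method)
  area_units <- match.arg(area_units)
  stopifnot(approximate_width > 0, intensity_above_background > 0,
            intensity_above_background <= max_gray,
            min_area > 0, max_area > min_area)
  if (background_method == "fixed" && is.null(background_value))
    stop("background_method = 'fixed' requires `background_value`")
  structure(list(approximate_width = approximate_width,
                 intensity_above_background = intensity_above_background,
                 max_gray = max_gray, min_area = min_area, max_area = max_area,
                 separate_touching = isTRUE(separate_touching),
                 background_method = background_method,
                 background_value = background_value,
                 area_units = area_units),
            class = "seg_params")
}

#' Perinuclear ring parameters
#'
#' Geometry of the two measurement regions derived from each nucleus:
#' the inner nuclear region (nucleus eroded by `inner_region_distance`)
#' and the cytoplasmic ring (annulus starting `outer_region_distance`
#' outside the nuclear boundary, `outer_region_width` wide). Defaults:
#' 0.5 um inner distance, 0.5 um outer distance, 2 um ring width.
#'
#' @param inner_region_distance Erosion distance of the nuclear region (um).
#' @param outer_region_distance Gap between nucleus boundary and ring (um).
#' @param outer_region_width Radial width of the ring (um), > 0.
#' @return An object of class `ring_params`.
#' @export
ring_params <- function(inner_region_distance = 0.5,
                        outer_region_distance = 0.5,
                        outer_region_width = 2) {
  stopifnot(inner_region_distance >= 0, outer_region_distance >= 0,
            outer_region_width > 0)
  structure(list(inner_region_distance = inner_region_distance,
                 outer_region_distance = outer_region_distance,
                 outer_region_width = outer_region_width),
            class = "ring_params")
}

#' Estimate the constant image background
#'
#' The `auto_constant` method returns the histogram mode of the image
#' (the most frequent integer gray-level), a robust constant-background
#' estimate when background pixels dominate; `fixed` returns the
#' supplied value.
#'
#' @param image Numeric matrix of gray-levels.
#' @param method `"auto_constant"` or `"fixed"`.
#' @param value Background gray-level for the fixed method.
#' @return A single background gray-level.
#' @export
estimate_background <- function(image, method = c("auto_constant", "fixed"),
                                value = NULL) {
  method <- match.arg(method)
  if (method == "fixed") {
    if (is.null(value)) stop("fixed background estimation requires `value`")
    return(as.numeric(value))
  }
  if (length(image) == 0L) stop("cannot estimate background of an empty image")
  v <- as.integer(round(image))
  if (all(v == v[1])) {
    if (v[1] >= 65535) warning("image is saturated/constant at the maximum gray-level")
    return(as.numeric(v[1]))
  }
  counts <- tabulate(v + 1L)
  as.numeric(which.max(counts) - 1L)
}

#' Segment nuclei from a DAPI image
#'
#' Thresholds the DAPI channel at `background + intensity_above_background`
#' gray-levels, fills holes, optionally separates touching objects with a
#' distance-transform watershed seeded at the `approximate_width` scale,
#' and removes objects outside the `[min_area, max_area]` window. Nuclei
#' touching the image border are kept but flagged, so downstream
#' aggregation can exclude them.
#'
#' @param dapi_image Numeric matrix, 16-bit gray-levels.
#' @param params A [seg_params()].
#' @param pixel_size Pixel size in um/pixel.
#' @return An object of class `nuclear_labels`: `labels` (integer label
#'   matrix, 0 = background, labels contiguous 1..N), `objects` (data
#'   frame: `label`, `row_um`, `col_um`, `area_px`, `area_um2`,
#'   `border`), `background` (the estimate used), plus the parameters.
#' @export
segment_nuclei <- function(dapi_image, params = seg_params(), pixel_size = 0.65) {
  stopifnot(is.matrix(dapi_image), inherits(params, "seg_params"), pixel_size > 0)
  bg <- estimate_background(dapi_image,
                            method = params$background_method,
                            value = params$background_value)
  lo <- bg + params$intensity_above_background
  mask <- dapi_image >= lo & dapi_image <= params$max_gray
  if (!any(mask)) {
    return(structure(list(labels = matrix(0L, nrow(dapi_image), ncol(dapi_image)),
                          objects = empty_object_table(),
                          background = bg, params = params,
                          pixel_size = pixel_size),
                     class = "nuclear_labels"))
  }
  maskimg <- EBImage::fillHull(EBImage::Image(mask * 1))
  if (params$separate_touching) {
    dm <- EBImage::distmap(maskimg)
    # Local-maximum seeds must be at least ~half an object width apart.
    ext <- max(1L, as.integer(round(params$approximate_width / (4 * pixel_size))))
    labimg <- EBImage::watershed(dm, tolerance = 1, ext = ext)
  } else {
    labimg <- EBImage::bwlabel(maskimg)
  }
  labels <- label_matrix(labimg)

  # Area window, in pixels.
  scale <- if (params$area_units == "um2") pixel_size^2 else 1
  min_px <- params$min_area / scale
  max_px <- params$max_area / scale
  n0 <- max(labels)
  areas <- tabulate(labels[labels > 0L], nbins = n0)
  keep <- which(areas >= min_px & areas <= max_px)
  drop <- setdiff(seq_len(n0), keep)
  if (length(drop)) labels[labels %in% drop] <- 0L
  labels <- relabel_sequential(labels)

  n <- max(labels, 0L)
  if (n == 0L) {
    objects <- empty_object_table()
  } else {
    idx <- which(labels > 0L)
    lab <- labels[idx]
    rr <- (idx - 1L) %% nrow(labels) + 1L
    cc <- (idx - 1L) %/% nrow(labels) + 1L
    area_px <- tabulate(lab, nbins = n)
    row_c <- tapply(rr, lab, mean)
    col_c <- tapply(cc, lab, mean)
    on_border <- rr == 1L | rr == nrow(labels) | cc == 1L | cc == ncol(labels)
    border <- as.logical(tapply(on_border, lab, any))
    objects <- data.frame(label = seq_len(n),
                          row_um = as.numeric(row_c - 0.5) * pixel_size,
                          col_um = as.numeric(col_c - 0.5) * pixel_size,
                          area_px = area_px,
                          area_um2 = area_px * pixel_size^2,
                          border = border,
                          stringsAsFactors = FALSE)
  }
  structure(list(labels = labels, objects = objects, background = bg,
                 params = params, pixel_size = pixel_size),
            class = "nuclear_labels")
}

empty_object_table <- function() {
  data.frame(label = integer(), row_um = numeric(), col_um = numeric(),
             area_px = integer(), area_um2 = numeric(), border = logical(),
             stringsAsFactors = FALSE)
}

#' @export
print.nuclear_labels <- function(x, ...) {
  cat(sprintf("Nuclear segmentation: %d object(s), background %.0f gray-levels, %d border-flagged\n",
              nrow(x$objects), x$background, sum(x$objects$border)))
  invisible(x)
}
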