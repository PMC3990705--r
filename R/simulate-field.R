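#' Simulate one imaged field (site) of a translocation assay well
#'
#' Renders a two-channel 16-bit microscopy field: a DAPI channel with
#' signal only in nuclei, and a FITC/EGFP channel in which each cell's
#' nuclear and cytoplasmic mean intensities stand in the cell's
#' translocation contrast ratio (nuclear/cytoplasmic) before background
#' and noise are added.
#'
#' Cells are elliptical nuclei with elliptical cytoplasm aprons, placed
#' by dart throwing with a minimum center separation of 0.8 times the
#' sum of the effective nuclear radii (touching nuclei are allowed, to
#' exercise object separation downstream). Where cytoplasm aprons
#' overlap, each pixel is owned by the nearest cell center, emulating a
#' confluent monolayer in which cells tile the substrate; this keeps the
#' per-cell ground-truth contrast exact.
#'
#' @param geom A [cell_geometry()].
#' @param contrasts Per-cell nuclear:cytoplasmic contrast ratio(s). A
#'   single value is recycled to the number of cells implied by
#'   `geom$cell_density` and the field area; a vector fixes the cell
#'   count to its length.
#' @param noise A [noise_model()].
#' @param seed Optional integer seed; identical inputs and seed give
#'   bit-identical images and truth tables.
#' @param dim Field size in pixels, `c(rows, cols)`.
#' @param n_cells Optional explicit cell count, overriding the count
#'   implied by `geom$cell_density` (contrasts are recycled to it).
#' @return An object of class `sim_field`: list with integer matrices
#'   `dapi` and `fitc`, a `truth` list (`cells` data frame, per-field
#'   `expected_ratio` = mean per-cell contrast before imaging noise,
#'   `n_cells`), and `ownership` label matrices (`nucleus`, `cell`)
#'   giving the ground-truth measurement masks.
#' @export
#' @examples
#' f <- simulate_field(cell_geometry(cell_density = 300), 0.65,
#'                     noise_model(), seed = 1, dim = c(128, 128))
#' f$truth$n_cells
simulate_field <- function(geom, contrasts, noise = noise_model(),
                           seed = NULL, dim = c(400, 400), n_cells = NULL) {
  stopifnot(inherits(geom, "cell_geometry"), inherits(noise, "noise_model"),
            is.numeric(contrasts), all(contrasts > 0),
            length(dim) == 2L, all(dim >= 16))
  with_seed(seed, {
    h <- as.integer(dim[1]); w <- as.integer(dim[2])
    px <- geom$pixel_size
    h_um <- h * px; w_um <- w * px
    area_mm2 <- h_um * w_um / 1e6

    n <- if (!is.null(n_cells)) as.integer(n_cells)
    else if (length(contrasts) == 1L)
      as.integer(round(geom$cell_density * area_mm2)) else length(contrasts)
    contrasts <- rep_len(contrasts, max(n, 0L))

    # Reject densities that cannot be placed even with touching nuclei.
    mean_r <- mean(geom$nucleus_semi_axes)
    if (n * pi * mean_r^2 > 0.65 * h_um * w_um)
      stop("cell density too high: requested nuclei cannot be packed into the field")

    if (n == 0L) {
      empty <- matrix(0, h, w)
      return(structure(list(
        dapi = apply_camera_noise(empty, noise),
        fitc = apply_camera_noise(empty, noise),
        truth = list(cells = empty_truth_cells(), expected_ratio = NA_real_,
                     n_cells = 0L),
        ownership = list(nucleus = matrix(0L, h, w), cell = matrix(0L, h, w)),
        geom = geom, noise = noise, dim = c(h, w)), class = "sim_field"))
    }

    # Per-cell morphology and expression.
    ax <- stats::runif(n, geom$nucleus_semi_axes[1], geom$nucleus_semi_axes[2])
    bx <- stats::runif(n, geom$nucleus_semi_axes[1], geom$nucleus_semi_axes[2])
    theta <- stats::runif(n, 0, pi)
    r_eff <- sqrt(ax * bx)
    expr <- stats::rlnorm(n, meanlog = -noise$expr_sdlog^2 / 2,
                          sdlog = noise$expr_sdlog)
    dapi_expr <- stats::rlnorm(n, meanlog = -0.005, sdlog = 0.1)

    # Dart-throwing placement with minimum center separation.
    cx <- numeric(n); cy <- numeric(n)
    placed <- 0L
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in seq_len(2000L)) {
        x <- stats::runif(1, 0, w_um); y <- stats::runif(1, 0, h_um)
        if (placed == 0L) { ok <- TRUE; break }
        j <- seq_len(placed)
        d <- sqrt((cx[j] - x)^2 + (cy[j] - y)^2)
        if (all(d >= 0.8 * (r_eff[j] + r_eff[i]))) { ok <- TRUE; break }
      }
      if (!ok) break
      placed <- placed + 1L
      cx[placed] <- x; cy[placed] <- y
    }
    if (placed < n)
      warning(sprintf("placed %d of %d requested cells before hitting the packing limit",
                      placed, n))
    n <- placed
    ax <- ax[1:n]; bx <- bx[1:n]; theta <- theta[1:n]
    expr <- expr[1:n]; dapi_expr <- dapi_expr[1:n]
    contrasts <- contrasts[1:n]; cx <- cx[1:n]; cy <- cy[1:n]

    # Ownership rendering: nearest-center tiling of nucleus and cytoplasm.
    cell_owner <- matrix(0L, h, w); cell_d2 <- matrix(Inf, h, w)
    nuc_owner <- matrix(0L, h, w); nuc_d2 <- matrix(Inf, h, w)
    ext <- geom$cytoplasm_extent
    for (k in seq_len(n)) {
      amax <- max(ax[k], bx[k]) + ext
      r0 <- max(1L, floor((cy[k] - amax) / px) + 1L)
      r1 <- min(h, ceiling((cy[k] + amax) / px))
      c0 <- max(1L, floor((cx[k] - amax) / px) + 1L)
      c1 <- min(w, ceiling((cx[k] + amax) / px))
      if (r0 > r1 || c0 > c1) next
      rows <- r0:r1; cols <- c0:c1
      ym <- (rows - 0.5) * px - cy[k]
      xm <- (cols - 0.5) * px - cx[k]
      dy <- matrix(ym, length(rows), length(cols))
      dx <- matrix(xm, length(rows), length(cols), byrow = TRUE)
      u <- dx * cos(theta[k]) + dy * sin(theta[k])
      v <- -dx * sin(theta[k]) + dy * cos(theta[k])
      d2 <- dx^2 + dy^2
      in_cyto <- (u / (ax[k] + ext))^2 + (v / (bx[k] + ext))^2 <= 1
      in_nuc <- (u / ax[k])^2 + (v / bx[k])^2 <= 1
      sub_co <- cell_owner[rows, cols, drop = FALSE]
      sub_cd <- cell_d2[rows, cols, drop = FALSE]
      upd <- in_cyto & d2 < sub_cd
      sub_co[upd] <- k; sub_cd[upd] <- d2[upd]
      cell_owner[rows, cols] <- sub_co; cell_d2[rows, cols] <- sub_cd
      sub_no <- nuc_owner[rows, cols, drop = FALSE]
      sub_nd <- nuc_d2[rows, cols, drop = FALSE]
      upd <- in_nuc & d2 < sub_nd
      sub_no[upd] <- k; sub_nd[upd] <- d2[upd]
      nuc_owner[rows, cols] <- sub_no; nuc_d2[rows, cols] <- sub_nd
    }

    # Photometry: uniform compartment intensities in the signal domain.
    cyt_val <- noise$signal_gain * expr
    nuc_val <- contrasts * cyt_val
    fitc_sig <- matrix(0, h, w)
    pos <- cell_owner > 0L
    fitc_sig[pos] <- cyt_val[cell_owner[pos]]
    npos <- nuc_owner > 0L
    fitc_sig[npos] <- nuc_val[nuc_owner[npos]]
    dapi_sig <- matrix(0, h, w)
    dapi_sig[npos] <- noise$dapi_level * dapi_expr[nuc_owner[npos]]

    n_px_nuc <- tabulate(nuc_owner[npos], nbins = n)
    n_px_cyto <- tabulate(cell_owner[pos & !npos], nbins = n)

    cells <- data.frame(
      cell = seq_len(n),
      x_um = cx, y_um = cy,
      semi_axis_a_um = ax, semi_axis_b_um = bx, theta = theta,
      contrast = contrasts,
      state = contrast_state(contrasts),
      expression = expr,
      n_px_nucleus = n_px_nuc,
      n_px_cytoplasm = n_px_cyto,
      stringsAsFactors = FALSE)

    structure(list(
      dapi = apply_camera_noise(dapi_sig, noise),
      fitc = apply_camera_noise(fitc_sig, noise),
      truth = list(cells = cells,
                   expected_ratio = mean(contrasts),
                   n_cells = n),
      ownership = list(nucleus = nuc_owner, cell = cell_owner),
      geom = geom, noise = noise, dim = c(h, w)), class = "sim_field")
  })
}

# Camera model: optional Poisson shot noise on the signal, then constant
# background offset plus Gaussian read noise, clamped to 16 bits.
apply_camera_noise <- function(signal, noise) {
  img <- signal
  if (noise$shot_noise)
    img <- matrix(stats::rpois(length(img), lambda = img), nrow(img), ncol(img))
  img <- img + noise$background_level
  if (noise$background_sd > 0)
    img <- img + stats::rnorm(length(img), 0, noise$background_sd)
  clamp16(img)
}

empty_truth_cells <- function() {
  data.frame(cell = integer(), x_um = numeric(), y_um = numeric(),
             semi_axis_a_um = numeric(), semi_axis_b_um = numeric(),
             theta = numeric(), contrast = numeric(), state = character(),
             expression = numeric(), n_px_nucleus = integer(),
             n_px_cytoplasm = integer(), stringsAsFactors = FALSE)
}

#' @export
print.sim_field <- function(x, ...) {
  cat(sprintf("Simulated field: %dx%d px (%.2f um/px), %d cells, expected ratio %s\n",
              x$dim[1], x$dim[2], x$geom$pixel_size, x$truth$n_cells,
              ifelse(is.na(x$truth$expected_ratio), "NA",
                     sprintf("%.3f", x$truth$expected_ratio))))
  invisible(x)
}

#' Ground-truth compartment means of a simulated field
#'
#' Recomputes, per cell, the mean FITC intensity over the ground-truth
#' nuclear and cytoplasmic ownership masks. On a noise-free field the
#' ratio equals the requested contrast exactly.
#'
#' @param field A [simulate_field()] result.
#' @return Data frame with one row per cell: `cell`, `nuc_mean`,
#'   `cyto_mean`, `ratio`.
#' @export
truth_compartment_means <- function(field) {
  stopifnot(inherits(field, "sim_field"))
  n <- field$truth$n_cells
  fitc <- field$fitc
  nucm <- field$ownership$nucleus
  cellm <- field$ownership$cell
  out <- data.frame(cell = seq_len(n), nuc_mean = rep(NA_real_, n),
                    cyto_mean = rep(NA_real_, n), ratio = rep(NA_real_, n))
  for (k in seq_len(n)) {
    np <- nucm == k
    cp <- cellm == k & nucm == 0L
    if (any(np)) out$nuc_mean[k] <- mean(fitc[np])
    if (any(cp)) out$cyto_mean[k] <- mean(fitc[cp])
  }
  out$ratio <- out$nuc_mean / out$cyto_mean
  out
}
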