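# Shared fixtures and independent oracles, built in code at test time.

PX <- 0.65  # um/pixel used throughout the tests

# Paint a filled disk of given radius (px) into a matrix.
draw_disk <- function(img, row0, col0, radius_px, value) {
  rr <- matrix(seq_len(nrow(img)), nrow(img), ncol(img))
  cc <- matrix(seq_len(ncol(img)), nrow(img), ncol(img), byrow = TRUE)
  img[(rr - row0)^2 + (cc - col0)^2 <= radius_px^2] <- value
  img
}

# Disk radius in px giving a target area in um^2.
disk_radius_px <- function(area_um2, pixel_size = PX) {
  sqrt(area_um2 / pi) / pixel_size
}

# Independent per-pixel recomputation of nuclear/ring means: plain loops,
# no vectorized sharing with the implementation under test.
brute_force_cell_means <- function(fitc, regions, background = 0) {
  labs <- regions$counts$label
  sums_i <- stats::setNames(numeric(length(labs)), labs)
  cnt_i <- sums_i; sums_r <- sums_i; cnt_r <- sums_i
  for (r in seq_len(nrow(fitc))) {
    for (cc in seq_len(ncol(fitc))) {
      v <- max(fitc[r, cc] - background, 0)
      li <- regions$inner[r, cc]
      if (li > 0L && as.character(li) %in% names(sums_i)) {
        sums_i[as.character(li)] <- sums_i[as.character(li)] + v
        cnt_i[as.character(li)] <- cnt_i[as.character(li)] + 1
      }
      lr <- regions$ring[r, cc]
      if (lr > 0L && as.character(lr) %in% names(sums_r)) {
        sums_r[as.character(lr)] <- sums_r[as.character(lr)] + v
        cnt_r[as.character(lr)] <- cnt_r[as.character(lr)] + 1
      }
    }
  }
  data.frame(label = labs,
             nuclear_mean = as.numeric(sums_i / cnt_i),
             ring_mean = as.numeric(sums_r / cnt_r))
}

# Euclidean distance from a pixel to the nearest pixel of a labelled nucleus.
dist_to_nucleus <- function(row, col, labels, k) {
  idx <- which(labels == k)
  nr <- (idx - 1L) %% nrow(labels) + 1L
  nc <- (idx - 1L) %/% nrow(labels) + 1L
  sqrt(min((nr - row)^2 + (nc - col)^2))
}

# Full well pipeline on a list of simulated fields (sites of one well).
measure_simulated_well <- function(fields, seg = seg_params(),
                                   ring = ring_params(), pixel_size = PX,
                                   min_cells = 50) {
  cells <- list()
  for (s in seq_along(fields)) {
    f <- fields[[s]]
    nl <- segment_nuclei(f$dapi, seg, pixel_size)
    if (nrow(nl$objects) == 0L) next
    reg <- make_measurement_regions(nl, ring)
    cm <- measure_cells(f$fitc, reg, background = estimate_background(f$fitc))
    if (nrow(cm)) { cm$site <- s; cells[[length(cells) + 1L]] <- cm }
  }
  cells <- do.call(rbind, cells)
  aggregate_well(cells, min_cells = min_cells, site_count = length(fields))
}
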