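#' Build inner-nuclear and perinuclear-ring measurement regions
#'
#' For every segmented nucleus, derives the two regions over which the
#' translocation ratio is measured: the inner region (nucleus eroded by
#' `inner_region_distance`) and the cytoplasmic ring (the annulus
#' between dilations of the nucleus by `outer_region_distance` and by
#' `outer_region_distance + outer_region_width`). Physical distances are
#' converted to pixel radii, rounding to the nearest pixel but never
#' below 1 px for positive distances.
#'
#' Ring pixels are excluded where they fall on any nucleus or off the
#' image; pixels contested by several rings are assigned to the nucleus
#' whose boundary is nearest (exact Euclidean distance to the candidate
#' nuclei, computed only over the contested set). Objects whose inner
#' region erodes below 5 px are dropped and counted.
#'
#' @param nl A [segment_nuclei()] result.
#' @param ring A [ring_params()].
#' @return An object of class `measurement_regions`: `inner` and `ring`
#'   integer label matrices, `objects` (surviving-object table with
#'   border flags), `counts` (per-object inner/ring pixel counts),
#'   `dropped` (labels removed because the inner region vanished).
#' @export
make_measurement_regions <- function(nl, ring = ring_params()) {
  stopifnot(inherits(nl, "nuclear_labels"), inherits(ring, "ring_params"))
  labels <- nl$labels
  px <- nl$pixel_size
  h <- nrow(labels); w <- ncol(labels)
  r_in <- px_radius(ring$inner_region_distance, px)
  r_gap <- px_radius(ring$outer_region_distance, px)
  r_out <- px_radius(ring$outer_region_distance + ring$outer_region_width, px)
  if (r_out <= r_gap) r_out <- r_gap + 1L

  n <- max(labels, 0L)
  inner <- matrix(0L, h, w)
  ring_lab <- matrix(0L, h, w)
  if (n == 0L) {
    return(structure(list(inner = inner, ring = ring_lab,
                          objects = nl$objects,
                          counts = data.frame(label = integer(),
                                              n_inner = integer(),
                                              n_ring = integer()),
                          dropped = integer(), ring_params = ring,
                          pixel_size = px), class = "measurement_regions"))
  }

  pos <- which(labels > 0L)
  by_lab <- split(pos, labels[pos])
  ring_cnt <- matrix(0L, h, w)
  ring_last <- matrix(0L, h, w)
  ann_idx <- vector("list", n)
  inner_px <- integer(n)
  pad <- r_out + 1L

  for (k in seq_len(n)) {
    gi <- by_lab[[as.character(k)]]
    rr <- (gi - 1L) %% h + 1L
    cc <- (gi - 1L) %/% h + 1L
    r0 <- max(1L, min(rr) - pad); r1 <- min(h, max(rr) + pad)
    c0 <- max(1L, min(cc) - pad); c1 <- min(w, max(cc) + pad)
    m <- matrix(0, r1 - r0 + 1L, c1 - c0 + 1L)
    m[cbind(rr - r0 + 1L, cc - c0 + 1L)] <- 1

    er <- if (r_in > 0L) EBImage::erode(m, disc_brush(r_in)) else m
    eidx <- which(er > 0)
    if (length(eidx)) {
      lr <- (eidx - 1L) %% nrow(m) + 1L
      lc <- (eidx - 1L) %/% nrow(m) + 1L
      gidx <- (lc + c0 - 2L) * h + (lr + r0 - 1L)
      inner[gidx] <- k
      inner_px[k] <- length(gidx)
    }

    d_out <- EBImage::dilate(m, disc_brush(r_out))
    d_gap <- if (r_gap > 0L) EBImage::dilate(m, disc_brush(r_gap)) else m
    aidx <- which(d_out > 0 & d_gap == 0)
    if (length(aidx)) {
      lr <- (aidx - 1L) %% nrow(m) + 1L
      lc <- (aidx - 1L) %/% nrow(m) + 1L
      gidx <- (lc + c0 - 2L) * h + (lr + r0 - 1L)
      gidx <- gidx[labels[gidx] == 0L]  # collision with any nucleus excluded
      if (length(gidx)) {
        ann_idx[[k]] <- gidx
        ring_cnt[gidx] <- ring_cnt[gidx] + 1L
        ring_last[gidx] <- k
      }
    }
  }

  single <- which(ring_cnt == 1L)
  ring_lab[single] <- ring_last[single]

  contested <- which(ring_cnt >= 2L)
  if (length(contested)) {
    best_d <- rep(Inf, length(contested))
    best_lab <- integer(length(contested))
    con_r <- (contested - 1L) %% h + 1L
    con_c <- (contested - 1L) %/% h + 1L
    for (k in seq_len(n)) {
      sel <- match(ann_idx[[k]], contested)
      sel <- sel[!is.na(sel)]
      if (!length(sel)) next
      gi <- by_lab[[as.character(k)]]
      nr <- (gi - 1L) %% h + 1L
      nc <- (gi - 1L) %/% h + 1L
      d2 <- outer(con_r[sel], nr, "-")^2 + outer(con_c[sel], nc, "-")^2
      dmin <- apply(d2, 1L, min)
      upd <- dmin < best_d[sel]
      if (any(upd)) {
        best_d[sel[upd]] <- dmin[upd]
        best_lab[sel[upd]] <- k
      }
    }
    ring_lab[contested] <- best_lab
  }

  dropped <- which(inner_px < 5L)
  if (length(dropped)) {
    inner[inner %in% dropped] <- 0L
    ring_lab[ring_lab %in% dropped] <- 0L
    message(length(dropped), " object(s) dropped: inner region eroded below 5 px")
  }
  keep <- setdiff(seq_len(n), dropped)
  ring_px <- tabulate(ring_lab[ring_lab > 0L], nbins = n)

  structure(list(inner = inner, ring = ring_lab,
                 objects = nl$objects[nl$objects$label %in% keep, , drop = FALSE],
                 counts = data.frame(label = keep,
                                     n_inner = inner_px[keep],
                                     n_ring = ring_px[keep]),
                 dropped = dropped, ring_params = ring, pixel_size = px),
            class = "measurement_regions")
}

#' @export
print.measurement_regions <- function(x, ...) {
  cat(sprintf("Measurement regions: %d object(s) (%d dropped), median inner %spx / ring %spx\n",
              nrow(x$counts), length(x$dropped),
              if (nrow(x$counts)) stats::median(x$counts$n_inner) else "-",
              if (nrow(x$counts)) stats::median(x$counts$n_ring) else "-"))
  invisible(x)
}
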