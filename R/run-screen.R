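#' Run the translocation-screen pipeline on one plate
#'
#' End-to-end orchestration: per-site nuclear segmentation, measurement
#' region construction, per-cell ratio measurement, well aggregation,
#' internal plate normalization, assay quality control (Z' from the
#' control wells, log-Z-scores against negative controls), activation
#' calls and single-plate hit listing. Optionally writes per-cell,
#' per-well and summary files.
#'
#' The run status reflects quality control: `0` = pass, `1` = QC fail
#' (Z' undefined or below `config$zprime_floor`). Stage errors abort
#' with a stage-tagged message.
#'
#' @param config A [run_config()].
#' @param plate Input plate: a [simulate_plate()] result with images, a
#'   [load_plate_images()] result, or `NULL` to simulate from `layout`.
#' @param layout Plate map used when `plate` is `NULL` (simulated with
#'   `config$seed`).
#' @param output_dir Optional directory for `cells.csv`, `wells.csv`
#'   and `summary.json`.
#' @param geom,dose,noise Simulation parameters used when simulating
#'   from `layout`.
#' @return An object of class `screen_run`: `status`, `zprime`,
#'   `wells` (with normalized ratios, log-Z-scores and activation
#'   calls), `cells`, `hits`, `plate_mean`, `files`, and a per-stage
#'   `log` of counts.
#' @export
run_screen <- function(config = run_config(), plate = NULL, layout = NULL,
                       output_dir = NULL, geom = cell_geometry(),
                       dose = dose_model(), noise = noise_model()) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[stage: ", name, "] ", conditionMessage(e), call. = FALSE))
  }
  log <- list()

  input <- stage("input", {
    if (is.null(plate)) {
      if (is.null(layout)) stop("either `plate` or `layout` is required")
      plate <- simulate_plate(layout, geom = geom, dose = dose, noise = noise,
                              seed = config$seed, n_sites = config$n_sites,
                              images = TRUE)
    }
    if (inherits(plate, "sim_plate")) {
      if (is.null(plate$images))
        stop("simulated plate has no images (images = FALSE)")
      list(wells = plate$wells[c("plate", "well", "compound_id",
                                 "concentration_nM", "role")],
           sites = lapply(seq_len(nrow(plate$wells)), function(i)
             lapply(plate$images[[i]], function(f)
               list(dapi = f$dapi, fitc = f$fitc))))
    } else if (inherits(plate, "plate_images")) {
      list(wells = plate$wells[c("plate", "well", "compound_id",
                                 "concentration_nM", "role")],
           sites = plate$images)
    } else stop("unsupported `plate` input of class ",
                paste(class(plate), collapse = "/"))
  })

  measured <- stage("segment/quantify", {
    all_cells <- list()
    well_rows <- list()
    n_segmented <- 0L; n_dropped <- 0L
    for (i in seq_len(nrow(input$wells))) {
      wellid <- input$wells$well[i]
      sites <- input$sites[[i]]
      cells_i <- list()
      for (s in seq_along(sites)) {
        nl <- segment_nuclei(sites[[s]]$dapi, config$seg, config$pixel_size)
        n_segmented <- n_segmented + nrow(nl$objects)
        if (nrow(nl$objects) == 0L) next
        regions <- make_measurement_regions(nl, config$ring)
        bg_fitc <- if (config$subtract_fitc_background)
          estimate_background(sites[[s]]$fitc) else 0
        cm <- measure_cells(sites[[s]]$fitc, regions, background = bg_fitc)
        n_dropped <- n_dropped + attr(cm, "n_dropped")
        if (nrow(cm)) {
          cm$plate <- input$wells$plate[i]; cm$well <- wellid; cm$site <- s
          cells_i[[length(cells_i) + 1L]] <- cm
        }
      }
      wc <- if (length(cells_i)) do.call(rbind, cells_i) else
        empty_cell_measurements()
      wr <- aggregate_well(wc, min_cells = config$min_cells,
                           exclude_border = config$exclude_border,
                           plate = input$wells$plate[i], well = wellid,
                           site_count = length(sites),
                           activation_threshold = config$activation_threshold)
      well_rows[[i]] <- wr
      all_cells[[i]] <- wc
    }
    wells <- do.call(rbind, well_rows)
    wells$role <- input$wells$role
    wells$compound_id <- input$wells$compound_id
    wells$concentration_nM <- input$wells$concentration_nM
    list(cells = do.call(rbind, all_cells), wells = wells,
         n_segmented = n_segmented, n_dropped = n_dropped)
  })
  log$cells_segmented <- measured$n_segmented
  log$cells_dropped <- measured$n_dropped
  log$wells_invalid <- sum(!measured$wells$valid)

  normed <- stage("normalize", normalize_plate(measured$wells))
  wells <- normed$wells

  qc <- stage("qc", {
    posv <- wells$mean_ratio[wells$role == "pos_ctrl" & wells$valid]
    negv <- wells$mean_ratio[wells$role == "neg_ctrl" & wells$valid]
    zp <- if (length(posv) >= 2 && length(negv) >= 2)
      suppressWarnings(zprime(posv, negv)) else NA_real_
    negn <- wells$normalized_ratio[wells$role == "neg_ctrl" & wells$valid]
    lz <- if (length(negn) >= 2 && stats::sd(log(negn)) > 0)
      log_z_score(wells$normalized_ratio, negn) else rep(NA_real_, nrow(wells))
    list(zprime = zp, log_z = lz)
  })
  wells$log_z_score <- qc$log_z

  hits <- stage("hits", {
    cw <- wells[wells$role == "compound" & wells$valid, , drop = FALSE]
    h <- cw[cw$normalized_ratio > config$hit_threshold,
            c("compound_id", "well", "normalized_ratio"), drop = FALSE]
    h[order(-h$normalized_ratio), , drop = FALSE]
  })

  status <- if (!is.finite(qc$zprime) || qc$zprime < config$zprime_floor) 1L else 0L

  files <- character()
  if (!is.null(output_dir)) {
    files <- stage("report", {
      if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
      fc <- file.path(output_dir, "cells.csv")
      fw <- file.path(output_dir, "wells.csv")
      fs <- file.path(output_dir, "summary.json")
      utils::write.csv(measured$cells, fc, row.names = FALSE)
      utils::write.csv(wells, fw, row.names = FALSE)
      jsonlite::write_json(list(
        status = status, zprime = qc$zprime, plate_mean = normed$plate_mean,
        n_wells = nrow(wells), n_wells_invalid = log$wells_invalid,
        n_cells = nrow(measured$cells),
        n_hits = nrow(hits), hits = hits$compound_id,
        activated_wells = wells$well[wells$activated %in% TRUE]),
        fs, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      c(fc, fw, fs)
    })
  }

  structure(list(status = status, zprime = qc$zprime,
                 plate_mean = normed$plate_mean, wells = wells,
                 cells = measured$cells, hits = hits, files = files,
                 log = log, config = config),
            class = "screen_run")
}

#' @export
print.screen_run <- function(x, ...) {
  cat(sprintf("Screen run: status %d (%s), Z' = %s\n", x$status,
              if (x$status == 0) "QC pass" else "QC FAIL",
              ifelse(is.finite(x$zprime), sprintf("%.3f", x$zprime), "undefined")))
  cat(sprintf("  %d wells (%d invalid), %d cells, %d hit(s)\n",
              nrow(x$wells), x$log$wells_invalid, nrow(x$cells), nrow(x$hits)))
  invisible(x)
}
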