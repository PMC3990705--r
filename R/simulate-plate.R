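#' Construct a plate map
#'
#' A plate map assigns each used well a role: a test compound at a
#' concentration, a positive control (reference inhibitor), a negative
#' control (vehicle/DMSO), or empty.
#'
#' @param plate Plate identifier.
#' @param well Character vector of well ids (letter row + 2-digit
#'   column, e.g. `"A01"`).
#' @param role One of `"compound"`, `"pos_ctrl"`, `"neg_ctrl"`,
#'   `"empty"` per well.
#' @param compound_id Compound identifier (NA for controls/empty).
#' @param concentration_nM Compound concentration in nM (NA for
#'   controls/empty).
#' @return A `data.frame` with columns plate, well, compound_id,
#'   concentration_nM, role.
#' @export
plate_map <- function(plate, well, role, compound_id = NA_character_,
                      concentration_nM = NA_real_) {
  map <- data.frame(plate = as.character(plate), well = as.character(well),
                    compound_id = as.character(compound_id),
                    concentration_nM = as.numeric(concentration_nM),
                    role = as.character(role), stringsAsFactors = FALSE)
  validate_plate_map(map)
  map
}

validate_plate_map <- function(map) {
  need <- c("plate", "well", "compound_id", "concentration_nM", "role")
  missing_cols <- setdiff(need, names(map))
  if (length(missing_cols))
    stop("plate map is missing column(s): ", paste(missing_cols, collapse = ", "))
  bad_well <- !grepl("^[A-P](0[1-9]|1[0-9]|2[0-4])$", map$well)
  if (any(bad_well))
    stop("malformed well id(s) at row(s) ", paste(which(bad_well), collapse = ", "),
         ": ", paste(unique(map$well[bad_well]), collapse = ", "),
         " (expected e.g. 'A01')")
  roles <- c("compound", "pos_ctrl", "neg_ctrl", "empty")
  bad_role <- !map$role %in% roles
  if (any(bad_role))
    stop("unknown role(s) at row(s) ", paste(which(bad_role), collapse = ", "),
         ": ", paste(unique(map$role[bad_role]), collapse = ", "))
  if (any(duplicated(map[c("plate", "well")])))
    stop("duplicated plate/well entries in plate map")
  invisible(map)
}

#' Convenience control-plate map
#'
#' Lays out `n_neg` negative-control and `n_pos` positive-control wells
#' (row A then row B by default), as used for assay quality-control
#' plates.
#'
#' @param plate Plate id.
#' @param n_neg,n_pos Number of control wells per group (max 12 each).
#' @return A plate map data frame.
#' @export
control_plate_map <- function(plate = "QC1", n_neg = 8, n_pos = 8) {
  stopifnot(n_neg >= 1, n_pos >= 1, n_neg <= 12, n_pos <= 12)
  plate_map(plate,
            well = c(sprintf("A%02d", seq_len(n_neg)),
                     sprintf("B%02d", seq_len(n_pos))),
            role = c(rep("neg_ctrl", n_neg), rep("pos_ctrl", n_pos)))
}

#' Simulate a plate of translocation-assay wells
#'
#' For each used well the expected nucleocytoplasmic ratio is set by its
#' role -- `r_active` for negative controls, `r_inhibited` for positive
#' controls, and the dose-response [dose_to_contrast()] for compound
#' wells -- then perturbed by an additive well-level Normal error with
#' sd `noise$well_to_well_sd`. Per-cell contrasts vary lognormally
#' (mean-one, log-sd `noise$cell_contrast_sdlog`) around the well value;
#' the truth table's per-well `expected_ratio` is the mean of the
#' per-cell contrasts actually placed, before imaging noise. All sites
#' of a well share the well's state.
#'
#' @param layout Plate map (see [plate_map()]).
#' @param geom A [cell_geometry()].
#' @param dose A [dose_model()] used for compound wells and as the
#'   source of the control phenotypes.
#' @param noise A [noise_model()].
#' @param seed Optional integer seed (full-plate determinism).
#' @param n_sites Imaged sites (fields) per well.
#' @param dim Per-site field size in pixels.
#' @param images Render site images? `FALSE` gives the fast tabular
#'   path: per-cell contrasts and well truth without rendering.
#' @return An object of class `sim_plate`: `wells` (per-well truth table
#'   with `true_ratio` = pre-perturbation role ratio, `well_ratio` =
#'   perturbed well-level ratio, `expected_ratio` = mean per-cell
#'   contrast, `n_cells`), `cells` (per-cell truth), and `images` (named
#'   list `well -> list of sim_field`, when `images = TRUE`).
#' @export
simulate_plate <- function(layout, geom = cell_geometry(), dose = dose_model(),
                           noise = noise_model(), seed = NULL,
                           n_sites = 4, dim = c(400, 400), images = TRUE) {
  validate_plate_map(layout)
  stopifnot(n_sites >= 1)
  with_seed(seed, {
    used <- layout[layout$role != "empty", , drop = FALSE]
    px <- geom$pixel_size
    site_area_mm2 <- prod(dim) * px^2 / 1e6
    n_per_site <- as.integer(round(geom$cell_density * site_area_mm2))

    wells <- used
    wells$true_ratio <- NA_real_
    wells$well_ratio <- NA_real_
    wells$expected_ratio <- NA_real_
    wells$n_cells <- 0L
    wells$n_sites <- as.integer(n_sites)
    cell_rows <- vector("list", nrow(used))
    img_list <- if (images) stats::setNames(vector("list", nrow(used)),
                                            used$well) else NULL

    for (i in seq_len(nrow(used))) {
      role <- used$role[i]
      base <- switch(role,
                     neg_ctrl = dose$r_active,
                     pos_ctrl = dose$r_inhibited,
                     compound = {
                       conc <- used$concentration_nM[i]
                       if (is.na(conc)) stop("compound well ", used$well[i],
                                             " has no concentration")
                       dose_to_contrast(conc, dose)
                     })
      well_ratio <- max(base + stats::rnorm(1, 0, noise$well_to_well_sd), 0.05)
      wells$true_ratio[i] <- base
      wells$well_ratio[i] <- well_ratio

      site_fields <- vector("list", n_sites)
      well_cells <- vector("list", n_sites)
      for (s in seq_len(n_sites)) {
        contr <- well_ratio * stats::rlnorm(
          n_per_site, meanlog = -noise$cell_contrast_sdlog^2 / 2,
          sdlog = noise$cell_contrast_sdlog)
        if (images) {
          f <- simulate_field(geom, contr, noise, seed = NULL, dim = dim)
          site_fields[[s]] <- f
          cells_s <- f$truth$cells
        } else {
          cells_s <- data.frame(cell = seq_along(contr), contrast = contr,
                                state = contrast_state(contr),
                                stringsAsFactors = FALSE)
        }
        if (nrow(cells_s)) {
          cells_s$plate <- used$plate[i]
          cells_s$well <- used$well[i]
          cells_s$site <- s
        }
        well_cells[[s]] <- cells_s
      }
      wc <- do.call(rbind, well_cells)
      wells$n_cells[i] <- nrow(wc)
      wells$expected_ratio[i] <- if (nrow(wc)) mean(wc$contrast) else NA_real_
      cell_rows[[i]] <- wc
      if (images) img_list[[i]] <- site_fields
    }

    structure(list(layout = layout, wells = wells,
                   cells = do.call(rbind, cell_rows),
                   images = img_list,
                   geom = geom, dose = dose, noise = noise,
                   n_sites = n_sites, dim = dim),
              class = "sim_plate")
  })
}

#' @export
print.sim_plate <- function(x, ...) {
  cat(sprintf("Simulated plate: %d used wells, %d site(s)/well, %s images\n",
              nrow(x$wells), x$n_sites,
              if (is.null(x$images)) "no" else "with"))
  tab <- table(x$wells$role)
  cat("  roles:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Simulate a primary screen in duplicate (tabular fast path)
#'
#' Draws one true nucleocytoplasmic ratio per compound and two
#' independent noisy replicate observations, emulating a primary screen
#' run in biological duplicate at a single concentration, without
#' rendering images. A fraction `active_fraction` of compounds are true
#' inhibitors whose ratio follows the dose-response at the screening
#' concentration with a compound-specific potency drawn from
#' `potency_sampler`; the remainder sit at the activated baseline with
#' compound-level variability `inactive_sd`.
#'
#' Defaults emulate a combinatorial library enriched for inhibitors of
#' the target pathway: 40% of compounds have some true activity, with
#' potencies spanning several orders of magnitude (lognormal around
#' 50 uM, log-sd 2.5), so screening at 15 uM yields a graded continuum
#' of ratios rather than a two-point mixture, roughly a tenth of the
#' library above a raw ratio of 1, and replicate rank concordance
#' (R-squared of ranks) around 0.9.
#'
#' @param n_compounds Number of compounds.
#' @param active_fraction Proportion of true actives in `[0, 1]`.
#' @param potency_sampler Function `n -> IC50s (nM)` for active
#'   compounds.
#' @param replicate_sd Additive Gaussian sd of each replicate
#'   observation (ratio units); biological-duplicate noise of a
#'   well mean.
#' @param inactive_sd Compound-to-compound sd of the true baseline
#'   ratio (reproducible compound effects: autofluorescence, mild
#'   toxicity, weak off-target activity).
#' @param concentration_nM Screening concentration (default 15000 nM,
#'   i.e. 15 uM).
#' @param dose A [dose_model()].
#' @param ratio_sampler Optional function `n -> true ratios` overriding
#'   the active/inactive mixture entirely.
#' @param seed Optional integer seed.
#' @return An object of class `sim_screen`: `replicates`, a list of two
#'   screen tables (`compound_id`, `replicate`, `concentration_nM`,
#'   `mean_ratio`, `normalized_ratio`, `rank` with rank 1 = highest
#'   ratio), and `truth` (`compound_id`, `true_ratio`, `active`).
#' @export
simulate_screen <- function(n_compounds, active_fraction = 0.4,
                            potency_sampler = function(n) stats::rlnorm(n, log(5e4), 2.5),
                            replicate_sd = 0.02, inactive_sd = 0.06,
                            concentration_nM = 15000, dose = dose_model(),
                            ratio_sampler = NULL, seed = NULL) {
  stopifnot(n_compounds >= 1, active_fraction >= 0, active_fraction <= 1,
            replicate_sd >= 0, inactive_sd >= 0)
  with_seed(seed, {
    ids <- sprintf("C%05d", seq_len(n_compounds))
    if (!is.null(ratio_sampler)) {
      true <- ratio_sampler(n_compounds)
      active <- rep(NA, n_compounds)
    } else {
      active <- stats::runif(n_compounds) < active_fraction
      true <- stats::rnorm(n_compounds, dose$r_active, inactive_sd)
      n_act <- sum(active)
      if (n_act > 0) {
        ic50 <- potency_sampler(n_act)
        r_act <- mapply(function(i50) dose_to_contrast(
          concentration_nM, dose_model(ic50 = i50, hill = dose$hill,
                                       r_active = dose$r_active,
                                       r_inhibited = dose$r_inhibited)), ic50)
        true[active] <- r_act + stats::rnorm(n_act, 0, inactive_sd)
      }
    }
    true <- pmax(true, 0.05)

    make_rep <- function(rep_no) {
      obs <- pmax(true + stats::rnorm(n_compounds, 0, replicate_sd), 0.01)
      data.frame(compound_id = ids, replicate = rep_no,
                 concentration_nM = concentration_nM,
                 mean_ratio = obs,
                 normalized_ratio = obs / mean(obs),
                 rank = rank(-obs, ties.method = "average"),
                 stringsAsFactors = FALSE)
    }
    structure(list(replicates = list(make_rep(1L), make_rep(2L)),
                   truth = data.frame(compound_id = ids, true_ratio = true,
                                      active = active, stringsAsFactors = FALSE),
                   concentration_nM = concentration_nM),
              class = "sim_screen")
  })
}

#' @export
print.sim_screen <- function(x, ...) {
  cat(sprintf("Simulated screen: %d compounds x 2 replicates at %g nM\n",
              nrow(x$truth), x$concentration_nM))
  if (!all(is.na(x$truth$active)))
    cat(sprintf("  true actives: %d\n", sum(x$truth$active, na.rm = TRUE)))
  invisible(x)
}
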