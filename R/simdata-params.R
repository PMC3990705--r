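#' Dose-response model for inhibitor-induced translocation block
#'
#' Forward model linking inhibitor concentration to the expected
#' nucleocytoplasmic reporter ratio of a well. At zero inhibitor the
#' pathway is fully activated and the reporter is cytoplasm-enriched
#' (ratio `r_active`); at saturating inhibitor the reporter is retained
#' in the nucleus (ratio `r_inhibited`). The transition follows a Hill
#' curve in concentration.
#'
#' Defaults anchor the two phenotypes to the assay's reference wells:
#' DMSO-treated activated cells at a well-mean ratio of 0.65 and
#' saturating Skepinone-L treatment at 1.19.
#'
#' @param ic50 Half-maximal inhibitory concentration in nM. Must be > 0.
#' @param hill Hill slope (dimensionless, > 0).
#' @param r_active Nucleocytoplasmic ratio of the fully activated
#'   (uninhibited) state.
#' @param r_inhibited Nucleocytoplasmic ratio at full inhibition. Must
#'   exceed `r_active`.
#' @return An object of class `dose_model`.
#' @seealso [dose_to_contrast()]
#' @export
#' @examples
#' m <- dose_model(ic50 = 200, hill = 1)
#' dose_to_contrast(c(0, 200, 2e4), m)
dose_model <- function(ic50 = 200, hill = 1, r_active = 0.65, r_inhibited = 1.19) {
  stopifnot(ic50 > 0, hill > 0, r_active > 0, r_inhibited > r_active)
  structure(list(ic50 = ic50, hill = hill,
                 r_active = r_active, r_inhibited = r_inhibited),
            class = "dose_model")
}

#' @export
print.dose_model <- function(x, ...) {
  cat(sprintf("Dose model: IC50 %.4g nM, Hill %.3g, ratio %.3g (active) -> %.3g (inhibited)\n",
              x$ic50, x$hill, x$r_active, x$r_inhibited))
  invisible(x)
}

#' Expected nucleocytoplasmic ratio at a given inhibitor concentration
#'
#' Evaluates the Hill dose-response:
#' `r_active + (r_inhibited - r_active) * conc^h / (conc^h + ic50^h)`.
#' Monotone non-decreasing in concentration; equals `r_active` at zero
#' concentration and the midpoint `(r_active + r_inhibited)/2` at
#' `conc == ic50` for any Hill slope.
#'
#' @param conc Concentration(s) in nM; non-negative, vectorized.
#' @param model A [dose_model()].
#' @return Numeric vector of expected ratios, same length as `conc`.
#' @export
dose_to_contrast <- function(conc, model) {
  stopifnot(inherits(model, "dose_model"), is.numeric(conc))
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("`conc` must be finite and non-negative")
  h <- model$hill
  frac <- ifelse(conc == 0, 0, conc^h / (conc^h + model$ic50^h))
  model$r_active + (model$r_inhibited - model$r_active) * frac
}

#' Cell and field geometry for the plate simulator
#'
#' Describes the simulated monolayer: nuclei are ellipses with semi-axes
#' drawn uniformly from `nucleus_semi_axes`, each surrounded by a
#' cytoplasm extending `cytoplasm_extent` beyond the nuclear boundary.
#' `cell_density` controls how many cells are seeded per imaged field
#' and emulates a near-confluent adherent monolayer.
#'
#' Default nuclear semi-axes (4.5-7 um) keep simulated nuclear areas
#' (pi*a*b, about 64-154 um^2) inside the default segmentation area
#' window of 60-355 um^2, and are consistent with a characteristic
#' object width around 13 um.
#'
#' @param nucleus_semi_axes Length-2 range (um) from which both nuclear
#'   semi-axes are drawn.
#' @param cytoplasm_extent Cytoplasm reach beyond the nuclear boundary (um).
#' @param cell_density Cells per mm^2 of field area.
#' @param pixel_size Physical pixel size in um/pixel (default 0.65,
#'   typical for a 20x widefield high-content camera).
#' @return An object of class `cell_geometry`.
#' @export
cell_geometry <- function(nucleus_semi_axes = c(4.5, 7), cytoplasm_extent = 5,
                          cell_density = 1500, pixel_size = 0.65) {
  stopifnot(length(nucleus_semi_axes) == 2L, all(nucleus_semi_axes > 0),
            diff(nucleus_semi_axes) >= 0,
            cytoplasm_extent > 0, cell_density > 0, pixel_size > 0)
  areas <- pi * nucleus_semi_axes^2
  if (areas[1] < 60 || areas[2] > 355)
    warning("nuclear area range [", round(areas[1], 1), ", ", round(areas[2], 1),
            "] um^2 extends outside the default 60-355 um^2 segmentation window")
  structure(list(nucleus_semi_axes = as.numeric(nucleus_semi_axes),
                 cytoplasm_extent = cytoplasm_extent,
                 cell_density = cell_density,
                 pixel_size = pixel_size),
            class = "cell_geometry")
}

#' Camera and assay noise model for the simulator
#'
#' @param background_level Constant camera background offset in
#'   gray-levels (default 600, just below the default segmentation
#'   threshold offset of 656 gray-levels above background).
#' @param background_sd Gaussian read-noise standard deviation in
#'   gray-levels (default 30).
#' @param signal_gain Gray-levels of cytoplasmic reporter signal per unit
#'   expression (default 1000).
#' @param dapi_level Mean nuclear DNA-stain signal in gray-levels
#'   (default 5000, well above threshold for segmentation).
#' @param shot_noise Apply Poisson shot noise to the signal before read
#'   noise? Default off.
#' @param well_to_well_sd Standard deviation of the additive well-level
#'   perturbation of the expected nucleocytoplasmic ratio (ratio units).
#' @param expr_sdlog Log-sd of per-cell lognormal reporter expression
#'   variability (dimensionless).
#' @param cell_contrast_sdlog Log-sd of per-cell lognormal variability of
#'   the translocation contrast around the well mean.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(background_level = 600, background_sd = 30,
                        signal_gain = 1000, dapi_level = 5000,
                        shot_noise = FALSE, well_to_well_sd = 0.03,
                        expr_sdlog = 0.2, cell_contrast_sdlog = 0.1) {
  stopifnot(background_level >= 0, background_level <= 65535,
            background_sd >= 0, signal_gain > 0, dapi_level > 0,
            is.logical(shot_noise), well_to_well_sd >= 0,
            expr_sdlog >= 0, cell_contrast_sdlog >= 0)
  structure(list(background_level = background_level,
                 background_sd = background_sd,
                 signal_gain = signal_gain,
                 dapi_level = dapi_level,
                 shot_noise = shot_noise,
                 well_to_well_sd = well_to_well_sd,
                 expr_sdlog = expr_sdlog,
                 cell_contrast_sdlog = cell_contrast_sdlog),
            class = "noise_model")
}

# Map a numeric contrast to the phenotype label used in truth tables.
contrast_state <- function(contrast, activation_threshold = 0.7) {
  ifelse(contrast < activation_threshold, "activated",
         ifelse(contrast > 1.0, "inhibited", "intermediate"))
}
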