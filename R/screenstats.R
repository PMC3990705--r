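#' Internal plate normalization
#'
#' Divides each valid well's mean ratio by the plate mean (the average
#' of the well means over all valid, non-empty wells), so normalized
#' ratios average exactly 1 across the wells used. Normalization is
#' idempotent: normalizing an already-normalized plate is the identity.
#'
#' @param wells Data frame with at least `mean_ratio`; optional `valid`
#'   (logical) and `role` columns restrict the wells entering the plate
#'   mean (invalid and `"empty"` wells are excluded).
#' @return An object of class `plate_result`: the input with a
#'   `normalized_ratio` column, plus `plate_mean` and the `used` flag as
#'   attributes-in-columns.
#' @export
normalize_plate <- function(wells) {
  stopifnot(is.data.frame(wells), "mean_ratio" %in% names(wells))
  used <- is.finite(wells$mean_ratio)
  if ("valid" %in% names(wells)) used <- used & wells$valid %in% TRUE
  if ("role" %in% names(wells)) used <- used & wells$role != "empty"
  if (sum(used) < 2) stop("plate normalization needs at least 2 valid wells")
  plate_mean <- mean(wells$mean_ratio[used])
  if (!is.finite(plate_mean) || plate_mean == 0)
    stop("plate mean is zero or undefined; cannot normalize")
  out <- wells
  out$used <- used
  out$normalized_ratio <- out$mean_ratio / plate_mean
  structure(list(wells = out, plate_mean = plate_mean),
            class = "plate_result")
}

#' @export
print.plate_result <- function(x, ...) {
  cat(sprintf("Plate result: %d wells (%d used), plate mean %.4f\n",
              nrow(x$wells), sum(x$wells$used), x$plate_mean))
  invisible(x)
}

#' Z-prime assay quality factor
#'
#' `Z' = 1 - 3 * (sd_pos + sd_neg) / |mean_pos - mean_neg|`, computed
#' with sample standard deviations over the control wells. Z' is at
#' most 1; values above 0.5 indicate a robust screening window. When
#' the control means coincide the separation band is undefined and a
#' failure sentinel (`NA` with a warning) is returned.
#'
#' @param pos_wells Numeric vector of positive-control well ratios
#'   (>= 2 values).
#' @param neg_wells Numeric vector of negative-control well ratios
#'   (>= 2 values).
#' @return A single numeric Z' value, or `NA` (with warning) when the
#'   group means are equal.
#' @export
#' @examples
#' zprime(rnorm(8, 1.19, 0.03), rnorm(8, 0.65, 0.03))
zprime <- function(pos_wells, neg_wells) {
  stopifnot(is.numeric(pos_wells), is.numeric(neg_wells),
            length(pos_wells) >= 2, length(neg_wells) >= 2,
            all(is.finite(pos_wells)), all(is.finite(neg_wells)))
  sep <- abs(mean(pos_wells) - mean(neg_wells))
  if (sep == 0) {
    warning("positive and negative control means are equal; Z' undefined")
    return(NA_real_)
  }
  1 - 3 * (stats::sd(pos_wells) + stats::sd(neg_wells)) / sep
}

#' Log-Z-scores against negative controls
#'
#' Scores each well's normalized nucleocytoplasmic ratio on the log
#' scale relative to the negative-control distribution:
#' `(log(ratio) - mean(log(neg))) / sd(log(neg))`.
#'
#' @param normalized_ratios Positive ratios to score.
#' @param neg_wells Positive negative-control ratios (>= 2 values).
#' @return Numeric vector of scores, one per input ratio.
#' @export
log_z_score <- function(normalized_ratios, neg_wells) {
  stopifnot(is.numeric(normalized_ratios), is.numeric(neg_wells),
            length(neg_wells) >= 2)
  if (any(normalized_ratios <= 0) || any(neg_wells <= 0))
    stop("log-Z-scores require strictly positive ratios")
  ln <- log(neg_wells)
  s <- stats::sd(ln)
  if (s == 0) stop("negative-control wells have zero variance on the log scale")
  (log(normalized_ratios) - mean(ln)) / s
}

#' Rank-rank concordance of two screen replicates
#'
#' Squared Pearson correlation of the within-replicate ranks of the two
#' biological replicates (ties mid-ranked), the usual reproducibility
#' summary of a primary screen run in duplicate. Invariant under any
#' strictly monotone transform of either replicate's values; sign-blind
#' (exactly reversed rankings also give R-squared 1).
#'
#' @param rep1,rep2 Screen tables (data frames with `compound_id` and a
#'   value column) or plain numeric vectors in matching compound order.
#' @param value Column holding the replicate value (default
#'   `"mean_ratio"`).
#' @return Squared correlation of ranks (scalar in `[0, 1]`).
#' @export
rank_rank_r2 <- function(rep1, rep2, value = "mean_ratio") {
  if (is.data.frame(rep1)) {
    stopifnot(is.data.frame(rep2),
              all(c("compound_id", value) %in% names(rep1)),
              all(c("compound_id", value) %in% names(rep2)))
    m <- merge(rep1[c("compound_id", value)], rep2[c("compound_id", value)],
               by = "compound_id", suffixes = c(".1", ".2"))
    if (!setequal(rep1$compound_id, rep2$compound_id))
      stop("replicates must cover the same compound set")
    x <- m[[paste0(value, ".1")]]
    y <- m[[paste0(value, ".2")]]
  } else {
    stopifnot(is.numeric(rep1), is.numeric(rep2),
              length(rep1) == length(rep2))
    x <- rep1; y <- rep2
  }
  if (length(x) < 3) stop("rank-rank comparison needs at least 3 compounds")
  stats::cor(rank(x, ties.method = "average"),
             rank(y, ties.method = "average"))^2
}

#' Call primary-screen hits
#'
#' Averages each compound's (normalized) ratio over the two replicates
#' and selects compounds whose replicate-mean ratio lies strictly above
#' the threshold (default 1: the reporter is at least as
#' nucleus-enriched as the plate average, indicating pathway
#' inhibition). Compounds missing from either replicate are excluded.
#'
#' @param rep1,rep2 Screen tables (data frames with `compound_id` and
#'   the `value` column).
#' @param threshold Hit threshold (strict `>`; default 1.0).
#' @param value Value column; default `"normalized_ratio"` (plate- or
#'   screen-normalized), `"mean_ratio"` gives raw-ratio calling.
#' @return Data frame of class `hit_list`, ordered by descending
#'   replicate-mean ratio: `compound_id`, `mean_value`.
#' @export
call_primary_hits <- function(rep1, rep2, threshold = 1.0,
                              value = "normalized_ratio") {
  stopifnot(is.data.frame(rep1), is.data.frame(rep2),
            all(c("compound_id", value) %in% names(rep1)),
            all(c("compound_id", value) %in% names(rep2)))
  m <- merge(rep1[c("compound_id", value)], rep2[c("compound_id", value)],
             by = "compound_id", suffixes = c(".1", ".2"))
  mv <- (m[[paste0(value, ".1")]] + m[[paste0(value, ".2")]]) / 2
  hits <- data.frame(compound_id = m$compound_id, mean_value = mv,
                     stringsAsFactors = FALSE)
  hits <- hits[hits$mean_value > threshold, , drop = FALSE]
  hits <- hits[order(-hits$mean_value), , drop = FALSE]
  rownames(hits) <- NULL
  class(hits) <- c("hit_list", "data.frame")
  attr(hits, "threshold") <- threshold
  hits
}

#' Normalize compound ratios to a benchmark inhibitor
#'
#' Expresses each compound's nucleocytoplasmic ratio relative to a
#' benchmark inhibitor measured under the same condition, so the
#' benchmark is 1 by construction. With a data frame input the
#' benchmark is matched per concentration; concentrations where the
#' benchmark is missing are skipped with a warning.
#'
#' @param ratios Numeric vector of ratios, or a data frame with
#'   `compound_id`, `concentration_nM` and the `value` column.
#' @param benchmark For vector input, the benchmark ratio (> 0). For
#'   data frame input, the benchmark `compound_id`.
#' @param value Value column for data frame input.
#' @return Same shape as `ratios`, with values divided by the matching
#'   benchmark ratio (`benchmark_normalized` column for data frames;
#'   `NA` at skipped concentrations).
#' @export
#' @examples
#' benchmark_normalize(1.288, 1.1851)  # compound vs reference inhibitor
benchmark_normalize <- function(ratios, benchmark, value = "mean_ratio") {
  if (is.numeric(ratios)) {
    stopifnot(is.numeric(benchmark), length(benchmark) == 1L, benchmark > 0)
    return(ratios / benchmark)
  }
  stopifnot(is.data.frame(ratios),
            all(c("compound_id", "concentration_nM", value) %in% names(ratios)))
  out <- ratios
  out$benchmark_normalized <- NA_real_
  for (conc in unique(ratios$concentration_nM)) {
    at <- ratios$concentration_nM == conc
    bench <- ratios[[value]][at & ratios$compound_id == benchmark]
    if (length(bench) == 0L || !is.finite(mean(bench)) || mean(bench) <= 0) {
      warning("no benchmark value at concentration ", conc, " nM; skipped")
      next
    }
    out$benchmark_normalized[at] <- ratios[[value]][at] / mean(bench)
  }
  out
}

#' Multi-concentration hit-validation cascade
#'
#' Re-tests primary hits at a descending concentration series (default
#' roles: 1500, 150, 15 nM) in duplicate. At each concentration a hit
#' passes when its replicate-mean (normalized) ratio lies strictly
#' above `pass_threshold` (default 0.95, against an activated baseline
#' of about 0.65). The validation rate is the passing fraction at the
#' highest concentration; the final shortlist contains the compounds
#' passing at the highest concentration, ranked by their ratio at the
#' lowest concentration (most potent first).
#'
#' Hits absent from a concentration's tables (either replicate) are
#' flagged and excluded from that concentration's denominator.
#'
#' @param primary_hits Character vector of hit compound ids (or a
#'   [call_primary_hits()] result).
#' @param tables Named list, one element per concentration (names are
#'   concentrations in nM), each a list of two replicate data frames
#'   with `compound_id` and the `value` column.
#' @param pass_threshold Pass threshold on the replicate-mean ratio.
#' @param value Value column (default `"normalized_ratio"`).
#' @return An object of class `cascade_result`: `per_concentration`
#'   (tested/passing ids and counts per concentration),
#'   `validation_rate`, `shortlist` (data frame with the low-
#'   concentration ranking), `pass_threshold`.
#' @export
run_validation_cascade <- function(primary_hits, tables, pass_threshold = 0.95,
                                   value = "normalized_ratio") {
  if (is.data.frame(primary_hits)) primary_hits <- primary_hits$compound_id
  stopifnot(is.character(primary_hits), length(primary_hits) >= 1,
            is.list(tables), length(tables) >= 1, !is.null(names(tables)),
            pass_threshold > 0)
  concs <- as.numeric(names(tables))
  if (any(is.na(concs))) stop("`tables` must be named by concentration (nM)")
  ord <- order(-concs)
  tables <- tables[ord]; concs <- concs[ord]

  per <- list()
  mean_by_conc <- list()
  for (i in seq_along(tables)) {
    reps <- tables[[i]]
    stopifnot(is.list(reps), length(reps) == 2)
    m <- merge(reps[[1]][c("compound_id", value)],
               reps[[2]][c("compound_id", value)],
               by = "compound_id", suffixes = c(".1", ".2"))
    m$mean_value <- (m[[paste0(value, ".1")]] + m[[paste0(value, ".2")]]) / 2
    tested <- intersect(primary_hits, m$compound_id)
    missing <- setdiff(primary_hits, tested)
    if (length(missing))
      warning(length(missing), " hit(s) absent from the ", concs[i],
              " nM tables; excluded from that denominator")
    mm <- m[m$compound_id %in% tested, c("compound_id", "mean_value")]
    passing <- mm$compound_id[mm$mean_value > pass_threshold]
    per[[as.character(concs[i])]] <- list(
      concentration_nM = concs[i], tested = tested, passing = passing,
      n_tested = length(tested), n_passing = length(passing),
      missing = missing)
    mean_by_conc[[as.character(concs[i])]] <- mm
  }

  top <- per[[1]]
  validation_rate <- if (top$n_tested > 0) top$n_passing / top$n_tested else NA_real_

  lowest <- mean_by_conc[[length(mean_by_conc)]]
  short_ids <- top$passing
  low_val <- lowest$mean_value[match(short_ids, lowest$compound_id)]
  shortlist <- data.frame(compound_id = short_ids,
                          ratio_at_lowest = low_val,
                          stringsAsFactors = FALSE)
  shortlist <- shortlist[order(-shortlist$ratio_at_lowest, na.last = TRUE), ,
                         drop = FALSE]
  rownames(shortlist) <- NULL

  structure(list(per_concentration = per,
                 validation_rate = validation_rate,
                 shortlist = shortlist,
                 pass_threshold = pass_threshold),
            class = "cascade_result")
}

#' @export
print.cascade_result <- function(x, ...) {
  cat("Validation cascade (pass threshold", x$pass_threshold, "):\n")
  for (p in x$per_concentration)
    cat(sprintf("  %8g nM: %d/%d passing\n",
                p$concentration_nM, p$n_passing, p$n_tested))
  cat(sprintf("  validation rate (highest conc.): %.3f\n", x$validation_rate))
  cat(sprintf("  shortlist: %d compound(s)\n", nrow(x$shortlist)))
  invisible(x)
}
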