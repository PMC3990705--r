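test_that("plate normalization divides by the plate mean and closes to 1", {
  w <- data.frame(mean_ratio = c(0.6, 0.8, 1.0))
  pr <- normalize_plate(w)
  expect_equal(pr$wells$normalized_ratio, c(0.75, 1.0, 1.25))
  expect_equal(mean(pr$wells$normalized_ratio[pr$wells$used]), 1, tolerance = 1e-9)
  # all equal wells normalize to exactly 1
  pr2 <- normalize_plate(data.frame(mean_ratio = rep(0.73, 8)))
  expect_equal(pr2$wells$normalized_ratio, rep(1, 8))
  # invalid wells are excluded from the plate mean
  w3 <- data.frame(mean_ratio = c(0.6, 0.8, 1.0, 99), valid = c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(normalize_plate(w3)$plate_mean, 0.8)
})

test_that("plate normalization is idempotent", {
  set.seed(2)
  w <- data.frame(mean_ratio = runif(24, 0.5, 1.4))
  once <- normalize_plate(w)
  twice <- normalize_plate(data.frame(mean_ratio = once$wells$normalized_ratio))
  expect_equal(twice$wells$normalized_ratio, once$wells$normalized_ratio,
               tolerance = 1e-12)
  expect_equal(twice$plate_mean, 1, tolerance = 1e-12)
})

test_that("Z-prime matches direct evaluation and its degenerate limits", {
  # sd(c(-1, 0, 1)) == 1, so these vectors hit the target moments exactly
  pos <- 1.20 + 0.05 * c(-1, 0, 1)
  neg <- 0.65 + 0.03 * c(-1, 0, 1)
  expect_equal(zprime(pos, neg), 1 - 3 * (0.05 + 0.03) / 0.55, tolerance = 1e-12)
  expect_equal(zprime(pos, neg), 0.5636364, tolerance = 1e-6)
  # zero-variance limit
  expect_equal(zprime(c(1.2, 1.2), c(0.65, 0.65)), 1)
  # equal means: failure sentinel with message
  expect_warning(z <- zprime(c(1, 1.2), c(1, 1.2)), "undefined")
  expect_true(is.na(z))
})

test_that("Z-prime is invariant under shift and positive scaling", {
  set.seed(3)
  pos <- rnorm(8, 1.19, 0.04); neg <- rnorm(8, 0.65, 0.03)
  z <- zprime(pos, neg)
  for (a in c(-2, 0.4)) expect_equal(zprime(pos + a, neg + a), z, tolerance = 1e-12)
  for (g in c(0.2, 7)) expect_equal(zprime(pos * g, neg * g), z, tolerance = 1e-12)
})

test_that("log-Z-scores are zero at the geometric mean and unit at one log-sd", {
  set.seed(4)
  neg <- rlnorm(12, log(1), 0.06)
  gm <- exp(mean(log(neg)))
  s <- sd(log(neg))
  expect_equal(log_z_score(gm, neg), 0)
  expect_equal(log_z_score(gm * exp(s), neg), 1)
  expect_error(log_z_score(c(1, -1), neg), "positive")
  expect_error(log_z_score(1, rep(2, 5)), "zero variance")
  # empirical score sd ~ 1 for draws from the negative-control distribution
  scores <- log_z_score(rlnorm(4000, log(1), 0.06), neg)
  expect_lt(abs(sd(scores) - 1), 0.15)
})

test_that("rank-rank R2 matches hand-computed values and is monotone-invariant", {
  expect_equal(rank_rank_r2(c(1, 2, 3, 4), c(2, 1, 3, 4)), 0.64, tolerance = 1e-12)
  set.seed(5)
  x <- runif(50); y <- x + rnorm(50, 0, 0.1)
  expect_equal(rank_rank_r2(x, x), 1)
  expect_equal(rank_rank_r2(x, -x), 1)  # reversed ranks: R2 is sign-blind
  base <- rank_rank_r2(x, y)
  expect_equal(rank_rank_r2(exp(5 * x), y), base, tolerance = 1e-12)
  expect_equal(rank_rank_r2(x, y^3 + 10), base, tolerance = 1e-12)
  expect_error(rank_rank_r2(c(1, 2), c(2, 1)), "at least 3")
})

test_that("hit calling selects strictly-above-threshold compounds, sorted", {
  rep1 <- data.frame(compound_id = c("A", "B", "C", "D"),
                     normalized_ratio = c(0.65, 1.02, 0.99, 1.30))
  hits <- call_primary_hits(rep1, rep1)
  expect_identical(hits$compound_id, c("D", "B"))
  none <- call_primary_hits(rep1, rep1, threshold = 2)
  expect_identical(nrow(none), 0L)
  # compound missing in one replicate is excluded
  rep2 <- rep1[rep1$compound_id != "D", ]
  expect_identical(call_primary_hits(rep1, rep2)$compound_id, "B")
})

test_that("hit recall on a simulated screen with known actives exceeds 95%", {
  n_inact <- 1700; n_act <- 300
  sc <- simulate_screen(n_inact + n_act, replicate_sd = 0.05, seed = 13,
                        ratio_sampler = function(n)
                          c(rep(0.65, n_inact), runif(n_act, 1.1, 1.4)))
  hits <- call_primary_hits(sc$replicates[[1]], sc$replicates[[2]],
                            threshold = 1.0, value = "mean_ratio")
  active_ids <- sc$truth$compound_id[(n_inact + 1):(n_inact + n_act)]
  recall <- mean(active_ids %in% hits$compound_id)
  expect_gte(recall, 0.95)
})

test_that("benchmark normalization reproduces the reference quotient and cancels scale", {
  expect_equal(benchmark_normalize(1.1851, 1.1851), 1)
  expect_equal(benchmark_normalize(1.288, 1.1851), 1.0868, tolerance = 1e-4)
  x <- c(0.9, 1.1, 1.3)
  expect_equal(benchmark_normalize(x * 3, 1.2 * 3), benchmark_normalize(x, 1.2))
  # data-frame mode: per-concentration benchmark, missing one skipped
  tab <- data.frame(compound_id = rep(c("SKL", "X"), 2),
                    concentration_nM = c(1500, 1500, 150, 150),
                    mean_ratio = c(1.2, 1.32, NA, 1.1))
  tab2 <- tab[!(tab$compound_id == "SKL" & tab$concentration_nM == 150), ]
  expect_warning(out <- benchmark_normalize(tab2, "SKL"), "skipped")
  expect_equal(out$benchmark_normalized[out$concentration_nM == 1500],
               c(1, 1.1))
  expect_true(all(is.na(out$benchmark_normalized[out$concentration_nM == 150])))
})

test_that("validation cascade follows the hand-walked toy example", {
  ids <- c("A", "B", "C")
  mk <- function(v) lapply(1:2, function(r)
    data.frame(compound_id = ids, normalized_ratio = v))
  tabs <- list("1500" = mk(c(1.2, 1.0, 0.9)),
               "150" = mk(c(1.1, 0.97, 0.8)),
               "15" = mk(c(0.9, 1.3, 0.7)))
  cr <- run_validation_cascade(ids, tabs, pass_threshold = 0.95)
  expect_equal(cr$validation_rate, 2 / 3)
  expect_setequal(cr$per_concentration[["1500"]]$passing, c("A", "B"))
  # shortlist: passing at highest conc, ordered by the 15 nM column
  expect_identical(cr$shortlist$compound_id, c("B", "A"))
  # all pass / none pass boundaries
  all_hi <- list("1500" = mk(rep(1.2, 3)), "150" = mk(rep(1.2, 3)),
                 "15" = mk(rep(1.2, 3)))
  expect_equal(run_validation_cascade(ids, all_hi)$validation_rate, 1)
  all_lo <- list("1500" = mk(rep(0.8, 3)))
  cr_lo <- run_validation_cascade(ids, all_lo)
  expect_equal(cr_lo$validation_rate, 0)
  expect_identical(nrow(cr_lo$shortlist), 0L)
  # hit absent from a table is flagged and excluded from the denominator
  tabs_miss <- list("1500" = mk(c(1.2, 1.0, 0.9)))
  expect_warning(cr_m <- run_validation_cascade(c(ids, "Z"), tabs_miss),
                 "absent")
  expect_equal(cr_m$per_concentration[["1500"]]$n_tested, 3L)
})

test_that("raising the pass threshold never grows the passing set", {
  set.seed(6)
  ids <- sprintf("H%02d", 1:30)
  mk <- function() lapply(1:2, function(r)
    data.frame(compound_id = ids, normalized_ratio = runif(30, 0.6, 1.4)))
  tabs <- list("1500" = mk(), "150" = mk(), "15" = mk())
  thresholds <- c(0.8, 0.95, 1.05, 1.2)
  passing <- lapply(thresholds, function(t)
    run_validation_cascade(ids, tabs, pass_threshold = t)$per_concentration[["1500"]]$passing)
  for (i in seq_len(length(thresholds) - 1))
    expect_true(all(passing[[i + 1]] %in% passing[[i]]))
})

test_that("cascade shortlist ordering tracks true potency on a noisy simulation", {
  set.seed(7)
  n <- 40
  ic50 <- rlnorm(n, log(50), 1.2)
  ids <- sprintf("H%03d", 1:n)
  mk <- function(conc) {
    true <- vapply(ic50, function(i)
      dose_to_contrast(conc, dose_model(ic50 = i)), numeric(1))
    lapply(1:2, function(r)
      data.frame(compound_id = ids,
                 normalized_ratio = true + rnorm(n, 0, 0.05)))
  }
  tabs <- list("1500" = mk(1500), "150" = mk(150), "15" = mk(15))
  cr <- run_validation_cascade(ids, tabs, pass_threshold = 0.95)
  sl <- cr$shortlist
  expect_gt(nrow(sl), 10)
  rho <- cor(-ic50[match(sl$compound_id, ids)], sl$ratio_at_lowest,
             method = "spearman")
  expect_gte(rho, 0.8)
})
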