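toy_space_1d <- function() new_search_space(list(hp_float("x", 0, 1)))
toy_space_2d <- function() {
  new_search_space(list(hp_float("x", 0, 1), hp_float("y", 0, 1)))
}

records_from <- function(xs, ys, fidelity = 1) {
  tibble::tibble(config = lapply(xs, function(x) list(x = x)),
                 fidelity = fidelity, objective = ys)
}

test_that("the surrogate needs at least two records", {
  expect_error(fit_surrogate(records_from(0.5, 0.5)[0, ], toy_space_1d()),
               class = "genarch_insufficient_data")
  expect_error(fit_surrogate(records_from(0.5, 0.5), toy_space_1d()),
               class = "genarch_insufficient_data")
})

test_that("the surrogate interpolates training points within its own uncertainty", {
  xs <- c(0.1, 0.4, 0.8)
  ys <- c(0.3, 0.9, 0.5)
  sur <- fit_surrogate(records_from(xs, ys), toy_space_1d())
  pr <- predict(sur, tibble::tibble(x = xs))
  expect_true(all(abs(pr$mean - ys) <= 2 * pr$sd + 1e-6))
})

test_that("constant objectives give a constant posterior mean", {
  xs <- seq(0.1, 0.9, length.out = 6)
  sur <- fit_surrogate(records_from(xs, rep(0.5, 6)), toy_space_1d())
  pr <- predict(sur, tibble::tibble(x = seq(0, 1, length.out = 50)))
  expect_lt(max(abs(pr$mean - 0.5)), 1e-6)
})

test_that("the surrogate recovers a smooth 1-D function, on par with an independent GP", {
  xs <- seq(0, 1, length.out = 20)
  truth <- function(x) sin(2 * pi * x)
  sur <- fit_surrogate(records_from(xs, truth(xs)), toy_space_1d())
  grid <- seq(0, 1, length.out = 101)
  pr <- predict(sur, tibble::tibble(x = grid))
  rmse <- sqrt(mean((pr$mean - truth(grid))^2))
  expect_lt(rmse, 0.05)

  # independent cross-check: kernlab's Gaussian process on the same data
  gp <- kernlab::gausspr(matrix(xs, ncol = 1), truth(xs),
                         kpar = list(sigma = 10), scaled = FALSE, var = 0.002)
  rmse_ref <- sqrt(mean((kernlab::predict(gp, matrix(grid, ncol = 1)) - truth(grid))^2))
  expect_lt(rmse_ref, 0.05)
})

test_that("batch proposals are q-wide, distinct and deterministic under seed", {
  sp <- toy_space_2d()
  obj <- function(cfg, fidelity) 1 - (cfg$x - 0.5)^2 - (cfg$y - 0.5)^2
  st <- run_mbo(obj, sp, iterations = 0, init_design = 8, fidelity = 1, seed = 4)
  sur <- fit_surrogate(st$records, sp)
  p1 <- propose_batch(st, sur, q = 3, seed = 21)
  p2 <- propose_batch(st, sur, q = 3, seed = 21)
  expect_length(p1, 3)
  expect_identical(p1, p2)
  keys <- vapply(p1, function(cfg) paste(format(unlist(cfg), digits = 10),
                                         collapse = "|"), character(1))
  expect_equal(anyDuplicated(keys), 0L)
  for (cfg in p1) expect_length(validate_config(sp, cfg), 0)
})

test_that("proposals concentrate near a sharp optimum", {
  sp <- toy_space_1d()
  xs <- seq(0, 1, length.out = 30)
  ys <- exp(-(xs - 0.6)^2 / 0.005)
  sur <- fit_surrogate(records_from(xs, ys), sp)
  st <- genarch:::new_mbo_state(sp, records_from(xs, ys), 1)
  props <- propose_batch(st, sur, q = 5, seed = 2)
  dist <- vapply(props, function(cfg) abs(cfg$x - 0.6), numeric(1))
  expect_lt(min(dist), 0.05)
})

test_that("run_mbo bookkeeping: design size, failure handling, reproducibility", {
  sp <- toy_space_2d()
  obj <- function(cfg, fidelity) cfg$x
  st <- run_mbo(obj, sp, iterations = 0, init_design = 4, fidelity = 1, seed = 9)
  expect_equal(nrow(st$records), 4L)
  expect_true(all(st$records$origin == "init"))

  # failures score 0 and the run continues
  obj_fail <- function(cfg, fidelity) {
    if (cfg$x > 0.5) stop("boom") else cfg$x
  }
  st2 <- suppressMessages(
    run_mbo(obj_fail, sp, iterations = 1, q = 2, init_design = 6, fidelity = 1,
            seed = 10))
  expect_equal(nrow(st2$records), 8L)
  fails <- vapply(st2$records$config, function(cfg) cfg$x > 0.5, logical(1))
  expect_true(all(st2$records$objective[fails] == 0))

  # full history reproduces bit-for-bit at the decoded-config level
  a <- run_mbo(obj, sp, iterations = 2, q = 2, init_design = 4, fidelity = 1,
               seed = 11)
  b <- run_mbo(obj, sp, iterations = 2, q = 2, init_design = 4, fidelity = 1,
               seed = 11)
  expect_identical(a$records$config, b$records$config)
  expect_identical(a$records$objective, b$records$objective)
})

test_that("MBO finds monotone optima in the top quartile", {
  sp <- toy_space_2d()
  obj <- function(cfg, fidelity) cfg$x
  for (seed in 1:3) {
    st <- run_mbo(obj, sp, iterations = 5, q = 3, init_design = 6, fidelity = 1,
                  seed = seed)
    expect_gt(best_config(st)$config$x, 0.75)
  }
})

test_that("warm starts carry records forward and keep fidelities distinguishable", {
  sp <- toy_space_2d()
  obj <- function(cfg, fidelity) cfg$x * min(fidelity / 6, 1)
  st1 <- run_mbo(obj, sp, iterations = 1, q = 3, init_design = 6, fidelity = 2,
                 seed = 5)
  n1 <- nrow(st1$records)
  ws <- warm_start(st1, 6)
  expect_equal(nrow(ws$records), n1)
  expect_equal(ws$current_fidelity, 6)
  expect_error(warm_start(st1, 2), "exceed")
  expect_error(warm_start(st1, 1), "exceed")

  st2 <- run_mbo(obj, sp, iterations = 1, q = 3, fidelity = 6, seed = 6,
                 warm_records = ws)
  expect_equal(nrow(st2$records), n1 + 3L)
  expect_true(all(st2$records$fidelity[seq_len(n1)] == 2))

  # the surrogate encoding separates the two fidelities
  sur <- fit_surrogate(st2$records, sp)
  fid_coords <- sur$X[, ncol(sur$X)]
  expect_equal(sort(unique(fid_coords)), c(0, 1))
})

test_that("objective extraction follows the two-phase rules", {
  expect_equal(extract_objective(c(0.5, 0.7, 0.6), phase = 1), 0.7)
  # the outlier-robust phase-2 rule drops a single spike
  w <- c(rep(0.80, 19), 0.99)
  expect_equal(extract_objective(w, phase = 2), 0.80)
  long <- c(rep(0.95, 30), w)
  expect_equal(extract_objective(long, phase = 2), 0.80)
  expect_equal(extract_objective(0.42, phase = 2), 0.42)
  expect_equal(extract_objective(tibble::tibble(balanced_accuracy = c(0.2, 0.9)),
                                 phase = 1), 0.9)
  expect_error(extract_objective(numeric(0), phase = 1), "empty")

  # sort-based oracle over random traces
  withr::with_seed(31, {
    for (i in 1:50) {
      acc <- runif(sample(1:40, 1))
      w20 <- utils::tail(acc, 20)
      oracle <- if (length(w20) < 2) max(w20) else sort(w20, decreasing = TRUE)[2]
      expect_equal(extract_objective(acc, phase = 2), oracle)
      expect_equal(extract_objective(acc, phase = 1), max(acc))
    }
  })
})

test_that("tidy/glance/autoplot summarise optimization states", {
  sp <- toy_space_2d()
  st <- run_mbo(function(cfg, f) cfg$x, sp, iterations = 1, q = 2,
                init_design = 4, fidelity = 1, seed = 12)
  td <- tidy(st)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 6L)
  expect_true(all(c("x", "y", "objective", "fidelity", "origin") %in% names(td)))
  gl <- glance(st)
  expect_equal(gl$n_evaluations, 6L)
  expect_equal(gl$best_objective, max(st$records$objective))
  expect_s3_class(autoplot(st), "ggplot")
})
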