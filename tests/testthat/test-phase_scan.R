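# synthetic sweep tables let the estimators be tested against closed forms
logistic_sweep <- function(Tc, T_grid, lo = 2, hi = 10, width = 0.4) {
  data.frame(T = T_grid,
             mean_Rg = lo + (hi - lo) / (1 + exp(-(log(T_grid) - log(Tc)) / width)))
}

test_that("the steepest-slope estimator localizes a logistic transition", {
  grid <- 10^seq(-2, 2, length.out = 25)
  est <- estimate_transition_temperature(logistic_sweep(2.0, grid), "Rg")
  spacing <- log(grid[2]) - log(grid[1])
  expect_lt(abs(log(est$Tc) - log(2.0)), spacing)
  expect_identical(est$method, "max_dRg_dlnT")
})

test_that("a flat curve yields the no-transition sentinel, not an error", {
  grid <- 10^seq(-2, 2, length.out = 15)
  flat <- data.frame(T = grid, mean_Rg = rep(5, 15))
  expect_true(is.na(estimate_transition_temperature(flat, "Rg")$Tc))
  flat_h <- data.frame(T = grid, mean_H = rep(0.02, 15))
  expect_true(is.na(estimate_transition_temperature(flat_h, "H")$Tc))
})

test_that("direction filtering separates the two branches of a reentrant curve", {
  grid <- 10^seq(-3, 2, length.out = 40)
  # helix (high Rg) -> globule (low) -> coil (high): falls at 0.05, rises at 1.25
  rg <- 9 - 6 / (1 + exp(-(log(grid) - log(0.05)) / 0.3)) +
        8 / (1 + exp(-(log(grid) - log(1.25)) / 0.3))
  sw <- data.frame(T = grid, mean_Rg = rg)
  up <- estimate_transition_temperature(sw, "Rg", direction = "increasing")
  down <- estimate_transition_temperature(sw, "Rg", direction = "decreasing")
  expect_equal(log(up$Tc), log(1.25), tolerance = 0.15)
  expect_equal(log(down$Tc), log(0.05), tolerance = 0.15)
})

test_that("the H = 0.5 crossing is interpolated on the log-T axis", {
  grid <- 10^seq(-3, 0, length.out = 20)
  h <- 1 / (1 + (grid / 0.05)^2)
  est <- estimate_transition_temperature(data.frame(T = grid, mean_H = h), "H")
  expect_equal(est$Tc, 0.05, tolerance = 0.05)
  expect_identical(est$method, "H_half_crossing")
})

test_that("the coarse-grid estimator agrees with a brute-force fine-grid argmax", {
  for (Tc in c(0.03, 0.7, 9)) {
    coarse <- 10^seq(-3, 2, length.out = 21)
    fine <- 10^seq(-3, 2, length.out = 201)
    est <- estimate_transition_temperature(logistic_sweep(Tc, coarse), "Rg")
    # independent brute force on the 10x finer synthetic grid
    y <- logistic_sweep(Tc, fine)$mean_Rg
    sl <- abs(diff(y) / diff(log(fine)))
    brute <- exp((log(fine)[which.max(sl)] + log(fine)[which.max(sl) + 1]) / 2)
    spacing <- log(coarse[2]) - log(coarse[1])
    expect_lt(abs(log(est$Tc) - log(brute)), spacing)
  }
})

test_that("fit_lambda is exact on proportional data and robust to mild noise", {
  eps <- c(0.5, 1, 2, 5)
  f <- fit_lambda(eps, 1.25 * eps)
  expect_equal(f$lambda, 1.25)
  expect_equal(f$residual, 0)
  expect_equal(fit_lambda(eps, 0.05 * eps)$lambda, 0.05)
  expect_error(fit_lambda(c(1, 2), c(1, 2)), "3")
  set.seed(19)
  eps6 <- c(0.5, 1, 1.5, 2, 3, 5)
  for (rep in 1:5) {
    tc <- 0.8 * eps6 * (1 + rnorm(6, sd = 0.05))
    expect_equal(fit_lambda(eps6, tc)$lambda, 0.8, tolerance = 0.1)
  }
})

test_that("sweep tables carry one row per grid point and round-trip as CSV", {
  p <- fast_params(n_steps = 10, n_directions = 100, seed = 50)
  grid <- c(0.01, 1, 100)
  sw <- sweep_temperature(p, grid, n_runs = 3)
  expect_s3_class(sw, "sirw_sweep")
  expect_equal(nrow(sw), 3L)
  expect_equal(sw$T, grid)
  expect_true(all(sw$mean_H >= 0 & sw$mean_H <= 1))
  path <- tempfile(fileext = ".csv")
  write_sweep_csv(sw, path)
  back <- utils::read.csv(path)
  expect_equal(back$mean_Rg, sw$mean_Rg)
  expect_error(sweep_temperature(p, c(2, 1)), "increasing")
})

test_that("phase labels follow the helix-first, then compactness rule", {
  df <- data.frame(T = 10^seq(-2, 1, length.out = 6),
                   mean_Rg = c(5.5, 5.4, 2.0, 2.2, 5.8, 6.0),
                   mean_H = c(0.95, 0.9, 0.2, 0.05, 0.02, 0.01))
  lab <- sirw:::label_phases(df)
  expect_identical(lab, c("helix", "helix", "globule", "globule", "coil", "coil"))
})
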