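# independent R-side replay of the categorical sampler: recompute weights
# with step_weights() (plain-R energies) and consume the same RNG stream
replay_walk <- function(params, dirs) {
  set.seed(params$seed)
  pos <- matrix(0, params$n_steps + 1, 3)
  for (n in seq_len(params$n_steps)) {
    w <- step_weights(pos[n, ], pos[seq_len(n), , drop = FALSE], dirs, params)
    pick <- match(TRUE, cumsum(w) >= stats::runif(1))
    pos[n + 1, ] <- pos[n, ] + params$d0 * unclass(dirs)[pick, ]
  }
  pos
}

test_that("step_weights normalizes Boltzmann weights over the candidate set", {
  dirs <- direction_set(64)
  p <- fast_params(temperature = 0.8, r0 = 1.3)
  # walker at the origin with only the origin visited: all candidates
  # equidistant, so the distribution is exactly uniform
  w <- step_weights(c(0, 0, 0), c(0, 0, 0), dirs, p)
  expect_equal(w, rep(1 / 64, 64))
  expect_lt(abs(sum(w) - 1), 1e-12)
  # asymmetric history: weights match direct normalization of exp(-U/T)
  visited <- rbind(c(0, 0, 0), c(1, 0, 0), c(1.4, 0.9, 0))
  w <- step_weights(visited[3, ], visited, dirs, p)
  e <- apply(sweep(unclass(dirs), 2, visited[3, ], "+"), 1, total_energy,
             visited = visited, epsilon = p$epsilon, r0 = p$r0)
  expect_equal(w, exp(-(e - min(e)) / p$temperature) /
                  sum(exp(-(e - min(e)) / p$temperature)))
  expect_lt(abs(sum(w) - 1), 1e-12)
})

test_that("trajectories start at the origin with exact step lengths", {
  p <- fast_params(n_steps = 1, d0 = 0.5)
  tr <- simulate_walk(p)
  expect_equal(nrow(tr$positions), 2L)
  expect_equal(tr$positions[1, ], c(0, 0, 0))
  expect_equal(sqrt(sum(diff(tr$positions)^2)), 0.5)
  expect_equal(radius_of_gyration(tr), 0.25)

  p <- fast_params(n_steps = 40, temperature = 0.05, r0 = 1.52)
  tr <- simulate_walk(p)
  steps <- sqrt(rowSums((tr$positions[-1, ] - tr$positions[-41, ])^2))
  expect_lt(max(abs(steps - p$d0)), 1e-9)
})

test_that("identical seeds give bit-identical trajectories; seeds differ otherwise", {
  p <- fast_params(seed = 77, temperature = 0.3)
  expect_identical(simulate_walk(p)$positions, simulate_walk(p)$positions)
  p2 <- p; p2$seed <- 78L
  expect_false(identical(simulate_walk(p)$positions,
                         simulate_walk(p2)$positions))
})

test_that("recorded per-step energies match an independent recomputation", {
  p <- fast_params(n_steps = 15, temperature = 0.5, r0 = 1.52, seed = 9)
  tr <- simulate_walk(p)
  expect_identical(tr$energy[1], 0)
  for (n in 2:16)
    expect_equal(tr$energy[n],
                 total_energy(tr$positions[n, ],
                              tr$positions[seq_len(n - 1), , drop = FALSE],
                              p$epsilon, p$r0, p$rmin),
                 tolerance = 1e-9)
})

test_that("the categorical sampler matches a plain-R replay of the same RNG stream", {
  dirs <- direction_set(100)
  for (s in c(3, 14, 159)) {
    p <- fast_params(n_steps = 8, n_directions = 100, temperature = 1,
                     r0 = 1.3, seed = s)
    tr <- simulate_walk(p, dirs)
    expect_equal(tr$positions, replay_walk(p, dirs), tolerance = 1e-12)
  }
})

test_that("at very low temperature the walker picks the minimum-energy candidate", {
  dirs <- direction_set(150)
  p <- fast_params(n_steps = 6, n_directions = 150, temperature = 1e-7,
                   r0 = 1.4, seed = 21)
  tr <- simulate_walk(p, dirs)
  for (n in 2:7) {
    hist <- tr$positions[seq_len(n - 1), , drop = FALSE]
    cand <- sweep(unclass(dirs), 2, tr$positions[n - 1, ], "+")
    e <- apply(cand, 1, total_energy, visited = hist,
               epsilon = p$epsilon, r0 = p$r0)
    chosen <- total_energy(tr$positions[n, ], hist, p$epsilon, p$r0)
    # near-degenerate minima can tie at fp precision; require the chosen
    # candidate to sit at the minimum within fp noise
    expect_lt(chosen - min(e), 1e-9 * max(1, abs(min(e))))
  }
})

test_that("the infinite-temperature limit recovers ideal random-walk statistics", {
  # at T = 1e12 the Boltzmann weights are uniform over all candidates outside
  # the hard core, whose residual excluded volume is negligible
  dirs <- direction_set(500)
  p <- walk_params(temperature = 1e12, epsilon = 1, r0 = 1, n_steps = 50,
                   n_directions = 500, seed = 1)
  ree2 <- vapply(1:2000, function(i) {
    p$seed <- 5000L + i
    sum(simulate_walk(p, dirs)$positions[51, ]^2)
  }, numeric(1))
  expect_lt(abs(mean(ree2) - 50) / 50, 0.05)
})

test_that("a walker whose candidates all violate the hard core reports trapping", {
  p <- fast_params(rmin = 2.5, n_steps = 3)
  expect_error(simulate_walk(p), "trapped")
  expect_error(run_ensemble(p, n_runs = 4), "trapped")
})

test_that("the Metropolis rule is reproducible and keeps the step-length contract", {
  p <- fast_params(rule = "metropolis", temperature = 2, n_steps = 20,
                   seed = 5)
  tr <- simulate_walk(p)
  steps <- sqrt(rowSums(diff(tr$positions)^2))
  expect_lt(max(abs(steps - 1)), 1e-9)
  expect_identical(simulate_walk(p)$positions, tr$positions)
})
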