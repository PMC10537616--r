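#' Parameters of one self-interacting walk
#'
#' Bundles everything that defines a single simulation: the temperature
#' \code{temperature} (\eqn{k_B = 1}), the Lennard-Jones well depth
#' \code{epsilon} and equilibrium distance \code{r0}, the step length
#' \code{d0} (the distance unit; 1 by convention), the number of steps
#' \code{n_steps} (published setting: 50, i.e. 51 visited positions), the
#' candidate-direction count and construction, the step-selection rule, and
#' the RNG seed.
#'
#' The selection rule interprets the Boltzmann move probability
#' \eqn{P \propto e^{-\Delta U / k_B T}} either as categorical sampling over
#' the full candidate set (default; reads the move rule most literally) or as
#' a uniform proposal with Metropolis-style accept/reject against the step's
#' minimum candidate energy -- exact rejection sampling of the same
#' distribution, kept as a sensitivity switch. (A reference inside the
#' candidate set is required because every move adds the large bonded pair
#' term \eqn{u(d_0)}, which cancels in the categorical rule.)
#'
#' @param temperature temperature, > 0.
#' @param epsilon LJ well depth, > 0.
#' @param r0 LJ equilibrium distance in units of \code{d0}, > 0.
#' @param d0 step distance (distance unit).
#' @param n_steps number of moves (trajectory has \code{n_steps + 1} points).
#' @param n_directions number of candidate directions (published: 15,212;
#'   fast default 2000).
#' @param method direction-set construction, see [direction_set()].
#' @param rule step-selection rule.
#' @param seed RNG seed.
#' @param rmin hard-core cutoff; candidates closer than this to any previous
#'   visit are excluded (weight exactly 0).
#' @return an object of class \code{"sirw_params"}.
#' @export
walk_params <- function(temperature = 1, epsilon = 1, r0 = 1.5, d0 = 1,
                        n_steps = 50, n_directions = 2000,
                        method = c("fibonacci", "geodesic"),
                        rule = c("categorical", "metropolis"),
                        seed = 1L, rmin = 0.1 * r0) {
  method <- match.arg(method)
  rule <- match.arg(rule)
  if (temperature <= 0) stop("'temperature' must be > 0")
  if (d0 <= 0) stop("'d0' must be > 0")
  if (n_steps < 1) stop("'n_steps' must be >= 1")
  check_potential(epsilon, r0)
  structure(list(temperature = temperature, epsilon = epsilon, r0 = r0,
                 d0 = d0, n_steps = as.integer(n_steps),
                 n_directions = as.integer(n_directions), method = method,
                 rule = rule, seed = as.integer(seed), rmin = rmin),
            class = "sirw_params")
}

#' @export
print.sirw_params <- function(x, ...) {
  cat(sprintf(
    "SIRW parameters: T=%g, epsilon=%g, r0=%g, d0=%g, steps=%d, directions=%d (%s), rule=%s, seed=%d\n",
    x$temperature, x$epsilon, x$r0, x$d0, x$n_steps, x$n_directions,
    x$method, x$rule, x$seed))
  invisible(x)
}

#' Boltzmann selection probabilities over a candidate set
#'
#' For a walker at \code{current} with visit history \code{visited},
#' candidate positions are \code{current + d0 * direction}. The selection
#' probability of candidate \eqn{j} is proportional to
#' \eqn{e^{-U_j / k_B T}} where \eqn{U_j} is the candidate's total
#' interaction energy with the history; the energy of the current position is
#' identical for all candidates and cancels on normalization, so adding any
#' constant to all candidate energies leaves the result unchanged. Weights
#' are computed with a max-shift before exponentiation.
#'
#' @param current 3D point, walker's current position.
#' @param visited matrix of visited 3D points (must include at least the
#'   origin of the walk).
#' @param directions a [direction_set()] or any m x 3 matrix of unit vectors.
#' @param params a [walk_params()] object.
#' @return normalized probability vector of length \code{nrow(directions)}.
#' @export
step_weights <- function(current, visited, directions, params) {
  visited <- as_points(visited)
  if (nrow(visited) == 0L) stop("'visited' must be non-empty")
  dirs <- unclass(directions)
  cand <- sweep(dirs * params$d0, 2, as.numeric(current), "+")
  e <- vapply(seq_len(nrow(cand)), function(j)
    total_energy(cand[j, ], visited, params$epsilon, params$r0, params$rmin),
    numeric(1))
  finite <- is.finite(e)
  if (!any(finite))
    stop("trapped walker: all candidates inside the hard core")
  w <- numeric(length(e))
  w[finite] <- exp(-(e[finite] - min(e[finite])) / params$temperature)
  w / sum(w)
}

#' Simulate one self-interacting random walk
#'
#' Grows a trajectory of \code{n_steps + 1} positions starting from the
#' origin. At each step the walker evaluates its total Lennard-Jones
#' interaction energy with all previously visited positions at every
#' candidate position (current position plus \code{d0} times each direction)
#' and selects the move by the Boltzmann rule in \code{params$rule}.
#' Identical parameters (including seed) give bit-identical trajectories.
#'
#' @param params a [walk_params()] object.
#' @param directions optional precomputed [direction_set()] (must match
#'   \code{params$n_directions} and \code{params$method}); generated on the
#'   fly when omitted. Passing it explicitly avoids regenerating the set when
#'   simulating many trajectories.
#' @return an object of class \code{"sirw_trajectory"}: list with
#'   \code{positions} (\code{(n_steps+1) x 3} matrix, first row the origin),
#'   \code{energy} (arrival energy \eqn{U_n} per position; 0 for the origin)
#'   and \code{params}.
#' @examples
#' p <- walk_params(temperature = 0.01, r0 = 1.52, n_steps = 50,
#'                  n_directions = 500, seed = 42)
#' tr <- simulate_walk(p)
#' radius_of_gyration(tr)
#' @export
simulate_walk <- function(params, directions = NULL) {
  stopifnot(inherits(params, "sirw_params"))
  if (is.null(directions))
    directions <- direction_set(params$n_directions, params$method)
  dirs <- unclass(directions)
  if (nrow(dirs) != params$n_directions)
    stop("direction set size does not match params$n_directions")
  set.seed(params$seed)
  res <- sirw_walk_cpp(dirs, params$n_steps, params$temperature,
                       params$epsilon, params$r0, params$d0, params$rmin,
                       if (params$rule == "categorical") 0L else 1L,
                       100000L)
  structure(list(positions = res$positions, energy = as.numeric(res$energy),
                 params = params),
            class = "sirw_trajectory")
}

#' @export
print.sirw_trajectory <- function(x, ...) {
  n <- nrow(x$positions)
  cat(sprintf("SIRW trajectory: %d positions (T=%g, epsilon=%g, r0=%g, seed=%d)\n",
              n, x$params$temperature, x$params$epsilon, x$params$r0,
              x$params$seed))
  cat(sprintf("  Rg = %.4f, final U = %.4f\n",
              radius_of_gyration(x$positions), x$energy[n]))
  invisible(x)
}
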