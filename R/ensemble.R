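#' Ensemble of independent walks at one parameter set
#'
#' Runs \code{n_runs} independent trajectories with seeds
#' \code{base_seed, base_seed + 1, ..., base_seed + n_runs - 1} and averages
#' the order parameters over runs. The seed sequence makes any single run
#' re-creatable, and results are identical regardless of execution order.
#' Trapped runs (all candidates excluded by the hard core) are excluded from
#' the averages and counted; more than 5\% trapped aborts.
#'
#' Per-run quantities are evaluated on the finished configuration: the radius
#' of gyration and helix fraction of the final \code{n_steps + 1} positions,
#' and the total pair energy of that configuration (both total and
#' per-position variants are kept).
#'
#' @param params a [walk_params()] object.
#' @param n_runs number of independent runs (published setting: 1000; fast
#'   default 100).
#' @param base_seed first seed of the run sequence (default:
#'   \code{params$seed}).
#' @param K helix-detection window length.
#' @return an object of class \code{"sirw_ensemble"}: list with a per-run
#'   data frame \code{runs} (seed, Rg, H, steps_per_turn, handedness,
#'   energy_total, energy_pp, final U), summary statistics \code{mean_Rg},
#'   \code{sem_Rg}, \code{mean_H}, \code{sem_H}, \code{mean_energy}
#'   (per-position), \code{mean_energy_total}, counts, and the last
#'   trajectory as \code{representative_trajectory}.
#' @export
run_ensemble <- function(params, n_runs = 100, base_seed = params$seed,
                         K = 10) {
  stopifnot(inherits(params, "sirw_params"), n_runs >= 1)
  dirs <- direction_set(params$n_directions, params$method)
  seeds <- as.integer(base_seed) + seq_len(n_runs) - 1L
  rows <- vector("list", n_runs)
  last <- NULL
  trapped <- 0L
  for (i in seq_len(n_runs)) {
    p <- params
    p$seed <- seeds[i]
    tr <- tryCatch(simulate_walk(p, dirs), error = function(e) e)
    if (inherits(tr, "error")) {
      trapped <- trapped + 1L
      rows[[i]] <- data.frame(seed = seeds[i], trapped = TRUE, Rg = NA_real_,
                              H = NA_real_, steps_per_turn = NA_real_,
                              handedness = NA_character_,
                              energy_total = NA_real_, energy_pp = NA_real_,
                              final_U = NA_real_)
      next
    }
    h <- helix_fraction(tr$positions, K = K)
    et <- configuration_energy(tr$positions, params$epsilon, params$r0,
                               params$rmin)
    m <- nrow(tr$positions)
    rows[[i]] <- data.frame(seed = seeds[i], trapped = FALSE,
                            Rg = radius_of_gyration(tr$positions),
                            H = h$H, steps_per_turn = h$steps_per_turn,
                            handedness = h$handedness,
                            energy_total = et, energy_pp = et / m,
                            final_U = tr$energy[m])
    last <- tr
  }
  runs <- do.call(rbind, rows)
  if (trapped > 0.05 * n_runs)
    stop(sprintf("%d of %d runs trapped (> 5%%)", trapped, n_runs))
  ok <- !runs$trapped
  sem <- function(x) if (sum(ok) > 1L) stats::sd(x[ok]) / sqrt(sum(ok)) else 0
  structure(list(
    params = params, n_runs = n_runs, base_seed = as.integer(base_seed),
    n_trapped = trapped, runs = runs,
    mean_Rg = mean(runs$Rg[ok]), sem_Rg = sem(runs$Rg),
    mean_H = mean(runs$H[ok]), sem_H = sem(runs$H),
    mean_energy = mean(runs$energy_pp[ok]),
    mean_energy_total = mean(runs$energy_total[ok]),
    mean_steps_per_turn = if (any(is.finite(runs$steps_per_turn[ok])))
      mean(runs$steps_per_turn[ok], na.rm = TRUE) else NA_real_,
    representative_trajectory = last), class = "sirw_ensemble")
}

#' @export
print.sirw_ensemble <- function(x, ...) {
  cat(sprintf(
    "SIRW ensemble: %d runs at T=%g, epsilon=%g, r0=%g (%d trapped)\n",
    x$n_runs, x$params$temperature, x$params$epsilon, x$params$r0,
    x$n_trapped))
  cat(sprintf("  <Rg> = %.4f (sem %.4f)\n", x$mean_Rg, x$sem_Rg))
  cat(sprintf("  <H>  = %.4f (sem %.4f)\n", x$mean_H, x$sem_H))
  cat(sprintf("  <E>/position = %.4f\n", x$mean_energy))
  invisible(x)
}

#' Serialize an ensemble summary to JSON
#'
#' @param x a \code{sirw_ensemble}.
#' @param path optional file path; when omitted the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
ensemble_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "sirw_ensemble"))
  obj <- list(params = unclass(x$params), n_runs = x$n_runs,
              base_seed = x$base_seed, n_trapped = x$n_trapped,
              mean_Rg = x$mean_Rg, sem_Rg = x$sem_Rg,
              mean_H = x$mean_H, sem_H = x$sem_H,
              mean_energy = x$mean_energy,
              mean_energy_total = x$mean_energy_total)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
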