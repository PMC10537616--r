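#' Temperature sweep at fixed potential parameters
#'
#' Runs one ensemble per temperature on an increasing grid (log spacing
#' recommended: the interesting range spans five decades) and collects the
#' order-parameter averages into a tidy table. Seeds are blocked per grid
#' point (\code{base_seed + (i-1) * n_runs}) so every ensemble is independent
#' and re-creatable.
#'
#' @param params a [walk_params()] object; its temperature field is ignored.
#' @param T_grid increasing vector of temperatures (>= 2 points; >= 8
#'   recommended for transition estimation).
#' @param n_runs runs per grid point.
#' @param base_seed seed of the first run of the first grid point.
#' @param K helix-detection window length.
#' @return an object of class \code{"sirw_sweep"}: a data frame with columns
#'   \code{T, epsilon, r0, mean_Rg, sem_Rg, mean_H, sem_H, mean_energy,}
#'   \code{mean_energy_total, n_trapped}, with the parameter set and seeds as
#'   attributes.
#' @export
sweep_temperature <- function(params, T_grid, n_runs = 100,
                              base_seed = params$seed, K = 10) {
  stopifnot(inherits(params, "sirw_params"))
  T_grid <- as.numeric(T_grid)
  if (length(T_grid) < 2L || is.unsorted(T_grid, strictly = TRUE))
    stop("'T_grid' must be a strictly increasing vector of >= 2 temperatures")
  rows <- lapply(seq_along(T_grid), function(i) {
    p <- params
    p$temperature <- T_grid[i]
    en <- run_ensemble(p, n_runs = n_runs,
                       base_seed = as.integer(base_seed) + (i - 1L) * n_runs,
                       K = K)
    data.frame(T = T_grid[i], epsilon = params$epsilon, r0 = params$r0,
               mean_Rg = en$mean_Rg, sem_Rg = en$sem_Rg,
               mean_H = en$mean_H, sem_H = en$sem_H,
               mean_energy = en$mean_energy,
               mean_energy_total = en$mean_energy_total,
               mean_steps_per_turn = en$mean_steps_per_turn,
               n_trapped = en$n_trapped)
  })
  out <- do.call(rbind, rows)
  structure(out, params = params, n_runs = n_runs,
            base_seed = as.integer(base_seed),
            class = c("sirw_sweep", "data.frame"))
}

#' Transition temperature from a sweep
#'
#' Two deterministic estimators, both acting on the tabulated sweep:
#' \describe{
#'   \item{Rg}{the temperature of steepest change of \eqn{\langle R_g\rangle}
#'     on the log-T axis (argmax of \eqn{|\Delta \langle R_g\rangle / \Delta
#'     \ln T|} over grid intervals, refined by a local quadratic through the
#'     three slopes around the maximum). \code{direction} restricts the
#'     search to intervals where \eqn{\langle R_g\rangle} increases or
#'     decreases with T, which separates the two branches of a reentrant
#'     curve.}
#'   \item{H}{the interpolated crossing of \eqn{\langle H\rangle = 0.5}
#'     (linear in \eqn{\ln T}), taking the crossing where \eqn{H} falls with
#'     increasing T.}
#' }
#' A flat curve returns a no-transition sentinel (\code{Tc = NA}) rather than
#' an error.
#'
#' @param sweep a \code{sirw_sweep}, or any data frame with a column \code{T}
#'   and the required observable column (\code{mean_Rg} or \code{mean_H}).
#' @param observable which order parameter to use.
#' @param direction for the Rg estimator: restrict to intervals where Rg
#'   \code{"increasing"} / \code{"decreasing"} in T, or \code{"any"}.
#' @param flat_tol minimum total variation of the observable (relative to its
#'   maximum magnitude) below which the curve is declared flat.
#' @return list with \code{Tc} (numeric, \code{NA} if no transition),
#'   \code{method}, \code{observable}, \code{direction}.
#' @export
estimate_transition_temperature <- function(sweep,
                                            observable = c("Rg", "H"),
                                            direction = c("any", "increasing",
                                                          "decreasing"),
                                            flat_tol = 0.05) {
  observable <- match.arg(observable)
  direction <- match.arg(direction)
  df <- as.data.frame(sweep)
  col <- if (observable == "Rg") "mean_Rg" else "mean_H"
  if (!all(c("T", col) %in% names(df)))
    stop(sprintf("sweep must have columns 'T' and '%s'", col))
  tt <- df$T
  y <- df[[col]]
  ok <- is.finite(tt) & is.finite(y)
  tt <- tt[ok]; y <- y[ok]
  no_tc <- list(Tc = NA_real_, method = "none", observable = observable,
                direction = direction)
  if (length(tt) < 3L) return(no_tc)
  if (diff(range(y)) < flat_tol * max(abs(y), 1e-12)) return(no_tc)

  lt <- log(tt)
  if (observable == "H") {
    # falling crossing of H = 0.5
    for (i in seq_len(length(y) - 1L)) {
      if (y[i] >= 0.5 && y[i + 1L] < 0.5) {
        f <- (y[i] - 0.5) / (y[i] - y[i + 1L])
        return(list(Tc = exp(lt[i] + f * (lt[i + 1L] - lt[i])),
                    method = "H_half_crossing", observable = observable,
                    direction = direction))
      }
    }
    return(no_tc)
  }

  slope <- diff(y) / diff(lt)
  mid <- (lt[-1] + lt[-length(lt)]) / 2
  use <- switch(direction,
                any = rep(TRUE, length(slope)),
                increasing = slope > 0,
                decreasing = slope < 0)
  if (!any(use)) return(no_tc)
  mag <- abs(slope)
  mag[!use] <- -Inf
  i <- which.max(mag)
  tc_log <- mid[i]
  # quadratic refinement through the three neighbouring slope magnitudes
  if (i > 1L && i < length(slope) && is.finite(mag[i - 1L]) &&
      is.finite(mag[i + 1L])) {
    y3 <- mag[(i - 1L):(i + 1L)]
    x3 <- mid[(i - 1L):(i + 1L)]
    den <- y3[1] - 2 * y3[2] + y3[3]
    if (is.finite(den) && den < 0) {
      off <- 0.5 * (y3[1] - y3[3]) / den
      if (abs(off) <= 1)  # stay within one grid interval
        tc_log <- x3[2] + off * (x3[3] - x3[1]) / 2
    }
  }
  list(Tc = exp(tc_log), method = "max_dRg_dlnT", observable = observable,
       direction = direction)
}

#' Fit the transition line kB*Tc = lambda * epsilon
#'
#' Least-squares slope through the origin of transition temperature versus
#' well depth: \eqn{\lambda = \sum \epsilon_i T_{c,i} / \sum \epsilon_i^2}.
#' \eqn{\lambda} is transition-specific: it is of order 1 for the coil-
#' globule collapse (the walker loses contacts worth about one well depth)
#' and much smaller for the globule-helix ordering transition.
#'
#' @param epsilon_grid well depths.
#' @param Tc_values transition temperatures (same length; NA pairs dropped).
#' @return an object of class \code{"sirw_lambda"}: list with \code{lambda},
#'   \code{residual} (RMS of \eqn{T_c - \lambda\epsilon}),
#'   \code{epsilon_grid}, \code{Tc_values}.
#' @export
fit_lambda <- function(epsilon_grid, Tc_values) {
  ok <- is.finite(epsilon_grid) & is.finite(Tc_values)
  e <- as.numeric(epsilon_grid[ok])
  tc <- as.numeric(Tc_values[ok])
  if (length(e) < 3L)
    stop("invalid input: need >= 3 (epsilon, Tc) pairs")
  lambda <- sum(e * tc) / sum(e^2)
  structure(list(lambda = lambda,
                 residual = sqrt(mean((tc - lambda * e)^2)),
                 epsilon_grid = e, Tc_values = tc),
            class = "sirw_lambda")
}

#' @export
print.sirw_lambda <- function(x, ...) {
  cat(sprintf("kB*Tc = lambda*epsilon fit: lambda = %.4g (RMS residual %.3g, %d points)\n",
              x$lambda, x$residual, length(x$epsilon_grid)))
  invisible(x)
}

#' Phase diagram in the temperature-well-depth plane
#'
#' Sweeps temperature at each well depth on the grid (fixed \code{r0}) and
#' labels every cell: \code{helix} when \eqn{\langle H\rangle \ge 0.5}
#' (checked first, since helix and globule are both compact); otherwise
#' \code{globule} when \eqn{\langle R_g\rangle} lies below the midpoint
#' between the globule and coil plateaus of that well depth's sweep;
#' otherwise \code{coil}. Both transition lines are estimated per well depth
#' and fitted as \eqn{k_B T_c = \lambda \epsilon}.
#'
#' @param params a [walk_params()] (temperature and epsilon fields ignored).
#' @param T_grid increasing temperature grid (>= 6 points recommended).
#' @param epsilon_grid increasing well-depth grid (>= 3 for the lambda fits).
#' @param n_runs runs per cell.
#' @param base_seed seed base; each (epsilon, T) cell gets its own block.
#' @return an object of class \code{"sirw_phase_diagram"}: a data frame with
#'   columns \code{T, epsilon, r0, mean_Rg, sem_Rg, mean_H, sem_H, phase},
#'   with the per-epsilon transition temperatures and the two
#'   [fit_lambda()] results as attributes \code{transitions},
#'   \code{lambda_coil_globule}, \code{lambda_globule_helix}.
#' @export
phase_diagram <- function(params, T_grid, epsilon_grid, n_runs = 50,
                          base_seed = params$seed) {
  stopifnot(inherits(params, "sirw_params"))
  epsilon_grid <- as.numeric(epsilon_grid)
  if (is.unsorted(epsilon_grid, strictly = TRUE))
    stop("'epsilon_grid' must be strictly increasing")
  cells <- list()
  tc_cg <- tc_gh <- rep(NA_real_, length(epsilon_grid))
  for (j in seq_along(epsilon_grid)) {
    p <- params
    p$epsilon <- epsilon_grid[j]
    sw <- sweep_temperature(p, T_grid, n_runs = n_runs,
                            base_seed = as.integer(base_seed) +
                              (j - 1L) * length(T_grid) * n_runs)
    tc_cg[j] <- estimate_transition_temperature(sw, "Rg",
                                                direction = "increasing")$Tc
    tc_gh[j] <- estimate_transition_temperature(sw, "H")$Tc
    df <- as.data.frame(sw)
    df$phase <- label_phases(df)
    cells[[j]] <- df[, c("T", "epsilon", "r0", "mean_Rg", "sem_Rg",
                         "mean_H", "sem_H", "phase")]
  }
  out <- do.call(rbind, cells)
  fit_cg <- if (sum(is.finite(tc_cg)) >= 3)
    fit_lambda(epsilon_grid, tc_cg) else NULL
  fit_gh <- if (sum(is.finite(tc_gh)) >= 3)
    fit_lambda(epsilon_grid, tc_gh) else NULL
  structure(out,
            transitions = data.frame(epsilon = epsilon_grid,
                                     Tc_coil_globule = tc_cg,
                                     Tc_globule_helix = tc_gh),
            lambda_coil_globule = fit_cg, lambda_globule_helix = fit_gh,
            class = c("sirw_phase_diagram", "data.frame"))
}

# Phase label per row of one temperature sweep (single epsilon).
# Coil plateau: mean Rg over the top grid points; globule plateau: the
# minimum mean Rg over the non-helical rows.
label_phases <- function(df) {
  n <- nrow(df)
  coil_plateau <- mean(df$mean_Rg[max(1, n - 2):n])
  nonhelix <- df$mean_H < 0.5
  globule_plateau <- if (any(nonhelix)) min(df$mean_Rg[nonhelix])
                     else min(df$mean_Rg)
  midpoint <- (coil_plateau + globule_plateau) / 2
  ifelse(df$mean_H >= 0.5, "helix",
         ifelse(df$mean_Rg < midpoint, "globule", "coil"))
}

#' Write a sweep or phase-diagram table as tidy CSV
#'
#' @param x a \code{sirw_sweep} or \code{sirw_phase_diagram}.
#' @param path output file.
#' @export
write_sweep_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
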