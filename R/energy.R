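#' Lennard-Jones pair potential
#'
#' \eqn{u(r) = \epsilon[(r_0/r)^{12} - 2 (r_0/r)^6]}: minimum value
#' \eqn{-\epsilon} at the equilibrium distance \eqn{r = r_0}, zero at
#' \eqn{r = 2^{-1/6} r_0}, and vanishing as \eqn{r \to \infty}. Energies are
#' in units with \eqn{k_B = 1}; distances in units of the step length.
#'
#' @param r distance(s), > 0; vectorized.
#' @param epsilon well depth (> 0).
#' @param r0 equilibrium distance (> 0).
#' @return energy value(s).
#' @examples
#' lj_pair(1.0, epsilon = 1, r0 = 1)        # -1 at the minimum
#' lj_pair(2^(-1/6), epsilon = 1, r0 = 1)   # 0 at the node
#' @export
lj_pair <- function(r, epsilon = 1, r0 = 1) {
  check_potential(epsilon, r0)
  if (any(r <= 0)) stop("singular distance: r must be > 0")
  s6 <- (r0 / r)^6
  epsilon * (s6 * s6 - 2 * s6)
}

#' Total interaction energy of the walker with its visit history
#'
#' Sum of Lennard-Jones pair energies between \code{position} and every
#' previously visited position (the bonded neighbour included). Pairs closer
#' than the hard-core cutoff \code{rmin} (default \eqn{0.1 r_0}) return
#' \code{+Inf}: the candidate is unreachable, never \code{NaN}.
#'
#' @param position 3D point.
#' @param visited matrix of previously visited 3D points (rows), or a single
#'   point.
#' @inheritParams lj_pair
#' @param rmin hard-core cutoff distance.
#' @return total energy (possibly \code{+Inf}).
#' @export
total_energy <- function(position, visited, epsilon = 1, r0 = 1,
                         rmin = 0.1 * r0) {
  check_potential(epsilon, r0)
  visited <- as_points(visited)
  if (nrow(visited) == 0L) stop("'visited' must contain at least one point")
  p <- as.numeric(position)
  r <- sqrt(rowSums(sweep(visited, 2, p)^2))
  if (any(r < rmin)) return(Inf)
  sum(lj_pair(r, epsilon, r0))
}

#' Total pair energy of a whole configuration
#'
#' Lennard-Jones energy summed over all unordered pairs of positions; the
#' per-position variant divides by the number of positions and is the
#' quantity used for the globule-coil energy-gap diagnostic.
#'
#' @param positions matrix of 3D points (rows) or a trajectory.
#' @inheritParams total_energy
#' @param per_position divide by the number of positions?
#' @return energy (scalar).
#' @export
configuration_energy <- function(positions, epsilon = 1, r0 = 1,
                                 rmin = 0.1 * r0, per_position = FALSE) {
  check_potential(epsilon, r0)
  pos <- as_points(positions)
  if (nrow(pos) < 2L) return(0)
  e <- config_energy_cpp(pos, epsilon, r0, rmin)
  if (per_position) e / nrow(pos) else e
}

check_potential <- function(epsilon, r0) {
  if (!is.numeric(epsilon) || epsilon <= 0) stop("'epsilon' must be > 0")
  if (!is.numeric(r0) || r0 <= 0) stop("'r0' must be > 0")
  invisible(TRUE)
}

# coerce a point, vector of points, or trajectory to an n x 3 matrix
as_points <- function(x) {
  if (inherits(x, "sirw_trajectory")) return(x$positions)
  if (is.null(dim(x))) {
    if (length(x) != 3L) stop("a 3D point must have length 3")
    return(matrix(as.numeric(x), 1L, 3L))
  }
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop("positions must be an n x 3 matrix")
  storage.mode(x) <- "double"
  x
}
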