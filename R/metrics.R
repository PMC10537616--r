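#' Root-mean-square radius of gyration
#'
#' \eqn{R_g = \sqrt{ \frac{1}{M} \sum_i \| R_i - \bar R \|^2 }} over the
#' \eqn{M} positions of the list, with \eqn{\bar R} their centroid. Invariant
#' under rigid motions; scales linearly under uniform dilation.
#'
#' @param positions n x 3 matrix of points, or a trajectory.
#' @return \eqn{R_g} in the same distance units as the input.
#' @export
radius_of_gyration <- function(positions) {
  pos <- as_points(positions)
  if (nrow(pos) == 0L) stop("invalid input: no positions")
  ctr <- colMeans(pos)
  sqrt(mean(rowSums(sweep(pos, 2, ctr)^2)))
}

#' Helix annotation of a chain by the turning-window rule
#'
#' Slides a window of \code{K} consecutive connection-to-previous-connection
#' turns along the chain (a window involves \code{K + 1} connections, i.e.
#' \code{K + 2} positions). A window qualifies as one helical turn when (a)
#' every local turn inside it has the same nonzero handedness (sign of the
#' scalar triple product of three consecutive connections) and (b) the sum of
#' its \code{K} turning angles exceeds \eqn{2\pi}. A position is helical when
#' it belongs to at least one qualifying window, so each position is counted
#' at most once and a perfect helix reaches \eqn{H = 1}.
#'
#' Windows containing a degenerate (zero-length) connection or a coplanar
#' turn are disqualified, not errors: a flat segment is not a helix turn.
#'
#' @param positions n x 3 matrix of points or a trajectory.
#' @param K window length in connections (default 10, chosen to tolerate
#'   local fluctuations while still requiring a full \eqn{2\pi} of turning).
#' @return an object of class \code{"sirw_helix"}: list with
#'   \code{is_helical} (logical per position), \code{n_h}, \code{H}
#'   (\eqn{n_h / M}), \code{steps_per_turn} (\eqn{2\pi K} divided by the
#'   window angle sum, averaged over qualifying windows; \code{NA} when no
#'   window qualifies) and \code{handedness} (\code{"right"}, \code{"left"},
#'   \code{"mixed"} or \code{"none"}).
#' @examples
#' h <- ideal_helix(51, points_per_turn = 4)
#' helix_fraction(h)$H         # 1
#' @export
helix_fraction <- function(positions, K = 10) {
  pos <- as_points(positions)
  m <- nrow(pos)
  if (m == 0L) stop("invalid input: no positions")
  ann <- list(is_helical = logical(m), n_h = 0L, H = 0,
              steps_per_turn = NA_real_, handedness = "none")
  if (m < K + 2L) return(structure(ann, class = "sirw_helix"))

  v <- pos[-1L, , drop = FALSE] - pos[-m, , drop = FALSE]  # connections
  nv <- sqrt(rowSums(v^2))
  nc <- nrow(v)
  # turning angle between connection i and i+1 (NA when degenerate)
  ang <- rep(NA_real_, nc - 1L)
  # handedness of the (i, i+1, i+2) connection triple
  sgn <- rep(NA_integer_, nc - 2L)
  for (i in seq_len(nc - 1L)) {
    if (nv[i] < 1e-12 || nv[i + 1L] < 1e-12) next
    cr <- cross3(v[i, ], v[i + 1L, ])
    ang[i] <- atan2(sqrt(sum(cr^2)), sum(v[i, ] * v[i + 1L, ]))
    if (i <= nc - 2L && nv[i + 2L] >= 1e-12) {
      s <- sum(cr * v[i + 2L, ]) / (nv[i] * nv[i + 1L] * nv[i + 2L])
      sgn[i] <- if (abs(s) < 1e-9) 0L else as.integer(sign(s))
    }
  }

  # window w uses connections w-1 .. w+K-1: angles ang[w-1 .. w+K-2],
  # signs sgn[w-1 .. w+K-3]
  helical <- logical(m)
  turns <- numeric(0)
  signs_seen <- integer(0)
  for (w in 2:(nc - K + 1L)) {
    a <- ang[(w - 1L):(w + K - 2L)]
    s <- sgn[(w - 1L):(w + K - 3L)]
    if (anyNA(a) || anyNA(s)) next
    if (any(s == 0L) || length(unique(s)) != 1L) next
    tot <- sum(a)
    if (tot <= 2 * pi) next
    helical[(w - 1L):(w + K)] <- TRUE   # positions spanned by the window
    turns <- c(turns, 2 * pi * K / tot)
    signs_seen <- c(signs_seen, s[1L])
  }
  ann$is_helical <- helical
  ann$n_h <- sum(helical)
  ann$H <- ann$n_h / m
  if (length(turns)) {
    ann$steps_per_turn <- mean(turns)
    u <- unique(signs_seen)
    ann$handedness <- if (length(u) > 1L) "mixed"
                      else if (u == 1L) "right" else "left"
  }
  structure(ann, class = "sirw_helix")
}

#' @export
print.sirw_helix <- function(x, ...) {
  cat(sprintf("Helix annotation: H = %.3f (%d of %d positions), handedness = %s",
              x$H, x$n_h, length(x$is_helical), x$handedness))
  if (!is.na(x$steps_per_turn))
    cat(sprintf(", %.2f steps/turn", x$steps_per_turn))
  cat("\n")
  invisible(x)
}

#' Mean interaction energy per position of a finished trajectory
#'
#' Total Lennard-Jones energy over all pairs of the final configuration,
#' divided by the number of positions. Near zero for a sparse random coil,
#' below \eqn{-1} for a compact globule with multiple favourable contacts.
#'
#' @param trajectory a \code{sirw_trajectory}.
#' @return energy per position.
#' @export
mean_energy <- function(trajectory) {
  stopifnot(inherits(trajectory, "sirw_trajectory"))
  p <- trajectory$params
  configuration_energy(trajectory$positions, p$epsilon, p$r0, p$rmin,
                       per_position = TRUE)
}

#' Steps per helical turn about the fitted helix axis
#'
#' The turning-window quantity \eqn{2\pi K / \sum\theta} underestimates the
#' azimuthal rotation of a helix with nonzero rise (the rise shrinks the 3D
#' angle between successive connections), so it overestimates the number of
#' steps per turn. This estimator counts actual rotation about the helix
#' axis: it takes the longest contiguous helical segment (per
#' [helix_fraction()]), fits the axis as the first principal component of
#' the segment, unwraps the azimuth of each position in the perpendicular
#' plane, and returns \eqn{2\pi} divided by the mean azimuthal advance per
#' step. For a protein-like helix this is the residues-per-turn count.
#'
#' @param positions n x 3 matrix of points or a trajectory.
#' @param K helix-detection window length used to locate the helical
#'   segment.
#' @return steps per turn (positive real), or \code{NA} when no helical
#'   segment of at least \code{K + 2} positions exists.
#' @export
steps_per_turn_axis <- function(positions, K = 10) {
  pos <- as_points(positions)
  ann <- helix_fraction(pos, K = K)
  r <- rle(ann$is_helical)
  if (!any(r$values)) return(NA_real_)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  best <- which.max(ifelse(r$values, r$lengths, 0L))
  seg <- pos[starts[best]:ends[best], , drop = FALSE]
  if (nrow(seg) < K + 2L) return(NA_real_)
  ctr <- sweep(seg, 2, colMeans(seg))
  sv <- svd(ctr)
  axial <- drop(ctr %*% sv$v[, 1])
  perp <- ctr - outer(axial, sv$v[, 1])
  phi <- atan2(drop(perp %*% sv$v[, 3]), drop(perp %*% sv$v[, 2]))
  dphi <- diff(phi)
  dphi <- (dphi + pi) %% (2 * pi) - pi   # unwrap to (-pi, pi]
  2 * pi / abs(mean(dphi))
}

#' Ideal parametric helix
#'
#' Helper generating \code{n} points on a circular helix with a given number
#' of points per full turn and rise per step, rescaled to unit bond length.
#' Useful as a reference structure for the helix detector.
#'
#' @param n number of points.
#' @param points_per_turn points per \eqn{2\pi} of azimuthal rotation.
#' @param rise axial rise per step before rescaling (as a fraction of the
#'   in-plane chord).
#' @param handed \code{"right"} or \code{"left"}.
#' @return n x 3 matrix with unit-length bonds.
#' @export
ideal_helix <- function(n, points_per_turn = 4, rise = 0.25,
                        handed = c("right", "left")) {
  handed <- match.arg(handed)
  th <- 2 * pi * (seq_len(n) - 1L) / points_per_turn
  chord <- 2 * sin(pi / points_per_turn)   # xy chord at unit radius
  z <- rise * chord * (seq_len(n) - 1L)
  pts <- cbind(cos(th), sin(th), z)
  if (handed == "left") pts[, 2] <- -pts[, 2]
  bond <- sqrt(sum((pts[2, ] - pts[1, ])^2))
  pts / bond
}
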