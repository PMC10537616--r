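#' Near-uniform unit vectors on the sphere
#'
#' Builds the fixed set of candidate move directions used by the walker: a
#' near-uniform covering of the unit sphere. Two deterministic constructions
#' are available. The Fibonacci (golden-angle) spiral lattice accepts any
#' count; the icosahedral geodesic construction accepts only counts of the
#' form \eqn{10f^2 + 2} (the vertex count of a frequency-\eqn{f} geodesic
#' sphere; \eqn{f = 39} gives 15,212, the density used for the published
#' simulations).
#'
#' @param count number of directions (>= 4). For \code{method = "geodesic"}
#'   it must equal \eqn{10f^2 + 2} for some integer \eqn{f >= 1}.
#' @param method construction: \code{"fibonacci"} (default, any count) or
#'   \code{"geodesic"} (icosahedral subdivision).
#' @return an object of class \code{"sirw_directions"}: a \code{count x 3}
#'   numeric matrix of unit vectors with attributes \code{count} and
#'   \code{method}.
#' @examples
#' d <- direction_set(1000)
#' range(sqrt(rowSums(d^2)))          # all 1
#' sqrt(sum(colMeans(d)^2))           # centroid norm ~ 0
#' @export
direction_set <- function(count, method = c("fibonacci", "geodesic")) {
  method <- match.arg(method)
  if (!is.numeric(count) || length(count) != 1L || count < 4 ||
      count != round(count))
    stop("'count' must be a single integer >= 4")
  count <- as.integer(count)
  dirs <- switch(method,
    fibonacci = fibonacci_sphere(count),
    geodesic  = geodesic_sphere(count)
  )
  dimnames(dirs) <- list(NULL, c("x", "y", "z"))
  structure(dirs, count = nrow(dirs), method = method,
            class = c("sirw_directions", "matrix", "array"))
}

# Golden-angle spiral lattice; the half-integer offset keeps the poles
# uncovered and the centroid near zero.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  rho <- sqrt(pmax(0, 1 - z^2))
  theta <- pi * (3 - sqrt(5)) * i
  cbind(rho * cos(theta), rho * sin(theta), z)
}

#' @rdname direction_set
#' @param f geodesic frequency
#' @return \code{geodesic_count} returns the vertex count \eqn{10f^2+2}.
#' @export
geodesic_count <- function(f) as.integer(10 * f^2 + 2)

geodesic_sphere <- function(count) {
  f <- sqrt((count - 2) / 10)
  if (abs(f - round(f)) > 1e-9 || round(f) < 1) {
    fl <- max(1, floor(f)); fu <- ceiling(f)
    if (fu <= fl) fu <- fl + 1
    stop(sprintf(
      "geodesic counts must be 10*f^2+2; nearest valid counts to %d are %d (f=%d) and %d (f=%d)",
      count, geodesic_count(fl), fl, geodesic_count(fu), fu))
  }
  f <- as.integer(round(f))
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  faces <- rbind(
    c(1, 12, 6),  c(1, 6, 2),   c(1, 2, 8),   c(1, 8, 11),  c(1, 11, 12),
    c(2, 6, 10),  c(6, 12, 5),  c(12, 11, 3), c(11, 8, 7),  c(8, 2, 9),
    c(4, 10, 5),  c(4, 5, 3),   c(4, 3, 7),   c(4, 7, 9),   c(4, 9, 10),
    c(5, 10, 6),  c(3, 5, 12),  c(7, 3, 11),  c(9, 7, 8),   c(10, 9, 2))
  # barycentric lattice i+j+k = f on each face, projected to the sphere
  idx <- expand.grid(i = 0:f, j = 0:f)
  idx <- idx[idx$i + idx$j <= f, ]
  w <- cbind(idx$i, idx$j, f - idx$i - idx$j) / f
  pts <- do.call(rbind, lapply(seq_len(nrow(faces)), function(t) {
    w %*% v[faces[t, ], , drop = FALSE]
  }))
  pts <- pts / sqrt(rowSums(pts^2))
  # shared edge/corner points appear on several faces; dedupe on a rounded key
  key <- paste(round(pts[, 1], 7), round(pts[, 2], 7), round(pts[, 3], 7))
  pts <- pts[!duplicated(key), , drop = FALSE]
  stopifnot(nrow(pts) == count)
  pts
}

#' Turning angle at an interior point of a chain
#'
#' Angle in \eqn{[0, \pi]} between the connection vectors \code{b - a} and
#' \code{c - b}: the exterior (turning) angle at \code{b}. Zero for three
#' collinear points walked in one direction, \eqn{\pi} for a full reversal.
#'
#' @param a,b,c 3D points (numeric length-3 vectors).
#' @return angle in radians.
#' @export
bond_angle <- function(a, b, c) {
  u <- as.numeric(b) - as.numeric(a)
  v <- as.numeric(c) - as.numeric(b)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < 1e-12 || nv < 1e-12)
    stop("degenerate geometry: zero-length connection")
  cr <- cross3(u, v)
  atan2(sqrt(sum(cr^2)), sum(u * v))
}

#' Handedness of a local turn
#'
#' Sign of the scalar triple product \eqn{(b-a) \times (c-b) \cdot (d-c)} of
#' three consecutive connection vectors: +1 for a locally right-handed turn,
#' -1 for left-handed, 0 when the three connections are coplanar (within a
#' relative tolerance of 1e-9). This is the standard rotation-invariant
#' chirality measure; it flips sign under reflection.
#'
#' @param a,b,c,d four consecutive 3D points.
#' @return integer -1, 0 or +1.
#' @export
turn_sign <- function(a, b, c, d) {
  u <- as.numeric(b) - as.numeric(a)
  v <- as.numeric(c) - as.numeric(b)
  w <- as.numeric(d) - as.numeric(c)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2)); nw <- sqrt(sum(w^2))
  if (nu < 1e-12 || nv < 1e-12 || nw < 1e-12)
    stop("degenerate geometry: zero-length connection")
  s <- sum(cross3(u, v) * w) / (nu * nv * nw)
  if (abs(s) < 1e-9) 0L else as.integer(sign(s))
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' @export
print.sirw_directions <- function(x, ...) {
  cat(sprintf("Direction set: %d unit vectors (%s construction)\n",
              attr(x, "count"), attr(x, "method")))
  invisible(x)
}
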