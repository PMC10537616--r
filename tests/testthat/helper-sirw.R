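# shared fixtures: rigid motions and reference chains

# deterministic rotation matrix from an axis-angle
rot3 <- function(axis = c(1, 2, 3), angle = 0.7) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}

apply_rigid <- function(pos, R = rot3(), shift = c(0.3, -1.1, 2.0)) {
  sweep(pos %*% t(R), 2, shift, "+")
}

# planar zigzag with alternating turn direction, unit bonds
zigzag_chain <- function(n) {
  ang <- pi / 3
  step <- rbind(c(cos(ang / 2), sin(ang / 2), 0),
                c(cos(ang / 2), -sin(ang / 2), 0))
  steps <- step[rep(1:2, length.out = n - 1), , drop = FALSE]
  rbind(0, apply(steps, 2, cumsum))
}

line_chain <- function(n, d = 1) cbind(seq_len(n) - 1, 0, 0) * d

fast_params <- function(...) {
  args <- list(temperature = 1, epsilon = 1, r0 = 1.5, n_steps = 12,
               n_directions = 200, seed = 1L)
  args[names(list(...))] <- list(...)
  do.call(walk_params, args)
}
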