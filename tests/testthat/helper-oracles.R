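# Independent oracles used across the suite.

# quaternion composition of retarder rotations on the Poincare sphere:
# a retarder (R, alpha) is the rotation by R about the equatorial axis
# (cos 2a, sin 2a, 0); the equivalent retardance of a stack is the rotation
# angle of the composed quaternion.
quat_retarder <- function(R, alpha) {
  R <- R * pi / 180; a <- alpha * pi / 180
  c(cos(R / 2), sin(R / 2) * cos(2 * a), sin(R / 2) * sin(2 * a), 0)
}

quat_mul <- function(q, p) {
  c(q[1] * p[1] - sum(q[2:4] * p[2:4]),
    q[1] * p[2:4] + p[1] * q[2:4] +
      c(q[3] * p[4] - q[4] * p[3],
        q[4] * p[2] - q[2] * p[4],
        q[2] * p[3] - q[3] * p[2]))
}

# equivalent retardance (degrees) of layers traversed first-to-last
quat_equivalent_retardance <- function(R, alpha) {
  q <- c(1, 0, 0, 0)
  for (k in seq_along(R)) q <- quat_mul(quat_retarder(R[k], alpha[k]), q)
  2 * acos(min(abs(q[1]), 1)) * 180 / pi
}

# canonical diattenuator Mueller matrix from a diattenuation vector
diattenuator_mueller <- function(Dvec) {
  D <- sqrt(sum(Dvec^2))
  stopifnot(D < 1)
  Dh <- Dvec / D
  a <- sqrt(1 - D^2)
  rbind(c(1, Dvec), cbind(Dvec, a * diag(3) + (1 - a) * (Dh %o% Dh)))
}

# full phasor readout of a single Mueller matrix
phasor_estimate <- function(M, noise_floor_M = 0) {
  fld <- phasor_transform(polarization_stack_from_mueller(mueller_image(M)))
  pm <- phasor_parameter_images(fld, noise_floor_M = noise_floor_M)
  list(R = pm$R[1, 1], alpha_R = pm$alpha_R[1, 1], branch = pm$branch[1, 1],
       M = pm$M[1, 1], phi = pm$phi[1, 1])
}

# smallest angular distance on the 180-degree periodic orientation axis
orientation_distance <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}
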