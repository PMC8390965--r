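test_that("polarization stacks project Mueller images onto virtual analyzer angles", {
  stk <- polarization_stack_from_mueller(diag(4))
  expect_equal(unname(stk[1, 1, "H", ]), c(1, 0.5, 0, 0.5))
  stk2 <- polarization_stack_from_mueller(retarder_mueller(60, 0))
  expect_equal(unname(stk2[1, 1, "RCP", ]),
               c(0.5, (1 + sin(pi / 3)) / 2, 0.5, (1 - sin(pi / 3)) / 2),
               tolerance = 1e-12)
  film <- reference_mm("film", "as_printed")$mean
  stk3 <- polarization_stack_from_mueller(film)
  expect_equal(unname(stk3[1, 1, "H", "0"]), (1.012 + 1.011) / 2)
})

test_that("air phasors sit at the canonical points for each input state", {
  fld <- phasor_transform(polarization_stack_from_mueller(diag(4)))
  expect_equal(unname(c(fld$g[1, 1, "H"], fld$s[1, 1, "H"])), c(0.5, 0))
  expect_equal(unname(c(fld$g[1, 1, "V"], fld$s[1, 1, "V"])), c(-0.5, 0))
  expect_equal(unname(c(fld$g[1, 1, "45"], fld$s[1, 1, "45"])), c(0, 0.5))
  expect_equal(unname(c(fld$g[1, 1, "RCP"], fld$s[1, 1, "RCP"])), c(0, 0),
               tolerance = 1e-15)
  # observed polarization angle psi = phi / 2: 0, 45, 90 for H, 45, V
  expect_equal(phasor_phase(fld, "H")[1, 1] / 2, 0)
  expect_equal(phasor_phase(fld, "45")[1, 1] / 2, 45)
  expect_equal(phasor_phase(fld, "V")[1, 1] / 2, 90)
})

test_that("a retarder moves the RCP phasor to (S1/2, S2/2)", {
  fld <- phasor_transform(polarization_stack_from_mueller(retarder_mueller(60, 0)))
  expect_equal(unname(c(fld$g[1, 1, "RCP"], fld$s[1, 1, "RCP"])),
               c(0, sin(pi / 3) / 2), tolerance = 1e-12)
  expect_equal(phasor_modulation(fld, "RCP")[1, 1], sin(pi / 3) / 2,
               tolerance = 1e-12)
})

test_that("all-zero pixels are masked, not errors", {
  a <- array(0, c(1, 2, 4, 4))
  a[1, 1, , ] <- diag(4) # second pixel all-zero
  fld <- phasor_transform(polarization_stack_from_mueller(mueller_image(a)))
  expect_true(is.na(fld$g[1, 2, "H"]))
  expect_false(is.na(fld$g[1, 1, "H"]))
})

test_that("closed-form phasor relations hold over the full retarder grid", {
  Rs <- rep(seq(5, 175, 5), each = 36)
  as <- rep(seq(-85, 90, 5), times = 35)
  img <- mueller_image_from_list(Map(retarder_mueller, Rs, as))
  fld <- phasor_transform(polarization_stack_from_mueller(img))
  # RCP modulation = sin(R)/2, independent of alpha
  expect_lt(max(abs(phasor_modulation(fld, "RCP") - sin(Rs * pi / 180) / 2)),
            1e-10)
  # RCP phase = 90 + 2 alpha (mod 360)
  dphi <- (phasor_phase(fld, "RCP") - (90 + 2 * as)) %% 360
  expect_lt(max(pmin(dphi, 360 - dphi)), 1e-10)
})

test_that("at half-wave retardance the H-channel phase is 4 alpha", {
  alphas <- seq(-85, 90, 5)
  img <- mueller_image_from_list(lapply(alphas, function(a) retarder_mueller(180, a)))
  fld <- phasor_transform(polarization_stack_from_mueller(img))
  dphi <- (phasor_phase(fld, "H") - 4 * alphas) %% 360
  expect_lt(max(pmin(dphi, 360 - dphi)), 1e-9)
})

test_that("merging the linear channels preserves the air and half-wave signatures", {
  fld <- phasor_transform(polarization_stack_from_mueller(diag(4)))
  m <- merge_linear_phasors(fld)
  expect_equal(unname(c(m$g[1, 1, "linear"], m$s[1, 1, "linear"])), c(0.5, 0),
               tolerance = 1e-12)
  f2 <- merge_linear_phasors(phasor_transform(polarization_stack_from_mueller(
    retarder_mueller(180, 10))))
  expect_equal(unname(atan2(f2$s[1, 1, "linear"], f2$g[1, 1, "linear"])) * 180 / pi,
               40, tolerance = 1e-9)
  # missing channel is an error
  stk <- polarization_stack_from_mueller(diag(4), input_states = psg_states()[, c(1, 2, 4)])
  expect_error(merge_linear_phasors(phasor_transform(stk)), "H, V and 45")
  # masked pixel in a channel is an error
  a <- array(0, c(1, 1, 4, 4))
  fzero <- phasor_transform(polarization_stack_from_mueller(mueller_image(a)))
  expect_error(merge_linear_phasors(fzero), "masked")
})

test_that("orientation reads off the RCP phase as phi/2 - 45", {
  expect_equal(alpha_from_rcp_phase(90), 0)
  expect_equal(alpha_from_rcp_phase(180), 45)
  expect_equal(alpha_from_rcp_phase(0), -45)
  # branch window (-90, 270]: -100 aliases to 260
  expect_equal(alpha_from_rcp_phase(-100), 85)
  expect_true(is.na(alpha_from_rcp_phase(NA)))
})

test_that("retardance reads off the RCP modulation per branch", {
  expect_equal(retardance_from_rcp_modulation(0.5, "low"), 90)
  expect_equal(retardance_from_rcp_modulation(0.5, "high"), 90)
  expect_equal(retardance_from_rcp_modulation(0.25, "low"), 30)
  expect_equal(retardance_from_rcp_modulation(0.25, "high"), 150)
  expect_equal(retardance_from_rcp_modulation(0, "low"), 0)
  expect_equal(retardance_from_rcp_modulation(0, "high"), 180)
  expect_equal(retardance_from_rcp_modulation(0.3, "boundary"), 90)
  expect_error(retardance_from_rcp_modulation(0.6, "low"), "0.5")
})

test_that("the H-phasor circle separates the retardance branches", {
  h_phasor <- function(R, a) {
    fld <- phasor_transform(polarization_stack_from_mueller(retarder_mueller(R, a)))
    c(fld$g[1, 1, "H"], fld$s[1, 1, "H"])
  }
  p1 <- h_phasor(45, 20)
  expect_equal(unname(p1), c(0.4395, 0.0721), tolerance = 1e-3)
  expect_equal(branch_from_h_phasor(p1[1], p1[2])[1], "low")
  p2 <- h_phasor(135, 20)
  expect_equal(unname(p2), c(0.1473, 0.4203), tolerance = 1e-3)
  expect_equal(branch_from_h_phasor(p2[1], p2[2])[1], "high")
  # at R = 90 the phasor lies on the circle exactly, for any alpha
  for (a in c(-70, -20, 10, 33, 80)) {
    p <- h_phasor(90, a)
    expect_lt(abs(sqrt((p[1] - 0.25)^2 + p[2]^2) - 0.25), 1e-12)
    expect_equal(branch_from_h_phasor(p[1], p[2])[1], "boundary")
  }
})

test_that("phasor parameter maps recover uniform retarders on both branches", {
  low <- phasor_estimate(retarder_mueller(60, 30))
  expect_equal(low$branch, "low")
  expect_equal(low$R, 60, tolerance = 1e-9)
  expect_equal(low$alpha_R, 30, tolerance = 1e-9)
  high <- phasor_estimate(retarder_mueller(120, -10))
  expect_equal(high$branch, "high")
  expect_equal(high$R, 120, tolerance = 1e-9)
  expect_equal(high$alpha_R, -10, tolerance = 1e-9)
})

test_that("the 45-channel fallback resolves the branch for axes near 0 or 90", {
  # at alpha = 0 the H phasor is pinned to (0.5, 0) for every retardance
  for (R in c(20, 60, 120, 160)) {
    est <- phasor_estimate(retarder_mueller(R, 0))
    expect_equal(est$R, R, tolerance = 1e-9)
    est90 <- phasor_estimate(retarder_mueller(R, 90))
    expect_equal(est90$R, R, tolerance = 1e-9)
  }
})

test_that("noisy air pixels are assimilated to air at the default floor", {
  ph <- make_phantom(phantom_spec("air", size = c(64, 64), seed = 7))
  fld <- phasor_transform(polarization_stack_from_mueller(ph$mueller))
  pm <- phasor_parameter_images(fld)
  frac <- mean(pm$branch == "undetermined")
  # Monte-Carlo level for the reference air noise (sigma_M ~ 0.02 against a
  # 0.05 floor); most but not all pixels fall below the floor
  expect_gt(frac, 0.8)
  expect_true(all(is.na(pm$R[pm$branch == "undetermined"])))
})

test_that("end-to-end phasor estimation matches the generating parameters and LC", {
  Rs <- rep(seq(10, 170, 20), each = 12)
  as <- rep(seq(-75, 90, 15), times = 9)
  img <- mueller_image_from_list(Map(retarder_mueller, Rs, as))
  fld <- phasor_transform(polarization_stack_from_mueller(img))
  pm <- phasor_parameter_images(fld, noise_floor_M = 0)
  expect_lt(max(abs(pm$R - matrix(Rs, 1))), 1e-6)
  expect_lt(max(orientation_distance(pm$alpha_R, matrix(as, 1))), 1e-6)
  lcres <- lc_image(img)
  expect_lt(max(abs(pm$R - lcres$R)), 1e-6)
  expect_lt(max(orientation_distance(pm$alpha_R, lcres$alpha_R)), 1e-6)
})

test_that("phasor histograms count unmasked pixels into (g, s) bins", {
  fld <- phasor_transform(polarization_stack_from_mueller(diag(4)))
  h <- phasor_histogram(fld, "H", bins = 10)
  expect_equal(sum(h$counts), 1)
  expect_equal(sum(h$counts[10, ]), 1L) # (0.5, 0) lands in the last g bin
  # film on air: two separable clusters in the RCP channel
  ph <- make_phantom(phantom_spec("film_on_air", size = c(16, 16), noise = FALSE))
  fld2 <- phasor_transform(polarization_stack_from_mueller(ph$mueller))
  h2 <- phasor_histogram(fld2, "RCP", bins = 64)
  expect_equal(sum(h2$counts), 256)
  expect_equal(sum(h2$counts > 0), 2) # air at the origin, film at sin(R)/2
  expect_error(phasor_histogram(fld2, "RCP", roi_mask = matrix(FALSE, 16, 16)),
               "empty")
})

test_that("phasor gates segment the image back from phasor space", {
  ph <- make_phantom(phantom_spec("film_on_air", size = c(16, 16), noise = FALSE))
  fld <- phasor_transform(polarization_stack_from_mueller(ph$mueller))
  airm <- ph$truth$region == "air"
  sel <- phasor_gate_segment(fld, gate_disc(c(0, 0), 0.1), "RCP")
  jac <- sum(sel & airm) / sum(sel | airm)
  expect_gte(jac, 0.95)
  # gate over the film cluster
  filmm <- !airm
  gfilm <- mean(fld$g[, , "RCP"][filmm])
  sfilm <- mean(fld$s[, , "RCP"][filmm])
  sel2 <- phasor_gate_segment(fld, gate_disc(c(gfilm, sfilm), 0.05), "RCP")
  expect_gte(sum(sel2 & filmm) / sum(sel2 | filmm), 0.95)
  # gate outside all data
  expect_equal(sum(phasor_gate_segment(fld, gate_disc(c(-0.45, -0.45), 0.02))), 0)
  expect_error(gate_disc(c(0, 0), 0), "radius")
  expect_error(gate_polygon(c(0, 1, 2), c(0, 0, 0)), "zero area")
  skip_if_not_installed("mgcv")
  poly <- gate_polygon(c(-0.11, 0.11, 0.11, -0.11), c(-0.11, -0.11, 0.11, 0.11))
  sel3 <- phasor_gate_segment(fld, poly, "RCP")
  expect_gte(sum(sel3 & airm) / sum(sel3 | airm), 0.95)
})

test_that("the modulation floor corresponds to a ~5.7 degree retardance limit", {
  f <- function(R) {
    fld <- phasor_transform(polarization_stack_from_mueller(retarder_mueller(R, 0)))
    phasor_modulation(fld, "RCP")[1, 1] - 0.05
  }
  Rfloor <- stats::uniroot(f, c(1, 20), tol = 1e-10)$root
  expect_gte(Rfloor, 5.7 - 0.1)
  expect_lte(Rfloor, 5.8 + 0.1)
})

test_that("dichroism and depolarization leave distinct phasor signatures", {
  # pure diattenuator at alpha_D = 0: RCP phasor displaced along +g with
  # M = D/2 -- unlike a retarder at alpha = 0, whose RCP phasor sits on +s.
  # (A diattenuator is non-depolarizing, so linear inputs keep M = 0.5.)
  MD <- diattenuator_mueller(c(0.4, 0, 0))
  fld <- phasor_transform(polarization_stack_from_mueller(MD))
  expect_equal(unname(fld$g[1, 1, "RCP"]), 0.2, tolerance = 1e-12)
  expect_equal(unname(fld$s[1, 1, "RCP"]), 0, tolerance = 1e-12)
  fret <- phasor_transform(polarization_stack_from_mueller(retarder_mueller(47, 0)))
  expect_equal(unname(fret$g[1, 1, "RCP"]), 0, tolerance = 1e-12)
  expect_gt(fret$s[1, 1, "RCP"], 0)
  expect_lte(phasor_modulation(fld, "45")[1, 1], 0.5 + 1e-12)
  # depolarizer mixed with a retarder: RCP modulation decreases with P_d
  mods <- sapply(c(1, 0.8, 0.6, 0.4, 0.2), function(p) {
    M <- diag(c(1, p, p, p)) %*% retarder_mueller(60, 30)
    phasor_modulation(phasor_transform(polarization_stack_from_mueller(M)),
                      "RCP")[1, 1]
  })
  expect_true(all(diff(mods) < 0))
})

test_that("non-default analyzer sets agree with the four-angle difference form", {
  M <- retarder_mueller(77, -33)
  stk6 <- polarization_stack_from_mueller(M, theta = seq(0, 150, 30))
  fld6 <- phasor_transform(stk6, phasor_config(theta = seq(0, 150, 30)))
  fld4 <- phasor_transform(polarization_stack_from_mueller(M))
  # the first Fourier coefficient of a pure second-harmonic signal is the
  # same for any uniform analyzer set
  expect_equal(phasor_modulation(fld6, "RCP")[1, 1],
               phasor_modulation(fld4, "RCP")[1, 1], tolerance = 1e-12)
  expect_equal(phasor_phase(fld6, "RCP")[1, 1],
               phasor_phase(fld4, "RCP")[1, 1], tolerance = 1e-10)
})
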