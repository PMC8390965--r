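test_that("Stokes vectors assemble from analyzer intensities in the H/V, 45/135, RCP/LCP basis", {
  expect_equal(unname(stokes_from_intensities(1, 0.5, 0, 0.5, 0.5, 0.5)),
               c(1, 1, 0, 0)) # pure H
  expect_equal(unname(stokes_from_intensities(0.5, 1, 0.5, 0, 0.5, 0.5)),
               c(1, 0, 1, 0)) # pure 45
  expect_equal(unname(stokes_from_intensities(0.5, 0.5, 0.5, 0.5, 1, 0)),
               c(1, 0, 0, 1)) # pure RCP
  expect_error(stokes_from_intensities(-0.1, 0.5, 0, 0.5, 0.5, 0.5), "negative")
})

test_that("linear analyzer intensities follow (S0 +/- S1)/2, (S0 +/- S2)/2", {
  expect_equal(unname(intensities_from_stokes(c(1, 1, 0, 0))),
               c(1, 0, 0.5, 0.5))
  expect_equal(unname(intensities_from_stokes(c(1, 0, 1, 0))),
               c(0.5, 0.5, 1, 0))
  expect_equal(unname(intensities_from_stokes(c(2, 1, -1, 0))),
               c(1.5, 0.5, 0.5, 1.5))
  # unphysical vectors are flagged, not rejected
  out <- intensities_from_stokes(c(1, 2, 0, 0))
  expect_true(attr(out, "unphysical"))
})

test_that("intensity -> Stokes -> intensity round trip restores S0, S1, S2 exactly", {
  set.seed(101)
  for (k in 1:25) {
    # random fully/partially polarized physical state
    S0 <- runif(1, 0.5, 2)
    p <- runif(1)
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    S <- c(S0, p * S0 * u)
    I <- intensities_from_stokes(S)
    S2 <- stokes_from_intensities(I[["I0"]], I[["I45"]], I[["I90"]], I[["I135"]],
                                  0.5 * (S[1] + S[4]), 0.5 * (S[1] - S[4]))
    expect_equal(unname(S2), S, tolerance = 1e-12)
  }
})

test_that("propagate performs the Stokes-Mueller product", {
  expect_equal(propagate(diag(4), c(1, 1, 0, 0)), c(1, 1, 0, 0))
  # a half-wave plate flips circular handedness
  expect_equal(propagate(retarder_mueller(180, 0), c(1, 0, 0, 1)),
               c(1, 0, 0, -1))
  film <- reference_mm("film", "as_printed")$mean
  expect_equal(propagate(film, c(1, 1, 0, 0)), c(1.012, 1.011, 0.383, 0.032),
               tolerance = 1e-12)
})

test_that("retarder Mueller matrices match the closed form at special angles", {
  expect_equal(retarder_mueller(0, 37), diag(4))
  expect_equal(retarder_mueller(180, 0), diag(c(1, 1, -1, -1)))
  expect_equal(retarder_mueller(90, 45),
               rbind(c(1, 0, 0, 0), c(0, 0, 0, -1),
                     c(0, 0, 1, 0), c(0, 1, 0, 0)),
               tolerance = 1e-15)
})

test_that("retarders are unimodular and preserve the degree of polarization", {
  set.seed(7)
  for (R in seq(0, 180, 15)) {
    for (a in seq(-90, 90, 15)) {
      M <- retarder_mueller(R, a)
      expect_equal(det(M), 1, tolerance = 1e-12)
      S <- c(1, rnorm(3) / 3)
      Sout <- propagate(M, S)
      expect_equal(sqrt(sum(Sout[2:4]^2)), sqrt(sum(S[2:4]^2)),
                   tolerance = 1e-12)
    }
  }
})

test_that("physical retardance follows 360 * delta_n * e / lambda", {
  expect_equal(retardance_from_physical(0.0017, 50, 808), 37.87129,
               tolerance = 1e-6)
  expect_equal(retardance_from_physical(0, 10, 808), 0)
  # thick film: unwrapped value far above a full wave
  expect_equal(retardance_from_physical(0.0077, 500, 808), 1715.347,
               tolerance = 1e-4)
  expect_error(retardance_from_physical(0.01, -1, 808), "positive")
  expect_error(retardance_from_physical(0.01, 10, 0), "positive")
})

test_that("retardance wrapping folds onto [0, 180] and is idempotent there", {
  expect_equal(wrap_retardance(55), 55)
  expect_equal(wrap_retardance(275.4), 84.6)
  expect_equal(wrap_retardance(360), 0)
  expect_equal(wrap_retardance(wrap_retardance(seq(0, 720, 7.5))),
               wrap_retardance(seq(0, 720, 7.5)))
  expect_error(wrap_retardance(-3), "non-negative")
})

test_that("double-pass correction mirrors about 180 degrees", {
  expect_equal(double_pass_correct(360), 0)
  expect_equal(double_pass_correct(304.5), 55.5)
  expect_equal(double_pass_correct(180), 180)
  expect_error(double_pass_correct(400), "\\[0, 360\\]")
})

test_that("retarder specs check the physical triple and carry degrees", {
  sp <- retarder_spec(alpha = 0, delta_n = 0.0017, thickness_um = 50,
                      wavelength_nm = 808)
  expect_equal(sp$R, 37.87129, tolerance = 1e-5)
  expect_error(retarder_spec(R = 10, alpha = 0, delta_n = 0.0017,
                             thickness_um = 50, wavelength_nm = 808),
               "inconsistent")
  expect_equal(retarder_spec(R = pi / 2, alpha = 95, unit = "radians")$R, 90)
  expect_equal(retarder_spec(R = 90, alpha = 95)$alpha, -85)
})

test_that("layered stacks compose in traversal order", {
  expect_equal(layered_mueller(37.87, alpha = 12),
               retarder_mueller(37.87, 12))
  # co-axial layers add their retardances
  expect_equal(layered_mueller(c(30, 45), alpha = c(10, 10)),
               retarder_mueller(75, 10), tolerance = 1e-12)
  # two tilted layers: equivalent retardance from the quaternion oracle
  M2 <- layered_mueller(c(37.87, 37.87), alpha = c(0, 10))
  R_eq <- quat_equivalent_retardance(c(37.87, 37.87), c(0, 10))
  expect_equal(R_eq, 74.55, tolerance = 0.01)
  expect_equal(lc_decompose(M2)$R, R_eq, tolerance = 1e-9)
  # reversed order transposes the polarization block for pure retarders
  Mr <- layered_mueller(c(30, 60), alpha = c(0, 25), reverse = TRUE)
  Mf <- layered_mueller(c(60, 30), alpha = c(25, 0))
  expect_equal(Mr, Mf, tolerance = 1e-14)
  expect_error(layered_mueller(list()), "non-empty")
})

test_that("a stack of pure retarders is itself a pure (elliptical) retarder", {
  for (n in 2:4) {
    M <- layered_mueller(rep(37.87, n), alpha = (0:(n - 1)) * 10)
    fit <- lc_decompose(M)
    expect_lt(fit$D, 1e-9)
    expect_equal(fit$P_d, 1, tolerance = 1e-9)
  }
})

test_that("orientation folding lands in (-90, 90]", {
  expect_equal(fold_orientation(94.3), -85.7)
  expect_equal(fold_orientation(-90), 90)
  expect_equal(fold_orientation(90), 90)
  expect_equal(fold_orientation(180), 0)
})
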