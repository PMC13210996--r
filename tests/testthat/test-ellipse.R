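# Geometric ellipse fitting and I/Q compensation.

test_that("a unit circle is fitted exactly", {
  th <- seq(0, 2 * pi, length.out = 101)[-101]
  fit <- fit_ellipse(complex(real = cos(th), imaginary = sin(th)))
  expect_equal(fit$center, c(0, 0), tolerance = 1e-8)
  expect_equal(fit$semi_axes, c(1, 1), tolerance = 1e-8)
})

test_that("the quadrature-imbalance ellipse is recovered from a dense sweep", {
  imp <- iq_impairments(AI = 1.2, AQ = 0.8, psi_e = 0.3, OI = 0.5, OQ = -0.2)
  psi <- seq(0, 2 * pi, length.out = 720)
  iq <- impaired_iq(psi, imp)
  fit <- fit_ellipse(iq)
  # orthogonal residuals of the generating points against the fit
  expect_lt(max(radarpcg:::.ellipse_residuals(
    c(fit$center, fit$semi_axes, fit$orientation), Re(iq), Im(iq))), 1e-6)
  expect_equal(fit$center, c(0.5, -0.2), tolerance = 1e-6)
})

test_that("degenerate inputs are rejected", {
  t <- seq(0, 1, length.out = 10)
  expect_error(fit_ellipse(complex(real = t, imaginary = 2 * t + 1)),
               "ill-conditioned")
  expect_error(fit_ellipse(complex(real = 1:4, imaginary = 1:4)), "6 samples")
  # short arc: 30 degrees of a circle is not enough
  th <- seq(0, pi / 6, length.out = 50)
  expect_error(fit_ellipse(complex(real = cos(th), imaginary = sin(th))),
               "arc")
})

test_that("compensation restores a circular, order-preserving trajectory", {
  # identity ellipse: compensation is the identity map
  th <- seq(0, 2 * pi, length.out = 200)
  circ <- complex(real = cos(th), imaginary = sin(th))
  ident <- structure(list(center = c(0, 0), semi_axes = c(1, 1),
                          orientation = 0), class = "ellipse_params")
  expect_equal(compensate_iq(circ, ident), circ)

  imp <- iq_impairments(AI = 1.2, AQ = 0.8, psi_e = 0.3, OI = 0.5, OQ = -0.2)
  psi <- seq(0, 2 * pi, length.out = 720)
  iq <- impaired_iq(psi, imp)
  xc <- compensate_iq(iq, fit_ellipse(iq))
  r <- Mod(xc)
  expect_lt(sd(r) / mean(r), 1e-6)
  # monotone psi sweep maps to a monotone trajectory angle
  ang <- radarpcg:::dacm_unwrap(xc)$delta_psi[-1]
  expect_true(all(ang > 0))
  # degenerate minor axis errors
  bad <- structure(list(center = c(0, 0), semi_axes = c(1, 1e-15),
                        orientation = 0), class = "ellipse_params")
  expect_error(compensate_iq(circ, bad), "minor")
})
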