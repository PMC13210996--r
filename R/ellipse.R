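# Geometric ellipse fitting for I/Q imbalance compensation: a numerically
# stable algebraic conic fit initializes Gauss-Newton refinement of the
# orthogonal (point-to-ellipse) distances.

# Distance from points (u, v) >= 0 to the axis-aligned ellipse (a, b), via
# robust bisection on the orthogonal-projection parameter (vectorized).
.ellipse_point_distance <- function(u, v, a, b, iters = 80) {
  u0 <- abs(u); v0 <- abs(v)
  u0 <- pmax(u0, 1e-14); v0 <- pmax(v0, 1e-14)
  lo <- -b^2 + b * v0
  hi <- -b^2 + sqrt(a^2 * u0^2 + b^2 * v0^2)
  for (i in seq_len(iters)) {
    t <- (lo + hi) / 2
    f <- (a * u0 / (t + a^2))^2 + (b * v0 / (t + b^2))^2 - 1
    up <- f > 0
    lo <- ifelse(up, t, lo)
    hi <- ifelse(up, hi, t)
  }
  t <- (lo + hi) / 2
  xe <- a^2 * u0 / (t + a^2)
  ye <- b^2 * v0 / (t + b^2)
  sqrt((u0 - xe)^2 + (v0 - ye)^2)
}

# Orthogonal distances of points to the ellipse given by params
# v = (cx, cy, a, b, theta).
.ellipse_residuals <- function(v, x, y) {
  ct <- cos(v[5]); st <- sin(v[5])
  dx <- x - v[1]; dy <- y - v[2]
  u <- ct * dx + st * dy
  w <- -st * dx + ct * dy
  .ellipse_point_distance(u, w, v[3], v[4])
}

# Algebraic (Halir-Flusser) direct least-squares ellipse fit.
.ellipse_algebraic <- function(x, y) {
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  if (rcond(S3) < 1e-12) stop("ill-conditioned input (degenerate trajectory)")
  Tm <- -solve(S3, t(S2))
  M <- S1 + S2 %*% Tm
  M2 <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M2)
  vecs <- Re(ev$vectors)
  cond <- 4 * vecs[1, ] * vecs[3, ] - vecs[2, ]^2
  ok <- which(cond > 0)
  if (length(ok) == 0) stop("fit did not converge to an ellipse")
  a1 <- vecs[, ok[1]]
  c(a1, Tm %*% a1)   # (A, B, C, D, E, F)
}

# Convert conic coefficients to geometric parameters.
.conic_to_geometric <- function(k) {
  A <- k[1]; B <- k[2]; C <- k[3]; D <- k[4]; E <- k[5]; F <- k[6]
  den <- B^2 - 4 * A * C
  if (den >= 0) stop("fit did not converge to an ellipse")
  cx <- (2 * C * D - B * E) / den
  cy <- (2 * A * E - B * D) / den
  Q <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  M0 <- det(matrix(c(F, D / 2, E / 2, D / 2, A, B / 2, E / 2, B / 2, C), 3, 3))
  eg <- eigen(Q, symmetric = TRUE)
  ax2 <- -M0 / (det(Q) * eg$values)
  if (any(ax2 <= 0)) stop("fit did not converge to an ellipse")
  ax <- sqrt(ax2)
  major_i <- which.max(ax)
  vec <- eg$vectors[, major_i]
  theta <- atan2(vec[2], vec[1]) %% pi
  list(center = c(cx, cy), semi_axes = c(max(ax), min(ax)), orientation = theta)
}

.geom_to_vec <- function(g) c(g$center, g$semi_axes, g$orientation)

#' Fit an ellipse to an I/Q trajectory
#'
#' Estimates the ellipse traced by an imbalanced quadrature receiver:
#' a numerically stable algebraic (conic least-squares) fit provides the
#' starting point for Gauss-Newton refinement of the orthogonal distances
#' between the samples and the ellipse. Refinement stops when the relative
#' cost change drops below `tol` or after `max_iter` iterations.
#'
#' @param iq Complex vector, or a two-column matrix of (I, Q) samples.
#'   At least 6 samples spanning roughly a quarter of the ellipse are needed
#'   for a conditioned fit.
#' @param tol Relative cost-change stopping tolerance (default 1e-10).
#' @param max_iter Maximum Gauss-Newton iterations (default 100).
#'
#' @return An object of class `ellipse_params`: list with `center` (cx, cy),
#'   `semi_axes` (major >= minor), `orientation` (radians in [0, pi)) and
#'   `rms_residual` (root-mean-square orthogonal distance).
#' @export
fit_ellipse <- function(iq, tol = 1e-10, max_iter = 100) {
  if (is.complex(iq)) {
    x <- Re(iq); y <- Im(iq)
  } else {
    x <- iq[, 1]; y <- iq[, 2]
  }
  if (length(x) < 6) stop("need at least 6 samples for an ellipse fit")
  # collinearity check via principal components of the centred cloud
  xc <- x - mean(x); yc <- y - mean(y)
  sv <- svd(cbind(xc, yc), nu = 0, nv = 0)$d
  if (sv[2] < 1e-10 * max(sv[1], 1e-300)) {
    stop("ill-conditioned input (collinear samples)")
  }
  k <- .ellipse_algebraic(x, y)
  g <- .conic_to_geometric(k)

  # arc-coverage check: angular span of the samples as seen from the centre
  ang <- sort(atan2(y - g$center[2], x - g$center[1]))
  gaps <- diff(c(ang, ang[1] + 2 * pi))
  coverage <- 2 * pi - max(gaps)
  if (coverage < pi / 2) {
    stop(sprintf(
      "ill-conditioned input (trajectory spans only %.0f degrees of arc)",
      coverage * 180 / pi))
  }

  v <- .geom_to_vec(g)
  r <- .ellipse_residuals(v, x, y)
  cost <- sum(r^2)
  lambda <- 1e-10
  for (it in seq_len(max_iter)) {
    # numerical Jacobian (central differences)
    J <- matrix(0, length(x), 5)
    for (j in 1:5) {
      h <- max(1e-7 * abs(v[j]), 1e-9)
      vp <- v; vp[j] <- v[j] + h
      vm <- v; vm[j] <- v[j] - h
      J[, j] <- (.ellipse_residuals(vp, x, y) -
                 .ellipse_residuals(vm, x, y)) / (2 * h)
    }
    A <- crossprod(J) + lambda * diag(5)
    step <- tryCatch(solve(A, crossprod(J, r)), error = function(e) NULL)
    if (is.null(step)) break
    vn <- v - as.numeric(step)
    vn[3:4] <- abs(vn[3:4])
    if (vn[3] < vn[4]) {  # keep major >= minor
      vn[3:4] <- vn[4:3]
      vn[5] <- vn[5] + pi / 2
    }
    vn[5] <- vn[5] %% pi
    rn <- .ellipse_residuals(vn, x, y)
    cn <- sum(rn^2)
    if (cn <= cost) {
      improved <- (cost - cn) <= tol * max(cost, 1e-300)
      v <- vn; r <- rn; cost <- cn
      lambda <- max(lambda / 10, 1e-12)
      if (improved) break
    } else {
      lambda <- lambda * 10
      if (lambda > 1e6) break
    }
  }
  if (v[4] <= 0) stop("fit did not converge to an ellipse")
  structure(list(center = v[1:2], semi_axes = v[3:4],
                 orientation = v[5] %% pi,
                 rms_residual = sqrt(mean(r^2))),
            class = "ellipse_params")
}

#' Compensate I/Q imbalance using fitted ellipse parameters
#'
#' Applies the affine map that restores a circular trajectory: translate by
#' the negative centre, rotate the ellipse axes onto the coordinate axes,
#' rescale by the inverse semi-axes, and rotate back. The map has positive
#' determinant, so the rotation sense of the trajectory (and hence the sign
#' of the recovered displacement) is preserved; points lying exactly on the
#' ellipse land on the unit circle.
#'
#' @param iq Complex vector of baseband samples.
#' @param ellipse An `ellipse_params` from [fit_ellipse()].
#' @return Complex vector of compensated samples.
#' @export
compensate_iq <- function(iq, ellipse) {
  a <- ellipse$semi_axes[1]; b <- ellipse$semi_axes[2]
  if (b <= 1e-12 * a) stop("degenerate ellipse: minor axis is ~0")
  th <- ellipse$orientation
  ct <- cos(th); st <- sin(th)
  dx <- Re(iq) - ellipse$center[1]
  dy <- Im(iq) - ellipse$center[2]
  u <- (ct * dx + st * dy) / a
  w <- (-st * dx + ct * dy) / b
  complex(real = ct * u - st * w, imaginary = st * u + ct * w)
}

#' @export
print.ellipse_params <- function(x, ...) {
  cat(sprintf(
    "<ellipse> center (%.4g, %.4g), semi-axes (%.4g, %.4g), orientation %.4g rad, rms residual %.3g\n",
    x$center[1], x$center[2], x$semi_axes[1], x$semi_axes[2],
    x$orientation, x$rms_residual))
  invisible(x)
}
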