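#' Rigid 3D transform
#'
#' Six-parameter rigid transform: ZYX Euler rotation (degrees) about a
#' centre point followed by a translation, `p' = R (p - c) + c + t`.
#'
#' @param rotation_deg Euler angles `c(rx, ry, rz)` in degrees, applied as
#'   `R = Rz %*% Ry %*% Rx`.
#' @param translation_m Translation `c(tx, ty, tz)` in metres.
#' @param center Rotation centre in metres (defaults to the origin; pass
#'   the volume centre for image registration).
#' @return An `rca_rigid`.
#' @export
rigid_transform <- function(rotation_deg = c(0, 0, 0),
                            translation_m = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  stopifnot(length(rotation_deg) == 3, length(translation_m) == 3)
  structure(list(rotation_deg = rotation_deg,
                 translation_m = translation_m, center = center,
                 convention = "ZYX about center"),
            class = "rca_rigid")
}

rotation_matrix_zyx <- function(deg) {
  a <- deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
  Rz %*% Ry %*% Rx
}

euler_zyx_from_matrix <- function(R) {
  ry <- asin(-R[3, 1])
  if (abs(cos(ry)) > 1e-9) {
    rx <- atan2(R[3, 2], R[3, 3])
    rz <- atan2(R[2, 1], R[1, 1])
  } else { # gimbal lock
    rx <- atan2(-R[2, 3], R[2, 2])
    rz <- 0
  }
  c(rx, ry, rz) * 180 / pi
}

#' @rdname rigid_transform
#' @param t An `rca_rigid`.
#' @export
invert_rigid <- function(t) {
  R <- rotation_matrix_zyx(t$rotation_deg)
  rigid_transform(euler_zyx_from_matrix(t(R)),
                  as.numeric(-t(R) %*% t$translation_m), t$center)
}

#' @rdname rigid_transform
#' @param t2,t1 Transforms with the same centre; returns `t2` composed after
#'   `t1`.
#' @export
compose_rigid <- function(t2, t1) {
  stopifnot(max(abs(t2$center - t1$center)) < 1e-12)
  R2 <- rotation_matrix_zyx(t2$rotation_deg)
  R1 <- rotation_matrix_zyx(t1$rotation_deg)
  rigid_transform(euler_zyx_from_matrix(R2 %*% R1),
                  as.numeric(R2 %*% t1$translation_m + t2$translation_m),
                  t1$center)
}

#' @export
print.rca_rigid <- function(x, ...) {
  cat(sprintf("<rca_rigid> rot (%.2f, %.2f, %.2f) deg, trans (%.2f, %.2f, %.2f) mm\n",
              x$rotation_deg[1], x$rotation_deg[2], x$rotation_deg[3],
              x$translation_m[1] * 1e3, x$translation_m[2] * 1e3,
              x$translation_m[3] * 1e3))
  invisible(x)
}

#' Apply a rigid transform to a volume
#'
#' Resamples the volume so its content moves by the transform:
#' `out(p) = vol(T^{-1}(p))`. Voxels mapping outside the original support
#' are zero; the support mask is attached as attribute `inside`.
#'
#' @param volume `rca_volume` or array with `grid`.
#' @param transform An `rca_rigid`.
#' @param grid [voxel_grid()] for bare arrays.
#' @param order Interpolation order: 1 (trilinear) or 3 (Catmull-Rom
#'   tricubic).
#' @return Transformed `rca_volume`.
#' @export
apply_rigid <- function(volume, transform, grid = NULL, order = 3L) {
  if (inherits(volume, "rca_volume")) {
    grid <- volume$grid
    v <- volume$values
  } else v <- volume
  res <- .resample_rigid_cpp(v, dim(v), grid$x, grid$y, grid$z,
                             rotation_matrix_zyx(transform$rotation_deg),
                             transform$translation_m, transform$center,
                             as.integer(order))
  out <- new_volume(array(res$values, dim(v)), grid)
  attr(out, "inside") <- array(res$inside, dim(v))
  out
}

#' Grid centre in physical coordinates
#' @param grid A [voxel_grid()].
#' @return `c(x, y, z)` of the volume centre in metres.
#' @export
grid_center <- function(grid) {
  c(mean(range(grid$x)), mean(range(grid$y)), mean(range(grid$z)))
}

#' Multiscale Hessian vesselness
#'
#' Frangi-style tubularity response for bright 3D tubes: at each scale
#' sigma, the volume is Gaussian-smoothed, the scale-normalised Hessian
#' eigenvalues `|l1| <= |l2| <= |l3|` are computed, and voxels with
#' `l2, l3 < 0` score
#' `(1 - exp(-RA^2 / 2 alpha^2)) * exp(-RB^2 / 2 beta^2) *
#'  (1 - exp(-S^2 / 2 c^2))` with `RA = |l2|/|l3|`,
#' `RB = |l1|/sqrt(|l2 l3|)` and structure energy `S`. The response is the
#' maximum over scales, normalised to `[0, 1]`.
#'
#' @param pd `rca_volume` (e.g. power Doppler) or array with `grid`.
#' @param scales Gaussian scales in metres.
#' @param grid Grid for bare arrays.
#' @param alpha,beta Plate/blob discrimination parameters.
#' @return Vesselness `rca_volume` in `[0, 1]`.
#' @export
vesselness <- function(pd, scales = c(150e-6, 300e-6), grid = NULL,
                       alpha = 0.5, beta = 0.5) {
  if (inherits(pd, "rca_volume")) {
    grid <- pd$grid
    v <- pd$values
  } else v <- pd
  stopifnot(length(scales) >= 1)
  sp <- c(grid$x[2] - grid$x[1], grid$y[2] - grid$y[1],
          grid$z[2] - grid$z[1])
  best <- array(0, dim(v))
  for (s in scales) {
    sm <- gauss_smooth_3d(v, s / sp)
    H <- hessian_3d(sm, sp)
    H <- lapply(H, function(h) h * s^2) # gamma-normalised scale space
    ev <- sym3_eigenvalues(H)
    o <- order_by_abs(ev)
    l1 <- o$l1; l2 <- o$l2; l3 <- o$l3
    S2 <- l1^2 + l2^2 + l3^2
    cpar <- sqrt(max(S2)) / 2
    resp <- array(0, dim(v))
    ok <- l2 < 0 & l3 < 0
    if (any(ok)) {
      RA <- abs(l2[ok]) / pmax(abs(l3[ok]), 1e-30)
      RB <- abs(l1[ok]) / pmax(sqrt(abs(l2[ok] * l3[ok])), 1e-30)
      resp[ok] <- (1 - exp(-RA^2 / (2 * alpha^2))) *
        exp(-RB^2 / (2 * beta^2)) *
        (1 - exp(-S2[ok] / (2 * cpar^2)))
    }
    best <- pmax(best, resp)
  }
  m <- max(best)
  if (m > 0) best <- best / m
  new_volume(best, grid)
}

# separable Gaussian smoothing, sigma per axis in voxels
gauss_smooth_3d <- function(v, sig_vox) {
  for (ax in 1:3) {
    s <- sig_vox[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-(-r:r)^2 / (2 * s^2)); k <- k / sum(k)
    v <- conv_axis_3d(v, k, ax)
  }
  v
}

# convolution along one axis with edge replication
conv_axis_3d <- function(v, k, ax) {
  d <- dim(v)
  perm <- c(ax, setdiff(1:3, ax))
  m <- aperm(v, perm)
  dm <- dim(m)
  dim(m) <- c(dm[1], prod(dm[-1]))
  r <- (length(k) - 1) / 2
  n <- dm[1]
  pad <- rbind(m[rep(1, r), , drop = FALSE], m,
               m[rep(n, r), , drop = FALSE])
  out <- matrix(0, n, ncol(m))
  for (i in seq_along(k)) {
    out <- out + k[i] * pad[i:(i + n - 1), , drop = FALSE]
  }
  dim(out) <- dm
  aperm(out, order(perm))
}

# central-difference Hessian components of a smoothed volume
hessian_3d <- function(v, sp) {
  dxx <- diff2_axis(v, 1) / sp[1]^2
  dyy <- diff2_axis(v, 2) / sp[2]^2
  dzz <- diff2_axis(v, 3) / sp[3]^2
  dx <- diff1_axis(v, 1) / sp[1]
  dxy <- diff1_axis(dx, 2) / sp[2]
  dxz <- diff1_axis(dx, 3) / sp[3]
  dyz <- diff1_axis(diff1_axis(v, 2) / sp[2], 3) / sp[3]
  list(xx = dxx, yy = dyy, zz = dzz, xy = dxy, xz = dxz, yz = dyz)
}

diff1_axis <- function(v, ax) {
  conv_axis_3d(v, c(-0.5, 0, 0.5), ax)
}
diff2_axis <- function(v, ax) {
  conv_axis_3d(v, c(1, -2, 1), ax)
}

# vectorised eigenvalues of symmetric 3x3 matrices (trigonometric method)
sym3_eigenvalues <- function(H) {
  a <- H$xx; b <- H$yy; c3 <- H$zz
  d <- H$xy; e <- H$yz; f <- H$xz
  p1 <- d^2 + f^2 + e^2
  q <- (a + b + c3) / 3
  p2 <- (a - q)^2 + (b - q)^2 + (c3 - q)^2 + 2 * p1
  p <- sqrt(pmax(p2 / 6, 0))
  iso <- p < 1e-300
  p[iso] <- 1
  B11 <- (a - q) / p; B22 <- (b - q) / p; B33 <- (c3 - q) / p
  B12 <- d / p; B13 <- f / p; B23 <- e / p
  detB <- B11 * (B22 * B33 - B23^2) - B12 * (B12 * B33 - B23 * B13) +
    B13 * (B12 * B23 - B22 * B13)
  r <- pmin(pmax(detB / 2, -1), 1)
  phi <- acos(r) / 3
  p[iso] <- 0
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  list(e1 = e1, e2 = e2, e3 = e3)
}

order_by_abs <- function(ev) {
  d <- dim(ev$e1) %||% length(ev$e1)
  E <- cbind(as.numeric(ev$e1), as.numeric(ev$e2), as.numeric(ev$e3))
  o <- t(apply(abs(E), 1, order))
  n <- nrow(E)
  idx <- function(k) E[cbind(seq_len(n), o[, k])]
  l1 <- array(idx(1), d); l2 <- array(idx(2), d); l3 <- array(idx(3), d)
  list(l1 = l1, l2 = l2, l3 = l3)
}

#' Threshold vesselness into a binary vessel map
#'
#' Voxels above the threshold, with connected components smaller than
#' `min_voxels` removed (6-connectivity).
#'
#' @param response Vesselness `rca_volume` (values in `[0, 1]`).
#' @param threshold Fraction in (0, 1).
#' @param min_voxels Minimum component size retained.
#' @return Logical array.
#' @export
segment_vessels <- function(response, threshold = 0.2, min_voxels = 27L) {
  stopifnot(threshold > 0, threshold <= 1)
  v <- if (inherits(response, "rca_volume")) response$values else response
  m <- v > threshold
  if (any(m)) {
    lab <- .label_components_cpp(m, dim(m))
    sizes <- tabulate(lab)
    small <- which(sizes < min_voxels)
    if (length(small)) m[lab %in% small] <- FALSE
  }
  if (!any(m)) stop("empty segmentation at threshold ", threshold,
                    call. = FALSE)
  m
}

#' Rigid registration of two volumes
#'
#' Estimates the 6-DOF rigid transform aligning `moving` to `fixed` by
#' maximising normalised cross-correlation over the common support, with a
#' coarse-to-fine search: Nelder-Mead on a 2x-downsampled pair, then
#' refinement at full resolution. Deterministic for a fixed `init`.
#'
#' @param moving,fixed `rca_volume`s on the same grid spacing.
#' @param init Initial `rca_rigid` (defaults to identity about the volume
#'   centre).
#' @param maxit Iterations per level.
#' @return List with `transform` (`rca_rigid`), `converged`, `ncc` (final
#'   correlation), and the optimiser value trace.
#' @export
register_rigid <- function(moving, fixed, init = NULL, maxit = 300) {
  stopifnot(inherits(moving, "rca_volume"), inherits(fixed, "rca_volume"))
  grid <- fixed$grid
  ctr <- grid_center(grid)
  if (is.null(init)) init <- rigid_transform(center = ctr)
  p0 <- c(init$rotation_deg, init$translation_m)

  cost_fn <- function(mv, fx, g) {
    force(mv); force(fx); force(g)
    function(p) {
      tf <- rigid_transform(p[1:3], p[4:6], ctr)
      w <- apply_rigid(mv, tf, g, order = 1L)
      ins <- attr(w, "inside")
      if (sum(ins) < 10) return(1)
      a <- w$values[ins]; b <- fx[ins]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) return(1)
      -stats::cor(a, b)
    }
  }
  # coarse level: 2x block-mean downsample
  dsg <- downsample2(moving$values, grid)
  dsf <- downsample2(fixed$values, grid)
  coarse_cost <- cost_fn(new_volume(dsg$v, dsg$g), dsf$v, dsg$g)
  # deterministic translation grid search seeds the simplex (the NCC
  # surface has shallow local minima once structures stop overlapping)
  sp <- c(if (length(grid$x) > 1) grid$x[2] - grid$x[1] else 1e-4,
          if (length(grid$y) > 1) grid$y[2] - grid$y[1] else 1e-4,
          if (length(grid$z) > 1) grid$z[2] - grid$z[1] else 1e-4)
  steps <- -3:3
  best <- list(par = p0, val = coarse_cost(p0))
  for (dx in steps) for (dy in steps) for (dz in -1:1) {
    p <- p0 + c(0, 0, 0, dx * 2 * sp[1], dy * 2 * sp[2], dz * 2 * sp[3])
    v <- coarse_cost(p)
    if (v < best$val) best <- list(par = p, val = v)
  }
  scl <- c(rep(2, 3), 4 * sp) # degrees vs metres parameter scales
  o1 <- stats::optim(best$par, coarse_cost, method = "Nelder-Mead",
                     control = list(maxit = maxit, parscale = scl,
                                    reltol = 1e-9))
  fine_cost <- cost_fn(moving, fixed$values, grid)
  o2 <- stats::optim(o1$par, fine_cost, method = "Nelder-Mead",
                     control = list(maxit = 2 * maxit,
                                    parscale = scl / 4, reltol = 1e-10))
  # fresh-simplex restart tightens the final estimate
  o3 <- stats::optim(o2$par, fine_cost, method = "Nelder-Mead",
                     control = list(maxit = maxit,
                                    parscale = scl / 16, reltol = 1e-12))
  tf <- rigid_transform(o3$par[1:3], o3$par[4:6], ctr)
  list(transform = tf, converged = -o3$value > 0.3,
       ncc = -o3$value, coarse_ncc = -o1$value)
}

downsample2 <- function(v, grid) {
  d <- dim(v)
  d2 <- pmax(d %/% 2, 1)
  out <- array(0, d2)
  for (ix in seq_len(d2[1])) for (iy in seq_len(d2[2])) {
    xs <- (2 * ix - 1):min(2 * ix, d[1])
    ys <- (2 * iy - 1):min(2 * iy, d[2])
    for (iz in seq_len(d2[3])) {
      zs <- (2 * iz - 1):min(2 * iz, d[3])
      out[ix, iy, iz] <- mean(v[xs, ys, zs])
    }
  }
  g2 <- voxel_grid(colMeans(matrix(grid$x[1:(2 * d2[1])], 2))[seq_len(d2[1])],
                   colMeans(matrix(grid$y[1:(2 * d2[2])], 2))[seq_len(d2[2])],
                   colMeans(matrix(grid$z[1:(2 * d2[3])], 2))[seq_len(d2[3])])
  list(v = out, g = g2)
}

#' Pearson correlation of two volumes over a mask
#'
#' @param a,b `rca_volume`s or arrays.
#' @param mask Logical array of the common support (defaults to all
#'   voxels).
#' @return Correlation coefficient.
#' @export
pearson_corr_volumes <- function(a, b, mask = NULL) {
  va <- if (inherits(a, "rca_volume")) a$values else a
  vb <- if (inherits(b, "rca_volume")) b$values else b
  if (is.null(mask)) mask <- array(TRUE, dim(va))
  stopifnot(any(mask))
  x <- va[mask]; y <- vb[mask]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero-variance input", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Common volume fraction under a rigid transform
#'
#' Fraction of the field of view still inside itself after the transform,
#' evaluated on a deterministic fine point lattice.
#'
#' @param transform An `rca_rigid`.
#' @param fov List with `x`, `y`, `z` ranges in metres.
#' @param n Lattice points per axis.
#' @return Fraction in `[0, 1]`.
#' @export
common_volume_fraction <- function(transform, fov, n = 64L) {
  cell <- function(r) r[1] + (seq_len(n) - 0.5) * (r[2] - r[1]) / n
  gx <- cell(fov$x); gy <- cell(fov$y); gz <- cell(fov$z)
  pts <- as.matrix(expand.grid(gx, gy, gz))
  R <- rotation_matrix_zyx(transform$rotation_deg)
  ctr <- transform$center
  moved <- t(R %*% (t(pts) - ctr) + ctr + transform$translation_m)
  inside <- moved[, 1] >= fov$x[1] & moved[, 1] <= fov$x[2] &
    moved[, 2] >= fov$y[1] & moved[, 2] <= fov$y[2] &
    moved[, 3] >= fov$z[1] & moved[, 3] <= fov$z[2]
  mean(inside)
}
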