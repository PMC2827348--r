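# Internal 3-D geometry helpers. All coordinates in Angstrom, row-per-point
# matrices with 3 columns.

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Place atom D given positions A, B, C, the bond length |C-D|, the angle
# B-C-D (degrees) and the torsion A-B-C-D (degrees). Standard internal-to-
# Cartesian (NeRF) construction.
nerf_place <- function(A, B, C, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  d_local <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  bc <- unit(C - B)
  n <- unit(cross3(B - A, bc))
  m <- cbind(bc, cross3(n, bc), n)
  C + as.vector(m %*% d_local)
}

# Optimal rigid transform (rotation R, translation t) mapping point set X
# onto Y in the least-squares sense (Kabsch, via SVD).
rigid_fit <- function(X, Y) {
  cx <- colMeans(X)
  cy <- colMeans(Y)
  H <- t(sweep(X, 2, cx)) %*% sweep(Y, 2, cy)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = R, t = cy - as.vector(R %*% cx))
}

apply_rigid <- function(X, fit) {
  sweep(X %*% t(fit$R), 2, fit$t, "+")
}

# Rotation matrix for angle deg (degrees) about unit axis.
rotation_about <- function(axis, deg) {
  a <- unit(axis)
  th <- deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Cumulative arclength of a polyline (n x 3 matrix); first entry 0.
arclength <- function(axis) {
  if (nrow(axis) < 2) return(0)
  d <- sqrt(rowSums((axis[-1, , drop = FALSE] - axis[-nrow(axis), , drop = FALSE])^2))
  c(0, cumsum(d))
}

# Resample a polyline at uniform arclength step; returns list(points, s).
resample_polyline <- function(axis, step) {
  s <- arclength(axis)
  L <- s[length(s)]
  if (L <= 0) return(list(points = axis[1, , drop = FALSE], s = 0))
  sq <- seq(0, L, by = step)
  if (sq[length(sq)] < L - 1e-9) sq <- c(sq, L)
  pts <- cbind(approx(s, axis[, 1], xout = sq)$y,
               approx(s, axis[, 2], xout = sq)$y,
               approx(s, axis[, 3], xout = sq)$y)
  list(points = pts, s = sq)
}

# Unit tangents of a polyline by central differences.
polyline_tangents <- function(pts) {
  n <- nrow(pts)
  if (n < 2) stop("need at least 2 points for tangents")
  fwd <- rbind(pts[-1, , drop = FALSE], pts[n, , drop = FALSE]) -
    rbind(pts[1, , drop = FALSE], pts[-n, , drop = FALSE])
  t(apply(fwd, 1, unit))
}

# Parallel-transport a reference direction along a polyline: at each point
# project the previous frame vector out of the local tangent and normalize.
# Returns n x 3 matrix of unit vectors perpendicular to the local tangent.
transport_normal <- function(pts, ref) {
  tg <- polyline_tangents(pts)
  n <- nrow(pts)
  out <- matrix(0, n, 3)
  v <- ref
  for (i in seq_len(n)) {
    w <- v - sum(v * tg[i, ]) * tg[i, ]
    if (vnorm(w) < 1e-8) w <- v  # degenerate: keep previous
    v <- unit(w)
    out[i, ] <- v
  }
  out
}

# Minimum distance between two polylines by dense resampling; returns
# list(dist, p1, p2) with the closest sampled points.
polyline_min_dist <- function(a, b, step = 0.25) {
  pa <- resample_polyline(a, step)$points
  pb <- resample_polyline(b, step)$points
  # squared distance matrix via outer sums
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)
  idx <- arrayInd(which.min(d2), dim(d2))
  list(dist = sqrt(max(0, d2[idx])), p1 = pa[idx[1], ], p2 = pb[idx[2], ])
}

# Smooth a polyline to its midline with a running mean over +/- window/2
# of arclength, truncated symmetrically near the ends (end points stay
# put). A window of one strand period removes the backbone pleat zigzag
# while keeping gentle sheet-perpendicular curvature.
smooth_axis <- function(axis, window = 6.7, step = 0.25) {
  if (nrow(axis) < 3) return(axis)
  rs <- resample_polyline(axis, step)
  s <- rs$s; p <- rs$points
  L <- s[length(s)]
  out <- p
  for (i in seq_along(s)) {
    h <- min(window / 2, s[i], L - s[i])
    sel <- which(s >= s[i] - h & s <= s[i] + h)
    out[i, ] <- colMeans(p[sel, , drop = FALSE])
  }
  out
}

circ_dist <- function(a, b, period = 1) {
  d <- (a - b) %% period
  pmin(d, period - d)
}
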