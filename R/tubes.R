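# Stage 1: locate beta-sheet strands as nearly parallel tubes of density.
# Ridgeline points are local density maxima in the plane perpendicular to
# the direction of least curvature; connected points form tubes; nearby
# nearly parallel tube pairs with no density bridge between them are the
# sheet signature.

#' Connection-test parameters
#'
#' Two ridge points count as connected when the density sampled along the
#' joining line never drops below \code{cut1} times the higher endpoint
#' density and its mean is at least \code{cut2} times that value.
#'
#' @param cut1 minimum-density ratio (default 0.5).
#' @param cut2 mean-density ratio (default 0.75).
#' @param line_step sampling step along the line, A (default 0.25).
#' @return A \code{conn_params} list.
#' @export
conn_params <- function(cut1 = 0.5, cut2 = 0.75, line_step = 0.25) {
  stopifnot(cut1 > 0, cut1 <= cut2, cut2 <= 1, line_step > 0)
  structure(list(cut1 = cut1, cut2 = cut2, line_step = line_step),
            class = "conn_params")
}

#' Tube-pairing and scoring parameters
#'
#' @param min_cos minimum |cosine| between paired tube axes (default 0.5).
#' @param target_sep expected inter-strand separation, A (default 4.5).
#' @param sep_tol tolerance on the separation, A (default 2.0).
#' @param cc_strand_min minimum correlation with the ideal tube template
#'   below which a tube is discarded (default 0.5).
#' @param tube_radius radius at which the ideal tube template falls to
#'   zero, A (default 1.5).
#' @param min_tube_len minimum axis length before pairing, A (default 4).
#' @return A \code{pair_params} list.
#' @export
pair_params <- function(min_cos = 0.5, target_sep = 4.5, sep_tol = 2.0,
                        cc_strand_min = 0.5, tube_radius = 1.5,
                        min_tube_len = 4) {
  stopifnot(min_cos > 0, min_cos < 1, sep_tol < target_sep)
  structure(list(min_cos = min_cos, target_sep = target_sep,
                 sep_tol = sep_tol, cc_strand_min = cc_strand_min,
                 tube_radius = tube_radius, min_tube_len = min_tube_len),
            class = "pair_params")
}

new_tube <- function(axis, density) {
  structure(list(axis = axis, point_density = density,
                 mean_axis_density = mean(density),
                 tube_cc = NA_real_, score = NA_real_,
                 neighbour_dir = NULL, rejected = FALSE),
            class = "tube_segment")
}

#' @export
print.tube_segment <- function(x, ...) {
  cat(sprintf("tube_segment: %d axis points, length %.1f A, mean density %.2f sigma",
              nrow(x$axis), tube_length(x), x$mean_axis_density))
  if (!is.na(x$tube_cc)) cat(sprintf(", cc %.2f, score %.2f", x$tube_cc, x$score))
  cat("\n")
  invisible(x)
}

tube_length <- function(tube) {
  s <- arclength(tube$axis)
  s[length(s)]
}

tube_direction <- function(tube) {
  unit(tube$axis[nrow(tube$axis), ] - tube$axis[1, ])
}

#' Find ridgeline points of high density
#'
#' Returns points that are local density maxima in the plane
#' perpendicular to the local ridge direction (the eigenvector of the
#' density Hessian with the least negative curvature), refined to the
#' ridge by one Newton step in that plane and thinned greedily by
#' descending density to the requested spacing.
#'
#' @param grid a normalized \code{density_grid}.
#' @param spacing target spacing between emitted points, A (default 2).
#' @param density_floor minimum density in sigma units (default 1).
#' @return data.frame with columns x, y, z, density (possibly 0 rows).
#' @export
find_ridgeline_points <- function(grid, spacing = 2.0, density_floor = 1.0) {
  v <- grid$values
  d <- grid$dims
  sp <- grid$spacing
  empty <- data.frame(x = numeric(), y = numeric(), z = numeric(),
                      density = numeric())
  if (all(d < 3)) return(empty)
  idx <- which(v >= density_floor, arr.ind = TRUE)
  keep <- idx[, 1] > 1 & idx[, 1] < d[1] & idx[, 2] > 1 & idx[, 2] < d[2] &
          idx[, 3] > 1 & idx[, 3] < d[3]
  idx <- idx[keep, , drop = FALSE]
  if (nrow(idx) == 0) return(empty)

  sh <- function(di, dj, dk) v[cbind(idx[, 1] + di, idx[, 2] + dj, idx[, 3] + dk)]
  v0 <- sh(0, 0, 0)
  # central-difference gradient and Hessian in world (A) units
  gx <- (sh(1, 0, 0) - sh(-1, 0, 0)) / (2 * sp[1])
  gy <- (sh(0, 1, 0) - sh(0, -1, 0)) / (2 * sp[2])
  gz <- (sh(0, 0, 1) - sh(0, 0, -1)) / (2 * sp[3])
  hxx <- (sh(1, 0, 0) - 2 * v0 + sh(-1, 0, 0)) / sp[1]^2
  hyy <- (sh(0, 1, 0) - 2 * v0 + sh(0, -1, 0)) / sp[2]^2
  hzz <- (sh(0, 0, 1) - 2 * v0 + sh(0, 0, -1)) / sp[3]^2
  hxy <- (sh(1, 1, 0) - sh(1, -1, 0) - sh(-1, 1, 0) + sh(-1, -1, 0)) /
    (4 * sp[1] * sp[2])
  hxz <- (sh(1, 0, 1) - sh(1, 0, -1) - sh(-1, 0, 1) + sh(-1, 0, -1)) /
    (4 * sp[1] * sp[3])
  hyz <- (sh(0, 1, 1) - sh(0, 1, -1) - sh(0, -1, 1) + sh(0, -1, -1)) /
    (4 * sp[2] * sp[3])

  world <- sweep(sweep(idx - 1, 2, sp, "*"), 2, grid$origin, "+")
  h <- 0.5 * min(sp)
  cand <- matrix(NA_real_, nrow(idx), 4)
  nc <- 0
  for (r in seq_len(nrow(idx))) {
    H <- matrix(c(hxx[r], hxy[r], hxz[r],
                  hxy[r], hyy[r], hyz[r],
                  hxz[r], hyz[r], hzz[r]), 3, 3)
    e <- eigen(H, symmetric = TRUE)
    if (e$values[2] >= 0) next  # need two negative curvatures across the ridge
    E <- e$vectors[, 2:3]
    # Newton step toward the ridge within the perpendicular plane
    g2 <- crossprod(E, c(gx[r], gy[r], gz[r]))
    H2 <- crossprod(E, H %*% E)
    delta <- tryCatch(-solve(H2, g2), error = function(e) c(0, 0))
    if (sqrt(sum(delta^2)) > h) delta <- delta * h / sqrt(sum(delta^2))
    p <- world[r, ] + as.vector(E %*% delta)
    dens <- interpolate_map(grid, p)
    if (dens < density_floor) next
    # plane-perpendicular local maximum check: the point must dominate
    # rings of probes out to the expected tube radius, which rejects thin
    # series-termination side ridges flanking a strong tube
    az <- seq(0, 2 * pi, length.out = 9)[-9]
    ring <- do.call(rbind, lapply(c(h, 0.75, 1.5), function(r)
      t(p + E %*% rbind(r * cos(az), r * sin(az)))))
    if (any(interpolate_map(grid, ring) > dens + 1e-9)) next
    nc <- nc + 1
    cand[nc, ] <- c(p, dens)
  }
  if (nc == 0) return(empty)
  cand <- cand[seq_len(nc), , drop = FALSE]
  # greedy thinning by descending density
  min_sep <- max(1.4, 0.7 * spacing)
  ord <- order(-cand[, 4])
  keep_idx <- integer(0)
  for (r in ord) {
    if (length(keep_idx) == 0 ||
        min(sqrt(colSums((t(cand[keep_idx, 1:3, drop = FALSE]) - cand[r, 1:3])^2))) >= min_sep)
      keep_idx <- c(keep_idx, r)
  }
  out <- as.data.frame(cand[keep_idx, , drop = FALSE])
  names(out) <- c("x", "y", "z", "density")
  out
}

#' Test whether two points are connected by high density
#'
#' Samples the map along the straight line between the points (clamping
#' densities at zero). The points are connected when the minimum sampled
#' density is at least \code{cut1} and the mean at least \code{cut2}
#' times the higher of the two endpoint densities. The minimum is
#' refined by local 0.05 A re-sampling around the coarse minimum.
#'
#' @param grid a \code{density_grid}.
#' @param p1,p2 numeric length-3 positions (A).
#' @param params a \code{conn_params}.
#' @return logical; \code{TRUE} for coincident points.
#' @export
points_connected <- function(grid, p1, p2, params = conn_params()) {
  p1 <- as.numeric(p1); p2 <- as.numeric(p2)
  d <- vnorm(p2 - p1)
  if (d < 1e-9) return(TRUE)
  n <- max(2L, ceiling(d / params$line_step) + 1L)
  tt <- seq(0, 1, length.out = n)
  pts <- outer(tt, p2 - p1) + rep(p1, each = n)
  rho <- pmax(0, interpolate_map(grid, pts))
  rho_max <- max(rho[1], rho[n])
  imin <- which.min(rho)
  lo <- max(0, tt[imin] - 1 / (n - 1))
  hi <- min(1, tt[imin] + 1 / (n - 1))
  nf <- max(3L, ceiling((hi - lo) * d / 0.05) + 1L)
  tf <- seq(lo, hi, length.out = nf)
  rho_fine <- pmax(0, interpolate_map(grid, outer(tf, p2 - p1) + rep(p1, each = nf)))
  rho_min <- min(rho, rho_fine)
  rho_min >= rho_max * params$cut1 - 1e-12 &&
    mean(rho) >= rho_max * params$cut2 - 1e-12
}

# Vectorized connection test for many point pairs (matrices n x 3).
# No minimum refinement: used for bulk tube building.
points_connected_many <- function(grid, P1, P2, params = conn_params()) {
  k <- nrow(P1)
  if (k == 0) return(logical(0))
  d <- sqrt(rowSums((P2 - P1)^2))
  n <- max(2L, ceiling(max(d) / params$line_step) + 1L)
  rho_min <- rep(Inf, k); rho_sum <- rep(0, k)
  rho_ends <- matrix(0, k, 2)
  for (s in seq_len(n)) {
    tt <- (s - 1) / (n - 1)
    rho <- pmax(0, interpolate_map(grid, P1 + tt * (P2 - P1)))
    rho_min <- pmin(rho_min, rho)
    rho_sum <- rho_sum + rho
    if (s == 1) rho_ends[, 1] <- rho
    if (s == n) rho_ends[, 2] <- rho
  }
  rho_max <- pmax(rho_ends[, 1], rho_ends[, 2])
  rho_mean <- rho_sum / n
  (rho_min >= rho_max * params$cut1 - 1e-12) &
    (rho_mean >= rho_max * params$cut2 - 1e-12) |
    d < 1e-9
}

#' Build tubes of density from ridgeline points
#'
#' Enumerates connected point pairs within \code{max_link} A and merges
#' mutually aligned connections (pairwise cosine at least
#' \code{min_cos}) into polyline tube segments. Connections are
#' processed by descending mean endpoint density, shorter links first on
#' ties, which keeps chains on nearest-neighbour steps.
#'
#' @param points data.frame from \code{\link{find_ridgeline_points}}.
#' @param grid the \code{density_grid}.
#' @param conn a \code{conn_params}.
#' @param min_cos alignment threshold for merging connections.
#' @param max_link maximum link length considered, A.
#' @return list of \code{tube_segment} objects (each >= 2 points).
#' @export
build_tubes <- function(points, grid, conn = conn_params(), min_cos = 0.5,
                        max_link = 4.2) {
  np <- nrow(points)
  if (np < 2) return(list())
  P <- as.matrix(points[, c("x", "y", "z")])
  dens <- points$density
  pr <- which(upper.tri(matrix(0, np, np)), arr.ind = TRUE)
  dd <- sqrt(rowSums((P[pr[, 1], , drop = FALSE] - P[pr[, 2], , drop = FALSE])^2))
  sel <- dd <= max_link & dd > 1e-6
  pr <- pr[sel, , drop = FALSE]
  dd <- dd[sel]
  if (nrow(pr) == 0) return(list())
  ok <- points_connected_many(grid, P[pr[, 1], , drop = FALSE],
                              P[pr[, 2], , drop = FALSE], conn)
  pr <- pr[ok, , drop = FALSE]
  dd <- dd[ok]
  if (nrow(pr) == 0) return(list())
  md <- (dens[pr[, 1]] + dens[pr[, 2]]) / 2
  ord <- order(-md, dd, pr[, 1], pr[, 2])
  pr <- pr[ord, , drop = FALSE]

  chains <- list()
  chain_of <- integer(np)      # 0 = unused; else chain index
  pos_of <- integer(np)        # position within chain
  term_dir <- function(ch, at_start) {
    q <- chains[[ch]]
    if (at_start) unit(P[q[1], ] - P[q[2], ]) else unit(P[q[length(q)], ] - P[q[length(q) - 1], ])
  }
  aligned <- function(vec, dir) sum(vec * dir) >= min_cos
  for (e in seq_len(nrow(pr))) {
    a <- pr[e, 1]; b <- pr[e, 2]
    ca <- chain_of[a]; cb <- chain_of[b]
    if (ca == 0 && cb == 0) {
      chains[[length(chains) + 1]] <- c(a, b)
      chain_of[c(a, b)] <- length(chains)
      pos_of[a] <- 1; pos_of[b] <- 2
    } else if (ca != 0 && cb == 0) {
      q <- chains[[ca]]
      if (a == q[1] && aligned(unit(P[b, ] - P[a, ]), term_dir(ca, TRUE))) {
        chains[[ca]] <- c(b, q); chain_of[b] <- ca
      } else if (a == q[length(q)] && aligned(unit(P[b, ] - P[a, ]), term_dir(ca, FALSE))) {
        chains[[ca]] <- c(q, b); chain_of[b] <- ca
      }
    } else if (ca == 0 && cb != 0) {
      q <- chains[[cb]]
      if (b == q[1] && aligned(unit(P[a, ] - P[b, ]), term_dir(cb, TRUE))) {
        chains[[cb]] <- c(a, q); chain_of[a] <- cb
      } else if (b == q[length(q)] && aligned(unit(P[a, ] - P[b, ]), term_dir(cb, FALSE))) {
        chains[[cb]] <- c(q, a); chain_of[a] <- cb
      }
    } else if (ca != cb) {
      qa <- chains[[ca]]; qb <- chains[[cb]]
      a_start <- a == qa[1]; a_end <- a == qa[length(qa)]
      b_start <- b == qb[1]; b_end <- b == qb[length(qb)]
      if ((a_start || a_end) && (b_start || b_end)) {
        v <- unit(P[b, ] - P[a, ])
        if (aligned(v, term_dir(ca, a_start)) &&
            aligned(-v, term_dir(cb, b_start))) {
          qa2 <- if (a_end) qa else rev(qa)
          qb2 <- if (b_start) qb else rev(qb)
          chains[[ca]] <- c(qa2, qb2)
          chain_of[qb2] <- ca
          chains[[cb]] <- integer(0)
        }
      }
    }
  }
  chains <- Filter(function(q) length(q) >= 2, chains)
  lapply(chains, function(q) new_tube(P[q, , drop = FALSE], dens[q]))
}

#' Find nearly parallel tube pairs
#'
#' A pair is retained when the tube axes are nearly parallel (|cosine|
#' at least \code{min_cos}; antiparallel counts, adjacent strands may
#' run either way), the closest approach lies in the
#' \code{target_sep +/- sep_tol} window, and there is no high-density
#' connection across the gap at closest approach. Each retained tube is
#' annotated with \code{neighbour_dir}, the direction toward the
#' highest-density partner at closest approach, projected perpendicular
#' to its axis.
#'
#' @param tubes list of \code{tube_segment}.
#' @param grid the \code{density_grid}.
#' @param params a \code{pair_params}.
#' @param conn a \code{conn_params} for the cross-gap connection test.
#' @return list with \code{pairs} (two-column matrix of tube indices)
#'   and \code{tubes} (annotated list).
#' @export
find_parallel_pairs <- function(tubes, grid, params = pair_params(),
                                conn = conn_params()) {
  nt <- length(tubes)
  pairs <- matrix(integer(0), 0, 2)
  info <- list()
  if (nt >= 2) {
    ok_len <- vapply(tubes, tube_length, 0) >= params$min_tube_len
    for (i in seq_len(nt - 1)) for (j in (i + 1):nt) {
      if (!ok_len[i] || !ok_len[j]) next
      cosang <- abs(sum(tube_direction(tubes[[i]]) * tube_direction(tubes[[j]])))
      if (cosang < params$min_cos) next
      cl <- polyline_min_dist(tubes[[i]]$axis, tubes[[j]]$axis)
      if (cl$dist < params$target_sep - params$sep_tol ||
          cl$dist > params$target_sep + params$sep_tol) next
      if (points_connected(grid, cl$p1, cl$p2, conn)) next
      pairs <- rbind(pairs, c(i, j))
      info[[length(info) + 1]] <- cl
    }
  }
  # neighbour_dir: toward the highest-density partner at closest approach
  if (nrow(pairs) > 0) {
    for (k in seq_len(nt)) {
      rows <- which(pairs[, 1] == k | pairs[, 2] == k)
      if (length(rows) == 0) next
      partners <- ifelse(pairs[rows, 1] == k, pairs[rows, 2], pairs[rows, 1])
      best <- rows[which.max(vapply(partners, function(p) tubes[[p]]$mean_axis_density, 0))]
      cl <- info[[best]]
      from <- if (pairs[best, 1] == k) cl$p1 else cl$p2
      to <- if (pairs[best, 1] == k) cl$p2 else cl$p1
      v <- to - from
      ax <- tube_direction(tubes[[k]])
      v <- v - sum(v * ax) * ax
      tubes[[k]]$neighbour_dir <- unit(v)
    }
  }
  list(pairs = pairs, tubes = tubes)
}

#' Extend a tube into the available density
#'
#' Grows the tube axis from both ends in fixed steps, allowing bends
#' only in the plane spanned by the local axis direction and the
#' sheet-perpendicular (axis x neighbour direction) -- the direction in
#' which beta-sheet strands naturally curve. Growth stops when the best
#' candidate density falls below \code{cut1} times the seed tube's mean
#' axis density.
#'
#' @param grid the \code{density_grid}.
#' @param tube a \code{tube_segment} with \code{neighbour_dir} set.
#' @param step growth step, A (default 1).
#' @param max_bend_deg bend limit per step, degrees (default 15).
#' @param bend_step_deg candidate bend increment, degrees (default 5).
#' @param conn a \code{conn_params} (supplies \code{cut1}).
#' @param max_steps growth cap per end.
#' @return The extended \code{tube_segment}.
#' @export
extend_tube <- function(grid, tube, step = 1.0, max_bend_deg = 15,
                        bend_step_deg = 5, conn = conn_params(),
                        max_steps = 40) {
  if (is.null(tube$neighbour_dir))
    stop("extend_tube requires a tube with a paired neighbour")
  thresh <- conn$cut1 * mean(pmax(0, interpolate_map(grid, tube$axis)))
  angles <- seq(-max_bend_deg, max_bend_deg, by = bend_step_deg) * pi / 180
  grow <- function(axis, densities) {
    for (it in seq_len(max_steps)) {
      n <- nrow(axis)
      tg <- unit(axis[n, ] - axis[n - 1, ])
      nb <- tube$neighbour_dir - sum(tube$neighbour_dir * tg) * tg
      if (vnorm(nb) < 1e-8) break
      u <- unit(cross3(tg, unit(nb)))
      cand <- t(vapply(angles, function(a)
        axis[n, ] + step * (cos(a) * tg + sin(a) * u), numeric(3)))
      rho <- pmax(0, interpolate_map(grid, cand))
      best <- which.max(rho)
      if (rho[best] < thresh || rho[best] <= 0) break
      axis <- rbind(axis, cand[best, ])
      densities <- c(densities, rho[best])
    }
    list(axis = axis, densities = densities)
  }
  fwd <- grow(tube$axis, tube$point_density)
  rev_in <- list(axis = fwd$axis[rev(seq_len(nrow(fwd$axis))), , drop = FALSE],
                 densities = rev(fwd$densities))
  bwd <- grow(rev_in$axis, rev_in$densities)
  axis <- bwd$axis[rev(seq_len(nrow(bwd$axis))), , drop = FALSE]
  out <- tube
  out$axis <- axis
  out$point_density <- rev(bwd$densities)
  out$mean_axis_density <- mean(out$point_density)
  out
}

#' Score a tube against the ideal tube template
#'
#' Computes the Pearson correlation between map density and an ideal
#' tube (density 1 on the axis falling linearly to 0 at
#' \code{tube_radius}) over a cylindrical sample lattice (radius up to
#' 2.5 A, axial step 0.5 A, 8 azimuths), and the tube score: mean
#' interpolated axis density times the square root of the axis length.
#' Tubes with correlation below \code{cc_strand_min} are marked
#' rejected.
#'
#' @param grid the \code{density_grid}.
#' @param tube a \code{tube_segment} of axis length >= 3 A.
#' @param params a \code{pair_params}.
#' @return The tube with \code{tube_cc}, \code{score} and
#'   \code{rejected} filled in.
#' @export
score_tube <- function(grid, tube, params = pair_params()) {
  L <- tube_length(tube)
  if (L < 3) stop("tube axis shorter than 3 A cannot be scored")
  rs <- resample_polyline(tube$axis, 0.5)
  pts <- rs$points
  ref <- tube$neighbour_dir %||% pick_perpendicular(tube_direction(tube))
  nn <- transport_normal(pts, ref)
  tg <- polyline_tangents(pts)
  radii <- seq(0.5, 2.5, by = 0.5)
  az <- seq(0, 2 * pi, length.out = 9)[-9]
  map_v <- numeric(0); tpl_v <- numeric(0)
  axis_rho <- interpolate_map(grid, pts)
  map_v <- axis_rho
  tpl_v <- rep(1, nrow(pts))
  for (r in radii) {
    tpl <- max(0, 1 - r / params$tube_radius)
    for (a in az) {
      b <- t(vapply(seq_len(nrow(pts)),
                    function(i) cross3(tg[i, ], nn[i, ]), numeric(3)))
      probe <- pts + r * (cos(a) * nn + sin(a) * b)
      map_v <- c(map_v, interpolate_map(grid, probe))
      tpl_v <- c(tpl_v, rep(tpl, nrow(pts)))
    }
  }
  cc <- if (stats::sd(map_v) < 1e-12 || stats::sd(tpl_v) < 1e-12) 0
        else stats::cor(map_v, tpl_v)
  tube$tube_cc <- cc
  tube$mean_axis_density <- mean(axis_rho)
  tube$score <- mean(axis_rho) * sqrt(L)
  tube$rejected <- cc < params$cc_strand_min
  tube
}

pick_perpendicular <- function(v) {
  a <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unit(cross3(v, a))
}
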