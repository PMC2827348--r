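# Stage 2: strand register and direction. Density near a tube axis is
# averaged over all 6.7 A strand repeats; the carbonyl-O positions show up
# as the density maximum ~1.5 A off-axis toward the neighbouring strand,
# offset by half a period on the far side, and the C-beta density
# (sheet-perpendicular) is offset by a third of a period from the
# carbonyls. The phase pattern fixes both register and chain direction.

#' Register-search parameters
#'
#' @param period beta-strand two-residue repeat, A (default 6.7).
#' @param probe_radius off-axis probe distance, A (default 1.5).
#' @param phase_tol phase agreement tolerance as a fraction of the
#'   period (default 1/12).
#' @param n_phase_bins phase bins per period (default 36).
#' @param smoothing circular boxcar width in bins applied to profiles
#'   before peak picking (default 3).
#' @return A \code{register_params} list.
#' @export
register_params <- function(period = 6.7, probe_radius = 1.5,
                            phase_tol = 1 / 12, n_phase_bins = 36,
                            smoothing = 3) {
  stopifnot(period > 0, phase_tol > 0, phase_tol < 0.5, n_phase_bins >= 12)
  structure(list(period = period, probe_radius = probe_radius,
                 phase_tol = phase_tol, n_phase_bins = n_phase_bins,
                 smoothing = smoothing),
            class = "register_params")
}

#' Average density over strand repeats
#'
#' Walks the axis in fine arclength steps, maps arclength s to phase
#' s mod period, and averages the density at \code{probe_radius} from
#' the axis in four directions -- toward the neighbouring strand
#' (plus_n), away from it (minus_n), and the two sheet-perpendiculars
#' (plus_b, minus_b) -- into phase bins. The neighbour direction is
#' parallel-transported along the axis and re-orthogonalized to the
#' local tangent; plus_b is tangent x plus_n (right-handed frame).
#'
#' @param grid the \code{density_grid}.
#' @param axis polyline matrix (n x 3, A) of the tube axis.
#' @param neighbour_dir unit vector toward the paired tube.
#' @param params a \code{register_params}.
#' @return A \code{repeat_profile}: list with \code{phases} (bin
#'   centres, fraction of period) and the four density arrays.
#' @export
average_over_repeats <- function(grid, axis, neighbour_dir,
                                 params = register_params()) {
  s_tot <- arclength(axis)
  if (s_tot[length(s_tot)] < params$period)
    stop("axis shorter than one period; cannot average repeats")
  nb <- params$n_phase_bins
  step <- params$period / (2 * nb)
  rs <- resample_polyline(axis, step)
  pts <- rs$points
  tg <- polyline_tangents(pts)
  nn <- transport_normal(pts, neighbour_dir)
  bb <- t(vapply(seq_len(nrow(pts)),
                 function(i) cross3(tg[i, ], nn[i, ]), numeric(3)))
  phase <- (rs$s %% params$period) / params$period
  bin <- floor(phase * nb) + 1
  bin[bin > nb] <- nb
  r <- params$probe_radius
  acc <- function(dirs) {
    rho <- interpolate_map(grid, pts + r * dirs)
    as.numeric(tapply(rho, factor(bin, levels = 1:nb), mean))
  }
  prof <- list(phases = (seq_len(nb) - 0.5) / nb,
               dens_plus_n = acc(nn), dens_minus_n = acc(-nn),
               dens_plus_b = acc(bb), dens_minus_b = acc(-bb),
               params = params)
  for (f in c("dens_plus_n", "dens_minus_n", "dens_plus_b", "dens_minus_b"))
    prof[[f]][is.na(prof[[f]])] <- mean(prof[[f]], na.rm = TRUE)
  structure(prof, class = "repeat_profile")
}

# Signed circular difference a - b mapped to (-0.5, 0.5].
circ_signed <- function(a, b, period = 1) {
  d <- (a - b) %% period
  ifelse(d > period / 2, d - period, d)
}

.calib_cache <- new.env(parent = emptyenv())

#' Calibrate register peak biases at a working resolution
#'
#' At finite resolution the apparent peak of the off-axis density is
#' shifted slightly from the generating atom's axial position by the
#' blend of flanking backbone features (about +0.05 of a period for the
#' carbonyl peaks at 2.5 A). This routine measures those shifts once on
#' the ideal strand's own model density (a two-strand sheet, probing the
#' strand with a neighbour on the +n side) and returns the per-direction
#' biases (detected peak minus true atom phase, fractions of the
#' period). The direction test applies them covariantly: for the reverse
#' hypothesis the two sheet-perpendicular biases swap and change sign.
#'
#' @param resolution map resolution, A.
#' @param params a \code{register_params}.
#' @return Named numeric: \code{pn}, \code{mn}, \code{pb}, \code{mb}.
#' @export
register_calibration <- function(resolution, params = register_params()) {
  key <- sprintf("%.4f|%g|%g|%d|%g", resolution, params$period,
                 params$probe_radius, params$n_phase_bins, params$smoothing)
  if (!is.null(.calib_cache[[key]])) return(.calib_cache[[key]])
  sheet <- build_sheet(sheet_spec(2, 8))
  grid <- density_from_model(sheet, map_spec(resolution))
  A <- sheet[sheet$chain == "A", , drop = FALSE]
  ca <- as.matrix(A[A$atom_name == "CA", c("x", "y", "z")])
  ax <- smooth_axis(ca, window = params$period)
  prof <- average_over_repeats(grid, ax, c(0, 1, 0), params)
  P <- attr(sheet, "period")
  s0 <- ax[1, 1]
  xyz <- as.matrix(A[, c("x", "y", "z")])
  ph <- function(rows) mean_circular(((xyz[rows, 1] - s0) / P) %% 1)
  oi <- which(A$atom_name == "O"); ci <- which(A$atom_name == "C")
  o_up <- oi[xyz[oi, 2] - xyz[ci, 2] > 0]
  o_dn <- oi[xyz[oi, 2] - xyz[ci, 2] < 0]
  cbi <- which(A$atom_name == "CB")
  cb_up <- cbi[xyz[cbi, 3] > 0]
  cb_dn <- cbi[xyz[cbi, 3] < 0]
  out <- c(
    pn = circ_signed(peak_phase(prof$dens_plus_n, params$smoothing), ph(o_up)),
    mn = circ_signed(peak_phase(prof$dens_minus_n, params$smoothing), ph(o_dn)),
    pb = circ_signed(peak_phase(prof$dens_plus_b, params$smoothing), ph(cb_up)),
    mb = circ_signed(peak_phase(prof$dens_minus_b, params$smoothing), ph(cb_dn)))
  .calib_cache[[key]] <- out
  out
}

no_calibration <- function() c(pn = 0, mn = 0, pb = 0, mb = 0)

mean_circular <- function(x) {
  (atan2(mean(sin(2 * pi * x)), mean(cos(2 * pi * x))) / (2 * pi)) %% 1
}

# Circular boxcar smoothing.
smooth_circular <- function(x, width) {
  if (width <= 1) return(x)
  n <- length(x)
  k <- floor(width / 2)
  idx <- outer(seq_len(n), -k:k, "+")
  idx <- ((idx - 1) %% n) + 1
  rowMeans(matrix(x[idx], n))
}

# Circular argmax with parabolic sub-bin refinement; returns phase in [0,1).
peak_phase <- function(y, smoothing = 3) {
  n <- length(y)
  ys <- smooth_circular(y, smoothing)
  i <- which.max(ys)
  ym <- ys[((i - 2) %% n) + 1]; y0 <- ys[i]; yp <- ys[(i %% n) + 1]
  denom <- ym - 2 * y0 + yp
  frac <- if (abs(denom) > 1e-12) 0.5 * (ym - yp) / denom else 0
  frac <- max(-0.5, min(0.5, frac))
  ((i - 0.5 + frac) / n) %% 1
}

#' Locate the carbonyl phase on a repeat profile
#'
#' The carbonyl position is the phase at which the density toward the
#' neighbouring strand (plus_n) peaks. The estimate is accepted when the
#' peak on the far side (minus_n) sits half a period away, within
#' \code{phase_tol} of the period (circular distance); flat profiles are
#' rejected.
#'
#' @param profile a \code{repeat_profile}.
#' @param params a \code{register_params}.
#' @param calibration peak biases from
#'   \code{\link{register_calibration}}; the half-period check allows
#'   for the known divergence of the two carbonyl-peak biases (which
#'   grows with worsening resolution), in either strand orientation.
#' @return list(phase = raw plus_n peak phase, fraction of period;
#'   accepted = logical).
#' @export
find_carbonyl_phase <- function(profile,
                                params = profile$params %||% register_params(),
                                calibration = no_calibration()) {
  yp <- profile$dens_plus_n
  ym <- profile$dens_minus_n
  flat <- (max(yp) - min(yp)) < 1e-6 || (max(ym) - min(ym)) < 1e-6
  phase <- peak_phase(yp, params$smoothing)
  if (flat) return(list(phase = phase, accepted = FALSE))
  opp <- peak_phase(ym, params$smoothing)
  d <- circ_signed(opp, (phase + 0.5) %% 1)
  delta <- unname(calibration["mn"] - calibration["pn"])
  ok <- min(abs(d - delta), abs(d + delta)) <= params$phase_tol
  list(phase = phase, accepted = ok)
}

# Phase targets (fractions of the period past the carbonyl phase) for the
# two direction hypotheses. Moving N->C from a carbonyl O pointing toward
# the neighbour (+n): the far-side carbonyl (atom 4 of the 6-atom
# two-residue repeat) sits at +3/6; the C-beta on the +b side (atom 3) at
# +2/6 and on the -b side (atom 6) at +5/6 for a chain running along the
# +tangent. The reverse hypothesis is the mirror: phases negate about the
# carbonyl and the two sheet-perpendicular sides swap.
direction_targets <- function() {
  list(forward = c(minus_n = 3 / 6, plus_b = 2 / 6, minus_b = 5 / 6),
       reverse = c(minus_n = 3 / 6, plus_b = 1 / 6, minus_b = 4 / 6))
}

#' Determine strand direction from the repeat profile
#'
#' Tests the carbonyl/C-beta phase pattern against the two chain
#' direction hypotheses: all three non-anchor peaks (far-side carbonyl
#' and the two C-beta peaks) must fall within \code{phase_tol} of the
#' period of their target phases. Exactly one passing hypothesis gives
#' the direction; both or neither give \code{"ambiguous"}. By chance a
#' random profile passes in about 1 percent of cases (two hypotheses,
#' three peaks, each within 1/12 of the period 1/6 of the time).
#'
#' @param profile a \code{repeat_profile}.
#' @param carbonyl_phase raw phase from
#'   \code{\link{find_carbonyl_phase}}.
#' @param params a \code{register_params}.
#' @param calibration per-direction peak biases from
#'   \code{\link{register_calibration}} (zero if omitted).
#' @return \code{"forward"}, \code{"reverse"} or \code{"ambiguous"}.
#' @export
determine_direction <- function(profile, carbonyl_phase,
                                params = profile$params %||% register_params(),
                                calibration = no_calibration()) {
  peaks <- c(minus_n = peak_phase(profile$dens_minus_n, params$smoothing),
             plus_b = peak_phase(profile$dens_plus_b, params$smoothing),
             minus_b = peak_phase(profile$dens_minus_b, params$smoothing))
  tg <- direction_targets()
  # hypothesis-specific bias correction: for a forward strand the
  # measured peak is geometry + bias; for a reverse strand the density
  # field is mirrored, so biases negate and the two b-sides swap
  corr <- list(
    forward = c(minus_n = unname(calibration["mn"]),
                plus_b = unname(calibration["pb"]),
                minus_b = unname(calibration["mb"])),
    reverse = c(minus_n = -unname(calibration["mn"]),
                plus_b = -unname(calibration["mb"]),
                minus_b = -unname(calibration["pb"])))
  anchor <- c(forward = (carbonyl_phase - unname(calibration["pn"])) %% 1,
              reverse = (carbonyl_phase + unname(calibration["pn"])) %% 1)
  pass <- vapply(names(tg), function(h) {
    target <- (anchor[[h]] + tg[[h]][names(peaks)]) %% 1
    all(circ_dist((peaks - corr[[h]][names(peaks)]) %% 1, target) <=
          params$phase_tol)
  }, logical(1))
  if (pass[["forward"]] && !pass[["reverse"]]) "forward"
  else if (pass[["reverse"]] && !pass[["forward"]]) "reverse"
  else "ambiguous"
}

#' Monte-Carlo chance rate of the direction test
#'
#' Draws the three non-anchor peak phases independently and uniformly on
#' [0, 1) of the period and accepts a trial when all three fall within
#' \code{phase_tol} of their targets under either direction hypothesis.
#' The analytic rate for tolerance 1/12 is 2 (1/6)^3, about 0.93
#' percent ("about 1 percent of cases by chance").
#'
#' @param n_trials number of Monte-Carlo trials.
#' @param seed RNG seed.
#' @param params a \code{register_params}.
#' @return list(rate = acceptance fraction, n = n_trials,
#'   analytic = closed-form rate).
#' @export
direction_chance_rate <- function(n_trials = 100000, seed = 1,
                                  params = register_params()) {
  tg <- direction_targets()
  u <- with_seed(seed, matrix(stats::runif(3 * n_trials), ncol = 3))
  tol <- params$phase_tol
  hit <- function(target) {
    circ_dist(u[, 1], target[["minus_n"]]) <= tol &
    circ_dist(u[, 2], target[["plus_b"]]) <= tol &
    circ_dist(u[, 3], target[["minus_b"]]) <= tol
  }
  acc <- hit(tg$forward) | hit(tg$reverse)
  list(rate = mean(acc), n = n_trials, analytic = 2 * (2 * tol)^3)
}

#' Place an idealized strand on a tube axis
#'
#' Superposes the ideal two-residue template repeat rigidly onto the
#' local axis frame (tangent, neighbour direction, sheet-perpendicular)
#' of each period-long window, at the axial phase fixed by the carbonyl
#' position, and concatenates the repeats into a strand model. Curvature
#' of the axis is followed per repeat, at the cost of slight distortion
#' between repeats. An ambiguous direction yields two candidates, one
#' per direction.
#'
#' @param axis tube axis polyline (n x 3), at least two periods long.
#' @param neighbour_dir unit vector toward the paired strand.
#' @param carbonyl_phase phase from \code{\link{find_carbonyl_phase}},
#'   fraction of period.
#' @param direction \code{"forward"}, \code{"reverse"} or
#'   \code{"ambiguous"}.
#' @param score tube score inherited by the candidates.
#' @param params a \code{register_params}.
#' @param template two-residue repeat unit from the ideal strand (as
#'   produced internally from \code{\link{build_ideal_strand}});
#'   rebuilt with default torsions if \code{NULL}.
#' @param calibration peak biases from
#'   \code{\link{register_calibration}}; the raw carbonyl phase is
#'   corrected by the carbonyl-peak bias (sign depending on direction)
#'   before anchoring the template.
#' @return list of \code{strand_candidate} objects (0, 1 or 2).
#' @export
place_strand <- function(axis, neighbour_dir, carbonyl_phase, direction,
                         score = NA_real_, params = register_params(),
                         template = NULL, calibration = no_calibration()) {
  L <- arclength(axis)
  L <- L[length(L)]
  if (L < 2 * params$period) return(list())
  dirs <- if (direction == "ambiguous") c("forward", "reverse") else direction
  out <- lapply(dirs, function(d) {
    ax <- axis
    if (d == "forward") {
      ph <- (carbonyl_phase - unname(calibration["pn"])) %% 1
    } else {
      ax <- axis[rev(seq_len(nrow(axis))), , drop = FALSE]
      ph <- ((L / params$period) -
               (carbonyl_phase + unname(calibration["pn"]))) %% 1
    }
    model <- place_forward(ax, neighbour_dir, ph, params, template)
    if (is.null(model)) return(NULL)
    structure(list(axis = ax, carbonyl_phase = carbonyl_phase,
                   direction = d, ambiguous = direction == "ambiguous",
                   model = model, score = score),
              class = "strand_candidate")
  })
  Filter(Negate(is.null), out)
}

# Two-residue repeat unit cut from the middle of a 6-residue ideal strand
# (end residues carry edge distortion of the canonical frame fit).
repeat_template <- function(phi = -125.094, psi = 121.952) {
  s6 <- build_ideal_strand(6, phi, psi)
  sub <- s6[s6$res_seq %in% c(3, 4), , drop = FALSE]
  xyz <- as.matrix(sub[, c("x", "y", "z")])
  ci <- which(sub$atom_name == "C"); oi <- which(sub$atom_name == "O")
  up <- which(xyz[oi, 2] - xyz[ci, 2] > 0)
  bb <- sub$atom_name %in% c("N", "CA", "C")
  list(xyz = xyz, period = attr(s6, "period"),
       anchor_x = xyz[oi[up[1]], 1], centre_x = mean(xyz[bb, 1]))
}

# Place the template along an axis traversed in the forward sense.
place_forward <- function(axis, neighbour_dir, phase, params, template) {
  if (is.null(template)) template <- repeat_template()
  P <- params$period
  half <- template$period / 2
  L_orig <- arclength(axis)
  L <- L_orig[length(L_orig)]
  # extrapolate the axis by half a period at both ends so repeat frames
  # near the termini remain well defined
  ext <- P / 2
  t1 <- unit(axis[1, ] - axis[2, ])
  t2 <- unit(axis[nrow(axis), ] - axis[nrow(axis) - 1, ])
  axis_ext <- rbind(axis[1, ] + ext * t1, axis, axis[nrow(axis), ] + ext * t2)
  rs <- resample_polyline(axis_ext, P / 24)
  s_ext <- rs$s - ext  # arclength in the original axis frame
  tg <- polyline_tangents(rs$points)
  nn <- transport_normal(rs$points, neighbour_dir)
  frame_at <- function(s) {
    i <- which.min(abs(s_ext - s))
    list(p = rs$points[i, ], t = tg[i, ], n = nn[i, ], b = cross3(tg[i, ], nn[i, ]))
  }
  # carbonyl anchors at arclength (phase + k) * P; a repeat is kept when
  # its backbone window overhangs the axis by at most P/4
  anchors <- (phase + seq(-2, ceiling(L / P) + 2)) * P
  rel <- template$centre_x - template$anchor_x
  keep <- (anchors + rel - half) >= -P / 4 & (anchors + rel + half) <= L + P / 4
  anchors <- anchors[keep]
  if (length(anchors) < 2) return(NULL)
  reps <- lapply(anchors, function(s0) {
    xs <- template$centre_x + seq(-half, half, length.out = 5)
    ss <- s0 + (xs - template$anchor_x)
    frames <- lapply(ss, frame_at)
    Xfit <- rbind(cbind(xs, 0, 0), cbind(xs, 1, 0), cbind(xs, 0, 1))
    Yfit <- rbind(t(vapply(frames, `[[`, numeric(3), "p")),
                  t(vapply(frames, function(f) f$p + f$n, numeric(3))),
                  t(vapply(frames, function(f) f$p + f$b, numeric(3))))
    fit <- rigid_fit(Xfit, Yfit)
    apply_rigid(template$xyz, fit)
  })
  n_res <- 2 * length(anchors)
  atoms <- data.frame(
    chain = "A", res_seq = rep(seq_len(n_res), each = 5),
    res_name = "ALA",
    atom_name = rep(c("N", "CA", "C", "O", "CB"), n_res),
    x = 0, y = 0, z = 0, is_strand = TRUE, stringsAsFactors = FALSE)
  xyz <- do.call(rbind, reps)
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  if (n_res < 4) return(NULL)
  chain_model(atoms)
}

#' @export
print.strand_candidate <- function(x, ...) {
  cat(sprintf("strand_candidate: %d residues, direction %s%s, phase %.3f, score %.2f\n",
              n_residues(x$model), x$direction,
              if (isTRUE(x$ambiguous)) " (ambiguous)" else "",
              x$carbonyl_phase, x$score))
  invisible(x)
}
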