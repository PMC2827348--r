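# Synthetic beta-sheet fixtures: idealized strand/sheet models (side chains
# truncated at C-beta) and model electron density computed at a stated
# resolution, so every pipeline stage can be exercised and scored against
# known ground truth.

# Engh & Huber style backbone geometry (lengths A, angles degrees).
.bond <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
              ca_cb = 1.530)
.angle <- list(c_n_ca = 121.7, n_ca_c = 111.2, ca_c_n = 116.2,
               ca_c_o = 120.8, n_ca_cb = 110.5)

#' Build an idealized beta-strand
#'
#' Constructs an extended backbone (N, CA, C, O, CB per residue) from
#' standard bond lengths and angles at the given backbone torsions. The
#' default torsions (phi = -125.094, psi = +121.952 degrees) lie in the
#' beta region and are solved so that the two-residue screw transform of
#' the chain is a pure translation of 6.70 A: the template then has an
#' exact two-residue translational repeat at the beta-strand period the
#' register search exploits. (Textbook antiparallel torsions near
#' (-139, +135) give a slightly longer, 6.9 A, repeat plus a residual
#' per-repeat twist with standard bond geometry.)
#'
#' The model is returned in a canonical frame: strand axis along +x
#' (N- to C-terminus), first carbonyl O pointing +y (the direction a
#' neighbouring strand would occupy), C-beta atoms along +/-z (the
#' sheet-perpendicular). Attributes \code{period} (A) and
#' \code{carbonyl_up_x} (axial position of the first +y carbonyl O) are
#' attached for register bookkeeping.
#'
#' @param n_res number of residues (>= 2).
#' @param phi,psi backbone torsions in degrees.
#' @param chain chain identifier.
#' @return A \code{chain_model} flagged as strand.
#' @export
build_ideal_strand <- function(n_res, phi = -125.094, psi = 121.952, chain = "A") {
  stopifnot(n_res >= 2)
  N <- matrix(0, n_res, 3); CA <- N; C <- N; O <- N; CB <- N
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(.bond$n_ca, 0, 0)
  ang <- .angle$n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + .bond$ca_c * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n_res)) {
    if (i < n_res) {
      N[i + 1, ] <- nerf_place(N[i, ], CA[i, ], C[i, ], .bond$c_n,
                               .angle$ca_c_n, psi)
      CA[i + 1, ] <- nerf_place(CA[i, ], C[i, ], N[i + 1, ], .bond$n_ca,
                                .angle$c_n_ca, 180)
      C[i + 1, ] <- nerf_place(C[i, ], N[i + 1, ], CA[i + 1, ], .bond$ca_c,
                               .angle$n_ca_c, phi)
    }
    O[i, ] <- nerf_place(N[i, ], CA[i, ], C[i, ], .bond$c_o,
                         .angle$ca_c_o, psi + 180)
    CB[i, ] <- place_cb(N[i, ], CA[i, ], C[i, ])
  }
  coords <- canonical_strand_frame(N, CA, C, O, CB)
  res <- rep(seq_len(n_res), each = 5)
  atoms <- data.frame(
    chain = chain, res_seq = res, res_name = "ALA",
    atom_name = rep(c("N", "CA", "C", "O", "CB"), n_res),
    x = coords$xyz[, 1], y = coords$xyz[, 2], z = coords$xyz[, 3],
    is_strand = TRUE, stringsAsFactors = FALSE)
  m <- chain_model(atoms)
  attr(m, "period") <- coords$period
  attr(m, "carbonyl_up_x") <- coords$carbonyl_up_x
  m
}

# C-beta placed tetrahedrally off CA; the sign of the out-of-plane
# component fixes L-amino-acid chirality.
place_cb <- function(N, CA, C) {
  b1 <- unit(N - CA)
  b2 <- unit(C - CA)
  m <- unit(b1 + b2)
  k <- unit(cross3(b1, b2))
  # angle(N-CA-CB) = 110.5 deg: component along -m from b1.m = cos(55.6 deg)
  x <- -cos(.angle$n_ca_cb * pi / 180) / sum(b1 * m)
  y <- sqrt(max(0, 1 - x^2))
  CA + .bond$ca_cb * (-x * m + y * k)
}

# Rotate/translate raw backbone arrays into the canonical strand frame.
canonical_strand_frame <- function(N, CA, C, O, CB) {
  n_res <- nrow(CA)
  ax <- svd(sweep(CA, 2, colMeans(CA)))$v[, 1]
  if (sum(ax * (CA[n_res, ] - CA[1, ])) < 0) ax <- -ax
  co <- O[1, ] - C[1, ]
  yv <- unit(co - sum(co * ax) * ax)
  zv <- unit(cross3(ax, yv))
  yv <- cross3(zv, ax)
  R <- rbind(ax, yv, zv)
  bb <- rbind(N, CA, C)
  centroid <- colMeans(bb)
  tr <- function(M) sweep(M, 2, centroid) %*% t(R)
  Nn <- tr(N); CAn <- tr(CA); Cn <- tr(C); On <- tr(O); CBn <- tr(CB)
  period <- if (n_res >= 3) {
    mean(sqrt(rowSums((CAn[-(1:2), , drop = FALSE] -
                       CAn[1:(n_res - 2), , drop = FALSE])^2)))
  } else 2 * vnorm(CAn[2, ] - CAn[1, ])
  up <- which(On[, 2] - Cn[, 2] > 0)
  xyz <- matrix(0, 5 * n_res, 3)
  for (i in seq_len(n_res))
    xyz[(5 * i - 4):(5 * i), ] <- rbind(Nn[i, ], CAn[i, ], Cn[i, ],
                                        On[i, ], CBn[i, ])
  list(xyz = xyz, period = period, carbonyl_up_x = On[up[1], 1])
}

#' Specify an idealized beta-sheet
#'
#' @param n_strands number of strands (>= 1).
#' @param residues_per_strand residues per strand (>= 3).
#' @param topology \code{"antiparallel"} or \code{"parallel"}.
#' @param inter_strand_separation A between adjacent strand axes at
#'   closest approach (default 4.5).
#' @param twist_deg_per_residue sheet twist; adjacent strands are
#'   inclined by \code{twist_deg_per_residue * residues_per_strand}
#'   degrees (default 0, a flat sheet).
#' @param phi,psi backbone torsions, degrees.
#' @return A \code{sheet_spec} list.
#' @export
sheet_spec <- function(n_strands = 4, residues_per_strand = 6,
                       topology = c("antiparallel", "parallel"),
                       inter_strand_separation = 4.5,
                       twist_deg_per_residue = 0,
                       phi = -125.094, psi = 121.952) {
  topology <- match.arg(topology)
  stopifnot(n_strands >= 1, residues_per_strand >= 3,
            inter_strand_separation > 0)
  structure(list(n_strands = n_strands,
                 residues_per_strand = residues_per_strand,
                 topology = topology,
                 inter_strand_separation = inter_strand_separation,
                 twist_deg_per_residue = twist_deg_per_residue,
                 phi = phi, psi = psi),
            class = "sheet_spec")
}

#' Build an idealized beta-sheet model
#'
#' Replicates the ideal strand along the in-sheet separation direction
#' (+y in the canonical frame). Antiparallel topology flips alternate
#' strands (180 degrees about y); strands are then shifted axially so
#' that carbonyl O atoms of adjacent strands face each other, and
#' inclined by the sheet twist.
#'
#' @param spec a \code{sheet_spec}.
#' @return A \code{chain_model} with one chain per strand (A, B, ...).
#' @export
build_sheet <- function(spec) {
  stopifnot(inherits(spec, "sheet_spec"))
  base <- build_ideal_strand(spec$residues_per_strand, spec$phi, spec$psi)
  period <- attr(base, "period")
  ids <- make_chain_ids(spec$n_strands)
  incline <- spec$twist_deg_per_residue * spec$residues_per_strand
  strands <- vector("list", spec$n_strands)
  prev_up_x <- NULL
  for (k in seq_len(spec$n_strands) - 1) {
    m <- as.data.frame(base)
    xyz <- as.matrix(m[, c("x", "y", "z")])
    flipped <- spec$topology == "antiparallel" && k %% 2 == 1
    if (flipped) xyz <- xyz %*% t(rotation_about(c(0, 1, 0), 180))
    # axial registration: hydrogen-bond the previous strand's +y carbonyl
    # O to this strand's amide N-H pointing -y (C=O...H-N ladder; aligning
    # carbonyls with carbonyls instead would clash the facing O atoms)
    if (k > 0) {
      down_x <- amide_x(m, xyz, toward_y = -1)
      delta <- (prev_up_x - down_x) %% period
      if (delta > period / 2) delta <- delta - period
      xyz[, 1] <- xyz[, 1] + delta
    }
    prev_up_x <- carbonyl_x(m, xyz, up = TRUE)
    if (incline != 0 && k > 0)
      xyz <- xyz %*% t(rotation_about(c(0, 1, 0), k * incline))
    xyz[, 2] <- xyz[, 2] + k * spec$inter_strand_separation
    m$x <- xyz[, 1]; m$y <- xyz[, 2]; m$z <- xyz[, 3]
    m$chain <- ids[k + 1]
    strands[[k + 1]] <- m
  }
  out <- chain_model(do.call(rbind, strands))
  attr(out, "period") <- period
  attr(out, "spec") <- spec
  rownames(out) <- NULL
  out
}

# Mean x (mod nothing -- representative value) of carbonyl C atoms whose O
# points in the +y (up = TRUE) or -y direction, for register alignment.
carbonyl_x <- function(m, xyz, up = TRUE) {
  ci <- which(m$atom_name == "C")
  oi <- which(m$atom_name == "O")
  dy <- xyz[oi, 2] - xyz[ci, 2]
  sel <- if (up) which(dy > 0) else which(dy < 0)
  xyz[oi[sel[1]], 1]
}

# Axial position of the first amide N whose H points along toward_y; the
# amide H of residue i+1 points opposite the carbonyl O of residue i in
# the trans peptide plane.
amide_x <- function(m, xyz, toward_y = -1) {
  nres <- max(m$res_seq)
  for (i in seq_len(nres - 1) + 1) {
    ci <- which(m$res_seq == i - 1 & m$atom_name == "C")
    oi <- which(m$res_seq == i - 1 & m$atom_name == "O")
    ni <- which(m$res_seq == i & m$atom_name == "N")
    h_y <- -(xyz[oi, 2] - xyz[ci, 2])
    if (sign(h_y) == sign(toward_y)) return(xyz[ni, 1])
  }
  stop("no facing amide found")
}

#' Bend a model about the sheet-perpendicular direction
#'
#' Applies a circular bend in the x-z plane (curvature perpendicular to
#' the sheet plane, the direction in which beta-sheets naturally curl),
#' emulating curved strands for extension tests.
#'
#' @param model a \code{chain_model} in the canonical sheet frame.
#' @param deg_per_residue bend angle per residue, degrees.
#' @param rise axial rise per residue (A), default half the strand period.
#' @return The bent \code{chain_model}.
#' @export
bend_model <- function(model, deg_per_residue, rise = NULL) {
  if (deg_per_residue == 0) return(model)
  period <- attr(model, "period") %||% 6.7
  if (is.null(rise)) rise <- period / 2
  rc <- rise / (deg_per_residue * pi / 180)
  a <- model$x / rc
  r <- rc - model$z
  out <- model
  out$x <- r * sin(a)
  out$z <- rc - r * cos(a)
  out
}

#' Specify map synthesis parameters
#'
#' @param resolution map resolution in A.
#' @param grid_spacing voxel size in A (default \code{resolution / 4}).
#' @param atom_b_factor isotropic B-factor (A^2) setting the Gaussian
#'   atom width.
#' @param noise_sigma Gaussian noise amplitude in units of the noise-free
#'   map standard deviation.
#' @param rng_seed seed for the noise generator.
#' @param pad A of empty margin around the model bounding box.
#' @return A \code{map_spec} list.
#' @export
map_spec <- function(resolution = 2.5, grid_spacing = resolution / 4,
                     atom_b_factor = 15, noise_sigma = 0, rng_seed = 1,
                     pad = 6) {
  stopifnot(resolution >= 2 * grid_spacing, noise_sigma >= 0)
  structure(list(resolution = resolution, grid_spacing = grid_spacing,
                 atom_b_factor = atom_b_factor, noise_sigma = noise_sigma,
                 rng_seed = rng_seed, pad = pad),
            class = "map_spec")
}

.atomic_number <- c(N = 7, CA = 6, C = 6, O = 8, CB = 6)

#' Compute model electron density on a grid
#'
#' Sums per-atom Gaussians (width from the B-factor, weight from the
#' atomic number), low-pass filters to the stated resolution by zeroing
#' Fourier components beyond 1/resolution, optionally adds seeded
#' Gaussian noise, and normalizes to sigma units.
#'
#' @param model a \code{chain_model}.
#' @param spec a \code{map_spec}.
#' @param normalize normalize the result to zero mean, unit sd
#'   (default \code{TRUE}).
#' @return A \code{density_grid} with \code{resolution_hint} set.
#' @export
density_from_model <- function(model, spec = map_spec(), normalize = TRUE) {
  stopifnot(inherits(model, "chain_model"), nrow(model) > 0)
  xyz <- as.matrix(model[, c("x", "y", "z")])
  w <- .atomic_number[model$atom_name]
  sp <- rep_len(spec$grid_spacing, 3)
  lo <- apply(xyz, 2, min) - spec$pad
  hi <- apply(xyz, 2, max) + spec$pad
  dims <- pmax(ceiling((hi - lo) / sp) + 1, 8)
  vals <- array(0, dim = dims)
  sigma <- sqrt(spec$atom_b_factor / (8 * pi^2))
  cutoff <- 4.5 * sigma
  ax <- lapply(1:3, function(a) lo[a] + (0:(dims[a] - 1)) * sp[a])
  for (i in seq_len(nrow(xyz))) {
    rng <- lapply(1:3, function(a) {
      which(abs(ax[[a]] - xyz[i, a]) <= cutoff)
    })
    if (any(lengths(rng) == 0)) next
    g <- lapply(1:3, function(a)
      exp(-(ax[[a]][rng[[a]]] - xyz[i, a])^2 / (2 * sigma^2)))
    vals[rng[[1]], rng[[2]], rng[[3]]] <-
      vals[rng[[1]], rng[[2]], rng[[3]], drop = FALSE] +
      w[i] * (g[[1]] %o% g[[2]] %o% g[[3]])
  }
  grid <- density_grid(vals, origin = lo, spacing = sp)
  grid <- lowpass_grid(grid, spec$resolution)
  grid$resolution_hint <- spec$resolution
  if (spec$noise_sigma > 0) {
    # band-limited noise: crystallographic map noise carries no detail
    # beyond the resolution cutoff, so the noise field is low-pass
    # filtered like the signal before scaling
    noise <- array(with_seed(spec$rng_seed, stats::rnorm(prod(dims))),
                   dim = dims)
    ngrid <- lowpass_grid(density_grid(noise, lo, sp), spec$resolution)
    grid$values <- grid$values + ngrid$values *
      (spec$noise_sigma * stats::sd(grid$values) / stats::sd(ngrid$values))
  }
  if (normalize) grid <- normalize_grid(grid)
  grid
}

# Evaluate thunk with a temporary RNG state; restores the caller's state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Ground-truth table for a fixture model
#'
#' One row per residue: chain, residue number, CA coordinates and the
#' strand direction unit vector (N- to C-terminal), used by
#' parameter-recovery tests and the evaluation module.
#'
#' @param model a \code{chain_model} (one chain per strand).
#' @return data.frame with columns chain, res_seq, ca_x..ca_z, dir_x..dir_z.
#' @export
sheet_truth <- function(model) {
  rows <- list()
  for (ch in unique(model$chain)) {
    sub <- model[model$chain == ch, , drop = FALSE]
    ca <- atom_coords(chain_model(as.data.frame(sub)), "CA")
    d <- unit(ca[nrow(ca), ] - ca[1, ])
    rows[[ch]] <- data.frame(
      chain = ch, res_seq = sub$res_seq[sub$atom_name == "CA"],
      ca_x = ca[, 1], ca_y = ca[, 2], ca_z = ca[, 3],
      dir_x = d[1], dir_y = d[2], dir_z = d[3],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a complete synthetic fixture
#'
#' Convenience wrapper: builds the sheet model, computes its density map
#' and exports the ground-truth table.
#'
#' @param spec a \code{sheet_spec}.
#' @param map a \code{map_spec}.
#' @return list with elements \code{model}, \code{map}, \code{truth},
#'   \code{spec}, \code{map_spec}.
#' @export
sheet_fixture <- function(spec = sheet_spec(), map = map_spec()) {
  model <- build_sheet(spec)
  grid <- density_from_model(model, map)
  list(model = model, map = grid, truth = sheet_truth(model),
       spec = spec, map_spec = map)
}
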