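# Shared fixtures (built once per test run) and independent oracles.

.fx_env <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fx_env[[name]])) .fx_env[[name]] <- expr
  .fx_env[[name]]
}

# standard noise-free 4-strand x 6-residue antiparallel sheet at 2.5 A
fx_sheet4 <- function() {
  cached("sheet4", sheet_fixture(sheet_spec(4, 6), map_spec(2.5)))
}

# 2-strand x 8-residue sheet (register / pairing tests)
fx_sheet2 <- function() {
  cached("sheet2", sheet_fixture(sheet_spec(2, 8), map_spec(2.5)))
}

# full multi-resolution pipeline run on the standard fixture
fx_build4 <- function() {
  cached("build4", build_sheets(fx_sheet4()$map))
}

# smoothed true CA axis of one fixture strand
truth_axis <- function(fx, chain, smooth = TRUE) {
  ax <- as.matrix(fx$truth[fx$truth$chain == chain,
                           c("ca_x", "ca_y", "ca_z")])
  if (smooth) sheetbuild:::smooth_axis(ax) else ax
}

# Gaussian-cross-section cylinder of density along x
cylinder_grid <- function(sigma = 1.0, spacing = 0.6, half = 12) {
  xs <- seq(-half, half, spacing)
  ys <- seq(-6, 6, spacing)
  zs <- seq(-6, 6, spacing)
  vals <- array(0, c(length(xs), length(ys), length(zs)))
  for (j in seq_along(ys)) for (k in seq_along(zs))
    vals[, j, k] <- exp(-(ys[j]^2 + zs[k]^2) / (2 * sigma^2))
  normalize_grid(density_grid(vals, origin = c(-half, -6, -6),
                              spacing = rep(spacing, 3)))
}

# uniform density everywhere (connection tests)
uniform_grid <- function(value = 1, n = 30, spacing = 1) {
  g <- density_grid(array(value, c(n, n, n)), origin = -c(n, n, n) / 2,
                    spacing = rep(spacing, 3))
  g  # deliberately not normalized: constant density
}

# --- independent oracles ----------------------------------------------------

# scalar trilinear interpolation written independently of the package
oracle_trilinear <- function(grid, p) {
  tq <- (p - grid$origin) / grid$spacing
  i <- floor(tq)
  i <- pmin(pmax(i, 0), grid$dims - 2)
  f <- tq - i
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- prod(ifelse(c(dx, dy, dz) == 1, f, 1 - f))
    acc <- acc + w * grid$values[i[1] + dx + 1, i[2] + dy + 1, i[3] + dz + 1]
  }
  acc
}

# fine-step (0.05 A) connection test, straightforward re-implementation
oracle_connected <- function(grid, p1, p2, cut1 = 0.5, cut2 = 0.75,
                             step = 0.05) {
  d <- sqrt(sum((p2 - p1)^2))
  if (d < 1e-9) return(TRUE)
  n <- max(2, ceiling(d / step) + 1)
  tt <- seq(0, 1, length.out = n)
  rho <- pmax(0, sapply(tt, function(t)
    interpolate_map(grid, p1 + t * (p2 - p1))))
  rho_max <- max(rho[1], rho[n])
  min(rho) >= rho_max * cut1 - 1e-12 && mean(rho) >= rho_max * cut2 - 1e-12
}

# brute-force greedy one-to-one CA matching (evaluation oracle)
oracle_match <- function(caB, caR, radius = 3) {
  d <- as.matrix(stats::dist(rbind(caB, caR)))[seq_len(nrow(caB)),
                                               nrow(caB) + seq_len(nrow(caR)),
                                               drop = FALSE]
  usedB <- rep(FALSE, nrow(caB)); usedR <- rep(FALSE, nrow(caR))
  n <- 0L
  repeat {
    d2 <- d
    d2[usedB, ] <- Inf; d2[, usedR] <- Inf
    if (all(!is.finite(d2)) || min(d2) > radius) break
    ij <- arrayInd(which.min(d2), dim(d2))
    usedB[ij[1]] <- TRUE; usedR[ij[2]] <- TRUE
    n <- n + 1L
  }
  n
}

# synthetic repeat profile with Gaussian bumps at given peak phases
synthetic_profile <- function(pn, mn, pb, mb, nbins = 36, width = 0.06) {
  bump <- function(centre) {
    ph <- (seq_len(nbins) - 0.5) / nbins
    d <- pmin(abs(ph - centre), 1 - abs(ph - centre))
    exp(-d^2 / (2 * width^2))
  }
  structure(list(phases = (seq_len(nbins) - 0.5) / nbins,
                 dens_plus_n = bump(pn), dens_minus_n = bump(mn),
                 dens_plus_b = bump(pb), dens_minus_b = bump(mb),
                 params = register_params()),
            class = "repeat_profile")
}

# mirror a profile: reversing the strand negates phases about the
# carbonyl and swaps the two sheet-perpendicular directions
mirror_profile <- function(prof) {
  flip <- function(y) {
    n <- length(y)
    # y'(phase) = y(-phase): bin centres map i -> n + 1 - i
    y[c(n:1)]
  }
  out <- prof
  out$dens_plus_n <- flip(prof$dens_plus_n)
  out$dens_minus_n <- flip(prof$dens_minus_n)
  out$dens_plus_b <- flip(prof$dens_minus_b)
  out$dens_minus_b <- flip(prof$dens_plus_b)
  out
}

# ideal-strand fragment as an assembly input (residues from:to)
strand_fragment <- function(from, to, score, id, n_res = 10, shift = c(0, 0, 0)) {
  s <- build_ideal_strand(n_res)
  m <- as.data.frame(s[s$res_seq %in% from:to, , drop = FALSE])
  m$res_seq <- m$res_seq - from + 1L
  m$x <- m$x + shift[1]; m$y <- m$y + shift[2]; m$z <- m$z + shift[3]
  rownames(m) <- NULL
  sheetbuild:::new_fragment(chain_model(m), score, id)
}

# reverse a fragment chain (N->C direction flipped, atoms untouched)
reverse_fragment <- function(frag, id = paste0(frag$id, "rev")) {
  m <- as.data.frame(frag$model)
  res <- unique(m$res_seq)
  m$res_seq <- max(res) - m$res_seq + 1L
  m <- m[order(m$res_seq), , drop = FALSE]
  rownames(m) <- NULL
  sheetbuild:::new_fragment(chain_model(m), frag$score, id)
}
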