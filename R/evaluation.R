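# Evaluation of built beta-sheet models against a reference model (with
# per-residue strand annotations) and against the map itself.

#' Count correctly built strand residues
#'
#' A built residue is correct when its CA lies within
#' \code{match_radius} of the CA of a strand-flagged reference residue.
#' Matching is greedy nearest-first and one-to-one (each reference
#' residue is matchable once), which prevents double counting. Recall
#' is the fraction of reference strand residues matched; precision the
#' fraction of built residues that are correct.
#'
#' @param built a \code{chain_model} (or \code{sheet_model} /
#'   \code{sheet_build}).
#' @param reference a \code{chain_model} carrying strand flags.
#' @param match_radius CA match radius, A (default 3).
#' @return list: n_built, n_correct, recall, precision, and the matched
#'   residue index pairs (\code{matches}, built row / reference row of
#'   the respective CA tables).
#' @export
count_correct <- function(built, reference, match_radius = 3.0) {
  built <- as_chain_model(built)
  if (!any(reference$is_strand))
    stop("reference carries no strand flags")
  caB <- atom_coords(built, "CA")
  ref_strand <- reference[reference$is_strand, , drop = FALSE]
  caR <- atom_coords(chain_model(as.data.frame(ref_strand)), "CA")
  n_built <- nrow(caB)
  n_ref <- nrow(caR)
  if (n_built == 0)
    return(list(n_built = 0L, n_correct = 0L, recall = 0, precision = NA_real_,
                matches = matrix(integer(0), 0, 2)))
  d <- outer(rowSums(caB^2), rowSums(caR^2), "+") - 2 * caB %*% t(caR)
  d[d < 0] <- 0
  d <- sqrt(d)
  cand <- which(d <= match_radius, arr.ind = TRUE)
  matches <- matrix(integer(0), 0, 2)
  if (nrow(cand) > 0) {
    cand <- cand[order(d[cand]), , drop = FALSE]
    usedB <- logical(n_built); usedR <- logical(n_ref)
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1]; j <- cand[r, 2]
      if (!usedB[i] && !usedR[j]) {
        usedB[i] <- TRUE; usedR[j] <- TRUE
        matches <- rbind(matches, c(i, j))
      }
    }
  }
  n_correct <- nrow(matches)
  list(n_built = n_built, n_correct = n_correct,
       recall = n_correct / n_ref, precision = n_correct / n_built,
       matches = matches)
}

as_chain_model <- function(x) {
  if (inherits(x, "sheet_build")) return(x$model)
  if (inherits(x, "sheet_model")) return(x$model)
  stopifnot(inherits(x, "chain_model"))
  x
}

#' Main-chain RMSD between built and reference strands
#'
#' RMSD over the N, CA, C and O atoms of residue pairs matched by
#' \code{\link{count_correct}}, pairing atoms by name, computed in the
#' map frame without re-superposition.
#'
#' @inheritParams count_correct
#' @return RMSD in A, or \code{NA} when no residues match.
#' @export
mainchain_rmsd <- function(built, reference, match_radius = 3.0) {
  built <- as_chain_model(built)
  cc <- count_correct(built, reference, match_radius)
  if (cc$n_correct == 0) return(NA_real_)
  rtB <- ca_residue_keys(built)
  ref_strand <- chain_model(as.data.frame(reference[reference$is_strand, ,
                                                    drop = FALSE]))
  rtR <- ca_residue_keys(ref_strand)
  sq <- c()
  for (r in seq_len(nrow(cc$matches))) {
    kb <- rtB[cc$matches[r, 1]]
    kr <- rtR[cc$matches[r, 2]]
    ab <- built[paste(built$chain, built$res_seq) == kb, , drop = FALSE]
    ar <- ref_strand[paste(ref_strand$chain, ref_strand$res_seq) == kr, ,
                     drop = FALSE]
    for (at in c("N", "CA", "C", "O")) {
      pb <- ab[ab$atom_name == at, c("x", "y", "z")]
      pr <- ar[ar$atom_name == at, c("x", "y", "z")]
      if (nrow(pb) == 1 && nrow(pr) == 1)
        sq <- c(sq, sum((as.numeric(pb) - as.numeric(pr))^2))
    }
  }
  sqrt(mean(sq))
}

# Residue keys (chain:res_seq) in CA-table order.
ca_residue_keys <- function(model) {
  sub <- model[model$atom_name == "CA", , drop = FALSE]
  paste(sub$chain, sub$res_seq)
}

#' Masked map-model correlation
#'
#' Pearson correlation between the map and density computed from the
#' model (same Gaussian-atom synthesis, truncated at the map's
#' resolution), over grid points within \code{mask_radius} of any model
#' atom -- the paper's real-space quality indicator for built strands.
#'
#' @param grid a \code{density_grid}.
#' @param model a \code{chain_model} (or \code{sheet_model} /
#'   \code{sheet_build}).
#' @param mask_radius mask radius around model atoms, A (default 2).
#' @param b_factor B-factor for the model density synthesis.
#' @return Correlation coefficient in [-1, 1].
#' @export
strand_map_cc <- function(grid, model, mask_radius = 2.0, b_factor = 15) {
  model <- as_chain_model(model)
  if (nrow(model) == 0) stop("empty model: map-model CC undefined")
  res <- grid$resolution_hint %||% (2 * max(grid$spacing))
  xyz <- as.matrix(model[, c("x", "y", "z")])
  model_vals <- model_density_on_grid(xyz, model$atom_name, grid, res, b_factor)
  mask <- mask_near_atoms(grid, xyz, mask_radius)
  if (!any(mask)) stop("empty mask: no grid points near the model")
  a <- grid$values[mask]; b <- model_vals[mask]
  if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) return(0)
  stats::cor(a, b)
}

# Model density sampled on an existing grid geometry (unnormalized).
model_density_on_grid <- function(xyz, atom_names, grid, resolution,
                                  b_factor = 15) {
  d <- grid$dims; sp <- grid$spacing; lo <- grid$origin
  vals <- array(0, dim = d)
  sigma <- sqrt(b_factor / (8 * pi^2))
  cutoff <- 4.5 * sigma
  ax <- lapply(1:3, function(a) lo[a] + (0:(d[a] - 1)) * sp[a])
  w <- .atomic_number[atom_names]
  for (i in seq_len(nrow(xyz))) {
    rng <- lapply(1:3, function(a) which(abs(ax[[a]] - xyz[i, a]) <= cutoff))
    if (any(lengths(rng) == 0)) next
    g <- lapply(1:3, function(a)
      exp(-(ax[[a]][rng[[a]]] - xyz[i, a])^2 / (2 * sigma^2)))
    vals[rng[[1]], rng[[2]], rng[[3]]] <-
      vals[rng[[1]], rng[[2]], rng[[3]], drop = FALSE] +
      w[i] * (g[[1]] %o% g[[2]] %o% g[[3]])
  }
  tmp <- density_grid(vals, origin = lo, spacing = sp)
  if (resolution >= 2 * max(sp)) tmp <- lowpass_grid(tmp, resolution)
  tmp$values
}

# Logical array: grid points within radius of any atom.
mask_near_atoms <- function(grid, xyz, radius) {
  d <- grid$dims; sp <- grid$spacing; lo <- grid$origin
  mask <- array(FALSE, dim = d)
  ax <- lapply(1:3, function(a) lo[a] + (0:(d[a] - 1)) * sp[a])
  for (i in seq_len(nrow(xyz))) {
    rng <- lapply(1:3, function(a) which(abs(ax[[a]] - xyz[i, a]) <= radius))
    if (any(lengths(rng) == 0)) next
    dx2 <- outer(outer((ax[[1]][rng[[1]]] - xyz[i, 1])^2,
                       (ax[[2]][rng[[2]]] - xyz[i, 2])^2, "+"),
                 (ax[[3]][rng[[3]]] - xyz[i, 3])^2, "+")
    mask[rng[[1]], rng[[2]], rng[[3]]] <-
      mask[rng[[1]], rng[[2]], rng[[3]], drop = FALSE] | (dx2 <= radius^2)
  }
  mask
}

#' Full evaluation report
#'
#' @param built a built model (\code{sheet_build}, \code{sheet_model}
#'   or \code{chain_model}).
#' @param reference reference \code{chain_model} with strand flags.
#' @param grid optional \code{density_grid} for the map-model CC.
#' @param match_radius CA match radius, A.
#' @param mask_radius CC mask radius, A.
#' @return An \code{eval_report} list: n_strand_ref, n_built, n_correct,
#'   recall, precision, rmsd_mainchain, strand_map_cc.
#' @export
evaluate_model <- function(built, reference, grid = NULL,
                           match_radius = 3.0, mask_radius = 2.0) {
  built <- as_chain_model(built)
  cc <- count_correct(built, reference, match_radius)
  rmsd <- if (cc$n_correct > 0) mainchain_rmsd(built, reference, match_radius)
          else NA_real_
  mcc <- if (!is.null(grid) && nrow(built) > 0)
    strand_map_cc(grid, built, mask_radius) else NA_real_
  structure(list(
    n_strand_ref = sum(reference$is_strand[!duplicated(
      paste(reference$chain, reference$res_seq))]),
    n_built = cc$n_built, n_correct = cc$n_correct,
    recall = cc$recall, precision = cc$precision,
    rmsd_mainchain = rmsd, strand_map_cc = mcc), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("strand residues: reference %d, built %d, correct %d\n",
              x$n_strand_ref, x$n_built, x$n_correct))
  cat(sprintf("recall %.2f, precision %.2f, main-chain RMSD %.2f A, map CC %.2f\n",
              x$recall, x$precision, x$rmsd_mainchain, x$strand_map_cc))
  invisible(x)
}

#' Sweep the tube-correlation threshold
#'
#' Re-runs the full pipeline for each value of \code{cc_strand_min} and
#' reports the main-chain RMSD and residues built against the
#' reference: the accuracy/completeness trade-off of the tube filter.
#'
#' @param grid a \code{density_grid}.
#' @param reference reference \code{chain_model} with strand flags.
#' @param values thresholds to test.
#' @param config base \code{\link{sheet_config}}.
#' @return data.frame with columns cc_strand_min, rmsd, n_built.
#' @export
sweep_cc_strand_min <- function(grid, reference,
                                values = seq(0.1, 0.7, by = 0.1),
                                config = sheet_config()) {
  rows <- lapply(values, function(v) {
    cfg <- config
    cfg$tubes$cc_strand_min <- v
    bs <- build_sheets(grid, cfg)
    ev <- evaluate_model(bs, reference)
    data.frame(cc_strand_min = v, rmsd = ev$rmsd_mainchain,
               n_built = ev$n_built)
  })
  do.call(rbind, rows)
}
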