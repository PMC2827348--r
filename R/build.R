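#' Configuration for the beta-sheet building pipeline
#'
#' Collects every tunable parameter, grouped by stage, with the method's
#' typical values as defaults. Any entry can be overridden by name;
#' configurations round-trip through YAML via
#' \code{\link{read_config}} / \code{\link{write_config}}.
#'
#' @param tubes named overrides for the tube stage: \code{spacing},
#'   \code{density_floor}, \code{cut1}, \code{cut2}, \code{line_step},
#'   \code{min_cos}, \code{target_sep}, \code{sep_tol},
#'   \code{cc_strand_min}, \code{tube_radius}, \code{min_tube_len},
#'   \code{max_link}, \code{extend_step}, \code{max_bend_deg},
#'   \code{bend_step_deg}.
#' @param register named overrides: \code{period}, \code{probe_radius},
#'   \code{phase_tol}, \code{n_phase_bins}, \code{smoothing},
#'   \code{calibrate}.
#' @param assembly named overrides: \code{overlap_dist},
#'   \code{min_sequential_overlap}, \code{min_fragment},
#'   \code{merge_resolutions}, \code{clash_dist}.
#' @param evaluate named overrides: \code{match_radius},
#'   \code{mask_radius}.
#' @param rng_seed seed for any stochastic component (the core
#'   map-to-model path is deterministic).
#' @param verbose print per-stage counts while running.
#' @return A \code{sheet_config} list.
#' @export
sheet_config <- function(tubes = list(), register = list(),
                         assembly = list(), evaluate = list(),
                         rng_seed = 1, verbose = FALSE) {
  merge_over <- function(defaults, over) {
    bad <- setdiff(names(over), names(defaults))
    if (length(bad)) stop("unknown config entries: ", paste(bad, collapse = ", "))
    defaults[names(over)] <- over
    defaults
  }
  cfg <- list(
    tubes = merge_over(list(
      spacing = 2.0, density_floor = 1.0, cut1 = 0.5, cut2 = 0.75,
      line_step = 0.25, min_cos = 0.5, target_sep = 4.5, sep_tol = 2.0,
      cc_strand_min = 0.5, tube_radius = 1.5, min_tube_len = 4,
      max_link = 4.2, extend_step = 1.0, max_bend_deg = 15,
      bend_step_deg = 5), tubes),
    register = merge_over(list(
      period = 6.7, probe_radius = 1.5, phase_tol = 1 / 12,
      n_phase_bins = 36, smoothing = 3, calibrate = TRUE), register),
    assembly = merge_over(list(
      overlap_dist = 1.0, min_sequential_overlap = 2, min_fragment = 4,
      merge_resolutions = c(2.5, 3.0, 4.0), clash_dist = 2.0), assembly),
    evaluate = merge_over(list(match_radius = 3.0, mask_radius = 2.0),
                          evaluate),
    rng_seed = rng_seed, verbose = verbose)
  structure(cfg, class = "sheet_config")
}

config_conn <- function(config)
  conn_params(config$tubes$cut1, config$tubes$cut2, config$tubes$line_step)

config_pair <- function(config)
  pair_params(config$tubes$min_cos, config$tubes$target_sep,
              config$tubes$sep_tol, config$tubes$cc_strand_min,
              config$tubes$tube_radius, config$tubes$min_tube_len)

config_register <- function(config)
  register_params(config$register$period, config$register$probe_radius,
                  config$register$phase_tol, config$register$n_phase_bins,
                  config$register$smoothing)

config_assembly <- function(config)
  assembly_params(config$assembly$overlap_dist,
                  config$assembly$min_sequential_overlap,
                  config$assembly$min_fragment,
                  config$assembly$merge_resolutions,
                  config$assembly$clash_dist)

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return \code{read_config} returns a \code{sheet_config};
#'   \code{write_config} returns \code{path} invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(sheet_config, raw)
}

#' @rdname read_config
#' @param config a \code{sheet_config}.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' Find placed strand candidates in a map at one resolution
#'
#' One pass of the first two stages: ridge points, tubes, parallel
#' pairing, sheet-perpendicular extension, template-correlation scoring,
#' then register and direction analysis and idealized strand placement
#' for each accepted tube.
#'
#' @param grid a normalized \code{density_grid}.
#' @param config a \code{\link{sheet_config}}.
#' @param resolution analysis resolution recorded in provenance (and
#'   used for register calibration); defaults to the grid's hint.
#' @return list of fragments (model + score + provenance).
#' @export
find_strand_candidates <- function(grid, config = sheet_config(),
                                   resolution = NULL) {
  resolution <- resolution %||% grid$resolution_hint %||% 2.5
  tp <- config$tubes
  conn <- config_conn(config)
  pairp <- config_pair(config)
  regp <- config_register(config)
  cal <- if (isTRUE(config$register$calibrate))
    register_calibration(resolution, regp) else no_calibration()
  template <- repeat_template()
  say <- function(...) if (isTRUE(config$verbose)) message(sprintf(...))

  pts <- find_ridgeline_points(grid, tp$spacing, tp$density_floor)
  say("[%.1f A] ridge points: %d", resolution, nrow(pts))
  if (nrow(pts) < 2) return(list())
  tubes <- build_tubes(pts, grid, conn, tp$min_cos, tp$max_link)
  say("[%.1f A] tubes: %d", resolution, length(tubes))
  pp <- find_parallel_pairs(tubes, grid, pairp, conn)
  tubes <- pp$tubes
  paired <- which(!vapply(tubes, function(t) is.null(t$neighbour_dir),
                          logical(1)))
  say("[%.1f A] paired tubes: %d (%d pairs)", resolution, length(paired),
      nrow(pp$pairs))
  out <- list()
  for (k in paired) {
    tube <- extend_tube(grid, tubes[[k]], tp$extend_step, tp$max_bend_deg,
                        tp$bend_step_deg, conn)
    tube$axis <- smooth_axis(tube$axis, window = regp$period)
    if (tube_length(tube) < max(3, 2 * regp$period)) next
    tube <- score_tube(grid, tube, pairp)
    if (tube$rejected) next
    prof <- average_over_repeats(grid, tube$axis, tube$neighbour_dir, regp)
    cp <- find_carbonyl_phase(prof, regp, cal)
    if (!cp$accepted) next
    dirn <- determine_direction(prof, cp$phase, regp, cal)
    # place both directions and refine each by a small rigid translation
    # maximizing atom-weighted density, so the two are compared at their
    # own optima; a reversed antiparallel strand nearly reproduces the
    # density pattern (pseudo-2-fold of the ladder), and the refined
    # whole-atom fit is what separates the twins reliably. The peak test
    # counts as unambiguous only when the density fit agrees with it.
    cands <- place_strand(tube$axis, tube$neighbour_dir, cp$phase,
                          "ambiguous", tube$score, regp, template, cal)
    if (length(cands) == 0) next
    fits <- lapply(cands, function(cd)
      refine_translation(grid, cd$model))
    best <- which.max(vapply(fits, `[[`, 0, "fit"))
    cd <- cands[[best]]
    cd$model <- fits[[best]]$model
    unambiguous <- dirn != "ambiguous" && dirn == cd$direction
    frag <- new_fragment(cd$model, score = NA_real_,
                         id = sprintf("r%.1f-t%02d-%s", resolution, k,
                                      substr(cd$direction, 1, 1)),
                         resolution = resolution,
                         direction = if (unambiguous) cd$direction
                                     else "ambiguous")
    # assembly rank: the tube score form evaluated on the placed atoms
    atom_rho <- interpolate_map(grid, as.matrix(cd$model[, c("x", "y", "z")]))
    frag$score <- mean(pmax(0, atom_rho)) * sqrt(frag_len_A(frag))
    frag$tube_score <- cd$score
    frag$placed_direction <- cd$direction
    out[[length(out) + 1]] <- frag
  }
  say("[%.1f A] placed candidates: %d", resolution, length(out))
  out
}

#' Refine a placed strand by rigid translation
#'
#' Shifts the model rigidly (up to \code{max_shift} per axis) to
#' maximize the atomic-number-weighted mean map density at its atoms.
#'
#' @param grid a \code{density_grid}.
#' @param model a \code{chain_model}.
#' @param max_shift bound on the shift per coordinate, A.
#' @return list(model = shifted model, fit = weighted mean density,
#'   shift = applied translation).
#' @export
refine_translation <- function(grid, model, max_shift = 1.2) {
  xyz <- as.matrix(model[, c("x", "y", "z")])
  w <- .atomic_number[model$atom_name]
  obj <- function(t)
    -sum(w * interpolate_map(grid, sweep(xyz, 2, t, "+"))) / sum(w)
  op <- stats::optim(c(0, 0, 0), obj, method = "L-BFGS-B",
                     lower = rep(-max_shift, 3), upper = rep(max_shift, 3))
  model$x <- model$x + op$par[1]
  model$y <- model$y + op$par[2]
  model$z <- model$z + op$par[3]
  list(model = model, fit = -op$value, shift = op$par)
}

#' Build the beta-sheet model for a density map
#'
#' The full pipeline: multi-resolution strand search (tubes, register,
#' placement), fragment joining and greedy non-overlapping selection.
#'
#' @param map a \code{density_grid} or path to a CCP4/MRC map.
#' @param config a \code{\link{sheet_config}}.
#' @return A \code{sheet_build} object: fields \code{model} (combined
#'   \code{chain_model}; empty when nothing was found), \code{sheet}
#'   (the \code{sheet_model}), \code{candidates}, \code{report}
#'   (per-stage counts) and \code{config}.
#' @export
build_sheets <- function(map, config = sheet_config()) {
  grid <- if (is.character(map)) read_map(map) else map
  stopifnot(inherits(grid, "density_grid"))
  ap <- config_assembly(config)
  cands <- run_multiresolution(grid, config)
  chains <- join_fragments(cands, ap)
  sheet <- greedy_select(chains, ap)
  report <- list(
    n_candidates = length(cands),
    n_joined = length(chains),
    n_fragments = length(sheet$fragments),
    n_residues = n_residues(sheet$model),
    resolutions = sort(unique(vapply(cands, `[[`, 0, "resolution"))),
    scores = vapply(sheet$fragments, `[[`, 0, "score"))
  structure(list(model = sheet$model, sheet = sheet, candidates = cands,
                 report = report, config = config, grid_dims = grid$dims),
            class = "sheet_build")
}

#' @export
print.sheet_build <- function(x, ...) {
  cat("Beta-sheet model building\n")
  cat(sprintf("  map: %d x %d x %d voxels\n", x$grid_dims[1], x$grid_dims[2],
              x$grid_dims[3]))
  cat(sprintf("  candidates: %d (resolutions %s A)\n", x$report$n_candidates,
              paste(x$report$resolutions, collapse = ", ")))
  cat(sprintf("  assembled: %d fragment(s), %d residues\n",
              x$report$n_fragments, x$report$n_residues))
  invisible(x)
}

#' @export
summary.sheet_build <- function(object, ...) {
  print(object)
  if (length(object$sheet$fragments)) {
    cat("  fragments:\n")
    for (f in object$sheet$fragments)
      cat(sprintf("    %-16s %2d residues  score %6.2f  direction %s\n",
                  f$id, n_residues(f$model), f$score, f$direction))
  }
  invisible(object)
}

#' Plot an assembled beta-sheet model
#'
#' Projects the CA traces of the assembled fragments onto two of the
#' three coordinate axes, one colour per fragment.
#'
#' @param x a \code{sheet_build}.
#' @param dims which two coordinates to plot (default x, y).
#' @param ... passed to \code{plot}.
#' @export
plot.sheet_build <- function(x, dims = c(1, 2), ...) {
  labs <- c("x (A)", "y (A)")[c(1, 2)]
  frags <- x$sheet$fragments
  if (length(frags) == 0) {
    plot(0, 0, type = "n", xlab = labs[1], ylab = labs[2],
         main = "no fragments built", ...)
    return(invisible(x))
  }
  cas <- lapply(frags, frag_ca)
  all_xy <- do.call(rbind, cas)[, dims, drop = FALSE]
  plot(all_xy, type = "n", xlab = c("x (A)", "y (A)", "z (A)")[dims[1]],
       ylab = c("x (A)", "y (A)", "z (A)")[dims[2]],
       main = "assembled beta-sheet CA traces", asp = 1, ...)
  cols <- grDevices::hcl.colors(max(3, length(cas)), "Dark 3")
  for (i in seq_along(cas)) {
    xy <- cas[[i]][, dims, drop = FALSE]
    graphics::lines(xy, col = cols[i], lwd = 2)
    graphics::points(xy, col = cols[i], pch = 16, cex = 0.7)
  }
  invisible(x)
}
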