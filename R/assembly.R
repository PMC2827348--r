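# Stage 3: assemble strand candidates into a single non-overlapping
# beta-sheet model. Candidates from analyses at several resolutions are
# pooled, fragments sharing sequential CA positions are spliced into
# longer chains, and a greedy selection keeps the highest-scoring
# non-overlapping set.

#' Assembly parameters
#'
#' @param overlap_dist CA-CA distance below which two residues count as
#'   the same position, A (default 1).
#' @param min_sequential_overlap sequential overlapping CA atoms
#'   required to join or to delete, residues (default 2).
#' @param min_fragment minimum fragment length kept, residues
#'   (default 4).
#' @param merge_resolutions resolutions whose strand searches are
#'   merged, A (default 2.5, 3, 4; entries finer than the map
#'   resolution are raised to it).
#' @param clash_dist CA-CA distance treated as a steric clash when
#'   trimming partially overlapping chains, A (default 2).
#' @return An \code{assembly_params} list.
#' @export
assembly_params <- function(overlap_dist = 1.0, min_sequential_overlap = 2,
                            min_fragment = 4,
                            merge_resolutions = c(2.5, 3.0, 4.0),
                            clash_dist = 2.0) {
  stopifnot(min_fragment >= min_sequential_overlap, overlap_dist > 0)
  structure(list(overlap_dist = overlap_dist,
                 min_sequential_overlap = min_sequential_overlap,
                 min_fragment = min_fragment,
                 merge_resolutions = merge_resolutions,
                 clash_dist = clash_dist),
            class = "assembly_params")
}

# A fragment: a chain model plus assembly bookkeeping.
new_fragment <- function(model, score, id, resolution = NA_real_,
                         direction = NA_character_) {
  list(model = model, score = score, id = id, resolution = resolution,
       direction = direction)
}

frag_ca <- function(frag) atom_coords(frag$model, "CA")

frag_len_A <- function(frag) {
  ca <- frag_ca(frag)
  s <- arclength(ca)
  s[length(s)]
}

# Longest run of TRUE values.
longest_run <- function(flags) {
  if (!any(flags)) return(0L)
  r <- rle(flags)
  max(r$lengths[r$values])
}

# Number of sequential residues of A whose CA lies within dist of some CA
# of B.
sequential_overlap <- function(caA, caB, dist) {
  d2 <- outer(rowSums(caA^2), rowSums(caB^2), "+") - 2 * caA %*% t(caB)
  near <- apply(d2, 1, min) <= dist^2 + 1e-12
  longest_run(near)
}

fragments_overlap <- function(fa, fb, params) {
  sequential_overlap(frag_ca(fa), frag_ca(fb), params$overlap_dist) >=
    params$min_sequential_overlap
}

#' Pool strand candidates from multi-resolution analyses
#'
#' Runs the tube-finding and register pipeline once per resolution in
#' \code{merge_resolutions} (the map is low-pass filtered to each;
#' entries finer than the map's own resolution are raised to it) and
#' concatenates the candidate pools with per-candidate provenance.
#'
#' @param grid a \code{density_grid} with \code{resolution_hint} set.
#' @param config a \code{\link{sheet_config}}.
#' @return list of fragments (placed strand models with scores,
#'   candidate ids and source resolutions).
#' @export
run_multiresolution <- function(grid, config = sheet_config()) {
  hint <- grid$resolution_hint %||% max(2.5, 2 * max(grid$spacing))
  res_list <- sort(unique(pmax(config$assembly$merge_resolutions, hint)))
  out <- list()
  for (r in res_list) {
    gr <- if (r > hint + 1e-6) normalize_grid(lowpass_grid(grid, r)) else grid
    cands <- find_strand_candidates(gr, config, resolution = r)
    out <- c(out, cands)
  }
  # make ids unique across the pool, keeping provenance
  for (i in seq_along(out)) out[[i]]$id <- sprintf("%s#%02d", out[[i]]$id, i)
  out
}

#' Join overlapping strand fragments into longer chains
#'
#' Fragments whose terminal stretches share at least
#' \code{min_sequential_overlap} sequential CA positions pairwise within
#' \code{overlap_dist} (running in the same direction) are spliced into
#' one chain, keeping the higher-scoring copy in the overlap region.
#' Fragments running in opposite directions are never joined. The
#' joined score is the length-weighted mean density score of the
#' members rescaled by the square root of the total length, staying
#' commensurate with the tube score.
#'
#' @param fragments list of fragments (from
#'   \code{\link{run_multiresolution}}).
#' @param params an \code{assembly_params}.
#' @return list of fragments with overlaps spliced.
#' @export
join_fragments <- function(fragments, params = assembly_params()) {
  pool <- fragments
  repeat {
    joined <- FALSE
    ord <- order(-vapply(pool, `[[`, 0, "score"))
    pool <- pool[ord]
    n <- length(pool)
    if (n < 2) break
    for (i in seq_len(n - 1)) {
      for (j in seq_len(n)) {
        if (i == j) next
        sp <- splice_fragments(pool[[i]], pool[[j]], params)
        if (!is.null(sp)) {
          pool <- c(pool[-c(i, j)], list(sp))
          joined <- TRUE
          break
        }
      }
      if (joined) break
    }
    if (!joined) break
  }
  pool
}

# Try to splice B onto A (suffix of A = prefix of B, or A contains B).
# Returns the joined fragment or NULL.
splice_fragments <- function(fa, fb, params) {
  caA <- frag_ca(fa); caB <- frag_ca(fb)
  nA <- nrow(caA); nB <- nrow(caB)
  if (nA < 2 || nB < 2) return(NULL)
  dirA <- unit(caA[nA, ] - caA[1, ])
  dirB <- unit(caB[nB, ] - caB[1, ])
  if (sum(dirA * dirB) <= 0) return(NULL)  # direction conflict
  kmax <- min(nA, nB)
  if (kmax < params$min_sequential_overlap) return(NULL)
  for (k in kmax:params$min_sequential_overlap) {
    idxA <- (nA - k + 1):nA
    idxB <- 1:k
    d <- sqrt(rowSums((caA[idxA, , drop = FALSE] - caB[idxB, , drop = FALSE])^2))
    if (all(d <= params$overlap_dist)) {
      if (k == nB) return(merge_models(fa, fb, nA, 0, params))  # B inside A
      if (k == nA && nB > nA) return(merge_models(fb, fa, nB, 0, params))
      return(merge_models(fa, fb, nA, nB - k, params))
    }
  }
  NULL
}

# Joined fragment: first keepA residues of A followed by the last keepB
# residues of B, with the overlap kept from the higher-scoring member.
merge_models <- function(fa, fb, keepA, keepB, params) {
  mA <- as.data.frame(fa$model)
  mB <- as.data.frame(fb$model)
  resA <- unique(mA$res_seq)
  resB <- unique(mB$res_seq)
  if (keepB > 0 && fb$score > fa$score) {
    # give the overlap region to B instead
    k <- length(resB) - keepB
    keepA <- keepA - k
    keepB <- keepB + k
  }
  segA <- mA[mA$res_seq %in% resA[seq_len(keepA)], , drop = FALSE]
  segB <- if (keepB > 0)
    mB[mB$res_seq %in% resB[(length(resB) - keepB + 1):length(resB)], , drop = FALSE]
  else mB[0, , drop = FALSE]
  out <- rbind(segA, segB)
  out$res_seq <- rep(seq_len(nrow(out) / 5), each = 5)
  out$chain <- "A"
  rownames(out) <- NULL
  model <- chain_model(out)
  lA <- frag_len_A(fa); lB <- frag_len_A(fb)
  mean_d <- (fa$score / sqrt(max(lA, 1e-6)) * lA +
             fb$score / sqrt(max(lB, 1e-6)) * lB) / (lA + lB)
  frag <- new_fragment(model, NA_real_,
                       id = paste(sort(c(fa$id, fb$id)), collapse = "+"),
                       resolution = fa$resolution)
  frag$score <- unname(mean_d * sqrt(frag_len_A(frag)))
  frag
}

#' Greedily select a non-overlapping beta-sheet model
#'
#' Repeatedly takes the highest-scoring chain (ties broken by longer
#' fragment, then lexicographic candidate id), deletes every remaining
#' chain that overlaps it in two or more sequential CA positions, and
#' trims surviving chains of residues clashing with the selected model,
#' until no chain of at least \code{min_fragment} residues remains.
#'
#' @param fragments list of fragments (typically from
#'   \code{\link{join_fragments}}).
#' @param params an \code{assembly_params}.
#' @return A \code{sheet_model}: list with \code{fragments} (selected,
#'   in selection order) and \code{model} (combined
#'   \code{chain_model}, chains named A, B, ... in score order).
#' @export
greedy_select <- function(fragments, params = assembly_params()) {
  pool <- Filter(function(f) n_residues(f$model) >= params$min_fragment,
                 fragments)
  chosen <- list()
  while (length(pool) > 0) {
    sc <- vapply(pool, `[[`, 0, "score")
    len <- vapply(pool, function(f) n_residues(f$model), 0L)
    ids <- vapply(pool, `[[`, "", "id")
    best <- order(-sc, -len, ids)[1]
    pick <- pool[[best]]
    chosen[[length(chosen) + 1]] <- pick
    pool <- pool[-best]
    if (length(pool) == 0) break
    keep <- !vapply(pool, function(f) fragments_overlap(f, pick, params),
                    logical(1))
    pool <- pool[keep]
    pool <- Filter(Negate(is.null),
                   lapply(pool, trim_clashes, pick = pick, params = params))
  }
  structure(list(fragments = chosen,
                 model = bind_models(lapply(chosen, `[[`, "model"))),
            class = "sheet_model")
}

# Drop residues of f whose CA clashes (< clash_dist) with the picked
# fragment; keep the longest contiguous remainder, or NULL if too short.
trim_clashes <- function(f, pick, params) {
  ca <- frag_ca(f)
  cap <- frag_ca(pick)
  d2 <- outer(rowSums(ca^2), rowSums(cap^2), "+") - 2 * ca %*% t(cap)
  clash <- apply(d2, 1, min) < params$clash_dist^2
  if (!any(clash)) return(f)
  ok <- !clash
  r <- rle(ok)
  if (!any(r$values)) return(NULL)
  runs <- which(r$values)
  lens <- r$lengths[runs]
  if (max(lens) < params$min_fragment) return(NULL)
  ri <- runs[which.max(lens)]
  start <- if (ri == 1) 1 else sum(r$lengths[1:(ri - 1)]) + 1
  keep_res <- unique(f$model$res_seq)[start:(start + max(lens) - 1)]
  m <- as.data.frame(f$model)
  m <- m[m$res_seq %in% keep_res, , drop = FALSE]
  m$res_seq <- rep(seq_len(nrow(m) / 5), each = 5)
  rownames(m) <- NULL
  f$model <- chain_model(m)
  f
}

#' @export
print.sheet_model <- function(x, ...) {
  cat(sprintf("sheet_model: %d fragment(s), %d residues\n",
              length(x$fragments), n_residues(x$model)))
  for (f in x$fragments)
    cat(sprintf("  %s: %d residues, score %.2f (%.1f A analysis)\n",
                f$id, n_residues(f$model), f$score, f$resolution))
  invisible(x)
}
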