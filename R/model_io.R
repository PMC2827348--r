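#' Construct a chain model
#'
#' A backbone-only atomic model: an ordered table of atoms (N, CA, C, O,
#' CB) with chain identifiers, residue numbers and Angstrom coordinates,
#' optionally carrying a per-residue beta-strand flag.
#'
#' @param atoms data.frame with columns \code{chain}, \code{res_seq},
#'   \code{res_name}, \code{atom_name}, \code{x}, \code{y}, \code{z} and
#'   optionally \code{is_strand}.
#' @return An object of class \code{chain_model} (a data.frame).
#' @export
chain_model <- function(atoms) {
  need <- c("chain", "res_seq", "res_name", "atom_name", "x", "y", "z")
  if (!all(need %in% names(atoms)))
    stop("atoms must have columns ", paste(need, collapse = ", "))
  bad <- !atoms$atom_name %in% c("N", "CA", "C", "O", "CB")
  if (any(bad))
    stop("unsupported atom names: ",
         paste(unique(atoms$atom_name[bad]), collapse = ", "))
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("atom coordinates must be finite")
  if (is.null(atoms$is_strand)) atoms$is_strand <- FALSE
  for (ch in unique(atoms$chain)) {
    rs <- unique(atoms$res_seq[atoms$chain == ch])
    if (any(diff(rs) <= 0))
      stop("residue numbers must be strictly increasing within chain ", ch)
  }
  class(atoms) <- c("chain_model", "data.frame")
  atoms
}

# Coordinates of one atom type per residue, in residue order.
# Returns a matrix with rownames "chain:res_seq".
atom_coords <- function(model, atom = "CA") {
  sub <- model[model$atom_name == atom, , drop = FALSE]
  m <- as.matrix(sub[, c("x", "y", "z")])
  rownames(m) <- paste(sub$chain, sub$res_seq, sep = ":")
  m
}

# Residue table: one row per residue with chain, res_seq, is_strand.
residue_table <- function(model) {
  key <- !duplicated(paste(model$chain, model$res_seq))
  data.frame(chain = model$chain[key], res_seq = model$res_seq[key],
             is_strand = model$is_strand[key], stringsAsFactors = FALSE)
}

n_residues <- function(model) {
  length(unique(paste(model$chain, model$res_seq)))
}

#' @export
print.chain_model <- function(x, ...) {
  cat(sprintf("chain_model: %d atoms, %d residues, %d chain(s)\n",
              nrow(x), n_residues(x), length(unique(x$chain))))
  invisible(x)
}

#' Read a PDB-format atomic model
#'
#' Reads backbone and C-beta atoms (N, CA, C, O, CB) via
#' \code{bio3d::read.pdb}; other atoms are dropped. A residue with no CA
#' atom triggers a warning but is retained.
#'
#' @param path PDB file path.
#' @param strand_flags optional path to a strand-flag TSV (see
#'   \code{\link{read_strand_flags}}) to annotate residues.
#' @return A \code{chain_model}.
#' @export
read_model <- function(path, strand_flags = NULL) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$elety %in% c("N", "CA", "C", "O", "CB"), , drop = FALSE]
  if (nrow(at) == 0) stop("no backbone atoms found in ", path)
  m <- chain_model(data.frame(
    chain = as.character(at$chain), res_seq = as.integer(at$resno),
    res_name = as.character(at$resid), atom_name = as.character(at$elety),
    x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE))
  rt <- residue_table(m)
  has_ca <- paste(m$chain, m$res_seq)[m$atom_name == "CA"]
  miss <- !(paste(rt$chain, rt$res_seq) %in% has_ca)
  if (any(miss))
    warning(sum(miss), " residue(s) without a CA atom retained but flagged")
  attr(m, "missing_ca") <- rt[miss, c("chain", "res_seq")]
  if (!is.null(strand_flags)) m <- apply_strand_flags(m, read_strand_flags(strand_flags))
  m
}

#' Write a chain model to a PDB file
#'
#' @param model a \code{chain_model}.
#' @param path output path.
#' @param b optional numeric vector (one per atom) written to the B-factor
#'   column; assembled models store fragment scores there.
#' @return \code{path}, invisibly.
#' @export
write_model <- function(model, path, b = NULL) {
  stopifnot(inherits(model, "chain_model"))
  xyz <- as.vector(t(as.matrix(model[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = model$res_seq,
                   resid = model$res_name,
                   chain = model$chain,
                   elety = model$atom_name,
                   o = rep(1, nrow(model)),
                   b = if (is.null(b)) rep(0, nrow(model)) else b)
  invisible(path)
}

#' Read / write per-residue strand flags
#'
#' Strand annotations are consumed as input (for synthetic fixtures they
#' come from the generator's truth table; for experimental references from
#' any secondary-structure assignment). TSV columns: chain, res_seq,
#' is_strand.
#'
#' @param path TSV file path.
#' @return data.frame with columns chain, res_seq, is_strand.
#' @export
read_strand_flags <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chain", "res_seq", "is_strand")
  if (!all(need %in% names(df)))
    stop("strand-flag table must have columns ", paste(need, collapse = ", "))
  df$is_strand <- as.logical(df$is_strand)
  df
}

#' @rdname read_strand_flags
#' @param flags data.frame with columns chain, res_seq, is_strand.
#' @export
write_strand_flags <- function(flags, path) {
  utils::write.table(flags[, c("chain", "res_seq", "is_strand")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

apply_strand_flags <- function(model, flags) {
  key <- paste(model$chain, model$res_seq)
  fkey <- paste(flags$chain, flags$res_seq)
  hit <- match(key, fkey)
  model$is_strand <- ifelse(is.na(hit), FALSE, flags$is_strand[hit])
  model
}

# Concatenate chain models, assigning fresh chain ids A, B, C, ... in the
# given order (assembly output convention).
bind_models <- function(models) {
  if (length(models) == 0)
    return(chain_model(data.frame(chain = character(), res_seq = integer(),
                                  res_name = character(), atom_name = character(),
                                  x = numeric(), y = numeric(), z = numeric(),
                                  is_strand = logical(), stringsAsFactors = FALSE)))
  ids <- make_chain_ids(length(models))
  out <- do.call(rbind, lapply(seq_along(models), function(i) {
    m <- as.data.frame(models[[i]])
    m$chain <- ids[i]
    m
  }))
  rownames(out) <- NULL
  chain_model(out)
}

make_chain_ids <- function(n) {
  pool <- c(LETTERS, letters, as.character(0:9))
  if (n <= length(pool)) return(pool[seq_len(n)])
  c(pool, paste0("Z", seq_len(n - length(pool))))
}
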