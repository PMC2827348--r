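#' Construct a density grid
#'
#' An orthogonal voxel grid of density values with an Angstrom coordinate
#' frame. The world coordinate of voxel (i, j, k) (0-based) is
#' \code{origin + c(i, j, k) * spacing}.
#'
#' @param values 3-D numeric array of density values.
#' @param origin numeric length-3, Angstrom position of voxel (0,0,0).
#' @param spacing numeric length-3, Angstrom per voxel along each axis.
#' @param resolution_hint optional resolution (Angstrom) the map was
#'   computed or truncated at.
#' @return An object of class \code{density_grid}.
#' @export
density_grid <- function(values, origin = c(0, 0, 0), spacing = c(1, 1, 1),
                         resolution_hint = NULL) {
  stopifnot(is.array(values), length(dim(values)) == 3)
  spacing <- unname(rep_len(as.numeric(spacing), 3))
  origin <- unname(rep_len(as.numeric(origin), 3))
  if (any(spacing <= 0)) stop("grid spacing must be positive")
  if (!all(is.finite(values))) stop("grid values must be finite")
  structure(list(values = values, origin = origin, spacing = spacing,
                 dims = unname(dim(values)), resolution_hint = resolution_hint),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("density_grid: %d x %d x %d voxels, spacing %.3g x %.3g x %.3g A\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%.2f, %.2f, %.2f) A; density mean %.3g sd %.3g\n",
              x$origin[1], x$origin[2], x$origin[3],
              mean(x$values), stats::sd(x$values)))
  if (!is.null(x$resolution_hint))
    cat(sprintf("  resolution hint %.2f A\n", x$resolution_hint))
  invisible(x)
}

#' Normalize a grid to zero mean and unit standard deviation
#'
#' Densities are reported in map-sigma units throughout the package;
#' ratio-based connection thresholds are unchanged by this but detection
#' floors become comparable across maps.
#'
#' @param grid a \code{density_grid}.
#' @return The normalized \code{density_grid}.
#' @export
normalize_grid <- function(grid) {
  s <- stats::sd(grid$values)
  if (s < 1e-12) {
    grid$values <- grid$values - mean(grid$values)
  } else {
    grid$values <- (grid$values - mean(grid$values)) / s
  }
  grid
}

# ---- CCP4/MRC binary format ------------------------------------------------
# 1024-byte header (MRC2014), mode 2 (float32), P1 orthorhombic cells only,
# axis order X, Y, Z. Little-endian on disk.

#' Write a density map in CCP4/MRC format
#'
#' @param grid a \code{density_grid}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_map <- function(grid, path) {
  stopifnot(inherits(grid, "density_grid"))
  con <- file(path, "wb")
  on.exit(close(con))
  dims <- as.integer(grid$dims)
  cell <- grid$dims * grid$spacing
  vals <- as.numeric(grid$values)
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(dims)                      # NX NY NZ (fastest axis first)
  wi(2L)                        # MODE 2 = float32
  wi(c(0L, 0L, 0L))             # NXSTART..NZSTART
  wi(dims)                      # MX MY MZ
  wf(cell)                      # CELLA
  wf(c(90, 90, 90))             # CELLB
  wi(c(1L, 2L, 3L))             # MAPC MAPR MAPS
  wf(c(min(vals), max(vals), mean(vals)))  # DMIN DMAX DMEAN
  wi(1L)                        # ISPG
  wi(0L)                        # NSYMBT
  wi(rep(0L, 13))               # EXTRA words 25-37
  # word 38 reused to carry the resolution hint (0 = unset)
  wf(if (is.null(grid$resolution_hint)) 0 else grid$resolution_hint)
  wi(rep(0L, 11))               # EXTRA words 39-49
  wf(grid$origin)               # ORIGIN (MRC2014)
  writeBin(charToRaw("MAP "), con)          # word 53
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machine stamp, LE
  wf(stats::sd(vals))           # RMS
  wi(0L)                        # NLABL
  writeBin(raw(800), con)       # labels
  writeBin(vals, con, size = 4, endian = "little")
  invisible(path)
}

#' Read a CCP4/MRC density map
#'
#' Only P1 orthorhombic maps in standard X, Y, Z axis order are supported;
#' the grid is normalized to zero mean and unit standard deviation on load.
#'
#' @param path path to a CCP4/MRC file.
#' @param normalize normalize to sigma units on load (default \code{TRUE}).
#' @return A \code{density_grid}.
#' @export
read_map <- function(path, normalize = TRUE) {
  if (!file.exists(path)) stop("map file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", 1024)
  if (length(hdr_raw) < 1024) stop("not a CCP4/MRC map: truncated header")
  ri <- function(word, n = 1)
    readBin(hdr_raw[(4 * (word - 1) + 1):(4 * (word - 1) + 4 * n)],
            "integer", n, size = 4, endian = "little")
  rf <- function(word, n = 1)
    readBin(hdr_raw[(4 * (word - 1) + 1):(4 * (word - 1) + 4 * n)],
            "numeric", n, size = 4, endian = "little")
  map_tag <- rawToChar(hdr_raw[209:212])
  if (!identical(substr(map_tag, 1, 3), "MAP"))
    stop("not a CCP4/MRC map (missing MAP tag): ", path)
  dims <- ri(1, 3)
  mode <- ri(4)
  if (mode != 2) stop("unsupported MRC mode ", mode, " (only mode 2, float32)")
  m_samp <- ri(8, 3)
  cell <- rf(11, 3)
  angles <- rf(14, 3)
  if (any(abs(angles - 90) > 1e-3))
    stop("unsupported non-orthogonal cell: angles ",
         paste(sprintf("%.2f", angles), collapse = ", "))
  axis_order <- ri(17, 3)
  if (!identical(axis_order, 1:3))
    stop("unsupported axis order (MAPC,MAPR,MAPS must be 1,2,3)")
  spacing <- cell / m_samp
  res_hint <- rf(38)
  origin <- rf(50, 3)
  if (all(origin == 0)) {
    nstart <- ri(5, 3)
    origin <- nstart * spacing
  }
  nsymbt <- ri(24)
  if (nsymbt > 0) readBin(con, "raw", nsymbt)
  nvox <- prod(dims)
  vals <- readBin(con, "numeric", nvox, size = 4, endian = "little")
  if (length(vals) < nvox) stop("map data truncated: ", path)
  grid <- density_grid(array(vals, dim = dims), origin = origin,
                       spacing = spacing,
                       resolution_hint = if (res_hint > 0) res_hint else NULL)
  if (normalize) grid <- normalize_grid(grid)
  grid
}

# ---- density lookup --------------------------------------------------------

#' Trilinear density interpolation
#'
#' Evaluates the map at arbitrary Angstrom positions by trilinear
#' interpolation of the eight surrounding voxel values; exact at voxel
#' centres.
#'
#' @param grid a \code{density_grid}.
#' @param xyz numeric length-3 vector or n x 3 matrix of query positions.
#' @param fill value returned for out-of-bounds queries; \code{NA} to
#'   raise an error instead.
#' @return Numeric vector of interpolated densities.
#' @export
interpolate_map <- function(grid, xyz, fill = 0) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  tq <- sweep(sweep(xyz, 2, grid$origin), 2, grid$spacing, "/")
  dims <- grid$dims
  oob <- tq[, 1] < 0 | tq[, 1] > dims[1] - 1 |
         tq[, 2] < 0 | tq[, 2] > dims[2] - 1 |
         tq[, 3] < 0 | tq[, 3] > dims[3] - 1
  if (any(oob) && is.na(fill))
    stop("interpolation query out of grid bounds")
  out <- rep(as.numeric(fill %||% 0), n)
  inb <- which(!oob)
  if (length(inb)) {
    tt <- tq[inb, , drop = FALSE]
    i0 <- pmin(floor(tt), matrix(rep(dims - 2, each = length(inb)),
                                 ncol = 3))
    i0 <- pmax(i0, 0)
    f <- tt - i0
    v <- grid$values
    g <- function(dx, dy, dz)
      v[cbind(i0[, 1] + dx + 1, i0[, 2] + dy + 1, i0[, 3] + dz + 1)]
    out[inb] <-
      g(0, 0, 0) * (1 - f[, 1]) * (1 - f[, 2]) * (1 - f[, 3]) +
      g(1, 0, 0) * f[, 1] * (1 - f[, 2]) * (1 - f[, 3]) +
      g(0, 1, 0) * (1 - f[, 1]) * f[, 2] * (1 - f[, 3]) +
      g(0, 0, 1) * (1 - f[, 1]) * (1 - f[, 2]) * f[, 3] +
      g(1, 1, 0) * f[, 1] * f[, 2] * (1 - f[, 3]) +
      g(1, 0, 1) * f[, 1] * (1 - f[, 2]) * f[, 3] +
      g(0, 1, 1) * (1 - f[, 1]) * f[, 2] * f[, 3] +
      g(1, 1, 1) * f[, 1] * f[, 2] * f[, 3]
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# World coordinates of every voxel centre, n_vox x 3 (column-major order,
# first axis fastest -- matches as.vector on the values array).
grid_coords <- function(grid) {
  d <- grid$dims
  idx <- cbind(rep(0:(d[1] - 1), times = d[2] * d[3]),
               rep(rep(0:(d[2] - 1), each = d[1]), times = d[3]),
               rep(0:(d[3] - 1), each = d[1] * d[2]))
  sweep(sweep(idx, 2, grid$spacing, "*"), 2, grid$origin, "+")
}

# Low-pass filter a grid by zeroing Fourier components with |s| > 1/resolution
# (s in reciprocal Angstrom). Used for map synthesis and multi-resolution runs.
lowpass_grid <- function(grid, resolution) {
  d <- grid$dims
  if (resolution < 2 * max(grid$spacing))
    stop("resolution ", resolution, " A below Nyquist limit for spacing ",
         max(grid$spacing), " A")
  fr <- function(n, dx) {
    k <- c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2):1))
    k / (n * dx)
  }
  sx <- fr(d[1], grid$spacing[1])
  sy <- fr(d[2], grid$spacing[2])
  sz <- fr(d[3], grid$spacing[3])
  s2 <- outer(outer(sx^2, sy^2, "+"), sz^2, "+")
  ft <- fft(grid$values)
  ft[s2 > 1 / resolution^2] <- 0
  grid$values <- Re(fft(ft, inverse = TRUE)) / prod(d)
  grid$resolution_hint <- max(resolution, grid$resolution_hint %||% 0)
  grid
}
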