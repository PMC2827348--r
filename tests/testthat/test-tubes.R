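test_that("ridgeline points trace a synthetic cylinder axis", {
  g <- cylinder_grid()
  pts <- find_ridgeline_points(g)
  expect_gt(nrow(pts), 5)
  off_axis <- sqrt(pts$y^2 + pts$z^2)
  expect_true(all(off_axis < 0.8))
  # thinning: emitted points at least 1.4 A apart
  d <- as.matrix(dist(pts[, c("x", "y", "z")]))
  diag(d) <- Inf
  expect_gte(min(d), 1.4)
})

test_that("a zero map yields no ridgeline points", {
  g <- density_grid(array(0, c(12, 12, 12)))
  expect_equal(nrow(find_ridgeline_points(g)), 0)
})

test_that("two parallel strands give two point clusters with an empty mid-plane", {
  fx <- fx_sheet2()
  pts <- find_ridgeline_points(fx$map)
  axA <- truth_axis(fx, "A", smooth = FALSE)
  axB <- truth_axis(fx, "B", smooth = FALSE)
  dA <- apply(pts[, 1:3], 1, function(p)
    sheetbuild:::polyline_min_dist(axA, matrix(p, 1, 3))$dist)
  dB <- apply(pts[, 1:3], 1, function(p)
    sheetbuild:::polyline_min_dist(axB, matrix(p, 1, 3))$dist)
  cl <- ifelse(dA < dB, "A", "B")
  expect_setequal(unique(cl), c("A", "B"))
  # strong points hug their strand; weaker ones sit on peripheral O/CB
  # features, never further than the sheet footprint
  strong <- pts$density >= 4
  expect_gt(mean(pmin(dA, dB)[strong] < 2.2), 0.8)
  expect_lt(max(pmin(dA, dB)), 4)
  # points appear between the strands only on genuinely high density
  # (hydrogen-bond bridges); none sit in low-density mid-plane regions
  mid_y <- mean(c(axA[1, 2], axB[1, 2]))
  in_mid <- abs(pts$y - mid_y) < 0.8 & abs(pts$z) < 2 &
    pts$x > min(axA[, 1]) & pts$x < max(axA[, 1])
  if (any(in_mid))
    expect_true(all(interpolate_map(fx$map,
                                    as.matrix(pts[in_mid, 1:3])) >= 1.0))
})

test_that("points_connected follows the min/mean density criteria", {
  g <- uniform_grid(1)
  p1 <- c(-5, 0, 0); p2 <- c(5, 0, 0)
  # constant density: connected for any cuts up to 1
  expect_true(points_connected(g, p1, p2, conn_params(1, 1)))
  expect_true(points_connected(g, p1, p1))  # coincident points
  # trough of 0.4 between unit endpoints fails criterion (i) at cut1 = 0.5
  n <- 41
  prof <- 1 - 0.6 * exp(-((seq(-5, 5, length.out = n))^2) / 2)
  vals <- array(rep(prof, times = 9 * 9), c(n, 9, 9))
  gt <- density_grid(vals, origin = c(-5, -4, -4),
                     spacing = c(10 / (n - 1), 1, 1))
  expect_false(points_connected(gt, c(-5, 0, 0), c(5, 0, 0)))
  # criterion (ii): shallow dip passes the min test but fails the mean test
  prof2 <- c(rep(1, 8), rep(0.7, 25), rep(1, 8))
  g2 <- density_grid(array(rep(prof2, times = 81), c(41, 9, 9)),
                     origin = c(-5, -4, -4), spacing = c(0.25, 1, 1))
  expect_true(points_connected(g2, c(-5, 0, 0), c(5, 0, 0),
                               conn_params(0.5, 0.6)))
  expect_false(points_connected(g2, c(-5, 0, 0), c(5, 0, 0),
                                conn_params(0.5, 0.9)))
})

test_that("points_connected is symmetric and monotone in the cuts", {
  fx <- fx_sheet4()
  g <- fx$map
  set.seed(11)
  lo <- g$origin + 1
  hi <- g$origin + (g$dims - 2) * g$spacing
  P1 <- cbind(runif(60, lo[1], hi[1]), runif(60, lo[2], hi[2]),
              runif(60, lo[3], hi[3]))
  P2 <- P1[sample(60), ] + matrix(runif(180, -3, 3), 60)
  P2 <- pmin(pmax(P2, rep(lo, each = 60)), rep(hi, each = 60))
  base <- conn_params(0.5, 0.75)
  strict1 <- conn_params(0.7, 0.75)
  strict2 <- conn_params(0.5, 0.9)
  for (i in seq_len(60)) {
    a <- points_connected(g, P1[i, ], P2[i, ], base)
    expect_identical(a, points_connected(g, P2[i, ], P1[i, ], base))
    if (points_connected(g, P1[i, ], P2[i, ], strict1)) expect_true(a)
    if (points_connected(g, P1[i, ], P2[i, ], strict2)) expect_true(a)
  }
})

test_that("collinear connected points merge into one tube", {
  g <- uniform_grid(1)
  pts <- data.frame(x = c(-2, 0, 2), y = 0, z = 0, density = 1)
  tubes <- build_tubes(pts, g)
  expect_length(tubes, 1)
  expect_equal(nrow(tubes[[1]]$axis), 3)
})

test_that("perpendicular crossing lines give two tubes, not one", {
  g <- uniform_grid(1)
  pts <- rbind(data.frame(x = c(-4, -2, 2, 4, 0), y = 0, z = 0, density = 1),
               data.frame(x = 0, y = c(-4, -2, 2, 4), z = 0, density = 1))
  tubes <- build_tubes(pts, g)
  expect_length(tubes, 2)
  dirs <- abs(vapply(tubes, function(t)
    sheetbuild:::unit(t$axis[nrow(t$axis), ] - t$axis[1, ]), numeric(3)))
  # one tube along x, one along y
  expect_equal(sort(round(dirs[1, ], 3)), c(0, 1))
})

test_that("fixture strand tubes track the true CA axes within 1 A RMS", {
  fx <- fx_sheet4()
  tubes <- build_tubes(find_ridgeline_points(fx$map), fx$map)
  lens <- vapply(tubes, sheetbuild:::tube_length, 0)
  main <- tubes[order(-lens)[1:4]]
  hits <- character(0)
  for (t in main) {
    ax <- sheetbuild:::smooth_axis(t$axis)
    rms <- sapply(unique(fx$truth$chain), function(ch) {
      tr <- truth_axis(fx, ch, smooth = FALSE)
      sqrt(mean(apply(ax, 1, function(p)
        sheetbuild:::polyline_min_dist(tr, matrix(p, 1, 3))$dist)^2))
    })
    expect_lt(min(rms), 1.0)
    hits <- c(hits, names(which.min(rms)))
  }
  expect_setequal(hits, c("A", "B", "C", "D"))  # one tube per strand
})

test_that("parallel pairing keeps 4.5 A pairs and rejects distant or bridged tubes", {
  fx <- fx_sheet2()
  g <- fx$map
  mk <- function(ax) sheetbuild:::new_tube(ax, interpolate_map(g, ax))
  tA <- mk(truth_axis(fx, "A"))
  tB <- mk(truth_axis(fx, "B"))
  pp <- find_parallel_pairs(list(tA, tB), g)
  expect_equal(nrow(pp$pairs), 1)
  expect_false(is.null(pp$tubes[[1]]$neighbour_dir))
  # neighbour direction points from A toward B, perpendicular to the axis
  nd <- pp$tubes[[1]]$neighbour_dir
  expect_gt(nd[2], 0.9)
  # 8 A apart: outside the 4.5 +/- 2 window
  tB8 <- mk(sweep(truth_axis(fx, "A"), 2, c(0, 8, 0), "+"))
  expect_equal(nrow(find_parallel_pairs(list(tA, tB8), g)$pairs), 0)
  # a continuous density bridge between the tubes vetoes the pair
  gu <- uniform_grid(5, n = 44)
  expect_equal(nrow(find_parallel_pairs(list(mk(truth_axis(fx, "A")),
                                             mk(truth_axis(fx, "B"))),
                                        gu)$pairs), 0)
})

test_that("extension grows a seed tube over the full strand and follows bends", {
  sh <- build_sheet(sheet_spec(2, 8))
  g <- density_from_model(sh, map_spec(2.5))
  caA <- sheetbuild:::atom_coords(
    chain_model(as.data.frame(sh[sh$chain == "A", ])), "CA")
  axA <- sheetbuild:::smooth_axis(caA)
  n <- nrow(axA)
  seed <- axA[floor(n / 3):ceiling(2 * n / 3), ]
  tube <- sheetbuild:::new_tube(seed, interpolate_map(g, seed))
  tube$neighbour_dir <- c(0, 1, 0)
  ext <- extend_tube(g, tube)
  span <- function(m) diff(range(m[, 1]))
  expect_gte(span(ext$axis), 0.9 * span(caA))
  # tube in empty surroundings stays unchanged
  g0 <- density_grid(array(0, c(20, 20, 20)), origin = c(-10, -10, -10))
  t0 <- sheetbuild:::new_tube(rbind(c(-2, 0, 0), c(0, 0, 0), c(2, 0, 0)),
                              c(0, 0, 0))
  t0$neighbour_dir <- c(0, 1, 0)
  expect_equal(nrow(extend_tube(g0, t0)$axis), 3)
  # curved strand: extension tracks the bent axis within 1 A RMS
  bentA <- bend_model(chain_model(as.data.frame(sh[sh$chain == "A", ])), 10)
  gb <- density_from_model(bentA, map_spec(2.5))
  caB <- sheetbuild:::atom_coords(bentA, "CA")
  axB <- sheetbuild:::smooth_axis(caB)
  nb <- nrow(axB)
  seedb <- axB[floor(nb / 3):ceiling(2 * nb / 3), ]
  tb <- sheetbuild:::new_tube(seedb, interpolate_map(gb, seedb))
  tb$neighbour_dir <- c(0, 1, 0)
  extb <- extend_tube(gb, tb)
  rms <- sqrt(mean(apply(extb$axis, 1, function(p)
    sheetbuild:::polyline_min_dist(caB, matrix(p, 1, 3))$dist)^2))
  expect_lt(rms, 1.0)
})

test_that("tube scoring matches the ideal template and the score algebra", {
  # density generated from the ideal tube template itself
  n <- c(41, 21, 21)
  sp <- 0.5
  org <- -(n - 1) / 2 * sp
  ax <- lapply(1:3, function(a) org[a] + (0:(n[a] - 1)) * sp)
  vals <- array(0, n)
  for (j in seq_len(n[2])) for (k in seq_len(n[3])) {
    r <- sqrt(ax[[2]][j]^2 + ax[[3]][k]^2)
    vals[, j, k] <- max(0, 1 - r / 1.5)
  }
  g <- density_grid(vals, origin = org, spacing = rep(sp, 3))
  axis <- cbind(seq(-8, 8, 1), 0, 0)
  tube <- sheetbuild:::new_tube(axis, interpolate_map(g, axis))
  scored <- score_tube(g, tube)
  expect_gte(scored$tube_cc, 0.99)
  expect_false(scored$rejected)
  # doubling the axis length at fixed mean density scales the score by sqrt(2)
  half <- sheetbuild:::new_tube(cbind(seq(-8, 0, 1), 0, 0), rep(1, 9))
  full <- sheetbuild:::new_tube(cbind(seq(-8, 8, 1), 0, 0), rep(1, 17))
  s1 <- score_tube(g, half)
  s2 <- score_tube(g, full)
  expect_equal(s2$score / s1$score, sqrt(2), tolerance = 1e-6)
  # degenerate zero-variance samples: cc defined as 0 and rejected
  g0 <- uniform_grid(1)
  t0 <- sheetbuild:::new_tube(cbind(seq(-4, 4, 1), 0, 0), rep(1, 9))
  s0 <- score_tube(g0, t0)
  expect_identical(s0$tube_cc, 0)
  expect_true(s0$rejected)
})

test_that("long tubes on a pure-noise map are rejected by the template filter", {
  set.seed(42)
  g <- normalize_grid(density_grid(array(rnorm(40^3), c(40, 40, 40)),
                                   spacing = c(0.7, 0.7, 0.7)))
  tubes <- build_tubes(find_ridgeline_points(g), g)
  long <- Filter(function(t) sheetbuild:::tube_length(t) >= 2 * 6.7, tubes)
  for (t in long) expect_true(score_tube(g, t)$rejected)
  # raising cc_strand_min never accepts more tubes (monotone filter)
  some <- Filter(function(t) sheetbuild:::tube_length(t) >= 4, tubes)
  acc <- function(thr) sum(vapply(some, function(t)
    !score_tube(g, t, pair_params(cc_strand_min = thr))$rejected, logical(1)))
  counts <- vapply(c(0.1, 0.3, 0.5, 0.7), acc, 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("noise-free pairing retains one accepted tube per sheet strand", {
  fx <- fx_sheet4()
  cands <- find_strand_candidates(fx$map, sheet_config(), resolution = 2.5)
  # candidates map one-to-one onto distinct true strands
  hit <- vapply(cands, function(f) {
    ca <- sheetbuild:::atom_coords(f$model, "CA")
    rms <- sapply(unique(fx$truth$chain), function(ch) {
      tr <- truth_axis(fx, ch, smooth = FALSE)
      mean(apply(ca, 1, function(p)
        sheetbuild:::polyline_min_dist(tr, matrix(p, 1, 3))$dist))
    })
    names(which.min(rms))
  }, "")
  expect_equal(length(hit), length(unique(hit)))
  expect_gte(length(hit), 3)
})
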