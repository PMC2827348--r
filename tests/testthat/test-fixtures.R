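test_that("ideal strand template has the beta-strand periodicity", {
  s <- build_ideal_strand(6)
  ca <- sheetbuild:::atom_coords(s, "CA")
  d2 <- sqrt(rowSums((ca[-(1:2), ] - ca[1:4, ])^2))
  expect_equal(mean(d2), 6.7, tolerance = 0.2 / 6.7)
  # exact two-residue translational repeat: per-repeat distances identical
  expect_lt(diff(range(d2)), 0.02)
})

test_that("a 2-residue strand has exactly 2 residues and 10 atoms", {
  s <- build_ideal_strand(2)
  expect_equal(length(unique(s$res_seq)), 2)
  expect_equal(nrow(s), 10)
  expect_setequal(unique(s$atom_name), c("N", "CA", "C", "O", "CB"))
})

test_that("C-beta axial phase trails the carbonyl phase by about P/3", {
  s <- build_ideal_strand(8)
  P <- attr(s, "period")
  anchor <- attr(s, "carbonyl_up_x")
  cb <- sheetbuild:::atom_coords(s, "CB")
  ph <- ((cb[, 1] - anchor) / P) %% 1
  # one C-beta of each repeat near +P/3, the other near +5P/6
  near <- function(x, t) pmin(abs(x - t), 1 - abs(x - t)) <= 1 / 12
  expect_true(all(near(ph, 1 / 3) | near(ph, 5 / 6)))
  expect_equal(sum(near(ph, 1 / 3)), 4)
})

test_that("strand chirality matches L-amino acids", {
  s <- build_ideal_strand(3)
  g <- function(at, r) as.numeric(s[s$res_seq == r & s$atom_name == at,
                                    c("x", "y", "z")])
  tp <- sum(sheetbuild:::cross3(g("N", 2) - g("CA", 2),
                                g("C", 2) - g("CA", 2)) *
              (g("CB", 2) - g("CA", 2)))
  expect_gt(tp, 0)
})

test_that("adjacent sheet strands sit at the requested separation", {
  sh <- build_sheet(sheet_spec(2, 6))
  # CA axes: the smoothed CA lines (the raw CA trace zigzags by the
  # backbone pleat, which does not change the strand separation)
  axA <- sheetbuild:::smooth_axis(sheetbuild:::atom_coords(
    chain_model(as.data.frame(sh[sh$chain == "A", ])), "CA"))
  axB <- sheetbuild:::smooth_axis(sheetbuild:::atom_coords(
    chain_model(as.data.frame(sh[sh$chain == "B", ])), "CA"))
  cl <- sheetbuild:::polyline_min_dist(axA, axB)
  expect_equal(cl$dist, 4.5, tolerance = 0.3 / 4.5)
})

test_that("a 1-strand sheet is the ideal strand itself", {
  sh <- build_sheet(sheet_spec(1, 6))
  s <- build_ideal_strand(6)
  expect_equal(as.matrix(sh[, c("x", "y", "z")]),
               as.matrix(s[, c("x", "y", "z")]), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("sheet twist keeps adjacent strand axes aligned above cos 0.5", {
  for (twist in c(2.5, 5)) {  # 15 and 30 degrees inclination for 6 residues
    sh <- build_sheet(sheet_spec(4, 6, twist_deg_per_residue = twist))
    dirs <- sapply(unique(sh$chain), function(ch) {
      ca <- sheetbuild:::atom_coords(
        chain_model(as.data.frame(sh[sh$chain == ch, ])), "CA")
      sheetbuild:::unit(ca[nrow(ca), ] - ca[1, ])
    })
    coss <- abs(colSums(dirs[, 1:3] * dirs[, 2:4]))
    expect_true(all(coss >= 0.5))
  }
})

test_that("model density peaks at an isolated atom and is deterministic", {
  m <- chain_model(data.frame(chain = "A", res_seq = 1L, res_name = "ALA",
                              atom_name = "CA", x = 0, y = 0, z = 0))
  g <- density_from_model(m, map_spec(2.5, pad = 5))
  idx <- arrayInd(which.max(g$values), g$dims)
  peak <- g$origin + (idx - 1) * g$spacing
  expect_lt(sqrt(sum(peak^2)), max(g$spacing) / 2 + 1e-9)
  # determinism without noise: seeds are irrelevant
  s6 <- build_ideal_strand(4)
  g1 <- density_from_model(s6, map_spec(2.5, noise_sigma = 0, rng_seed = 1))
  g2 <- density_from_model(s6, map_spec(2.5, noise_sigma = 0, rng_seed = 99))
  expect_identical(g1$values, g2$values)
})

test_that("noise is reproducible per seed and differs across seeds", {
  s <- build_ideal_strand(4)
  a1 <- density_from_model(s, map_spec(2.5, noise_sigma = 0.3, rng_seed = 5))
  a2 <- density_from_model(s, map_spec(2.5, noise_sigma = 0.3, rng_seed = 5))
  b <- density_from_model(s, map_spec(2.5, noise_sigma = 0.3, rng_seed = 6))
  expect_identical(a1$values, a2$values)
  expect_gt(max(abs(a1$values - b$values)), 0.1)
})

test_that("density synthesis is linear in the model before normalization", {
  sh <- build_sheet(sheet_spec(2, 4))
  A <- as.data.frame(sh[sh$chain == "A", ])
  B <- as.data.frame(sh[sh$chain == "B", ])
  grid <- density_from_model(sh, map_spec(2.5), normalize = FALSE)
  on_grid <- function(m)
    sheetbuild:::model_density_on_grid(as.matrix(m[, c("x", "y", "z")]),
                                       m$atom_name, grid, 2.5)
  vAB <- on_grid(as.data.frame(sh))
  expect_equal(vAB, on_grid(A) + on_grid(B), tolerance = 1e-9)
})

test_that("density along the CA lines dominates off-sheet positions", {
  fx <- fx_sheet4()
  ca <- as.matrix(fx$truth[, c("ca_x", "ca_y", "ca_z")])
  on_axis <- interpolate_map(fx$map, ca)
  off <- ca; off[, 3] <- off[, 3] + 3  # 3 A off perpendicular to the sheet
  off_axis <- interpolate_map(fx$map, off)
  expect_true(all(on_axis > off_axis))
})

test_that("the truth table exports one row per residue with unit directions", {
  fx <- fx_sheet4()
  expect_equal(nrow(fx$truth), 24)
  expect_equal(sort(unique(fx$truth$chain)), c("A", "B", "C", "D"))
  dn <- sqrt(fx$truth$dir_x^2 + fx$truth$dir_y^2 + fx$truth$dir_z^2)
  expect_equal(dn, rep(1, 24), tolerance = 1e-9)
  # antiparallel topology: adjacent strand directions oppose
  dA <- as.numeric(fx$truth[fx$truth$chain == "A", 6:8][1, ])
  dB <- as.numeric(fx$truth[fx$truth$chain == "B", 6:8][1, ])
  expect_lt(sum(dA * dB), -0.9)
})

test_that("bend_model curves the strand by the requested angle", {
  s <- build_ideal_strand(8)
  bent <- bend_model(s, 10)
  ca <- sheetbuild:::atom_coords(bent, "CA")
  v1 <- sheetbuild:::unit(ca[3, ] - ca[1, ])
  v2 <- sheetbuild:::unit(ca[8, ] - ca[6, ])
  ang <- acos(sum(v1 * v2)) * 180 / pi
  expect_equal(ang, 50, tolerance = 0.15)  # 5 inter-CA spans x 10 deg
  expect_equal(bend_model(s, 0), s)
})

test_that("map_spec enforces the Nyquist bound", {
  expect_error(map_spec(resolution = 2, grid_spacing = 1.5), "resolution")
  expect_error(density_from_model(build_ideal_strand(3),
                                  structure(list(resolution = 1,
                                                 grid_spacing = 1,
                                                 atom_b_factor = 15,
                                                 noise_sigma = 0,
                                                 rng_seed = 1, pad = 4),
                                            class = "map_spec")),
               "Nyquist")
})
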