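test_that("repeat averaging shows one carbonyl peak per period at half-period
           offset on the far side", {
  fx <- fx_sheet2()
  prof <- average_over_repeats(fx$map, truth_axis(fx, "A"), c(0, 1, 0))
  y <- sheetbuild:::smooth_circular(prof$dens_plus_n, 3)
  # exactly one dominant maximum per period
  above <- y > min(y) + 0.6 * (max(y) - min(y))
  runs <- rle(above)
  k <- sum(runs$values)
  if (above[1] && above[length(above)] && k > 1) k <- k - 1  # circular wrap
  expect_equal(k, 1)
  # far-side carbonyls offset by half the period
  p_up <- sheetbuild:::peak_phase(prof$dens_plus_n, 3)
  p_dn <- sheetbuild:::peak_phase(prof$dens_minus_n, 3)
  expect_lte(sheetbuild:::circ_dist(p_dn, p_up + 0.5), 1 / 12)
})

test_that("a constant map gives flat profiles that are not accepted", {
  g <- uniform_grid(2, n = 40)
  axis <- cbind(seq(-10, 10, 0.5), 0, 0)
  prof <- average_over_repeats(g, axis, c(0, 1, 0))
  for (f in c("dens_plus_n", "dens_minus_n", "dens_plus_b", "dens_minus_b"))
    expect_lt(diff(range(prof[[f]])), 1e-9)
  expect_false(find_carbonyl_phase(prof)$accepted)
})

test_that("averaging requires at least one period of axis", {
  g <- uniform_grid(1)
  expect_error(average_over_repeats(g, cbind(c(0, 3), 0, 0), c(0, 1, 0)),
               "period")
})

test_that("carbonyl phase is recovered on the noise-free fixture", {
  fx <- fx_sheet2()
  cal <- register_calibration(2.5)
  ax <- truth_axis(fx, "A")
  prof <- average_over_repeats(fx$map, ax, c(0, 1, 0))
  cp <- find_carbonyl_phase(prof, calibration = cal)
  expect_true(cp$accepted)
  # true carbonyl phase: O atoms pointing +y projected onto the axis
  A <- fx$model[fx$model$chain == "A", ]
  o <- as.matrix(A[A$atom_name == "O", c("x", "y", "z")])
  cc <- as.matrix(A[A$atom_name == "C", c("x", "y", "z")])
  up <- o[, 2] - cc[, 2] > 0
  true_phase <- mean(((o[up, 1] - ax[1, 1]) / 6.7) %% 1)
  got <- (cp$phase - cal["pn"]) %% 1
  expect_lte(sheetbuild:::circ_dist(got, true_phase), 1 / 12)
})

test_that("half-period disagreement rejects the phase", {
  # far-side peak displaced to phase + 0.25: criterion must fail
  prof <- synthetic_profile(pn = 0.2, mn = 0.45, pb = 0.5, mb = 0.9)
  cp <- find_carbonyl_phase(prof)
  expect_false(cp$accepted)
  prof_ok <- synthetic_profile(pn = 0.2, mn = 0.7, pb = 0.5, mb = 0.9)
  expect_true(find_carbonyl_phase(prof_ok)$accepted)
})

test_that("peak finding is equivariant under circular shifts", {
  prof <- synthetic_profile(pn = 0.30, mn = 0.80, pb = 0.55, mb = 0.05)
  base <- find_carbonyl_phase(prof)$phase
  for (shift_bins in c(3, 10, 17)) {
    shifted <- prof
    for (f in c("dens_plus_n", "dens_minus_n", "dens_plus_b", "dens_minus_b"))
      shifted[[f]] <- prof[[f]][((seq_len(36) - 1 - shift_bins) %% 36) + 1]
    got <- find_carbonyl_phase(shifted)$phase
    expect_lt(sheetbuild:::circ_dist(got, base + shift_bins / 36), 1e-6)
  }
})

test_that("phase arithmetic is circular", {
  prof <- synthetic_profile(pn = 0.1, mn = 0.6, pb = 0.1 + 1 / 3,
                            mb = 0.1 + 5 / 6)
  d1 <- determine_direction(prof, 0.1)
  d2 <- determine_direction(prof, 1.1)
  d3 <- determine_direction(prof, -0.9)
  expect_identical(d1, d2)
  expect_identical(d1, d3)
})

test_that("clean sixths patterns give forward; mirrored profiles reverse", {
  ph <- 0.22
  prof <- synthetic_profile(pn = ph, mn = ph + 0.5,
                            pb = (ph + 1 / 3) %% 1, mb = (ph + 5 / 6) %% 1)
  expect_identical(determine_direction(prof, ph), "forward")
  mp <- mirror_profile(prof)
  mph <- find_carbonyl_phase(mp)$phase
  expect_identical(determine_direction(mp, mph), "reverse")
})

test_that("direction and its mirror are always opposite or both ambiguous", {
  set.seed(9)
  swap <- c(forward = "reverse", reverse = "forward",
            ambiguous = "ambiguous")
  for (i in 1:50) {
    ph <- runif(1)
    prof <- synthetic_profile(pn = ph, mn = runif(1), pb = runif(1),
                              mb = runif(1))
    d <- determine_direction(prof, ph)
    md <- determine_direction(mirror_profile(prof),
                              find_carbonyl_phase(mirror_profile(prof))$phase)
    expect_identical(md, unname(swap[d]))
  }
})

test_that("no returned direction is wrong on noise-free fixtures", {
  # both 2.5 and 4 A analyses of the standard sheet; truth axes run N->C,
  # so any non-ambiguous call must be forward
  for (res in c(2.5, 4)) {
    fx <- fx_sheet4()
    g <- if (res > 2.5) normalize_grid(sheetbuild:::lowpass_grid(fx$map, res))
         else fx$map
    cal <- register_calibration(res)
    for (ch in unique(fx$truth$chain)) for (side in c(1, -1)) {
      prof <- average_over_repeats(g, truth_axis(fx, ch), c(0, side, 0))
      cp <- find_carbonyl_phase(prof, calibration = cal)
      if (!cp$accepted) next
      d <- determine_direction(prof, cp$phase, calibration = cal)
      expect_true(d %in% c("forward", "ambiguous"),
                  label = sprintf("direction at %.1f A, strand %s", res, ch))
    }
  }
})

test_that("the chance acceptance rate of the direction test is about 1%", {
  cr <- direction_chance_rate(20000, seed = 3)
  expect_equal(cr$analytic, 2 * (1 / 6)^3, tolerance = 1e-12)
  # binomial 99.9% envelope around the analytic 0.926%
  se <- sqrt(cr$analytic * (1 - cr$analytic) / cr$n)
  expect_lt(abs(cr$rate - cr$analytic), 4 * se)
})

test_that("placement recovers the fixture strand and handles ambiguity", {
  fx <- fx_sheet2()
  cal <- register_calibration(2.5)
  ax <- truth_axis(fx, "A")
  prof <- average_over_repeats(fx$map, ax, c(0, 1, 0))
  cp <- find_carbonyl_phase(prof, calibration = cal)
  cands <- place_strand(ax, c(0, 1, 0), cp$phase, "forward",
                        score = 1, calibration = cal)
  expect_length(cands, 1)
  caP <- sheetbuild:::atom_coords(cands[[1]]$model, "CA")
  caT <- truth_axis(fx, "A", smooth = FALSE)
  d <- sqrt(outer(rowSums(caP^2), rowSums(caT^2), "+") - 2 * caP %*% t(caT))
  matched <- apply(d, 1, min)
  expect_lt(sqrt(mean(matched^2)), 1.0)
  # ambiguous direction: exactly two candidates with reversed residue order
  both <- place_strand(ax, c(0, 1, 0), cp$phase, "ambiguous",
                       score = 1, calibration = cal)
  expect_length(both, 2)
  ca1 <- sheetbuild:::atom_coords(both[[1]]$model, "CA")
  ca2 <- sheetbuild:::atom_coords(both[[2]]$model, "CA")
  expect_equal(dim(ca1), dim(ca2))
  expect_lt(max(abs(ca1 - ca2[nrow(ca2):1, ])), 1.5)
  expect_lt(sum(sheetbuild:::unit(ca1[nrow(ca1), ] - ca1[1, ]) *
                  sheetbuild:::unit(ca2[nrow(ca2), ] - ca2[1, ])), -0.95)
})

test_that("placement on a curved axis keeps the backbone intact", {
  s8 <- build_ideal_strand(8)
  bent <- bend_model(s8, 10)
  gb <- density_from_model(bent, map_spec(2.5))
  cal <- register_calibration(2.5)
  ax <- sheetbuild:::smooth_axis(sheetbuild:::atom_coords(bent, "CA"))
  prof <- average_over_repeats(gb, ax, c(0, 1, 0))
  cp <- find_carbonyl_phase(prof, calibration = cal)
  cands <- place_strand(ax, c(0, 1, 0), cp$phase, "forward", 1,
                        calibration = cal)
  ca <- sheetbuild:::atom_coords(cands[[1]]$model, "CA")
  dd <- sqrt(rowSums((ca[-1, , drop = FALSE] -
                      ca[-nrow(ca), , drop = FALSE])^2))
  expect_true(all(dd >= 3.6 & dd <= 4.0))
})

test_that("short axes yield no placement", {
  expect_length(place_strand(cbind(c(0, 5), 0, 0), c(0, 1, 0), 0.3,
                             "forward"), 0)
})
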