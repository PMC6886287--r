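test_that("DVH is exact on voxels with the closed >= convention", {
  mask <- rep(TRUE, 4)
  expect_equal(volume_at_dose(c(40, 55, 60, 70), mask, 50), 75)
  u <- rep(78, 10)
  expect_equal(volume_at_dose(u, rep(TRUE, 10), 78), 100)
  expect_equal(volume_at_dose(u, rep(TRUE, 10), 78.1), 0)
  expect_equal(volume_at_dose(c(40, 55, 60, 70), mask, 0), 100)
  curve <- dvh(c(40, 55, 60, 70), mask)
  expect_s3_class(curve, "dvh_curve")
  expect_true(all(diff(curve$volume_pct) <= 0))   # monotone non-increasing
  expect_equal(curve$volume_pct[curve$dose_Gy == 0], 100)
  expect_error(dvh(c(1, 2), c(FALSE, FALSE)), "empty")
})

test_that("dose_at_volume uses the descending-rank convention", {
  d <- c(70, 74, 78, 82)
  mask <- rep(TRUE, 4)
  expect_equal(dose_at_volume(d, mask, 50), 78)    # rank 2 of 4
  expect_equal(dose_at_volume(d, mask, 100), 70)   # min dose
  expect_equal(dose_at_volume(rep(66, 9), rep(TRUE, 9), 37), 66)
  expect_error(dose_at_volume(d, mask, 0), "x_pct")
  # consistency: D at x% is the largest level with V(d) >= x
  set.seed(3)
  dd <- runif(57, 0, 80)
  m <- rep(TRUE, 57)
  for (x in c(5, 37, 62, 95)) {
    dx <- dose_at_volume(dd, m, x)
    expect_gte(volume_at_dose(dd, m, dx), x)
  }
})

test_that("conformity index follows the two-ratio definition", {
  # worked example: Vt = 100, Vt_ref = 80, Vref = 160
  dose <- c(rep(80, 80), rep(10, 20),      # PTV: 80 hot, 20 cold
            rep(80, 80), rep(10, 120))     # rest of body: 80 hot
  ptv <- c(rep(TRUE, 100), rep(FALSE, 200))
  body <- rep(TRUE, 300)
  expect_equal(conformity_index(dose, ptv, body, 74), 0.4)
  # reference isodose exactly the PTV -> CI = 1
  dose2 <- c(rep(78, 100), rep(10, 200))
  expect_equal(conformity_index(dose2, ptv, body, 74), 1)
  # nothing reaches the reference dose -> 0 with warning
  expect_warning(ci0 <- conformity_index(rep(1, 300), ptv, body, 74), "CI set to 0")
  expect_equal(ci0, 0)
})

test_that("homogeneity index is D5 over D95 and at least 1", {
  expect_equal(homogeneity_index(rep(78, 40), rep(TRUE, 40)), 1)
  d <- c(rep(82, 2), rep(80, 35), rep(78, 3))   # D5 = rank 2 = 82, D95 = rank 38 = 78
  expect_equal(homogeneity_index(d, rep(TRUE, 40)), 1.05128205128205,
               tolerance = 1e-12)
  set.seed(5)
  for (i in 1:10) {
    dd <- runif(50, 40, 90)
    expect_gte(homogeneity_index(dd, rep(TRUE, 50)), 1)
  }
  expect_error(homogeneity_index(rep(70, 10), rep(TRUE, 10)), "20 voxels")
  expect_error(homogeneity_index(rep(0, 30), rep(TRUE, 30)), "unirradiated")
})

test_that("gEUD is the Niemierko power mean", {
  m2 <- rep(TRUE, 2)
  expect_equal(geud(c(60, 60), m2, a = 7.3), 60)
  expect_equal(geud(c(40, 80), m2, a = 1), 60)
  expect_equal(geud(c(40, 80), m2, a = 2), 63.2455532033676, tolerance = 1e-12)
  expect_error(geud(c(40, 80), m2, a = 0), "nonzero")
  expect_error(geud(c(0, 80), m2, a = -2), "undefined")
  # monotone in a; bounded by min and max; large a approaches the max
  set.seed(9)
  for (i in 1:10) {
    d <- runif(30, 10, 80)
    m <- rep(TRUE, 30)
    g <- vapply(c(1, 2, 4, 8, 16), function(a) geud(d, m, a), numeric(1))
    expect_true(all(diff(g) >= -1e-9))
    expect_gte(min(g), min(d))
    expect_lte(max(g), max(d))
    expect_lt(abs(geud(d, m, 512) - max(d)) / max(d), 0.01)
  }
})

test_that("LKB NTCP is the normal CDF of the gEUD excess over TD50", {
  m <- rep(TRUE, 5)
  expect_equal(ntcp_lkb(rep(76.9, 5), m, 76.9, 0.13, 0.09), 0.5, tolerance = 1e-12)
  expect_equal(ntcp_lkb(rep(66.9, 5), m, 76.9, 0.13, 1), 0.158582651824907,
               tolerance = 1e-9)
  # strictly increasing in uniform dose
  p <- vapply(seq(60, 90, by = 5), function(u) ntcp_lkb(rep(u, 5), m, 76.9, 0.13, 0.09),
              numeric(1))
  expect_true(all(diff(p) > 0))
  expect_error(ntcp_lkb(rep(70, 5), m, -1, 0.13, 0.09), "positive")
})

test_that("metrics agree with brute-force recomputation from the raw dose vector", {
  ph <- generate_phantom(tiny_spec())
  im <- compute_influence_matrix(ph, beam_spec())
  set.seed(21)
  dose <- compute_dose(im, runif(ncol(im$A), 0, 4))
  for (nm in c("ptv", "rectum", "bladder")) {
    d <- dose[ph$masks[[nm]]]
    n <- length(d)
    for (t in c(20, 45, 60)) {
      expect_identical(volume_at_dose(dose, ph$masks[[nm]], t),
                       100 * sum(d >= t) / n)
    }
    for (x in c(5, 50, 95)) {
      expect_identical(dose_at_volume(dose, ph$masks[[nm]], x),
                       sort(d, decreasing = TRUE)[ceiling(n * x / 100)])
    }
    expect_equal(geud(dose, ph$masks[[nm]], 4), (mean(d^4))^(1 / 4),
                 tolerance = 1e-12)
  }
  tbl <- suppressWarnings(plan_metrics(dose, ph, ref_dose = 40))  # random fluence may miss the 40 Gy isodose
  prow <- tbl[tbl$structure == "ptv", ]
  expect_true(all(tbl$D_min <= tbl$D_mean & tbl$D_mean <= tbl$D_max))
  expect_equal(prow$D_mean, mean(dose[ph$masks$ptv]))
})
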