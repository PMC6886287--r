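test_that("subscores reproduce their hand-computed values and boundary conventions", {
  # mean squared underdose
  expect_equal(f_min(c(70, 80), 74), 8)
  expect_equal(f_min(c(74, 80), 74), 0)          # equality is penalty-free (strict H)
  expect_equal(f_min(c(75, 80), 74), 0)
  # mean squared deviation from the mean-dose prescription
  expect_equal(f_mean(c(76, 80), 78), 4)
  expect_equal(f_mean(rep(78, 7), 78), 0)
  d <- runif(20, 60, 80)
  expect_equal(f_mean(d + 3, 70 + 3), f_mean(d, 70))   # shift invariance
  # D2: current dose level at the prescribed hot volume
  expect_equal(compute_d2(c(40, 55, 60, 70), 25), 70)
  expect_equal(compute_d2(c(40, 55, 60, 70), 100), 40)
  expect_equal(compute_d2(rep(66, 13), 40), 66)
  # dv surrogate window (strict at both edges)
  expect_equal(f_dvmax(c(40, 55, 60, 70), 50, 70), 31.25)
  expect_equal(f_dvmax(c(30, 40, 45), 50, 70), 0)
  # constraint already satisfied: window collapses
  d_ok <- c(40, 42, 44, 72)
  expect_lte(compute_d2(d_ok, 25) , 50 + 22)  # D2 is the single hot voxel
  expect_equal(f_dvmax(d_ok, 50, compute_d2(d_ok, 25)), 0)
  # gEUD overshoot is linear
  expect_equal(f_geud(rep(65, 4), 60, a = 1), 5)
  expect_equal(f_geud(rep(58, 4), 60, a = 1), 0)
  expect_equal(f_geud(rep(70, 4), 60, a = 1), 2 * f_geud(rep(65, 4), 60, a = 1))
  # logarithmic NTCP penalty
  expect_equal(f_ntcp(rep(76.9, 5), 0.5, 76.9, 0.13, 0.09), 0)  # at prescription
  d05 <- 76.9 * (1 + 0.13 * qnorm(0.10))   # uniform dose giving NTCP = 0.10
  expect_equal(f_ntcp(rep(d05, 5), 0.05, 76.9, 0.13, 1),
               0.0540672212702622, tolerance = 1e-9)
})

test_that("NTCP penalty increases with complication probability above prescription", {
  lev <- seq(0.06, 0.5, by = 0.05)
  pen <- vapply(lev, function(p) {
    u <- 76.9 * (1 + 0.13 * qnorm(p))
    f_ntcp(rep(u, 3), 0.05, 76.9, 0.13, 1)
  }, numeric(1))
  expect_true(all(diff(pen) > 0))
  expect_warning(f_ntcp(rep(1e4, 3), 0.05, 76.9, 0.13, 1), "capped")
})

test_that("the weighted total objective is the importance-weighted sum", {
  expect_equal(total_objective(c(8, 4), c(0.5, 0.5)), 6)
  expect_equal(total_objective(rep(0, 5), runif(5)), 0)
  expect_error(total_objective(1:3, 1:2), "lengths differ")
})

test_that("weight rescaling plus renormalization leaves the optimum unchanged", {
  prob <- tiny_problem()
  presc <- default_prostate_prescription()
  spec <- objective_spec(presc, prob$phantom, "dv")
  x0 <- initial_fluence(prob$im, prob$phantom$masks$ptv, 78)
  w <- runif(spec$n_subscores, 0.1, 1)
  w1 <- w / sum(w)
  p1 <- solve_fmo(prob$im, spec, w1, x0)
  p2 <- solve_fmo(prob$im, spec, (7 * w) / sum(7 * w), x0)
  expect_equal(p1$x, p2$x, tolerance = 1e-6)
})

test_that("every subscore is nonnegative and zero exactly when its condition is met", {
  set.seed(17)
  for (i in 1:20) {
    d <- runif(40, 30, 90)
    expect_gte(f_min(d, 60), 0)
    expect_identical(f_min(d, 60) == 0, all(d >= 60))
    expect_gte(f_dvmax(d, 55, compute_d2(d, 30)), 0)
    v_at_55 <- 100 * mean(d >= 55)
    expect_identical(f_dvmax(d, 55, compute_d2(d, 30)) == 0, v_at_55 <= 30)
    g <- geud(d, rep(TRUE, 40), 4)
    expect_identical(f_geud(d, 60, 4) == 0, g <= 60)
  }
})

test_that("analytic gradients match central finite differences on random instances", {
  audit <- fd_gradient_suite(n_per_type = 20)
  expect_lt(audit$max_rel_err, 1e-5)
  expect_true(all(audit$n_checked >= 20L))
})

test_that("gradient vanishes at zero fluence (square-root parameterization)", {
  prob <- tiny_problem()
  spec <- objective_spec(default_prostate_prescription(), prob$phantom, "dv")
  u0 <- rep(0, ncol(prob$im$A))
  g <- objective_gradient(spec, rep(1 / spec$n_subscores, spec$n_subscores),
                          prob$im, u0)
  expect_identical(g, rep(0, length(u0)))
})

test_that("objective specs assemble the right subscores per model", {
  prob <- tiny_problem()
  presc <- default_prostate_prescription()
  sdv <- objective_spec(presc, prob$phantom, "dv")
  expect_equal(sdv$n_subscores, 8)
  types <- vapply(sdv$subscores, function(s) s$constraint$type, character(1))
  expect_equal(types[1:2], c("min_dose", "mean_dose"))
  expect_equal(sum(types == "dv_max"), 6)
  sg <- objective_spec(presc, prob$phantom, "geud")
  expect_equal(sg$n_subscores, 4)
  sn <- objective_spec(presc, prob$phantom, "ntcp")
  expect_equal(sn$n_subscores, 4)
  expect_equal(vapply(sn$subscores, function(s) s$constraint$type, character(1))[3:4],
               c("ntcp", "ntcp"))
  # a prescription without a PTV minimum-dose constraint is unusable
  expect_error(
    prescription(list(constraint_mean_dose("ptv", 78))),
    "minimum-dose"
  )
})
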