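test_that("correction factors follow the prescription-value ratios", {
  # minimum dose: pre/cur
  expect_equal(correction_factor(constraint_min_dose("ptv", 74), c(70, 80)),
               74 / 70)
  # maximum dose: cur/pre
  expect_equal(correction_factor(constraint_max_dose("oar", 60), c(40, 66)),
               66 / 60)
  # mean dose, PTV: max/min ratio; OAR: cur/pre (can drop below 1)
  expect_equal(correction_factor(constraint_mean_dose("ptv", 78, role = "ptv"),
                                 rep(76, 4)), 78 / 76)
  expect_equal(correction_factor(constraint_mean_dose("ptv", 78, role = "ptv"),
                                 rep(80, 4)), 80 / 78)
  expect_equal(correction_factor(constraint_mean_dose("oar", 40, role = "oar"),
                                 rep(30, 4)), 0.75)
  # dose-volume: current over prescribed volume at D1
  d <- c(rep(60, 5), rep(30, 5))            # V(50) = 50%
  expect_equal(correction_factor(constraint_dv_max("oar", 50, 40), d), 1.25)
  d2 <- c(rep(60, 3), rep(30, 7))           # V(50) = 30%
  expect_equal(correction_factor(constraint_dv_max("oar", 50, 40), d2), 0.75)
  # NTCP at prescription: no pressure change
  u05 <- 76.9 * (1 + 0.13 * qnorm(0.05))
  expect_equal(correction_factor(constraint_ntcp("oar", 0.05, 76.9, 0.13, 1),
                                 rep(u05, 4)), 1, tolerance = 1e-9)
  # zero denominator never crashes: clamped with a warning or floor/ceiling
  expect_warning(
    fac0 <- correction_factor(constraint_min_dose("ptv", 74), rep(0, 3)),
    "clamped"
  )
  expect_equal(fac0, 100)
  expect_equal(correction_factor(constraint_geud("oar", 60, 2), rep(1e-9, 3)), 0.01)
})

test_that("factor monotonicity: larger violation never lowers the factor", {
  con <- constraint_dv_max("oar", 50, 40)
  vols <- seq(0, 100, by = 10)
  f <- vapply(vols, function(v) {
    nhot <- round(v / 10)
    correction_factor(con, c(rep(60, nhot), rep(30, 10 - nhot)))
  }, numeric(1))
  expect_true(all(diff(f) >= 0))
  con2 <- constraint_min_dose("ptv", 74)
  f2 <- vapply(seq(40, 74, by = 2), function(dmin)
    correction_factor(con2, c(dmin, 80)), numeric(1))
  expect_true(all(diff(f2) <= 0))
})

test_that("weight updates add k times the factor then renormalize", {
  expect_equal(update_weights(c(0.5, 0.5), c(1.2, 0.8), k = 1),
               c(1.7, 1.3) / 3, tolerance = 1e-12)
  expect_equal(update_weights(c(0.5, 0.5), c(1.2, 0.8), k = c(2, 1)),
               c(2.9, 1.3) / 4.2, tolerance = 1e-12)
  # symmetric factors leave equal weights unchanged
  expect_equal(update_weights(c(0.25, 0.25, 0.25, 0.25), rep(1.3, 4)),
               rep(0.25, 4))
  expect_error(update_weights(c(0.5, 0.5), 1), "lengths differ")
  # normalization property over random updates
  set.seed(31)
  w <- rep(1 / 6, 6)
  for (i in 1:50) {
    w <- update_weights(w, runif(6, 0.01, 3), k = sample(1:5, 1))
    expect_lt(abs(sum(w) - 1), 1e-12)
    expect_true(all(w > 0 & w < 1))
  }
})

test_that("plan evaluation checks coverage and DV rules and picks targets high-dose first", {
  prob <- tiny_problem()
  ph <- prob$phantom
  presc <- default_prostate_prescription()
  spec <- objective_spec(presc, ph, "dv")
  n <- prod(ph$grid_shape)

  # synthetic dose: full coverage, cold OARs -> acceptable, no targets
  dose <- rep(0, n)
  dose[ph$masks$ptv] <- 78
  ev <- evaluate_plan(dose, ph, presc, spec)
  expect_true(ev$ptv_satisfied)
  expect_true(ev$all_satisfied)
  expect_length(ev$compensation_targets, 0)

  # degraded coverage below 95% -> PTV subscores are the targets
  dose2 <- dose
  ptv_idx <- which(ph$masks$ptv)
  dose2[ptv_idx[seq_len(ceiling(0.07 * length(ptv_idx)))]] <- 70
  ev2 <- evaluate_plan(dose2, ph, presc, spec)
  expect_false(ev2$ptv_satisfied)
  expect_equal(ev2$compensation_targets, c(1L, 2L))

  # coverage fine but rectum hot at both 65 and 75 Gy -> the 75 Gy subscore
  # (high-dose region first)
  dose3 <- dose
  dose3[ph$masks$rectum] <- 76
  ev3 <- evaluate_plan(dose3, ph, presc, spec)
  expect_true(ev3$ptv_satisfied)
  expect_false(ev3$all_satisfied)
  viol <- ev3$criteria[!ev3$criteria$satisfied, ]
  expect_true(all(c(65, 75) %in% viol$dose_Gy[viol$structure == "rectum"]))
  d1_target <- spec$subscores[[ev3$compensation_targets]]$constraint$d1
  expect_equal(d1_target, 75)
  expect_equal(spec$subscores[[ev3$compensation_targets]]$structure, "rectum")
})

test_that("a trivially satisfiable prescription exits after the adjustment stage", {
  prob <- tiny_problem()
  easy <- prescription(
    list(constraint_min_dose("ptv", 40),
         constraint_mean_dose("ptv", 60),
         constraint_dv_max("rectum", 70, 95),
         constraint_dv_max("bladder", 70, 95))
  )
  run <- run_automatic(prob$phantom, prob$im, easy, model = "dv")
  expect_true(run$accepted)
  expect_equal(run$n_solves, 5)
  expect_true(all(run$history$stage == "adjust"))
  expect_true(is.na(run$k_final))    # compensation never applied
})

test_that("an impossible prescription exhausts the budget with the full k schedule", {
  prob <- tiny_problem()
  # PTV minimum dose far above anything achievable alongside a near-zero OAR cap
  impossible <- prescription(
    list(constraint_min_dose("ptv", 74),
         constraint_mean_dose("ptv", 78),
         constraint_dv_max("rectum", 5, 1),
         constraint_dv_max("bladder", 70, 90))
  )
  loop <- loop_config(inner_adjust_iters = 2, max_compensation_iters = 4)
  run <- run_automatic(prob$phantom, prob$im, impossible, model = "dv",
                       loop = loop, solver = solver_config(max_iters = 15))
  expect_false(run$accepted)
  expect_equal(run$n_solves, 2 * (1 + 4))
  ks <- unique(run$history$k[run$history$stage == "compensation"])
  expect_equal(ks, 1 + (seq_len(4) - 1) * 1)   # arithmetic schedule k0=1, step=1
  expect_false(run$evaluation$all_satisfied)
})

test_that("compensation k schedules take their model-specific defaults", {
  expect_equal(autofmo:::model_compensation_defaults("dv"),
               list(k0 = 1, steplength = 1))
  expect_equal(autofmo:::model_compensation_defaults("geud"),
               list(k0 = 10, steplength = 5))
  expect_equal(autofmo:::model_compensation_defaults("ntcp"),
               list(k0 = 1, steplength = 1))
  prob <- tiny_problem()
  impossible <- prescription(
    list(constraint_min_dose("ptv", 74),
         constraint_mean_dose("ptv", 78),
         constraint_geud("rectum", 5, a = 4),
         constraint_geud("bladder", 40, a = 2)),
    evaluation = tibble::tibble(structure = "rectum", dose_Gy = 5, volume_pct = 1)
  )
  loop <- loop_config(inner_adjust_iters = 2, max_compensation_iters = 3)
  run <- run_automatic(prob$phantom, prob$im, impossible, model = "geud",
                       loop = loop, solver = solver_config(max_iters = 15))
  ks <- unique(run$history$k[run$history$stage == "compensation"])
  expect_equal(ks, 10 + (seq_len(3) - 1) * 5)
})

test_that("full runs are reproducible and bounded by the iteration budget", {
  prob <- tiny_problem()
  presc <- default_prostate_prescription()
  r1 <- run_automatic(prob$phantom, prob$im, presc, model = "dv")
  r2 <- run_automatic(prob$phantom, prob$im, presc, model = "dv")
  expect_identical(r1$plan$x, r2$plan$x)
  expect_identical(r1$history$objective, r2$history$objective)
  loop <- r1$loop
  expect_lte(r1$n_solves,
             loop$inner_adjust_iters * (1 + loop$max_compensation_iters))
  # weights stay normalized in every recorded iteration
  for (w in r1$history$weights) {
    expect_lt(abs(sum(w) - 1), 1e-12)
    expect_true(all(w > 0 & w < 1))
  }
})
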