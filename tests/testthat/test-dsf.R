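test_that("melt curves validate their grid", {
  expect_error(melt_curve(1:5, 1:5), "at least 10")
  expect_error(melt_curve(c(1:9, 9), 1:10), "strictly increasing")
  expect_error(melt_curve(c(1:9, 11), 1:10), "constant step")
  expect_error(melt_curve(1:10, 1:9), "lengths differ")
  cv <- melt_curve(25:40, rnorm(16))
  expect_s3_class(cv, "melt_curve")
})

test_that("control subtraction is pointwise and grid-checked", {
  cv <- simulate_melt_curve(noise_sd = 0)
  zero <- melt_curve(cv$temperature, rep(0, length(cv$temperature)),
                     condition = "dye-only")
  expect_equal(subtract_control(cv, zero)$intensity, cv$intensity)
  expect_equal(subtract_control(cv, cv)$intensity,
               rep(0, length(cv$intensity)))
  other <- melt_curve(seq(30, 79, 1), cv$intensity, condition = "dye-only")
  expect_error(subtract_control(cv, other), "grids differ")
})

test_that("replicate averaging is the pointwise mean", {
  cv <- simulate_melt_curve(noise_sd = 0)
  avg <- average_replicates(list(cv, cv))
  expect_equal(avg$intensity, cv$intensity)
  neg <- cv
  neg$intensity <- -cv$intensity
  expect_equal(average_replicates(list(cv, neg))$intensity,
               rep(0, length(cv$intensity)))
  expect_warning(single <- average_replicates(list(cv)), "single replicate")
  expect_equal(attr(single, "n_replicates"), 1L)
})

test_that("the Boltzmann model halves its amplitude exactly at the midpoint", {
  expect_equal(boltzmann(55, 100, 1000, 55, 1.5), 550)
  expect_equal(boltzmann(40, 200, 800, 40, 3), 500)
})

test_that("noiseless Boltzmann curves are recovered to high precision", {
  cv <- simulate_melt_curve(t_m = 55, a = 1.5, i_min = 100, i_max = 1000)
  fit <- fit_boltzmann(cv)
  expect_true(fit$converged)
  expect_equal(fit$t_m, 55, tolerance = 1e-4)
  expect_equal(fit$a, 1.5, tolerance = 1e-4)
  expect_equal(fit$i_min, 100, tolerance = 1e-4)
  expect_equal(fit$i_max, 1000, tolerance = 1e-4)
})

test_that("Tm recovery under 2% noise stays within 0.2 degrees (median)", {
  errs <- vapply(1:100, function(s) {
    cv <- simulate_melt_curve(noise_sd = 18, seed = s)
    fit <- fit_boltzmann(cv)
    if (!fit$converged) return(NA_real_)
    abs(fit$t_m - 55)
  }, numeric(1))
  expect_true(all(!is.na(errs)))
  expect_lt(median(errs), 0.2)
})

test_that("flat and too-short traces fail gracefully", {
  flat <- simulate_melt_curve(n_transitions = 0, noise_sd = 2, seed = 8)
  fit <- fit_boltzmann(flat)
  expect_false(fit$converged)
  short <- melt_curve(1:10, c(1:9, 5))
  expect_error(fit_boltzmann(short, min_points = 11), "usable points")
})

test_that("Q is fitted amplitude over observed range, clamped", {
  cv <- simulate_melt_curve()
  fit <- fit_boltzmann(cv)
  expect_equal(q_score(cv, fit), 1)
  flat <- simulate_melt_curve(n_transitions = 0, noise_sd = 2, seed = 3)
  expect_equal(q_score(flat, fit_boltzmann(flat)), 0)
  # initial-spike artifact doubling the observed range halves Q
  spiked <- cv
  spiked$intensity[1] <- min(cv$intensity) + 2 * (fit$i_max - fit$i_min)
  expect_equal(q_score(spiked, fit), 0.5, tolerance = 1e-5)
})

test_that("transition counting separates none / single / multi", {
  expect_equal(classify_curve(simulate_melt_curve())$verdict, "single")
  two <- simulate_melt_curve(t_m = c(45, 62), n_transitions = 2)
  cls <- classify_curve(two)
  expect_equal(cls$verdict, "multi")
  expect_equal(cls$n_transitions, 2L)
  expect_equal(cls$peak_temperatures, c(45, 62), tolerance = 1)
  flat <- simulate_melt_curve(n_transitions = 0)
  expect_equal(classify_curve(flat)$verdict, "none")
  # robust across noise realizations
  verdicts <- vapply(1:25, function(s) {
    classify_curve(simulate_melt_curve(t_m = c(45, 62), n_transitions = 2,
                                       noise_sd = 18, seed = s))$verdict
  }, character(1))
  expect_true(all(verdicts == "multi"))
})

test_that("delta Tm preserves sign and demands convergence", {
  f1 <- fit_boltzmann(simulate_melt_curve(t_m = 60))
  f0 <- fit_boltzmann(simulate_melt_curve(t_m = 55))
  d <- delta_tm(f1, f0)
  expect_equal(d$delta_tm, 5, tolerance = 1e-3)
  expect_false(d$destabilizer)
  expect_equal(delta_tm(f0, f0)$delta_tm, 0)
  down <- delta_tm(f0, f1)
  expect_equal(down$delta_tm, -5, tolerance = 1e-3)
  expect_true(down$destabilizer)
  bad <- fit_boltzmann(simulate_melt_curve(n_transitions = 0, noise_sd = 2,
                                           seed = 4))
  expect_error(delta_tm(bad, f0), "converged")
})

test_that("van't Hoff enthalpy equals R Tm^2 / a in Kelvin", {
  fit <- structure(list(t_m = 55, a = 1.5, converged = TRUE),
                   class = "boltzmann_fit")
  expect_equal(vant_hoff_enthalpy(fit), 1.987 * 328.15^2 / 1.5)
  expect_equal(vant_hoff_enthalpy(fit), 1.426e5, tolerance = 1e-3)
  fit2 <- fit
  fit2$a <- 3
  expect_equal(vant_hoff_enthalpy(fit2), vant_hoff_enthalpy(fit) / 2)
})

test_that("kd_estimate implements the van't Hoff association constant", {
  # no shift: K_D equals the ligand concentration
  no_shift <- kd_estimate(1e5, 328.15, 328.15, 1e-4)
  expect_equal(no_shift$k_d, 1e-4)
  expect_equal(no_shift$k_l, 1 / 1e-4)
  k <- kd_estimate(5e4, 330, 325, 1e-4)
  expect_equal(k$k_d, exp(5e4 / 1.987 * (1 / 330 - 1 / 325)) * 1e-4)
  expect_equal(k$k_d, 3.1e-5, tolerance = 0.01)
  expect_equal(k$k_l * k$k_d, 1)
  # larger stabilizing shift at fixed enthalpy strictly lowers K_D
  kds <- vapply(seq(326, 336, 2),
                function(tm) kd_estimate(5e4, tm, 325, 1e-4)$k_d, numeric(1))
  expect_true(all(diff(kds) < 0))
  expect_error(kd_estimate(5e4, 330, 325, 0), "positive")
})

test_that("kd_estimate round-trips through its numerically inverted shift", {
  dh <- 1.2e5; t0 <- 328.15; conc <- 1e-4
  for (target_kd in c(1e-7, 1e-5, 5e-5)) {
    tm <- uniroot(function(t) kd_estimate(dh, t, t0, conc)$k_d - target_kd,
                  c(t0, t0 + 40), tol = 1e-10)$root
    expect_equal(kd_estimate(dh, tm, t0, conc)$k_d, target_kd,
                 tolerance = 1e-6)
  }
})

test_that("hit bookkeeping reproduces tallies and conserves totals", {
  tab <- data.frame(
    target = c("DHFR", "1000006", "1000001", "TrpRS", "UCE", "TP2", "cDPK", "NAP1"),
    n_tested = c(83, 59, 86, 94, 80, 67, 80, 82),
    n_interpretable = c(32, 43, 42, 12, 51, 12, 19, 54),
    n_positive = c(15, 6, 10, 5, 2, 2, 3, 4))
  s <- summarize_hits(tab)
  expect_equal(s$per_target$pct_positive[s$per_target$target == "DHFR"], 46.9)
  expect_equal(s$per_target$pct_positive[s$per_target$target == "UCE"], 3.9)
  expect_equal(s$total_positives, 47)
  shuffled <- summarize_hits(tab[sample.int(8), ])
  expect_equal(shuffled$total_positives, 47)
  bad <- tab
  bad$n_positive[1] <- 40  # more positives than interpretable curves
  expect_error(summarize_hits(bad), "inconsistent")
})
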