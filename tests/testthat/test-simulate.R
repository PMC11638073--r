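test_that("simulation specs validate their inputs", {
  expect_error(simulation_spec("etbr_decay", time_points = c(3, 1)), "sorted")
  expect_error(simulation_spec("etbr_decay", missing_rate = 1), "missing_rate")
  expect_error(simulation_spec("etbr_decay", noise_cv = -1), "noise_cv")
  sp <- simulation_spec("gradient_chase")
  expect_equal(sp$time_points, c(0, 1.5, 3, 6, 12))
})

test_that("global turnover simulation matches the solver and sums to one", {
  gr <- growth_model()
  sp <- simulation_spec("global_turnover", noise_cv = 0, seed = 1)
  truth <- tibble(protein = c("one", "two"),
                  model = c("one_state", "two_state"),
                  k_a = c(0.05, 0.2), k_ab = c(NA, 0.1), k_b = c(NA, 0.01))
  d <- simulate_global_turnover(sp, truth, gr)
  sums <- d %>%
    group_by(protein, time, replicate) %>%
    summarise(s = sum(proportion), .groups = "drop")
  expect_equal(sums$s, rep(1, nrow(sums)), tolerance = 1e-9)
  # noiseless output equals the closed-form solution
  sol <- solve_turnover(one_state_params(0.05), gr, sp$time_points)
  got <- d %>% dplyr::filter(protein == "one", replicate == 1, label == "H")
  expect_equal(got$proportion, sol$H, tolerance = 1e-12)
  # two-state with k_ab = 0 equals one-state with the same k_a
  t2 <- tibble(protein = "x", model = "two_state", k_a = 0.05, k_ab = 0,
               k_b = 0.4, b0 = 0)
  d2 <- simulate_global_turnover(sp, t2, gr)
  expect_equal(dplyr::filter(d2, replicate == 1, label == "H")$proportion,
               sol$H, tolerance = 1e-10)
  expect_error(
    simulate_global_turnover(sp, tibble(protein = "x", model = "one_state",
                                        k_a = -1), gr),
    "negative")
})

test_that("gradient chase conserves label and concentrates the subunit", {
  tr <- default_gradient_truth(mtssu_pathway, seed = 5)
  sp <- simulation_spec("gradient_chase", noise_cv = 0, seed = 5)
  sim <- simulate_gradient_chase(sp, mtssu_pathway, tr)
  # noiseless label conservation at the protein-fraction level:
  # M_i(t) = H_i(0) - H_i(t)
  chk <- sim$abundance %>%
    group_by(protein, fraction) %>%
    summarise(dev = max(abs(M - (first(H) - H))), .groups = "drop")
  expect_lt(max(chk$dev), 1e-9)
  # the mature subunit sediments in the configured mature fraction band
  tot7 <- sim$abundance %>%
    dplyr::filter(time == 0, fraction %in% 6:8) %>%
    summarise(s = sum(H)) %>% pull(s)
  tot_all <- sim$abundance %>% dplyr::filter(time == 0) %>%
    summarise(s = sum(H)) %>% pull(s)
  expect_gt(tot7 / tot_all, 0.3)
  # H/L normalization recovers the noiseless abundances exactly
  norm <- normalize_to_standard(sim$data, quiet = TRUE)
  j <- norm %>% dplyr::filter(label == "H") %>%
    left_join(sim$abundance, by = c("protein", "fraction", "time"))
  expect_lt(max(abs(j$abundance - j$H)), 1e-9)
})

test_that("missingness removes the expected share of measurements", {
  tr <- default_gradient_truth(mtssu_pathway, seed = 2)
  sp0 <- simulation_spec("gradient_chase", noise_cv = 0, missing_rate = 0,
                         seed = 3)
  sp5 <- simulation_spec("gradient_chase", noise_cv = 0, missing_rate = 0.5,
                         seed = 3)
  full <- simulate_gradient_chase(sp0, mtssu_pathway, tr)$data
  half <- simulate_gradient_chase(sp5, mtssu_pathway, tr)$data
  frac <- nrow(half) / nrow(full)
  # binomial tolerance around 0.5
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / nrow(full)) + 0.01)
})

test_that("transcription-block decay follows 100 exp(-kt)", {
  sp <- simulation_spec("etbr_decay", noise_cv = 0, seed = 1)
  tau <- 15
  d <- simulate_etbr_decay(sp, log(2) / tau)
  expect_equal(d$value[d$time == 0], rep(100, 3))
  # half the signal remains at t = tau for k = ln2/tau
  sp2 <- simulation_spec("etbr_decay", time_points = c(0, tau), noise_cv = 0)
  d2 <- simulate_etbr_decay(sp2, log(2) / tau)
  expect_equal(d2$value[d2$time == tau], rep(50, 3), tolerance = 1e-9)
  # k = 0: constant 100
  d0 <- simulate_etbr_decay(sp, 0)
  expect_equal(d0$value, rep(100, nrow(d0)))
  expect_error(simulate_etbr_decay(sp, -0.1), "negative")
})

test_that("fixed seeds reproduce simulations byte-identically", {
  sp <- simulation_spec("etbr_decay", noise_cv = 0.1, seed = 11)
  expect_identical(simulate_etbr_decay(sp, 0.2), simulate_etbr_decay(sp, 0.2))
  tr <- default_gradient_truth(mtssu_pathway, seed = 3)
  spg <- simulation_spec("gradient_chase", noise_cv = 0.05, seed = 12)
  s1 <- simulate_gradient_chase(spg, mtssu_pathway, tr)
  s2 <- simulate_gradient_chase(spg, mtssu_pathway, tr)
  expect_identical(s1$data, s2$data)
})

test_that("log-normal noise has unit mean at the stated CV", {
  set.seed(99)
  x <- mitoflux:::.ln_noise(1e4, 0.2)
  expect_equal(mean(x), 1, tolerance = 0.01)
  expect_equal(sd(x), 0.2, tolerance = 0.02)
  expect_equal(mitoflux:::.ln_noise(5, 0), rep(1, 5))
})
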