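test_that("growth factor matches its closed form", {
  gr <- growth_model(46.4, 30.8)
  expect_equal(growth_factor(gr, -12), 1)
  expect_equal(growth_factor(gr, 0), 2^(12 / 46.4), tolerance = 1e-12)
  expect_equal(growth_factor(gr, 0), 1.196334, tolerance = 1e-6)
  # continuity at the chase switch and monotonicity
  expect_equal(growth_factor(gr, -1e-9), growth_factor(gr, 0),
               tolerance = 1e-6)
  tt <- seq(-12, 24, by = 0.5)
  expect_true(all(diff(growth_factor(gr, tt)) > 0))
  # equal doubling times collapse to a single exponential
  gr2 <- growth_model(40, 40)
  expect_equal(growth_factor(gr2, c(-6, 0, 10)),
               2^((c(-6, 0, 10) + 12) / 40), tolerance = 1e-12)
})

test_that("turnover solution matches independent oracles", {
  gr <- growth_model(46.4, 30.8)
  times <- c(-12, -5, 0, 2, 7, 13, 21)
  # two-state vs fine-step Euler (the stated oracle)
  o <- oracle_turnover_euler(0.05, 0.02, 0.01, gr, times)
  s <- solve_turnover(two_state_params(0.05, 0.02, 0.01), gr, times)
  expect_equal(as.matrix(s[, c("H", "M", "L")]), o, tolerance = 1e-4,
               ignore_attr = TRUE)
  # H proportion declines fast then slow (complex protection)
  h <- s$H
  expect_true(all(diff(h) < 0))
  # one-state vs piecewise lsoda at tight tolerance
  kap <- 0.07
  A0 <- 1 / (gr$g_m + kap)
  rhs <- function(t, y, p, piM, piL) {
    C <- growth_factor(gr, t)
    list(c(-kap * y[1], piM * C - kap * y[2], piL * C - kap * y[3]))
  }
  o1 <- deSolve::lsoda(c(A0, 0, 0), c(-12, -5, 0),
                       function(t, y, p) rhs(t, y, p, 1, 0), NULL,
                       rtol = 1e-11, atol = 1e-14)
  o2 <- deSolve::lsoda(o1[3, -1], c(0, 2, 7, 13, 21),
                       function(t, y, p) rhs(t, y, p, 0, 1), NULL,
                       rtol = 1e-11, atol = 1e-14)
  om <- rbind(o1[1:2, -1], o2[, -1])
  props <- om / rowSums(om)
  s1 <- solve_turnover(one_state_params(kap), gr, times)
  expect_equal(as.matrix(s1[, c("H", "M", "L")]), props, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("two-state model nests the one-state model exactly", {
  gr <- growth_model()
  times <- seq(-12, 21, by = 1.5)
  s1 <- solve_turnover(one_state_params(0.07), gr, times)
  s2 <- solve_turnover(two_state_params(0.07, 0, 0.3, b0 = 0), gr, times)
  expect_equal(s1$H, s2$H, tolerance = 1e-10)
  expect_equal(s1$M, s2$M, tolerance = 1e-10)
  expect_equal(s1$L, s2$L, tolerance = 1e-10)
  # k_a = 0, no growth effect during M chase only: H proportion stays 1
  s0 <- solve_turnover(one_state_params(0), growth_model(1e9, 1e9),
                       c(-12, -6, 0))
  expect_equal(s0$H, rep(1, 3), tolerance = 1e-6)
  expect_error(one_state_params(-0.1), "negative")
  expect_error(two_state_params(0.1, -0.1, 0.1), "negative")
})

test_that("likelihood-ratio test follows the chi-square reference", {
  f1 <- list(logLik = -10, n = 30)
  f2 <- list(logLik = -10, n = 30)
  lrt <- likelihood_ratio_test(f1, f2)
  expect_equal(lrt$statistic, 0)
  expect_equal(lrt$p_value, 1)
  # statistic 5.99 on 2 df sits at p ~ 0.05
  lrt2 <- likelihood_ratio_test(list(logLik = 0, n = 30),
                                list(logLik = 5.99 / 2, n = 30))
  expect_equal(lrt2$p_value, exp(-5.99 / 2), tolerance = 1e-12)
  expect_equal(lrt2$p_value, 0.05, tolerance = 1e-3)
  # larger model worse (sampler artifact): clipped to 0
  lrt3 <- likelihood_ratio_test(list(logLik = -5, n = 30),
                                list(logLik = -7, n = 30))
  expect_equal(lrt3$statistic, 0)
  expect_equal(lrt3$p_value, 1)
  expect_error(likelihood_ratio_test(list(logLik = 0, n = 30),
                                     list(logLik = 0, n = 31)),
               "same data")
})

test_that("fit_turnover recovers noiseless rates and logs exclusions", {
  gr <- growth_model()
  sp <- simulation_spec("global_turnover", noise_cv = 0, seed = 1)
  d <- simulate_global_turnover(
    sp, tibble(protein = "p", model = "one_state", k_a = 0.1), gr)
  fit <- fit_turnover(d, gr, "one_state", n_iter = 2000, seed = 1)
  expect_equal(unname(fit$ml$one_state$theta["k_a"]), 0.1, tolerance = 1e-4)
  expect_equal(unname(median(fit$posterior$one_state[, "k_a"])), 0.1,
               tolerance = 0.01)
  expect_match(fit$log, "excluded time points: 0, 24", all = FALSE)
  # excluded points are really absent from the fit
  expect_equal(fit$n_obs, nrow(dplyr::filter(d, !time %in% c(0, 24))))
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "conf.low", "conf.high") %in%
                    names(td)))
  expect_error(
    fit_turnover(dplyr::filter(d, time %in% c(0, 3, 24)), gr),
    "3 usable time points")
})

test_that("unrelated-protein filter equals an independent brute-force filter", {
  set.seed(42)
  n <- 100
  reps <- 3
  base <- tidyr::crossing(protein = sprintf("P%03d", 1:n),
                          time = c(15, 18, 21), replicate = 1:reps)
  base$proportion <- runif(nrow(base), 0.3, 0.9)
  base$label <- "H"
  sel <- select_unrelated_proteins(base, exclude = c("P001", "P002"))

  # literal reimplementation of the three quantile windows
  h <- base
  v <- tapply(h$proportion, list(h$protein, h$time), var)
  vv <- rowMeans(v)
  m18 <- tapply(h$proportion[h$time == 18], h$protein[h$time == 18], mean)
  m21 <- tapply(h$proportion[h$time == 21], h$protein[h$time == 21], mean)
  keep <- names(vv)[vv < quantile(vv, 0.9) &
                      m18 > quantile(m18, 0.925) & m18 < quantile(m18, 0.99) &
                      m21 > quantile(m21, 0.95) & m21 < quantile(m21, 0.99)]
  keep <- setdiff(keep, c("P001", "P002"))
  expect_setequal(sel, keep)

  # identical proteins: strict inequalities empty the windows
  same <- base
  same$proportion <- 0.5
  expect_length(select_unrelated_proteins(same), 0)
  expect_error(select_unrelated_proteins(dplyr::filter(base, time != 18)),
               "18 h")
})

test_that("shared growth rates are recovered from an unrelated pool", {
  gr <- growth_model(46.4, 30.8)
  sp <- simulation_spec("global_turnover", noise_cv = 0.02, seed = 7)
  # the filtered pool is dilution-dominated: long half-lives by construction
  set.seed(107)
  truth <- tibble(protein = sprintf("U%02d", 1:10), model = "one_state",
                  k_a = runif(10, 0, 0.003))
  d <- simulate_global_turnover(sp, truth, gr)
  fit <- infer_growth_rates(d, n_iter = 4000, seed = 7)
  expect_lt(abs(fit$t_m - 46.4) / 46.4, 0.10)
  expect_lt(abs(fit$t_l - 30.8) / 30.8, 0.10)
  expect_error(infer_growth_rates(dplyr::filter(d, protein == "U01")),
               "at least")
})

test_that("exponential decay fit matches the closed form", {
  d <- tibble(time = c(0, 2, 5, 10, 20),
              value = 100 * exp(-0.2 * c(0, 2, 5, 10, 20)))
  fit <- fit_decay(d, n_iter = 3000, seed = 1)
  expect_equal(fit$k, 0.2, tolerance = 0.01)
  expect_equal(fit$t_half, log(2) / 0.2, tolerance = 0.05)
  # half-life identity holds exactly for every posterior draw
  expect_equal(fit$samples[, "t_half"] * fit$samples[, "k"],
               rep(log(2), nrow(fit$samples)), tolerance = 1e-12,
               ignore_attr = TRUE)
  # constant signal: k near zero, half-life effectively infinite
  d0 <- tibble(time = c(0, 5, 10, 20), value = rep(100, 4))
  f0 <- fit_decay(d0, n_iter = 3000, seed = 2)
  expect_lt(f0$k, 0.01)
  expect_gt(f0$t_half, 69)
  expect_error(fit_decay(tibble(time = 0:2, value = 0)), "zero")
})
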