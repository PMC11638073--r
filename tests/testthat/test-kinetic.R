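test_that("packaged mtSSU kinetic model satisfies the structural identities", {
  m <- build_model(mtssu_pathway)
  expect_equal(m$counts$n_singles, 30)
  expect_equal(m$counts$n_modules, 17)
  expect_equal(m$counts$n_components, 47)
  expect_equal(m$counts$n_initial_conditions, 47)
  expect_equal(m$counts$n_unknown_rates, 111)
  expect_equal(m$counts$n_dependent_rates, 47)
  expect_equal(m$counts$n_free_rates, 64)
  expect_equal(m$counts$n_sampled_parameters, 112)
  expect_equal(length(m$free_names), 64)
  expect_equal(nrow(reaction_table(m)), 17)
})

test_that("toy model counts and mass-action terms are correct", {
  m <- build_model(toy_pathway)
  expect_equal(m$counts$n_components, 3)
  expect_equal(m$counts$n_unknown_rates, 7) # 3 turnovers + 2 supplies + on + off
  expect_equal(m$counts$n_free_rates, 4)
  # d[AB]/dt contribution of A + B -> AB with on = 1 is [A][B]
  dx <- mitoflux:::.assembly_deriv(m, c(A = 2, B = 3, AB = 0.5),
                                   on = 1, off = 0)
  expect_equal(dx, c(-6, -6, 6))
  dx2 <- mitoflux:::.assembly_deriv(m, c(A = 2, B = 3, AB = 0.5),
                                    on = 0, off = 2)
  expect_equal(dx2, c(1, 1, -1))
})

test_that("steady-state elimination reproduces the hand-derived toy balance", {
  m <- build_model(toy_pathway)
  free <- c(k.A = 0.1, k.B = 0.1, on.AB = 1, off.AB = 0)
  q <- c(A = 1, B = 1, AB = 1)
  el <- eliminate_steady_state(m, q, free)
  # sup_A = on [A][B] + k_A [A] - off [AB] = 1 + 0.1 - 0 = 1.1
  expect_equal(el$dependent$value[el$dependent$parameter == "sup.A"], 1.1)
  expect_equal(el$dependent$value[el$dependent$parameter == "sup.B"], 1.1)
  # module turnover k_AB = (on [A][B] - off [AB]) / [AB] = 1
  expect_equal(el$dependent$value[el$dependent$parameter == "k.AB"], 1)
  expect_false(el$any_negative)
  expect_error(eliminate_steady_state(m, c(A = 1, B = 1, AB = 0), free),
               "zero module abundance")
})

test_that("elimination yields an exact fixed point for random draws", {
  m <- build_model(mtssu_pathway)
  set.seed(10)
  worst_rhs <- 0
  worst_drift <- 0
  for (i in 1:20) {
    free <- setNames(runif(64, 0.01, 0.5), m$free_names)
    q <- setNames(runif(47, 0.2, 2), m$components$id)
    el <- eliminate_steady_state(m, q, free)
    rates <- list(k = el$k, sup = el$sup, on = el$on, off = el$off)
    rhs <- mitoflux:::.kinetic_rhs(m, rates)(0, q, NULL)[[1]]
    worst_rhs <- max(worst_rhs, max(abs(rhs)))
    sim <- simulate_total(m, rates, q, c(0, 48))
    worst_drift <- max(worst_drift, max(abs(sim[2, ] - q) / q))
  }
  expect_lt(worst_rhs, 1e-8)
  expect_lt(worst_drift, 1e-6)
})

test_that("labeled simulation decays from the ICs and conserves label", {
  tr <- default_gradient_truth(mtssu_pathway, seed = 4)
  times <- c(0, 1.5, 3, 6, 12)
  lab <- simulate_labeled(build_model(mtssu_pathway), tr$free, tr$q, times)
  # t = 0 equals the IC parameters exactly
  q0 <- lab$H[lab$time == 0]
  expect_equal(q0, unname(tr$q), tolerance = 1e-12)
  # H + M constant per component (label conservation)
  cons <- lab %>%
    group_by(component) %>%
    summarise(dev = max(abs(H + M - first(H + M))))
  expect_lt(max(cons$dev), 1e-9)
  # total labeled pool is non-increasing
  tot <- tapply(lab$H, lab$time, sum)
  expect_true(all(diff(tot) <= 1e-9))
  # all binding rates zero: independent exponential decay per component
  m3 <- build_model(toy3_pathway)
  free0 <- c(k.A = 0.2, k.B = 0.1, k.C = 0.3, on.AB = 0, on.ABC = 0,
             off.AB = 0, off.ABC = 0)
  q3 <- c(A = 1, B = 2, C = 0.5, AB = 1, ABC = 2)
  lab3 <- simulate_labeled(m3, free0, q3, c(0, 2, 5))
  # with zero binding the module turnovers eliminate to zero; singles decay
  hA <- lab3$H[lab3$component == "A"]
  expect_equal(hA, 1 * exp(-0.2 * c(0, 2, 5)), tolerance = 1e-7)
  hAB <- lab3$H[lab3$component == "AB"]
  expect_equal(hAB, rep(1, 3), tolerance = 1e-7)
})

test_that("toy labeled simulation matches a fine-step explicit integrator", {
  m <- build_model(toy_pathway)
  free <- c(k.A = 0.15, k.B = 0.05, on.AB = 0.6, off.AB = 0.02)
  q <- c(A = 0.8, B = 1.2, AB = 1.5)
  el <- eliminate_steady_state(m, q, free)
  lab <- simulate_labeled(m, free, q, c(1, 4, 10))
  # explicit Euler with supplies zero
  state <- unname(q)
  dt <- 1e-4
  tt <- 0
  out <- NULL
  for (target in c(1, 4, 10)) {
    while (tt < target - 1e-12) {
      v <- el$on * state[1] * state[2] - el$off * state[3]
      d <- c(-v - el$k[1] * state[1], -v - el$k[2] * state[2],
             v - el$k[3] * state[3])
      state <- state + dt * d
      tt <- tt + dt
    }
    out <- rbind(out, state)
  }
  for (j in 1:3) {
    expect_equal(lab$H[lab$component == m$components$id[j]], unname(out[, j]),
                 tolerance = 1e-4)
  }
  # inadmissible rates (negative dependent) are an error here
  bad <- c(k.A = 0.1, k.B = 0.1, on.AB = 0, off.AB = 5)
  expect_error(simulate_labeled(m, bad, q, c(0, 1)), "negative dependent")
})

test_that("kinetic log likelihood matches brute-force density sums", {
  m <- build_model(toy_pathway)
  free <- c(k.A = 0.15, k.B = 0.05, on.AB = 0.6, off.AB = 0.02)
  q <- c(A = 0.8, B = 1.2, AB = 1.5)
  times <- c(1, 3, 6)
  lab <- simulate_labeled(m, free, q, times)
  # model prediction equals data, sd = 1: each of the 3 x 9 terms is
  # -log(2 pi)/2
  ll <- kinetic_log_likelihood(lab, m, free, q, 1)
  expect_equal(ll, -27 * log(2 * pi) / 2, tolerance = 1e-9)
  # brute force with perturbed data
  data <- lab
  set.seed(1)
  data$H <- data$H + rnorm(nrow(data), 0, 0.05)
  data$M <- data$M + rnorm(nrow(data), 0, 0.05)
  sdv <- 0.07
  brute <- 0
  for (i in seq_len(nrow(data))) {
    predH <- lab$H[i]
    predM <- lab$M[i]
    brute <- brute + dnorm(data$H[i], predH, sdv, log = TRUE) +
      dnorm(data$M[i], predM, sdv, log = TRUE) +
      dnorm(log(max(data$M[i], 0) / max(data$H[i], 1e-12) + 1),
            log(max(predM, 0) / max(predH, 1e-12) + 1), sdv, log = TRUE)
  }
  expect_equal(kinetic_log_likelihood(data, m, free, q, sdv), brute,
               tolerance = 1e-9)
  # a draw with negative dependent parameters hits the rejection constant
  bad <- c(k.A = 0.1, k.B = 0.1, on.AB = 0, off.AB = 5)
  expect_equal(kinetic_log_likelihood(data, m, bad, q, sdv), -1e10)
})

test_that("packaged mtSSU fit samples 112 parameters", {
  tr <- default_gradient_truth(mtssu_pathway, seed = 1)
  m <- build_model(mtssu_pathway)
  lab <- simulate_labeled(m, tr$free, tr$q, c(0, 1.5, 3, 6, 12))
  fit <- fit_kinetic(lab, m, n_iter = 300, seed = 1)
  expect_equal(ncol(fit$samples), 112)
  expect_equal(fit$n_parameters, 112)
})
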