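# Synthetic triple-SILAC data generator.
#
# Emulates the statistical structure of the three experimental designs so
# that every downstream stage runs and is tested without the deposited raw
# data: (a) the whole-cell double-chase (H -> M -> L) turnover time course,
# (b) the H -> M chase over sucrose-gradient fractions with an L spike-in
# standard, and (c) transcription-block (ethidium bromide) decay courses.
# Noise is multiplicative log-normal with a given coefficient of variation
# (mean exactly 1); missingness is completely at random at the measurement
# level.

#' Simulation specification
#'
#' @param experiment one of `"global_turnover"`, `"gradient_chase"`,
#'   `"etbr_decay"`.
#' @param time_points sampling times (h), nonnegative for the chase designs
#'   (the global design also admits the convention that time runs on the
#'   L-chase clock); sorted.
#' @param replicates number of biological replicates.
#' @param noise_cv coefficient of variation of the multiplicative log-normal
#'   noise (0.1 by default, a typical relative intensity error for this kind
#'   of MS quantification).
#' @param missing_rate probability that a measurement is unobserved.
#' @param seed integer seed.
#' @return list of class `simulation_spec`.
#' @export
simulation_spec <- function(experiment = c("global_turnover",
                                           "gradient_chase", "etbr_decay"),
                            time_points = NULL, replicates = 3,
                            noise_cv = 0.1, missing_rate = 0, seed = 1) {
  experiment <- match.arg(experiment)
  if (is.null(time_points)) {
    time_points <- switch(experiment,
      global_turnover = c(0, 3, 6, 9, 12, 15, 18, 21, 24),
      gradient_chase = c(0, 1.5, 3, 6, 12),
      etbr_decay = c(0, 3, 6, 12, 24, 48))
  }
  if (is.unsorted(time_points)) abort("time_points must be sorted")
  if (missing_rate < 0 || missing_rate >= 1) {
    abort("missing_rate must be in [0, 1)")
  }
  if (noise_cv < 0) abort("noise_cv must be nonnegative")
  structure(list(experiment = experiment, time_points = time_points,
                 replicates = replicates, noise_cv = noise_cv,
                 missing_rate = missing_rate, seed = seed),
            class = "simulation_spec")
}

# multiplicative log-normal noise with mean 1 and the requested CV
.ln_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdl <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdl^2 / 2, sdlog = sdl)
}

.apply_missing <- function(df, rate) {
  if (rate == 0) return(df)
  df[runif(nrow(df)) >= rate, , drop = FALSE]
}

#' Simulate the global double-chase turnover experiment
#'
#' @param spec a [simulation_spec()] (`global_turnover`).
#' @param truth tibble with one row per protein: `protein`, `model`
#'   (`"one_state"`/`"two_state"`), `k_a`, and for two-state rows `k_ab`,
#'   `k_b` (optional `b0`; default steady state).
#' @param growth a [growth_model()].
#' @return tibble `protein`, `time`, `replicate`, `label`, `proportion`.
#'   Before noise, proportions per cell sum to one.
#' @export
simulate_global_turnover <- function(spec, truth, growth = growth_model()) {
  set.seed(spec$seed)
  if (any(truth$k_a < 0, na.rm = TRUE)) abort("negative rates are not allowed")
  out <- purrr::map_dfr(seq_len(nrow(truth)), function(i) {
    tr <- truth[i, ]
    params <- if (tr$model == "one_state") {
      one_state_params(k_a = tr$k_a)
    } else {
      if (any(c(tr$k_ab, tr$k_b) < 0)) abort("negative rates are not allowed")
      two_state_params(k_a = tr$k_a, k_ab = tr$k_ab, k_b = tr$k_b,
                       b0 = if ("b0" %in% names(tr) && !is.na(tr$b0)) {
                         tr$b0
                       } else NULL)
    }
    sol <- solve_turnover(params, growth, spec$time_points)
    tidyr::crossing(replicate = seq_len(spec$replicates),
                    time = spec$time_points) %>%
      left_join(sol[, c("time", "H", "M", "L")], by = "time") %>%
      tidyr::pivot_longer(c("H", "M", "L"), names_to = "label",
                          values_to = "proportion") %>%
      mutate(protein = tr$protein, .before = 1)
  })
  out$proportion <- out$proportion * .ln_noise(nrow(out), spec$noise_cv)
  .apply_missing(out, spec$missing_rate)
}

#' Simulate the gradient-fraction chase experiment
#'
#' Simulates the labeled pools of every pathway component under the
#' mass-action assembly model, places each component in its assigned gradient
#' fraction, and emits a MaxQuant-style raw intensity grid with an L
#' spike-in standard: protein H intensity in a fraction is the component H
#' abundance times the protein's spike-in constant, the L intensity is the
#' spike-in constant itself, and M follows by label conservation before
#' noise.
#'
#' @param spec a [simulation_spec()] (`gradient_chase`).
#' @param pathway an `assembly_pathway`.
#' @param truth list with `free` (named free rates), `q` (steady abundances
#'   per component) and `fraction_of` (named integer, assigned fraction per
#'   component); optional `spike_range` (log-uniform range of spike-in
#'   constants, default `c(0.2, 5)`).
#' @param n_fractions total fractions in the gradient (default 16).
#' @param spread sedimentation kernel: weights over fractions
#'   `(assigned - 1, assigned, assigned + 1)`, emulating the smearing of a
#'   complex across adjacent gradient fractions (renormalized at the gradient
#'   edges). Set `c(0, 1, 0)` for sharp banding.
#' @param detection_limit optional intensity floor below which measurements
#'   are recorded as 0 (unquantified). Default 0 (off): censoring the early,
#'   near-zero M observations removes exactly the measurements that pin down
#'   slow label exchange, so the default missingness is purely the
#'   completely-at-random `spec$missing_rate`.
#' @return list with `data` (raw grid: `protein`, `fraction`, `time`,
#'   `replicate`, `label`, `intensity`), `abundance` (noiseless protein-level
#'   H/M abundances) and `truth` (with spike constants appended).
#' @export
simulate_gradient_chase <- function(spec, pathway, truth, n_fractions = 16,
                                    spread = c(0.15, 0.7, 0.15),
                                    detection_limit = 0) {
  set.seed(spec$seed)
  model <- build_model(pathway)
  if (!setequal(names(truth$fraction_of), model$components$id)) {
    abort("truth$fraction_of must cover every pathway component")
  }
  lab <- simulate_labeled(model, truth$free, truth$q, spec$time_points)
  members <- c(as.list(setNames(pathway$species$id, pathway$species$id)),
               setNames(pathway$modules$members, pathway$modules$id))
  # protein-level noiseless abundance per fraction: sum of the abundances of
  # components assigned there that contain the protein
  ab <- purrr::map_dfr(names(truth$fraction_of), function(comp) {
    sub <- lab[lab$component == comp, ]
    fo <- truth$fraction_of[[comp]]
    fr <- (fo - 1):(fo + 1)
    ok <- fr >= 1 & fr <= n_fractions
    w <- spread[ok] / sum(spread[ok])
    purrr::map_dfr(seq_along(w), function(j) {
      tibble(protein = rep(members[[comp]], each = nrow(sub)),
             fraction = fr[ok][j],
             time = rep(sub$time, length(members[[comp]])),
             H = rep(sub$H * w[j], length(members[[comp]])),
             M = rep(sub$M * w[j], length(members[[comp]])))
    })
  }) %>%
    group_by(.data$protein, .data$fraction, .data$time) %>%
    summarise(H = sum(.data$H), M = sum(.data$M), .groups = "drop")
  proteins <- sort(unique(ab$protein))
  spike_range <- truth$spike_range %||% c(0.2, 5)
  spike <- setNames(exp(runif(length(proteins), log(spike_range[1]),
                              log(spike_range[2]))), proteins)
  raw <- ab %>%
    mutate(L = unname(spike[.data$protein]),
           H = .data$H * .data$L, M = .data$M * .data$L) %>%
    tidyr::pivot_longer(c("H", "M", "L"), names_to = "label",
                        values_to = "intensity") %>%
    tidyr::crossing(replicate = seq_len(spec$replicates)) %>%
    select("protein", "fraction", "time", "replicate", "label", "intensity") %>%
    arrange(.data$protein, .data$fraction, .data$time, .data$replicate)
  raw$intensity <- raw$intensity * .ln_noise(nrow(raw), spec$noise_cv)
  raw$intensity[raw$intensity < detection_limit] <- 0
  raw <- .apply_missing(raw, spec$missing_rate)
  attr(raw, "n_fractions") <- n_fractions
  truth$spike <- spike
  list(data = raw, abundance = ab, truth = truth)
}

#' Simulate a transcription-block decay time course
#'
#' Percentage of the initial abundance remaining under exponential decay at
#' rate `k`: noiseless values are `100 exp(-k t)`.
#'
#' @param spec a [simulation_spec()] (`etbr_decay`).
#' @param k decay rate (1/h), nonnegative.
#' @return tibble `time`, `replicate`, `value`.
#' @export
simulate_etbr_decay <- function(spec, k) {
  if (k < 0) abort("negative decay rate")
  set.seed(spec$seed)
  out <- tidyr::crossing(time = spec$time_points,
                         replicate = seq_len(spec$replicates)) %>%
    mutate(value = 100 * exp(-k * .data$time))
  out$value <- out$value * .ln_noise(nrow(out), spec$noise_cv)
  .apply_missing(out, spec$missing_rate)
}

#' Simulate normalized abundances directly from the flux model
#'
#' Generates the H/M abundance grid of a single protein from given
#' per-fraction flux parameters, for parameter-recovery checks of
#' [fit_flux()].
#'
#' @param spec a [simulation_spec()] (`gradient_chase`).
#' @param k,a,H0 flux-model parameters (length N).
#' @return tidy grid `fraction`, `time`, `replicate`, `label`, `abundance`.
#' @export
simulate_flux_profile <- function(spec, k, a, H0) {
  set.seed(spec$seed)
  sol <- solve_flux(k, a, H0, spec$time_points)
  out <- sol %>%
    tidyr::pivot_longer(c("H", "M"), names_to = "label",
                        values_to = "abundance") %>%
    tidyr::crossing(replicate = seq_len(spec$replicates)) %>%
    select("fraction", "time", "replicate", "label", "abundance")
  out$abundance <- out$abundance * .ln_noise(nrow(out), spec$noise_cv)
  .apply_missing(out, spec$missing_rate)
}

#' Default synthetic truth for a pathway
#'
#' Draws a reproducible, admissible ground truth for
#' [simulate_gradient_chase()]: nonnegative turnover, supply, binding and
#' unbinding rates are drawn first, the total-abundance system is integrated
#' to its steady state, and that steady state becomes the initial H
#' abundances `q`. By construction the steady-state elimination then
#' reproduces nonnegative supply and module-turnover rates. Fraction
#' assignment: single species sediment in the light fractions (1-3),
#' intermediate modules in fractions 3-6 by member count, the terminal
#' subunit in the mature fraction.
#'
#' @param pathway an `assembly_pathway`.
#' @param mature_fraction fraction of the mature subunit (7 for mtSSU).
#' @param seed integer seed.
#' @return truth list (`free`, `q`, `fraction_of`) for
#'   [simulate_gradient_chase()].
#' @export
default_gradient_truth <- function(pathway, mature_fraction = 7, seed = 1) {
  set.seed(seed)
  model <- build_model(pathway)
  ns <- model$counts$n_singles
  nm <- model$counts$n_modules
  # rate regime chosen so that intermediate-module pools are a substantial
  # share of the mature-subunit pool (as in the measured gradients, where
  # early-fraction abundances are within an order of magnitude of the
  # subunit reference), and so that different modules differ visibly in
  # abundance and turnover
  # free single pools turn over fast and stay modest; intermediate modules
  # are moderately stable; the mature subunit is long-lived and accumulates
  # the largest pool, as in the measured gradients
  k <- c(runif(ns, 0.1, 0.4), runif(nm, 0.002, 0.02))
  k[model$components$id == model$terminal] <- runif(1, 0.002, 0.01)
  sup <- c(runif(ns, 0.05, 0.3), rep(0, nm))
  on <- runif(nm, 0.5, 2)
  off <- runif(nm, 0.005, 0.05)
  rates <- list(k = k, sup = sup, on = on, off = off)
  x0 <- pmax(sup / k, 0.1)
  rhs <- .kinetic_rhs(model, rates)
  for (chunk in 1:10) { # integrate until the relative drift is negligible
    sim <- simulate_total(model, rates, x0, c(0, 2000),
                          rtol = 1e-10, atol = 1e-12)
    x0 <- pmax(sim[nrow(sim), ], 1e-9)
    if (max(abs(rhs(0, x0, NULL)[[1]]) / pmax(x0, 1e-9)) < 1e-7) break
  }
  q <- setNames(x0, model$components$id)
  free <- setNames(c(k[1:ns], on, off), model$free_names)
  # modules sediment by assembly depth; singles in the light fractions
  depth <- setNames(rep(0L, ns + nm), model$components$id)
  for (pass in seq_len(nm)) { # fixed-point over arbitrary reaction order
    for (r in model$reactions) {
      depth[r$product] <- 1L + max(depth[r$reactants])
    }
  }
  frac <- integer(ns + nm)
  frac[1:ns] <- sample(1:2, ns, replace = TRUE)
  frac[(ns + 1):(ns + nm)] <-
    pmin(3L + depth[(ns + 1):(ns + nm)], mature_fraction - 1L)
  frac[model$components$id == model$terminal] <- mature_fraction
  names(frac) <- model$components$id
  list(free = free, q = q, fraction_of = frac)
}
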