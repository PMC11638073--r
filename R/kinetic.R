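# Mass-action kinetic model of small-subunit assembly.
#
# Each module P_j is the product of exactly one binding reaction with
# reactants E_k (single species and/or smaller modules):
#
#   d[P_j]/dt  +=  on_j prod_k [E_k]  -  off_j [P_j]
#   d[E_k]/dt  -=  on_j prod_k [E_k]  -  off_j [P_j]
#
# Every component C additionally turns over at rate k_C, and every single
# species is supplied (imported) at rate sup_C. Because total abundances are
# at steady state, the supply rates of singles and the turnover rates of
# modules are eliminated: they are expressed in terms of the remaining rates
# and the steady abundances, so that every component's total derivative
# vanishes exactly. The labeled (H) pool obeys the same equations with all
# supplies set to zero; M follows by label conservation M(t) = H(0) - H(t).

#' Build a kinetic assembly model from a pathway
#'
#' @param pathway an `assembly_pathway` from [load_pathway()].
#' @return object of class `kinetic_model`: component table, indexed
#'   reactions, free/dependent parameter names and the structural counts
#'   (`counts`): unknown rates = component turnovers + supplies + binding +
#'   unbinding; free rates after steady-state elimination = single turnovers
#'   + binding + unbinding; sampled parameters = free rates + initial
#'   conditions + noise sd.
#' @export
build_model <- function(pathway) {
  singles <- pathway$species$id
  modules <- pathway$modules$id
  comp <- c(singles, modules)
  cidx <- setNames(seq_along(comp), comp)
  reactions <- lapply(pathway$reactions, function(r) {
    list(product = unname(cidx[r$product]),
         reactants = unname(cidx[r$reactants]),
         product_id = r$product)
  })
  ns <- length(singles); nm <- length(modules); nc <- ns + nm
  counts <- list(
    n_singles = ns, n_modules = nm, n_components = nc,
    n_initial_conditions = nc,
    n_unknown_rates = nc + ns + 2 * nm,
    n_dependent_rates = ns + nm,
    n_free_rates = ns + 2 * nm,
    n_sampled_parameters = ns + 2 * nm + nc + 1
  )
  structure(
    list(components = tibble(id = comp,
                             type = rep(c("single", "module"), c(ns, nm))),
         singles = singles, modules = modules, reactions = reactions,
         terminal = pathway$terminal, counts = counts,
         free_names = c(paste0("k.", singles),
                        paste0("on.", modules), paste0("off.", modules)),
         ic_names = paste0("P0.", comp)),
    class = "kinetic_model"
  )
}

#' @export
print.kinetic_model <- function(x, ...) {
  ct <- x$counts
  cat("Mass-action assembly model:", ct$n_singles, "single species,",
      ct$n_modules, "modules\n")
  cat("  unknown rates:", ct$n_unknown_rates,
      "| free after steady-state elimination:", ct$n_free_rates, "\n")
  cat("  sampled parameters (free rates + ICs + sd):",
      ct$n_sampled_parameters, "\n")
  invisible(x)
}

# assembly part of the derivative (binding/unbinding only)
.assembly_deriv <- function(model, x, on, off) {
  dx <- numeric(length(x))
  for (j in seq_along(model$reactions)) {
    r <- model$reactions[[j]]
    v <- on[j] * prod(x[r$reactants]) - off[j] * x[r$product]
    dx[r$product] <- dx[r$product] + v
    dx[r$reactants] <- dx[r$reactants] - v
  }
  dx
}

.split_free <- function(model, free) {
  ns <- length(model$singles); nm <- length(model$modules)
  if (is.null(names(free))) names(free) <- model$free_names
  list(k_single = free[1:ns], on = free[ns + 1:nm], off = free[ns + nm + 1:nm])
}

#' Eliminate dependent parameters via the steady-state condition
#'
#' Given steady total abundances `q` and the free rates, derives the supply
#' rate of every single species and the turnover rate of every module such
#' that every component's total derivative is exactly zero at `q`:
#' `sup_C = k_C q_C - A_C` for singles and `k_C = A_C / q_C` for modules,
#' where `A_C` is the assembly (binding/unbinding) part of the derivative.
#'
#' @param model a `kinetic_model`.
#' @param q named (or ordered) vector of steady abundances per component,
#'   all positive.
#' @param free named vector of free rates (`k.<single>`, `on.<module>`,
#'   `off.<module>`).
#' @return list with `sup` (per component; zero for modules), `k` (turnover
#'   per component), `on`, `off`, `dependent` (tibble of the eliminated
#'   parameters) and `any_negative`.
#' @export
eliminate_steady_state <- function(model, q, free) {
  nc <- model$counts$n_components
  ns <- model$counts$n_singles
  if (!is.null(names(q))) q <- q[model$components$id]
  q <- unname(q)
  if (length(q) != nc || anyNA(q)) abort("q must cover every component")
  fr <- .split_free(model, free)
  mod_q <- q[(ns + 1):nc]
  if (any(mod_q <= 0)) abort("zero module abundance; cannot eliminate turnover")
  A <- .assembly_deriv(model, q, fr$on, fr$off)
  k <- c(fr$k_single, A[(ns + 1):nc] / mod_q)
  sup <- c(k[1:ns] * q[1:ns] - A[1:ns], rep(0, nc - ns))
  dep <- tibble(
    parameter = c(paste0("sup.", model$singles),
                  paste0("k.", model$modules)),
    value = unname(c(sup[1:ns], k[(ns + 1):nc])))
  list(sup = sup, k = unname(k), on = unname(fr$on), off = unname(fr$off),
       dependent = dep, any_negative = any(dep$value < 0))
}

.kinetic_rhs <- function(model, rates) {
  force(rates)
  function(t, x, parms) {
    dx <- .assembly_deriv(model, x, rates$on, rates$off) -
      rates$k * x + rates$sup
    list(dx)
  }
}

#' Simulate total component abundances
#'
#' Integrates the full mass-action system (with supplies) from the given
#' state. With rates from [eliminate_steady_state()] and `x0 = q`, the
#' trajectory is constant (steady-state fixed point).
#'
#' @param model a `kinetic_model`.
#' @param rates list as returned by [eliminate_steady_state()].
#' @param x0 initial abundances per component.
#' @param times times (h).
#' @param rtol,atol solver tolerances.
#' @param maxsteps solver step budget per output interval.
#' @return matrix (length(times) x components) of abundances.
#' @export
simulate_total <- function(model, rates, x0, times, rtol = 1e-8,
                           atol = 1e-10, maxsteps = 100000) {
  out <- deSolve::lsoda(unname(x0), times, .kinetic_rhs(model, rates),
                        parms = NULL, rtol = rtol, atol = atol,
                        maxsteps = maxsteps)
  m <- out[, -1, drop = FALSE]
  colnames(m) <- model$components$id
  m
}

# internal labeled-pool simulation; returns NULL on rejection
.simulate_labeled_impl <- function(model, free, q, times, rtol = 1e-8) {
  dep <- tryCatch(eliminate_steady_state(model, q, free),
                  error = function(e) NULL)
  if (is.null(dep) || dep$any_negative) return(NULL)
  rates <- list(k = dep$k, sup = rep(0, length(dep$k)),
                on = dep$on, off = dep$off)
  tt <- sort(unique(c(0, times)))
  out <- tryCatch(
    deSolve::lsoda(unname(q), tt, .kinetic_rhs(model, rates), parms = NULL,
                   rtol = rtol, atol = 1e-10),
    warning = function(w) NULL, error = function(e) NULL)
  if (is.null(out) || nrow(out) < length(tt)) return(NULL)
  H <- out[match(times, tt), -1, drop = FALSE]
  colnames(H) <- model$components$id
  H
}

#' Simulate the H-labeled pools after the chase switch
#'
#' Same mass-action system with all supply rates set to zero (no newly made
#' H protein after the medium switch); initial H abundances equal the total
#' steady abundances `q`, and the M pools follow by label conservation.
#' Negative dependent parameters (an inadmissible steady state for the given
#' free rates) are an error here; during fitting they are handled by the
#' likelihood rejection constant.
#'
#' @inheritParams eliminate_steady_state
#' @param times times (h) after the switch.
#' @param rtol solver relative tolerance.
#' @return tibble `component`, `time`, `H`, `M`.
#' @export
simulate_labeled <- function(model, free, q, times, rtol = 1e-8) {
  H <- .simulate_labeled_impl(model, free, q, times, rtol)
  if (is.null(H)) {
    abort("negative dependent parameter or integration failure")
  }
  if (!is.null(names(q))) q <- q[model$components$id]
  q <- unname(q)
  tibble(
    component = rep(model$components$id, each = length(times)),
    time = rep(times, model$counts$n_components),
    H = as.vector(H),
    M = rep(q, each = length(times)) - as.vector(H)
  )
}

#' Component-level H/M time courses from a protein grid
#'
#' Singles take the H/M abundances of their protein in the component's
#' assigned fraction; module abundances are the mean over the normalized
#' abundances of all member proteins in the module's fraction.
#'
#' @param grid normalized (replicate-averaged) grid: `protein`, `fraction`,
#'   `time`, `label`, `abundance`.
#' @param pathway the `assembly_pathway`.
#' @param fraction_of named integer vector: assigned fraction per component.
#' @return tibble `component`, `time`, `H`, `M`.
#' @export
component_abundances <- function(grid, pathway, fraction_of) {
  grid <- average_replicates(grid)
  members <- c(as.list(setNames(pathway$species$id, pathway$species$id)),
               setNames(pathway$modules$members, pathway$modules$id))
  purrr::map_dfr(names(fraction_of), function(comp) {
    mem <- members[[comp]]
    sub <- grid %>%
      filter(.data$protein %in% mem,
             .data$fraction == fraction_of[[comp]]) %>%
      group_by(.data$time, .data$label) %>%
      summarise(abundance = mean(.data$abundance), .groups = "drop") %>%
      tidyr::pivot_wider(names_from = "label", values_from = "abundance")
    if (!nrow(sub)) return(NULL)
    if (!"H" %in% names(sub)) sub$H <- NA_real_
    if (!"M" %in% names(sub)) sub$M <- NA_real_
    tibble(component = comp, time = sub$time, H = sub$H, M = sub$M)
  })
}

#' Log likelihood of the labeled kinetic model
#'
#' Three normal terms per observed component and time: the H abundance, the
#' M abundance and the log ratio `R = log(M/H + 1)`, with one shared noise
#' sd. Parameter combinations whose eliminated (dependent) parameters turn
#' negative receive the rejection constant `-1e10`.
#'
#' @param data tibble `component`, `time`, `H`, `M` (observed).
#' @param model a `kinetic_model`.
#' @param free named free-rate vector.
#' @param q steady abundances / H initial conditions per component.
#' @param sdv shared noise standard deviation.
#' @param rejection value returned for inadmissible parameters.
#' @return scalar log likelihood.
#' @export
kinetic_log_likelihood <- function(data, model, free, q, sdv,
                                   rejection = -1e10) {
  times <- sort(unique(data$time))
  H <- .simulate_labeled_impl(model, free, q, times)
  if (is.null(H)) return(rejection)
  qv <- unname(q[model$components$id] %||% q)
  ci <- match(data$component, model$components$id)
  ti <- match(data$time, times)
  predH <- H[cbind(ti, ci)]
  predM <- qv[ci] - predH
  predR <- log(pmax(predM, 0) / pmax(predH, 1e-12) + 1)
  obsR <- log(pmax(data$M, 0) / pmax(data$H, 1e-12) + 1)
  sum(dnorm(data$H, predH, sdv, log = TRUE)) +
    sum(dnorm(data$M, predM, sdv, log = TRUE)) +
    sum(dnorm(obsR, predR, sdv, log = TRUE))
}

#' Fit the kinetic assembly model by DE-MCMC
#'
#' Samples the free rates, the initial conditions of all components and the
#' shared noise sd. Rates have truncated-normal priors on `[0, rate_max]`;
#' initial conditions of observed components have truncated-normal priors
#' with the mean and sd of their measured abundance and bounds at 75% and
#' 125% of the mean; unobserved components get broad truncated-normal priors
#' centred on a pathway-informed guess with sd ten times the mean.
#'
#' @param data tibble `component`, `time`, `H`, `M`.
#' @param model a `kinetic_model`.
#' @param ic_stats optional tibble `component`, `mean`, `sd` overriding the
#'   measured abundance statistics (defaults to per-component mean/sd of
#'   observed H + M).
#' @param rate_mean,rate_sd,rate_max prior hyperparameters for rates.
#' @param n_iter MCMC iterations per chain.
#' @param sampler `"am"` (adaptive Metropolis, default) or `"demc"`
#'   (differential-evolution ensemble with snooker updates).
#' @param seed optional seed.
#' @return object of class `kinetic_fit`: `samples`, `rhat`, `model`,
#'   `counts`, `observed` component ids.
#' @export
fit_kinetic <- function(data, model, ic_stats = NULL, rate_mean = 0.1,
                        rate_sd = 1, rate_max = 10, n_iter = 10000,
                        sampler = c("am", "demc"), seed = NULL) {
  sampler <- match.arg(sampler)
  comp <- model$components$id
  if (is.null(ic_stats)) {
    ic_stats <- data %>%
      mutate(total = .data$H + .data$M) %>%
      group_by(.data$component) %>%
      summarise(mean = mean(.data$total, na.rm = TRUE),
                sd = max(sd(.data$total, na.rm = TRUE), 1e-3, na.rm = TRUE),
                .groups = "drop")
  }
  if (any(ic_stats$mean <= 0)) {
    abort("non-positive measured abundance for an observed component")
  }
  observed <- intersect(comp, ic_stats$component)
  guess <- mean(ic_stats$mean)
  ic <- tibble(component = comp) %>%
    left_join(ic_stats, by = "component") %>%
    mutate(observed = .data$component %in% observed,
           mean = ifelse(.data$observed, .data$mean, guess),
           sd = ifelse(.data$observed, .data$sd, 10 * guess),
           lo = ifelse(.data$observed, 0.75 * .data$mean, 0),
           hi = ifelse(.data$observed, 1.25 * .data$mean, Inf))
  nf <- length(model$free_names)
  nc <- length(comp)
  d <- nf + nc + 1
  sd_scale <- max(sd(c(data$H, data$M), na.rm = TRUE), 1e-3)
  lp <- function(th) {
    free <- th[1:nf]
    q <- th[nf + 1:nc]
    sdv <- th[d]
    if (any(free < 0) || any(free > rate_max) || sdv <= 0 ||
        any(q < ic$lo) || any(q > ic$hi)) {
      return(-Inf)
    }
    names(free) <- model$free_names
    ll <- kinetic_log_likelihood(data, model, free, q, sdv)
    ll + sum(dnorm(free, rate_mean, rate_sd, log = TRUE)) +
      sum(dnorm(q, ic$mean, ic$sd, log = TRUE)) +
      dnorm(sdv, 0, sd_scale, log = TRUE)
  }
  init <- function(n) {
    t(vapply(seq_len(n), function(i) {
      q0 <- pmin(pmax(ic$mean * exp(rnorm(nc, 0, 0.05)),
                      ic$lo + 1e-9), ifelse(is.finite(ic$hi),
                                            ic$hi - 1e-9, Inf))
      c(runif(nf, 0.01, 0.5), q0, runif(1, 0.05, 0.5) * sd_scale)
    }, numeric(d)))
  }
  fit <- if (sampler == "am") {
    am_sample(lp, init, n_iter = n_iter, seed = seed,
              init_scale = pmax(0.1 * c(rep(0.2, nf), ic$mean,
                                        0.2 * sd_scale), 1e-3))
  } else {
    demc_sample(lp, init, n_iter = n_iter, seed = seed)
  }
  colnames(fit$samples) <- c(model$free_names, model$ic_names, "sd")
  structure(
    list(samples = fit$samples, rhat = setNames(fit$rhat,
                                                colnames(fit$samples)),
         model = model, counts = model$counts, observed = observed,
         acceptance = fit$acceptance,
         n_parameters = model$counts$n_sampled_parameters),
    class = "kinetic_fit"
  )
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("Kinetic assembly fit:", x$n_parameters, "sampled parameters (",
      x$counts$n_free_rates, "free rates +", x$counts$n_initial_conditions,
      "ICs + sd)\n")
  invisible(x)
}

#' @export
tidy.kinetic_fit <- function(x, ...) {
  s <- x$samples
  tibble(term = colnames(s),
         estimate = apply(s, 2, median),
         conf.low = apply(s, 2, quantile, 0.05),
         conf.high = apply(s, 2, quantile, 0.95),
         rhat = as.numeric(x$rhat))
}

#' @export
glance.kinetic_fit <- function(x, ...) {
  tibble(n_parameters = x$n_parameters,
         n_free_rates = x$counts$n_free_rates,
         max_rhat = max(x$rhat, na.rm = TRUE),
         acceptance = x$acceptance)
}

#' Point estimate of the kinetic model by bounded optimisation
#'
#' Minimises the total squared residual of the three observation channels
#' (H, M and the log ratio) over the free rates and initial conditions, with
#' the noise sd profiled out. Suited to noiseless or near-noiseless recovery
#' checks, where the sampled posterior degenerates (the likelihood grows
#' without bound as the residual sd shrinks).
#'
#' @inheritParams fit_kinetic
#' @return tibble `term`, `estimate` over free rates and ICs, with the
#'   residual sum of squares as attribute `rss`.
#' @export
fit_kinetic_map <- function(data, model, ic_stats = NULL, rate_max = 10) {
  comp <- model$components$id
  if (is.null(ic_stats)) {
    ic_stats <- data %>%
      mutate(total = .data$H + .data$M) %>%
      group_by(.data$component) %>%
      summarise(mean = mean(.data$total, na.rm = TRUE), .groups = "drop")
  }
  ic0 <- tibble(component = comp) %>%
    left_join(ic_stats, by = "component") %>%
    mutate(mean = ifelse(is.na(.data$mean), mean(ic_stats$mean), .data$mean))
  nf <- length(model$free_names)
  nc <- length(comp)
  times <- sort(unique(data$time))
  ci <- match(data$component, comp)
  ti <- match(data$time, times)
  obsR <- log(pmax(data$M, 0) / pmax(data$H, 1e-12) + 1)
  rss <- function(th) {
    free <- setNames(th[1:nf], model$free_names)
    q <- th[nf + 1:nc]
    # negative dependent rates are clamped for the simulation and penalised
    # quadratically, keeping the objective continuous so the optimiser is
    # steered back into the admissible region rather than stonewalled
    dep <- tryCatch(eliminate_steady_state(model, q, free),
                    error = function(e) NULL)
    if (is.null(dep)) return(1e10)
    pen <- 1e3 * sum(pmin(dep$dependent$value, 0)^2)
    rates <- list(k = pmax(dep$k, 0), sup = rep(0, length(dep$k)),
                  on = dep$on, off = dep$off)
    out <- tryCatch(
      deSolve::lsoda(unname(q), sort(unique(c(0, times))),
                     .kinetic_rhs(model, rates), parms = NULL,
                     rtol = 1e-8, atol = 1e-10),
      warning = function(w) NULL, error = function(e) NULL)
    if (is.null(out)) return(1e10)
    H <- out[match(times, sort(unique(c(0, times)))), -1, drop = FALSE]
    predH <- H[cbind(ti, ci)]
    predM <- q[ci] - predH
    predR <- log(pmax(predM, 0) / pmax(predH, 1e-12) + 1)
    pen + sum((data$H - predH)^2) + sum((data$M - predM)^2) +
      sum((obsR - predR)^2)
  }
  best <- NULL
  for (r0 in c(0.1, 0.3)) {
    o <- tryCatch(
      nlminb(c(rep(r0, nf), ic0$mean), rss,
             lower = rep(1e-6, nf + nc),
             upper = c(rep(rate_max, nf), rep(Inf, nc))),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$objective < best$objective)) {
      best <- o
    }
  }
  out <- tibble(term = c(model$free_names, model$ic_names),
                estimate = best$par)
  attr(out, "rss") <- best$objective
  out
}

#' Export a kinetic model as a reaction table
#'
#' @param model a `kinetic_model`.
#' @return tibble `product`, `reactants` (collapsed with `+`), `on`, `off`
#'   parameter names.
#' @export
reaction_table <- function(model) {
  purrr::map_dfr(model$reactions, function(r) {
    tibble(product = r$product_id,
           reactants = paste(model$components$id[r$reactants],
                             collapse = " + "),
           on = paste0("on.", r$product_id),
           off = paste0("off.", r$product_id))
  })
}
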