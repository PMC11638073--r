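# Global turnover models for the double-chase (H -> M -> L) labeling design.
#
# Time is measured on the second-chase clock: the M chase occupies
# t in [-12, 0] h, the L chase t >= 0. Observed data are per-isotope
# proportions H/(H+M+L) etc., which are invariant to the production rate, so
# p = 1 throughout.

#' Growth model for the double-chase experiment
#'
#' Cell growth is exponential with one doubling time during the M chase and
#' another during the L chase.
#'
#' @param t_m,t_l doubling times (h) during the M and L chase; both positive.
#' @return list of class `growth_model` with `t_m`, `t_l`, `g_m`, `g_l`
#'   (rates `log(2)/t`, 1/h).
#' @export
growth_model <- function(t_m = 46.4, t_l = 30.8) {
  if (t_m <= 0 || t_l <= 0) abort("doubling times must be positive")
  structure(list(t_m = t_m, t_l = t_l,
                 g_m = log(2) / t_m, g_l = log(2) / t_l),
            class = "growth_model")
}

#' Cell-count multiplier C(t)
#'
#' Piecewise-exponential growth normalised to `C(-12) = 1` (start of the M
#' chase): `exp(g_m (t + 12))` for `t < 0`, `exp(12 g_m + g_l t)` for
#' `t >= 0`. Continuous at the chase switch and strictly increasing for
#' positive rates.
#'
#' @param growth a [growth_model()].
#' @param t time (h), vectorised; `t = 0` is the start of the L chase.
#' @return numeric vector of multipliers.
#' @export
growth_factor <- function(growth, t) {
  ifelse(t < 0,
         exp(growth$g_m * (t + 12)),
         exp(growth$g_m * 12 + growth$g_l * t))
}

#' One-state turnover parameters
#'
#' Production at rate `p` (scaled by cell count) and first-order degradation
#' at `k_a`.
#' @param k_a degradation rate (1/h).
#' @param p production rate (proportions do not depend on it).
#' @param sd observation noise standard deviation.
#' @return list of class `one_state_params`.
#' @export
one_state_params <- function(k_a, p = 1, sd = 0) {
  if (k_a < 0 || p < 0 || sd < 0) abort("negative rates are not allowed")
  structure(list(p = p, k_a = k_a, sd = sd), class = "one_state_params")
}

#' Two-state turnover parameters
#'
#' Free pool A (production `p`, degradation `k_a`, transfer to the
#' complex-bound pool B at `k_ab`) and bound pool B degraded at `k_b`.
#' `b0` optionally fixes the bound amount at the start of the M chase;
#' `NULL` uses the growing-culture steady state.
#'
#' @param k_a,k_ab,k_b rates (1/h).
#' @param p production rate.
#' @param b0 optional initial B amount at t = -12 h.
#' @param sd observation noise standard deviation.
#' @return list of class `two_state_params`.
#' @export
two_state_params <- function(k_a, k_ab, k_b, p = 1, b0 = NULL, sd = 0) {
  if (any(c(k_a, k_ab, k_b, p, sd) < 0) || (!is.null(b0) && b0 < 0)) {
    abort("negative rates are not allowed")
  }
  structure(list(p = p, k_a = k_a, k_ab = k_ab, k_b = k_b, b0 = b0, sd = sd),
            class = "two_state_params")
}

# closed-form propagation of A (and B) over one interval with growth g,
# production indicator pi and cell count C0 at interval start.
# A and B are represented exactly as sums of exponentials in s = t - t0.
.interval_AB <- function(A0, B0, C0, g, pi, kappa, k_ab, k_b, p, s) {
  c1 <- pi * p * C0 / (g + kappa)
  c2 <- A0 - c1
  A <- c1 * exp(g * s) + c2 * exp(-kappa * s)
  if (k_ab == 0 && B0 == 0) {
    return(list(A = A, B = rep(0, length(s))))
  }
  lam <- c(g, -kappa)
  cc <- c(c1, c2)
  den <- lam + k_b
  den[abs(den) < 1e-9] <- 1e-9 # measure-zero degeneracy guard
  b <- k_ab * cc / den
  B <- b[1] * exp(lam[1] * s) + b[2] * exp(lam[2] * s) +
    (B0 - sum(b)) * exp(-k_b * s)
  list(A = A, B = B)
}

#' Solve the turnover model per isotope
#'
#' Closed-form solution of the one-/two-state turnover system for the three
#' isotope pools under the double-chase design: H production is zero
#' throughout (pre-existing pool, at its growing-culture steady state at
#' t = -12 h), M is produced during the M chase only, L during the L chase
#' only. Each pool obeys the same linear system; the solution on each chase
#' interval is an exact sum of exponentials.
#'
#' @param params a [one_state_params()] or [two_state_params()].
#' @param growth a [growth_model()].
#' @param times times (h) on the L-chase clock, within `[-12, max]`.
#' @return tibble with columns `time`, `H`, `M`, `L` (proportions summing to
#'   one) and amount columns `H_amt`, `M_amt`, `L_amt`.
#' @export
solve_turnover <- function(params, growth, times) {
  if (any(times < -12)) abort("times must be >= -12 h (start of the M chase)")
  two <- inherits(params, "two_state_params")
  kappa <- params$k_a + if (two) params$k_ab else 0
  k_ab <- if (two) params$k_ab else 0
  k_b <- if (two) params$k_b else 0
  p <- params$p
  g_m <- growth$g_m
  g_l <- growth$g_l
  # steady state of a growing culture in H medium at t = -12
  A0_H <- p / (g_m + kappa)
  B0_H <- if (two) {
    if (is.null(params$b0)) k_ab * A0_H / (g_m + k_b) else params$b0
  } else 0

  iso <- list(H = c(0, 0), M = c(1, 0), L = c(0, 1)) # production per interval
  init <- list(H = c(A0_H, B0_H), M = c(0, 0), L = c(0, 0))
  amounts <- matrix(0, length(times), 3, dimnames = list(NULL, c("H", "M", "L")))
  C12 <- exp(12 * g_m)
  for (lab in c("H", "M", "L")) {
    A0 <- init[[lab]][1]
    B0 <- init[[lab]][2]
    # interval 1: M chase, t in [-12, 0]
    s1 <- pmin(times, 0) + 12
    r1 <- .interval_AB(A0, B0, 1, g_m, iso[[lab]][1], kappa, k_ab, k_b, p, s1)
    end1 <- .interval_AB(A0, B0, 1, g_m, iso[[lab]][1], kappa, k_ab, k_b, p, 12)
    # interval 2: L chase, t >= 0
    s2 <- pmax(times, 0)
    r2 <- .interval_AB(end1$A, end1$B, C12, g_l, iso[[lab]][2],
                       kappa, k_ab, k_b, p, s2)
    tot <- ifelse(times < 0, r1$A + r1$B, r2$A + r2$B)
    amounts[, lab] <- tot
  }
  total <- rowSums(amounts)
  tibble(time = times,
         H = amounts[, "H"] / total,
         M = amounts[, "M"] / total,
         L = amounts[, "L"] / total,
         H_amt = amounts[, "H"], M_amt = amounts[, "M"], L_amt = amounts[, "L"])
}

# ---- likelihood machinery ---------------------------------------------------

# fast path: proportions as a (times x 3) matrix, no tibble construction
.turnover_prop_mat <- function(kappa, k_ab, k_b, b0, growth, times) {
  g_m <- growth$g_m
  g_l <- growth$g_l
  A0_H <- 1 / (g_m + kappa)
  iso_pi <- list(H = c(0, 0), M = c(1, 0), L = c(0, 1))
  init <- list(H = c(A0_H, b0), M = c(0, 0), L = c(0, 0))
  C12 <- exp(12 * g_m)
  amounts <- matrix(0, length(times), 3)
  s1 <- pmin(times, 0) + 12
  s2 <- pmax(times, 0)
  neg <- times < 0
  for (j in 1:3) {
    lab <- c("H", "M", "L")[j]
    A0 <- init[[lab]][1]; B0 <- init[[lab]][2]
    r1 <- .interval_AB(A0, B0, 1, g_m, iso_pi[[lab]][1], kappa, k_ab, k_b, 1, s1)
    e1 <- .interval_AB(A0, B0, 1, g_m, iso_pi[[lab]][1], kappa, k_ab, k_b, 1, 12)
    r2 <- .interval_AB(e1$A, e1$B, C12, g_l, iso_pi[[lab]][2], kappa, k_ab, k_b,
                       1, s2)
    amounts[, j] <- ifelse(neg, r1$A + r1$B, r2$A + r2$B)
  }
  amounts / rowSums(amounts)
}

# builds a fast residual-sum-of-squares function over the observed cells;
# the returned function takes (theta, growth) so shared growth rates can be
# sampled jointly
.make_rss_fn <- function(data, model) {
  times <- sort(unique(data$time))
  ti <- match(data$time, times)
  li <- match(data$label, c("H", "M", "L"))
  y <- data$proportion
  idx <- cbind(ti, li)
  if (model == "one_state") {
    function(th, growth) {
      pm <- .turnover_prop_mat(th[1], 0, 0, 0, growth, times)
      sum((y - pm[idx])^2)
    }
  } else {
    function(th, growth) {
      kappa <- th[1] + th[2]
      A0 <- 1 / (growth$g_m + kappa)
      b0 <- A0 * th[4] / (1 - th[4])
      pm <- .turnover_prop_mat(kappa, th[2], th[3], b0, growth, times)
      sum((y - pm[idx])^2)
    }
  }
}

.turnover_predict <- function(theta, model, growth, times) {
  params <- if (model == "one_state") {
    one_state_params(k_a = theta[["k_a"]])
  } else {
    b0f <- theta[["b0f"]]
    kappa <- theta[["k_a"]] + theta[["k_ab"]]
    A0 <- 1 / (growth$g_m + kappa)
    two_state_params(k_a = theta[["k_a"]], k_ab = theta[["k_ab"]],
                     k_b = theta[["k_b"]],
                     b0 = A0 * b0f / (1 - b0f))
  }
  solve_turnover(params, growth, times)
}

.turnover_rss <- function(theta, model, growth, data) {
  pred <- .turnover_predict(theta, model, growth, unique(data$time))
  pl <- tidyr::pivot_longer(pred[, c("time", "H", "M", "L")],
                            c("H", "M", "L"),
                            names_to = "label", values_to = "pred")
  dd <- dplyr::left_join(data, pl, by = c("time", "label"))
  sum((dd$proportion - dd$pred)^2)
}

.theta_names <- function(model) {
  if (model == "one_state") "k_a" else c("k_a", "k_ab", "k_b", "b0f")
}

.theta_bounds <- function(model) {
  if (model == "one_state") {
    list(lower = 0, upper = 5)
  } else {
    list(lower = c(0, 0, 0, 0), upper = c(5, 5, 5, 0.99))
  }
}

# maximum likelihood with the noise sd profiled out analytically:
# for additive normal error, sd_hat^2 = RSS/n and
# maxLL = -n/2 (log(2 pi sd_hat^2) + 1), so ML reduces to RSS minimisation.
.ml_turnover <- function(data, growth, model) {
  nm <- .theta_names(model)
  b <- .theta_bounds(model)
  starts <- if (model == "one_state") {
    list(0.005, 0.02, 0.1, 0.5)
  } else {
    list(c(0.05, 0.05, 0.01, 0.3), c(0.3, 0.1, 0.01, 0.5),
         c(0.02, 0.3, 0.05, 0.7), c(0.5, 0.5, 0.002, 0.2))
  }
  rss_fn <- .make_rss_fn(data, model)
  obj <- function(th) rss_fn(th, growth)
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      nlminb(st, obj, lower = b$lower, upper = b$upper),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$objective < best$objective)) {
      best <- fit
    }
  }
  n <- nrow(data)
  rss <- best$objective
  sd_hat <- sqrt(max(rss / n, 1e-300))
  ll <- -n / 2 * (log(2 * pi * sd_hat^2) + 1)
  theta <- setNames(best$par, nm)
  list(model = model, theta = theta, sd = sd_hat, logLik = ll, rss = rss, n = n)
}

#' Likelihood-ratio test between nested turnover models
#'
#' The one-state model is the two-state model with `k_ab = 0` and no bound
#' pool, so twice the difference in maximised log likelihood is referred to a
#' chi-square distribution. The statistic is clipped at zero (an optimiser
#' artifact can make the larger model appear worse). Degrees of freedom
#' default to 2 (transfer rate and bound-pool initial condition); the
#' chi-square reference is conservative at the `k_ab = 0` boundary.
#'
#' @param fit1 one-state fit (from [fit_turnover()] or an internal ML fit).
#' @param fit2 two-state fit on the same data.
#' @param df degrees of freedom.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
likelihood_ratio_test <- function(fit1, fit2, df = 2) {
  ll1 <- if (!is.null(fit1$logLik)) fit1$logLik else fit1$ml$logLik
  ll2 <- if (!is.null(fit2$logLik)) fit2$logLik else fit2$ml$logLik
  n1 <- if (!is.null(fit1$n)) fit1$n else fit1$ml$n
  n2 <- if (!is.null(fit2$n)) fit2$n else fit2$ml$n
  if (!identical(n1, n2)) abort("fits were not computed on the same data")
  stat <- max(0, 2 * (ll2 - ll1))
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df = df, lower.tail = FALSE))
}

#' Fit protein turnover from double-chase proportion data
#'
#' Fits the one-state and/or two-state turnover model to isotope-proportion
#' time courses by maximum likelihood (for model selection) and DE-MCMC (for
#' posteriors). When both models are fitted, the likelihood-ratio test at
#' `alpha = 0.05` decides the verdict: `two_state` iff p < 0.05.
#'
#' Time points 0 h and 24 h are excluded before fitting by default (they are
#' incoherent with the remaining chase time points in this design); the
#' exclusion is recorded in the returned `log`.
#'
#' Priors: half-normal(1) on rates, uniform on the bound fraction `b0f` in
#' `[0, 0.99]`, half-normal(0.2) on the noise sd.
#'
#' @param data tibble with columns `time`, `replicate`, `label` (H/M/L) and
#'   `proportion`.
#' @param growth a [growth_model()]; fixed constants here (growth rates are
#'   inferred separately from the unrelated-protein pool).
#' @param model_kind `"both"` (default), `"one_state"` or `"two_state"`.
#' @param exclude_times time points dropped before fitting.
#' @param n_iter MCMC iterations per chain.
#' @param mcmc sample posteriors (set `FALSE` for ML-only fits, e.g. in
#'   model-selection screens where only the likelihood-ratio test is
#'   needed).
#' @param seed optional seed.
#' @return object of class `turnover_fit`: `ml` fits, `posterior` draws,
#'   `rhat`, `lrt`, `verdict`, `log`.
#' @export
fit_turnover <- function(data, growth = growth_model(),
                         model_kind = c("both", "one_state", "two_state"),
                         exclude_times = c(0, 24), n_iter = 4000,
                         mcmc = TRUE, seed = NULL) {
  model_kind <- match.arg(model_kind)
  log_lines <- character(0)
  dropped <- intersect(unique(data$time), exclude_times)
  if (length(dropped)) {
    log_lines <- c(log_lines,
                   paste("excluded time points:",
                         paste(sort(dropped), collapse = ", "), "h"))
    data <- dplyr::filter(data, !.data$time %in% exclude_times)
  }
  if (dplyr::n_distinct(data$time) < 3) {
    abort("fewer than 3 usable time points; refusing to fit")
  }

  models <- switch(model_kind, both = c("one_state", "two_state"),
                   model_kind)
  ml <- lapply(setNames(models, models),
               function(m) .ml_turnover(data, growth, m))

  post <- list()
  rhat <- list()
  for (m in if (mcmc) models else character(0)) {
    nm <- c(.theta_names(m), "sd")
    b <- .theta_bounds(m)
    lower <- c(b$lower, 0)
    upper <- c(b$upper, Inf)
    rss_fn <- .make_rss_fn(data, m)
    lp <- function(th) {
      if (any(th < lower) || any(th[is.finite(upper)] > upper[is.finite(upper)])) {
        return(-Inf)
      }
      names(th) <- nm
      sdv <- th[["sd"]]
      if (sdv <= 0) return(-Inf)
      rss <- rss_fn(th[-length(th)], growth)
      llik <- -nrow(data) * log(sdv) - rss / (2 * sdv^2)
      # half-normal priors on rates and sd, uniform on b0f
      rates <- th[setdiff(nm, c("b0f", "sd"))]
      llik + sum(dnorm(rates, 0, 1, log = TRUE)) +
        dnorm(sdv, 0, 0.2, log = TRUE)
    }
    init <- function(n) {
      t(vapply(seq_len(n), function(i) {
        th <- c(ml[[m]]$theta * exp(rnorm(length(ml[[m]]$theta), 0, 0.2)) +
                  1e-4,
                max(ml[[m]]$sd, 1e-3) * exp(rnorm(1, 0, 0.2)))
        pmin(pmax(th, lower + 1e-6),
             ifelse(is.finite(upper), upper - 1e-6, th))
      }, numeric(length(nm))))
    }
    fit <- demc_sample(lp, init, n_iter = n_iter, seed = seed)
    colnames(fit$samples) <- nm
    post[[m]] <- fit$samples
    rhat[[m]] <- setNames(fit$rhat, nm)
  }

  lrt <- NULL
  verdict <- models[1]
  if (model_kind == "both") {
    lrt <- likelihood_ratio_test(ml$one_state, ml$two_state)
    verdict <- if (lrt$p_value < 0.05) "two_state" else "one_state"
  }
  structure(
    list(ml = ml, posterior = post, rhat = rhat, lrt = lrt,
         verdict = verdict, growth = growth, log = log_lines,
         n_obs = nrow(data)),
    class = "turnover_fit"
  )
}

#' @export
print.turnover_fit <- function(x, ...) {
  cat("Turnover fit (", x$n_obs, " observations)\n", sep = "")
  for (m in names(x$ml)) {
    cat("  ", m, ": logLik ", signif(x$ml[[m]]$logLik, 6), "  ",
        paste(names(x$ml[[m]]$theta),
              signif(x$ml[[m]]$theta, 3), sep = "=", collapse = " "),
        "\n", sep = "")
  }
  if (!is.null(x$lrt)) {
    cat("  LRT p =", signif(x$lrt$p_value, 3), "-> verdict:", x$verdict, "\n")
  }
  invisible(x)
}

#' @export
tidy.turnover_fit <- function(x, ...) {
  purrr::map_dfr(names(x$posterior), function(m) {
    s <- x$posterior[[m]]
    tibble(model = m, term = colnames(s),
           estimate = apply(s, 2, median),
           conf.low = apply(s, 2, quantile, 0.05),
           conf.high = apply(s, 2, quantile, 0.95),
           rhat = as.numeric(x$rhat[[m]]))
  })
}

#' @export
glance.turnover_fit <- function(x, ...) {
  tibble(verdict = x$verdict,
         lrt_p = if (is.null(x$lrt)) NA_real_ else x$lrt$p_value,
         n_obs = x$n_obs,
         converged = all(unlist(x$rhat) < 1.05, na.rm = TRUE))
}

# ---- unrelated protein pool and growth inference ----------------------------

#' Select unrelated (stable, abundant) proteins for growth-rate inference
#'
#' Filters a global-turnover dataset for proteins whose H-pool loss is
#' dominated by dilution through cell division rather than degradation:
#' (1) replicate variance of the H proportion below the 0.9 quantile;
#' (2) replicate-mean H proportion at 18 h strictly between the 0.925 and
#' 0.99 quantiles; (3) at 21 h strictly between the 0.95 and 0.99 quantiles;
#' (4) not on the exclusion list (ribosomal proteins, assembly factors,
#' known complex members). All quantiles are empirical over the proteins in
#' `data`.
#'
#' @param data tibble with columns `protein`, `time`, `replicate`, `label`,
#'   `proportion` containing at least times 18 and 21 h.
#' @param exclude character vector of protein ids to drop regardless.
#' @return character vector of selected protein ids.
#' @export
select_unrelated_proteins <- function(data, exclude = character()) {
  hd <- dplyr::filter(data, .data$label == "H")
  if (!all(c(18, 21) %in% hd$time)) {
    abort("data must contain H proportions at 18 h and 21 h")
  }
  repvar <- hd %>%
    group_by(.data$protein, .data$time) %>%
    summarise(v = var(.data$proportion), .groups = "drop") %>%
    group_by(.data$protein) %>%
    summarise(v = mean(.data$v, na.rm = TRUE))
  prop_at <- function(tt) {
    hd %>%
      filter(.data$time == tt) %>%
      group_by(.data$protein) %>%
      summarise(m = mean(.data$proportion), .groups = "drop")
  }
  p18 <- prop_at(18)
  p21 <- prop_at(21)
  keep_var <- repvar$protein[repvar$v < quantile(repvar$v, 0.9)]
  w18 <- quantile(p18$m, c(0.925, 0.99))
  keep18 <- p18$protein[p18$m > w18[1] & p18$m < w18[2]]
  w21 <- quantile(p21$m, c(0.95, 0.99))
  keep21 <- p21$protein[p21$m > w21[1] & p21$m < w21[2]]
  setdiff(Reduce(intersect, list(keep_var, keep18, keep21)), exclude)
}

#' Infer shared growth rates from an unrelated-protein pool
#'
#' Joint one-state model over the pool: per-protein degradation rates, one
#' shared doubling time per chase, one shared noise sd; posterior medians of
#' `t_m` and `t_l` are reported.
#'
#' Shifting both growth rates by a constant and all pool degradation rates
#' by its negative leaves every isotope proportion unchanged, so growth is
#' identified only through the stable-pool assumption: the filtered pool's
#' H-pool decline is dominated by dilution through cell division, not by
#' degradation. That assumption is encoded as a tight half-normal prior on
#' the pool degradation rates (`pool_rate_prior_sd`, default 0.005 per hour,
#' i.e. half-lives of hundreds of hours).
#'
#' @param data tibble (`protein`, `time`, `replicate`, `label`, `proportion`)
#'   restricted to the unrelated pool.
#' @param min_proteins minimum pool size.
#' @param exclude_times time points dropped before fitting.
#' @param n_iter MCMC iterations per chain.
#' @param seed optional seed.
#' @return object of class `growth_fit` with `samples`, `t_m`, `t_l`
#'   (medians), `rhat`.
#' @export
#' @param pool_rate_prior_sd half-normal prior scale (1/h) for the pool
#'   degradation rates.
infer_growth_rates <- function(data, min_proteins = 10,
                               exclude_times = c(0, 24),
                               n_iter = 6000, pool_rate_prior_sd = 0.005,
                               seed = NULL) {
  data <- dplyr::filter(data, !.data$time %in% exclude_times)
  prots <- sort(unique(data$protein))
  if (length(prots) < min_proteins) {
    abort(paste("need at least", min_proteins, "unrelated proteins"))
  }
  dl <- lapply(setNames(prots, prots),
               function(p) dplyr::filter(data, .data$protein == p))
  rss_fns <- lapply(dl, .make_rss_fn, model = "one_state")
  nn <- vapply(dl, nrow, integer(1))
  d <- length(prots) + 3 # t_m, t_l, k_a[...], sd

  # profile-likelihood start: the growth/degradation ridge is stiff, so the
  # chains are started at the maximum of the profiled surface
  prof_ka <- function(t_m, t_l) {
    gr <- growth_model(t_m, t_l)
    vapply(rss_fns, function(fn) {
      stats::optimize(function(k) fn(k, gr), c(0, 1), tol = 1e-9)$minimum
    }, numeric(1))
  }
  prof_rss <- function(th) {
    gr <- growth_model(th[1], th[2])
    ka <- prof_ka(th[1], th[2])
    sum(vapply(seq_along(prots),
               function(i) rss_fns[[i]](ka[i], gr), numeric(1)))
  }
  ml <- optim(c(45, 35), prof_rss, method = "Nelder-Mead",
              control = list(maxit = 200, reltol = 1e-10))
  ka_ml <- prof_ka(ml$par[1], ml$par[2])
  sd_ml <- sqrt(ml$value / sum(nn))
  start <- c(ml$par, ka_ml, max(sd_ml, 1e-4))
  lp <- function(th) {
    t_m <- th[1]; t_l <- th[2]; sdv <- th[length(th)]
    ka <- th[3:(length(th) - 1)]
    if (t_m < 5 || t_m > 200 || t_l < 5 || t_l > 200 ||
        any(ka < 0) || sdv <= 0) {
      return(-Inf)
    }
    gr <- growth_model(t_m, t_l)
    ll <- 0
    for (i in seq_along(prots)) {
      rss <- rss_fns[[i]](ka[i], gr)
      ll <- ll - nn[i] * log(sdv) - rss / (2 * sdv^2)
    }
    ll + sum(dnorm(ka, 0, pool_rate_prior_sd, log = TRUE)) +
      dnorm(sdv, 0, 0.2, log = TRUE)
  }
  init <- function(n) {
    t(vapply(seq_len(n), function(i) {
      pmax(start * exp(rnorm(d, 0, 0.02)), 1e-5)
    }, numeric(d)))
  }
  fit <- am_sample(lp, init, n_iter = n_iter, seed = seed,
                   init_scale = pmax(0.05 * start, 1e-4))
  colnames(fit$samples) <- c("t_m", "t_l", paste0("k_a.", prots), "sd")
  structure(
    list(samples = fit$samples,
         t_m = median(fit$samples[, "t_m"]),
         t_l = median(fit$samples[, "t_l"]),
         rhat = setNames(fit$rhat, colnames(fit$samples)),
         proteins = prots),
    class = "growth_fit"
  )
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("Shared growth-rate fit over", length(x$proteins), "proteins\n")
  cat("  t_m =", signif(x$t_m, 4), "h;  t_l =", signif(x$t_l, 4), "h\n")
  invisible(x)
}

# ---- exponential decay (rRNA-depletion time courses) ------------------------

#' Fit an exponential decay to percentage-remaining data
#'
#' Model `p(t) = 100 exp(-k t)` for the percentage of the t = 0 signal
#' remaining at time `t`; the decay rate has a uniform prior on `[0, max_k]`
#' and additive normal observation noise. The half-life is `log(2)/k` per
#' posterior draw (so `t_half * k = log(2)` exactly for every draw).
#'
#' @param data tibble with columns `time` (h) and `value` (percent of t = 0).
#' @param max_k upper bound of the uniform prior on `k` (1/h).
#' @param sd_prior_scale half-normal scale for the noise sd (percent units).
#' @param n_iter MCMC iterations per chain.
#' @param seed optional seed.
#' @return object of class `decay_fit` with `samples` (k, t_half, sd),
#'   `k` and `t_half` posterior medians, and `rhat`.
#' @export
fit_decay <- function(data, max_k = 2, sd_prior_scale = 10,
                      n_iter = 3000, seed = NULL) {
  if (all(data$value == 0)) abort("all values are zero; nothing to fit")
  if (!any(data$time == 0)) {
    warn("no t = 0 observation; values are assumed to be percent of baseline")
  }
  lp <- function(th) {
    k <- th[1]; sdv <- th[2]
    if (k < 0 || k > max_k || sdv <= 0) return(-Inf)
    pred <- 100 * exp(-k * data$time)
    sum(dnorm(data$value, pred, sdv, log = TRUE)) +
      dnorm(sdv, 0, sd_prior_scale, log = TRUE)
  }
  init <- function(n) {
    cbind(runif(n, 1e-3, max_k / 2), runif(n, 1, 15))
  }
  fit <- demc_sample(lp, init, n_iter = n_iter, seed = seed)
  k <- fit$samples[, 1]
  samples <- cbind(k = k, t_half = log(2) / k, sd = fit$samples[, 2])
  structure(
    list(samples = samples, k = median(k), t_half = log(2) / median(k),
         rhat = setNames(fit$rhat, c("k", "sd"))),
    class = "decay_fit"
  )
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("Exponential decay fit: k =", signif(x$k, 4), "per h;  t1/2 =",
      signif(x$t_half, 4), "h\n")
  invisible(x)
}

#' @export
tidy.decay_fit <- function(x, ...) {
  s <- x$samples
  tibble(term = colnames(s),
         estimate = apply(s, 2, median),
         conf.low = apply(s, 2, quantile, 0.05),
         conf.high = apply(s, 2, quantile, 0.95))
}

#' @export
glance.decay_fit <- function(x, ...) {
  tibble(k = x$k, t_half = x$t_half,
         converged = all(x$rhat < 1.05, na.rm = TRUE))
}

#' @export
autoplot.decay_fit <- function(object, data = NULL, ...) {
  tt <- seq(0, max(if (is.null(data)) 48 else data$time), length.out = 100)
  pred <- purrr::map_dfr(seq_along(tt), function(i) {
    v <- 100 * exp(-object$samples[, "k"] * tt[i])
    tibble(time = tt[i], median = median(v),
           lo = quantile(v, 0.05), hi = quantile(v, 0.95))
  })
  p <- ggplot2::ggplot(pred, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median)) +
    ggplot2::labs(x = "time after transcription block (h)",
                  y = "% of initial abundance")
  if (!is.null(data)) {
    p <- p + ggplot2::geom_point(data = data,
                                 ggplot2::aes(y = .data$value))
  }
  p
}
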