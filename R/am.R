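#' Adaptive Metropolis sampler
#'
#' Random-walk Metropolis with a multivariate normal proposal whose
#' covariance adapts to the running empirical covariance of the chain
#' (scaled by `2.38^2/d`) and whose global scale is tuned towards an
#' acceptance rate of 0.234 by Robbins-Monro updates during burn-in. Used
#' for the higher-dimensional posteriors (flux and kinetic models), where it
#' reaches calibrated posteriors within far fewer iterations than
#' difference-based ensemble proposals; the convergence contract (r-hat) is
#' the same.
#'
#' @inheritParams demc_sample
#' @param init_scale initial diagonal proposal scales (numeric vector of
#'   length `d` or scalar); defaults to `0.1 x |init|` + small floor.
#' @return object of class `demc_fit` (same structure as [demc_sample()]).
#' @export
am_sample <- function(log_post, init, n_iter = 10000, n_chains = 3,
                      thin = 10, burn_frac = 0.5, seed = NULL,
                      init_scale = NULL) {
  if (n_iter < 20 * thin) abort("n_iter must be at least 20 x thin")
  if (!is.null(seed)) set.seed(seed)
  if (is.function(init)) init <- init(n_chains)
  init <- as.matrix(init)
  if (nrow(init) < n_chains) {
    init <- init[rep_len(seq_len(nrow(init)), n_chains), , drop = FALSE]
  }
  d <- ncol(init)
  sc0 <- init_scale %||% pmax(0.1 * abs(init[1, ]), 1e-3)
  if (length(sc0) == 1) sc0 <- rep(sc0, d)
  n_keep <- floor(n_iter / thin)
  n_adapt <- floor(n_iter * burn_frac)
  chains <- vector("list", n_chains)
  keep_lp <- vector("list", n_chains)
  acc_tot <- 0L
  prop_tot <- 0L

  for (k in seq_len(n_chains)) {
    x <- init[k, ]
    lp <- log_post(x)
    tries <- 0
    while (!is.finite(lp) && tries < 200) {
      x <- init[k, ] * (1 + rnorm(d, 0, 0.05))
      lp <- log_post(x)
      tries <- tries + 1
    }
    if (!is.finite(lp)) abort("no finite-posterior starting state found")
    mu <- x
    cv <- diag(sc0^2, d)
    n_cov <- 1
    lambda <- 1
    chol_c <- NULL
    keep <- matrix(NA_real_, n_keep, d)
    klp <- numeric(n_keep)
    ki <- 0L
    acc_win <- 0
    for (it in seq_len(n_iter)) {
      use_emp <- it > max(2 * d, 200) && !is.null(chol_c)
      step <- if (use_emp) {
        lambda * sqrt(2.38^2 / d) * drop(rnorm(d) %*% chol_c)
      } else {
        lambda * sqrt(2.38^2 / d) * rnorm(d) * sc0
      }
      xp <- x + step
      lpp <- log_post(xp)
      prop_tot <- prop_tot + 1L
      if (is.finite(lpp) && log(runif(1)) < lpp - lp) {
        x <- xp
        lp <- lpp
        acc_tot <- acc_tot + 1L
        acc_win <- acc_win + 1
      }
      # recursive mean/covariance update
      n_cov <- n_cov + 1
      dx <- x - mu
      mu <- mu + dx / n_cov
      cv <- cv * (n_cov - 2) / (n_cov - 1) + tcrossprod(dx) / n_cov
      if (it %% 100 == 0) {
        if (it <= n_adapt) {
          lambda <- lambda * exp((acc_win / 100 - 0.234) * 0.5)
          lambda <- min(max(lambda, 1e-3), 1e3)
        }
        acc_win <- 0
        if (it >= max(2 * d, 200)) {
          chol_c <- tryCatch(
            chol(cv + diag(1e-10 + 1e-8 * mean(diag(cv)), d)),
            error = function(e) NULL)
        }
      }
      if (it %% thin == 0) {
        ki <- ki + 1L
        keep[ki, ] <- x
        klp[ki] <- lp
      }
    }
    chains[[k]] <- keep
    keep_lp[[k]] <- klp
  }

  drop_n <- floor(n_keep * burn_frac)
  sel <- seq.int(drop_n + 1L, n_keep)
  chains <- lapply(chains, function(m) m[sel, , drop = FALSE])
  samples <- do.call(rbind, chains)
  lps <- unlist(lapply(keep_lp, function(v) v[sel]), use.names = FALSE)
  rhat <- rep(NA_real_, d)
  if (length(sel) >= 10 && n_chains >= 2) {
    rhat <- tryCatch({
      ml <- coda::mcmc.list(lapply(chains, coda::mcmc))
      gd <- coda::gelman.diag(ml, autoburnin = FALSE, multivariate = FALSE)
      as.numeric(gd$psrf[, 1])
    }, error = function(e) rep(NA_real_, d))
  }
  structure(
    list(samples = samples, chains = chains, log_post = lps,
         acceptance = acc_tot / max(1L, prop_tot), rhat = rhat,
         n_iter = n_iter, n_chains = n_chains, thin = thin),
    class = "demc_fit"
  )
}
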