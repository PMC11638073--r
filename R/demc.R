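#' Differential-evolution MCMC with snooker updates
#'
#' Ensemble sampler for posterior inference in the turnover, flux and kinetic
#' models. Proposals are differences of states drawn from an archive `Z` of
#' past states (the "Z with snooker" variant of differential-evolution MCMC):
#' with probability `snooker_prob` a snooker move along the line towards a
#' random archive member is used, otherwise the classic two-member difference
#' move with scaling `gamma = 2.38 / sqrt(2 d)`, occasionally reset to 1 to
#' allow mode jumps. The scaling is jittered multiplicatively by
#' `U(-noise, noise)` each step.
#'
#' The target is supplied as an (unnormalised) log-posterior; parameters are
#' sampled on their natural scale and the target should return `-Inf` outside
#' its support.
#'
#' @param log_post function taking a numeric parameter vector, returning the
#'   unnormalised log posterior density (may be `-Inf`).
#' @param init numeric matrix (`n_chains` x `d`) of starting states, or a
#'   function `(n)` drawing `n` random starting states as such a matrix.
#' @param init_archive overdispersed states seeding the past-state archive
#'   `Z` (matrix or function `(n)`); defaults to `init` draws. The archive
#'   must start overdispersed relative to the posterior (e.g. drawn from the
#'   prior) for difference proposals to traverse the target quickly; chain
#'   starting points may sit near the mode.
#' @param n_iter total iterations per chain (archive updates), including
#'   burn-in.
#' @param n_chains number of interacting chains (default 3, as in the
#'   gradient-fraction analyses).
#' @param thin keep every `thin`-th state.
#' @param burn_frac fraction of iterations discarded as burn-in.
#' @param snooker_prob probability of a snooker update.
#' @param gamma_one_prob probability of resetting the scaling factor to 1.
#' @param noise multiplicative jitter on the scaling factor.
#' @param seed optional integer seed for reproducibility.
#'
#' @return object of class `demc_fit`: list with `samples` (matrix of
#'   post-burn-in draws, chains interleaved), `chains` (list of per-chain
#'   matrices), `log_post` (vector of log posteriors for `samples`),
#'   `acceptance` rate, and `rhat` (Gelman-Rubin potential scale reduction per
#'   parameter, from [coda::gelman.diag()]).
#' @export
demc_sample <- function(log_post, init, n_iter = 10000, n_chains = 3,
                        thin = 10, burn_frac = 0.5, snooker_prob = 0.001,
                        gamma_one_prob = 0.1, noise = 0.2, seed = NULL,
                        init_archive = NULL) {
  if (n_iter < 20 * thin) abort("n_iter must be at least 20 x thin")
  if (!is.null(seed)) set.seed(seed)
  init_fn <- if (is.function(init)) init else NULL
  if (is.function(init)) init <- init(n_chains)
  init <- as.matrix(init)
  if (nrow(init) < n_chains) {
    init <- init[rep_len(seq_len(nrow(init)), n_chains), , drop = FALSE]
  }
  d <- ncol(init)
  x <- init
  lp <- apply(x, 1, log_post)
  if (all(!is.finite(lp))) {
    abort("all starting states have zero posterior density")
  }
  # replace non-finite starts by the best finite one, jittered
  bad <- !is.finite(lp)
  if (any(bad)) {
    best <- which.max(lp)
    for (i in which(bad)) {
      repeat {
        cand <- x[best, ] * (1 + rnorm(d, 0, 0.05))
        lc <- log_post(cand)
        if (is.finite(lc)) {
          x[i, ] <- cand
          lp[i] <- lc
          break
        }
      }
    }
  }

  gamma0 <- 2.38 / sqrt(2 * d)
  # archive of past states, seeded with an overdispersed population
  n0 <- max(10 * d, 3 * n_chains)
  Z0 <- if (is.null(init_archive)) {
    if (!is.null(init_fn)) init_fn(n0) else init[rep_len(seq_len(nrow(init)),
                                                         n0), , drop = FALSE]
  } else if (is.function(init_archive)) {
    init_archive(n0)
  } else {
    as.matrix(init_archive)
  }
  z_cap <- nrow(Z0) + n_chains * (ceiling(n_iter / 10) + 2)
  Z <- matrix(NA_real_, z_cap, d)
  Z[seq_len(nrow(Z0)), ] <- Z0
  nz <- nrow(Z0)

  keep <- vector("list", n_chains)
  keep_lp <- vector("list", n_chains)
  n_keep <- floor(n_iter / thin)
  for (k in seq_len(n_chains)) {
    keep[[k]] <- matrix(NA_real_, n_keep, d)
    keep_lp[[k]] <- numeric(n_keep)
  }
  n_acc <- 0L
  n_prop <- 0L
  ki <- 0L

  for (it in seq_len(n_iter)) {
    for (k in seq_len(n_chains)) {
      if (runif(1) < snooker_prob && nz >= 3) {
        # snooker update: move along the line x -> z, using projected difference
        idx <- sample.int(nz, 3)
        z <- Z[idx[1], ]
        dvec <- x[k, ] - z
        nrm2 <- sum(dvec * dvec)
        if (nrm2 < .Machine$double.eps) next
        z1 <- Z[idx[2], ]
        z2 <- Z[idx[3], ]
        proj <- function(v) sum(v * dvec) / nrm2 * dvec
        gs <- runif(1, 1.2, 2.2) # standard snooker gamma ~ U(1.2, 2.2)
        xp <- x[k, ] + gs * (proj(z1) - proj(z2))
        dp <- xp - z
        # Jacobian correction (d-1 power of length ratio)
        lr <- 0.5 * (d - 1) * (log(sum(dp * dp) + 1e-300) - log(nrm2))
        lpp <- log_post(xp)
        n_prop <- n_prop + 1L
        if (is.finite(lpp) && log(runif(1)) < lpp - lp[k] + lr) {
          x[k, ] <- xp
          lp[k] <- lpp
          n_acc <- n_acc + 1L
        }
      } else {
        idx <- sample.int(nz, 2)
        g <- if (runif(1) < gamma_one_prob) 1 else gamma0
        g <- g * (1 + runif(1, -noise, noise))
        xp <- x[k, ] + g * (Z[idx[1], ] - Z[idx[2], ])
        lpp <- log_post(xp)
        n_prop <- n_prop + 1L
        if (is.finite(lpp) && log(runif(1)) < lpp - lp[k]) {
          x[k, ] <- xp
          lp[k] <- lpp
          n_acc <- n_acc + 1L
        }
      }
    }
    # append current states to archive every 10th iteration (K=10)
    if (it %% 10 == 0) {
      Z[nz + seq_len(n_chains), ] <- x
      nz <- nz + n_chains
    }
    if (it %% thin == 0) {
      ki <- ki + 1L
      for (k in seq_len(n_chains)) {
        keep[[k]][ki, ] <- x[k, ]
        keep_lp[[k]][ki] <- lp[k]
      }
    }
  }

  drop_n <- floor(ki * burn_frac)
  sel <- seq.int(drop_n + 1L, ki)
  chains <- lapply(keep, function(m) m[sel, , drop = FALSE])
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
         acceptance = n_acc / max(1L, n_prop), rhat = rhat,
         n_iter = n_iter, n_chains = n_chains, thin = thin),
    class = "demc_fit"
  )
}

#' @export
print.demc_fit <- function(x, ...) {
  cat("DE-MCMC(zs) fit:", nrow(x$samples), "draws,",
      ncol(x$samples), "parameters\n")
  cat("  acceptance rate:", signif(x$acceptance, 3),
      " max r-hat:", signif(max(x$rhat, na.rm = TRUE), 4), "\n")
  invisible(x)
}

#' Convergence check for a DE-MCMC fit
#'
#' A fit is declared converged when every parameter's potential scale
#' reduction factor is below `threshold` (1.05 by default).
#'
#' @param fit a `demc_fit`.
#' @param threshold r-hat threshold.
#' @return logical scalar (`NA` if r-hat could not be computed).
#' @export
demc_converged <- function(fit, threshold = 1.05) {
  if (all(is.na(fit$rhat))) return(NA)
  all(fit$rhat < threshold, na.rm = TRUE)
}
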