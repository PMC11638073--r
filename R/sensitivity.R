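# Local sensitivity of the terminal (mature-subunit) abundance to each free
# kinetic rate: one parameter at a time is multiplied by a factor x spanning
# 1e-4..1e4 while the eliminated (dependent) parameters stay at their
# baseline values, the system is simulated to 48 h, and the terminal
# abundance is compared to the unperturbed baseline per posterior particle.

#' Terminal-product abundance at the sensitivity horizon
#'
#' Simulates the full total-abundance model (with supplies) for one posterior
#' particle and returns the terminal component's abundance at `t_end`. For a
#' steady-state-consistent particle this equals the steady terminal
#' abundance.
#'
#' @param model a `kinetic_model`.
#' @param particle list with `free` (named free rates) and `q` (initial/steady
#'   abundances per component), e.g. one row of a `kinetic_fit`'s samples via
#'   [particle_from_sample()].
#' @param t_end horizon (h), default 48.
#' @return nonnegative scalar, or `NA` if integration fails (particle is
#'   skipped and logged by [scan_parameter()]).
#' @export
baseline_abundance <- function(model, particle, t_end = 48) {
  dep <- tryCatch(eliminate_steady_state(model, particle$q, particle$free),
                  error = function(e) NULL)
  if (is.null(dep)) return(NA_real_)
  .terminal_at(model, dep, particle$q, t_end)
}

.terminal_at <- function(model, rates, q, t_end) {
  out <- tryCatch(
    simulate_total(model, rates, q, c(0, t_end)),
    warning = function(w) NULL, error = function(e) NULL)
  if (is.null(out)) return(NA_real_)
  unname(out[2, model$terminal])
}

#' Extract a particle from a kinetic-fit sample row
#'
#' @param fit a `kinetic_fit` (or its `model` plus a named numeric vector).
#' @param i row index of the posterior draw.
#' @return list with `free` and `q` suitable for [baseline_abundance()] and
#'   [scan_parameter()].
#' @export
particle_from_sample <- function(fit, i) {
  s <- fit$samples[i, ]
  model <- fit$model
  list(free = s[model$free_names],
       q = setNames(s[model$ic_names], model$components$id))
}

#' Local sensitivity scan of one kinetic rate
#'
#' For each posterior particle the chosen free rate is multiplied by each
#' factor `x` of a log-spaced grid (dependent parameters are kept at their
#' baseline values; perturbing a dependent parameter directly is not allowed
#' since they are recomputed quantities), the model is simulated to `t_end`,
#' and the terminal-abundance fold change relative to the particle's baseline
#' is recorded; the median over particles is reported per `x`. The fold
#' change at `x = 1` is exactly 1.
#'
#' @param model a `kinetic_model`.
#' @param particles list of particles (see [particle_from_sample()]).
#' @param parameter name of a free rate (`k.<single>`, `on.<module>`,
#'   `off.<module>`).
#' @param x_grid multipliers; default 17 log-spaced points over
#'   `[1e-4, 1e4]`.
#' @param t_end horizon (h).
#' @return object of class `sensitivity_scan`: tibble `parameter`, `x`,
#'   `fold_change` (median over particles), with attributes `n_particles`
#'   and `n_excluded` (zero-baseline or failed integrations).
#' @export
scan_parameter <- function(model, particles, parameter,
                           x_grid = 10^seq(-4, 4, length.out = 17),
                           t_end = 48) {
  if (!parameter %in% model$free_names) {
    abort(paste0("'", parameter,
                 "' is not a free rate (dependent parameters are recomputed ",
                 "and cannot be perturbed)"))
  }
  fc <- matrix(NA_real_, length(particles), length(x_grid))
  excluded <- 0L
  for (p in seq_along(particles)) {
    part <- particles[[p]]
    dep <- tryCatch(eliminate_steady_state(model, part$q, part$free),
                    error = function(e) NULL)
    if (is.null(dep)) {
      excluded <- excluded + 1L
      next
    }
    base <- .terminal_at(model, dep, part$q, t_end)
    if (!is.finite(base) || base <= 0) {
      excluded <- excluded + 1L
      next
    }
    for (xi in seq_along(x_grid)) {
      x <- x_grid[xi]
      if (x == 1) {
        fc[p, xi] <- 1
        next
      }
      free2 <- part$free
      free2[parameter] <- free2[parameter] * x
      fr2 <- .split_free(model, free2)
      rates2 <- list(k = c(fr2$k_single,
                           dep$k[-seq_along(model$singles)]),
                     sup = dep$sup, on = unname(fr2$on),
                     off = unname(fr2$off))
      pert <- .terminal_at(model, rates2, part$q, t_end)
      fc[p, xi] <- if (is.finite(pert)) pert / base else NA_real_
    }
  }
  out <- tibble(parameter = parameter, x = x_grid,
                fold_change = apply(fc, 2, median, na.rm = TRUE))
  structure(out, class = c("sensitivity_scan", class(out)),
            n_particles = length(particles), n_excluded = excluded)
}

#' Classify kinetic rates from sensitivity scans
#'
#' A rate is `enhancing` when its maximal median fold change exceeds
#' `1 + threshold`, `inhibiting` when its minimal median fold change falls
#' below `1 - threshold`, `sensitive_both` when both, and `nonsensitive`
#' otherwise.
#'
#' @param results tibble binding one or more [scan_parameter()] outputs
#'   (`parameter`, `x`, `fold_change`).
#' @param threshold classification threshold (default 0.2).
#' @return tibble `parameter`, `max_fc`, `min_fc`, `class`.
#' @export
classify_rates <- function(results, threshold = 0.2) {
  results %>%
    group_by(.data$parameter) %>%
    summarise(max_fc = max(.data$fold_change, na.rm = TRUE),
              min_fc = min(.data$fold_change, na.rm = TRUE),
              .groups = "drop") %>%
    mutate(class = case_when(
      .data$max_fc > 1 + threshold & .data$min_fc < 1 - threshold ~
        "sensitive_both",
      .data$max_fc > 1 + threshold ~ "enhancing",
      .data$min_fc < 1 - threshold ~ "inhibiting",
      TRUE ~ "nonsensitive"))
}

#' Order sensitivity profiles by hierarchical clustering
#'
#' Ward-linkage clustering (Euclidean distance) of log2 fold-change profiles
#' across the multiplier grid, for display ordering only.
#'
#' @param results long tibble `parameter`, `x`, `fold_change`.
#' @return character vector of parameter names in dendrogram order.
#' @export
order_sensitivity_profiles <- function(results) {
  wide <- results %>%
    mutate(l2 = log2(pmax(.data$fold_change, 1e-6))) %>%
    select("parameter", "x", "l2") %>%
    tidyr::pivot_wider(names_from = "x", values_from = "l2")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$parameter
  if (nrow(m) < 3) return(wide$parameter)
  hc <- stats::hclust(stats::dist(m), method = "ward.D")
  wide$parameter[hc$order]
}

#' @export
autoplot.sensitivity_scan <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$fold_change)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "rate multiplier x",
                  y = "terminal abundance fold change (median)",
                  title = unique(object$parameter))
}
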