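# Shared fixtures and independent oracles, built in code.

suppressPackageStartupMessages({
  library(dplyr)
  library(tibble)
})

mtssu_pathway <- load_pathway(mitoflux_example("mtssu_pathway.yaml"))
mtssu_contacts <- load_contact_matrix(
  mitoflux_example("contact_mtssu_synthetic.tsv"))

# minimal A + B -> AB pathway written to a temp file once
toy_pathway_file <- local({
  f <- tempfile(fileext = ".yaml")
  writeLines(c(
    "subunit: mtSSU",
    "terminal: AB",
    "species:",
    "  - {id: A, kind: protein}",
    "  - {id: B, kind: protein}",
    "modules:",
    "  - {id: AB}",
    "reactions:",
    "  - {product: AB, reactants: [A, B]}"), f)
  f
})
toy_pathway <- load_pathway(toy_pathway_file)

# a three-level toy pathway used for reduced-scale kinetic fits
toy3_pathway <- local({
  f <- tempfile(fileext = ".yaml")
  writeLines(c(
    "subunit: mtSSU",
    "terminal: ABC",
    "species:",
    "  - {id: A, kind: protein}",
    "  - {id: B, kind: protein}",
    "  - {id: C, kind: protein}",
    "modules:",
    "  - {id: AB}",
    "  - {id: ABC}",
    "reactions:",
    "  - {product: AB, reactants: [A, B]}",
    "  - {product: ABC, reactants: [AB, C]}"), f)
  load_pathway(f)
})

# independent brute-force heterogeneity oracle: literal loops over the
# definition (unordered distinct pairs; fractions without a valid pair drop
# out of the outer mean)
oracle_heterogeneity <- function(members, profiles, N0, N) {
  terms <- c()
  for (n in N0:N) {
    vals <- profiles[profiles$fraction == n &
                       profiles$protein %in% members, ]
    vals <- vals[!is.na(vals$flux) & !is.na(vals$q), ]
    if (nrow(vals) < 2) next
    df2 <- c(); dq2 <- c()
    for (i in seq_len(nrow(vals) - 1)) {
      for (j in (i + 1):nrow(vals)) {
        df2 <- c(df2, (vals$flux[i] - vals$flux[j])^2)
        dq2 <- c(dq2, (vals$q[i] - vals$q[j])^2)
      }
    }
    terms <- c(terms, 0.5 * (mean(df2) + mean(dq2)))
  }
  if (!length(terms)) NA_real_ else mean(terms)
}

# fine-step explicit-Euler oracle for the turnover system (piecewise in the
# two chase intervals, production switching per isotope)
oracle_turnover_euler <- function(k_a, k_ab, k_b, growth, times, dt = 1e-4) {
  kap <- k_a + k_ab
  A0 <- 1 / (growth$g_m + kap)
  B0 <- if (k_ab > 0) k_ab * A0 / (growth$g_m + k_b) else 0
  state <- c(A0, B0, 0, 0, 0, 0) # (A,B) x (H,M,L)
  out <- matrix(NA_real_, length(times), 3)
  tt <- -12
  ti <- order(times)
  for (idx in ti) {
    target <- times[idx]
    while (tt < target - 1e-12) {
      h <- min(dt, target - tt)
      C <- growth_factor(growth, tt)
      piM <- as.numeric(tt < 0)
      piL <- as.numeric(tt >= 0)
      d <- c(-kap * state[1], k_ab * state[1] - k_b * state[2],
             piM * C - kap * state[3], k_ab * state[3] - k_b * state[4],
             piL * C - kap * state[5], k_ab * state[5] - k_b * state[6])
      state <- state + h * d
      tt <- tt + h
    }
    tot <- sum(state)
    out[idx, ] <- c(state[1] + state[2], state[3] + state[4],
                    state[5] + state[6]) / tot
  }
  colnames(out) <- c("H", "M", "L")
  out
}

# simple normalized toy grid builder (stage "standard")
toy_grid <- function(df) {
  mitoflux:::.set_stage(as_tibble(df), "standard")
}
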