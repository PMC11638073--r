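# Contact-constrained cluster analysis of fluxes and steady-state abundances.
#
# A candidate assembly cluster is scored by its heterogeneity H: the mean,
# over the gradient fractions from the cluster's earliest assigned fraction
# N0 up to the mature-subunit fraction N, of half the sum of the mean
# pairwise squared flux difference and the mean pairwise squared abundance
# difference among its members. Pairwise means run over unordered distinct
# member pairs; a pair contributes in a fraction only when both members have
# a defined flux and abundance there (robust detection).

#' Cluster heterogeneity
#'
#' @param members character vector of species ids (>= 2).
#' @param profiles tibble with columns `protein`, `fraction`, `flux`, `q`
#'   (per-fraction flux and steady-state abundance; rows absent or NA where a
#'   protein is not robustly detected).
#' @param N0 earliest fraction in which the cluster is assigned.
#' @param N last fraction (7 for mtSSU, 8 for mtLSU).
#' @return heterogeneity H (dimensionless); NA when no fraction has a valid
#'   member pair.
#' @export
cluster_heterogeneity <- function(members, profiles, N0, N) {
  if (length(members) < 2) abort("a cluster needs at least 2 members")
  terms <- vapply(N0:N, function(n) {
    sub <- profiles[profiles$protein %in% members & profiles$fraction == n &
                      !is.na(profiles$flux) & !is.na(profiles$q), ,
                    drop = FALSE]
    if (nrow(sub) < 2) return(NA_real_)
    pr <- utils::combn(nrow(sub), 2)
    df2 <- (sub$flux[pr[1, ]] - sub$flux[pr[2, ]])^2
    dq2 <- (sub$q[pr[1, ]] - sub$q[pr[2, ]])^2
    0.5 * (mean(df2) + mean(dq2))
  }, numeric(1))
  if (all(is.na(terms))) return(NA_real_)
  mean(terms, na.rm = TRUE)
}

#' Enumerate alternative clusters of a target species
#'
#' All clusters of the given size formed by the target plus `size - 1` of its
#' structural contact neighbours, each scored by heterogeneity; the cluster
#' of the target with all its neighbours is scored as well. When the target
#' has fewer than `size - 1` neighbours there are no alternative clusters
#' (flagged, the `***` case).
#'
#' @param target species id.
#' @param size cluster size (including the target), >= 2.
#' @param cm contact matrix (see [load_contact_matrix()]).
#' @param profiles flux/abundance profile tibble (see
#'   [cluster_heterogeneity()]).
#' @param N0,N fraction range.
#' @return object of class `cluster_alternatives`: list with `alternatives`
#'   (tibble: `members` list-column, `H`), `all_contact_H`, `target`, `size`,
#'   `no_alternatives` flag.
#' @export
enumerate_alternatives <- function(target, size, cm, profiles, N0, N) {
  if (size < 2) abort("cluster size must be at least 2")
  nb <- neighbors(cm, target)
  no_alt <- length(nb) < size - 1
  alternatives <- tibble(members = list(), H = numeric(0))
  if (!no_alt) {
    combs <- utils::combn(nb, size - 1, simplify = FALSE)
    alternatives <- tibble(
      members = lapply(combs, function(x) sort(c(target, x))),
      H = vapply(combs, function(x) {
        cluster_heterogeneity(c(target, x), profiles, N0, N)
      }, numeric(1)))
  }
  all_contact_H <- if (length(nb) >= 1) {
    cluster_heterogeneity(c(target, nb), profiles, N0, N)
  } else {
    NA_real_
  }
  structure(
    list(alternatives = alternatives, all_contact_H = all_contact_H,
         target = target, size = size, no_alternatives = no_alt),
    class = "cluster_alternatives"
  )
}

#' @export
print.cluster_alternatives <- function(x, ...) {
  cat("Alternative clusters for ", x$target, " (size ", x$size, "): ",
      if (x$no_alternatives) "none (***)" else nrow(x$alternatives),
      "\n", sep = "")
  invisible(x)
}

#' Quantile of a selected cluster among its alternatives
#'
#' Fraction of alternative clusters with strictly lower heterogeneity than
#' the selected cluster; 0 means the selected cluster is the most homogeneous
#' (ties count in its favour).
#'
#' @param selected_H heterogeneity of the selected cluster.
#' @param alternative_H numeric vector of alternative heterogeneities.
#' @return quantile in [0, 1].
#' @export
selected_cluster_quantile <- function(selected_H, alternative_H) {
  alternative_H <- alternative_H[!is.na(alternative_H)]
  if (!length(alternative_H)) abort("no alternative clusters to compare to")
  mean(alternative_H < selected_H)
}

#' Dendrogram distance between a species and its module
#'
#' `d = ((f_mod - f_i)^2 + (q_mod - q_i)^2) / 2`, where the module flux and
#' abundance are means over the assigned members in the assigned fraction.
#' Larger `d` means the species is more divergent from its module.
#'
#' @param species species id.
#' @param module_members character vector of the module's assigned members.
#' @param profiles flux/abundance tibble (see [cluster_heterogeneity()]).
#' @param fraction the module's assigned fraction.
#' @return nonnegative scalar distance.
#' @export
module_distance <- function(species, module_members, profiles, fraction) {
  sub <- profiles[profiles$fraction == fraction, , drop = FALSE]
  f_i <- sub$flux[sub$protein == species]
  q_i <- sub$q[sub$protein == species]
  mod <- sub[sub$protein %in% module_members, , drop = FALSE]
  if (!length(f_i) || !nrow(mod) || is.na(f_i) || is.na(q_i)) {
    abort("flux/abundance undefined for species or module in this fraction")
  }
  f_mod <- mean(mod$flux, na.rm = TRUE)
  q_mod <- mean(mod$q, na.rm = TRUE)
  0.5 * ((f_mod - f_i)^2 + (q_mod - q_i)^2)
}

#' Evaluate a selected cluster against its contact-constrained alternatives
#'
#' Convenience wrapper: heterogeneity of the selected cluster, enumeration of
#' the alternatives of the same size, and the quantile of the selected
#' cluster within them.
#'
#' @param target species id.
#' @param members selected cluster members (including the target).
#' @param cm contact matrix.
#' @param profiles flux/abundance tibble.
#' @param N0,N fraction range.
#' @return tibble with one row: `target`, `n_members`, `H`, `quantile`,
#'   `n_alternatives`, `no_alternatives`.
#' @export
evaluate_cluster <- function(target, members, cm, profiles, N0, N) {
  H_sel <- cluster_heterogeneity(members, profiles, N0, N)
  alt <- enumerate_alternatives(target, length(members), cm, profiles, N0, N)
  qv <- if (alt$no_alternatives || !nrow(alt$alternatives)) {
    NA_real_
  } else {
    selected_cluster_quantile(H_sel, alt$alternatives$H)
  }
  tibble(target = target, n_members = length(members), H = H_sel,
         quantile = qv, n_alternatives = nrow(alt$alternatives),
         no_alternatives = alt$no_alternatives)
}
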