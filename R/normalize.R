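# Normalization of H/M intensity grids from sucrose-gradient fractions.
#
# Grids are tidy tibbles with columns protein, fraction, time, replicate,
# label and a value column (`intensity` for raw data, `abundance` after
# spike-in normalization). A `stage` attribute tracks the pipeline position:
# raw -> standard -> steady -> subunit. Stages must run in order and each is
# idempotent.

.grid_stage <- function(grid) attr(grid, "stage") %||% "raw"

.set_stage <- function(grid, stage) {
  attr(grid, "stage") <- stage
  grid
}

#' Normalize H and M intensities to the spike-in standard
#'
#' Divides H and M intensities by the L intensity of the same cell (the
#' spiked-in purified-monosome standard), giving abundances in arbitrary
#' units relative to the standard that are comparable across proteins and
#' fractions. Cells with a missing or zero L intensity cannot be normalized
#' and are masked (dropped, with the count reported).
#'
#' @param grid raw tidy grid with columns `protein`, `fraction`, `time`,
#'   `replicate`, `label` (H/M/L), `intensity`. Zero intensity is treated as
#'   missing.
#' @param quiet suppress the masking message.
#' @return tidy grid (`label` H/M, column `abundance`), stage `"standard"`,
#'   with attribute `n_masked`.
#' @export
normalize_to_standard <- function(grid, quiet = FALSE) {
  if (.grid_stage(grid) != "raw") abort("grid is already normalized")
  wide <- grid %>%
    mutate(intensity = ifelse(is.na(.data$intensity) | .data$intensity <= 0,
                              NA_real_, .data$intensity)) %>%
    tidyr::pivot_wider(names_from = "label", values_from = "intensity")
  for (lab in c("H", "M", "L")) {
    if (!lab %in% names(wide)) wide[[lab]] <- NA_real_
  }
  n_cells <- sum(!is.na(wide$H) | !is.na(wide$M))
  out <- wide %>%
    filter(!is.na(.data$L)) %>%
    mutate(H = .data$H / .data$L, M = .data$M / .data$L) %>%
    select(-"L") %>%
    tidyr::pivot_longer(c("H", "M"), names_to = "label",
                        values_to = "abundance") %>%
    filter(!is.na(.data$abundance)) %>%
    arrange(.data$protein, .data$fraction, .data$time, .data$replicate,
            .data$label)
  n_masked <- n_cells - sum(!is.na(wide$L) &
                              (!is.na(wide$H) | !is.na(wide$M)))
  if (!quiet && n_masked > 0) {
    inform(paste(n_masked, "cells masked (missing spike-in standard)"))
  }
  out <- .set_stage(out, "standard")
  attr(out, "n_masked") <- n_masked
  out
}

#' Average replicates of a normalized grid
#'
#' Replicates are averaged after spike-in normalization and before
#' steady-state normalization; a cell observed in any replicate counts as
#' observed.
#'
#' @param grid grid at stage `"standard"` or later.
#' @return grid without a `replicate` column.
#' @export
average_replicates <- function(grid) {
  if (!"replicate" %in% names(grid)) return(grid)
  st <- .grid_stage(grid)
  out <- grid %>%
    group_by(dplyr::across(dplyr::any_of(c("protein", "fraction", "time",
                                           "label")))) %>%
    summarise(abundance = mean(.data$abundance, na.rm = TRUE),
              .groups = "drop")
  .set_stage(out, st)
}

#' Steady-state normalization per gradient fraction
#'
#' Under steady state the total protein abundance in a fraction is constant
#' over time, so each time point of a fraction is rescaled such that its
#' total (H + M summed over proteins) equals the across-time mean total of
#' that fraction. Idempotent; a fraction whose totals are all zero is left
#' unscaled and flagged.
#'
#' @param grid replicate-averaged grid at stage `"standard"` (or `"steady"`,
#'   in which case it is returned unchanged up to round-off).
#' @return grid at stage `"steady"`; attribute `unscaled_fractions` lists
#'   all-zero fractions.
#' @export
steady_state_normalize <- function(grid) {
  st <- .grid_stage(grid)
  if (!st %in% c("standard", "steady")) {
    abort("steady-state normalization expects a spike-in-normalized grid")
  }
  grid <- average_replicates(grid)
  totals <- grid %>%
    group_by(.data$fraction, .data$time) %>%
    summarise(total = sum(.data$abundance, na.rm = TRUE), .groups = "drop") %>%
    group_by(.data$fraction) %>%
    mutate(target = mean(.data$total),
           scale = ifelse(.data$total > 0, .data$target / .data$total, 1)) %>%
    ungroup()
  unscaled <- totals %>%
    group_by(.data$fraction) %>%
    summarise(zero = all(.data$total == 0)) %>%
    filter(.data$zero) %>%
    pull(.data$fraction)
  out <- grid %>%
    left_join(select(totals, "fraction", "time", "scale"),
              by = c("fraction", "time")) %>%
    mutate(abundance = .data$abundance * .data$scale) %>%
    select(-"scale")
  out <- .set_stage(out, "steady")
  attr(out, "unscaled_fractions") <- unscaled
  out
}

#' Scale a grid to the subunit reference abundance
#'
#' Expresses abundances relative to the mature-subunit steady-state
#' abundance: all values are divided by the across-time mean of the summed
#' H + M abundance of the subunit's proteins in the reference fraction
#' (fraction 7 for the small subunit, fraction 8 for the large subunit, where
#' the mature particles sediment).
#'
#' @param grid grid at stage `"steady"`.
#' @param roster character vector of the subunit's protein ids (e.g. from
#'   [load_roster()]).
#' @param reference_fraction reference fraction; default 7 (mtSSU) or 8
#'   (mtLSU) via `subunit`.
#' @param subunit `"mtSSU"` or `"mtLSU"` (sets the default reference
#'   fraction).
#' @return grid at stage `"subunit"`; attribute `reference_value` stores the
#'   divisor.
#' @export
scale_to_subunit <- function(grid, roster, subunit = c("mtSSU", "mtLSU"),
                             reference_fraction = NULL) {
  subunit <- match.arg(subunit)
  if (.grid_stage(grid) == "subunit") return(grid)
  if (.grid_stage(grid) != "steady") {
    abort("subunit scaling expects a steady-state-normalized grid")
  }
  ref_frac <- reference_fraction %||% if (subunit == "mtSSU") 7 else 8
  ref <- grid %>%
    filter(.data$fraction == ref_frac, .data$protein %in% roster) %>%
    group_by(.data$time) %>%
    summarise(total = sum(.data$abundance, na.rm = TRUE), .groups = "drop") %>%
    pull(.data$total) %>%
    mean()
  if (!is.finite(ref) || ref <= 0) {
    abort("subunit reference abundance is zero in the reference fraction")
  }
  out <- mutate(grid, abundance = .data$abundance / ref)
  out <- .set_stage(out, "subunit")
  attr(out, "reference_value") <- ref
  out
}

#' Detection filter for a protein/fraction cell
#'
#' A protein counts as robustly detected in a fraction when, for at least
#' three time points, finite positive ratios can be formed between the H and
#' M isotopes (i.e. both replicate-mean H and M abundances are positive).
#'
#' @param grid replicate-averaged (or replicate-carrying) normalized grid.
#' @param protein,fraction cell to test.
#' @param min_times required number of valid time points.
#' @return logical scalar.
#' @export
detection_filter <- function(grid, protein, fraction, min_times = 3) {
  dm <- detection_mask(grid, min_times = min_times)
  hit <- dm$detected[dm$protein == protein & dm$fraction == fraction]
  if (!length(hit)) FALSE else hit
}

#' Detection mask over all protein/fraction cells
#'
#' @param grid normalized grid.
#' @param min_times required number of time points with positive H and M.
#' @return tibble `protein`, `fraction`, `n_valid_times`, `detected`.
#' @export
detection_mask <- function(grid, min_times = 3) {
  average_replicates(grid) %>%
    tidyr::pivot_wider(names_from = "label", values_from = "abundance") %>%
    group_by(.data$protein, .data$fraction) %>%
    summarise(
      n_valid_times = sum(!is.na(.data$H) & !is.na(.data$M) &
                            .data$H > 0 & .data$M > 0),
      .groups = "drop") %>%
    mutate(detected = .data$n_valid_times >= min_times)
}

#' Steady-state abundance of a protein in a fraction
#'
#' Across-time mean of the replicate-averaged summed H + M abundance;
#' defined only where the detection filter passes (`NA` otherwise).
#'
#' @param grid normalized grid.
#' @param protein,fraction cell.
#' @param min_times detection filter threshold.
#' @return numeric scalar (NA when not detected).
#' @export
steady_state_abundance <- function(grid, protein, fraction, min_times = 3) {
  p <- steady_state_profile(grid, min_times = min_times)
  q <- p$q[p$protein == protein & p$fraction == fraction]
  if (!length(q)) NA_real_ else q
}

#' Steady-state abundance profile over all cells
#'
#' @inheritParams steady_state_abundance
#' @return tibble `protein`, `fraction`, `q`, `detected`; `q` is `NA` where
#'   the detection filter fails.
#' @export
steady_state_profile <- function(grid, min_times = 3) {
  q <- average_replicates(grid) %>%
    group_by(.data$protein, .data$fraction, .data$time) %>%
    summarise(total = sum(.data$abundance, na.rm = TRUE), .groups = "drop") %>%
    group_by(.data$protein, .data$fraction) %>%
    summarise(q = mean(.data$total), .groups = "drop")
  detection_mask(grid, min_times = min_times) %>%
    left_join(q, by = c("protein", "fraction")) %>%
    mutate(q = ifelse(.data$detected, .data$q, NA_real_)) %>%
    select("protein", "fraction", "q", "detected")
}

#' Per-fraction profile of an assembly factor
#'
#' Assembly factors are not part of the spike-in standard, so their raw H + M
#' intensities are used directly: the steady-state intensity per fraction is
#' the across-time mean of the summed H and M intensities, scaled per protein
#' by its maximum so the profile lies in [0, 1] with maximum 1.
#'
#' @param data tibble with columns `fraction`, `time`, `label` (H/M) and
#'   `intensity` (optionally `replicate`, averaged first) for one factor.
#' @return tibble `fraction`, `profile`.
#' @export
assembly_factor_profile <- function(data) {
  if (all(is.na(data$intensity) | data$intensity == 0)) {
    abort("factor has no signal in any fraction")
  }
  prof <- data %>%
    filter(.data$label %in% c("H", "M")) %>%
    group_by(dplyr::across(dplyr::any_of(c("fraction", "time",
                                           "replicate")))) %>%
    summarise(total = sum(.data$intensity, na.rm = TRUE), .groups = "drop") %>%
    group_by(.data$fraction) %>%
    summarise(profile = mean(.data$total), .groups = "drop")
  prof$profile <- prof$profile / max(prof$profile)
  prof
}
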