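# Readers/writers for MaxQuant-style intensity tables and the pipeline
# driver chaining the analysis stages.

.default_sample_regex <- "^F([0-9]+)_T([0-9.]+)_R([0-9]+)$"

#' Read a MaxQuant-style intensity table
#'
#' Parses a tab-separated protein-group table with per-sample intensity
#' columns `Intensity H <sample>`, `Intensity M <sample>`,
#' `Intensity L <sample>`. Sample names encode fraction, time and replicate;
#' the default convention is `F<fraction>_T<time>_R<rep>` and can be
#' overridden with a regex with three capture groups for real exports.
#' Zero intensities are kept as 0 and treated as missing downstream
#' (unquantified signals are written as 0 in these exports).
#'
#' @param path TSV file.
#' @param protein_col name of the protein id column (default: first
#'   non-intensity column).
#' @param sample_regex regex with capture groups (fraction, time, replicate).
#' @param quiet suppress the unmatched-column message.
#' @return raw tidy grid: `protein`, `fraction`, `time`, `replicate`,
#'   `label`, `intensity` (stage `"raw"`).
#' @export
read_intensity_table <- function(path, protein_col = NULL,
                                 sample_regex = .default_sample_regex,
                                 quiet = FALSE) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  ic <- grep("^Intensity [HML] ", names(df), value = TRUE)
  if (!length(ic)) abort("no 'Intensity H/M/L <sample>' columns found")
  if (is.null(protein_col)) protein_col <- setdiff(names(df), ic)[1]
  meta <- stringr::str_match(ic, "^Intensity ([HML]) (.+)$")
  smp <- stringr::str_match(meta[, 3], sample_regex)
  bad <- is.na(smp[, 1])
  if (any(bad) && !quiet) {
    inform(paste("ignoring", sum(bad),
                 "intensity columns with unparseable sample names"))
  }
  if (all(bad)) abort("no intensity column matches the sample-name pattern")
  keep <- which(!bad)
  out <- purrr::map_dfr(keep, function(i) {
    tibble(protein = df[[protein_col]],
           fraction = as.integer(smp[i, 2]),
           time = as.numeric(smp[i, 3]),
           replicate = as.integer(smp[i, 4]),
           label = meta[i, 2],
           intensity = as.numeric(df[[ic[i]]]))
  }) %>%
    arrange(.data$protein, .data$fraction, .data$time, .data$replicate,
            .data$label)
  .set_stage(out, "raw")
}

#' Write a tidy raw grid as a MaxQuant-style intensity table
#'
#' Inverse of [read_intensity_table()] for the packaged sample-name
#' convention; round-trips losslessly.
#'
#' @param grid raw tidy grid.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_intensity_table <- function(grid, path) {
  wide <- grid %>%
    mutate(col = paste0("Intensity ", .data$label, " F", .data$fraction,
                        "_T", .data$time, "_R", .data$replicate)) %>%
    select("protein", "col", "intensity") %>%
    tidyr::pivot_wider(names_from = "col", values_from = "intensity")
  names(wide)[1] <- "Protein IDs"
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' Derive cluster targets from a pathway
#'
#' For every protein, the selected cluster is the protein membership of the
#' smallest module containing it, and the earliest assigned fraction N0 is
#' that module's assigned fraction.
#'
#' @param pathway an `assembly_pathway`.
#' @param fraction_of named integer vector, assigned fraction per component.
#' @return tibble `target`, `members` (list-column), `N0`.
#' @export
pathway_cluster_targets <- function(pathway, fraction_of) {
  prot <- pathway$species$id[pathway$species$kind == "protein"]
  purrr::map_dfr(prot, function(p) {
    has <- vapply(pathway$modules$members, function(m) p %in% m, logical(1))
    if (!any(has)) return(NULL)
    i <- which(has)[which.min(pathway$modules$n_members[has])]
    mem <- intersect(pathway$modules$members[[i]], prot)
    if (length(mem) < 2) return(NULL)
    tibble(target = p, members = list(mem),
           N0 = unname(fraction_of[[pathway$modules$id[i]]]))
  })
}

#' Run the analysis pipeline on an intensity grid
#'
#' Chains the stages normalize -> flux -> cluster (-> kinetic ->
#' sensitivity), writing plain TSV/JSON artifacts and a manifest with
#' checksums to the output directory. Every stage is skippable via
#' `stages`; later stages reuse earlier results within the run. With a fixed
#' `seed` the run is reproducible (identical manifest checksums).
#'
#' @param config list with entries:
#'   * `input`: raw grid tibble or path to a MaxQuant-style TSV,
#'   * `pathway`: `assembly_pathway` or path to its YAML,
#'   * `contact_matrix`: `contact_matrix` or TSV path (cluster stage),
#'   * `fraction_of`: named fraction assignment per component (cluster
#'     target derivation and kinetic stage),
#'   * `subunit`: `"mtSSU"` (default) or `"mtLSU"`,
#'   * `out_dir`: output directory,
#'   * `stages`: subset of `c("normalize", "flux", "cluster", "kinetic",
#'     "sensitivity")`,
#'   * `seed`: integer seed,
#'   * `flux_method`: `"map"` (default) or `"mcmc"`,
#'   * `iterations`: MCMC iterations for the mcmc/kinetic stages,
#'   * `cluster_targets`: optional tibble (`target`, `members`, `N0`),
#'   * `sensitivity_parameters`: free rates to scan (default: binding and
#'     unbinding rate of the terminal product),
#'   * `n_particles`: posterior particles for the sensitivity stage.
#' @return invisibly, list with `out_dir` and `manifest`.
#' @export
run_pipeline <- function(config) {
  stages <- config$stages %||% c("normalize", "flux", "cluster")
  out_dir <- config$out_dir %||% abort("config$out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  set.seed(seed)
  subunit <- config$subunit %||% "mtSSU"
  log_lines <- c(paste("seed:", seed), paste("subunit:", subunit))
  files <- character(0)

  pathway <- config$pathway
  if (is.character(pathway)) pathway <- load_pathway(pathway)
  grid <- config$input
  if (is.character(grid)) grid <- read_intensity_table(grid, quiet = TRUE)
  if (is.null(grid)) abort("config$input is required")

  norm <- NULL
  if ("normalize" %in% stages) {
    roster <- pathway$species$id[pathway$species$kind == "protein"]
    norm <- grid %>%
      normalize_to_standard(quiet = TRUE) %>%
      steady_state_normalize() %>%
      scale_to_subunit(roster, subunit = subunit)
    log_lines <- c(log_lines,
                   "normalize: replicates averaged after spike-in normalization",
                   paste0("normalize: subunit reference fraction ",
                          if (subunit == "mtSSU") 7 else 8))
    f <- file.path(out_dir, "normalized_grid.tsv")
    readr::write_tsv(norm, f, progress = FALSE)
    files <- c(files, f)
  }
  if (is.null(norm)) abort("later stages require the normalize stage")

  flux_tbl <- NULL
  if (any(c("flux", "cluster") %in% stages)) {
    method <- config$flux_method %||% "map"
    iters <- config$iterations %||% 10000
    log_lines <- c(log_lines, paste("flux: method", method))
    proteins <- sort(unique(norm$protein))
    flux_tbl <- purrr::map_dfr(proteins, function(p) {
      sub <- dplyr::filter(norm, .data$protein == p) %>% select(-"protein")
      res <- tryCatch({
        if (method == "map") {
          fit_flux_map(sub, subunit = subunit) %>%
            filter(.data$detected) %>%
            mutate(f_median = .data$f, f_lo = NA_real_, f_hi = NA_real_) %>%
            select("fraction", "f_median", "f_lo", "f_hi")
        } else {
          summarize_flux(fit_flux(sub, subunit = subunit, n_iter = iters,
                                  seed = seed + match(p, proteins)))
        }
      }, error = function(e) NULL)
      if (is.null(res)) return(NULL)
      mutate(res, protein = p, .before = 1)
    })
    f <- file.path(out_dir, "flux_summary.tsv")
    readr::write_tsv(flux_tbl, f, progress = FALSE)
    files <- c(files, f)
  }

  if ("cluster" %in% stages) {
    cm <- config$contact_matrix
    if (is.null(cm)) {
      abort("cluster stage requires a contact matrix (config$contact_matrix)")
    }
    if (is.character(cm)) cm <- load_contact_matrix(cm)
    targets <- config$cluster_targets
    if (is.null(targets)) {
      fo <- config$fraction_of %||%
        abort("cluster stage needs cluster_targets or fraction_of")
      targets <- pathway_cluster_targets(pathway, fo)
    }
    N <- if (subunit == "mtSSU") 7 else 8
    ssp <- steady_state_profile(norm)
    profiles <- flux_tbl %>%
      select("protein", "fraction", flux = "f_median") %>%
      left_join(select(ssp, "protein", "fraction", "q"),
                by = c("protein", "fraction"))
    cl <- purrr::map_dfr(seq_len(nrow(targets)), function(i) {
      evaluate_cluster(targets$target[i], targets$members[[i]], cm,
                       profiles, targets$N0[i], N) %>%
        mutate(members = paste(targets$members[[i]], collapse = ","))
    })
    f <- file.path(out_dir, "clusters.tsv")
    readr::write_tsv(cl, f, progress = FALSE)
    files <- c(files, f)
    dd <- purrr::map_dfr(seq_len(nrow(targets)), function(i) {
      d <- tryCatch(
        module_distance(targets$target[i], targets$members[[i]], profiles,
                        targets$N0[i]),
        error = function(e) NA_real_)
      tibble(species = targets$target[i],
             module_members = paste(targets$members[[i]], collapse = ","),
             fraction = targets$N0[i], d = d)
    })
    f <- file.path(out_dir, "dendrogram_distances.tsv")
    readr::write_tsv(dd, f, progress = FALSE)
    files <- c(files, f)
  }

  kin <- NULL
  if ("kinetic" %in% stages) {
    fo <- config$fraction_of %||% abort("kinetic stage needs fraction_of")
    model <- build_model(pathway)
    cdat <- component_abundances(norm, pathway, fo) %>%
      filter(!is.na(.data$H), !is.na(.data$M))
    kin <- fit_kinetic(cdat, model,
                       n_iter = config$iterations %||% 2000, seed = seed)
    f <- file.path(out_dir, "kinetic_posterior_summary.tsv")
    readr::write_tsv(tidy(kin), f, progress = FALSE)
    files <- c(files, f)
    f <- file.path(out_dir, "kinetic_reactions.tsv")
    readr::write_tsv(reaction_table(model), f, progress = FALSE)
    files <- c(files, f)
  }

  if ("sensitivity" %in% stages) {
    if (is.null(kin)) abort("sensitivity stage requires the kinetic stage")
    n_part <- config$n_particles %||% 20
    idx <- sample.int(nrow(kin$samples), min(n_part, nrow(kin$samples)))
    particles <- lapply(idx, function(i) particle_from_sample(kin, i))
    pars <- config$sensitivity_parameters %||%
      c(paste0("on.", kin$model$terminal), paste0("off.", kin$model$terminal))
    scans <- dplyr::bind_rows(lapply(pars, function(p) {
      scan_parameter(kin$model, particles, p)
    }))
    f <- file.path(out_dir, "sensitivity.tsv")
    readr::write_tsv(scans, f, progress = FALSE)
    files <- c(files, f)
    f <- file.path(out_dir, "sensitivity_classes.tsv")
    readr::write_tsv(classify_rates(scans), f, progress = FALSE)
    files <- c(files, f)
  }

  manifest <- list(
    package = "mitoflux",
    version = as.character(utils::packageVersion("mitoflux")),
    seed = seed, stages = stages, log = log_lines,
    files = as.list(setNames(unname(tools::md5sum(files)), basename(files)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(out_dir = out_dir, manifest = manifest))
}
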