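#' Load an assembly pathway configuration
#'
#' Reads a YAML description of an assembly pathway: the species universe
#' (proteins and rRNA), the assembly modules, and the binding reactions that
#' produce each module. Module membership (the set of protein/rRNA species a
#' module ultimately contains) is derived from the reaction graph; primed
#' kinetic variants (e.g. `B5'`) inherit the member set of their base module
#' and must not alter it.
#'
#' The packaged small-subunit configuration
#' (`mitoflux_example("mtssu_pathway.yaml")`) transcribes the reconstructed
#' mtSSU assembly route: 30 single species (29 mitoribosomal proteins plus the
#' 12S rRNA) feeding 17 modules up to the mature subunit. mS37 is part of the
#' mtSSU roster but excluded from the kinetic species set because it was not
#' continuously detected; this membership table is editable.
#'
#' @param path YAML file.
#' @return object of class `assembly_pathway`: list with `species` (tibble:
#'   id, subunit, kind), `modules` (tibble: id, variant_of, n_members plus a
#'   `members` list-column), `reactions` (list of `list(product=, reactants=)`),
#'   `terminal` (id of the mature subunit) and `subunit`.
#' @export
load_pathway <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (field in c("subunit", "species", "modules", "reactions", "terminal")) {
    if (is.null(cfg[[field]])) abort(paste0("pathway config lacks '", field, "'"))
  }
  species <- dplyr::bind_rows(lapply(cfg$species, tibble::as_tibble)) %>%
    mutate(subunit = cfg$subunit)
  if (anyDuplicated(species$id)) {
    abort(paste("duplicate species id:",
                species$id[duplicated(species$id)][1]))
  }
  mods <- dplyr::bind_rows(lapply(cfg$modules, function(m) {
    tibble(id = m$id, variant_of = m$variant_of %||% NA_character_)
  }))
  if (anyDuplicated(mods$id)) {
    abort(paste("duplicate module id:", mods$id[duplicated(mods$id)][1]))
  }
  if (any(mods$id %in% species$id)) {
    abort("module ids must not collide with species ids")
  }
  reactions <- lapply(cfg$reactions, function(r) {
    list(product = r$product, reactants = unlist(r$reactants))
  })

  products <- vapply(reactions, `[[`, character(1), "product")
  if (anyDuplicated(products)) {
    abort(paste("module is the product of more than one reaction:",
                products[duplicated(products)][1]))
  }
  orphan <- setdiff(mods$id, products)
  if (length(orphan)) {
    abort(paste("module with no producing reaction:", orphan[1]))
  }
  extra <- setdiff(products, mods$id)
  if (length(extra)) abort(paste("reaction product is not a module:", extra[1]))

  all_ids <- c(species$id, mods$id)
  for (r in reactions) {
    unknown <- setdiff(r$reactants, all_ids)
    if (length(unknown)) {
      abort(paste("unknown reactant id:", unknown[1]))
    }
  }

  # topological order over modules; cycles are an error
  order <- character(0)
  resolved <- species$id
  pending <- reactions
  while (length(pending)) {
    ready <- vapply(pending, function(r) all(r$reactants %in% resolved),
                    logical(1))
    if (!any(ready)) {
      abort("cycle in reaction graph (no reaction has all reactants resolved)")
    }
    order <- c(order, vapply(pending[ready], `[[`, character(1), "product"))
    resolved <- c(resolved, order)
    pending <- pending[!ready]
  }

  # derive member sets bottom-up
  members <- as.list(setNames(species$id, species$id))
  for (pid in order) {
    r <- reactions[[which(products == pid)]]
    members[[pid]] <- sort(unique(unlist(members[r$reactants])))
  }
  mods <- mods %>%
    mutate(members = unname(members[.data$id]),
           n_members = lengths(.data$members)) %>%
    arrange(match(.data$id, order))
  if (any(mods$n_members < 1)) abort("module with empty member set")

  # primed variants must preserve composition
  for (i in which(!is.na(mods$variant_of))) {
    base <- mods$variant_of[i]
    if (!base %in% mods$id) abort(paste("variant_of references unknown module:", base))
    if (!identical(mods$members[[i]],
                   mods$members[[match(base, mods$id)]])) {
      abort(paste0("primed variant ", mods$id[i],
                   " does not share the member set of ", base))
    }
  }

  if (!cfg$terminal %in% mods$id) abort("terminal product is not a module")

  structure(
    list(species = species, modules = mods, reactions = reactions,
         terminal = cfg$terminal, subunit = cfg$subunit),
    class = "assembly_pathway"
  )
}

#' @export
print.assembly_pathway <- function(x, ...) {
  cat("Assembly pathway (", x$subunit, "): ",
      nrow(x$species), " single species, ",
      nrow(x$modules), " modules, ",
      length(x$reactions), " reactions; terminal product ", x$terminal, "\n",
      sep = "")
  invisible(x)
}

#' Load a subunit roster
#'
#' Reads a YAML roster of species (and, optionally, module membership lists
#' without reaction topology), as shipped for the large subunit. Returns a
#' tibble of species plus a `modules` attribute.
#'
#' @param path YAML file with `subunit`, `species`, and optional `modules`
#'   (id + members).
#' @return tibble with columns id, subunit, kind.
#' @export
load_roster <- function(path) {
  cfg <- yaml::read_yaml(path)
  species <- dplyr::bind_rows(lapply(cfg$species, tibble::as_tibble)) %>%
    mutate(subunit = cfg$subunit)
  if (anyDuplicated(species$id)) abort("duplicate species id in roster")
  mods <- NULL
  if (!is.null(cfg$modules)) {
    mods <- lapply(cfg$modules, function(m) {
      unknown <- setdiff(unlist(m$members), species$id)
      if (length(unknown)) abort(paste("unknown species id in module:", unknown[1]))
      list(id = m$id, members = unlist(m$members))
    })
  }
  attr(species, "modules") <- mods
  species
}

#' Path to a packaged configuration or fixture file
#'
#' @param file file name under `inst/extdata`; with no argument, lists the
#'   available files.
#' @return absolute path (or character vector of file names).
#' @export
mitoflux_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "mitoflux")))
  }
  p <- system.file("extdata", file, package = "mitoflux")
  if (p == "") abort(paste("no packaged file named", file))
  p
}

# ---- contact matrix ---------------------------------------------------------

#' Load a pairwise contact (buried surface area) matrix
#'
#' Reads a TSV whose first row and first column are species ids and whose
#' cells are pairwise buried surface areas in square Angstrom, as exported
#' from an interface-area analysis of the assembled subunit structure. Input
#' that is asymmetric within `tol` (relative to the largest entry) is
#' symmetrized by averaging; larger asymmetry is an error. The diagonal is
#' forced to zero.
#'
#' @param path TSV file.
#' @param species optional character vector of known species ids; any row or
#'   column id outside this set is an error.
#' @param tol relative asymmetry tolerance.
#' @return symmetric numeric matrix with dimnames, class `contact_matrix`,
#'   carrying a `report` attribute (list with `n_species`, `n_contacts`,
#'   `max_asymmetry`).
#' @export
load_contact_matrix <- function(path, species = NULL, tol = 1e-6) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1)
  m <- as.matrix(df)
  if (!is.numeric(m)) abort("contact matrix cells must be numeric")
  if (!identical(rownames(m), colnames(m))) {
    abort("contact matrix row and column ids differ")
  }
  if (!is.null(species)) {
    unknown <- setdiff(rownames(m), species)
    if (length(unknown)) abort(paste("unknown species id:", unknown[1]))
  }
  if (any(m < 0, na.rm = TRUE)) abort("negative buried surface area")
  m[is.na(m)] <- 0
  asym <- max(abs(m - t(m)))
  scale <- max(m, 1e-300)
  if (asym / scale > tol) {
    abort(sprintf("contact matrix asymmetry %.3g exceeds tolerance", asym))
  }
  m <- (m + t(m)) / 2
  diag(m) <- 0
  structure(m, class = c("contact_matrix", "matrix", "array"),
            report = list(n_species = nrow(m),
                          n_contacts = sum(m[upper.tri(m)] > 0),
                          max_asymmetry = asym))
}

#' Write a contact matrix as TSV
#'
#' Inverse of [load_contact_matrix()]; round-trips bit-identically for the
#' packaged fixtures.
#'
#' @param cm contact matrix.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_contact_matrix <- function(cm, path) {
  df <- as.data.frame(unclass(cm))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     col.names = NA, row.names = TRUE)
  invisible(path)
}

#' Contact neighbours of a species
#'
#' All species sharing strictly positive buried surface area with the target.
#' Any positive area counts as a contact (no area cutoff is applied).
#'
#' @param cm contact matrix from [load_contact_matrix()].
#' @param target species id.
#' @return character vector of species ids.
#' @export
neighbors <- function(cm, target) {
  if (!target %in% rownames(cm)) abort(paste("unknown species id:", target))
  ids <- colnames(cm)[cm[target, ] > 0]
  setdiff(ids, target)
}

#' @export
tidy.contact_matrix <- function(x, ...) {
  ids <- rownames(x)
  idx <- which(upper.tri(x) & x > 0, arr.ind = TRUE)
  tibble(species_a = ids[idx[, 1]], species_b = ids[idx[, 2]],
         area = x[idx])
}
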