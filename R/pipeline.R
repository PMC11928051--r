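#' Run the full hover scaling pipeline
#'
#' Orchestrates ingest, aerodynamic derivation, and the OLS/PGLS allometry
#' battery, and writes a reproducible report bundle:
#' \itemize{
#'   \item `derived_parameters.csv` — the observation table (native units)
#'     with `U, c, AR, k, C_L, Re` appended;
#'   \item `fit_table.csv` — one row per trait and method with the
#'     theoretical exponent alongside the fitted one;
#'   \item `fit_table_<subgroup>.csv` — the same battery on each subgroup
#'     exclusion run (e.g. without a hyperallometric clade);
#'   \item `manifest.json` — input checksums, configuration, package and R
#'     versions, and the seed, sufficient to re-run bit-identically.
#' }
#'
#' @param data path to a canonical observation CSV, or a `"hover_obs"`
#'   data frame / native-unit data frame.
#' @param tree path to a Newick file, or a `phylo` object.
#' @param out_dir output directory (created if absent).
#' @param lambda Pagel's lambda for PGLS: fixed value or `"ML"`, see
#'   [fit_allometries()].
#' @param exclusions named list of character vectors; each entry re-runs
#'   the battery without those species (e.g.
#'   `list(no_trochilidae = hummingbird_species)`).
#' @param synonyms optional species-synonym map, see [as_observations()].
#' @param seed integer seed recorded in the manifest (the pipeline itself
#'   is deterministic; the seed matters when the inputs were generated).
#' @param g,mu physical constants, see [derive_aero()].
#' @return Invisibly, a list with elements `obs`, `derived`, `fits`,
#'   `subgroup_fits`, `manifest`.
#' @export
run_pipeline <- function(data, tree, out_dir, lambda = 0.5,
                         exclusions = list(), synonyms = NULL,
                         seed = 1L, g = .g_default, mu = .mu_default) {
  # fail fast on config before any computation
  data_path <- tree_path <- NULL
  if (is.character(data)) {
    if (!file.exists(data)) stop("data file not found: ", data)
    data_path <- data
  }
  if (is.character(tree)) {
    if (!file.exists(tree)) stop("tree file not found: ", tree)
    tree_path <- tree
  }
  if (!identical(lambda, "ML") &&
      (!is.numeric(lambda) || lambda < 0 || lambda > 1))
    stop("lambda must lie in [0, 1] or be \"ML\"")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  obs <- if (is.character(data)) read_observations(data, synonyms = synonyms)
         else if (inherits(data, "hover_obs")) data
         else as_observations(data, synonyms = synonyms)
  phy <- if (is.character(tree)) read_phylogeny(tree)
         else validate_phylogeny(tree)
  missing_tips <- setdiff(unique(obs$species), phy$tip.label)
  if (length(missing_tips))
    stop("species absent from tree: ", paste(missing_tips, collapse = ", "))

  derived <- derive_aero(obs, g = g, mu = mu)
  derived_native <- cbind(observations_to_native(obs),
                          derived[, c("c", "AR", "U", "k", "C_L", "Re")])
  utils::write.csv(derived_native,
                   file.path(out_dir, "derived_parameters.csv"),
                   row.names = FALSE)

  fits <- fit_allometries(obs, phy, lambda = lambda, g = g, mu = mu)
  utils::write.csv(as.data.frame(fits), file.path(out_dir, "fit_table.csv"),
                   row.names = FALSE)

  subgroup_fits <- list()
  for (nm in names(exclusions)) {
    sf <- fit_allometries(obs, phy, lambda = lambda,
                          exclude_species = exclusions[[nm]],
                          g = g, mu = mu)
    subgroup_fits[[nm]] <- sf
    utils::write.csv(as.data.frame(sf),
                     file.path(out_dir, sprintf("fit_table_%s.csv", nm)),
                     row.names = FALSE)
  }

  manifest <- list(
    inputs = list(
      data = if (!is.null(data_path))
        list(path = data_path,
             md5 = unname(tools::md5sum(data_path))) else "in-memory",
      tree = if (!is.null(tree_path))
        list(path = tree_path,
             md5 = unname(tools::md5sum(tree_path))) else "in-memory"
    ),
    config = list(lambda = lambda, g = g, mu = mu,
                  exclusions = exclusions, seed = seed),
    counts = list(
      n_rows = nrow(obs),
      n_species = length(unique(obs$species)),
      n_rows_kinematics = sum(!is.na(obs$f) & !is.na(obs$Phi))
    ),
    versions = list(
      hoverscale = as.character(utils::packageVersion("hoverscale")),
      R = paste(R.version$major, R.version$minor, sep = ".")
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(obs = obs, derived = derived, fits = fits,
                 subgroup_fits = subgroup_fits, manifest = manifest))
}
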