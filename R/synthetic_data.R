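#' Specification of a synthetic hovering clade
#'
#' Describes a clade of hovering animals whose traits follow known power
#' laws \eqn{y = \beta m^{\gamma}} with lognormal scatter, so the whole
#' pipeline (ingest, aerodynamic derivation, aggregation, OLS/PGLS) can be
#' exercised and parameter recovery quantified without external data.
#'
#' Defaults emulate the comparative hovering dataset: 27 species spanning
#' masses of 0.1 mg (small fruit flies) to 10 g (large hummingbirds),
#' generating exponents equal to the theoretical values from
#' [derive_exponents()], and intercepts chosen so trait magnitudes are
#' realistic (e.g. a frequency intercept of \eqn{10^{2.45} \approx 282} Hz
#' at 1 mg, decaying as \eqn{m^{-1/6}}; a stroke amplitude around
#' \eqn{10^{2.057} \approx 114} degrees independent of mass).
#'
#' Species-level residuals (log10 scale, SD `sigma_species`) are a mixture
#' of a Brownian-motion component on the tree and an independent component,
#' mixed by `lambda_signal` — the same structure Pagel's lambda regression
#' assumes, which makes recovery tests well-posed. Observation-level
#' scatter (SD `sigma_meas`) is added per literature row. A fraction
#' `missing_kinematics` of rows lacks `f` and `Phi`, exercising the
#' partial-data path (morphology-only rows). An optional
#' `hyper` component adds `extra` to the mass exponent of one trait for a
#' named species subset, mimicking hummingbird wing-area hyperallometry.
#'
#' @param n_species number of species (>= 3).
#' @param mass_range mass range in mg, log-uniform.
#' @param gamma named numeric vector of generating exponents for
#'   `R, S, R_b, f, Phi, theta_m`.
#' @param log10_beta named numeric vector of generating intercepts (log10,
#'   native units: mm, mm^2, mm, Hz, deg, deg).
#' @param sigma_species species-level residual SD (log10 scale).
#' @param lambda_signal fraction of species residual variance structured by
#'   Brownian motion on the tree, in `[0, 1]`.
#' @param n_obs_range integer range of observation rows per species.
#' @param sigma_meas within-species observation SD (log10 scale).
#' @param missing_kinematics fraction of rows with `f`, `Phi` missing.
#' @param hyper optional `list(species = <chr>, trait = <name>,
#'   extra = <numeric>)` hyperallometric subgroup.
#' @return A list of class `"synth_clade_spec"`.
#' @export
synth_clade_spec <- function(n_species = 27,
                             mass_range = c(0.1, 1e4),
                             gamma = c(R = 1 / 3, S = 2 / 3, R_b = 1 / 3,
                                       f = -1 / 6, Phi = 0, theta_m = 0),
                             log10_beta = c(R = 0.412, S = 0.238,
                                            R_b = 0.572, f = 2.450,
                                            Phi = 2.057, theta_m = 1.602),
                             sigma_species = 0.05,
                             lambda_signal = 0.5,
                             n_obs_range = c(2L, 10L),
                             sigma_meas = 0.02,
                             missing_kinematics = 0.15,
                             hyper = NULL) {
  stopifnot(n_species >= 3, length(mass_range) == 2, all(mass_range > 0),
            mass_range[1] < mass_range[2],
            sigma_species >= 0, sigma_meas >= 0,
            lambda_signal >= 0, lambda_signal <= 1,
            missing_kinematics >= 0, missing_kinematics < 1)
  need <- c("R", "S", "R_b", "f", "Phi", "theta_m")
  stopifnot(all(need %in% names(gamma)), all(need %in% names(log10_beta)))
  if (!is.null(hyper))
    stopifnot(is.list(hyper), hyper$trait %in% need,
              is.numeric(hyper$extra))
  structure(list(n_species = as.integer(n_species),
                 mass_range = mass_range, gamma = gamma,
                 log10_beta = log10_beta, sigma_species = sigma_species,
                 lambda_signal = lambda_signal,
                 n_obs_range = as.integer(n_obs_range),
                 sigma_meas = sigma_meas,
                 missing_kinematics = missing_kinematics,
                 hyper = hyper),
            class = "synth_clade_spec")
}

#' Generate a random ultrametric phylogeny
#'
#' Pure-birth (Yule) tree with `n_species` extant tips via
#' [ape::rphylo()], rescaled to unit depth so root-to-tip distances are all
#' exactly 1. Tip labels are `sp01, sp02, ...`. Deterministic given the
#' seed.
#'
#' @param n_species number of tips (>= 3).
#' @param seed integer RNG seed.
#' @return An ultrametric `phylo` object of depth 1.
#' @export
synth_tree <- function(n_species, seed = 1L) {
  if (n_species < 3) stop("need at least 3 species")
  tree <- withr::with_seed(seed,
    ape::rphylo(n_species, birth = 1, death = 0))
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- sprintf("sp%02d", seq_len(n_species))
  tree
}

#' Tips of an internal clade of roughly a given size
#'
#' Convenience for constructing hyperallometric subgroups: returns the tip
#' set of the internal node whose descendant count is closest to
#' `frac * n_tips` (at least 2).
#'
#' @param tree a `phylo` object.
#' @param frac target clade fraction of the tips.
#' @return Character vector of tip labels (a monophyletic group).
#' @export
synth_clade_species <- function(tree, frac = 0.25) {
  n <- length(tree$tip.label)
  target <- max(2, round(frac * n))
  internal <- (n + 2):(n + tree$Nnode)   # exclude the root
  sizes <- vapply(internal, function(nd)
    length(ape::extract.clade(tree, nd)$tip.label), integer(1))
  best <- internal[which.min(abs(sizes - target))]
  ape::extract.clade(tree, best)$tip.label
}

#' Generate a synthetic observation table on a phylogeny
#'
#' Draws species masses log-uniformly over the spec's mass range, builds
#' per-species trait values \eqn{y_s = \beta m_s^{\gamma} 10^{b_s}} with a
#' tree-structured species residual \eqn{b_s}, then emits several
#' observation rows per species with lognormal measurement scatter, in the
#' dataset-native units (mg, mm, mm^2, Hz, degrees). The species residual
#' is \eqn{b_s = \sigma_{sp}(\sqrt{\lambda}\, z^{BM}_s +
#' \sqrt{1-\lambda}\, z^{iid}_s)} with the Brownian component drawn from
#' the tree's covariance matrix by Cholesky factorisation.
#'
#' Identical `spec` and `seed` give bit-identical output.
#'
#' @param spec a [synth_clade_spec()].
#' @param tree phylogeny with at least `n_species` tips (e.g.
#'   [synth_tree()]); the first `n_species` tips are used.
#' @param seed integer RNG seed.
#' @return Native-unit observation data frame (canonical columns, see
#'   [as_observations()]), with attribute `"species_truth"` holding the
#'   per-species noise-free trait table.
#' @export
synth_observations <- function(spec, tree, seed = 1L) {
  stopifnot(inherits(spec, "synth_clade_spec"))
  tree <- validate_phylogeny(tree)
  if (length(tree$tip.label) < spec$n_species)
    stop("tree has fewer tips than n_species")
  sp <- tree$tip.label[seq_len(spec$n_species)]
  if (!is.null(spec$hyper)) {
    missing_sp <- setdiff(spec$hyper$species, sp)
    if (length(missing_sp))
      stop("hyperallometric clade species not on tree: ",
           paste(missing_sp, collapse = ", "))
  }
  traits <- c("R", "S", "R_b", "f", "Phi", "theta_m")

  withr::with_seed(seed, {
    lm10 <- stats::runif(spec$n_species, log10(spec$mass_range[1]),
                         log10(spec$mass_range[2]))
    mass_mg <- 10^sort(lm10)
    names(mass_mg) <- sp

    # species-level residuals: BM on tree mixed with independent noise
    Vt <- ape::vcv.phylo(ape::keep.tip(tree, sp))[sp, sp]
    Lt <- t(chol(Vt / max(diag(Vt))))   # unit-variance BM deviates
    resid_sp <- sapply(traits, function(tr) {
      z_bm <- as.vector(Lt %*% stats::rnorm(spec$n_species))
      z_iid <- stats::rnorm(spec$n_species)
      spec$sigma_species * (sqrt(spec$lambda_signal) * z_bm +
                              sqrt(1 - spec$lambda_signal) * z_iid)
    })
    rownames(resid_sp) <- sp

    truth <- sapply(traits, function(tr) {
      g <- spec$gamma[[tr]]
      extra <- if (!is.null(spec$hyper) && spec$hyper$trait == tr)
        ifelse(sp %in% spec$hyper$species, spec$hyper$extra, 0) else 0
      10^(spec$log10_beta[[tr]] + (g + extra) * log10(mass_mg) +
            resid_sp[, tr])
    })
    rownames(truth) <- sp

    rows <- lapply(sp, function(s) {
      n_obs <- if (spec$n_obs_range[1] == spec$n_obs_range[2])
        spec$n_obs_range[1]
      else sample(seq(spec$n_obs_range[1], spec$n_obs_range[2]), 1L)
      obs <- sapply(traits, function(tr)
        truth[s, tr] * 10^stats::rnorm(n_obs, 0, spec$sigma_meas))
      obs <- matrix(obs, nrow = n_obs,
                    dimnames = list(NULL, traits))
      data.frame(
        species = s,
        mass_mg = rep(mass_mg[[s]], n_obs),
        wing_length_mm = obs[, "R"],
        wing_area_mm2 = obs[, "S"],
        body_length_mm = obs[, "R_b"],
        frequency_hz = obs[, "f"],
        amplitude_deg = obs[, "Phi"],
        pitch_deg = obs[, "theta_m"],
        altitude_m = NA_real_,
        density_kgm3 = NA_real_,
        n_meas = sample(1:5, n_obs, replace = TRUE),
        source = "synthetic",
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL

    if (spec$missing_kinematics > 0) {
      # every species keeps at least one kinematic row so N_sp is unchanged
      drop <- which(stats::runif(nrow(out)) < spec$missing_kinematics)
      keep_one <- vapply(split(seq_len(nrow(out)), out$species),
                         `[`, integer(1), 1L)
      drop <- setdiff(drop, keep_one)
      out$frequency_hz[drop] <- NA_real_
      out$amplitude_deg[drop] <- NA_real_
    }
    attr(out, "species_truth") <-
      data.frame(species = sp, mass_mg = unname(mass_mg), truth,
                 row.names = NULL, stringsAsFactors = FALSE)
    out
  })
}
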