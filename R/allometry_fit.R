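# Native reporting units per trait: regressions and intercepts are on the
# dataset's native scale (mass mg; R, R_b mm; S mm^2; theta_m, Phi deg;
# f Hz; U m/s; AR, k, C_L, Re dimensionless).
.native_scale <- c(m = 1e6, R = 1e3, S = 1e6, R_b = 1e3,
                   theta_m = 180 / pi, Phi = 180 / pi,
                   f = 1, U = 1, AR = 1, k = 1, C_L = 1, Re = 1)

.hover_traits <- c("R", "S", "AR", "R_b", "theta_m", "f", "Phi",
                   "U", "k", "C_L", "Re")

#' Per-species weighted trait means
#'
#' Aggregates observation-level values of one trait into one value per
#' species, the unit of analysis of the comparative regressions. Weights are
#' the number of replicate measurements behind each literature row
#' (`n_meas`), via [stats::weighted.mean()]. Species with no value for the
#' trait are excluded from that trait's aggregate (each trait has its own
#' species coverage).
#'
#' @param records data frame of observation records (typically
#'   [derive_aero()] output) with columns `species`, `n_meas` and the trait.
#' @param trait trait column name.
#' @return Data frame with columns `species`, `value` (weighted mean on the
#'   input scale), `n_obs` (observation rows) and `n_total` (summed
#'   `n_meas`).
#' @export
species_means <- function(records, trait) {
  stopifnot(trait %in% names(records))
  keep <- !is.na(records[[trait]])
  if (!any(keep))
    stop("trait '", trait, "' has no non-missing values")
  rec <- records[keep, , drop = FALSE]
  sp <- split(seq_len(nrow(rec)), rec$species)
  out <- data.frame(
    species = names(sp),
    value = vapply(sp, function(i)
      stats::weighted.mean(rec[[trait]][i], w = rec$n_meas[i]), numeric(1)),
    n_obs = vapply(sp, length, integer(1)),
    n_total = vapply(sp, function(i) sum(rec$n_meas[i]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out
}

#' Log-log ordinary least squares power-law fit
#'
#' Fits \eqn{y = \beta m^{\gamma}} by regressing \eqn{\log_{10} y} on
#' \eqn{\log_{10} m} with the closed-form normal equations. Reports the
#' slope (allometric exponent), intercept (\eqn{\log_{10}\beta}), adjusted
#' \eqn{r^2}, the two-sided t-test of slope = 0, and the 95% confidence
#' interval of the slope (t quantile, \eqn{n-2} df). Adjusted \eqn{r^2}
#' can be negative for slopes near zero, which is informative for the
#' mass-invariance checks.
#'
#' @param x positive predictor values (body masses).
#' @param y positive response values (trait means).
#' @param trait optional trait label carried into the result.
#' @param n_ob optional total observation count behind the species means.
#' @return A one-row data frame of class `"power_law_fit"`: `trait`,
#'   `method`, `N_ob`, `N_sp`, `gamma_hat`, `log10_beta_hat`, `se_gamma`,
#'   `r2_adj`, `p_value`, `ci_lo`, `ci_hi`, `lambda` (`NA` for OLS).
#' @export
ols_loglog <- function(x, y, trait = NA_character_, n_ob = NA_integer_) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 species for a fit")
  if (any(x <= 0) || any(y <= 0)) stop("x and y must be positive")
  lx <- log10(x); ly <- log10(y)
  n <- length(lx)
  sxx <- sum((lx - mean(lx))^2)
  if (sxx == 0) stop("degenerate design: zero variance in log10(x)")
  slope <- sum((lx - mean(lx)) * (ly - mean(ly))) / sxx
  intercept <- mean(ly) - slope * mean(lx)
  resid <- ly - intercept - slope * lx
  df <- n - 2
  s2 <- sum(resid^2) / df
  se <- sqrt(s2 / sxx)
  syy <- sum((ly - mean(ly))^2)
  r2 <- if (syy == 0) 1 else 1 - sum(resid^2) / syy
  r2_adj <- 1 - (1 - r2) * (n - 1) / df
  tval <- if (se == 0) Inf * sign(slope) else slope / se
  p <- 2 * stats::pt(-abs(tval), df)
  tq <- stats::qt(0.975, df)
  out <- data.frame(
    trait = trait, method = "OLS",
    N_ob = as.integer(n_ob), N_sp = as.integer(n),
    gamma_hat = slope, log10_beta_hat = intercept, se_gamma = se,
    r2_adj = r2_adj, p_value = p,
    ci_lo = slope - tq * se, ci_hi = slope + tq * se,
    lambda = NA_real_, stringsAsFactors = FALSE
  )
  class(out) <- c("power_law_fit", "data.frame")
  out
}

#' Phylogenetic covariance matrix under Pagel's lambda
#'
#' Builds the Brownian-motion species covariance matrix from a phylogeny —
#' \eqn{V_{ij}} is the shared root-to-MRCA path length of tips \eqn{i} and
#' \eqn{j}, via [ape::vcv.phylo()] — then applies Pagel's \eqn{\lambda}
#' transform: off-diagonals are multiplied by \eqn{\lambda} while the
#' diagonal (root-to-tip lengths) is left unchanged. \eqn{\lambda = 0}
#' gives an independence (diagonal) model, \eqn{\lambda = 1} full Brownian
#' covariance.
#'
#' @param tree a `phylo` object containing all requested species as tips.
#' @param lambda Pagel's lambda in `[0, 1]`.
#' @param species optional character vector: order (and subset) of species;
#'   defaults to the tree's tip order.
#' @return Symmetric positive-semidefinite matrix with `species` dimnames
#'   and attribute `"lambda"`.
#' @export
phylo_covariance <- function(tree, lambda = 0.5, species = NULL) {
  tree <- validate_phylogeny(tree)
  if (length(lambda) != 1 || is.na(lambda) || lambda < 0 || lambda > 1)
    stop("lambda must be a single value in [0, 1]")
  if (is.null(species)) species <- tree$tip.label
  missing_sp <- setdiff(species, tree$tip.label)
  if (length(missing_sp))
    stop("species missing from tree: ", paste(missing_sp, collapse = ", "))
  V <- ape::vcv.phylo(tree)[species, species, drop = FALSE]
  d <- diag(V)
  V <- lambda * V
  diag(V) <- d
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(ev))
    stop("lambda-transformed covariance is not positive semidefinite")
  attr(V, "lambda") <- lambda
  V
}

#' Log-log phylogenetic generalized least squares power-law fit
#'
#' GLS estimator on the \eqn{\log_{10}} scale with residual covariance
#' proportional to a phylogenetic covariance matrix `V` (typically from
#' [phylo_covariance()]):
#' \deqn{\hat b = (X^T V^{-1} X)^{-1} X^T V^{-1} y,\quad
#'       \hat\sigma^2 = e^T V^{-1} e / (n - 2),}
#' with standard errors from \eqn{\hat\sigma^2 (X^T V^{-1} X)^{-1}} and a
#' two-sided t test of slope = 0. Because \eqn{\hat\sigma^2} rescales with
#' `V`, the fit is invariant under uniform branch-length rescaling, which is
#' what makes unit-branch-length taxonomy trees usable. A singular `V` is an
#' error; no silent regularisation is applied.
#'
#' @param x,y positive masses and trait means, named by species or in the
#'   order of `V`'s dimnames.
#' @param V phylogenetic covariance matrix from [phylo_covariance()].
#' @param trait,n_ob labels carried into the result, as in [ols_loglog()].
#' @return A one-row `"power_law_fit"` data frame with `method = "PGLS"`
#'   and the `lambda` used. `r2_adj` is reported as `NA` (not defined for
#'   GLS in a way comparable with OLS).
#' @export
pgls_loglog <- function(x, y, V, trait = NA_character_, n_ob = NA_integer_) {
  stopifnot(length(x) == length(y), nrow(V) == length(x))
  if (length(x) < 3) stop("need at least 3 species for a fit")
  if (any(x <= 0) || any(y <= 0)) stop("x and y must be positive")
  if (!is.null(names(x)) && !is.null(rownames(V))) {
    if (!setequal(names(x), rownames(V)))
      stop("species of x do not match covariance matrix")
    ord <- rownames(V)
    x <- x[ord]; y <- y[ord]
  }
  n <- length(x)
  X <- cbind(1, log10(x))
  yv <- log10(y)
  ch <- tryCatch(chol(V), error = function(e)
    stop("singular or non-PD phylogenetic covariance: ", conditionMessage(e)))
  # whiten: solve L^T z = w  with V = L^T L (chol gives upper triangular)
  Xw <- backsolve(ch, X, transpose = TRUE)
  yw <- backsolve(ch, yv, transpose = TRUE)
  XtX <- crossprod(Xw)
  b <- solve(XtX, crossprod(Xw, yw))
  e <- yw - Xw %*% b
  df <- n - 2
  s2 <- sum(e^2) / df
  covb <- s2 * solve(XtX)
  slope <- b[2]; intercept <- b[1]
  se <- sqrt(covb[2, 2])
  tval <- if (se == 0) Inf * sign(slope) else slope / se
  p <- 2 * stats::pt(-abs(tval), df)
  tq <- stats::qt(0.975, df)
  out <- data.frame(
    trait = trait, method = "PGLS",
    N_ob = as.integer(n_ob), N_sp = as.integer(n),
    gamma_hat = slope, log10_beta_hat = intercept, se_gamma = se,
    r2_adj = NA_real_, p_value = p,
    ci_lo = slope - tq * se, ci_hi = slope + tq * se,
    lambda = attr(V, "lambda") %||% NA_real_, stringsAsFactors = FALSE
  )
  class(out) <- c("power_law_fit", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Maximum-likelihood estimate of Pagel's lambda for one regression
#'
#' Profiles the Gaussian log-likelihood of the log-log regression over
#' \eqn{\lambda \in [0, 1]}: for each candidate the GLS coefficients and
#' \eqn{\hat\sigma^2 = e^T V(\lambda)^{-1} e / n} are concentrated out,
#' leaving \deqn{\ell(\lambda) = -\tfrac12\left(n \log(2\pi\hat\sigma^2) +
#' \log|V(\lambda)| + n\right),} maximised by [stats::optimize()]. This is
#' the optional alternative to fixing \eqn{\lambda}; the default analysis
#' keeps \eqn{\lambda} fixed for reproducibility.
#'
#' @param x,y positive masses and trait means, named by species.
#' @param tree phylogeny covering the species.
#' @return List with `lambda` (the ML estimate) and `logLik`.
#' @export
estimate_lambda <- function(x, y, tree) {
  species <- names(x)
  if (is.null(species)) stop("x must be named by species")
  n <- length(x)
  X <- cbind(1, log10(x)); yv <- log10(y)
  negll <- function(lam) {
    V <- phylo_covariance(tree, lambda = lam, species = species)
    ch <- chol(V)
    Xw <- backsolve(ch, X, transpose = TRUE)
    yw <- backsolve(ch, yv, transpose = TRUE)
    b <- solve(crossprod(Xw), crossprod(Xw, yw))
    e <- yw - Xw %*% b
    s2 <- sum(e^2) / n
    0.5 * (n * log(2 * pi * s2) + 2 * sum(log(diag(ch))) + n)
  }
  opt <- stats::optimize(negll, interval = c(0, 1))
  list(lambda = opt$minimum, logLik = -opt$objective)
}

#' Fit the full battery of hover allometries
#'
#' For every trait in `R, S, AR, R_b, theta_m, f, Phi, U, k, C_L, Re`:
#' derive per-record aerodynamic parameters ([derive_aero()]), aggregate to
#' weighted species means ([species_means()]) on the dataset's native
#' reporting scale, and fit both OLS and PGLS power laws against species
#' mean body mass in mg. The theoretical exponent column from
#' [derive_exponents()] is attached for comparison. Traits with fewer than
#' 3 species are skipped (recorded in the `"skipped"` attribute), not
#' fatal.
#'
#' @param obs `"hover_obs"` data frame in SI units.
#' @param tree phylogeny whose tips cover the analysis species.
#' @param lambda Pagel's lambda for the PGLS fits: a fixed value in
#'   `[0, 1]` (default 0.5), or `"ML"` to estimate it per trait by
#'   profile maximum likelihood ([estimate_lambda()]).
#' @param exclude_species optional character vector of species to drop
#'   before fitting (e.g. a hyperallometric clade for a sensitivity run).
#' @param traits traits to fit (default: the full battery).
#' @param methods subset of `c("OLS", "PGLS")`.
#' @param level `"species"` (default): regress on weighted species means,
#'   the unit of analysis PGLS requires; `"observation"`: sensitivity mode
#'   running the OLS fits on all observation rows instead (PGLS always
#'   uses species means).
#' @param g,mu constants passed to [derive_aero()].
#' @return Data frame of class `"power_law_fit"`: one row per trait and
#'   method, with `gamma_theory` attached. Attribute `"skipped"` lists
#'   traits not fitted with reasons.
#' @export
fit_allometries <- function(obs, tree = NULL, lambda = 0.5,
                            exclude_species = NULL,
                            traits = .hover_traits,
                            methods = c("OLS", "PGLS"),
                            level = c("species", "observation"),
                            g = .g_default, mu = .mu_default) {
  methods <- match.arg(methods, several.ok = TRUE)
  level <- match.arg(level)
  estimate_lam <- identical(lambda, "ML")
  if (!estimate_lam &&
      (!is.numeric(lambda) || lambda < 0 || lambda > 1))
    stop("lambda must lie in [0, 1] or be \"ML\"")
  if ("PGLS" %in% methods && is.null(tree))
    stop("PGLS requested but no tree supplied")
  if (!is.null(exclude_species))
    obs <- obs[!(obs$species %in% exclude_species), , drop = FALSE]
  if (!nrow(obs)) stop("no observations left after exclusions")
  rec <- derive_aero(obs, g = g, mu = mu)

  theory <- derive_exponents()
  mass_mean <- species_means(rec, "m")   # SI; converted per trait below

  fits <- list(); skipped <- list()
  for (tr in traits) {
    if (!tr %in% names(rec)) { skipped[[tr]] <- "trait column absent"; next }
    if (all(is.na(rec[[tr]]))) { skipped[[tr]] <- "no data"; next }
    agg <- species_means(rec, tr)
    # mass aggregated over the same rows the trait is observed in
    m_agg <- species_means(rec[!is.na(rec[[tr]]), , drop = FALSE], "m")
    stopifnot(identical(agg$species, m_agg$species))
    if (nrow(agg) < 3) {
      skipped[[tr]] <- sprintf("only %d species", nrow(agg)); next
    }
    xs <- m_agg$value * .native_scale[["m"]]
    ys <- agg$value * .native_scale[[tr]]
    names(xs) <- names(ys) <- agg$species
    n_ob <- sum(agg$n_obs)
    gtheo <- theory$gamma_num[match(tr, theory$quantity)]
    gchr <- theory$gamma[match(tr, theory$quantity)]
    if ("OLS" %in% methods) {
      fo <- if (level == "observation") {
        rows <- !is.na(rec[[tr]])
        ols_loglog(rec$m[rows] * .native_scale[["m"]],
                   rec[[tr]][rows] * .native_scale[[tr]],
                   trait = tr, n_ob = n_ob)
      } else {
        ols_loglog(xs, ys, trait = tr, n_ob = n_ob)
      }
      fo$gamma_theory <- gtheo; fo$gamma_theory_frac <- gchr
      fits[[length(fits) + 1L]] <- fo
    }
    if ("PGLS" %in% methods) {
      sub <- ape::keep.tip(tree, agg$species)
      lam <- if (estimate_lam) estimate_lambda(xs, ys, sub)$lambda
             else lambda
      V <- phylo_covariance(sub, lambda = lam, species = agg$species)
      fp <- pgls_loglog(xs, ys, V, trait = tr, n_ob = n_ob)
      fp$gamma_theory <- gtheo; fp$gamma_theory_frac <- gchr
      fits[[length(fits) + 1L]] <- fp
    }
  }
  if (!length(fits)) stop("no trait could be fitted")
  out <- do.call(rbind, fits)
  rownames(out) <- NULL
  class(out) <- c("power_law_fit", "data.frame")
  attr(out, "skipped") <- skipped
  out
}

#' @export
print.power_law_fit <- function(x, digits = 3, ...) {
  cat("Power-law allometry fit(s): y = beta * m^gamma (log10 scale)\n")
  cols <- intersect(c("trait", "method", "N_ob", "N_sp", "gamma_theory_frac",
                      "gamma_hat", "log10_beta_hat", "r2_adj", "p_value",
                      "ci_lo", "ci_hi", "lambda"), names(x))
  df <- as.data.frame(x)[, cols, drop = FALSE]
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = digits)
  print(df, row.names = FALSE)
  sk <- attr(x, "skipped")
  if (length(sk))
    cat("skipped:", paste(names(sk), unlist(sk), sep = ": ",
                          collapse = "; "), "\n")
  invisible(x)
}
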