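test_that("weighted species means follow the replicate counts", {
  rec <- data.frame(species = c("a", "a", "b"), y = c(2, 4, 7),
                    n_meas = c(1L, 3L, 2L))
  agg <- species_means(rec, "y")
  expect_equal(agg$value[agg$species == "a"], 3.5)  # (2*1 + 4*3)/4
  expect_equal(agg$value[agg$species == "b"], 7)    # single obs = itself
  expect_equal(agg$n_obs, c(2L, 1L))
  # equal weights reduce to the ordinary mean
  rec$n_meas <- 2L
  expect_equal(species_means(rec, "y")$value[1], 3)
  expect_error(species_means(rec, "absent"))
})

test_that("noiseless power law is recovered exactly by OLS", {
  m <- 10^seq(-1, 4, length.out = 9)
  y <- 10^0.4 * m^(1 / 3)
  fit <- ols_loglog(m, y)
  expect_equal(fit$gamma_hat, 1 / 3, tolerance = 1e-12)
  expect_equal(fit$log10_beta_hat, 0.4, tolerance = 1e-12)
  expect_equal(fit$r2_adj, 1, tolerance = 1e-12)
})

test_that("OLS matches the frozen closed-form oracle on a 5-point set", {
  x <- c(0.5, 2.0, 10.0, 55.0, 300.0)
  y <- c(1.1, 1.9, 3.4, 6.0, 10.5)
  fit <- ols_loglog(x, y)
  # frozen from an independent normal-equations evaluation
  expect_equal(fit$gamma_hat, 0.3509999814206993, tolerance = 1e-12)
  expect_equal(fit$log10_beta_hat, 0.16392579702500254, tolerance = 1e-12)
  expect_equal(fit$se_gamma, 0.007389303276015388, tolerance = 1e-12)
  expect_equal(fit$r2_adj, 0.9982295823027719, tolerance = 1e-12)
  expect_equal(fit$p_value, 2.054316997499554e-05, tolerance = 1e-9)
  expect_equal(fit$ci_lo, 0.32748392051132336, tolerance = 1e-10)
  expect_equal(fit$ci_hi, 0.3745160423300753, tolerance = 1e-10)
  expect_error(ols_loglog(x[1:2], y[1:2]), "at least 3")
  expect_error(ols_loglog(rep(2, 5), y), "degenerate design")
})

test_that("OLS agrees with lm() on random inputs", {
  set.seed(31)
  for (i in 1:10) {
    n <- sample(5:40, 1)
    x <- 10^stats::runif(n, -1, 4)
    y <- 10^(0.3 + 0.4 * log10(x) + stats::rnorm(n, 0, 0.2))
    fit <- ols_loglog(x, y)
    ref <- summary(stats::lm(log10(y) ~ log10(x)))
    expect_equal(fit$gamma_hat, unname(ref$coefficients[2, 1]),
                 tolerance = 1e-10)
    expect_equal(fit$se_gamma, unname(ref$coefficients[2, 2]),
                 tolerance = 1e-10)
    expect_equal(fit$p_value, unname(ref$coefficients[2, 4]),
                 tolerance = 1e-10)
    expect_equal(fit$r2_adj, ref$adj.r.squared, tolerance = 1e-10)
  }
})

test_that("Pagel-lambda covariance has shared path lengths and transform", {
  tree <- read_phylogeny("((A:1,B:1):1,C:2);")
  V1 <- phylo_covariance(tree, lambda = 1)
  expect_equal(V1["A", "B"], 1)
  expect_equal(diag(V1), c(A = 2, B = 2, C = 2))
  expect_equal(V1["A", "C"], 0)
  # lambda scales off-diagonals, leaves the diagonal unchanged
  V5 <- phylo_covariance(tree, lambda = 0.5)
  expect_equal(V5["A", "B"], 0.5)
  expect_equal(diag(V5), diag(V1))
  # lambda = 0 -> diagonal regardless of topology
  V0 <- phylo_covariance(tree, lambda = 0)
  expect_true(all(V0[upper.tri(V0)] == 0))
  # star tree -> diagonal for any lambda
  star <- read_phylogeny("(A:1,B:1,C:1);")
  Vs <- phylo_covariance(star, lambda = 0.8)
  expect_true(all(Vs[upper.tri(Vs)] == 0))
  expect_error(phylo_covariance(tree, lambda = 2), "lambda")
  expect_error(phylo_covariance(tree, species = c("A", "Z")),
               "missing from tree.*Z")
})

test_that("PGLS with identity covariance reproduces OLS exactly", {
  set.seed(17)
  n <- 12
  x <- 10^stats::runif(n, -1, 4)
  y <- 10^(0.2 + 0.35 * log10(x) + stats::rnorm(n, 0, 0.1))
  V <- diag(n)
  fo <- ols_loglog(x, y)
  fp <- pgls_loglog(x, y, V)
  expect_equal(fp$gamma_hat, fo$gamma_hat, tolerance = 1e-10)
  expect_equal(fp$log10_beta_hat, fo$log10_beta_hat, tolerance = 1e-10)
  expect_equal(fp$se_gamma, fo$se_gamma, tolerance = 1e-10)
  expect_equal(fp$p_value, fo$p_value, tolerance = 1e-10)
})

test_that("PGLS matches the frozen 3-taxon hand-solved oracle", {
  tree <- read_phylogeny("((A:1,B:1):1,C:2);")
  V <- phylo_covariance(tree, lambda = 1)
  x <- c(A = 1.0, B = 4.0, C = 60.0)
  y <- c(A = 1.2, B = 1.8, C = 5.0)
  fit <- pgls_loglog(x, y, V)
  # frozen from explicit 3x3 matrix arithmetic
  expect_equal(fit$gamma_hat, 0.3447811235761937, tolerance = 1e-10)
  expect_equal(fit$log10_beta_hat, 0.07306295954031461, tolerance = 1e-10)
  expect_equal(fit$se_gamma, 0.028199621620372997, tolerance = 1e-10)
})

test_that("PGLS slope is invariant under uniform branch rescaling", {
  cl <- make_clade(n_species = 14, seed = 41,
                   spec = synth_clade_spec(n_species = 14,
                                           sigma_species = 0.08))
  agg <- species_means(cl$obs, "f")
  m_agg <- species_means(cl$obs[!is.na(cl$obs$f), ], "m")
  x <- stats::setNames(m_agg$value * 1e6, m_agg$species)
  y <- stats::setNames(agg$value, agg$species)
  base <- pgls_loglog(x, y, phylo_covariance(cl$tree, 0.5))
  for (cc in c(0.1, 10)) {
    t2 <- cl$tree
    t2$edge.length <- t2$edge.length * cc
    fit <- pgls_loglog(x, y, phylo_covariance(t2, 0.5))
    expect_equal(fit$gamma_hat, base$gamma_hat, tolerance = 1e-10)
    expect_equal(fit$se_gamma, base$se_gamma, tolerance = 1e-10)
  }
})

test_that("PGLS agrees with nlme::gls + ape::corPagel at fixed lambda", {
  cl <- make_clade(n_species = 15, seed = 3,
                   spec = synth_clade_spec(n_species = 15,
                                           sigma_species = 0.08,
                                           sigma_meas = 0.03,
                                           missing_kinematics = 0))
  agg <- species_means(derive_aero(cl$obs), "f")
  m_agg <- species_means(cl$obs, "m")
  x <- stats::setNames(m_agg$value * 1e6, m_agg$species)
  y <- stats::setNames(agg$value, agg$species)
  mine <- pgls_loglog(x, y, phylo_covariance(cl$tree, 0.5,
                                             species = agg$species))
  d <- data.frame(lx = log10(x), ly = log10(y), species = agg$species)
  ref <- nlme::gls(ly ~ lx, data = d,
                   correlation = ape::corPagel(0.5, phy = cl$tree,
                                               form = ~species,
                                               fixed = TRUE))
  expect_equal(mine$gamma_hat, unname(stats::coef(ref)[2]),
               tolerance = 1e-8)
  expect_equal(mine$se_gamma, sqrt(stats::vcov(ref)[2, 2]),
               tolerance = 1e-8)
  expect_equal(mine$p_value, summary(ref)$tTable[2, 4], tolerance = 1e-8)
})

test_that("fit_allometries recovers generating exponents without noise", {
  cl <- make_clade(n_species = 12, seed = 101)
  fits <- fit_allometries(cl$obs, cl$tree)
  for (i in seq_len(nrow(fits)))
    expect_equal(fits$gamma_hat[i], fits$gamma_theory[i], tolerance = 1e-8)
  # both methods, full trait battery
  expect_setequal(unique(fits$method), c("OLS", "PGLS"))
  expect_setequal(unique(fits$trait),
                  c("R", "S", "AR", "R_b", "theta_m", "f", "Phi",
                    "U", "k", "C_L", "Re"))
})

test_that("exponent estimates are unbiased with covered CIs under the
           generating noise model", {
  spec <- synth_clade_spec(sigma_species = 0.05)
  slopes <- numeric(200); covered <- logical(200)
  for (i in 1:200) {
    tree <- synth_tree(27, seed = 5000 + i)
    nat <- synth_observations(spec, tree, seed = 6000 + i)
    obs <- as_observations(nat)
    agg <- species_means(obs, "f")
    m_agg <- species_means(obs[!is.na(obs$f), ], "m")
    fit <- ols_loglog(m_agg$value * 1e6, agg$value, trait = "f")
    slopes[i] <- fit$gamma_hat
    covered[i] <- fit$ci_lo <= -1 / 6 && -1 / 6 <= fit$ci_hi
  }
  expect_lt(abs(mean(slopes) - (-1 / 6)), 0.01)
  expect_gte(mean(covered), 0.90)
})

test_that("ML lambda estimation tracks the generating phylogenetic signal", {
  est <- function(lam_gen, seed) {
    tree <- synth_tree(40, seed = seed)
    spec <- synth_clade_spec(n_species = 40, lambda_signal = lam_gen,
                             sigma_species = 0.15, sigma_meas = 0.01)
    obs <- as_observations(synth_observations(spec, tree, seed = seed + 1))
    agg <- species_means(obs, "R")
    m_agg <- species_means(obs, "m")
    x <- stats::setNames(m_agg$value * 1e6, m_agg$species)
    y <- stats::setNames(agg$value * 1e3, agg$species)
    estimate_lambda(x, y, tree)$lambda
  }
  lam_hi <- mean(vapply(1:8, function(i) est(1, 700 + 10 * i), numeric(1)))
  lam_lo <- mean(vapply(1:8, function(i) est(0, 800 + 10 * i), numeric(1)))
  expect_gt(lam_hi, 0.6)
  expect_lt(lam_lo, 0.4)
  # and the "ML" mode plugs into the battery
  cl <- make_clade(n_species = 12, seed = 19,
                   spec = synth_clade_spec(n_species = 12,
                                           sigma_species = 0.05))
  fits <- fit_allometries(cl$obs, cl$tree, lambda = "ML", traits = "R",
                          methods = "PGLS")
  expect_true(fits$lambda >= 0 && fits$lambda <= 1)
})

test_that("observation-level OLS sensitivity mode uses all rows", {
  cl <- make_clade(n_species = 10, seed = 23,
                   spec = synth_clade_spec(n_species = 10,
                                           sigma_species = 0.05,
                                           missing_kinematics = 0))
  sp_fit <- fit_allometries(cl$obs, traits = "R", methods = "OLS")
  ob_fit <- fit_allometries(cl$obs, traits = "R", methods = "OLS",
                            level = "observation")
  expect_equal(sp_fit$N_sp, 10L)
  expect_equal(ob_fit$N_sp, nrow(cl$obs))  # every row is a point
  expect_gt(ob_fit$N_sp, sp_fit$N_sp)
  # same underlying power law: slopes agree to sampling precision
  expect_equal(ob_fit$gamma_hat, sp_fit$gamma_hat, tolerance = 0.05)
})

test_that("excluding an injected hyperallometric clade restores isometry", {
  tree <- synth_tree(27, seed = 77)
  hyper_sp <- synth_clade_species(tree, frac = 0.3)
  spec <- synth_clade_spec(sigma_species = 0.03, sigma_meas = 0.02,
                           hyper = list(species = hyper_sp, trait = "S",
                                        extra = 0.2))
  nat <- synth_observations(spec, tree, seed = 78)
  obs <- as_observations(nat)
  full <- fit_allometries(obs, tree, traits = "S", methods = "OLS")
  sub <- fit_allometries(obs, tree, traits = "S", methods = "OLS",
                         exclude_species = hyper_sp)
  expect_gt(full$gamma_hat, 2 / 3)  # pooled exponent pulled up
  expect_lt(abs(sub$gamma_hat - 2 / 3), abs(full$gamma_hat - 2 / 3))
})
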