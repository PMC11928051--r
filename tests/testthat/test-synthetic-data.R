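test_that("synthetic trees are ultrametric, sized and deterministic", {
  tree <- synth_tree(27, seed = 4)
  expect_equal(length(tree$tip.label), 27)
  expect_equal(tree$Nnode, 26)
  depths <- ape::node.depth.edgelength(tree)[1:27]
  expect_equal(max(abs(depths - 1)), 0, tolerance = 1e-12)
  # determinism
  tree2 <- synth_tree(27, seed = 4)
  expect_identical(ape::write.tree(tree), ape::write.tree(tree2))
  expect_false(identical(ape::write.tree(tree),
                         ape::write.tree(synth_tree(27, seed = 5))))
  expect_error(synth_tree(2), "at least 3")
})

test_that("identical spec and seed give byte-identical tables", {
  spec <- synth_clade_spec(n_species = 10)
  tree <- synth_tree(10, seed = 2)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(synth_observations(spec, tree, seed = 9), f1,
                   row.names = FALSE)
  utils::write.csv(synth_observations(spec, tree, seed = 9), f2,
                   row.names = FALSE)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("generated tables are plausible and exercise partial kinematics", {
  spec <- synth_clade_spec()  # defaults: 27 species, missing kinematics
  tree <- synth_tree(27, seed = 12)
  nat <- synth_observations(spec, tree, seed = 13)
  obs <- as_observations(nat)
  expect_equal(nrow(attr(obs, "rejected")), 0)
  expect_equal(length(unique(obs$species)), 27)
  expect_true(min(obs$m) >= 0.1e-6 && max(obs$m) <= 1e4 * 1e-6)
  # some rows lack kinematics, but every species keeps at least one
  kin <- !is.na(obs$f)
  expect_true(any(!kin))
  expect_equal(length(unique(obs$species[kin])), 27)
  # frequency magnitudes follow the generating power law
  # (~282 Hz at 1 mg, decaying as m^(-1/6)) up to the species scatter
  truth <- attr(nat, "species_truth")
  fit <- ols_loglog(truth$mass_mg, truth$f)
  expect_equal(fit$gamma_hat, -1 / 6, tolerance = 0.05)
  expect_equal(fit$log10_beta_hat, 2.450, tolerance = 0.1)
})

test_that("generator + aero + fit closes on the theoretical exponents", {
  cl <- make_clade(n_species = 27, seed = 55,
                   spec = noiseless_spec(27))
  fits <- fit_allometries(cl$obs, cl$tree, methods = "OLS",
                          traits = c("k", "C_L", "Re"))
  expect_equal(fits$gamma_hat[fits$trait == "k"], 0, tolerance = 1e-10)
  expect_equal(fits$gamma_hat[fits$trait == "C_L"], 0, tolerance = 1e-10)
  expect_equal(fits$gamma_hat[fits$trait == "Re"], 0.5, tolerance = 1e-10)
})

test_that("phylogenetic signal changes estimator efficiency, not OLS bias", {
  # Gauss-Markov direction: PGLS (Brownian covariance) is the efficient
  # estimator when species residuals are fully tree-structured; OLS is
  # efficient when they are independent. OLS stays unbiased in both.
  sd_ols <- sd_pgls <- mean_ols <- c()
  for (lam in c(1, 0)) {
    spec <- synth_clade_spec(n_species = 20, lambda_signal = lam,
                             sigma_species = 0.08)
    so <- sp <- numeric(60)
    for (i in 1:60) {
      tree <- synth_tree(20, seed = 300 + i)
      obs <- as_observations(synth_observations(spec, tree, seed = 400 + i))
      agg <- species_means(obs, "R")
      m_agg <- species_means(obs, "m")
      x <- stats::setNames(m_agg$value * 1e6, m_agg$species)
      y <- stats::setNames(agg$value * 1e3, agg$species)
      so[i] <- ols_loglog(x, y)$gamma_hat
      sp[i] <- pgls_loglog(x, y, phylo_covariance(tree, 1,
                                                  species = agg$species))$gamma_hat
    }
    sd_ols <- c(sd_ols, stats::sd(so)); sd_pgls <- c(sd_pgls, stats::sd(sp))
    mean_ols <- c(mean_ols, mean(so))
  }
  expect_lt(sd_pgls[1], sd_ols[1])   # full signal: PGLS more precise
  expect_lt(sd_ols[2], sd_pgls[2])   # no signal: OLS more precise
  expect_lt(abs(mean_ols[1] - 1 / 3), 0.02)
  expect_lt(abs(mean_ols[2] - 1 / 3), 0.02)
})

test_that("spec validation rejects inconsistent configurations", {
  expect_error(synth_clade_spec(n_species = 2))
  expect_error(synth_clade_spec(lambda_signal = 1.2))
  expect_error(synth_clade_spec(hyper = list(trait = "bogus", extra = 1)))
  tree <- synth_tree(8, seed = 1)
  spec <- synth_clade_spec(n_species = 8,
                           hyper = list(species = "not_a_tip", trait = "S",
                                        extra = 0.2))
  expect_error(synth_observations(spec, tree, seed = 1), "not on tree")
})
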