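test_that("AAFE matches hand-computed fold errors", {
  expect_equal(aafe(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(aafe(c(2, 4, 8), c(1, 2, 4)), 2)
  expect_equal(aafe(c(10, 0.1), c(1, 1)), 10)
  # symmetric under inversion and invariant to common rescaling
  p <- c(3.2, 0.7, 12); o <- c(2.1, 1.9, 8)
  expect_equal(aafe(p, o), aafe(o, p))
  expect_equal(aafe(1000 * p, 1000 * o), aafe(p, o))
  expect_gte(aafe(p, o), 1)
  expect_message(aafe(c(1, 0), c(1, 1)), "excluded 1")
  expect_error(suppressMessages(aafe(0, 1)), "no positive")
  expect_error(aafe(1:3, 1:2), "equal length")
})

test_that("objective is zero at the generating truth and rises around it", {
  sc <- pbpk_scenario()
  truth <- drug_parameters()
  obs <- generate_synthetic_observations(
    sc, mouse_phys, truth,
    design = study_design(organs = c("liver", "spleen")),
    noise = noise_model(cv = 0))
  tr <- list(Pup = 0.995, KBile = 0.0128, sigma_IS = 0.64, F = 0.76)
  l0 <- pbpk_objective(tr, obs, sc, mouse_phys)
  expect_lt(l0, 1e-8)
  # perturbing any single parameter away from truth increases the loss
  for (nm in names(tr)) {
    up <- tr; up[[nm]] <- tr[[nm]] * 1.25
    expect_gt(pbpk_objective(up, obs, sc, mouse_phys), l0 + 1e-6)
    dn <- tr; dn[[nm]] <- tr[[nm]] * 0.75
    expect_gt(pbpk_objective(dn, obs, sc, mouse_phys), l0 + 1e-6)
  }
})

test_that("objective excludes zero observations and validates bounds", {
  sc <- pbpk_scenario()
  obs <- generate_synthetic_observations(
    sc, mouse_phys, drug_parameters(),
    design = study_design(times_days = c(1, 7),
                          organs = c("liver", "spleen")),
    noise = noise_model(cv = 0))
  obs$value[1] <- 0
  tr <- list(Pup = 0.995, KBile = 0.0128, sigma_IS = 0.64, F = 0.76)
  expect_message(pbpk_objective(tr, obs, sc, mouse_phys),
                 "excluded 1 zero observation")
  bad <- tr; bad$Pup <- 100
  expect_error(pbpk_objective(bad, obs, sc, mouse_phys), "outside bounds")
  expect_error(pbpk_objective(tr[-1], obs, sc, mouse_phys), "missing")
})

test_that("fit machinery converges from a nearby start on clean data", {
  sc <- pbpk_scenario()
  obs <- generate_synthetic_observations(
    sc, mouse_phys, drug_parameters(),
    design = study_design(organs = c("liver", "spleen")),
    noise = noise_model(cv = 0))
  fit <- fit_pbpk(obs, sc, mouse_phys, seed = 3,
                  start = list(Pup = 1.2, KBile = 0.02, sigma_IS = 0.5,
                               F = 0.6),
                  sann_iter = 30, polish_iter = 200)
  expect_lt(fit$objective, 1e-4)
  expect_true(all(fit$par >= c(0.075, 0, 0, 0)))
  expect_true(all(fit$par <= c(40, 1, 1, 1)))
  expect_s3_class(fit, "pbpk_fit")
  expect_named(coef(fit), c("Pup", "KBile", "sigma_IS", "F"))
  r <- residuals(fit)
  expect_length(r, nrow(obs))
  expect_lt(max(abs(r)), 0.05)
  s <- summary(fit)
  expect_lt(s$aafe, 1.05)
  # bounds validation
  expect_error(fit_pbpk(obs, sc, mouse_phys,
                        bounds = list(Pup = c(0.075, 100), KBile = c(0, 1),
                                      sigma_IS = c(0, 1), F = c(0, 1))),
               "invalid bounds")
})

test_that("annealing is reproducible by seed and stable across seeds", {
  sc <- pbpk_scenario()
  obs <- generate_synthetic_observations(
    sc, mouse_phys, drug_parameters(),
    design = study_design(times_days = c(1, 14, 56),
                          organs = c("liver", "spleen")),
    noise = noise_model(cv = 0))
  f1 <- fit_pbpk(obs, sc, mouse_phys, seed = 5, sann_iter = 40,
                 polish_iter = 120)
  f2 <- fit_pbpk(obs, sc, mouse_phys, seed = 5, sann_iter = 40,
                 polish_iter = 120)
  expect_identical(f1$par, f2$par)
  f3 <- fit_pbpk(obs, sc, mouse_phys, seed = 6, sann_iter = 40,
                 polish_iter = 120)
  # two seeds land on objective values of the same (near-zero) magnitude
  expect_lt(abs(f1$objective - f3$objective), 0.01)
})

test_that("identifiability diagnostics flag degeneracies and pass the design", {
  sc <- pbpk_scenario()
  obs <- generate_synthetic_observations(
    sc, mouse_phys, drug_parameters(),
    design = study_design(organs = c("liver", "spleen")),
    noise = noise_model(cv = 0))
  params <- list(Pup = 0.995, KBile = 0.0128, sigma_IS = 0.64, F = 0.76)
  rep <- identifiability_check(params, obs, sc, mouse_phys)
  expect_true(rep$identifiable)
  expect_equal(dim(rep$sensitivity), c(nrow(obs), 4L))
  # a duplicated parameter yields a perfectly correlated sensitivity vector
  S <- rep$sensitivity
  C <- stats::cor(cbind(S, S[, "Pup"]))
  expect_gt(abs(C[5, 1]), 0.999)
  # a parameter with no pathway to the outputs is flagged
  rep0 <- identifiability_check(c(params, list(KAbs = 0)), obs,
                                pbpk_scenario(route = "IV"), mouse_phys)
  expect_false(rep0$identifiable)
  expect_true(any(grepl("KAbs", rep0$flags)))
})
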