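test_that("the generator is a pure function of its configuration", {
  cfg <- community_sim_config(n_species = 10, seed = 17)
  s1 <- simulate_community(cfg)
  s2 <- simulate_community(cfg)
  expect_identical(s1$profiles, s2$profiles)
  expect_identical(s1$lwr, s2$lwr)
  expect_identical(s1$survey, s2$survey)
  expect_equal(nrow(s1$profiles), 10)
  # a different seed changes the draws
  s3 <- simulate_community(community_sim_config(n_species = 10, seed = 18))
  expect_false(identical(s1$survey, s3$survey))
})

test_that("generated lengths match the configured dispersion", {
  set.seed(100)
  len <- gtlbiomass:::draw_lengths(12, 0.3, 1e4)
  expect_equal(sd(log(len)), 0.3, tolerance = 0.1 * 0.3)
  expect_equal(median(len), 12, tolerance = 0.03 * 12)
  # degenerate dispersion: every individual at the GTL
  expect_equal(gtlbiomass:::draw_lengths(9, 0, 50), rep(9, 50))
})

test_that("densities conserve the realized mean individual mass", {
  cfg <- community_sim_config(n_species = 15, months = 6,
                              juvenile_fraction = 0.3, seed = 23)
  sv <- simulate_survey(simulate_species_pool(cfg)$truth, cfg)
  recovered <- sv$survey$biomass_density / sv$survey$number_density
  expect_equal(recovered, sv$truth$mean_mass_g, tolerance = 1e-12)
})

test_that("noiseless survey reproduces a GTL^b exactly through Eq-1 recovery", {
  cfg <- community_sim_config(n_species = 8, months = 3,
                              dispersion_freshwater = 0,
                              dispersion_seawater = 0,
                              gtl_offset_seawater = 1,
                              juvenile_fraction = 0, seed = 31)
  pool <- simulate_species_pool(cfg)
  sv <- simulate_survey(pool$truth, cfg)
  recovered <- sv$survey$biomass_density / sv$survey$number_density
  idx <- match(sv$survey$species_name, pool$truth$species_name)
  expected <- pool$truth$true_a[idx] * pool$truth$gtl_pop_cm[idx] ^
    pool$truth$true_b[idx]
  expect_equal(recovered, expected, tolerance = 1e-12)
})

test_that("noiseless coefficient reports recover the truth exactly", {
  cfg <- community_sim_config(n_species = 6, a_report_sd = 0,
                              b_report_sd = 0, reports_per_species = 3,
                              seed = 41)
  truth <- simulate_species_pool(cfg)$truth
  lwr <- simulate_coefficient_reports(truth, cfg)
  reps <- representative_coefficients(lwr)
  idx <- match(reps$species_name, tolower(truth$species_name))
  expect_equal(reps$a_rep, truth$true_a[idx], tolerance = 1e-12)
  expect_equal(reps$b_rep, truth$true_b[idx], tolerance = 1e-12)

  # a single report passes through unchanged
  cfg1 <- community_sim_config(n_species = 6, reports_per_species = 1,
                               a_report_sd = 0.3, seed = 41)
  lwr1 <- simulate_coefficient_reports(truth, cfg1)
  reps1 <- representative_coefficients(lwr1)
  expect_equal(reps1$a_rep, lwr1$a[match(reps1$species_name,
                                         tolower(lwr1$species_name))])
})

test_that("geometric-mean bias under report noise matches the analytic value", {
  # E[a_rep] = a * exp(sigma^2 / (2k)) for k lognormal reports of sd sigma
  sigma <- 0.5; k <- 3
  truth <- data.frame(species_name = sprintf("s%04d", 1:3000),
                      true_a = 0.01, true_b = 3,
                      stringsAsFactors = FALSE)
  cfg <- community_sim_config(reports_per_species = k, a_report_sd = sigma,
                              seed = 53)
  lwr <- simulate_coefficient_reports(truth, cfg)
  reps <- representative_coefficients(lwr)
  expect_equal(mean(reps$a_rep), 0.01 * exp(sigma^2 / (2 * k)),
               tolerance = 0.02)
})

test_that("juvenile cohorts depress the pooled mean mass", {
  base <- community_sim_config(n_species = 20, months = 24, seed = 61)
  adult <- simulate_survey(simulate_species_pool(base)$truth, base)
  cont_cfg <- community_sim_config(n_species = 20, months = 24,
                                   juvenile_fraction = 0.3, seed = 61)
  cont <- simulate_survey(simulate_species_pool(cont_cfg)$truth, cont_cfg)
  expect_lt(mean(cont$truth$mean_mass_g), mean(adult$truth$mean_mass_g))
  expect_gt(mean(cont$truth$juvenile_cohort), 0.2)
  expect_lt(mean(cont$truth$juvenile_cohort), 0.4)
})

test_that("concordance degrades with dispersion and contamination", {
  grid_r2 <- function(field, values, seeds = 1:5) {
    sapply(values, function(v) {
      sapply(seeds, function(s) {
        args <- list(gtl_offset_seawater = 1, seed = s)
        if (field == "dispersion") {
          args$dispersion_freshwater <- v
          args$dispersion_seawater <- v
        } else {
          args$juvenile_fraction <- v
        }
        cfg <- do.call(community_sim_config, args)
        res <- suppressMessages(run_full_analysis(list(simulate = cfg)))
        res$reports$r2_identity[res$reports$dataset_label == "whole_raw"]
      })
    })
  }
  r2_disp <- grid_r2("dispersion", c(0.05, 0.3, 0.6))
  mono_disp <- apply(r2_disp, 1, function(r) all(diff(r) <= 0))
  expect_gte(sum(mono_disp), 3)  # majority of seeds

  r2_juv <- grid_r2("juvenile", c(0, 0.2, 0.4))
  mono_juv <- apply(r2_juv, 1, function(r) all(diff(r) <= 0))
  expect_gte(sum(mono_juv), 3)
})
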