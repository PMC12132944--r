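test_that("individual biomass is the density ratio, guarded by preconditions", {
  expect_equal(individual_biomass(5.0, 2.0), 2.5)
  expect_equal(individual_biomass(12.6, 4.0), 3.15)
  expect_equal(individual_biomass(0.0, 3.0), 0.0)  # rejected downstream
  expect_error(individual_biomass(5, 0), "number_density")
  expect_error(individual_biomass(-1, 2), "biomass_density")
})

test_that("representative a is the geometric mean, computed stably in logs", {
  expect_equal(representative_a(c(0.01, 0.04)), 0.02)
  expect_equal(representative_a(0.0123), 0.0123)
  expect_error(representative_a(c(0.01, 0)), "> 0")
  expect_error(representative_a(numeric(0)), "empty")

  set.seed(1)
  for (i in 1:50) {
    a <- exp(rnorm(sample(2:50, 1), -4.6, 1))
    g <- representative_a(a)
    direct <- prod(a)^(1 / length(a))  # independent direct-product oracle
    expect_equal(g, direct, tolerance = 1e-12)
    expect_lte(g, mean(a) * (1 + 1e-12))  # AM-GM
    # scale equivariance
    expect_equal(representative_a(3 * a), 3 * g, tolerance = 1e-12)
  }
  expect_equal(representative_a(rep(0.02, 5)), 0.02)  # AM-GM equality case
})

test_that("representative b is the arithmetic mean", {
  expect_equal(representative_b(c(2.9, 3.1)), 3.0)
  expect_equal(representative_b(3.2), 3.2)
  expect_equal(representative_b(c(3.0, 3.0, 3.6)), 3.2)
  expect_error(representative_b(numeric(0)), "empty")
})

test_that("pooled representatives stay within the per-species record range", {
  set.seed(2)
  lwr <- data.frame(
    species_name = rep(sprintf("sp%02d", 1:8), times = sample(1:5, 8, TRUE)),
    stringsAsFactors = FALSE)
  lwr$a <- exp(rnorm(nrow(lwr), -4.6, 0.5))
  lwr$b <- rnorm(nrow(lwr), 3, 0.1)
  reps <- representative_coefficients(lwr)
  expect_equal(sum(reps$n_sources), nrow(lwr))
  for (i in seq_len(nrow(reps))) {
    sub <- lwr[tolower(lwr$species_name) == reps$species_name[i], ]
    expect_gte(reps$a_rep[i], min(sub$a) * (1 - 1e-12))
    expect_lte(reps$a_rep[i], max(sub$a) * (1 + 1e-12))
    expect_gte(reps$b_rep[i], min(sub$b) - 1e-12)
    expect_lte(reps$b_rep[i], max(sub$b) + 1e-12)
  }
})

test_that("GTL derivation: midpoint rule, small-n exclusion, explicit precedence", {
  profiles <- data.frame(
    species_name = c("mid", "smalln", "explicit", "fieldguide_smalln"),
    habitats = "freshwater",
    gtl_cm = c(NA, NA, 12.3, NA),
    length_min_cm = c(5, 8, 10, 8),
    length_max_cm = c(15, 12, 20, 12),
    sample_n = c(100, 19, 50, 19),
    gtl_source = c("meta-database", "meta-database", "meta-database",
                   "field-guide"),
    stringsAsFactors = FALSE
  )
  g <- suppressMessages(compute_gtl(profiles))
  expect_equal(g$gtl_cm[g$species_name == "mid"], 10)
  # meta-database range with n = 19 < 20 and no fallback: dropped
  expect_true(is.na(g$gtl_cm[g$species_name == "smalln"]))
  expect_match(g$drop_reason[g$species_name == "smalln"], "n = 19")
  # explicit stated average beats a conflicting range
  expect_equal(g$gtl_cm[g$species_name == "explicit"], 12.3)
  expect_equal(g$gtl_basis[g$species_name == "explicit"], "explicit")
  # the small-n rule only applies to meta-database ranges
  expect_equal(g$gtl_cm[g$species_name == "fieldguide_smalln"], 10)
})

test_that("GTL range with unrecorded sample size stays eligible", {
  profiles <- data.frame(
    species_name = "no_n", habitats = "freshwater", gtl_cm = NA,
    length_min_cm = 6, length_max_cm = 10, sample_n = NA,
    gtl_source = "meta-database", stringsAsFactors = FALSE)
  expect_equal(compute_gtl(profiles)$gtl_cm, 8)
})

test_that("weight estimation follows W = a L^b", {
  expect_equal(estimate_weight(0.01, 3, 10), 10.0)
  expect_equal(estimate_weight(0.5, 0, 7), 0.5)
  # log-space evaluation agrees with the direct power form
  expect_equal(estimate_weight(0.0085, 3.1, 12),
               0.0085 * 12^3.1, tolerance = 1e-13)
  expect_error(estimate_weight(0.01, 3, -1), "gtl_cm")

  set.seed(3)
  for (i in 1:25) {
    a <- exp(rnorm(1, -4.6, 1)); b <- runif(1, 2, 4); L <- runif(1, 2, 60)
    expect_equal(estimate_weight(a, b, L), exp(log(a) + b * log(L)))
    # allometry: doubling L multiplies weight by 2^b
    expect_equal(estimate_weight(a, b, 2 * L) / estimate_weight(a, b, L),
                 2^b, tolerance = 1e-12)
    # a single-record species' representatives reproduce its own prediction
    expect_equal(estimate_weight(representative_a(a), representative_b(b), L),
                 estimate_weight(a, b, L), tolerance = 1e-14)
  }
})
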