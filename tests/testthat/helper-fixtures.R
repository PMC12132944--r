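# In-code fixtures shared across test files.

# A tiny fully joined three-species community with hand-checkable numbers.
tiny_tables <- function() {
  survey <- data.frame(
    species_name = c("Zacco platypus", "Carassius auratus", "Mugil cephalus"),
    period = c("M05", "M05", "M06"),
    biomass_density = c(5.0, 12.6, NA),
    number_density = c(2.0, 4.0, NA),
    individual_biomass_g = c(NA, NA, 80),
    stringsAsFactors = FALSE
  )
  lwr <- data.frame(
    species_name = c("Zacco platypus", "Zacco platypus",
                     "Carassius auratus", "Mugil cephalus"),
    a = c(0.01, 0.04, 0.02, 0.0085),
    b = c(2.9, 3.1, 3.0, 3.1),
    source_id = c("s1", "s2", "s3", "s4"),
    stringsAsFactors = FALSE
  )
  profiles <- data.frame(
    species_name = c("Zacco platypus", "Carassius auratus", "Mugil cephalus"),
    habitats = c("freshwater", "freshwater", "seawater|mudflat"),
    gtl_cm = c(NA, 12.3, NA),
    length_min_cm = c(5, 10, 20),
    length_max_cm = c(15, 20, 40),
    sample_n = c(100, 50, 30),
    gtl_source = c("meta-database", "field-guide", "meta-database"),
    stringsAsFactors = FALSE
  )
  list(survey = survey, lwr = lwr, profiles = profiles)
}

write_tiny_tables <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  t <- tiny_tables()
  paths <- list(survey = file.path(dir, "survey.csv"),
                lwr = file.path(dir, "lwr.csv"),
                species = file.path(dir, "species.csv"))
  write.csv(t$survey, paths$survey, row.names = FALSE)
  write.csv(t$lwr, paths$lwr, row.names = FALSE)
  write.csv(t$profiles, paths$species, row.names = FALSE)
  paths
}

# Random paired weight vectors with positive values and non-constant y.
random_pair <- function(n = 20) {
  measured <- exp(rnorm(n, 2, 1))
  estimated <- measured * exp(rnorm(n, 0, 0.5))
  list(measured = measured, estimated = estimated)
}

# Independent brute-force leave-one-out Cook's distances (deletion form).
loo_cooks <- function(x, y) {
  n <- length(x)
  X <- cbind(1, x)
  beta <- solve(crossprod(X), crossprod(X, y))
  fitted_all <- drop(X %*% beta)
  mse <- sum((y - fitted_all)^2) / (n - 2)
  vapply(seq_len(n), function(i) {
    Xi <- X[-i, , drop = FALSE]
    bi <- solve(crossprod(Xi), crossprod(Xi, y[-i]))
    fit_i <- drop(X %*% bi)  # predictions for all n points
    sum((fitted_all - fit_i)^2) / (2 * mse)
  }, numeric(1))
}
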