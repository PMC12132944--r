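#' Pair field-measured with LWR-estimated weights per survey record
#'
#' Joins the three ingested tables into the unit of all concordance
#' analyses: one (measured, estimated) pair per usable survey record.
#' The measured weight is the record's direct individual biomass when
#' present, otherwise biomass density / number density
#' ([individual_biomass()]); the estimated weight is
#' `a_rep * GTL^b_rep` from the species' representative coefficients and
#' GTL. Species matching is exact on the trimmed, case-folded name.
#' Records that cannot be paired (species without a usable GTL, without
#' any LWR record, outside the analysis habitat groups, or with a
#' non-positive weight on either side) are dropped with a per-cause
#' count, never silently.
#'
#' @param survey data.frame from [read_field_survey_table()].
#' @param lwr data.frame from [read_lwr_table()].
#' @param profiles data.frame from [read_species_table()].
#' @param min_sample_n passed to [compute_gtl()].
#' @return list with `points` (data.frame: `species_name`,
#'   `habitat_group`, `period`, `measured_g`, `estimated_g`, `gtl_cm`,
#'   `a_rep`, `b_rep`) and `dropped` (data.frame of `reason`, `n`).
#' @export
build_paired_points <- function(survey, lwr, profiles, min_sample_n = 20) {
  groups <- classify_habitat_groups(profiles)
  gtl <- compute_gtl(profiles, min_sample_n = min_sample_n)
  reps <- representative_coefficients(lwr)

  key <- normalize_species(survey$species_name)
  gi <- match(key, groups$species_name)
  ti <- match(key, gtl$species_name)
  ci <- match(key, reps$species_name)

  n <- nrow(survey)
  measured <- rep(NA_real_, n)
  direct <- !is.na(survey$individual_biomass_g)
  measured[direct] <- survey$individual_biomass_g[direct]
  calc <- !direct & !is.na(survey$biomass_density) &
    !is.na(survey$number_density) & survey$number_density > 0
  measured[calc] <- survey$biomass_density[calc] / survey$number_density[calc]

  reason <- rep(NA_character_, n)
  no_profile <- is.na(gi)
  reason[no_profile] <- "species missing from profile table"
  off_scope <- !no_profile &
    !(groups$habitat_group[gi] %in% c("only_freshwater", "only_seawater_mud"))
  reason[is.na(reason) & off_scope] <- "species in mixed/no-record habitat group"
  no_gtl <- !no_profile & (is.na(ti) | is.na(gtl$gtl_cm[ti]))
  reason[is.na(reason) & no_gtl] <- "species without a usable GTL"
  no_coef <- is.na(ci)
  reason[is.na(reason) & no_coef] <- "species without LWR coefficients"
  bad_meas <- is.na(measured) | !is.finite(measured) | measured <= 0
  reason[is.na(reason) & bad_meas] <- "non-positive or missing measured weight"

  usable <- is.na(reason)
  if (!any(usable)) {
    tab <- table(reason[!usable])
    stop("no usable paired points; drop causes: ",
         paste(sprintf("%s (%d)", names(tab), as.integer(tab)),
               collapse = "; "))
  }
  est <- rep(NA_real_, n)
  est[usable] <- estimate_weight(reps$a_rep[ci[usable]],
                                 reps$b_rep[ci[usable]],
                                 gtl$gtl_cm[ti[usable]])
  bad_est <- usable & (!is.finite(est) | est <= 0)
  reason[bad_est] <- "non-positive estimated weight"
  usable <- is.na(reason)

  points <- data.frame(
    species_name = key[usable],
    habitat_group = groups$habitat_group[gi[usable]],
    period = as.character(survey$period[usable]),
    measured_g = measured[usable],
    estimated_g = est[usable],
    gtl_cm = gtl$gtl_cm[ti[usable]],
    a_rep = reps$a_rep[ci[usable]],
    b_rep = reps$b_rep[ci[usable]],
    stringsAsFactors = FALSE
  )
  rownames(points) <- NULL
  tab <- table(reason[!usable])
  dropped <- data.frame(reason = names(tab), n = as.integer(tab),
                        stringsAsFactors = FALSE)
  for (i in seq_len(nrow(dropped))) {
    message(sprintf("dropped %d survey record(s): %s",
                    dropped$n[i], dropped$reason[i]))
  }
  list(points = points, dropped = dropped)
}

#' Build the six analysis dataset variants
#'
#' Three habitat scopes (freshwater-only, seawater/mudflat-only, and
#' their union "whole") each in a raw and a Q-filtered version. The
#' whole-species scope is the multiset union of the two habitat scopes'
#' points and derives its own Q scores from that union (it does not
#' inherit the per-scope Q decisions). Mixed and no-record species never
#' enter any variant.
#'
#' @param points paired points from [build_paired_points()].
#' @param q_threshold Q threshold (default 6).
#' @return named list of variants; each has `label`, `scope`,
#'   `q_filtered`, `points`, and for filtered variants `q_removed` (the
#'   removed points with their Q scores).
#' @export
make_dataset_variants <- function(points, q_threshold = 6) {
  scopes <- list(
    freshwater = points[points$habitat_group == "only_freshwater", ,
                        drop = FALSE],
    seawater = points[points$habitat_group == "only_seawater_mud", ,
                      drop = FALSE],
    whole = points[points$habitat_group %in%
                     c("only_freshwater", "only_seawater_mud"), ,
                   drop = FALSE]
  )
  out <- list()
  for (sc in names(scopes)) {
    pts <- scopes[[sc]]
    rownames(pts) <- NULL
    out[[paste0(sc, "_raw")]] <- list(
      label = paste0(sc, "_raw"), scope = sc, q_filtered = FALSE,
      points = pts)
    fq <- if (nrow(pts) > 0) filter_q(pts, q_threshold) else {
      list(kept = pts, removed = pts)
    }
    out[[paste0(sc, "_qfiltered")]] <- list(
      label = paste0(sc, "_qfiltered"), scope = sc, q_filtered = TRUE,
      points = fq$kept, q_removed = fq$removed)
  }
  out
}

#' Concordance statistics for one dataset variant
#'
#' Computes the four R-squared summaries used to score a variant:
#' \itemize{
#'   \item regression R^2 of the OLS fit on all points (trend
#'     consistency),
#'   \item identity-line R^2 against y = x on all points (absolute
#'     agreement),
#'   \item the same two after removing influential points flagged by
#'     Cook's distance (recomputed on this variant's own point set),
#' }
#' plus the slope/intercept of the all-points and influential-removed
#' regression lines and RMSE/MAE for both the identity-line and the
#' fitted-line model, before and after removal. Variants with fewer than
#' `min_points` points (or left with fewer after removal) are returned
#' flagged `degenerate` with NA statistics instead of erroring, so
#' synthetic sweeps never abort.
#'
#' @param variant one element of [make_dataset_variants()]'s list (or any
#'   list with `label` and `points`).
#' @param cooks_rule influence rule, see [filter_influential()].
#' @param min_points minimum usable points (default 4).
#' @return one-row data.frame (a concordance report).
#' @export
evaluate_variant <- function(variant, cooks_rule = list(rule = "4n"),
                             min_points = 4) {
  pts <- variant$points
  na_report <- function(n, n_removed = NA_integer_) data.frame(
    dataset_label = variant$label, n_points = n,
    slope = NA_real_, intercept = NA_real_,
    r2_regression = NA_real_, r2_identity = NA_real_,
    rmse_identity = NA_real_, mae_identity = NA_real_,
    rmse_regression = NA_real_, mae_regression = NA_real_,
    n_influential = n_removed,
    slope_removed = NA_real_, intercept_removed = NA_real_,
    r2_regression_removed = NA_real_, r2_identity_removed = NA_real_,
    rmse_identity_removed = NA_real_, mae_identity_removed = NA_real_,
    rmse_regression_removed = NA_real_, mae_regression_removed = NA_real_,
    degenerate = TRUE, stringsAsFactors = FALSE)
  if (is.null(pts) || nrow(pts) < min_points) {
    return(na_report(if (is.null(pts)) 0L else nrow(pts)))
  }
  x <- pts$estimated_g
  y <- pts$measured_g
  fit_all <- ols_fit(x, y)
  rep_all <- data.frame(
    dataset_label = variant$label, n_points = nrow(pts),
    slope = fit_all$slope, intercept = fit_all$intercept,
    r2_regression = fit_all$r2, r2_identity = yx_r2(y, x),
    rmse_identity = rmse(y, x), mae_identity = mae(y, x),
    rmse_regression = rmse(y, fit_all$fitted),
    mae_regression = mae(y, fit_all$fitted),
    stringsAsFactors = FALSE)

  fi <- filter_influential(pts, rule = cooks_rule)
  kept <- fi$kept
  if (nrow(kept) < min_points || length(unique(kept$estimated_g)) < 2) {
    out <- cbind(rep_all, data.frame(
      n_influential = nrow(fi$removed),
      slope_removed = NA_real_, intercept_removed = NA_real_,
      r2_regression_removed = NA_real_, r2_identity_removed = NA_real_,
      rmse_identity_removed = NA_real_, mae_identity_removed = NA_real_,
      rmse_regression_removed = NA_real_, mae_regression_removed = NA_real_,
      degenerate = TRUE, stringsAsFactors = FALSE))
    return(out)
  }
  fit_k <- ols_fit(kept$estimated_g, kept$measured_g)
  cbind(rep_all, data.frame(
    n_influential = nrow(fi$removed),
    slope_removed = fit_k$slope, intercept_removed = fit_k$intercept,
    r2_regression_removed = fit_k$r2,
    r2_identity_removed = yx_r2(kept$measured_g, kept$estimated_g),
    rmse_identity_removed = rmse(kept$measured_g, kept$estimated_g),
    mae_identity_removed = mae(kept$measured_g, kept$estimated_g),
    rmse_regression_removed = rmse(kept$measured_g, fit_k$fitted),
    mae_regression_removed = mae(kept$measured_g, fit_k$fitted),
    degenerate = FALSE, stringsAsFactors = FALSE))
}

#' Per-point audit table for one variant
#' @keywords internal
audit_variant <- function(variant, cooks_rule) {
  pts <- variant$points
  base_cols <- c("species_name", "period", "habitat_group",
                 "measured_g", "estimated_g")
  empty <- data.frame(dataset_label = character(), species_name = character(),
                      period = character(), habitat_group = character(),
                      measured_g = numeric(), estimated_g = numeric(),
                      q = numeric(), q_removed = logical(),
                      cooks_d = numeric(), influential = logical(),
                      stringsAsFactors = FALSE)
  rows <- list()
  if (!is.null(pts) && nrow(pts) > 0) {
    qs <- q_scores(pts$measured_g, pts$estimated_g)
    cd <- rep(NA_real_, nrow(pts))
    infl <- rep(NA, nrow(pts))
    if (nrow(pts) >= 4 && length(unique(pts$estimated_g)) >= 2) {
      fi <- filter_influential(pts, rule = cooks_rule)
      cd <- fi$d
      infl <- rep(FALSE, nrow(pts))
      if (nrow(fi$removed) > 0) {
        if (is.na(fi$cutoff)) {
          infl[order(cd, decreasing = TRUE)[seq_len(nrow(fi$removed))]] <- TRUE
        } else {
          infl <- cd > fi$cutoff
        }
      }
    }
    rows[[1]] <- data.frame(dataset_label = variant$label,
                            pts[, base_cols], q = qs$q, q_removed = FALSE,
                            cooks_d = cd, influential = infl,
                            stringsAsFactors = FALSE)
  }
  qr <- variant$q_removed
  if (!is.null(qr) && nrow(qr) > 0) {
    rows[[length(rows) + 1]] <- data.frame(
      dataset_label = variant$label, qr[, base_cols], q = qr$q,
      q_removed = TRUE, cooks_d = NA_real_, influential = NA,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full concordance study
#'
#' End-to-end driver: ingests the three input tables (or generates them
#' from a simulation scenario), pairs measured with estimated weights,
#' builds the six dataset variants, evaluates each, and writes
#' `reports.csv` (+ `.json`), `audit_points.csv` and `manifest.json` to
#' `out_dir` when given. Deterministic: the same configuration and seed
#' produce byte-identical outputs.
#'
#' The configuration list understands:
#' \describe{
#'   \item{inputs}{list with `survey`, `lwr`, `species` file paths and
#'     optional per-table `dialects`.}
#'   \item{simulate}{a [community_sim_config()] list; used when `inputs`
#'     is absent.}
#'   \item{q_threshold}{Q outlier threshold, default 6.}
#'   \item{cooks_rule}{influence rule, default `list(rule = "4n")`.}
#'   \item{min_sample_n}{GTL range eligibility, default 20.}
#'   \item{seed}{integer seed for simulation scenarios.}
#'   \item{out_dir}{output directory (optional).}
#' }
#'
#' @param config named list (or a path via [load_config()]).
#' @return list with `reports` (6-row data.frame), `audit` (per-point
#'   table), `points`, `dropped`, `manifest`.
#' @export
run_full_analysis <- function(config) {
  if (is.character(config)) config <- load_config(config)
  q_threshold <- config$q_threshold %||% 6
  cooks_rule <- config$cooks_rule %||% list(rule = "4n")
  min_sample_n <- config$min_sample_n %||% 20

  if (!is.null(config$inputs)) {
    dial <- config$inputs$dialects %||% list()
    survey <- read_field_survey_table(config$inputs$survey, dial$survey)
    lwr <- read_lwr_table(config$inputs$lwr, dial$lwr)
    profiles <- read_species_table(config$inputs$species, dial$species)
  } else if (!is.null(config$simulate)) {
    sim_cfg <- do.call(community_sim_config, config$simulate)
    if (!is.null(config$seed)) sim_cfg$seed <- config$seed
    sim <- simulate_community(sim_cfg)
    survey <- sim$survey
    lwr <- sim$lwr
    profiles <- sim$profiles
  } else {
    stop("config needs either $inputs (file paths) or $simulate (scenario)")
  }

  paired <- build_paired_points(survey, lwr, profiles,
                                min_sample_n = min_sample_n)
  variants <- make_dataset_variants(paired$points, q_threshold = q_threshold)
  reports <- do.call(rbind, lapply(variants, evaluate_variant,
                                   cooks_rule = cooks_rule))
  rownames(reports) <- NULL
  audit <- do.call(rbind, lapply(variants, audit_variant,
                                 cooks_rule = cooks_rule))
  rownames(audit) <- NULL

  manifest <- list(
    package = "gtlbiomass",
    q_threshold = q_threshold,
    cooks_rule = cooks_rule,
    min_sample_n = min_sample_n,
    seed = config$seed %||% NA,
    config_hash = hash_config(config),
    n_input_records = nrow(survey),
    n_paired_points = nrow(paired$points),
    dropped = paired$dropped,
    n_q_removed = vapply(
      variants[grepl("qfiltered", names(variants))],
      function(v) nrow(v$q_removed %||% data.frame()), integer(1))
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report(reports, file.path(config$out_dir, "reports.csv"))
    utils::write.csv(audit, file.path(config$out_dir, "audit_points.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows", na = "null")
  }
  list(reports = reports, audit = audit, points = paired$points,
       dropped = paired$dropped, manifest = manifest)
}

#' Stable hash of a configuration (for the run manifest)
#'
#' Canonicalizes the configuration to sorted-key JSON, excluding the
#' output directory (which does not affect results), and hashes it with
#' MD5 so identical analytic settings yield identical manifests.
#' @keywords internal
hash_config <- function(config) {
  cfg <- config[setdiff(names(config), "out_dir")]
  cfg <- cfg[order(names(cfg))]
  js <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(js), tf)
  unname(tools::md5sum(tf))
}
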