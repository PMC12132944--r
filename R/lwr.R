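#' Per-individual biomass from survey densities
#'
#' Field surveys report standing stock as a biomass density (g/m^2) and a
#' number density (ind/m^2); their ratio is the mean per-individual
#' biomass for that species in that survey period. Applied once per
#' species x period record; records are never pooled across periods
#' before pairing.
#'
#' @param biomass_density g/m^2, >= 0. Vectorized.
#' @param number_density ind/m^2, > 0. Vectorized.
#' @return per-individual biomass in g.
#' @export
#' @examples
#' individual_biomass(5, 2)     # 2.5 g
#' individual_biomass(12.6, 4)  # 3.15 g
individual_biomass <- function(biomass_density, number_density) {
  if (any(!is.finite(number_density)) || any(number_density <= 0)) {
    stop("number_density must be finite and > 0")
  }
  if (any(!is.finite(biomass_density)) || any(biomass_density < 0)) {
    stop("biomass_density must be finite and >= 0")
  }
  biomass_density / number_density
}

#' Representative LWR scale coefficient: geometric mean of a
#'
#' When several published (a, b) pairs exist for a species, the
#' representative a is the geometric mean of the a values. Computed as
#' `exp(mean(log(a)))` to avoid underflow at the typical magnitudes
#' (a ~ 1e-3 to 1e-2 g cm^-b).
#'
#' @param a_values positive numeric vector.
#' @return geometric mean.
#' @export
#' @examples
#' representative_a(c(0.01, 0.04))  # 0.02
representative_a <- function(a_values) {
  if (length(a_values) == 0) stop("empty coefficient list")
  if (any(!is.finite(a_values)) || any(a_values <= 0)) {
    stop("all a values must be finite and > 0")
  }
  exp(mean(log(a_values)))
}

#' Representative allometric exponent: arithmetic mean of b
#'
#' @param b_values finite numeric vector.
#' @return arithmetic mean.
#' @export
#' @examples
#' representative_b(c(2.9, 3.1))  # 3.0
representative_b <- function(b_values) {
  if (length(b_values) == 0) stop("empty coefficient list")
  if (any(!is.finite(b_values))) stop("all b values must be finite")
  mean(b_values)
}

#' Pool published LWR records into per-species representative coefficients
#'
#' @param lwr data.frame with `species_name`, `a`, `b` (one row per
#'   published record; see [read_lwr_table()]).
#' @return data.frame with one row per species: `species_name` (canonical
#'   key), `a_rep` (geometric mean), `b_rep` (arithmetic mean),
#'   `n_sources`.
#' @export
representative_coefficients <- function(lwr) {
  stopifnot(all(c("species_name", "a", "b") %in% names(lwr)))
  key <- normalize_species(lwr$species_name)
  split_idx <- split(seq_len(nrow(lwr)), key)
  out <- data.frame(
    species_name = names(split_idx),
    a_rep = vapply(split_idx, function(i) representative_a(lwr$a[i]),
                   numeric(1)),
    b_rep = vapply(split_idx, function(i) representative_b(lwr$b[i]),
                   numeric(1)),
    n_sources = vapply(split_idx, length, integer(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Derive the General Total Length (GTL) for each species profile
#'
#' The GTL is the single representative total length per species. An
#' explicitly recorded GTL (a stated average, typically from a field
#' guide) takes precedence. Otherwise the GTL is the midpoint of the
#' recorded min-max length range; a meta-database range backed by a small
#' sample (n < `min_sample_n`, default 20) is ineligible and, with no
#' other source, the species is dropped with a logged reason. Ranges with
#' no recorded n are treated as eligible.
#'
#' @param profiles data.frame of species profiles (see
#'   [read_species_table()]).
#' @param min_sample_n minimum sample size backing a meta-database range.
#' @return data.frame with `species_name` (canonical), `gtl_cm` (NA when
#'   dropped), `gtl_basis` (`"explicit"`, `"midpoint"` or `"dropped"`) and
#'   `drop_reason`.
#' @export
compute_gtl <- function(profiles, min_sample_n = 20) {
  stopifnot(is.data.frame(profiles), "species_name" %in% names(profiles))
  n <- nrow(profiles)
  get <- function(col) if (col %in% names(profiles)) profiles[[col]] else rep(NA_real_, n)
  gtl <- get("gtl_cm")
  lmin <- get("length_min_cm")
  lmax <- get("length_max_cm")
  nref <- get("sample_n")
  src <- if ("gtl_source" %in% names(profiles)) {
    as.character(profiles$gtl_source)
  } else rep(NA_character_, n)

  out_gtl <- rep(NA_real_, n)
  basis <- rep("dropped", n)
  reason <- rep("", n)
  for (i in seq_len(n)) {
    if (!is.na(gtl[i]) && gtl[i] > 0) {
      out_gtl[i] <- gtl[i]
      basis[i] <- "explicit"
      next
    }
    if (!is.na(lmin[i]) && !is.na(lmax[i]) && lmin[i] > 0 &&
        lmax[i] >= lmin[i]) {
      meta <- !is.na(src[i]) && identical(tolower(src[i]), "meta-database")
      if (meta && !is.na(nref[i]) && nref[i] < min_sample_n) {
        reason[i] <- sprintf(
          "meta-database range backed by n = %d < %d and no other source",
          as.integer(nref[i]), as.integer(min_sample_n))
        message(sprintf("dropped species '%s': %s",
                        profiles$species_name[i], reason[i]))
        next
      }
      out_gtl[i] <- (lmin[i] + lmax[i]) / 2
      basis[i] <- "midpoint"
      next
    }
    reason[i] <- "no eligible GTL source"
    message(sprintf("dropped species '%s': %s",
                    profiles$species_name[i], reason[i]))
  }
  data.frame(species_name = normalize_species(profiles$species_name),
             gtl_cm = out_gtl, gtl_basis = basis, drop_reason = reason,
             stringsAsFactors = FALSE)
}

#' Allometric weight estimate from representative coefficients and GTL
#'
#' The standard length-weight relationship W = a * L^b with L the General
#' Total Length in cm and W in g; evaluated in log space
#' (`exp(log(a) + b * log(L))`) for numerical stability. Strictly
#' increasing in L when b > 0.
#'
#' @param a_rep scale coefficient, > 0 (g cm^-b).
#' @param b_rep allometric exponent (dimensionless).
#' @param gtl_cm length in cm, > 0. Vectorized (recycled with a/b).
#' @return estimated weight in g.
#' @export
#' @examples
#' estimate_weight(0.01, 3, 10)  # 10 g
estimate_weight <- function(a_rep, b_rep, gtl_cm) {
  if (any(!is.finite(gtl_cm)) || any(gtl_cm <= 0)) {
    stop("gtl_cm must be finite and > 0")
  }
  if (any(!is.finite(a_rep)) || any(a_rep <= 0)) {
    stop("a_rep must be finite and > 0")
  }
  exp(log(a_rep) + b_rep * log(gtl_cm))
}
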