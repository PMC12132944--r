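#' Read a delimited table (comma or tab), auto-detecting the separator
#' @keywords internal
read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "", fill = TRUE)
}

#' Apply a column dialect to a raw table
#'
#' A dialect is a named character vector or list mapping logical field
#' names to the physical column headers of a particular file, so one
#' reader serves both the compiled-literature spreadsheets (exported to
#' CSV) and synthetic tables. Logical fields absent from the dialect are
#' looked up under their own name.
#'
#' @param raw data.frame as read from disk.
#' @param dialect named character vector/list, logical -> physical name.
#' @param fields character vector of logical field names to extract.
#' @param required character vector of fields that must be present.
#' @keywords internal
apply_dialect <- function(raw, dialect, fields, required) {
  dialect <- as.list(dialect %||% list())
  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (f in fields) {
    phys <- dialect[[f]] %||% f
    out[[f]] <- if (phys %in% names(raw)) raw[[phys]] else NA
  }
  miss <- required[!vapply(required, function(f) {
    (dialect[[f]] %||% f) %in% names(raw)
  }, logical(1))]
  if (length(miss) > 0) {
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Collect per-row validation failures
#' @keywords internal
reject_rows <- function(df, bad, reason, rejected) {
  if (any(bad)) {
    rejected <- rbind(rejected, data.frame(row = which(bad), reason = reason,
                                           stringsAsFactors = FALSE))
    for (i in which(bad)) {
      message(sprintf("rejected row %d: %s", i, reason))
    }
  }
  rejected
}

finalize_read <- function(df, rejected, n_input) {
  keep <- setdiff(seq_len(n_input), rejected$row)
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  rejected <- rejected[order(rejected$row), , drop = FALSE]
  rownames(rejected) <- NULL
  attr(out, "rejected") <- rejected
  stopifnot(nrow(out) + length(unique(rejected$row)) == n_input)
  out
}

#' Read a field-survey table
#'
#' Each row is one species x period (typically month) survey record. A row
#' must carry either a direct per-individual biomass, or both a biomass
#' density (g/m^2, >= 0) and a number density (ind/m^2, > 0) from which the
#' per-individual biomass is later derived. Invalid rows are rejected with
#' a logged reason and reported in the `"rejected"` attribute, never
#' silently dropped.
#'
#' @param path delimited text file (comma or tab separated).
#' @param dialect optional named mapping of logical fields
#'   (`species_name`, `period`, `biomass_density`, `number_density`,
#'   `individual_biomass_g`) to the file's column headers.
#' @return data.frame of validated records with canonical column names;
#'   attribute `"rejected"` holds a data.frame of `row`/`reason` pairs.
#' @export
read_field_survey_table <- function(path, dialect = NULL) {
  raw <- read_delim_auto(path)
  fields <- c("species_name", "period", "biomass_density",
              "number_density", "individual_biomass_g")
  df <- apply_dialect(raw, dialect, fields, required = "species_name")
  for (f in fields[-(1:2)]) df[[f]] <- suppressWarnings(as.numeric(df[[f]]))
  rejected <- data.frame(row = integer(), reason = character(),
                         stringsAsFactors = FALSE)

  df$species_name <- as.character(df$species_name)
  bad_name <- is.na(df$species_name) | !nzchar(trimws(df$species_name))
  rejected <- reject_rows(df, bad_name, "empty species name", rejected)

  direct <- !is.na(df$individual_biomass_g)
  has_dens <- !is.na(df$biomass_density) & !is.na(df$number_density)
  bad_source <- !bad_name & !direct & !has_dens
  rejected <- reject_rows(df, bad_source,
                          "neither direct biomass nor both densities present",
                          rejected)
  bad_dens <- !bad_name & !direct & has_dens &
    (df$number_density <= 0 | df$biomass_density < 0)
  rejected <- reject_rows(df, bad_dens,
                          "number density must be > 0 and biomass density >= 0",
                          rejected)
  bad_direct <- !bad_name & direct &
    (!is.finite(df$individual_biomass_g) | df$individual_biomass_g < 0)
  rejected <- reject_rows(df, bad_direct,
                          "direct individual biomass must be finite and >= 0",
                          rejected)
  finalize_read(df, rejected, nrow(df))
}

#' Read a length-weight coefficient table
#'
#' One row per published (a, b) pair for a species; several rows per
#' species are expected and are later pooled into representative
#' coefficients. Coefficients follow the allometric convention
#' W = a * TL^b with TL in cm and W in g. Rows with a <= 0 are rejected
#' (the geometric mean requires positivity); b outside the plausible
#' allometric range [2, 4] triggers a warning but is kept.
#'
#' @inheritParams read_field_survey_table
#' @return data.frame with `species_name`, `a`, `b`, `source_id`;
#'   attribute `"rejected"` as in [read_field_survey_table()].
#' @export
read_lwr_table <- function(path, dialect = NULL) {
  raw <- read_delim_auto(path)
  fields <- c("species_name", "a", "b", "source_id")
  df <- apply_dialect(raw, dialect, fields,
                      required = c("species_name", "a", "b"))
  df$a <- suppressWarnings(as.numeric(df$a))
  df$b <- suppressWarnings(as.numeric(df$b))
  rejected <- data.frame(row = integer(), reason = character(),
                         stringsAsFactors = FALSE)
  df$species_name <- as.character(df$species_name)
  bad_name <- is.na(df$species_name) | !nzchar(trimws(df$species_name))
  rejected <- reject_rows(df, bad_name, "empty species name", rejected)
  bad_a <- !bad_name & (is.na(df$a) | !is.finite(df$a) | df$a <= 0)
  rejected <- reject_rows(df, bad_a, "coefficient a must be finite and > 0",
                          rejected)
  bad_b <- !bad_name & (is.na(df$b) | !is.finite(df$b))
  rejected <- reject_rows(df, bad_b, "coefficient b must be finite", rejected)
  odd_b <- !bad_name & !bad_b & (df$b < 2 | df$b > 4)
  if (any(odd_b)) {
    warning(sprintf("%d LWR record(s) with b outside [2, 4]; kept",
                    sum(odd_b)))
  }
  finalize_read(df, rejected, nrow(df))
}

#' Read a species profile table (habitat and length information)
#'
#' Each species carries a habitat set (see [classify_habitat_groups()])
#' and its representative-length information: either an explicit General
#' Total Length (GTL, cm) or a (min length, max length, n) triple whose
#' midpoint supplies the GTL (see [compute_gtl()]). Rows lacking both are
#' rejected; all lengths must be strictly positive.
#'
#' @inheritParams read_field_survey_table
#' @return data.frame with `species_name`, `habitats`, `gtl_cm`,
#'   `length_min_cm`, `length_max_cm`, `sample_n`, `gtl_source`;
#'   attribute `"rejected"` as in [read_field_survey_table()].
#' @export
read_species_table <- function(path, dialect = NULL) {
  raw <- read_delim_auto(path)
  fields <- c("species_name", "habitats", "gtl_cm", "length_min_cm",
              "length_max_cm", "sample_n", "gtl_source")
  df <- apply_dialect(raw, dialect, fields,
                      required = c("species_name", "habitats"))
  for (f in c("gtl_cm", "length_min_cm", "length_max_cm", "sample_n")) {
    df[[f]] <- suppressWarnings(as.numeric(df[[f]]))
  }
  rejected <- data.frame(row = integer(), reason = character(),
                         stringsAsFactors = FALSE)
  df$species_name <- as.character(df$species_name)
  bad_name <- is.na(df$species_name) | !nzchar(trimws(df$species_name))
  rejected <- reject_rows(df, bad_name, "empty species name", rejected)
  has_gtl <- !is.na(df$gtl_cm)
  has_range <- !is.na(df$length_min_cm) & !is.na(df$length_max_cm)
  bad_len <- !bad_name & !has_gtl & !has_range
  rejected <- reject_rows(df, bad_len,
                          "needs an explicit GTL or a min/max length range",
                          rejected)
  nonpos <- function(v) !is.na(v) & v <= 0
  bad_pos <- !bad_name & (nonpos(df$gtl_cm) | nonpos(df$length_min_cm) |
                            nonpos(df$length_max_cm))
  rejected <- reject_rows(df, bad_pos, "lengths must be strictly positive",
                          rejected)
  bad_order <- !bad_name & has_range & !nonpos(df$length_min_cm) &
    !nonpos(df$length_max_cm) & df$length_min_cm > df$length_max_cm
  rejected <- reject_rows(df, bad_order, "min length exceeds max length",
                          rejected)
  finalize_read(df, rejected, nrow(df))
}

#' Write concordance reports to disk
#'
#' Writes a tidy delimited table (`path`) plus a machine-readable JSON
#' summary alongside it (`<path>.json`). Numeric columns are serialized
#' with 17 significant digits so that [read_report()] round-trips the
#' table to full double precision.
#'
#' @param reports data.frame of concordance reports (one row per dataset
#'   variant), as produced by [evaluate_variant()]/[run_full_analysis()].
#' @param path output CSV path.
#' @return invisibly, the paths written.
#' @export
write_report <- function(reports, path) {
  stopifnot(is.data.frame(reports))
  out <- reports
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) {
      out[[j]] <- vapply(out[[j]], function(v) {
        if (is.na(v)) NA_character_ else sprintf("%.17g", v)
      }, character(1))
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  json_path <- paste0(path, ".json")
  jsonlite::write_json(reports, json_path, dataframe = "rows", digits = NA,
                       na = "null", auto_unbox = TRUE, pretty = TRUE)
  invisible(c(csv = path, json = json_path))
}

#' Read back a concordance report table written by [write_report()]
#' @param path CSV path previously written by [write_report()].
#' @return data.frame with numeric columns restored to full precision.
#' @export
read_report <- function(path) {
  # 17-significant-digit decimal strings parse back to the identical double,
  # so base type inference restores the table exactly.
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                  na.strings = "")
}

#' Load a pipeline configuration file (YAML or JSON)
#'
#' The configuration carries input paths and column dialects, the Q
#' threshold, the Cook's-distance rule, scopes and the seed; values left
#' out fall back to the pipeline defaults (see [run_full_analysis()]).
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON configuration file.
#' @return named list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}
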