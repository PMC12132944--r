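#' @keywords internal
"_PACKAGE"

HABITAT_LABELS <- c("freshwater", "seawater", "mudflat", "estuary")
HABITAT_GROUPS <- c("only_freshwater", "only_seawater_mud", "mixed", "no_record")

#' Parse a habitat label set
#'
#' Habitat sets arrive as a single string per species with labels separated
#' by `|`, `;` or `,` (e.g. `"freshwater|estuary"`), or the literal marker
#' `"unrecorded"`. Labels are trimmed and case-folded.
#'
#' @param x character vector, one habitat-set string per species.
#' @return list of character vectors; the marker `"unrecorded"` stays a
#'   length-1 vector.
#' @keywords internal
parse_habitats <- function(x) {
  lapply(as.character(x), function(s) {
    s <- tolower(trimws(s))
    if (is.na(s) || !nzchar(s) || s == "unrecorded" || s == "no record") {
      return("unrecorded")
    }
    labs <- unique(trimws(strsplit(s, "[|;,]")[[1]]))
    labs <- labs[nzchar(labs)]
    bad <- setdiff(labs, HABITAT_LABELS)
    if (length(bad) > 0) {
      stop("unknown habitat label(s): ", paste(bad, collapse = ", "))
    }
    if (length(labs) == 0) "unrecorded" else labs
  })
}

#' Assign each species to its analysis habitat group
#'
#' Species are partitioned into the four analysis groups used to stratify
#' the concordance analysis:
#' \describe{
#'   \item{only_freshwater}{habitat set is exactly \{freshwater\}}
#'   \item{only_seawater_mud}{non-empty subset of \{seawater, mudflat\}}
#'   \item{mixed}{any set spanning the freshwater and marine/estuarine
#'     sides, or containing estuary (estuary-only species are treated as
#'     mixed and flagged in the returned log)}
#'   \item{no_record}{habitat marked unrecorded}
#' }
#' The assignment is deterministic and total: every valid profile lands in
#' exactly one group.
#'
#' @param profiles data.frame with at least `species_name` and `habitats`
#'   columns (see [read_species_table()]).
#' @return data.frame with columns `species_name`, `habitat_group`, `note`
#'   (non-empty where a convention was applied, e.g. estuary-only).
#' @export
#' @examples
#' p <- data.frame(species_name = c("A", "B", "C", "D"),
#'                 habitats = c("freshwater", "seawater|mudflat",
#'                              "freshwater|seawater", "unrecorded"))
#' classify_habitat_groups(p)
classify_habitat_groups <- function(profiles) {
  stopifnot(is.data.frame(profiles),
            all(c("species_name", "habitats") %in% names(profiles)))
  sets <- parse_habitats(profiles$habitats)
  grp <- character(length(sets))
  note <- character(length(sets))
  for (i in seq_along(sets)) {
    s <- sets[[i]]
    if (identical(s, "unrecorded")) {
      grp[i] <- "no_record"
    } else if (length(s) == 1 && s == "freshwater") {
      grp[i] <- "only_freshwater"
    } else if (all(s %in% c("seawater", "mudflat"))) {
      grp[i] <- "only_seawater_mud"
    } else {
      grp[i] <- "mixed"
      if (identical(s, "estuary")) {
        note[i] <- "estuary-only species treated as mixed"
      }
    }
  }
  data.frame(species_name = normalize_species(profiles$species_name),
             habitat_group = grp,
             note = note,
             stringsAsFactors = FALSE)
}

#' Canonical species key
#'
#' Matching across the survey, coefficient and species tables is exact on
#' the trimmed, case-folded name; no fuzzy matching.
#' @param x character vector of species names.
#' @return character vector of canonical keys.
#' @keywords internal
normalize_species <- function(x) {
  tolower(trimws(as.character(x)))
}
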