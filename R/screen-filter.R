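# IUPAC 2021 standard atomic weights (conventional values for interval
# elements), g/mol. Covers the elements of a drug-like screening library.
ATOMIC_MASSES <- c(
  H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.990, Mg = 24.305, Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45,
  K = 39.098, Ca = 40.078, Se = 78.971, Br = 79.904, I = 126.904
)

#' Molecular mass from a Hill-notation formula
#'
#' Sums standard atomic weights times element counts, e.g. `"C12H22O11"`
#' gives 342.30 g/mol (sucrose).
#'
#' @param formula Hill-notation formula string.
#' @return mass in g/mol.
#' @export
mass_from_formula <- function(formula) {
  if (length(formula) != 1L || !is.character(formula) || !nzchar(trimws(formula)))
    stop("formula must be a single non-empty string")
  f <- trimws(formula)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f, perl = TRUE)[[1L]]
  tokens <- regmatches(f, list(m))[[1L]]
  if (sum(nchar(tokens)) != nchar(f))
    stop("malformed formula string: ", formula)
  total <- 0
  for (tok in tokens) {
    el <- sub("[0-9]*$", "", tok)
    cnt <- sub("^[A-Za-z]+", "", tok)
    cnt <- if (nzchar(cnt)) as.integer(cnt) else 1L
    if (!el %in% names(ATOMIC_MASSES))
      stop("unknown element symbol '", el, "' in formula ", formula)
    total <- total + ATOMIC_MASSES[[el]] * cnt
  }
  total
}

#' Build a compound library table
#'
#' Normalizes a screening-library data.frame: fills missing masses from the
#' formula column and checks required fields. Expected columns:
#' `compound_id`, `has_charged_group` (logical), and at least one of
#' `formula` / `mass`; optional `name`, `docking_score_sp`,
#' `docking_score_xp`, plus any extra columns (e.g. a scaffold key).
#'
#' @param library data.frame as above.
#' @return the normalized data.frame with a complete `mass` column.
#' @export
as_compound_library <- function(library) {
  stopifnot(is.data.frame(library))
  req <- c("compound_id", "has_charged_group")
  miss <- setdiff(req, names(library))
  if (length(miss)) stop("library lacks required columns: ",
                         paste(miss, collapse = ", "))
  if (!"mass" %in% names(library)) library$mass <- NA_real_
  if (!"formula" %in% names(library)) library$formula <- NA_character_
  need <- is.na(library$mass)
  no_source <- need & (is.na(library$formula) | !nzchar(library$formula))
  if (any(no_source))
    stop("compounds lack both formula and mass: ",
         paste(library$compound_id[no_source], collapse = ", "))
  library$mass[need] <- vapply(library$formula[need], mass_from_formula,
                               numeric(1L))
  if (any(library$mass <= 0)) stop("masses must be > 0")
  for (col in c("docking_score_sp", "docking_score_xp"))
    if (!col %in% names(library)) library[[col]] <- NA_real_
  library$has_charged_group <- as.logical(library$has_charged_group)
  library
}

#' Apply the staged virtual-screen triage filters
#'
#' Reproduces the triage sequence of the docking screen: (1) remove every
#' compound with any charged group at the prepared protonation state, (2)
#' remove molecular masses below `mass_min` or above `mass_max` (bounds
#' inclusive-pass: exactly 100 or 600 g/mol survives), (3) keep compounds
#' whose standard-precision docking score is at or below `score_cutoff`
#' (more negative = better predicted binding; -7.0 passes at the default).
#' Survivors with an extra-precision (XP) score become MD candidates. A
#' compound failing several criteria is labelled by the first failed filter
#' only; a compound with no SP (or no XP) score stalls as `pending`.
#'
#' @param library data.frame accepted by [as_compound_library()].
#' @param mass_min,mass_max mass window in g/mol (defaults 100 and 600).
#' @param score_cutoff SP docking-score cut-off (default -7.0).
#' @return object of class `screen_report`: `$table` (per-compound status)
#'   and `$counts` (monotone stage counts: input, after_charge, after_mass,
#'   after_score, xp_docked, md_candidates).
#' @export
apply_filters <- function(library, mass_min = 100, mass_max = 600,
                          score_cutoff = -7.0) {
  lib <- as_compound_library(library)
  n <- nrow(lib)
  status <- rep("pending", n)

  charged <- lib$has_charged_group
  status[charged] <- "rejected_charge"

  mass_fail <- !charged & (lib$mass < mass_min | lib$mass > mass_max)
  status[mass_fail] <- "rejected_mass"

  at_score <- !charged & !mass_fail
  score_fail <- at_score & !is.na(lib$docking_score_sp) &
    lib$docking_score_sp > score_cutoff
  status[score_fail] <- "rejected_score"

  passed_sp <- at_score & !is.na(lib$docking_score_sp) &
    lib$docking_score_sp <= score_cutoff
  md <- passed_sp & !is.na(lib$docking_score_xp)
  status[md] <- "md_candidate"
  # passed_sp without XP score stays "pending" (stalled before MD selection)

  lib$status <- status
  counts <- c(input = n,
              after_charge = sum(!charged),
              after_mass = sum(at_score),
              after_score = sum(passed_sp),
              xp_docked = sum(md),
              md_candidates = sum(md))
  structure(list(table = lib, counts = counts,
                 thresholds = c(mass_min = mass_min, mass_max = mass_max,
                                score_cutoff = score_cutoff)),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat("<screen_report>\n")
  print(x$counts)
  invisible(x)
}

#' Shortlist MD candidates from a screen report
#'
#' Deterministic surrogate for manual scaffold-diversity picking: rank the
#' filter survivors by best (most negative) XP score, optionally keep at
#' most one compound per diversity group, and return the top `k`. Ties are
#' broken by compound id, lexicographically.
#'
#' @param report a `screen_report` from [apply_filters()].
#' @param k number of candidates to return (> 0; fewer are returned when
#'   fewer survive).
#' @param diversity_key optional name of a grouping column in the library
#'   table (e.g. a scaffold class); at most one compound per group.
#' @return character vector of compound ids, best first.
#' @export
shortlist_md_candidates <- function(report, k, diversity_key = NULL) {
  stopifnot(inherits(report, "screen_report"))
  if (!is.numeric(k) || k <= 0) stop("k must be a positive integer")
  tab <- report$table[report$table$status == "md_candidate", , drop = FALSE]
  if (nrow(tab) == 0L) return(character(0L))
  tab <- tab[order(tab$docking_score_xp, tab$compound_id), , drop = FALSE]
  if (!is.null(diversity_key)) {
    if (!diversity_key %in% names(tab))
      stop("diversity_key column '", diversity_key, "' not in library table")
    tab <- tab[!duplicated(tab[[diversity_key]]), , drop = FALSE]
  }
  utils::head(tab$compound_id, n = as.integer(k))
}

#' Read a compound library table from a delimited file
#'
#' @param path CSV/TSV file with a header row (comma or tab separated;
#'   gzip accepted).
#' @return normalized library data.frame.
#' @export
read_compound_library <- function(path) {
  con <- open_text(path)
  on.exit(close(con))
  first <- readLines(con, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  close(con); on.exit()
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  as_compound_library(df)
}

#' Write a screen report (status table + JSON stage counts)
#'
#' @param report a `screen_report`.
#' @param table_path CSV path for the per-compound status table.
#' @param counts_path optional JSON path for the stage counts.
#' @return `report`, invisibly.
#' @export
write_screen_report <- function(report, table_path, counts_path = NULL) {
  stopifnot(inherits(report, "screen_report"))
  utils::write.csv(report$table, table_path, row.names = FALSE)
  if (!is.null(counts_path))
    jsonlite::write_json(as.list(report$counts), counts_path,
                         auto_unbox = TRUE, digits = NA)
  invisible(report)
}
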