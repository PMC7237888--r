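# Public TCR repertoire construction and exact CDR3beta matching.
#
# A sequence is "public" when it appears in at least `min_subjects` distinct
# subjects of a species' repertoire (e.g. >= 25 of 28 mice, >= 400 of 785
# humans). Autoreactive CDR3beta sequences (from patients or disease models)
# are then matched character-exactly against the public sets; no V/J-gene
# constraint and no fuzzy matching. Statistical enrichment is deliberately not
# computed: the question is presence, not excess.

.AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
.AA_REGEX <- "^[ACDEFGHIKLMNPQRSTVWY]+$"

normalize_cdr3 <- function(x) toupper(gsub("\\s+", "", x))

#' Read a TCR repertoire table from TSV
#'
#' Expects a header with columns `subject_id`, `species` and `cdr3_aa`
#' (`junction_aa` is accepted as an alias, following AIRR Rearrangement
#' naming). Sequences are upper-cased and whitespace-stripped; rows whose
#' sequence contains characters outside the 20 standard amino-acid codes
#' (stop codons, ambiguity codes) are rejected with a warning listing the
#' offending rows. Duplicate (subject, sequence) pairs are collapsed.
#'
#' @param path TSV file path.
#' @return A tibble of class `repertoire_table` with columns `subject_id`,
#'   `species`, `cdr3_aa` and attribute `n_subjects`.
#' @export
read_repertoire <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = "c"))
  as_repertoire(df)
}

#' Coerce a data frame to a validated repertoire table
#'
#' @param df Data frame with `subject_id`, `species`, and `cdr3_aa` (or
#'   `junction_aa`).
#' @return A `repertoire_table` tibble.
#' @export
as_repertoire <- function(df) {
  if (!"cdr3_aa" %in% names(df) && "junction_aa" %in% names(df)) {
    names(df)[names(df) == "junction_aa"] <- "cdr3_aa"
  }
  needed <- c("subject_id", "species", "cdr3_aa")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("repertoire table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df$cdr3_aa <- normalize_cdr3(df$cdr3_aa)
  bad <- which(!grepl(.AA_REGEX, df$cdr3_aa))
  if (length(bad)) {
    warning(sprintf(
      "dropping %d row(s) with non-standard amino-acid characters (rows: %s)",
      length(bad), paste(utils::head(bad, 10), collapse = ", ")),
      call. = FALSE)
    df <- df[-bad, , drop = FALSE]
  }
  out <- dplyr::distinct(
    tibble::as_tibble(df[, needed]), .data$subject_id, .data$species,
    .data$cdr3_aa)
  attr(out, "n_subjects") <- length(unique(out$subject_id))
  class(out) <- c("repertoire_table", class(out))
  out
}

#' Coerce a data frame to an autoreactive CDR3 set
#'
#' @param df Data frame with `cdr3_aa` (or `junction_aaaa` alias
#'   `junction_aa`), `disease`, `antigen`, `species`.
#' @return A tibble of class `autoreactive_set`.
#' @export
as_autoreactive <- function(df) {
  if (!"cdr3_aa" %in% names(df) && "junction_aa" %in% names(df)) {
    names(df)[names(df) == "junction_aa"] <- "cdr3_aa"
  }
  needed <- c("cdr3_aa", "disease", "antigen", "species")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("autoreactive table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df$cdr3_aa <- normalize_cdr3(df$cdr3_aa)
  bad <- which(!grepl(.AA_REGEX, df$cdr3_aa))
  if (length(bad)) {
    warning(sprintf(
      "dropping %d autoreactive row(s) with non-standard characters", length(bad)),
      call. = FALSE)
    df <- df[-bad, , drop = FALSE]
  }
  out <- tibble::as_tibble(df[, needed])
  class(out) <- c("autoreactive_set", class(out))
  out
}

#' Read an autoreactive CDR3 set from TSV
#'
#' Columns: `cdr3_aa` (alias `junction_aa`), `disease`, `antigen`, `species`.
#'
#' @param path TSV file path.
#' @return An `autoreactive_set` tibble.
#' @export
read_autoreactive <- function(path) {
  as_autoreactive(readr::read_tsv(path, show_col_types = FALSE,
                                  col_types = readr::cols(.default = "c")))
}

#' Build a public repertoire by subject-sharing threshold
#'
#' Keeps the sequences present in at least `min_subjects` distinct subjects.
#' Deterministic set semantics: row order, within-subject duplicates and case
#' do not affect the result. Raising the threshold can only shrink the set.
#'
#' @param table A `repertoire_table` (one species).
#' @param min_subjects Sharing threshold, `<=` the number of subjects.
#' @return A list of class `public_repertoire`: `species`, `sequences`
#'   (character vector, sorted), `min_subjects`, `total_subjects`.
#' @export
build_public_set <- function(table, min_subjects) {
  stopifnot(inherits(table, "repertoire_table"),
            is.numeric(min_subjects), min_subjects >= 1)
  species <- unique(table$species)
  if (length(species) != 1L) {
    stop("repertoire table must contain a single species; found: ",
         paste(species, collapse = ", "), call. = FALSE)
  }
  n_subjects <- length(unique(table$subject_id))
  if (min_subjects > n_subjects) {
    stop("`min_subjects` (", min_subjects, ") exceeds subject count (",
         n_subjects, ")", call. = FALSE)
  }
  counts <- table(unique(table[, c("subject_id", "cdr3_aa")])$cdr3_aa)
  seqs <- sort(names(counts)[counts >= min_subjects])
  structure(list(species = species, sequences = seqs,
                 min_subjects = min_subjects, total_subjects = n_subjects),
            class = "public_repertoire")
}

#' @export
print.public_repertoire <- function(x, ...) {
  cat(sprintf("<public_repertoire> %s: %d sequences shared by >= %d of %d subjects\n",
              x$species, length(x$sequences), x$min_subjects,
              x$total_subjects))
  invisible(x)
}

#' Exact matching of autoreactive CDR3s against public repertoires
#'
#' Character-exact set intersection of the autoreactive sequences with each
#' public set; order-independent. Reports per-disease match counts and, when
#' both a mouse and a human public set are supplied, the cross-species core
#' and the matches falling inside it.
#'
#' @param auto An `autoreactive_set`.
#' @param publics List of [build_public_set()] results (typically one per
#'   species).
#' @return A list of class `match_report`: `matches` (tibble `cdr3_aa`,
#'   `disease`, `antigen`, `matched_in` — comma-joined species), `n_matches`
#'   (distinct matched sequences), `by_disease` (tibble), and if two or more
#'   species are present, `cross_species_core_size` and `matches_in_core`.
#' @export
match_exact <- function(auto, publics) {
  stopifnot(inherits(auto, "autoreactive_set"), length(publics) >= 1)
  for (p in publics) stopifnot(inherits(p, "public_repertoire"))
  auto_u <- dplyr::distinct(auto, .data$cdr3_aa, .data$disease, .data$antigen)
  matched_in <- vapply(auto_u$cdr3_aa, function(s) {
    hit <- vapply(publics, function(p) s %in% p$sequences, logical(1))
    paste(sort(vapply(publics[hit], `[[`, character(1), "species")),
          collapse = ",")
  }, character(1), USE.NAMES = FALSE)
  matches <- auto_u[nzchar(matched_in), , drop = FALSE]
  matches$matched_in <- matched_in[nzchar(matched_in)]
  by_disease <- dplyr::count(
    dplyr::distinct(matches, .data$cdr3_aa, .data$disease),
    .data$disease, name = "n")
  out <- list(matches = matches,
              n_matches = length(unique(matches$cdr3_aa)),
              by_disease = by_disease)
  if (length(publics) >= 2) {
    core <- cross_species_core(publics[[1]], publics[[2]])
    out$cross_species_core_size <- length(core)
    out$matches_in_core <- length(intersect(unique(matches$cdr3_aa), core))
  }
  structure(out, class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf("<match_report> %d exact matches\n", x$n_matches))
  if (nrow(x$by_disease)) {
    for (i in seq_len(nrow(x$by_disease))) {
      cat(sprintf("  %s: %d\n", x$by_disease$disease[i], x$by_disease$n[i]))
    }
  }
  if (!is.null(x$cross_species_core_size)) {
    cat(sprintf("  cross-species core: %d sequences, %d matches inside\n",
                x$cross_species_core_size, x$matches_in_core))
  }
  invisible(x)
}

#' Sequences public in both species
#'
#' Exact, symmetric intersection of two public repertoires from different
#' species.
#'
#' @param a,b [build_public_set()] results with differing `species`.
#' @return Sorted character vector of shared sequences.
#' @export
cross_species_core <- function(a, b) {
  stopifnot(inherits(a, "public_repertoire"), inherits(b, "public_repertoire"))
  if (identical(a$species, b$species)) {
    stop("cross-species core requires repertoires from different species",
         call. = FALSE)
  }
  sort(intersect(a$sequences, b$sequences))
}
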