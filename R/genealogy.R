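#' Construct a genealogy from a data frame
#'
#' A genealogy is a parent-pointer forest: one row per individual with
#' pointers to father and mother (absent for founders), demographic
#' attributes used for cohort matching, and the individual's linked death
#' record. The object is a tibble of class `genealogy`, so all dplyr verbs
#' apply; analysis functions take it as their first argument.
#'
#' @param x A data frame with columns `id`, `father_id`, `mother_id`, `sex`
#'   (`"male"`, `"female"` or `"unknown"`), `birth_year`, `birthplace`
#'   (`"in_state"` or `"out_of_state"`), `death_year` (NA while alive or
#'   unlinked) and `causes` (semicolon-separated `revision:code` tokens,
#'   e.g. `"10:G30;9:331.0"`; empty for a death certificate that lists no
#'   qualifying cause). Missing parents are `NA` or `""`.
#' @param lenient If `TRUE`, parent ids that do not resolve to a row are
#'   downgraded to absent with a warning instead of an error.
#'
#' @details
#' Validation enforces: unique ids; every non-absent parent id resolves;
#' fathers are never recorded as female nor mothers as male; the parent
#' graph is acyclic; and `death_year >= birth_year` where both are present.
#' An individual has a death certificate iff `death_year` is present; the
#' cause list may then be empty (such individuals count in denominators but
#' can never be cases).
#'
#' @return A `genealogy` tibble.
#' @export
#' @examples
#' trio <- genealogy(data.frame(
#'   id = c("f", "m", "c"), father_id = c(NA, NA, "f"),
#'   mother_id = c(NA, NA, "m"), sex = c("male", "female", "female"),
#'   birth_year = c(1900L, 1902L, 1930L), birthplace = "in_state",
#'   death_year = c(1980L, 1985L, NA), causes = c("9:331.0", "", NA)
#' ))
#' founders(trio)
genealogy <- function(x, lenient = FALSE) {
  required <- c("id", "father_id", "mother_id", "sex", "birth_year",
                "birthplace", "death_year", "causes")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("genealogy input lacks column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  g <- tibble::as_tibble(x)[required]
  blank_to_na <- function(v) {
    v <- as.character(v)
    v[!is.na(v) & v == ""] <- NA_character_
    v
  }
  g$id <- as.character(g$id)
  g$father_id <- blank_to_na(g$father_id)
  g$mother_id <- blank_to_na(g$mother_id)
  g$sex <- as.character(g$sex)
  g$birth_year <- suppressWarnings(as.integer(g$birth_year))
  g$birthplace <- as.character(g$birthplace)
  g$death_year <- suppressWarnings(as.integer(g$death_year))
  g$causes <- as.character(g$causes)
  g$causes[is.na(g$causes)] <- ""
  class(g) <- c("genealogy", class(tibble::tibble()))
  validate_genealogy(g, lenient = lenient)
}

#' Validate genealogy invariants
#'
#' @param g A `genealogy` (or coercible data frame).
#' @inheritParams genealogy
#' @return The validated `genealogy`, invisibly usable in a pipe.
#' @export
validate_genealogy <- function(g, lenient = FALSE) {
  if (anyNA(g$id)) rlang::abort("missing individual id")
  dup <- g$id[duplicated(g$id)]
  if (length(dup) > 0) {
    rlang::abort(paste0("duplicate id(s): ", paste(unique(dup), collapse = ", ")))
  }
  bad_sex <- setdiff(unique(g$sex), c("male", "female", "unknown"))
  if (length(bad_sex) > 0) {
    rlang::abort(paste0("invalid sex value(s): ", paste(bad_sex, collapse = ", ")))
  }
  for (col in c("father_id", "mother_id")) {
    unresolved <- !is.na(g[[col]]) & !(g[[col]] %in% g$id)
    if (any(unresolved)) {
      if (lenient) {
        rlang::warn(paste0(sum(unresolved), " dangling ", col,
                           " pointer(s) downgraded to absent"))
        g[[col]][unresolved] <- NA_character_
      } else {
        rlang::abort(paste0("unresolved ", col, " for id(s): ",
                            paste(utils::head(g$id[unresolved], 5), collapse = ", ")))
      }
    }
  }
  fidx <- match(g$father_id, g$id)
  midx <- match(g$mother_id, g$id)
  if (any(g$sex[fidx[!is.na(fidx)]] == "female")) {
    rlang::abort("an individual recorded as female appears as a father")
  }
  if (any(g$sex[midx[!is.na(midx)]] == "male")) {
    rlang::abort("an individual recorded as male appears as a mother")
  }
  gen <- cpp_generation(idx0(fidx), idx0(midx))
  if (any(gen < 0)) {
    rlang::abort(paste0("parental cycle detected involving id ",
                        g$id[which(gen < 0)[1]]))
  }
  both <- !is.na(g$birth_year) & !is.na(g$death_year)
  if (any(both & g$death_year < g$birth_year)) {
    rlang::abort(paste0("death before birth for id ",
                        g$id[which(both & g$death_year < g$birth_year)[1]]))
  }
  g
}

# 0-based indices for the C++ layer (NA preserved as NA_INTEGER)
idx0 <- function(i) {
  out <- as.integer(i - 1L)
  out[is.na(i)] <- NA_integer_
  out
}

# parent indices, generation numbers and a topological order; recomputed on
# demand (cheap relative to any analysis that needs it)
ped_index <- function(g) {
  fidx <- match(g$father_id, g$id)
  midx <- match(g$mother_id, g$id)
  gen <- cpp_generation(idx0(fidx), idx0(midx))
  list(fidx = fidx, midx = midx, gen = gen, ord = order(gen))
}

#' Founders of a genealogy
#'
#' Founders are individuals with neither parent recorded; every pedigree in
#' the descendancy scan is the recorded descendancy of one founder (or
#' founding couple).
#'
#' @param g A `genealogy`.
#' @return Character vector of founder ids.
#' @export
founders <- function(g) {
  g$id[is.na(g$father_id) & is.na(g$mother_id)]
}

#' @export
has_death_certificate <- function(g) {
  !is.na(g$death_year)
}

#' Read / write the genealogy table
#'
#' The on-disk format is a UTF-8 delimited table with a header row naming
#' `id, father_id, mother_id, sex, birth_year, birthplace, death_year,
#' causes`; empty string means absent, and causes are semicolon-separated
#' `revision:code` tokens.
#'
#' @param path File path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @inheritParams genealogy
#' @return `read_genealogy()` a validated `genealogy`; `write_genealogy()`
#'   the input, invisibly.
#' @export
read_genealogy <- function(path, dialect = c("tsv", "csv"), lenient = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) rlang::abort(paste0("no such file: ", path))
  sep <- if (dialect == "tsv") "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           colClasses = "character", na.strings = character(),
                           check.names = FALSE, comment.char = "",
                           fileEncoding = "UTF-8")
  genealogy(raw, lenient = lenient)
}

#' @rdname read_genealogy
#' @param g A `genealogy`.
#' @export
write_genealogy <- function(g, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  out <- as.data.frame(g)
  for (col in names(out)) {
    out[[col]] <- as.character(out[[col]])
    out[[col]][is.na(out[[col]])] <- ""
  }
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(g)
}

#' Read a 6-column pre-header PED file
#'
#' Strict reader for the classic linkage-format pedigree file: columns
#' `family, id, father, mother, sex, phenotype` with no header, `0` for a
#' missing parent, sex coded 1 = male / 2 = female / other = unknown, and
#' phenotype 2 = affected. Demographic columns absent from the format are
#' filled with `NA`; an `affected` column carries the phenotype.
#'
#' @param path PED file path.
#' @return A `genealogy` with extra columns `family` and `affected`.
#' @export
read_ped <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("no such file: ", path))
  raw <- utils::read.table(path, header = FALSE, colClasses = "character")
  if (ncol(raw) != 6) {
    rlang::abort("PED reader expects exactly 6 whitespace-separated columns")
  }
  names(raw) <- c("family", "id", "father_id", "mother_id", "sex", "phenotype")
  zero_na <- function(v) { v[v == "0"] <- NA_character_; v }
  g <- genealogy(tibble::tibble(
    id = raw$id,
    father_id = zero_na(raw$father_id),
    mother_id = zero_na(raw$mother_id),
    sex = dplyr::case_match(raw$sex, "1" ~ "male", "2" ~ "female",
                            .default = "unknown"),
    birth_year = NA_integer_,
    birthplace = NA_character_,
    death_year = NA_integer_,
    causes = ""
  ))
  g$family <- raw$family
  g$affected <- raw$phenotype == "2"
  g
}

#' Ancestor completeness over the 14 immediate-ancestor slots
#'
#' Counts how many of an individual's 14 immediate-ancestor slots (2
#' parents, 4 grandparents, 8 great-grandparents) are filled. Counting is
#' per slot, not per person: under pedigree collapse one person occupying
#' two slots is counted twice, once for each slot.
#'
#' @param g A `genealogy`.
#' @param ids Ids to score (default: everyone).
#' @return Integer vector in `[0, 14]`, aligned with `ids`.
#' @export
ancestor_completeness <- function(g, ids = g$id) {
  pos <- match(ids, g$id)
  if (anyNA(pos)) {
    rlang::abort(paste0("unknown id(s): ",
                        paste(utils::head(ids[is.na(pos)], 5), collapse = ", ")))
  }
  px <- ped_index(g)
  up <- function(which, i) {
    out <- rep(NA_integer_, length(i))
    ok <- !is.na(i)
    out[ok] <- if (which == "f") px$fidx[i[ok]] else px$midx[i[ok]]
    out
  }
  slots <- list(up("f", pos), up("m", pos))        # depth 1
  d2 <- unlist(lapply(slots, function(s) list(up("f", s), up("m", s))),
               recursive = FALSE)                   # depth 2
  d3 <- unlist(lapply(d2, function(s) list(up("f", s), up("m", s))),
               recursive = FALSE)                   # depth 3
  filled <- lapply(c(slots, d2, d3), function(s) !is.na(s))
  as.integer(Reduce(`+`, filled))
}

#' Eligible decedents: the analysis universe
#'
#' The universe for every downstream statistic (cases, matched controls,
#' cohort denominators, relatives' observed/expected counts) is the set of
#' individuals with a linked death certificate and at least
#' `min_completeness` of their 14 immediate ancestors recorded, ensuring
#' equivalent genealogy quantity for cases and controls. Individuals with
#' no recorded birth year cannot be cohort-assigned and are excluded with a
#' message reporting the count.
#'
#' @param g A `genealogy`.
#' @param min_completeness Minimum filled ancestor slots (default 12 of 14).
#' @return Character vector of ids.
#' @export
eligible_decedents <- function(g, min_completeness = 12) {
  dead <- has_death_certificate(g)
  no_by <- dead & is.na(g$birth_year)
  if (any(no_by)) {
    rlang::inform(paste0(sum(no_by),
                         " decedent(s) without birth year excluded from the universe"))
  }
  cand <- which(dead & !no_by)
  comp <- ancestor_completeness(g, g$id[cand])
  g$id[cand][comp >= min_completeness]
}

#' Cause-of-death case definition
#'
#' A case definition is a set of (ICD revision, code prefix) pairs; a
#' decedent is a case when at least one listed cause matches a pair by code
#' prefix after stripping dots (so ICD-10 "G30.1" matches prefix "G30", and
#' "331.0" matches "3310"). The default targets Alzheimer's disease coded as
#' ICD-9 331.0 or ICD-10 G30; deliberately narrower diagnoses such as
#' senility or senile dementia never match.
#'
#' @param codes Character vector of `revision:code` tokens.
#' @param require_primary_only If `TRUE`, only the first-listed
#'   (underlying) cause is eligible to match.
#' @return A `case_definition` object.
#' @export
case_definition <- function(codes = c("9:331.0", "10:G30"),
                            require_primary_only = FALSE) {
  if (length(codes) == 0) rlang::abort("case definition needs at least one code")
  parts <- strsplit(codes, ":", fixed = TRUE)
  bad <- lengths(parts) != 2
  if (any(bad)) {
    rlang::abort(paste0("malformed code token(s): ",
                        paste(codes[bad], collapse = ", ")))
  }
  defn <- list(
    revision = as.integer(vapply(parts, `[[`, "", 1)),
    prefix = norm_code(vapply(parts, `[[`, "", 2)),
    require_primary_only = isTRUE(require_primary_only)
  )
  if (!all(defn$revision %in% c(9L, 10L))) {
    rlang::abort("ICD revision must be 9 or 10")
  }
  structure(defn, class = "case_definition")
}

norm_code <- function(code) gsub(".", "", toupper(code), fixed = TRUE)

# split a causes string into a tibble of (revision, code); "" -> 0 rows
parse_causes <- function(causes) {
  toks <- strsplit(causes, ";", fixed = TRUE)
  lapply(toks, function(tk) {
    tk <- tk[nzchar(tk)]
    if (length(tk) == 0) {
      return(list(revision = integer(), code = character()))
    }
    sp <- strsplit(tk, ":", fixed = TRUE)
    list(revision = as.integer(vapply(sp, `[[`, "", 1)),
         code = norm_code(vapply(sp, `[[`, "", 2)))
  })
}

#' Classify disease cases within the universe
#'
#' @param g A `genealogy`.
#' @param universe Ids returned by [eligible_decedents()] (any subset of
#'   `g$id` with death certificates).
#' @param definition A [case_definition()].
#' @return Character vector of case ids (a subset of `universe`).
#' @export
classify_cases <- function(g, universe, definition = case_definition()) {
  pos <- match(universe, g$id)
  if (anyNA(pos)) rlang::abort("universe contains ids not in the genealogy")
  parsed <- parse_causes(g$causes[pos])
  hit <- vapply(parsed, function(p) {
    if (length(p$code) == 0) return(FALSE)
    k <- if (definition$require_primary_only) 1L else length(p$code)
    for (i in seq_len(k)) {
      same_rev <- definition$revision == p$revision[i]
      if (any(same_rev & startsWith(p$code[i], definition$prefix[same_rev]))) {
        return(TRUE)
      }
    }
    FALSE
  }, logical(1))
  universe[hit]
}
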