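#' Cohort table of cause-specific death rates
#'
#' Assigns every universe member to exactly one stratum (sex x 5-year birth
#' interval x birthplace) and computes the stratum-specific disease death
#' rate: cases over all deaths in the stratum. These internally estimated
#' rates standardize the expected counts in [rr_table()] and
#' [scan_pedigrees()].
#'
#' @param g A `genealogy`.
#' @param universe The analysis universe (all decedents retained by the
#'   eligibility filter).
#' @param cases Case ids, a subset of `universe`.
#' @return Tibble with columns `sex`, `birth_bin`, `birthplace`, `key`,
#'   `n_deaths`, `n_case_deaths`, `rate`.
#' @export
build_cohorts <- function(g, universe, cases) {
  universe <- as.character(universe)
  cases <- as.character(cases)
  if (!all(cases %in% universe)) rlang::abort("cases must lie in the universe")
  keys <- matching_key(g, universe)
  keys$is_case <- keys$id %in% cases
  keys |>
    dplyr::group_by(.data$sex, .data$birth_bin, .data$birthplace, .data$key) |>
    dplyr::summarise(n_deaths = dplyr::n(),
                     n_case_deaths = sum(.data$is_case), .groups = "drop") |>
    dplyr::mutate(rate = .data$n_case_deaths / .data$n_deaths)
}

# structural relationship sets, by position, for one genealogy
rel_maps <- function(g) {
  px <- ped_index(g)
  n <- nrow(g)
  kids_f <- split(which(!is.na(px$fidx)), px$fidx[!is.na(px$fidx)])
  kids_m <- split(which(!is.na(px$midx)), px$midx[!is.na(px$midx)])
  kids <- function(i) {
    unique(c(kids_f[[as.character(i)]], kids_m[[as.character(i)]]))
  }
  parents <- function(i) {
    p <- c(px$fidx[i], px$midx[i])
    p[!is.na(p)]
  }
  fullsibs <- function(i) {
    f <- px$fidx[i]; m <- px$midx[i]
    if (is.na(f) || is.na(m)) return(integer())
    s <- intersect(kids_f[[as.character(f)]], kids_m[[as.character(m)]])
    setdiff(s, i)
  }
  halfsibs <- function(i) {
    f <- px$fidx[i]; m <- px$midx[i]
    s <- integer()
    if (!is.na(f)) s <- c(s, kids_f[[as.character(f)]])
    if (!is.na(m)) s <- c(s, kids_m[[as.character(m)]])
    setdiff(unique(s), c(i, fullsibs(i)))
  }
  over <- function(set, fn) unique(unlist(lapply(set, fn)))
  list(px = px, kids = kids, parents = parents, fullsibs = fullsibs,
       halfsibs = halfsibs, over = over)
}

# degree-specific relationship sets (positions) of one proband
degree_sets <- function(rm, i) {
  p1 <- rm$parents(i)
  c1 <- rm$kids(i)
  fs <- rm$fullsibs(i)
  gp <- rm$over(p1, rm$parents)
  gc <- rm$over(c1, rm$kids)
  d1 <- unique(c(p1, c1, fs))
  d2 <- unique(c(gp, gc, rm$halfsibs(i),
                 rm$over(p1, rm$fullsibs),      # aunts / uncles
                 rm$over(fs, rm$kids)))         # nieces / nephews
  d3 <- unique(c(rm$over(gp, rm$parents),       # great-grandparents
                 rm$over(gc, rm$kids),          # great-grandchildren
                 rm$over(rm$over(p1, rm$fullsibs), rm$kids),  # first cousins
                 rm$over(p1, rm$halfsibs),      # half-aunts/-uncles
                 rm$over(rm$halfsibs(i), rm$kids),  # half-nieces/-nephews
                 rm$over(gp, rm$fullsibs),      # great-aunts/-uncles
                 rm$over(rm$over(fs, rm$kids), rm$kids)))  # grand-nieces/-nephews
  list(d1 = d1, d2 = d2, d3 = d3)
}

#' Enumerate relatives of probands at a given degree
#'
#' Returns the deduplicated union, over all probands, of relatives at the
#' requested degree, intersected with the universe. Degree follows the
#' genetic convention: first degree is parents, offspring and full
#' siblings; second degree is grandparents, grandchildren, half-siblings,
#' aunts/uncles and nieces/nephews; third degree is first cousins,
#' great-grandparents, great-grandchildren, half- and grand-avunculars. An
#' individual related to different probands at several degrees is assigned
#' to the closest degree only, so the three degree sets are disjoint.
#' Probands who are themselves relatives of other probands remain in the
#' result — they are legitimately at risk.
#'
#' @param g A `genealogy`.
#' @param probands Proband ids.
#' @param degree 1, 2 or 3.
#' @param universe Ids the result is restricted to.
#' @return Character vector of relative ids.
#' @export
enumerate_relatives <- function(g, probands, degree, universe = g$id) {
  if (!degree %in% 1:3) rlang::abort("degree must be 1, 2 or 3")
  sets <- relative_degree_sets(g, probands, universe)
  sets[[degree]]
}

# all three disjoint degree sets at once (closest-degree precedence)
relative_degree_sets <- function(g, probands, universe = g$id) {
  probands <- unique(as.character(probands))
  pos <- match(probands, g$id)
  if (anyNA(pos)) rlang::abort("unknown proband id(s)")
  rm <- rel_maps(g)
  d1 <- integer(); d2 <- integer(); d3 <- integer()
  for (i in pos) {
    ds <- degree_sets(rm, i)
    d1 <- c(d1, ds$d1); d2 <- c(d2, ds$d2); d3 <- c(d3, ds$d3)
  }
  d1 <- unique(d1)
  d2 <- setdiff(unique(d2), d1)
  d3 <- setdiff(unique(d3), c(d1, d2))
  universe <- as.character(universe)
  list(intersect(g$id[d1], universe),
       intersect(g$id[d2], universe),
       intersect(g$id[d3], universe))
}

#' Confidence interval for an observed/expected ratio
#'
#' Exact Poisson interval for the mean of the observed count, divided by
#' the expected count: `low = qchisq(alpha/2, 2 * observed) / (2 *
#' expected)` (0 when `observed = 0`) and `high = qchisq(1 - alpha/2, 2 *
#' observed + 2) / (2 * expected)`. Byar's closed-form approximation to the
#' same interval is available as an alternative.
#'
#' @param observed Non-negative integer count(s).
#' @param expected Positive expected count(s).
#' @param level Confidence level.
#' @param method `"exact"` (chi-square quantile) or `"byar"`.
#' @return Tibble with columns `ci_low`, `ci_high`.
#' @export
rr_confidence_interval <- function(observed, expected, level = 0.95,
                                   method = c("exact", "byar")) {
  method <- match.arg(method)
  if (any(expected <= 0)) rlang::abort("expected must be positive")
  alpha <- 1 - level
  if (method == "exact") {
    low <- ifelse(observed == 0, 0,
                  stats::qchisq(alpha / 2, 2 * observed) / (2 * expected))
    high <- stats::qchisq(1 - alpha / 2, 2 * observed + 2) / (2 * expected)
  } else {
    z <- stats::qnorm(1 - alpha / 2)
    low <- ifelse(observed == 0, 0,
                  observed * (1 - 1 / (9 * observed) -
                              z / (3 * sqrt(observed)))^3 / expected)
    ob1 <- observed + 1
    high <- ob1 * (1 - 1 / (9 * ob1) + z / (3 * sqrt(ob1)))^3 / expected
  }
  tibble::tibble(ci_low = low, ci_high = high)
}

# exact Poisson tail p for an observed/expected contrast: upper tail when
# the ratio exceeds 1, lower tail otherwise
poisson_oe_p <- function(observed, expected) {
  upper <- observed / expected > 1
  ifelse(upper,
         stats::ppois(observed - 1, expected, lower.tail = FALSE),
         stats::ppois(observed, expected))
}

#' Observed/expected relative risk for a relative set
#'
#' The observed count is the number of cases among the relatives; the
#' expected count applies each stratum's population death rate to the
#' number of relatives in that stratum and sums over strata — a
#' standardized mortality ratio restricted to relatives of cases.
#'
#' @param g A `genealogy`.
#' @param universe,cases As in [build_cohorts()].
#' @param relatives Relative ids (subset of `universe`).
#' @param cohorts Cohort table from [build_cohorts()]; recomputed when
#'   `NULL`.
#' @param level Confidence level for the interval.
#' @param ci_method Passed to [rr_confidence_interval()].
#' @return One-row tibble: `n_relatives`, `observed`, `expected`, `rr`,
#'   `ci_low`, `ci_high`, `p_value` (exact Poisson tail).
#' @export
rr_estimate <- function(g, universe, cases, relatives, cohorts = NULL,
                        level = 0.95, ci_method = "exact") {
  universe <- as.character(universe)
  relatives <- unique(as.character(relatives))
  if (!all(relatives %in% universe)) {
    rlang::abort("relatives must lie in the universe")
  }
  if (is.null(cohorts)) cohorts <- build_cohorts(g, universe, cases)
  keys <- matching_key(g, relatives)
  counts <- table(keys$key)
  rate <- cohorts$rate[match(names(counts), cohorts$key)]
  if (anyNA(rate)) {
    rlang::warn("relatives in strata absent from the cohort table; rate 0 assumed")
    rate[is.na(rate)] <- 0
  }
  expected <- sum(rate * as.numeric(counts))
  observed <- length(intersect(relatives, as.character(cases)))
  if (expected == 0 && observed > 0) {
    rlang::abort("degenerate rates: expected 0 with observed > 0")
  }
  ci <- if (expected > 0) {
    rr_confidence_interval(observed, expected, level, ci_method)
  } else {
    tibble::tibble(ci_low = NA_real_, ci_high = NA_real_)
  }
  tibble::tibble(
    n_relatives = length(relatives),
    observed = observed,
    expected = expected,
    rr = if (expected > 0) observed / expected else NA_real_,
    ci_low = ci$ci_low,
    ci_high = ci$ci_high,
    p_value = if (expected > 0) poisson_oe_p(observed, expected) else NA_real_
  )
}

#' Relative risks in first-, second- and third-degree relatives
#'
#' Builds the full relative-risk table: for each degree, relatives of all
#' case probands are enumerated without duplication (closest degree wins),
#' and the observed disease deaths among them are compared with the count
#' expected from cohort-specific population rates. With `age_cutoff` set,
#' an additional proband stratum restricted to cases dying before that age
#' is reported; its relatives and the standardizing rates still come from
#' the all-ages universe.
#'
#' @inheritParams rr_estimate
#' @param age_cutoff Optional age in years; adds rows for probands with
#'   `death_year - birth_year < age_cutoff`.
#' @return An `rr_table` tibble: `age_stratum`, `degree`, `n_relatives`,
#'   `observed`, `expected`, `p_value`, `rr`, `ci_low`, `ci_high`.
#' @export
rr_table <- function(g, universe, cases, age_cutoff = NULL, cohorts = NULL,
                     level = 0.95, ci_method = "exact") {
  universe <- as.character(universe)
  cases <- unique(as.character(cases))
  if (is.null(cohorts)) cohorts <- build_cohorts(g, universe, cases)
  strata <- list(all = cases)
  if (!is.null(age_cutoff)) {
    pos <- match(cases, g$id)
    young <- cases[!is.na(g$death_year[pos]) & !is.na(g$birth_year[pos]) &
                     (g$death_year[pos] - g$birth_year[pos]) < age_cutoff]
    strata[[paste0("under_", age_cutoff)]] <- young
  }
  rows <- purrr::imap(strata, function(probands, label) {
    if (length(probands) == 0) {
      return(tibble::tibble(age_stratum = label, degree = 1:3,
                            n_relatives = 0L, observed = 0L, expected = 0,
                            p_value = NA_real_, rr = NA_real_,
                            ci_low = NA_real_, ci_high = NA_real_))
    }
    sets <- relative_degree_sets(g, probands, universe)
    purrr::map_dfr(1:3, function(d) {
      est <- rr_estimate(g, universe, cases, sets[[d]], cohorts,
                         level, ci_method)
      dplyr::bind_cols(tibble::tibble(age_stratum = label, degree = d),
                       est[c("n_relatives", "observed", "expected")],
                       est[c("p_value", "rr", "ci_low", "ci_high")])
    })
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("rr_table", class(out))
  out
}
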