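#' Descendants of a founder (or founding couple)
#'
#' Transitive closure of the child relation from the founder, excluding the
#' founder itself; individuals who married into the descendancy but share
#' no founder ancestry are not included.
#'
#' @param g A `genealogy`.
#' @param founder A founder id (no recorded parents), or a vector of two
#'   ids for a founding couple.
#' @return Character vector of descendant ids.
#' @export
descendants <- function(g, founder) {
  founder <- as.character(founder)
  pos <- match(founder, g$id)
  if (anyNA(pos)) rlang::abort("unknown founder id")
  if (!all(founder %in% founders(g))) {
    # couple mode pairs a founder with a co-parent who may have ancestry
    if (length(founder) == 1) {
      rlang::abort(paste0(founder, " is not a founder (has recorded parents)"))
    }
  }
  px <- ped_index(g)
  d <- cpp_descendants(idx0(px$fidx), idx0(px$midx), idx0(pos))
  g$id[d + 1L]
}

scan_p_value <- function(observed, expected, n, method) {
  switch(method,
    poisson = stats::ppois(observed - 1, expected, lower.tail = FALSE),
    binomial = {
      p <- ifelse(n > 0, pmin(expected / n, 1), 0)
      ifelse(n > 0, stats::pbinom(observed - 1, n, p, lower.tail = FALSE),
             1)
    },
    midp = stats::ppois(observed, expected, lower.tail = FALSE) +
      0.5 * stats::dpois(observed, expected)
  )
}

#' Scan founder descendancies for excess disease mortality
#'
#' Every founder's recorded descendancy, restricted to the analysis
#' universe, is treated as one pedigree. The expected number of disease
#' deaths applies the cohort-specific rates to the deceased descendants in
#' each cohort; the observed/expected excess is tested with the exact
#' Poisson upper tail. A pedigree is flagged high-risk when `p_value <
#' p_threshold` and it holds at least `min_cases` observed disease deaths.
#' Raw p-values are reported (mirroring how such scans are usually read);
#' a Bonferroni-adjusted column is included for convenience.
#'
#' @inheritParams rr_estimate
#' @param p_threshold Significance threshold for flagging.
#' @param min_cases Minimum observed disease deaths for flagging.
#' @param couple_mode If `TRUE`, each founder is merged with each of their
#'   co-parents into a founding-couple unit scanned jointly.
#' @param method Tail probability: `"poisson"` (exact, default),
#'   `"binomial"` or `"midp"`.
#' @return A `pedigree_scan` tibble sorted by ascending p-value:
#'   `founder_id`, `n_desc_with_cert`, `observed`, `expected`, `ratio`,
#'   `p_value`, `p_bonferroni`, `flagged`.
#' @export
scan_pedigrees <- function(g, universe, cases, cohorts = NULL,
                           p_threshold = 0.01, min_cases = 5,
                           couple_mode = FALSE,
                           method = c("poisson", "binomial", "midp")) {
  method <- match.arg(method)
  universe <- as.character(universe)
  cases <- unique(as.character(cases))
  if (is.null(cohorts)) cohorts <- build_cohorts(g, universe, cases)
  px <- ped_index(g)
  fnd <- founders(g)
  units <- if (couple_mode) founder_couples(g, fnd, px) else as.list(fnd)
  keys <- matching_key(g, universe)
  rate_of <- cohorts$rate[match(keys$key, cohorts$key)]
  rate_of[is.na(rate_of)] <- 0
  rows <- purrr::map_dfr(units, function(u) {
    desc <- descendants(g, u)
    du <- desc[desc %in% universe]
    obs <- sum(du %in% cases)
    exp_ <- sum(rate_of[match(du, keys$id)])
    tibble::tibble(
      founder_id = paste(u, collapse = "+"),
      n_desc_with_cert = length(du),
      observed = obs,
      expected = exp_,
      ratio = ifelse(exp_ > 0, obs / exp_, NA_real_),
      p_value = scan_p_value(obs, exp_, length(du), method)
    )
  })
  rows$p_bonferroni <- pmin(1, rows$p_value * nrow(rows))
  rows$flagged <- rows$p_value < p_threshold & rows$observed >= min_cases
  out <- dplyr::arrange(rows, .data$p_value, dplyr::desc(.data$observed))
  class(out) <- c("pedigree_scan", class(out))
  attr(out, "p_threshold") <- p_threshold
  attr(out, "min_cases") <- min_cases
  out
}

# one unit per (founder, co-parent) pair; founders with no children are
# kept as singleton units
founder_couples <- function(g, fnd, px) {
  units <- list()
  for (f in fnd) {
    i <- match(f, g$id)
    kids <- which(px$fidx == i | px$midx == i)
    if (length(kids) == 0) {
      units[[length(units) + 1]] <- f
      next
    }
    via_father <- !is.na(px$fidx[kids]) & px$fidx[kids] == i
    other <- ifelse(via_father, px$midx[kids], px$fidx[kids])
    other <- unique(other[!is.na(other)])
    if (length(other) == 0) {
      units[[length(units) + 1]] <- f
    } else {
      for (o in other) units[[length(units) + 1]] <- sort(c(f, g$id[o]))
    }
  }
  unique(units)
}
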