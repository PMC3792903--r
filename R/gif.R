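#' Matching key: sex, 5-year birth cohort, birthplace
#'
#' Every universe member maps to exactly one stratum formed by sex, the
#' 5-year birth interval containing the birth year (bins anchored at
#' calendar years divisible by 5: 1900-1904, 1905-1909, ...), and the
#' binary birthplace flag. The same strata serve control matching in the
#' GIF test and rate standardization in the relative-risk and pedigree-scan
#' analyses.
#'
#' @param g A `genealogy`.
#' @param ids Ids to key (default: everyone).
#' @return Tibble with columns `id`, `sex`, `birth_bin` (first year of the
#'   5-year interval), `birthplace`, `key` (the stratum label).
#' @export
matching_key <- function(g, ids = g$id) {
  pos <- match(as.character(ids), g$id)
  if (anyNA(pos)) rlang::abort("unknown id(s) in matching_key")
  bin <- 5L * (g$birth_year[pos] %/% 5L)
  tibble::tibble(
    id = g$id[pos],
    sex = g$sex[pos],
    birth_bin = bin,
    birthplace = g$birthplace[pos],
    key = paste(g$sex[pos], bin, g$birthplace[pos], sep = "|")
  )
}

#' Genealogical Index of Familiality statistic
#'
#' The GIF is the average pairwise kinship over all possible pairs of a set
#' — unrelated pairs contribute 0 to the numerator but stay in the
#' denominator — scaled by `scale` (10^5 by convention, so typical
#' population values land near single digits). With `min_distance = 4` the
#' statistic becomes the distant GIF: every pair related more closely than
#' first cousins is dropped from the numerator entirely.
#'
#' @param g A `genealogy`.
#' @param ids Set of at least 2 ids.
#' @param min_distance Smallest meiotic distance class retained.
#' @param max_distance Largest distance class contributing kinship.
#' @param scale Scale factor applied to the mean pairwise kinship.
#' @return List with `gif` (numeric) and `by_distance` (named vector of the
#'   per-distance contributions, summing to `gif`).
#' @export
gif_statistic <- function(g, ids, min_distance = 1, max_distance = 12,
                          scale = 1e5) {
  ids <- unique(as.character(ids))
  if (length(ids) < 2) {
    rlang::abort("GIF is undefined for fewer than 2 individuals")
  }
  ks <- pairwise_kinship_sum(g, ids, min_distance, max_distance)
  npairs <- choose(length(ids), 2)
  list(gif = scale * ks$total / npairs,
       by_distance = scale * ks$by_distance / npairs)
}

# stratum bookkeeping shared by sample_control_set and gif_test
control_strata <- function(g, universe, cases) {
  universe <- as.character(universe)
  cases <- as.character(cases)
  if (!all(cases %in% universe)) rlang::abort("cases must lie in the universe")
  keys <- matching_key(g, universe)
  pool <- split(keys$id[!(keys$id %in% cases)], keys$key[!(keys$id %in% cases)])
  need <- table(keys$key[keys$id %in% cases])
  short <- names(need)[need > vapply(names(need), function(k)
    length(pool[[k]] %||% character()), integer(1))]
  list(pool = pool, need = need, short = short)
}

#' Sample one matched control set
#'
#' Draws one control per case: within each case's stratum (sex x 5-year
#' birth cohort x birthplace), controls are drawn uniformly without
#' replacement from the non-case members of the universe. Control sets are
#' independent across repeated calls, so the same control can recur in
#' different sets. Uses the session RNG; seed with [set.seed()] for
#' reproducibility.
#'
#' @param g A `genealogy`.
#' @param universe The analysis universe (see [eligible_decedents()]).
#' @param cases Case ids, a subset of `universe`.
#' @param relax_matching If `TRUE`, a stratum with fewer available controls
#'   than cases borrows the shortfall from the adjacent 5-year birth bins
#'   (same sex and birthplace); otherwise such a stratum is an error.
#' @return Character vector of control ids, `length(unique(cases))` long.
#' @export
sample_control_set <- function(g, universe, cases, relax_matching = FALSE) {
  st <- control_strata(g, universe, unique(as.character(cases)))
  draw_control_set(st, relax_matching)
}

draw_control_set <- function(st, relax_matching = FALSE) {
  if (length(st$short) > 0 && !relax_matching) {
    rlang::abort(paste0("control stratum exhausted: ", st$short[1],
                        " (fewer eligible controls than cases)"))
  }
  out <- character(0)
  for (k in names(st$need)) {
    n_k <- st$need[[k]]
    pool_k <- st$pool[[k]] %||% character()
    if (length(pool_k) < n_k && relax_matching) {
      parts <- strsplit(k, "|", fixed = TRUE)[[1]]
      bin <- as.integer(parts[2])
      for (nb in c(bin - 5L, bin + 5L)) {
        extra <- st$pool[[paste(parts[1], nb, parts[3], sep = "|")]]
        pool_k <- c(pool_k, extra %||% character())
        if (length(pool_k) >= n_k) break
      }
      if (length(pool_k) < n_k) {
        rlang::abort(paste0("control stratum exhausted even after relaxation: ", k))
      }
    }
    out <- c(out, pool_k[sample.int(length(pool_k), n_k)])
  }
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' GIF test with matched-control resampling
#'
#' Compares the case-set GIF against the distribution of the statistic over
#' `n_sets` matched random control sets drawn from the same universe, and
#' reports a one-sided upper-tail empirical p-value with the add-one
#' estimator `(1 + #\{control GIF >= case GIF\}) / (n_sets + 1)` (so the
#' smallest attainable p is `1/(n_sets + 1)`, never 0). `variant =
#' "distant"` ignores all relationships closer than first cousins (meiotic
#' distance < 4) in both case and control statistics, isolating clustering
#' that shared household environment is unlikely to explain.
#'
#' Uses the session RNG; seed with [set.seed()] to fix all control sets.
#'
#' @inheritParams sample_control_set
#' @param variant `"all"` (every distance class from 1) or `"distant"`
#'   (classes 4 and beyond only).
#' @param n_sets Number of matched control sets.
#' @param max_distance Largest distance class contributing kinship.
#' @param scale Scale factor for the statistic.
#' @return A `gif_test` object: list with `n_cases`, `variant`,
#'   `min_distance`, `case_gif`, `case_by_distance`, `control_gifs`,
#'   `control_by_distance` (matrix, one row per set), `mean_control_gif`,
#'   `empirical_p`, `n_sets`. Has [tidy()], [glance()] and
#'   [ggplot2::autoplot()] methods.
#' @export
gif_test <- function(g, universe, cases, variant = c("all", "distant"),
                     n_sets = 1000, max_distance = 12, scale = 1e5,
                     relax_matching = FALSE) {
  variant <- match.arg(variant)
  gif_resample(g, universe, cases, variants = variant, n_sets = n_sets,
               max_distance = max_distance, scale = scale,
               relax_matching = relax_matching)[[variant]]
}

#' Run the GIF and distant-GIF tests on shared control sets
#'
#' Computes both variants from one resampling pass: the same matched
#' control sets are scored for every distance class once, and the two
#' statistics read off the same decomposition (the distant variant sums
#' the classes from first cousins outward). This makes the close/distant
#' comparison a reanalysis of identical control draws.
#'
#' @inheritParams gif_test
#' @return Named list with `gif_test` objects `all` and `distant`.
#' @export
gif_tests <- function(g, universe, cases, n_sets = 1000, max_distance = 12,
                      scale = 1e5, relax_matching = FALSE) {
  gif_resample(g, universe, cases, variants = c("all", "distant"),
               n_sets = n_sets, max_distance = max_distance, scale = scale,
               relax_matching = relax_matching)
}

# one resampling pass; per-pair kinship and distance memoized across sets
gif_resample <- function(g, universe, cases, variants, n_sets, max_distance,
                         scale, relax_matching) {
  universe <- as.character(universe)
  cases <- unique(as.character(cases))
  if (length(cases) < 2) {
    rlang::abort("GIF test is undefined for fewer than 2 cases")
  }
  npairs <- choose(length(cases), 2)
  st <- control_strata(g, universe, cases)
  sets <- c(list(match(cases, g$id)),
            lapply(seq_len(n_sets), function(r)
              match(draw_control_set(st, relax_matching), g$id)))
  px <- ped_index(g)
  anc <- cpp_ancestor_table(idx0(px$fidx), idx0(px$midx),
                            idx0(order(px$gen)), as.integer(max_distance))
  bins <- cpp_gif_sets(idx0(px$fidx), idx0(px$midx), px$gen,
                       anc$ptr, anc$idx, anc$depth,
                       lapply(sets, idx0), as.integer(max_distance))
  bins <- bins * scale / npairs
  colnames(bins) <- as.character(seq_len(max_distance))
  out <- lapply(variants, function(variant) {
    min_distance <- if (variant == "distant") 4L else 1L
    vb <- bins
    if (min_distance > 1) vb[, seq_len(min_distance - 1)] <- 0
    case_bins <- vb[1, ]
    ctrl_bins <- vb[-1, , drop = FALSE]
    control_gifs <- rowSums(ctrl_bins)
    case_gif <- sum(case_bins)
    structure(list(
      n_cases = length(cases),
      variant = variant,
      min_distance = min_distance,
      max_distance = max_distance,
      scale = scale,
      n_sets = n_sets,
      case_gif = case_gif,
      case_by_distance = case_bins,
      control_gifs = control_gifs,
      control_by_distance = ctrl_bins,
      mean_control_gif = mean(control_gifs),
      empirical_p = (1 + sum(control_gifs >= case_gif)) / (n_sets + 1)
    ), class = "gif_test")
  })
  stats::setNames(out, variants)
}

#' @export
print.gif_test <- function(x, ...) {
  label <- if (x$variant == "distant") "distant GIF" else "GIF"
  cat(sprintf("%s test (%d cases, %d matched control sets)\n",
              label, x$n_cases, x$n_sets))
  cat(sprintf("  case %s:        %.3f\n", label, x$case_gif))
  cat(sprintf("  mean control %s: %.3f\n", label, x$mean_control_gif))
  cat(sprintf("  empirical p:    %.4g\n", x$empirical_p))
  invisible(x)
}

#' Contribution to the GIF statistic by pairwise genetic distance
#'
#' Tidy table behind the contribution-by-distance figure: for each meiotic
#' distance class, the case contribution and the mean contribution over
#' control sets. The case column sums to the case GIF.
#'
#' @param r A `gif_test` result.
#' @return Tibble with columns `distance`, `case_contribution`,
#'   `mean_control_contribution`.
#' @export
contribution_plot_data <- function(r) {
  stopifnot(inherits(r, "gif_test"))
  tibble::tibble(
    distance = seq_len(r$max_distance),
    case_contribution = as.numeric(r$case_by_distance),
    mean_control_contribution = as.numeric(colMeans(r$control_by_distance))
  )
}
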