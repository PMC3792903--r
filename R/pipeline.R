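#' Run the full familial-clustering analysis
#'
#' End-to-end pipeline: eligibility filtering, case classification, the
#' GIF and distant-GIF tests, the relative-risk table for first- to
#' third-degree relatives (all ages and, optionally, probands dying young),
#' and the founder-descendancy scan. Counts are logged at every filter
#' step. With `out_dir` set, a machine-readable JSON report and
#' human-readable TSV tables are written; with a fixed `seed` the report is
#' byte-identical across runs.
#'
#' @param g A `genealogy`, or a path passed to [read_genealogy()].
#' @param definition A [case_definition()].
#' @param min_completeness Eligibility threshold on the 14 ancestor slots.
#' @param n_sets Matched control sets for each GIF variant.
#' @param age_cutoff Optional young-proband age cutoff for [rr_table()].
#' @param p_threshold,min_cases Flagging thresholds for [scan_pedigrees()].
#' @param relax_matching Passed to [gif_tests()]; allows neighbouring-bin
#'   control matching when a stratum runs short.
#' @param seed Optional integer seed controlling all resampling.
#' @param out_dir Optional output directory.
#' @param quiet Suppress progress messages.
#' @return A `famclust_report` list: `counts`, `gif_all`, `gif_distant`,
#'   `rr`, `scan`, `summary` (the headline numbers as a one-row tibble per
#'   statistic).
#' @export
run_full_analysis <- function(g, definition = case_definition(),
                              min_completeness = 12, n_sets = 1000,
                              age_cutoff = 65, p_threshold = 0.01,
                              min_cases = 5, relax_matching = FALSE,
                              seed = NULL, out_dir = NULL, quiet = FALSE) {
  if (is.character(g)) g <- read_genealogy(g)
  if (!is.null(seed)) set.seed(seed)
  say <- function(...) if (!quiet) rlang::inform(sprintf(...))

  say("individuals: %d", nrow(g))
  universe <- withCallingHandlers(
    eligible_decedents(g, min_completeness),
    message = function(m) if (quiet) invokeRestart("muffleMessage"))
  say("decedents with certificate: %d", sum(has_death_certificate(g)))
  say("eligible universe (completeness >= %d): %d", min_completeness,
      length(universe))
  cases <- classify_cases(g, universe, definition)
  say("disease cases: %d", length(cases))
  if (length(cases) < 2) {
    rlang::abort("fewer than 2 cases; familial clustering analysis undefined")
  }

  both <- gif_tests(g, universe, cases, n_sets = n_sets,
                    relax_matching = relax_matching)
  gif_all <- both$all
  gif_distant <- both$distant
  cohorts <- build_cohorts(g, universe, cases)
  say("cohort strata: %d", nrow(cohorts))
  rr <- rr_table(g, universe, cases, age_cutoff = age_cutoff,
                 cohorts = cohorts)
  scan <- scan_pedigrees(g, universe, cases, cohorts = cohorts,
                         p_threshold = p_threshold, min_cases = min_cases)
  say("pedigrees flagged: %d", sum(scan$flagged))

  report <- structure(list(
    counts = list(
      n_individuals = nrow(g),
      n_certificates = sum(has_death_certificate(g)),
      n_universe = length(universe),
      n_cases = length(cases),
      n_strata = nrow(cohorts),
      n_pedigrees_flagged = sum(scan$flagged)
    ),
    gif_all = gif_all,
    gif_distant = gif_distant,
    rr = rr,
    scan = scan
  ), class = "famclust_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.famclust_report <- function(x, ...) {
  cat("familial clustering report\n")
  cat(sprintf("  universe %d, cases %d\n", x$counts$n_universe,
              x$counts$n_cases))
  print(x$gif_all)
  print(x$gif_distant)
  cat("relative risks:\n")
  print(as.data.frame(x$rr), digits = 3)
  cat(sprintf("pedigrees flagged: %d\n", x$counts$n_pedigrees_flagged))
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Emits `report.json` (full machine-readable report: counts, the summary
#' line of each GIF variant with its control distribution, the RR table,
#' and the pedigree scan), plus TSV tables `rr_table.tsv`, `scan.tsv` and
#' `gif_by_distance.tsv`.
#'
#' @param report A `famclust_report`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gif_json <- function(r) list(
    n = r$n_cases, variant = r$variant, n_sets = r$n_sets,
    case_gif = r$case_gif, mean_control_gif = r$mean_control_gif,
    empirical_p = r$empirical_p,
    case_by_distance = as.numeric(r$case_by_distance),
    mean_control_by_distance = as.numeric(colMeans(r$control_by_distance)),
    control_gifs = as.numeric(r$control_gifs)
  )
  json <- list(
    counts = report$counts,
    gif = gif_json(report$gif_all),
    dgif = gif_json(report$gif_distant),
    relative_risks = report$rr,
    pedigree_scan = report$scan
  )
  p_json <- file.path(out_dir, "report.json")
  jsonlite::write_json(json, p_json, auto_unbox = TRUE, digits = NA)
  p_rr <- file.path(out_dir, "rr_table.tsv")
  utils::write.table(report$rr, p_rr, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p_scan <- file.path(out_dir, "scan.tsv")
  utils::write.table(report$scan, p_scan, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  fig <- dplyr::full_join(
    contribution_plot_data(report$gif_all),
    contribution_plot_data(report$gif_distant) |>
      dplyr::rename(distant_case_contribution = "case_contribution",
                    distant_mean_control_contribution =
                      "mean_control_contribution"),
    by = "distance")
  p_fig <- file.path(out_dir, "gif_by_distance.tsv")
  utils::write.table(fig, p_fig, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p_json, p_rr, p_scan, p_fig))
}
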