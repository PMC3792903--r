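test_that("cohort tables partition the universe with per-stratum rates", {
  study <- sim_case_study(sim_config(n_founder_couples = 40))
  coh <- build_cohorts(study$g, study$universe, study$cases)
  expect_equal(sum(coh$n_deaths), length(study$universe))
  expect_equal(sum(coh$n_case_deaths), length(study$cases))
  expect_equal(coh$rate, coh$n_case_deaths / coh$n_deaths)
  # removing one case lowers exactly its stratum's numerator by one
  drop <- study$cases[1]
  coh2 <- build_cohorts(study$g, study$universe, setdiff(study$cases, drop))
  key <- matching_key(study$g, drop)$key
  merged <- dplyr::left_join(coh, coh2, by = "key",
                             suffix = c("", "_2"))
  expect_equal(merged$n_case_deaths[merged$key == key] -
                 merged$n_case_deaths_2[merged$key == key], 1)
  expect_equal(merged$n_case_deaths[merged$key != key],
               merged$n_case_deaths_2[merged$key != key])
})

test_that("single-stratum arithmetic: 2 cases in 100 deaths is rate 0.02", {
  g <- genealogy(tibble::tibble(
    id = sprintf("p%03d", 1:100), father_id = NA_character_,
    mother_id = NA_character_, sex = "male", birth_year = 1900L,
    birthplace = "in_state", death_year = 1970L,
    causes = c("10:G30", "10:G30", rep("10:I25.1", 98))
  ))
  u <- g$id
  coh <- build_cohorts(g, u, classify_cases(g, u))
  expect_equal(nrow(coh), 1)
  expect_equal(coh$rate, 0.02)
})

nuclear5 <- function() {
  genealogy(tibble::tibble(
    id = c("f", "m", "p", "s1", "s2"),
    father_id = c(NA, NA, "f", "f", "f"),
    mother_id = c(NA, NA, "m", "m", "m"),
    sex = c("male", "female", "male", "female", "male"),
    birth_year = c(1900L, 1901L, 1930L, 1932L, 1934L),
    birthplace = "in_state",
    death_year = c(1970L, 1975L, 2000L, 2002L, 2004L),
    causes = ""
  ))
}

test_that("first-degree relatives of one proband are parents and siblings", {
  g <- nuclear5()
  d1 <- enumerate_relatives(g, "p", 1, g$id)
  expect_setequal(d1, c("f", "m", "s1", "s2"))
  expect_length(enumerate_relatives(g, "p", 2, g$id), 0)
})

test_that("relatives deduplicate across probands and keep co-probands", {
  g <- nuclear5()
  d1 <- enumerate_relatives(g, c("p", "s1"), 1, g$id)
  # each sibling proband is the other's first-degree relative; shared
  # parents appear once
  expect_setequal(d1, c("f", "m", "p", "s1", "s2"))
})

test_that("an individual related at several degrees lands in the closest", {
  fx <- fixture_pedigrees()$cousins
  # probands c1 and a2: c2 is a first cousin of c1 (degree 3) and a child
  # of a2 (degree 1)
  sets <- famclust:::relative_degree_sets(fx, c("c1", "a2"), fx$id)
  expect_true("c2" %in% sets[[1]])
  expect_false("c2" %in% sets[[3]])
  # the three degree sets never overlap
  expect_length(intersect(sets[[1]], sets[[2]]), 0)
  expect_length(intersect(sets[[1]], sets[[3]]), 0)
  expect_length(intersect(sets[[2]], sets[[3]]), 0)
})

test_that("degree classification matches the kinship-coefficient oracle", {
  # immigrant-only marriages: no inbreeding, no double relationships, so
  # kinship pins the degree exactly
  for (seed in c(2, 9)) {
    g <- random_pedigree(seed, n_couples = 3, n_gen = 5, within = 0,
                         offspring = 2.5)
    probands <- sample(g$id, 5)
    sets <- famclust:::relative_degree_sets(g, probands, g$id)
    K <- kinship_matrix(g)
    others <- setdiff(g$id, character(0))
    for (x in sample(others, min(40, length(others)))) {
      phi <- max(K[x, probands][probands != x])
      want <- oracle_degree_from_kinship(phi)
      got <- if (x %in% sets[[1]]) 1L else if (x %in% sets[[2]]) 2L
             else if (x %in% sets[[3]]) 3L else NA_integer_
      expect_identical(got, want)
    }
  }
})

test_that("the exact Poisson O/E interval behaves at the boundaries", {
  ci <- rr_confidence_interval(0, 5)
  expect_equal(ci$ci_low, 0)
  expect_gt(ci$ci_high, 0)
  # observed equal to expected: interval straddles 1
  ci2 <- rr_confidence_interval(20, 20)
  expect_lt(ci2$ci_low, 1)
  expect_gt(ci2$ci_high, 1)
  # Byar's approximation tracks the exact interval for moderate counts
  exact <- rr_confidence_interval(50, 40)
  byar <- rr_confidence_interval(50, 40, method = "byar")
  expect_equal(byar$ci_low, exact$ci_low, tolerance = 0.01)
  expect_equal(byar$ci_high, exact$ci_high, tolerance = 0.01)
})

test_that("rr_estimate against the whole universe is exactly 1", {
  study <- sim_case_study(sim_config(n_founder_couples = 40))
  est <- rr_estimate(study$g, study$universe, study$cases, study$universe)
  expect_equal(est$rr, 1, tolerance = 1e-12)
  expect_equal(est$observed, length(study$cases))
  expect_equal(est$expected, length(study$cases), tolerance = 1e-9)
})

test_that("expected counts are invariant to rate-preserving refinements", {
  # one stratum split in two with identical rates leaves expected unchanged
  g <- genealogy(tibble::tibble(
    id = sprintf("p%03d", 1:100), father_id = NA_character_,
    mother_id = NA_character_,
    sex = rep(c("male", "female"), each = 50),
    birth_year = 1900L, birthplace = "in_state", death_year = 1970L,
    causes = rep(c("10:G30", rep("", 49)), 2)
  ))
  u <- g$id
  cases <- classify_cases(g, u)
  rel <- g$id[3:60]
  est <- rr_estimate(g, u, cases, rel)
  # same population, all in one stratum
  g2 <- g
  g2$sex <- "male"
  g2 <- genealogy(as.data.frame(g2))
  est2 <- rr_estimate(g2, u, classify_cases(g2, u), rel)
  expect_equal(est$expected, est2$expected, tolerance = 1e-12)
})

test_that("rr_table produces the full degree-by-age-stratum layout", {
  study <- sim_case_study(sim_config(n_founder_couples = 60))
  tab <- rr_table(study$g, study$universe, study$cases, age_cutoff = 65)
  expect_s3_class(tab, "rr_table")
  expect_equal(nrow(tab), 6)
  expect_setequal(unique(tab$age_stratum), c("all", "under_65"))
  expect_equal(tab$degree[tab$age_stratum == "all"], 1:3)
  expect_true(all(tab$rr[!is.na(tab$rr)] >= 0))
  # no individual is counted in two degree sets
  sets <- famclust:::relative_degree_sets(study$g, study$cases,
                                          study$universe)
  expect_equal(length(unique(unlist(sets))), length(unlist(sets)))
  # removing all cases empties the observed column
  tab0 <- rr_table(study$g, study$universe, character(0))
  expect_true(all(tab0$observed == 0))
})
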