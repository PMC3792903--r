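sibship_ids <- c("s1", "s2", "s3", paste0("u", 1:7))

test_that("the GIF statistic is the scaled mean kinship over all pairs", {
  fx <- fixture_pedigrees()$sibship
  # ten mutually unrelated founders
  g0 <- gif_statistic(fx, paste0("u", 1:7))
  expect_equal(g0$gif, 0)
  # one sibship of 3 among 10: 1e5 * (3/4) / 45
  gs <- gif_statistic(fx, sibship_ids)
  expect_equal(gs$gif, 1e5 * 0.75 / 45, tolerance = 1e-12)
  expect_equal(sum(gs$by_distance), gs$gif)
  # distant variant drops every pair (all related pairs are siblings)
  expect_equal(gif_statistic(fx, sibship_ids, min_distance = 4)$gif, 0)
  expect_error(gif_statistic(fx, "s1"), "fewer than 2")
})

test_that("GIF is invariant to iteration order and relabelling", {
  g <- random_pedigree(31, n_couples = 3, n_gen = 5, within = 0.9)
  ids <- sample(g$id, 15)
  a <- gif_statistic(g, ids)
  b <- gif_statistic(g, rev(ids))
  expect_equal(a$gif, b$gif)
  expect_equal(a$by_distance, b$by_distance)
  # relabel ids bijectively
  map <- stats::setNames(paste0("X", seq_len(nrow(g))), g$id)
  g2 <- g
  g2$id <- unname(map[g$id])
  g2$father_id <- ifelse(is.na(g$father_id), NA, unname(map[g$father_id]))
  g2$mother_id <- ifelse(is.na(g$mother_id), NA, unname(map[g$mother_id]))
  g2 <- genealogy(as.data.frame(g2))
  expect_equal(gif_statistic(g2, unname(map[ids]))$gif, a$gif)
})

make_matched_world <- function() {
  # two parallel sibships per stratum so every case has matchable controls
  rows <- list()
  k <- 0
  for (fam in 1:6) {
    k <- k + 1
    fid <- paste0("F", fam); mid <- paste0("M", fam)
    rows[[length(rows) + 1]] <- tibble::tibble(
      id = c(fid, mid), father_id = NA_character_, mother_id = NA_character_,
      sex = c("male", "female"), birth_year = c(1898L, 1899L),
      birthplace = "in_state", death_year = 1970L, causes = "9:414.0"
    )
    rows[[length(rows) + 1]] <- tibble::tibble(
      id = paste0("c", fam, "_", 1:4),
      father_id = fid, mother_id = mid,
      sex = c("male", "male", "female", "female"),
      birth_year = 1931L, birthplace = "in_state",
      death_year = 2000L,
      causes = ""
    )
  }
  genealogy(dplyr::bind_rows(rows))
}

test_that("matched control sets share the cases' stratum profile", {
  g <- make_matched_world()
  universe <- g$id[startsWith(g$id, "c")]
  cases <- c("c1_1", "c1_3", "c2_2")
  set.seed(1)
  ctrl <- sample_control_set(g, universe, cases)
  expect_length(ctrl, 3)
  expect_true(!any(ctrl %in% cases))
  key_of <- function(ids) sort(matching_key(g, ids)$key)
  expect_equal(key_of(ctrl), key_of(cases))
  # forced case: exactly one matching non-case per case
  u2 <- c("c1_1", "c1_2", "c3_3", "c3_4")   # one male pair, one female pair
  forced <- sample_control_set(g, u2, c("c1_1", "c3_3"))
  expect_setequal(forced, c("c1_2", "c3_4"))
})

test_that("exhausted strata error unless relaxation is requested", {
  g <- make_matched_world()
  # all males of the 1931 bin are cases: no within-stratum controls left
  males <- g$id[g$sex == "male" & startsWith(g$id, "c")]
  universe <- g$id[startsWith(g$id, "c")]
  expect_error(sample_control_set(g, universe, males), "exhausted")
  # neighbouring-bin relaxation borrows the shortfall from adjacent bins
  g2 <- g
  g2$birth_year[g2$id == "c6_1"] <- 1927L
  g2 <- genealogy(as.data.frame(g2))
  u3 <- c("c1_1", "c6_1")                   # both male, bins 1930 and 1925
  expect_error(sample_control_set(g2, u3, "c1_1"), "exhausted")
  expect_equal(sample_control_set(g2, u3, "c1_1", relax_matching = TRUE),
               "c6_1")
})

test_that("control draws are uniform within a stratum", {
  g <- make_matched_world()
  universe <- g$id[startsWith(g$id, "c")]
  cases <- "c1_1"
  pool <- setdiff(g$id[g$sex == "male" & startsWith(g$id, "c")], cases)
  set.seed(42)
  draws <- replicate(3000, sample_control_set(g, universe, cases))
  tab <- table(factor(draws, levels = pool))
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)
})

test_that("gif_test is reproducible and decomposes exactly", {
  study <- sim_case_study(sim_config(n_founder_couples = 60))
  set.seed(7)
  r1 <- gif_test(study$g, study$universe, study$cases, n_sets = 30,
                 relax_matching = TRUE)
  set.seed(7)
  r2 <- gif_test(study$g, study$universe, study$cases, n_sets = 30,
                 relax_matching = TRUE)
  expect_identical(r1, r2)
  expect_equal(sum(r1$case_by_distance), r1$case_gif, tolerance = 1e-9)
  expect_equal(rowSums(r1$control_by_distance), r1$control_gifs)
  expect_gte(r1$empirical_p, 1 / 31)
  expect_lte(r1$empirical_p, 1)
})

test_that("both variants from shared draws are mutually consistent", {
  study <- sim_case_study(sim_config(n_founder_couples = 60))
  set.seed(11)
  both <- gif_tests(study$g, study$universe, study$cases, n_sets = 25,
                    relax_matching = TRUE)
  expect_named(both, c("all", "distant"))
  # the distant statistic is the all-variant decomposition from class 4 on
  expect_equal(both$distant$case_gif,
               sum(both$all$case_by_distance[4:12]), tolerance = 1e-9)
  expect_true(all(both$distant$case_by_distance[1:3] == 0))
  expect_true(all(both$distant$control_by_distance[, 1:3] == 0))
})

test_that("cases planted in one extended pedigree hit the empirical floor", {
  study <- sim_case_study(sim_config(n_founder_couples = 60))
  g <- study$g
  # take the founder with the most eligible descendants and call a tight
  # cluster of them the case set
  fnd <- founders(g)
  sizes <- vapply(fnd, function(f)
    sum(descendants(g, f) %in% study$universe), integer(1))
  top <- fnd[which.max(sizes)]
  cluster <- intersect(descendants(g, top), study$universe)
  cases <- cluster[seq_len(min(12, length(cluster)))]
  set.seed(3)
  r <- gif_test(g, study$universe, cases, n_sets = 99, relax_matching = TRUE)
  expect_equal(r$empirical_p, 1 / 100)
})

test_that("contribution tables follow the decomposition identities", {
  study <- sim_case_study(sim_config(n_founder_couples = 60))
  set.seed(5)
  r <- gif_test(study$g, study$universe, study$cases, n_sets = 20,
                relax_matching = TRUE)
  tab <- contribution_plot_data(r)
  expect_named(tab, c("distance", "case_contribution",
                      "mean_control_contribution"))
  expect_equal(nrow(tab), 12)
  expect_equal(sum(tab$case_contribution), r$case_gif)
  expect_equal(sum(tab$mean_control_contribution), r$mean_control_gif,
               tolerance = 1e-9)
  expect_equal(tidy(r), tab)
  gl <- glance(r)
  expect_equal(gl$empirical_p, r$empirical_p)
})
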