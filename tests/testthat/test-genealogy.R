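test_that("reading a minimal trio gives 3 individuals and 2 founders", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "id\tfather_id\tmother_id\tsex\tbirth_year\tbirthplace\tdeath_year\tcauses",
    "f\t\t\tmale\t1900\tin_state\t1975\t9:414.0",
    "m\t\t\tfemale\t1902\tin_state\t1980\t",
    "c\tf\tm\tfemale\t1930\tin_state\t\t"
  ), path)
  g <- read_genealogy(path)
  expect_s3_class(g, "genealogy")
  expect_equal(nrow(g), 3)
  expect_setequal(founders(g), c("f", "m"))
  expect_equal(sum(has_death_certificate(g)), 2)
})

test_that("structural errors are caught: self-parenting, cycles, duplicates", {
  base <- tibble::tibble(
    id = "a", father_id = "a", mother_id = NA_character_, sex = "male",
    birth_year = 1900L, birthplace = "in_state", death_year = NA_integer_,
    causes = ""
  )
  expect_error(genealogy(base), "cycle")
  two <- tibble::tibble(
    id = c("a", "b"), father_id = c("b", NA), mother_id = c(NA, "a"),
    sex = c("male", "male"), birth_year = 1900L, birthplace = "in_state",
    death_year = NA_integer_, causes = ""
  )
  expect_error(genealogy(two), "cycle|female|mother")
  dup <- tibble::tibble(
    id = c("a", "a"), father_id = NA_character_, mother_id = NA_character_,
    sex = "male", birth_year = 1900L, birthplace = "in_state",
    death_year = NA_integer_, causes = ""
  )
  expect_error(genealogy(dup), "duplicate")
})

test_that("dangling parent pointers error unless lenient downgrades them", {
  raw <- tibble::tibble(
    id = "c", father_id = "ghost", mother_id = NA_character_, sex = "male",
    birth_year = 1950L, birthplace = "in_state", death_year = NA_integer_,
    causes = ""
  )
  expect_error(genealogy(raw), "unresolved")
  expect_warning(g <- genealogy(raw, lenient = TRUE), "dangling")
  expect_true(is.na(g$father_id[1]))
})

test_that("parental sex consistency is enforced", {
  raw <- tibble::tibble(
    id = c("p", "c"), father_id = c(NA, "p"), mother_id = NA_character_,
    sex = c("female", "male"), birth_year = c(1900L, 1930L),
    birthplace = "in_state", death_year = NA_integer_, causes = ""
  )
  expect_error(genealogy(raw), "female")
})

test_that("write/read round-trips a generated multi-generation genealogy", {
  g <- random_pedigree(404, n_couples = 5, n_gen = 5)
  for (dialect in c("tsv", "csv")) {
    path <- withr::local_tempfile(fileext = paste0(".", dialect))
    write_genealogy(g, path, dialect = dialect)
    g2 <- read_genealogy(path, dialect = dialect)
    expect_equal(as.data.frame(g2), as.data.frame(g))
  }
})

test_that("ancestor completeness counts filled slots, not persons", {
  fx <- fixture_pedigrees()
  # founders have empty ancestry; full 3-generation ancestry scores 14
  expect_equal(ancestor_completeness(fx$cousins, "gpa"), 0L)
  full <- tibble::tibble(
    id = c(paste0("g", 1:8), paste0("gp", 1:4), "f", "m", "x"),
    father_id = c(rep(NA, 8), "g1", "g3", "g5", "g7", "gp1", "gp3", "f"),
    mother_id = c(rep(NA, 8), "g2", "g4", "g6", "g8", "gp2", "gp4", "m"),
    sex = c(rep(c("male", "female"), 6), "male", "female", "female"),
    birth_year = rep(1900L, 15), birthplace = "in_state",
    death_year = NA_integer_, causes = ""
  )
  gfull <- genealogy(full)
  expect_equal(ancestor_completeness(gfull, "x"), 14L)
  # drop one grandparent (and its ancestors): parents 2 + grandparents 3
  cut <- gfull[gfull$id != "gp4", ]
  cut$mother_id[cut$id == "m"] <- NA
  expect_equal(ancestor_completeness(genealogy(cut), "x"), 5L + 6L)
  # no great-grandparents at all: 2 + 3 = 5
  cut2 <- full[!grepl("^g[0-9]$", full$id), ]
  cut2$father_id[cut2$id %in% paste0("gp", 1:4)] <- NA
  cut2$mother_id[cut2$id %in% paste0("gp", 1:4)] <- NA
  cut2 <- cut2[cut2$id != "gp4", ]
  cut2$mother_id[cut2$id == "m"] <- NA
  expect_equal(ancestor_completeness(genealogy(cut2), "x"), 5L)
  # pedigree collapse: one grandparent couple occupying both slots still
  # fills all four grandparent slots
  collapsed <- tibble::tibble(
    id = c("gp1", "gp2", "f", "m", "x"),
    father_id = c(NA, NA, "gp1", "gp1", "f"),
    mother_id = c(NA, NA, "gp2", "gp2", "m"),
    sex = c("male", "female", "male", "female", "female"),
    birth_year = 1900L, birthplace = "in_state",
    death_year = NA_integer_, causes = ""
  )
  expect_equal(ancestor_completeness(genealogy(collapsed), "x"), 6L)
})

test_that("completeness never increases when an individual is removed", {
  g <- random_pedigree(77, n_couples = 3, n_gen = 4)
  before <- ancestor_completeness(g)
  victim <- sample(founders(g), 1)
  cut <- g[g$id != victim, ]
  cut$father_id[!is.na(cut$father_id) & cut$father_id == victim] <- NA
  cut$mother_id[!is.na(cut$mother_id) & cut$mother_id == victim] <- NA
  g2 <- genealogy(as.data.frame(cut))
  after <- ancestor_completeness(g2)
  expect_true(all(after <= before[match(g2$id, g$id)]))
})

test_that("eligibility boundary sits exactly at the completeness threshold", {
  sim <- simulate_genealogy(sim_config(n_founder_couples = 20), seed = 99)
  g <- sim$genealogy
  comp <- ancestor_completeness(g)
  u <- suppressMessages(eligible_decedents(g))
  in_u <- g$id %in% u
  expect_true(all(comp[in_u] >= 12))
  expect_true(all(has_death_certificate(g)[in_u]))
  # decedents failing either condition are excluded
  out <- has_death_certificate(g) & !is.na(g$birth_year) & comp < 12
  expect_false(any(g$id[out] %in% u))
  # generator bookkeeping agrees exactly
  expect_setequal(u, sim$truth$individuals$id[sim$truth$individuals$eligible])
})

test_that("all-founder decedent populations have an empty universe", {
  g <- genealogy(tibble::tibble(
    id = c("a", "b"), father_id = NA_character_, mother_id = NA_character_,
    sex = c("male", "female"), birth_year = 1900L, birthplace = "in_state",
    death_year = 1980L, causes = ""
  ))
  expect_length(eligible_decedents(g), 0)
})

test_that("case classification matches by code prefix with dot stripping", {
  fx <- fixture_pedigrees()$trio
  u <- fx$id[has_death_certificate(fx)]
  expect_setequal(classify_cases(fx, u), "c")          # G30.9 matches G30
  # dotted and undotted ICD-9 forms match the same definition
  g <- genealogy(tibble::tibble(
    id = c("a", "b", "c", "d"), father_id = NA_character_,
    mother_id = NA_character_, sex = "male", birth_year = 1900L,
    birthplace = "in_state", death_year = 1980L,
    causes = c("9:331.0", "9:3310", "9:290.0", "10:G301")
  ))
  got <- classify_cases(g, g$id)
  expect_setequal(got, c("a", "b", "d"))               # senile dementia is not a case
})

test_that("primary-only definitions ignore contributing causes", {
  g <- genealogy(tibble::tibble(
    id = c("a", "b"), father_id = NA_character_, mother_id = NA_character_,
    sex = "male", birth_year = 1900L, birthplace = "in_state",
    death_year = 1980L,
    causes = c("10:G30;10:I25.1", "10:I25.1;10:G30")
  ))
  expect_setequal(classify_cases(g, g$id), c("a", "b"))
  primary <- case_definition(require_primary_only = TRUE)
  expect_setequal(classify_cases(g, g$id, primary), "a")
})

test_that("classified cases recover the generator's planted case labels", {
  study <- sim_case_study(sim_config(scenario = "genetic",
                                     n_founder_couples = 40))
  expect_setequal(study$cases, study$sim$truth$eligible_case_ids)
  expect_true(all(study$cases %in% study$universe))
})

test_that("the PED reader maps the linkage format onto the genealogy model", {
  path <- withr::local_tempfile(fileext = ".ped")
  writeLines(c(
    "FAM1 f 0 0 1 1",
    "FAM1 m 0 0 2 1",
    "FAM1 c f m 2 2"
  ), path)
  g <- read_ped(path)
  expect_equal(nrow(g), 3)
  expect_setequal(founders(g), c("f", "m"))
  expect_equal(g$affected, c(FALSE, FALSE, TRUE))
  expect_equal(g$sex, c("male", "female", "female"))
})
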