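#' Simulation configuration for the synthetic genealogy generator
#'
#' Defines the demographic and disease model behind
#' [simulate_genealogy()]. Defaults emulate a settler-descendant population
#' genealogy with linked death certificates: founder couples from the early
#' 19th century, about six recorded generations, Poisson family sizes,
#' immigrant spouses entering as founders (so ancestor-completeness
#' filtering bites), a certificate window that truncates both early and
#' recent deaths, and a disease coded on roughly 1.4% of certificates
#' absent any risk factor.
#'
#' @param n_founder_couples Founder couples seeding generation 0.
#' @param n_generations Total generations (founders included).
#' @param mean_offspring Mean children per couple (Poisson).
#' @param p_mate Probability an individual forms a union.
#' @param p_marry_within Probability a union partner is drawn from the
#'   population (same generation, first-cousin-or-closer unions barred);
#'   otherwise the spouse is a new immigrant founder.
#' @param founder_birth_year_range Birth-year interval for generation-0
#'   founders.
#' @param generation_gap_mean,generation_gap_sd Years from mean parental
#'   birth to child birth.
#' @param age_death_mean,age_death_sd Age at death, normal truncated to
#'   \[1, 105\].
#' @param cert_year_range Deaths outside this window have no linked
#'   certificate.
#' @param cert_prob Linkage probability for deaths inside the window.
#' @param baseline_case_rate Probability a certificated death is
#'   disease-coded absent risk factors.
#' @param scenario `"null"` (no familial clustering), `"genetic"`
#'   (transmitted dominant risk allele) or `"environment"`
#'   (nuclear-family-shared risk, no transmission).
#' @param allele_freq Founder/immigrant risk-allele frequency (genetic
#'   scenario).
#' @param penetrance_rr Multiplicative disease-coding risk for carriers.
#' @param p_household Probability a nuclear family is risk-exposed
#'   (environment scenario).
#' @param household_rr Multiplicative risk shared by members of an exposed
#'   nuclear family.
#' @param icd10_year Deaths from this year on are coded with the ICD-10
#'   disease code, earlier deaths with the ICD-9 code.
#' @param p_immigrant_out_of_state,p_native_out_of_state Birthplace-flag
#'   probabilities.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_founder_couples = 120,
                       n_generations = 6,
                       mean_offspring = 2.6,
                       p_mate = 0.85,
                       p_marry_within = 0.6,
                       founder_birth_year_range = c(1810, 1840),
                       generation_gap_mean = 27,
                       generation_gap_sd = 5,
                       age_death_mean = 74,
                       age_death_sd = 14,
                       cert_year_range = c(1904, 2025),
                       cert_prob = 0.85,
                       baseline_case_rate = 0.0144,
                       scenario = c("null", "genetic", "environment"),
                       allele_freq = 0.02,
                       penetrance_rr = 50,
                       p_household = 0.05,
                       household_rr = 30,
                       icd10_year = 1999,
                       p_immigrant_out_of_state = 0.7,
                       p_native_out_of_state = 0.15) {
  cfg <- list(
    n_founder_couples = n_founder_couples, n_generations = n_generations,
    mean_offspring = mean_offspring, p_mate = p_mate,
    p_marry_within = p_marry_within,
    founder_birth_year_range = founder_birth_year_range,
    generation_gap_mean = generation_gap_mean,
    generation_gap_sd = generation_gap_sd,
    age_death_mean = age_death_mean, age_death_sd = age_death_sd,
    cert_year_range = cert_year_range, cert_prob = cert_prob,
    baseline_case_rate = baseline_case_rate,
    scenario = match.arg(scenario),
    allele_freq = allele_freq, penetrance_rr = penetrance_rr,
    p_household = p_household, household_rr = household_rr,
    icd10_year = icd10_year,
    p_immigrant_out_of_state = p_immigrant_out_of_state,
    p_native_out_of_state = p_native_out_of_state
  )
  probs <- c("p_mate", "p_marry_within", "cert_prob", "baseline_case_rate",
             "allele_freq", "p_household", "p_immigrant_out_of_state",
             "p_native_out_of_state")
  for (p in probs) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) {
      rlang::abort(paste0(p, " must be a probability in [0, 1]"))
    }
  }
  if (n_founder_couples < 1 || n_generations < 1) {
    rlang::abort("population must have at least one founder couple and generation")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a genealogy with linked synthetic death certificates
#'
#' Generates a multi-generation population from founder couples: per
#' generation, individuals form unions (within the population, under an
#' incest bar excluding relationships of degree 2 or closer, or with new
#' immigrant founders), have Poisson-distributed numbers of children, and
#' are assigned birth years, sexes, ages at death and linked death
#' certificates. Disease coding at death follows the configured scenario:
#' a transmitted dominant risk allele (genetic), a nuclear-family-shared
#' risk multiplier with no transmission (environment), or baseline risk
#' only (null). The phenotype is "disease contributed to death" — an
#' attribute of the death record, not an illness process.
#'
#' @param cfg A [sim_config()].
#' @param seed Optional integer seed (forwarded to [set.seed()]); with a
#'   fixed seed the output is bit-reproducible.
#' @return List with `genealogy` (a validated `genealogy`) and `truth`, the
#'   generator's own bookkeeping: a tibble (`id`, `generation`,
#'   `immigrant`, `carrier`, `household_exposed`, `completeness`,
#'   `eligible`, `case`) plus the config and derived counts.
#' @export
simulate_genealogy <- function(cfg = sim_config(), seed = NULL) {
  if (!inherits(cfg, "sim_config")) rlang::abort("cfg must be a sim_config")
  if (!is.null(seed)) set.seed(seed)

  # growing columns, indexed by position; batch appends per generation
  fb <- cfg$founder_birth_year_range
  nf0 <- 2 * cfg$n_founder_couples
  sex <- rep(c("male", "female"), cfg$n_founder_couples)
  father <- rep(NA_integer_, nf0)
  mother <- rep(NA_integer_, nf0)
  by <- round(stats::runif(nf0, fb[1], fb[2]))
  gen <- rep(0L, nf0)
  imm <- rep(TRUE, nf0)
  append_people <- function(sex_, father_, mother_, by_, gen_, imm_) {
    k <- length(sex)
    sex <<- c(sex, sex_); father <<- c(father, father_)
    mother <<- c(mother, mother_); by <<- c(by, by_)
    gen <<- c(gen, gen_); imm <<- c(imm, imm_)
    k + seq_along(sex_)
  }
  couples <- cbind(seq(1, nf0, by = 2), seq(2, nf0, by = 2))

  # marriage bar: reject unions sharing any ancestor within three
  # generations of both partners (second cousins or closer). Distant
  # consanguineous unions (third cousins on) remain possible, so pedigree
  # loops still arise.
  parents_of <- function(i) { p <- c(father[i], mother[i]); p[!is.na(p)] }
  anc3_of <- function(i) {
    p1 <- parents_of(i)
    p2 <- unlist(lapply(p1, parents_of))
    p3 <- unlist(lapply(p2, parents_of))
    c(p1, p2, p3)
  }
  too_close <- function(a, b) {
    length(intersect(anc3_of(a), anc3_of(b))) > 0
  }

  for (gnum in seq_len(cfg$n_generations - 1) - 1L) {
    if (gnum > 0) {
      members <- which(gen == gnum)
      members <- members[sample.int(length(members))]
      mate <- stats::runif(length(members)) <= cfg$p_mate
      within <- stats::runif(length(members)) < cfg$p_marry_within
      partnered <- logical(length(members))
      male_cpl <- integer(); female_cpl <- integer()
      need_immigrant <- integer()
      for (k in seq_along(members)) {
        if (partnered[k] || !mate[k]) next
        i <- members[k]
        spouse_k <- NA_integer_
        if (within[k]) {
          cand <- which(!partnered & sex[members] != sex[i] &
                          sex[members] != "unknown")
          cand <- cand[cand != k]
          for (ck in utils::head(cand[sample.int(length(cand))], 10)) {
            if (!too_close(i, members[ck])) { spouse_k <- ck; break }
          }
        }
        if (is.na(spouse_k)) {
          need_immigrant <- c(need_immigrant, i)
          partnered[k] <- TRUE
        } else {
          partnered[c(k, spouse_k)] <- TRUE
          j <- members[spouse_k]
          if (sex[i] == "male") { male_cpl <- c(male_cpl, i); female_cpl <- c(female_cpl, j) }
          else { male_cpl <- c(male_cpl, j); female_cpl <- c(female_cpl, i) }
        }
      }
      if (length(need_immigrant) > 0) {
        sp <- append_people(
          ifelse(sex[need_immigrant] == "male", "female", "male"),
          rep(NA_integer_, length(need_immigrant)),
          rep(NA_integer_, length(need_immigrant)),
          by[need_immigrant] + round(stats::rnorm(length(need_immigrant), 0, 4)),
          rep(gnum, length(need_immigrant)),
          rep(TRUE, length(need_immigrant)))
        male_sp <- sex[need_immigrant] == "male"
        male_cpl <- c(male_cpl, need_immigrant[male_sp], sp[!male_sp])
        female_cpl <- c(female_cpl, sp[male_sp], need_immigrant[!male_sp])
      }
      couples <- cbind(male_cpl, female_cpl)
    }
    # children of this generation's couples, batch-created
    n_kids <- stats::rpois(nrow(couples), cfg$mean_offspring)
    f <- rep(couples[, 1], n_kids)
    m <- rep(couples[, 2], n_kids)
    if (length(f) > 0) {
      byr <- round((by[f] + by[m]) / 2 +
                     stats::rnorm(length(f), cfg$generation_gap_mean,
                                  cfg$generation_gap_sd))
      byr <- pmax(byr, pmax(by[f], by[m]) + 15)
      append_people(ifelse(stats::runif(length(f)) < 0.5, "male", "female"),
                    f, m, byr, rep(gnum + 1L, length(f)),
                    rep(FALSE, length(f)))
    }
  }

  n <- length(sex)
  id <- sprintf("I%06d", seq_len(n))
  # mortality and certificate linkage
  age <- pmin(pmax(stats::rnorm(n, cfg$age_death_mean, cfg$age_death_sd), 1), 105)
  dy_true <- round(by + age)
  in_window <- dy_true >= cfg$cert_year_range[1] & dy_true <= cfg$cert_year_range[2]
  linked <- in_window & stats::runif(n) < cfg$cert_prob
  death_year <- ifelse(linked, dy_true, NA_real_)

  # risk-allele gene drop (used by the genetic scenario; tracked always so
  # truth files are comparable across scenarios)
  copies <- integer(n)
  fnd <- is.na(father)
  copies[fnd] <- stats::rbinom(sum(fnd), 2, cfg$allele_freq)
  for (gg in seq_len(max(gen))) {
    kids <- which(gen == gg & !fnd)
    if (length(kids) > 0) {
      copies[kids] <- stats::rbinom(length(kids), 1, copies[father[kids]] / 2) +
        stats::rbinom(length(kids), 1, copies[mother[kids]] / 2)
    }
  }
  carrier <- copies > 0

  # nuclear-family exposure (environment scenario)
  fam_key <- ifelse(is.na(father), NA_character_, paste(father, mother))
  fams <- unique(stats::na.omit(fam_key))
  exposed_fam <- fams[stats::runif(length(fams)) < cfg$p_household]
  exposed <- fam_key %in% exposed_fam
  for (fam in exposed_fam) {
    fm <- as.integer(strsplit(fam, " ", fixed = TRUE)[[1]])
    exposed[fm] <- TRUE
  }

  p_case <- rep(cfg$baseline_case_rate, n)
  if (cfg$scenario == "genetic") p_case[carrier] <- p_case[carrier] * cfg$penetrance_rr
  if (cfg$scenario == "environment") p_case[exposed] <- p_case[exposed] * cfg$household_rr
  p_case <- pmin(p_case, 1)
  is_case <- linked & stats::runif(n) < p_case

  causes <- sim_causes(n, is_case, death_year, linked, cfg$icd10_year)

  birthplace <- ifelse(
    stats::runif(n) < ifelse(imm, cfg$p_immigrant_out_of_state,
                             cfg$p_native_out_of_state),
    "out_of_state", "in_state")

  g <- genealogy(tibble::tibble(
    id = id,
    father_id = ifelse(is.na(father), NA_character_, id[father]),
    mother_id = ifelse(is.na(mother), NA_character_, id[mother]),
    sex = sex,
    birth_year = as.integer(by),
    birthplace = birthplace,
    death_year = as.integer(death_year),
    causes = causes
  ))

  # construction-side completeness bookkeeping: filled slots at depths 1-3
  s1 <- (!is.na(father)) + (!is.na(mother))
  sum_par <- function(v) {
    out <- numeric(n)
    hf <- !is.na(father); hm <- !is.na(mother)
    out[hf] <- v[father[hf]]
    out[hm] <- out[hm] + v[mother[hm]]
    out
  }
  completeness <- as.integer(s1 + sum_par(s1) + sum_par(sum_par(s1)))
  eligible <- linked & completeness >= 12

  if (!any(eligible)) {
    rlang::abort("degenerate population: no eligible decedents; enlarge the configuration")
  }

  truth <- list(
    individuals = tibble::tibble(
      id = id, generation = gen, immigrant = imm, carrier = carrier,
      household_exposed = exposed, completeness = completeness,
      eligible = eligible, case = is_case
    ),
    config = cfg,
    n_individuals = n,
    n_certificates = sum(linked),
    n_eligible = sum(eligible),
    case_ids = id[is_case],
    eligible_case_ids = id[is_case & eligible]
  )
  list(genealogy = g, truth = truth)
}

# cause-of-death strings: cases get the disease code (primary or, ~35% of
# the time, contributing after another cause); non-cases draw from a pool
# that includes senile-dementia codes the case definition must NOT match
sim_causes <- function(n, is_case, death_year, linked, icd10_year) {
  icd9_pool <- c("9:414.0", "9:162.9", "9:436", "9:250.0")
  icd10_pool <- c("10:I25.1", "10:C34.9", "10:I64", "10:E11.9")
  causes <- rep("", n)
  li <- which(linked)
  k <- length(li)
  if (k == 0) return(causes)
  pre10 <- death_year[li] < icd10_year
  other1 <- ifelse(pre10, icd9_pool[sample.int(4, k, replace = TRUE)],
                   icd10_pool[sample.int(4, k, replace = TRUE)])
  other2 <- ifelse(pre10, icd9_pool[sample.int(4, k, replace = TRUE)],
                   icd10_pool[sample.int(4, k, replace = TRUE)])
  disease <- ifelse(pre10, "9:331.0", "10:G30")
  senile <- ifelse(pre10, "9:290.0", "10:F03")
  u1 <- stats::runif(k)
  u2 <- stats::runif(k)
  case_i <- is_case[li]
  out <- character(k)
  # cases: disease as contributing cause (~35%), else primary, sometimes
  # followed by another condition
  out[case_i] <- ifelse(u1[case_i] < 0.35,
                        paste(other1[case_i], disease[case_i], sep = ";"),
                        ifelse(u2[case_i] < 0.4,
                               paste(disease[case_i], other1[case_i], sep = ";"),
                               disease[case_i]))
  # non-cases: rare empty certificates, senile dementia (which the default
  # case definition must NOT match), or one-two ordinary causes
  nc <- !case_i
  two <- u2 < 0.5 & other1 != other2
  out[nc] <- ifelse(u1[nc] < 0.02, "",
                    ifelse(u1[nc] < 0.10, senile[nc],
                           ifelse(two[nc],
                                  paste(other1[nc], other2[nc], sep = ";"),
                                  other1[nc])))
  causes[li] <- out
  causes
}

#' Canonical small pedigrees used throughout the test bed
#'
#' Deterministic hand-built pedigrees exercising the analytically forced
#' kinship values: a parent-offspring trio; a sibship of three plus seven
#' unrelated singletons; four first cousins descending from one
#' grandparental couple; and a five-generation pedigree with a
#' first-cousin marriage whose offspring has self-kinship 17/32.
#'
#' @return Named list of `genealogy` objects: `trio`, `sibship`,
#'   `cousins`, `inbred_loop`.
#' @export
fixture_pedigrees <- function() {
  person <- function(id, f = NA, m = NA, sex = "male", by = 1900,
                     dy = NA, causes = "") {
    tibble::tibble(id = id, father_id = as.character(f),
                   mother_id = as.character(m), sex = sex,
                   birth_year = as.integer(by), birthplace = "in_state",
                   death_year = as.integer(dy), causes = causes)
  }
  trio <- genealogy(dplyr::bind_rows(
    person("f", sex = "male", by = 1900, dy = 1975, causes = "9:414.0"),
    person("m", sex = "female", by = 1902, dy = 1980, causes = ""),
    person("c", "f", "m", sex = "female", by = 1930, dy = 2005,
           causes = "10:G30.9")
  ))
  sibship <- genealogy(dplyr::bind_rows(
    person("p1", sex = "male", by = 1900, dy = 1970),
    person("p2", sex = "female", by = 1903, dy = 1975),
    person("s1", "p1", "p2", "male", by = 1930, dy = 2000),
    person("s2", "p1", "p2", "female", by = 1932, dy = 2002),
    person("s3", "p1", "p2", "male", by = 1934, dy = 2004),
    dplyr::bind_rows(lapply(1:7, function(k)
      person(paste0("u", k), sex = "female", by = 1930 + k, dy = 2000 + k)))
  ))
  gp <- dplyr::bind_rows(
    person("gpa", sex = "male", by = 1880, dy = 1950),
    person("gma", sex = "female", by = 1882, dy = 1955))
  sibs <- dplyr::bind_rows(lapply(1:4, function(k)
    person(paste0("a", k), "gpa", "gma",
           sex = if (k %% 2) "male" else "female", by = 1905 + k, dy = 1980 + k)))
  spouses <- dplyr::bind_rows(lapply(1:4, function(k)
    person(paste0("sp", k), sex = if (k %% 2) "female" else "male",
           by = 1905 + k, dy = 1985 + k)))
  kids <- dplyr::bind_rows(lapply(1:4, function(k)
    person(paste0("c", k),
           f = if (k %% 2) paste0("a", k) else paste0("sp", k),
           m = if (k %% 2) paste0("sp", k) else paste0("a", k),
           sex = "female", by = 1935 + k, dy = 2010 + k)))
  cousins <- genealogy(dplyr::bind_rows(gp, sibs, spouses, kids))
  inbred <- genealogy(dplyr::bind_rows(
    person("g1a", sex = "male", by = 1850, dy = 1920),
    person("g1b", sex = "female", by = 1852, dy = 1925),
    person("b1", "g1a", "g1b", "male", by = 1880, dy = 1950),
    person("b2", "g1a", "g1b", "female", by = 1882, dy = 1955),
    person("b1w", sex = "female", by = 1881, dy = 1952),
    person("b2h", sex = "male", by = 1880, dy = 1950),
    person("c1", "b1", "b1w", "male", by = 1910, dy = 1985),
    person("c2", "b2h", "b2", "female", by = 1912, dy = 1990),
    person("d1", "c1", "c2", "male", by = 1940, dy = 2015),   # cousin marriage
    person("d1w", sex = "female", by = 1941, dy = 2016),
    person("e1", "d1", "d1w", "female", by = 1970)
  ))
  list(trio = trio, sibship = sibship, cousins = cousins, inbred_loop = inbred)
}

#' Write the canonical fixture suite to disk
#'
#' Emits the small hand-built pedigrees of [fixture_pedigrees()] plus one
#' medium population (a few thousand individuals) per scenario, each with a
#' JSON truth file recording the generator's bookkeeping.
#'
#' @param out_dir Writable directory (created if needed).
#' @param seed Base seed; scenario populations use `seed`, `seed + 1`,
#'   `seed + 2`.
#' @return Invisibly, the paths written.
#' @export
emit_fixture_suite <- function(out_dir, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  small <- fixture_pedigrees()
  for (nm in names(small)) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    write_genealogy(small[[nm]], p)
    paths <- c(paths, p)
  }
  scens <- c("null", "genetic", "environment")
  for (k in seq_along(scens)) {
    sim <- simulate_genealogy(sim_config(scenario = scens[k]), seed = seed + k - 1)
    p <- file.path(out_dir, paste0("medium_", scens[k], ".tsv"))
    write_genealogy(sim$genealogy, p)
    tp <- file.path(out_dir, paste0("medium_", scens[k], "_truth.json"))
    truth <- sim$truth
    truth$config <- unclass(truth$config)
    jsonlite::write_json(truth, tp, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p, tp)
  }
  invisible(paths)
}
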