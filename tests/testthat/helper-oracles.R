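# Independent oracles, written in plain R against the same definitions but
# none of the package's computational machinery.

# all ancestors of one individual with minimum meiotic depth, by upward BFS
oracle_ancestor_depths <- function(g, id) {
  fa <- stats::setNames(g$father_id, g$id)
  mo <- stats::setNames(g$mother_id, g$id)
  depth <- stats::setNames(0L, id)
  frontier <- id
  d <- 0L
  while (length(frontier) > 0) {
    d <- d + 1L
    up <- unique(stats::na.omit(c(fa[frontier], mo[frontier])))
    frontier <- up[!(up %in% names(depth))]
    if (length(frontier) > 0) {
      depth[frontier] <- d
    }
    # shorter paths always found first in BFS; nothing to update
  }
  depth
}

# minimum meiotic distance by exhaustive scan over all common ancestors
oracle_distance <- function(g, a, b, max_distance = Inf) {
  da <- oracle_ancestor_depths(g, a)
  db <- oracle_ancestor_depths(g, b)
  common <- intersect(names(da), names(db))
  if (length(common) == 0) return(Inf)
  d <- min(da[common] + db[common])
  if (d > max_distance) Inf else unname(d)
}

# textbook recursive kinship with no memoization; exponential, so only for
# small pedigrees
oracle_kinship <- function(g, a, b) {
  fa <- stats::setNames(g$father_id, g$id)
  mo <- stats::setNames(g$mother_id, g$id)
  dep <- function(x) {
    if (is.na(x)) return(-1L)
    1L + max(dep(fa[[x]]), dep(mo[[x]]))
  }
  phi <- function(x, y) {
    if (is.na(x) || is.na(y)) return(0)
    if (x == y) return(0.5 * (1 + phi(fa[[x]], mo[[x]])))
    if (dep(x) < dep(y)) { tmp <- x; x <- y; y <- tmp }
    0.5 * (phi(fa[[x]], y) + phi(mo[[x]], y))
  }
  phi(a, b)
}

# relationship degree (1-3, or NA beyond) from the kinship coefficient;
# valid as an oracle only on pedigrees free of inbreeding and of multiple
# relationships, where phi is an exact power of two
oracle_degree_from_kinship <- function(phi) {
  if (phi >= 0.25 - 1e-12 && phi <= 0.25 + 1e-12) return(1L)
  if (abs(phi - 0.125) < 1e-12) return(2L)
  if (abs(phi - 0.0625) < 1e-12) return(3L)
  NA_integer_
}

# small random pedigree built directly (independent of the package's
# generator, whose analysis-oriented guards reject tiny populations).
# `within` is the chance a spouse comes from the same generation of the
# population — relatives included, so inbreeding loops arise freely; with
# within = 0 all spouses are fresh immigrants and every relationship is
# single-path (no inbreeding, no double relationships).
random_pedigree <- function(seed, n_couples = 2, n_gen = 5, within = 0.8,
                            offspring = 2.2) {
  set.seed(seed)
  sex <- rep(c("male", "female"), n_couples)
  fa <- rep(NA_integer_, 2 * n_couples)
  mo <- rep(NA_integer_, 2 * n_couples)
  gen <- rep(0L, 2 * n_couples)
  couples <- cbind(seq(1, 2 * n_couples, 2), seq(2, 2 * n_couples, 2))
  for (g in seq_len(n_gen - 1)) {
    kids <- stats::rpois(nrow(couples), offspring)
    if (sum(kids) == 0) kids[1] <- 1L   # keep the lineage alive
    f <- rep(couples[, 1], kids)
    m <- rep(couples[, 2], kids)
    ks <- ifelse(stats::runif(length(f)) < 0.5, "male", "female")
    idx <- length(sex) + seq_along(f)
    sex <- c(sex, ks); fa <- c(fa, f); mo <- c(mo, m)
    gen <- c(gen, rep(g, length(f)))
    if (g == n_gen - 1) break
    # unions for the new generation
    mc <- integer(); fc <- integer()
    free <- idx
    for (i in idx) {
      if (!(i %in% free)) next
      free <- setdiff(free, i)
      cand <- free[sex[free] != sex[i]]
      if (length(cand) > 0 && stats::runif(1) < within) {
        j <- cand[sample.int(length(cand), 1)]
        free <- setdiff(free, j)
      } else {
        j <- length(sex) + 1L
        sex <- c(sex, if (sex[i] == "male") "female" else "male")
        fa <- c(fa, NA_integer_); mo <- c(mo, NA_integer_)
        gen <- c(gen, g)
      }
      if (sex[i] == "male") { mc <- c(mc, i); fc <- c(fc, j) }
      else { mc <- c(mc, j); fc <- c(fc, i) }
    }
    couples <- cbind(mc, fc)
    if (nrow(couples) == 0) break
  }
  n <- length(sex)
  id <- sprintf("P%04d", seq_len(n))
  by <- 1850L + 28L * gen + sample.int(5, n, replace = TRUE)
  genealogy(tibble::tibble(
    id = id,
    father_id = ifelse(is.na(fa), NA_character_, id[fa]),
    mother_id = ifelse(is.na(mo), NA_character_, id[mo]),
    sex = sex,
    birth_year = by,
    birthplace = "in_state",
    death_year = by + 65L,
    causes = ""
  ))
}

# simulate + filter + classify, retrying with fresh populations when the
# configuration happens to produce fewer than 2 cases
sim_case_study <- function(cfg, max_tries = 5) {
  for (k in seq_len(max_tries)) {
    sim <- simulate_genealogy(cfg)
    g <- sim$genealogy
    u <- suppressMessages(eligible_decedents(g))
    cs <- classify_cases(g, u)
    if (length(cs) >= 2) {
      return(list(sim = sim, g = g, universe = u, cases = cs))
    }
  }
  stop("no population with >= 2 cases in ", max_tries, " tries")
}
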