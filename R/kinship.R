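# ancestor closure (positions) of a set of ids, self included
ancestor_closure <- function(g, ids) {
  px <- ped_index(g)
  pos <- match(ids, g$id)
  if (anyNA(pos)) {
    rlang::abort(paste0("unknown id(s): ",
                        paste(utils::head(ids[is.na(pos)], 5), collapse = ", ")))
  }
  seen <- logical(nrow(g))
  frontier <- unique(pos)
  while (length(frontier) > 0) {
    seen[frontier] <- TRUE
    up <- unique(c(px$fidx[frontier], px$midx[frontier]))
    up <- up[!is.na(up)]
    frontier <- up[!seen[up]]
  }
  which(seen)
}

# Working context for kinship/distance computations on the sub-pedigree
# spanned by `ids` and their ancestors: local parent indices, the full
# kinship matrix on the subset, and the CSR ancestor-depth table.
ped_context <- function(g, ids, max_distance = 12) {
  keep <- ancestor_closure(g, ids)
  sub_id <- g$id[keep]
  loc <- function(global) match(g$id[global], sub_id)
  px <- ped_index(g)
  fidx <- loc(px$fidx[keep])
  midx <- loc(px$midx[keep])
  gen <- px$gen[keep]
  ord <- order(gen)
  K <- cpp_kinship_matrix(idx0(fidx), idx0(midx), as.integer(ord - 1L))
  anc <- cpp_ancestor_table(idx0(fidx), idx0(midx), idx0(ord),
                            as.integer(max_distance))
  list(id = sub_id, K = K, anc = anc, max_distance = max_distance)
}

ctx_pos <- function(ctx, ids) {
  pos <- match(ids, ctx$id)
  if (anyNA(pos)) rlang::abort("id outside the pedigree context")
  pos
}

# distance-binned kinship sums for one member set, via the context
ctx_kin_by_distance <- function(ctx, ids, min_distance, max_distance) {
  pos <- ctx_pos(ctx, ids)
  bins <- cpp_kin_by_distance(idx0(pos), ctx$K, ctx$anc$ptr, ctx$anc$idx,
                              ctx$anc$depth, as.integer(min_distance),
                              as.integer(max_distance))
  names(bins) <- as.character(seq_len(max_distance))
  bins
}

#' Malecot kinship coefficient
#'
#' The kinship coefficient phi(a, b) is the probability that one allele
#' drawn at random from each of `a` and `b` is identical by descent. It is
#' computed by the standard pedigree recursion in topological order —
#' phi(a, a) = (1 + phi(father(a), mother(a))) / 2, and for distinct
#' individuals phi(a, b) = (phi(father(a), b) + phi(mother(a), b)) / 2 with
#' `a` the individual of greater generation number; absent parents
#' contribute 0 — so inbreeding loops and multiple connecting paths are
#' fully accounted for. Parent and offspring in a non-inbred pedigree have
#' phi = 1/4; first cousins 1/16.
#'
#' @param g A `genealogy`.
#' @param a,b Id vectors, recycled to a common length.
#' @return Numeric vector of kinship coefficients.
#' @seealso [kinship_matrix()] for all pairs at once, [gene_drop_kinship()]
#'   for a Monte-Carlo estimate of the same quantity.
#' @export
kinship <- function(g, a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  ctx <- ped_context(g, unique(c(a, b)), max_distance = 1)
  ctx$K[cbind(ctx_pos(ctx, a), ctx_pos(ctx, b))]
}

#' Kinship matrix for a set of individuals
#'
#' @param g A `genealogy`.
#' @param ids Ids to include (default: everyone).
#' @return Symmetric numeric matrix with `ids` as dimnames; diagonal
#'   entries are self-kinship, (1 + f)/2 for inbreeding coefficient f.
#' @export
kinship_matrix <- function(g, ids = g$id) {
  ids <- as.character(ids)
  ctx <- ped_context(g, ids, max_distance = 1)
  pos <- ctx_pos(ctx, ids)
  K <- ctx$K[pos, pos, drop = FALSE]
  dimnames(K) <- list(ids, ids)
  K
}

#' Minimum meiotic genetic distance between individuals
#'
#' The genetic distance between two individuals is the minimum, over all
#' common ancestors, of the number of meioses from each individual up to
#' that ancestor: 1 for parent/offspring, 2 for siblings or
#' grandparent/grandchild, 3 for avunculars, 4 for first cousins, and so
#' on. Pairs related through several paths are classified by the minimum.
#'
#' @param g A `genealogy`.
#' @param a,b Id vectors, recycled to a common length (`a != b` pairwise).
#' @param max_distance Search horizon in meioses; pairs with no common
#'   ancestor within `max_distance` meioses of either individual are
#'   reported as `Inf` (unrelated).
#' @return Numeric vector of distances (`Inf` for unrelated pairs).
#' @export
genetic_distance <- function(g, a, b, max_distance = 12) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  if (any(a == b)) rlang::abort("genetic distance is defined for distinct individuals")
  ctx <- ped_context(g, unique(c(a, b)), max_distance = max_distance)
  d <- cpp_pair_distances(idx0(ctx_pos(ctx, a)), idx0(ctx_pos(ctx, b)),
                          ctx$anc$ptr, ctx$anc$idx, ctx$anc$depth)
  d <- as.numeric(d)
  d[d < 0] <- Inf
  d[d > max_distance] <- Inf
  d
}

#' Kinship sum over pairs, decomposed by genetic distance
#'
#' Sums the kinship coefficient over all unordered pairs of `ids` whose
#' minimum meiotic distance lies in `[min_distance, max_distance]`, and
#' reports the partial sum per distance class. Each pair is classified at
#' its minimum distance and its full (all-paths) kinship credited to that
#' single class; pairs closer than `min_distance` are dropped entirely,
#' which is the exclusion rule behind the distant-GIF variant.
#'
#' @param g A `genealogy`.
#' @param ids Set of ids (duplicates ignored).
#' @param min_distance Smallest distance class retained (1 keeps all
#'   related pairs; 4 drops every relationship closer than first cousins).
#' @param max_distance Largest distance class considered; more distant
#'   pairs contribute 0.
#' @return List with `total` (numeric) and `by_distance` (named numeric
#'   vector indexed `1..max_distance`).
#' @export
pairwise_kinship_sum <- function(g, ids, min_distance = 1, max_distance = 12) {
  if (min_distance < 1) rlang::abort("min_distance must be >= 1")
  ids <- unique(as.character(ids))
  ctx <- ped_context(g, ids, max_distance = max_distance)
  bins <- ctx_kin_by_distance(ctx, ids, min_distance, max_distance)
  list(total = sum(bins), by_distance = bins)
}

#' Monte-Carlo kinship by gene dropping
#'
#' Estimates pairwise kinship by simulation instead of recursion: two
#' uniquely labelled alleles are assigned to every founder (and to every
#' missing-parent slot), transmitted down the pedigree with independent
#' Mendelian draws in each replicate, and the kinship of a pair is
#' estimated as the average probability that one allele drawn from each is
#' identical by descent. Provided as an independent check of [kinship()].
#'
#' @param g A `genealogy`.
#' @param ids Ids whose pairwise kinship to estimate.
#' @param n_drops Number of gene-dropping replicates.
#' @param chunk Replicates per vectorized batch (memory knob).
#' @return Tibble with columns `a`, `b`, `estimate`, `se`, one row per
#'   unordered pair of `ids`. The standard error is the binomial-model
#'   Monte-Carlo error `sqrt(p(1-p)/n_drops)`, a guaranteed upper bound on
#'   the true error of the four-allele average each replicate contributes.
#' @export
gene_drop_kinship <- function(g, ids, n_drops = 200000, chunk = 20000) {
  ids <- unique(as.character(ids))
  keep <- ancestor_closure(g, ids)
  sub_id <- g$id[keep]
  px <- ped_index(g)
  fidx <- match(g$id[px$fidx[keep]], sub_id)
  midx <- match(g$id[px$midx[keep]], sub_id)
  ord <- order(px$gen[keep])
  n <- length(sub_id)
  pairs <- utils::combn(match(ids, sub_id), 2)
  m <- ncol(pairs)
  sum_s <- numeric(m)
  done <- 0
  while (done < n_drops) {
    nd <- min(chunk, n_drops - done)
    A1 <- matrix(0L, n, nd)
    A2 <- matrix(0L, n, nd)
    lbl <- 0L
    for (i in ord) {
      f <- fidx[i]; m_ <- midx[i]
      if (is.na(f)) {
        lbl <- lbl + 1L
        A1[i, ] <- lbl
      } else {
        pick <- stats::runif(nd) < 0.5
        A1[i, ] <- ifelse(pick, A1[f, ], A2[f, ])
      }
      if (is.na(m_)) {
        lbl <- lbl + 1L
        A2[i, ] <- lbl
      } else {
        pick <- stats::runif(nd) < 0.5
        A2[i, ] <- ifelse(pick, A1[m_, ], A2[m_, ])
      }
    }
    for (k in seq_len(m)) {
      i <- pairs[1, k]; j <- pairs[2, k]
      s <- ((A1[i, ] == A1[j, ]) + (A1[i, ] == A2[j, ]) +
            (A2[i, ] == A1[j, ]) + (A2[i, ] == A2[j, ])) / 4
      sum_s[k] <- sum_s[k] + sum(s)
    }
    done <- done + nd
  }
  est <- sum_s / n_drops
  tibble::tibble(
    a = sub_id[pairs[1, ]],
    b = sub_id[pairs[2, ]],
    estimate = est,
    se = sqrt(est * (1 - est) / n_drops)
  )
}

#' Write the sparse non-zero kinship pair list
#'
#' @param g A `genealogy`.
#' @param path Output path (three-column delimited: `id_a`, `id_b`,
#'   `coefficient`; zero pairs omitted).
#' @param ids Ids to include (default: everyone).
#' @return The table written, invisibly.
#' @export
write_kinship_pairs <- function(g, path, ids = g$id) {
  K <- kinship_matrix(g, ids)
  ut <- which(upper.tri(K) & K > 0, arr.ind = TRUE)
  out <- tibble::tibble(
    id_a = rownames(K)[ut[, 1]],
    id_b = colnames(K)[ut[, 2]],
    coefficient = K[ut]
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
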