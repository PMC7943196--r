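# Clonality tests on binary insertion matrices.
#
# Under strictly clonal descent with unique insertion sites, presence/absence
# patterns across loci are nested: every polymorphic character fits the clone
# genealogy with a single change, so the parsimony consistency index is 1 and
# multilocus associations are strong. Sexual reproduction shuffles variation
# among loci, producing homoplasy (CI < 1) and erasing multilocus linkage
# disequilibrium (index of association near 0).

drop_monomorphic <- function(m) {
  cs <- colSums(m)
  m[, cs > 0 & cs < nrow(m), drop = FALSE]
}

#' Parsimony-informative loci
#'
#' A locus is informative iff both states occur in at least two individuals;
#' singletons and monomorphic loci fit any topology equally well.
#'
#' @param m 0/1 matrix, individuals x loci.
#' @return Integer vector of informative column indices.
#' @export
informative_characters <- function(m) {
  cs <- colSums(m)
  which(cs >= 2 & (nrow(m) - cs) >= 2)
}

#' Fitch parsimony length of a tree
#'
#' Small-parsimony evaluation of a binary character matrix on a fixed
#' topology: state sets are propagated leaf-to-root, counting one step per
#' empty intersection. The basal multifurcation of an unrooted tree is
#' combined child-by-child, which equals rooting the tree along one of its
#' edges; parsimony length does not depend on that choice. Returns per-locus
#' steps or their sum.
#'
#' @param tree Unrooted (or rooted) `phylo` whose tips are the individuals.
#' @param m 0/1 matrix with rownames matching the tip labels.
#' @param per_locus Return the per-locus step vector instead of the total.
#' @return Total steps (default) or integer vector per locus.
#' @export
fitch_length <- function(tree, m, per_locus = FALSE) {
  if (!setequal(tree$tip.label, rownames(m)))
    stop_input("tree tips and matrix rownames must name the same individuals")
  if (ncol(m) == 0) return(if (per_locus) integer(0) else 0L)
  tree <- stats::reorder(tree, "postorder")
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  L <- ncol(m)
  # state sets as bit masks: 1 = state 0, 2 = state 1, 3 = {0,1}
  S <- matrix(0L, nn, L)
  S[seq_len(nt), ] <- m[tree$tip.label, , drop = FALSE] + 1L
  steps <- integer(L)
  e1 <- tree$edge[, 1]; e2 <- tree$edge[, 2]
  for (i in seq_along(e1)) {
    p <- e1[i]; ch <- e2[i]
    if (S[p, 1] == 0L && all(S[p, ] == 0L)) {
      S[p, ] <- S[ch, ]
    } else {
      inter <- bitwAnd(S[p, ], S[ch, ])
      miss <- inter == 0L
      steps[miss] <- steps[miss] + 1L
      inter[miss] <- bitwOr(S[p, miss], S[ch, miss])
      S[p, ] <- inter
    }
  }
  if (per_locus) steps else sum(steps)
}

nni_neighbours <- function(tree) {
  nb <- phangorn::nni(tree)
  if (inherits(nb, "phylo")) list(nb) else nb
}

#' Most-parsimonious tree search
#'
#' Exhaustive search over all unrooted topologies for up to `exhaustive_max`
#' individuals ((2n-5)!! trees); beyond that, hill-climbing by
#' nearest-neighbour interchange from `restarts` random starting topologies
#' (seeded, reported as heuristic).
#'
#' @param m 0/1 matrix, >= 3 individuals, with rownames.
#' @param restarts Random restarts for the heuristic (default 10).
#' @param seed Seed for the heuristic restarts.
#' @param max_trees Cap on the number of co-optimal topologies returned.
#' @param exhaustive_max Largest n for exhaustive search (default 8).
#' @param force_heuristic Use the heuristic even for small n (testing aid).
#' @return List with `trees` (co-optimal `phylo` list, up to `max_trees`),
#'   `mp_length`, `heuristic` flag.
#' @export
max_parsimony <- function(m, restarts = 10, seed = 1, max_trees = 100,
                          exhaustive_max = 8, force_heuristic = FALSE) {
  n <- nrow(m)
  if (n < 3) stop_input("parsimony search needs at least 3 individuals")
  m <- drop_monomorphic(m)
  if (n <= exhaustive_max && !force_heuristic) {
    trees <- phangorn::allTrees(n, rooted = FALSE, tip.label = rownames(m))
    lens <- vapply(trees, fitch_length, numeric(1), m = m)
    best <- min(lens)
    keep <- which(lens == best)
    return(list(trees = trees[keep[seq_len(min(length(keep), max_trees))]],
                mp_length = best, heuristic = FALSE))
  }
  seeds <- derive_seeds(seed, restarts)
  best_len <- Inf; best_trees <- list()
  for (r in seq_len(restarts)) {
    tree <- withr::with_seed(seeds[r],
      ape::unroot(ape::rtree(n, tip.label = sample(rownames(m)))))
    len <- fitch_length(tree, m)
    repeat {
      nb <- nni_neighbours(tree)
      nb_len <- vapply(nb, fitch_length, numeric(1), m = m)
      if (min(nb_len) >= len) break
      i <- which.min(nb_len)
      tree <- nb[[i]]; len <- nb_len[i]
    }
    if (len < best_len) {
      best_len <- len; best_trees <- list(tree)
    } else if (len == best_len && length(best_trees) < max_trees) {
      best_trees <- c(best_trees, list(tree))
    }
  }
  list(trees = best_trees, mp_length = best_len, heuristic = TRUE)
}

#' Ensemble consistency index
#'
#' CI = (sum of per-character minimum steps) / (most-parsimonious tree
#' length); for binary characters the minimum is one step per polymorphic
#' locus. CI = 1 means perfect nesting with no homoplasy, as expected under
#' strictly clonal inheritance of uniquely arising insertions.
#'
#' With `method = "auto"`, pairwise four-gamete compatibility of all loci is
#' checked first: for binary characters pairwise compatibility guarantees a
#' perfect phylogeny, so CI = 1 exactly without a tree search.
#' `method = "search"` always runs [max_parsimony()].
#'
#' @param m 0/1 matrix with >= 1 polymorphic locus.
#' @param method "auto" (compatibility shortcut) or "search".
#' @param ... Passed to [max_parsimony()].
#' @return List with `ci`, `mp_length`, `min_length` (number of polymorphic
#'   loci), `heuristic`.
#' @export
consistency_index <- function(m, method = c("auto", "search"), ...) {
  method <- match.arg(method)
  poly <- drop_monomorphic(m)
  k <- ncol(poly)
  if (k == 0) stop_input("consistency index undefined: all loci monomorphic")
  if (method == "auto" && compatibility(m)$compatible)
    return(list(ci = 1, mp_length = k, min_length = k, heuristic = FALSE))
  mp <- max_parsimony(m, ...)
  list(ci = k / mp$mp_length, mp_length = mp$mp_length, min_length = k,
       heuristic = mp$heuristic)
}

#' Character compatibility and laminar (nesting) structure
#'
#' Two binary loci are incompatible (unrooted four-gamete test) iff all four
#' joint patterns 00/01/10/11 occur among the individuals. The matrix is
#' laminar iff the carrier sets of all loci are pairwise nested or disjoint
#' -- the pattern produced by unique gains on a clonal genealogy with no
#' losses.
#'
#' @param m 0/1 matrix.
#' @return List with `compatible` (no incompatible pair), `laminar`,
#'   `incompatible_pairs` (two-column matrix of locus indices),
#'   `fraction_incompatible` (of polymorphic-locus pairs).
#' @export
compatibility <- function(m) {
  poly_idx <- which(colSums(m) > 0 & colSums(m) < nrow(m))
  k <- length(poly_idx)
  inc <- matrix(integer(), 0, 2)
  lam <- TRUE
  if (k >= 2) {
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      x <- m[, poly_idx[a]]; y <- m[, poly_idx[b]]
      if (length(unique(paste0(x, y))) == 4)
        inc <- rbind(inc, c(poly_idx[a], poly_idx[b]))
      # carrier sets properly overlap: neither nested nor disjoint
      both <- sum(x == 1 & y == 1)
      if (both > 0 && both != sum(x) && both != sum(y)) lam <- FALSE
    }
  }
  n_pairs <- if (k >= 2) choose(k, 2) else 0
  list(compatible = nrow(inc) == 0, laminar = lam,
       incompatible_pairs = inc,
       fraction_incompatible = if (n_pairs > 0) nrow(inc) / n_pairs else 0)
}

# Core r_bar_d / I_A computation from per-locus pairwise distance columns.
# dmat: n_pairs x L matrix of |x_a - x_b| per pair and locus.
ia_from_dmat <- function(dmat) {
  D <- rowSums(dmat)
  pvar <- function(v) mean(v^2) - mean(v)^2   # population variance over pairs
  V_O <- pvar(D)
  vj <- apply(dmat, 2, pvar)
  V_E <- sum(vj)
  sq <- sqrt(vj)
  denom <- sum(sq)^2 - sum(vj)   # = 2 * sum_{j<k} sqrt(vj vk)
  c(I_A = V_O / V_E - 1, r_bar_d = (V_O - V_E) / denom, V_O = V_O, V_E = V_E)
}

pair_dist_matrix <- function(m) {
  apply(m, 2, function(x) as.vector(stats::dist(x, method = "manhattan")))
}

# Exact permutation null: shuffling a column uniformly over the n! row
# orders is uniform over the same-weight 0/1 patterns (each pattern has the
# same multiplicity), and the statistic is invariant to a common row
# permutation, so enumeration over per-column distinct patterns is exact.
ia_exhaustive_p <- function(m, observed) {
  n <- nrow(m)
  pats <- lapply(seq_len(ncol(m)), function(j) {
    k <- sum(m[, j])
    combos <- utils::combn(n, k)
    lapply(seq_len(ncol(combos)), function(i) {
      v <- integer(n); v[combos[, i]] <- 1L; v
    })
  })
  grid <- expand.grid(lapply(pats, seq_along))
  stats_all <- vapply(seq_len(nrow(grid)), function(r) {
    cols <- vapply(seq_len(ncol(m)),
                   function(j) pats[[j]][[grid[r, j]]], integer(n))
    ia_from_dmat(pair_dist_matrix(cols))["r_bar_d"]
  }, numeric(1))
  mean(stats_all >= observed - 1e-12)
}

#' Standardized index of association with permutation test
#'
#' Computes the index of association I_A = V_O / V_E - 1 and its
#' loci-count-corrected form r_bar_d, where V_O is the variance over
#' individual pairs of the multilocus distance and V_E the sum of per-locus
#' distance variances. Significant positive values indicate multilocus
#' linkage disequilibrium, as expected under clonal inheritance. The null
#' shuffles each locus column independently among individuals (the fully
#' recombining expectation); the p-value is (1 + #permuted >= observed) /
#' (n_perm + 1). `perm_method = "exhaustive"` enumerates the exact null via
#' weight-preserving column patterns (feasible for small matrices only).
#'
#' @param m 0/1 matrix with >= 3 individuals and >= 2 polymorphic loci
#'   (monomorphic loci are excluded).
#' @param n_perm Permutation count (default 999); 0 skips the test.
#' @param seed Seed for the permutations.
#' @param perm_method "sample" (Monte Carlo) or "exhaustive".
#' @return List with `I_A`, `r_bar_d`, `p_value` (NA when `n_perm = 0`),
#'   `V_O`, `V_E`, `n_loci`.
#' @export
index_of_association <- function(m, n_perm = 999, seed = 1,
                                 perm_method = c("sample", "exhaustive")) {
  perm_method <- match.arg(perm_method)
  if (nrow(m) < 3) stop_input("need at least 3 individuals")
  m <- drop_monomorphic(m)
  if (ncol(m) < 2) stop_input("need at least 2 polymorphic loci")
  dmat <- pair_dist_matrix(m)
  vj <- apply(dmat, 2, function(v) mean(v^2) - mean(v)^2)
  if (any(vj == 0))
    stop_input("a polymorphic locus has zero pairwise-distance variance")
  obs <- ia_from_dmat(dmat)
  p <- NA_real_
  if (perm_method == "exhaustive") {
    p <- ia_exhaustive_p(m, obs["r_bar_d"])
  } else if (n_perm > 0) {
    n <- nrow(m)
    perm_stats <- withr::with_seed(as.integer(seed), {
      vapply(seq_len(n_perm), function(i) {
        pm <- apply(m, 2, function(col) col[sample.int(n)])
        ia_from_dmat(pair_dist_matrix(pm))["r_bar_d"]
      }, numeric(1))
    })
    p <- (1 + sum(perm_stats >= obs["r_bar_d"] - 1e-12)) / (n_perm + 1)
  }
  list(I_A = unname(obs["I_A"]), r_bar_d = unname(obs["r_bar_d"]),
       p_value = p, V_O = unname(obs["V_O"]), V_E = unname(obs["V_E"]),
       n_loci = ncol(m))
}

#' Full clonality report for a binary matrix
#'
#' Bundles the parsimony statistics (CI, most-parsimonious length,
#' informative-locus count), compatibility/laminarity, and the index of
#' association with its permutation p-value.
#'
#' @param m 0/1 matrix, individuals x loci.
#' @param n_perm Permutations for the index of association.
#' @param seed Seed.
#' @param ... Passed to [max_parsimony()] via [consistency_index()].
#' @return List of class `clonality_stats`.
#' @export
clonality_stats <- function(m, n_perm = 999, seed = 1, ...) {
  ci <- consistency_index(m, ...)
  comp <- compatibility(m)
  ia <- tryCatch(index_of_association(m, n_perm = n_perm, seed = seed),
                 error = function(e) list(I_A = NA_real_,
                                          r_bar_d = NA_real_,
                                          p_value = NA_real_,
                                          V_O = NA_real_, V_E = NA_real_,
                                          n_loci = NA_integer_))
  structure(list(
    ci = ci$ci, mp_length = ci$mp_length, heuristic = ci$heuristic,
    n_informative = length(informative_characters(m)),
    compatible = comp$compatible, laminar = comp$laminar,
    fraction_incompatible = comp$fraction_incompatible,
    I_A = ia$I_A, r_bar_d = ia$r_bar_d, p_value = ia$p_value,
    V_O = ia$V_O, V_E = ia$V_E), class = "clonality_stats")
}

#' Write a clonality report as JSON
#' @param stats A `clonality_stats` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clonality_json <- function(stats, path) {
  jsonlite::write_json(unclass(stats), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
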