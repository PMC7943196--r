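# Shared fixture builders: a reference genome with planted elements, a
# nested (clonal) truth matrix, derived individuals and reads. Everything is
# generated in code at test time; sizes are kept small so whole-pipeline
# tests stay fast.

make_fixture <- function(n_ind = 5, n_elem = 5, scaffold_len = 20000,
                         ltr_len = 100, internal_len = 300, gc = 0.4,
                         seed = 11) {
  spacing <- floor(scaffold_len / (n_elem + 1))
  stopifnot(spacing > ltr_len + 200)
  ref <- make_genome(1, scaffold_len, gc = gc, seed = seed)
  specs <- lapply(seq_len(n_elem), function(i)
    list(scaffold = "scf1", position = spacing * i, ltr_len = ltr_len,
         internal_len = internal_len, strand = if (i %% 2) "+" else "-",
         seed = seed + 100 + i, id = sprintf("e%02d", i)))
  pl <- plant_ltr_elements(ref, specs)
  truth <- nested_truth_matrix(paste0("s", seq_len(n_ind)), pl$elements$id)
  pop <- derive_population(pl$genome, pl$elements, truth)
  list(reference = pl$genome, elements = pl$elements, truth = truth,
       population = pop, specs = specs, ltr_len = ltr_len,
       internal_len = internal_len)
}

# Score a whole fixture population and return the presence matrix.
score_fixture <- function(fx, coverage = 20, error_rate = 0, seed = 3) {
  pairs <- extract_tag_pairs(fx$elements, fx$reference)
  coll <- collapse_tags(pairs)
  scored <- lapply(names(fx$population), function(s) {
    reads <- simulate_reads(fx$population[[s]], coverage, 100,
                            error_rate, seed = seed + match(s, names(fx$population)))
    score_sample(coll$pairs, reads = reads)
  })
  names(scored) <- names(fx$population)
  build_presence_matrix(scored)
}

# Brute-force minimum changes of one binary column on a fixed topology:
# enumerate all internal-node state assignments and count changed edges.
# Independent of the package Fitch implementation.
brute_force_steps <- function(tree, column) {
  tree <- ape::reorder.phylo(tree, "postorder")
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  internal <- (nt + 1):nn
  best <- Inf
  combos <- expand.grid(rep(list(c(0L, 1L)), length(internal)))
  tipstate <- column[tree$tip.label]
  for (r in seq_len(nrow(combos))) {
    st <- integer(nn)
    st[seq_len(nt)] <- tipstate
    st[internal] <- unlist(combos[r, ])
    changes <- sum(st[tree$edge[, 1]] != st[tree$edge[, 2]])
    best <- min(best, changes)
  }
  best
}

brute_force_length <- function(tree, m) {
  sum(vapply(seq_len(ncol(m)), function(j)
    brute_force_steps(tree, stats::setNames(m[, j], rownames(m))),
    numeric(1)))
}

# Naive r_bar_d / I_A via explicit loops over pairs and loci; the oracle for
# the vectorized implementation.
naive_ia <- function(m) {
  n <- nrow(m); L <- ncol(m)
  pairs <- utils::combn(n, 2)
  np <- ncol(pairs)
  d <- matrix(0, np, L)
  for (p in seq_len(np)) for (j in seq_len(L))
    d[p, j] <- abs(m[pairs[1, p], j] - m[pairs[2, p], j])
  D <- rowSums(d)
  pvar <- function(v) mean((v - mean(v))^2)
  V_O <- pvar(D)
  vj <- apply(d, 2, pvar)
  V_E <- sum(vj)
  denom <- 0
  for (j in seq_len(L - 1)) for (k in (j + 1):L)
    denom <- denom + sqrt(vj[j] * vj[k])
  c(I_A = V_O / V_E - 1, r_bar_d = (V_O - V_E) / (2 * denom))
}

random_binary_matrix <- function(n, L, p = 0.5, seed = 1,
                                 require_polymorphic = TRUE) {
  withr::with_seed(seed, {
    repeat {
      m <- matrix(rbinom(n * L, 1, p), n, L,
                  dimnames = list(paste0("i", seq_len(n)),
                                  paste0("l", seq_len(L))))
      cs <- colSums(m)
      if (!require_polymorphic || all(cs > 0 & cs < n)) return(m)
    }
  })
}
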