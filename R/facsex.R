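# Facultative-sex Wright-Fisher simulator and rejection ABC.
#
# The simulator produces binary insertion matrices under a forward-time
# Wright-Fisher model with facultative sex: each offspring clones one
# uniformly chosen parent with probability 1 - sigma, or with probability
# sigma draws two parents and inherits each locus independently from either
# (free recombination among dispersed TE loci). New insertions arise
# Poisson(theta) per genome per generation at globally unique sites
# (infinite sites); each carried copy is excised with probability mu per
# generation. The frequency of sex sigma is then estimated from observed
# clonality statistics by rejection ABC against simulated reference tables.

#' Simulator parameters
#'
#' @param N Population size (constant).
#' @param sigma Per-reproduction probability of sex in [0, 1].
#' @param theta Expected new insertions per genome per generation.
#' @param mu Per-copy per-generation excision probability.
#' @param sample_n Individuals sampled at the end.
#' @param n_loci Target number of polymorphic loci in the sample.
#' @param generations Run length after burn-in (default 10 * N).
#' @param burn_in Burn-in generations (default 10 * N).
#' @param seed Integer seed.
#' @return List of class `sim_params`.
#' @export
sim_params <- function(N = 50, sigma = 0, theta = 0.1, mu = 0.01,
                       sample_n = 10, n_loci = 20, generations = NULL,
                       burn_in = NULL, seed = 1) {
  if (sigma < 0 || sigma > 1) stop_input("sigma must lie in [0, 1]")
  if (theta < 0) stop_input("theta must be >= 0")
  if (mu < 0 || mu > 1) stop_input("mu must lie in [0, 1]")
  if (sample_n > N) stop_input("sample_n cannot exceed N")
  structure(list(N = N, sigma = sigma, theta = theta, mu = mu,
                 sample_n = sample_n, n_loci = n_loci,
                 generations = generations %||% (10 * N),
                 burn_in = burn_in %||% (10 * N),
                 seed = seed), class = "sim_params")
}

facsex_forward <- function(N, sigma, theta, mu, gens) {
  G <- matrix(FALSE, N, 0)
  prune <- function(G) {
    cs <- colSums(G)
    # fixed columns can only re-polymorphize through loss; with mu = 0 they
    # are permanently monomorphic and safe to drop
    keep <- cs > 0 & !(mu == 0 & cs == N)
    G[, keep, drop = FALSE]
  }
  for (g in seq_len(gens)) {
    L <- ncol(G)
    p1 <- sample.int(N, N, replace = TRUE)
    off <- G[p1, , drop = FALSE]
    sex <- stats::runif(N) < sigma
    ns <- sum(sex)
    if (ns > 0 && L > 0) {
      p2 <- sample.int(N, ns, replace = TRUE)
      A <- G[p1[sex], , drop = FALSE]
      B <- G[p2, , drop = FALSE]
      pick <- matrix(stats::runif(ns * L) < 0.5, ns, L)
      off[sex, ] <- (A & pick) | (B & !pick)
    }
    if (mu > 0 && L > 0)
      off <- off & (matrix(stats::runif(N * L), N, L) >= mu)
    k <- stats::rpois(N, theta)
    K <- sum(k)
    if (K > 0) {
      newc <- matrix(FALSE, N, K)
      newc[cbind(rep.int(seq_len(N), k), seq_len(K))] <- TRUE
      off <- cbind(off, newc)
    }
    G <- if (g %% 10 == 0) prune(off) else off
  }
  prune(G)
}

#' Simulate a binary insertion matrix under facultative sex
#'
#' Runs the forward model for `burn_in + generations` generations, samples
#' `sample_n` individuals without replacement, drops loci monomorphic in the
#' sample, and subsamples columns uniformly down to `n_loci`. If fewer than
#' `n_loci` polymorphic loci are available, the simulation is rerun with a
#' fresh seed, up to 100 attempts.
#'
#' @param params A `sim_params` list.
#' @return 0/1 matrix `sample_n` x `n_loci` with rownames `ind1..` and
#'   column names `locus1..`.
#' @export
simulate_facsex <- function(params) {
  p <- params
  seeds <- derive_seeds(p$seed, 100)
  for (attempt in seq_len(100)) {
    m <- withr::with_seed(seeds[attempt], {
      G <- facsex_forward(p$N, p$sigma, p$theta, p$mu,
                          p$burn_in + p$generations)
      take <- sample.int(p$N, p$sample_n)
      S <- G[take, , drop = FALSE]
      cs <- colSums(S)
      S <- S[, cs > 0 & cs < p$sample_n, drop = FALSE]
      if (ncol(S) >= p$n_loci)
        S[, sort(sample.int(ncol(S), p$n_loci)), drop = FALSE]
      else NULL
    })
    if (!is.null(m)) {
      m <- m + 0L
      dimnames(m) <- list(paste0("ind", seq_len(nrow(m))),
                          paste0("locus", seq_len(ncol(m))))
      return(m)
    }
  }
  stop_input("could not obtain ", p$n_loci, " polymorphic loci in 100 ",
             "attempts; increase theta or the run length")
}

#' Summary-statistic vector for ABC
#'
#' The vector is (ci, r_bar_d), computed by the clonality module; entries are
#' NA when a statistic is undefined (such simulations are discarded and
#' redrawn by [build_reference_table()]).
#'
#' @param m 0/1 matrix.
#' @param restarts,seed Passed to the parsimony search behind the CI.
#' @return Named numeric vector `c(ci, r_bar_d)`.
#' @export
summarize_matrix <- function(m, restarts = 10, seed = 1) {
  ci <- tryCatch(
    consistency_index(m, restarts = restarts, seed = seed)$ci,
    error = function(e) NA_real_)
  rbd <- tryCatch(
    index_of_association(m, n_perm = 0)$r_bar_d,
    error = function(e) NA_real_)
  c(ci = ci, r_bar_d = rbd)
}

#' ABC configuration
#'
#' @param n_sims Number of simulated datasets (default 50000; scale down for
#'   desk-size runs).
#' @param tolerance Euclidean acceptance distance on the summary statistics
#'   (default 0.05).
#' @param sigma_range Prior bounds for sigma (default 1e-7 to 1,
#'   log10-uniform).
#' @param grid Use a log10 grid over `sigma_range` instead of the continuous
#'   prior (NULL, or the number of grid points).
#' @param normalize Divide each statistic by its median absolute deviation
#'   across the table before computing distances (default FALSE: raw
#'   statistics).
#' @param seed Integer seed.
#' @return List of class `abc_config`.
#' @export
abc_config <- function(n_sims = 50000, tolerance = 0.05,
                       sigma_range = c(1e-7, 1), grid = NULL,
                       normalize = FALSE, seed = 1) {
  if (tolerance <= 0) stop_input("tolerance must be positive")
  if (n_sims < 1) stop_input("n_sims must be >= 1")
  structure(list(n_sims = n_sims, tolerance = tolerance,
                 sigma_range = sigma_range, grid = grid,
                 normalize = normalize, seed = seed), class = "abc_config")
}

# Draws from the sigma prior: log10-uniform over cfg$sigma_range, or uniform
# over a log10 grid when cfg$grid is set. Uses the current RNG stream.
sample_sigma_prior <- function(cfg, n) {
  lo <- log10(cfg$sigma_range[1]); hi <- log10(cfg$sigma_range[2])
  if (!is.null(cfg$grid)) {
    g <- 10^seq(lo, hi, length.out = cfg$grid)
    sample(g, n, replace = TRUE)
  } else {
    10^stats::runif(n, lo, hi)
  }
}

#' Build the ABC reference table
#'
#' Draws sigma from the log10-uniform prior (or grid), simulates one dataset
#' per draw with the observed matrix shape, and records the summary
#' statistics. Simulations with undefined statistics are redrawn.
#'
#' @param obs_shape Integer vector `c(sample_n, n_loci)` of the observed
#'   binarized matrix.
#' @param sim_template A `sim_params` list supplying N, theta, mu and run
#'   lengths; sigma, shape and seeds are overridden per draw.
#' @param cfg An `abc_config`.
#' @return Data.frame with columns `sigma`, `ci`, `r_bar_d`.
#' @export
build_reference_table <- function(obs_shape, sim_template, cfg) {
  n <- cfg$n_sims
  seeds <- derive_seeds(cfg$seed, 3)
  sigmas <- withr::with_seed(seeds[1], sample_sigma_prior(cfg, n))
  sim_seeds <- derive_seeds(seeds[2], n)
  redraw_seeds <- derive_seeds(seeds[3], n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sg <- sigmas[i]; sd_i <- sim_seeds[i]
    for (try in seq_len(50)) {
      p <- sim_params(N = sim_template$N, sigma = sg,
                      theta = sim_template$theta, mu = sim_template$mu,
                      sample_n = obs_shape[1], n_loci = obs_shape[2],
                      generations = sim_template$generations,
                      burn_in = sim_template$burn_in, seed = sd_i)
      st <- summarize_matrix(simulate_facsex(p))
      if (!anyNA(st)) break
      sd_i <- (sd_i + try * redraw_seeds[i]) %% .Machine$integer.max + 1
    }
    rows[[i]] <- data.frame(sigma = sg, ci = st["ci"],
                            r_bar_d = st["r_bar_d"])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rejection ABC on a reference table
#'
#' Accepts rows whose summary statistics lie within `cfg$tolerance`
#' (Euclidean distance) of the observed vector; optionally each statistic is
#' scaled by its median absolute deviation across the table first.
#'
#' @param observed Named numeric vector `c(ci, r_bar_d)` from the observed
#'   matrix.
#' @param table Reference table from [build_reference_table()].
#' @param cfg An `abc_config`.
#' @return List of class `abc_result`: `accepted` (data.frame of accepted
#'   rows with distances), `acceptance_rate`, `posterior_summary`
#'   (sigma quantiles at 2.5/25/50/75/97.5%), `min_distance`.
#' @export
abc_rejection <- function(observed, table, cfg = abc_config()) {
  if (nrow(table) == 0) stop_input("reference table is empty")
  if (anyNA(observed)) stop_input("observed statistics must be finite")
  stat_cols <- c("ci", "r_bar_d")
  sims <- as.matrix(table[, stat_cols])
  obs <- as.numeric(observed[stat_cols])
  if (isTRUE(cfg$normalize)) {
    scale <- apply(sims, 2, stats::mad)
    scale[scale == 0] <- 1
    sims <- sweep(sims, 2, scale, "/")
    obs <- obs / scale
  }
  d <- sqrt(rowSums(sweep(sims, 2, obs)^2))
  acc <- which(d <= cfg$tolerance)
  if (length(acc) == 0)
    warning("no simulations accepted; minimum distance ",
            format(min(d), digits = 4), call. = FALSE)
  accepted <- cbind(table[acc, , drop = FALSE], distance = d[acc])
  qs <- if (length(acc)) stats::quantile(accepted$sigma,
                                         c(0.025, 0.25, 0.5, 0.75, 0.975))
        else stats::setNames(rep(NA_real_, 5),
                             c("2.5%", "25%", "50%", "75%", "97.5%"))
  structure(list(accepted = accepted,
                 acceptance_rate = length(acc) / nrow(table),
                 posterior_summary = qs,
                 min_distance = min(d)), class = "abc_result")
}

#' Write an ABC posterior sample and summary
#'
#' @param result An `abc_result`.
#' @param prefix Output path prefix; `<prefix>.posterior.tsv` and
#'   `<prefix>.summary.json` are written.
#' @return The two paths, invisibly.
#' @export
write_abc_result <- function(result, prefix) {
  p1 <- paste0(prefix, ".posterior.tsv")
  p2 <- paste0(prefix, ".summary.json")
  utils::write.table(result$accepted, p1, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(acceptance_rate = result$acceptance_rate,
         posterior_summary = as.list(result$posterior_summary),
         min_distance = result$min_distance),
    p2, auto_unbox = TRUE, digits = NA)
  invisible(c(p1, p2))
}
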