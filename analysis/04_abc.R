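#!/usr/bin/env Rscript
# Stage 4: rejection-ABC estimate of the frequency of sex.
#
# Simulates binary insertion matrices under the facultative-sex
# Wright-Fisher model across a log10-uniform prior on sigma (1e-7 .. 1),
# then accepts parameter draws whose (ci, r_bar_d) lie within Euclidean
# distance 0.05 of the observed statistics. 1,000 simulations keep this
# driver quick; raise n_sims for production-grade posteriors.

suppressPackageStartupMessages(library(ltrclone))

m <- read_truth_tsv("results/pipeline/binary_matrix.tsv")
obs <- summarize_matrix(m, seed = 2024)
cat(sprintf("Observed statistics: ci = %.3f, r_bar_d = %.3f\n",
            obs["ci"], obs["r_bar_d"]))

tmpl <- sim_params(N = 50, theta = 0.1, mu = 0.01)
cfg <- abc_config(n_sims = 1000, tolerance = 0.05, seed = 2024)
tab <- build_reference_table(dim(m), tmpl, cfg)
utils::write.table(tab, "results/abc_reference.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

res <- abc_rejection(obs, tab, cfg)
write_abc_result(res, "results/abc")

cat(sprintf("Accepted %d of %d simulations (rate %.3f).\n",
            nrow(res$accepted), cfg$n_sims, res$acceptance_rate))
cat("Posterior quantiles of sigma:\n")
print(signif(res$posterior_summary, 3))
if (any(res$accepted$sigma < 1e-3))
  cat("Sigma values below 1e-3 are accepted:",
      "strictly clonal evolution is not rejected.\n")
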