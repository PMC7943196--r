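#!/usr/bin/env Rscript
# Stage 1: build the synthetic study population.
#
# One reference genome gets 8 planted full-length LTR elements; five
# individuals descend clonally from it, so their carrier sets are nested and
# each individual genome lacks the elements its truth row codes 0. 20x
# error-bearing reads are simulated per individual. Everything lands under
# results/data/ for the later stages.

suppressPackageStartupMessages(library(ltrclone))

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 2024

ref <- make_genome(1, 30000, gc = 0.35, seed = seed)
specs <- lapply(1:8, function(i)
  list(scaffold = "scf1", position = 3300 * i, ltr_len = 120,
       internal_len = 400, strand = if (i %% 2) "+" else "-",
       seed = seed + i, id = sprintf("ltr%02d", i)))
planted <- plant_ltr_elements(ref, specs)
truth <- nested_truth_matrix(paste0("ind", 1:5), planted$elements$id)
pop <- derive_population(planted$genome, planted$elements, truth)

write_genome_fasta(planted$genome, file.path(out, "reference.fasta"))
write_elements_gff3(planted$elements, file.path(out, "elements.gff3"))
write_truth_tsv(truth, file.path(out, "truth_matrix.tsv"))
# repeat-homology support for every planted element (the detector's
# cross-evidence, which the filter stage requires)
writeLines(sprintf("%s\t%d\t%d", planted$elements$scaffold,
                   planted$elements$start, planted$elements$end),
           file.path(out, "repeat_support.bed"))

for (ind in names(pop)) {
  reads <- simulate_reads(pop[[ind]], coverage = 20, read_len = 100,
                          error_rate = 0.005,
                          seed = seed + 50 + match(ind, names(pop)))
  write_reads_fastq(reads, file.path(out, paste0(ind, ".fastq.gz")))
}

cat("Planted", nrow(planted$elements), "elements on a",
    sum(Biostrings::width(planted$genome)), "bp reference;",
    nrow(truth), "individuals with nested carrier sets;",
    "reads at 20x, 0.5% substitution error.\n")
cat("Truth matrix:\n")
print(truth)
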