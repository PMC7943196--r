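# Pipeline orchestration: config validation, stage sequencing, manifest.

#' Assemble a pipeline configuration
#'
#' Defaults are the pipeline's standard constants: 150 bp N-scan window,
#' 50 bp tag flank, 0.1 collapse divergence, 0.5 minimum alignment identity,
#' 0.875 presence threshold, 999 permutations.
#'
#' @param genome_fasta Reference genome FASTA.
#' @param elements_gff3 Full-length element annotation GFF3.
#' @param reads Named character vector or list: sample name -> FASTQ path
#'   (plain or gzipped), or -> SAM/BAM path when `reads_are_alignments`.
#' @param genes_path Optional gene annotation (GFF3/BED).
#' @param repeat_support_path Optional repeat-homology support intervals
#'   (GFF3/BED or RepeatMasker `.out`).
#' @param out_dir Output directory (created if needed).
#' @param flank_window,collapse_threshold,min_identity,binarize_threshold
#'   Stage parameters (see module docs).
#' @param permutations Permutations for the index of association.
#' @param abc NULL to skip ABC, or a list with `n_sims`, `tolerance`, and
#'   simulator fields `N`, `theta`, `mu`.
#' @param reads_are_alignments Treat `reads` entries as SAM/BAM against the
#'   tag FASTA.
#' @param seed Global seed; all stage randomness derives from it.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(genome_fasta, elements_gff3, reads,
                            genes_path = NULL, repeat_support_path = NULL,
                            out_dir = "ltrclone_out",
                            flank_window = 150, collapse_threshold = 0.1,
                            min_identity = 0.5, binarize_threshold = 0.875,
                            permutations = 999, abc = NULL,
                            reads_are_alignments = FALSE, seed = 1) {
  structure(list(genome_fasta = genome_fasta, elements_gff3 = elements_gff3,
                 reads = reads, genes_path = genes_path,
                 repeat_support_path = repeat_support_path,
                 out_dir = out_dir, flank_window = flank_window,
                 collapse_threshold = collapse_threshold,
                 min_identity = min_identity,
                 binarize_threshold = binarize_threshold,
                 permutations = permutations, abc = abc,
                 reads_are_alignments = reads_are_alignments, seed = seed),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' The YAML keys mirror the arguments of [pipeline_config()]; `reads` is a
#' mapping of sample name to file path.
#'
#' @param path YAML path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

sniff_format <- function(path) {
  if (grepl("\\.(fa|fasta|fna)(\\.gz)?$", path, ignore.case = TRUE))
    return("fasta")
  if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
    return("fastq")
  if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE)) return("gff3")
  if (grepl("\\.bed$", path, ignore.case = TRUE)) return("bed")
  if (grepl("\\.(sam|bam)$", path, ignore.case = TRUE)) return("sam")
  if (grepl("\\.out$", path, ignore.case = TRUE)) return("rmout")
  "unknown"
}

#' Validate pipeline inputs
#'
#' Checks that all referenced files exist, that formats look plausible, that
#' parameters lie in their documented ranges, and that annotation scaffold
#' names are consistent with the genome FASTA. All problems are collected
#' and reported together.
#'
#' @param cfg A `pipeline_config`.
#' @param error Throw on problems (default TRUE); otherwise return them.
#' @return Invisibly, a character vector of problems (empty when valid).
#' @export
validate_inputs <- function(cfg, error = TRUE) {
  problems <- character()
  need <- c(genome_fasta = cfg$genome_fasta, elements_gff3 = cfg$elements_gff3,
            unlist(cfg$reads))
  for (nm in names(need))
    if (!file.exists(need[[nm]]))
      problems <- c(problems, paste0("missing file (", nm, "): ", need[[nm]]))
  for (opt in c("genes_path", "repeat_support_path"))
    if (!is.null(cfg[[opt]]) && !file.exists(cfg[[opt]]))
      problems <- c(problems, paste0("missing file (", opt, "): ", cfg[[opt]]))
  if (cfg$binarize_threshold < 0 || cfg$binarize_threshold > 1)
    problems <- c(problems, "binarize_threshold outside [0, 1]")
  if (cfg$min_identity < 0 || cfg$min_identity > 1)
    problems <- c(problems, "min_identity outside [0, 1]")
  if (cfg$collapse_threshold < 0 || cfg$collapse_threshold > 1)
    problems <- c(problems, "collapse_threshold outside [0, 1]")

  if (file.exists(cfg$genome_fasta) && file.exists(cfg$elements_gff3)) {
    genome <- Biostrings::readDNAStringSet(cfg$genome_fasta)
    names(genome) <- sub("\\s.*", "", names(genome))
    ann <- tryCatch(load_elements(cfg$elements_gff3),
                    error = function(e) NULL)
    if (is.null(ann)) {
      problems <- c(problems, paste0("unparsable GFF3: ", cfg$elements_gff3))
    } else if (nrow(ann)) {
      bad <- setdiff(unique(ann$scaffold), names(genome))
      if (length(bad))
        problems <- c(problems, paste0(
          "annotation scaffold(s) absent from genome FASTA: ",
          paste(bad, collapse = ", ")))
    }
  }
  for (rp in unlist(cfg$reads)) {
    if (file.exists(rp)) {
      fmt <- sniff_format(rp)
      want <- if (isTRUE(cfg$reads_are_alignments)) "sam" else "fastq"
      if (fmt != want)
        problems <- c(problems,
                      paste0("read file does not look like ", want, ": ", rp))
    }
  }
  if (error && length(problems))
    stop_input("input validation failed:\n  ",
               paste(problems, collapse = "\n  "))
  invisible(problems)
}

#' Run the full presence/absence and clonality pipeline
#'
#' Stages: load genome and element annotation; filter candidates; extract
#' and collapse tag pairs; score every sample; assemble and binarize the
#' presence matrix; compute clonality statistics; optionally run ABC. All
#' outputs plus a JSON manifest (parameters, seed, versions) are written
#' under `cfg$out_dir`; a rerun with the same config reproduces identical
#' matrices.
#'
#' @param cfg A `pipeline_config`.
#' @return List with `elements`, `reports`, `pairs` (collapsed),
#'   `membership`, `presence` (a `presence_matrix`), `binary`, `clonality`,
#'   and `abc` (NULL unless configured).
#' @export
run_pipeline <- function(cfg) {
  validate_inputs(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  genome <- Biostrings::readDNAStringSet(cfg$genome_fasta)
  names(genome) <- sub("\\s.*", "", names(genome))
  elements <- load_elements(cfg$elements_gff3, genome)
  genes <- if (!is.null(cfg$genes_path)) load_intervals(cfg$genes_path, "gene")
  support <- if (!is.null(cfg$repeat_support_path)) {
    if (sniff_format(cfg$repeat_support_path) == "rmout")
      read_repeatmasker_out(cfg$repeat_support_path)
    else load_intervals(cfg$repeat_support_path)
  }
  reports <- filter_candidates(elements, genes, support, genome,
                               flank_window = cfg$flank_window)
  utils::write.table(reports, file.path(cfg$out_dir, "filter_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  pairs <- extract_tag_pairs(elements, genome, reports)
  if (is.null(pairs) || nrow(pairs) == 0)
    stop_input("tag stage: no elements survived filtering")
  coll <- collapse_tags(pairs, threshold = cfg$collapse_threshold)
  write_tags_fasta(coll$pairs, file.path(cfg$out_dir, "tags.fasta"))
  utils::write.table(coll$membership,
                     file.path(cfg$out_dir, "tag_clusters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  scored <- lapply(names(cfg$reads), function(s) {
    path <- cfg$reads[[s]]
    if (isTRUE(cfg$reads_are_alignments))
      score_sample(coll$pairs, sam = path, min_identity = cfg$min_identity)
    else
      score_sample(coll$pairs, reads = read_reads_fastq(path),
                   min_identity = cfg$min_identity)
  })
  names(scored) <- names(cfg$reads)
  pm <- build_presence_matrix(scored)
  write_presence_tsv(pm, file.path(cfg$out_dir, "scores"))
  binary <- binarize_matrix(pm, cfg$binarize_threshold)
  write_truth_tsv(binary, file.path(cfg$out_dir, "binary_matrix.tsv"))
  write_binary_nexus(binary, file.path(cfg$out_dir, "binary_matrix.nex"))

  seeds <- derive_seeds(cfg$seed, 2)
  clon <- clonality_stats(binary, n_perm = cfg$permutations, seed = seeds[1])
  write_clonality_json(clon, file.path(cfg$out_dir, "clonality.json"))

  abc_res <- NULL
  if (!is.null(cfg$abc)) {
    a <- cfg$abc
    acfg <- abc_config(n_sims = a$n_sims %||% 2000,
                       tolerance = a$tolerance %||% 0.05,
                       seed = seeds[2])
    tmpl <- sim_params(N = a$N %||% 50, theta = a$theta %||% 0.1,
                       mu = a$mu %||% 0.01)
    tab <- build_reference_table(dim(binary), tmpl, acfg)
    utils::write.table(tab, file.path(cfg$out_dir, "abc_reference.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    obs <- summarize_matrix(binary)
    abc_res <- abc_rejection(obs, tab, acfg)
    write_abc_result(abc_res, file.path(cfg$out_dir, "abc"))
  }

  manifest <- list(
    package = "ltrclone",
    version = as.character(utils::packageVersion("ltrclone")),
    r_version = R.version.string,
    seed = cfg$seed,
    parameters = cfg[c("flank_window", "collapse_threshold", "min_identity",
                       "binarize_threshold", "permutations")],
    inputs = list(genome = cfg$genome_fasta, elements = cfg$elements_gff3,
                  reads = as.list(cfg$reads)),
    n_elements = nrow(elements), n_retained = sum(reports$retained),
    n_tags = nrow(coll$pairs), samples = names(cfg$reads))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  list(elements = elements, reports = reports, pairs = coll$pairs,
       membership = coll$membership, presence = pm, binary = binary,
       clonality = clon, abc = abc_res)
}
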