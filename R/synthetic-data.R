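# Synthetic genomes, planted LTR elements, derived individuals and reads.
#
# Every downstream stage of the pipeline (tag extraction, scoring, clonality
# testing) can be exercised against ground truth generated here, with no
# external sequencing data. Coordinates are 0-based half-open internally;
# GFF3 output is converted to 1-based inclusive at the boundary.

DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

#' Simulate a genome of random scaffolds
#'
#' Bases are drawn i.i.d. at the requested GC content. The result is a
#' [Biostrings::DNAStringSet] with unique scaffold names `scf1`, `scf2`, ...
#'
#' @param n_scaffolds Number of scaffolds.
#' @param lengths Integer vector of scaffold lengths (bases), length
#'   `n_scaffolds`.
#' @param gc GC fraction in (0, 1).
#' @param seed Integer seed; the same seed always yields the same genome.
#' @return A `DNAStringSet` of scaffolds.
#' @export
make_genome <- function(n_scaffolds, lengths, gc = 0.5, seed = 1) {
  if (!is_count(n_scaffolds) || n_scaffolds < 1)
    stop_input("n_scaffolds must be a positive integer")
  if (length(lengths) != n_scaffolds)
    stop_input("lengths must have one entry per scaffold")
  if (any(!is.finite(lengths)) || any(lengths < 1))
    stop_input("scaffold lengths must be positive")
  if (!is.numeric(gc) || gc <= 0 || gc >= 1)
    stop_input("gc must lie strictly between 0 and 1")
  seqs <- withr::with_seed(as.integer(seed), {
    vapply(lengths, random_dna, character(1), gc = gc)
  })
  names(seqs) <- paste0("scf", seq_len(n_scaffolds))
  Biostrings::DNAStringSet(seqs)
}

#' Plant a full-length LTR retrotransposon into a genome
#'
#' Inserts an element consisting of a 5' LTR, an internal region, and a 3'
#' LTR identical to the 5' copy (as for a newly transposed element) at the
#' given 0-based position. No target-site duplication is modelled, so the
#' flank/element junction arithmetic is exact. Coordinates of any
#' pre-existing features downstream of the insertion point must be shifted
#' by the caller.
#'
#' @param genome A `DNAStringSet`.
#' @param spec List with fields `scaffold`, `position` (0-based insertion
#'   point), `ltr_len` (>= 1), `internal_len` (>= 0), `strand` ("+" or "-"),
#'   `seed`, and optionally `id`.
#' @return List with `genome` (modified `DNAStringSet`) and `element` (a
#'   one-row data.frame in the element-table layout: `id`, `scaffold`,
#'   `start`, `end`, `ltr5_start`, `ltr5_end`, `ltr3_start`, `ltr3_end`,
#'   `strand`, all coordinates 0-based half-open on the modified genome).
#' @export
plant_ltr_element <- function(genome, spec) {
  stopifnot(is(genome, "DNAStringSet"))
  req <- c("scaffold", "position", "ltr_len", "internal_len", "strand", "seed")
  if (!all(req %in% names(spec)))
    stop_input("plant spec missing fields: ",
               paste(setdiff(req, names(spec)), collapse = ", "))
  if (!spec$scaffold %in% names(genome))
    stop_input("scaffold '", spec$scaffold, "' not in genome")
  if (spec$ltr_len < 1) stop_input("ltr_len must be >= 1")
  if (spec$internal_len < 0) stop_input("internal_len must be >= 0")
  if (!spec$strand %in% c("+", "-")) stop_input("strand must be '+' or '-'")
  scaf <- as.character(genome[[spec$scaffold]])
  slen <- nchar(scaf)
  pos <- spec$position
  if (!is_count(pos) || pos < 0 || pos > slen)
    stop_input("position ", pos, " out of range for scaffold of length ", slen)

  parts <- withr::with_seed(as.integer(spec$seed), {
    list(ltr = random_dna(spec$ltr_len),
         internal = if (spec$internal_len > 0) random_dna(spec$internal_len) else "")
  })
  elem_seq <- paste0(parts$ltr, parts$internal, parts$ltr)
  span <- nchar(elem_seq)
  new_scaf <- paste0(substr(scaf, 1, pos), elem_seq,
                     substr(scaf, pos + 1, slen))
  genome[[spec$scaffold]] <- Biostrings::DNAString(new_scaf)

  id <- spec$id %||% sprintf("ltr_%s_%d", spec$scaffold, pos)
  element <- data.frame(
    id = id, scaffold = spec$scaffold,
    start = pos, end = pos + span,
    ltr5_start = pos, ltr5_end = pos + spec$ltr_len,
    ltr3_start = pos + span - spec$ltr_len, ltr3_end = pos + span,
    strand = spec$strand, stringsAsFactors = FALSE)
  list(genome = genome, element = element)
}

#' Plant several non-overlapping elements at once
#'
#' Positions in `specs` refer to the original genome; elements are planted
#' right-to-left so earlier insertions do not shift later positions, and the
#' returned element table carries coordinates on the final genome.
#'
#' @param genome A `DNAStringSet`.
#' @param specs List of plant specs (see [plant_ltr_element()]).
#' @return List with `genome` and `elements` (data.frame, one row per
#'   element, ordered as `specs`).
#' @export
plant_ltr_elements <- function(genome, specs) {
  ord <- order(vapply(specs, function(s) s$position, numeric(1)),
               decreasing = TRUE)
  rows <- vector("list", length(specs))
  for (i in ord) {
    res <- plant_ltr_element(genome, specs[[i]])
    genome <- res$genome
    rows[[i]] <- res$element
  }
  elements <- do.call(rbind, rows)
  # shift each element by the spans of elements planted to its left
  spans <- elements$end - elements$start
  pos0 <- vapply(specs, function(s) s$position, numeric(1))
  for (i in seq_along(specs)) {
    shift <- sum(spans[pos0 < pos0[i]])
    elements$start[i] <- elements$start[i] + shift
    elements$end[i] <- elements$end[i] + shift
    elements$ltr5_start[i] <- elements$ltr5_start[i] + shift
    elements$ltr5_end[i] <- elements$ltr5_end[i] + shift
    elements$ltr3_start[i] <- elements$ltr3_start[i] + shift
    elements$ltr3_end[i] <- elements$ltr3_end[i] + shift
  }
  rownames(elements) <- NULL
  list(genome = genome, elements = elements)
}

#' Derive individual genomes from a reference and a truth matrix
#'
#' For each individual (row of `truth`), elements with a 0 cell are excised
#' cleanly: the flanking sequences are joined with no scar, emulating the
#' pre-insertion (empty) allele. Individuals with an all-ones row equal the
#' reference.
#'
#' @param reference Reference `DNAStringSet` carrying all elements.
#' @param elements Element table as returned by [plant_ltr_elements()].
#' @param truth 0/1 matrix, individuals x elements; dimnames required and
#'   column names must match `elements$id`.
#' @return Named list of `DNAStringSet`, one per individual.
#' @export
derive_population <- function(reference, elements, truth) {
  if (is.null(rownames(truth)) || is.null(colnames(truth)))
    stop_input("truth matrix needs row (individual) and column (element) names")
  if (!setequal(colnames(truth), elements$id))
    stop_input("truth columns must correspond to element ids")
  # refuse overlapping elements: clean excision is undefined there
  for (sc in unique(elements$scaffold)) {
    e <- elements[elements$scaffold == sc, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    if (nrow(e) > 1 && any(e$start[-1] < e$end[-nrow(e)]))
      stop_input("overlapping elements on scaffold '", sc,
                 "' are not supported")
  }
  elements <- elements[match(colnames(truth), elements$id), , drop = FALSE]
  out <- lapply(rownames(truth), function(ind) {
    absent <- elements[truth[ind, ] == 0, , drop = FALSE]
    g <- as.character(reference)
    if (nrow(absent)) {
      absent <- absent[order(absent$start, decreasing = TRUE), , drop = FALSE]
      for (i in seq_len(nrow(absent))) {
        sc <- absent$scaffold[i]
        g[[sc]] <- paste0(substr(g[[sc]], 1, absent$start[i]),
                          substr(g[[sc]], absent$end[i] + 1, nchar(g[[sc]])))
      }
    }
    Biostrings::DNAStringSet(g)
  })
  names(out) <- rownames(truth)
  out
}

#' Build a nested (strictly clonal) truth matrix
#'
#' Carrier sets form a chain: individual i carries the first
#' `n_elements - (i - 1) * step` elements, the pattern expected when unique
#' insertions accumulate along a clonal line of descent.
#'
#' @param individuals Character vector of individual names.
#' @param element_ids Character vector of element ids.
#' @return 0/1 matrix individuals x elements with nested carrier sets.
#' @export
nested_truth_matrix <- function(individuals, element_ids) {
  n <- length(individuals); L <- length(element_ids)
  m <- matrix(0L, n, L, dimnames = list(individuals, element_ids))
  # individual i carries a prefix of the elements, longest first
  cuts <- round(seq(L, 0, length.out = n))
  for (i in seq_len(n)) if (cuts[i] > 0) m[i, seq_len(cuts[i])] <- 1L
  m
}

#' Simulate single-end reads with substitution errors
#'
#' Read starts are uniform over valid positions (scaffolds weighted by the
#' number of valid starts); each read is taken from either strand with equal
#' probability; substitution errors are i.i.d. per base. Read count is
#' `round(coverage * genome_span / read_len)`.
#'
#' @param genome A `DNAStringSet`.
#' @param coverage Fold coverage (> 0).
#' @param read_len Read length (<= shortest scaffold).
#' @param error_rate Per-base substitution probability in [0, 0.25).
#' @param seed Integer seed.
#' @return A `DNAStringSet` of reads named `read1`, `read2`, ...; the
#'   sampling metadata (scaffold, 0-based start, strand) is attached as
#'   `S4Vectors::mcols`.
#' @export
simulate_reads <- function(genome, coverage, read_len = 100, error_rate = 0,
                           seed = 1) {
  stopifnot(is(genome, "DNAStringSet"))
  if (!is.numeric(coverage) || coverage <= 0)
    stop_input("coverage must be positive")
  slens <- Biostrings::width(genome)
  if (read_len > min(slens))
    stop_input("read_len exceeds the shortest scaffold")
  if (error_rate < 0 || error_rate >= 0.25)
    stop_input("error_rate must lie in [0, 0.25)")
  span <- sum(slens)
  n_reads <- round(coverage * span / read_len)
  starts_per <- slens - read_len + 1L

  withr::with_seed(as.integer(seed), {
    scaf_idx <- sample.int(length(genome), n_reads, replace = TRUE,
                           prob = starts_per)
    start0 <- floor(stats::runif(n_reads) * starts_per[scaf_idx])  # 0-based
    seqs <- character(n_reads)
    chars <- as.character(genome)
    for (s in seq_along(genome)) {
      sel <- which(scaf_idx == s)
      if (length(sel))
        seqs[sel] <- substring(chars[[s]], start0[sel] + 1,
                               start0[sel] + read_len)
    }
    if (error_rate > 0) {
      mat <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                    nrow = read_len)
      hit <- which(matrix(stats::runif(length(mat)) < error_rate,
                          nrow = read_len))
      if (length(hit)) {
        # substitute with one of the three other bases, uniformly
        old <- mat[hit]
        pick <- function(b) sample(setdiff(DNA_BASES, b), 1L)
        mat[hit] <- vapply(old, pick, character(1))
        seqs <- apply(mat, 2, paste, collapse = "")
      }
    }
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    rc <- strand == "-"
    if (any(rc)) seqs[rc] <- revcomp(seqs[rc])
    reads <- Biostrings::DNAStringSet(seqs)
    names(reads) <- paste0("read", seq_len(n_reads))
    S4Vectors::mcols(reads) <- S4Vectors::DataFrame(
      scaffold = names(genome)[scaf_idx], start = as.integer(start0),
      strand = strand)
    reads
  })
}

#' Write reads as FASTQ with fixed base quality
#'
#' Base qualities carry no information in this pipeline (scoring uses
#' alignment matches only), so all bases get quality 'I' (Phred 40).
#' Gzip output is selected by a `.gz` suffix.
#'
#' @param reads `DNAStringSet` of reads.
#' @param path Output path (`.fastq` or `.fastq.gz`).
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  quals <- Biostrings::BStringSet(strrep("I", Biostrings::width(reads)))
  S4Vectors::mcols(reads) <- NULL  # sampling metadata has no FASTQ field
  x <- Biostrings::QualityScaledDNAStringSet(
    reads, Biostrings::PhredQuality(quals))
  Biostrings::writeQualityScaledXStringSet(
    x, path, compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read FASTQ (optionally gzipped) as a DNAStringSet
#' @param path FASTQ path.
#' @return `DNAStringSet`.
#' @export
read_reads_fastq <- function(path) {
  Biostrings::readDNAStringSet(path, format = "fastq")
}

#' Write genome FASTA
#' @param genome `DNAStringSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Write a truth (or any binary) matrix as TSV
#'
#' Header row gives element ids; first column holds individual names.
#' @param m 0/1 matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(m, path) {
  df <- data.frame(individual = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a binary matrix written by [write_truth_tsv()]
#' @param path TSV path.
#' @return Integer 0/1 matrix with dimnames.
#' @export
read_truth_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  m
}
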