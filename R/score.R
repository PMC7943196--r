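# Presence/absence scoring and the sample x tag matrix.
#
# Each insertion i is scored in each sample as
#   S_i = ((M_Li - X_Li) + (M_Ri - X_Ri)) / 200,
# from the best read per tag side; a perfect alignment over both 100 bp tags
# scores 200 raw, 1 after normalisation. A sample carrying only the empty
# site matches just the 50 genomic bases of each tag, giving S close to 0.5,
# which the strict binarization threshold (S > 0.875) codes as absent.

#' Combine per-side best-read stats into a presence score
#'
#' Applies the score formula, flooring negative raw values at zero so the
#' score stays in [0, 1] (more than half mismatches would otherwise go
#' negative). Coverage is the total read count over both sides.
#'
#' @param left,right Lists with `M`, `X`, `n_reads` (see
#'   [best_read_stats()]).
#' @return List with `S` (in [0, 1]), `raw` (un-normalised, not floored),
#'   `coverage`.
#' @export
presence_score <- function(left, right) {
  raw <- (left$M - left$X) + (right$M - right$X)
  list(S = max(0, raw) / 200, raw = raw,
       coverage = left$n_reads + right$n_reads)
}

#' Score every collapsed tag pair in one sample
#'
#' Aligns the sample's reads to all left and right tags (built-in aligner)
#' or consumes an external SAM/BAM produced against the tag FASTA, then
#' takes best-read stats per side and combines them.
#'
#' @param pairs Condensed tag-pair data.frame.
#' @param reads `DNAStringSet` of the sample's reads (ignored when `sam` is
#'   given).
#' @param min_identity Minimum alignment identity (default 0.5).
#' @param sam Optional SAM/BAM path of reads aligned to the tag FASTA whose
#'   reference names follow `elementID|side|scaffold|boundary`.
#' @param prefilter Passed to [align_reads_to_tags()].
#' @return Data.frame with `tag` (element id), `S`, `coverage`.
#' @export
score_sample <- function(pairs, reads = NULL, min_identity = 0.5, sam = NULL,
                         prefilter = TRUE) {
  tag_names <- c(sprintf("%s|left|%s|%d", pairs$element_id, pairs$scaffold,
                         pairs$left_boundary),
                 sprintf("%s|right|%s|%d", pairs$element_id, pairs$scaffold,
                         pairs$right_boundary))
  if (is.null(sam)) {
    if (is.null(reads)) stop_input("either reads or sam must be supplied")
    tags <- stats::setNames(c(pairs$left, pairs$right), tag_names)
    recs <- align_reads_to_tags(tags, reads, min_identity = min_identity,
                                prefilter = prefilter)
  } else {
    recs <- read_sam_stats(sam, min_identity = min_identity)
  }
  by_tag <- split(recs, recs$tag)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    l <- best_read_stats(by_tag[[tag_names[i]]])
    r <- best_read_stats(by_tag[[tag_names[nrow(pairs) + i]]])
    sc <- presence_score(l, r)
    data.frame(tag = pairs$element_id[i], S = sc$S, coverage = sc$coverage,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Assemble the samples x tags presence matrix
#'
#' @param scored Named list (one entry per sample) of [score_sample()]
#'   outputs; every sample must cover every tag.
#' @return A `presence_matrix`: list with numeric matrix `S` and integer
#'   matrix `coverage`, both samples x tags.
#' @export
build_presence_matrix <- function(scored) {
  samples <- names(scored)
  if (is.null(samples)) stop_input("scored list must be named by sample")
  tags <- scored[[1]]$tag
  S <- matrix(NA_real_, length(samples), length(tags),
              dimnames = list(samples, tags))
  cov <- matrix(NA_integer_, length(samples), length(tags),
                dimnames = list(samples, tags))
  for (s in samples) {
    sc <- scored[[s]]
    idx <- match(tags, sc$tag)
    if (anyNA(idx))
      stop_input("sample '", s, "' is missing scores for tag(s): ",
                 paste(tags[is.na(idx)], collapse = ", "))
    S[s, ] <- sc$S[idx]
    cov[s, ] <- sc$coverage[idx]
  }
  if (anyNA(S)) stop_input("presence matrix has unpopulated cells")
  structure(list(S = S, coverage = cov), class = "presence_matrix")
}

#' Binarize a presence matrix
#'
#' Scores strictly above `threshold` are coded present (1), all others
#' absent (0). The default 0.875 requires that no more than half of the
#' genome context or LTR region is missing from both tags combined.
#'
#' @param pm A `presence_matrix` or a plain numeric score matrix.
#' @param threshold Presence threshold in [0, 1]; strict `>`.
#' @return Integer 0/1 matrix with the same dimnames.
#' @export
binarize_matrix <- function(pm, threshold = 0.875) {
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1)
    stop_input("threshold must lie in [0, 1]")
  S <- if (inherits(pm, "presence_matrix")) pm$S else pm
  out <- (S > threshold) + 0L
  storage.mode(out) <- "integer"
  out
}

#' Write a presence matrix as TSV (long and wide form)
#'
#' The long form has columns `sample`, `tag`, `S`, `coverage`; the wide form
#' is the score matrix with samples as rows.
#'
#' @param pm A `presence_matrix`.
#' @param path Base output path; `<path>.long.tsv` and `<path>.wide.tsv` are
#'   written.
#' @return Character vector of the two paths, invisibly.
#' @export
write_presence_tsv <- function(pm, path) {
  long <- data.frame(
    sample = rep(rownames(pm$S), ncol(pm$S)),
    tag = rep(colnames(pm$S), each = nrow(pm$S)),
    S = sprintf("%.6f", as.vector(pm$S)),
    coverage = as.vector(pm$coverage))
  p1 <- paste0(path, ".long.tsv"); p2 <- paste0(path, ".wide.tsv")
  utils::write.table(long, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  wide <- data.frame(sample = rownames(pm$S),
                     matrix(sprintf("%.6f", pm$S), nrow(pm$S),
                            dimnames = list(NULL, colnames(pm$S))),
                     check.names = FALSE)
  utils::write.table(wide, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2))
}

#' Read a long-form presence TSV back into a `presence_matrix`
#' @param path Path to a `.long.tsv` written by [write_presence_tsv()].
#' @return A `presence_matrix`.
#' @export
read_presence_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  samples <- unique(df$sample); tags <- unique(df$tag)
  S <- matrix(NA_real_, length(samples), length(tags),
              dimnames = list(samples, tags))
  cov <- S
  S[cbind(match(df$sample, samples), match(df$tag, tags))] <- df$S
  cov[cbind(match(df$sample, samples), match(df$tag, tags))] <- df$coverage
  storage.mode(cov) <- "integer"
  structure(list(S = S, coverage = cov), class = "presence_matrix")
}

#' Export a binary matrix as NEXUS (standard datatype)
#'
#' Suitable for external parsimony programs.
#'
#' @param m 0/1 matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_binary_nexus <- function(m, path) {
  rows <- split(as.character(m), row(m))
  dat <- lapply(rows, function(r) r)
  names(dat) <- rownames(m)
  ape::write.nexus.data(dat, path, format = "standard", interleaved = FALSE)
  invisible(path)
}
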