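# Candidate element filtering and the LTR-tag library.
#
# A full-length element is usable as a presence/absence marker only if its
# insertion boundaries are trustworthy: LTRs that overlap predicted genes,
# assembly gaps ('N') near the insertion site, or candidates without
# independent repeat-homology support are removed. Each retained element
# yields a pair of 100 bp boundary tags (50 bp genomic flank + 50 bp element
# terminus on each side), which uniquely mark one insertion event.

TAG_FLANK <- 50L   # bases of genomic context on each side of a boundary
TAG_LEN <- 100L    # total tag length

#' Write an element table as GFF3
#'
#' Each element becomes an `LTR_retrotransposon` feature with two
#' `long_terminal_repeat` children linked by `Parent`. Internal 0-based
#' half-open coordinates are converted to GFF3 1-based inclusive.
#'
#' @param elements Element table (see [plant_ltr_element()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_elements_gff3 <- function(elements, path) {
  line <- function(scaf, type, s0, e0, strand, attrs) {
    paste(scaf, "ltrclone", type, s0 + 1, e0, ".", strand, ".", attrs,
          sep = "\t")
  }
  out <- c("##gff-version 3")
  for (i in seq_len(nrow(elements))) {
    e <- elements[i, ]
    out <- c(out,
      line(e$scaffold, "LTR_retrotransposon", e$start, e$end, e$strand,
           sprintf("ID=%s", e$id)),
      line(e$scaffold, "long_terminal_repeat", e$ltr5_start, e$ltr5_end,
           e$strand, sprintf("ID=%s_ltr5;Parent=%s", e$id, e$id)),
      line(e$scaffold, "long_terminal_repeat", e$ltr3_start, e$ltr3_end,
           e$strand, sprintf("ID=%s_ltr3;Parent=%s", e$id, e$id)))
  }
  writeLines(out, path)
  invisible(path)
}

#' Load full-length LTR elements from GFF3
#'
#' Expects element features (`LTR_retrotransposon` or `repeat_region`) with
#' two `long_terminal_repeat` sub-features referencing the element via
#' `Parent`. Elements lacking both LTR sub-features are skipped with a
#' warning; GFF3 1-based inclusive coordinates become internal 0-based
#' half-open.
#'
#' @param path GFF3 path.
#' @param genome Optional `DNAStringSet`; when given, coordinates are checked
#'   against scaffold bounds.
#' @return Element table data.frame.
#' @export
load_elements <- function(path, genome = NULL) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop_input("malformed GFF3 '", path,
                                                "': ", conditionMessage(e)))
  type <- as.character(gr$type)
  is_elem <- type %in% c("LTR_retrotransposon", "repeat_region")
  is_ltr <- type == "long_terminal_repeat"
  parents <- vapply(gr$Parent, function(p)
    if (length(p)) as.character(p)[1] else NA_character_, character(1))
  rows <- list()
  for (i in which(is_elem)) {
    id <- gr$ID[i]
    kids <- which(is_ltr & parents == id)
    if (length(kids) < 2) {
      warning("element '", id, "' lacks two LTR sub-features; skipped",
              call. = FALSE)
      next
    }
    kids <- kids[order(GenomicRanges::start(gr)[kids])][c(1, length(kids))]
    scaf <- as.character(GenomicRanges::seqnames(gr))[i]
    if (!is.null(genome)) {
      if (!scaf %in% names(genome))
        stop_input("GFF3 scaffold '", scaf, "' not present in genome")
      if (GenomicRanges::end(gr)[i] >
            Biostrings::width(genome)[match(scaf, names(genome))])
        stop_input("element '", id, "' extends past scaffold '", scaf, "'")
    }
    strand <- as.character(GenomicRanges::strand(gr))[i]
    rows[[length(rows) + 1L]] <- data.frame(
      id = id, scaffold = scaf,
      start = GenomicRanges::start(gr)[i] - 1L,
      end = GenomicRanges::end(gr)[i],
      ltr5_start = GenomicRanges::start(gr)[kids[1]] - 1L,
      ltr5_end = GenomicRanges::end(gr)[kids[1]],
      ltr3_start = GenomicRanges::start(gr)[kids[2]] - 1L,
      ltr3_end = GenomicRanges::end(gr)[kids[2]],
      strand = if (strand %in% c("+", "-")) strand else "+",
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows) %||% data.frame()
}

#' Load feature intervals from GFF3 or BED
#'
#' Used for gene annotations and repeat-homology support intervals. BED is
#' already 0-based half-open; GFF3 is converted.
#'
#' @param path GFF3 or BED path (sniffed by extension).
#' @param feature_type Optional GFF3 `type` filter (e.g. "gene").
#' @return Data.frame with `scaffold`, `start`, `end` (0-based half-open).
#' @export
load_intervals <- function(path, feature_type = NULL) {
  fmt <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  gr <- rtracklayer::import(path, format = fmt)
  if (!is.null(feature_type) && fmt == "gff3")
    gr <- gr[as.character(gr$type) %in% feature_type]
  data.frame(scaffold = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Read RepeatMasker .out as intervals
#'
#' Parses the whitespace-delimited RepeatMasker table (three header lines,
#' then one row per hit; columns 5-7 are query, begin, end in 1-based
#' inclusive coordinates).
#'
#' @param path `.out` path.
#' @return Data.frame with `scaffold`, `start`, `end` (0-based half-open).
#' @export
read_repeatmasker_out <- function(path) {
  tab <- utils::read.table(path, skip = 3, header = FALSE, fill = TRUE,
                           stringsAsFactors = FALSE)
  data.frame(scaffold = as.character(tab[[5]]),
             start = as.integer(tab[[6]]) - 1L,
             end = as.integer(tab[[7]]),
             stringsAsFactors = FALSE)
}

intervals_to_granges <- function(df) {
  GenomicRanges::GRanges(df$scaffold,
                         IRanges::IRanges(df$start + 1L, df$end))
}

#' Filter candidate elements for tag extraction
#'
#' Applies the false-positive filters: (1) `gene_overlap` — a predicted gene
#' overlaps the 5' or 3' LTR itself by at least one base; (2) `n_in_flank` —
#' an 'N' base within `flank_window` bases upstream or downstream of the
#' element span (a mark of possible local mis-assembly); (3)
#' `no_repeat_support` — no overlap of at least one base between the element
#' span and any repeat-homology support interval. Elements with less than 50
#' bases of scaffold on either side get `insufficient_flank` (a tag cannot be
#' extracted). Reports are returned for every element; nothing throws for
#' per-element conditions.
#'
#' @param elements Element table.
#' @param genes Gene intervals (data.frame scaffold/start/end, 0-based
#'   half-open), or NULL for none.
#' @param repeat_support Support intervals, same layout; NULL disables the
#'   support filter.
#' @param genome `DNAStringSet` (used for the N scan and flank check).
#' @param flank_window Bases scanned for 'N' on each side of the span.
#' @return Data.frame with `element_id`, `retained`, `reasons`
#'   (comma-separated; empty iff retained).
#' @export
filter_candidates <- function(elements, genes, repeat_support, genome,
                              flank_window = 150) {
  n <- nrow(elements)
  gene_gr <- if (!is.null(genes) && nrow(genes)) intervals_to_granges(genes)
  sup_gr <- if (!is.null(repeat_support) && nrow(repeat_support))
    intervals_to_granges(repeat_support)
  ltr_gr <- GenomicRanges::GRanges(
    rep(elements$scaffold, 2),
    IRanges::IRanges(c(elements$ltr5_start, elements$ltr3_start) + 1L,
                     c(elements$ltr5_end, elements$ltr3_end)))
  span_gr <- GenomicRanges::GRanges(
    elements$scaffold, IRanges::IRanges(elements$start + 1L, elements$end))

  gene_hit <- rep(FALSE, n)
  if (!is.null(gene_gr)) {
    ov <- GenomicRanges::countOverlaps(ltr_gr, gene_gr) > 0
    gene_hit <- ov[seq_len(n)] | ov[n + seq_len(n)]
  }
  sup_hit <- rep(TRUE, n)
  if (!is.null(sup_gr))
    sup_hit <- GenomicRanges::countOverlaps(span_gr, sup_gr) > 0

  chars <- as.character(genome)
  reports <- lapply(seq_len(n), function(i) {
    e <- elements[i, ]
    slen <- nchar(chars[[e$scaffold]])
    reasons <- character()
    if (gene_hit[i]) reasons <- c(reasons, "gene_overlap")
    up <- substr(chars[[e$scaffold]], max(1, e$start - flank_window + 1),
                 e$start)
    down <- substr(chars[[e$scaffold]], e$end + 1,
                   min(slen, e$end + flank_window))
    if (grepl("N", up, fixed = TRUE) || grepl("N", down, fixed = TRUE))
      reasons <- c(reasons, "n_in_flank")
    if (!sup_hit[i]) reasons <- c(reasons, "no_repeat_support")
    if (e$start < TAG_FLANK || e$end + TAG_FLANK > slen)
      reasons <- c(reasons, "insufficient_flank")
    data.frame(element_id = e$id, retained = length(reasons) == 0L,
               reasons = paste(reasons, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, reports)
}

#' Extract the 100 bp boundary tag pair for one element
#'
#' The left tag spans the upstream insertion boundary (50 bases of genomic
#' flank followed by the first 50 bases of the element); the right tag spans
#' the downstream boundary (last 50 element bases followed by 50 genomic
#' bases). For minus-strand elements both tags are reverse-complemented and
#' swapped, so "left" always crosses the element-5' junction in element
#' orientation.
#'
#' @param element One-row element table.
#' @param genome `DNAStringSet`.
#' @return List with `element_id`, `left`, `right` (100-base strings),
#'   `scaffold`, `left_boundary`, `right_boundary` (the genome coordinates
#'   crossed, 0-based).
#' @export
extract_tag_pair <- function(element, genome) {
  e <- as.list(element)
  scaf <- as.character(genome[[e$scaffold]])
  slen <- nchar(scaf)
  if (e$start < TAG_FLANK || e$end + TAG_FLANK > slen)
    stop_input("element '", e$id, "': insufficient flank for tag extraction")
  left <- substr(scaf, e$start - TAG_FLANK + 1, e$start + TAG_FLANK)
  right <- substr(scaf, e$end - TAG_FLANK + 1, e$end + TAG_FLANK)
  if (grepl("N", left, fixed = TRUE) || grepl("N", right, fixed = TRUE))
    stop_input("element '", e$id, "': N base inside tag region")
  if (identical(e$strand, "-")) {
    tmp <- revcomp(right); right <- revcomp(left); left <- tmp
  }
  list(element_id = e$id, left = left, right = right, scaffold = e$scaffold,
       left_boundary = e$start, right_boundary = e$end)
}

#' Extract tag pairs for all retained elements
#'
#' @param elements Element table.
#' @param genome `DNAStringSet`.
#' @param reports Optional filter report from [filter_candidates()]; when
#'   given, only retained elements are processed.
#' @return Data.frame with one row per element: `element_id`, `left`,
#'   `right`, `scaffold`, `left_boundary`, `right_boundary`.
#' @export
extract_tag_pairs <- function(elements, genome, reports = NULL) {
  if (!is.null(reports))
    elements <- elements[elements$id %in%
                           reports$element_id[reports$retained], ,
                         drop = FALSE]
  rows <- lapply(seq_len(nrow(elements)), function(i)
    as.data.frame(extract_tag_pair(elements[i, ], genome),
                  stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Pairwise divergence between tag pairs
#'
#' Uncorrected p-distance over the concatenated left+right sequences
#' (ungapped, end-to-end, 200 positions).
#'
#' @param pairs Tag-pair data.frame.
#' @return A `dist` object over `pairs$element_id`.
#' @export
tag_divergence <- function(pairs) {
  seqs <- paste0(pairs$left, pairs$right)
  lens <- unique(nchar(seqs))
  if (length(lens) != 1)
    stop_input("tags of unequal length cannot be compared ungapped")
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(pairs$element_id, pairs$element_id))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- mean(mat[i, ] != mat[j, ])
  }
  stats::as.dist(d)
}

#' Collapse orthologous tag pairs by sequence divergence
#'
#' Tag pairs found from searches started in different reference genomes can
#' mark the same insertion; pairs within `threshold` divergence are merged.
#' Single-linkage clusters under divergence strictly below `threshold` are
#' formed, and the representative of each cluster is the lexicographically
#' smallest element id.
#'
#' @param pairs Tag-pair data.frame (>= 1 row).
#' @param threshold Divergence threshold (default 0.1); merges happen below
#'   it (strict).
#' @return List with `pairs` (condensed tag-pair data.frame, representatives
#'   only) and `membership` (data.frame element_id -> representative).
#' @export
collapse_tags <- function(pairs, threshold = 0.1) {
  if (nrow(pairs) < 1) stop_input("at least one tag pair required")
  if (nrow(pairs) == 1) {
    return(list(pairs = pairs,
                membership = data.frame(element_id = pairs$element_id,
                                        representative = pairs$element_id,
                                        stringsAsFactors = FALSE)))
  }
  d <- tag_divergence(pairs)
  hc <- stats::hclust(d, method = "single")
  # cutree merges clusters joined at height <= h; shave epsilon for strict <
  # (at threshold 0, identical pairs -- divergence 0 -- still merge)
  cl <- stats::cutree(hc, h = max(threshold - 1e-12, 0))
  reps <- vapply(split(pairs$element_id, cl),
                 function(ids) min(ids), character(1))
  membership <- data.frame(element_id = pairs$element_id,
                           representative = reps[as.character(cl)],
                           stringsAsFactors = FALSE)
  cond <- pairs[pairs$element_id %in% unique(membership$representative), ,
                drop = FALSE]
  rownames(cond) <- NULL
  list(pairs = cond, membership = membership)
}

#' Write tag pairs as FASTA
#'
#' Headers follow `elementID|side|scaffold|boundary`, one record per tag
#' (two per pair).
#'
#' @param pairs Tag-pair data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tags_fasta <- function(pairs, path) {
  seqs <- c(pairs$left, pairs$right)
  names(seqs) <- c(
    sprintf("%s|left|%s|%d", pairs$element_id, pairs$scaffold,
            pairs$left_boundary),
    sprintf("%s|right|%s|%d", pairs$element_id, pairs$scaffold,
            pairs$right_boundary))
  ord <- order(rep(seq_len(nrow(pairs)), 2))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs[ord]), path)
  invisible(path)
}

#' Read a tag FASTA written by [write_tags_fasta()]
#' @param path FASTA path.
#' @return Tag-pair data.frame.
#' @export
read_tags_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(x), "|", fixed = TRUE)
  df <- data.frame(element_id = vapply(parts, `[`, "", 1),
                   side = vapply(parts, `[`, "", 2),
                   scaffold = vapply(parts, `[`, "", 3),
                   boundary = as.integer(vapply(parts, `[`, "", 4)),
                   seq = as.character(x), stringsAsFactors = FALSE)
  left <- df[df$side == "left", ]
  right <- df[df$side == "right", ]
  m <- match(left$element_id, right$element_id)
  data.frame(element_id = left$element_id, left = left$seq,
             right = right$seq[m], scaffold = left$scaffold,
             left_boundary = left$boundary, right_boundary = right$boundary[m],
             stringsAsFactors = FALSE)
}
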