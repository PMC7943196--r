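# Read-to-tag alignment.
#
# Presence of an insertion in a sample is judged from the single best read
# crossing each tag (highest number of alignment matches, penalised by
# mismatches), so the aligner only needs to find, per tag, the best local
# alignment of any read. The built-in route uses Smith-Waterman local
# alignment (match +1, mismatch -1, gap open -2, gap extend -1) with a
# k-mer prefilter to skip reads that cannot share a seed with a tag;
# alternatively, alignments produced externally against the tag FASTA can be
# supplied as SAM/BAM.

ALN_MATCH <- 1; ALN_MISMATCH <- -1
ALN_GAP_OPEN <- 2; ALN_GAP_EXT <- 1   # Biostrings penalty convention
SEED_K <- 12L

tag_kmers <- function(seqs, k = SEED_K) {
  lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    unique(substring(s, 1:(n - k + 1), k:n))
  })
}

# For each read (character vector), the indices of tags sharing >= 1 k-mer.
seed_candidates <- function(tags, reads, k = SEED_K) {
  km <- tag_kmers(tags, k)
  lookup <- data.frame(kmer = unlist(km),
                       tag = rep(seq_along(tags), lengths(km)))
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(lookup$kmer))
  hits <- Biostrings::vwhichPDict(pd, Biostrings::DNAStringSet(reads))
  lapply(hits, function(h) unique(lookup$tag[h]))
}

#' Align reads to LTR-tags with a local aligner
#'
#' Both read orientations are tried against every candidate tag; the better
#' orientation is kept per (read, tag). Alignments whose identity over the
#' aligned span (matches / alignment columns) falls below `min_identity`
#' are discarded. `M` counts tag positions aligned and matching the read,
#' `X` tag positions aligned but mismatching; unaligned tag positions count
#' to neither.
#'
#' A k-mer prefilter (shared 12-mer, either orientation) skips read/tag pairs
#' that cannot produce a useful local alignment; set `prefilter = FALSE` to
#' align every read against every tag.
#'
#' @param tags Named character vector (or `DNAStringSet`) of tag sequences.
#' @param reads `DNAStringSet` (or named character vector) of reads.
#' @param min_identity Minimum identity over the aligned span (default 0.5).
#' @param prefilter Use the k-mer seed prefilter (default TRUE).
#' @return Data.frame of alignment records: `tag`, `read`, `orientation`,
#'   `M`, `X`, `identity`, `score`.
#' @export
align_reads_to_tags <- function(tags, reads, min_identity = 0.5,
                                prefilter = TRUE) {
  if (length(tags) == 0) stop_input("tag set must be non-empty")
  tag_names <- names(tags) %||% paste0("tag", seq_along(tags))
  read_names <- names(reads) %||% paste0("read", seq_len(length(reads)))
  tag_seq <- unname(as.character(tags))
  read_seq <- unname(as.character(reads))
  if (length(read_seq) == 0)
    return(data.frame(tag = character(), read = character(),
                      orientation = character(), M = integer(), X = integer(),
                      identity = numeric(), score = numeric()))
  read_rc <- revcomp(read_seq)

  if (prefilter) {
    cand_f <- seed_candidates(tag_seq, read_seq)
    cand_r <- seed_candidates(tag_seq, read_rc)
  } else {
    all_tags <- seq_along(tag_seq)
    cand_f <- cand_r <- rep(list(all_tags), length(read_seq))
  }

  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = ALN_MATCH, mismatch = ALN_MISMATCH, baseOnly = TRUE)
  align_batch <- function(patterns, subject) {
    Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(patterns), Biostrings::DNAString(subject),
      type = "local", substitutionMatrix = submat,
      gapOpening = ALN_GAP_OPEN, gapExtension = ALN_GAP_EXT)
  }

  out <- list()
  for (t in seq_along(tag_seq)) {
    recs <- list()
    for (ori in c("+", "-")) {
      cand <- if (ori == "+") cand_f else cand_r
      sel <- which(vapply(cand, function(x) t %in% x, logical(1)))
      if (!length(sel)) next
      pats <- if (ori == "+") read_seq[sel] else read_rc[sel]
      pa <- align_batch(pats, tag_seq[t])
      ind <- Biostrings::nindel(pa)
      span <- Biostrings::nmatch(pa) + Biostrings::nmismatch(pa) +
        Biostrings::insertion(ind)[, "WidthSum"] +
        Biostrings::deletion(ind)[, "WidthSum"]
      recs[[ori]] <- data.frame(
        tag = tag_names[t], read = read_names[sel], orientation = ori,
        M = Biostrings::nmatch(pa), X = Biostrings::nmismatch(pa),
        identity = ifelse(span > 0, Biostrings::nmatch(pa) / span, 0),
        score = BiocGenerics::score(pa), stringsAsFactors = FALSE)
    }
    rec <- do.call(rbind, recs)
    if (is.null(rec) || !nrow(rec)) next
    # keep the better orientation per read
    rec <- rec[order(rec$read, -rec$score), , drop = FALSE]
    rec <- rec[!duplicated(rec$read), , drop = FALSE]
    rec <- rec[rec$identity >= min_identity, , drop = FALSE]
    out[[t]] <- rec
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(tag = character(), read = character(),
                      orientation = character(), M = integer(), X = integer(),
                      identity = numeric(), score = numeric())
  rownames(res) <- NULL
  res
}

# --- SAM/BAM route ---------------------------------------------------------

cigar_op_sum <- function(cigar, ops) {
  n <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  o <- regmatches(cigar, gregexpr("[A-Z=]", cigar))[[1]]
  sum(n[o %in% ops])
}

parse_md_stats <- function(md) {
  # MD: runs of matches, substitution bases, ^-prefixed deletion runs
  toks <- regmatches(md, gregexpr("[0-9]+|\\^[A-Z]+|[A-Z]", md))[[1]]
  matches <- sum(as.integer(toks[grepl("^[0-9]+$", toks)]))
  subs <- sum(grepl("^[A-Z]$", toks))
  c(M = matches, X = subs)
}

#' Extract per-record match/mismatch stats from SAM or BAM
#'
#' Reads alignments of sample reads against the tag FASTA and derives the
#' matched (`M`) and mismatched (`X`) tag bases per record, preferring
#' extended CIGAR `=`/`X` operations, then the MD tag, then NM minus indel
#' bases. Records carrying none of these are an error (the score cannot be
#' computed from them).
#'
#' @param path SAM or BAM path (SAM is converted via [Rsamtools::asBam()]).
#' @param min_identity Minimum identity over the aligned span (matches /
#'   (aligned M-ops + indel bases)); lower records are dropped, mirroring the
#'   built-in aligner.
#' @return Data.frame with `tag`, `read`, `M`, `X`, `identity`.
#' @export
read_sam_stats <- function(path, min_identity = 0.5) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- tempfile(fileext = ".bam")
    path <- Rsamtools::asBam(path, sub("\\.bam$", "", bam),
                             overwrite = TRUE, indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "cigar", "flag"), tag = c("MD", "NM"))
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  keep <- !is.na(b$rname) & !bitwAnd(b$flag, 4L)
  rows <- lapply(which(keep), function(i) {
    cig <- b$cigar[i]
    eqx <- cigar_op_sum(cig, "=") + cigar_op_sum(cig, "X") > 0
    ins <- cigar_op_sum(cig, "I")
    del <- cigar_op_sum(cig, "D")
    if (eqx) {
      M <- cigar_op_sum(cig, "=")
      X <- cigar_op_sum(cig, "X")
    } else if (!is.null(b$tag$MD) && !is.na(b$tag$MD[i])) {
      st <- parse_md_stats(b$tag$MD[i])
      M <- unname(st["M"]); X <- unname(st["X"])
    } else if (!is.null(b$tag$NM) && !is.na(b$tag$NM[i])) {
      aligned <- cigar_op_sum(cig, c("M"))
      X <- b$tag$NM[i] - ins - del
      M <- aligned - X
    } else {
      stop_input("SAM record '", b$qname[i],
                 "' has neither =/X CIGAR nor MD/NM; cannot score it")
    }
    span <- M + X + ins + del
    data.frame(tag = as.character(b$rname[i]), read = b$qname[i],
               M = as.integer(M), X = as.integer(X),
               identity = if (span > 0) M / span else 0,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    return(data.frame(tag = character(), read = character(), M = integer(),
                      X = integer(), identity = numeric()))
  res[res$identity >= min_identity, , drop = FALSE]
}

#' Best-read statistics for one tag in one sample
#'
#' Selects the single read with the highest number of matches `M` (ties
#' broken by fewer mismatches `X`, then by read id) and returns its stats
#' together with the number of reads aligned to the tag (the coverage
#' estimate). An empty record set gives (M = 0, X = 0, n_reads = 0).
#'
#' @param records Alignment records for one tag (rows of
#'   [align_reads_to_tags()] or [read_sam_stats()] output).
#' @return List with `M`, `X`, `n_reads`.
#' @export
best_read_stats <- function(records) {
  if (is.null(records) || nrow(records) == 0)
    return(list(M = 0L, X = 0L, n_reads = 0L))
  ord <- order(-records$M, records$X, records$read)
  best <- records[ord[1], ]
  list(M = as.integer(best$M), X = as.integer(best$X),
       n_reads = nrow(records))
}
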