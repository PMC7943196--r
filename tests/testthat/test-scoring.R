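# Alignment, best-read statistics, presence score and matrix handling.

test_that("built-in aligner finds exact and threshold-level matches", {
  fx <- make_fixture(n_elem = 2)
  tp <- extract_tag_pair(fx$elements[1, ], fx$reference)
  tags <- c(L = tp$left, R = tp$right)

  # read identical to a tag: one alignment, identity 1, M = 100, X = 0
  recs <- align_reads_to_tags(tags, c(r1 = tp$left))
  hit <- recs[recs$tag == "L", ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$M, 100)
  expect_equal(hit$X, 0)
  expect_equal(hit$identity, 1)

  # reverse-complement read aligns in the minus orientation with same stats
  rc <- align_reads_to_tags(tags, c(r1 = ltrclone:::revcomp(tp$left)))
  hit_rc <- rc[rc$tag == "L", ]
  expect_equal(hit_rc$M, 100)
  expect_equal(hit_rc$orientation, "-")

  # ~60% identity read: retained at min_identity 0.5, discarded at 0.7
  s <- strsplit(tp$left, "")[[1]]
  rot <- c(A = "C", C = "G", G = "T", T = "A")
  mism <- seq(2, 100, length.out = 40)
  s[mism] <- rot[s[mism]]
  read60 <- paste(s, collapse = "")
  r05 <- align_reads_to_tags(tags, c(x = read60), min_identity = 0.5,
                             prefilter = FALSE)
  expect_true("L" %in% r05$tag)
  id60 <- r05$identity[r05$tag == "L"]
  expect_gt(id60, 0.5); expect_lt(id60, 0.7)
  r07 <- align_reads_to_tags(tags, c(x = read60), min_identity = 0.7,
                             prefilter = FALSE)
  expect_false("L" %in% r07$tag)

  expect_error(align_reads_to_tags(character(), c(r = "ACGT")), "non-empty")
})

test_that("best_read_stats picks max matches with documented tie-breaks", {
  recs <- data.frame(tag = "t", read = c("a", "b"), orientation = "+",
                     M = c(80, 95), X = c(0, 2), identity = 1, score = 1)
  st <- best_read_stats(recs)
  expect_equal(st$M, 95)
  expect_equal(st$X, 2)
  expect_equal(st$n_reads, 2)

  # tie on M: smaller X wins; tie on both: lexicographically first read
  recs2 <- data.frame(tag = "t", read = c("b", "a"), orientation = "+",
                      M = c(90, 90), X = c(3, 1), identity = 1, score = 1)
  expect_equal(best_read_stats(recs2)$X, 1)
  recs3 <- data.frame(tag = "t", read = c("b", "a"), orientation = "+",
                      M = c(90, 90), X = c(1, 1), identity = 1, score = 1)
  expect_equal(best_read_stats(recs3)$n_reads, 2)

  expect_equal(best_read_stats(NULL), list(M = 0L, X = 0L, n_reads = 0L))
})

test_that("presence_score implements the stated formula with flooring", {
  mk <- function(M, X, n = 1) list(M = M, X = X, n_reads = n)
  expect_equal(presence_score(mk(100, 0), mk(100, 0))$S, 1.0)
  expect_equal(presence_score(mk(100, 0), mk(100, 0))$raw, 200)
  expect_equal(presence_score(mk(0, 0, 0), mk(0, 0, 0))$S, 0)
  expect_equal(presence_score(mk(100, 0), mk(75, 0))$S, 0.875)
  # negative raw scores floor to zero
  sc <- presence_score(mk(10, 60), mk(5, 40))
  expect_equal(sc$raw, -85)
  expect_equal(sc$S, 0)
  expect_equal(presence_score(mk(100, 0, 4), mk(75, 0, 3))$coverage, 7)
})

test_that("score is monotone in matches and mismatches", {
  mk <- function(M, X) list(M = M, X = X, n_reads = 1)
  base <- presence_score(mk(80, 5), mk(70, 3))$S
  expect_gte(presence_score(mk(85, 5), mk(70, 3))$S, base)
  expect_lte(presence_score(mk(80, 9), mk(70, 3))$S, base)
  expect_lte(presence_score(mk(80, 5), mk(70, 8))$S, base)
})

test_that("SAM records yield match/mismatch stats per tag semantics", {
  fx <- make_fixture(n_elem = 2)
  pairs <- extract_tag_pairs(fx$elements, fx$reference)
  tagname <- sprintf("%s|left|%s|%d", pairs$element_id[1], pairs$scaffold[1],
                     pairs$left_boundary[1])
  tag_seq <- pairs$left[1]
  # read = tag with 2 substitutions; aligned span 100, no indels
  s <- strsplit(tag_seq, "")[[1]]
  rot <- c(A = "C", C = "G", G = "T", T = "A")
  s[c(10, 20)] <- rot[s[c(10, 20)]]
  read2 <- paste(s, collapse = "")

  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:100", tagname),
    # NM route: 100M with NM:i:2 -> M=98, X=2
    sprintf("nm_read\t0\t%s\t1\t60\t100M\t*\t0\t0\t%s\t*\tNM:i:2", tagname, read2),
    # extended CIGAR route
    sprintf("eqx_read\t0\t%s\t1\t60\t9=1X9=1X80=\t*\t0\t0\t%s\t*", tagname, read2),
    # MD route (no NM, no =/X): MD encodes 2 substitutions
    sprintf("md_read\t0\t%s\t1\t60\t100M\t*\t0\t0\t%s\t*\tMD:Z:9A9C80",
            tagname, read2)),
    sam)
  st <- read_sam_stats(sam)
  expect_equal(st$M[st$read == "nm_read"], 98)
  expect_equal(st$X[st$read == "nm_read"], 2)
  expect_equal(st$M[st$read == "eqx_read"], 98)
  expect_equal(st$X[st$read == "eqx_read"], 2)
  expect_equal(st$M[st$read == "md_read"], 98)
  expect_equal(st$X[st$read == "md_read"], 2)

  # record with neither =/X nor MD/NM is unusable and names the read
  sam_bad <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:100", tagname),
    sprintf("orphan\t0\t%s\t1\t60\t100M\t*\t0\t0\t%s\t*", tagname, read2)),
    sam_bad)
  expect_error(read_sam_stats(sam_bad), "orphan")
  unlink(c(sam, sam_bad))
})

test_that("built-in aligner scores agree with an external SAM on exact reads", {
  fx <- make_fixture(n_elem = 3)
  pairs <- extract_tag_pairs(fx$elements, fx$reference)
  coll <- collapse_tags(pairs)
  p <- coll$pairs
  # one read identical to every tag, plus unrelated reads
  tag_names <- c(sprintf("%s|left|%s|%d", p$element_id, p$scaffold,
                         p$left_boundary),
                 sprintf("%s|right|%s|%d", p$element_id, p$scaffold,
                         p$right_boundary))
  tag_seqs <- c(p$left, p$right)
  junk <- as.character(simulate_reads(make_genome(1, 2000, 0.5, seed = 99),
                                      2, 100, 0, seed = 1))
  reads <- stats::setNames(c(tag_seqs, junk),
                           paste0("r", seq_along(c(tag_seqs, junk))))

  s_builtin <- score_sample(p, reads = Biostrings::DNAStringSet(reads))

  # SAM constructed from ground truth (each tag read maps 100M, NM 0)
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:100", tag_names),
    sprintf("r%d\t0\t%s\t1\t60\t100M\t*\t0\t0\t%s\t*\tNM:i:0",
            seq_along(tag_seqs), tag_names, tag_seqs)),
    sam)
  s_sam <- score_sample(p, sam = sam)
  expect_equal(s_builtin$S, s_sam$S)
  expect_equal(s_builtin$S, rep(1, nrow(p)))
  unlink(sam)
})

test_that("presence matrix assembles, round-trips and binarizes strictly", {
  scored <- list(
    a = data.frame(tag = c("t1", "t2"), S = c(1.0, 0.51), coverage = c(5L, 4L)),
    b = data.frame(tag = c("t1", "t2"), S = c(0.875, 0.9), coverage = c(3L, 6L)),
    c = data.frame(tag = c("t1", "t2"), S = c(0.0, 0.123456), coverage = c(0L, 2L)))
  pm <- build_presence_matrix(scored)
  expect_equal(dim(pm$S), c(3, 2))
  expect_false(anyNA(pm$S))

  f <- tempfile()
  write_presence_tsv(pm, f)
  back <- read_presence_tsv(paste0(f, ".long.tsv"))
  expect_equal(back$S, pm$S, tolerance = 1e-6)
  expect_equal(back$coverage, pm$coverage)
  unlink(paste0(f, c(".long.tsv", ".wide.tsv")))

  b <- binarize_matrix(pm)
  # strict threshold: S = 0.875 codes absent, 0.9 present, 1 present, 0 absent
  expect_equal(b["a", "t1"], 1L)
  expect_equal(b["b", "t1"], 0L)
  expect_equal(b["b", "t2"], 1L)
  expect_equal(b["c", "t1"], 0L)
  expect_error(binarize_matrix(pm, threshold = 1.5), "threshold")

  # missing cell is an assembly error naming sample and tag
  scored$b <- scored$b[1, ]
  expect_error(build_presence_matrix(scored), "b.*t2")
})

test_that("NEXUS export of the binary matrix is readable", {
  m <- nested_truth_matrix(paste0("s", 1:4), paste0("e", 1:3))
  f <- tempfile(fileext = ".nex")
  write_binary_nexus(m, f)
  txt <- readLines(f)
  expect_true(any(grepl("NEXUS", txt, ignore.case = TRUE)))
  back <- ape::read.nexus.data(f)
  expect_equal(names(back), rownames(m))
  expect_equal(unname(vapply(back, paste, "", collapse = "")),
               unname(apply(m, 1, paste, collapse = "")))
  unlink(f)
})

test_that("empty insertion sites score near one half", {
  fx <- make_fixture(n_ind = 3, n_elem = 3)
  pm <- score_fixture(fx, coverage = 20)
  truth <- fx$truth[rownames(pm$S), colnames(pm$S)]
  absent <- pm$S[truth == 0]
  present <- pm$S[truth == 1]
  # genomic half matches, element half does not: S ~ 0.5 well below 0.875
  expect_true(all(absent > 0.3 & absent < 0.7))
  expect_true(all(present > 0.875))
})
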