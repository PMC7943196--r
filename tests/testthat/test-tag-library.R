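# Element loading, candidate filtering, tag extraction and collapsing.

write_test_gff3 <- function(lines, path = tempfile(fileext = ".gff3")) {
  writeLines(c("##gff-version 3", lines), path)
  path
}

test_that("load_elements converts GFF3 1-based inclusive to 0-based half-open", {
  f <- write_test_gff3(c(
    "scf1\tsrc\tLTR_retrotransposon\t1001\t1300\t.\t+\t.\tID=el1",
    "scf1\tsrc\tlong_terminal_repeat\t1001\t1050\t.\t+\t.\tID=el1_5;Parent=el1",
    "scf1\tsrc\tlong_terminal_repeat\t1251\t1300\t.\t+\t.\tID=el1_3;Parent=el1"))
  el <- load_elements(f)
  expect_equal(el$start, 1000)
  expect_equal(el$end, 1300)
  expect_equal(el$ltr5_start, 1000)
  expect_equal(el$ltr5_end, 1050)
  expect_equal(el$ltr3_start, 1250)
  expect_equal(el$ltr3_end, 1300)
  unlink(f)
})

test_that("elements lacking both LTR sub-features are skipped with a warning", {
  f <- write_test_gff3(c(
    "scf1\tsrc\tLTR_retrotransposon\t101\t400\t.\t+\t.\tID=only_one",
    "scf1\tsrc\tlong_terminal_repeat\t101\t150\t.\t+\t.\tID=x;Parent=only_one",
    "scf1\tsrc\tLTR_retrotransposon\t1001\t1300\t.\t+\t.\tID=good",
    "scf1\tsrc\tlong_terminal_repeat\t1001\t1050\t.\t+\t.\tID=a;Parent=good",
    "scf1\tsrc\tlong_terminal_repeat\t1251\t1300\t.\t+\t.\tID=b;Parent=good"))
  expect_warning(el <- load_elements(f), "only_one")
  expect_equal(el$id, "good")
  unlink(f)
})

test_that("fixture element table round-trips through GFF3", {
  fx <- make_fixture(n_elem = 4)
  f <- tempfile(fileext = ".gff3")
  write_elements_gff3(fx$elements, f)
  back <- load_elements(f, fx$reference)
  cols <- c("id", "scaffold", "start", "end", "ltr5_start", "ltr5_end",
            "ltr3_start", "ltr3_end", "strand")
  back <- back[match(fx$elements$id, back$id), cols]
  rownames(back) <- NULL
  expect_equal(back, fx$elements[, cols])
  unlink(f)
})

test_that("filter_candidates assigns reasons per rule", {
  fx <- make_fixture(n_elem = 4)
  els <- fx$elements
  support <- data.frame(scaffold = els$scaffold, start = els$start,
                        end = els$end)
  # clean elements are retained with empty reasons
  rep0 <- filter_candidates(els, NULL, support, fx$reference)
  expect_true(all(rep0$retained))
  expect_true(all(rep0$reasons == ""))

  # gene overlapping the 5' LTR by 10 bp
  genes <- data.frame(scaffold = "scf1", start = els$ltr5_start[1] - 40,
                      end = els$ltr5_start[1] + 10)
  rep1 <- filter_candidates(els, genes, support, fx$reference)
  expect_false(rep1$retained[1])
  expect_match(rep1$reasons[1], "gene_overlap")
  expect_true(all(rep1$retained[-1]))

  # a gene in the internal region (not in either LTR) does not remove
  genes_int <- data.frame(scaffold = "scf1", start = els$ltr5_end[1] + 5,
                          end = els$ltr5_end[1] + 50)
  rep1b <- filter_candidates(els, genes_int, support, fx$reference)
  expect_true(rep1b$retained[1])

  # 'N' 120 bases downstream of the span end
  g2 <- fx$reference
  chr <- as.character(g2[[1]])
  pos <- els$end[2] + 120  # 0-based offset -> character position pos+1
  substr(chr, pos + 1, pos + 1) <- "N"
  g2[[1]] <- Biostrings::DNAString(chr)
  rep2 <- filter_candidates(els, NULL, support, g2)
  expect_false(rep2$retained[2])
  expect_match(rep2$reasons[2], "n_in_flank")
  # N beyond the 150-base window is ignored
  g3 <- fx$reference
  chr <- as.character(g3[[1]])
  pos <- els$end[2] + 200
  substr(chr, pos + 1, pos + 1) <- "N"
  g3[[1]] <- Biostrings::DNAString(chr)
  expect_true(filter_candidates(els, NULL, support, g3)$retained[2])

  # missing repeat support
  sup3 <- support[-3, ]
  rep3 <- filter_candidates(els, NULL, sup3, fx$reference)
  expect_false(rep3$retained[3])
  expect_match(rep3$reasons[3], "no_repeat_support")

  # insufficient flank
  el_edge <- els[1, ]
  el_edge$start <- 10; el_edge$end <- 200
  repe <- filter_candidates(el_edge, NULL, NULL, fx$reference)
  expect_match(repe$reasons[1], "insufficient_flank")
})

test_that("filtering is order-independent", {
  fx <- make_fixture(n_elem = 4)
  els <- fx$elements
  genes <- data.frame(scaffold = "scf1", start = els$ltr3_start[2],
                      end = els$ltr3_start[2] + 5)
  support <- data.frame(scaffold = els$scaffold[-4], start = els$start[-4],
                        end = els$end[-4])
  r1 <- filter_candidates(els, genes, support, fx$reference)
  perm <- c(3, 1, 4, 2)
  r2 <- filter_candidates(els[perm, ], genes, support, fx$reference)
  r2 <- r2[match(r1$element_id, r2$element_id), ]
  rownames(r2) <- NULL
  expect_equal(r1, r2)
})

test_that("extract_tag_pair does the stated coordinate arithmetic", {
  g <- make_genome(1, 5000, 0.5, seed = 10)
  chr <- as.character(g[[1]])
  el <- data.frame(id = "e", scaffold = "scf1", start = 1000, end = 3600,
                   ltr5_start = 1000, ltr5_end = 1300, ltr3_start = 3300,
                   ltr3_end = 3600, strand = "+")
  tp <- extract_tag_pair(el, g)
  expect_identical(tp$left, substr(chr, 951, 1050))    # bases [950,1050)
  expect_identical(tp$right, substr(chr, 3551, 3650))  # bases [3550,3650)
  expect_equal(nchar(tp$left), 100)
  expect_equal(nchar(tp$right), 100)

  # minus strand: tags reverse-complemented and swapped
  el$strand <- "-"
  tm <- extract_tag_pair(el, g)
  expect_identical(tm$left, ltrclone:::revcomp(substr(chr, 3551, 3650)))
  expect_identical(tm$right, ltrclone:::revcomp(substr(chr, 951, 1050)))

  # planted element: tags equal flank + known LTR prefix/suffix
  fx <- make_fixture(n_elem = 2)
  e <- fx$elements[1, ]
  ref <- as.character(fx$reference[[1]])
  ltr <- substr(ref, e$ltr5_start + 1, e$ltr5_end)
  tpp <- extract_tag_pair(e, fx$reference)
  expect_identical(tpp$left, paste0(substr(ref, e$start - 49, e$start),
                                    substr(ltr, 1, 50)))
  expect_identical(tpp$right,
                   paste0(substr(ltr, nchar(ltr) - 49, nchar(ltr)),
                          substr(ref, e$end + 1, e$end + 50)))

  # N inside the tag region is an error naming the element
  gn <- g
  chrN <- chr; substr(chrN, 1000, 1000) <- "N"
  gn[[1]] <- Biostrings::DNAString(chrN)
  el$strand <- "+"
  expect_error(extract_tag_pair(el, gn), "N base")
  el2 <- el; el2$start <- 30
  expect_error(extract_tag_pair(el2, g), "insufficient flank")
})

mutate_at <- function(seq, positions) {
  rot <- c(A = "C", C = "G", G = "T", T = "A")
  s <- strsplit(seq, "")[[1]]
  s[positions] <- rot[s[positions]]
  paste(s, collapse = "")
}

test_that("collapse_tags merges by single-linkage p-distance", {
  fx <- make_fixture(n_elem = 3)
  pairs <- extract_tag_pairs(fx$elements, fx$reference)

  # two pairs differing at 10/200 positions (divergence 0.05) collapse
  p2 <- pairs[1:2, ]
  p2$element_id <- c("a", "b")
  cat2 <- paste0(pairs$left[1], pairs$right[1])
  mut <- mutate_at(cat2, 1:10)
  p2$left[2] <- substr(mut, 1, 100); p2$right[2] <- substr(mut, 101, 200)
  cl <- collapse_tags(p2)
  expect_equal(nrow(cl$pairs), 1)
  expect_equal(unique(cl$membership$representative), "a")

  # identical pairs: one cluster, lexicographically smallest id represents
  p3 <- p2; p3$left[2] <- p2$left[1]; p3$right[2] <- p2$right[1]
  p3$element_id <- c("zz", "aa")
  cl3 <- collapse_tags(p3)
  expect_equal(cl3$membership$representative, c("aa", "aa"))

  # chain: d(A,B)=0.08, d(B,C)=0.08, d(A,C)=0.16 -> one single-linkage cluster
  base <- cat2
  B <- mutate_at(base, 1:16)
  C <- mutate_at(base, 1:32)
  chain <- data.frame(element_id = c("A", "B", "C"),
                      left = substr(c(base, B, C), 1, 100),
                      right = substr(c(base, B, C), 101, 200),
                      scaffold = "scf1", left_boundary = 0, right_boundary = 0)
  d <- as.matrix(tag_divergence(chain))
  expect_equal(d["A", "B"], 0.08)
  expect_equal(d["B", "C"], 0.08)
  expect_equal(d["A", "C"], 0.16)
  cl4 <- collapse_tags(chain, threshold = 0.1)
  expect_equal(nrow(cl4$pairs), 1)

  # boundary is strict: divergence exactly at the threshold does not merge
  expect_equal(nrow(collapse_tags(chain, threshold = 0.08)$pairs), 3)

  # threshold 0 collapses only identical pairs; threshold 1 collapses all
  expect_equal(nrow(collapse_tags(p3, threshold = 0)$pairs), 1)
  expect_equal(nrow(collapse_tags(p2, threshold = 0)$pairs), 2)
  expect_equal(nrow(collapse_tags(pairs, threshold = 1)$pairs), 1)

  # unequal tag lengths are rejected
  bad <- chain; bad$left[1] <- substr(bad$left[1], 1, 50)
  expect_error(collapse_tags(bad), "unequal")
})

test_that("tag FASTA round-trips with structured headers", {
  fx <- make_fixture(n_elem = 3)
  pairs <- extract_tag_pairs(fx$elements, fx$reference)
  f <- tempfile(fileext = ".fasta")
  write_tags_fasta(pairs, f)
  back <- read_tags_fasta(f)
  expect_equal(back[order(back$element_id), ],
               pairs[order(pairs$element_id), ], ignore_attr = TRUE)
  unlink(f)
})

test_that("RepeatMasker .out tables parse to intervals", {
  f <- tempfile(fileext = ".out")
  writeLines(c(
    "   SW  perc perc perc  query     position in query    matching repeat",
    "score  div. del. ins.  sequence  begin   end  (left)  repeat class",
    "",
    "  239 29.4  1.9  1.0  scf1      101     400  (600)  + LTR/Gypsy x 1 4",
    "  100 10.0  0.0  0.0  scf2      51      80   (100)  C LTR/Copia y 2 5"),
    f)
  iv <- read_repeatmasker_out(f)
  expect_equal(iv$scaffold, c("scf1", "scf2"))
  expect_equal(iv$start, c(100, 50))
  expect_equal(iv$end, c(400, 80))
  unlink(f)
})
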