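test_that("aligned FASTA round-trips with normalization", {
  tf <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", "acd.e", ">s2", "ACD-E", ">s3", "AC--E"), tf)
  m <- read_msa(tf)
  expect_equal(m$seqs, c("ACD-E", "ACD-E", "AC--E"))
  expect_equal(m$n_columns, 5)
  tf2 <- withr::local_tempfile(fileext = ".fasta")
  write_msa(m, tf2)
  m2 <- read_msa(tf2)
  expect_equal(m2$ids, m$ids)
  expect_equal(m2$seqs, m$seqs)
})

test_that("ragged alignments, duplicate ids and bad characters are errors", {
  tf <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", "ACDE", ">s2", "ACD"), tf)
  expect_error(read_msa(tf), class = "pe_bad_msa")
  expect_error(porineva:::new_msa(c("a", "a"), c("AC", "AC")),
               class = "pe_bad_msa")
  expect_error(porineva:::new_msa("a", "AB1"), class = "pe_bad_msa")
})

test_that("pairwise identity uses shared non-gap columns", {
  expect_equal(pairwise_identity("ACDE", "ACDE"), 1)
  expect_equal(pairwise_identity("AC-E", "ACD-"), 1)   # 2 shared, 2 match
  expect_equal(pairwise_identity("ACDE", "ACDF"), 0.75)
  expect_warning(id <- pairwise_identity("AC--", "--DE"),
                 "no shared non-gap")
  expect_equal(id, 0)
  expect_error(pairwise_identity("ACD", "AC"), class = "pe_bad_msa")
})

test_that("redundancy filtering removes duplicates and respects the ceiling", {
  m <- porineva:::new_msa(c("a", "b", "c"),
                          c("ACDEFGHIKL", "ACDEFGHIKL", "ACDEFGHIKW"))
  fr <- filter_redundant(m)
  expect_equal(fr$report$survivors, 2)
  expect_equal(nrow(fr$report$removed), 1)
  expect_equal(fr$report$removed$reason, "high_identity")
  # identities all below the ceiling: untouched
  m2 <- porineva:::new_msa(c("a", "b"), c("AAAAAAAAAA", "CCCCCAAAAA"))
  fr2 <- filter_redundant(m2)
  expect_equal(length(fr2$msa$ids), 2)
  expect_equal(nrow(fr2$report$removed), 0)
})

test_that("redundancy filtering is deterministic, idempotent and leaves no hot pair", {
  set.seed(21)
  base <- sample(AA20, 40, replace = TRUE)
  mutate <- function(s, k) {
    p <- sample(40, k); s[p] <- sample(AA20, k, replace = TRUE); s
  }
  seqs <- vapply(c(0, 1, 2, 20, 22, 3), function(k)
    paste(mutate(base, k), collapse = ""), character(1))
  m <- porineva:::new_msa(sprintf("s%d", 1:6), seqs)
  f1 <- filter_redundant(m)
  f2 <- filter_redundant(m)
  expect_identical(f1$msa$ids, f2$msa$ids)
  idm <- porineva:::identity_matrix(f1$msa)
  diag(idm) <- 0
  expect_lte(max(idm), 0.90)
  f3 <- filter_redundant(f1$msa)
  expect_identical(f3$msa$ids, f1$msa$ids)
  expect_equal(nrow(f3$report$removed), 0)
})

test_that("greedy filtering matches minimal-removal brute force on small cliques", {
  # planted 3-clique of near-identical sequences plus two distinct ones
  base <- paste(rep(c("A", "C", "D", "E", "F"), 8), collapse = "")
  v <- strsplit(base, "")[[1]]
  tweak <- function(pos, to) { w <- v; w[pos] <- to; paste(w, collapse = "") }
  m <- porineva:::new_msa(
    sprintf("s%d", 1:5),
    c(base, tweak(1, "W"), tweak(2, "Y"),
      paste(rev(v), collapse = ""),
      paste(sample(AA20, 40, replace = TRUE), collapse = "")))
  f <- filter_redundant(m)
  sols <- brute_min_removals(m)
  kept <- match(f$msa$ids, m$ids)
  expect_true(any(vapply(sols, function(s) setequal(s, kept), logical(1))))
})

test_that("divergence filtering drops low-identity sequences, never the reference", {
  set.seed(22)
  ref <- paste(sample(AA20, 50, replace = TRUE), collapse = "")
  near <- ref
  far <- paste(sample(setdiff(AA20, strsplit(ref, "")[[1]][1]), 50,
                      replace = TRUE), collapse = "")
  m <- porineva:::new_msa(c("REF", "near", "far"), c(ref, near, far))
  fd <- filter_divergent(m, "REF", min_id = 0.20)
  expect_true(all(c("REF", "near") %in% fd$msa$ids))
  expect_false("far" %in% fd$msa$ids)
  expect_equal(fd$report$removed$reason, "low_identity")
  # vacuous bound removes nothing
  fd0 <- filter_divergent(m, "REF", min_id = 0)
  expect_equal(length(fd0$msa$ids), 3)
  expect_error(filter_divergent(m, "nope"), class = "pe_missing_reference")
})

test_that("column mapping skips reference gaps and stays monotone", {
  model <- toy_model(cbind(3.8 * 1:8, 0, 0), sequence = "ACDEFGHI")
  msa <- porineva:::new_msa(c("REF", "o"),
                            c("AC--DEFG-HI-", "ACWWDEFGWHIW"))
  map <- map_columns(msa, "REF", model)
  expect_equal(map$column_index, c(1, 2, 5, 6, 7, 8, 10, 11))
  expect_equal(map$residue_index, 1:8)
  expect_true(all(diff(map$column_index) > 0))
  expect_true(all(diff(map$residue_index) > 0))
  # identity case
  msa2 <- porineva:::new_msa(c("REF", "o"), c("ACDEFGHI", "ACDEFGHI"))
  map2 <- map_columns(msa2, "REF", model)
  expect_equal(map2$column_index, 1:8)
  expect_equal(map2$residue_index, 1:8)
  # grossly mismatched reference errors
  msa3 <- porineva:::new_msa(c("REF", "o"), c("WWWWWWWW", "ACDEFGHI"))
  expect_error(map_columns(msa3, "REF", model),
               class = "pe_reference_mismatch")
})
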