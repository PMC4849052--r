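test_that("entropy matches closed forms and the counting oracle", {
  expect_equal(column_entropy(rep("A", 50)), 0)
  expect_equal(column_entropy(c(rep("A", 25), rep("G", 25))), log(2))
  expect_true(is.na(column_entropy(rep("-", 10))))
  set.seed(31)
  for (i in 1:20) {
    col <- sample(c(AA20, "-"), 100, replace = TRUE)
    expect_equal(column_entropy(col), naive_entropy(col), tolerance = 1e-12)
  }
  # log base is configurable
  col <- c(rep("A", 50), rep("G", 50))
  expect_equal(column_entropy(col, base = 2), 1)
})

test_that("variability counts types strictly above the frequency threshold", {
  expect_equal(column_variability(rep("A", 10)), 1L)
  col <- c(rep("A", 990), rep("G", 6), rep("C", 4))
  expect_equal(column_variability(col), 2L)   # C at 0.4% does not count
  col2 <- c(rep("A", 995), rep("G", 5))
  expect_equal(column_variability(col2), 1L)  # 0.5% exactly is excluded
  expect_equal(column_variability(rep("-", 5)), 0L)
})

test_that("box classification is total, hits the corners, and is monotone", {
  sc <- ev_scheme()
  expect_equal(classify_box(0, 1L, sc), "11")
  expect_equal(classify_box(log(20), 20L, sc), "33")
  grid <- expand.grid(V = 1:20, E = seq(0, log(20), length.out = 61))
  boxes <- classify_box(grid$E, grid$V, sc)
  expect_false(any(is.na(boxes)))
  expect_true(all(boxes %in% c("11", "12", "22", "23", "33")))
  # oracle: direct predicate evaluation
  oracle <- with(grid, ifelse(V <= 4 & E <= sc$e_lo, "11",
                  ifelse(V <= 4, "12",
                   ifelse(V <= 12 & E <= sc$e_hi, "22",
                    ifelse(V > 12 & E > sc$e_hi, "33", "23")))))
  expect_equal(boxes, oracle)
  # raising e_lo never decreases the Box 11 count
  n11 <- vapply(seq(0.1, log(20) * 0.6, length.out = 8), function(e_lo) {
    sum(classify_box(grid$E, grid$V,
                     ev_scheme(e_lo = e_lo, e_hi = log(20) * 0.9)) == "11")
  }, numeric(1))
  expect_true(all(diff(n11) >= 0))
  expect_error(ev_scheme(v_lo = 10, v_hi = 5), class = "pe_bad_scheme")
})

test_that("compute_eva handles conserved alignments and gap-heavy columns", {
  m <- porineva:::new_msa(sprintf("s%d", 1:10),
                          rep(strrep("ACDEF", 4), 10))
  ev <- compute_eva(m)
  expect_true(all(ev$stats$valid))
  expect_true(all(ev$stats$box == "11"))
  expect_true(all(ev$stats$entropy == 0))
  # a column with 60% gaps is invalid
  seqs <- c(rep("A-CD", 6), rep("AACD", 4))
  m2 <- porineva:::new_msa(sprintf("s%d", 1:10), seqs)
  ev2 <- compute_eva(m2)
  expect_false(ev2$stats$valid[2])
  expect_true(is.na(ev2$stats$box[2]))
  expect_error(compute_eva(porineva:::new_msa("a", "ACD")),
               class = "pe_empty_input")
})

test_that("entropy is permutation-invariant and grows with type replacement", {
  set.seed(32)
  col <- sample(c("A", "G", "L"), 60, replace = TRUE, prob = c(.6, .3, .1))
  expect_equal(column_entropy(col), column_entropy(sample(col)))
  # replacing one copy of the majority type with a new distinct type
  col2 <- col
  col2[which(col2 == "A")[1]] <- "W"
  expect_gte(column_entropy(col2), column_entropy(col))
})

test_that("region box table rows sum to 100 and reflect planted structure", {
  fx <- generate_study_fixture("inward", n_strands = 8, strand_length = 8,
                               n_sequences = 150, seed = 41)
  ev <- compute_eva(fx$msa)
  map <- map_columns(fx$msa, fx$reference_id, fx$model)
  ann <- annotate_topology(fx$model)
  ori <- orient_residues(fx$model, ann)
  lf <- classify_long_loops(ann)
  tab <- region_box_distribution(ev, map, ann, ori, lf, NA)
  sums <- rowSums(tab[, c("11", "12", "22", "23", "33")])
  counts <- attr(tab, "counts")
  expect_true(all(abs(sums[rowSums(counts) > 0] - 100) < 0.1))
  # planted inward conservation: inward conserved share beats outward
  summ <- interface_conservation_summary(tab)
  expect_gt(summ$inward, 0.9)
  expect_lt(summ$outward, 0.1)
  expect_gt(summ$difference, 0.8)
  expect_false(summ$outward_conserved)
})

test_that("interface summary flags outward conservation above the floor", {
  counts <- matrix(0, 9, 5,
                   dimnames = list(porineva:::REGION_ROWS,
                                   porineva:::BOXES))
  counts["inward", ] <- c(10, 5, 5, 10, 10)
  counts["outward", ] <- c(6, 3, 3, 10, 18)
  pct <- counts / pmax(rowSums(counts), 1) * 100
  tab <- structure(data.frame(region = rownames(counts), pct,
                              check.names = FALSE),
                   counts = counts,
                   class = c("region_box_table", "data.frame"))
  s <- interface_conservation_summary(tab)
  expect_equal(s$outward, 0.30)
  expect_true(s$outward_conserved)
  counts2 <- counts
  counts2["outward", ] <- c(0, 0, 0, 10, 30)
  tab2 <- structure(as.data.frame(tab), counts = counts2,
                    class = c("region_box_table", "data.frame"))
  s2 <- interface_conservation_summary(tab2)
  expect_equal(s2$outward, 0)
  expect_false(s2$outward_conserved)
  expect_equal(s2$difference, s2$inward)
})

test_that("a negative control: conservation planted on loops, not inward", {
  fx <- generate_study_fixture("long_loops", n_strands = 8,
                               strand_length = 8, n_sequences = 150,
                               seed = 42)
  ev <- compute_eva(fx$msa)
  map <- map_columns(fx$msa, fx$reference_id, fx$model)
  ann <- annotate_topology(fx$model)
  ori <- orient_residues(fx$model, ann)
  lf <- classify_long_loops(ann)
  tab <- region_box_distribution(ev, map, ann, ori, lf, NA)
  counts <- attr(tab, "counts")
  long_cons <- sum(counts["extracellular_long", c("11", "12", "22")]) /
    sum(counts["extracellular_long", ])
  inward_cons <- sum(counts["inward", c("11", "12", "22")]) /
    sum(counts["inward", ])
  expect_gt(long_cons, 0.9)
  expect_lt(inward_cons, 0.2)
})
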