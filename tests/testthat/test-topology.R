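test_that("ladder assignment: barrels all E, helices and short chains none", {
  b0 <- generate_barrel(barrel_spec(n_strands = 16, strand_length = 10,
                                    loop_lengths_extracellular = 0,
                                    loop_lengths_periplasmic = 0))
  expect_true(all(assign_secondary_structure(b0$model) == "E"))
  expect_true(all(assign_secondary_structure(helix_model(20)) == "-"))
  short <- helix_model(3)
  expect_true(all(assign_secondary_structure(short) == "-"))
})

test_that("residues with missing backbone atoms are labelled '-' with warning", {
  m <- generate_barrel(barrel_spec(n_strands = 8, strand_length = 8))$model
  m$atoms <- m$atoms[!(m$atoms$residue_index == 5 &
                         m$atoms$atom_name == "O"), ]
  expect_warning(ss <- assign_secondary_structure(m), "missing backbone")
  expect_equal(ss[5], "-")
})

test_that("region classification matches generator ground truth exactly", {
  for (n in c(8, 14, 22)) {
    bar <- generate_barrel(barrel_spec(n_strands = n, strand_length = 10))
    ann <- annotate_topology(bar$model)
    gt <- bar$annotation
    expect_equal(ann$label, gt$label)
    expect_equal(ann$loop_index, gt$loop_index)
    expect_equal(attr(ann, "strand_count"), n)
    # partition completeness
    expect_equal(sum(table(ann$label)), n_residues(bar$model))
  }
})

test_that("zero-length connectors give an all-strand classification", {
  b0 <- generate_barrel(barrel_spec(n_strands = 16, strand_length = 10,
                                    loop_lengths_extracellular = 0,
                                    loop_lengths_periplasmic = 0))
  ann <- annotate_topology(b0$model)
  expect_true(all(ann$label == "STRAND"))
  expect_equal(attr(ann, "strand_count"), 16)
})

test_that("an all-coil structure is rejected as not a barrel", {
  hel <- helix_model(30)
  ss <- assign_secondary_structure(hel)
  expect_error(detect_barrel(hel, ss), class = "pe_not_barrel")
})

test_that("core extraction keeps exactly the strand residues, idempotently", {
  bar <- generate_barrel(barrel_spec(n_strands = 16, strand_length = 10,
                                     loop_lengths_extracellular = 6))
  ann <- annotate_topology(bar$model)
  core <- extract_core(bar$model, ann)
  expect_equal(n_residues(core), 160)
  core2 <- extract_core(core, attr(core, "core_annotation"))
  expect_equal(core2$atoms[, c("x", "y", "z")], core$atoms[, c("x", "y", "z")])
  expect_equal(core2$sequence, core$sequence)
  # all-strand input is the identity
  b0 <- generate_barrel(barrel_spec(n_strands = 8, strand_length = 8,
                                    loop_lengths_extracellular = 0,
                                    loop_lengths_periplasmic = 0))
  ann0 <- annotate_topology(b0$model)
  expect_equal(n_residues(extract_core(b0$model, ann0)),
               n_residues(b0$model))
  ann_none <- ann
  ann_none$label <- "EXTRACELLULAR_LOOP"
  expect_error(extract_core(bar$model, ann_none),
               class = "pe_empty_structure")
})

test_that("constriction loop is found when planted and absent otherwise", {
  spc <- barrel_spec(n_strands = 16, strand_length = 10,
                     constriction_loop = list(index = 2, depth = 0.3))
  bc <- generate_barrel(spc)
  ann <- annotate_topology(bc$model)
  cl <- detect_constriction_loop(bc$model, ann)
  expect_equal(as.integer(cl), 2L)
  expect_gt(attr(cl, "inside_fraction")[["2"]], 0.5)
  bar <- generate_barrel(barrel_spec(n_strands = 16, strand_length = 10))
  ann2 <- annotate_topology(bar$model)
  expect_true(is.na(detect_constriction_loop(bar$model, ann2)))
})

test_that("constriction detection and orientation are rigid-motion invariant", {
  spc <- barrel_spec(n_strands = 8, strand_length = 8,
                     constriction_loop = list(index = 1, depth = 0.3))
  bc <- generate_barrel(spc)
  ann <- annotate_topology(bc$model)
  ori <- orient_residues(bc$model, ann)
  mt <- rigid_transform_model(bc$model)
  annt <- annotate_topology(mt)
  expect_equal(as.integer(detect_constriction_loop(mt, annt)),
               as.integer(detect_constriction_loop(bc$model, ann)))
  expect_equal(orient_residues(mt, annt), ori)
})

test_that("long-loop rule: >15% of total extracellular length, with override", {
  # loop lengths 20/5/5/3: threshold 4.95 -> TRUE TRUE TRUE FALSE
  bar <- generate_barrel(barrel_spec(n_strands = 8, strand_length = 8,
                                     loop_lengths_extracellular =
                                       c(20, 5, 5, 3)))
  ann <- annotate_topology(bar$model)
  expect_equal(unname(classify_long_loops(ann)),
               c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(unname(classify_long_loops(ann, override = c(1, 3, 4))),
               c(TRUE, FALSE, TRUE, TRUE))
  # a single loop is always long
  b1 <- generate_barrel(barrel_spec(n_strands = 8, strand_length = 8,
                                    loop_lengths_extracellular =
                                      c(6, 0, 0, 0)))
  ann1 <- annotate_topology(b1$model)
  expect_true(all(classify_long_loops(ann1)))
})

test_that("orientation alternates along strands and handles glycine", {
  seqs <- strrep("A", 8 * 8 + 4 * 5 + 3 * 3)
  bar <- generate_barrel(barrel_spec(n_strands = 8, strand_length = 8,
                                     loop_lengths_extracellular = 5,
                                     loop_lengths_periplasmic = 3,
                                     sequence = seqs))
  ann <- annotate_topology(bar$model)
  ori <- orient_residues(bar$model, ann)
  expect_equal(ori, bar$orientation)
  strand_res <- which(ann$label == "STRAND")
  # alternation within each strand
  for (s in 1:8) {
    lab <- ori[which(ann$strand_index == s)]
    expect_true(all(lab[-1] != lab[-length(lab)]))
  }
  # glycine gets a virtual C-beta, never an error
  gseq <- sub("A", "G", seqs)
  barg <- generate_barrel(barrel_spec(n_strands = 8, strand_length = 8,
                                      loop_lengths_extracellular = 5,
                                      loop_lengths_periplasmic = 3,
                                      sequence = gseq))
  anng <- annotate_topology(barg$model)
  orig <- orient_residues(barg$model, anng)
  expect_false(is.na(orig[1]))
})

test_that("composition statistics average structures equally", {
  b1 <- generate_barrel(barrel_spec(n_strands = 8, strand_length = 6,
                                    loop_lengths_extracellular = 2,
                                    loop_lengths_periplasmic = 1))
  b2 <- generate_barrel(barrel_spec(n_strands = 8, strand_length = 9,
                                    loop_lengths_extracellular = 4,
                                    loop_lengths_periplasmic = 2))
  a1 <- b1$annotation; a2 <- b2$annotation
  cs <- composition_stats(list(a1, a2))
  p <- function(a, lab) 100 * mean(a$label == lab)
  expect_equal(cs$pct_barrel,
               mean(c(p(a1, "STRAND"), p(a2, "STRAND"))))
  expect_equal(cs$pct_extracellular,
               mean(c(p(a1, "EXTRACELLULAR_LOOP"),
                      p(a2, "EXTRACELLULAR_LOOP"))))
  expect_equal(cs$pct_barrel + cs$pct_periplasmic + cs$pct_extracellular,
               100, tolerance = 1e-9)
  # single all-strand structure
  b0 <- generate_barrel(barrel_spec(n_strands = 8, strand_length = 8,
                                    loop_lengths_extracellular = 0,
                                    loop_lengths_periplasmic = 0))
  cs0 <- composition_stats(annotate_topology(b0$model))
  expect_equal(cs0$pct_barrel, 100)
  expect_equal(cs0$pct_extracellular, 0)
  expect_error(composition_stats(list()), class = "pe_empty_input")
})

test_that("detected axis stays within 2 degrees of the construction axis", {
  for (n in c(8, 16, 26)) {
    bar <- generate_barrel(barrel_spec(n_strands = n, strand_length = 10))
    ss <- assign_secondary_structure(bar$model)
    b <- detect_barrel(bar$model, ss)
    ang <- acos(min(abs(sum(b$axis * c(0, 0, 1))), 1)) * 180 / pi
    expect_lt(ang, 2)
  }
})
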