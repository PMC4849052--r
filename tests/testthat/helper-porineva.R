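# Fixture builders and independent oracles used across the suite.
# Everything is generated in code; no binary fixtures.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Minimal structure model from per-residue CA coordinates (one atom each).
toy_model <- function(xyz, sequence = NULL, vdw = 1.7, id = "toy") {
  n <- nrow(xyz)
  if (is.null(sequence)) sequence <- strrep("A", n)
  aa3 <- porineva:::aa_one_to_three(strsplit(sequence, "")[[1]])
  atoms <- data.frame(
    atom_name = "CA", element = "C", residue_index = seq_len(n),
    residue_name = aa3, chain_id = "A",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occ = 1, vdw = vdw, is_backbone = TRUE, orig_resno = seq_len(n),
    stringsAsFactors = FALSE)
  porineva:::new_structure_model(atoms, id, 1L, "A")
}

# Hollow cylinder of spheres: rings of `nring` atoms at radius `radius`.
cylinder_model <- function(radius = 8, vdw = 1.7, nring = 40,
                           zs = seq(-10, 10, by = 1)) {
  th <- seq(0, 2 * pi, length.out = nring + 1)[-(nring + 1)]
  g <- expand.grid(t = th, z = zs)
  toy_model(cbind(radius * cos(g$t), radius * sin(g$t), g$z),
            vdw = vdw, id = "cylinder")
}

# Idealized alpha-helix with full backbone: carbonyls point along the helix
# axis, giving the i -> i+4 hydrogen-bond pattern and no ladder.
helix_model <- function(n = 20) {
  t <- seq_len(n)
  phi <- t * 100 * pi / 180
  ca <- cbind(2.3 * cos(phi), 2.3 * sin(phi), 1.5 * t)
  rows <- lapply(seq_len(n), function(i) {
    dphi <- 100 * pi / 180
    dirv <- c(-2.3 * sin(phi[i]) * dphi, 2.3 * cos(phi[i]) * dphi, 1.5)
    dirv <- dirv / sqrt(sum(dirv^2))
    np <- ca[i, ] - 1.2 * dirv
    cp <- ca[i, ] + 1.2 * dirv
    op <- cp + 1.23 * c(0, 0, 1)
    data.frame(atom_name = c("N", "CA", "C", "O"),
               element = c("N", "C", "C", "O"),
               residue_index = i, residue_name = "ALA", chain_id = "A",
               x = c(np[1], ca[i, 1], cp[1], op[1]),
               y = c(np[2], ca[i, 2], cp[2], op[2]),
               z = c(np[3], ca[i, 3], cp[3], op[3]),
               occ = 1, vdw = 1.7,
               is_backbone = TRUE, orig_resno = i,
               stringsAsFactors = FALSE)
  })
  porineva:::new_structure_model(do.call(rbind, rows), "helix", 1L, "A")
}

# ---- plain-text structure fixtures ----------------------------------------

pdb_atom_line <- function(record, serial, name, alt, resid, chain, resno,
                          x, y, z, occ = 1, elem = substr(name, 1, 1)) {
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, paste0(" ", name), alt, resid, chain, resno,
          x, y, z, occ, 0, elem)
}

# Five-residue poly-alanine with one water and one altloc pair on the CA of
# residue 3 (occupancies 0.6/0.4).
write_cleaning_pdb <- function(path, chain = "A") {
  ln <- character(0); s <- 0
  for (i in 1:5) {
    for (at in c("N", "CA", "C", "O")) {
      if (i == 3 && at == "CA") next
      s <- s + 1
      ln <- c(ln, pdb_atom_line("ATOM", s, at, " ", "ALA", chain, i,
                                3.8 * i, 1 + s %% 2, 0))
    }
    if (i == 3) {
      ln <- c(ln, pdb_atom_line("ATOM", s + 1, "CA", "A", "ALA", chain, 3,
                                3.8 * 3, 1, 0, occ = 0.6))
      ln <- c(ln, pdb_atom_line("ATOM", s + 2, "CA", "B", "ALA", chain, 3,
                                3.8 * 3 + 0.5, 1, 0, occ = 0.4))
      s <- s + 2
    }
  }
  ln <- c(ln, pdb_atom_line("HETATM", s + 1, "O", " ", "HOH", chain, 101,
                            20, 20, 20))
  writeLines(c(ln, "END"), path)
  invisible(path)
}

# Same five residues (no water/altloc) as a minimal mmCIF.
write_cleaning_cif <- function(path) {
  hdr <- c("data_toy", "#", "loop_",
           "_atom_site.group_PDB", "_atom_site.id",
           "_atom_site.type_symbol", "_atom_site.auth_atom_id",
           "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
           "_atom_site.auth_seq_id", "_atom_site.Cartn_x",
           "_atom_site.Cartn_y", "_atom_site.Cartn_z",
           "_atom_site.occupancy", "_atom_site.pdbx_PDB_model_num")
  rows <- character(0); s <- 0
  for (i in 1:5) for (at in c("N", "CA", "C", "O")) {
    s <- s + 1
    rows <- c(rows, sprintf("ATOM %d %s %s ALA A %d %.3f %.3f %.3f 1.00 1",
                            s, substr(at, 1, 1), at, i, 3.8 * i,
                            1 + s %% 2, 0))
  }
  writeLines(c(hdr, rows, "#"), path)
  invisible(path)
}

write_multichain_pdb <- function(path, chains = c("A", "B", "C")) {
  ln <- character(0); s <- 0
  for (ch in chains) for (i in 1:3) for (at in c("N", "CA", "C", "O")) {
    s <- s + 1
    ln <- c(ln, pdb_atom_line("ATOM", s, at, " ", "GLY", ch, i,
                              3.8 * i + 10 * match(ch, chains), 0, 0))
  }
  writeLines(c(ln, "END"), path)
  invisible(path)
}

# ---- oracles ---------------------------------------------------------------

naive_entropy <- function(col) {
  r <- col[col != "-"]
  tb <- table(r) / length(r)
  -sum(tb * log(tb))
}

naive_variability <- function(col, thr = 0.005) {
  r <- col[col != "-"]
  tb <- table(r) / length(r)
  sum(tb > thr)
}

# Exhaustive fine-grid pore radius at one axial position.
brute_pore_radius <- function(model, axis, origin, z, disc_radius = 5,
                              grid = 0.02) {
  fr <- porineva:::axis_frame(axis)
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  d <- sweep(xyz, 2, origin)
  px <- as.numeric(d %*% fr$e1); py <- as.numeric(d %*% fr$e2)
  ax <- as.numeric(d %*% fr$axis)
  g <- expand.grid(dx = seq(-disc_radius, disc_radius, by = grid),
                   dy = seq(-disc_radius, disc_radius, by = grid))
  g <- g[g$dx^2 + g$dy^2 <= disc_radius^2, ]
  vdw <- model$atoms$vdw
  best <- rep(Inf, nrow(g))
  for (a in seq_along(px)) {
    cl <- sqrt((g$dx - px[a])^2 + (g$dy - py[a])^2 + (ax[a] - z)^2) - vdw[a]
    best <- pmin(best, cl)
  }
  max(best)
}

# Axis-angle rotation from a 3-vector (angle = norm).
aa_rotation <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-12) return(diag(3))
  k <- v / th
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

# Independent rigid-fit oracle: coarse axis-angle grid plus Nelder-Mead
# refinement of the superposition RMSD (translation optimal by centroids).
brute_rigid_rmsd <- function(P, Q) {
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  f <- function(v) {
    R <- aa_rotation(v)
    sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
  }
  axes <- expand.grid(x = -1:1, y = -1:1, z = -1:1)
  axes <- axes[rowSums(axes^2) > 0, ]
  best <- Inf; bv <- c(0, 0, 0)
  for (i in seq_len(nrow(axes))) {
    k <- unlist(axes[i, ]) / sqrt(sum(axes[i, ]^2))
    for (th in seq(0, 2 * pi, length.out = 37)) {
      v <- k * th
      r <- f(v)
      if (r < best) { best <- r; bv <- v }
    }
  }
  o <- stats::optim(bv, f, method = "Nelder-Mead",
                    control = list(maxit = 2000, reltol = 1e-12))
  o$value
}

# Minimal-removal redundancy filtering by exhaustive subset search.
brute_min_removals <- function(msa, max_id = 0.90) {
  n <- length(msa$ids)
  idm <- porineva:::identity_matrix(msa)
  ok <- function(keep) {
    if (length(keep) < 2) return(TRUE)
    sub <- idm[keep, keep]
    diag(sub) <- 0
    max(sub) <= max_id
  }
  for (k in 0:n) {
    drops <- utils::combn(n, k, simplify = FALSE)
    sols <- Filter(function(d) ok(setdiff(seq_len(n), d)), drops)
    if (length(sols) > 0)
      return(lapply(sols, function(d) setdiff(seq_len(n), d)))
  }
}

# Barrel + related-sequence pair for superposition tests.
related_barrels <- function(n_strands = 8, strand_length = 8, seed = 1,
                            n_mut = 6) {
  set.seed(seed)
  nres <- n_strands * strand_length + (n_strands / 2) * 5 +
    (n_strands / 2 - 1) * 3
  s1 <- sample(setdiff(AA20, "G"), nres, replace = TRUE)
  s2 <- s1
  pos <- sample(nres, n_mut)
  s2[pos] <- vapply(s2[pos], function(a) sample(setdiff(AA20, c(a, "G")), 1),
                    character(1))
  b1 <- generate_barrel(barrel_spec(n_strands = n_strands,
                                    strand_length = strand_length,
                                    loop_lengths_extracellular = 5,
                                    loop_lengths_periplasmic = 3,
                                    sequence = paste(s1, collapse = "")))
  b2 <- generate_barrel(barrel_spec(n_strands = n_strands,
                                    strand_length = strand_length,
                                    loop_lengths_extracellular = 5,
                                    loop_lengths_periplasmic = 3,
                                    sequence = paste(s2, collapse = "")))
  list(b1 = b1, b2 = b2)
}

rigid_transform_model <- function(model, v = c(0.3, 0.8, -0.5),
                                  t = c(5, -3, 10)) {
  R <- aa_rotation(v)
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")]) %*% t(R)
  model$atoms$x <- xyz[, 1] + t[1]
  model$atoms$y <- xyz[, 2] + t[2]
  model$atoms$z <- xyz[, 3] + t[3]
  model
}
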