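# Generators for idealized beta-barrels and alignments with known ground
# truth. The barrel generator places C-alpha atoms on the standard sheared
# cylindrical lattice (strand count n and shear number S fix the radius
# R = sqrt((S*a)^2 + (n*b)^2) / (2*pi) and the strand tilt), and builds the
# backbone so that the Kabsch-Sander ladder forms between adjacent strands.
# Fixtures are geometric, not thermodynamic: no energy minimisation.

#' Specification for an idealized beta-barrel
#'
#' @param n_strands Even strand count, 8..26.
#' @param shear Shear number S (even; defaults to `n_strands + 4`, the typical
#'   porin value, e.g. S = 20 for 16-stranded barrels).
#' @param strand_length Residues per strand.
#' @param loop_lengths_extracellular,loop_lengths_periplasmic Residue count
#'   per connector on each side; scalar or vector of length `n_strands/2`.
#' @param ca_rise Along-strand C-alpha spacing in Angstrom (standard 3.3).
#' @param strand_spacing Inter-strand spacing in Angstrom (standard 4.4).
#' @param constriction_loop Optional `list(index =, depth =)`: route the
#'   given extracellular loop inside the barrel at radius `depth * R`.
#' @param cb_alternation Alternate C-beta placement inward/outward along each
#'   strand (the beta-sheet pleat). If `FALSE`, all C-beta point outward.
#' @param sequence Optional 1-letter amino-acid string for the whole chain;
#'   default poly-alanine. Glycine positions get no C-beta atom.
#' @param seed Integer seed (used only when a random sequence is requested).
#' @return A `barrel_spec` list.
#' @export
barrel_spec <- function(n_strands = 16L, shear = n_strands + 4L,
                        strand_length = 10L,
                        loop_lengths_extracellular = 6L,
                        loop_lengths_periplasmic = 3L,
                        ca_rise = 3.3, strand_spacing = 4.4,
                        constriction_loop = NULL,
                        cb_alternation = TRUE,
                        sequence = NULL, seed = 1L) {
  n <- as.integer(n_strands)
  if (n < 8L || n %% 2L != 0L)
    pe_stop("n_strands must be an even integer >= 8", "pe_bad_spec")
  if (shear %% 2L != 0L || shear <= 0L)
    pe_stop("shear must be a positive even integer (seam hydrogen-bond registry)",
            "pe_bad_spec")
  nc <- n / 2L
  ext <- rep_len(as.integer(loop_lengths_extracellular), nc)
  per <- rep_len(as.integer(loop_lengths_periplasmic), nc)
  if (any(ext < 0) || any(per < 0))
    pe_stop("loop lengths must be non-negative", "pe_bad_spec")
  if (!is.null(constriction_loop)) {
    if (!is.list(constriction_loop) ||
        is.null(constriction_loop$index) || is.null(constriction_loop$depth))
      pe_stop("constriction_loop must be list(index =, depth =)", "pe_bad_spec")
    if (constriction_loop$index < 1 || constriction_loop$index > nc)
      pe_stop("constriction_loop$index out of range", "pe_bad_spec")
  }
  structure(list(
    n_strands = n, shear = as.integer(shear),
    strand_length = as.integer(strand_length),
    loop_lengths_extracellular = ext,
    loop_lengths_periplasmic = per,
    ca_rise = ca_rise, strand_spacing = strand_spacing,
    constriction_loop = constriction_loop,
    cb_alternation = isTRUE(cb_alternation),
    sequence = sequence, seed = as.integer(seed)
  ), class = "barrel_spec")
}

# Lattice position of residue row m on strand k, unrolled-and-wrapped.
barrel_lattice <- function(spec) {
  n <- spec$n_strands; S <- spec$shear
  a <- spec$ca_rise; b <- spec$strand_spacing
  C <- sqrt((S * a)^2 + (n * b)^2)
  R <- C / (2 * pi)
  pos <- function(k, m) {
    u <- (k * n * b^2 + m * S * a^2) / C
    phi <- 2 * pi * u / C
    v <- a * b * (m * n - k * S) / C
    cbind(R * cos(phi), R * sin(phi), v)
  }
  # unit tangents in 3D: along-strand (increasing m) and inter-strand
  tangent_m <- function(k, m) {
    u <- (k * n * b^2 + m * S * a^2) / C
    phi <- 2 * pi * u / C
    dphi <- 2 * pi * S * a^2 / C^2
    t3 <- c(-R * sin(phi) * dphi, R * cos(phi) * dphi, a * b * n / C)
    t3 / vnorm(t3)
  }
  tangent_k <- function(k, m) {
    u <- (k * n * b^2 + m * S * a^2) / C
    phi <- 2 * pi * u / C
    dphi <- 2 * pi * n * b^2 / C^2
    s3 <- c(-R * sin(phi) * dphi, R * cos(phi) * dphi, -a * b * S / C)
    s3 / vnorm(s3)
  }
  radial <- function(k, m) {
    u <- (k * n * b^2 + m * S * a^2) / C
    phi <- 2 * pi * u / C
    c(cos(phi), sin(phi), 0)
  }
  list(C = C, R = R, pos = pos, tangent_m = tangent_m,
       tangent_k = tangent_k, radial = radial,
       alpha = atan2(S * a, n * b))
}

# Quadratic/cubic Bezier samples (interior points only).
bezier_points <- function(ctrl, n_points) {
  t <- seq_len(n_points) / (n_points + 1)
  k <- nrow(ctrl) - 1
  out <- matrix(0, n_points, 3)
  for (i in 0:k) {
    w <- choose(k, i) * t^i * (1 - t)^(k - i)
    out <- out + outer(w, ctrl[i + 1, ])
  }
  out
}

#' Generate an idealized beta-barrel with ground-truth topology
#'
#' Builds a single-chain structure whose strand residues sit on the sheared
#' barrel lattice, with backbone N/C/O placed so that the Kabsch-Sander
#' hydrogen-bond ladder forms between adjacent strands (including the closure
#' seam), loops built as smooth arcs on the designated side, an optional
#' constriction loop routed inside the barrel, and C-beta atoms placed
#' radially with the beta-pleat alternation. Deterministic for a given spec.
#'
#' @param spec A [barrel_spec()].
#' @return A list with elements `model` (a `structure_model`), `annotation`
#'   (ground-truth `topology_annotation`), `orientation` (ground-truth
#'   INWARD/OUTWARD per residue, NA off strands) and `geometry`
#'   (list with barrel radius `R`, circumference `C`, tilt `alpha`).
#' @export
generate_barrel <- function(spec) {
  stopifnot(inherits(spec, "barrel_spec"))
  n <- spec$n_strands; S <- spec$shear; L <- spec$strand_length
  lat <- barrel_lattice(spec)
  m_off <- m_offsets(spec)

  res <- list()  # per residue: list(ca, dirs, label, strand, loop, pleat)
  add_res <- function(ca, dir, wdir, rdir, label, strand_index, loop_index,
                      pleat, o_len = 1.23) {
    res[[length(res) + 1L]] <<- list(ca = ca, dir = dir, w = wdir, r = rdir,
                                     label = label, strand = strand_index,
                                     loop = loop_index, pleat = pleat,
                                     o_len = o_len)
  }

  for (k in 0:(n - 1)) {
    rows <- m_off[k + 1] + 0:(L - 1)
    if (k %% 2 == 1) rows <- rev(rows)
    for (m in rows) {
      tm <- lat$tangent_m(k, m)
      dir <- if (k %% 2 == 0) tm else -tm
      sk <- lat$tangent_k(k, m)
      sigma <- if ((m + k) %% 2 == 0) 1 else -1
      pleat <- if (spec$cb_alternation) (if (m %% 2 == 0) 1 else -1) else 1
      ca <- drop(lat$pos(k, m))
      add_res(ca, dir, sigma * sk, lat$radial(k, m),
              "STRAND", k + 1L, NA_integer_, pleat)
    }
    if (k < n - 1) {
      extracellular <- (k %% 2 == 0)   # even strands end at the top
      conn_idx <- k %/% 2L + 1L
      nl <- if (extracellular) spec$loop_lengths_extracellular[conn_idx]
            else spec$loop_lengths_periplasmic[conn_idx]
      m_first <- m_off[k + 2] + (if ((k + 1) %% 2 == 1) L - 1 else 0)
      if (nl > 0) {
        A <- res[[length(res)]]$ca
        B <- drop(lat$pos(k + 1, m_first))
        mid <- (A + B) / 2
        phi_mid <- atan2(mid[2], mid[1])
        r_mid <- c(cos(phi_mid), sin(phi_mid), 0)
        con <- spec$constriction_loop
        side <- if (extracellular) 1 else -1
        if (extracellular && !is.null(con) && con$index == conn_idx) {
          z_mid <- a_slab_mid(spec, lat)
          pin <- con$depth * lat$R * r_mid + c(0, 0, z_mid)
          ctrl <- rbind(A, pin, pin, B)
        } else {
          bulge <- side * (3.5 + 1.1 * nl)
          ctrl <- rbind(A, mid + c(0, 0, bulge) + 2.0 * r_mid, B)
        }
        pts <- bezier_points(ctrl, nl)
        path <- rbind(A, pts, B)
        # carbonyl of the last loop residue is aimed so that the next
        # strand residue's rebuilt amide H points at its ladder partner
        sk1 <- lat$tangent_k(k + 1, m_first)
        sigma1 <- if ((m_first + k + 1) %% 2 == 0) 1 else -1
        w_entry <- -sigma1 * sk1
        for (i in seq_len(nl)) {
          p <- pts[i, ]
          dir <- unitv(path[i + 2, ] - path[i, ])
          phi <- atan2(p[2], p[1])
          rloc <- c(cos(phi), sin(phi), 0)
          lab <- if (extracellular) "EXTRACELLULAR_LOOP" else
            "PERIPLASMIC_TURN"
          # interior loop carbonyls point back at the sheet plane so the
          # rebuilt loop amide hydrogens all point away from it and cannot
          # donate into the ladder; the final loop residue's carbonyl
          # steers the next strand residue's rebuilt amide H, with a
          # near-degenerate dipole length so it cannot act as an acceptor
          wdir <- if (i == nl) w_entry else c(0, 0, -side)
          add_res(p, dir, wdir, rloc, lab, NA_integer_, conn_idx, 1,
                  o_len = if (i == nl) 0.1 else 1.23)
        }
      }
    }
  }

  N <- length(res)
  seq1 <- spec$sequence
  if (is.null(seq1)) seq1 <- strrep("A", N)
  if (nchar(seq1) != N)
    pe_stop(sprintf("sequence length %d != residue count %d",
                    nchar(seq1), N), "pe_bad_spec")
  aa1 <- strsplit(seq1, "")[[1]]
  aa3 <- aa_one_to_three(aa1)

  rows <- vector("list", N)
  for (i in seq_len(N)) {
    r <- res[[i]]
    ca <- r$ca
    npos <- ca - 1.2 * r$dir
    cpos <- ca + 1.2 * r$dir
    opos <- cpos + r$o_len * r$w
    at <- data.frame(
      atom_name = c("N", "CA", "C", "O"),
      element = c("N", "C", "C", "O"),
      x = c(npos[1], ca[1], cpos[1], opos[1]),
      y = c(npos[2], ca[2], cpos[2], opos[2]),
      z = c(npos[3], ca[3], cpos[3], opos[3]),
      stringsAsFactors = FALSE)
    if (aa3[i] != "GLY") {
      cb <- ca + 1.5 * r$pleat * r$r
      at <- rbind(at, data.frame(atom_name = "CB", element = "C",
                                 x = cb[1], y = cb[2], z = cb[3]))
    }
    at$residue_index <- i
    at$residue_name <- aa3[i]
    rows[[i]] <- at
  }
  atoms <- do.call(rbind, rows)
  vdw_table <- default_vdw_radii()
  atoms$chain_id <- "A"
  atoms$occ <- 1
  atoms$vdw <- unname(vdw_table[atoms$element])
  atoms$is_backbone <- atoms$atom_name %in% c("N", "CA", "C", "O")
  atoms$orig_resno <- atoms$residue_index
  atoms <- atoms[, c("atom_name", "element", "residue_index", "residue_name",
                     "chain_id", "x", "y", "z", "occ", "vdw", "is_backbone",
                     "orig_resno")]
  model <- new_structure_model(atoms, source_id = "synthetic_barrel",
                               model_number = 1L, chain_id = "A")

  lab <- vapply(res, function(r) r$label, character(1))
  strand_index <- as.integer(vapply(res, function(r)
    as.numeric(r$strand %||% NA), numeric(1)))
  loop_index <- as.integer(vapply(res, function(r)
    as.numeric(r$loop %||% NA), numeric(1)))
  strand_z <- vapply(res[lab == "STRAND"], function(r) r$ca[3], numeric(1))
  ann <- new_topology_annotation(
    data.frame(residue_index = seq_len(N), label = lab,
               strand_index = strand_index, loop_index = loop_index,
               stringsAsFactors = FALSE),
    strand_count = n, axis = c(0, 0, 1), origin = c(0, 0, mean(strand_z)),
    slab = stats::quantile(strand_z, c(0.05, 0.95), names = FALSE),
    extracellular_sign = 1, source_id = "synthetic_barrel")
  orientation <- ifelse(lab == "STRAND",
                        ifelse(vapply(res, function(r) r$pleat, numeric(1)) < 0,
                               "INWARD", "OUTWARD"), NA_character_)
  list(model = model, annotation = ann, orientation = orientation,
       geometry = list(R = lat$R, C = lat$C, alpha = lat$alpha),
       spec = spec)
}

# Per-strand starting lattice row. The mean slope S/n distributes the shear;
# the parity adjustment makes each strand's bottom row hydrogen-bond to the
# preceding strand and its top row to the following one, so that (for even
# strand lengths) every strand residue has a ladder partner.
m_offsets <- function(spec) {
  n <- spec$n_strands; S <- spec$shear
  m_off <- round((0:(n - 1)) * S / n)
  k <- 0:(n - 1)
  m_off + ifelse((m_off + k) %% 2 == 0, 1L, 0L)
}

# Axial midpoint of the strand slab for a spec (used to park the
# constriction loop inside the barrel).
a_slab_mid <- function(spec, lat) {
  n <- spec$n_strands; S <- spec$shear; L <- spec$strand_length
  a <- spec$ca_rise; b <- spec$strand_spacing
  m_off <- m_offsets(spec)
  v <- function(k, m) a * b * (m * n - k * S) / lat$C
  zs <- unlist(lapply(0:(n - 1), function(k)
    v(k, m_off[k + 1] + c(0, L - 1))))
  mean(range(zs))
}

#' Per-column conservation profile for the MSA generator
#'
#' Each column draws residues independently: the dominant residue with
#' probability `p_dominant`, a gap with probability `gap_rate`, and the
#' remaining mass split equally over `alternatives`.
#'
#' @param dominant Character vector of dominant residues (one per column).
#' @param p_dominant Numeric vector of dominant-residue probabilities.
#' @param alternatives List of character vectors of alternative residues.
#' @param gap_rate Numeric vector of per-column gap probabilities.
#' @param n_sequences Number of sequences to draw.
#' @param seed Integer seed.
#' @return A `conservation_profile` data frame with attributes
#'   `n_sequences` and `seed`.
#' @export
conservation_profile <- function(dominant, p_dominant, alternatives,
                                 gap_rate = 0, n_sequences = 100L,
                                 seed = 1L) {
  nc <- length(dominant)
  p_dominant <- rep_len(p_dominant, nc)
  gap_rate <- rep_len(gap_rate, nc)
  if (!is.list(alternatives)) alternatives <- rep(list(alternatives), nc)
  alternatives <- rep_len(alternatives, nc)
  if (any(p_dominant + gap_rate > 1 + 1e-12))
    pe_stop("p_dominant + gap_rate must not exceed 1", "pe_bad_spec")
  bad <- mapply(function(d, al) d %in% al, dominant, alternatives)
  if (any(bad))
    pe_stop("dominant residue must not appear among alternatives",
            "pe_bad_spec")
  structure(data.frame(dominant = dominant, p_dominant = p_dominant,
                       gap_rate = gap_rate, stringsAsFactors = FALSE,
                       row.names = NULL),
            alternatives = alternatives,
            n_sequences = as.integer(n_sequences),
            seed = as.integer(seed),
            class = c("conservation_profile", "data.frame"))
}

# Analytic per-column frequencies implied by a profile row (non-gap
# normalised), as a named vector.
profile_freqs <- function(profile, i) {
  alts <- attr(profile, "alternatives")[[i]]
  p <- profile$p_dominant[i]; g <- profile$gap_rate[i]
  rest <- (1 - p - g) / max(length(alts), 1)
  f <- c(stats::setNames(p, profile$dominant[i]),
         stats::setNames(rep(rest, length(alts)), alts))
  f <- f[f > 0]
  f / sum(f)
}

#' Generate an alignment from a conservation profile
#'
#' Sequences are drawn column-independently (no phylogenetic correlation; a
#' documented limitation matched to the column-independent entropy model).
#' The analytic entropy, variability and box label implied by the profile are
#' attached as the `"truth"` attribute. Byte-identical for a given seed.
#'
#' @param profile A [conservation_profile()].
#' @param scheme Box scheme used for the ground-truth labels
#'   ([ev_scheme()] default).
#' @return An `msa` object with attribute `truth` (data frame with columns
#'   `column`, `entropy`, `variability`, `box`).
#' @export
generate_msa <- function(profile, scheme = ev_scheme()) {
  stopifnot(inherits(profile, "conservation_profile"))
  nseq <- attr(profile, "n_sequences")
  nc <- nrow(profile)
  set.seed(attr(profile, "seed"))
  cols <- matrix("-", nseq, nc)
  for (i in seq_len(nc)) {
    alts <- attr(profile, "alternatives")[[i]]
    p <- profile$p_dominant[i]; g <- profile$gap_rate[i]
    rest <- if (length(alts)) (1 - p - g) / length(alts) else 0
    cols[, i] <- sample(c(profile$dominant[i], alts, "-"),
                        nseq, replace = TRUE,
                        prob = c(p, rep(rest, length(alts)), g))
  }
  seqs <- apply(cols, 1, paste, collapse = "")
  ids <- sprintf("seq%04d", seq_len(nseq))
  truth <- data.frame(
    column = seq_len(nc),
    entropy = vapply(seq_len(nc), function(i) {
      f <- profile_freqs(profile, i); -sum(f * log(f))
    }, numeric(1)),
    variability = vapply(seq_len(nc), function(i)
      sum(profile_freqs(profile, i) > 0.005), integer(1)))
  truth$box <- classify_box(truth$entropy, truth$variability, scheme)
  m <- new_msa(ids, seqs)
  attr(m, "truth") <- truth
  m
}

#' Tiered conservation profile targeting each conservation box
#'
#' Convenience constructor: builds columns whose analytic entropy and
#' variability fall squarely inside each requested box of the default scheme.
#'
#' @param boxes Character vector of box labels from
#'   `c("11","12","22","23","33")` (recycled over `n_columns`).
#' @param n_columns Total number of columns.
#' @param n_sequences Sequences to draw.
#' @param gap_rate Per-column gap probability.
#' @param seed Integer seed.
#' @return A [conservation_profile()].
#' @export
tiered_conservation_profile <- function(boxes = c("11", "12", "22", "23", "33"),
                                        n_columns = length(boxes),
                                        n_sequences = 500L, gap_rate = 0,
                                        seed = 1L) {
  boxes <- rep_len(boxes, n_columns)
  aa <- .AA1
  tier <- function(box) {
    switch(box,
      "11" = list(p = 1.00, k = 0),
      "12" = list(p = 0.40, k = 3),    # V=4, E ~ 1.33 nats
      "22" = list(p = 0.50, k = 5),    # V=6, E ~ 1.50 nats
      "23" = list(p = 0.10, k = 9),    # V=10, E ~ ln 10
      "33" = list(p = 0.0625, k = 15), # V=16, E ~ ln 16
      pe_stop(sprintf("unknown box '%s'", box), "pe_bad_spec"))
  }
  dominant <- character(n_columns)
  alts <- vector("list", n_columns)
  pdom <- numeric(n_columns)
  for (i in seq_len(n_columns)) {
    tr <- tier(boxes[i])
    dominant[i] <- aa[1 + (i - 1) %% 20]
    pool <- setdiff(aa, dominant[i])
    alts[[i]] <- pool[seq_len(tr$k)]
    pdom[i] <- tr$p * (1 - gap_rate)
  }
  prof <- conservation_profile(dominant, pdom, alts, gap_rate,
                               n_sequences, seed)
  attr(prof, "target_box") <- boxes
  prof
}

#' Generate a full study fixture: barrel, reference sequence and MSA
#'
#' Builds a barrel, a matching reference sequence, and an MSA whose strongly
#' conserved columns are planted at configured structural positions (inward
#' strand faces, long loops, or the constriction loop), enabling end-to-end
#' pipeline assertions with known ground truth.
#'
#' @param conserved_at One of `"inward"`, `"long_loops"`, `"constriction"`.
#' @param n_strands,strand_length,loop_ext,loop_peri Barrel layout.
#' @param n_sequences MSA depth.
#' @param gap_rate Per-column gap probability.
#' @param seed Integer seed.
#' @return List with `model`, `annotation`, `orientation` (ground truth),
#'   `msa`, `reference_id`, `target_residues` (planted conserved residue
#'   indices) and `geometry`.
#' @export
generate_study_fixture <- function(conserved_at = c("inward", "long_loops",
                                                    "constriction"),
                                   n_strands = 8L, strand_length = 8L,
                                   loop_ext = 5L, loop_peri = 3L,
                                   n_sequences = 200L, gap_rate = 0.02,
                                   seed = 1L) {
  conserved_at <- match.arg(conserved_at)
  set.seed(seed)
  con <- if (conserved_at == "constriction")
    list(index = 1L, depth = 0.3) else NULL
  ext <- rep_len(loop_ext, n_strands / 2)
  if (conserved_at == "long_loops") ext[1] <- 4L * max(loop_ext, 3L)
  sp0 <- barrel_spec(n_strands = n_strands, strand_length = strand_length,
                     loop_lengths_extracellular = ext,
                     loop_lengths_periplasmic = loop_peri,
                     constriction_loop = con, seed = seed)
  nres <- n_strands * strand_length + sum(ext) +
    (n_strands / 2 - 1) * loop_peri
  refseq <- paste(sample(setdiff(.AA1, "G"), nres, replace = TRUE),
                  collapse = "")
  sp <- barrel_spec(n_strands = n_strands, strand_length = strand_length,
                    loop_lengths_extracellular = ext,
                    loop_lengths_periplasmic = loop_peri,
                    constriction_loop = con, sequence = refseq, seed = seed)
  bar <- generate_barrel(sp)
  ann_df <- as.data.frame(bar$annotation)
  target <- switch(conserved_at,
    inward = which(!is.na(bar$orientation) & bar$orientation == "INWARD"),
    long_loops = which(ann_df$label == "EXTRACELLULAR_LOOP" &
                       ann_df$loop_index == 1L),
    constriction = which(ann_df$label == "EXTRACELLULAR_LOOP" &
                         ann_df$loop_index == 1L))
  aa1 <- strsplit(refseq, "")[[1]]
  pdom <- rep(0.10, nres)
  alts <- vector("list", nres)
  for (i in seq_len(nres)) {
    pool <- setdiff(.AA1, aa1[i])
    alts[[i]] <- pool[1:14]
  }
  pdom[target] <- 0.98 - gap_rate
  for (i in target) alts[[i]] <- setdiff(.AA1, aa1[i])[1:3]
  pdom[-target] <- 0.10 * (1 - gap_rate)
  prof <- conservation_profile(aa1, pdom, alts, gap_rate,
                               n_sequences - 1L, seed = seed + 1L)
  m <- generate_msa(prof)
  m <- new_msa(c("REF", m$ids), c(refseq, m$seqs))
  list(model = bar$model, annotation = bar$annotation,
       orientation = bar$orientation, msa = m, reference_id = "REF",
       target_residues = target, geometry = bar$geometry)
}
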