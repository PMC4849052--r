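# Beta-barrel topology: secondary-structure assignment (Kabsch-Sander style
# backbone hydrogen bonds), barrel detection, region classification
# (strand / periplasmic turn / extracellular loop), core extraction,
# constriction- and long-loop detection, residue orientation, and
# composition statistics.

new_topology_annotation <- function(df, strand_count, axis, origin, slab,
                                    extracellular_sign, source_id,
                                    constriction_loop_index = NA_integer_) {
  stopifnot(all(c("residue_index", "label", "strand_index", "loop_index")
                %in% names(df)))
  structure(df,
            strand_count = as.integer(strand_count),
            axis = axis, origin = origin, slab = slab,
            extracellular_sign = extracellular_sign,
            constriction_loop_index = constriction_loop_index,
            source_id = source_id,
            class = c("topology_annotation", "data.frame"))
}

#' @export
print.topology_annotation <- function(x, ...) {
  tb <- table(x$label)
  cat(sprintf("<topology_annotation> %s: %d strands, %d residues\n",
              attr(x, "source_id"), attr(x, "strand_count"), nrow(x)))
  cat("  ", paste(sprintf("%s=%d", names(tb), tb), collapse = "  "), "\n")
  invisible(x)
}

#' Kabsch-Sander style secondary-structure assignment
#'
#' Labels a residue `E` when it takes part in a backbone hydrogen-bond ladder
#' (two or more consecutive parallel or antiparallel bridges) with a
#' neighbouring strand. Hydrogen-bond energies use the classic electrostatic
#' model with the amide hydrogen rebuilt from the preceding carbonyl; a bond
#' exists when the energy falls below `cutoff`.
#'
#' @param model A `structure_model`.
#' @param cutoff Hydrogen-bond energy cutoff in kcal/mol (default -0.5).
#' @return Character vector per residue, `"E"` or `"-"`. Residues with
#'   missing backbone atoms are labelled `"-"` with a warning. The attribute
#'   `"bridges"` holds a two-column matrix of bridged residue pairs.
#' @export
assign_secondary_structure <- function(model, cutoff = -0.5) {
  n <- n_residues(model)
  Nc <- atom_coords(model, "N")
  CAc <- atom_coords(model, "CA")
  Cc <- atom_coords(model, "C")
  Oc <- atom_coords(model, "O")
  have <- stats::complete.cases(Nc) & stats::complete.cases(CAc) &
    stats::complete.cases(Cc) & stats::complete.cases(Oc)
  if (any(!have))
    warning(sprintf("%d residue(s) missing backbone atoms; labelled '-'",
                    sum(!have)))
  ss <- rep("-", n)
  if (sum(have) < 4) {
    attr(ss, "bridges") <- matrix(integer(0), 0, 2)
    return(ss)
  }
  # rebuilt amide hydrogen: H_i = N_i + unit(C_{i-1} - O_{i-1})
  H <- matrix(NA_real_, n, 3)
  for (i in 2:n) {
    if (have[i] && have[i - 1]) {
      d <- Cc[i - 1, ] - Oc[i - 1, ]
      nd <- vnorm(d)
      if (nd > 1e-6) H[i, ] <- Nc[i, ] + d / nd
    }
  }
  can_donate <- stats::complete.cases(H)

  dm2 <- function(A, B) {
    outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  }
  ca_close <- dm2(CAc, CAc) < 81  # 9 A screen
  q <- 0.084 * 332
  dON <- sqrt(pmax(dm2(Oc, Nc), 1e-12))
  dCN <- sqrt(pmax(dm2(Cc, Nc), 1e-12))
  dOH <- sqrt(pmax(dm2(Oc, H), 1e-12))
  dCH <- sqrt(pmax(dm2(Cc, H), 1e-12))
  # energy[j, i]: donor N-H of i, acceptor C=O of j
  E <- q * (1 / dON + 1 / dCH - 1 / dOH - 1 / dCN)
  hb <- matrix(FALSE, n, n)  # hb[i, j]: N-H of i donates to C=O of j
  for (i in seq_len(n)) {
    if (!can_donate[i]) next
    js <- which(have & ca_close[, i] & abs(seq_len(n) - i) >= 2)
    js <- js[E[js, i] < cutoff]
    hb[i, js] <- TRUE
  }

  hbond <- function(i, j) {
    i >= 1 && j >= 1 && i <= n && j <= n && hb[i, j]
  }
  bridges <- list()
  btype <- character(0)
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      par <- (hbond(i - 1, j) && hbond(j, i + 1)) ||
             (hbond(j - 1, i) && hbond(i, j + 1))
      anti <- (hbond(i, j) && hbond(j, i)) ||
              (hbond(i - 1, j + 1) && hbond(j - 1, i + 1))
      if (par || anti) {
        bridges[[length(bridges) + 1L]] <- c(i, j)
        btype <- c(btype, if (anti) "A" else "P")
      }
    }
  }
  bm <- if (length(bridges)) do.call(rbind, bridges) else
    matrix(integer(0), 0, 2)
  # ladders: two or more consecutive bridges of the same type
  in_ladder <- rep(FALSE, n)
  if (nrow(bm) > 0) {
    key <- paste(bm[, 1], bm[, 2], btype)
    has <- function(i, j, ty) paste(i, j, ty) %in% key
    for (r in seq_len(nrow(bm))) {
      i <- bm[r, 1]; j <- bm[r, 2]; ty <- btype[r]
      ext <- if (ty == "P")
        has(i + 1, j + 1, ty) || has(i - 1, j - 1, ty)
      else
        has(i + 1, j - 1, ty) || has(i - 1, j + 1, ty)
      if (ext) in_ladder[c(i, j)] <- TRUE
    }
  }
  ss[in_ladder] <- "E"
  # conservative strand extension: a residue fully flanked by ladder
  # residues (both chain neighbours, or the single neighbour at a chain
  # terminus) that shares a backbone hydrogen bond with a ladder residue is
  # absorbed into the strand. This covers beta-bulge interiors and the
  # chain-initial residue, whose amide hydrogen cannot be rebuilt.
  lad <- ss == "E"
  prev_ok <- c(TRUE, lad[-n])   # treat missing neighbours as satisfied
  next_ok <- c(lad[-1], TRUE)
  has_e_nb <- c(FALSE, lad[-n]) | c(lad[-1], FALSE)
  cand <- which(!lad & have & prev_ok & next_ok & has_e_nb)
  for (i in cand) {
    ps <- unique(c(which(hb[i, ]), which(hb[, i]),
                   bm[bm[, 1] == i, 2], bm[bm[, 2] == i, 1]))
    if (any(lad[ps] & abs(ps - i) >= 2)) ss[i] <- "E"
  }
  ss[!have] <- "-"  # incomplete backbone cannot be assigned
  attr(ss, "bridges") <- bm
  hp <- which(hb, arr.ind = TRUE)
  attr(ss, "hbonds") <- hp[abs(hp[, 1] - hp[, 2]) >= 2, , drop = FALSE]
  ss
}

#' Detect the closed beta-barrel
#'
#' Strands are maximal runs of `E` (bridging interruptions up to `gap_tol`
#' residues); they are grouped into the closed barrel by circular adjacency
#' (each strand hydrogen-bonded to exactly two neighbours). The barrel axis
#' is the principal axis of strand C-alpha coordinates (the eigenvector best
#' aligned with the mean strand direction), and the membrane slab is the
#' axial 5th-95th percentile span of strand C-alpha positions.
#'
#' @param model A `structure_model`.
#' @param ss Secondary-structure labels from [assign_secondary_structure()].
#' @param gap_tol Strand-run interruption tolerance in residues (default 1,
#'   bridging beta-bulges).
#' @param slab_percentiles Axial percentile range defining the membrane slab.
#' @param min_bridges Minimum inter-strand bridge count for adjacency.
#' @return List with `strand_count`, `strands` (list of residue-index
#'   vectors in chain order), `residue_strand` (per-residue strand id or NA),
#'   `axis`, `origin`, `slab`.
#' @export
detect_barrel <- function(model, ss, gap_tol = 1L,
                          slab_percentiles = c(0.05, 0.95),
                          min_bridges = 2L) {
  n <- n_residues(model)
  if (sum(ss == "E") < 8)
    pe_stop("not a barrel: fewer than 8 strand residues", "pe_not_barrel")
  e <- ss == "E"
  # merge runs separated by <= gap_tol non-E residues
  runs <- rle(e)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  idx <- which(runs$values)
  merged <- list()
  cur <- NULL
  for (r in idx) {
    seg <- c(starts[r], ends[r])
    if (is.null(cur)) cur <- seg
    else if (seg[1] - cur[2] - 1 <= gap_tol) cur[2] <- seg[2]
    else { merged[[length(merged) + 1L]] <- cur; cur <- seg }
  }
  if (!is.null(cur)) merged[[length(merged) + 1L]] <- cur
  merged <- Filter(function(s) s[2] - s[1] + 1 >= 3, merged)
  if (length(merged) < 1)
    pe_stop("not a barrel: no strand runs", "pe_not_barrel")
  strands <- lapply(merged, function(s) seq(s[1], s[2]))

  # split runs at axial direction reversals: barrel strands alternate
  # up/down, and direct strand-to-strand junctions (very short or absent
  # connectors) can fuse into one run
  CAc <- atom_coords(model, "CA")
  ecas <- CAc[unlist(strands), , drop = FALSE]
  ecas <- ecas[stats::complete.cases(ecas), , drop = FALSE]
  ev0 <- eigen(stats::cov(ecas), symmetric = TRUE)
  # provisional axis: the principal direction with the largest mean
  # absolute per-residue step component within runs (strand steps run
  # dominantly along the barrel axis; tangential components cancel)
  step_score <- vapply(1:3, function(k) {
    v <- ev0$vectors[, k]
    mean(unlist(lapply(strands, function(run) {
      if (length(run) < 2) return(numeric(0))
      abs(diff(as.numeric(CAc[run, , drop = FALSE] %*% v)))
    })), na.rm = TRUE)
  }, numeric(1))
  prov_axis <- ev0$vectors[, which.max(step_score)]
  axc <- as.numeric(CAc %*% prov_axis)
  split_run <- function(run) {
    if (length(run) < 6) return(list(run))
    st <- diff(axc[run])
    sg <- sign(st) * (abs(st) > 1.0)
    pieces <- list(); cur <- run[1]; cur_sign <- 0
    for (i in seq_along(st)) {
      s <- sg[i]
      if (s != 0 && cur_sign != 0 && s != cur_sign) {
        pieces[[length(pieces) + 1L]] <- seq(cur, run[i])
        cur <- run[i + 1]; cur_sign <- s
      } else {
        if (s != 0 && cur_sign == 0) cur_sign <- s
      }
    }
    pieces[[length(pieces) + 1L]] <- seq(cur, run[length(run)])
    pieces
  }
  strands <- unlist(lapply(strands, split_run), recursive = FALSE)
  strands <- Filter(function(s) length(s) >= 3, strands)
  if (length(strands) < 3)
    pe_stop("not a barrel: fewer than 3 strands", "pe_not_barrel")
  residue_strand <- rep(NA_integer_, n)
  for (s in seq_along(strands)) residue_strand[strands[[s]]] <- s

  # strand adjacency from ladder bridges plus raw backbone hydrogen bonds
  # (the latter keep the graph dense at junctions, where near pairs fall
  # below the bridge chain-distance rule)
  bm <- rbind(attr(ss, "bridges"),
              unname(attr(ss, "hbonds") %||% matrix(integer(0), 0, 2)))
  if (is.null(bm) || nrow(bm) == 0)
    pe_stop("not a barrel: no bridges recorded", "pe_not_barrel")
  s1 <- residue_strand[bm[, 1]]
  s2 <- residue_strand[bm[, 2]]
  ok <- !is.na(s1) & !is.na(s2) & s1 != s2
  pair_key <- paste(pmin(s1[ok], s2[ok]), pmax(s1[ok], s2[ok]))
  cnt <- table(pair_key)
  ns <- length(strands)
  adj <- matrix(0L, ns, ns)
  for (p in names(cnt)) {
    ij <- as.integer(strsplit(p, " ")[[1]])
    adj[ij[1], ij[2]] <- adj[ij[2], ij[1]] <- as.integer(cnt[[p]])
  }
  A <- adj >= min_bridges
  # keep each strand's two strongest partners, require mutual agreement
  keep <- matrix(FALSE, ns, ns)
  for (i in seq_len(ns)) {
    nb <- which(A[i, ])
    if (length(nb) > 2) nb <- nb[order(-adj[i, nb])][1:2]
    keep[i, nb] <- TRUE
  }
  A <- keep & t(keep)
  deg <- rowSums(A)
  if (any(deg != 2))
    pe_stop("not a barrel: strand adjacency is not a closed cycle",
            "pe_not_barrel")
  # walk the cycle
  visited <- 1L; prev <- 0L; cur <- 1L
  repeat {
    nb <- which(A[cur, ])
    nxt <- nb[nb != prev][1]
    if (nxt == 1L) break
    visited <- c(visited, nxt)
    prev <- cur; cur <- nxt
    if (length(visited) > ns) break
  }
  if (length(visited) != ns)
    pe_stop("not a barrel: strand adjacency is not a single closed cycle",
            "pe_not_barrel")

  CAc <- atom_coords(model, "CA")
  sca <- CAc[unlist(strands), , drop = FALSE]
  sca <- sca[stats::complete.cases(sca), , drop = FALSE]
  origin <- colMeans(sca)
  ev <- eigen(stats::cov(sca), symmetric = TRUE)
  # mean strand direction (sign-aligned) picks the physical axis among the
  # principal directions
  dirs <- t(vapply(strands, function(s) {
    p <- CAc[s, , drop = FALSE]
    p <- p[stats::complete.cases(p), , drop = FALSE]
    d <- p[nrow(p), ] - p[1, ]
    d / max(vnorm(d), 1e-9)
  }, numeric(3)))
  ref <- dirs[1, ]
  flip <- sign(dirs %*% ref)
  mdir <- colMeans(dirs * as.numeric(flip))
  scores <- abs(t(ev$vectors) %*% mdir)
  axis <- ev$vectors[, which.max(scores)]
  if (sum(axis * mdir) < 0) axis <- -axis
  axis <- unitv(axis)
  ax <- axial_coord(sca, axis, origin)
  slab <- stats::quantile(ax, slab_percentiles, names = FALSE)
  list(strand_count = ns, strands = strands,
       residue_strand = residue_strand,
       axis = axis, origin = origin, slab = slab)
}

#' Partition residues into strands, periplasmic turns and extracellular loops
#'
#' Non-strand residues are assigned to the connector joining consecutive
#' strands; a connector's side is the sign of its mean axial coordinate
#' relative to the slab midplane. The extracellular side is the side whose
#' connectors have the greater mean length (porins have short periplasmic
#' turns and longer extracellular loops) unless overridden. Terminal tails
#' are counted with the side they exit.
#'
#' @param model A `structure_model`.
#' @param barrel Output of [detect_barrel()].
#' @param extracellular_sign Optional override: `+1` or `-1` along the axis.
#' @return A `topology_annotation`.
#' @export
classify_regions <- function(model, barrel, extracellular_sign = NULL) {
  n <- n_residues(model)
  CAc <- atom_coords(model, "CA")
  ax <- axial_coord(CAc, barrel$axis, barrel$origin)
  mid <- mean(barrel$slab)
  rs <- barrel$residue_strand
  label <- ifelse(!is.na(rs), "STRAND", NA_character_)

  # connectors between consecutive strand runs + terminal tails
  strand_spans <- t(vapply(barrel$strands, range, numeric(2)))
  ord <- order(strand_spans[, 1])
  spans <- strand_spans[ord, , drop = FALSE]
  segs <- list()
  if (spans[1, 1] > 1)
    segs[[length(segs) + 1L]] <- list(res = 1:(spans[1, 1] - 1), tail = TRUE)
  if (nrow(spans) > 1) {
    for (i in 1:(nrow(spans) - 1)) {
      a <- spans[i, 2] + 1; b <- spans[i + 1, 1] - 1
      if (b >= a)
        segs[[length(segs) + 1L]] <- list(res = a:b, tail = FALSE)
    }
  }
  if (spans[nrow(spans), 2] < n)
    segs[[length(segs) + 1L]] <- list(res = (spans[nrow(spans), 2] + 1):n,
                                      tail = TRUE)
  side <- vapply(segs, function(s)
    sign(mean(ax[s$res], na.rm = TRUE) - mid), numeric(1))
  side[side == 0] <- 1
  lens <- vapply(segs, function(s) length(s$res), numeric(1))
  tails <- vapply(segs, function(s) s$tail, logical(1))
  if (is.null(extracellular_sign)) {
    mean_len <- function(sg) if (any(side == sg & !tails))
      mean(lens[side == sg & !tails]) else -Inf
    extracellular_sign <- if (mean_len(1) >= mean_len(-1)) 1 else -1
  }
  loop_counter <- c(`1` = 0L, `-1` = 0L)
  loop_index <- rep(NA_integer_, n)
  for (i in seq_along(segs)) {
    sgn <- side[i]
    lab <- if (sgn == extracellular_sign) "EXTRACELLULAR_LOOP"
           else "PERIPLASMIC_TURN"
    key <- as.character(sgn)
    loop_counter[key] <- loop_counter[key] + 1L
    label[segs[[i]]$res] <- lab
    loop_index[segs[[i]]$res] <- loop_counter[key]
  }
  df <- data.frame(residue_index = seq_len(n), label = label,
                   strand_index = rs, loop_index = loop_index,
                   stringsAsFactors = FALSE)
  ann <- new_topology_annotation(df, barrel$strand_count, barrel$axis,
                                 barrel$origin, barrel$slab,
                                 extracellular_sign, model$source_id)
  attr(ann, "tail_residues") <- unlist(lapply(segs[tails],
                                              function(s) s$res))
  ann
}

#' Extract the barrel core (strand residues only)
#'
#' @param model A `structure_model`.
#' @param annotation A `topology_annotation` for `model`.
#' @return A `structure_model` holding only STRAND residues, order and
#'   original residue indices preserved; its sequence is the concatenation of
#'   the strand segments. The matching all-strand annotation is attached as
#'   attribute `"core_annotation"`.
#' @export
extract_core <- function(model, annotation) {
  stopifnot(nrow(annotation) == n_residues(model))
  keep <- annotation$residue_index[annotation$label == "STRAND"]
  if (length(keep) == 0)
    pe_stop("empty core: no strand residues", "pe_empty_structure")
  atoms <- model$atoms[model$atoms$residue_index %in% keep, , drop = FALSE]
  old <- sort(unique(atoms$residue_index))
  atoms$orig_resno <- atoms$residue_index
  atoms$residue_index <- match(atoms$residue_index, old)
  core <- new_structure_model(atoms, paste0(model$source_id, "_core"),
                              model$model_number, model$chain_id)
  sub <- annotation[annotation$label == "STRAND", , drop = FALSE]
  core_ann <- new_topology_annotation(
    data.frame(residue_index = seq_along(old), label = "STRAND",
               strand_index = sub$strand_index,
               loop_index = NA_integer_, stringsAsFactors = FALSE),
    attr(annotation, "strand_count"), attr(annotation, "axis"),
    attr(annotation, "origin"), attr(annotation, "slab"),
    attr(annotation, "extracellular_sign"),
    paste0(attr(annotation, "source_id"), "_core"))
  attr(core, "core_annotation") <- core_ann
  core
}

#' Detect the constriction loop
#'
#' Returns the extracellular loop maximising the fraction of its C-alpha
#' atoms lying radially inside the barrel wall (distance to the axis below
#' the mean strand radius minus `margin`), provided that fraction exceeds
#' `threshold`; otherwise `NA`. In substrate-specific channels this is
#' usually loop L3, folded inside the barrel where it narrows the pore.
#'
#' @param model A `structure_model`.
#' @param annotation A `topology_annotation`.
#' @param margin Radial margin in Angstrom (default 1.0).
#' @param threshold Minimum inside fraction (default 0.5).
#' @return Extracellular loop index or `NA`; per-loop inside fractions are
#'   attached as attribute `"inside_fraction"`.
#' @export
detect_constriction_loop <- function(model, annotation, margin = 1.0,
                                     threshold = 0.5) {
  CAc <- atom_coords(model, "CA")
  axis <- attr(annotation, "axis"); origin <- attr(annotation, "origin")
  rad <- radial_dist(CAc, axis, origin)
  strand_r <- mean(rad[annotation$label == "STRAND"], na.rm = TRUE)
  el <- annotation$label == "EXTRACELLULAR_LOOP"
  if (!any(el)) pe_stop("no extracellular loops", "pe_no_loops")
  loops <- sort(unique(annotation$loop_index[el]))
  frac <- vapply(loops, function(l) {
    r <- rad[el & annotation$loop_index == l]
    mean(r < strand_r - margin, na.rm = TRUE)
  }, numeric(1))
  names(frac) <- loops
  best <- loops[which.max(frac)]
  out <- if (max(frac) > threshold) best else NA_integer_
  attr(out, "inside_fraction") <- frac
  out
}

#' Flag long extracellular loops
#'
#' A loop is long when its residue count exceeds 15% of the structure's total
#' extracellular-loop residue count. A per-subclass override (a vector of
#' loop indices to flag regardless, as used for the petite-porin class where
#' three of the four loops are treated as long) is honoured when supplied.
#'
#' @param annotation A `topology_annotation`.
#' @param fraction Length threshold as a fraction of the total (default 0.15).
#' @param override Optional integer vector of loop indices to flag as long
#'   (all others flagged short).
#' @return Named logical vector, one entry per extracellular loop.
#' @export
classify_long_loops <- function(annotation, fraction = 0.15,
                                override = NULL) {
  el <- annotation$label == "EXTRACELLULAR_LOOP"
  if (!any(el)) pe_stop("no extracellular loops", "pe_no_loops")
  lens <- table(annotation$loop_index[el])
  loops <- as.integer(names(lens))
  if (!is.null(override)) {
    out <- loops %in% override
  } else {
    out <- as.numeric(lens) > fraction * sum(lens)
  }
  stats::setNames(out, names(lens))
}

#' Label strand residues inward (pore-facing) or outward (lipid-facing)
#'
#' A strand residue is INWARD when its C-alpha to C-beta vector has a
#' negative component along the outward radial direction at that residue.
#' Glycine uses an idealized virtual C-beta rebuilt from backbone geometry,
#' as does any residue whose C-beta is missing.
#'
#' @param model A `structure_model`.
#' @param annotation A `topology_annotation`.
#' @return Character vector per residue: `"INWARD"`/`"OUTWARD"` for strand
#'   residues, `NA` elsewhere.
#' @export
orient_residues <- function(model, annotation) {
  n <- n_residues(model)
  CAc <- atom_coords(model, "CA")
  CBc <- atom_coords(model, "CB")
  Nc <- atom_coords(model, "N")
  Cc <- atom_coords(model, "C")
  axis <- attr(annotation, "axis"); origin <- attr(annotation, "origin")
  out <- rep(NA_character_, n)
  for (i in which(annotation$label == "STRAND")) {
    if (!all(is.finite(CAc[i, ])))
      pe_stop(sprintf("residue %d: missing CA", i), "pe_missing_atom")
    cb <- CBc[i, ]
    if (!all(is.finite(cb))) cb <- virtual_cb(Nc[i, ], CAc[i, ], Cc[i, ])
    d <- CAc[i, ] - origin
    axc <- sum(d * axis)
    rvec <- d - axc * axis
    nr <- vnorm(rvec)
    if (nr < 1e-9) { out[i] <- "OUTWARD"; next }
    out[i] <- if (sum((cb - CAc[i, ]) * (rvec / nr)) < 0) "INWARD"
              else "OUTWARD"
  }
  out
}

# Idealized virtual C-beta from backbone N, CA, C.
virtual_cb <- function(n, ca, c) {
  if (!all(is.finite(c(n, ca, c))))
    pe_stop("cannot build virtual C-beta: missing backbone atoms",
            "pe_missing_atom")
  b <- ca - n
  cc <- c - ca
  a <- c(b[2] * cc[3] - b[3] * cc[2],
         b[3] * cc[1] - b[1] * cc[3],
         b[1] * cc[2] - b[2] * cc[1])
  -0.58273431 * a + 0.56802827 * b - 0.54067466 * cc + ca
}

#' Secondary-structure composition statistics
#'
#' Mean percentages of residues in strands, periplasmic turns and
#' extracellular loops, plus mean chain length, each structure weighted
#' equally (set `weight = "residue"` to pool residues instead).
#'
#' @param annotations A `topology_annotation` or list of them.
#' @param weight `"structure"` (default) or `"residue"`.
#' @return A `composition_stats` list with `pct_barrel`, `pct_periplasmic`,
#'   `pct_extracellular`, `mean_length`, `n_structures`.
#' @export
composition_stats <- function(annotations, weight = c("structure",
                                                      "residue")) {
  weight <- match.arg(weight)
  if (inherits(annotations, "topology_annotation"))
    annotations <- list(annotations)
  if (length(annotations) == 0)
    pe_stop("no annotations supplied", "pe_empty_input")
  per <- t(vapply(annotations, function(a) {
    n <- nrow(a)
    c(strand = sum(a$label == "STRAND"),
      peri = sum(a$label == "PERIPLASMIC_TURN"),
      extra = sum(a$label == "EXTRACELLULAR_LOOP"),
      n = n)
  }, numeric(4)))
  if (weight == "structure") {
    pct <- colMeans(per[, 1:3, drop = FALSE] / per[, 4] * 100)
  } else {
    pct <- colSums(per[, 1:3, drop = FALSE]) / sum(per[, 4]) * 100
  }
  structure(list(pct_barrel = unname(pct[1]),
                 pct_periplasmic = unname(pct[2]),
                 pct_extracellular = unname(pct[3]),
                 mean_length = mean(per[, 4]),
                 n_structures = nrow(per)),
            class = "composition_stats")
}

#' @export
print.composition_stats <- function(x, ...) {
  cat(sprintf(paste0("<composition_stats> %d structure(s), mean length ",
                     "%.1f\n  barrel %s%% | periplasmic %s%% | ",
                     "extracellular %s%%\n"),
              x$n_structures, x$mean_length, fmt_pct(x$pct_barrel),
              fmt_pct(x$pct_periplasmic), fmt_pct(x$pct_extracellular)))
  invisible(x)
}

#' One-call topology annotation of a structure
#'
#' Convenience wrapper running [assign_secondary_structure()],
#' [detect_barrel()] and [classify_regions()].
#'
#' @param model A `structure_model`.
#' @param ... Passed to [detect_barrel()].
#' @return A `topology_annotation`.
#' @export
annotate_topology <- function(model, ...) {
  ss <- assign_secondary_structure(model)
  barrel <- detect_barrel(model, ss, ...)
  classify_regions(model, barrel)
}
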