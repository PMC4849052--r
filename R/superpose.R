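# Pairwise rigid-body superposition of barrel cores: global sequence
# alignment seeds the residue correspondence, a least-squares (Kabsch)
# fit is iteratively re-estimated while trimming pairs that deviate beyond
# a cutoff, and per-subclass statistics aggregate the pairwise results.

#' Global pairwise sequence alignment
#'
#' Needleman-Wunsch global alignment under a substitution matrix with affine
#' gap penalties. Identity is the number of matches over the alignment
#' columns where both sequences hold a residue.
#'
#' @param seq_a,seq_b Amino-acid strings (unaligned).
#' @param substitution_matrix Name of a built-in scoring matrix
#'   (default "BLOSUM62").
#' @param gap_opening,gap_extension Gap penalties (defaults 10 and 0.5).
#' @return List with `alignment` (two aligned strings), `pct_identity`
#'   (0-100) and `score`.
#' @export
global_align <- function(seq_a, seq_b, substitution_matrix = "BLOSUM62",
                         gap_opening = 10, gap_extension = 0.5) {
  if (nchar(seq_a) == 0 || nchar(seq_b) == 0)
    pe_stop("cannot align an empty sequence", "pe_empty_input")
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    type = "global", substitutionMatrix = substitution_matrix,
    gapOpening = gap_opening, gapExtension = gap_extension)
  pa <- as.character(Biostrings::alignedPattern(al))
  pb <- as.character(Biostrings::alignedSubject(al))
  ca <- strsplit(pa, "")[[1]]; cb <- strsplit(pb, "")[[1]]
  both <- ca != "-" & cb != "-"
  pct <- if (any(both)) 100 * sum(ca[both] == cb[both]) / sum(both) else 0
  list(alignment = c(pa, pb), pct_identity = pct,
       score = Biostrings::score(al))
}

# Least-squares rigid fit (Kabsch, via SVD): returns the proper rotation R
# and translation t minimising ||Q - (P R' + t)||.
kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- t(Pc) %*% Qc
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- cq - as.numeric(R %*% cp)
  list(rotation = R, translation = t)
}

apply_rigid <- function(P, rot, trans) {
  sweep(P %*% t(rot), 2, trans, "+")
}

#' Superpose two barrel cores
#'
#' The residue correspondence is seeded by a global alignment of the core
#' sequences; matched C-alpha pairs are fit by least squares, pairs deviating
#' by more than `cutoff` are trimmed and the fit repeated until the retained
#' set is stable. The percentage superposed uses the shorter core as
#' denominator. Both the structural-match identity (over retained pairs) and
#' the global-alignment identity are reported.
#'
#' @param core_a,core_b `structure_model`s (typically [extract_core()]
#'   output) with at least 8 C-alpha atoms.
#' @param cutoff Trimming cutoff in Angstrom (default 3.5).
#' @param max_iter Safety bound on trim iterations.
#' @param ... Passed to [global_align()].
#' @return A `superposition` object: `rotation` (3x3, det +1),
#'   `translation`, `rmsd` (Angstrom, over retained pairs), `n_matched`,
#'   `pct_superposed`, `pct_identity_structural`, `pct_identity_global`,
#'   `retained` (residue index pairs), `rmsd_trajectory`.
#' @export
superpose_cores <- function(core_a, core_b, cutoff = 3.5, max_iter = 100L,
                            ...) {
  ca_a <- atom_coords(core_a, "CA")
  ca_b <- atom_coords(core_b, "CA")
  if (sum(stats::complete.cases(ca_a)) < 8 ||
      sum(stats::complete.cases(ca_b)) < 8)
    pe_stop("need at least 8 C-alpha atoms in each core", "pe_too_few")
  al <- global_align(core_a$sequence, core_b$sequence, ...)
  pa <- strsplit(al$alignment[1], "")[[1]]
  pb <- strsplit(al$alignment[2], "")[[1]]
  ia <- cumsum(pa != "-"); ib <- cumsum(pb != "-")
  keep <- pa != "-" & pb != "-"
  pairs <- cbind(a = ia[keep], b = ib[keep])
  ok <- stats::complete.cases(ca_a[pairs[, 1], , drop = FALSE]) &
    stats::complete.cases(ca_b[pairs[, 2], , drop = FALSE])
  pairs <- pairs[ok, , drop = FALSE]
  match_aa <- strsplit(core_a$sequence, "")[[1]][pairs[, 1]] ==
    strsplit(core_b$sequence, "")[[1]][pairs[, 2]]

  retained <- rep(TRUE, nrow(pairs))
  rmsd_traj <- numeric(0)
  fit <- NULL
  for (it in seq_len(max_iter)) {
    if (sum(retained) < 8)
      pe_stop("fewer than 8 matched pairs after trimming", "pe_too_few")
    P <- ca_a[pairs[retained, 1], , drop = FALSE]
    Q <- ca_b[pairs[retained, 2], , drop = FALSE]
    fit <- kabsch(P, Q)
    dev_all <- sqrt(rowSums((apply_rigid(ca_a[pairs[, 1], , drop = FALSE],
                                         fit$rotation, fit$translation) -
                             ca_b[pairs[, 2], , drop = FALSE])^2))
    rmsd_traj <- c(rmsd_traj, sqrt(mean(dev_all[retained]^2)))
    new_retained <- retained & dev_all <= cutoff
    if (identical(new_retained, retained)) break
    retained <- new_retained
  }
  dev <- sqrt(rowSums((apply_rigid(ca_a[pairs[retained, 1], , drop = FALSE],
                                   fit$rotation, fit$translation) -
                       ca_b[pairs[retained, 2], , drop = FALSE])^2))
  nmin <- min(n_residues(core_a), n_residues(core_b))
  nret <- sum(retained)
  structure(list(
    rotation = fit$rotation, translation = fit$translation,
    rmsd = sqrt(mean(dev^2)),
    n_matched = nret,
    pct_superposed = 100 * nret / nmin,
    pct_identity_structural = 100 * sum(match_aa[retained]) / nret,
    pct_identity_global = al$pct_identity,
    retained = pairs[retained, , drop = FALSE],
    rmsd_trajectory = rmsd_traj
  ), class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf(paste0("<superposition> rmsd %.3f A over %d pairs ",
                     "(%.1f%% superposed)\n  identity: %.1f%% structural, ",
                     "%.1f%% global\n"),
              x$rmsd, x$n_matched, x$pct_superposed,
              x$pct_identity_structural, x$pct_identity_global))
  invisible(x)
}

#' Per-subclass superposition statistics
#'
#' Means of RMSD, percentage superposed and both identities over all
#' within-subclass pairs, plus an overall average in which each subclass is
#' weighted equally. Subclasses with a single structure (no pairs) are
#' reported as `NA` rows, matching the dashes of a printed table.
#'
#' @param results List of `superposition` objects; each must carry a
#'   `subclass` attribute (or supply `grouping`).
#' @param grouping Optional character vector of subclass labels, parallel to
#'   `results`.
#' @param singletons Optional character vector of subclass labels that hold
#'   only one structure (emitted as `NA` rows).
#' @return Data frame with one row per subclass plus an `"Average"` row.
#' @export
subclass_stats <- function(results, grouping = NULL, singletons = NULL) {
  if (length(results) == 0 && length(singletons) == 0)
    pe_stop("no superposition results supplied", "pe_empty_input")
  if (is.null(grouping))
    grouping <- vapply(results, function(r)
      attr(r, "subclass") %||% NA_character_, character(1))
  stopifnot(length(grouping) == length(results))
  take <- function(field, idx) vapply(results[idx], function(r)
    r[[field]], numeric(1))
  subs <- unique(c(grouping, singletons))
  rows <- lapply(subs, function(s) {
    idx <- which(grouping == s)
    if (length(idx) == 0)
      return(data.frame(subclass = s, n_pairs = 0L, rmsd = NA_real_,
                        pct_superposed = NA_real_,
                        pct_identity_structural = NA_real_,
                        pct_identity_global = NA_real_))
    data.frame(subclass = s, n_pairs = length(idx),
               rmsd = mean(take("rmsd", idx)),
               pct_superposed = mean(take("pct_superposed", idx)),
               pct_identity_structural =
                 mean(take("pct_identity_structural", idx)),
               pct_identity_global = mean(take("pct_identity_global", idx)))
  })
  tab <- do.call(rbind, rows)
  with_pairs <- tab[tab$n_pairs > 0, , drop = FALSE]
  avg <- data.frame(subclass = "Average", n_pairs = sum(tab$n_pairs),
                    rmsd = mean(with_pairs$rmsd),
                    pct_superposed = mean(with_pairs$pct_superposed),
                    pct_identity_structural =
                      mean(with_pairs$pct_identity_structural),
                    pct_identity_global =
                      mean(with_pairs$pct_identity_global))
  rbind(tab, avg)
}
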