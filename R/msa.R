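# Multiple-sequence-alignment I/O, pairwise identity, iterative
# redundancy/divergence filtering, and column-to-structure mapping.

VALID_MSA_CHARS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                     "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V",
                     "-", "X")

new_msa <- function(ids, seqs) {
  ids <- as.character(ids); seqs <- toupper(as.character(seqs))
  seqs <- gsub("\\.", "-", seqs)
  if (length(ids) != length(seqs))
    pe_stop("ids and sequences differ in length", "pe_bad_msa")
  if (anyDuplicated(ids))
    pe_stop(sprintf("duplicate sequence ids: %s",
                    paste(unique(ids[duplicated(ids)]), collapse = ", ")),
            "pe_bad_msa")
  w <- unique(nchar(seqs))
  if (length(w) > 1)
    pe_stop("ragged alignment: sequences have unequal lengths", "pe_bad_msa")
  chars <- unique(strsplit(paste(seqs, collapse = ""), "")[[1]])
  bad <- setdiff(chars, VALID_MSA_CHARS)
  if (length(bad) > 0)
    pe_stop(sprintf("invalid alignment characters: %s",
                    paste(bad, collapse = " ")), "pe_bad_msa")
  structure(list(ids = ids, seqs = seqs,
                 n_columns = if (length(w)) w else 0L),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> %d sequences x %d columns\n",
              length(x$ids), x$n_columns))
  invisible(x)
}

#' Number of sequences / length of an alignment
#' @param x An `msa`.
#' @export
length.msa <- function(x) length(x$ids)

# Character matrix view (n_sequences x n_columns).
msa_matrix <- function(msa) {
  m <- do.call(rbind, strsplit(msa$seqs, ""))
  rownames(m) <- msa$ids
  m
}

#' Read an aligned FASTA file
#'
#' Lowercase is normalised to uppercase and `.` gap characters to `-`.
#' Ragged alignments and duplicate ids are errors.
#'
#' @param path Path to an aligned FASTA file.
#' @return An `msa` object.
#' @export
read_msa <- function(path) {
  if (!file.exists(path))
    pe_stop(sprintf("file not found: %s", path), "pe_parse_error")
  s <- Biostrings::readBStringSet(path)
  new_msa(sub("\\s.*$", "", names(s)), as.character(s))
}

#' Write an alignment to FASTA
#' @param msa An `msa`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_msa <- function(msa, path) {
  stopifnot(inherits(msa, "msa"))
  x <- Biostrings::BStringSet(stats::setNames(msa$seqs, msa$ids))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Pairwise identity between two aligned sequences
#'
#' Identity is the number of matching residues divided by the number of
#' columns where both sequences hold a residue (doubly- and half-gapped
#' columns excluded from the denominator). Returns 0 with a warning when the
#' two gap patterns share no columns.
#'
#' @param a,b Aligned sequences of equal length.
#' @return Identity fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b) {
  if (nchar(a) != nchar(b))
    pe_stop("aligned sequences differ in length", "pe_bad_msa")
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  both <- ca != "-" & cb != "-"
  if (!any(both)) {
    warning("no shared non-gap columns; identity reported as 0")
    return(0)
  }
  sum(ca[both] == cb[both]) / sum(both)
}

# Full identity matrix of an msa (symmetric, diagonal 1).
identity_matrix <- function(msa) {
  M <- msa_matrix(msa)
  n <- nrow(M); L <- ncol(M)
  ng <- M != "-"
  out <- diag(1, n)
  if (n < 2) return(out)
  for (i in 1:(n - 1)) {
    block <- M[(i + 1):n, , drop = FALSE]
    bng <- ng[(i + 1):n, , drop = FALSE]
    mi <- matrix(M[i, ], nrow(block), L, byrow = TRUE)
    both <- bng & matrix(ng[i, ], nrow(block), L, byrow = TRUE)
    shared <- rowSums(both)
    matches <- rowSums((block == mi) & both)
    id <- ifelse(shared > 0, matches / shared, 0)
    out[i, (i + 1):n] <- id
    out[(i + 1):n, i] <- id
  }
  out
}

new_filter_report <- function(removed_id, removed_reason, removed_round,
                              survivors) {
  structure(list(
    removed = data.frame(id = removed_id, reason = removed_reason,
                         round = removed_round, stringsAsFactors = FALSE),
    survivors = as.integer(survivors)), class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> %d removed, %d survivors\n",
              nrow(x$removed), x$survivors))
  if (nrow(x$removed) > 0) print(utils::head(x$removed, 10))
  invisible(x)
}

#' Remove redundant sequences above an identity ceiling
#'
#' Iteratively, while any pair exceeds `max_id` (strictly): take the current
#' highest-identity pair and remove the member with the greater mean identity
#' to all remaining sequences (the more redundant one; ties broken by later
#' input order). Deterministic; the surviving set contains no pair above
#' `max_id`.
#'
#' @param msa An `msa`.
#' @param max_id Identity ceiling (default 0.90).
#' @return List with elements `msa` (survivors) and `report`
#'   (a `filter_report`).
#' @export
filter_redundant <- function(msa, max_id = 0.90) {
  stopifnot(inherits(msa, "msa"))
  n <- length(msa$ids)
  idm <- identity_matrix(msa)
  alive <- rep(TRUE, n)
  rem_id <- character(0); rem_round <- integer(0)
  round <- 0L
  repeat {
    idx <- which(alive)
    if (length(idx) < 2) break
    sub <- idm[idx, idx, drop = FALSE]
    diag(sub) <- -1
    mx <- max(sub)
    if (mx <= max_id) break
    round <- round + 1L
    w <- which(sub == mx, arr.ind = TRUE)
    # deterministic pair choice: smallest row then column index
    w <- w[order(w[, 1], w[, 2]), , drop = FALSE]
    pair <- idx[w[1, ]]
    mean_to_rest <- vapply(pair, function(p) {
      others <- setdiff(idx, p)
      mean(idm[p, others])
    }, numeric(1))
    victim <- if (mean_to_rest[1] > mean_to_rest[2]) pair[1]
              else if (mean_to_rest[2] > mean_to_rest[1]) pair[2]
              else max(pair)  # tie: later input order
    alive[victim] <- FALSE
    rem_id <- c(rem_id, msa$ids[victim])
    rem_round <- c(rem_round, round)
  }
  out <- new_msa(msa$ids[alive], msa$seqs[alive])
  list(msa = out,
       report = new_filter_report(rem_id,
                                  rep("high_identity", length(rem_id)),
                                  rem_round, sum(alive)))
}

#' Remove sequences too divergent from a reference
#'
#' Sequences with identity to the reference below `min_id` are removed; the
#' reference itself is never removed. This discards alignment noise while
#' losing little signal.
#'
#' @param msa An `msa`.
#' @param reference_id Id of the reference (structure-derived) sequence.
#' @param min_id Identity floor (default 0.20; the field uses 0.20-0.30).
#' @return List with elements `msa` and `report`.
#' @export
filter_divergent <- function(msa, reference_id, min_id = 0.20) {
  stopifnot(inherits(msa, "msa"))
  ri <- match(reference_id, msa$ids)
  if (is.na(ri))
    pe_stop(sprintf("reference '%s' not in alignment", reference_id),
            "pe_missing_reference")
  ids <- vapply(seq_along(msa$ids), function(i)
    if (i == ri) 1 else suppressWarnings(
      pairwise_identity(msa$seqs[i], msa$seqs[ri])), numeric(1))
  drop <- ids < min_id
  out <- new_msa(msa$ids[!drop], msa$seqs[!drop])
  list(msa = out,
       report = new_filter_report(msa$ids[drop],
                                  rep("low_identity", sum(drop)),
                                  rep(1L, sum(drop)), sum(!drop)))
}

#' Map alignment columns onto structure residues
#'
#' Columns where the reference sequence holds a residue map to the structure
#' residue carrying that character; columns where the reference is gapped are
#' unmapped. When the ungapped reference does not equal the model sequence it
#' is globally aligned to it and must reach `min_identity`.
#'
#' @param msa An `msa`.
#' @param reference_id Id of the reference sequence within the MSA.
#' @param model A `structure_model`.
#' @param min_identity Required reference/model identity (default 0.95).
#' @return A `column_map` data frame with columns `column_index` and
#'   `residue_index` (both 1-based), strictly increasing in both.
#' @export
map_columns <- function(msa, reference_id, model, min_identity = 0.95) {
  stopifnot(inherits(msa, "msa"))
  ri <- match(reference_id, msa$ids)
  if (is.na(ri))
    pe_stop(sprintf("reference '%s' not in alignment", reference_id),
            "pe_missing_reference")
  aligned <- strsplit(msa$seqs[ri], "")[[1]]
  nongap_cols <- which(aligned != "-")
  refseq <- paste(aligned[nongap_cols], collapse = "")
  mseq <- model$sequence
  if (identical(refseq, mseq)) {
    ref_to_model <- seq_len(nchar(refseq))
  } else {
    al <- global_align(refseq, mseq)
    if (al$pct_identity < min_identity * 100)
      pe_stop(sprintf(
        "reference/model sequences disagree (%.1f%% identity < %.0f%%)",
        al$pct_identity, min_identity * 100), "pe_reference_mismatch")
    pa <- strsplit(al$alignment[1], "")[[1]]
    pb <- strsplit(al$alignment[2], "")[[1]]
    ia <- cumsum(pa != "-"); ib <- cumsum(pb != "-")
    keep <- pa != "-" & pb != "-"
    ref_to_model <- rep(NA_integer_, nchar(refseq))
    ref_to_model[ia[keep]] <- ib[keep]
  }
  resi <- ref_to_model[seq_along(nongap_cols)]
  ok <- !is.na(resi)
  structure(data.frame(column_index = nongap_cols[ok],
                       residue_index = resi[ok]),
            class = c("column_map", "data.frame"))
}
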