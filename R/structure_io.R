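# Structure reading, cleaning, selection, renumbering and writing.
#
# A cleaned structure is represented as a `structure_model`: a list holding an
# atom table (one row per atom) plus metadata. After preparation it contains a
# single model and a single chain, only the 20 standard amino acids, resolved
# alternate locations, residues renumbered 1..N, and per-atom van der Waals
# radii used by the pore profiler.

new_structure_model <- function(atoms, source_id, model_number, chain_id,
                                n_gaps = 0L) {
  resseq <- unique(atoms$residue_index)
  stopifnot(all(diff(resseq) == 1L), resseq[1] == 1L)
  seq1 <- aa_three_to_one(atoms$residue_name[!duplicated(atoms$residue_index)])
  structure(list(
    atoms = atoms,
    source_id = source_id,
    model_number = as.integer(model_number),
    chain_id = chain_id,
    sequence = paste(seq1, collapse = ""),
    n_gaps = as.integer(n_gaps)
  ), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %s  chain %s  model %d\n",
              x$source_id, x$chain_id, x$model_number))
  cat(sprintf("  %d residues, %d atoms, %d missing-residue gap(s)\n",
              n_residues(x), nrow(x$atoms), x$n_gaps))
  cat("  sequence: ",
      if (nchar(x$sequence) > 60) paste0(substr(x$sequence, 1, 57), "...")
      else x$sequence, "\n", sep = "")
  invisible(x)
}

#' Number of residues in a structure model
#' @param model A `structure_model`.
#' @return Integer residue count.
#' @export
n_residues <- function(model) {
  length(unique(model$atoms$residue_index))
}

# Cartesian coordinates (n_atoms x 3) of a structure model.
coords <- function(model) {
  as.matrix(model$atoms[, c("x", "y", "z")])
}

# Coordinates of one named atom per residue (NA rows where absent).
atom_coords <- function(model, name) {
  n <- n_residues(model)
  out <- matrix(NA_real_, n, 3)
  sel <- model$atoms$atom_name == name
  out[model$atoms$residue_index[sel], ] <- as.matrix(
    model$atoms[sel, c("x", "y", "z")])
  out
}

# ---- raw parsing -----------------------------------------------------------

derive_element <- function(atom_name, type_symbol = NULL) {
  # heuristic fallback: first alphabetic character of the atom name
  el <- substr(gsub("^[0-9]*", "", toupper(atom_name)), 1, 1)
  if (!is.null(type_symbol)) {
    ts <- toupper(trimws(type_symbol))
    use <- !is.na(ts) & ts != "" & ts != "?"
    el[use] <- ts[use]
  }
  el
}

read_raw_atoms <- function(path, model_number = 1L) {
  if (!file.exists(path))
    pe_stop(sprintf("file not found: %s", path), "pe_parse_error")
  if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
    return(read_raw_cif(path, model_number))
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) pe_stop(
      sprintf("unparseable structure file %s: %s", path, conditionMessage(e)),
      "pe_parse_error"))
  xyz <- pdb$xyz
  n_models <- if (is.matrix(xyz)) nrow(xyz) else 1L
  if (model_number < 1L || model_number > n_models)
    pe_stop(sprintf("model %d not present in %s (%d model(s))",
                    model_number, path, n_models), "pe_missing_model")
  xyzrow <- if (is.matrix(xyz)) xyz[model_number, ] else as.numeric(xyz)
  xm <- matrix(xyzrow, ncol = 3, byrow = TRUE)
  at <- pdb$atom
  if (nrow(at) != nrow(xm))
    pe_stop("atom/coordinate count mismatch", "pe_parse_error")
  elesy <- if ("elesy" %in% names(at)) at$elesy else NULL
  df <- data.frame(
    type = at$type,
    atom_name = trimws(at$elety),
    element = derive_element(trimws(at$elety), elesy),
    resno = at$resno,
    resid = trimws(at$resid),
    chain = ifelse(is.na(at$chain) | at$chain == "", " ", at$chain),
    insert = ifelse(is.na(at$insert), "", at$insert),
    alt = ifelse(is.na(at$alt), "", at$alt),
    occ = ifelse(is.na(at$o), 1, at$o),
    x = xm[, 1], y = xm[, 2], z = xm[, 3],
    stringsAsFactors = FALSE)
  attr(df, "n_models") <- n_models
  df
}

read_raw_cif <- function(path, model_number = 1L) {
  lines <- readLines(path, warn = FALSE)
  i <- 1L; n <- length(lines)
  fields <- character(); rows <- list()
  while (i <= n) {
    if (trimws(lines[i]) == "loop_") {
      j <- i + 1L
      hdr <- character()
      while (j <= n && startsWith(trimws(lines[j]), "_")) {
        hdr <- c(hdr, trimws(lines[j])); j <- j + 1L
      }
      if (length(hdr) > 0 && all(startsWith(hdr, "_atom_site."))) {
        fields <- sub("^_atom_site\\.", "", hdr)
        while (j <= n) {
          ln <- trimws(lines[j])
          if (ln == "" || startsWith(ln, "#") || startsWith(ln, "_") ||
              ln == "loop_" || startsWith(ln, "data_")) break
          rows[[length(rows) + 1L]] <- scan(text = ln, what = "",
                                            quiet = TRUE)
          j <- j + 1L
        }
        break
      }
      i <- j
    } else i <- i + 1L
  }
  if (length(fields) == 0 || length(rows) == 0)
    pe_stop(sprintf("no _atom_site loop found in %s", path), "pe_parse_error")
  if (any(lengths(rows) != length(fields)))
    pe_stop(sprintf("malformed _atom_site rows in %s", path), "pe_parse_error")
  m <- do.call(rbind, rows)
  colnames(m) <- fields
  pick <- function(...) {
    for (nm in c(...)) if (nm %in% fields) return(m[, nm])
    rep(NA_character_, nrow(m))
  }
  model_col <- pick("pdbx_PDB_model_num")
  if (!all(is.na(model_col))) {
    models <- sort(unique(as.integer(model_col)))
    if (!(model_number %in% models))
      pe_stop(sprintf("model %d not present in %s", model_number, path),
              "pe_missing_model")
    keep <- as.integer(model_col) == model_number
    m <- m[keep, , drop = FALSE]
  } else if (model_number != 1L) {
    pe_stop(sprintf("model %d not present in %s", model_number, path),
            "pe_missing_model")
  }
  pick2 <- function(...) {
    for (nm in c(...)) if (nm %in% fields) return(m[, nm])
    rep(NA_character_, nrow(m))
  }
  blank <- function(x) ifelse(is.na(x) | x %in% c(".", "?"), "", x)
  df <- data.frame(
    type = pick2("group_PDB"),
    atom_name = blank(pick2("auth_atom_id", "label_atom_id")),
    element = NA_character_,
    resno = as.integer(blank(pick2("auth_seq_id", "label_seq_id"))),
    resid = blank(pick2("auth_comp_id", "label_comp_id")),
    chain = blank(pick2("auth_asym_id", "label_asym_id")),
    insert = blank(pick2("pdbx_PDB_ins_code")),
    alt = blank(pick2("label_alt_id")),
    occ = suppressWarnings(as.numeric(blank(pick2("occupancy")))),
    x = as.numeric(pick2("Cartn_x")),
    y = as.numeric(pick2("Cartn_y")),
    z = as.numeric(pick2("Cartn_z")),
    stringsAsFactors = FALSE)
  df$occ[is.na(df$occ)] <- 1
  df$element <- derive_element(df$atom_name, pick2("type_symbol"))
  n_models <- if (!all(is.na(model_col)))
    length(unique(model_col)) else 1L
  attr(df, "n_models") <- n_models
  df
}

# ---- cleaning --------------------------------------------------------------

clean_atoms <- function(raw, source_id, model_number, chain_id = NULL) {
  res_key <- function(d) paste(d$chain, d$resno, d$insert, d$resid)
  # selenomethionine is retained as methionine
  mse <- raw$resid == "MSE"
  raw$resid[mse] <- "MET"
  raw$atom_name[mse & raw$atom_name == "SE"] <- "SD"
  raw$element[mse & raw$element == "SE"] <- "S"

  protein_chains <- unique(raw$chain[raw$resid %in% .AA3])
  if (length(protein_chains) == 0)
    pe_stop(sprintf("%s: no protein residues after cleaning", source_id),
            "pe_empty_structure")
  if (is.null(chain_id)) {
    chain_id <- if ("A" %in% protein_chains) "A" else protein_chains[1]
  } else if (!(chain_id %in% unique(raw$chain))) {
    pe_stop(sprintf("%s: chain '%s' not present (chains: %s)", source_id,
                    chain_id, paste(unique(raw$chain), collapse = ", ")),
            "pe_missing_chain")
  }
  d <- raw[raw$chain == chain_id, , drop = FALSE]

  is_water <- d$resid %in% .WATERS
  n_waters <- length(unique(res_key(d)[is_water]))
  d <- d[!is_water, , drop = FALSE]

  d <- d[!(d$element %in% c("H", "D")), , drop = FALSE]

  is_het <- !(d$resid %in% .AA3)
  n_hetero <- length(unique(res_key(d)[is_het]))
  d <- d[!is_het, , drop = FALSE]
  if (nrow(d) == 0)
    pe_stop(sprintf("%s: chain %s holds no standard amino-acid residues",
                    source_id, chain_id), "pe_empty_structure")

  # alternate locations: keep highest occupancy, ties to first altloc id
  akey <- paste(d$resno, d$insert, d$atom_name)
  dup_groups <- unique(akey[duplicated(akey)])
  n_altloc <- length(dup_groups)
  if (n_altloc > 0) {
    idx <- seq_len(nrow(d))
    best <- vapply(split(idx, factor(akey, levels = unique(akey))),
                   function(ii) ii[order(-d$occ[ii], d$alt[ii])][1],
                   integer(1))
    d <- d[sort(unname(best)), , drop = FALSE]
  }

  rk <- paste(d$resno, d$insert)
  uk <- unique(rk)
  d$residue_index <- match(rk, uk)
  orig <- d$resno[!duplicated(d$residue_index)]
  gaps <- diff(orig) - 1L
  n_gaps_res <- sum(gaps[gaps > 0])

  vdw_table <- attr(raw, "vdw_table")
  if (is.null(vdw_table)) vdw_table <- default_vdw_radii()
  vdw <- unname(vdw_table[d$element])
  vdw[is.na(vdw)] <- attr(vdw_table, "default") %||% 1.70
  atoms <- data.frame(
    atom_name = d$atom_name,
    element = d$element,
    residue_index = as.integer(d$residue_index),
    residue_name = d$resid,
    chain_id = chain_id,
    x = d$x, y = d$y, z = d$z,
    occ = d$occ,
    vdw = vdw,
    is_backbone = d$atom_name %in% c("N", "CA", "C", "O"),
    orig_resno = d$resno,
    stringsAsFactors = FALSE)
  model <- new_structure_model(atoms, source_id, model_number, chain_id,
                               n_gaps = n_gaps_res)
  report <- structure(list(
    n_waters_removed = as.integer(n_waters),
    n_hetero_removed = as.integer(n_hetero),
    n_altloc_resolved = as.integer(n_altloc),
    chain_kept = chain_id,
    model_kept = as.integer(model_number)
  ), class = "cleaning_report")
  list(model = model, report = report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cleaning_report <- function(x, ...) {
  cat(sprintf(paste0("<cleaning_report> chain %s, model %d: %d water(s), ",
                     "%d hetero residue(s) removed, %d altloc position(s) ",
                     "resolved\n"),
              x$chain_kept, x$model_kept, x$n_waters_removed,
              x$n_hetero_removed, x$n_altloc_resolved))
  invisible(x)
}

#' Read and clean a protein structure
#'
#' Parses a PDB or mmCIF file, keeps a single model and chain, removes waters,
#' hydrogens and hetero residues (co-factors, substrates, lipids, ions), maps
#' selenomethionine to methionine, resolves alternate locations to the highest
#' occupancy (ties broken by altloc identifier), renumbers residues 1..N and
#' assigns van der Waals radii per element.
#'
#' Residues missing from the experimental model (e.g. disordered loops) remain
#' a numbering gap; the count of skipped positions is kept in the model's
#' `n_gaps` field and downstream statistics are computed over observed
#' residues only.
#'
#' @param path Path to a `.pdb`, `.ent`, `.cif` or `.mmcif` file.
#' @param model_number Model to keep (relevant for NMR ensembles). Default 1.
#' @param chain_id Chain to keep. `NULL` selects chain "A" when present, else
#'   the first protein chain in file order.
#' @param vdw_table Named radius table, see [default_vdw_radii()].
#' @return A list with elements `model` (a `structure_model`) and `report`
#'   (a `cleaning_report` with removal counts).
#' @seealso [write_structure()], [first_monomer()]
#' @export
read_structure <- function(path, model_number = 1L, chain_id = NULL,
                           vdw_table = default_vdw_radii()) {
  raw <- read_raw_atoms(path, model_number)
  attr(raw, "vdw_table") <- vdw_table
  source_id <- sub("\\.[A-Za-z]+$", "", basename(path))
  clean_atoms(raw, source_id, model_number, chain_id)
}

#' Write a structure model to a PDB file
#'
#' A round trip through [read_structure()] reproduces residue count, sequence
#' and coordinates to PDB precision (3 decimals).
#'
#' @param model A `structure_model`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_structure <- function(model, path) {
  if (!inherits(model, "structure_model") || nrow(model$atoms) == 0)
    pe_stop("empty or invalid structure model", "pe_empty_structure")
  if (!dir.exists(dirname(path)))
    pe_stop(sprintf("unwritable path: %s", path), "pe_unwritable")
  a <- model$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$residue_index,
                   resid = a$residue_name,
                   eleno = seq_len(nrow(a)),
                   elety = a$atom_name,
                   chain = rep(model$chain_id, nrow(a)),
                   o = a$occ,
                   b = rep(0, nrow(a)))
  invisible(path)
}

#' Select the first monomer of a (possibly multimeric) structure file
#'
#' Multimeric channel structures are analysed one monomer at a time: chain "A"
#' is used when present, otherwise the first protein chain in file order (with
#' a warning naming the chain used).
#'
#' @inheritParams read_structure
#' @return A `structure_model` (the cleaning report is attached as attribute
#'   `"report"`).
#' @export
first_monomer <- function(path, model_number = 1L,
                          vdw_table = default_vdw_radii()) {
  raw <- read_raw_atoms(path, model_number)
  attr(raw, "vdw_table") <- vdw_table
  protein_chains <- unique(raw$chain[raw$resid %in% c(.AA3, "MSE")])
  if (length(protein_chains) == 0)
    pe_stop("no protein chains in file", "pe_missing_chain")
  chain <- if ("A" %in% protein_chains) "A" else {
    warning(sprintf("chain 'A' absent; using first protein chain '%s'",
                    protein_chains[1]))
    protein_chains[1]
  }
  source_id <- sub("\\.[A-Za-z]+$", "", basename(path))
  res <- clean_atoms(raw, source_id, model_number, chain)
  attr(res$model, "report") <- res$report
  res$model
}
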