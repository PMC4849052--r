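# Study-workflow orchestration: structure preparation -> topology -> core
# extraction -> within-subclass superposition -> pore profiling -> MSA
# filtering -> EVA -> region tables, over a subclass configuration, with a
# reproducible run manifest.

#' Validate a pipeline run configuration
#'
#' A configuration is a list (or path to a JSON file) with a `subclasses`
#' element: one entry per subclass, each holding `name`, `template` (member
#' id), `members` (named list: member id -> structure file path), and `msa`
#' (aligned FASTA path). Optional top-level elements: `seed`,
#' `thresholds` (named list overriding module defaults: `max_id`, `min_id`,
#' `max_gap_fraction`, `trim_cutoff`, `pore_step`) and per-subclass
#' `model_number` / `chain_id`.
#'
#' @param config List or JSON file path.
#' @return The validated configuration (invisibly), with defaults filled in.
#' @export
validate_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config))
      pe_stop(sprintf("config file not found: %s", config), "pe_bad_config")
    config <- jsonlite::read_json(config, simplifyVector = FALSE)
  }
  if (!is.list(config) || is.null(config$subclasses) ||
      length(config$subclasses) == 0)
    pe_stop("config must hold a non-empty 'subclasses' list", "pe_bad_config")
  seen <- character(0)
  missing_files <- character(0)
  for (id in names(config$subclasses)) {
    sc <- config$subclasses[[id]]
    if (is.null(sc$members) || length(sc$members) == 0)
      pe_stop(sprintf("subclass %s has no members", id), "pe_bad_config")
    if (is.null(sc$template) || !(sc$template %in% names(sc$members)))
      pe_stop(sprintf("subclass %s: template must be one of its members", id),
              "pe_bad_config")
    dup <- intersect(names(sc$members), seen)
    if (length(dup) > 0)
      pe_stop(sprintf("structure(s) in more than one subclass: %s",
                      paste(dup, collapse = ", ")), "pe_bad_config")
    seen <- c(seen, names(sc$members))
    for (p in unlist(sc$members))
      if (!file.exists(p)) missing_files <- c(missing_files, p)
    if (!is.null(sc$msa) && !file.exists(sc$msa))
      missing_files <- c(missing_files, sc$msa)
  }
  if (length(missing_files) > 0)
    pe_stop(paste0("missing input file(s):\n  ",
                   paste(missing_files, collapse = "\n  ")),
            "pe_missing_inputs")
  defaults <- list(max_id = 0.90, min_id = 0.20, max_gap_fraction = 0.5,
                   trim_cutoff = 3.5, pore_step = 0.25)
  th <- config$thresholds %||% list()
  for (nm in names(defaults)) th[[nm]] <- th[[nm]] %||% defaults[[nm]]
  config$thresholds <- th
  config$seed <- config$seed %||% 1L
  invisible(config)
}

write_tsv <- function(df, path, digits = 1) {
  num <- vapply(df, is.numeric, logical(1))
  for (nm in names(df)[num])
    df[[nm]] <- ifelse(is.na(df[[nm]]), "", sprintf(paste0("%.", digits, "f"),
                                                    df[[nm]]))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full porin analysis pipeline
#'
#' For every subclass: reads and cleans the member structures, annotates
#' their barrel topology, extracts cores, superposes all within-subclass
#' core pairs, profiles whole and core pore radii, filters the subclass MSA
#' (redundancy then divergence against the template sequence), computes the
#' entropy-variability statistics, maps the columns onto the template
#' structure, and tabulates box distributions per structural region.
#' Missing input files are enumerated before any computation starts, and
#' re-running with the same configuration reproduces byte-identical outputs.
#'
#' @param config Run configuration (list or JSON path); see
#'   [validate_run_config()].
#' @param output_dir Directory for output tables and the manifest.
#' @return Invisibly, a list with the composition table, the superposition
#'   (Table-4 style) table, per-subclass EVA objects and region tables, and
#'   the manifest.
#' @export
run_pipeline <- function(config, output_dir) {
  config <- validate_run_config(config)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  th <- config$thresholds
  outputs <- character(0)
  emit <- function(df, name, digits = 1) {
    p <- file.path(output_dir, name)
    write_tsv(df, p, digits)
    outputs <<- c(outputs, p)
    p
  }

  annotations <- list()
  superpositions <- list()
  sp_groups <- character(0)
  singletons <- character(0)
  pore_rows <- list()
  eva_objects <- list()
  region_tables <- list()

  for (sid in names(config$subclasses)) {
    sc <- config$subclasses[[sid]]
    models <- list(); anns <- list(); cores <- list()
    for (mid in names(sc$members)) {
      rs <- read_structure(sc$members[[mid]],
                           model_number = sc$model_number %||% 1L,
                           chain_id = sc$chain_id %||% NULL)
      models[[mid]] <- rs$model
      anns[[mid]] <- annotate_topology(rs$model)
      cores[[mid]] <- extract_core(rs$model, anns[[mid]])
      tsv <- data.frame(residue = anns[[mid]]$residue_index,
                        region = anns[[mid]]$label,
                        strand = anns[[mid]]$strand_index,
                        loop = anns[[mid]]$loop_index)
      emit(tsv, sprintf("topology_%s.tsv", mid), digits = 0)
    }
    annotations[[sid]] <- anns

    mids <- names(models)
    if (length(mids) >= 2) {
      for (i in 1:(length(mids) - 1)) for (j in (i + 1):length(mids)) {
        s <- superpose_cores(cores[[mids[i]]], cores[[mids[j]]],
                             cutoff = th$trim_cutoff)
        superpositions[[length(superpositions) + 1L]] <- s
        sp_groups <- c(sp_groups, sid)
      }
    } else singletons <- c(singletons, sid)

    for (mid in mids) {
      pr <- pore_analysis(models[[mid]], anns[[mid]], step = th$pore_step)
      pore_rows[[length(pore_rows) + 1L]] <- data.frame(
        subclass = sid, structure = mid,
        strand_count = attr(anns[[mid]], "strand_count"),
        pore_core = pr$core$min_radius,
        pore_whole = pr$whole$min_radius,
        pore_polyA = pr$polyA$min_radius)
    }

    if (!is.null(sc$msa)) {
      msa <- read_msa(sc$msa)
      fr <- filter_redundant(msa, max_id = th$max_id)
      ref_id <- sc$reference %||% sc$template
      msa2 <- fr$msa
      if (ref_id %in% msa2$ids) {
        fd <- filter_divergent(msa2, ref_id, min_id = th$min_id)
        msa2 <- fd$msa
      }
      ev <- compute_eva(msa2, max_gap_fraction = th$max_gap_fraction)
      eva_objects[[sid]] <- ev
      emit(ev$stats, sprintf("eva_%s.tsv", sid), digits = 4)
      if (ref_id %in% msa2$ids) {
        tmpl <- sc$template
        map <- map_columns(msa2, ref_id, models[[tmpl]])
        ori <- orient_residues(models[[tmpl]], anns[[tmpl]])
        lf <- classify_long_loops(anns[[tmpl]])
        cl <- detect_constriction_loop(models[[tmpl]], anns[[tmpl]])
        rt <- region_box_distribution(ev, map, anns[[tmpl]], ori, lf, cl)
        region_tables[[sid]] <- rt
        emit(as.data.frame(rt), sprintf("regions_%s.tsv", sid))
      }
    }
  }

  comp_rows <- lapply(names(annotations), function(sid) {
    cs <- composition_stats(annotations[[sid]])
    data.frame(subclass = sid, n = cs$n_structures,
               mean_length = cs$mean_length, pct_barrel = cs$pct_barrel,
               pct_periplasmic = cs$pct_periplasmic,
               pct_extracellular = cs$pct_extracellular)
  })
  composition <- do.call(rbind, comp_rows)
  emit(composition, "composition.tsv")

  sp_tab <- subclass_stats(superpositions, grouping = sp_groups,
                           singletons = singletons)
  pore_tab <- do.call(rbind, pore_rows)
  pore_by_sub <- stats::aggregate(pore_tab[, c("pore_core", "pore_whole")],
                                  list(subclass = pore_tab$subclass), mean)
  sp_tab <- merge(sp_tab, pore_by_sub, by = "subclass", all.x = TRUE,
                  sort = FALSE)
  avg <- sp_tab$subclass == "Average"
  sp_tab$pore_core[avg] <- mean(pore_by_sub$pore_core)
  sp_tab$pore_whole[avg] <- mean(pore_by_sub$pore_whole)
  emit(sp_tab, "superposition.tsv")
  emit(pore_tab, "pore.tsv", digits = 2)

  manifest <- list(
    package_version = as.character(utils::packageVersion("porineva")),
    seed = config$seed,
    thresholds = config$thresholds,
    subclasses = lapply(config$subclasses, function(sc)
      list(template = sc$template, members = names(sc$members))),
    checksums = {
      md5 <- tools::md5sum(sort(outputs))
      stats::setNames(as.list(unname(md5)), basename(names(md5)))
    })
  manifest_path <- file.path(output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(composition = composition, superposition = sp_tab,
                 pore = pore_tab, eva = eva_objects,
                 regions = region_tables, manifest = manifest))
}
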