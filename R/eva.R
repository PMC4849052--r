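# Entropy-variability analysis (EVA): per-column Shannon entropy and
# variability, five-box functional classification, EV plot data, and
# conservation distributions over structural regions.
#
# Entropy is reported with the conventional non-negative sign, -sum(P ln P),
# in nats (natural log by default; configurable base). Variability is the
# number of amino-acid types observed at a column with frequency strictly
# above 0.5%.

#' Per-column Shannon entropy
#'
#' `E = -sum(p * log(p))` over the non-gap residue frequencies of the
#' column. An all-gap column is invalid and yields `NA`.
#'
#' @param column Character vector of single characters (residues and `-`).
#' @param base Logarithm base (default `exp(1)`: nats).
#' @return Non-negative entropy, or `NA` for an all-gap column.
#' @export
column_entropy <- function(column, base = exp(1)) {
  r <- column[column != "-"]
  if (length(r) == 0) return(NA_real_)
  p <- as.numeric(table(r)) / length(r)
  -sum(p * log(p, base = base))
}

#' Per-column variability
#'
#' The number of amino-acid types observed at the column with non-gap
#' frequency strictly greater than `freq_threshold`.
#'
#' @param column Character vector of single characters.
#' @param freq_threshold Frequency threshold (default 0.005, i.e. 0.5%).
#' @return Integer count (0 for an all-gap column).
#' @export
column_variability <- function(column, freq_threshold = 0.005) {
  r <- column[column != "-"]
  if (length(r) == 0) return(0L)
  p <- as.numeric(table(r)) / length(r)
  sum(p > freq_threshold)
}

#' Five-box entropy-variability scheme
#'
#' The EV plane is divided into five sectors named by two digits
#' (variability tier, entropy tier): 11 main active site (red), 12 active-
#' site support (orange), 22 signal/communication (yellow), 23 modulation
#' (green), 33 no known function (blue). Boundaries default to terciles of
#' both axes, which reproduces the two-digit naming structure; all four
#' thresholds are configurable.
#'
#' @param v_lo,v_hi Variability thresholds (1 <= v_lo < v_hi <= 20).
#' @param e_lo,e_hi Entropy thresholds in nats (0 <= e_lo < e_hi <= ln 20).
#' @param colors Named box-to-colour map.
#' @return An `ev_scheme` list.
#' @export
ev_scheme <- function(v_lo = 4L, v_hi = 12L,
                      e_lo = log(20) / 3, e_hi = 2 * log(20) / 3,
                      colors = c(`11` = "red", `12` = "orange",
                                 `22` = "yellow", `23` = "green",
                                 `33` = "blue")) {
  if (!(1 <= v_lo && v_lo < v_hi && v_hi <= 20))
    pe_stop("need 1 <= v_lo < v_hi <= 20", "pe_bad_scheme")
  if (!(0 <= e_lo && e_lo < e_hi && e_hi <= log(20) + 1e-9))
    pe_stop("need 0 <= e_lo < e_hi <= ln 20", "pe_bad_scheme")
  stopifnot(all(c("11", "12", "22", "23", "33") %in% names(colors)))
  structure(list(v_lo = as.integer(v_lo), v_hi = as.integer(v_hi),
                 e_lo = e_lo, e_hi = e_hi, colors = colors),
            class = "ev_scheme")
}

#' Classify (entropy, variability) pairs into the five boxes
#'
#' Box 11 iff `V <= v_lo` and `E <= e_lo`; Box 12 iff `V <= v_lo` and
#' `E > e_lo`; Box 22 iff `v_lo < V <= v_hi` and `E <= e_hi`; Box 33 iff
#' `V > v_hi` and `E > e_hi`; Box 23 otherwise. Every pair maps to exactly
#' one box.
#'
#' @param entropy Numeric vector (nats).
#' @param variability Integer vector.
#' @param scheme An [ev_scheme()].
#' @return Character vector of box labels; `NA` where inputs are `NA`.
#' @export
classify_box <- function(entropy, variability, scheme = ev_scheme()) {
  stopifnot(inherits(scheme, "ev_scheme"))
  v <- variability; e <- entropy
  out <- rep(NA_character_, length(e))
  ok <- !is.na(e) & !is.na(v)
  out[ok & v <= scheme$v_lo & e <= scheme$e_lo] <- "11"
  out[ok & v <= scheme$v_lo & e > scheme$e_lo] <- "12"
  out[ok & v > scheme$v_lo & v <= scheme$v_hi & e <= scheme$e_hi] <- "22"
  out[ok & v > scheme$v_hi & e > scheme$e_hi] <- "33"
  out[ok & is.na(out)] <- "23"
  out
}

#' Entropy-variability analysis of an alignment
#'
#' Computes per-column entropy, variability, gap fraction and box label.
#' Columns whose gap fraction exceeds `max_gap_fraction` are marked invalid
#' and excluded from distributions.
#'
#' @param msa A filtered `msa` with at least 2 sequences.
#' @param scheme An [ev_scheme()].
#' @param max_gap_fraction Maximum tolerated per-column gap fraction
#'   (default 0.5).
#' @param freq_threshold Variability frequency threshold (default 0.005).
#' @param base Entropy logarithm base.
#' @return An `eva` object: list with `stats` (data frame: `column`,
#'   `entropy`, `variability`, `gap_fraction`, `valid`, `box`, `color`),
#'   `scheme`, `n_sequences`. Has `print`, `summary` and `plot` methods.
#' @export
compute_eva <- function(msa, scheme = ev_scheme(), max_gap_fraction = 0.5,
                        freq_threshold = 0.005, base = exp(1)) {
  stopifnot(inherits(msa, "msa"))
  if (length(msa$ids) < 2)
    pe_stop("need at least 2 sequences", "pe_empty_input")
  M <- msa_matrix(msa)
  nc <- ncol(M)
  ent <- numeric(nc); var <- integer(nc); gapf <- numeric(nc)
  for (i in seq_len(nc)) {
    col <- M[, i]
    gapf[i] <- mean(col == "-")
    ent[i] <- column_entropy(col, base = base)
    var[i] <- column_variability(col, freq_threshold = freq_threshold)
  }
  valid <- !is.na(ent) & gapf <= max_gap_fraction
  box <- ifelse(valid, classify_box(ent, var, scheme), NA_character_)
  stats <- data.frame(column = seq_len(nc), entropy = ent,
                      variability = var, gap_fraction = gapf,
                      valid = valid, box = box,
                      color = unname(scheme$colors[box]),
                      stringsAsFactors = FALSE)
  structure(list(stats = stats, scheme = scheme,
                 n_sequences = length(msa$ids)),
            class = "eva")
}

#' @export
print.eva <- function(x, ...) {
  cat(sprintf("<eva> %d columns (%d valid) from %d sequences\n",
              nrow(x$stats), sum(x$stats$valid), x$n_sequences))
  tb <- table(factor(x$stats$box, levels = c("11", "12", "22", "23", "33")))
  pct <- 100 * as.numeric(tb) / max(sum(tb), 1)
  cat("  box:  ", paste(sprintf("%s %s%%", names(tb), fmt_pct(pct)),
                        collapse = "  "), "\n")
  invisible(x)
}

#' @export
summary.eva <- function(object, ...) {
  s <- object$stats[object$stats$valid, ]
  tb <- table(factor(s$box, levels = c("11", "12", "22", "23", "33")))
  out <- list(n_columns = nrow(object$stats), n_valid = nrow(s),
              box_counts = tb, box_pct = 100 * as.numeric(tb) / nrow(s),
              mean_entropy = mean(s$entropy),
              mean_variability = mean(s$variability))
  class(out) <- "summary.eva"
  out
}

#' @export
print.summary.eva <- function(x, ...) {
  cat(sprintf("EVA summary: %d/%d valid columns\n", x$n_valid, x$n_columns))
  cat(sprintf("  mean entropy %.3f nats, mean variability %.2f\n",
              x$mean_entropy, x$mean_variability))
  for (i in seq_along(x$box_counts))
    cat(sprintf("  box %s: %4d (%s%%)\n", names(x$box_counts)[i],
                x$box_counts[i], fmt_pct(x$box_pct[i])))
  invisible(x)
}

#' EV plot of an analysis
#'
#' Variability against entropy, coloured by box, with the sector boundaries.
#'
#' @param x An `eva` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.eva <- function(x, ...) {
  s <- x$stats[x$stats$valid, ]
  graphics::plot(s$variability, s$entropy, col = s$color, pch = 19,
                 xlab = "variability (residue types > 0.5%)",
                 ylab = "entropy (nats)",
                 xlim = c(0, 20), ylim = c(0, log(20)), ...)
  sc <- x$scheme
  graphics::abline(v = c(sc$v_lo, sc$v_hi) + 0.5, lty = 2, col = "grey40")
  graphics::abline(h = c(sc$e_lo, sc$e_hi), lty = 2, col = "grey40")
  invisible(x)
}

REGION_ROWS <- c("all", "strand", "periplasmic", "extracellular",
                 "extracellular_long", "extracellular_short",
                 "constriction", "inward", "outward")
BOXES <- c("11", "12", "22", "23", "33")

#' Conservation-box distribution over structural regions
#'
#' Percentages of mapped residues per box, for the whole structure and for
#' each structural region: strands, periplasmic turns, extracellular loops
#' (split into long and short by [classify_long_loops()]), the constriction
#' loop, and inward/outward strand faces.
#'
#' @param eva An `eva` object.
#' @param map A `column_map` from [map_columns()].
#' @param annotation A `topology_annotation`.
#' @param orientation Optional output of [orient_residues()].
#' @param long_flags Optional output of [classify_long_loops()].
#' @param constriction Optional output of [detect_constriction_loop()].
#' @return A `region_box_table`: data frame of percentages (rows regions,
#'   columns boxes), counts in attribute `"counts"`.
#' @export
region_box_distribution <- function(eva, map, annotation,
                                    orientation = NULL, long_flags = NULL,
                                    constriction = NULL) {
  stopifnot(inherits(eva, "eva"), inherits(map, "column_map"))
  if (nrow(map) == 0) pe_stop("empty column map", "pe_empty_input")
  cov <- nrow(map) / nrow(annotation)
  if (cov < 0.5)
    warning(sprintf("mapped columns cover only %.0f%% of residues",
                    100 * cov))
  st <- eva$stats[match(map$column_index, eva$stats$column), ]
  d <- data.frame(residue = map$residue_index, box = st$box,
                  valid = st$valid, stringsAsFactors = FALSE)
  d <- d[d$valid & !is.na(d$box), ]
  lab <- annotation$label[d$residue]
  loop <- annotation$loop_index[d$residue]
  ori <- if (!is.null(orientation)) orientation[d$residue] else
    rep(NA_character_, nrow(d))
  long_of <- function(l) {
    if (is.null(long_flags)) return(NA)
    unname(long_flags[as.character(l)])
  }
  is_long <- vapply(loop, function(l)
    if (is.na(l)) NA else isTRUE(long_of(l)), logical(1))
  sel <- list(
    all = rep(TRUE, nrow(d)),
    strand = lab == "STRAND",
    periplasmic = lab == "PERIPLASMIC_TURN",
    extracellular = lab == "EXTRACELLULAR_LOOP",
    extracellular_long = lab == "EXTRACELLULAR_LOOP" & is_long %in% TRUE,
    extracellular_short = lab == "EXTRACELLULAR_LOOP" & is_long %in% FALSE,
    constriction = if (!is.null(constriction) && !is.na(constriction))
      lab == "EXTRACELLULAR_LOOP" & loop %in% constriction
      else rep(FALSE, nrow(d)),
    inward = ori %in% "INWARD",
    outward = ori %in% "OUTWARD")
  counts <- t(vapply(sel, function(s)
    as.numeric(table(factor(d$box[s], levels = BOXES))), numeric(5)))
  colnames(counts) <- BOXES
  pct <- counts / pmax(rowSums(counts), 1) * 100
  out <- as.data.frame(pct)
  out$region <- rownames(counts)
  out <- out[, c("region", BOXES)]
  rownames(out) <- NULL
  structure(out, counts = counts,
            class = c("region_box_table", "data.frame"))
}

#' @export
print.region_box_table <- function(x, ...) {
  y <- x
  for (b in BOXES) y[[b]] <- fmt_pct(y[[b]])
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Conserved-fraction summary for interface analysis
#'
#' Conserved means boxes 11 + 12 + 22. Reports the conserved fraction on the
#' inward (pore-facing) and outward (lipid- or interface-facing) strand
#' faces, on the extracellular loops and in the barrel, with the
#' inward-outward difference. Conserved outward-facing patches are the
#' sequence signature of oligomeric (trimer) interfaces, so the summary
#' flags them when the outward conserved fraction exceeds `floor`.
#'
#' @param table A `region_box_table`.
#' @param floor Flagging threshold for the outward conserved fraction
#'   (default 0.1).
#' @return A list: `inward`, `outward`, `difference`, `loops`, `barrel`
#'   (fractions in 0..1) and `outward_conserved` (logical flag).
#' @export
interface_conservation_summary <- function(table, floor = 0.1) {
  stopifnot(inherits(table, "region_box_table"))
  counts <- attr(table, "counts")
  conserved_frac <- function(row) {
    tot <- sum(counts[row, ])
    if (tot == 0) return(NA_real_)
    sum(counts[row, c("11", "12", "22")]) / tot
  }
  inward <- conserved_frac("inward")
  outward <- conserved_frac("outward")
  list(inward = inward, outward = outward,
       difference = inward - outward,
       loops = conserved_frac("extracellular"),
       barrel = conserved_frac("strand"),
       outward_conserved = isTRUE(!is.na(outward) && outward > floor))
}
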