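# Internal helpers: error conditions, residue tables, small geometry utilities.

pe_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "porineva_error", "error", "condition")))
}

#' Standard residue and van der Waals tables
#'
#' `default_vdw_radii()` returns the element-based van der Waals radius table
#' (Bondi-style values, in Angstrom) used when assigning radii to atoms. The
#' table is an ordinary named vector, so callers can edit entries and pass the
#' result to [read_structure()].
#'
#' @return Named numeric vector of radii in Angstrom, keyed by element symbol.
#'   The attribute `"default"` holds the fallback radius used for elements not
#'   in the table.
#' @examples
#' r <- default_vdw_radii()
#' r[["C"]]
#' @export
default_vdw_radii <- function() {
  r <- c(H = 1.20, D = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
         P = 1.80, SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
         FE = 2.00, ZN = 1.39, MG = 1.73, CA = 2.31, "NA" = 2.27, K = 2.75)
  attr(r, "default") <- 1.70
  r
}

.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")
.AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H",
          "I", "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
names(.AA1) <- .AA3
.AA3from1 <- stats::setNames(.AA3, .AA1)

.WATERS <- c("HOH", "WAT", "DOD", "H2O", "SOL")

aa_three_to_one <- function(x) {
  out <- unname(.AA1[x])
  out[is.na(out)] <- "X"
  out
}

aa_one_to_three <- function(x) {
  out <- unname(.AA3from1[x])
  out[is.na(out)] <- "UNK"
  out
}

vnorm <- function(v) sqrt(sum(v^2))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) pe_stop("degenerate zero-length vector", "pe_degenerate")
  v / n
}

# Rows of `x` (n x 3) projected on unit `axis` relative to `origin`.
axial_coord <- function(x, axis, origin) {
  as.numeric((x - matrix(origin, nrow(x), 3, byrow = TRUE)) %*% axis)
}

# Radial (perpendicular-to-axis) distances of rows of `x`.
radial_dist <- function(x, axis, origin) {
  d <- x - matrix(origin, nrow(x), 3, byrow = TRUE)
  ax <- as.numeric(d %*% axis)
  perp <- d - outer(ax, axis)
  sqrt(rowSums(perp^2))
}

# Orthonormal frame completing unit vector `axis` to a right-handed basis.
axis_frame <- function(axis) {
  axis <- unitv(axis)
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unitv(ref - sum(ref * axis) * axis)
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  list(axis = axis, e1 = e1, e2 = e2)
}

fmt_pct <- function(x) sprintf("%.1f", x)
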