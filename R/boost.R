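#' Per-frame boost-energy series
#'
#' Dual-boost aMD adds two boosts per frame: one on the dihedral energy
#' and one on the total potential. Both are stored in kcal/mol and must
#' be non-negative.
#'
#' @param dv_dihedral per-frame dihedral boost, kcal/mol.
#' @param dv_total per-frame total-potential boost, kcal/mol.
#' @return An object of class `boost_series`.
#' @export
boost_series <- function(dv_dihedral, dv_total) {
  dv_dihedral <- as.numeric(dv_dihedral)
  dv_total <- as.numeric(dv_total)
  if (length(dv_dihedral) != length(dv_total))
    stopf("dihedral and total boost series differ in length (%d vs %d)",
          length(dv_dihedral), length(dv_total))
  if (!length(dv_dihedral)) stopf("boost series is empty")
  if (any(!is.finite(dv_dihedral)) || any(!is.finite(dv_total)))
    stopf("boost energies must be finite")
  if (any(dv_dihedral < 0) || any(dv_total < 0))
    stopf("boost energies must be >= 0 kcal/mol")
  structure(list(dv_dihedral = dv_dihedral, dv_total = dv_total),
            class = "boost_series")
}

#' @export
print.boost_series <- function(x, ...) {
  cat(sprintf("boost_series: %d frames; <dV_dih> = %.3f, <dV_tot> = %.3f kcal/mol\n",
              length(x$dv_dihedral), mean(x$dv_dihedral), mean(x$dv_total)))
  invisible(x)
}

#' @export
length.boost_series <- function(x) length(x$dv_dihedral)

#' Read a per-frame boost-energy log
#'
#' Plain-text whitespace-separated log with a comment header (`#` or any
#' non-numeric leading line) followed by one row per frame. The column
#' map defaults to a two-column (dihedral, total) layout; `dialect =
#' "amber"` selects the AMBER amd.log layout, where the potential and
#' dihedral boosts are the 7th and 8th columns.
#'
#' @param path log file.
#' @param columns named integer vector `c(dihedral = , total = )` giving
#'   1-based column positions; overrides `dialect`.
#' @param dialect `"plain"` (columns 1, 2) or `"amber"` (columns 8, 7).
#' @return A [boost_series()] object.
#' @export
read_boost_log <- function(path, columns = NULL, dialect = c("plain", "amber")) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  dialect <- match.arg(dialect)
  if (is.null(columns))
    columns <- switch(dialect,
                      plain = c(dihedral = 1L, total = 2L),
                      amber = c(dihedral = 8L, total = 7L))
  if (!all(c("dihedral", "total") %in% names(columns)))
    stopf("columns must name both 'dihedral' and 'total'")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(trimws(lines), "#")]
  need <- max(columns)
  rows <- lapply(lines, function(ln) {
    flds <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(flds) < need) return(NULL)
    vals <- suppressWarnings(as.numeric(flds[columns[c("dihedral", "total")]]))
    if (anyNA(vals)) return(NULL)
    vals
  })
  bad <- vapply(rows, is.null, logical(1))
  if (any(bad) && !all(bad))
    warnf("skipped %d non-numeric row(s) in %s", sum(bad), path)
  rows <- rows[!bad]
  if (!length(rows)) stopf("no numeric boost rows in %s", path)
  m <- do.call(rbind, rows)
  boost_series(dv_dihedral = m[, 1], dv_total = m[, 2])
}

#' aMD boost functional
#'
#' The standard accelerated-MD boost: below the threshold `e` the
#' potential is raised by `dV = (e - v)^2 / (alpha + e - v)`; at or above
#' the threshold the boost is zero. Continuous and non-increasing in `v`.
#'
#' @param v instantaneous energy, kcal/mol (vectorized).
#' @param e boost threshold, kcal/mol.
#' @param alpha smoothing parameter, kcal/mol (> 0).
#' @return Boost energy dV >= 0, kcal/mol.
#' @export
boost_energy <- function(v, e, alpha) {
  if (!is.numeric(alpha) || alpha <= 0) stopf("alpha must be > 0")
  ifelse(v >= e, 0, (e - v)^2 / (alpha + e - v))
}

#' Dual-boost aMD parameters
#'
#' @param e_dih,alpha_dih dihedral boost threshold and smoothing, kcal/mol.
#' @param e_tot,alpha_tot total-potential boost threshold and smoothing.
#' @return An object of class `amd_params`.
#' @export
amd_params <- function(e_dih, alpha_dih, e_tot, alpha_tot) {
  if (alpha_dih <= 0 || alpha_tot <= 0) stopf("alpha parameters must be > 0")
  structure(list(e_dih = e_dih, alpha_dih = alpha_dih,
                 e_tot = e_tot, alpha_tot = alpha_tot),
            class = "amd_params")
}

#' @export
print.amd_params <- function(x, ...) {
  cat(sprintf(paste0("amd_params (kcal/mol):\n",
                     "  dihedral: E = %.3f, alpha = %.3f\n",
                     "  total:    E = %.3f, alpha = %.3f\n"),
              x$e_dih, x$alpha_dih, x$e_tot, x$alpha_tot))
  invisible(x)
}

#' Dual-boost parameter selection
#'
#' Sizes the dihedral boost by the number of freely movable backbone
#' dihedrals (threshold offset and smoothing per movable dihedral follow
#' the common aqueous-phase aMD convention and are overridable) and the
#' total-potential boost by the atom count. For DMSO, which has more
#' internal degrees of freedom than water or chloroform, the potential
#' threshold is raised to 0.56 kcal/mol per atom above the average
#' unbiased potential; aqueous-like solvents use 0.2 kcal/mol per atom.
#'
#' @param avg_dihedral_energy average unbiased dihedral energy, kcal/mol.
#' @param avg_total_potential average unbiased total potential, kcal/mol.
#' @param n_free_backbone_dihedrals number of freely movable backbone
#'   dihedrals (>= 0).
#' @param n_atoms total atom count of the solvated system (> 0).
#' @param solvent_class `"aqueous_like"` or `"dmso"`.
#' @param dih_offset,dih_alpha threshold offset and smoothing per movable
#'   dihedral, kcal/mol.
#' @param tot_coeff_aqueous,tot_coeff_dmso per-atom potential-threshold
#'   coefficients, kcal/mol.
#' @param tot_alpha_coeff per-atom smoothing coefficient, kcal/mol.
#' @return An [amd_params()] object.
#' @export
dual_boost_params <- function(avg_dihedral_energy, avg_total_potential,
                              n_free_backbone_dihedrals, n_atoms,
                              solvent_class = c("aqueous_like", "dmso"),
                              dih_offset = 3.5, dih_alpha = 3.5 / 5,
                              tot_coeff_aqueous = 0.2, tot_coeff_dmso = 0.56,
                              tot_alpha_coeff = 0.2) {
  solvent_class <- match.arg(solvent_class)
  if (n_atoms <= 0) stopf("n_atoms must be > 0")
  if (n_free_backbone_dihedrals < 0)
    stopf("n_free_backbone_dihedrals must be >= 0")
  coeff <- if (solvent_class == "dmso") tot_coeff_dmso else tot_coeff_aqueous
  nd <- n_free_backbone_dihedrals
  amd_params(
    e_dih = avg_dihedral_energy + dih_offset * nd,
    # with no movable dihedrals the window is zero; keep alpha positive
    alpha_dih = if (nd > 0) dih_alpha * nd else dih_alpha,
    e_tot = avg_total_potential + coeff * n_atoms,
    alpha_tot = tot_alpha_coeff * n_atoms)
}
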