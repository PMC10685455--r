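#' Per-conformer partial charges
#'
#' One partial charge per atom, elementary charge units, tagged with a
#' conformer identifier.
#'
#' @param charges numeric vector, one charge per atom.
#' @param conformer_id identifying string.
#' @return An object of class `charge_set`.
#' @export
charge_set <- function(charges, conformer_id = "conformer") {
  charges <- as.numeric(charges)
  if (!length(charges)) stopf("charge set is empty")
  if (any(!is.finite(charges))) stopf("charges must be finite")
  structure(list(charges = charges, conformer_id = as.character(conformer_id)),
            class = "charge_set")
}

#' @export
print.charge_set <- function(x, ...) {
  cat(sprintf("charge_set '%s': %d atoms, total %+.4f e\n",
              x$conformer_id, length(x$charges), sum(x$charges)))
  invisible(x)
}

#' Read a plain-text charge table
#'
#' One float per line; lines beginning with `#` are ignored.
#'
#' @param path charge table file.
#' @param conformer_id identifier (defaults to the file name).
#' @return A [charge_set()] object.
#' @export
read_charges <- function(path, conformer_id = basename(path)) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stopf("no charges in %s", path)
  vals <- suppressWarnings(as.numeric(lines))
  if (anyNA(vals)) stopf("non-numeric charge line in %s", path)
  charge_set(vals, conformer_id)
}

#' Write a charge table
#' @param set a [charge_set()] object.
#' @param path output file.
#' @export
write_charges <- function(set, path) {
  writeLines(c(sprintf("# %s", set$conformer_id),
               sprintf("%.6f", set$charges)), path)
  invisible(path)
}

check_charge_sets <- function(sets, min_sets = 1L) {
  if (!length(sets) || length(sets) < min_sets)
    stopf("need at least %d charge set(s)", min_sets)
  lens <- vapply(sets, function(s) length(s$charges), integer(1))
  if (length(unique(lens)) != 1L)
    stopf("charge sets differ in atom count: %s", paste(lens, collapse = ", "))
  invisible(lens[1])
}

#' Conformer-averaged partial charges
#'
#' Element-wise arithmetic mean over conformers. Averaging over several
#' (typically 10) independently generated conformations damps the
#' conformation dependence of charges fitted to any single — possibly
#' high-free-energy — structure.
#'
#' @param sets list of [charge_set()] objects with identical atom
#'   ordering.
#' @param expected_n conformer count below which a warning is issued
#'   (default 10).
#' @return A [charge_set()] with `conformer_id = "averaged(n)"`.
#' @export
average_charges <- function(sets, expected_n = 10) {
  check_charge_sets(sets)
  if (length(sets) < expected_n)
    warnf("averaging over %d conformers (< %d)", length(sets), expected_n)
  m <- vapply(sets, function(s) s$charges, numeric(length(sets[[1]]$charges)))
  m <- matrix(m, ncol = length(sets))
  charge_set(rowMeans(m), sprintf("averaged(%d)", length(sets)))
}

#' Validate a charge set against the molecular formal charge
#'
#' @param set a [charge_set()] object.
#' @param formal_charge integer formal charge, elementary units.
#' @param tol allowed deviation of the charge sum (default 1e-4 e).
#' @param outlier_mag per-atom magnitude beyond which an atom is listed
#'   as an outlier (default 1.5 e).
#' @return List with `pass`, `deviation`, `total`, and `outliers` (atom
#'   indices).
#' @export
validate_charges <- function(set, formal_charge, tol = 1e-4,
                             outlier_mag = 1.5) {
  total <- sum(set$charges)
  deviation <- abs(total - formal_charge)
  list(pass = deviation <= tol, deviation = deviation, total = total,
       outliers = which(abs(set$charges) > outlier_mag))
}

#' Per-atom charge spread across conformers
#'
#' Sample standard deviation of each atom's charge over the conformer
#' set — a diagnostic for how conformation-dependent each fitted charge
#' is.
#'
#' @param sets list of at least two [charge_set()] objects.
#' @return List with `sd` (per-atom) and `ranking` (atom indices by
#'   decreasing spread).
#' @export
charge_spread <- function(sets) {
  check_charge_sets(sets, min_sets = 2L)
  m <- vapply(sets, function(s) s$charges, numeric(length(sets[[1]]$charges)))
  m <- matrix(m, ncol = length(sets))
  sds <- apply(m, 1, stats::sd)
  list(sd = sds, ranking = order(sds, decreasing = TRUE))
}
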