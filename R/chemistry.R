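# Physicochemical classification of the 20 canonical amino acids and of
# wild-type -> mutant substitutions. The category sets are fixed: hydrophobic
# vs polar and small vs large each partition the 20 residues; aromatic /
# aliphatic and positive / negative cover only part of the alphabet, so a
# substitution carries a label on those axes only when both residues do.
# Note Lys is listed as aliphatic here (its long methylene side chain),
# which departs from some textbook groupings; the whole table is kept as a
# single authoritative constant so tests can assert it residue by residue.

#' The 20 canonical amino acids (one-letter codes)
#' @format Character vector of length 20, alphabetical.
#' @export
AA_CANONICAL <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.aa_sets <- list(
  hydrophobic = c("A", "C", "G", "I", "L", "M", "F", "P", "W", "V"),
  polar       = c("D", "E", "K", "R", "H", "N", "Q", "S", "T", "Y"),
  aromatic    = c("H", "F", "W", "Y"),
  aliphatic   = c("A", "I", "K", "L", "M", "P", "V"),
  positive    = c("H", "K", "R"),
  negative    = c("D", "E"),
  small       = c("A", "C", "G", "S", "N", "D", "P", "T", "V"),
  large       = c("R", "Q", "E", "H", "I", "L", "K", "M", "F", "W", "Y")
)

#' Amino-acid chemistry category sets
#'
#' Returns the fixed category sets used throughout the package:
#' `hydrophobic`/`polar` (a partition of the 20 residues),
#' `small`/`large` (a partition), `aromatic`/`aliphatic` (partial, disjoint)
#' and `positive`/`negative` (partial, disjoint).
#'
#' @return Named list of character vectors of one-letter codes.
#' @examples
#' aa_chemistry()$aromatic
#' @export
aa_chemistry <- function() .aa_sets

.check_canonical <- function(aa, arg = "aa") {
  bad <- !(aa %in% AA_CANONICAL)
  if (any(bad)) {
    stop(sprintf("%s contains non-canonical residue(s): %s", arg,
                 paste(unique(aa[bad]), collapse = ", ")), call. = FALSE)
  }
  invisible(aa)
}

# Per-axis lookup vectors, NA where the axis does not apply.
.axis_lookup <- local({
  mk <- function(a, b) {
    v <- rep(NA_character_, 20)
    names(v) <- AA_CANONICAL
    v[.aa_sets[[a]]] <- a
    v[.aa_sets[[b]]] <- b
    v
  }
  list(hydropathy = mk("hydrophobic", "polar"),
       size       = mk("small", "large"),
       ring       = mk("aromatic", "aliphatic"),
       charge     = mk("positive", "negative"))
})

#' Chemistry categories of one residue
#'
#' @param aa Single one-letter amino-acid code (canonical).
#' @return Character vector of category names: exactly one of
#'   hydrophobic/polar, exactly one of small/large, zero or one of
#'   aromatic/aliphatic, zero or one of positive/negative.
#' @examples
#' classify_residue("W") # hydrophobic, aromatic, large
#' @export
classify_residue <- function(aa) {
  if (length(aa) != 1L) stop("classify_residue() takes a single residue", call. = FALSE)
  .check_canonical(aa)
  out <- c(.axis_lookup$hydropathy[[aa]], .axis_lookup$ring[[aa]],
           .axis_lookup$charge[[aa]], .axis_lookup$size[[aa]])
  out[!is.na(out)]
}

#' Substitution-pair categories of a wild-type -> mutant change
#'
#' Labels are directional (`"negative-positive"` and `"positive-negative"`
#' are distinct categories). The aromatic/aliphatic and charge labels are
#' emitted only when both residues carry a label on that axis.
#'
#' @param wt,mut One-letter codes, `wt != mut`.
#' @return Character vector of `"wtcat-mutcat"` labels: one hydropathy pair,
#'   one size pair, and optionally a ring and a charge pair.
#' @examples
#' substitution_categories("D", "K") # polar-polar, small-large, negative-positive
#' @export
substitution_categories <- function(wt, mut) {
  if (length(wt) != 1L || length(mut) != 1L) {
    stop("substitution_categories() takes single residues", call. = FALSE)
  }
  .check_canonical(wt, "wt"); .check_canonical(mut, "mut")
  if (wt == mut) stop("wt and mut must differ", call. = FALSE)
  out <- character(0)
  for (axis in c("hydropathy", "size", "ring", "charge")) {
    a <- .axis_lookup[[axis]][[wt]]
    b <- .axis_lookup[[axis]][[mut]]
    if (!is.na(a) && !is.na(b)) out <- c(out, paste(a, b, sep = "-"))
  }
  out
}

# Vectorized per-axis pair labels for annotation; NA where the axis is absent.
.pair_label <- function(wt, mut, axis) {
  a <- .axis_lookup[[axis]][wt]
  b <- .axis_lookup[[axis]][mut]
  ifelse(is.na(a) | is.na(b), NA_character_, paste(a, b, sep = "-"))
}
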