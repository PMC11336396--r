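# IUPAC nucleotide codes as bitmasks over {A=1, C=2, G=4, T=8}.
# The gap character maps to 0 so "no base" never intersects a base set.

IUPAC_MASK <- c(
  A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
  R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
  B = 14L, D = 13L, H = 11L, V = 7L, N = 15L,
  `-` = 0L
)

IUPAC_LETTERS <- setdiff(names(IUPAC_MASK), c("U", "-"))

#' Expand an IUPAC code to the set of bases it denotes
#'
#' @param code Single IUPAC letter (case-insensitive).
#' @return Character vector of plain bases ("A","C","G","T").
#' @examples
#' iupac_bases("R")
#' @export
iupac_bases <- function(code) {
  m <- iupac_mask(code)
  c("A", "C", "G", "T")[bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0L]
}

iupac_mask <- function(x) {
  m <- IUPAC_MASK[toupper(x)]
  if (anyNA(m)) {
    bad <- unique(x[is.na(m)])
    stop("character(s) outside the IUPAC DNA alphabet: ",
         paste(shQuote(bad), collapse = ", "), call. = FALSE)
  }
  unname(m)
}

# residues string -> integer mask vector (vectorised over characters)
mask_vector <- function(residues) {
  iupac_mask(strsplit(residues, "", fixed = TRUE)[[1]])
}

is_ambiguity_mask <- function(m) {
  m != 0L & !(m %in% c(1L, 2L, 4L, 8L))
}

#' Does a degenerate primer code cover a target base?
#'
#' A primer position matches a template base when the base's set is a
#' subset of the primer code's set, i.e. the primer degeneracy covers
#' every reading of the template. A template `N` (any base) is therefore
#' only covered by a primer `N`; set `target_n_matches = TRUE` to treat
#' template `N` as compatible with everything.
#'
#' @param primer_code IUPAC letter(s) on the primer (vectorised).
#' @param target_base IUPAC letter(s) on the template.
#' @param target_n_matches Treat a template `N` as always compatible.
#' @return Logical vector.
#' @examples
#' iupac_compatible("R", "A")  # TRUE
#' iupac_compatible("R", "C")  # FALSE
#' @export
iupac_compatible <- function(primer_code, target_base, target_n_matches = FALSE) {
  p <- iupac_mask(primer_code)
  t <- iupac_mask(target_base)
  ok <- bitwAnd(p, t) == t & t != 0L
  if (target_n_matches) ok[t == 15L] <- TRUE
  ok
}
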