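# Printed-diagnosis text: "ITS2 positions 127–146 gaaccgcaaattacgcatta,
# one mismatch allowed". Ranges use an en-dash; the allowance is worded
# ("no"/"one") for 0 and 1 mismatches.

EN_DASH <- "–"

allowance_word <- function(k) {
  words <- c("no", "one", "two", "three", "four", "five")
  ifelse(k >= 0 & k < length(words), words[k + 1L], as.character(k))
}

#' Format one diagnosis fragment
#'
#' The parenthetical fragment of a printed diagnosis:
#' `[<prefix> ]positions <a>-<b> <barcode><sep><word> mismatch(es) allowed`
#' with an en-dash in the range. `sep` is `"; "` in most diagnoses and
#' `", "` in a few.
#'
#' @param start,end 1-based inclusive region-relative positions.
#' @param barcode Barcode string (printed lower-case).
#' @param allowance Integer mismatch allowance.
#' @param prefix Region prefix (`"ITS2"`, `"5.8S"`, ... or `""` when the
#'   printed diagnosis omits it).
#' @param sep `"semicolon"` or `"comma"`.
#' @return Character scalar.
#' @examples
#' format_fragment(127, 146, "gaaccgcaaattacgcatta", 1, prefix = "ITS2",
#'                 sep = "comma")
#' @export
format_fragment <- function(start, end, barcode, allowance, prefix = "",
                            sep = c("semicolon", "comma")) {
  sep <- match.arg(sep)
  sp <- if (sep == "semicolon") "; " else ", "
  plural <- ifelse(allowance > 1, "es", "")
  paste0(
    ifelse(nzchar(prefix), paste0(prefix, " "), ""),
    "positions ", start, EN_DASH, end, " ", tolower(barcode), sp,
    allowance_word(allowance), " mismatch", plural, " allowed"
  )
}

#' Parse a printed diagnosis fragment
#'
#' Inverse of [format_fragment()].
#'
#' @param text Fragment text.
#' @return One-row tibble with `prefix`, `start`, `end`, `barcode`,
#'   `allowance`, `sep`.
#' @export
parse_fragment <- function(text) {
  pat <- paste0("^(?:(\\S+) )?positions (\\d+)", EN_DASH,
                "(\\d+) ([a-z]+)(;|,) (\\S+) mismatch(?:es)? allowed$")
  m <- stringr::str_match(text, pat)
  if (is.na(m[1, 1])) stop("unparseable diagnosis fragment: ", text,
                           call. = FALSE)
  word <- m[1, 7]
  words <- c(no = 0L, one = 1L, two = 2L, three = 3L, four = 4L, five = 5L)
  k <- if (word %in% names(words)) words[[word]] else as.integer(word)
  tibble::tibble(
    prefix = ifelse(is.na(m[1, 2]), "", m[1, 2]),
    start = as.integer(m[1, 3]), end = as.integer(m[1, 4]),
    barcode = m[1, 5],
    allowance = k,
    sep = ifelse(m[1, 6] == ";", "semicolon", "comma")
  )
}

#' Format a full diagnosis sentence
#'
#' Renders the fixed sentence used in species diagnoses: separation from
#' a sibling scope based on the ITS region and, when available, LSU.
#'
#' @param diagnoses A `dna_diagnosis` tibble (rows for ITS-side regions
#'   and/or `"LSU"`).
#' @param scope Sibling scope phrase, e.g. `"other species of Hoforsa"`.
#' @param lsu_scope Optional distinct scope phrase for the LSU clause.
#' @param sep Fragment separator style.
#' @return Character scalar.
#' @export
format_diagnosis <- function(diagnoses, scope, lsu_scope = NULL,
                             sep = c("semicolon", "comma")) {
  sep <- match.arg(sep)
  its <- diagnoses[diagnoses$region != "LSU", , drop = FALSE]
  lsu <- diagnoses[diagnoses$region == "LSU", , drop = FALSE]
  frag <- function(row, prefix) {
    format_fragment(row$start, row$end, row$barcode, row$allowance,
                    prefix = prefix, sep = sep)
  }
  parts <- character()
  if (nrow(its) > 0L) {
    r <- its[1, ]
    prefix <- if (r$region %in% c("ITS", "full")) "" else r$region
    parts <- c(parts, paste0("based on the ITS region (", frag(r, prefix), ")"))
  }
  if (nrow(lsu) > 0L) {
    r <- lsu[1, ]
    clause <- paste0("LSU (", frag(r, ""), ")")
    if (!is.null(lsu_scope)) {
      clause <- paste0("from ", lsu_scope, " based on ", clause)
    }
    parts <- c(parts, clause)
  }
  if (length(parts) == 0L) stop("no diagnoses to format", call. = FALSE)
  paste0("Separation from ", scope, " ", paste(parts, collapse = " and "), ".")
}

#' Packaged transcription of the printed species diagnoses
#'
#' The 29 parenthetical barcode fragments printed for the 15 described
#' species (one species has an ITS barcode only), with their parsed
#' parameters and a provenance column. Known internal inconsistencies of
#' the printed material (position spans not matching barcode lengths; one
#' barcode string shared by two genera) are preserved verbatim so that
#' [validate_diagnosis()] can flag them.
#'
#' @return Tibble with columns `species`, `genus`, `marker`, `prefix`,
#'   `start`, `end`, `barcode`, `allowance`, `sep`, `fragment`,
#'   `provenance`.
#' @export
load_printed_diagnoses <- function() {
  path <- system.file("extdata", "printed_diagnoses.tsv", package = "dnadiag",
                      mustWork = TRUE)
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(start = "i", end = "i",
                                                 allowance = "i", .default = "c"))
  out$prefix[is.na(out$prefix)] <- ""
  out
}
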