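# In-silico primer screening: IUPAC-aware best placement per sequence,
# mismatch positions indexed from the 3' end and classified as terminal,
# near-terminal or central, then summarised per lineage.

revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", U = "A",
            R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
            B = "V", D = "H", H = "D", V = "B", N = "N", `-` = "-")
  vapply(x, function(s) {
    ch <- rev(strsplit(toupper(s), "", fixed = TRUE)[[1]])
    paste(comp[ch], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Read a primer table
#'
#' TSV with columns `name`, `sequence` (IUPAC, 5'->3'), `orientation`
#' (`forward`/`reverse`) and `target_region`. The packaged table
#' (`system.file("extdata", "primers.tsv", package = "dnadiag")`) carries
#' the three primer sequences published with this marker system
#' (LF350End, LR3-End2, LR3-End2a) and named placeholder rows, with
#' empty sequences, for the other commonly screened SSU/ITS/LSU primers,
#' whose sequences users must supply from the literature.
#'
#' @param source Path to a TSV (default: the packaged table).
#' @return Tibble; placeholder rows (empty sequence) are kept but
#'   flagged in `has_sequence`.
#' @export
read_primers <- function(source = NULL) {
  if (is.null(source)) {
    source <- system.file("extdata", "primers.tsv", package = "dnadiag",
                          mustWork = TRUE)
  }
  p <- readr::read_tsv(source, show_col_types = FALSE,
                       col_types = readr::cols(.default = "c"))
  stopifnot(all(c("name", "sequence", "orientation") %in% names(p)))
  p$sequence <- toupper(ifelse(is.na(p$sequence), "", p$sequence))
  p$has_sequence <- nzchar(p$sequence)
  bad <- p$has_sequence &
    (!grepl(sprintf("^[%s]+$", paste(IUPAC_LETTERS, collapse = "")), p$sequence) |
       nchar(p$sequence) < 10L)
  if (any(bad)) {
    stop("invalid primer sequence(s): ", paste(p$name[bad], collapse = ", "),
         " (IUPAC letters only, length >= 10)", call. = FALSE)
  }
  p
}

#' Classify a mismatch position relative to the primer 3' end
#'
#' Position 1 is the 3'-terminal base -- the critical one for extension;
#' positions 2..`near_window` are near-terminal; the rest central.
#'
#' @param pos_from_3prime Integer position(s), 1 = 3' terminus.
#' @param near_window Last position still counted near-terminal
#'   (default 3).
#' @return Character vector in `{"terminal","near_terminal","central"}`.
#' @export
classify_position <- function(pos_from_3prime, near_window = 3L) {
  stopifnot(all(pos_from_3prime >= 1L))
  dplyr::case_when(
    pos_from_3prime == 1L ~ "terminal",
    pos_from_3prime <= near_window ~ "near_terminal",
    TRUE ~ "central"
  )
}

#' Best primer placement on one sequence
#'
#' Slides the primer along the degapped sequence (reverse primers are
#' matched against the reverse complement, so the reported offset is
#' strand-resolved) and keeps the placement with the fewest
#' IUPAC-incompatible positions, ties resolved towards the smallest
#' offset. Mismatch positions are indexed from the primer's 3' end and
#' classified via [classify_position()].
#'
#' @param primer_sequence IUPAC primer string (5'->3').
#' @param sequence Template sequence (gaps are removed).
#' @param orientation `"forward"` or `"reverse"`.
#' @param near_window Passed to [classify_position()].
#' @param target_n_matches Treat template `N` as matching (see
#'   [iupac_compatible()]).
#' @return One-row tibble: `offset`, `mismatch_count`,
#'   `mismatch_positions_from_3prime` (list-column), `n_terminal`,
#'   `n_near_terminal`, `n_central`, `no_site` flag.
#' @export
best_site <- function(primer_sequence, sequence,
                      orientation = c("forward", "reverse"),
                      near_window = 3L, target_n_matches = FALSE) {
  orientation <- match.arg(orientation)
  pr <- toupper(primer_sequence)
  seq <- gsub("-", "", toupper(sequence), fixed = TRUE)
  if (orientation == "reverse") seq <- revcomp(seq)
  np <- nchar(pr)
  ns <- nchar(seq)
  if (ns < np) {
    return(tibble::tibble(offset = NA_integer_, mismatch_count = NA_integer_,
                          mismatch_positions_from_3prime = list(integer()),
                          n_terminal = NA_integer_, n_near_terminal = NA_integer_,
                          n_central = NA_integer_, no_site = TRUE))
  }
  pch <- strsplit(pr, "", fixed = TRUE)[[1]]
  sch <- strsplit(seq, "", fixed = TRUE)[[1]]
  pm <- iupac_mask(pch)
  sm <- iupac_mask(sch)
  compat_base <- outer(pm, sm, function(p, t) bitwAnd(p, t) == t & t != 0L)
  if (target_n_matches) compat_base[, sm == 15L] <- TRUE
  offsets <- seq_len(ns - np + 1L)
  counts <- vapply(offsets, function(o) {
    sum(!compat_base[cbind(seq_len(np), o + seq_len(np) - 1L)])
  }, integer(1))
  best <- offsets[which.min(counts)]  # which.min takes the first = smallest offset
  hit <- !compat_base[cbind(seq_len(np), best + seq_len(np) - 1L)]
  pos3 <- np - which(hit) + 1L
  cls <- classify_position(pos3, near_window)
  tibble::tibble(
    offset = best, mismatch_count = as.integer(sum(hit)),
    mismatch_positions_from_3prime = list(sort(pos3)),
    n_terminal = sum(cls == "terminal"),
    n_near_terminal = sum(cls == "near_terminal"),
    n_central = sum(cls == "central"),
    no_site = FALSE
  )
}

#' Screen primers against every sequence of an alignment
#'
#' @param aln A `dna_alignment`.
#' @param primers Primer tibble from [read_primers()] (placeholder rows
#'   without a sequence are skipped with a warning).
#' @inheritParams best_site
#' @return Tibble of per-sequence hits: `primer`, `accession`, plus the
#'   [best_site()] columns.
#' @export
screen_primers <- function(aln, primers, near_window = 3L,
                           target_n_matches = FALSE) {
  if (!"has_sequence" %in% names(primers)) {
    primers$has_sequence <- nzchar(primers$sequence)
  }
  skipped <- primers$name[!primers$has_sequence]
  if (length(skipped)) {
    warning("skipping primer(s) without a sequence: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }
  primers <- primers[primers$has_sequence, , drop = FALSE]
  purrr::pmap_dfr(
    list(primers$name, primers$sequence, primers$orientation),
    function(nm, sq, ori) {
      hits <- purrr::map2_dfr(aln$accession, aln$sequence, function(acc, s) {
        dplyr::bind_cols(tibble::tibble(accession = acc),
                         best_site(sq, s, orientation = ori,
                                   near_window = near_window,
                                   target_n_matches = target_n_matches))
      })
      dplyr::bind_cols(tibble::tibble(primer = nm), hits)
    }
  )
}

#' Summarise primer mismatches per taxonomic group
#'
#' For each primer and group: the fraction of sequences matched with no
#' mismatch, with at least one terminal or near-terminal mismatch, the
#' median mismatch count, and a verdict -- `"matches well"` when at
#' least `well_fraction` of the group has at most one mismatch and none
#' of those mismatches is (near-)terminal, else `"potential bias"`.
#'
#' @param hits Output of [screen_primers()].
#' @param taxa Data frame mapping `accession` to rank columns.
#' @param rank Grouping rank (default `"order"`).
#' @param well_fraction Threshold for the verdict (default 0.9).
#' @return Tibble, one row per primer x group.
#' @export
group_summary <- function(hits, taxa, rank = "order", well_fraction = 0.9) {
  grp <- taxa[[rank]][match(hits$accession, taxa$accession)]
  hits$group <- grp
  empty <- is.na(grp) | hits$no_site
  if (any(empty)) {
    warning(sum(empty), " hit(s) dropped (unmapped accession or no site)",
            call. = FALSE)
  }
  hits <- hits[!empty, , drop = FALSE]
  out <- hits |>
    dplyr::group_by(.data$primer, .data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      fraction_zero = mean(.data$mismatch_count == 0L),
      fraction_terminal = mean(.data$n_terminal >= 1L),
      fraction_near_terminal = mean(.data$n_near_terminal >= 1L),
      median_mismatches = stats::median(.data$mismatch_count),
      fraction_central_only_le1 = mean(.data$mismatch_count <= 1L &
                                         .data$n_terminal == 0L &
                                         .data$n_near_terminal == 0L),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      verdict = ifelse(.data$fraction_central_only_le1 >= well_fraction,
                       "matches well", "potential bias")
    )
  out
}
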