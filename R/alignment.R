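#' Read a labelled multiple sequence alignment
#'
#' Reads an aligned FASTA (gap character `-`) together with a taxon map
#' TSV (`accession<TAB>species<TAB>genus<TAB>family<TAB>order`, header
#' required, empty cells allowed) into a tidy alignment: one row per
#' sequence with its taxonomy labels and the aligned residue string.
#'
#' Residues are case-folded to upper case and `U` is mapped to `T`.
#' The accession is the first whitespace-delimited token of the FASTA
#' header. Accessions missing from the taxon map are kept with `NA`
#' labels and flagged via the `mapped` column.
#'
#' @param fasta_source Path to an aligned FASTA file.
#' @param taxonmap_source Path to the taxon map TSV, or a data frame with
#'   an `accession` column; `NULL` leaves all labels `NA`.
#' @return A tibble of class `dna_alignment` with columns `accession`,
#'   `species`, `genus`, `family`, `order`, `mapped`, `sequence`, and an
#'   `n_columns` attribute.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "ACGT-ACGTA", ">s2", "ACGTTACGTA"), fa)
#' aln <- read_alignment(fa)
#' n_columns(aln)
#' @export
read_alignment <- function(fasta_source, taxonmap_source = NULL) {
  seqs <- Biostrings::readBStringSet(fasta_source)
  if (length(seqs) < 2L) {
    stop("alignment must contain at least 2 sequences", call. = FALSE)
  }
  acc <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  residues <- toupper(as.character(seqs))
  residues <- gsub("U", "T", residues, fixed = TRUE)
  names(residues) <- NULL
  alignment_from_strings(acc, residues, taxonmap = taxonmap_source)
}

#' Build an alignment tibble from residue strings
#'
#' Programmatic constructor behind [read_alignment()]; useful for
#' simulations and tests.
#'
#' @param accession Character vector of unique identifiers.
#' @param residues Character vector of aligned residue strings (equal
#'   lengths, IUPAC codes plus `-`).
#' @param taxonmap Optional data frame (or TSV path) mapping `accession`
#'   to `species`, `genus`, `family`, `order`.
#' @return A `dna_alignment` tibble.
#' @export
alignment_from_strings <- function(accession, residues, taxonmap = NULL) {
  stopifnot(length(accession) == length(residues))
  if (anyDuplicated(accession)) {
    stop("duplicated accession(s): ",
         paste(unique(accession[duplicated(accession)]), collapse = ", "),
         call. = FALSE)
  }
  residues <- gsub("U", "T", toupper(residues), fixed = TRUE)
  lens <- nchar(residues)
  if (length(unique(lens)) > 1L) {
    tab <- table(lens)
    # modal length wins; ties resolve to the longer (shorter reads are
    # the usual defect), so the error names the short record
    ref <- as.integer(names(tab)[order(-tab, -as.integer(names(tab)))][1])
    bad <- accession[lens != ref]
    stop("ragged alignment: sequence length differs for ",
         paste(bad, collapse = ", "), " (expected ", ref, " columns)",
         call. = FALSE)
  }
  if (lens[1] == 0L) stop("empty sequences", call. = FALSE)
  ok <- grepl(sprintf("^[%s-]*$", paste(IUPAC_LETTERS, collapse = "")), residues)
  if (!all(ok)) {
    first_bad <- which(!ok)[1]
    col <- regexpr(sprintf("[^%s-]", paste(IUPAC_LETTERS, collapse = "")),
                   residues[first_bad])
    stop("illegal character in ", accession[first_bad],
         " at alignment column ", as.integer(col), call. = FALSE)
  }

  tm <- read_taxon_map(taxonmap)
  out <- tibble::tibble(accession = accession) |>
    dplyr::left_join(tm, by = "accession") |>
    dplyr::mutate(
      mapped = .data$accession %in% tm$accession,
      sequence = residues
    )
  attr(out, "n_columns") <- lens[1]
  class(out) <- c("dna_alignment", class(tibble::tibble()))
  out
}

read_taxon_map <- function(taxonmap) {
  ranks <- c("species", "genus", "family", "order")
  if (is.null(taxonmap)) {
    tm <- tibble::tibble(accession = character())
  } else if (is.character(taxonmap) && length(taxonmap) == 1L) {
    tm <- readr::read_tsv(taxonmap, show_col_types = FALSE,
                          col_types = readr::cols(.default = "c"))
  } else {
    tm <- tibble::as_tibble(taxonmap)
  }
  if (!"accession" %in% names(tm)) {
    stop("taxon map must have an 'accession' column", call. = FALSE)
  }
  for (r in ranks) if (!r %in% names(tm)) tm[[r]] <- NA_character_
  tm[, c("accession", ranks)]
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat(sprintf("# A dna_alignment: %d sequences x %d columns\n",
              nrow(x), n_columns(x)))
  NextMethod()
}

#' Number of alignment columns
#' @param aln A `dna_alignment`.
#' @return Integer.
#' @export
n_columns <- function(aln) {
  nc <- attr(aln, "n_columns")
  if (is.null(nc)) nc <- unique(nchar(aln$sequence))[1]
  as.integer(nc)
}

#' Write an alignment back to FASTA (+ optional taxon map TSV)
#'
#' @param aln A `dna_alignment`.
#' @param fasta_path Output FASTA path.
#' @param taxonmap_path Optional output TSV path.
#' @return `fasta_path`, invisibly.
#' @export
write_alignment <- function(aln, fasta_path, taxonmap_path = NULL) {
  x <- Biostrings::BStringSet(aln$sequence)
  names(x) <- aln$accession
  Biostrings::writeXStringSet(x, fasta_path)
  if (!is.null(taxonmap_path)) {
    readr::write_tsv(
      aln[, c("accession", "species", "genus", "family", "order")],
      taxonmap_path
    )
  }
  invisible(fasta_path)
}

# ---- region maps -----------------------------------------------------------

#' Read a region map (ITS1 / 5.8S / ITS2 / LSU ... boundaries)
#'
#' Accepts a JSON file (`{"ITS1": [1, 120], ...}` or
#' `{"ITS1": {"start": 1, "end": 120}}`), a TSV with columns
#' `region`, `start`, `end`, or a data frame in the same shape.
#' Coordinates are 1-based inclusive alignment columns.
#'
#' @param source Path or data frame.
#' @param n_columns Optional alignment width used to validate bounds and
#'   to supply an implicit `full` region.
#' @return A tibble with columns `region`, `start`, `end`.
#' @export
read_region_map <- function(source, n_columns = NULL) {
  if (is.data.frame(source)) {
    rm <- tibble::as_tibble(source)
  } else if (grepl("\\.json$", source, ignore.case = TRUE)) {
    raw <- jsonlite::read_json(source, simplifyVector = TRUE)
    rm <- purrr::imap_dfr(raw, function(v, nm) {
      v <- unlist(v)
      tibble::tibble(region = nm, start = as.integer(v[[1]]), end = as.integer(v[[2]]))
    })
  } else {
    rm <- readr::read_tsv(source, show_col_types = FALSE)
  }
  rm <- dplyr::mutate(rm, start = as.integer(.data$start), end = as.integer(.data$end))
  validate_region_map(rm, n_columns)
}

validate_region_map <- function(rm, n_columns = NULL) {
  stopifnot(all(c("region", "start", "end") %in% names(rm)))
  if (any(rm$start < 1L) || any(rm$end < rm$start)) {
    stop("region map coordinates must satisfy 1 <= start <= end", call. = FALSE)
  }
  if (!is.null(n_columns) && any(rm$end > n_columns)) {
    stop("region map exceeds alignment width (", n_columns, " columns)",
         call. = FALSE)
  }
  sub <- rm[rm$region != "full", , drop = FALSE]
  if (nrow(sub) > 1L) {
    o <- order(sub$start)
    if (any(sub$start[o][-1] <= sub$end[o][-nrow(sub)])) {
      stop("region map regions overlap", call. = FALSE)
    }
  }
  rm[, c("region", "start", "end")]
}

# columns (integer vector) covered by a region name
region_columns <- function(regions, region, n_columns) {
  if (identical(region, "full")) {
    if ("full" %in% regions$region) {
      r <- regions[regions$region == "full", ]
      return(seq.int(r$start[1], r$end[1]))
    }
    return(seq_len(n_columns))
  }
  hit <- regions[regions$region == region, ]
  if (nrow(hit) == 0L) {
    stop("region ", shQuote(region), " not defined in the region map",
         call. = FALSE)
  }
  seq.int(hit$start[1], hit$end[1])
}

# ---- coordinate conversion -------------------------------------------------

#' Map an alignment column to a region-relative degapped position
#'
#' Printed diagnoses give 1-based positions on the degapped reference
#' (lectotype) sequence within a named region; internal computation is
#' alignment-column based. This converts one to the other.
#'
#' @param aln A `dna_alignment`.
#' @param regions Region map tibble (see [read_region_map()]).
#' @param accession Reference sequence.
#' @param column 1-based alignment column.
#' @return A list with `region` and `position`.
#' @export
column_to_region_position <- function(aln, regions, accession, column) {
  seq <- alignment_sequence(aln, accession)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (column < 1L || column > length(chars)) {
    stop("column ", column, " outside alignment", call. = FALSE)
  }
  if (chars[column] == "-") {
    stop("reference ", accession, " has a gap at column ", column,
         "; no degapped image", call. = FALSE)
  }
  hit <- regions[regions$region != "full" &
                   regions$start <= column & regions$end >= column, ]
  if (nrow(hit) == 0L) {
    region <- "full"
    start <- 1L
  } else {
    region <- hit$region[1]
    start <- hit$start[1]
  }
  pos <- sum(chars[start:column] != "-")
  list(region = region, position = as.integer(pos))
}

#' Map a region-relative degapped position back to an alignment column
#'
#' Inverse of [column_to_region_position()] on non-gap sites.
#'
#' @inheritParams column_to_region_position
#' @param region Region name.
#' @param position 1-based degapped position within the region.
#' @return Integer alignment column.
#' @export
region_position_to_column <- function(aln, regions, accession, region, position) {
  cols <- region_columns(regions, region, n_columns(aln))
  chars <- strsplit(alignment_sequence(aln, accession), "", fixed = TRUE)[[1]]
  nongap <- cols[chars[cols] != "-"]
  if (position < 1L || position > length(nongap)) {
    stop("position ", position, " outside degapped ", region, " of ",
         accession, call. = FALSE)
  }
  nongap[position]
}

alignment_sequence <- function(aln, accession) {
  i <- match(accession, aln$accession)
  if (is.na(i)) stop("unknown accession: ", accession, call. = FALSE)
  aln$sequence[i]
}

# ---- pairwise distance -----------------------------------------------------

# comparable / differing masks under a policy; returns list(comparable, diff)
compare_masks <- function(ma, mb, ca, cb, gap_policy, ambig) {
  gap_a <- ma == 0L
  gap_b <- mb == 0L
  comparable <- !(gap_a & gap_b)
  if (identical(gap_policy, "exclude")) comparable <- comparable & !(gap_a | gap_b)
  if (identical(ambig, "exclude")) {
    comparable <- comparable & !is_ambiguity_mask(ma) & !is_ambiguity_mask(mb)
  }
  both <- !gap_a & !gap_b
  if (identical(ambig, "strict")) {
    match <- both & (ca == cb)
  } else {
    match <- both & bitwAnd(ma, mb) > 0L
  }
  list(comparable = comparable, diff = comparable & !match)
}

# gap runs longer than max_indel, per sequence, as a logical column mask
long_gap_run_mask <- function(chars, max_indel) {
  r <- rle(chars == "-")
  drop <- r$values & r$lengths > max_indel
  rep(drop, r$lengths)
}

#' Uncorrected pairwise distance over a region
#'
#' Proportion of differing comparable columns (p-distance) between two
#' aligned sequences. Under the default `gap_policy = "count"` a
#' gap-vs-base column is a difference and gap-vs-gap is excluded;
#' contiguous gap runs longer than `max_indel` columns are excluded
#' entirely, so a long deletion does not inflate within-species
#' variability. Ambiguity codes match leniently when their IUPAC sets
#' intersect (`ambig = "lenient"`), must be identical under `"strict"`,
#' or are dropped from the comparison under `"exclude"`.
#'
#' @param aln A `dna_alignment`.
#' @param a,b Accessions.
#' @param region Region name (default `"full"`).
#' @param regions Region map tibble; only needed for named regions.
#' @param gap_policy `"count"` or `"exclude"`.
#' @param max_indel Longest gap run still scored column-wise; longer runs
#'   are masked (default 20).
#' @param ambig Ambiguity-code policy.
#' @return Proportion in `[0, 1]`.
#' @examples
#' aln <- alignment_from_strings(c("x", "y"), c("ACGTACGTAC", "ACGTACGTAT"))
#' pairwise_distance(aln, "x", "y")
#' @export
pairwise_distance <- function(aln, a, b, region = "full", regions = NULL,
                              gap_policy = c("count", "exclude"),
                              max_indel = 20L,
                              ambig = c("lenient", "strict", "exclude")) {
  gap_policy <- match.arg(gap_policy)
  ambig <- match.arg(ambig)
  if (is.null(regions)) regions <- tibble::tibble(region = character(),
                                                 start = integer(), end = integer())
  cols <- region_columns(regions, region, n_columns(aln))
  ca <- strsplit(alignment_sequence(aln, a), "", fixed = TRUE)[[1]][cols]
  cb <- strsplit(alignment_sequence(aln, b), "", fixed = TRUE)[[1]][cols]
  keep <- !long_gap_run_mask(ca, max_indel) & !long_gap_run_mask(cb, max_indel)
  ca <- ca[keep]; cb <- cb[keep]
  ma <- iupac_mask(ca); mb <- iupac_mask(cb)
  cm <- compare_masks(ma, mb, ca, cb, gap_policy, ambig)
  n_comp <- sum(cm$comparable)
  if (n_comp == 0L) {
    stop("no comparable columns between ", a, " and ", b, " in region ",
         region, call. = FALSE)
  }
  sum(cm$diff) / n_comp
}
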