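# Diagnostic-barcode selection: enumerate candidate 20-30 base windows in a
# region, score how the target taxon separates from everything else, and
# report the best window per region as a printable diagnosis.

target_rows <- function(aln, target, rank) {
  if (!rank %in% names(aln)) stop("unknown rank: ", rank, call. = FALSE)
  which(!is.na(aln[[rank]]) & aln[[rank]] == target)
}

#' Hamming distance between two sequences over a window
#'
#' Counts alignment columns in the window where the residues differ:
#' gap-vs-base is a difference, gap-vs-gap is not, and ambiguity codes
#' match leniently (intersecting IUPAC sets) unless `ambig = "strict"`.
#'
#' @param aln A `dna_alignment`.
#' @param start 1-based first alignment column of the window.
#' @param length Window length in columns.
#' @param ref,other Accessions to compare.
#' @param ambig `"lenient"` or `"strict"`.
#' @return Integer mismatch count.
#' @export
hamming_window <- function(aln, start, length, ref, other,
                           ambig = c("lenient", "strict")) {
  ambig <- match.arg(ambig)
  cols <- seq.int(start, start + length - 1L)
  if (start < 1L || max(cols) > n_columns(aln)) {
    stop("window outside alignment", call. = FALSE)
  }
  ca <- strsplit(alignment_sequence(aln, ref), "", fixed = TRUE)[[1]][cols]
  cb <- strsplit(alignment_sequence(aln, other), "", fixed = TRUE)[[1]][cols]
  ma <- iupac_mask(ca); mb <- iupac_mask(cb)
  cm <- compare_masks(ma, mb, ca, cb, gap_policy = "count", ambig = ambig)
  sum(cm$diff)
}

#' Enumerate candidate barcode windows within a region
#'
#' All contiguous windows of each length in `[l_min, l_max]` that fit
#' entirely inside the region, ordered by start column then length.
#'
#' @param aln A `dna_alignment`.
#' @param region Region name.
#' @param regions Region map tibble.
#' @param l_min,l_max Window length bounds in columns (default 20-30).
#' @return Tibble with columns `start`, `length`, `end` (alignment columns).
#' @export
enumerate_windows <- function(aln, region, regions = NULL,
                              l_min = 20L, l_max = 30L) {
  if (is.null(regions)) regions <- tibble::tibble(region = character(),
                                                 start = integer(), end = integer())
  cols <- region_columns(regions, region, n_columns(aln))
  width <- length(cols)
  if (width < l_min) {
    warning("region ", region, " (", width, " columns) shorter than l_min = ",
            l_min, "; no windows", call. = FALSE)
    return(tibble::tibble(start = integer(), length = integer(), end = integer()))
  }
  first <- cols[1]
  out <- tidyr::expand_grid(
    start = seq.int(first, first + width - 1L),
    length = seq.int(l_min, min(l_max, width))
  )
  out <- out[out$start + out$length - 1L <= first + width - 1L, ]
  out <- out[order(out$start, out$length), ]
  out$end <- out$start + out$length - 1L
  out
}

# per-sequence-vs-canonical difference matrix restricted to given columns;
# rows follow aln order. Also returns ambiguity and canonical-gap indicators.
window_scan_matrices <- function(aln, cols, canonical_row, ambig) {
  chars <- lapply(aln$sequence, function(s) strsplit(s, "", fixed = TRUE)[[1]][cols])
  masks <- lapply(chars, iupac_mask)
  cc <- chars[[canonical_row]]
  mc <- masks[[canonical_row]]
  diff <- t(vapply(seq_along(chars), function(i) {
    cm <- compare_masks(masks[[i]], mc, chars[[i]], cc,
                        gap_policy = "count", ambig = ambig)
    as.integer(cm$diff)
  }, integer(length(cols))))
  ambig_ind <- t(vapply(masks, function(m) as.integer(is_ambiguity_mask(m)),
                        integer(length(cols))))
  list(diff = diff, ambig = ambig_ind,
       canonical_gap = as.integer(mc == 0L),
       canonical_chars = cc)
}

#' Distance profile of one window for a target taxon
#'
#' `d_in` is the maximum Hamming distance from the canonical (lectotype)
#' barcode to any target sequence over the window; `d_out` the minimum to
#' any non-target sequence; `ambiguous_in_target` counts ambiguity-code
#' residues among target sequences inside the window.
#'
#' @inheritParams hamming_window
#' @param target Taxon name.
#' @param rank Rank column holding `target` (default `"species"`).
#' @param canonical Canonical accession (default: first target member).
#' @return One-row tibble with `d_in`, `d_out`, `nearest_out`,
#'   `ambiguous_in_target`, `margin`.
#' @export
window_profile <- function(aln, start, length, target, rank = "species",
                           canonical = NULL, ambig = c("lenient", "strict")) {
  ambig <- match.arg(ambig)
  t_rows <- target_rows(aln, target, rank)
  if (length(t_rows) == 0L) stop("target ", target, " absent", call. = FALSE)
  if (length(t_rows) == nrow(aln)) {
    stop("target covers the whole alignment; nothing to separate from",
         call. = FALSE)
  }
  if (is.null(canonical)) canonical <- aln$accession[t_rows[1]]
  can_row <- match(canonical, aln$accession)
  cols <- seq.int(start, start + length - 1L)
  sm <- window_scan_matrices(aln, cols, can_row, ambig)
  d <- rowSums(sm$diff)
  o_rows <- setdiff(seq_len(nrow(aln)), t_rows)
  d_out <- min(d[o_rows])
  tibble::tibble(
    start = as.integer(start), length = as.integer(length),
    d_in = as.integer(max(d[t_rows])),
    d_out = as.integer(d_out),
    nearest_out = aln$accession[o_rows[which.min(d[o_rows])]],
    ambiguous_in_target = as.integer(sum(sm$ambig[t_rows, , drop = FALSE])),
    margin = as.integer(d_out - max(d[t_rows]))
  )
}

#' Mismatch allowance interval for a window profile
#'
#' A sequence is attributed to the target when it matches the barcode
#' with at most k mismatches. Any k in `[d_in, d_out - 1]` separates the
#' target from its relatives; the reported single value is capped
#' (default 1, matching the convention of quoting "no" or "one" mismatch
#' allowed) but never dropped below `d_in`.
#'
#' @param d_in,d_out Window profile distances (or a profile tibble row as
#'   first argument).
#' @param cap Preferred upper bound on the reported allowance.
#' @return List with `k_lo`, `k_hi`, `reported`, `diagnostic`.
#' @examples
#' mismatch_allowance(0, 2)  # interval [0,1], reported 1
#' @export
mismatch_allowance <- function(d_in, d_out = NULL, cap = 1L) {
  if (is.data.frame(d_in)) {
    d_out <- d_in$d_out[1]
    d_in <- d_in$d_in[1]
  }
  k_lo <- as.integer(d_in)
  k_hi <- as.integer(d_out) - 1L
  if (k_lo > k_hi) {
    return(list(k_lo = NA_integer_, k_hi = NA_integer_,
                reported = NA_integer_, diagnostic = FALSE))
  }
  r <- min(k_hi, as.integer(cap))
  if (r < k_lo) r <- k_lo
  list(k_lo = k_lo, k_hi = k_hi, reported = as.integer(r), diagnostic = TRUE)
}

#' Find the best diagnostic barcode per region
#'
#' Scans every 20-30 base window of each requested region, keeps windows
#' with no ambiguity code in the target, at least `min_sep` differences
#' to every non-target sequence and a non-empty allowance interval, and
#' ranks them by separation margin (descending), then fewer canonical
#' gap columns, then leftmost start, then shorter length. The top window
#' per region is reported with region-relative degapped positions on the
#' canonical sequence.
#'
#' @inheritParams window_profile
#' @param aln A `dna_alignment`.
#' @param target Target taxon name.
#' @param regions Region map tibble.
#' @param region_names Regions to scan (default: all named regions except
#'   `"full"`).
#' @param l_min,l_max Window length bounds.
#' @param min_sep Minimum `d_out` (default 2 differences).
#' @param cap Reported-allowance cap (default 1).
#' @return A tibble of class `dna_diagnosis`, one row per region with a
#'   qualifying window; regions with none are recorded in the
#'   `"rejected"` attribute with the best margin achieved.
#' @export
find_diagnoses <- function(aln, target, regions, region_names = NULL,
                           rank = "species", canonical = NULL,
                           l_min = 20L, l_max = 30L, min_sep = 2L, cap = 1L,
                           ambig = c("lenient", "strict")) {
  ambig <- match.arg(ambig)
  t_rows <- target_rows(aln, target, rank)
  if (length(t_rows) == 0L) stop("target ", target, " absent", call. = FALSE)
  if (length(t_rows) == nrow(aln)) {
    stop("target covers the whole alignment; nothing to separate from",
         call. = FALSE)
  }
  if (is.null(canonical)) canonical <- aln$accession[t_rows[1]]
  can_row <- match(canonical, aln$accession)
  if (!can_row %in% t_rows) stop("canonical must be a target member", call. = FALSE)
  if (is.null(region_names)) {
    region_names <- setdiff(unique(regions$region), "full")
  }
  o_rows <- setdiff(seq_len(nrow(aln)), t_rows)

  rows <- list()
  rejected <- list()
  for (rg in region_names) {
    cols <- region_columns(regions, rg, n_columns(aln))
    sm <- window_scan_matrices(aln, cols, can_row, ambig)
    # column-cumulative sums for O(1) window scores
    cs_diff <- cbind(0L, t(apply(sm$diff, 1, cumsum)))
    amb_target <- c(0L, cumsum(colSums(sm$ambig[t_rows, , drop = FALSE])))
    gaps_can <- c(0L, cumsum(sm$canonical_gap))
    width <- length(cols)
    cand <- NULL
    for (L in seq.int(l_min, min(l_max, width))) {
      if (width < L) next
      starts <- seq_len(width - L + 1L)
      w <- cs_diff[, starts + L, drop = FALSE] - cs_diff[, starts, drop = FALSE]
      d_in <- apply(w[t_rows, , drop = FALSE], 2, max)
      d_out <- apply(w[o_rows, , drop = FALSE], 2, min)
      tab <- tibble::tibble(
        offset = starts, length = L,
        d_in = as.integer(d_in), d_out = as.integer(d_out),
        amb = amb_target[starts + L] - amb_target[starts],
        can_gaps = gaps_can[starts + L] - gaps_can[starts]
      )
      cand <- dplyr::bind_rows(cand, tab)
    }
    if (is.null(cand) || nrow(cand) == 0L) {
      rejected[[rg]] <- tibble::tibble(region = rg, reason = "region too short",
                                       best_margin = NA_integer_)
      next
    }
    cand$margin <- cand$d_out - cand$d_in
    keep <- cand$amb == 0L & cand$d_out >= min_sep & cand$d_in <= cand$d_out - 1L
    if (!any(keep)) {
      reason <- if (max(cand$d_out) < min_sep) "no separation" else
        "no window passes filters"
      rejected[[rg]] <- tibble::tibble(region = rg, reason = reason,
                                      best_margin = max(cand$margin))
      next
    }
    ok <- cand[keep, ]
    ok <- ok[order(-ok$margin, ok$can_gaps, ok$offset, ok$length), ]
    best <- ok[1, ]
    start_col <- cols[best$offset]
    win_cols <- seq.int(start_col, start_col + best$length - 1L)
    can_chars <- strsplit(aln$sequence[can_row], "", fixed = TRUE)[[1]]
    barcode <- paste(can_chars[win_cols][can_chars[win_cols] != "-"],
                     collapse = "")
    first_nongap <- win_cols[can_chars[win_cols] != "-"][1]
    pos <- column_to_region_position(aln, regions, canonical, first_nongap)
    allow <- mismatch_allowance(best$d_in, best$d_out, cap = cap)
    o_w <- hamming_many(aln, win_cols, can_row, o_rows, ambig)
    rows[[rg]] <- tibble::tibble(
      target = target, rank = rank, region = rg,
      start = pos$position, end = pos$position + nchar(barcode) - 1L,
      barcode = tolower(barcode),
      canonical = canonical,
      start_col = start_col, length = best$length,
      d_in = best$d_in, d_out = best$d_out,
      nearest_out = aln$accession[o_rows[which.min(o_w)]],
      margin = best$margin,
      k_lo = allow$k_lo, k_hi = allow$k_hi, allowance = allow$reported,
      canonical_gaps = best$can_gaps
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "rejected") <- dplyr::bind_rows(rejected)
  class(out) <- c("dna_diagnosis", class(tibble::tibble()))
  out
}

hamming_many <- function(aln, cols, can_row, rows, ambig) {
  vapply(rows, function(i) {
    ca <- strsplit(aln$sequence[i], "", fixed = TRUE)[[1]][cols]
    cb <- strsplit(aln$sequence[can_row], "", fixed = TRUE)[[1]][cols]
    cm <- compare_masks(iupac_mask(ca), iupac_mask(cb), ca, cb,
                        gap_policy = "count", ambig = ambig)
    sum(cm$diff)
  }, integer(1))
}

#' Within-taxon variability over a region
#'
#' Maximum pairwise proportion of differences (p-distance) among all
#' members of a taxon over a marker region -- the within-species
#' variability quoted in taxon descriptions. Gap runs longer than
#' `max_indel` columns are excluded (so, e.g., a 29-base deletion in one
#' accession does not inflate the estimate); the excluded runs are
#' reported.
#'
#' @inheritParams pairwise_distance
#' @param taxon Taxon name.
#' @param rank Rank column (default `"species"`).
#' @return One-row tibble: `taxon`, `region`, `max_pairwise`,
#'   `n_sequences`, `single_sequence` flag and an `excluded_indel_runs`
#'   list-column of `(accession, run_length)` rows.
#' @export
within_group_variability <- function(aln, taxon, region = "full",
                                     regions = NULL, rank = "species",
                                     gap_policy = c("count", "exclude"),
                                     max_indel = 20L,
                                     ambig = c("lenient", "strict", "exclude")) {
  gap_policy <- match.arg(gap_policy)
  ambig <- match.arg(ambig)
  rows <- target_rows(aln, taxon, rank)
  if (length(rows) == 0L) stop("taxon ", taxon, " absent", call. = FALSE)
  if (is.null(regions)) regions <- tibble::tibble(region = character(),
                                                 start = integer(), end = integer())
  cols <- region_columns(regions, region, n_columns(aln))
  runs <- purrr::map_dfr(rows, function(i) {
    ch <- strsplit(aln$sequence[i], "", fixed = TRUE)[[1]][cols]
    r <- rle(ch == "-")
    ln <- r$lengths[r$values & r$lengths > max_indel]
    if (length(ln) == 0L) return(NULL)
    tibble::tibble(accession = aln$accession[i], run_length = as.integer(ln))
  })
  if (length(rows) < 2L) {
    return(tibble::tibble(taxon = taxon, region = region, max_pairwise = 0,
                          n_sequences = length(rows), single_sequence = TRUE,
                          excluded_indel_runs = list(runs)))
  }
  acc <- aln$accession[rows]
  mx <- 0
  for (i in seq_along(acc)[-length(acc)]) {
    for (j in seq.int(i + 1L, length(acc))) {
      d <- pairwise_distance(aln, acc[i], acc[j], region = region,
                             regions = regions, gap_policy = gap_policy,
                             max_indel = max_indel, ambig = ambig)
      if (d > mx) mx <- d
    }
  }
  tibble::tibble(taxon = taxon, region = region, max_pairwise = mx,
                 n_sequences = length(rows), single_sequence = FALSE,
                 excluded_indel_runs = list(runs))
}

#' Validate a diagnosis against an alignment
#'
#' Reverse check of a (possibly printed) diagnosis: does every target
#' sequence match the barcode within the reported allowance, does every
#' non-target sequence exceed it, and are the positions self-consistent
#' with the barcode length? Failures are enumerated, never corrected.
#'
#' @param aln A `dna_alignment`.
#' @param diagnosis One row of a `dna_diagnosis` tibble (or any tibble
#'   with `target`, `rank`, `region`, `start`, `end`, `barcode`,
#'   `canonical`, `allowance`).
#' @param regions Region map tibble.
#' @param ambig Ambiguity policy for barcode matching.
#' @return Tibble with one row per check: `check`, `pass`, `detail`.
#' @export
validate_diagnosis <- function(aln, diagnosis, regions,
                               ambig = c("lenient", "strict")) {
  ambig <- match.arg(ambig)
  d <- as.list(diagnosis[1, ])
  barcode <- toupper(d$barcode)
  if (!grepl(sprintf("^[%s]+$", paste(IUPAC_LETTERS, collapse = "")), barcode)) {
    stop("barcode contains characters outside the IUPAC alphabet", call. = FALSE)
  }
  bc <- strsplit(barcode, "", fixed = TRUE)[[1]]
  checks <- list()
  span <- d$end - d$start + 1L
  checks$length <- tibble::tibble(
    check = "positions_match_length",
    pass = span == length(bc),
    detail = sprintf("span %d vs barcode length %d", span, length(bc))
  )
  rnk <- if (!is.null(d$rank)) d$rank else "species"
  t_rows <- target_rows(aln, d$target, rnk)
  o_rows <- setdiff(seq_len(nrow(aln)), t_rows)
  cols <- tryCatch(
    vapply(seq.int(d$start, d$start + length(bc) - 1L), function(p)
      region_position_to_column(aln, regions, d$canonical, d$region, p),
      integer(1)),
    error = function(e) NULL
  )
  if (is.null(cols)) {
    checks$map <- tibble::tibble(check = "positions_mappable", pass = FALSE,
                                 detail = "positions do not map onto the canonical sequence")
  } else {
    mism <- vapply(seq_len(nrow(aln)), function(i) {
      ch <- strsplit(aln$sequence[i], "", fixed = TRUE)[[1]][cols]
      cm <- compare_masks(iupac_mask(ch), iupac_mask(bc), ch, bc,
                          gap_policy = "count", ambig = ambig)
      sum(cm$diff)
    }, integer(1))
    bad_t <- t_rows[mism[t_rows] > d$allowance]
    checks$targets <- tibble::tibble(
      check = "targets_within_allowance",
      pass = length(bad_t) == 0L,
      detail = if (length(bad_t)) paste(aln$accession[bad_t], collapse = ",") else ""
    )
    bad_o <- o_rows[mism[o_rows] <= d$allowance]
    checks$others <- tibble::tibble(
      check = "nontargets_exceed_allowance",
      pass = length(bad_o) == 0L,
      detail = if (length(bad_o)) paste(aln$accession[bad_o], collapse = ",") else ""
    )
  }
  dplyr::bind_rows(checks)
}

#' Predict the number of potential species in a genus
#'
#' Single-linkage clustering of a genus' sequences at a p-distance
#' threshold (default 0.03 on ITS): members closer than the threshold
#' chain into one cluster, and the cluster count approximates the number
#' of (potential) species the genus contains.
#'
#' @inheritParams pairwise_distance
#' @param genus Genus name.
#' @param threshold Linkage distance threshold (default 0.03).
#' @return List with `count`, `threshold` and a `clusters` tibble
#'   (`accession`, `cluster`).
#' @export
estimate_species_count <- function(aln, genus, region = "full", regions = NULL,
                                   threshold = 0.03, gap_policy = "count",
                                   max_indel = 20L, ambig = "lenient") {
  rows <- target_rows(aln, genus, "genus")
  if (length(rows) == 0L) stop("genus ", genus, " absent", call. = FALSE)
  acc <- aln$accession[rows]
  n <- length(acc)
  if (n == 1L) {
    return(list(count = 1L, threshold = threshold,
                clusters = tibble::tibble(accession = acc, cluster = 1L)))
  }
  dm <- matrix(0, n, n, dimnames = list(acc, acc))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      d <- tryCatch(
        pairwise_distance(aln, acc[i], acc[j], region = region,
                          regions = regions, gap_policy = gap_policy,
                          max_indel = max_indel, ambig = ambig),
        error = function(e) 1
      )
      dm[i, j] <- dm[j, i] <- d
    }
  }
  hc <- stats::hclust(stats::as.dist(dm), method = "single")
  cl <- stats::cutree(hc, h = threshold)
  list(count = length(unique(cl)), threshold = threshold,
       clusters = tibble::tibble(accession = acc, cluster = unname(cl)))
}
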