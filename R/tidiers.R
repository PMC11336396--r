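# broom-style accessors and ggplot2 autoplot methods for result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a diagnosis table
#'
#' @param x A `dna_diagnosis` from [find_diagnoses()].
#' @param ... Unused.
#' @return A plain tibble, one row per region-level diagnosis.
#' @method tidy dna_diagnosis
#' @export
tidy.dna_diagnosis <- function(x, ...) {
  out <- tibble::as_tibble(x)
  attr(out, "rejected") <- NULL
  out
}

#' @rdname tidy.dna_diagnosis
#' @method glance dna_diagnosis
#' @export
glance.dna_diagnosis <- function(x, ...) {
  tibble::tibble(
    target = if (nrow(x)) x$target[1] else NA_character_,
    n_regions = nrow(x),
    n_rejected = nrow(attr(x, "rejected") %||% tibble::tibble()),
    best_margin = if (nrow(x)) max(x$margin) else NA_integer_,
    min_allowance = if (nrow(x)) min(x$allowance) else NA_integer_
  )
}

#' Tidy clade-delimitation candidates
#'
#' @param x A `dna_clades` from [propose_taxa()].
#' @param ... Unused.
#' @return Tibble of candidates with leaves collapsed to a string.
#' @method tidy dna_clades
#' @export
tidy.dna_clades <- function(x, ...) {
  cand <- x$candidates
  if (nrow(cand) == 0L) {
    return(tibble::tibble(code = character(), node = integer(),
                          support = double(), n_leaves = integer(),
                          breadth = double(), leaves = character()))
  }
  cand$leaves <- vapply(cand$leaves, paste, character(1), collapse = ",")
  if (!"code" %in% names(cand)) cand$code <- NA_character_
  cand[, c("code", "node", "support", "n_leaves", "breadth", "leaves")]
}

#' @rdname tidy.dna_clades
#' @method glance dna_clades
#' @export
glance.dna_clades <- function(x, ...) {
  tibble::tibble(
    rank = x$config$rank,
    n_candidates = nrow(x$candidates),
    n_assigned = sum(x$candidates$n_leaves %||% 0L),
    n_unassigned = length(x$unassigned),
    support_min = x$config$support_min,
    band_lo = x$config$band_abs[1],
    band_hi = x$config$band_abs[2]
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plot diagnosis windows along their regions
#'
#' One horizontal segment per region-level diagnosis, positioned at its
#' region-relative coordinates and coloured by separation margin.
#'
#' @param object A `dna_diagnosis`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dna_diagnosis
#' @export
autoplot.dna_diagnosis <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(y = .data$region)) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start, xend = .data$end,
                   yend = .data$region, colour = .data$margin),
      linewidth = 4
    ) +
    ggplot2::geom_text(
      ggplot2::aes(x = (.data$start + .data$end) / 2,
                   label = sprintf("%d–%d (k=%d)", .data$start,
                                   .data$end, .data$allowance)),
      vjust = -1, size = 3
    ) +
    ggplot2::labs(x = "region-relative position (degapped canonical)",
                  y = NULL, colour = "margin",
                  title = paste("Diagnostic barcodes:", df$target[1])) +
    ggplot2::theme_minimal()
}

#' Plot candidate clades: breadth against support
#'
#' @param object A `dna_clades`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dna_clades
#' @export
autoplot.dna_clades <- function(object, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$support, y = .data$breadth,
                                        size = .data$n_leaves)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "bootstrap support", y = "patristic breadth",
                  size = "leaves",
                  title = sprintf("Candidate %s-level clades",
                                  object$config$rank)) +
    ggplot2::theme_minimal()
  if (is.finite(object$config$band_abs[2])) {
    p <- p + ggplot2::geom_hline(yintercept = object$config$band_abs,
                                 linetype = "dashed", colour = "grey50")
  }
  if (!all(is.na(df$code))) {
    p <- p + ggplot2::geom_text(ggplot2::aes(label = .data$code),
                                vjust = -1, size = 3, show.legend = FALSE)
  }
  p
}

#' Plot per-group primer mismatch summaries
#'
#' Stacked view of the fraction of sequences per lineage that match a
#' primer with zero mismatches, split by primer.
#'
#' @param summary Output of [group_summary()].
#' @return A ggplot.
#' @export
plot_primer_summary <- function(summary) {
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = .data$group, y = .data$fraction_zero,
                               fill = .data$verdict)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~primer) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "fraction with 0 mismatches", fill = NULL) +
    ggplot2::theme_minimal()
}
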