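# Fixtures are built in code; no data files. Helpers deliberately use
# naive loop implementations so they stay independent of the package's
# vectorised paths.

BASES <- c("A", "C", "G", "T")

`%||%` <- function(a, b) if (is.null(a)) b else a

random_alignment <- function(n_seq, n_col, taxa = NULL, gap_rate = 0,
                             ambig_rate = 0) {
  seqs <- vapply(seq_len(n_seq), function(i) {
    ch <- sample(BASES, n_col, replace = TRUE)
    if (gap_rate > 0) ch[stats::runif(n_col) < gap_rate] <- "-"
    if (ambig_rate > 0) {
      hit <- which(stats::runif(n_col) < ambig_rate & ch != "-")
      ch[hit] <- sample(c("R", "Y", "N"), length(hit), replace = TRUE)
    }
    paste(ch, collapse = "")
  }, character(1))
  acc <- sprintf("seq%02d", seq_len(n_seq))
  if (is.null(taxa)) {
    taxa <- tibble::tibble(accession = acc,
                           species = sprintf("sp%02d", seq_len(n_seq)))
  }
  alignment_from_strings(acc, seqs, taxonmap = taxa)
}

# two-species random alignment: first n_target rows are the target
random_two_group_alignment <- function(n_target, n_other, n_col,
                                       gap_rate = 0, ambig_rate = 0) {
  n <- n_target + n_other
  taxa <- tibble::tibble(
    accession = sprintf("seq%02d", seq_len(n)),
    species = rep(c("target", "other"), c(n_target, n_other))
  )
  random_alignment(n, n_col, taxa = taxa, gap_rate = gap_rate,
                   ambig_rate = ambig_rate)
}

full_region <- function(aln) {
  tibble::tibble(region = "R1", start = 1L, end = n_columns(aln))
}
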