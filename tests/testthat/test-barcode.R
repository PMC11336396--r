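toy_two_species <- function(target_seq, other_seqs) {
  n_o <- length(other_seqs)
  alignment_from_strings(
    c("t1", sprintf("o%d", seq_len(n_o))),
    c(target_seq, other_seqs),
    taxonmap = tibble::tibble(
      accession = c("t1", sprintf("o%d", seq_len(n_o))),
      species = c("tgt", rep("oth", n_o)))
  )
}

test_that("window Hamming counts match hand counts and gap rules", {
  aln <- alignment_from_strings(c("a", "b", "c"),
                                c("ACGTACGT", "ACGTAGGA", "AC-TACGT"))
  expect_equal(hamming_window(aln, 1, 4, "a", "a"), 0L)
  expect_equal(hamming_window(aln, 5, 4, "a", "b"), 2L)  # ACGT vs AGGA
  expect_equal(hamming_window(aln, 1, 4, "a", "c"), 1L)  # gap counts
})

test_that("window enumeration counts and bounds are exact", {
  mk <- function(width) {
    random_alignment(2, width) |>
      (\(a) list(a, tibble::tibble(region = "R", start = 1L,
                                   end = n_columns(a))))()
  }
  withr::local_seed(7)
  x <- mk(30)
  expect_equal(nrow(enumerate_windows(x[[1]], "R", x[[2]],
                                      l_min = 30, l_max = 30)), 1L)
  x <- mk(19)
  expect_warning(w <- enumerate_windows(x[[1]], "R", x[[2]]), "shorter")
  expect_equal(nrow(w), 0L)
  x <- mk(100)
  w <- enumerate_windows(x[[1]], "R", x[[2]])
  expect_equal(nrow(w), sum(101 - 20:30))  # 836
  expect_true(all(w$end <= 100))
  expect_equal(w, w[order(w$start, w$length), ])
})

test_that("window profiles match exhaustive comparison", {
  t_seq <- strrep("A", 40)
  o1 <- paste0(strrep("A", 38), "CC")
  aln <- alignment_from_strings(
    c("t1", "t2", "o1"), c(t_seq, t_seq, o1),
    taxonmap = tibble::tibble(accession = c("t1", "t2", "o1"),
                              species = c("tgt", "tgt", "oth")))
  p <- window_profile(aln, 21, 20, "tgt")
  expect_equal(p$d_in, 0L)
  expect_equal(p$d_out, 2L)
  expect_equal(p$nearest_out, "o1")
  expect_equal(p$ambiguous_in_target, 0L)

  withr::local_seed(31)
  for (rep in 1:5) {
    aln <- random_two_group_alignment(3, 7, 120, gap_rate = 0.02,
                                      ambig_rate = 0.01)
    start <- sample(1:100, 1)
    p <- window_profile(aln, start, 20, "target")
    cols <- start:(start + 19)
    d <- vapply(seq_len(nrow(aln)), function(i)
      oracle_hamming(aln$sequence[i], aln$sequence[1], cols), integer(1))
    expect_equal(p$d_in, max(d[1:3]))
    expect_equal(p$d_out, min(d[4:10]))
  }
})

test_that("allowance interval is [d_in, d_out-1], reported capped at 1", {
  a <- mismatch_allowance(0, 2)
  expect_equal(c(a$k_lo, a$k_hi, a$reported), c(0L, 1L, 1L))
  a <- mismatch_allowance(0, 1)
  expect_equal(c(a$k_lo, a$k_hi, a$reported), c(0L, 0L, 0L))
  expect_false(mismatch_allowance(2, 2)$diagnostic)   # empty interval
  # reported never below d_in even when the cap is lower
  a <- mismatch_allowance(2, 5)
  expect_equal(a$reported, 2L)
  expect_equal(c(a$k_lo, a$k_hi), c(2L, 4L))
})

test_that("find_diagnoses rejects inseparable targets with a reason", {
  s <- strrep("ACGTG", 10)
  aln <- alignment_from_strings(
    c("t1", "o1"), c(s, s),
    taxonmap = tibble::tibble(accession = c("t1", "o1"),
                              species = c("tgt", "oth")))
  regions <- tibble::tibble(region = "R", start = 1L, end = 50L)
  d <- find_diagnoses(aln, "tgt", regions)
  expect_equal(nrow(d), 0L)
  rej <- attr(d, "rejected")
  expect_equal(rej$reason, "no separation")
  expect_equal(rej$best_margin, 0L)
})

test_that("ambiguity codes in the target disqualify a window", {
  t_seq <- paste0(strrep("A", 10), "N", strrep("A", 14))   # N at col 11
  o1 <- strrep("C", 25)
  aln <- toy_two_species(t_seq, o1)
  regions <- tibble::tibble(region = "R", start = 1L, end = 25L)
  p <- window_profile(aln, 1, 25, "tgt")
  expect_gte(p$ambiguous_in_target, 1L)
  d <- find_diagnoses(aln, "tgt", regions, l_min = 25, l_max = 25)
  expect_equal(nrow(d), 0L)  # only window contains the N
})

test_that("best window matches the brute-force enumerator", {
  withr::local_seed(4711)
  for (rep in 1:8) {
    aln <- random_two_group_alignment(sample(2:4, 1), sample(4:8, 1),
                                      sample(60:120, 1),
                                      gap_rate = 0.02, ambig_rate = 0.01)
    regions <- tibble::tibble(region = "R", start = 1L,
                              end = n_columns(aln))
    got <- find_diagnoses(aln, "target", regions)
    want <- oracle_best_window(aln, "target", 1L, n_columns(aln))
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(got$start_col, unname(want["start"]))
      expect_equal(got$length, unname(want["length"]))
      expect_equal(got$d_in, unname(want["d_in"]))
      expect_equal(got$d_out, unname(want["d_out"]))
    }
  }
})

test_that("growing the comparison sets moves d_out/d_in monotonically", {
  withr::local_seed(99)
  base <- random_alignment(12, 80)
  taxa <- tibble::tibble(accession = base$accession,
                         species = rep(c("tgt", "oth"), each = 6))
  aln <- alignment_from_strings(base$accession, base$sequence,
                                taxonmap = taxa)
  win <- list(start = 11, length = 25)
  sub_o <- alignment_from_strings(aln$accession[1:9], aln$sequence[1:9],
                                  taxonmap = taxa[1:9, ])
  p_small <- window_profile(sub_o, win$start, win$length, "tgt")
  p_full <- window_profile(aln, win$start, win$length, "tgt")
  expect_lte(p_full$d_out, p_small$d_out)   # more non-targets: d_out down

  sub_t <- alignment_from_strings(aln$accession[c(1:3, 7:12)],
                                  aln$sequence[c(1:3, 7:12)],
                                  taxonmap = taxa[c(1:3, 7:12), ])
  p_fewer_t <- window_profile(sub_t, win$start, win$length, "tgt")
  expect_gte(p_full$d_in, p_fewer_t$d_in)   # more targets: d_in up
})

test_that("emitted diagnoses validate against their own alignment", {
  withr::local_seed(2024)
  for (rep in 1:5) {
    sim <- simulate_dataset(
      simulation_config(n_species = 5, seqs_per_species = 3, seed = rep),
      plant = list(species = "sp02"))
    d <- find_diagnoses(sim$alignment, "sp02", sim$regions,
                        region_names = "ITS2")
    expect_equal(nrow(d), 1L)
    chk <- validate_diagnosis(sim$alignment, d, sim$regions)
    expect_true(all(chk$pass))
  }
})

test_that("validation flags length inconsistencies and bad allowances", {
  sim <- simulate_dataset(simulation_config(n_species = 4,
                                            seqs_per_species = 3,
                                            seed = 7),
                          plant = list(species = "sp01"))
  d <- find_diagnoses(sim$alignment, "sp01", sim$regions,
                      region_names = "ITS2")
  # barcode longer than the declared span
  d_bad <- d
  d_bad$end <- d_bad$start + 19L
  d_bad$barcode <- strrep("a", 30)
  chk <- validate_diagnosis(sim$alignment, d_bad, sim$regions)
  expect_false(chk$pass[chk$check == "positions_match_length"])
  # allowance below d_in fails the target check
  d2 <- find_diagnoses(sim$alignment, "sp01", sim$regions,
                       region_names = "LSU")
  if (nrow(d2) == 1L && d2$d_in > 0L) {
    d2$allowance <- d2$d_in - 1L
    chk2 <- validate_diagnosis(sim$alignment, d2, sim$regions)
    expect_false(chk2$pass[chk2$check == "targets_within_allowance"])
  }
  expect_error(validate_diagnosis(sim$alignment,
                                  dplyr::mutate(d, barcode = "acg!t"),
                                  sim$regions),
               "alphabet")
})

fix_single <- function(row) {
  alignment_from_strings(row$accession, row$sequence,
                         taxonmap = tibble::tibble(accession = row$accession,
                                                   species = row$species))
}

test_that("within-group variability is the max pairwise p-distance", {
  s <- strrep("ACGT", 50)
  aln <- alignment_from_strings(
    c("a", "b", "c"), c(s, s, s),
    taxonmap = tibble::tibble(accession = c("a", "b", "c"),
                              species = "sp"))
  v <- within_group_variability(aln, "sp")
  expect_equal(v$max_pairwise, 0)
  expect_equal(v$n_sequences, 3L)

  s2 <- paste0(strrep("ACGT", 25), strrep("TGCA", 25))
  s3 <- sub("^ACGTACGTACGTACGTACGTACGTACGT", "ACGAACGAACGAACGAACGAACGAACGA", s2)
  aln2 <- alignment_from_strings(
    c("a", "b"), c(s2, s3),
    taxonmap = tibble::tibble(accession = c("a", "b"), species = "sp"))
  expect_equal(within_group_variability(aln2, "sp")$max_pairwise, 7 / 200)

  v1 <- within_group_variability(aln2[1, ] |> fix_single(), "sp")
  expect_true(v1$single_sequence)
  expect_equal(v1$max_pairwise, 0)
})

test_that("species counting clusters by single linkage at the threshold", {
  # 6 members, 3 groups: intra <= 1%, inter >= 5% over 200 columns
  base <- sample(BASES, 200, replace = TRUE)
  mutate_at <- function(x, idx) {
    x[idx] <- vapply(x[idx], function(b) setdiff(BASES, b)[1], character(1))
    x
  }
  g1 <- base
  g2 <- mutate_at(base, 1:12)        # 6% from g1
  g3 <- mutate_at(base, 101:114)     # 7% from g1, disjoint sites from g2
  seqs <- c(paste(g1, collapse = ""), paste(mutate_at(g1, 1), collapse = ""),
            paste(g2, collapse = ""), paste(mutate_at(g2, 20), collapse = ""),
            paste(g3, collapse = ""), paste(mutate_at(g3, 50), collapse = ""))
  aln <- alignment_from_strings(
    sprintf("m%d", 1:6), seqs,
    taxonmap = tibble::tibble(accession = sprintf("m%d", 1:6),
                              species = NA_character_, genus = "G"))
  res <- estimate_species_count(aln, "G", threshold = 0.03)
  expect_equal(res$count, 3L)
  expect_equal(res$clusters$cluster[1], res$clusters$cluster[2])
  # count never increases as the threshold grows
  th <- c(0.001, 0.01, 0.03, 0.08, 0.5)
  counts <- vapply(th, function(t)
    estimate_species_count(aln, "G", threshold = t)$count, integer(1))
  expect_true(all(diff(counts) <= 0))
})
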