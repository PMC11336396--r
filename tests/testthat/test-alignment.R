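test_that("reading validates shape and alphabet", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  tm <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(">s1 some description", "ACGTRYacgt", ">s2", "ACGT-ACGTN"), fa)
  writeLines(c("accession\tspecies\tgenus\tfamily\torder",
               "s1\tSpA\tGenA\t\t", "s2\tSpB\tGenA\t\t"), tm)
  aln <- read_alignment(fa, tm)
  expect_s3_class(aln, "dna_alignment")
  expect_equal(n_columns(aln), 10L)
  expect_equal(aln$accession, c("s1", "s2"))
  expect_equal(aln$species, c("SpA", "SpB"))
  expect_equal(aln$sequence[1], "ACGTRYACGT")  # case-folded

  writeLines(c(">s1", "ACGTACGTAC", ">shorty", "ACGTACGTA"), fa)
  expect_error(read_alignment(fa), "shorty")

  writeLines(c(">s1", "ACGTACGTAC", ">s2", "ACGTACGXAC"), fa)
  expect_error(read_alignment(fa), "column 8")
})

test_that("U is mapped to T and unmapped accessions are flagged", {
  aln <- alignment_from_strings(c("a", "b"), c("ACGU", "ACGT"),
                                taxonmap = tibble::tibble(accession = "a",
                                                          species = "x"))
  expect_equal(aln$sequence[1], "ACGT")
  expect_equal(aln$mapped, c(TRUE, FALSE))
  expect_true(is.na(aln$species[2]))
})

test_that("pairwise distance counts differing comparable columns", {
  a <- paste(rep("A", 200), collapse = "")
  b <- paste(c(rep("A", 199), "C"), collapse = "")
  aln <- alignment_from_strings(c("x", "y", "z"), c(a, a, b))
  expect_equal(pairwise_distance(aln, "x", "y"), 0)
  expect_equal(pairwise_distance(aln, "x", "z"), 1 / 200)  # 0.005
  expect_equal(pairwise_distance(aln, "z", "x"),
               pairwise_distance(aln, "x", "z"))
})

test_that("long gap runs are excluded, short ones count", {
  base <- strrep("ACGT", 20)  # 80 columns
  gapped29 <- paste0(substr(base, 1, 20), strrep("-", 29),
                     substr(base, 50, 80))
  aln <- alignment_from_strings(c("a", "b"), c(base, gapped29))
  # 29-column deletion exceeds max_indel = 20: masked entirely
  expect_equal(pairwise_distance(aln, "a", "b"), 0)
  # with a higher threshold the gap columns count as differences
  expect_equal(pairwise_distance(aln, "a", "b", max_indel = 30), 29 / 80)
  # a 5-column gap is below the mask threshold
  gapped5 <- paste0(substr(base, 1, 20), "-----", substr(base, 26, 80))
  aln2 <- alignment_from_strings(c("a", "b"), c(base, gapped5))
  expect_equal(pairwise_distance(aln2, "a", "b"), 5 / 80)
})

test_that("ambiguity policies behave as documented", {
  aln <- alignment_from_strings(c("a", "b"), c("RCGT", "ACGT"))
  expect_equal(pairwise_distance(aln, "a", "b"), 0)            # lenient
  expect_equal(pairwise_distance(aln, "a", "b", ambig = "strict"), 1 / 4)
  expect_equal(pairwise_distance(aln, "a", "b", ambig = "exclude"), 0)
  aln2 <- alignment_from_strings(c("a", "b"), c("NCGT", "ACGA"))
  expect_equal(pairwise_distance(aln2, "a", "b", ambig = "exclude"), 1 / 3)
  expect_error(
    pairwise_distance(alignment_from_strings(c("a", "b"), c("--", "--")),
                      "a", "b"),
    "comparable")
})

test_that("distance equals a brute-force column loop on random fixtures", {
  withr::local_seed(101)
  for (rep in 1:10) {
    aln <- random_alignment(4, sample(50:500, 1), gap_rate = 0.05,
                            ambig_rate = 0.02)
    pairs <- utils::combn(aln$accession, 2)
    for (k in seq_len(ncol(pairs))) {
      a <- pairs[1, k]; b <- pairs[2, k]
      expect_equal(
        pairwise_distance(aln, a, b),
        oracle_p_distance(aln$sequence[match(a, aln$accession)],
                          aln$sequence[match(b, aln$accession)]))
    }
  }
})

test_that("column/region coordinate conversion round-trips on non-gaps", {
  #            1234567890123456
  s1 <- "AAAAACCCCCGGGGG"        # no gaps
  s2 <- "AAAAACC--CG-GGG"        # gaps inside region 2
  aln <- alignment_from_strings(c("r1", "r2"), c(s1, s2))
  regions <- tibble::tibble(region = c("R1", "R2"),
                            start = c(1L, 6L), end = c(5L, 15L))
  expect_equal(column_to_region_position(aln, regions, "r1", 8),
               list(region = "R2", position = 3L))
  # r2 has 2 gaps before column 11 within R2
  expect_equal(column_to_region_position(aln, regions, "r2", 11),
               list(region = "R2", position = 4L))
  expect_error(column_to_region_position(aln, regions, "r2", 8), "gap")

  for (col in c(1:7, 10:11, 13:15)) {      # all non-gap columns of r2
    p <- column_to_region_position(aln, regions, "r2", col)
    expect_equal(
      region_position_to_column(aln, regions, "r2", p$region, p$position),
      col)
  }
})

test_that("region maps reject overlap and out-of-bounds coordinates", {
  expect_error(dnadiag:::validate_region_map(
    tibble::tibble(region = c("A", "B"), start = c(1L, 5L), end = c(6L, 9L))),
    "overlap")
  expect_error(dnadiag:::validate_region_map(
    tibble::tibble(region = "A", start = 1L, end = 50L), n_columns = 20),
    "exceeds")
  ok <- dnadiag:::validate_region_map(
    tibble::tibble(region = c("A", "full"), start = c(1L, 1L),
                   end = c(10L, 10L)), n_columns = 10)
  expect_equal(nrow(ok), 2L)
})

test_that("region map JSON and TSV readers agree", {
  js <- withr::local_tempfile(fileext = ".json")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines('{"ITS1": [1, 5], "ITS2": [6, 12]}', js)
  writeLines(c("region\tstart\tend", "ITS1\t1\t5", "ITS2\t6\t12"), tsv)
  expect_equal(read_region_map(js), read_region_map(tsv))
})
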