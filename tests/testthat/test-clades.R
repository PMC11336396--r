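toy_newick <- "((A,B)95,(C,(D,E)98)87);"

test_that("Newick supports are parsed, normalised, or warned about", {
  tr <- read_tree(toy_newick)
  expect_setequal(tr$support[!is.na(tr$support)], c(95, 87, 98))
  # proportions scale to [0,100]
  tr2 <- read_tree("((A,B)0.95,(C,D)0.87);")
  expect_setequal(tr2$support[!is.na(tr2$support)], c(95, 87))
  # slash dialect takes the chosen field
  tr3 <- read_tree("((A,B)80.2/99,(C,D)70/91);", dialect = "slash")
  expect_setequal(tr3$support[!is.na(tr3$support)], c(99, 91))
  expect_warning(read_tree("((A,B),(C,D));"), "no numeric support")
  suppressWarnings(expect_error(read_tree("((A,B"), "Newick"))
})

test_that("write-then-read preserves topology, supports and lengths", {
  withr::local_seed(500)
  for (rep in 1:25) {
    tr <- random_support_tree(sample(4:20, 1))
    f <- tempfile(fileext = ".nwk")
    ape::write.tree(tr, f)
    back <- read_tree(f)
    expect_true(ape::all.equal.phylo(tr, back, use.edge.length = TRUE))
    expect_equal(back$support, as.numeric(tr$node.label))
    unlink(f)
  }
})

test_that("least inclusive clades match the toy tree and a path oracle", {
  tr <- read_tree(toy_newick)
  lic <- least_inclusive_clade(tr, c("D", "E"))
  expect_equal(lic$support, 98)
  expect_setequal(lic$leafset, c("D", "E"))
  expect_equal(lic$swept_in, character())

  lic2 <- least_inclusive_clade(tr, c("A", "D"))
  expect_setequal(lic2$leafset, c("A", "B", "C", "D", "E"))
  expect_setequal(lic2$swept_in, c("B", "C", "E"))
  expect_error(least_inclusive_clade(tr, c("A", "ZZ")), "ZZ")

  withr::local_seed(77)
  for (rep in 1:40) {
    tr <- random_support_tree(sample(5:15, 1))
    k <- sample(2:4, 1)
    leaves <- sample(tr$tip.label, k)
    lic <- least_inclusive_clade(tr, leaves)
    expect_equal(lic$node, oracle_mrca(tr, leaves))
    # idempotence: the clade is its own least-inclusive clade
    again <- least_inclusive_clade(tr, lic$leafset)
    expect_equal(again$node, lic$node)
  }
})

test_that("monophyly reports intruders", {
  tr <- read_tree(toy_newick)
  expect_true(is_monophyletic(tr, c("A", "B"))$monophyletic)
  m <- is_monophyletic(tr, c("B", "C"))
  expect_false(m$monophyletic)
  expect_true(all(m$intruders %in% c("A", "D", "E")))
  taxa <- tibble::tibble(accession = c("A", "B", "C", "D", "E"),
                         genus = c("g1", "g1", "g2", "g2", "g2"))
  expect_true(is_monophyletic(tr, "g2", taxa = taxa)$monophyletic)
})

# reference genus {A,B} with breadth 2; unlabelled C,D,E
delimit_toy <- function() {
  tr <- read_tree("((A:1,B:1)96:2,(C:2.2,(D:1,E:1)99:1.2)90:1);")
  taxa <- tibble::tibble(accession = c("A", "B", "C", "D", "E"),
                         genus = c("ref", "ref", NA, NA, NA))
  list(tree = tr, taxa = taxa)
}

test_that("qualifying clades are accepted greedily and disjointly", {
  x <- delimit_toy()
  res <- propose_taxa(x$tree, x$taxa)
  # (D,E): support 99, breadth 2 within [1,4] -> accepted;
  # (C,(D,E)) has support 90 -> rejected; C alone has breadth 0 -> unassigned
  expect_equal(nrow(res$candidates), 1L)
  expect_setequal(res$candidates$leaves[[1]], c("D", "E"))
  expect_equal(res$unassigned, "C")
  # post-hoc: every candidate is monophyletic and well supported
  for (i in seq_len(nrow(res$candidates))) {
    expect_true(is_monophyletic(x$tree,
                                res$candidates$leaves[[i]])$monophyletic)
    expect_gt(res$candidates$support[i], 95)
  }
  # dropping the support bar never assigns fewer leaves
  res0 <- propose_taxa(x$tree, x$taxa, support_min = 0)
  expect_gte(sum(res0$candidates$n_leaves), sum(res$candidates$n_leaves))
})

test_that("absent supports fail conservatively unless told otherwise", {
  tr <- suppressWarnings(read_tree("((A:1,B:1):2,((C:1,D:1):1.0,E:2):1);"))
  taxa <- tibble::tibble(accession = c("A", "B", "C", "D", "E"),
                         genus = c("ref", "ref", NA, NA, NA))
  res_fail <- propose_taxa(tr, taxa)
  expect_equal(nrow(res_fail$candidates), 0L)
  res_pass <- propose_taxa(tr, taxa, absent_support = "pass")
  expect_gte(nrow(res_pass$candidates), 1L)
})

test_that("codes are stable, ordered by smallest accession, prefixable", {
  x <- delimit_toy()
  res <- assign_codes(propose_taxa(x$tree, x$taxa))
  expect_equal(res$candidates$code, "GEN01")
  res2 <- assign_codes(propose_taxa(x$tree, x$taxa))
  expect_identical(res$candidates$code, res2$candidates$code)
  # order-level "GS" style labels
  res3 <- assign_codes(propose_taxa(x$tree, x$taxa, rank = "genus"),
                       prefix = "GS", start = 22L)
  expect_equal(res3$candidates$code, "GS22")
})

test_that("greedy partitions are minimal on small trees (exhaustive check)", {
  withr::local_seed(1234)
  for (rep in 1:12) {
    n <- sample(6:12, 1)
    tr <- random_support_tree(n)
    taxa <- tibble::tibble(
      accession = tr$tip.label,
      genus = ifelse(seq_len(n) <= 2, "ref", NA))
    res <- propose_taxa(tr, taxa, support_min = 90)
    # rebuild the qualification predicate independently
    unlab <- taxa$accession[is.na(taxa$genus)]
    qual <- Filter(function(s) {
      if (!all(s %in% unlab)) return(FALSE)
      lic <- least_inclusive_clade(tr, s)
      if (!setequal(lic$leafset, s)) return(FALSE)
      if (length(s) > 1L && (is.na(lic$support) || lic$support <= 90)) {
        return(FALSE)
      }
      cfg <- res$config
      lic$breadth >= cfg$band_abs[1] && lic$breadth <= cfg$band_abs[2]
    }, oracle_clades(tr))
    best <- oracle_min_partition(qual, unlab)
    expect_equal(sum(res$candidates$n_leaves %||% 0L), best$covered,
                 info = sprintf("coverage, rep %d", rep))
    expect_equal(nrow(res$candidates), best$count,
                 info = sprintf("count, rep %d", rep))
  }
})

test_that("planted genus boundaries are recovered from simulated trees", {
  withr::local_seed(321)
  hits <- 0L
  n_rep <- 10L
  for (rep in seq_len(n_rep)) {
    cfg <- simulation_config(n_species = 9, seqs_per_species = 2,
                             n_genera = 3, between_genus_divergence = 0.5,
                             seed = 5000 + rep)
    tr <- simulate_tree(cfg)
    taxa <- attr(tr, "sim_taxa")
    # first genus is the labelled reference; the others are to be found
    taxa$genus[taxa$genus != "gen01"] <- NA
    res <- propose_taxa(tr, taxa, band = c(0.3, 3))
    got <- lapply(res$candidates$leaves, sort)
    truth <- attr(tr, "sim_taxa")
    want <- unname(lapply(
      split(truth$accession, truth$genus)[c("gen02", "gen03")], sort))
    if (length(got) == 2L && setequal(sapply(got, paste, collapse = ","),
                                      sapply(want, paste, collapse = ","))) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, ceiling(0.8 * n_rep))
})
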