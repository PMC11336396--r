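# Seeded generator of multi-species ITS+LSU alignments with the
# statistical structure the analysis assumes: tight intraspecific
# clusters, larger interspecific divergence, occasional gap runs and
# ambiguity codes, and (optionally) a planted diagnostic motif whose
# ground truth is recorded alongside the alignment.

#' Simulation configuration
#'
#' Defaults emulate the data regime of soil-eDNA rRNA surveys of
#' arbuscular mycorrhizal fungi: 10 congeneric species with 5 sequences
#' each, ITS1/5.8S/ITS2/LSU region lengths of 120/160/250/600 columns,
#' within-species divergence around 1% (intraspecific ITS variability in
#' such groups runs roughly 0.5-4%), between-species divergence around
#' 10%, sparse indel runs and rare ambiguity codes.
#'
#' @param n_species Number of species.
#' @param seqs_per_species Sequences per species.
#' @param n_genera Number of genera the species are split across
#'   (1 = all congeneric).
#' @param region_lengths Named integer vector of region lengths in
#'   alignment columns (ITS1, 5.8S, ITS2, LSU).
#' @param within_divergence Target mean within-species p-distance.
#' @param between_divergence Target mean between-species p-distance
#'   (must exceed `within_divergence`).
#' @param between_genus_divergence Target mean between-genus p-distance
#'   (used when `n_genera > 1`).
#' @param indel_rate Expected number of indel runs per sequence
#'   (Poisson).
#' @param indel_mean_length Mean indel run length (geometric).
#' @param ambiguity_rate Per-site probability of replacing a base by an
#'   ambiguity code containing it.
#' @param model Substitution model; `"JC69"` is the implemented member.
#' @param seed Mandatory RNG seed.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(n_species = 10L, seqs_per_species = 5L,
                              n_genera = 1L,
                              region_lengths = c(ITS1 = 120L, `5.8S` = 160L,
                                                 ITS2 = 250L, LSU = 600L),
                              within_divergence = 0.01,
                              between_divergence = 0.10,
                              between_genus_divergence = 0.20,
                              indel_rate = 0.5, indel_mean_length = 6,
                              ambiguity_rate = 0.001,
                              model = "JC69", seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(within_divergence >= 0, within_divergence < 1,
            between_divergence < 1, n_species >= 1, seqs_per_species >= 1)
  if (within_divergence >= between_divergence) {
    stop("within-species divergence must be below between-species divergence",
         call. = FALSE)
  }
  if (!identical(model, "JC69")) stop("only JC69 is implemented", call. = FALSE)
  structure(list(
    n_species = as.integer(n_species),
    seqs_per_species = as.integer(seqs_per_species),
    n_genera = as.integer(n_genera),
    region_lengths = region_lengths,
    within_divergence = within_divergence,
    between_divergence = between_divergence,
    between_genus_divergence = between_genus_divergence,
    indel_rate = indel_rate, indel_mean_length = indel_mean_length,
    ambiguity_rate = ambiguity_rate, model = model,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Expected JC69 per-site difference after divergence t
#'
#' @param t Branch length in expected substitutions per site.
#' @return Probability that the two ends of the branch differ.
#' @examples
#' jc69_p_diff(0.1)  # 0.0936
#' @export
jc69_p_diff <- function(t) 0.75 * (1 - exp(-4 * t / 3))

# inverse: branch length giving an expected p-distance
jc69_t <- function(p) -0.75 * log(1 - 4 * p / 3)

rescale_mean_pairwise <- function(tr, target) {
  if (length(tr$tip.label) < 2L || target <= 0) {
    tr$edge.length <- tr$edge.length * 0
    return(tr)
  }
  pd <- ape::cophenetic.phylo(tr)
  m <- mean(pd[upper.tri(pd)])
  tr$edge.length <- tr$edge.length * (target / m)
  tr
}

#' Simulate a species tree with within-species tips
#'
#' A Yule (pure-birth) tree over species -- nested inside a Yule genus
#' tree when `n_genera > 1` -- with a small coalescent tip cluster per
#' species. Branch lengths are rescaled so that mean pairwise patristic
#' distances hit the JC69 branch lengths implied by the configured
#' within-/between-species p-distance targets. All internal nodes carry
#' support 100 (the simulated topology is exact). Deterministic per
#' seed.
#'
#' @param config A `sim_config` from [simulation_config()].
#' @return A `phylo` whose tip labels are accessions `spNN_M`, with a
#'   `support` vector, plus `sim_taxa`: a tibble mapping accessions to
#'   species/genus labels.
#' @export
simulate_tree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ns <- config$n_species
  ng <- config$n_genera
  t_within <- jc69_t(config$within_divergence)
  t_between <- jc69_t(config$between_divergence)

  species_subtree <- function(k, labels) {
    if (k == 1L) return(NULL)
    st <- ape::rcoal(k, tip.label = labels)
    rescale_mean_pairwise(st, t_within)
  }

  # species-level backbone (possibly nested in genera)
  genus_of_species <- sort(rep_len(seq_len(ng), ns))
  sp_labels <- sprintf("sp%02d", seq_len(ns))
  if (ng == 1L) {
    backbone <- if (ns == 1L) NULL else
      rescale_mean_pairwise(ape::rphylo(ns, birth = 1, death = 0), t_between)
    if (!is.null(backbone)) backbone$tip.label <- sp_labels
  } else {
    t_genus <- jc69_t(config$between_genus_divergence)
    backbone <- rescale_mean_pairwise(ape::rphylo(ng, birth = 1, death = 0),
                                      t_genus)
    backbone$tip.label <- sprintf("gstub%02d", seq_len(ng))
    for (g in seq_len(ng)) {
      sps <- sp_labels[genus_of_species == g]
      sub <- if (length(sps) == 1L) NULL else
        rescale_mean_pairwise(ape::rphylo(length(sps), birth = 1, death = 0),
                              t_between)
      if (is.null(sub)) {
        backbone$tip.label[backbone$tip.label == sprintf("gstub%02d", g)] <- sps
      } else {
        sub$tip.label <- sps
        backbone <- ape::bind.tree(backbone, sub,
                                   where = which(backbone$tip.label ==
                                                   sprintf("gstub%02d", g)))
      }
    }
  }

  # graft within-species clusters onto each species tip
  k <- config$seqs_per_species
  tip_labels <- function(sp) sprintf("%s_%d", sp, seq_len(k))
  if (is.null(backbone)) {
    tree <- if (k == 1L) {
      ape::read.tree(text = sprintf("(%s:0);", tip_labels(sp_labels)[1]))
    } else {
      st <- species_subtree(k, tip_labels(sp_labels[1]))
      st
    }
  } else {
    tree <- backbone
    for (sp in sp_labels) {
      if (k == 1L) {
        tree$tip.label[tree$tip.label == sp] <- tip_labels(sp)[1]
      } else {
        st <- species_subtree(k, tip_labels(sp))
        tree <- ape::bind.tree(tree, st, where = which(tree$tip.label == sp))
      }
    }
  }
  tree$node.label <- rep("100", tree$Nnode)
  tree$support <- rep(100, tree$Nnode)
  sp_of_tip <- sub("_\\d+$", "", tree$tip.label)
  attr(tree, "sim_taxa") <- tibble::tibble(
    accession = tree$tip.label,
    species = sp_of_tip,
    genus = sprintf("gen%02d", genus_of_species[match(sp_of_tip, sp_labels)]),
    family = NA_character_, order = NA_character_
  )
  tree
}

# ambiguity codes containing each base (two-fold codes + N)
AMBIG_FOR_BASE <- list(
  A = c("R", "W", "M", "N"), C = c("Y", "S", "M", "N"),
  G = c("R", "S", "K", "N"), T = c("Y", "W", "K", "N")
)

#' Evolve sequences along a tree under JC69
#'
#' The root sequence is uniform over {A,C,G,T}; along each branch of
#' length t every site differs from its parent with probability
#' `jc69_p_diff(t)`, changed sites drawn uniformly from the other three
#' bases. Indel runs are then laid down as aligned gap runs (the
#' simulator emits an alignment directly) and ambiguity codes injected
#' at the configured rate. The returned truth record holds the species
#' map and, per species, the realized maximum within-species p-distance
#' computed by an independent column-loop implementation of the same
#' definition used by [within_group_variability()].
#'
#' @param tree Tree from [simulate_tree()].
#' @param config The `sim_config` used to build it.
#' @return List with `alignment` (a `dna_alignment`), `regions` (region
#'   map tibble incl. `full`), `tree`, `truth`.
#' @export
evolve_sequences <- function(tree, config) {
  rl <- config$region_lengths
  nsites <- sum(rl)
  bases <- c("A", "C", "G", "T")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  seqs <- vector("list", nnode)
  root <- ntip + 1L
  seqs[[root]] <- sample.int(4L, nsites, replace = TRUE)
  # cladewise order visits parents before children
  po <- ape::reorder.phylo(tree, "cladewise")$edge
  el <- tree$edge.length[match(paste(po[, 1], po[, 2]),
                               paste(tree$edge[, 1], tree$edge[, 2]))]
  for (i in seq_len(nrow(po))) {
    parent <- po[i, 1]; child <- po[i, 2]
    p <- jc69_p_diff(el[i])
    s <- seqs[[parent]]
    hit <- stats::runif(nsites) < p
    if (any(hit)) {
      shift <- sample.int(3L, sum(hit), replace = TRUE)
      s[hit] <- ((s[hit] - 1L + shift) %% 4L) + 1L
    }
    seqs[[child]] <- s
  }
  chars <- lapply(seq_len(ntip), function(i) bases[seqs[[i]]])

  # indel runs as aligned gap runs
  for (i in seq_len(ntip)) {
    n_runs <- stats::rpois(1, config$indel_rate)
    for (r in seq_len(n_runs)) {
      len <- stats::rgeom(1, 1 / config$indel_mean_length) + 1L
      start <- sample.int(max(1L, nsites - len + 1L), 1)
      chars[[i]][seq.int(start, min(nsites, start + len - 1L))] <- "-"
    }
  }
  # ambiguity codes containing the true base
  for (i in seq_len(ntip)) {
    hit <- which(stats::runif(nsites) < config$ambiguity_rate &
                   chars[[i]] != "-")
    for (j in hit) {
      opts <- AMBIG_FOR_BASE[[chars[[i]][j]]]
      chars[[i]][j] <- opts[sample.int(length(opts), 1)]
    }
  }

  taxa <- attr(tree, "sim_taxa")
  aln <- alignment_from_strings(
    tree$tip.label, vapply(chars, paste, character(1), collapse = ""),
    taxonmap = taxa
  )
  bounds <- unname(cumsum(rl))
  regions <- tibble::tibble(
    region = c(names(rl), "full"),
    start = c(1L, utils::head(bounds, -1) + 1L, 1L),
    end = c(bounds, nsites)
  )
  truth <- list(
    seed = config$seed,
    species = stats::setNames(as.list(taxa$species), taxa$accession),
    within_species_max = truth_within_max(aln, taxa),
    planted = NULL
  )
  list(alignment = aln, regions = regions, tree = tree, truth = truth)
}

# independent (plain double-loop) implementation of max within-species
# p-distance: gap-vs-base counts, gap-vs-gap excluded, gap runs > 20
# columns masked, lenient ambiguity matching
truth_within_max <- function(aln, taxa, max_indel = 20L) {
  out <- list()
  for (sp in unique(taxa$species)) {
    acc <- taxa$accession[taxa$species == sp]
    mx <- 0
    if (length(acc) >= 2L) {
      mats <- lapply(acc, function(a)
        strsplit(aln$sequence[match(a, aln$accession)], "", fixed = TRUE)[[1]])
      masks <- lapply(mats, function(ch) {
        r <- rle(ch == "-")
        rep(r$values & r$lengths > max_indel, r$lengths)
      })
      for (i in seq_along(acc)[-length(acc)]) {
        for (j in seq.int(i + 1L, length(acc))) {
          keep <- !masks[[i]] & !masks[[j]]
          a <- mats[[i]][keep]; b <- mats[[j]][keep]
          ncomp <- 0L; ndiff <- 0L
          for (cix in seq_along(a)) {
            ga <- a[cix] == "-"; gb <- b[cix] == "-"
            if (ga && gb) next
            ncomp <- ncomp + 1L
            if (ga || gb) { ndiff <- ndiff + 1L; next }
            if (bitwAnd(IUPAC_MASK[[a[cix]]], IUPAC_MASK[[b[cix]]]) == 0L) {
              ndiff <- ndiff + 1L
            }
          }
          d <- if (ncomp > 0L) ndiff / ncomp else 0
          if (d > mx) mx <- d
        }
      }
    }
    out[[sp]] <- mx
  }
  out
}

#' Plant a diagnostic motif for one species
#'
#' Chooses a gap-free window of the requested length inside a region,
#' rewrites every target sequence to a motif derived from the canonical
#' target window with `min_separation` positions changed (preferring a
#' base absent from that column in all sequences), then minimally edits
#' any non-target sequence still closer than `min_separation`
#' differences. The truth record gains the planted window and its
#' realized `d_out`. Planting is a no-op for sequences already carrying
#' the motif at sufficient separation.
#'
#' @param sim Output of [evolve_sequences()] (or [simulate_dataset()]).
#' @param species Target species label.
#' @param length Motif length in columns (default 25).
#' @param min_separation Minimum differences to every non-target
#'   sequence (default 3).
#' @param region Region to plant in (default `"ITS2"`).
#' @return `sim` with modified alignment and updated truth.
#' @export
plant_barcode <- function(sim, species, length = 25L, min_separation = 3L,
                          region = "ITS2") {
  aln <- sim$alignment
  regions <- sim$regions
  # no-op when this species already carries a planted motif at
  # sufficient separation in the requested region
  pl <- sim$truth$planted
  if (!is.null(pl) && identical(pl$species, species) &&
      identical(pl$region, region) && pl$length == as.integer(length) &&
      pl$min_separation >= min_separation) {
    win0 <- seq.int(pl$start_col, pl$start_col + pl$length - 1L)
    motif0 <- toupper(strsplit(pl$barcode, "", fixed = TRUE)[[1]])
    t_rows0 <- which(aln$species == species)
    carried <- all(vapply(t_rows0, function(i)
      identical(strsplit(aln$sequence[i], "", fixed = TRUE)[[1]][win0],
                motif0), logical(1)))
    if (carried && pl$d_out >= min_separation) return(sim)
  }
  cols_all <- region_columns(regions, region, n_columns(aln))
  if (base::length(cols_all) < length) {
    stop("region ", region, " shorter than the requested motif", call. = FALSE)
  }
  t_rows <- which(aln$species == species)
  if (base::length(t_rows) == 0L) stop("species absent: ", species, call. = FALSE)
  o_rows <- setdiff(seq_len(nrow(aln)), t_rows)
  mat <- do.call(rbind, strsplit(aln$sequence, "", fixed = TRUE))

  # window where no target sequence has a gap or ambiguity code
  ok_col <- colSums(mat[t_rows, cols_all, drop = FALSE] == "-") == 0L &
    colSums(matrix(is_ambiguity_mask(iupac_mask(mat[t_rows, cols_all])),
                   nrow = base::length(t_rows))) == 0L
  starts <- which(vapply(seq_len(base::length(cols_all) - length + 1L),
                         function(s) all(ok_col[seq.int(s, s + length - 1L)]),
                         logical(1)))
  if (base::length(starts) == 0L) {
    stop("no gap-free window of length ", length, " in ", region,
         " for ", species, call. = FALSE)
  }
  start <- cols_all[starts[ceiling(stats::runif(1) * base::length(starts))]]
  win <- seq.int(start, start + length - 1L)

  # motif: canonical window with min_separation positions made novel
  motif <- mat[t_rows[1], win]
  bases <- c("A", "C", "G", "T")
  edit_pos <- sample(seq_len(length), min_separation)
  for (p in edit_pos) {
    present <- unique(mat[, win[p]])
    novel <- setdiff(bases, present)
    motif[p] <- if (base::length(novel)) novel[1] else
      setdiff(bases, motif[p])[1]
  }
  mat[t_rows, win] <- matrix(motif, nrow = base::length(t_rows),
                             ncol = length, byrow = TRUE)

  mm <- iupac_mask(motif)
  row_dist <- function(i) {
    ch <- mat[i, win]
    m <- iupac_mask(ch)
    gap_a <- m == 0L
    sum(gap_a | bitwAnd(m, mm) == 0L)
  }
  for (i in o_rows) {
    d <- row_dist(i)
    while (d < min_separation) {
      cand <- which(mat[i, win] != "-" &
                      bitwAnd(iupac_mask(mat[i, win]), mm) > 0L)
      p <- cand[1]
      mat[i, win[p]] <- setdiff(bases, c(motif[p], mat[i, win[p]]))[1]
      d <- row_dist(i)
    }
  }

  aln$sequence <- apply(mat, 1, paste, collapse = "")
  sim$alignment <- aln
  d_out <- min(vapply(o_rows, row_dist, numeric(1)))
  first_pos <- column_to_region_position(aln, regions, aln$accession[t_rows[1]],
                                         start)
  sim$truth$planted <- list(
    species = species, region = region,
    start_col = start, length = as.integer(length),
    start = first_pos$position,
    end = first_pos$position + as.integer(length) - 1L,
    barcode = tolower(paste(motif, collapse = "")),
    min_separation = as.integer(min_separation),
    d_out = as.integer(d_out)
  )
  sim$truth$within_species_max <- truth_within_max(
    aln, tibble::tibble(accession = aln$accession, species = aln$species))
  sim
}

#' Simulate a full dataset (tree, alignment, truth)
#'
#' Convenience wrapper: [simulate_tree()] then [evolve_sequences()],
#' optionally followed by [plant_barcode()] for the first species.
#'
#' @param config A `sim_config`.
#' @param plant `NULL`, or a list with any of `species`, `length`,
#'   `min_separation`, `region` to plant a motif.
#' @return As [evolve_sequences()].
#' @export
simulate_dataset <- function(config, plant = NULL) {
  tree <- simulate_tree(config)
  sim <- evolve_sequences(tree, config)
  if (!is.null(plant)) {
    args <- utils::modifyList(
      list(species = sim$alignment$species[1], length = 25L,
           min_separation = 3L, region = "ITS2"), plant)
    sim <- plant_barcode(sim, species = args$species, length = args$length,
                         min_separation = args$min_separation,
                         region = args$region)
  }
  sim
}

#' Write a simulated dataset to disk
#'
#' Emits exactly the formats the pipeline consumes: aligned FASTA, taxon
#' map TSV, region map JSON, Newick tree and truth JSON.
#'
#' @param sim Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Named list of file paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    fasta = file.path(dir, "alignment.fasta"),
    taxa = file.path(dir, "taxa.tsv"),
    regions = file.path(dir, "regions.json"),
    tree = file.path(dir, "tree.nwk"),
    truth = file.path(dir, "truth.json")
  )
  write_alignment(sim$alignment, paths$fasta, paths$taxa)
  rj <- stats::setNames(
    lapply(seq_len(nrow(sim$regions)),
           function(i) c(sim$regions$start[i], sim$regions$end[i])),
    sim$regions$region)
  jsonlite::write_json(rj, paths$regions, auto_unbox = FALSE)
  ape::write.tree(sim$tree, paths$tree)
  jsonlite::write_json(sim$truth, paths$truth, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paths)
}

#' Read a simulated dataset back and cross-validate its parts
#'
#' Loads the five files written by [write_simulation()] and checks that
#' alignment, taxon map, tree and truth agree on accessions, counts and
#' widths.
#'
#' @param dir Directory written by [write_simulation()].
#' @return List with `alignment`, `regions`, `tree`, `truth`.
#' @export
read_simulation <- function(dir) {
  aln <- read_alignment(file.path(dir, "alignment.fasta"),
                        file.path(dir, "taxa.tsv"))
  regions <- read_region_map(file.path(dir, "regions.json"),
                             n_columns = n_columns(aln))
  tree <- suppressWarnings(read_tree(file.path(dir, "tree.nwk")))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  if (!setequal(tree$tip.label, aln$accession)) {
    stop("tree tips and alignment accessions disagree", call. = FALSE)
  }
  if (!setequal(names(truth$species), aln$accession)) {
    stop("truth species map and alignment accessions disagree", call. = FALSE)
  }
  sp <- unlist(truth$species)[aln$accession]
  if (!all(sp == aln$species)) {
    stop("truth species labels disagree with taxon map", call. = FALSE)
  }
  list(alignment = aln, regions = regions, tree = tree, truth = truth)
}
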