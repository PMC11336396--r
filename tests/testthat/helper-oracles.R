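# Independent brute-force oracles: plain character loops and exhaustive
# searches, written without reusing the package's internals.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# pairwise "differs" lookup enumerated straight from the code sets:
# gap-vs-base differs, gap-vs-gap does not, ambiguity codes match when
# their sets intersect
ORACLE_DIFF <- local({
  syms <- c(names(IUPAC_SETS), "-")
  m <- matrix(FALSE, length(syms), length(syms),
              dimnames = list(syms, syms))
  for (a in syms) {
    for (b in syms) {
      if (a == "-" && b == "-") next
      if (a == "-" || b == "-") { m[a, b] <- TRUE; next }
      m[a, b] <- length(intersect(IUPAC_SETS[[a]], IUPAC_SETS[[b]])) == 0L
    }
  }
  m
})

# Hamming count over explicit columns via the enumerated lookup
oracle_hamming <- function(sa, sb, cols) {
  a <- strsplit(sa, "", fixed = TRUE)[[1]][cols]
  b <- strsplit(sb, "", fixed = TRUE)[[1]][cols]
  sum(ORACLE_DIFF[cbind(a, b)])
}

# proportion of differing comparable columns, long gap runs masked
oracle_p_distance <- function(sa, sb, max_indel = 20L) {
  a <- strsplit(sa, "", fixed = TRUE)[[1]]
  b <- strsplit(sb, "", fixed = TRUE)[[1]]
  mask_runs <- function(x) {
    r <- rle(x == "-")
    rep(r$values & r$lengths > max_indel, r$lengths)
  }
  keep <- !mask_runs(a) & !mask_runs(b)
  a <- a[keep]; b <- b[keep]
  ncomp <- 0L; ndiff <- 0L
  for (i in seq_along(a)) {
    ga <- a[i] == "-"; gb <- b[i] == "-"
    if (ga && gb) next
    ncomp <- ncomp + 1L
    if (ga || gb || length(intersect(IUPAC_SETS[[a[i]]],
                                     IUPAC_SETS[[b[i]]])) == 0L) {
      ndiff <- ndiff + 1L
    }
  }
  ndiff / ncomp
}

# Exhaustive window enumeration + filtering + ranking for the best
# diagnostic window of one region; mirrors the published selection rules
# through plain loops.
oracle_best_window <- function(aln, target, region_start, region_end,
                               l_min = 20L, l_max = 30L, min_sep = 2L) {
  t_rows <- which(aln$species == target)
  o_rows <- setdiff(seq_len(nrow(aln)), t_rows)
  can <- t_rows[1]
  chars <- strsplit(aln$sequence, "", fixed = TRUE)
  count <- function(i, cols) {
    sum(ORACLE_DIFF[cbind(chars[[i]][cols], chars[[can]][cols])])
  }
  best <- NULL
  for (s in seq.int(region_start, region_end)) {
    for (L in seq.int(l_min, l_max)) {
      e <- s + L - 1L
      if (e > region_end) next
      cols <- s:e
      amb <- 0L
      for (i in t_rows) {
        amb <- amb + sum(chars[[i]][cols] %in%
                           c("R", "Y", "S", "W", "K", "M",
                             "B", "D", "H", "V", "N"))
      }
      d_in <- max(vapply(t_rows, count, integer(1), cols = cols))
      d_out <- min(vapply(o_rows, count, integer(1), cols = cols))
      if (amb > 0L || d_out < min_sep || d_in > d_out - 1L) next
      gaps <- sum(chars[[can]][cols] == "-")
      row <- c(margin = d_out - d_in, gaps = gaps, start = s, length = L,
               d_in = d_in, d_out = d_out)
      if (is.null(best) ||
          row["margin"] > best["margin"] ||
          (row["margin"] == best["margin"] && row["gaps"] < best["gaps"]) ||
          (row["margin"] == best["margin"] && row["gaps"] == best["gaps"] &&
             row["start"] < best["start"]) ||
          (row["margin"] == best["margin"] && row["gaps"] == best["gaps"] &&
             row["start"] == best["start"] && row["length"] < best["length"])) {
        best <- row
      }
    }
  }
  best
}

# MRCA as the deepest node on the intersection of root paths
oracle_mrca <- function(tree, leaves) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  parent_of <- integer(max(tree$edge))
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  path_to_root <- function(node) {
    p <- node
    while (node != root) {
      node <- parent_of[node]
      p <- c(p, node)
    }
    p
  }
  idx <- match(leaves, tree$tip.label)
  paths <- lapply(idx, path_to_root)
  common <- Reduce(intersect, paths)
  # deepest common node = the one with the longest root path
  common[which.max(vapply(common, function(n) length(path_to_root(n)),
                          integer(1)))]
}

# All clades (internal-node leafsets and singletons) of a tree
oracle_clades <- function(tree) {
  ntip <- length(tree$tip.label)
  sets <- lapply(seq_len(ntip), function(i) tree$tip.label[i])
  for (n in seq.int(ntip + 1L, ntip + tree$Nnode)) {
    stack <- n; tips <- integer()
    while (length(stack)) {
      x <- stack[1]; stack <- stack[-1]
      if (x <= ntip) tips <- c(tips, x) else {
        stack <- c(stack, tree$edge[tree$edge[, 1] == x, 2])
      }
    }
    sets[[length(sets) + 1L]] <- sort(tree$tip.label[tips])
  }
  unique(sets)
}

# Exhaustive minimal disjoint cover of `leaves` by qualifying leafsets:
# maximise covered leaves, then minimise the number of sets.
oracle_min_partition <- function(qualifying, leaves) {
  leaves <- sort(leaves)
  best <- list(covered = -1L, count = Inf)
  recurse <- function(remaining, chosen_count, covered) {
    if (length(remaining) == 0L) {
      if (covered > best$covered ||
          (covered == best$covered && chosen_count < best$count)) {
        best <<- list(covered = covered, count = chosen_count)
      }
      return(invisible())
    }
    # bound: even covering everything left cannot beat the best
    if (covered + length(remaining) < best$covered) return(invisible())
    leaf <- remaining[1]
    opts <- Filter(function(s) leaf %in% s && all(s %in% remaining),
                   qualifying)
    for (s in opts) {
      recurse(setdiff(remaining, s), chosen_count + 1L, covered + length(s))
    }
    recurse(setdiff(remaining, leaf), chosen_count, covered)  # leave it out
  }
  recurse(leaves, 0L, 0L)
  best
}

# random support-annotated ultrametric-ish tree for round-trip tests
random_support_tree <- function(n) {
  tr <- ape::rtree(n)
  tr$node.label <- as.character(sample(50:100, tr$Nnode, replace = TRUE))
  tr
}
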