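# Tree-based delimitation of candidate higher taxa: least-inclusive
# clades under monophyly / support / phylogenetic-breadth / minimality
# criteria, with provisional alphanumeric codes.

#' Read a support-annotated Newick tree
#'
#' Internal-node labels are parsed as support values; the
#' `"label/value"` dialect (e.g. SH-aLRT/UFboot) takes the part selected
#' by `support_field`. Supports on a 0-1 scale are normalised to 0-100.
#'
#' @param newick_source Path to a Newick file, or a Newick string.
#' @param dialect `"plain"` (label is the support) or `"slash"`
#'   (`label/value` pairs).
#' @param support_field Which slash-separated field holds the support
#'   (default 2, the usual UFboot position).
#' @return An `ape::phylo` with a numeric `support` vector aligned to
#'   internal nodes (NA where absent).
#' @export
read_tree <- function(newick_source, dialect = c("plain", "slash"),
                      support_field = 2L) {
  dialect <- match.arg(dialect)
  tr <- tryCatch(
    if (length(newick_source) == 1L && grepl("[(;]", newick_source) &&
        !file.exists(newick_source)) {
      ape::read.tree(text = newick_source)
    } else {
      ape::read.tree(newick_source)
    },
    error = function(e) stop("unparseable Newick: ", conditionMessage(e),
                             call. = FALSE)
  )
  if (is.null(tr)) stop("unparseable Newick input", call. = FALSE)
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicated leaf accessions in tree", call. = FALSE)
  }
  labs <- tr$node.label
  if (is.null(labs)) labs <- rep("", tr$Nnode)
  if (dialect == "slash") {
    labs <- vapply(strsplit(labs, "/", fixed = TRUE), function(p) {
      if (length(p) >= support_field) p[support_field] else ""
    }, character(1))
  }
  sup <- suppressWarnings(as.numeric(labs))
  if (any(!is.na(sup)) && max(sup, na.rm = TRUE) <= 1) sup <- sup * 100
  if (sum(is.na(sup) & nzchar(labs)) > 0L || all(is.na(sup))) {
    if (all(is.na(sup))) {
      warning("tree carries no numeric support values", call. = FALSE)
    }
  }
  tr$support <- sup
  tr
}

node_support <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(NA_real_)
  sup <- tree$support
  if (is.null(sup)) return(NA_real_)
  sup[node - ntip]
}

# leaf indices below each node (simple postorder accumulation)
descendant_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, descendant_tips, tree = tree))
}

#' Least-inclusive clade covering a set of accessions
#'
#' The most recent common ancestor of the query leaves, with the full
#' leaf set under it; leaves swept in beyond the query are reported.
#'
#' @param tree A support-annotated `phylo` (see [read_tree()]).
#' @param accessions Leaf labels.
#' @return List with `node`, `leafset`, `swept_in`, `support`, `breadth`
#'   (max within-clade patristic distance; NA without branch lengths).
#' @export
least_inclusive_clade <- function(tree, accessions) {
  idx <- match(accessions, tree$tip.label)
  if (anyNA(idx)) {
    stop("unknown accession(s): ",
         paste(accessions[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  ntip <- length(tree$tip.label)
  node <- if (length(idx) == 1L) idx else ape::getMRCA(tree, idx)
  leaves <- sort(descendant_tips(tree, node))
  leafset <- tree$tip.label[leaves]
  breadth <- NA_real_
  if (!is.null(tree$edge.length) && length(leaves) > 1L) {
    pd <- ape::cophenetic.phylo(tree)[leafset, leafset, drop = FALSE]
    breadth <- max(pd)
  } else if (length(leaves) == 1L) {
    breadth <- 0
  }
  list(node = node, leafset = leafset,
       swept_in = setdiff(leafset, accessions),
       support = node_support(tree, node),
       breadth = breadth)
}

#' Test a leaf set (or labelled taxon) for monophyly
#'
#' @param tree A `phylo`.
#' @param leafset Character vector of leaf labels, or a taxon name
#'   resolved through `taxa` (a data frame with `accession` and the
#'   `rank` column).
#' @param taxa,rank Optional taxon map used to resolve a taxon name.
#' @return List with `monophyletic` (logical) and `intruders` (leaves
#'   under the MRCA that are not in the query).
#' @export
is_monophyletic <- function(tree, leafset, taxa = NULL, rank = "genus") {
  if (!is.null(taxa) && length(leafset) == 1L &&
      !leafset %in% tree$tip.label) {
    leafset <- taxa$accession[!is.na(taxa[[rank]]) & taxa[[rank]] == leafset]
  }
  if (length(leafset) == 0L) stop("empty leaf set", call. = FALSE)
  lic <- least_inclusive_clade(tree, leafset)
  list(monophyletic = length(lic$swept_in) == 0L, intruders = lic$swept_in)
}

clade_breadth <- function(pd, leafset) {
  if (length(leafset) < 2L) return(0)
  max(pd[leafset, leafset])
}

#' Propose candidate higher taxa on a tree
#'
#' Partitions the unlabelled leaves into the minimal number of clades
#' each satisfying: monophyly (only unlabelled leaves below the node),
#' bootstrap support above `support_min` (default 95), and phylogenetic
#' breadth (max within-clade patristic distance) within
#' `[band[1] * min_ref, band[2] * max_ref]` of the reference taxa's
#' breadths. The partition is found greedily from the root: the deepest
#' qualifying clade is accepted and its subtree skipped. Because the
#' qualifying clades of a tree form a nested family, accepting the
#' largest first also minimises the number of proposed taxa.
#'
#' @param tree A support-annotated `phylo` with branch lengths.
#' @param taxa Data frame with `accession` plus rank columns; leaves
#'   with a non-NA label at `rank` are the references, NA leaves are to
#'   be assigned.
#' @param rank Rank being delimited (default `"genus"`).
#' @param support_min Support threshold; clades must exceed it
#'   (default 95).
#' @param band Breadth calibration band relative to the reference
#'   breadth range (default `c(0.5, 2)`).
#' @param absent_support `"fail"` (conservative default) or `"pass"` for
#'   nodes without a support value. Single leaves always pass support.
#' @param use_breadth Set `FALSE` to skip the breadth criterion (also
#'   implied when the tree has no branch lengths).
#' @return List of class `dna_clades`: `candidates` tibble (`code`
#'   blank until [assign_codes()]), `unassigned` leaves, `reference`
#'   breadth table and the resolved configuration.
#' @export
propose_taxa <- function(tree, taxa, rank = "genus", support_min = 95,
                         band = c(0.5, 2), absent_support = c("fail", "pass"),
                         use_breadth = TRUE) {
  absent_support <- match.arg(absent_support)
  ntip <- length(tree$tip.label)
  lab <- taxa[[rank]][match(tree$tip.label, taxa$accession)]
  unlab <- tree$tip.label[is.na(lab)]
  have_bl <- !is.null(tree$edge.length)
  if (use_breadth && !have_bl) {
    stop("breadth criterion requested but tree has no branch lengths; ",
         "set use_breadth = FALSE", call. = FALSE)
  }
  pd <- if (have_bl) ape::cophenetic.phylo(tree) else NULL

  ref_tbl <- tibble::tibble(taxon = character(), n = integer(),
                            breadth = double())
  band_abs <- c(0, Inf)
  if (use_breadth) {
    refs <- split(tree$tip.label[!is.na(lab)], lab[!is.na(lab)])
    if (length(refs) == 0L) {
      stop("breadth criterion needs at least one labelled reference taxon",
           call. = FALSE)
    }
    ref_tbl <- purrr::imap_dfr(refs, function(lv, nm)
      tibble::tibble(taxon = nm, n = length(lv),
                     breadth = clade_breadth(pd, lv)))
    band_abs <- c(band[1] * min(ref_tbl$breadth), band[2] * max(ref_tbl$breadth))
  }

  qualifies <- function(node) {
    leaves <- tree$tip.label[descendant_tips(tree, node)]
    if (!all(leaves %in% unlab)) return(NULL)
    if (length(leaves) > 1L) {
      sup <- node_support(tree, node)
      sup_ok <- if (is.na(sup)) absent_support == "pass" else sup > support_min
      if (!sup_ok) return(NULL)
    }
    br <- if (have_bl) clade_breadth(pd, leaves) else NA_real_
    if (use_breadth && !(br >= band_abs[1] && br <= band_abs[2])) return(NULL)
    list(leaves = leaves, breadth = br)
  }

  cands <- list()
  visit <- function(node) {
    q <- qualifies(node)
    if (!is.null(q)) {
      sup <- node_support(tree, node)
      depth <- if (have_bl) max(0, pd_node_depth(tree, node)) else NA_real_
      cands[[length(cands) + 1L]] <<- tibble::tibble(
        node = node, support = sup, n_leaves = length(q$leaves),
        breadth = q$breadth, depth = depth,
        leaves = list(sort(q$leaves))
      )
      return(invisible())
    }
    if (node > ntip) {
      for (k in tree$edge[tree$edge[, 1] == node, 2]) visit(k)
    }
    invisible()
  }
  visit(ntip + 1L)

  candidates <- if (length(cands)) dplyr::bind_rows(cands) else
    tibble::tibble(node = integer(), support = double(),
                   n_leaves = integer(), breadth = double(),
                   depth = double(), leaves = list())
  assigned <- if (nrow(candidates)) unlist(candidates$leaves) else character()
  out <- list(
    candidates = candidates,
    unassigned = setdiff(unlab, assigned),
    reference = ref_tbl,
    config = list(rank = rank, support_min = support_min, band = band,
                  band_abs = band_abs, absent_support = absent_support,
                  use_breadth = use_breadth)
  )
  class(out) <- "dna_clades"
  out
}

pd_node_depth <- function(tree, node) {
  tips <- descendant_tips(tree, node)
  d <- ape::dist.nodes(tree)
  max(d[node, tips])
}

#' @export
print.dna_clades <- function(x, ...) {
  cat(sprintf("Candidate %s-level clades: %d (%d leaves unassigned)\n",
              x$config$rank, nrow(x$candidates), length(x$unassigned)))
  print(tidy(x))
  invisible(x)
}

#' Assign provisional alphanumeric codes to clade candidates
#'
#' Candidates are ordered by their smallest leaf accession and labelled
#' `<prefix><zero-padded integer>`; the default prefix depends on rank
#' (GEN/FAM/ORD) and can be replaced, e.g. by `"GS"` for the soil-clade
#' style labels used for order-level groups.
#'
#' @param x A `dna_clades` object from [propose_taxa()].
#' @param prefix Code prefix; default chosen from the rank.
#' @param width Zero-padding width (default 2).
#' @param start First integer (default 1).
#' @return `x` with a `code` column on `candidates`.
#' @export
assign_codes <- function(x, prefix = NULL, width = 2L, start = 1L) {
  stopifnot(inherits(x, "dna_clades"))
  if (is.null(prefix)) {
    prefix <- c(genus = "GEN", family = "FAM", order = "ORD")[[x$config$rank]]
    if (is.null(prefix)) prefix <- toupper(substr(x$config$rank, 1, 3))
  }
  cand <- x$candidates
  if (nrow(cand) > 0L) {
    key <- vapply(cand$leaves, function(lv) min(lv), character(1))
    cand <- cand[order(key), ]
    cand$code <- sprintf("%s%0*d", prefix, width,
                         seq.int(start, length.out = nrow(cand)))
    cand <- cand[, c("code", setdiff(names(cand), "code"))]
  }
  x$candidates <- cand
  x
}
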