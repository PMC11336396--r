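# End-to-end commands behind the command-line wrapper
# (inst/scripts/dnadiag.R): each run_* reads the standard input formats,
# executes one stage, and writes machine-readable outputs plus a log of
# the resolved configuration and input checksums. Status codes follow a
# small contract: 0 success, 2 usage/input error (raised as an R error),
# 3 structurally valid run with an empty result.

write_run_log <- function(out_dir, command, config, inputs) {
  inputs <- inputs[!vapply(inputs, is.null, logical(1))]
  md5 <- if (length(inputs)) as.list(tools::md5sum(unlist(inputs))) else
    list()
  log <- list(
    command = command,
    package_version = as.character(utils::packageVersion("dnadiag")),
    config = config,
    input_md5 = md5
  )
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

check_inputs <- function(...) {
  paths <- c(...)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("missing input file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
}

#' Run the diagnosis stage end to end
#'
#' Reads an alignment + taxon map + region map, finds the best
#' diagnostic barcode per region for the target taxon, estimates the
#' target's within-group variability per region, and writes
#' `diagnosis.txt` (formatted sentence), `diagnosis.json`,
#' `diagnosis.tsv` and `variability.tsv`.
#'
#' @param alignment,taxa,regions Input file paths (FASTA, TSV,
#'   JSON/TSV).
#' @param target Target taxon name.
#' @param out_dir Output directory.
#' @param rank Rank of the target (default `"species"`).
#' @param ... Passed to [find_diagnoses()].
#' @return List with `status` (0 = wrote at least one diagnosis,
#'   3 = none found) and output paths.
#' @export
run_diagnose <- function(alignment, taxa, regions, target, out_dir,
                         rank = "species", ...) {
  check_inputs(alignment, taxa, regions)
  aln <- read_alignment(alignment, taxa)
  rm <- read_region_map(regions, n_columns = n_columns(aln))
  if (length(target_rows(aln, target, rank)) == 0L) {
    stop("target ", target, " absent from the taxon map", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  diags <- find_diagnoses(aln, target, rm, rank = rank, ...)
  var_tbl <- purrr::map_dfr(
    setdiff(unique(rm$region), "full"),
    function(rg) within_group_variability(aln, target, region = rg,
                                          regions = rm, rank = rank))
  var_out <- dplyr::select(var_tbl, -"excluded_indel_runs")
  paths <- list(txt = file.path(out_dir, "diagnosis.txt"),
                json = file.path(out_dir, "diagnosis.json"),
                tsv = file.path(out_dir, "diagnosis.tsv"),
                variability = file.path(out_dir, "variability.tsv"))
  readr::write_tsv(tidy(diags), paths$tsv)
  readr::write_tsv(var_out, paths$variability)
  jsonlite::write_json(
    list(diagnoses = tidy(diags), rejected = attr(diags, "rejected"),
         variability = var_out),
    paths$json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (nrow(diags) > 0L) {
    genus <- aln$genus[target_rows(aln, target, rank)][1]
    scope <- if (!is.na(genus)) paste("other species of", genus) else
      "related taxa"
    writeLines(format_diagnosis(diags, scope = scope), paths$txt)
  } else {
    writeLines(character(), paths$txt)
  }
  write_run_log(out_dir, "diagnose",
                c(list(target = target, rank = rank), list(...)),
                list(alignment = alignment, taxa = taxa, regions = regions))
  list(status = if (nrow(diags) > 0L) 0L else 3L, paths = paths,
       diagnoses = diags)
}

#' Run the clade-delimitation stage end to end
#'
#' @param tree Newick path.
#' @param taxa Taxon map TSV path.
#' @param out_dir Output directory.
#' @param rank Rank to delimit (default `"genus"`).
#' @param prefix Code prefix for [assign_codes()].
#' @param ... Passed to [propose_taxa()].
#' @return List with `status` (0, or 3 when no candidate qualifies) and
#'   output paths.
#' @export
run_delimit <- function(tree, taxa, out_dir, rank = "genus", prefix = NULL,
                        ...) {
  check_inputs(tree, taxa)
  tr <- suppressWarnings(read_tree(tree))
  tm <- read_taxon_map(taxa)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- propose_taxa(tr, tm, rank = rank, ...)
  res <- assign_codes(res, prefix = prefix)
  paths <- list(tsv = file.path(out_dir, "candidates.tsv"),
                json = file.path(out_dir, "candidates.json"))
  readr::write_tsv(tidy(res), paths$tsv)
  jsonlite::write_json(
    list(candidates = tidy(res), unassigned = res$unassigned,
         reference = res$reference, config = res$config),
    paths$json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_run_log(out_dir, "delimit",
                c(list(rank = rank, prefix = prefix), res$config),
                list(tree = tree, taxa = taxa))
  list(status = if (nrow(res$candidates) > 0L) 0L else 3L, paths = paths,
       clades = res)
}

#' Run the primer screen end to end
#'
#' @param alignment FASTA path.
#' @param taxa Taxon map TSV path.
#' @param out_dir Output directory.
#' @param primers Primer table path (default: the packaged table).
#' @param rank Grouping rank for [group_summary()].
#' @param ... Passed to [screen_primers()].
#' @return List with `status` and output paths.
#' @export
run_primers <- function(alignment, taxa, out_dir, primers = NULL,
                        rank = "order", ...) {
  check_inputs(alignment, taxa)
  if (!is.null(primers)) check_inputs(primers)
  aln <- read_alignment(alignment, taxa)
  ptab <- read_primers(primers)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hits <- suppressWarnings(screen_primers(aln, ptab, ...))
  summ <- suppressWarnings(
    group_summary(hits, aln[, c("accession", "species", "genus", "family",
                                "order")], rank = rank))
  paths <- list(summary = file.path(out_dir, "primer_summary.tsv"),
                hits = file.path(out_dir, "primer_hits.json"))
  readr::write_tsv(summ, paths$summary)
  hits_out <- hits
  hits_out$mismatch_positions_from_3prime <-
    vapply(hits_out$mismatch_positions_from_3prime, paste,
           character(1), collapse = ",")
  jsonlite::write_json(hits_out, paths$hits, auto_unbox = TRUE, digits = NA)
  write_run_log(out_dir, "primers", list(rank = rank),
                list(alignment = alignment, taxa = taxa, primers = primers))
  list(status = 0L, paths = paths, summary = summ)
}

#' Simulate a dataset and write it to disk
#'
#' @param out_dir Output directory.
#' @param seed RNG seed (mandatory for reproducibility).
#' @param config_json Optional JSON file overriding
#'   [simulation_config()] fields.
#' @param plant Optional planted-barcode request (see
#'   [simulate_dataset()]).
#' @return List with `status` and the written file paths.
#' @export
run_simulate <- function(out_dir, seed, config_json = NULL, plant = NULL) {
  overrides <- list()
  if (!is.null(config_json)) {
    check_inputs(config_json)
    overrides <- jsonlite::read_json(config_json, simplifyVector = TRUE)
    if (!is.null(overrides$region_lengths)) {
      overrides$region_lengths <- unlist(overrides$region_lengths)
    }
  }
  cfg <- do.call(simulation_config, c(overrides, list(seed = seed)))
  sim <- simulate_dataset(cfg, plant = plant)
  paths <- write_simulation(sim, out_dir)
  write_run_log(out_dir, "simulate", unclass(cfg),
                list(config_json = config_json))
  list(status = 0L, paths = paths, sim = sim)
}

#' Check printed diagnoses against an alignment
#'
#' For every row of the packaged printed-diagnoses table (or a
#' user-supplied one in the same shape) that can be located in the
#' alignment, runs [validate_diagnosis()]; rows whose canonical
#' accession or taxon is absent are marked `unevaluable` rather than
#' failing the run. Positional inconsistencies of the printed material
#' (span not matching the barcode length) are flagged for every row,
#' data or no data.
#'
#' @param alignment FASTA path.
#' @param taxa Taxon map TSV path.
#' @param regions Region map path.
#' @param out_dir Output directory.
#' @param printed Printed-diagnoses tibble (default
#'   [load_printed_diagnoses()]).
#' @return List with `status` and the report tibble (`report.tsv` on
#'   disk).
#' @export
run_validate <- function(alignment, taxa, regions, out_dir,
                         printed = load_printed_diagnoses()) {
  check_inputs(alignment, taxa, regions)
  aln <- read_alignment(alignment, taxa)
  rm <- read_region_map(regions, n_columns = n_columns(aln))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- purrr::map_dfr(seq_len(nrow(printed)), function(i) {
    row <- printed[i, ]
    span_ok <- row$end - row$start + 1L == nchar(row$barcode)
    region <- if (nzchar(row$prefix)) row$prefix else
      if (row$marker == "LSU") "LSU" else "ITS"
    t_rows <- which(!is.na(aln$species) & aln$species == row$species)
    evaluable <- length(t_rows) > 0L && region %in% rm$region &&
      length(t_rows) < nrow(aln)
    base <- tibble::tibble(
      species = row$species, marker = row$marker, region = region,
      positions_match_length = span_ok
    )
    if (!evaluable) {
      return(dplyr::mutate(base, status = "unevaluable",
                           targets_within_allowance = NA,
                           nontargets_exceed_allowance = NA))
    }
    diag <- tibble::tibble(
      target = row$species, rank = "species", region = region,
      start = row$start, end = row$end, barcode = row$barcode,
      canonical = aln$accession[t_rows[1]], allowance = row$allowance
    )
    chk <- tryCatch(validate_diagnosis(aln, diag, rm),
                    error = function(e) NULL)
    if (is.null(chk) || !"targets_within_allowance" %in% chk$check) {
      return(dplyr::mutate(base, status = "unevaluable",
                           targets_within_allowance = NA,
                           nontargets_exceed_allowance = NA))
    }
    dplyr::mutate(
      base, status = "evaluated",
      targets_within_allowance =
        chk$pass[chk$check == "targets_within_allowance"],
      nontargets_exceed_allowance =
        chk$pass[chk$check == "nontargets_exceed_allowance"]
    )
  })
  path <- file.path(out_dir, "report.tsv")
  readr::write_tsv(report, path)
  write_run_log(out_dir, "validate", list(),
                list(alignment = alignment, taxa = taxa, regions = regions))
  list(status = 0L, report = report, paths = list(report = path))
}
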