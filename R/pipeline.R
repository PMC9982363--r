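# Orchestration of the full per-family analysis protocol and of
# comparative thermodynamic scenarios, with reproducible run manifests.

#' Build a run manifest
#'
#' @param subcommand Name of the protocol step.
#' @param config Named list of resolved parameters.
#' @param seed Seed in force.
#' @param inputs Character vector of input file paths (digested with MD5
#'   when they exist).
#' @return A `run_manifest` list.
#' @export
run_manifest <- function(subcommand, config = list(), seed = NA_integer_,
                         inputs = character(0)) {
  digests <- if (length(inputs)) tools::md5sum(inputs[file.exists(inputs)]) else NULL
  structure(list(
    subcommand = subcommand,
    config = config,
    seed = seed,
    inputs = as.list(digests),
    package_version = as.character(utils::packageVersion("methanotrace")),
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    finished = NA_character_
  ), class = "run_manifest")
}

finish_manifest <- function(manifest) {
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  manifest
}

#' Run the full rooting-and-reconciliation protocol for one gene family
#'
#' Executes, in order: candidate rootings (outgroup when given, midpoint,
#' MAD, reconciliation-based), the consensus rule, the transfer-cost sweep
#' that finds the smallest `T` whose optimal rootings recover the
#' consensus branch, and finally event-support aggregation at that `T`
#' with duplication costs `{T/4, T/2, 3T/4}`.
#'
#' @param gene Gene tree (rooted input is unrooted first).
#' @param species Rooted species tree.
#' @param map Named character vector, gene leaf -> species leaf.
#' @param outgroup Optional outgroup leaf labels.
#' @param t_grid Ascending transfer costs swept during calibration.
#' @param loss Loss cost.
#' @param n_runs Aggregation runs.
#' @param seed Integer seed; all stage seeds derive from it by fixed
#'   offsets.
#' @param subunit Subunit identifier for the candidate records.
#' @return List with `candidates`, `consensus`, `transfer_cost`,
#'   `rooted_gene`, `reconciliation` (a representative run at `D = T/2`),
#'   `supports` (the aggregated [aggregate_reconciliations()] table), and
#'   `manifest`.
#' @export
run_family_protocol <- function(gene, species, map, outgroup = NULL,
                                t_grid = c(2, 4, 6, 8, 10, 12, 16),
                                loss = 1, n_runs = 100L, seed = 1L,
                                subunit = "family") {
  manifest <- run_manifest(
    "family-protocol",
    config = list(t_grid = t_grid, loss = loss, n_runs = n_runs,
                  outgroup = outgroup),
    seed = seed
  )
  utree <- unrooted_form(gene)
  mid_t <- t_grid[ceiling(length(t_grid) / 2)]
  cands <- list(
    midpoint = midpoint_root(utree, subunit = subunit),
    mad = mad_root(utree, subunit = subunit)[[1L]],
    reconciliation = reconciliation_root(
      utree, species, map,
      dtl_costs(dup = mid_t / 2, transfer = mid_t, loss = loss),
      subunit = subunit)[[1L]]
  )
  if (!is.null(outgroup)) {
    cands <- c(list(outgroup = outgroup_root(utree, outgroup, subunit = subunit)),
               cands)
  }
  consensus <- consensus_root(cands)
  chosen_side <- consensus$outgroup_side %||% consensus$side

  sweep <- optimize_transfer_cost(utree, species, map, chosen_side,
                                  t_grid = t_grid, loss = loss)
  t_final <- sweep$transfer_cost
  if (is.na(t_final)) t_final <- mid_t

  root_cand <- Find(function(cc)
    same_bipartition(cc$side, cc$leaves, chosen_side, utree$tip.label), cands)
  rooted <- if (is.null(root_cand)) {
    reroot_on_split(utree, chosen_side)
  } else {
    apply_rooting(utree, root_cand)
  }
  supports <- aggregate_reconciliations(rooted, species, map,
                                        transfer_cost = t_final,
                                        loss_cost = loss, n_runs = n_runs,
                                        seed = child_seed(seed, 10L))
  recon <- reconcile(rooted, species, map,
                     dtl_costs(dup = t_final / 2, transfer = t_final,
                               loss = loss),
                     seed = child_seed(seed, 11L))
  list(candidates = cands, consensus = consensus,
       transfer_cost = sweep$transfer_cost, rooted_gene = rooted,
       reconciliation = recon, supports = supports,
       manifest = finish_manifest(manifest))
}

# Root an unrooted tree on the edge realizing a given leaf bipartition.
reroot_on_split <- function(utree, side) {
  leaves <- utree$tip.label
  for (k in seq_len(nrow(utree$edge))) {
    child <- utree$edge[k, 2]
    below <- edge_bipartition(utree, child)
    if (same_bipartition(below, leaves, side, leaves)) {
      return(reroot_at(utree, child, 0.5))
    }
  }
  stop("no edge realizes the requested bipartition", call. = FALSE)
}

#' Solve and compare thermodynamic scenarios side by side
#'
#' @param models A list of [thermo_model()] objects and/or paths to YAML
#'   scenario files.
#' @param tol,max_iter Passed to [solve_equilibrium()].
#' @param highlight Species placed first in the comparison table
#'   (default the methyl-S-CoM intermediate, the comparison axis between
#'   CO2- and methyl-reducing methanogenesis).
#' @return List with `comparison` (data frame: species x scenario values,
#'   highlighted species first), `states` (per-scenario
#'   `equilibrium_state`s), `converged` (named logical), and `manifest`.
#'   Unconverged scenarios are flagged but still reported.
#' @export
run_thermo_scenarios <- function(models, tol = 1e-6, max_iter = 10000,
                                 highlight = "CH3-S-CoM") {
  stopifnot(length(models) >= 1L)
  paths <- vapply(models, function(m) if (is.character(m)) m else NA_character_,
                  character(1))
  manifest <- run_manifest("thermo-scenarios",
                           config = list(tol = tol, max_iter = max_iter),
                           inputs = paths[!is.na(paths)])
  states <- lapply(models, function(m) {
    model <- if (is.character(m)) read_thermo_model(m) else m
    suppressWarnings(solve_equilibrium(model, tol = tol, max_iter = max_iter))
  })
  names(states) <- make.unique(vapply(states, function(s) s$model$name,
                                      character(1)))
  all_species <- unique(unlist(lapply(states, function(s) names(s$values))))
  ord <- c(intersect(highlight, all_species),
           setdiff(all_species, highlight))
  comparison <- data.frame(species = ord)
  for (nm in names(states)) {
    comparison[[nm]] <- as.numeric(states[[nm]]$values[ord])
  }
  list(comparison = comparison, states = states,
       converged = vapply(states, `[[`, logical(1), "converged"),
       manifest = finish_manifest(manifest))
}

#' Write a scenario report or comparison as TSV and JSON
#'
#' @param x A [scenario_report()] list or the `comparison` data frame of
#'   [run_thermo_scenarios()].
#' @param path_prefix Output path without extension; `<prefix>.tsv` and
#'   `<prefix>.json` are written.
#' @return The paths, invisibly.
#' @export
write_report <- function(x, path_prefix) {
  tsv <- paste0(path_prefix, ".tsv")
  json <- paste0(path_prefix, ".json")
  tab <- if (is.data.frame(x)) x else x$species
  utils::write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(x, json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(tsv = tsv, json = json))
}

#' Read back a JSON report written by [write_report()]
#'
#' @param path Path to the JSON file.
#' @return The deserialized report.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
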