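#' Read a run configuration file
#'
#' The run configuration is a single JSON file:
#' \preformatted{
#' {
#'   "options": {"inner_pct": 0.5, "outer_pct": 99.5, "probe": 1.4,
#'               "cutoff": 4.0, "voxel": 2.0, "polya_nt": 200},
#'   "entries": [
#'     {"label": "my virus", "structure": "path/to/au.pdb",
#'      "genome_nt": 12333, "pdb_id": "xxxx",
#'      "t_number": "T=1 (pseudo T=3)",
#'      "chain_map": {"A": "VP4A", "B": "VP4B", "C": "VP4C"}}
#'   ]
#' }
#' }
#' Structures are never fetched from the network; `structure` must be a
#' local file. Labels must be unique and genome lengths positive.
#'
#' @param path JSON config path.
#' @return list with `entries` and `options` (defaults filled in).
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  defaults <- list(inner_pct = 0.5, outer_pct = 99.5, probe = 1.4,
                   cutoff = 4.0, voxel = 2.0, polya_nt = 200)
  opts <- utils::modifyList(defaults, if (is.null(cfg$options)) list() else cfg$options)
  entries <- cfg$entries
  if (is.null(entries)) entries <- list()
  labels <- vapply(entries, function(e) as.character(e$label), character(1))
  if (anyDuplicated(labels)) stop("entry labels must be unique")
  for (e in entries)
    if (is.null(e$genome_nt) || e$genome_nt <= 0)
      stop("entry '", e$label, "' needs a positive genome_nt")
  list(entries = entries, options = opts)
}

#' Run the comparative capsid report over a configuration
#'
#' Builds one [build_geometry_report] row per config entry and writes the
#' table as CSV (comparison-table column order and rounding) and JSON.
#' Per-entry failures are logged and reported in the `error` column without
#' aborting the remaining entries. Deterministic: identical config and
#' inputs give byte-identical CSV.
#'
#' @param config path to a JSON config, or the list from [read_run_config].
#' @param out_csv,out_json optional output paths.
#' @param quiet suppress log lines.
#' @return data.frame of report rows, invisibly when writing files.
#' @export
run_report <- function(config, out_csv = NULL, out_json = NULL, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  opts <- config$options
  log <- function(...) if (!quiet) message(sprintf(...))
  log("capsid report: %d entries | inner_pct %.2f outer_pct %.2f polyA +%d nt",
      length(config$entries), opts$inner_pct, opts$outer_pct, opts$polya_nt)
  rows <- lapply(config$entries, function(e) {
    t0 <- Sys.time()
    res <- tryCatch({
      model <- read_structure(e$structure)
      ops <- if (!is.null(model$biomt) && length(model$biomt) == 60)
        operators_from_biomt(model) else icosahedral_operators()
      rep <- build_geometry_report(
        model, ops, genome_nt = e$genome_nt, label = e$label,
        pdb_id = if (is.null(e$pdb_id)) "" else e$pdb_id,
        t_number = if (is.null(e$t_number)) "" else e$t_number,
        inner_pct = opts$inner_pct, outer_pct = opts$outer_pct,
        polya_nt = opts$polya_nt)
      df <- geometry_report_table(rep)
      df$error <- ""
      df
    }, error = function(err) {
      log("entry '%s' FAILED: %s", e$label, conditionMessage(err))
      data.frame(label = e$label, pdb_id = "", inner_diameter = NA_real_,
                 shell_thickness = NA_real_, inner_volume = NA_real_,
                 genome_size = NA_real_, volume_per_nt = NA_real_,
                 buried_area = NA_real_, t_number = "",
                 error = conditionMessage(err), stringsAsFactors = FALSE)
    })
    log("entry '%s' done in %.2f s", e$label,
        as.numeric(difftime(Sys.time(), t0, units = "secs")))
    res
  })
  tab <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(label = character(), pdb_id = character(),
               inner_diameter = numeric(), shell_thickness = numeric(),
               inner_volume = numeric(), genome_size = numeric(),
               volume_per_nt = numeric(), buried_area = numeric(),
               t_number = character(), error = character(),
               stringsAsFactors = FALSE)
  if (length(rows) == 0) log("no entries: writing header-only report")
  if (!is.null(out_csv)) utils::write.csv(tab, out_csv, row.names = FALSE)
  if (!is.null(out_json))
    jsonlite::write_json(tab, out_json, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null")
  if (is.null(out_csv) && is.null(out_json)) tab else invisible(tab)
}

#' Run a single structural measurement
#'
#' One-shot measurements with provenance (operator convention, tolerance and
#' parameters echoed in the result):
#' * `"axis_distance"`: [symmetry_mate_distance]; args `chain`, `res_seq`,
#'   `atom_name`, `axis_order`.
#' * `"contacts"`: [contact_network] between two selections; args `sel_a`,
#'   `sel_b` (lists passed to [select_atoms]), `cutoff`.
#' * `"bsa"`: [buried_surface_area] between two chains; args `chain_a`,
#'   `chain_b`, `probe`, `n_points`.
#' * `"accounting"`: [modeled_residue_accounting]; args `chain_map`,
#'   `expected_lengths`.
#' * `"charges"`: [basic_residue_map] on the expanded capsid; args
#'   `inner_shell`.
#'
#' @param command one of the measurement names above.
#' @param model a [structure_model] (asymmetric unit).
#' @param ops `symmetry_operators` (defaults to the generated icosahedral
#'   set, or the file's own operators when present and complete).
#' @param ... command arguments, see above.
#' @return list with `command`, `provenance` and `result`.
#' @export
run_measurement <- function(command = c("axis_distance", "contacts", "bsa",
                                        "accounting", "charges"),
                            model, ops = NULL, ...) {
  command <- match.arg(command)
  args <- list(...)
  if (is.null(ops))
    ops <- if (!is.null(model$biomt) && length(model$biomt) == 60)
      operators_from_biomt(model) else icosahedral_operators()
  result <- switch(command,
    axis_distance = {
      d <- symmetry_mate_distance(model, ops, chain = args$chain,
                                  res_seq = args$res_seq,
                                  atom_name = args$atom_name,
                                  axis_order = if (is.null(args$axis_order))
                                    "nearest" else args$axis_order)
      list(distance = unname(d), operator = names(d))
    },
    contacts = {
      cutoff <- if (is.null(args$cutoff)) 4.0 else args$cutoff
      a <- do.call(select_atoms, c(list(model), args$sel_a))
      b <- do.call(select_atoms, c(list(model), args$sel_b))
      contact_network(a, b, cutoff)
    },
    bsa = {
      a <- select_atoms(model, chain = args$chain_a)
      b <- select_atoms(model, chain = args$chain_b)
      probe <- if (is.null(args$probe)) 1.4 else args$probe
      np <- if (is.null(args$n_points)) 960 else args$n_points
      list(bsa_A2 = buried_surface_area(a, b, probe = probe, n_points = np))
    },
    accounting = modeled_residue_accounting(model, args$chain_map,
                                            args$expected_lengths),
    charges = {
      expanded <- expand_capsid(model, ops)
      basic_residue_map(expanded, find_axes(ops), args$inner_shell)
    })
  list(command = command,
       provenance = list(convention = ops$convention,
                         n_operators = length(ops$rotations),
                         tolerances = .ico_tol, args = args),
       result = result)
}
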