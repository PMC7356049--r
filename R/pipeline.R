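#' Assemble a validated pipeline configuration
#'
#' Accepts a YAML file path or a plain list and fills defaults. Either a
#' `simulate` block (parameters of [toy_system_spec()]) or an `input` block
#' (`structure`, `trajectory`, `dt`, plus optional reader arguments) must
#' be present.
#'
#' @param config list or path to a YAML file.
#' @return object of class `run_config`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- list(
    simulate = NULL, input = NULL,
    equilibration_cut = 0,
    geminate_cutoff = 3.5, protein_cutoff = 6.0,
    contact_cutoff = 4.0,
    pocket = list(),
    rmsf_threshold_nm = 0.15,
    volume_dm3 = NULL, n_protein = 1,
    wrap = TRUE, seed = 1,
    output_dir = NULL)
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$simulate) && is.null(cfg$input)) {
    stop("config must provide either 'simulate' or 'input'", call. = FALSE)
  }
  # validate cutoffs up front, before any computation
  classifier_config(cfg$geminate_cutoff, cfg$protein_cutoff)
  do.call(pocket_config, c(cfg$pocket,
                           list(contact_cutoff = cfg$contact_cutoff)))
  class(cfg) <- "run_config"
  cfg
}

# split a selection into one selection per ligand species (by residue name
# of the ligand's first site)
.split_species <- function(structure) {
  sel <- structure$selection
  resid <- structure$atoms$resid
  species <- vapply(sel$ligands, function(s) resid[s[1]], "")
  lapply(split(seq_along(sel$ligands), species), function(idx) {
    site_selection(sel$protein_heavy, sel$fe, sel$ligands[idx],
                   reference = sel$reference)
  })
}

#' Run the full gas-migration analysis pipeline
#'
#' Orchestrates simulate/read -> equilibration cut -> three-state
#' classification -> global event counting -> rate constants -> contact
#' descriptors -> RMSF -> pocket identification, per ligand species, and
#' returns a report bundle whose tables mirror the rate-constant,
#' global-descriptor and pocket layouts of the reference analysis. With
#' `output_dir` set, all tables, the state matrices and a JSON report are
#' persisted.
#'
#' @param config a [run_config()] (or list/path coercible to one).
#' @return list of class `report_bundle`: `kinetics_table` (numeric),
#'   `table1` (formatted), `descriptors`, `pocket_table`, `rmsf`,
#'   `summaries`, `state_matrices`, `warnings`, `config`, `config_hash`,
#'   `versions`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  warn <- character()
  note <- function(...) warn <<- c(warn, sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  sys <- stage("input", {
    if (!is.null(config$simulate)) {
      spec <- do.call(toy_system_spec,
                      utils::modifyList(config$simulate,
                                        list(seed = config$seed)))
      generate_toy_system(spec)
    } else {
      topo <- do.call(read_structure,
                      c(list(path = config$input$structure),
                        config$input$structure_args))
      traj <- read_trajectory(config$input$trajectory, topo,
                              dt = config$input$dt %||% 4,
                              equilibration_cut = 0)
      list(structure = topo, trajectory = traj)
    }
  })
  structure_obj <- sys$structure
  traj <- stage("equilibration", {
    if (config$equilibration_cut > 0) {
      trim_equilibration(sys$trajectory, config$equilibration_cut)
    } else sys$trajectory
  })

  if (is.null(config$volume_dm3)) {
    config$volume_dm3 <- box_volume_dm3(traj$box)
  }
  cc <- classifier_config(config$geminate_cutoff, config$protein_cutoff)
  pc <- do.call(pocket_config, c(config$pocket,
                                 list(contact_cutoff = config$contact_cutoff)))
  by_species <- .split_species(structure_obj)

  kin_rows <- list(); fmt_rows <- list(); desc_list <- list()
  sm_list <- list(); summ_list <- list(); pocket_rows <- list()

  for (sp in names(by_species)) {
    sel <- by_species[[sp]]
    sm <- stage("classify", classify_trajectory(traj, sel, cc,
                                                wrap = config$wrap))
    summary <- stage("events", count_global_events(sm))
    kin <- stage("kinetics", withCallingHandlers(
      compute_kinetics(summary, config$volume_dm3,
                       n_protein = config$n_protein),
      warning = function(w) {
        note("[%s] %s", sp, conditionMessage(w))
        invokeRestart("muffleWarning")
      }))
    if (kin$low_sampling) {
      note("[%s] fewer than 5 completed cycles: rate constants unreliable", sp)
    }
    desc <- stage("descriptors", withCallingHandlers(
      global_descriptors(traj, sel, sm, contact_cutoff = config$contact_cutoff,
                         wrap = config$wrap),
      warning = function(w) {
        note("[%s] %s", sp, conditionMessage(w))
        invokeRestart("muffleWarning")
      }))
    pk <- stage("pockets", {
      res <- withCallingHandlers(
        find_pockets(traj, sel, pc, wrap = config$wrap,
                     residue_ids = structure_obj$atoms$resno),
        warning = function(w) {
          note("[%s] %s", sp, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      distal <- named_site_statistics("distal", traj, sel,
                                      occupancy_cutoff = pc$occupancy_cutoff,
                                      wrap = config$wrap)
      rows <- list(.pocket_row(sp, "distal", NULL, distal))
      for (i in seq_along(res$pockets)) {
        rows[[length(rows) + 1L]] <-
          .pocket_row(sp, sprintf("pocket%d", i), res$pockets[[i]],
                      res$stats[[i]])
      }
      do.call(rbind, rows)
    })
    kin_rows[[sp]] <- data.frame(
      species = sp, n_in_out = kin$n_events, t_sim_ns = kin$t_sim_ns,
      t_geminate_ns = kin$t_geminate_ns, k1 = kin$k1,
      k_minus1 = kin$k_minus1, K = kin$K, stringsAsFactors = FALSE)
    fmt_rows[[sp]] <- format_table1_row(summary, kin, species = sp)
    desc_list[[sp]] <- desc
    sm_list[[sp]] <- sm
    summ_list[[sp]] <- summary
    pocket_rows[[sp]] <- pk
  }

  rmsf <- stage("rmsf", {
    prot <- structure_obj$selection$protein_heavy
    fitted <- if (.is_static(traj$coords, prot)) traj else
      superpose_frames(traj, prot)
    compute_rmsf(fitted, prot, structure_obj$atoms$resno[prot],
                 threshold_nm = config$rmsf_threshold_nm)
  })

  analysis_params <- config[c("equilibration_cut", "geminate_cutoff",
                              "protein_cutoff", "contact_cutoff", "pocket",
                              "rmsf_threshold_nm", "volume_dm3", "n_protein",
                              "wrap", "seed", "simulate", "input")]
  bundle <- structure(
    list(kinetics_table = do.call(rbind, kin_rows),
         table1 = do.call(rbind, fmt_rows),
         descriptors = desc_list,
         pocket_table = do.call(rbind, pocket_rows),
         rmsf = rmsf,
         summaries = summ_list,
         state_matrices = sm_list,
         warnings = warn,
         config = config,
         config_hash = .config_hash(paste(deparse(analysis_params),
                                          collapse = "")),
         versions = list(
           gasflux = as.character(utils::packageVersion("gasflux")),
           R = paste(R.version$major, R.version$minor, sep = "."))),
    class = "report_bundle")
  if (!is.null(config$output_dir)) write_report(bundle, config$output_dir)
  bundle
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.pocket_row <- function(species, label, pocket, stats) {
  data.frame(
    species = species, pocket = label,
    n_atoms = if (is.null(pocket)) NA_integer_ else length(pocket$member_atoms),
    residues = if (is.null(pocket) || is.null(pocket$member_residues))
      NA_character_ else paste(pocket$member_residues, collapse = "+"),
    occupancy_pct = stats$occupancy_pct,
    avg_simultaneous = stats$avg_simultaneous,
    max_simultaneous = stats$max_simultaneous,
    mean_residence_ps = stats$mean_residence_ps,
    n_in_out_events = stats$n_in_out_events,
    mean_fe_distance_A = stats$mean_anchor_distance %||% NA_real_,
    stringsAsFactors = FALSE)
}

#' Format one kinetics table row
#'
#' Fields ordered as in the reference rate-constant table: completed
#' events, simulation time (ns), geminate residence (ns), then k1, k-1 and
#' K in 2-significant-figure scientific notation. A run with zero
#' completed cycles prints `-` placeholders for the rate constants.
#'
#' @param summary an `event_summary`.
#' @param kin the matching `kinetics_result`.
#' @param species row label.
#' @return one-row data frame of character/numeric report fields.
#' @export
format_table1_row <- function(summary, kin, species = "XO") {
  none <- kin$n_events == 0
  data.frame(
    species = species,
    n_in_out = if (none) "-" else as.character(kin$n_events),
    t_sim_ns = formatC(summary$t_sim_ns, format = "g", digits = 3),
    t_geminate_ns = if (none) "-" else
      formatC(summary$t_geminate_ns, format = "g", digits = 3),
    k1 = if (none) "-" else .sci2(kin$k1),
    k_minus1 = if (none) "-" else .sci2(kin$k_minus1),
    K = if (none) "-" else .sci2(kin$K),
    stringsAsFactors = FALSE)
}

#' Persist a report bundle
#'
#' Writes `table1.csv` (kinetics, formatted), `kinetics.csv` (full
#' precision), `table2.json` (global descriptors), `table3.csv` (pockets),
#' `rmsf.csv`, one state matrix per species, and `report.json` with config,
#' hash, versions and warnings.
#'
#' @param bundle a `report_bundle`.
#' @param dir output directory (created if missing).
#' @export
write_report <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(bundle$table1, file.path(dir, "table1.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$kinetics_table, file.path(dir, "kinetics.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    lapply(bundle$descriptors, function(d) d[c("avg_gas_in_protein",
                                               "avg_contacts_total",
                                               "contacts_per_molecule")]),
    file.path(dir, "table2.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(bundle$pocket_table, file.path(dir, "table3.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(bundle$rmsf), file.path(dir, "rmsf.csv"),
                   row.names = FALSE)
  for (sp in names(bundle$state_matrices)) {
    write_state_matrix(bundle$state_matrices[[sp]],
                       file.path(dir, sprintf("states_%s.txt", sp)))
  }
  jsonlite::write_json(
    list(config = bundle$config[setdiff(names(bundle$config), "output_dir")],
         config_hash = bundle$config_hash,
         versions = bundle$versions,
         warnings = bundle$warnings,
         kinetics = bundle$kinetics_table),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE)
  invisible(dir)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("report_bundle (config", x$config_hash, ")\n\nKinetics:\n")
  print(x$table1)
  cat("\nPockets:\n")
  print(x$pocket_table)
  if (length(x$warnings)) {
    cat("\nWarnings:\n")
    cat(paste0("  - ", x$warnings, collapse = "\n"), "\n")
  }
  invisible(x)
}
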