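#' Previously published estimates for the HS2 evaluation
#'
#' The headline results reported in the original published economic
#' evaluation of the HS2 intervention, for side-by-side comparison with this
#' implementation's outputs. The published provider attribution of composite
#' states is under-specified and its baseline arithmetic is not internally
#' consistent at the penny level, so these are comparison values, not
#' targets: [compare_reference()] tabulates the deviations rather than
#' forcing agreement.
#'
#' @return A tibble with columns `quantity`, `unit` and `reported`.
#' @export
reference_values <- function() {
  tibble::tribble(
    ~quantity,                         ~unit,        ~reported,
    "cost_hs2_ems",                    "GBP",        24.60,
    "cost_hs2_iuc",                    "GBP",        0.41,
    "cost_hs2_primary",                "GBP",        13.27,
    "cost_hs2_secondary",              "GBP",        11.51,
    "cost_hs2_total",                  "GBP",        49.79,
    "cost_sc_ems",                     "GBP",        16.56,
    "cost_sc_iuc",                     "GBP",        0.54,
    "cost_sc_primary",                 "GBP",        10.19,
    "cost_sc_secondary",               "GBP",        13.20,
    "cost_sc_total",                   "GBP",        40.50,
    "delta_cost",                      "GBP",        9.29,
    "icer_baseline",                   "GBP/case",   309.36,
    "type_cost_hs2_read_action",       "GBP",        75.71,
    "type_cost_hs2_read_only",         "GBP",        46.66,
    "type_cost_hs2_no_action",         "GBP",        49.05,
    "type_cost_sc_action",             "GBP",        72.14,
    "type_cost_sc_no_action",          "GBP",        39.70,
    "icer_intervention_cost_low",      "GBP/case",   201.14,
    "icer_intervention_cost_high",     "GBP/case",   591.66,
    "icer_r_hs2_low",                  "GBP/case",   128.77,
    "icer_severe_rate_high",           "GBP/case",   363.76,
    "icer_severe_rate_low",            "GBP/case",   254.82,
    "icer_cost_utility",               "GBP/QALY",   270000,
    "psa_dominated_pct",               "%",          41.81,
    "psa_dominant_pct",                "%",          1.28,
    "costmin_cycle2_pct",              "%",          37,
    "costmin_cycle3_pct",              "%",          57,
    "costmin_cycle4_pct",              "%",          65,
    "costmin_cycle5_pct",              "%",          68
  )
}

#' Recompute every published quantity and tabulate deviations
#'
#' Runs the baseline, one-way sensitivity, cost-utility, probabilistic and
#' cost-minimisation analyses and joins the modelled values against
#' [reference_values()].
#'
#' @param config Model configuration.
#' @param n_sims Simulations for the probabilistic analyses.
#' @param seed Integer seed for the probabilistic analyses.
#' @return A tibble with `quantity`, `unit`, `reported`, `modelled`,
#'   `deviation` (modelled minus reported).
#' @export
compare_reference <- function(config = default_config(), n_sims = 10000,
                              seed = 1) {
  base <- run_baseline(config)
  sens <- one_way_sensitivity(config)
  cua <- run_cost_utility(config)
  psa <- run_psa(config, n_sims = n_sims, seed = seed)
  cm <- estimate_least_cost_probability(config, n_sims = n_sims, seed = seed)

  tc_h <- patient_type_costs(build_arm("hs2", config))
  tc_s <- patient_type_costs(build_arm("sc", config))
  type_cost <- function(tab, type) tab$cost[tab$patient_type == type]
  sens_row <- function(param, side) {
    sens[[paste0("icer_", side)]][sens$parameter == param]
  }
  quad <- function(q) {
    100 * psa$quadrants$proportion[psa$quadrants$quadrant == q]
  }
  cm_cycle <- function(cy) 100 * cm$average$proportion[cm$average$cycle == cy]

  modelled <- c(
    cost_hs2_ems = base$costs$hs2[1], cost_hs2_iuc = base$costs$hs2[2],
    cost_hs2_primary = base$costs$hs2[3],
    cost_hs2_secondary = base$costs$hs2[4],
    cost_hs2_total = base$costs$hs2[5],
    cost_sc_ems = base$costs$sc[1], cost_sc_iuc = base$costs$sc[2],
    cost_sc_primary = base$costs$sc[3], cost_sc_secondary = base$costs$sc[4],
    cost_sc_total = base$costs$sc[5],
    delta_cost = base$delta_cost,
    icer_baseline = base$icer$value,
    type_cost_hs2_read_action = type_cost(tc_h, "read_action"),
    type_cost_hs2_read_only = type_cost(tc_h, "read_only"),
    type_cost_hs2_no_action = type_cost(tc_h, "no_action"),
    type_cost_sc_action = type_cost(tc_s, "action"),
    type_cost_sc_no_action = type_cost(tc_s, "no_action"),
    icer_intervention_cost_low = sens_row("intervention_cost", "low"),
    icer_intervention_cost_high = sens_row("intervention_cost", "high"),
    icer_r_hs2_low = sens_row("r_hs2", "low"),
    icer_severe_rate_high = sens_row("hs2_severe_rate", "high"),
    icer_severe_rate_low = sens_row("hs2_severe_rate", "low"),
    icer_cost_utility = cua$icer$value,
    psa_dominated_pct = quad("NW"),
    psa_dominant_pct = quad("SE"),
    costmin_cycle2_pct = cm_cycle(2),
    costmin_cycle3_pct = cm_cycle(3),
    costmin_cycle4_pct = cm_cycle(4),
    costmin_cycle5_pct = cm_cycle(5)
  )
  out <- reference_values()
  stopifnot(identical(out$quantity, names(modelled)))
  out$modelled <- unname(unlist(modelled))
  out$deviation <- out$modelled - out$reported
  out
}

#' Run every analysis and write the full output set
#'
#' Executes the baseline cost-effectiveness analysis, the one-way
#' sensitivity analyses, the cost-utility analysis, the probabilistic
#' sensitivity analysis and the cost-minimisation analysis in sequence, and
#' writes machine-readable outputs to `out_dir`: the resolved parameter set
#' (YAML), the pathway audit table, the baseline results table, scenario and
#' tornado data, the cost-effectiveness scatter, per-cycle least-cost
#' proportions, the published-value comparison table and a run manifest
#' (command, configuration hash, seed, package version, timestamps, output
#' list).
#'
#' @param config Model configuration.
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed for the probabilistic analyses.
#' @param n_sims Simulations for the probabilistic analyses.
#' @return The manifest list, invisibly.
#' @export
run_all <- function(config = default_config(), out_dir, seed = 1,
                    n_sims = config$psa$n_sims) {
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  path <- function(f) file.path(out_dir, f)
  outputs <- character()
  emit <- function(f) {
    outputs <<- c(outputs, f)
    path(f)
  }

  write_config(config, emit("config_resolved.yaml"))
  write_pathways(config, emit("pathways.csv"))

  base <- run_baseline(config)
  base_tab <- base$costs
  base_tab$p0_hs2 <- c(rep(NA, 4), base$p0_hs2)
  base_tab$p0_sc <- c(rep(NA, 4), base$p0_sc)
  base_tab$icer <- c(rep(NA, 4), base$icer$value)
  utils::write.csv(base_tab, emit("baseline.csv"), row.names = FALSE)

  sens <- one_way_sensitivity(config)
  utils::write.csv(as.data.frame(sens), emit("sensitivity.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(baseline_icer = base$icer$value,
         bars = lapply(seq_len(nrow(sens)), function(i) {
           list(name = sens$name[i], low = sens$icer_low[i],
                high = sens$icer_high[i], range = sens$range[i])
         })),
    emit("tornado.json"), auto_unbox = TRUE, digits = NA)

  cua <- run_cost_utility(config)
  jsonlite::write_json(
    list(qaly_difference = cua$qaly_diff,
         annualisation_factor = cua$annualisation_factor,
         delta_cost = cua$delta_cost,
         cost_per_qaly = cua$icer$value,
         cost_per_qaly_2sf = cua$icer$value_2sf),
    emit("cost_utility.json"), auto_unbox = TRUE, digits = NA)

  psa <- run_psa(config, n_sims = n_sims, seed = seed)
  utils::write.csv(psa$points, emit("psa_scatter.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(n_sims = psa$n_sims, n_excluded = psa$n_excluded,
         seed = seed, baseline = as.list(psa$baseline),
         quadrants = psa$quadrants),
    emit("psa_summary.json"), auto_unbox = TRUE, digits = NA)

  cm <- estimate_least_cost_probability(config, n_sims = n_sims, seed = seed)
  utils::write.csv(cm$by_pgp, emit("costmin_cycles.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(n_sims = cm$n_sims, n_excluded = cm$n_excluded, seed = seed,
         average = cm$average),
    emit("costmin_summary.json"), auto_unbox = TRUE, digits = NA)

  cmp <- compare_reference(config, n_sims = n_sims, seed = seed)
  utils::write.csv(cmp, emit("reference_comparison.csv"), row.names = FALSE)

  manifest <- list(
    command = "run_all",
    package = "hs2cea",
    version = as.character(utils::packageVersion("hs2cea")),
    config_hash = unname(tools::md5sum(path("config_resolved.yaml"))),
    seed = seed,
    n_sims = n_sims,
    started = started,
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = outputs
  )
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE)
  invisible(manifest)
}
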