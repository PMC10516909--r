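#' Full growth-coupled target-identification pipeline
#'
#' Orchestrates the whole workflow: load model, apply constraints,
#' initialize, build the step schedule, scan, filter, classify, score,
#' screen essentiality, and write the report. Each stage logs its key
#' numbers via `message()`.
#'
#' @param config a named list (or path to a YAML file) with fields:
#'   `model` (path or a `gem` object), `format` (optional), `biomass_id`,
#'   `target_id`, `constraints` (path to YAML, a `constraint_set`, or
#'   `NULL`), `substrate`, `n_steps` (default 5), `cap_fraction` (default
#'   0.9), `swf_variant` (default `"deviation"`), `change_tol` (default
#'   0.01), `monotonicity_tol` (default 1e-4), `essentiality_fraction`
#'   (default 0.001), `screen_all` (default `FALSE`: screen only the
#'   downregulation candidates; `TRUE` screens every reaction),
#'   `deterministic` (default `TRUE`), `out_dir` (optional: write report).
#' @return a `report_bundle`, invisibly when a report is written.
#' @export
run_full <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- function(name, default = NULL) config[[name]] %||% default

  model <- config$model
  if (is.character(model)) {
    if (!file.exists(model)) stop("model file not found: ", model)
    model <- read_gem(model, cfg("format"))
  }
  stopifnot(inherits(model, "gem"))
  message("loaded model ", model$id, ": ", nrow(model$mets),
          " metabolites, ", nrow(model$rxns), " reactions")

  constraints <- cfg("constraints")
  if (is.character(constraints)) constraints <- read_constraints(constraints)
  biomass_id <- cfg("biomass_id") %||%
    select_biomass(model, cfg("substrate",
                              constraints$substrate %||% NA_character_))
  target_id <- cfg("target_id")
  if (is.null(target_id)) stop("config must name a target_id")
  if (!is.null(constraints)) {
    model <- apply_constraints(model, constraints, biomass_id)
    message("applied ", length(constraints$bounds), " bound constraint(s)")
  }

  init <- initialize_scan(model, biomass_id, target_id,
                          cfg("atp_maintenance_override"))
  message("init: biomass in [", fmt_num(init$biomass_min), ", ",
          fmt_num(init$biomass_max), "], target max ",
          fmt_num(init$target_max), ", maintenance floor ",
          fmt_num(init$atp_maintenance_floor))

  schedule <- build_step_schedule(init$target_max,
                                  n_steps = cfg("n_steps", 5),
                                  cap_fraction = cfg("cap_fraction", 0.9))
  message("schedule: ", paste(fmt_num(schedule$enforced_values),
                              collapse = " "))

  table <- run_scan(model, biomass_id, target_id, schedule,
                    deterministic = cfg("deterministic", TRUE))
  message("biomass per step: ", paste(fmt_num(table$biomass_per_step),
                                      collapse = " "))

  table <- filter_valid_profiles(table, cfg("monotonicity_tol", 1e-4))
  message(nrow(table$profiles), " profiles retained after validity filter")

  cls <- classify_reactions(table, cfg("change_tol", 0.01))
  message("classes: ", sum(cls$reaction_type == "flux_increasing"),
          " increasing, ", sum(cls$reaction_type == "flux_decreasing"),
          " decreasing, ", sum(cls$reaction_type == "unaffected"),
          " unaffected")

  swf <- score_scan(table, cfg("swf_variant", "deviation"))
  up <- rank_candidates(cls, swf, "upregulation")
  down <- rank_candidates(cls, swf, "downregulation")

  screen_ids <- if (isTRUE(cfg("screen_all", FALSE))) NULL else down
  ess <- if (length(down) || isTRUE(cfg("screen_all", FALSE))) {
    screen_essentiality(model, screen_ids, biomass_id,
                        cfg("essentiality_fraction", 0.001))
  } else {
    NULL
  }
  down_ok <- if (is.null(ess)) down else filter_nonessential(ess, down)
  message(length(up), " upregulation candidate(s); ", length(down_ok),
          " non-essential downregulation candidate(s) of ", length(down))

  bundle <- report_bundle(
    table, cls, swf, ess, up, down_ok,
    metadata = list(
      model_id = model$id,
      biomass_id = biomass_id, target_id = target_id,
      constraints_digest = constraints_digest(constraints),
      schedule = list(n_steps = schedule$n_steps,
                      cap_fraction = schedule$cap_fraction,
                      target_max = schedule$target_max,
                      enforced_values = schedule$enforced_values),
      init = unclass(init),
      tolerances = list(change_tol = cfg("change_tol", 0.01),
                        monotonicity_tol = cfg("monotonicity_tol", 1e-4),
                        essentiality_fraction = cfg("essentiality_fraction",
                                                    0.001)),
      swf_variant = cfg("swf_variant", "deviation"),
      deterministic = cfg("deterministic", TRUE)))

  out_dir <- cfg("out_dir")
  if (!is.null(out_dir)) {
    paths <- write_report(bundle, out_dir)
    message("report written to ", out_dir, " (", length(paths), " files)")
    return(invisible(bundle))
  }
  bundle
}

# md5 of the canonical YAML form; NULL constraints digest to "none"
constraints_digest <- function(constraints) {
  if (is.null(constraints)) return("none")
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(unclass(constraints), f)
  unname(tools::md5sum(f))
}
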