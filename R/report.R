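#' Assemble a reproducible report bundle
#'
#' Collects a model run (and optionally scenario runs and sweeps) into the
#' two headline tables — incremental clinical events per cohort and the
#' per-infant cost breakdown — together with provenance metadata: an MD5
#' hash of the full parameter configuration, the package version and an
#' optional seed. Re-running from the same configuration and seed
#' reproduces the bundle, and its CSV exports, byte for byte.
#'
#' @param model An \code{"ehmd_model"}.
#' @param scenarios Optional named list of \code{"ehmd_scenario"} objects.
#' @param sweeps Optional named list of \code{"ehmd_sweep"} objects.
#' @param seed Optional integer recorded in the metadata (for runs
#'   involving simulation).
#' @return Object of class \code{"ehmd_report"} with components
#'   \code{events}, \code{costs}, \code{scenarios}, \code{sweeps} and
#'   \code{metadata}.
#' @export
report_bundle <- function(model, scenarios = list(), sweeps = list(),
                          seed = NULL) {
  stopifnot(inherits(model, "ehmd_model"))
  sm <- summary(model)
  scen_tab <- NULL
  if (length(scenarios)) {
    scen_tab <- do.call(rbind, lapply(names(scenarios), function(nm) {
      s <- scenarios[[nm]]
      data.frame(scenario = nm,
                 incremental_cost_total = s$incremental_costs$total,
                 inc_deaths = s$events$deaths, inc_nec = s$events$nec_total,
                 inc_sepsis = s$events$sepsis, inc_bpd = s$events$bpd,
                 inc_rop = s$events$rop, inc_cp = s$events$cp,
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(
    events = sm$events, costs = sm$costs,
    scenarios = scen_tab, sweeps = sweeps,
    metadata = list(config_hash = config_hash(model), seed = seed,
                    package_version =
                      as.character(utils::packageVersion("ehmdecon")),
                    cohort_size = model$settings$cohort_size,
                    view = model$incremental_costs$view)
  ), class = "ehmd_report")
}

config_hash <- function(model) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  doc <- list(clinical = unclass(model$clinical),
              costs = unclass(model$costs),
              settings = unclass(model$settings),
              societal = model$societal,
              cp_or_method = model$cp_or_method)
  jsonlite::write_json(doc, tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

#' Write a report bundle to disk
#'
#' Writes \code{events.csv} and \code{costs.csv} (values rounded for
#' reading: event counts half-to-even to integers, costs to whole dollars),
#' one \code{sweep_<name>.csv} per sweep (full precision), an optional
#' \code{scenarios.csv}, a full-precision JSON twin \code{report.json}
#' including the metadata, and a short markdown summary \code{report.md}.
#'
#' @param bundle An \code{"ehmd_report"}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_report <- function(bundle, dir) {
  stopifnot(inherits(bundle, "ehmd_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ev <- bundle$events
  ev[c("ehmd", "usual", "incremental")] <-
    lapply(ev[c("ehmd", "usual", "incremental")], round)
  utils::write.csv(ev, file.path(dir, "events.csv"), row.names = FALSE)
  co <- bundle$costs
  co[c("ehmd", "usual", "incremental")] <-
    lapply(co[c("ehmd", "usual", "incremental")], round)
  utils::write.csv(co, file.path(dir, "costs.csv"), row.names = FALSE)
  if (!is.null(bundle$scenarios))
    utils::write.csv(bundle$scenarios, file.path(dir, "scenarios.csv"),
                     row.names = FALSE)
  for (nm in names(bundle$sweeps))
    utils::write.csv(as.data.frame(bundle$sweeps[[nm]]),
                     file.path(dir, paste0("sweep_", nm, ".csv")),
                     row.names = FALSE)
  jsonlite::write_json(
    list(events = bundle$events, costs = bundle$costs,
         scenarios = bundle$scenarios, metadata = bundle$metadata),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  writeLines(render_report_md(bundle), file.path(dir, "report.md"))
  invisible(dir)
}

render_report_md <- function(bundle) {
  md_table <- function(df) {
    fmt <- vapply(df, function(col)
      if (is.numeric(col)) formatC(round(col), format = "d") else
        as.character(col), character(nrow(df)))
    fmt <- matrix(fmt, nrow = nrow(df))
    c(paste0("| ", paste(names(df), collapse = " | "), " |"),
      paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
      apply(fmt, 1, function(r) paste0("| ", paste(r, collapse = " | "),
                                       " |")))
  }
  total <- bundle$costs$incremental[bundle$costs$component == "Total"]
  c(sprintf("# EHMD cost-consequence report (%s perspective)",
            bundle$metadata$view),
    "",
    sprintf("Cohort size: %s. Config hash: `%s`. Package version: %s.%s",
            format(bundle$metadata$cohort_size),
            bundle$metadata$config_hash,
            bundle$metadata$package_version,
            if (is.null(bundle$metadata$seed)) "" else
              sprintf(" Seed: %d.", bundle$metadata$seed)),
    "",
    sprintf("Incremental cost per infant: **%s USD** (%s).",
            formatC(round(total), format = "d", big.mark = ","),
            if (total < 0) "EHMD cost-saving" else "EHMD cost-increasing"),
    "",
    "## Incremental clinical events", "",
    md_table(bundle$events), "",
    "## Costs per infant (USD)", "",
    md_table(bundle$costs),
    if (!is.null(bundle$scenarios))
      c("", "## Scenarios", "", md_table(bundle$scenarios)))
}
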