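# Configuration files: one YAML/JSON schema with nested scenario presets.
# Unknown keys are rejected so typos never silently fall back to defaults.

config_sections <- c("clinical", "costs", "settings", "scenarios")

#' Named scenario presets
#'
#' The four built-in analyses:
#' \describe{
#'   \item{base_case}{Retrospective-cohort baselines with trial relative
#'     risks (trial mortality effect excluded as implausibly large).}
#'   \item{lower_cost}{The data source per parameter under which the EHMD
#'     yields the greatest savings (trial baselines and the stronger
#'     cohort-study sepsis/BPD effects).}
#'   \item{higher_cost}{The data source per parameter yielding the least
#'     savings (weaker cohort NEC/RoP effects; trial mortality effect, which
#'     saves more lives and so incurs more survivor costs).}
#'   \item{mortality_rct}{Base case with the trial mortality effect
#'     (rr_death 0.24) applied to the cohort baseline 0.172.}
#' }
#'
#' @return Named list; each element is a list of clinical-parameter
#'   overrides relative to the base case.
#' @export
scenario_presets <- function() {
  list(
    base_case = list(),
    lower_cost = list(
      p_nec_usual = 0.172,
      frac_nec_surgical_usual = 0.688,
      p_sepsis_usual = 0.344,
      p_death_usual = 0.075,
      p_bpd_usual = 0.301,
      p_rop_usual = 0.107,
      rr_sepsis = 0.63,
      rr_bpd = 0.85
    ),
    higher_cost = list(
      rr_nec = 0.41,
      rr_rop = 0.58,
      rr_death = 0.24
    ),
    mortality_rct = list(
      rr_death = 0.24
    )
  )
}

apply_overrides <- function(base, overrides, constructor, what) {
  if (length(overrides) == 0L) return(base)
  unknown <- setdiff(names(overrides), names(unclass(base)))
  if (length(unknown))
    stop("unknown ", what, " field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  vals <- unclass(base)
  vals[names(overrides)] <- overrides
  do.call(constructor, vals)
}

#' Load and validate a model configuration
#'
#' Reads a YAML or JSON configuration document holding \code{clinical},
#' \code{costs} and \code{settings} sections (each optional; omitted fields
#' take the base-case defaults) plus an optional \code{scenarios} section of
#' named presets, each a set of overrides. Unknown keys anywhere raise an
#' error naming the offending field, as do out-of-range probabilities and
#' relative risks that push a probability above 1.
#'
#' @param config Path to a \code{.yaml}/\code{.yml}/\code{.json} file, or an
#'   already-parsed nested list.
#' @param scenario Name of the preset to resolve. \code{"base_case"} returns
#'   the document's own parameter values; other names first apply the
#'   built-in presets of [scenario_presets()] and then any same-named
#'   overrides in the document's \code{scenarios} section.
#' @return A list with validated components \code{clinical}
#'   (\code{ehmd_clinical}), \code{costs} (\code{ehmd_costs}) and
#'   \code{settings} (\code{ehmd_settings}).
#' @export
#' @examples
#' cfg <- system.file("extdata", "base_case.yaml", package = "ehmdecon")
#' p <- load_params(cfg)
#' p$clinical$p_nec_usual
load_params <- function(config, scenario = "base_case") {
  doc <- read_config_document(config)
  unknown <- setdiff(names(doc), config_sections)
  if (length(unknown))
    stop("unknown configuration section(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)

  clinical <- do.call(clinical_params, doc$clinical %||% list())
  costs <- do.call(cost_params, doc$costs %||% list())
  settings <- do.call(econ_settings, doc$settings %||% list())

  if (!identical(scenario, "base_case")) {
    presets <- scenario_presets()
    doc_scen <- doc$scenarios %||% list()
    if (!scenario %in% names(presets) && !scenario %in% names(doc_scen))
      stop("unknown scenario preset '", scenario, "'", call. = FALSE)
    ov <- presets[[scenario]] %||% list()
    doc_ov <- doc_scen[[scenario]] %||% list()
    bad <- setdiff(names(doc_ov), c("clinical", "costs", "settings"))
    if (length(bad))
      stop("unknown section(s) in scenario '", scenario, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
    clinical <- apply_overrides(clinical, ov, clinical_params, "clinical")
    clinical <- apply_overrides(clinical, doc_ov$clinical %||% list(),
                                clinical_params, "clinical")
    costs <- apply_overrides(costs, doc_ov$costs %||% list(),
                             cost_params, "cost")
    settings <- apply_overrides(settings, doc_ov$settings %||% list(),
                                econ_settings, "settings")
  }
  list(clinical = clinical, costs = costs, settings = settings)
}

read_config_document <- function(config) {
  if (is.list(config)) return(config)
  if (!is.character(config) || length(config) != 1L)
    stop("'config' must be a file path or a nested list", call. = FALSE)
  if (!file.exists(config))
    stop("configuration file not found: ", config, call. = FALSE)
  ext <- tolower(tools::file_ext(config))
  doc <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(config),
    json = jsonlite::read_json(config, simplifyVector = TRUE),
    stop("unsupported configuration format '.", ext,
         "' (use YAML or JSON)", call. = FALSE)
  )
  if (!is.list(doc) || length(doc) == 0L)
    stop("configuration document is empty", call. = FALSE)
  doc
}

#' Write a validated parameter set back to a configuration file
#'
#' Serialises the three parameter containers into the same schema read by
#' [load_params()], so that loading the written file reproduces the values
#' exactly.
#'
#' @param params List with \code{clinical}, \code{costs}, \code{settings}
#'   components as returned by [load_params()].
#' @param path Output file path ending in \code{.yaml}, \code{.yml} or
#'   \code{.json}.
#' @return \code{path}, invisibly.
#' @export
write_params <- function(params, path) {
  doc <- list(clinical = unclass(params$clinical),
              costs = unclass(params$costs),
              settings = unclass(params$settings))
  doc$costs$societal <- params$costs$societal  # keep NULL out of YAML
  if (is.null(doc$costs$societal)) doc$costs$societal <- NULL
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(doc, path, precision = 15)
  } else if (ext == "json") {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    stop("unsupported configuration format '.", ext, "'", call. = FALSE)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
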