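#' Evaluate the EHMD cost-consequence model
#'
#' The central entry point: evaluates the cohort decision tree for both diet
#' arms (usual practice of care and the exclusive human milk diet), attaches
#' costs, and returns the incremental cost-consequence comparison for the
#' hypothetical cohort.
#'
#' The model is a single-pass decision tree evaluated in expectation (no
#' sampling): infants may develop NEC (medical or surgical), late-onset
#' sepsis, both, or neither; may die during the initial stay; and survivors
#' may develop BPD, retinopathy of prematurity and cerebral palsy, with
#' short bowel syndrome possible after surgical NEC. See [run_arm()] for
#' the structural assumptions and [arm_costs()] for the cost attachment.
#'
#' @param clinical A [clinical_params()] object.
#' @param costs A [cost_params()] object.
#' @param settings An [econ_settings()] object.
#' @param societal Evaluate the societal perspective in addition to the
#'   payer perspective? Requires the \code{societal} block of
#'   [cost_params()].
#' @param cp_or_method How the cerebral-palsy odds ratio is applied; see
#'   [cp_probability()].
#' @return Object of class \code{"ehmd_model"} with components
#'   \code{arms} (the two \code{"ehmd_arm"} results), \code{events}
#'   (\code{"ehmd_incremental"}), \code{costs_by_arm} (two
#'   \code{"ehmd_cost_breakdown"}s), \code{incremental_costs}, and the
#'   parameter containers used.
#' @seealso [summary.ehmd_model()], [predict.ehmd_model()],
#'   [simulate.ehmd_model()], [run_scenario()], [threshold_incidence()]
#' @export
#' @examples
#' m <- ehmd_model()
#' m
#' summary(m)
#' round(m$incremental_costs$total)   # about -16500: EHMD is cost-saving
ehmd_model <- function(clinical = clinical_params(),
                       costs = cost_params(),
                       settings = econ_settings(),
                       societal = FALSE,
                       cp_or_method = c("risk_multiplier", "odds")) {
  cp_or_method <- match.arg(cp_or_method)
  usual <- run_arm(clinical, settings, "usual", cp_or_method)
  ehmd <- run_arm(clinical, settings, "ehmd", cp_or_method)
  cu <- arm_costs(usual, costs, societal = societal)
  ce <- arm_costs(ehmd, costs, societal = societal)
  structure(list(
    clinical = clinical, costs = costs, settings = settings,
    societal = societal, cp_or_method = cp_or_method,
    arms = list(usual = usual, ehmd = ehmd),
    events = incremental_events(ehmd, usual),
    costs_by_arm = list(usual = cu, ehmd = ce),
    incremental_costs = incremental_costs(ce, cu),
    call = match.call()
  ), class = "ehmd_model")
}

#' @export
print.ehmd_model <- function(x, ...) {
  cat("EHMD vs usual care cost-consequence model",
      sprintf("(cohort of %s infants, %s perspective)\n",
              format(x$settings$cohort_size),
              x$incremental_costs$view))
  inc <- x$events
  key <- c("deaths", "nec_total", "sepsis", "bpd", "rop", "cp", "sbs")
  v <- round(unlist(inc[key]))
  names(v) <- c("deaths", "NEC", "sepsis", "BPD", "RoP", "CP", "SBS")
  cat("Incremental events (EHMD - usual care):\n")
  print(v)
  cat(sprintf("Incremental cost per infant: %s USD (%s)\n",
              formatC(round(x$incremental_costs$total), format = "d",
                      big.mark = ","),
              if (x$incremental_costs$total < 0) "cost-saving"
              else "cost-increasing"))
  invisible(x)
}

#' Summarise an EHMD model run
#'
#' Builds the two headline tables: incremental clinical events per cohort
#' (counts rounded half-to-even) and the per-infant cost breakdown by arm
#' with its incremental column (whole dollars). Full-precision values remain
#' available on the model object itself.
#'
#' @param object An \code{"ehmd_model"}.
#' @param ... Ignored.
#' @return Object of class \code{"summary.ehmd_model"} with data-frame
#'   components \code{events} and \code{costs}.
#' @export
summary.ehmd_model <- function(object, ...) {
  ev <- as.data.frame(object$events)
  comps <- intersect(c(cost_components, "societal", "total"),
                     names(object$incremental_costs))
  costs <- data.frame(
    component = cost_labels()[comps],
    ehmd = unlist(object$costs_by_arm$ehmd[comps]),
    usual = unlist(object$costs_by_arm$usual[comps]),
    incremental = unlist(object$incremental_costs[comps]),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(events = ev, costs = costs,
                 cohort_size = object$settings$cohort_size,
                 view = object$incremental_costs$view),
            class = "summary.ehmd_model")
}

#' @export
print.summary.ehmd_model <- function(x, ...) {
  cat(sprintf(
    "Incremental events per %s infants (EHMD - usual practice of care):\n",
    format(x$cohort_size)))
  ev <- x$events
  ev[c("ehmd", "usual", "incremental")] <-
    lapply(ev[c("ehmd", "usual", "incremental")], round)
  print(ev, row.names = FALSE)
  cat(sprintf("\nCosts per infant (USD, %s perspective):\n", x$view))
  co <- x$costs
  co[c("ehmd", "usual", "incremental")] <-
    lapply(co[c("ehmd", "usual", "incremental")], round)
  print(co, row.names = FALSE)
  invisible(x)
}

#' Model parameters as a named vector
#'
#' @param object An \code{"ehmd_model"}.
#' @param ... Ignored.
#' @return Named numeric vector of all clinical and cost parameters
#'   (societal block flattened with a \code{societal.} prefix when present).
#' @export
coef.ehmd_model <- function(object, ...) {
  cl <- unlist(unclass(object$clinical))
  co <- unclass(object$costs)
  soc <- co$societal
  co$societal <- NULL
  out <- c(cl, unlist(co))
  if (!is.null(soc)) out <- c(out, unlist(list(societal = soc)))
  out
}

#' Re-evaluate the model under modified parameters
#'
#' Evaluates the incremental outcomes at each row of \code{newdata}, a data
#' frame whose columns name clinical or cost parameters to override (all
#' other parameters held at the model's values). This is the engine behind
#' [sweep_param()] and [threshold_incidence()].
#'
#' @param object An \code{"ehmd_model"}.
#' @param newdata Data frame of parameter overrides; \code{NULL} re-returns
#'   the model's own incremental outcomes (one row).
#' @param ... Ignored.
#' @return Data frame with one row per row of \code{newdata}: the override
#'   columns, the incremental total cost per infant
#'   (\code{incremental_cost_total}) and incremental event counts
#'   (\code{inc_} columns), all at full precision.
#' @export
#' @examples
#' m <- ehmd_model()
#' predict(m, data.frame(p_nec_usual = c(0.02, 0.05, 0.167)))
predict.ehmd_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- data.frame(row.names = 1)
  stopifnot(is.data.frame(newdata))
  clin_names <- names(unclass(object$clinical))
  cost_names <- setdiff(names(unclass(object$costs)), "societal")
  bad <- setdiff(names(newdata), c(clin_names, cost_names))
  if (length(bad))
    stop("unknown parameter(s) in 'newdata': ", paste(bad, collapse = ", "),
         call. = FALSE)
  rows <- lapply(seq_len(nrow(newdata)), function(i) {
    cl_ov <- as.list(newdata[i, intersect(names(newdata), clin_names),
                             drop = FALSE])
    co_ov <- as.list(newdata[i, intersect(names(newdata), cost_names),
                             drop = FALSE])
    clinical <- apply_overrides(object$clinical, cl_ov, clinical_params,
                                "clinical")
    costs <- apply_overrides(object$costs, co_ov, cost_params, "cost")
    m <- ehmd_model(clinical, costs, object$settings,
                    societal = object$societal,
                    cp_or_method = object$cp_or_method)
    ev <- m$events
    cbind(newdata[i, , drop = FALSE],
          data.frame(incremental_cost_total = m$incremental_costs$total,
                     inc_deaths = ev$deaths, inc_nec = ev$nec_total,
                     inc_nec_surgical = ev$nec_surgical,
                     inc_sepsis = ev$sepsis, inc_bpd = ev$bpd,
                     inc_rop = ev$rop, inc_cp = ev$cp, inc_sbs = ev$sbs))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate from the model
#'
#' Two stochastic companions to the deterministic expected-value engine:
#' \describe{
#'   \item{\code{method = "microsimulation"}}{Individual-level Bernoulli
#'     sampling of \code{n} infants per arm following exactly the tree
#'     structure of [run_arm()]; the validation oracle for the
#'     expectations. See [microsimulate()].}
#'   \item{\code{method = "psa"}}{Probabilistic sensitivity analysis:
#'     \code{nsim} parameter sets drawn from [param_distributions()] and
#'     pushed through the deterministic model. See [run_psa()].}
#' }
#'
#' @param object An \code{"ehmd_model"}.
#' @param nsim Number of PSA draws (ignored for microsimulation).
#' @param seed Integer seed; required for reproducibility.
#' @param method \code{"microsimulation"} or \code{"psa"}.
#' @param n Number of simulated infants per arm (microsimulation only).
#' @param dists A [param_distributions()] specification (PSA only; defaults
#'   to distributions centred on the model's own parameters).
#' @param ... Ignored.
#' @return See [microsimulate()] and [run_psa()].
#' @export
simulate.ehmd_model <- function(object, nsim = 1000, seed = NULL,
                                method = c("microsimulation", "psa"),
                                n = 10000, dists = NULL, ...) {
  method <- match.arg(method)
  if (is.null(seed)) seed <- 1L
  if (method == "microsimulation") {
    microsimulate(object$clinical, object$costs, n = n, seed = seed,
                  settings = object$settings,
                  cp_or_method = object$cp_or_method)
  } else {
    if (is.null(dists))
      dists <- param_distributions(object$clinical, object$costs,
                                   seed = seed)
    run_psa(dists, nsim, settings = object$settings,
            cp_or_method = object$cp_or_method)
  }
}
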