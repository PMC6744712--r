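#' Run a named scenario through the full pipeline
#'
#' Resolves a scenario preset (see [scenario_presets()]), evaluates the
#' full model under it, and returns the incremental results alongside the
#' scenario name. \code{"base_case"} reproduces the default pipeline
#' exactly.
#'
#' @param name Preset name: \code{"base_case"}, \code{"lower_cost"},
#'   \code{"higher_cost"} or \code{"mortality_rct"}.
#' @param clinical,costs,settings Base parameters before the preset's
#'   overrides are applied.
#' @param societal Evaluate the societal perspective? (A flag on any
#'   scenario, not a separate model.)
#' @param cp_or_method See [cp_probability()].
#' @return Object of class \code{"ehmd_scenario"}: the scenario name, the
#'   full \code{"ehmd_model"} and shortcuts \code{events} and
#'   \code{incremental_costs}.
#' @export
#' @examples
#' sc <- run_scenario("mortality_rct")
#' round(-sc$events$deaths)   # about 131 lives saved per 1000
run_scenario <- function(name, clinical = clinical_params(),
                         costs = cost_params(),
                         settings = econ_settings(),
                         societal = FALSE,
                         cp_or_method = c("risk_multiplier", "odds")) {
  presets <- scenario_presets()
  if (!name %in% names(presets))
    stop("unknown scenario preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  clinical <- apply_overrides(clinical, presets[[name]], clinical_params,
                              "clinical")
  m <- ehmd_model(clinical, costs, settings, societal = societal,
                  cp_or_method = match.arg(cp_or_method))
  structure(list(name = name, model = m, events = m$events,
                 incremental_costs = m$incremental_costs),
            class = "ehmd_scenario")
}

#' @export
print.ehmd_scenario <- function(x, ...) {
  cat("Scenario:", x$name, "\n")
  print(x$model)
  invisible(x)
}

#' One-way parameter sweep
#'
#' Recomputes the incremental outcomes over a strictly increasing grid of
#' values for one clinical or cost parameter, all other inputs held fixed
#' (including relative risks, the surgical share and all downstream
#' conditionals).
#'
#' @param object An \code{"ehmd_model"} serving as the base configuration.
#' @param param Name of a clinical or cost parameter.
#' @param grid Strictly increasing numeric vector of values, each valid for
#'   the parameter.
#' @return Object of class \code{"ehmd_sweep"}: a data frame (one row per
#'   grid point) with the parameter value, \code{incremental_cost_total}
#'   (USD per infant) and incremental event counts, with attributes
#'   \code{param} and \code{base_value}.
#' @seealso [threshold_incidence()], [plot.ehmd_sweep()]
#' @export
#' @examples
#' m <- ehmd_model()
#' sw <- sweep_param(m, "p_nec_usual", seq(0.02, 0.20, by = 0.01))
#' round(-sw$inc_nec[sw$p_nec_usual == 0.05])  # NEC cases avoided at 5%
sweep_param <- function(object, param, grid) {
  stopifnot(inherits(object, "ehmd_model"))
  if (!is.numeric(grid) || length(grid) < 1L)
    stop("'grid' must be a non-empty numeric vector", call. = FALSE)
  if (is.unsorted(grid, strictly = TRUE))
    stop("'grid' must be strictly increasing", call. = FALSE)
  for (g in grid) {
    nd <- data.frame(g)
    names(nd) <- param
    ok <- tryCatch({predict(object, nd); TRUE},
                   error = function(e) conditionMessage(e))
    if (!isTRUE(ok))
      stop("invalid grid value ", g, " for '", param, "': ", ok,
           call. = FALSE)
  }
  nd <- data.frame(grid)
  names(nd) <- param
  out <- predict(object, nd)
  base_value <- unclass(object$clinical)[[param]] %||%
    unclass(object$costs)[[param]]
  structure(out, class = c("ehmd_sweep", "data.frame"),
            param = param, base_value = base_value)
}

#' Plot a one-way sweep
#'
#' Line plot of the incremental total cost per infant against the swept
#' parameter, with the zero line (break-even) and the base-case value
#' marked.
#'
#' @param x An \code{"ehmd_sweep"}.
#' @param ... Passed to [plot.default()].
#' @return \code{x}, invisibly.
#' @export
plot.ehmd_sweep <- function(x, ...) {
  param <- attr(x, "param")
  plot(x[[param]], x$incremental_cost_total, type = "l",
       xlab = param, ylab = "Incremental cost per infant (USD)", ...)
  abline(h = 0, lty = 2, col = "grey40")
  bv <- attr(x, "base_value")
  if (!is.null(bv)) abline(v = bv, lty = 3, col = "grey40")
  invisible(x)
}

#' Break-even (threshold) analysis
#'
#' Finds the value of a parameter at which the incremental total cost per
#' infant crosses zero, all other inputs fixed: below the threshold the
#' EHMD is cost-increasing, above it cost-saving (for event incidences,
#' whose savings grow with incidence). The root is located by bracketing
#' bisection to an absolute tolerance on the parameter. Because the
#' incremental cost is affine in each baseline incidence, the closed-form
#' linear solution is also computed (after a three-point affinity check)
#' and returned for cross-validation.
#'
#' When the incremental cost does not change sign over \code{interval}, the
#' nearer boundary is returned with status \code{"always-saving"} (negative
#' throughout) or \code{"never-saving"} (positive throughout).
#'
#' @param object An \code{"ehmd_model"} base configuration.
#' @param param Parameter to solve over (e.g. \code{"p_nec_usual"},
#'   \code{"p_sepsis_usual"}).
#' @param interval Length-2 search interval within the parameter's valid
#'   range.
#' @param tol Absolute tolerance on the parameter for the bisection.
#' @return List with \code{param}, \code{value} (the root, or the boundary
#'   when flagged), \code{status} (\code{"interior"}, \code{"always-saving"}
#'   or \code{"never-saving"}), \code{closed_form} (affine solution, or
#'   \code{NA} when the response is not affine over the interval),
#'   \code{percent} (value as a percentage rounded to the nearest whole
#'   percent, for incidence parameters), and \code{f_lower}, \code{f_upper}
#'   (incremental costs at the interval ends).
#' @export
#' @examples
#' m <- ehmd_model()
#' th <- threshold_incidence(m, "p_nec_usual")
#' th$value      # break-even baseline NEC incidence
#' threshold_incidence(m, "p_sepsis_usual")$status  # "always-saving"
threshold_incidence <- function(object, param, interval = c(0, 1),
                                tol = 1e-6) {
  stopifnot(inherits(object, "ehmd_model"), length(interval) == 2L,
            interval[1] < interval[2])
  f <- function(v) {
    nd <- data.frame(v)
    names(nd) <- param
    predict(object, nd)$incremental_cost_total
  }
  lo <- interval[1]; hi <- interval[2]
  flo <- f(lo); fhi <- f(hi)

  # affinity check and closed-form solution
  mid <- (lo + hi) / 2
  fmid <- f(mid)
  affine <- isTRUE(all.equal(fmid, (flo + fhi) / 2,
                             tolerance = 1e-8,
                             scale = max(abs(c(flo, fhi)), 1)))
  closed_form <- if (affine && fhi != flo)
    lo - flo * (hi - lo) / (fhi - flo) else NA_real_

  if (flo <= 0 && fhi <= 0) {
    res <- list(value = lo, status = "always-saving")
  } else if (flo >= 0 && fhi >= 0) {
    res <- list(value = hi, status = "never-saving")
  } else {
    # bracketing bisection on the sign change
    a <- lo; b <- hi; fa <- flo
    while (b - a > tol) {
      m <- (a + b) / 2
      fm <- f(m)
      if (fm == 0) { a <- b <- m; break }
      if (sign(fm) == sign(fa)) { a <- m; fa <- fm } else b <- m
    }
    res <- list(value = (a + b) / 2, status = "interior")
  }
  c(list(param = param), res,
    list(closed_form = if (res$status == "interior") closed_form
           else NA_real_,
         percent = round(100 * res$value),
         f_lower = flo, f_upper = fhi))
}
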