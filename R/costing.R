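#' Per-infant diet costs
#'
#' The EHMD diet cost is built from the median milk volumes and the
#' fortifier mixing rule: every \code{milk_per_vial_ml} mL of milk (mother's
#' or donor) takes one fortifier vial, so the (fractional) number of vials
#' is total milk volume divided by \code{milk_per_vial_ml}. Donor milk is
#' priced per litre; mother's milk is free. Vials are deliberately kept
#' fractional: the published total is the continuous computation, not a
#' whole-vial ceiling.
#'
#' The usual-care diet enters as the flat cost \code{cost_diet_usual} of the
#' cow's-milk-based products.
#'
#' @param costs A [cost_params()] object.
#' @return Cost in USD per infant.
#' @export
#' @examples
#' diet_cost_ehmd(cost_params())        # 7731.23
#' incremental_diet_cost(cost_params()) # 7505.23
diet_cost_ehmd <- function(costs) {
  stopifnot(inherits(costs, "ehmd_costs"))
  total_milk <- costs$vol_mother_ehmd_ml + costs$vol_donor_ehmd_ml
  vials <- total_milk / costs$milk_per_vial_ml
  vials * costs$price_fortifier_vial +
    costs$vol_donor_ehmd_ml / 1000 * costs$price_donor_milk_per_l
}

#' @rdname diet_cost_ehmd
#' @export
incremental_diet_cost <- function(costs) {
  diet_cost_ehmd(costs) - costs$cost_diet_usual
}

cost_components <- c("diet", "baseline_stay", "nec_and_sepsis", "sequelae")

#' Attach costs to an evaluated arm
#'
#' Produces the per-infant cost breakdown for one arm. All event costs are
#' incremental to the baseline stay of an infant with no complications and
#' are additive. Non-survivors accrue the diet, the baseline stay and their
#' NEC/sepsis event costs, but no sequela costs (BPD, RoP and CP are
#' survivor-only events). SBS adds no cost of its own (it is included in
#' the surgical-NEC cost).
#'
#' With \code{societal = TRUE} the breakdown gains a \code{societal}
#' component: the excess of the societal over the payer lifetime CP cost,
#' lifetime earnings lost through IQ reduction after NEC/sepsis, and
#' productivity losses attached to RoP. These require the \code{societal}
#' block of [cost_params()].
#'
#' @param arm An \code{"ehmd_arm"} object from [run_arm()].
#' @param costs A [cost_params()] object.
#' @param societal Include the societal-cost extension?
#' @return Object of class \code{"ehmd_cost_breakdown"}: per-infant USD
#'   components \code{diet}, \code{baseline_stay}, \code{nec_and_sepsis},
#'   \code{sequelae}, optionally \code{societal}, and their \code{total}.
#' @export
#' @examples
#' usual <- run_arm(clinical_params(), econ_settings(), "usual")
#' arm_costs(usual, cost_params())
arm_costs <- function(arm, costs, societal = FALSE) {
  stopifnot(inherits(arm, "ehmd_arm"), inherits(costs, "ehmd_costs"))
  if (societal && is.null(costs$societal))
    stop("societal view requested but 'costs$societal' is absent; supply ",
         "cost_cp_lifetime_societal, earnings_loss_per_iq_point and ",
         "rop_productivity_loss", call. = FALSE)
  n <- arm$cohort_size
  diet <- if (arm$arm == "ehmd") diet_cost_ehmd(costs) else
    costs$cost_diet_usual
  nec_sep <- (arm$nec_surgical * costs$cost_nec_surgical +
                arm$nec_medical * costs$cost_nec_medical +
                arm$sepsis * costs$cost_sepsis) / n
  sequelae <- (arm$bpd * costs$cost_bpd +
                 arm$rop * costs$cost_rop +
                 arm$cp * costs$cost_cp_lifetime_payer) / n
  out <- list(arm = arm$arm, view = if (societal) "societal" else "payer",
              diet = diet, baseline_stay = costs$cost_baseline_stay,
              nec_and_sepsis = nec_sep, sequelae = sequelae)
  if (societal) {
    soc <- costs$societal
    cp_excess <- soc$cost_cp_lifetime_societal - costs$cost_cp_lifetime_payer
    out$societal <- (arm$cp * cp_excess +
                       arm$iq_points_lost_total *
                         soc$earnings_loss_per_iq_point +
                       arm$rop * soc$rop_productivity_loss) / n
  }
  comps <- c(cost_components, if (societal) "societal")
  out$total <- sum(unlist(out[comps]))
  structure(out, class = "ehmd_cost_breakdown")
}

#' Incremental cost breakdown between arms
#'
#' Component-wise EHMD-minus-usual-care differences. Both breakdowns must
#' use the same perspective (payer or societal). The baseline-stay
#' difference is structurally zero: every infant accrues it in both arms.
#'
#' @param ehmd,usual \code{"ehmd_cost_breakdown"} objects.
#' @return An \code{"ehmd_cost_breakdown"} with \code{arm = "incremental"}.
#' @export
incremental_costs <- function(ehmd, usual) {
  stopifnot(inherits(ehmd, "ehmd_cost_breakdown"),
            inherits(usual, "ehmd_cost_breakdown"))
  if (!identical(ehmd$view, usual$view))
    stop("cannot difference a '", ehmd$view, "' breakdown against a '",
         usual$view, "' breakdown", call. = FALSE)
  comps <- c(cost_components, if (ehmd$view == "societal") "societal",
             "total")
  diff <- lapply(comps, function(f) ehmd[[f]] - usual[[f]])
  names(diff) <- comps
  structure(c(list(arm = "incremental", view = ehmd$view), diff),
            class = "ehmd_cost_breakdown")
}

#' @export
print.ehmd_cost_breakdown <- function(x, ...) {
  cat("Per-infant costs (USD, ", x$view, " perspective), ",
      switch(x$arm, incremental = "EHMD - usual care",
             ehmd = "EHMD arm", usual = "usual care arm"), ":\n", sep = "")
  comps <- intersect(c(cost_components, "societal", "total"), names(x))
  v <- round(unlist(x[comps]))
  print(v)
  invisible(x)
}

#' @export
as.data.frame.ehmd_cost_breakdown <- function(x, row.names = NULL,
                                              optional = FALSE, ...) {
  comps <- intersect(c(cost_components, "societal", "total"), names(x))
  data.frame(component = cost_labels()[comps],
             usd_per_infant = unlist(x[comps]),
             row.names = NULL, stringsAsFactors = FALSE)
}

cost_labels <- function() {
  c(diet = "Diet",
    baseline_stay = "Baseline hospital costs",
    nec_and_sepsis = "NEC and late onset sepsis",
    sequelae = "Sequelae",
    societal = "Societal costs",
    total = "Total")
}
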