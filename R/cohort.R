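#' Apply a relative risk to a baseline probability
#'
#' Returns \code{p * rr} clamped into \[0, 1\]; a warning is emitted when
#' clamping occurred. Vectorised over both arguments.
#'
#' @param p Baseline probability (or vector of them) in \[0, 1\].
#' @param rr Relative risk, non-negative.
#' @return Probability of the event in the intervention arm.
#' @export
#' @examples
#' apply_relative_risk(0.167, 0.31)  # 0.05177
apply_relative_risk <- function(p, rr) {
  stopifnot(all(p >= 0 & p <= 1), all(rr >= 0))
  out <- p * rr
  if (any(out > 1)) {
    warning("relative risk pushed ", sum(out > 1),
            " probability value(s) above 1; clamped to 1", call. = FALSE)
    out <- pmin(out, 1)
  }
  out
}

#' Cerebral palsy probability by NEC / late-onset sepsis history
#'
#' CP risk in the model depends only on whether a surviving infant had NEC,
#' late-onset sepsis, both, or neither. Source data give the same
#' probability for sepsis-only infants as for unaffected infants, and an
#' odds ratio for infants with NEC; when both events occurred the higher of
#' the two probabilities applies (the NEC value).
#'
#' By default the odds ratio is applied as a multiplicative risk factor,
#' \code{p_cp_base * or_cp_nec}, the reading that reproduces the published
#' incremental CP count. Set \code{or_method = "odds"} for the strict
#' odds-scale conversion \eqn{p' = qOR/(1 + q(OR - 1))} with
#' \eqn{q = p/(1-p)} odds, which yields a slightly smaller risk (0.2121 vs
#' 0.2294 at the defaults).
#'
#' @param p_cp_base CP probability without NEC (and with or without sepsis).
#' @param or_cp_nec Odds ratio for CP following NEC.
#' @param has_nec,has_sepsis Logical event flags (vectorised).
#' @param or_method \code{"risk_multiplier"} (default) or \code{"odds"}.
#' @return CP probability, clamped to \[0, 1\].
#' @export
#' @examples
#' cp_probability(0.148, 1.55, has_nec = FALSE, has_sepsis = FALSE) # 0.148
#' cp_probability(0.148, 1.55, has_nec = TRUE,  has_sepsis = TRUE)  # 0.2294
cp_probability <- function(p_cp_base, or_cp_nec, has_nec, has_sepsis,
                           or_method = c("risk_multiplier", "odds")) {
  or_method <- match.arg(or_method)
  stopifnot(p_cp_base >= 0, p_cp_base <= 1, or_cp_nec > 0)
  p_nec_cp <- cp_risk_after_nec(p_cp_base, or_cp_nec, or_method)
  # max rule: with both events the NEC value (the larger) applies
  ifelse(has_nec, pmax(p_nec_cp, p_cp_base), p_cp_base)
}

cp_risk_after_nec <- function(p_cp_base, or_cp_nec, or_method) {
  if (or_method == "risk_multiplier") {
    min(p_cp_base * or_cp_nec, 1)
  } else {
    odds <- p_cp_base / (1 - p_cp_base) * or_cp_nec
    odds / (1 + odds)
  }
}

#' IQ points lost by NEC / late-onset sepsis history
#'
#' Survivors lose \code{iq_loss_nec} points after NEC, \code{iq_loss_sepsis}
#' after sepsis alone, and nothing otherwise. Losses are not additive: an
#' infant with both events takes the NEC loss only (the larger estimate).
#'
#' @param has_nec,has_sepsis Logical event flags (vectorised).
#' @param iq_loss_nec,iq_loss_sepsis Non-negative IQ-point losses.
#' @return IQ points lost.
#' @export
iq_loss <- function(has_nec, has_sepsis, iq_loss_nec = 11,
                    iq_loss_sepsis = 9) {
  stopifnot(iq_loss_nec >= 0, iq_loss_sepsis >= 0)
  ifelse(has_nec, iq_loss_nec, ifelse(has_sepsis, iq_loss_sepsis, 0))
}

# Per-arm event probabilities. Usual care uses the baselines; the EHMD arm
# multiplies each baseline by its relative risk. Surgical NEC has its own
# relative effect applied to the usual-care surgical probability.
arm_probabilities <- function(clinical, arm) {
  cl <- clinical
  p_surg_usual <- cl$p_nec_usual * cl$frac_nec_surgical_usual
  if (arm == "usual") {
    p <- list(nec = cl$p_nec_usual, nec_surgical = p_surg_usual,
              sepsis = cl$p_sepsis_usual, death = cl$p_death_usual,
              bpd = cl$p_bpd_usual, rop = cl$p_rop_usual)
  } else {
    p <- list(nec = apply_relative_risk(cl$p_nec_usual, cl$rr_nec),
              nec_surgical = apply_relative_risk(p_surg_usual,
                                                 cl$rr_nec_surgical),
              sepsis = apply_relative_risk(cl$p_sepsis_usual, cl$rr_sepsis),
              death = apply_relative_risk(cl$p_death_usual, cl$rr_death),
              bpd = apply_relative_risk(cl$p_bpd_usual, cl$rr_bpd),
              rop = apply_relative_risk(cl$p_rop_usual, cl$rr_rop))
  }
  if (p$nec_surgical > p$nec + 1e-12)
    stop("surgical NEC probability exceeds total NEC probability in the ",
         arm, " arm", call. = FALSE)
  p$nec_medical <- p$nec - p$nec_surgical
  p
}

#' Evaluate one diet arm of the cohort decision tree
#'
#' Computes the expected event counts for a cohort of
#' \code{settings$cohort_size} infants under one diet. All quantities are
#' expectations (no rounding, no sampling):
#' \itemize{
#'   \item NEC and late-onset sepsis apply to the full cohort; their joint
#'     occurrence is the product of the marginals (independence).
#'   \item Surgical NEC is the usual-care surgical probability (baseline
#'     NEC \eqn{\times} surgical share), multiplied by
#'     \code{rr_nec_surgical} in the EHMD arm; medical NEC is the remainder.
#'   \item Death during the initial stay applies to the full cohort,
#'     independently of the events; survivors are the complement.
#'   \item BPD, RoP and CP apply to survivors only, with the event mix
#'     among survivors equal to the cohort mix (events independent of
#'     survival).
#'   \item SBS follows surgical NEC at a fixed conditional probability.
#'   \item Total IQ points lost aggregate [iq_loss()] over the surviving
#'     NEC/sepsis mix.
#' }
#'
#' @param clinical An [clinical_params()] object.
#' @param settings An [econ_settings()] object.
#' @param arm \code{"usual"} or \code{"ehmd"}.
#' @param cp_or_method How the CP odds ratio is applied; see
#'   [cp_probability()].
#' @return Object of class \code{"ehmd_arm"}: a list of expected counts
#'   (\code{cohort_size}, \code{deaths}, \code{survivors}, \code{nec_total},
#'   \code{nec_medical}, \code{nec_surgical}, \code{sepsis},
#'   \code{nec_and_sepsis}, \code{bpd}, \code{rop}, \code{cp}, \code{sbs},
#'   \code{iq_points_lost_total}).
#' @export
#' @examples
#' run_arm(clinical_params(), econ_settings(), "usual")$deaths    # 172
#' run_arm(clinical_params(), econ_settings(), "ehmd")$deaths     # 135.88
run_arm <- function(clinical, settings = econ_settings(),
                    arm = c("usual", "ehmd"),
                    cp_or_method = c("risk_multiplier", "odds")) {
  arm <- match.arg(arm)
  cp_or_method <- match.arg(cp_or_method)
  stopifnot(inherits(clinical, "ehmd_clinical"),
            inherits(settings, "ehmd_settings"))
  validate_clinical_params(clinical)
  n <- settings$cohort_size
  p <- arm_probabilities(clinical, arm)

  deaths <- n * p$death
  survivors <- n - deaths

  # survivor event mix (events independent of survival)
  p_nec <- p$nec
  p_sep <- p$sepsis
  cp_mix <- p_nec * cp_risk_after_nec(clinical$p_cp_base,
                                      clinical$or_cp_nec, cp_or_method) +
    (1 - p_nec) * clinical$p_cp_base
  iq_mix <- p_nec * clinical$iq_loss_nec +
    (1 - p_nec) * p_sep * clinical$iq_loss_sepsis

  structure(list(
    arm = arm,
    cohort_size = n,
    deaths = deaths,
    survivors = survivors,
    nec_total = n * p$nec,
    nec_medical = n * p$nec_medical,
    nec_surgical = n * p$nec_surgical,
    sepsis = n * p$sepsis,
    nec_and_sepsis = n * p$nec * p$sepsis,
    bpd = survivors * p$bpd,
    rop = survivors * p$rop,
    cp = survivors * cp_mix,
    sbs = n * p$nec_surgical * clinical$p_sbs_given_surgical_nec,
    iq_points_lost_total = survivors * iq_mix
  ), class = "ehmd_arm")
}

arm_event_fields <- c("deaths", "survivors", "nec_total", "nec_medical",
                      "nec_surgical", "sepsis", "nec_and_sepsis", "bpd",
                      "rop", "cp", "sbs", "iq_points_lost_total")

#' Incremental events between the two diet arms
#'
#' Element-wise EHMD-minus-usual-care differences in expected event counts.
#' Full precision is kept internally; the reporting layer
#' ([report_bundle()], [summary.ehmd_model()]) rounds half-to-even.
#'
#' @param ehmd,usual \code{"ehmd_arm"} objects evaluated at the same cohort
#'   size.
#' @return Object of class \code{"ehmd_incremental"}: the per-event
#'   differences plus the two arm results (\code{$ehmd}, \code{$usual}).
#' @export
incremental_events <- function(ehmd, usual) {
  stopifnot(inherits(ehmd, "ehmd_arm"), inherits(usual, "ehmd_arm"))
  if (!isTRUE(all.equal(ehmd$cohort_size, usual$cohort_size)))
    stop("arms were evaluated at different cohort sizes (",
         ehmd$cohort_size, " vs ", usual$cohort_size, ")", call. = FALSE)
  diff <- lapply(arm_event_fields, function(f) ehmd[[f]] - usual[[f]])
  names(diff) <- arm_event_fields
  structure(c(diff, list(cohort_size = usual$cohort_size,
                         ehmd = ehmd, usual = usual)),
            class = "ehmd_incremental")
}

#' @export
print.ehmd_arm <- function(x, ...) {
  cat("Cohort decision-tree arm: ",
      if (x$arm == "ehmd") "exclusive human milk diet" else
        "usual practice of care",
      " (n = ", format(x$cohort_size), ")\n", sep = "")
  v <- unlist(x[arm_event_fields])
  print(round(v, 2))
  invisible(x)
}

#' @export
print.ehmd_incremental <- function(x, ...) {
  cat("Incremental events (EHMD - usual care) per",
      format(x$cohort_size), "infants:\n")
  v <- unlist(x[arm_event_fields])
  print(round(v))
  invisible(x)
}

#' Convert arm or incremental results to a data frame
#'
#' One row per event category, with stable labels matching the published
#' clinical-results table.
#'
#' @param x An \code{"ehmd_arm"} or \code{"ehmd_incremental"} object.
#' @param row.names,optional Ignored (base-generic compatibility).
#' @param ... Ignored.
#' @return A data frame with columns \code{event} and \code{count} (arm) or
#'   \code{event}, \code{ehmd}, \code{usual}, \code{incremental}
#'   (incremental results).
#' @export
as.data.frame.ehmd_incremental <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  data.frame(
    event = event_labels()[arm_event_fields],
    ehmd = unlist(x$ehmd[arm_event_fields]),
    usual = unlist(x$usual[arm_event_fields]),
    incremental = unlist(x[arm_event_fields]),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' @rdname as.data.frame.ehmd_incremental
#' @export
as.data.frame.ehmd_arm <- function(x, row.names = NULL, optional = FALSE,
                                   ...) {
  data.frame(event = event_labels()[arm_event_fields],
             count = unlist(x[arm_event_fields]),
             row.names = NULL, stringsAsFactors = FALSE)
}

event_labels <- function() {
  c(deaths = "Deaths (initial hospital stay)",
    survivors = "Survivors",
    nec_total = "Cases of NEC",
    nec_medical = "NEC, medically treated",
    nec_surgical = "NEC, surgically treated",
    sepsis = "Cases of late onset sepsis",
    nec_and_sepsis = "NEC and late onset sepsis",
    bpd = "Cases of bronchopulmonary dysplasia",
    rop = "Cases of retinopathy of prematurity",
    cp = "Cases of cerebral palsy",
    sbs = "Cases of short bowel syndrome",
    iq_points_lost_total = "IQ points lost (total)")
}
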