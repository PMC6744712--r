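# Random but internally valid parameter sets (for probabilistic sensitivity
# analysis and property tests) and the individual-level microsimulation that
# validates the expected-value engine.

prob_fields <- c("p_nec_usual", "frac_nec_surgical_usual", "p_sepsis_usual",
                 "p_death_usual", "p_bpd_usual", "p_rop_usual",
                 "p_sbs_given_surgical_nec", "p_cp_base")
rr_fields <- c("rr_nec", "rr_sepsis", "rr_death", "rr_bpd", "rr_rop",
               "rr_nec_surgical", "or_cp_nec")
cost_draw_fields <- c("vol_mother_ehmd_ml", "vol_donor_ehmd_ml",
                      "vol_mother_usual_ml", "vol_formula_usual_ml",
                      "price_fortifier_vial", "price_donor_milk_per_l",
                      "cost_diet_usual", "cost_baseline_stay",
                      "cost_nec_surgical", "cost_nec_medical", "cost_sepsis",
                      "cost_bpd", "cost_rop", "cost_cp_lifetime_payer")

#' Parameter distributions for probabilistic sensitivity analysis
#'
#' Specifies one distribution per model parameter, centred on a base
#' parameter set: Beta for probabilities (mean and concentration
#' \eqn{\kappa}, i.e. shapes \eqn{m\kappa} and \eqn{(1-m)\kappa}),
#' mean-preserving log-normal for relative risks and the CP odds ratio
#' (log-sd \code{rr_sdlog}), and Gamma for costs and volumes (mean and
#' coefficient of variation \code{cost_cv}). The source analysis is a
#' deterministic scenario study and prints no uncertainty intervals, so the
#' default spreads are conventional parameter-uncertainty choices, not
#' literature-calibrated ones.
#'
#' Degenerate limits are supported: \code{concentration = Inf},
#' \code{rr_sdlog = 0} or \code{cost_cv = 0} fix draws at the base values.
#'
#' @param clinical,costs Base parameter sets the distributions are centred
#'   on.
#' @param concentration Beta concentration for probability parameters.
#' @param rr_sdlog Log-scale standard deviation for relative risks.
#' @param cost_cv Coefficient of variation for cost and volume parameters.
#' @param seed Integer seed controlling [draw_params()].
#' @return Object of class \code{"ehmd_dists"}.
#' @export
param_distributions <- function(clinical = clinical_params(),
                                costs = cost_params(),
                                concentration = 100,
                                rr_sdlog = 0.1,
                                cost_cv = 0.2,
                                seed = 1L) {
  if (!is.numeric(concentration) || concentration <= 0)
    stop("'concentration' must be > 0 (Inf for degenerate draws)",
         call. = FALSE)
  if (!is.numeric(rr_sdlog) || rr_sdlog < 0 || !is.finite(rr_sdlog))
    stop("'rr_sdlog' must be a finite number >= 0", call. = FALSE)
  if (!is.numeric(cost_cv) || cost_cv < 0 || !is.finite(cost_cv))
    stop("'cost_cv' must be a finite number >= 0", call. = FALSE)
  cl <- unclass(clinical)
  for (f in prob_fields)
    if (cl[[f]] < 0 || cl[[f]] > 1)
      stop("Beta mean for '", f, "' is outside [0, 1]", call. = FALSE)
  structure(list(clinical = clinical, costs = costs,
                 concentration = concentration, rr_sdlog = rr_sdlog,
                 cost_cv = cost_cv, seed = as.integer(seed)),
            class = "ehmd_dists")
}

draw_beta <- function(n, mean, concentration) {
  if (!is.finite(concentration) || mean %in% c(0, 1)) return(rep(mean, n))
  stats::rbeta(n, mean * concentration, (1 - mean) * concentration)
}

draw_lnorm <- function(n, mean, sdlog) {
  if (sdlog == 0 || mean == 0) return(rep(mean, n))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

draw_gamma <- function(n, mean, cv) {
  if (cv == 0 || mean == 0) return(rep(mean, n))
  shape <- 1 / cv^2
  stats::rgamma(n, shape = shape, rate = shape / mean)
}

#' Draw validated random parameter sets
#'
#' Draws \code{n} parameter sets from a [param_distributions()]
#' specification. Draws that would violate the joint validity constraints
#' (a relative risk pushing its probability above 1, or surgical NEC
#' exceeding total NEC in the EHMD arm) are clamped into range rather than
#' rejected, so exactly \code{n} sets are returned; the number of clamped
#' values is recorded in the \code{"clamp_count"} attribute so misspecified
#' distributions surface rather than pass silently. Identical seeds give
#' identical sequences.
#'
#' @param dists An \code{"ehmd_dists"} specification.
#' @param n Number of parameter sets (>= 1).
#' @return List of \code{n} elements, each a list with validated
#'   \code{clinical} and \code{costs} containers; attribute
#'   \code{"clamp_count"}.
#' @export
#' @examples
#' d <- param_distributions(seed = 42)
#' draws <- draw_params(d, 3)
#' draws[[1]]$clinical$p_nec_usual
draw_params <- function(dists, n) {
  stopifnot(inherits(dists, "ehmd_dists"), n >= 1)
  set.seed(dists$seed)
  cl <- unclass(dists$clinical)
  co <- unclass(dists$costs)
  mat <- list()
  for (f in prob_fields)
    mat[[f]] <- draw_beta(n, cl[[f]], dists$concentration)
  for (f in rr_fields)
    mat[[f]] <- draw_lnorm(n, cl[[f]], dists$rr_sdlog)
  for (f in cost_draw_fields)
    mat[[f]] <- draw_gamma(n, co[[f]], dists$cost_cv)

  clamps <- 0L
  clamp <- function(x, hi) {
    over <- x > hi
    clamps <<- clamps + sum(over)
    pmin(x, hi)
  }
  # joint validity: rr * baseline <= 1; EHMD surgical NEC <= EHMD total NEC
  rr_pairs <- list(rr_nec = "p_nec_usual", rr_sepsis = "p_sepsis_usual",
                   rr_death = "p_death_usual", rr_bpd = "p_bpd_usual",
                   rr_rop = "p_rop_usual")
  for (rr in names(rr_pairs))
    mat[[rr]] <- clamp(mat[[rr]], 1 / pmax(mat[[rr_pairs[[rr]]]], 1e-12))
  mat$rr_nec_surgical <- clamp(
    mat$rr_nec_surgical,
    mat$rr_nec / pmax(mat$frac_nec_surgical_usual, 1e-12))

  out <- lapply(seq_len(n), function(i) {
    cl_i <- cl
    for (f in c(prob_fields, rr_fields)) cl_i[[f]] <- mat[[f]][i]
    co_i <- co
    for (f in cost_draw_fields) co_i[[f]] <- mat[[f]][i]
    list(clinical = do.call(clinical_params, cl_i),
         costs = do.call(cost_params, co_i))
  })
  attr(out, "clamp_count") <- clamps
  out
}

#' Probabilistic sensitivity analysis
#'
#' Pushes random parameter sets through the deterministic model and
#' collects the incremental outcomes, one row per draw.
#'
#' @param dists An \code{"ehmd_dists"} specification (carries the seed).
#' @param n Number of draws.
#' @param settings An [econ_settings()] object.
#' @param cp_or_method See [cp_probability()].
#' @return Data frame with one row per draw: the drawn parameter values,
#'   \code{incremental_cost_total} and incremental event counts. Suitable
#'   for direct [utils::write.csv()].
#' @export
run_psa <- function(dists, n, settings = econ_settings(),
                    cp_or_method = c("risk_multiplier", "odds")) {
  cp_or_method <- match.arg(cp_or_method)
  draws <- draw_params(dists, n)
  rows <- lapply(draws, function(d) {
    m <- ehmd_model(d$clinical, d$costs, settings,
                    cp_or_method = cp_or_method)
    pars <- c(unlist(unclass(d$clinical)),
              unlist(unclass(d$costs)[cost_draw_fields]))
    ev <- m$events
    c(pars, incremental_cost_total = m$incremental_costs$total,
      inc_deaths = ev$deaths, inc_nec = ev$nec_total,
      inc_sepsis = ev$sepsis, inc_bpd = ev$bpd, inc_rop = ev$rop,
      inc_cp = ev$cp, inc_sbs = ev$sbs)
  })
  out <- as.data.frame(do.call(rbind, rows))
  attr(out, "clamp_count") <- attr(draws, "clamp_count")
  out
}

#' Individual-level microsimulation of the decision tree
#'
#' Samples \code{n} infants per arm with Bernoulli draws following exactly
#' the structural assumptions of the expected-value engine: death, NEC
#' (with the surgical split), and late-onset sepsis are drawn independently
#' for every infant; BPD, RoP and CP are drawn for survivors only, with CP
#' risk depending on the infant's NEC/sepsis history; SBS follows surgical
#' NEC. Per-infant costs are accumulated the same way as [arm_costs()].
#'
#' This is the validation oracle for [run_arm()]: with large \code{n} every
#' simulated count converges to the deterministic expectation at the
#' Monte-Carlo rate. Each arm consumes an independent RNG stream derived
#' from \code{seed}, so the arms are independently sampled.
#'
#' @param clinical,costs Parameter containers.
#' @param n Simulated infants per arm.
#' @param seed Integer seed.
#' @param settings An [econ_settings()] object; counts are rescaled to its
#'   \code{cohort_size}.
#' @param cp_or_method See [cp_probability()].
#' @return List with elements \code{usual} and \code{ehmd}, each containing
#'   \code{arm} (an \code{"ehmd_arm"} of counts rescaled to the cohort
#'   size), \code{costs} (an \code{"ehmd_cost_breakdown"} of mean per-infant
#'   costs) and \code{n}; plus \code{n} and \code{seed} at the top level.
#' @export
#' @examples
#' ms <- microsimulate(clinical_params(), cost_params(), n = 5000, seed = 7)
#' ms$usual$arm$deaths   # close to 172
microsimulate <- function(clinical, costs, n, seed,
                          settings = econ_settings(),
                          cp_or_method = c("risk_multiplier", "odds")) {
  stopifnot(inherits(clinical, "ehmd_clinical"),
            inherits(costs, "ehmd_costs"), n >= 1)
  cp_or_method <- match.arg(cp_or_method)
  seed <- as.integer(seed)
  arms <- list()
  offsets <- c(usual = 0L, ehmd = 1L)
  for (arm in c("usual", "ehmd")) {
    set.seed((seed + offsets[[arm]]) %% .Machine$integer.max)
    arms[[arm]] <- microsimulate_arm(clinical, costs, n, arm, settings,
                                     cp_or_method)
  }
  c(arms, list(n = n, seed = seed))
}

microsimulate_arm <- function(clinical, costs, n, arm, settings,
                              cp_or_method) {
  p <- arm_probabilities(clinical, arm)
  rb <- function(prob) stats::rbinom(n, 1L, prob) == 1L

  dead <- rb(p$death)
  nec <- rb(p$nec)
  p_surg_given_nec <- if (p$nec > 0) p$nec_surgical / p$nec else 0
  surgical <- nec & rb(p_surg_given_nec)
  sepsis <- rb(p$sepsis)
  alive <- !dead
  bpd <- alive & rb(p$bpd)
  rop <- alive & rb(p$rop)
  p_cp <- cp_probability(clinical$p_cp_base, clinical$or_cp_nec,
                         has_nec = nec, has_sepsis = sepsis,
                         or_method = cp_or_method)
  cp <- alive & (stats::runif(n) < p_cp)
  sbs <- surgical & rb(clinical$p_sbs_given_surgical_nec)
  iq <- ifelse(alive,
               iq_loss(nec, sepsis, clinical$iq_loss_nec,
                       clinical$iq_loss_sepsis), 0)

  scale <- settings$cohort_size / n
  arm_res <- structure(list(
    arm = arm, cohort_size = settings$cohort_size,
    deaths = sum(dead) * scale, survivors = sum(alive) * scale,
    nec_total = sum(nec) * scale,
    nec_medical = sum(nec & !surgical) * scale,
    nec_surgical = sum(surgical) * scale,
    sepsis = sum(sepsis) * scale,
    nec_and_sepsis = sum(nec & sepsis) * scale,
    bpd = sum(bpd) * scale, rop = sum(rop) * scale, cp = sum(cp) * scale,
    sbs = sum(sbs) * scale,
    iq_points_lost_total = sum(iq) * scale
  ), class = "ehmd_arm")
  list(arm = arm_res, costs = arm_costs(arm_res, costs), n = n)
}
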