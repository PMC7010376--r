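#' Default prior specification
#'
#' Deliberately low-information priors for every parameter of the msIPM:
#' flat U(0,1) for all probabilities (combined juvenile survival,
#' pre-recruitment fidelities, band retention, breeding probability,
#' area-specific chick resight probabilities, immature survival); U(-5,5)
#' for logistic-regression intercepts, the trap-dependence constants and
#' the reporting-trend coefficients; N(0, 10^4) (variance) for the adult
#' baseline resight probabilities on the logit scale; U(0,3) for the
#' random-effect SDs; and U(0, 15000) for the puffin observation SD,
#' U(0, 5000) for the other species (puffin counts are an order of
#' magnitude larger). Posterior mass piling up against a uniform bound
#' should be checked after fitting.
#'
#' @param config a [study_config()].
#' @return object of class `"msipm_priors"`.
#' @export
default_priors <- function(config) {
  structure(list(
    prob_unit = c("phi_c", "F5", "F6", "psi", "B", "p_area", "s1", "s2", "s35"),
    intercept_bounds = c(-5, 5),
    pstar_logit_sd = 100,
    sd_bounds = c(0, 3),
    sigma_x_upper = c(R = 5000, P = 15000, M = 5000)
  ), class = "msipm_priors")
}

dunif_log <- function(x, lo, hi) {
  ifelse(x >= lo & x <= hi, -log(hi - lo), -Inf)
}

#' Prior log-density of a parameter state
#'
#' Sum of the log prior densities of every top-level parameter in the
#' state under a prior specification. Random effects and latent abundances
#' are auxiliary variables: their densities enter the joint posterior
#' through [re_logpdf()] and the system-process/initialization components,
#' not here.
#'
#' @param state a [parameter_state()].
#' @param priors a [default_priors()] specification.
#' @param config a [study_config()].
#' @return log prior density (`-Inf` outside the support).
#' @export
prior_logpdf <- function(state, priors, config) {
  b <- priors$intercept_bounds
  lp <- 0
  # intercepts, trap dependence, reporting trend
  lp <- lp + sum(dunif_log(state$sync_rho$beta, b[1], b[2]))
  lp <- lp + sum(dunif_log(state$sync_phi$beta, b[1], b[2]))
  lp <- lp + sum(dunif_log(state$a, b[1], b[2]))
  lp <- lp + dunif_log(state$mrr$alpha0, b[1], b[2])
  lp <- lp + dunif_log(state$mrr$alpha1, b[1], b[2])
  # random-effect SDs
  sb <- priors$sd_bounds
  lp <- lp + dunif_log(state$sync_rho$sigma_delta, sb[1], sb[2])
  lp <- lp + dunif_log(state$sync_phi$sigma_delta, sb[1], sb[2])
  lp <- lp + sum(dunif_log(state$sync_rho$sigma_eps, sb[1], sb[2]))
  lp <- lp + sum(dunif_log(state$sync_phi$sigma_eps, sb[1], sb[2]))
  # unit-interval probabilities
  unit <- c(state$phi_c, state$B, state$mrr$s1, state$mrr$s2, state$mrr$s35,
            state$mrr$F5, state$mrr$F6, state$mrr$psi,
            unlist(state$mrr$p, use.names = FALSE))
  lp <- lp + sum(dunif_log(unit, 0, 1))
  # adult baseline resight probabilities: normal on the logit scale
  lp <- lp + sum(stats::dnorm(stats::qlogis(state$p_star), 0,
                              priors$pstar_logit_sd, log = TRUE))
  # observation SDs
  up <- priors$sigma_x_upper
  lp <- lp + sum(dunif_log(state$sigma_x, 0, up[names(state$sigma_x)]))
  lp
}
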