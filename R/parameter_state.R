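#' Full parameter state of the msIPM
#'
#' One point in the joint parameter space: the two synchrony blocks
#' (productivity over `1..T`, adult survival over `1..T-1`), the adult
#' mark-resight parameters (baseline resight probabilities and
#' trap-dependence constants), observation SDs, combined juvenile survival
#' for razorbill and puffin, the murre breeding-probability series, the
#' structural chick-MRR parameters, and the latent population trajectories.
#' Murre adult survival appears once — in the survival synchrony block —
#' and is consumed by the adult CJS, the chick MRR and the murre population
#' model alike.
#'
#' @param sync_rho,sync_phi [synchrony_block()]s for productivity
#'   (length `T`) and adult survival (length `T - 1`).
#' @param p_star `(T-1) x 3` matrix of baseline adult resight
#'   probabilities (columns R, P, M).
#' @param a named trap-dependence constants (R, P, M).
#' @param sigma_x named observation SDs (R, P, M).
#' @param phi_c named combined juvenile survival (R, P).
#' @param B murre breeding-probability series, length `T`.
#' @param mrr list of structural chick-MRR parameters: `s1` (length
#'   `T - 1`), `s2`, `s35`, `F5`, `F6`, `psi`, `alpha0`, `alpha1` and the
#'   nested resight-probability list `p` (see [mrr_structural_params()];
#'   `s_a` is not stored here — it is derived from `sync_phi`).
#' @param latent list of [latent_population()]s named R, P, M.
#' @param config a [study_config()].
#' @return object of class `"msipm_state"`.
#' @export
parameter_state <- function(sync_rho, sync_phi, p_star, a, sigma_x, phi_c,
                            B, mrr, latent, config) {
  Tn <- config$n_years
  stopifnot(length(sync_rho$delta) == Tn,
            length(sync_phi$delta) == Tn - 1L,
            is.matrix(p_star), nrow(p_star) == Tn - 1L, ncol(p_star) == 3L,
            length(a) == 3L, length(sigma_x) == 3L, length(phi_c) == 2L,
            length(B) == Tn, length(mrr$s1) == Tn - 1L,
            all(c("R", "P", "M") %in% names(latent)))
  colnames(p_star) <- c("R", "P", "M")
  names(a) <- c("R", "P", "M")
  names(sigma_x) <- c("R", "P", "M")
  names(phi_c) <- c("R", "P")
  for (sp in c("R", "P", "M")) {
    stopifnot(latent[[sp]]$d == config$d[[sp]],
              length(latent[[sp]]$N) == Tn)
  }
  structure(list(sync_rho = sync_rho, sync_phi = sync_phi,
                 p_star = p_star, a = a, sigma_x = sigma_x, phi_c = phi_c,
                 B = B, mrr = mrr, latent = latent),
            class = "msipm_state")
}

# structural MRR parameter object with murre adult survival taken from the
# survival synchrony block (the single shared parameter)
state_mrr_structural <- function(state, config) {
  mrr_structural_params(
    s1 = state$mrr$s1, s2 = state$mrr$s2, s35 = state$mrr$s35,
    s_a = assemble_rate_series(state$sync_phi, "M"),
    F5 = state$mrr$F5, F6 = state$mrr$F6, psi = state$mrr$psi,
    alpha0 = state$mrr$alpha0, alpha1 = state$mrr$alpha1,
    p = state$mrr$p, config = config)
}

#' Component-wise log-posterior terms
#'
#' Evaluates every likelihood/prior component of the joint posterior at a
#' parameter state: breeding success, non-breeding, adult CJS, chick MRR,
#' system process, count observation and initialization priors per species,
#' the random-effect densities of the two synchrony blocks, and the
#' parameter priors. The datasets are modelled as independent, so the joint
#' log-posterior is simply their sum. Missing data components (e.g. an
#' all-zero MRR array) contribute 0.
#'
#' @param state a [parameter_state()].
#' @param bundle a [dataset_bundle()].
#' @param priors a [default_priors()] specification.
#' @param config a [study_config()].
#' @return named numeric vector of component log-densities.
#' @export
msipm_components <- function(state, bundle, priors, config) {
  out <- c()
  rho <- sapply(c("R", "P", "M"), function(sp)
    assemble_rate_series(state$sync_rho, sp))
  s_a <- sapply(c("R", "P", "M"), function(sp)
    assemble_rate_series(state$sync_phi, sp))
  for (sp in c("R", "P", "M")) {
    out[paste0("bs_", sp)] <- bs_loglik(bundle$bs[[sp]], rho[, sp])
    out[paste0("cjs_", sp)] <-
      if (is.null(bundle$adults[[sp]])) 0 else
        cjs_loglik(bundle$adults[[sp]], s_a[, sp], state$p_star[, sp],
                   state$a[[sp]])
  }
  out["nb_M"] <- nb_loglik(bundle$nb, state$B)
  out["mrr_M"] <- mrr_loglik(bundle$mrr$A, bundle$mrr$B,
                             state_mrr_structural(state, config), config)
  for (sp in c("R", "P")) {
    out[paste0("sys_", sp)] <-
      rp_system_loglik(state$latent[[sp]], rho[, sp], s_a[, sp],
                       state$phi_c[[sp]])
  }
  out["sys_M"] <- murre_system_loglik(
    state$latent$M, state$B, rho[, "M"], state$mrr$s1, state$mrr$s2,
    state$mrr$s35, state$mrr$F5, state$mrr$F6, s_a[, "M"])
  for (sp in c("R", "P", "M")) {
    d <- config$d[[sp]]
    out[paste0("obs_", sp)] <-
      observation_loglik(bundle$counts[, sp], state$latent[[sp]],
                         state$sigma_x[[sp]], d)
    out[paste0("init_", sp)] <-
      init_prior_logpdf(state$latent[[sp]],
                        init_prior_means(bundle$counts[, sp], d),
                        state$sigma_x[[sp]])
  }
  out["re_rho"] <- re_logpdf(state$sync_rho)
  out["re_phi"] <- re_logpdf(state$sync_phi)
  out["prior"] <- prior_logpdf(state, priors, config)
  out
}

#' Joint log-posterior density
#'
#' Sum of all components returned by [msipm_components()]. `-Inf` signals a
#' state outside the support (an impossible latent configuration, a
#' parameter outside its prior bounds, or data inconsistent with a
#' structural zero); in-support states never raise an error.
#'
#' @inheritParams msipm_components
#' @return a single numeric value.
#' @export
joint_logposterior <- function(state, bundle, priors, config) {
  comp <- msipm_components(state, bundle, priors, config)
  if (any(is.na(comp))) return(-Inf)
  sum(comp)
}
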