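#' Scenario configuration for the synthetic-data generator
#'
#' Defines a complete simulated study: the temporal frame, the generating
#' parameter values and the monitoring/marking effort. The defaults are a
#' reduced-scale community — 15 occasions and roughly a quarter of the
#' original field effort (3/10/15 adults newly marked per year for
#' razorbill/puffin/murre, preserving the 5:1 and 1.5:1 banded-murre
#' ratios; 50 and 24 chicks banded per year in areas A and B) — with
#' generating values matching the posterior medians estimated from the
#' full-scale study for the structural parameters, and random-effect SDs
#' set so the true synchrony index is 0.8 for every species and both rates
#' (`sigma_eps = sigma_delta / 2`). Puffin counts are restricted to seven
#' non-consecutive occasions, mirroring their sparse census.
#'
#' @param config a [study_config()]; the default is the reduced frame.
#' @param beta_rho,beta_phi species intercepts (logit productivity, logit
#'   adult survival).
#' @param sigma_delta_rho,sigma_eps_rho,sigma_delta_phi,sigma_eps_phi
#'   random-effect SDs.
#' @param trap_a trap-dependence constants.
#' @param p_star_mean baseline adult resight probability (constant over
#'   years in the generator).
#' @param sigma_x observation SDs on the count scale.
#' @param phi_c combined juvenile survival (razorbill, puffin).
#' @param B_mean,B_sd_logit mean and logit-scale SD of the yearly murre
#'   breeding probability.
#' @param s1_mean,s1_sd_logit mean and logit-scale SD of yearly first-year
#'   survival.
#' @param s2,s35,F5,F6,psi,alpha0,alpha1 structural chick-MRR parameters.
#' @param p_class per-area age-class chick resight probabilities (constant
#'   within each configured window).
#' @param n_marked_adults adults newly marked per species per year.
#' @param n_chicks chicks banded per area per banding year.
#' @param E_monitored monitored breeding pairs per species per year.
#' @param xi_monitored monitored murres (non-breeding check) per year.
#' @param init_N initial adult female abundance per species.
#' @return object of class `"msipm_scenario"`.
#' @export
scenario_config <- function(
    config = study_config(n_years = 15L, first_year = 1995L,
                          areaB_last_banding = 8L,
                          puffin_count_years = c(1L, 6L, 9L, 11L, 13L, 14L, 15L)),
    beta_rho = c(R = 0.689, P = 0.890, M = 1.002),
    beta_phi = c(R = 2.319, P = 2.436, M = 2.789),
    sigma_delta_rho = 0.357,
    sigma_eps_rho = c(R = 0.1785, P = 0.1785, M = 0.1785),
    sigma_delta_phi = 0.493,
    sigma_eps_phi = c(R = 0.2465, P = 0.2465, M = 0.2465),
    trap_a = c(R = 1.826, P = 1.928, M = 3.240),
    p_star_mean = 0.6,
    sigma_x = c(R = 90, P = 1400, M = 375),
    phi_c = c(R = 0.501, P = 0.761),
    B_mean = 0.93, B_sd_logit = 0.3,
    s1_mean = 0.5, s1_sd_logit = 0.8,
    s2 = 0.763, s35 = 0.898, F5 = 0.865, F6 = 0.834, psi = 0.850,
    alpha0 = -3.084, alpha1 = -0.687,
    p_class = list(A = c(p2 = 0.25, p3 = 0.45, p45 = 0.60, pa = 0.65),
                   B = c(p2 = 0.12, p3 = 0.25, p45 = 0.35, pa = 0.40)),
    n_marked_adults = c(R = 3L, P = 10L, M = 15L),
    n_chicks = c(A = 50L, B = 24L),
    E_monitored = c(R = 34L, P = 40L, M = 207L),
    xi_monitored = 78L,
    init_N = c(R = 375L, P = 2850L, M = 3250L)) {
  structure(as.list(environment()), class = "msipm_scenario")
}

# draw the generating parameter state (without latents) for a scenario;
# uses the current RNG stream
simulate_parameters <- function(scenario) {
  cfg <- scenario$config
  Tn <- cfg$n_years
  sync_rho <- synchrony_block(
    beta = scenario$beta_rho,
    delta = stats::rnorm(Tn, 0, scenario$sigma_delta_rho),
    eps = sapply(c("R", "P", "M"), function(sp)
      stats::rnorm(Tn, 0, scenario$sigma_eps_rho[[sp]])),
    sigma_delta = scenario$sigma_delta_rho,
    sigma_eps = scenario$sigma_eps_rho)
  sync_phi <- synchrony_block(
    beta = scenario$beta_phi,
    delta = stats::rnorm(Tn - 1L, 0, scenario$sigma_delta_phi),
    eps = sapply(c("R", "P", "M"), function(sp)
      stats::rnorm(Tn - 1L, 0, scenario$sigma_eps_phi[[sp]])),
    sigma_delta = scenario$sigma_delta_phi,
    sigma_eps = scenario$sigma_eps_phi)
  p_area <- lapply(c(A = "A", B = "B"), function(ar)
    lapply(stats::setNames(nm = c("p2", "p3", "p45", "pa")), function(cl)
      rep(scenario$p_class[[ar]][[cl]], length(cfg$windows[[ar]][[cl]]))))
  mrr <- list(
    s1 = stats::plogis(stats::qlogis(scenario$s1_mean) +
                         stats::rnorm(Tn - 1L, 0, scenario$s1_sd_logit)),
    s2 = scenario$s2, s35 = scenario$s35,
    F5 = scenario$F5, F6 = scenario$F6, psi = scenario$psi,
    alpha0 = scenario$alpha0, alpha1 = scenario$alpha1, p = p_area)
  list(sync_rho = sync_rho, sync_phi = sync_phi,
       p_star = matrix(scenario$p_star_mean, Tn - 1L, 3L,
                       dimnames = list(NULL, c("R", "P", "M"))),
       a = scenario$trap_a, sigma_x = scenario$sigma_x,
       phi_c = scenario$phi_c,
       B = stats::plogis(stats::qlogis(scenario$B_mean) +
                           stats::rnorm(Tn, 0, scenario$B_sd_logit)),
       mrr = mrr)
}

#' Simulate latent population trajectories
#'
#' Draws the year random effects and yearly rates of a scenario, then
#' iterates the binomial system process forward from the configured initial
#' abundances: recruits are binomial on the breeders the appropriate number
#' of years earlier (with the combined-juvenile-survival rate for razorbill
#' and puffin, the full age-structured rate for murre) and survivors
#' binomial on last year's breeders. Extinction is permitted and flagged.
#'
#' @param scenario a [scenario_config()].
#' @param params optionally, a pre-drawn generating parameter set (as
#'   produced internally); drawn fresh when `NULL`.
#' @return list with the generating `params`, per-species
#'   [latent_population()]s (`latent`), the rate series `rho` and `s_a`
#'   (matrices, columns R, P, M), and an `extinct` flag per species.
#' @export
simulate_latents <- function(scenario, params = NULL) {
  cfg <- scenario$config
  Tn <- cfg$n_years
  if (is.null(params)) params <- simulate_parameters(scenario)
  rho <- sapply(c("R", "P", "M"), function(sp)
    assemble_rate_series(params$sync_rho, sp))
  s_a <- sapply(c("R", "P", "M"), function(sp)
    assemble_rate_series(params$sync_phi, sp))
  latent <- list()
  extinct <- c(R = FALSE, P = FALSE, M = FALSE)
  for (sp in c("R", "P", "M")) {
    d <- cfg$d[[sp]]
    N <- R <- S <- rep(NA_real_, Tn)
    N[seq_len(d)] <- scenario$init_N[[sp]]
    for (t in seq(d + 1L, Tn)) {
      tau <- if (sp == "M") {
        params$B[t - 6L] * rho[t - 6L, sp] * 0.5 * params$mrr$s1[t - 6L] *
          params$mrr$s2 * params$mrr$s35^3 * params$mrr$F5 * params$mrr$F6
      } else {
        rho[t - d, sp] * params$phi_c[[sp]] / 2
      }
      R[t] <- stats::rbinom(1L, N[t - d], tau * s_a[t - 1L, sp])
      S[t] <- stats::rbinom(1L, N[t - 1L], s_a[t - 1L, sp])
      N[t] <- R[t] + S[t]
    }
    if (any(N == 0)) extinct[sp] <- TRUE
    latent[[sp]] <- latent_population(N, R, S, d)
  }
  list(params = params, latent = latent, rho = rho, s_a = s_a,
       extinct = extinct)
}

#' Simulate the observation-level datasets
#'
#' Counts are the latent abundances plus normal observation noise, rounded
#' to the nearest integer and floored at zero (the fitted observation model
#' is an untruncated normal; the mismatch is negligible at realistic
#' signal-to-noise ratios and acts as a mild robustness probe). Puffin
#' counts are masked to the configured sparse census occasions. Fledged
#' chicks and breeding murres are binomial draws from the monitoring
#' efforts at the true yearly rates.
#'
#' @param truth a [simulate_latents()] result.
#' @param scenario a [scenario_config()].
#' @return list with `counts` (matrix `T x 3`), `bs` (list of
#'   [breeding_success_series()]) and `nb` (a [nonbreeding_series()]).
#' @export
simulate_observations <- function(truth, scenario) {
  cfg <- scenario$config
  Tn <- cfg$n_years
  counts <- matrix(NA_real_, Tn, 3L, dimnames = list(NULL, c("R", "P", "M")))
  bs <- list()
  for (sp in c("R", "P", "M")) {
    x <- pmax(0, round(truth$latent[[sp]]$N +
                         stats::rnorm(Tn, 0, scenario$sigma_x[[sp]])))
    if (sp == "P") x[setdiff(seq_len(Tn), cfg$puffin_count_years)] <- NA
    counts[, sp] <- x
    E <- rep(scenario$E_monitored[[sp]], Tn)
    bs[[sp]] <- breeding_success_series(E, stats::rbinom(Tn, E, truth$rho[, sp]))
  }
  xi_m <- rep(scenario$xi_monitored, Tn)
  nb <- nonbreeding_series(xi_m, stats::rbinom(Tn, xi_m, truth$params$B))
  list(counts = counts, bs = bs, nb = nb)
}

#' Simulate marked individuals
#'
#' Adults: cohorts marked each year survive with the true adult survival
#' and are resighted with the trap-dependent probabilities (the marking
#' occasion counts as "seen" for the one-year lag); adults never emigrate.
#' Chicks: each banded bird ages through the age-structured survival rates;
#' at each transition it may permanently emigrate (fidelity `F5`/`F6`
#' before recruitment) or, once adult, lose its readable band / move out of
#' view (rate `1 - psi` per year) — both absorbing into the unobservable
#' state; residents are resighted with the area- and age-class-specific
#' probabilities (zero at age 1 and outside the configured windows); dead
#' birds in either state are reported with the declining reporting
#' probability of their last year alive. Area B banding stops at its
#' configured cutoff.
#'
#' @param truth a [simulate_latents()] result.
#' @param scenario a [scenario_config()].
#' @return list with `adults` (list of [adult_histories()]), `chicks`
#'   (data frame of encounter records for [build_mrr_sufficient_stats()])
#'   and `fates` (per-chick truth: death and emigration occasions).
#' @export
simulate_marked_individuals <- function(truth, scenario) {
  cfg <- scenario$config
  Tn <- cfg$n_years
  adults <- list()
  for (sp in c("R", "P", "M")) {
    n_per_year <- scenario$n_marked_adults[[sp]]
    pr <- effective_resight_probs(truth$params$p_star[, sp],
                                  truth$params$a[[sp]])
    rows <- list()
    for (f in seq_len(Tn - 1L)) {
      for (k in seq_len(n_per_year)) {
        w <- integer(Tn)
        w[f] <- 1L
        seen_prev <- TRUE
        for (t in seq(f + 1L, Tn)) {
          if (stats::runif(1) > truth$s_a[t - 1L, sp]) break
          pd <- if (seen_prev) pr$p[t - 1L] else pr$p_bar[t - 1L]
          w[t] <- as.integer(stats::runif(1) < pd)
          seen_prev <- w[t] == 1L
        }
        rows[[length(rows) + 1L]] <- w
      }
    }
    adults[[sp]] <- adult_histories(do.call(rbind, rows))
  }

  structural <- mrr_structural_params(
    s1 = truth$params$mrr$s1, s2 = truth$params$mrr$s2,
    s35 = truth$params$mrr$s35, s_a = truth$s_a[, "M"],
    F5 = truth$params$mrr$F5, F6 = truth$params$mrr$F6,
    psi = truth$params$mrr$psi, alpha0 = truth$params$mrr$alpha0,
    alpha1 = truth$params$mrr$alpha1, p = truth$params$mrr$p, config = cfg)
  tabs <- lapply(c(A = "A", B = "B"), function(ar)
    assemble_age_year_params(structural, cfg, ar))
  recs <- list()
  fates <- list()
  for (area in c("A", "B")) {
    tb <- tabs[[area]]
    for (t0 in cfg$banding_years[[area]]) {
      for (k in seq_len(scenario$n_chicks[[area]])) {
        id <- sprintf("%s%02d_%03d", area, t0, k)
        a <- 1L; t <- t0
        resident <- TRUE
        resights <- integer(0)
        recovery <- NA_integer_
        death <- NA_integer_
        emig <- NA_integer_
        while (t < Tn && a < cfg$max_age) {
          if (stats::runif(1) > tb$phi[a, t]) {
            death <- t  # died aged a; report falls at t + 1
            if (stats::runif(1) < tb$lambda[t]) recovery <- t + 1L
            break
          }
          if (resident && stats::runif(1) > tb$F[a]) {
            resident <- FALSE
            emig <- t + 1L
          }
          a <- a + 1L; t <- t + 1L
          if (resident && stats::runif(1) < tb$p[a, t]) {
            resights <- c(resights, t)
          }
        }
        recs[[length(recs) + 1L]] <- data.frame(
          id = id, area = area, band_occasion = t0,
          resight_occasions = paste(resights, collapse = ";"),
          recovery_occasion = recovery, stringsAsFactors = FALSE)
        fates[[length(fates) + 1L]] <- data.frame(
          id = id, area = area, band_occasion = t0,
          death_occasion = death, emigration_occasion = emig,
          stringsAsFactors = FALSE)
      }
    }
  }
  list(adults = adults, chicks = do.call(rbind, recs),
       fates = do.call(rbind, fates))
}

#' Simulate a complete dataset bundle with its generating truth
#'
#' Orchestrates [simulate_latents()], [simulate_observations()] and
#' [simulate_marked_individuals()] into a validated [dataset_bundle()]
#' plus a truth record holding the full generating [parameter_state()]
#' (including the latent trajectories) and the per-chick fates.
#'
#' @param scenario a [scenario_config()].
#' @param seed integer RNG seed.
#' @return list with elements `bundle` and `truth` (the truth holds
#'   `state`, `rho`, `s_a`, `fates`, `extinct`).
#' @export
simulate_bundle <- function(scenario = scenario_config(), seed = 1L) {
  set.seed(seed)
  cfg <- scenario$config
  truth <- simulate_latents(scenario)
  obs <- simulate_observations(truth, scenario)
  marked <- simulate_marked_individuals(truth, scenario)
  mrr <- build_mrr_sufficient_stats(marked$chicks, cfg)
  bundle <- dataset_bundle(obs$counts, obs$bs, obs$nb, marked$adults, mrr,
                           cfg, chick_records = marked$chicks)
  state <- parameter_state(
    sync_rho = truth$params$sync_rho, sync_phi = truth$params$sync_phi,
    p_star = truth$params$p_star, a = truth$params$a,
    sigma_x = truth$params$sigma_x, phi_c = truth$params$phi_c,
    B = truth$params$B, mrr = truth$params$mrr, latent = truth$latent,
    config = cfg)
  list(bundle = bundle,
       truth = list(state = state, rho = truth$rho, s_a = truth$s_a,
                    fates = marked$fates, extinct = truth$extinct,
                    seed = seed))
}
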