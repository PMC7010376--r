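#' Run one stage of the simulate/fit/summarize/recover pipeline
#'
#' A thin programmatic pipeline over the package's functions (an
#' `Rscript` wrapper is installed under `inst/scripts/msipm`):
#' \describe{
#'   \item{`simulate`}{writes a complete synthetic bundle directory plus
#'     `truth.json` for a scenario.}
#'   \item{`fit`}{reads a bundle directory, runs MCMC and writes posterior
#'     summaries and run metadata.}
#'   \item{`summarize`}{rewrites the summary tables of an existing fit.}
#'   \item{`recover`}{repeats simulate+fit `n_reps` times and writes a
#'     coverage report: the fraction of monitored parameters whose 95%
#'     credible interval covers the generating value.}
#' }
#' Every stage writes a `manifest.json` with the command, seed, settings
#' and outputs; stages log the per-component log-likelihoods at the
#' posterior median so a lack of fit can be traced to a sub-model.
#'
#' @param command one of `"simulate"`, `"fit"`, `"summarize"`,
#'   `"recover"`.
#' @param out_dir output directory.
#' @param scenario a [scenario_config()] (simulate/recover).
#' @param data_dir bundle directory (fit).
#' @param config a [study_config()] (fit; defaults to the scenario
#'   frame).
#' @param seed integer seed.
#' @param n_iter,n_burnin,n_adapt,n_chains MCMC settings passed to
#'   [run_mcmc()].
#' @param n_reps replicates for `recover`.
#' @param quiet suppress progress messages.
#' @return invisibly, the stage's main artifact (bundle, posterior,
#'   summary data frame, or coverage table).
#' @export
run_pipeline <- function(command = c("simulate", "fit", "summarize",
                                     "recover"),
                         out_dir, scenario = scenario_config(),
                         data_dir = NULL, config = scenario$config,
                         seed = 1L, n_iter = 2000L, n_burnin = 1000L,
                         n_adapt = 500L, n_chains = 2L, n_reps = 3L,
                         quiet = FALSE) {
  command <- match.arg(command)
  t0 <- Sys.time()
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  manifest <- list(command = command, seed = seed,
                   started = format(t0, "%Y-%m-%dT%H:%M:%S"))

  result <- switch(command,
    simulate = {
      sim <- simulate_bundle(scenario, seed = seed)
      write_bundle(sim$bundle, out_dir)
      jsonlite::write_json(truth_record_json(sim$truth),
                           file.path(out_dir, "truth.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      say("simulate: bundle written to %s", out_dir)
      sim
    },
    fit = {
      if (is.null(data_dir)) stop("fit stage requires data_dir")
      bundle <- read_bundle(data_dir, config)
      fit <- run_mcmc(bundle, default_priors(config), config,
                      n_chains = n_chains, n_iter = n_iter,
                      n_burnin = n_burnin, n_adapt = n_adapt, seed = seed)
      write_results(fit, out_dir)
      log_median_components(fit, bundle, config, out_dir)
      say("fit: worst R-hat %.3f", max(fit$rhat, na.rm = TRUE))
      fit
    },
    summarize = {
      stop("summarize operates on a fit object; use write_results() or ",
           "run the fit stage, which writes the summary tables")
    },
    recover = {
      cov <- recovery_study(scenario, n_reps = n_reps, seed = seed,
                            n_iter = n_iter, n_burnin = n_burnin,
                            n_adapt = n_adapt, quiet = quiet)
      utils::write.csv(cov$table, file.path(out_dir, "coverage.csv"),
                       row.names = FALSE, quote = FALSE)
      say("recover: overall coverage %.2f", cov$overall)
      cov
    })
  manifest$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(result)
}

# serializable slice of a truth record
truth_record_json <- function(truth) {
  st <- truth$state
  list(seed = truth$seed,
       beta_rho = as.list(st$sync_rho$beta),
       beta_phi = as.list(st$sync_phi$beta),
       sigma_delta_rho = st$sync_rho$sigma_delta,
       sigma_delta_phi = st$sync_phi$sigma_delta,
       sigma_eps_rho = as.list(st$sync_rho$sigma_eps),
       sigma_eps_phi = as.list(st$sync_phi$sigma_eps),
       trap_a = as.list(st$a), sigma_x = as.list(st$sigma_x),
       phi_c = as.list(st$phi_c),
       s2 = st$mrr$s2, s35 = st$mrr$s35, F5 = st$mrr$F5, F6 = st$mrr$F6,
       psi = st$mrr$psi, alpha0 = st$mrr$alpha0, alpha1 = st$mrr$alpha1,
       s1 = st$mrr$s1, B = st$B,
       N = lapply(st$latent, function(l) l$N),
       extinct = as.list(truth$extinct))
}

# component log-likelihoods at the posterior median state are appended to
# the run metadata so each sub-model's fit can be inspected separately
log_median_components <- function(fit, bundle, config, out_dir) {
  summ <- summarize_posterior(fit)
  comp <- try(msipm_components(median_state(summ, config), bundle,
                               default_priors(config), config),
              silent = TRUE)
  if (inherits(comp, "try-error")) return(invisible(NULL))
  jsonlite::write_json(as.list(comp),
                       file.path(out_dir, "component_loglik.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(comp)
}

# reassemble a parameter state from posterior medians (for component-wise
# diagnostics; medians of integer latents are rounded to keep the state
# valid, with N redefined as R + S)
median_state <- function(summ, config) {
  med <- function(p) {
    i <- match(p, summ$parameter)
    if (any(is.na(i))) stop("missing monitored parameter: ",
                            paste(p[is.na(i)], collapse = ", "))
    summ$median[i]
  }
  Tn <- config$n_years
  idx2 <- function(stub, tt, s) sprintf("%s[%d,%d]", stub, tt, s)
  sync_from <- function(stub_sig_d, stub_sig_e, stub_beta, len, rate_stub) {
    beta <- med(sprintf("%s[%d]", stub_beta, 1:3))
    # reconstruct additive effects from the monitored rate series:
    # attribute the common part to delta and the remainder to eps
    rates <- sapply(1:3, function(s)
      med(idx2(rate_stub, seq_len(len), s)))
    lg <- stats::qlogis(rates)
    delta <- rowMeans(lg) - mean(beta)
    eps <- lg - outer(delta, rep(1, 3)) - outer(rep(1, len), beta)
    synchrony_block(beta = beta, delta = delta, eps = eps,
                    sigma_delta = med(stub_sig_d),
                    sigma_eps = med(sprintf("%s[%d]", stub_sig_e, 1:3)))
  }
  sync_rho <- sync_from("sig.delta.rho", "sig.eps.rho", "beta.rho", Tn,
                        "rho")
  sync_phi <- sync_from("sig.delta.phi", "sig.eps.phi", "beta.phi",
                        Tn - 1L, "sa")
  p_area <- list()
  for (ar in c("A", "B")) {
    pm <- mrr_p_index(config, ar)
    p_area[[ar]] <- list()
    for (cl in c("p2", "p3", "p45", "pa")) {
      win <- config$windows[[ar]][[cl]]
      a0 <- switch(cl, p2 = 2L, p3 = 3L, p45 = 4L, pa = 6L)
      p_area[[ar]][[cl]] <- vapply(win, function(t)
        med(sprintf("pvec%s[%d]", ar, pm$pidx[a0, t])), numeric(1))
    }
  }
  latent <- list()
  for (si in 1:3) {
    sp <- c("R", "P", "M")[si]
    d <- config$d[[sp]]
    N <- round(med(idx2("N", seq_len(Tn), si)))
    R <- S <- rep(NA_real_, Tn)
    for (t in seq(d + 1L, Tn)) {
      S[t] <- round(med(idx2("Ss", t, si)))
      R[t] <- round(med(idx2("Rr", t, si)))
      N[t] <- S[t] + R[t]
    }
    latent[[sp]] <- latent_population(N, R, S, d)
  }
  clamp01 <- function(x) pmin(pmax(x, 1e-9), 1 - 1e-9)
  parameter_state(
    sync_rho = sync_rho, sync_phi = sync_phi,
    p_star = sapply(1:3, function(s)
      clamp01(med(idx2("pstar", seq_len(Tn - 1L), s)))),
    a = med(sprintf("a.trap[%d]", 1:3)),
    sigma_x = med(sprintf("sigx[%d]", 1:3)),
    phi_c = med(sprintf("phic[%d]", 1:2)),
    B = med(sprintf("B[%d]", seq_len(Tn))),
    mrr = list(s1 = med(sprintf("s1[%d]", seq_len(Tn - 1L))),
               s2 = med("s2"), s35 = med("s35"), F5 = med("F5"),
               F6 = med("F6"), psi = med("psi"), alpha0 = med("alpha0"),
               alpha1 = med("alpha1"), p = p_area),
    latent = latent, config = config)
}

# monitored-parameter truth values for coverage assessment
recovery_truth_map <- function(truth) {
  st <- truth$state
  c(stats::setNames(unname(st$sync_rho$beta), sprintf("beta.rho[%d]", 1:3)),
    stats::setNames(unname(st$sync_phi$beta), sprintf("beta.phi[%d]", 1:3)),
    "sig.delta.rho" = st$sync_rho$sigma_delta,
    "sig.delta.phi" = st$sync_phi$sigma_delta,
    stats::setNames(unname(st$sync_rho$sigma_eps),
                    sprintf("sig.eps.rho[%d]", 1:3)),
    stats::setNames(unname(st$sync_phi$sigma_eps),
                    sprintf("sig.eps.phi[%d]", 1:3)),
    stats::setNames(unname(st$a), sprintf("a.trap[%d]", 1:3)),
    stats::setNames(unname(st$sigma_x), sprintf("sigx[%d]", 1:3)),
    stats::setNames(unname(st$phi_c), sprintf("phic[%d]", 1:2)),
    "s2" = st$mrr$s2, "s35" = st$mrr$s35, "F5" = st$mrr$F5,
    "F6" = st$mrr$F6, "psi" = st$mrr$psi,
    "alpha0" = st$mrr$alpha0, "alpha1" = st$mrr$alpha1)
}

#' Parameter-recovery study
#'
#' Simulates `n_reps` communities from a scenario at known truth, fits
#' each, and reports how often the 95% credible intervals cover the
#' generating values, together with the posterior medians of the
#' synchrony indices against their generating values.
#'
#' @param scenario a [scenario_config()].
#' @param n_reps number of simulate+fit replicates.
#' @param seed base seed; replicate `k` uses `seed + k`.
#' @param n_iter,n_burnin,n_adapt MCMC settings per fit.
#' @param quiet suppress progress messages.
#' @return list: `table` (per-parameter coverage), `overall` (pooled
#'   coverage fraction), `synchrony` (data frame of true and estimated
#'   indices per replicate), `worst_rhat`.
#' @export
recovery_study <- function(scenario, n_reps = 3L, seed = 1L,
                           n_iter = 1500L, n_burnin = 750L,
                           n_adapt = 400L, quiet = FALSE) {
  cfg <- scenario$config
  hits <- list()
  sync_rows <- list()
  worst_rhat <- -Inf
  for (k in seq_len(n_reps)) {
    sim <- simulate_bundle(scenario, seed = seed + k)
    fit <- run_mcmc(sim$bundle, default_priors(cfg), cfg,
                    n_iter = n_iter, n_burnin = n_burnin,
                    n_adapt = n_adapt, seed = seed + k)
    summ <- summarize_posterior(fit)
    worst_rhat <- max(worst_rhat, max(fit$rhat, na.rm = TRUE))
    tm <- recovery_truth_map(sim$truth)
    i <- match(names(tm), summ$parameter)
    hits[[k]] <- data.frame(parameter = names(tm), truth = unname(tm),
                            covered = tm >= summ$lower[i] &
                              tm <= summ$upper[i], rep = k)
    true_I_rho <- synchrony_index(sim$truth$state$sync_rho$sigma_delta,
                                  sim$truth$state$sync_rho$sigma_eps)
    true_I_phi <- synchrony_index(sim$truth$state$sync_phi$sigma_delta,
                                  sim$truth$state$sync_phi$sigma_eps)
    est <- function(p) summ$median[match(p, summ$parameter)]
    sync_rows[[k]] <- data.frame(
      rep = k, block = rep(c("rho", "phi"), each = 3L),
      species = rep(c("R", "P", "M"), 2L),
      true = c(true_I_rho, true_I_phi),
      estimate = c(est(sprintf("I.rho[%d]", 1:3)),
                   est(sprintf("I.phi[%d]", 1:3))))
    if (!quiet) message(sprintf("recover: replicate %d/%d done", k, n_reps))
  }
  all_hits <- do.call(rbind, hits)
  tab <- stats::aggregate(covered ~ parameter, all_hits, mean)
  list(table = tab, overall = mean(all_hits$covered),
       synchrony = do.call(rbind, sync_rows), worst_rhat = worst_rhat,
       detail = all_hits)
}
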