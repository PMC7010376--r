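#' Latent population trajectory
#'
#' Integer-valued true abundances of adult breeding females. For years
#' after the age at first breeding `d`, the breeding population is the sum
#' of surviving adults and new recruits: `N(t) = S(t) + R(t)`, with
#' `S(t) <= N(t-1)` and `R(t) <= N(t-d)`. `R` and `S` are `NA` during the
#' initialization period `t = 1..d`.
#'
#' @param N adult breeding females, length `T`.
#' @param R new female recruits (NA for `t <= d`).
#' @param S surviving adult females (NA for `t <= d`).
#' @param d age at first breeding.
#' @return object of class `"msipm_latent_population"`.
#' @export
latent_population <- function(N, R, S, d) {
  Tn <- length(N)
  stopifnot(length(R) == Tn, length(S) == Tn, d >= 1L, d < Tn)
  tt <- seq(d + 1L, Tn)
  if (any(is.na(N)) || any(is.na(R[tt])) || any(is.na(S[tt]))) {
    stop("N must be complete and R, S defined for t > d")
  }
  if (any(N < 0) || any(R[tt] < 0) || any(S[tt] < 0)) {
    stop("latent abundances must be non-negative")
  }
  if (any(N != round(N)) || any(R[tt] != round(R[tt])) ||
      any(S[tt] != round(S[tt]))) {
    stop("latent abundances must be integers")
  }
  if (any(N[tt] != R[tt] + S[tt])) {
    stop("N(t) must equal R(t) + S(t) for t > d")
  }
  structure(list(N = as.numeric(N), R = as.numeric(R), S = as.numeric(S),
                 d = as.integer(d)),
            class = "msipm_latent_population")
}

# binomial log-pmf that scores impossible configurations as -Inf rather
# than warning/raising (x > size or x < 0)
dbinom_safe <- function(x, size, prob) {
  out <- rep(-Inf, length(x))
  ok <- x >= 0 & x <= size
  out[ok] <- stats::dbinom(x[ok], size[ok], prob[ok], log = TRUE)
  out
}

#' System-process log-likelihood: combined-juvenile-survival variant
#'
#' For species without direct data on immature survival (razorbill,
#' puffin), recruits at `t` arise from breeders `d` years earlier with
#' success probability `rho(t-d) * phi_c * s_a(t-1) / 2`: productivity,
#' a combined fledging-to-prerecruitment apparent survival `phi_c` (which
#' absorbs both immature mortality and permanent emigration), survival of
#' the final pre-recruitment winter at the adult rate, and a 0.5 factor for
#' the female share of fledglings. Surviving adults are binomial on the
#' previous year's breeders with rate `s_a(t-1)`.
#'
#' @param latent a [latent_population()].
#' @param rho productivity series, length `T`.
#' @param s_a adult survival series, length `T - 1`.
#' @param phi_c combined juvenile survival in `[0, 1]`.
#' @param d age at first breeding.
#' @return log-likelihood of the latent trajectory (may be `-Inf`).
#' @export
rp_system_loglik <- function(latent, rho, s_a, phi_c, d = latent$d) {
  stopifnot(inherits(latent, "msipm_latent_population"), d == latent$d)
  Tn <- length(latent$N)
  stopifnot(length(rho) == Tn, length(s_a) == Tn - 1L,
            phi_c >= 0, phi_c <= 1)
  tt <- seq(d + 1L, Tn)
  tau <- rho[tt - d] * phi_c / 2
  sum(dbinom_safe(latent$R[tt], latent$N[tt - d], tau * s_a[tt - 1L])) +
    sum(dbinom_safe(latent$S[tt], latent$N[tt - 1L], s_a[tt - 1L]))
}

#' System-process log-likelihood: full age-structured variant (murre)
#'
#' Murres have direct information on immature survival from the chick MRR
#' component, so the recruit rate is fully structured: breeding probability
#' and productivity `d = 6` years earlier, the female factor 1/2,
#' first-year survival of that cohort, constant second-year and (cubed)
#' third-to-fifth-year survival, the two pre-recruitment fidelities, and
#' adult survival over the final winter:
#' `B(t-6) rho(t-6) (1/2) s1(t-6) s2 s35^3 F5 F6 s_a(t-1)`.
#'
#' @param latent a [latent_population()] with `d = 6`.
#' @param B breeding-probability series, length `T`.
#' @param rho productivity series, length `T`.
#' @param s1 first-year survival series, length `T - 1`.
#' @param s2,s35 constant immature survival probabilities.
#' @param F5,F6 pre-recruitment fidelities.
#' @param s_a adult survival series, length `T - 1`.
#' @return log-likelihood of the latent trajectory.
#' @export
murre_system_loglik <- function(latent, B, rho, s1, s2, s35, F5, F6, s_a) {
  stopifnot(inherits(latent, "msipm_latent_population"), latent$d == 6L)
  Tn <- length(latent$N)
  stopifnot(length(B) == Tn, length(rho) == Tn, length(s1) == Tn - 1L,
            length(s_a) == Tn - 1L)
  tt <- seq(7L, Tn)
  tau <- B[tt - 6L] * rho[tt - 6L] * 0.5 * s1[tt - 6L] *
    s2 * s35^3 * F5 * F6
  sum(dbinom_safe(latent$R[tt], latent$N[tt - 6L], tau * s_a[tt - 1L])) +
    sum(dbinom_safe(latent$S[tt], latent$N[tt - 1L], s_a[tt - 1L]))
}

#' Observation log-likelihood for whole-colony counts
#'
#' Counts are the true number of breeding females observed with additive
#' normal error: `x(t) ~ N(N_a(t), sigma_x^2)` for `t = d+1..T`. Missing
#' counts are skipped; the density is untruncated and evaluated at the
#' integer abundances without continuity correction.
#'
#' @param x observed counts (NA allowed), length `T`.
#' @param latent a [latent_population()].
#' @param sigma_x observation SD (> 0).
#' @param d age at first breeding.
#' @return log-likelihood.
#' @export
observation_loglik <- function(x, latent, sigma_x, d = latent$d) {
  stopifnot(inherits(latent, "msipm_latent_population"),
            length(x) == length(latent$N))
  if (sigma_x <= 0) stop("sigma_x must be > 0")
  tt <- seq(d + 1L, length(x))
  tt <- tt[!is.na(x[tt])]
  if (!length(tt)) return(0)
  sum(stats::dnorm(x[tt], latent$N[tt], sigma_x, log = TRUE))
}

#' Initialization-prior means from early counts
#'
#' The population model cannot express `N_a(t)` in terms of earlier
#' abundance for the first `d` years, so those years get informative normal
#' priors centred on the observed counts (with the observation SD). Years
#' without a count take the linear interpolation between the nearest
#' counted years (on either side, also using anchors beyond `d` when the
#' later anchor falls outside the initialization window).
#'
#' @param x observed counts, length `T`, NA where missing.
#' @param d age at first breeding.
#' @return numeric vector of length `d` of prior means.
#' @export
init_prior_means <- function(x, d) {
  obs <- which(!is.na(x))
  if (!length(obs)) stop("cannot initialize: no counts at all")
  stats::approx(obs, x[obs], xout = seq_len(d), rule = 2)$y
}

#' Initialization-prior log-density
#'
#' Sum of normal log-densities of the first `d` latent abundances at the
#' interpolated early-count means, with the observation SD.
#'
#' @param latent a [latent_population()].
#' @param init_means prior means, length `d` (see [init_prior_means()]).
#' @param sigma_x observation SD (> 0).
#' @return log-density.
#' @export
init_prior_logpdf <- function(latent, init_means, sigma_x) {
  stopifnot(inherits(latent, "msipm_latent_population"),
            length(init_means) == latent$d)
  if (sigma_x <= 0) stop("sigma_x must be > 0")
  sum(stats::dnorm(latent$N[seq_len(latent$d)], init_means, sigma_x,
                   log = TRUE))
}
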