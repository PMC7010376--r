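#' Adult encounter histories
#'
#' Encounter histories for birds marked as breeding adults, one row per
#' bird over the `T` study occasions. Entry `w[i, t]` is 1 if bird `i` was
#' seen at occasion `t`. The first 1 in a row is the marking occasion
#' `f_i` (physical capture counts as a sighting, including for the one-year
#' trap-dependence lag); entries before `f_i` must be 0.
#'
#' @param w 0/1 integer matrix, `n` birds by `T` occasions.
#' @return object of class `"msipm_adult_histories"` with elements `w` and
#'   `f` (vector of marking occasions).
#' @export
adult_histories <- function(w) {
  w <- as.matrix(w)
  if (!all(w %in% c(0L, 1L))) stop("histories must be 0/1")
  storage.mode(w) <- "integer"
  if (any(rowSums(w) == 0L)) stop("every history must contain a marking occasion")
  f <- apply(w, 1L, function(r) which(r == 1L)[1L])
  if (any(f >= ncol(w))) {
    stop("birds marked at the final occasion carry no information (need f < T)")
  }
  structure(list(w = w, f = as.integer(f)), class = "msipm_adult_histories")
}

#' Trap-dependent resight probabilities
#'
#' The baseline year-specific resight probability `p*(t)` applies to birds
#' not seen the previous season (`p_bar = p*`); for birds seen the previous
#' season the probability is shifted on the logit scale by the constant
#' trap-dependence parameter: `logit(p) = logit(p*) + a`. A positive `a` is
#' trap-happiness; `a = 0` removes the dependence. `p*(t)` is indexed by
#' interval: it governs detection at occasion `t + 1`.
#'
#' @param p_star baseline resight probabilities in (0, 1), length `T - 1`.
#' @param a trap-dependence constant (logit scale).
#' @return list with components `p` (seen previous season) and `p_bar`.
#' @export
effective_resight_probs <- function(p_star, a) {
  stopifnot(all(p_star > 0 & p_star < 1), length(a) == 1L, is.finite(a))
  list(p = stats::plogis(stats::qlogis(p_star) + a), p_bar = p_star)
}

# Probability of never being seen again after occasion t, given alive at t,
# split by whether the bird was seen at t (trap-dependence state).
# chi1[t]: seen at t; chi0[t]: not seen at t. Detection at occasion t+1 uses
# p[t] (seen at t) or p_bar[t] (not seen at t); survival over (t, t+1) is
# s[t]. chi[T] = 1.
cjs_chi <- function(s, p, p_bar) {
  Tn <- length(s) + 1L
  chi1 <- chi0 <- rep(1, Tn)
  for (t in seq(Tn - 1L, 1L)) {
    chi0[t] <- (1 - s[t]) + s[t] * (1 - p_bar[t]) * chi0[t + 1L]
    chi1[t] <- (1 - s[t]) + s[t] * (1 - p[t]) * chi0[t + 1L]
  }
  list(chi1 = chi1, chi0 = chi0)
}

#' Cormack-Jolly-Seber log-likelihood with one-year trap dependence
#'
#' Conditional-on-first-capture likelihood for adult mark-resight data,
#' with fully year-dependent survival `s(t)` and year-dependent baseline
#' resight probability `p*(t)` modified by a constant trap-dependence term
#' (see [effective_resight_probs()]). Computed bird by bird: between first
#' and last sighting the bird is certainly alive, so each interval
#' contributes a survival term and a detection/non-detection term whose
#' probability depends on whether the bird was seen the season before; the
#' unobserved tail after the last sighting contributes the appropriate
#' chi-type recursion. Adults are assumed not to emigrate, so `s` is true
#' survival.
#'
#' @param histories an [adult_histories()] object.
#' @param s survival probabilities, length `T - 1`.
#' @param p_star baseline resight probabilities, length `T - 1`.
#' @param a trap-dependence constant.
#' @return log-likelihood.
#' @export
cjs_loglik <- function(histories, s, p_star, a) {
  stopifnot(inherits(histories, "msipm_adult_histories"))
  Tn <- ncol(histories$w)
  stopifnot(length(s) == Tn - 1L, length(p_star) == Tn - 1L,
            all(s > 0 & s < 1))
  pr <- effective_resight_probs(p_star, a)
  chi <- cjs_chi(s, pr$p, pr$p_bar)
  ll <- 0
  for (i in seq_along(histories$f)) {
    w <- histories$w[i, ]
    f <- histories$f[i]
    l <- max(which(w == 1L))
    if (l > f) {
      for (t in seq(f + 1L, l)) {
        pd <- if (w[t - 1L] == 1L) pr$p[t - 1L] else pr$p_bar[t - 1L]
        ll <- ll + log(s[t - 1L]) + if (w[t] == 1L) log(pd) else log(1 - pd)
      }
    }
    ll <- ll + log(chi$chi1[l])
  }
  ll
}

# Sufficient statistics of the trap-dependent CJS likelihood, aggregated
# over birds. For t = 2..T (within each bird's first-to-last-sighting
# span): u11 counts (seen at t-1, seen at t), u10 (seen, missed), u01
# (missed, seen), u00 (missed, missed); nsurv = u11+u10+u01+u00 multiplies
# log s(t-1). last[t] counts birds whose final sighting (possibly the
# marking) is at t, multiplying log chi1[t]. Used by the MCMC backend; the
# reference likelihood is cjs_loglik().
cjs_sufficient_stats <- function(histories) {
  Tn <- ncol(histories$w)
  u11 <- u10 <- u01 <- u00 <- last <- integer(Tn)
  for (i in seq_along(histories$f)) {
    w <- histories$w[i, ]
    f <- histories$f[i]
    l <- max(which(w == 1L))
    if (l > f) {
      for (t in seq(f + 1L, l)) {
        prev <- w[t - 1L] == 1L
        cur <- w[t] == 1L
        if (prev && cur) u11[t] <- u11[t] + 1L
        else if (prev) u10[t] <- u10[t] + 1L
        else if (cur) u01[t] <- u01[t] + 1L
        else u00[t] <- u00[t] + 1L
      }
    }
    last[l] <- last[l] + 1L
  }
  list(u11 = u11, u10 = u10, u01 = u01, u00 = u00, last = last)
}

# Same likelihood evaluated from the sufficient statistics; algebraically
# identical to cjs_loglik() and much cheaper for large datasets.
cjs_loglik_suff <- function(stats, s, p_star, a) {
  Tn <- length(stats$last)
  pr <- effective_resight_probs(p_star, a)
  chi <- cjs_chi(s, pr$p, pr$p_bar)
  tt <- seq(2L, Tn)
  nsurv <- stats$u11 + stats$u10 + stats$u01 + stats$u00
  sum(nsurv[tt] * log(s[tt - 1L]) +
        stats$u11[tt] * log(pr$p[tt - 1L]) +
        stats$u10[tt] * log(1 - pr$p[tt - 1L]) +
        stats$u01[tt] * log(pr$p_bar[tt - 1L]) +
        stats$u00[tt] * log(1 - pr$p_bar[tt - 1L])) +
    sum(stats$last * log(chi$chi1))
}
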