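#' Structural parameters of the chick mark-resight-recovery model
#'
#' The murre chick MRR component tracks two mutually exclusive states:
#' state 1 ("resident": recruited, or due to recruit, to the study colony)
#' and state 0 ("emigrated": permanently recruited elsewhere, or carrying a
#' lost/unreadable band). Survival is the same in both states; birds in
#' state 0 are never resighted but their metal band can still be reported
#' when they die.
#'
#' Age/year structure: year-specific first-year survival `s1(t)`; constant
#' second-year (`s2`) and third-to-fifth-year (`s35`) survival; adult
#' (age > 5) survival equal to the murre adult survival series `s_a(t)`
#' shared with the adult CJS component. Fidelity is 1 up to age 4, `F5` and
#' `F6` in the two pre-recruitment years, and `psi` (the probability of
#' keeping a readable band and breeding at a visible location) for ages
#' above 6. Resighting uses age classes (ages 2, 3, 4-5, adult) with
#' year-specific probabilities per banding area, defined only on the
#' configured occasion windows and structurally zero outside them; age-1
#' birds are never resighted. Dead-recovery reporting follows a logit-linear
#' trend over standardized occasions, common to all ages.
#'
#' @param s1 first-year survival, length `T - 1`.
#' @param s2,s35 constant immature survival probabilities.
#' @param s_a adult survival series, length `T - 1` (shared with the adult
#'   CJS component for murres).
#' @param F5,F6 pre-recruitment fidelity probabilities.
#' @param psi band-retention/visible-breeding probability for ages > 6.
#' @param alpha0,alpha1 intercept and slope of the logit-linear reporting
#'   trend.
#' @param p nested list `p[[area]][[class]]` of year-specific resight
#'   probabilities, `area` in `"A"`, `"B"` and `class` in
#'   `"p2"`, `"p3"`, `"p45"`, `"pa"`; each vector matches the length of the
#'   corresponding configured window.
#' @param config a [study_config()].
#' @return object of class `"msipm_mrr_params"`.
#' @export
mrr_structural_params <- function(s1, s2, s35, s_a, F5, F6, psi,
                                  alpha0, alpha1, p, config) {
  Tn <- config$n_years
  stopifnot(length(s1) == Tn - 1L, length(s_a) == Tn - 1L,
            all(c(s1, s2, s35, s_a, F5, F6, psi) >= 0),
            all(c(s1, s2, s35, s_a, F5, F6, psi) <= 1),
            is.finite(alpha0), is.finite(alpha1))
  for (area in c("A", "B")) {
    for (cl in c("p2", "p3", "p45", "pa")) {
      win <- config$windows[[area]][[cl]]
      if (length(p[[area]][[cl]]) != length(win)) {
        stop(sprintf("p$%s$%s must have length %d (its window)",
                     area, cl, length(win)))
      }
      if (any(p[[area]][[cl]] < 0 | p[[area]][[cl]] > 1)) {
        stop("resight probabilities must lie in [0, 1]")
      }
    }
  }
  structure(list(s1 = s1, s2 = s2, s35 = s35, s_a = s_a,
                 F5 = F5, F6 = F6, psi = psi,
                 alpha0 = alpha0, alpha1 = alpha1, p = p),
            class = "msipm_mrr_params")
}

# Standardized occasion index used by the reporting trend: occasions
# 1..T-1 centred and scaled by their sample SD.
standardized_years <- function(n_years) {
  y <- seq_len(n_years - 1L)
  (y - mean(y)) / stats::sd(y)
}

#' Expand structural MRR parameters to full age-by-year tables
#'
#' Maps the structural parameters onto fully age- and year-indexed tables:
#' survival `phi[a, t]` (`t = 1..T-1`), fidelity `F[a]`, resight
#' probability `p[a, t]` (`t = 1..T`, zero at age 1 and outside the
#' configured windows of each age class) and reporting probability
#' `lambda[t] = plogis(alpha0 + alpha1 * y(t))` with `y` the standardized
#' occasion index.
#'
#' @param structural an [mrr_structural_params()].
#' @param config a [study_config()].
#' @param area banding area, `"A"` or `"B"` (areas share survival, fidelity
#'   and reporting but have their own resight probabilities).
#' @return list with elements `phi`, `F`, `p`, `lambda`.
#' @export
assemble_age_year_params <- function(structural, config, area = "A") {
  stopifnot(inherits(structural, "msipm_mrr_params"), area %in% c("A", "B"))
  Tn <- config$n_years
  A <- config$max_age
  phi <- matrix(NA_real_, A, Tn - 1L)
  phi[1L, ] <- structural$s1
  if (A >= 2L) phi[2L, ] <- structural$s2
  for (a in 3:5) if (A >= a) phi[a, ] <- structural$s35
  if (A >= 6L) {
    for (a in 6:A) phi[a, ] <- structural$s_a
  }
  Fa <- rep(NA_real_, A)
  Fa[1:min(4L, A)] <- 1
  if (A >= 5L) Fa[5L] <- structural$F5
  if (A >= 6L) Fa[6L] <- structural$F6
  if (A >= 7L) Fa[7:A] <- structural$psi
  p <- matrix(0, A, Tn)
  for (a in seq_len(A)) {
    cl <- resight_age_class(a)
    if (cl == "p1") next
    win <- config$windows[[area]][[cl]]
    p[a, win] <- structural$p[[area]][[cl]]
  }
  lambda <- stats::plogis(structural$alpha0 +
                            structural$alpha1 * standardized_years(Tn))
  list(phi = phi, F = Fa, p = p, lambda = lambda)
}

#' Multi-state MRR probability tables
#'
#' Computes, from expanded age-by-year tables, the recursive probabilities
#' of the two-state mark-resight-recovery likelihood:
#' \describe{
#'   \item{`Q11[a,b,t]`, `Q10[a,b,t]`, `Q00[a,b,t]`}{probability that a bird
#'     in the first-index state aged `a` at year `t` is in the second-index
#'     state at age `b + 1` and unobserved in between (transitions into
#'     state 1 from state 0 are impossible).}
#'   \item{`O[a,b,t]`}{probability of remaining unobserved until a live
#'     resighting at age `b + 1` (only possible in state 1).}
#'   \item{`D[a,b,t]`}{probability of dying aged `b` and being reported
#'     dead, given last observed alive in state 1 aged `a` at year `t`.}
#'   \item{`chi1[a,t]`, `chi0[a,t]`}{probability of never being seen again,
#'     alive or dead, after being alive in state 1 (resp. 0) aged `a` at
#'     year `t`; equal to 1 at `t = T`.}
#' }
#' Entries are computed exactly on the index ranges of the likelihood
#' (`t >= a`, `b <= a + T - 1 - t`) and `NA` elsewhere. Birds that would
#' exceed the maximum tracked age `A` are treated as unobservable
#' thereafter (their remaining probability is absorbed by `chi`).
#'
#' @param params expanded tables from [assemble_age_year_params()].
#' @param config a [study_config()].
#' @return list of arrays `Q11`, `Q10`, `Q00` (`A x A x T`), `O`, `D`
#'   (`A x A x T`), `chi1`, `chi0` (`A x T`); class `"msipm_mrr_tables"`.
#' @export
compute_mrr_tables <- function(params, config) {
  Tn <- config$n_years
  A <- config$max_age
  phi <- params$phi
  Fa <- params$F
  p <- params$p
  lam <- params$lambda
  Q11 <- Q10 <- Q00 <- O <- D <- array(NA_real_, c(A, A, Tn))
  chi1 <- chi0 <- matrix(NA_real_, A, Tn)

  # chi backwards in t. Birds at the maximum tracked age A are unobservable
  # from then on, alive or dead (no likelihood cell can represent a
  # resighting at age A + 1 or a recovery at age A), so chi at age A is
  # exactly 1; with A = T this row is only ever needed at t = T, where the
  # printed recursions give the same value.
  for (a in seq_len(A)) {
    if (a <= Tn) {
      chi1[a, Tn] <- 1
      chi0[a, Tn] <- 1
    }
  }
  for (t in seq(Tn - 1L, 1L)) {
    for (a in seq_len(min(t, A))) {
      if (a == A) {
        chi0[a, t] <- 1
        chi1[a, t] <- 1
        next
      }
      c0n <- chi0[a + 1L, t + 1L]
      c1n <- chi1[a + 1L, t + 1L]
      pn <- p[a + 1L, t + 1L]
      dead <- (1 - lam[t]) * (1 - phi[a, t])
      chi0[a, t] <- dead + phi[a, t] * c0n
      chi1[a, t] <- dead + phi[a, t] *
        ((1 - Fa[a]) * c0n + Fa[a] * (1 - pn) * c1n)
    }
  }

  if (A >= 2L) {
    # base diagonal b = a, then increasing unobserved span b - a
    for (a in seq_len(A - 1L)) {
      tt <- seq(a, Tn - 1L)
      Q11[a, a, tt] <- phi[a, tt] * Fa[a]
      Q10[a, a, tt] <- phi[a, tt] * (1 - Fa[a])
      Q00[a, a, tt] <- phi[a, tt]
      O[a, a, tt] <- Q11[a, a, tt] * p[a + 1L, tt + 1L]
      D[a, a, tt] <- (1 - phi[a, tt]) * lam[tt]
    }
    for (span in seq_len(A - 2L)) {
      for (a in seq_len(A - 1L - span)) {
        b <- a + span
        tmax <- Tn - 1L + a - b
        if (tmax < a) next
        tt <- seq(a, tmax)
        Q00[a, b, tt] <- phi[a, tt] * Q00[a + 1L, b, tt + 1L]
        Q11[a, b, tt] <- phi[a, tt] * Fa[a] * (1 - p[a + 1L, tt + 1L]) *
          Q11[a + 1L, b, tt + 1L]
        Q10[a, b, tt] <- phi[a, tt] *
          ((1 - Fa[a]) * Q00[a + 1L, b, tt + 1L] +
             Fa[a] * (1 - p[a + 1L, tt + 1L]) * Q10[a + 1L, b, tt + 1L])
        O[a, b, tt] <- Q11[a, b, tt] * p[b + 1L, tt + b - a + 1L]
        D[a, b, tt] <- (1 - phi[b, tt + b - a]) * lam[tt + b - a] *
          (Q10[a, b - 1L, tt] + (1 - p[b, tt + b - a]) * Q11[a, b - 1L, tt])
      }
    }
  }
  structure(list(Q11 = Q11, Q10 = Q10, Q00 = Q00, O = O, D = D,
                 chi1 = chi1, chi0 = chi0),
            class = "msipm_mrr_tables")
}

#' Multinomial cell probabilities for one MRR release cohort
#'
#' The likelihood of the chick MRR data is product-multinomial over release
#' cohorts. For birds observed in state 1 aged `a` in year `t`, the cells
#' are: next seen alive at age `b + 1` (`O[a,b,t]`, `b = a..bmax`),
#' recovered dead at age `b` (`D[a,b,t]`, same range), or never seen again
#' (`chi1[a,t]`), where `bmax = min(A - 1, a + T - 1 - t)` truncates at the
#' study horizon. The cells sum to 1 for every valid cohort.
#'
#' @param a cohort age (1..A), `t` cohort occasion (`a <= t <= T - 1`).
#' @param t cohort occasion.
#' @param tables a [compute_mrr_tables()] result.
#' @param config a [study_config()].
#' @return named probability vector
#'   (`O_a..O_bmax`, `D_a..D_bmax`, `chi`).
#' @export
mrr_cohort_cell_probs <- function(a, t, tables, config) {
  Tn <- config$n_years
  A <- config$max_age
  if (a < 1L || a > A || t < a || t > Tn - 1L) {
    stop(sprintf("invalid release cohort (a=%d, t=%d)", a, t))
  }
  bmax <- min(A - 1L, a + Tn - 1L - t)
  if (bmax >= a) {
    bb <- seq(a, bmax)
    out <- c(tables$O[a, bb, t], tables$D[a, bb, t], tables$chi1[a, t])
    names(out) <- c(paste0("O_", bb), paste0("D_", bb), "chi")
  } else {
    out <- c(chi = tables$chi1[a, t])
  }
  out
}

#' Sufficient statistics of the chick MRR data for one banding area
#'
#' Arrays `n[a, b, t]` (birds observed in state 1 aged `a` in year `t` and
#' next seen alive aged `b + 1`), `d[a, b, t]` (birds recovered dead aged
#' `b`, last observed aged `a` in year `t`) and `v[a, t]` (birds seen alive
#' — including the initial release — for the last time aged `a` in year
#' `t`, never recovered). Together with the release totals they summarize
#' the encounter data without information loss.
#'
#' @param n,d integer arrays `A x A x T`.
#' @param v integer matrix `A x T`.
#' @param config a [study_config()].
#' @return object of class `"msipm_mrr_stats"`.
#' @export
mrr_sufficient_stats <- function(n, d, v, config) {
  Tn <- config$n_years
  A <- config$max_age
  stopifnot(identical(dim(n), c(A, A, Tn)), identical(dim(d), c(A, A, Tn)),
            identical(dim(v), as.integer(c(A, Tn))) ||
              identical(dim(v), c(A, Tn)))
  if (any(n < 0) || any(d < 0) || any(v < 0)) stop("counts must be >= 0")
  for (a in seq_len(A)) {
    for (b in seq_len(A)) {
      bad_t <- which(n[a, b, ] > 0 | d[a, b, ] > 0)
      if (length(bad_t)) {
        bmax_ok <- b >= a & b <= A - 1L
        t_ok <- bad_t >= a & bad_t <= Tn - 1L + a - b
        if (!bmax_ok || !all(t_ok)) {
          stop(sprintf("count outside the valid (a,b,t) index range at a=%d b=%d", a, b))
        }
      }
    }
    bad_t <- which(v[a, ] > 0)
    if (length(bad_t) && any(bad_t < a)) {
      stop("v[a, t] requires t >= a")
    }
  }
  structure(list(n = n, d = d, v = v), class = "msipm_mrr_stats")
}

# all-zero sufficient statistics
empty_mrr_stats <- function(config) {
  A <- config$max_age
  Tn <- config$n_years
  mrr_sufficient_stats(array(0L, c(A, A, Tn)), array(0L, c(A, A, Tn)),
                       matrix(0L, A, Tn), config)
}

# release totals per cohort implied by the sufficient statistics:
# every bird observed at (a, t) is next seen alive, recovered dead, or never
# seen again, exactly once.
mrr_release_totals <- function(stats) {
  A <- dim(stats$n)[1L]
  apply(stats$n, c(1L, 3L), sum) + apply(stats$d, c(1L, 3L), sum) + stats$v
}

#' Chick MRR log-likelihood (both banding areas)
#'
#' Product-multinomial log-likelihood of the sufficient statistics of both
#' banding areas, which share survival, fidelity and reporting parameters
#' but have area-specific resight probabilities. Multinomial coefficients
#' are constant in the parameters and omitted; [mrr_cohort_cell_probs()] is
#' the exact probability surface. A positive count on a structurally zero
#' cell yields `-Inf`.
#'
#' @param statsA,statsB [mrr_sufficient_stats()] for areas A and B.
#' @param structural an [mrr_structural_params()].
#' @param config a [study_config()].
#' @return log-likelihood.
#' @export
mrr_loglik <- function(statsA, statsB, structural, config) {
  stopifnot(inherits(statsA, "msipm_mrr_stats"),
            inherits(statsB, "msipm_mrr_stats"))
  ll <- 0
  for (area in c("A", "B")) {
    stats <- if (area == "A") statsA else statsB
    tables <- compute_mrr_tables(
      assemble_age_year_params(structural, config, area), config)
    for (arr_name in c("n", "d", "v")) {
      cnt <- stats[[arr_name]]
      prob <- switch(arr_name, n = tables$O, d = tables$D, v = tables$chi1)
      idx <- which(cnt > 0)
      if (!length(idx)) next
      pr <- prob[idx]
      if (any(is.na(pr)) || any(pr <= 0)) return(-Inf)
      ll <- ll + sum(cnt[idx] * log(pr))
    }
  }
  ll
}
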