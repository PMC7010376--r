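# Independent oracles used across the suite. These are deliberately naive
# re-derivations (exhaustive enumeration, direct density arithmetic) kept
# separate from the package's recursive implementations.

# hand-coded binomial log pmf (no dbinom)
oracle_lbinom <- function(x, n, p) {
  if (x < 0 || x > n) return(-Inf)
  lchoose(n, x) + ifelse(x == 0, 0, x * log(p)) +
    ifelse(n - x == 0, 0, (n - x) * log(1 - p))
}

# hand-coded normal log density
oracle_lnorm <- function(x, mu, sd) {
  -log(sd * sqrt(2 * pi)) - (x - mu)^2 / (2 * sd^2)
}

# exhaustive fate enumeration for one MRR release cohort: every bird path
# (death year, recovery, emigration year, sighting pattern) is walked
# recursively and its probability accumulated into the multinomial cells.
# Ages at the maximum tracked age A are unobservable from then on.
oracle_mrr_cells <- function(a0, t0, par, A, Tn) {
  nb <- min(A - 1, a0 + Tn - 1 - t0)
  cells <- c(setNames(rep(0, max(0, nb - a0 + 1)), paste0("O_", seq(a0, length.out = max(0, nb - a0 + 1)))),
             setNames(rep(0, max(0, nb - a0 + 1)), paste0("D_", seq(a0, length.out = max(0, nb - a0 + 1)))),
             chi = 0)
  rec <- function(a, t, resident, prob) {
    if (t >= Tn || a >= A) {
      cells["chi"] <<- cells["chi"] + prob
      return()
    }
    pdie <- 1 - par$phi[a, t]
    lam <- par$lambda[t]
    cells[paste0("D_", a)] <<- cells[paste0("D_", a)] + prob * pdie * lam
    cells["chi"] <<- cells["chi"] + prob * pdie * (1 - lam)
    psurv <- par$phi[a, t]
    if (resident) {
      pem <- 1 - par$F[a]
      rec(a + 1, t + 1, FALSE, prob * psurv * pem)
      pseen <- par$p[a + 1, t + 1]
      cells[paste0("O_", a)] <<- cells[paste0("O_", a)] +
        prob * psurv * (1 - pem) * pseen
      rec(a + 1, t + 1, TRUE, prob * psurv * (1 - pem) * (1 - pseen))
    } else {
      rec(a + 1, t + 1, FALSE, prob * psurv)
    }
  }
  rec(a0, t0, TRUE, 1)
  cells
}

# random expanded MRR parameter tables for a toy frame
random_mrr_tables_input <- function(A, Tn) {
  par <- list(phi = matrix(runif(A * (Tn - 1), 0.05, 0.95), A),
              F = runif(A, 0.3, 1),
              p = matrix(runif(A * Tn, 0.05, 0.9), A),
              lambda = runif(Tn - 1, 0, 0.6))
  par$p[1, ] <- 0
  par
}

toy_config <- function(A, Tn) {
  structure(list(n_years = Tn, max_age = A), class = "msipm_config")
}

# CJS probability of one encounter history by summing over all death
# occasions (marking occasion f, detections w over 1..T, trap dependence)
oracle_cjs_history_prob <- function(w, f, s, p_star, a) {
  Tn <- length(w)
  p_seen <- plogis(qlogis(p_star) + a)
  l <- max(which(w == 1))
  total <- 0
  for (death in l:Tn) { # alive through occasion `death`
    pr <- 1
    if (death > f) pr <- prod(s[f:(death - 1)])
    if (death < Tn) pr <- pr * (1 - s[death])
    if (death > f) {
      for (t in (f + 1):death) {
        pd <- if (w[t - 1] == 1) p_seen[t - 1] else p_star[t - 1]
        pr <- pr * if (w[t] == 1) pd else (1 - pd)
      }
    }
    total <- total + pr
  }
  total
}

# all 0/1 detection patterns after a release at occasion f
all_patterns_after <- function(f, Tn) {
  k <- Tn - f
  if (k == 0) return(matrix(integer(0), nrow = 1))
  as.matrix(expand.grid(rep(list(0:1), k)))
}

# an independently coded classic CJS chi recursion (single state, no
# recovery): probability of no detection after (a, t)
oracle_cjs_chi_by_age <- function(phi, p, A, Tn) {
  chi <- matrix(NA_real_, A, Tn)
  chi[, Tn] <- 1
  for (t in seq(Tn - 1, 1)) {
    for (a in seq_len(min(t, A))) {
      if (a == A) { chi[a, t] <- 1; next }
      chi[a, t] <- (1 - phi[a, t]) +
        phi[a, t] * (1 - p[a + 1, t + 1]) * chi[a + 1, t + 1]
    }
  }
  chi
}

# small three-species frame + a consistent parameter state and bundle,
# built quickly for posterior-level tests
tiny_scenario <- function(n_years = 12L) {
  scenario_config(
    config = study_config(n_years = n_years, first_year = 2000L,
                          areaB_last_banding = max(2L, n_years - 7L),
                          puffin_count_years = c(1L, 4L, 6L,
                                                 n_years - 2L, n_years)),
    n_marked_adults = c(R = 3L, P = 6L, M = 8L),
    n_chicks = c(A = 20L, B = 8L),
    E_monitored = c(R = 20L, P = 25L, M = 80L),
    init_N = c(R = 200L, P = 900L, M = 1200L),
    sigma_x = c(R = 40, P = 300, M = 120))
}
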