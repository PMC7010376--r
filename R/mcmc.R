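# MCMC backend. The joint posterior is defined by the reference likelihood
# functions of this package (see joint_logposterior()); sampling is
# delegated to JAGS with a model authored here that encodes the identical
# structure: latent abundances and year random effects are sampled as
# auxiliary variables, the CJS and MRR likelihoods enter through their
# sufficient statistics, and the initial-abundance priors use a
# Poisson-with-truncated-normal-mean construction (a binomial population
# process needs integer sizes; at the count scales of this system the extra
# Poisson variance is negligible relative to the observation variance).

# ---- data preparation ---------------------------------------------------

# index map from (age, occasion) to the free resight-probability vector of
# one banding area; row A+1 is the virtual "beyond max age" row (mask 0)
mrr_p_index <- function(config, area) {
  A <- config$max_age
  Tn <- config$n_years
  pidx <- matrix(1L, A + 1L, Tn)
  mask <- matrix(0L, A + 1L, Tn)
  offset <- 0L
  for (cl in c("p2", "p3", "p45", "pa")) {
    win <- config$windows[[area]][[cl]]
    ages <- switch(cl, p2 = 2L, p3 = 3L, p45 = c(4L, 5L),
                   pa = seq(6L, A))
    for (k in seq_along(win)) {
      for (a in ages) {
        if (a <= A) {
          pidx[a, win[k]] <- offset + k
          mask[a, win[k]] <- 1L
        }
      }
    }
    offset <- offset + length(win)
  }
  list(pidx = pidx, mask = mask, K = offset)
}

# flatten the nonzero cells of one sufficient-statistics array set
mrr_flat_cells <- function(stats) {
  flat <- function(arr) {
    idx <- which(arr > 0, arr.ind = TRUE)
    list(n = nrow(idx), a = idx[, 1L], b = idx[, 2L], t = idx[, 3L],
         cnt = arr[idx])
  }
  vidx <- which(stats$v > 0, arr.ind = TRUE)
  list(O = flat(stats$n), D = flat(stats$d),
       V = list(n = nrow(vidx), a = vidx[, 1L], t = vidx[, 2L],
                cnt = stats$v[vidx]))
}

jags_prepare <- function(bundle, priors, config) {
  Tn <- config$n_years
  A <- config$max_age
  dat <- list(T = Tn)
  present <- list()

  # breeding success
  bs <- do.call(rbind, lapply(seq_along(c("R", "P", "M")), function(si) {
    sp <- c("R", "P", "M")[si]
    keep <- which(bundle$bs[[sp]]$E > 0)
    if (!length(keep)) return(NULL)
    cbind(t = keep, s = si, E = bundle$bs[[sp]]$E[keep],
          C = bundle$bs[[sp]]$C[keep])
  }))
  present$bs <- !is.null(bs) && nrow(bs) > 0
  if (present$bs) {
    dat$nBS <- nrow(bs); dat$tBS <- bs[, "t"]; dat$sBS <- bs[, "s"]
    dat$EBS <- bs[, "E"]; dat$CBS <- bs[, "C"]
  }

  # non-breeding
  keep <- which(bundle$nb$xi_m > 0)
  present$nb <- length(keep) > 0
  if (present$nb) {
    dat$nNB <- length(keep); dat$tNB <- keep
    dat$ximNB <- bundle$nb$xi_m[keep]; dat$xibNB <- bundle$nb$xi_b[keep]
  }

  # adult CJS sufficient statistics
  u11 <- u10 <- u01 <- u00 <- wlast <- matrix(0L, Tn, 3L)
  any_cjs <- FALSE
  for (si in 1:3) {
    h <- bundle$adults[[c("R", "P", "M")[si]]]
    if (is.null(h)) next
    st <- cjs_sufficient_stats(h)
    u11[, si] <- st$u11; u10[, si] <- st$u10
    u01[, si] <- st$u01; u00[, si] <- st$u00
    wlast[, si] <- st$last
    any_cjs <- TRUE
  }
  present$cjs <- any_cjs
  if (any_cjs) {
    dat$u11 <- u11; dat$u10 <- u10; dat$u01 <- u01; dat$u00 <- u00
    dat$wlast <- wlast; dat$nsurv <- u11 + u10 + u01 + u00
    dat$zero.cjs <- rep(0L, 3L)
  }

  # chick MRR
  cells <- lapply(list(A = bundle$mrr$A, B = bundle$mrr$B), mrr_flat_cells)
  present$mrr <- sum(vapply(cells, function(cl)
    cl$O$n + cl$D$n + cl$V$n, numeric(1))) > 0
  if (present$mrr) {
    dat$A <- A
    dat$amax <- pmin(seq_len(Tn), A)
    dat$ystd <- standardized_years(Tn)
    for (ar in c("A", "B")) {
      pm <- mrr_p_index(config, ar)
      dat[[paste0("pidx", ar)]] <- pm$pidx
      dat[[paste0("mask", ar)]] <- pm$mask
      dat[[paste0("K", ar)]] <- pm$K
      for (ty in c("O", "D", "V")) {
        cl <- cells[[ar]][[ty]]
        if (cl$n > 0) {
          dat[[paste0("n", ty, ar)]] <- cl$n
          dat[[paste0("a", ty, ar)]] <- cl$a
          if (ty != "V") dat[[paste0("b", ty, ar)]] <- cl$b
          dat[[paste0("t", ty, ar)]] <- cl$t
          dat[[paste0("cnt", ty, ar)]] <- cl$cnt
        }
      }
    }
    dat$zero.mrr <- 0L
    present$mrr_cells <- lapply(cells, function(cl)
      c(O = cl$O$n > 0, D = cl$D$n > 0, V = cl$V$n > 0))
  }

  # population / counts
  initmean <- matrix(0, Tn, 3L)
  obs <- NULL
  for (si in 1:3) {
    sp <- c("R", "P", "M")[si]
    d <- config$d[[sp]]
    initmean[seq_len(d), si] <- init_prior_means(bundle$counts[, sp], d)
    tt <- which(!is.na(bundle$counts[, sp]))
    tt <- tt[tt > d]
    if (length(tt)) {
      obs <- rbind(obs, cbind(t = tt, s = si, x = bundle$counts[tt, sp]))
    }
  }
  dat$initmean <- initmean
  present$obs <- !is.null(obs) && nrow(obs) > 0
  if (present$obs) {
    dat$nX <- nrow(obs); dat$tX <- obs[, "t"]; dat$sX <- obs[, "s"]
    dat$xX <- obs[, "x"]
  }
  dat$sigxup <- unname(priors$sigma_x_upper[c("R", "P", "M")])
  list(data = dat, present = present)
}

# ---- model text ---------------------------------------------------------

jags_model_string <- function(config, present) {
  Tn <- config$n_years
  A <- config$max_age
  dR <- config$d[["R"]]; dP <- config$d[["P"]]; dM <- config$d[["M"]]
  blocks <- character(0)
  add <- function(x) blocks <<- c(blocks, x)

  add("
  # synchrony layer: intercepts + shared/species year effects
  for (s in 1:3) {
    beta.rho[s] ~ dunif(-5, 5)
    beta.phi[s] ~ dunif(-5, 5)
    a.trap[s] ~ dunif(-5, 5)
    sig.eps.rho[s] ~ dunif(0, 3)
    sig.eps.phi[s] ~ dunif(0, 3)
    tau.eps.rho[s] <- pow(sig.eps.rho[s], -2)
    tau.eps.phi[s] <- pow(sig.eps.phi[s], -2)
    I.rho[s] <- pow(sig.delta.rho, 2) /
      (pow(sig.delta.rho, 2) + pow(sig.eps.rho[s], 2))
    I.phi[s] <- pow(sig.delta.phi, 2) /
      (pow(sig.delta.phi, 2) + pow(sig.eps.phi[s], 2))
  }
  sig.delta.rho ~ dunif(0, 3)
  sig.delta.phi ~ dunif(0, 3)
  tau.delta.rho <- pow(sig.delta.rho, -2)
  tau.delta.phi <- pow(sig.delta.phi, -2)
  for (t in 1:T) {
    delta.rho[t] ~ dnorm(0, tau.delta.rho)
    for (s in 1:3) {
      eps.rho[t, s] ~ dnorm(0, tau.eps.rho[s])
      logit(rho[t, s]) <- beta.rho[s] + delta.rho[t] + eps.rho[t, s]
    }
  }
  for (t in 1:(T-1)) {
    delta.phi[t] ~ dnorm(0, tau.delta.phi)
    for (s in 1:3) {
      eps.phi[t, s] ~ dnorm(0, tau.eps.phi[s])
      logit(sa[t, s]) <- beta.phi[s] + delta.phi[t] + eps.phi[t, s]
    }
  }
  # adult baseline resight probabilities (logit-normal low-information)
  for (s in 1:3) {
    for (t in 1:(T-1)) {
      lp.star[t, s] ~ dnorm(0, 1.0E-4)
      pstar[t, s] <- ilogit(lp.star[t, s])
      ptrap[t, s] <- ilogit(lp.star[t, s] + a.trap[s])
    }
  }
  # murre breeding probability and structural chick-MRR parameters
  for (t in 1:T) { B[t] ~ dunif(0, 1) }
  for (t in 1:(T-1)) { s1[t] ~ dunif(0, 1) }
  s2 ~ dunif(0, 1)
  s35 ~ dunif(0, 1)
  F5 ~ dunif(0, 1)
  F6 ~ dunif(0, 1)
  psi ~ dunif(0, 1)
  alpha0 ~ dunif(-5, 5)
  alpha1 ~ dunif(-5, 5)
  phic[1] ~ dunif(0, 1)
  phic[2] ~ dunif(0, 1)
  for (s in 1:3) {
    sigx[s] ~ dunif(0, sigxup[s])
    taux[s] <- pow(sigx[s], -2)
  }")

  if (isTRUE(present$bs)) add("
  for (k in 1:nBS) { CBS[k] ~ dbin(rho[tBS[k], sBS[k]], EBS[k]) }")

  if (isTRUE(present$nb)) add("
  for (k in 1:nNB) { xibNB[k] ~ dbin(B[tNB[k]], ximNB[k]) }")

  if (isTRUE(present$cjs)) add("
  # adult CJS with 1-year trap dependence, via sufficient statistics
  for (s in 1:3) {
    chi0.ad[T, s] <- 1
    chi1.ad[T, s] <- 1
    for (t in 1:(T-1)) {
      chi0.ad[t, s] <- (1 - sa[t, s]) +
        sa[t, s] * (1 - pstar[t, s]) * chi0.ad[t+1, s]
      chi1.ad[t, s] <- (1 - sa[t, s]) +
        sa[t, s] * (1 - ptrap[t, s]) * chi0.ad[t+1, s]
    }
    for (t in 2:T) {
      ll.cjs.t[t, s] <- nsurv[t, s] * log(sa[t-1, s]) +
        u11[t, s] * log(ptrap[t-1, s]) +
        u10[t, s] * log(1 - ptrap[t-1, s]) +
        u01[t, s] * log(pstar[t-1, s]) +
        u00[t, s] * log(1 - pstar[t-1, s]) +
        wlast[t, s] * log(chi1.ad[t, s])
    }
    ll.cjs[s] <- sum(ll.cjs.t[2:T, s]) + wlast[1, s] * log(chi1.ad[1, s])
    zero.cjs[s] ~ dpois(1 - ll.cjs[s])
  }")

  if (isTRUE(present$mrr)) {
    add("
  # chick MRR: expanded tables and two-state recursions
  for (t in 1:(T-1)) {
    lam[t] <- ilogit(alpha0 + alpha1 * ystd[t])
    phiM[1, t] <- s1[t]
    phiM[2, t] <- s2
    for (a in 3:5) { phiM[a, t] <- s35 }
    for (a in 6:A) { phiM[a, t] <- sa[t, 3] }
  }
  for (a in 1:4) { FM[a] <- 1 }
  FM[5] <- F5
  FM[6] <- F6
  for (a in 7:A) { FM[a] <- psi }
  for (j in 1:KA) { pvecA[j] ~ dunif(0, 1) }
  for (j in 1:KB) { pvecB[j] ~ dunif(0, 1) }
  for (t in 1:T) {
    for (a in 1:A) {
      pA[a, t] <- maskA[a, t] * pvecA[pidxA[a, t]]
      pB[a, t] <- maskB[a, t] * pvecB[pidxB[a, t]]
    }
    pA[A+1, t] <- 0
    pB[A+1, t] <- 0
    chi0M[A+1, t] <- 1
    chi1MA[A+1, t] <- 1
    chi1MB[A+1, t] <- 1
  }
  for (a in 1:A) {
    chi0M[a, T] <- 1
    chi1MA[a, T] <- 1
    chi1MB[a, T] <- 1
  }
  for (t in 1:(T-1)) {
    for (a in 1:amax[t]) {
      chi0M[a, t] <- (1 - lam[t]) * (1 - phiM[a, t]) +
        phiM[a, t] * chi0M[a+1, t+1]
      chi1MA[a, t] <- (1 - lam[t]) * (1 - phiM[a, t]) + phiM[a, t] *
        ((1 - FM[a]) * chi0M[a+1, t+1] +
         FM[a] * (1 - pA[a+1, t+1]) * chi1MA[a+1, t+1])
      chi1MB[a, t] <- (1 - lam[t]) * (1 - phiM[a, t]) + phiM[a, t] *
        ((1 - FM[a]) * chi0M[a+1, t+1] +
         FM[a] * (1 - pB[a+1, t+1]) * chi1MB[a+1, t+1])
    }
  }
  for (a in 1:(A-1)) {
    for (t in a:(T-1)) {
      Q00[a, a, t] <- phiM[a, t]
      Q11A[a, a, t] <- phiM[a, t] * FM[a]
      Q10A[a, a, t] <- phiM[a, t] * (1 - FM[a])
      OA[a, a, t] <- Q11A[a, a, t] * pA[a+1, t+1]
      DA[a, a, t] <- (1 - phiM[a, t]) * lam[t]
      Q11B[a, a, t] <- Q11A[a, a, t]
      Q10B[a, a, t] <- Q10A[a, a, t]
      OB[a, a, t] <- Q11B[a, a, t] * pB[a+1, t+1]
      DB[a, a, t] <- DA[a, a, t]
    }
  }
  for (a in 1:(A-2)) {
    for (b in (a+1):(A-1)) {
      for (t in a:(T-1+a-b)) {
        Q00[a, b, t] <- phiM[a, t] * Q00[a+1, b, t+1]
        Q11A[a, b, t] <- phiM[a, t] * FM[a] * (1 - pA[a+1, t+1]) *
          Q11A[a+1, b, t+1]
        Q10A[a, b, t] <- phiM[a, t] * ((1 - FM[a]) * Q00[a+1, b, t+1] +
          FM[a] * (1 - pA[a+1, t+1]) * Q10A[a+1, b, t+1])
        OA[a, b, t] <- Q11A[a, b, t] * pA[b+1, t+b-a+1]
        DA[a, b, t] <- (1 - phiM[b, t+b-a]) * lam[t+b-a] *
          (Q10A[a, b-1, t] + (1 - pA[b, t+b-a]) * Q11A[a, b-1, t])
        Q11B[a, b, t] <- phiM[a, t] * FM[a] * (1 - pB[a+1, t+1]) *
          Q11B[a+1, b, t+1]
        Q10B[a, b, t] <- phiM[a, t] * ((1 - FM[a]) * Q00[a+1, b, t+1] +
          FM[a] * (1 - pB[a+1, t+1]) * Q10B[a+1, b, t+1])
        OB[a, b, t] <- Q11B[a, b, t] * pB[b+1, t+b-a+1]
        DB[a, b, t] <- (1 - phiM[b, t+b-a]) * lam[t+b-a] *
          (Q10B[a, b-1, t] + (1 - pB[b, t+b-a]) * Q11B[a, b-1, t])
      }
    }
  }")
    terms <- character(0)
    for (ar in c("A", "B")) {
      cc <- present$mrr_cells[[ar]]
      if (cc[["O"]]) {
        add(sprintf("
  for (k in 1:nO%s) { llO%s[k] <- cntO%s[k] * log(O%s[aO%s[k], bO%s[k], tO%s[k]]) }",
                    ar, ar, ar, ar, ar, ar, ar))
        terms <- c(terms, sprintf("sum(llO%s)", ar))
      }
      if (cc[["D"]]) {
        add(sprintf("
  for (k in 1:nD%s) { llD%s[k] <- cntD%s[k] * log(D%s[aD%s[k], bD%s[k], tD%s[k]]) }",
                    ar, ar, ar, ar, ar, ar, ar))
        terms <- c(terms, sprintf("sum(llD%s)", ar))
      }
      if (cc[["V"]]) {
        add(sprintf("
  for (k in 1:nV%s) { llV%s[k] <- cntV%s[k] * log(chi1M%s[aV%s[k], tV%s[k]]) }",
                    ar, ar, ar, ar, ar, ar))
        terms <- c(terms, sprintf("sum(llV%s)", ar))
      }
    }
    add(sprintf("
  ll.mrr <- %s
  zero.mrr ~ dpois(1 - ll.mrr)", paste(terms, collapse = " + ")))
  }

  # binomial state-space population processes (initial abundances as
  # Poisson counts around truncated-normal means, see file header)
  pop_block <- function(si, d, tau_expr) sprintf("
  for (t in 1:%d) {
    lamN[t, %d] ~ dnorm(initmean[t, %d], taux[%d]) T(0,)
    N[t, %d] ~ dpois(lamN[t, %d])
  }
  for (t in %d:T) {
    prR[t, %d] <- %s
    Rr[t, %d] ~ dbin(prR[t, %d], N[t-%d, %d])
    Ss[t, %d] ~ dbin(sa[t-1, %d], N[t-1, %d])
    N[t, %d] <- Rr[t, %d] + Ss[t, %d]
  }", d, si, si, si, si, si, d + 1L, si, tau_expr, si, si, d, si, si, si,
      si, si, si, si)
  add(pop_block(1L, dR,
                sprintf("rho[t-%d, 1] * phic[1] / 2 * sa[t-1, 1]", dR)))
  add(pop_block(2L, dP,
                sprintf("rho[t-%d, 2] * phic[2] / 2 * sa[t-1, 2]", dP)))
  add(pop_block(3L, dM, paste0(
    sprintf("B[t-%d] * rho[t-%d, 3] * 0.5 * s1[t-%d]", dM, dM, dM),
    " * s2 * pow(s35, 3) * F5 * F6 * sa[t-1, 3]")))

  if (isTRUE(present$obs)) add("
  for (k in 1:nX) { xX[k] ~ dnorm(N[tX[k], sX[k]], taux[sX[k]]) }")

  paste0("model {\n", paste(blocks, collapse = "\n"), "\n}\n")
}

# priors-only model used for prior-recovery checks (no data, no latents)
jags_prior_model_string <- function(config) {
  "model {
  for (s in 1:3) {
    beta.rho[s] ~ dunif(-5, 5)
    beta.phi[s] ~ dunif(-5, 5)
    a.trap[s] ~ dunif(-5, 5)
    sig.eps.rho[s] ~ dunif(0, 3)
    sig.eps.phi[s] ~ dunif(0, 3)
    sigx[s] ~ dunif(0, sigxup[s])
  }
  sig.delta.rho ~ dunif(0, 3)
  sig.delta.phi ~ dunif(0, 3)
  for (t in 1:T) { B[t] ~ dunif(0, 1) }
  for (t in 1:(T-1)) { s1[t] ~ dunif(0, 1) }
  s2 ~ dunif(0, 1)
  s35 ~ dunif(0, 1)
  F5 ~ dunif(0, 1)
  F6 ~ dunif(0, 1)
  psi ~ dunif(0, 1)
  alpha0 ~ dunif(-5, 5)
  alpha1 ~ dunif(-5, 5)
  phic[1] ~ dunif(0, 1)
  phic[2] ~ dunif(0, 1)
}
"
}

# ---- initial values -----------------------------------------------------

# crude data-informed starting values, jittered differently per chain so
# that convergence can be assessed from dispersed starts
jags_inits <- function(bundle, priors, config, chain, seed) {
  Tn <- config$n_years
  shift <- if (chain %% 2L == 0L) 0.4 else -0.4
  inits <- list(
    .RNG.name = "base::Mersenne-Twister",
    .RNG.seed = as.integer(seed + chain),
    beta.rho = rep(0.8 + shift, 3L),
    beta.phi = rep(2.5 + shift, 3L),
    a.trap = rep(1 + shift, 3L),
    sig.delta.rho = 0.4 + 0.2 * (chain %% 2L),
    sig.delta.phi = 0.4 + 0.2 * (chain %% 2L),
    sig.eps.rho = rep(0.3, 3L), sig.eps.phi = rep(0.3, 3L),
    lp.star = matrix(0.4 + shift, Tn - 1L, 3L),
    B = rep(0.9, Tn), s1 = rep(0.5, Tn - 1L),
    s2 = 0.7 + 0.1 * shift, s35 = 0.85, F5 = 0.85, F6 = 0.85, psi = 0.85,
    alpha0 = -3 + shift, alpha1 = -0.5,
    phic = c(0.5, 0.7) + 0.1 * shift,
    sigx = unname(priors$sigma_x_upper[c("R", "P", "M")]) / 20,
    pvecA = NULL, pvecB = NULL)
  for (ar in c("A", "B")) {
    K <- mrr_p_index(config, ar)$K
    inits[[paste0("pvec", ar)]] <- rep(0.3, K)
  }
  if (!is.null(bundle)) {
    # feasible integer latent trajectory: start at the initialization means
    # and iterate the process at the crude rates
    dmax <- max(config$d)
    lamN <- matrix(NA_real_, dmax, 3L)
    Nmat <- matrix(NA_real_, Tn, 3L)
    Rr <- Ss <- matrix(NA_real_, Tn, 3L)
    for (si in 1:3) {
      sp <- c("R", "P", "M")[si]
      d <- config$d[[sp]]
      im <- init_prior_means(bundle$counts[, sp], d)
      lamN[seq_len(d), si] <- pmax(im, 1)
      N <- numeric(Tn)
      N[seq_len(d)] <- pmax(round(im), 1)
      for (t in seq(d + 1L, Tn)) {
        Ss[t, si] <- round(0.9 * N[t - 1L])
        Rr[t, si] <- round(0.08 * N[t - d])
        N[t] <- Ss[t, si] + Rr[t, si]
      }
      Nmat[seq_len(d), si] <- N[seq_len(d)]
    }
    inits$lamN <- lamN
    inits$N <- Nmat
    inits$Rr <- Rr
    inits$Ss <- Ss
  }
  inits
}

# ---- driver -------------------------------------------------------------

default_monitors <- c("beta.rho", "beta.phi", "sig.delta.rho",
                      "sig.delta.phi", "sig.eps.rho", "sig.eps.phi",
                      "I.rho", "I.phi", "a.trap", "sigx", "phic",
                      "s2", "s35", "F5", "F6", "psi", "alpha0", "alpha1",
                      "B", "s1", "pstar", "pvecA", "pvecB", "N", "Rr",
                      "Ss", "rho", "sa")

prior_monitors <- c("beta.rho", "beta.phi", "sig.delta.rho",
                    "sig.delta.phi", "sig.eps.rho", "sig.eps.phi",
                    "a.trap", "sigx", "phic", "B", "s1", "s2", "s35",
                    "F5", "F6", "psi", "alpha0", "alpha1")

#' Fit the msIPM by MCMC
#'
#' Assembles the joint model for a dataset bundle (or, when `bundle` is
#' `NULL`, the priors alone), runs `n_chains >= 2` chains from dispersed
#' data-informed starting values, and returns draws, Gelman-Rubin
#' diagnostics and summaries. Random effects and latent abundances are
#' sampled as auxiliary variables. Runs are reproducible: the same seed
#' produces identical draws.
#'
#' @param bundle a [dataset_bundle()], or `NULL` for a prior-only run.
#' @param priors a [default_priors()] specification.
#' @param config a [study_config()] (defaults to the bundle's).
#' @param n_chains number of chains (>= 2 for convergence diagnostics).
#' @param n_iter posterior iterations kept per chain (after burn-in).
#' @param n_burnin iterations discarded after adaptation.
#' @param n_adapt JAGS adaptation steps.
#' @param n_thin thinning interval.
#' @param seed integer seed driving all chains.
#' @param monitor character vector of nodes to monitor (defaults cover all
#'   model parameters, derived synchrony indices and latent abundances).
#' @return object of class `"msipm_posterior"`: `samples` (a
#'   `coda::mcmc.list`), `rhat` (named vector), the run settings and the
#'   configuration.
#' @export
run_mcmc <- function(bundle, priors = default_priors(config),
                     config = bundle$config, n_chains = 2L,
                     n_iter = 2000L, n_burnin = 500L, n_adapt = 500L,
                     n_thin = 1L, seed = 1L, monitor = NULL) {
  if (n_chains < 2L) stop("need at least 2 chains for convergence diagnostics")
  prior_only <- is.null(bundle)
  if (prior_only) {
    model_txt <- jags_prior_model_string(config)
    dat <- list(T = config$n_years,
                sigxup = unname(priors$sigma_x_upper[c("R", "P", "M")]))
    if (is.null(monitor)) monitor <- prior_monitors
  } else {
    prep <- jags_prepare(bundle, priors, config)
    model_txt <- jags_model_string(config, prep$present)
    dat <- prep$data
    if (is.null(monitor)) monitor <- default_monitors
  }
  # a reduced model (e.g. no MRR observations) lacks some default nodes
  monitor <- monitor[vapply(monitor, function(m)
    grepl(m, model_txt, fixed = TRUE), logical(1))]
  inits <- lapply(seq_len(n_chains), function(ch) {
    ji <- jags_inits(if (prior_only) NULL else bundle, priors, config,
                     ch, seed)
    ji[intersect(names(ji), c(".RNG.name", ".RNG.seed",
                              jags_init_nodes(model_txt)))]
  })
  model <- tryCatch(
    rjags::jags.model(textConnection(model_txt), data = dat, inits = inits,
                      n.chains = n_chains, n.adapt = n_adapt,
                      quiet = TRUE),
    error = function(e) stop("JAGS failed to initialize the model: ",
                             conditionMessage(e), call. = FALSE))
  if (n_burnin > 0L) stats::update(model, n_burnin, progress.bar = "none")
  samples <- rjags::coda.samples(model, variable.names = monitor,
                                 n.iter = n_iter * n_thin, thin = n_thin,
                                 progress.bar = "none")
  rhat <- gelman_rubin(samples)
  structure(list(samples = samples, rhat = rhat, seed = seed,
                 n_chains = n_chains, n_iter = n_iter,
                 n_burnin = n_burnin, n_thin = n_thin, n_adapt = n_adapt,
                 config = config, prior_only = prior_only),
            class = "msipm_posterior")
}

# node names that appear as stochastic parents in the model text; used to
# drop initial values for nodes a reduced model does not contain
jags_init_nodes <- function(model_txt) {
  m <- gregexpr("([A-Za-z][A-Za-z0-9._]*)(\\[[^]]*\\])?[ \t]*~", model_txt)
  nm <- unlist(regmatches(model_txt, m))
  unique(sub("\\[.*", "", sub("[ \t]*~$", "", nm)))
}

#' @export
print.msipm_posterior <- function(x, ...) {
  cat(sprintf("msIPM posterior: %d chains x %d iterations (thin %d)%s\n",
              x$n_chains, x$n_iter, x$n_thin,
              if (x$prior_only) " [prior-only]" else ""))
  cat(sprintf("  %d monitored quantities, worst R-hat %.3f (%s)\n",
              length(x$rhat), max(x$rhat, na.rm = TRUE),
              names(x$rhat)[which.max(x$rhat)]))
  invisible(x)
}

#' Gelman-Rubin potential scale reduction
#'
#' The split between- and within-chain variance comparison computed for
#' every monitored scalar: with `m` chains of length `n`, within-chain
#' variance `W`, between-chain variance `B/n`,
#' `Rhat = sqrt(((n-1)/n W + B/n) / W)`. Chains that are all constant and
#' identical have no scale to reduce; they are flagged with `NA` rather
#' than an error.
#'
#' @param chains a `coda::mcmc.list`, or a list of equal-size matrices
#'   (iterations x parameters), one per chain.
#' @return named numeric vector of R-hat values.
#' @export
gelman_rubin <- function(chains) {
  if (inherits(chains, "mcmc.list")) {
    chains <- lapply(chains, function(ch) as.matrix(ch))
  }
  if (!is.list(chains) || length(chains) < 2L) {
    stop("need at least two chains of equal length")
  }
  dims <- vapply(chains, dim, integer(2L))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L])) {
    stop("chains must have identical dimensions")
  }
  n <- dims[1L, 1L]
  m <- length(chains)
  p <- dims[2L, 1L]
  out <- numeric(p)
  for (j in seq_len(p)) {
    draws <- vapply(chains, function(ch) ch[, j], numeric(n))
    mns <- colMeans(draws)
    W <- mean(apply(draws, 2L, stats::var))
    if (W == 0) {
      out[j] <- if (stats::var(mns) == 0) NA_real_ else Inf
      next
    }
    B_over_n <- stats::var(mns)
    out[j] <- sqrt(((n - 1) / n * W + B_over_n) / W)
  }
  names(out) <- colnames(chains[[1L]])
  out
}
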