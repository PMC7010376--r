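toy_latent <- function(Tn = 8L, d = 5L, seed = 5L) {
  set.seed(seed)
  N <- R <- S <- rep(NA_real_, Tn)
  N[1:d] <- 100
  for (t in (d + 1):Tn) {
    R[t] <- rbinom(1, N[t - d], 0.12)
    S[t] <- rbinom(1, N[t - 1], 0.9)
    N[t] <- R[t] + S[t]
  }
  latent_population(N, R, S, d)
}

test_that("combined-juvenile-survival system likelihood matches a direct pmf oracle", {
  Tn <- 8L; d <- 5L
  lat <- toy_latent(Tn, d)
  set.seed(6)
  rho <- runif(Tn, 0.5, 0.8)
  s_a <- runif(Tn - 1, 0.85, 0.95)
  phi_c <- 0.5
  want <- 0
  for (t in (d + 1):Tn) {
    pR <- rho[t - d] * phi_c / 2 * s_a[t - 1]
    want <- want + oracle_lbinom(lat$R[t], lat$N[t - d], pR) +
      oracle_lbinom(lat$S[t], lat$N[t - 1], s_a[t - 1])
  }
  expect_equal(rp_system_loglik(lat, rho, s_a, phi_c), want,
               tolerance = 1e-10)
})

test_that("recruit rate composes productivity, combined survival, the female factor and adult survival", {
  # a trajectory with a single certain recruit year pins the rate exactly
  Tn <- 6L; d <- 5L
  N <- c(rep(1, 5), 1)
  R <- c(rep(NA, 5), 1)
  S <- c(rep(NA, 5), 0)
  lat <- latent_population(N, R, S, d)
  rho <- rep(0.6, Tn); s_a <- rep(0.9, Tn - 1); phi_c <- 0.5
  pR <- rho[1] * phi_c / 2 * s_a[5]
  want <- log(pR) + log(1 - s_a[5])
  expect_equal(rp_system_loglik(lat, rho, s_a, phi_c), want,
               tolerance = 1e-12)
})

test_that("murre system likelihood matches the oracle and reduces to the combined form", {
  Tn <- 9L; d <- 6L
  set.seed(7)
  N <- R <- S <- rep(NA_real_, Tn)
  N[1:d] <- 300
  for (t in (d + 1):Tn) {
    R[t] <- rbinom(1, N[t - d], 0.05)
    S[t] <- rbinom(1, N[t - 1], 0.92)
    N[t] <- R[t] + S[t]
  }
  lat <- latent_population(N, R, S, d)
  B <- runif(Tn, 0.85, 0.98)
  rho <- runif(Tn, 0.5, 0.8)
  s1 <- runif(Tn - 1, 0.3, 0.7)
  s_a <- runif(Tn - 1, 0.88, 0.96)
  s2 <- 0.76; s35 <- 0.9; F5 <- 0.86; F6 <- 0.83
  want <- 0
  for (t in (d + 1):Tn) {
    tau <- B[t - 6] * rho[t - 6] * 0.5 * s1[t - 6] * s2 * s35^3 * F5 * F6
    want <- want + oracle_lbinom(lat$R[t], lat$N[t - 6], tau * s_a[t - 1]) +
      oracle_lbinom(lat$S[t], lat$N[t - 1], s_a[t - 1])
  }
  got <- murre_system_loglik(lat, B, rho, s1, s2, s35, F5, F6, s_a)
  expect_equal(got, want, tolerance = 1e-10)

  # with B = 1 and unit later-age survival/fidelity the rate collapses to
  # the combined-juvenile form with phi_c = s1
  got2 <- murre_system_loglik(lat, rep(1, Tn), rho, rep(0.5, Tn - 1),
                              1, 1, 1, 1, s_a)
  lat6 <- lat
  want2 <- rp_system_loglik(lat6, rho, s_a, 0.5, d = 6L)
  expect_equal(got2, want2, tolerance = 1e-10)

  # s35 enters cubed: d log(tau) / d s35 = 3 / s35
  eps <- 1e-6
  l1 <- murre_system_loglik(lat, B, rho, s1, s2, s35 + eps, F5, F6, s_a)
  l0 <- murre_system_loglik(lat, B, rho, s1, s2, s35 - eps, F5, F6, s_a)
  # compare against the analytic derivative of the recruit terms
  grad_num <- (l1 - l0) / (2 * eps)
  grad_an <- 0
  for (t in (d + 1):Tn) {
    tau <- B[t - 6] * rho[t - 6] * 0.5 * s1[t - 6] * s2 * s35^3 * F5 * F6
    pr <- tau * s_a[t - 1]
    grad_an <- grad_an +
      (lat$R[t] / pr - (lat$N[t - 6] - lat$R[t]) / (1 - pr)) *
      pr * 3 / s35
  }
  expect_equal(grad_num, grad_an, tolerance = 1e-3)
})

test_that("impossible latent configurations score -Inf, valid simulated ones are finite", {
  Tn <- 8L; d <- 5L
  lat <- toy_latent(Tn, d)
  rho <- rep(0.6, Tn); s_a <- rep(0.9, Tn - 1)
  expect_true(is.finite(rp_system_loglik(lat, rho, s_a, 0.5)))
  neg <- lat
  neg$R[7] <- -1
  neg$N[7] <- neg$R[7] + neg$S[7]
  expect_error(latent_population(neg$N, neg$R, neg$S, d), "non-negative")
  bad2 <- lat
  bad2$S[7] <- bad2$N[6] + 5
  bad2$N[7] <- bad2$R[7] + bad2$S[7]
  lat2 <- latent_population(bad2$N, bad2$R, bad2$S, d)
  expect_identical(rp_system_loglik(lat2, rho, s_a, 0.5), -Inf)
})

test_that("observation likelihood handles missing counts and matches the normal density", {
  Tn <- 8L; d <- 5L
  lat <- toy_latent(Tn, d)
  x <- lat$N
  expect_equal(observation_loglik(x, lat, 1),
               -(Tn - d) * log(sqrt(2 * pi)), tolerance = 1e-12)
  # a single observation with residual 2 and sd 2
  x2 <- rep(NA_real_, Tn)
  x2[7] <- lat$N[7] + 2
  expect_equal(observation_loglik(x2, lat, 2),
               -log(2 * sqrt(2 * pi)) - 0.5, tolerance = 1e-12)
  expect_equal(observation_loglik(x2, lat, 2), oracle_lnorm(2, 0, 2),
               tolerance = 1e-12)
  expect_error(observation_loglik(x, lat, 0), "sigma_x")
})

test_that("sparse puffin counts contribute exactly the post-initialization observed years", {
  cfg <- study_config()
  x <- rep(NA_real_, cfg$n_years)
  x[cfg$puffin_count_years] <- 10000
  d <- cfg$d[["P"]]
  contributing <- sum(!is.na(x[(d + 1):cfg$n_years]))
  expect_identical(contributing, 5L)  # 1992, 1998, 2003, 2008, 2009
})

test_that("initialization means interpolate between the nearest counted years", {
  cfg <- study_config()
  x <- rep(NA_real_, cfg$n_years)
  x[1] <- 11390   # 1984 anchor
  x[6] <- 20000   # 1989 anchor
  x[9] <- 26000   # 1992 anchor
  m <- init_prior_means(x, d = 7L)
  expect_equal(m[1], 11390)
  expect_equal(m[6], 20000)
  # 1986 sits two fifths of the way from 1984 to 1989
  expect_equal(m[3], 11390 + 2 / 5 * (20000 - 11390), tolerance = 1e-9)
  # 1990 interpolates the 1989 -> 1992 anchors
  expect_equal(m[7], 20000 + 1 / 3 * (26000 - 20000), tolerance = 1e-9)
  # complete counts: the means are the observed counts themselves
  xm <- seq(100, 100 + cfg$n_years - 1)
  expect_equal(init_prior_means(xm, 6L), xm[1:6])
  # d = 1 reduces to a single normal term
  lat <- toy_latent(8L, 5L)
  expect_equal(init_prior_logpdf(lat, rep(100, 5), 10),
               sum(oracle_lnorm(lat$N[1:5], 100, 10)), tolerance = 1e-12)
})

test_that("iterated mean recursion matches simulated trajectories", {
  # small frame, many replicates: E[N(t)] from the deterministic recursion
  scen <- tiny_scenario(10L)
  set.seed(77)
  params <- msipm:::simulate_parameters(scen)
  nrep <- 600
  sims <- replicate(nrep, simulate_latents(scen, params)$latent$R$N)
  cfg <- scen$config
  d <- cfg$d[["R"]]
  rho <- assemble_rate_series(params$sync_rho, "R")
  s_a <- assemble_rate_series(params$sync_phi, "R")
  EN <- rep(NA_real_, cfg$n_years)
  EN[1:d] <- scen$init_N[["R"]]
  for (t in (d + 1):cfg$n_years) {
    tau <- rho[t - d] * params$phi_c[["R"]] / 2
    EN[t] <- EN[t - d] * tau * s_a[t - 1] + EN[t - 1] * s_a[t - 1]
  }
  mn <- rowMeans(sims)
  se <- apply(sims, 1, sd) / sqrt(nrep)
  tt <- (d + 1):cfg$n_years
  expect_true(all(abs(mn[tt] - EN[tt]) <= 3 * se[tt] + 1e-9))
})
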