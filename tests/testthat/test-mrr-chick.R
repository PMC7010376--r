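make_structural <- function(config, p_const = 0.4, lambda_trend = TRUE) {
  Tn <- config$n_years
  p <- lapply(c(A = "A", B = "B"), function(ar)
    lapply(config$windows[[ar]], function(win) rep(p_const, length(win))))
  mrr_structural_params(
    s1 = rep(0.55, Tn - 1), s2 = 0.76, s35 = 0.9,
    s_a = rep(0.93, Tn - 1), F5 = 0.86, F6 = 0.83, psi = 0.85,
    alpha0 = -3, alpha1 = if (lambda_trend) -0.7 else 0,
    p = p, config = config)
}

test_that("age/year expansion follows the structural model", {
  cfg <- study_config(n_years = 12L, areaB_last_banding = 5L,
                      puffin_count_years = c(1L, 6L, 9L, 12L))
  st <- make_structural(cfg)
  ex <- assemble_age_year_params(st, cfg, "A")
  # fidelity fixed at one before age 5
  expect_identical(ex$F[1:4], rep(1, 4))
  expect_equal(ex$F[5], 0.86)
  expect_equal(ex$F[6], 0.83)
  expect_equal(ex$F[7:cfg$max_age], rep(0.85, cfg$max_age - 6))
  # first-years are never resighted
  expect_identical(ex$p[1, ], rep(0, 12))
  # survival rows
  expect_equal(ex$phi[1, ], st$s1)
  expect_equal(ex$phi[3, ], rep(0.9, 11))
  expect_equal(ex$phi[8, ], st$s_a)
  # reporting with no trend is constant
  ex0 <- assemble_age_year_params(make_structural(cfg, lambda_trend = FALSE),
                                  cfg, "A")
  expect_equal(ex0$lambda, rep(plogis(-3), 11), tolerance = 1e-12)
  # with a trend it is logit-linear in the standardized occasion
  y <- (1:11 - mean(1:11)) / sd(1:11)
  expect_equal(ex$lambda, plogis(-3 - 0.7 * y), tolerance = 1e-12)
})

test_that("resight windows gate the probabilities per area", {
  cfg <- study_config()  # T = 26, area B banding to t = 14
  expect_identical(cfg$windows$A$p2, 3:26)
  expect_identical(cfg$windows$B$p2, 3:17)
  expect_identical(cfg$windows$B$p3, 4:18)
  expect_identical(cfg$windows$B$p45, 5:20)
  expect_identical(cfg$windows$B$pa, 7:26)
  st <- make_structural(cfg)
  exB <- assemble_age_year_params(st, cfg, "B")
  expect_identical(exB$p[2, 18:26], rep(0, 9))  # outside the p2 window
  expect_equal(exB$p[2, 17], 0.4)
  expect_identical(exB$p[4, 21:26], rep(0, 6))  # outside the p45 window
})

test_that("recursion base cases match the printed forms", {
  cfg <- study_config(n_years = 10L, areaB_last_banding = 3L,
                      puffin_count_years = c(1L, 6L, 9L))
  st <- make_structural(cfg)
  ex <- assemble_age_year_params(st, cfg, "A")
  tb <- compute_mrr_tables(ex, cfg)
  # chi at the final occasion is one for every age and state
  expect_true(all(tb$chi1[cbind(1:10, 10)] == 1))
  expect_true(all(tb$chi0[cbind(1:10, 10)] == 1))
  # same-age transition: survive and stay
  for (a in c(1, 4, 6)) {
    for (t in seq(a, 9)) {
      expect_equal(tb$Q11[a, a, t], ex$phi[a, t] * ex$F[a],
                   tolerance = 1e-12)
    }
  }
})

test_that("with full fidelity and no recoveries the MRR chi reduces to CJS", {
  cfg <- study_config(n_years = 9L, areaB_last_banding = 2L,
                      puffin_count_years = c(1L, 6L, 9L))
  Tn <- cfg$n_years
  p <- lapply(c(A = "A", B = "B"), function(ar)
    lapply(cfg$windows[[ar]], function(win) runif(length(win), 0.2, 0.8)))
  set.seed(3)
  st <- mrr_structural_params(
    s1 = runif(Tn - 1, 0.3, 0.9), s2 = 0.7, s35 = 0.88,
    s_a = runif(Tn - 1, 0.85, 0.97), F5 = 1, F6 = 1, psi = 1,
    alpha0 = -40, alpha1 = 0, p = p, config = cfg)  # lambda ~ 0
  ex <- assemble_age_year_params(st, cfg, "A")
  tb <- compute_mrr_tables(ex, cfg)
  chi_cjs <- oracle_cjs_chi_by_age(ex$phi, ex$p, cfg$max_age, Tn)
  for (a in 1:(cfg$max_age - 1)) {
    for (t in seq(a, Tn)) {
      expect_equal(tb$chi1[a, t], chi_cjs[a, t], tolerance = 1e-12)
    }
  }
})

test_that("cohort cells normalize and match exhaustive fate enumeration", {
  set.seed(21)
  for (frame in list(c(A = 3L, Tn = 4L), c(A = 4L, Tn = 5L))) {
    A <- frame[["A"]]; Tn <- frame[["Tn"]]
    cfg <- toy_config(A, Tn)
    for (draw in 1:20) {
      par <- random_mrr_tables_input(A, Tn)
      tb <- compute_mrr_tables(par, cfg)
      for (a0 in 1:(A - 1)) {
        for (t0 in a0:(Tn - 1)) {
          got <- mrr_cohort_cell_probs(a0, t0, tb, cfg)
          want <- oracle_mrr_cells(a0, t0, par, A, Tn)
          expect_equal(sum(got), 1, tolerance = 1e-10)
          expect_equal(got[names(want)], want, tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("nothing is observable when resighting and reporting are off", {
  A <- 4L; Tn <- 5L
  cfg <- toy_config(A, Tn)
  par <- random_mrr_tables_input(A, Tn)
  par$p[] <- 0
  par$lambda[] <- 0
  tb <- compute_mrr_tables(par, cfg)
  cells <- mrr_cohort_cell_probs(1, 1, tb, cfg)
  expect_equal(unname(cells["chi"]), 1, tolerance = 1e-12)
  expect_true(all(cells[names(cells) != "chi"] == 0))
})

test_that("raising reporting uniformly cannot decrease any recovery cell", {
  set.seed(31)
  A <- 4L; Tn <- 5L
  cfg <- toy_config(A, Tn)
  par <- random_mrr_tables_input(A, Tn)
  par$lambda <- rep(0.2, Tn - 1)
  tb1 <- compute_mrr_tables(par, cfg)
  par$lambda <- rep(0.5, Tn - 1)
  tb2 <- compute_mrr_tables(par, cfg)
  ok <- !is.na(tb1$D)
  expect_true(all(tb2$D[ok] >= tb1$D[ok] - 1e-14))
})

test_that("mrr_loglik scores sufficient statistics correctly", {
  cfg <- study_config(n_years = 8L, areaB_last_banding = 2L,
                      puffin_count_years = c(1L, 6L, 8L))
  st <- make_structural(cfg)
  emptyA <- msipm:::empty_mrr_stats(cfg)
  expect_identical(mrr_loglik(emptyA, emptyA, st, cfg), 0)

  # one bird released at age 1, occasion 2, next seen at age 3
  n <- array(0L, c(cfg$max_age, cfg$max_age, 8L))
  n[1, 2, 2] <- 1L
  v <- matrix(0L, cfg$max_age, 8L)
  v[3, 4] <- 1L
  one <- mrr_sufficient_stats(n, array(0L, dim(n)), v, cfg)
  tb <- compute_mrr_tables(assemble_age_year_params(st, cfg, "A"), cfg)
  expect_equal(mrr_loglik(one, msipm:::empty_mrr_stats(cfg), st, cfg),
               log(tb$O[1, 2, 2]) + log(tb$chi1[3, 4]), tolerance = 1e-12)

  # positive count on a structurally zero cell (age-1 resight) is -Inf
  n2 <- array(0L, dim(n))
  n2[1, 1, 2] <- 1L  # next seen at age 2 occasion 3 is fine...
  v2 <- matrix(0L, cfg$max_age, 8L)
  v2[2, 3] <- 1L
  ok <- mrr_sufficient_stats(n2, array(0L, dim(n)), v2, cfg)
  expect_true(is.finite(mrr_loglik(ok, msipm:::empty_mrr_stats(cfg), st, cfg)))
  n3 <- array(0L, dim(n)); v3 <- matrix(0L, cfg$max_age, 8L)
  n3[2, 2, 3] <- 1L  # area B: age-3 resight at occasion 4 is inside p3 window
  v3[3, 4] <- 1L
  expect_true(is.finite(mrr_loglik(
    msipm:::empty_mrr_stats(cfg),
    mrr_sufficient_stats(n3, array(0L, dim(n)), v3, cfg), st, cfg)))
  # age-2 resight in area B past its window end (window 3..6, resight at 7)
  n4 <- array(0L, dim(n)); v4 <- matrix(0L, cfg$max_age, 8L)
  n4[1, 1, 6] <- 1L
  v4[2, 7] <- 1L
  cfg6 <- study_config(n_years = 8L, areaB_last_banding = 3L,
                       puffin_count_years = c(1L, 6L, 8L))
  expect_identical(
    mrr_loglik(msipm:::empty_mrr_stats(cfg6),
               mrr_sufficient_stats(n4, array(0L, dim(n)), v4, cfg6),
               make_structural(cfg6), cfg6),
    -Inf)
})
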