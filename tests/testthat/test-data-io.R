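test_that("a minimal hand-built bundle reads, validates and round-trips", {
  dir <- withr::local_tempdir()
  cfg <- study_config(n_years = 5L, first_year = 2001L,
                      d = c(R = 2L, P = 3L, M = 2L),
                      areaB_last_banding = 2L,
                      puffin_count_years = c(1L, 3L, 5L))
  years <- 2001:2005
  write.csv(data.frame(
    species = rep(c("R", "P", "M"), each = 5),
    year = rep(years, 3),
    pairs = c(10, 11, NA, 13, 14, 100, NA, NA, 130, 140, 55, 56, 57, 58, 59)),
    file.path(dir, "counts.csv"), row.names = FALSE, na = "")
  write.csv(data.frame(
    species = rep(c("R", "P", "M"), each = 5), year = rep(years, 3),
    monitored = rep(4, 15), fledged = rep(2, 15)),
    file.path(dir, "breeding_success.csv"), row.names = FALSE)
  write.csv(data.frame(year = years, monitored = 10, bred = 9),
            file.path(dir, "nonbreeding.csv"), row.names = FALSE)
  hist <- data.frame(species = c("R", "R", "R"), id = c("r1", "r2", "r3"),
                     mark_year = c(2001, 2002, 2002))
  wcols <- matrix(0L, 3, 5, dimnames = list(NULL, paste0("y", years)))
  wcols[1, c(1, 3)] <- 1L
  wcols[2, 2] <- 1L
  wcols[3, c(2, 5)] <- 1L
  write.csv(cbind(hist, wcols), file.path(dir, "adult_histories.csv"),
            row.names = FALSE)
  write.csv(data.frame(id = "c1", area = "A", band_year = 2001,
                       resight_years = "2005", recovery_year = NA),
            file.path(dir, "chick_records.csv"), row.names = FALSE, na = "")

  b <- read_bundle(dir, cfg)
  expect_s3_class(b, "msipm_bundle")
  expect_identical(nrow(b$adults$R$w), 3L)
  expect_true(is.na(b$counts[3, "R"]))
  expect_identical(unname(b$counts[1, "M"]), 55)
  # the chick record became sufficient statistics: banded age 1 at t=1,
  # resighted age 5 at t=5 (the first window-legal class for that cohort),
  # never seen again
  expect_identical(b$mrr$A$n[1, 4, 1], 1L)
  expect_identical(b$mrr$A$v[5, 5], 1L)
  expect_identical(sum(b$mrr$A$n) + sum(b$mrr$A$v) + sum(b$mrr$A$d), 2L)

  # round trip: write, re-read, re-write; the two written copies match
  out1 <- file.path(dir, "copy1")
  out2 <- file.path(dir, "copy2")
  write_bundle(b, out1)
  b2 <- read_bundle(out1, cfg)
  write_bundle(b2, out2)
  for (f in list.files(out1)) {
    expect_identical(readLines(file.path(out2, f)),
                     readLines(file.path(out1, f)), label = f)
  }
})

test_that("schema violations raise errors naming file and row", {
  dir <- withr::local_tempdir()
  cfg <- study_config(n_years = 5L, first_year = 2001L,
                      d = c(R = 2L, P = 3L, M = 2L),
                      areaB_last_banding = 2L,
                      puffin_count_years = c(1L, 3L, 5L))
  years <- 2001:2005
  write.csv(data.frame(species = rep(c("R", "P", "M"), each = 5),
                       year = rep(years, 3), pairs = 10),
            file.path(dir, "counts.csv"), row.names = FALSE)
  bsf <- data.frame(species = rep(c("R", "P", "M"), each = 5),
                    year = rep(years, 3), monitored = rep(4, 15),
                    fledged = rep(2, 15))
  bsf$fledged[2] <- 5  # C > E in row 2
  write.csv(bsf, file.path(dir, "breeding_success.csv"), row.names = FALSE)
  write.csv(data.frame(year = years, monitored = 10, bred = 9),
            file.path(dir, "nonbreeding.csv"), row.names = FALSE)
  expect_error(read_bundle(dir, cfg), "breeding_success.csv row 2")

  bsf$fledged[2] <- 2
  write.csv(bsf, file.path(dir, "breeding_success.csv"), row.names = FALSE)
  write.csv(data.frame(year = years, monitored = 10,
                       bred = c(9, 11, 9, 9, 9)),
            file.path(dir, "nonbreeding.csv"), row.names = FALSE)
  expect_error(read_bundle(dir, cfg), "nonbreeding.csv row 2")

  write.csv(data.frame(year = years, monitored = 10, bred = 9),
            file.path(dir, "nonbreeding.csv"), row.names = FALSE)
  hist <- data.frame(species = "R", id = "r1", mark_year = 2003)
  wcols <- matrix(0L, 1, 5, dimnames = list(NULL, paste0("y", years)))
  wcols[1, 2] <- 1L  # sighting before marking
  wcols[1, 3] <- 1L
  write.csv(cbind(hist, wcols), file.path(dir, "adult_histories.csv"),
            row.names = FALSE)
  expect_error(read_bundle(dir, cfg), "sighting before marking")
})

test_that("sufficient statistics match hand enumeration of single histories", {
  cfg <- study_config(n_years = 8L, areaB_last_banding = 2L,
                      puffin_count_years = c(1L, 6L, 8L))
  # banded at t0 = 1, resighted at age 5 (t = 5), never seen again
  rec <- data.frame(id = "x", area = "A", band_occasion = 1L,
                    resight_occasions = "5",
                    recovery_occasion = NA_integer_)
  st <- build_mrr_sufficient_stats(rec, cfg)
  expect_identical(st$A$n[1, 4, 1], 1L)
  expect_identical(st$A$v[5, 5], 1L)
  expect_identical(sum(st$A$n), 1L)
  expect_identical(sum(st$A$v), 1L)
  expect_identical(sum(st$A$d) + sum(st$B$n) + sum(st$B$d) + sum(st$B$v), 0L)

  # banded at t0 = 1, recovered dead before age 2 (report at t = 2)
  rec2 <- data.frame(id = "y", area = "A", band_occasion = 1L,
                     resight_occasions = "", recovery_occasion = 2L)
  st2 <- build_mrr_sufficient_stats(rec2, cfg)
  expect_identical(st2$A$d[1, 1, 1], 1L)
  expect_identical(sum(st2$A$v), 0L)
  expect_identical(sum(st2$A$n), 0L)

  # empty record set: all-zero arrays
  st0 <- build_mrr_sufficient_stats(rec[0, ], cfg)
  expect_identical(sum(st0$A$n) + sum(st0$A$d) + sum(st0$A$v) +
                     sum(st0$B$n) + sum(st0$B$d) + sum(st0$B$v), 0L)

  # inconsistent records are rejected
  bad <- data.frame(id = "z", area = "A", band_occasion = 3L,
                    resight_occasions = "2", recovery_occasion = NA_integer_)
  expect_error(build_mrr_sufficient_stats(bad, cfg), "before marking")
  bad2 <- data.frame(id = "z", area = "A", band_occasion = 1L,
                     resight_occasions = "5",
                     recovery_occasion = 4L)
  expect_error(build_mrr_sufficient_stats(bad2, cfg), "recovery occasion")
  # age-2 resight in area B outside its window
  bad3 <- data.frame(id = "z", area = "B", band_occasion = 5L,
                     resight_occasions = "6",
                     recovery_occasion = NA_integer_)
  expect_error(build_mrr_sufficient_stats(bad3, cfg), "structurally zero")
})

test_that("sufficient statistics agree with a naive per-bird double loop on random histories", {
  scen <- tiny_scenario()
  cfg <- scen$config
  set.seed(123)
  sim <- simulate_bundle(scen, seed = 99)
  recs <- sim$bundle$chick_records
  st <- build_mrr_sufficient_stats(recs, cfg)
  # naive recount: walk each bird's observation sequence independently
  for (area in c("A", "B")) {
    n2 <- array(0L, dim(st[[area]]$n))
    d2 <- array(0L, dim(st[[area]]$d))
    v2 <- matrix(0L, nrow(st[[area]]$v), ncol(st[[area]]$v))
    rows <- recs[recs$area == area, ]
    for (i in seq_len(nrow(rows))) {
      t0 <- rows$band_occasion[i]
      rs <- if (nzchar(rows$resight_occasions[i]))
        as.integer(strsplit(rows$resight_occasions[i], ";")[[1]]) else integer(0)
      occs <- c(t0, sort(rs))
      ages <- occs - t0 + 1L
      if (length(occs) > 1) {
        for (k in 1:(length(occs) - 1)) {
          n2[ages[k], ages[k + 1] - 1L, occs[k]] <-
            n2[ages[k], ages[k + 1] - 1L, occs[k]] + 1L
        }
      }
      last <- length(occs)
      if (!is.na(rows$recovery_occasion[i])) {
        b <- rows$recovery_occasion[i] - t0
        d2[ages[last], b, occs[last]] <- d2[ages[last], b, occs[last]] + 1L
      } else {
        v2[ages[last], occs[last]] <- v2[ages[last], occs[last]] + 1L
      }
    }
    expect_identical(st[[area]]$n, n2)
    expect_identical(st[[area]]$d, d2)
    expect_identical(st[[area]]$v, v2)
  }
  # release accounting: every observation event is partitioned exactly once
  relA <- msipm:::mrr_release_totals(st$A)
  n_chicksA <- sum(recs$area == "A")
  n_eventsA <- n_chicksA + sum(vapply(
    recs$resight_occasions[recs$area == "A"],
    function(s) if (nzchar(s)) length(strsplit(s, ";")[[1]]) else 0L,
    integer(1)))
  expect_identical(as.integer(sum(relA)), as.integer(n_eventsA))
})

test_that("posterior summaries are draw-order invariant and medians recompute from draws", {
  # a small synthetic posterior object
  set.seed(8)
  m1 <- coda::mcmc(matrix(rnorm(600), 200, 3,
                          dimnames = list(NULL, c("x", "y", "z"))))
  m2 <- coda::mcmc(matrix(rnorm(600), 200, 3,
                          dimnames = list(NULL, c("x", "y", "z"))))
  res <- structure(list(samples = coda::mcmc.list(m1, m2),
                        rhat = gelman_rubin(coda::mcmc.list(m1, m2)),
                        seed = 1, n_chains = 2, n_iter = 200,
                        n_burnin = 0, n_thin = 1,
                        config = study_config(), prior_only = FALSE),
                   class = "msipm_posterior")
  s1 <- summarize_posterior(res)
  draws <- rbind(as.matrix(m1), as.matrix(m2))
  expect_equal(s1$median, unname(apply(draws, 2, median)), tolerance = 1e-12)
  expect_equal(s1$lower,
               unname(apply(draws, 2, quantile, 0.025, type = 7)),
               tolerance = 1e-12)
  # permuting draws within chains leaves the summary unchanged
  perm <- sample(200)
  res2 <- res
  res2$samples <- coda::mcmc.list(coda::mcmc(as.matrix(m1)[perm, ]),
                                  coda::mcmc(as.matrix(m2)[perm, ]))
  s2 <- summarize_posterior(res2)
  expect_equal(s2$median, s1$median, tolerance = 1e-12)
  expect_equal(s2$lower, s1$lower, tolerance = 1e-12)
  expect_equal(s2$upper, s1$upper, tolerance = 1e-12)

  # write_results emits the three artifacts
  dir <- withr::local_tempdir()
  write_results(res, dir)
  expect_true(file.exists(file.path(dir, "parameter_summary.csv")))
  expect_true(file.exists(file.path(dir, "run_meta.json")))
  summ_csv <- read.csv(file.path(dir, "parameter_summary.csv"))
  expect_identical(nrow(summ_csv), 3L)
  meta <- jsonlite::read_json(file.path(dir, "run_meta.json"))
  expect_equal(meta$worst_rhat, max(res$rhat), tolerance = 1e-6)
})
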