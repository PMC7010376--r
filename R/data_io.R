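#' Dataset bundle for the three-species community
#'
#' All observed data consumed by the msIPM: per-species whole-colony
#' counts (missing years allowed — a missing count is `NA`, never 0),
#' breeding-success series and adult encounter histories; and, for murres
#' only, the non-breeding series and the chick MRR sufficient statistics
#' for banding areas A and B (optionally accompanied by the raw chick
#' encounter records they were built from).
#'
#' @param counts numeric `T x 3` matrix (columns R, P, M), `NA` where no
#'   count was made.
#' @param bs list of [breeding_success_series()] named R, P, M.
#' @param nb a [nonbreeding_series()].
#' @param adults list of [adult_histories()] named R, P, M (an element may
#'   be `NULL` if no adults were marked).
#' @param mrr list with [mrr_sufficient_stats()] elements `A` and `B`.
#' @param config a [study_config()].
#' @param chick_records optional data frame of raw chick encounter records
#'   (see [build_mrr_sufficient_stats()]).
#' @return object of class `"msipm_bundle"`.
#' @export
dataset_bundle <- function(counts, bs, nb, adults, mrr, config,
                           chick_records = NULL) {
  Tn <- config$n_years
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == Tn, ncol(counts) == 3L)
  colnames(counts) <- c("R", "P", "M")
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be >= 0")
  for (sp in c("R", "P", "M")) {
    stopifnot(inherits(bs[[sp]], "msipm_breeding_success"),
              length(bs[[sp]]$E) == Tn)
    if (!is.null(adults[[sp]])) {
      stopifnot(inherits(adults[[sp]], "msipm_adult_histories"),
                ncol(adults[[sp]]$w) == Tn)
    }
  }
  stopifnot(inherits(nb, "msipm_nonbreeding"), length(nb$xi_m) == Tn,
            inherits(mrr$A, "msipm_mrr_stats"),
            inherits(mrr$B, "msipm_mrr_stats"))
  structure(list(config = config, counts = counts, bs = bs, nb = nb,
                 adults = adults, mrr = mrr, chick_records = chick_records),
            class = "msipm_bundle")
}

#' @export
print.msipm_bundle <- function(x, ...) {
  cat(sprintf("msIPM dataset bundle: %d occasions\n", x$config$n_years))
  for (sp in c("R", "P", "M")) {
    nb_ad <- if (is.null(x$adults[[sp]])) 0L else nrow(x$adults[[sp]]$w)
    cat(sprintf("  %s: %d counts, %d monitored pair-years, %d adult histories\n",
                x$config$species_names[[sp]], sum(!is.na(x$counts[, sp])),
                sum(x$bs[[sp]]$E > 0, na.rm = TRUE), nb_ad))
  }
  rel <- sum(mrr_release_totals(x$mrr$A)) + sum(mrr_release_totals(x$mrr$B))
  cat(sprintf("  murre chick MRR: %d cohort observations (areas A+B)\n", rel))
  invisible(x)
}

#' Build chick MRR sufficient statistics from raw encounter records
#'
#' Each record is one banded chick: the banding occasion (the bird is aged
#' `a` at occasion `band_occasion + a - 1`, so banding is the age-1
#' observation), the occasions of live resightings, and the occasion at
#' which its band was reported after death, if any (the report falls the
#' occasion after the bird's last year alive, so a bird dying aged `b` is
#' reported at occasion `band_occasion + b`). Each consecutive pair of live
#' observations at (age `a`, year `t`) then (age `b + 1`) increments
#' `n[a, b, t]`; a dead recovery aged `b` after a last live observation at
#' `(a, t)` increments `d[a, b, t]`; the final live observation of a
#' never-recovered bird increments `v[a, t]`. The initial release counts as
#' a live observation.
#'
#' @param records data frame with columns `id`, `area` (`"A"`/`"B"`),
#'   `band_occasion`, `resight_occasions` (semicolon-separated occasions,
#'   `""` for none) and `recovery_occasion` (`NA` for none).
#' @param config a [study_config()].
#' @return list of [mrr_sufficient_stats()] named `A` and `B`.
#' @export
build_mrr_sufficient_stats <- function(records, config) {
  Tn <- config$n_years
  A <- config$max_age
  arrays <- list()
  for (area in c("A", "B")) {
    arrays[[area]] <- list(n = array(0L, c(A, A, Tn)),
                           d = array(0L, c(A, A, Tn)),
                           v = matrix(0L, A, Tn))
  }
  parse_resights <- function(s) {
    if (is.na(s) || !nzchar(s)) return(integer(0))
    sort(as.integer(strsplit(s, ";", fixed = TRUE)[[1L]]))
  }
  for (i in seq_len(nrow(records))) {
    rec <- records[i, ]
    area <- as.character(rec$area)
    if (!area %in% c("A", "B")) stop(sprintf("row %d: unknown area '%s'", i, area))
    t0 <- as.integer(rec$band_occasion)
    if (t0 < 1L || t0 > Tn) stop(sprintf("row %d: banding occasion out of range", i))
    rs <- parse_resights(as.character(rec$resight_occasions))
    if (length(rs) && (any(rs <= t0) || any(rs > Tn))) {
      stop(sprintf("row %d: resighting before marking or beyond the study", i))
    }
    ages <- c(1L, rs - t0 + 1L)
    occs <- c(t0, rs)
    if (any(ages > A)) stop(sprintf("row %d: resighting above the maximum tracked age", i))
    # live resightings must fall inside the configured window of their class
    for (k in seq_along(rs)) {
      a_k <- ages[k + 1L]
      cl <- resight_age_class(a_k)
      if (cl == "p1" || !(rs[k] %in% config$windows[[area]][[cl]])) {
        stop(sprintf("row %d: resighting at age %d, occasion %d lies in a structurally zero resight window (area %s)",
                     i, a_k, rs[k], area))
      }
    }
    n_obs <- length(occs)
    if (n_obs > 1L) {
      for (k in seq_len(n_obs - 1L)) {
        a <- ages[k]
        b <- ages[k + 1L] - 1L
        arrays[[area]]$n[a, b, occs[k]] <- arrays[[area]]$n[a, b, occs[k]] + 1L
      }
    }
    a_last <- ages[n_obs]
    t_last <- occs[n_obs]
    tr <- rec$recovery_occasion
    if (!is.na(tr)) {
      tr <- as.integer(tr)
      if (tr <= t_last || tr > Tn) {
        stop(sprintf("row %d: recovery occasion must follow the last live sighting and lie within the study", i))
      }
      b <- tr - t0  # age in the bird's last year alive
      if (b > A - 1L) stop(sprintf("row %d: recovery above the maximum tracked age", i))
      arrays[[area]]$d[a_last, b, t_last] <- arrays[[area]]$d[a_last, b, t_last] + 1L
    } else {
      arrays[[area]]$v[a_last, t_last] <- arrays[[area]]$v[a_last, t_last] + 1L
    }
  }
  list(A = mrr_sufficient_stats(arrays$A$n, arrays$A$d, arrays$A$v, config),
       B = mrr_sufficient_stats(arrays$B$n, arrays$B$d, arrays$B$v, config))
}

bundle_file_names <- c(counts = "counts.csv",
                       bs = "breeding_success.csv",
                       nb = "nonbreeding.csv",
                       adults = "adult_histories.csv",
                       chicks = "chick_records.csv",
                       mrr_nd = "mrr_nd.csv",
                       mrr_v = "mrr_v.csv")

#' Read a dataset bundle from delimited files
#'
#' Reads and validates the CSV files of a bundle directory:
#' `counts.csv` (species, year, pairs; blank pairs = no count),
#' `breeding_success.csv` (species, year, monitored, fledged),
#' `nonbreeding.csv` (year, monitored, bred),
#' `adult_histories.csv` (species, id, mark_year, one 0/1 column per year),
#' and either `chick_records.csv` (id, area, band_year, semicolon-separated
#' resight years, recovery_year) or the pre-built sufficient-statistic
#' files `mrr_nd.csv` (area, a, b, t, n, d) and `mrr_v.csv` (area, a, t,
#' v). Calendar years in the files are converted to 1-based occasions.
#' Violations raise errors naming the file and row.
#'
#' @param dir directory containing the files.
#' @param config a [study_config()].
#' @return a validated [dataset_bundle()].
#' @export
read_bundle <- function(dir, config) {
  Tn <- config$n_years
  pth <- function(key) file.path(dir, bundle_file_names[[key]])
  rd <- function(key) utils::read.csv(pth(key), stringsAsFactors = FALSE)

  cts <- rd("counts")
  counts <- matrix(NA_real_, Tn, 3L, dimnames = list(NULL, c("R", "P", "M")))
  for (i in seq_len(nrow(cts))) {
    t <- year_to_occasion(cts$year[i], config)
    if (t < 1L || t > Tn) stop(sprintf("%s row %d: year out of range", bundle_file_names[["counts"]], i))
    if (!cts$species[i] %in% c("R", "P", "M")) {
      stop(sprintf("%s row %d: unknown species", bundle_file_names[["counts"]], i))
    }
    counts[t, cts$species[i]] <- cts$pairs[i]
  }

  bsf <- rd("bs")
  bs <- list()
  for (sp in c("R", "P", "M")) {
    E <- C <- integer(Tn)
    rows <- which(bsf$species == sp)
    tt <- year_to_occasion(bsf$year[rows], config)
    E[tt] <- bsf$monitored[rows]
    C[tt] <- bsf$fledged[rows]
    bad <- rows[which(bsf$fledged[rows] > bsf$monitored[rows])]
    if (length(bad)) {
      stop(sprintf("%s row %d: fledged exceeds monitored",
                   bundle_file_names[["bs"]], bad[1L]))
    }
    bs[[sp]] <- breeding_success_series(E, C)
  }

  nbf <- rd("nb")
  xi_m <- xi_b <- integer(Tn)
  tt <- year_to_occasion(nbf$year, config)
  xi_m[tt] <- nbf$monitored
  xi_b[tt] <- nbf$bred
  bad <- which(nbf$bred > nbf$monitored)
  if (length(bad)) {
    stop(sprintf("%s row %d: bred exceeds monitored", bundle_file_names[["nb"]], bad[1L]))
  }
  nb <- nonbreeding_series(xi_m, xi_b)

  adf <- rd("adults")
  ycols <- paste0("y", occasion_to_year(seq_len(Tn), config))
  if (!all(ycols %in% names(adf))) {
    stop(sprintf("%s: expected occasion columns %s..%s",
                 bundle_file_names[["adults"]], ycols[1L], ycols[Tn]))
  }
  adults <- list()
  for (sp in c("R", "P", "M")) {
    rows <- which(adf$species == sp)
    if (!length(rows)) { adults[sp] <- list(NULL); next }
    w <- as.matrix(adf[rows, ycols])
    f <- year_to_occasion(adf$mark_year[rows], config)
    for (k in seq_along(rows)) {
      if (f[k] < 1L || f[k] >= Tn || w[k, f[k]] != 1L) {
        stop(sprintf("%s row %d: mark year inconsistent with history",
                     bundle_file_names[["adults"]], rows[k]))
      }
      if (f[k] > 1L && any(w[k, seq_len(f[k] - 1L)] != 0L)) {
        stop(sprintf("%s row %d: sighting before marking",
                     bundle_file_names[["adults"]], rows[k]))
      }
    }
    adults[[sp]] <- adult_histories(w)
  }

  chick_records <- NULL
  if (file.exists(pth("chicks"))) {
    crf <- rd("chicks")
    chick_records <- data.frame(
      id = crf$id, area = crf$area,
      band_occasion = year_to_occasion(crf$band_year, config),
      resight_occasions = vapply(crf$resight_years, function(s) {
        if (is.na(s) || !nzchar(s)) return("")
        paste(year_to_occasion(as.integer(strsplit(as.character(s), ";")[[1L]]),
                               config), collapse = ";")
      }, character(1L), USE.NAMES = FALSE),
      recovery_occasion = ifelse(is.na(crf$recovery_year), NA_integer_,
                                 year_to_occasion(crf$recovery_year, config)),
      stringsAsFactors = FALSE)
    mrr <- build_mrr_sufficient_stats(chick_records, config)
  } else {
    A <- config$max_age
    mk <- function() list(n = array(0L, c(A, A, Tn)),
                          d = array(0L, c(A, A, Tn)), v = matrix(0L, A, Tn))
    arrays <- list(A = mk(), B = mk())
    ndf <- rd("mrr_nd")
    for (i in seq_len(nrow(ndf))) {
      ar <- ndf$area[i]
      arrays[[ar]]$n[ndf$a[i], ndf$b[i], ndf$t[i]] <- ndf$n[i]
      arrays[[ar]]$d[ndf$a[i], ndf$b[i], ndf$t[i]] <- ndf$d[i]
    }
    vdf <- rd("mrr_v")
    for (i in seq_len(nrow(vdf))) {
      arrays[[vdf$area[i]]]$v[vdf$a[i], vdf$t[i]] <- vdf$v[i]
    }
    mrr <- list(
      A = mrr_sufficient_stats(arrays$A$n, arrays$A$d, arrays$A$v, config),
      B = mrr_sufficient_stats(arrays$B$n, arrays$B$d, arrays$B$v, config))
  }

  dataset_bundle(counts, bs, nb, adults, mrr, config,
                 chick_records = chick_records)
}

#' Write a dataset bundle to delimited files
#'
#' Inverse of [read_bundle()]: writes the canonical CSV files into a
#' directory, in a deterministic row order so that reading and rewriting a
#' bundle reproduces the files exactly.
#'
#' @param bundle a [dataset_bundle()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  config <- bundle$config
  Tn <- config$n_years
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, key) {
    utils::write.csv(df, file.path(dir, bundle_file_names[[key]]),
                     row.names = FALSE, quote = FALSE, na = "")
  }
  cts <- do.call(rbind, lapply(c("R", "P", "M"), function(sp) {
    data.frame(species = sp, year = occasion_to_year(seq_len(Tn), config),
               pairs = bundle$counts[, sp])
  }))
  wr(cts, "counts")
  bsf <- do.call(rbind, lapply(c("R", "P", "M"), function(sp) {
    data.frame(species = sp, year = occasion_to_year(seq_len(Tn), config),
               monitored = bundle$bs[[sp]]$E, fledged = bundle$bs[[sp]]$C)
  }))
  wr(bsf, "bs")
  wr(data.frame(year = occasion_to_year(seq_len(Tn), config),
                monitored = bundle$nb$xi_m, bred = bundle$nb$xi_b), "nb")
  adf <- do.call(rbind, lapply(c("R", "P", "M"), function(sp) {
    h <- bundle$adults[[sp]]
    if (is.null(h)) return(NULL)
    df <- data.frame(species = sp, id = paste0(sp, seq_len(nrow(h$w))),
                     mark_year = occasion_to_year(h$f, config))
    w <- as.data.frame(h$w)
    names(w) <- paste0("y", occasion_to_year(seq_len(Tn), config))
    cbind(df, w)
  }))
  wr(adf, "adults")
  if (!is.null(bundle$chick_records)) {
    cr <- bundle$chick_records
    wr(data.frame(
      id = cr$id, area = cr$area,
      band_year = occasion_to_year(cr$band_occasion, config),
      resight_years = vapply(cr$resight_occasions, function(s) {
        if (!nzchar(s)) return("")
        paste(occasion_to_year(as.integer(strsplit(s, ";")[[1L]]), config),
              collapse = ";")
      }, character(1L), USE.NAMES = FALSE),
      recovery_year = ifelse(is.na(cr$recovery_occasion), NA_integer_,
                             occasion_to_year(cr$recovery_occasion, config))),
      "chicks")
  }
  nd <- do.call(rbind, lapply(c("A", "B"), function(ar) {
    st <- bundle$mrr[[ar]]
    idx <- which(st$n > 0 | st$d > 0, arr.ind = TRUE)
    if (!nrow(idx)) return(NULL)
    idx <- idx[order(idx[, 1L], idx[, 2L], idx[, 3L]), , drop = FALSE]
    data.frame(area = ar, a = idx[, 1L], b = idx[, 2L], t = idx[, 3L],
               n = st$n[idx], d = st$d[idx])
  }))
  wr(if (is.null(nd)) data.frame(area = character(0), a = integer(0),
                                 b = integer(0), t = integer(0),
                                 n = integer(0), d = integer(0)) else nd,
     "mrr_nd")
  vv <- do.call(rbind, lapply(c("A", "B"), function(ar) {
    st <- bundle$mrr[[ar]]
    idx <- which(st$v > 0, arr.ind = TRUE)
    if (!nrow(idx)) return(NULL)
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    data.frame(area = ar, a = idx[, 1L], t = idx[, 2L], v = st$v[idx])
  }))
  wr(if (is.null(vv)) data.frame(area = character(0), a = integer(0),
                                 t = integer(0), v = integer(0)) else vv,
     "mrr_v")
  invisible(dir)
}

#' Write posterior results to files
#'
#' Writes `parameter_summary.csv` (median and symmetric 95% credible
#' interval per parameter), `abundance.csv` (posterior abundance
#' trajectories per species and year) and `run_meta.json` (seed, chain
#' settings, worst-case Gelman-Rubin statistic).
#'
#' @param result a posterior result from [run_mcmc()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_results <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  summ <- summarize_posterior(result)
  utils::write.csv(summ, file.path(out_dir, "parameter_summary.csv"),
                   row.names = FALSE, quote = FALSE)
  ab <- summ[grepl("^N\\[", summ$parameter), , drop = FALSE]
  utils::write.csv(ab, file.path(out_dir, "abundance.csv"),
                   row.names = FALSE, quote = FALSE)
  meta <- list(seed = result$seed, n_chains = result$n_chains,
               n_iter = result$n_iter, n_burnin = result$n_burnin,
               n_thin = result$n_thin,
               worst_rhat = max(result$rhat, na.rm = TRUE),
               worst_rhat_parameter =
                 names(result$rhat)[which.max(result$rhat)])
  jsonlite::write_json(meta, file.path(out_dir, "run_meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
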