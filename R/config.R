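#' Study configuration for a three-species breeding community
#'
#' Fixes the temporal frame and structural constants of the community model:
#' the number of annual occasions, the calendar year of the first occasion,
#' the set of species, each species' median age at first breeding, the
#' maximum tracked age for the chick mark-resight-recovery (MRR) component,
#' the last banding occasion of the secondary banding area, the occasions at
#' which puffin whole-colony counts exist, and the occasion windows over
#' which the age-class resight probabilities of the chick MRR component are
#' defined for each banding area.
#'
#' Species are indexed in the fixed order razorbill (`"R"`), puffin (`"P"`),
#' murre (`"M"`). Occasions are 1-based throughout the package; calendar
#' years appear only in input/output files.
#'
#' @param n_years number of annual occasions `T`.
#' @param first_year calendar year of occasion 1.
#' @param d named integer vector of ages at first breeding, one per species.
#' @param max_age maximum tracked age `A` for the chick MRR component.
#'   Birds older than `A` are treated as unobservable (resight and reporting
#'   probabilities zero beyond `A`); with the default `A = n_years` this
#'   convention is never exercised because no bird can outlive the study.
#' @param areaB_last_banding last occasion at which chicks are banded in
#'   area B.
#' @param puffin_count_years occasions at which puffin counts are available.
#' @return an object of class `"msipm_config"`.
#' @export
study_config <- function(n_years = 26L,
                         first_year = 1984L,
                         d = c(R = 5L, P = 7L, M = 6L),
                         max_age = n_years,
                         areaB_last_banding = 14L,
                         puffin_count_years = c(1L, 6L, 9L, 15L, 20L, 25L, 26L)) {
  n_years <- as.integer(n_years)
  stopifnot(n_years >= 4L, length(d) == 3L)
  if (!identical(names(d), c("R", "P", "M"))) {
    stop("`d` must be a named vector with names R, P, M (in that order)")
  }
  d <- as.integer(d)
  names(d) <- c("R", "P", "M")
  if (any(d < 1L) || any(d >= n_years)) {
    stop("ages at first breeding must satisfy 1 <= d < n_years")
  }
  puffin_count_years <- sort(unique(as.integer(puffin_count_years)))
  if (any(puffin_count_years < 1L) || any(puffin_count_years > n_years)) {
    stop("puffin_count_years must lie in 1..n_years")
  }
  areaB_last_banding <- as.integer(areaB_last_banding)
  if (areaB_last_banding < 1L || areaB_last_banding > n_years - 1L) {
    stop("areaB_last_banding must lie in 1..(n_years - 1)")
  }
  cfg <- list(
    n_years = n_years,
    first_year = as.integer(first_year),
    species = c("R", "P", "M"),
    species_names = c(R = "razorbill", P = "puffin", M = "murre"),
    d = d,
    max_age = as.integer(max_age),
    areaB_last_banding = areaB_last_banding,
    puffin_count_years = puffin_count_years,
    banding_years = list(A = seq_len(n_years - 1L),
                         B = seq_len(areaB_last_banding)),
    windows = resight_windows(n_years, areaB_last_banding)
  )
  class(cfg) <- "msipm_config"
  cfg
}

# Occasion windows over which each age-class resight probability of the chick
# MRR component is defined, per banding area. Area A windows are open-ended
# (they run to T); area B windows close a few seasons after banding there
# stops, reproducing the published windows (end occasions 17, 18, 20 for a
# study with T = 26 and last area-B banding at occasion 14). Outside a window
# the probability is structurally zero.
resight_windows <- function(n_years, areaB_last_banding) {
  tB <- areaB_last_banding
  clamp <- function(from, to) {
    if (to < from) return(integer(0))
    seq.int(from, to)
  }
  list(
    A = list(p2  = clamp(3L, n_years),
             p3  = clamp(4L, n_years),
             p45 = clamp(5L, n_years),
             pa  = clamp(7L, n_years)),
    B = list(p2  = clamp(3L, min(n_years, tB + 3L)),
             p3  = clamp(4L, min(n_years, tB + 4L)),
             p45 = clamp(5L, min(n_years, tB + 6L)),
             pa  = clamp(7L, n_years))
  )
}

#' Map an age to its resight-probability age class
#'
#' Age 1 birds are never resighted (class `"p1"`, probability fixed at zero),
#' ages 2 and 3 have their own classes, ages 4-5 share a class, and ages 6
#' and above use the adult class.
#'
#' @param age integer vector of ages (>= 1).
#' @return character vector of class labels among
#'   `"p1"`, `"p2"`, `"p3"`, `"p45"`, `"pa"`.
#' @export
resight_age_class <- function(age) {
  stopifnot(all(age >= 1L))
  out <- character(length(age))
  out[age == 1L] <- "p1"
  out[age == 2L] <- "p2"
  out[age == 3L] <- "p3"
  out[age %in% c(4L, 5L)] <- "p45"
  out[age >= 6L] <- "pa"
  out
}

#' @export
print.msipm_config <- function(x, ...) {
  cat("msIPM study configuration\n")
  cat(sprintf("  occasions: %d (%d-%d)\n", x$n_years, x$first_year,
              x$first_year + x$n_years - 1L))
  cat(sprintf("  ages at first breeding: R=%d P=%d M=%d\n",
              x$d["R"], x$d["P"], x$d["M"]))
  cat(sprintf("  chick MRR: max age %d, area B banding ends t=%d\n",
              x$max_age, x$areaB_last_banding))
  cat(sprintf("  puffin count occasions: %s\n",
              paste(x$puffin_count_years, collapse = ", ")))
  invisible(x)
}

# occasion -> calendar year and back (I/O only)
occasion_to_year <- function(t, config) config$first_year + t - 1L
year_to_occasion <- function(y, config) as.integer(y) - config$first_year + 1L
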