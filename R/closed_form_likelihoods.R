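#' Breeding-success series
#'
#' Yearly counts of monitored breeding pairs `E(t)` and of chicks fledged
#' from them `C(t)`. All three species lay a single egg, so
#' `C(t) ~ bin(E(t), rho(t))` with `rho(t)` the productivity.
#'
#' @param E integer vector of monitored pairs, one per occasion.
#' @param C integer vector of fledged chicks, `0 <= C <= E`.
#' @return list with elements `E` and `C`, class
#'   `"msipm_breeding_success"`.
#' @export
breeding_success_series <- function(E, C) {
  stopifnot(length(E) == length(C))
  ok <- !(is.na(E) | is.na(C))
  if (any(E[ok] < 0) || any(C[ok] < 0) || any(C[ok] > E[ok])) {
    stop("breeding success requires 0 <= C(t) <= E(t)")
  }
  if (any(E[ok] != round(E[ok])) || any(C[ok] != round(C[ok]))) {
    stop("breeding success counts must be integers")
  }
  structure(list(E = as.integer(round(E)), C = as.integer(round(C))),
            class = "msipm_breeding_success")
}

#' Non-breeding series (murre)
#'
#' Yearly counts of monitored murres `xi_m(t)` and of those that bred
#' (did not skip breeding) `xi_b(t)`; `xi_b(t) ~ bin(xi_m(t), B(t))` with
#' `B(t)` the probability of breeding.
#'
#' @param xi_m integer vector of monitored murres.
#' @param xi_b integer vector of murres that bred, `0 <= xi_b <= xi_m`.
#' @return list with elements `xi_m` and `xi_b`, class
#'   `"msipm_nonbreeding"`.
#' @export
nonbreeding_series <- function(xi_m, xi_b) {
  stopifnot(length(xi_m) == length(xi_b))
  ok <- !(is.na(xi_m) | is.na(xi_b))
  if (any(xi_m[ok] < 0) || any(xi_b[ok] < 0) || any(xi_b[ok] > xi_m[ok])) {
    stop("non-breeding requires 0 <= xi_b(t) <= xi_m(t)")
  }
  structure(list(xi_m = as.integer(round(xi_m)),
                 xi_b = as.integer(round(xi_b))),
            class = "msipm_nonbreeding")
}

# shared binomial-series kernel: sum over years of the full log pmf,
# including the binomial coefficient; years with size 0 (or missing data)
# contribute 0; a rate of 0 (or 1) only scores -Inf when the data contradict
# it, never raises.
binomial_series_loglik <- function(size, x, prob) {
  if (length(prob) != length(size)) {
    stop("rate series and data series must have the same length")
  }
  if (any(prob < 0 | prob > 1, na.rm = TRUE)) {
    stop("rates must lie in [0, 1]")
  }
  keep <- !(is.na(size) | is.na(x)) & size > 0L
  if (!any(keep)) return(0)
  sum(stats::dbinom(x[keep], size[keep], prob[keep], log = TRUE))
}

#' Breeding-success log-likelihood
#'
#' Sum over years of the binomial log pmf of `C(t)` fledged chicks out of
#' `E(t)` monitored pairs with productivity `rho(t)`. The binomial
#' coefficient is included, so the value is a true log pmf (summing the
#' exponentiated values over all possible `C(t)` gives 1). Years with
#' `E(t) = 0` contribute 0.
#'
#' @param data a [breeding_success_series()].
#' @param rho productivity series in `[0, 1]`, same length as the data.
#' @return log-likelihood (may be `-Inf` if the data are impossible under
#'   `rho`, e.g. `rho(t) = 0` with `C(t) > 0`).
#' @export
bs_loglik <- function(data, rho) {
  stopifnot(inherits(data, "msipm_breeding_success"))
  binomial_series_loglik(data$E, data$C, rho)
}

#' Non-breeding log-likelihood
#'
#' Same functional form as [bs_loglik()] with monitored murres as trials,
#' breeders as successes and the yearly breeding probability `B(t)` as rate.
#'
#' @param data a [nonbreeding_series()].
#' @param B breeding-probability series in `[0, 1]`.
#' @return log-likelihood.
#' @export
nb_loglik <- function(data, B) {
  stopifnot(inherits(data, "msipm_nonbreeding"))
  binomial_series_loglik(data$xi_m, data$xi_b, B)
}
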