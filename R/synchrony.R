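#' Synchrony random-effects block
#'
#' A demographic rate (productivity or adult survival) is modelled on the
#' logit scale as a species intercept plus a year effect shared by all
#' species (the synchronous, community-wide component) plus a
#' species-specific year effect (the asynchronous component):
#' `logit(rate_S(t)) = beta_S + delta(t) + eps_S(t)`. Both sets of effects
#' are independent zero-mean normals with their own standard deviations.
#' Productivity effects span occasions `1..T`; survival effects span
#' `1..T-1` (one per annual interval) and the two lengths are never padded
#' to match.
#'
#' No sum-to-zero constraint is imposed on the year effects; the additive
#' confounding between an intercept and the mean of its effects is resolved
#' by the hierarchical zero-mean priors, not by reparameterization.
#'
#' @param beta named numeric vector (R, P, M) of species intercepts
#'   (logit scale).
#' @param delta numeric vector of shared year effects.
#' @param eps numeric matrix (`length(delta)` x 3, columns R, P, M) of
#'   species-specific year effects.
#' @param sigma_delta standard deviation of the shared effects (>= 0).
#' @param sigma_eps named numeric vector (R, P, M) of standard deviations of
#'   the species-specific effects (>= 0).
#' @return an object of class `"msipm_synchrony_block"`.
#' @export
synchrony_block <- function(beta, delta, eps, sigma_delta, sigma_eps) {
  beta <- unlist(beta)
  stopifnot(length(beta) == 3L, is.numeric(delta),
            is.matrix(eps), ncol(eps) == 3L,
            nrow(eps) == length(delta),
            length(sigma_delta) == 1L, sigma_delta >= 0,
            length(sigma_eps) == 3L, all(sigma_eps >= 0))
  names(beta) <- c("R", "P", "M")
  colnames(eps) <- c("R", "P", "M")
  names(sigma_eps) <- c("R", "P", "M")
  structure(list(beta = beta, delta = as.numeric(delta), eps = eps,
                 sigma_delta = as.numeric(sigma_delta),
                 sigma_eps = sigma_eps),
            class = "msipm_synchrony_block")
}

#' Assemble a demographic-rate series from a synchrony block
#'
#' Returns `plogis(beta_S + delta(t) + eps_S(t))`, the per-year rate for one
#' species, strictly inside (0, 1).
#'
#' @param block a [synchrony_block()].
#' @param species one of `"R"`, `"P"`, `"M"`.
#' @return numeric vector of rates, one per year effect.
#' @export
assemble_rate_series <- function(block, species) {
  stopifnot(inherits(block, "msipm_synchrony_block"),
            species %in% c("R", "P", "M"))
  stats::plogis(block$beta[[species]] + block$delta + block$eps[, species])
}

#' Log-density of the random effects in a synchrony block
#'
#' Sum of independent zero-mean normal log-densities for the shared and
#' species-specific year effects. A standard deviation of exactly zero with
#' any non-zero effect yields `-Inf` (and 0 contribution when all its
#' effects are zero, the degenerate point mass).
#'
#' @param block a [synchrony_block()].
#' @return a single numeric log-density.
#' @export
re_logpdf <- function(block) {
  stopifnot(inherits(block, "msipm_synchrony_block"))
  term <- function(x, sd) {
    if (sd == 0) {
      if (all(x == 0)) return(0)
      return(-Inf)
    }
    sum(stats::dnorm(x, 0, sd, log = TRUE))
  }
  out <- term(block$delta, block$sigma_delta)
  for (sp in c("R", "P", "M")) {
    out <- out + term(block$eps[, sp], block$sigma_eps[[sp]])
  }
  out
}

#' Synchrony index
#'
#' The fraction of between-year variance of a logit-scale demographic rate
#' that is common to all species:
#' `I_S = sigma_delta^2 / (sigma_delta^2 + sigma_eps_S^2)`.
#' In a Bayesian fit the index is computed draw by draw and the draws are
#' then summarized; the plug-in index of posterior-median SDs is a different
#' (secondary) quantity.
#'
#' @param sigma_delta SD of the shared year effect (vectorized).
#' @param sigma_eps SD of the species-specific year effect (vectorized).
#' @return numeric in `[0, 1]`; `NA` (with a warning) where both SDs are
#'   zero, since the index is then undefined.
#' @export
synchrony_index <- function(sigma_delta, sigma_eps) {
  stopifnot(all(sigma_delta >= 0, na.rm = TRUE),
            all(sigma_eps >= 0, na.rm = TRUE))
  v <- sigma_delta^2 + sigma_eps^2
  out <- sigma_delta^2 / v
  if (any(v == 0, na.rm = TRUE)) {
    warning("synchrony index undefined where both SDs are zero; returning NA")
    out[v == 0] <- NA_real_
  }
  out
}
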