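#' Summarize a posterior result
#'
#' Median and symmetric 95% credible interval (2.5% and 97.5% quantiles,
#' type-7 linear interpolation, so summaries are exactly reproducible from
#' the stored draws) for every monitored quantity, pooling chains, plus
#' the Gelman-Rubin statistic. Derived quantities (synchrony indices,
#' abundance trajectories, yearly rates) are computed draw by draw inside
#' the model and summarized like any parameter; the plug-in synchrony
#' index evaluated at the posterior-median SDs is also attached (attribute
#' `"plugin_synchrony"`) for comparison, but the draw-wise summary is the
#' reported quantity.
#'
#' @param result an [run_mcmc()] result.
#' @return data frame with columns `parameter`, `median`, `lower`,
#'   `upper`, `rhat`.
#' @export
summarize_posterior <- function(result) {
  stopifnot(inherits(result, "msipm_posterior"))
  draws <- as.matrix(do.call(rbind, lapply(result$samples, as.matrix)))
  qs <- t(apply(draws, 2L, stats::quantile,
                probs = c(0.5, 0.025, 0.975), type = 7, names = FALSE))
  out <- data.frame(parameter = colnames(draws), median = qs[, 1L],
                    lower = qs[, 2L], upper = qs[, 3L],
                    rhat = unname(result$rhat[colnames(draws)]),
                    row.names = NULL, stringsAsFactors = FALSE)
  plugin <- plugin_synchrony(out)
  attr(out, "plugin_synchrony") <- plugin
  out
}

# plug-in synchrony indices from posterior-median SDs (secondary summary;
# differs in general from the draw-wise posterior of the index)
plugin_synchrony <- function(summary_df) {
  med <- function(p) {
    i <- match(p, summary_df$parameter)
    if (is.na(i)) NA_real_ else summary_df$median[i]
  }
  out <- c()
  for (blk in c("rho", "phi")) {
    sd_d <- med(sprintf("sig.delta.%s", blk))
    for (s in 1:3) {
      sd_e <- med(sprintf("sig.eps.%s[%d]", blk, s))
      out[sprintf("I.%s.plugin[%d]", blk, s)] <-
        if (is.na(sd_d) || is.na(sd_e)) NA_real_ else
          synchrony_index(sd_d, sd_e)
    }
  }
  out
}

# extract pooled draws of one monitored quantity as a vector/matrix
posterior_draws <- function(result, parameter) {
  draws <- do.call(rbind, lapply(result$samples, as.matrix))
  cols <- colnames(draws)
  if (parameter %in% cols) return(draws[, parameter])
  sel <- startsWith(cols, paste0(parameter, "["))
  if (!any(sel)) stop(sprintf("'%s' was not monitored", parameter))
  draws[, sel, drop = FALSE]
}
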