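#' Confidence interval for a difference of group means
#'
#' Estimates `mean(values_b) - mean(values_a)` with a confidence interval,
#' either by bootstrap percentile (resampling each group independently) or
#' by a Welch t-interval. The difference is declared significant exactly
#' when the interval excludes zero.
#'
#' @param values_a,values_b numeric vectors of per-replicate values (e.g.
#'   per-sample or per-FoV means), at least 2 each.
#' @param level confidence level.
#' @param method `"bootstrap"` (percentile) or `"welch"`.
#' @param n_boot number of bootstrap resamples.
#' @param seed optional integer seed for the bootstrap.
#' @return object of class `group_difference_ci` with `estimate`,
#'   `ci_low`, `ci_high`, `level`, `method` and `significant`.
#' @export
group_difference_ci <- function(values_a, values_b, level = 0.95,
                                method = c("bootstrap", "welch"),
                                n_boot = 1e4, seed = NULL) {
  method <- match.arg(method)
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("each group needs at least 2 values")
  est <- mean(values_b) - mean(values_a)
  if (method == "bootstrap") {
    if (!is.null(seed)) set.seed(seed)
    na <- length(values_a); nb <- length(values_b)
    diffs <- vapply(seq_len(n_boot), function(i) {
      mean(values_b[sample.int(nb, nb, replace = TRUE)]) -
        mean(values_a[sample.int(na, na, replace = TRUE)])
    }, numeric(1))
    p <- (1 - level) / 2
    ci <- unname(stats::quantile(diffs, c(p, 1 - p), names = FALSE))
  } else {
    tt <- stats::t.test(values_b, values_a, conf.level = level)
    ci <- unname(tt$conf.int)
  }
  structure(list(estimate = est, ci_low = ci[1], ci_high = ci[2],
                 level = level, method = method,
                 significant = interval_excludes_zero(ci[1], ci[2])),
            class = "group_difference_ci")
}

#' Zero-exclusion significance rule for an interval
#'
#' A group difference is statistically meaningful exactly when its
#' confidence interval does not contain 0.
#'
#' @param ci_low,ci_high interval endpoints.
#' @return logical.
#' @export
interval_excludes_zero <- function(ci_low, ci_high) {
  ci_low > 0 | ci_high < 0
}

#' @export
print.group_difference_ci <- function(x, ...) {
  cat(sprintf("Difference of means: %.4f, %d%% CI [%.4f, %.4f] (%s)%s\n",
              x$estimate, round(100 * x$level), x$ci_low, x$ci_high,
              x$method, if (x$significant) " *" else ""))
  invisible(x)
}

#' Per-stage summary of aggregate and co-occurrence metrics
#'
#' Collates the per-stage headline metrics from the upstream tables:
#' synaptosome occupancy, aggregates per occupied synaptosome, mean length
#' and eccentricity per compartment, fibril-like percentage per
#' compartment, and (when flag tables are supplied) the four co-occurrence
#' metrics. Undefined summaries (e.g. lengths at a stage with no
#' aggregates) are reported as `NA`.
#'
#' @param aggregates data frame with at least `stage`, `compartment`,
#'   `length_nm`, `eccentricity`, `fibril_like`.
#' @param occupancy data frame with `stage`, `occupancy_fraction`,
#'   `aggregates_per_occupied` (one row per stage or per FoV).
#' @param flags optional data frame with `stage`, `at8`, `signal` for the
#'   co-occurrence metrics.
#' @return data frame with one row per stage.
#' @export
summarise_stage <- function(aggregates, occupancy, flags = NULL) {
  stages <- sort(unique(c(as.character(aggregates$stage),
                          as.character(occupancy$stage))))
  rows <- lapply(stages, function(st) {
    agg <- aggregates[aggregates$stage == st, , drop = FALSE]
    occ <- occupancy[occupancy$stage == st, , drop = FALSE]
    syn <- agg[agg$compartment == "synaptic", , drop = FALSE]
    ext <- agg[agg$compartment == "extra_synaptic", , drop = FALSE]
    mstat <- function(v) if (length(v)) mean(v) else NA_real_
    out <- data.frame(
      stage = st,
      occupancy_pct = 100 * mstat(occ$occupancy_fraction),
      aggregates_per_occupied = mstat(occ$aggregates_per_occupied),
      mean_length_synaptic_nm = mstat(syn$length_nm),
      mean_length_extra_nm = mstat(ext$length_nm),
      mean_ecc_synaptic = mstat(syn$eccentricity),
      mean_ecc_extra = mstat(ext$eccentricity),
      fibril_pct_synaptic = if (nrow(syn)) 100 * mean(syn$fibril_like) else NA_real_,
      fibril_pct_extra = if (nrow(ext)) 100 * mean(ext$fibril_like) else NA_real_
    )
    if (!is.null(flags)) {
      fl <- flags[flags$stage == st, , drop = FALSE]
      if (nrow(fl)) {
        m <- cooccurrence_metrics(fl)
        out$marginal_pct <- m$marginal_pct
        out$conditional_pct <- m$conditional_pct
        out$joint_pct <- m$joint_pct
      } else {
        out$marginal_pct <- out$conditional_pct <- out$joint_pct <- NA_real_
      }
    }
    out
  })
  do.call(rbind, rows)
}
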