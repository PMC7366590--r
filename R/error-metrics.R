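#' Symmetric forecast error ratio
#'
#' \eqn{\mathrm{error} = e^{|\ln(\mathrm{observed}/\mathrm{predicted})|}}:
#' always >= 1, identical for over- and underprediction of the same relative
#' magnitude, so opposite-sign errors cannot cancel in aggregation. An error
#' of 2 for an observed monthly BI of EUR 10,000 means a prediction of
#' EUR 5,000 or EUR 20,000.
#'
#' @param observed_eur,predicted_eur strictly positive euro amounts
#'   (vectorized).
#' @return the dimensionless error ratio.
#' @export
error_ratio <- function(observed_eur, predicted_eur) {
  if (any(observed_eur <= 0) || any(predicted_eur <= 0))
    stop("error_ratio requires strictly positive observed and predicted BI",
         call. = FALSE)
  exp(abs(log(observed_eur / predicted_eur)))
}

#' Signed percentage difference of a prediction
#'
#' `(predicted - observed) / observed * 100`; the asymmetric, literature-
#' comparable companion of [error_ratio()] used for the +/-40% and +/-100%
#' band fractions.
#'
#' @param predicted_eur predicted monthly BI.
#' @param observed_eur observed monthly BI (> 0).
#' @return signed percent.
#' @export
pct_difference <- function(predicted_eur, observed_eur) {
  if (any(observed_eur <= 0))
    stop("pct_difference requires strictly positive observed BI",
         call. = FALSE)
  (predicted_eur - observed_eur) / observed_eur * 100
}

#' Error samples from validation cells
#'
#' Keeps the cells with an observed BI and attaches `ln_ratio =
#' ln(observed/predicted)` (positive = underprediction), `error_ratio =
#' exp(|ln_ratio|)` and the signed `pct_diff`.
#'
#' @param cells a `validation_cells` data.frame ([rolling_validate()]).
#' @return data.frame of error samples (one per cell with observed BI).
#' @export
error_samples <- function(cells) {
  s <- as.data.frame(cells)
  s <- s[!is.na(s$observed_eur), , drop = FALSE]
  s$ln_ratio <- log(s$observed_eur / s$pred_eur)
  s$error_ratio <- error_ratio(s$observed_eur, s$pred_eur)
  s$pct_diff <- pct_difference(s$pred_eur, s$observed_eur)
  rownames(s) <- NULL
  s
}

summarise_group <- function(v) {
  q <- stats::quantile(v, c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE,
                       type = 7)
  data.frame(n = length(v), mean = mean(v),
             sd = if (length(v) > 1L) stats::sd(v) else 0,
             median = q[3L], iqr = q[4L] - q[2L],
             p5 = q[1L], p25 = q[2L], p75 = q[4L], p95 = q[5L])
}

#' Aggregate error samples
#'
#' The three compilations of the validation outcomes: per `(t_pred, t_data)`
#' point, per `t_data`, or not aggregated at all. Summaries report n, mean,
#' sd, median, IQR (a single width, p75 - p25) and the 5/25/75/95th
#' percentiles (linear interpolation between order statistics). For a
#' single-sample group the sd is reported as 0 with its n = 1 visible.
#'
#' @param samples an [error_samples()] data.frame.
#' @param mode `"per_tpred_tdata"`, `"per_tdata"` or `"none"`.
#' @param value column to summarize (default `"error_ratio"`).
#' @return data.frame of group summaries (empty groups omitted).
#' @export
aggregate_errors <- function(samples,
                             mode = c("per_tpred_tdata", "per_tdata", "none"),
                             value = "error_ratio") {
  mode <- match.arg(mode)
  v <- samples[[value]]
  if (mode == "none") return(summarise_group(v))
  keys <- if (mode == "per_tdata") list(t_data = samples$t_data) else
    list(t_pred = samples$t_pred, t_data = samples$t_data)
  sp <- split(seq_along(v), keys, drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(ix) summarise_group(v[ix])))
  keycols <- do.call(rbind, lapply(sp, function(ix)
    as.data.frame(lapply(keys, function(kk) kk[ix[1L]]))))
  out <- cbind(keycols, out)
  out <- out[do.call(order, keycols), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fraction of predictions within percentage bands
#'
#' For each band `b`, the fraction of samples with `|pct_diff| <= b` (closed
#' bands). Defaults to the +/-40% and +/-100% bands used to compare forecast
#' accuracy across the literature.
#'
#' @param samples an [error_samples()] data.frame.
#' @param bands percent half-widths.
#' @return data.frame with `band`, `n_within`, `fraction`.
#' @export
band_fractions <- function(samples, bands = c(40, 100)) {
  if (!nrow(samples)) stop("no error samples", call. = FALSE)
  data.frame(band = bands,
             n_within = vapply(bands, function(b)
               sum(abs(samples$pct_diff) <= b), 0L),
             fraction = vapply(bands, function(b)
               mean(abs(samples$pct_diff) <= b), 0))
}

#' Summary statistical tests on the error samples
#'
#' (a) one-sample t-test of mean `ln_ratio` against 0 (does the model over-
#' or underpredict on average on the log scale?); (b) exact binomial test of
#' the underprediction probability (`ln_ratio > 0`) against 0.5, exact ties
#' excluded; (c) OLS regression of the error ratio on `t_data` across
#' individual samples — its slope quantifies how accuracy improves as a
#' product accrues data.
#'
#' @param samples an [error_samples()] data.frame (needs >= 2 rows).
#' @param regression_response `"error_ratio"` (default) or `"ln_error"` to
#'   regress `log(error_ratio)` instead.
#' @return list with `t_test` (mean, ci, p, n), `binomial` (prob
#'   underprediction, ci, p, n, ties excluded) and `regression` (slope, se,
#'   p, n).
#' @export
summary_tests <- function(samples, regression_response = "error_ratio") {
  if (nrow(samples) < 2L) stop("need at least 2 error samples", call. = FALSE)
  tt <- stats::t.test(samples$ln_ratio, mu = 0)
  ties <- sum(samples$ln_ratio == 0)
  n_eff <- nrow(samples) - ties
  bt <- stats::binom.test(sum(samples$ln_ratio > 0), n_eff, p = 0.5)
  y <- if (regression_response == "ln_error") log(samples$error_ratio) else
    samples$error_ratio
  fit <- stats::lm(y ~ t_data, data = samples)
  sm <- summary(fit)$coefficients
  list(
    t_test = list(mean = unname(tt$estimate), ci = unname(tt$conf.int),
                  p = tt$p.value, n = nrow(samples)),
    binomial = list(prob_underprediction = unname(bt$estimate),
                    ci = unname(bt$conf.int), p = bt$p.value, n = n_eff,
                    ties_excluded = ties),
    regression = list(slope = sm["t_data", "Estimate"],
                      se = sm["t_data", "Std. Error"],
                      p = sm["t_data", "Pr(>|t|)"], n = nrow(samples),
                      response = regression_response))
}

#' Cap scenario analyses
#'
#' Recomputes the headline metrics under four capping regimes applied to the
#' retained raw predictions: both caps (base case), minimum only, maximum
#' only, and none, together with the counts of min- and max-adjusted
#' predictions per scenario. Isolates how much of the reported accuracy the
#' caps themselves contribute.
#'
#' @param cells `validation_cells` carrying `raw_pred_eur` and cap
#'   attributes (or supply `min_cap`/`max_cap`).
#' @param min_cap,max_cap the caps; default from the cells' attributes.
#' @param bands percent bands for [band_fractions()].
#' @return data.frame, one row per scenario: n, adjusted counts, unaggregated
#'   mean/sd/median/IQR of the error ratio and the band fractions.
#' @export
scenario_caps <- function(cells, min_cap = attr(cells, "min_cap"),
                          max_cap = attr(cells, "max_cap"),
                          bands = c(40, 100)) {
  if (is.null(min_cap) || is.null(max_cap))
    stop("caps not found on cells; pass min_cap and max_cap", call. = FALSE)
  scen <- list(base = c(TRUE, TRUE), min_only = c(TRUE, FALSE),
               max_only = c(FALSE, TRUE), none = c(FALSE, FALSE))
  rows <- lapply(names(scen), function(nm) {
    lo <- if (scen[[nm]][1L]) min_cap else -Inf
    hi <- if (scen[[nm]][2L]) max_cap else Inf
    cc <- as.data.frame(cells)
    cp <- cap_prediction(cc$raw_pred_eur, lo, hi)
    cc$pred_eur <- cp$pred_eur
    s <- error_samples(cc)
    ag <- aggregate_errors(s, "none")
    bf <- band_fractions(s, bands)
    out <- data.frame(scenario = nm, n = ag$n,
                      n_min_adjusted = sum(cp$capped == "min"),
                      n_max_adjusted = sum(cp$capped == "max"),
                      mean_error = ag$mean, sd_error = ag$sd,
                      median_error = ag$median, iqr_error = ag$iqr)
    for (i in seq_along(bands))
      out[[paste0("within_", bands[i], "pct")]] <- bf$fraction[i]
    out
  })
  do.call(rbind, rows)
}
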