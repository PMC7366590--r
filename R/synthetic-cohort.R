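#' Configure a synthetic budget-impact cohort
#'
#' The generator is the exact generative mirror of the model the package
#' fits: per product i it draws covariates, random effects
#' \eqn{(b_{0i}, b_{1i}) \sim N_2(0, G)} and a stationary AR(1) residual
#' series with marginal variance \eqn{\sigma^2} and lag-1 correlation
#' \eqn{\phi} (innovation variance \eqn{\sigma^2 (1-\phi^2)}), and sets
#' \eqn{\log \mathrm{BI}_{it} = x_{it}'\beta + b_{0i} + b_{1i} t +
#' \varepsilon_{it}}. Euro-scale BI is the exponential, rounded to cents, so
#' the euro-scale distribution is right-skewed by construction.
#'
#' @param n_products number of products; ignored when `launch_plan` is given.
#' @param months_range integer length-2: months per product are drawn
#'   uniformly from this range, then censored by `panel_end` (later launches
#'   have shorter series, as in real panels).
#' @param launch_window `c(start, end)` `"YYYY-MM"` months from which
#'   `first_record_month` is drawn uniformly.
#' @param launch_plan optional data.frame with columns `start`, `end`, `n`:
#'   launch strata with fixed product counts (used to pin cohort sizes on
#'   either side of a split month); overrides `n_products`/`launch_window`.
#' @param panel_end last calendar month with data (`"YYYY-MM"`).
#' @param spec generating [model_spec()] (fixed-effects structure).
#' @param beta named coefficients on the log-euro scale, aligned to the
#'   design columns of `spec`.
#' @param re_cov 2x2 symmetric PSD covariance of (intercept, slope) random
#'   effects.
#' @param sigma2 marginal residual variance (>= 0).
#' @param phi AR(1) lag-1 correlation, |phi| < 1.
#' @param covariate_prevalence list: probabilities `orphan`, `ce`, `fic` and
#'   named probability vectors `tumor_site`, `molecule_type` (each summing
#'   to 1 over the spec's registry levels).
#' @param seed integer RNG seed; the same config yields a byte-identical
#'   panel.
#' @return a `simulation_config`.
#' @export
simulation_config <- function(n_products, months_range, launch_window = NULL,
                              launch_plan = NULL, panel_end, spec, beta,
                              re_cov, sigma2, phi, covariate_prevalence,
                              seed = 1L) {
  if (is.null(launch_plan)) {
    stopifnot(length(launch_window) == 2L)
    launch_plan <- data.frame(start = launch_window[1L],
                              end = launch_window[2L], n = n_products)
  }
  stopifnot(all(c("start", "end", "n") %in% names(launch_plan)))
  re_cov <- as.matrix(re_cov)
  if (!isTRUE(all.equal(re_cov, t(re_cov))) ||
      any(eigen(re_cov, symmetric = TRUE, only.values = TRUE)$values < -1e-10))
    stop("re_cov must be symmetric positive semi-definite", call. = FALSE)
  if (abs(phi) >= 1) stop("|phi| must be < 1", call. = FALSE)
  if (sigma2 < 0) stop("sigma2 must be >= 0", call. = FALSE)
  for (cc in c("tumor_site", "molecule_type")) {
    pr <- covariate_prevalence[[cc]]
    if (!isTRUE(all.equal(sum(pr), 1)))
      stop("covariate_prevalence$", cc, " must sum to 1", call. = FALSE)
    if (!setequal(names(pr), spec$levels[[cc]]))
      stop("covariate_prevalence$", cc, " names must match the spec registry",
           call. = FALSE)
  }
  for (cc in c("orphan", "ce", "fic")) {
    p <- covariate_prevalence[[cc]]
    if (is.null(p) || p < 0 || p > 1)
      stop("covariate_prevalence$", cc, " must be a probability", call. = FALSE)
  }
  structure(list(launch_plan = launch_plan,
                 months_range = as.integer(months_range),
                 panel_end = panel_end, spec = spec, beta = beta,
                 re_cov = re_cov, sigma2 = sigma2, phi = phi,
                 covariate_prevalence = covariate_prevalence,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# stationary AR(1): marginal variance sigma2, lag-1 correlation phi
sim_ar1 <- function(n, sigma2, phi) {
  if (sigma2 == 0) return(numeric(n))
  e <- numeric(n)
  e[1L] <- stats::rnorm(1L, 0, sqrt(sigma2))
  if (n > 1L) {
    innov <- stats::rnorm(n - 1L, 0, sqrt(sigma2 * (1 - phi^2)))
    for (t in 2L:n) e[t] <- phi * e[t - 1L] + innov[t - 1L]
  }
  e
}

#' Simulate a synthetic BI panel
#'
#' @param config a [simulation_config()].
#' @return a valid [panel_dataset()]; identical config (including seed)
#'   gives identical output.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  cp <- config$covariate_prevalence
  plan <- config$launch_plan
  n_tot <- sum(plan$n)
  ids <- sprintf("P%03d", seq_len(n_tot))
  first <- integer(0)
  for (i in seq_len(nrow(plan))) {
    lo <- ym_to_int(plan$start[i]); hi <- ym_to_int(plan$end[i])
    first <- c(first, lo + sample.int(hi - lo + 1L, plan$n[i],
                                      replace = TRUE) - 1L)
  }
  end_int <- ym_to_int(config$panel_end)
  profiles <- data.frame(
    product_id = ids,
    tumor_site = sample(names(cp$tumor_site), n_tot, TRUE, cp$tumor_site),
    molecule_type = sample(names(cp$molecule_type), n_tot, TRUE,
                           cp$molecule_type),
    orphan = stats::runif(n_tot) < cp$orphan,
    ce = stats::runif(n_tot) < cp$ce,
    fic = stats::runif(n_tot) < cp$fic,
    first_record_month = int_to_ym(first),
    stringsAsFactors = FALSE)

  mr <- config$months_range
  months <- mr[1L] + sample.int(mr[2L] - mr[1L] + 1L, n_tot,
                                replace = TRUE) - 1L
  months <- pmin(months, end_int - first + 1L)
  if (any(months < 1L))
    stop("launch_plan places a product after panel_end", call. = FALSE)

  Lre <- if (all(config$re_cov == 0)) matrix(0, 2L, 2L) else
    t(chol(config$re_cov + diag(1e-12, 2L)))

  rec <- vector("list", n_tot)
  for (i in seq_len(n_tot)) {
    n <- months[i]
    t <- seq_len(n)
    row <- profiles[i, , drop = FALSE]
    row$month_index <- 1
    X <- build_design(row, config$spec, t_values = t)
    if (!identical(colnames(X), names(config$beta)))
      stop("beta names must match design columns: ",
           paste(colnames(X), collapse = ", "), call. = FALSE)
    b <- as.vector(Lre %*% stats::rnorm(2L))
    eta <- as.vector(X %*% config$beta) + b[1L] + b[2L] * t +
      sim_ar1(n, config$sigma2, config$phi)
    bi <- pmax(round(exp(eta), 2), 0.01)
    rec[[i]] <- data.frame(product_id = ids[i],
                           calendar_month = int_to_ym(first[i] + t - 1L),
                           month_index = t, bi_eur = bi,
                           stringsAsFactors = FALSE)
  }
  panel_dataset(do.call(rbind, rec), profiles)
}

#' Default configuration emulating the study cohort
#'
#' Returns a documented configuration whose cohort, split at `"2012-05"`,
#' contains exactly `n_training` products launched before the split and
#' `n_validation` launched on/after it (defaults 25 and 44, the study's
#' cohort sizes), with up to 45 months of data per product, series censored
#' at the panel end so late launches are shorter, and right-skewed euro-scale
#' BI. The generating fixed-effects structure is the study's final model:
#' time, time x CE, molecule type, and sqrt(time) x (orphan, first-in-class,
#' tumor site). The source data report no distributional parameters, so
#' absolute euro levels and variance components are the generator's own
#' realistic choices (documented in the methods vignette).
#'
#' @param n_training products launched in the pre-split window.
#' @param n_validation products launched on/after the split month.
#' @param seed RNG seed stored in the config.
#' @return a [simulation_config()]; its split month is `"2012-05"`.
#' @export
paperlike_config <- function(n_training = 25L, n_validation = 44L, seed = 1L) {
  tumor_levels <- c("breast", "colorectal", "hematological", "lung",
                    "melanoma", "other", "prostate")
  mol_levels <- c("monoclonal_antibody", "other", "small_molecule")
  spec <- model_spec(list(
    model_term("time", "t"),
    model_term("ce", "t"),
    model_term("molecule_type"),
    model_term("orphan", "sqrt_t"),
    model_term("fic", "sqrt_t"),
    model_term("tumor_site", "sqrt_t")
  ), levels = list(tumor_site = tumor_levels, molecule_type = mol_levels))

  beta <- c(
    "intercept" = log(3e4),          # ~ EUR 30k in the first month
    "time[t]" = 0.045,               # uptake: ~4.6%/month growth
    "t:ce" = -0.012,                 # conditional approvals grow slower
    "molecule_type=other" = 0.25,
    "molecule_type=small_molecule" = -0.20,
    "sqrt(t):orphan" = -0.30,        # rare-disease products stay smaller
    "sqrt(t):fic" = 0.18,
    "sqrt(t):tumor_site=colorectal" = -0.05,
    "sqrt(t):tumor_site=hematological" = 0.15,
    "sqrt(t):tumor_site=lung" = 0.10,
    "sqrt(t):tumor_site=melanoma" = 0.05,
    "sqrt(t):tumor_site=other" = -0.10,
    "sqrt(t):tumor_site=prostate" = 0.02)

  simulation_config(
    launch_plan = data.frame(
      start = c("2008-06", "2012-05"),
      end = c("2012-04", "2016-01"),
      n = c(n_training, n_validation)),
    months_range = c(24L, 45L),
    panel_end = "2017-10",
    spec = spec, beta = beta,
    re_cov = matrix(c(1.0, -0.01, -0.01, 0.004), 2L, 2L),
    sigma2 = 0.25, phi = 0.6,
    covariate_prevalence = list(
      orphan = 0.30, ce = 0.20, fic = 0.25,
      tumor_site = c(breast = 0.15, colorectal = 0.12, hematological = 0.25,
                     lung = 0.16, melanoma = 0.10, other = 0.14,
                     prostate = 0.08),
      molecule_type = c(monoclonal_antibody = 0.35, other = 0.15,
                        small_molecule = 0.50)),
    seed = seed)
}
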