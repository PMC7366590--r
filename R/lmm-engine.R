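#' Fixed-effect terms and model specifications
#'
#' The fixed-effects structure of the BI model is a list of terms, each a
#' covariate paired with an optional time transform. A transform other than
#' `"none"` denotes an interaction of the covariate indicator with that
#' function of time; the covariate `"time"` paired with a transform is a time
#' main effect on that scale. Admissible transforms are `t`, `t^2` .. `t^6`
#' and `sqrt(t)` — the candidate set used to model time dependence. At most
#' one time transform per covariate is allowed in any specification.
#'
#' @param covariate one of `"intercept"`, `"time"`, `"tumor_site"`,
#'   `"molecule_type"`, `"orphan"`, `"ce"`, `"fic"`.
#' @param transform one of `"none"`, `"t"`, `"t2"` .. `"t6"`, `"sqrt_t"`.
#' @return a `model_term`.
#' @export
model_term <- function(covariate, transform = "none") {
  covariate <- match.arg(covariate, c("intercept", "time", "tumor_site",
                                      "molecule_type", "orphan", "ce", "fic"))
  transform <- match.arg(transform, c("none", "t", "t2", "t3", "t4", "t5",
                                      "t6", "sqrt_t"))
  if (covariate == "intercept" && transform != "none")
    stop("the intercept takes no time transform", call. = FALSE)
  if (covariate == "time" && transform == "none")
    stop("a time term needs a transform (use transform = \"t\" for linear time)",
         call. = FALSE)
  structure(list(covariate = covariate, transform = transform),
            class = "model_term")
}

transform_fun <- function(transform) {
  switch(transform,
         none = function(t) rep(1, length(t)),
         t = function(t) t,
         t2 = function(t) t^2, t3 = function(t) t^3, t4 = function(t) t^4,
         t5 = function(t) t^5, t6 = function(t) t^6,
         sqrt_t = function(t) sqrt(t))
}

transform_label <- function(transform) {
  switch(transform, none = "", t = "t", t2 = "t^2", t3 = "t^3", t4 = "t^4",
         t5 = "t^5", t6 = "t^6", sqrt_t = "sqrt(t)")
}

#' @rdname model_term
#' @export
term_label <- function(term) {
  if (term$covariate == "intercept") return("intercept")
  if (term$covariate == "time") return(paste0("time[", transform_label(term$transform), "]"))
  if (term$transform == "none") return(term$covariate)
  paste0(transform_label(term$transform), ":", term$covariate)
}

#' @export
print.model_term <- function(x, ...) {
  cat(term_label(x), "\n")
  invisible(x)
}

#' Build a model specification
#'
#' Collects fixed-effect terms together with the level registry of the
#' categorical covariates. The registry is fixed once — typically from the
#' full covariate table — so that dummy coding and reference levels stay
#' identical across every refit of a validation run. Reference levels are the
#' lexicographically smallest level of each categorical. The random-effects
#' structure (random intercept and time slope per product) and the AR(1)
#' within-product residual correlation are not part of the specification:
#' they are fixed properties of the model family.
#'
#' @param terms list of [model_term()]s; an intercept is prepended when absent.
#' @param levels named list with character vectors `tumor_site` and
#'   `molecule_type` (sorted internally); required when any term uses a
#'   categorical covariate, or supply via `registry_from_profiles()`.
#' @return a `model_spec`.
#' @export
model_spec <- function(terms = list(), levels = list()) {
  terms <- lapply(terms, function(x) {
    if (!inherits(x, "model_term")) x <- do.call(model_term, x)
    x
  })
  labs <- vapply(terms, term_label, "")
  if (anyDuplicated(labs)) stop("duplicate term: ",
                                labs[duplicated(labs)][1L], call. = FALSE)
  if (!"intercept" %in% labs)
    terms <- c(list(model_term("intercept")), terms)
  # at most one time transform per covariate
  cov <- vapply(terms, function(x) x$covariate, "")
  tr <- vapply(terms, function(x) x$transform, "")
  inter <- cov[tr != "none"]
  if (anyDuplicated(inter))
    stop("only a single time interaction per covariate is allowed (covariate ",
         inter[duplicated(inter)][1L], ")", call. = FALSE)
  for (cc in intersect(cov, c("tumor_site", "molecule_type"))) {
    if (is.null(levels[[cc]]) || length(levels[[cc]]) < 2L)
      stop("spec uses categorical covariate ", cc,
           " but the level registry has fewer than 2 levels for it",
           call. = FALSE)
  }
  levels <- lapply(levels, function(l) sort(unique(as.character(l))))
  structure(list(terms = terms, levels = levels), class = "model_spec")
}

#' @rdname model_spec
#' @export
registry_from_profiles <- function(profiles) {
  list(tumor_site = sort(unique(as.character(profiles$tumor_site))),
       molecule_type = sort(unique(as.character(profiles$molecule_type))))
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Fixed effects: ",
      paste(vapply(x$terms, term_label, ""), collapse = " + "), "\n", sep = "")
  cat("Random effects: ~ time | product;  correlation: AR(1) in time\n")
  invisible(x)
}

spec_labels <- function(spec) vapply(spec$terms, term_label, "")

#' Build the fixed-effects design matrix
#'
#' One row per product-month. Categorical covariates are dummy-coded against
#' the lexicographically smallest level of the spec's registry; a term with a
#' time transform contributes indicator-times-f(t) columns. Column order
#' follows the spec's term order and is deterministic. A categorical value
#' absent from the registry is mapped to the reference level with a warning —
#' prediction must not fail mid-validation.
#'
#' @param data a [panel_dataset()], a `panel_frame`-style data.frame with a
#'   `month_index` column, or a single-row profile data.frame combined with
#'   `t_values`.
#' @param spec a [model_spec()].
#' @param t_values optional integer months; when supplied with a single-row
#'   profile the profile is expanded to one row per month.
#' @return numeric matrix with attributes `assign` (term index per column)
#'   and `term_labels`.
#' @export
build_design <- function(data, spec, t_values = NULL) {
  if (inherits(data, "panel_dataset")) data <- panel_frame(data)
  if (!is.null(t_values)) {
    if (nrow(data) == 1L) {
      data <- data[rep(1L, length(t_values)), , drop = FALSE]
      data$month_index <- as.numeric(t_values)
    } else if (nrow(data) != length(t_values)) {
      stop("t_values must match the number of profile rows", call. = FALSE)
    } else data$month_index <- as.numeric(t_values)
  }
  t <- as.numeric(data$month_index)
  if (any(!is.finite(t) | t < 1))
    stop("month_index must be >= 1 for every design row", call. = FALSE)
  cols <- list(); assign <- integer(0)
  for (j in seq_along(spec$terms)) {
    term <- spec$terms[[j]]
    f <- transform_fun(term$transform)(t)
    lab <- term_label(term)
    if (term$covariate == "intercept") {
      cols[[lab]] <- rep(1, length(t)); assign <- c(assign, j)
    } else if (term$covariate == "time") {
      cols[[lab]] <- f; assign <- c(assign, j)
    } else if (term$covariate %in% c("orphan", "ce", "fic")) {
      cols[[lab]] <- as.numeric(data[[term$covariate]]) * f
      assign <- c(assign, j)
    } else {
      lv <- spec$levels[[term$covariate]]
      x <- as.character(data[[term$covariate]])
      unseen <- setdiff(unique(x), lv)
      if (length(unseen)) {
        warning("level(s) ", paste(unseen, collapse = ", "), " of ",
                term$covariate, " absent from the registry; mapped to ",
                "reference level ", lv[1L])
        x[x %in% unseen] <- lv[1L]
      }
      for (l in lv[-1L]) {
        nm <- if (term$transform == "none") paste0(term$covariate, "=", l)
              else paste0(transform_label(term$transform), ":",
                          term$covariate, "=", l)
        cols[[nm]] <- as.numeric(x == l) * f
        assign <- c(assign, j)
      }
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  attr(X, "assign") <- assign
  attr(X, "term_labels") <- spec_labels(spec)
  X
}

## ---- likelihood machinery -------------------------------------------------
## Per product i with n_i consecutive months 1..n_i:
##   y_i = X_i beta + Z_i b_i + e_i,   Z_i = [1, t],
##   b_i ~ N(0, G),  e_i ~ N(0, sigma2 * R_i(phi)),  R_i(phi)[a,b] = phi^|a-b|
## so V_i = Z_i G Z_i' + sigma2 R_i(phi). Because every series runs over the
## grid 1..n_i, V_i depends on the parameters and n_i only; products are
## grouped by series length and each V is factored once per evaluation.

# context: everything about (data, spec) that does not depend on parameters
lmm_context <- function(df, spec) {
  df <- df[order(df$product_id, df$month_index), , drop = FALSE]
  X <- build_design(df, spec)
  y <- df$log_bi
  pid <- df$product_id
  n_i <- as.integer(table(factor(pid, levels = unique(pid))))
  prods <- unique(pid)
  groups <- list()
  offs <- c(0L, cumsum(n_i))
  for (n in sort(unique(n_i))) {
    which_p <- which(n_i == n)
    rows <- unlist(lapply(which_p, function(k) (offs[k] + 1L):offs[k + 1L]),
                   use.names = FALSE)
    groups[[as.character(n)]] <- list(n = n, g = length(which_p),
                                      rows = rows, products = prods[which_p])
  }
  list(X = X, y = y, N = length(y), p = ncol(X), groups = groups,
       products = prods, n_i = n_i, df = df)
}

theta_to_params <- function(theta) {
  L <- matrix(c(exp(theta[1L]), theta[2L], 0, exp(theta[3L])), 2L, 2L)
  list(G = L %*% t(L), sigma2 = exp(theta[4L]), phi = tanh(theta[5L]))
}

params_to_theta <- function(re_cov, sigma2, phi) {
  L <- t(chol(re_cov + diag(1e-12, 2L)))
  c(log(L[1L, 1L]), L[2L, 1L], log(L[2L, 2L]), log(sigma2), atanh(phi))
}

group_cov <- function(n, G, sigma2, phi) {
  tg <- seq_len(n)
  Z <- cbind(1, tg)
  R <- phi^abs(outer(tg, tg, "-"))
  Z %*% G %*% t(Z) + sigma2 * R
}

# whiten the stacked observations group by group; returns whitened X, y and
# the total log-determinant, or NULL when some V is not positive definite
whiten_all <- function(ctx, G, sigma2, phi) {
  Xw <- matrix(0, ctx$N, ctx$p); yw <- numeric(ctx$N); logdet <- 0
  for (grp in ctx$groups) {
    n <- grp$n; g <- grp$g; rows <- grp$rows
    V <- group_cov(n, G, sigma2, phi)
    U <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(U)) return(NULL)
    logdet <- logdet + g * 2 * sum(log(diag(U)))
    # solve L w = v for all series at once: columns are (product, coefficient)
    M <- matrix(cbind(matrix(ctx$y[rows], nrow = n),
                      matrix(ctx$X[rows, , drop = FALSE], nrow = n)),
                nrow = n)
    W <- backsolve(U, M, transpose = TRUE)
    yw[rows] <- as.vector(W[, seq_len(g)])
    Xw[rows, ] <- matrix(W[, -seq_len(g), drop = FALSE], nrow = n * g)
  }
  list(Xw = Xw, yw = yw, logdet = logdet)
}

BIG_NLL <- 1e10

# deterministic starting values: (1) method-of-moments — per-product OLS
# intercept/slope covariance for G, pooled lag-1 autocorrelation of the OLS
# residuals for phi; (2) a flat fallback (G = 0.1 I, phi = 0). The likelihood
# has a known near-ridge where the random intercept trades off against a
# high-phi AR(1) process, so the optimizer is run from both starts and the
# better optimum kept.
default_starts <- function(ctx) {
  ols <- stats::lm.fit(ctx$X, ctx$y)
  s2 <- max(sum(ols$residuals^2) / ctx$N, 1e-8)
  flat <- c(log(sqrt(0.1)), 0, log(sqrt(0.1)), log(s2), 0)
  B <- NULL; num <- 0; den <- 0; rss <- 0; nres <- 0
  off <- 0L
  for (i in seq_along(ctx$n_i)) {
    n <- ctx$n_i[i]; rows <- off + seq_len(n); off <- off + n
    if (n >= 3L) {
      t <- seq_len(n)
      f <- stats::lm.fit(cbind(1, t), ctx$y[rows])
      B <- rbind(B, f$coefficients)
      r <- f$residuals
      num <- num + sum(r[-1L] * r[-n]); den <- den + sum(r[-n]^2)
      rss <- rss + sum(r^2); nres <- nres + n
    }
  }
  if (is.null(B) || nrow(B) < 3L) return(list(flat))
  G0 <- stats::cov(B)
  G0 <- G0 + diag(c(1e-4, 1e-6))
  phi0 <- max(min(num / max(den, 1e-12), 0.9), -0.9)
  s20 <- max(rss / nres, 1e-8)
  mom <- params_to_theta(G0, s20, phi0)
  list(mom, flat)
}

# negative log-likelihood profiled over beta (GLS via QR on whitened design)
profile_nll <- function(theta, ctx, want_beta = FALSE) {
  if (any(!is.finite(theta))) return(if (want_beta) NULL else BIG_NLL)
  pr <- theta_to_params(theta)
  w <- whiten_all(ctx, pr$G, pr$sigma2, pr$phi)
  if (is.null(w) || !is.finite(w$logdet) || anyNA(w$Xw) ||
      any(!is.finite(w$yw)) || any(!is.finite(w$Xw)))
    return(if (want_beta) NULL else BIG_NLL)
  qrw <- qr(w$Xw)
  if (qrw$rank < ctx$p) return(if (want_beta) NULL else BIG_NLL)
  beta <- qr.coef(qrw, w$yw)
  rss <- sum(qr.resid(qrw, w$yw)^2)
  nll <- 0.5 * (ctx$N * log(2 * pi) + w$logdet + rss)
  if (!want_beta) return(nll)
  Rmat <- qr.R(qrw)[, order(qrw$pivot), drop = FALSE]
  beta_vcov <- chol2inv(chol(crossprod(Rmat)))
  dimnames(beta_vcov) <- list(colnames(ctx$X), colnames(ctx$X))
  list(nll = nll, beta = beta, beta_vcov = beta_vcov, params = pr)
}

#' Negative log-likelihood of the mixed model at given parameters
#'
#' Evaluates \eqn{-\ell = \sum_i \frac12 [n_i \log 2\pi + \log|V_i| +
#' r_i' V_i^{-1} r_i]} with \eqn{r_i = y_i - X_i\beta} (y is log BI) and
#' \eqn{V_i = Z_i G Z_i' + \sigma^2 R_i(\phi)}, \eqn{R_i(\phi)_{ab} =
#' \phi^{|a-b|}}. Exposed mainly for audit: [fit_lmm()] maximizes this
#' likelihood with \eqn{\beta} profiled out.
#'
#' @param dataset a [panel_dataset()] or panel frame.
#' @param spec a [model_spec()].
#' @param params list with `beta` (aligned to [build_design()] columns),
#'   `re_cov` (2x2 PSD), `sigma2` (> 0) and `phi` (|phi| < 1).
#' @return the scalar negative log-likelihood.
#' @export
neg_log_likelihood <- function(dataset, spec, params) {
  df <- if (inherits(dataset, "panel_dataset")) panel_frame(dataset) else dataset
  ctx <- lmm_context(df, spec)
  stopifnot(length(params$beta) == ctx$p, abs(params$phi) < 1,
            params$sigma2 >= 0)
  G <- (params$re_cov + t(params$re_cov)) / 2
  w <- whiten_all(ctx, G, params$sigma2, params$phi)
  if (is.null(w)) {
    bad <- ctx$groups[[1L]]$products[1L]
    stop("marginal covariance not positive definite (e.g. product ", bad, ")",
         call. = FALSE)
  }
  r <- w$yw - w$Xw %*% params$beta
  0.5 * (ctx$N * log(2 * pi) + w$logdet + sum(r^2))
}

#' Fit the budget-impact mixed model by maximum likelihood
#'
#' Maximum-likelihood estimation of the log-BI linear mixed model with a
#' random intercept and time slope per product and AR(1) within-product
#' residual correlation. \eqn{\beta} is profiled out by generalized least
#' squares; the five variance parameters are maximized by quasi-Newton (BFGS)
#' on unconstrained transforms: the log-Cholesky factor of G, \eqn{\log
#' \sigma^2} and \eqn{\mathrm{atanh}\,\phi}. Starting values are a fixed,
#' deterministic pair — a method-of-moments start (per-product OLS
#' intercept/slope covariance, pooled residual lag-1 autocorrelation) and a
#' flat start (OLS residual variance, G = 0.1 I, phi = 0) — with the better
#' optimum kept, so refits of the same data are bit-identical. ML rather
#' than REML is used throughout because the stepwise
#' search compares AICs across different fixed-effects structures, which is
#' only valid under ML.
#'
#' @param dataset a [panel_dataset()] or panel frame (>= 2 products, more
#'   observations than parameters).
#' @param spec a [model_spec()].
#' @param start optional 5-vector of unconstrained starting values (used by
#'   internal warm paths; the default is the documented fixed start).
#' @return a `bi_lmm`: coefficients with standard errors, `re_cov`, `sigma2`,
#'   `phi`, `loglik`, `aic` (= 2k - 2 loglik with k = p + 5), per-product
#'   BLUPs and a `converged` flag. Non-convergence is flagged, never silent.
#' @export
fit_lmm <- function(dataset, spec, start = NULL) {
  df <- if (inherits(dataset, "panel_dataset")) panel_frame(dataset) else dataset
  ctx <- lmm_context(df, spec)
  if (length(ctx$products) < 2L)
    stop("at least 2 products are required to estimate the model", call. = FALSE)
  k <- ctx$p + 5L
  if (ctx$N <= k)
    stop("too few observations (", ctx$N, ") for ", k, " parameters",
         call. = FALSE)
  if (length(unique(df$month_index)) < 2L)
    stop("degenerate data: a single time point overall", call. = FALSE)
  starts <- if (is.null(start)) default_starts(ctx) else list(start)
  opt <- NULL
  for (st in starts) {
    o <- stats::optim(st, profile_nll, ctx = ctx, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-8))
    if (is.null(opt) || o$value < opt$value) opt <- o
  }
  at <- profile_nll(opt$par, ctx, want_beta = TRUE)
  if (is.null(at))
    stop("likelihood undefined at optimizer solution", call. = FALSE)
  pr <- at$params
  blups <- compute_blups(ctx, at$beta, pr$G, pr$sigma2, pr$phi)
  loglik <- -at$nll
  structure(list(
    spec = spec,
    beta = stats::setNames(as.numeric(at$beta), colnames(ctx$X)),
    beta_vcov = at$beta_vcov,
    se = sqrt(diag(at$beta_vcov)),
    re_cov = pr$G, sigma2 = pr$sigma2, phi = pr$phi,
    loglik = loglik, aic = 2 * k - 2 * loglik,
    n_obs = ctx$N, n_params = k, n_products = length(ctx$products),
    blups = blups,
    assign = attr(ctx$X, "assign"),
    converged = opt$convergence == 0L,
    theta = opt$par
  ), class = "bi_lmm")
}

compute_blups <- function(ctx, beta, G, sigma2, phi) {
  resid <- ctx$y - as.vector(ctx$X %*% beta)
  out <- data.frame(product_id = ctx$products, b0 = 0, b1 = 0,
                    stringsAsFactors = FALSE)
  for (grp in ctx$groups) {
    n <- grp$n
    V <- group_cov(n, G, sigma2, phi)
    Z <- cbind(1, seq_len(n))
    # b_i = G Z' V^-1 r_i for all series of this length at once
    B <- G %*% t(Z) %*% solve(V, matrix(resid[grp$rows], nrow = n))
    ix <- match(grp$products, out$product_id)
    out$b0[ix] <- B[1L, ]; out$b1[ix] <- B[2L, ]
  }
  out
}

#' @export
print.bi_lmm <- function(x, ...) {
  cat("Linear mixed model on log monthly BI (ML",
      if (!x$converged) ", NOT CONVERGED" else "", ")\n", sep = "")
  print(x$spec)
  cat(sprintf("  logLik %.3f  AIC %.3f  (n = %d obs, %d products, k = %d)\n",
              x$loglik, x$aic, x$n_obs, x$n_products, x$n_params))
  co <- cbind(estimate = x$beta, se = x$se)
  print(round(co, 4))
  cat(sprintf("  re_cov: var(b0) %.4f, var(b1) %.5f, cov %.5f\n",
              x$re_cov[1, 1], x$re_cov[2, 2], x$re_cov[1, 2]))
  cat(sprintf("  sigma2 %.4f  phi %.4f\n", x$sigma2, x$phi))
  invisible(x)
}

#' Predict log budget impact for a product
#'
#' Population-level prediction \eqn{x'\hat\beta} when the product contributed
#' no data to the fit; conditional prediction \eqn{x'\hat\beta + \hat b_{0i}
#' + \hat b_{1i} t} using the product's BLUPs when it did. The prediction is
#' marginal over the AR(1) residual process: residual autocorrelation
#' sharpens estimation but is not used to forecast future residuals.
#'
#' @param model a fitted `bi_lmm`.
#' @param profile single-row data.frame with the product's covariates.
#' @param t_range integer months (>= 1) to predict.
#' @param product_id id used to look up BLUPs; defaults to the profile's id.
#'   Products absent from the fit get the population prediction.
#' @return numeric vector of predicted log BI, one per month of `t_range`.
#' @export
predict_log_bi <- function(model, profile, t_range,
                           product_id = profile$product_id) {
  t_range <- as.integer(t_range)
  if (any(t_range < 1L)) stop("t_range months must be >= 1", call. = FALSE)
  X <- build_design(profile, model$spec, t_values = t_range)
  pred <- as.vector(X %*% model$beta)
  ix <- match(as.character(product_id), model$blups$product_id)
  if (!is.na(ix))
    pred <- pred + model$blups$b0[ix] + model$blups$b1[ix] * t_range
  pred
}

#' Wald test for a fixed-effect term
#'
#' Two-sided p-value from coefficient / s.e. against the standard normal for
#' single-column terms; a joint Wald chi-square across the term's dummy
#' columns for multi-level categorical terms. This is the p < 0.10 gate of
#' the forward stepwise search.
#'
#' @param model a fitted `bi_lmm`.
#' @param term a [model_term()] (or its label) present in the model's spec.
#' @return the p-value.
#' @export
wald_p <- function(model, term) {
  lab <- if (is.character(term)) term else term_label(term)
  labs <- spec_labels(model$spec)
  j <- match(lab, labs)
  if (is.na(j)) stop("term '", lab, "' is not in the model", call. = FALSE)
  cols <- which(model$assign == j)
  b <- model$beta[cols]
  if (length(cols) == 1L) {
    z <- b / model$se[cols]
    return(unname(2 * stats::pnorm(-abs(z))))
  }
  Vb <- model$beta_vcov[cols, cols, drop = FALSE]
  W <- as.numeric(t(b) %*% solve(Vb, b))
  stats::pchisq(W, df = length(cols), lower.tail = FALSE)
}

#' Serialize / restore a fitted model as JSON
#'
#' Coefficients, variance parameters, BLUPs and convergence metadata are
#' written for audit and resumption; the level registry travels with the
#' spec so predictions are reproducible from the file alone.
#'
#' @param model a fitted `bi_lmm`.
#' @param path file path.
#' @return `model_to_json` invisibly returns `path`; `model_from_json` a list
#'   mirroring the fitted model (without refitting machinery).
#' @export
model_to_json <- function(model, path) {
  obj <- list(
    terms = lapply(model$spec$terms, function(tm)
      list(covariate = tm$covariate, transform = tm$transform)),
    levels = model$spec$levels,
    beta = as.list(model$beta),
    se = as.list(stats::setNames(model$se, names(model$beta))),
    re_cov = model$re_cov, sigma2 = model$sigma2, phi = model$phi,
    loglik = model$loglik, aic = model$aic,
    n_obs = model$n_obs, n_params = model$n_params,
    blups = model$blups, converged = model$converged)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname model_to_json
#' @export
model_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$spec <- model_spec(lapply(seq_len(nrow(obj$terms)), function(i)
    model_term(obj$terms$covariate[i], obj$terms$transform[i])),
    levels = obj$levels)
  obj$beta <- unlist(obj$beta)
  obj$se <- unlist(obj$se)
  obj$re_cov <- matrix(unlist(obj$re_cov), 2L, 2L)
  obj
}
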