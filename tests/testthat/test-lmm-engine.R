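# independent oracle: joint multivariate-normal density over the explicit
# block-diagonal covariance of all observations, evaluated with determinant()
# and solve() only
dense_mvn_nll <- function(df, X, beta, G, sigma2, phi) {
  ids <- unique(df$product_id)
  N <- nrow(df)
  Vfull <- matrix(0, N, N)
  for (k in ids) {
    ix <- which(df$product_id == k)
    t <- df$month_index[ix]
    Z <- cbind(1, t)
    R <- phi^abs(outer(t, t, "-"))
    Vfull[ix, ix] <- Z %*% G %*% t(Z) + sigma2 * R
  }
  r <- df$log_bi - as.vector(X %*% beta)
  ld <- as.numeric(determinant(Vfull, logarithm = TRUE)$modulus)
  0.5 * (N * log(2 * pi) + ld + as.numeric(t(r) %*% solve(Vfull) %*% r))
}

test_that("design matrices code terms, transforms and dummies correctly", {
  ds <- toy_panel()
  X1 <- build_design(ds, model_spec(list(), levels = toy_levels()))
  expect_equal(unname(X1[, 1]), rep(1, 5))   # intercept-only: column of ones
  prof <- ds$profiles[1, ]                    # orphan product
  Xs <- build_design(prof, toy_spec(), t_values = c(4, 9))
  expect_equal(unname(Xs[, "sqrt(t):orphan"]), c(2, 3))  # sqrt(9) = 3
  Xc <- build_design(ds$profiles[2, ],        # non-CE product
                     model_spec(list(model_term("ce", "t")),
                                levels = toy_levels()), t_values = 1:3)
  expect_equal(unname(Xc[, "t:ce"]), c(0, 0, 0))
  # categorical dummy against lexicographic reference + interaction naming
  Xd <- build_design(ds, model_spec(list(model_term("tumor_site", "sqrt_t")),
                                    levels = toy_levels()))
  expect_true("sqrt(t):tumor_site=lung" %in% colnames(Xd))
  expect_false(any(grepl("breast", colnames(Xd))))  # reference level
  # unseen level maps to reference with a warning
  odd <- ds$profiles[1, ]; odd$tumor_site <- "pancreas"
  expect_warning(
    Xu <- build_design(odd, model_spec(list(model_term("tumor_site")),
                                       levels = toy_levels()), t_values = 1),
    "pancreas")
  expect_equal(unname(Xu[, "tumor_site=lung"]), 0)
  expect_error(build_design(prof, toy_spec(), t_values = 0), ">= 1")
})

test_that("model_spec enforces one time transform per covariate", {
  expect_error(model_spec(list(model_term("orphan", "t"),
                               model_term("orphan", "sqrt_t")),
                          levels = toy_levels()),
               "single time interaction")
  expect_error(model_term("intercept", "t"), "no time transform")
  sp <- model_spec(list(model_term("orphan"), model_term("orphan", "t")),
                   levels = toy_levels())  # main + one interaction is fine
  expect_length(sp$terms, 3L)              # intercept prepended
})

test_that("AR(1) correlation follows phi^|lag| and the iid limit is exact", {
  V <- bipanel:::group_cov(3, matrix(0, 2, 2), 1, 0.5)
  expect_equal(V, rbind(c(1, .5, .25), c(.5, 1, .5), c(.25, .5, 1)))
  ds <- simulate_cohort(toy_config(n_products = 4, months = c(5, 8), seed = 2))
  spec <- toy_spec()
  beta <- c(10, 0.05, -0.3)
  nll <- neg_log_likelihood(ds, spec, list(beta = beta,
                                           re_cov = matrix(0, 2, 2),
                                           sigma2 = 0.4, phi = 0))
  df <- panel_frame(ds)
  r <- df$log_bi - as.vector(build_design(ds, spec) %*% beta)
  expect_equal(nll, -sum(stats::dnorm(r, 0, sqrt(0.4), log = TRUE)),
               tolerance = 1e-12)
})

test_that("likelihood matches the dense-MVN oracle on small instances", {
  ds <- simulate_cohort(toy_config(n_products = 3, months = c(4, 4), seed = 8))
  df <- panel_frame(ds)
  expect_lte(nrow(df), 12L)
  spec <- toy_spec()
  X <- build_design(ds, spec)
  cases <- list(
    list(beta = c(10, 0.05, -0.3),
         G = matrix(c(0.8, -0.01, -0.01, 0.003), 2), s2 = 0.3, phi = 0.5),
    list(beta = c(9, 0.1, 0),
         G = matrix(c(0.2, 0.01, 0.01, 0.01), 2), s2 = 1.5, phi = -0.4),
    list(beta = c(11, -0.02, 0.2),
         G = matrix(c(2, 0.1, 0.1, 0.05), 2), s2 = 0.05, phi = 0.9))
  for (cs in cases) {
    ours <- neg_log_likelihood(ds, spec, list(beta = cs$beta, re_cov = cs$G,
                                              sigma2 = cs$s2, phi = cs$phi))
    oracle <- dense_mvn_nll(df, X, cs$beta, cs$G, cs$s2, cs$phi)
    expect_equal(ours, oracle, tolerance = 1e-8)
  }
})

test_that("fit collapses to OLS when there are no random effects", {
  cfg <- toy_config(n_products = 40, re_cov = matrix(0, 2, 2), phi = 0,
                    sigma2 = 0.3, seed = 12)
  ds <- simulate_cohort(cfg)
  m <- fit_lmm(ds, toy_spec())
  X <- build_design(ds, toy_spec())
  ols <- stats::lm.fit(X, panel_frame(ds)$log_bi)
  expect_lt(max(abs(m$beta - ols$coefficients) / m$se), 2)
  expect_lt(m$re_cov[1, 1], 0.05)
  expect_lt(abs(m$phi), 0.1)
})

test_that("refitting the same data is bit-identical and AIC is 2k - 2l", {
  ds <- simulate_cohort(toy_config(n_products = 12, seed = 4))
  m1 <- fit_lmm(ds, toy_spec())
  m2 <- fit_lmm(ds, toy_spec())
  expect_identical(m1$beta, m2$beta)
  expect_identical(m1$theta, m2$theta)
  expect_identical(m1$aic, 2 * m1$n_params - 2 * m1$loglik)
  expect_equal(m1$n_params, length(m1$beta) + 5L)
  expect_true(m1$converged)
})

test_that("estimates agree with the reference mixed-model implementation", {
  skip_if_not_installed("nlme")
  ds <- simulate_cohort(toy_config(n_products = 40, seed = 21))
  m <- fit_lmm(ds, toy_spec())
  df <- panel_frame(ds)
  df$t <- df$month_index; df$sq <- sqrt(df$t) * df$orphan
  fm <- nlme::lme(log_bi ~ t + sq, random = ~ t | product_id, data = df,
                  correlation = nlme::corAR1(form = ~ t | product_id),
                  method = "ML",
                  control = nlme::lmeControl(maxIter = 300, msMaxIter = 300))
  expect_equal(m$loglik, as.numeric(stats::logLik(fm)), tolerance = 1e-6)
  expect_equal(unname(m$beta), unname(nlme::fixef(fm)), tolerance = 1e-4)
  expect_equal(m$sigma2, fm$sigma^2, tolerance = 1e-3)
  expect_equal(m$phi,
               as.numeric(stats::coef(fm$modelStruct$corStruct,
                                      unconstrained = FALSE)),
               tolerance = 1e-3)
  expect_lt(max(abs(unclass(nlme::getVarCov(fm))[1:4] - as.vector(m$re_cov))),
            0.01)
})

test_that("BLUPs match the closed form and vanish with the random variance", {
  ds <- simulate_cohort(toy_config(n_products = 6, months = c(6, 10), seed = 6))
  m <- fit_lmm(ds, toy_spec())
  df <- panel_frame(ds)
  X <- build_design(ds, toy_spec())
  r <- df$log_bi - as.vector(X %*% m$beta)
  for (k in m$blups$product_id) {
    ix <- which(df$product_id == k)
    t <- df$month_index[ix]
    Z <- cbind(1, t)
    V <- Z %*% m$re_cov %*% t(Z) + m$sigma2 * m$phi^abs(outer(t, t, "-"))
    b <- as.vector(m$re_cov %*% t(Z) %*% solve(V, r[ix]))
    i <- match(k, m$blups$product_id)
    expect_equal(c(m$blups$b0[i], m$blups$b1[i]), b, tolerance = 1e-8)
  }
  # monotone shrinkage: scaling re_cov -> 0 drives every BLUP to 0
  ctx <- bipanel:::lmm_context(df, toy_spec())
  sizes <- vapply(c(1, 0.1, 0.01, 1e-6), function(s) {
    bl <- bipanel:::compute_blups(ctx, m$beta, s * m$re_cov, m$sigma2, m$phi)
    max(abs(c(bl$b0, bl$b1)))
  }, 0)
  expect_true(all(diff(sizes) < 0))
  expect_lt(sizes[4], 1e-4)
})

test_that("predictions use BLUPs for fitted products, population otherwise", {
  ds <- simulate_cohort(toy_config(n_products = 8, seed = 31))
  m <- fit_lmm(ds, toy_spec())
  prof <- ds$profiles[1, ]
  t <- 1:10
  X <- build_design(prof, toy_spec(), t_values = t)
  pop <- as.vector(X %*% m$beta)
  i <- match(prof$product_id, m$blups$product_id)
  expect_equal(predict_log_bi(m, prof, t),
               pop + m$blups$b0[i] + m$blups$b1[i] * t)
  expect_equal(predict_log_bi(m, prof, t, product_id = "not-in-fit"), pop)
  expect_error(predict_log_bi(m, prof, 0:3), ">= 1")
  # a product with large positive residuals gets a positive BLUP intercept
  df <- panel_frame(ds)
  rbar <- tapply(df$log_bi - as.vector(build_design(ds, toy_spec()) %*% m$beta),
                 df$product_id, mean)
  top <- names(which.max(rbar))
  expect_gt(m$blups$b0[match(top, m$blups$product_id)], 0)
})

test_that("adding a constant to log BI only shifts the intercept", {
  ds <- simulate_cohort(toy_config(n_products = 15, seed = 41))
  m0 <- fit_lmm(ds, toy_spec())
  shifted <- ds
  shifted$records$bi_eur <- shifted$records$bi_eur * exp(1)
  m1 <- fit_lmm(shifted, toy_spec())
  expect_equal(m1$beta[["intercept"]], m0$beta[["intercept"]] + 1,
               tolerance = 1e-4)
  expect_equal(m1$beta[-1], m0$beta[-1], tolerance = 1e-4)
  expect_equal(m1$sigma2, m0$sigma2, tolerance = 1e-3)
  expect_equal(m1$phi, m0$phi, tolerance = 1e-3)
  expect_equal(m1$re_cov, m0$re_cov, tolerance = 1e-2)
})

test_that("Wald p-values follow the normal/chi-square reference", {
  fake <- structure(list(
    spec = model_spec(list(model_term("orphan"),
                           model_term("tumor_site")),
                      levels = toy_levels()),
    beta = c(intercept = 5, orphan = 0, "tumor_site=lung" = 0),
    se = c(1, 0.5, 1),
    beta_vcov = diag(c(1, 0.25, 1)),
    assign = c(1L, 2L, 3L)), class = "bi_lmm")
  expect_equal(wald_p(fake, model_term("orphan")), 1)          # z = 0
  fake$beta[["orphan"]] <- 1.96 * 0.5
  expect_equal(wald_p(fake, "orphan"), 0.05, tolerance = 1e-3) # z = 1.96
  expect_equal(wald_p(fake, "tumor_site"), 1)                  # joint, b = 0
  expect_error(wald_p(fake, model_term("fic")), "not in the model")
})

test_that("fitted likelihood is at least that of the generating parameters", {
  truth <- list(beta = c(10, 0.05, -0.3),
                re_cov = matrix(c(0.8, -0.01, -0.01, 0.003), 2),
                sigma2 = 0.3, phi = 0.5)
  for (s in c(2, 9)) {
    ds <- simulate_cohort(toy_config(n_products = 25, seed = s))
    m <- fit_lmm(ds, toy_spec())
    expect_lte(-m$loglik, neg_log_likelihood(ds, toy_spec(), truth) + 1e-6)
  }
})

test_that("fitted models survive a JSON round trip", {
  ds <- simulate_cohort(toy_config(n_products = 8, seed = 55))
  m <- fit_lmm(ds, toy_spec())
  p <- withr::local_tempfile(fileext = ".json")
  model_to_json(m, p)
  back <- model_from_json(p)
  expect_equal(back$beta, m$beta, tolerance = 1e-12)
  expect_equal(back$phi, m$phi)
  expect_equal(vapply(back$spec$terms, term_label, ""),
               vapply(m$spec$terms, term_label, ""))
  expect_equal(back$blups$b0, m$blups$b0, tolerance = 1e-12)
})
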