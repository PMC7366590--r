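# fixtures are built in code: small registries, configs and cohorts shared
# across test files

toy_levels <- function() {
  list(tumor_site = c("breast", "lung"),
       molecule_type = c("mab", "small"))
}

toy_spec <- function(terms = list(model_term("time", "t"),
                                  model_term("orphan", "sqrt_t"))) {
  model_spec(terms, levels = toy_levels())
}

toy_prevalence <- function() {
  list(orphan = 0.4, ce = 0.2, fic = 0.3,
       tumor_site = c(breast = 0.5, lung = 0.5),
       molecule_type = c(mab = 0.5, small = 0.5))
}

toy_config <- function(n_products = 30, months = c(20, 40), seed = 1,
                       spec = toy_spec(),
                       beta = c(intercept = 10, "time[t]" = 0.05,
                                "sqrt(t):orphan" = -0.3),
                       re_cov = matrix(c(0.8, -0.01, -0.01, 0.003), 2),
                       sigma2 = 0.3, phi = 0.5,
                       launch_window = c("2009-01", "2013-01")) {
  simulation_config(n_products = n_products, months_range = months,
                    launch_window = launch_window, panel_end = "2017-10",
                    spec = spec, beta = beta, re_cov = re_cov,
                    sigma2 = sigma2, phi = phi,
                    covariate_prevalence = toy_prevalence(), seed = seed)
}

spec_labels_of <- function(spec) vapply(spec$terms, term_label, "")

# two-product hand-written panel, the smallest valid dataset
toy_panel <- function() {
  records <- data.frame(
    product_id = c("A", "A", "A", "B", "B"),
    calendar_month = c("2010-01", "2010-02", "2010-03", "2012-06", "2012-07"),
    bi_eur = c(1000, 1500, 2000, 50000, 60000))
  profiles <- data.frame(
    product_id = c("A", "B"),
    tumor_site = c("breast", "lung"),
    molecule_type = c("mab", "small"),
    orphan = c(TRUE, FALSE), ce = c(FALSE, FALSE), fic = c(FALSE, TRUE),
    first_record_month = c("2010-01", "2012-06"))
  panel_dataset(records, profiles)
}

# a small validated rolling run, computed once and reused by metric tests
small_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- toy_config(n_products = 16, months = c(10, 14), seed = 42,
                        launch_window = c("2009-06", "2012-12"))
      ds <- trim_to_tmax(simulate_cohort(cfg), 8)
      rc <- run_config(8, toy_spec(), min_cap_eur = 5000)
      cache <<- list(dataset = ds,
                     cells = rolling_validate(ds, "2011-06", rc),
                     config = rc)
    }
    cache
  }
})
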