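#' Enumerate candidate terms for a forward step
#'
#' For each covariate in the registry: its main effect (if not already in the
#' spec) and its interaction with each time transform in \{t, t^2 .. t^6,
#' sqrt(t)\} — excluding every transform for a covariate that already carries
#' a time interaction, since only a single time interaction per covariate is
#' allowed — plus the linear time main effect.
#'
#' @param current a [model_spec()] (the model built so far).
#' @param covariates character vector of covariate names to consider
#'   (default: all five regulatory covariates).
#' @return list of [model_term()] candidates, in deterministic order.
#' @export
candidate_terms <- function(current,
                            covariates = c("tumor_site", "molecule_type",
                                           "orphan", "ce", "fic")) {
  have <- spec_labels(current)
  has_interaction <- vapply(covariates, function(cc)
    any(vapply(current$terms, function(tm)
      tm$covariate == cc && tm$transform != "none", NA)), NA)
  out <- list()
  if (!any(vapply(current$terms, function(tm) tm$covariate == "time", NA)))
    out[[length(out) + 1L]] <- model_term("time", "t")
  for (cc in covariates) {
    main <- model_term(cc)
    if (!term_label(main) %in% have) out[[length(out) + 1L]] <- main
    if (!has_interaction[[cc]]) {
      for (f in c("t", "t2", "t3", "t4", "t5", "t6", "sqrt_t")) {
        cand <- model_term(cc, f)
        if (!term_label(cand) %in% have) out[[length(out) + 1L]] <- cand
      }
    }
  }
  out
}

#' Forward stepwise selection of the fixed-effects structure
#'
#' Starting from the intercept-only model, every candidate term is added in
#' turn and the augmented model refit by ML; candidates are ranked by AIC and
#' the best is accepted only if its AIC improves strictly on the current
#' model AND its Wald p-value is below `p_enter`; when the best-AIC candidate
#' fails the p gate the next-best improving candidate is considered, and so
#' on. Selection stops when no candidate qualifies. Main effects of accepted
#' interactions are NOT forced into the model — predictor choice is purely
#' association-driven, which limits overfitting in a prediction model. The
#' random-effects and correlation structure are held fixed throughout. AIC
#' ties within `1e-6` break by enumeration order; the search is
#' deterministic.
#'
#' @param training_dataset a [panel_dataset()] or panel frame.
#' @param covariates covariate names offered to [candidate_terms()].
#' @param levels level registry; default taken from the dataset's profiles
#'   (fix it from the full covariate table when the model will predict
#'   products outside the training set).
#' @param p_enter Wald p-value gate for acceptance (default 0.10).
#' @param test `"wald"` (default) or `"lr"` for a likelihood-ratio gate.
#' @param max_steps safety bound on accepted steps.
#' @return list with `spec` (the selected [model_spec()]), `model` (its fit)
#'   and `trace` (a `selection_trace` data.frame: step, candidate, aic, p,
#'   accepted, chosen).
#' @export
forward_select <- function(training_dataset,
                           covariates = c("tumor_site", "molecule_type",
                                          "orphan", "ce", "fic"),
                           levels = NULL, p_enter = 0.10, test = "wald",
                           max_steps = 30L) {
  test <- match.arg(test, c("wald", "lr"))
  df <- if (inherits(training_dataset, "panel_dataset"))
    panel_frame(training_dataset) else training_dataset
  if (is.null(levels)) levels <- registry_from_profiles(df)
  current <- model_spec(list(), levels = levels)
  fit_cur <- fit_lmm(df, current)
  trace <- list()
  for (step in seq_len(max_steps)) {
    cands <- candidate_terms(current, covariates)
    if (!length(cands)) break
    rows <- vector("list", length(cands))
    fits <- vector("list", length(cands))
    for (j in seq_along(cands)) {
      cand <- cands[[j]]
      spec_j <- model_spec(c(current$terms, list(cand)), levels = levels)
      fj <- tryCatch(fit_lmm(df, spec_j), error = function(e) NULL)
      if (is.null(fj) || !fj$converged) {
        if (is.null(fj))
          warning("candidate ", term_label(cand), " failed to fit; skipped")
        else
          warning("candidate ", term_label(cand), " did not converge; skipped")
        rows[[j]] <- data.frame(step = step, candidate = term_label(cand),
                                aic = NA_real_, p = NA_real_,
                                accepted = FALSE)
        next
      }
      p <- if (test == "wald") wald_p(fj, cand) else
        stats::pchisq(2 * (fj$loglik - fit_cur$loglik),
                      df = fj$n_params - fit_cur$n_params,
                      lower.tail = FALSE)
      fits[[j]] <- fj
      rows[[j]] <- data.frame(step = step, candidate = term_label(cand),
                              aic = fj$aic, p = p, accepted = FALSE)
    }
    tab <- do.call(rbind, rows)
    tab$aic_before <- fit_cur$aic
    ok <- which(!is.na(tab$aic) & tab$aic < fit_cur$aic - 1e-9)
    ok <- ok[order(round(tab$aic[ok] / 1e-6) * 1e-6, ok)]
    chosen <- NA_integer_
    for (j in ok) if (tab$p[j] < p_enter) { chosen <- j; break }
    if (is.na(chosen)) { trace[[step]] <- tab; break }
    tab$accepted[chosen] <- TRUE
    trace[[step]] <- tab
    current <- model_spec(c(current$terms, list(cands[[chosen]])),
                          levels = levels)
    fit_cur <- fits[[chosen]]
  }
  trace <- do.call(rbind, trace)
  if (!is.null(trace)) {
    rownames(trace) <- NULL
  } else {
    trace <- data.frame(step = integer(0), candidate = character(0),
                        aic = numeric(0), p = numeric(0),
                        accepted = logical(0), aic_before = numeric(0))
  }
  class(trace) <- c("selection_trace", "data.frame")
  list(spec = current, model = fit_cur, trace = trace)
}

#' Export a selection trace as CSV
#'
#' @param trace the `trace` element of a [forward_select()] result.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
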