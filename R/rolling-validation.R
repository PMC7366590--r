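#' Configuration of a rolling-origin validation run
#'
#' @param t_max horizon in months (the study design uses 45 with a
#'   robustness run at 42).
#' @param spec the fixed [model_spec()] selected on the initial training set;
#'   coefficients are re-estimated each cycle, the structure never is.
#' @param min_cap_eur floor on predicted monthly BI (default EUR 5000, an
#'   arbitrary macro-level relevance floor).
#' @param max_cap_factor the ceiling is `max_cap_factor` times the maximum
#'   monthly BI observed anywhere in the dataset (default 2).
#' @param apply_min_cap,apply_max_cap scenario switches; both `TRUE` is the
#'   base case.
#' @return a `run_config`.
#' @export
run_config <- function(t_max, spec, min_cap_eur = 5000, max_cap_factor = 2,
                       apply_min_cap = TRUE, apply_max_cap = TRUE) {
  t_max <- as.integer(t_max)
  if (t_max < 2L) stop("t_max must be >= 2", call. = FALSE)
  if (min_cap_eur <= 0) stop("min_cap_eur must be > 0", call. = FALSE)
  if (max_cap_factor <= 0) stop("max_cap_factor must be > 0", call. = FALSE)
  stopifnot(inherits(spec, "model_spec"))
  structure(list(t_max = t_max, spec = spec, min_cap_eur = min_cap_eur,
                 max_cap_factor = max_cap_factor,
                 apply_min_cap = apply_min_cap, apply_max_cap = apply_max_cap),
            class = "run_config")
}

#' Prediction ceiling from the total dataset
#'
#' `factor` times the maximum monthly BI over ALL records (training and
#' validation sides alike), computed once per run.
#'
#' @param dataset a [panel_dataset()].
#' @param factor multiplier (default 2).
#' @return euros.
#' @export
compute_max_cap <- function(dataset, factor = 2) {
  stopifnot(inherits(dataset, "panel_dataset"))
  if (!nrow(dataset$records)) stop("empty dataset", call. = FALSE)
  factor * max(dataset$records$bi_eur)
}

#' Cap a predicted monthly BI
#'
#' Clamps the raw euro-scale prediction into `[min_cap, max_cap]` to limit
#' the influence of outliers, recording which bound (if any) fired. Observed
#' BI is never capped — real records below the floor exist; caps apply to
#' predictions only.
#'
#' @param raw_eur raw predicted monthly BI (vectorized).
#' @param min_cap,max_cap bounds in euros; `min_cap < max_cap`. Either may be
#'   `-Inf`/`Inf` in scenario analyses.
#' @return data.frame with `pred_eur` and `capped` (`"none"`, `"min"` or
#'   `"max"`).
#' @export
cap_prediction <- function(raw_eur, min_cap, max_cap) {
  if (min_cap >= max_cap) stop("min_cap must be below max_cap", call. = FALSE)
  flag <- rep("none", length(raw_eur))
  flag[raw_eur < min_cap] <- "min"
  flag[raw_eur > max_cap] <- "max"
  data.frame(pred_eur = pmin(pmax(raw_eur, min_cap), max_cap), capped = flag,
             stringsAsFactors = FALSE)
}

#' The training records of one validation cycle
#'
#' For validation product `k` with `t_data` months of own data the cycle's
#' split date is `t_split = first_record_month(k) + t_data`. Training
#' consists of every other product's records with `calendar_month < t_split`
#' (each product contributing at most its first `t_max` months) plus the
#' first `t_data` records of `k` itself. No record of `k` beyond `t_data` can
#' ever enter, and no record postdating `t_split` can enter for any product —
#' the no-leakage guarantee of the rolling origin.
#'
#' @param frame a panel frame (see [build_design()]) of the t_max-trimmed
#'   dataset.
#' @param k validation product id.
#' @param t_data months of `k`'s data available (>= 0).
#' @param t_max horizon.
#' @return the training subset of `frame`.
#' @export
cycle_training_frame <- function(frame, k, t_data, t_max) {
  first_k <- ym_to_int(frame$first_record_month[match(k, frame$product_id)])
  t_split <- first_k + t_data
  cm <- ym_to_int(frame$calendar_month)
  keep_b <- frame$product_id != k & cm < t_split & frame$month_index <= t_max
  keep_k <- frame$product_id == k & frame$month_index <= t_data
  frame[keep_b | keep_k, , drop = FALSE]
}

#' Rolling-forecasting-origin cross-validation
#'
#' Simulates the passage of time for every validation product `k`: starting
#' with no own data (`t_data = 0`, population-level prediction) and adding
#' one month per cycle, the model — with its structure fixed — is refit on
#' the cycle's training records and the remaining months `t_pred` in
#' `[t_data + 1, t_max]` are predicted, capped and paired with `k`'s observed
#' BI where present. A validation product observed for `m >= t_max` months
#' yields `t_max (t_max + 1) / 2` cells (1035 at `t_max = 45`). Cycles whose
#' refit fails are excluded with a warning; more than 5% failed cycles
#' raises a run-level warning.
#'
#' @param dataset a [panel_dataset()] (trimmed internally to `t_max`).
#' @param split_month `"YYYY-MM"` cohort split; products launched on/after it
#'   are validated.
#' @param config a [run_config()].
#' @param progress print one line per validation product.
#' @return a `validation_cells` data.frame: `product_id`, `t_data`, `t_pred`,
#'   `raw_pred_eur`, `pred_eur`, `observed_eur` (NA when `k` has no record at
#'   `t_pred`), `capped`, `t_max_run`. Attributes `min_cap`, `max_cap`,
#'   `failed_cycles`.
#' @export
rolling_validate <- function(dataset, split_month, config, progress = FALSE) {
  stopifnot(inherits(dataset, "panel_dataset"), inherits(config, "run_config"))
  t_max <- config$t_max
  dataset <- trim_to_tmax(dataset, t_max)
  max_cap <- if (config$apply_max_cap)
    compute_max_cap(dataset, config$max_cap_factor) else Inf
  min_cap <- if (config$apply_min_cap) config$min_cap_eur else -Inf
  split <- split_cohort(dataset, split_month)
  frame <- panel_frame(dataset)
  cells <- list(); failed <- 0L; n_cycles <- 0L
  for (k in split$validation_products) {
    prof <- dataset$profiles[dataset$profiles$product_id == k, , drop = FALSE]
    obs_k <- frame[frame$product_id == k, c("month_index", "bi_eur")]
    m_k <- nrow(obs_k)
    if (progress) cat("validating", k, "(", m_k, "months observed )\n")
    for (t_data in 0:min(m_k, t_max - 1L)) {
      n_cycles <- n_cycles + 1L
      train <- cycle_training_frame(frame, k, t_data, t_max)
      model <- tryCatch(fit_lmm(train, config$spec), error = function(e) NULL)
      if (is.null(model)) { failed <- failed + 1L; next }
      t_pred <- (t_data + 1L):t_max
      raw <- exp(predict_log_bi(model, prof, t_pred, product_id = k))
      cp <- cap_prediction(raw, min_cap, max_cap)
      cells[[length(cells) + 1L]] <- data.frame(
        product_id = k, t_data = t_data, t_pred = t_pred,
        raw_pred_eur = raw, pred_eur = cp$pred_eur,
        observed_eur = obs_k$bi_eur[match(t_pred, obs_k$month_index)],
        capped = cp$capped, t_max_run = as.character(t_max),
        stringsAsFactors = FALSE)
    }
  }
  if (failed > 0L) {
    warning(failed, " of ", n_cycles, " refit cycles failed and were excluded")
    if (failed > 0.05 * n_cycles)
      warning("more than 5% of validation cycles failed; treat run with care")
  }
  out <- if (length(cells)) do.call(rbind, cells) else
    data.frame(product_id = character(0), t_data = integer(0),
               t_pred = integer(0), raw_pred_eur = numeric(0),
               pred_eur = numeric(0), observed_eur = numeric(0),
               capped = character(0), t_max_run = character(0))
  rownames(out) <- NULL
  attr(out, "min_cap") <- min_cap
  attr(out, "max_cap") <- max_cap
  attr(out, "failed_cycles") <- failed
  class(out) <- c("validation_cells", "data.frame")
  out
}

#' Dual-horizon validation with averaged predictions
#'
#' Runs model selection and rolling validation independently at `t_max = 45`
#' and `t_max = 42` (structure re-selected per horizon on that horizon's
#' initial training set) and merges: each `(product, t_data, t_pred)` cell
#' takes the arithmetic mean of the two capped euro-scale predictions where
#' both runs produced one, else the single available prediction. Raw
#' predictions are averaged the same way; a merged cell counts as capped when
#' either contributing run capped it.
#'
#' @param dataset a [panel_dataset()].
#' @param split_month cohort split month.
#' @param base_config a [run_config()] providing caps and the horizons'
#'   shared settings; its `t_max` is ignored.
#' @param t_maxes the two horizons (default `c(45, 42)`).
#' @param covariates,levels passed to [forward_select()] per horizon.
#' @param progress print progress lines.
#' @return merged `validation_cells` with `t_max_run = "merged"`; attribute
#'   `runs` keeps the per-horizon selected specs.
#' @export
dual_tmax_run <- function(dataset, split_month, base_config,
                          t_maxes = c(45L, 42L),
                          covariates = c("tumor_site", "molecule_type",
                                         "orphan", "ce", "fic"),
                          levels = NULL, progress = FALSE) {
  if (is.null(levels)) levels <- registry_from_profiles(dataset$profiles)
  split <- split_cohort(dataset, split_month)
  runs <- list()
  for (tm in t_maxes) {
    trimmed <- trim_to_tmax(dataset, tm)
    train_ds <- panel_dataset(
      trimmed$records[trimmed$records$product_id %in% split$training_products,
                      , drop = FALSE],
      trimmed$profiles)
    sel <- forward_select(train_ds, covariates = covariates, levels = levels)
    cfg <- run_config(tm, sel$spec, min_cap_eur = base_config$min_cap_eur,
                      max_cap_factor = base_config$max_cap_factor,
                      apply_min_cap = base_config$apply_min_cap,
                      apply_max_cap = base_config$apply_max_cap)
    runs[[as.character(tm)]] <- list(
      spec = sel$spec, trace = sel$trace,
      cells = rolling_validate(trimmed, split_month, cfg, progress = progress))
  }
  merged <- merge_cells(lapply(runs, `[[`, "cells"))
  attr(merged, "runs") <- lapply(runs, function(r) r[c("spec", "trace")])
  merged
}

merge_cells <- function(cell_list) {
  all <- do.call(rbind, lapply(cell_list, as.data.frame))
  key <- interaction(all$product_id, all$t_data, all$t_pred, drop = TRUE)
  agg <- function(v, f) as.vector(tapply(v, key, f))
  out <- data.frame(
    product_id = agg(all$product_id, function(x) x[1L]),
    t_data = agg(all$t_data, function(x) x[1L]),
    t_pred = agg(all$t_pred, function(x) x[1L]),
    raw_pred_eur = agg(all$raw_pred_eur, mean),
    pred_eur = agg(all$pred_eur, mean),
    observed_eur = agg(all$observed_eur, function(x) x[1L]),
    capped = agg(all$capped, function(x)
      if (all(x == "none")) "none" else paste(sort(unique(x[x != "none"])),
                                              collapse = "+")),
    t_max_run = "merged", stringsAsFactors = FALSE)
  out <- out[order(out$product_id, out$t_data, out$t_pred), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("validation_cells", "data.frame")
  out
}

#' Read/write validation cells as CSV
#'
#' @param cells a `validation_cells` data.frame.
#' @param path CSV path.
#' @return `write_cells_csv` invisibly returns `path`; `read_cells_csv` the
#'   cells.
#' @export
write_cells_csv <- function(cells, path) {
  utils::write.csv(as.data.frame(cells), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cells_csv
#' @export
read_cells_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(product_id = "character"))
  class(out) <- c("validation_cells", "data.frame")
  out
}
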