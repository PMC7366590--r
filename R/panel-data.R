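#' Monthly budget-impact panel datasets
#'
#' A `panel_dataset` bundles the two tables the forecasting pipeline consumes:
#'
#' * `records`: one row per product per calendar month with the product's
#'   monthly budget impact (BI, list price times volume) in euros. Columns
#'   `product_id`, `calendar_month` (`"YYYY-MM"`), `month_index` (1 for the
#'   product's first BI record, consecutive thereafter) and `bi_eur` (> 0, so
#'   the log transform is always defined).
#' * `profiles`: one row per product with the regulatory covariates recorded
#'   at marketing authorization: `tumor_site` and `molecule_type`
#'   (categorical), `orphan`, `ce` (conditional approval OR approval under
#'   exceptional circumstances, a single combined flag) and `fic` (FDA first
#'   in class) as logicals, plus `first_record_month`.
#'
#' The constructor validates referential integrity (every record's product has
#' exactly one profile and vice versa), strict positivity of `bi_eur`, gapless
#' `month_index` sequences starting at 1, and consistency of
#' `calendar_month == first_record_month + (month_index - 1)`.
#'
#' @param records data.frame of BI records; `month_index` is derived from
#'   `calendar_month` when absent.
#' @param profiles data.frame of product covariates.
#' @return an object of class `panel_dataset`.
#' @export
panel_dataset <- function(records, profiles) {
  rec_cols <- c("product_id", "calendar_month", "bi_eur")
  prof_cols <- c("product_id", "tumor_site", "molecule_type", "orphan",
                 "ce", "fic", "first_record_month")
  miss <- setdiff(rec_cols, names(records))
  if (length(miss)) stop("records is missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  miss <- setdiff(prof_cols, names(profiles))
  if (length(miss)) stop("profiles is missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)

  records <- as.data.frame(records)
  profiles <- as.data.frame(profiles)
  records$product_id <- as.character(records$product_id)
  profiles$product_id <- as.character(profiles$product_id)
  records$bi_eur <- as.numeric(records$bi_eur)
  for (col in c("orphan", "ce", "fic")) {
    v <- profiles[[col]]
    if (is.numeric(v)) {
      if (!all(v %in% c(0, 1))) stop("profiles$", col, " must be 0/1 or logical",
                                     call. = FALSE)
      v <- v == 1
    }
    profiles[[col]] <- as.logical(v)
  }
  profiles$tumor_site <- as.character(profiles$tumor_site)
  profiles$molecule_type <- as.character(profiles$molecule_type)

  if (anyDuplicated(profiles$product_id))
    stop("duplicate product_id in profiles", call. = FALSE)

  if (nrow(records)) {
    only_rec <- setdiff(records$product_id, profiles$product_id)
    if (length(only_rec))
      stop("product(s) present in records but lacking a covariate profile: ",
           paste(utils::head(only_rec, 5L), collapse = ", "), call. = FALSE)
    bad <- !is.finite(records$bi_eur) | records$bi_eur <= 0
    if (any(bad)) {
      i <- which(bad)[1L]
      stop("non-positive or missing bi_eur for product ",
           records$product_id[i], " at ", records$calendar_month[i],
           " (log transform undefined)", call. = FALSE)
    }
    cm <- ym_to_int(records$calendar_month)
    ord <- order(records$product_id, cm)
    records <- records[ord, , drop = FALSE]
    cm <- cm[ord]
    # derive month_index from calendar months when absent
    first <- tapply(cm, records$product_id, min)[records$product_id]
    derived <- as.integer(cm - first + 1L)
    if (is.null(records$month_index)) {
      records$month_index <- derived
    } else if (!all(as.integer(records$month_index) == derived)) {
      i <- which(as.integer(records$month_index) != derived)[1L]
      stop("month_index inconsistent with calendar_month for product ",
           records$product_id[i], " at ", records$calendar_month[i],
           call. = FALSE)
    }
    records$month_index <- as.integer(records$month_index)
    # gapless consecutive months starting at 1 per product
    by_prod <- split(records$month_index, records$product_id)
    for (pid in names(by_prod)) {
      mi <- by_prod[[pid]]
      if (!identical(mi, seq_along(mi)))
        stop("gap or duplicate in monthly records of product ", pid,
             ": month_index must be consecutive from 1", call. = FALSE)
    }
    # first_record_month in the profile must match the records
    frm <- tapply(cm, records$product_id, min)
    prof_frm <- ym_to_int(profiles$first_record_month)
    names(prof_frm) <- profiles$product_id
    mism <- names(frm)[prof_frm[names(frm)] != frm]
    if (length(mism))
      stop("first_record_month in profile disagrees with records for: ",
           paste(utils::head(mism, 5L), collapse = ", "), call. = FALSE)
    rownames(records) <- NULL
  } else if (is.null(records$month_index)) {
    records$month_index <- integer(0)
  }

  structure(list(records = records, profiles = profiles),
            class = "panel_dataset")
}

#' @export
print.panel_dataset <- function(x, ...) {
  np <- nrow(x$profiles)
  nr <- nrow(x$records)
  cat("Monthly budget-impact panel:", np, "products,", nr, "product-months\n")
  if (nr) {
    rng <- range(ym_to_int(x$records$calendar_month))
    cat("  calendar range:", int_to_ym(rng[1L]), "to", int_to_ym(rng[2L]), "\n")
    mo <- table(x$records$product_id)
    cat("  months per product: median", stats::median(mo),
        "(range", paste(range(mo), collapse = "-"), ")\n")
  }
  invisible(x)
}

#' @method all.equal panel_dataset
#' @export
all.equal.panel_dataset <- function(target, current, ...) {
  norm <- function(d) {
    r <- d$records[order(d$records$product_id, d$records$month_index),
                   c("product_id", "calendar_month", "month_index", "bi_eur")]
    p <- d$profiles[order(d$profiles$product_id), ]
    rownames(r) <- NULL; rownames(p) <- NULL
    list(r = r, p = p[, sort(names(p))])
  }
  all.equal(norm(target), norm(current), ...)
}

#' Read a BI panel and its covariate table from CSV
#'
#' Expects the panel CSV with columns `product_id`, `calendar_month`
#' (`"YYYY-MM"`) and `bi_eur`, and the covariates CSV with columns
#' `product_id`, `tumor_site`, `molecule_type`, `orphan`, `ce`, `fic` (0/1)
#' and `first_record_month`. Both UTF-8 with a header row.
#'
#' @param path path to the panel CSV.
#' @param covariates_path path to the covariates CSV.
#' @return a validated [panel_dataset()].
#' @export
read_panel_csv <- function(path, covariates_path) {
  if (!file.exists(path)) stop("panel file not found: ", path, call. = FALSE)
  if (!file.exists(covariates_path))
    stop("covariates file not found: ", covariates_path, call. = FALSE)
  rec <- utils::read.csv(path, colClasses = "character",
                         fileEncoding = "UTF-8")
  prof <- utils::read.csv(covariates_path, colClasses = "character",
                          fileEncoding = "UTF-8")
  need <- setdiff(c("product_id", "calendar_month", "bi_eur"), names(rec))
  if (length(need)) stop("panel CSV missing column(s): ",
                         paste(need, collapse = ", "), call. = FALSE)
  need <- setdiff(c("product_id", "tumor_site", "molecule_type", "orphan",
                    "ce", "fic", "first_record_month"), names(prof))
  if (length(need)) stop("covariates CSV missing column(s): ",
                         paste(need, collapse = ", "), call. = FALSE)
  rec$bi_eur <- as.numeric(rec$bi_eur)
  for (col in c("orphan", "ce", "fic")) prof[[col]] <- as.numeric(prof[[col]])
  panel_dataset(rec, prof)
}

#' Write a panel dataset to CSV files
#'
#' Inverse of [read_panel_csv()]: `read_panel_csv(write_panel_csv(d))`
#' reproduces `d` field for field.
#'
#' @param dataset a [panel_dataset()].
#' @param path output path for the panel CSV.
#' @param covariates_path output path for the covariates CSV.
#' @return invisibly, the two paths.
#' @export
write_panel_csv <- function(dataset, path, covariates_path) {
  stopifnot(inherits(dataset, "panel_dataset"))
  rec <- dataset$records[, c("product_id", "calendar_month", "bi_eur")]
  prof <- dataset$profiles
  for (col in c("orphan", "ce", "fic")) prof[[col]] <- as.integer(prof[[col]])
  prof <- prof[, c("product_id", "tumor_site", "molecule_type", "orphan",
                   "ce", "fic", "first_record_month")]
  utils::write.csv(rec, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  utils::write.csv(prof, covariates_path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(c(path, covariates_path))
}

#' Split a cohort into training and validation products
#'
#' A product belongs to the validation side iff its first BI record falls on
#' or after `split_month`; all earlier launches are training. The study design
#' this mirrors places the boundary at month 149 of the panel (2012-05): the
#' training pool is every product already on the market, the validation set
#' every product launched afterwards.
#'
#' @param dataset a [panel_dataset()].
#' @param split_month `"YYYY-MM"` boundary month.
#' @return a `cohort_split`: list with `training_products`,
#'   `validation_products` and `split_month`.
#' @export
split_cohort <- function(dataset, split_month) {
  stopifnot(inherits(dataset, "panel_dataset"))
  s <- ym_to_int(split_month)
  frm <- ym_to_int(dataset$profiles$first_record_month)
  validation <- dataset$profiles$product_id[frm >= s]
  training <- dataset$profiles$product_id[frm < s]
  if (!length(validation))
    warning("empty validation set: no product launched on/after ", split_month)
  if (!length(training))
    warning("empty training set: no product launched before ", split_month)
  structure(list(training_products = training,
                 validation_products = validation,
                 split_month = split_month),
            class = "cohort_split")
}

#' @export
print.cohort_split <- function(x, ...) {
  cat("Cohort split at", x$split_month, "->",
      length(x$training_products), "training /",
      length(x$validation_products), "validation products\n")
  invisible(x)
}

#' Trim every product's series to its first t_max months
#'
#' Keeps only records with `month_index <= t_max`; products with shorter
#' series are untouched. Idempotent. The study design uses `t_max = 45`
#' (robustness run 42) because 45 months is the horizon being predicted.
#'
#' @param dataset a [panel_dataset()].
#' @param t_max positive integer horizon.
#' @return the trimmed [panel_dataset()].
#' @export
trim_to_tmax <- function(dataset, t_max) {
  stopifnot(inherits(dataset, "panel_dataset"))
  t_max <- as.integer(t_max)
  if (is.na(t_max) || t_max < 1L) stop("t_max must be a positive integer",
                                       call. = FALSE)
  keep <- dataset$records$month_index <= t_max
  panel_dataset(dataset$records[keep, , drop = FALSE], dataset$profiles)
}

#' Flatten a panel dataset to one row per observation
#'
#' Joins records with profiles, ordered by product then month, and adds the
#' `log_bi` response. This is the flat shape the design-matrix, likelihood
#' and validation code consumes.
#'
#' @param dataset a [panel_dataset()].
#' @return a data.frame with record, covariate and `log_bi` columns.
#' @export
panel_frame <- function(dataset) {
  df <- merge(dataset$records, dataset$profiles, by = "product_id",
              sort = FALSE)
  df <- df[order(df$product_id, df$month_index), , drop = FALSE]
  df$log_bi <- log(df$bi_eur)
  rownames(df) <- NULL
  df
}
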