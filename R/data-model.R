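#' Declare variable roles for an analytic dataset
#'
#' The equity analysis needs to know which column is the binary utilization
#' outcome, which continuous column measures living standard (per-capita
#' household consumption expenditure net of health expenditure), which
#' covariates are *need* variables (unavoidable determinants of service
#' need — typically age group, sex, disability, chronic disease) and which
#' are *controls* (residence, region, education, marital status, insurance,
#' economic-status tertile, smoking, drinking).  Need contributions are
#' treated as legitimate when the horizontal inequity index is formed;
#' control contributions are not.
#'
#' @param outcome Column name of the binary (0/1) outcome.
#' @param living_standard Column name of the continuous living-standard
#'   measure used for ranking.
#' @param need Character vector of need-covariate column names.
#' @param control Character vector of control-covariate column names.
#' @param weight Optional column name of nonnegative sampling weights.
#'   When `NULL`, every record gets weight 1.
#' @param wave Optional column name of the survey wave/year.
#'
#' @return An object of class `variable_roles`.
#' @examples
#' variable_roles("exam", "pce_net",
#'                need = c("age_group", "sex"),
#'                control = c("residence", "education"),
#'                wave = "wave")
#' @export
variable_roles <- function(outcome, living_standard, need = character(),
                           control = character(), weight = NULL, wave = NULL) {
  stopifnot(is.character(outcome), length(outcome) == 1L,
            is.character(living_standard), length(living_standard) == 1L)
  need <- as.character(need)
  control <- as.character(control)
  overlap <- intersect(need, control)
  if (length(overlap) > 0)
    stop("need and control roles must be disjoint; shared: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  covars <- c(need, control)
  bad <- intersect(covars, c(outcome, living_standard))
  if (length(bad) > 0)
    stop("outcome/living-standard columns cannot also be covariates: ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(
    list(outcome = outcome, living_standard = living_standard,
         need = need, control = control,
         weight = weight, wave = wave),
    class = "variable_roles"
  )
}

#' @export
print.variable_roles <- function(x, ...) {
  cat("<variable_roles>\n")
  cat("  outcome:        ", x$outcome, "\n")
  cat("  living standard:", x$living_standard, "\n")
  cat("  need:           ", paste(x$need, collapse = ", "), "\n")
  cat("  control:        ", paste(x$control, collapse = ", "), "\n")
  cat("  weight:         ", x$weight %||% "<unit weights>", "\n")
  cat("  wave:           ", x$wave %||% "<single wave>", "\n")
  invisible(x)
}

role_columns <- function(roles) {
  c(roles$outcome, roles$living_standard, roles$need, roles$control,
    roles$weight, roles$wave)
}

#' Construct an analytic dataset from a data frame
#'
#' Validates a raw table against a role declaration and applies the
#' complete-case policy: rows with a missing outcome, a non-finite living
#' standard, a missing/invalid weight, or a missing covariate are dropped,
#' with counts retained by reason.  Outcome values other than 0/1 are a
#' validation error (not silently dropped).
#'
#' @param data A data frame of person-wave records.
#' @param roles A [variable_roles()] declaration.
#' @param reference Optional named list mapping factor columns to their
#'   reference level (the level is moved first so model fits use it as the
#'   baseline), e.g. `list(region = "west")`.
#' @param quiet Suppress the dropped-row message.
#'
#' @return An object of class `analytic_dataset`: a list with elements
#'   `data` (tibble of retained records, weights filled in), `roles`, and
#'   `dropped` (named integer vector of drop counts by reason).
#' @seealso [load_dataset()], [write_dataset()], [assign_tertiles()]
#' @export
analytic_dataset <- function(data, roles, reference = NULL, quiet = FALSE) {
  stopifnot(inherits(roles, "variable_roles"))
  data <- tibble::as_tibble(data)
  missing_cols <- setdiff(role_columns(roles), names(data))
  if (length(missing_cols) > 0)
    stop("role column(s) not present in data: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  n_raw <- nrow(data)
  y <- data[[roles$outcome]]
  if (is.logical(y)) y <- as.numeric(y)
  if (is.factor(y) || is.character(y)) y <- suppressWarnings(as.numeric(as.character(y)))
  bad_y <- stats::na.omit(setdiff(unique(y), c(0, 1)))
  if (length(bad_y) > 0)
    stop("outcome '", roles$outcome, "' must be binary 0/1; found: ",
         paste(utils::head(bad_y, 5), collapse = ", "), call. = FALSE)
  data[[roles$outcome]] <- y

  keep <- rep(TRUE, n_raw)
  dropped <- c(missing_outcome = 0L, nonfinite_living_standard = 0L,
               invalid_weight = 0L, missing_covariate = 0L)

  miss_y <- is.na(y)
  dropped[["missing_outcome"]] <- sum(miss_y)
  keep <- keep & !miss_y

  ls_val <- data[[roles$living_standard]]
  if (!is.numeric(ls_val))
    stop("living-standard column '", roles$living_standard,
         "' must be numeric", call. = FALSE)
  bad_ls <- !is.finite(ls_val)
  dropped[["nonfinite_living_standard"]] <- sum(bad_ls & keep)
  keep <- keep & !bad_ls

  if (!is.null(roles$weight)) {
    w <- data[[roles$weight]]
    if (any(w < 0, na.rm = TRUE))
      stop("weights must be nonnegative", call. = FALSE)
    bad_w <- !is.finite(w)
    dropped[["invalid_weight"]] <- sum(bad_w & keep)
    keep <- keep & !bad_w
  } else {
    data[[".weight"]] <- rep(1, n_raw)
    roles$weight <- ".weight"
  }

  covars <- c(roles$need, roles$control, roles$wave)
  if (length(covars) > 0) {
    cc <- stats::complete.cases(data[covars])
    dropped[["missing_covariate"]] <- sum(!cc & keep)
    keep <- keep & cc
  }

  data <- data[keep, , drop = FALSE]
  if (!is.null(reference)) {
    for (nm in names(reference)) {
      if (!nm %in% names(data)) next
      data[[nm]] <- stats::relevel(factor(data[[nm]]), ref = reference[[nm]])
    }
  }
  if (!quiet && sum(dropped) > 0)
    message("dropped ", sum(dropped), "/", n_raw, " rows (",
            paste(names(dropped), dropped, sep = "=", collapse = ", "), ")")

  structure(list(data = data, roles = roles, dropped = dropped,
                 n_raw = n_raw),
            class = "analytic_dataset")
}

#' @export
print.analytic_dataset <- function(x, ...) {
  waves <- dataset_waves(x)
  cat("<analytic_dataset> ", nrow(x$data), " records",
      if (length(waves) > 1) paste0(" across ", length(waves), " waves"),
      "\n", sep = "")
  if (sum(x$dropped) > 0)
    cat("  dropped ", sum(x$dropped), " of ", x$n_raw, " raw rows\n", sep = "")
  print(x$roles)
  invisible(x)
}

#' Accessors for analytic datasets
#'
#' @param x An `analytic_dataset`.
#' @return `dataset_records()` the tibble of retained records;
#'   `dataset_roles()` the `variable_roles`; `dataset_weights()` the numeric
#'   weight vector; `dataset_waves()` the sorted unique wave labels (a single
#'   `"all"` when no wave role is declared).
#' @export
dataset_records <- function(x) {
  stopifnot(inherits(x, "analytic_dataset"))
  x$data
}

#' @rdname dataset_records
#' @export
dataset_roles <- function(x) {
  stopifnot(inherits(x, "analytic_dataset"))
  x$roles
}

#' @rdname dataset_records
#' @export
dataset_weights <- function(x) {
  dataset_records(x)[[dataset_roles(x)$weight]]
}

#' @rdname dataset_records
#' @export
dataset_waves <- function(x) {
  wv <- dataset_roles(x)$wave
  if (is.null(wv)) return("all")
  sort(unique(dataset_records(x)[[wv]]))
}

#' Subset an analytic dataset to one wave
#'
#' @param x An `analytic_dataset`.
#' @param wave A wave label present in the wave column.
#' @return An `analytic_dataset` holding the single wave's records.
#' @export
filter_wave <- function(x, wave) {
  roles <- dataset_roles(x)
  if (is.null(roles$wave)) return(x)
  d <- dataset_records(x)
  d <- d[d[[roles$wave]] == wave, , drop = FALSE]
  if (nrow(d) == 0) stop("no records in wave ", wave, call. = FALSE)
  out <- x
  out$data <- d
  out
}

#' Read a delimited file into an analytic dataset
#'
#' Reads a CSV/TSV with a header row and validates it against the role
#' declaration (see [analytic_dataset()] for the dropping policy).
#'
#' @inheritParams analytic_dataset
#' @param path Path to a delimited text file (delimiter inferred from the
#'   extension; `.tsv` is tab, everything else comma).
#' @return An `analytic_dataset`.
#' @export
load_dataset <- function(path, roles, reference = NULL, quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  # character covariates become factors so model fits get stable dummy coding
  for (nm in intersect(c(roles$need, roles$control), names(raw))) {
    if (is.character(raw[[nm]])) raw[[nm]] <- factor(raw[[nm]])
  }
  analytic_dataset(raw, roles, reference = reference, quiet = quiet)
}

#' Write an analytic dataset back to CSV
#'
#' The written file round-trips through [load_dataset()] to an identical
#' dataset (given the same roles and reference levels).
#'
#' @param x An `analytic_dataset`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(x, path) {
  readr::write_csv(dataset_records(x), path, progress = FALSE)
  invisible(path)
}

#' Living standard net of health spending
#'
#' Per-capita household consumption expenditure minus per-capita health-care
#' expenditure.  The result may be negative; a negative value is retained as
#' is, because the index only uses the ordering of living standards.
#'
#' @param expenditure Nonnegative per-capita consumption expenditure.
#' @param health_expenditure Per-capita health-care expenditure.
#' @return `expenditure - health_expenditure`.
#' @examples
#' net_expenditure(6000, 581)  # 5419
#' @export
net_expenditure <- function(expenditure, health_expenditure) {
  if (!all(is.finite(expenditure)) || !all(is.finite(health_expenditure)))
    stop("expenditure values must be finite", call. = FALSE)
  if (any(expenditure < 0))
    stop("consumption expenditure must be nonnegative", call. = FALSE)
  expenditure - health_expenditure
}

#' Assign economic-status tertiles
#'
#' Splits each wave's sample into three equal-sized groups (low / medium /
#' high) on the living-standard column, using type-1 (left-continuous)
#' sample quantiles at 1/3 and 2/3.  Values tied at a cut point all go to
#' the lower group, so group sizes can differ by at most 2 before tie
#' spill-over.  Assignment depends only on the ordering, so it is invariant
#' to any strictly increasing transform of the living standard.
#'
#' @param x An `analytic_dataset`.
#' @param per_wave Compute cut points within each wave (default) or on the
#'   pooled sample.
#' @param column Name of the tertile column to add.
#' @param add_role Append the new column to the control roles when absent.
#' @return The dataset with a `low`/`medium`/`high` factor column added and
#'   the cut points recorded in element `tertile_cuts`.
#' @export
assign_tertiles <- function(x, per_wave = TRUE, column = "econ_tertile",
                            add_role = TRUE) {
  roles <- dataset_roles(x)
  d <- dataset_records(x)
  ls_val <- d[[roles$living_standard]]
  grp <- if (per_wave && !is.null(roles$wave)) d[[roles$wave]] else rep("all", nrow(d))

  lab <- rep(NA_character_, nrow(d))
  cuts <- list()
  for (g in sort(unique(grp))) {
    idx <- which(grp == g)
    v <- ls_val[idx]
    if (length(v) < 3)
      stop("fewer than 3 records in wave ", g, "; cannot form tertiles",
           call. = FALSE)
    q <- stats::quantile(v, probs = c(1, 2) / 3, type = 1, names = FALSE)
    lab[idx] <- ifelse(v <= q[1], "low", ifelse(v <= q[2], "medium", "high"))
    cuts[[as.character(g)]] <- q
  }
  d[[column]] <- factor(lab, levels = c("low", "medium", "high"))
  out <- x
  out$data <- d
  out$tertile_cuts <- tibble::tibble(
    wave = names(cuts),
    cut_low_medium = vapply(cuts, `[`, numeric(1), 1),
    cut_medium_high = vapply(cuts, `[`, numeric(1), 2)
  )
  if (add_role && !column %in% c(out$roles$need, out$roles$control))
    out$roles$control <- c(out$roles$control, column)
  out
}

#' Standard reference levels for the covariate coding
#'
#' Reference categories used throughout: west region, female, youngest age
#' band, elementary-or-below education, married, uninsured, low tertile,
#' non-smoker, non-drinker, no disability, no chronic disease, rural
#' residence.
#'
#' @return A named list suitable for the `reference` argument of
#'   [load_dataset()] / [analytic_dataset()].
#' @export
default_reference_levels <- function() {
  list(region = "west", sex = "female", age_group = "45-50",
       education = "elementary_or_below", marital = "married",
       insurance = "no", smoke = "no", drink = "no",
       disability = "no", chronic = "no", residence = "rural",
       econ_tertile = "low")
}
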