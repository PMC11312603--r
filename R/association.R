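#' Stratified logistic regression with survey-year fixed effects
#'
#' For each level of the stratifying column (e.g. rural/urban residence),
#' fits a maximum-likelihood logit of the outcome on the survey-year
#' dummies plus the declared need and control covariates, and reports
#' exponentiated coefficients (odds ratios) with Wald 95% intervals and
#' p-values.  Reference categories are printed with OR fixed at 1.00.
#'
#' "Two-way fixed effects" here means year dummies together with region
#' dummies in a pooled cross-section logit; individual fixed effects are
#' not used (time-invariant covariates such as sex would be unidentifiable
#' under them).
#'
#' @param x An `analytic_dataset` with a wave role (pooled waves).
#' @param stratum Optional column to stratify on; `NULL` fits one pooled
#'   model labelled `"total"`.
#' @param fixed_effects Columns entered as factor dummies in addition to the
#'   role covariates; defaults to the wave column.
#' @param conf_level Confidence level for the Wald intervals.
#' @return An `or_table` tibble: `stratum`, `variable`, `level`,
#'   `reference`, `or`, `lower`, `upper`, `p`.
#' @export
fit_fe_logit <- function(x, stratum = NULL, fixed_effects = NULL,
                         conf_level = 0.95) {
  roles <- dataset_roles(x)
  fixed_effects <- fixed_effects %||% roles$wave
  d <- dataset_records(x)
  strata <- if (is.null(stratum)) {
    list(total = rep(TRUE, nrow(d)))
  } else {
    levs <- sort(unique(as.character(d[[stratum]])))
    stats::setNames(lapply(levs, function(l) d[[stratum]] == l), levs)
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)

  out <- lapply(names(strata), function(s) {
    ds <- d[strata[[s]], , drop = FALSE]
    covars <- setdiff(unique(c(fixed_effects, roles$need, roles$control)),
                      stratum)
    for (fe in intersect(fixed_effects, names(ds)))
      if (!is.factor(ds[[fe]])) ds[[fe]] <- factor(ds[[fe]])
    covars <- covars[vapply(covars, function(nm)
      length(unique(ds[[nm]])) > 1L, logical(1))]
    fml <- stats::reformulate(covars, response = roles$outcome)
    w <- ds[[roles$weight]]
    fam <- if (all(w == round(w))) stats::binomial() else stats::quasibinomial()
    fit <- stats::glm(fml, data = ds, weights = w, family = fam)
    if (!fit$converged)
      stop("logit did not converge in stratum ", s,
           " (possible separation); deviance = ", format(fit$deviance),
           call. = FALSE)
    sm <- summary(fit)$coefficients
    X <- stats::model.matrix(fit)
    assign_idx <- attr(X, "assign")
    term_labels <- attr(stats::terms(fit), "term.labels")

    rows <- list()
    for (tl in term_labels) {
      cols <- colnames(X)[assign_idx == match(tl, term_labels)]
      v <- ds[[tl]]
      if (is.factor(v)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          stratum = s, variable = tl, level = levels(v)[1],
          reference = TRUE, or = 1, lower = NA_real_, upper = NA_real_,
          p = NA_real_)
      }
      for (cl in cols) {
        est <- sm[cl, "Estimate"]
        se <- sm[cl, "Std. Error"]
        lev <- if (is.factor(v)) sub(paste0("^", tl), "", cl) else cl
        rows[[length(rows) + 1L]] <- tibble::tibble(
          stratum = s, variable = tl, level = lev, reference = FALSE,
          or = exp(est), lower = exp(est - z * se), upper = exp(est + z * se),
          p = sm[cl, 4])
      }
    }
    dplyr::bind_rows(rows)
  })
  res <- dplyr::bind_rows(out)
  class(res) <- c("or_table", class(res))
  res
}
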