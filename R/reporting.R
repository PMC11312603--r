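#' Utilization rates by grouping columns
#'
#' Weighted percentage of records with outcome 1 in each cell defined by
#' the grouping columns (e.g. wave and residence), with the cell size.
#'
#' @param x An `analytic_dataset`.
#' @param by Character vector of grouping column names; `NULL` gives the
#'   overall rate.
#' @return A tibble with the grouping columns, `n`, and `rate_pct`.
#' @export
utilization_rates <- function(x, by = NULL) {
  roles <- dataset_roles(x)
  d <- dataset_records(x)
  d$.y <- d[[roles$outcome]]
  d$.w <- d[[roles$weight]]
  if (is.null(by)) {
    return(tibble::tibble(n = nrow(d),
                          rate_pct = 100 * wmean(d$.y, d$.w)))
  }
  d |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(n = dplyr::n(),
                     rate_pct = 100 * sum(.data$.w * .data$.y) / sum(.data$.w),
                     .groups = "drop")
}

fmt_pct <- function(x) sprintf("%.2f", x)

#' Descriptive sample characteristics by group
#'
#' Table-1-style summary: categorical covariates as count (percent) per
#' group level with a chi-square test across groups; continuous variables
#' as mean (SD) with a two-sample t test (two groups) or one-way ANOVA
#' (more).  Constant columns are skipped with a note.
#'
#' @param x An `analytic_dataset`.
#' @param group Grouping column (>= 2 observed levels).
#' @param vars Columns to summarise; defaults to the declared need and
#'   control covariates plus the living standard.
#' @return A tibble: `variable`, `level`, one formatted column per group
#'   level plus `total`, and the test `p` (repeated within a variable).
#' @export
describe_sample <- function(x, group, vars = NULL) {
  roles <- dataset_roles(x)
  d <- dataset_records(x)
  g <- factor(d[[group]])
  if (nlevels(g) < 2) stop("group must have at least 2 levels", call. = FALSE)
  vars <- vars %||% c(roles$need, roles$control, roles$living_standard)
  vars <- setdiff(vars, group)

  blocks <- lapply(vars, function(nm) {
    v <- d[[nm]]
    if (length(unique(v)) < 2) {
      message("skipping constant column: ", nm)
      return(NULL)
    }
    if (is.numeric(v) && !is.factor(v)) {
      p <- if (nlevels(g) == 2)
        stats::t.test(v ~ g)$p.value
      else stats::oneway.test(v ~ g)$p.value
      cells <- vapply(levels(g), function(l)
        sprintf("%.2f (%.2f)", mean(v[g == l]), stats::sd(v[g == l])),
        character(1))
      tibble::tibble(variable = nm, level = "mean (SD)",
                     total = sprintf("%.2f (%.2f)", mean(v), stats::sd(v)),
                     !!!stats::setNames(as.list(cells), levels(g)),
                     p = p)
    } else {
      v <- factor(v)
      tab <- table(g, v)
      p <- suppressWarnings(stats::chisq.test(tab)$p.value)
      dplyr::bind_rows(lapply(levels(v), function(lv) {
        cells <- vapply(levels(g), function(l) {
          k <- sum(v == lv & g == l)
          sprintf("%d (%s)", k, fmt_pct(100 * k / sum(g == l)))
        }, character(1))
        tibble::tibble(variable = nm, level = lv,
                       total = sprintf("%d (%s)", sum(v == lv),
                                       fmt_pct(100 * mean(v == lv))),
                       !!!stats::setNames(as.list(cells), levels(g)),
                       p = p)
      }))
    }
  })
  dplyr::bind_rows(blocks)
}

#' Concentration-curve points per wave
#'
#' @param x An `analytic_dataset`.
#' @return A tibble of curve points `p`, `L` with a `wave` column.
#' @export
concentration_curves <- function(x) {
  roles <- dataset_roles(x)
  dplyr::bind_rows(lapply(dataset_waves(x), function(wv) {
    ds <- filter_wave(x, wv)
    d <- dataset_records(ds)
    cv <- concentration_curve(d[[roles$outcome]], d[[roles$living_standard]],
                              d[[roles$weight]])
    dplyr::mutate(cv$points, wave = wv, .before = 1)
  }))
}

#' Plot concentration curves with the equality diagonal
#'
#' @param x An `analytic_dataset` or the tibble from
#'   [concentration_curves()].
#' @return A ggplot object: one curve per wave against the 45-degree line.
#' @export
plot_concentration_curves <- function(x) {
  pts <- if (inherits(x, "analytic_dataset")) concentration_curves(x) else x
  pts$wave <- factor(pts$wave)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$p, y = .data$L,
                                    colour = .data$wave)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey40") +
    ggplot2::geom_line() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Cumulative population share (poorest first)",
                  y = "Cumulative share of utilization",
                  colour = "Wave") +
    ggplot2::theme_minimal()
}

#' Configure the end-to-end reporting pipeline
#'
#' Exactly one of `input`/`synthetic` must be supplied.
#'
#' @param input Path to a delimited data file (with `roles`).
#' @param roles A [variable_roles()] declaration (required with `input`).
#' @param synthetic A [synthetic_config()] to generate data instead.
#' @param stratum Stratifying column for OR tables and CI/HI tables.
#' @param outdir Output directory (created if absent).
#' @param seed Seed forwarded to the generator.
#' @param economic `"tertile"` enters economic status as within-wave
#'   tertile dummies; `"log"` enters log living standard as a continuous
#'   control instead.
#' @param reference Reference-level list for [load_dataset()].
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, roles = NULL, synthetic = NULL,
                            stratum = "residence", outdir = tempfile("report"),
                            seed = 1L, economic = c("tertile", "log"),
                            reference = default_reference_levels()) {
  if (is.null(input) == is.null(synthetic))
    stop("supply exactly one of input / synthetic", call. = FALSE)
  if (!is.null(input) && is.null(roles))
    stop("roles are required with a file input", call. = FALSE)
  structure(list(input = input, roles = roles, synthetic = synthetic,
                 stratum = stratum, outdir = outdir, seed = as.integer(seed),
                 economic = match.arg(economic), reference = reference),
            class = "pipeline_config")
}

#' Run the full equity-analysis pipeline
#'
#' Loads or generates the data, forms economic-status tertiles (or the log
#' living standard), then writes: utilization rates by wave and stratum,
#' a descriptive comparison table, odds-ratio tables from the stratified
#' year-fixed-effects logit, a per-wave/per-stratum concentration-index +
#' horizontal-inequity table, per-wave decomposition tables, the
#' concentration-curve points and figure, and a JSON manifest recording
#' the seed, package version, dropped-row counts and the files written.
#' Any stage error is recorded in the manifest before the error is
#' re-thrown (non-zero exit under Rscript).
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with every computed artifact (`dataset`,
#'   `rates`, `descriptives`, `or_table`, `ci_hi`, `decompositions`,
#'   `curves`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  status <- list()
  emit <- function(obj, name) {
    path <- file.path(config$outdir, name)
    readr::write_csv(obj, path, progress = FALSE)
    files <<- c(files, path)
    path
  }
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) {
      status[[name]] <<- paste("ERROR:", conditionMessage(res))
      manifest <- list(status = status, files = files, seed = config$seed,
                       package_version = as.character(packageVersion("concindex")))
      jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(res),
           call. = FALSE)
    }
    status[[name]] <<- "ok"
    res
  }

  ds <- stage("data", {
    if (!is.null(config$synthetic))
      generate_panel(config$synthetic, seed = config$seed)
    else
      load_dataset(config$input, config$roles, reference = config$reference,
                   quiet = TRUE)
  })
  ds <- stage("economic_status", {
    if (config$economic == "tertile") {
      assign_tertiles(ds)
    } else {
      roles <- dataset_roles(ds)
      d <- dataset_records(ds)
      lsv <- d[[roles$living_standard]]
      if (any(lsv <= 0))
        stop("log living standard requires positive values")
      d$log_pce <- log(lsv)
      ds$data <- d
      ds$roles$control <- union(ds$roles$control, "log_pce")
      ds
    }
  })
  roles <- dataset_roles(ds)
  wave_col <- roles$wave

  rates <- stage("rates", {
    by <- c(wave_col, config$stratum)
    by <- by[by %in% names(dataset_records(ds))]
    r1 <- utilization_rates(ds, by = if (length(by)) by else NULL)
    r2 <- utilization_rates(ds, by = wave_col)
    out <- dplyr::bind_rows(r1, r2)
    emit(out, "rates.csv")
    out
  })
  descriptives <- stage("descriptives", {
    if (!is.null(config$stratum) &&
        config$stratum %in% names(dataset_records(ds))) {
      first_wave <- dataset_waves(ds)[1]
      dsc <- describe_sample(filter_wave(ds, first_wave), config$stratum)
      emit(dsc, "table1.csv")
      dsc
    } else NULL
  })
  or_table <- stage("association", {
    tab <- fit_fe_logit(ds, stratum = config$stratum)
    emit(tab, "or_table.csv")
    tab
  })

  waves <- dataset_waves(ds)
  decomps <- list()
  ci_hi <- stage("ci_decomposition", {
    rows <- list()
    for (wv in waves) {
      dsw <- filter_wave(ds, wv)
      strata <- list(total = dsw)
      if (!is.null(config$stratum) &&
          config$stratum %in% names(dataset_records(dsw))) {
        for (l in sort(unique(as.character(
          dataset_records(dsw)[[config$stratum]])))) {
          di <- dsw
          di$data <- di$data[as.character(di$data[[config$stratum]]) == l, ,
                             drop = FALSE]
          strata[[l]] <- di
        }
      }
      for (s in names(strata)) {
        dec <- decompose_ci(strata[[s]])
        decomps[[paste(wv, s, sep = "_")]] <- dec
        emit(dplyr::mutate(dec$rows, wave = wv, stratum = s, .before = 1),
             sprintf("decomposition_%s_%s.csv", wv, s))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          wave = wv, stratum = s, n = dec$n, mu = dec$mu,
          ci = dec$total$value,
          lower = dec$total$ci95[["lower"]], upper = dec$total$ci95[["upper"]],
          hi = dec$hi)
      }
    }
    out <- dplyr::bind_rows(rows)
    emit(out, "ci_hi.csv")
    out
  })
  curves <- stage("curves", {
    pts <- concentration_curves(ds)
    emit(pts, "curves.csv")
    plt <- plot_concentration_curves(pts)
    fig <- file.path(config$outdir, "curves.png")
    try(suppressMessages(ggplot2::ggsave(fig, plt, width = 6, height = 6,
                                         dpi = 120)), silent = TRUE)
    if (file.exists(fig)) files <<- c(files, fig)
    pts
  })

  manifest <- list(
    seed = config$seed,
    package_version = as.character(packageVersion("concindex")),
    generated = !is.null(config$synthetic),
    dropped_rows = as.list(ds$dropped),
    n_records = nrow(dataset_records(ds)),
    waves = waves,
    status = status,
    files = basename(files)
  )
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(dataset = ds, rates = rates, descriptives = descriptives,
                 or_table = or_table, ci_hi = ci_hi,
                 decompositions = decomps, curves = curves,
                 manifest = manifest))
}
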