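#' Filter survival records by minimum follow-up
#'
#' Drops records with follow-up shorter than `min_days` (strictly; 30 days
#' by default) and validates times are positive.
#'
#' @param records Tibble with `sample`, `time_days`, `event`.
#' @param min_days Minimum follow-up retained (default 30).
#' @return The filtered tibble.
#' @export
filter_followup <- function(records, min_days = 30) {
  stopifnot(all(c("sample", "time_days", "event") %in% names(records)))
  if (any(records$time_days <= 0)) abort("survival times must be > 0")
  records[records$time_days >= min_days, , drop = FALSE]
}

#' Split samples into high/low groups at the median of a gene's expression
#'
#' Values strictly above the median go to `high`; values at or below the
#' median go to `low` (ties to the low group by convention; flip with
#' `ties`).
#'
#' @param expr Numeric genes x samples matrix.
#' @param gene Gene id.
#' @param samples Optional subset of samples.
#' @param ties `"low"` (default) or `"high"`: group receiving values equal
#'   to the median.
#' @return Named character vector (`high`/`low`) per sample.
#' @export
median_split <- function(expr, gene, samples = colnames(expr), ties = c("low", "high")) {
  ties <- arg_match(ties)
  check_expr(expr, "expr")
  if (!gene %in% rownames(expr)) abort(sprintf("gene %s not in matrix", gene))
  x <- expr[gene, samples]
  if (length(x) < 4) abort("need at least 4 samples for a median split")
  if (sd(x) == 0) abort("constant expression: no median split possible")
  med <- median(x)
  grp <- if (ties == "low") {
    ifelse(x > med, "high", "low")
  } else {
    ifelse(x >= med, "high", "low")
  }
  setNames(grp, samples)
}

#' Kaplan-Meier product-limit estimate
#'
#' Wraps the survival package's product-limit estimator and returns a tidy
#' step-function table per group.
#'
#' @param records Tibble with `time_days`, `event`, and optionally `group`.
#' @param group Optional named group vector (overrides a `group` column).
#' @return A tibble of class `km_fit`: `group`, `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv`.
#' @export
km_estimate <- function(records, group = NULL) {
  if (!is.null(group)) {
    records$group <- as.character(group[records$sample])
  }
  if (!"group" %in% names(records)) records$group <- "all"
  if (nrow(records) < 1) abort("need at least one record")
  fit <- survival::survfit(
    survival::Surv(time_days, event) ~ group,
    data = records
  )
  sm <- summary(fit, censored = TRUE)
  grp <- if (is.null(sm$strata)) {
    rep(unique(records$group)[1], length(sm$time))
  } else {
    sub("^group=", "", as.character(sm$strata))
  }
  out <- tibble(
    group = grp,
    time = sm$time,
    n_risk = sm$n.risk,
    n_event = sm$n.event,
    n_censor = sm$n.censor,
    surv = sm$surv
  )
  class(out) <- c("km_fit", class(out))
  out
}

#' Kaplan-Meier survival at a given time
#'
#' Right-continuous lookup of `S(t)` in a [km_estimate()] table.
#'
#' @param km A `km_fit` tibble.
#' @param t Time.
#' @param group Group label (defaults to the first).
#' @return `S(t)`.
#' @export
km_surv_at <- function(km, t, group = km$group[1]) {
  kg <- km[km$group == group & km$time <= t, , drop = FALSE]
  if (!nrow(kg)) {
    return(1)
  }
  kg$surv[nrow(kg)]
}

#' Two-group log-rank test
#'
#' `chi2 = (O - E)^2 / V` summed over event times, compared to a
#' chi-square with 1 df. Errors when neither group has an observed event.
#'
#' @param records Tibble with `time_days`, `event`, `group` (two levels).
#' @return A tibble with `chisq`, `df`, `p`.
#' @export
logrank <- function(records) {
  if (length(unique(records$group)) != 2) {
    abort("log-rank needs exactly two non-empty groups")
  }
  if (sum(records$event) == 0) {
    abort("no events observed in either group; log-rank undefined")
  }
  sd_fit <- survival::survdiff(
    survival::Surv(time_days, event) ~ group,
    data = records
  )
  tibble(
    chisq = sd_fit$chisq,
    df = 1,
    p = pchisq(sd_fit$chisq, df = 1, lower.tail = FALSE)
  )
}

#' Median-split survival analysis for a panel of genes
#'
#' For each gene: median split, follow-up filter, Kaplan-Meier fit per
#' group, and log-rank test.
#'
#' @param expr Numeric genes x samples matrix.
#' @param records Survival tibble (`sample`, `time_days`, `event`).
#' @param genes Genes to analyse (default: all rows of `expr`).
#' @param min_days Follow-up filter (default 30).
#' @return A list of class `survival_panel` with `summary` (tibble: `gene_id`,
#'   `n`, `chisq`, `p`) and `fits` (named list of `km_fit` tables).
#' @export
survival_panel <- function(expr, records, genes = rownames(expr), min_days = 30) {
  records <- filter_followup(records, min_days)
  records <- records[records$sample %in% colnames(expr), , drop = FALSE]
  fits <- list()
  rows <- purrr::map_dfr(genes, function(g) {
    grp <- median_split(expr, g, samples = records$sample)
    rec <- records
    rec$group <- grp[rec$sample]
    lr <- tryCatch(logrank(rec), error = function(e) NULL)
    fits[[g]] <<- km_estimate(rec)
    tibble(
      gene_id = g, n = nrow(rec),
      chisq = if (is.null(lr)) NA_real_ else lr$chisq,
      p = if (is.null(lr)) NA_real_ else lr$p
    )
  })
  structure(list(summary = rows, fits = fits), class = "survival_panel")
}

#' @method tidy survival_panel
#' @export
tidy.survival_panel <- function(x, ...) x$summary

#' @export
print.survival_panel <- function(x, ...) {
  cat(sprintf(
    "<survival_panel> %d genes; %d with log-rank p < 0.05\n",
    nrow(x$summary), sum(x$summary$p < 0.05, na.rm = TRUE)
  ))
  invisible(x)
}

#' Kaplan-Meier step curves for one analysed gene
#'
#' @param object A [survival_panel()] result.
#' @param gene Gene id (defaults to the smallest log-rank p).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot survival_panel
#' @export
autoplot.survival_panel <- function(object, gene = NULL, ...) {
  if (is.null(gene)) {
    gene <- object$summary$gene_id[which.min(object$summary$p)]
  }
  km <- object$fits[[gene]]
  p <- object$summary$p[object$summary$gene_id == gene]
  start <- km |>
    group_by(.data$group) |>
    summarise(time = 0, surv = 1, .groups = "drop")
  df <- bind_rows(start, km[, c("group", "time", "surv")])
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$surv, colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      title = sprintf("%s (log-rank p = %.3g)", gene, p),
      x = "time (days)", y = "survival probability", colour = "expression"
    ) +
    ggplot2::theme_minimal()
}
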