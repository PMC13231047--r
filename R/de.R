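#' Empirical-Bayes moderated two-group differential expression
#'
#' Fits, per gene, the case-minus-control log2 fold change and a moderated
#' t-statistic. Residual variances `s^2` (pooled two-group, `d = n - 2` df)
#' are shrunk toward a common prior: `s~^2 = (d0 * s0^2 + d * s^2) / (d0 + d)`,
#' with the prior `(d0, s0^2)` estimated by moment-matching the distribution
#' of `log s^2` (closed form through digamma/trigamma inversion). The
#' moderated t is `log2FC / (s~ * sqrt(1/n1 + 1/n2))` on `d0 + d` df, and
#' p-values are Benjamini-Hochberg adjusted across genes.
#'
#' With `moderation = "none"` the ordinary two-sample (pooled-variance) t is
#' used — the `d0 = 0` limit — which serves as the pipeline's second,
#' unmoderated DE configuration.
#'
#' If the empirical variance of `log s^2` shows no excess dispersion beyond
#' `trigamma(d/2)`, `d0` is set to infinity and `s0^2` to the geometric mean
#' of the sample variances, so that equal sample variances are left exactly
#' unshrunk.
#'
#' @param expr Numeric genes x samples matrix (log scale).
#' @param group Character/factor per sample with levels `case` and
#'   `control`, or a phenotype tibble with `sample` and `group` columns.
#' @param moderation `"eb"` (empirical Bayes) or `"none"` (ordinary t).
#' @return An object of class `de_fit`: a list with `table` (per-gene
#'   tibble: `gene_id`, `log2fc`, `t`, `p`, `adj_p`, `direction`), `d0`,
#'   `s0sq`, and group sizes. [tidy()] returns the table; [glance()] the
#'   moderation parameters.
#' @export
#' @examples
#' sim <- generate_expression(synth_config(n_genes = 150, seed = 1))
#' fit <- fit_de(sim$cohorts$a2$expr, sim$cohorts$a2$pheno)
#' glance(fit)
fit_de <- function(expr, group, moderation = c("eb", "none")) {
  moderation <- arg_match(moderation)
  check_expr(expr, "expr")
  if (is.data.frame(group)) {
    group <- setNames(group$group, group$sample)[colnames(expr)]
  }
  group <- as.character(group)
  if (length(group) != ncol(expr)) {
    abort("`group` must supply one label per sample")
  }
  if (!all(group %in% c("case", "control"))) {
    abort('`group` labels must be "case" or "control"')
  }
  n1 <- sum(group == "case")
  n2 <- sum(group == "control")
  if (n1 < 2 || n2 < 2) {
    abort("each group needs at least 2 samples for differential expression")
  }

  case <- expr[, group == "case", drop = FALSE]
  ctrl <- expr[, group == "control", drop = FALSE]
  m1 <- rowMeans(case)
  m2 <- rowMeans(ctrl)
  log2fc <- m1 - m2

  ss1 <- rowSums((case - m1)^2)
  ss2 <- rowSums((ctrl - m2)^2)
  d <- n1 + n2 - 2
  s2 <- (ss1 + ss2) / d

  if (moderation == "none") {
    d0 <- 0
    s0sq <- NA_real_
    s2_tilde <- s2
  } else {
    prior <- estimate_variance_prior(s2, d)
    d0 <- prior$d0
    s0sq <- prior$s0sq
    s2_tilde <- if (is.infinite(d0)) {
      rep(s0sq, length(s2))
    } else {
      (d0 * s0sq + d * s2) / (d0 + d)
    }
  }

  se <- sqrt(s2_tilde * (1 / n1 + 1 / n2))
  t_mod <- log2fc / se
  df_total <- d0 + d
  p <- 2 * pt(-abs(t_mod), df = df_total)
  p[se == 0] <- NA_real_
  adj_p <- bh_adjust(ifelse(is.na(p), 1, p))
  adj_p[is.na(p)] <- NA_real_

  table <- tibble(
    gene_id = rownames(expr),
    log2fc = unname(log2fc),
    t = unname(t_mod),
    p = unname(p),
    adj_p = unname(adj_p)
  )
  table$direction <- de_direction_call(table$log2fc, table$adj_p)

  structure(
    list(
      table = table, d0 = d0, s0sq = s0sq, df_residual = d,
      df_total = df_total, n_case = n1, n_control = n2,
      moderation = moderation
    ),
    class = "de_fit"
  )
}

# Moment-matching estimate of the inverse-chisquare variance prior
# (d0, s0^2) from log sample variances on d df.
estimate_variance_prior <- function(s2, d) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2) {
    return(list(d0 = Inf, s0sq = if (any(ok)) exp(mean(log(s2[ok]))) else 1))
  }
  z <- log(s2[ok])
  e <- z - digamma(d / 2) + log(d / 2)
  ev <- var(z) - trigamma(d / 2)
  if (!is.finite(ev) || ev <= 0) {
    # no excess dispersion: infinite prior df, geometric-mean prior variance
    return(list(d0 = Inf, s0sq = exp(mean(z))))
  }
  d0 <- 2 * trigamma_inverse(ev)
  s0sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0sq = s0sq)
}

# Solve trigamma(y) = x for y > 0 by Newton iteration on 1/trigamma
# (monotone, near-linear), following the standard approach.
trigamma_inverse <- function(x) {
  if (x > 1e7) {
    return(1 / sqrt(x))
  }
  if (x < 1e-6) {
    return(1 / x)
  }
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

de_direction_call <- function(log2fc, adj_p, lfc = 1, alpha = 0.05) {
  dplyr::case_when(
    log2fc > lfc & adj_p < alpha ~ "up",
    log2fc < -lfc & adj_p < alpha ~ "down",
    .default = "none"
  )
}

#' @method tidy de_fit
#' @export
tidy.de_fit <- function(x, ...) x$table

#' @method glance de_fit
#' @export
glance.de_fit <- function(x, ...) {
  tibble(
    d0 = x$d0, s0sq = x$s0sq, df_residual = x$df_residual,
    n_case = x$n_case, n_control = x$n_control,
    n_genes = nrow(x$table),
    n_up = sum(x$table$direction == "up", na.rm = TRUE),
    n_down = sum(x$table$direction == "down", na.rm = TRUE),
    moderation = x$moderation
  )
}

#' @export
print.de_fit <- function(x, ...) {
  cat(sprintf(
    "<de_fit> %d genes, %d case vs %d control (%s moderation)\n",
    nrow(x$table), x$n_case, x$n_control, x$moderation
  ))
  cat(sprintf(
    "  d0 = %s, s0^2 = %s; %d up / %d down at |log2FC| > 1 & adj p < 0.05\n",
    format(x$d0, digits = 4), format(x$s0sq, digits = 4),
    sum(x$table$direction == "up", na.rm = TRUE),
    sum(x$table$direction == "down", na.rm = TRUE)
  ))
  invisible(x)
}

#' Volcano plot of a differential-expression fit
#'
#' @param object A [fit_de()] result.
#' @param lfc,alpha Thresholds drawn and used for colouring.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot de_fit
#' @export
autoplot.de_fit <- function(object, lfc = 1, alpha = 0.05, ...) {
  df <- object$table
  df$direction <- de_direction_call(df$log2fc, df$adj_p, lfc, alpha)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$log2fc, y = -log10(.data$adj_p),
    colour = .data$direction
  )) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(-lfc, lfc), linetype = 2) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2) +
    ggplot2::scale_colour_manual(
      values = c(up = "#d73027", down = "#4575b4", none = "grey60")
    ) +
    ggplot2::labs(
      x = "log2 fold change (case - control)",
      y = "-log10 adjusted p", colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Classify genes as up/down regulated
#'
#' Strict thresholds as conventionally printed: `up` iff `log2FC > lfc` and
#' `adj_p < alpha`; `down` iff `log2FC < -lfc` and `adj_p < alpha`.
#'
#' @param de A `de_fit` or its tidied per-gene tibble.
#' @param lfc Log2 fold-change threshold (strict).
#' @param alpha Adjusted-p threshold (strict).
#' @return A list with sorted character vectors `up` and `down`.
#' @export
classify_degs <- function(de, lfc = 1, alpha = 0.05) {
  tab <- if (inherits(de, "de_fit")) de$table else de
  ok <- !is.na(tab$adj_p)
  up <- tab$gene_id[ok & tab$log2fc > lfc & tab$adj_p < alpha]
  down <- tab$gene_id[ok & tab$log2fc < -lfc & tab$adj_p < alpha]
  list(up = sorted_unique(up), down = sorted_unique(down))
}

#' Intersect DEG calls from two datasets, keeping consistent directions
#'
#' @param degs_1,degs_2 Lists with `up` and `down` elements, as returned by
#'   [classify_degs()].
#' @return A list with sorted `up` and `down` vectors; genes with opposite
#'   directions in the two inputs are excluded.
#' @export
intersect_consistent <- function(degs_1, degs_2) {
  list(
    up = sorted_unique(intersect(degs_1$up, degs_2$up)),
    down = sorted_unique(intersect(degs_1$down, degs_2$down))
  )
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values (same order as input).
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Write a differential-expression table as TSV
#'
#' @param de A `de_fit`.
#' @param path Output path.
#' @export
write_de_table <- function(de, path) {
  readr::write_tsv(tidy(de), path, progress = FALSE)
  invisible(path)
}
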