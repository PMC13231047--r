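#' Normalize an expression matrix and collapse duplicate gene rows
#'
#' Applies, in order: `log2(x + 1)` transformation (for non-negative
#' intensity/TPM-like input), optional quantile normalization across
#' samples, and collapse of duplicate gene ids to their per-sample mean.
#'
#' @param expr Numeric genes x samples matrix (duplicate gene rownames
#'   allowed before collapsing).
#' @param log_transform Apply `log2(x + 1)`? Requires non-negative input.
#' @param quantile_normalize Apply quantile normalization after the log
#'   transform? Off by default (synthetic and TPM-like input is already on
#'   a comparable scale).
#' @param collapse Collapse duplicate gene rows by their mean?
#' @return A numeric matrix with unique gene rownames.
#' @export
#' @examples
#' m <- matrix(c(0, 3, 1, 3, 3, 5), 3, 2,
#'   dimnames = list(c("A", "G", "G"), c("s1", "s2"))
#' )
#' preprocess_expression(m, log_transform = FALSE)
preprocess_expression <- function(expr, log_transform = TRUE,
                                  quantile_normalize = FALSE,
                                  collapse = TRUE) {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    abort("`expr` must be a numeric matrix")
  }
  if (is.null(rownames(expr))) abort("`expr` must have gene rownames")
  if (log_transform) {
    if (any(expr < 0, na.rm = TRUE)) {
      abort("negative values are incompatible with the log2(x + 1) transform")
    }
    expr <- log2(expr + 1)
  }
  if (quantile_normalize) {
    nm <- dimnames(expr)
    expr <- limma::normalizeQuantiles(expr)
    dimnames(expr) <- nm
  }
  if (collapse && anyDuplicated(rownames(expr))) {
    expr <- rowsum(expr, group = rownames(expr)) /
      as.vector(table(rownames(expr))[sorted_unique(rownames(expr))])
    expr <- expr[sorted_unique(rownames(expr)), , drop = FALSE]
  }
  expr
}
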