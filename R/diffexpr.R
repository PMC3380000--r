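#' Omnibus two-way ANOVA p-value for one probe
#'
#' Fits a main-effects linear model `expression ~ condition + time` on the
#' non-baseline samples and returns the omnibus F-test p-value of the model
#' against the intercept-only null. A factor with a single observed level is
#' dropped (the model collapses to one-way ANOVA); if no factor with at
#' least two levels remains the design is degenerate and an error is
#' raised. Probes with (numerically) zero total variance return p = 1: no
#' variance is no evidence.
#'
#' @param values Numeric vector, one expression value per non-baseline
#'   sample (same order as `design` rows after baseline removal).
#' @param design Sample-design data frame covering exactly these samples.
#' @return Scalar p-value in \[0, 1\].
#' @export
probe_anova <- function(values, design) {
  X <- anova_model_matrix(design)
  anova_pvalues(matrix(values, nrow = 1L), X)[1L]
}

# Model matrix for condition + time main effects; single-level factors are
# dropped. Returns the matrix with df attributes used by anova_pvalues().
anova_model_matrix <- function(design) {
  cond <- factor(design$condition)
  time <- factor(design$time)
  terms <- list()
  if (nlevels(cond) >= 2L) terms$condition <- cond
  if (nlevels(time) >= 2L) terms$time <- time
  if (length(terms) == 0L) {
    stop("degenerate design: neither condition nor time has >= 2 levels")
  }
  df <- as.data.frame(terms)
  X <- stats::model.matrix(~ ., data = df)
  if (nrow(X) <= ncol(X)) stop("degenerate design: no residual degrees of freedom")
  X
}

# Vectorized omnibus F-test over the rows of Y against model matrix X.
anova_pvalues <- function(Y, X) {
  qrX <- qr(X)
  n <- ncol(Y)
  res <- t(qr.resid(qrX, t(Y)))          # residuals of the full model
  rss <- rowSums(res^2)
  tss <- rowSums((Y - rowMeans(Y))^2)
  df1 <- qrX$rank - 1L
  df2 <- n - qrX$rank
  fstat <- ((tss - rss) / df1) / (rss / df2)
  p <- stats::pf(fstat, df1, df2, lower.tail = FALSE)
  # zero total variance: F is 0/0, return 1 (conservative)
  p[tss < n * .Machine$double.eps * 100] <- 1
  # zero residual variance with real signal: F -> Inf
  p[!is.finite(fstat) & tss > 0] <- 0
  p[tss < n * .Machine$double.eps * 100] <- 1
  unname(p)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (the Hochberg-Benjamini
#' procedure as used throughout microarray work), order-preserving and
#' clipped to 1. Thin wrapper over `stats::p.adjust(method = "BH")` with
#' domain validation.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
adjust_pvalues <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Select differentially regulated probesets
#'
#' Per probe: omnibus two-way ANOVA (condition + time) on the non-baseline
#' samples, BH adjustment across probes, and the largest absolute mean log2
#' difference of any condition-by-time group versus the mean of the
#' baseline-control samples. A probe is selected when `p_adjusted < alpha`
#' and `max_abs_log2_fc >= log2(fc_threshold)`.
#'
#' @param mat Expression matrix (probes x samples, log2 scale).
#' @param design Sample-design data frame; must flag at least one
#'   `is_baseline_control` sample.
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @param fc_threshold Fold-change cutoff on the linear scale (default 2.0,
#'   i.e. 1 log2 unit).
#' @return `data.frame` with columns `probe_id`, `p_value`, `p_adjusted`,
#'   `max_abs_log2_fc`, `selected`.
#' @export
select_differential <- function(mat, design, alpha = 0.05, fc_threshold = 2.0) {
  validate_design(mat, design)
  if (!any(design$is_baseline_control)) {
    stop("differential filtering needs at least one baseline-control sample")
  }
  design <- design[match(colnames(mat), design$sample_id), ]
  base <- design$is_baseline_control
  treat_design <- design[!base, , drop = FALSE]
  Y <- mat[, !base, drop = FALSE]

  X <- anova_model_matrix(treat_design)
  p <- anova_pvalues(Y, X)
  padj <- adjust_pvalues(p)

  base_mean <- rowMeans(mat[, base, drop = FALSE])
  groups <- interaction(treat_design$condition, treat_design$time, drop = TRUE)
  group_means <- vapply(levels(groups), function(g) {
    rowMeans(Y[, groups == g, drop = FALSE])
  }, numeric(nrow(Y)))
  if (is.null(dim(group_means))) group_means <- matrix(group_means, nrow = 1L)
  max_fc <- apply(abs(group_means - base_mean), 1L, max)

  data.frame(
    probe_id = rownames(mat),
    p_value = p,
    p_adjusted = padj,
    max_abs_log2_fc = unname(max_fc),
    selected = padj < alpha & max_fc >= log2(fc_threshold),
    stringsAsFactors = FALSE
  )
}
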