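#' Regulatory-coherence test of a gene neighborhood
#'
#' On a gene x perturbation response matrix (e.g. expression responses to a
#' panel of regulator knock-downs), computes the Pearson correlation across
#' perturbations for every gene pair and compares the within-group pairwise
#' correlations (`r_in`) against the correlations of group-to-non-group
#' pairs (`r_out`) with a Welch two-sample t test. Pairs of two non-group
#' genes are not part of `r_out`: the comparison is group-anchored
#' ("the neighborhood versus other genes"). Genes with zero variance
#' across perturbations carry no correlation information and are excluded
#' with a warning.
#'
#' @param responses Numeric matrix, rows = genes (named), columns =
#'   perturbations (>= 3).
#' @param group Character vector of group gene symbols (subset of the
#'   matrix rows, >= 2 after exclusions; at least one non-group gene must
#'   remain).
#' @return List: `group_genes`, `r_in`, `r_out`, `t_statistic`, `p_value`,
#'   `n_in_pairs`, `n_out_pairs`, `excluded` (zero-variance genes). The t
#'   statistic and p-value are `NA` when either collection has fewer than
#'   two pairs.
#' @export
coherence_test <- function(responses, group) {
  stopifnot(is.matrix(responses), !is.null(rownames(responses)))
  if (ncol(responses) < 3L) stop("need >= 3 perturbation columns")
  missing <- setdiff(group, rownames(responses))
  if (length(missing) > 0L) {
    stop("group gene(s) absent from matrix: ", paste(missing, collapse = ", "))
  }
  vars <- apply(responses, 1L, stats::var)
  excluded <- rownames(responses)[vars == 0]
  if (length(excluded) > 0L) {
    warning(sprintf("excluding %d zero-variance gene(s): %s",
                    length(excluded), paste(excluded, collapse = ", ")))
    responses <- responses[vars > 0, , drop = FALSE]
  }
  group <- intersect(group, rownames(responses))
  nongroup <- setdiff(rownames(responses), group)
  if (length(group) < 2L) stop("fewer than 2 group genes with nonzero variance")
  if (length(nongroup) == 0L) stop("no non-group genes: r_out is undefined")

  cc <- stats::cor(t(responses))
  in_vals <- cc[group, group][upper.tri(diag(length(group)))]
  out_vals <- as.vector(cc[group, nongroup, drop = FALSE])

  if (length(in_vals) >= 2L && length(out_vals) >= 2L) {
    tt <- stats::t.test(in_vals, out_vals)  # Welch by default
    t_stat <- unname(tt$statistic)
    p <- tt$p.value
  } else {
    t_stat <- NA_real_
    p <- NA_real_
  }
  list(
    group_genes = group,
    r_in = mean(in_vals),
    r_out = mean(out_vals),
    t_statistic = t_stat,
    p_value = p,
    n_in_pairs = length(in_vals),
    n_out_pairs = length(out_vals),
    excluded = excluded
  )
}

#' Read a gene x perturbation response matrix from TSV
#' @param path TSV with first column gene symbols, header = perturbation
#'   labels.
#' @return Numeric matrix with rownames = genes.
#' @export
read_response_matrix <- function(path) {
  read_expression(path)
}
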