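#' Read a log2 expression matrix from TSV
#'
#' Expression matrices are plain tab-separated files: a header row of sample
#' ids and a first column of probeset ids. Values are assumed to be already
#' log2-normalized (e.g. RMA output); the loader validates finiteness and
#' identifier uniqueness only, it never imputes.
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix, rows = probesets, columns = samples, with
#'   `rownames` and `colnames` set.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression file needs a probe column and >=1 sample column")
  probes <- as.character(df[[1L]])
  if (anyDuplicated(probes)) {
    stop("duplicate probe id(s): ",
         paste(unique(probes[duplicated(probes)]), collapse = ", "))
  }
  samples <- colnames(df)[-1L]
  if (anyDuplicated(samples)) stop("duplicate sample id(s) in header")
  mat <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -1L, drop = FALSE], 2L,
                                              function(x) as.numeric(x)))) &
                   !is.na(as.matrix(df[, -1L, drop = FALSE])), arr.ind = TRUE)
    if (nrow(bad) > 0L) {
      stop(sprintf("non-numeric value at probe '%s', sample '%s'",
                   probes[bad[1L, 1L]], samples[bad[1L, 2L]]))
    }
    stop("expression values are not numeric")
  }
  if (any(!is.finite(mat))) {
    idx <- which(!is.finite(mat), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite value at probe '%s', sample '%s' (missing values are rejected, not imputed)",
                 probes[idx[1L]], samples[idx[2L]]))
  }
  dimnames(mat) <- list(probes, samples)
  mat
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression()]. Numbers are written with full precision
#' (`format = "%.15g"` via `write.table` default formatting is avoided by
#' explicit character conversion) so a write/read round trip is value-stable.
#'
#' @param mat Numeric matrix with row and column names.
#' @param path Output path.
#' @export
write_expression <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  df <- data.frame(probe_id = rownames(mat),
                   apply(mat, 2L, function(x) sprintf("%.15g", x)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("probe_id", colnames(mat))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample-design table
#'
#' Columns: `sample_id`, `condition`, `time`, `replicate`,
#' `is_baseline_control` (logical or 0/1).
#'
#' @param path Path to a TSV file.
#' @return `data.frame` with the five columns, `replicate` integer,
#'   `is_baseline_control` logical.
#' @export
read_sample_design <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  needed <- c("sample_id", "condition", "time", "replicate", "is_baseline_control")
  missing <- setdiff(needed, colnames(df))
  if (length(missing) > 0L) {
    stop("design file missing column(s): ", paste(missing, collapse = ", "))
  }
  df <- df[, needed]
  df$replicate <- as.integer(df$replicate)
  df$is_baseline_control <- as.logical(df$is_baseline_control)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in design")
  if (any(df$replicate < 1L)) stop("replicate must be >= 1")
  df
}

#' Write a sample-design table
#' @param design Data frame as returned by [read_sample_design()].
#' @param path Output path.
#' @export
write_sample_design <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Check that an expression matrix and a design describe the same samples
#'
#' @param mat Expression matrix.
#' @param design Sample design data frame.
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_design <- function(mat, design) {
  if (!setequal(colnames(mat), design$sample_id) ||
      ncol(mat) != nrow(design)) {
    stop("design samples do not match expression matrix columns")
  }
  invisible(TRUE)
}

#' Read a probeset-to-gene annotation table
#'
#' Two tab-separated columns: `probe_id`, `gene_symbol`. Empty symbols mark
#' unannotated probes; those are carried through network stages under their
#' probe id and dropped only from gene-level operations.
#'
#' @param path Path to a TSV file.
#' @return Named character vector, names = probe ids, values = gene symbols
#'   (possibly `""`).
#' @export
read_probe_annotation <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = NULL)
  if (!all(c("probe_id", "gene_symbol") %in% colnames(df))) {
    stop("annotation file needs columns probe_id, gene_symbol")
  }
  if (anyDuplicated(df$probe_id)) stop("duplicate probe_id in annotation")
  stats::setNames(df$gene_symbol, df$probe_id)
}

#' Map probe ids to gene symbols
#'
#' Lookup of a probe absent from the annotation is an error, not a silent
#' empty string.
#'
#' @param annot Named character vector from [read_probe_annotation()].
#' @param probes Character vector of probe ids.
#' @return Character vector of gene symbols (`""` for unannotated probes).
#' @export
probe_genes <- function(annot, probes) {
  unknown <- setdiff(probes, names(annot))
  if (length(unknown) > 0L) {
    stop("probe id(s) absent from annotation: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  }
  unname(annot[probes])
}

#' Read a gene-set collection in GMT format
#'
#' One term per line: term id, description, then member gene symbols, all
#' tab-separated. Empty member lists and duplicate term ids are format
#' errors.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors (members), with per-term
#'   descriptions in `attr(, "descriptions")`.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  ids <- character(length(lines))
  desc <- character(length(lines))
  members <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) stop(sprintf("GMT line %d has fewer than 3 fields", i))
    ids[i] <- f[1L]
    desc[i] <- f[2L]
    mem <- unique(f[-(1:2)])
    mem <- mem[nzchar(mem)]
    if (length(mem) == 0L) stop(sprintf("GMT line %d ('%s') has an empty member list", i, f[1L]))
    members[[i]] <- mem
  }
  if (anyDuplicated(ids)) {
    stop("duplicate term id(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(members) <- ids
  attr(members, "descriptions") <- stats::setNames(desc, ids)
  members
}

#' Write a gene-set collection in GMT format
#' @param sets Named list of character vectors; optional `descriptions`
#'   attribute (named character).
#' @param path Output path.
#' @export
write_gene_sets <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  if (is.null(desc)) desc <- stats::setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(id) {
    paste(c(id, desc[[id]], sets[[id]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}
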