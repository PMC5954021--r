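#' Construct a two-arm EMT gene signature
#'
#' @param mesenchymal_genes,epithelial_genes Character vectors of gene ids;
#'   whitespace-stripped, must be non-empty and disjoint.
#' @return Object of class `emt_signature`.
#' @export
emt_signature <- function(mesenchymal_genes, epithelial_genes) {
  m <- trimws(as.character(mesenchymal_genes))
  e <- trimws(as.character(epithelial_genes))
  if (!length(m) || !length(e)) abort_invalid("both signature arms must be non-empty")
  if (anyDuplicated(c(m, e))) abort_invalid("signature arms must be disjoint and duplicate-free")
  structure(list(mesenchymal_genes = m, epithelial_genes = e),
            class = "emt_signature")
}

#' @export
print.emt_signature <- function(x, ...) {
  cat(sprintf(
    "<emt_signature> %d mesenchymal + %d epithelial genes\n",
    length(x$mesenchymal_genes), length(x$epithelial_genes)
  ))
  invisible(x)
}

#' Read a two-arm signature from TSV
#'
#' Expects columns `gene` and `arm` (values `mesenchymal` / `epithelial`).
#'
#' @param path TSV file path.
#' @return An [emt_signature()].
#' @export
read_emt_signature <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "arm") %in% names(df))) {
    abort_validation(sprintf("'%s': signature file needs columns gene, arm", path))
  }
  bad <- setdiff(unique(df$arm), c("mesenchymal", "epithelial"))
  if (length(bad)) {
    abort_validation(sprintf("unknown signature arm '%s'", bad[1]))
  }
  emt_signature(df$gene[df$arm == "mesenchymal"], df$gene[df$arm == "epithelial"])
}

#' The packaged EMT signature fixture
#'
#' Loads the signature shipped with the package:
#' `extdata/emt_signature_synthetic.tsv`, a synthetic stand-in with the
#' canonical shape of published core-EMT signatures (20 mesenchymal + 17
#' epithelial = 37 genes), populated with widely used EMT marker genes. It is
#' a structural fixture, not a reproduction of any specific published gene
#' list.
#'
#' @return An [emt_signature()] with 37 genes.
#' @export
default_emt_signature <- function() {
  read_emt_signature(
    system.file("extdata", "emt_signature_synthetic.tsv",
                package = "glycoEMT", mustWork = TRUE)
  )
}

#' Log2-ratio transform of a raw expression matrix
#'
#' Converts non-negative raw expression (e.g. RSEM) to gene-wise log ratios:
#' `log2(x + pseudocount)` followed by centering each gene at its median (or
#' mean) across samples, so a value of 0 means "unchanged relative to the
#' cohort" -- the convention the heat-map color scale assumes.
#'
#' @param matrix Numeric gene x sample matrix with row and column names; raw
#'   space (all values >= 0).
#' @param pseudocount Non-negative value added before the log (default 1).
#' @param center `"median"` (default) or `"mean"` gene-wise centering.
#' @return The transformed matrix with attribute `space = "log_ratio"`.
#' @export
log_ratio_transform <- function(matrix, pseudocount = 1, center = c("median", "mean")) {
  center <- match.arg(center)
  validate_expression_matrix(matrix, space = "raw")
  check_number(pseudocount, "pseudocount", lower = 0)
  if (pseudocount == 0 && any(matrix == 0)) {
    abort_glyco(
      "matrix contains zeros; use a positive pseudocount to take log2",
      "glycoEMT_domain_error"
    )
  }
  lg <- log2(matrix + pseudocount)
  ctr <- apply(lg, 1, if (center == "median") stats::median else mean)
  out <- lg - ctr
  attr(out, "space") <- "log_ratio"
  out
}

validate_expression_matrix <- function(matrix, space = NULL) {
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    abort_invalid("expression matrix must be a numeric matrix")
  }
  if (is.null(rownames(matrix)) || is.null(colnames(matrix))) {
    abort_invalid("expression matrix needs gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(matrix))) abort_invalid("duplicate gene ids")
  if (anyDuplicated(colnames(matrix))) abort_invalid("duplicate sample ids")
  declared <- attr(matrix, "space") %||% "raw"
  if (identical(space, "raw")) {
    if (declared == "log_ratio") abort_invalid("matrix already in log-ratio space")
    if (any(matrix < 0)) abort_invalid("raw-space matrix must be non-negative")
  }
  invisible(matrix)
}

#' Per-sample EMT score
#'
#' Score of a sample = mean log ratio over the mesenchymal-arm genes found in
#' the matrix minus the mean over the epithelial-arm genes found. Higher means
#' more mesenchymal-like. Signature genes missing from the matrix are dropped
#' with a warning; an arm with no matching gene is an error. Gene matching is
#' exact and case-sensitive after whitespace stripping.
#'
#' @param matrix Gene x sample matrix in log-ratio space (see
#'   [log_ratio_transform()]; a matrix without a `space` attribute is assumed
#'   already logged).
#' @param signature An [emt_signature()].
#' @return Object of class `emt_scores`: data frame with columns `sample_id`
#'   and `emt_score`, plus a `coverage` attribute giving the fraction of each
#'   arm found in the matrix.
#' @export
emt_score <- function(matrix, signature) {
  if (!inherits(signature, "emt_signature")) {
    abort_invalid("'signature' must be an emt_signature")
  }
  validate_expression_matrix(matrix)
  if (identical(attr(matrix, "space") %||% "log_ratio", "raw")) {
    abort_invalid("matrix is in raw space; apply log_ratio_transform() first")
  }
  genes <- trimws(rownames(matrix))
  mes <- intersect(signature$mesenchymal_genes, genes)
  epi <- intersect(signature$epithelial_genes, genes)
  miss <- setdiff(c(signature$mesenchymal_genes, signature$epithelial_genes), genes)
  if (!length(mes) || !length(epi)) {
    abort_glyco(
      sprintf("signature unusable: %s arm has no gene in the matrix",
              if (length(mes)) "epithelial" else "mesenchymal"),
      "glycoEMT_unusable_signature"
    )
  }
  if (length(miss)) {
    warning(sprintf(
      "%d signature gene(s) missing from matrix: %s",
      length(miss), paste(miss, collapse = ", ")
    ), call. = FALSE)
  }
  mes_mean <- colMeans(matrix[match(mes, genes), , drop = FALSE])
  epi_mean <- colMeans(matrix[match(epi, genes), , drop = FALSE])
  structure(
    data.frame(
      sample_id = colnames(matrix),
      emt_score = unname(mes_mean - epi_mean),
      stringsAsFactors = FALSE
    ),
    coverage = c(
      mesenchymal = length(mes) / length(signature$mesenchymal_genes),
      epithelial = length(epi) / length(signature$epithelial_genes)
    ),
    class = c("emt_scores", "data.frame")
  )
}

#' Swap the arms of a signature
#'
#' @param signature An [emt_signature()].
#' @return The signature with mesenchymal and epithelial arms exchanged.
#' @export
swap_arms <- function(signature) {
  emt_signature(signature$epithelial_genes, signature$mesenchymal_genes)
}

#' Pearson correlation with a two-sided p-value
#'
#' Thin wrapper around [stats::cor.test()] with the input validation the
#' pipeline needs: equal lengths, at least 3 paired values, no constant
#' vector.
#'
#' @param x,y Numeric vectors of equal length (n >= 3).
#' @return Object of class `correlation_result`: list with `r`, `p_value`, `n`.
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y)) abort_invalid("'x' and 'y' must have equal length")
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) abort_invalid("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort_glyco("correlation undefined for a constant vector",
                "glycoEMT_undefined_correlation")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(
    list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x)),
    class = "correlation_result"
  )
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation> r = %.4f, p = %.3g, n = %d\n", x$r, x$p_value, x$n))
  invisible(x)
}

#' Correlate genes with the per-sample EMT score
#'
#' @param matrix Log-ratio gene x sample matrix.
#' @param scores An [emt_score()] result for the same samples.
#' @param genes Character vector of gene ids to correlate with the score.
#' @return Data frame with columns `gene`, `r`, `p`, `n`; genes absent from
#'   the matrix or with undefined correlation get `NA` values.
#' @export
correlate_with_score <- function(matrix, scores, genes) {
  validate_expression_matrix(matrix)
  s <- scores$emt_score[match(colnames(matrix), scores$sample_id)]
  rows <- lapply(genes, function(g) {
    if (!g %in% rownames(matrix)) {
      return(data.frame(gene = g, r = NA_real_, p = NA_real_, n = NA_integer_))
    }
    res <- tryCatch(correlate(matrix[g, ], s), glycoEMT_error = function(e) NULL)
    if (is.null(res)) {
      data.frame(gene = g, r = NA_real_, p = NA_real_, n = NA_integer_)
    } else {
      data.frame(gene = g, r = res$r, p = res$p_value, n = res$n)
    }
  })
  do.call(rbind, rows)
}

#' Heat-map colors for expression log ratios and EMT scores
#'
#' Linear two-sided ramp reproducing the conventional coloring: expression log
#' ratios run black (0) to pure red at `+vmax` and pure green at `-vmax`; EMT
#' scores run gray (0) to yellow (mesenchymal, positive) and blue (epithelial,
#' negative). Intensity scales linearly with magnitude and saturates at
#' `|value| >= vmax`.
#'
#' @param values Numeric vector.
#' @param kind `"expression"` or `"emt_score"`.
#' @param vmax Positive saturation point; defaults to 3 log2 units for
#'   expression and 1 for EMT scores.
#' @return Integer matrix with columns `r`, `g`, `b` (0-255), one row per
#'   value, and attribute `hex` with the equivalent hex strings.
#' @export
heatmap_colors <- function(values, kind = c("expression", "emt_score"), vmax = NULL) {
  kind <- match.arg(kind)
  vmax <- vmax %||% if (kind == "expression") 3 else 1
  check_number(vmax, "vmax", lower = .Machine$double.xmin)
  t <- pmin(abs(values) / vmax, 1)
  pos <- values >= 0
  mix <- function(zero, full) round(outer(t, full - zero) + rep(zero, each = length(t)))
  if (kind == "expression") {
    up <- mix(c(0, 0, 0), c(255, 0, 0))     # black -> red
    dn <- mix(c(0, 0, 0), c(0, 255, 0))     # black -> green
  } else {
    up <- mix(c(128, 128, 128), c(255, 255, 0)) # gray -> yellow
    dn <- mix(c(128, 128, 128), c(0, 0, 255))   # gray -> blue
  }
  out <- ifelse(matrix(pos, nrow = length(values), ncol = 3), up, dn)
  out <- matrix(as.integer(out), ncol = 3, dimnames = list(NULL, c("r", "g", "b")))
  attr(out, "hex") <- grDevices::rgb(out[, 1], out[, 2], out[, 3], maxColorValue = 255)
  out
}
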