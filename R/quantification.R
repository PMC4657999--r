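# Median-of-ratios normalization, no-replicate fold change, and stem-loop
# qRT-PCR relative quantification (2^-dCt against U6).

#' Median-of-ratios size factors
#'
#' For each library j the size factor is the median, over features with
#' strictly positive counts in every library, of count(i, j) divided by the
#' geometric mean of row i across libraries. This is the no-replicate
#' normalization estimator of the DESeq family, re-implemented here.
#'
#' @param mat numeric matrix or data.frame of nonnegative counts, features in
#'   rows, libraries in columns (named).
#' @return named numeric vector of positive size factors.
#' @export
size_factors <- function(mat) {
  mat <- as.matrix(mat)
  .check(nrow(mat) >= 1L, "count matrix needs at least one feature")
  .check(mat >= 0, "counts must be nonnegative")
  pos <- rowSums(mat > 0) == ncol(mat)
  if (!any(pos)) {
    .fail("normalization impossible: no feature has positive counts in ",
          "every library")
  }
  loggm <- rowMeans(log(mat[pos, , drop = FALSE]))
  apply(mat[pos, , drop = FALSE], 2L,
        function(col) exp(stats::median(log(col) - loggm)))
}

#' No-replicate fold change between two libraries
#'
#' FC = (count_A / factor_A) / (count_B / factor_B) per feature. A zero
#' numerator gives 0; a zero denominator with nonzero numerator is flagged
#' infinite. No pseudocount is added by default; `pseudocount` can be set for
#' degenerate inputs.
#'
#' @param mat count matrix (features x libraries).
#' @param factors named positive size factors (e.g. from [size_factors()]).
#' @param pair ordered pair c(A, B): the fold change of A over B.
#' @param pseudocount added to every count before normalization (default 0).
#' @return data.frame: feature, norm_A, norm_B, fc (Inf flagged as is).
#' @export
fold_change <- function(mat, factors, pair, pseudocount = 0) {
  mat <- as.matrix(mat)
  .check(length(pair) == 2L, "pair must name two libraries")
  missing <- setdiff(pair, colnames(mat))
  if (length(missing)) {
    .fail("library not in matrix: ", paste(missing, collapse = ", "))
  }
  .check(all(pair %in% names(factors)) && all(factors[pair] > 0),
         "size factors must be positive and cover both libraries")
  na <- (mat[, pair[1L]] + pseudocount) / factors[[pair[1L]]]
  nb <- (mat[, pair[2L]] + pseudocount) / factors[[pair[2L]]]
  fc <- ifelse(na == 0, 0, ifelse(nb == 0, Inf, na / nb))
  data.frame(feature = rownames(mat) %||% as.character(seq_len(nrow(mat))),
             norm_A = na, norm_B = nb, fc = fc,
             row.names = NULL, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a Ct table (assay, ct, sd)
#'
#' @param path TSV path.
#' @return data.frame with assay, ct, sd.
#' @export
read_ct_table <- function(path) {
  if (!file.exists(path)) .fail("no such file: ", path)
  tbl <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("assay", "ct", "sd"), names(tbl))
  if (length(missing)) {
    .fail("Ct table is missing column(s): ", paste(missing, collapse = ", "))
  }
  tbl$ct <- as.numeric(tbl$ct)
  tbl$sd <- as.numeric(tbl$sd)
  .check(tbl$ct > 0, "Ct values must be positive")
  .check(tbl$sd >= 0, "Ct standard deviations must be nonnegative")
  tbl
}

#' qRT-PCR expression calls and relative quantification
#'
#' An assay is called expressed when its Ct is strictly below `ct_max`
#' (default 35). Relative quantity against the control (U6 snRNA by default)
#' is 2^-dCt with dCt = Ct(assay) - Ct(control).
#'
#' @param records data.frame with columns assay, ct (and optionally sd).
#' @param control control assay name (default "U6").
#' @param ct_max expression threshold in cycles (default 35, strict).
#' @return data.frame: assay, ct, expressed, delta_ct, rq.
#' @export
qpcr_quantify <- function(records, control = "U6", ct_max = 35) {
  sel <- records$assay == control
  if (!any(sel)) .fail("control assay not found: ", control)
  ct_control <- records$ct[which(sel)[1L]]
  delta <- records$ct - ct_control
  data.frame(assay = records$assay, ct = records$ct,
             expressed = records$ct < ct_max,
             delta_ct = delta, rq = 2^(-delta),
             row.names = NULL, stringsAsFactors = FALSE)
}
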