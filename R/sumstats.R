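#' @importFrom utils head tail read.table write.table modifyList
NULL

# Internal: validate a summary-statistics data.frame and normalize columns.
# Required: snp_id, y (log-odds ratio), v (sampling variance, > 0).
# Optional: daf in (0,1), p_ref in [0,1], stratum.
.checkSumstats <- function(data, requireDaf = FALSE, requirePref = FALSE) {
  if (!is.data.frame(data) || nrow(data) == 0L)
    stop("summary statistics must be a nonempty data.frame")
  need <- c("snp_id", "y", "v")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(data$snp_id))
    stop("duplicate snp_id values are not allowed")
  if (!is.numeric(data$y) || !is.numeric(data$v))
    stop("y and v must be numeric")
  if (any(!is.finite(data$y))) stop("y must be finite for every SNP")
  if (any(!is.finite(data$v) | data$v <= 0))
    stop("sampling variance v must be positive and finite for every SNP")
  if (!is.null(data$daf)) {
    bad <- !is.na(data$daf) & (data$daf <= 0 | data$daf >= 1)
    if (any(bad)) stop("daf must lie strictly inside (0, 1)")
  }
  if (requireDaf && (is.null(data$daf) || all(is.na(data$daf))))
    stop("this operation needs derived allele frequencies (column 'daf')")
  if (requirePref && is.null(data$p_ref))
    stop("this operation needs reference P-values (column 'p_ref')")
  invisible(data)
}

#' Assemble a GWAS summary-statistics table
#'
#' Builds the per-SNP table every model function consumes: one row per SNP
#' with the estimated log-odds ratio of the derived allele (`beta`, natural
#' log scale) and its sampling uncertainty, given either as a standard error
#' or as a variance. Variance is what is stored (`v = se^2`).
#'
#' @param snp_id character vector of unique SNP identifiers.
#' @param beta estimated per-allele log-odds ratios \eqn{\hat\beta_j}.
#' @param se standard errors of `beta` (mutually exclusive with `var`).
#' @param var sampling variances \eqn{\hat V_{\hat\beta_j}} of `beta`.
#' @param daf optional derived allele frequencies, strictly in (0, 1).
#' @param p_ref optional association P-values from a reference GWAS, used by
#'   [pvaluePrune()].
#' @param stratum optional stratum labels (e.g. `"eQTL"`, `"DAF_bin_1"`).
#' @return a data.frame with columns `snp_id`, `y`, `v` and any optional
#'   columns supplied.
#' @examples
#' ss <- sumstats(c("rs1", "rs2"), beta = c(0.02, -0.10), se = c(0.01, 0.04))
#' ss$v  # 1e-04 1.6e-03
#' @export
sumstats <- function(snp_id, beta, se = NULL, var = NULL, daf = NULL,
                     p_ref = NULL, stratum = NULL) {
  if (is.null(se) == is.null(var))
    stop("supply exactly one of 'se' or 'var'")
  v <- if (is.null(var)) se^2 else var
  out <- data.frame(snp_id = as.character(snp_id), y = as.numeric(beta),
                    v = as.numeric(v), stringsAsFactors = FALSE)
  if (!is.null(daf)) out$daf <- as.numeric(daf)
  if (!is.null(p_ref)) out$p_ref <- as.numeric(p_ref)
  if (!is.null(stratum)) out$stratum <- as.character(stratum)
  .checkSumstats(out)
  out
}
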