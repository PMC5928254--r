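# File I/O for summary-statistics and LD tables, LD pruning (P-value-based
# and random), DAF binning, and stratified fits.

#' Read a summary-statistics TSV
#'
#' Tab-delimited with a header; required columns `snp_id`, `beta`, and one
#' of `se` or `var`; optional `daf`, `p_ref`, `stratum`. `.` marks a
#' missing value. Rows violating row-level invariants (non-numeric fields,
#' `se`/`var` not positive, non-finite `beta`, `daf` outside (0,1)) are
#' rejected with a warning naming their line numbers; structural problems
#' (missing columns, duplicated `snp_id`) are errors.
#'
#' @param path file to read.
#' @return summary-statistics data.frame (variance stored as `v = se^2`
#'   when the file declares `se`).
#' @export
readSumstats <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           na.strings = ".", colClasses = "character",
                           quote = "", comment.char = "")
  if (!"snp_id" %in% names(raw) || !"beta" %in% names(raw))
    stop("missing required column(s): need snp_id and beta")
  hasSe <- "se" %in% names(raw); hasVar <- "var" %in% names(raw)
  if (!hasSe && !hasVar)
    stop("missing required column(s): need one of se or var")
  num <- function(x) suppressWarnings(as.numeric(x))
  beta <- num(raw$beta)
  v <- if (hasVar) num(raw$var) else num(raw$se)^2
  daf <- if ("daf" %in% names(raw)) num(raw$daf) else NULL
  pref <- if ("p_ref" %in% names(raw)) num(raw$p_ref) else NULL
  bad <- !is.finite(beta) | !is.finite(v) | v <= 0
  if (!is.null(daf)) bad <- bad | (!is.na(raw$daf) & (is.na(daf) |
                                                      daf <= 0 | daf >= 1))
  if (!is.null(pref)) bad <- bad | (!is.na(raw$p_ref) & (is.na(pref) |
                                                         pref < 0 | pref > 1))
  if (any(bad))
    warning("rejected ", sum(bad), " malformed row(s) at line(s): ",
            paste(which(bad) + 1L, collapse = ", "))
  if (!any(!bad)) stop("no valid rows in ", path)
  keep <- which(!bad)
  out <- data.frame(snp_id = raw$snp_id[keep], y = beta[keep],
                    v = v[keep], stringsAsFactors = FALSE)
  if (!is.null(daf)) out$daf <- daf[keep]
  if (!is.null(pref)) out$p_ref <- pref[keep]
  if ("stratum" %in% names(raw)) out$stratum <- raw$stratum[keep]
  if (anyDuplicated(out$snp_id))
    stop("duplicate snp_id values in ", path)
  .checkSumstats(out)
  out
}

#' Write a summary-statistics TSV
#'
#' Inverse of [readSumstats()]: writes `snp_id`, `beta`, `var` and any
#' optional columns, with `.` for missing values.
#'
#' @param data summary-statistics data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSumstats <- function(data, path) {
  .checkSumstats(data)
  out <- data.frame(snp_id = data$snp_id, beta = data$y, var = data$v,
                    stringsAsFactors = FALSE)
  for (col in c("daf", "p_ref", "stratum"))
    if (!is.null(data[[col]])) out[[col]] <- data[[col]]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}

#' Read a pairwise LD table
#'
#' Three tab-separated columns `SNP_A`, `SNP_B`, `R2` (PLINK `.ld`-like;
#' pairs below the pruning threshold may be omitted by the producer).
#'
#' @param path file to read.
#' @return data.frame with columns `SNP_A`, `SNP_B`, `R2`.
#' @export
readLdPairs <- function(path) {
  ld <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("SNP_A", "SNP_B", "R2")
  if (!all(need %in% names(ld)))
    stop("LD table needs columns SNP_A, SNP_B, R2")
  if (!is.numeric(ld$R2) || any(!is.finite(ld$R2) | ld$R2 < 0 | ld$R2 > 1))
    stop("R2 values must be numeric in [0, 1]")
  ld[need]
}

# Internal: adjacency list over SNPs for pairs with R2 > threshold.
.ldAdjacency <- function(ids, ldPairs, r2Threshold) {
  adj <- vector("list", length(ids))
  names(adj) <- ids
  if (is.null(ldPairs) || nrow(ldPairs) == 0L) return(adj)
  sel <- ldPairs$R2 > r2Threshold &
    ldPairs$SNP_A %in% ids & ldPairs$SNP_B %in% ids
  a <- c(ldPairs$SNP_A[sel], ldPairs$SNP_B[sel])
  b <- c(ldPairs$SNP_B[sel], ldPairs$SNP_A[sel])
  for (nm in unique(a)) adj[[nm]] <- character(0)
  sp <- split(b, a)
  for (nm in names(sp)) adj[[nm]] <- unique(sp[[nm]])
  adj
}

# Internal greedy pruner: walk candidates in `order`; keep a SNP unless a
# previously kept SNP removed it; on keeping, remove all its r2>threshold
# neighbours. Equivalent to repeatedly selecting the best remaining SNP.
.greedyPrune <- function(ids, order, adj) {
  removed <- setNames(logical(length(ids)), ids)
  kept <- character(0)
  for (id in order) {
    if (removed[[id]]) next
    kept <- c(kept, id)
    nb <- adj[[id]]
    if (length(nb)) removed[nb] <- TRUE
  }
  kept
}

#' P-value-based LD pruning
#'
#' Greedy clumping: repeatedly select the remaining SNP with the lowest
#' reference-GWAS P-value into the pruned set and remove every remaining
#' SNP in LD (`r2 > r2Threshold`) with it, until no SNPs remain. SNPs
#' absent from the LD table are treated as unlinked. Using an independent
#' reference GWAS for the P-values corrects the selection for the winner's
#' curse in the analyzed GWAS.
#'
#' @param data summary-statistics data.frame with a `p_ref` column; SNPs
#'   missing `p_ref` are excluded with a warning.
#' @param ldPairs data.frame `SNP_A`, `SNP_B`, `R2` (see [readLdPairs()]),
#'   or `NULL` for no LD.
#' @param r2Threshold LD threshold; pairs strictly above it are linked.
#' @return character vector of kept `snp_id`s in selection order.
#' @examples
#' ss <- sumstats(c("A", "B", "C"), beta = c(0.2, 0.1, 0),
#'                se = c(0.05, 0.05, 0.05), p_ref = c(1e-8, 1e-3, 0.5))
#' ld <- data.frame(SNP_A = "A", SNP_B = "B", R2 = 0.5)
#' pvaluePrune(ss, ld)  # "A" "C"
#' @export
pvaluePrune <- function(data, ldPairs = NULL, r2Threshold = 0.1) {
  .checkSumstats(data, requirePref = TRUE)
  miss <- is.na(data$p_ref)
  if (any(miss))
    warning(sum(miss), " SNP(s) lack a reference P-value; excluded")
  data <- data[!miss, , drop = FALSE]
  if (nrow(data) == 0L) return(character(0))
  ord <- data$snp_id[order(data$p_ref, data$snp_id)]
  adj <- .ldAdjacency(data$snp_id, ldPairs, r2Threshold)
  .greedyPrune(data$snp_id, ord, adj)
}

#' Random LD pruning
#'
#' As [pvaluePrune()] but SNPs enter in uniform-random order, irrespective
#' of association strength, so the pruned set is a random maximal
#' independent set of the `r2 > r2Threshold` LD graph.
#'
#' @inheritParams pvaluePrune
#' @param seed integer seed for the selection order.
#' @return character vector of kept `snp_id`s in selection order.
#' @export
randomPrune <- function(data, ldPairs = NULL, r2Threshold = 0.1,
                        seed = NULL) {
  .checkSumstats(data)
  if (!is.null(seed)) set.seed(seed)
  ord <- sample(data$snp_id)
  adj <- .ldAdjacency(data$snp_id, ldPairs, r2Threshold)
  .greedyPrune(data$snp_id, ord, adj)
}

#' Assign derived-allele-frequency bins
#'
#' Equal-width bins over (0, 1\] with right-closed edges: bin k covers
#' \eqn{((k-1)/n, k/n]}, so with the default five bins the labels follow
#' the convention "DAF <= 0.2", ..., "DAF > 0.8".
#'
#' @param data summary-statistics data.frame with a `daf` column.
#' @param nBins number of bins.
#' @return factor of length `nrow(data)` with levels `DAF_bin_1` ...
#'   `DAF_bin_<nBins>`; `NA` (with a warning) where `daf` is missing.
#' @examples
#' ss <- sumstats(c("a", "b"), beta = c(0, 0), se = c(1, 1),
#'                daf = c(0.15, 0.2))
#' dafBins(ss)  # both DAF_bin_1 (edges are right-closed)
#' @export
dafBins <- function(data, nBins = 5L) {
  .checkSumstats(data, requireDaf = TRUE)
  if (any(is.na(data$daf)))
    warning(sum(is.na(data$daf)),
            " SNP(s) lack a derived allele frequency; unassigned")
  k <- ceiling(data$daf * nBins)
  k[!is.na(k)] <- pmin(pmax(k[!is.na(k)], 1L), nBins)
  factor(paste0("DAF_bin_", k), levels = paste0("DAF_bin_", seq_len(nBins)))
}

#' Fit the mixture model independently within strata
#'
#' Splits the data by stratum labels, fits the full three-stage EM in each
#' stratum with at least `floorN` SNPs (smaller strata are skipped with a
#' warning), and reports per-stratum \eqn{\hat\pi}, mean per-SNP
#' liability-scale variance (when `K` is given and frequencies are
#' present), and the fitted mass curves \eqn{\hat\pi \times \hat g}. The
#' ratio of per-SNP mean variances between two strata is their fold
#' enrichment.
#'
#' @inheritParams sphmmFit
#' @param strata vector of stratum labels, one per SNP (defaults to the
#'   data's `stratum` column).
#' @param K optional disease prevalence; enables per-stratum variance.
#' @param floorN minimum SNPs per fitted stratum.
#' @param pruned set to `FALSE` when the strata were not LD-pruned; a
#'   message then records that the model's independence assumption is
#'   relaxed (estimates on unpruned panels tend to be close, but the
#'   likelihood is no longer exactly that of independent SNPs).
#' @return list with `fits` (named list of [SphmmFit-class]), `table`
#'   (per-stratum `stratum`, `n`, `pi_hat`, `mean_v_hat`), and `pixg`
#'   (matrix of per-stratum \eqn{\hat\pi \hat p_b} curves).
#' @export
stratifiedFit <- function(data, strata = data$stratum,
                          config = fitConfig(), K = NULL, floorN = 100L,
                          pruned = TRUE) {
  .checkSumstats(data)
  if (!pruned)
    message("fitting unpruned strata: the independence assumption over ",
            "SNPs is relaxed")
  if (is.null(strata)) stop("no stratum labels supplied")
  if (length(strata) != nrow(data))
    stop("strata must have one label per SNP")
  pieces <- split(data, strata, drop = TRUE)
  fits <- list()
  rows <- list()
  grid <- effectGrid(config$gridLo, config$gridHi, config$gridStep)
  pixg <- matrix(NA_real_, length(grid), 0)
  for (nm in names(pieces)) {
    d <- pieces[[nm]]
    if (nrow(d) < floorN) {
      warning("stratum '", nm, "' has ", nrow(d), " SNPs (< ", floorN,
              "); skipped")
      next
    }
    fit <- sphmmFit(d, config)
    fits[[nm]] <- fit
    meanV <- if (!is.null(K) && !is.null(d$daf) && any(!is.na(d$daf))) {
      rep <- totalLiabilityVariance(d[!is.na(d$daf), , drop = FALSE],
                                    fit, K)
      rep$Vhat / rep$nUsed
    } else NA_real_
    rows[[nm]] <- data.frame(stratum = nm, n = nrow(d),
                             pi_hat = priorPi(fit), mean_v_hat = meanV,
                             stringsAsFactors = FALSE)
    pixg <- cbind(pixg, priorPi(fit) * priorMasses(fit))
    colnames(pixg)[ncol(pixg)] <- nm
  }
  if (!length(fits)) stop("no stratum reached the size floor of ", floorN)
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  rownames(pixg) <- format(gridPoints(grid))
  list(fits = fits, table = tab, pixg = pixg)
}
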