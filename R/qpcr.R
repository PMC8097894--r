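#' qPCR threshold-cycle table
#'
#' Couples a gene-by-sample Ct matrix with its sample conditions, the
#' housekeeping genes used for normalization (at least two), the reference
#' condition (fold change 1 by construction) and the amplification
#' efficiency (factor per cycle, classically 2).
#'
#' @param ct numeric matrix with genes as rows and samples as columns,
#'   both dimnames set. `NA` entries are treated as missing measurements
#'   and dropped per gene-sample pair, never imputed.
#' @param conditions character vector, one condition per sample (column).
#' @param hk_genes housekeeping gene ids (>= 2, subset of the row names).
#' @param reference the reference condition; must appear in `conditions`.
#' @param efficiency amplification factor per cycle (> 1, default 2).
#' @return Object of class `ct_table`.
#' @export
ct_table <- function(ct, conditions, hk_genes, reference, efficiency = 2) {
  ct <- as.matrix(ct)
  if (is.null(rownames(ct)) || is.null(colnames(ct)))
    stop("`ct` must have gene row names and sample column names")
  if (length(conditions) != ncol(ct))
    stop("one condition per sample (column) is required")
  if (length(unique(hk_genes)) < 2L)
    stop("at least two housekeeping genes are required")
  if (!all(hk_genes %in% rownames(ct)))
    stop("`hk_genes` must be a subset of the gene row names")
  if (!reference %in% conditions)
    stop("`reference` must be one of `conditions`")
  if (length(reference) != 1L)
    stop("exactly one reference condition must be designated")
  if (!is.numeric(efficiency) || efficiency <= 1)
    stop("`efficiency` must be > 1")
  if (any(!is.finite(ct) & !is.na(ct)))
    stop("Ct values must be finite or NA")
  structure(list(ct = ct, genes = rownames(ct), samples = colnames(ct),
                 conditions = as.character(conditions),
                 hk_genes = as.character(hk_genes),
                 reference = reference, efficiency = efficiency),
            class = "ct_table")
}

#' @export
print.ct_table <- function(x, ...) {
  cat(sprintf(paste0("<ct_table> %d genes x %d samples | conditions: %s | ",
                     "housekeeping: %s | reference: %s | efficiency %g\n"),
              nrow(x$ct), ncol(x$ct),
              paste(unique(x$conditions), collapse = ", "),
              paste(x$hk_genes, collapse = ", "), x$reference,
              x$efficiency))
  invisible(x)
}

#' Relative quantities from Ct values
#'
#' For each gene, `Q = efficiency^(calibrator_ct - ct)` with the calibrator
#' taken per gene as its minimum Ct across samples (so the most expressing
#' sample has Q = 1), or the mean Ct when `calibrator = "mean"`. Missing Ct
#' values yield missing Q values.
#'
#' @param tab a [ct_table()].
#' @param calibrator `"min"` (default) or `"mean"` per-gene calibrator Ct.
#' @return Numeric matrix of relative quantities, same shape as the Ct
#'   matrix.
#' @export
relative_quantity <- function(tab, calibrator = c("min", "mean")) {
  stopifnot(inherits(tab, "ct_table"))
  calibrator <- match.arg(calibrator)
  cal <- apply(tab$ct, 1L, function(r)
    if (calibrator == "min") min(r, na.rm = TRUE) else mean(r, na.rm = TRUE))
  tab$efficiency^(cal - tab$ct)
}

#' geNorm normalization factor per sample
#'
#' The geometric mean of the housekeeping genes' relative quantities in
#' each sample. Samples in which any housekeeping gene is missing get an
#' `NA` factor, with a warning of class `myoquant_undefined_warning`.
#'
#' @param tab a [ct_table()].
#' @param Q optional precomputed [relative_quantity()] matrix.
#' @param calibrator passed to [relative_quantity()] when `Q` is NULL.
#' @return Named numeric vector, one normalization factor per sample.
#' @export
normalization_factor <- function(tab, Q = NULL, calibrator = "min") {
  stopifnot(inherits(tab, "ct_table"))
  if (is.null(Q)) Q <- relative_quantity(tab, calibrator)
  hk <- Q[tab$hk_genes, , drop = FALSE]
  nf <- exp(colMeans(log(hk)))
  if (anyNA(nf))
    warn_undefined(sprintf(
      "normalization factor undefined for sample(s): %s",
      paste(colnames(Q)[is.na(nf)], collapse = ", ")))
  nf
}

#' geNorm fold changes relative to the reference condition
#'
#' Each gene-sample relative quantity is divided by the sample's
#' normalization factor; normalized quantities are averaged per condition
#' and divided by the reference-condition mean, so the reference fold
#' change is exactly 1. The SEM is computed over the per-sample normalized
#' quantities on the fold-change scale.
#'
#' @param tab a [ct_table()].
#' @param calibrator per-gene calibrator choice (see [relative_quantity()]).
#' @return data.frame of class `fold_change_result` with `gene`,
#'   `condition`, `fold_change`, `sem`, `n` (samples used). Errors when a
#'   reference mean is zero or not computable.
#' @export
fold_change <- function(tab, calibrator = "min") {
  stopifnot(inherits(tab, "ct_table"))
  Q <- relative_quantity(tab, calibrator)
  NF <- normalization_factor(tab, Q = Q)
  norm <- sweep(Q, 2L, NF, "/")
  conds <- unique(tab$conditions)
  if (sum(tab$conditions == tab$reference) < 1L)
    stop("reference condition has no samples")
  rows <- list()
  for (g in tab$genes) {
    by_cond <- lapply(conds, function(cc) {
      v <- norm[g, tab$conditions == cc]
      v[!is.na(v)]
    })
    names(by_cond) <- conds
    ref_mean <- mean(by_cond[[tab$reference]])
    if (!is.finite(ref_mean) || ref_mean <= 0)
      stop(sprintf("reference-condition mean is zero or missing for gene %s",
                   g))
    for (cc in conds) {
      v <- by_cond[[cc]] / ref_mean
      n <- length(v)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, condition = cc,
        fold_change = if (n > 0L) mean(v) else NA_real_,
        sem = if (n > 1L) stats::sd(v) / sqrt(n) else NA_real_,
        n = n)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("fold_change_result", "data.frame")
  out
}

#' geNorm expression-stability measure M (diagnostic)
#'
#' For each gene in the candidate set, M is the mean, over all other
#' candidates, of the standard deviation across samples of the pairwise
#' log2 expression ratio. Lower M means more stable expression. This is a
#' diagnostic only: the housekeeping genes used for normalization are
#' fixed by the `ct_table`, not selected by ranking.
#'
#' @param tab a [ct_table()].
#' @param genes candidate genes (default: the table's housekeeping genes).
#' @param calibrator passed to [relative_quantity()].
#' @return Named numeric vector of M values.
#' @export
genorm_stability <- function(tab, genes = tab$hk_genes, calibrator = "min") {
  stopifnot(inherits(tab, "ct_table"), length(genes) >= 2L,
            all(genes %in% tab$genes))
  Q <- relative_quantity(tab, calibrator)[genes, , drop = FALSE]
  lg <- log2(Q)
  m <- vapply(seq_along(genes), function(j) {
    others <- setdiff(seq_along(genes), j)
    mean(vapply(others, function(k)
      stats::sd(lg[j, ] - lg[k, ], na.rm = TRUE), numeric(1)))
  }, numeric(1))
  stats::setNames(m, genes)
}
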