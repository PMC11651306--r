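# Group-level statistics: exact proportion tests, mean +/- SEM summaries,
# Benjamini-Hochberg adjustment, and the RNA-seq TPM filtering/transform
# rules.

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact conditional test with fixed margins: the two-sided p-value sums
#' the probabilities of all hypergeometric tables no more likely than the
#' observed one (no normal approximation). Rows are groups, columns
#' responder/non-responder counts. A table with an empty margin is
#' degenerate: p = 1 by convention, flagged.
#'
#' @param table 2x2 matrix of non-negative integer counts
#' @return list: `p` (two-sided), `degenerate`
#' @examples
#' fisher_exact_2x2(matrix(c(9, 2, 2, 10), 2, byrow = TRUE))$p  # 0.0033
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("need a 2x2 table")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    return(list(p = 1, degenerate = TRUE))
  list(p = stats::fisher.test(table)$p.value, degenerate = FALSE)
}

#' Proportion as a percentage
#'
#' `100 * k / n`, with the reporting convention used for responder rates
#' (nearest integer) or one decimal place.
#'
#' @param k,n numerator and denominator (n > 0)
#' @param digits decimal places of the printed percentage
#' @return percentage
#' @examples
#' proportion(29, 36)              # 81
#' proportion(36, 57, digits = 1)  # 63.2
#' @export
proportion <- function(k, n, digits = 0) {
  if (n <= 0) stop("denominator must be positive")
  round(100 * k / n, digits)
}

#' Mean, SEM and n per metric and group
#'
#' Summary-table statistics (mean +/- standard error of the mean). Cells
#' excluded by the resting-potential rule are dropped before any group
#' statistic; single-cell groups report the mean with SEM flagged absent.
#'
#' @param cells per-cell data.frame with a `group` column (and optionally
#'   `included`)
#' @param metrics character vector of metric column names
#' @param groups group labels to summarize (default: all present)
#' @return data.frame: `metric`, `group`, `mean`, `sem`, `n`
#' @export
summarize_groups <- function(cells, metrics, groups = NULL) {
  if (is.null(groups)) groups <- unique(cells$group)
  if (!all(groups %in% cells$group))
    stop("unknown group label(s): ",
         paste(setdiff(groups, cells$group), collapse = ", "))
  if ("included" %in% names(cells)) cells <- cells[!isFALSE(cells$included) &
                                                    (is.na(cells$included) | cells$included), ]
  out <- expand.grid(metric = metrics, group = groups,
                     stringsAsFactors = FALSE)
  out$mean <- NA_real_; out$sem <- NA_real_; out$n <- NA_integer_
  for (r in seq_len(nrow(out))) {
    x <- cells[cells$group == out$group[r], out$metric[r]]
    x <- x[!is.na(x)]
    out$n[r] <- length(x)
    if (length(x)) out$mean[r] <- mean(x)
    if (length(x) >= 2) out$sem[r] <- stats::sd(x) / sqrt(length(x))
  }
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjusted p-values, capped at 1, invariant
#' to input order.
#'
#' @param p vector of p-values in `[0, 1]`
#' @return adjusted p-values in the input order
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' TPM expression matrix
#'
#' Gene-by-sample transcripts-per-million table with a sample-to-group map
#' and per-gene protein-coding flags.
#'
#' @param tpm numeric matrix, genes x samples, non-negative
#' @param groups factor/character of length `ncol(tpm)` mapping samples to
#'   treatment groups
#' @param protein_coding logical per gene (default all TRUE)
#' @return a `tpm_matrix` list
#' @export
tpm_matrix <- function(tpm, groups, protein_coding = NULL) {
  tpm <- as.matrix(tpm)
  if (any(tpm < 0)) stop("TPM values must be non-negative")
  if (length(groups) != ncol(tpm))
    stop("one group label per sample required")
  if (any(table(groups) == 0)) stop("every group needs at least one sample")
  if (is.null(protein_coding)) protein_coding <- rep(TRUE, nrow(tpm))
  if (length(protein_coding) != nrow(tpm))
    stop("one protein-coding flag per gene required")
  structure(list(tpm = tpm, groups = as.character(groups),
                 protein_coding = protein_coding),
            class = "tpm_matrix")
}

#' Expression filter and protein-coding renormalization
#'
#' A gene counts as expressed only if, in at least one treatment group,
#' every sample of that group has TPM above the detection level (0.2).
#' When `renormalize` is on, each sample's protein-coding TPMs are first
#' rescaled to sum to one million over protein-coding genes (the
#' protein-coding TPM convention), and non-coding genes are dropped,
#' before the filter is applied.
#'
#' @param x a [tpm_matrix]
#' @param threshold detection level, default 0.2 TPM
#' @param renormalize rescale protein-coding TPMs to 1e6 per sample first
#' @return list: `kept` (gene names/indices), `matrix` (filtered, possibly
#'   renormalized TPM matrix), `expressed` (per-gene logical on the input)
#' @export
filter_expressed_genes <- function(x, threshold = 0.2, renormalize = FALSE) {
  stopifnot(inherits(x, "tpm_matrix"))
  tpm <- x$tpm
  if (renormalize) {
    tpm <- tpm[x$protein_coding, , drop = FALSE]
    tpm <- sweep(tpm, 2, colSums(tpm), "/") * 1e6
  }
  grp <- split(seq_len(ncol(tpm)), x$groups)
  expressed <- apply(tpm, 1, function(g)
    any(vapply(grp, function(j) all(g[j] > threshold), TRUE)))
  kept <- rownames(tpm)
  if (is.null(kept)) kept <- which(expressed) else kept <- kept[expressed]
  list(kept = kept, matrix = tpm[expressed, , drop = FALSE],
       expressed = expressed)
}

#' Offset log transform for TPM values
#'
#' `log2(TPM + 0.2)`: the detection level is added before the log so
#' unexpressed genes map to a finite floor. Base 2 is this package's
#' convention.
#'
#' @param tpm non-negative TPM values
#' @param offset detection level added before the log
#' @return transformed values
#' @export
log_tpm <- function(tpm, offset = 0.2) {
  if (any(tpm < 0)) stop("TPM values must be non-negative")
  log2(tpm + offset)
}
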