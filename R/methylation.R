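#' Copy-number to methylation coupling per gene
#'
#' Pearson correlation of each gene's CNV log-ratio row with its
#' methylation beta values. Genes may carry several probes; the
#' \code{probe_policy} controls how they are summarized:
#' \code{"best_abs"} keeps the probe with the largest absolute
#' correlation, \code{"mean_beta"} averages betas across the gene's
#' probes before correlating, and \code{"per_probe"} emits one record per
#' probe. The policies agree exactly for single-probe genes.
#'
#' @param cohort an \linkS4class{OncoCohort} with methylation.
#' @param gene_set genes to evaluate (default: all genes with a probe).
#' @param probe_policy probe summarization policy.
#' @param min_pairs minimum paired observations; below it the record is
#'   dropped.
#' @return data.frame with columns \code{gene}, \code{probe},
#'   \code{n_probes}, \code{cnv_meth_r}. Genes without mapped probes or
#'   with zero variance are excluded.
#' @export
cnvMethylationCorrelation <- function(cohort, gene_set = NULL,
                                      probe_policy = c("best_abs",
                                                       "mean_beta",
                                                       "per_probe"),
                                      min_pairs = 10) {
  probe_policy <- match.arg(probe_policy)
  beta <- methMatrix(cohort)
  if (is.null(beta)) stop("cohort has no methylation layer")
  pm <- probeMap(cohort)
  pm <- pm[pm$probe %in% rownames(beta) &
             pm$gene %in% cohortGenes(cohort), , drop = FALSE]
  if (is.null(gene_set)) gene_set <- unique(pm$gene)
  pm <- pm[pm$gene %in% gene_set, , drop = FALSE]
  cnv <- cnvMatrix(cohort)

  pairCor <- function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < min_pairs) return(NA_real_)
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
    stats::cor(x[ok], y[ok])
  }

  rows <- lapply(unique(pm$gene), function(g) {
    probes <- pm$probe[pm$gene == g]
    x <- cnv[g, ]
    if (probe_policy == "mean_beta") {
      b <- if (length(probes) == 1) beta[probes, ] else
        colMeans(beta[probes, , drop = FALSE], na.rm = TRUE)
      r <- pairCor(x, b)
      data.frame(gene = g, probe = paste(probes, collapse = ";"),
                 n_probes = length(probes), cnv_meth_r = r,
                 stringsAsFactors = FALSE)
    } else {
      r <- vapply(probes, function(p) pairCor(x, beta[p, ]), numeric(1))
      if (probe_policy == "per_probe")
        data.frame(gene = g, probe = probes, n_probes = length(probes),
                   cnv_meth_r = unname(r), stringsAsFactors = FALSE)
      else {
        if (all(is.na(r)))
          data.frame(gene = g, probe = probes[1],
                     n_probes = length(probes), cnv_meth_r = NA_real_,
                     stringsAsFactors = FALSE)
        else {
          best <- which.max(abs(r))
          data.frame(gene = g, probe = probes[best],
                     n_probes = length(probes),
                     cnv_meth_r = unname(r[best]),
                     stringsAsFactors = FALSE)
        }
      }
    }
  })
  out <- do.call(rbind, rows)
  out[!is.na(out$cnv_meth_r), , drop = FALSE]
}

#' Coherence of methylation coupling with dosage coupling
#'
#' Spearman rank correlation, and ordinary least-squares slope, of the
#' per-gene CNV-methylation correlation (response) on the per-gene
#' CNV-mRNA correlation (predictor). A negative coherence reflects
#' methylation compensation: amplified dosage-coupled genes lose
#' methylation while amplified uncoupled genes gain it.
#'
#' @param meth_r named per-gene CNV-methylation correlations (or the
#'   data.frame from \code{\link{cnvMethylationCorrelation}}).
#' @param mrna_r named per-gene CNV-mRNA correlations.
#' @return list with \code{spearman_rho}, \code{ols_slope}, \code{n}.
#' @export
methylationCoherence <- function(meth_r, mrna_r) {
  if (is.data.frame(meth_r)) {
    v <- meth_r$cnv_meth_r
    names(v) <- meth_r$gene
    meth_r <- v
  }
  shared <- intersect(names(meth_r), names(mrna_r))
  a <- meth_r[shared]; b <- mrna_r[shared]
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 10) stop("fewer than 10 genes with both correlations")
  a <- a[ok]; b <- b[ok]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("degenerate variance in correlation vectors")
  list(spearman_rho = stats::cor(a, b, method = "spearman"),
       ols_slope = unname(stats::coef(stats::lm(a ~ b))[2]),
       n = sum(ok))
}

# two-sided Mann-Whitney p by full enumeration of group assignments,
# valid under ties (average ranks); used when the enumeration is small
exactRankSumP <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  rk <- rank(c(x, y))
  obs <- sum(rk[seq_len(n1)])
  combos <- utils::combn(n, n1)
  sums <- colSums(matrix(rk[combos], nrow = n1))
  dev <- abs(sums - n1 * (n + 1) / 2)
  mean(dev >= abs(obs - n1 * (n + 1) / 2) - 1e-12)
}

#' Compare beta values between copy-gain and 2N samples
#'
#' Splits samples at one gene by copy-number status -- gain
#' (CNV log-ratio > 0.5) or, with \code{side = "loss"}, hemizygous loss
#' (CNV < -0.5) -- against 2N samples (|CNV| <= 0.5), and compares the
#' probe's beta values with a two-sided Mann-Whitney test.
#'
#' @param cohort an \linkS4class{OncoCohort} with methylation.
#' @param gene gene identifier.
#' @param probe probe identifier; default: the gene's first mapped probe.
#' @param side compare the gain group or the loss group against 2N.
#' @param min_group minimum samples required in each group.
#' @param alpha significance level for calling a direction.
#' @param exact_limit use the exact enumeration null (valid under ties)
#'   when \code{choose(n1+n2, n1)} does not exceed this; larger groups
#'   fall back to \code{\link[stats]{wilcox.test}}.
#' @return one-row data.frame: \code{gene}, \code{probe}, medians and
#'   IQRs of both groups, group sizes, \code{direction} (hyper/hypo/none,
#'   relative to 2N) and \code{p_value}.
#' @export
betaGainVs2N <- function(cohort, gene, probe = NULL,
                         side = c("gain", "loss"), min_group = 5,
                         alpha = 0.05, exact_limit = 2e5) {
  side <- match.arg(side)
  beta <- methMatrix(cohort)
  if (is.null(beta)) stop("cohort has no methylation layer")
  if (is.null(probe)) {
    pm <- probeMap(cohort)
    probe <- pm$probe[pm$gene == gene][1]
    if (is.na(probe)) stop("no probe mapped to gene ", gene)
  }
  x <- cnvMatrix(cohort)[gene, ]
  grp <- if (side == "gain") which(!is.na(x) & x > 0.5) else
    which(!is.na(x) & x < -0.5)
  ref <- which(!is.na(x) & abs(x) <= 0.5)
  b_grp <- beta[probe, grp]; b_grp <- b_grp[!is.na(b_grp)]
  b_ref <- beta[probe, ref]; b_ref <- b_ref[!is.na(b_ref)]
  if (length(b_grp) < min_group || length(b_ref) < min_group)
    stop("fewer than ", min_group, " samples in a group")
  p_value <- if (choose(length(b_grp) + length(b_ref),
                        length(b_grp)) <= exact_limit)
    exactRankSumP(b_grp, b_ref)
  else
    suppressWarnings(stats::wilcox.test(b_grp, b_ref)$p.value)
  direction <- if (p_value < alpha) {
    if (stats::median(b_grp) > stats::median(b_ref)) "hyper"
    else if (stats::median(b_grp) < stats::median(b_ref)) "hypo"
    else "none"
  } else "none"
  wt <- list(p.value = p_value)
  data.frame(gene = gene, probe = probe, side = side,
             n_2N = length(b_ref), n_cn = length(b_grp),
             beta_2N_median = stats::median(b_ref),
             beta_2N_iqr = stats::IQR(b_ref),
             beta_cn_median = stats::median(b_grp),
             beta_cn_iqr = stats::IQR(b_grp),
             direction = direction, p_value = wt$p.value,
             stringsAsFactors = FALSE)
}
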