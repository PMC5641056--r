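#' Per-gene dosage correlation
#'
#' For each gene, the Pearson correlation across samples of its own
#' copy-number log-ratio with its own log2(count+1) expression. This is
#' the quantity whose bimodal genome-wide distribution separates
#' dosage-coupled (CR-high) from dosage-uncoupled (CR-low) genes.
#'
#' @param cohort an \linkS4class{OncoCohort} with expression.
#' @param gene_set genes to evaluate (default: all cohort genes).
#' @param min_pairs minimum paired non-missing observations per gene;
#'   genes below it, or with zero variance in either row, get \code{NA}.
#' @return named numeric vector of correlations over \code{gene_set}.
#' @export
perGeneDosageCorrelation <- function(cohort, gene_set = NULL,
                                     min_pairs = 10) {
  if (is.null(exprMatrix(cohort))) stop("cohort has no expression layer")
  if (is.null(gene_set)) gene_set <- cohortGenes(cohort)
  x <- cnvMatrix(cohort)[gene_set, , drop = FALSE]
  y <- log2(exprMatrix(cohort)[gene_set, , drop = FALSE] + 1)
  ok <- !is.na(x) & !is.na(y)
  x[!ok] <- NA; y[!ok] <- NA
  n <- rowSums(ok)
  cx <- x - rowMeans(x, na.rm = TRUE)
  cy <- y - rowMeans(y, na.rm = TRUE)
  r <- rowSums(cx * cy, na.rm = TRUE) /
    sqrt(rowSums(cx^2, na.rm = TRUE) * rowSums(cy^2, na.rm = TRUE))
  r[!is.finite(r) | n < min_pairs] <- NA_real_
  names(r) <- gene_set
  r
}

#' Locate the valley between the two modes of a correlation density
#'
#' Fits a Gaussian kernel density (Silverman rule-of-thumb bandwidth) on a
#' 512-point grid over \code{[-1, 1]}, takes the two highest-density local
#' maxima, and returns the grid location of the minimum density strictly
#' between them. If fewer than two local maxima exist, if the lesser of
#' the two hills does not rise above the valley by the prominence factor
#' (which rejects noise wiggles on a unimodal density), or if the valley
#' lies outside the admissible window, the fixed fallback is returned
#' with a warning.
#'
#' @param r_values numeric vector of per-gene correlations (NAs dropped);
#'   at least 50 values required.
#' @param fallback cutoff used when no admissible valley is found.
#' @param window admissible interval for the valley.
#' @param min_prominence required ratio of the lower peak density to the
#'   valley density for the two hills to count as distinct.
#' @return list with \code{cutoff} and \code{source} (\code{"valley"} or
#'   \code{"fallback"}).
#' @export
findValleyCutoff <- function(r_values, fallback = 0.4,
                             window = c(0.0, 0.8),
                             min_prominence = 1.1) {
  r <- r_values[is.finite(r_values)]
  if (length(r) < 50) stop("need at least 50 correlation values")
  d <- stats::density(r, bw = "nrd0", n = 512, from = -1, to = 1)
  y <- d$y
  ix <- which(y[2:511] > y[1:510] & y[2:511] > y[3:512]) + 1
  if (length(ix) < 2) {
    warning("fewer than two density modes; using fallback cutoff")
    return(list(cutoff = fallback, source = "fallback"))
  }
  top2 <- ix[order(y[ix], decreasing = TRUE)[1:2]]
  lo <- min(top2); hi <- max(top2)
  between <- (lo + 1):(hi - 1)
  valley <- between[which.min(y[between])]
  cutoff <- d$x[valley]
  if (min(y[top2]) < min_prominence * y[valley]) {
    warning("density modes are not distinct; using fallback cutoff")
    return(list(cutoff = fallback, source = "fallback"))
  }
  if (cutoff < window[1] || cutoff > window[2]) {
    warning("valley outside admissible window; using fallback cutoff")
    return(list(cutoff = fallback, source = "fallback"))
  }
  list(cutoff = cutoff, source = "valley")
}

#' Classify genes into CR-high and CR-low
#'
#' Strictly above the cutoff is CR-high; at or below is CR-low; missing
#' correlations are excluded.
#'
#' @param r_values named numeric vector of per-gene CNV-mRNA correlations.
#' @param cutoff finite correlation cutoff.
#' @param cutoff_source provenance recorded in the result
#'   (\code{"valley"}, \code{"fallback"} or \code{"fixed"}).
#' @return A \linkS4class{CRClassification}.
#' @export
classifyCR <- function(r_values, cutoff, cutoff_source = "fixed") {
  stopifnot(is.finite(cutoff))
  label <- ifelse(is.na(r_values), "excluded",
                  ifelse(r_values > cutoff, "CR-high", "CR-low"))
  tab <- data.frame(gene = names(r_values), r = as.numeric(r_values),
                    label = label, stringsAsFactors = FALSE,
                    row.names = NULL)
  new("CRClassification", table = tab, cutoff = cutoff,
      cutoffSource = cutoff_source)
}

#' One-step CR classification of a cohort
#'
#' Computes per-gene dosage correlations, fits the valley cutoff (unless a
#' fixed cutoff is supplied) and labels the genes.
#'
#' @param cohort an \linkS4class{OncoCohort}.
#' @param gene_set genes to classify (default: all).
#' @param cutoff optional fixed cutoff; when \code{NULL} the valley of the
#'   correlation density is used, falling back to \code{fallback}.
#' @param fallback fallback cutoff for \code{\link{findValleyCutoff}}.
#' @return A \linkS4class{CRClassification}.
#' @export
crClassify <- function(cohort, gene_set = NULL, cutoff = NULL,
                       fallback = 0.4) {
  r <- perGeneDosageCorrelation(cohort, gene_set)
  if (is.null(cutoff)) {
    v <- findValleyCutoff(r, fallback = fallback)
    classifyCR(r, v$cutoff, v$source)
  } else {
    classifyCR(r, cutoff, "fixed")
  }
}
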