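#' GeneProfile: genome-wide association profile of an index oncogene
#'
#' Per-gene Pearson correlations (or their t-statistics) of an index
#' gene's copy-number log-ratio vector against every gene's row in one
#' data layer: its co-amplification profile (DNA level), co-expression
#' profile (mRNA level) or methylation profile.
#'
#' @slot indexGene identifier of the index oncogene.
#' @slot level one of \code{"DNA"}, \code{"mRNA"}, \code{"methylation"}.
#' @slot statistic \code{"pearson_r"} or \code{"t_statistic"}.
#' @slot values named numeric vector over genes; \code{NA} where fewer
#'   than the minimum paired observations or zero variance.
#' @aliases GeneProfile-class
#' @export
setClass("GeneProfile",
  representation(indexGene = "character", level = "character",
                 statistic = "character", values = "numeric"))

setValidity("GeneProfile", function(object) {
  msg <- character(0)
  if (!object@level %in% c("DNA", "mRNA", "methylation"))
    msg <- c(msg, "level must be DNA, mRNA or methylation")
  if (!object@statistic %in% c("pearson_r", "t_statistic"))
    msg <- c(msg, "statistic must be pearson_r or t_statistic")
  if (is.null(names(object@values)))
    msg <- c(msg, "values must be named by gene")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GeneProfile", function(object) {
  cat(sprintf("GeneProfile of %s at %s level: %d genes (%s)\n",
              object@indexGene, object@level, length(object@values),
              object@statistic))
})

#' @rdname GeneProfile-class
#' @param x a GeneProfile.
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))
#' @rdname GeneProfile-class
#' @export
setMethod("profileValues", "GeneProfile", function(x) x@values)

# row-wise Pearson correlation of one vector against each matrix row,
# pairwise-complete; rows with < min_pairs paired obs or zero variance -> NA
rowCorWithVector <- function(m, x, min_pairs = 10) {
  ok <- !is.na(m) & matrix(rep(!is.na(x), each = nrow(m)), nrow(m))
  mm <- m; mm[!ok] <- NA
  xx <- matrix(rep(x, each = nrow(m)), nrow(m)); xx[!ok] <- NA
  n <- rowSums(ok)
  cm <- mm - rowMeans(mm, na.rm = TRUE)
  cx <- xx - rowMeans(xx, na.rm = TRUE)
  r <- rowSums(cm * cx, na.rm = TRUE) /
    sqrt(rowSums(cm^2, na.rm = TRUE) * rowSums(cx^2, na.rm = TRUE))
  r[!is.finite(r) | n < min_pairs] <- NA_real_
  names(r) <- rownames(m)
  attr(r, "n_pairs") <- n
  r
}

# methylation betas summarized to gene level by averaging a gene's probes
geneLevelMeth <- function(cohort) {
  pm <- probeMap(cohort)
  beta <- methMatrix(cohort)
  if (is.null(beta)) stop("cohort has no methylation layer")
  pm <- pm[pm$probe %in% rownames(beta), , drop = FALSE]
  genes <- unique(pm$gene)
  out <- matrix(NA_real_, length(genes), ncol(beta),
                dimnames = list(genes, colnames(beta)))
  for (g in genes) {
    pr <- pm$probe[pm$gene == g]
    out[g, ] <- if (length(pr) == 1) beta[pr, ]
      else colMeans(beta[pr, , drop = FALSE], na.rm = TRUE)
  }
  out
}

#' Genome-wide association profile of an index gene's CNV
#'
#' Correlates the index gene's copy-number log-ratio across samples with
#' every gene's row in the chosen layer: CNV (co-amplification profile),
#' log2(count+1) expression (co-expression profile) or gene-level
#' methylation beta. Pairwise-complete Pearson; genes with zero variance
#' or fewer than \code{min_pairs} paired observations are \code{NA}.
#'
#' @param cohort an \linkS4class{OncoCohort}.
#' @param index_gene gene identifier with a non-constant CNV row.
#' @param level \code{"DNA"}, \code{"mRNA"} or \code{"methylation"}.
#' @param statistic report raw Pearson r, or its t-statistic
#'   \code{t = r * sqrt((n-2)/(1-r^2))}.
#' @param min_pairs minimum paired observations per gene.
#' @return A \linkS4class{GeneProfile}.
#' @export
associationProfile <- function(cohort, index_gene,
                               level = c("DNA", "mRNA", "methylation"),
                               statistic = c("pearson_r", "t_statistic"),
                               min_pairs = 10) {
  level <- match.arg(level)
  statistic <- match.arg(statistic)
  x <- cnvMatrix(cohort)[index_gene, ]
  if (stats::sd(x, na.rm = TRUE) == 0 || all(is.na(x)))
    stop("index gene has constant CNV")
  m <- switch(level,
    DNA = cnvMatrix(cohort),
    mRNA = {
      e <- exprMatrix(cohort)
      if (is.null(e)) stop("cohort has no expression layer")
      log2(e + 1)
    },
    methylation = geneLevelMeth(cohort))
  r <- rowCorWithVector(m, x, min_pairs)
  n <- attr(r, "n_pairs")
  vals <- if (statistic == "pearson_r") r
    else r * sqrt((n - 2) / (1 - r^2))
  vals <- as.numeric(vals)
  names(vals) <- rownames(m)
  new("GeneProfile", indexGene = index_gene, level = level,
      statistic = statistic, values = vals)
}

#' Concordance of two genome-wide profiles
#'
#' Pearson (or Spearman) correlation across genes of two association
#' profiles, pairwise-complete, with the index gene excluded.
#'
#' @param p1,p2 \linkS4class{GeneProfile} objects over the same gene
#'   universe (typically DNA vs mRNA level for one index gene).
#' @param method correlation method across genes.
#' @return numeric scalar.
#' @export
profileConcordance <- function(p1, p2, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  shared <- intersect(names(p1@values), names(p2@values))
  shared <- setdiff(shared, c(p1@indexGene, p2@indexGene))
  if (length(shared) < 3) stop("fewer than 3 shared genes")
  stats::cor(p1@values[shared], p2@values[shared], method = method,
             use = "pairwise.complete.obs")
}

#' Upper-tail hypergeometric enrichment probability
#'
#' Probability of observing at least \code{n_overlap} co-amplified genes
#' when drawing \code{n_overexpressed} genes without replacement from a
#' population of \code{n_population} genes of which
#' \code{n_coamplified} are co-amplified.
#'
#' @param n_population,n_coamplified,n_overexpressed,n_overlap
#'   non-negative integers with
#'   \code{n_overlap <= min(n_coamplified, n_overexpressed)}.
#' @return the tail probability in (0, 1].
#' @export
enrichmentPValue <- function(n_population, n_coamplified,
                             n_overexpressed, n_overlap) {
  stopifnot(n_overlap <= min(n_coamplified, n_overexpressed),
            n_coamplified <= n_population,
            n_overexpressed <= n_population)
  stats::phyper(n_overlap - 1, n_coamplified,
                n_population - n_coamplified, n_overexpressed,
                lower.tail = FALSE)
}

# vectorized Welch two-sample t-test per gene (rows) between sample groups
rowWelch <- function(m, group1, group2) {
  m1 <- rowMeans(m[, group1, drop = FALSE], na.rm = TRUE)
  m2 <- rowMeans(m[, group2, drop = FALSE], na.rm = TRUE)
  v1 <- apply(m[, group1, drop = FALSE], 1, stats::var, na.rm = TRUE)
  v2 <- apply(m[, group2, drop = FALSE], 1, stats::var, na.rm = TRUE)
  n1 <- rowSums(!is.na(m[, group1, drop = FALSE]))
  n2 <- rowSums(!is.na(m[, group2, drop = FALSE]))
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  data.frame(mean_diff = m1 - m2, t = t, df = df, p = p)
}

#' Enrichment of co-amplified genes among index-associated overexpression
#'
#' Splits samples by the index gene's copy-number gain (CNV log-ratio
#' > 0.5), finds genes overexpressed in the gain group (Welch t-test on
#' log2 counts at \code{P < overexpr_alpha} with higher mean in gain
#' samples), intersects them with the index gene's co-amplified set (DNA
#' profile r above \code{coamp_r_threshold}) and tests the overlap with
#' the upper-tail hypergeometric distribution.
#'
#' @param cohort an \linkS4class{OncoCohort} with expression.
#' @param index_gene index oncogene.
#' @param overexpr_alpha Welch t-test significance level.
#' @param coamp_r_threshold co-amplification correlation cutoff.
#' @param scope \code{"genome"} for all retained genes;
#'   \code{"trans_only"} drops genes on the index gene's chromosome.
#' @param gene_set optional gene universe (defaults to all cohort genes).
#' @param gain_threshold index CNV log-ratio defining a gain sample.
#' @return one-row data.frame with \code{n_population},
#'   \code{n_coamplified}, \code{n_overexpressed}, \code{n_overlap},
#'   \code{fraction}, \code{p_value}, \code{flagged}.
#' @export
coamplificationEnrichment <- function(cohort, index_gene,
                                      overexpr_alpha = 0.001,
                                      coamp_r_threshold = 0.4,
                                      scope = c("genome", "trans_only"),
                                      gene_set = NULL,
                                      gain_threshold = 0.5) {
  scope <- match.arg(scope)
  if (is.null(exprMatrix(cohort))) stop("cohort has no expression layer")
  x <- cnvMatrix(cohort)[index_gene, ]
  gain <- which(!is.na(x) & x > gain_threshold)
  rest <- which(!is.na(x) & x <= gain_threshold)
  if (length(gain) < 10)
    stop("index gene has fewer than 10 copy-gain samples")
  if (is.null(gene_set)) gene_set <- cohortGenes(cohort)
  gene_set <- setdiff(gene_set, index_gene)
  if (scope == "trans_only") {
    gr <- geneRanges(cohort)
    idx_chr <- as.character(GenomicRanges::seqnames(gr[index_gene]))
    gene_set <- gene_set[
      as.character(GenomicRanges::seqnames(gr[gene_set])) != idx_chr]
  }
  le <- log2(exprMatrix(cohort)[gene_set, , drop = FALSE] + 1)
  tt <- rowWelch(le, gain, rest)
  prof <- profileValues(
    associationProfile(cohort, index_gene, level = "DNA"))[gene_set]
  valid <- is.finite(tt$p) & !is.na(prof)
  pop <- gene_set[valid]
  over <- pop[tt$p[valid] < overexpr_alpha & tt$mean_diff[valid] > 0]
  coamp <- pop[prof[valid] > coamp_r_threshold]
  n_overlap <- length(intersect(over, coamp))
  flagged <- length(over) == 0
  p <- enrichmentPValue(length(pop), length(coamp), length(over),
                        n_overlap)
  data.frame(n_population = length(pop), n_coamplified = length(coamp),
             n_overexpressed = length(over), n_overlap = n_overlap,
             fraction = if (flagged) NA_real_ else
               n_overlap / length(over),
             p_value = p, flagged = flagged)
}
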