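#' Read a SEG-dialect segmentation table
#'
#' Expects the tab-separated header
#' \code{Sample Chromosome Start End Num_Probes Segment_Mean} with 1-based
#' inclusive coordinates; coordinates are stored 0-based half-open after
#' parsing.
#'
#' @param path path to the SEG file.
#' @return data.frame with columns \code{sample}, \code{chromosome},
#'   \code{start0}, \code{end0}, \code{segment_mean}.
#' @export
readSegments <- function(path) {
  seg <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("Sample", "Chromosome", "Start", "End", "Segment_Mean")
  if (!all(need %in% colnames(seg)))
    stop("SEG file missing columns: ",
         paste(setdiff(need, colnames(seg)), collapse = ", "))
  out <- data.frame(sample = as.character(seg$Sample),
                    chromosome = as.character(seg$Chromosome),
                    start0 = seg$Start - 1, end0 = seg$End,
                    segment_mean = seg$Segment_Mean,
                    stringsAsFactors = FALSE)
  if (any(out$start0 >= out$end0))
    stop("segments must satisfy start < end")
  if (any(!is.finite(out$segment_mean)))
    stop("segment means must be finite")
  out
}

#' Read gene coordinates from a BED file
#'
#' @param path BED file (0-based half-open) with at least 4 columns; the
#'   4th column supplies gene identifiers.
#' @return named \link[GenomicRanges]{GRanges}.
#' @export
readGeneBED <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (is.null(gr$name) || anyDuplicated(gr$name))
    stop("gene BED must carry unique names in column 4")
  names(gr) <- gr$name
  gr
}

#' Read a genes/probes x samples TSV matrix
#'
#' @param path TSV with a header row of sample identifiers; first column
#'   holds row identifiers.
#' @return numeric matrix with row and column names.
#' @export
readMatrixTSV <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Read the clinical outcome table
#'
#' @param path TSV with columns \code{sample}, \code{time_days},
#'   \code{event}.
#' @return data.frame.
#' @export
readClinical <- function(path) {
  cl <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "time_days", "event")
  if (!all(need %in% colnames(cl)))
    stop("clinical table missing columns: ",
         paste(setdiff(need, colnames(cl)), collapse = ", "))
  cl$sample <- as.character(cl$sample)
  cl
}

#' Read the probe-to-gene map
#'
#' @param path TSV with columns \code{probe}, \code{gene} (extra columns
#'   kept).
#' @return data.frame.
#' @export
readProbeMap <- function(path) {
  pm <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("probe", "gene") %in% colnames(pm)))
    stop("probe map needs columns 'probe' and 'gene'")
  pm
}

#' Map copy-number segments to gene-level log-ratios
#'
#' Each gene's value in a sample is the length-weighted mean of the segment
#' means over the bases of the gene body covered by that sample's segments.
#' Genes with no covered base in a sample get \code{NA}; these are excluded
#' pairwise from all downstream correlations. Overlapping segments within
#' one sample on the same chromosome are an error.
#'
#' @param segments data.frame as returned by \code{\link{readSegments}}.
#' @param genes named \link[GenomicRanges]{GRanges} of gene bodies.
#' @return gene x sample numeric matrix.
#' @export
mapSegmentsToGenes <- function(segments, genes) {
  if (is.null(names(genes)))
    stop("genes must be a named GRanges")
  samples <- unique(segments$sample)
  out <- matrix(NA_real_, length(genes), length(samples),
                dimnames = list(names(genes), samples))
  gene_chroms <- unique(as.character(GenomicRanges::seqnames(genes)))
  absent <- setdiff(gene_chroms, unique(segments$chromosome))
  if (length(absent))
    warning("no segmentation for chromosome(s): ",
            paste(absent, collapse = ", "),
            "; affected genes are all-missing")
  for (s in samples) {
    ss <- segments[segments$sample == s, , drop = FALSE]
    sgr <- GenomicRanges::GRanges(
      seqnames = ss$chromosome,
      ranges = IRanges::IRanges(start = ss$start0 + 1, end = ss$end0))
    self <- GenomicRanges::findOverlaps(sgr, drop.self = TRUE,
                                        drop.redundant = TRUE)
    if (length(self) > 0)
      stop("overlapping segments within sample ", s)
    hits <- GenomicRanges::findOverlaps(genes, sgr)
    if (length(hits) == 0) next
    ov <- GenomicRanges::pintersect(
      genes[S4Vectors::queryHits(hits)], sgr[S4Vectors::subjectHits(hits)])
    w <- GenomicRanges::width(ov)
    mean_seg <- ss$segment_mean[S4Vectors::subjectHits(hits)]
    num <- tapply(w * mean_seg, S4Vectors::queryHits(hits), sum)
    den <- tapply(w, S4Vectors::queryHits(hits), sum)
    out[as.integer(names(num)), s] <- as.numeric(num / den)
  }
  out
}

#' Call copy-number gain/loss for one gene
#'
#' A gene is a gain if the 90th percentile of its per-sample log-ratios is
#' strictly greater than \code{gain_threshold}; a loss if the 10th
#' percentile is strictly below \code{loss_threshold}. Percentiles are
#' computed by linear interpolation between order statistics
#' (\code{quantile} type 7). A gene triggering both rules is flagged
#' \code{"both"}.
#'
#' @param values per-sample CNV log-ratios for one gene (NAs dropped).
#' @param gain_threshold,loss_threshold log-ratio cutoffs.
#' @return one-row data.frame: \code{status} (gain/loss/neither/both),
#'   \code{percentile_stat} (the percentile that triggered the call),
#'   \code{q10}, \code{q90}.
#' @export
callGainLoss <- function(values, gain_threshold = 0.50,
                         loss_threshold = -0.50) {
  v <- values[!is.na(values)]
  if (length(v) < 10)
    stop("need at least 10 non-missing values to call gain/loss")
  q <- stats::quantile(v, c(0.10, 0.90), type = 7, names = FALSE)
  gain <- q[2] > gain_threshold
  loss <- q[1] < loss_threshold
  status <- if (gain && loss) "both" else if (gain) "gain" else
    if (loss) "loss" else "neither"
  stat <- switch(status, gain = q[2], loss = q[1], NA_real_)
  data.frame(status = status, percentile_stat = stat,
             q10 = q[1], q90 = q[2], stringsAsFactors = FALSE)
}

#' Call gain/loss for every gene of a CNV matrix
#'
#' @param cnv gene x sample matrix.
#' @param gain_threshold,loss_threshold see \code{\link{callGainLoss}}.
#' @param min_values genes with fewer non-missing values are reported with
#'   status \code{NA}.
#' @return data.frame with one row per gene (column \code{gene} first).
#' @export
callGainLossMatrix <- function(cnv, gain_threshold = 0.50,
                               loss_threshold = -0.50, min_values = 10) {
  rows <- lapply(rownames(cnv), function(g) {
    v <- cnv[g, ]
    if (sum(!is.na(v)) < min_values)
      return(data.frame(gene = g, status = NA_character_,
                        percentile_stat = NA_real_, q10 = NA_real_,
                        q90 = NA_real_, stringsAsFactors = FALSE))
    cbind(gene = g, callGainLoss(v, gain_threshold, loss_threshold))
  })
  do.call(rbind, rows)
}

#' Filter constitutively suppressed genes
#'
#' Keeps genes whose normalized count exceeds \code{min_count} in at least
#' \code{ceiling(min_fraction * n_samples)} samples.
#'
#' @param expression gene x sample non-negative matrix.
#' @param min_count count threshold (strictly greater than).
#' @param min_fraction minimum fraction of samples (at least).
#' @return character vector of retained gene identifiers.
#' @export
filterExpressed <- function(expression, min_count = 30,
                            min_fraction = 0.10) {
  if (nrow(expression) == 0 || ncol(expression) == 0)
    stop("expression matrix is empty")
  need <- ceiling(min_fraction * ncol(expression))
  n_pass <- rowSums(expression > min_count, na.rm = TRUE)
  rownames(expression)[n_pass >= need]
}

#' Read a cohort directory written by \code{\link{writeCohort}}
#'
#' @param dir directory containing \code{segments.seg}, \code{genes.bed}
#'   and optionally \code{expression.tsv}, \code{methylation.tsv},
#'   \code{probe_map.tsv}, \code{clinical.tsv}.
#' @return An \linkS4class{OncoCohort}.
#' @export
readCohort <- function(dir) {
  genes <- readGeneBED(file.path(dir, "genes.bed"))
  seg <- readSegments(file.path(dir, "segments.seg"))
  cnv <- mapSegmentsToGenes(seg, genes)
  maybe <- function(f, reader) {
    p <- file.path(dir, f)
    if (file.exists(p)) reader(p) else NULL
  }
  expr <- maybe("expression.tsv", readMatrixTSV)
  meth <- maybe("methylation.tsv", readMatrixTSV)
  pm <- maybe("probe_map.tsv", readProbeMap)
  cl <- maybe("clinical.tsv", readClinical)
  samp <- colnames(cnv)
  align <- function(m) if (is.null(m)) NULL else m[, samp, drop = FALSE]
  if (!is.null(cl)) cl <- cl[match(samp, cl$sample), , drop = FALSE]
  OncoCohort(cnv = cnv, genes = genes, expression = align(expr),
             methylation = align(meth), probeMap = pm, clinical = cl)
}
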