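#' @import methods
#' @importFrom S4Vectors isConstant
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))
setClassUnion("dfOrNULL", c("data.frame", "NULL"))

#' OncoCohort: an aligned multi-omic tumor cohort
#'
#' Container for the gene-level data layers used throughout the package:
#' copy-number log-ratios and expression (gene x sample), methylation beta
#' values (probe x sample) with a probe-to-gene map, per-sample clinical
#' outcomes, and gene coordinates as a \link[GenomicRanges]{GRanges}.
#' Layers other than \code{cnv} may be absent (\code{NULL}); every layer
#' that is present must carry the identical ordered set of sample
#' identifiers as its column names.
#'
#' @slot cnv gene x sample numeric matrix of copy-number log-ratios;
#'   missing values mark genes with no segment coverage in a sample.
#' @slot expression gene x sample non-negative numeric matrix of normalized
#'   counts, or \code{NULL}.
#' @slot methylation probe x sample numeric matrix of beta values in
#'   \code{[0,1]}, or \code{NULL}.
#' @slot probeMap data.frame with columns \code{probe}, \code{gene} mapping
#'   methylation probes to genes, or \code{NULL}.
#' @slot clinical data.frame with columns \code{sample}, \code{time_days}
#'   (positive), \code{event} (0/1), or \code{NULL}.
#' @slot genes named \link[GenomicRanges]{GRanges} of gene bodies (0-based
#'   half-open intervals are converted to GRanges' 1-based form on import).
#'
#' @aliases OncoCohort-class
#' @export
setClass("OncoCohort",
  representation(
    cnv = "matrix",
    expression = "matrixOrNULL",
    methylation = "matrixOrNULL",
    probeMap = "dfOrNULL",
    clinical = "dfOrNULL",
    genes = "GRanges"
  )
)

setValidity("OncoCohort", function(object) {
  msg <- character(0)
  samp <- colnames(object@cnv)
  if (ncol(object@cnv) > 0 && (is.null(samp) || anyDuplicated(samp)))
    msg <- c(msg, "cnv must have unique sample column names")
  if (is.null(rownames(object@cnv)) || anyDuplicated(rownames(object@cnv)))
    msg <- c(msg, "cnv must have unique gene row names")
  for (layer in c("expression", "methylation")) {
    m <- slot(object, layer)
    if (!is.null(m) && !identical(colnames(m), samp))
      msg <- c(msg, sprintf("%s samples differ from cnv samples", layer))
  }
  if (!is.null(object@expression) &&
      any(object@expression < 0, na.rm = TRUE))
    msg <- c(msg, "expression counts must be non-negative")
  if (!is.null(object@methylation)) {
    b <- object@methylation
    if (any(b < 0 | b > 1, na.rm = TRUE))
      msg <- c(msg, "methylation betas must lie in [0,1]")
    if (is.null(object@probeMap))
      msg <- c(msg, "methylation layer requires a probeMap")
    else if (!all(c("probe", "gene") %in% colnames(object@probeMap)))
      msg <- c(msg, "probeMap needs columns 'probe' and 'gene'")
  }
  cl <- object@clinical
  if (!is.null(cl)) {
    if (!all(c("sample", "time_days", "event") %in% colnames(cl)))
      msg <- c(msg, "clinical needs columns sample, time_days, event")
    else {
      if (!identical(as.character(cl$sample), samp))
        msg <- c(msg, "clinical samples differ from cnv samples")
      if (any(cl$time_days <= 0))
        msg <- c(msg, "survival times must be positive")
      if (!all(cl$event %in% c(0, 1)))
        msg <- c(msg, "event indicator must be 0 or 1")
    }
  }
  if (length(object@genes) != nrow(object@cnv) ||
      !identical(names(object@genes), rownames(object@cnv)))
    msg <- c(msg, "genes GRanges must be named and parallel to cnv rows")
  if (length(msg)) msg else TRUE
})

#' Construct an OncoCohort
#'
#' @param cnv gene x sample matrix of copy-number log-ratios.
#' @param genes named GRanges of gene coordinates, parallel to rows of cnv.
#' @param expression,methylation,probeMap,clinical optional layers; see
#'   \linkS4class{OncoCohort}.
#' @return An \linkS4class{OncoCohort}.
#' @export
OncoCohort <- function(cnv, genes, expression = NULL, methylation = NULL,
                       probeMap = NULL, clinical = NULL) {
  new("OncoCohort", cnv = cnv, expression = expression,
      methylation = methylation, probeMap = probeMap,
      clinical = clinical, genes = genes)
}

setMethod("show", "OncoCohort", function(object) {
  cat("OncoCohort with", nrow(object@cnv), "genes,",
      ncol(object@cnv), "samples\n")
  layers <- c("cnv",
              if (!is.null(object@expression)) "expression",
              if (!is.null(object@methylation))
                sprintf("methylation (%d probes)", nrow(object@methylation)),
              if (!is.null(object@clinical)) "clinical")
  cat("  layers:", paste(layers, collapse = ", "), "\n")
})

#' @rdname accessors
#' @export
setGeneric("cnvMatrix", function(x) standardGeneric("cnvMatrix"))
#' @rdname accessors
#' @export
setGeneric("exprMatrix", function(x) standardGeneric("exprMatrix"))
#' @rdname accessors
#' @export
setGeneric("methMatrix", function(x) standardGeneric("methMatrix"))
#' @rdname accessors
#' @export
setGeneric("probeMap", function(x) standardGeneric("probeMap"))
#' @rdname accessors
#' @export
setGeneric("clinicalData", function(x) standardGeneric("clinicalData"))
#' @rdname accessors
#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))

#' Accessors for OncoCohort layers
#'
#' @param x an \linkS4class{OncoCohort}.
#' @return The requested layer (matrix, data.frame or GRanges); \code{NULL}
#'   for absent optional layers.
#' @name accessors
#' @rdname accessors
#' @export
setMethod("cnvMatrix", "OncoCohort", function(x) x@cnv)
#' @rdname accessors
#' @export
setMethod("exprMatrix", "OncoCohort", function(x) x@expression)
#' @rdname accessors
#' @export
setMethod("methMatrix", "OncoCohort", function(x) x@methylation)
#' @rdname accessors
#' @export
setMethod("probeMap", "OncoCohort", function(x) x@probeMap)
#' @rdname accessors
#' @export
setMethod("clinicalData", "OncoCohort", function(x) x@clinical)
#' @rdname accessors
#' @export
setMethod("geneRanges", "OncoCohort", function(x) x@genes)

#' @rdname accessors
#' @export
setGeneric("cohortSamples", function(x) standardGeneric("cohortSamples"))
#' @rdname accessors
#' @export
setMethod("cohortSamples", "OncoCohort", function(x) colnames(x@cnv))
#' @rdname accessors
#' @export
setGeneric("cohortGenes", function(x) standardGeneric("cohortGenes"))
#' @rdname accessors
#' @export
setMethod("cohortGenes", "OncoCohort", function(x) rownames(x@cnv))

#' CRClassification: dosage-coupling class labels
#'
#' Per-gene coupling of copy number with expression. Genes whose own
#' CNV-mRNA Pearson correlation exceeds the cutoff are labelled
#' \code{CR-high} (dosage-coupled); genes at or below it \code{CR-low};
#' genes with no computable correlation \code{excluded}.
#'
#' @slot table data.frame with columns \code{gene}, \code{r}, \code{label}.
#' @slot cutoff numeric scalar in \code{[-1,1]}.
#' @slot cutoffSource \code{"valley"} if fitted from the correlation
#'   density, \code{"fallback"} if the fixed default was used,
#'   \code{"fixed"} if supplied by the caller.
#' @aliases CRClassification-class
#' @export
setClass("CRClassification",
  representation(table = "data.frame", cutoff = "numeric",
                 cutoffSource = "character")
)

setValidity("CRClassification", function(object) {
  msg <- character(0)
  if (!all(c("gene", "r", "label") %in% colnames(object@table)))
    msg <- c(msg, "table needs columns gene, r, label")
  if (!all(object@table$label %in% c("CR-high", "CR-low", "excluded")))
    msg <- c(msg, "labels must be CR-high, CR-low or excluded")
  if (length(object@cutoff) != 1 || !is.finite(object@cutoff) ||
      abs(object@cutoff) > 1)
    msg <- c(msg, "cutoff must be a finite scalar in [-1,1]")
  if (!object@cutoffSource %in% c("valley", "fallback", "fixed"))
    msg <- c(msg, "cutoffSource must be valley, fallback or fixed")
  inc <- object@table$label != "excluded"
  r <- object@table$r[inc]
  lab <- object@table$label[inc]
  if (any((r > object@cutoff) != (lab == "CR-high"), na.rm = TRUE))
    msg <- c(msg, "labels inconsistent with cutoff rule")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CRClassification", function(object) {
  n <- table(factor(object@table$label,
                    levels = c("CR-high", "CR-low", "excluded")))
  cat(sprintf(
    "CRClassification: %d CR-high, %d CR-low, %d excluded (cutoff %.3f, %s)\n",
    n[["CR-high"]], n[["CR-low"]], n[["excluded"]],
    object@cutoff, object@cutoffSource))
})

#' @rdname crAccessors
#' @export
setGeneric("crTable", function(x) standardGeneric("crTable"))
#' @rdname crAccessors
#' @export
setGeneric("crCutoff", function(x) standardGeneric("crCutoff"))

#' Accessors for CRClassification
#' @param x a \linkS4class{CRClassification}.
#' @return \code{crTable}: the per-gene data.frame; \code{crCutoff}: the
#'   numeric cutoff with its source as attribute \code{"source"}.
#' @name crAccessors
#' @rdname crAccessors
#' @export
setMethod("crTable", "CRClassification", function(x) x@table)
#' @rdname crAccessors
#' @export
setMethod("crCutoff", "CRClassification", function(x)
  structure(x@cutoff, source = x@cutoffSource))
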