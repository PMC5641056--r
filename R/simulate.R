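#' SimulationConfig: parameters of the synthetic multi-omic cohort
#'
#' Describes a cohort in which driver amplifications drag neighbouring
#' passenger genes along in large segments, passenger expression either
#' follows gene dosage (CR-high) or is uncoupled from it (CR-low),
#' methylation compensates the uncoupled genes, and a small set of outcome
#' genes carries proportional-hazards survival effects.
#'
#' @slot n_samples,n_genes,n_chromosomes positive integers; genes are laid
#'   out evenly across chromosomes on a fixed coordinate grid.
#' @slot driver_loci list of integer pairs \code{c(chromosome, gene index
#'   within chromosome)} marking driver genes.
#' @slot amp_frequency per-driver amplification probability, recycled to
#'   the number of drivers; each in \code{[0,1]}.
#' @slot segment_decay expected amplified extent per side of the driver, in
#'   genes (geometric).
#' @slot cnv_noise_sd standard deviation of the per-chromosome background
#'   log-ratio.
#' @slot cr_low_fraction fraction of amplicon passenger genes whose
#'   expression is uncoupled from copy number.
#' @slot dosage_slope change in log2 expression per unit CNV log-ratio for
#'   dosage-coupled genes.
#' @slot methyl_compensation strength in \code{[0,1]} of the copy-number to
#'   beta-value coupling that enacts the compensation.
#' @slot hazard_coef_crhigh,hazard_coef_crlow log hazard ratio per SD of
#'   expression for the planted CR-high / CR-low outcome genes.
#' @slot censor_rate marginal probability of independent censoring.
#' @slot seed integer RNG seed; cohorts are bit-identical given the seed.
#' @aliases SimulationConfig-class
#' @export
setClass("SimulationConfig",
  representation(
    n_samples = "integer", n_genes = "integer", n_chromosomes = "integer",
    driver_loci = "list", amp_frequency = "numeric",
    segment_decay = "numeric", cnv_noise_sd = "numeric",
    cr_low_fraction = "numeric", dosage_slope = "numeric",
    methyl_compensation = "numeric", hazard_coef_crhigh = "numeric",
    hazard_coef_crlow = "numeric", censor_rate = "numeric", seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character(0)
  pos <- c(n_samples = object@n_samples, n_genes = object@n_genes,
           n_chromosomes = object@n_chromosomes)
  if (any(pos < 1)) msg <- c(msg, "counts must be positive integers")
  prob <- c(object@amp_frequency, object@cr_low_fraction,
            object@methyl_compensation, object@censor_rate)
  if (any(!is.finite(prob)) || any(prob < 0 | prob > 1))
    msg <- c(msg, "probabilities must lie in [0,1]")
  if (!is.finite(object@segment_decay) || object@segment_decay <= 0)
    msg <- c(msg, "segment_decay must be > 0")
  if (!is.finite(object@cnv_noise_sd) || object@cnv_noise_sd <= 0)
    msg <- c(msg, "cnv_noise_sd must be > 0")
  if (any(!is.finite(c(object@dosage_slope, object@hazard_coef_crhigh,
                       object@hazard_coef_crlow))))
    msg <- c(msg, "slopes and hazard coefficients must be finite")
  per_chr <- genesPerChromosome(object@n_genes, object@n_chromosomes)
  for (d in object@driver_loci) {
    if (length(d) != 2 || d[1] < 1 || d[1] > object@n_chromosomes ||
        d[2] < 1 || d[2] > per_chr[d[1]])
      msg <- c(msg, "driver locus outside the simulated gene grid")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname SimulationConfig-class
#' @param n_samples,n_genes,n_chromosomes,driver_loci,amp_frequency
#'   see slots.
#' @param segment_decay,cnv_noise_sd,cr_low_fraction,dosage_slope see slots.
#' @param methyl_compensation,hazard_coef_crhigh,hazard_coef_crlow see
#'   slots.
#' @param censor_rate,seed see slots.
#' @return A validated \code{SimulationConfig}.
#' @export
SimulationConfig <- function(n_samples = 200L, n_genes = 2000L,
                             n_chromosomes = 10L,
                             driver_loci = list(c(1L, 100L), c(4L, 100L),
                                                c(7L, 100L)),
                             amp_frequency = 0.4, segment_decay = 30,
                             cnv_noise_sd = 0.1, cr_low_fraction = 0.3,
                             dosage_slope = 1, methyl_compensation = 1,
                             hazard_coef_crhigh = 0.5,
                             hazard_coef_crlow = -0.5, censor_rate = 0.3,
                             seed = 1L) {
  new("SimulationConfig",
      n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
      n_chromosomes = as.integer(n_chromosomes),
      driver_loci = lapply(driver_loci, as.integer),
      amp_frequency = amp_frequency, segment_decay = segment_decay,
      cnv_noise_sd = cnv_noise_sd, cr_low_fraction = cr_low_fraction,
      dosage_slope = dosage_slope,
      methyl_compensation = methyl_compensation,
      hazard_coef_crhigh = hazard_coef_crhigh,
      hazard_coef_crlow = hazard_coef_crlow, censor_rate = censor_rate,
      seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: %d samples, %d genes on %d chromosomes, %d drivers\n",
    object@n_samples, object@n_genes, object@n_chromosomes,
    length(object@driver_loci)))
})

genesPerChromosome <- function(n_genes, n_chromosomes) {
  base <- n_genes %/% n_chromosomes
  extra <- n_genes %% n_chromosomes
  base + as.integer(seq_len(n_chromosomes) <= extra)
}

# Fixed coordinate grid: gene j on a chromosome occupies the 0-based
# half-open interval [(j-1)*1e5, (j-1)*1e5 + 5e4).
GENE_SPACING <- 1e5
GENE_WIDTH <- 5e4

simGeneGrid <- function(config) {
  per_chr <- genesPerChromosome(config@n_genes, config@n_chromosomes)
  chrom <- rep(paste0("chr", seq_len(config@n_chromosomes)), per_chr)
  idx <- unlist(lapply(per_chr, seq_len))
  gene <- sprintf("g%04d", seq_len(config@n_genes))
  data.frame(gene = gene, chrom = chrom, idx = idx,
             start0 = (idx - 1) * GENE_SPACING,
             end0 = (idx - 1) * GENE_SPACING + GENE_WIDTH,
             stringsAsFactors = FALSE)
}

#' Simulate a multi-omic cohort with planted dosage coupling
#'
#' Generates, deterministically for a given seed, a cohort with four
#' aligned layers: (i) segmented copy number in which each driver is
#' amplified with its configured frequency and carries a geometrically
#' extending segment of co-amplified passengers (segment mean drawn from
#' Normal(0.8, 0.1), background per chromosome from
#' Normal(0, \code{cnv_noise_sd})); (ii) expression with
#' \code{log2(count+1) = baseline + slope * CNV + Normal(0, 0.3)}, where
#' the slope is \code{dosage_slope} for dosage-coupled genes and 0 for
#' CR-low genes; (iii) one methylation probe per gene with
#' \code{beta = plogis(qlogis(b0) + methyl_compensation * k * CNV + noise)},
#' \code{k > 0} for amplified CR-low genes (hypermethylation on gain) and
#' \code{k < 0} for CR-high genes; (iv) exponential proportional-hazards
#' survival driven by the standardized expression of a small set of planted
#' outcome genes, with independent exponential censoring calibrated to the
#' configured marginal censoring probability.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return A list with elements \code{cohort} (an
#'   \linkS4class{OncoCohort}) and \code{truth}, a data.frame with one row
#'   per gene: \code{gene}, \code{class} (CR-high/CR-low/neutral),
#'   \code{amplicon} (logical), \code{dosage_slope}, \code{meth_k},
#'   \code{meth_compensated}, \code{hazard_coef}, \code{outcome_gene}.
#' @export
simulateCohort <- function(config) {
  validObject(config)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()))
  set.seed(config@seed)

  grid <- simGeneGrid(config)
  n_g <- config@n_genes
  n_s <- config@n_samples
  samples <- sprintf("s%04d", seq_len(n_s))
  drivers <- config@driver_loci
  amp_freq <- rep_len(config@amp_frequency, length(drivers))

  # amplicon membership in ground truth: within segment_decay genes of a
  # driver on its chromosome
  amplicon <- rep(FALSE, n_g)
  driver_row <- integer(length(drivers))
  for (k in seq_along(drivers)) {
    d <- drivers[[k]]
    chr <- paste0("chr", d[1])
    on_chr <- which(grid$chrom == chr)
    driver_row[k] <- on_chr[d[2]]
    win <- abs(grid$idx[on_chr] - d[2]) <= round(config@segment_decay)
    amplicon[on_chr[win]] <- TRUE
  }

  class <- rep("neutral", n_g)
  amp_idx <- which(amplicon)
  class[amp_idx] <- "CR-high"
  n_low <- round(config@cr_low_fraction * length(amp_idx))
  if (n_low > 0)
    class[sample(amp_idx, n_low)] <- "CR-low"

  # copy number: per-chromosome background, driver segments overwrite
  cnv <- matrix(0, n_g, n_s, dimnames = list(grid$gene, samples))
  p_geo <- 1 / (1 + config@segment_decay)
  for (s in seq_len(n_s)) {
    bg <- rnorm(config@n_chromosomes, 0, config@cnv_noise_sd)
    cnv[, s] <- bg[match(grid$chrom, paste0("chr",
                                            seq_len(config@n_chromosomes)))]
    for (k in seq_along(drivers)) {
      if (runif(1) < amp_freq[k]) {
        ext_l <- rgeom(1, p_geo)
        ext_r <- rgeom(1, p_geo)
        seg_mean <- rnorm(1, 0.8, 0.1)
        d <- drivers[[k]]
        on_chr <- which(grid$chrom == paste0("chr", d[1]))
        lo <- max(1, d[2] - ext_l)
        hi <- min(length(on_chr), d[2] + ext_r)
        cnv[on_chr[lo:hi], s] <- seg_mean
      }
    }
  }

  # expression
  slope <- ifelse(class == "CR-low", 0, config@dosage_slope)
  baseline <- runif(n_g, 6, 12)
  log_expr <- baseline + slope * cnv +
    matrix(rnorm(n_g * n_s, 0, 0.3), n_g, n_s)
  expr <- pmax(2^log_expr - 1, 0)
  dimnames(expr) <- dimnames(cnv)

  # methylation: one probe per gene; k sign encodes compensation direction
  meth_k <- rep(0, n_g)
  meth_k[class == "CR-low"] <- 2
  meth_k[class == "CR-high" & amplicon] <- -2
  b0 <- runif(n_g, 0.2, 0.8)
  beta <- plogis(qlogis(b0) + config@methyl_compensation * meth_k * cnv +
                 matrix(rnorm(n_g * n_s, 0, 0.3), n_g, n_s))
  probes <- paste0("p_", grid$gene)
  dimnames(beta) <- list(probes, samples)
  probe_map <- data.frame(probe = probes, gene = grid$gene,
                          stringsAsFactors = FALSE)

  # survival: planted outcome genes among amplicon passengers
  pick <- function(cls, n = 5) {
    cand <- which(class == cls & amplicon)
    cand[seq_len(min(n, length(cand)))]
  }
  out_high <- pick("CR-high")
  out_low <- pick("CR-low")
  hazard_coef <- rep(0, n_g)
  hazard_coef[out_high] <- config@hazard_coef_crhigh
  hazard_coef[out_low] <- config@hazard_coef_crlow
  outcome <- seq_len(n_g) %in% c(out_high, out_low)
  lp <- rep(0, n_s)
  for (g in which(outcome)) {
    z <- as.numeric(scale(log2(expr[g, ] + 1)))
    lp <- lp + hazard_coef[g] * z
  }
  lambda0 <- 1 / 1000
  t_event <- rexp(n_s, rate = lambda0 * exp(lp))
  if (config@censor_rate > 0) {
    rate_c <- lambda0 * config@censor_rate / (1 - config@censor_rate)
    t_cens <- rexp(n_s, rate = rate_c)
  } else t_cens <- rep(Inf, n_s)
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)
  clinical <- data.frame(sample = samples, time_days = time, event = event,
                         stringsAsFactors = FALSE)

  genes <- GenomicRanges::GRanges(
    seqnames = grid$chrom,
    ranges = IRanges::IRanges(start = grid$start0 + 1, end = grid$end0))
  names(genes) <- grid$gene

  truth <- data.frame(
    gene = grid$gene, class = class, amplicon = amplicon,
    driver = grid$gene[driver_row][match(seq_len(n_g), driver_row,
                                         nomatch = NA)],
    dosage_slope = slope, meth_k = meth_k,
    meth_compensated = class == "CR-low" & amplicon,
    hazard_coef = hazard_coef, outcome_gene = outcome,
    stringsAsFactors = FALSE)

  cohort <- OncoCohort(cnv = cnv, genes = genes, expression = expr,
                       methylation = beta, probeMap = probe_map,
                       clinical = clinical)
  list(cohort = cohort, truth = truth)
}

#' Write a cohort to plain-text files
#'
#' Emits the standard on-disk representation read back by
#' \code{\link{readCohort}}: SEG-dialect segmentation (1-based inclusive
#' coordinates, segments reconstructed by run-length encoding of the
#' gene-level log-ratios along each chromosome), expression and beta TSV
#' matrices, the probe map, the clinical table and a BED file (0-based
#' half-open) of gene bodies.
#'
#' @param cohort an \linkS4class{OncoCohort}.
#' @param dir output directory, created if needed.
#' @return Invisibly, the named vector of written file paths.
#' @export
writeCohort <- function(cohort, dir) {
  if (ncol(cnvMatrix(cohort)) == 0 || nrow(cnvMatrix(cohort)) == 0)
    stop("cannot write an empty cohort (no samples or no genes)")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gr <- geneRanges(cohort)
  ord <- order(as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr))
  cnv <- cnvMatrix(cohort)[ord, , drop = FALSE]
  chrom <- as.character(GenomicRanges::seqnames(gr))[ord]
  g_start <- GenomicRanges::start(gr)[ord]  # 1-based inclusive
  g_end <- GenomicRanges::end(gr)[ord]

  seg_rows <- vector("list", ncol(cnv))
  for (s in seq_len(ncol(cnv))) {
    segs <- list()
    for (chr in unique(chrom)) {
      on_chr <- which(chrom == chr)
      v <- cnv[on_chr, s]
      keep <- !is.na(v)
      if (!any(keep)) next
      on_chr <- on_chr[keep]; v <- v[keep]
      # runs of identical value over consecutive covered genes
      brk <- if (length(v) > 1)
        c(TRUE, v[-1] != v[-length(v)] | diff(on_chr) != 1)
      else TRUE
      run <- cumsum(brk)
      for (r in unique(run)) {
        i <- on_chr[run == r]
        segs[[length(segs) + 1]] <- data.frame(
          Sample = colnames(cnv)[s], Chromosome = chr,
          Start = g_start[i[1]], End = g_end[i[length(i)]],
          Num_Probes = length(i), Segment_Mean = cnv[i[1], s],
          stringsAsFactors = FALSE)
      }
    }
    seg_rows[[s]] <- do.call(rbind, segs)
  }
  seg <- do.call(rbind, seg_rows)

  paths <- c(
    seg = file.path(dir, "segments.seg"),
    expression = file.path(dir, "expression.tsv"),
    methylation = file.path(dir, "methylation.tsv"),
    probes = file.path(dir, "probe_map.tsv"),
    clinical = file.path(dir, "clinical.tsv"),
    genes = file.path(dir, "genes.bed"))

  writeTSV <- function(df, path, col.names = TRUE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = col.names)
  seg$Start <- sprintf("%d", as.integer(seg$Start))
  seg$End <- sprintf("%d", as.integer(seg$End))
  writeTSV(seg, paths["seg"])
  writeMat <- function(m, id_col, path) {
    df <- data.frame(rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df) <- c(id_col, colnames(m))
    writeTSV(df, path)
  }
  if (!is.null(exprMatrix(cohort)))
    writeMat(exprMatrix(cohort), "gene", paths["expression"])
  if (!is.null(methMatrix(cohort))) {
    writeMat(methMatrix(cohort), "probe", paths["methylation"])
    writeTSV(probeMap(cohort), paths["probes"])
  }
  if (!is.null(clinicalData(cohort)))
    writeTSV(clinicalData(cohort), paths["clinical"])
  bed <- data.frame(chrom = chrom,
                    start = sprintf("%d", as.integer(g_start - 1)),
                    end = sprintf("%d", as.integer(g_end)),
                    name = rownames(cnv))
  writeTSV(bed, paths["genes"], col.names = FALSE)
  invisible(paths[file.exists(paths)])
}
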