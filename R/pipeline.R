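#' Default analysis thresholds
#'
#' The thresholds used throughout the pipeline: copy-gain when the 90th
#' percentile log-ratio exceeds 0.50, loss when the 10th percentile is
#' below -0.50, genes kept when expression exceeds 30 normalized counts
#' in at least 10\% of samples, CR pivot at r = 0.4, overexpression alpha
#' 0.001, Cox z band at |z| = 2, walk restart 0.05.
#'
#' @return named list of threshold defaults.
#' @export
defaultThresholds <- function() {
  list(gain = 0.50, loss = -0.50, min_count = 30, min_fraction = 0.10,
       cr_pivot = 0.4, overexpr_alpha = 0.001, z_cut = 2, restart = 0.05)
}

#' Run the onco-passenger analysis pipeline end to end
#'
#' Executes ingest, expression filtering, gain/loss calls, per-gene
#' dosage correlation, CR classification, index-gene profiles and
#' enrichment, methylation coupling and coherence, Cox screening with CR
#' stratification, and (when a network and gene sets are supplied)
#' pathway flux scoring. Each stage writes a TSV into the run directory;
#' a JSON manifest records the configuration, its hash and the seed. A
#' stage failure halts the run with the stage name; earlier outputs are
#' preserved. Reruns with the same inputs and seed are byte-identical.
#'
#' @param cohort an \linkS4class{OncoCohort}, or a directory readable by
#'   \code{\link{readCohort}}.
#' @param out_dir run directory, created if needed.
#' @param index_genes oncogenes for the profile/enrichment stage
#'   (skipped when empty).
#' @param network optional edge-list file or igraph for the pathway
#'   stage.
#' @param gmt optional GMT file or named list of gene sets.
#' @param thresholds named list; defaults from
#'   \code{\link{defaultThresholds}}, overrides are recorded in the
#'   manifest.
#' @param stages character vector of stages to run.
#' @param cr_cutoff \code{NULL} to fit the valley cutoff, or a fixed
#'   value; the pathway stage always pivots at
#'   \code{thresholds$cr_pivot}.
#' @param n_permutations permutations for the pathway null.
#' @param seed integer seed for all randomized stages.
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(cohort, out_dir, index_genes = character(0),
                        network = NULL, gmt = NULL,
                        thresholds = list(), stages = c(
                          "filter", "calls", "cr", "profiles",
                          "methylation", "survival", "netflux"),
                        cr_cutoff = NULL, n_permutations = 1000,
                        seed = 1L) {
  thr <- utils::modifyList(defaultThresholds(), thresholds)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "",
                            file = log_path, append = TRUE)
  cat("", file = log_path)

  stage <- function(name, expr) {
    logf("stage %s: start", name)
    tryCatch(expr, error = function(e)
      stop("pipeline halted at stage '", name, "': ",
           conditionMessage(e), call. = FALSE))
  }
  writeTSV <- function(df, f)
    utils::write.table(df, file.path(out_dir, f), sep = "\t",
                       quote = FALSE, row.names = FALSE)

  if (is.character(cohort))
    cohort <- stage("ingest", readCohort(cohort))

  kept <- cohortGenes(cohort)
  if ("filter" %in% stages) {
    kept <- stage("filter", {
      if (is.null(exprMatrix(cohort)))
        stop("expression layer is absent")
      filterExpressed(exprMatrix(cohort), thr$min_count,
                      thr$min_fraction)
    })
    writeTSV(data.frame(gene = kept), "filtered_genes.tsv")
  }

  if ("calls" %in% stages) {
    calls <- stage("calls", callGainLossMatrix(
      cnvMatrix(cohort), thr$gain, thr$loss))
    writeTSV(calls, "gene_calls.tsv")
  } else calls <- NULL

  cr <- NULL
  r_dosage <- NULL
  if ("cr" %in% stages) {
    cr <- stage("cr", {
      if (is.null(exprMatrix(cohort)))
        stop("expression layer is absent")
      crClassify(cohort, gene_set = kept, cutoff = cr_cutoff,
                 fallback = thr$cr_pivot)
    })
    r_dosage <- stats::setNames(crTable(cr)$r, crTable(cr)$gene)
    out <- crTable(cr)
    out$cutoff <- crCutoff(cr)
    out$cutoff_source <- attr(crCutoff(cr), "source")
    writeTSV(out, "cr_classification.tsv")
  }

  if ("profiles" %in% stages && length(index_genes) > 0) {
    stage("profiles", for (ig in index_genes) {
      p_dna <- associationProfile(cohort, ig, "DNA")
      p_mrna <- associationProfile(cohort, ig, "mRNA")
      conc <- profileConcordance(p_dna, p_mrna)
      writeTSV(data.frame(gene = names(profileValues(p_dna)),
                          r_dna = as.numeric(profileValues(p_dna)),
                          r_mrna = as.numeric(profileValues(p_mrna))),
               paste0("profiles_", ig, ".tsv"))
      enr <- coamplificationEnrichment(
        cohort, ig, overexpr_alpha = thr$overexpr_alpha,
        coamp_r_threshold = thr$cr_pivot, gene_set = kept)
      enr$index_gene <- ig
      enr$concordance <- conc
      writeTSV(enr, paste0("enrichment_", ig, ".tsv"))
    })
  }

  if ("methylation" %in% stages) {
    stage("methylation", {
      if (is.null(methMatrix(cohort)))
        stop("methylation layer is absent")
      mc <- cnvMethylationCorrelation(cohort, gene_set = kept)
      writeTSV(mc, "methylation_coupling.tsv")
      if (!is.null(r_dosage)) {
        coh <- methylationCoherence(mc, r_dosage)
        writeTSV(data.frame(spearman_rho = coh$spearman_rho,
                            ols_slope = coh$ols_slope, n = coh$n),
                 "methylation_coherence.tsv")
      }
    })
  }

  if ("survival" %in% stages) {
    stage("survival", {
      if (is.null(clinicalData(cohort)))
        stop("clinical layer is absent")
      cox <- coxPerGene(cohort, gene_set = kept)
      writeTSV(cox, "cox.tsv")
      if (!is.null(cr)) {
        st <- stratifyByCR(cox, cr, thr$z_cut)
        summ <- st$summary
        summ$spearman_rho <- st$spearman_rho
        writeTSV(summ, "cox_stratified.tsv")
      }
    })
  }

  if ("netflux" %in% stages && !is.null(network) && !is.null(gmt)) {
    stage("netflux", {
      if (is.null(r_dosage))
        stop("pathway stage requires the cr stage")
      g <- if (is.character(network)) interactionNetwork(network)
        else network
      sets <- if (is.character(gmt)) readGMT(gmt) else gmt
      vals <- transformCRValues(r_dosage[is.finite(r_dosage)],
                                pivot = thr$cr_pivot)
      fl <- stationaryFlux(g, vals, restart = thr$restart)
      pf <- pathwayFlux(fl, sets, n_permutations = n_permutations,
                        seed = seed)
      writeTSV(pf, "pathway_flux.tsv")
    })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("oncopassenger")),
    thresholds = thr, stages = stages, seed = seed,
    index_genes = index_genes, n_permutations = n_permutations,
    cr_cutoff = if (is.null(cr_cutoff)) "valley" else cr_cutoff,
    n_genes = nrow(cnvMatrix(cohort)), n_samples = ncol(cnvMatrix(cohort)))
  cfg_json <- jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA)
  tmp <- file.path(out_dir, "manifest.json")
  writeLines(cfg_json, tmp)
  manifest$config_hash <- unname(tools::md5sum(tmp))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA),
             tmp)
  logf("run complete")
  invisible(manifest)
}
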