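# shared fixtures and independent oracles

# small deterministic cohort built directly in memory
makeToyCohort <- function(n_genes = 6, n_samples = 20, seed = 42) {
  set.seed(seed)
  genes <- sprintf("t%02d", seq_len(n_genes))
  samples <- sprintf("s%02d", seq_len(n_samples))
  cnv <- matrix(rnorm(n_genes * n_samples, 0, 0.4), n_genes, n_samples,
                dimnames = list(genes, samples))
  expr <- matrix(2^(8 + rnorm(n_genes * n_samples, 0, 0.5)) - 1,
                 n_genes, n_samples, dimnames = list(genes, samples))
  beta <- matrix(runif(n_genes * n_samples, 0.1, 0.9), n_genes,
                 n_samples,
                 dimnames = list(paste0("p_", genes), samples))
  gr <- GenomicRanges::GRanges(
    rep(c("chr1", "chr2"), length.out = n_genes),
    IRanges::IRanges(start = seq_len(n_genes) * 1000 + 1, width = 500))
  names(gr) <- genes
  OncoCohort(cnv = cnv, genes = gr, expression = expr,
             methylation = beta,
             probeMap = data.frame(probe = paste0("p_", genes),
                                   gene = genes),
             clinical = data.frame(sample = samples,
                                   time_days = rexp(n_samples, 1 / 500),
                                   event = rbinom(n_samples, 1, 0.6)))
}

# per-base brute-force oracle for segment-to-gene mapping; coordinates
# are 0-based half-open
bruteForceSegValue <- function(seg_df, gene_chrom, gene_start0,
                               gene_end0) {
  vals <- rep(NA_real_, gene_end0 - gene_start0)
  for (i in seq_len(nrow(seg_df))) {
    if (seg_df$chromosome[i] != gene_chrom) next
    lo <- max(seg_df$start0[i], gene_start0)
    hi <- min(seg_df$end0[i], gene_end0)
    if (lo < hi)
      vals[(lo - gene_start0 + 1):(hi - gene_start0)] <-
        seg_df$segment_mean[i]
  }
  if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
}

# direct sum-formula Pearson correlation (independent of stats::cor)
pearsonOracle <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# Cox partial log-likelihood written from the definition (no ties);
# independent oracle maximized by stats::optimize in tests
coxLoglikOracle <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# random segmentation fixture on a small genome
randomSegFixture <- function(seed) {
  set.seed(seed)
  n_genes <- sample(3:20, 1)
  genes <- data.frame(
    gene = sprintf("g%02d", seq_len(n_genes)),
    chrom = sample(c("chr1", "chr2"), n_genes, replace = TRUE))
  genes$start0 <- sample(0:500, n_genes) * 10
  genes$end0 <- genes$start0 + sample(5:200, n_genes) * 10
  gr <- GenomicRanges::GRanges(genes$chrom,
    IRanges::IRanges(start = genes$start0 + 1, end = genes$end0))
  names(gr) <- genes$gene
  n_seg <- sample(2:10, 1)
  segs <- do.call(rbind, lapply(seq_len(n_seg), function(i) {
    chrom <- sample(c("chr1", "chr2"), 1)
    s <- sample(0:5000, 1)
    data.frame(sample = "s1", chromosome = chrom, start0 = s,
               end0 = s + sample(50:2000, 1),
               segment_mean = round(rnorm(1, 0, 0.5), 3))
  }))
  # drop overlapping segments within a chromosome to satisfy the
  # non-overlap precondition
  keep <- rep(TRUE, nrow(segs))
  for (chr in unique(segs$chromosome)) {
    idx <- which(segs$chromosome == chr)
    idx <- idx[order(segs$start0[idx])]
    last_end <- -1
    for (i in idx) {
      if (segs$start0[i] < last_end) keep[i] <- FALSE
      else last_end <- segs$end0[i]
    }
  }
  list(genes = gr, genes_df = genes, segs = segs[keep, , drop = FALSE])
}
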