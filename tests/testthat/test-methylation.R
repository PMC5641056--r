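test_that("monotone CNV-beta coupling gives near-perfect correlation", {
  set.seed(41)
  n <- 60
  cnv <- matrix(rnorm(n, 0.2, 0.4), 1, n,
                dimnames = list("gA", sprintf("s%02d", 1:n)))
  beta <- matrix(pmin(pmax(0.1 + 0.3 * cnv[1, ], 1e-6), 1 - 1e-6), 1, n,
                 dimnames = list("pA", colnames(cnv)))
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 500))
  names(gr) <- "gA"
  co <- OncoCohort(cnv = cnv, genes = gr, methylation = beta,
                   probeMap = data.frame(probe = "pA", gene = "gA"))
  mc <- cnvMethylationCorrelation(co)
  expect_gt(mc$cnv_meth_r, 0.99)
  # constant beta -> excluded
  co2 <- OncoCohort(cnv = cnv, genes = gr,
                    methylation = matrix(0.5, 1, n,
                                         dimnames = dimnames(beta)),
                    probeMap = data.frame(probe = "pA", gene = "gA"))
  expect_equal(nrow(cnvMethylationCorrelation(co2)), 0)
})

test_that("CNV-methylation correlation matches the formula oracle", {
  co <- makeToyCohort(n_genes = 5, n_samples = 6)
  mc <- cnvMethylationCorrelation(co, min_pairs = 6)
  for (i in seq_len(nrow(mc))) {
    g <- mc$gene[i]
    expect_equal(mc$cnv_meth_r[i],
                 pearsonOracle(cnvMatrix(co)[g, ],
                               methMatrix(co)[paste0("p_", g), ]),
                 tolerance = 1e-12)
  }
})

test_that("probe policies agree for single-probe genes and differ as
           documented for multi-probe genes", {
  co <- makeToyCohort(n_genes = 4, n_samples = 30)
  best <- cnvMethylationCorrelation(co, probe_policy = "best_abs")
  meanb <- cnvMethylationCorrelation(co, probe_policy = "mean_beta")
  expect_equal(best$cnv_meth_r, meanb$cnv_meth_r, tolerance = 1e-12)
  # two probes for one gene
  set.seed(52)
  n <- 40
  cnv <- matrix(rnorm(n, 0, 0.5), 1, n,
                dimnames = list("gA", sprintf("s%02d", 1:n)))
  beta <- rbind(p1 = plogis(1.5 * cnv[1, ] + rnorm(n, 0, 0.1)),
                p2 = plogis(rnorm(n, 0, 0.5)))
  colnames(beta) <- colnames(cnv)
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 500))
  names(gr) <- "gA"
  co2 <- OncoCohort(cnv = cnv, genes = gr, methylation = beta,
                    probeMap = data.frame(probe = c("p1", "p2"),
                                          gene = "gA"))
  bb <- cnvMethylationCorrelation(co2, probe_policy = "best_abs")
  expect_equal(bb$probe, "p1")
  expect_equal(bb$n_probes, 2)
  pp <- cnvMethylationCorrelation(co2, probe_policy = "per_probe")
  expect_equal(nrow(pp), 2)
})

test_that("coherence reproduces exact negation and null independence", {
  set.seed(71)
  mrna <- stats::setNames(runif(200, -0.5, 0.9), sprintf("g%03d", 1:200))
  coh <- methylationCoherence(-mrna, mrna)
  expect_equal(coh$spearman_rho, -1)
  expect_equal(coh$ols_slope, -1, tolerance = 1e-12)
  indep <- stats::setNames(rnorm(1000), sprintf("h%04d", 1:1000))
  coh0 <- methylationCoherence(indep,
                               stats::setNames(rnorm(1000),
                                               names(indep)))
  expect_lt(abs(coh0$spearman_rho), 0.1)
})

test_that("simulated methylation compensation yields negative coherence
           among amplicon genes", {
  sim <- simulateCohort(SimulationConfig(
    n_samples = 300, n_genes = 200, n_chromosomes = 2,
    driver_loci = list(c(1L, 50L)), segment_decay = 25,
    methyl_compensation = 1, cr_low_fraction = 0.4, seed = 19))
  amp <- sim$truth$gene[sim$truth$amplicon]
  mc <- cnvMethylationCorrelation(sim$cohort, gene_set = amp)
  r <- perGeneDosageCorrelation(sim$cohort, amp)
  coh <- methylationCoherence(mc, r)
  expect_lt(coh$spearman_rho, 0)
})

test_that("beta comparison flags the extreme separation with the exact
           rank-sum p-value", {
  n <- 10
  samples <- sprintf("s%02d", 1:(4 * n))
  cnv <- matrix(c(rep(0.8, n), rep(0, 3 * n)), 1, 4 * n,
                dimnames = list("gA", samples))
  beta <- matrix(c(rep(0.8, n), rep(0.2, 3 * n)), 1, 4 * n,
                 dimnames = list("pA", samples))
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 500))
  names(gr) <- "gA"
  co <- OncoCohort(cnv = cnv, genes = gr, methylation = beta,
                   probeMap = data.frame(probe = "pA", gene = "gA"))
  # compare 10 gain vs first 10 2N samples via a trimmed cohort
  co10 <- OncoCohort(cnv = cnv[, 1:(2 * n), drop = FALSE],
                     genes = gr,
                     methylation = beta[, 1:(2 * n), drop = FALSE],
                     probeMap = data.frame(probe = "pA", gene = "gA"))
  res <- betaGainVs2N(co10, "gA")
  expect_equal(res$direction, "hyper")
  # only the observed split (and its mirror) reach the extreme rank sum
  expect_equal(res$p_value, 2 / choose(2 * n, n), tolerance = 1e-12)
})

test_that("identical beta distributions give direction none and small
           groups error", {
  set.seed(33)
  n <- 30
  cnv <- matrix(c(rep(0.8, 12), rep(0, n - 12)), 1, n,
                dimnames = list("gA", sprintf("s%02d", 1:n)))
  b <- rep(c(0.3, 0.5, 0.7), 10)
  beta <- matrix(b, 1, n, dimnames = list("pA", colnames(cnv)))
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 500))
  names(gr) <- "gA"
  co <- OncoCohort(cnv = cnv, genes = gr, methylation = beta,
                   probeMap = data.frame(probe = "pA", gene = "gA"))
  expect_equal(betaGainVs2N(co, "gA")$direction, "none")
  cnv3 <- cnv; cnv3[1, ] <- c(rep(0.8, 3), rep(0, n - 3))
  co3 <- OncoCohort(cnv = cnv3, genes = gr, methylation = beta,
                    probeMap = data.frame(probe = "pA", gene = "gA"))
  expect_error(betaGainVs2N(co3, "gA"), "fewer than 5")
})

test_that("the loss side mirrors the gain machinery", {
  set.seed(44)
  n <- 40
  cnv <- matrix(c(rep(-0.8, 15), rep(0, n - 15)), 1, n,
                dimnames = list("gA", sprintf("s%02d", 1:n)))
  beta_vals <- c(plogis(qlogis(0.5) - 1.5 + rnorm(15, 0, 0.2)),
                 plogis(qlogis(0.5) + rnorm(n - 15, 0, 0.2)))
  beta <- matrix(beta_vals, 1, n, dimnames = list("pA", colnames(cnv)))
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 500))
  names(gr) <- "gA"
  co <- OncoCohort(cnv = cnv, genes = gr, methylation = beta,
                   probeMap = data.frame(probe = "pA", gene = "gA"))
  res <- betaGainVs2N(co, "gA", side = "loss")
  expect_equal(res$side, "loss")
  expect_equal(res$direction, "hypo")
})
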