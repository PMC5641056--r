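test_that("the Cox fit maximizes the partial likelihood on an 8-subject
           fixture and agrees with coxph", {
  time <- c(3, 5, 7, 11, 13, 17, 19, 23)
  event <- c(1, 0, 1, 1, 0, 1, 1, 0)
  x <- c(0.5, -1.2, 0.8, -0.3, 1.5, -0.7, 0.2, 0.9)
  fit <- coxUnivariate(time, event, x)
  expect_true(fit$converged)
  # independent oracle: numerical maximization of the explicit
  # partial likelihood
  opt <- stats::optimize(coxLoglikOracle, c(-5, 5), time = time,
                         event = event, x = x, maximum = TRUE,
                         tol = 1e-10)
  expect_equal(fit$coef, opt$maximum, tolerance = 1e-6)
  # cross-check against the reference implementation
  library(survival)
  ref <- coxph(Surv(time, event) ~ x, ties = "efron")
  expect_equal(fit$coef, unname(coef(ref)), tolerance = 1e-6)
  expect_equal(fit$se, sqrt(unname(vcov(ref)[1, 1])), tolerance = 1e-6)
})

test_that("Efron tie handling matches coxph on tied event times", {
  set.seed(24)
  time <- sample(1:6, 40, replace = TRUE)  # heavy ties
  event <- rbinom(40, 1, 0.7)
  x <- rnorm(40)
  fit <- coxUnivariate(time, event, x)
  library(survival)
  ref <- coxph(Surv(time, event) ~ x, ties = "efron")
  expect_equal(fit$coef, unname(coef(ref)), tolerance = 1e-7)
  expect_equal(fit$z, unname(summary(ref)$coefficients[1, "z"]),
               tolerance = 1e-6)
})

test_that("the permutation null keeps z scores calibrated", {
  set.seed(55)
  n <- 200
  time <- rexp(n, 1 / 500)
  event <- rbinom(n, 1, 0.7)
  x <- rnorm(n)
  zs <- vapply(1:100, function(i)
    coxUnivariate(time, event, sample(x))$z, numeric(1))
  expect_gte(mean(abs(zs) < 3), 0.99)
})

test_that("planted hazard coefficients recover with the right signs", {
  sim <- simulateCohort(SimulationConfig(
    n_samples = 250, n_genes = 150, n_chromosomes = 2,
    driver_loci = list(c(1L, 40L)), segment_decay = 20,
    hazard_coef_crhigh = 0.5, hazard_coef_crlow = -0.5, seed = 66))
  out <- sim$truth[sim$truth$outcome_gene, ]
  cox <- coxPerGene(sim$cohort, gene_set = out$gene)
  sign_ok <- sign(cox$z) == sign(out$hazard_coef[match(cox$gene,
                                                       out$gene)])
  expect_gte(mean(sign_ok), 0.8)
  expect_true(all(cox$converged))
})

test_that("KM steps equal hand-computed product-limit values", {
  time <- c(1, 2, 3, 4, 5, 6)
  event <- c(1, 1, 0, 1, 0, 1)
  km <- kmEstimate(time, event)
  # hand calculation: S(1)=5/6, S(2)=5/6*4/5=2/3, S(4)=2/3*2/3=4/9,
  # S(6)=4/9*0=0
  expect_equal(km$time, c(1, 2, 4, 6))
  expect_equal(km$survival, c(5 / 6, 2 / 3, 4 / 9, 0))
  # cross-check with survfit
  library(survival)
  sf <- summary(survfit(Surv(time, event) ~ 1))
  expect_equal(km$survival, unname(sf$surv))
})

test_that("without censoring KM equals one minus the empirical CDF", {
  set.seed(27)
  time <- rexp(50, 1 / 100)
  km <- kmEstimate(time, rep(1, 50))
  ecdf_surv <- 1 - ecdf(time)(km$time)
  expect_equal(km$survival, ecdf_surv, tolerance = 1e-12)
})

test_that("degenerate survival inputs are flagged", {
  # all censored -> flat at 1, log-rank flagged
  km <- kmEstimate(c(5, 10, 15), c(0, 0, 0))
  expect_equal(nrow(km), 0)
  lr <- logRankTest(c(5, 10, 15, 20), rep(0, 4), c(1, 1, 2, 2))
  expect_true(lr$flagged)
  # identical group outcomes -> statistic 0
  time <- rep(c(2, 4, 6, 8, 10), 2)
  event <- rep(c(1, 1, 0, 1, 1), 2)
  grp <- rep(c("a", "b"), each = 5)
  lr2 <- logRankTest(time, event, grp)
  expect_equal(lr2$chisq, 0, tolerance = 1e-12)
})

test_that("log-rank agrees with survdiff on random data", {
  set.seed(88)
  time <- rexp(60, 1 / 300)
  event <- rbinom(60, 1, 0.7)
  grp <- rep(c("a", "b"), 30)
  lr <- logRankTest(time, event, grp)
  library(survival)
  ref <- survdiff(Surv(time, event) ~ grp)
  expect_equal(lr$chisq, ref$chisq, tolerance = 1e-9)
})

test_that("kmCurves splits by expression and runs the log-rank test", {
  sim <- simulateCohort(SimulationConfig(
    n_samples = 100, n_genes = 60, n_chromosomes = 2,
    driver_loci = list(c(1L, 15L)), segment_decay = 10, seed = 10))
  g <- sim$truth$gene[sim$truth$outcome_gene][1]
  res <- kmCurves(sim$cohort, g, split = "median")
  expect_named(res$curves, c("low", "high"))
  expect_false(res$logrank$flagged)
  res3 <- kmCurves(sim$cohort, g, split = "tertile")
  expect_length(res3$curves, 3)
})

test_that("CR stratification recovers the planted survival pattern and
           its reversal", {
  mk_rho <- function(ch, cl, seed) {
    sim <- simulateCohort(SimulationConfig(
      n_samples = 250, n_genes = 200, n_chromosomes = 2,
      driver_loci = list(c(1L, 50L)), segment_decay = 25,
      cr_low_fraction = 0.5, hazard_coef_crhigh = ch,
      hazard_coef_crlow = cl, seed = seed))
    amp <- sim$truth$gene[sim$truth$amplicon]
    cox <- coxPerGene(sim$cohort, gene_set = amp)
    cr <- crClassify(sim$cohort, gene_set = amp, cutoff = 0.4)
    stratifyByCR(cox, cr)
  }
  st <- mk_rho(0.8, -0.8, 101)
  # poor-survival genes are dosage-coupled, better-survival uncoupled
  summ <- st$summary
  expect_gt(summ$median[summ$group == "poor"],
            summ$median[summ$group == "better"])
  expect_gt(st$spearman_rho, 0)
  # reversed coefficients flip the rank correlation (deletion-context
  # pattern)
  st_rev <- mk_rho(-0.8, 0.8, 101)
  expect_lt(st_rev$spearman_rho, 0)
})

test_that("perfect agreement between z and dosage correlation gives
           rho = 1", {
  r <- stats::setNames(seq(-0.5, 0.9, length.out = 30),
                       sprintf("g%02d", 1:30))
  cox <- data.frame(gene = names(r), coef = r, se = 1, z = unname(r),
                    n_events = 10, converged = TRUE)
  st <- stratifyByCR(cox, r)
  expect_equal(st$spearman_rho, 1)
  expect_true(all(st$summary$n[st$summary$group == "NS"] == 30))
})
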