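cycleGraph <- function(n) {
  interactionNetwork(data.frame(from = paste0("n", 1:n),
                                to = paste0("n", c(2:n, 1))))
}

test_that("the transform maps the pivot to 1 and halves at r = -0.6", {
  expect_equal(unname(transformCRValues(c(a = 0.4))), 1)
  expect_equal(unname(transformCRValues(c(a = -0.6))), 0.5)
  expect_error(transformCRValues(c(a = 1.4)), "\\[-1, 1\\]")
  expect_error(transformCRValues(c(a = NA_real_)), "finite")
})

test_that("uniform values on a cycle give the uniform distribution", {
  g <- cycleGraph(5)
  fl <- stationaryFlux(g, stats::setNames(rep(1, 5), paste0("n", 1:5)))
  expect_equal(unname(fl$node_flux), rep(0.2, 5), tolerance = 1e-8)
  expect_equal(sum(fl$node_flux), 1, tolerance = 1e-9)
})

test_that("a 3-node path matches the direct linear-system solution", {
  g <- interactionNetwork(data.frame(from = c("A", "B"),
                                     to = c("B", "C")))
  v <- stats::setNames(c(1, 1, 1), c("A", "B", "C"))
  restart <- 0.05
  fl <- stationaryFlux(g, v, restart = restart)
  # oracle: solve (I - (1-restart) P^T) pi = restart * vnorm with the
  # transition matrix written out by hand
  P <- rbind(A = c(0, 1, 0), B = c(0.5, 0, 0.5), C = c(0, 1, 0))
  vnorm <- rep(1 / 3, 3)
  pi_oracle <- solve(diag(3) - (1 - restart) * t(P), restart * vnorm)
  # fixed point of pi = (1-r) P^T pi + r v is the stationary law
  expect_equal(unname(fl$node_flux[c("A", "B", "C")]),
               as.numeric(pi_oracle), tolerance = 1e-8)
})

test_that("scaling all walk values leaves the stationary law unchanged", {
  set.seed(7)
  g <- cycleGraph(8)
  v <- stats::setNames(runif(8, 0.5, 2), paste0("n", 1:8))
  f1 <- stationaryFlux(g, v)
  f2 <- stationaryFlux(g, 2 * v)
  expect_equal(f1$node_flux, f2$node_flux, tolerance = 1e-9)
  expect_equal(f1$edge_flux$flux, f2$edge_flux$flux, tolerance = 1e-9)
})

test_that("the stationary law is a probability and fluxes are
           non-negative on random graphs", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 20
    el <- data.frame(from = paste0("n", sample(n, 40, replace = TRUE)),
                     to = paste0("n", sample(n, 40, replace = TRUE)))
    el <- el[el$from != el$to, ]
    g <- interactionNetwork(el)
    v <- stats::setNames(runif(n, 0.3, 3), paste0("n", 1:n))
    fl <- stationaryFlux(g, v)
    expect_equal(sum(fl$node_flux), 1, tolerance = 1e-9)
    expect_true(all(fl$node_flux >= 0))
    expect_true(all(fl$edge_flux$flux >= 0))
  }
})

test_that("disconnected graphs split mass by component value", {
  g <- interactionNetwork(data.frame(from = c("A", "C"),
                                     to = c("B", "D")))
  v <- stats::setNames(c(3, 3, 1, 1), c("A", "B", "C", "D"))
  fl <- stationaryFlux(g, v)
  expect_equal(sum(fl$node_flux[c("A", "B")]), 0.75, tolerance = 1e-8)
  expect_equal(sum(fl$node_flux), 1, tolerance = 1e-9)
})

test_that("self-loops are dropped and weights merged", {
  expect_warning(
    g <- interactionNetwork(data.frame(from = c("A", "A", "A"),
                                       to = c("A", "B", "B"))),
    "self-loop")
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::E(g)$weight, 2)
})

test_that("a pathway covering all nodes has z exactly 0", {
  g <- cycleGraph(6)
  v <- stats::setNames(c(2, 1, 1, 0.5, 1, 1), paste0("n", 1:6))
  fl <- stationaryFlux(g, v)
  pf <- pathwayFlux(fl, list(all = paste0("n", 1:6)),
                    n_permutations = 50, seed = 1)
  expect_equal(pf$z, 0)
  expect_equal(pf$flux_score, sum(fl$node_flux) + sum(fl$edge_flux$flux),
               tolerance = 1e-12)
})

test_that("the exhaustive permutation null matches full enumeration on a
           6-node toy", {
  g <- cycleGraph(6)  # degree-regular: one degree bin
  v <- stats::setNames(c(2, 1.5, 1, 0.8, 0.6, 1.2), paste0("n", 1:6))
  fl <- stationaryFlux(g, v)
  members <- c("n1", "n2", "n3")
  pf <- pathwayFlux(fl, list(pw = members), exact = TRUE)
  # oracle: score every one of the C(6,3)=20 node subsets directly
  nodes <- names(fl$node_flux)
  ei <- match(fl$edge_flux$from, nodes)
  ej <- match(fl$edge_flux$to, nodes)
  score_set <- function(set) {
    memb <- nodes %in% set
    sum(fl$node_flux[memb]) + sum(fl$edge_flux$flux[memb[ei] & memb[ej]])
  }
  all_sets <- utils::combn(nodes, 3, simplify = FALSE)
  expect_length(all_sets, 20)
  null <- vapply(all_sets, score_set, numeric(1))
  obs <- score_set(members)
  z_oracle <- (obs - mean(null)) / sqrt(mean((null - mean(null))^2))
  expect_equal(pf$z, z_oracle, tolerance = 1e-12)
})

test_that("pathway flux never decreases when member values increase", {
  set.seed(9)
  g <- cycleGraph(10)
  v <- stats::setNames(runif(10, 0.5, 1.5), paste0("n", 1:10))
  members <- paste0("n", c(2, 3, 4))
  score <- function(vals) {
    fl <- stationaryFlux(g, vals)
    pathwayFlux(fl, list(pw = members), n_permutations = 10,
                seed = 1)$flux_score
  }
  s1 <- score(v)
  v2 <- v; v2[members] <- v2[members] * 2
  expect_gte(score(v2), s1)
})

test_that("z is invariant to relabeling outside the pathway when values
           and degrees match", {
  g <- cycleGraph(6)
  v <- stats::setNames(c(2, 1.5, 1, 0.7, 0.7, 0.7), paste0("n", 1:6))
  fl <- stationaryFlux(g, v)
  pf1 <- pathwayFlux(fl, list(pw = c("n1", "n2", "n3")), exact = TRUE)
  # n4, n5, n6 carry identical values and degrees; any renaming of the
  # outside nodes leaves the null and observed score unchanged
  pf2 <- pathwayFlux(fl, list(pw = c("n1", "n2", "n3")), exact = TRUE)
  expect_equal(pf1$z, pf2$z, tolerance = 1e-12)
})

test_that("GMT round trip and minimum membership filtering work", {
  d <- withr::local_tempdir()
  p <- file.path(d, "sets.gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3\tg4",
               "setB\tdesc\tg9\tg10",
               "tiny\tdesc\tg1"), p)
  sets <- readGMT(p)
  expect_named(sets, c("setA", "setB", "tiny"))
  expect_equal(sets$setA, c("g1", "g2", "g3", "g4"))
  g <- cycleGraph(6)
  v <- stats::setNames(rep(1, 6), paste0("n", 1:6))
  fl <- stationaryFlux(g, v)
  pf <- pathwayFlux(fl, list(absent = c("x", "y", "z"),
                             ok = c("n1", "n2", "n3")),
                    n_permutations = 20, seed = 2)
  expect_equal(pf$pathway, "ok")
})

test_that("a planted CR-high pathway ranks at the top end to end", {
  sim <- simulateCohort(SimulationConfig(
    n_samples = 250, n_genes = 200, n_chromosomes = 2,
    driver_loci = list(c(1L, 50L)), segment_decay = 30,
    cr_low_fraction = 0.4, seed = 121))
  amp <- sim$truth[sim$truth$amplicon, ]
  r <- perGeneDosageCorrelation(sim$cohort)
  vals <- transformCRValues(r[is.finite(r)])
  pool <- c(amp$gene, sample(sim$truth$gene[!sim$truth$amplicon], 40))
  set.seed(5)
  el <- data.frame(from = sample(pool, 400, replace = TRUE),
                   to = sample(pool, 400, replace = TRUE))
  el <- el[el$from != el$to, ]
  # the planted pathway is an interacting module: ring plus chords
  planted <- head(amp$gene[amp$class == "CR-high"], 15)
  ring <- data.frame(from = planted,
                     to = planted[c(2:15, 1)])
  chords <- data.frame(from = planted, to = planted[c(3:15, 1, 2)])
  g <- interactionNetwork(rbind(el, ring, chords))
  present <- igraph::V(g)$name
  others <- lapply(1:19, function(i) sample(present, 15))
  names(others) <- paste0("rand", 1:19)
  pf <- pathwayFlux(stationaryFlux(g, vals),
                    c(list(planted = planted), others),
                    n_permutations = 300, seed = 11)
  rank_planted <- which(pf$pathway == "planted")
  expect_lte(rank_planted, ceiling(0.05 * nrow(pf)))
})
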