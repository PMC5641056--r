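#' Transform dosage correlations into walk-bias values
#'
#' Centers per-gene CNV-mRNA correlations at the CR cutoff and
#' exponentiates: \code{value = 2^(r - pivot)}. Dosage-coupled genes
#' (r above the pivot) map above 1 and uncoupled genes below 1, giving the
#' strictly positive, 1-centered node values the biased walk requires.
#'
#' @param r_values named numeric vector of correlations in \code{[-1,1]}.
#' @param pivot centering value (the CR cutoff).
#' @return named numeric vector of positive walk-bias values.
#' @export
transformCRValues <- function(r_values, pivot = 0.4) {
  if (any(!is.finite(r_values)))
    stop("correlation values must be finite")
  if (any(r_values < -1 | r_values > 1))
    stop("correlation values must lie in [-1, 1]")
  2^(r_values - pivot)
}

#' Build an interaction network from an edge list
#'
#' @param edges data.frame or matrix with columns geneA, geneB and an
#'   optional non-negative weight (default 1); or a path to a 2- or
#'   3-column tab-separated edge-list file without header.
#' @return an undirected \link[igraph]{igraph} graph with edge attribute
#'   \code{weight}; self-loops are dropped with a warning and duplicate
#'   edges collapsed (weights summed).
#' @export
interactionNetwork <- function(edges) {
  if (is.character(edges) && length(edges) == 1)
    edges <- utils::read.delim(edges, header = FALSE,
                               stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2) stop("edge list needs at least 2 columns")
  w <- if (ncol(edges) >= 3) as.numeric(edges[[3]]) else
    rep(1, nrow(edges))
  if (any(!is.finite(w)) || any(w < 0))
    stop("edge weights must be finite and non-negative")
  self <- edges[[1]] == edges[[2]]
  if (any(self)) {
    warning("dropping ", sum(self), " self-loop(s)")
    edges <- edges[!self, , drop = FALSE]; w <- w[!self]
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges[[1]]),
               to = as.character(edges[[2]]), weight = w),
    directed = FALSE)
  igraph::simplify(g, edge.attr.comb = list(weight = "sum"))
}

#' Stationary flux of a value-biased random walk with restart
#'
#' Runs a random walk whose transition probability from node i to
#' neighbour j is proportional to \code{edge_weight(i,j) * value(j)} and
#' which restarts with probability \code{restart} into a distribution
#' proportional to the node values. The stationary distribution is found
#' by power iteration; the flux over an edge is
#' \code{pi(i) P(i->j) + pi(j) P(j->i)}. Disconnected graphs are walked
#' per component, with each component weighted by its share of the total
#' node value.
#'
#' @param network an \link[igraph]{igraph} graph (see
#'   \code{\link{interactionNetwork}}).
#' @param values named positive walk-bias values; network genes absent
#'   from the map are assigned 1. Scaling all values by a constant leaves
#'   the result unchanged.
#' @param restart restart probability in (0, 1).
#' @param tol L1 convergence tolerance of the power iteration.
#' @param max_iter iteration cap (error on non-convergence).
#' @return list with \code{node_flux} (named stationary probabilities,
#'   summing to 1), \code{edge_flux} (data.frame from, to, flux),
#'   \code{degree} (named) and \code{restart}.
#' @export
stationaryFlux <- function(network, values, restart = 0.05, tol = 1e-10,
                           max_iter = 1e5) {
  stopifnot(restart > 0, restart < 1)
  nodes <- igraph::V(network)$name
  v <- rep(1, length(nodes)); names(v) <- nodes
  hit <- intersect(nodes, names(values))
  v[hit] <- values[hit]
  if (any(v <= 0)) stop("walk-bias values must be positive")
  el <- igraph::as_data_frame(network, what = "edges")
  if (is.null(el$weight)) el$weight <- 1
  A <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  ei <- match(el$from, nodes); ej <- match(el$to, nodes)
  A[cbind(ei, ej)] <- el$weight
  A[cbind(ej, ei)] <- el$weight

  comp <- igraph::components(network)$membership
  pi_all <- rep(0, length(nodes)); names(pi_all) <- nodes
  P <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  v_total <- sum(v)
  for (cc in unique(comp)) {
    idx <- which(comp == cc)
    vc <- v[idx]
    B <- A[idx, idx, drop = FALSE] * rep(vc, each = length(idx))
    rs <- rowSums(B)
    Pc <- B
    Pc[rs > 0, ] <- Pc[rs > 0, , drop = FALSE] / rs[rs > 0]
    # isolated node inside its own component: stays via restart only
    if (any(rs == 0)) diag(Pc)[rs == 0] <- 1
    rvec <- vc / sum(vc)
    p <- rvec
    for (it in seq_len(max_iter)) {
      p_new <- (1 - restart) * as.numeric(crossprod(Pc, p)) +
        restart * rvec
      if (sum(abs(p_new - p)) < tol) { p <- p_new; break }
      p <- p_new
      if (it == max_iter) stop("power iteration did not converge")
    }
    pi_all[idx] <- p * (sum(vc) / v_total)
    P[idx, idx] <- Pc
  }
  flux <- pi_all[ei] * P[cbind(ei, ej)] + pi_all[ej] * P[cbind(ej, ei)]
  list(node_flux = pi_all,
       edge_flux = data.frame(from = el$from, to = el$to,
                              flux = as.numeric(flux),
                              stringsAsFactors = FALSE),
       degree = stats::setNames(igraph::degree(network), nodes),
       restart = restart)
}

# degree bins for the permutation null: exact up to degree 10,
# logarithmic (doubling) above
degreeBin <- function(d) ifelse(d <= 10, d, 10 + ceiling(log2(d / 10)))

#' Read gene sets in GMT format
#'
#' @param path GMT file: one tab-separated line per set -- name,
#'   description, member genes.
#' @return named list of character vectors.
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, character(1), 1)
  sets
}

#' Pathway flux scores with a degree-binned permutation null
#'
#' A pathway's flux score is the sum of its members' node flux plus the
#' flux over edges internal to the pathway. Significance comes from a
#' null in which node labels are permuted within degree bins (exact bins
#' up to degree 10, doubling bins above), which preserves hub structure;
#' z is the observed score standardized against that null. A high
#' positive z marks enrichment of the pathway for dosage-coupled
#' (CR-high) genes, a negative z enrichment for CR-low genes.
#'
#' @param flux result of \code{\link{stationaryFlux}}.
#' @param pathways named list of gene sets (see \code{\link{readGMT}}).
#' @param n_permutations permutation count for the sampled null.
#' @param seed RNG seed; results are deterministic given the seed.
#' @param exact enumerate every degree-bin-consistent placement of the
#'   pathway instead of sampling (small graphs only); the null standard
#'   deviation is then the population value.
#' @param min_members pathways with fewer members present in the network
#'   are omitted.
#' @return data.frame with \code{pathway}, \code{n_members},
#'   \code{flux_score}, \code{null_mean}, \code{null_sd}, \code{z},
#'   ordered by decreasing z.
#' @export
pathwayFlux <- function(flux, pathways, n_permutations = 1000, seed = 1,
                        exact = FALSE, min_members = 3) {
  nodes <- names(flux$node_flux)
  nf <- flux$node_flux
  ei <- match(flux$edge_flux$from, nodes)
  ej <- match(flux$edge_flux$to, nodes)
  ef <- flux$edge_flux$flux
  bins <- degreeBin(flux$degree)

  score <- function(member_idx) {
    memb <- logical(length(nodes)); memb[member_idx] <- TRUE
    sum(nf[memb]) + sum(ef[memb[ei] & memb[ej]])
  }

  members <- lapply(pathways, function(p) which(nodes %in% p))
  keep <- vapply(members, length, integer(1)) >= min_members
  members <- members[keep]
  if (length(members) == 0)
    return(data.frame(pathway = character(0), n_members = integer(0),
                      flux_score = numeric(0), null_mean = numeric(0),
                      null_sd = numeric(0), z = numeric(0)))

  null_scores <- if (exact) {
    lapply(members, function(mi) {
      by_bin <- split(mi, bins[mi])
      choices <- lapply(names(by_bin), function(b) {
        pool <- which(bins == as.numeric(b))
        utils::combn(pool, length(by_bin[[b]]), simplify = FALSE)
      })
      combos <- Reduce(function(acc, ch) {
        unlist(lapply(acc, function(a) lapply(ch, function(x) c(a, x))),
               recursive = FALSE)
      }, choices, accumulate = FALSE, init = list(integer(0)))
      if (length(combos) > 1e5)
        stop("exact enumeration too large; use sampled null")
      vapply(combos, score, numeric(1))
    })
  } else {
    old_seed <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, globalenv()))
    set.seed(seed)
    perms <- replicate(n_permutations, {
      perm <- seq_along(nodes)
      for (b in unique(bins)) {
        bn <- which(bins == b)
        if (length(bn) > 1) perm[bn] <- sample(bn)
      }
      perm
    })
    lapply(members, function(mi)
      apply(perms, 2, function(perm) score(perm[mi])))
  }

  rows <- mapply(function(name, mi, ns) {
    obs <- score(mi)
    mu <- mean(ns)
    sdv <- if (exact) sqrt(mean((ns - mu)^2)) else stats::sd(ns)
    z <- if (sdv > 0) (obs - mu) / sdv else
      if (isTRUE(all.equal(obs, mu))) 0 else NA_real_
    data.frame(pathway = name, n_members = length(mi), flux_score = obs,
               null_mean = mu, null_sd = sdv, z = z,
               stringsAsFactors = FALSE)
  }, names(members), members, null_scores, SIMPLIFY = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(-out$z), , drop = FALSE]
}
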