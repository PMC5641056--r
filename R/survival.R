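#' Univariate Cox proportional-hazards fit
#'
#' Maximizes the Cox partial likelihood for a single covariate by
#' Newton-Raphson, with Efron's approximation for tied event times. The
#' standard error comes from the observed information at the maximum.
#'
#' @param time positive follow-up times.
#' @param event 0/1 event indicator.
#' @param x numeric covariate.
#' @param max_iter Newton-Raphson iteration cap; non-convergence is
#'   flagged, not an error.
#' @param tol convergence tolerance on the score.
#' @return list with \code{coef}, \code{se}, \code{z}, \code{loglik},
#'   \code{n_events}, \code{converged}.
#' @export
coxUnivariate <- function(time, event, x, max_iter = 50, tol = 1e-9) {
  stopifnot(length(time) == length(event), length(x) == length(time))
  ok <- is.finite(time) & is.finite(x) & event %in% c(0, 1)
  time <- time[ok]; event <- event[ok]; x <- x[ok]
  if (sum(event) < 1) stop("no events")
  if (stats::sd(x) == 0) stop("zero-variance covariate")
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  ev_times <- unique(time[event == 1])

  scoreInfo <- function(beta) {
    eta <- beta * x
    w <- exp(eta)
    U <- 0; I <- 0; ll <- 0
    for (tj in ev_times) {
      R <- time >= tj
      D <- time == tj & event == 1
      dj <- sum(D)
      s0r <- sum(w[R]); s1r <- sum(w[R] * x[R]); s2r <- sum(w[R] * x[R]^2)
      s0d <- sum(w[D]); s1d <- sum(w[D] * x[D]); s2d <- sum(w[D] * x[D]^2)
      ll <- ll + sum(eta[D])
      U <- U + sum(x[D])
      for (l in seq_len(dj) - 1) {
        a <- l / dj
        s0 <- s0r - a * s0d; s1 <- s1r - a * s1d; s2 <- s2r - a * s2d
        ll <- ll - log(s0)
        U <- U - s1 / s0
        I <- I + s2 / s0 - (s1 / s0)^2
      }
    }
    list(U = U, I = I, ll = ll)
  }

  beta <- 0; converged <- FALSE; si <- scoreInfo(beta)
  for (it in seq_len(max_iter)) {
    if (si$I <= 0) break
    step <- si$U / si$I
    beta <- beta + step
    si <- scoreInfo(beta)
    if (abs(si$U) < tol || abs(step) < tol) { converged <- TRUE; break }
  }
  se <- if (si$I > 0) 1 / sqrt(si$I) else NA_real_
  list(coef = beta, se = se, z = beta / se, loglik = si$ll,
       n_events = sum(event), converged = converged)
}

#' Per-gene Cox screening
#'
#' Fits a univariate Cox model per gene on the standardized log2(count+1)
#' expression, so coefficients are log hazard ratios per expression SD
#' and comparable genome-wide.
#'
#' @param cohort an \linkS4class{OncoCohort} with expression and clinical
#'   layers.
#' @param gene_set genes to screen (default: all).
#' @param min_events minimum number of events required in the cohort.
#' @return data.frame with \code{gene}, \code{coef}, \code{se}, \code{z},
#'   \code{n_events}, \code{converged}; zero-variance genes are dropped.
#' @export
coxPerGene <- function(cohort, gene_set = NULL, min_events = 10) {
  cl <- clinicalData(cohort)
  if (is.null(cl)) stop("cohort has no clinical layer")
  if (is.null(exprMatrix(cohort))) stop("cohort has no expression layer")
  if (sum(cl$event) < min_events)
    stop("fewer than ", min_events, " events in cohort")
  if (is.null(gene_set)) gene_set <- cohortGenes(cohort)
  le <- log2(exprMatrix(cohort)[gene_set, , drop = FALSE] + 1)
  rows <- lapply(gene_set, function(g) {
    xv <- le[g, ]
    if (stats::sd(xv, na.rm = TRUE) == 0 || all(is.na(xv))) return(NULL)
    z <- as.numeric(scale(xv))
    fit <- coxUnivariate(cl$time_days, cl$event, z)
    data.frame(gene = g, coef = fit$coef, se = fit$se, z = fit$z,
               n_events = fit$n_events, converged = fit$converged,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Kaplan-Meier product-limit estimate
#'
#' @param time positive follow-up times.
#' @param event 0/1 event indicator.
#' @return data.frame with one row per distinct event time: \code{time},
#'   \code{n_risk}, \code{n_event}, \code{survival}. With no events the
#'   curve is flat at 1.
#' @export
kmEstimate <- function(time, event) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  et <- unique(time[event == 1])
  surv <- 1
  rows <- lapply(et, function(tj) {
    n_risk <- sum(time >= tj)
    n_event <- sum(time == tj & event == 1)
    data.frame(time = tj, n_risk = n_risk, n_event = n_event)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(time = numeric(0), n_risk = integer(0),
                      n_event = integer(0), survival = numeric(0)))
  out$survival <- cumprod(1 - out$n_event / out$n_risk)
  out
}

#' Log-rank test across groups
#'
#' Standard (Mantel-Haenszel) log-rank chi-square comparing the survival
#' experience of two or more groups; two groups use the
#' observed-minus-expected form with hypergeometric variance.
#'
#' @param time,event follow-up and status vectors.
#' @param group group factor.
#' @return list with \code{chisq}, \code{df}, \code{p_value}; with no
#'   events the statistic is \code{NA} and \code{flagged} is TRUE.
#' @export
logRankTest <- function(time, event, group) {
  group <- as.factor(group)
  k <- nlevels(group)
  if (k < 2) stop("need at least 2 groups")
  if (sum(event) == 0)
    return(list(chisq = NA_real_, df = k - 1L, p_value = NA_real_,
                flagged = TRUE))
  et <- sort(unique(time[event == 1]))
  OmE <- rep(0, k); V <- matrix(0, k, k)
  for (tj in et) {
    at_risk <- time >= tj
    n <- sum(at_risk)
    d <- sum(time == tj & event == 1)
    ng <- tabulate(group[at_risk], nbins = k)
    dg <- tabulate(group[time == tj & event == 1], nbins = k)
    e <- d * ng / n
    OmE <- OmE + dg - e
    if (n > 1) {
      vfac <- d * (n - d) / (n - 1)
      V <- V + vfac * (diag(ng / n, k) - (ng / n) %o% (ng / n))
    }
  }
  idx <- seq_len(k - 1)
  Vi <- V[idx, idx, drop = FALSE]
  chisq <- tryCatch(
    as.numeric(t(OmE[idx]) %*% solve(Vi) %*% OmE[idx]),
    error = function(e) NA_real_)
  list(chisq = chisq, df = k - 1L,
       p_value = stats::pchisq(chisq, k - 1, lower.tail = FALSE),
       flagged = !is.finite(chisq))
}

#' Kaplan-Meier curves split by a gene's expression
#'
#' Splits samples at the median (two groups) or into tertiles (three
#' groups) of the gene's log2 expression and returns the product-limit
#' curves with a log-rank comparison.
#'
#' @param cohort an \linkS4class{OncoCohort} with expression and clinical
#'   layers.
#' @param gene gene identifier.
#' @param split \code{"median"} or \code{"tertile"}.
#' @param min_group minimum samples per group.
#' @return list with \code{curves} (named list of KM data.frames),
#'   \code{logrank} (see \code{\link{logRankTest}}) and \code{groups}
#'   (per-sample assignment).
#' @export
kmCurves <- function(cohort, gene, split = c("median", "tertile"),
                     min_group = 5) {
  split <- match.arg(split)
  cl <- clinicalData(cohort)
  if (is.null(cl)) stop("cohort has no clinical layer")
  xv <- log2(exprMatrix(cohort)[gene, ] + 1)
  grp <- if (split == "median") {
    factor(ifelse(xv > stats::median(xv), "high", "low"),
           levels = c("low", "high"))
  } else {
    q <- stats::quantile(xv, c(1 / 3, 2 / 3), type = 7)
    cut(xv, breaks = c(-Inf, q, Inf),
        labels = c("low", "medium", "high"))
  }
  if (any(table(grp) < min_group)) stop("degenerate expression split")
  curves <- lapply(levels(grp), function(g)
    kmEstimate(cl$time_days[grp == g], cl$event[grp == g]))
  names(curves) <- levels(grp)
  list(curves = curves,
       logrank = logRankTest(cl$time_days, cl$event, grp),
       groups = stats::setNames(as.character(grp), cl$sample))
}

#' Stratify dosage correlations by Cox survival class
#'
#' Groups genes into survival classes by their Cox z-score -- better
#' prognosis (z < -z_cut), poor prognosis (z > z_cut), and NS
#' (|z| <= z_cut, boundary inclusive) -- and summarizes the distribution
#' of CNV-mRNA correlations in each, together with the genome-wide
#' Spearman rank correlation of dosage correlation against z.
#'
#' @param cox data.frame from \code{\link{coxPerGene}}.
#' @param cr a \linkS4class{CRClassification} (or named vector of
#'   dosage correlations).
#' @param z_cut z-score magnitude delimiting the NS band.
#' @return list with \code{summary} (one row per group: n, median,
#'   quartiles of the dosage correlation; empty groups marked absent) and
#'   \code{spearman_rho}.
#' @export
stratifyByCR <- function(cox, cr, z_cut = 2) {
  r <- if (is(cr, "CRClassification")) {
    stats::setNames(crTable(cr)$r, crTable(cr)$gene)
  } else cr
  shared <- intersect(cox$gene, names(r))
  z <- stats::setNames(cox$z, cox$gene)[shared]
  rv <- r[shared]
  ok <- is.finite(z) & is.finite(rv)
  z <- z[ok]; rv <- rv[ok]
  grp <- ifelse(z < -z_cut, "better", ifelse(z > z_cut, "poor", "NS"))
  summ <- do.call(rbind, lapply(c("better", "NS", "poor"), function(g) {
    v <- rv[grp == g]
    if (length(v) == 0)
      data.frame(group = g, n = 0L, median = NA_real_, q1 = NA_real_,
                 q3 = NA_real_, absent = TRUE)
    else
      data.frame(group = g, n = length(v), median = stats::median(v),
                 q1 = unname(stats::quantile(v, 0.25)),
                 q3 = unname(stats::quantile(v, 0.75)), absent = FALSE)
  }))
  list(summary = summ,
       spearman_rho = stats::cor(rv, z, method = "spearman"))
}
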