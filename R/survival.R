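#' @importFrom survival Surv survfit survdiff coxph
NULL

#' Kaplan-Meier product-limit estimate
#'
#' Wraps [survival::survfit()] and reports the step function at the distinct
#' event times, the at-risk and event counts, and the median survival (the
#' first time the curve drops to 0.5 or below; undefined when it never does).
#'
#' @param times non-negative follow-up times.
#' @param events event indicators in \{0, 1\}.
#' @return list of class `kmEstimate`: `event_times`, `survival`, `at_risk`,
#'   `events`, `median_survival` (NA when undefined).
#' @export
kmCurve <- function(times, events) {
  stopifnot(length(times) == length(events), length(times) > 0L,
            all(times >= 0), all(events %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  keep <- fit$n.event > 0
  s <- fit$surv[keep]
  tt <- fit$time[keep]
  med <- if (any(s <= 0.5)) tt[which(s <= 0.5)[1L]] else NA_real_
  structure(list(event_times = tt, survival = s,
                 at_risk = fit$n.risk[keep], events = fit$n.event[keep],
                 median_survival = med), class = "kmEstimate")
}

#' Log-rank test across groups
#'
#' Standard observed-minus-expected log-rank statistic via
#' [survival::survdiff()]; df = number of groups minus one, p from the
#' chi-square upper tail. This is the single group-comparison test the whole
#' package routes through.
#'
#' @param times,events follow-up data.
#' @param group categorical group label (>= 2 non-empty groups).
#' @return list `chi2`, `df`, `p`.
#' @export
logrank <- function(times, events, group) {
  g <- droplevels(as.factor(group))
  if (nlevels(g) < 2L) stop("log-rank needs >= 2 groups")
  sd <- survival::survdiff(survival::Surv(times, events) ~ g)
  df <- nlevels(g) - 1L
  list(chi2 = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Maximizes the partial likelihood via [survival::coxph()] (Newton-Raphson;
#' Efron tie handling by default, Breslow selectable) and reports coefficients,
#' hazard ratios with 95% CIs, Wald p-values and the log partial likelihood.
#' Monotone-likelihood/separation problems surface as `converged = FALSE`.
#'
#' @param covariates samples-by-p numeric matrix (or vector for p = 1).
#' @param times,events follow-up data.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return list of class `coxFit`: `term`, `beta`, `se`, `hr`, `ci95_lo`,
#'   `ci95_hi`, `wald_p`, `loglik`, `converged`.
#' @export
coxFit <- function(covariates, times, events, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  X <- as.matrix(covariates)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (any(apply(X, 2L, stats::sd) == 0)) stop("constant covariate column")
  if (nrow(X) <= ncol(X)) stop("need more samples than covariates")
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(times, events) ~ X, ties = ties),
    warning = function(w) {
      if (grepl("converge|infinite|beta may be", conditionMessage(w))) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      }
    })
  beta <- unname(stats::coef(fit))
  se <- unname(sqrt(diag(stats::vcov(fit))))
  if (any(!is.finite(beta))) converged <- FALSE
  structure(list(term = colnames(X), beta = beta, se = se, hr = exp(beta),
                 ci95_lo = exp(beta - 1.96 * se), ci95_hi = exp(beta + 1.96 * se),
                 wald_p = unname(2 * stats::pnorm(-abs(beta / se))),
                 loglik = unname(fit$loglik[2L]), converged = converged),
            class = "coxFit")
}

#' Multigene Cox risk score with median split
#'
#' Fits a multivariate Cox model on the supplied genes, scores each sample by
#' the linear predictor \eqn{\sum_i \beta_i x_{ij}}, and dichotomizes at the
#' median risk (samples exactly at the median go to the low-risk group).
#'
#' @param expr log-scale [ICIExpression-class] or genes-by-samples matrix.
#' @param genes genes entering the model.
#' @param clinical clinical table (see [validateClinical()]) covering all
#'   samples.
#' @return list: `fit` (a `coxFit`), `risk` (named numeric), `group`
#'   (`"high"`/`"low"`), `logrank` (high-vs-low test).
#' @export
riskModel <- function(expr, genes, clinical) {
  if (methods::is(expr, "ICIExpression")) expr <- exprValues(expr)
  clinical <- validateClinical(clinical)
  miss <- setdiff(genes, rownames(expr))
  if (length(miss)) stop("genes absent from expression: ",
                         paste(miss, collapse = ", "))
  ord <- match(colnames(expr), clinical$sample_id)
  if (anyNA(ord)) stop("clinical data missing for some samples")
  cl <- clinical[ord, ]
  X <- t(expr[genes, , drop = FALSE])
  fit <- coxFit(X, cl$os_time, cl$os_event)
  risk <- as.vector(X %*% fit$beta)
  names(risk) <- colnames(expr)
  group <- ifelse(risk > stats::median(risk), "high", "low")
  list(fit = fit, risk = risk, group = group,
       logrank = logrank(cl$os_time, cl$os_event, group))
}

#' Time-dependent cumulative/dynamic AUC
#'
#' At each horizon t, cases are subjects with an event by t and controls those
#' still at risk beyond t; concordance between risk scores and case/control
#' status is weighted by inverse-probability-of-censoring weights from the
#' Kaplan-Meier estimate of the censoring distribution. Horizons beyond
#' follow-up return `NA` with a warning.
#'
#' @param risk per-sample risk score (higher = worse).
#' @param clinical clinical table aligned with `names(risk)` (or positionally
#'   when unnamed).
#' @param horizons evaluation times.
#' @return named numeric AUC per horizon.
#' @export
tdAuc <- function(risk, clinical, horizons) {
  clinical <- validateClinical(clinical)
  if (!is.null(names(risk))) {
    ord <- match(names(risk), clinical$sample_id)
    if (anyNA(ord)) stop("clinical data missing for some samples")
    clinical <- clinical[ord, ]
  }
  tt <- clinical$os_time; ev <- clinical$os_event
  # KM of the censoring distribution (events flipped)
  cfit <- survival::survfit(survival::Surv(tt, 1 - ev) ~ 1)
  G <- function(t) {
    s <- c(1, cfit$surv)[findInterval(t, c(0, cfit$time), left.open = FALSE)]
    pmax(s, 1e-10)
  }
  out <- stats::setNames(rep(NA_real_, length(horizons)), horizons)
  for (h in seq_along(horizons)) {
    t0 <- horizons[h]
    if (t0 >= max(tt)) { warning("horizon ", t0, " beyond follow-up"); next }
    case <- which(tt <= t0 & ev == 1)
    ctrl <- which(tt > t0)
    if (!length(case) || !length(ctrl)) { warning("no cases or controls at ", t0); next }
    wCase <- 1 / G(pmax(tt[case] - 1e-12, 0))
    wCtrl <- rep(1 / G(t0), length(ctrl))
    cmp <- outer(risk[case], risk[ctrl], function(a, b) (a > b) + 0.5 * (a == b))
    W <- outer(wCase, wCtrl)
    out[h] <- sum(W * cmp) / sum(W)
  }
  out
}

# Vectorized two-group log-rank chi-square for many candidate splits.
# memberships: candidates-by-n 0/1 matrix (1 = group "high").
.logrank_scan <- function(times, events, memberships) {
  et <- sort(unique(times[events == 1]))
  R <- outer(times, et, ">=") * 1          # n x m at-risk indicator
  D <- (outer(times, et, "==") & events == 1) * 1
  nTot <- colSums(R)
  dTot <- colSums(D)
  N1 <- memberships %*% R                  # cand x m at-risk in group 1
  D1 <- memberships %*% D
  E <- sweep(N1, 2L, dTot / nTot, "*")
  P1 <- sweep(N1, 2L, nTot, "/")           # share of the risk set in group 1
  V <- sweep(P1 * (1 - P1), 2L,
             dTot * (nTot - dTot) / pmax(nTot - 1, 1), "*")
  O <- rowSums(D1)
  Esum <- rowSums(E)
  Vsum <- rowSums(V)
  chi2 <- (O - Esum)^2 / Vsum
  chi2[Vsum <= 0] <- 0
  chi2
}

#' Maximally selected log-rank cutoff
#'
#' Scans every observed score value that leaves both groups at least a `floor`
#' fraction of the cohort, splitting at `score > cutoff`, and picks the cutoff
#' maximizing the two-group log-rank chi-square. Because the cutoff is chosen
#' to maximize separation, the naive log-rank p is optimistic; the
#' selection-adjusted p-value compares the maximal chi-square against its
#' permutation null (scores permuted against survival `nPerm` times, the scan
#' repeated each time).
#'
#' @param score per-sample numeric score.
#' @param clinical clinical table aligned with `names(score)` (or
#'   positionally).
#' @param floor minimum group fraction in (0, 0.5) (default 0.1).
#' @param nPerm permutations for the adjusted p (default 1000; 0 skips).
#' @param seed integer seed.
#' @return list: `cutoff`, `chi2` (maximal), `perm_p` (NA when `nPerm = 0`),
#'   `candidates`, `chi2_by_cutoff`.
#' @export
optimalCutoff <- function(score, clinical, floor = 0.1, nPerm = 1000L,
                          seed = 2020L) {
  clinical <- validateClinical(clinical)
  n <- length(score)
  if (n < 20L) stop("need >= 20 samples for cutoff selection")
  stopifnot(floor > 0, floor < 0.5)
  if (!is.null(names(score))) {
    ord <- match(names(score), clinical$sample_id)
    if (anyNA(ord)) stop("clinical data missing for some samples")
    clinical <- clinical[ord, ]
  }
  if (length(unique(score)) == 1L) stop("all scores identical")
  tt <- clinical$os_time; ev <- clinical$os_event
  minG <- ceiling(floor * n)
  cand <- sort(unique(score))
  nHigh <- vapply(cand, function(c) sum(score > c), 1L)
  keep <- nHigh >= minG & (n - nHigh) >= minG
  cand <- cand[keep]
  if (!length(cand)) stop("no cutoff leaves both groups above the floor")
  M <- t(vapply(cand, function(c) as.numeric(score > c), numeric(n)))
  chi2 <- .logrank_scan(tt, ev, M)
  best <- which.max(chi2)
  permP <- NA_real_
  if (nPerm > 0L) {
    set.seed(seed)
    obs <- chi2[best]
    exceed <- 0L
    for (b in seq_len(nPerm)) {
      sp <- sample(score)
      Mp <- t(vapply(cand, function(c) as.numeric(sp > c), numeric(n)))
      if (max(.logrank_scan(tt, ev, Mp)) >= obs) exceed <- exceed + 1L
    }
    permP <- (exceed + 1) / (nPerm + 1)
  }
  list(cutoff = cand[best], chi2 = chi2[best], perm_p = permP,
       candidates = cand, chi2_by_cutoff = chi2)
}
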