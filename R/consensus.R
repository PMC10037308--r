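#' Resampled (Monti-style) consensus clustering
#'
#' Repeatedly subsamples `ceiling(sampleFrac * n)` samples, clusters each
#' subsample into `k` groups with the base method, and records for every sample
#' pair the proportion of co-sampled runs in which the pair co-clustered.
#' Final labels come from average-linkage hierarchical clustering of
#' `1 - consensus` cut at `k`, relabelled by decreasing cluster size so labels
#' are deterministic. Pairs never co-sampled are `NA` in the consensus matrix
#' (counted in `neverCoSampled`), never silently zero; they enter the linkage
#' as maximal dissimilarity.
#'
#' @param features samples-by-features numeric matrix (rows named).
#' @param k number of clusters (`2 <= k < nrow`).
#' @param reps resampling iterations (default 1000).
#' @param sampleFrac subsampling fraction in (0, 1] (default 0.8).
#' @param base base clusterer, `"kmeans"` (default; fast and deterministic
#'   under seeding) or `"hclust"` (Ward linkage on Euclidean distance).
#' @param standardize z-score feature columns first (default TRUE).
#' @param seed integer seed.
#' @return A [ConsensusResult-class].
#' @export
consensusMatrix <- function(features, k, reps = 1000L, sampleFrac = 0.8,
                            base = c("kmeans", "hclust"), standardize = TRUE,
                            seed = 2020L) {
  base <- match.arg(base)
  features <- as.matrix(features)
  if (anyNA(features)) stop("feature matrix contains NA/NaN")
  n <- nrow(features)
  if (!(k >= 2L && k < n)) stop("need 2 <= k < n_samples")
  stopifnot(sampleFrac > 0, sampleFrac <= 1, reps >= 1L)
  if (is.null(rownames(features))) rownames(features) <- paste0("s", seq_len(n))
  if (standardize) {
    sds <- apply(features, 2L, stats::sd)
    keep <- sds > 0
    features <- scale(features[, keep, drop = FALSE])
  }
  set.seed(seed)
  m <- ceiling(sampleFrac * n)
  co <- matrix(0, n, n)
  tog <- matrix(0, n, n)
  for (r in seq_len(reps)) {
    idx <- sample.int(n, m)
    sub <- features[idx, , drop = FALSE]
    lab <- if (base == "kmeans") {
      stats::kmeans(sub, centers = k, nstart = 2L, iter.max = 30L)$cluster
    } else {
      stats::cutree(stats::hclust(stats::dist(sub), method = "ward.D2"), k = k)
    }
    M <- outer(lab, lab, "==") * 1
    co[idx, idx] <- co[idx, idx] + M
    tog[idx, idx] <- tog[idx, idx] + 1
  }
  cons <- co / tog
  cons[tog == 0] <- NA_real_
  diag(cons) <- ifelse(diag(tog) > 0, 1, NA_real_)
  dimnames(cons) <- list(rownames(features), rownames(features))
  never <- sum(is.na(cons[upper.tri(cons)]))

  d <- 1 - cons
  d[is.na(d)] <- 1
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  lab <- stats::cutree(hc, k = k)
  lab <- .relabel_by_size(lab)

  off <- cons[upper.tri(cons)]
  off <- off[!is.na(off)]
  pacv <- mean(off > 0.1 & off < 0.9)
  cdfArea <- .cdf_area(off)

  methods::new("ConsensusResult", k = as.integer(k), consensus = cons,
               labels = stats::setNames(as.integer(lab), rownames(features)),
               pac = pacv, cdfArea = cdfArea, neverCoSampled = as.integer(never))
}

.relabel_by_size <- function(lab) {
  sizes <- table(lab)
  ord <- order(-as.vector(sizes), as.integer(names(sizes)))
  map <- stats::setNames(seq_along(ord), names(sizes)[ord])
  unname(map[as.character(lab)])
}

.cdf_area <- function(x) {
  # area under the empirical CDF of consensus entries over [0, 1]
  x <- sort(x)
  n <- length(x)
  if (n == 0L) return(NA_real_)
  xs <- c(0, x, 1)
  cdf <- c(0, seq_len(n) / n, 1)
  sum(diff(xs) * cdf[-length(cdf)])
}

#' Choose the number of clusters from consensus diagnostics
#'
#' Given [consensusMatrix()] results for a range of `k`, computes the PAC
#' (proportion of ambiguous consensus entries in (0.1, 0.9)), the consensus CDF
#' area and its relative change, and selects the `k` minimizing PAC (ties go to
#' the smaller `k`). When even the best PAC exceeds 0.5 a "no structure"
#' warning is raised.
#'
#' @param results list of [ConsensusResult-class] for distinct `k` (>= 2
#'   candidates).
#' @return list: `k` (chosen), `pac`, `cdfArea`, `deltaArea` (relative change
#'   between successive `k`), `noStructure` flag.
#' @export
selectK <- function(results) {
  stopifnot(is.list(results), length(results) >= 2L)
  ks <- vapply(results, function(r) r@k, 1L)
  ord <- order(ks)
  results <- results[ord]; ks <- ks[ord]
  pacs <- vapply(results, function(r) r@pac, 1)
  areas <- vapply(results, function(r) r@cdfArea, 1)
  delta <- c(areas[1L], diff(areas) / areas[-length(areas)])
  chosen <- ks[which.min(pacs)]   # which.min takes the first (smallest k) tie
  noStructure <- min(pacs) > 0.5
  if (noStructure)
    warning("no consensus structure detected (min PAC > 0.5)")
  list(k = chosen, pac = stats::setNames(pacs, ks),
       cdfArea = stats::setNames(areas, ks),
       deltaArea = stats::setNames(delta, ks), noStructure = noStructure)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same samples; 1 is
#' identity (up to label permutation), 0 the expectation under independence.
#'
#' @param a,b label vectors of equal length.
#' @return numeric scalar.
#' @export
adjustedRandIndex <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  sumij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(length(a), 2)
  expected <- ai * bj / n2
  maxidx <- (ai + bj) / 2
  if (maxidx == expected) return(1)
  (sumij - expected) / (maxidx - expected)
}
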