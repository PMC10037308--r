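#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test of each set's overlap with the query against
#' the universe, BH-adjusted across sets. Sets are intersected with the
#' universe first; the query must be a subset of the universe.
#'
#' @param query gene ids of interest.
#' @param universe background gene ids.
#' @param sets named list of gene-id vectors (see [readGmt()]).
#' @return data.frame `set_id`, `overlap`, `set_size`, `query_size`, `p`,
#'   `p_adj`, sorted by p.
#' @export
hypergeomEnrich <- function(query, universe, sets) {
  query <- unique(query); universe <- unique(universe)
  if (!length(query) || !length(universe)) stop("empty query or universe")
  if (!all(query %in% universe)) stop("query must be a subset of the universe")
  rows <- lapply(names(sets), function(s) {
    set <- intersect(sets[[s]], universe)
    k <- length(intersect(query, set))
    p <- stats::phyper(k - 1, length(set), length(universe) - length(set),
                       length(query), lower.tail = FALSE)
    data.frame(set_id = s, overlap = k, set_size = length(set),
               query_size = length(query), p = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adj <- stats::p.adjust(res$p, "BH")
  res[order(res$p), ]
}

.gsea_es <- function(stat, inset, weightP) {
  # running-sum enrichment score over genes ordered by decreasing stat
  N <- length(stat)
  m <- sum(inset)
  if (m == N) return(list(es = 0, running = rep(0, N)))
  w <- abs(stat)^weightP
  w[!inset] <- 0
  tot <- sum(w)
  inc <- if (tot > 0) w / tot else inset / m   # all-zero stats: unweighted
  dec <- (!inset) / (N - m)
  running <- unname(cumsum(inc - dec))
  es <- running[which.max(abs(running))]
  list(es = es, running = running)
}

#' Gene Set Enrichment Analysis on a supplied ranking
#'
#' Orders genes by decreasing ranking statistic and walks the list: in-set
#' genes increment the running sum by their normalized `|stat|^weightP`
#' weight, out-of-set genes decrement by `1/(N - m)`. The enrichment score
#' (ES) is the signed maximal deviation. Significance comes from a gene-label
#' permutation null (`nPerm` resamplings of the set positions): NES is the ES
#' divided by the mean magnitude of same-sign permutation ESs, and `perm_p`
#' the same-sign exceedance fraction. With `weightP = 0` the statistic reduces
#' to the unweighted Kolmogorov-Smirnov running sum and is invariant under any
#' order-preserving transformation of the ranking.
#'
#' @param ranking named numeric per-gene ranking statistic (e.g. a moderated
#'   t between score groups).
#' @param set gene ids; singleton overlap is allowed with a warning.
#' @param weightP weight exponent (default 1).
#' @param nPerm permutations (default 1000; 0 gives ES only).
#' @param seed integer seed.
#' @return list: `es`, `nes`, `perm_p`, `overlap`, `running` (the running
#'   sum in ranking order).
#' @export
gsea <- function(ranking, set, weightP = 1, nPerm = 1000L, seed = 2020L) {
  stopifnot(!is.null(names(ranking)))
  ord <- order(ranking, decreasing = TRUE)
  stat <- ranking[ord]
  inset <- names(stat) %in% set
  m <- sum(inset)
  if (m == 0L) stop("empty intersection between set and ranked genes")
  if (m == 1L) warning("singleton set after intersection")
  obs <- .gsea_es(stat, inset, weightP)
  nes <- NA_real_; permP <- NA_real_
  if (nPerm > 0L && m < length(stat)) {
    set.seed(seed)
    null <- replicate(nPerm, {
      idx <- sample.int(length(stat), m)
      ins <- logical(length(stat)); ins[idx] <- TRUE
      .gsea_es(stat, ins, weightP)$es
    })
    same <- if (obs$es >= 0) null[null >= 0] else -null[null < 0]
    if (length(same)) {
      nes <- abs(obs$es) / mean(same) * sign(obs$es)
      permP <- (1 + sum(same >= abs(obs$es))) / (1 + length(same))
    }
  }
  list(es = obs$es, nes = nes, perm_p = permP, overlap = m,
       running = obs$running)
}
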