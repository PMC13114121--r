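#' Mutual information of each feature with the binary response
#'
#' Scores every abundance feature by its mutual information (in nats) with
#' the response label. The default estimator is the nearest-neighbor
#' estimator for a continuous covariate against a discrete label (Ross 2014,
#' the construction behind scikit-learn's `mutual_info_classif`): for each
#' sample the distance to its k-th nearest neighbor within the same class
#' sets a radius, and the number of samples of any class inside that radius
#' enters a digamma average. RPKM columns are heavily zero-inflated, so a
#' seeded micro-jitter (1e-10 of the feature SD) breaks exact ties; jitter
#' is assigned in a canonical (value, label)-sorted order, which makes the
#' scores exactly invariant to sample permutation while staying
#' reproducible from `seed`. A quantile-binned histogram plug-in estimator
#' is available as `method = "histogram"`.
#'
#' @param ab Abundance tibble (raw or standardized).
#' @param labels Label tibble (`sample_id`, `response`); joined on
#'   `sample_id`.
#' @param seed Integer seed for the jitter stream.
#' @param method `"knn"` (default) or `"histogram"`.
#' @param k Neighbor count for the knn estimator (default 3).
#' @param n_bins Bin count for the histogram estimator (default 8).
#' @return Tibble `feature_id`, `mi` (non-negative, nats), in the input
#'   feature order.
#' @references Ross, B.C. (2014) Mutual information between discrete and
#'   continuous data sets. PLoS ONE 9(2): e87357.
#' @export
mi_scores <- function(ab, labels, seed = 42, method = c("knn", "histogram"),
                      k = 3, n_bins = 8) {
  method <- match.arg(method)
  j <- join_cohort(ab, labels)
  x <- abundance_matrix(j$abundance)
  y <- j$labels$response
  n <- length(y)
  if (n < 10) abort("mi_scores needs at least 10 samples")
  if (length(unique(y)) < 2) abort("both classes must be present to score features")
  scores <- numeric(ncol(x))
  rng <- local({ set.seed(as.integer(seed)); NULL })
  for (jj in seq_len(ncol(x))) {
    v <- x[, jj]
    if (max(v) == min(v)) {
      # constant feature carries no information; keep the jitter stream in
      # step so scores of later features do not depend on earlier ones
      if (method == "knn") rnorm(n)
      scores[jj] <- 0
      next
    }
    scores[jj] <- if (method == "knn") {
      mi_knn_cd(v, y, k = k)
    } else {
      mi_histogram_cd(v, y, n_bins = n_bins)
    }
  }
  tibble::tibble(feature_id = colnames(x), mi = pmax(scores, 0))
}

# Ross (2014) continuous-discrete MI estimator for one feature.
# Jitter is drawn from the current RNG stream but assigned along the
# canonical order(value, label) ordering, so the resulting multiset of
# (value, label) pairs -- and hence the estimate -- does not depend on the
# order samples arrive in.
mi_knn_cd <- function(v, y, k = 3) {
  n <- length(v)
  jit <- rnorm(n) * 1e-10 * stats::sd(v)
  ord <- order(v, y)
  v[ord] <- v[ord] + jit
  radius <- numeric(n)
  kk <- integer(n)
  keep <- rep(TRUE, n)
  for (cls in unique(y)) {
    idx <- which(y == cls)
    m <- length(idx)
    if (m < 2) { keep[idx] <- FALSE; next }
    ki <- min(k, m - 1)
    vs <- sort(v[idx])
    pos <- match(v[idx], vs)
    # k-th smallest distance among same-class values via a +/- ki window
    cand <- matrix(Inf, m, 2 * ki)
    for (off in seq_len(ki)) {
      lo <- pos - off; hi <- pos + off
      okl <- lo >= 1; okh <- hi <= m
      cand[okl, off] <- v[idx][okl] - vs[lo[okl]]
      cand[okh, ki + off] <- vs[hi[okh]] - v[idx][okh]
    }
    radius[idx] <- apply(cand, 1, function(d) sort(d, partial = ki)[ki])
    kk[idx] <- ki
  }
  if (!any(keep)) return(0)
  vall <- sort(v)
  # strict count of points within the open interval (v - r, v + r), self included
  m_i <- findInterval(v + radius, vall, left.open = TRUE) -
    findInterval(v - radius, vall)
  ny <- table(y)[as.character(y)]
  est <- digamma(n) - mean(digamma(as.numeric(ny)[keep])) +
    mean(digamma(kk[keep])) - mean(digamma(pmax(m_i[keep], 1)))
  max(est, 0)
}

# Plug-in MI on a quantile-binned contingency table (nats).
mi_histogram_cd <- function(v, y, n_bins = 8) {
  br <- unique(quantile(v, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(br) < 2) return(0)
  b <- cut(v, breaks = br, include.lowest = TRUE)
  tab <- table(b, y)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  terms <- p * log(p / outer(px, py))
  max(sum(terms[p > 0]), 0)
}

#' Select the k top-scoring features
#'
#' @param scores Tibble from [mi_scores()] (`feature_id`, `mi`).
#' @param k Number of features to keep (the study default is 80,000;
#'   synthetic runs use small k). Values above the feature count return all
#'   features.
#' @return Character vector of feature ids in descending-score order, ties
#'   broken by ascending feature id.
#' @export
select_top_k <- function(scores, k) {
  stopifnot(k >= 1)
  ord <- order(-scores$mi, scores$feature_id)
  scores$feature_id[ord][seq_len(min(k, nrow(scores)))]
}

#' Cumulative mutual-information contribution curve
#'
#' Features are ranked by descending MI; the curve gives, at each rank, the
#' fraction of total MI carried by the top-ranked features. Used to judge
#' how many features carry most of the label information.
#'
#' @param scores Tibble from [mi_scores()].
#' @return Tibble `rank`, `feature_id`, `cumulative_fraction` — monotone
#'   non-decreasing, ending at 1.
#' @export
cumulative_mi_curve <- function(scores) {
  if (all(scores$mi <= 0)) abort("all MI scores are zero; no curve to compute")
  ord <- order(-scores$mi, scores$feature_id)
  s <- scores$mi[ord]
  tibble::tibble(rank = seq_along(s),
                 feature_id = scores$feature_id[ord],
                 cumulative_fraction = cumsum(s) / sum(s))
}
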