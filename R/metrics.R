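#' Size of the top-fraction selection target
#'
#' k is the largest integer less than or equal to `fraction * ncp`, clamped
#' to at least 1.
#'
#' @param ncp Number of candidates.
#' @param fraction Selected fraction (default 0.05, the top 5 percent).
#' @return Integer k.
#' @export
top_k <- function(ncp, fraction = 0.05) {
  stopifnot(is_count(ncp, 1L))
  max(1L, as.integer(floor(fraction * ncp)))
}

#' Rank permutation induced by predicted values
#'
#' Candidates are ordered by predicted value (GEBV) in descending order, ties
#' broken by ascending candidate index. Position i of the result holds the
#' true-value (TBV) rank of the candidate predicted to be i-th best, where
#' rank 1 is the highest TBV (TBV ties also broken by ascending index).
#' A perfect predictor yields the identity permutation.
#'
#' @param tbv Numeric vector of true values.
#' @param gebv Numeric vector of predicted values, same length.
#' @return Integer permutation of 1..length(tbv).
#' @export
rank_permutation <- function(tbv, gebv) {
  n <- length(tbv)
  if (length(gebv) != n) stop("tbv and gebv must have the same length", call. = FALSE)
  true_order <- order(-tbv, seq_len(n))
  true_rank <- integer(n)
  true_rank[true_order] <- seq_len(n)
  pred_order <- order(-gebv, seq_len(n))
  true_rank[pred_order]
}

#' Normalized discounted cumulative gain at k
#'
#' DCG of the predicted ranking divided by DCG of the ideal ranking, with
#' the linear gain f(v) = v and discount d(i) = 1/log2(i+1). Gains must be
#' positive for the score to be meaningful; if any gain entering the sums is
#' non-positive, all values are shifted by 1 - min(tbv) with a warning.
#'
#' @param tbv Numeric vector of true values.
#' @param pi Rank permutation from [rank_permutation()].
#' @param k Evaluation depth (<= length(tbv)).
#' @return NDCG\@k in (0, 1\].
#' @export
ndcg_at_k <- function(tbv, pi, k) {
  n <- length(tbv)
  stopifnot(length(pi) == n, k >= 1L, k <= n)
  v_sorted <- sort(tbv, decreasing = TRUE)
  used <- c(seq_len(k), pi[seq_len(k)])
  if (any(v_sorted[used] <= 0)) {
    shift <- 1 - min(tbv)
    warning("non-positive gains; shifting all values by ", format(shift))
    v_sorted <- v_sorted + shift
  }
  disc <- 1 / log2(seq_len(k) + 1)
  sum(v_sorted[pi[seq_len(k)]] * disc) / sum(v_sorted[seq_len(k)] * disc)
}

#' Rank correlation at k
#'
#' Pearson correlation of the pairs (i, pi_i) for i = 1..k: the correlation
#' between predicted and true ranks of the k top-predicted candidates.
#'
#' @param pi Rank permutation from [rank_permutation()].
#' @param k Evaluation depth (>= 2).
#' @return Correlation in \[-1, 1\], or NaN when the true ranks are constant.
#' @export
src_at_k <- function(pi, k) {
  if (k < 2L) stop("k must be >= 2 for a correlation", call. = FALSE)
  stopifnot(k <= length(pi))
  x <- seq_len(k)
  y <- pi[x]
  if (stats::sd(y) == 0) return(NaN)
  stats::cor(x, y)
}

#' Rank-sum ratio at k
#'
#' Sum of the ideal ranks 1..k divided by the sum of the true ranks of the k
#' top-predicted candidates. Equals 1 exactly when the predicted top-k set
#' is the true top-k set, and is otherwise in (0, 1).
#'
#' @param pi Rank permutation from [rank_permutation()].
#' @param k Evaluation depth (>= 1).
#' @return Score in (0, 1\].
#' @export
rs_ratio_at_k <- function(pi, k) {
  stopifnot(k >= 1L, k <= length(pi))
  sum(seq_len(k)) / sum(pi[seq_len(k)])
}
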