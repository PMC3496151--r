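## Cluster-robust (family) sandwich covariance.

#' Cluster-robust sandwich covariance
#'
#' Computes `A^{-1} B A^{-1}` where `A = -hessian` (the observed
#' information) and `B` is the outer-product of score sums within
#' clusters: `B = sum_c (sum_{i in c} U_i)(sum_{i in c} U_i)'`.  With
#' every cluster a singleton this is the ordinary heteroskedasticity
#' sandwich.  Used for all reported confidence intervals and Wald tests
#' to account for the non-independence of related carriers within a
#' family; likelihood-ratio tests remain model-based.
#'
#' @param scores n x p matrix of per-observation score vectors at the
#'   MLE.
#' @param hessian p x p Hessian of the log-likelihood at the MLE
#'   (negative definite).
#' @param cluster length-n cluster key (e.g. `family_id`); `NULL`
#'   treats observations as independent.
#' @param df_correction apply the finite-cluster factor `G/(G-1)`
#'   (off by default).
#' @return symmetric positive semi-definite p x p covariance matrix.
#' @export
sandwich_cov <- function(scores, hessian, cluster = NULL,
                         df_correction = FALSE) {
  scores <- as.matrix(scores)
  A <- -hessian
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop(sprintf(
      "information matrix not positive definite (condition number %.3g)",
      max(ev) / max(min(ev), .Machine$double.eps)))
  if (is.null(cluster)) cluster <- seq_len(nrow(scores))
  U <- rowsum(scores, group = as.character(cluster))
  B <- crossprod(U)
  if (df_correction) {
    G <- nrow(U)
    if (G > 1) B <- B * G / (G - 1)
  }
  Ainv <- solve(A)
  V <- Ainv %*% B %*% Ainv
  (V + t(V)) / 2
}
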