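# Exact (O(n^2)) t-distributed stochastic neighbour embedding.
# Perplexity-calibrated Gaussian input affinities (binary search on the
# per-point bandwidth), symmetrized and exaggerated early, Student-t
# output kernel, gradient descent with momentum.  Deliberately compact:
# it is used to project at most a few thousand pooled patient vectors.

tsne_affinities <- function(X, perplexity, tol = 1e-5, max_iter = 50) {
  n <- nrow(X)
  D2 <- as.matrix(dist(X))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; bmin <- -Inf; bmax <- Inf
    di <- D2[i, -i]
    for (it in seq_len(max_iter)) {
      p <- exp(-di * beta)
      s <- sum(p)
      if (s == 0) { p[] <- 1 / length(p); s <- 1 }
      H <- log(s) + beta * sum(di * p) / s
      diffH <- H - logU
      if (abs(diffH) < tol) break
      if (diffH > 0) { bmin <- beta
        beta <- if (is.finite(bmax)) (beta + bmax) / 2 else beta * 2
      } else { bmax <- beta
        beta <- if (is.finite(bmin)) (beta + bmin) / 2 else beta / 2
      }
    }
    P[i, -i] <- p / sum(p)
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

#' Project pooled patient vectors to 2D with t-SNE
#'
#' Embeds each patient's global max-pooling output vector in two
#' dimensions so that similar patients land nearby, for the
#' distribution-view scatter plot.  Fully seeded and deterministic.
#'
#' @param pooled Numeric matrix, one row per patient (>= 2 rows, finite).
#' @param seed Integer seed for the initial layout.
#' @param perplexity Effective neighbourhood size (clamped to
#'   (n - 1) / 3).
#' @param n_iter Gradient-descent iterations.
#' @param labels Optional 0/1 outcome per patient, carried through to the
#'   output.
#' @param patient_id Optional ids, carried through.
#' @return `data.frame` with columns `patient_id`, `label`, `x`, `y`.
#' @export
project_cohort <- function(pooled, seed = 1, perplexity = 30,
                           n_iter = 300, labels = NULL,
                           patient_id = NULL) {
  pooled <- as.matrix(pooled)
  n <- nrow(pooled)
  if (n < 2) stop("need at least 2 patients to project")
  if (!all(is.finite(pooled))) stop("pooled vectors must be finite")
  perplexity <- max(2, min(perplexity, (n - 1) / 3))
  P <- tsne_affinities(pooled, perplexity)
  set.seed(as.integer(seed))
  Y <- matrix(rnorm(n * 2, sd = 1e-4), n, 2)
  G <- matrix(0, n, 2)          # momentum buffer
  gains <- matrix(1, n, 2)
  eta <- 100
  for (it in seq_len(n_iter)) {
    ex <- if (it <= 100) 4 else 1      # early exaggeration
    D2 <- as.matrix(dist(Y))^2
    Qnum <- 1 / (1 + D2); diag(Qnum) <- 0
    Q <- pmax(Qnum / sum(Qnum), 1e-12)
    W <- (ex * P - Q) * Qnum
    grad <- 4 * (diag(rowSums(W)) - W) %*% Y
    mom <- if (it <= 100) 0.5 else 0.8
    gains <- ifelse(sign(grad) != sign(G), gains + 0.2, gains * 0.8)
    gains <- pmax(gains, 0.01)
    G <- mom * G - eta * gains * grad
    Y <- Y + G
    Y <- sweep(Y, 2, colMeans(Y))
  }
  data.frame(
    patient_id = if (is.null(patient_id)) as.character(seq_len(n))
                 else patient_id,
    label = if (is.null(labels)) NA_integer_ else labels,
    x = Y[, 1], y = Y[, 2])
}
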