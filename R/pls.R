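#' Partial least squares by NIPALS
#'
#' Fits a PLS model with the classical NIPALS deflation: per component an
#' X-weight vector of unit norm, scores, X- and Y-loadings, and rank-one
#' deflation of both blocks. Successive score vectors are mutually
#' orthogonal; at the full rank of X the fitted regression equals ordinary
#' least squares, which is the correctness oracle used in the tests.
#' Predictors are centered on the training means (stored in the model);
#' prediction is linear in X.
#'
#' @param X Numeric matrix, samples x features.
#' @param y Numeric response vector, or a matrix with one column per
#'   response.
#' @param n_components Number of latent components (must not exceed the
#'   rank of the centered X).
#' @param keep Optional per-component sparsity: the number of X-weight
#'   entries retained (largest absolute values; the rest set to zero)
#'   before scores are computed. `NULL` fits the dense model.
#' @param tol,max_iter NIPALS inner-iteration convergence control (only
#'   relevant for multi-column Y).
#' @return A `pls_model`: weights `W`, loadings `P`, Y-loadings `Q`,
#'   scores `T`, rotation `R` (projects centered X to scores), regression
#'   coefficients `B`, centering vectors, and the kept-feature sets.
#' @export
pls_fit <- function(X, y, n_components, keep = NULL, tol = 1e-10, max_iter = 500) {
  X <- as.matrix(X)
  Y <- as.matrix(y)
  n <- nrow(X)
  p <- ncol(X)
  m <- ncol(Y)
  if (nrow(Y) != n) abort("X and y must have the same number of rows")
  if (!is.null(keep)) {
    if (any(keep < 1)) abort("keep must be >= 1")
    if (any(keep > p)) abort("keep exceeds the feature count")
    keep <- rep_len(keep, n_components)
  }
  x_mean <- colMeans(X)
  y_mean <- colMeans(Y)
  Xc <- sweep(X, 2, x_mean)
  Yc <- sweep(Y, 2, y_mean)
  # exact rank via QR is affordable unless the matrix is wide (centering
  # makes wide matrices rank deficient, which sends the pivoted QR into
  # column cycling); for those the cheap bound plus the degeneracy check
  # inside the NIPALS loop (a zero score vector means the rank was
  # exhausted) guards the same precondition
  if (p <= max(n, 200)) {
    rank_x <- qr(Xc)$rank
    if (n_components > rank_x) {
      abort(sprintf("n_components (%d) exceeds rank of centered X (%d)",
                    n_components, rank_x))
    }
  } else if (n_components > min(n - 1, p)) {
    abort(sprintf("n_components (%d) exceeds rank of centered X (at most %d)",
                  n_components, min(n - 1, p)))
  }

  W <- matrix(0, p, n_components)
  P <- matrix(0, p, n_components)
  Q <- matrix(0, m, n_components)
  Tm <- matrix(0, n, n_components)
  kept <- vector("list", n_components)

  for (a in seq_len(n_components)) {
    u <- Yc[, which.max(colSums(Yc^2)), drop = TRUE]
    w <- NULL
    for (it in seq_len(max_iter)) {
      w <- drop(crossprod(Xc, u)) / sum(u^2)
      nw <- sqrt(sum(w^2))
      if (nw == 0) abort("degenerate component: zero X-weight vector")
      w <- w / nw
      tt <- drop(Xc %*% w)
      if (sum(tt^2) == 0) {
        abort("n_components exceeds rank of centered X (degenerate score)")
      }
      q <- drop(crossprod(Yc, tt)) / sum(tt^2)
      if (m == 1) break
      u_new <- drop(Yc %*% q) / sum(q^2)
      if (sqrt(sum((u_new - u)^2)) < tol * sqrt(sum(u_new^2))) {
        u <- u_new
        break
      }
      u <- u_new
    }
    if (!is.null(keep) && keep[a] < p) {
      thr <- sort(abs(w), decreasing = TRUE)[keep[a]]
      w[abs(w) < thr] <- 0
      # ties at the threshold: retain the first `keep` by index for
      # determinism
      nz <- which(w != 0)
      if (length(nz) > keep[a]) {
        w[setdiff(nz, head(nz[order(-abs(w[nz]), nz)], keep[a]))] <- 0
      }
      w <- w / sqrt(sum(w^2))
      tt <- drop(Xc %*% w)
      q <- drop(crossprod(Yc, tt)) / sum(tt^2)
    }
    pp <- drop(crossprod(Xc, tt)) / sum(tt^2)
    Xc <- Xc - tcrossprod(tt, pp)
    Yc <- Yc - tcrossprod(tt, q)
    W[, a] <- w
    P[, a] <- pp
    Q[, a] <- q
    Tm[, a] <- tt
    kept[[a]] <- which(w != 0)
  }

  R <- W %*% solve(crossprod(P, W))
  B <- R %*% t(Q)
  structure(
    list(
      W = W, P = P, Q = Q, scores = Tm, R = R, B = B,
      x_mean = x_mean, y_mean = y_mean,
      n_components = n_components, keep = keep, kept = kept,
      y_names = colnames(Y)
    ),
    class = "pls_model"
  )
}

#' Predict from a PLS model
#'
#' @param object A `pls_model`.
#' @param newdata Matrix of new samples (same features as training X).
#' @param type `"response"` for fitted Y values, `"scores"` for latent
#'   scores.
#' @param ncomp Number of components to use (default: all fitted).
#' @param ... Unused.
#' @return A matrix of predictions or scores.
#' @export
predict.pls_model <- function(object, newdata, type = c("response", "scores"),
                              ncomp = object$n_components, ...) {
  type <- match.arg(type)
  Xc <- sweep(as.matrix(newdata), 2, object$x_mean)
  idx <- seq_len(ncomp)
  if (type == "scores") {
    return(Xc %*% object$R[, idx, drop = FALSE])
  }
  B <- object$R[, idx, drop = FALSE] %*% t(object$Q[, idx, drop = FALSE])
  sweep(Xc %*% B, 2, object$y_mean, `+`)
}

#' @method tidy pls_model
#' @export
tidy.pls_model <- function(x, ...) {
  purrr::map_dfr(seq_len(x$n_components), function(a) {
    nz <- which(x$W[, a] != 0)
    tibble::tibble(
      component = a,
      feature = nz,
      weight = x$W[nz, a],
      loading = x$P[nz, a]
    )
  })
}

#' @method glance pls_model
#' @export
glance.pls_model <- function(x, ...) {
  tibble::tibble(
    n_components = x$n_components,
    sparse = !is.null(x$keep),
    n_selected = length(unique(unlist(x$kept)))
  )
}

class_indicator <- function(labels) {
  f <- factor(labels)
  ind <- model.matrix(~ 0 + f)
  colnames(ind) <- levels(f)
  ind
}

#' Sparse PLS discriminant analysis
#'
#' PLS on the class-indicator response with per-component truncation of
#' the X-weight vector to its `keep` largest absolute entries. Samples
#' are classified by the nearest training-class centroid in latent score
#' space (Euclidean distance over all components).
#'
#' @param X Numeric matrix, samples x features.
#' @param labels Class labels (one per row of X).
#' @param n_components Number of components; the convention is one fewer
#'   than the number of classes.
#' @param keep Number of features retained per component (`NULL` = dense
#'   PLS-DA).
#' @return An `spls_da` model (a `pls_model` plus class levels and
#'   centroids).
#' @export
spls_fit <- function(X, labels, n_components = NULL, keep = NULL) {
  f <- factor(labels)
  k <- nlevels(f)
  if (k < 2) abort("at least two classes are required")
  if (is.null(n_components)) n_components <- k - 1
  fit <- pls_fit(X, class_indicator(labels), n_components, keep = keep)
  centroids <- rowsum(fit$scores, f) / as.vector(table(f))
  fit$levels <- levels(f)
  fit$labels <- as.character(f)
  fit$centroids <- centroids
  class(fit) <- c("spls_da", class(fit))
  fit
}

#' Classify new samples with a sparse PLS-DA model
#'
#' @param object An `spls_da` model.
#' @param newdata Matrix of new samples.
#' @param type `"class"` (default) for labels, else passed to the PLS
#'   predict method.
#' @param ... Passed on.
#' @return Character vector of predicted class labels (or the PLS
#'   prediction).
#' @export
predict.spls_da <- function(object, newdata, type = "class", ...) {
  if (!identical(type, "class")) {
    return(NextMethod())
  }
  sc <- predict.pls_model(object, newdata, type = "scores")
  d2 <- outer(rowSums(sc^2), rowSums(object$centroids^2), `+`) -
    2 * sc %*% t(object$centroids)
  object$levels[max.col(-d2, ties.method = "first")]
}
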