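#' Sparse partial least-squares discriminant analysis
#'
#' Two-class sPLS-DA built from first principles. Per component, the loading
#' direction is the dominant left singular vector of the cross-covariance
#' between the (column-standardized) feature matrix and the centered one-hot
#' class indicator, soft-thresholded by absolute-value rank so that exactly
#' `keep_x` entries are nonzero (ties broken by column order), then
#' renormalized to unit length. The feature and indicator matrices are
#' deflated by each fitted component (regression mode), making successive
#' score vectors orthogonal.
#'
#' @param X Numeric matrix or data frame (n x p) of features (e.g. the 16
#'   duration-scale EPG variables, [epg_discriminant_variables()]). Columns
#'   are standardized internally; missing cells are mean-imputed with a
#'   message stating how many.
#' @param y Binary class factor (e.g. high-CT vs low-CT host genotypes).
#' @param n_components Number of latent components (default 2).
#' @param keep_x Number of variables retained per component (default 10);
#'   scalar or vector of length `n_components`.
#' @return Object of class `epg_splsda`: unit-norm sparse weights
#'   (`x_weights`, p x ncomp), regression loadings (`x_loadings`), `scores`
#'   (n x ncomp), selected variable names per component (`selected`),
#'   per-component explained variance in X (`explained_variance`), class
#'   `centroids` in score space, and the centering/scaling used.
#' @export
fit_splsda <- function(X, y, n_components = 2, keep_x = 10) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- factor(y)
  if (nlevels(y) != 2L) stop("y must have exactly two classes")
  if (length(y) != nrow(X)) stop("length(y) != nrow(X)")
  n <- nrow(X); p <- ncol(X)
  keep_x <- rep_len(keep_x, n_components)
  if (any(keep_x < 1L) || any(keep_x > p))
    stop("keep_x must lie in [1, ", p, "]")
  if (n_components > min(n - 1L, p))
    stop("n_components exceeds min(n - 1, p)")

  n_imputed <- sum(is.na(X))
  if (n_imputed) {
    message("mean-imputing ", n_imputed, " missing cell(s)")
    for (j in seq_len(p)) {
      nas <- is.na(X[, j])
      if (any(nas)) X[nas, j] <- mean(X[, j], na.rm = TRUE)
    }
  }
  x_center <- colMeans(X)
  x_scale <- apply(X, 2L, stats::sd)
  zero_var <- colnames(X)[x_scale == 0 | is.na(x_scale)]
  if (length(zero_var))
    stop("zero-variance column(s): ", paste(zero_var, collapse = ", "))
  Xs <- scale(X, center = x_center, scale = x_scale)
  Y <- stats::model.matrix(~ y - 1)
  Ys <- scale(Y)

  W <- P <- matrix(0, p, n_components,
                   dimnames = list(colnames(X), paste0("comp", 1:n_components)))
  Tm <- matrix(0, n, n_components,
               dimnames = list(rownames(X), paste0("comp", 1:n_components)))
  selected <- vector("list", n_components)
  expl <- numeric(n_components)
  ssx <- sum(Xs^2)
  Xd <- Xs; Yd <- Ys
  for (h in seq_len(n_components)) {
    M <- crossprod(Xd, Yd)
    w <- svd(M, nu = 1L, nv = 0L)$u[, 1L]
    if (keep_x[h] < p) {
      ord <- order(abs(w), decreasing = TRUE)   # stable: ties by column order
      lambda <- abs(w)[ord[keep_x[h] + 1L]]
      w <- sign(w) * pmax(abs(w) - lambda, 0)
    }
    w <- w / sqrt(sum(w^2))
    t_h <- drop(Xd %*% w)
    p_h <- drop(crossprod(Xd, t_h)) / sum(t_h^2)
    q_h <- drop(crossprod(Yd, t_h)) / sum(t_h^2)
    Xd <- Xd - tcrossprod(t_h, p_h)
    Yd <- Yd - tcrossprod(t_h, q_h)
    W[, h] <- w; P[, h] <- p_h; Tm[, h] <- t_h
    selected[[h]] <- colnames(X)[w != 0]
    expl[h] <- sum(t_h^2) * sum(p_h^2) / ssx
  }
  centroids <- apply(Tm, 2L, function(t) tapply(t, y, mean))
  structure(list(x_weights = W, x_loadings = P, scores = Tm,
                 selected = selected, explained_variance = expl,
                 centroids = centroids, classes = levels(y), y = y,
                 keep_x = keep_x, n_components = n_components,
                 x_center = x_center, x_scale = x_scale,
                 n_imputed = n_imputed),
            class = "epg_splsda")
}

#' @export
print.epg_splsda <- function(x, ...) {
  cat(sprintf("sPLS-DA: %d components, keep_x = %s, classes %s vs %s\n",
              x$n_components, paste(x$keep_x, collapse = "/"),
              x$classes[1L], x$classes[2L]))
  cat(sprintf("explained variance in X: %s\n",
              paste(sprintf("%.1f%%", 100 * x$explained_variance),
                    collapse = ", ")))
  for (h in seq_len(x$n_components))
    cat(sprintf("comp %d selected: %s\n", h,
                paste(x$selected[[h]], collapse = ", ")))
  invisible(x)
}

## Projection of new standardized data onto the latent space:
## T_new = X_new W (P'W)^{-1} reproduces training scores on training data.
splsda_project <- function(model, X_new, n_components = model$n_components) {
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != length(model$x_center))
    stop("X_new has ", ncol(X_new), " columns; model expects ",
         length(model$x_center))
  h <- seq_len(n_components)
  Xs <- scale(X_new, center = model$x_center, scale = model$x_scale)
  Xs[is.na(Xs)] <- 0    # mean-imputed under training standardization
  W <- model$x_weights[, h, drop = FALSE]
  P <- model$x_loadings[, h, drop = FALSE]
  Xs %*% W %*% solve(crossprod(P, W))
}

#' Classify new observations with a fitted sPLS-DA model
#'
#' Observations are projected into the latent score space and assigned the
#' class of the nearest class centroid (Euclidean distance) — the fixed
#' centroid decision rule.
#'
#' @param object A fitted [fit_splsda()] model.
#' @param newdata Feature matrix with the same columns as the training data.
#' @param n_components Number of leading components used (default: all).
#' @param ... Unused.
#' @return Factor of predicted classes.
#' @export
predict.epg_splsda <- function(object, newdata,
                               n_components = object$n_components, ...) {
  Tn <- splsda_project(object, newdata, n_components)
  cen <- object$centroids[, seq_len(n_components), drop = FALSE]
  d2 <- sapply(seq_len(nrow(cen)), function(k)
    rowSums(sweep(Tn, 2L, cen[k, ], `-`)^2))
  d2 <- matrix(d2, nrow = nrow(Tn))
  factor(object$classes[max.col(-d2, ties.method = "first")],
         levels = object$classes)
}

#' @rdname predict.epg_splsda
#' @param model A fitted `epg_splsda` model.
#' @param X_new Feature matrix to classify.
#' @export
classify <- function(model, X_new, n_components = model$n_components) {
  predict(model, X_new, n_components = n_components)
}

#' @export
plot.epg_splsda <- function(x, ...) {
  s <- x$scores
  if (ncol(s) < 2L) stop("need >= 2 components to plot")
  cls <- as.integer(x$y)
  plot(s[, 1L], s[, 2L], col = cls + 1L, pch = 19,
       xlab = sprintf("Component 1 (%.1f%%)", 100 * x$explained_variance[1L]),
       ylab = sprintf("Component 2 (%.1f%%)", 100 * x$explained_variance[2L]),
       main = "sPLS-DA scores", ...)
  graphics::legend("topright", legend = x$classes, col = 2:3, pch = 19)
  invisible(x)
}

#' Cross-validated misclassification rate of the sPLS-DA pipeline
#'
#' Stratified k-fold cross-validation refitting the full sparse pipeline
#' (standardization, thresholding, deflation) inside every fold, so no
#' information leaks from held-out samples. Reports the mean fold error for
#' each cumulative number of components.
#'
#' @inheritParams fit_splsda
#' @param folds Number of folds (>= 2; every class must populate every fold).
#' @param seed Integer seed fixing the fold assignment.
#' @return Numeric vector `error[h]` = CV misclassification rate using the
#'   first `h` components.
#' @export
cv_error <- function(X, y, n_components = 2, keep_x = 10, folds = 5,
                     seed = 1) {
  X <- as.matrix(X); y <- factor(y)
  stopifnot(folds >= 2L)
  if (min(table(y)) < folds)
    stop("each class needs >= `folds` observations for stratified folds")
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  err <- matrix(NA_real_, folds, n_components)
  for (f in seq_len(folds)) {
    tr <- fold != f
    m <- fit_splsda(X[tr, , drop = FALSE], y[tr],
                    n_components = n_components, keep_x = keep_x)
    for (h in seq_len(n_components)) {
      pred <- predict(m, X[!tr, , drop = FALSE], n_components = h)
      err[f, h] <- mean(pred != y[!tr])
    }
  }
  stats::setNames(colMeans(err), paste0("comp", seq_len(n_components)))
}
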