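# Sparse partial least squares in regression mode. Per component the
# weight pair (u, v) maximizes cov(X u, Y v) under cardinality budgets
# (keepX, keepY), imposed by soft-thresholding at the magnitude of the
# first excluded entry; X and Y are deflated by the X-variate (regression
# mode: Y is predicted from X).

soft_threshold_keep <- function(a, keep) {
  keep <- min(keep, length(a))
  if (keep >= length(a)) return(a)
  ab <- abs(a)
  # threshold at the (keep+1)-th largest magnitude; ties beyond the
  # budget shrink to zero together
  lambda <- sort(ab, decreasing = TRUE)[keep + 1L]
  sign(a) * pmax(ab - lambda, 0)
}

unitize <- function(x) {
  nrm <- sqrt(sum(x^2))
  if (nrm == 0) stop("all-zero weight vector: sparsity budget too tight for the data")
  x / nrm
}

#' Fit a sparse PLS regression of phenotypes on expression
#'
#' Columns of X (samples x genes) and Y (samples x phenotypes) are centred
#' and scaled to unit variance. For each of \code{n_components}: the weight
#' pair is initialized from the leading singular pair of M = X_h' Y_h and
#' iterated with alternating soft-thresholded updates until the X-weight
#' stabilizes; the X-variate t_h = X_h u_h then deflates both blocks
#' (regression mode). Each component's X-weight is oriented so its
#' largest-magnitude entry is positive, making fits run-to-run
#' deterministic.
#'
#' @param X samples x genes matrix.
#' @param Y samples x phenotypes matrix (row-aligned with X).
#' @param n_components number of latent components H (default 3).
#' @param keepX number of genes retained per component (scalar or vector
#'   of length H). Default: all genes (dense PLS).
#' @param keepY phenotypes retained per component. Default: all.
#' @param tol convergence tolerance on max |u - u_old| (default 1e-9).
#' @param max_iter iteration cap per component (default 500).
#' @return object of class \code{spls_model}: loadings (u, v), variates
#'   (t, s), centring/scaling vectors, per-component convergence info.
#' @export
fit_spls <- function(X, Y, n_components = 3, keepX = ncol(X),
                     keepY = ncol(Y), tol = 1e-9, max_iter = 500) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must be row-aligned")
  if (anyNA(X) || anyNA(Y)) stop("missing values are not supported")
  n <- nrow(X)
  if (n_components > min(n - 1, ncol(Y))) {
    stop("n_components must be <= min(samples - 1, phenotypes)")
  }
  keepX <- rep_len(keepX, n_components)
  keepY <- rep_len(keepY, n_components)

  drop_const <- function(M, nm) {
    sdv <- apply(M, 2, stats::sd)
    if (any(sdv == 0)) {
      message("dropping zero-variance ", nm, " column(s): ",
              paste(colnames(M)[sdv == 0], collapse = ", "))
    }
    M[, sdv > 0, drop = FALSE]
  }
  X <- drop_const(X, "X"); Y <- drop_const(Y, "Y")

  if (is.null(rownames(X))) {
    rownames(X) <- rownames(Y) <- sprintf("sample%03d", seq_len(n))
  }
  if (is.null(colnames(X))) colnames(X) <- sprintf("X%d", seq_len(ncol(X)))
  if (is.null(colnames(Y))) colnames(Y) <- sprintf("Y%d", seq_len(ncol(Y)))
  x_center <- colMeans(X); y_center <- colMeans(Y)
  x_scale <- apply(X, 2, stats::sd); y_scale <- apply(Y, 2, stats::sd)
  Xs <- scale(X, x_center, x_scale)
  Ys <- scale(Y, y_center, y_scale)
  Xh <- Xs; Yh <- Ys

  p <- ncol(Xs); q <- ncol(Ys)
  U <- matrix(0, p, n_components, dimnames = list(colnames(Xs), NULL))
  V <- matrix(0, q, n_components, dimnames = list(colnames(Ys), NULL))
  Tm <- matrix(0, n, n_components, dimnames = list(rownames(Xs), NULL))
  Sm <- matrix(0, n, n_components, dimnames = list(rownames(Ys), NULL))
  conv <- data.frame(component = seq_len(n_components),
                     iterations = NA_integer_, converged = NA)

  for (h in seq_len(n_components)) {
    M <- crossprod(Xh, Yh)
    sv <- svd(M, nu = 1, nv = 1)
    u <- sv$u[, 1]; v <- sv$v[, 1]
    it <- 0L; converged <- FALSE
    repeat {
      it <- it + 1L
      u_old <- u
      u <- unitize(soft_threshold_keep(M %*% v, keepX[h]))
      v <- unitize(soft_threshold_keep(crossprod(M, u), keepY[h]))
      if (max(abs(u - u_old)) < tol) { converged <- TRUE; break }
      if (it >= max_iter) break
    }
    if (!converged) {
      warning(sprintf("component %d did not converge in %d iterations",
                      h, max_iter))
    }
    # deterministic orientation: largest-|u| entry positive
    flip <- sign(u[which.max(abs(u))])
    u <- u * flip; v <- v * flip
    t_h <- drop(Xh %*% u)
    s_h <- drop(Yh %*% v)
    U[, h] <- u; V[, h] <- v; Tm[, h] <- t_h; Sm[, h] <- s_h
    conv$iterations[h] <- it; conv$converged[h] <- converged
    tt <- sum(t_h^2)
    Xh <- Xh - t_h %*% crossprod(t_h, Xh) / tt
    Yh <- Yh - t_h %*% crossprod(t_h, Yh) / tt
  }

  structure(list(u = U, v = V, variates_x = Tm, variates_y = Sm,
                 keepX = keepX, keepY = keepY,
                 n_components = n_components,
                 x_center = x_center, x_scale = x_scale,
                 y_center = y_center, y_scale = y_scale,
                 X_scaled = Xs, Y_scaled = Ys,
                 convergence = conv),
            class = "spls_model")
}

#' @export
print.spls_model <- function(x, ...) {
  cat("sparse PLS (regression mode):", x$n_components, "components,",
      nrow(x$u), "genes x", nrow(x$v), "phenotypes\n")
  cat("keepX:", paste(x$keepX, collapse = "/"),
      " keepY:", paste(x$keepY, collapse = "/"), "\n")
  invisible(x)
}

#' Project new samples onto a fitted sPLS model
#'
#' Applies the stored centring/scaling and the deflation-consistent
#' projection to produce X-variate scores for new samples.
#'
#' @param model a fitted \code{spls_model}.
#' @param X_new samples x genes matrix; columns must match the training
#'   genes (any order, matched by name when named).
#' @return samples x H matrix of t-scores.
#' @export
spls_transform <- function(model, X_new) {
  X_new <- as.matrix(X_new)
  train_cols <- rownames(model$u)
  if (!is.null(colnames(X_new))) {
    if (!setequal(colnames(X_new), train_cols)) {
      stop("X_new columns do not match training genes")
    }
    X_new <- X_new[, train_cols, drop = FALSE]
  } else if (ncol(X_new) != length(train_cols)) {
    stop("X_new has a different number of genes than the training matrix")
  }
  Xh <- scale(X_new, model$x_center, model$x_scale)
  H <- model$n_components
  scores <- matrix(0, nrow(Xh), H, dimnames = list(rownames(X_new), NULL))
  for (h in seq_len(H)) {
    t_h <- drop(Xh %*% model$u[, h])
    scores[, h] <- t_h
    t_train <- model$variates_x[, h]
    tt <- sum(t_train^2)
    # deflate with the training loadings so later components are consistent
    proj <- crossprod(t_train, model$X_scaled) / tt
    Xh <- Xh - t_h %*% proj
  }
  scores
}

#' Correlation-circle and sample coordinates of a fitted model
#'
#' For components 1..H, emits the correlation of every gene and phenotype
#' column with the X-variates (correlation-circle coordinates) and the
#' per-sample scores.
#'
#' @param model a fitted \code{spls_model}.
#' @return list: \code{genes} and \code{phenotypes} (variable x component
#'   correlation data.frames), \code{samples} (scores).
#' @export
export_coordinates <- function(model) {
  gene_cor <- suppressWarnings(stats::cor(model$X_scaled, model$variates_x))
  phen_cor <- suppressWarnings(stats::cor(model$Y_scaled, model$variates_x))
  gene_cor[is.na(gene_cor)] <- 0
  phen_cor[is.na(phen_cor)] <- 0
  comp_names <- paste0("comp", seq_len(model$n_components))
  colnames(gene_cor) <- colnames(phen_cor) <- comp_names
  scores <- model$variates_x
  colnames(scores) <- comp_names
  list(genes = data.frame(variable = rownames(gene_cor), gene_cor,
                          row.names = NULL, check.names = FALSE),
       phenotypes = data.frame(variable = rownames(phen_cor), phen_cor,
                               row.names = NULL, check.names = FALSE),
       samples = data.frame(sample = rownames(scores), scores,
                            row.names = NULL, check.names = FALSE))
}
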