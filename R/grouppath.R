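#' Grouped penalized regression paths
#'
#' Least-squares regression with a grouped penalty — group Lasso, group MCP or
#' group SCAD — so that all dummy columns of a factor (or interaction) enter
#' or leave the model together. Solved by block coordinate descent over a
#' decreasing lambda grid with warm starts. Columns are orthonormalized within
#' each group before thresholding and back-transformed afterwards, the
#' standard device that makes the groupwise update exact; the penalty on group
#' g is lambda * sqrt(K_g) * ||beta_g||_2 (K_g = group size), with MCP/SCAD
#' concavity gamma applied on the group norm. The intercept is unpenalized.
#'
#' @name grouppath
NULL

# Groupwise threshold operators on the norm of the unpenalized update z.
# lam is the group-level penalty lambda * sqrt(K_g).
group_threshold <- function(z, lam, method, gamma) {
  nz <- sqrt(sum(z^2))
  if (nz == 0) return(z)
  soft <- function(v, t) max(0, 1 - t / v)
  scale <- switch(method,
    group_lasso = soft(nz, lam),
    group_mcp = if (nz <= gamma * lam) soft(nz, lam) / (1 - 1 / gamma) else 1,
    group_scad = {
      if (nz <= 2 * lam) soft(nz, lam)
      else if (nz <= gamma * lam) soft(nz, gamma * lam / (gamma - 1)) / (1 - 1 / (gamma - 1))
      else 1
    },
    stop("unknown method: ", method)
  )
  scale * z
}

# Within-group orthonormalization: X_g = Q_g T_g with crossprod(Q_g)/n = I_r,
# r = rank(X_g). Returns Q and the back-transform matrix B (K x r) with
# beta_g = B %*% b_g. Rank-deficient groups (e.g. a level absent from the
# data) simply contribute fewer orthonormal columns.
orthonormalize_group <- function(Xg, n) {
  sv <- svd(Xg, nu = 0)
  keep <- sv$d > max(sv$d[1], 1e-12) * 1e-9
  if (!any(keep)) return(NULL)
  V <- sv$v[, keep, drop = FALSE]
  d <- sv$d[keep]
  B <- sweep(V, 2, sqrt(n) / d, "*")     # beta = B b
  Q <- Xg %*% B                           # crossprod(Q)/n = I
  list(Q = Q, B = B, r = sum(keep))
}

#' The smallest lambda that zeroes every penalized group
#' @keywords internal
lambda_max_group <- function(std) {
  r0 <- std$yc
  mx <- 0
  for (g in std$ortho) {
    if (is.null(g)) next
    z <- crossprod(g$Q, r0) / std$n
    mx <- max(mx, sqrt(sum(z^2)) / sqrt(g$K))
  }
  mx
}

# Shared standardization for a grouped design: center y, center X, and
# orthonormalize each group.
standardize_design <- function(design, y) {
  X <- design$X
  n <- nrow(X)
  groups <- design$groups
  gids <- unique(groups)
  xbar <- colMeans(X)
  Xc <- sweep(X, 2, xbar)
  ortho <- lapply(gids, function(g) {
    cols <- which(groups == g)
    o <- orthonormalize_group(Xc[, cols, drop = FALSE], n)
    if (!is.null(o)) { o$cols <- cols; o$K <- length(cols) }
    o
  })
  names(ortho) <- as.character(gids)
  list(n = n, xbar = xbar, ybar = mean(y), yc = y - mean(y),
       ortho = ortho, gids = gids, p = ncol(X), colnames = colnames(X))
}

#' Fit a grouped penalized regression path
#'
#' @param design a `grouped_design` from [build_design()], or any list with a
#'   numeric matrix `X` (no intercept column) and integer vector `groups`
#'   mapping columns to groups, plus `group_names`.
#' @param y numeric response (counts, on their raw scale).
#' @param method `"group_lasso"`, `"group_mcp"` or `"group_scad"`.
#' @param lambda optional decreasing grid; by default 100 log-spaced values
#'   from the full-shrinkage lambda down to 0.001 of it.
#' @param gamma concavity for MCP (default 3) / SCAD (default 4); ignored for
#'   the group Lasso.
#' @param nlambda,lambda_min_ratio grid shape when `lambda` is not given.
#' @param tol,max_iter block-coordinate-descent convergence control: stop when
#'   the largest coefficient change in a sweep falls below `tol`.
#' @return a `penalty_path`: matrix `beta` ((p+1) x nlambda, intercept first,
#'   original column scale), `lambda`, per-lambda `n_groups` (nonzero
#'   penalized groups), `converged` flags, `method`, `gamma`.
#' @export
fit_group_path <- function(design, y, method = c("group_lasso", "group_mcp", "group_scad"),
                           lambda = NULL, gamma = NULL,
                           nlambda = 100, lambda_min_ratio = 0.001,
                           tol = 1e-8, max_iter = 10000L) {
  method <- match.arg(method)
  if (any(!is.finite(y))) stop("y must be finite")
  if (is.null(gamma)) gamma <- if (method == "group_scad") 4 else 3
  if (method == "group_mcp" && gamma <= 1) stop("gamma must be > 1 for MCP")
  if (method == "group_scad" && gamma <= 2) stop("gamma must be > 2 for SCAD")
  std <- standardize_design(design, y)
  if (is.null(lambda)) {
    lmax <- lambda_max_group(std)
    if (lmax == 0) lmax <- 1e-8
    lambda <- exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = nlambda))
  } else {
    if (is.unsorted(rev(lambda))) stop("lambda grid must be decreasing")
  }
  nl <- length(lambda)

  # state: b (orthonormal scale) per group; residual of centered problem
  b <- lapply(std$ortho, function(g) if (is.null(g)) NULL else numeric(g$r))
  r <- std$yc
  beta <- matrix(0, std$p + 1L, nl,
                 dimnames = list(c("(Intercept)", std$colnames), NULL))
  n_groups <- integer(nl)
  converged <- logical(nl)

  for (i in seq_len(nl)) {
    lam <- lambda[i]
    ok <- FALSE
    for (it in seq_len(max_iter)) {
      delta <- 0
      for (gi in seq_along(std$ortho)) {
        g <- std$ortho[[gi]]
        if (is.null(g)) next
        bold <- b[[gi]]
        z <- as.vector(crossprod(g$Q, r)) / std$n + bold
        bnew <- if (lam > 0)
          group_threshold(z, lam * sqrt(g$K), method, gamma) else z
        db <- bnew - bold
        if (any(db != 0)) {
          r <- r - g$Q %*% db
          b[[gi]] <- bnew
          delta <- max(delta, max(abs(db)))
        }
      }
      if (delta < tol) { ok <- TRUE; break }
    }
    converged[i] <- ok
    # back-transform to the original column scale
    bcol <- numeric(std$p)
    ng <- 0L
    for (gi in seq_along(std$ortho)) {
      g <- std$ortho[[gi]]
      if (is.null(g)) next
      if (any(b[[gi]] != 0)) ng <- ng + 1L
      bcol[g$cols] <- g$B %*% b[[gi]]
    }
    beta[1, i] <- std$ybar - sum(std$xbar * bcol)
    beta[-1, i] <- bcol
    n_groups[i] <- ng
  }
  if (!all(converged))
    warning(sum(!converged), " lambda value(s) did not converge in ",
            max_iter, " sweeps")
  structure(list(beta = beta, lambda = lambda, n_groups = n_groups,
                 converged = converged, method = method, gamma = gamma,
                 groups = design$groups, group_names = design$group_names),
            class = "penalty_path")
}

#' Predict from a penalized path
#'
#' @param object a `penalty_path`.
#' @param newx design matrix without intercept, columns as in the fit.
#' @param lambda_index column(s) of the path to use; default all.
#' @param ... unused.
#' @return matrix n x length(lambda_index) of linear predictions.
#' @export
predict.penalty_path <- function(object, newx, lambda_index = NULL, ...) {
  idx <- if (is.null(lambda_index)) seq_along(object$lambda) else lambda_index
  cbind(1, newx) %*% object$beta[, idx, drop = FALSE]
}

#' Nonzero penalized groups at one lambda
#' @param path a `penalty_path`.
#' @param lambda_index path column.
#' @return character vector of group names with any nonzero coefficient.
#' @export
selected_groups <- function(path, lambda_index) {
  bc <- path$beta[-1, lambda_index]
  gids <- unique(path$groups)
  sel <- vapply(gids, function(g) any(bc[path$groups == g] != 0), logical(1))
  path$group_names[gids[sel]]
}

#' Cross-validate the regularization parameter
#'
#' Ten-fold (by default) cross-validation of held-out squared error over the
#' lambda grid computed on the full data; the selected `lambda_star` minimizes
#' the mean cross-validation error.
#'
#' @inheritParams fit_group_path
#' @param nfolds number of folds (default 10).
#' @param seed integer; fold assignment is seeded and reproducible.
#' @return list with `lambda`, `cve` (mean held-out MSE per lambda), `cvse`
#'   (SD across folds of the per-fold MSE), `lambda_star`, `index_star`, and
#'   the full-data `fit` at the same grid.
#' @export
cross_validate_lambda <- function(design, y, method = "group_lasso",
                                  nfolds = 10L, seed = 1L, gamma = NULL,
                                  lambda = NULL, nlambda = 100,
                                  lambda_min_ratio = 0.001) {
  n <- nrow(design$X)
  if (n < nfolds) stop("need at least as many observations as folds")
  fit <- fit_group_path(design, y, method, lambda = lambda, gamma = gamma,
                        nlambda = nlambda, lambda_min_ratio = lambda_min_ratio)
  lambda <- fit$lambda
  folds <- with_seed(seed, sample(rep_len(seq_len(nfolds), n)))
  per_fold <- matrix(NA_real_, nfolds, length(lambda))
  for (k in seq_len(nfolds)) {
    test <- folds == k
    if (!any(test) || all(test)) stop("fold with zero rows")
    sub <- design
    sub$X <- design$X[!test, , drop = FALSE]
    fk <- fit_group_path(sub, y[!test], method, lambda = lambda, gamma = gamma)
    pred <- predict(fk, design$X[test, , drop = FALSE])
    per_fold[k, ] <- colMeans((y[test] - pred)^2)
  }
  cve <- colMeans(per_fold)
  cvse <- apply(per_fold, 2, stats::sd)
  index_star <- which.min(cve)
  list(lambda = lambda, cve = cve, cvse = cvse,
       lambda_star = lambda[index_star], index_star = index_star,
       fit = fit, nfolds = nfolds, seed = seed, method = method)
}

#' Test-set prediction accuracy
#'
#' The headline accuracy measure is root-mean-square error on the count scale
#' (`type = "rmse"`); a variance-normalized alternative (MSE divided by the
#' population variance of the test response) is available as `type = "nmse"`.
#'
#' @param y observed test responses.
#' @param yhat predictions.
#' @param type `"rmse"` (default) or `"nmse"`.
#' @return a single number.
#' @export
evaluate_smse <- function(y, yhat, type = c("rmse", "nmse")) {
  type <- match.arg(type)
  if (length(y) == 0L) stop("test set is empty")
  mse <- mean((y - yhat)^2)
  if (type == "rmse") sqrt(mse) else mse / mean((y - mean(y))^2)
}
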