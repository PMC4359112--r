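#' Entrywise soft-thresholding
#'
#' Proximal operator of `tau * ||Y||_1`: shrinks every entry of `A`
#' toward zero by `tau`, i.e. `sign(a) * max(|a| - tau, 0)`.  This is
#' the closed-form solution of the sparse-foreground subproblem inside
#' the ADMM decomposition.
#'
#' @param A Numeric matrix (or vector).
#' @param tau Single nonnegative threshold.
#' @return Matrix of the same shape as `A`.
#' @examples
#' soft_threshold(matrix(c(3, -0.5), 1), 1)
#' @export
soft_threshold <- function(A, tau) {
  .check_scalar(tau, "tau", nonneg = TRUE)
  A <- .as_expr_matrix(A, "A")
  sign(A) * pmax(abs(A) - tau, 0)
}

#' Euclidean projection onto a Frobenius-norm ball
#'
#' Returns `A` unchanged when `||A||_F <= delta`, otherwise rescales it
#' to Frobenius norm `delta`.  With `delta = 0` the result is the zero
#' matrix.  Solves the noise subproblem `argmin_{||Z||_F <= delta}
#' ||Z - A||_F` of the ADMM decomposition.
#'
#' @param A Numeric matrix.
#' @param delta Single nonnegative radius (Frobenius norm units).
#' @return Matrix of the same shape with `||.||_F <= delta`.
#' @export
project_frobenius_ball <- function(A, delta) {
  .check_scalar(delta, "delta", nonneg = TRUE)
  A <- .as_expr_matrix(A, "A")
  nrm <- sqrt(sum(A^2))
  if (nrm <= delta) A else A * (delta / max(nrm, .Machine$double.xmin))
}

#' Closed-form background update (row-wise mean)
#'
#' The background subproblem of the augmented Lagrangian,
#' `argmin_x gamma/2 * ||x %o% 1 - R||_F^2`, is separable by gene and
#' minimized by the row-wise mean of `R`.  The caller assembles
#' `R = M - Y - Z + D/gamma`.
#'
#' @param R Numeric matrix (m genes by n samples).
#' @return Numeric vector of length `nrow(R)`.
#' @export
update_background <- function(R) {
  R <- .as_expr_matrix(R, "R")
  rowMeans(R)
}

#' Singular-value thresholding
#'
#' Proximal operator of `tau * ||X||_*` (nuclear norm): computes the
#' SVD of `A` and shrinks every singular value by `tau`, dropping those
#' below it.  This is the low-rank background update of the
#' multi-condition decomposition.
#'
#' @param A Numeric matrix.
#' @param tau Single nonnegative threshold.
#' @return Matrix of the same shape as `A`.
#' @export
singular_value_threshold <- function(A, tau) {
  .check_scalar(tau, "tau", nonneg = TRUE)
  A <- .as_expr_matrix(A, "A")
  s <- svd(A)
  d <- pmax(s$d - tau, 0)
  keep <- d > 0
  if (!any(keep)) return(array(0, dim(A), dimnames = dimnames(A)))
  out <- s$u[, keep, drop = FALSE] %*% (d[keep] * t(s$v[, keep, drop = FALSE]))
  dimnames(out) <- dimnames(A)
  out
}

#' Common-background and sparse-foreground decomposition (ADMM)
#'
#' Decomposes a genes-by-samples matrix `M` into `x %o% 1 + Y + Z`
#' where the background has every column equal to the per-gene vector
#' `x`, the foreground `Y` has minimal L1 norm, and the noise `Z` is
#' bounded by `||Z||_F <= delta`:
#'
#' \deqn{\min \|Y\|_1 \quad s.t.\; x\iota + Y + Z = M,\; \|Z\|_F \le \delta}
#'
#' The convex program is solved by the alternating direction method of
#' multipliers: closed-form sequential updates of `x` (row means), `Y`
#' (soft-thresholding at `1/gamma`), `Z` (projection onto the
#' Frobenius ball) and a dual ascent step on the multiplier `D`.
#' Initialization is `Y = Z = D = 0`, so the solver is deterministic.
#'
#' Iterations stop when the relative primal residual
#' `||x.1 + Y + Z - M||_F / max(1, ||M||_F)` falls below `tol` *and*
#' the relative change of the objective `||Y||_1` falls below `tol`,
#' or at `max_iter` (with a warning; the result is then flagged
#' `converged = FALSE`).
#'
#' When `delta >= ||M - rowMeans(M) %o% 1||_F`, the noise term alone can
#' absorb all deviation from a row-constant matrix and the optimum is
#' `Y = 0`; this degenerate regime is valid input, not an error.
#'
#' @param M Numeric genes-by-samples matrix (see [expression_matrix()]).
#' @param delta Nonnegative noise budget (Frobenius norm units, on the
#'   scale of `M`'s entries; it is data-scale dependent and has no
#'   universal default).
#' @param gamma Positive ADMM penalty parameter.  Default
#'   `1/mean(abs(M))`, which scales the soft-threshold `1/gamma` to the
#'   magnitude of the data.
#' @param tol Relative convergence tolerance (default `1e-6`).
#' @param max_iter Iteration cap (default 2000).
#' @param init Optional list with starting values `Y`, `Z`, `D`.
#' @return An object of class `"csd"`: list with background vector `x`,
#'   foreground `Y`, noise `Z`, multiplier `D`, `delta`, `gamma`,
#'   `iterations`, `converged`, `objective` (`||Y||_1`) and
#'   `primal_residual_trace` (per-iteration `||x.1 + Y + Z - M||_F`).
#' @examples
#' toy <- generate_fig1_toy(seed = 1)
#' fit <- decompose_common_vector(toy$M, delta = 0, tol = 1e-9)
#' max(abs(fit$Y - toy$foreground))
#' @seealso [decompose_multi_condition()] for the low-rank background
#'   variant, [mbi_cocluster()] for co-clustering the foreground.
#' @export
decompose_common_vector <- function(M, delta, gamma = NULL, tol = 1e-6,
                                    max_iter = 2000L, init = NULL) {
  M <- .as_expr_matrix(M, "M")
  .check_scalar(delta, "delta", nonneg = TRUE)
  .check_scalar(tol, "tol", positive = TRUE)
  max_iter <- .check_count(max_iter, "max_iter")
  if (is.null(gamma)) {
    scale <- mean(abs(M))
    gamma <- if (scale > 0) 1 / scale else 1
  }
  .check_scalar(gamma, "gamma", positive = TRUE)

  m <- nrow(M); n <- ncol(M)
  zero <- array(0, c(m, n))
  Y <- init$Y %||% zero
  Z <- init$Z %||% zero
  D <- init$D %||% zero
  stopifnot(all(dim(Y) == c(m, n)), all(dim(Z) == c(m, n)),
            all(dim(D) == c(m, n)))

  m_norm <- max(1, sqrt(sum(M^2)))
  res_trace <- numeric(max_iter)
  obj_prev <- Inf
  converged <- FALSE
  iter <- 0L

  for (k in seq_len(max_iter)) {
    iter <- k
    x <- update_background(M - Y - Z + D / gamma)
    Xb <- matrix(x, m, n)
    Y <- soft_threshold(M - Xb - Z + D / gamma, 1 / gamma)
    Z <- project_frobenius_ball(M - Xb - Y + D / gamma, delta)
    R <- Xb + Y + Z - M
    D <- D - gamma * R
    res_trace[k] <- sqrt(sum(R^2))
    obj <- sum(abs(Y))
    if (res_trace[k] / m_norm < tol &&
        abs(obj - obj_prev) <= tol * max(1, obj)) {
      converged <- TRUE
      break
    }
    obj_prev <- obj
  }
  if (!converged)
    warning(sprintf(
      "ADMM did not meet tol = %g within %d iterations (relative residual %g)",
      tol, max_iter, res_trace[iter] / m_norm), call. = FALSE)

  dimnames(Y) <- dimnames(Z) <- dimnames(D) <- dimnames(M)
  names(x) <- rownames(M)
  structure(list(
    x = x, Y = Y, Z = Z, D = D,
    delta = delta, gamma = gamma, tol = tol,
    iterations = iter, converged = converged,
    objective = sum(abs(Y)),
    primal_residual_trace = res_trace[seq_len(iter)],
    gene_ids = rownames(M), sample_ids = colnames(M)
  ), class = "csd")
}

#' @export
print.csd <- function(x, ...) {
  cat("Common-background / sparse-foreground decomposition (ADMM)\n")
  cat(sprintf("  %d genes x %d samples; delta = %g, gamma = %g\n",
              length(x$x), ncol(x$Y), x$delta, x$gamma))
  cat(sprintf("  iterations: %d (%s); ||Y||_1 = %g; final residual = %g\n",
              x$iterations,
              if (x$converged) "converged" else "NOT converged",
              x$objective, utils::tail(x$primal_residual_trace, 1)))
  cat(sprintf("  foreground support: %d / %d entries nonzero\n",
              sum(x$Y != 0), length(x$Y)))
  invisible(x)
}

#' Background matrix of a decomposition
#'
#' Expands the per-gene background vector `x` to the full rank-one
#' matrix `x %o% 1` (every column equal to `x`).
#'
#' @param fit A `"csd"` object.
#' @return Numeric matrix of the same shape as the input data.
#' @export
csd_background <- function(fit) {
  stopifnot(inherits(fit, "csd"))
  out <- matrix(fit$x, length(fit$x), ncol(fit$Y))
  dimnames(out) <- dimnames(fit$Y)
  out
}

#' Multi-condition low-rank background decomposition (ADMM)
#'
#' Joint decomposition of `K` same-shaped matrices `M_i` into a shared
#' background `X` plus per-condition sparse foregrounds `Y_i` and
#' bounded noise `Z_i`:
#'
#' \deqn{\min \|X\|_* + \sum_i \rho_i \|Y_i\|_1 \quad s.t.\;
#'   X + Y_i + Z_i = M_i,\; \|Z_i\|_F \le \delta}
#'
#' This is the convex relaxation of the rank + cardinality model: the
#' nuclear norm stands in for `rank(X)` and the L1 norms for the entry
#' counts of the `Y_i`.  ADMM updates: `X` by singular-value
#' thresholding at `1/(K*gamma)` of the average residual, each `Y_i` by
#' soft-thresholding at `rho_i/gamma`, each `Z_i` by ball projection,
#' one multiplier per condition.
#'
#' With `common_vector = TRUE` the background is constrained to the
#' rank-one form `x %o% 1` shared by the single-matrix model; the rank
#' is then fixed by construction, the nuclear-norm term is dropped, and
#' for `K = 1` the solution coincides with [decompose_common_vector()].
#'
#' @param M_list List of numeric matrices with identical dimensions and
#'   gene/sample ordering (a single matrix is accepted and wrapped).
#' @param rho_list Positive sparsity weights, one per condition
#'   (recycled from length 1).  Default `1/sqrt(max(m, n))`.
#' @param delta Nonnegative per-condition noise budget.
#' @param gamma Positive ADMM penalty; default `1/mean(abs(M))` over
#'   all conditions.
#' @param tol,max_iter Stopping rule as in [decompose_common_vector()].
#' @param common_vector Constrain the background to `x %o% 1`?
#' @return An object of class `"csd_multi"`: shared background `X`
#'   (and `x` when `common_vector = TRUE`), lists `Y_list`, `Z_list`,
#'   `D_list`, the weights, diagnostics and convergence flag.
#' @export
decompose_multi_condition <- function(M_list, rho_list = NULL, delta = 0,
                                      gamma = NULL, tol = 1e-6,
                                      max_iter = 2000L,
                                      common_vector = FALSE) {
  if (is.matrix(M_list) || is.data.frame(M_list)) M_list <- list(M_list)
  if (!is.list(M_list) || length(M_list) < 1L)
    stop("`M_list` must be a nonempty list of matrices", call. = FALSE)
  M_list <- lapply(M_list, .as_expr_matrix)
  K <- length(M_list)
  dims <- dim(M_list[[1L]])
  ok <- vapply(M_list, function(Mi) all(dim(Mi) == dims), logical(1))
  if (!all(ok))
    stop("all condition matrices must have identical dimensions",
         call. = FALSE)
  m <- dims[1L]; n <- dims[2L]
  .check_scalar(delta, "delta", nonneg = TRUE)
  .check_scalar(tol, "tol", positive = TRUE)
  max_iter <- .check_count(max_iter, "max_iter")
  if (is.null(rho_list)) rho_list <- 1 / sqrt(max(m, n))
  rho_list <- rep_len(as.numeric(rho_list), K)
  if (any(!is.finite(rho_list)) || any(rho_list <= 0))
    stop("`rho_list` entries must be positive", call. = FALSE)
  if (is.null(gamma)) {
    scale <- mean(vapply(M_list, function(Mi) mean(abs(Mi)), numeric(1)))
    gamma <- if (scale > 0) 1 / scale else 1
  }
  .check_scalar(gamma, "gamma", positive = TRUE)

  zero <- array(0, c(m, n))
  Y <- Z <- D <- rep(list(zero), K)
  X <- zero
  x <- NULL
  m_norm <- max(1, sqrt(sum(vapply(M_list, function(Mi) sum(Mi^2),
                                   numeric(1)))))
  res_trace <- numeric(max_iter)
  obj_prev <- Inf
  converged <- FALSE
  iter <- 0L

  for (k in seq_len(max_iter)) {
    iter <- k
    Rbar <- Reduce(`+`, Map(function(Mi, Yi, Zi, Di) Mi - Yi - Zi + Di / gamma,
                            M_list, Y, Z, D)) / K
    if (common_vector) {
      x <- update_background(Rbar)
      X <- matrix(x, m, n)
    } else {
      X <- singular_value_threshold(Rbar, 1 / (K * gamma))
    }
    res2 <- 0
    obj <- if (common_vector) 0 else sum(svd(X, nu = 0, nv = 0)$d)
    for (i in seq_len(K)) {
      Y[[i]] <- soft_threshold(M_list[[i]] - X - Z[[i]] + D[[i]] / gamma,
                               rho_list[i] / gamma)
      Z[[i]] <- project_frobenius_ball(
        M_list[[i]] - X - Y[[i]] + D[[i]] / gamma, delta)
      R <- X + Y[[i]] + Z[[i]] - M_list[[i]]
      D[[i]] <- D[[i]] - gamma * R
      res2 <- res2 + sum(R^2)
      obj <- obj + rho_list[i] * sum(abs(Y[[i]]))
    }
    res_trace[k] <- sqrt(res2)
    if (res_trace[k] / m_norm < tol &&
        abs(obj - obj_prev) <= tol * max(1, obj)) {
      converged <- TRUE
      break
    }
    obj_prev <- obj
  }
  if (!converged)
    warning(sprintf(
      "multi-condition ADMM did not meet tol = %g within %d iterations",
      tol, max_iter), call. = FALSE)

  dn <- dimnames(M_list[[1L]])
  dimnames(X) <- dn
  for (i in seq_len(K)) dimnames(Y[[i]]) <- dimnames(Z[[i]]) <- dn
  structure(list(
    X = X, x = x, Y_list = Y, Z_list = Z, D_list = D,
    rho_list = rho_list, delta = delta, gamma = gamma,
    iterations = iter, converged = converged, objective = obj_prev,
    primal_residual_trace = res_trace[seq_len(iter)],
    common_vector = common_vector
  ), class = "csd_multi")
}

#' @export
print.csd_multi <- function(x, ...) {
  cat("Multi-condition background / sparse-foreground decomposition\n")
  cat(sprintf("  K = %d conditions of %d x %d; delta = %g; rho = %s\n",
              length(x$Y_list), nrow(x$X), ncol(x$X), x$delta,
              paste(signif(x$rho_list, 3), collapse = ", ")))
  cat(sprintf("  background: %s; iterations: %d (%s)\n",
              if (x$common_vector) "rank-one x.1" else
                sprintf("rank %d", qr(x$X)$rank),
              x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

# --- argument checking helpers -------------------------------------------

.check_scalar <- function(v, name, nonneg = FALSE, positive = FALSE) {
  if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (nonneg && v < 0)
    stop(sprintf("`%s` must be nonnegative", name), call. = FALSE)
  if (positive && v <= 0)
    stop(sprintf("`%s` must be positive", name), call. = FALSE)
  invisible(v)
}

.check_count <- function(v, name) {
  if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 1)
    stop(sprintf("`%s` must be a positive integer", name), call. = FALSE)
  as.integer(v)
}
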