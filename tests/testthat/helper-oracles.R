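# Independent oracles used across the suite.  Each one recomputes a
# quantity by a route different from the package implementation
# (closed forms, brute-force enumeration, a generic NLP solver, or
# hand accumulation) so the two can be compared.

# --- convex decomposition oracles ----------------------------------------

# At delta = 0 the common-vector program reduces per gene to
# min_x sum_j |M_ij - x|: the optimum is the row median and the optimal
# objective has a closed form.
oracle_l1_objective_delta0 <- function(M) {
  sum(abs(M - apply(M, 1, stats::median)))
}

# Generic-solver oracle for delta >= 0: LP reformulation with one
# quadratic constraint (t >= |M - x.1 - Z|, ||Z||_F^2 <= delta^2),
# solved by SciPy's SLSQP through the system python.
py_csd_objective <- function(M, delta) {
  script <- file.path(tempdir(), "csd_oracle.py")
  if (!file.exists(script)) writeLines(.csd_oracle_py, script)
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  jsonlite::write_json(list(M = unname(M), delta = delta), fin,
                       auto_unbox = TRUE, digits = NA)
  status <- system2("python", c(script, fin, fout), stdout = TRUE,
                    stderr = TRUE)
  if (!file.exists(fout))
    stop("python oracle failed: ", paste(status, collapse = "\n"))
  jsonlite::fromJSON(fout)$objective
}

.csd_oracle_py <- c(
  "import json, sys",
  "import numpy as np",
  "from scipy.optimize import minimize, LinearConstraint, NonlinearConstraint",
  "spec = json.load(open(sys.argv[1]))",
  "M = np.array(spec['M'], dtype=float)",
  "delta = float(spec['delta'])",
  "m, n = M.shape",
  "mn = m * n",
  "nv = m + 2 * mn",
  "c = np.zeros(nv); c[m + mn:] = 1.0",
  "A = np.zeros((2 * mn, nv))",
  "flat = M.flatten(order='F')",
  "idx = 0",
  "for j in range(n):",
  "    for i in range(m):",
  "        A[idx, i] = 1.0; A[idx, m + idx] = 1.0; A[idx, m + mn + idx] = 1.0",
  "        A[mn + idx, i] = -1.0; A[mn + idx, m + idx] = -1.0; A[mn + idx, m + mn + idx] = 1.0",
  "        idx += 1",
  "lin = LinearConstraint(A, lb=np.concatenate([flat, -flat]), ub=np.inf)",
  "cons = [lin]",
  "if delta > 0:",
  "    def ballfun(v): return float(np.sum(v[m:m+mn]**2))",
  "    def balljac(v):",
  "        g = np.zeros(nv); g[m:m+mn] = 2*v[m:m+mn]; return g",
  "    cons.append(NonlinearConstraint(ballfun, -np.inf, delta**2, jac=balljac))",
  "    bounds = [(None,None)]*m + [(None,None)]*mn + [(0,None)]*mn",
  "else:",
  "    bounds = [(None,None)]*m + [(0.0,0.0)]*mn + [(0,None)]*mn",
  "x0 = np.median(M, axis=1)",
  "v0 = np.concatenate([x0, np.zeros(mn), np.abs(M - x0[:,None]).flatten(order='F') + 1e-3])",
  "res = minimize(lambda v: float(c @ v), v0, jac=lambda v: c, method='SLSQP',",
  "               constraints=cons, bounds=bounds,",
  "               options={'maxiter': 2000, 'ftol': 1e-14})",
  "x = res.x[:m]; Z = res.x[m:m+mn].reshape((m,n), order='F')",
  "Y = M - x[:,None] - Z",
  "json.dump({'objective': float(np.abs(Y).sum())}, open(sys.argv[2], 'w'))"
)

# Douglas-Rachford splitting for min ||X||_* + rho * ||M - X||_1
# (the K = 1, delta = 0 low-rank model), with its own prox code.
oracle_dr_nuclear_l1 <- function(M, rho, lam = 1, iters = 20000) {
  svt <- function(A, tau) {
    s <- svd(A); d <- pmax(s$d - tau, 0)
    s$u %*% (d * t(s$v))
  }
  soft <- function(A, tau) sign(A) * pmax(abs(A) - tau, 0)
  W <- M * 0
  for (i in seq_len(iters)) {
    Xg <- M - soft(M - W, lam * rho)
    Xf <- svt(2 * Xg - W, lam)
    W <- W + Xf - Xg
  }
  X <- M - soft(M - W, lam * rho)
  sum(svd(X, nu = 0, nv = 0)$d) + rho * sum(abs(M - X))
}

# Per-entry scalar-minimization oracle for the L1 prox
oracle_soft_prox <- function(A, tau) {
  out <- A
  for (k in seq_along(A)) {
    a <- A[k]
    out[k] <- stats::optimize(function(y) tau * abs(y) + 0.5 * (y - a)^2,
                              interval = c(-abs(a) - 1, abs(a) + 1),
                              tol = 1e-10)$minimum
  }
  out
}

# Subgradient optimality certificate for X* = prox of tau*||.||_* at A:
# A - X* must equal tau * (U1 V1' + W) with U1, V1 the singular vectors
# of X*'s positive part, U1'W = 0, W V1 = 0 and spectral norm of W <= 1.
svt_certificate_ok <- function(A, Xstar, tau, tol = 1e-6) {
  G <- (A - Xstar) / tau
  s <- svd(Xstar)
  pos <- s$d > tol
  U1 <- s$u[, pos, drop = FALSE]
  V1 <- s$v[, pos, drop = FALSE]
  W <- G - U1 %*% t(V1)
  ok_orth <- max(abs(t(U1) %*% W)) < tol && max(abs(W %*% V1)) < tol
  ok_norm <- max(svd(W, nu = 0, nv = 0)$d) <= 1 + tol
  ok_orth && ok_norm
}

# --- co-clustering oracles -----------------------------------------------

# brute-force block means by explicit loops
oracle_block_means <- function(A, rl, cl, k1, k2) {
  out <- matrix(0, k1, k2)
  for (g in seq_len(k1)) for (h in seq_len(k2)) {
    vals <- A[rl == g, cl == h]
    out[g, h] <- if (length(vals)) mean(vals) else 0
  }
  out
}

# naive double-loop objective
oracle_cc_objective <- function(A, rl, cl, core) {
  tot <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(ncol(A)))
    tot <- tot + (A[i, j] - core[rl[i], cl[j]])^2
  tot
}

# exhaustive global optimum over all 2-group labelings
oracle_enumerate_cocluster <- function(A, k1 = 2, k2 = 2) {
  m <- nrow(A); n <- ncol(A)
  rls <- as.matrix(expand.grid(rep(list(seq_len(k1)), m)))
  cls <- as.matrix(expand.grid(rep(list(seq_len(k2)), n)))
  best <- Inf
  for (a in seq_len(nrow(rls))) for (b in seq_len(nrow(cls))) {
    core <- oracle_block_means(A, rls[a, ], cls[b, ], k1, k2)
    o <- sum((A - core[rls[a, ], cls[b, ]])^2)
    if (o < best) best <- o
  }
  best
}

# pairwise co-assignment by explicit pair counting
oracle_pair_counts <- function(labelings) {
  n <- length(labelings[[1]])
  C <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    C[i, j] <- mean(vapply(labelings, function(l) l[i] == l[j], logical(1)))
  }
  C
}

# --- downstream oracles --------------------------------------------------

# Welch t statistic and p-value from the closed-form expressions
oracle_welch <- function(x, y) {
  v1 <- var(x) / length(x); v2 <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
  list(t = t, p = 2 * stats::pt(-abs(t), df))
}

# direct product-limit computation at the distinct event times
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(ts))
  for (k in seq_along(ts)) {
    d <- sum(time == ts[k] & event == 1)
    r <- sum(time >= ts[k])
    s <- s * (1 - d / r)
    surv[k] <- s
  }
  data.frame(time = ts, surv = surv)
}

# hand O-E / hypergeometric-variance accumulation for the log-rank test
oracle_logrank <- function(time, event, group) {
  g1 <- sort(unique(group))[1]
  ts <- sort(unique(time[event == 1]))
  OE <- 0; V <- 0
  for (tk in ts) {
    at_risk <- time >= tk
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == tk & event == 1)
    d1 <- sum(time == tk & event == 1 & group == g1)
    OE <- OE + d1 - d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- OE^2 / V
  list(statistic = stat, p = stats::pchisq(stat, 1, lower.tail = FALSE))
}

# adjusted Rand index (mclust's reference implementation)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
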