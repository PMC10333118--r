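# Simplex-constrained least squares: the inner problem of the synthetic
# control estimator.  min_w (x1 - X0 w)' diag(v) (x1 - X0 w)  s.t. w >= 0,
# sum(w) = 1.  The equality constraint is enforced by a heavily weighted
# penalty row appended to the design, which reduces the problem to plain
# non-negative least squares, solved by Lawson-Hanson (finite termination);
# the solution is renormalized onto the simplex.  A tiny ridge in the
# passive-set solves regularizes rank-deficient designs (k < J is the
# generic case) and makes the tie-break among equivalent optima
# deterministic.

#' Donor weights for a fixed predictor weighting
#'
#' Solves the inner quadratic program of the synthetic control method: finds
#' the convex combination of donor predictor columns closest (in the metric
#' `diag(v)`) to the treated unit's predictor vector.
#'
#' @param pm A predictor matrix from [build_predictors()] (list with
#'   `x_treated`, `x_donors`).
#' @param v Non-negative predictor weights summing to 1 (the V matrix
#'   diagonal).
#' @return List with `w` (donor weights on the simplex, named by donor id)
#'   and `objective` (attained weighted squared discrepancy).
#' @export
inner_weights <- function(pm, v) {
  x1 <- pm$x_treated
  X0 <- pm$x_donors
  if (any(!is.finite(x1)) || any(!is.finite(X0)) || any(!is.finite(v))) {
    stop("numeric error: non-finite predictor values", call. = FALSE)
  }
  stopifnot(length(v) == length(x1), all(v >= -1e-12))
  v <- pmax(v, 0)
  sv <- sqrt(v)
  A <- X0 * sv            # rows scaled by sqrt(v)
  b <- x1 * sv
  w <- simplex_lsq(A, b)
  names(w) <- colnames(X0)
  r <- b - A %*% w
  list(w = w, objective = drop(crossprod(r)))
}

# min ||b - A w||^2 over the probability simplex.  A penalty-row NNLS pass
# seeds the support; a primal active-set loop on the exact
# equality-constrained KKT system (step-to-boundary when a subproblem
# solution leaves the feasible region, dual-feasibility releases otherwise)
# then delivers the solution to optimizer precision.  A strict-decrease
# guard on releases rules out cycling on degenerate instances.
simplex_lsq <- function(A, b) {
  J <- ncol(A)
  if (J == 1) return(1)
  scl <- max(1, max(abs(A)), max(abs(b)))
  M <- 100 * scl      # modest penalty: conditioning beats constraint slack,
                      # the polish below restores the simplex exactly
  w0 <- nnls_lh(rbind(A, rep(M, J)), c(b, M))
  if (sum(w0) <= 0) w0 <- rep(1 / J, J)   # pathological fallback
  w0 <- w0 / sum(w0)

  H <- crossprod(A)
  cvec <- -drop(crossprod(A, b))
  eps <- 1e-11 * (mean(diag(H)) + 1)
  hscale <- max(abs(H)) + 1
  obj <- function(w) 0.5 * drop(crossprod(w, H %*% w)) + sum(cvec * w)
  eqp <- function(S, ridge = eps) {
    nf <- length(S)
    K <- rbind(cbind(H[S, S, drop = FALSE] + diag(ridge, nf), rep(1, nf)),
               c(rep(1, nf), 0))
    sol <- tryCatch(solve(K, c(-cvec[S], 1)), error = function(e) NULL)
    if (is.null(sol)) {
      sol <- qr.coef(qr(K, LAPACK = TRUE), c(-cvec[S], 1))
      sol[is.na(sol)] <- 0
    }
    z <- numeric(J)
    z[S] <- sol[seq_len(nf)]
    list(z = z, mu = sol[nf + 1])
  }

  w <- w0
  w[w < 1e-12] <- 0
  w <- w / sum(w)
  free <- which(w > 0)
  if (length(free) == 0) { w <- rep(1 / J, J); free <- seq_len(J) }
  best <- obj(w)
  best_w <- w
  pending_release <- FALSE
  for (iter in seq_len(8L * J)) {
    sol <- eqp(free)
    z <- sol$z
    if (min(z[free]) >= -1e-12) {
      w <- pmax(z, 0)
      w <- w / sum(w)
      o <- obj(w)
      if (o < best - 1e-13 * hscale) {
        best <- o
        best_w <- w
        pending_release <- FALSE
      } else if (pending_release) {
        break       # a release must strictly pay off, else we are cycling
      }
      out <- setdiff(seq_len(J), free)
      if (length(out) == 0) break
      red <- (drop(H %*% w) + cvec)[out] - sol$mu
      jm <- which.min(red)
      if (red[jm] >= -1e-10 * hscale) break
      free <- sort(c(free, out[jm]))
      pending_release <- TRUE
    } else {
      # step from w toward z until the first free coordinate hits zero
      dec <- free[z[free] < -1e-12]
      alpha <- min(w[dec] / (w[dec] - z[dec]))
      w <- w + alpha * (z - w)
      w[w < 1e-12] <- 0
      w <- w / sum(w)
      free <- which(w > 0)
      if (length(free) == 0) { w <- rep(1 / J, J); free <- seq_len(J) }
    }
  }
  # ridge-free refinement on the final support removes the regularization
  # bias when the support's KKT system is well posed
  S <- which(best_w > 0)
  if (length(S) >= 1) {
    ref <- tryCatch(eqp(S, ridge = 0), error = function(e) NULL)
    if (!is.null(ref) && all(is.finite(ref$z)) && min(ref$z[S]) >= -1e-12) {
      w_ref <- pmax(ref$z, 0)
      w_ref <- w_ref / sum(w_ref)
      if (obj(w_ref) <= best + 1e-12 * hscale) best_w <- w_ref
    }
  }
  best_w
}

# Lawson-Hanson non-negative least squares.  Passive-set solves use the
# ridge-regularized normal equations for determinism on rank-deficient sets.
nnls_lh <- function(A, b, tol = NULL) {
  J <- ncol(A)
  H <- crossprod(A)
  f <- drop(crossprod(A, b))
  eps <- 1e-10 * (mean(diag(H)) + 1)
  if (is.null(tol)) tol <- 1e-10 * (max(diag(H)) + 1)
  P <- logical(J)
  w <- numeric(J)
  g <- f                           # gradient of -0.5||b-Aw||^2 at w = 0
  solve_p <- function(P) {
    idx <- which(P)
    z <- numeric(J)
    z[idx] <- solve(H[idx, idx, drop = FALSE] + diag(eps, length(idx)),
                    f[idx])
    z
  }
  for (outer in seq_len(3L * J)) {
    cand <- which(!P & g > tol)
    if (length(cand) == 0) break
    P[cand[which.max(g[cand])]] <- TRUE
    repeat {
      z <- solve_p(P)
      if (min(z[P]) > 0) { w <- z; break }
      Q <- P & (z <= 0)
      alpha <- min(w[Q] / (w[Q] - z[Q]))
      w <- w + alpha * (z - w)
      P <- P & (w > tol * 1e-2)
      w[!P] <- 0
      if (!any(P)) break
    }
    g <- f - drop(H %*% w)
  }
  pmax(w, 0)
}
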