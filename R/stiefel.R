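# Stiefel-manifold geometry and Riemannian minimizers.
#
# St(n, R) is the set of n x R real matrices with orthonormal columns. Every
# embedding sub-problem is an unconstrained minimization over one such block,
# solved either by limited-memory Riemannian BFGS or by Riemannian steepest
# descent with Armijo backtracking.

#' Frobenius inner product
#' @noRd
frob_inner <- function(A, B) sum(A * B)

#' Frobenius norm
#' @noRd
frob_norm <- function(A) sqrt(sum(A * A))

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so callers' RNG streams are not
#' disturbed. Used by every seeded operation in the package.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    set.seed(as.integer(seed))
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
  }
  force(expr)
}

#' QR factorization with the nonnegative-diagonal sign convention
#'
#' Returns the thin Q factor of `M`, with columns flipped so the diagonal of
#' the triangular factor is nonnegative. This makes the factorization (and
#' therefore random initialization and retraction) unique and deterministic.
#'
#' @param M numeric matrix with at least as many rows as columns.
#' @return matrix with orthonormal columns, same shape as `M`.
#' @noRd
qr_positive <- function(M) {
  qr_fac <- qr(M)
  if (qr_fac$rank < ncol(M)) {
    stop("matrix is numerically rank-deficient; cannot orthonormalize",
         call. = FALSE)
  }
  Q <- qr.Q(qr_fac)
  d <- sign(diag(qr.R(qr_fac)))
  d[d == 0] <- 1
  sweep(Q, 2L, d, `*`)
}

#' Check the orthonormality invariant of a Stiefel point
#'
#' @param X numeric matrix.
#' @param tol maximum allowed elementwise deviation of `t(X) %*% X` from the
#'   identity.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
stiefel_check <- function(X, tol = 1e-10) {
  dev <- stiefel_deviation(X)
  if (is.na(dev) || dev > tol) {
    stop(sprintf("not a Stiefel point: max |X'X - I| = %.3g > %.3g", dev, tol),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Max-norm deviation of X'X from the identity
#' @export
#' @rdname stiefel_check
stiefel_deviation <- function(X) {
  max(abs(crossprod(X) - diag(ncol(X))))
}

#' Random point on the Stiefel manifold
#'
#' Draws an n x R standard-normal matrix and returns the Q factor of its QR
#' factorization (nonnegative-diagonal convention). This is the standard
#' construction of a uniformly distributed (Haar) point on St(n, R).
#'
#' @param n number of rows (embedded objects).
#' @param R number of orthonormal columns (subspace dimensionality), `R <= n`.
#' @param seed optional integer seed; when given the draw is deterministic and
#'   the caller's RNG state is left untouched.
#' @return an n x R matrix with orthonormal columns.
#' @export
random_stiefel <- function(n, R, seed = NULL) {
  if (R > n) {
    stop(sprintf("invalid dimensions: R = %d exceeds n = %d", R, n),
         call. = FALSE)
  }
  M <- with_seed(seed, matrix(stats::rnorm(n * R), nrow = n, ncol = R))
  qr_positive(M)
}

#' Project an ambient gradient onto the tangent space of St(n, R)
#'
#' For the embedded geometry, the tangent space at X is
#' \{V : sym(X'V) = 0\} and the orthogonal projection of G is
#' `G - X sym(X'G)` with `sym(A) = (A + A') / 2`.
#'
#' @param X Stiefel point (n x R, orthonormal columns).
#' @param G ambient (Euclidean) gradient, n x R.
#' @return the tangent component of `G`.
#' @export
tangent_project <- function(X, G) {
  if (!identical(dim(X), dim(G))) {
    stop("shape mismatch between point and gradient", call. = FALSE)
  }
  XtG <- crossprod(X, G)
  G - X %*% ((XtG + t(XtG)) / 2)
}

#' QR retraction on the Stiefel manifold
#'
#' Maps a point plus a tangent perturbation back onto the manifold via the
#' QR factorization of `X + V` (nonnegative-diagonal convention), restoring
#' exact orthonormality.
#'
#' @param X Stiefel point.
#' @param V perturbation matrix of the same shape.
#' @return a Stiefel point.
#' @export
qr_retract <- function(X, V) {
  if (!identical(dim(X), dim(V))) {
    stop("shape mismatch between point and perturbation", call. = FALSE)
  }
  qr_positive(X + V)
}

#' Options for the Riemannian minimizers
#'
#' @param memory_size number of curvature pairs kept by the limited-memory
#'   BFGS recursion (ignored by steepest descent).
#' @param max_iters maximum number of outer iterations of the minimizer.
#' @param grad_tol termination threshold on the Frobenius norm of the
#'   Riemannian gradient.
#' @param initial_step first trial step of the backtracking line search.
#' @param contraction multiplicative backtracking factor, in (0, 1).
#' @param sufficient_decrease Armijo sufficient-decrease constant, in (0, 1).
#' @return a list of class `kpe_optimizer_options`.
#' @export
optimizer_options <- function(memory_size = 8L,
                              max_iters = 200L,
                              grad_tol = 1e-6,
                              initial_step = 1,
                              contraction = 0.5,
                              sufficient_decrease = 1e-4) {
  stopifnot(memory_size >= 1,
            max_iters >= 0,
            grad_tol >= 0,
            initial_step > 0,
            contraction > 0, contraction < 1,
            sufficient_decrease > 0, sufficient_decrease < 1)
  structure(list(memory_size = as.integer(memory_size),
                 max_iters = as.integer(max_iters),
                 grad_tol = grad_tol,
                 initial_step = initial_step,
                 contraction = contraction,
                 sufficient_decrease = sufficient_decrease),
            class = "kpe_optimizer_options")
}

#' Signal an optimizer failure carrying its trace
#' @noRd
opt_error <- function(message, trace) {
  stop(structure(list(message = message, call = NULL, trace = trace),
                 class = c("kpe_opt_error", "error", "condition")))
}

#' Two-loop recursion: apply the implicit inverse-Hessian to g, negated
#' @noRd
two_loop_direction <- function(g, S, Y, rho) {
  m <- length(S)
  if (m == 0L) return(-g)
  q <- g
  alpha <- numeric(m)
  for (i in m:1) {
    alpha[i] <- rho[i] * frob_inner(S[[i]], q)
    q <- q - alpha[i] * Y[[i]]
  }
  gamma <- frob_inner(S[[m]], Y[[m]]) / frob_inner(Y[[m]], Y[[m]])
  r <- gamma * q
  for (i in seq_len(m)) {
    beta <- rho[i] * frob_inner(Y[[i]], r)
    r <- r + (alpha[i] - beta) * S[[i]]
  }
  -r
}

#' Shared Riemannian descent loop
#'
#' `use_memory = TRUE` gives limited-memory Riemannian BFGS: search directions
#' from the two-loop recursion on stored curvature pairs, history transported
#' between tangent spaces by orthogonal projection, pairs with non-positive
#' curvature skipped so the implicit inverse-Hessian stays positive definite.
#' `use_memory = FALSE` gives Riemannian steepest descent. Both retract with
#' QR and enforce Armijo sufficient decrease by backtracking.
#' @noRd
riemannian_descent <- function(f, grad, X0, opts, use_memory) {
  X <- X0
  fx <- f(X)
  trace <- list(objective = numeric(0), grad_norm = numeric(0),
                step = numeric(0), reason = "max_iters")
  if (!is.finite(fx)) opt_error("objective non-finite at initial point", trace)
  g <- tangent_project(X, grad(X))
  if (!all(is.finite(g))) opt_error("gradient non-finite at initial point", trace)
  gnorm <- frob_norm(g)
  trace$objective <- fx
  trace$grad_norm <- gnorm
  trace$step <- NA_real_
  iters <- 0L

  S <- list(); Y <- list(); rho <- numeric(0)
  bb_step <- opts$initial_step  # Barzilai-Borwein trial step (descent mode)

  for (k in seq_len(opts$max_iters)) {
    if (gnorm <= opts$grad_tol) {
      trace$reason <- "grad_tol"
      break
    }
    d <- if (use_memory) two_loop_direction(g, S, Y, rho) else -g
    gd <- frob_inner(g, d)
    if (!all(is.finite(d)) || gd >= 0) {
      # defective quasi-Newton direction: drop history, fall back to -g
      S <- list(); Y <- list(); rho <- numeric(0)
      d <- -g
      gd <- -gnorm^2
    }

    # quasi-Newton directions carry their own scale; raw gradient steps use
    # the Barzilai-Borwein estimate of the inverse curvature
    step <- if (use_memory) opts$initial_step else bb_step
    accepted <- FALSE
    X_new <- NULL
    f_new <- NA_real_
    while (step >= 1e-20) {
      X_try <- qr_retract(X, step * d)
      f_try <- f(X_try)
      if (is.finite(f_try) &&
          f_try <= fx + opts$sufficient_decrease * step * gd) {
        X_new <- X_try
        f_new <- f_try
        accepted <- TRUE
        break
      }
      step <- step * opts$contraction
    }
    if (!accepted) {
      trace$reason <- "line_search_failure"
      break
    }

    g_new_amb <- grad(X_new)
    if (!all(is.finite(g_new_amb))) {
      opt_error("gradient non-finite during search", trace)
    }
    g_new <- tangent_project(X_new, g_new_amb)

    # transported curvature pair at the new point
    s_k <- tangent_project(X_new, step * d)
    y_k <- g_new - tangent_project(X_new, g)
    sy <- frob_inner(s_k, y_k)
    if (use_memory) {
      # transport history into the new tangent space by projection; skip
      # pairs with non-positive curvature to keep the implicit inverse
      # Hessian positive definite
      S <- lapply(S, function(M) tangent_project(X_new, M))
      Y <- lapply(Y, function(M) tangent_project(X_new, M))
      if (sy > 1e-12 * frob_inner(s_k, s_k)) {
        S <- c(S, list(s_k))
        Y <- c(Y, list(y_k))
        rho <- c(rho, 1 / sy)
        if (length(S) > opts$memory_size) {
          S <- S[-1L]; Y <- Y[-1L]; rho <- rho[-1L]
        }
      }
    } else {
      bb_step <- if (sy > 0) frob_inner(s_k, s_k) / sy else opts$initial_step
      bb_step <- min(max(bb_step, 1e-12), 1e6)
    }

    X <- X_new
    fx <- f_new
    g <- g_new
    gnorm <- frob_norm(g)
    iters <- iters + 1L
    trace$objective <- c(trace$objective, fx)
    trace$grad_norm <- c(trace$grad_norm, gnorm)
    trace$step <- c(trace$step, step)
    if (k == opts$max_iters) trace$reason <- "max_iters"
  }
  if (gnorm <= opts$grad_tol) trace$reason <- "grad_tol"
  trace$iterations <- iters
  list(X = X, objective = fx, trace = trace)
}

#' Limited-memory Riemannian BFGS on the Stiefel manifold
#'
#' Minimizes `f` over St(n, R) starting from `X0`. `grad` must return the
#' ambient (Euclidean) gradient; its tangent projection is the Riemannian
#' gradient. Curvature history is transported by tangent-space projection,
#' iterates stay feasible through QR retraction, and steps satisfy the Armijo
#' sufficient-decrease condition, so accepted objective values never increase.
#'
#' @param f objective; takes an n x R matrix, returns a finite scalar.
#' @param grad ambient gradient of `f`; returns an n x R matrix.
#' @param X0 starting Stiefel point.
#' @param opts an [optimizer_options()] list.
#' @return list with elements `X` (final Stiefel point), `objective` (final
#'   value) and `trace` (per-iteration objective, gradient norm, step size,
#'   iteration count and termination reason).
#' @export
lrbfgs_minimize <- function(f, grad, X0, opts = optimizer_options()) {
  riemannian_descent(f, grad, X0, opts, use_memory = TRUE)
}

#' Riemannian steepest descent with Armijo line search
#'
#' Baseline minimizer: identical loop to [lrbfgs_minimize()] but the search
#' direction is the negated Riemannian gradient; typically needs many more
#' iterations on ill-conditioned problems.
#'
#' @inheritParams lrbfgs_minimize
#' @return as [lrbfgs_minimize()].
#' @export
steepest_descent_armijo <- function(f, grad, X0, opts = optimizer_options()) {
  riemannian_descent(f, grad, X0, opts, use_memory = FALSE)
}
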