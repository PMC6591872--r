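#' SVD initialization of the latent factors
#'
#' Initializes the factor pair from the rank-`k` truncated singular value
#' decomposition of `Y`: `A = U_k S_k^(1/2)`, `B = V_k S_k^(1/2)`, so that
#' `A %*% t(B)` is the best rank-`k` approximation of `Y`. Singular vectors
#' follow a deterministic sign convention (the largest-magnitude component of
#' each left singular vector is made positive, with the matching right vector
#' flipped in step), so initialization is reproducible without a seed.
#'
#' @param Y numeric matrix (n x m).
#' @param k target rank, `1 <= k <= min(n, m)`.
#' @return list with components `A` (n x k) and `B` (m x k).
#' @export
svd_init <- function(Y, k) {
  n <- nrow(Y); m <- ncol(Y)
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != round(k) || k > min(n, m)) {
    stop("`k` must be an integer in [1, min(n, m)]", call. = FALSE)
  }
  sv <- svd(Y, nu = k, nv = k)
  d <- sv$d[seq_len(k)]
  U <- sv$u; V <- sv$v
  for (j in seq_len(k)) {
    i_max <- which.max(abs(U[, j]))
    if (U[i_max, j] < 0) {
      U[, j] <- -U[, j]
      V[, j] <- -V[, j]
    }
  }
  root <- sqrt(pmax(d, 0))
  A <- U * rep(root, each = n)
  B <- V * rep(root, each = m)
  list(A = A, B = B)
}

#' Regularized factorization objective
#'
#' Evaluates the nearest-profile collaborative matrix factorization objective
#' `||Y - A B'||_F^2 + lambda_l (||A||_F^2 + ||B||_F^2) +
#'  lambda_d ||Rm - A A'||_F^2 + lambda_t ||Rd - B B'||_F^2`,
#' where `Rm`/`Rd` are the side regularizer targets: nearest-profile matrices
#' for the full model, or dense similarity/fused kernels for the collaborative
#' matrix factorization ablations.
#'
#' @param Y data matrix (n x m), typically the WKNKN-imputed associations.
#' @param A,B factor matrices (n x k, m x k).
#' @param Rm,Rd side regularizer target matrices (n x n, m x m).
#' @param lambda_l,lambda_d,lambda_t non-negative regularization weights.
#' @return a single non-negative number.
#' @export
npcmf_objective <- function(Y, A, B, Rm, Rd, lambda_l, lambda_d, lambda_t) {
  if (nrow(A) != nrow(Y) || nrow(B) != ncol(Y) || ncol(A) != ncol(B) ||
      nrow(Rm) != nrow(Y) || ncol(Rm) != nrow(Y) ||
      nrow(Rd) != ncol(Y) || ncol(Rd) != ncol(Y)) {
    stop("inconsistent matrix shapes in objective", call. = FALSE)
  }
  frob2(Y - tcrossprod(A, B)) +
    lambda_l * (frob2(A) + frob2(B)) +
    lambda_d * frob2(Rm - tcrossprod(A)) +
    lambda_t * frob2(Rd - tcrossprod(B))
}

#' One alternating least squares update
#'
#' Performs one sequential (Gauss-Seidel) fixed-point update of the factor
#' pair:
#' `A <- (Y B + lambda_d Rm A) (B'B + lambda_l I + lambda_d A'A)^(-1)` with
#' the pre-update `A` in the regularizer terms, then
#' `B <- (Y'A + lambda_t Rd B) (A'A + lambda_l I + lambda_t B'B)^(-1)` using
#' the freshly updated `A` and the pre-update `B` in its regularizer terms.
#' A singular k x k system is retried once with a `1e-10` diagonal jitter.
#'
#' @inheritParams npcmf_objective
#' @return list with updated `A` and `B`.
#' @export
als_step <- function(Y, A, B, Rm, Rd, lambda_l, lambda_d, lambda_t) {
  k <- ncol(A)
  Ik <- diag(k)
  M_a <- crossprod(B) + lambda_l * Ik + lambda_d * crossprod(A)
  A_new <- t(solve_jitter(M_a, t(Y %*% B + lambda_d * (Rm %*% A))))
  M_b <- crossprod(A_new) + lambda_l * Ik + lambda_t * crossprod(B)
  B_new <- t(solve_jitter(M_b, t(crossprod(Y, A_new) + lambda_t * (Rd %*% B))))
  list(A = A_new, B = B_new)
}

solve_jitter <- function(M, R) {
  tryCatch(solve(M, R), error = function(e) {
    tryCatch(solve(M + 1e-10 * diag(nrow(M)), R), error = function(e2) {
      stop("singular system in ALS update (after jitter retry): ",
           conditionMessage(e2), call. = FALSE)
    })
  })
}

#' Fit a nearest-profile collaborative matrix factorization model
#'
#' Factorizes a binary miRNA-disease association matrix `Y ~ A B'` with
#' similarity-based side regularization, the model underlying NPCMF
#' association prediction. The pipeline is:
#'
#' 1. GIP kernels are computed from `Y` on both sides and fused with the
#'    supplied functional/semantic similarities (`Km = alpha Sm +
#'    (1-alpha) GIPm`, likewise `Kd`); when no similarity is supplied the
#'    pure GIP kernel is used.
#' 2. Optionally, WKNKN pre-imputation fills likely-missing associations.
#' 3. Side regularizer targets are chosen by `mode`: `"nearest_profile"`
#'    (the full model) sparsifies the fused kernels to per-entity nearest
#'    neighbours; `"fused"` uses the fused kernels densely; `"semantic"` uses
#'    the supplied similarities directly (classic collaborative matrix
#'    factorization).
#' 4. Factors are initialized by truncated SVD and refined by alternating
#'    least squares until the relative objective change drops below `tol` or
#'    `max_iter` updates have run.
#'
#' @param Y binary association matrix (miRNAs x diseases), ideally with
#'   dimnames.
#' @param sim_mirna,sim_disease optional symmetric similarity matrices with
#'   unit diagonal (e.g. MISIM functional similarity; DAG semantic
#'   similarity). Required for `mode = "semantic"`.
#' @param mode side regularizer flavour, see Details.
#' @param k latent rank; default `min(50, n, m)`.
#' @param lambda_l Tikhonov weight on the factor norms; default 1.
#' @param lambda_d,lambda_t weights of the miRNA- and disease-side
#'   regularizers; default 0.01.
#' @param alpha kernel fusion weight in `[0, 1]`; default 0.5.
#' @param gamma GIP bandwidth; default 1.
#' @param wknkn logical, apply WKNKN pre-imputation; default `TRUE`.
#' @param wknkn_k,wknkn_p WKNKN neighbour count and decay; defaults 5 and 0.7.
#' @param max_iter maximum ALS updates (at least 1); default 100.
#' @param tol relative objective-change convergence tolerance; default 1e-6.
#' @return an object of class `"npcmf"`: a list with factors `A`, `B`, the
#'   kernels and regularizer targets used (`Km`, `Kd`, `Rm`, `Rd`), the
#'   imputed data matrix `Y_imputed`, `objective` (trace of length
#'   `iterations + 1`, starting at the initial value), `iterations`,
#'   `converged`, and the hyperparameters.
#' @examples
#' sim <- simulate_mda(n_mirna = 30, n_disease = 20, planted_rank = 3,
#'                     seed = 1)
#' fit <- npcmf(sim$observed, sim$sim_mirna, sim$sim_disease, k = 5)
#' fit
#' scores <- predict(fit)
#' @export
npcmf <- function(Y, sim_mirna = NULL, sim_disease = NULL,
                  mode = c("nearest_profile", "fused", "semantic"),
                  k = min(50L, nrow(Y), ncol(Y)),
                  lambda_l = 1, lambda_d = 0.01, lambda_t = 0.01,
                  alpha = 0.5, gamma = 1,
                  wknkn = TRUE, wknkn_k = 5, wknkn_p = 0.7,
                  max_iter = 100L, tol = 1e-6) {
  mode <- match.arg(mode)
  check_binary_matrix(Y)
  if (any(c(lambda_l, lambda_d, lambda_t) < 0)) {
    stop("regularization weights must be non-negative", call. = FALSE)
  }
  if (!is.numeric(max_iter) || length(max_iter) != 1 || max_iter < 1 ||
      max_iter != round(max_iter)) {
    stop("`max_iter` must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(tol) || length(tol) != 1 || tol <= 0) {
    stop("`tol` must be positive", call. = FALSE)
  }
  if (mode == "semantic" && (is.null(sim_mirna) || is.null(sim_disease))) {
    stop('mode = "semantic" requires both similarity matrices', call. = FALSE)
  }

  Gm <- gip_kernel(Y, "mirna", gamma)
  Gd <- gip_kernel(Y, "disease", gamma)
  Km <- if (is.null(sim_mirna)) Gm else fuse_kernels(sim_mirna, Gm, alpha)
  Kd <- if (is.null(sim_disease)) Gd else fuse_kernels(sim_disease, Gd, alpha)

  Rm <- switch(mode,
    nearest_profile = nearest_profile(Km),
    fused = Km,
    semantic = sim_mirna)
  Rd <- switch(mode,
    nearest_profile = nearest_profile(Kd),
    fused = Kd,
    semantic = sim_disease)

  Y_fit <- if (wknkn) wknkn(Y, Km, Kd, k = wknkn_k, p = wknkn_p) else Y

  init <- svd_init(Y_fit, k)
  A <- init$A; B <- init$B
  obj <- npcmf_objective(Y_fit, A, B, Rm, Rd, lambda_l, lambda_d, lambda_t)
  trace <- obj
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(max_iter)) {
    upd <- als_step(Y_fit, A, B, Rm, Rd, lambda_l, lambda_d, lambda_t)
    A <- upd$A; B <- upd$B
    obj_new <- npcmf_objective(Y_fit, A, B, Rm, Rd, lambda_l, lambda_d, lambda_t)
    trace <- c(trace, obj_new)
    iters <- it
    if (abs(obj_new - obj) / max(obj, 1e-12) < tol) {
      converged <- TRUE
      break
    }
    obj <- obj_new
  }

  structure(
    list(A = A, B = B,
         Km = Km, Kd = Kd, Rm = Rm, Rd = Rd,
         Y = Y, Y_imputed = Y_fit,
         objective = trace, iterations = iters, converged = converged,
         mode = mode,
         hyperparams = list(k = k, lambda_l = lambda_l, lambda_d = lambda_d,
                            lambda_t = lambda_t, alpha = alpha, gamma = gamma,
                            wknkn = wknkn, wknkn_k = wknkn_k,
                            wknkn_p = wknkn_p, max_iter = max_iter, tol = tol),
         dims = dim(Y), dimnames = dimnames(Y),
         call = match.call()),
    class = "npcmf")
}

#' Predicted association score matrix
#'
#' @param object a fitted [npcmf] model.
#' @param ... unused.
#' @return the n x m score matrix `A %*% t(B)`, carrying the dimnames of `Y`.
#' @export
predict.npcmf <- function(object, ...) {
  scores <- tcrossprod(object$A, object$B)
  dimnames(scores) <- object$dimnames
  scores
}

#' @export
fitted.npcmf <- function(object, ...) predict(object)

#' @export
residuals.npcmf <- function(object, ...) object$Y_imputed - predict(object)

#' @export
coef.npcmf <- function(object, ...) list(A = object$A, B = object$B)

#' @export
print.npcmf <- function(x, ...) {
  cat("Nearest-profile collaborative matrix factorization\n")
  cat(sprintf("  %d miRNAs x %d diseases, rank %d, mode '%s'\n",
              x$dims[1], x$dims[2], x$hyperparams$k, x$mode))
  cat(sprintf("  %d ALS iterations (%s), final objective %.6g\n",
              x$iterations,
              if (x$converged) "converged" else "max_iter reached",
              x$objective[length(x$objective)]))
  invisible(x)
}

#' @export
summary.npcmf <- function(object, ...) {
  scores <- predict(object)
  res <- list(
    dims = object$dims, mode = object$mode,
    hyperparams = object$hyperparams,
    iterations = object$iterations, converged = object$converged,
    objective_initial = object$objective[1],
    objective_final = object$objective[length(object$objective)],
    rmse_fit = sqrt(mean((object$Y_imputed - scores)^2)),
    n_known = sum(object$Y))
  class(res) <- "summary.npcmf"
  res
}

#' @export
print.summary.npcmf <- function(x, ...) {
  cat("NPCMF model summary\n")
  cat(sprintf("  dimensions      : %d miRNAs x %d diseases (%d known associations)\n",
              x$dims[1], x$dims[2], x$n_known))
  cat(sprintf("  mode / rank     : %s / k = %d\n", x$mode, x$hyperparams$k))
  cat(sprintf("  lambdas (l,d,t) : %g, %g, %g\n", x$hyperparams$lambda_l,
              x$hyperparams$lambda_d, x$hyperparams$lambda_t))
  cat(sprintf("  alpha, gamma    : %g, %g\n", x$hyperparams$alpha,
              x$hyperparams$gamma))
  cat(sprintf("  WKNKN           : %s (K = %d, p = %g)\n",
              if (x$hyperparams$wknkn) "on" else "off",
              x$hyperparams$wknkn_k, x$hyperparams$wknkn_p))
  cat(sprintf("  ALS             : %d iterations, %s\n", x$iterations,
              if (x$converged) "converged" else "max_iter reached"))
  cat(sprintf("  objective       : %.6g -> %.6g\n", x$objective_initial,
              x$objective_final))
  cat(sprintf("  fit RMSE        : %.4g\n", x$rmse_fit))
  invisible(x)
}

#' Plot the objective trace of a fitted model
#'
#' @param x a fitted [npcmf] model.
#' @param ... passed to [graphics::plot()].
#' @export
plot.npcmf <- function(x, ...) {
  graphics::plot(seq_along(x$objective) - 1L, x$objective, type = "b",
                 pch = 20, xlab = "ALS iteration", ylab = "objective",
                 main = "NPCMF convergence", ...)
  invisible(x)
}
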