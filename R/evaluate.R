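#' Pair-masking cross-validation split (CV-p)
#'
#' Randomly partitions the known association pairs (the 1-entries of `Y`)
#' into `n_folds` near-equal folds. All entities stay present in every fold;
#' only pairs are masked, the cross-validation protocol for association
#' prediction over a fixed entity universe.
#'
#' @param Y binary association matrix.
#' @param n_folds number of folds; default 5.
#' @param seed optional integer seed; the caller's RNG stream is untouched.
#' @return data frame with columns `mirna`, `disease` (integer indices) and
#'   `fold`; fold sizes differ by at most 1.
#' @export
cvp_split <- function(Y, n_folds = 5, seed = NULL) {
  check_binary_matrix(Y)
  pos <- which(Y == 1)
  if (length(pos) < n_folds) {
    stop(sprintf("need at least %d known pairs for %d folds", n_folds, n_folds),
         call. = FALSE)
  }
  perm <- with_seed(seed, sample(pos))
  fold <- rep_len(seq_len(n_folds), length(perm))
  idx <- arrayInd(perm, dim(Y))
  data.frame(mirna = idx[, 1], disease = idx[, 2], fold = fold)
}

#' Area under the ROC curve
#'
#' Computes the AUC as the tie-aware rank statistic: the probability that a
#' random positive outscores a random negative, with ties counted half. This
#' equals the area under the ROC curve traced by sweeping a threshold over
#' the unique scores.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels of the same length; both classes must be present.
#' @return a number in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop("`scores` and `labels` must have equal length", call. = FALSE)
  }
  if (!all(labels %in% c(0, 1))) stop("`labels` must be 0/1", call. = FALSE)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("both classes must be present to compute AUC", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Repeated cross-validated evaluation of the factorization pipeline
#'
#' Runs `n_repeats` rounds of `n_folds`-fold pair-masking cross-validation.
#' In every fold the held-out pairs are zeroed in the training matrix and the
#' *entire* pipeline — GIP kernels, kernel fusion, WKNKN imputation,
#' nearest-profile construction, and the factorization — is recomputed from
#' the masked training matrix, so held-out information never leaks into
#' model building. Held-out positives are then scored against all pairs that
#' are 0 in the full matrix, and the fold AUCs are averaged per repeat.
#'
#' @param Y binary association matrix.
#' @param sim_mirna,sim_disease optional side similarity matrices, passed to
#'   [npcmf()].
#' @param n_folds folds per repeat; default 5.
#' @param n_repeats number of repeats; default 1.
#' @param seed optional integer seed controlling all fold assignments.
#' @param audit if `TRUE`, keep the per-fold training matrices and fitted
#'   models so the no-leakage property can be verified; default `FALSE`.
#' @param ... further arguments to [npcmf()] (mode, k, lambdas, WKNKN
#'   settings, ...).
#' @return an object of class `"npcmf_cv"`: list with `mean_auc`, `sd_auc`,
#'   `per_repeat_auc`, `per_fold_auc` (repeats x folds matrix), `splits`
#'   (fold assignment per repeat), and (when `audit`) `folds`, a list of
#'   per-fold records `(train, fit, test_idx, neg_idx)`.
#' @export
run_cv <- function(Y, sim_mirna = NULL, sim_disease = NULL,
                   n_folds = 5, n_repeats = 1, seed = NULL,
                   audit = FALSE, ...) {
  check_binary_matrix(Y)
  neg_idx <- which(Y == 0)
  per_fold <- matrix(NA_real_, n_repeats, n_folds)
  splits <- vector("list", n_repeats)
  audit_rec <- if (audit) list() else NULL
  with_seed(seed, {
    for (r in seq_len(n_repeats)) {
      split <- cvp_split(Y, n_folds = n_folds, seed = NULL)
      splits[[r]] <- split
      for (f in seq_len(n_folds)) {
        test <- split[split$fold == f, ]
        test_idx <- cbind(test$mirna, test$disease)
        Ytr <- Y
        Ytr[test_idx] <- 0
        fit <- npcmf(Ytr, sim_mirna = sim_mirna, sim_disease = sim_disease, ...)
        scores <- predict(fit)
        sc <- c(scores[test_idx], scores[neg_idx])
        lab <- c(rep(1, nrow(test_idx)), rep(0, length(neg_idx)))
        per_fold[r, f] <- auc_score(sc, lab)
        if (audit) {
          audit_rec[[length(audit_rec) + 1L]] <-
            list(repeat_i = r, fold = f, train = Ytr, fit = fit,
                 test_idx = test_idx, neg_idx = neg_idx)
        }
      }
    }
  })
  per_repeat <- rowMeans(per_fold)
  structure(
    list(mean_auc = mean(per_repeat),
         sd_auc = if (n_repeats > 1) stats::sd(per_repeat) else NA_real_,
         per_repeat_auc = per_repeat,
         per_fold_auc = per_fold,
         splits = splits,
         folds = audit_rec,
         n_folds = n_folds, n_repeats = n_repeats, seed = seed,
         params = list(...)),
    class = "npcmf_cv")
}

#' @export
print.npcmf_cv <- function(x, ...) {
  cat(sprintf("Pair-masking cross-validation: %d x %d-fold\n",
              x$n_repeats, x$n_folds))
  if (is.na(x$sd_auc)) {
    cat(sprintf("  mean AUC = %.4f\n", x$mean_auc))
  } else {
    cat(sprintf("  mean AUC = %.4f (sd %.4f over repeats)\n",
                x$mean_auc, x$sd_auc))
  }
  invisible(x)
}

#' Grid search over the regularization weights
#'
#' Exhaustively evaluates `lambda_l` and the ratios `lambda_d / lambda_l` and
#' `lambda_t / lambda_l` by cross-validation and returns the combination with
#' the highest mean AUC. The default grids are `lambda_l` in
#' `{2^-2, 2^-1, 2^0, 2^1}` and both ratios in `{0, 1e-4, 1e-3, 1e-2, 1e-1}`
#' (the disease-side ratio grid reused symmetrically for the miRNA side).
#' Ties resolve to the lexicographically smallest
#' `(lambda_l, ratio_d, ratio_t)`.
#'
#' @param Y binary association matrix.
#' @param sim_mirna,sim_disease optional side similarity matrices.
#' @param lambda_l grid of Tikhonov weights.
#' @param ratio_d,ratio_t grids of side-regularizer/Tikhonov ratios.
#' @param n_folds,n_repeats,seed cross-validation settings; every grid point
#'   is evaluated on the same fold assignments.
#' @param ... further arguments to [npcmf()].
#' @return list with `best` (one-row data frame) and `table` (the full grid
#'   with `mean_auc`).
#' @export
grid_search <- function(Y, sim_mirna = NULL, sim_disease = NULL,
                        lambda_l = c(0.25, 0.5, 1, 2),
                        ratio_d = c(0, 1e-4, 1e-3, 1e-2, 1e-1),
                        ratio_t = ratio_d,
                        n_folds = 5, n_repeats = 1, seed = NULL, ...) {
  grid <- expand.grid(lambda_l = lambda_l, ratio_d = ratio_d,
                      ratio_t = ratio_t, KEEP.OUT.ATTRS = FALSE)
  if (!nrow(grid)) stop("empty hyperparameter grid", call. = FALSE)
  grid$mean_auc <- NA_real_
  cv_seed <- if (is.null(seed)) sample.int(.Machine$integer.max, 1) else seed
  for (g in seq_len(nrow(grid))) {
    cv <- run_cv(Y, sim_mirna, sim_disease,
                 n_folds = n_folds, n_repeats = n_repeats, seed = cv_seed,
                 lambda_l = grid$lambda_l[g],
                 lambda_d = grid$lambda_l[g] * grid$ratio_d[g],
                 lambda_t = grid$lambda_l[g] * grid$ratio_t[g], ...)
    grid$mean_auc[g] <- cv$mean_auc
  }
  ord <- order(-grid$mean_auc, grid$lambda_l, grid$ratio_d, grid$ratio_t)
  list(best = grid[ord[1], , drop = FALSE], table = grid)
}

#' Sensitivity sweep over a single pipeline parameter
#'
#' Re-runs cross-validation while varying one of the WKNKN parameters (`K`,
#' `p`) or the kernel fusion weight (`alpha`), everything else fixed — the
#' standard stability analysis for these tuning knobs.
#'
#' @param parameter one of `"K"` (WKNKN neighbour count), `"p"` (WKNKN
#'   decay), `"alpha"` (fusion weight).
#' @param values values to sweep; each must lie in the parameter's legal
#'   range (`1 <= K <= side size - 1`, `0 < p <= 1`, `0 <= alpha <= 1`).
#' @param Y binary association matrix.
#' @param sim_mirna,sim_disease optional side similarity matrices.
#' @param n_folds,n_repeats,seed cross-validation settings.
#' @param ... further arguments to [npcmf()].
#' @return data frame with columns `parameter`, `value`, `mean_auc`,
#'   `sd_auc` — one row per swept value, ready for plotting.
#' @export
sensitivity_sweep <- function(parameter = c("K", "p", "alpha"), values,
                              Y, sim_mirna = NULL, sim_disease = NULL,
                              n_folds = 5, n_repeats = 1, seed = NULL, ...) {
  parameter <- match.arg(parameter)
  if (!length(values)) stop("`values` must be non-empty", call. = FALSE)
  max_k <- min(dim(Y)) - 1L
  for (v in values) {
    ok <- switch(parameter,
      K = v >= 1 && v <= max_k && v == round(v),
      p = v > 0 && v <= 1,
      alpha = v >= 0 && v <= 1)
    if (!ok) {
      bound <- switch(parameter,
        K = sprintf("K must be an integer in [1, %d]", max_k),
        p = "p must be in (0, 1]",
        alpha = "alpha must be in [0, 1]")
      stop(sprintf("illegal value %g for '%s': %s", v, parameter, bound),
           call. = FALSE)
    }
  }
  res <- lapply(values, function(v) {
    args <- list(Y = Y, sim_mirna = sim_mirna, sim_disease = sim_disease,
                 n_folds = n_folds, n_repeats = n_repeats, seed = seed, ...)
    args[[switch(parameter, K = "wknkn_k", p = "wknkn_p", alpha = "alpha")]] <- v
    cv <- do.call(run_cv, args)
    data.frame(parameter = parameter, value = v,
               mean_auc = cv$mean_auc, sd_auc = cv$sd_auc)
  })
  do.call(rbind, res)
}

#' Ranked candidate miRNAs for one disease
#'
#' Sorts all miRNAs by decreasing predicted score for a disease and flags
#' each as a known association (`Y = 1`) or a novel candidate (`Y = 0`) —
#' the ranked-table layout used for case-study validation of predicted
#' associations. Score ties resolve to the smaller miRNA index.
#'
#' @param Y binary association matrix.
#' @param scores score matrix of the same shape (e.g. from
#'   [predict.npcmf()]).
#' @param disease disease column name or index.
#' @param top_k number of top-ranked miRNAs to return; default 10.
#' @return data frame with columns `rank`, `mirna`, `score`, `known`.
#' @export
rank_for_disease <- function(Y, scores, disease, top_k = 10) {
  if (!identical(dim(Y), dim(scores))) {
    stop("`Y` and `scores` must have identical dimensions", call. = FALSE)
  }
  if (top_k < 1) stop("`top_k` must be at least 1", call. = FALSE)
  j <- if (is.character(disease)) match(disease, colnames(Y)) else disease
  if (is.na(j) || j < 1 || j > ncol(Y)) {
    stop("unknown disease: ", disease, call. = FALSE)
  }
  ord <- order(-scores[, j], seq_len(nrow(Y)))
  top <- ord[seq_len(min(top_k, nrow(Y)))]
  mirnas <- rownames(Y)
  if (is.null(mirnas)) mirnas <- as.character(seq_len(nrow(Y)))
  data.frame(rank = seq_along(top),
             mirna = mirnas[top],
             score = scores[top, j],
             known = Y[top, j] == 1,
             row.names = NULL)
}
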