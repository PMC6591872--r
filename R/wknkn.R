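#' WKNKN pre-imputation of likely-missing associations
#'
#' Weighted K Nearest Known Neighbours: replaces unknown zeros of a binary
#' association matrix by decay-weighted combinations of the profiles of the
#' `k` most similar entities that have at least one known association, on each
#' side. For miRNA `i` the miRNA-side estimate is
#' `sum_t p^(t-1) * Km(i, i_t) * Y(i_t, .) / sum_t Km(i, i_t)` over the `k`
#' nearest known neighbours `i_1..i_k` ranked by decreasing similarity (ties
#' towards the smaller index); the disease side is analogous over columns with
#' `Kd`. The two per-side estimates are averaged and combined with the
#' original matrix by an elementwise maximum, so known 1-entries are always
#' preserved.
#'
#' Entities with fewer than `k` known neighbours use all available ones; an
#' entity with no known neighbour keeps a zero estimate on that side.
#'
#' @param Y binary association matrix (miRNAs x diseases).
#' @param Km,Kd fused kernel matrices for the miRNA and disease sides.
#' @param k number of nearest known neighbours, `1 <= k <= side size - 1`;
#'   default 5.
#' @param p decay factor in `(0, 1]` applied by neighbour rank; default 0.7.
#' @return a real-valued matrix in `[0, 1]` with `wknkn(Y, ...) >= Y`
#'   elementwise.
#' @export
wknkn <- function(Y, Km, Kd, k = 5, p = 0.7) {
  check_binary_matrix(Y)
  check_square(Km, "Km")
  check_square(Kd, "Kd")
  n <- nrow(Y); m <- ncol(Y)
  if (nrow(Km) != n || nrow(Kd) != m) {
    stop("kernel dimensions do not match `Y`", call. = FALSE)
  }
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != round(k)) {
    stop("`k` must be a positive integer", call. = FALSE)
  }
  if (k > n - 1 || k > m - 1) {
    stop(sprintf("`k` must be at most side size - 1 (here %d)", min(n, m) - 1L),
         call. = FALSE)
  }
  if (!is.numeric(p) || length(p) != 1 || p <= 0 || p > 1) {
    stop("`p` must be in (0, 1]", call. = FALSE)
  }
  est_m <- wknkn_side(Y, Km, k, p)
  est_d <- t(wknkn_side(t(Y), Kd, k, p))
  out <- pmax(Y, (est_m + est_d) / 2)
  dimnames(out) <- dimnames(Y)
  out
}

# Row-side WKNKN estimate: each row as a decay-weighted combination of its k
# most similar rows having at least one association.
wknkn_side <- function(Y, K, k, p) {
  n <- nrow(Y)
  known <- which(rowSums(Y) > 0)
  est <- matrix(0, n, ncol(Y))
  for (i in seq_len(n)) {
    cand <- setdiff(known, i)
    if (!length(cand)) next
    ord <- order(-K[i, cand], cand)
    nb <- cand[ord[seq_len(min(k, length(cand)))]]
    s <- K[i, nb]
    denom <- sum(s)
    if (denom <= 0) next
    w <- p^(seq_along(nb) - 1) * s
    est[i, ] <- colSums(w * Y[nb, , drop = FALSE]) / denom
  }
  est
}
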