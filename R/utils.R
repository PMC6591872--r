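# Internal helpers shared across the package.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. A NULL seed uses the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

check_binary_matrix <- function(Y, arg = "Y") {
  if (!is.matrix(Y) || !is.numeric(Y)) {
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  }
  if (!all(Y == 0 | Y == 1)) {
    stop(sprintf("`%s` must contain only 0/1 entries", arg), call. = FALSE)
  }
  invisible(Y)
}

check_square <- function(K, arg = "K") {
  if (!is.matrix(K) || nrow(K) != ncol(K)) {
    stop(sprintf("`%s` must be a square matrix", arg), call. = FALSE)
  }
  invisible(K)
}

frob2 <- function(M) sum(M * M)

# squared euclidean distances between all row pairs of P
row_sqdist <- function(P) {
  sq <- rowSums(P^2)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(P)
  D2[D2 < 0] <- 0
  D2
}
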