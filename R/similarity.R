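#' Gaussian interaction profile (GIP) kernel
#'
#' Computes the GIP kernel over one side of a binary association matrix: the
#' similarity of two entities is a Gaussian of the squared euclidean distance
#' between their association profiles,
#' `K(i, j) = exp(-gamma * ||y_i - y_j||^2)`, where `y_i` is row `i` of `Y`
#' (miRNA side) or column `i` (disease side). The bandwidth `gamma` is used
#' literally, without per-profile normalization; the default `gamma = 1` is
#' the conventional choice for this kernel in association prediction.
#'
#' @param Y binary association matrix (miRNAs x diseases).
#' @param side `"mirna"` (rows) or `"disease"` (columns).
#' @param gamma positive kernel bandwidth; default 1.
#' @return symmetric kernel matrix with unit diagonal and entries in `(0, 1]`.
#' @export
gip_kernel <- function(Y, side = c("mirna", "disease"), gamma = 1) {
  side <- match.arg(side)
  check_binary_matrix(Y)
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma <= 0) {
    stop("`gamma` must be a single positive number", call. = FALSE)
  }
  P <- if (side == "mirna") Y else t(Y)
  K <- exp(-gamma * row_sqdist(P))
  K <- (K + t(K)) / 2
  diag(K) <- 1
  dimnames(K) <- list(rownames(P), rownames(P))
  K
}

#' Fuse a similarity matrix with a GIP kernel
#'
#' Linear kernel fusion `alpha * S + (1 - alpha) * G` combining a provided
#' similarity (functional or semantic) with the network-derived GIP kernel of
#' the same side. `alpha = 1` keeps only `S`, `alpha = 0` only `G`.
#'
#' @param S,G square matrices of identical shape.
#' @param alpha mixing weight in `[0, 1]`; default 0.5.
#' @return the fused kernel matrix.
#' @export
fuse_kernels <- function(S, G, alpha = 0.5) {
  check_square(S, "S")
  check_square(G, "G")
  if (!identical(dim(S), dim(G))) {
    stop("`S` and `G` must have identical dimensions", call. = FALSE)
  }
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha < 0 || alpha > 1) {
    stop("`alpha` must be a single value in [0, 1]", call. = FALSE)
  }
  alpha * S + (1 - alpha) * G
}

#' Nearest-profile matrix
#'
#' Sparsifies a kernel matrix to its per-row nearest neighbour: self-similarity
#' is removed, each row keeps only its single most similar other entity, and
#' the retained entry keeps the kernel value (not 1), since nearest-profile
#' prediction scales the neighbour's association profile by that similarity.
#' Ties are broken towards the smallest column index so results are
#' reproducible.
#'
#' @param K square kernel matrix over at least two entities.
#' @param symmetrize if `TRUE`, return `(N + t(N)) / 2` instead of the raw
#'   (generally asymmetric) nearest-neighbour matrix; default `FALSE`.
#' @return square matrix with zero diagonal and exactly one nonzero per row
#'   (two half-entries per row when symmetrized).
#' @export
nearest_profile <- function(K, symmetrize = FALSE) {
  check_square(K)
  n <- nrow(K)
  if (n < 2) stop("nearest neighbour undefined for a single entity", call. = FALSE)
  N <- matrix(0, n, n, dimnames = dimnames(K))
  for (i in seq_len(n)) {
    row <- K[i, ]
    row[i] <- -Inf
    j <- which.max(row)  # first max = smallest index on ties
    N[i, j] <- K[i, j]
  }
  if (symmetrize) N <- (N + t(N)) / 2
  N
}

#' Nearest-profile association prediction for one entity
#'
#' Predicts the association profile of an entity (typically a new miRNA or
#' disease with no known associations) from its single most similar other
#' entity: the neighbour's observed profile scaled by the kernel similarity
#' between the two.
#'
#' @param K square kernel matrix for the chosen side.
#' @param Y binary association matrix (miRNAs x diseases).
#' @param entity row/column index (or name) of the entity on `side`.
#' @param side `"mirna"` or `"disease"`.
#' @return numeric profile vector in `[0, 1]` (length `ncol(Y)` for miRNAs,
#'   `nrow(Y)` for diseases).
#' @export
np_profile <- function(K, Y, entity, side = c("mirna", "disease")) {
  side <- match.arg(side)
  check_square(K)
  n <- nrow(K)
  if (n < 2) stop("nearest neighbour undefined for a single entity", call. = FALSE)
  if (is.character(entity)) entity <- match(entity, rownames(K))
  if (is.na(entity) || entity < 1 || entity > n) {
    stop("`entity` not valid for this side", call. = FALSE)
  }
  row <- K[entity, ]
  row[entity] <- -Inf
  j <- which.max(row)
  if (side == "mirna") K[entity, j] * Y[j, ] else K[entity, j] * Y[, j]
}
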