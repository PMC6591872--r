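#' Read a miRNA-disease association matrix
#'
#' Reads a binary bipartite adjacency matrix `Y` (rows = miRNAs, columns =
#' diseases) either from a headerless two-column edge list (`miRNA_id`,
#' `disease_id`) or from a dense TSV whose first row holds disease identifiers
#' and first column holds miRNA identifiers.
#'
#' For edge lists the row/column order is first-appearance order unless
#' explicit identifier vectors are supplied (which also allows all-zero rows or
#' columns). Repeated edges collapse to a single 1.
#'
#' @param path path to a TSV file.
#' @param format `"edge_list"` or `"dense"`.
#' @param mirna_ids,disease_ids optional character vectors pinning the entity
#'   order for edge lists; ids appearing in the file but not listed are an
#'   error.
#' @return a binary numeric matrix with miRNA row names and disease column
#'   names.
#' @seealso [write_scores()], [read_similarity()]
#' @export
read_associations <- function(path, format = c("edge_list", "dense"),
                              mirna_ids = NULL, disease_ids = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "edge_list") {
    info <- file.info(path)
    if (info$size == 0 || length(readLines(path, n = 1L)) == 0L) {
      df <- data.frame(V1 = character(), V2 = character())
    } else {
      df <- utils::read.delim(path, header = FALSE, colClasses = "character")
    }
    if (ncol(df) >= 2) {
      edges <- df[, 1:2]
    } else {
      edges <- data.frame(V1 = character(), V2 = character())
    }
    if (is.null(mirna_ids)) mirna_ids <- unique(edges[[1]])
    if (is.null(disease_ids)) disease_ids <- unique(edges[[2]])
    check_ids(mirna_ids, "miRNA")
    check_ids(disease_ids, "disease")
    missing_m <- setdiff(edges[[1]], mirna_ids)
    missing_d <- setdiff(edges[[2]], disease_ids)
    if (length(missing_m) || length(missing_d)) {
      stop("identifiers in edge list absent from declared id lists: ",
           paste(c(missing_m, missing_d), collapse = ", "), call. = FALSE)
    }
    Y <- matrix(0, length(mirna_ids), length(disease_ids),
                dimnames = list(mirna_ids, disease_ids))
    if (nrow(edges)) {
      Y[cbind(match(edges[[1]], mirna_ids), match(edges[[2]], disease_ids))] <- 1
    }
  } else {
    Y <- read_dense_tsv(path)
    check_ids(rownames(Y), "miRNA")
    check_ids(colnames(Y), "disease")
    bad <- which(!(Y == 0 | Y == 1), arr.ind = TRUE)
    if (nrow(bad)) {
      stop(sprintf("non-binary entry %g at row '%s', column '%s'",
                   Y[bad[1, 1], bad[1, 2]],
                   rownames(Y)[bad[1, 1]], colnames(Y)[bad[1, 2]]),
           call. = FALSE)
    }
  }
  Y
}

#' Read an entity-entity similarity matrix
#'
#' Reads a dense square similarity matrix (e.g. MISIM miRNA functional
#' similarity or a precomputed disease semantic similarity), reorders it to the
#' requested identifier order, symmetrizes it by averaging with its transpose,
#' and forces the diagonal to 1. Asymmetry beyond `1e-6` before averaging
#' triggers a warning.
#'
#' @param path path to a dense TSV (first row and first column are
#'   identifiers).
#' @param ids ordered character vector of entity identifiers; every id must be
#'   present in the file.
#' @return a symmetric numeric matrix with unit diagonal, ordered as `ids`.
#' @export
read_similarity <- function(path, ids) {
  S <- read_dense_tsv(path)
  if (nrow(S) != ncol(S)) stop("similarity file must be square", call. = FALSE)
  check_ids(rownames(S), "row")
  check_ids(colnames(S), "column")
  missing <- setdiff(ids, rownames(S))
  if (length(missing)) {
    stop("ids missing from similarity file: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  S <- S[ids, ids, drop = FALSE]
  asym <- max(abs(S - t(S)))
  if (asym > 1e-6) {
    warning(sprintf("similarity matrix asymmetric (max |S - t(S)| = %g); symmetrizing", asym))
  }
  S <- (S + t(S)) / 2
  diag(S) <- 1
  S
}

#' Read a disease DAG from a child-parent edge list
#'
#' Reads a headerless TSV whose rows are `(child, parent)` pairs; a one-column
#' row declares an isolated node (e.g. a DAG root with no recorded parent).
#' The edge relation is checked for cycles.
#'
#' @param path path to the edge-list TSV.
#' @return a [disease_dag] object.
#' @export
read_disease_dag <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  singles <- vapply(parts, function(p) sum(nzchar(p)) < 2L, logical(1))
  nodes <- unlist(lapply(parts[singles], function(p) p[nzchar(p)][1]))
  edges <- do.call(rbind, lapply(parts[!singles], function(p) p[nzchar(p)][1:2]))
  if (is.null(edges)) edges <- matrix(character(), 0, 2)
  disease_dag(edges, nodes = nodes)
}

#' Write a prediction score matrix
#'
#' Writes a dense TSV with miRNA rows and disease columns at full double
#' precision, round-trippable through [read_scores()].
#'
#' @param scores numeric matrix with row and column names.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  if (is.null(rownames(scores)) || is.null(colnames(scores))) {
    stop("`scores` must carry miRNA row names and disease column names",
         call. = FALSE)
  }
  old <- options(digits = 17)
  on.exit(options(old), add = TRUE)
  df <- data.frame(id = rownames(scores), scores, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) read_dense_tsv(path)

#' Write an association matrix as a dense TSV
#'
#' @param Y binary matrix with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_associations <- function(Y, path) {
  check_binary_matrix(Y)
  write_scores(Y, path)
}

#' Write a similarity/kernel matrix as a dense TSV
#'
#' @param K square matrix with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_similarity <- function(K, path) {
  check_square(K)
  write_scores(K, path)
}

read_dense_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, row.names = 1,
                          check.names = FALSE)
  as.matrix(df)
}

check_ids <- function(ids, what) {
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop(sprintf("duplicate %s identifier(s): %s", what,
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  invisible(ids)
}
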