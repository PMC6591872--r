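#' Simulate a miRNA-disease association benchmark
#'
#' Generates a fully in-silico benchmark with planted low-rank cluster
#' structure, mimicking the shape of a curated association gold standard:
#'
#' * miRNAs and diseases are assigned to clusters; each cluster has a random
#'   latent prototype in `planted_rank` dimensions and each entity's latent
#'   factor is its prototype plus Gaussian noise, so entities of one cluster
#'   share association patterns ("similar miRNAs associate with similar
#'   diseases" holds by construction);
#' * the ground-truth matrix flags the top `density` fraction of the latent
#'   score matrix as true associations;
#' * the observed matrix hides a `mask_fraction` of the true 1s (the
#'   "undiscovered" associations a method should recover);
#' * side similarities are cluster-consistent (high within, low between, plus
#'   noise), symmetrized, clipped to `[0, 1]`, with unit diagonal;
#' * the disease DAG is a rooted hierarchy: every disease hangs under its
#'   cluster node, and cluster nodes hang under a common root.
#'
#' @param n_mirna,n_disease entity counts; defaults 100 and 80.
#' @param planted_rank latent dimension of the planted structure; default 5.
#' @param n_clusters clusters per side; defaults to `planted_rank`.
#' @param density fraction of pairs that are true associations, in `(0, 1)`;
#'   default 0.1.
#' @param mask_fraction fraction of true associations hidden from the
#'   observed matrix, in `[0, 1)`; default 0.1.
#' @param noise_sd standard deviation of the Gaussian noise on latent factors
#'   and similarities; default 0.1.
#' @param seed optional integer seed; identical seeds reproduce the
#'   simulation exactly.
#' @return an object of class `"mda_sim"`: list with `truth`, `observed`
#'   (binary matrices), `sim_mirna`, `sim_disease`, `dag` (a [disease_dag]),
#'   `masked` (index matrix of hidden true pairs), `clusters`, and the
#'   generating parameters in `spec`.
#' @export
simulate_mda <- function(n_mirna = 100, n_disease = 80, planted_rank = 5,
                         n_clusters = planted_rank, density = 0.1,
                         mask_fraction = 0.1, noise_sd = 0.1, seed = NULL) {
  if (planted_rank > min(n_mirna, n_disease)) {
    stop("`planted_rank` must not exceed min(n_mirna, n_disease)",
         call. = FALSE)
  }
  if (density <= 0 || density >= 1) stop("`density` must be in (0, 1)", call. = FALSE)
  if (mask_fraction < 0 || mask_fraction >= 1) {
    stop("`mask_fraction` must be in [0, 1)", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  if (round(density * n_mirna * n_disease) < 5) {
    stop("too few planted associations for 5-fold evaluation", call. = FALSE)
  }
  mirna_ids <- sprintf("mir%03d", seq_len(n_mirna))
  disease_ids <- sprintf("dis%03d", seq_len(n_disease))

  with_seed(seed, {
    cm <- sample(rep_len(seq_len(n_clusters), n_mirna))
    cd <- sample(rep_len(seq_len(n_clusters), n_disease))
    centers_m <- matrix(stats::rnorm(n_clusters * planted_rank), n_clusters)
    centers_d <- matrix(stats::rnorm(n_clusters * planted_rank), n_clusters)
    A <- centers_m[cm, , drop = FALSE] +
      noise_sd * matrix(stats::rnorm(n_mirna * planted_rank), n_mirna)
    B <- centers_d[cd, , drop = FALSE] +
      noise_sd * matrix(stats::rnorm(n_disease * planted_rank), n_disease)
    latent <- tcrossprod(A, B)

    n_pos <- round(density * n_mirna * n_disease)
    thresh <- sort(latent, decreasing = TRUE)[n_pos]
    truth <- (latent >= thresh) + 0
    dimnames(truth) <- list(mirna_ids, disease_ids)

    pos <- which(truth == 1)
    n_mask <- round(mask_fraction * length(pos))
    masked_lin <- sort(sample(pos, n_mask))
    observed <- truth
    observed[masked_lin] <- 0

    sim_mirna <- cluster_similarity(cm, noise_sd, mirna_ids)
    sim_disease <- cluster_similarity(cd, noise_sd, disease_ids)

    cluster_nodes <- sprintf("cluster%02d", seq_len(n_clusters))
    edges <- rbind(cbind(cluster_nodes, "root"),
                   cbind(disease_ids, cluster_nodes[cd]))
    dag <- disease_dag(edges)

    structure(
      list(truth = truth, observed = observed,
           sim_mirna = sim_mirna, sim_disease = sim_disease,
           dag = dag,
           masked = arrayInd(masked_lin, dim(truth)),
           clusters = list(mirna = cm, disease = cd),
           spec = list(n_mirna = n_mirna, n_disease = n_disease,
                       planted_rank = planted_rank, n_clusters = n_clusters,
                       density = density, mask_fraction = mask_fraction,
                       noise_sd = noise_sd, seed = seed)),
      class = "mda_sim")
  })
}

# within-cluster high / between-cluster low similarity with symmetric noise
cluster_similarity <- function(clusters, noise_sd, ids) {
  same <- outer(clusters, clusters, "==")
  S <- 0.2 + 0.6 * same
  n <- length(clusters)
  E <- matrix(stats::rnorm(n * n, sd = noise_sd), n)
  S <- S + (E + t(E)) / 2
  S[S < 0] <- 0
  S[S > 1] <- 1
  diag(S) <- 1
  dimnames(S) <- list(ids, ids)
  S
}

#' @export
print.mda_sim <- function(x, ...) {
  cat(sprintf("Synthetic MDA benchmark: %d miRNAs x %d diseases\n",
              x$spec$n_mirna, x$spec$n_disease))
  cat(sprintf("  planted rank %d, %d clusters/side, density %.2g\n",
              x$spec$planted_rank, x$spec$n_clusters, x$spec$density))
  cat(sprintf("  %d true associations, %d masked from the observed matrix\n",
              sum(x$truth), nrow(x$masked)))
  invisible(x)
}

#' Recovery metrics for masked associations
#'
#' Scores how well a prediction matrix recovers the true associations hidden
#' from the observed matrix: AUC of the masked positives against the true
#' negatives, and the mean rank of each disease's masked positives among its
#' candidate (unobserved) miRNAs.
#'
#' @param truth,observed binary matrices as produced by [simulate_mda()].
#' @param scores numeric score matrix of the same shape.
#' @return list with `auc`, `mean_rank`, and `per_disease` (data frame of
#'   disease index, masked count, mean rank).
#' @export
recovery_report <- function(truth, observed, scores) {
  if (!identical(dim(truth), dim(observed)) ||
      !identical(dim(truth), dim(scores))) {
    stop("`truth`, `observed` and `scores` must have identical dimensions",
         call. = FALSE)
  }
  masked <- truth == 1 & observed == 0
  if (!any(masked)) stop("no masked positives to evaluate", call. = FALSE)
  neg <- truth == 0
  auc <- auc_score(c(scores[masked], scores[neg]),
                   c(rep(1, sum(masked)), rep(0, sum(neg))))
  per <- lapply(which(colSums(masked) > 0), function(j) {
    cand <- which(observed[, j] == 0)
    r <- rank(-scores[cand, j])
    data.frame(disease = j, n_masked = sum(masked[, j]),
               mean_rank = mean(r[masked[cand, j]]))
  })
  per <- do.call(rbind, per)
  list(auc = auc, mean_rank = mean(per$mean_rank), per_disease = per)
}
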