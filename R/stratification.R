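# Ancestry clustering and construction of array-group x ancestry x sex
# analysis strata. Every downstream burden and association test conditions
# on these strata.

#' Cluster samples by genetic ancestry from principal components
#'
#' Builds a k-nearest-neighbour graph on the first `n_pcs` principal
#' components (Euclidean distance) and partitions it with Louvain
#' modularity-maximizing community detection. PCA itself is upstream: the
#' function consumes a PC matrix computed from LD-pruned genotypes.
#'
#' @param pc_matrix numeric matrix (samples x PCs) with sample ids as
#'   rownames, or a data.frame whose first column is `sample_id`.
#' @param n_pcs number of leading PCs used (default 6).
#' @param knn_k neighbours per sample in the kNN graph (default 15).
#' @param seed RNG seed making the Louvain pass deterministic.
#' @return integer cluster labels named by sample id.
#' @export
cluster_ancestry <- function(pc_matrix, n_pcs = 6, knn_k = 15, seed = 1) {
  if (is.data.frame(pc_matrix)) {
    ids <- as.character(pc_matrix[[1]])
    pc_matrix <- as.matrix(pc_matrix[, -1, drop = FALSE])
    rownames(pc_matrix) <- ids
  }
  n <- nrow(pc_matrix)
  if (n < knn_k + 1) {
    stop(sprintf("need at least knn_k + 1 = %d samples, got %d",
                 knn_k + 1, n), call. = FALSE)
  }
  if (ncol(pc_matrix) < n_pcs) {
    stop(sprintf("pc_matrix has %d columns; n_pcs = %d requested",
                 ncol(pc_matrix), n_pcs), call. = FALSE)
  }
  x <- pc_matrix[, seq_len(n_pcs), drop = FALSE]
  d <- as.matrix(dist(x))
  # k nearest neighbours per sample (self excluded); ties broken by index
  # so the graph is invariant to input order up to relabeling
  el <- do.call(rbind, lapply(seq_len(n), function(i) {
    nb <- order(d[i, ], seq_len(n))[2:(knn_k + 1)]
    cbind(i, nb)
  }))
  g <- igraph::simplify(igraph::graph_from_edgelist(el, directed = FALSE))
  memb <- with_seed(seed, igraph::membership(igraph::cluster_louvain(g)))
  labels <- as.integer(memb)
  names(labels) <- rownames(pc_matrix)
  labels
}

#' Build array-group x ancestry-cluster x sex strata
#'
#' Groups samples by the unique combination of array group, ancestry
#' cluster and sex, keeping combinations with at least `min_cases` cases
#' and `min_controls` controls and a case fraction inside `frac_range`
#' (bounds inclusive). Samples in failing combinations are reported as
#' dropped, never silently discarded.
#'
#' @param samples a sample table ([sample_table()]).
#' @param labels optional integer ancestry labels named by sample id
#'   (e.g. from [cluster_ancestry()]); defaults to the samples'
#'   `ancestry_cluster` column.
#' @param min_cases,min_controls minimum arm sizes per stratum.
#' @param frac_range allowed case fraction, inclusive bounds.
#' @return list of class `strata` with elements
#'   \describe{
#'     \item{strata}{data.frame: `stratum_id`, `array_group`,
#'       `ancestry_cluster`, `sex`, `n_case`, `n_control`.}
#'     \item{assignment}{data.frame: `sample_id`, `stratum_id`, `status`.}
#'     \item{dropped}{data.frame: `sample_id`, `stratum_id`, `reason`.}
#'   }
#' @export
build_strata <- function(samples, labels = NULL, min_cases = 5,
                         min_controls = 5, frac_range = c(0.10, 0.90)) {
  if (is.null(labels)) {
    labels <- setNames(samples$ancestry_cluster, samples$sample_id)
  }
  cl <- labels[samples$sample_id]
  if (any(is.na(cl))) {
    stop("missing ancestry label for sample(s): ",
         paste(head(samples$sample_id[is.na(cl)], 3), collapse = ", "),
         call. = FALSE)
  }
  sid <- sprintf("%s.c%s.%s", samples$array_group, cl, samples$sex)
  combos <- unique(data.frame(stratum_id = sid,
                              array_group = samples$array_group,
                              ancestry_cluster = as.integer(cl),
                              sex = samples$sex, stringsAsFactors = FALSE))
  n_case <- tapply(samples$status == "case", sid, sum)
  n_control <- tapply(samples$status == "control", sid, sum)
  combos$n_case <- as.integer(n_case[combos$stratum_id])
  combos$n_control <- as.integer(n_control[combos$stratum_id])
  frac <- combos$n_case / (combos$n_case + combos$n_control)
  ok_counts <- combos$n_case >= min_cases & combos$n_control >= min_controls
  ok_frac <- frac >= frac_range[1] & frac <= frac_range[2]
  combos$kept <- ok_counts & ok_frac
  reason <- ifelse(!ok_counts, "arm_too_small",
                   ifelse(!ok_frac, "case_fraction_out_of_range", ""))

  kept_ids <- combos$stratum_id[combos$kept]
  in_kept <- sid %in% kept_ids
  assignment <- data.frame(sample_id = samples$sample_id[in_kept],
                           stratum_id = sid[in_kept],
                           status = samples$status[in_kept],
                           stringsAsFactors = FALSE)
  dropped <- data.frame(sample_id = samples$sample_id[!in_kept],
                        stratum_id = sid[!in_kept],
                        reason = reason[match(sid[!in_kept], combos$stratum_id)],
                        stringsAsFactors = FALSE)
  strata <- combos[combos$kept, setdiff(names(combos), "kept"), drop = FALSE]
  rownames(strata) <- NULL
  structure(list(strata = strata, assignment = assignment, dropped = dropped),
            class = "strata")
}

#' @export
print.strata <- function(x, ...) {
  cat(sprintf("strata: %d retained (%d samples), %d samples dropped\n",
              nrow(x$strata), nrow(x$assignment), nrow(x$dropped)))
  print(x$strata)
  invisible(x)
}
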