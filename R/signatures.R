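#' Embedding and clustering parameters for stress signatures
#'
#' Defaults follow the published analysis settings: UMAP with 25 nearest
#' neighbours, minimum embedded distance 0 and the Chebyshev metric; K-means
#' with K = 5; 125 forks subsampled per sequencing run.
#'
#' @param n_neighbors UMAP nearest-neighbour count.
#' @param min_dist UMAP minimum embedded point distance.
#' @param metric Distance metric for the k-nearest-neighbour graph
#'   (`"chebyshev"`, `"euclidean"` or `"manhattan"`).
#' @param k_clusters Number of K-means clusters.
#' @param forks_per_run Forks subsampled from each sequencing run before
#'   embedding.
#' @param seed Integer seed controlling subsampling, UMAP and K-means.
#' @param cluster_on `"embedding"` (default; centroids live in the 2-d UMAP
#'   plane, as plotted) or `"features"` to cluster in the rescaled feature
#'   space.
#' @return A list of class `embedding_params`.
#' @export
embedding_params <- function(n_neighbors = 25L, min_dist = 0,
                             metric = c("chebyshev", "euclidean", "manhattan"),
                             k_clusters = 5L, forks_per_run = 125L,
                             seed = 1L,
                             cluster_on = c("embedding", "features")) {
  metric <- match.arg(metric)
  cluster_on <- match.arg(cluster_on)
  stopifnot(n_neighbors >= 2, min_dist >= 0, k_clusters >= 1,
            forks_per_run >= 1)
  structure(list(n_neighbors = as.integer(n_neighbors), min_dist = min_dist,
                 metric = metric, k_clusters = as.integer(k_clusters),
                 forks_per_run = as.integer(forks_per_run),
                 seed = as.integer(seed), cluster_on = cluster_on),
            class = "embedding_params")
}

#' Eight-feature replication-stress signature of one fork
#'
#' The signature comprises: (1) total fork-track length in bp, (2) EdU track
#' length, (3) BrdU track length, (4) fraction of thymidines called BrdU in
#' the EdU segment, (5) fraction called EdU in the EdU segment, (6) fraction
#' called EdU in the BrdU segment, (7) fraction called BrdU in the BrdU
#' segment, and (8) the stall score. Call fractions use the same strict
#' threshold as segmentation.
#'
#' @param track The fork's [analogue_track()].
#' @param fork One row of a fork-call data.frame.
#' @param stall A [stall_score()] result for the fork (must not be declined).
#' @param threshold Positive-call threshold. Default 0.5.
#' @return Named numeric vector of length 8.
#' @export
fork_features <- function(track, fork, stall, threshold = 0.5) {
  if (!is.na(stall$declined))
    stop("fork has a declined stall score (", stall$declined,
         "); no signature computed")
  pos <- track$positions
  ce <- track$p_edu > threshold
  cb <- track$p_brdu > threshold
  in_e <- pos >= fork$edu_start & pos < fork$edu_end
  in_b <- pos >= fork$brdu_start & pos < fork$brdu_end
  frac <- function(x, sel) if (any(sel)) sum(x[sel]) / sum(sel) else NA_real_
  c(track_len = as.numeric(fork$track_end - fork$track_start),
    edu_len = as.numeric(fork$edu_end - fork$edu_start),
    brdu_len = as.numeric(fork$brdu_end - fork$brdu_start),
    brdu_in_edu = frac(cb, in_e),
    edu_in_edu = frac(ce, in_e),
    edu_in_brdu = frac(ce, in_b),
    brdu_in_brdu = frac(cb, in_b),
    stall = stall$score)
}

#' Signature matrix for a metrics table
#'
#' Builds the 8-feature signature for every fork in a [fork_metrics()] table
#' whose stall score was not declined; declined forks are skipped with a
#' message.
#'
#' @param tracks List of [analogue_track()] objects.
#' @param metrics A [fork_metrics()] data.frame.
#' @param threshold Positive-call threshold.
#' @return Numeric matrix (forks x 8) with the retained metrics rows as
#'   attribute `"metrics"`.
#' @export
signature_matrix <- function(tracks, metrics, threshold = 0.5) {
  keep <- is.na(metrics$stall_declined)
  if (any(!keep))
    message(sum(!keep), " fork(s) skipped: declined stall score")
  metrics <- metrics[keep, , drop = FALSE]
  track_by_id <- stats::setNames(tracks, vapply(tracks, `[[`, "", "read_id"))
  rows <- lapply(seq_len(nrow(metrics)), function(i) {
    fork <- metrics[i, ]
    st <- list(declined = NA_character_, score = fork$stall)
    fork_features(track_by_id[[fork$read_id]], fork, st, threshold)
  })
  m <- do.call(rbind, rows)
  attr(m, "metrics") <- metrics
  m
}

#' Rescale signature features to the interquartile range
#'
#' Each feature column is centred on its median and divided by its IQR across
#' all forks. A feature with zero IQR carries no information and is set to 0
#' with a warning.
#'
#' @param x Numeric matrix, forks in rows, features in columns.
#' @return Matrix of the same shape; columns have median 0 and IQR 1 (or are
#'   all zero).
#' @export
robust_rescale <- function(x) {
  stopifnot(is.matrix(x), nrow(x) >= 4)
  out <- apply(x, 2, function(col) {
    iqr <- stats::IQR(col, na.rm = TRUE)
    if (iqr == 0) {
      warning("feature with zero IQR rescaled to all zeros")
      rep(0, length(col))
    } else {
      (col - stats::median(col, na.rm = TRUE)) / iqr
    }
  })
  dimnames(out) <- dimnames(x)
  out
}

# Exact k-nearest neighbours under the Chebyshev (L-infinity) metric (or
# another dist() method); returned in the precomputed-graph form uwot accepts.
.knn_graph <- function(x, k, metric) {
  dm <- switch(metric,
               chebyshev = as.matrix(stats::dist(x, method = "maximum")),
               euclidean = as.matrix(stats::dist(x, method = "euclidean")),
               manhattan = as.matrix(stats::dist(x, method = "manhattan")))
  n <- nrow(dm)
  idx <- matrix(0L, n, k); dst <- matrix(0, n, k)
  for (i in seq_len(n)) {
    o <- order(dm[i, ], seq_len(n))  # self first (distance 0), stable ties
    o <- c(i, setdiff(o, i))[seq_len(k)]
    idx[i, ] <- o
    dst[i, ] <- dm[i, o]
  }
  list(idx = idx, dist = dst)
}

#' Embed stress signatures and cluster them
#'
#' Rescales the signature matrix to the IQR, subsamples `forks_per_run` forks
#' per sequencing run, embeds into two dimensions with UMAP (Chebyshev
#' metric, exact nearest neighbours), clusters with K-means, and tabulates
#' cluster label against condition. With `exclude_speed = TRUE` the three
#' track-length features are dropped, leaving the 5-dimensional
#' incorporation/stall space.
#'
#' @param features Numeric matrix of signatures (forks x 8), as from
#'   [signature_matrix()].
#' @param run Character/factor vector: sequencing-run identifier per fork.
#' @param condition Character/factor vector: treatment condition per fork.
#' @param params An [embedding_params()].
#' @param exclude_speed Drop the track-length features (columns 1-3)?
#' @return An object of class `stress_signature`: list with `embedding`
#'   (n x 2), `cluster` (integer labels), `centroids`, `confusion`
#'   (cluster x condition table), `purity`, `subsample` (row indices used),
#'   `run`, `condition`, `params`.
#' @export
embed_signatures <- function(features, run, condition,
                             params = embedding_params(),
                             exclude_speed = FALSE) {
  stopifnot(nrow(features) == length(run), length(run) == length(condition))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(params$seed)
  idx <- unlist(lapply(split(seq_along(run), run), function(ii) {
    if (length(ii) <= params$forks_per_run) {
      if (length(ii) < params$forks_per_run)
        warning("run with only ", length(ii), " forks; using all")
      ii
    } else sample(ii, params$forks_per_run)
  }), use.names = FALSE)
  idx <- sort(idx)
  x <- features[idx, , drop = FALSE]
  if (exclude_speed) x <- x[, -(1:3), drop = FALSE]
  x <- robust_rescale(x)
  k <- min(params$n_neighbors, nrow(x) - 1L)
  nn <- .knn_graph(x, k, params$metric)
  emb <- uwot::umap(x, nn_method = nn, min_dist = params$min_dist,
                    n_threads = 1, n_sgd_threads = 0)
  cl_input <- if (params$cluster_on == "embedding") emb else x
  km <- stats::kmeans(cl_input, centers = params$k_clusters, nstart = 10)
  confusion <- table(cluster = km$cluster, condition = condition[idx])
  purity <- sum(apply(confusion, 1, max)) / sum(confusion)
  structure(list(embedding = emb, cluster = km$cluster,
                 centroids = km$centers, confusion = confusion,
                 purity = purity, subsample = idx,
                 run = run[idx], condition = condition[idx],
                 params = params, exclude_speed = exclude_speed),
            class = "stress_signature")
}

#' @export
print.stress_signature <- function(x, ...) {
  cat("<stress_signature> ", nrow(x$embedding), " forks, ",
      x$params$k_clusters, " clusters, purity ",
      sprintf("%.3f", x$purity), "\n", sep = "")
  print(x$confusion)
  invisible(x)
}

#' Plot a stress-signature embedding
#'
#' Left: embedded forks coloured by condition with K-means centroids; right:
#' Gaussian kernel density of the embedded points.
#'
#' @param x A `stress_signature` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.stress_signature <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  cond <- factor(x$condition)
  graphics::plot(x$embedding, col = as.integer(cond), pch = 16, cex = 0.6,
                 xlab = "UMAP 1", ylab = "UMAP 2",
                 main = "stress signatures", ...)
  if (x$params$cluster_on == "embedding")
    graphics::points(x$centroids, pch = 4, cex = 2, lwd = 2, col = "red")
  graphics::legend("topright", legend = levels(cond), col = seq_along(levels(cond)),
                   pch = 16, cex = 0.7, bty = "n")
  kd <- MASS::kde2d(x$embedding[, 1], x$embedding[, 2], n = 100)
  graphics::image(kd, col = grDevices::hcl.colors(32, "Spectral", rev = TRUE),
                  xlab = "UMAP 1", ylab = "UMAP 2", main = "density")
  invisible(x)
}
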