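# Pearson correlation with a zero guard for constant columns.
safe_cor <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(a, b)
}

# CFS merit of a feature subset: k * mean|r_cf| / sqrt(k + k (k-1) mean|r_ff|).
cfs_merit <- function(rcf, rff_mean) {
  k <- length(rcf)
  k * mean(abs(rcf)) / sqrt(k + k * (k - 1) * rff_mean)
}

#' Correlation-based feature selection (CFS)
#'
#' Greedy forward selection maximising the CFS merit
#' `k * mean|r_cf| / sqrt(k + k (k-1) * mean|r_ff|)`, where `r_cf` is the
#' Pearson correlation of each selected feature with the class label (coded
#' 0/1) and `r_ff` the mean absolute pairwise correlation within the selected
#' set. Ties are broken by column order; constant columns contribute zero
#' correlation.
#'
#' Subject-independence screen: when `subjects` is supplied, the label
#' correlation of each feature is recomputed leaving one subject out at a
#' time, and only features whose leave-one-subject-out correlation sign
#' matches the pooled sign for at least `consistency` of the subjects are
#' ranked first; remaining slots (if any) are filled from the rest.
#'
#' @param X Numeric matrix or data.frame of features (rows = time windows,
#'   pooled across subjects; named columns).
#' @param labels Class label per row (factor, character or 0/1 numeric).
#' @param n_select Number of features to select (default 15).
#' @param subjects Optional subject id per row for the independence screen.
#' @param consistency Sign-consistency fraction required (default 0.8).
#' @return Character vector of selected feature names, in selection order,
#'   with the merit trace as attribute `"merit"`.
#' @export
cfs_select <- function(X, labels, n_select = 15, subjects = NULL,
                       consistency = 0.8) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (anyDuplicated(colnames(X))) stop("feature names must be unique")
  if (anyNA(X)) stop("feature matrix contains missing values")
  if (ncol(X) < n_select) stop("fewer features than `n_select`")
  y <- as.numeric(factor(labels)) - 1
  if (length(y) != nrow(X)) stop("one label per row required")
  rcf <- apply(X, 2, safe_cor, b = y)

  eligible <- rep(TRUE, ncol(X))
  if (!is.null(subjects) && length(unique(subjects)) > 2) {
    pooled_sign <- sign(rcf)
    subj <- unique(subjects)
    agree <- matrix(NA, length(subj), ncol(X))
    for (s in seq_along(subj)) {
      keep <- subjects != subj[s]
      if (length(unique(y[keep])) < 2) next
      r_s <- apply(X[keep, , drop = FALSE], 2, safe_cor, b = y[keep])
      agree[s, ] <- sign(r_s) == pooled_sign
    }
    frac <- colMeans(agree, na.rm = TRUE)
    eligible <- !is.na(frac) & frac >= consistency
  }

  order_pool <- c(which(eligible), which(!eligible))  # screened features first
  selected <- integer(0)
  merit_trace <- numeric(0)
  # incremental mean pairwise |r| within the selected set
  rff_sum <- 0
  cand_rff <- numeric(ncol(X))  # sum over selected of |cor(candidate, sel)|
  pool_groups <- list(which(eligible), which(!eligible))
  for (step in seq_len(n_select)) {
    best <- NA_integer_; best_merit <- -Inf
    for (grp in pool_groups) {
      cands <- setdiff(grp, selected)
      if (!length(cands)) next
      for (cand in cands) {
        k <- length(selected) + 1
        rff_mean <- if (k == 1) 0 else
          (rff_sum + cand_rff[cand]) / (k * (k - 1) / 2)
        m <- cfs_merit(rcf[c(selected, cand)], rff_mean)
        if (m > best_merit + 1e-12) { best_merit <- m; best <- cand }
      }
      if (!is.na(best)) break  # only fall through to unscreened when needed
    }
    selected <- c(selected, best)
    merit_trace <- c(merit_trace, best_merit)
    rff_sum <- rff_sum + cand_rff[best]
    if (length(selected) < n_select) {
      for (j in setdiff(seq_len(ncol(X)), selected))
        cand_rff[j] <- cand_rff[j] + abs(safe_cor(X[, j], X[, best]))
    }
  }
  structure(colnames(X)[selected], merit = merit_trace)
}

#' Isomap embedding to a one-dimensional emotion trajectory
#'
#' Builds a symmetric k-nearest-neighbour Euclidean graph over the rows of
#' `X`, computes all-pairs geodesic distances with Dijkstra's algorithm, and
#' applies classical multidimensional scaling (double-centering of the
#' squared geodesic distances, top eigenvector scaled by the square root of
#' its eigenvalue). The output is centred to zero mean, with the sign fixed
#' so the first nonzero value is positive. A disconnected neighbourhood
#' graph triggers incrementing `k_neighbors` (with a message) until the
#' graph connects.
#'
#' @param X Numeric matrix, rows = time windows, columns = selected features.
#' @param k_neighbors Neighbourhood size (default 10).
#' @param d Embedding dimension (default 1; the emotion trajectory).
#' @param timestamps Optional window times carried into the result.
#' @return An `emotion_trajectory`: `values` (zero-mean series, or an
#'   n-by-d matrix when `d > 1`), `timestamps`, `k_neighbors` actually used.
#' @export
isomap_embed <- function(X, k_neighbors = 10, d = 1, timestamps = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2) stop("need at least two points to embed")
  k_neighbors <- min(max(1L, k_neighbors), n - 1L)
  DE <- as.matrix(stats::dist(X))
  repeat {
    A <- matrix(0, n, n)
    for (i in seq_len(n)) {
      nb <- order(DE[i, -i])[seq_len(k_neighbors)]
      nb <- which(seq_len(n) != i)[nb]
      A[i, nb] <- DE[i, nb]
    }
    A <- pmax(A, t(A))  # symmetric union of directed kNN edges
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                             weighted = TRUE)
    if (igraph::components(g)$no == 1 || k_neighbors >= n - 1) break
    k_neighbors <- k_neighbors + 1L
    message("neighbourhood graph disconnected; increasing k to ", k_neighbors)
  }
  G <- igraph::distances(g, algorithm = "dijkstra")
  if (any(!is.finite(G))) stop("geodesic distances not finite (disconnected graph)")
  # classical MDS on squared geodesics
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (G^2) %*% J
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  d_eff <- min(d, sum(eig$values > 1e-12))
  Yv <- matrix(0, n, d)
  if (d_eff > 0)
    Yv[, seq_len(d_eff)] <- eig$vectors[, seq_len(d_eff), drop = FALSE] %*%
      diag(sqrt(eig$values[seq_len(d_eff)]), d_eff)
  for (j in seq_len(d)) {
    Yv[, j] <- Yv[, j] - mean(Yv[, j])
    nz <- which(abs(Yv[, j]) > 1e-12)
    if (length(nz) && Yv[nz[1], j] < 0) Yv[, j] <- -Yv[, j]
  }
  values <- if (d == 1) as.vector(Yv) else Yv
  structure(list(values = values, timestamps = timestamps,
                 k_neighbors = k_neighbors, zero_mean = TRUE),
            class = "emotion_trajectory")
}

#' @export
print.emotion_trajectory <- function(x, ...) {
  v <- if (is.matrix(x$values)) x$values[, 1] else x$values
  cat(sprintf("<emotion_trajectory> %d points, sd %.3g\n", length(v), stats::sd(v)))
  invisible(x)
}

#' Write per-subject trajectories as CSV
#'
#' Columns: subject, timestamp, value.
#'
#' @param trajectories Named list of [isomap_embed()] results.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories_csv <- function(trajectories, path) {
  rows <- lapply(names(trajectories), function(s) {
    tr <- trajectories[[s]]
    ts <- if (is.null(tr$timestamps)) seq_along(tr$values) - 1 else tr$timestamps
    data.frame(subject = s, timestamp = ts, value = tr$values)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
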