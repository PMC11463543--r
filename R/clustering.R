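#' Standardize abundance profiles
#'
#' Missing timepoints are linearly interpolated within each row (boundary
#' gaps carried from the nearest observed value), then each row is centred
#' to mean 0 and scaled to population standard deviation 1. Rows with fewer
#' than three finite values or zero variance are dropped and reported.
#'
#' @param m proteins x timepoints numeric matrix.
#' @return standardized matrix with attribute \code{dropped}: the row names
#'   removed (and why).
#' @export
zscore_profiles <- function(m) {
  stopifnot(is.matrix(m), ncol(m) >= 3L)
  n_finite <- rowSums(is.finite(m))
  dropped <- character(0)
  few <- n_finite < 3L
  if (any(few)) {
    dropped <- c(dropped, stats::setNames(rep("too few observations",
                                              sum(few)),
                                          rownames(m)[few]))
    m <- m[!few, , drop = FALSE]
  }
  xs <- seq_len(ncol(m))
  interp <- t(apply(m, 1L, function(row) {
    if (anyNA(row)) {
      row <- stats::approx(xs[is.finite(row)], row[is.finite(row)],
                           xout = xs, rule = 2)$y
    }
    row
  }))
  dimnames(interp) <- dimnames(m)
  sd_pop <- sqrt(rowMeans((interp - rowMeans(interp))^2))
  flat <- sd_pop == 0
  if (any(flat)) {
    dropped <- c(dropped, stats::setNames(rep("zero variance", sum(flat)),
                                          rownames(interp)[flat]))
    log_stage("cluster", "dropped ", sum(flat), " zero-variance profile(s)")
    interp <- interp[!flat, , drop = FALSE]
    sd_pop <- sd_pop[!flat]
  }
  z <- (interp - rowMeans(interp)) / sd_pop
  attr(z, "dropped") <- dropped
  z
}

# mean silhouette width for a labelling of rows of z (Euclidean)
mean_silhouette <- function(z, labels) {
  sil <- cluster::silhouette(labels, stats::dist(z))
  mean(sil[, "sil_width"])
}

#' Cluster standardized abundance profiles
#'
#' k-means (20 restarts per k, fixed seed) over a range of k; the returned
#' k maximizes the mean Euclidean silhouette width. Clusters are renumbered
#' by the timepoint at which their centroid peaks, earliest first, so
#' labels are stable under row permutation of the input.
#'
#' @param z standardized profile matrix from [zscore_profiles()].
#' @param k_range candidate cluster counts (default 2:10).
#' @param seed RNG seed governing the k-means restarts.
#' @return list with \code{labels} (named integer vector), \code{k},
#'   \code{silhouette} (mean width at the chosen k), \code{silhouettes}
#'   (per candidate k), and \code{centers}.
#' @export
cluster_profiles <- function(z, k_range = 2:10, seed = 1L) {
  stopifnot(is.matrix(z))
  if (nrow(z) < 2L * max(k_range))
    stop("need >= ", 2L * max(k_range), " profiles for k_range up to ",
         max(k_range))
  # row-order invariance: run k-means on rows sorted by name, map back
  ord <- order(rownames(z))
  zs <- z[ord, , drop = FALSE]
  fits <- list()
  sils <- stats::setNames(numeric(length(k_range)), k_range)
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    fits[[i]] <- with_substream(seed, paste0("kmeans_k", k),
                                stats::kmeans(zs, centers = k, nstart = 20,
                                              iter.max = 100))
    sils[i] <- mean_silhouette(zs, fits[[i]]$cluster)
  }
  best <- which.max(sils)
  fit <- fits[[best]]
  k <- k_range[best]
  peak <- apply(fit$centers, 1L, which.max)
  relabel <- match(seq_len(k), order(peak, seq_len(k)))
  labels <- relabel[fit$cluster]
  names(labels) <- rownames(zs)
  labels <- labels[rownames(z)]
  centers <- fit$centers[order(peak, seq_len(k)), , drop = FALSE]
  rownames(centers) <- seq_len(k)
  list(labels = labels, k = k, silhouette = unname(sils[best]),
       silhouettes = sils, centers = centers)
}
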