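#' Identity-by-state distance matrix
#'
#' For each sample pair, similarity is the mean over mutually called loci
#' of `1 - |g_i - g_j| / 2`; the distance is one minus the similarity.
#' A pair with no mutually called locus is an error.
#'
#' @param gm A [geno_matrix()] with at least two samples.
#' @return A symmetric numeric matrix with zero diagonal and entries in
#'   \[0, 1\], with sample ids as dimnames.
#' @export
ibs_distance <- function(gm) {
  check_that(inherits(gm, "geno_matrix"), "`gm` must be a geno_matrix")
  g <- gm$geno
  n <- nrow(g)
  check_that(n >= 2, "need at least two samples")
  D <- matrix(0, n, n, dimnames = list(rownames(g), rownames(g)))
  for (i in seq_len(n - 1)) {
    gi <- g[i, ]
    for (j in (i + 1):n) {
      shared <- !is.na(gi) & !is.na(g[j, ])
      if (!any(shared)) {
        abort(sprintf("samples %s and %s share no called locus",
                      rownames(g)[i], rownames(g)[j]))
      }
      d <- mean(abs(gi[shared] - g[j, shared]) / 2)
      D[i, j] <- d
      D[j, i] <- d
    }
  }
  D
}

#' Classical (metric) multidimensional scaling
#'
#' Double-centres the squared distance matrix, eigendecomposes it and
#' returns coordinates on the top `k` axes scaled by the square roots of
#' the eigenvalues. Negative eigenvalues (non-Euclidean input) are
#' truncated to zero with a warning.
#'
#' @param D A symmetric distance matrix.
#' @param k Number of dimensions, `k < nrow(D)`.
#' @return A list of class `mds_result`: `points` (n x k matrix) and
#'   `eig` (all n eigenvalues, descending, negatives truncated to zero).
#' @export
classical_mds <- function(D, k = 2) {
  D <- as.matrix(D)
  n <- nrow(D)
  check_that(k >= 1 && k < n, "`k` must satisfy 1 <= k < n")
  fit <- cmdscale(D, k = k, eig = TRUE)
  eig <- fit$eig
  if (any(eig < -1e-8 * max(abs(eig)))) {
    warn("distance matrix is not Euclidean; negative eigenvalues truncated to zero")
  }
  pts <- fit$points
  if (ncol(pts) < k) {  # degenerate input (e.g. all-zero distances)
    pts <- cbind(pts, matrix(0, n, k - ncol(pts)))
  }
  rownames(pts) <- rownames(D)
  colnames(pts) <- paste0("axis", seq_len(k))
  structure(list(points = pts, eig = pmax(sort(eig, decreasing = TRUE), 0)),
            class = "mds_result")
}

#' @export
print.mds_result <- function(x, ...) {
  cat(sprintf("<mds_result> %d samples x %d axes\n",
              nrow(x$points), ncol(x$points)))
  ev <- x$eig[x$eig > 0]
  cat(sprintf("variance on shown axes: %.1f%%\n",
              100 * sum(x$eig[seq_len(ncol(x$points))]) / sum(ev)))
  invisible(x)
}

#' Tidy MDS coordinates
#'
#' @param x An `mds_result`.
#' @param ... Unused.
#' @return A tibble with `sample_id` and one column per axis.
#' @method tidy mds_result
#' @export
tidy.mds_result <- function(x, ...) {
  out <- as_tibble(x$points)
  out$sample_id <- rownames(x$points) %||% as.character(seq_len(nrow(x$points)))
  select(out, "sample_id", dplyr::everything())
}

#' Plot the first two MDS axes
#'
#' @param object An `mds_result`.
#' @param populations Optional vector of population labels (one per
#'   sample) used for colour.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mds_result
#' @export
autoplot.mds_result <- function(object, populations = NULL, ...) {
  d <- tidy(object)
  d$population <- populations %||% "all"
  ggplot2::ggplot(d, ggplot2::aes(x = .data$axis1, y = .data$axis2,
                                  colour = .data$population)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "MDS axis 1", y = "MDS axis 2") +
    ggplot2::theme_minimal()
}

#' Pairwise linkage disequilibrium r-squared
#'
#' Squared Pearson correlation of allele dosages over mutually called
#' samples (the composite estimator for unphased data). Undefined when a
#' column is constant on the shared samples; such pairs are reported as
#' `NA` and excluded from profile means.
#'
#' @param g1,g2 Genotype columns (dosages with `NA` for missing).
#' @return r-squared in \[0, 1\], or `NA`.
#' @export
r2_pair <- function(g1, g2) {
  shared <- !is.na(g1) & !is.na(g2)
  if (sum(shared) < 2) return(NA_real_)
  a <- g1[shared]
  b <- g2[shared]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  cor(a, b)^2
}

#' Linkage-disequilibrium decay profile
#'
#' Assigns every intra-chromosome marker pair within `max_dist` to
#' contiguous distance bins of `bin_width` bp and averages the pairwise
#' r-squared per bin (undefined pairs excluded).
#'
#' @param gm A [geno_matrix()] whose loci carry `chrom` and `pos`.
#' @param max_dist Largest pair distance considered, bp.
#' @param bin_width Bin width, bp.
#' @return A tibble `bin_start`, `bin_end`, `mean_r2`, `n_pairs`
#'   (`n_pairs` counts pairs with defined r-squared).
#' @export
ld_decay_profile <- function(gm, max_dist = 40000, bin_width = 5000) {
  check_that(inherits(gm, "geno_matrix"), "`gm` must be a geno_matrix")
  n_bins <- ceiling(max_dist / bin_width)
  sums <- counts <- numeric(n_bins)
  for (cn in unique(gm$loci$chrom)) {
    idx <- which(gm$loci$chrom == cn)
    idx <- idx[order(gm$loci$pos[idx])]
    pos <- gm$loci$pos[idx]
    for (a in seq_along(idx)) {
      b <- a + 1L
      while (b <= length(idx) && pos[b] - pos[a] <= max_dist) {
        r2 <- r2_pair(gm$geno[, idx[a]], gm$geno[, idx[b]])
        if (!is.na(r2)) {
          k <- min(n_bins, floor((pos[b] - pos[a]) / bin_width) + 1L)
          sums[k] <- sums[k] + r2
          counts[k] <- counts[k] + 1
        }
        b <- b + 1L
      }
    }
  }
  tibble(bin_start = (seq_len(n_bins) - 1) * bin_width,
         bin_end = pmin(seq_len(n_bins) * bin_width, max_dist),
         mean_r2 = ifelse(counts > 0, sums / counts, NA_real_),
         n_pairs = as.integer(counts))
}

#' Mean r-squared between adjacent markers
#'
#' @param gm A [geno_matrix()].
#' @param chromosome Chromosome to evaluate.
#' @return Mean r-squared over consecutive marker pairs with defined
#'   values.
#' @export
adjacent_r2_mean <- function(gm, chromosome) {
  idx <- which(gm$loci$chrom == chromosome)
  check_that(length(idx) >= 2, "need at least two markers on the chromosome")
  idx <- idx[order(gm$loci$pos[idx])]
  r2 <- vapply(seq_len(length(idx) - 1), function(a) {
    r2_pair(gm$geno[, idx[a]], gm$geno[, idx[a + 1]])
  }, numeric(1))
  r2 <- r2[!is.na(r2)]
  check_that(length(r2) >= 1, "no adjacent pair with defined r-squared")
  mean(r2)
}

#' Plot an LD decay profile
#'
#' @param profile Output of [ld_decay_profile()].
#' @return A ggplot of mean r-squared against bin midpoint.
#' @export
plot_ld_decay <- function(profile) {
  d <- mutate(profile, mid_kb = (.data$bin_start + .data$bin_end) / 2000)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mid_kb, y = .data$mean_r2)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "distance (kb)", y = expression(mean ~ r^2)) +
    ggplot2::theme_minimal()
}
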