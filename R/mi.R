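# Mutual information between each continuous feature and the discrete
# beat class, by the k-nearest-neighbour estimator for mixed
# continuous/discrete pairs (Ross 2014): for each point, take the
# distance to its k-th nearest neighbour among points with the same
# label, count the points of any label within that distance, and
# combine the digamma terms
#   MI = psi(N) - <psi(N_y)> + <psi(k_i)> - <psi(m_i)>.

mi_mixed_knn <- function(x, y, k = 3) {
  n <- length(x)
  counts <- table(y)
  keep <- y %in% names(counts)[counts > 1]
  x <- x[keep]; y <- y[keep]
  n_eff <- length(x)
  if (n_eff < 2) return(0)
  d <- numeric(n_eff); k_i <- integer(n_eff)
  for (lab in unique(y)) {
    idx <- which(y == lab)
    ord <- order(x[idx])
    xs <- x[idx][ord]
    nl <- length(xs)
    kk <- min(k, nl - 1)
    for (j in seq_len(nl)) {
      lo <- max(1, j - kk); hi <- min(nl, j + kk)
      dd <- sort(abs(xs[lo:hi] - xs[j]))
      d_j <- dd[kk + 1]  # k-th non-self neighbour
      d[idx[ord[j]]] <- d_j
      k_i[idx[ord[j]]] <- kk
    }
  }
  xs_all <- sort(x)
  m_i <- vapply(seq_len(n_eff), function(i) {
    hi <- findInterval(x[i] + d[i], xs_all, left.open = TRUE)  # x_j < x+d
    lo <- findInterval(x[i] - d[i], xs_all)                    # x_j <= x-d
    # points strictly inside the radius, the centre point included
    max(hi - lo, k_i[i], 1L)
  }, numeric(1))
  ny <- as.numeric(counts[match(y, names(counts))])
  mi <- digamma(n_eff) - mean(digamma(ny)) +
    mean(digamma(k_i)) - mean(digamma(m_i))
  max(mi, 0)
}

#' Rank features by mutual information with the beat class
#'
#' MI is estimated per feature by a k-nearest-neighbour estimator for
#' continuous-feature/discrete-label pairs (k = 3 by default). A
#' single seeded tie-breaking noise vector, scaled by each feature's
#' standard deviation, is shared across features so that duplicated
#' columns receive identical scores. Features are sorted by descending
#' MI, ties broken by feature name.
#'
#' @param features Data frame or matrix of per-beat features (rows =
#'   beats).
#' @param labels Per-beat class labels (>= 2 distinct values).
#' @param seed Seed for the tie-breaking noise.
#' @param k Neighbour count.
#' @return Tibble `feature`, `mi` (nats), sorted by descending `mi`.
#' @export
mi_rank <- function(features, labels, seed = 1L, k = 3) {
  features <- as.data.frame(features)
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) {
    stop("mutual-information ranking needs at least 2 classes")
  }
  stopifnot(nrow(features) == length(labels))
  noise <- with_local_rng(as.integer(seed),
                          stats::rnorm(length(labels)))
  scores <- vapply(names(features), function(nm) {
    x <- as.numeric(features[[nm]])
    s <- stats::sd(x)
    if (!is.finite(s)) s <- 0
    mi_mixed_knn(x + 1e-10 * max(s, 1e-30) * noise, labels, k = k)
  }, 0)
  tibble::tibble(feature = names(features), mi = unname(scores)) |>
    dplyr::arrange(dplyr::desc(.data$mi), .data$feature)
}

#' Select the top-ranked features
#'
#' @param ranked Output of [mi_rank()].
#' @param n_f Number of features to keep (default 6).
#' @return Character vector of the first `n_f` feature names.
#' @export
select_top <- function(ranked, n_f = 6) {
  stopifnot(n_f >= 0, n_f <= nrow(ranked))
  utils::head(ranked$feature, n_f)
}
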