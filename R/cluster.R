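# Nonparametric cluster-based permutation tests over channel x frequency,
# channel x time, and time-only data (paired designs, sign-flip null).

#' Build the channel neighborhood graph
#'
#' Channels are neighbors iff their 3-D Euclidean distance is below
#' `radius` (40 mm by default).
#'
#' @param layout Sensor layout from [channel_layout()].
#' @param radius Neighborhood radius in meters.
#' @return An object of class `neighbor_graph`: `adjacency` (logical,
#'   symmetric, irreflexive), `radius`, `degree`.
#' @export
build_neighbors <- function(layout, radius = 0.040) {
  d <- layout_distances(layout)
  adj <- d < radius
  diag(adj) <- FALSE
  structure(
    list(adjacency = adj, radius = radius, degree = rowSums(adj)),
    class = "neighbor_graph"
  )
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat(sprintf(
    "<neighbor_graph> %d channels, radius %.0f mm, mean degree %.1f\n",
    nrow(x$adjacency), x$radius * 1000, mean(x$degree)
  ))
  invisible(x)
}

# Cluster a thresholded t map. tmat: channel x bin. Returns list of
# clusters (cell indices + mass). A supra-threshold sample enters a
# cluster only if at least `min_neighbors` of its spatial neighbors are
# supra-threshold with the same sign in the same bin (FieldTrip-style
# gating; disabled when `adj` is NULL, i.e. the 1-D case).
cluster_mask <- function(tmat, crit, adj, min_neighbors) {
  n_ch <- nrow(tmat)
  n_bin <- ncol(tmat)
  out <- list()
  for (sign in c(1, -1)) {
    mask <- if (sign > 0) tmat > crit else tmat < -crit
    if (!any(mask)) next
    if (!is.null(adj) && min_neighbors > 0) {
      nb_count <- adj %*% mask
      mask <- mask & (nb_count >= min_neighbors)
      if (!any(mask)) next
    }
    # connected components over (channel, bin) cells
    lab <- matrix(0L, n_ch, n_bin)
    cur <- 0L
    cells <- which(mask, arr.ind = TRUE)
    for (k in seq_len(nrow(cells))) {
      ch0 <- cells[k, 1]
      b0 <- cells[k, 2]
      if (lab[ch0, b0] != 0L) next
      cur <- cur + 1L
      queue <- matrix(c(ch0, b0), 1)
      lab[ch0, b0] <- cur
      while (nrow(queue)) {
        ch <- queue[1, 1]
        b <- queue[1, 2]
        queue <- queue[-1, , drop = FALSE]
        cand <- NULL
        if (b > 1 && mask[ch, b - 1] && lab[ch, b - 1] == 0L) {
          cand <- rbind(cand, c(ch, b - 1L))
        }
        if (b < n_bin && mask[ch, b + 1] && lab[ch, b + 1] == 0L) {
          cand <- rbind(cand, c(ch, b + 1L))
        }
        if (!is.null(adj)) {
          nbs <- which(adj[ch, ] & mask[, b] & lab[, b] == 0L)
          if (length(nbs)) cand <- rbind(cand, cbind(nbs, b))
        }
        if (!is.null(cand)) {
          lab[cand] <- cur
          queue <- rbind(queue, cand)
        }
      }
      members <- which(lab == cur, arr.ind = TRUE)
      out[[length(out) + 1]] <- list(
        sign = sign, members = members,
        mass = sum(tmat[members])
      )
    }
  }
  out
}

max_cluster_mass <- function(tmat, crit, adj, min_neighbors) {
  cl <- cluster_mask(tmat, crit, adj, min_neighbors)
  if (!length(cl)) {
    return(0)
  }
  max(abs(vapply(cl, `[[`, numeric(1), "mass")))
}

# shared engine for the 2-D (channel x bin) and 1-D (bin only) tests
cluster_perm_engine <- function(diff, crit, adj, min_neighbors, n_perm,
                                seed, channels, bins) {
  n <- nrow(diff)
  p_cells <- ncol(diff)
  n_ch <- if (is.null(adj)) 1L else nrow(adj)
  n_bin <- p_cells / n_ch
  ss <- colSums(diff^2)
  t_of <- function(m) {
    v <- (ss - n * m^2) / (n - 1)
    tvec <- m / sqrt(pmax(v, .Machine$double.eps) / n)
    matrix(tvec, n_ch, n_bin)
  }
  t_obs <- t_of(colMeans(diff))
  clusters <- cluster_mask(t_obs, crit, adj, min_neighbors)
  null_max <- with_seed(seed, {
    S <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    M <- (S %*% diff) / n
    vapply(seq_len(n_perm), function(i) {
      max_cluster_mass(t_of(M[i, ]), crit, adj, min_neighbors)
    }, numeric(1))
  })
  tbl <- if (length(clusters)) {
    tibble::tibble(
      cluster = seq_along(clusters),
      sign = vapply(clusters, `[[`, numeric(1), "sign"),
      mass = vapply(clusters, `[[`, numeric(1), "mass"),
      n_cells = vapply(clusters, function(c) nrow(c$members), integer(1)),
      p = vapply(clusters, function(c) {
        (1 + sum(null_max >= abs(c$mass))) / (1 + n_perm)
      }, numeric(1))
    )
  } else {
    tibble::tibble(
      cluster = integer(), sign = numeric(), mass = numeric(),
      n_cells = integer(), p = numeric()
    )
  }
  structure(
    list(
      clusters = tbl,
      members = lapply(clusters, `[[`, "members"),
      t_obs = t_obs, crit = crit, null_max = null_max,
      n_perm = n_perm, seed = seed, channels = channels, bins = bins
    ),
    class = "cluster_result"
  )
}

#' Cluster-based permutation test over channel x bin data
#'
#' Paired test between two conditions measured as participant x channel x
#' bin arrays (bins are frequency or time). Dependent-samples t values are
#' thresholded at the two-tailed `alpha_cluster` critical value,
#' supra-threshold samples are clustered by spatial adjacency (the
#' neighbor graph) and bin adjacency with positive and negative clusters
#' formed separately, cluster mass is the summed t, and each observed
#' mass is referred to the permutation null of the maximum absolute mass
#' under random within-participant condition swaps (sign flips of the
#' paired differences). The Monte Carlo p includes the observed statistic:
#' `p = (1 + #[null >= observed]) / (1 + n_perm)`, so the smallest
#' attainable p is `1/(n_perm + 1)`.
#'
#' A supra-threshold sample is clusterable only if at least
#' `min_neighbors` spatial neighbors are supra-threshold in the same bin.
#'
#' @param data_a,data_b Arrays participant x channel x bin.
#' @param graph A [build_neighbors()] graph.
#' @param alpha_cluster Two-tailed cluster-forming alpha (0.025).
#' @param min_neighbors Minimum supra-threshold spatial neighbors (2).
#' @param n_perm Number of random permutations.
#' @param seed Integer seed for the permutation draw.
#' @param bins Optional labels for the bin axis.
#' @return A `cluster_result`: tibble of clusters (sign, mass, Monte Carlo
#'   p), member cells, the observed t map, and the null distribution.
#' @export
cluster_permutation <- function(data_a, data_b, graph, alpha_cluster = 0.025,
                                min_neighbors = 2, n_perm = 1000, seed = 1,
                                bins = NULL) {
  if (!identical(dim(data_a), dim(data_b))) {
    abort("`data_a` and `data_b` must have identical dimensions")
  }
  if (length(dim(data_a)) != 3) {
    abort("expected participant x channel x bin arrays")
  }
  n <- dim(data_a)[1]
  if (n < 2) abort("need at least 2 participants")
  if (dim(data_a)[2] != nrow(graph$adjacency)) {
    abort("channel dimension does not match the neighbor graph")
  }
  diff <- data_a - data_b
  dim(diff) <- c(n, dim(data_a)[2] * dim(data_a)[3])
  crit <- qt(1 - alpha_cluster / 2, n - 1)
  cluster_perm_engine(
    diff, crit, graph$adjacency, min_neighbors, n_perm,
    seed,
    channels = rownames(graph$adjacency),
    bins = bins %||% seq_len(dim(data_a)[3])
  )
}

#' Cluster-based permutation test over time-only data
#'
#' The same procedure as [cluster_permutation()] without the spatial
#' dimension: adjacency is between consecutive time bins only (used for
#' pupil time courses and single-channel profiles).
#'
#' @param data_a,data_b Matrices participant x time.
#' @inheritParams cluster_permutation
#' @return A `cluster_result`.
#' @export
cluster_permutation_1d <- function(data_a, data_b, alpha_cluster = 0.025,
                                   n_perm = 1000, seed = 1, bins = NULL) {
  if (!identical(dim(data_a), dim(data_b))) {
    abort("`data_a` and `data_b` must have identical dimensions")
  }
  n <- nrow(data_a)
  if (n < 2) abort("need at least 2 participants")
  diff <- data_a - data_b
  crit <- qt(1 - alpha_cluster / 2, n - 1)
  cluster_perm_engine(
    diff, crit,
    adj = NULL, min_neighbors = 0, n_perm, seed,
    channels = NULL, bins = bins %||% seq_len(ncol(data_a))
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf(
    "<cluster_result> %d cluster(s), %d permutations (min p = %.4g)\n",
    nrow(x$clusters), x$n_perm, 1 / (x$n_perm + 1)
  ))
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}

#' @rdname cluster_permutation
#' @param x A `cluster_result`.
#' @param ... Unused.
#' @export
tidy.cluster_result <- function(x, ...) {
  x$clusters
}

#' @rdname cluster_permutation
#' @export
glance.cluster_result <- function(x, ...) {
  tibble::tibble(
    n_clusters = nrow(x$clusters),
    min_p = if (nrow(x$clusters)) min(x$clusters$p) else NA_real_,
    n_perm = x$n_perm,
    crit_t = x$crit
  )
}
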