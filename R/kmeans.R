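#' Matched-restart k-means clustering
#'
#' Runs Lloyd's k-means `restarts` times from random initializations
#' (uniform random selection of `k` distinct observations as initial
#' centers, or k-means++ if requested), keeps the best-inertia solution and
#' reports a *stability* score: the fraction of restarts whose centroid
#' sets, after optimal matching against the best run's centroids
#' ([match_centroids()]), coincide within a relative L2 tolerance of 1e-6.
#' A stability of 1.0 is the restart-agreement property ("every restart
#' found the same collection of cluster centers").
#'
#' Empty clusters arising during Lloyd iterations are re-seeded at the
#' observation farthest from its currently assigned centroid (distinct
#' points preferred), which lets duplicated initial centers escape to
#' uncovered regions.
#'
#' @param X Numeric matrix, rows = observations (typically de-correlated
#'   charts from [apply_decorrelation()]).
#' @param k Number of clusters, `1 <= k <= nrow(X)`.
#' @param restarts Number of random restarts.
#' @param seed Integer seed; the full run is deterministic given it.
#' @param init `"random"` (uniform choice of data points, the default) or
#'   `"kmeans++"`.
#' @param max_iter Lloyd iteration cap per restart.
#' @return A `cluster_result`: list with `k`, `centroids` (k x ncol(X)),
#'   `assignments` (integer per row of X), `inertia`, `stability`,
#'   `restarts`, `seed`.
#' @export
kmeans_restarts <- function(X, k, restarts = 100, seed = NULL,
                            init = c("random", "kmeans++"), max_iter = 200) {
  X <- as.matrix(X)
  n <- nrow(X)
  init <- match.arg(init)
  if (k < 1) stop("k must be >= 1")
  if (k > n) stop(sprintf("k = %d exceeds the number of observations (%d)", k, n))
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  runs <- vector("list", restarts)
  for (r in seq_len(restarts)) {
    centers <- if (init == "random") X[sample.int(n, k), , drop = FALSE]
               else kmeanspp_init(X, k)
    fit <- lloyd(X, centers, max_iter)
    runs[[r]] <- fit
    if (is.null(best) || fit$inertia < best$inertia) best <- fit
  }
  scale <- 1 + sqrt(sum(best$centroids^2))
  agree <- vapply(runs, function(f) {
    m <- match_centroids(f$centroids, best$centroids)
    m$cost / scale <= 1e-6
  }, logical(1))
  structure(list(k = k, centroids = best$centroids,
                 assignments = best$assignments, inertia = best$inertia,
                 stability = mean(agree), restarts = restarts, seed = seed),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: k = %d, inertia = %.6g, stability = %.2f over %d restarts\n",
              x$k, x$inertia, x$stability, x$restarts))
  invisible(x)
}

# squared Euclidean distances between rows of X and rows of C
dist2_to_centers <- function(X, C) {
  d2 <- outer(rowSums(X^2), rowSums(C^2), "+") - 2 * X %*% t(C)
  pmax(d2, 0)
}

lloyd <- function(X, centers, max_iter) {
  n <- nrow(X); k <- nrow(centers)
  assign_old <- integer(0)
  for (iter in seq_len(max_iter)) {
    d2 <- dist2_to_centers(X, centers)
    assignments <- max.col(-d2, ties.method = "first")
    empties <- setdiff(seq_len(k), unique(assignments))
    if (length(empties)) {
      # re-seed each empty centroid at the point farthest from its assigned
      # center, preferring points distinct from all current centers
      dmin <- d2[cbind(seq_len(n), assignments)]
      ord <- order(dmin, decreasing = TRUE)
      used <- integer(0)
      for (e in empties) {
        cand <- ord[!(ord %in% used)]
        distinct <- cand[vapply(cand, function(i)
          min(dist2_to_centers(X[i, , drop = FALSE], centers)) > 0, logical(1))]
        pick <- if (length(distinct)) distinct[1] else cand[1]
        centers[e, ] <- X[pick, ]
        used <- c(used, pick)
      }
      next
    }
    if (identical(assignments, assign_old)) break
    assign_old <- assignments
    centers <- rowsum(X, assignments) / as.numeric(table(assignments))
  }
  d2 <- dist2_to_centers(X, centers)
  assignments <- max.col(-d2, ties.method = "first")
  inertia <- sum(d2[cbind(seq_len(n), assignments)])
  list(centroids = centers, assignments = assignments, inertia = inertia)
}

kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- X[sample.int(n, 1), , drop = FALSE]
  while (nrow(centers) < k) {
    d2 <- apply(dist2_to_centers(X, centers), 1, min)
    probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers <- rbind(centers, X[sample.int(n, 1, prob = probs), ])
  }
  centers
}

#' Optimal matching between two centroid sets
#'
#' Finds the bijection between two sets of k centroids minimizing the total
#' Euclidean distance between matched pairs (the assignment problem, solved
#' exactly by dynamic programming over column subsets; intended for the
#' k <= 16 range of cluster hierarchies).  Used to compare restarts and
#' consecutive hierarchy levels, where cluster labels are arbitrary.
#'
#' @param a,b Centroid matrices with the same number of columns;
#'   `nrow(a) <= nrow(b)` (equal for restart matching, `k` vs `k+1` for
#'   hierarchy links).
#' @return List with `permutation` (for each row of `a`, the matched row of
#'   `b`) and `cost` (total Euclidean distance over matched pairs).
#' @export
match_centroids <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (ncol(a) != ncol(b)) stop("centroid dimensionality differs")
  if (nrow(a) > nrow(b))
    stop(sprintf("cannot match %d centroids into %d", nrow(a), nrow(b)))
  cost <- sqrt(dist2_to_centers(a, b))
  sol <- assignment_dp(cost)
  list(permutation = sol$match, cost = sol$cost)
}

# exact rectangular assignment (n rows into m >= n columns) by bitmask DP
assignment_dp <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  if (m > 16) stop("assignment solver supports at most 16 columns")
  nmask <- bitwShiftL(1L, m)
  f <- rep(Inf, nmask); f[1] <- 0
  from <- integer(nmask)   # which column was added to reach this mask
  bitcount <- vapply(0:(nmask - 1), function(x) sum(bitwAnd(x, bitwShiftL(1L, 0:15)) > 0), numeric(1))
  for (mask in (0:(nmask - 1))[order(bitcount)]) {
    r <- bitcount[mask + 1] + 1   # next row to assign
    if (r > n || !is.finite(f[mask + 1])) next
    for (j in seq_len(m)) {
      bit <- bitwShiftL(1L, j - 1)
      if (bitwAnd(mask, bit) == 0) {
        nm <- bitwOr(mask, bit)
        v <- f[mask + 1] + cost[r, j]
        if (v < f[nm + 1]) { f[nm + 1] <- v; from[nm + 1] <- j }
      }
    }
  }
  full <- which(bitcount == n) - 1
  bestmask <- full[which.min(f[full + 1])]
  # backtrack
  match <- integer(n)
  mask <- bestmask
  for (r in n:1) {
    j <- from[mask + 1]
    match[r] <- j
    mask <- bitwAnd(mask, bitwNot(bitwShiftL(1L, j - 1)))
  }
  list(match = match, cost = f[bestmask + 1])
}

#' k-means hierarchy across a range of k with persistence links
#'
#' Runs [kmeans_restarts()] independently for each `k` in
#' `k_min..k_max` (seeds derived deterministically from `seed`), then reads
#' the sequence left to right, matching the `k` centroids of each level
#' into the `k + 1` centroids of the next by optimal partial assignment.
#' The matched pairs are reported as *persistence links* (with matching
#' distances), and the centroid sets are scanned for *split-and-re-merge*
#' events: a cluster center present at some level, absent (no centroid
#' within tolerance) at a later level, and present again at a yet later
#' level — the "clusters splitting and re-merging" pathology that motivates
#' de-correlating before clustering.  In a well-behaved hierarchy, once a
#' center has been picked it persists (approximately unchanged) through all
#' larger k; coarse centers that dissolve as k grows simply never return.
#' Presence is judged by nearest-centroid distance against
#' `persistence_tol` times the overall centroid diameter.
#'
#' @inheritParams kmeans_restarts
#' @param k_min,k_max Range of cluster counts (inclusive).
#' @param persistence_tol Relative tolerance (fraction of the centroid-set
#'   diameter) under which two centroids count as the same center.
#' @return A `cluster_hierarchy`: list with `results` (one `cluster_result`
#'   per k), `links` (data frame `k`, `from`, `to`, `distance`), and
#'   `split_remerge_events` (data frame `k_seen`, `cluster`, `k_absent`,
#'   `k_reappear`, one row per vanish-and-return pattern; zero rows = clean
#'   hierarchy).
#' @export
cluster_hierarchy <- function(X, k_min = 2, k_max = 11, restarts = 100,
                              seed = NULL, init = "random",
                              persistence_tol = 0.01) {
  X <- as.matrix(X)
  if (k_min > k_max) stop("k_min must be <= k_max")
  if (k_max > nrow(X)) stop("k_max exceeds the number of observations")
  ks <- k_min:k_max
  results <- lapply(ks, function(k)
    kmeans_restarts(X, k, restarts = restarts,
                    seed = if (is.null(seed)) NULL else seed + 101L * k,
                    init = init))
  names(results) <- paste0("k", ks)
  links <- NULL
  if (length(ks) > 1) {
    links <- do.call(rbind, lapply(seq_len(length(ks) - 1), function(i) {
      m <- match_centroids(results[[i]]$centroids, results[[i + 1]]$centroids)
      pair_d <- sqrt(rowSums((results[[i]]$centroids -
                              results[[i + 1]]$centroids[m$permutation, , drop = FALSE])^2))
      data.frame(k = ks[i], from = seq_len(ks[i]), to = m$permutation,
                 distance = pair_d)
    }))
  }
  events <- split_remerge_events(lapply(results, `[[`, "centroids"), ks,
                                 tol = persistence_tol)
  structure(list(results = results, links = links,
                 split_remerge_events = events,
                 k_min = k_min, k_max = k_max),
            class = "cluster_hierarchy")
}

#' Detect vanish-and-reappear cluster centers across hierarchy levels
#'
#' For every centroid of every level, builds its presence profile over the
#' later levels (present = some centroid of that level lies within
#' `tol * diameter`, where diameter is the largest distance between any two
#' centroids across all levels) and flags centers that are absent at some
#' level and present again later.
#'
#' @param centroid_list List of centroid matrices, one per level (same
#'   column dimension).
#' @param ks Integer vector of the k value of each level.
#' @param tol Relative presence tolerance.
#' @return Data frame `k_seen`, `cluster`, `k_absent`, `k_reappear` (zero
#'   rows if the hierarchy is clean).
#' @export
split_remerge_events <- function(centroid_list, ks, tol = 0.01) {
  out <- data.frame(k_seen = integer(0), cluster = integer(0),
                    k_absent = integer(0), k_reappear = integer(0))
  L <- length(centroid_list)
  if (L < 3) return(out)
  allc <- do.call(rbind, centroid_list)
  diam <- sqrt(max(dist2_to_centers(allc, allc)))
  eps <- tol * diam
  for (li in seq_len(L - 2)) {
    C <- centroid_list[[li]]
    for (ci in seq_len(nrow(C))) {
      u <- C[ci, , drop = FALSE]
      present <- vapply(seq(li + 1, L), function(lj)
        sqrt(min(dist2_to_centers(u, centroid_list[[lj]]))) <= eps, logical(1))
      gone <- which(!present)[1]
      if (is.na(gone)) next
      back <- which(present[seq(gone, length(present))])[1]
      if (is.na(back)) next
      out <- rbind(out, data.frame(k_seen = ks[li], cluster = ci,
                                   k_absent = ks[li + gone],
                                   k_reappear = ks[li + gone + back - 1]))
    }
  }
  out
}

#' @export
print.cluster_hierarchy <- function(x, ...) {
  cat(sprintf("cluster_hierarchy: k = %d..%d, %d split-and-re-merge event(s)\n",
              x$k_min, x$k_max, nrow(x$split_remerge_events)))
  invisible(x)
}

#' Sum the original charts belonging to each cluster
#'
#' For display, clustering runs in the de-correlated space but results are
#' rendered in the original response space: per cluster, the entrywise sum
#' of the untransformed charts assigned to it.
#'
#' @param charts The original `chart_set` that was clustered.
#' @param assignments Integer cluster ids, one per chart.
#' @return A cluster-level `chart_set`, one summed chart per cluster.
#' @export
cluster_sum_charts <- function(charts, assignments) {
  if (!inherits(charts, "chart_set")) stop("charts must be a chart_set")
  if (length(assignments) != nrow(charts$values))
    stop("assignments must cover all charts")
  values <- rowsum(charts$values, group = assignments, reorder = TRUE)
  info <- data.frame(language = "cluster",
                     term = paste0("cluster", rownames(values)),
                     stringsAsFactors = FALSE)
  chart_set(values, info, charts$chip_id, "cluster")
}
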