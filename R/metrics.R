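#' Euclidean distance between two charts
#'
#' The baseline vector metric: `sqrt(sum_c (P_c - Q_c)^2)` over chip entries.
#' It is invariant under any permutation of the chips applied to both charts,
#' so it ignores the perceptual layout entirely — the central pitfall the
#' ground-metric-aware distances in this package address.
#'
#' @param p,q Numeric chart vectors of equal length.
#' @return A single nonnegative number.
#' @export
euclidean_distance <- function(p, q) {
  p <- chart_values(p); q <- chart_values(q)
  if (length(p) != length(q)) stop("charts have different lengths")
  sqrt(sum((p - q)^2))
}

#' Pearson correlation between two charts
#'
#' The correlation of the two charts' entries, using each chart's sample
#' mean and standard deviation.  A *similarity* in [-1, 1], permutation
#' invariant like [euclidean_distance()].  For ranking it is converted to
#' the dissimilarity `1 - r`.
#'
#' @param p,q Numeric chart vectors of equal length, neither constant.
#' @return Correlation coefficient in [-1, 1].
#' @export
pearson_similarity <- function(p, q) {
  p <- chart_values(p); q <- chart_values(q)
  if (length(p) != length(q)) stop("charts have different lengths")
  if (sd(p) == 0 || sd(q) == 0)
    stop("correlation undefined: constant chart (zero variance)")
  cor(p, q)
}

chart_values <- function(x) {
  if (inherits(x, "chart_set")) stop("expected a single chart vector, got a chart_set")
  v <- as.numeric(x)
  if (anyNA(v)) stop("chart contains NA")
  v
}

#' Earth Mover's Distance between two charts
#'
#' Interprets the charts as piles of mass over the chips and computes the
#' minimum work (mass times ground distance) needed to transform one into
#' the other, by solving the transportation linear program
#' `min sum_ij f_ij D_ij` subject to the flow constraints.  With
#' `normalize = TRUE` (default) both charts are scaled to unit mass first,
#' which makes charts with very different totals comparable; otherwise the
#' raw masses are used and the optimal work is divided by the total flow
#' `min(sum P, sum Q)` (partial matching).  Zero-mass bins are dropped from
#' the LP.
#'
#' @param p,q Numeric chart vectors with positive total mass.
#' @param D Ground distance matrix over the same chips
#'   ([ground_distance_matrix()]).
#' @param normalize Scale both charts to unit mass first.
#' @param flow If `TRUE`, return a list with the distance and the optimal
#'   flow plan as a sparse triplet data frame (`from`, `to`, `flow` in chip
#'   indices).
#' @return The EMD (mean ground distance travelled per unit of mass), or a
#'   list if `flow = TRUE`.
#' @examples
#' D <- ground_distance_matrix(synthetic_lab_coordinates(wcs_grid()))
#' p <- q <- numeric(330); p[50] <- 1; q[60] <- 2
#' emd(p, q, D) == D[50, 60]
#' @export
emd <- function(p, q, D, normalize = TRUE, flow = FALSE) {
  p <- chart_values(p); q <- chart_values(q)
  if (length(p) != length(q)) stop("charts have different lengths")
  if (!all(dim(D) == length(p))) stop("ground distance matrix does not match charts")
  emd_core(p, q, D, normalize = normalize, flow = flow)
}

emd_core <- function(p, q, D, normalize, flow = FALSE) {
  sp <- sum(p); sq <- sum(q)
  if (sp <= 0 || sq <= 0) stop("charts must have positive total mass")
  if (normalize) { p <- p / sp; q <- q / sq }
  i <- which(p > 0); j <- which(q > 0)
  sol <- emd_flow_cpp(p[i], q[j], D[i, j, drop = FALSE])
  if (sol$total_flow <= 0) stop("EMD solver failed: zero total flow")
  value <- sol$work / sol$total_flow
  if (!flow) return(value)
  f <- sol$flow
  nz <- which(f > 0, arr.ind = TRUE)
  plan <- data.frame(from = i[nz[, 1]], to = j[nz[, 2]], flow = f[nz])
  plan <- plan[order(plan$from, plan$to), ]
  rownames(plan) <- NULL
  list(value = value, flow = plan, total_flow = sol$total_flow)
}

#' Earth Mover's Distance across different stimulus grids
#'
#' Because EMD only needs chip-to-chip perceptual distances, charts elicited
#' on *different* charts (e.g. the 330-chip WCS grid and an 84-chip study)
#' can be compared directly: supply the rectangular Delta-E matrix between
#' the two chip sets.  Unit-mass normalization is always applied.
#'
#' @param p Chart on the first grid (length = `nrow(D12)`).
#' @param q Chart on the second grid (length = `ncol(D12)`).
#' @param D12 Rectangular nonnegative Delta-E matrix between the grids.
#' @inheritParams emd
#' @return The cross-support EMD.
#' @export
cross_support_emd <- function(p, q, D12, flow = FALSE) {
  p <- chart_values(p); q <- chart_values(q)
  if (nrow(D12) != length(p) || ncol(D12) != length(q))
    stop(sprintf("D12 must be %d x %d, got %d x %d",
                 length(p), length(q), nrow(D12), ncol(D12)))
  if (any(D12 < 0)) stop("ground distances must be nonnegative")
  emd_core(p, q, D12, normalize = TRUE, flow = flow)
}

#' Quadratic Chi-squared distance between two charts
#'
#' The cross-bin histogram distance of Pele & Werman: with normalizers
#' `Z_i = (sum_c (P_c + Q_c) A_ci)^m` and the convention 0/0 := 0,
#' \deqn{QC(P,Q) = \sqrt{\sum_{ij} \frac{P_i-Q_i}{Z_i}\,\frac{P_j-Q_j}{Z_j}\,A_{ij}}.}
#' The similarity matrix `A` injects the perceptual ground structure (here
#' the exponential Delta-E kernel from [similarity_matrix()]); the exponent
#' `m` in [0, 1) controls the chi-squared-style attenuation of differences
#' in heavily used regions.  With `A = I` and `m = 0` it reduces to the
#' Euclidean distance.  Tiny negative radicands (>= -1e-12, floating point)
#' are clamped to zero; anything more negative signals a non-PSD similarity
#' and is an error.
#'
#' @param p,q Numeric chart vectors of equal length.
#' @param A Chip similarity matrix over the same chips.
#' @param m Normalization exponent, `0 <= m < 1`; default 0.9 (the value
#'   recommended by the distance's authors).
#' @param normalize Scale both charts to unit mass first (default), so
#'   language charts with very different totals are comparable.
#' @return The QC distance, a nonnegative number.
#' @export
quadratic_chi <- function(p, q, A, m = 0.9, normalize = TRUE) {
  p <- chart_values(p); q <- chart_values(q)
  if (length(p) != length(q)) stop("charts have different lengths")
  if (!all(dim(A) == length(p))) stop("similarity matrix does not match charts")
  if (!(m >= 0 && m < 1)) stop("m must satisfy 0 <= m < 1")
  if (normalize) {
    sp <- sum(p); sq <- sum(q)
    if (sp <= 0 || sq <= 0) stop("charts must have positive total mass")
    p <- p / sp; q <- q / sq
  }
  Z <- as.numeric((p + q) %*% A)^m
  d <- p - q
  r <- ifelse(Z == 0, 0, d / Z)   # 0/0 := 0 (Z_i = 0 forces P_i = Q_i = 0)
  val2 <- as.numeric(r %*% A %*% r)
  if (val2 < -1e-12)
    stop(sprintf("negative QC radicand %.3e: similarity matrix is not PSD", val2))
  sqrt(max(val2, 0))
}

#' Metric specifications
#'
#' Internal dispatcher turning a metric name plus its parameters into a
#' pair function.  `emd` needs `D`, `qchi2` needs `K`; `pearson` is a
#' similarity (handled by callers).
#' @noRd
chart_metric_fun <- function(metric, D = NULL, K = NULL, m = 0.9, normalize = TRUE) {
  metric <- match.arg(metric, c("euclidean", "pearson", "emd", "qchi2"))
  switch(metric,
    euclidean = euclidean_distance,
    pearson = pearson_similarity,
    emd = {
      if (is.null(D)) stop("metric 'emd' needs a ground distance matrix D")
      function(p, q) emd(p, q, D, normalize = normalize)
    },
    qchi2 = {
      if (is.null(K)) stop("metric 'qchi2' needs a similarity matrix K")
      function(p, q) quadratic_chi(p, q, K, m = m, normalize = normalize)
    })
}

metric_is_similarity <- function(metric) metric == "pearson"

#' Full pairwise dissimilarity matrix over a chart set
#'
#' Computes every unordered pair once and mirrors the result.  For the
#' distance-type metrics the result is symmetric with zero diagonal; for
#' `pearson` it is a similarity matrix with unit diagonal.
#'
#' @param charts A `chart_set` (or a plain numeric matrix, rows = charts).
#' @param metric One of `"euclidean"`, `"pearson"`, `"emd"`, `"qchi2"`.
#' @param D Ground distance matrix (required for `emd`).
#' @param K Similarity matrix (required for `qchi2`).
#' @param m QC exponent.
#' @param normalize Unit-mass normalization for `emd` / `qchi2`.
#' @return An n x n matrix with chart labels as dimnames and attributes
#'   `metric` and `parameters`.
#' @export
pairwise_distance_matrix <- function(charts, metric, D = NULL, K = NULL,
                                     m = 0.9, normalize = TRUE) {
  X <- if (inherits(charts, "chart_set")) charts$values else as.matrix(charts)
  n <- nrow(X)
  if (n < 2) stop("need at least 2 charts")
  fun <- chart_metric_fun(metric, D, K, m, normalize)
  M <- matrix(0, n, n, dimnames = list(rownames(X), rownames(X)))
  diag(M) <- if (metric_is_similarity(metric)) 1 else 0
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    v <- tryCatch(fun(X[i, ], X[j, ]), error = function(e)
      stop(sprintf("metric failed for pair (%s, %s): %s",
                   rownames(X)[i] %||% i, rownames(X)[j] %||% j,
                   conditionMessage(e)), call. = FALSE))
    M[i, j] <- M[j, i] <- v
  }
  attr(M, "metric") <- metric
  attr(M, "parameters") <- list(m = m, normalize = normalize,
                                sigma = attr(K, "sigma"))
  M
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rank charts by dissimilarity to a reference chart
#'
#' Orders a set of charts by their dissimilarity to a reference word's
#' chart, ascending — the diagnostic used to probe whether a metric places
#' perceptually neighboring terms before diametrically opposed ones.
#' Similarities (`pearson`) are converted to the dissimilarity `1 - r`
#' before ranking.  Ties are broken lexicographically by chart label.
#'
#' @param reference A chart vector, or the label (rowname) of a chart in
#'   `charts`.
#' @param charts A `chart_set` or chart matrix.
#' @inheritParams pairwise_distance_matrix
#' @return A data frame `(label, value)` sorted by ascending dissimilarity.
#' @export
rank_by_distance <- function(reference, charts, metric, D = NULL, K = NULL,
                             m = 0.9, normalize = TRUE) {
  X <- if (inherits(charts, "chart_set")) charts$values else as.matrix(charts)
  if (is.character(reference) && length(reference) == 1) {
    if (!reference %in% rownames(X))
      stop("reference label '", reference, "' not found among charts")
    reference <- X[reference, ]
  }
  ref <- chart_values(reference)
  if (length(ref) != ncol(X)) stop("reference chart not comparable: wrong length")
  fun <- chart_metric_fun(metric, D, K, m, normalize)
  vals <- vapply(seq_len(nrow(X)), function(i) fun(ref, X[i, ]), numeric(1))
  if (metric_is_similarity(metric)) vals <- 1 - vals
  labels <- rownames(X) %||% as.character(seq_len(nrow(X)))
  out <- data.frame(label = labels, value = vals, stringsAsFactors = FALSE)
  out <- out[order(out$value, out$label), ]
  rownames(out) <- NULL
  out
}

#' Write a pairwise matrix as labelled TSV
#' @param M Matrix with dimnames.
#' @param path File path.
#' @param header_lines Provenance comment lines.
#' @export
write_distance_matrix <- function(M, path, header_lines = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header_lines) writeLines(paste0("# ", h), con)
  writeLines(paste(c("label", colnames(M)), collapse = "\t"), con)
  write.table(cbind(rownames(M), format(M, digits = 12, trim = TRUE)), con,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
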