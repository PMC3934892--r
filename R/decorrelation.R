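#' Cholesky de-correlation operator from a similarity kernel
#'
#' Factors the chip similarity matrix as `K = R'R` (Cholesky, `R` upper
#' triangular).  Applying `R` to chart vectors turns the kernel bilinear
#' form into the canonical inner product — `<Rx, Ry> = x'Ky` — so that
#' classical Euclidean statistics (k-means, PCA, ...) on the transformed
#' vectors implicitly respect the perceptual similarity structure.
#' Perceptually close chips produce correlated responses; this transform
#' controls for exactly that expected correlation.
#'
#' If the plain factorization fails numerically, `jitter * I` is added once
#' and the factorization retried; failing that, an error reports the
#' smallest eigenvalue.
#'
#' @param K Similarity matrix from [similarity_matrix()] (symmetric PSD).
#' @param jitter Diagonal regularization used only on retry.
#' @return A `decorrelation_operator`: list with the factor `R`, the kernel
#'   bandwidth `sigma`, and a grid fingerprint (dimension + chip ids).
#' @export
factor_similarity <- function(K, jitter = 1e-10) {
  K <- as.matrix(K)
  if (nrow(K) != ncol(K) || max(abs(K - t(K))) > 1e-8)
    stop("K must be symmetric")
  R <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(R))
    R <- tryCatch(chol(K + diag(jitter, nrow(K))), error = function(e) NULL)
  if (is.null(R)) {
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    stop(sprintf(
      "similarity matrix is not positive semidefinite (smallest eigenvalue %.3e)",
      min(ev)))
  }
  attr(R, "sigma") <- NULL
  attr(R, "min_eigenvalue") <- NULL
  structure(list(R = R, sigma = attr(K, "sigma"),
                 n = nrow(K), chip_id = colnames(K)),
            class = "decorrelation_operator")
}

#' @export
print.decorrelation_operator <- function(x, ...) {
  cat(sprintf("decorrelation_operator: %d x %d Cholesky factor (sigma = %s)\n",
              x$n, x$n, format(x$sigma)))
  invisible(x)
}

#' Apply the de-correlation transform to charts
#'
#' Maps each chart `x` to `R x`.  After the transform, ordinary Euclidean
#' distance between charts equals the kernel-induced distance
#' `sqrt(x'Kx - 2 x'Ky + y'Ky)`: disjoint charts on perceptually close
#' chips end up closer than disjoint charts on remote chips.
#'
#' @param op A `decorrelation_operator` from [factor_similarity()].
#' @param charts A numeric vector, a matrix (rows = charts), or a
#'   `chart_set`.
#' @return Transformed vector or matrix (same rows as the input).
#' @export
apply_decorrelation <- function(op, charts) {
  if (!inherits(op, "decorrelation_operator")) stop("not a decorrelation_operator")
  X <- if (inherits(charts, "chart_set")) charts$values
       else if (is.matrix(charts)) charts
       else matrix(as.numeric(charts), nrow = 1)
  if (ncol(X) != op$n)
    stop(sprintf("dimension mismatch: operator is %d-dimensional, charts have %d entries",
                 op$n, ncol(X)))
  out <- X %*% t(op$R)          # row x  ->  (R x)'
  rownames(out) <- rownames(X)
  if (is.numeric(charts) && !is.matrix(charts)) as.numeric(out) else out
}

#' Persist / load a de-correlation operator as TSV
#'
#' The factor matrix is written as a TSV with a one-line provenance header
#' `# sigma=..., n=...`.
#'
#' @param op A `decorrelation_operator`.
#' @param path File path.
#' @export
write_decorrelation_operator <- function(op, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sigma=%s, n=%d", format(op$sigma), op$n), con)
  writeLines(paste(op$chip_id %||% seq_len(op$n), collapse = "\t"), con)
  write.table(format(op$R, digits = 17, trim = TRUE), con, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_decorrelation_operator
#' @export
read_decorrelation_operator <- function(path) {
  first <- readLines(path, n = 1)
  sigma <- NA_real_
  if (grepl("^# *sigma=", first))
    sigma <- suppressWarnings(as.numeric(sub("^# *sigma=([^,]+),.*$", "\\1", first)))
  tab <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    check.names = FALSE)
  R <- as.matrix(tab)
  colnames(R) <- names(tab)
  structure(list(R = unname(R) * 1, sigma = sigma, n = ncol(R),
                 chip_id = names(tab)),
            class = "decorrelation_operator")
}
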