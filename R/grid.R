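#' Construct the standard WCS stimulus grid
#'
#' The World Color Survey stimulus chart has 330 chips: 10 achromatic chips
#' (a grey scale, rows A through J at column 0) and 320 chromatic chips of
#' maximally saturated color (rows B through I, hue columns 1 through 40).
#' Chips are ordered deterministically row-major (A0, B0..B40, ..., I0..I40,
#' J0) and numbered `chip_id` 1..330; all matrices in the package follow this
#' order.
#'
#' @return A `chip_grid` data frame with columns `chip_id` (integer, 1..330),
#'   `row` (letter A-J, lightest to darkest), `col` (integer 0-40, 0 =
#'   achromatic) and `is_achromatic` (logical).
#' @examples
#' g <- wcs_grid()
#' nrow(g)                  # 330
#' sum(g$is_achromatic)     # 10
#' @export
wcs_grid <- function() {
  rows <- c(list(data.frame(row = "A", col = 0L)),
            lapply(LETTERS[2:9], function(r) data.frame(row = r, col = 0:40)),
            list(data.frame(row = "J", col = 0L)))
  g <- do.call(rbind, rows)
  g <- data.frame(chip_id = seq_len(nrow(g)), row = g$row, col = as.integer(g$col),
                  is_achromatic = g$col == 0L, stringsAsFactors = FALSE)
  class(g) <- c("chip_grid", "data.frame")
  g
}

assert_chip_grid <- function(grid) {
  if (!is.data.frame(grid) ||
      !all(c("chip_id", "row", "col", "is_achromatic") %in% names(grid)))
    stop("not a chip_grid: expected columns chip_id, row, col, is_achromatic")
  if (!identical(as.integer(grid$chip_id), seq_len(nrow(grid))))
    stop("chip_grid invariant violated: chip_ids must be contiguous 1..N")
  invisible(grid)
}

#' Synthetic CIELAB coordinates for a stimulus grid
#'
#' Places the chips of a grid in CIELAB space: lightness L* is assigned
#' linearly by row (row A lightest at `l_max`, the last row darkest at
#' `l_min`), chromatic chips sit on a hue circle of radius `chroma` in the
#' (a*, b*) plane at hue angle `2 * pi * (col - 1) / 40`, and achromatic chips
#' have a* = b* = 0.  This is a stand-in coordinate table with the qualitative
#' geometry of the real chart (perceptually even hue spacing, a grey axis);
#' measured chip coordinates can be supplied through [load_lab_table()]
#' instead.
#'
#' @param grid A [wcs_grid()]-style `chip_grid`.
#' @param chroma Hue-circle radius for chromatic chips, CIELAB units (> 0).
#' @param l_min,l_max Lightness range, `0 <= l_min < l_max <= 100`.
#' @return A `lab_table` data frame with columns `chip_id`, `L`, `a`, `b`,
#'   one row per chip in grid order.
#' @examples
#' lab <- synthetic_lab_coordinates(wcs_grid())
#' @export
synthetic_lab_coordinates <- function(grid, chroma = 40, l_min = 15, l_max = 95) {
  assert_chip_grid(grid)
  if (chroma <= 0) stop("chroma must be > 0")
  if (!(l_min >= 0 && l_min < l_max && l_max <= 100))
    stop("need 0 <= l_min < l_max <= 100")
  lev <- match(grid$row, LETTERS)
  if (anyNA(lev)) stop("grid rows must be single letters A-J")
  nlev <- max(lev)
  L <- l_max - (lev - 1) / (nlev - 1) * (l_max - l_min)
  theta <- 2 * pi * (grid$col - 1) / 40
  a <- ifelse(grid$is_achromatic, 0, chroma * cos(theta))
  b <- ifelse(grid$is_achromatic, 0, chroma * sin(theta))
  lab <- data.frame(chip_id = grid$chip_id, L = L, a = a, b = b)
  class(lab) <- c("lab_table", "data.frame")
  lab
}

#' Read / write a chip CIELAB coordinate table
#'
#' The on-disk format is a TSV with a header row and columns
#' `chip_id`, `L`, `a`, `b` — a trivially reformatted version of the WCS
#' `cnum-vhcm-lab-new` distribution file fits it.
#'
#' @param path File path.
#' @param grid Optional `chip_grid`; if supplied, the table must cover every
#'   chip of the grid.
#' @return `load_lab_table()`: a `lab_table` data frame sorted by `chip_id`.
#' @examples
#' lab <- synthetic_lab_coordinates(wcs_grid())
#' f <- tempfile(fileext = ".tsv")
#' write_lab_table(lab, f)
#' identical(load_lab_table(f)$L, lab$L)
#' @export
load_lab_table <- function(path, grid = NULL) {
  tab <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
  need <- c("chip_id", "L", "a", "b")
  if (!all(need %in% names(tab)))
    stop("lab table must have columns chip_id, L, a, b; got: ",
         paste(names(tab), collapse = ", "))
  tab <- tab[need]
  for (cn in need) {
    v <- suppressWarnings(as.numeric(tab[[cn]]))
    bad <- which(is.na(v) & !is.na(tab[[cn]]))
    if (length(bad) || anyNA(tab[[cn]]))
      stop(sprintf("non-numeric or missing '%s' in lab table at data line %d",
                   cn, c(bad, which(is.na(tab[[cn]])))[1]))
    tab[[cn]] <- v
  }
  dup <- which(duplicated(tab$chip_id))
  if (length(dup))
    stop(sprintf("duplicate chip_id %d in lab table at data line %d",
                 as.integer(tab$chip_id[dup[1]]), dup[1]))
  if (!is.null(grid)) {
    assert_chip_grid(grid)
    missing <- setdiff(grid$chip_id, tab$chip_id)
    if (length(missing))
      stop("lab table is missing chips: ", paste(head(missing, 5), collapse = ", "))
    tab <- tab[tab$chip_id %in% grid$chip_id, ]
  }
  tab <- tab[order(tab$chip_id), ]
  rownames(tab) <- NULL
  class(tab) <- c("lab_table", "data.frame")
  tab
}

#' @rdname load_lab_table
#' @param lab A `lab_table`.
#' @export
write_lab_table <- function(lab, path) {
  write.table(as.data.frame(lab)[c("chip_id", "L", "a", "b")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pairwise CIELAB-76 ground distances between chips
#'
#' Computes the N x N matrix of Delta-E distances
#' `D_ij = sqrt((L_i-L_j)^2 + (a_i-a_j)^2 + (b_i-b_j)^2)` — the CIELAB-76
#' Euclidean definition of perceptual dissimilarity.  This is the ground
#' metric underlying [emd()] and, through [similarity_matrix()], the
#' Quadratic Chi-squared distance and the de-correlation transform.
#'
#' @param lab A complete `lab_table`.
#' @return A symmetric numeric matrix with zero diagonal, dimnames =
#'   chip ids.
#' @export
ground_distance_matrix <- function(lab) {
  if (!all(c("L", "a", "b") %in% names(lab))) stop("not a lab_table")
  D <- as.matrix(dist(as.matrix(lab[, c("L", "a", "b")]), method = "euclidean"))
  dimnames(D) <- list(lab$chip_id, lab$chip_id)
  D
}

#' Exponential chip-similarity kernel
#'
#' Turns ground distances into similarities `K_ij = exp(-D_ij / sigma)`.
#' The bandwidth `sigma` (CIELAB units) controls how quickly similarity
#' decays with perceptual distance; the default 30 gives a wide spread of
#' off-diagonal values (roughly 0.01 to 0.95) on the synthetic 330-chip
#' table.  The exponential of a Euclidean metric is positive semidefinite;
#' the smallest eigenvalue is computed and attached as a diagnostic.
#'
#' @param D Ground distance matrix from [ground_distance_matrix()].
#' @param sigma Kernel bandwidth, CIELAB units (> 0).
#' @return A symmetric matrix with unit diagonal, attributes `sigma` and
#'   `min_eigenvalue`.
#' @export
similarity_matrix <- function(D, sigma = 30) {
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0)
    stop("sigma must be a single value > 0")
  K <- exp(-D / sigma)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  attr(K, "sigma") <- sigma
  attr(K, "min_eigenvalue") <- min(ev)
  K
}
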