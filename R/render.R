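#' Render a chart as a grayscale Munsell-chart raster
#'
#' Lays the chart out as the stimulus grid (rows A-J top to bottom, columns
#' 0-40 left to right) and writes a grayscale PNG with darker cells for
#' higher distribution values.  Grid positions that hold no chip (the
#' chromatic columns of the pure-grey rows) are white.
#'
#' @param chart Numeric chart vector in grid order.
#' @param grid The `chip_grid`.
#' @param path Output PNG path.
#' @param cell Pixel size of one grid cell.
#' @return Invisibly, the path.
#' @export
render_chart_grid <- function(chart, grid, path, cell = 10) {
  assert_chip_grid(grid)
  v <- chart_values(chart)
  if (length(v) != nrow(grid)) stop("chart length does not match grid")
  rows <- sort(unique(grid$row))
  nr <- length(rows); nc <- max(grid$col) + 1
  img <- matrix(1, nr, nc)      # empty positions stay white
  rel <- if (max(v) > 0) v / max(v) else v
  gray <- 0.92 - 0.84 * rel     # value 0 -> light grey, max -> near black
  img[cbind(match(grid$row, rows), grid$col + 1)] <- gray
  big <- img[rep(seq_len(nr), each = cell), rep(seq_len(nc), each = cell)]
  png::writePNG(big, target = path)
  invisible(path)
}
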