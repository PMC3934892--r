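#' Read / write a WCS-style response table
#'
#' A response table records which term each speaker used for each chip.
#' The file dialect is a 4-column TSV with header
#' `language<TAB>speaker<TAB>chip<TAB>term`.  (The WCS archive's `term.txt`
#' has the same content with columns language, speaker, chip, term — it can
#' be used directly after adding this header.)  Each (language, speaker,
#' chip) triple may carry at most one term; rows duplicating an identical
#' triple+term are collapsed, conflicting terms for one triple are an error.
#'
#' @param path File path.
#' @param grid A `chip_grid`; chip ids are validated against it.
#' @return A `response_table` data frame with columns `language`, `speaker`,
#'   `chip_id`, `term`.
#' @export
read_responses <- function(path, grid) {
  assert_chip_grid(grid)
  tab <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "integer", "character"))
  if (!all(c("language", "speaker", "chip", "term") %in% names(tab)))
    stop("response table must have columns language, speaker, chip, term")
  rt <- data.frame(language = tab$language, speaker = tab$speaker,
                   chip_id = as.integer(tab$chip), term = tab$term,
                   stringsAsFactors = FALSE)
  validate_responses(rt, grid)
}

validate_responses <- function(rt, grid) {
  bad <- which(!(rt$chip_id %in% grid$chip_id))
  if (length(bad))
    stop(sprintf("unknown chip_id %d at data line %d (grid has %d chips)",
                 rt$chip_id[bad[1]], bad[1], nrow(grid)))
  rt <- unique(rt)
  key <- paste(rt$language, rt$speaker, rt$chip_id, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    d <- rt[dup[1], ]
    stop(sprintf(
      "conflicting terms for (language=%s, speaker=%s, chip=%d)",
      d$language, d$speaker, d$chip_id))
  }
  rownames(rt) <- NULL
  class(rt) <- c("response_table", "data.frame")
  rt
}

#' @rdname read_responses
#' @param rt A `response_table`.
#' @export
write_responses <- function(rt, path) {
  out <- data.frame(language = rt$language, speaker = rt$speaker,
                    chip = rt$chip_id, term = rt$term)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Chart sets: response distributions over the chip grid
#'
#' A `chart_set` bundles an `n x N` matrix of chart values (rows = charts,
#' columns = chips in grid order) with per-chart metadata.  Speaker-level
#' charts are 0/1 indicator vectors ("the term is represented by a
#' 330-dimensional vector with 0 when T was not used and 1 when T was
#' used"); language-level charts are the entrywise sums of the speaker
#' charts for a (language, term) pair.
#'
#' @param values Numeric matrix, one row per chart.
#' @param info Data frame with columns `language`, `term` and (for
#'   speaker-level sets) `speaker`.
#' @param chip_id Integer vector of chip ids labelling the columns.
#' @param level `"speaker"`, `"language"` or `"cluster"`.
#' @return A `chart_set` object.
#' @export
chart_set <- function(values, info, chip_id, level) {
  values <- as.matrix(values)
  if (nrow(values) != nrow(info)) stop("values / info row mismatch")
  if (ncol(values) != length(chip_id)) stop("values / chip_id length mismatch")
  if (any(values < 0)) stop("chart values must be nonnegative")
  if (any(rowSums(values) == 0)) stop("charts must have at least one nonzero entry")
  rownames(values) <- chart_labels(info)
  colnames(values) <- chip_id
  structure(list(values = values, info = info, chip_id = as.integer(chip_id),
                 level = level),
            class = "chart_set")
}

chart_labels <- function(info) {
  if (!is.null(info$speaker))
    paste(info$language, info$speaker, info$term, sep = ":")
  else paste(info$language, info$term, sep = ":")
}

#' @export
print.chart_set <- function(x, ...) {
  cat(sprintf("chart_set: %d %s-level charts over %d chips\n",
              nrow(x$values), x$level, ncol(x$values)))
  invisible(x)
}

#' Speaker response vectors from a response table
#'
#' Builds one 0/1 chart per (language, speaker, term) triple observed in the
#' data: entry c is 1 exactly when that speaker used that term for chip c.
#' Terms a speaker never used produce no chart.
#'
#' @param rt A `response_table`.
#' @param grid The `chip_grid` the responses refer to.
#' @return A speaker-level `chart_set`.
#' @export
speaker_response_vectors <- function(rt, grid) {
  assert_chip_grid(grid)
  key <- paste(rt$language, rt$speaker, rt$term, sep = "\r")
  groups <- split(match(rt$chip_id, grid$chip_id), key)
  ord <- order(names(groups))
  groups <- groups[ord]
  parts <- do.call(rbind, strsplit(names(groups), "\r", fixed = TRUE))
  values <- matrix(0, nrow = length(groups), ncol = nrow(grid))
  for (i in seq_along(groups)) values[i, groups[[i]]] <- 1
  info <- data.frame(language = parts[, 1], speaker = parts[, 2],
                     term = parts[, 3], stringsAsFactors = FALSE)
  chart_set(values, info, grid$chip_id, "speaker")
}

#' Language response vectors by summing speaker charts
#'
#' All the speaker response vectors for a particular word in a language are
#' summed entrywise into one language response vector per (language, term).
#'
#' @param charts A speaker-level `chart_set`.
#' @return A language-level `chart_set` of nonnegative integer counts.
#' @export
language_response_vectors <- function(charts) {
  if (!inherits(charts, "chart_set") || charts$level != "speaker")
    stop("language_response_vectors expects a speaker-level chart_set")
  key <- paste(charts$info$language, charts$info$term, sep = "\r")
  values <- rowsum(charts$values, group = key, reorder = TRUE)
  parts <- do.call(rbind, strsplit(rownames(values), "\r", fixed = TRUE))
  info <- data.frame(language = parts[, 1], term = parts[, 2],
                     stringsAsFactors = FALSE)
  chart_set(values, info, charts$chip_id, "language")
}

#' Exclude charts touching the achromatic chips
#'
#' Keeps exactly the charts whose support contains no achromatic chip — the
#' filter used to restrict an analysis to naming patterns wholly contained
#' within the 320 chromatic chips.  Idempotent.
#'
#' @param charts A `chart_set`.
#' @param grid The `chip_grid` defining which chips are achromatic.
#' @return The filtered `chart_set`; an error if no chart survives (an empty
#'   chart set is not representable).
#' @export
filter_achromatic <- function(charts, grid) {
  assert_chip_grid(grid)
  achro <- which(grid$is_achromatic)
  keep <- rowSums(charts$values[, achro, drop = FALSE] != 0) == 0
  subset_charts(charts, keep)
}

subset_charts <- function(charts, keep) {
  if (!any(keep)) stop("no charts left after subsetting")
  chart_set(charts$values[keep, , drop = FALSE],
            charts$info[keep, , drop = FALSE],
            charts$chip_id, charts$level)
}

#' Centroid chip of a term's usage
#'
#' The classical single-representative reduction: for each speaker the mean
#' CIELAB coordinate of the chips they named with the term, then the mean of
#' the speaker means for the language, projected out to the closest chip
#' (smallest Delta-E; ties broken by lowest chip_id).  Averaging
#' speaker-then-language (not pooling chips) means each speaker contributes
#' equally regardless of how many chips they named.
#'
#' @param charts Speaker-level `chart_set`, all rows for one
#'   (language, term).
#' @param lab A complete `lab_table` in grid order.
#' @return The `chip_id` of the nearest chip to the language-average color.
#' @export
centroid_representative <- function(charts, lab) {
  if (!inherits(charts, "chart_set") || charts$level != "speaker")
    stop("centroid_representative expects speaker-level charts")
  if (nrow(charts$values) == 0) stop("empty input")
  if (nrow(unique(charts$info[c("language", "term")])) != 1)
    stop("charts must all belong to one (language, term)")
  xyz <- as.matrix(lab[, c("L", "a", "b")])
  speaker_means <- t(apply(charts$values, 1, function(v) {
    idx <- which(v > 0)
    colMeans(xyz[idx, , drop = FALSE])
  }))
  center <- colMeans(speaker_means)
  d2 <- colSums((t(xyz) - center)^2)
  lab$chip_id[which.min(d2)]  # which.min takes the first (lowest chip_id) on ties
}

#' Read / write chart sets as TSV matrices
#'
#' The exchange format for charts: one row per chart; metadata columns
#' `language`, `term`, `speaker` (empty for language-level charts), `level`;
#' then one column per chip, headed by its chip_id.
#'
#' @param charts A `chart_set`.
#' @param path File path.
#' @export
write_charts <- function(charts, path, header_lines = character()) {
  info <- charts$info
  meta <- data.frame(language = info$language, term = info$term,
                     speaker = if (is.null(info$speaker)) "" else info$speaker,
                     level = charts$level, stringsAsFactors = FALSE)
  out <- cbind(meta, as.data.frame(charts$values, check.names = FALSE))
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header_lines) writeLines(paste0("# ", h), con)
  writeLines(paste(c(names(meta), charts$chip_id), collapse = "\t"), con)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_charts
#' @param header_lines Provenance comment lines (written prefixed with `#`).
#' @export
read_charts <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE)
  meta_cols <- c("language", "term", "speaker", "level")
  if (!all(meta_cols %in% names(tab)))
    stop("chart TSV must start with columns language, term, speaker, level")
  chip_cols <- setdiff(names(tab), meta_cols)
  values <- as.matrix(tab[chip_cols])
  level <- unique(tab$level)
  if (length(level) != 1) stop("mixed chart levels in one file")
  info <- data.frame(language = as.character(tab$language),
                     term = as.character(tab$term), stringsAsFactors = FALSE)
  spk <- as.character(tab$speaker)
  if (any(!is.na(spk) & spk != "")) info$speaker <- spk
  chart_set(values, info, as.integer(chip_cols), level)
}
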