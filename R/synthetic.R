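#' Configuration for the synthetic naming simulator
#'
#' The simulator emulates a WCS-style elicitation: every speaker names every
#' chip of the grid with exactly one term; terms form spatially coherent
#' regions around focal colors.  `temperature` (CIELAB units) is the
#' softness of the term boundaries: the probability of naming chip c with
#' the term of focal f is proportional to `exp(-DeltaE(c, f)^2 /
#' temperature^2)`, so temperature 0 is deterministic nearest-focal
#' (Voronoi) naming and larger temperatures blur the boundaries.  The
#' default temperature of 10 is moderate: boundary chips (a few Delta-E
#' from the dividing line) are genuinely ambiguous while region cores are
#' stable, which is the qualitative regime of real naming data.
#'
#' @param n_terms Number of color terms (>= 2).
#' @param n_speakers Number of simulated speakers.
#' @param temperature Boundary softness, CIELAB units (>= 0).
#' @param seed Integer seed for the simulation.
#' @param focal_mode `"ring"` places focals at equally spaced hue columns on
#'   a middle-lightness row, so hue-adjacent and antipodal term pairs exist
#'   by construction; `"random"` samples distinct chromatic chips.
#' @param language Language id written into the response table.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_terms = 8, n_speakers = 20, temperature = 10,
                              seed = 1, focal_mode = c("ring", "random"),
                              language = "synth") {
  focal_mode <- match.arg(focal_mode)
  if (n_terms < 2) stop("n_terms must be >= 2")
  if (temperature < 0) stop("temperature must be >= 0")
  if (n_speakers < 1) stop("n_speakers must be >= 1")
  structure(list(n_terms = as.integer(n_terms),
                 n_speakers = as.integer(n_speakers),
                 temperature = temperature, seed = as.integer(seed),
                 focal_mode = focal_mode, language = language),
            class = "simulation_config")
}

#' Place focal points for the synthetic terms
#'
#' Ring mode puts the focals at (approximately) equally spaced hue columns
#' of one middle-lightness chromatic row, so that for every term the
#' hue-adjacent and the antipodal terms are known by construction; with 8
#' terms on the 40-column grid the focals are exactly 5 columns apart.
#' Random mode samples distinct chromatic chips using the config seed.
#'
#' @param grid A `chip_grid`.
#' @param lab Matching `lab_table` (used only by random mode for
#'   validation of chromaticity).
#' @param cfg A [simulation_config()].
#' @return Integer vector of focal `chip_id`s, one per term.
#' @export
generate_focal_points <- function(grid, lab, cfg) {
  assert_chip_grid(grid)
  chromatic <- grid[!grid$is_achromatic, ]
  if (cfg$n_terms > nrow(chromatic)) stop("more terms than chromatic chips")
  if (cfg$focal_mode == "ring") {
    rows <- sort(unique(chromatic$row))
    midrow <- rows[ceiling(length(rows) / 2)]
    ncol_hue <- max(chromatic$col)
    cols <- 1 + round((seq_len(cfg$n_terms) - 1) * ncol_hue / cfg$n_terms)
    ids <- vapply(cols, function(cc)
      grid$chip_id[grid$row == midrow & grid$col == cc], integer(1))
  } else {
    set.seed(cfg$seed)
    ids <- sample(chromatic$chip_id, cfg$n_terms)
  }
  as.integer(ids)
}

#' Voronoi (nearest-focal) partition of the grid
#'
#' Ground-truth labels: each chip gets the index of its nearest focal by
#' Delta-E (ties broken by lowest focal index).  This is the temperature-0
#' limit of the simulator and the reference partition for recoverability
#' checks.
#'
#' @param lab A `lab_table` in grid order.
#' @param focals Focal `chip_id`s from [generate_focal_points()].
#' @return Integer vector, one term index (1..n_terms) per chip.
#' @export
voronoi_partition <- function(lab, focals) {
  xyz <- as.matrix(lab[, c("L", "a", "b")])
  fidx <- match(focals, lab$chip_id)
  if (anyNA(fidx)) stop("focal chip missing from lab table")
  d2 <- dist2_to_centers(xyz, xyz[fidx, , drop = FALSE])
  max.col(-d2, ties.method = "first")
}

#' Simulate a WCS-shaped response table
#'
#' Each of `cfg$n_speakers` speakers names each chip with exactly one term,
#' sampled with probability proportional to
#' `exp(-DeltaE(chip, focal)^2 / temperature^2)` over the terms'
#' focals; at temperature 0 every speaker reproduces the Voronoi partition
#' exactly.  Deterministic given `cfg$seed`.
#'
#' @param grid A `chip_grid`.
#' @param lab Matching `lab_table`.
#' @param focals Focal chip ids, one per term.
#' @param cfg A [simulation_config()].
#' @return A `response_table` with terms `t1`, `t2`, ... and speakers
#'   `s01`, `s02`, ...
#' @export
simulate_responses <- function(grid, lab, focals, cfg) {
  assert_chip_grid(grid)
  n_chip <- nrow(grid)
  n_terms <- length(focals)
  xyz <- as.matrix(lab[, c("L", "a", "b")])
  fidx <- match(focals, lab$chip_id)
  d2 <- dist2_to_centers(xyz, xyz[fidx, , drop = FALSE])   # n_chip x n_terms
  terms <- paste0("t", seq_len(n_terms))
  speakers <- sprintf("s%02d", seq_len(cfg$n_speakers))
  if (cfg$temperature == 0) {
    labels <- max.col(-d2, ties.method = "first")
    picks <- matrix(rep(labels, cfg$n_speakers), ncol = cfg$n_speakers)
  } else {
    set.seed(cfg$seed)
    logw <- -(d2 - apply(d2, 1, min)) / cfg$temperature^2   # stabilized
    w <- exp(logw)
    picks <- apply(w, 1, function(p)
      sample.int(n_terms, cfg$n_speakers, replace = TRUE, prob = p))
    picks <- t(picks)                                       # n_chip x n_speakers
  }
  rt <- data.frame(
    language = cfg$language,
    speaker = rep(speakers, each = n_chip),
    chip_id = rep(grid$chip_id, times = cfg$n_speakers),
    term = terms[as.vector(picks)],
    stringsAsFactors = FALSE)
  validate_responses(rt, grid)
}
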