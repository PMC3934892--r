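# Shared fixtures, built in code.  The full 330-chip space (grid, synthetic
# Lab table, Delta-E matrix, similarity kernel) is memoized because several
# files need it and the kernel eigencheck is the slow part.

.space_cache <- new.env(parent = emptyenv())

test_space <- function() {
  if (is.null(.space_cache$s)) {
    grid <- wcs_grid()
    lab <- synthetic_lab_coordinates(grid)
    D <- ground_distance_matrix(lab)
    K <- similarity_matrix(D)
    .space_cache$s <- list(grid = grid, lab = lab, D = D, K = K)
  }
  .space_cache$s
}

# sparse nonnegative chart over n chips with a small random support
random_sparse_chart <- function(n, support = 3:12) {
  v <- numeric(n)
  idx <- sample.int(n, sample(support, 1))
  v[idx] <- runif(length(idx), 0.1, 1)
  v
}

# small hand-rolled response table: one language, two speakers
toy_response_table <- function(grid) {
  rt <- data.frame(
    language = "L1",
    speaker = c("s1", "s1", "s1", "s2", "s2"),
    chip_id = c(2L, 7L, 12L, 2L, 3L),
    term = c("red", "red", "blue", "red", "red"),
    stringsAsFactors = FALSE)
  chartmetrics:::validate_responses(rt, grid)
}

# small ring simulation shared by metric / clustering tests
ring_simulation <- function(temperature, seed, n_terms = 8, n_speakers = 20) {
  s <- test_space()
  cfg <- simulation_config(n_terms = n_terms, n_speakers = n_speakers,
                           temperature = temperature, seed = seed)
  focals <- generate_focal_points(s$grid, s$lab, cfg)
  rt <- simulate_responses(s$grid, s$lab, focals, cfg)
  list(cfg = cfg, focals = focals, responses = rt, space = s)
}
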