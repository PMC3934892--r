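test_that("euclidean distance matches the elementwise formula", {
  p <- c(1, 0, 2); q <- c(0, 0, 2)
  expect_equal(euclidean_distance(p, p), 0)
  expect_equal(euclidean_distance(c(1, 0, 0), c(0, 1, 0)), sqrt(2))
  set.seed(1)
  a <- runif(50); b <- runif(50)
  expect_equal(euclidean_distance(a, b), sqrt(sum((a - b)^2)))
  expect_error(euclidean_distance(a, b[-1]), "lengths")
})

test_that("pearson similarity is the sample correlation of chart entries", {
  set.seed(2)
  p <- runif(40)
  expect_equal(pearson_similarity(p, p), 1)
  expect_equal(pearson_similarity(p, -p + 3), -1)
  q <- runif(40)
  brute <- sum((p - mean(p)) * (q - mean(q))) /
    ((length(p) - 1) * sd(p) * sd(q))
  expect_equal(pearson_similarity(p, q), brute, tolerance = 1e-12)
  expect_error(pearson_similarity(p, rep(2, 40)), "constant chart")
})

test_that("EMD solves the transportation problem exactly", {
  s <- test_space()
  p <- q <- numeric(330); p[50] <- 1; q[60] <- 2
  expect_equal(emd(p, p, s$D), 0)
  expect_equal(emd(p, q, s$D), s$D[50, 60])  # single forced flow

  # normalization makes totals irrelevant
  set.seed(3)
  a <- random_sparse_chart(330); b <- random_sparse_chart(330)
  expect_equal(emd(a, b, s$D), emd(3.7 * a, 0.2 * b, s$D), tolerance = 1e-9)

  # the optimal flow plan satisfies the marginal constraints
  sol <- emd(a, b, s$D, flow = TRUE)
  an <- a / sum(a); bn <- b / sum(b)
  rows <- tapply(sol$flow$flow, sol$flow$from, sum)
  cols <- tapply(sol$flow$flow, sol$flow$to, sum)
  expect_true(all(rows <= an[as.integer(names(rows))] + 1e-9))
  expect_true(all(cols <= bn[as.integer(names(cols))] + 1e-9))
  expect_equal(sum(sol$flow$flow), 1, tolerance = 1e-9)
  expect_equal(sum(sol$flow$flow *
                     s$D[cbind(sol$flow$from, sol$flow$to)]),
               sol$value, tolerance = 1e-9)
})

test_that("EMD on a line ground metric equals the CDF closed form", {
  Dline <- abs(outer(1:8, 1:8, "-"))
  set.seed(4)
  for (rep in 1:50) {
    p <- runif(8) * rbinom(8, 1, 0.7); if (sum(p) == 0) p[1] <- 1
    q <- runif(8) * rbinom(8, 1, 0.7); if (sum(q) == 0) q[3] <- 1
    oracle <- sum(abs(cumsum(p / sum(p) - q / sum(q))))
    expect_equal(emd(p, q, Dline), oracle, tolerance = 1e-7)
  }
})

test_that("EMD agrees with an independent generic LP formulation", {
  set.seed(5)
  for (rep in 1:25) {
    C <- matrix(runif(36, 0, 10), 6, 6)
    p <- runif(6); q <- runif(6); p <- p / sum(p); q <- q / sum(q)
    A3 <- matrix(0, 11, 36)                      # variables f_ij, row-major
    for (i in 1:6) A3[i, ((i - 1) * 6 + 1):(i * 6)] <- 1   # row sums = p
    for (j in 1:5) A3[6 + j, seq(j, 36, by = 6)] <- 1      # col sums = q
    lp <- boot::simplex(a = as.vector(t(C)), A3 = A3, b3 = c(p, q[1:5]),
                        maxi = FALSE)
    expect_equal(emd(p, q, C), unname(lp$value), tolerance = 1e-7)
  }
})

test_that("EMD is a metric on unit-mass charts over the chip geometry", {
  s <- test_space()
  set.seed(6)
  charts <- lapply(1:36, function(.) random_sparse_chart(330))
  for (rep in 1:60) {
    ijk <- sample.int(36, 3)
    d12 <- emd(charts[[ijk[1]]], charts[[ijk[2]]], s$D)
    d21 <- emd(charts[[ijk[2]]], charts[[ijk[1]]], s$D)
    d13 <- emd(charts[[ijk[1]]], charts[[ijk[3]]], s$D)
    d23 <- emd(charts[[ijk[2]]], charts[[ijk[3]]], s$D)
    expect_equal(d12, d21, tolerance = 1e-7)
    expect_lte(d13, d12 + d23 + 1e-6)
    expect_lte(d12, max(s$D))      # work bounded by the chart diameter
  }
  expect_equal(emd(charts[[1]], charts[[1]], s$D), 0, tolerance = 1e-12)
})

test_that("permutation invariance separates the metric families", {
  s <- test_space()
  set.seed(8)
  p <- random_sparse_chart(330, support = 8:15)
  q <- random_sparse_chart(330, support = 8:15)
  perm <- sample.int(330)
  expect_equal(euclidean_distance(p[perm], q[perm]),
               euclidean_distance(p, q), tolerance = 1e-12)
  expect_equal(pearson_similarity(p[perm], q[perm]),
               pearson_similarity(p, q), tolerance = 1e-12)
  # a generic permutation is not a Delta-E isometry: EMD must change
  expect_gt(abs(emd(p[perm], q[perm], s$D) - emd(p, q, s$D)), 1e-3)
  # rotating hue columns within each row IS an isometry of the synthetic
  # Lab table: EMD is unchanged
  g <- s$grid
  rot <- ifelse(g$col == 0, g$col, (g$col %% 40) + 1)
  iso <- integer(330)
  for (i in seq_len(330))
    iso[i] <- which(g$row == g$row[i] & g$col == rot[i])
  pi_inv <- order(iso)
  expect_equal(emd(p[pi_inv], q[pi_inv], s$D), emd(p, q, s$D),
               tolerance = 1e-6)
})

test_that("quadratic chi reduces, symmetrizes and respects similarity", {
  s <- test_space()
  set.seed(9)
  p <- random_sparse_chart(330); q <- random_sparse_chart(330)
  expect_equal(quadratic_chi(p, p, s$K), 0, tolerance = 1e-10)
  expect_equal(quadratic_chi(p, q, s$K), quadratic_chi(q, p, s$K),
               tolerance = 1e-10)
  # A = identity, m = 0 reduces to plain Euclidean distance
  I <- diag(330)
  for (rep in 1:10) {
    a <- runif(330); b <- runif(330)
    expect_equal(quadratic_chi(a, b, I, m = 0, normalize = FALSE),
                 euclidean_distance(a, b), tolerance = 1e-9)
  }
  # increasing similarity toward all-ones drives equal-mass distances to 0
  pn <- p / sum(p); qn <- q / sum(q)
  ones <- matrix(1, 330, 330)
  near1 <- 0.999 * ones + 0.001 * diag(330)
  expect_lt(quadratic_chi(pn, qn, near1, normalize = FALSE),
            quadratic_chi(pn, qn, s$K, normalize = FALSE))
  expect_lt(quadratic_chi(pn, qn, near1, normalize = FALSE), 0.05)
  expect_error(quadratic_chi(p, q, s$K, m = 1), "m must")
})

test_that("pairwise matrices mirror the single-pair calls", {
  s <- test_space()
  set.seed(10)
  X <- rbind(random_sparse_chart(330), random_sparse_chart(330),
             random_sparse_chart(330))
  rownames(X) <- c("a", "b", "c")
  M <- pairwise_distance_matrix(X, "emd", D = s$D)
  expect_equal(M, t(M), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(diag(M), c(a = 0, b = 0, c = 0))
  expect_equal(M["a", "b"], emd(X[1, ], X[2, ], s$D), tolerance = 1e-10)
  same <- rbind(X[1, ], X[1, ], X[1, ])
  expect_true(all(pairwise_distance_matrix(same, "euclidean") == 0))
})

test_that("ranking orders charts by dissimilarity with the reference first", {
  s <- test_space()
  set.seed(11)
  X <- do.call(rbind, lapply(1:5, function(.) random_sparse_chart(330)))
  rownames(X) <- paste0("w", 1:5)
  rk <- rank_by_distance(X["w3", ], X, "emd", D = s$D)
  expect_equal(rk$label[1], "w3")
  expect_equal(rk$value[1], 0, tolerance = 1e-10)
  expect_true(!is.unsorted(rk$value))
  rkp <- rank_by_distance("w3", X, "pearson")   # similarity converted to 1 - r
  expect_equal(rkp$value[1], 0, tolerance = 1e-10)
  expect_true(!is.unsorted(rkp$value))
  expect_error(rank_by_distance("nope", X, "euclidean"), "not found")
})

test_that("cross-support EMD handles rectangular ground matrices", {
  s <- test_space()
  set.seed(12)
  p <- random_sparse_chart(330); q <- random_sparse_chart(330)
  expect_equal(cross_support_emd(p, q, s$D), emd(p, q, s$D), tolerance = 1e-9)

  D12 <- matrix(17.2, 1, 1)
  expect_equal(cross_support_emd(1, 5, D12), 17.2)

  # refinement invariance: splitting one chip into two co-located chips
  # (duplicated Lab row, mass halved) leaves the value unchanged
  i <- which(p > 0)[1]
  p2 <- c(p, p[i] / 2); p2[i] <- p[i] / 2
  D12 <- rbind(s$D, s$D[i, ])
  expect_equal(cross_support_emd(p2, q, D12), cross_support_emd(p, q, s$D),
               tolerance = 1e-7)
  expect_error(cross_support_emd(p, q, s$D[1:10, ]), "must be")
})

test_that("on the 8-term ring EMD ranks hue neighbors above the antipode", {
  sim <- ring_simulation(temperature = 5, seed = 1)
  lv <- language_response_vectors(
    speaker_response_vectors(sim$responses, sim$space$grid))
  rk <- rank_by_distance("synth:t1", lv, "emd", D = sim$space$D)
  pos <- match(c("synth:t2", "synth:t8", "synth:t5"), rk$label)
  expect_true(all(pos[1:2] < pos[3]))
})
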