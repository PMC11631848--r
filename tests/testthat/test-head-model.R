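test_that("head construction honours its contract and is deterministic", {
  head <- study_head()
  expect_identical(sort(unique(head$parcellation)), 1:50)
  expect_equal(dim(head$leadfield_regional), c(32, 50))
  expect_equal(dim(head$leadfield_full), c(32, 400))
  # average reference: every column sums to zero
  expect_lt(max(abs(colSums(head$leadfield_full))), 1e-10)
  expect_lt(max(abs(colSums(head$leadfield_regional))), 1e-10)
  # adjacency is a simple symmetric connected graph
  expect_true(all(head$region_adjacency == t(head$region_adjacency)))
  expect_false(any(diag(head$region_adjacency)))
  reach <- 1
  repeat {
    nb <- unique(c(reach,
                   which(apply(head$region_adjacency[reach, , drop = FALSE],
                               2, any))))
    if (length(nb) == length(reach)) break
    reach <- nb
  }
  expect_length(reach, 50)
  # determinism
  head2 <- build_spherical_head(32, 400, 50, rng_seed = 7)
  expect_identical(head2$leadfield_full, head$leadfield_full)
  expect_identical(head2$parcellation, head$parcellation)
})

test_that("every region is non-empty and connected in the source graph", {
  head <- study_head()
  edges <- esibench:::knn_edges(head$source_positions, k = 7)
  adj <- vector("list", nrow(head$source_positions))
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  for (r in 1:50) {
    members <- which(head$parcellation == r)
    expect_gt(length(members), 0)
    seen <- members[1]
    repeat {
      nb <- unique(c(seen, intersect(unlist(adj[seen]), members)))
      if (length(nb) == length(seen)) break
      seen <- nb
    }
    expect_length(seen, length(members))
  }
})

test_that("invalid head geometries are rejected", {
  expect_error(build_spherical_head(shell_radii = c(87, 82, 79)),
               "increasing")
  expect_error(build_spherical_head(conductivities = c(0.3, -1, 0.3)),
               "positive")
  expect_error(build_spherical_head(16, 40, 60), "exceeds")
})

test_that("singleton regions reproduce the full leadfield up to permutation", {
  head <- build_spherical_head(16, 60, 60, rng_seed = 2)
  expect_identical(sort(unique(head$parcellation)), 1:60)
  expect_equal(head$leadfield_regional[, head$parcellation],
               head$leadfield_full)
})

test_that("dipole potentials are linear and vanish for a zero moment", {
  head <- study_head()
  expect_equal(leadfield_dipole(head, c(10, 20, 30), c(0, 0, 0)),
               rep(0, 32))
  set.seed(42)
  for (i in 1:5) {
    p <- runif(3, -30, 30)
    q1 <- rnorm(3) * 1e-9
    q2 <- rnorm(3) * 1e-9
    v12 <- leadfield_dipole(head, p, q1 + q2)
    v1 <- leadfield_dipole(head, p, q1)
    v2 <- leadfield_dipole(head, p, q2)
    expect_lt(max(abs(v12 - v1 - v2)) / max(abs(v12)), 1e-12)
  }
  expect_error(leadfield_dipole(head, c(0, 0, 85), c(1e-9, 0, 0)),
               "outside")
})

test_that("equal-conductivity shells match the homogeneous closed form", {
  head <- build_spherical_head(32, 16, 8, conductivities = c(0.3, 0.3, 0.3),
                               rng_seed = 1)
  set.seed(7)
  for (i in 1:20) {
    pos <- rnorm(3)
    pos <- pos / sqrt(sum(pos^2)) * runif(1, 5, 75)
    m <- rnorm(3) * 1e-9
    v_series <- leadfield_dipole(head, pos, m)
    v_closed <- homogeneous_sphere_dipole(head$electrode_positions, pos, m,
                                          87, 0.3)
    expect_lt(max(abs(v_series - v_closed)) / max(abs(v_closed)), 1e-6)
  }
})

test_that("regional aggregation equals brute-force summation and is linear", {
  set.seed(5)
  L <- matrix(rnorm(8 * 20), 8, 20)
  labels <- sample(1:5, 20, replace = TRUE)
  labels[1:5] <- 1:5  # every region non-empty
  agg <- aggregate_regional_leadfield(L, labels)
  oracle <- matrix(0, 8, 5)
  for (i in 1:8) for (j in 1:20) {
    oracle[i, labels[j]] <- oracle[i, labels[j]] + L[i, j]
  }
  expect_equal(agg, oracle)
  # singleton identity, duplicated-column doubling
  expect_equal(aggregate_regional_leadfield(L, 1:20), L)
  L2 <- cbind(L[, 1], L[, 1])
  expect_equal(aggregate_regional_leadfield(L2, c(1, 1)),
               matrix(2 * L[, 1]))
  # exact linearity: aggregate(L) x == L expand(x)
  x_reg <- rnorm(5)
  expect_equal(as.vector(agg %*% x_reg), as.vector(L %*% x_reg[labels]))
  expect_error(aggregate_regional_leadfield(L, labels[1:3]), "label")
})

test_that("forward projection equals the triple-loop product", {
  set.seed(6)
  L <- matrix(rnorm(4 * 6), 4, 6)
  X <- matrix(rnorm(6 * 5), 6, 5)
  Y <- project_forward(L, X)
  oracle <- matrix(0, 4, 5)
  for (i in 1:4) for (t in 1:5) for (j in 1:6) {
    oracle[i, t] <- oracle[i, t] + L[i, j] * X[j, t]
  }
  expect_equal(Y, oracle)
  expect_equal(project_forward(L, matrix(0, 6, 5)), matrix(0, 4, 5))
  X1 <- matrix(0, 6, 5); X1[3, 2] <- 1
  expect_equal(project_forward(L, X1)[, 2], L[, 3])
  expect_error(project_forward(L, matrix(0, 5, 5)), "sources")
})

test_that("swapping electrodes permutes leadfield rows; potentials decay with depth", {
  head <- study_head()
  swapped <- head
  swapped$electrode_positions <- head$electrode_positions[c(2, 1, 3:32), ]
  v <- leadfield_dipole(head, c(5, -10, 40), c(0, 1e-9, 0))
  v_sw <- leadfield_dipole(swapped, c(5, -10, 40), c(0, 1e-9, 0))
  expect_equal(v_sw, v[c(2, 1, 3:32)])
  m <- c(1e-9, 0, 0)
  shallow <- max(abs(leadfield_dipole(head, c(0, 0, 0.8 * 79), m)))
  deep <- max(abs(leadfield_dipole(head, c(0, 0, 0.3 * 79), m)))
  expect_gt(shallow, deep)
})

test_that("head containers round-trip through disk", {
  head <- tiny_head()
  path <- withr::local_tempfile()
  write_head(head, path)
  back <- read_head(path)
  expect_equal(back$leadfield_regional, head$leadfield_regional)
  expect_true(file.exists(paste0(path, ".json")))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$n_regions, 24)
  # imported-leadfield path provides the same interface
  imported <- head_from_arrays(head$leadfield_full,
                               head$electrode_positions,
                               head$source_positions, head$parcellation)
  expect_equal(imported$leadfield_regional, head$leadfield_regional)
})
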