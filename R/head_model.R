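## Synthetic spherical head model: source space, electrode montage, leadfield,
## parcellation into regions and the regional (summed-column) leadfield.

# Quasi-uniform points on the unit sphere (Fibonacci lattice).
fibonacci_sphere <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  rho <- sqrt(pmax(0, 1 - z^2))
  cbind(x = rho * cos(phi), y = rho * sin(phi), z = z)
}

# Farthest-point seeding over Euclidean distances; returns indices of k seeds.
farthest_point_seeds <- function(pts, k, first) {
  n <- nrow(pts)
  seeds <- integer(k)
  seeds[1] <- first
  d2 <- rowSums((pts - matrix(pts[first, ], n, 3, byrow = TRUE))^2)
  if (k > 1) for (j in 2:k) {
    seeds[j] <- which.max(d2)
    d2 <- pmin(d2, rowSums((pts - matrix(pts[seeds[j], ], n, 3,
                                         byrow = TRUE))^2))
  }
  seeds
}

# Symmetric k-nearest-neighbour graph over source positions, as an edge list.
knn_edges <- function(pts, k = 7) {
  n <- nrow(pts)
  d <- as.matrix(dist(pts))
  diag(d) <- Inf
  from <- rep(seq_len(n), each = k)
  to <- as.vector(apply(d, 1, function(row) order(row)[seq_len(k)]))
  e <- cbind(pmin(from, to), pmax(from, to))
  unique(e)
}

# Ensure each region's members form a connected subgraph of the source graph:
# stray components (not containing the region seed source) are reassigned to
# the neighbouring region with most boundary edges.
repair_parcellation <- function(labels, edges, seed_sources) {
  n <- length(labels)
  adj <- vector("list", n)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  for (pass in 1:20) {
    moved <- FALSE
    for (r in seq_along(seed_sources)) {
      members <- which(labels == r)
      if (length(members) == 0) next
      # BFS from the seed source within the region
      seen <- rep(FALSE, n)
      queue <- seed_sources[r]; seen[queue] <- TRUE
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        for (w in adj[[v]]) if (!seen[w] && labels[w] == r) {
          seen[w] <- TRUE; queue <- c(queue, w)
        }
      }
      stray <- members[!seen[members]]
      for (v in stray) {
        nb <- labels[adj[[v]]]
        nb <- nb[nb != r]
        if (length(nb)) {
          labels[v] <- as.integer(names(sort(table(nb), decreasing = TRUE))[1])
          moved <- TRUE
        }
      }
    }
    if (!moved) break
  }
  labels
}

#' Build a synthetic three-shell spherical head model
#'
#' Constructs the whole forward-model apparatus from scratch: quasi-uniform
#' radially-oriented sources on a sphere at 0.85 x the brain-shell radius,
#' quasi-uniform electrodes on the scalp shell, the analytic multilayer
#' leadfield, a farthest-point/nearest-centroid parcellation into `n_regions`
#' regions, the region adjacency graph and the regional leadfield obtained by
#' summing member-source columns. All leadfields are average-referenced.
#'
#' @param n_electrodes,n_sources_full,n_regions counts (all >= 4,
#'   `n_regions <= n_sources_full`).
#' @param shell_radii strictly increasing mm triple (brain, skull, scalp).
#' @param conductivities positive S/m triple.
#' @param rng_seed integer; parcellation seeding is the only stochastic step.
#' @return an object of class `esi_head`.
#' @export
build_spherical_head <- function(n_electrodes = 32, n_sources_full = 400,
                                 n_regions = 50,
                                 shell_radii = c(79, 82, 87),
                                 conductivities = c(0.3, 0.006, 0.3),
                                 rng_seed = 1) {
  if (n_electrodes < 4 || n_sources_full < 4 || n_regions < 4)
    stopf("all counts must be >= 4")
  if (n_regions > n_sources_full)
    stopf("n_regions (%d) exceeds n_sources_full (%d)",
          n_regions, n_sources_full)
  if (length(shell_radii) != 3 || any(diff(shell_radii) <= 0))
    stopf("shell_radii must be three strictly increasing values")
  if (length(conductivities) != 3 || any(conductivities <= 0))
    stopf("conductivities must be three positive values")

  electrode_positions <- fibonacci_sphere(n_electrodes) * shell_radii[3]
  src_radius <- 0.85 * shell_radii[1]
  source_positions <- fibonacci_sphere(n_sources_full) * src_radius
  source_orientations <- source_positions / src_radius  # radial unit vectors

  head <- structure(list(
    electrode_positions = electrode_positions,
    source_positions = source_positions,
    source_orientations = source_orientations,
    shell_radii = shell_radii,
    conductivities = conductivities,
    rng_seed = as.integer(rng_seed)
  ), class = "esi_head")
  head$.transfer <- sphere_transfer_factors(shell_radii, conductivities)

  L <- matrix(0, n_electrodes, n_sources_full)
  for (j in seq_len(n_sources_full)) {
    L[, j] <- leadfield_dipole(head, source_positions[j, ],
                               source_orientations[j, ])
  }

  first <- with_seed(derive_seed(rng_seed, "parcellation"),
                     sample.int(n_sources_full, 1))
  seed_src <- farthest_point_seeds(source_positions, n_regions, first)
  d2seed <- vapply(seq_len(n_regions), function(r) {
    rowSums((source_positions -
               matrix(source_positions[seed_src[r], ], n_sources_full, 3,
                      byrow = TRUE))^2)
  }, numeric(n_sources_full))
  labels <- max.col(-d2seed, ties.method = "first")
  edges <- knn_edges(source_positions, k = 7)
  labels <- repair_parcellation(labels, edges, seed_src)

  adjacency <- matrix(FALSE, n_regions, n_regions)
  el <- cbind(labels[edges[, 1]], labels[edges[, 2]])
  el <- el[el[, 1] != el[, 2], , drop = FALSE]
  adjacency[el] <- TRUE
  adjacency <- adjacency | t(adjacency)

  centroids <- t(vapply(seq_len(n_regions), function(r) {
    colMeans(source_positions[labels == r, , drop = FALSE])
  }, numeric(3)))

  head$leadfield_full <- L
  head$parcellation <- labels
  head$leadfield_regional <- aggregate_regional_leadfield(L, labels)
  head$region_adjacency <- adjacency
  head$region_centroids <- centroids
  head$region_seed_sources <- seed_src
  head
}

#' Sum full-leadfield columns over a parcellation
#'
#' Column j of the result is the sum of the full-leadfield columns of all
#' sources labelled j (no normalization by region size): all member sources
#' are assumed equally active.
#'
#' @param leadfield_full Ne x Ns matrix.
#' @param parcellation integer region label per source (1..Nr, all present).
#' @return Ne x Nr matrix.
#' @export
aggregate_regional_leadfield <- function(leadfield_full, parcellation) {
  if (length(parcellation) != ncol(leadfield_full))
    stopf("one label per leadfield column required")
  labels <- sort(unique(parcellation))
  if (length(labels) == 0) stopf("empty region label set")
  if (!identical(as.integer(labels), seq_along(labels)))
    stopf("region labels must cover 1..Nr")
  ind <- matrix(0, ncol(leadfield_full), length(labels))
  ind[cbind(seq_along(parcellation), parcellation)] <- 1
  leadfield_full %*% ind
}

#' Project source activity to the electrodes
#'
#' The noiseless forward map: `Y = L X`.
#'
#' @param L Ne x Ns leadfield (V per A.m).
#' @param X Ns x T source matrix (A.m).
#' @return Ne x T matrix of potentials (V).
#' @export
project_forward <- function(L, X) {
  X <- as.matrix(X)
  if (ncol(L) != nrow(X))
    stopf("leadfield has %d sources but X has %d rows", ncol(L), nrow(X))
  L %*% X
}

#' Assemble a head model from externally supplied arrays
#'
#' Compatibility path for precomputed leadfields (e.g. from a realistic BEM
#' head model): supplies the same `esi_head` interface from a full leadfield,
#' source/electrode coordinates and a parcellation.
#'
#' @param leadfield_full Ne x Ns matrix (V per A.m); average-referenced here.
#' @param electrode_positions,source_positions coordinate matrices (mm).
#' @param parcellation integer labels 1..Nr covering all sources.
#' @param region_adjacency optional Nr x Nr logical matrix; defaults to a
#'   nearest-centroid proxy built from a source k-nearest-neighbour graph.
#' @return an `esi_head`.
#' @export
head_from_arrays <- function(leadfield_full, electrode_positions,
                             source_positions, parcellation,
                             region_adjacency = NULL) {
  leadfield_full <- sweep(leadfield_full, 2, colMeans(leadfield_full))
  nr <- length(unique(parcellation))
  centroids <- t(vapply(seq_len(nr), function(r) {
    colMeans(source_positions[parcellation == r, , drop = FALSE])
  }, numeric(3)))
  if (is.null(region_adjacency)) {
    edges <- knn_edges(source_positions, k = 7)
    region_adjacency <- matrix(FALSE, nr, nr)
    el <- cbind(parcellation[edges[, 1]], parcellation[edges[, 2]])
    el <- el[el[, 1] != el[, 2], , drop = FALSE]
    region_adjacency[el] <- TRUE
    region_adjacency <- region_adjacency | t(region_adjacency)
  }
  structure(list(
    electrode_positions = electrode_positions,
    source_positions = source_positions,
    source_orientations = NULL,
    shell_radii = NULL, conductivities = NULL,
    leadfield_full = leadfield_full,
    parcellation = as.integer(parcellation),
    leadfield_regional = aggregate_regional_leadfield(leadfield_full,
                                                      parcellation),
    region_adjacency = region_adjacency,
    region_centroids = centroids,
    rng_seed = NA_integer_
  ), class = "esi_head")
}

#' @export
print.esi_head <- function(x, ...) {
  cat("Spherical head model (esi_head)\n")
  cat(sprintf("  electrodes: %d   sources: %d   regions: %d\n",
              nrow(x$electrode_positions), nrow(x$source_positions),
              ncol(x$leadfield_regional)))
  if (!is.null(x$shell_radii))
    cat(sprintf("  shells (mm): %s   conductivities (S/m): %s\n",
                paste(x$shell_radii, collapse = "/"),
                paste(x$conductivities, collapse = "/")))
  cat(sprintf("  region sizes: %s\n",
              paste(range(tabulate(x$parcellation)), collapse = "-")))
  invisible(x)
}

#' Write / read a head model container
#'
#' Array container (RDS) with a JSON sidecar holding provenance metadata
#' (seed, radii, conductivities, counts).
#'
#' @param head an `esi_head`.
#' @param path file path (sidecar written to `<path>.json`).
#' @rdname head_io
#' @export
write_head <- function(head, path) {
  saveRDS(head[setdiff(names(head), ".transfer")], path)
  meta <- list(seed = head$rng_seed, shell_radii = head$shell_radii,
               conductivities = head$conductivities,
               n_electrodes = nrow(head$electrode_positions),
               n_sources_full = nrow(head$source_positions),
               n_regions = ncol(head$leadfield_regional))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname head_io
#' @export
read_head <- function(path) {
  head <- readRDS(path)
  class(head) <- "esi_head"
  if (!is.null(head$shell_radii))
    head$.transfer <- sphere_transfer_factors(head$shell_radii,
                                              head$conductivities)
  head
}
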