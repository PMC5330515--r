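# Synthetic idealized left-atrial geometry and the octopus model of
# ganglionated plexi (GP), nerves and the acetylcholine field. A parametric
# ellipsoidal shell with four pulmonary-vein (PV) ostia and a mitral opening
# stands in for patient-derived meshes.

# subdivided icosahedron on the unit sphere
icosphere <- function(subdiv = 4) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    nv <- nrow(v)
    edge_key <- function(a, b) ifelse(a < b, a * (nv + 1) + b, b * (nv + 1) + a)
    mids <- new.env()
    newv <- list()
    midpoint <- function(a, b) {
      k <- as.character(edge_key(a, b))
      if (!is.null(mids[[k]])) return(mids[[k]])
      m <- v[a, ] + v[b, ]
      m <- m / sqrt(sum(m^2))
      newv[[length(newv) + 1]] <<- m
      id <- nv + length(newv)
      mids[[k]] <- id
      id
    }
    nf <- matrix(0L, nrow(f) * 4, 3)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; c <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      nf[(t - 1) * 4 + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                       c(c, ca, bc), c(ab, bc, ca))
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- nf
  }
  list(vertices = v, triangles = f)
}

# boundary edges (edges with a single incident triangle), grouped into loops
mesh_boundary_loops <- function(triangles) {
  e <- rbind(triangles[, 1:2], triangles[, 2:3], triangles[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  single <- names(which(table(key) == 1))
  be <- e[key %in% single, , drop = FALSE]
  if (!nrow(be)) return(list())
  loops <- list()
  nxt <- split(seq_len(nrow(be)), be[, 1])
  used <- rep(FALSE, nrow(be))
  for (start in seq_len(nrow(be))) {
    if (used[start]) next
    loop <- be[start, 1]
    cur <- start
    repeat {
      used[cur] <- TRUE
      vtx <- be[cur, 2]
      loop <- c(loop, vtx)
      cand <- nxt[[as.character(vtx)]]
      cand <- cand[!used[cand]]
      if (!length(cand)) break
      cur <- cand[1]
    }
    loops[[length(loops) + 1]] <- loop[-length(loop)]
  }
  loops
}

# igraph over mesh edges weighted by Euclidean length
mesh_graph <- function(vertices, triangles) {
  e <- rbind(triangles[, 1:2], triangles[, 2:3], triangles[, c(3, 1)])
  e <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  w <- sqrt(rowSums((vertices[e[, 1], ] - vertices[e[, 2], ])^2))
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  igraph::E(g)$weight <- w
  g
}

#' Geodesic (graph) distances from a vertex set
#'
#' Shortest-path distances along mesh edges, a standard approximation of
#' geodesic distance on fine meshes.
#'
#' @param geom an `la_geometry` or a list with `vertices`/`triangles`.
#' @param from integer vertex indices.
#' @return Numeric vector: distance (mm) of every vertex to the nearest
#'   vertex in `from`.
#' @export
geodesic_distance <- function(geom, from) {
  g <- if (!is.null(geom$graph)) geom$graph else
    mesh_graph(geom$vertices, geom$triangles)
  d <- igraph::distances(g, v = from)
  apply(d, 2, min)
}

#' Generate an idealized left-atrium surface
#'
#' Closed ellipsoidal shell with four PV ostium openings and a mitral
#' opening, per-vertex region labels (`LA`, `PV1`..`PV4`, `BachmannSite`)
#' and the five boundary loops. PV regions are antral sleeves extending a
#' configurable geodesic distance from each ostium.
#'
#' @param radii ellipsoid semi-axes (mm); the default approximates a 45-mm
#'   LA diameter.
#' @param subdiv icosphere subdivision level (4 gives ~5000 triangles).
#' @param pv_theta,mitral_theta angular radii (degrees) of the PV and mitral
#'   openings on the unit sphere.
#' @param pv_sleeve geodesic extent (mm) of the PV-labeled sleeve beyond the
#'   ostium rim.
#' @param pv_dirs optional 4 x 3 matrix of PV opening directions
#'   (rows: PV1 = left superior, PV2 = left inferior, PV3 = right superior,
#'   PV4 = right inferior).
#' @param seed integer; the construction is deterministic, the seed is
#'   recorded for provenance and used by downstream stochastic layers.
#' @return An `la_geometry`: vertices (mm), triangles, `region` factor,
#'   boundary `loops` (named), mesh `graph`, and the generation parameters.
#' @export
generate_idealized_la <- function(radii = c(25, 20, 18), subdiv = 4,
                                  pv_theta = 12, mitral_theta = 38,
                                  pv_sleeve = 7, pv_dirs = NULL, seed = 1) {
  ico <- icosphere(subdiv)
  u <- ico$vertices
  if (is.null(pv_dirs)) {
    pv_dirs <- rbind(
      PV1 = c(-0.55, 0.60, 0.58),   # left superior
      PV2 = c(-0.70, 0.58, -0.42),  # left inferior
      PV3 = c(0.55, 0.60, 0.58),    # right superior
      PV4 = c(0.70, 0.58, -0.42))   # right inferior
  }
  pv_dirs <- pv_dirs / sqrt(rowSums(pv_dirs^2))
  mitral_dir <- c(0, -1, 0)
  holes <- rbind(pv_dirs, mitral = mitral_dir)
  thetas <- c(rep(pv_theta, 4), mitral_theta) * pi / 180

  # pairwise feasibility: openings must not share vertices
  for (i in 1:4) for (j in (i + 1):5) {
    sep <- acos(pmin(1, sum(holes[i, ] * holes[j, ])))
    if (sep < thetas[i] + thetas[j] + 4 * pi / 180)
      stop("infeasible ostium placement: openings ", i, " and ", j,
           " overlap")
  }

  ang <- function(dir) acos(pmax(-1, pmin(1, u %*% dir)))
  inside_any <- rep(FALSE, nrow(ico$triangles))
  vertex_hole <- matrix(FALSE, nrow(u), 5)
  for (h in 1:5) vertex_hole[, h] <- ang(holes[h, ]) < thetas[h]
  # drop triangles whose centroid direction lies inside a cap
  cent <- (u[ico$triangles[, 1], ] + u[ico$triangles[, 2], ] +
             u[ico$triangles[, 3], ]) / 3
  cent <- cent / sqrt(rowSums(cent^2))
  for (h in 1:5) {
    a <- acos(pmax(-1, pmin(1, cent %*% holes[h, ])))
    inside_any <- inside_any | (a < thetas[h])
  }
  tri <- ico$triangles[!inside_any, , drop = FALSE]
  keep <- sort(unique(as.vector(tri)))
  remap <- integer(nrow(u)); remap[keep] <- seq_along(keep)
  tri <- matrix(remap[tri], ncol = 3)
  u <- u[keep, , drop = FALSE]

  vtx <- sweep(u, 2, radii, `*`)
  loops <- mesh_boundary_loops(tri)
  if (length(loops) != 5)
    stop("expected 5 boundary loops, got ", length(loops),
         "; adjust opening sizes/resolution")
  # name loops by nearest hole direction
  loop_dir <- t(vapply(loops, function(l) {
    m <- colMeans(u[l, , drop = FALSE]); m / sqrt(sum(m^2))
  }, numeric(3)))
  assign_hole <- apply(loop_dir %*% t(holes), 1, which.max)
  if (length(unique(assign_hole)) != 5) stop("ambiguous boundary loop naming")
  names(loops) <- c("PV1", "PV2", "PV3", "PV4", "mitral")[assign_hole]
  loops <- loops[c("PV1", "PV2", "PV3", "PV4", "mitral")]

  geom <- list(vertices = vtx, triangles = tri, loops = loops,
               params = list(radii = radii, subdiv = subdiv,
                             pv_theta = pv_theta,
                             mitral_theta = mitral_theta,
                             pv_sleeve = pv_sleeve, seed = seed),
               pv_dirs = pv_dirs)
  geom$graph <- mesh_graph(vtx, tri)

  region <- rep("LA", nrow(vtx))
  for (k in 1:4) {
    d <- geodesic_distance(geom, loops[[k]])
    # sleeve on the PV side of the rim: vertices near the ostium direction
    near_dir <- as.vector(u %*% pv_dirs[k, ]) > cos((pv_theta + 14) * pi / 180)
    region[d <= pv_sleeve & near_dir] <- paste0("PV", k)
  }
  bb_dir <- c(0.4, -0.25, 0.88); bb_dir <- bb_dir / sqrt(sum(bb_dir^2))
  bb_center <- which.max(u %*% bb_dir)
  d_bb <- geodesic_distance(geom, bb_center)
  region[d_bb <= 3 & region == "LA"] <- "BachmannSite"
  geom$region <- factor(region,
                        levels = c("LA", "PV1", "PV2", "PV3", "PV4",
                                   "BachmannSite"))
  class(geom) <- "la_geometry"
  geom
}

#' @export
print.la_geometry <- function(x, ...) {
  cat("<la_geometry> ", nrow(x$vertices), " vertices, ", nrow(x$triangles),
      " triangles, ", length(x$loops), " boundary loops\n", sep = "")
  print(table(x$region))
  invisible(x)
}

#' Euler characteristic of a triangulated surface
#' @param geom an `la_geometry` or list with `vertices`/`triangles`.
#' @return Integer V - E + F.
#' @export
euler_characteristic <- function(geom) {
  tri <- geom$triangles
  e <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
  ne <- nrow(unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))))
  nrow(geom$vertices) - ne + nrow(tri)
}

#' Generate the octopus GP/nerve layout and ACh field
#'
#' Places one ganglionated-plexus patch at the antrum of each PV ostium
#' (LSGP, LIGP, RAGP, RIGP), radiates `n_nerves_per_gp` geodesic nerve
#' branches outward at near-uniform angles, and assigns a uniform ACh
#' concentration to the GP and nerve vertices (zero elsewhere).
#'
#' @param geom an [generate_idealized_la()] geometry.
#' @param n_nerves_per_gp nerve branches per GP (default 8).
#' @param nerve_length branch length (mm); default 0.4 x LA diameter.
#' @param gp_radius GP patch radius (mm).
#' @param ach ACh concentration on GP and nerves (uM).
#' @param seed integer seed for the angular jitter of branch directions.
#' @return A `gp_layout`: per-GP center vertex, patch vertex sets, nerve
#'   polylines and band vertex sets, and the per-vertex `ach` field.
#' @export
generate_gp_octopus <- function(geom, n_nerves_per_gp = 8,
                                nerve_length = NULL, gp_radius = 4,
                                ach = 0.05, seed = 1) {
  stopifnot(inherits(geom, "la_geometry"), ach >= 0)
  nv <- nrow(geom$vertices)
  if (is.null(nerve_length)) nerve_length <- 0.4 * 2 * max(geom$params$radii)
  max_geo <- NULL
  gp_names <- c(PV1 = "LSGP", PV2 = "LIGP", PV3 = "RAGP", PV4 = "RIGP")
  set.seed(seed)
  gps <- list()
  ach_field <- numeric(nv)
  taken <- rep(FALSE, nv)
  for (k in 1:4) {
    pv <- paste0("PV", k)
    d_ost <- geodesic_distance(geom, geom$loops[[pv]])
    # antral position: just outside the PV sleeve, toward the mitral side
    cand <- which(geom$region == "LA" &
                    d_ost >= geom$params$pv_sleeve + 1 &
                    d_ost <= geom$params$pv_sleeve + 5)
    if (!length(cand)) stop("no antral candidates for GP at ", pv)
    # prefer the inferior/mitral-facing side of the antrum
    center <- cand[which.min(geom$vertices[cand, 2])]
    d_c <- geodesic_distance(geom, center)
    patch <- which(d_c <= gp_radius & !taken)
    taken[patch] <- TRUE
    if (max(d_c[is.finite(d_c)]) < nerve_length)
      warning("nerve_length exceeds mesh extent; branches truncated")
    # nerve targets: vertices near the geodesic circle of radius nerve_length
    ring <- which(abs(d_c - nerve_length) <= max(1.5, nerve_length * 0.08))
    if (!length(ring)) ring <- which.max(ifelse(is.finite(d_c), d_c, -1))
    # spread targets by angle around the GP center (tangent-plane azimuth)
    nrm <- geom$vertices[center, ] / sqrt(sum(geom$vertices[center, ]^2))
    t1 <- c(-nrm[2], nrm[1], 0); t1 <- t1 / sqrt(sum(t1^2))
    t2 <- c(nrm[2] * t1[3] - nrm[3] * t1[2],
            nrm[3] * t1[1] - nrm[1] * t1[3],
            nrm[1] * t1[2] - nrm[2] * t1[1])
    rel <- sweep(geom$vertices[ring, , drop = FALSE], 2,
                 geom$vertices[center, ])
    az <- atan2(rel %*% t2, rel %*% t1)
    want <- seq(-pi, pi, length.out = n_nerves_per_gp + 1)[-1] +
      stats::runif(max(n_nerves_per_gp, 1), -0.1, 0.1)
    nerves <- list()
    if (n_nerves_per_gp > 0) {
      for (a in want) {
        dd <- abs(atan2(sin(az - a), cos(az - a)))
        tgt <- ring[which.min(dd)]
        sp <- igraph::shortest_paths(geom$graph, from = center, to = tgt,
                                     output = "vpath")$vpath[[1]]
        nerves[[length(nerves) + 1]] <- as.integer(sp)
      }
    }
    nerve_vts <- unique(unlist(nerves))
    gps[[gp_names[pv]]] <- list(pv = pv, center = center, patch = patch,
                                nerves = nerves,
                                nerve_vertices = setdiff(nerve_vts, patch))
    ach_field[patch] <- ach
    ach_field[nerve_vts] <- ach
  }
  structure(list(gps = gps, ach = ach_field, ach_level = ach,
                 n_nerves_per_gp = n_nerves_per_gp,
                 nerve_length = nerve_length, gp_radius = gp_radius,
                 seed = seed),
            class = "gp_layout")
}

#' @export
print.gp_layout <- function(x, ...) {
  cat("<gp_layout> 4 GPs (", paste(names(x$gps), collapse = ", "), "), ",
      x$n_nerves_per_gp, " nerves/GP, ACh ", x$ach_level, " uM on ",
      sum(x$ach > 0), " vertices\n", sep = "")
  invisible(x)
}

#' Area-weighted overlap of two vertex sets
#'
#' Percentage of the (lumped vertex) area of set A lying inside set B; used
#' e.g. for GP / CFAE-area co-localization.
#'
#' @param maskA,maskB integer vertex indices or logical masks.
#' @param geom an `la_geometry` (or mesh `tissue_domain`).
#' @return Percentage in [0, 100].
#' @export
label_overlap <- function(maskA, maskB, geom) {
  nv <- nrow(geom$vertices)
  toMask <- function(m) {
    if (is.logical(m)) { stopifnot(length(m) == nv); m }
    else { x <- rep(FALSE, nv); x[m] <- TRUE; x }
  }
  a <- toMask(maskA); b <- toMask(maskB)
  dom <- list(type = "mesh", n = nv, coords = geom$vertices,
              tri = geom$triangles)
  va <- vertex_areas(dom)
  if (!sum(va[a])) return(0)
  100 * sum(va[a & b]) / sum(va[a])
}

#' Build a tissue domain from an LA geometry and GP layout
#'
#' Assigns the PV variant to PV-region vertices and the LA variant
#' elsewhere, and sets the per-node ACh field from the layout.
#'
#' @param geom an [generate_idealized_la()] geometry.
#' @param layout optional [generate_gp_octopus()] layout (for the ACh field).
#' @param la_variant,pv_variant [model_variant()]s for the two regions.
#' @param D diffusion coefficient (mm^2/ms).
#' @return A mesh `tissue_domain`.
#' @export
la_tissue_domain <- function(geom, layout = NULL,
                             la_variant = model_variant(),
                             pv_variant = apply_pv_variant(la_variant),
                             D = default_diffusion()) {
  dom <- tissue_mesh(geom$vertices, geom$triangles, D = D)
  is_pv <- grepl("^PV", as.character(geom$region))
  dom <- set_variants(dom, list(la_variant, pv_variant),
                      ifelse(is_pv, 2L, 1L))
  ach <- numeric(dom$n)
  if (!is.null(layout)) ach <- layout$ach
  # local GP ACh adds to any uniform ACh carried by the variants
  dom <- set_ach_field(dom, pmax(dom$ach, ach))
  dom$geom <- geom
  dom
}
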