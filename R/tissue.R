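# Voronoi tissue geometry and elastic vertex-model mechanics.
#
# The tissue is a set of generator points inside a simple polygonal domain;
# cell shapes are the Voronoi regions clipped to the domain, which tile it
# exactly. The elastic energy is the standard two-term vertex-model form,
#   E = sum_i [ Kv/2 (A_i - A0_i)^2 + Kc/2 (P_i - P0_i)^2 ],
# with the preferred perimeter tied to the preferred area through the
# regular-hexagon isoperimetric ratio so a confluent ground state has E = 0.
# Forces are central finite differences of E through the tessellation.

#' Rectangular tissue domain
#'
#' A rectangle used mainly by unit tests. The duct is one side of the
#' rectangle: cells touching it are glucose sources, and duct elongation
#' extends the rectangle along its axis.
#'
#' @param width,height rectangle dimensions (model lengths; one unit is of
#'   the order of a cell diameter).
#' @param duct which side carries the duct lumen (`"left"` or `"none"`).
#' @export
tissue_domain_rect <- function(width = 10, height = 10,
                               duct = c("left", "none")) {
  duct <- match.arg(duct)
  boundary <- cbind(x = c(0, width, width, 0), y = c(0, 0, height, height))
  structure(list(
    type = "rect",
    params = list(width = width, height = height, duct = duct),
    boundary = boundary,
    # boundary edge k runs from vertex k to k+1; edge 4 is the left side
    source_edges = if (duct == "left") 4L else integer(0),
    duct_axis = rbind(c(0, height / 2), c(width, height / 2)),
    duct_length = width,
    area = width * height), class = "tissue_domain")
}

#' U-shaped acinar-ductal domain
#'
#' The default geometry: a two-dimensional projection of the end of a duct
#' opening into an acinus, i.e. a rectangle with a rectangular lumen slot
#' cut into it from the top. The three lumen-facing walls are the glucose
#' source boundary, and duct elongation extends the arms (and the lumen)
#' upward.
#'
#' @param width,height outer rectangle dimensions.
#' @param base_height y of the lumen bottom (acinus depth).
#' @param lumen_halfwidth half-width of the duct lumen slot.
#' @export
tissue_domain_u <- function(width = 10, height = 10, base_height = 6,
                            lumen_halfwidth = 1) {
  stopifnot(base_height < height, lumen_halfwidth < width / 2)
  cx <- width / 2
  boundary <- cbind(
    x = c(0, width, width, cx + lumen_halfwidth, cx + lumen_halfwidth,
          cx - lumen_halfwidth, cx - lumen_halfwidth, 0),
    y = c(0, 0, height, height, base_height, base_height, height, height))
  structure(list(
    type = "u",
    params = list(width = width, height = height, base_height = base_height,
                  lumen_halfwidth = lumen_halfwidth),
    boundary = boundary,
    source_edges = c(4L, 5L, 6L), # the two lumen walls and the lumen bottom
    duct_axis = rbind(c(cx, base_height), c(cx, height)),
    duct_length = height - base_height,
    area = width * height - 2 * lumen_halfwidth * (height - base_height)),
    class = "tissue_domain")
}

# rebuild a domain after changing its parameters
rebuild_domain <- function(domain) {
  p <- domain$params
  switch(domain$type,
         rect = tissue_domain_rect(p$width, p$height, p$duct),
         u = tissue_domain_u(p$width, p$height, p$base_height,
                             p$lumen_halfwidth),
         stop("unknown domain type"))
}

#' Extend a domain along its duct axis
#' @param domain a tissue domain.
#' @param dL non-negative elongation length.
#' @export
elongate_domain <- function(domain, dL) {
  stopifnot(dL >= 0)
  if (domain$type == "rect") domain$params$width <- domain$params$width + dL
  else domain$params$height <- domain$params$height + dL
  rebuild_domain(domain)
}

#' Preferred perimeter for a preferred area
#'
#' Perimeter of the regular hexagon with the given area (the confluent
#' ground-state shape), `P0 = sqrt(8 sqrt(3) A0)`.
#' @param A0 preferred area(s).
#' @export
hex_perimeter <- function(A0) sqrt(8 * sqrt(3) * A0)

#' Mechanical parameters
#'
#' `Kc` and `Kv` are the perimeter (contact) and area stiffnesses, 0.3 and
#' 0.06 in model units (their reported physical units, Pa m and Pa m^-1,
#' identify which constant multiplies which term). `friction` is the damping
#' coefficient in model units, defaulted near critical for the default
#' stiffnesses so relaxation completes within its window; the reported
#' physical friction 0.001 Pa m s is kept as metadata.
#'
#' @param Kc,Kv stiffnesses (positive).
#' @param friction damping coefficient (model units).
#' @param k_friction_phys the reported physical friction value (metadata).
#' @param force_tol relaxation stops when `max |F|` falls below this.
#' @param max_relax_time relaxation window in mechanical time units.
#' @param dt integration step of the damped-Newtonian dynamics.
#' @param fd_step finite-difference step; default `1e-6` times the domain
#'   diameter, set at call time.
#' @export
mech_params <- function(Kc = 0.3, Kv = 0.06, friction = 1,
                        k_friction_phys = 0.001, force_tol = 1e-3,
                        max_relax_time = 30, dt = 0.05, fd_step = NULL) {
  stopifnot(Kc > 0, Kv > 0, friction > 0, force_tol > 0,
            max_relax_time > 0, dt > 0)
  structure(list(Kc = Kc, Kv = Kv, friction = friction,
                 k_friction_phys = k_friction_phys, force_tol = force_tol,
                 max_relax_time = max_relax_time, dt = dt,
                 fd_step = fd_step), class = "mech_params")
}

domain_diameter <- function(domain) {
  b <- domain$boundary
  sqrt(diff(range(b[, 1]))^2 + diff(range(b[, 2]))^2)
}

#' Clipped Voronoi tessellation
#'
#' Voronoi regions of the generator points intersected with the domain
#' polygon. The polygons partition the domain; the adjacency graph carries
#' the shared-edge lengths and the finite-volume weights
#' `w_ij = shared edge length / generator distance`.
#'
#' @param points two-column matrix of generator positions, all inside the
#'   domain and pairwise distinct (coincident points are jittered with a
#'   warning).
#' @param domain a tissue domain.
#' @return list with `polygons`, `area`, `perimeter`, `edges` (data.frame
#'   `i, j, len, w`) and `bnd` (data.frame of boundary segments per cell:
#'   `cell, edge, len, mx, my`).
#' @export
build_voronoi <- function(points, domain) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2, nrow(points) >= 1)
  inside <- cpp_point_in_poly(points[, 1], points[, 2],
                              domain$boundary[, 1], domain$boundary[, 2])
  if (!all(inside))
    stop("generator point(s) outside the domain: ",
         paste(which(!inside), collapse = ", "))
  d <- as.matrix(stats::dist(points))
  diag(d) <- Inf
  if (any(d < 1e-9)) {
    warning("coincident generator points jittered")
    dup <- unique(which(d < 1e-9, arr.ind = TRUE)[, 1])
    points[dup, ] <- points[dup, ] +
      matrix(stats::runif(2 * length(dup), -1e-7, 1e-7), ncol = 2)
  }
  v <- cpp_voronoi(points[, 1], points[, 2],
                   domain$boundary[, 1], domain$boundary[, 2])
  edges <- data.frame(i = v$edge_i, j = v$edge_j, len = v$edge_len)
  if (nrow(edges)) {
    dist_ij <- sqrt((points[edges$i, 1] - points[edges$j, 1])^2 +
                    (points[edges$i, 2] - points[edges$j, 2])^2)
    edges$w <- edges$len / dist_ij
  } else edges$w <- numeric(0)
  list(polygons = v$polygons, area = v$area, perimeter = v$perimeter,
       edges = edges,
       bnd = data.frame(cell = v$bnd_cell, edge = v$bnd_edge,
                        len = v$bnd_len, mx = v$bnd_mx, my = v$bnd_my))
}

#' Construct a tissue state
#'
#' @param points generator positions (one biological cell each).
#' @param domain a tissue domain.
#' @param A0 preferred areas (default: domain area / cell count, the basal
#'   cell size).
#' @param lineage `"healthy"` or `"cancer"`, recycled.
#' @param mass cell masses (mother default 1), recycled.
#' @return object of class `tissue_state`: `$cells` data.frame (position,
#'   velocity, mass, preferred area `A0`, glucose `ci`, clock `Ti`, `age`,
#'   `lineage`) plus the current tessellation in `$geom`.
#' @export
make_tissue <- function(points, domain, A0 = NULL, lineage = "healthy",
                        mass = 1) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (is.null(A0)) A0 <- domain$area / n
  cells <- data.frame(
    id = seq_len(n), x = points[, 1], y = points[, 2],
    vx = 0, vy = 0, mass = rep_len(mass, n),
    A0 = rep_len(A0, n), ci = 0.5, Ti = 0, age = 0,
    lineage = rep_len(lineage, n), stringsAsFactors = FALSE)
  tis <- structure(list(cells = cells, domain = domain, geom = NULL,
                        next_id = n + 1L), class = "tissue_state")
  retessellate(tis)
}

#' Recompute the tessellation of a tissue
#' @param tissue a `tissue_state`.
#' @export
retessellate <- function(tissue) {
  tissue$geom <- build_voronoi(cbind(tissue$cells$x, tissue$cells$y),
                               tissue$domain)
  tissue
}

#' Elastic energy of a tissue
#'
#' @param tissue a `tissue_state` with a current tessellation.
#' @param p a [mech_params()].
#' @export
elastic_energy <- function(tissue, p = mech_params()) {
  cpp_energy(tissue$cells$x, tissue$cells$y,
             tissue$domain$boundary[, 1], tissue$domain$boundary[, 2],
             tissue$cells$A0, hex_perimeter(tissue$cells$A0), p$Kc, p$Kv)
}

#' Mechanical forces on the cell generators
#'
#' `F_i = -dE/dr_i` by central finite differences through the clipped
#' tessellation.
#'
#' @inheritParams elastic_energy
#' @return n x 2 matrix of force vectors.
#' @export
tissue_forces <- function(tissue, p = mech_params()) {
  h <- if (is.null(p$fd_step)) 1e-6 * domain_diameter(tissue$domain)
       else p$fd_step
  cpp_forces(tissue$cells$x, tissue$cells$y,
             tissue$domain$boundary[, 1], tissue$domain$boundary[, 2],
             tissue$cells$A0, hex_perimeter(tissue$cells$A0),
             p$Kc, p$Kv, h)
}

#' Relax a tissue toward mechanical equilibrium
#'
#' Damped-Newtonian dynamics `m r'' = F - friction * r'` integrated with
#' semi-implicit Euler, re-tessellating after every position update. Stops
#' at `duration` or when `max |F| < force_tol`. Points that would leave the
#' domain are held back and their velocity zeroed. The total mechanical
#' energy (kinetic + elastic) recorded at checkpoints is non-increasing up
#' to integrator slack.
#'
#' @inheritParams elastic_energy
#' @param duration relaxation window in mechanical time units.
#' @return the relaxed `tissue_state`; attributes `converged`, `steps` and
#'   `energy_trace` (checkpointed total energy).
#' @export
relax <- function(tissue, p = mech_params(), duration = p$max_relax_time) {
  stopifnot(duration > 0)
  nsteps <- max(1L, ceiling(duration / p$dt))
  cl <- tissue$cells
  n <- nrow(cl)
  converged <- FALSE
  trace <- numeric(0)
  checkpoint_every <- 20L
  steps_done <- 0L
  h <- if (is.null(p$fd_step)) 1e-6 * domain_diameter(tissue$domain)
       else p$fd_step
  bx <- tissue$domain$boundary[, 1]; by <- tissue$domain$boundary[, 2]
  for (s in seq_len(nsteps)) {
    # the force kernel clips each affected cell against exactly its
    # neighbour set, so the adjacency must be current at every step
    nb <- cpp_neighbors(tissue$cells$x, tissue$cells$y, bx, by)
    F <- cpp_forces(tissue$cells$x, tissue$cells$y, bx, by,
                    tissue$cells$A0, hex_perimeter(tissue$cells$A0),
                    p$Kc, p$Kv, h, nb)
    fmax <- if (n > 0) max(sqrt(rowSums(F^2))) else 0
    if (fmax < p$force_tol) { converged <- TRUE; break }
    cl <- tissue$cells
    damp <- 1 + p$dt * p$friction / cl$mass
    vx <- (cl$vx + p$dt * F[, 1] / cl$mass) / damp
    vy <- (cl$vy + p$dt * F[, 2] / cl$mass) / damp
    nx <- cl$x + p$dt * vx
    ny <- cl$y + p$dt * vy
    inside <- cpp_point_in_poly(nx, ny, tissue$domain$boundary[, 1],
                                tissue$domain$boundary[, 2])
    if (!all(inside)) { # hold escapers at their previous position
      nx[!inside] <- cl$x[!inside]
      ny[!inside] <- cl$y[!inside]
      vx[!inside] <- 0
      vy[!inside] <- 0
    }
    tissue$cells$x <- nx; tissue$cells$y <- ny
    tissue$cells$vx <- vx; tissue$cells$vy <- vy
    steps_done <- s
    if (s %% checkpoint_every == 0L) {
      tissue <- retessellate(tissue)
      ke <- 0.5 * sum(tissue$cells$mass *
                        (tissue$cells$vx^2 + tissue$cells$vy^2))
      trace <- c(trace, ke + elastic_energy(tissue, p))
    }
  }
  tissue <- retessellate(tissue)
  attr(tissue, "converged") <- converged
  attr(tissue, "steps") <- steps_done
  attr(tissue, "energy_trace") <- trace
  tissue
}
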