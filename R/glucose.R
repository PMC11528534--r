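# Glucose transport on the Voronoi adjacency graph.
#
# Finite-volume diffusion on the dual mesh: A_i dc_i/dt =
# D * sum_j w_ij (c_j - c_i) - uptake, with w_ij = shared edge length /
# generator distance. Cells whose polygon touches the duct lumen hold
# c = 1 (Dirichlet sources); the outer boundary is no-flux. The optional
# linear consumption term is per *cell* (uptake 2 kappa c_i per cell,
# mirroring the clock rate law): metabolic demand follows cell count, so
# crowded regions deplete glucose faster than sparse ones. Without sinks
# the sourced steady state is uniform 1.

#' Construct a glucose field on a tissue
#'
#' @param tissue a `tissue_state`.
#' @param conc initial per-cell concentrations in `[0, 1]`; default 0.5
#'   everywhere with sources at 1.
#' @param D diffusivity (model units; default 10, fast transport relative
#'   to consumption so gradients stay shallow at tissue scale).
#' @param sources `"duct"` (cells touching the domain's source boundary),
#'   `"none"`, or a logical/integer vector of source cells.
#' @export
glucose_field <- function(tissue, conc = NULL, D = 10, sources = "duct") {
  n <- nrow(tissue$cells)
  if (is.character(sources)) {
    sources <- match.arg(sources, c("duct", "none"))
    src <- rep(FALSE, n)
    if (sources == "duct" && length(tissue$domain$source_edges)) {
      b <- tissue$geom$bnd
      hit <- b$cell[b$edge %in% tissue$domain$source_edges & b$len > 1e-9]
      src[unique(hit)] <- TRUE
    }
  } else if (is.logical(sources)) {
    stopifnot(length(sources) == n)
    src <- sources
  } else {
    src <- rep(FALSE, n)
    src[sources] <- TRUE
  }
  if (is.null(conc)) { conc <- rep(0.5, n); conc[src] <- 1 }
  stopifnot(length(conc) == n, all(conc >= 0), all(conc <= 1), D > 0)
  structure(list(c = conc, source = src, D = D), class = "glucose_field")
}

#' Explicit stability bound for a diffusion step
#' @param tissue,field tissue and glucose field.
#' @param consumption linear uptake coefficient, scalar or per cell
#'   (see [diffuse_step()]).
#' @export
glucose_stability_dt <- function(tissue, field, consumption = 0) {
  e <- tissue$geom$edges
  n <- nrow(tissue$cells)
  wsum <- numeric(n)
  if (nrow(e)) {
    wsum <- wsum + as.numeric(tapply(c(e$w, e$w), c(e$i, e$j), sum)[
      as.character(seq_len(n))])
    wsum[is.na(wsum)] <- 0
  }
  rate <- (field$D * wsum + 2 * consumption) / tissue$geom$area
  if (all(rate == 0)) return(Inf)
  1 / max(rate)
}

#' One explicit finite-volume diffusion step
#'
#' `A_i dc_i/dt = D sum_j w_ij (c_j - c_i) - 2 consumption_i c_i`;
#' source cells are reset to 1 after the step. The uptake coefficient is
#' per cell (scalar or vector): metabolic consumption mirrors the clock-rate
#' law (2 c_i) and scales with cell count, not area. Without sources and
#' consumption the total glucose `sum c_i A_i` is conserved exactly.
#'
#' @inheritParams glucose_stability_dt
#' @param dt step; must satisfy the explicit stability bound
#'   ([glucose_stability_dt()]), else an error.
#' @export
diffuse_step <- function(tissue, field, dt, consumption = 0) {
  stopifnot(dt > 0, all(consumption >= 0))
  bound <- glucose_stability_dt(tissue, field, consumption)
  if (dt > bound)
    stop(sprintf("dt = %g violates the stability bound %g", dt, bound))
  conc <- field$c
  n <- length(conc)
  flux <- numeric(n)
  e <- tissue$geom$edges
  if (nrow(e)) {
    f <- field$D * e$w * (conc[e$j] - conc[e$i]) # symmetric pairwise flux
    flux <- flux + as.numeric(tapply(c(f, -f), c(e$i, e$j), sum)[
      as.character(seq_len(n))])
    flux[is.na(flux)] <- 0
  }
  conc <- conc + dt * (flux - 2 * consumption * conc) / tissue$geom$area
  conc[field$source] <- 1
  field$c <- conc
  field
}

#' Steady-state glucose field
#'
#' Dirichlet sources at 1, no-flux outer boundary, optional linear
#' consumption. `method = "direct"` solves the (linear) discrete balance
#' with a sparse solve; `method = "iterate"` repeats [diffuse_step()] at
#' 0.9 of the stability bound until the per-step change falls below `tol`.
#' Both satisfy the discrete Laplace balance and the maximum principle.
#'
#' @inheritParams diffuse_step
#' @param tol convergence tolerance for the iterative method.
#' @param max_iter iteration cap (error on non-convergence).
#' @param method `"direct"` or `"iterate"`.
#' @export
steady_state <- function(tissue, field, tol = 1e-10, max_iter = 200000,
                         consumption = 0, method = c("direct", "iterate")) {
  method <- match.arg(method)
  if (!any(field$source)) stop("steady_state needs at least one source cell")
  n <- nrow(tissue$cells)
  if (method == "iterate") {
    dt <- 0.9 * glucose_stability_dt(tissue, field, consumption)
    for (it in seq_len(max_iter)) {
      old <- field$c
      field <- diffuse_step(tissue, field, dt, consumption)
      if (max(abs(field$c - old)) < tol) return(field)
    }
    stop("glucose steady state did not converge")
  }
  # direct sparse solve of D L c - 2 consumption c = 0 with c = 1 on sources
  e <- tissue$geom$edges
  A <- tissue$geom$area
  i <- c(e$i, e$j, seq_len(n))
  j <- c(e$j, e$i, seq_len(n))
  wsum <- numeric(n)
  if (nrow(e)) {
    s <- as.numeric(tapply(c(e$w, e$w), c(e$i, e$j), sum)[
      as.character(seq_len(n))])
    s[is.na(s)] <- 0
    wsum <- s
  }
  x <- c(field$D * e$w, field$D * e$w,
         -field$D * wsum - 2 * rep_len(consumption, n))
  M <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n))
  rhs <- numeric(n)
  src <- which(field$source)
  # Dirichlet rows
  M[src, ] <- 0
  M[cbind(src, src)] <- 1
  rhs[src] <- 1
  field$c <- as.numeric(Matrix::solve(M, rhs))
  field$c <- pmin(pmax(field$c, 0), 1)
  field
}

#' Area-weighted mean glucose concentration
#' @param tissue,field tissue and glucose field.
#' @export
mean_concentration <- function(tissue, field) {
  if (nrow(tissue$cells) == 0) stop("empty tissue")
  sum(field$c * tissue$geom$area) / sum(tissue$geom$area)
}
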