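# Configuration, serialization, fixtures and rendering.
#
# Config files are JSON (human-editable, typed); tissue snapshots are JSON
# with a schema version; time series are plain data.frames the caller can
# write as CSV. All randomness flows from the seed in the configuration.

SNAPSHOT_SCHEMA <- "paninsim-snapshot-1"

#' Load a simulation configuration from JSON
#'
#' Missing fields take the model defaults; unknown keys are an error;
#' invariants are re-validated through [sim_config()]. An empty file (or
#' `{}`) yields the full default configuration (Kc = 0.3, Kv = 0.06,
#' gamma = 16, lambda_h = 0.15, T0 = 36 d, tau1 = 17.13 y, tau2 = 13.82 y).
#'
#' @param path path to a JSON config file.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  lst <- if (!nzchar(trimws(txt))) list()
         else jsonlite::fromJSON(txt, simplifyVector = TRUE)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(lst), c(known, "scenario"))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  lst$scenario <- NULL
  do.call(sim_config, lst)
}

#' Write a configuration to JSON
#' @param cfg a [sim_config()].
#' @param path output path.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write / read a tissue snapshot
#'
#' JSON round-trip of the full tissue state (cells with polygon vertex
#' lists, per-cell scalars, domain, glucose field) at full precision.
#' Snapshots are self-describing; a schema mismatch on read is an error.
#'
#' @param state a `sim_state` or `tissue_state`.
#' @param path file path.
#' @export
write_snapshot <- function(state, path) {
  tissue <- if (inherits(state, "sim_state")) state$tissue else state
  field <- if (inherits(state, "sim_state")) state$field else NULL
  doc <- list(
    schema = SNAPSHOT_SCHEMA,
    time = if (inherits(state, "sim_state")) state$time else 0,
    domain = list(type = tissue$domain$type, params = tissue$domain$params),
    cells = tissue$cells,
    polygons = lapply(tissue$geom$polygons, function(m)
      list(x = m[, 1], y = m[, 2])),
    glucose = if (!is.null(field))
      list(c = field$c, source = field$source, D = field$D))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_snapshot
#' @export
read_snapshot <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(doc$schema, SNAPSHOT_SCHEMA))
    stop("snapshot schema mismatch: ", doc$schema %||% "<missing>")
  p <- doc$domain$params
  domain <- if (doc$domain$type == "u")
    tissue_domain_u(p$width, p$height, p$base_height, p$lumen_halfwidth)
  else tissue_domain_rect(p$width, p$height, p$duct)
  cells <- as.data.frame(doc$cells)
  tis <- structure(list(cells = cells, domain = domain, geom = NULL,
                        next_id = max(cells$id) + 1L),
                   class = "tissue_state")
  tis <- retessellate(tis)
  out <- list(time = doc$time, tissue = tis)
  if (!is.null(doc$glucose))
    out$field <- structure(list(c = doc$glucose$c,
                                source = doc$glucose$source,
                                D = doc$glucose$D),
                           class = "glucose_field")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Deterministic tissue fixtures
#'
#' Small tissues used throughout the test-suite: `"lattice"` (hexagonal
#' lattice in a rectangle, preferred areas set to the realized areas so the
#' construction is at mechanical equilibrium), `"random"` (seeded cloud in
#' the U-domain), `"two_cell"` (mirror-symmetric pair in the unit square)
#' and `"perturbed_hex"` (19-cell hexagonal patch with a seeded jitter).
#'
#' @param kind fixture name.
#' @param seed random seed (used by the random/perturbed kinds).
#' @param n target cell count for `"random"`.
#' @export
make_fixture <- function(kind = c("lattice", "random", "two_cell",
                                  "perturbed_hex"), seed = 1, n = 60) {
  kind <- match.arg(kind)
  set.seed(seed)
  if (kind == "two_cell") {
    dom <- tissue_domain_rect(1, 1, duct = "none")
    return(make_tissue(rbind(c(0.25, 0.5), c(0.75, 0.5)), dom, A0 = 0.5))
  }
  if (kind == "random") {
    dom <- tissue_domain_u()
    pts <- sample_points(n, dom, 0.3 * sqrt(dom$area / n))
    return(make_tissue(pts, dom))
  }
  # hexagonal lattice: rows offset by half a spacing
  hex_points <- function(nx, ny, s) {
    pts <- NULL
    for (r in seq_len(ny)) {
      xs <- (seq_len(nx) - 0.5 + ifelse(r %% 2 == 0, 0.5, 0)) * s
      ys <- rep((r - 0.5) * s * sqrt(3) / 2 + 0.125 * s, nx)
      pts <- rbind(pts, cbind(xs, ys))
    }
    pts
  }
  if (kind == "lattice") {
    s <- 1
    pts <- hex_points(6, 6, s)
    w <- max(pts[, 1]) + 0.5 * s
    h <- max(pts[, 2]) + 0.5 * s
    dom <- tissue_domain_rect(w, h, duct = "none")
    tis <- make_tissue(pts, dom)
    # start from realized areas and relax the residual perimeter
    # mismatch out, so the fixture is at mechanical equilibrium
    tis$cells$A0 <- tis$geom$area
    tis <- relax(tis, mech_params(), duration = 100)
    tis$cells$vx <- 0
    tis$cells$vy <- 0
    return(tis)
  }
  # perturbed_hex: 19 cells (central + two rings), jittered
  s <- 1
  centre <- c(2.5, 2.2)
  ring <- function(r, k) {
    th <- 2 * pi * (seq_len(k) - 1) / k + pi / 6
    cbind(centre[1] + r * cos(th), centre[2] + r * sin(th))
  }
  pts <- rbind(matrix(centre, 1), ring(s, 6), ring(2 * s * 0.94, 12))
  pts <- pts + matrix(stats::runif(38, -0.08, 0.08), ncol = 2)
  dom <- tissue_domain_rect(5, 4.4, duct = "none")
  make_tissue(pts, dom)
}

#' Render a tissue snapshot as SVG
#'
#' Cell polygons filled with a blue-to-yellow glucose colour map; cancer
#' cells outlined in red.
#'
#' @param tissue a `tissue_state`.
#' @param path output `.svg` path.
#' @param field optional glucose field (defaults to the cells' `ci`).
#' @export
render_svg <- function(tissue, path, field = NULL) {
  conc <- if (!is.null(field)) field$c else tissue$cells$ci
  b <- tissue$domain$boundary
  xr <- range(b[, 1]); yr <- range(b[, 2])
  wpx <- 500
  scl <- wpx / diff(xr)
  hpx <- diff(yr) * scl
  px <- function(x) (x - xr[1]) * scl
  py <- function(y) hpx - (y - yr[1]) * scl
  col <- function(v) {
    v <- max(0, min(1, v))
    sprintf("#%02x%02x%02x", round(40 + 215 * v), round(60 + 180 * v),
            round(200 - 160 * v))
  }
  lines <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
    round(wpx), round(hpx)))
  for (k in seq_along(tissue$geom$polygons)) {
    m <- tissue$geom$polygons[[k]]
    ptstr <- paste(sprintf("%.2f,%.2f", px(m[, 1]), py(m[, 2])),
                   collapse = " ")
    stroke <- if (tissue$cells$lineage[k] == "cancer") "#cc0000" else "#333"
    lines <- c(lines, sprintf(
      '<polygon points="%s" fill="%s" stroke="%s" stroke-width="%s"/>',
      ptstr, col(conc[k]), stroke,
      if (stroke == "#cc0000") "2" else "0.5"))
  }
  lines <- c(lines, "</svg>")
  writeLines(lines, path)
  invisible(path)
}

#' Run manifest
#'
#' Metadata sufficient to re-run a simulation bit-identically: the config
#' echo, package version, seed, model time range and checksums of the
#' written artifact files.
#'
#' @param state a finished `sim_state`.
#' @param files character vector of artifact paths to checksum.
#' @param path optional output path for the manifest JSON.
#' @export
run_manifest <- function(state, files = character(0), path = NULL) {
  stopifnot(inherits(state, "sim_state"))
  man <- list(
    package = "paninsim",
    version = as.character(utils::packageVersion("paninsim")),
    seed = state$config$seed,
    config = unclass(state$config),
    t_start = 0, t_end = state$time,
    files = if (length(files))
      data.frame(path = files, md5 = unname(tools::md5sum(files)))
    else NULL)
  if (is.null(path)) return(man)
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
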