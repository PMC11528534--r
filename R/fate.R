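# Glucose-paced cell-cycle clocks and the division/death rules.
#
# Each cell carries an internal clock Ti that advances at a rate set by its
# local glucose concentration; at mean glucose <ci> = 0.5 the clock
# completes exactly one basal cycle T0 per elapsed T0 (the gamma = 16
# calibration). Fate is decided at T0/2 check intervals: a cell divides when
# its clock runs ahead, (Ti - T0)/T0 > lambda_h, and dies when it lags,
# (T0 - Ti)/T0 > lambda_h, with lambda_h = 0.15. Cells younger than the
# death-eligibility age (two basal cycles) are exempt from the death rule:
# a newborn clock starts at zero, and starvation must persist beyond a
# transient dip before it commits a cell to death.

#' Cell-cycle clock parameters
#'
#' @param T0 basal cycle duration in model time units (default 1 unit =
#'   36 days).
#' @param gamma clock gain; the default 16 corresponds to one basal
#'   oscillation per T0 at mean glucose 0.5 under the linear law
#'   `rate(ci) = (gamma/8) ci`.
#' @param beta0 half-saturation of the alternative saturating law
#'   `rate(ci) = 2 ci^2 / (ci^2 + beta0^2)` (also calibrated to
#'   `rate(0.5) = 1` at the default `beta0 = 0.5`).
#' @param lambda_h fate threshold (0 < lambda_h < 1).
#' @param check_interval fate-check cadence (default T0/2).
#' @param law `"linear"` (default) or `"hill"`.
#' @param t_grow timescale on which a daughter's preferred area regrows
#'   toward the basal cell size.
#' @param death_age minimum age before the death rule applies (default two
#'   basal cycles: starvation must persist, not merely dip).
#' @export
clock_params <- function(T0 = 1, gamma = 16, beta0 = 0.5, lambda_h = 0.15,
                         check_interval = T0 / 2,
                         law = c("linear", "hill"), t_grow = T0 / 2,
                         death_age = 2 * T0) {
  law <- match.arg(law)
  stopifnot(T0 > 0, gamma > 0, beta0 > 0, lambda_h > 0, lambda_h < 1,
            check_interval > 0, t_grow > 0, death_age >= T0)
  structure(list(T0 = T0, gamma = gamma, beta0 = beta0, lambda_h = lambda_h,
                 check_interval = check_interval, law = law, t_grow = t_grow,
                 death_age = death_age),
            class = "clock_params")
}

#' Clock advance rate as a function of glucose
#'
#' Monotone non-decreasing, `rate(0) = 0`, calibrated so `rate(0.5) = 1`
#' (one basal cycle per T0 at mean glucose).
#'
#' @param ci glucose concentration(s) in `[0, 1]`.
#' @param p a [clock_params()].
#' @export
clock_rate <- function(ci, p = clock_params()) {
  if (any(ci < 0 | ci > 1)) stop("glucose concentration outside [0, 1]")
  if (p$law == "linear") (p$gamma / 8) * ci
  else 2 * ci^2 / (ci^2 + p$beta0^2)
}

#' Advance internal clocks
#'
#' `Ti <- Ti + dt * rate(ci)`.
#'
#' @param Ti clock value(s).
#' @param dt elapsed time (> 0).
#' @param ci glucose concentration(s).
#' @param p a [clock_params()].
#' @export
advance_clock <- function(Ti, dt, ci, p = clock_params()) {
  stopifnot(dt > 0)
  Ti + dt * clock_rate(ci, p)
}

#' Fate decision from the clock
#'
#' Divide when `(Ti - T0)/T0 > lambda_h`, die when `(T0 - Ti)/T0 > lambda_h`
#' (strict inequalities; both cannot hold for lambda_h > 0). The death rule
#' applies only to cells at least `death_age` old (default two basal
#' cycles: starvation must persist, not merely dip).
#'
#' @param Ti clock value(s), non-negative.
#' @param p a [clock_params()].
#' @param age cell age(s); default `Inf` (death rule active).
#' @return character vector in `{"divide", "die", "none"}`.
#' @export
decide_fate <- function(Ti, p = clock_params(), age = Inf) {
  stopifnot(all(Ti >= 0))
  eps <- 1e-9 # strict inequalities, robust to representation error
  ahead <- (Ti - p$T0) / p$T0
  behind <- (p$T0 - Ti) / p$T0
  out <- rep("none", length(Ti))
  out[ahead > p$lambda_h + eps] <- "divide"
  out[behind > p$lambda_h + eps & age >= p$death_age] <- "die"
  out
}

#' Divide a cell
#'
#' Geometric daughter generation: with mother area `A` and effective radius
#' `R = sqrt(A/pi)`, the daughters are placed at `+/- (R/2) u` from the
#' mother centre along a uniformly random unit vector `u` (option
#' `offset = "sqrt2"` uses `R/sqrt(2)` instead, the offset that makes two
#' disks of half the mother's area tangent). Masses and preferred areas are
#' halved, the glucose concentration is inherited (amounts split with the
#' re-tessellated areas), clocks and ages reset to zero, lineage is
#' inherited. Velocities: mother velocity plus opposite kicks of magnitude
#' `|v|/sqrt(2)` along the division axis -- momentum is conserved exactly
#' and the total daughter kinetic energy is 3/2 of the mother's.
#'
#' @param tissue a `tissue_state`.
#' @param id id of the dividing cell.
#' @param offset `"half"` (`R/2`, the printed rule) or `"sqrt2"`.
#' @param kick `"momentum"` (default rule above) or `"none"`.
#' @param max_tries resampling attempts when a daughter lands outside the
#'   domain.
#' @return the tissue with the mother replaced by two daughters,
#'   re-tessellated; attribute `daughter_ids`.
#' @export
divide_cell <- function(tissue, id, offset = c("half", "sqrt2"),
                        kick = c("momentum", "none"), max_tries = 100) {
  tissue <- divide_no_retess(tissue, id, match.arg(offset), match.arg(kick),
                             max_tries)
  ids <- attr(tissue, "daughter_ids")
  tissue <- retessellate(tissue)
  attr(tissue, "daughter_ids") <- ids
  tissue
}

# daughter placement and bookkeeping without the (expensive) tessellation
# update, so the orchestrator can batch several divisions per fate check
divide_no_retess <- function(tissue, id, offset, kick, max_tries = 100,
                             area = NULL) {
  k <- which(tissue$cells$id == id)
  if (length(k) != 1) stop("no such cell: ", id)
  mother <- tissue$cells[k, ]
  # when batching, the caller passes the mother's area from the shared
  # pre-division tessellation (row indices shift as daughters are added)
  A <- if (is.null(area)) tissue$geom$area[k] else area
  Reff <- sqrt(A / pi)
  d <- if (offset == "half") Reff / 2 else Reff / sqrt(2)
  bx <- tissue$domain$boundary[, 1]; by <- tissue$domain$boundary[, 2]
  ok <- FALSE
  for (try in seq_len(max_tries)) {
    th <- stats::runif(1, 0, 2 * pi)
    u <- c(cos(th), sin(th))
    p1 <- c(mother$x, mother$y) + d * u
    p2 <- c(mother$x, mother$y) - d * u
    ins <- cpp_point_in_poly(c(p1[1], p2[1]), c(p1[2], p2[2]), bx, by)
    if (all(ins)) { ok <- TRUE; break }
  }
  if (!ok) stop("could not place daughters inside the domain")
  vm <- c(mother$vx, mother$vy)
  w <- if (kick == "momentum") sqrt(sum(vm^2)) / sqrt(2) else 0
  v1 <- vm + w * u
  v2 <- vm - w * u
  ids <- tissue$next_id + c(0L, 1L)
  tissue$next_id <- tissue$next_id + 2L
  daughters <- data.frame(
    id = ids, x = c(p1[1], p2[1]), y = c(p1[2], p2[2]),
    vx = c(v1[1], v2[1]), vy = c(v1[2], v2[2]),
    mass = mother$mass / 2, A0 = mother$A0 / 2, ci = mother$ci,
    Ti = 0, age = 0, lineage = mother$lineage, stringsAsFactors = FALSE)
  tissue$cells <- rbind(tissue$cells[-k, ], daughters)
  rownames(tissue$cells) <- NULL
  attr(tissue, "daughter_ids") <- ids
  tissue
}

#' Remove a dead cell
#'
#' Deletes the generator and recomputes the tessellation; the neighbours
#' absorb the freed area, so the partition of the domain is maintained.
#'
#' @param tissue a `tissue_state`.
#' @param id id of the dying cell.
#' @export
kill_cell <- function(tissue, id) {
  k <- which(tissue$cells$id == id)
  if (length(k) != 1) stop("no such cell: ", id)
  if (nrow(tissue$cells) == 1) stop("cannot remove the last cell")
  tissue$cells <- tissue$cells[-k, ]
  rownames(tissue$cells) <- NULL
  retessellate(tissue)
}
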