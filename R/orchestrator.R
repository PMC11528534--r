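# Scenario assembly and the main simulation loop.
#
# Per half basal cycle (T0/2): (1) mechanical relaxation; (2) glucose
# steady state, with metabolic uptake carried by the proliferation-competent
# cells (growth requires glucose consumption); (3) clock advance and
# preferred-area regrowth; (4) fate checks: division when the clock runs
# ahead and the network phenotype gate is open (a gate-blocked completed
# cycle re-arms, Ti <- Ti - T0), death when the clock lags after at least
# one full basal cycle of age; (5) inflammation index and duct elongation;
# (6) a short settling relaxation after tissue events. The two shared
# network trajectories (healthy variant; cancer variant when cancer cells
# are present) are integrated once at initialisation over the whole horizon
# and read out at check times.

#' Simulation configuration
#'
#' All scenario parameters with model defaults. Times are in model units
#' (1 unit = one basal cytokine period T0 = 36 days); the full-length run
#' of 400 cycles corresponds to 480 months at 30 days/month.
#'
#' @param seed integer seed fixing every random draw.
#' @param n_cells initial cell count.
#' @param n_cancer initial cancer-cell count (0, 6, 10, 14 and 18 are the
#'   reference scenarios).
#' @param total_cycles simulated basal cycles (desk-scale default 10; the
#'   long-run profile is 400).
#' @param domain `"u"` or `"rect"`.
#' @param domain_params named overrides for the domain constructor.
#' @param grn list: `dt` (integrator step), `history` (`"none"` or
#'   `"active"` for the cancer variant's pre-history).
#' @param delays,driver,mech,clock,glucose,homeo parameter blocks (see
#'   [delay_config()], [cytokine_driver()], [mech_params()],
#'   [clock_params()]; `glucose`: `D` and `target_mean`, the calibrated
#'   initial mean concentration; `homeo`: `A_up`, `eta`).
#' @param gate gate division on the phenotype read-outs (healthy cells need
#'   z2 > 0.5, cancer cells z4 > 0.5).
#' @param space_gate contact-inhibition threshold: a cell divides only when
#'   its realized area is at least this fraction of the basal cell size
#'   (division needs room for two daughters; 0 disables).
#' @param seeding `"near_duct"` (cancer cells seeded closest to the duct
#'   lumen) or `"random"`.
#' @param offset_rule,kick_rule division geometry/velocity rules
#'   (see [divide_cell()]).
#' @param relax_window,init_relax_window per-check and initial relaxation
#'   windows in mechanical time units.
#' @param min_spacing_frac minimum initial spacing as a fraction of the
#'   basal cell diameter.
#' @export
sim_config <- function(seed = 1L, n_cells = 100L, n_cancer = 0L,
                       total_cycles = 10, domain = c("u", "rect"),
                       domain_params = list(),
                       grn = list(dt = 2e-3, history = "active"),
                       delays = list(tau1_years = 17.13,
                                     tau2_years = 13.82),
                       driver = list(u = 1.5, v = 0.7, T0 = 1),
                       mech = list(), clock = list(),
                       glucose = list(D = 10, target_mean = 0.5,
                                      basal_frac = 0.02),
                       homeo = list(A_up = 1.1, eta = 0.03, cap = 1e6),
                       gate = TRUE, space_gate = 0.7,
                       seeding = c("near_duct", "random"),
                       offset_rule = "half", kick_rule = "momentum",
                       relax_window = 4, init_relax_window = 20,
                       min_spacing_frac = 0.3) {
  domain <- match.arg(domain)
  seeding <- match.arg(seeding)
  n_cells <- as.integer(n_cells); n_cancer <- as.integer(n_cancer)
  if (n_cancer < 0) stop("n_cancer must be non-negative")
  if (n_cancer > n_cells) stop("n_cancer must not exceed n_cells")
  stopifnot(total_cycles > 0, relax_window > 0, init_relax_window > 0)
  grn <- utils::modifyList(list(dt = 2e-3, history = "active"), grn)
  glucose <- utils::modifyList(list(D = 10, target_mean = 0.5,
                                    basal_frac = 0.02), glucose)
  homeo <- utils::modifyList(list(A_up = 1.1, eta = 0.03, cap = 1e6),
                             homeo)
  cfg <- list(seed = as.integer(seed), n_cells = n_cells,
              n_cancer = n_cancer, total_cycles = total_cycles,
              domain = domain, domain_params = domain_params,
              grn = grn, delays = delays, driver = driver,
              mech = mech, clock = clock, glucose = glucose, homeo = homeo,
              gate = isTRUE(gate), space_gate = space_gate,
              seeding = seeding,
              offset_rule = offset_rule, kick_rule = kick_rule,
              relax_window = relax_window,
              init_relax_window = init_relax_window,
              min_spacing_frac = min_spacing_frac)
  class(cfg) <- "sim_config"
  cfg
}

#' Reference scenario configurations
#'
#' `"healthy"` has no cancer cells; `"panin2-6"` ... `"panin2-18"` seed the
#' corresponding cancer-cell counts with an activated cancer-network
#' pre-history.
#'
#' @param scenario scenario name.
#' @param ... further arguments to [sim_config()].
#' @export
scenario_config <- function(scenario = c("healthy", "panin1", "panin2-6",
                                         "panin2-10", "panin2-14",
                                         "panin2-18"), ...) {
  scenario <- match.arg(scenario)
  n_cancer <- switch(scenario, healthy = 0L, panin1 = 0L,
                     `panin2-6` = 6L, `panin2-10` = 10L,
                     `panin2-14` = 14L, `panin2-18` = 18L)
  cfg <- sim_config(n_cancer = n_cancer, ...)
  cfg$scenario <- scenario
  cfg
}

build_domain <- function(cfg) {
  ctor <- if (cfg$domain == "u") tissue_domain_u else tissue_domain_rect
  do.call(ctor, cfg$domain_params)
}

# distance from points to the domain's glucose-source boundary
dist_to_duct <- function(points, domain) {
  segs <- domain$source_edges
  b <- domain$boundary
  nb <- nrow(b)
  if (length(segs) == 0)
    segs <- NULL
  seg_dist <- function(px, py, ax, ay, bx2, by2) {
    dx <- bx2 - ax; dy <- by2 - ay
    t <- pmax(0, pmin(1, ((px - ax) * dx + (py - ay) * dy) /
                        (dx * dx + dy * dy)))
    sqrt((px - (ax + t * dx))^2 + (py - (ay + t * dy))^2)
  }
  if (is.null(segs)) {
    a <- domain$duct_axis
    return(seg_dist(points[, 1], points[, 2], a[1, 1], a[1, 2],
                    a[2, 1], a[2, 2]))
  }
  d <- rep(Inf, nrow(points))
  for (k in segs) {
    k2 <- if (k == nb) 1L else k + 1L
    d <- pmin(d, seg_dist(points[, 1], points[, 2],
                          b[k, 1], b[k, 2], b[k2, 1], b[k2, 2]))
  }
  d
}

sample_points <- function(n, domain, min_spacing) {
  b <- domain$boundary
  xr <- range(b[, 1]); yr <- range(b[, 2])
  pts <- matrix(NA_real_, n, 2)
  got <- 0L
  for (try in seq_len(500L * n)) {
    p <- c(stats::runif(1, xr[1], xr[2]), stats::runif(1, yr[1], yr[2]))
    if (!cpp_point_in_poly(p[1], p[2], b[, 1], b[, 2])) next
    if (got > 0L) {
      dd <- sqrt((pts[seq_len(got), 1] - p[1])^2 +
                 (pts[seq_len(got), 2] - p[2])^2)
      if (min(dd) < min_spacing) next
    }
    got <- got + 1L
    pts[got, ] <- p
    if (got == n) return(pts)
  }
  stop("infeasible placement: too many cells for the domain at the ",
       "minimum spacing")
}

# calibrate the consumption coefficient so that a hypothetical fully active
# tissue (every cell consuming) would sit at the target steady-state mean
# concentration (the <ci> = 0.5 operating point of the clock calibration)
calibrate_consumption <- function(tissue, field, target) {
  if (!any(field$source) || is.null(target)) return(0)
  mean_at <- function(k) mean_concentration(
    tissue, steady_state(tissue, field, consumption = k))
  lo <- 0; hi <- 1
  while (mean_at(hi) > target && hi < 2^20) hi <- hi * 2
  if (mean_at(hi) > target) return(hi)
  for (it in 1:50) {
    mid <- (lo + hi) / 2
    if (mean_at(mid) > target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Initialise a simulation
#'
#' Seeds the random generators, scatters the cells in the domain, tags the
#' cancer cells (nearest the duct by default), solves the initial glucose
#' steady state after calibrating the consumption coefficient to the mean
#' concentration 0.5 operating point, and integrates the shared
#' regulatory-network trajectories over the whole horizon.
#'
#' @param cfg a [sim_config()].
#' @return a `sim_state`.
#' @export
init_simulation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  domain <- build_domain(cfg)
  a0 <- domain$area / cfg$n_cells
  pts <- sample_points(cfg$n_cells, domain,
                       cfg$min_spacing_frac * sqrt(a0))
  lineage <- rep("healthy", cfg$n_cells)
  if (cfg$n_cancer > 0) {
    dd <- if (cfg$seeding == "near_duct") dist_to_duct(pts, domain)
          else stats::runif(cfg$n_cells)
    lineage[order(dd)[seq_len(cfg$n_cancer)]] <- "cancer"
  }
  tissue <- make_tissue(pts, domain, A0 = a0, lineage = lineage)
  field <- glucose_field(tissue, D = cfg$glucose$D)
  kappa <- calibrate_consumption(tissue, field, cfg$glucose$target_mean)
  if (any(field$source)) # nobody is cycling yet: uptake-free steady state
    field <- steady_state(tissue, field)
  tissue$cells$ci <- field$c

  delays <- delay_config(cfg$delays$tau1_years, cfg$delays$tau2_years)
  driver <- cytokine_driver(cfg$driver$u, cfg$driver$v, cfg$driver$T0)
  horizon <- cfg$total_cycles + 1
  stride <- max(1L, round(0.01 / cfg$grn$dt))
  grn <- list(sample_dt = cfg$grn$dt * stride)
  grn$healthy <- integrate_grn("healthy", t_end = horizon,
                               delays = delays, driver = driver,
                               history = "none", dt = cfg$grn$dt,
                               stride = stride)$samples
  if (cfg$n_cancer > 0)
    grn$cancer <- integrate_grn("cancer", t_end = horizon,
                                delays = delays, driver = driver,
                                history = cfg$grn$history, dt = cfg$grn$dt,
                                stride = stride)$samples
  state <- list(config = cfg, tissue = tissue, field = field,
                kappa = kappa, grn = grn, delays = delays,
                driver = driver,
                mech = do.call(mech_params, cfg$mech),
                clock = do.call(clock_params, cfg$clock),
                a0_basal = a0, time = 0,
                series = NULL, events = NULL)
  class(state) <- "sim_state"
  state
}

# phenotype read-out from the shared trajectories at time t
grn_phenotype <- function(state, variant, column, t) {
  traj <- state$grn[[variant]]
  if (is.null(traj)) return(0)
  k <- min(nrow(traj), max(1L, round(t / state$grn$sample_dt) + 1L))
  traj[[column]][k]
}

#' Run a simulation
#'
#' Executes the half-cycle loop for `cycles` basal cycles (default: the
#' configured horizon). Pass a `sim_config` to initialise and run, or an
#' existing `sim_state` to continue it.
#'
#' @param x a [sim_config()] or `sim_state`.
#' @param cycles number of basal cycles to simulate.
#' @return a `sim_state` with `$series` (one row per check: time, cell
#'   counts, events, inflammation index and label, stage, mean glucose) and
#'   `$events` (division/death log).
#' @export
run_simulation <- function(x, cycles = NULL) {
  state <- if (inherits(x, "sim_config")) init_simulation(x) else x
  stopifnot(inherits(state, "sim_state"))
  cfg <- state$config
  if (is.null(cycles)) cycles <- cfg$total_cycles
  if (cycles == 0) return(state)
  n_checks <- round(2 * cycles)
  T0 <- state$clock$T0
  half <- T0 / 2
  for (chk in seq_len(n_checks)) {
    first <- state$time == 0
    t_next <- state$time + half
    # common random numbers: the stream at a given check depends only on
    # (seed, model time), so matched-seed scenario runs stay coupled no
    # matter how many draws earlier checks consumed
    set.seed((cfg$seed * 131071L +
                as.integer(round(2 * t_next))) %% 2147483647L)
    # (1) mechanical relaxation
    state$tissue <- relax(state$tissue, state$mech,
                          duration = if (first) cfg$init_relax_window
                                     else cfg$relax_window)
    # (2) glucose transport to steady state; uptake follows the
    # proliferation-competent cells (phenotype gate open)
    cl <- state$tissue$cells
    z2 <- grn_phenotype(state, "healthy", "z_z2", t_next)
    z4 <- grn_phenotype(state, "cancer", "z_z4", t_next)
    gate_ok <- if (cfg$gate) ifelse(cl$lineage == "cancer", z4 > 0.5,
                                    z2 > 0.5)
               else rep(TRUE, nrow(cl))
    # cycling = phenotype gate open and room to divide; quiescent cells
    # consume at the basal (maintenance) fraction of the full uptake
    room_ok <- state$tissue$geom$area >= cfg$space_gate * state$a0_basal
    cycling <- gate_ok & room_ok
    bf <- cfg$glucose$basal_frac
    state$field <- glucose_field(state$tissue, conc = cl$ci,
                                 D = cfg$glucose$D)
    if (any(state$field$source))
      state$field <- steady_state(state$tissue, state$field,
                                  consumption =
                                    state$kappa * (bf + (1 - bf) * cycling))
    state$tissue$cells$ci <- state$field$c
    # (3) clocks, ages, preferred-area regrowth
    cl <- state$tissue$cells
    cl$Ti <- advance_clock(cl$Ti, half, cl$ci, state$clock)
    cl$age <- cl$age + half
    shrink <- exp(-half / state$clock$t_grow)
    cl$A0 <- state$a0_basal + (cl$A0 - state$a0_basal) * shrink
    state$tissue$cells <- cl
    # (4) fate checks; a gate-blocked completed cycle re-arms the clock.
    # Division also needs room: contact inhibition blocks cells compressed
    # below space_gate x basal area (no space for two daughters).
    fate <- decide_fate(cl$Ti, state$clock, age = cl$age)
    blocked <- fate == "divide" & !(gate_ok & room_ok)
    if (any(blocked)) {
      cl$Ti[blocked] <- pmax(0, cl$Ti[blocked] - state$clock$T0)
      state$tissue$cells <- cl
      fate[blocked] <- "none"
    }
    died <- cl$id[fate == "die"]
    if (length(died) >= nrow(cl)) # keep the tissue alive
      died <- died[-length(died)]
    divided <- cl$id[fate == "divide"]
    done_div <- integer(0)
    ev <- NULL
    if (length(died)) {
      keep <- !(state$tissue$cells$id %in% died)
      state$tissue$cells <- state$tissue$cells[keep, ]
      rownames(state$tissue$cells) <- NULL
      state$tissue <- retessellate(state$tissue)
      ev <- data.frame(time = t_next, id = died, event = "die",
                       child1 = NA_integer_, child2 = NA_integer_)
    }
    area_by_id <- stats::setNames(state$tissue$geom$area,
                                  state$tissue$cells$id)
    for (id in divided) {
      # a cell wedged against a corner may have no room for the +/- R/2
      # daughter placement: the division is skipped and its cycle re-arms.
      # Placements are batched on the pre-division tessellation and the
      # tissue is re-tessellated once afterwards.
      tis2 <- tryCatch(divide_no_retess(state$tissue, id,
                                        cfg$offset_rule, cfg$kick_rule,
                                        area = area_by_id[[as.character(id)]]),
                       error = function(e) NULL)
      if (is.null(tis2)) {
        k <- which(state$tissue$cells$id == id)
        state$tissue$cells$Ti[k] <-
          max(0, state$tissue$cells$Ti[k] - state$clock$T0)
        next
      }
      state$tissue <- tis2
      done_div <- c(done_div, id)
      ds <- attr(state$tissue, "daughter_ids")
      ev <- rbind(ev, data.frame(time = t_next, id = id, event = "divide",
                                 child1 = ds[1], child2 = ds[2]))
    }
    if (length(done_div)) state$tissue <- retessellate(state$tissue)
    state$events <- rbind(state$events, ev)
    # (5) homeostasis: index and duct elongation
    idx <- as.numeric(inflammation_index(state$tissue))
    if (idx > cfg$homeo$A_up) {
      state$tissue <- elongate_duct(state$tissue, index = idx,
                                    A_up = cfg$homeo$A_up,
                                    eta = cfg$homeo$eta,
                                    cap = cfg$homeo$cap)
      idx <- as.numeric(inflammation_index(state$tissue))
    }
    # (6) settle after tissue events
    if (length(died) || length(done_div))
      state$tissue <- relax(state$tissue, state$mech,
                            duration = cfg$relax_window / 2)
    state$field <- glucose_field(state$tissue,
                                 conc = state$tissue$cells$ci,
                                 D = cfg$glucose$D)
    state$series <- rbind(state$series, data.frame(
      time = t_next, n_cells = nrow(state$tissue$cells),
      n_cancer = sum(state$tissue$cells$lineage == "cancer"),
      divisions = length(done_div), deaths = length(died),
      index = idx, label = classify_inflammation(idx),
      stage = stage_of(t_next, state$delays),
      mean_ci = mean_concentration(state$tissue, state$field)))
    state$time <- t_next
  }
  state
}
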