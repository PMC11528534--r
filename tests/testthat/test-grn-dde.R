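empty_lits <- data.frame(agent = integer(0), src = character(0),
                         sign = integer(0), delay = integer(0))

one_agent_net <- function(eps, lits = empty_lits, n = -6, m = -10) {
  hill_network(stats::setNames(eps, "a1"), lits, agents = "a1", n = n, m = m)
}

test_that("hill regulation term has the tabulated limits", {
  for (n in c(-10, -6, -1, 1, 6)) expect_equal(hill(1, n), 0.5)
  expect_equal(hill(c(0.1, 1, 7), 0), rep(0.5, 3)) # constitutive
  expect_equal(hill(2, -6), 64 / 65)
  expect_equal(hill(0, -6), 0) # activator off at zero input
  expect_equal(hill(0, 6), 1)  # repressor fully open at zero input
  expect_error(hill(-1, -6), "x >= 0")
})

test_that("cytokine oscillator conserves its invariant and period", {
  # centre (1,1) is stationary
  d0 <- cytokine_driver(u = 1, v = 1)
  d1 <- step_cytokines(d0, 0.01)
  expect_equal(c(d1$u, d1$v), c(1, 1), tolerance = 1e-12)
  # invariant drift over one period at the default step
  d <- cytokine_driver()
  H0 <- lv_invariant(d$u, d$v)
  dt <- 1e-3
  for (k in seq_len(round(1 / dt))) d <- step_cytokines(d, dt)
  expect_lt(abs(lv_invariant(d$u, d$v) - H0), 1e-6)
  # period equals T0 = 1 within 1%: measure upward crossings of u = 1
  d <- cytokine_driver()
  ts <- seq(0, 3, by = dt)
  us <- numeric(length(ts)); vs <- numeric(length(ts))
  us[1] <- d$u; vs[1] <- d$v
  for (k in 2:length(ts)) {
    d <- step_cytokines(d, dt)
    us[k] <- d$u; vs[k] <- d$v
  }
  cross <- which(us[-length(us)] <= 1 & us[-1] > 1 & vs[-length(us)] < 1)
  tc <- ts[cross] + dt * (1 - us[cross]) / (us[cross + 1] - us[cross])
  expect_gte(length(tc), 2)
  expect_equal(diff(tc)[1], 1, tolerance = 0.01)
  expect_error(step_cytokines(d, -1))
})

test_that("linear no-delay limit reproduces the closed form", {
  # single always-on input literal: dR/dt = a * hill(1, n) - R = a/2 - R
  a <- 3.7
  net <- one_agent_net(a, data.frame(agent = 1L, src = "x1", sign = 1L,
                                     delay = 0L))
  res <- dde_integrate(net, t_end = 2, dt = 1e-3, cytokines = c(1, 1),
                       frozen = TRUE, stride = 100)
  s <- res$samples
  closed <- a / 2 * (1 - exp(-s$time))
  expect_equal(s$R_a1, closed, tolerance = 1e-8)
})

test_that("single-activator steady state matches the fixed-point solution", {
  for (eps in c(0.4, 1, 2.5)) {
    net <- one_agent_net(eps, data.frame(agent = 1L, src = "x1", sign = 1L,
                                         delay = 0L))
    res <- dde_integrate(net, t_end = 40, dt = 5e-3, cytokines = c(1, 1),
                         frozen = TRUE, stride = 1e4)
    Rstar <- eps * 0.5
    zstar <- 1 / (1 + Rstar^(-10))
    expect_equal(res$final[3], Rstar, tolerance = 1e-6)
    expect_equal(res$final[4], zstar, tolerance = 1e-6)
  }
  # constitutive agent (no regulators) settles at z = 0.5
  net0 <- one_agent_net(1)
  res0 <- dde_integrate(net0, t_end = 40, dt = 5e-3, cytokines = c(1, 1),
                        frozen = TRUE, stride = 1e4)
  expect_equal(res0$final[4], 0.5, tolerance = 1e-8)
})

test_that("R-level vector field agrees with the compiled integrator", {
  net <- build_rhs("cancer")
  set.seed(7)
  R0 <- runif(12); z0 <- runif(12)
  u <- 1.3; v <- 0.8
  h <- c(runif(1), 0, 0, 0, 0, 0, runif(1), 0, 0, 0, 0, 0) # y1, c3 history
  d <- net$f(0, u, v, R0, z0, y1d = h[1], c3d = h[7])
  dt <- 1e-6
  res <- dde_integrate(net, t_end = dt, dt = dt, R0 = R0, z0 = z0,
                       cytokines = c(u, v), frozen = TRUE,
                       tau1 = 5, tau2 = 5, history0 = h, stride = 1)
  num <- (res$final - c(u, v, R0, z0)) / dt
  expect_equal(num[3:14], d$dR, tolerance = 1e-4)
  expect_equal(num[15:26], d$dz, tolerance = 1e-4)
})

test_that("delay ablation matches the literal no-delay system to 1e-10", {
  params <- grn_parameters()
  net <- build_rhs("cancer", params)
  lits0 <- paninsim:::grn_literals("cancer")
  lits0$delay <- 0L
  net0 <- hill_network(params$epsilon, lits0, agents = paninsim:::GRN_AGENTS,
                       n = params$n, m = params$m, zscale = params$zscale)
  z0 <- rep(0.3, 12)
  a <- dde_integrate(net, t_end = 2, dt = 1e-3, z0 = z0,
                     driver = cytokine_driver(), tau1 = 0, tau2 = 0,
                     stride = 200)
  b <- dde_integrate(net0, t_end = 2, dt = 1e-3, z0 = z0,
                     driver = cytokine_driver(), stride = 200)
  expect_equal(a$final, b$final, tolerance = 1e-10)
})

test_that("solver shows fourth-order convergence on the full network", {
  endpoint <- function(dt) {
    integrate_grn("cancer", t_end = 1, dt = dt, history = "active",
                  stride = round(1 / dt))$final
  }
  y1 <- endpoint(0.02); y2 <- endpoint(0.01); y4 <- endpoint(0.005)
  e1 <- sqrt(sum((y1 - y2)^2)); e2 <- sqrt(sum((y2 - y4)^2))
  expect_gte(log2(e1 / e2), 3.5)
})

test_that("trajectories stay bounded by the rule structure", {
  res <- integrate_grn("cancer", t_end = 400, dt = 5e-3, history = "active",
                       stride = 500)
  s <- res$samples
  zcols <- paste0("z_", paninsim:::GRN_AGENTS)
  Rcols <- paste0("R_", paninsim:::GRN_AGENTS)
  expect_true(all(is.finite(as.matrix(s[, c(zcols, Rcols)]))))
  expect_true(all(s[, zcols] >= -1e-9 & s[, zcols] <= 1 + 1e-9))
  lits <- paninsim:::grn_literals("cancer")
  K <- table(factor(lits$agent, levels = paninsim:::GRN_AGENTS))
  eps <- paninsim:::GRN_EPSILON
  for (a in paninsim:::GRN_AGENTS)
    expect_true(all(s[[paste0("R_", a)]] <= as.numeric(K[[a]]) * eps[[a]] + 1e-9))
})

test_that("healthy variant keeps healthy proliferation above cancer's", {
  res <- integrate_grn("healthy", t_end = 100, dt = 2e-3, history = "none",
                       stride = 250)
  s <- res$samples
  # skip the start-up transient from the all-zero initial state (the
  # reference regime is the established oscillation)
  s <- s[s$time > 5, ]
  expect_true(all(s$z_z2 > s$z_z4))
})

test_that("stage labels follow the closed-boundary convention", {
  d <- delay_config()
  expect_equal(stage_of(d$tau1, d), "PanIN1")
  expect_equal(stage_of(d$tau1 + 1e-9, d), "PanIN2")
  expect_equal(stage_of(d$tau1 + d$tau2, d), "PanIN2")
  expect_equal(stage_of(d$tau1 + d$tau2 + 1, d), "post")
  expect_error(stage_of(-1, d), "negative")
  # labels partition the axis
  tt <- seq(0, 400, by = 0.5)
  lab <- stage_of(tt, d)
  expect_true(all(lab %in% c("PanIN1", "PanIN2", "post")))
  expect_false(is.unsorted(match(lab, c("PanIN1", "PanIN2", "post"))))
  # profile needs tau1 + tau2 of coverage
  short <- data.frame(time = 1:10, z_z1 = 0, z_z2 = 0, z_z3 = 0, z_z4 = 0)
  expect_error(phenotype_profile(short, d), "too short")
})

test_that("steep-Hill steady state encodes a Boolean fixed point", {
  att <- enumerate_attractors("cancer", c(1, 0), c(1, 1))
  fps <- att$attractors[lengths(att$codes) == 1]
  expect_gt(length(fps), 0)
  fp <- fps[[1]][1, ]
  res <- steep_limit_state(fp, "cancer", inputs = c(1, 0), delays = c(1, 1))
  expect_identical(unname(res$bits), unname(as.integer(fp)))
})
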