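test_that("clock calibration: one basal cycle per T0 at mean glucose", {
  p <- clock_params()
  expect_equal(advance_clock(0, dt = 1, ci = 0.5, p), 1)   # gamma = 16 law
  expect_equal(advance_clock(3, dt = 1, ci = 0, p), 3)     # no glucose
  expect_equal(advance_clock(0, dt = 1, ci = 1, p), 2)     # linear-law value
  expect_error(advance_clock(0, dt = 1, ci = 1.2, p), "outside")
  # the saturating alternative satisfies the same calibration point
  ph <- clock_params(law = "hill")
  expect_equal(clock_rate(0.5, ph), 1)
  expect_true(all(diff(clock_rate(seq(0, 1, 0.05), ph)) >= 0))
})

test_that("fate thresholds follow the lambda_h = 0.15 rule strictly", {
  p <- clock_params()
  expect_equal(decide_fate(1.20, p), "divide")
  expect_equal(decide_fate(1.00, p), "none")
  expect_equal(decide_fate(0.80, p), "die")
  expect_equal(decide_fate(1.15, p), "none") # strict inequality
  expect_equal(decide_fate(0.85, p), "none")
  # young cells are exempt from the death rule until death_age
  expect_equal(decide_fate(0.5, p, age = 0.5), "none")
  expect_equal(decide_fate(0.5, p, age = 1.5), "none")
  expect_equal(decide_fate(0.5, p, age = 2), "die")
})

test_that("divide and die are mutually exclusive for any lambda_h > 0", {
  for (lh in c(0.05, 0.15, 0.5)) {
    p <- clock_params(lambda_h = lh)
    Ti <- seq(0, 3, by = 0.01)
    f <- decide_fate(Ti, p)
    expect_false(any((Ti - 1) > lh & (1 - Ti) > lh))
    expect_true(all(f %in% c("divide", "die", "none")))
  }
})

test_that("division conserves mass, momentum and splits the mother cell", {
  set.seed(21)
  dom <- tissue_domain_rect(4, 4, duct = "none")
  pts <- cbind(runif(9, 0.4, 3.6), runif(9, 0.4, 3.6))
  tis <- make_tissue(pts, dom)
  tis$cells$vx <- runif(9, -1, 1); tis$cells$vy <- runif(9, -1, 1)
  k <- 5
  mother <- tis$cells[k, ]
  mom_before <- c(mother$mass * mother$vx, mother$mass * mother$vy)
  t2 <- divide_cell(tis, id = mother$id)
  ids <- attr(t2, "daughter_ids")
  d <- t2$cells[t2$cells$id %in% ids, ]
  expect_equal(nrow(t2$cells), 10)
  expect_equal(sum(d$mass), mother$mass)                       # mass
  mom_after <- c(sum(d$mass * d$vx), sum(d$mass * d$vy))
  expect_equal(mom_after, mom_before, tolerance = 1e-12)       # momentum
  expect_equal(d$A0, rep(mother$A0 / 2, 2))                    # demand split
  expect_equal(d$ci, rep(mother$ci, 2))                        # concentration
  expect_equal(d$Ti, c(0, 0))
  expect_equal(d$lineage, rep(mother$lineage, 2))
  # daughters sit at +/- R/2 from the mother centre
  off <- sqrt((d$x - mother$x)^2 + (d$y - mother$y)^2)
  A <- tis$geom$area[k]
  expect_equal(off, rep(sqrt(A / pi) / 2, 2), tolerance = 1e-12)
  # partition: total area is unchanged by the event
  expect_equal(sum(t2$geom$area), dom$area, tolerance = 1e-9)
})

test_that("an isolated mother's daughters inherit her area", {
  dom <- tissue_domain_rect(6, 6, duct = "none")
  tis <- make_tissue(rbind(c(3, 3), c(0.6, 0.6), c(5.4, 0.6), c(0.6, 5.4),
                           c(5.4, 5.4)), dom)
  A_mother <- tis$geom$area[1]
  set.seed(2)
  t2 <- divide_cell(tis, id = 1)
  ids <- attr(t2, "daughter_ids")
  dA <- sum(t2$geom$area[t2$cells$id %in% ids])
  # daughters absorb (nearly all of) the mother's region; corner cells only
  # trade area along the far bisectors
  expect_equal(dA, A_mother, tolerance = 0.05 * A_mother)
  expect_equal(sum(t2$geom$area), dom$area, tolerance = 1e-9)
})

test_that("kill removes exactly one generator and keeps the partition", {
  tis <- make_fixture("random", seed = 31, n = 30)
  dom_area <- tis$domain$area
  victim <- tis$cells$id[12]
  before <- tis$geom$polygons
  nb <- with(tis$geom$edges, unique(c(j[i == 12], i[j == 12])))
  t2 <- kill_cell(tis, victim)
  expect_equal(nrow(t2$cells), 29)
  expect_false(victim %in% t2$cells$id)
  expect_equal(sum(t2$geom$area), dom_area, tolerance = 1e-9)
  # locality: exactly the neighbours' polygons change
  changed <- integer(0)
  for (kk in seq_len(nrow(t2$cells))) {
    old_k <- if (kk < 12) kk else kk + 1L
    same <- isTRUE(all.equal(before[[old_k]], t2$geom$polygons[[kk]],
                             tolerance = 1e-12))
    if (!same) changed <- c(changed, old_k)
  }
  expect_setequal(changed, nb)
  # removing the last cell is refused
  one <- make_tissue(rbind(c(0.5, 0.5)), tissue_domain_rect(1, 1, "none"))
  expect_error(kill_cell(one, 1), "last cell")
})
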