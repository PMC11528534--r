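test_that("tabulated rule examples evaluate correctly", {
  # RAS is an OR gate over TNFa, PIP3, ERK, PIP3c and its delayed copy
  expect_equal(eval_agent("y1", bool_state(x1 = 1)), 1L)
  expect_equal(eval_agent("y1", bool_state()), 0L)
  # healthy variant drops the c3 literal from RAS
  expect_equal(eval_agent("y1", bool_state(c3 = 1), "cancer"), 1L)
  expect_equal(eval_agent("y1", bool_state(c3 = 1), "healthy"), 0L)
  # P53: (y1) & (-y2) & (-y3)
  expect_equal(eval_agent("y2", bool_state(y1 = 1)), 1L)
  expect_equal(eval_agent("y2", bool_state(y1 = 1, y3 = 1)), 0L)
  # P53c on the all-zero state: !(0|0) & (!0|0) = 1
  expect_equal(eval_agent("c2", bool_state()), 1L)
  # cancer proliferation needs both delayed literals and no P21
  expect_equal(eval_agent("z4", bool_state(y1d = 1, c3d = 1)), 1L)
  expect_equal(eval_agent("z4", bool_state(y1d = 1, c3d = 1, c4 = 1)), 0L)
  # inputs have no rule
  expect_error(eval_agent("x1", bool_state()), "exogenous")
  expect_error(eval_agent("foo", bool_state()), "unknown")
})

test_that("synchronous update works on the old state and is deterministic", {
  s0 <- bool_state()
  s1 <- step_sync(s0)
  # from all-zero only P53c fires; everything else stays off
  expect_equal(unname(s1[["c2"]]), 1L)
  off <- setdiff(paninsim:::GRN_AGENTS, "c2")
  expect_true(all(unlist(s1[off]) == 0L))
  # inputs and delayed bits pass through
  s <- bool_state(x1 = 1, y1d = 1, c3d = 1)
  s2 <- step_sync(s)
  expect_equal(unname(s2[["x1"]]), 1L)
  expect_equal(unname(s2[["y1d"]]), 1L)
  # successor carries cancer proliferation per the delayed AND rule
  expect_equal(unname(s2[["z4"]]), 1L)
  # purity: same input gives the same output
  expect_identical(step_sync(s), s2)
})

test_that("eval_agent and step_sync agree with the vectorized table", {
  set.seed(42)
  for (variant in c("cancer", "healthy")) {
    succ <- paninsim:::grn_transition_table(variant, c(1, 0), c(0, 1))
    for (code in sample(0:4095, 25)) {
      bits <- paninsim:::grn_decode(code)
      s <- do.call(bool_state, c(as.list(bits),
                                 list(x1 = 1, x2 = 0, y1d = 0, c3d = 1)))
      nxt <- step_sync(s, variant)
      nxt_code <- sum(unlist(nxt[paninsim:::GRN_AGENTS]) *
                        2^(0:11))
      expect_identical(as.integer(nxt_code), succ[code + 1])
    }
  }
})

test_that("attractor enumeration partitions all 4096 states", {
  res <- enumerate_attractors("cancer", c(0, 0), c(0, 0))
  expect_equal(sum(res$basin_sizes), 4096)
  expect_true(all(res$membership >= 1))
  # each state appears in at most one attractor
  all_states <- unlist(res$codes)
  expect_equal(anyDuplicated(all_states), 0L)
  # attractor states are actual cycles of the map
  succ <- paninsim:::grn_transition_table("cancer", c(0, 0), c(0, 0))
  for (cyc in res$codes)
    expect_setequal(succ[cyc + 1L], cyc)
})

test_that("attractors match the independent brute-force oracle", {
  # spot combination here; the exhaustive sweep lives in the acceptance suite
  res <- enumerate_attractors("cancer", c(0, 0), c(0, 0))
  succ <- oracle_transition_table("cancer", c(0, 0), c(0, 0))
  expect_identical(canon_cycles(res$codes), canon_cycles(oracle_attractors(succ)))
})

test_that("network serialization is complete and diffable", {
  js <- jsonlite::fromJSON(grn_network_json("cancer"))
  expect_equal(length(js$agents$name), 12)
  expect_equal(js$hill_exponents$n, -6)
  expect_equal(js$agents$epsilon[js$agents$name == "y2"], 1 / 2.2)
  hl <- jsonlite::fromJSON(grn_network_json("healthy"))
  expect_false(grepl("c3", hl$agents$rule[hl$agents$name == "y1"]))
  expect_true(grepl("c3", js$agents$rule[js$agents$name == "y1"]))
})
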