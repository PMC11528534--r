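#' @useDynLib paninsim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Regulated agents in table order; x1 (TNFa) and x2 (TGFb1) are exogenous
# inputs and carry no update rule. y1d and c3d are the delayed copies
# y1(t - tau1) and c3(t - tau2).
GRN_AGENTS <- c("y1", "y2", "y3", "y4", "c1", "c2", "c3", "c4",
                "z1", "z2", "z3", "z4")
GRN_INPUTS <- c("x1", "x2")
GRN_DELAYED <- c("y1d", "c3d")

GRN_AGENT_LABELS <- c(
  y1 = "RAS", y2 = "P53", y3 = "PIP3", y4 = "ERK",
  c1 = "BCL-XL", c2 = "P53c", c3 = "PIP3c", c4 = "P21",
  z1 = "healthy apoptosis", z2 = "healthy proliferation",
  z3 = "cancer apoptosis", z4 = "cancer proliferation")

GRN_EPSILON <- c(
  y1 = 1 / 0.3, y2 = 1 / 2.2, y3 = 1, y4 = 1 / 0.3,
  c1 = 1 / 1.25, c2 = 1 / 1.4, c3 = 1, c4 = 1 / 0.2,
  z1 = 1, z2 = 1, z3 = 1 / 0.68, z4 = 1 / 1.14)

#' Boolean rule strings
#'
#' The regulation formulas in the source table's syntax (`||` OR, `&` AND,
#' `-` NOT), named by agent. Used for serialization and as input to
#' independent rule evaluators; the package's own evaluation is hard-coded.
#'
#' @param variant `"cancer"` or `"healthy"`.
#' @export
grn_rule_strings <- function(variant = c("cancer", "healthy")) {
  variant <- match.arg(variant)
  r <- c(
    y1 = "(x1||y3||y4||c3||y1d)",
    y2 = "(y1)&(-y2)&(-y3)",
    y3 = "(y4)&(-y2)",
    y4 = "(x2||y1)",
    c1 = "(c3||y1d)&(-c2)",
    c2 = "-(c2||c3)&(-c3||c4)",
    c3 = "(-c2)&(y1d)",
    c4 = "(x2||c2)",
    z1 = "(y2)",
    z2 = "(y3)",
    z3 = "(-c3)&(-c1||c2)&(z3)",
    z4 = "(y1d)&(c3d)&(-c4)")
  if (variant == "healthy") r[["y1"]] <- "(x1||y3||y4||y1d)"
  r
}

#' Construct a Boolean network state
#'
#' A state holds one bit per regulated agent plus the two exogenous inputs
#' and the two delayed copies `y1d = y1(t - tau1)` and `c3d = c3(t - tau2)`,
#' which are supplied externally (they reference past states).
#'
#' @param ... named bits among `y1,y2,y3,y4,c1,c2,c3,c4,z1,z2,z3,z4`,
#'   inputs `x1,x2` and delayed bits `y1d,c3d`; unnamed fields default to 0.
#' @return named integer vector of 16 bits, class `bool_state`.
#' @examples
#' s <- bool_state(x1 = 1)
#' eval_agent("y1", s) # RAS activates on TNFa
#' @export
bool_state <- function(...) {
  fields <- c(GRN_INPUTS, GRN_AGENTS, GRN_DELAYED)
  s <- stats::setNames(integer(length(fields)), fields)
  args <- list(...)
  if (length(args)) {
    nm <- names(args)
    if (is.null(nm) || any(nm == ""))
      stop("all arguments to bool_state() must be named")
    bad <- setdiff(nm, fields)
    if (length(bad)) stop("unknown state fields: ", paste(bad, collapse = ", "))
    vals <- unlist(args)
    if (!all(vals %in% c(0, 1))) stop("state bits must be 0 or 1")
    s[nm] <- as.integer(vals)
  }
  class(s) <- "bool_state"
  s
}

#' Evaluate one agent's Boolean update rule
#'
#' Truth value of the agent's regulation formula on the supplied state.
#' In the healthy network variant the `c3` literal is absent from the RAS
#' (`y1`) rule; everything else is shared between variants.
#'
#' @param agent one of the 12 regulated agent names (`x1`/`x2` have no rule).
#' @param state a [bool_state()] (or any named 0/1 vector with the 16 fields).
#' @param variant `"cancer"` or `"healthy"`.
#' @return 0 or 1.
#' @export
eval_agent <- function(agent, state, variant = c("cancer", "healthy")) {
  variant <- match.arg(variant)
  if (agent %in% GRN_INPUTS)
    stop("'", agent, "' is an exogenous input and has no update rule")
  if (!agent %in% GRN_AGENTS) stop("unknown agent: ", agent)
  b <- function(f) as.logical(state[[f]])
  val <- switch(agent,
    y1 = if (variant == "cancer")
           b("x1") || b("y3") || b("y4") || b("c3") || b("y1d")
         else
           b("x1") || b("y3") || b("y4") || b("y1d"),
    y2 = b("y1") && !b("y2") && !b("y3"),
    y3 = b("y4") && !b("y2"),
    y4 = b("x2") || b("y1"),
    c1 = (b("c3") || b("y1d")) && !b("c2"),
    c2 = !(b("c2") || b("c3")) && (!b("c3") || b("c4")),
    c3 = !b("c2") && b("y1d"),
    c4 = b("x2") || b("c2"),
    z1 = b("y2"),
    z2 = b("y3"),
    z3 = !b("c3") && (!b("c1") || b("c2")) && b("z3"),
    z4 = b("y1d") && b("c3d") && !b("c4"))
  as.integer(val)
}

#' Synchronous Boolean update
#'
#' Replaces every regulated agent by its rule evaluated on the *old* state;
#' inputs and delayed bits pass through unchanged.
#'
#' @inheritParams eval_agent
#' @return the successor `bool_state`.
#' @export
step_sync <- function(state, variant = c("cancer", "healthy")) {
  variant <- match.arg(variant)
  out <- state
  for (a in GRN_AGENTS) out[[a]] <- eval_agent(a, state, variant)
  out
}

# ---- vectorized transition table ------------------------------------------

# successor code (0..4095) for every state code, with frozen inputs/delays.
# bit k-1 of the code is agent GRN_AGENTS[k].
grn_transition_table <- function(variant = c("cancer", "healthy"),
                                 inputs = c(0, 0), delays = c(0, 0)) {
  variant <- match.arg(variant)
  idx <- 0:4095
  bit <- function(k) bitwAnd(bitwShiftR(idx, k - 1L), 1L) == 1L
  v <- lapply(seq_along(GRN_AGENTS), bit)
  names(v) <- GRN_AGENTS
  x1 <- as.logical(inputs[1]); x2 <- as.logical(inputs[2])
  y1d <- as.logical(delays[1]); c3d <- as.logical(delays[2])
  nw <- list(
    y1 = if (variant == "cancer") x1 | v$y3 | v$y4 | v$c3 | y1d
         else x1 | v$y3 | v$y4 | y1d,
    y2 = v$y1 & !v$y2 & !v$y3,
    y3 = v$y4 & !v$y2,
    y4 = x2 | v$y1,
    c1 = (v$c3 | y1d) & !v$c2,
    c2 = !(v$c2 | v$c3) & (!v$c3 | v$c4),
    c3 = !v$c2 & y1d,
    c4 = x2 | v$c2,
    z1 = v$y2,
    z2 = v$y3,
    z3 = !v$c3 & (!v$c1 | v$c2) & v$z3,
    z4 = y1d & c3d & !v$c4)
  succ <- integer(4096)
  for (k in seq_along(GRN_AGENTS))
    succ <- succ + as.integer(nw[[k]]) * bitwShiftL(1L, k - 1L)
  succ
}

# decode a state code into a named bit vector over GRN_AGENTS
grn_decode <- function(code) {
  vapply(seq_along(GRN_AGENTS),
         function(k) bitwAnd(bitwShiftR(as.integer(code), k - 1L), 1L),
         integer(1)) |> stats::setNames(GRN_AGENTS)
}

#' Enumerate the attractors of the synchronous Boolean dynamics
#'
#' Exhaustive enumeration over all 2^12 regulated states with the inputs and
#' the delayed bits held fixed (frozen-delay approximation). Fixed points are
#' returned as 1-cycles. Every state maps to exactly one attractor, so basin
#' sizes sum to 4096.
#'
#' @param variant `"cancer"` or `"healthy"`.
#' @param inputs bits `(x1, x2)`.
#' @param delays bits `(y1d, c3d)`.
#' @return list with `attractors` (list of integer matrices, one row per
#'   cycle state, columns = agents), `codes` (list of integer state codes),
#'   `basin_sizes`, and `membership` (attractor index for each state code
#'   0..4095).
#' @export
enumerate_attractors <- function(variant = c("cancer", "healthy"),
                                 inputs = c(0, 0), delays = c(0, 0)) {
  variant <- match.arg(variant)
  succ <- grn_transition_table(variant, inputs, delays) # 0-based codes
  f <- succ + 1L                                        # 1-based map
  land <- seq_len(4096)
  for (k in 1:12) land <- f[land] # succ applied 2^12 times: inside a cycle
  cyc_nodes <- sort(unique(land))
  assigned <- integer(4096) # attractor id per 1-based node, 0 = none
  cycles <- list()
  for (s in cyc_nodes) {
    if (assigned[s] > 0L) next
    cyc <- s
    cur <- f[s]
    while (cur != s) { cyc <- c(cyc, cur); cur <- f[cur] }
    cycles[[length(cycles) + 1L]] <- cyc
    assigned[cyc] <- length(cycles)
  }
  membership <- assigned[land]
  basin <- tabulate(membership, nbins = length(cycles))
  attractors <- lapply(cycles, function(cyc) {
    m <- t(vapply(cyc - 1L, grn_decode, integer(length(GRN_AGENTS))))
    rownames(m) <- NULL
    m
  })
  list(attractors = attractors,
       codes = lapply(cycles, function(cyc) cyc - 1L),
       basin_sizes = basin,
       membership = membership)
}

#' Serialize the regulatory network to JSON
#'
#' Emits agents, rule strings in the source table's syntax, regulation
#' strengths and Hill exponents, so the transcription can be diffed.
#'
#' @param variant `"cancer"` or `"healthy"`.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @export
grn_network_json <- function(variant = c("cancer", "healthy"), path = NULL) {
  variant <- match.arg(variant)
  doc <- list(
    variant = variant,
    inputs = as.list(stats::setNames(c("TNFa", "TGFb1"), GRN_INPUTS)),
    agents = lapply(GRN_AGENTS, function(a) list(
      name = a, label = unname(GRN_AGENT_LABELS[a]),
      rule = unname(grn_rule_strings(variant)[a]),
      epsilon = unname(GRN_EPSILON[a]))),
    hill_exponents = list(n = -6, m = -10),
    delayed = list(y1d = "y1(t - tau1)", c3d = "c3(t - tau2)"))
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
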