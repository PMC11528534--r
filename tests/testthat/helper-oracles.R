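# Independent Boolean transition-table oracle: parses the serialized rule
# strings (table syntax) into R expressions and evaluates them, a second
# implementation kept separate from the hand-coded rules in the package.
oracle_transition_table <- function(variant, inputs, delays) {
  rules <- paninsim::grn_rule_strings(variant)
  agents <- names(rules)
  exprs <- lapply(rules, function(r) {
    r <- gsub("||", "|", r, fixed = TRUE)
    r <- gsub("-", "!", r, fixed = TRUE)
    str2lang(r)
  })
  idx <- 0:4095
  env <- new.env()
  for (k in seq_along(agents))
    assign(agents[k], bitwAnd(bitwShiftR(idx, k - 1L), 1L) == 1L, envir = env)
  assign("x1", as.logical(inputs[1]), envir = env)
  assign("x2", as.logical(inputs[2]), envir = env)
  assign("y1d", as.logical(delays[1]), envir = env)
  assign("c3d", as.logical(delays[2]), envir = env)
  succ <- integer(4096)
  for (k in seq_along(agents)) {
    v <- eval(exprs[[k]], envir = env)
    succ <- succ + as.integer(v) * bitwShiftL(1L, k - 1L)
  }
  succ
}

# attractor decomposition of a 0-based successor table (independent of the
# package's doubling-based implementation: plain walk with colouring)
oracle_attractors <- function(succ) {
  f <- succ + 1L
  n <- length(f)
  colour <- integer(n) # 0 unvisited, -1 in progress stack, >0 attractor id
  cycles <- list()
  for (s0 in seq_len(n)) {
    if (colour[s0] != 0L) next
    path <- integer(0)
    s <- s0
    while (colour[s] == 0L) {
      colour[s] <- -1L
      path <- c(path, s)
      s <- f[s]
    }
    if (colour[s] == -1L) { # new cycle found within path
      start <- match(s, path)
      cyc <- path[start:length(path)]
      cycles[[length(cycles) + 1L]] <- cyc
      id <- length(cycles)
      colour[cyc] <- id
      if (start > 1) colour[path[1:(start - 1)]] <- id
    } else {
      colour[path] <- colour[s]
    }
  }
  lapply(cycles, function(cyc) sort(cyc - 1L))
}

# canonical form of a set of cycles for comparison
canon_cycles <- function(lst) {
  lst <- lapply(lst, function(x) sort(as.integer(x)))
  lst[order(vapply(lst, min, integer(1)))]
}
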