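# Tissue-level inflammation quantification and the duct-elongation
# anti-inflammatory mechanism.
#
# The inflammation index is the ratio of demanded to realized cell area,
# sum(A0_i) / sum(A_i): above 1 the cells are on average compressed below
# their preferred size (inflamed), below 1 they have room to migrate
# (relaxed). When the index exceeds the elongation threshold A_up the duct
# grows along its axis, adding realizable area and relieving the stress.

#' Tissue inflammation index
#'
#' `sum(A0_i) / sum(A_i)`: total preferred (demanded) area over total
#' realized Voronoi area. Equals 1 when every cell realizes its preferred
#' area; `> 1` under compression. The per-cell ratios `A0_i / A_i` are
#' returned as an attribute for rendering.
#'
#' @param tissue a `tissue_state`.
#' @export
inflammation_index <- function(tissue) {
  if (nrow(tissue$cells) == 0) stop("empty tissue")
  idx <- sum(tissue$cells$A0) / sum(tissue$geom$area)
  attr(idx, "per_cell") <- tissue$cells$A0 / tissue$geom$area
  idx
}

#' Classify an inflammation index
#'
#' Reporting bins: relaxed `< 1`, soft `[1, 1.15)`, moderate `[1.15, 1.35)`,
#' severe `>= 1.35`. The labels are monotone in the index.
#'
#' @param index positive inflammation index (vectorized).
#' @param breaks the three bin edges.
#' @export
classify_inflammation <- function(index, breaks = c(1, 1.15, 1.35)) {
  stopifnot(all(index > 0), length(breaks) == 3, !is.unsorted(breaks))
  labs <- c("relaxed", "soft", "moderate", "severe")
  labs[findInterval(as.numeric(index), breaks) + 1]
}

#' Duct elongation (anti-inflammatory relief)
#'
#' If the index exceeds the threshold `A_up`, the domain boundary is
#' extended along the duct axis by `dL = eta (index - A_up) L0` with `L0`
#' the *original* duct length (a fixed relief scale: tying it to the
#' current length makes domain growth self-amplifying); the cell generators
#' are unmoved, so the recomputed index strictly decreases. Below the
#' threshold the tissue is returned unchanged. Repeated application
#' converges to an index at or below `A_up` on a static tissue.
#'
#' @param tissue a `tissue_state`.
#' @param index current inflammation index (recomputed when `NULL`).
#' @param A_up elongation threshold (default 1.1).
#' @param eta relief gain (default 0.1).
#' @param cap saturation of the growth response: at most `cap * L0` of
#'   elongation per application (tissue growth rate is bounded no matter
#'   how inflamed the duct is). `Inf` disables.
#' @export
elongate_duct <- function(tissue, index = NULL, A_up = 1.1, eta = 0.1,
                          cap = Inf) {
  stopifnot(A_up > 0, eta > 0, cap > 0)
  if (is.null(index)) index <- inflammation_index(tissue)
  if (index <= A_up) return(tissue)
  L0 <- tissue$domain$duct_length0 %||% tissue$domain$duct_length
  dL <- min(eta * (index - A_up), cap) * L0
  tissue$domain <- elongate_domain(tissue$domain, dL)
  tissue$domain$duct_length0 <- L0
  retessellate(tissue)
}

#' Inflammation time series of a run
#'
#' Extracts the per-check-interval index values from one or more run logs
#' and stacks them for overlaying scenarios.
#'
#' @param ... run results from [run_simulation()] (or their `series`
#'   data.frames), optionally named by scenario.
#' @return data.frame `time, index, label, scenario`.
#' @export
inflammation_series <- function(...) {
  runs <- list(...)
  if (length(runs) == 0) stop("empty log")
  nm <- names(runs)
  if (is.null(nm)) nm <- rep("", length(runs))
  out <- lapply(seq_along(runs), function(k) {
    r <- runs[[k]]
    s <- if (is.data.frame(r)) r else r$series
    if (is.null(s) || nrow(s) == 0) stop("empty log")
    scen <- if (nzchar(nm[k])) nm[k]
            else if (!is.data.frame(r) && !is.null(r$config))
              paste0("n_cancer=", r$config$n_cancer)
            else as.character(k)
    data.frame(time = s$time, index = s$index,
               label = classify_inflammation(s$index),
               scenario = scen, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
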