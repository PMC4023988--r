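#' Configure a planted-partition bipartite scenario
#'
#' Three benchmark designs with known community structure. All of them fix
#' the degree of every mode-1 node at `d = round(density * n2)` and send each
#' tie inside the node's designated mode-2 region with probability
#' `p_within`, otherwise outside it:
#'
#' * `equal_3_3` — three equal communities in both modes; mode-1 third s ties
#'   within mode-2 third s.
#' * `unequal_3_2` — mode 1 is split into three equal subsections tying,
#'   respectively, within the first half, the middle third and the second
#'   half of mode 2. The overlap makes the best non-overlapping description
#'   three mode-1 communities but only two mode-2 communities (the halves).
#' * `unequal_2_10` — mode 1 is split into twenty equal subsections: odd
#'   subsections anchor to one mode-2 tenth each, even subsections bridge two
#'   consecutive tenths with a region of `n2/30` nodes straddling their
#'   boundary. No
#'   bridge spans the boundary between the 5th and 6th tenths (subsections 10
#'   and 20 anchor to tenths 5 and 10 instead), so the planted structure is
#'   two mode-1 communities (the halves of mode 1) and ten mode-2 communities
#'   (the tenths).
#'
#' @param scenario `"equal_3_3"`, `"unequal_3_2"` or `"unequal_2_10"`.
#' @param size convenience preset: `"small"` (60 x 120, density 0.125) or
#'   `"large"` (600 x 1200; density 0.025 for the three-subsection scenarios,
#'   0.125 for `unequal_2_10`). Ignored when `n1`, `n2` and `density` are all
#'   supplied. The `unequal_2_10` large design keeps the small design's
#'   density because at 0.025 the planted ten-community structure is no
#'   longer the modularity optimum of the mode-2 projection (the narrow
#'   bridge windows out-weigh the tenths), i.e. the benchmark would not plant
#'   the structure it claims to plant; at 0.125 every designated region
#'   saturates and the planted tenths are cleanly recoverable.
#' @param n1,n2 mode sizes; `n1` must be divisible by 3 (scenarios with three
#'   subsections) or 20 (`unequal_2_10`), `n2` by 6 or 30 respectively.
#' @param density overall edge density; the fixed mode-1 degree is
#'   `round(density * n2)`.
#' @param p_within probability that a tie falls inside its designated region;
#'   default 0.9.
#' @param seed RNG seed used by [generate_bipartite()]; `NULL` leaves the
#'   global RNG state untouched.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(scenario = c("equal_3_3", "unequal_3_2", "unequal_2_10"),
                            size = c("small", "large"),
                            n1 = NULL, n2 = NULL, density = NULL,
                            p_within = 0.9, seed = NULL) {
  scenario <- match.arg(scenario)
  if (is.null(n1) || is.null(n2) || is.null(density)) {
    size <- match.arg(size)
    if (is.null(n1)) n1 <- if (size == "small") 60L else 600L
    if (is.null(n2)) n2 <- if (size == "small") 120L else 1200L
    if (is.null(density)) {
      density <- if (size == "small" || scenario == "unequal_2_10") 0.125 else 0.025
    }
  }
  n1 <- as.integer(n1)
  n2 <- as.integer(n2)
  div1 <- if (scenario == "unequal_2_10") 20L else 3L
  div2 <- if (scenario == "unequal_2_10") 30L else 6L
  if (n1 %% div1 != 0L) {
    stop(sprintf("n1 must be divisible by %d for scenario %s", div1, scenario))
  }
  if (n2 %% div2 != 0L) {
    stop(sprintf("n2 must be divisible by %d for scenario %s", div2, scenario))
  }
  if (!(density > 0 && density <= 1)) stop("density must be in (0, 1]")
  if (p_within < 0 || p_within > 1) stop("p_within must be in [0, 1]")
  d <- as.integer(round(density * n2))
  if (d < 1L || d > n2 - 1L) {
    stop("fixed mode-1 degree round(density * n2) must be in [1, n2 - 1]")
  }
  structure(list(scenario = scenario, n1 = n1, n2 = n2, density = density,
                 p_within = p_within, seed = seed, d = d),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("Scenario %s: %d x %d, density %g (mode-1 degree %d), p_within %g\n",
              x$scenario, x$n1, x$n2, x$density, x$d, x$p_within))
  invisible(x)
}

#' Designated regions and planted labels of a scenario
#'
#' Lays out the scenario's design: which mode-2 region each mode-1 subsection
#' ties into, and the planted (ground-truth) community labels of both modes.
#'
#' @param config a `scenario_config`.
#' @return A list with `subsection` (subsection index of each mode-1 node),
#'   `regions` (per subsection, the integer vector of designated mode-2
#'   nodes), `labels1` and `labels2` (planted partitions of the two modes).
#' @export
scenario_regions <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  n1 <- config$n1
  n2 <- config$n2
  if (config$scenario == "unequal_2_10") {
    ns <- 20L
    tenth <- function(t) ((t - 1L) * n2 %/% 10L + 1L):(t * n2 %/% 10L)
    w <- n2 %/% 30L
    regions <- lapply(seq_len(ns), function(s) {
      if (s %% 2L == 1L) {
        tenth((s + 1L) %/% 2L)
      } else if (s == 10L) {
        tenth(5L)                      # no bridge across the 5-6 boundary
      } else if (s == 20L) {
        tenth(10L)                     # there is no 11th tenth to bridge to
      } else {
        b <- s %/% 2L                  # boundary between tenths b and b+1
        left <- w %/% 2L
        (b * n2 %/% 10L - left + 1L):(b * n2 %/% 10L + (w - left))
      }
    })
    labels1 <- partition(rep(c(1L, 2L), each = n1 %/% 2L))
    labels2 <- partition(rep(seq_len(10L), each = n2 %/% 10L))
  } else {
    ns <- 3L
    regions <- if (config$scenario == "equal_3_3") {
      lapply(1:3, function(s) ((s - 1L) * n2 %/% 3L + 1L):(s * n2 %/% 3L))
    } else {
      list(1L:(n2 %/% 2L),
           (n2 %/% 3L + 1L):(2L * n2 %/% 3L),
           (n2 %/% 2L + 1L):n2)
    }
    labels1 <- partition(rep(1:3, each = n1 %/% 3L))
    labels2 <- if (config$scenario == "equal_3_3") {
      partition(rep(1:3, each = n2 %/% 3L))
    } else {
      partition(rep(1:2, each = n2 %/% 2L))
    }
  }
  list(subsection = rep(seq_len(ns), each = n1 %/% ns),
       regions = regions, labels1 = labels1, labels2 = labels2)
}

#' Generate a planted-partition bipartite graph
#'
#' Draws one realization of the configured scenario. Every mode-1 node
#' receives exactly `d = round(density * n2)` distinct ties: a
#' `Binomial(d, p_within)` number of them are sampled uniformly without
#' replacement inside the node's designated mode-2 region, the rest uniformly
#' outside it, so the realized overall density is exactly `density` while
#' mode-2 degrees are left free. If the within draw exceeds the region size
#' (possible when `d` is larger than a small designated region), the excess
#' ties spill uniformly outside and a condition of class `bicomm_spill` is
#' signalled.
#'
#' @param config a `scenario_config`; `config$seed`, when non-`NULL`, seeds
#'   the RNG so the realization is reproducible.
#' @return A list with `graph` (the `bipartite_graph`), `truth` (list of
#'   planted `labels1`, `labels2`) and `config`.
#' @examples
#' cfg <- scenario_config("equal_3_3", "small", seed = 1)
#' r <- generate_bipartite(cfg)
#' r$graph
#' @export
generate_bipartite <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  if (!is.null(config$seed)) set.seed(as.integer(config$seed))
  layout <- scenario_regions(config)
  n1 <- config$n1
  n2 <- config$n2
  d <- config$d
  outside <- lapply(layout$regions, function(r) seq_len(n2)[-r])
  n_in <- stats::rbinom(n1, d, config$p_within)
  spilled <- 0L
  ei <- vector("list", n1)
  for (i in seq_len(n1)) {
    s <- layout$subsection[i]
    region <- layout$regions[[s]]
    out <- outside[[s]]
    k_in <- n_in[i]
    if (k_in > length(region)) {
      spilled <- spilled + (k_in - length(region))
      k_in <- length(region)
    }
    k_out <- d - k_in
    if (k_out > length(out)) {      # outside saturated: excess goes within
      k_in <- k_in + (k_out - length(out))
      k_out <- length(out)
    }
    targets <- c(if (k_in > 0L) region[sample.int(length(region), k_in)],
                 if (k_out > 0L) out[sample.int(length(out), k_out)])
    ei[[i]] <- cbind(i, targets)
  }
  if (spilled > 0L) {
    warning(structure(
      class = c("bicomm_spill", "warning", "condition"),
      list(message = sprintf(
             "%d within-region ties spilled outside saturated regions (scenario %s)",
             spilled, config$scenario),
           call = sys.call())))
  }
  graph <- bipartite_graph(do.call(rbind, ei), n1, n2)
  list(graph = graph,
       truth = list(labels1 = layout$labels1, labels2 = layout$labels2),
       config = config)
}
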