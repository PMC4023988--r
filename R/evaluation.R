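#' Normalized mutual information between two partitions
#'
#' `NMI = I(a; b) / sqrt(H(a) * H(b))` with natural-log entropies computed
#' from the joint label contingency table (the sqrt-normalized form of
#' Strehl and Ghosh). 1 means the partitions are identical up to label
#' permutation, 0 that they are independent. Degenerate cases: if both
#' partitions are a single community they are identical, so NMI is 1; if
#' exactly one has zero entropy, NMI is 0.
#'
#' @param a,b partitions (label vectors) over the same nodes.
#' @return NMI in `[0, 1]`.
#' @examples
#' nmi(c(1, 1, 2, 2), c(2, 2, 1, 1))  # 1: same grouping
#' nmi(c(1, 1, 2, 2), c(1, 1, 1, 1))  # 0: one side is uninformative
#' @export
nmi <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must cover the same nodes")
  a <- partition(a)
  b <- partition(b)
  n <- length(a)
  joint <- table(a, b) / n
  pa <- rowSums(joint)
  pb <- colSums(joint)
  Ha <- -sum(pa * log(pa), na.rm = TRUE)
  Hb <- -sum(pb * log(pb), na.rm = TRUE)
  if (Ha <= 0 && Hb <= 0) return(1)
  if (Ha <= 0 || Hb <= 0) return(0)
  nz <- joint > 0
  I <- sum(joint[nz] * log(joint[nz] / outer(pa, pb)[nz]))
  min(max(I / sqrt(Ha * Hb), 0), 1)
}

#' Score a joint partition against planted ground truth
#'
#' NMI is computed per mode between the planted labels and the recovered
#' per-mode partition, then combined as the node-count-weighted mean:
#' `(n1 * NMI_1 + n2 * NMI_2) / (n1 + n2)`. This is well defined for both
#' detection strategies and for unequal community counts between the modes.
#'
#' @param truth list with `labels1`, `labels2` (e.g. from
#'   [generate_bipartite()]).
#' @param result a `joint_partition`.
#' @return Weighted NMI in `[0, 1]`.
#' @export
score_joint <- function(truth, result) {
  stopifnot(inherits(result, "joint_partition"))
  n1 <- length(result$partition1)
  n2 <- length(result$partition2)
  if (length(truth$labels1) != n1 || length(truth$labels2) != n2) {
    stop("ground truth does not cover the partitioned nodes")
  }
  (n1 * nmi(truth$labels1, result$partition1) +
   n2 * nmi(truth$labels2, result$partition2)) / (n1 + n2)
}

#' Monte-Carlo comparison of the dual-projection and combined strategies
#'
#' Draws `reps` independent realizations of a scenario (replicate r uses seed
#' `base_seed + r - 1`), runs both detection pipelines on the *same* graph
#' (paired design; pairing reduces the variance of the difference without
#' biasing either mean), and scores each against the planted labels with
#' [score_joint()]. Spill warnings from saturated generator regions are
#' counted rather than repeated per replicate; a failing replicate is
#' recorded and skipped, not fatal.
#'
#' @param config a `scenario_config`; its `seed` is the default `base_seed`.
#' @param reps number of replicates.
#' @param base_seed seed of the first replicate.
#' @param methods which pipelines to run: subset of `c("dual", "combined")`.
#' @param steps walktrap random-walk length; default 4.
#' @param verbose print per-replicate progress every 100 replicates.
#' @return A `bicomm_simulation` object: `results` is a data.frame with
#'   columns `replicate`, `seed`, `method`, `nmi`; `summary()` gives mean and
#'   across-replicate standard deviation per method.
#' @examples
#' cfg <- scenario_config("equal_3_3", "small")
#' sim <- run_simulation(cfg, reps = 3, base_seed = 1)
#' summary(sim)
#' @export
run_simulation <- function(config, reps, base_seed = NULL,
                           methods = c("dual", "combined"),
                           steps = 4L, verbose = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  reps <- as.integer(reps)
  if (is.na(reps) || reps < 1L) stop("reps must be a positive integer")
  methods <- match.arg(methods, several.ok = TRUE)
  if (is.null(base_seed)) base_seed <- if (is.null(config$seed)) 1L else config$seed
  base_seed <- as.integer(base_seed)
  rows <- vector("list", reps)
  errors <- character(0)
  spilled <- 0L
  for (r in seq_len(reps)) {
    seed_r <- base_seed + r - 1L
    cfg_r <- config
    cfg_r$seed <- seed_r
    res <- tryCatch({
      gen <- withCallingHandlers(
        generate_bipartite(cfg_r),
        bicomm_spill = function(w) {
          spilled <<- spilled + 1L
          invokeRestart("muffleWarning")
        })
      vals <- vapply(methods, function(mth) {
        jp <- if (mth == "dual") detect_dual(gen$graph, steps = steps)
              else detect_combined(gen$graph, steps = steps)
        score_joint(gen$truth, jp)
      }, 0)
      data.frame(replicate = r, seed = seed_r, method = methods, nmi = vals,
                 row.names = NULL)
    }, error = function(e) {
      errors <<- c(errors, sprintf("replicate %d (seed %d): %s",
                                   r, seed_r, conditionMessage(e)))
      data.frame(replicate = r, seed = seed_r, method = methods,
                 nmi = NA_real_, row.names = NULL)
    })
    rows[[r]] <- res
    if (verbose && r %% 100L == 0L) {
      message(sprintf("replicate %d / %d", r, reps))
    }
  }
  structure(
    list(scenario = config$scenario, config = config, reps = reps,
         base_seed = base_seed, results = do.call(rbind, rows),
         spill_replicates = spilled, errors = errors),
    class = "bicomm_simulation")
}

#' @export
summary.bicomm_simulation <- function(object, ...) {
  res <- object$results
  agg <- do.call(rbind, lapply(split(res, res$method), function(df) {
    data.frame(scenario = object$scenario, method = df$method[1L],
               reps = sum(!is.na(df$nmi)),
               mean_nmi = mean(df$nmi, na.rm = TRUE),
               sd_nmi = stats::sd(df$nmi, na.rm = TRUE))
  }))
  rownames(agg) <- NULL
  agg[order(agg$method), ]
}

#' @export
print.bicomm_simulation <- function(x, ...) {
  cat(sprintf("Simulation: scenario %s, %d x %d, %d replicates (base seed %d)\n",
              x$scenario, x$config$n1, x$config$n2, x$reps, x$base_seed))
  s <- summary(x)
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-8s mean NMI %.3f +/- %.3f sd  (n = %d)\n",
                s$method[i], s$mean_nmi[i], s$sd_nmi[i], s$reps[i]))
  }
  if (length(x$errors) > 0L) {
    cat(sprintf("  %d failed replicate(s)\n", length(x$errors)))
  }
  invisible(x)
}

#' Mean NMI per method of a simulation
#'
#' @param sim a `bicomm_simulation`.
#' @return Named numeric vector of mean NMI, one entry per method.
#' @export
mean_nmi <- function(sim) {
  stopifnot(inherits(sim, "bicomm_simulation"))
  s <- summary(sim)
  stats::setNames(s$mean_nmi, s$method)
}
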