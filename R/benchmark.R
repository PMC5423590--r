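#' Run the planted-network benchmark
#'
#' For every test problem in `design` (a [benchmark_design()] frame),
#' generates the planted network and runs one annealing trajectory of
#' `reference_budget` trials, recording the best-found correlation at each
#' budget in `budgets` as a checkpoint of that shared trajectory. Because
#' every budget is a prefix of the same run, the best-found correlation is
#' non-decreasing in \eqn{\xi} for each problem, and the reference budget
#' attains the problem's best-found value by construction.
#'
#' Per problem and budget the deviations from the reference are recorded:
#' `deviation_raw` \eqn{= r(\xi_{ref}) - r(\xi) \ge 0}, `deviation_pct`
#' \eqn{= 100 \cdot} raw\eqn{/r(\xi_{ref})}, and `matched` (raw deviation
#' within `tol`). [benchmark_summary()] aggregates these into MRCD, MPCD
#' and MPBF.
#'
#' @param design data.frame from [benchmark_design()] (columns `problem`,
#'   `n`, `core_fraction`, `p_core`, `p_periphery`, `p_between`, `seed`).
#' @param budgets trial budgets \eqn{\xi} to evaluate.
#' @param reference_budget the benchmark budget; must be at least
#'   `max(budgets)`.
#' @param restarts independent trajectories per problem (default 1); with
#'   more than one, each budget takes the best value across restarts at
#'   that checkpoint.
#' @param tol match tolerance on the correlation (default `1e-5`).
#' @return data.frame with one row per (problem, budget): the design
#'   columns, `budget`, `r`, `r_reference`, `deviation_raw`,
#'   `deviation_pct`, `matched`.
#' @seealso [benchmark_summary()]
#' @export
run_benchmark <- function(design, budgets, reference_budget,
                          restarts = 1L, tol = 1e-5) {
  if (!is.data.frame(design) || nrow(design) == 0L)
    stop("`design` must be a non-empty data.frame; see benchmark_design()")
  need <- c("problem", "n", "core_fraction", "p_core", "p_periphery",
            "p_between", "seed")
  if (!all(need %in% names(design)))
    stop("`design` lacks columns: ",
         paste(setdiff(need, names(design)), collapse = ", "))
  budgets <- sort(unique(round(budgets)))
  if (length(budgets) == 0L || any(budgets < 1))
    stop("`budgets` must be positive trial counts")
  if (reference_budget < max(budgets))
    stop("reference_budget must be >= max(budgets)")
  restarts <- as.integer(restarts)
  ck <- sort(unique(c(budgets, reference_budget)))

  rows <- lapply(seq_len(nrow(design)), function(i) {
    p <- design[i, ]
    pl <- generate_planted_network(p$n, p$core_fraction, p$p_core,
                                   p$p_periphery, p$p_between,
                                   seed = p$seed)
    # per-budget best over restarts; each restart is one shared trajectory
    ck_best <- rep(-Inf, length(ck))
    for (s in seq_len(restarts)) {
      fit <- anneal(pl$network, xi = reference_budget,
                    seed = p$seed + 7919L * s, checkpoints = ck)
      ck_best <- pmax(ck_best, fit$trace$best_r)
    }
    r_ref <- ck_best[length(ck)]
    at <- match(budgets, ck)
    data.frame(p[, need, drop = FALSE], row.names = NULL,
               budget = budgets,
               r = ck_best[at],
               r_reference = r_ref,
               deviation_raw = r_ref - ck_best[at],
               deviation_pct = if (r_ref > 0)
                 100 * (r_ref - ck_best[at]) / r_ref else NA_real_,
               matched = abs(r_ref - ck_best[at]) <= tol)
  })
  do.call(rbind, rows)
}

#' Summarize benchmark deviations (MRCD / MPCD / MPBF)
#'
#' Aggregates a [run_benchmark()] table into the three summary measures,
#' per budget, overall and within each level of the design features:
#' \describe{
#'   \item{MRCD}{mean raw correlation deviation from the reference budget.}
#'   \item{MPCD}{mean percentage correlation deviation.}
#'   \item{MPBF}{percentage of problems matching the best-found
#'     (reference) correlation within tolerance.}
#' }
#'
#' @param results data.frame from [run_benchmark()].
#' @param features design columns to slice by (default the five design
#'   features present in the results).
#' @return data.frame with columns `feature`, `level`, `budget`, `mrcd`,
#'   `mpcd`, `mpbf`, `problems`; the first rows carry
#'   `feature = "overall"`.
#' @export
benchmark_summary <- function(results,
                              features = c("n", "core_fraction", "p_core",
                                           "p_periphery", "p_between")) {
  stopifnot(is.data.frame(results), nrow(results) > 0L)
  features <- intersect(features, names(results))
  one <- function(df, feature, level) {
    agg <- lapply(split(df, df$budget), function(b)
      data.frame(feature = feature, level = level,
                 budget = b$budget[1L],
                 mrcd = mean(b$deviation_raw),
                 mpcd = mean(b$deviation_pct),
                 mpbf = 100 * mean(b$matched),
                 problems = nrow(b)))
    do.call(rbind, agg)
  }
  out <- one(results, "overall", "")
  for (f in features) {
    for (lv in sort(unique(results[[f]]))) {
      out <- rbind(out, one(results[results[[f]] == lv, ], f,
                            format(lv)))
    }
  }
  rownames(out) <- NULL
  out
}
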