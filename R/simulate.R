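#' Breeding-campaign configuration
#'
#' Bundles the knobs of one campaign: the selection method, deadline,
#' per-generation population size and budget, and method-specific parameters.
#' Defaults follow the standard comparison setting: `N = 200` individuals,
#' `S = 20` selected into `nc = 10` crosses of `np = 20` progenies each
#' (constant population size 200) over `T = 10` generations; OHV uses
#' `B = 12` blocks per chromosome with prefilter `F = 0.7`, OPV `B = 1` with
#' `F = 0.4`, and LAS searches the full population (`F = 0`).
#'
#' @param method One of `"cgs"`, `"wgs"`, `"ohv"`, `"opv"`, `"las"`.
#' @param T Deadline (number of generations bred).
#' @param N Population size (founders used per campaign).
#' @param S Number of parents selected per generation (even).
#' @param total_progeny Progeny budget per generation (default `N`).
#' @param B Haplotype blocks per chromosome (method-dependent default).
#' @param F GEBV prefilter fraction (method-dependent default).
#' @param las Named list of look-ahead settings: `K`, `n_reps`, `restarts`,
#'   `max_iters`, `exchange_moves`, `tol` (see [swap_optimize_las()]).
#' @param seed Optional root seed for the campaign.
#' @return An object of class `CampaignConfig`.
#' @export
campaign_config <- function(method = c("cgs", "wgs", "ohv", "opv", "las"),
                            T = 10, N = 200, S = 20, total_progeny = N,
                            B = NULL, F = NULL, las = list(), seed = NULL) {
  method <- match.arg(method)
  if (S %% 2 != 0 || S < 2) stop("S must be even and >= 2")
  if (S > N) stop("cannot select more parents than the population size")
  nc <- S / 2
  if (total_progeny < nc) stop("progeny budget must cover one progeny per cross")
  B <- B %||% switch(method, ohv = 12, opv = 1, las = 1, 1)
  F <- F %||% switch(method, ohv = 0.7, opv = 0.4, 0)
  las_defaults <- list(K = 200, n_reps = 1, restarts = 1, max_iters = 50,
                       exchange_moves = TRUE, tol = 0,
                       R_exponent = "intermating")
  las <- utils::modifyList(las_defaults, las)
  structure(list(method = method, T = T, N = N, S = S, nc = nc,
                 total_progeny = total_progeny, B = B, F = F, las = las,
                 seed = seed),
            class = "CampaignConfig")
}

#' @export
print.CampaignConfig <- function(x, ...) {
  cat(sprintf("CampaignConfig: %s, T=%d, N=%d, S=%d (%d crosses), budget %d/gen\n",
              toupper(x$method), x$T, x$N, x$S, x$nc, x$total_progeny))
  invisible(x)
}

#' Advance a breeding population by one generation
#'
#' Runs the selection and reproduction steps of one breeding cycle under the
#' configured method: truncation selection on GEBV (`cgs`), weighted GEBV
#' (`wgs`) or OHV (`ohv`, after the GEBV prefilter) followed by random
#' pairing and equal progeny counts; swap-heuristic group selection on OPV
#' (`opv`, after the prefilter) with random pairing; or look-ahead selection
#' (`las`) with horizon `T - t`, which jointly chooses the parents and their
#' pairing and then allocates progenies in proportion to pair diversity.
#' Every pair is then crossed, producing the configured total progeny count.
#'
#' @inheritParams compute_gebv
#' @param config A [campaign_config()].
#' @param t Current generation number (0-based; must be `< T`).
#' @param seed Optional integer seed for this generation.
#' @return The progeny [Population] of size `config$total_progeny`.
#' @export
advance_generation <- function(pop, spec, config, t, seed = NULL) {
  if (t >= config$T) stop("t must be smaller than the deadline T")
  if (n_ind(pop) < config$S) stop("population smaller than the selection size")
  blocks <- make_blocks(spec, config$B)
  plan <- switch(config$method,
    cgs = ,
    wgs = ,
    ohv = {
      surv <- prefilter_by_gebv(pop, spec, config$F, S = config$S)
      sub <- subset_population(pop, surv)
      scores <- switch(config$method,
        cgs = compute_gebv(sub, spec),
        wgs = weighted_gebv(sub, spec),
        ohv = compute_ohv(sub, spec, blocks))
      sel <- surv[truncation_select(scores, config$S)]
      random_pairing(sel, seed = child_seed(seed, 1))
    },
    opv = {
      sel <- swap_optimize_opv(pop, spec, blocks, S = config$S, F = config$F,
                               seed = child_seed(seed, 1))
      random_pairing(sel, seed = child_seed(seed, 2))
    },
    las = swap_optimize_las(pop, spec, S = config$S, horizon = config$T - t,
                            K = config$las$K, n_reps = config$las$n_reps,
                            F = config$F, seed = child_seed(seed, 1),
                            max_iters = config$las$max_iters,
                            restarts = config$las$restarts,
                            exchange_moves = config$las$exchange_moves,
                            tol = config$las$tol,
                            R_exponent = config$las$R_exponent))
  plan <- if (config$method == "las")
    allocate_progenies(plan, pop, spec, config$total_progeny)
  else
    MatingPlan(plan$selected, equal_split(config$total_progeny, config$nc))
  progeny <- lapply(seq_len(config$nc), function(p)
    cross(pop, plan$selected[2 * p - 1], plan$selected[2 * p],
          plan$n_progeny[p], spec, seed = child_seed(seed, 100 + p)))
  out <- Population(do.call(cbind, lapply(progeny, `[[`, "haplo")),
                    ids = unlist(lapply(progeny, `[[`, "ids")))
  attr(out, "plan") <- plan
  out
}

# total progenies split as evenly as possible over nc crosses
equal_split <- function(total, nc) {
  base <- total %/% nc
  rep(base, nc) + c(rep(1L, total %% nc), rep(0L, nc - total %% nc))
}

population_stats <- function(pop, spec) {
  gebv <- compute_gebv(pop, spec)
  lim <- selection_limits(pop, spec)
  data.frame(min = min(gebv), mean = mean(gebv), max = max(gebv),
             diversity = diversity(pop, spec),
             lower = lim[["lower"]], upper = lim[["upper"]])
}

#' Run a breeding campaign
#'
#' Applies [advance_generation()] `T` times and records per-generation
#' population statistics, including generation 0 (the founders before any
#' selection). Cumulative gain is the mean GEBV minus the generation-0 mean.
#'
#' @param founders Founder [Population] (used as-is; see [compare_methods()]
#'   for subsampling).
#' @param spec A [GenomeSpec].
#' @param config A [campaign_config()].
#' @param seed Optional root seed (defaults to `config$seed`).
#' @return A `Trajectory` data frame with columns `generation`, `min`,
#'   `mean`, `max`, `diversity`, `lower`, `upper`, `gain`; the terminal
#'   population is attached as attribute `"final_population"`.
#' @export
run_program <- function(founders, spec, config, seed = NULL) {
  seed <- seed %||% config$seed
  pop <- founders
  rows <- vector("list", config$T + 1)
  rows[[1]] <- population_stats(pop, spec)
  if (config$T > 0) for (t in 0:(config$T - 1)) {
    pop <- advance_generation(pop, spec, config, t, seed = child_seed(seed, t))
    rows[[t + 2]] <- population_stats(pop, spec)
  }
  traj <- do.call(rbind, rows)
  traj <- cbind(generation = 0:config$T, traj)
  traj$gain <- traj$mean - traj$mean[1]
  class(traj) <- c("Trajectory", "data.frame")
  attr(traj, "final_population") <- pop
  traj
}

#' Compare selection methods on shared founders
#'
#' Runs each configured method `reps` times; within a repetition all methods
#' share the same founder draw (a random subset of `config$N` founders when
#' more are supplied, the founders as-is otherwise), so method contrasts are
#' paired. Optionally re-runs every method at a sweep of deadlines, sharing
#' founder draws across deadlines.
#'
#' @param founders Founder [Population] pool.
#' @param spec A [GenomeSpec].
#' @param configs Named list of [campaign_config()]s (names label methods).
#' @param reps Number of repetitions (>= 1).
#' @param seed Optional root seed.
#' @param deadlines Optional integer vector of deadlines for a sweep.
#' @return A list with `trajectories` (long data frame: method, rep,
#'   generation, stats), `gain` and `diversity_traj` (mean trajectories per
#'   method), `terminal` (terminal min/mean/max, mean and sd across reps),
#'   `maxima` (per-rep terminal population maxima, for CDF plots) and, when
#'   requested, `deadline_sweep` (terminal gain per method and deadline).
#' @export
compare_methods <- function(founders, spec, configs, reps = 1, seed = NULL,
                            deadlines = NULL) {
  stopifnot(reps >= 1, length(configs) >= 1)
  if (is.null(names(configs)))
    names(configs) <- vapply(configs, `[[`, "", "method")
  out <- list()
  for (rep_i in seq_len(reps)) {
    fd <- draw_founders(founders, configs[[1]]$N, seed = child_seed(seed, rep_i))
    for (mi in seq_along(configs)) {
      traj <- run_program(fd, spec, configs[[mi]],
                          seed = child_seed(seed, rep_i, mi))
      traj <- cbind(method = names(configs)[mi], rep = rep_i,
                    as.data.frame(traj))
      out[[length(out) + 1]] <- traj
    }
  }
  trajectories <- do.call(rbind, out)
  agg <- function(col) {
    stats::aggregate(trajectories[[col]],
                     by = list(method = trajectories$method,
                               generation = trajectories$generation),
                     FUN = mean) |>
      stats::setNames(c("method", "generation", col))
  }
  terminal <- trajectories[trajectories$generation == max(trajectories$generation), ]
  sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0
  term_tab <- do.call(rbind, lapply(split(terminal, terminal$method), function(d)
    data.frame(method = d$method[1],
               min_mean = mean(d$min), min_sd = sd0(d$min),
               mean_mean = mean(d$mean), mean_sd = sd0(d$mean),
               max_mean = mean(d$max), max_sd = sd0(d$max))))
  rownames(term_tab) <- NULL
  res <- list(trajectories = trajectories,
              gain = agg("gain"),
              diversity_traj = agg("diversity"),
              terminal = term_tab,
              maxima = terminal[, c("method", "rep", "max")])
  if (!is.null(deadlines)) {
    sweep <- list()
    for (Td in deadlines) {
      cfgs <- lapply(configs, function(cf) { cf$T <- Td; cf })
      sub <- compare_methods(founders, spec, cfgs, reps = reps, seed = seed)
      g <- sub$gain[sub$gain$generation == Td, c("method", "gain")]
      sweep[[length(sweep) + 1]] <- cbind(deadline = Td, g)
    }
    res$deadline_sweep <- do.call(rbind, sweep)
  }
  res
}

# One shared founder draw: subsample N individuals when more are available.
draw_founders <- function(founders, N, seed = NULL) {
  if (n_ind(founders) <= N) return(founders)
  idx <- with_seed(seed, sort(sample.int(n_ind(founders), N)))
  subset_population(founders, idx)
}
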