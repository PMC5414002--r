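#' Treadmilling velocity of a tracked filament
#'
#' Velocity is defined from end-resolved event counts on one surviving
#' filament: `(net additions at the plus end - net additions at the minus
#' end) / 2` per unit time. A filament treadmilling steadily at speed `v`
#' gains `v t` subunits at one end and loses `v t` at the other, so this
#' estimator returns `v` with sign tied to the structural polarity. The
#' confidence interval is a block bootstrap over equal time blocks of the
#' filament's surviving epoch.
#'
#' @param trajectory an `ssa_trajectory` from [run_ssa()].
#' @param fil_id filament to track (default: the first seeded filament).
#' @param n_blocks number of time blocks (default 20).
#' @param n_boot bootstrap resamples (default 1000).
#' @param conf confidence level (default 0.95).
#' @param boot_seed seed for the bootstrap resampling.
#' @return List: `velocity` (subunits/s), `ci` (length 2), `plus_flux`,
#'   `minus_flux` (net subunits/s per end), `t_span`, `n_events`, `fil_id`.
#' @export
measure_treadmilling <- function(trajectory, fil_id = NULL, n_blocks = 20,
                                 n_boot = 1000, conf = 0.95, boot_seed = 1L) {
  stopifnot(inherits(trajectory, "ssa_trajectory"))
  ev <- trajectory$events
  if (is.null(fil_id)) fil_id <- 1L
  mine <- ev[!is.na(ev$fil) & ev$fil == fil_id, , drop = FALSE]
  # surviving epoch: until the filament dissolves (dimer dissolution) or t_end
  death <- mine$time[mine$type == "dimer_diss"]
  t_span <- if (length(death)) min(death) else trajectory$t_end
  if (t_span <= 0) stop("no surviving filament epoch to measure")
  mine <- mine[mine$time <= t_span, , drop = FALSE]
  sgn <- c(assoc_plus = 1, loss_plus = -1, assoc_minus = 1, loss_minus = -1)
  endof <- c(assoc_plus = "plus", loss_plus = "plus",
             assoc_minus = "minus", loss_minus = "minus")
  mine <- mine[mine$type %in% names(sgn), , drop = FALSE]
  if (nrow(mine) == 0L) {
    return(list(velocity = 0, ci = c(0, 0), plus_flux = 0, minus_flux = 0,
                t_span = t_span, n_events = 0L, fil_id = fil_id))
  }
  contrib <- sgn[mine$type] * ifelse(endof[mine$type] == "plus", 1, -1) / 2
  net_p <- sum(sgn[mine$type][endof[mine$type] == "plus"])
  net_m <- sum(sgn[mine$type][endof[mine$type] == "minus"])
  velocity <- (net_p - net_m) / 2 / t_span
  # block bootstrap
  blk <- pmin(n_blocks, pmax(1L, floor(mine$time / (t_span / n_blocks)) + 1L))
  per_block <- vapply(seq_len(n_blocks), function(b) {
    sum(contrib[blk == b]) / (t_span / n_blocks)
  }, numeric(1))
  set.seed(boot_seed)
  boots <- vapply(seq_len(n_boot), function(i) {
    mean(per_block[sample.int(n_blocks, replace = TRUE)])
  }, numeric(1))
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(boots, c(alpha, 1 - alpha)))
  list(velocity = velocity, ci = ci,
       plus_flux = net_p / t_span, minus_flux = net_m / t_span,
       t_span = t_span, n_events = nrow(mine), fil_id = fil_id)
}

#' Breakage versus end-loss rate ratio
#'
#' Compares the per-interface event rates of internal breakage and terminal
#' subunit loss over interfaces of one nucleotide class:
#' `(breakage events / internal interface-time) / (end-loss events /
#' terminal interface-time)`. By construction the switch makes this ratio
#' `exp(-dG_switch)` — 1 for rigid subunits (breakage is the same reaction
#' as end loss), smaller when ends can cash in the monomer conformation.
#' The CI is the exact conditional (binomial) interval for a two-rate
#' Poisson comparison.
#'
#' @param trajectory an `ssa_trajectory` with both exposure classes.
#' @param nucleotide `"D"` (default) or `"T"`.
#' @param conf confidence level.
#' @return List: `ratio`, `ci`, `breakage_events`, `end_loss_events`,
#'   `internal_time`, `terminal_time` (interface-time integrals).
#' @export
breakage_vs_endloss <- function(trajectory, nucleotide = c("D", "T"),
                                conf = 0.95) {
  stopifnot(inherits(trajectory, "ssa_trajectory"))
  nucleotide <- match.arg(nucleotide)
  ex <- trajectory$exposures
  ct <- trajectory$counts
  ti <- ex[[paste0("int_", nucleotide)]]
  tt <- ex[[paste0("term_", nucleotide)]]
  if (ti <= 0 || tt <= 0) {
    stop("zero exposure time for internal or terminal ", nucleotide, " interfaces")
  }
  xb <- ct[[paste0("breakage_", nucleotide)]]
  xe <- ct[[paste0("end_loss_", nucleotide)]]
  if (xb + xe == 0L) stop("no breakage or end-loss events recorded")
  pt <- stats::poisson.test(c(xb, xe), T = c(ti, tt), conf.level = conf)
  list(ratio = (xb / ti) / (xe / tt), ci = unname(pt$conf.int),
       breakage_events = xb, end_loss_events = xe,
       internal_time = ti, terminal_time = tt)
}

#' Equilibrium polymer mass versus total concentration
#'
#' Runs closed-system simulations over a concentration grid, reporting the
#' equilibrated mean polymerized mass fraction (time average over the second
#' half of each run, flagged when the two quarters of that window drift) and
#' the time to half-plateau as a lag-phase proxy.
#'
#' @param params a [sim_params()] template (mode and totals are overridden).
#' @param c_grid total concentrations to scan (units of c0).
#' @param t_eq run length per concentration.
#' @param replicates independent runs per concentration.
#' @param n_total subunit count per run (sets the volume).
#' @param seed base seed; run r at grid point i uses
#'   `seed + 131 * i + r`.
#' @return data.frame: `c_total`, `replicate`, `mass_fraction`, `t_half`,
#'   `n_filaments`, `equilibrated`.
#' @export
mass_curve <- function(params, c_grid, t_eq, replicates = 2, n_total = 150,
                       seed = 1L) {
  stopifnot(inherits(params, "sim_params"))
  rows <- list()
  for (i in seq_along(c_grid)) {
    for (r in seq_len(replicates)) {
      p <- params
      p$mode <- "closed_system"
      p$c_total <- c_grid[i]
      p$n_total <- as.integer(n_total)
      if (c_grid[i] == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          c_total = 0, replicate = r, mass_fraction = 0, t_half = NA_real_,
          n_filaments = 0L, equilibrated = TRUE)
        next
      }
      tr <- run_ssa(p, t_max = t_eq, seed = seed + 131L * i + r,
                    snapshot_dt = t_eq / 400)
      sn <- tr$snapshots
      late <- sn$time >= t_eq / 2
      frac <- mean(sn$polymer[late]) / n_total
      q3 <- sn$time >= t_eq / 2 & sn$time < 3 * t_eq / 4
      q4 <- sn$time >= 3 * t_eq / 4
      drift <- abs(mean(sn$polymer[q3]) - mean(sn$polymer[q4])) / n_total
      plateau <- mean(sn$polymer[late])
      th <- sn$time[which(sn$polymer >= plateau / 2)[1]]
      rows[[length(rows) + 1L]] <- data.frame(
        c_total = c_grid[i], replicate = r, mass_fraction = frac,
        t_half = if (plateau > 0) th else NA_real_,
        n_filaments = sn$n_fil[nrow(sn)],
        equilibrated = drift < 0.05)
    }
  }
  do.call(rbind, rows)
}

#' Estimate the critical concentration from a mass curve
#'
#' Above the critical concentration the free-monomer concentration pins at
#' `c_crit`; the estimator averages the free concentration
#' `c_total * (1 - mass_fraction)` over grid points with substantial
#' polymer.
#'
#' @param curve data.frame from [mass_curve()].
#' @param min_fraction minimum polymerized fraction for a point to
#'   contribute (default 0.3).
#' @return Estimated critical concentration (units of c0).
#' @export
estimate_c_crit <- function(curve, min_fraction = 0.3) {
  use <- curve$mass_fraction >= min_fraction & curve$c_total > 0
  if (!any(use)) stop("no grid point reaches mass fraction ", min_fraction)
  mean(curve$c_total[use] * (1 - curve$mass_fraction[use]))
}

#' Filament length distribution of a final state
#'
#' @param trajectory an `ssa_trajectory`.
#' @return Integer vector of filament lengths.
#' @export
filament_lengths <- function(trajectory) {
  vapply(trajectory$final_state$filaments, length, 1L)
}
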