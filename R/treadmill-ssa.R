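# Gillespie direct-method simulator for single-stranded filament kinetics.
#
# Internal representation: a filament is an integer vector ordered from the
# minus end (index 1, bottom face exposed) to the plus end (index n, top face
# exposed); element i is the nucleotide bound to subunit i (1 = NTP, 0 = NDP),
# which sits on that subunit's top face and therefore forms interface i
# (between subunits i and i+1). The plus-end subunit's nucleotide is solvent
# exposed. Conformation is implied: polymerized subunits are open, free
# monomers closed (switch variant).

EVENT_TYPES <- c("assoc_plus", "assoc_minus", "nucleation", "loss_plus",
                 "loss_minus", "dimer_diss", "breakage", "hydrolysis",
                 "exchange_fil", "exchange_free", "anneal")

N_FIL_CH <- 11L  # propensity channels per filament
N_GLOB_CH <- 6L  # nuc_TT, nuc_TD, nuc_DT, nuc_DD, exch_free, anneal

#' Construct a simulation state
#'
#' @param filaments list of integer vectors (1 = NTP, 0 = NDP), minus end
#'   first; every filament must have length >= 2.
#' @param free named counts `c(T = , D = )` of free monomers (ignored /
#'   clamped in `fixed_monomer` mode).
#' @return An object of class `sim_state`.
#' @export
make_sim_state <- function(filaments = list(), free = c(T = 0, D = 0)) {
  filaments <- lapply(filaments, as.integer)
  if (any(vapply(filaments, length, 1L) < 2L)) stop("filaments must have >= 2 subunits")
  if (any(unlist(filaments) %in% c(0L, 1L) == FALSE)) stop("nucleotide states must be 0 (NDP) or 1 (NTP)")
  free <- c(T = as.integer(free[["T"]]), D = as.integer(free[["D"]]))
  if (any(free < 0)) stop("free monomer counts must be >= 0")
  structure(list(filaments = filaments, free = free), class = "sim_state")
}

# propensity vector for the current state; layout: 11 channels per filament
# then 6 global channels
ssa_propensities <- function(filaments, free, p, rt) {
  nf <- length(filaments)
  if (p$mode == "closed_system") {
    omega <- p$n_total / p$c_total
    cT <- free[["T"]] / omega
    cD <- free[["D"]] / omega
  } else {
    omega <- NA_real_
    cT <- p$c_free
    cD <- 0
  }
  a <- numeric(nf * N_FIL_CH + N_GLOB_CH)
  for (k in seq_len(nf)) {
    f <- filaments[[k]]
    L <- length(f)
    b <- (k - 1L) * N_FIL_CH
    a[b + 1L] <- rt$assoc_plus * cT
    a[b + 2L] <- rt$assoc_plus * cD
    a[b + 3L] <- rt$assoc_minus * cT
    a[b + 4L] <- rt$assoc_minus * cD
    if (L == 2L) {
      a[b + 5L] <- if (f[1] == 1L) rt$dimer_diss_T else rt$dimer_diss_D
    } else {
      a[b + 6L] <- if (f[L - 1L] == 1L) rt$end_loss_T_plus else rt$end_loss_D_plus
      a[b + 7L] <- if (f[1] == 1L) rt$end_loss_T_minus else rt$end_loss_D_minus
    }
    if (p$enable_breakage && L >= 4L) {
      int <- f[2:(L - 2L)]
      a[b + 8L] <- sum(int == 1L) * rt$breakage_T
      a[b + 9L] <- sum(int == 0L) * rt$breakage_D
    }
    if (p$k_hyd > 0) a[b + 10L] <- sum(f[1:(L - 1L)] == 1L) * rt$hydrolysis
    if (p$exchange_in_filament && f[L] == 0L) a[b + 11L] <- rt$exchange
  }
  g <- nf * N_FIL_CH
  if (p$mode == "closed_system") {
    NT <- free[["T"]]; ND <- free[["D"]]
    a[g + 1L] <- rt$nucleation * NT * (NT - 1) / omega
    a[g + 2L] <- rt$nucleation * NT * ND / omega
    a[g + 3L] <- rt$nucleation * ND * NT / omega
    a[g + 4L] <- rt$nucleation * ND * (ND - 1) / omega
    a[g + 5L] <- rt$exchange * ND
    if (p$enable_annealing && nf >= 2L) a[g + 6L] <- rt$annealing * nf * (nf - 1) / omega
  }
  a
}

#' Total propensity of a state
#'
#' Sum of all reaction propensities: the exponential waiting-time rate of
#' the embedded jump process at this state.
#'
#' @param state a [make_sim_state()] object.
#' @param params a [sim_params()].
#' @return Numeric total propensity (1/s).
#' @export
total_propensity <- function(state, params) {
  stopifnot(inherits(state, "sim_state"), inherits(params, "sim_params"))
  rt <- build_rates(params)
  sum(ssa_propensities(state$filaments, state$free, params, rt))
}

#' Draw inter-event waiting times at a fixed state
#'
#' Samples `n` waiting times from the simulator's waiting-time law at
#' `state` (exponential with the total-propensity rate), using the same
#' random-number pathway as [run_ssa()].
#'
#' @param params a [sim_params()].
#' @param state a [make_sim_state()] object.
#' @param n number of draws.
#' @param seed PRNG seed.
#' @return List with `times` (length n) and `rate` (total propensity).
#' @export
sample_waiting_times <- function(params, state, n, seed = 1L) {
  rate <- total_propensity(state, params)
  if (rate <= 0) stop("state has zero total propensity")
  set.seed(seed)
  list(times = stats::rexp(n, rate), rate = rate)
}

#' Run the stochastic simulation (Gillespie direct method)
#'
#' Exact stochastic realization of the filament reaction network in
#' [build_rates()]: exponential waiting times from the total propensity,
#' categorical selection of the next reaction. Reproducible: identical
#' `params` + `seed` give bit-identical event logs.
#'
#' If `params$asymmetric_end == "minus"` the canonical plus-asymmetric
#' process is simulated and the emitted event labels are mirrored
#' (plus <-> minus), which realizes the mirrored chain exactly.
#'
#' @param params a [sim_params()].
#' @param t_max simulated time horizon (> 0).
#' @param seed PRNG seed (defaults to `params$seed`).
#' @param init optional [make_sim_state()] initial state. Defaults: one
#'   all-NTP filament of `params$init_length` (`fixed_monomer`), or
#'   `n_total` free NTP monomers (`closed_system`).
#' @param snapshot_dt interval for state snapshots (`NULL` = 200 over the
#'   run).
#' @param record_states also record the canonical state label at snapshots
#'   (small systems only).
#' @param max_events safety cap on the number of events.
#' @return An object of class `ssa_trajectory`: `events` (data.frame: time,
#'   type, fil, pos, nuc), `snapshots` (data.frame), `final_state`,
#'   `exposures` (interface time integrals), `counts` (event class counts),
#'   `t_end`, `termination`, `params`, `seed`, `mirrored`.
#' @export
run_ssa <- function(params, t_max, seed = params$seed, init = NULL,
                    snapshot_dt = NULL, record_states = FALSE,
                    max_events = 2e6) {
  stopifnot(inherits(params, "sim_params"), t_max > 0)
  mirrored <- params$asymmetric_end == "minus"
  p <- params
  p$asymmetric_end <- "plus"
  rt <- build_rates(p)
  set.seed(seed)

  if (is.null(init)) {
    if (p$mode == "fixed_monomer") {
      filaments <- list(rep(1L, p$init_length))
      free <- c(T = 0L, D = 0L)
    } else {
      filaments <- list()
      free <- c(T = as.integer(p$n_total), D = 0L)
    }
  } else {
    stopifnot(inherits(init, "sim_state"))
    filaments <- init$filaments
    free <- init$free
    if (p$mode == "closed_system") {
      tot <- sum(vapply(filaments, length, 1L)) + sum(free)
      if (tot != p$n_total) stop("initial state holds ", tot,
                                 " subunits but n_total = ", p$n_total)
    }
  }
  fil_ids <- seq_along(filaments)
  next_id <- length(filaments) + 1L

  if (is.null(snapshot_dt)) snapshot_dt <- t_max / 200
  snap_times <- seq(0, t_max, by = snapshot_dt)
  ns <- length(snap_times)
  snap <- list(time = snap_times, polymer = numeric(ns), n_fil = integer(ns),
               free_T = integer(ns), free_D = integer(ns),
               label = if (record_states) character(ns) else NULL)
  snap_i <- 1L

  cap <- 4096L
  ev_time <- numeric(cap); ev_type <- integer(cap)
  ev_fil <- integer(cap); ev_pos <- integer(cap); ev_nuc <- integer(cap)
  nev <- 0L
  push <- function(tm, ty, fl, po, nu) {
    if (nev == cap) {
      cap <<- cap * 2L
      length(ev_time) <<- cap; length(ev_type) <<- cap
      length(ev_fil) <<- cap; length(ev_pos) <<- cap; length(ev_nuc) <<- cap
    }
    nev <<- nev + 1L
    ev_time[nev] <<- tm; ev_type[nev] <<- ty; ev_fil[nev] <<- fl
    ev_pos[nev] <<- po; ev_nuc[nev] <<- nu
  }

  expos <- c(int_T = 0, int_D = 0, term_T = 0, term_D = 0)
  counts <- c(breakage_T = 0L, breakage_D = 0L, end_loss_T = 0L, end_loss_D = 0L)

  take_snapshots <- function(up_to) {
    while (snap_i <= ns && snap_times[snap_i] <= up_to + 1e-12) {
      snap$polymer[snap_i] <<- sum(vapply(filaments, length, 1L))
      snap$n_fil[snap_i] <<- length(filaments)
      snap$free_T[snap_i] <<- free[["T"]]
      snap$free_D[snap_i] <<- free[["D"]]
      if (record_states) snap$label[snap_i] <<- canonical_state_label(filaments, free)
      snap_i <<- snap_i + 1L
    }
  }
  add_exposure <- function(dt) {
    for (f in filaments) {
      L <- length(f)
      if (L == 2L) {
        if (f[1] == 1L) expos[["term_T"]] <<- expos[["term_T"]] + dt
        else expos[["term_D"]] <<- expos[["term_D"]] + dt
      } else {
        for (x in c(f[1], f[L - 1L])) {
          if (x == 1L) expos[["term_T"]] <<- expos[["term_T"]] + dt
          else expos[["term_D"]] <<- expos[["term_D"]] + dt
        }
        if (L >= 4L) {
          int <- f[2:(L - 2L)]
          expos[["int_T"]] <<- expos[["int_T"]] + dt * sum(int == 1L)
          expos[["int_D"]] <<- expos[["int_D"]] + dt * sum(int == 0L)
        }
      }
    }
  }

  t <- 0
  termination <- "t_max"
  repeat {
    a <- ssa_propensities(filaments, free, p, rt)
    total <- sum(a)
    if (total <= 0) {
      add_exposure(t_max - t)
      take_snapshots(t_max)
      t <- t_max
      termination <- "exhausted"
      break
    }
    dt <- stats::rexp(1, total)
    if (t + dt > t_max) {
      add_exposure(t_max - t)
      take_snapshots(t_max)
      t <- t_max
      break
    }
    add_exposure(dt)
    take_snapshots(t + dt)
    t <- t + dt
    u <- stats::runif(1) * total
    ca <- cumsum(a)
    ch <- findInterval(u, ca) + 1L
    if (ch > length(a)) ch <- length(a)
    while (a[ch] <= 0 && ch < length(a)) ch <- ch + 1L  # boundary-tie guard
    nf <- length(filaments)
    if (ch <= nf * N_FIL_CH) {
      k <- (ch - 1L) %/% N_FIL_CH + 1L
      slot <- (ch - 1L) %% N_FIL_CH + 1L
      f <- filaments[[k]]
      L <- length(f)
      id <- fil_ids[k]
      if (slot == 1L || slot == 2L) {            # association at plus end
        X <- if (slot == 1L) 1L else 0L
        filaments[[k]] <- c(f, X)
        if (p$mode == "closed_system") free[[if (X == 1L) "T" else "D"]] <- free[[if (X == 1L) "T" else "D"]] - 1L
        push(t, 1L, id, L + 1L, X)
      } else if (slot == 3L || slot == 4L) {     # association at minus end
        X <- if (slot == 3L) 1L else 0L
        filaments[[k]] <- c(X, f)
        if (p$mode == "closed_system") free[[if (X == 1L) "T" else "D"]] <- free[[if (X == 1L) "T" else "D"]] - 1L
        push(t, 2L, id, 1L, X)
      } else if (slot == 5L) {                   # dimer dissolution
        X <- f[1]
        counts[[if (X == 1L) "end_loss_T" else "end_loss_D"]] <-
          counts[[if (X == 1L) "end_loss_T" else "end_loss_D"]] + 1L
        if (p$mode == "closed_system") {
          free[["T"]] <- free[["T"]] + sum(f == 1L)
          free[["D"]] <- free[["D"]] + sum(f == 0L)
        }
        filaments[[k]] <- NULL
        fil_ids <- fil_ids[-k]
        push(t, 6L, id, 1L, X)
      } else if (slot == 6L) {                   # loss at plus end
        X <- f[L - 1L]
        counts[[if (X == 1L) "end_loss_T" else "end_loss_D"]] <-
          counts[[if (X == 1L) "end_loss_T" else "end_loss_D"]] + 1L
        if (p$mode == "closed_system") free[[if (f[L] == 1L) "T" else "D"]] <- free[[if (f[L] == 1L) "T" else "D"]] + 1L
        filaments[[k]] <- f[-L]
        push(t, 4L, id, L, X)
      } else if (slot == 7L) {                   # loss at minus end
        X <- f[1]
        counts[[if (X == 1L) "end_loss_T" else "end_loss_D"]] <-
          counts[[if (X == 1L) "end_loss_T" else "end_loss_D"]] + 1L
        if (p$mode == "closed_system") free[[if (X == 1L) "T" else "D"]] <- free[[if (X == 1L) "T" else "D"]] + 1L
        filaments[[k]] <- f[-1L]
        push(t, 5L, id, 1L, X)
      } else if (slot == 8L || slot == 9L) {     # breakage at internal interface
        X <- if (slot == 8L) 1L else 0L
        idx <- which(f[2:(L - 2L)] == X) + 1L
        i <- if (length(idx) == 1L) idx else idx[1L + floor(stats::runif(1) * length(idx))]
        counts[[if (X == 1L) "breakage_T" else "breakage_D"]] <-
          counts[[if (X == 1L) "breakage_T" else "breakage_D"]] + 1L
        filaments[[k]] <- f[1:i]
        filaments[[length(filaments) + 1L]] <- f[(i + 1L):L]
        fil_ids <- c(fil_ids, next_id)
        next_id <- next_id + 1L
        push(t, 7L, id, i, X)
      } else if (slot == 10L) {                  # hydrolysis of a buried NTP
        idx <- which(f[1:(L - 1L)] == 1L)
        i <- if (length(idx) == 1L) idx else idx[1L + floor(stats::runif(1) * length(idx))]
        f[i] <- 0L
        filaments[[k]] <- f
        push(t, 8L, id, i, 0L)
      } else {                                   # terminal nucleotide exchange
        f[L] <- 1L
        filaments[[k]] <- f
        push(t, 9L, id, L, 1L)
      }
    } else {
      g <- ch - nf * N_FIL_CH
      if (g <= 4L) {                             # nucleation (lower, upper)
        X <- if (g %in% c(1L, 2L)) 1L else 0L
        Y <- if (g %in% c(1L, 3L)) 1L else 0L
        filaments[[length(filaments) + 1L]] <- c(X, Y)
        fil_ids <- c(fil_ids, next_id)
        free[["T"]] <- free[["T"]] - (X == 1L) - (Y == 1L)
        free[["D"]] <- free[["D"]] - (X == 0L) - (Y == 0L)
        push(t, 3L, next_id, 1L, X)
        next_id <- next_id + 1L
      } else if (g == 5L) {                      # free monomer exchange
        free[["D"]] <- free[["D"]] - 1L
        free[["T"]] <- free[["T"]] + 1L
        push(t, 10L, NA_integer_, NA_integer_, 1L)
      } else {                                   # annealing of an ordered pair
        nfa <- length(filaments)
        i <- 1L + floor(stats::runif(1) * nfa)
        j <- 1L + floor(stats::runif(1) * (nfa - 1L))
        if (j >= i) j <- j + 1L
        filaments[[i]] <- c(filaments[[i]], filaments[[j]])
        push(t, 11L, fil_ids[i], length(filaments[[i]]), NA_integer_)
        filaments[[j]] <- NULL
        fil_ids <- fil_ids[-j]
      }
    }
    if (nev >= max_events) { termination <- "max_events"; break }
  }

  events <- data.frame(time = ev_time[seq_len(nev)],
                       type = EVENT_TYPES[ev_type[seq_len(nev)]],
                       fil = ev_fil[seq_len(nev)], pos = ev_pos[seq_len(nev)],
                       nuc = c("D", "T")[ev_nuc[seq_len(nev)] + 1L],
                       stringsAsFactors = FALSE)
  if (mirrored) {
    swap <- c(assoc_plus = "assoc_minus", assoc_minus = "assoc_plus",
              loss_plus = "loss_minus", loss_minus = "loss_plus")
    hit <- events$type %in% names(swap)
    events$type[hit] <- unname(swap[events$type[hit]])
  }
  snapshots <- data.frame(time = snap$time[seq_len(snap_i - 1L)],
                          polymer = snap$polymer[seq_len(snap_i - 1L)],
                          n_fil = snap$n_fil[seq_len(snap_i - 1L)],
                          free_T = snap$free_T[seq_len(snap_i - 1L)],
                          free_D = snap$free_D[seq_len(snap_i - 1L)])
  if (record_states) snapshots$label <- snap$label[seq_len(snap_i - 1L)]
  structure(list(events = events, snapshots = snapshots,
                 final_state = make_sim_state(filaments, free),
                 final_ids = fil_ids,
                 exposures = expos, counts = counts,
                 t_end = t, termination = termination,
                 params = params, seed = seed, mirrored = mirrored),
            class = "ssa_trajectory")
}

# canonical multiset label of a small closed-system state, e.g. "4+2|m0"
canonical_state_label <- function(filaments, free) {
  lens <- sort(vapply(filaments, length, 1L), decreasing = TRUE)
  paste0(if (length(lens)) paste(lens, collapse = "+") else "-",
         "|m", sum(free))
}

#' @export
print.ssa_trajectory <- function(x, ...) {
  st <- x$final_state
  cat(sprintf(
    "SSA trajectory: %d events to t = %.3g (%s); %d filament(s), %d+%d free monomers\n",
    nrow(x$events), x$t_end, x$termination, length(st$filaments),
    st$free[["T"]], st$free[["D"]]))
  invisible(x)
}
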