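# Exact small-system stationary distributions and closed-form equilibria
# used as independent oracles for the stochastic simulator.

# all states of a closed system of n subunits with all-NTP nucleotides:
# multisets of filament lengths (parts >= 2) plus free monomers
enumerate_closed_states <- function(n_total) {
  # generate with non-increasing parts >= 2 so each multiset appears once
  rec2 <- function(remaining, parts, max_part) {
    out[[length(out) + 1L]] <<- list(lengths = parts, free = remaining)
    L <- min(remaining, max_part)
    while (L >= 2L) {
      rec2(remaining - L, c(parts, L), L)
      L <- L - 1L
    }
  }
  out <- list()
  rec2(n_total, integer(0), n_total)
  out
}

state_key <- function(st) {
  paste0(if (length(st$lengths)) paste(sort(st$lengths, decreasing = TRUE),
                                       collapse = "+") else "-",
         "|m", st$free)
}

#' Exact stationary distribution of a small closed system
#'
#' Enumerates the full state space of a closed system with `n_total`
#' subunits (all NTP; requires `k_hyd = 0`) — every multiset of filament
#' lengths plus free monomers — builds the CTMC generator from the same
#' elementary rates as the simulator, and solves for the stationary
#' distribution by a linear solve. This is the correctness oracle for
#' [run_ssa()].
#'
#' @param params a [sim_params()] in `closed_system` mode with `k_hyd = 0`.
#' @param n_total total subunit count (<= 8; the space grows quickly).
#' @return Named numeric vector of stationary probabilities; names are
#'   canonical state labels like `"4+2|m0"`. Attribute `"Q"` carries the
#'   generator.
#' @export
exact_stationary_small <- function(params, n_total = params$n_total) {
  stopifnot(inherits(params, "sim_params"))
  if (params$mode != "closed_system") stop("oracle requires closed_system mode")
  if (params$k_hyd != 0) stop("oracle enumerates the all-NTP space; set k_hyd = 0")
  if (n_total > 8) stop("state space cap exceeded (n_total <= 8)")
  if (n_total != params$n_total) stop("n_total must match params$n_total")
  rt <- build_rates(params)
  omega <- params$n_total / params$c_total
  states <- enumerate_closed_states(n_total)
  keys <- vapply(states, state_key, character(1))
  ns <- length(states)
  if (ns == 1L) {
    pi <- 1; names(pi) <- keys
    return(pi)
  }
  idx <- function(lengths, free) {
    match(state_key(list(lengths = lengths, free = free)), keys)
  }
  Q <- matrix(0, ns, ns, dimnames = list(keys, keys))
  add <- function(i, j, rate) {
    if (rate > 0) Q[i, j] <<- Q[i, j] + rate
  }
  # per-filament loss rate over NTP interfaces: minus end + plus end
  # (the plus-end constant already carries any dissociation asymmetry)
  loss_rate <- rt$end_loss_T_minus + rt$end_loss_T_plus
  assoc_rate <- rt$assoc_plus + rt$assoc_minus
  for (i in seq_len(ns)) {
    st <- states[[i]]
    m <- st$free
    lens <- st$lengths
    # nucleation
    if (m >= 2L) add(i, idx(c(lens, 2L), m - 2L), rt$nucleation * m * (m - 1) / omega)
    tab <- table(lens)
    for (nm in names(tab)) {
      L <- as.integer(nm)
      k <- as.integer(tab[[nm]])
      rest <- lens[-match(L, lens)]
      # association at either end
      if (m >= 1L) add(i, idx(c(rest, L + 1L), m - 1L), k * assoc_rate * m / omega)
      if (L == 2L) {
        add(i, idx(rest, m + 2L), k * rt$dimer_diss_T)
      } else {
        add(i, idx(c(rest, L - 1L), m + 1L), k * loss_rate)
      }
      if (params$enable_breakage && L >= 4L) {
        for (cut in 2:(L - 2L)) {
          add(i, idx(c(rest, cut, L - cut), m), k * rt$breakage_T)
        }
      }
    }
    if (params$enable_annealing && length(lens) >= 2L) {
      nf <- length(lens)
      for (x in seq_len(nf - 1)) for (y in (x + 1):nf) {
        rest <- lens[-c(x, y)]
        # ordered pair (x below y) and (y below x): same merged multiset
        add(i, idx(c(rest, lens[x] + lens[y]), m), 2 * rt$annealing / omega)
      }
    }
  }
  diag(Q) <- -rowSums(Q)
  A <- rbind(t(Q), rep(1, ns))
  b <- c(rep(0, ns), 1)
  pi <- as.numeric(qr.solve(A, b))
  pi[pi < 0 & pi > -1e-12] <- 0
  names(pi) <- keys
  attr(pi, "Q") <- Q
  pi
}

#' Isodesmic assembly equilibrium (closed form)
#'
#' For isodesmic (single equilibrium constant `K` per added subunit)
#' assembly at total concentration `c_total`, the free-monomer
#' concentration solves `c_total = c1 / (1 - K c1)^2`; species of length n
#' have concentration `K^(n-1) c1^n` (a geometric length distribution with
#' ratio `q = K c1`).
#'
#' @param K stepwise association constant (1/conc).
#' @param c_total total subunit concentration.
#' @return List: `c1` (free monomer), `mass_fraction` (in species of length
#'   >= 2), `q` (geometric ratio), `mean_length` (number-average length of
#'   polymers >= 2).
#' @export
isodesmic_equilibrium <- function(K, c_total) {
  stopifnot(K > 0, c_total >= 0)
  if (c_total == 0) return(list(c1 = 0, mass_fraction = 0, q = 0, mean_length = NA))
  c1 <- (2 * K * c_total + 1 - sqrt(4 * K * c_total + 1)) / (2 * K^2 * c_total)
  q <- K * c1
  # number concentration of n-mers: K^(n-1) c1^n = c1 q^(n-1)
  mass_poly <- c_total - c1
  num_poly <- c1 * q / (1 - q)           # sum over n >= 2 of c1 q^(n-1)
  list(c1 = c1, mass_fraction = mass_poly / c_total, q = q,
       mean_length = if (num_poly > 0) mass_poly / num_poly else NA)
}

#' Stepwise elongation constant of the filament model
#'
#' Adding one closed monomer to a filament end gains one interface and pays
#' one switch: `K = exp(-(dG_interface_T + dG_switch)) / c0`.
#'
#' @param params a [sim_params()].
#' @return Association constant, 1/conc.
#' @export
elongation_K <- function(params) {
  exp(-(params$dG_interface_T + params$dG_switch)) / params$c0
}

#' Critical concentration (nucleation-elongation closed form)
#'
#' Above the critical concentration the free monomer pool pins at
#' `c_crit = c0 * exp(dG_interface_T + dG_switch)` (the inverse of the
#' elongation constant) and all additional subunits enter polymer; the
#' switch cost suppresses nucleation by `exp(-dG_switch)` relative to
#' elongation, which is what makes assembly cooperative.
#'
#' @param params a [sim_params()].
#' @return Critical concentration in units of c0.
#' @export
critical_concentration <- function(params) {
  params$c0 * exp(params$dG_interface_T + params$dG_switch)
}

#' Closed-form dimer occupancy of a 2-subunit closed system
#'
#' With two subunits in volume `Omega = n_total / c_total` the system is a
#' two-state chain (2 monomers <-> dimer, two distinguishable dimer
#' orientations) with occupancy `K / (1 + K)`,
#' `K = 2 exp(-dG_interface_T - 2 dG_switch) / (Omega c0)`.
#'
#' @param params a [sim_params()] (closed system, n_total = 2).
#' @return Stationary probability of the dimer state.
#' @export
dimer_occupancy <- function(params) {
  omega <- params$n_total / params$c_total
  K <- 2 * exp(-params$dG_interface_T - 2 * params$dG_switch) / (omega * params$c0)
  K / (1 + K)
}
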