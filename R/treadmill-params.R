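#' Parameters of the filament kinetics simulator
#'
#' Reduced-unit parameterization of a single-stranded, tubulin-like filament
#' in which the interface nucleotide sits on the lower subunit's top face.
#' Energies are in kT (negative = favorable), concentrations in units of the
#' reference concentration `c0`, times in units of `1 / (k_on * c0)` when
#' `k_on = c0 = 1`.
#'
#' Two variants are supported. The `"switch"` variant carries a
#' polymerization-associated conformational switch: free monomers are closed,
#' polymerized subunits open, and the closed-to-open cost `dG_switch` is paid
#' on joining a filament and recovered on leaving one — which makes subunit
#' loss from ends faster than breakage of an equivalent interface inside the
#' filament (the two halves of a broken filament stay polymerized and cannot
#' cash in the switch). The `"rigid"` variant forces `dG_switch = 0` and
#' `end_asymmetry = 1`: isodesmic assembly with no coupling of structural and
#' kinetic polarity.
#'
#' `end_asymmetry` is a kinetic prefactor on the reactions at the
#' `asymmetric_end`: subunit addition at either end has the same net energy
#' change but proceeds through stereochemically different pathways, so the
#' factor multiplies association and dissociation alike by default
#' (`asymmetry_on = "both"`), leaving every equilibrium constant untouched.
#'
#' @param variant `"switch"` or `"rigid"`.
#' @param k_on base association rate constant, 1/(conc * s).
#' @param end_asymmetry unitless factor (>= 0) applied at `asymmetric_end`.
#' @param asymmetric_end `"plus"` (top face exposed) or `"minus"`. The label
#'   is structural; no claim is made about which biological end it is.
#'   `"minus"` is realized as the exact head-to-tail mirror of the `"plus"`
#'   process (ends relabelled in the emitted log).
#' @param asymmetry_on `"both"`, `"association"` or `"dissociation"`.
#' @param dG_interface_T,dG_interface_D interface free energies for NTP/NDP
#'   interfaces, kT (NTP interfaces are the stronger, i.e. more negative).
#' @param dG_switch closed-to-open conformational cost, kT, >= 0.
#' @param k_hyd hydrolysis rate per formed (buried) NTP interface, 1/s.
#' @param k_exch nucleotide exchange rate per solvent-exposed NDP, 1/s.
#' @param c0 reference concentration (sets the dissociation scale), default 1.
#' @param mode `"fixed_monomer"` (clamped free-monomer bath, seeded
#'   filament) or `"closed_system"` (finite pool, subunit count conserved).
#' @param c_free free NTP-monomer concentration for `fixed_monomer`, in c0.
#' @param c_total total subunit concentration for `closed_system`, in c0.
#' @param n_total total subunit count for `closed_system` (sets the volume
#'   `Omega = n_total / c_total`).
#' @param exchange_in_filament should the solvent-exposed terminal nucleotide
#'   of a filament exchange NDP -> NTP (default TRUE)?
#' @param enable_breakage allow internal interface breakage (default TRUE).
#' @param enable_annealing allow end-to-end joining of two filaments
#'   (default FALSE).
#' @param init_length seeded filament length for `fixed_monomer` runs.
#' @param seed default PRNG seed for [run_ssa()].
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(variant = c("switch", "rigid"),
                       k_on = 1, end_asymmetry = 5,
                       asymmetric_end = c("plus", "minus"),
                       asymmetry_on = c("both", "association", "dissociation"),
                       dG_interface_T = -13, dG_interface_D = -9,
                       dG_switch = 8, k_hyd = 0.02, k_exch = 10, c0 = 1,
                       mode = c("fixed_monomer", "closed_system"),
                       c_free = 0.07, c_total = NULL, n_total = NULL,
                       exchange_in_filament = TRUE,
                       enable_breakage = TRUE, enable_annealing = FALSE,
                       init_length = 20L, seed = 1L) {
  variant <- match.arg(variant)
  mode <- match.arg(mode)
  asymmetric_end <- match.arg(asymmetric_end)
  asymmetry_on <- match.arg(asymmetry_on)
  if (variant == "rigid") {
    dG_switch <- 0
    end_asymmetry <- 1
  }
  if (any(c(k_on, k_hyd, k_exch, end_asymmetry, c0) < 0)) stop("rates must be >= 0")
  if (dG_switch < 0) stop("dG_switch must be >= 0 (closed -> open cost)")
  if (mode == "closed_system") {
    if (is.null(c_total) || is.null(n_total)) {
      stop("closed_system mode needs c_total and n_total")
    }
    if (c_total <= 0 || n_total < 1) stop("invalid c_total / n_total")
  } else if (c_free < 0) stop("c_free must be >= 0")
  structure(list(variant = variant, k_on = k_on, end_asymmetry = end_asymmetry,
                 asymmetric_end = asymmetric_end, asymmetry_on = asymmetry_on,
                 dG_interface_T = dG_interface_T, dG_interface_D = dG_interface_D,
                 dG_switch = dG_switch, k_hyd = k_hyd, k_exch = k_exch, c0 = c0,
                 mode = mode, c_free = c_free, c_total = c_total,
                 n_total = n_total,
                 exchange_in_filament = exchange_in_filament,
                 enable_breakage = enable_breakage,
                 enable_annealing = enable_annealing,
                 init_length = as.integer(init_length), seed = as.integer(seed)),
            class = "sim_params")
}

#' Reaction rate table
#'
#' Expands [sim_params()] into the elementary rate constants of the model,
#' all detailed-balance consistent:
#' \itemize{
#' \item association at the minus end `k_on * c`, at the plus end
#'   `k_on * end_asymmetry * c` (asymmetry optionally on association,
#'   dissociation or both);
#' \item end dissociation over an interface of nucleotide state X at
#'   `k_on * c0 * exp(dG_X + dG_switch)` — the departing subunit relaxes to
#'   the closed monomer form, and that switch payoff makes end loss fast;
#' \item internal breakage of an X interface at `k_on * c0 * exp(dG_X)` —
#'   no switch payoff, because both new end subunits remain in filaments;
#' \item dimer nucleation association scaled by `exp(-dG_switch)` (two
#'   switches paid, one interface gained) with dimer dissolution at the end
#'   dissociation rate, so K_dimer = exp(-dG_X - 2 dG_switch) / c0;
#' \item hydrolysis `k_hyd` per buried NTP interface; exchange `k_exch` per
#'   solvent-exposed NDP; annealing at `k_on` per ordered filament pair.
#' }
#'
#' @param params a [sim_params()].
#' @return An object of class `rate_table`: named list of rate constants
#'   plus a printable data.frame under `$table`.
#' @export
build_rates <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  a <- p$end_asymmetry
  a_assoc <- if (p$asymmetry_on %in% c("both", "association")) a else 1
  a_diss <- if (p$asymmetry_on %in% c("both", "dissociation")) a else 1
  s <- p$dG_switch
  base_off <- function(dG) p$k_on * p$c0 * exp(dG + s)
  rt <- list(
    assoc_plus = p$k_on * a_assoc,          # x concentration
    assoc_minus = p$k_on,                   # x concentration
    nucleation = p$k_on * exp(-s),          # x c^2 (ordered pair)
    end_loss_T_plus = base_off(p$dG_interface_T) * a_diss,
    end_loss_D_plus = base_off(p$dG_interface_D) * a_diss,
    end_loss_T_minus = base_off(p$dG_interface_T),
    end_loss_D_minus = base_off(p$dG_interface_D),
    dimer_diss_T = base_off(p$dG_interface_T),
    dimer_diss_D = base_off(p$dG_interface_D),
    breakage_T = p$k_on * p$c0 * exp(p$dG_interface_T),
    breakage_D = p$k_on * p$c0 * exp(p$dG_interface_D),
    hydrolysis = p$k_hyd,
    exchange = p$k_exch,
    annealing = p$k_on                      # x 1/Omega per ordered pair
  )
  tab <- data.frame(reaction = names(rt), rate = unlist(rt), row.names = NULL)
  structure(c(rt, list(table = tab, params = p)), class = "rate_table")
}

#' Mirror a parameter set end-for-end
#'
#' Swaps the asymmetric end; the mirrored process is the head-to-tail mirror
#' image of the original, so every end-resolved observable changes sign.
#'
#' @param params a [sim_params()].
#' @return A [sim_params()] with `asymmetric_end` swapped.
#' @export
mirror_params <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  params$asymmetric_end <- if (params$asymmetric_end == "plus") "minus" else "plus"
  params
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(
    "sim_params (%s, %s): k_on=%g, asym=%g@%s(%s), dG_T=%g, dG_D=%g, dG_switch=%g,\n  k_hyd=%g, k_exch=%g, %s\n",
    x$variant, x$mode, x$k_on, x$end_asymmetry, x$asymmetric_end, x$asymmetry_on,
    x$dG_interface_T, x$dG_interface_D, x$dG_switch, x$k_hyd, x$k_exch,
    if (x$mode == "fixed_monomer") sprintf("c_free=%g", x$c_free)
    else sprintf("c_total=%g, n_total=%d", x$c_total, x$n_total)))
  invisible(x)
}

#' @export
print.rate_table <- function(x, ...) {
  print(x$table, row.names = FALSE)
  invisible(x)
}
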