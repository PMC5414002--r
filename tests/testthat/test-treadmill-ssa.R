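test_that("a system with all rates zero produces no events and an unchanged state", {
  p <- sim_params(variant = "rigid", k_on = 0, k_hyd = 0, k_exch = 0)
  init <- make_sim_state(list(c(1L, 1L, 0L, 1L)))
  tr <- run_ssa(p, t_max = 10, seed = 1, init = init)
  expect_identical(nrow(tr$events), 0L)
  expect_identical(tr$final_state$filaments, init$filaments)
  expect_identical(tr$termination, "exhausted")
  expect_identical(tr$t_end, 10)
})

test_that("identical parameters and seed give bit-identical event logs", {
  p <- sim_params(variant = "switch")
  init <- make_sim_state(list(rep(1L, 20)))
  a <- run_ssa(p, t_max = 40, seed = 7, init = init)
  b <- run_ssa(p, t_max = 40, seed = 7, init = init)
  expect_identical(a$events, b$events)
  expect_identical(a$exposures, b$exposures)
  c2 <- run_ssa(p, t_max = 40, seed = 8, init = init)
  expect_false(identical(a$events, c2$events))
})

test_that("subunit count is conserved at every snapshot in a closed system", {
  p <- sim_params(variant = "switch", dG_interface_T = -5, dG_switch = 1, k_hyd = 0.1,
                  k_exch = 2, mode = "closed_system", c_total = 0.5, n_total = 40L,
                  end_asymmetry = 2)
  tr <- run_ssa(p, t_max = 300, seed = 17, snapshot_dt = 1)
  sn <- tr$snapshots
  expect_true(all(sn$polymer + sn$free_T + sn$free_D == 40L))
  fin <- tr$final_state
  expect_identical(sum(vapply(fin$filaments, length, 1L)) + sum(fin$free), 40L)
})

test_that("two-subunit closed system reproduces the analytic dimerization equilibrium", {
  p <- sim_params(variant = "switch", dG_interface_T = -4.5, dG_switch = 1, k_hyd = 0,
                  k_exch = 0, end_asymmetry = 1,
                  mode = "closed_system", c_total = 0.5, n_total = 2L)
  expected <- dimer_occupancy(p)
  t_max <- 20000
  tr <- run_ssa(p, t_max = t_max, seed = 42, snapshot_dt = 5, record_states = TRUE)
  occ <- mean(tr$snapshots$label == "2|m0")
  # time-average variance of a 2-state chain: p(1-p) * 2 tau / T, with the
  # relaxation time tau = 1 / (k_form + k_dissolve)
  rt <- build_rates(p)
  omega <- p$n_total / p$c_total
  k_form <- rt$nucleation * 2 / omega
  tau <- 1 / (k_form + rt$dimer_diss_T)
  sd_occ <- sqrt(expected * (1 - expected) * 2 * tau / t_max)
  expect_lt(abs(occ - expected), 4 * sd_occ)
  # and the enumerated oracle agrees with the closed form exactly
  pi <- exact_stationary_small(p)
  expect_equal(unname(pi["2|m0"]), expected, tolerance = 1e-10)
})

test_that("the exact stationary oracle handles degenerate and enriched cases", {
  p1 <- sim_params(variant = "switch", mode = "closed_system", c_total = 1,
                   n_total = 1L, k_hyd = 0)
  pi1 <- exact_stationary_small(p1)
  expect_identical(unname(pi1), 1)
  expect_identical(names(pi1), "-|m1")
  p <- sim_params(variant = "switch", dG_interface_T = -5, dG_switch = 2, k_hyd = 0,
                  k_exch = 0, end_asymmetry = 1, mode = "closed_system",
                  c_total = 1, n_total = 4L)
  pi <- exact_stationary_small(p)
  expect_equal(sum(pi), 1, tolerance = 1e-10)
  expect_setequal(names(pi), c("-|m4", "4|m0", "3|m1", "2|m2", "2+2|m0"))
  # stationarity: pi Q = 0
  expect_lt(max(abs(as.numeric(pi %*% attr(pi, "Q")))), 1e-12)
  expect_error(exact_stationary_small(sim_params(mode = "closed_system",
                                                 c_total = 1, n_total = 4L,
                                                 k_hyd = 0.1)), "k_hyd")
})

test_that("SSA time-average histogram matches the enumerated CTMC (n_total = 4)", {
  # fast-mixing regime so snapshots 10 time units apart are near-independent
  p <- sim_params(variant = "switch", dG_interface_T = -2, dG_switch = 1, k_hyd = 0,
                  k_exch = 0, end_asymmetry = 1, mode = "closed_system",
                  c_total = 1, n_total = 4L)
  pi <- exact_stationary_small(p)
  tr <- run_ssa(p, t_max = 8000, seed = 7, snapshot_dt = 10, record_states = TRUE)
  obs <- table(factor(tr$snapshots$label, levels = names(pi)))
  chi <- suppressWarnings(stats::chisq.test(obs, p = as.numeric(pi)))
  expect_gt(chi$p.value, 0.01)
})

test_that("waiting times at a fixed state are exponential with the total-propensity rate", {
  st <- make_sim_state(list(c(1L, 1L, 0L, 1L, 0L, 1L)), free = c(T = 5, D = 2))
  p <- sim_params(variant = "switch", mode = "closed_system", c_total = 0.5,
                  n_total = 13L)
  w <- sample_waiting_times(p, st, 10000, seed = 8)
  expect_equal(w$rate, total_propensity(st, p))
  ks <- stats::ks.test(w$times, "pexp", rate = w$rate)
  expect_gt(ks$p.value, 0.01)
})

test_that("rigid-variant event counts are end-symmetric under label exchange", {
  # equilibrium rigid filament: association events at the plus and minus end
  # are exchangeable, so the plus-end share is Binomial(n, 1/2)
  p <- sim_params(variant = "rigid", k_hyd = 0, dG_interface_T = -4,
                  dG_interface_D = -4, c_free = 0.98 * exp(-4), k_exch = 0,
                  init_length = 60L, enable_breakage = FALSE)
  tr <- run_ssa(p, t_max = 8000, seed = 15)
  ev <- tr$events
  n_plus <- sum(ev$type == "assoc_plus")
  n_minus <- sum(ev$type == "assoc_minus")
  expect_gt(n_plus + n_minus, 50)
  bt <- stats::binom.test(n_plus, n_plus + n_minus, p = 0.5)
  expect_gt(bt$p.value, 0.01)
  lt <- stats::binom.test(sum(ev$type == "loss_plus"),
                          sum(ev$type %in% c("loss_plus", "loss_minus")), p = 0.5)
  expect_gt(lt$p.value, 0.01)
})
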