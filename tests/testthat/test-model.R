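test_that("firing rate is a bounded increasing sigmoid with the sqrt(2) exponent", {
  expect_equal(firing_rate(-50, 0.5, -50, 3), 0.25)          # midpoint
  expect_equal(firing_rate(-1e4, 0.5, -50, 3), 0)            # saturation
  expect_equal(firing_rate(1e4, 0.5, -50, 3), 0.5)
  # one threshold SD above threshold, S_max = 0.5/ms
  expect_equal(firing_rate(-47, 0.5, -50, 3), 0.5 / (1 + exp(-sqrt(2))),
               tolerance = 1e-12)
  h <- seq(-90, -10, by = 0.5)
  expect_true(all(diff(firing_rate(h, 0.3, -45, 5)) > 0))
  expect_error(firing_rate(-50, 0.5, -50, 0), "sigma")
  # the exponent constant is configurable
  withr::with_options(list(alphamass.sigmoid_scale = 2), {
    expect_equal(firing_rate(-47, 0.5, -50, 3), 0.5 / (1 + exp(-2)),
                 tolerance = 1e-12)
  })
})

test_that("the uncoupled system rests at the resting potentials", {
  eq <- find_equilibrium(fx_uncoupled())
  expect_equal(eq$h_e, -70, tolerance = 1e-10)
  expect_equal(eq$h_i, -70, tolerance = 1e-10)
  expect_equal(unname(eq$I), rep(0, 4), tolerance = 1e-12)
  expect_lt(eq$residual, 1e-9)
})

test_that("every equilibrium zeroes the ODE right-hand side to 1e-9", {
  for (th in fx_stable_thetas(25)) {
    eq <- suppressWarnings(find_equilibrium(denormalize_params(th)))
    expect_lt(eq$residual, 1e-9)
    # synaptic steady states satisfy the closed form (Gamma e / gamma) (N S + p)
    p <- unclass(denormalize_params(th))
    Se <- firing_rate(eq$h_e, p["S_e_max"], p["mu_e"], p["sigma_e"])
    Si <- firing_rate(eq$h_i, p["S_i_max"], p["mu_i"], p["sigma_i"])
    expect_equal(unname(eq$I["I_ee"]),
                 unname(p["Gamma_e"] * exp(1) / p["gamma_e"] * (p["N_ee"] * Se + p["p_ee"])),
                 tolerance = 1e-9)
    expect_equal(unname(eq$I["I_ii"]),
                 unname(p["Gamma_i"] * exp(1) / p["gamma_i"] * p["N_ii"] * Si),
                 tolerance = 1e-9)
  }
})

test_that("single-loop equilibrium matches a 1-d bisection oracle", {
  p <- unclass(fx_uncoupled())
  p["N_ee"] <- 3000
  p <- npm_params(values = p)
  eq <- find_equilibrium(p)
  # self-consistency in h_e alone: tau_e dh_e/dt = 0 with I_ee = I_ee*(h_e)
  f <- function(he) {
    v <- unclass(p)
    Se <- firing_rate(he, v["S_e_max"], v["mu_e"], v["sigma_e"])
    Iee <- v["Gamma_e"] * exp(1) / v["gamma_e"] * v["N_ee"] * Se
    wee <- (v["h_e_eq"] - he) / abs(v["h_e_eq"] - v["h_e_rest"])
    unname(v["h_e_rest"] - he + wee * Iee)
  }
  oracle <- uniroot(f, c(-100, 0), tol = 1e-12)$root
  expect_equal(eq$h_e, oracle, tolerance = 1e-8)
})

test_that("parameter sets are classified into exactly one stability class", {
  set.seed(12)
  seen <- character(0)
  for (i in 1:40) {
    cl <- classify_params(denormalize_params(runif(22, -1, 1)))
    expect_true(cl %in% c("stable", "unstable", "no_equilibrium"))
    seen <- union(seen, cl)
  }
  expect_true("stable" %in% seen)
})

test_that("unstable parameter sets raise a distinct catchable condition", {
  set.seed(5)
  th_un <- NULL
  for (i in 1:500) {
    th <- runif(22, -1, 1)
    if (classify_params(denormalize_params(th)) == "unstable") {
      th_un <- th
      break
    }
  }
  expect_false(is.null(th_un))
  p <- denormalize_params(th_un)
  expect_error(find_equilibrium(p), class = "alphamass_unstable")
  expect_error(model_spectrum(p, c(2, 10)), class = "alphamass_unstable")
  # the fitting layers translate the condition into penalty / zero likelihood
  spec <- fx_spectrum()
  expect_equal(ls_cost(th_un, spec, normalized = TRUE), 1e12)
  expect_identical(log_likelihood(th_un, spec, normalized = TRUE), -Inf)
})

test_that("linearization of the uncoupled system has the closed-form eigenvalues", {
  p <- fx_uncoupled()
  ss <- linearize(p)
  v <- unclass(p)
  want <- c(-1 / v[["tau_e"]], -1 / v[["tau_i"]],
            rep(-v[["gamma_e"]], 4), rep(-v[["gamma_i"]], 4))
  expect_equal(sort(Re(ss$eigenvalues)), sort(want), tolerance = 1e-8)
  expect_equal(max(abs(Im(ss$eigenvalues))), 0, tolerance = 1e-8)
  expect_true(ss$stable)
  # C selects h_e only
  expect_equal(sum(ss$C != 0), 1L)
  expect_equal(unname(ss$C["h_e"]), 1)
  # B drives dI_ee/dt only, with amplitude Gamma_e gamma_e e
  expect_equal(sum(ss$B != 0), 1L)
  expect_equal(unname(ss$B["dI_ee"]),
               unname(v[["Gamma_e"]] * v[["gamma_e"]] * exp(1)))
})

test_that("the analytic Jacobian matches central finite differences", {
  for (th in fx_stable_thetas(20)) {
    p <- denormalize_params(th)
    eq <- suppressWarnings(find_equilibrium(p))
    ss <- linearize(p, eq)
    x0 <- c(eq$h_e, eq$h_i, eq$I["I_ee"], 0, eq$I["I_ie"], 0,
            eq$I["I_ei"], 0, eq$I["I_ii"], 0)
    h <- 1e-6
    Afd <- matrix(0, 10, 10)
    for (j in 1:10) {
      e <- numeric(10); e[j] <- h
      Afd[, j] <- (ode_rhs(p, x0 + e) - ode_rhs(p, x0 - e)) / (2 * h)
    }
    expect_lt(max(abs(Afd - unname(ss$A))) / max(abs(ss$A)), 1e-5)
    expect_identical(ss$stable, max(Re(ss$eigenvalues)) < 0)
  }
})

test_that("transfer gain decays at high frequency and the two routes agree", {
  gt <- fx_ground_truth()
  ss <- linearize(gt$params)
  tail_f <- c(1000, 3000, 10000)
  g <- transfer_gain(ss, tail_f)
  expect_true(all(diff(g) < 0))
  expect_lt(g[3], 1e-10 * max(transfer_gain(ss, c(5, 10))))
  # closed-form spectrum (hot path) vs full state-space solve
  freqs <- seq(2, 20, by = 0.25)
  expect_equal(model_spectrum(gt$params, freqs), transfer_gain(ss, freqs),
               tolerance = 1e-10)
  # direct linear solve vs explicit matrix inverse at one frequency
  w <- 2 * pi * 10 / 1000
  M <- diag(10) * 1i * w - unname(ss$A)
  g_solve <- Mod(sum(ss$C * solve(M, as.complex(ss$B))))^2
  g_inv <- Mod(sum(ss$C * (solve(M) %*% as.complex(ss$B))))^2
  expect_equal(g_solve, g_inv, tolerance = 1e-10)
  expect_equal(g_solve, transfer_gain(ss, 10), tolerance = 1e-10)
})

test_that("model spectrum is positive, alpha-peaked for ground truths, and fast", {
  gt <- fx_ground_truth()
  freqs <- seq(2, 20, by = 0.25)
  S <- model_spectrum(gt$params, freqs)
  expect_length(S, 73)
  expect_true(all(is.finite(S) & S > 0))
  expect_true(freqs[which.max(S)] >= 8 && freqs[which.max(S)] <= 13)
  el <- system.time(for (i in 1:20) model_spectrum(gt$params, freqs))[3]
  expect_lt(el / 20, 0.05)
})

test_that("the model spectrum reproduces a frozen reference bit for bit", {
  ref <- read_spectrum(test_path("fixtures", "ref_spectrum.csv"))
  p <- denormalize_params(ref_theta())
  expect_equal(model_spectrum(p, ref$freqs), ref$power, tolerance = 1e-12)
})
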