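#' Two-stage reaction-network specification
#'
#' The full mass-action manifold of the multicomponent process:
#' \preformatted{
#'   stage 1 (kinetic resolution)   A_S + L -> I_S   (k1_S = s * k1_R)
#'                                  A_R + L -> I_R   (k1_R)
#'   stage 2 (coupling)             I_S + A_R -> P_SR (k2_hetero)
#'                                  I_R + A_S -> P_RS (k2_hetero)
#'                                  I_S + A_S -> P_SS (k2_homo)
#'                                  I_R + A_R -> P_RR (k2_homo)
#' }
#' A is the racemic substrate, L the unsymmetrical linker, I the
#' linker-bearing intermediate, P the dimeric product. Default units are
#' normalized: A0 = 2 (1 S + 1 R), L0 = A0 / 2 (one linker per two substrate
#' molecules, so the resolution stalls at exactly 50% conversion), k1_R = 1;
#' all reported outputs are dimensionless ratios.
#'
#' The timescale-separation regime of the sequential closed-form model
#' ("the coupling step is much slower than the resolution") is realized by
#' `separation_factor`: k2_homo = k1_R / separation_factor, with
#' k2_hetero = induction_ratio * k2_homo. `separation_factor = 1e3` makes
#' the deterministic simulation agree with the sequential closed forms to
#' about 1e-4 in e.e.; `separation_factor = 1` deliberately breaks the
#' assumption, and `induction_ratio != 1` breaks the no-induction
#' assumption.
#'
#' @param s Selectivity factor of the resolution stage (>= 1).
#' @param induction_ratio k2_hetero / k2_homo (1 = statistical coupling).
#' @param separation_factor k1_R / k2_homo (>= as large as the separation
#'   assumption demands; default 1e3).
#' @param A0 Initial racemic substrate amount (split ee0-weighted S/R).
#' @param L0 Initial linker amount; default `A0 / 2`.
#' @param ee0 Initial substrate e.e. (0 = racemate; nonzero values support
#'   mirror-symmetry and enantiopure-limit checks).
#' @param k1_R Rate constant scale (default 1).
#' @return Object of class `network_spec` bundling [kr_parameters()],
#'   [coupling_parameters()] and the initial amounts.
#' @export
network_spec <- function(s, induction_ratio = 1, separation_factor = 1e3,
                         A0 = 2, L0 = A0 / 2, ee0 = 0, k1_R = 1) {
  check_number(A0, "A0", lower = 0, strict_lower = TRUE)
  check_number(L0, "L0", lower = 0, strict_lower = TRUE)
  check_number(ee0, "ee0", lower = -1, upper = 1)
  check_number(separation_factor, "separation_factor", lower = 0, strict_lower = TRUE)
  check_number(induction_ratio, "induction_ratio", lower = 0, strict_lower = TRUE)
  kr <- kr_parameters(s, k1_R = k1_R)
  k2_homo <- kr$k1_R / separation_factor
  coupling <- coupling_parameters(k2_hetero = induction_ratio * k2_homo,
                                  k2_homo = k2_homo)
  structure(list(kr = kr, coupling = coupling,
                 A0 = as.numeric(A0), L0 = as.numeric(L0),
                 ee0 = as.numeric(ee0),
                 separation_factor = as.numeric(separation_factor)),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf(
    "<network_spec> s = %g, induction ratio = %g, separation = %g, A0 = %g (e.e. %g), L0 = %g\n",
    x$kr$s, x$coupling$induction_ratio, x$separation_factor, x$A0, x$ee0, x$L0))
  invisible(x)
}

species_names <- c("A_S", "A_R", "L", "I_S", "I_R",
                   "P_SR", "P_RS", "P_SS", "P_RR")

initial_state <- function(spec) {
  y <- c(A_S = spec$A0 * (1 + spec$ee0) / 2,
         A_R = spec$A0 * (1 - spec$ee0) / 2,
         L = spec$L0,
         I_S = 0, I_R = 0, P_SR = 0, P_RS = 0, P_SS = 0, P_RR = 0)
  y
}

network_rates <- function(y, k) {
  c(r1S = k[["k1_S"]] * y[["A_S"]] * y[["L"]],
    r1R = k[["k1_R"]] * y[["A_R"]] * y[["L"]],
    rSR = k[["k2_het"]] * y[["I_S"]] * y[["A_R"]],
    rRS = k[["k2_het"]] * y[["I_R"]] * y[["A_S"]],
    rSS = k[["k2_hom"]] * y[["I_S"]] * y[["A_S"]],
    rRR = k[["k2_hom"]] * y[["I_R"]] * y[["A_R"]])
}

network_rhs <- function(t, y, parms) {
  r <- network_rates(y, parms)
  list(c(A_S = -r[["r1S"]] - r[["rRS"]] - r[["rSS"]],
         A_R = -r[["r1R"]] - r[["rSR"]] - r[["rRR"]],
         L   = -r[["r1S"]] - r[["r1R"]],
         I_S = r[["r1S"]] - r[["rSR"]] - r[["rSS"]],
         I_R = r[["r1R"]] - r[["rRS"]] - r[["rRR"]],
         P_SR = r[["rSR"]], P_RS = r[["rRS"]],
         P_SS = r[["rSS"]], P_RR = r[["rRR"]]))
}

rate_params <- function(spec) {
  c(k1_S = spec$kr$k1_S, k1_R = spec$kr$k1_R,
    k2_het = spec$coupling$k2_hetero, k2_hom = spec$coupling$k2_homo)
}

new_trajectory <- function(times, states, metadata) {
  stopifnot(nrow(states) == length(times))
  structure(list(times = times,
                 states = as.data.frame(states),
                 metadata = metadata),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d time points over [0, %g] (%s)\n",
              length(x$times), max(x$times), x$metadata$mode))
  fin <- final_state(x)
  cat("  final amounts:\n")
  print(round(fin, 6))
  invisible(x)
}

#' Accessors for trajectory objects
#'
#' `final_state` returns the named species vector at the last time point;
#' `trajectory_distribution` the dimeric-product [product_distribution()]
#' at a given time index (default: last); `intermediate_pool` and
#' `substrate_pool` the corresponding [enantiomer_pool()]s.
#'
#' @param traj A `trajectory` from [simulate_deterministic()] or
#'   [simulate_stochastic()].
#' @param i Time index (default last).
#' @export
final_state <- function(traj) {
  unlist(traj$states[nrow(traj$states), species_names])
}

#' @rdname final_state
#' @export
trajectory_distribution <- function(traj, i = nrow(traj$states)) {
  st <- traj$states[i, ]
  product_distribution(st$P_SR, st$P_RS, st$P_SS, st$P_RR)
}

#' @rdname final_state
#' @export
intermediate_pool <- function(traj, i = nrow(traj$states)) {
  st <- traj$states[i, ]
  enantiomer_pool(st$I_S, st$I_R, "intermediate")
}

#' @rdname final_state
#' @export
substrate_pool <- function(traj, i = nrow(traj$states)) {
  st <- traj$states[i, ]
  enantiomer_pool(st$A_S, st$A_R, "substrate")
}

#' Conservation residuals of a trajectory
#'
#' Two exact invariants of the network: substrate units
#' `A_S + A_R + I_S + I_R + 2 * (P_SR + P_RS + P_SS + P_RR) = A0` and
#' linker units `L + I_S + I_R + P_SR + P_RS + P_SS + P_RR = L0`.
#' Returns the maximum relative residual of each over all time points.
#'
#' @param traj A `trajectory`.
#' @export
conservation_residuals <- function(traj) {
  s <- traj$states
  prod_sum <- s$P_SR + s$P_RS + s$P_SS + s$P_RR
  a0 <- traj$metadata$A0; l0 <- traj$metadata$L0
  c(substrate = max(abs(s$A_S + s$A_R + s$I_S + s$I_R + 2 * prod_sum - a0)) / a0,
    linker = max(abs(s$L + s$I_S + s$I_R + prod_sum - l0)) / l0)
}

#' Deterministic simulation of the full reaction network
#'
#' Integrates the mass-action rate equations of the nine-species network
#' with a stiffness-capable solver (`deSolve::ode`, `lsodar`), at tight
#' tolerances (relative 1e-10, absolute 1e-12) so that quantities quoted to
#' two significant figures are never solver-limited — the separated
#' timescale regime spans three or more decades in rate.
#'
#' With `t_end = NULL` the run continues to completion: integration stops
#' (via the solver's root finder) once every reaction-rate magnitude has
#' fallen below `eps_rate` times the fastest initial rate, subject to a
#' hard time cap `t_cap` (a warning is issued if the cap is hit before the
#' steady-state criterion).
#'
#' @param spec A [network_spec()].
#' @param t_end End time, or `NULL` to run to completion.
#' @param n_out Number of output time points (log-spaced after the first).
#' @param rtol,atol Solver tolerances.
#' @param eps_rate Steady-state threshold relative to the fastest initial
#'   rate (default 1e-10).
#' @param t_cap Hard time cap for run-to-completion (default 1e9 in
#'   normalized time units).
#' @param stop_at_conversion Optional conversion in (0, 1): terminate the
#'   integration exactly (solver root location) when the substrate pool
#'   `A_S + A_R` crosses `A0 * (1 - C)`; the last row of the trajectory is
#'   then the state at that conversion.
#' @return A `trajectory` whose states satisfy both conservation
#'   invariants to ~1e-8 relative.
#' @examples
#' tr <- simulate_deterministic(network_spec(s = 8))
#' hetero_ee(trajectory_distribution(tr))  # ~0.898
#' @export
simulate_deterministic <- function(spec, t_end = NULL, n_out = 400,
                                   rtol = 1e-10, atol = 1e-12,
                                   eps_rate = 1e-10, t_cap = 1e9,
                                   stop_at_conversion = NULL) {
  stopifnot(inherits(spec, "network_spec"))
  y0 <- initial_state(spec)
  parms <- rate_params(spec)
  r0 <- max(network_rates(y0, parms))
  if (r0 <= 0) stop_input("network has zero initial rate; nothing to simulate")
  run_to_completion <- is.null(t_end)
  t_max <- if (run_to_completion) t_cap else t_end
  # first output after ~1e-4 of the fastest initial timescale
  t1 <- 1e-4 * max(y0) / r0
  times <- unique(c(0, 10^seq(log10(t1), log10(t_max), length.out = n_out - 1)))
  a_target <- if (!is.null(stop_at_conversion)) {
    check_number(stop_at_conversion, "stop_at_conversion", lower = 0, upper = 1,
                 strict_lower = TRUE, strict_upper = TRUE)
    spec$A0 * (1 - stop_at_conversion)
  } else NULL
  rootfun <- if (run_to_completion || !is.null(a_target)) {
    function(t, y, parms) {
      g <- numeric(0)
      if (run_to_completion)
        g <- max(abs(network_rates(y, parms))) - eps_rate * r0
      if (!is.null(a_target))
        g <- c(g, y[["A_S"]] + y[["A_R"]] - a_target)
      g
    }
  } else NULL
  sol <- deSolve::ode(y = y0, times = times, func = network_rhs,
                      parms = parms, method = "lsodar",
                      rtol = rtol, atol = atol, rootfunc = rootfun)
  sol <- as.data.frame(sol)
  states <- sol[, species_names]
  if (min(as.matrix(states)) < -1e-10)
    stop_solver(sprintf("solver produced negative amount %.3g",
                        min(as.matrix(states))))
  states[states < 0] <- 0
  if (run_to_completion && is.null(a_target)) {
    fin <- unlist(states[nrow(states), ])
    if (max(abs(network_rates(fin, parms))) > eps_rate * r0 &&
        max(sol$time) >= t_cap * (1 - 1e-9))
      warning("time cap reached before steady-state criterion", call. = FALSE)
  }
  new_trajectory(sol$time, states,
                 metadata = list(mode = "deterministic", spec = spec,
                                 A0 = spec$A0, L0 = spec$L0,
                                 rtol = rtol, atol = atol,
                                 eps_rate = eps_rate,
                                 run_to_completion = run_to_completion))
}

#' Interpolate the network state at a given substrate conversion
#'
#' Locates the crossing of `A_S + A_R` through `A0 * (1 - C)` inside a
#' continuous run and interpolates every species there (monotone cubic
#' interpolation in conversion). Used to sample "the state at 50%
#' conversion" from a single trajectory.
#'
#' @param traj A `trajectory`.
#' @param C Target conversion of the substrate pool, in (0, 1).
#' @return Named species vector at the crossing.
#' @export
state_at_conversion <- function(traj, C) {
  check_number(C, "C", lower = 0, upper = 1, strict_lower = TRUE, strict_upper = TRUE)
  s <- traj$states
  a0 <- traj$metadata$A0
  conv <- 1 - (s$A_S + s$A_R) / a0
  if (C > max(conv))
    stop_domain(sprintf("trajectory only reaches conversion %.4f < %.4f",
                        max(conv), C))
  # strictly increasing subsequence (solver tails can stall or wiggle at
  # roundoff level)
  keep <- conv == cummax(conv) & !duplicated(conv)
  out <- vapply(species_names, function(nm) {
    stats::spline(conv[keep], s[[nm]][keep], xout = C, method = "natural")$y
  }, numeric(1))
  names(out) <- species_names
  out
}

#' Selectivity-factor sweep of the sequential model
#'
#' For each s, runs the sequential closed-form pipeline — resolution to 50%
#' conversion (where, by mass balance, intermediate and recovered substrate
#' have equal e.e.), then statistical coupling — and reports the
#' intermediate e.e., the final heterochiral e.e. and the final d.r.
#' All three columns are strictly increasing in s. With `ode = TRUE` the
#' full deterministic network (at the spec's separation and induction
#' settings) is run to completion as well and its final e.e./d.r. appended.
#'
#' @param s_values Selectivity factors, all >= 1.
#' @param induction_ratio,separation_factor Passed to [network_spec()] for
#'   the optional ODE columns.
#' @param ode Also run the full network per s (slower).
#' @return A data.frame with columns `s`, `ee_intermediate_50`, `ee_final`,
#'   `dr_final` (and `ee_final_ode`, `dr_final_ode` when `ode = TRUE`).
#' @examples
#' sweep_selectivity(c(1, 8, 28))
#' @export
sweep_selectivity <- function(s_values, induction_ratio = 1,
                              separation_factor = 1e3, ode = FALSE) {
  if (length(s_values) == 0) stop_input("empty s_values")
  bad <- which(s_values < 1)
  if (length(bad))
    stop_domain(sprintf("s_values[%d] = %g is < 1", bad[1], s_values[bad[1]]))
  ee_int <- vapply(s_values, ee_product_at_conversion, numeric(1), C = 0.5)
  out <- data.frame(s = s_values,
                    ee_intermediate_50 = ee_int,
                    ee_final = coupled_ee(ee_int, ee_int),
                    dr_final = coupled_dr(ee_int, ee_int))
  if (ode) {
    runs <- lapply(s_values, function(s) {
      tr <- simulate_deterministic(network_spec(
        s, induction_ratio = induction_ratio,
        separation_factor = separation_factor))
      d <- trajectory_distribution(tr)
      c(ee = hetero_ee(d), dr = dr_of(d))
    })
    out$ee_final_ode <- vapply(runs, `[[`, numeric(1), "ee")
    out$dr_final_ode <- vapply(runs, `[[`, numeric(1), "dr")
  }
  out
}
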