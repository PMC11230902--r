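#' Exact stochastic simulation of the reaction network
#'
#' Gillespie direct-method simulation of the same six-reaction mass-action
#' network as [simulate_deterministic()], in integer molecule counts. Serves
#' as an independent oracle for the deterministic solution: over replicates,
#' the mean final e.e. and d.r. converge to the deterministic values as the
#' molecule number grows.
#'
#' The initial substrate pool is scaled to `n_molecules` (split according to
#' `spec$ee0`), the linker to `n_molecules * L0 / A0`, and the bimolecular
#' rate constants are divided by the system-size factor
#' `omega = n_molecules / A0` so that concentrations match the deterministic
#' units. The seed is required and logged in the trajectory metadata; the
#' same seed and spec reproduce the trajectory bit-for-bit.
#'
#' @param spec A [network_spec()].
#' @param n_molecules Number of substrate molecules (>= 100).
#' @param seed Integer seed (required; no global-state dependence).
#' @param n_snapshots Approximate number of recorded states.
#' @return A `trajectory` with integer-valued states and metadata
#'   `seed`, `n_molecules`, `omega`, `n_events`.
#' @examples
#' tr <- simulate_stochastic(network_spec(s = 8), n_molecules = 1e4, seed = 1)
#' hetero_ee(trajectory_distribution(tr))
#' @export
simulate_stochastic <- function(spec, n_molecules, seed, n_snapshots = 200) {
  stopifnot(inherits(spec, "network_spec"))
  check_number(n_molecules, "n_molecules", lower = 100)
  if (length(seed) != 1L || !is.numeric(seed) || !is.finite(seed) ||
      seed != round(seed))
    stop_input("`seed` must be a single integer")
  nA <- round(n_molecules)
  nS <- round(nA * (1 + spec$ee0) / 2)
  nL <- round(nA * spec$L0 / spec$A0)
  y0 <- c(nS, nA - nS, nL, 0L, 0L, 0L, 0L, 0L, 0L)
  omega <- nA / spec$A0
  cs <- c(spec$kr$k1_S, spec$kr$k1_R,
          spec$coupling$k2_hetero, spec$coupling$k2_homo) / omega
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  res <- .ssa_run(as.integer(y0), cs, as.integer(n_snapshots))
  states <- res$states
  colnames(states) <- species_names
  new_trajectory(res$times, states,
                 metadata = list(mode = "stochastic", spec = spec,
                                 A0 = nA, L0 = nL,
                                 seed = as.integer(seed),
                                 n_molecules = nA, omega = omega,
                                 n_events = res$n_events))
}
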