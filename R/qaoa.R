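# Classical statevector simulation of QAOA on QUBO-derived diagonal
# Hamiltonians, with shot sampling and a CVaR objective.
#
# The QUBO cost becomes a diagonal Hamiltonian by substituting each binary
# variable with (I - Z)/2, so the energy of basis state |b> equals the cost
# of assignment b. The circuit is a Hadamard layer followed by p alternating
# cost layers exp(-i * gamma * H) (an elementwise phase on the diagonal) and
# mixer layers exp(-i * beta * sum_i X_i) (a product of single-qubit X
# rotations, applied axis by axis).

#' Diagonal Hamiltonian of a QUBO instance
#'
#' @param instance a `qubo_instance` with at most `n_max` variables.
#' @param n_max hard cap on qubit count (default 20; dense diagonal).
#' @return object of class `diagonal_hamiltonian` with `n_qubits`,
#'   `energies` (length `2^n`, entry `b + 1` = cost of bitstring `b`,
#'   little-endian) and `offset_included = TRUE`.
#' @export
hamiltonian_from_qubo <- function(instance, n_max = 20) {
  if (instance$n_vars > n_max)
    stop("hamiltonian_from_qubo requires n_vars <= ", n_max,
         ", got ", instance$n_vars)
  structure(list(
    n_qubits = instance$n_vars,
    energies = qubo_energies(instance, n_max = n_max),
    offset_included = TRUE
  ), class = "diagonal_hamiltonian")
}

apply_rx_axis <- function(state, q, n, c, s) {
  # exp(-i*beta*X) on qubit q: [[cos b, -i sin b], [-i sin b, cos b]]
  dim(state) <- c(2^(q - 1), 2, 2^(n - q))
  a0 <- state[, 1, , drop = FALSE]
  a1 <- state[, 2, , drop = FALSE]
  state[, 1, ] <- c * a0 - 1i * s * a1
  state[, 2, ] <- -1i * s * a0 + c * a1
  dim(state) <- 2^n
  state
}

#' QAOA output distribution by statevector simulation
#'
#' @param h a `diagonal_hamiltonian`.
#' @param gammas cost-layer angles, length `p`.
#' @param betas mixer-layer angles, length `p`.
#' @return numeric probability vector over the `2^n` bitstrings
#'   (little-endian order), summing to 1.
#' @export
qaoa_statevector <- function(h, gammas, betas) {
  if (length(gammas) != length(betas) || length(gammas) < 1)
    stop("gammas and betas must have equal length p >= 1")
  n <- h$n_qubits
  state <- rep(complex(real = 1 / sqrt(2^n)), 2^n)
  for (l in seq_along(gammas)) {
    state <- state * exp(-1i * gammas[l] * h$energies)
    cb <- cos(betas[l]); sb <- sin(betas[l])
    for (q in seq_len(n)) state <- apply_rx_axis(state, q, n, cb, sb)
  }
  p <- as.vector(Re(state * Conj(state)))
  p / sum(p)
}

#' Conditional value at risk of a sample of energies
#'
#' Mean of the `ceiling(alpha * n)` smallest energies; `alpha = 1` is the
#' plain mean and `alpha -> 1/n` approaches the minimum.
#'
#' @param energies non-empty numeric vector.
#' @param alpha fraction in (0, 1].
#' @return numeric scalar.
#' @export
cvar <- function(energies, alpha) {
  if (length(energies) == 0) stop("empty energy sample")
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  m <- ceiling(alpha * length(energies))
  mean(sort(energies)[seq_len(m)])
}

#' Run the CVaR-QAOA loop
#'
#' Shot-sampled, derivative-free optimization of the QAOA angles: at each
#' objective evaluation the exact statevector distribution is sampled
#' `shots` times and the CVaR of the sampled energies is returned to a
#' Nelder-Mead simplex search (restarted from fresh random initial angles
#' while the evaluation budget lasts). A final sample is drawn at the best
#' angles found; the lowest-energy sampled bitstring is the solution.
#' Fully reproducible for a fixed seed.
#'
#' @param h a `diagonal_hamiltonian`.
#' @param p number of QAOA layers (default 4).
#' @param shots samples per objective evaluation (default 256).
#' @param cvar_alpha CVaR fraction in (0, 1] (default 0.1).
#' @param max_iters objective-evaluation budget (default 100).
#' @param seed RNG seed.
#' @param init `"random"` (angles uniform in (0, 0.1*pi)) or `"ramp"`
#'   (linear ramp: gammas increasing, betas decreasing).
#' @param restart_iters simplex iterations per Nelder-Mead restart
#'   (default 25). Short restarted searches from fresh random angles
#'   navigate the shot-noisy CVaR landscape far better than one long
#'   descent, which tends to stall in a noise-induced basin.
#' @return object of class `qaoa_run`: `p`, `shots`, `cvar_alpha`,
#'   `max_iters`, `seed`, `trace` (data frame `iter`, `cvar`, plus the
#'   angles), `best_params`, `final_samples` (data frame `bitstring`,
#'   `energy`), `best_sample` (list `bitstring`, `energy`).
#' @export
run_qaoa <- function(h, p = 4, shots = 256, cvar_alpha = 0.1,
                     max_iters = 100, seed = 1, init = "random",
                     restart_iters = 25) {
  n <- h$n_qubits
  local_seed(seed, {
    iter <- 0L
    tr_cvar <- numeric(0)
    tr_par <- matrix(numeric(0), ncol = 2 * p)
    best_val <- Inf; best_par <- NULL
    objective <- function(par) {
      if (iter >= max_iters)
        stop(structure(class = c("qaoa_budget", "condition"),
                       list(message = "budget", call = NULL)))
      iter <<- iter + 1L
      probs <- qaoa_statevector(h, par[seq_len(p)], par[p + seq_len(p)])
      idx <- sample.int(length(probs), shots, replace = TRUE, prob = probs)
      val <- cvar(h$energies[idx], cvar_alpha)
      tr_cvar <<- c(tr_cvar, val)
      tr_par <<- rbind(tr_par, par)
      if (val < best_val) { best_val <<- val; best_par <<- par }
      val
    }
    init_par <- function() {
      if (init == "ramp") {
        c(seq(0.1, 1, length.out = p) * 0.1 * pi,
          seq(1, 0.1, length.out = p) * 0.1 * pi)
      } else runif(2 * p, 0, 0.1 * pi)
    }
    while (iter < max_iters) {
      done <- tryCatch({
        optim(init_par(), objective, method = "Nelder-Mead",
              control = list(maxit = restart_iters))
        FALSE
      }, qaoa_budget = function(e) TRUE)
      if (done) break
    }
    probs <- qaoa_statevector(h, best_par[seq_len(p)],
                              best_par[p + seq_len(p)])
    idx <- sample.int(length(probs), shots, replace = TRUE, prob = probs)
    bits <- idx - 1L
    energies <- h$energies[idx]
    k <- which.min(energies)
    trace <- data.frame(iter = seq_along(tr_cvar), cvar = tr_cvar)
    structure(list(
      p = p, shots = shots, cvar_alpha = cvar_alpha, max_iters = max_iters,
      seed = seed, trace = trace, params_trace = tr_par,
      best_params = best_par,
      final_samples = data.frame(bitstring = bits, energy = energies),
      best_sample = list(bitstring = bits[k], energy = energies[k])
    ), class = "qaoa_run")
  })
}

#' @export
print.qaoa_run <- function(x, ...) {
  cat(sprintf(
    "qaoa_run: p=%d, %d iterations, best sampled energy %.6g\n",
    x$p, nrow(x$trace), x$best_sample$energy))
  invisible(x)
}
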