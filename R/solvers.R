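# Classical QUBO solvers. All maintain the local-field vector
#   g_i = M_ii + 2 * sum_{j != i} M_ij x_j,
# so that flipping bit i changes the energy by dE_i = (1 - 2 x_i) g_i and a
# flip of bit k updates g in O(n). No full-matrix re-evaluation happens
# inside the search loops.

solver_result <- function(instance, x, energy, n_eval, trace, seed,
                          wall_ok = TRUE) {
  structure(list(
    best_assignment = x, best_energy = energy, n_evaluations = n_eval,
    trace = trace, seed = seed, wall_limit_honored = wall_ok
  ), class = "solve_result")
}

#' @export
print.solve_result <- function(x, ...) {
  cat(sprintf("solve_result: energy %.6g after %d evaluations\n",
              x$best_energy, x$n_evaluations))
  invisible(x)
}

local_fields <- function(M, x) {
  diag(M) + 2 * as.vector(M %*% x) - 2 * diag(M) * x
}

#' Exhaustive QUBO minimization
#'
#' Enumerates all `2^n` assignments (n <= 24). Ties are broken by the
#' lowest assignment read as a little-endian binary integer.
#'
#' @param instance a `qubo_instance`.
#' @return a `solve_result`.
#' @export
solve_exhaustive <- function(instance) {
  n <- instance$n_vars
  if (n > 24) stop("solve_exhaustive requires n_vars <= 24, got ", n)
  E <- qubo_energies(instance, n_max = 24)
  b <- which.min(E) - 1L  # first minimum = lowest integer
  x <- as.numeric(int_to_bits(b, n))
  solver_result(instance, x, E[b + 1], length(E),
                trace = data.frame(step = 0L, energy = E[b + 1]),
                seed = NA_integer_)
}

#' Simulated annealing for QUBO
#'
#' Single-bit-flip Metropolis sweeps under a geometric inverse-temperature
#' schedule, restarted from fresh random assignments; the best assignment
#' ever visited is returned. Deterministic for a fixed seed.
#'
#' @param instance a `qubo_instance`.
#' @param n_sweeps sweeps (each proposes `n_vars` flips) per restart
#'   (default 2000).
#' @param beta_schedule inverse-temperature range `c(start, end)`,
#'   start < end (default `c(0.1, 10)`).
#' @param n_restarts independent restarts (default 1).
#' @param seed RNG seed.
#' @return a `solve_result`.
#' @export
solve_anneal <- function(instance, n_sweeps = 2000,
                         beta_schedule = c(0.1, 10), n_restarts = 1,
                         seed = 1) {
  if (n_sweeps < 1) stop("n_sweeps must be >= 1")
  if (beta_schedule[1] >= beta_schedule[2])
    stop("invalid beta schedule: start must be < end")
  n <- instance$n_vars
  M <- instance$M
  betas <- exp(seq(log(beta_schedule[1]), log(beta_schedule[2]),
                   length.out = n_sweeps))
  local_seed(seed, {
    best_x <- NULL; best_E <- Inf; n_eval <- 0L
    tr_step <- integer(0); tr_E <- numeric(0)
    for (r in seq_len(n_restarts)) {
      x <- as.numeric(runif(n) < 0.5)
      g <- local_fields(M, x)
      E <- qubo_energy(instance, x)
      if (E < best_E) { best_E <- E; best_x <- x }
      for (sw in seq_len(n_sweeps)) {
        beta <- betas[sw]
        ks <- sample.int(n, n, replace = TRUE)
        us <- runif(n)
        for (p in seq_len(n)) {
          k <- ks[p]
          dE <- (1 - 2 * x[k]) * g[k]
          n_eval <- n_eval + 1L
          if (dE <= 0 || us[p] < exp(-beta * dE)) {
            s <- 1 - 2 * x[k]
            x[k] <- 1 - x[k]
            E <- E + dE
            g <- g + 2 * M[, k] * s
            g[k] <- g[k] - 2 * M[k, k] * s
            if (E < best_E) { best_E <- E; best_x <- x }
          }
        }
        tr_step <- c(tr_step, (r - 1L) * n_sweeps + sw)
        tr_E <- c(tr_E, best_E)
      }
    }
    solver_result(instance, best_x, best_E, n_eval,
                  trace = data.frame(step = tr_step, energy = tr_E),
                  seed = seed)
  })
}

#' Multistart tabu search for QUBO
#'
#' Steepest-descent single-flip moves with a recency tabu list; a tabu
#' move is allowed when it improves the best energy found so far
#' (aspiration). After `max_stagnation` consecutive non-improving moves
#' the search restarts from a fresh random assignment, up to `n_starts`
#' starts or `time_limit` seconds. Deterministic for a fixed seed when no
#' time limit is set.
#'
#' @param instance a `qubo_instance`.
#' @param tenure moves a flipped variable stays tabu; default
#'   `max(10, n_vars / 10)`.
#' @param max_stagnation non-improving moves before a restart (default 500).
#' @param n_starts number of random starts (default 10).
#' @param time_limit wall-clock budget in seconds, checked between moves
#'   (default NULL: none).
#' @param seed RNG seed.
#' @return a `solve_result`.
#' @export
solve_tabu <- function(instance, tenure = NULL, max_stagnation = 500,
                       n_starts = 10, time_limit = NULL, seed = 1) {
  n <- instance$n_vars
  M <- instance$M
  if (is.null(tenure)) tenure <- max(10, ceiling(n / 10))
  if (tenure < 1) stop("tenure must be >= 1")
  t0 <- Sys.time()
  over_time <- function() {
    !is.null(time_limit) &&
      as.numeric(difftime(Sys.time(), t0, units = "secs")) > time_limit
  }
  local_seed(seed, {
    best_x <- NULL; best_E <- Inf; n_eval <- 0L
    tr_step <- integer(0); tr_E <- numeric(0)
    move_no <- 0L
    wall_ok <- TRUE
    for (r in seq_len(n_starts)) {
      if (over_time()) break
      x <- as.numeric(runif(n) < 0.5)
      g <- local_fields(M, x)
      E <- qubo_energy(instance, x)
      if (E < best_E) { best_E <- E; best_x <- x }
      tabu_until <- integer(n)
      stagnation <- 0L
      while (stagnation < max_stagnation) {
        move_no <- move_no + 1L
        if (move_no %% 64L == 0L && over_time()) { wall_ok <- TRUE; break }
        dE <- (1 - 2 * x) * g
        n_eval <- n_eval + n
        cand <- dE
        blocked <- tabu_until >= move_no & (E + dE >= best_E)  # aspiration
        cand[blocked] <- Inf
        if (all(is.infinite(cand))) cand <- dE  # all tabu: ignore the list
        k <- which.min(cand)
        s <- 1 - 2 * x[k]
        x[k] <- 1 - x[k]
        E <- E + dE[k]
        g <- g + 2 * M[, k] * s
        g[k] <- g[k] - 2 * M[k, k] * s
        tabu_until[k] <- move_no + as.integer(tenure)
        if (E < best_E - 1e-12) {
          best_E <- E; best_x <- x; stagnation <- 0L
          tr_step <- c(tr_step, move_no); tr_E <- c(tr_E, best_E)
        } else stagnation <- stagnation + 1L
      }
    }
    solver_result(instance, best_x, best_E, n_eval,
                  trace = data.frame(step = tr_step, energy = tr_E),
                  seed = seed, wall_ok = wall_ok)
  })
}

#' Solve a QUBO and decode the result
#'
#' Convenience wrapper: run a solver and decode the best assignment into
#' walks (when the instance carries its source graph).
#'
#' @param instance a `qubo_instance` built by [build_qubo()].
#' @param method `"exhaustive"`, `"anneal"` or `"tabu"`.
#' @param seed RNG seed for the heuristic methods.
#' @param ... further arguments for the chosen solver.
#' @return list with `result` (a `solve_result`) and `decoded` (see
#'   [decode_assignment()]).
#' @export
solve_and_decode <- function(instance, method = "tabu", seed = 1, ...) {
  res <- switch(method,
    exhaustive = solve_exhaustive(instance),
    anneal = solve_anneal(instance, seed = seed, ...),
    tabu = solve_tabu(instance, seed = seed, ...),
    stop("unknown method '", method, "'")
  )
  decoded <- if (!is.null(instance$graph))
    decode_assignment(instance, res$best_assignment) else NULL
  list(result = res, decoded = decoded)
}
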