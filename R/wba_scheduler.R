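#' Warm-up bat-algorithm (WBA) learning-rate schedule
#'
#' The schedule has two phases. For the first `warmup_iterations =
#' floor(max_iterations / 20)` optimizer steps the learning rate ramps
#' linearly from `initial_learning_rate / warmup_iterations` up to
#' `initial_learning_rate`. Afterwards the rate decays multiplicatively by a
#' "loudness" factor
#' `loudness_min + (loudness_max - loudness_min) * exp(-pulse_rate * t / max_iterations)`
#' and is floored at `min_learning_rate`. Iterations are optimizer steps,
#' not epochs.
#'
#' @param max_iterations Total number of optimizer steps the run will take.
#' @param initial_learning_rate Peak rate reached at the end of warm-up.
#'   Default 4e-5, the rate used for full-scale transformer fine-tuning.
#' @param min_learning_rate Floor for the decay phase.
#' @param loudness_min,loudness_max Loudness band; must satisfy
#'   `loudness_min < loudness_max <= 1`.
#' @param pulse_rate Exponential shrink rate of the loudness.
#' @param exploration_enabled If `TRUE`, the decay phase may propose a
#'   seeded multiplicative perturbation of the rate (an extrapolation beyond
#'   the deterministic schedule; off by default).
#' @param rng_seed Seed for the optional exploration proposals.
#' @return An object of class `wba_state`.
#' @export
scheduler_state <- function(max_iterations,
                            initial_learning_rate = 4e-5,
                            min_learning_rate = 1e-6,
                            loudness_min = 0.95,
                            loudness_max = 1.0,
                            pulse_rate = 0.9,
                            exploration_enabled = FALSE,
                            rng_seed = 1L) {
  stopifnot(max_iterations >= 1,
            initial_learning_rate > 0,
            min_learning_rate > 0,
            min_learning_rate <= initial_learning_rate,
            loudness_min < loudness_max, loudness_max <= 1,
            pulse_rate > 0)
  structure(list(
    initial_learning_rate = initial_learning_rate,
    min_learning_rate = min_learning_rate,
    max_iterations = as.integer(max_iterations),
    warmup_iterations = compute_warmup_iterations(max_iterations),
    current_iteration = 0L,
    current_learning_rate = initial_learning_rate /
      compute_warmup_iterations(max_iterations),
    loudness_min = loudness_min,
    loudness_max = loudness_max,
    pulse_rate = pulse_rate,
    exploration_enabled = isTRUE(exploration_enabled),
    rng_seed = as.integer(rng_seed)
  ), class = "wba_state")
}

#' Number of warm-up iterations
#'
#' One twentieth of the total iteration budget, floored, and clamped below
#' at 1 so tiny runs never divide by zero.
#'
#' @param max_iterations Total number of optimizer steps.
#' @return Integer warm-up length.
#' @export
compute_warmup_iterations <- function(max_iterations) {
  stopifnot(max_iterations >= 1)
  max(1L, as.integer(floor(max_iterations / 20)))
}

#' Warm-up learning rate at a given iteration
#'
#' Linear ramp `initial_learning_rate * (iteration + 1) / warmup_iterations`
#' for 0-based `iteration` in `[0, warmup_iterations)`; the final warm-up
#' step reaches `initial_learning_rate` exactly.
#'
#' @param iteration 0-based iteration index within the warm-up phase.
#' @param state A `wba_state`.
#' @return Learning rate.
#' @export
warmup_lr <- function(iteration, state) {
  if (iteration < 0 || iteration >= state$warmup_iterations) {
    stop("`iteration` outside the warm-up range [0, warmup_iterations)")
  }
  state$initial_learning_rate * (iteration + 1) / state$warmup_iterations
}

#' Loudness factor at a given iteration
#'
#' `loudness_min + (loudness_max - loudness_min) * exp(-pulse_rate * iteration / max_iterations)`;
#' strictly decreasing in `iteration`, confined to
#' `(loudness_min, loudness_max]`.
#'
#' @param iteration 0-based iteration index.
#' @param state A `wba_state`.
#' @return Loudness value.
#' @export
wba_loudness <- function(iteration, state) {
  state$loudness_min + (state$loudness_max - state$loudness_min) *
    exp(-state$pulse_rate * iteration / state$max_iterations)
}

#' One multiplicative loudness decay of the learning rate
#'
#' @param state A `wba_state` whose `current_learning_rate` is decayed by
#'   the loudness at its `current_iteration`, floored at
#'   `min_learning_rate`.
#' @return The decayed learning rate.
#' @export
decay_lr <- function(state) {
  max(state$current_learning_rate *
        wba_loudness(state$current_iteration, state),
      state$min_learning_rate)
}

#' Advance the schedule one optimizer step
#'
#' Dispatches to the linear warm-up ramp while
#' `current_iteration < warmup_iterations`, then to the multiplicative
#' loudness decay. With `exploration_enabled`, a seeded multiplicative
#' perturbation of the decayed rate is proposed; the caller may accept it by
#' passing `accept_proposal = TRUE` on the next call (the deterministic rate
#' is kept otherwise).
#'
#' @param state A `wba_state`.
#' @param accept_proposal Whether to accept the previous exploration
#'   proposal (ignored when exploration is disabled).
#' @return List with elements `state` (advanced) and `lr` (the rate to use
#'   for this step).
#' @export
wba_step <- function(state, accept_proposal = FALSE) {
  it <- state$current_iteration
  if (it < state$warmup_iterations) {
    lr <- warmup_lr(it, state)
  } else {
    lr <- decay_lr(state)
    if (state$exploration_enabled) {
      prop <- with_seed(derive_seed(state$rng_seed, paste0("explore", it)),
                        lr * exp(stats::rnorm(1, 0, 0.05)))
      if (isTRUE(accept_proposal)) {
        lr <- min(max(prop, state$min_learning_rate),
                  state$initial_learning_rate)
      }
    }
  }
  state$current_learning_rate <- lr
  state$current_iteration <- it + 1L
  list(state = state, lr = lr)
}

#' Full learning-rate trace of a WBA schedule
#'
#' Replays `wba_step` for `n` steps (default the full `max_iterations`) and
#' returns one row per step. Useful for plotting the warm-up/decay curve.
#'
#' @param state A fresh `wba_state`.
#' @param n Number of steps to trace.
#' @return `data.frame` with columns `iteration` (0-based), `phase`,
#'   `loudness`, `lr`.
#' @export
wba_schedule <- function(state, n = state$max_iterations) {
  out <- data.frame(iteration = seq_len(n) - 1L,
                    phase = character(n),
                    loudness = numeric(n),
                    lr = numeric(n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    it <- state$current_iteration
    out$phase[i] <- if (it < state$warmup_iterations) "warmup" else "decay"
    out$loudness[i] <- wba_loudness(it, state)
    stp <- wba_step(state)
    state <- stp$state
    out$lr[i] <- stp$lr
  }
  out
}
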