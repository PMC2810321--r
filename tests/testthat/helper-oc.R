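# Shared fixtures for the test suite. The full tuned 100-model ensemble is
# expensive (~1 min), so it is computed once per session and reused by the
# acceptance blocks.

.oc_cache <- new.env(parent = emptyenv())

default_ensemble <- function() {
  if (is.null(.oc_cache$traj)) {
    .oc_cache$elapsed <- system.time(
      .oc_cache$traj <- run_ensemble(oc_config(), n_models = 100L,
                                     base_seed = 1L)
    )[["elapsed"]]
  }
  .oc_cache$traj
}

default_ensemble_elapsed <- function() {
  default_ensemble()
  .oc_cache$elapsed
}

# A small, fast configuration for structural tests (dynamics untuned).
quick_config <- function(...) {
  oc_config(protocol = list(n_sessions = 1L, trials_per_session = 10L,
                            steps_lever_out = 20L, steps_iti = 5L), ...)
}

# Closed-form discounted value of a deterministic CS -> US chain where the
# CS lasts `n_cs` steps and reward r arrives right after the last CS step:
# V at chain position t (t = 1 .. n_cs) is gamma^(n_cs - t) * r.
value_iteration_chain <- function(n_cs, r = 1, gamma = 0.9) {
  gamma^(n_cs - seq_len(n_cs)) * r
}

# Run episodic tabular TD on that chain until convergence.
td_train_chain <- function(n_cs, r = 1, gamma = 0.9, alpha = 0.2,
                           n_episodes = 2000L) {
  w <- numeric(n_cs)
  for (ep in seq_len(n_episodes)) {
    x_prev <- numeric(n_cs)
    for (t in seq_len(n_cs)) {
      x_cur <- numeric(n_cs); x_cur[t] <- 1
      delta <- td_error(w, x_prev, x_cur, 0, gamma)
      w <- td_update(w, delta, x_prev, alpha)
      x_prev <- x_cur
    }
    x_cur <- numeric(n_cs)  # terminal: reward, features off
    delta <- td_error(w, x_prev, x_cur, r, gamma)
    w <- td_update(w, delta, x_prev, alpha)
  }
  w
}
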