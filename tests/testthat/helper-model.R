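# Shared fixtures, computed lazily and cached for the whole test run.
.tcache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .tcache)) {
    assign(key, force(expr), envir = .tcache)
  }
  get(key, envir = .tcache)
}

default_p <- function() cached("p", default_parameters())

quiescent0 <- function() cached("q0", find_quiescent_state(default_p(), S = 0))

# Wild-type stimulation: quiescent start, S = 1.
wt_run <- function() cached("wt", {
  tr <- run_timecourse(default_p(), quiescent0(), t_end = 100, dt_out = 0.25)
  list(traj = tr, events = event_times(tr))
})

# Rb-E2F subsystem branch in S (shared by bifurcation tests).
rb_branch <- function() cached("rb_branch", {
  sys <- rb_e2f_subsystem(default_p())
  br <- continue_model_branch(sys, "S", p_range = c(-0.8, 3),
                              start = unname(quiescent0()[sys$free]), p0 = 0,
                              direction = 1, h0 = 0.02, h_max = 0.08,
                              max_steps = 800)
  list(sys = sys, branch = br)
})
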