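# Build a cumulative profile directly from q values (bypasses the sampling
# correction; for operations downstream of kinetics_core).
make_profile <- function(q, t, id = "p1") {
  structure(list(replicate_id = id, times_h = t, q_ug_cm2 = q),
            class = "cumulative_profile")
}

# Noise-free Higuchi profile q = K * sqrt(t)
higuchi_profile <- function(K, t = c(0.5, 1, 2, 3, 4, 5, 6), id = "h1") {
  make_profile(K * sqrt(t), t, id)
}
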