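# Shared simulation helpers. All stochastic tests in the suite fix the RNG
# with set.seed(1) (or a config seed of 1) before drawing.

# Direct discrete-time two-group survival simulator: per-interval hazards
# h0/h1 over tp imaging intervals, censoring after the last. Independent of
# the package's generator so the Cox tests have their own data path.
sim_two_groups <- function(n_per_group, h0, h1, tp = 10, interval = 24) {
  h <- rep(c(h0, h1), each = n_per_group)
  x <- rep(0:1, each = n_per_group)
  u <- matrix(runif(2 * n_per_group * tp), 2 * n_per_group, tp)
  di <- apply(u < h, 1, function(r) {
    w <- which(r)
    if (length(w)) w[1] else NA_integer_
  })
  data.frame(time = ifelse(is.na(di), tp * interval, di * interval),
             event = !is.na(di), x = x)
}

# Hand-written Cox log partial likelihood (no ties expected in the data it
# is applied to); the independent oracle for the Newton-Raphson fitter.
naive_cox_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# Brute-force Mann-Whitney AUC: fraction of (aggregated, diffuse) score
# pairs won, ties counted half.
pairwise_auc <- function(cv, label) {
  a <- cv[label == "aggregated"]
  d <- cv[label == "diffuse"]
  g <- expand.grid(a = a, d = d)
  mean((g$a > g$d) + 0.5 * (g$a == g$d))
}

# One-group cohort run through the full imaging chain, matched to ground
# truth; returns the per-track table with planted and called annotations.
run_cohort_vs_truth <- function(cfg, threshold = 1.0) {
  truth <- sample_cohort(cfg)
  out <- NULL
  for (f in unique(truth$neurons$field)) {
    m <- render_movie(truth, cfg, f)
    rois <- segment_movie(m)
    tr <- link_tracks(rois)
    if (nrow(tr) == 0L) next
    de <- call_death(tr, cfg$n_timepoints)
    de <- match_truth(de, truth, f)
    cl <- classify_neurons(tr, de, threshold)
    de$agg_call <- cl$aggregated[match(de$track_id, cl$track_id)]
    de$field <- f
    out <- rbind(out, de)
  }
  attr(out, "truth") <- truth
  out
}
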