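# Small session builders shared across test files. Sizes are kept small
# enough that the whole suite runs in a few minutes; the acceptance
# tests use the full-scale study conditions.

tiny_social_spec <- function(n_neurons = 40, dynamic = TRUE,
                             pre_frames = 1000, interaction_frames = 1000,
                             baseline_rate = 0.02) {
  session_spec(n_neurons = n_neurons,
               baseline_rate = baseline_rate,
               epoch_plan = social_epoch_plan(dynamic = dynamic,
                                              pre_frames = pre_frames,
                                              interaction_frames = interaction_frames))
}

tiny_social_session <- function(seed = 1, truth = truth_config(), ...) {
  generate_session(tiny_social_spec(...), truth, seed = seed,
                   make_traces = FALSE)
}

# One-epoch session with no planted effects, for null-calibration tests.
null_session <- function(seed, n_neurons = 60, pre = 1500, inter = 1500) {
  spec <- session_spec(n_neurons = n_neurons,
                       epoch_plan = social_epoch_plan(pre_frames = pre,
                                                      interaction_frames = inter)[1])
  generate_session(spec, truth_config(social_frac = 0, context_frac = 0),
                   seed = seed, make_traces = FALSE)
}

# Noise-free trace with transients of the generator's kernel at the
# given onset frames (1-based).
kernel_trace <- function(onsets, n_frames, amp = 0.3, tau = 0.5,
                         frame_rate = 20) {
  imp <- numeric(n_frames)
  imp[onsets] <- amp
  as.numeric(stats::filter(imp, exp(-1 / (tau * frame_rate)),
                           method = "recursive"))
}

# Area under the ROC curve of score vs binary label (rank formula).
auc_score <- function(score, label) {
  ok <- !is.na(score)
  r <- rank(score[ok]); pos <- label[ok]
  (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) / (sum(pos) * sum(!pos))
}
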