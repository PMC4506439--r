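# Shared fixture builders. Everything is generated in code; no stored data.

# Trajectory with explicit dominance durations; the other categories are held
# constant and small enough that any dominance <= 200 keeps daily sums under
# 360 s.
make_traj <- function(pre_dom, post_dom, id = "fix") {
  phase <- function(dom) {
    data.frame(dominance_s = dom, social_s = 60, nonsocial_s = 70,
               submissive_s = 10)
  }
  behaviour_trajectory(id, phase(pre_dom), phase(post_dom))
}

# Small-field configuration that keeps image work cheap in unit tests.
small_config <- function(seed = 1L, ...) {
  cohort_config(
    seed = seed,
    image_params = utils::modifyList(default_image_params(),
                                     list(width_px = 160L, height_px = 160L)),
    n_fields = 3L,
    ...
  )
}

# Severity ordering of labels used by the threshold-monotonicity property.
label_rank <- function(label) {
  match(label, c("PainAlone", "PainTransientDisability", "PainDisability"))
}
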