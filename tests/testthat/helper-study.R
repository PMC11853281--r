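# The reference synthetic study used by the end-to-end checks: 8 subjects
# with 3 positional clips of 120 s each at the default scene settings.
# Built once per test run and cached (denoising dominates the cost).
.study_cache <- new.env(parent = emptyenv())

ci_study <- function() {
  if (is.null(.study_cache$study))
    .study_cache$study <- generate_study(
      8, 3, cfg = scene_config(duration_s = 120), seed = 20260923)
  .study_cache$study
}

ci_dataset <- function() {
  if (is.null(.study_cache$ds))
    .study_cache$ds <- extract_study_features(ci_study())
  .study_cache$ds
}
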