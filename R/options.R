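# Frozen package-level conventions. These were fixed once, by the one-time
# calibration documented in the methods vignette, and are used identically for
# every variant. They are not per-experiment tuning knobs.

#' Package-level frozen conventions
#'
#' * `branch_width_ratio`: every parallel pyramid branch outputs
#'   `round(in_channels * branch_width_ratio)` channels (calibration documented
#'   in the methods vignette).
#' * `flops_per_mac`: GFLOPs are reported as `flops_per_mac * MACs / 1e9`.
#' * `include_elementwise`: whether normalization/activation elementwise
#'   operations are counted (the frozen convention excludes them).
#'
#' @return named list of conventions.
#' @export
laam_options <- function() {
  list(branch_width_ratio = 1.42,
       flops_per_mac = 2,
       include_elementwise = FALSE)
}

#' The frozen GFLOPs counting convention
#' @return list with `flops_per_mac` and `include_elementwise`.
#' @export
gflops_convention <- function() {
  o <- laam_options()
  list(flops_per_mac = o$flops_per_mac,
       include_elementwise = o$include_elementwise)
}
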