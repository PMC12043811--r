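# shared small-scale study conditions for fast tests
tiny_config <- function(...) {
  phantom_config(dim = c(48L, 48L, 24L), spacing = c(2, 2, 3),
                 gland_semiaxes = c(22, 18, 16), ...)
}

perfect_oc <- function(sensitivity = 1, ...) {
  operating_characteristics(sensitivity = sensitivity, conf_fixed = 0.9,
                            fp_rate_inside = 0, fp_rate_outside = 0, ...)
}

# all cases carry exactly n aggressive (ISUP 2) lesions
all_aggressive_config <- function(n = 2L, ...) {
  probs <- rep(0, 5)
  probs[n + 1] <- 1
  tiny_config(lesion_count_probs = probs,
              isup_probs = c(0, 0, 1, 0, 0, 0), ...)
}
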