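# Published reference values for the two prevalence tables, frozen here.
REF_POSTTEST <- data.frame(
  prevalence = seq(0.1, 0.9, 0.1),
  lr_pos = 19, lr_neg = 0.0526, se = 0.95, sp = 0.95,
  post_pos = c(0.6786, 0.8261, 0.8906, 0.9268, 0.95,
               0.9661, 0.9779, 0.987, 0.9942),
  post_neg = c(0.0058, 0.013, 0.0221, 0.0339, 0.05,
               0.0732, 0.1094, 0.1739, 0.3214))

REF_REQUIREMENTS <- data.frame(
  prevalence = seq(0.1, 0.9, 0.1),
  post_pos = 0.95, post_neg = 0.05,
  lr_pos = c(171, 76, 44.3333, 28.5, 19, 12.6667, 8.1429, 4.75, 2.1111),
  lr_neg = c(0.4737, 0.2105, 0.1228, 0.0789, 0.0526,
             0.0351, 0.0226, 0.0132, 0.0058),
  se = c(0.5278, 0.7917, 0.8796, 0.9236, 0.95,
         0.9676, 0.9802, 0.9896, 0.9969),
  sp = c(0.9969, 0.9896, 0.9802, 0.9676, 0.95,
         0.9236, 0.8796, 0.7917, 0.5278))

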