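#!/usr/bin/env Rscript
# Build the REM Gating Integrity composites per channel: logit-transformed
# coupling, control z-scores, weakest-link RGI_min, and the signed
# shrinkage-covariance (lambda = 0.20) distance-to-control.

suppressPackageStartupMessages(library(remgate))

for (ch in c("C3C4", "F3F4")) {
  f <- read_features(sprintf("results/features_%s.csv", ch))
  r <- compute_rgi(f, lambda = 0.20)
  write.csv(r, sprintf("results/rgi_%s.csv", ch), row.names = FALSE)
  write_reference(attr(r, "reference"), sprintf("results/ref_%s.json", ch))
  message(ch, ": epic RGI_min mean ",
          round(mean(r$rgi_min[r$group == "epic"]), 3),
          " vs control ", round(mean(r$rgi_min[r$group == "control"]), 3),
          "; signed distance mean ",
          round(mean(r$signed_distance[r$group == "epic"]), 3),
          " vs ", round(mean(r$signed_distance[r$group == "control"]), 3))
}
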