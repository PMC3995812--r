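#!/usr/bin/env Rscript
# Step 2: run the virtual-double-staining scoring pipeline over the
# simulated image manifest and compare the measured TBS against the
# generator ground truth stored in the sidecars.

suppressMessages(library(mirstroma))

manifest <- read.csv("results/images_manifest.csv", stringsAsFactors = FALSE)
batch <- run_score_batch(manifest[, c("sample_id", "ihc_path", "ish_path",
                                      "roi_path")],
                         out_csv = "results/scores.csv")

truth <- vapply(manifest$truth_path, function(p)
  jsonlite::read_json(p)$tbs_true, numeric(1))
rel_err <- abs(batch$scores$tbs - truth) / truth
for (i in seq_len(nrow(batch$scores))) {
  message(sprintf("%s: TBS = %8.1f (truth %8.1f, %+.1f%%)  NCC %.3f",
                  batch$scores$sample_id[i], batch$scores$tbs[i], truth[i],
                  100 * (batch$scores$tbs[i] / truth[i] - 1),
                  batch$scores$registration_score[i]))
}
message(sprintf("median |relative error| %.2f%%, max %.2f%%; Spearman rho %.3f",
                100 * median(rel_err), 100 * max(rel_err),
                cor(batch$scores$tbs, truth, method = "spearman")))
if (nrow(batch$failures)) {
  message("failures: ", paste(batch$failures$sample_id, collapse = ", "))
}
message("wrote results/scores.csv")
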