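#!/usr/bin/env Rscript

# Step 4: the packaged narrative fixtures. Loads the three single-loop
# CLDs (commercial drivers of unhealthy diet; mental health and
# unhealthy diet; social media, body image and motivation to exercise),
# classifies each loop, profiles its themes, and merges the three into
# one map to show how shared variables (self-esteem) knit separate
# narratives together.

suppressPackageStartupMessages(library(cldmapr))

out <- "results/narratives"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

fx <- load_narrative_fixtures()
for (nm in names(fx)) {
  loop <- find_feedback_loops(fx[[nm]])[[1]]
  prof <- loop_theme_profile(loop, fx[[nm]])
  cat(sprintf("%s: length %d, %d negative links -> %s\n", nm,
              loop$length, sum(loop$polarities == -1L),
              loop$classification))
  cat("  themes:", paste(sprintf("%s=%d", names(prof), prof),
                         collapse = ", "), "\n")
  write_cld(fx[[nm]], file.path(out, paste0(nm, ".dot")), "dot",
            highlight = loop)
}

paths <- narrative_fixture_paths()
cfg <- list(mode = "files",
            files = list(all = paths[grepl("_edges", paths)]),
            out_dir = file.path(out, "merged"))
res <- run_pipeline(cfg, quiet = TRUE)
cat("\nmerged narrative map:\n")
cat(summarize_cld(res$master, res$loops), sep = "\n")
cat("wrote", out, "\n")
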