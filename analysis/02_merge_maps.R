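#!/usr/bin/env Rscript

# Step 2: hierarchical merge. Reads the group-map CSVs written by step
# 01, prunes endpoint-only variables from each, folds the four maps of
# each country into a country map and the five country maps into the
# master map, and writes every map plus the per-fold merge reports.

suppressPackageStartupMessages(library(cldmapr))

src <- "results/synthetic_study"
out <- "results/merged"
if (!dir.exists(src)) stop("run analysis/01_simulate_study.R first")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

edge_files <- list.files(src, pattern = "_g[0-9]+[.]csv$",
                         full.names = TRUE)
countries <- unique(sub("_g[0-9]+$", "", sub("[.]csv$", "",
                                             basename(edge_files))))
files <- lapply(setNames(countries, countries), function(ctry) {
  sort(edge_files[startsWith(basename(edge_files), paste0(ctry, "_g"))])
})

groups <- load_file_groups(files)
res <- merge_hierarchical(groups)

for (ctry in names(res$country_maps)) {
  write_cld(res$country_maps[[ctry]],
            file.path(out, paste0("country_", ctry, ".csv")), "csv")
}
write_cld(res$master, file.path(out, "master.csv"), "csv")
write_cld(res$master, file.path(out, "master.graphml"), "graphml")
write_merge_reports(res$reports, file.path(out, "merge_reports.json"))

n_dup <- sum(vapply(res$reports, `[[`, integer(1), "n_duplicates"))
n_add <- sum(vapply(res$reports, `[[`, integer(1), "n_added"))
n_conf <- sum(vapply(res$reports, function(r) {
  nrow(r$polarity_conflicts)
}, integer(1)))
n_pruned <- length(unlist(res$pruned))
cat(sprintf("pruned %d endpoint-only variables across %d maps\n",
            n_pruned, length(res$pruned)))
cat(sprintf("%d folds: %d duplicates merged, %d variables added, %d polarity conflicts\n",
            length(res$reports), n_dup, n_add, n_conf))
print(res$master)
cat("wrote", out, "\n")
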