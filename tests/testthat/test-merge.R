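test_that("endpoint pruning follows the degree rule in both modes", {
  chain <- cld_from_edges(list(c("A", "B", 1), c("B", "C", 1)))
  sp <- prune_endpoint_variables(chain, "single_pass")
  expect_setequal(sp$removed, c("a", "c"))
  expect_identical(sp$cld$variables$id, "b")

  fp <- prune_endpoint_variables(chain, "fixpoint")
  expect_setequal(fp$removed, c("a", "b", "c"))
  expect_identical(nrow(fp$cld$variables), 0L)

  cyc <- cld_from_edges(list(c("A", "B", 1), c("B", "C", 1),
                             c("C", "A", 1)))
  for (mode in c("single_pass", "fixpoint")) {
    expect_length(prune_endpoint_variables(cyc, mode)$removed, 0)
  }
  # input is never mutated
  expect_identical(nrow(chain$variables), 3L)
})

test_that("fixpoint pruning is sound, monotone and idempotent", {
  set.seed(31)
  for (i in 1:20) {
    cld <- random_cld(sample(3:10, 1), p = 0.25)
    pr <- prune_endpoint_variables(cld)$cld
    ids <- pr$variables$id
    if (length(ids)) {
      indeg <- table(factor(pr$links$target, levels = ids))
      outdeg <- table(factor(pr$links$source, levels = ids))
      expect_true(all(indeg >= 1 & outdeg >= 1))
    }
    expect_true(all(ids %in% cld$variables$id))
    again <- prune_endpoint_variables(pr)
    expect_length(again$removed, 0)
    expect_identical(again$cld$variables$id, ids)
  }
})

test_that("base-map selection is argmax with documented tie-breaks", {
  mk <- function(id, nv, nl) {
    cld <- create_cld(id)
    for (i in seq_len(nv)) cld <- add_variable(cld, paste0("v", i))
    for (i in seq_len(nl)) {
      cld <- add_link(cld, paste0("v", i), paste0("v", i %% nv + 1), 1L)
    }
    cld
  }
  expect_identical(select_base_map(list(mk("a", 12, 3), mk("b", 15, 3),
                                        mk("c", 9, 3))), "b")
  expect_identical(select_base_map(list(mk("a", 15, 10), mk("b", 15, 12))),
                   "b")
  expect_identical(select_base_map(list(mk("b", 5, 5), mk("a", 5, 5))),
                   "a")
  expect_error(select_base_map(list()), "no maps")
})

test_that("normalize_label lowercases, strips punctuation and plurals", {
  expect_identical(normalize_label("Stress-Eating "), "stress eating")
  expect_identical(normalize_label("Influencers"), "influencer")
  expect_identical(normalize_label("stress"), "stress")   # double-s kept
  expect_identical(normalize_label(""), "")
})

test_that("variable matching applies exact, synonym, fuzzy in order", {
  base <- cld_from_edges(list(c("Stress-eating", "Advertisement", 1)))
  d <- match_variable("stress eating", base)
  expect_identical(d$outcome, "duplicate")
  expect_identical(d$base_id, "stress_eating")
  expect_identical(d$method, "exact")

  syn <- setNames("Advertisement", normalize_label("fast food ads"))
  d2 <- match_variable("fast food ads", base, synonyms = syn)
  expect_identical(d2$method, "synonym")
  expect_identical(d2$base_id, "advertisement")

  # edit distance 1 over max length 13: similarity 12/13 ~ 0.923
  d3 <- match_variable("advertisment", base, fuzzy_threshold = 0.85)
  expect_identical(d3$method, "fuzzy")
  expect_identical(d3$base_id, "advertisement")
  d4 <- match_variable("advertisment", base)   # fuzzy off by default
  expect_identical(d4$outcome, "added")
})

test_that("polarity conflicts resolve by majority with base tie-break", {
  expect_identical(resolve_polarity_conflict(c("1" = 3, "-1" = 1), -1L), 1L)
  expect_identical(resolve_polarity_conflict(c("1" = 2, "-1" = 2), 1L), 1L)
  expect_identical(resolve_polarity_conflict(c("-1" = 1), -1L), -1L)
})

test_that("merging a map with itself is the identity up to provenance", {
  fx <- load_narrative_fixtures()$social_media
  m <- merge_into_base(fx, fx)
  expect_identical(m$cld$variables$id, fx$variables$id)
  expect_identical(m$cld$links[, c("source", "target", "polarity")],
                   fx$links[, c("source", "target", "polarity")])
  expect_true(all(m$report$decisions$outcome == "duplicate"))
  expect_identical(nrow(m$report$polarity_conflicts), 0L)
})

test_that("feeder links are re-targeted through duplicate decisions", {
  base <- cld_from_edges(list(c("A", "B", 1)), map_id = "base")
  feeder <- cld_from_edges(list(c("C", "D", 1)), map_id = "feeder")
  syn <- setNames("A", normalize_label("C"))
  m <- merge_into_base(base, feeder, synonyms = syn)
  expect_true(any(m$cld$links$source == "a" & m$cld$links$target == "d"))
  # provenance of the retargeted link traces to the feeder
  i <- which(m$cld$links$source == "a" & m$cld$links$target == "d")
  expect_identical(m$cld$links$provenance[[i]], "feeder")
})

test_that("opposite-sign duplicate links are logged and resolved", {
  base <- cld_from_edges(list(c("A", "B", 1)), map_id = "base")
  feeder <- cld_from_edges(list(c("A", "B", -1)), map_id = "feeder")
  m <- merge_into_base(base, feeder)
  expect_identical(nrow(m$report$polarity_conflicts), 1L)
  # one map per sign: tie, base sign kept
  expect_identical(m$cld$links$polarity, 1L)
  expect_setequal(m$cld$links$provenance[[1]], c("base", "feeder"))
})

test_that("manual decision files park or discard before matching", {
  base <- cld_from_edges(list(c("A", "B", 1)), map_id = "base")
  feeder <- cld_from_edges(list(c("Odd one", "B", 1),
                                c("B", "Junk", -1)), map_id = "feeder")
  dec <- setNames(c("park", "discard"),
                  normalize_label(c("Odd one", "Junk")))
  m <- merge_into_base(base, feeder, config = list(decisions = dec))
  expect_identical(m$report$parked, "Odd one")
  expect_identical(m$report$discarded, "Junk")
  expect_false("odd_one" %in% m$cld$variables$id)
  expect_false("junk" %in% m$cld$variables$id)
  expect_identical(m$report$skipped_links, 2L)
})

test_that("merged links equal base links plus the image of feeder links", {
  set.seed(41)
  for (i in 1:10) {
    base <- random_cld(sample(3:6, 1), p = 0.4, map_id = "base")
    feeder <- random_cld(sample(3:6, 1), p = 0.4, map_id = "feeder")
    # overlap: rename some feeder variables onto base ids
    m <- merge_into_base(base, feeder)
    dec <- m$report$decisions
    map <- setNames(ifelse(dec$outcome == "duplicate", dec$base_id,
                           dec$feeder_id), dec$feeder_id)
    img <- unique(paste(map[feeder$links$source], map[feeder$links$target]))
    img <- img[vapply(strsplit(img, " "), function(x) x[1] != x[2],
                      logical(1))]
    want <- union(paste(base$links$source, base$links$target), img)
    got <- paste(m$cld$links$source, m$cld$links$target)
    expect_setequal(got, want)
  }
})

test_that("merge counts reconcile with the report", {
  base <- load_narrative_fixtures()$mental_health
  feeder <- load_narrative_fixtures()$social_media
  m <- merge_into_base(base, feeder)
  r <- m$report
  expect_identical(nrow(r$decisions), nrow(feeder$variables))
  expect_identical(nrow(m$cld$variables),
                   nrow(base$variables) + r$n_added)
  expect_identical(r$n_duplicates + r$n_added +
                     length(r$parked) + length(r$discarded),
                   nrow(feeder$variables))
})

test_that("hierarchical merging recovers shared structure", {
  loop_edges <- list(c("Stress", "Comfort eating", 1),
                     c("Comfort eating", "Body weight", 1),
                     c("Body weight", "Stress", 1))
  groups <- lapply(setNames(nm = c("no", "pl", "pt", "uk", "nl")),
                   function(ctry) {
    lapply(1:4, function(g) {
      cld_from_edges(loop_edges, map_id = paste0(ctry, "_g", g))
    })
  })
  res <- merge_hierarchical(groups)
  expect_identical(res$master$level, "master")
  expect_setequal(res$master$variables$id,
                  c("stress", "comfort_eating", "body_weight"))
  expect_identical(nrow(res$master$links), 3L)
  # provenance of every master element traces to all 20 group maps
  expect_length(res$master$variables$provenance[[1]], 20)
  expect_length(res$reports, 5 * 3 + 4)
})

test_that("a single group degenerates to its pruned map", {
  cld <- cld_from_edges(list(c("A", "B", 1), c("B", "A", 1),
                             c("B", "C", 1)), map_id = "solo")
  res <- merge_hierarchical(list(uk = list(cld)))
  expect_setequal(res$master$variables$id, c("a", "b"))
  expect_identical(res$master$map_id, "master")
})

test_that("every master element carries provenance to some group map", {
  set.seed(51)
  cfg <- synthetic_study_config(n_countries = 2, groups_per_country = 2,
                                vars_per_group = c(8L, 12L),
                                shared_vocabulary_size = 15,
                                seed = 99L)
  study <- generate_study(cfg)
  groups <- lapply(study, function(e) lapply(e, `[[`, "cld"))
  group_ids <- unlist(lapply(groups, function(g) {
    vapply(g, `[[`, character(1), "map_id")
  }), use.names = FALSE)
  res <- merge_hierarchical(groups)
  for (pv in res$master$variables$provenance) {
    expect_gt(length(pv), 0)
    expect_true(all(pv %in% group_ids))
  }
  for (pv in res$master$links$provenance) {
    expect_gt(length(pv), 0)
    expect_true(all(pv %in% group_ids))
  }
})

test_that("merging is deterministic: identical runs, identical bytes", {
  d <- withr::local_tempdir()
  run <- function(out) {
    cfg <- synthetic_study_config(n_countries = 2, groups_per_country = 2,
                                  vars_per_group = c(8L, 12L),
                                  shared_vocabulary_size = 15, seed = 5L)
    study <- generate_study(cfg)
    groups <- lapply(study, function(e) lapply(e, `[[`, "cld"))
    res <- merge_hierarchical(groups)
    write_cld(res$master, out, "csv")
    out
  }
  f1 <- run(file.path(d, "m1.csv")); f2 <- run(file.path(d, "m2.csv"))
  expect_identical(readLines(f1), readLines(f2))
})

test_that("synonym and decision CSV readers validate their headers", {
  d <- withr::local_tempdir()
  sp <- file.path(d, "syn.csv")
  writeLines(c("feeder_label,base_label", "fast food ads,Advertisement"),
             sp)
  syn <- read_synonym_map(sp)
  expect_identical(unname(syn[normalize_label("fast food ads")]),
                   "Advertisement")
  dp <- file.path(d, "dec.csv")
  writeLines(c("label,action", "Junk,discard", "Odd,park"), dp)
  expect_setequal(unname(read_decision_file(dp)), c("discard", "park"))
  writeLines(c("label,action", "Junk,obliterate"), dp)
  expect_error(read_decision_file(dp), "invalid")
})
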