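test_that("simple-cycle enumeration handles canonical small cases", {
  cyc3 <- cld_from_edges(list(c("A", "B", 1), c("B", "C", 1),
                              c("C", "A", 1)))
  expect_identical(enumerate_simple_cycles(cyc3), list(c("a", "b", "c")),
                   ignore_attr = TRUE)

  dag <- cld_from_edges(list(c("a", "b", 1), c("a", "c", 1),
                             c("b", "d", 1), c("c", "d", 1),
                             c("d", "e", 1), c("e", "f", 1)))
  expect_length(enumerate_simple_cycles(dag), 0)

  # complete digraph on 4 nodes: 6 + 8 + 6 = 20 simple cycles
  k4 <- create_cld("k4")
  for (v in c("a", "b", "c", "d")) k4 <- add_variable(k4, v)
  for (s in c("a", "b", "c", "d")) for (t in c("a", "b", "c", "d")) {
    if (s != t) k4 <- add_link(k4, s, t, 1L)
  }
  cycles <- enumerate_simple_cycles(k4)
  expect_length(cycles, 20)
  expect_identical(unname(table(lengths(cycles))),
                   as.integer(c(6, 8, 6)), ignore_attr = TRUE)
})

test_that("every cycle starts at its smallest id and order is fixed", {
  set.seed(61)
  for (i in 1:10) {
    cld <- random_cld(6, p = 0.4)
    cycles <- enumerate_simple_cycles(cld)
    for (cyc in cycles) {
      expect_identical(cyc[1], sort(cyc, method = "radix")[1])
    }
    len <- lengths(cycles)
    expect_true(all(diff(len) >= 0))
    # declaring variables/links in another order changes nothing
    perm <- sample(nrow(cld$variables))
    shuffled <- cld
    shuffled$variables <- cld$variables[perm, ]
    shuffled$links <- cld$links[sample(nrow(cld$links)), ]
    expect_identical(enumerate_simple_cycles(shuffled), cycles)
  }
})

test_that("max_length bounds cycles and truncation is flagged", {
  k5 <- create_cld("k5")
  ids <- letters[1:5]
  for (v in ids) k5 <- add_variable(k5, v)
  for (s in ids) for (t in ids) if (s != t) k5 <- add_link(k5, s, t, 1L)
  short <- enumerate_simple_cycles(k5, max_length = 2)
  expect_true(all(lengths(short) == 2))
  expect_length(short, 10)
  expect_false(attr(short, "truncated"))

  expect_warning(capped <- enumerate_simple_cycles(k5, max_cycles = 7),
                 "truncated")
  expect_length(capped, 7)
  expect_true(attr(capped, "truncated"))
})

test_that("enumeration agrees with brute-force oracle on random digraphs", {
  set.seed(71)
  for (i in 1:40) {
    n <- sample(2:7, 1)
    cld <- random_cld(n, p = stats::runif(1, 0.2, 0.6))
    expect_identical(enumerate_simple_cycles(cld),
                     oracle_simple_cycles(cld), ignore_attr = TRUE)
  }
})

test_that("loop parity classification equals the sign-product oracle", {
  expect_identical(classify_loop(rep(1, 6)), "reinforcing")
  expect_identical(classify_loop(c(1, -1, 1)), "balancing")
  expect_identical(classify_loop(c(1, -1, -1, 1, 1, 1, 1)), "reinforcing")
  expect_error(classify_loop(integer(0)), "empty")
  expect_error(classify_loop(c(1, 0)), "polarities")
  for (len in 1:8) {
    grid <- as.matrix(expand.grid(rep(list(c(1L, -1L)), len)))
    for (r in seq_len(nrow(grid))) {
      expect_identical(classify_loop(grid[r, ]), oracle_classify(grid[r, ]))
    }
  }
})

test_that("flipping one loop link flips the class; flipping twice restores", {
  set.seed(81)
  for (i in 1:20) {
    pol <- sample(c(1L, -1L), sample(2:9, 1), replace = TRUE)
    before <- classify_loop(pol)
    j <- sample(length(pol), 1)
    pol[j] <- -pol[j]
    expect_false(classify_loop(pol) == before)
    pol[j] <- -pol[j]
    expect_identical(classify_loop(pol), before)
  }
})

test_that("find_feedback_loops wraps cycles with signs and themes", {
  fx <- load_narrative_fixtures()
  l3 <- find_feedback_loops(fx$mental_health)
  expect_length(l3, 1)
  expect_identical(l3[[1]]$length, 6L)
  expect_identical(sum(l3[[1]]$polarities == -1L), 2L)
  expect_identical(l3[[1]]$classification, "reinforcing")

  l4 <- find_feedback_loops(fx$social_media)
  expect_identical(l4[[1]]$length, 7L)
  expect_identical(sum(l4[[1]]$polarities == -1L), 2L)
  expect_identical(l4[[1]]$classification, "reinforcing")

  expect_length(find_feedback_loops(create_cld("empty")), 0)
})

test_that("polarities are read in cycle order", {
  # a -> b (-), b -> c (+), c -> a (-): canonical start "a"
  cld <- cld_from_edges(list(c("a", "b", -1), c("b", "c", 1),
                             c("c", "a", -1)))
  l <- find_feedback_loops(cld)[[1]]
  expect_identical(l$nodes, c("a", "b", "c"))
  expect_identical(l$polarities, c(-1L, 1L, -1L))
  expect_identical(l$classification, "reinforcing")
})

test_that("theme profiles count loop nodes per theme", {
  fx <- load_narrative_fixtures()
  lc <- find_feedback_loops(fx$commercial)[[1]]
  expect_identical(loop_theme_profile(lc, fx$commercial),
                   c(economic_commercial = 6L))
  ls <- find_feedback_loops(fx$social_media)[[1]]
  prof <- loop_theme_profile(ls, fx$social_media)
  expect_setequal(names(prof), c("online", "emotional",
                                 "physical_activity"))
  expect_identical(sum(prof), 7L)
  bogus <- ls; bogus$nodes[1] <- "ghost"
  expect_error(loop_theme_profile(bogus, fx$social_media), "ghost")
})

test_that("loop ranking is deterministic and stable", {
  fx <- load_narrative_fixtures()
  loops <- c(find_feedback_loops(fx$commercial),
             find_feedback_loops(fx$mental_health),
             find_feedback_loops(fx$social_media))
  ranked <- rank_loops(loops)
  tc <- vapply(ranked, `[[`, integer(1), "theme_count")
  expect_identical(tc, sort(tc, decreasing = TRUE))
  # equal keys preserve input order (stable sort)
  same <- rank_loops(list(loops[[2]], loops[[3]]))
  expect_identical(vapply(same, `[[`, integer(1), "length"), c(6L, 7L))
  expect_identical(rank_loops(list()), list())
})

test_that("loop tables and reports serialize every field", {
  d <- withr::local_tempdir()
  loops <- find_feedback_loops(load_narrative_fixtures()$mental_health)
  df <- loops_to_df(loops)
  expect_identical(names(df), c("loop_id", "length", "classification",
                                "theme_count", "node_sequence",
                                "polarity_sequence"))
  write_loop_report(loops, file.path(d, "r.tsv"), file.path(d, "r.json"))
  back <- utils::read.delim(file.path(d, "r.tsv"))
  expect_identical(back$classification, "reinforcing")
  expect_identical(jsonlite::read_json(file.path(d, "r.json"),
                                       simplifyVector = TRUE)$length, 6L)
})
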