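#' @title Synthetic group-model-building ensembles
#' @description Generates ensembles of group-level CLDs that emulate the
#'   structure of a multi-country GMB study: a fixed number of countries,
#'   each contributing several group maps whose variables are drawn
#'   partly from a shared, theme-organized vocabulary, with random signed
#'   links and planted feedback loops recorded as ground truth. The
#'   generator emulates graph structure and theme mix, not the content
#'   realism of participant discussion.
#' @name synthetic_gmb
NULL

#' Configuration for a synthetic GMB study
#'
#' Defaults mirror a five-country study with four school groups per
#' country. Group maps hold 15-40 variables; 60% are drawn from a shared
#' 60-label vocabulary organized over the nine themes (group findings in
#' such studies are largely congruent across countries); link density is
#' 1.8 links per variable and 20% of links are negative (the mix seen in
#' published loop narratives). One loop is planted per group, and by
#' default the same loops (same shared nodes and signs) are planted in
#' every map, providing the common structure hierarchical merging is
#' meant to recover.
#'
#' @param n_countries number of countries.
#' @param groups_per_country group maps per country.
#' @param vars_per_group length-2 integer range of variables per map.
#' @param shared_vocabulary_size number of shared canonical labels.
#' @param shared_fraction fraction of each map's variables drawn from
#'   the shared vocabulary.
#' @param edge_density expected links per variable.
#' @param p_negative probability a random link is negative.
#' @param planted_loops_per_group planted cycles per map.
#' @param planted_loop_length length-2 integer range for planted cycles.
#' @param shared_planted_loops if TRUE (default) the same planted loops
#'   appear in every map; if FALSE each map gets its own.
#' @param label_noise if TRUE, shared labels get case/punctuation/plural
#'   jitter, exercising normalization and fuzzy matching. Default off.
#' @param seed master RNG seed; all per-group streams derive from it.
#' @return object of class `synthetic_study_config`.
#' @export
synthetic_study_config <- function(n_countries = 5,
                                   groups_per_country = 4,
                                   vars_per_group = c(15L, 40L),
                                   shared_vocabulary_size = 60,
                                   shared_fraction = 0.6,
                                   edge_density = 1.8,
                                   p_negative = 0.2,
                                   planted_loops_per_group = 1,
                                   planted_loop_length = c(3L, 6L),
                                   shared_planted_loops = TRUE,
                                   label_noise = FALSE,
                                   seed = 1L) {
  cfg <- list(n_countries = as.integer(n_countries),
              groups_per_country = as.integer(groups_per_country),
              vars_per_group = as.integer(vars_per_group),
              shared_vocabulary_size = as.integer(shared_vocabulary_size),
              shared_fraction = shared_fraction,
              edge_density = edge_density,
              p_negative = p_negative,
              planted_loops_per_group = as.integer(planted_loops_per_group),
              planted_loop_length = as.integer(planted_loop_length),
              shared_planted_loops = isTRUE(shared_planted_loops),
              label_noise = isTRUE(label_noise),
              seed = as.integer(seed))
  stopifnot(cfg$n_countries >= 1, cfg$groups_per_country >= 1,
            length(cfg$vars_per_group) == 2,
            cfg$vars_per_group[1] >= 2,
            cfg$vars_per_group[1] <= cfg$vars_per_group[2],
            cfg$shared_vocabulary_size >= 1,
            cfg$shared_fraction >= 0, cfg$shared_fraction <= 1,
            cfg$edge_density >= 0,
            cfg$p_negative >= 0, cfg$p_negative <= 1,
            cfg$planted_loops_per_group >= 0,
            length(cfg$planted_loop_length) == 2,
            cfg$planted_loop_length[1] >= 2,
            cfg$planted_loop_length[1] <= cfg$planted_loop_length[2])
  if (cfg$planted_loop_length[2] > cfg$vars_per_group[1]) {
    stop("config infeasible: planted loops may exceed the smallest map")
  }
  if (cfg$planted_loops_per_group * cfg$planted_loop_length[2] >
      cfg$shared_vocabulary_size) {
    stop("config infeasible: planted loops exceed the shared vocabulary")
  }
  structure(cfg, class = "synthetic_study_config")
}

# Theme-organized shared vocabulary; deterministic (no RNG).
shared_vocabulary <- function(config) {
  stems <- list(
    emotional = c("stress", "body image pressure", "self esteem",
                  "anxiety", "mood swings"),
    online = c("social media use", "influencer exposure", "screen time",
               "online gaming"),
    physical_activity = c("physical activity", "exercise motivation",
                          "sedentary time", "sport participation"),
    food_drink = c("unhealthy food intake", "snacking",
                   "sugary drink consumption", "comfort eating"),
    economic_commercial = c("food advertising", "junk food price",
                            "food company power", "marketing pressure"),
    knowledge = c("nutrition knowledge", "health information",
                  "food literacy"),
    home_life = c("family meals", "parental support", "home cooking"),
    body_weight = c("body weight", "weight gain"))
  flat <- unlist(stems, use.names = FALSE)
  n <- config$shared_vocabulary_size
  out <- character(n)
  for (i in seq_len(n)) {
    k <- ((i - 1) %% length(flat)) + 1
    rep_i <- ((i - 1) %/% length(flat))
    out[i] <- if (rep_i == 0) flat[k] else paste(flat[k], rep_i + 1)
  }
  out
}

country_ids <- function(n) {
  base <- c("netherlands", "norway", "poland", "portugal", "uk")
  if (n <= length(base)) return(base[seq_len(n)])
  c(base, sprintf("country%02d", seq_len(n - length(base)) + 5))
}

# Planted-loop specs. With shared_planted_loops the stream is keyed only
# on (seed, loop index), so every map plants the same nodes and signs.
planted_loop_specs <- function(config, country, group_index) {
  vocab <- shared_vocabulary(config)
  lapply(seq_len(config$planted_loops_per_group), function(k) {
    key <- if (config$shared_planted_loops) {
      paste("planted", k)
    } else {
      paste("planted", k, country, group_index)
    }
    withr::with_seed(derive_seed(config$seed, key), {
      len <- sample(config$planted_loop_length[1]:
                    config$planted_loop_length[2], 1)
      labels <- sample(vocab, len)
      pol <- ifelse(stats::runif(len) < config$p_negative, -1L, 1L)
      list(nodes = slugify(labels), labels = labels,
           polarities = pol, classification = classify_loop(pol))
    })
  })
}

jitter_label <- function(label) {
  toks <- strsplit(label, " ", fixed = TRUE)[[1]]
  if (stats::runif(1) < 0.5) {
    i <- sample(length(toks), 1)
    toks[i] <- paste0(toupper(substring(toks[i], 1, 1)),
                      substring(toks[i], 2))
  }
  sep <- if (stats::runif(1) < 0.3) "-" else " "
  out <- paste(toks, collapse = sep)
  if (stats::runif(1) < 0.2 && !grepl("s$", out)) out <- paste0(out, "s")
  out
}

#' Generate one synthetic group CLD
#'
#' Deterministic given (config seed, country, group index): the map's
#' variable count is drawn from `vars_per_group`; `shared_fraction` of
#' variables come from the shared vocabulary (always including any
#' planted-loop nodes), the rest get map-unique labels; random links are
#' laid at `edge_density` links per variable with sign -1 at probability
#' `p_negative`; planted loops are inserted over shared-vocabulary
#' nodes and returned as ground-truth specs.
#'
#' @param config a `synthetic_study_config`.
#' @param country country identifier.
#' @param group_index 1-based group number within the country.
#' @return list with `cld` and `planted` (list of planted-loop specs,
#'   each with map_id, nodes, labels, polarities, classification).
#' @export
generate_group_cld <- function(config, country, group_index) {
  stopifnot(inherits(config, "synthetic_study_config"))
  map_id <- paste0(country, "_g", group_index)
  planted <- planted_loop_specs(config, country, group_index)
  vocab <- shared_vocabulary(config)
  withr::with_seed(
    derive_seed(config$seed, paste("group", country, group_index)), {
    n_vars <- sample(config$vars_per_group[1]:config$vars_per_group[2], 1)
    planted_labels <- unique(unlist(lapply(planted, `[[`, "labels")))
    if (length(planted_labels) > n_vars) {
      stop("config infeasible: planted loop nodes exceed map size")
    }
    n_shared <- max(round(config$shared_fraction * n_vars),
                    length(planted_labels))
    n_shared <- min(n_shared, length(vocab), n_vars)
    extra <- setdiff(vocab, planted_labels)
    shared <- c(planted_labels,
                if (n_shared > length(planted_labels)) {
                  sample(extra, n_shared - length(planted_labels))
                })
    n_unique <- n_vars - length(shared)
    uniq <- if (n_unique > 0) {
      sprintf("%s local factor %d", gsub("_", " ", map_id),
              seq_len(n_unique))
    } else character(0)

    cld <- create_cld(map_id, "group")
    for (lab in shared) {
      shown <- if (config$label_noise) jitter_label(lab) else lab
      cld <- add_variable(cld, shown, theme = assign_theme(lab))
    }
    for (lab in uniq) cld <- add_variable(cld, lab)

    have <- new.env(parent = emptyenv())
    for (sp in planted) {
      # shared labels were added in order, so position in `shared` maps a
      # planted label to its (possibly jittered) variable id
      nodes <- cld$variables$id[match(sp$labels, shared)]
      nxt <- c(nodes[-1], nodes[1])
      for (j in seq_along(nodes)) {
        key <- paste(nodes[j], nxt[j])
        if (!isTRUE(get0(key, envir = have)) &&
            !identical(nodes[j], nxt[j])) {
          cld <- add_link(cld, nodes[j], nxt[j], sp$polarities[j])
          assign(key, TRUE, envir = have)
        }
      }
    }

    ids <- cld$variables$id
    n_links <- round(config$edge_density * n_vars)
    attempts <- 0L
    laid <- nrow(cld$links)
    while (laid < n_links && attempts < 50L * n_links) {
      attempts <- attempts + 1L
      s <- ids[sample.int(length(ids), 1)]
      t <- ids[sample.int(length(ids), 1)]
      key <- paste(s, t)
      if (identical(s, t) || isTRUE(get0(key, envir = have))) next
      pol <- if (stats::runif(1) < config$p_negative) -1L else 1L
      cld <- add_link(cld, s, t, pol)
      assign(key, TRUE, envir = have)
      laid <- laid + 1L
    }
    planted <- lapply(planted, function(sp) {
      sp$map_id <- map_id
      sp
    })
    list(cld = cld, planted = planted)
  })
}

#' Generate a full synthetic study
#'
#' `n_countries` x `groups_per_country` group CLDs. Each group's RNG
#' stream is derived from the master seed and the group's identity, so
#' per-group output does not depend on generation order.
#'
#' @param config a `synthetic_study_config`.
#' @return named list (one element per country), each a list of
#'   `list(cld, planted)` entries; the config is attached as an
#'   attribute.
#' @export
generate_study <- function(config = synthetic_study_config()) {
  stopifnot(inherits(config, "synthetic_study_config"))
  countries <- country_ids(config$n_countries)
  out <- lapply(stats::setNames(countries, countries), function(ctry) {
    lapply(seq_len(config$groups_per_country), function(g) {
      generate_group_cld(config, ctry, g)
    })
  })
  attr(out, "config") <- config
  out
}

#' Ground-truth table of planted loops
#'
#' @param study result of `generate_study()`.
#' @return data.frame: map_id, loop_index, length, classification,
#'   node_sequence, polarity_sequence.
#' @export
study_ground_truth <- function(study) {
  rows <- list()
  for (ctry in names(study)) {
    for (entry in study[[ctry]]) {
      for (k in seq_along(entry$planted)) {
        sp <- entry$planted[[k]]
        rows[[length(rows) + 1]] <- data.frame(
          map_id = sp$map_id, loop_index = k,
          length = length(sp$nodes),
          classification = sp$classification,
          node_sequence = paste(sp$nodes, collapse = " -> "),
          polarity_sequence = paste(ifelse(sp$polarities > 0, "+1", "-1"),
                                    collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows) %||%
    data.frame(map_id = character(), loop_index = integer(),
               length = integer(), classification = character(),
               node_sequence = character(),
               polarity_sequence = character(), stringsAsFactors = FALSE)
}
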