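#' @title The hierarchical map-merging protocol
#' @description Group maps are merged into country maps and country maps
#'   into a single master map. Each fold prunes endpoint-only variables,
#'   picks the largest remaining map as the base, then judges every
#'   feeder variable against the base: duplicate of an existing base
#'   variable, added to the base, or parked/discarded by an explicit
#'   manual decision file. Links are carried across through the decision
#'   mapping with full provenance, and sign disagreements are resolved by
#'   a logged majority vote.
#' @name map_merge
NULL

#' Remove endpoint-only variables
#'
#' Variables whose connections go only in or only out (in-degree 0 or
#' out-degree 0) cannot take part in any feedback loop. `single_pass`
#' removes exactly those variables present in the input;
#' `fixpoint` (the default) repeats until none remain, since removing a
#' sink can strand its neighbours. Links incident to removed variables
#' are dropped. The input is not modified.
#'
#' @param cld a `cld`.
#' @param mode "fixpoint" or "single_pass".
#' @return list with elements `cld` (pruned copy) and `removed`
#'   (character vector of removed variable ids, in removal order).
#' @export
prune_endpoint_variables <- function(cld, mode = c("fixpoint",
                                                   "single_pass")) {
  mode <- match.arg(mode)
  removed <- character(0)
  repeat {
    ids <- cld$variables$id
    indeg <- table(factor(cld$links$target, levels = ids))
    outdeg <- table(factor(cld$links$source, levels = ids))
    drop <- ids[indeg[ids] == 0 | outdeg[ids] == 0]
    if (length(drop) == 0) break
    drop <- sort_c(drop)
    removed <- c(removed, drop)
    cld$variables <- cld$variables[!cld$variables$id %in% drop, ,
                                   drop = FALSE]
    keep <- !(cld$links$source %in% drop | cld$links$target %in% drop)
    cld$links <- cld$links[keep, , drop = FALSE]
    if (mode == "single_pass") break
  }
  rownames(cld$variables) <- NULL
  rownames(cld$links) <- NULL
  list(cld = cld, removed = removed)
}

#' Select the base map
#'
#' The base is the map with the most variables remaining after pruning;
#' ties are broken by most links, then lexicographically smallest map
#' id.
#'
#' @param clds non-empty list of `cld` objects.
#' @return the chosen map_id.
#' @export
select_base_map <- function(clds) {
  if (length(clds) == 0) stop("no maps to select a base from")
  ids <- vapply(clds, function(x) x$map_id, character(1))
  nv <- vapply(clds, function(x) nrow(x$variables), integer(1))
  nl <- vapply(clds, function(x) nrow(x$links), integer(1))
  ids[order_c(-nv, -nl, ids)][1]
}

#' Read a synonym map CSV
#'
#' Header `feeder_label,base_label`; feeder labels are compared after
#' `normalize_label()`.
#'
#' @param path CSV path.
#' @return named character vector: normalized feeder label -> base label.
#' @export
read_synonym_map <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  miss <- setdiff(c("feeder_label", "base_label"), names(df))
  if (length(miss)) stop("synonym CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  stats::setNames(df$base_label, normalize_label(df$feeder_label))
}

#' Read a manual decision file
#'
#' Header `label,action` with action in {park, discard}; operationalizes
#' the researchers' judgment that a variable fits nowhere (parked for
#' later deliberation) or should be dropped entirely. Nothing is parked
#' or discarded automatically.
#'
#' @param path CSV path.
#' @return named character vector: normalized label -> action.
#' @export
read_decision_file <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  miss <- setdiff(c("label", "action"), names(df))
  if (length(miss)) stop("decision CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$action), c("park", "discard"))
  if (length(bad)) stop("invalid decision action(s): ",
                        paste(bad, collapse = ", "))
  stats::setNames(df$action, normalize_label(df$label))
}

edit_similarity <- function(a, b) {
  d <- utils::adist(a, b)[1, 1]
  m <- max(nchar(a), nchar(b))
  if (m == 0) return(1)
  1 - d / m
}

#' Judge one feeder variable against the base map
#'
#' Fixed-order decision pipeline: (1) exact slug equality with a base
#' variable; (2) synonym-map hit; (3) if a fuzzy threshold is given,
#' highest normalized edit similarity at or above it (ties broken by
#' smallest base id); otherwise the variable is added. Fuzzy matching is
#' off by default because duplicate judgment in group model building is
#' semantic and silent fuzzy merges risk false joins.
#'
#' @param feeder_label label of the feeder variable.
#' @param base the base `cld`.
#' @param synonyms optional named vector from `read_synonym_map()`.
#' @param fuzzy_threshold similarity threshold in \[0, 1\], or NULL (off).
#' @return one-row data.frame: feeder_label, feeder_id, outcome
#'   ("duplicate" or "added"), base_id (NA when added), method ("exact",
#'   "synonym", "fuzzy" or NA).
#' @export
match_variable <- function(feeder_label, base, synonyms = NULL,
                           fuzzy_threshold = NULL) {
  fid <- slugify(feeder_label)
  dec <- function(outcome, base_id = NA_character_,
                  method = NA_character_) {
    data.frame(feeder_label = feeder_label, feeder_id = fid,
               outcome = outcome, base_id = base_id, method = method,
               stringsAsFactors = FALSE)
  }
  if (fid %in% base$variables$id) {
    return(dec("duplicate", fid, "exact"))
  }
  if (!is.null(synonyms)) {
    norm <- normalize_label(feeder_label)
    if (norm %in% names(synonyms)) {
      return(dec("duplicate", slugify(synonyms[[norm]]), "synonym"))
    }
  }
  if (!is.null(fuzzy_threshold)) {
    norm <- normalize_label(feeder_label)
    base_ids <- sort_c(base$variables$id)
    base_norm <- normalize_label(
      base$variables$label[match(base_ids, base$variables$id)])
    sims <- vapply(base_norm, function(b) edit_similarity(norm, b),
                   numeric(1), USE.NAMES = FALSE)
    if (length(sims) && max(sims) >= fuzzy_threshold) {
      return(dec("duplicate", base_ids[which.max(sims)], "fuzzy"))
    }
  }
  dec("added")
}

#' Resolve a polarity conflict by majority vote
#'
#' When a merged link pair carries both signs, the sign backed by more
#' contributing source maps wins; an exact tie keeps the base map's
#' sign.
#'
#' @param votes named numeric vector with names "1" and/or "-1" giving
#'   the count of contributing maps per sign.
#' @param base_sign the sign currently on the base (+1 or -1).
#' @return +1 or -1.
#' @export
resolve_polarity_conflict <- function(votes, base_sign) {
  stopifnot(length(votes) >= 1, base_sign %in% c(1L, -1L))
  pos <- if ("1" %in% names(votes)) votes[["1"]] else 0
  neg <- if ("-1" %in% names(votes)) votes[["-1"]] else 0
  if (pos > neg) 1L else if (neg > pos) -1L else as.integer(base_sign)
}

#' Fold one feeder CLD into a base CLD
#'
#' Every feeder variable receives exactly one decision (manual
#' park/discard, duplicate, or added); feeder links are re-targeted
#' through the decision mapping. A re-targeted link already on the base
#' with the same sign merges provenance; with the opposite sign it is
#' recorded as a polarity conflict and resolved by
#' `resolve_polarity_conflict()` with provenance-set sizes as votes. A
#' link whose endpoints collapse onto one base variable is dropped and
#' counted. After folding, the result is re-validated and every retained
#' feeder link is verified present.
#'
#' @param base,feeder `cld` objects (pruned per protocol).
#' @param synonyms optional named vector from `read_synonym_map()`.
#' @param config list; recognised fields `fuzzy_threshold` (NULL = off)
#'   and `decisions` (named vector from `read_decision_file()`).
#' @return list with `cld` (the merged base) and `report` (a
#'   `merge_report`).
#' @export
merge_into_base <- function(base, feeder, synonyms = NULL,
                            config = list()) {
  stopifnot(inherits(base, "cld"), inherits(feeder, "cld"))
  fuzzy <- config$fuzzy_threshold
  manual <- config$decisions
  orig_base <- base
  decisions <- list()
  mapping <- character(0)   # feeder id -> merged id; NA = parked/discarded
  parked <- character(0)
  discarded <- character(0)

  union_var_prov <- function(cld, id, prov) {
    i <- match(id, cld$variables$id)
    cld$variables$provenance[[i]] <-
      sort_c(union(cld$variables$provenance[[i]], prov))
    cld
  }

  for (i in seq_len(nrow(feeder$variables))) {
    v <- feeder$variables[i, ]
    norm <- normalize_label(v$label)
    if (!is.null(manual) && norm %in% names(manual)) {
      act <- manual[[norm]]
      decisions[[length(decisions) + 1]] <- data.frame(
        feeder_label = v$label, feeder_id = v$id,
        outcome = if (act == "park") "parked" else "discarded",
        base_id = NA_character_, method = "manual_file",
        stringsAsFactors = FALSE)
      if (act == "park") parked <- c(parked, v$label)
      else discarded <- c(discarded, v$label)
      mapping[v$id] <- NA_character_
      next
    }
    d <- match_variable(v$label, orig_base, synonyms, fuzzy)
    if (d$outcome == "duplicate") {
      if (!d$base_id %in% base$variables$id) {
        # synonym target not yet on the base: create its canonical variable
        if (is.na(d$method) || d$method != "synonym") {
          stop("match produced unknown base id ", dQuote(d$base_id))
        }
        canon <- synonyms[[normalize_label(v$label)]]
        base <- add_variable(base, canon, theme = assign_theme(canon),
                             provenance = v$provenance[[1]])
      }
      base <- union_var_prov(base, d$base_id, v$provenance[[1]])
      mapping[v$id] <- d$base_id
    } else {
      if (v$id %in% base$variables$id) {
        base <- union_var_prov(base, v$id, v$provenance[[1]])
      } else {
        base <- add_variable(base, v$label, theme = v$theme,
                             provenance = v$provenance[[1]])
      }
      mapping[v$id] <- v$id
    }
    decisions[[length(decisions) + 1]] <- d
  }

  conflicts <- data.frame(source = character(), target = character(),
                          votes_positive = numeric(),
                          votes_negative = numeric(),
                          base_sign = integer(), resolution = integer(),
                          stringsAsFactors = FALSE)
  skipped_links <- 0L
  collapsed_links <- 0L
  carried <- character(0)
  for (i in seq_len(nrow(feeder$links))) {
    lk <- feeder$links[i, ]
    s <- mapping[[lk$source]]
    t <- mapping[[lk$target]]
    if (is.na(s) || is.na(t)) { skipped_links <- skipped_links + 1L; next }
    if (identical(s, t)) { collapsed_links <- collapsed_links + 1L; next }
    j <- which(base$links$source == s & base$links$target == t)
    if (length(j) == 0) {
      base <- add_link(base, s, t, lk$polarity,
                       provenance = lk$provenance[[1]])
    } else {
      j <- j[1]
      if (base$links$polarity[j] == lk$polarity) {
        base$links$provenance[[j]] <-
          sort_c(union(base$links$provenance[[j]], lk$provenance[[1]]))
      } else {
        votes <- stats::setNames(
          c(0, 0), c("1", "-1"))
        votes[[as.character(base$links$polarity[j])]] <-
          length(base$links$provenance[[j]])
        votes[[as.character(lk$polarity)]] <-
          votes[[as.character(lk$polarity)]] + length(lk$provenance[[1]])
        res <- resolve_polarity_conflict(votes, base$links$polarity[j])
        conflicts <- rbind(conflicts, data.frame(
          source = s, target = t,
          votes_positive = votes[["1"]], votes_negative = votes[["-1"]],
          base_sign = base$links$polarity[j], resolution = res,
          stringsAsFactors = FALSE))
        base$links$polarity[j] <- res
        base$links$provenance[[j]] <-
          sort_c(union(base$links$provenance[[j]], lk$provenance[[1]]))
      }
    }
    carried <- c(carried, paste(s, t))
  }

  # scour: every retained feeder link must be represented on the merged map
  present <- paste(base$links$source, base$links$target)
  if (!all(carried %in% present)) {
    stop("internal error: feeder link lost during merge")
  }
  bad <- validate_cld(base)
  if (nrow(bad)) {
    stop("merged CLD fails validation: ", paste(bad$message, collapse = "; "))
  }

  dec_df <- do.call(rbind, decisions) %||%
    data.frame(feeder_label = character(), feeder_id = character(),
               outcome = character(), base_id = character(),
               method = character(), stringsAsFactors = FALSE)
  report <- structure(list(
    base_map_id = orig_base$map_id, feeder_map_id = feeder$map_id,
    decisions = dec_df, polarity_conflicts = conflicts,
    parked = parked, discarded = discarded,
    n_duplicates = sum(dec_df$outcome == "duplicate"),
    n_added = sum(dec_df$outcome == "added"),
    skipped_links = skipped_links, collapsed_links = collapsed_links),
    class = "merge_report")
  list(cld = base, report = report)
}

#' Merge group maps into country maps and country maps into the master
#'
#' Per country: every group map is pruned, the largest remaining map
#' becomes the base, and the others are folded in (sorted by map id).
#' The identical protocol is then applied across the country maps to
#' produce the master. Fold order is fixed and documented because the
#' result can depend on it.
#'
#' @param groups named list: country id -> list of group `cld` objects.
#' @param synonyms optional named vector from `read_synonym_map()`.
#' @param config list; `prune_mode` ("fixpoint" default or
#'   "single_pass"), plus fields forwarded to `merge_into_base()`.
#' @return list with `master` (cld at master level), `country_maps`
#'   (named list of cld), `reports` (list of `merge_report`, one per
#'   fold), and `pruned` (named list: map id -> removed variable ids).
#' @export
merge_hierarchical <- function(groups, synonyms = NULL, config = list()) {
  if (length(groups) == 0) stop("no countries to merge")
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stop("groups must be a named list keyed by country id")
  }
  prune_mode <- config$prune_mode %||% "fixpoint"
  reports <- list()
  pruned <- list()

  fold_level <- function(clds, out_id, out_level, stage) {
    pr <- lapply(clds, prune_endpoint_variables, mode = prune_mode)
    for (p in pr) pruned[[p$cld$map_id]] <<- p$removed
    clds <- lapply(pr, `[[`, "cld")
    names(clds) <- vapply(clds, `[[`, character(1), "map_id")
    base_id <- select_base_map(clds)
    base <- clds[[base_id]]
    feeders <- clds[setdiff(sort_c(names(clds)), base_id)]
    for (f in feeders) {
      m <- merge_into_base(base, f, synonyms, config)
      base <- m$cld
      m$report$stage <- stage
      reports[[length(reports) + 1]] <<- m$report
    }
    base$map_id <- out_id
    base$level <- out_level
    base
  }

  country_maps <- list()
  for (ctry in sort_c(names(groups))) {
    country_maps[[ctry]] <- fold_level(groups[[ctry]], ctry, "country",
                                       stage = "country")
  }
  master <- fold_level(unname(country_maps), "master", "master",
                       stage = "master")
  list(master = master, country_maps = country_maps, reports = reports,
       pruned = pruned)
}

#' @export
print.merge_report <- function(x, ...) {
  cat(sprintf(paste0("<merge_report> %s <- %s: %d duplicates, %d added, ",
                     "%d parked, %d discarded, %d polarity conflicts\n"),
              x$base_map_id, x$feeder_map_id, x$n_duplicates, x$n_added,
              length(x$parked), length(x$discarded),
              nrow(x$polarity_conflicts)))
  invisible(x)
}

#' Serialize merge reports to JSON
#'
#' @param reports a single `merge_report` or a list of them.
#' @param path output JSON path.
#' @return invisibly, the path.
#' @export
write_merge_reports <- function(reports, path) {
  if (inherits(reports, "merge_report")) reports <- list(reports)
  payload <- lapply(reports, function(r) {
    list(base_map_id = r$base_map_id, feeder_map_id = r$feeder_map_id,
         stage = r$stage %||% NA_character_,
         decisions = r$decisions, polarity_conflicts = r$polarity_conflicts,
         parked = r$parked, discarded = r$discarded,
         n_duplicates = r$n_duplicates, n_added = r$n_added,
         skipped_links = r$skipped_links,
         collapsed_links = r$collapsed_links)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
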