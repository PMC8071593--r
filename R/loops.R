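#' @title Feedback-loop enumeration and classification
#' @description A feedback loop is a simple directed cycle in a CLD. A
#'   loop is reinforcing when it carries an even number of negative
#'   links (the product of its signs is +1): perturbations travelling
#'   around it are amplified. With an odd number of negative links the
#'   loop is balancing: it acts as a force of resistance, counteracting
#'   change. Loops are the candidate leverage points of a causal map.
#' @name loop_analysis
NULL

canonical_rotation <- function(nodes) {
  k <- order_c(nodes)[1]
  if (k == 1) nodes else c(nodes[k:length(nodes)], nodes[seq_len(k - 1)])
}

#' Enumerate simple directed cycles
#'
#' Finds every simple (node-disjoint) directed cycle of length >= 2 up
#' to `max_length`, by depth-first search rooted at each node in
#' lexicographic order, restricted to nodes that sort after the root --
#' so each cycle is found exactly once, already in canonical rotation
#' (starting at its smallest id). Enumeration stops at `max_cycles`;
#' truncation is flagged in the result (`attr(x, "truncated")`) and
#' raised as a warning, never silent, because cycle counts grow
#' exponentially with density.
#'
#' @param cld a `cld`.
#' @param max_length maximum cycle length (default 12); `Inf` for
#'   unlimited.
#' @param max_cycles stop after this many cycles (default 10000).
#' @return list of character vectors (canonical node sequences), sorted
#'   by length then lexicographic sequence, with attribute `truncated`.
#' @export
enumerate_simple_cycles <- function(cld, max_length = 12,
                                    max_cycles = 10000) {
  stopifnot(inherits(cld, "cld"))
  # work over integer indices in radix (C-locale) id order, so "smallest
  # node" and traversal order never depend on the session locale
  ids <- sort_c(cld$variables$id)
  n_nodes <- length(ids)
  src <- match(cld$links$source, ids)
  tgt <- match(cld$links$target, ids)
  adj <- lapply(seq_len(n_nodes), function(v) sort(tgt[src == v]))
  env <- new.env(parent = emptyenv())
  env$cycles <- vector("list", 256)
  env$n <- 0L
  env$truncated <- FALSE

  for (s in seq_len(n_nodes)) {
    if (env$truncated) break
    path <- integer(n_nodes)
    onpath <- logical(n_nodes)
    dfs <- function(v, depth) {
      if (env$truncated) return()
      for (w in adj[[v]]) {
        if (env$truncated) return()
        if (w == s) {
          if (depth >= 2) {
            if (env$n >= max_cycles) { env$truncated <- TRUE; return() }
            env$n <- env$n + 1L
            if (env$n > length(env$cycles)) {
              env$cycles <- c(env$cycles, vector("list", length(env$cycles)))
            }
            env$cycles[[env$n]] <- path[seq_len(depth)]
          }
        } else if (w > s && depth < max_length && !onpath[w]) {
          path[depth + 1] <<- w
          onpath[w] <<- TRUE
          dfs(w, depth + 1L)
          onpath[w] <<- FALSE
        }
      }
    }
    path[1] <- s
    onpath[s] <- TRUE
    dfs(s, 1L)
  }
  cycles <- lapply(env$cycles[seq_len(env$n)], function(ix) ids[ix])
  if (env$n > 0) {
    len <- lengths(cycles)
    key <- vapply(cycles, paste, character(1), collapse = "")
    cycles <- cycles[order_c(len, key)]
  }
  if (env$truncated) {
    warning("cycle enumeration truncated at max_cycles = ", max_cycles)
  }
  attr(cycles, "truncated") <- env$truncated
  cycles
}

#' Classify a loop from its link signs
#'
#' Reinforcing iff the product of polarities is +1 (an even number of
#' negative links); balancing otherwise.
#'
#' @param polarities non-empty vector of +1/-1 link signs along the
#'   cycle.
#' @return "reinforcing" or "balancing".
#' @examples
#' classify_loop(c(1, 1, 1))       # reinforcing
#' classify_loop(c(1, -1, 1))      # balancing
#' @export
classify_loop <- function(polarities) {
  if (length(polarities) == 0) stop("empty polarity sequence")
  if (!all(polarities %in% c(1, -1))) stop("polarities must be +1 or -1")
  if (prod(polarities) > 0) "reinforcing" else "balancing"
}

new_feedback_loop <- function(nodes, polarities, themes) {
  structure(list(nodes = nodes, polarities = as.integer(polarities),
                 classification = classify_loop(polarities),
                 length = length(nodes),
                 theme_count = length(unique(themes))),
            class = "feedback_loop")
}

#' Find and classify all feedback loops of a CLD
#'
#' Wraps every enumerated cycle with the link polarities read from the
#' CLD, its reinforcing/balancing classification, and the number of
#' distinct themes among its nodes. Order is inherited from
#' `enumerate_simple_cycles()` and is deterministic.
#'
#' @inheritParams enumerate_simple_cycles
#' @return list of `feedback_loop` objects with attribute `truncated`.
#' @export
find_feedback_loops <- function(cld, max_length = 12, max_cycles = 10000) {
  cycles <- enumerate_simple_cycles(cld, max_length, max_cycles)
  themes <- stats::setNames(cld$variables$theme, cld$variables$id)
  loops <- lapply(cycles, function(nodes) {
    nxt <- c(nodes[-1], nodes[1])
    pol <- mapply(function(s, t) get_polarity(cld, s, t), nodes, nxt)
    new_feedback_loop(nodes, pol, themes[nodes])
  })
  attr(loops, "truncated") <- attr(cycles, "truncated")
  loops
}

#' Extract a specific loop from a CLD, if present
#'
#' Checks that each consecutive link of the given node cycle exists and
#' returns the corresponding `feedback_loop` (with polarities as they
#' stand on the CLD), or NULL when any link is absent. Used to verify
#' planted-loop recovery after merging.
#'
#' @param cld a `cld`.
#' @param nodes variable ids in cycle order.
#' @return a `feedback_loop` or NULL.
#' @export
extract_loop <- function(cld, nodes) {
  if (length(nodes) < 2) return(NULL)
  if (!all(nodes %in% cld$variables$id)) return(NULL)
  nxt <- c(nodes[-1], nodes[1])
  pol <- mapply(function(s, t) get_polarity(cld, s, t), nodes, nxt)
  if (anyNA(pol)) return(NULL)
  themes <- stats::setNames(cld$variables$theme, cld$variables$id)
  canon <- canonical_rotation(nodes)
  shift <- which(nodes == canon[1])[1]
  pol <- c(pol, pol)[shift:(shift + length(nodes) - 1)]
  new_feedback_loop(canon, pol, themes[canon])
}

#' Theme profile of a loop
#'
#' @param loop a `feedback_loop`.
#' @param cld the `cld` the loop lives in.
#' @return named integer vector: theme -> node count (themes absent from
#'   the loop are absent from the result); counts sum to the loop
#'   length.
#' @export
loop_theme_profile <- function(loop, cld) {
  i <- match(loop$nodes, cld$variables$id)
  if (anyNA(i)) {
    stop("unknown node(s): ",
         paste(loop$nodes[is.na(i)], collapse = ", "))
  }
  tab <- table(cld$variables$theme[i])
  stats::setNames(as.integer(tab), names(tab))
}

#' Rank loops for reporting
#'
#' Stable sort by descending theme count (loops spanning more of the map
#' first), then ascending length, then lexicographic node sequence.
#' Salience of a loop is ultimately a narrative judgment; this ordering
#' is a documented deterministic default, not a claim about importance.
#'
#' @param loops list of `feedback_loop`.
#' @return the reordered list.
#' @export
rank_loops <- function(loops) {
  if (length(loops) == 0) return(loops)
  tc <- vapply(loops, `[[`, integer(1), "theme_count")
  ln <- vapply(loops, `[[`, integer(1), "length")
  key <- vapply(loops, function(l) paste(l$nodes, collapse = ""),
                character(1))
  loops[order_c(-tc, ln, key)]
}

#' Tabulate feedback loops
#'
#' @param loops list of `feedback_loop`.
#' @return data.frame with columns loop_id, length, classification,
#'   theme_count, node_sequence, polarity_sequence.
#' @export
loops_to_df <- function(loops) {
  data.frame(
    loop_id = sprintf("L%03d", seq_along(loops)),
    length = vapply(loops, `[[`, integer(1), "length"),
    classification = vapply(loops, `[[`, character(1), "classification"),
    theme_count = vapply(loops, `[[`, integer(1), "theme_count"),
    node_sequence = vapply(loops, function(l) paste(l$nodes,
                                                    collapse = " -> "),
                           character(1)),
    polarity_sequence = vapply(loops, function(l) {
      paste(ifelse(l$polarities > 0, "+1", "-1"), collapse = ",")
    }, character(1)),
    stringsAsFactors = FALSE)
}

#' Write a loop report as TSV and/or JSON
#'
#' @param loops list of `feedback_loop`.
#' @param tsv_path,json_path output paths (NULL to skip either).
#' @return invisibly, the paths written.
#' @export
write_loop_report <- function(loops, tsv_path = NULL, json_path = NULL) {
  df <- loops_to_df(loops)
  written <- character(0)
  if (!is.null(tsv_path)) {
    utils::write.table(df, tsv_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    written <- c(written, tsv_path)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(df, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    written <- c(written, json_path)
  }
  invisible(written)
}

#' @export
print.feedback_loop <- function(x, ...) {
  cat(sprintf("<feedback_loop> %s (length %d, %d themes): %s\n",
              x$classification, x$length, x$theme_count,
              paste(x$nodes, collapse = " -> ")))
  invisible(x)
}
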