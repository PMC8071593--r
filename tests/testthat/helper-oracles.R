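# Independent oracles and small builders used across the suite.

# Quick CLD from a list of c(source, target, polarity) triples; variables
# are declared implicitly, themes optional.
cld_from_edges <- function(edges, map_id = "m", level = "group",
                           themes = NULL) {
  cld <- create_cld(map_id, level)
  labs <- unique(unlist(lapply(edges, function(e) e[1:2])))
  for (l in labs) {
    cld <- add_variable(cld, l, theme = themes[[l]] %||% NULL)
  }
  for (e in edges) {
    cld <- add_link(cld, slugify(e[1]), slugify(e[2]), as.integer(e[3]))
  }
  cld
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random signed digraph as a CLD (Erdos-Renyi on ordered pairs).
random_cld <- function(n, p = 0.3, p_neg = 0.3, map_id = "rand") {
  ids <- sprintf("v%02d", seq_len(n))
  cld <- create_cld(map_id)
  for (i in ids) cld <- add_variable(cld, i)
  for (s in ids) for (t in ids) {
    if (s != t && stats::runif(1) < p) {
      pol <- if (stats::runif(1) < p_neg) -1L else 1L
      cld <- add_link(cld, s, t, pol)
    }
  }
  cld
}

# Brute-force enumeration of all simple directed cycles by checking every
# rotation-canonical permutation of every vertex subset. Independent of
# the package's DFS: feasible only for small graphs, which is the point.
.perm_cache <- new.env(parent = emptyenv())
perms_of <- function(k) {
  key <- as.character(k)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  res <- if (k == 0) list(integer(0)) else {
    out <- list()
    rec <- function(left, acc) {
      if (length(left) == 0) { out[[length(out) + 1]] <<- acc; return() }
      for (i in seq_along(left)) rec(left[-i], c(acc, left[i]))
    }
    rec(seq_len(k), integer(0))
    out
  }
  .perm_cache[[key]] <- res
  res
}

oracle_simple_cycles <- function(cld, max_length = Inf) {
  ids <- sort(cld$variables$id, method = "radix")
  n <- length(ids)
  adj <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  if (nrow(cld$links)) {
    adj[cbind(cld$links$source, cld$links$target)] <- TRUE
  }
  res <- list()
  if (n >= 2) {
    for (L in 2:min(n, max_length)) {
      for (sub in utils::combn(n, L, simplify = FALSE)) {
        first <- sub[1]              # smallest index = canonical start
        rest <- sub[-1]
        for (p in perms_of(L - 1)) {
          cyc <- c(first, rest[p])
          nxt <- c(cyc[-1], cyc[1])
          if (all(adj[cbind(cyc, nxt)])) {
            res[[length(res) + 1]] <- ids[cyc]
          }
        }
      }
    }
  }
  if (length(res)) {
    len <- lengths(res)
    key <- vapply(res, paste, character(1), collapse = "")
    res <- res[order(len, key, method = "radix")]
  }
  res
}

# Sign-product classification oracle.
oracle_classify <- function(polarities) {
  if (prod(polarities) > 0) "reinforcing" else "balancing"
}
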