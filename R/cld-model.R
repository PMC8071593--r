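#' @title Causal loop diagrams as signed digraphs
#' @description A CLD is a simple signed directed graph: nodes are named
#'   factors ("variables"), edges assert monotone causal influence with
#'   polarity +1 (an increase drives an increase) or -1 (an increase
#'   drives a decrease). CLDs carry a level (group, country or master)
#'   reflecting their place in the hierarchical merge, and every variable
#'   and link records provenance: the set of source group maps it came
#'   from.
#' @name cld
NULL

#' The nine variable theme classes
#'
#' Variables are colour-coded into nine broad themes: emotional/mental
#' pressure, online activity and influence, physical activity, food and
#' drink intake, economic/commercial influence, knowledge/information,
#' home life, body weight, and unclassified.
#'
#' @return character vector of valid theme names.
#' @export
cld_themes <- function() {
  c("emotional", "online", "physical_activity", "food_drink",
    "economic_commercial", "knowledge", "home_life", "body_weight",
    "unclassified")
}

#' Valid CLD levels
#' @return character vector: group, country, master.
#' @export
cld_levels <- function() c("group", "country", "master")

empty_variables <- function() {
  df <- data.frame(id = character(), label = character(),
                   theme = character(), stringsAsFactors = FALSE)
  df$provenance <- list()
  df
}

empty_links <- function() {
  df <- data.frame(source = character(), target = character(),
                   polarity = integer(), stringsAsFactors = FALSE)
  df$provenance <- list()
  df
}

#' Create an empty CLD
#'
#' @param map_id non-empty identifier for the map.
#' @param level one of `cld_levels()`.
#' @return an object of class `cld` with no variables or links.
#' @examples
#' create_cld("uk_g1", "group")
#' @export
create_cld <- function(map_id, level = "group") {
  if (!is.character(map_id) || length(map_id) != 1 || !nzchar(map_id)) {
    stop("map_id must be a non-empty string")
  }
  if (!is.character(level) || length(level) != 1 ||
      !level %in% cld_levels()) {
    stop("level must be one of: ", paste(cld_levels(), collapse = ", "))
  }
  structure(list(map_id = map_id, level = level,
                 variables = empty_variables(), links = empty_links()),
            class = "cld")
}

#' Add a variable to a CLD
#'
#' The variable's id is `slugify(label)`; adding a label whose slug is
#' already present is an error (two spellings of the same factor must be
#' merged, not duplicated).
#'
#' @param cld a `cld` object.
#' @param label free-text display name.
#' @param theme one of `cld_themes()`; defaults to "unclassified".
#' @param provenance character vector of source-map ids; defaults to the
#'   CLD's own map_id.
#' @return the updated `cld`.
#' @export
add_variable <- function(cld, label, theme = NULL, provenance = NULL) {
  stopifnot(inherits(cld, "cld"))
  id <- slugify(label)
  if (!nzchar(id)) stop("label slugs to an empty id: ", dQuote(label))
  if (id %in% cld$variables$id) {
    stop("duplicate variable: ", dQuote(label), " slugs to existing id ",
         dQuote(id))
  }
  theme <- theme %||% "unclassified"
  if (!theme %in% cld_themes()) stop("invalid theme: ", dQuote(theme))
  provenance <- provenance %||% cld$map_id
  row <- data.frame(id = id, label = as.character(label), theme = theme,
                    stringsAsFactors = FALSE)
  row$provenance <- list(sort_c(unique(provenance)))
  cld$variables <- rbind(cld$variables, row)
  cld
}

#' Add a signed causal link to a CLD
#'
#' @param cld a `cld` object.
#' @param source,target existing variable ids.
#' @param polarity +1 or -1.
#' @param provenance character vector of source-map ids; defaults to the
#'   CLD's own map_id.
#' @return the updated `cld`.
#' @export
add_link <- function(cld, source, target, polarity, provenance = NULL) {
  stopifnot(inherits(cld, "cld"))
  for (v in c(source, target)) {
    if (!v %in% cld$variables$id) stop("unknown endpoint: ", dQuote(v))
  }
  if (identical(source, target)) {
    stop("self-loop rejected: ", dQuote(source))
  }
  if (!length(polarity) == 1 || !polarity %in% c(1L, -1L)) {
    stop("polarity must be +1 or -1")
  }
  if (any(cld$links$source == source & cld$links$target == target)) {
    stop("duplicate link: ", source, " -> ", target)
  }
  provenance <- provenance %||% cld$map_id
  row <- data.frame(source = source, target = target,
                    polarity = as.integer(polarity),
                    stringsAsFactors = FALSE)
  row$provenance <- list(sort_c(unique(provenance)))
  cld$links <- rbind(cld$links, row)
  cld
}

violation <- function(invariant, element, message) {
  data.frame(invariant = invariant, element = element, message = message,
             stringsAsFactors = FALSE)
}

#' Validate a CLD against its structural invariants
#'
#' Checks: non-empty map id, valid level, unique slug-form variable ids,
#' themes from the closed vocabulary, link endpoints declared, polarities
#' in {+1, -1}, no self-loops, no parallel links, non-empty provenance.
#'
#' @param cld a `cld` object.
#' @return a data.frame of violations (zero rows when the CLD is valid),
#'   with columns invariant, element, message.
#' @export
validate_cld <- function(cld) {
  out <- violation(character(), character(), character())
  if (!nzchar(cld$map_id)) {
    out <- rbind(out, violation("map_id", cld$map_id, "empty map_id"))
  }
  if (!cld$level %in% cld_levels()) {
    out <- rbind(out, violation("level", cld$level, "invalid level"))
  }
  v <- cld$variables
  dup <- v$id[duplicated(v$id)]
  for (d in unique(dup)) {
    out <- rbind(out, violation("unique_id", d, "duplicated variable id"))
  }
  bad_id <- v$id[!grepl("^[a-z0-9][a-z0-9_]*$", v$id)]
  for (b in bad_id) {
    out <- rbind(out, violation("slug_id", b, "id not in slug form"))
  }
  bad_theme <- v$id[!v$theme %in% cld_themes()]
  for (b in bad_theme) {
    out <- rbind(out, violation("theme", b, "theme outside vocabulary"))
  }
  for (i in seq_len(nrow(v))) {
    if (length(v$provenance[[i]]) == 0) {
      out <- rbind(out, violation("provenance", v$id[i],
                                  "variable has empty provenance"))
    }
  }
  l <- cld$links
  for (i in seq_len(nrow(l))) {
    key <- paste0(l$source[i], " -> ", l$target[i])
    for (endp in c(l$source[i], l$target[i])) {
      if (!endp %in% v$id) {
        out <- rbind(out, violation("endpoint", endp,
                                    paste0("link ", key,
                                           " references undeclared variable ",
                                           dQuote(endp))))
      }
    }
    if (l$source[i] == l$target[i]) {
      out <- rbind(out, violation("self_loop", key, "self-loop"))
    }
    if (!l$polarity[i] %in% c(1L, -1L)) {
      out <- rbind(out, violation("polarity", key,
                                  paste0("polarity ", l$polarity[i])))
    }
    if (length(l$provenance[[i]]) == 0) {
      out <- rbind(out, violation("provenance", key,
                                  "link has empty provenance"))
    }
  }
  keys <- paste(l$source, l$target)
  for (k in unique(keys[duplicated(keys)])) {
    out <- rbind(out, violation("parallel_link", k, "duplicate ordered pair"))
  }
  out
}

get_polarity <- function(cld, source, target) {
  i <- which(cld$links$source == source & cld$links$target == target)
  if (length(i) == 0) return(NA_integer_)
  cld$links$polarity[i[1]]
}

#' @export
print.cld <- function(x, ...) {
  neg <- sum(x$links$polarity == -1L)
  cat(sprintf("<cld> %s [%s]: %d variables, %d links (%d positive, %d negative)\n",
              x$map_id, x$level, nrow(x$variables), nrow(x$links),
              nrow(x$links) - neg, neg))
  invisible(x)
}
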