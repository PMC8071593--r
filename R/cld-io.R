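parse_polarity <- function(cells) {
  cells <- trimws(cells)
  # accept hand-edited variants, including the Unicode minus
  cells <- gsub("−", "-", cells)
  out <- integer(length(cells))
  for (i in seq_along(cells)) {
    p <- switch(cells[i],
                "+" = 1L, "+1" = 1L, "1" = 1L,
                "-" = -1L, "-1" = -1L,
                NA_integer_)
    if (is.na(p)) {
      stop("unparseable polarity ", dQuote(cells[i]), " at row ", i)
    }
    out[i] <- p
  }
  out
}

#' Read a CLD from edge-list CSV
#'
#' The edge file must have header `source_label,target_label,polarity`;
#' polarity cells may be `+`, `-`, `+1`, `-1`, `1` or use a Unicode
#' minus. An optional variables file (`label,theme`) assigns themes and
#' may declare isolated variables; labels it does not cover are themed
#' with `assign_theme()` and the default lexicon. A variables-file row
#' with an unknown theme raises a warning and falls back to
#' "unclassified".
#'
#' @param edges_path path to the edge CSV.
#' @param variables_path optional path to the variable CSV.
#' @param map_id identifier for the resulting CLD.
#' @param level CLD level, default "group".
#' @param lexicon theme lexicon for labels not covered by the variables
#'   file.
#' @return a `cld`.
#' @export
read_cld_csv <- function(edges_path, variables_path = NULL, map_id,
                         level = "group",
                         lexicon = default_theme_lexicon()) {
  if (!file.exists(edges_path)) stop("input file not found: ", edges_path)
  edges <- utils::read.csv(edges_path, stringsAsFactors = FALSE,
                           colClasses = "character", encoding = "UTF-8")
  need <- c("source_label", "target_label", "polarity")
  miss <- setdiff(need, names(edges))
  if (length(miss)) {
    stop("edge CSV ", edges_path, " missing column(s): ",
         paste(miss, collapse = ", "))
  }
  cld <- create_cld(map_id, level)
  themes <- character(0)    # slug -> theme from the variables file
  labels <- character(0)    # slug -> display label
  if (!is.null(variables_path)) {
    if (!file.exists(variables_path)) {
      stop("input file not found: ", variables_path)
    }
    vars <- utils::read.csv(variables_path, stringsAsFactors = FALSE,
                            colClasses = "character", encoding = "UTF-8")
    vmiss <- setdiff(c("label", "theme"), names(vars))
    if (length(vmiss)) {
      stop("variable CSV ", variables_path, " missing column(s): ",
           paste(vmiss, collapse = ", "))
    }
    for (i in seq_len(nrow(vars))) {
      th <- vars$theme[i]
      if (!th %in% cld_themes()) {
        warning("unknown theme ", dQuote(th), " for label ",
                dQuote(vars$label[i]), "; using unclassified")
        th <- "unclassified"
      }
      sl <- slugify(vars$label[i])
      themes[sl] <- th
      labels[sl] <- vars$label[i]
      cld <- add_variable(cld, vars$label[i], theme = th)
    }
  }
  ensure_var <- function(cld, label) {
    sl <- slugify(label)
    if (!sl %in% cld$variables$id) {
      cld <- add_variable(cld, label, theme = assign_theme(label, lexicon))
    }
    cld
  }
  pol <- parse_polarity(edges$polarity)
  for (i in seq_len(nrow(edges))) {
    cld <- ensure_var(cld, edges$source_label[i])
    cld <- ensure_var(cld, edges$target_label[i])
    cld <- add_link(cld, slugify(edges$source_label[i]),
                    slugify(edges$target_label[i]), pol[i])
  }
  cld
}

default_variables_path <- function(path) {
  sub("\\.csv$", "_variables.csv", path)
}

cld_to_igraph <- function(cld) {
  v <- cld$variables
  vdf <- data.frame(name = v$id, label = v$label, theme = v$theme,
                    provenance = vapply(v$provenance, paste,
                                        character(1), collapse = ";"),
                    stringsAsFactors = FALSE)
  l <- cld$links
  edf <- data.frame(from = l$source, to = l$target,
                    polarity = l$polarity,
                    provenance = vapply(l$provenance, paste,
                                        character(1), collapse = ";"),
                    stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edf, directed = TRUE, vertices = vdf)
}

#' Write a CLD to CSV, GraphML or DOT
#'
#' CSV writes two files -- the edge list at `path` and a variables file
#' (default `<path stem>_variables.csv`) -- ordered deterministically so
#' identical CLDs produce byte-identical output; the pair round-trips
#' through `read_cld_csv()`. GraphML carries label, theme and provenance
#' as typed attributes. DOT fills each node with its theme colour
#' (purple, red, green, orange, fuchsia, light blue, dark blue, black,
#' white) and renders negative links dashed, positive solid; an optional
#' `highlight` loop is drawn in bold.
#'
#' @param cld a `cld`.
#' @param path output path.
#' @param format one of "csv", "graphml", "dot".
#' @param variables_path variables CSV path (csv format only).
#' @param highlight optional `feedback_loop` whose edges are emphasised
#'   (dot format only).
#' @return invisibly, the path(s) written.
#' @export
write_cld <- function(cld, path, format = c("csv", "graphml", "dot"),
                      variables_path = NULL, highlight = NULL) {
  format <- match.arg(format)
  if (format == "csv") {
    variables_path <- variables_path %||% default_variables_path(path)
    v <- cld$variables[order_c(cld$variables$id), , drop = FALSE]
    l <- cld$links[order_c(cld$links$source, cld$links$target), ,
                   drop = FALSE]
    lab <- stats::setNames(v$label, v$id)
    edf <- data.frame(source_label = unname(lab[l$source]),
                      target_label = unname(lab[l$target]),
                      polarity = ifelse(l$polarity > 0, "+1", "-1"),
                      stringsAsFactors = FALSE)
    utils::write.csv(edf, path, row.names = FALSE, quote = TRUE)
    vdf <- data.frame(label = v$label, theme = v$theme,
                      stringsAsFactors = FALSE)
    utils::write.csv(vdf, variables_path, row.names = FALSE, quote = TRUE)
    return(invisible(c(path, variables_path)))
  }
  if (format == "graphml") {
    igraph::write_graph(cld_to_igraph(cld), path, format = "graphml")
    return(invisible(path))
  }
  # dot
  cols <- theme_colours()
  dark <- c("black", "darkblue", "purple", "red")
  hl_keys <- character(0)
  if (!is.null(highlight)) {
    n <- highlight$nodes
    hl_keys <- paste(n, c(n[-1], n[1]))
  }
  v <- cld$variables[order_c(cld$variables$id), , drop = FALSE]
  l <- cld$links[order_c(cld$links$source, cld$links$target), ,
                 drop = FALSE]
  esc <- function(x) gsub('"', '\\\\"', x)
  lines <- c(sprintf("digraph \"%s\" {", esc(cld$map_id)),
             "  node [style=filled];")
  for (i in seq_len(nrow(v))) {
    fill <- cols[[v$theme[i]]]
    font <- if (fill %in% dark) "white" else "black"
    lines <- c(lines, sprintf(
      "  \"%s\" [label=\"%s\", fillcolor=\"%s\", fontcolor=\"%s\"];",
      v$id[i], esc(v$label[i]), fill, font))
  }
  for (i in seq_len(nrow(l))) {
    style <- if (l$polarity[i] < 0) "dashed" else "solid"
    pen <- if (paste(l$source[i], l$target[i]) %in% hl_keys) {
      ", penwidth=3, style=\"bold\""
    } else ""
    if (nzchar(pen) && l$polarity[i] < 0) {
      pen <- ", penwidth=3, style=\"bold,dashed\""
      style <- NULL
    }
    attr <- if (is.null(style)) sub("^, ", "", pen) else {
      paste0("style=", style, pen)
    }
    lines <- c(lines, sprintf("  \"%s\" -> \"%s\" [%s];",
                              l$source[i], l$target[i], attr))
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}
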