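.cldmapr_env <- new.env(parent = emptyenv())

#' Construct a theme lexicon
#'
#' A lexicon is a keyword table mapping lowercase keywords/phrases to
#' themes; `assign_theme()` picks the theme of the longest keyword
#' contained in a label. The colour-coding of real maps was a broad human
#' judgment; the lexicon is its reproducible surrogate and is editable.
#'
#' @param keywords data.frame with columns `keyword`, `theme`.
#' @return object of class `theme_lexicon`.
#' @export
theme_lexicon <- function(keywords) {
  stopifnot(is.data.frame(keywords),
            all(c("keyword", "theme") %in% names(keywords)))
  keywords$keyword <- tolower(trimws(keywords$keyword))
  if (anyDuplicated(keywords$keyword)) {
    stop("duplicate lexicon keywords: ",
         paste(unique(keywords$keyword[duplicated(keywords$keyword)]),
               collapse = ", "))
  }
  bad <- setdiff(unique(keywords$theme), cld_themes())
  if (length(bad)) stop("invalid lexicon themes: ", paste(bad, collapse = ", "))
  structure(keywords[, c("keyword", "theme")], class = c("theme_lexicon",
                                                         "data.frame"))
}

#' The default theme lexicon shipped with the package
#'
#' Read once from `extdata/theme_lexicon.csv` and cached.
#'
#' @return a `theme_lexicon`.
#' @export
default_theme_lexicon <- function() {
  if (is.null(.cldmapr_env$lexicon)) {
    path <- system.file("extdata", "theme_lexicon.csv", package = "cldmapr",
                        mustWork = TRUE)
    .cldmapr_env$lexicon <- theme_lexicon(
      utils::read.csv(path, stringsAsFactors = FALSE))
  }
  .cldmapr_env$lexicon
}

#' Assign a theme to a label
#'
#' Total, deterministic: the label is lowercased with punctuation
#' collapsed to spaces, and the theme of the longest lexicon keyword
#' occurring as a substring is returned (ties broken by lexicographically
#' smallest keyword); "unclassified" when no keyword matches. Because the
#' longest match wins, adding a shorter keyword never changes labels
#' already matched by a longer one.
#'
#' @param label free-text variable label.
#' @param lexicon a `theme_lexicon`; defaults to the packaged one.
#' @return a single theme name.
#' @examples
#' assign_theme("Body weight")              # "body_weight"
#' assign_theme("social media influencers") # "online"
#' @export
assign_theme <- function(label, lexicon = default_theme_lexicon()) {
  s <- tolower(label)
  s <- gsub("[^a-z0-9]+", " ", s)
  s <- trimws(s)
  hit <- vapply(lexicon$keyword, function(k) grepl(k, s, fixed = TRUE),
                logical(1), USE.NAMES = FALSE)
  if (!any(hit)) return("unclassified")
  cand <- lexicon[hit, , drop = FALSE]
  cand <- cand[order_c(-nchar(cand$keyword), cand$keyword), , drop = FALSE]
  cand$theme[1]
}

# DOT fill colours for the nine themes (fuchsia is not an X11 name, so hex)
theme_colours <- function() {
  c(emotional = "purple", online = "red", physical_activity = "green",
    food_drink = "orange", economic_commercial = "#ff00ff",
    knowledge = "lightblue", home_life = "darkblue", body_weight = "black",
    unclassified = "white")
}
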