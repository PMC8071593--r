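#' Packaged narrative loop fixtures
#'
#' Three small CLDs, shipped as edge/variable CSV pairs under
#' `extdata/fixtures/`, each encoding one published loop narrative as a
#' single simple cycle:
#'
#' \describe{
#'   \item{commercial}{Corporate power funds unhealthy-food advertising,
#'     raising exposure to and demand for unhealthy food, consumption,
#'     and company profit, which feeds back into corporate power. Six
#'     all-positive links: a reinforcing loop.}
#'   \item{mental_health}{Higher body weight raises body-image pressure,
#'     which lowers self-esteem; lower self-esteem raises stress (the
#'     link is negative because self-esteem is oriented so that more is
#'     better), driving stress-eating, unhealthy food intake and weight
#'     gain. Two negative links: reinforcing.}
#'   \item{social_media}{Social media use raises influencer exposure and
#'     unrealistic body ideals, lowering self-esteem and with it
#'     motivation to exercise and physical activity; less activity means
#'     more screen time and more social media use. Two negative links:
#'     reinforcing.}
#' }
#'
#' Variables are phrased so every narrated relation maps onto a monotone
#' signed link; the reinforcing outcome of each loop is invariant to any
#' consistent re-orientation of its variables. The edge lists are pinned
#' by checksum tests and never change.
#'
#' @return named list of three `cld` objects (level "group"):
#'   commercial, mental_health, social_media.
#' @export
load_narrative_fixtures <- function() {
  dir <- system.file("extdata", "fixtures", package = "cldmapr",
                     mustWork = TRUE)
  names <- c("commercial", "mental_health", "social_media")
  out <- lapply(stats::setNames(names, names), function(nm) {
    read_cld_csv(file.path(dir, paste0(nm, "_edges.csv")),
                 file.path(dir, paste0(nm, "_variables.csv")),
                 map_id = nm, level = "group")
  })
  out
}

#' Paths of the packaged fixture files
#'
#' @return character vector of the six CSV paths.
#' @export
narrative_fixture_paths <- function() {
  dir <- system.file("extdata", "fixtures", package = "cldmapr",
                     mustWork = TRUE)
  sort_c(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
}
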