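# Current-path grammar: the seven contact sites, the composite electrodes
# BH (both hands) and BF (both feet), and the expansion wildcards xH/xF/xT.
# "A-B" drives current from electrode set A (source, at touch voltage) to
# electrode set B (sink, grounded).

#' The seven contact electrode sites
#'
#' Right/left hand, right/left foot, posterior/anterior thorax, and the
#' posterior seat (abbreviated `PS` in path labels).
#' @export
ELECTRODE_SITES <- c("RH", "LH", "RF", "LF", "PT", "AT", "SEAT")

# composite electrode tokens -> site sets
.COMPOSITE <- list(BH = c("RH", "LH"), BF = c("RF", "LF"), PS = "SEAT")

# wildcard tokens -> alternative tokens (one path per alternative)
.WILDCARD <- list(xF = c("LF", "RF", "BF"),
                  xH = c("LH", "RH", "BH"),
                  xT = c("PT", "AT"))

#' The 16 standard (IEC) current paths
#'
#' Ten longitudinal paths (hand/seat to feet or hands) and six transversal
#' paths (across the trunk), in the row order of the heart-current-factor
#' tables.
#' @export
IEC_PATHS <- c("LH-BF", "LH-LF", "LH-RF", "BH-BF", "RH-BF", "RH-LF", "RH-RF",
               "PS-LH", "PS-RH", "PS-BH",
               "LH-RH", "PT-RH", "PT-LH", "AT-RH", "AT-LH", "RF-LF")

.resolve_token <- function(token, label, pos) {
  if (token %in% ELECTRODE_SITES) return(token)
  if (token %in% names(.COMPOSITE)) return(.COMPOSITE[[token]])
  stop("unknown electrode token '", token, "' at position ", pos,
       " of path label '", label, "'")
}

#' Parse one current-path label
#'
#' @param label Path label such as `"LH-BF"`: two electrode tokens joined by
#'   a hyphen. Tokens: the seven sites (`PS` aliases `SEAT`) and the
#'   composites `BH`, `BF`.
#' @return A list with `label`, `source_sites`, `sink_sites`
#'   (class `current_path`).
#' @export
current_path <- function(label) {
  parts <- strsplit(label, "-", fixed = TRUE)[[1]]
  if (length(parts) != 2L || any(!nzchar(parts))) {
    stop("path label '", label, "' must be two electrode tokens joined by '-'")
  }
  src <- .resolve_token(parts[1], label, 1L)
  snk <- .resolve_token(parts[2], label, 2L)
  if (length(intersect(src, snk))) {
    stop("source and sink electrode sets overlap in path '", label, "'")
  }
  structure(list(label = label, source_sites = src, sink_sites = snk),
            class = "current_path")
}

#' Expand path labels (with wildcards) to concrete current paths
#'
#' Wildcards expand to one path per alternative: `"LH-xF"` gives `LH-LF`,
#' `LH-RF`, `LH-BF`; `xH`/`xT` behave analogously.
#'
#' @param labels Character vector of path labels.
#' @return Tibble with columns `label`, `source_sites` and `sink_sites`
#'   (list-columns of site vectors), one row per concrete path.
#' @examples
#' expand_paths(c("BH-BF", "LH-xF"))
#' @export
expand_paths <- function(labels) {
  concrete <- unlist(purrr::map(labels, function(lab) {
    parts <- strsplit(lab, "-", fixed = TRUE)[[1]]
    if (length(parts) != 2L) {
      stop("path label '", lab, "' must be two electrode tokens joined by '-'")
    }
    alts <- purrr::map(seq_along(parts), function(i) {
      tok <- parts[i]
      if (tok %in% names(.WILDCARD)) .WILDCARD[[tok]] else tok
    })
    as.vector(outer(alts[[1]], alts[[2]], paste, sep = "-"))
  }))
  concrete <- unique(concrete)
  parsed <- purrr::map(concrete, current_path)
  tibble::tibble(
    label = concrete,
    source_sites = purrr::map(parsed, "source_sites"),
    sink_sites = purrr::map(parsed, "sink_sites")
  )
}
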