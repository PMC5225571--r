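# ICD-9-CM category mapping: broad physical chapters by 3-digit-root range,
# psychiatric categories by explicit code-prefix sets, plus derived unions
# (substance use = alcohol + opioid + amphetamine).

#' Does a string match the numeric ICD-9-CM code grammar?
#'
#' The grammar accepted is a 3-digit root with an optional decimal part of one
#' or two digits (e.g. \code{"486"}, \code{"301.83"}). V- and E-prefixed codes
#' are outside the physical category ranges used here and do not match.
#'
#' @param code character vector.
#' @return logical vector.
#' @export
is_icd9_code <- function(code) {
  !is.na(code) & grepl("^[0-9]{3}(\\.[0-9]{1,2})?$", code)
}

#' Read a diagnosis category map from a YAML file
#'
#' The file defines physical categories as inclusive 3-digit-root ranges,
#' psychiatric categories as code-prefix sets, optional union categories, and
#' the index disorder code/label. See the packaged default
#' (\code{system.file("extdata", "category_map.yaml", package = "comorbidARM")})
#' for the format.
#'
#' @param path path to a YAML category map.
#' @return an object of class \code{category_map}.
#' @export
read_category_map <- function(path) {
  raw <- yaml::read_yaml(path)
  phys <- do.call(rbind, lapply(raw$physical, function(p) {
    do.call(rbind, lapply(p$ranges, function(r) {
      data.frame(name = p$name, lo = as.integer(r[[1]]), hi = as.integer(r[[2]]))
    }))
  }))
  if (any(phys$lo > phys$hi)) stop("physical range with lo > hi in ", path)
  # ranges must not overlap within the physical list
  o <- order(phys$lo)
  if (any(phys$hi[o][-nrow(phys)] >= phys$lo[o][-1])) {
    stop("overlapping physical category ranges in ", path)
  }
  psy <- lapply(raw$psychiatric, as.character)
  if (any(lengths(psy) == 0)) stop("empty psychiatric code set in ", path)
  map <- list(
    index_code = raw$index$code, index_label = raw$index$label,
    physical = phys, psychiatric = psy,
    unions = lapply(raw$unions %||% list(), as.character)
  )
  class(map) <- "category_map"
  map
}

#' The packaged default category map
#'
#' Thirteen physical categories (infectious and parasitic 001-139 through
#' injury and poisoning 800-999) and conventional psychiatric groupings for
#' depressive, bipolar, anxiety, sleep, substance use (alcohol/opioid/
#' amphetamine subtypes), eating, autistic spectrum, mental retardation and
#' ADHD, with index disorder 301.83 labelled \code{"BPD"}.
#'
#' @return an object of class \code{category_map}.
#' @export
default_category_map <- function() {
  if (is.null(.map_cache$map)) {
    .map_cache$map <- read_category_map(
      system.file("extdata", "category_map.yaml", package = "comorbidARM")
    )
  }
  .map_cache$map
}
.map_cache <- new.env(parent = emptyenv())

# prefix semantics: "296.2" matches itself and deeper subdivisions;
# a bare root "311" matches "311" and "311.x"
code_matches_prefix <- function(code, prefix) {
  if (grepl(".", prefix, fixed = TRUE)) {
    code == prefix | startsWith(code, prefix)
  } else {
    code == prefix | startsWith(code, paste0(prefix, "."))
  }
}

#' Map one ICD-9-CM code to its diagnosis categories
#'
#' Physical membership is decided by the integer 3-digit root falling in a
#' category's range; psychiatric membership by prefix lookup; union categories
#' (e.g. substance use disorder) are added when any member category matches.
#' The index code maps to the index label and, by construction of the default
#' map, to no physical category. A code may carry a physical and a psychiatric
#' label simultaneously.
#'
#' @param code a single ICD-9-CM code string.
#' @param map a \code{category_map}; defaults to [default_category_map()].
#' @return character vector of category names (empty, with a warning, for
#'   V/E-prefixed or malformed codes).
#' @export
categorize <- function(code, map = default_category_map()) {
  stopifnot(length(code) == 1)
  if (!is_icd9_code(code)) {
    warning("code ", code, " does not match the ICD-9-CM numeric grammar; no category")
    return(character(0))
  }
  out <- character(0)
  if (code == map$index_code) out <- c(out, map$index_label)
  root <- as.integer(substr(code, 1, 3))
  out <- c(out, map$physical$name[root >= map$physical$lo & root <= map$physical$hi])
  psy <- names(map$psychiatric)[vapply(
    map$psychiatric,
    function(p) any(vapply(p, function(pp) code_matches_prefix(code, pp), logical(1))),
    logical(1)
  )]
  out <- c(out, psy)
  for (u in names(map$unions)) {
    if (any(map$unions[[u]] %in% psy)) out <- c(out, u)
  }
  unique(out)
}

# vectorised internal: categories for each unique code, one warning for the
# lot of invalid codes
categorize_codes <- function(codes, map = default_category_map()) {
  uc <- unique(codes)
  bad <- !is_icd9_code(uc)
  if (any(bad)) {
    warning(sum(bad), " code(s) outside the ICD-9-CM numeric grammar ignored (e.g. ",
            uc[bad][1], ")")
  }
  cl <- vector("list", length(uc))
  names(cl) <- uc
  for (i in seq_along(uc)) {
    cl[[i]] <- if (bad[i]) character(0) else suppressWarnings(categorize(uc[i], map))
  }
  cl[match(codes, uc)]
}

#' Diagnosis categories of one person within a comorbidity window
#'
#' Takes the union of [categorize()] over the person's diagnoses dated within
#' \code{window_years} of the index date. The window is closed: a diagnosis
#' exactly \code{window_years} years away (365.25-day years) is included.
#'
#' @param diagnoses data frame with columns \code{icd9_code} and
#'   \code{diagnosis_date} (the person's own records).
#' @param index_date the anchoring date.
#' @param window_years half-width of the window in years (default 3).
#' @param map a \code{category_map}.
#' @return sorted character vector of category names.
#' @export
person_category_set <- function(diagnoses, index_date, window_years = 3,
                                map = default_category_map()) {
  stopifnot(window_years > 0)
  if (nrow(diagnoses) == 0) return(character(0))
  # closed window, measured in whole days: w years = round(w * 365.25) days,
  # so a record dated exactly w calendar years away is included
  keep <- !is.na(diagnoses$diagnosis_date) &
    abs(as.numeric(as.Date(diagnoses$diagnosis_date) - as.Date(index_date))) <=
      round(window_years * 365.25)
  codes <- unique(diagnoses$icd9_code[keep])
  codes <- codes[!is.na(codes)]
  if (length(codes) == 0) return(character(0))
  sort(unique(unlist(categorize_codes(codes, map))))
}
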