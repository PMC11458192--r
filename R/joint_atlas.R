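# mvdH Sharp joint inventory ------------------------------------------------

# Per-hand site table. Order: erosion inventory first (distal radius/ulna,
# carpal bones, M1 base, MCP1-5, IPP1-5), then the JSN-only carpal
# articulations and carpometacarpal joints. The thumb interphalangeal (IPP1)
# is scored for erosion only, so each hand carries 16 erosion sites and 15
# JSN sites.
hand_site_defs <- function() {
  scaph <- "Scapho\u00efd"
  tibble::tribble(
    ~slug,               ~name,                            ~erosion, ~jsn,
    "radius",            "Radius",                         TRUE,     FALSE,
    "ulna",              "Ulna",                           TRUE,     FALSE,
    "scaphoid",          scaph,                            TRUE,     FALSE,
    "lunatum",           "Lunatum",                        TRUE,     FALSE,
    "trapezium",         "Trapezium",                      TRUE,     FALSE,
    "m1_base",           "M1 base",                        TRUE,     FALSE,
    "mcp1",              "MCP1",                           TRUE,     TRUE,
    "mcp2",              "MCP2",                           TRUE,     TRUE,
    "mcp3",              "MCP3",                           TRUE,     TRUE,
    "mcp4",              "MCP4",                           TRUE,     TRUE,
    "mcp5",              "MCP5",                           TRUE,     TRUE,
    "ipp1",              "IPP1",                           TRUE,     FALSE,
    "ipp2",              "IPP2",                           TRUE,     TRUE,
    "ipp3",              "IPP3",                           TRUE,     TRUE,
    "ipp4",              "IPP4",                           TRUE,     TRUE,
    "ipp5",              "IPP5",                           TRUE,     TRUE,
    "scaphoid_radius",   paste0(scaph, "-radius"),         FALSE,    TRUE,
    "scaphoid_capitatum", paste0(scaph, "-Capitatum"),     FALSE,    TRUE,
    "scaphoid_trapezium", paste0(scaph, "-Trapezium"),     FALSE,    TRUE,
    "mcc3",              "MCC3",                           FALSE,    TRUE,
    "mcc4",              "MCC4",                           FALSE,    TRUE,
    "mcc5",              "MCC5",                           FALSE,    TRUE
  )
}

# Per-foot site table: six joints, each scored for both erosion and JSN.
foot_site_defs <- function() {
  tibble::tribble(
    ~slug,      ~name,      ~erosion, ~jsn,
    "ip1",      "IP1 foot", TRUE,     TRUE,
    "mtp1",     "MTP1",     TRUE,     TRUE,
    "mtp2",     "MTP2",     TRUE,     TRUE,
    "mtp3",     "MTP3",     TRUE,     TRUE,
    "mtp4",     "MTP4",     TRUE,     TRUE,
    "mtp5",     "MTP5",     TRUE,     TRUE
  )
}

#' Build the default mvdH Sharp joint atlas for one patient
#'
#' Enumerates every joint site scored by the modified van der Heijde Sharp
#' method for a single patient: 16 erosion sites and 15 joint-space-narrowing
#' (JSN) sites per hand, and 6 sites per foot scored for both lesion types.
#' That yields 44 erosion-scored and 42 JSN-scored sites per patient.
#'
#' Enumeration order is deterministic: hands before feet, right before left,
#' and within a hand the erosion inventory first (radius, ulna, carpal bones,
#' M1 base, MCP1-5, IPP1-5) followed by the JSN-only carpal articulations and
#' carpometacarpal joints.
#'
#' Score caps follow the mvdH convention: erosions are graded up to 5 per hand
#' joint and up to 10 per foot joint; JSN is graded up to 4 everywhere.
#'
#' @return A tibble of class `mvdh_atlas` with one row per joint site and
#'   columns `site_id`, `region` (`"hand"`/`"foot"`), `side`
#'   (`"right"`/`"left"`), `name`, `erosion`, `jsn` (logical: is the lesion
#'   scored at this site), `max_erosion`, `max_jsn`.
#' @examples
#' atlas <- build_default_atlas()
#' sum(atlas$erosion)  # 44 erosion-scored sites per patient
#' @export
build_default_atlas <- function() {
  one_region <- function(defs, region, side) {
    ero_cap <- if (region == "hand") 5L else 10L
    tibble::tibble(
      site_id = paste(region, substr(side, 1, 1), defs$slug, sep = "_"),
      region = region,
      side = side,
      name = defs$name,
      erosion = defs$erosion,
      jsn = defs$jsn,
      max_erosion = ifelse(defs$erosion, ero_cap, NA_integer_),
      max_jsn = ifelse(defs$jsn, 4L, NA_integer_)
    )
  }
  atlas <- dplyr::bind_rows(
    one_region(hand_site_defs(), "hand", "right"),
    one_region(hand_site_defs(), "hand", "left"),
    one_region(foot_site_defs(), "foot", "right"),
    one_region(foot_site_defs(), "foot", "left")
  )
  class(atlas) <- c("mvdh_atlas", class(atlas))
  atlas
}

lesion_types <- function() c("erosion", "jsn")

check_lesion <- function(lesion) {
  if (!is.character(lesion) || length(lesion) != 1L || !lesion %in% lesion_types()) {
    stop("`lesion` must be one of: ", paste(lesion_types(), collapse = ", "),
         call. = FALSE)
  }
  lesion
}

#' Filter atlas sites by region and lesion type
#'
#' @param atlas An atlas from [build_default_atlas()].
#' @param region Optional: `"hand"` or `"foot"`.
#' @param lesion Optional: `"erosion"` or `"jsn"`; keeps sites scored for it.
#' @return The matching atlas rows, in atlas (enumeration) order.
#' @examples
#' nrow(sites_for(build_default_atlas(), region = "hand", lesion = "jsn"))  # 30
#' @export
sites_for <- function(atlas, region = NULL, lesion = NULL) {
  stopifnot(inherits(atlas, "mvdh_atlas"))
  out <- atlas
  if (!is.null(region)) {
    if (!region %in% c("hand", "foot")) {
      stop("`region` must be \"hand\" or \"foot\"", call. = FALSE)
    }
    out <- out[out$region == region, ]
  }
  if (!is.null(lesion)) {
    check_lesion(lesion)
    out <- out[out[[lesion]], ]
  }
  out
}

#' Maximum score for a joint site and lesion type
#'
#' Returns the integer cap applied when rounding eye-tracking scores: 5 for
#' hand erosions, 10 for foot erosions, 4 for JSN anywhere.
#'
#' @param site One or more atlas rows (a subset of an `mvdh_atlas`).
#' @param lesion `"erosion"` or `"jsn"`.
#' @return Integer vector of caps, one per site row.
#' @export
score_cap <- function(site, lesion) {
  check_lesion(lesion)
  if (!all(site[[lesion]])) {
    bad <- site$site_id[!site[[lesion]]]
    stop("site(s) not scored for ", lesion, ": ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (lesion == "erosion") site$max_erosion else site$max_jsn
}

#' Write an atlas to JSON
#'
#' Serializes the full site table; [read_atlas_json()] round-trips it
#' losslessly.
#'
#' @param atlas An `mvdh_atlas`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_atlas_json <- function(atlas, path) {
  stopifnot(inherits(atlas, "mvdh_atlas"))
  jsonlite::write_json(as.data.frame(atlas), path, auto_unbox = FALSE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' Read an atlas from JSON
#'
#' @param path File written by [write_atlas_json()].
#' @return An `mvdh_atlas` tibble.
#' @export
read_atlas_json <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  atlas <- tibble::as_tibble(df)
  atlas$max_erosion <- as.integer(atlas$max_erosion)
  atlas$max_jsn <- as.integer(atlas$max_jsn)
  class(atlas) <- c("mvdh_atlas", class(atlas))
  atlas
}
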