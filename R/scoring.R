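# Fixation duration -> mvdH Sharp score conversion --------------------------

#' Convert a total fixation duration to a raw Sharp score
#'
#' The reading protocol assigns one Sharp point per 2 s of fixation on a
#' joint, on top of a 1 s dwell spent even on a healthy joint. The conversion
#' divides the total fixation duration in milliseconds by 1000, halves it,
#' and subtracts 0.5 to remove that background dwell:
#' `max(0, ms / 1000 / 2 - 0.5)`. Durations under 1 s clip to 0 rather than
#' going negative.
#'
#' @param total_fixation_ms Total fixation duration(s) in ms; must be >= 0.
#' @return Raw (continuous, non-negative) Sharp points.
#' @examples
#' fixation_to_raw_score(3000)  # 1 point
#' @export
fixation_to_raw_score <- function(total_fixation_ms) {
  if (any(!is.finite(total_fixation_ms)) || any(total_fixation_ms < 0)) {
    stop("total_fixation_ms must be finite and >= 0", call. = FALSE)
  }
  pmax(0, total_fixation_ms / 1000 / 2 - 0.5)
}

#' Round a raw score to an integer and clip to the site's cap
#'
#' Nearest integer with half-up ties, then clipped to `[0, cap]`.
#'
#' @param raw Non-negative raw score(s).
#' @param cap Integer cap(s), >= 1 (recycled against `raw`).
#' @return Integer score(s).
#' @export
round_and_clip <- function(raw, cap) {
  stopifnot(all(raw >= 0), all(cap >= 1))
  as.integer(pmin(floor(raw + 0.5), cap))
}

#' Class bins used for agreement tables
#'
#' Scores are compared in seven ordinal classes: 0, 1, 2, 3, 4, 5 and an
#' open-ended top class for 6 or more.
#'
#' @return Character vector of bin labels in order.
#' @export
mvdh_bins <- function() c("0", "1", "2", "3", "4", "5", "\u22656")

#' Bin an integer score into the agreement classes
#'
#' @param score Integer score(s) >= 0.
#' @return Factor with levels [mvdh_bins()]: the score itself for 0-5, the
#'   top class for anything >= 6.
#' @export
class_bin <- function(score) {
  stopifnot(all(score >= 0))
  lab <- ifelse(score >= 6, "\u22656", as.character(score))
  factor(lab, levels = mvdh_bins())
}

#' Score one eye-tracking reading
#'
#' Applies the duration-to-score conversion, rounding and class binning to a
#' per-site fixation summary. Sites flagged non-analyzable are omitted, as
#' their fixation time could not be attributed.
#'
#' @param summaries Per-site summary from [assign_fixations()].
#' @param atlas An `mvdh_atlas`.
#' @param lesion `"erosion"` or `"jsn"`; every site scored for this lesion
#'   must appear in `summaries`.
#' @return A tibble `site_id, lesion, total_fixation_ms, raw_score, score,
#'   class_bin`, one row per analyzable site.
#' @export
score_reading <- function(summaries, atlas, lesion) {
  check_lesion(lesion)
  sites <- sites_for(atlas, lesion = lesion)
  idx <- match(sites$site_id, summaries$site_id)
  if (anyNA(idx)) {
    stop("summaries are missing site(s): ",
         paste(sites$site_id[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  caps <- score_cap(sites, lesion)
  keep <- summaries$analyzable[idx]
  total <- summaries$total_fixation_ms[idx][keep]
  raw <- fixation_to_raw_score(total)
  score <- round_and_clip(raw, caps[keep])
  tibble::tibble(
    site_id = sites$site_id[keep],
    lesion = lesion,
    total_fixation_ms = total,
    raw_score = raw,
    score = score,
    class_bin = class_bin(score)
  )
}

#' Write a score table CSV
#'
#' Header `patient,radiograph,site_id,lesion,total_fixation_ms,raw_score,score,class_bin`.
#'
#' @param scores Score table (e.g. from [score_reading()], with `patient` and
#'   `radiograph` columns added by the caller; missing ones are filled with
#'   `NA`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_csv <- function(scores, path) {
  cols <- c("patient", "radiograph", "site_id", "lesion",
            "total_fixation_ms", "raw_score", "score", "class_bin")
  for (col in setdiff(cols, names(scores))) scores[[col]] <- NA
  utils::write.csv(scores[, cols], path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
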