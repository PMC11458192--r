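# Synthetic gaze-data generator ---------------------------------------------
#
# Emulates the reading protocol the pipeline assumes: a trained reader dwells
# on each joint for baseline_ms plus ms_per_point per Sharp point, with
# additive timing noise, and occasionally two close pathological joints
# receive fixations that land in the overlap of their regions of interest and
# cannot be attributed to either.

# Per-joint Sharp score means and SDs used as sampling defaults, keyed by
# joint name and lesion type (left and right share parameters).
default_score_params <- function() {
  scaph <- "Scapho\u00efd"
  ero_hand <- tibble::tribble(
    ~name, ~mean, ~sd,
    "Radius", 0.25, 0.64,
    "Ulna", 0.45, 0.89,
    scaph, 0.40, 1.05,
    "Lunatum", 0.35, 0.75,
    "Trapezium", 0.30, 0.57,
    "M1 base", 0.35, 0.75,
    "MCP1", 0.25, 0.55,
    "MCP2", 0.90, 1.12,
    "MCP3", 0.80, 1.12,
    "MCP4", 0.30, 0.66,
    "MCP5", 0.10, 0.31,
    "IPP1", 0.15, 0.67,
    "IPP2", 0.45, 0.89,
    "IPP3", 0.50, 0.83,
    "IPP4", 0.30, 0.58,
    "IPP5", 0.30, 0.89
  )
  ero_foot <- tibble::tribble(
    ~name, ~mean, ~sd,
    "IP1 foot", 0.55, 0.93,
    "MTP1", 0.75, 2.05,
    "MTP2", 0.25, 0.64,
    "MTP3", 1.20, 1.99,
    "MTP4", 1.10, 2.08,
    "MTP5", 1.15, 1.73
  )
  jsn_hand <- tibble::tribble(
    ~name, ~mean, ~sd,
    paste0(scaph, "-radius"), 0.95, 1.40,
    paste0(scaph, "-Capitatum"), 0.90, 1.02,
    paste0(scaph, "-Trapezium"), 0.75, 1.41,
    "MCC3", 0.75, 1.55,
    "MCC4", 0.35, 1.09,
    "MCC5", 0.45, 0.95,
    "MCP1", 0.40, 0.82,
    "MCP2", 1.50, 1.54,
    "MCP3", 1.40, 1.47,
    "MCP4", 0.85, 1.39,
    "MCP5", 0.85, 1.53,
    "IPP2", 0.60, 1.19,
    "IPP3", 0.65, 1.22,
    "IPP4", 0.65, 1.35,
    "IPP5", 0.55, 1.10
  )
  jsn_foot <- tibble::tribble(
    ~name, ~mean, ~sd,
    "IP1 foot", 0.90, 1.25,
    "MTP1", 0.70, 1.49,
    "MTP2", 0.80, 1.54,
    "MTP3", 1.25, 1.80,
    "MTP4", 1.45, 1.73,
    "MTP5", 0.80, 1.32
  )
  dplyr::bind_rows(
    dplyr::mutate(dplyr::bind_rows(ero_hand, ero_foot), lesion = "erosion"),
    dplyr::mutate(dplyr::bind_rows(jsn_hand, jsn_foot), lesion = "jsn")
  )[, c("name", "lesion", "mean", "sd")]
}

#' Simulation configuration for the synthetic gaze generator
#'
#' Bundles the parameters of the simulated reading protocol. Defaults emulate
#' the study design the pipeline targets: 10 patients, a 1 s per-joint
#' baseline dwell, 2 s of fixation per Sharp point, two replicate readings
#' per lesion type, and a 5\% chance that a pathological joint pair is too
#' close for its fixation time to be attributed.
#'
#' @param n_patients Number of simulated patients.
#' @param baseline_ms Dwell time in ms spent on any joint, healthy or not.
#' @param ms_per_point Additional fixation ms per Sharp point (the reader is
#'   trained to 2 s per point).
#' @param duration_noise_sd_ms SD of additive Gaussian timing noise in ms;
#'   totals are floored at 1 ms. 0 gives exact, noiseless durations.
#' @param score_params Data frame `name, lesion, mean, sd` giving the per-site
#'   Sharp score distribution parameters; defaults to the built-in per-joint
#'   means/SDs.
#' @param n_replicates Replicate readings per lesion type.
#' @param ambiguity_rate Probability that an adjacent ROI pair containing at
#'   least one pathological joint is read ambiguously (fixations land in the
#'   overlap of the two ROIs and the pair becomes non-analyzable).
#' @param canvas_w,canvas_h Canvas size in pixels.
#' @param roi_radius ROI radius in pixels for the synthetic layout.
#' @param n_background Off-ROI background fixations added per reading.
#' @param seed Integer seed; fully determines all generator output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 10L,
                       baseline_ms = 1000,
                       ms_per_point = 2000,
                       duration_noise_sd_ms = 300,
                       score_params = default_score_params(),
                       n_replicates = 2L,
                       ambiguity_rate = 0.05,
                       canvas_w = 1920L,
                       canvas_h = 1080L,
                       roi_radius = 30,
                       n_background = 5L,
                       seed = 1L) {
  stopifnot(
    n_patients >= 0, baseline_ms >= 0, ms_per_point >= 0,
    duration_noise_sd_ms >= 0, n_replicates >= 1,
    ambiguity_rate >= 0, ambiguity_rate <= 1,
    canvas_w > 0, canvas_h > 0, roi_radius > 0, n_background >= 0
  )
  stopifnot(all(c("name", "lesion", "mean", "sd") %in% names(score_params)))
  stopifnot(all(score_params$mean >= 0), all(score_params$sd >= 0))
  structure(
    list(
      n_patients = as.integer(n_patients),
      baseline_ms = baseline_ms,
      ms_per_point = ms_per_point,
      duration_noise_sd_ms = duration_noise_sd_ms,
      score_params = score_params,
      n_replicates = as.integer(n_replicates),
      ambiguity_rate = ambiguity_rate,
      canvas_w = as.integer(canvas_w),
      canvas_h = as.integer(canvas_h),
      roi_radius = roi_radius,
      n_background = as.integer(n_background),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# Discretized truncated normal on 0..cap: integer k gets the normal mass in
# (k - 0.5, k + 0.5), with both tails folded into 0 and cap.
disc_truncnorm_probs <- function(mu, sigma, cap) {
  k <- 0:cap
  hi <- c(k[-length(k)] + 0.5, Inf)
  lo <- c(-Inf, k[-1] - 0.5)
  p <- stats::pnorm(hi, mu, sigma) - stats::pnorm(lo, mu, sigma)
  p / sum(p)
}

# Solve for the latent normal mean so the discretized distribution has the
# requested mean: naive truncation at 0 would otherwise inflate low means.
calibrate_score_probs <- function(target_mean, sigma, cap) {
  k <- 0:cap
  if (target_mean <= 0) {
    return(c(1, rep(0, cap)))
  }
  if (target_mean >= cap) {
    return(c(rep(0, cap), 1))
  }
  if (sigma < 1e-9) {
    p <- rep(0, cap + 1)
    p[min(floor(target_mean + 0.5), cap) + 1] <- 1
    return(p)
  }
  f <- function(mu) sum(k * disc_truncnorm_probs(mu, sigma, cap)) - target_mean
  lo <- -10 * sigma - 1
  hi <- cap + 10 * sigma + 1
  mu <- stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
  disc_truncnorm_probs(mu, sigma, cap)
}

#' Simulate ground-truth Sharp scores for every scored joint
#'
#' Draws one integer score per (patient, site, lesion) from a discretized
#' truncated normal on `0..cap` whose mean is calibrated to the configured
#' per-site mean (so sample means recover the configured means, unbiased by
#' truncation). Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @param atlas An atlas from [build_default_atlas()].
#' @return A tibble `patient, site_id, lesion, true_score`.
#' @export
simulate_true_scores <- function(config, atlas) {
  stopifnot(inherits(config, "sim_config"), inherits(atlas, "mvdh_atlas"))
  set.seed(config$seed)
  rows <- lapply(lesion_types(), function(lesion) {
    sites <- sites_for(atlas, lesion = lesion)
    caps <- score_cap(sites, lesion)
    par <- config$score_params[config$score_params$lesion == lesion, ]
    idx <- match(sites$name, par$name)
    if (anyNA(idx)) {
      stop("no score parameters for site name(s): ",
           paste(unique(sites$name[is.na(idx)]), collapse = ", "), call. = FALSE)
    }
    tibble::tibble(
      site_id = rep(sites$site_id, each = config$n_patients),
      lesion = lesion,
      patient = rep(seq_len(config$n_patients), times = nrow(sites)),
      mean = rep(par$mean[idx], each = config$n_patients),
      sd = rep(par$sd[idx], each = config$n_patients),
      cap = rep(caps, each = config$n_patients)
    )
  })
  tab <- dplyr::bind_rows(rows)
  if (nrow(tab) == 0L) {
    return(tibble::tibble(patient = integer(), site_id = character(),
                          lesion = character(), true_score = integer()))
  }
  # draw per (mean, sd, cap) group so calibration is done once per group
  tab$true_score <- NA_integer_
  key <- paste(tab$mean, tab$sd, tab$cap)
  for (k in unique(key)) {
    sel <- key == k
    p <- calibrate_score_probs(tab$mean[sel][1], tab$sd[sel][1], tab$cap[sel][1])
    tab$true_score[sel] <- sample(0:tab$cap[sel][1], sum(sel),
                                  replace = TRUE, prob = p)
  }
  out <- tab[order(tab$patient, match(tab$site_id, atlas$site_id), tab$lesion),
             c("patient", "site_id", "lesion", "true_score")]
  tibble::as_tibble(out)
}

#' Build the synthetic ROI layout for one lesion type
#'
#' Lays the lesion's joint sites out on the canvas as circles, in atlas order,
#' grouped by region and side. Consecutive sites within a group form adjacent
#' pairs whose centres are 1.5 radii apart (so the two discs overlap: "too
#' close" pairs); distinct pairs and rows are widely separated. This geometry
#' lets the generator place ambiguous fixations inside a pair's overlap while
#' keeping ordinary fixations unambiguous.
#'
#' @param atlas An `mvdh_atlas`.
#' @param lesion `"erosion"` or `"jsn"`.
#' @param config A [sim_config()] supplying canvas size and ROI radius.
#' @return A tibble `site_id, cx, cy, radius` of class `roi_layout`.
#' @export
build_roi_layout <- function(atlas, lesion, config = sim_config()) {
  check_lesion(lesion)
  r <- config$roi_radius
  per_row <- 8L
  pair_gap <- 1.5 * r       # centres of a pair: discs overlap
  pair_pitch <- 1.5 * r + 4 * r
  row_pitch <- 5 * r
  x0 <- 3 * r + 10
  y0 <- 3 * r + 10
  groups <- list(c("hand", "right"), c("hand", "left"),
                 c("foot", "right"), c("foot", "left"))
  row_offset <- 0L
  out <- list()
  for (g in groups) {
    sites <- sites_for(atlas, region = g[1], lesion = lesion)
    sites <- sites[sites$side == g[2], ]
    m <- nrow(sites)
    if (m == 0L) next
    j <- seq_len(m)
    row_in_group <- ceiling(j / per_row)
    j_in_row <- j - (row_in_group - 1L) * per_row
    pair <- ceiling(j_in_row / 2)
    member <- (j_in_row - 1L) %% 2L
    cx <- x0 + (pair - 1) * pair_pitch + member * pair_gap
    cy <- y0 + (row_offset + row_in_group - 1L) * row_pitch
    out[[length(out) + 1L]] <- tibble::tibble(
      site_id = sites$site_id, cx = cx, cy = cy, radius = r
    )
    row_offset <- row_offset + max(row_in_group)
  }
  layout <- dplyr::bind_rows(out)
  if (any(layout$cx > config$canvas_w - r) || any(layout$cy > config$canvas_h - r)) {
    stop("canvas too small for the ROI layout at this radius", call. = FALSE)
  }
  class(layout) <- c("roi_layout", class(layout))
  layout
}

# Disjoint "too close" pairs: greedy pass over sites in layout order, pairing
# each unpaired site with the first later unpaired site whose centre lies
# within 2 radii (i.e. the discs overlap).
close_pairs <- function(layout) {
  n <- nrow(layout)
  taken <- rep(FALSE, n)
  pairs <- list()
  for (i in seq_len(n)) {
    if (taken[i]) next
    for (j in seq_len(n)[-seq_len(i)]) {
      if (taken[j]) next
      d <- sqrt((layout$cx[i] - layout$cx[j])^2 + (layout$cy[i] - layout$cy[j])^2)
      if (d < layout$radius[i] + layout$radius[j]) {
        pairs[[length(pairs) + 1L]] <- c(i, j)
        taken[i] <- taken[j] <- TRUE
        break
      }
    }
  }
  pairs
}

# Split an integer total into k positive integer chunks (random proportions).
split_duration <- function(total, k) {
  k <- max(1L, min(k, total))
  if (k == 1L) return(total)
  w <- stats::runif(k, 0.5, 1.5)
  chunk <- floor(total * w / sum(w))
  chunk[chunk < 1L] <- 1L
  rem <- total - sum(chunk)
  chunk[1] <- chunk[1] + rem
  if (chunk[1] < 1L) { # pathological small totals: fall back to one chunk
    return(total)
  }
  chunk
}

#' Simulate one eye-tracking reading of a radiograph
#'
#' Emits a fixation stream for one patient, lesion type and replicate. Each
#' scored joint receives fixations inside its ROI totalling
#' `baseline_ms + ms_per_point * true_score` plus truncated Gaussian noise.
#' With probability `ambiguity_rate`, an adjacent ROI pair containing at least
#' one pathological joint (true score >= 1) is read ambiguously: both joints'
#' fixations are placed in the overlap of the two discs, which downstream
#' assignment flags as non-analyzable. Off-ROI background fixations are
#' appended. Fixations are time-ordered and non-overlapping.
#'
#' @param truth Truth table from [simulate_true_scores()].
#' @param layout ROI layout from [build_roi_layout()].
#' @param config A [sim_config()].
#' @param lesion `"erosion"` or `"jsn"`.
#' @param replicate Replicate index (1-based).
#' @param patient Patient index present in `truth`.
#' @return A fixation stream: tibble `t_start_ms, x, y, duration_ms`, all
#'   integer-valued.
#' @export
simulate_reading <- function(truth, layout, config, lesion, replicate = 1L,
                             patient = 1L) {
  stopifnot(inherits(config, "sim_config"))
  check_lesion(lesion)
  tr <- truth[truth$patient == patient & truth$lesion == lesion, ]
  idx <- match(layout$site_id, tr$site_id)
  if (anyNA(idx)) {
    stop("truth table does not cover layout site(s): ",
         paste(layout$site_id[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  scores <- tr$true_score[idx]
  set.seed((config$seed %% 100000L) * 17389L + patient * 1009L +
             (lesion == "jsn") * 389L + replicate * 31L)

  n <- nrow(layout)
  centre_x <- layout$cx
  centre_y <- layout$cy
  jitter_r <- 0.25 * layout$radius

  ambiguous <- rep(FALSE, n)
  for (p in close_pairs(layout)) {
    if (any(scores[p] >= 1L) && stats::runif(1) < config$ambiguity_rate) {
      ambiguous[p] <- TRUE
      mx <- mean(layout$cx[p]); my <- mean(layout$cy[p])
      d <- sqrt(diff(layout$cx[p])^2 + diff(layout$cy[p])^2)
      centre_x[p] <- mx
      centre_y[p] <- my
      # stay inside both discs (and clear of integer rounding) after jitter
      jitter_r[p] <- max(0, min(layout$radius[p]) - d / 2 - 1.5) * 0.8
    }
  }

  ev <- list()
  for (i in seq_len(n)) {
    total <- config$baseline_ms + config$ms_per_point * scores[i]
    if (config$duration_noise_sd_ms > 0) {
      total <- total + stats::rnorm(1, 0, config$duration_noise_sd_ms)
    }
    total <- max(1L, as.integer(round(total)))
    chunks <- split_duration(total, k = as.integer(ceiling(total / 1500)))
    k <- length(chunks)
    ang <- stats::runif(k, 0, 2 * pi)
    rad <- jitter_r[i] * sqrt(stats::runif(k))
    ev[[i]] <- tibble::tibble(
      x = as.integer(round(centre_x[i] + rad * cos(ang))),
      y = as.integer(round(centre_y[i] + rad * sin(ang))),
      duration_ms = as.integer(chunks)
    )
  }

  if (config$n_background > 0L) {
    bg <- matrix(NA_real_, 0, 2)
    tries <- 0L
    while (nrow(bg) < config$n_background && tries < 1000L) {
      px <- stats::runif(1, 1, config$canvas_w - 1)
      py <- stats::runif(1, 1, config$canvas_h - 1)
      d2 <- (px - layout$cx)^2 + (py - layout$cy)^2
      if (all(d2 > (2.2 * layout$radius)^2)) bg <- rbind(bg, c(px, py))
      tries <- tries + 1L
    }
    if (nrow(bg) > 0L) {
      ev[[length(ev) + 1L]] <- tibble::tibble(
        x = as.integer(round(bg[, 1])),
        y = as.integer(round(bg[, 2])),
        duration_ms = as.integer(round(stats::runif(nrow(bg), 100, 400)))
      )
    }
  }

  stream <- dplyr::bind_rows(ev)
  gaps <- as.integer(round(stats::runif(nrow(stream), 30, 120)))
  ends <- cumsum(as.numeric(stream$duration_ms) + gaps)
  stream$t_start_ms <- as.integer(c(0, ends[-length(ends)]))
  stream[, c("t_start_ms", "x", "y", "duration_ms")]
}

#' Write a fixation stream to the tab-separated export dialect
#'
#' Columns `t_start_ms`, `x`, `y`, `duration_ms`, tab-separated, UTF-8, one
#' fixation per row. [read_fixation_export()] round-trips the stream exactly.
#'
#' @param stream Fixation stream tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fixation_export <- function(stream, path) {
  cols <- c("t_start_ms", "x", "y", "duration_ms")
  stopifnot(all(cols %in% names(stream)))
  utils::write.table(stream[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n",
                     fileEncoding = "UTF-8")
  invisible(path)
}
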