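# Agreement statistics: contingency tables, Cohen's kappa, ICC --------------

#' Build an ordinal contingency table from paired class labels
#'
#' Rows index the eye-tracking class, columns the reference class.
#'
#' @param eye,ref Paired class labels (character, factor or integer); every
#'   value must be one of `bins`.
#' @param bins Ordered bin labels; defaults to [mvdh_bins()].
#' @return A square integer matrix of class `contingency_table` with
#'   `dimnames = list(eye = bins, ref = bins)`.
#' @export
build_contingency <- function(eye, ref, bins = mvdh_bins()) {
  stopifnot(length(eye) == length(ref))
  eye <- as.character(eye)
  ref <- as.character(ref)
  bad <- setdiff(unique(c(eye, ref)), bins)
  if (length(bad) > 0L) {
    stop("class label(s) outside the bins: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  counts <- table(factor(eye, levels = bins), factor(ref, levels = bins))
  m <- matrix(as.integer(counts), nrow = length(bins),
              dimnames = list(eye = bins, ref = bins))
  structure(m, class = c("contingency_table", class(m)))
}

as_contingency <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m), all(m >= 0))
  if (!inherits(m, "contingency_table")) {
    class(m) <- c("contingency_table", class(m))
  }
  m
}

#' Unweighted Cohen's kappa with an asymptotic 95\% confidence interval
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` on a square
#' contingency table, with the large-sample (Fleiss-Cohen-Everitt) standard
#' error and a `kappa +/- 1.96 se` interval.
#'
#' @param table A square counts matrix (rows = eye-tracking, columns =
#'   reference), e.g. from [build_contingency()].
#' @return A list of class `kappa_result`: `kappa`, `se`, `ci_low`,
#'   `ci_high`, `p_o`, `p_e`, `n`.
#' @export
cohen_kappa <- function(table) {
  m <- as_contingency(unclass(table))
  n <- sum(m)
  if (n <= 0) stop("contingency table is empty", call. = FALSE)
  p <- m / n
  po <- sum(diag(p))
  pr <- rowSums(p)
  pc <- colSums(p)
  pe <- sum(pr * pc)
  if (pe >= 1 - 1e-12) {
    stop("degenerate table: all mass in a single class (p_e = 1)",
         call. = FALSE)
  }
  kappa <- (po - pe) / (1 - pe)
  # Fleiss, Cohen & Everitt large-sample variance of kappa-hat
  a_term <- sum(diag(p) * ((1 - pe) - (pr + pc) * (1 - po))^2)
  b_mat <- p * outer(seq_along(pr), seq_along(pc), function(i, j) {
    (pc[i] + pr[j])^2
  })
  diag(b_mat) <- 0
  b_term <- (1 - po)^2 * sum(b_mat)
  c_term <- (po * pe - 2 * pe + po)^2
  var_k <- (a_term + b_term - c_term) / (n * (1 - pe)^4)
  se <- sqrt(max(0, var_k))
  structure(
    list(kappa = kappa, se = se,
         ci_low = kappa - 1.96 * se, ci_high = kappa + 1.96 * se,
         p_o = po, p_e = pe, n = n),
    class = "kappa_result"
  )
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa: %.3f (95%% CI %.3f-%.3f), p_o = %.3f, p_e = %.3f, n = %d\n",
              x$kappa, x$ci_low, x$ci_high, x$p_o, x$p_e, x$n))
  invisible(x)
}

#' Collapse a contingency table to lesion present / absent
#'
#' `"no"` is the first bin (score 0); `"yes"` pools every other bin (at least
#' one erosion or JSN).
#'
#' @param table A square counts matrix whose first bin is score 0.
#' @return A 2x2 `contingency_table` with bins `no`, `yes`.
#' @export
dichotomize <- function(table) {
  m <- unclass(as_contingency(table))
  if (nrow(m) < 2L) stop("need at least two bins to dichotomize", call. = FALSE)
  out <- matrix(
    c(m[1, 1], sum(m[1, -1]),
      sum(m[-1, 1]), sum(m[-1, -1])),
    nrow = 2, byrow = TRUE,
    dimnames = list(eye = c("no", "yes"), ref = c("no", "yes"))
  )
  structure(out, class = c("contingency_table", class(out)))
}

#' Intraclass correlation for replicate readings
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC -- the
#' reproducibility of a single reading when the same reader re-reads the same
#' joints -- with the F-distribution 95\% confidence bounds of McGraw & Wong.
#'
#' @param ratings Numeric matrix or data frame, one row per joint and one
#'   column per replicate reading; rows with missing values are dropped.
#' @return A list of class `icc_result`: `icc`, `ci_low`, `ci_high`, the mean
#'   squares (`msr` rows, `msc` columns, `mse` residual), `n` joints and `k`
#'   replicates.
#' @export
icc <- function(ratings) {
  x <- as.matrix(ratings)
  storage.mode(x) <- "double"
  x <- x[stats::complete.cases(x), , drop = FALSE]
  n <- nrow(x)
  k <- ncol(x)
  if (n < 2L || k < 2L) {
    stop("need >= 2 joints with >= 2 replicate ratings", call. = FALSE)
  }
  grand <- mean(x)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  ss_total <- sum((x - grand)^2)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (denom <= 0) stop("no variance in ratings", call. = FALSE)
  est <- (msr - mse) / denom
  if (abs(1 - est) < 1e-12 || mse <= 0) {
    ci <- c(est, est)
  } else {
    alpha <- 0.05
    a <- (k * est) / (n * (1 - est))
    b <- 1 + (k * est * (n - 1)) / (n * (1 - est))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
    ci <- c(lower, upper)
  }
  structure(
    list(icc = est, ci_low = ci[1], ci_high = ci[2],
         msr = msr, msc = msc, mse = mse, n = n, k = k),
    class = "icc_result"
  )
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(A,1): %.3f (95%% CI %.3f-%.3f), n = %d joints, k = %d replicates\n",
              x$icc, x$ci_low, x$ci_high, x$n, x$k))
  invisible(x)
}

#' Pair two score tables for agreement analysis
#'
#' Joins an eye-tracking score table and a reference score table on their
#' common identifier columns (`site_id`, plus `patient` and `lesion` when
#' present in both) and returns the paired class bins. Joints absent from
#' either table -- e.g. non-analyzable in the eye-tracking reading -- are
#' excluded pairwise.
#'
#' @param eye,ref Data frames with a `score` column and identifier columns.
#' @return A tibble with the join keys plus `eye_class`, `ref_class`.
#' @export
pair_scores <- function(eye, ref) {
  keys <- intersect(intersect(names(eye), names(ref)),
                    c("patient", "site_id", "lesion"))
  if (!"site_id" %in% keys) stop("both tables need a site_id column", call. = FALSE)
  stopifnot("score" %in% names(eye), "score" %in% names(ref))
  joined <- dplyr::inner_join(
    eye[, c(keys, "score")],
    ref[, c(keys, "score")],
    by = keys, suffix = c("_eye", "_ref")
  )
  joined$eye_class <- class_bin(joined$score_eye)
  joined$ref_class <- class_bin(joined$score_ref)
  tibble::as_tibble(joined[, c(keys, "eye_class", "ref_class")])
}

#' Write / read a contingency table as CSV
#'
#' Bin labels form the header row and the first column.
#'
#' @param table A `contingency_table`.
#' @param path File path.
#' @return `write_contingency_csv()`: `path` invisibly;
#'   `read_contingency_csv()`: a `contingency_table`.
#' @export
write_contingency_csv <- function(table, path) {
  m <- unclass(as_contingency(table))
  df <- data.frame(bin = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_contingency_csv
#' @export
read_contingency_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  dimnames(m) <- list(eye = as.character(df[[1]]), ref = colnames(df)[-1])
  as_contingency(m)
}

#' Packaged agreement tables of the published study design
#'
#' Returns the packaged 7x7 eye-tracking vs reference contingency table for
#' one lesion type (bins 0-5 and an open top bin), as shipped in
#' `inst/extdata/`.
#'
#' @param lesion `"erosion"` or `"jsn"`.
#' @return A `contingency_table`.
#' @export
mvdh_table2 <- function(lesion = c("erosion", "jsn")) {
  lesion <- match.arg(lesion)
  path <- system.file("extdata", paste0("table2_", lesion, ".csv"),
                      package = "gazesharp", mustWork = TRUE)
  read_contingency_csv(path)
}
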