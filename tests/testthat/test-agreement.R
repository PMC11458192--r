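test_that("contingency tables count paired class labels", {
  tab <- build_contingency(c("0", "0", "1"), c("0", "0", "1"))
  expect_equal(unname(diag(unclass(tab))[1:2]), c(2L, 1L))
  expect_equal(sum(tab), 3L)

  empty <- build_contingency(character(), character())
  expect_equal(sum(empty), 0L)
  expect_error(cohen_kappa(empty), "empty")

  expect_error(build_contingency("7", "0"), "outside the bins")
})

test_that("kappa is 1 on diagonal tables and matches the printed tables", {
  diag_tab <- build_contingency(class_bin(c(0, 1, 1, 3)), class_bin(c(0, 1, 1, 3)))
  expect_equal(cohen_kappa(diag_tab)$kappa, 1.0)

  ero <- cohen_kappa(mvdh_table2("erosion"))
  expect_equal(ero$p_o, 384 / 414)
  expect_equal(ero$p_e, 99272 / 171396)
  expect_equal(ero$kappa, 0.828, tolerance = 1e-3)

  jsn <- cohen_kappa(mvdh_table2("jsn"))
  expect_equal(jsn$p_o, 330 / 396)
  expect_equal(jsn$p_e, 74592 / 156816)
  expect_equal(jsn$kappa, 0.682, tolerance = 1e-3)

  # independent library cross-check
  expect_equal(ero$kappa,
               e1071::classAgreement(unclass(mvdh_table2("erosion")))$kappa)
  expect_equal(jsn$kappa,
               e1071::classAgreement(unclass(mvdh_table2("jsn")))$kappa)

  expect_true(ero$ci_low <= ero$kappa && ero$kappa <= ero$ci_high)
})

test_that("kappa errors on a single-cell table", {
  m <- matrix(0L, 2, 2)
  m[1, 1] <- 10L
  expect_error(cohen_kappa(m), "degenerate")
})

test_that("kappa agrees with a first-principles computation on small tables", {
  set.seed(2024)
  for (rep in 1:50) {
    n_bins <- sample(2:4, 1)
    n <- sample(5:20, 1)
    bins <- as.character(seq_len(n_bins) - 1)
    eye <- sample(bins, n, replace = TRUE)
    ref <- sample(bins, n, replace = TRUE)
    if (all(eye == eye[1]) && all(ref == eye[1])) next  # degenerate
    tab <- build_contingency(eye, ref, bins = bins)
    expected <- kappa_brute(eye, ref)
    got <- cohen_kappa(tab)
    expect_equal(got$kappa, expected, tolerance = 1e-12)
    expect_gte(got$kappa, -1)
    expect_lte(got$kappa, 1)
  }
})

test_that("kappa is equivariant under a shared permutation of the bins", {
  tab <- unclass(mvdh_table2("jsn"))
  k0 <- cohen_kappa(tab)$kappa
  set.seed(1)
  for (rep in 1:5) {
    p <- sample(nrow(tab))
    expect_equal(cohen_kappa(tab[p, p])$kappa, k0)
  }
})

test_that("dichotomization pools every positive bin into yes", {
  d_ero <- dichotomize(mvdh_table2("erosion"))
  expect_equal(unname(unclass(d_ero)), matrix(c(307, 1, 3, 103), 2, byrow = TRUE))
  expect_equal(cohen_kappa(d_ero)$kappa, 0.975, tolerance = 1e-3)
  expect_equal(cohen_kappa(dichotomize(mvdh_table2("jsn")))$kappa, 0.949,
               tolerance = 1e-3)

  diag_tab <- build_contingency(class_bin(c(0, 0, 2)), class_bin(c(0, 0, 2)))
  d <- dichotomize(diag_tab)
  expect_equal(unname(unclass(d)), matrix(c(2, 0, 0, 1), 2, byrow = TRUE))
})

test_that("dichotomized-table kappa equals kappa on binarized pairs", {
  set.seed(9)
  eye <- sample(0:6, 300, replace = TRUE, prob = c(0.6, 0.2, rep(0.04, 5)))
  ref <- pmax(0, eye + sample(c(-1, 0, 0, 0, 1), 300, replace = TRUE))
  tab <- build_contingency(class_bin(eye), class_bin(ref))
  k_table <- cohen_kappa(dichotomize(tab))$kappa
  k_pairs <- kappa_brute(ifelse(eye == 0, "no", "yes"),
                         ifelse(ref == 0, "no", "yes"))
  expect_equal(k_table, k_pairs, tolerance = 1e-12)
})

test_that("table CSV serialization round-trips", {
  tab <- mvdh_table2("erosion")
  f <- withr::local_tempfile(fileext = ".csv")
  write_contingency_csv(tab, f)
  expect_equal(unclass(read_contingency_csv(f)), unclass(tab))
})

test_that("ICC is 1 for identical replicates and errors on degenerate input", {
  expect_equal(icc(cbind(1:10, 1:10))$icc, 1.0)
  expect_error(icc(cbind(1, 1)), ">= 2")
  expect_error(icc(matrix(1:4, 2, 2)[, 1, drop = FALSE]), ">= 2")
})

test_that("ICC recovers known variance components", {
  set.seed(5)
  joint <- rnorm(400, 0, 2)                      # between-joint variance 4
  x <- cbind(joint + rnorm(400, 0, 0.5),         # within variance 0.25
             joint + rnorm(400, 0, 0.5))
  r <- icc(x)
  expect_equal(r$icc, 4 / 4.25, tolerance = 0.015)  # ~3 Monte-Carlo SE
  expect_true(r$ci_low <= r$icc && r$icc <= r$ci_high)

  # mean squares equal the two-way ANOVA decomposition
  df <- data.frame(y = c(x), joint = factor(rep(1:400, 2)),
                   rater = factor(rep(1:2, each = 400)))
  ms <- summary(stats::aov(y ~ joint + rater, data = df))[[1]][["Mean Sq"]]
  expect_equal(c(r$msr, r$msc, r$mse), ms, tolerance = 1e-10)
})

test_that("a constant replicate against a varying one gives near-zero ICC", {
  set.seed(3)
  x <- cbind(rnorm(50), rep(0, 50))
  r <- icc(x)
  expect_lt(abs(r$icc), 0.2)
  # ANOVA oracle via aov on the same data
  df <- data.frame(y = c(x), joint = factor(rep(1:50, 2)),
                   rater = factor(rep(1:2, each = 50)))
  ms <- summary(stats::aov(y ~ joint + rater, data = df))[[1]][["Mean Sq"]]
  oracle <- (ms[1] - ms[3]) /
    (ms[1] + ms[3] + (2 / 50) * (ms[2] - ms[3]))
  expect_equal(r$icc, oracle, tolerance = 1e-10)
})

test_that("pair_scores joins on shared keys and excludes missing joints", {
  eye <- tibble::tibble(patient = c(1, 1, 2), site_id = c("A", "B", "A"),
                        lesion = "erosion", score = c(0L, 2L, 7L))
  ref <- tibble::tibble(patient = c(1, 1, 2, 2),
                        site_id = c("A", "B", "A", "B"),
                        lesion = "erosion", score = c(0L, 1L, 6L, 3L))
  pairs <- pair_scores(eye, ref)
  expect_equal(nrow(pairs), 3L)  # (2, B) missing from eye -> excluded
  expect_equal(as.character(pairs$eye_class), c("0", "2", "≥6"))
  expect_equal(as.character(pairs$ref_class), c("0", "1", "≥6"))
})
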