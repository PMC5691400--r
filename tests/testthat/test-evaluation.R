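test_that("the overlap condition bounds matching at d_max", {
  truth <- matrix(c(0, 0, 0), 1, 3)
  near <- matrix(c(3.9, 0, 0), 1, 3)
  far <- matrix(c(4.1, 0, 0), 1, 3)
  m1 <- match_centers(near, truth)
  expect_equal(nrow(m1$pairs), 1L)
  expect_equal(m1$pairs$distance, 3.9)
  m2 <- match_centers(far, truth)
  expect_equal(nrow(m2$pairs), 0L)
  expect_equal(m2$unmatched_pred, 1L)
  expect_equal(m2$unmatched_truth, 1L)
})

test_that("matching is one-to-one, nearest first", {
  truth <- matrix(c(0, 0, 0), 1, 3)
  pred <- rbind(c(2, 0, 0), c(1, 0, 0))
  m <- match_centers(pred, truth)
  expect_equal(nrow(m$pairs), 1L)
  expect_equal(m$pairs$pred, 2L)
  expect_equal(m$pairs$distance, 1.0)
  expect_equal(m$unmatched_pred, 1L)
})

test_that("scoring splits accepted/rejected into TP/FP and FN/TN", {
  truth <- rbind(c(0, 0, 0), c(20, 0, 0))
  accepted <- rbind(c(1, 0, 0), c(40, 0, 0))
  sc <- score_detection(accepted, NULL, truth)
  expect_equal(sc$TP, 1L)
  expect_equal(sc$FP, 1L)
  expect_equal(sc$TN, 0L)
  expect_equal(sc$FN, 0L)
  # a rejected cluster matching a still-unmatched truth centre is FN
  rejected <- matrix(c(19, 0, 0), 1, 3)
  sc2 <- score_detection(accepted, rejected, truth)
  expect_equal(sc2$FN, 1L)
  expect_equal(sc2$TN, 0L)
  expect_equal(sc2$C_N, 1L)
  # a rejected cluster near an already-matched truth centre is TN
  sc3 <- score_detection(accepted, matrix(c(0.5, 0, 0), 1, 3), truth)
  expect_equal(sc3$FN, 0L)
  expect_equal(sc3$TN, 1L)
})

test_that("distance bins are closed at 1 then left-open, and sum to TP", {
  truth <- rbind(c(0, 0, 0), c(20, 0, 0))
  pred <- rbind(c(1.0, 0, 0), c(20 + 1.001, 0, 0))
  sc <- score_detection(pred, NULL, truth)
  expect_equal(unname(sc$bins), c(1L, 1L, 0L, 0L))
  expect_equal(sum(sc$bins), sc$TP)
  # d = 0 falls in the first bin
  sc0 <- score_detection(matrix(0, 1, 3), NULL, matrix(0, 1, 3))
  expect_equal(unname(sc0$bins), c(1L, 0L, 0L, 0L))
})

test_that("greedy scoring matches the exhaustive assignment oracle", {
  set.seed(31)
  for (it in 1:60) {
    nt <- sample(1:6, 1)
    truth <- matrix(numeric(0), ncol = 3)
    while (nrow(truth) < nt) {
      cand <- matrix(runif(3, 0, 20), ncol = 3)
      if (!nrow(truth) ||
          min(sqrt(rowSums(sweep(truth, 2, cand)^2))) >= 5) {
        truth <- rbind(truth, cand)
      }
    }
    nhit <- sample(0:nt, 1)
    pred <- truth[seq_len(nhit), , drop = FALSE] +
      matrix(runif(nhit * 3, -2, 2), ncol = 3)
    pred <- rbind(pred, matrix(runif(sample(0:3, 1) * 3, 25, 40), ncol = 3))
    sc <- score_detection(pred, NULL, truth)
    expect_equal(sc$TP, oracle_assignment(pred, truth)$n)
    expect_equal(sc$TP + sc$FP, nrow(pred))
    expect_equal(sum(sc$bins), sc$TP)
  }
})

test_that("the five metrics follow their formulas on published-scale counts", {
  m1 <- compute_metrics(confusion_counts(TP = 7697, FP = 1033, TN = 2045,
                                         FN = 393), C = 8150)
  expect_equal(round(m1$S_v, 3), 0.951)
  expect_equal(round(m1$S_c, 3), 0.664)
  expect_equal(round(m1$a, 3), 0.872)
  expect_equal(round(m1$r_d, 3), 0.944)
  expect_equal(m1$C_u, 453)

  m2 <- compute_metrics(confusion_counts(TP = 17191, FP = 2460, TN = 3231,
                                         FN = 440), C = 17850)
  expect_equal(round(m2$S_v, 3), 0.975)
  expect_equal(round(m2$a, 3), 0.876)
  expect_equal(round(m2$r_d, 3), 0.963)
  expect_equal(m2$C_u, 659)
})

test_that("degenerate zero counts give NaN rates, not errors", {
  cc <- confusion_counts(0, 0, 0, 0)
  ws <- capture_warnings(m <- compute_metrics(cc, 0))
  expect_true(all(grepl("undefined", ws)))
  expect_length(ws, 4L)
  expect_true(is.nan(m$S_v))
  expect_true(is.nan(m$S_c))
  expect_true(is.nan(m$a))
  expect_true(is.nan(m$r_d))
  expect_equal(m$C_u, 0)
  expect_error(compute_metrics(confusion_counts(5, 0, 0, 0), C = 3),
               "C < TP")
})

test_that("rates are invariant under scaling all counts", {
  for (k in c(2, 10)) {
    m1 <- compute_metrics(confusion_counts(30, 10, 20, 5), C = 40)
    mk <- compute_metrics(confusion_counts(30 * k, 10 * k, 20 * k, 5 * k),
                          C = 40 * k)
    expect_equal(mk$S_v, m1$S_v)
    expect_equal(mk$S_c, m1$S_c)
    expect_equal(mk$a, m1$a)
  }
})

test_that("bin counts validate against TP in the raw-count constructor", {
  expect_error(confusion_counts(5, 1, 1, 1, bins = c(1, 1, 1, 1)),
               "sum to TP")
  cc <- confusion_counts(4, 1, 1, 1, bins = c(1, 1, 1, 1))
  expect_equal(sum(cc$bins), cc$TP)
})

test_that("centre tables round-trip through TSV", {
  centers <- matrix(rnorm(9), 3, 3)
  path <- tempfile(fileext = ".tsv")
  write_centers_tsv(centers, path, protein_id = "demo")
  tab <- read_centers_tsv(path)
  expect_equal(as.matrix(tab[, c("x", "y", "z")]), centers,
               ignore_attr = TRUE)
  expect_error(read_centers_tsv(textConnection("a\tb\n1\t2")), "columns")
})

test_that("the cumulative detection curve is monotone and ends at r_d", {
  truth <- rbind(c(0, 0, 0), c(20, 0, 0), c(40, 0, 0))
  pred <- rbind(c(0.5, 0, 0), c(22.5, 0, 0))
  sc <- score_detection(pred, NULL, truth)
  curve <- cumulative_detection_curve(sc, C = 3)
  expect_true(all(diff(curve$cumulative_pct) >= 0))
  expect_equal(curve$cumulative_pct[nrow(curve)], 100 * sc$TP / 3)
})
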