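#' Greedy one-to-one matching of predicted and ground-truth centres
#'
#' Implements the overlap condition used for benchmarking: a predicted
#' cavity can only match a ground-truth cavity whose geometric centre lies
#' within `d_max` (default 4.0 Angstrom, tied to the minimum cavity size and
#' the water-molecule diameter). Candidate pairs are sorted by ascending
#' distance (ties broken by predicted then truth index) and accepted
#' greedily while both members are still unmatched, giving a deterministic
#' one-to-one assignment.
#'
#' @param predicted Numeric matrix of predicted centres (3 columns).
#' @param truth Numeric matrix of ground-truth centres (3 columns).
#' @param d_max Maximum matching distance, Angstrom (default 4.0).
#' @return List with `pairs` (data frame `pred`, `truth`, `distance`),
#'   `unmatched_pred` and `unmatched_truth` (integer index vectors).
#' @export
match_centers <- function(predicted, truth, d_max = 4.0) {
  if (!is.finite(d_max) || d_max <= 0) stop("d_max must be > 0")
  predicted <- matrix(as.numeric(predicted), ncol = 3)
  truth <- matrix(as.numeric(truth), ncol = 3)
  np <- nrow(predicted); nt <- nrow(truth)
  empty <- data.frame(pred = integer(0), truth = integer(0),
                      distance = numeric(0))
  if (np == 0L || nt == 0L) {
    return(list(pairs = empty, unmatched_pred = seq_len(np),
                unmatched_truth = seq_len(nt)))
  }
  d2 <- outer(rowSums(predicted^2), rowSums(truth^2), "+") -
    2 * predicted %*% t(truth)
  d <- sqrt(pmax(d2, 0))   # clamp tiny negative radicands
  cand <- which(d <= d_max, arr.ind = TRUE)
  if (nrow(cand)) {
    dist <- d[cand]
    o <- order(dist, cand[, 1], cand[, 2])
    cand <- cand[o, , drop = FALSE]
    dist <- dist[o]
  } else {
    dist <- numeric(0)
  }
  p_used <- logical(np); t_used <- logical(nt)
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    if (!p_used[i] && !t_used[j]) {
      keep[r] <- TRUE
      p_used[i] <- TRUE
      t_used[j] <- TRUE
    }
  }
  list(
    pairs = data.frame(pred = as.integer(cand[keep, 1]),
                       truth = as.integer(cand[keep, 2]),
                       distance = dist[keep]),
    unmatched_pred = which(!p_used),
    unmatched_truth = which(!t_used)
  )
}

#' Confusion counts of a detection against a ground truth
#'
#' Accepted (positive) cavities matched to a ground-truth centre are true
#' positives, unmatched ones false positives. The matching is then repeated
#' between the rejected (negative) clusters and the still-unmatched
#' ground-truth centres: rejected clusters that match are false negatives
#' (real cavities the detector discarded), the remainder true negatives.
#' True-positive match distances are binned into [0,1], ]1,2], ]2,3], ]3,4]
#' Angstrom (first bin closed, later bins left-open).
#'
#' @param accepted Matrix of accepted (positive) cavity centres.
#' @param rejected Matrix of rejected (negative) cluster centres.
#' @param truth Matrix of ground-truth cavity centres.
#' @param d_max Overlap-condition distance, default 4.0 Angstrom.
#' @return An object of class `confusion_counts`: list with `TP`, `FP`,
#'   `TN`, `FN`, `C_P`, `C_N`, `bins` (named integer vector of TP counts per
#'   distance bin) and `tp_distances`.
#' @export
score_detection <- function(accepted, rejected = NULL, truth, d_max = 4.0) {
  accepted <- matrix(as.numeric(accepted), ncol = 3)
  truth <- matrix(as.numeric(truth), ncol = 3)
  rejected <- if (is.null(rejected)) matrix(numeric(0), ncol = 3) else
    matrix(as.numeric(rejected), ncol = 3)

  pos <- match_centers(accepted, truth, d_max)
  TP <- nrow(pos$pairs)
  FP <- nrow(accepted) - TP
  remaining <- truth[pos$unmatched_truth, , drop = FALSE]
  neg <- match_centers(rejected, remaining, d_max)
  FN <- nrow(neg$pairs)
  TN <- nrow(rejected) - FN

  breaks <- c(0, 1, 2, 3, 4)
  dists <- pos$pairs$distance
  bin_of <- pmax(1L, findInterval(dists, breaks, left.open = TRUE))
  bins <- vapply(1:4, function(b) sum(bin_of == b & dists <= d_max), 1L)
  names(bins) <- c("[0,1]", "]1,2]", "]2,3]", "]3,4]")
  structure(list(TP = TP, FP = FP, TN = TN, FN = FN,
                 C_P = TP + FP, C_N = TN + FN,
                 bins = bins, tp_distances = dists),
            class = "confusion_counts")
}

#' Construct confusion counts from raw totals
#'
#' Convenience constructor for reproducing printed benchmark tables, where
#' only the four totals (and optionally the per-bin TP counts) are known.
#'
#' @param TP,FP,TN,FN Non-negative integer counts.
#' @param bins Optional TP counts per distance bin; must sum to `TP`.
#' @return A `confusion_counts`.
#' @export
confusion_counts <- function(TP, FP, TN, FN, bins = NULL) {
  counts <- c(TP, FP, TN, FN)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("confusion counts must be non-negative")
  }
  if (!is.null(bins)) {
    if (length(bins) != 4L) stop("bins must have 4 entries")
    if (sum(bins) != TP) stop("distance-bin counts must sum to TP")
    names(bins) <- c("[0,1]", "]1,2]", "]2,3]", "]3,4]")
  }
  structure(list(TP = TP, FP = FP, TN = TN, FN = FN,
                 C_P = TP + FP, C_N = TN + FN,
                 bins = bins, tp_distances = NULL),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("Confusion counts: TP=%d FP=%d TN=%d FN=%d (C_P=%d, C_N=%d)\n",
              x$TP, x$FP, x$TN, x$FN, x$C_P, x$C_N))
  if (!is.null(x$bins)) {
    cat("  TP by distance bin (A): ",
        paste(sprintf("%s=%d", names(x$bins), x$bins), collapse = "  "), "\n")
  }
  invisible(x)
}

safe_rate <- function(num, den, what) {
  if (den == 0) {
    warning("undefined ", what, ": zero denominator")
    return(NaN)
  }
  num / den
}

#' Benchmark quality metrics from confusion counts
#'
#' Computes sensitivity (true positive rate) `S_v = TP / (TP + FN)`,
#' specificity (true negative rate) `S_c = TN / (TN + FP)`, accuracy
#' `a = (TP + TN) / (TP + FP + FN + TN)`, the rate of detected ground-truth
#' cavities `r_d = TP / C`, and the number of undetected ground-truth
#' cavities `C_u = C - TP`, where `C` is the total number of ground-truth
#' cavities. A zero denominator yields `NaN` with a warning, never an error.
#'
#' @param counts A `confusion_counts`.
#' @param C Total number of ground-truth cavities (`C >= TP`).
#' @return An object of class `cavity_metrics`: list with `S_v`, `S_c`,
#'   `a`, `r_d`, `C_u` plus the input counts and `C`.
#' @examples
#' compute_metrics(confusion_counts(TP = 7697, FP = 1033, TN = 2045,
#'                                  FN = 393), C = 8150)
#' @export
compute_metrics <- function(counts, C) {
  stopifnot(inherits(counts, "confusion_counts"))
  if (!is.finite(C) || C < 0) stop("C must be a non-negative count")
  if (C < counts$TP) stop("inconsistent ground truth: C < TP")
  structure(list(
    S_v = safe_rate(counts$TP, counts$TP + counts$FN, "sensitivity"),
    S_c = safe_rate(counts$TN, counts$TN + counts$FP, "specificity"),
    a = safe_rate(counts$TP + counts$TN,
                  counts$TP + counts$FP + counts$FN + counts$TN, "accuracy"),
    r_d = safe_rate(counts$TP, C, "detection rate"),
    C_u = C - counts$TP,
    counts = counts, C = C
  ), class = "cavity_metrics")
}

#' @export
print.cavity_metrics <- function(x, digits = 3, ...) {
  cat("Cavity benchmark metrics (C =", x$C, "ground-truth cavities):\n")
  cat(sprintf("  sensitivity    S_v = %.*f\n", digits, x$S_v))
  cat(sprintf("  specificity    S_c = %.*f\n", digits, x$S_c))
  cat(sprintf("  accuracy       a   = %.*f\n", digits, x$a))
  cat(sprintf("  detection rate r_d = %.*f\n", digits, x$r_d))
  cat(sprintf("  undetected     C_u = %d\n", x$C_u))
  invisible(x)
}

#' Read cavity centres from a TSV table
#'
#' Expects tab-separated columns `protein_id`, `cavity_id`, `x`, `y`, `z`
#' (header required), the interchange format for both predicted and
#' ground-truth centres.
#'
#' @param path Path to the TSV file.
#' @return Data frame with those five columns.
#' @export
read_centers_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "cavity_id", "x", "y", "z")
  if (!all(need %in% names(tab))) {
    stop("centre table must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(tab) == 0L) {
    for (col in c("x", "y", "z")) tab[[col]] <- numeric(0)
  } else if (!all(vapply(tab[c("x", "y", "z")], is.numeric, TRUE))) {
    stop("centre coordinates must be numeric")
  }
  tab[, need]
}

#' Write cavity centres as a TSV table
#' @param centers Matrix or data frame of centres (3 columns or x/y/z).
#' @param path Output path.
#' @param protein_id Protein label column value.
#' @return Invisibly, `path`.
#' @export
write_centers_tsv <- function(centers, path, protein_id = "protein") {
  if (is.data.frame(centers)) centers <- as.matrix(centers[, c("x", "y", "z")])
  centers <- matrix(as.numeric(centers), ncol = 3)
  tab <- data.frame(protein_id = protein_id,
                    cavity_id = seq_len(nrow(centers)),
                    x = centers[, 1], y = centers[, 2], z = centers[, 3])
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Cumulative detection-rate curve over matching distance
#'
#' Returns, for a grid of distances `d`, the cumulative percentage of
#' ground-truth cavities detected within `d` (100 * TP(d) / C), the data
#' behind cumulative cavity-percentage benchmark curves.
#'
#' @param counts A `confusion_counts` with `tp_distances` (from
#'   [score_detection()]), or a numeric vector of TP match distances.
#' @param C Total ground-truth cavity count.
#' @param d Distance grid, default `seq(0, 4, by = 0.5)`.
#' @return Data frame with columns `d` and `cumulative_pct`.
#' @export
cumulative_detection_curve <- function(counts, C, d = seq(0, 4, by = 0.5)) {
  dists <- if (inherits(counts, "confusion_counts")) counts$tp_distances else counts
  if (is.null(dists)) stop("no per-match distances available")
  data.frame(d = d,
             cumulative_pct = vapply(d, function(t) 100 * sum(dists <= t) / C,
                                     1.0))
}
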