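#' Confusion counts
#'
#' @param tp,fn,fp non-negative integers.
#' @return object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp = 0, fn = 0, fp = 0) {
  assert_that(tp >= 0 && fn >= 0 && fp >= 0,
              "counts must be non-negative")
  structure(list(tp = as.integer(tp), fn = as.integer(fn),
                 fp = as.integer(fp)), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP %d, FN %d, FP %d (PPV %s, TPR %s)\n",
              x$tp, x$fn, x$fp,
              format(round_half_away(ppv(x))), format(round_half_away(tpr(x)))))
  invisible(x)
}

# distance between two closed intervals: 0 when they overlap, else the gap
interval_distance <- function(a_on, a_off, b_on, b_off) {
  pmax(0, pmax(a_on, b_on) - pmin(a_off, b_off))
}

#' Match detections to annotated events
#'
#' A detection and an annotation are at distance 0 when their intervals
#' overlap, otherwise at the gap between their nearest endpoints. Pairs are
#' matched greedily one-to-one in increasing distance (ties: earlier
#' annotation, then earlier detection); a matched pair within `tol_s` is a
#' true positive. Unmatched detections are false positives, unmatched
#' annotations false negatives. The default tolerance of 0.5 s absorbs the
#' sync inaccuracy between the two measurement systems and the therapist's
#' reaction time.
#'
#' @param detections a `detection_result` or a data frame with `onset_s`,
#'   `offset_s`.
#' @param annotations an [assist_annotations()] data frame (events at any
#'   body location count).
#' @param tol_s matching tolerance in seconds, >= 0.
#' @return `list(counts = confusion_counts, pairs = data.frame(annotation,
#'   detection, distance_s))`.
#' @export
match_events <- function(detections, annotations, tol_s = 0.5) {
  assert_that(tol_s >= 0, "tol_s must be >= 0")
  if (inherits(detections, "detection_result")) detections <- detections$intervals
  nd <- nrow(detections); na <- nrow(annotations)
  pairs <- data.frame(annotation = integer(), detection = integer(),
                      distance_s = numeric())
  if (nd > 0 && na > 0) {
    cand <- expand.grid(annotation = seq_len(na), detection = seq_len(nd))
    cand$distance_s <- interval_distance(
      annotations$start_s[cand$annotation], annotations$stop_s[cand$annotation],
      detections$onset_s[cand$detection], detections$offset_s[cand$detection])
    cand <- cand[cand$distance_s <= tol_s + 1e-12, , drop = FALSE]
    cand <- cand[order(cand$distance_s,
                       annotations$start_s[cand$annotation],
                       detections$onset_s[cand$detection]), , drop = FALSE]
    used_a <- logical(na); used_d <- logical(nd)
    for (k in seq_len(nrow(cand))) {
      a <- cand$annotation[k]; d <- cand$detection[k]
      if (!used_a[a] && !used_d[d]) {
        used_a[a] <- TRUE; used_d[d] <- TRUE
        pairs <- rbind(pairs, cand[k, , drop = FALSE])
      }
    }
  }
  tp <- nrow(pairs)
  list(counts = confusion_counts(tp = tp, fn = na - tp, fp = nd - tp),
       pairs = pairs)
}

#' Positive predictive value and true positive rate
#'
#' `PPV = TP / (TP + FP) * 100`, `TPR = TP / (TP + FN) * 100`, both on the
#' 0-100 scale. With a zero denominator the value is undefined and `NA` is
#' returned (such grid points are excluded from aggregation). The reporting
#' layer rounds to the nearest integer with [round_half_away()].
#'
#' @param counts a [confusion_counts()] (or list with `tp`, `fn`, `fp`).
#' @return percentage, or `NA_real_` when undefined.
#' @export
ppv <- function(counts) {
  d <- counts$tp + counts$fp
  if (d == 0) return(NA_real_)
  counts$tp / d * 100
}

#' @rdname ppv
#' @export
tpr <- function(counts) {
  d <- counts$tp + counts$fn
  if (d == 0) return(NA_real_)
  counts$tp / d * 100
}

#' Pool confusion counts
#'
#' Element-wise sum over measurement trials or patients; group-level scores
#' are computed from pooled counts (pool-then-score), not by averaging
#' per-trial percentages.
#'
#' @param counts_list list of [confusion_counts()].
#' @return a [confusion_counts()].
#' @export
pool_counts <- function(counts_list) {
  assert_that(length(counts_list) >= 1L, "empty list of counts")
  tp <- sum(vapply(counts_list, function(c) c$tp, 0L))
  fn <- sum(vapply(counts_list, function(c) c$fn, 0L))
  fp <- sum(vapply(counts_list, function(c) c$fp, 0L))
  confusion_counts(tp, fn, fp)
}

# shared detector front end used by detect() and grid_search(): the trimmed
# free-acceleration resultant of one session
prepare_detection_signal <- function(accel, trim = "auto", rectify = FALSE) {
  if (inherits(accel, "session_recording")) accel <- accel$accel
  free <- free_acceleration(resultant_acceleration(accel$x, accel$y, accel$z))
  trimmed <- if (identical(trim, "none"))
    list(track = free, kept = c(free$t0, track_end(free)))
  else if (identical(trim, "auto")) trim_stationary(free)
  else trim_stationary(free, manual = trim)
  sig <- trimmed$track
  if (rectify) sig <- track_with(sig, abs(sig$samples))
  sig
}

# lexicographic ranking of grid rows: max objective = min(ppv, tpr), then
# max ppv + tpr, then smaller delta, then smaller alpha. Undefined -> -Inf.
rank_grid <- function(table) {
  obj <- pmin(table$ppv, table$tpr)
  obj[is.na(obj)] <- -Inf
  ssum <- table$ppv + table$tpr
  ssum[is.na(ssum)] <- -Inf
  best_obj <- max(obj)
  plateau <- which(obj == best_obj & ssum == max(ssum[obj == best_obj]))
  ord <- plateau[order(table$delta[plateau], table$alpha[plateau])]
  list(objective = obj, plateau = plateau, best = ord[1L])
}

#' Grid search over (alpha, delta)
#'
#' Runs the detector on every session at every grid combination, matches
#' against the annotations, pools counts over sessions and scores PPV/TPR.
#' The objective is `min(PPV, TPR)` ("the highest score of PPV and TPR at
#' the same time"), ties broken by `PPV + TPR`, then smaller `delta`, then
#' smaller `alpha`. All maximizers (the plateau) are reported. Defaults
#' reproduce the published grid: alpha 0.5..3.0 step 0.1, delta 0.5..3.0 s
#' step 0.01.
#'
#' @param sessions list of `list(recording = , annotations = )`.
#' @param alpha_grid,delta_grid numeric grids.
#' @param tol_s matching tolerance in seconds.
#' @param trim,quartiles_on,rectify,convention forwarded to [detect()].
#' @return object of class `grid_search_result`: list with `table` (one row
#'   per grid point: alpha, delta, tp, fn, fp, ppv, tpr, objective),
#'   `plateau` (subset of `table`), and `best` (single row).
#' @export
grid_search <- function(sessions,
                        alpha_grid = seq(0.5, 3.0, by = 0.1),
                        delta_grid = seq(0.5, 3.0, by = 0.01),
                        tol_s = 0.5, trim = "auto",
                        quartiles_on = c("raw", "smoothed"),
                        rectify = FALSE, convention = "linear") {
  quartiles_on <- match.arg(quartiles_on)
  assert_that(length(sessions) >= 1L, "need at least one session")
  sigs <- lapply(sessions, function(s)
    prepare_detection_signal(s$recording, trim = trim, rectify = rectify))
  anns <- lapply(sessions, function(s) s$annotations)
  raw_q <- lapply(sigs, function(sig) signal_quartiles(sig$samples, convention))
  nA <- length(alpha_grid); nD <- length(delta_grid)
  tp <- fn <- fp <- matrix(0L, nA, nD)
  for (j in seq_len(nD)) {
    smoothed <- lapply(sigs, moving_average, delta_s = delta_grid[j])
    sm_q <- if (quartiles_on == "smoothed")
      lapply(smoothed, function(s) signal_quartiles(s$samples, convention))
    else raw_q
    for (i in seq_len(nA)) {
      counts <- vector("list", length(sigs))
      for (s in seq_along(sigs)) {
        thr <- sm_q[[s]]["q3"] + alpha_grid[i] * sm_q[[s]]["iqr"]
        runs <- runs_to_intervals(smoothed[[s]]$samples > thr)
        intervals <- if (nrow(runs)) indices_to_times(runs, smoothed[[s]])
                     else data.frame(onset_s = numeric(), offset_s = numeric())
        counts[[s]] <- match_events(intervals, anns[[s]], tol_s)$counts
      }
      pooled <- pool_counts(counts)
      tp[i, j] <- pooled$tp; fn[i, j] <- pooled$fn; fp[i, j] <- pooled$fp
    }
  }
  table <- data.frame(alpha = rep(alpha_grid, times = nD),
                      delta = rep(delta_grid, each = nA),
                      tp = as.vector(tp), fn = as.vector(fn),
                      fp = as.vector(fp))
  table$ppv <- ifelse(table$tp + table$fp > 0,
                      table$tp / (table$tp + table$fp) * 100, NA_real_)
  table$tpr <- ifelse(table$tp + table$fn > 0,
                      table$tp / (table$tp + table$fn) * 100, NA_real_)
  r <- rank_grid(table)
  table$objective <- r$objective
  structure(list(table = table,
                 plateau = table[r$plateau, , drop = FALSE],
                 best = table[r$best, , drop = FALSE],
                 alpha_grid = alpha_grid, delta_grid = delta_grid,
                 tol_s = tol_s),
            class = "grid_search_result")
}

#' @export
print.grid_search_result <- function(x, ...) {
  b <- x$best
  cat(sprintf(
    "<grid_search_result> %d grid points; best alpha %.2f, delta %.2f s (PPV %.1f, TPR %.1f); plateau size %d\n",
    nrow(x$table), b$alpha, b$delta, b$ppv, b$tpr, nrow(x$plateau)))
  invisible(x)
}

#' Development/validation split evaluation
#'
#' Tunes `(alpha, delta)` by [grid_search()] on the development patients,
#' fixes `alpha` to a stated constant within the plateau (default 1.0),
#' takes the plateau's `delta`, then detects and scores each validation
#' patient and the pooled group.
#'
#' @param sessions named list (names = patient ids) of
#'   `list(recording = , annotations = )`.
#' @param dev_ids,val_ids disjoint character/integer vectors of patient ids.
#' @param fixed_alpha constant alpha applied to the validation set; if
#'   `NULL` the tuned best alpha is used.
#' @param alpha_grid,delta_grid,tol_s,... forwarded to [grid_search()] /
#'   [detect()].
#' @return list with `chosen` (`alpha`, `delta`), `dev` (the
#'   `grid_search_result`), and `table` (per-patient rows plus a pooled
#'   `"group"` row with integer-rounded PPV/TPR).
#' @export
split_validation <- function(sessions, dev_ids, val_ids, fixed_alpha = 1.0,
                             alpha_grid = seq(0.5, 3.0, by = 0.1),
                             delta_grid = seq(0.5, 3.0, by = 0.01),
                             tol_s = 0.5, ...) {
  ids <- names(sessions)
  assert_that(!is.null(ids), "sessions must be a named list (patient ids)")
  dev_ids <- as.character(dev_ids); val_ids <- as.character(val_ids)
  assert_that(length(intersect(dev_ids, val_ids)) == 0L,
              "development and validation ids overlap")
  assert_that(all(c(dev_ids, val_ids) %in% ids), "unknown patient id(s)")
  dev <- grid_search(sessions[dev_ids], alpha_grid, delta_grid, tol_s, ...)
  alpha <- if (is.null(fixed_alpha)) dev$best$alpha else fixed_alpha
  delta <- dev$best$delta
  params <- detector_params(alpha = alpha, delta_s = delta)
  per <- lapply(val_ids, function(id) {
    s <- sessions[[id]]
    m <- match_events(detect(s$recording, params, ...), s$annotations, tol_s)
    m$counts
  })
  names(per) <- val_ids
  pooled <- pool_counts(per)
  row <- function(id, c) data.frame(
    patient_id = id, tp = c$tp, fn = c$fn, fp = c$fp,
    ppv_pct = round_half_away(ppv(c)), tpr_pct = round_half_away(tpr(c)),
    stringsAsFactors = FALSE)
  table <- do.call(rbind, c(Map(row, val_ids, per),
                            list(row("group", pooled))))
  rownames(table) <- NULL
  list(chosen = list(alpha = alpha, delta_s = delta), dev = dev,
       table = table)
}

#' Demographic summary table
#'
#' Mean, sample standard deviation (n - 1 denominator), median and IQR for
#' every numeric column of a patient table, as printed in cohort
#' descriptions ("mean +/- SD" and "median (IQR)").
#'
#' @param patients data frame, one row per patient.
#' @return data frame with one row per numeric column: `mean`, `sd`,
#'   `median`, `iqr`, `n`. With a single patient `sd` is `NA`.
#' @export
summarize_demographics <- function(patients) {
  num <- names(patients)[vapply(patients, is.numeric, TRUE)]
  assert_that(length(num) >= 1L, "no numeric columns")
  rows <- lapply(num, function(cl) {
    x <- patients[[cl]]
    x <- x[!is.na(x)]
    data.frame(column = cl, mean = mean(x),
               sd = if (length(x) >= 2L) stats::sd(x) else NA_real_,
               median = stats::median(x),
               iqr = unname(diff(stats::quantile(x, c(0.25, 0.75), type = 7))),
               n = length(x), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
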