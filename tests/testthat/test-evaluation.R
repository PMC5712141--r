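test_that("event matching honours the temporal tolerance", {
  det <- function(...) data.frame(onset_s = c(...)[c(TRUE, FALSE)],
                                  offset_s = c(...)[c(FALSE, TRUE)])
  ann1 <- assist_annotations(10.6, 11.5, "iliac_crest", "both")
  m <- match_events(det(10.0, 10.4), ann1, tol_s = 0.5)  # gap 0.2 -> TP
  expect_equal(unlist(m$counts[c("tp", "fn", "fp")]), c(tp = 1, fn = 0, fp = 0))

  ann2 <- assist_annotations(2.0, 2.5, "iliac_crest", "both")
  m2 <- match_events(det(1.0, 1.2), ann2, tol_s = 0.5)   # gap 0.8 -> FP + FN
  expect_equal(unlist(m2$counts[c("tp", "fn", "fp")]), c(tp = 0, fn = 1, fp = 1))

  m3 <- match_events(det(), ann2, tol_s = 0.5)
  expect_equal(unlist(m3$counts[c("tp", "fn", "fp")]), c(tp = 0, fn = 1, fp = 0))

  # overlap counts as distance zero
  m4 <- match_events(det(2.2, 2.4), ann2, tol_s = 0)
  expect_equal(m4$counts$tp, 1)
})

test_that("matching invariants hold for random interval sets", {
  set.seed(20)
  for (k in 1:25) {
    na <- sample(0:6, 1); nd <- sample(0:6, 1)
    ann <- if (na) {
      st <- sort(runif(na, 0, 50))
      assist_annotations(st, st + runif(na, 0.2, 1.5),
                         rep("iliac_crest", na))
    } else assist_annotations()
    on <- sort(runif(nd, 0, 50))
    dets <- data.frame(onset_s = on, offset_s = on + runif(nd, 0.1, 2))
    tols <- c(0, 0.25, 0.5, 1, 2)
    tps <- sapply(tols, function(tl) {
      c <- match_events(dets, ann, tl)$counts
      expect_equal(c$tp + c$fn, na)
      expect_equal(c$tp + c$fp, nd)
      c$tp
    })
    expect_true(all(diff(tps) >= 0))  # TP monotone in tolerance
  }
})

test_that("PPV and TPR formulas, rounding and undefined sentinel", {
  expect_equal(ppv(confusion_counts(13, 3, 2)), 13 / 15 * 100)
  expect_equal(round_half_away(ppv(confusion_counts(13, 3, 2))), 87)
  expect_equal(tpr(confusion_counts(13, 3, 2)), 81.25)
  expect_equal(round_half_away(tpr(confusion_counts(13, 3, 2))), 81)
  expect_true(is.na(ppv(confusion_counts(0, 5, 0))))
  expect_true(is.na(tpr(confusion_counts(0, 0, 5))))
  # defined values live in [0, 100]; 100/100 iff no errors with TP > 0
  c_perfect <- confusion_counts(4, 0, 0)
  expect_equal(c(ppv(c_perfect), tpr(c_perfect)), c(100, 100))
})

test_that("pooling counts is an element-wise sum", {
  pooled <- pool_counts(list(confusion_counts(1, 0, 0),
                             confusion_counts(2, 1, 1)))
  expect_equal(unlist(pooled[c("tp", "fn", "fp")]), c(tp = 3, fn = 1, fp = 1))

  val <- reference_table("confusion_validation")
  g <- pool_counts(Map(confusion_counts, val$tp, val$fn, val$fp))
  expect_equal(unlist(g[c("tp", "fn", "fp")]), c(tp = 13, fn = 3, fp = 2))

  with_empty <- pool_counts(list(confusion_counts(2, 1, 1),
                                 confusion_counts(0, 0, 0)))
  expect_equal(unlist(with_empty[c("tp", "fn", "fp")]), c(tp = 2, fn = 1, fp = 1))
})

test_that("grid ranking: min(PPV,TPR) objective with documented tie-breaks", {
  tab <- data.frame(alpha = c(1, 1, 2, 2), delta = c(1, 2, 1, 2),
                    tp = 1, fn = 1, fp = 1,
                    ppv = c(80, 80, 90, 80), tpr = c(80, 90, 80, 80))
  r <- gaitassist:::rank_grid(tab)
  # all share objective 80; rows 2 and 3 share the larger sum 170
  expect_setequal(r$plateau, c(2, 3))
  expect_equal(r$best, 3)  # smaller delta wins inside the plateau

  tab$ppv[1] <- NA  # undefined scores rank below everything
  r2 <- gaitassist:::rank_grid(tab)
  expect_false(1 %in% r2$plateau)
})

test_that("grid search agrees with fresh detect + match calls", {
  s <- simulate_session(separable_config(seed = 31))
  sessions <- list(list(recording = s$recording, annotations = s$annotations))
  ag <- seq(0.5, 3, by = 0.5); dg <- seq(0.5, 3, by = 0.5)
  gs <- grid_search(sessions, ag, dg, trim = "none")
  set.seed(32)
  pick <- sample(nrow(gs$table), 10)
  for (i in pick) {
    row <- gs$table[i, ]
    d <- detect(s$recording, detector_params(row$alpha, row$delta),
                trim = "none")
    c <- match_events(d, s$annotations, 0.5)$counts
    expect_equal(c(row$tp, row$fn, row$fp), c(c$tp, c$fn, c$fp))
  }
})

test_that("a uniformly perfect grid yields a full-grid plateau", {
  s <- simulate_session(separable_config(seed = 33))
  sessions <- list(list(recording = s$recording, annotations = s$annotations))
  gs <- grid_search(sessions, alpha_grid = seq(0.5, 1.5, 0.5),
                    delta_grid = c(0.5, 1.0), trim = "none")
  if (all(gs$table$ppv == 100 & gs$table$tpr == 100)) {
    expect_equal(nrow(gs$plateau), nrow(gs$table))
  } else {
    expect_gte(nrow(gs$plateau), 1)  # plateau never empty
  }
})

test_that("development/validation split: degenerate split reproduces dev scores", {
  cohort <- simulate_cohort(4, separable_config(seed = 0, duration_s = 60),
                            seed = 7)
  sessions <- lapply(cohort, function(s)
    list(recording = s$recording, annotations = s$annotations))
  ag <- c(0.8, 1.0, 1.2); dg <- seq(0.5, 2.5, by = 0.5)
  # degenerate: validate on copies of the development patients at the tuned
  # settings; validation must reproduce the development-set scores
  sv2 <- split_validation(c(sessions, stats::setNames(sessions, paste0("v", 1:4))),
                          dev_ids = names(sessions),
                          val_ids = paste0("v", 1:4), fixed_alpha = NULL,
                          alpha_grid = ag, delta_grid = dg)
  grp <- sv2$table[sv2$table$patient_id == "group", ]
  expect_equal(c(grp$tp, grp$fn, grp$fp),
               c(sv2$dev$best$tp, sv2$dev$best$fn, sv2$dev$best$fp))

  expect_error(split_validation(sessions, names(sessions)[1:2],
                                names(sessions)[2:3]), "overlap")

  # 4/4 split on an 8-patient cohort: schema and ranges
  cohort8 <- simulate_cohort(8, separable_config(seed = 0, duration_s = 60),
                             seed = 7)
  sessions8 <- lapply(cohort8, function(s)
    list(recording = s$recording, annotations = s$annotations))
  sv8 <- split_validation(sessions8, dev_ids = as.character(1:4),
                          val_ids = as.character(5:8), fixed_alpha = 1.0,
                          alpha_grid = ag, delta_grid = dg)
  expect_equal(sv8$table$patient_id, c(as.character(5:8), "group"))
  ok <- !is.na(sv8$table$ppv_pct)
  expect_true(all(sv8$table$ppv_pct[ok] >= 0 & sv8$table$ppv_pct[ok] <= 100))
  expect_true(all(sv8$table$tpr_pct >= 0 & sv8$table$tpr_pct <= 100))
})

test_that("demographic summaries reproduce the reference cohort description", {
  demo <- reference_table("demographics")
  s <- summarize_demographics(demo[, c("age_yrs", "weight_kg")])
  age <- s[s$column == "age_yrs", ]
  wt <- s[s$column == "weight_kg", ]
  expect_equal(round_half_away(age$mean), 58)
  expect_equal(wt$mean, 84.0)
  expect_equal(round_half_away(wt$sd, 1), 7.2)
  expect_equal(age$median, 58)
  expect_equal(age$iqr, 5.5)

  same <- summarize_demographics(data.frame(v = rep(4, 5)))
  expect_equal(c(same$sd, same$iqr), c(0, 0))
  single <- summarize_demographics(data.frame(v = 3))
  expect_true(is.na(single$sd))
})

test_that("grid search recovers the episode duration scale (stochastic)", {
  # boost >= 3x baseline SD, fixed 1.75 s episodes; success = plateau
  # contains a delta within +/-0.5 s of the episode duration
  hits <- 0
  n_seeds <- 20
  for (k in seq_len(n_seeds)) {
    cfg <- sim_config(duration_s = 120, n_events = 5, min_separation_s = 8,
                      event_duration_median_s = 1.75,
                      event_duration_sdlog = 0,
                      event_boost_mps2 = 1.1,  # ~3x the baseline free-accel SD
                      seed = 100 + k)
    s <- simulate_session(cfg)
    gs <- grid_search(list(list(recording = s$recording,
                                annotations = s$annotations)),
                      alpha_grid = c(0.8, 1.0, 1.2),
                      delta_grid = seq(0.5, 3, by = 0.25))
    if (any(abs(gs$plateau$delta - 1.75) <= 0.5)) hits <- hits + 1
  }
  expect_gte(hits / n_seeds, 0.8)
})
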