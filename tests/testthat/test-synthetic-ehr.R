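test_that("identical config and seed reproduce identical cohorts", {
  cfg <- synthConfig(n_patients = 10, case_fraction = 0.5, seed = 1)
  a <- generateCohort(cfg)
  b <- generateCohort(cfg)
  expect_identical(a$events, b$events)
  expect_identical(a$patients, b$patients)
  expect_identical(a$truth, b$truth)
})

test_that("configuration errors are caught", {
  expect_error(synthConfig(n_patients = 10, case_fraction = 0.01),
               "case_fraction")
  bad_motif <- list(list(tokens = c("G400", "G401"), hazard = rep(0.1, 36)))
  expect_error(synthConfig(n_patients = 10, vocab_size = 100,
                           motifs = bad_motif,
                           subgroups = defaultSubgroups(vocab_size = 100)),
               "vocab_size too small")
  expect_error(synthConfig(n_patients = 10,
                           control_strata_weights = c(respiratory = 0.5,
                                                      other_cancer = 0.5,
                                                      other = 0.5)),
               "sum to 1")
})

test_that("event dates parse, stay within the window, never pass the index", {
  coh <- smallCohort()
  expect_s3_class(coh$events$event_date, "Date")
  expect_false(anyNA(coh$events$event_date))
  for (i in seq_len(nrow(coh$truth))) {
    pid <- coh$truth$patient_id[i]
    ev <- coh$events[coh$events$patient_id == pid, ]
    idx <- coh$truth$index_date[i]
    expect_true(all(ev$event_date <= idx))
    expect_true(all(ev$event_date >= monthsBefore(idx, 36L)))
    # histories span (almost) the full 36-month lookback
    expect_gte(as.numeric(idx - min(ev$event_date)), 30 * 28)
  }
  # birth precedes all events
  born <- coh$patients$birth_date[match(coh$events$patient_id,
                                        coh$patients$patient_id)]
  expect_true(all(born < coh$events$event_date))
})

test_that("emitted code map covers all emitted raw codes; labels consistent", {
  coh <- smallCohort()
  expect_true(all(coh$events$raw_code %in% coh$code_map@map$raw_code))
  # cases carry a lung diagnostic code on their index date; controls none
  cur <- curateEvents(coh$events, coh$code_map)
  has_lung <- tapply(cur$group_id %in% coh$code_lists$lung, cur$patient_id,
                     any)
  expect_equal(as.logical(has_lung[coh$truth$patient_id]),
               coh$truth$label == 1L)
})

test_that("case pathways contain their motif tokens in motif order", {
  cfg <- synthConfig(n_patients = 60, case_fraction = 0.5, seed = 33)
  coh <- generateCohort(cfg)
  cur <- curateEvents(coh$events, coh$code_map)
  cases <- coh$truth[coh$truth$label == 1L, ]
  ok <- 0L
  for (i in seq_len(nrow(cases))) {
    ev <- cur[cur$patient_id == cases$patient_id[i], ]
    ev <- ev[order(ev$event_date), ]
    sg <- as.integer(sub("subgroup", "", cases$subgroup[i]))
    motif <- cfg$motifs[[min(sg, length(cfg$motifs))]]$tokens
    pos <- match(motif, ev$group_id)  # first occurrence of each motif token
    if (!anyNA(pos) && all(diff(pos) > 0)) ok <- ok + 1L
  }
  # every case contains the full motif; first occurrences in motif order
  # for the single-instance majority (interleaved instances can reorder
  # first occurrences, so demand a clear majority)
  expect_gte(ok / nrow(cases), 0.5)
  # all cases contain every motif token
  for (i in seq_len(nrow(cases))) {
    ev <- cur[cur$patient_id == cases$patient_id[i], ]
    sg <- as.integer(sub("subgroup", "", cases$subgroup[i]))
    motif <- cfg$motifs[[min(sg, length(cfg$motifs))]]$tokens
    expect_true(all(motif %in% ev$group_id))
  }
})

test_that("motif hazard rises toward the index date in case pathways", {
  cfg <- synthConfig(n_patients = 200, case_fraction = 0.5, seed = 5)
  coh <- generateCohort(cfg)
  cur <- curateEvents(coh$events, coh$code_map)
  motif_toks <- unlist(lapply(cfg$motifs, `[[`, "tokens"))
  cases <- coh$truth[coh$truth$label == 1L, ]
  cur_cases <- cur[cur$patient_id %in% cases$patient_id &
                     cur$group_id %in% motif_toks, ]
  idx <- cases$index_date[match(cur_cases$patient_id, cases$patient_id)]
  days_before <- as.numeric(idx - cur_cases$event_date)
  # half-life ~4 months: far more motif mass in the last 6 months than in
  # months 7-12
  n_recent <- sum(days_before <= 182)
  n_older <- sum(days_before > 182 & days_before <= 365)
  expect_gt(n_recent, 2 * n_older)
})

test_that("mean curated pathway length tracks the configured 170", {
  cfg <- synthConfig(n_patients = 1000, case_fraction = 0.444, seed = 77)
  coh <- generateCohort(cfg)
  cur <- curateEvents(coh$events, coh$code_map)
  pw <- buildPathways(cur, coh$code_lists$lung, coh$code_lists$other_cancer,
                      coh$code_lists$respiratory,
                      diagnostic_codes = coh$code_lists$diagnostic,
                      lookback_months = 36, trim_months = 0)
  m <- mean(lengths(pathwayTokens(pw)))
  expect_gt(m, 165); expect_lt(m, 175)
})

test_that("order-only mode matches case/control token marginals", {
  cfg <- synthConfig(n_patients = 2000, case_fraction = 0.5,
                     signal_mode = "order_only", seed = 13)
  coh <- generateCohort(cfg)
  cur <- curateEvents(coh$events, coh$code_map)
  # window tokens only (exclude the index-date diagnostic anchors)
  pw <- buildPathways(cur, coh$code_lists$lung, coh$code_lists$other_cancer,
                      coh$code_lists$respiratory,
                      diagnostic_codes = coh$code_lists$diagnostic,
                      trim_months = 0)
  pw <- stripLabelCodes(pw, coh$code_lists$lung, coh$code_lists$other_cancer)
  lab <- pathwayLabels(pw)
  tc <- table(unlist(pathwayTokens(pw)[lab == 1]))
  tn <- table(unlist(pathwayTokens(pw)[lab == 0]))
  toks <- union(names(tc), names(tn))
  counts <- cbind(case = as.numeric(tc[toks]), ctrl = as.numeric(tn[toks]))
  counts[is.na(counts)] <- 0
  # chi-square homogeneity over the token-count table
  p <- suppressWarnings(stats::chisq.test(counts)$p.value)
  expect_gt(p, 0.01)
  # per-token two-proportion z: no token beyond chance given 450 tests
  n1 <- sum(counts[, 1]); n0 <- sum(counts[, 2])
  p1 <- counts[, 1] / n1; p0 <- counts[, 2] / n0
  pp <- (counts[, 1] + counts[, 2]) / (n1 + n0)
  z <- (p1 - p0) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n0))
  expect_lt(max(abs(z), na.rm = TRUE), qnorm(1 - 0.005 / length(toks)))
})
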