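test_that("index selection: first lung code wins, lung takes precedence", {
  ev <- tinyEvents(dates = c("2018-01-01", "2019-05-02", "2020-01-01"),
                   groups = c("Gcough", "Glung", "Glung"))
  sel <- selectIndexDate(ev, "Glung", "Gbreast")
  expect_equal(sel$index_date, as.Date("2019-05-02"))
  expect_equal(sel$stratum, "lung")

  ev <- tinyEvents(dates = c("2019-03-03", "2018-01-01"),
                   groups = c("Gbreast", "Glung"))
  sel <- selectIndexDate(ev, "Glung", "Gbreast")
  expect_equal(sel$index_date, as.Date("2018-01-01"))
  expect_equal(sel$stratum, "lung")
})

test_that("controls use the most recent diagnostic code as endpoint", {
  ev <- tinyEvents(dates = c("2017-02-01", "2019-09-09", "2019-12-31"),
                   groups = c("Gcopd", "Gcopd", "Gcough"))
  sel <- selectIndexDate(ev, "Glung", "Gbreast", respiratory_codes = "Gcopd")
  expect_equal(sel$index_date, as.Date("2019-09-09"))
  expect_equal(sel$stratum, "respiratory")

  # no diagnostic code at all -> NULL (excluded upstream)
  expect_null(selectIndexDate(tinyEvents(groups = c("Ga", "Gb", "Gc")),
                              "Glung", "Gbreast"))
})

test_that("window is [index - lookback, index - trim): boundary behaviour", {
  idx <- as.Date("2020-06-15")
  ev <- tinyEvents(dates = c("2020-05-15", "2020-05-14", "2020-06-14"),
                   groups = c("Ga", "Gb", "Gc"))
  toks <- derivePathway(ev, idx, lookback_months = 36, trim_months = 1)
  expect_false("Ga" %in% toks)  # exactly at upper bound, excluded
  expect_true("Gb" %in% toks)
  toks0 <- derivePathway(ev, idx, trim_months = 0)
  expect_setequal(toks0, c("Ga", "Gb", "Gc"))  # all before index included
  expect_error(derivePathway(ev, idx, lookback_months = 12, trim_months = 12),
               "smaller")
})

test_that("window retention matches a brute-force per-event oracle", {
  set.seed(42)
  idx <- as.Date("2020-06-15")
  n <- 100
  ev <- data.frame(patient_id = "P1",
                   event_date = idx - sample.int(1400, n, replace = TRUE),
                   group_id = sprintf("G%03d", sample(9:60, n, replace = TRUE)))
  for (trim in c(0L, 1L, 3L)) {
    toks <- derivePathway(ev, idx, 36L, trim)
    lo <- monthsBefore(idx, 36L); hi <- monthsBefore(idx, trim)
    keep <- vapply(seq_len(n), function(i)
      ev$event_date[i] >= lo && ev$event_date[i] < hi, logical(1))
    expect_equal(sort(toks), sort(ev$group_id[keep]))
  }
})

test_that("windowing is translation invariant and trimming monotone", {
  set.seed(7)
  idx <- as.Date("2019-10-01")
  ev <- data.frame(patient_id = "P1",
                   event_date = idx - sample.int(1200, 80, replace = TRUE),
                   group_id = sprintf("G%03d", sample(9:50, 80, replace = TRUE)))
  t1 <- derivePathway(ev, idx, 36L, 1L)
  ev2 <- ev; ev2$event_date <- ev2$event_date + 97L
  expect_equal(derivePathway(ev2, idx + 97L, 36L, 1L), t1)
  # monotone: larger trim keeps a subset
  t3 <- derivePathway(ev, idx, 36L, 3L)
  expect_true(all(table(t3) <= table(t1)[names(table(t3))]))
})

test_that("same-day ties order by group id then input row; duplicates kept", {
  idx <- as.Date("2020-01-01")
  ev <- data.frame(patient_id = "P1",
                   event_date = as.Date(rep("2019-05-05", 3)),
                   group_id = c("Gb", "Ga", "Gb"))
  expect_equal(derivePathway(ev, idx), c("Ga", "Gb", "Gb"))
})

test_that("minimum-code filter boundary: 9 removed, 10 retained", {
  mk <- function(n, pid) list(tokens = rep("G010", n), pid = pid)
  pws <- methods::new("PathwaySet",
                      tokens = list(rep("G010", 9), rep("G010", 10),
                                    rep("G010", 25)),
                      info = data.frame(patient_id = c("A", "B", "C"),
                                        index_date = as.Date("2020-01-01"),
                                        label = c(1L, 0L, 1L),
                                        stratum = c("lung", "other", "lung")))
  kept <- filterMinCodes(pws, 10L)
  expect_equal(pathwayInfo(kept)$patient_id, c("B", "C"))
  all_long <- filterMinCodes(pws[2:3], 10L)
  expect_equal(length(all_long), 2L)
})

test_that("label-code stripping removes diagnostic tokens, preserves order", {
  expect_equal(stripLabelCodes(c("Gcough", "Glung", "Gdysp"), "Glung", "Gbr"),
               c("Gcough", "Gdysp"))
  expect_equal(stripLabelCodes(c("Ga", "Gb"), "Glung", "Gbr"), c("Ga", "Gb"))
  # set-membership recount oracle on a random pathway
  set.seed(1)
  toks <- sprintf("G%03d", sample(1:30, 200, replace = TRUE))
  lung <- "G001"; oc <- c("G002", "G003")
  out <- stripLabelCodes(toks, lung, oc)
  expect_equal(out, toks[vapply(toks, function(t)
    !(t %in% c(lung, oc)), logical(1))])
})

test_that("tokenizer prepends [CLS], truncates keeping recent tokens", {
  v <- buildVocabulary(c("A", "B"))
  expect_equal(tokenizePathway(c("A", "B"), v, 10L), c(2L, 4L, 5L))
  expect_equal(tokenizePathway(character(0), v, 10L), 2L)
  expect_equal(tokenizePathway(c("A", "zzz"), v, 10L), c(2L, 4L, 1L)) # [UNK]
  long <- rep(c("A", "B"), 300)
  ids <- tokenizePathway(long, v, 512L)
  expect_length(ids, 512L)
  expect_equal(ids[1], 2L)
  expect_equal(ids[-1], tokenToId(v, long[(600 - 510):600]))
})

test_that("vocabulary ids are contiguous with fixed specials", {
  v <- buildVocabulary(c("Gb", "Ga"))
  expect_equal(vocabSize(v), 6L)
  expect_equal(tokenToId(v, c("Ga", "Gb")), c(4L, 5L))
  expect_equal(idToToken(v, 0:5),
               c("[PAD]", "[UNK]", "[CLS]", "[MASK]", "Ga", "Gb"))
})

test_that("calendar-month stepping clamps to month end", {
  expect_equal(monthsBefore(as.Date("2020-03-31"), 1), as.Date("2020-02-29"))
  expect_equal(monthsBefore(as.Date("2019-03-31"), 1), as.Date("2019-02-28"))
  expect_equal(monthsBefore(as.Date("2020-06-15"), 36), as.Date("2017-06-15"))
  expect_equal(monthsBefore(as.Date("2020-01-10"), 0), as.Date("2020-01-10"))
})
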