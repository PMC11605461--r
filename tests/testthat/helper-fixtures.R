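# Small fixtures shared across test files. Everything is generated in
# code; nothing is read from disk except the shipped demo map.

demoMapPath <- function() {
  system.file("extdata", "demo_codemap.csv", package = "codepaths")
}

# a tiny curated event table for one patient
tinyEvents <- function(pid = "P1",
                       dates = c("2019-01-05", "2019-03-01", "2019-06-30"),
                       groups = c("G010", "G011", "G012")) {
  data.frame(patient_id = pid, event_date = as.Date(dates),
             group_id = groups, stringsAsFactors = FALSE)
}

# small synthetic cohort shared by several test files (cached per session)
smallCohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generateCohort(synthConfig(n_patients = 120,
                                           case_fraction = 0.4, seed = 404))
    cache
  }
})

# a desk-preset model over a small vocabulary
tinyModel <- function(V = 40L, seed = 7L) {
  initSeqModel(seqModelConfig(preset = "desk", vocab_size = V), seed = seed)
}

randomIdSeq <- function(n, V = 40L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  c(2L, sample(4:(V - 1L), n, replace = TRUE))
}
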