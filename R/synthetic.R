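#' Default planted progression motifs
#'
#' Each motif is an ordered token subsequence (a stylised
#' symptom-test-referral progression) plus a per-month emission hazard over
#' the 36 months before the index date (month 1 = the month adjacent to
#' the index). The hazard sums to the expected number of motif instances
#' per case and by default rises steeply toward the index date, emulating
#' the acceleration of presentations and investigations in the run-up to a
#' cancer diagnosis.
#'
#' @param n number of motifs (one per latent subgroup).
#' @param rate expected motif instances per case pathway.
#' @param concentration decay constant (months) of the hazard away from
#'   the index; smaller concentrates the motif closer to diagnosis.
#' @return list of `list(tokens, hazard)`.
#' @export
defaultMotifs <- function(n = 3L, rate = 2, concentration = 4) {
  shape <- exp(-(seq_len(36L) - 1L) / concentration)
  hazard <- rate * shape / sum(shape)
  lapply(seq_len(n), function(i) {
    base <- 8L + (i - 1L) * 12L
    list(tokens = sprintf("G%03d", base + 1:4), hazard = hazard)
  })
}

#' Default latent patient subgroups
#'
#' Each subgroup has a background token-frequency profile: all
#' non-diagnostic groups get weight 1, the subgroup's 8 anchor groups get
#' `anchor_weight`. Subgroup `i` is tied to motif `i`.
#'
#' @param n number of subgroups.
#' @param vocab_size curated group count.
#' @param anchor_weight relative frequency boost of anchor groups.
#' @return list of `list(label, weights)` with `weights` named by group.
#' @export
defaultSubgroups <- function(n = 3L, vocab_size = 450L, anchor_weight = 20) {
  bg <- sprintf("G%03d", 9:vocab_size)  # G001-G008 reserved for diagnoses
  lapply(seq_len(n), function(i) {
    w <- stats::setNames(rep(1, length(bg)), bg)
    anchors <- sprintf("G%03d", 8L + (i - 1L) * 12L + 5:12)
    w[intersect(anchors, bg)] <- anchor_weight
    list(label = paste0("subgroup", i), weights = w)
  })
}

#' Configure the synthetic coded-EHR generator
#'
#' The generator emulates the structure of the study cohort: ~3-year
#' event histories, a curated vocabulary of 450 groups reached through a
#' many-to-one raw-code map, a mean of ~170 curated codes per pathway,
#' case pathways carrying ordered progression motifs whose hazard rises
#' toward the index date, controls over-sampled from other-cancer and
#' chronic-respiratory strata, and latent patient subgroups with distinct
#' background code profiles.
#'
#' Two signal regimes are supported. `"marginal_shift"` (default): only
#' cases receive motif instances, so case/control code frequencies differ.
#' `"order_only"`: every control is assigned the exact window token
#' multiset of a (cycled) case of the same subgroup, re-dated uniformly
#' over its own window — case and control marginal token frequencies are
#' then identical by construction and the two arms differ only in token
#' ordering/timing, isolating what a sequence model can learn that a
#' bag-of-codes model cannot.
#'
#' @param n_patients cohort size.
#' @param case_fraction fraction of lung-cancer cases (study value 0.444).
#' @param control_strata_weights proportions over
#'   `c(respiratory, other_cancer, other)` among controls; defaults to the
#'   study composition 2932/2030/2279.
#' @param vocab_size curated group count (default 450).
#' @param mean_pathway_length target mean curated codes per 36-month
#'   pathway (default 170).
#' @param motifs list of `list(tokens, hazard)`; see [defaultMotifs()].
#' @param subgroups list of `list(label, weights)`; see
#'   [defaultSubgroups()].
#' @param signal_mode `"marginal_shift"` or `"order_only"`.
#' @param admin_rate administrative events per curated event (exercises
#'   curation; dropped downstream).
#' @param resp_monitor_rate expected chronic-respiratory monitoring codes
#'   for respiratory-stratum controls (marginal mode only).
#' @param seed integer seed; identical config + seed reproduces identical
#'   output.
#' @return a validated config list of class `synth_config`.
#' @export
synthConfig <- function(n_patients,
                        case_fraction = 0.444,
                        control_strata_weights = c(respiratory = 2932,
                                                   other_cancer = 2030,
                                                   other = 2279) / 7241,
                        vocab_size = 450L,
                        mean_pathway_length = 170,
                        motifs = defaultMotifs(),
                        subgroups = defaultSubgroups(vocab_size = vocab_size),
                        signal_mode = c("marginal_shift", "order_only"),
                        admin_rate = 0.05,
                        resp_monitor_rate = 6,
                        seed = 1L) {
  signal_mode <- match.arg(signal_mode)
  if (n_patients < 1L) stop("n_patients must be positive")
  if (case_fraction <= 0 || case_fraction >= 1)
    stop("case_fraction must be in (0,1)")
  if (n_patients * case_fraction < 1)
    stop("configuration error: n_patients * case_fraction < 1")
  w <- control_strata_weights
  if (any(w < 0) || abs(sum(w) - 1) > 1e-8)
    stop("control_strata_weights must be non-negative and sum to 1")
  if (!all(c("respiratory", "other_cancer", "other") %in% names(w)))
    stop("control_strata_weights must name respiratory, other_cancer, other")
  motif_tokens <- unique(unlist(lapply(motifs, `[[`, "tokens")))
  max_ref <- max(as.integer(sub("^G", "", motif_tokens)))
  if (vocab_size < max_ref)
    stop("configuration error: vocab_size too small for motif tokens")
  for (m in motifs) {
    if (any(m$hazard < 0)) stop("motif hazard must be non-negative")
    if (length(m$hazard) != 36L) stop("motif hazard must have 36 months")
  }
  if (length(subgroups) < length(motifs))
    stop("need at least one subgroup per motif")
  structure(list(
    n_patients = as.integer(n_patients), case_fraction = case_fraction,
    control_strata_weights = w[c("respiratory", "other_cancer", "other")],
    vocab_size = as.integer(vocab_size),
    mean_pathway_length = mean_pathway_length,
    motifs = motifs, subgroups = subgroups, signal_mode = signal_mode,
    admin_rate = admin_rate, resp_monitor_rate = resp_monitor_rate,
    seed = as.integer(seed)), class = "synth_config")
}

# uniform date in [lo, hi]
runifDate <- function(n, lo, hi) {
  lo + floor(stats::runif(n) * (as.integer(hi - lo) + 1L))
}

# draw event dates for one motif instance: months from the hazard profile,
# uniform day within month, sorted ascending so tokens land in motif order
motifInstanceDates <- function(hazard, index_date) {
  m <- sample.int(36L, 1L, prob = hazard)  # one month per instance anchor
  # tokens of an instance fall in consecutive days around the anchor month
  lo <- monthsBefore(index_date, m)
  hi <- monthsBefore(index_date, m - 1L) - 1L
  list(lo = lo, hi = hi)
}

#' Generate a synthetic coded-EHR cohort
#'
#' Emits raw event-level data in the package's tabular formats: a patient
#' table, an event table of raw codes (background events from each
#' patient's subgroup profile via a homogeneous process over the 36-month
#' window; motif instances from the motif's monthly hazard; administrative
#' noise; one diagnostic code at the index date), the raw-to-group
#' [CodeMap-class], the diagnosis code lists, and the ground truth.
#'
#' Case pathways contain each motif instance's tokens in motif order. No
#' event is dated after the patient's index date.
#'
#' @param config a [synthConfig()].
#' @return list with `patients`, `events`, `code_map`, `code_lists`
#'   (group-level `lung`, `other_cancer`, `respiratory`, `diagnostic`),
#'   and `truth` (`patient_id`, `label`, `stratum`, `subgroup`,
#'   `index_date`).
#' @export
generateCohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_patients
  n_case <- round(n * config$case_fraction)
  n_ctrl <- n - n_case
  strata <- c(rep("lung", n_case),
              sampleVec(names(config$control_strata_weights), n_ctrl,
                        replace = TRUE,
                        prob = config$control_strata_weights))
  sg_idx <- sample.int(length(config$subgroups), n, replace = TRUE)
  ids <- sprintf("P%06d", seq_len(n))
  code_map <- demoCodeMap(n_groups = config$vocab_size)
  lists <- demoCodeLists()
  lists$diagnostic <- c(lists$lung, lists$other_cancer, lists$respiratory,
                        "G008")
  # index dates: cancer strata over 2019-2020; non-cancer controls get
  # the most-recent-diagnostic-code analogue, uniform over the last
  # observation year (2020)
  idx_date <- rep(as.Date(NA), n)
  cancerish <- strata %in% c("lung", "other_cancer")
  idx_date[cancerish] <- runifDate(sum(cancerish), as.Date("2019-01-01"),
                                   as.Date("2020-12-31"))
  idx_date[!cancerish] <- runifDate(sum(!cancerish), as.Date("2020-01-01"),
                                    as.Date("2020-12-31"))
  age <- round(ifelse(strata == "lung", stats::rnorm(n, 71, 9),
                      stats::rnorm(n, 58, 14)))
  age <- pmin(pmax(age, 25), 99)
  patients <- data.frame(
    patient_id = ids,
    birth_date = as.Date(sprintf(
      "%04d-%02d-%02d", as.integer(format(idx_date, "%Y")) - age,
      sample.int(12L, n, replace = TRUE), sample.int(28L, n, replace = TRUE))),
    sex = sampleVec(c("F", "M"), n, replace = TRUE),
    ethnicity = sampleVec(c("white_british", "white_other", "asian",
                            "black", "other"), n, replace = TRUE,
                          prob = c(0.35, 0.2, 0.2, 0.1, 0.15)),
    stringsAsFactors = FALSE)

  rawFor <- function(groups) {
    # map each group occurrence to one of its raw codes uniformly
    paste0(groups, "r", sample.int(3L, length(groups), replace = TRUE))
  }
  ev_pid <- vector("list", n); ev_date <- vector("list", n)
  ev_grp <- vector("list", n)
  case_bank <- list()   # per-subgroup token multisets of cases (order_only)

  exp_motif <- vapply(config$motifs, function(m)
    sum(m$hazard) * length(m$tokens), numeric(1))

  for (i in seq_len(n)) {
    st <- strata[i]; sg <- sg_idx[i]; idx <- idx_date[i]
    lo <- monthsBefore(idx, 36L)
    is_case <- st == "lung"
    motif <- config$motifs[[min(sg, length(config$motifs))]]
    grp <- character(0); dts <- as.Date(character(0))
    sgk <- min(sg, length(config$motifs))
    if (config$signal_mode == "order_only" && !is_case &&
        length(case_bank) >= sgk && !is.null(case_bank[[sgk]]) &&
        length(case_bank[[sgk]])) {
      # copy a case's window multiset, re-dated uniformly: identical
      # marginals, scrambled order
      bank <- case_bank[[sgk]]
      toks <- bank[[1L + (i %% length(bank))]]
      grp <- toks
      dts <- runifDate(length(toks), lo, idx - 1L)
    } else {
      extra <- if (is_case) exp_motif[min(sg, length(exp_motif))] else 0
      extra <- extra + if (st == "respiratory" &&
                           config$signal_mode == "marginal_shift")
        config$resp_monitor_rate else 0
      n_bg <- stats::rpois(1L, max(5, config$mean_pathway_length - extra))
      sgw <- config$subgroups[[sg]]$weights
      bg <- sampleVec(names(sgw), n_bg, replace = TRUE, prob = sgw)
      grp <- bg
      dts <- runifDate(n_bg, lo, idx - 1L)
      if (st == "respiratory" && config$signal_mode == "marginal_shift") {
        k <- stats::rpois(1L, config$resp_monitor_rate)
        if (k) {
          grp <- c(grp, sampleVec(lists$respiratory, k, replace = TRUE))
          dts <- c(dts, runifDate(k, lo, idx - 1L))
        }
      }
      if (is_case) {
        k_inst <- max(1L, stats::rpois(1L, sum(motif$hazard)))
        for (r in seq_len(k_inst)) {
          win <- motifInstanceDates(motif$hazard, idx)
          d <- sort(runifDate(length(motif$tokens), win$lo,
                              min(win$hi, idx - 1L)))
          grp <- c(grp, motif$tokens)
          dts <- c(dts, d)
        }
      }
    }
    if (config$signal_mode == "order_only" && is_case) {
      if (length(case_bank) < sgk || is.null(case_bank[[sgk]]))
        case_bank[[sgk]] <- list()
      case_bank[[sgk]][[length(case_bank[[sgk]]) + 1L]] <- grp
    }
    # administrative noise (curation drops it)
    k_adm <- stats::rpois(1L, config$admin_rate * length(grp))
    if (k_adm) {
      grp <- c(grp, sprintf("ADM%02d", sample.int(8L, k_adm, replace = TRUE)))
      dts <- c(dts, runifDate(k_adm, lo, idx - 1L))
    }
    # the index-date diagnostic code
    dx <- switch(st,
                 lung = lists$lung,
                 other_cancer = sampleVec(lists$other_cancer, 1L),
                 respiratory = sampleVec(lists$respiratory, 1L),
                 other = "G008")
    grp <- c(grp, dx)
    dts <- c(dts, idx)
    ord <- order(dts)
    ev_pid[[i]] <- rep(ids[i], length(grp))
    ev_date[[i]] <- dts[ord]
    ev_grp[[i]] <- grp[ord]
  }
  events <- data.frame(patient_id = unlist(ev_pid),
                       event_date = as.Date(unlist(ev_date),
                                            origin = "1970-01-01"),
                       raw_code = rawFor(unlist(ev_grp)),
                       stringsAsFactors = FALSE)
  truth <- data.frame(
    patient_id = ids,
    label = as.integer(strata == "lung"),
    stratum = strata,
    subgroup = vapply(config$subgroups[sg_idx], `[[`, "", "label"),
    index_date = idx_date, stringsAsFactors = FALSE)
  list(patients = patients, events = events, code_map = code_map,
       code_lists = lists, truth = truth)
}
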