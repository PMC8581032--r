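#' Classify trial responses
#'
#' Attributes each keypress to the trial whose window `[onset, next onset)`
#' contains it (first press in a window wins; presses before the first onset
#' are left unattributed with a message) and assigns each stimulus one of
#' the four Go/NoGo response types: `go_pos` (pressed on a Go trial),
#' `go_neg` (missed a Go), `nogo_pos` (correctly withheld on a NoGo),
#' `nogo_neg` (pressed on a NoGo). Response time is the press time minus the
#' stimulus onset, reported as a positive latency.
#'
#' @param session A [session_log()].
#' @return Tibble with one row per stimulus: the stimulus columns plus
#'   `response_type` and `rt` (ms; `NA` when no press was attributed).
#' @export
classify_responses <- function(session) {
  st <- session$stimuli
  if (nrow(st) == 0) {
    return(dplyr::mutate(st, response_type = character(), rt = numeric()))
  }
  presses <- sort(session$responses$t)
  next_onset <- c(st$onset[-1], Inf)
  early <- sum(presses < st$onset[1])
  if (early > 0) {
    inform(sprintf("%d press(es) before the first stimulus onset left unattributed",
                   early))
  }
  rt <- vapply(seq_len(nrow(st)), function(i) {
    in_win <- presses[presses >= st$onset[i] & presses < next_onset[i]]
    if (length(in_win) == 0) NA_real_ else in_win[1] - st$onset[i]
  }, numeric(1))
  st %>%
    mutate(
      rt = rt,
      response_type = dplyr::case_when(
        kind == "go" & !is.na(rt) ~ "go_pos",
        kind == "go" & is.na(rt) ~ "go_neg",
        kind == "nogo" & is.na(rt) ~ "nogo_pos",
        TRUE ~ "nogo_neg"
      )
    ) %>%
    select(dplyr::all_of(c("trial_id", "onset", "offset", "location", "cx",
                           "cy", "kind", "response_type", "rt")))
}

#' Response-type percentages and response-time statistics
#'
#' Percentages are per stimulus kind (Go-positive and Go-negative sum to 100,
#' as do NoGo-positive and NoGo-negative). The response-time mean and
#' variability pool pressed Go and NoGo trials; variability is the sample
#' standard deviation (0 by convention for a single press, missing when no
#' trial was pressed).
#'
#' @param trials Output of [classify_responses()].
#' @return One-row tibble: `go_pos_pct`, `go_neg_pct`, `nogo_pos_pct`,
#'   `nogo_neg_pct`, `rt_mean`, `rt_var`.
#' @export
response_stats <- function(trials) {
  n_go <- sum(trials$kind == "go")
  n_nogo <- sum(trials$kind == "nogo")
  pct <- function(type, denom) {
    if (denom == 0) return(NA_real_)
    100 * sum(trials$response_type == type) / denom
  }
  rts <- trials$rt[!is.na(trials$rt)]
  if (length(rts) == 0) {
    inform("no pressed trials: RT statistics are missing")
    rt_mean <- NA_real_
    rt_var <- NA_real_
  } else {
    rt_mean <- mean(rts)
    rt_var <- if (length(rts) == 1) 0 else sd(rts)
  }
  tibble::tibble(
    go_pos_pct = pct("go_pos", n_go), go_neg_pct = pct("go_neg", n_go),
    nogo_pos_pct = pct("nogo_pos", n_nogo),
    nogo_neg_pct = pct("nogo_neg", n_nogo),
    rt_mean = rt_mean, rt_var = rt_var
  )
}
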