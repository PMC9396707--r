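#' Configuration for behavioral parameter derivation
#'
#' @param short_C_threshold_min Pathway bouts shorter than this count as
#'   "short probes" (default 3 min).
#' @param sustained_E2_threshold_min Phloem-ingestion bouts longer than this
#'   count as sustained (default 10 min).
#' @param rpd_mode `"annotated"` (repetitive potential drops arrive as RPD
#'   segments from the annotator, the default) or `"derived"` (materialize
#'   them from runs of PD bouts with [detect_rpd()]).
#' @param rpd_gap_s Maximum pathway time between consecutive PDs of one
#'   repetitive run (derived mode).
#' @param rpd_min_pds Minimum number of PDs forming a repetitive run.
#' @param merge_c_across_pd Treat a pathway bout interrupted by potential
#'   drops as a single bout whose duration sums the pathway pieces (standard
#'   EPG convention; affects the short-probe count). Set `FALSE` to count
#'   every pathway segment as its own bout.
#' @return A list of class `epg_param_config`.
#' @export
param_config <- function(short_C_threshold_min = 3,
                         sustained_E2_threshold_min = 10,
                         rpd_mode = c("annotated", "derived"),
                         rpd_gap_s = 15, rpd_min_pds = 2,
                         merge_c_across_pd = TRUE) {
  rpd_mode <- match.arg(rpd_mode)
  stopifnot(short_C_threshold_min > 0, sustained_E2_threshold_min > 0,
            rpd_gap_s > 0, rpd_min_pds >= 2)
  structure(list(short_C_threshold_min = short_C_threshold_min,
                 sustained_E2_threshold_min = sustained_E2_threshold_min,
                 rpd_mode = rpd_mode, rpd_gap_s = rpd_gap_s,
                 rpd_min_pds = rpd_min_pds,
                 merge_c_across_pd = merge_c_across_pd),
            class = "epg_param_config")
}

## Pathway bouts: maximal runs of segments labeled C (optionally allowing PD
## and RPD interruptions); returns one duration (minutes) per bout.
c_bout_durations <- function(seg, merge_across_pd) {
  dur_min <- (seg$offset_ms - seg$onset_ms) / 60000
  if (!merge_across_pd) return(dur_min[seg$label == "C"])
  in_run <- seg$label %in% c("C", "PD", "RPD")
  run_id <- cumsum(c(TRUE, diff(in_run) != 0))
  out <- numeric()
  for (r in unique(run_id[in_run])) {
    idx <- which(run_id == r & seg$label == "C")
    if (length(idx)) out <- c(out, sum(dur_min[idx]))
  }
  out
}

bout_stats <- function(durations, total_min) {
  n <- length(durations)
  list(n = n,
       total = if (n) sum(durations) else 0,
       mean = if (n) mean(durations) else NA_real_,
       max = if (n) max(durations) else 0)
}

#' Derive the behavioral parameter suite from one recording
#'
#' Computes, per aphid, the standard probing-behavior variables from an 8-h
#' EPG recording: nonprobing time, pathway bout counts and durations, the
#' potential-drop rate, repetitive-PD, phloem-salivation and phloem-ingestion
#' statistics, penetration-difficulty and xylem-ingestion activity, plus the
#' per-activity time shares. Handling rules for edge cases: waveforms that
#' never occur get total duration 0, a *missing* mean, and a latency equal to
#' the full recording length; a bout still running when the recording ends is
#' counted with its truncated duration.
#'
#' @param rec An `epg_recording`.
#' @param cfg A [param_config()]. In `"derived"` RPD mode, [detect_rpd()] is
#'   applied before any variable is computed.
#' @return One-row data frame (durations in minutes, counts as integers,
#'   `share_*` columns as fractions of the recording).
#' @export
compute_parameters <- function(rec, cfg = param_config()) {
  problems <- validate_recording(rec)
  if (length(problems))
    stop("invalid recording '", rec$recording_id, "': ",
         paste(problems, collapse = "; "))
  if (cfg$rpd_mode == "derived") rec <- detect_rpd(rec, cfg)
  seg <- rec$segments
  dur_min <- (seg$offset_ms - seg$onset_ms) / 60000
  total_min <- rec$total_ms / 60000
  tot <- function(lab) sum(dur_min[seg$label == lab])

  c_bouts <- c_bout_durations(seg, cfg$merge_c_across_pd)
  e1 <- bout_stats(dur_min[seg$label == "E1"], total_min)
  e2_d <- dur_min[seg$label == "E2"]
  e2 <- bout_stats(e2_d, total_min)
  rpd <- bout_stats(dur_min[seg$label == "RPD"], total_min)
  n_pd <- sum(seg$label == "PD")
  total_c <- tot("C")
  first_e1 <- which(seg$label == "E1")[1L]
  total_e1 <- e1$total; total_e2 <- e2$total
  shares <- activity_time_shares(rec)

  data.frame(
    recording_id = rec$recording_id,
    genotype_id = rec$genotype_id,
    total_np_min = tot("NP"),
    n_c = length(c_bouts),
    n_c_short = sum(c_bouts < cfg$short_C_threshold_min),
    mean_c_min = if (length(c_bouts)) mean(c_bouts) else NA_real_,
    total_c_min = total_c,
    n_pd = n_pd,
    total_pd_min = tot("PD"),
    pd_rate_per_min_c = if (total_c > 0) n_pd / total_c else NA_real_,
    n_rpd = rpd$n, mean_rpd_min = rpd$mean, total_rpd_min = rpd$total,
    n_e1 = e1$n, mean_e1_min = e1$mean, total_e1_min = total_e1,
    max_e1_min = e1$max,
    latency_first_e1_min = if (is.na(first_e1)) total_min
                           else seg$onset_ms[first_e1] / 60000,
    n_e1_not_followed_by_e2 = count_e1_not_followed_by_e2(rec),
    pct_e1_of_phloem_phase = if (total_e1 + total_e2 > 0)
      100 * total_e1 / (total_e1 + total_e2) else NA_real_,
    n_e2 = e2$n, mean_e2_min = e2$mean, total_e2_min = total_e2,
    total_e2_sustained_min = sum(e2_d[e2_d > cfg$sustained_E2_threshold_min]),
    max_e2_min = e2$max,
    n_f = sum(seg$label == "F"), total_f_min = tot("F"),
    n_g = sum(seg$label == "G"), total_g_min = tot("G"),
    share_np = shares[["NP"]], share_c = shares[["C"]],
    share_pd = shares[["PD"]], share_rpd = shares[["RPD"]],
    share_e1 = shares[["E1"]], share_e2 = shares[["E2"]],
    share_f = shares[["F"]], share_g = shares[["G"]],
    stringsAsFactors = FALSE)
}

#' Behavioral parameter table for a set of recordings
#'
#' @param recordings List of `epg_recording` objects.
#' @param cfg A [param_config()].
#' @return Data frame with one row per recording (see [compute_parameters()]).
#' @export
compute_parameter_table <- function(recordings, cfg = param_config()) {
  stopifnot(length(recordings) >= 1L)
  do.call(rbind, lapply(recordings, compute_parameters, cfg = cfg))
}

#' Count phloem salivation bouts not followed by phloem ingestion
#'
#' An E1 bout counts when the next segment, ignoring potential drops, is not
#' E2; an E1 bout that ends the recording also counts.
#'
#' @param rec An `epg_recording`.
#' @return Integer count.
#' @export
count_e1_not_followed_by_e2 <- function(rec) {
  lab <- rec$segments$label
  scan <- lab[lab != "PD"]
  idx <- which(scan == "E1")
  if (!length(idx)) return(0L)
  nxt <- scan[pmin(idx + 1L, length(scan))]
  sum(idx == length(scan) | nxt != "E2")
}

#' Materialize repetitive potential drops from PD runs
#'
#' Relabels every maximal run of at least `rpd_min_pds` potential-drop bouts,
#' in which consecutive PDs are separated only by pathway time of at most
#' `rpd_gap_s` seconds, as a single RPD bout spanning the first PD's onset to
#' the last PD's offset (intervening short pathway pieces are absorbed).
#'
#' @param rec An `epg_recording` containing PD segments.
#' @param cfg A [param_config()] with `rpd_mode = "derived"`.
#' @return An `epg_recording` with RPD bouts materialized.
#' @export
detect_rpd <- function(rec, cfg = param_config(rpd_mode = "derived")) {
  if (cfg$rpd_mode != "derived")
    stop("RPD detector disabled: rpd_mode is 'annotated'")
  seg <- rec$segments
  n <- nrow(seg)
  gap_ms <- cfg$rpd_gap_s * 1000
  keep <- rep(TRUE, n)
  out <- seg
  i <- 1L
  while (i <= n) {
    if (seg$label[i] == "PD") {
      j <- i
      while (j + 2L <= n && seg$label[j + 1L] == "C" &&
             seg$offset_ms[j + 1L] - seg$onset_ms[j + 1L] <= gap_ms &&
             seg$label[j + 2L] == "PD")
        j <- j + 2L
      n_pds <- (j - i) / 2L + 1L
      if (n_pds >= cfg$rpd_min_pds) {
        out$label[i] <- "RPD"
        out$offset_ms[i] <- seg$offset_ms[j]
        if (j > i) keep[(i + 1L):j] <- FALSE
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  rec$segments <- out[keep, , drop = FALSE]
  rownames(rec$segments) <- NULL
  merge_adjacent(rec)
}

#' Fraction of recording time spent on each activity
#'
#' @param rec An `epg_recording`.
#' @return Named numeric vector over all waveform labels; sums to 1.
#' @export
activity_time_shares <- function(rec) {
  seg <- rec$segments
  dur <- seg$offset_ms - seg$onset_ms
  by_lab <- tapply(dur, factor(seg$label, levels = epg_labels), sum,
                   default = 0)
  as.vector(by_lab / rec$total_ms) -> shares
  stats::setNames(shares, epg_labels)
}

round_half_up <- function(x) floor(x + 0.5)

#' Cohort summary of behavioral parameters for one genotype
#'
#' Mean, standard error and n per variable (over non-missing values; the SE
#' of a single observation is reported as 0, matching the `x ± 0` convention
#' of printed cohort tables), plus the integer percentage of aphids that
#' performed phloem ingestion (E2), penetration difficulties (F) and xylem
#' ingestion (G) at least once.
#'
#' @param params Parameter table ([compute_parameter_table()]) for a single
#'   genotype.
#' @return A list of class `epg_cohort_summary` with elements `genotype_id`,
#'   `n`, `summary` (variable/mean/se/n data frame) and `pct_performing`.
#' @export
aggregate_cohort <- function(params) {
  if (!nrow(params)) stop("empty parameter table")
  if (length(unique(params$genotype_id)) != 1L)
    stop("mixed genotypes in cohort: ",
         paste(unique(params$genotype_id), collapse = ", "))
  num <- params[vapply(params, is.numeric, TRUE)]
  smry <- do.call(rbind, lapply(names(num), function(v) {
    x <- num[[v]][!is.na(num[[v]])]
    data.frame(variable = v, mean = if (length(x)) mean(x) else NA_real_,
               se = if (length(x) > 1L) stats::sd(x) / sqrt(length(x))
                    else if (length(x) == 1L) 0 else NA_real_,
               n = length(x), stringsAsFactors = FALSE)
  }))
  pct <- c(E2 = round_half_up(100 * sum(params$n_e2 >= 1) / nrow(params)),
           F  = round_half_up(100 * sum(params$n_f >= 1) / nrow(params)),
           G  = round_half_up(100 * sum(params$n_g >= 1) / nrow(params)))
  structure(list(genotype_id = params$genotype_id[1L], n = nrow(params),
                 summary = smry, pct_performing = pct),
            class = "epg_cohort_summary")
}

#' @export
print.epg_cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort summary, genotype %s (n = %d)\n", x$genotype_id, x$n))
  s <- x$summary
  cat(paste(sprintf("  %-28s %8.2f +/- %.2f (n=%d)", s$variable, s$mean,
                    s$se, s$n), collapse = "\n"), "\n")
  cat(sprintf("  %% performing E2/F/G: %d%% / %d%% / %d%%\n",
              x$pct_performing["E2"], x$pct_performing["F"],
              x$pct_performing["G"]))
  invisible(x)
}

#' The 16 duration-scale EPG variables used for class discrimination
#'
#' Eight total durations (nonprobing, pathway, phloem salivation, phloem
#' ingestion, sustained phloem ingestion, penetration difficulties, xylem
#' ingestion, repetitive potential drops), four mean durations (pathway,
#' salivation, phloem ingestion, RPD), the potential-drop rate, the maximum
#' salivation and phloem-ingestion bout durations, and the latency to first
#' salivation. Counts and proportions are excluded by design.
#'
#' @return Character vector of 16 column names of the parameter table.
#' @export
epg_discriminant_variables <- function() {
  c("total_np_min", "total_c_min", "total_e1_min", "total_e2_min",
    "total_e2_sustained_min", "total_f_min", "total_g_min", "total_rpd_min",
    "mean_c_min", "mean_e1_min", "mean_e2_min", "mean_rpd_min",
    "pd_rate_per_min_c", "max_e1_min", "max_e2_min", "latency_first_e1_min")
}
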