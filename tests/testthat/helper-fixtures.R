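# Fixture builders and an independent brute-force parameter oracle.
# The oracle re-derives every behavioral variable by a separate rescan of the
# segment table (seconds-based data frame, explicit loops), deliberately
# sharing no code with compute_parameters().

random_recording <- function(max_segments = 30, labels = epg_labels,
                             id = "rand", genotype = "G1") {
  n <- sample.int(max_segments, 1L)
  lab <- character(n)
  lab[1L] <- sample(labels, 1L)
  for (i in seq_len(n)[-1L])
    lab[i] <- sample(setdiff(labels, lab[i - 1L]), 1L)
  dur <- round(stats::runif(n, 0.5, 2000), 1L)
  off <- cumsum(dur)
  epg_recording(id, genotype, lab, onset_s = c(0, off[-n]), offset_s = off,
                total_duration_s = off[n])
}

rec_from_labels <- function(labels, durations_s, id = "fx", genotype = "G1") {
  off <- cumsum(durations_s)
  epg_recording(id, genotype, labels, onset_s = c(0, off[-length(off)]),
                offset_s = off, total_duration_s = off[length(off)])
}

oracle_params <- function(rec, cfg = param_config()) {
  df <- as.data.frame(rec)
  lab <- df$label
  dmin <- df$duration_s / 60
  n <- nrow(df)
  total_min <- (df$offset_s[n]) / 60
  tot <- function(L) {
    s <- 0
    for (i in seq_len(n)) if (lab[i] == L) s <- s + dmin[i]
    s
  }

  # pathway bouts via an explicit open/close state machine
  c_id <- rep(NA_integer_, n)
  cur <- 0L; open <- FALSE
  for (i in seq_len(n)) {
    if (lab[i] == "C") {
      if (!open || !cfg$merge_c_across_pd) { cur <- cur + 1L; open <- TRUE }
      c_id[i] <- cur
    } else if (!(lab[i] %in% c("PD", "RPD"))) open <- FALSE
  }
  c_bouts <- if (cur) vapply(seq_len(cur), function(b)
    sum(dmin[which(!is.na(c_id) & c_id == b)]), 0) else numeric()

  stats_for <- function(L) {
    d <- dmin[lab == L]
    list(n = length(d), total = sum(d),
         mean = if (length(d)) sum(d) / length(d) else NA_real_,
         max = if (length(d)) max(d) else 0)
  }
  e1 <- stats_for("E1"); e2 <- stats_for("E2"); rpd <- stats_for("RPD")
  e2d <- dmin[lab == "E2"]

  not_followed <- 0L
  for (i in which(lab == "E1")) {
    j <- i + 1L
    while (j <= n && lab[j] == "PD") j <- j + 1L
    if (j > n || lab[j] != "E2") not_followed <- not_followed + 1L
  }

  first_e1 <- Inf
  for (i in seq_len(n)) if (lab[i] == "E1") { first_e1 <- df$onset_s[i] / 60; break }

  total_c <- tot("C")
  shares <- vapply(epg_labels, function(L) tot(L) / total_min, 0)

  data.frame(
    recording_id = rec$recording_id, genotype_id = rec$genotype_id,
    total_np_min = tot("NP"),
    n_c = length(c_bouts),
    n_c_short = sum(c_bouts < cfg$short_C_threshold_min),
    mean_c_min = if (length(c_bouts)) mean(c_bouts) else NA_real_,
    total_c_min = total_c,
    n_pd = sum(lab == "PD"), total_pd_min = tot("PD"),
    pd_rate_per_min_c = if (total_c > 0) sum(lab == "PD") / total_c else NA_real_,
    n_rpd = rpd$n, mean_rpd_min = rpd$mean, total_rpd_min = rpd$total,
    n_e1 = e1$n, mean_e1_min = e1$mean, total_e1_min = e1$total,
    max_e1_min = e1$max,
    latency_first_e1_min = if (is.finite(first_e1)) first_e1 else total_min,
    n_e1_not_followed_by_e2 = not_followed,
    pct_e1_of_phloem_phase = if (e1$total + e2$total > 0)
      100 * e1$total / (e1$total + e2$total) else NA_real_,
    n_e2 = e2$n, mean_e2_min = e2$mean, total_e2_min = e2$total,
    total_e2_sustained_min = sum(e2d[e2d > cfg$sustained_E2_threshold_min]),
    max_e2_min = e2$max,
    n_f = sum(lab == "F"), total_f_min = tot("F"),
    n_g = sum(lab == "G"), total_g_min = tot("G"),
    share_np = shares[["NP"]], share_c = shares[["C"]],
    share_pd = shares[["PD"]], share_rpd = shares[["RPD"]],
    share_e1 = shares[["E1"]], share_e2 = shares[["E2"]],
    share_f = shares[["F"]], share_g = shares[["G"]],
    stringsAsFactors = FALSE)
}

# semi-Markov stationary time shares implied by a genotype profile
profile_stationary_shares <- function(profile) {
  P <- profile$transition_matrix
  e <- eigen(t(P))
  pi_emb <- Re(e$vectors[, which.min(abs(e$values - 1))])
  pi_emb <- pi_emb / sum(pi_emb)
  m <- profile$dwell_shape * profile$dwell_scale
  sh <- pi_emb * m
  stats::setNames(sh / sum(sh), rownames(P))
}

# random recording over exactly one 8-h session (total = 480 min on the grid)
random_recording_8h <- function(max_segments = 30) {
  n <- sample.int(max_segments, 1L)
  cuts <- sort(sample(seq(100, 287900, by = 1L), n - 1L)) / 10  # 0.1 s grid
  bounds <- c(0, cuts, 28800)
  lab <- character(n)
  lab[1L] <- sample(epg_labels, 1L)
  for (i in seq_len(n)[-1L])
    lab[i] <- sample(setdiff(epg_labels, lab[i - 1L]), 1L)
  epg_recording("acc", "G1", lab, onset_s = bounds[-(n + 1L)],
                offset_s = bounds[-1L], total_duration_s = 28800)
}
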