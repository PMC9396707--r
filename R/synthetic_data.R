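#' Generative profile for one host genotype
#'
#' Bundles everything the simulators need for one genotype: a semi-Markov
#' behavioral model (embedded transition matrix over the waveform states and
#' gamma dwell-time parameters per state, in seconds), leaf condensed-tannin
#' means (constitutive and locally induced, mg/g DW, with between-plant SD),
#' and a reproduction model (baseline log mean nymph production, NB
#' dispersion, prereproductive-period distribution).
#'
#' Structural stylet logic is enforced: from nonprobing the only exit is into
#' pathway; potential drops and phloem salivation are enterable only from
#' pathway; phloem ingestion only from salivation.
#'
#' @param genotype_id Identifier.
#' @param ct_class `"high"` or `"low"` condensed-tannin producer.
#' @param transition_matrix Row-stochastic 7 x 7 matrix over states
#'   `NP, C, PD, E1, E2, F, G` with zero diagonal.
#' @param dwell_shape,dwell_scale Named per-state gamma parameters (seconds).
#' @param ct_constitutive_mean,ct_constitutive_sd Constitutive leaf CT
#'   (mg/g DW).
#' @param ct_induced_mean,ct_induced_sd Locally induced leaf CT (mg/g DW).
#' @param repro_log_mean Baseline log nymph production of the genotype.
#' @param repro_theta NB dispersion of nymph counts.
#' @param d_mean,d_sd Prereproductive period distribution (days).
#' @return Object of class `genotype_profile`.
#' @export
genotype_profile <- function(genotype_id, ct_class, transition_matrix,
                             dwell_shape, dwell_scale,
                             ct_constitutive_mean, ct_constitutive_sd,
                             ct_induced_mean, ct_induced_sd,
                             repro_log_mean, repro_theta = 2,
                             d_mean = 13, d_sd = 1) {
  states <- c("NP", "C", "PD", "E1", "E2", "F", "G")
  P <- as.matrix(transition_matrix)
  dimnames(P) <- list(states, states)
  if (any(abs(rowSums(P) - 1) > 1e-9)) stop("transition rows must sum to 1")
  if (any(diag(P) != 0)) stop("transition diagonal must be zero")
  if (any(P < 0)) stop("negative transition probability")
  if (any(P[, "PD"][states != "C"] > 0) || any(P[, "E1"][states != "C"] > 0))
    stop("PD and E1 must be enterable only from pathway (C)")
  if (any(P[, "E2"][states != "E1"] > 0))
    stop("E2 must be enterable only from E1")
  if (any(P["NP", setdiff(states, "C")] > 0))
    stop("from NP the only exit is into pathway (C)")
  stopifnot(all(dwell_shape[states] > 0), all(dwell_scale[states] > 0),
            ct_constitutive_mean >= 0, ct_induced_mean >= 0,
            repro_theta > 0, d_mean > 0)
  ## reachability of feeding states from the start state NP
  reach <- (diag(7) + P) %*% (diag(7) + P) %*% (diag(7) + P) %*% (diag(7) + P)
  unreachable <- setdiff(states[reach["NP", ] == 0], "NP")
  if (length(unreachable))
    warning("state(s) unreachable from NP: ",
            paste(unreachable, collapse = ", "))
  structure(list(genotype_id = genotype_id,
                 ct_class = match.arg(ct_class, c("high", "low")),
                 transition_matrix = P,
                 dwell_shape = dwell_shape[states],
                 dwell_scale = dwell_scale[states],
                 ct_constitutive_mean = ct_constitutive_mean,
                 ct_constitutive_sd = ct_constitutive_sd,
                 ct_induced_mean = ct_induced_mean,
                 ct_induced_sd = ct_induced_sd,
                 repro_log_mean = repro_log_mean, repro_theta = repro_theta,
                 d_mean = d_mean, d_sd = d_sd),
            class = "genotype_profile")
}

trans_row <- function(np = 0, c = 0, pd = 0, e1 = 0, e2 = 0, f = 0, g = 0)
  c(NP = np, C = c, PD = pd, E1 = e1, E2 = e2, F = f, G = g)

make_trans <- function(c_np, c_pd, c_e1, c_f, c_g,
                       e1_e2 = 0.5, e1_c = 0.35,
                       e2_c = 0.6, f_c = 0.7, g_c = 0.6) {
  rbind(NP = trans_row(c = 1),
        C  = trans_row(np = c_np, pd = c_pd, e1 = c_e1, f = c_f, g = c_g),
        PD = trans_row(c = 1),
        E1 = trans_row(e2 = e1_e2, c = e1_c, np = 1 - e1_e2 - e1_c),
        E2 = trans_row(c = e2_c, np = 1 - e2_c),
        F  = trans_row(c = f_c, np = 1 - f_c),
        G  = trans_row(c = g_c, np = 1 - g_c))
}

#' Default genotype profiles
#'
#' Five host genotypes: two low-CT producers (SwAsp50, SwAsp60) and three
#' high-CT producers (SwAsp69, SwAsp72, SwAsp79). The behavioral parameters
#' are calibrated to the qualitative class contrasts reported for aphids on
#' aspen — longer nonprobing and phloem salivation on low-CT hosts; more
#' penetration difficulties, and more xylem ingestion (on the order of
#' 10-20% of an 8-h session), on high-CT hosts — and to realistic bout
#' magnitudes; they are not estimates fitted to any real recording set.
#'
#' @return Named list of [genotype_profile()] objects.
#' @export
default_genotype_profiles <- function() {
  dwell_shape_low  <- c(NP = 1.2, C = 0.7, PD = 4, E1 = 1.5, E2 = 0.8,
                        F = 1.2, G = 1.5)
  dwell_scale_low  <- c(NP = 580, C = 229, PD = 1.25, E1 = 133, E2 = 3000,
                        F = 250, G = 400)
  dwell_shape_high <- dwell_shape_low
  dwell_scale_high <- c(NP = 210, C = 229, PD = 1.25, E1 = 40, E2 = 3000,
                        F = 333, G = 400)
  low_tm  <- make_trans(c_np = 0.32, c_pd = 0.44, c_e1 = 0.11, c_f = 0.03,
                        c_g = 0.10)
  high_tm <- make_trans(c_np = 0.24, c_pd = 0.44, c_e1 = 0.04, c_f = 0.14,
                        c_g = 0.14)
  list(
    SwAsp50 = genotype_profile("SwAsp50", "low", low_tm,
      dwell_shape_low, dwell_scale_low, 25, 7, 31, 8,
      repro_log_mean = 3.9, d_mean = 14.2),
    SwAsp60 = genotype_profile("SwAsp60", "low", low_tm,
      dwell_shape_low, dwell_scale_low, 30, 8, 36, 9,
      repro_log_mean = 3.4, d_mean = 12.9),
    SwAsp69 = genotype_profile("SwAsp69", "high", high_tm,
      dwell_shape_high, dwell_scale_high, 82, 12, 112, 15,
      repro_log_mean = 4.0, d_mean = 11.7),
    SwAsp72 = genotype_profile("SwAsp72", "high", high_tm,
      dwell_shape_high, dwell_scale_high, 95, 14, 132, 18,
      repro_log_mean = 3.2, d_mean = 14.0),
    SwAsp79 = genotype_profile("SwAsp79", "high", high_tm,
      dwell_shape_high, dwell_scale_high, 88, 13, 120, 16,
      repro_log_mean = 3.7, d_mean = 13.4))
}

#' Simulate one EPG recording from a genotype profile
#'
#' Semi-Markov simulation: starting in nonprobing, alternately draw a gamma
#' dwell time (rounded to the millisecond grid, minimum 1 ms) and the next
#' state from the embedded transition matrix, until the recording duration
#' is reached; the final bout is kept in truncated form.
#'
#' @param profile A [genotype_profile()].
#' @param duration_s Recording length in seconds (default 28800 = 8 h).
#' @param recording_id Identifier for the new recording.
#' @param seed Optional integer seed (otherwise the current RNG stream is
#'   used).
#' @return An `epg_recording`.
#' @export
simulate_recording <- function(profile, duration_s = 28800,
                               recording_id = "sim", seed = NULL) {
  stopifnot(inherits(profile, "genotype_profile"))
  if (!is.null(seed)) set.seed(seed)
  total_ms <- .ms(duration_s)
  states <- rownames(profile$transition_matrix)
  cap <- 256L
  lab <- character(cap); on <- numeric(cap)
  t <- 0; k <- 0L
  s <- "NP"
  while (t < total_ms) {
    k <- k + 1L
    if (k > cap) {            # grow geometrically
      cap <- cap * 2L
      length(lab) <- cap; length(on) <- cap
    }
    lab[k] <- s; on[k] <- t
    dwell <- max(1, .ms(stats::rgamma(1, shape = profile$dwell_shape[[s]],
                                      scale = profile$dwell_scale[[s]])))
    t <- t + dwell
    s <- sample(states, 1L, prob = profile$transition_matrix[s, ])
  }
  lab <- lab[seq_len(k)]; on <- on[seq_len(k)]
  off <- c(on[-1L], total_ms)
  rec <- new_recording(recording_id, profile$genotype_id, lab, on, off,
                       total_ms)
  merge_adjacent(rec)
}

#' Simulate a cohort of recordings across genotypes
#'
#' @param profiles List of [genotype_profile()] objects.
#' @param n_per_genotype Recordings per genotype (default 12).
#' @param duration_s Recording length (seconds).
#' @param seed Integer seed fixing the whole cohort.
#' @param cfg [param_config()] used for the parameter table.
#' @return List with `recordings` (list of `epg_recording`), `metadata`
#'   (recording_id, genotype_id, ct_class) and `params` (behavioral
#'   parameter table).
#' @export
simulate_cohort <- function(profiles, n_per_genotype = 12,
                            duration_s = 28800, seed = NULL,
                            cfg = param_config(rpd_mode = "derived")) {
  if (!length(profiles)) stop("at least one profile required")
  if (!is.null(seed)) set.seed(seed)
  recs <- list(); md <- list()
  for (pr in profiles) {
    for (i in seq_len(n_per_genotype)) {
      id <- sprintf("%s_r%02d", pr$genotype_id, i)
      recs[[id]] <- simulate_recording(pr, duration_s, recording_id = id)
      md[[id]] <- data.frame(recording_id = id, genotype_id = pr$genotype_id,
                             ct_class = pr$ct_class,
                             stringsAsFactors = FALSE)
    }
  }
  metadata <- if (length(md))
    do.call(rbind, c(md, list(make.row.names = FALSE)))
  else data.frame(recording_id = character(), genotype_id = character(),
                  ct_class = character(), stringsAsFactors = FALSE)
  params <- if (length(recs)) compute_parameter_table(recs, cfg) else NULL
  list(recordings = recs, metadata = metadata, params = params)
}

rtruncnorm0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  lo <- stats::pnorm(0, mean, sd)
  stats::qnorm(stats::runif(n, lo, 1), mean, sd)
}

#' Simulate one founder's reproduction series
#'
#' Total nymph production is drawn from a negative binomial with mean
#' `exp(repro_log_mean + beta * induced_ct)` and dispersion `repro_theta`;
#' the prereproductive period `d` from a (rounded, >= 1 day) normal. Births
#' are spread over the reproductive days with geometrically decaying weights
#' and reported either as daily counts with removal or as cumulative
#' standing counts on fixed census days.
#'
#' @param profile A [genotype_profile()].
#' @param induced_ct Locally induced CT concentration (mg/g DW).
#' @param protocol `"removal"` (daily) or `"census"`.
#' @param beta CT effect on log mean nymph production (default -0.009 per
#'   mg/g).
#' @param census_days Census days postinfestation (census protocol).
#' @param repro_span Number of reproductive days over which births spread.
#' @param founder_id Identifier.
#' @param seed Optional integer seed.
#' @return Data frame `founder_id, genotype_id, day, nymphs` (long format).
#' @export
simulate_reproduction <- function(profile, induced_ct,
                                  protocol = c("removal", "census"),
                                  beta = -0.009,
                                  census_days = c(1, 7, 13, 22),
                                  repro_span = 20, founder_id = "f1",
                                  seed = NULL) {
  protocol <- match.arg(protocol)
  stopifnot(inherits(profile, "genotype_profile"))
  if (!is.null(seed)) set.seed(seed)
  d <- max(1L, round(stats::rnorm(1, profile$d_mean, profile$d_sd)))
  mu <- exp(profile$repro_log_mean + beta * induced_ct)
  M <- stats::rnbinom(1, size = profile$repro_theta, mu = mu)
  birth_days <- d:(d + repro_span - 1L)
  w <- 0.85^(seq_along(birth_days) - 1L)
  ## day d is by definition the first reproduction day, so it gets the first
  ## nymph; the remaining births spread with geometric decay
  births <- integer(length(birth_days))
  if (M > 0) {
    births <- drop(stats::rmultinom(1, M - 1L, w))
    births[1L] <- births[1L] + 1L
  }
  if (protocol == "removal") {
    days <- seq_len(max(birth_days))
    nymphs <- integer(length(days))
    nymphs[birth_days] <- births
  } else {
    days <- census_days
    cum_by_day <- stats::stepfun(birth_days, c(0, cumsum(births)))
    nymphs <- as.integer(cum_by_day(days))
  }
  out <- data.frame(founder_id = founder_id,
                    genotype_id = profile$genotype_id,
                    day = days, nymphs = nymphs, stringsAsFactors = FALSE)
  attr(out, "d") <- d
  attr(out, "M") <- M
  out
}

#' Simulate negative-binomial counts with a group random intercept
#'
#' Generic generator for count data of the form
#' `y ~ NB(mean = exp(a_g + beta * x), dispersion theta)` with group
#' intercepts `a_g ~ N(intercept, sigma2_group)` — the data-generating shape
#' of the reproduction-vs-induced-CT mixed model.
#'
#' @param n_groups,n_per_group Design size.
#' @param intercept Population log-mean intercept.
#' @param beta Covariate effect on the log mean.
#' @param theta NB dispersion (> 0).
#' @param sigma2_group Random-intercept variance (>= 0).
#' @param covariate Optional numeric covariate (length
#'   `n_groups * n_per_group`); standard-normal draws by default.
#' @param seed Optional integer seed.
#' @return Data frame `y, x, group`.
#' @export
simulate_nb_counts <- function(n_groups, n_per_group, intercept = 3,
                               beta = -0.3, theta = 2, sigma2_group = 0.35,
                               covariate = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(theta > 0, sigma2_group >= 0)
  n <- n_groups * n_per_group
  g <- factor(rep(seq_len(n_groups), each = n_per_group))
  x <- if (is.null(covariate)) stats::rnorm(n) else covariate
  stopifnot(length(x) == n)
  a <- stats::rnorm(n_groups, intercept, sqrt(sigma2_group))
  mu <- exp(a[as.integer(g)] + beta * x)
  data.frame(y = stats::rnbinom(n, size = theta, mu = mu), x = x, group = g)
}

#' Simulate a leaf condensed-tannin assay table
#'
#' Per plant, constitutive (old uncolonized leaf) and locally induced
#' (colonized leaf) CT concentrations are drawn from truncated-normal
#' (>= 0) distributions around the genotype means. `delta_ct` is the
#' induction contrast, induced minus constitutive (positive = local CT
#' accumulation).
#'
#' @param profiles List of [genotype_profile()] objects.
#' @param n_per_genotype Plants per genotype (default 4).
#' @param seed Optional integer seed.
#' @return Data frame `plant_id, genotype_id, ct_class, constitutive,
#'   induced, delta_ct` (mg/g DW).
#' @export
simulate_ct <- function(profiles, n_per_genotype = 4, seed = NULL) {
  stopifnot(n_per_genotype >= 1)
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(profiles, function(pr) {
    cons <- rtruncnorm0(n_per_genotype, pr$ct_constitutive_mean,
                        pr$ct_constitutive_sd)
    ind <- rtruncnorm0(n_per_genotype, pr$ct_induced_mean, pr$ct_induced_sd)
    data.frame(plant_id = sprintf("%s_p%02d", pr$genotype_id,
                                  seq_len(n_per_genotype)),
               genotype_id = pr$genotype_id, ct_class = pr$ct_class,
               constitutive = cons, induced = ind,
               delta_ct = ind - cons, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
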