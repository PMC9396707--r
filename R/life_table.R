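#' Intrinsic rate of increase (Wyatt-White approximation)
#'
#' `r_m = c * ln(M_d) / d`, where `d` is the prereproductive period in days,
#' `M_d` the total number of nymphs produced, and `c = 0.738` a correction
#' constant estimated across several aphid species.
#'
#' @param M_d Total nymph production (>= 1).
#' @param d Prereproductive period in days (> 0).
#' @param c Correction constant (default 0.738).
#' @return Intrinsic rate of increase, per day.
#' @export
intrinsic_rate <- function(M_d, d, c = 0.738) {
  if (any(M_d < 1)) stop("M_d must be >= 1 (ln undefined or negative)")
  if (any(d <= 0)) stop("d must be positive")
  c * log(M_d) / d
}

#' Population doubling time
#'
#' `DT = ln(2) / r_m` days.
#'
#' @param r_m Intrinsic rate of increase (> 0), per day.
#' @return Doubling time in days.
#' @export
doubling_time <- function(r_m) {
  if (any(r_m <= 0)) stop("r_m must be positive")
  log(2) / r_m
}

#' Life-table record for one founder
#'
#' The prereproductive period `d` is the first observation day with a
#' positive nymph count. Under the daily-removal protocol `M_d` is the sum of
#' all counts; under the census protocol (nymphs counted without removal on a
#' few fixed days) `M_d` is the final census count. `r_m` and `DT` are left
#' missing (not silently zeroed) when their preconditions fail (`M_d < 1`,
#' or `r_m <= 0`).
#'
#' @param days Observation days postinfestation (strictly increasing).
#' @param nymphs Nonnegative integer counts, one per day.
#' @param protocol `"removal"` (daily counts, nymphs removed) or `"census"`
#'   (cumulative standing counts).
#' @param c Correction constant passed to [intrinsic_rate()].
#' @return One-row data frame with `d`, `M_d`, `r_m`, `DT`.
#' @export
derive_life_table <- function(days, nymphs,
                              protocol = c("removal", "census"), c = 0.738) {
  protocol <- match.arg(protocol)
  stopifnot(length(days) == length(nymphs), length(days) >= 1L)
  if (any(diff(days) <= 0)) stop("days must be strictly increasing")
  if (any(days < 0)) stop("days must be nonnegative")
  if (any(nymphs < 0) || any(nymphs != round(nymphs)))
    stop("nymph counts must be nonnegative integers")
  first_pos <- which(nymphs > 0)[1L]
  d <- if (is.na(first_pos)) NA_real_ else days[first_pos]
  M_d <- if (protocol == "removal") sum(nymphs) else nymphs[length(nymphs)]
  r_m <- if (!is.na(d) && M_d >= 1 && d > 0) intrinsic_rate(M_d, d, c)
         else NA_real_
  DT <- if (!is.na(r_m) && r_m > 0) doubling_time(r_m) else NA_real_
  data.frame(d = d, M_d = M_d, r_m = r_m, DT = DT)
}

#' Life table for a cohort of founders
#'
#' @param data Long-format data frame with columns `founder_id`,
#'   `genotype_id`, `day`, `nymphs`.
#' @param protocol Counting protocol, see [derive_life_table()].
#' @param c Correction constant.
#' @return Data frame with one row per founder (`founder_id`, `genotype_id`,
#'   `d`, `M_d`, `r_m`, `DT`).
#' @export
life_table <- function(data, protocol = c("removal", "census"), c = 0.738) {
  protocol <- match.arg(protocol)
  need <- c("founder_id", "genotype_id", "day", "nymphs")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  out <- lapply(split(data, data$founder_id), function(dd) {
    dd <- dd[order(dd$day), ]
    cbind(data.frame(founder_id = dd$founder_id[1L],
                     genotype_id = dd$genotype_id[1L],
                     stringsAsFactors = FALSE),
          derive_life_table(dd$day, dd$nymphs, protocol, c))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-genotype cumulative reproduction curves
#'
#' For each genotype, the pointwise mean of per-founder cumulative nymph
#' counts on the union of observation days, using step ("last observation
#' carried forward") interpolation; curves are monotone nondecreasing.
#'
#' @param data Long-format reproduction table as in [life_table()], recorded
#'   under the daily-removal protocol.
#' @return Data frame with columns `genotype_id`, `day`, `mean_cum_nymphs`.
#' @export
cumulative_curves <- function(data) {
  need <- c("founder_id", "genotype_id", "day", "nymphs")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  out <- lapply(split(data, data$genotype_id), function(dd) {
    days <- sort(unique(dd$day))
    series <- split(dd, dd$founder_id)
    cum <- vapply(series, function(s) {
      s <- s[order(s$day), ]
      cs <- cumsum(s$nymphs)
      ## step interpolation on the union grid; 0 before the first observation
      idx <- findInterval(days, s$day)
      c(0, cs)[idx + 1L]
    }, numeric(length(days)))
    cum <- matrix(cum, nrow = length(days))
    data.frame(genotype_id = dd$genotype_id[1L], day = days,
               mean_cum_nymphs = rowMeans(cum), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
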