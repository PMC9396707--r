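write_report_tsv <- function(df, path, seed, config_tag) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed: %s | config: %s", seed, config_tag), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

config_tag <- function(cfg) {
  paste(vapply(cfg, function(x) paste(format(x), collapse = ","), ""),
        collapse = ";")
}

#' End-to-end EPG behavior analysis
#'
#' Parses (or accepts) a cohort of recordings, derives the behavioral
#' parameter table, summarizes each genotype cohort with pairwise
#' Mann-Whitney letter annotations, tabulates per-activity time shares, and
#' runs the sparse PLS-DA contrast of high- vs low-CT genotype classes.
#' All outputs are TSV files stamped with the seed and configuration.
#'
#' @param recordings List of `epg_recording` objects, or `NULL` to parse
#'   every annotation file in `annotations_dir`.
#' @param metadata Data frame with `recording_id`, `genotype_id`,
#'   `ct_class` (see [read_epg_metadata()]).
#' @param out_dir Output directory (created if missing), or `NULL` to skip
#'   writing.
#' @param annotations_dir Directory of annotation files (used when
#'   `recordings` is `NULL`); file base names must match `recording_id`s.
#' @param cfg [param_config()].
#' @param alpha Significance level for letter displays.
#' @param n_components,keep_x,cv_folds sPLS-DA settings.
#' @param seed Integer seed (stratified CV folds).
#' @param codemap [epg_codemap()] for parsing.
#' @return List: `params`, `cohorts` (per-genotype summaries), `letters`
#'   (per-variable letter displays), `activity_shares`, `splsda`,
#'   `cv_error`.
#' @export
run_epg_analysis <- function(recordings = NULL, metadata, out_dir = NULL,
                             annotations_dir = NULL, cfg = param_config(),
                             alpha = 0.05, n_components = 2, keep_x = 10,
                             cv_folds = 5, seed = 1,
                             codemap = epg_codemap()) {
  if (is.null(recordings)) {
    if (is.null(annotations_dir) || !dir.exists(annotations_dir))
      stop("annotations directory not found: ",
           if (is.null(annotations_dir)) "<NULL>" else annotations_dir)
    files <- list.files(annotations_dir, full.names = TRUE)
    if (!length(files)) stop("no annotation files in ", annotations_dir)
    recordings <- lapply(files, function(f) {
      rid <- tools::file_path_sans_ext(basename(f))
      row <- match(rid, metadata$recording_id)
      if (is.na(row)) stop("no metadata for recording: ", rid)
      parse_annotation(f, codemap, recording_id = rid,
                       genotype_id = metadata$genotype_id[row])
    })
  }
  params <- compute_parameter_table(recordings, cfg)
  params$ct_class <-
    metadata$ct_class[match(params$genotype_id, metadata$genotype_id)]

  cohorts <- lapply(split(params, params$genotype_id), aggregate_cohort)

  vars <- setdiff(names(params)[vapply(params, is.numeric, TRUE)],
                  "pd_rate_per_min_c")
  vars <- c(vars, "pd_rate_per_min_c")
  letter_tabs <- list()
  for (v in vars) {
    ok <- !is.na(params[[v]])
    grp <- factor(params$genotype_id[ok])
    if (nlevels(grp) >= 2L && all(table(grp) >= 1L) &&
        length(unique(params[[v]][ok])) > 1L)
      letter_tabs[[v]] <- pairwise_mwu_letters(params[[v]][ok], grp,
                                               alpha = alpha)
  }

  share_cols <- grep("^share_", names(params), value = TRUE)
  shares <- do.call(rbind, lapply(split(params, params$genotype_id),
    function(pp) {
      data.frame(genotype_id = pp$genotype_id[1L],
                 t(colMeans(pp[share_cols])), stringsAsFactors = FALSE)
    }))
  rownames(shares) <- NULL

  splsda_fit <- NULL; cv <- NULL
  if (length(unique(params$ct_class)) == 2L) {
    Xv <- as.matrix(params[epg_discriminant_variables()])
    ## variables carrying no information in this cohort (all missing, or
    ## constant across aphids) cannot be standardized and are set aside
    keep <- apply(Xv, 2L, function(col)
      sum(!is.na(col)) >= 2L && stats::sd(col, na.rm = TRUE) > 0)
    if (any(!keep))
      message("excluding uninformative variable(s) from sPLS-DA: ",
              paste(colnames(Xv)[!keep], collapse = ", "))
    Xv <- Xv[, keep, drop = FALSE]
    yv <- factor(params$ct_class)
    kx <- min(keep_x, ncol(Xv))
    splsda_fit <- fit_splsda(Xv, yv, n_components = n_components,
                             keep_x = kx)
    cv <- cv_error(Xv, yv, n_components = n_components, keep_x = kx,
                   folds = cv_folds, seed = seed)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    tag <- config_tag(cfg)
    write_report_tsv(params, file.path(out_dir, "parameters.tsv"), seed, tag)
    smry <- do.call(rbind, lapply(cohorts, function(co) {
      s <- co$summary
      s$genotype_id <- co$genotype_id
      s$letters <- vapply(s$variable, function(v)
        if (!is.null(letter_tabs[[v]]))
          letter_tabs[[v]]$letters[[co$genotype_id]] else "", "")
      s
    }))
    write_report_tsv(smry, file.path(out_dir, "cohort_summary.tsv"), seed, tag)
    write_report_tsv(shares, file.path(out_dir, "activity_shares.tsv"),
                     seed, tag)
    if (!is.null(splsda_fit)) {
      lo <- data.frame(variable = rownames(splsda_fit$x_weights),
                       splsda_fit$x_weights)
      write_report_tsv(lo, file.path(out_dir, "splsda_loadings.tsv"),
                       seed, tag)
      write_report_tsv(data.frame(components = seq_along(cv), cv_error = cv),
                       file.path(out_dir, "splsda_cv_error.tsv"), seed, tag)
    }
  }
  list(params = params, cohorts = cohorts, letters = letter_tabs,
       activity_shares = shares, splsda = splsda_fit, cv_error = cv)
}

#' Aphid performance analysis: demography and tannin effects
#'
#' Derives the per-founder life table (prereproductive period, total
#' fecundity, intrinsic rate of increase, doubling time), fits the
#' negative-binomial mixed model of total reproduction on induced leaf CT
#' with a genotype random intercept, checks for residual overdispersion,
#' and - when the reproduction table carries at least two experimental
#' conditions - the two-way sequential ANOVA of final counts on genotype,
#' condition and their interaction.
#'
#' @param reproduction Long-format reproduction table (`founder_id`,
#'   `genotype_id`, `day`, `nymphs`, optional `condition`).
#' @param ct CT assay table (as from [simulate_ct()]): `genotype_id`,
#'   `induced` at minimum.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param protocol Counting protocol for the life table.
#' @param seed Stamped into outputs.
#' @return List: `life_table`, `genotype_summary`, `nb_glmm`,
#'   `overdispersion`, `anova` (`NULL` with a notice when only one
#'   condition is present).
#' @export
run_performance_analysis <- function(reproduction, ct, out_dir = NULL,
                                     protocol = c("removal", "census"),
                                     seed = 1) {
  protocol <- match.arg(protocol)
  lt <- life_table(reproduction, protocol)
  gsum <- do.call(rbind, lapply(split(lt, lt$genotype_id), function(g) {
    data.frame(genotype_id = g$genotype_id[1L], n = nrow(g),
               d_mean = mean(g$d, na.rm = TRUE),
               M_d_mean = mean(g$M_d, na.rm = TRUE),
               r_m_mean = mean(g$r_m, na.rm = TRUE),
               DT_mean = mean(g$DT, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(gsum) <- NULL

  ct_by_geno <- tapply(ct$induced, ct$genotype_id, mean)
  lt$induced_ct <- as.numeric(ct_by_geno[lt$genotype_id])
  if (anyNA(lt$induced_ct))
    stop("no induced CT values for genotype(s): ",
         paste(unique(lt$genotype_id[is.na(lt$induced_ct)]), collapse = ", "))
  fit <- fit_nb_glmm(lt$M_d, lt$induced_ct, lt$genotype_id)
  od <- check_overdispersion(fit)

  aov_tab <- NULL
  if (!is.null(reproduction$condition) &&
      length(unique(reproduction$condition)) >= 2L) {
    finals <- life_table(reproduction, protocol)
    cond <- reproduction$condition[match(finals$founder_id,
                                         reproduction$founder_id)]
    dd <- data.frame(count = finals$M_d, genotype = finals$genotype_id,
                     condition = cond)
    aov_tab <- anova_sequential(count ~ genotype * condition, dd)
  } else {
    message("single experimental condition: skipping two-way ANOVA")
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report_tsv(lt, file.path(out_dir, "life_table.tsv"), seed, protocol)
    write_report_tsv(gsum, file.path(out_dir, "life_table_by_genotype.tsv"),
                     seed, protocol)
    co <- data.frame(term = rownames(fit$coefficients), fit$coefficients)
    write_report_tsv(co, file.path(out_dir, "nb_glmm.tsv"), seed, protocol)
    write_report_tsv(data.frame(pearson_chi_sq = od$pearson_chi_sq,
                                residual_df = od$residual_df,
                                ratio = od$ratio, p_value = od$p.value),
                     file.path(out_dir, "overdispersion.tsv"), seed, protocol)
    if (!is.null(aov_tab))
      write_report_tsv(aov_tab, file.path(out_dir, "anova_two_way.tsv"),
                       seed, protocol)
  }
  list(life_table = lt, genotype_summary = gsum, nb_glmm = fit,
       overdispersion = od, anova = aov_tab)
}
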