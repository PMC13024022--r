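# End-to-end orchestration: synthesize (or load) a cohort, preprocess,
# spectral analysis, connectivity, topology, statistics, report. All
# randomness is fanned out from one master seed via derive_seed(), so any
# stage is reproducible in isolation and identical config + seed gives a
# byte-identical report.

#' Pipeline run configuration
#'
#' @param input `"synthetic"` (generate the cohort from `truth`) or
#'   `"files"` (read an EDF directory with a `manifest.csv`,
#'   `behavioral.csv`, `body_composition.csv` as written by
#'   [write_cohort_edf()]).
#' @param truth A [cohort_truth()] (synthetic mode).
#' @param data_dir Input directory (files mode).
#' @param montage Montage used throughout.
#' @param bands Band set to analyse (subset of [eeg_bands()]).
#' @param epoch_length,epoch_step Welch segmentation (s).
#' @param nfft FFT length; `NULL` uses the epoch length in samples.
#' @param wpli_window Connectivity window length (s).
#' @param sparsities Sparsity grid for topology.
#' @param reject_uv Epoch-rejection threshold (microvolts).
#' @param alpha Significance level.
#' @param n_perm NBS permutations.
#' @param n_boot Bootstrap resamples for regression CIs.
#' @param seed Master seed.
#' @param out_dir Report output directory (`NULL`: nothing written).
#' @return A `run_config` list.
#' @export
run_config <- function(input = c("synthetic", "files"), truth = cohort_truth(),
                       data_dir = NULL, montage = default_montage(),
                       bands = eeg_bands(), epoch_length = 5, epoch_step = 1,
                       nfft = NULL, wpli_window = 2,
                       sparsities = sparsity_grid(), reject_uv = 100,
                       alpha = 0.05, n_perm = 5000, n_boot = 2000,
                       seed = 42L, out_dir = NULL) {
  input <- match.arg(input)
  if (input == "files") {
    if (is.null(data_dir) || !file.exists(file.path(data_dir, "manifest.csv"))) {
      stop("files mode needs data_dir containing manifest.csv", call. = FALSE)
    }
  }
  structure(list(input = input, truth = truth, data_dir = data_dir,
                 montage = montage, bands = bands,
                 epoch_length = epoch_length, epoch_step = epoch_step,
                 nfft = nfft, wpli_window = wpli_window,
                 sparsities = sparsities, reject_uv = reject_uv,
                 alpha = alpha, n_perm = n_perm, n_boot = n_boot,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

load_cohort <- function(cfg) {
  if (cfg$input == "synthetic") {
    return(simulate_cohort(cfg$truth, cfg$montage))
  }
  manifest <- utils::read.csv(file.path(cfg$data_dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  behavioral <- utils::read.csv(file.path(cfg$data_dir, "behavioral.csv"),
                                stringsAsFactors = FALSE)
  body <- utils::read.csv(file.path(cfg$data_dir, "body_composition.csv"),
                          stringsAsFactors = FALSE)
  subjects <- unique(manifest[, c("subject", "group")])
  list(subjects = subjects, behavioral = behavioral, body = body,
       recording = function(subject, condition = c("pre", "post")) {
         condition <- match.arg(condition)
         row <- manifest[manifest$subject == subject &
                           manifest$condition == condition, ]
         if (nrow(row) != 1L) stop("manifest lookup failed for ", subject,
                                   "/", condition, call. = FALSE)
         read_edf(file.path(cfg$data_dir, row$file))
       })
}

stage_msg <- function(stage, ...) {
  message(sprintf("[oscnet:%s] %s", stage, sprintf(...)))
}

#' Run the full analysis pipeline
#'
#' Stages: cohort -> preprocessing -> Welch band powers and channel-wise
#' pre/post tests -> wPLI connectivity, whole-brain strength tests and NBS
#' -> sparsity-AUC topology tests -> behavioral group comparisons ->
#' older-group univariate regressions with BCa CIs. Identical `cfg` and
#' seed produce an identical report; with `out_dir` set, CSV/JSON outputs
#' are written there.
#'
#' @param cfg A [run_config()].
#' @return A `study_report` list with elements `behavioral_stats`,
#'   `demographics`, `psd_stats`, `strength_stats`, `nbs`, `topology_stats`,
#'   `regressions`, `band_powers`, `meta`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  cohort <- load_cohort(cfg)
  subjects <- cohort$subjects
  bands <- cfg$bands
  groups <- unique(subjects$group)

  # ---- per-subject signal processing -------------------------------------
  stage_msg("preprocess", "processing %d subjects x 2 conditions",
            nrow(subjects))
  bp_tables <- list()   # [[subject]][[condition]] channel x band matrix
  conn <- list()        # [[band]][[group]][[condition]] list of conn_matrix
  topo_auc <- list()    # [[band]][[group]][[condition]] matrix subj x metric
  for (i in seq_len(nrow(subjects))) {
    id <- subjects$subject[i]
    grp <- subjects$group[i]
    for (cond in c("pre", "post")) {
      rec <- cohort$recording(id, cond)
      pp <- preprocess(rec, band = c(0.5, min(46, rec$fs / 2 - 5)),
                       notch_freq = 50, target_fs = rec$fs,
                       reject_uv = cfg$reject_uv)
      clean <- pp$recording
      es <- segment_epochs(clean, cfg$epoch_length, cfg$epoch_step)
      psd <- welch_psd(es, cfg$nfft %||% dim(es$epochs)[3])
      bp_tables[[id]][[cond]] <- band_power_table(psd, bands, subject = id,
                                                  condition = cond)
      rts <- map_to_regions(clean, cfg$montage)
      for (b in seq_len(nrow(bands))) {
        bn <- bands$band[b]
        cm <- wpli_matrix(rts, bands[b, , drop = FALSE],
                          window = cfg$wpli_window)
        conn[[bn]][[grp]][[cond]][[id]] <- cm
        gm <- graph_metric_set(cm, cfg$sparsities)
        topo_auc[[bn]][[grp]][[cond]] <-
          rbind(topo_auc[[bn]][[grp]][[cond]], gm$global_auc)
      }
    }
  }

  # ---- spectral statistics ----------------------------------------------
  stage_msg("spectra", "channel-wise pre/post tests")
  psd_stats <- list()
  for (grp in groups) {
    ids <- subjects$subject[subjects$group == grp]
    pre_l <- lapply(ids, function(id) bp_tables[[id]]$pre)
    post_l <- lapply(ids, function(id) bp_tables[[id]]$post)
    for (b in bands$band) {
      res <- channelwise_prepost_tests(pre_l, post_l, b)
      res$group <- grp
      res$band <- b
      psd_stats[[paste(grp, b)]] <- res
    }
  }
  psd_stats <- do.call(rbind, psd_stats)
  rownames(psd_stats) <- NULL

  # ---- connectivity statistics ------------------------------------------
  stage_msg("connectivity", "whole-brain strength and NBS")
  strength_rows <- list()
  nbs_results <- list()
  for (grp in groups) {
    for (b in bands$band) {
      pre_m <- conn[[b]][[grp]]$pre
      post_m <- conn[[b]][[grp]]$post
      pre_s <- vapply(pre_m, mean_connectivity_strength, numeric(1))
      post_s <- vapply(post_m, mean_connectivity_strength, numeric(1))
      st <- paired_tests(pre_s, post_s)
      strength_rows[[paste(grp, b)]] <- data.frame(
        group = grp, band = b, test = st$test, statistic = st$statistic,
        p = st$p, effect = st$effect,
        effect_convention = st$effect_convention, stringsAsFactors = FALSE)
      if (length(pre_m) >= 5L) {
        nbs_results[[paste(grp, b, sep = ".")]] <- nbs_paired(
          pre_m, post_m, primary_alpha = 0.01, n_perm = cfg$n_perm,
          seed = derive_seed(cfg$seed, paste("nbs", grp, b)))
      }
    }
  }
  strength_stats <- do.call(rbind, strength_rows)
  strength_stats$p_fdr <- NA_real_
  for (grp in groups) {
    sel <- strength_stats$group == grp
    strength_stats$p_fdr[sel] <- bh_fdr(strength_stats$p[sel])
  }
  rownames(strength_stats) <- NULL

  # ---- topology statistics ----------------------------------------------
  stage_msg("topology", "sparsity-AUC paired tests")
  topo_rows <- list()
  for (grp in groups) {
    for (b in bands$band) {
      pre_m <- topo_auc[[b]][[grp]]$pre
      post_m <- topo_auc[[b]][[grp]]$post
      for (metric in colnames(pre_m)) {
        if (anyNA(pre_m[, metric]) || anyNA(post_m[, metric])) next
        st <- tryCatch(paired_tests(pre_m[, metric], post_m[, metric]),
                       error = function(e) NULL)
        if (is.null(st)) next
        topo_rows[[paste(grp, b, metric)]] <- data.frame(
          group = grp, band = b, metric = metric, test = st$test,
          statistic = st$statistic, p = st$p, effect = st$effect,
          effect_convention = st$effect_convention, stringsAsFactors = FALSE)
      }
    }
  }
  topology_stats <- do.call(rbind, topo_rows)
  rownames(topology_stats) <- NULL

  # ---- behavioral and demographic comparisons ---------------------------
  stage_msg("behavior", "group comparisons")
  beh <- cohort$behavioral
  body <- cohort$body
  young <- function(tab, v) tab[[v]][tab$group == "young"]
  old <- function(tab, v) tab[[v]][tab$group == "old"]
  group_test <- function(x, y) {
    # normality-dispatched independent comparison (x = young, y = old)
    normal <- isTRUE(shapiro_wilk(x)$normal) && isTRUE(shapiro_wilk(y)$normal)
    if (normal) t_independent(x, y) else mann_whitney_u(x, y)
  }
  beh_vars <- c("Acc", "T", "Perf")
  behavioral_stats <- do.call(rbind, lapply(beh_vars, function(v) {
    st <- group_test(young(beh, v), old(beh, v))
    pw <- if (st$test == "t_independent") {
      posthoc_power(abs(st$effect), length(young(beh, v)),
                    length(old(beh, v)), family = "independent_t",
                    alpha = cfg$alpha)
    } else {
      posthoc_power(st$effect, length(young(beh, v)), length(old(beh, v)),
                    family = "mann_whitney", alpha = cfg$alpha,
                    seed = derive_seed(cfg$seed, paste("power", v)))
    }
    data.frame(variable = v, test = st$test, statistic = st$statistic,
               p = st$p, effect = st$effect,
               effect_convention = st$effect_convention,
               power = as.numeric(pw), stringsAsFactors = FALSE)
  }))
  demo_vars <- c("BMI", "SMI", "VFA", "P_LM")
  demographics <- do.call(rbind, lapply(demo_vars, function(v) {
    st <- group_test(young(body, v), old(body, v))
    data.frame(variable = v,
               mean_old = mean(old(body, v)), sd_old = stats::sd(old(body, v)),
               mean_young = mean(young(body, v)),
               sd_young = stats::sd(young(body, v)),
               test = st$test, statistic = st$statistic, p = st$p,
               stringsAsFactors = FALSE)
  }))

  # ---- older-group regressions ------------------------------------------
  stage_msg("regression", "older-group univariate models with BCa CIs")
  old_beh <- beh[beh$group == "old", ]
  old_body <- body[body$group == "old", ]
  # per-subject task-modulation scalar: mean band-power delta over the
  # channels/bands of the configured selection (default: all)
  dpsd <- vapply(old_beh$subject, function(id) {
    delta_psd_scalar(delta_psd(bp_tables[[id]]$pre, bp_tables[[id]]$post))
  }, numeric(1))
  reg_specs <- list(
    c("MoCA_B", "Acc"), c("MoCA_B", "T"), c("MoCA_B", "Perf"),
    c("dPSD", "Acc"), c("dPSD", "MoCA_B"), c("dPSD", "Perf"),
    c("MoCA_B", "VFA"), c("dPSD", "VFA"),
    c("MoCA_B", "P_LM"), c("dPSD", "P_LM")
  )
  getvar <- function(v) {
    if (v == "dPSD") dpsd
    else if (v %in% names(old_beh)) old_beh[[v]]
    else old_body[[v]]
  }
  regressions <- do.call(rbind, lapply(reg_specs, function(sp) {
    y <- getvar(sp[1]); x <- getvar(sp[2])
    rr <- linear_regression_bca(x, y, n_boot = cfg$n_boot,
                                seed = derive_seed(cfg$seed,
                                                   paste("bca", sp[1], sp[2])))
    data.frame(outcome = sp[1], predictor = sp[2], slope = rr$slope,
               r = rr$r, r_squared = rr$r_squared, f = rr$f, df1 = rr$df1,
               df2 = rr$df2, p = rr$p, ci_lower = rr$ci_lower,
               ci_upper = rr$ci_upper, stringsAsFactors = FALSE)
  }))
  regressions$p_fdr <- bh_fdr(regressions$p)

  report <- structure(
    list(behavioral_stats = behavioral_stats, demographics = demographics,
         psd_stats = psd_stats, strength_stats = strength_stats,
         nbs = nbs_results, topology_stats = topology_stats,
         regressions = regressions, band_powers = bp_tables,
         meta = list(seed = cfg$seed, alpha = cfg$alpha,
                     n_perm = cfg$n_perm, n_boot = cfg$n_boot,
                     bands = bands$band, epoch_length = cfg$epoch_length,
                     epoch_step = cfg$epoch_step,
                     wpli_window = cfg$wpli_window,
                     sparsities = cfg$sparsities,
                     reject_uv = cfg$reject_uv,
                     effect_conventions = c("cohen_d_paired = t/sqrt(n)",
                                            "rank_ratio = W/max",
                                            "cliffs_delta = |2U/(n1 n2)-1|"),
                     dpsd_selection = "all channels x all bands")),
    class = "study_report")
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  }
  wr(report$behavioral_stats, "behavioral_stats.csv")
  wr(report$demographics, "demographics.csv")
  wr(report$psd_stats, "psd_stats.csv")
  wr(report$strength_stats, "strength_stats.csv")
  wr(report$topology_stats, "topology_stats.csv")
  wr(report$regressions, "regressions.csv")
  nbs_summary <- lapply(report$nbs, function(r) {
    list(n_components = length(r$component_sizes),
         component_sizes = r$component_sizes, fwe_p = r$fwe_p,
         primary_alpha = r$primary_alpha, n_perm = r$n_perm)
  })
  jsonlite::write_json(list(meta = report$meta, nbs = nbs_summary),
                       file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Formatted summary tables of a study report
#'
#' A demographics/behavioral table (variable, group summaries, statistic,
#' p) and a spectral-results table (group, band, electrode, statistic, p,
#' FDR-adjusted p, effect) restricted to FDR-significant electrodes.
#'
#' @param report A `study_report`.
#' @param alpha FDR significance cutoff for the spectral table.
#' @return List with data.frames `table1` and `table2`.
#' @export
report_tables <- function(report, alpha = 0.05) {
  stopifnot(inherits(report, "study_report"))
  t1 <- report$demographics
  t1$summary_old <- sprintf("%.3f +/- %.3f", t1$mean_old, t1$sd_old)
  t1$summary_young <- sprintf("%.3f +/- %.3f", t1$mean_young, t1$sd_young)
  table1 <- t1[, c("variable", "summary_old", "summary_young", "test",
                   "statistic", "p")]
  ps <- report$psd_stats
  sig <- !is.na(ps$p_fdr) & ps$p_fdr < alpha
  table2 <- ps[sig, c("group", "band", "channel", "test", "statistic", "p",
                      "p_fdr", "effect", "effect_convention")]
  rownames(table2) <- NULL
  list(table1 = table1, table2 = table2)
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  cat("  behavioral comparisons:", nrow(x$behavioral_stats), "\n")
  cat("  PSD channel tests:", nrow(x$psd_stats), "\n")
  cat("  strength tests:", nrow(x$strength_stats), "\n")
  cat("  NBS contrasts:", length(x$nbs), "\n")
  cat("  topology tests:", nrow(x$topology_stats %||% data.frame()), "\n")
  cat("  regressions:", nrow(x$regressions), "\n")
  invisible(x)
}
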