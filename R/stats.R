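## Cohort statistics: one-tailed paired t tests, Pearson correlations, and
## the cohort report tables (kinetic-parameter table, correlation panels,
## AUC and ISI exports).

#' One-tailed paired t test
#'
#' t statistic on the paired differences `post - pre`; the p value is the
#' upper tail for `direction = "greater"` (post exceeds pre) or the lower
#' tail for `"less"`. Pairs with a missing entry are dropped listwise. A
#' degenerate all-zero difference vector gives `t = 0, p = 0.5`.
#'
#' @param pre,post aligned numeric vectors.
#' @param direction `"greater"` or `"less"`: the alternative for post - pre.
#' @return list with `t`, `p`, `df`, `n`.
#' @export
paired_t_one_tailed <- function(pre, post, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  ok <- !is.na(pre) & !is.na(post)
  d <- post[ok] - pre[ok]
  n <- length(d)
  if (n < 2)
    vldl_error("need >= 2 complete pairs", "vldlkin_validation_error")
  s <- sd(d)
  t <- if (s == 0) {
    if (mean(d) == 0) 0 else sign(mean(d)) * Inf
  } else mean(d) / (s / sqrt(n))
  p <- if (direction == "greater") pt(t, n - 1, lower.tail = FALSE)
       else pt(t, n - 1)
  list(t = t, p = p, df = n - 1, n = n)
}

#' Pearson correlation with a t-based two-sided p value
#'
#' Sample correlation on pairwise-complete observations; p from the exact t
#' transform `t = r sqrt((n-2)/(1-r^2))`. Zero variance in either variable
#' gives `r = NA` (metric undefined).
#'
#' @param x,y aligned numeric vectors (>= 3 complete pairs).
#' @return list with `r`, `p` (two-sided), `n`.
#' @export
pearson <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 3)
    vldl_error("need >= 3 complete pairs", "vldlkin_validation_error")
  if (var(x[ok]) == 0 || var(y[ok]) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n))
  r <- cor(x[ok], y[ok])
  if (abs(r) >= 1) return(list(r = r, p = 0, n = n))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(abs(t), n - 2, lower.tail = FALSE), n = n)
}

# permutation null for the Pearson p value (used as an internal oracle)
pearson_perm_p <- function(x, y, n_perm = 10000, seed = 1) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  r0 <- abs(cor(x, y))
  set.seed(seed)
  hits <- sum(vapply(seq_len(n_perm),
                     function(i) abs(cor(x, sample(y))) >= r0 - 1e-12,
                     logical(1)))
  (hits + 1) / (n_perm + 1)
}

TABLE2_VARS <- c("P_B1", "P_B2d", "P_B2_total", "P_T1", "P_T2d", "P_T2_total",
                 "FCR_B1", "k_FTR_B", "k_FDC_B1", "k_FCR_B2",
                 "FCR_T1", "k_FTR_T", "k_FDC_T1", "k_FCR_T2",
                 "k_CM", "f_abs", "ISI", "pct_direct_B2", "pct_direct_T2",
                 "tg_apob_V1", "tg_apob_V2",
                 "auc_V1B", "auc_V2B", "auc_V1TG", "auc_V2TG", "auc_CMTG",
                 "auc_PlasmaTG", "peak_V1B", "peak_V2B", "peak_V1TG",
                 "peak_V2TG", "peak_CMTG", "peak_PlasmaTG", "homa_ir")

#' Build the cohort report tables
#'
#' Produces the kinetic-parameter table analogue (mean ± SD per condition
#' with a one-tailed paired t test per row), the correlation panels
#' (HOMA-IR against VLDL1 apoB and TG production, per condition and
#' combined; lipolysis ISI against the insulin-normalised clamp indices,
#' post), per-patient postprandial AUC exports, and the paired ISI export.
#'
#' @param summaries data.frame of stacked [derive_kinetics()] /
#'   [true_kinetics()] rows (paired by `patient_id` across conditions).
#' @param clamp_summaries optional stacked [clamp_summary()] rows.
#' @param directions optional named vector (`"greater"`/`"less"`, names =
#'   table variables) giving the one-tailed alternative for post vs pre;
#'   defaults to the direction of the observed cohort mean change.
#' @param out_dir optional directory; when given, writes `table2.csv`,
#'   `correlations.csv`, `fig1_auc.csv`, `fig4_isi.csv`.
#' @param alpha significance threshold (0.05).
#' @return list with `table2`, `correlations`, `fig1_auc`, `fig4_isi`.
#' @export
build_cohort_tables <- function(summaries, clamp_summaries = NULL,
                                directions = NULL, out_dir = NULL,
                                alpha = 0.05) {
  pre <- summaries[summaries$condition == "pre", ]
  post <- summaries[summaries$condition == "post", ]
  common <- intersect(pre$patient_id, post$patient_id)
  unpaired <- setdiff(unique(summaries$patient_id), common)
  if (length(unpaired))
    warning("excluding unpaired patients: ", paste(unpaired, collapse = ", "))
  pre <- pre[match(common, pre$patient_id), ]
  post <- post[match(common, post$patient_id), ]

  rows <- lapply(intersect(TABLE2_VARS, names(summaries)), function(v) {
    a <- pre[[v]]; b <- post[[v]]
    dir <- if (!is.null(directions) && v %in% names(directions))
      directions[[v]]
    else if (mean(b, na.rm = TRUE) >= mean(a, na.rm = TRUE)) "greater"
    else "less"
    tt <- tryCatch(paired_t_one_tailed(a, b, dir),
                   error = function(e) list(t = NA, p = NA, n = 0))
    data.frame(variable = v,
               pre_mean = mean(a, na.rm = TRUE), pre_sd = sd(a, na.rm = TRUE),
               post_mean = mean(b, na.rm = TRUE),
               post_sd = sd(b, na.rm = TRUE),
               mean_pct_change = mean(percent_change(a, b), na.rm = TRUE),
               direction = dir, t = tt$t, p = tt$p,
               significant = !is.na(tt$p) & tt$p < alpha)
  })
  table2 <- do.call(rbind, rows)

  cor_rows <- list()
  add_cor <- function(label, x, y, subset) {
    res <- tryCatch(pearson(x, y), error = function(e)
      list(r = NA_real_, p = NA_real_, n = sum(!is.na(x) & !is.na(y))))
    cor_rows[[length(cor_rows) + 1]] <<-
      data.frame(panel = label, subset = subset, r = res$r, p = res$p,
                 n = res$n)
  }
  both <- rbind(pre, post)
  for (v in c("P_B1", "P_T1")) {
    add_cor(paste0("HOMA_IR_vs_", v), pre$homa_ir, pre[[v]], "pre")
    add_cor(paste0("HOMA_IR_vs_", v), post$homa_ir, post[[v]], "post")
    add_cor(paste0("HOMA_IR_vs_", v), both$homa_ir, both[[v]], "combined")
  }
  fig4 <- NULL
  if (!is.null(clamp_summaries)) {
    cpost <- clamp_summaries[clamp_summaries$condition == "post", ]
    cpost <- cpost[match(common, cpost$patient_id), ]
    for (v in c("lipolysis_suppression_norm", "EGP_suppression_norm",
                "Rd_stimulation_norm"))
      add_cor(paste0("ISI_vs_", v), post$ISI, cpost[[v]], "post")
    fig4 <- data.frame(patient_id = common, ISI_pre = pre$ISI,
                       ISI_post = post$ISI,
                       lipolysis_suppression_norm_post =
                         cpost$lipolysis_suppression_norm,
                       EGP_suppression_norm_post = cpost$EGP_suppression_norm,
                       Rd_stimulation_norm_post = cpost$Rd_stimulation_norm)
  } else {
    fig4 <- data.frame(patient_id = common, ISI_pre = pre$ISI,
                       ISI_post = post$ISI)
  }
  correlations <- do.call(rbind, cor_rows)

  auc_cols <- grep("^auc_", names(summaries), value = TRUE)
  fig1_auc <- summaries[, c("patient_id", "condition", auc_cols)]

  out <- list(table2 = table2, correlations = correlations,
              fig1_auc = fig1_auc, fig4_isi = fig4)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    for (nm in names(out))
      write.csv(out[[nm]], file.path(out_dir, paste0(
        c(table2 = "table2", correlations = "correlations",
          fig1_auc = "fig1_auc", fig4_isi = "fig4_isi")[[nm]], ".csv")),
        row.names = FALSE)
  }
  out
}
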