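#' Assemble a cohort table
#'
#' @param subject_id character vector.
#' @param group factor/character in `{NC, SS, NASH}`.
#' @param fibrosis_grade factor/character in `{F0, F1, F2, F3}`.
#' @param lsn_score numeric, finite.
#' @param observer optional observer id for agreement analyses.
#' @return a validated `cohort_table` data.frame.
#' @export
cohort_table <- function(subject_id, group, fibrosis_grade, lsn_score,
                         observer = NULL) {
  group <- as.character(group)
  fibrosis_grade <- as.character(fibrosis_grade)
  if (!all(group %in% c("NC", "SS", "NASH"))) {
    stop_domain("group labels must be NC, SS or NASH")
  }
  if (!all(fibrosis_grade %in% c("F0", "F1", "F2", "F3"))) {
    stop_domain("fibrosis grades must be F0..F3")
  }
  if (!all(is.finite(lsn_score))) stop_domain("lsn_score must be finite")
  df <- data.frame(subject_id = as.character(subject_id), group = group,
                   fibrosis_grade = fibrosis_grade, lsn_score = lsn_score,
                   stringsAsFactors = FALSE)
  if (!is.null(observer)) df$observer <- as.character(observer)
  class(df) <- c("cohort_table", class(df))
  df
}

#' Read a cohort CSV
#'
#' Expected columns: `subject_id, group, fibrosis_grade, lsn_score`
#' (optional `observer`).
#'
#' @param path CSV path.
#' @return a `cohort_table`.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop_io("cohort file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "fibrosis_grade", "lsn_score")
  if (!all(need %in% names(df))) {
    stop_io("cohort CSV must have columns ", paste(need, collapse = ", "))
  }
  cohort_table(df$subject_id, df$group, df$fibrosis_grade, df$lsn_score,
               observer = df$observer)
}

group_summary <- function(scores) {
  c(n = length(scores), mean = mean(scores), sd = stats::sd(scores),
    cv = if (mean(scores) != 0) stats::sd(scores) / mean(scores) * 100 else 0)
}

# Fibrosis stratum with F2 and F3 merged into one stratum.
fibrosis_stratum <- function(grade) {
  ifelse(grade %in% c("F2", "F3"), "F2&F3", grade)
}

pairwise_label <- c("NC vs SS" = "a", "SS vs NASH" = "b", "NASH vs NC" = "c",
                    "F0 vs F1" = "a", "F1 vs F2&F3" = "b", "F2&F3 vs F0" = "c")

pairwise_tests <- function(values, labels, pairs, holm = FALSE) {
  res <- lapply(pairs, function(pr) {
    a <- values[labels == pr[1]]; b <- values[labels == pr[2]]
    nm <- paste(pr[1], "vs", pr[2])
    if (length(a) < 2 || length(b) < 2) {
      warning("comparison skipped (empty or singleton stratum): ", nm)
      return(NULL)
    }
    mw <- mann_whitney(a, b)
    data.frame(comparison = nm, label = unname(pairwise_label[nm]),
               U = mw$statistic, p_value = mw$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (!is.null(out) && holm) out$p_adjusted <- stats::p.adjust(out$p_value, "holm")
  out
}

#' Cohort-level diagnostic report
#'
#' Reproduces the clinical analysis layout: per-group mean, SD and CV with a
#' Kruskal-Wallis test and labelled pairwise Mann-Whitney comparisons (a:
#' NC vs SS, b: SS vs NASH, c: NASH vs NC); the same by fibrosis stratum with
#' F2 and F3 merged (a: F0 vs F1, b: F1 vs F2&F3, c: F2&F3 vs F0); and ROC
#' analyses for F0 vs F1-F3, F0&F1 vs F2&F3 and F1 vs F2&F3. Pairwise
#' p-values are unadjusted by default (an optional Holm correction can be
#' switched on).
#'
#' @param table a `cohort_table`.
#' @param holm apply a Holm correction to pairwise p-values (default FALSE).
#' @return a `cohort_report` list.
#' @export
cohort_report <- function(table, holm = FALSE) {
  stopifnot(inherits(table, "cohort_table"))
  x <- table$lsn_score
  grp <- table$group
  groups_present <- intersect(c("NC", "SS", "NASH"), unique(grp))
  group_stats <- t(vapply(groups_present, function(g) group_summary(x[grp == g]),
                          numeric(4)))
  kw_groups <- if (length(groups_present) >= 3) {
    kruskal_wallis(split(x, factor(grp, levels = groups_present)))
  } else NULL
  pw_groups <- pairwise_tests(x, grp,
                              list(c("NC", "SS"), c("SS", "NASH"), c("NASH", "NC")),
                              holm = holm)
  fib <- fibrosis_stratum(table$fibrosis_grade)
  fib_present <- intersect(c("F0", "F1", "F2&F3"), unique(fib))
  fib_stats <- t(vapply(fib_present, function(g) group_summary(x[fib == g]),
                        numeric(4)))
  kw_fib <- if (length(fib_present) >= 3) {
    kruskal_wallis(split(x, factor(fib, levels = fib_present)))
  } else NULL
  pw_fib <- pairwise_tests(x, fib,
                           list(c("F0", "F1"), c("F1", "F2&F3"), c("F2&F3", "F0")),
                           holm = holm)
  roc_of <- function(pos_strata) {
    lab <- as.integer(fib %in% pos_strata)
    if (length(unique(lab)) < 2) {
      warning("ROC skipped (single class): ", paste(pos_strata, collapse = "+"))
      return(NULL)
    }
    roc_analysis(x, lab)
  }
  rocs <- list(
    "F0 vs F1-F3" = roc_of(c("F1", "F2&F3")),
    "F0-1 vs F2&F3" = roc_of("F2&F3"),
    "F1 vs F2&F3" = {
      keep <- fib %in% c("F1", "F2&F3")
      if (length(unique(fib[keep])) < 2) NULL
      else roc_analysis(x[keep], as.integer(fib[keep] == "F2&F3"))
    })
  structure(list(group_stats = group_stats, kruskal_groups = kw_groups,
                 pairwise_groups = pw_groups,
                 fibrosis_stats = fib_stats, kruskal_fibrosis = kw_fib,
                 pairwise_fibrosis = pw_fib, roc = rocs, holm = holm),
            class = "cohort_report")
}

fmt1 <- function(x) formatC(x, format = "f", digits = 1)

#' Render a cohort report as Markdown tables
#'
#' ROC rows carry the raw counts in parentheses next to each percentage
#' (e.g. `91.3 (21/23)`).
#'
#' @param report a `cohort_report`.
#' @return character vector of Markdown lines.
#' @export
render_report_markdown <- function(report) {
  stopifnot(inherits(report, "cohort_report"))
  out <- character(0)
  add <- function(...) out <<- c(out, paste0(...))
  stat_table <- function(stats, kw, title) {
    add("## ", title)
    add("")
    add("| Stratum | n | LSN score (mean ± SD) | CV [%] |")
    add("|---|---|---|---|")
    for (g in rownames(stats)) {
      add("| ", g, " | ", stats[g, "n"], " | ", fmt1(stats[g, "mean"]),
          " ± ", fmt1(stats[g, "sd"]), " | ", fmt1(stats[g, "cv"]), " |")
    }
    if (!is.null(kw)) {
      add("")
      add("Kruskal-Wallis H = ", formatC(kw$statistic, format = "f", digits = 3),
          ", p = ", formatC(kw$p_value, format = "g", digits = 3))
    }
    add("")
  }
  stat_table(report$group_stats, report$kruskal_groups, "LSN score by group")
  if (!is.null(report$pairwise_groups)) {
    add("Pairwise Mann-Whitney: ",
        paste(sprintf("%s (%s): p = %.3g", report$pairwise_groups$comparison,
                      report$pairwise_groups$label, report$pairwise_groups$p_value),
              collapse = "; "))
    add("")
  }
  stat_table(report$fibrosis_stats, report$kruskal_fibrosis,
             "LSN score by fibrosis stratum (F2 and F3 merged)")
  if (!is.null(report$pairwise_fibrosis)) {
    add("Pairwise Mann-Whitney: ",
        paste(sprintf("%s (%s): p = %.3g", report$pairwise_fibrosis$comparison,
                      report$pairwise_fibrosis$label, report$pairwise_fibrosis$p_value),
              collapse = "; "))
    add("")
  }
  add("## ROC analysis by fibrosis stratum")
  add("")
  add("| Comparison | Threshold (LSN) | Sensitivity (%) | Specificity (%) | PPV (%) | NPV (%) | AUROC | p-value |")
  add("|---|---|---|---|---|---|---|---|")
  pctn <- function(p, num, den) {
    if (is.na(p)) "-" else paste0(fmt1(p), " (", num, "/", den, ")")
  }
  for (nm in names(report$roc)) {
    rr <- report$roc[[nm]]
    if (is.null(rr)) next
    ct <- rr$counts
    add("| ", nm, " | ", formatC(rr$cutoff, format = "f", digits = 2), " | ",
        pctn(rr$sensitivity, ct["tp"], ct["tp"] + ct["fn"]), " | ",
        pctn(rr$specificity, ct["tn"], ct["tn"] + ct["fp"]), " | ",
        pctn(rr$ppv, ct["tp"], ct["tp"] + ct["fp"]), " | ",
        pctn(rr$npv, ct["tn"], ct["tn"] + ct["fn"]), " | ",
        formatC(rr$auc, format = "f", digits = 3), " | ",
        formatC(rr$p_vs_half, format = "g", digits = 3), " |")
  }
  out
}
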