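#' Classify thrombectomy outcome from the TICI grade
#'
#' TICI 0, 1 and 2a are futile recanalisations; 2b, 2c and 3 are successful.
#'
#' @param tici Character vector of grades in `{"0","1","2a","2b","2c","3"}`.
#' @return Character vector, `"futile"` or `"successful"`.
#' @export
classify_tici <- function(tici) {
  tici <- as.character(tici)
  bad <- !tici %in% c("0", "1", "2a", "2b", "2c", "3") & !is.na(tici)
  if (any(bad))
    stop("classify_tici: unknown TICI grade: ",
         paste(unique(tici[bad]), collapse = ", "), call. = FALSE)
  ifelse(is.na(tici), NA_character_,
         ifelse(tici %in% c("0", "1", "2a"), "futile", "successful"))
}

# "HH:MM" -> minutes past midnight
clock_to_minutes <- function(x) {
  parts <- strsplit(x, ":", fixed = TRUE)
  vapply(parts, function(p) as.numeric(p[1]) * 60 + as.numeric(p[2]),
         numeric(1))
}

#' Presumed last-known-well time for wake-up stroke
#'
#' The LKW clock time is presumed to be the midpoint between going to sleep
#' and waking up, handling the midnight wrap (wake times at or before the
#' sleep time are interpreted as next-day).
#'
#' @param sleep_time,wake_time Clock times as `"HH:MM"` strings; vectorised.
#' @return `"HH:MM"` midpoint clock times.
#' @export
#' @examples
#' lkw_midpoint("22:00", "06:00") # "02:00"
lkw_midpoint <- function(sleep_time, wake_time) {
  s <- clock_to_minutes(sleep_time)
  w <- clock_to_minutes(wake_time)
  if (any(is.na(s) | is.na(w)))
    stop("lkw_midpoint: unparseable clock time", call. = FALSE)
  w <- ifelse(w <= s, w + 1440, w)  # crossed midnight
  minutes_to_clock((s + w) / 2)
}

#' Assign the presentation time window
#'
#' Patients presenting < 360 min from last known well are `<6h`; 360-1440
#' min are `6-24h`; missing times are `unknown` (excluded from windowed
#' strata but counted).
#'
#' @param lkw_to_cta_min Minutes from LKW to CTA; `NA` allowed.
#' @return Character vector in `{"<6h", "6-24h", "unknown"}`.
#' @export
assign_time_window <- function(lkw_to_cta_min) {
  if (any(lkw_to_cta_min < 0, na.rm = TRUE))
    stop("assign_time_window: negative time", call. = FALSE)
  dplyr::case_when(
    is.na(lkw_to_cta_min) ~ "unknown",
    lkw_to_cta_min < 360 ~ "<6h",
    lkw_to_cta_min <= 1440 ~ "6-24h",
    TRUE ~ "unknown"
  )
}

# stratifier group labels for one record table
stratifier_groups <- function(records, stratifier) {
  switch(stratifier,
    all = rep("all", nrow(records)),
    Miteff = as.character(records$miteff),
    HIR = ifelse(is.na(records$hir), NA_character_,
                 ifelse(records$hir < 0.5, "<0.5", ">=0.5")),
    TICI = classify_tici(records$tici),
    stop("unknown stratifier: ", stratifier, call. = FALSE)
  )
}

#' Stratified agreement report
#'
#' The full analysis layer: for every presentation window (`all`, `<6h`,
#' `6-24h`) and stratifier (overall, Miteff grade, HIR dichotomy, TICI
#' outcome), computes per-stratum agreement between the CTA-based estimate
#' and the final infarct volume (Pearson + ICC(2,1) with 95% CIs, OLS), a
#' per-stratifier Kruskal-Wallis comparison of medians for both the
#' estimate and the FIV, and overall Bland-Altman + OLS of the estimate
#' against perfusion core and penumbra volumes. Strata smaller than `min_n`
#' are reported with counts but flagged not-evaluable; records missing the
#' active stratifier are excluded from that stratification only and
#' tallied.
#'
#' @param records Cohort table (one row per patient) with the columns of
#'   [simulate_cohort()].
#' @param min_n Minimum stratum size for statistics; default 4.
#' @return An object of class `stratified_report`: a list with tibbles
#'   `agreement`, `medians`, `fig3`, `counts`, and `n_total`.
#' @export
#' @examples
#' rep <- build_report(simulate_cohort(cohort_params(n_patients = 60)))
#' tidy(rep)
build_report <- function(records, min_n = 4) {
  if (is.null(records) || nrow(records) == 0)
    stop("build_report: empty cohort", call. = FALSE)
  records <- tibble::as_tibble(records)
  records$.window <- assign_time_window(records$lkw_to_cta_min)
  windows <- list(all = rep(TRUE, nrow(records)),
                  `<6h` = records$.window == "<6h",
                  `6-24h` = records$.window == "6-24h")
  stratifiers <- c("all", "Miteff", "HIR", "TICI")

  agreement_rows <- list(); median_rows <- list(); count_rows <- list()
  for (wname in names(windows)) {
    wrec <- records[windows[[wname]], ]
    for (st in stratifiers) {
      grp <- stratifier_groups(wrec, st)
      miss <- sum(is.na(grp))
      count_rows[[length(count_rows) + 1]] <- tibble::tibble(
        window = wname, stratifier = st, n = sum(!is.na(grp)),
        n_missing_stratifier = miss)
      keep <- !is.na(grp)
      srec <- wrec[keep, ]; sgrp <- grp[keep]
      for (g in sort(unique(sgrp))) {
        sub <- srec[sgrp == g, ]
        evaluable <- nrow(sub) >= min_n &&
          stats::sd(sub$cnn_volume_mL) > 0 && stats::sd(sub$fiv_mL) > 0
        row <- tibble::tibble(window = wname, stratifier = st, group = g,
                              n = nrow(sub), evaluable = evaluable)
        if (evaluable) {
          row <- dplyr::bind_cols(
            row, dplyr::select(agreement(sub), -n))
        }
        agreement_rows[[length(agreement_rows) + 1]] <- row

        med_c <- median_iqr(sub$cnn_volume_mL)
        med_f <- median_iqr(sub$fiv_mL)
        median_rows[[length(median_rows) + 1]] <- tibble::tibble(
          window = wname, stratifier = st, group = g, n = nrow(sub),
          cnn_median = med_c$median, cnn_q25 = med_c$q25, cnn_q75 = med_c$q75,
          fiv_median = med_f$median, fiv_q25 = med_f$q25, fiv_q75 = med_f$q75)
      }
      # Kruskal-Wallis across the stratifier's groups (needs >= 2 groups)
      if (st != "all" && length(unique(sgrp)) >= 2 && nrow(srec) >= 3) {
        kw_c <- tryCatch(kruskal_wallis(srec$cnn_volume_mL, sgrp),
                         error = function(e) NULL)
        kw_f <- tryCatch(kruskal_wallis(srec$fiv_mL, sgrp),
                         error = function(e) NULL)
        i <- length(median_rows)
        ng <- length(unique(sgrp))
        for (j in seq_len(ng)) {
          median_rows[[i - ng + j]]$cnn_kw_p <-
            if (is.null(kw_c)) NA_real_ else kw_c$p
          median_rows[[i - ng + j]]$fiv_kw_p <-
            if (is.null(kw_f)) NA_real_ else kw_f$p
        }
      }
    }
  }
  agreement_tbl <- dplyr::bind_rows(agreement_rows)
  medians_tbl <- dplyr::bind_rows(median_rows)

  fig3 <- dplyr::bind_rows(lapply(c(core = "core_mL", penumbra = "penumbra_mL"),
    function(ref) {
      ok <- nrow(records) >= min_n && stats::sd(records[[ref]]) > 0 &&
        stats::sd(records$cnn_volume_mL) > 0
      if (!ok) return(tibble::tibble(reference = ref, evaluable = FALSE))
      ba <- bland_altman(records$cnn_volume_mL, records[[ref]])
      dplyr::bind_cols(
        tibble::tibble(reference = ref, evaluable = TRUE),
        tibble::as_tibble(ba),
        dplyr::select(ols_fit(records[[ref]], records$cnn_volume_mL),
                      slope, intercept),
        dplyr::select(pearson_ci(records[[ref]], records$cnn_volume_mL),
                      r, p))
    }))

  structure(list(agreement = agreement_tbl, medians = medians_tbl,
                 fig3 = fig3, counts = dplyr::bind_rows(count_rows),
                 n_total = nrow(records),
                 n_unknown_lkw = sum(records$.window == "unknown")),
            class = "stratified_report")
}

#' @export
print.stratified_report <- function(x, ...) {
  cat(sprintf("Stratified agreement report: %d patients (%d with unknown LKW)\n",
              x$n_total, x$n_unknown_lkw))
  ev <- x$agreement[x$agreement$evaluable, ]
  cat(sprintf("  %d evaluable strata; overall r = %.2f (n = %d)\n",
              nrow(ev),
              ev$r[ev$window == "all" & ev$stratifier == "all"][1],
              ev$n[ev$window == "all" & ev$stratifier == "all"][1]))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a stratified report into its per-stratum agreement table
#' @param x A `stratified_report`.
#' @param ... Unused.
#' @return The `agreement` tibble.
#' @exportS3Method generics::tidy
tidy.stratified_report <- function(x, ...) x$agreement

#' One-row summary of a stratified report
#' @param x A `stratified_report`.
#' @param ... Unused.
#' @return One-row tibble with overall n, r, ICC and median volumes.
#' @exportS3Method generics::glance
glance.stratified_report <- function(x, ...) {
  ov <- x$agreement[x$agreement$window == "all" & x$agreement$group == "all", ]
  md <- x$medians[x$medians$window == "all" & x$medians$group == "all", ]
  tibble::tibble(n = x$n_total, n_unknown_lkw = x$n_unknown_lkw,
                 r = ov$r[1], icc = ov$icc[1],
                 cnn_median = md$cnn_median[1], fiv_median = md$fiv_median[1])
}

#' Write a stratified report to disk
#'
#' Emits `table2.csv` (per-stratum agreement), `table3.csv` (medians and
#' Kruskal-Wallis P), `figure3_stats.json` (Bland-Altman + OLS against core
#' and penumbra) and `run_log.json` (stratum and missing-value counts).
#'
#' @param report A `stratified_report`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "stratified_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(report$agreement, file.path(dir, "table2.csv"))
  readr::write_csv(report$medians, file.path(dir, "table3.csv"))
  jsonlite::write_json(report$fig3, file.path(dir, "figure3_stats.json"),
                       dataframe = "rows", digits = NA)
  jsonlite::write_json(
    list(n_total = report$n_total, n_unknown_lkw = report$n_unknown_lkw,
         counts = report$counts),
    file.path(dir, "run_log.json"), dataframe = "rows", digits = NA,
    auto_unbox = TRUE)
  invisible(dir)
}
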