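cohort_domains <- list(
  physician_risk = c("low", "high"),
  bos_risk = c("low", "moderate", "high"),
  treatment = c("none", "rt_single", "rt_multiple", "elective_surgery"))

#' Load a femur-level pilot cohort table
#'
#' One record per femur: the physician's initial (binary) fracture-risk
#' estimate, the model-based risk category, the delivered treatment, six-
#' month fracture and vital status, the report delivery interval in working
#' days, and whether the score was used.  Values are validated against their
#' categorical domains; violations are reported with their row number.
#'
#' The packaged fixture `pilot_cohort.csv` encodes the 42-femur pilot cohort
#' with these published marginals; the pairing of femurs to anonymous
#' patient ids, delivery days and death flags within each risk stratum is a
#' synthetic assignment consistent with the published totals.
#'
#' @param path CSV path; defaults to the packaged pilot cohort.
#' @return validated data frame of class `bos_cohort`.
#' @export
load_cohort <- function(path = system.file("extdata", "pilot_cohort.csv",
                                           package = "bosscore")) {
  need <- c("patient_id", "femur_id", "physician_risk", "bos_risk",
            "treatment", "fractured_6mo", "died_6mo", "delivery_days",
            "bos_used")
  df <- utils::read.csv(path, colClasses = "character")
  if (nrow(df) == 0) {
    df <- as.data.frame(setNames(rep(list(character(0)), length(need)), need))
  }
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop("cohort file lacks columns: ", paste(missing_cols, collapse = ", "))
  for (col in names(cohort_domains)) {
    bad <- which(!(df[[col]] %in% cohort_domains[[col]]))
    if (length(bad) > 0)
      stop(sprintf("row %d: invalid %s value '%s'", bad[1], col,
                   df[[col]][bad[1]]))
  }
  for (col in c("fractured_6mo", "died_6mo", "bos_used")) {
    v <- toupper(df[[col]]) %in% c("TRUE", "1", "YES")
    bad <- which(!(toupper(df[[col]]) %in%
                     c("TRUE", "FALSE", "0", "1", "YES", "NO")))
    if (length(bad) > 0)
      stop(sprintf("row %d: invalid %s value '%s'", bad[1], col,
                   df[[col]][bad[1]]))
    df[[col]] <- v
  }
  df$delivery_days <- suppressWarnings(as.integer(df$delivery_days))
  bad <- which(is.na(df$delivery_days) | !(df$delivery_days %in% 0:2))
  if (nrow(df) > 0 && length(bad) > 0)
    stop(sprintf("row %d: delivery_days must be 0, 1 or 2", bad[1]))
  dup <- which(duplicated(df$femur_id))
  if (length(dup) > 0)
    stop(sprintf("row %d: duplicate femur id '%s'", dup[1],
                 df$femur_id[dup[1]]))
  class(df) <- c("bos_cohort", class(df))
  df
}

#' Decision-impact summary of a pilot cohort
#'
#' Tabulates physician-versus-model risk estimates against the delivered
#' treatment and derives the pilot study's headline counts:
#' \itemize{
#'   \item \emph{discrepancy}: the binary physician estimate differs from
#'     the model category; a moderate model category is discrepant with
#'     either physician call.
#'   \item \emph{adapted (probable)}: physician said low, model said moderate
#'     or high, and the delivered treatment escalated to multiple-fraction
#'     radiotherapy or elective surgery.
#'   \item \emph{adapted (possible)}: physician said high but the model said
#'     moderate (treatment intent not inferable).
#' }
#' Percentages are rounded to the nearest integer.  Death percentage is
#' patient-level (a patient with bilateral femurs counts once).
#'
#' @param cohort a `bos_cohort` from [load_cohort()].
#' @return an `audit_summary` list; see Details.
#' @export
summarize_cohort <- function(cohort) {
  n <- nrow(cohort)
  pct <- function(num, den) if (den == 0) NA_real_ else round(100 * num / den)
  phys <- factor(cohort$physician_risk, levels = cohort_domains$physician_risk)
  bosr <- factor(cohort$bos_risk, levels = cohort_domains$bos_risk)
  treat <- factor(cohort$treatment, levels = cohort_domains$treatment)
  crosstab <- table(physician = phys, bos = bosr)
  treatment_tab <- table(physician = phys, bos = bosr, treatment = treat)
  discrepant <- cohort$bos_risk == "moderate" |
    cohort$bos_risk != cohort$physician_risk
  adapted_probable <- cohort$physician_risk == "low" &
    cohort$bos_risk %in% c("moderate", "high") &
    cohort$treatment %in% c("rt_multiple", "elective_surgery")
  adapted_possible <- cohort$physician_risk == "high" &
    cohort$bos_risk == "moderate"
  pat <- cohort[!duplicated(cohort$patient_id), , drop = FALSE]
  delivery <- table(factor(cohort$delivery_days, levels = 0:2))
  structure(list(
    n_femurs = n,
    n_patients = nrow(pat),
    crosstab = crosstab,
    treatment_table = treatment_tab,
    bos_totals = c(high = sum(cohort$bos_risk == "high"),
                   moderate = sum(cohort$bos_risk == "moderate"),
                   low = sum(cohort$bos_risk == "low")),
    discrepancy_count = sum(discrepant),
    adapted_probable = sum(adapted_probable),
    adapted_possible = sum(adapted_possible),
    fracture_count = sum(cohort$fractured_6mo),
    fracture_pct = pct(sum(cohort$fractured_6mo), n),
    death_count = sum(pat$died_6mo),
    death_pct = pct(sum(pat$died_6mo), nrow(pat)),
    delivery_days = as.vector(delivery),
    same_day_pct = pct(sum(cohort$delivery_days == 0), n),
    used_count = sum(cohort$bos_used),
    used_pct = pct(sum(cohort$bos_used), n)),
    class = "audit_summary")
}

#' @export
print.audit_summary <- function(x, ...) {
  cat(sprintf("<audit_summary> %d femurs in %d patients\n", x$n_femurs,
              x$n_patients))
  cat(sprintf("  model risk: %d high / %d moderate / %d low\n",
              x$bos_totals["high"], x$bos_totals["moderate"],
              x$bos_totals["low"]))
  cat(sprintf("  discrepant with physician: %d; treatment adapted: %d probable + %d possible\n",
              x$discrepancy_count, x$adapted_probable, x$adapted_possible))
  cat(sprintf("  fractures: %d (%s%%); deaths: %d patients (%s%%)\n",
              x$fracture_count, x$fracture_pct, x$death_count, x$death_pct))
  cat(sprintf("  delivery days 0/1/2: %s; same-day %s%%; score used %s%%\n",
              paste(x$delivery_days, collapse = "/"), x$same_day_pct,
              x$used_pct))
  invisible(x)
}

#' Write an audit summary as JSON and a Markdown table
#'
#' @param summary an `audit_summary`.
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
write_audit_summary <- function(summary, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  js <- summary
  js$crosstab <- as.data.frame(summary$crosstab)
  js$treatment_table <- as.data.frame(summary$treatment_table)
  class(js) <- NULL
  jsonlite::write_json(js, file.path(out_dir, "audit_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  ct <- as.data.frame(summary$crosstab)
  lines <- c("# Decision-impact audit", "",
             "| physician risk | model risk | n |",
             "|---|---|---|",
             sprintf("| %s | %s | %d |", ct$physician, ct$bos, ct$Freq),
             "",
             sprintf("Discrepant estimates: %d of %d femurs.",
                     summary$discrepancy_count, summary$n_femurs),
             sprintf("Treatment adapted: %d probable, %d possible.",
                     summary$adapted_probable, summary$adapted_possible),
             sprintf("Fractures: %d (%s%%); deaths: %d patients (%s%%).",
                     summary$fracture_count, summary$fracture_pct,
                     summary$death_count, summary$death_pct),
             sprintf("Reports delivered same day: %s%%; score used: %s%%.",
                     summary$same_day_pct, summary$used_pct))
  writeLines(lines, file.path(out_dir, "audit_summary.md"))
  invisible(out_dir)
}
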