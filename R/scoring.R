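#' Patient metadata
#'
#' @param body_weight_kg body weight in kg (> 0).
#' @param age,sex,primary_tumor,pain_score,kps optional clinical fields;
#'   pain on a 0-10 scale, Karnofsky performance score on 0-100.
#' @return object of class `bos_patient`.
#' @export
bos_patient <- function(body_weight_kg, age = NA, sex = NA_character_,
                        primary_tumor = NA_character_, pain_score = NA,
                        kps = NA) {
  if (!is.finite(body_weight_kg) || body_weight_kg <= 0)
    stop("body weight must be positive")
  if (!is.na(pain_score) && (pain_score < 0 || pain_score > 10))
    stop("pain score must lie in [0, 10]")
  if (!is.na(kps) && (kps < 0 || kps > 100))
    stop("KPS must lie in [0, 100]")
  structure(list(body_weight_kg = body_weight_kg, age = age, sex = sex,
                 primary_tumor = primary_tumor, pain_score = pain_score,
                 kps = kps),
            class = "bos_patient")
}

#' Compute the BOS score
#'
#' The Bone Strength score is the simulated femoral strength divided by the
#' patient's body weight expressed as a force: `BOS = F_max / (m * g)`,
#' dimensionless.
#'
#' @param strength_N peak total reaction force from the simulation (N).
#' @param patient a [bos_patient] (or a body weight in kg).
#' @param g_N_per_kg gravitational conversion (default 9.81 N/kg).
#' @return a `bos_score` with fields `value`, `strength_N`, `weight_N`.
#' @export
compute_bos <- function(strength_N, patient, g_N_per_kg = 9.81) {
  if (is.numeric(patient)) patient <- bos_patient(patient)
  if (!is.finite(strength_N) || strength_N <= 0)
    stop("strength must be positive")
  weight_N <- patient$body_weight_kg * g_N_per_kg
  structure(list(value = strength_N / weight_N, strength_N = strength_N,
                 weight_N = weight_N),
            class = "bos_score")
}

#' @export
print.bos_score <- function(x, ...) {
  cat(sprintf("<bos_score> %.2f (strength %.1f N / body weight %.1f N)\n",
              x$value, x$strength_N, x$weight_N))
  invisible(x)
}

#' Classify fracture risk from a BOS score
#'
#' Fixed clinical thresholds: below 7.5 the fracture risk is high, above 8.5
#' it is low, and the closed interval [7.5, 8.5] is moderate.  Scores exactly
#' on a threshold are moderate (closed-interval tie rule; this choice is
#' deliberate and affects classification at the boundaries).
#'
#' @param score a `bos_score` or numeric score value.
#' @param high_cut,moderate_upper risk thresholds (defaults 7.5 and 8.5).
#' @return one of `"high"`, `"moderate"`, `"low"`.
#' @export
classify_risk <- function(score, high_cut = 7.5, moderate_upper = 8.5) {
  v <- if (inherits(score, "bos_score")) score$value else score
  if (!is.finite(v)) stop("invalid score")
  if (v < high_cut) "high" else if (v <= moderate_upper) "moderate" else "low"
}

#' Load a BOS score database
#'
#' CSV with header `bos_score,fractured_6mo`: one row per historical femur,
#' its score and whether it fractured within six months of the scan.
#'
#' @param path CSV path; default is the packaged synthetic database.
#' @return data frame with columns `bos_score` (numeric, > 0) and
#'   `fractured_6mo` (logical).
#' @export
load_score_database <- function(path = system.file("extdata",
                                                   "score_db_synthetic.csv",
                                                   package = "bosscore")) {
  db <- utils::read.csv(path)
  if (!all(c("bos_score", "fractured_6mo") %in% names(db)))
    stop("score database needs columns bos_score, fractured_6mo")
  db$fractured_6mo <- as.logical(db$fractured_6mo)
  if (any(!is.finite(db$bos_score)) || any(db$bos_score <= 0))
    stop("database scores must be positive")
  db
}

#' Predictive statistics of the high-risk call against the database
#'
#' A score below the cut is the positive (high-risk) call.  PPV is the
#' fraction of below-cut femurs that fractured; NPV the fraction of at-or-
#' above-cut femurs that did not.  The percentile of a new score uses
#' mid-rank tie handling: `100 * (#below + 0.5 * #equal) / n`.
#'
#' @param db data frame as returned by [load_score_database()].
#' @param cut decision threshold (default 7.5).
#' @param score optional score whose database percentile is wanted.
#' @return list with `ppv`, `npv`, `sensitivity`, `specificity`, `n`,
#'   `n_below`, `n_above` and (when `score` given) `percentile`.  Empty
#'   strata yield `NA` for the affected statistic.
#' @export
database_stats <- function(db, cut = 7.5, score = NULL) {
  if (nrow(db) == 0) stop("score database is empty")
  pos <- db$bos_score < cut
  frac <- db$fractured_6mo
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  out <- list(
    ppv = safe_div(sum(pos & frac), sum(pos)),
    npv = safe_div(sum(!pos & !frac), sum(!pos)),
    sensitivity = safe_div(sum(pos & frac), sum(frac)),
    specificity = safe_div(sum(!pos & !frac), sum(!frac)),
    n = nrow(db), n_below = sum(pos), n_above = sum(!pos))
  if (!is.null(score)) {
    v <- if (inherits(score, "bos_score")) score$value else score
    out$percentile <- 100 * (sum(db$bos_score < v) +
                               0.5 * sum(db$bos_score == v)) / nrow(db)
  }
  out
}

#' Render the clinical BOS report
#'
#' Writes a machine-readable JSON sidecar and a human-readable Markdown
#' report with the score, risk category, database percentile and predictive
#' values, plus (when a simulation result is supplied) a force-displacement
#' figure and a projection of the weakest location: the elements that had
#' deformed plastically at the moment of maximal total reaction force.
#'
#' @param score a `bos_score`.
#' @param category risk category string from [classify_risk()].
#' @param db optional score database (data frame); `NULL` omits the
#'   percentile/predictive panel with a notice.
#' @param simulation optional `simulation_result`; when missing the figure is
#'   skipped and a warning logged.
#' @param mesh optional `tet_mesh` (for the weakest-location rendering).
#' @param out_dir output directory (created if needed).
#' @param cut high-risk threshold used for the database panel.
#' @return list with the report contents (also written to
#'   `out_dir/report.json` and `out_dir/report.md`), invisibly.
#' @export
render_report <- function(score, category, db = NULL, simulation = NULL,
                          mesh = NULL, out_dir, cut = 7.5) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  caution <- paste("ATTENTION: Fracture localization by experimental",
                   "fracturing in computer model does not necessarily",
                   "coincide with metastatic location")
  rep <- list(bos_score = score$value, strength_N = score$strength_N,
              weight_N = score$weight_N, risk_category = category,
              caution = caution)
  if (!is.null(db) && nrow(db) > 0) {
    st <- database_stats(db, cut = cut, score = score)
    rep$percentile <- st$percentile
    rep$ppv <- st$ppv
    rep$npv <- st$npv
    rep$database_n <- st$n
  } else {
    rep$database_notice <- "score database empty: percentile and predictive values omitted"
  }
  if (is.null(simulation)) {
    warning("no simulation result supplied: report rendered without figure")
  } else {
    rep$plastic_elements_at_peak <- simulation$plastic_elements_at_peak
    grDevices::pdf(file.path(out_dir, "report_figures.pdf"), width = 8,
                   height = 4)
    graphics::par(mfrow = c(1, if (is.null(db)) 1 else 2))
    plot(simulation$curve$displacement_mm, simulation$curve$force_N,
         type = "b", xlab = "applied displacement [mm]",
         ylab = "total reaction force [N]",
         main = sprintf("F_max = %.0f N", simulation$F_max_N))
    if (!is.null(db) && nrow(db) > 0) {
      plot_score_strip(score, db, cut)
    }
    grDevices::dev.off()
    if (!is.null(mesh) && length(simulation$plastic_elements_at_peak) > 0) {
      write_vtk_mesh(mesh, file.path(out_dir, "weakest_location.vtk"),
                     cell_data = list(eq_plastic_strain =
                                        simulation$eqpl_at_peak))
    }
  }
  lines <- c("# Bone strength report", "",
             sprintf("* BOS score: **%.2f**", score$value),
             sprintf("* Femoral strength: %.1f N", score$strength_N),
             sprintf("* Fracture risk: **%s**", category))
  if (!is.null(rep$percentile))
    lines <- c(lines,
               sprintf("* Percentile vs. database (n = %d): %.0f", rep$database_n,
                       rep$percentile),
               sprintf("* PPV %.2f / NPV %.2f at the %.1f threshold",
                       rep$ppv, rep$npv, cut))
  if (!is.null(rep$database_notice))
    lines <- c(lines, paste0("* ", rep$database_notice))
  lines <- c(lines, "", caution)
  writeLines(lines, file.path(out_dir, "report.md"))
  jsonlite::write_json(rep, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(rep)
}

plot_score_strip <- function(score, db, cut) {
  set.seed(0)  # jitter only; cosmetic
  y <- stats::runif(nrow(db), -0.3, 0.3)
  plot(db$bos_score, y, pch = 19, cex = 0.6, yaxt = "n", ylab = "",
       xlab = "BOS score",
       col = ifelse(db$fractured_6mo, "red3", "grey40"),
       main = "score vs. database")
  graphics::abline(v = cut, lty = 2)
  graphics::points(score$value, 0, pch = 23, bg = "dodgerblue", cex = 1.6)
}
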