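# Patient stratification by K-means on miRNA expression and survival
# comparison (log-rank, Kaplan-Meier), built on the survival package.

#' Assemble a survival cohort
#'
#' @param patient Character vector of patient identifiers.
#' @param time Non-negative follow-up times (consistent units).
#' @param event Event indicator: 1 = death/event, 0 = censored.
#' @param mirna_expr Patients x miRNAs numeric expression matrix; row names
#'   must match \code{patient}.
#' @return An object of class \code{SurvivalCohort}.
#' @export
survival_cohort <- function(patient, time, event, mirna_expr) {
  patient <- as.character(patient)
  stopifnot(length(patient) == length(time), length(time) == length(event))
  if (any(time < 0)) stop("follow-up times must be non-negative")
  if (!all(event %in% c(0, 1))) stop("event indicator must be 0 or 1")
  mirna_expr <- as.matrix(mirna_expr)
  if (is.null(rownames(mirna_expr))) rownames(mirna_expr) <- patient
  mirna_expr <- mirna_expr[patient, , drop = FALSE]
  if (anyNA(mirna_expr) || anyNA(time) || anyNA(event))
    stop("cohort contains missing values; filter before construction")
  structure(list(patient = patient, time = as.numeric(time),
                 event = as.integer(event), mirna_expr = mirna_expr),
            class = "SurvivalCohort")
}

#' @export
print.SurvivalCohort <- function(x, ...) {
  cat("SurvivalCohort:", length(x$patient), "patients,",
      ncol(x$mirna_expr), "miRNAs,", sum(x$event), "events\n")
  invisible(x)
}

#' Read a cohort from clinical and expression TSVs
#'
#' @param clinical_path TSV with columns \code{patient}, \code{time},
#'   \code{event}.
#' @param expr_path TSV: first column patient id, remaining columns miRNAs.
#' @return A \code{SurvivalCohort}.
#' @export
read_cohort <- function(clinical_path, expr_path) {
  clin <- utils::read.delim(clinical_path, stringsAsFactors = FALSE)
  expr <- utils::read.delim(expr_path, check.names = FALSE)
  m <- as.matrix(expr[, -1L, drop = FALSE])
  rownames(m) <- expr[[1L]]
  survival_cohort(clin$patient, clin$time, clin$event,
                  m[clin$patient, , drop = FALSE])
}

#' Two-group K-means clustering of patients
#'
#' Euclidean 2-means on the supplied expression submatrix, best of
#' \code{n_restarts} random initialisations by within-cluster sum of
#' squares; deterministic under \code{seed}.
#'
#' @param expr_submatrix Patients x features numeric matrix (>= 2 rows).
#' @param seed Integer seed.
#' @param n_restarts Random restarts (default 10).
#' @return Integer vector of group labels (1/2), named by row.
#' @export
kmeans2 <- function(expr_submatrix, seed = 1L, n_restarts = 10L) {
  x <- as.matrix(expr_submatrix)
  if (nrow(x) < 2L) stop("need at least two patients to cluster")
  if (nrow(unique(x)) < 2L)
    stop("all expression rows are identical; 2-group clustering is degenerate")
  set.seed(seed)
  km <- stats::kmeans(x, centers = 2L, nstart = n_restarts)
  stats::setNames(km$cluster, rownames(x))
}

#' Two-group log-rank test
#'
#' Standard one-degree-of-freedom log-rank chi-square comparing the survival
#' curves of two non-empty groups (observed minus expected events summed over
#' event times, hypergeometric variance).
#'
#' @param time,event Follow-up times and 0/1 event indicators.
#' @param labels Two-level group labels.
#' @return List with \code{statistic} (chi-square), \code{p} and the
#'   per-group observed/expected table; \code{p} is NA with a \code{note}
#'   when no events occurred.
#' @export
logrank_test <- function(time, event, labels) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) != 2L)
    stop("log-rank test requires exactly two non-empty groups")
  if (sum(event) == 0L)
    return(list(statistic = NA_real_, p = NA_real_, table = NULL,
                note = "no events in either group; test undefined"))
  sd <- survival::survdiff(survival::Surv(time, event) ~ labels)
  stat <- sd$chisq
  list(statistic = stat, p = stats::pchisq(stat, df = 1L, lower.tail = FALSE),
       table = cbind(observed = sd$obs, expected = sd$exp), note = NULL)
}

#' Kaplan-Meier product-limit curve
#'
#' @param time,event Follow-up times and 0/1 event indicators.
#' @return Data frame step table (time, n_risk, n_event, survival),
#'   survival starting at 1 and non-increasing.
#' @export
km_curve <- function(time, event) {
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
             survival = sf$surv)
}

#' Survival probability at a given time from a KM step table
#' @param curve Data frame from \code{\link{km_curve}}.
#' @param t Time point.
#' @return Estimated survival S(t).
#' @export
km_at <- function(curve, t) {
  steps <- curve[curve$time <= t & curve$n_event > 0, , drop = FALSE]
  if (nrow(steps) == 0L) return(1)
  steps$survival[nrow(steps)]
}

#' Per-miRNA fold change between prognosis groups
#'
#' Ratio of group mean expression, good over poor.
#'
#' @param expr Patients x miRNAs matrix.
#' @param labels Group labels.
#' @param good_label The label of the good-prognosis group.
#' @return Named numeric vector of fold changes; NA (with a warning) where
#'   the poor-group mean is zero.
#' @export
group_fold_change <- function(expr, labels, good_label) {
  good <- colMeans(expr[labels == good_label, , drop = FALSE])
  poor <- colMeans(expr[labels != good_label, , drop = FALSE])
  fc <- good / poor
  if (any(poor == 0)) {
    warning("zero poor-group mean for: ",
            paste(colnames(expr)[poor == 0], collapse = ", "))
    fc[poor == 0] <- NA_real_
  }
  fc
}

#' Stratify a cohort by miRNA expression and compare survival
#'
#' Clusters the patients into two groups by K-means (K = 2) on the selected
#' miRNAs, labels the group with the higher Kaplan-Meier survival at the last
#' time both groups were under observation as "good" prognosis, and compares
#' the groups with a log-rank test. Expression is log2(x + 1)-transformed and
#' per-miRNA z-scored before clustering unless \code{preprocess = FALSE}
#' (fold changes are always computed on the raw scale).
#'
#' @param cohort A \code{SurvivalCohort}.
#' @param mirnas miRNA column names to cluster on; default all.
#' @param seed Integer seed for K-means.
#' @param n_restarts K-means restarts (default 10).
#' @param preprocess Apply log2(x + 1) + z-score before clustering (default
#'   TRUE).
#' @return An object of class \code{StratificationResult}: list with
#'   \code{groups} (factor "good"/"poor" per patient), \code{logrank}
#'   (statistic, p), \code{km} (named list of step tables), and
#'   \code{fold_change} (good over poor, raw scale).
#' @export
stratify_cohort <- function(cohort, mirnas = NULL, seed = 1L,
                            n_restarts = 10L, preprocess = TRUE) {
  stopifnot(inherits(cohort, "SurvivalCohort"))
  if (is.null(mirnas)) mirnas <- colnames(cohort$mirna_expr)
  missing <- setdiff(mirnas, colnames(cohort$mirna_expr))
  if (length(missing) > 0L)
    stop("miRNAs absent from the cohort: ", paste(missing, collapse = ", "))
  x <- cohort$mirna_expr[, mirnas, drop = FALSE]
  if (preprocess) {
    x <- log2(x + 1)
    sds <- apply(x, 2L, stats::sd)
    keep_scale <- sds > 0
    x[, keep_scale] <- scale(x[, keep_scale, drop = FALSE])
  }
  cl <- kmeans2(x, seed = seed, n_restarts = n_restarts)
  km <- lapply(split(seq_along(cl), cl), function(idx) {
    km_curve(cohort$time[idx], cohort$event[idx])
  })
  # good = higher survival at the last time both groups are still observed
  t_common <- min(vapply(split(cohort$time, cl), max, 0))
  s_at <- vapply(km, km_at, 0, t = t_common)
  good_cluster <- names(s_at)[which.max(s_at)]
  groups <- factor(ifelse(cl == good_cluster, "good", "poor"),
                   levels = c("good", "poor"))
  names(groups) <- names(cl)
  lr <- logrank_test(cohort$time, cohort$event, groups)
  fc <- group_fold_change(cohort$mirna_expr[, mirnas, drop = FALSE],
                          groups, "good")
  structure(list(groups = groups, logrank = lr,
                 km = stats::setNames(km[c(good_cluster,
                                           setdiff(names(km), good_cluster))],
                                      c("good", "poor")),
                 fold_change = fc, mirnas = mirnas, seed = seed),
            class = "StratificationResult")
}

#' @export
print.StratificationResult <- function(x, ...) {
  cat("StratificationResult:", sum(x$groups == "good"), "good /",
      sum(x$groups == "poor"), "poor prognosis patients\n")
  if (!is.null(x$logrank$note)) cat("  log-rank:", x$logrank$note, "\n")
  else cat(sprintf("  log-rank chi-square %.3f, p = %.4g\n",
                   x$logrank$statistic, x$logrank$p))
  invisible(x)
}

#' Write Kaplan-Meier step tables as TSV
#'
#' @param result A \code{StratificationResult}.
#' @param path Output path (columns group, time, n_risk, n_event, survival).
#' @export
write_km_tables <- function(result, path) {
  rows <- do.call(rbind, lapply(names(result$km), function(g) {
    cbind(data.frame(group = g, stringsAsFactors = FALSE), result$km[[g]])
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
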