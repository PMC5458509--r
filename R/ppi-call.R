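#' Score protein-protein interactions against reporter-free controls
#'
#' Aggregates used lineage fitness estimates to the genotype-pair level
#' within each environment (condition x methotrexate) - about 75 estimates
#' per pair at the default design (25 barcode pairs x 3 replicates) - and
#' tests each pair's fitness sample against the pooled control sample with a
#' one-sided (greater) t-test, Bonferroni-corrected by multiplying by
#' `n_tests` (500 by convention for this assay, the correction applied in
#' the published score tables regardless of the number of rows actually
#' tested).
#'
#' @param fit a `ppiseq_fit`, or its `estimates` data.frame.
#' @param n_tests Bonferroni multiplier (default 500).
#' @param alpha significance level on the corrected p-value (default 0.05).
#' @param var_equal use the pooled-variance t-test instead of Welch
#'   (default `FALSE`: Welch, the safe choice for unequal group sizes).
#' @param blacklist `PPI_pair` values to exclude (e.g. pairs suspected of
#'   carrying adaptive mutations).
#' @return data.frame of class `ppi_scores`: one row per genotype pair per
#'   environment with `mean_fitness`, `sem`, `n`, `p_value`, `p_corrected`,
#'   `significant` and `test_skipped`.
#' @export
score_ppis <- function(fit, n_tests = 500, alpha = 0.05, var_equal = FALSE,
                       blacklist = NULL) {
  e <- if (inherits(fit, "ppiseq_fit")) fit$estimates else fit
  stopifnot(all(c("PPI_pair", "fitness", "used", "is_control") %in% names(e)))
  e <- e[e$used & !is.na(e$fitness), , drop = FALSE]
  if (!is.null(blacklist)) e <- e[!(e$PPI_pair %in% blacklist), , drop = FALSE]
  env <- interaction(e$Condition, e$Methotrexate_selection, drop = TRUE,
                     sep = "|")
  out <- list()
  for (v in levels(env)) {
    i <- env == v
    ctrl <- e$fitness[i & e$is_control]
    if (length(ctrl) == 0) stop("no usable control estimates in ", v)
    for (pp in unique(e$PPI_pair[i & !e$is_control])) {
      x <- e$fitness[i & e$PPI_pair == pp]
      row <- data.frame(
        PPI_pair = pp,
        Bait = e$Bait[i & e$PPI_pair == pp][1] %||% sub(":.*", "", pp),
        Prey = e$Prey[i & e$PPI_pair == pp][1] %||% sub(".*:", "", pp),
        Condition = e$Condition[i][1],
        Methotrexate_selection = e$Methotrexate_selection[i][1],
        mean_fitness = mean(x),
        sem = stats::sd(x) / sqrt(length(x)),
        n = length(x),
        p_value = NA_real_, p_corrected = NA_real_,
        significant = FALSE,
        test_skipped = "", stringsAsFactors = FALSE)
      if (length(x) < 2 || length(ctrl) < 2) {
        row$test_skipped <- "fewer than 2 estimates in a group"
      } else {
        p <- stats::t.test(x, ctrl, alternative = "greater",
                           var.equal = var_equal)$p.value
        row$p_value <- p
        row$p_corrected <- min(1, p * n_tests)
        row$significant <- row$p_corrected < alpha
      }
      out[[paste(v, pp)]] <- row
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$Condition, res$Methotrexate_selection,
                   -res$mean_fitness), ]
  rownames(res) <- NULL
  class(res) <- c("ppi_scores", "data.frame")
  res
}

#' Detect environment-dependent (dynamic) interactions
#'
#' Compares each genotype pair's fitness sample in every non-reference
#' environment against the same pair in the reference (permissive)
#' environment with a two-sided t-test, Bonferroni-corrected by `n_tests`
#' (400 by convention for this assay).
#'
#' @param fit a `ppiseq_fit` or estimates data.frame (as in [score_ppis()]).
#' @param reference_condition the permissive condition (default `"DMSO"`);
#'   only methotrexate-selected pools are compared.
#' @param n_tests Bonferroni multiplier (default 400).
#' @param alpha significance level (default 0.05).
#' @param var_equal pooled-variance t-test instead of Welch.
#' @return data.frame of class `dynamic_calls`: one row per pair per
#'   non-reference environment with `delta_fitness`, `p_value`,
#'   `p_corrected`, `significant` and `direction` (`"gain"`/`"loss"`).
#' @export
detect_dynamic <- function(fit, reference_condition = "DMSO", n_tests = 400,
                           alpha = 0.05, var_equal = FALSE) {
  e <- if (inherits(fit, "ppiseq_fit")) fit$estimates else fit
  e <- e[e$used & !is.na(e$fitness) & e$Methotrexate_selection &
           !e$is_control, , drop = FALSE]
  if (!reference_condition %in% e$Condition)
    stop("reference condition ", reference_condition, " absent from estimates")
  out <- list()
  for (pp in unique(e$PPI_pair)) {
    ref <- e$fitness[e$PPI_pair == pp & e$Condition == reference_condition]
    for (cond in setdiff(unique(e$Condition), reference_condition)) {
      x <- e$fitness[e$PPI_pair == pp & e$Condition == cond]
      if (length(x) < 2 || length(ref) < 2) next
      p <- stats::t.test(x, ref, alternative = "two.sided",
                         var.equal = var_equal)$p.value
      d <- mean(x) - mean(ref)
      out[[paste(pp, cond)]] <- data.frame(
        PPI_pair = pp, Condition = cond,
        reference = reference_condition,
        mean_fitness = mean(x), reference_fitness = mean(ref),
        delta_fitness = d,
        p_value = p, p_corrected = min(1, p * n_tests),
        significant = min(1, p * n_tests) < alpha,
        direction = if (d >= 0) "gain" else "loss",
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    res <- data.frame(PPI_pair = character(0), Condition = character(0),
                      reference = character(0), mean_fitness = numeric(0),
                      reference_fitness = numeric(0),
                      delta_fitness = numeric(0), p_value = numeric(0),
                      p_corrected = numeric(0), significant = logical(0),
                      direction = character(0), stringsAsFactors = FALSE)
  } else {
    res <- do.call(rbind, out)
    rownames(res) <- NULL
  }
  class(res) <- c("dynamic_calls", "data.frame")
  res
}

#' Summarize dynamic behaviour of the detected interaction set
#'
#' "Detected" interactions are those significant against the control in at
#' least one environment of the score table. The summary reports what
#' fraction of those change significantly in at least one perturbation
#' relative to the reference, and what fraction are undetectable (not
#' significant against the control) in at least one environment.
#'
#' @param scores output of [score_ppis()] across environments.
#' @param dynamic output of [detect_dynamic()].
#' @return List with the detected set, counts and the two fractions.
#' @export
summarize_dynamic <- function(scores, dynamic) {
  sc <- scores[scores$Methotrexate_selection, , drop = FALSE]
  detected <- unique(sc$PPI_pair[sc$significant])
  changed <- intersect(detected,
                       unique(dynamic$PPI_pair[dynamic$significant]))
  undetectable <- vapply(detected, function(pp) {
    any(!sc$significant[sc$PPI_pair == pp])
  }, logical(1))
  list(detected = detected,
       n_detected = length(detected),
       n_changed = length(changed),
       frac_changed = if (length(detected)) length(changed) / length(detected)
                      else NA_real_,
       n_undetectable = sum(undetectable),
       frac_undetectable = if (length(detected)) mean(undetectable)
                           else NA_real_)
}

#' Relative fitness from isolated-growth optical density curves
#'
#' The area under an OD time course is the sum of readings before the
#' saturation time; a strain's relative fitness in a condition is
#'
#'   (AUC_target - AUC_control)_condition / (AUC_target - AUC_control)_DMSO
#'
#' @param od data.frame with columns `strain`, `condition`, `time`, `od`
#'   (replicate readings are summed into the AUC together).
#' @param control_strain name of the reference strain, measured in every
#'   condition.
#' @param reference_condition denominator condition (default `"DMSO"`).
#' @param saturation_time readings at or after this time are excluded
#'   (default 32 h).
#' @return data.frame with `strain`, `condition`, `auc_diff`,
#'   `relative_fitness` and `undefined` (flagged `TRUE` when the reference
#'   denominator is not positive).
#' @export
od_auc_relative_fitness <- function(od, control_strain,
                                    reference_condition = "DMSO",
                                    saturation_time = 32) {
  stopifnot(all(c("strain", "condition", "time", "od") %in% names(od)))
  if (!control_strain %in% od$strain)
    stop("control strain ", control_strain, " absent from OD table")
  od <- od[od$time < saturation_time, , drop = FALSE]
  auc <- stats::aggregate(od ~ strain + condition, data = od, FUN = sum)
  ctrl <- auc[auc$strain == control_strain, ]
  targets <- auc[auc$strain != control_strain, ]
  targets$auc_diff <- targets$od -
    ctrl$od[match(targets$condition, ctrl$condition)]
  denom <- targets$auc_diff[match(paste(targets$strain, reference_condition),
                                  paste(targets$strain, targets$condition))]
  targets$relative_fitness <- ifelse(denom > 0, targets$auc_diff / denom,
                                     NA_real_)
  targets$undefined <- !(denom > 0) | is.na(denom)
  res <- targets[, c("strain", "condition", "auc_diff", "relative_fitness",
                     "undefined")]
  rownames(res) <- NULL
  res
}

#' Luminescence response ratio of a luciferase complementation assay
#'
#' The interaction response to a perturbation is the ratio of luminescence
#' in the condition over luminescence in the DMSO reference; the log2 ratio
#' is reported alongside for plotting.
#'
#' @param lum_condition,lum_dmso positive luminescence readings (vectors
#'   recycle).
#' @return data.frame with `ratio` and `log2_ratio`.
#' @export
rluc_response <- function(lum_condition, lum_dmso) {
  if (any(lum_condition <= 0) || any(lum_dmso <= 0))
    stop("luminescence readings must be positive")
  r <- lum_condition / lum_dmso
  data.frame(ratio = r, log2_ratio = log2(r))
}
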