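#' @export
print.ppiseq_fit <- function(x, ...) {
  e <- x$estimates
  np <- nrow(unique(e[, c("Condition", "Methotrexate_selection", "Replicate")]))
  cat("Pooled-growth Poisson ML fitness fit\n")
  cat(sprintf("  %d lineages in %d pool(s); generations %s\n",
              nrow(e) / np, np, paste(x$generations, collapse = ",")))
  cat(sprintf("  used trajectories: %d / %d (likelihood threshold %.3g)\n",
              sum(e$used), nrow(e), x$likelihood_threshold))
  fr <- range(e$fitness[e$used], na.rm = TRUE)
  cat(sprintf("  fitness range (used): %.3f .. %.3f per generation\n",
              fr[1], fr[2]))
  invisible(x)
}

#' @export
summary.ppiseq_fit <- function(object, ...) {
  e <- object$estimates
  pool <- interaction(e$Condition, e$Methotrexate_selection, e$Replicate,
                      drop = TRUE, sep = " | ")
  tab <- do.call(rbind, lapply(levels(pool), function(p) {
    i <- pool == p
    data.frame(pool = p,
               lineages = sum(i),
               used = sum(e$used[i]),
               median_se = stats::median(e$se[i], na.rm = TRUE),
               fitness_range = paste0(
                 sprintf("%.3f", min(e$fitness[i & e$used], na.rm = TRUE)), " .. ",
                 sprintf("%.3f", max(e$fitness[i & e$used], na.rm = TRUE))),
               stringsAsFactors = FALSE)
  }))
  structure(list(pools = tab, threshold = object$likelihood_threshold,
                 generations = object$generations,
                 meanfit = object$meanfit,
                 reference_shift = object$reference_shift),
            class = "summary.ppiseq_fit")
}

#' @export
print.summary.ppiseq_fit <- function(x, ...) {
  cat("Pooled-growth Poisson ML fitness fit\n")
  cat("  generations:", paste(x$generations, collapse = ", "), "\n")
  cat("  likelihood threshold (used flag):", x$threshold, "\n")
  if (!is.null(x$reference_shift))
    cat("  control-zeroing shifts:",
        paste(sprintf("%.4f", x$reference_shift), collapse = ", "), "\n")
  print(x$pools, row.names = FALSE)
  invisible(x)
}

#' Extract per-lineage fitness estimates
#'
#' @param object a `ppiseq_fit`.
#' @param used_only drop lineages flagged `used = FALSE`.
#' @param ... unused.
#' @return Named numeric vector of relative fitnesses (per generation),
#'   named by `barcode_pair`.
#' @export
coef.ppiseq_fit <- function(object, used_only = FALSE, ...) {
  e <- object$estimates
  if (used_only) e <- e[e$used, , drop = FALSE]
  stats::setNames(e$fitness, e$barcode_pair)
}

# expected read counts under the fitted model, one matrix per pool
.fitted_mu <- function(object) {
  e <- object$estimates
  gens <- object$generations
  pool <- interaction(e$Condition, e$Methotrexate_selection, e$Replicate,
                      drop = TRUE, sep = "|")
  mf_pool <- interaction(object$meanfit$Condition,
                         object$meanfit$Methotrexate_selection,
                         object$meanfit$Replicate, drop = TRUE, sep = "|")
  out <- list()
  for (p in levels(pool)) {
    i <- pool == p
    xbar <- object$meanfit$xbar[mf_pool == p]
    D <- object$depths[[p]]
    shift <- 0
    if (!is.null(object$reference_shift) &&
        p %in% names(object$reference_shift))
      shift <- object$reference_shift[[p]]
    s_raw <- e$fitness[i] + shift
    mu <- outer(e$f0[i], rep(1, length(gens))) *
      exp(outer(s_raw, gens) - matrix(xbar, sum(i), length(gens), byrow = TRUE)) *
      matrix(D, sum(i), length(gens), byrow = TRUE)
    dimnames(mu) <- list(e$barcode_pair[i], gens)
    out[[p]] <- mu
  }
  out
}

#' @export
fitted.ppiseq_fit <- function(object, ...) {
  .fitted_mu(object)
}

#' Pearson residuals of the Poisson trajectory fit
#'
#' `(R - mu) / sqrt(mu)` per lineage and time point, one matrix per pool.
#'
#' @param object a `ppiseq_fit`.
#' @param ... unused.
#' @return List of matrices (lineage x generation), one per pool.
#' @export
residuals.ppiseq_fit <- function(object, ...) {
  mu <- .fitted_mu(object)
  e <- object$estimates
  pool <- interaction(e$Condition, e$Methotrexate_selection, e$Replicate,
                      drop = TRUE, sep = "|")
  dpool <- interaction(object$data$Condition,
                       object$data$Methotrexate_selection,
                       object$data$Replicate, drop = TRUE, sep = "|")
  out <- list()
  for (p in levels(pool)) {
    R <- as.matrix(object$data[dpool == p, object$reads_cols, drop = FALSE])
    storage.mode(R) <- "double"
    out[[p]] <- (R - mu[[p]]) / sqrt(pmax(mu[[p]], 1e-300))
  }
  out
}

#' Simulate read counts from a fitted pool model
#'
#' Draws Poisson counts at the fitted expected reads, one replicate data set
#' per `nsim`. Useful for parametric-bootstrap checks of the trajectory fit.
#'
#' @param object a `ppiseq_fit`.
#' @param nsim number of simulated data sets.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return List of length `nsim`; each element is a list of count matrices
#'   parallel to [fitted.ppiseq_fit()].
#' @export
simulate.ppiseq_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- .fitted_mu(object)
  replicate(nsim, lapply(mu, function(m) {
    out <- matrix(stats::rpois(length(m), m), nrow(m), ncol(m),
                  dimnames = dimnames(m))
    out
  }), simplify = FALSE)
}

#' Plot fitted lineage trajectories and the mean-fitness curve
#'
#' Left panel: observed read frequencies over generations (log scale), one
#' line per lineage, coloured by inferred fitness. Right panel: the pool's
#' cumulative mean-fitness curve.
#'
#' @param x a `ppiseq_fit`.
#' @param pool which pool to draw (index into the fitted pools, default 1).
#' @param max_lineages cap on the number of lineages drawn.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.ppiseq_fit <- function(x, pool = 1, max_lineages = 500, ...) {
  e <- x$estimates
  pf <- interaction(e$Condition, e$Methotrexate_selection, e$Replicate,
                    drop = TRUE, sep = "|")
  p <- levels(pf)[pool]
  dpool <- interaction(x$data$Condition, x$data$Methotrexate_selection,
                       x$data$Replicate, drop = TRUE, sep = "|")
  R <- as.matrix(x$data[dpool == p, x$reads_cols, drop = FALSE])
  D <- x$depths[[p]]
  freq <- sweep(R, 2, pmax(D, 1), "/")
  i <- seq_len(min(nrow(freq), max_lineages))
  s <- e$fitness[pf == p][i]
  cols <- grDevices::hcl.colors(32, "viridis")[
    pmin(31, pmax(0, round(30 * (s - min(s, na.rm = TRUE)) /
      max(diff(range(s, na.rm = TRUE)), 1e-9)))) + 1]
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::matplot(x$generations, t(pmax(freq[i, , drop = FALSE], 1e-7)),
                    type = "l", lty = 1, log = "y", col = cols,
                    xlab = "generation", ylab = "barcode frequency",
                    main = p, ...)
  mfp <- interaction(x$meanfit$Condition, x$meanfit$Methotrexate_selection,
                     x$meanfit$Replicate, drop = TRUE, sep = "|")
  graphics::plot(x$meanfit$generation[mfp == p], x$meanfit$xbar[mfp == p],
                 type = "b", xlab = "generation",
                 ylab = expression(bar(x)(t)), main = "mean fitness integral")
  invisible(x)
}
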