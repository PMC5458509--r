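#' Fit per-lineage relative fitness by global Poisson maximum likelihood
#'
#' The central model of the package. Each double-barcode lineage l in a
#' pooled serial-dilution competition is described by an initial frequency
#' `f_l` and a per-generation relative fitness `s_l`; its expected frequency
#' at generation t is
#'
#'   phi_l(t) = f_l * exp(s_l * t - xbar(t))
#'
#' where `xbar(t)` is the cumulative mean-fitness integral of the pool, the
#' normalization that makes high-fitness trajectories "bend" as competition
#' stiffens. Observed reads `R_{l,t}` at sequencing depth `D_t` are modelled
#' as Poisson with mean `D_t * phi_l(t)`, and `(f_l, s_l)` are obtained by
#' maximizing the per-lineage Poisson log-likelihood with `f_l` profiled out
#' (it has a closed form given `s_l`). Global self-consistency - the
#' frequencies must sum to one at every time point - is imposed by a
#' fixed-point update of `xbar` alternating with the per-lineage fits, until
#' `max |delta xbar| < tol`.
#'
#' Fitness is reported relative to reporter-free control lineages, whose
#' mean fitness is set exactly to zero (see [normalize_to_reference()]).
#' Each trajectory carries a goodness-of-fit score: the mean per-time-point
#' log-likelihood of the fitted model minus that of the saturated model
#' (0 = perfect fit, more negative = worse); trajectories below
#' `likelihood_threshold` are flagged `used = FALSE` and excluded from
#' control zeroing and downstream scoring (see [flag_trajectories()]).
#'
#' Tables with several growth cultures (condition x methotrexate x
#' replicate) are fitted pool by pool, each with its own mean-fitness curve.
#'
#' @param data trajectory data.frame (see [as_trajectory_table()]) with
#'   `Reads_<g>_generations` columns, or a bare count matrix (lineages x
#'   time points) accompanied by `generations`.
#' @param generations integer vector of generation numbers; by default taken
#'   from the column names.
#' @param corrected use the `_corrected` read columns (default `TRUE` when
#'   present).
#' @param controls logical vector marking control lineages, or a character
#'   vector of `PPI_pair` / `barcode_pair` values; by default rows whose
#'   `Bait` and `Prey` are both `"control"`.
#' @param likelihood_threshold normalized log-likelihood below which a
#'   trajectory is not used (default -1.5; calibrated on the experiment-scale
#'   simulation so that well under 5\% of well-behaved trajectories are
#'   flagged).
#' @param s_bounds box for the fitness parameter, per generation.
#' @param tol convergence tolerance for the mean-fitness fixed point.
#' @param max_iter cap on fixed-point iterations.
#' @return An object of class `ppiseq_fit`; see Details. Its `estimates`
#'   component has one row per lineage per pool with columns `fitness`, `f0`,
#'   `log_likelihood` (normalized), `se`, `used`, `converged`.
#' @seealso [coef.ppiseq_fit()], [summary.ppiseq_fit()], [plot.ppiseq_fit()],
#'   [simulate.ppiseq_fit()], [score_ppis()]
#' @export
#' @examples
#' sim <- simulate_pool(sim_config(n_bait = 4, n_prey = 4,
#'                                 barcodes_per_genotype = 4,
#'                                 read_depth = 3000, seed = 1))
#' traj <- correct_counts(as_trajectory_table(sim), rate = sim$config$chimera_rate)
#' fit <- fit_pool_fitness(traj)
#' fit
#' head(coef(fit))
fit_pool_fitness <- function(data, generations = NULL, corrected = NULL,
                             controls = NULL, likelihood_threshold = -1.5,
                             s_bounds = c(-2, 2), tol = 1e-4, max_iter = 100) {
  cl <- match.call()
  if (is.matrix(data)) {
    if (is.null(generations))
      stop("matrix input needs explicit `generations`")
    df <- data.frame(barcode_pair = rownames(data) %||%
                       sprintf("L%04d", seq_len(nrow(data))))
    df$PPI_pair <- df$barcode_pair
    for (i in seq_along(generations))
      df[[sprintf("Reads_%d_generations", generations[i])]] <- data[, i]
    df$Condition <- "pool"; df$Methotrexate_selection <- TRUE; df$Replicate <- 1L
    data <- df
    corrected <- FALSE
  }
  has_corr <- length(reads_columns(data, corrected = TRUE)) > 0
  if (is.null(corrected)) corrected <- has_corr
  if (corrected && !has_corr)
    stop("no corrected read columns; run correct_counts() or set corrected = FALSE")
  cols <- reads_columns(data, corrected = corrected)
  gens <- as.integer(names(cols))
  if (!is.null(generations)) {
    keep <- gens %in% generations
    cols <- cols[keep]; gens <- gens[keep]
  }
  if (length(gens) < 2) stop("need at least two time points")

  is_ctrl <- .resolve_controls(data, controls)

  pool <- interaction(data$Condition, data$Methotrexate_selection,
                      data$Replicate, drop = TRUE, sep = "|")
  est_list <- list(); mf_list <- list(); depth_list <- list()
  for (p in levels(pool)) {
    i <- which(pool == p)
    R <- as.matrix(data[i, cols, drop = FALSE])
    storage.mode(R) <- "double"
    fit <- .fit_one_pool(R, gens, s_bounds = s_bounds, tol = tol,
                         max_iter = max_iter)
    est <- data.frame(
      Condition = data$Condition[i][1],
      Methotrexate_selection = data$Methotrexate_selection[i][1],
      Replicate = data$Replicate[i][1],
      PPI_pair = data$PPI_pair[i],
      barcode_pair = data$barcode_pair[i],
      is_control = is_ctrl[i],
      fitness = fit$s, f0 = fit$f, log_likelihood = fit$ll_norm,
      se = fit$se, converged = fit$converged,
      stringsAsFactors = FALSE)
    est_list[[p]] <- est
    mf_list[[p]] <- data.frame(
      Condition = est$Condition[1],
      Methotrexate_selection = est$Methotrexate_selection[1],
      Replicate = est$Replicate[1],
      generation = gens, xbar = fit$xbar,
      iterations = fit$iterations, converged = fit$pool_converged)
    depth_list[[p]] <- fit$depths
  }
  estimates <- do.call(rbind, est_list)
  rownames(estimates) <- NULL
  res <- structure(list(
    estimates = estimates,
    meanfit = do.call(rbind, mf_list),
    generations = gens,
    depths = depth_list,
    data = data, reads_cols = cols,
    likelihood_threshold = likelihood_threshold,
    s_bounds = s_bounds, call = cl), class = "ppiseq_fit")
  res <- flag_trajectories(res, likelihood_threshold)
  if (any(is_ctrl)) res <- normalize_to_reference(res)
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.resolve_controls <- function(data, controls) {
  if (is.null(controls)) {
    if (all(c("Bait", "Prey") %in% names(data)))
      return(data$Bait == "control" & data$Prey == "control")
    return(rep(FALSE, nrow(data)))
  }
  if (is.logical(controls)) {
    stopifnot(length(controls) == nrow(data))
    return(controls)
  }
  data$PPI_pair %in% controls | data$barcode_pair %in% controls
}

# Core estimator for one pool: R is lineages x time points, t in generations.
# Profile-likelihood Newton in s (f profiled out in closed form), alternated
# with the mean-fitness fixed point. All lineages updated vectorized.
.fit_one_pool <- function(R, t, s_bounds = c(-2, 2), tol = 1e-4,
                          max_iter = 100) {
  L <- nrow(R); T <- length(t)
  D <- colSums(R)
  informative <- D > 0
  if (sum(informative) < 2) stop("need at least two time points with reads")
  tm <- matrix(t, L, T, byrow = TRUE)
  tot <- rowSums(R)
  dead <- tot == 0          # never seen: no information at all

  # initial values: f from t0 (pseudo-count 1/2), s from end-to-start slope
  i1 <- which(informative)[1]; i2 <- rev(which(informative))[1]
  f <- (R[, i1] + 0.5 * (R[, i1] == 0)) / D[i1]
  s <- (log((R[, i2] + 0.5) / D[i2]) - log((R[, i1] + 0.5) / D[i1])) /
    (t[i2] - t[i1])
  s <- pmin(pmax(s, s_bounds[1]), s_bounds[2])
  xbar <- numeric(T)

  mu_of <- function(f, s, xbar) {
    w <- exp(tm * s - matrix(xbar, L, T, byrow = TRUE)) *
      matrix(D, L, T, byrow = TRUE)
    f * w
  }

  pool_converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    # per-lineage profile Newton in s
    for (inner in 1:60) {
      w <- exp(tm * s - matrix(xbar, L, T, byrow = TRUE)) *
        matrix(D, L, T, byrow = TRUE)
      f <- ifelse(dead, 0.5 / sum(D), tot / rowSums(w))
      mu <- f * w
      score <- rowSums((R - mu) * tm)
      i11 <- rowSums(mu); i12 <- rowSums(mu * tm); i22 <- rowSums(mu * tm^2)
      info <- pmax(i22 - i12^2 / pmax(i11, 1e-300), 1e-12)
      step <- score / info
      step[dead] <- 0
      step <- pmin(pmax(step, -0.5), 0.5)   # damped
      s_new <- pmin(pmax(s + step, s_bounds[1]), s_bounds[2])
      moved <- max(abs(s_new - s))
      s <- s_new
      if (moved < 1e-9) break
    }
    # mean-fitness fixed point: force sum_l phi_l(t) = 1
    phi_tot <- colSums(mu) / D
    phi_tot[!informative] <- 1
    xbar_new <- xbar + log(phi_tot)
    xbar_new <- xbar_new - xbar_new[1]   # gauge: xbar(0) = 0
    delta <- max(abs(xbar_new - xbar))
    xbar <- xbar_new
    if (delta < tol) { pool_converged <- TRUE; break }
  }

  w <- exp(tm * s - matrix(xbar, L, T, byrow = TRUE)) *
    matrix(D, L, T, byrow = TRUE)
  f <- ifelse(dead, 0.5 / sum(D), tot / rowSums(w))
  mu <- f * w
  # likelihood of fit minus saturated model, mean per time point
  ll_fit <- rowSums(R * log(pmax(mu, 1e-300)) - mu - lgamma(R + 1))
  ll_sat <- rowSums(ifelse(R > 0, R * log(R) - R, 0) - lgamma(R + 1))
  ll_norm <- (ll_fit - ll_sat) / sum(informative)
  i11 <- rowSums(mu); i12 <- rowSums(mu * tm); i22 <- rowSums(mu * tm^2)
  se <- sqrt(1 / pmax(i22 - i12^2 / pmax(i11, 1e-300), 1e-12))
  conv <- rep(pool_converged, L)
  at_bound <- !dead & (s <= s_bounds[1] + 1e-9 | s >= s_bounds[2] - 1e-9)
  s[dead] <- NA_real_; se[dead] <- NA_real_; ll_norm[dead] <- NA_real_
  list(s = s, f = f, ll_norm = ll_norm, se = se,
       converged = conv & !at_bound | dead,
       xbar = xbar, iterations = iter, pool_converged = pool_converged,
       depths = D, mu = mu)
}

#' Zero fitness on the reporter-free control lineages
#'
#' Shifts every fitness in each pool by minus the mean fitness of the used
#' control lineages of that pool, so the control mean is exactly zero and
#' fitnesses are comparable across replicates, pools and environments.
#'
#' @param fit a `ppiseq_fit` object.
#' @param control_ids optional `PPI_pair`/`barcode_pair` values naming the
#'   reference lineages; defaults to the fit's `is_control` flags.
#' @return The fit with shifted `fitness` values (and the applied shift per
#'   pool recorded in `reference_shift`).
#' @export
normalize_to_reference <- function(fit, control_ids = NULL) {
  stopifnot(inherits(fit, "ppiseq_fit"))
  e <- fit$estimates
  ctrl <- if (is.null(control_ids)) e$is_control
          else e$PPI_pair %in% control_ids | e$barcode_pair %in% control_ids
  pool <- interaction(e$Condition, e$Methotrexate_selection, e$Replicate,
                      drop = TRUE, sep = "|")
  shifts <- numeric(0)
  for (p in levels(pool)) {
    i <- pool == p
    ref <- ctrl & i & e$used & !is.na(e$fitness)
    if (!any(ref))
      stop("no usable control lineage in pool ", p,
           "; pass control_ids= to choose a reference explicitly")
    sh <- mean(e$fitness[ref])
    e$fitness[i] <- e$fitness[i] - sh
    shifts[p] <- sh
  }
  fit$estimates <- e
  fit$reference_shift <- shifts
  fit
}

#' Flag low-likelihood trajectories
#'
#' Recomputes the `used` flag: a trajectory is used when its normalized
#' log-likelihood (mean per-time-point log-likelihood of the fitted model
#' minus the saturated model) is at or above `threshold` and its fitness is
#' defined. `threshold = -Inf` keeps everything.
#'
#' @param fit a `ppiseq_fit` object.
#' @param threshold normalized log-likelihood floor.
#' @return The fit with updated `used` flags.
#' @export
flag_trajectories <- function(fit, threshold = fit$likelihood_threshold) {
  stopifnot(inherits(fit, "ppiseq_fit"))
  e <- fit$estimates
  e$used <- !is.na(e$fitness) &
    (is.na(e$log_likelihood) | e$log_likelihood >= threshold)
  e$used[is.na(e$log_likelihood)] <- FALSE
  fit$estimates <- e
  fit$likelihood_threshold <- threshold
  fit
}
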