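# Gaussian-process smoothing of per-group speed / persistence time
# courses: squared-exponential kernel plus iid observation noise,
# hyperparameters by marginal-likelihood maximization. Because all cells
# are sampled on the same 5-minute grid, observations are collapsed to
# per-timepoint means observed with noise variance sigma_n^2 / n_t, which
# is the exact sufficient statistic for this model and keeps the fit
# O(#timepoints^3).

se_kernel <- function(x1, x2, ell, sf2) {
  sf2 * exp(-0.5 * outer(x1, x2, "-")^2 / ell^2)
}

gp_neg_loglik <- function(par, t, ybar, nt) {
  ell <- exp(par[1L]); sf2 <- exp(par[2L]); sn2 <- exp(par[3L])
  k <- se_kernel(t, t, ell, sf2) + diag(sn2 / nt + 1e-10, length(t))
  ch <- tryCatch(chol(k), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  a <- backsolve(ch, backsolve(ch, ybar, transpose = TRUE))
  0.5 * sum(ybar * a) + sum(log(diag(ch))) + 0.5 * length(t) * log(2 * pi)
}

gp_fit_posterior <- function(t, ybar, nt, grid) {
  mu0 <- mean(ybar)
  yc <- ybar - mu0
  span <- max(diff(range(t)), 1)
  v <- max(var(yc), 1e-8)
  init <- log(c(span / 3, v, v / 2))
  opt <- tryCatch(
    optim(init, gp_neg_loglik, t = t, ybar = yc, nt = nt, method = "L-BFGS-B",
          lower = log(c(span / 50, v * 1e-4, v * 1e-4)),
          upper = log(c(span * 10, v * 100, v * 100))),
    error = function(e) NULL)
  fallback <- is.null(opt) || opt$convergence > 1
  par <- if (fallback) init else opt$par
  ell <- exp(par[1L]); sf2 <- exp(par[2L]); sn2 <- exp(par[3L])
  k <- se_kernel(t, t, ell, sf2) + diag(sn2 / nt + 1e-10, length(t))
  ks <- se_kernel(grid, t, ell, sf2)
  ch <- chol(k)
  a <- backsolve(ch, backsolve(ch, yc, transpose = TRUE))
  post_mean <- mu0 + as.vector(ks %*% a)
  vchol <- backsolve(ch, t(ks), transpose = TRUE)
  post_var <- pmax(sf2 - colSums(vchol^2), 0)
  # band is predictive for the per-timepoint group mean: latent posterior
  # variance plus the sampling noise of a mean over ~n cells
  post_var <- post_var + sn2 / mean(nt)
  list(mean = post_mean, sd = sqrt(post_var),
       hyper = c(lengthscale = ell, signal_var = sf2, noise_var = sn2),
       fallback = fallback)
}

#' Gaussian-process smoothing of motility time courses
#'
#' Fits, per group, a GP regression of the cumulative speed or persistence
#' series against time and returns the posterior mean with a 95% band,
#' alongside the empirical per-timepoint means. Groups with fewer than
#' `min_cells` cells are skipped with a warning. If the hyperparameter
#' optimizer fails, fixed default hyperparameters are used and flagged in
#' the `fallback` column.
#'
#' @param series long-format data frame with columns `cell_id`, `t_min`,
#'   a value column and a group column.
#' @param value_col name of the value column (e.g. `"speed"`).
#' @param group_col name of the grouping column.
#' @param grid_n number of grid points for the posterior curve.
#' @param min_cells minimum cells per group.
#' @return List with `curves` (group, t_min, mean, lower, upper,
#'   fallback) and `empirical` (group, t_min, mean over cells).
#' @export
gpr_timecourse <- function(series, value_col, group_col = "group",
                           grid_n = 50L, min_cells = 5L) {
  need <- c("cell_id", "t_min", value_col, group_col)
  miss <- setdiff(need, names(series))
  if (length(miss)) stop_macmot("missing columns: ", paste(miss, collapse = ", "))
  curves <- list(); emp <- list()
  for (g in unique(series[[group_col]])) {
    sub <- series[series[[group_col]] == g, , drop = FALSE]
    if (length(unique(sub$cell_id)) < min_cells) {
      warning("skipping group ", g, ": fewer than ", min_cells, " cells")
      next
    }
    ag <- aggregate(sub[[value_col]], by = list(t_min = sub$t_min),
                    FUN = function(v) c(mean(v), length(v)))
    t <- ag$t_min
    ybar <- ag$x[, 1L]
    nt <- ag$x[, 2L]
    grid <- seq(min(t), max(t), length.out = grid_n)
    fit <- gp_fit_posterior(t, ybar, nt, grid)
    curves[[length(curves) + 1L]] <- data.frame(
      group = g, t_min = grid, mean = fit$mean,
      lower = fit$mean - 1.96 * fit$sd, upper = fit$mean + 1.96 * fit$sd,
      fallback = fit$fallback)
    emp[[length(emp) + 1L]] <- data.frame(group = g, t_min = t, mean = ybar)
  }
  list(curves = do.call(rbind, curves), empirical = do.call(rbind, emp))
}

#' Long-format motility series for a set of tracks or simulated cells
#'
#' Helper producing the input of [gpr_timecourse()]: cumulative speed and
#' persistence at every endpoint 2..n for each cell.
#'
#' @param tracks a `track_list`, or a list of n x 2 trajectory matrices.
#' @param groups vector of group labels, one per track.
#' @param frame_interval_min frame interval for plain matrices.
#' @return Data frame `cell_id, t_min, speed, persistence, group`.
#' @export
motility_series <- function(tracks, groups, frame_interval_min = 5) {
  stopifnot(length(tracks) == length(groups))
  rows <- lapply(seq_along(tracks), function(i) {
    tr <- tracks[[i]]
    if (inherits(tr, "cell_track")) {
      xy <- tr$centroids; dt <- tr$frame_interval_min; id <- tr$cell_id
    } else { xy <- as.matrix(tr); dt <- frame_interval_min; id <- i }
    data.frame(cell_id = id,
               t_min = dt * seq_len(nrow(xy) - 1L),
               speed = speed_series(xy, dt),
               persistence = persistence_series(xy),
               group = groups[i])
  })
  do.call(rbind, rows)
}
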