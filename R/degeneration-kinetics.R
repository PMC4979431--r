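#' One-phase exponential decay fit of a density time course
#'
#' Fits `y = (Y0 - Plateau) * exp(-K * X) + Plateau` to a longitudinal
#' density profile by bounded nonlinear least squares
#' (Levenberg-Marquardt). `Y0` is the baseline density, `Plateau` the
#' surviving density, and `K` the decay rate; the half-life is `ln(2)/K`
#' and the overall percentage loss `100 * (Y0 - Plateau) / Y0`.
#' Replicates at a time point enter as individual unweighted residuals.
#'
#' Initialisation: `Y0` from the earliest observations, `Plateau` from the
#' latest, `K = ln(2) / median(positive times)`; bounds `Y0, Plateau >= 0`,
#' `K > 0`. Non-convergence (or a constant profile, for which `K` is
#' unidentifiable) yields a flagged fit (`converged = FALSE`), not an error.
#'
#' @param series Data frame with columns `day` and `density` (>= 4 distinct
#'   time points, days >= 0).
#' @return Object of class `one_phase_fit`: list with `Y0`, `Plateau`, `K`,
#'   `half_life_days`, `percent_loss`, `rss`, `converged`, `n`.
#' @export
fit_one_phase <- function(series) {
  check_series(series)
  x <- series$day; y <- series$density
  flagged <- function(msg) {
    structure(list(Y0 = mean(y), Plateau = mean(y), K = NA_real_,
                   half_life_days = NA_real_, percent_loss = NA_real_,
                   rss = NA_real_, converged = FALSE, flag = msg,
                   n = length(y)),
              class = "one_phase_fit")
  }
  if (sd(y) == 0) return(flagged("constant profile: rate unidentifiable"))
  y0_init <- mean(y[x == min(x)])
  pl_init <- max(0, mean(y[x == max(x)]))
  k_init <- log(2) / max(median(x[x > 0]), .Machine$double.eps)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ (Y0 - Plateau) * exp(-K * x) + Plateau,
                      start = list(Y0 = y0_init, Plateau = pl_init,
                                   K = k_init),
                      lower = c(Y0 = 0, Plateau = 0, K = 1e-8),
                      upper = c(Y0 = 100 * max(y) + 1, Plateau = 100 * max(y) + 1,
                                K = 1e3),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(flagged("fit did not converge"))
  p <- coef(fit)
  structure(list(Y0 = unname(p["Y0"]), Plateau = unname(p["Plateau"]),
                 K = unname(p["K"]),
                 half_life_days = log(2) / unname(p["K"]),
                 percent_loss = 100 * (p[["Y0"]] - p[["Plateau"]]) /
                   p[["Y0"]],
                 rss = sum(resid(fit)^2), converged = TRUE, flag = NA_character_,
                 n = length(y)),
            class = "one_phase_fit")
}

check_series <- function(series) {
  if (!is.data.frame(series) || !all(c("day", "density") %in% names(series))) {
    stop("series must be a data frame with day and density columns",
         call. = FALSE)
  }
  if (length(unique(series$day)) < 4) {
    stop("need at least 4 distinct time points", call. = FALSE)
  }
  if (any(series$day < 0) || any(series$density < 0)) {
    stop("days and densities must be non-negative", call. = FALSE)
  }
  invisible(series)
}

#' Two-phase exponential decay fit with fixed fast/slow half-lives
#'
#' Separates primary (fast) from secondary (slow) degeneration by fitting
#' `y = Plateau + SF * exp(-KF * X) + SS * exp(-KS * X)` where the spans are
#' `SF = (Y0 - Plateau) * PF * 0.01` and
#' `SS = (Y0 - Plateau) * (100 - PF) * 0.01`, and the rate constants `KF`
#' and `KS` are fixed from the supplied fast and slow half-lives
#' (`K = ln(2) / t_half`; defaults 1.7 and 16.3 days for primary and
#' secondary RGC degeneration). The free parameters are `Y0`, `Plateau`,
#' and `PF`, the percentage of primary degeneration, constrained to
#' `[0, 100]`. At `PF = 100` the model reduces exactly to the one-phase
#' fast decay.
#'
#' @param series Data frame with `day` and `density` columns.
#' @param t_half_fast_days,t_half_slow_days Fixed half-lives (fast < slow).
#' @return Object of class `two_phase_fit`: `Y0`, `Plateau`, `PF`, `SF`,
#'   `SS`, `KF`, `KS`, `rss`, `converged`, `pf_at_bound`, `n`.
#' @export
fit_two_phase <- function(series, t_half_fast_days = 1.7,
                          t_half_slow_days = 16.3) {
  check_series(series)
  stopifnot(t_half_fast_days > 0, t_half_slow_days > 0,
            t_half_fast_days < t_half_slow_days)
  KF <- log(2) / t_half_fast_days
  KS <- log(2) / t_half_slow_days
  x <- series$day; y <- series$density
  flagged <- function(msg) {
    structure(list(Y0 = mean(y), Plateau = mean(y), PF = NA_real_,
                   SF = NA_real_, SS = NA_real_, KF = KF, KS = KS,
                   rss = NA_real_, converged = FALSE, pf_at_bound = FALSE,
                   flag = msg, n = length(y)),
              class = "two_phase_fit")
  }
  if (sd(y) == 0) return(flagged("constant profile"))
  y0_init <- mean(y[x == min(x)])
  pl_init <- max(0, mean(y[x == max(x)]))
  span_init <- max(y0_init - pl_init, 1e-3)
  # the model is linear in (Plateau, SF, SS); fitting in that
  # parameterisation keeps the Jacobian constant and full-rank, and the
  # non-negativity bounds enforce Y0 >= Plateau and PF in [0, 100]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ Plateau + SF * exp(-KF * x) + SS * exp(-KS * x),
      start = list(Plateau = pl_init, SF = span_init / 2,
                   SS = span_init / 2),
      lower = c(Plateau = 0, SF = 0, SS = 0),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(flagged("fit did not converge"))
  p <- coef(fit)
  span <- p[["SF"]] + p[["SS"]]
  if (span == 0) return(flagged("no decaying component: PF unidentifiable"))
  pf <- 100 * p[["SF"]] / span
  structure(list(Y0 = p[["Plateau"]] + span, Plateau = p[["Plateau"]],
                 PF = pf,
                 SF = span * pf * 0.01, SS = span * (100 - pf) * 0.01,
                 KF = KF, KS = KS, rss = sum(resid(fit)^2),
                 converged = TRUE,
                 pf_at_bound = pf <= 1e-6 || pf >= 100 - 1e-6,
                 flag = NA_character_, n = length(y)),
            class = "two_phase_fit")
}

#' Evaluate a fitted decay model
#'
#' @param fit A `one_phase_fit` or `two_phase_fit`.
#' @param times Numeric vector of times (days).
#' @return Predicted densities.
#' @export
predict_decay <- function(fit, times) {
  if (inherits(fit, "one_phase_fit")) {
    (fit$Y0 - fit$Plateau) * exp(-fit$K * times) + fit$Plateau
  } else if (inherits(fit, "two_phase_fit")) {
    fit$Plateau + fit$SF * exp(-fit$KF * times) +
      fit$SS * exp(-fit$KS * times)
  } else stop("fit must be a one_phase_fit or two_phase_fit", call. = FALSE)
}

#' @export
print.one_phase_fit <- function(x, ...) {
  cat("One-phase decay fit:", if (!x$converged) "[not converged]",
      sprintf("Y0 = %.4g, Plateau = %.4g, t1/2 = %.3g d, loss = %.1f%%\n",
              x$Y0, x$Plateau, x$half_life_days, x$percent_loss))
  invisible(x)
}

#' @export
print.two_phase_fit <- function(x, ...) {
  cat("Two-phase decay fit:", if (!x$converged) "[not converged]",
      sprintf("Y0 = %.4g, Plateau = %.4g, primary = %.1f%%\n",
              x$Y0, x$Plateau, x$PF))
  invisible(x)
}

#' Percentage density loss relative to baseline
#'
#' `100 * (1 - density_t / density_baseline)`. Full precision is returned;
#' use [round_half_away()] for comparison against integer-rounded tabulated
#' percentages.
#'
#' @param density_t Density at the time of interest.
#' @param density_baseline Control/baseline density (> 0).
#' @return Percentage loss (vectorised).
#' @export
#' @examples
#' round_half_away(percent_loss(491.7, 1695))  # 71
percent_loss <- function(density_t, density_baseline) {
  if (any(density_baseline <= 0)) stop("baseline density must be positive",
                                       call. = FALSE)
  100 * (1 - density_t / density_baseline)
}

#' Per-sector kinetics maps
#'
#' Fits every sector's density time course to the one-phase model (per-cent
#' loss, half-life) and the fixed-rate two-phase model (percentage of
#' primary degeneration), and renders the three sector colour maps.
#'
#' @param series_long Data frame with columns `ring`, `quadrant`, `day`,
#'   `density` (one series per sector).
#' @param t_half_fast_days,t_half_slow_days Fixed two-phase half-lives.
#' @param grid Optional [sector_grid()] giving the full sector set expected
#'   (defaults to the sectors present in the data).
#' @return List with `table` (per-sector `percent_loss`, `half_life_days`,
#'   `pf_percent`, convergence flags) and `plots` (named list of three
#'   ggplot sector maps). Sectors whose fits fail carry `converged = FALSE`
#'   and are greyed in the maps.
#' @export
sector_kinetics_map <- function(series_long, t_half_fast_days = 1.7,
                                t_half_slow_days = 16.3, grid = NULL) {
  stopifnot(all(c("ring", "quadrant", "day", "density") %in%
                names(series_long)))
  key <- interaction(series_long$ring, series_long$quadrant, drop = TRUE)
  rows <- lapply(split(series_long, key), function(d) {
    f1 <- fit_one_phase(d[, c("day", "density")])
    f2 <- fit_two_phase(d[, c("day", "density")], t_half_fast_days,
                        t_half_slow_days)
    data.frame(ring = d$ring[1], quadrant = d$quadrant[1],
               percent_loss = if (f1$converged) f1$percent_loss else NA_real_,
               half_life_days = if (f1$converged) f1$half_life_days else NA_real_,
               pf_percent = if (f2$converged) f2$PF else NA_real_,
               converged = f1$converged && f2$converged)
  })
  tab <- do.call(rbind, rows)
  if (!is.null(grid)) {
    full <- expand.grid(ring = seq_len(grid$n_rings),
                        quadrant = grid$quadrant_labels,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    tab <- merge(full, tab, all.x = TRUE, sort = FALSE)
    tab$converged[is.na(tab$converged)] <- FALSE
  }
  tab <- tab[order(tab$quadrant, tab$ring), ]
  rownames(tab) <- NULL
  plots <- list(
    percent_loss = plot_sector_map(tab, "percent_loss", "% density loss"),
    half_life = plot_sector_map(tab, "half_life_days", "half-life (days)"),
    primary = plot_sector_map(tab, "pf_percent", "% primary degeneration"))
  list(table = tab, plots = plots)
}

#' Polar sector colour map
#'
#' @param table Data frame with `ring`, `quadrant` and the value column.
#' @param value Name of the column to map to fill.
#' @param title Legend title.
#' @return A ggplot: rings radially, quadrants angularly; `NA` sectors grey.
#' @export
plot_sector_map <- function(table, value, title = value) {
  quads <- c("Superior", "Nasal", "Inferior", "Temporal")
  d <- table
  d$q <- match(d$quadrant, quads)
  d$xmin <- (d$q - 1) * 90; d$xmax <- d$q * 90
  d$val <- d[[value]]
  ggplot2::ggplot(d) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                    ymin = .data$ring - 1, ymax = .data$ring,
                                    fill = .data$val), colour = "grey30",
                       linewidth = 0.2) +
    ggplot2::scale_fill_gradientn(
      colours = c("blue", "green", "yellow", "orange", "red"),
      na.value = "grey70", name = title) +
    ggplot2::coord_polar(theta = "x", start = -pi / 4) +
    ggplot2::scale_x_continuous(breaks = c(45, 135, 225, 315),
                                labels = quads, limits = c(0, 360)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.title = ggplot2::element_blank(),
                   axis.text.y = ggplot2::element_blank())
}

#' Cumulative intraocular-pressure exposure
#'
#' The integral over time of the IOP elevation above baseline (area under
#' the curve of `max(IOP - baseline, 0)`), in mmHg-days. The IOP profile is
#' taken as piecewise linear between measurements and segments crossing the
#' baseline are integrated exactly.
#'
#' @param times_days Measurement times, strictly increasing.
#' @param iop_mmHg IOP readings, same length.
#' @param baseline_mmHg Reference pressure.
#' @return Cumulative exposure, mmHg-days.
#' @export
#' @examples
#' cumulative_iop(c(0, 10), c(18, 18), 10)  # 80 mmHg-days
cumulative_iop <- function(times_days, iop_mmHg, baseline_mmHg) {
  if (length(times_days) != length(iop_mmHg)) {
    stop("times and IOP vectors differ in length", call. = FALSE)
  }
  if (any(diff(times_days) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  e <- iop_mmHg - baseline_mmHg
  total <- 0
  for (i in seq_len(length(e) - 1)) {
    e1 <- e[i]; e2 <- e[i + 1]; dt <- times_days[i + 1] - times_days[i]
    total <- total + if (e1 >= 0 && e2 >= 0) {
      (e1 + e2) / 2 * dt
    } else if (e1 <= 0 && e2 <= 0) {
      0
    } else {                       # one crossing within the segment
      f <- e1 / (e1 - e2)          # fraction of dt at which elevation hits 0
      if (e1 > 0) e1 / 2 * f * dt else e2 / 2 * (1 - f) * dt
    }
  }
  total
}
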