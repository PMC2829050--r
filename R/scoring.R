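#' Fit a beta-uniform mixture to a p-value distribution
#'
#' Models the p-value density as f(x) = pi + (1 - pi) a x^(a-1): a
#' uniform noise component of weight pi plus a Beta(a, 1) signal component
#' concentrated near zero (a < 1). Parameters are estimated by maximum
#' likelihood with box-constrained `optim` (L-BFGS-B) from five
#' deterministic starting points; the best converged fit is returned.
#'
#' @param p_values Numeric vector (>= 20 recommended); zeros are floored
#'   at `p_floor` before taking logs.
#' @param p_floor Lower bound applied to p-values.
#' @param bounds Box constraints for both parameters.
#' @return A `bum_fit` object: list with `pi`, `a`, `log_likelihood`,
#'   `n`, `pi_upper` (the BUM upper bound pi + (1 - pi) a on the null
#'   proportion) and `no_signal` (TRUE when the fit is indistinguishable
#'   from pure noise).
#' @export
fit_bum <- function(p_values, p_floor = 1e-12,
                    bounds = c(1e-5, 1 - 1e-5)) {
  p <- pmax(pmin(p_values, 1), p_floor)
  if (length(p) < 2) {
    abort("need at least 2 p-values to fit a mixture",
          class = "metamodule_data_error")
  }
  nll <- function(par) {
    f <- par[1] + (1 - par[1]) * par[2] * p^(par[2] - 1)
    -sum(log(pmax(f, 1e-300)))
  }
  starts <- list(c(0.5, 0.5), c(0.7, 0.3), c(0.3, 0.7), c(0.9, 0.1), c(0.1, 0.9))
  fits <- purrr::map(starts, function(s) {
    tryCatch(optim(s, nll, method = "L-BFGS-B",
                   lower = rep(bounds[1], 2), upper = rep(bounds[2], 2)),
             error = function(e) NULL)
  })
  fits <- purrr::compact(fits)
  fits <- purrr::keep(fits, ~ .x$convergence == 0)
  if (length(fits) == 0) {
    abort("beta-uniform mixture optimization failed at all starts",
          class = "metamodule_fit_error")
  }
  best <- fits[[which.min(purrr::map_dbl(fits, "value"))]]
  structure(list(
    pi = best$par[1], a = best$par[2],
    pi_upper = best$par[1] + (1 - best$par[1]) * best$par[2],
    log_likelihood = -best$value, n = length(p),
    no_signal = best$par[1] >= bounds[2] - 1e-4,
    tau = NA_real_, fdr = NA_real_
  ), class = "bum_fit")
}

#' BUM mixture density
#'
#' @param x P-values in (0, 1].
#' @param fit A `bum_fit`.
#' @return Density values f(x) = pi + (1 - pi) a x^(a-1).
#' @export
bum_density <- function(x, fit) {
  fit$pi + (1 - fit$pi) * fit$a * x^(fit$a - 1)
}

#' P-value threshold achieving a target FDR under a BUM fit
#'
#' Under the fitted mixture the p-value cutoff controlling the false
#' discovery rate at `fdr` has the closed form
#' tau = ((pi_ub - pi fdr) / (fdr (1 - pi)))^(1 / (a - 1)),
#' where pi_ub = pi + (1 - pi) a bounds the null proportion from above.
#'
#' @param fit A `bum_fit` with a < 1.
#' @param fdr Target false discovery rate (default 0.01).
#' @return The threshold tau in (0, 1).
#' @export
tau_from_fdr <- function(fit, fdr = 0.01) {
  if (fit$a >= 1) {
    abort("fitted shape a >= 1: no signal enrichment near zero; tau undefined",
          class = "metamodule_fit_error")
  }
  if (fdr <= 0 || fdr >= 1) {
    abort("fdr must be in (0, 1)", class = "metamodule_config_error")
  }
  base <- (fit$pi_upper - fit$pi * fdr) / (fdr * (1 - fit$pi))
  if (!is.finite(base) || base <= 0) {
    abort("requested fdr incompatible with fitted mixture",
          class = "metamodule_fit_error")
  }
  tau <- base^(1 / (fit$a - 1))
  if (!is.finite(tau) || tau <= 0 || tau >= 1) {
    abort(sprintf("fdr %.4g yields no valid threshold (tau = %.4g)", fdr, tau),
          class = "metamodule_fit_error")
  }
  tau
}

#' Attach the FDR threshold to a fit
#'
#' @param fit A `bum_fit`.
#' @param fdr Target FDR.
#' @return The fit with `tau` and `fdr` fields set.
#' @export
set_fdr_threshold <- function(fit, fdr = 0.01) {
  fit$tau <- tau_from_fdr(fit, fdr)
  fit$fdr <- fdr
  fit
}

#' Convert p-values to additive node scores
#'
#' S(p) = (a - 1) (log p - log tau): zero at p = tau, positive below it
#' and negative above it whenever a < 1, so only nodes more significant
#' than the FDR threshold contribute positive weight to a module.
#'
#' @param p P-values in (0, 1]; exact zeros are floored at `p_floor`.
#' @param fit A `bum_fit`.
#' @param tau Threshold (defaults to the fit's stored tau).
#' @param p_floor Floor applied to zeros.
#' @return Numeric scores.
#' @export
score_pvalue <- function(p, fit, tau = fit$tau, p_floor = 1e-12) {
  if (any(p < 0, na.rm = TRUE) || any(is.na(p))) {
    abort("p-values must be positive", class = "metamodule_data_error")
  }
  if (is.na(tau)) abort("no tau supplied or stored in fit",
                        class = "metamodule_config_error")
  p <- pmax(p, p_floor)
  (fit$a - 1) * (log(p) - log(tau))
}

#' Score the measured nodes of a network
#'
#' @param net igraph network with measured flags placed (EMRN or CMRN
#'   convention, see [assign_measured_compartment()]).
#' @param change Change table with `metabolite` and `p_value`.
#' @param fit A `bum_fit` carrying tau.
#' @param tau Threshold override.
#' @return The network with vertex attribute `score` on measured nodes
#'   (NA elsewhere) and `p_value` stored alongside.
#' @export
assign_scores <- function(net, change, fit, tau = fit$tau) {
  nodes <- mrn_nodes(net)
  meas <- nodes |> dplyr::filter(.data$measured)
  pv <- change$p_value[match(meas$metabolite, change$metabolite)]
  if (any(is.na(pv))) {
    abort(sprintf("measured node(s) without a p-value: %s",
                  paste(meas$node[is.na(pv)], collapse = ", ")),
          class = "metamodule_data_error")
  }
  score <- rep(NA_real_, nrow(nodes))
  pval <- rep(NA_real_, nrow(nodes))
  idx <- match(meas$node, nodes$node)
  pval[idx] <- pv
  score[idx] <- score_pvalue(pv, fit, tau)
  igraph::V(net)$p_value <- pval
  igraph::V(net)$score <- score
  net
}
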