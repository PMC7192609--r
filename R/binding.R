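#' Relative phase amplitudes of a double-exponential fit
#'
#' Amplitudes normalized by the total fluorescence change A1 + A2. The
#' fast-phase share relA1 rises with the amount of specific dNTP as
#' incorporation outcompetes background probe hydrolysis.
#'
#' @param fit an `exp_fit` with `model == "double"` and A1 + A2 > 0.
#' @return Named numeric `c(relA1, relA2)`; the two always sum to 1.
#' @export
relative_amplitudes <- function(fit) {
  if (fit$model != "double")
    stop("relative amplitudes are defined for double-model fits only")
  tot <- fit$A1 + fit$A2
  if (!is.finite(tot) || tot <= 0) stop("need A1 + A2 > 0")
  c(relA1 = fit$A1 / tot, relA2 = fit$A2 / tot)
}

#' Evaluate the quadratic tight-binding model
#'
#' One-to-one stoichiometric binding of the specific dNTP (total ligand
#' L_T) to the polymerase:template:primer:probe complex (total E_T), with
#' no cooperativity:
#' \deqn{F(L_T) = F_0 + A_{quad} \frac{(E_T + L_T + K_{app}) -
#'   \sqrt{(E_T + L_T + K_{app})^2 - 4 E_T L_T}}{2 E_T}}
#' The minus root is the physical branch: it gives \eqn{F_0} at zero ligand
#' and saturates at \eqn{F_0 + A_{quad}}; the plus root is unbounded and is
#' rejected.
#'
#' @param params named list/vector with `F0`, `A_quad`, `E_T` (pmol, > 0)
#'   and `K_app` (pmol, >= 0).
#' @param L_T total added specific dNTP (pmol, >= 0); vectorized.
#' @return Model value at `L_T`.
#' @export
eval_quadratic_binding <- function(params, L_T) {
  p <- as.list(params)
  if (!is.finite(p$E_T) || p$E_T <= 0) stop("E_T must be positive")
  if (p$K_app < 0) stop("K_app must be nonnegative")
  if (any(L_T < 0)) stop("L_T must be nonnegative")
  s <- p$E_T + L_T + p$K_app
  disc <- pmax(s^2 - 4 * p$E_T * L_T, 0)
  p$F0 + p$A_quad * (s - sqrt(disc)) / (2 * p$E_T)
}

#' Fit the quadratic binding model to relative amplitudes
#'
#' Nonlinear least squares over (amount, relative amplitude) points that
#' should span sub- and superstoichiometric amounts of the specific dNTP.
#' The saturating value F0 + A_quad estimates the fraction of the
#' polymerase:template:primer:probe complex available for specific
#' incorporation; its complement is consumed by the competing background
#' hydrolysis.
#'
#' @param amount_pmol,rel amounts and relative amplitudes (equal length,
#'   >= 5 points at >= 2 distinct amounts).
#' @param init optional named start values (`F0`, `A_quad`, `E_T`, `K_app`).
#' @param fix_E_T optionally fix the complex concentration at this value
#'   (pmol) instead of fitting it.
#' @param multistart randomized restarts on failure.
#' @return A `quad_binding_fit`: estimates, standard errors (`se`), `RSS`,
#'   `N`, and `saturation` = F0 + A_quad.
#' @export
fit_quadratic_binding <- function(amount_pmol, rel, init = NULL,
                                  fix_E_T = NULL, multistart = 20L) {
  stopifnot(length(amount_pmol) == length(rel))
  if (length(amount_pmol) < 5) stop("need at least 5 points")
  if (length(unique(amount_pmol)) < 2)
    stop("points must span more than one amount")
  d <- data.frame(L = amount_pmol, y = rel)
  rising <- stats::coef(stats::lm(y ~ L, d))[2] >= 0
  start <- list(
    F0 = if (rising) min(rel) else max(rel),
    A_quad = if (rising) max(rel) - min(rel) else min(rel) - max(rel),
    E_T = stats::median(amount_pmol), K_app = stats::median(amount_pmol) / 10)
  if (!is.null(init)) start[names(init)] <- init
  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-12, ptol = 1e-12,
                                     maxiter = 1024)
  fit1 <- function(st) {
    if (is.null(fix_E_T)) {
      form <- y ~ F0 + A_quad * ((E_T + L + K_app) -
        sqrt((E_T + L + K_app)^2 - 4 * E_T * L)) / (2 * E_T)
      lower <- c(F0 = -Inf, A_quad = -Inf, E_T = 1e-9, K_app = 0)
      st <- st[c("F0", "A_quad", "E_T", "K_app")]
    } else {
      E_T <- fix_E_T
      form <- y ~ F0 + A_quad * ((E_T + L + K_app) -
        sqrt((E_T + L + K_app)^2 - 4 * E_T * L)) / (2 * E_T)
      lower <- c(F0 = -Inf, A_quad = -Inf, K_app = 0)
      st <- st[c("F0", "A_quad", "K_app")]
    }
    tryCatch(suppressWarnings(minpack.lm::nlsLM(
      form, data = d, start = st, lower = lower, control = ctrl)),
      error = function(e) NULL)
  }
  fit <- fit1(start)
  if (is.null(fit) || !isTRUE(fit$convInfo$isConv)) {
    for (i in seq_len(multistart)) {
      st <- start
      st$E_T <- stats::runif(1, min(amount_pmol[amount_pmol > 0]),
                             max(amount_pmol))
      st$K_app <- stats::runif(1, 0, max(amount_pmol))
      cand <- fit1(st)
      if (!is.null(cand) && isTRUE(cand$convInfo$isConv) &&
          (is.null(fit) || sum(stats::resid(cand)^2) <
             sum(stats::resid(fit)^2))) fit <- cand
    }
  }
  if (is.null(fit)) stop("quadratic binding fit did not converge")
  co <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) stats::setNames(
                   rep(NA_real_, length(co)), names(co)))
  if (!is.null(fix_E_T)) {
    co <- c(co, E_T = fix_E_T)
    se <- c(se, E_T = NA_real_)
  }
  structure(list(A_quad = unname(co["A_quad"]), F0 = unname(co["F0"]),
                 E_T = unname(co["E_T"]), K_app = unname(co["K_app"]),
                 se = se, RSS = sum(stats::resid(fit)^2),
                 N = length(rel),
                 saturation = unname(co["F0"] + co["A_quad"])),
            class = "quad_binding_fit")
}

#' @export
print.quad_binding_fit <- function(x, ...) {
  cat(sprintf(paste0(
    "Quadratic binding fit: A_quad = %.4g, F0 = %.4g, E_T = %.4g pmol, ",
    "K_app = %.4g pmol\n  saturation F0 + A_quad = %.4g, RSS = %.4g, ",
    "N = %d\n"),
    x$A_quad, x$F0, x$E_T, x$K_app, x$saturation, x$RSS, x$N))
  invisible(x)
}
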