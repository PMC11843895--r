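#' 1:1 biolayer-interferometry forward model
#'
#' Two-phase Langmuir 1:1 binding. During association (`t <= t_assoc`):
#' `R(t) = Req * (1 - exp(-(kon*conc + koff) * t))` with
#' `Req = Rmax * conc / (conc + koff/kon)`. During dissociation
#' (`t > t_assoc`): `R(t) = R(t_assoc) * exp(-koff * (t - t_assoc))`.
#' Continuous at the phase boundary by construction.
#'
#' @param t Time vector in seconds (association starts at 0).
#' @param kon Association rate, 1/(M s).
#' @param koff Dissociation rate, 1/s.
#' @param rmax Maximal response, instrument response units.
#' @param conc Analyte concentration, M.
#' @param t_assoc Association phase duration, s.
#' @return Response vector.
#' @export
bli_forward <- function(t, kon, koff, rmax, conc, t_assoc = 300) {
  stopifnot(kon > 0, koff > 0, rmax > 0, conc > 0, t_assoc > 0)
  kobs <- kon * conc + koff
  req <- rmax * conc / (conc + koff / kon)
  r_end <- req * (1 - exp(-kobs * t_assoc))
  ifelse(t <= t_assoc,
         req * (1 - exp(-kobs * t)),
         r_end * exp(-koff * (t - t_assoc)))
}

#' Construct a sensorgram object
#'
#' @param times Strictly increasing time vector, s (association starts
#'   at 0).
#' @param responses Response vector, same length.
#' @param conc Analyte concentration, M (> 0).
#' @param t_assoc Association end time, s.
#' @param t_dissoc Dissociation end time, s (> `t_assoc`).
#' @return An object of class `sensorgram`.
#' @export
sensorgram <- function(times, responses, conc, t_assoc, t_dissoc) {
  stopifnot(length(times) == length(responses), conc > 0,
            t_assoc > 0, t_dissoc > t_assoc)
  if (any(diff(times) <= 0))
    stop("sensorgram times must be strictly increasing", call. = FALSE)
  structure(list(times = as.numeric(times),
                 responses = as.numeric(responses),
                 conc = conc, t_assoc = t_assoc, t_dissoc = t_dissoc),
            class = "sensorgram")
}

#' Read a sensorgram from TSV plus metadata sidecar
#'
#' The TSV has header `time_s  response`; the sidecar is a small JSON file
#' with fields `conc_M`, `assoc_end_s`, `dissoc_end_s`.
#'
#' @param path TSV path.
#' @param meta_path Sidecar path; default `paste0(path, ".json")`.
#' @return A [sensorgram()].
#' @export
read_sensorgram <- function(path, meta_path = paste0(path, ".json")) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  if (!all(c("time_s", "response") %in% names(dt)))
    stop("sensorgram TSV needs columns time_s and response", call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (f in c("conc_M", "assoc_end_s", "dissoc_end_s"))
    if (is.null(meta[[f]]))
      stop("sensorgram sidecar missing field ", f, call. = FALSE)
  sensorgram(dt$time_s, dt$response, conc = meta$conc_M,
             t_assoc = meta$assoc_end_s, t_dissoc = meta$dissoc_end_s)
}

#' Fit the 1:1 binding model to a sensorgram
#'
#' Least-squares fit of `(kon, koff, Rmax)` on the log scale (all rates are
#' positive by parameterization). Initialization is analytic: `koff` from a
#' log-linear fit of the dissociation tail, the observed rate `kobs` from a
#' log-linear fit of the association approach to plateau, then
#' `kon = (kobs - koff)/conc`. `Kd = koff/kon` is derived. With a single
#' analyte concentration `kon` and `koff` are only weakly identified
#' individually; `Kd` is the robust quantity.
#'
#' @param sg A [sensorgram()] with >= 10 points in each phase.
#' @param kon_seed Fallback initial `kon` when the analytic start fails;
#'   default `1e5` 1/(M s).
#' @return An object of class `kinetic_fit`: list with `kon`, `koff`,
#'   `rmax`, `kd`, `rmse`, `se` (named vector of asymptotic standard errors
#'   from the residual covariance, `NA` when the curvature is singular),
#'   `converged`, and `n`.
#' @export
fit_bli <- function(sg, kon_seed = 1e5) {
  stopifnot(inherits(sg, "sensorgram"))
  t <- sg$times; y <- sg$responses
  assoc <- t <= sg$t_assoc
  if (sum(assoc) < 10L || sum(!assoc) < 10L)
    stop("fit_bli: need >= 10 points in each phase", call. = FALSE)
  if (stats::sd(y) < 1e-12 * max(1, abs(mean(y))) || all(abs(y) < 1e-12))
    stop("fit_bli: flat sensorgram, no binding signal to fit",
         call. = FALSE)
  ## analytic initialization
  td <- t[!assoc] - sg$t_assoc; yd <- y[!assoc]
  pos <- yd > 0
  koff0 <- if (sum(pos) >= 3L) {
    sl <- stats::coef(stats::lm(log(yd[pos]) ~ td[pos]))[2]
    max(-sl, 1e-6)
  } else 1e-3
  req0 <- max(stats::quantile(y[assoc], 0.98), 1e-9)
  ta <- t[assoc]; ya <- y[assoc]
  frac <- 1 - ya / (req0 * 1.001)
  use <- frac > 1e-3 & ta > 0
  kobs0 <- if (sum(use) >= 3L) {
    max(-stats::coef(stats::lm(log(frac[use]) ~ ta[use]))[2], koff0 * 1.01)
  } else koff0 * 2
  kon0 <- max((kobs0 - koff0) / sg$conc, kon_seed * 1e-3)
  if (!is.finite(kon0) || kon0 <= 0) kon0 <- kon_seed
  kd0 <- koff0 / kon0
  rmax0 <- req0 * (sg$conc + kd0) / sg$conc
  obj <- function(par) {
    kon <- exp(par[1]); koff <- exp(par[2]); rmax <- exp(par[3])
    sum((y - bli_forward(t, kon, koff, rmax, sg$conc, sg$t_assoc))^2)
  }
  par0 <- log(c(kon0, koff0, rmax0))
  fit <- stats::optim(par0, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
  fit <- stats::optim(fit$par, obj, method = "BFGS", hessian = TRUE,
                      control = list(maxit = 1000, reltol = 1e-14))
  kon <- exp(fit$par[1]); koff <- exp(fit$par[2]); rmax <- exp(fit$par[3])
  n <- length(y)
  rmse <- sqrt(fit$value / n)
  sigma2 <- fit$value / max(n - 3L, 1L)
  se <- tryCatch({
    cov_log <- 2 * sigma2 * solve(fit$hessian)
    sd_log <- sqrt(pmax(diag(cov_log), 0))
    # delta method back to the natural scale; kd = koff/kon
    var_log_kd <- cov_log[2, 2] + cov_log[1, 1] - 2 * cov_log[1, 2]
    c(kon = kon * sd_log[1], koff = koff * sd_log[2],
      rmax = rmax * sd_log[3],
      kd = (koff / kon) * sqrt(max(var_log_kd, 0)))
  }, error = function(e) c(kon = NA_real_, koff = NA_real_,
                           rmax = NA_real_, kd = NA_real_))
  structure(list(kon = kon, koff = koff, rmax = rmax, kd = koff / kon,
                 rmse = rmse, se = se,
                 converged = fit$convergence == 0L, n = n),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf(
    "1:1 kinetic fit: kon = %.4g /(M s), koff = %.4g /s, Rmax = %.4g, Kd = %.4g nM (rmse %.3g)\n",
    x$kon, x$koff, x$rmax, x$kd * 1e9, x$rmse))
  invisible(x)
}

#' Construct an inhibition curve
#'
#' @param inhibitor_concs Inhibitor concentrations, M (>= 0), at least 4
#'   points for fitting.
#' @param methylation_fractions Matching methylation fractions in `[0, 1]`.
#' @return An object of class `inhibition_curve`.
#' @export
inhibition_curve <- function(inhibitor_concs, methylation_fractions) {
  stopifnot(length(inhibitor_concs) == length(methylation_fractions))
  if (any(inhibitor_concs < 0))
    stop("inhibitor concentrations must be >= 0", call. = FALSE)
  if (any(methylation_fractions < 0 | methylation_fractions > 1))
    stop("methylation fractions must be in [0, 1]", call. = FALSE)
  structure(list(inhibitor_concs = as.numeric(inhibitor_concs),
                 methylation_fractions = as.numeric(methylation_fractions)),
            class = "inhibition_curve")
}

#' Read an inhibition curve from TSV
#'
#' Header `inhibitor_conc_M  methylation_fraction`.
#'
#' @param path TSV path.
#' @return An [inhibition_curve()].
#' @export
read_inhibition <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  if (!all(c("inhibitor_conc_M", "methylation_fraction") %in% names(dt)))
    stop("inhibition TSV needs columns inhibitor_conc_M and methylation_fraction",
         call. = FALSE)
  inhibition_curve(dt$inhibitor_conc_M, dt$methylation_fraction)
}

ic50_model <- function(conc, f0, ic50, hill) {
  f0 / (1 + (conc / ic50)^hill)
}

#' Fit a log-logistic IC50 inhibition model
#'
#' Least-squares fit of `f([I]) = f0 / (1 + ([I]/IC50)^h)` with bottom
#' fixed at 0. The Hill slope `h` is fixed at 1 by default and can be
#' freed. `f0` is the uninhibited methylation fraction; at `[I] = IC50`
#' (with `h = 1`) the model gives `f0/2`.
#'
#' @param curve An [inhibition_curve()] with >= 4 points including one near
#'   zero inhibitor (below `IC50/10` of the eventual fit is advisable).
#' @param fix_hill Keep the Hill slope at 1 (default `TRUE`).
#' @return An object of class `ic50_fit`: list with `ic50` (M), `f0`,
#'   `hill`, `rmse`, `se` (asymptotic standard errors for the free
#'   parameters), `converged`, `n`.
#' @export
fit_ic50 <- function(curve, fix_hill = TRUE) {
  stopifnot(inherits(curve, "inhibition_curve"))
  x <- curve$inhibitor_concs; y <- curve$methylation_fractions
  if (length(x) < 4L)
    stop("fit_ic50: need >= 4 concentration points", call. = FALSE)
  if (stats::sd(y) < 1e-12)
    stop("fit_ic50: all responses equal, nothing to fit", call. = FALSE)
  f00 <- max(y)
  half <- f00 / 2
  below <- which(y <= half)
  ic500 <- if (length(below)) {
    max(x[min(below[x[below] > 0])], min(x[x > 0]))
  } else max(x[x > 0])
  if (!is.finite(ic500) || ic500 <= 0) ic500 <- stats::median(x[x > 0])
  obj <- function(par) {
    f0 <- exp(par[1]); ic50 <- exp(par[2])
    hill <- if (fix_hill) 1 else exp(par[3])
    sum((y - ic50_model(x, f0, ic50, hill))^2)
  }
  par0 <- if (fix_hill) log(c(f00, ic500)) else log(c(f00, ic500, 1))
  fit <- stats::optim(par0, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
  fit <- stats::optim(fit$par, obj, method = "BFGS", hessian = TRUE,
                      control = list(maxit = 1000, reltol = 1e-14))
  f0 <- exp(fit$par[1]); ic50 <- exp(fit$par[2])
  hill <- if (fix_hill) 1 else exp(fit$par[3])
  if (f0 > 1 + 1e-6)
    warning("fit_ic50: fitted f0 exceeds 1 (", signif(f0, 4), ")")
  n <- length(y)
  sigma2 <- fit$value / max(n - length(fit$par), 1L)
  se <- tryCatch({
    cov_log <- 2 * sigma2 * solve(fit$hessian)
    sd_log <- sqrt(pmax(diag(cov_log), 0))
    nat <- exp(fit$par) * sd_log
    names(nat) <- if (fix_hill) c("f0", "ic50") else c("f0", "ic50", "hill")
    nat
  }, error = function(e) {
    v <- rep(NA_real_, length(fit$par))
    names(v) <- if (fix_hill) c("f0", "ic50") else c("f0", "ic50", "hill")
    v
  })
  structure(list(ic50 = ic50, f0 = f0, hill = hill,
                 rmse = sqrt(fit$value / n), se = se,
                 converged = fit$convergence == 0L, n = n),
            class = "ic50_fit")
}

#' @export
print.ic50_fit <- function(x, ...) {
  cat(sprintf("IC50 fit: IC50 = %.4g uM, f0 = %.4g, hill = %.3g (rmse %.3g)\n",
              x$ic50 * 1e6, x$f0, x$hill, x$rmse))
  invisible(x)
}

#' Methylation efficiency from a restriction-protection assay
#'
#' Methylation protects the substrate from cleavage by a
#' methylation-sensitive endonuclease, so efficiency is the relative drop in
#' cleavage: `(w0 - w_meth) / w0`, where `w0` is the cleaved fraction before
#' methylation and `w_meth` after.
#'
#' @param w0 Cleaved fraction of the unmethylated substrate, in `(0, 1]`. A
#'   substrate with `w0 = 0` is not cleavable and the efficiency is
#'   undefined (error).
#' @param w_meth Cleaved fraction after methylation, in `[0, 1]`.
#' @return Methylation efficiency (vectorized).
#' @examples
#' methylation_efficiency(0.9, 0.45)  # 0.5
#' @export
methylation_efficiency <- function(w0, w_meth) {
  if (any(w0 <= 0))
    stop("w0 = 0: substrate not cleavable, efficiency undefined",
         call. = FALSE)
  if (any(w0 > 1) || any(w_meth < 0 | w_meth > 1))
    stop("cleavage extents must be fractions in [0, 1]", call. = FALSE)
  (w0 - w_meth) / w0
}

#' Write a fit object as JSON
#'
#' Emits parameters, asymptotic uncertainties and rmse for a
#' [fit_bli()] or [fit_ic50()] result.
#'
#' @param fit A `kinetic_fit` or `ic50_fit`.
#' @param path Output path.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(unclass(fit), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
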