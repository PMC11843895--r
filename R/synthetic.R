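#' Truth/noise presets for the read simulator
#'
#' Presets bundle a methylation truth table (per strand x region
#' probability of 5mC) with a noise configuration for the probability-call
#' emitter. They are stored as JSON under `inst/extdata/presets.json` so
#' every constant (including the control preset's false-modified-call rate,
#' calibrated so that the thresholded global 5mC level of simulated control
#' reads is about 0.04) is visible configuration rather than code.
#'
#' Available presets:
#' * `control`: unmethylated everywhere (truth 0).
#' * `dnmt3a`: strand- and region-specific truth - PQS region G-strand
#'   0.33 / C-strand 0.58, outside 0.47 / 0.49.
#' * `msssi`: 0.62 on both strands everywhere.
#'
#' @param name Preset name.
#' @return A list with `truth` (2x2 numeric matrix, rows `"+"`/`"-"`,
#'   columns `"PQS"`/`"non-PQS"`) and `noise` (list: see
#'   [simulate_reads()]).
#' @export
preset_truth <- function(name) {
  path <- system.file("extdata", "presets.json", package = "quadmeth",
                      mustWork = TRUE)
  presets <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!name %in% names(presets))
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  p <- presets[[name]]
  means <- matrix(c(p$truth$c_pqs, p$truth$c_nonpqs,
                    p$truth$g_pqs, p$truth$g_nonpqs),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(c("+", "-"), c("PQS", "non-PQS")))
  if (any(means < 0 | means > 1))
    stop("preset truth probabilities out of [0, 1]", call. = FALSE)
  truth <- list(means = means,
                site_sd = c("PQS" = p$truth$site_sd_pqs,
                            "non-PQS" = p$truth$site_sd_nonpqs))
  list(truth = truth, noise = p$noise)
}

#' Simulate per-read modification-probability calls
#'
#' Emulates the per-read (p_C, p_5mC, p_5hmC) calls a modification-aware
#' basecaller produces on an amplicon: for every read x CpG site, a truth
#' state (5mC with the strand- and region-dependent probability from
#' `truth`, else canonical C) and then a probability triple drawn from a
#' Dirichlet distribution centred on the truth state.
#'
#' The per-site methylation probability is the region x strand cell mean
#' plus an optional between-site random effect: a Gaussian site propensity
#' (sd `truth$site_sd[region]`, on the probability scale) that is shared
#' between the two strands of a site, centred to mean zero within each
#' region, and clipped to `[0, 1]` after addition. This emulates the large
#' site-to-site dispersion of real methylation patterns (local sequence
#' context modulates both strands alike) while keeping the cell means equal
#' to the configured truth. Calls come in a
#' confident component (concentration mass `high_conf_concentration` on the
#' true state; `Inf` gives an exact point mass) and a near-uniform
#' low-confidence component (symmetric concentration
#' `low_conf_concentration`) whose frequency depends on PQS membership
#' (`p_low_conf_inside_pqs` vs `p_low_conf_outside`), reproducing the
#' elevated low-confidence error rate seen over G/C-rich quadruplex-prone
#' tracts. With probability `false_mod_rate` an unmethylated truth emits a
#' confident 5mC call. 5hmC never occurs in truth; it arises only through
#' the low-confidence component.
#'
#' @param amp An [amplicon()].
#' @param cpg_index Its [find_cpg_sites()] index.
#' @param pqs_labels `"PQS"`/`"non-PQS"` labels parallel to
#'   `cpg_index$positions` (e.g. from [pqs_cpg_overlap()]).
#' @param truth Either a 2x2 matrix of cell means (rows `"+"`, `"-"`;
#'   columns `"PQS"`, `"non-PQS"`; between-site sd taken as 0), or a list
#'   as from [preset_truth()] with `means` (that matrix) and `site_sd`
#'   (named vector of between-site standard deviations per region).
#' @param noise List with `high_conf_concentration`,
#'   `low_conf_concentration`, `p_low_conf_inside_pqs`,
#'   `p_low_conf_outside`, `false_mod_rate`.
#' @param n_reads_per_strand Reads per strand; default 500.
#' @param seed Optional integer; with a seed the output is a pure function
#'   of `(configuration, seed)`.
#' @return A [mod_calls()] table with every read covering every site,
#'   ordered by strand, read, site.
#' @export
simulate_reads <- function(amp, cpg_index, pqs_labels, truth, noise,
                           n_reads_per_strand = 500L, seed = NULL) {
  stopifnot(inherits(amp, "amplicon"), inherits(cpg_index, "cpg_index"))
  n_sites <- length(cpg_index$positions)
  if (n_sites == 0L) stop("amplicon has no CpG sites", call. = FALSE)
  if (length(pqs_labels) != n_sites)
    stop("'pqs_labels' must label every CpG site (", n_sites, ")",
         call. = FALSE)
  if (!all(pqs_labels %in% c("PQS", "non-PQS")))
    stop("'pqs_labels' values must be 'PQS' or 'non-PQS'", call. = FALSE)
  validate_noise(noise)
  if (is.matrix(truth)) truth <- list(truth = truth)
  if (!is.null(truth$truth) && is.null(truth$means))
    truth$means <- truth$truth
  means <- truth$means
  site_sd <- truth$site_sd
  if (is.null(site_sd)) site_sd <- c("PQS" = 0, "non-PQS" = 0)
  if (!is.matrix(means) || !all(dim(means) == c(2L, 2L)) ||
      any(means < 0 | means > 1))
    stop("'truth' must carry a 2x2 probability matrix of cell means",
         call. = FALSE)
  if (any(site_sd < 0))
    stop("'site_sd' must be non-negative", call. = FALSE)
  if (n_reads_per_strand < 1L) stop("need n_reads_per_strand >= 1",
                                    call. = FALSE)
  run <- function() {
    # per-site propensity, shared between strands, mean-centred per region
    delta <- numeric(n_sites)
    for (rg in c("PQS", "non-PQS")) {
      in_rg <- which(pqs_labels == rg)
      sdv <- if (rg %in% names(site_sd)) site_sd[[rg]] else 0
      if (length(in_rg) >= 2L && sdv > 0) {
        d <- stats::rnorm(length(in_rg), sd = sdv)
        delta[in_rg] <- d - mean(d)
      }
    }
    grid <- data.table::CJ(strand = c("+", "-"),
                           read = seq_len(n_reads_per_strand),
                           site = seq_len(n_sites), sorted = FALSE)
    grid[, region := pqs_labels[site]]
    grid[, p_true := pmin(pmax(
      means[cbind(strand, region)] + delta[site], 0), 1)]
    n <- nrow(grid)
    meth <- stats::runif(n) < grid$p_true
    false_mod <- !meth & stats::runif(n) < noise$false_mod_rate
    emit_m <- meth | false_mod
    p_low <- ifelse(grid$region == "PQS", noise$p_low_conf_inside_pqs,
                    noise$p_low_conf_outside)
    low <- !false_mod & stats::runif(n) < p_low
    tri <- draw_triples(emit_state = ifelse(emit_m, 2L, 1L), low = low,
                        high_conc = noise$high_conf_concentration,
                        low_conc = noise$low_conf_concentration)
    out <- data.table::data.table(
      read_id = paste0(ifelse(grid$strand == "+", "fwd_", "rev_"),
                       formatC(grid$read, width = 5, flag = "0")),
      strand = grid$strand,
      site_pos = cpg_index$positions[grid$site],
      p_c = tri[, 1], p_m = tri[, 2], p_h = tri[, 3])
    data.table::setorder(out, strand, read_id, site_pos)
    mod_calls(out, tol = 1e-9)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

validate_noise <- function(noise) {
  req <- c("high_conf_concentration", "low_conf_concentration",
           "p_low_conf_inside_pqs", "p_low_conf_outside", "false_mod_rate")
  miss <- setdiff(req, names(noise))
  if (length(miss))
    stop("noise config missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  probs <- unlist(noise[c("p_low_conf_inside_pqs", "p_low_conf_outside",
                          "false_mod_rate")])
  if (any(probs < 0 | probs > 1))
    stop("noise probabilities must be in [0, 1]", call. = FALSE)
  if (noise$low_conf_concentration <= 0 ||
      noise$high_conf_concentration <= 0)
    stop("noise concentrations must be positive", call. = FALSE)
  invisible(noise)
}

# emit_state: 1 = canonical, 2 = 5mC. Confident calls: Dirichlet with mass
# high_conc on the emitted state and 0.5 on each other state (point mass
# when high_conc is Inf). Low-confidence calls: symmetric
# Dirichlet(low_conc).
draw_triples <- function(emit_state, low, high_conc, low_conc) {
  n <- length(emit_state)
  alpha <- matrix(0.5, nrow = n, ncol = 3)
  alpha[low, ] <- low_conc
  hi <- which(!low)
  if (is.infinite(high_conc)) {
    tri <- matrix(0, nrow = n, ncol = 3)
    tri[cbind(hi, emit_state[hi])] <- 1
    if (any(low)) {
      lw <- which(low)
      g <- matrix(stats::rgamma(length(lw) * 3, shape = low_conc),
                  ncol = 3)
      tri[lw, ] <- g / rowSums(g)
    }
    return(tri)
  }
  alpha[cbind(hi, emit_state[hi])] <- high_conc
  g <- matrix(stats::rgamma(n * 3, shape = as.vector(alpha)), ncol = 3)
  g / rowSums(g)
}

#' Simulate a two-phase BLI sensorgram
#'
#' [bli_forward()] evaluated on a regular time grid plus i.i.d. Gaussian
#' noise. Defaults mirror a standard single-concentration protocol: 300 s
#' association, 120 s dissociation, 690 nM analyte.
#'
#' @inheritParams bli_forward
#' @param t_dissoc Dissociation phase duration, s.
#' @param dt Sampling interval, s.
#' @param noise_sd Gaussian noise standard deviation (response units);
#'   0 gives the exact forward model.
#' @param seed Optional integer seed.
#' @return A [sensorgram()].
#' @export
simulate_sensorgram <- function(kon, koff, rmax, conc = 690e-9,
                                t_assoc = 300, t_dissoc = 120, dt = 0.5,
                                noise_sd = 0, seed = NULL) {
  stopifnot(t_assoc > 0, t_dissoc > 0, dt > 0, noise_sd >= 0)
  times <- seq(0, t_assoc + t_dissoc, by = dt)
  clean <- bli_forward(times, kon, koff, rmax, conc, t_assoc)
  run <- function() clean + stats::rnorm(length(clean), sd = noise_sd)
  responses <- if (noise_sd == 0) clean
               else if (is.null(seed)) run() else withr::with_seed(seed, run())
  sensorgram(times, responses, conc = conc, t_assoc = t_assoc,
             t_dissoc = t_assoc + t_dissoc)
}

#' Simulate a dose-dependent methylation-inhibition curve
#'
#' Log-logistic model values plus truncated Gaussian noise (clipped to
#' `[0, 1]`).
#'
#' @param f0 Uninhibited methylation fraction.
#' @param ic50 Half-inhibition concentration, M.
#' @param hill Hill slope; default 1.
#' @param concs Inhibitor concentrations, M. The default spans 0 to about
#'   20x the default IC50 in doubling steps.
#' @param noise_sd Gaussian noise sd on the fraction scale.
#' @param seed Optional integer seed.
#' @return An [inhibition_curve()].
#' @export
simulate_inhibition <- function(f0 = 0.95, ic50 = 0.61e-6, hill = 1,
                                concs = c(0, 0.1, 0.2, 0.4, 0.8, 1.6,
                                          3.2, 6.4, 12.8) * 1e-6,
                                noise_sd = 0, seed = NULL) {
  stopifnot(f0 > 0, f0 <= 1, ic50 > 0, hill > 0, noise_sd >= 0)
  clean <- ic50_model(concs, f0, ic50, hill)
  run <- function() clean + stats::rnorm(length(clean), sd = noise_sd)
  y <- if (noise_sd == 0) clean
       else if (is.null(seed)) run() else withr::with_seed(seed, run())
  inhibition_curve(concs, pmin(pmax(y, 0), 1))
}
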