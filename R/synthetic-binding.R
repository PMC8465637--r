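# Synthetic SPR sensorgrams and titration isotherms.

#' Describe an SPR scenario
#'
#' Generator truth for dose-response sensorgrams: a fixed number of protein
#' dimers bound per immobilised DNA sets the true saturating response via
#' the mass-proportionality relation
#' `Rmax = dimers * 2 * (MW_analyte / (bp * mw_per_bp)) * R_L`.
#'
#' @param true_dimers_bound dimers per DNA at saturation.
#' @param mw_analyte analyte monomer mass, Da (default 44000; the
#'   stoichiometry chain is self-consistent under any value because the
#'   generator and estimator share it).
#' @param bp_ligand immobilised DNA length, bp.
#' @param mw_per_bp duplex DNA mass convention, Da/bp (default 660).
#' @param rl_immobilized immobilised DNA amount, RU.
#' @param ka_true,kd_true kinetic truth, 1/(M s) and 1/s.
#' @param concentrations strictly increasing analyte concentrations, M.
#' @param t_assoc,t_dissoc association and dissociation durations, s.
#' @param t_step sampling interval, s.
#' @param noise_sd additive Gaussian noise, RU.
#' @param seed integer seed.
#' @return list of class `spr_scenario`; `rmax_true` is precomputed.
#' @export
spr_scenario <- function(true_dimers_bound = 3, mw_analyte = 44000,
                         bp_ligand = 136, mw_per_bp = 660,
                         rl_immobilized = 300,
                         ka_true = 1e5, kd_true = 1e-2,
                         concentrations = c(0.05, 0.1, 0.25, 0.5, 1,
                                            1.5, 3, 4.5) * 1e-6,
                         t_assoc = 180, t_dissoc = 300, t_step = 1,
                         noise_sd = 5, seed = 1L) {
  stopifnot(true_dimers_bound >= 0, mw_analyte > 0, bp_ligand > 0,
            mw_per_bp > 0, rl_immobilized > 0, ka_true > 0, kd_true > 0,
            noise_sd >= 0)
  if (t_assoc <= 0 || t_dissoc <= 0) stop("durations must be positive")
  if (any(diff(concentrations) <= 0)) {
    stop("concentrations must be strictly increasing")
  }
  mw_ligand <- bp_ligand * mw_per_bp
  structure(list(
    true_dimers_bound = true_dimers_bound, mw_analyte = mw_analyte,
    bp_ligand = bp_ligand, mw_per_bp = mw_per_bp, mw_ligand = mw_ligand,
    rl_immobilized = rl_immobilized, ka_true = ka_true, kd_true = kd_true,
    concentrations = concentrations, t_assoc = t_assoc,
    t_dissoc = t_dissoc, t_step = t_step, noise_sd = noise_sd,
    seed = as.integer(seed),
    rmax_true = true_dimers_bound * 2 * (mw_analyte / mw_ligand) *
      rl_immobilized
  ), class = "spr_scenario")
}

#' Simulate dose-response SPR sensorgrams
#'
#' One sensorgram per scenario concentration, following the 1:1 Langmuir
#' forward model with the scenario's true Rmax plus i.i.d. Gaussian noise.
#' Identical scenario + seed gives bit-identical output.
#'
#' @param s an `spr_scenario`.
#' @return list of `sensorgram` objects (fields `times`, `response`,
#'   `conc`, `t_on`, `t_off`).
#' @export
simulate_sensorgrams <- function(s) {
  stopifnot(inherits(s, "spr_scenario"))
  times <- seq(0, s$t_assoc + s$t_dissoc, by = s$t_step)
  with_seed(derive_seed(s$seed, "sensorgrams"), {
    lapply(seq_along(s$concentrations), function(i) {
      conc <- s$concentrations[i]
      clean <- if (s$rmax_true == 0) {
        numeric(length(times))
      } else {
        langmuir_forward(s$ka_true, s$kd_true, s$rmax_true, conc, times,
                         t_on = 0, t_off = s$t_assoc)
      }
      resp <- clean + stats::rnorm(length(times), 0, s$noise_sd)
      structure(list(times = times, response = resp, conc = conc,
                     t_on = 0, t_off = s$t_assoc),
                class = "sensorgram")
    })
  })
}

#' Describe a titration scenario
#'
#' @param model_kind `"hill"` (cooperative gel-shift style) or
#'   `"depletion"` (tight binding, KD near probe concentration).
#' @param kd_true true apparent KD, nM.
#' @param hill_h_true true Hill coefficient (hill model; >= 1).
#' @param probe_conc labelled probe concentration, nM.
#' @param protein_concs protein concentrations, nM.
#' @param noise_sd additive noise in fraction-bound units.
#' @param seed integer seed.
#' @return list of class `titration_scenario`.
#' @export
titration_scenario <- function(model_kind = c("hill", "depletion"),
                               kd_true = 85, hill_h_true = 3,
                               probe_conc = 15,
                               protein_concs = 10^seq(log10(4), log10(30000),
                                                      length.out = 16),
                               noise_sd = 0.03, seed = 1L) {
  model_kind <- match.arg(model_kind)
  stopifnot(probe_conc > 0, kd_true > 0, noise_sd >= 0)
  if (model_kind == "hill" && hill_h_true < 1) {
    stop("hill_h_true must be >= 1 for the hill model")
  }
  structure(list(model_kind = model_kind, kd_true = kd_true,
                 hill_h_true = hill_h_true, probe_conc = probe_conc,
                 protein_concs = protein_concs, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "titration_scenario")
}

#' Default gel-shift (EMSA) titration scenario
#'
#' Cooperative Hill truth with apparent KD 85 nM, 15 nM probe and protein
#' from 4 nM to 30 uM (the experimental titration range). The Hill
#' coefficient truth of 3 encodes the "sharp slope" of the cooperative
#' three-dimer assembly; no measured value exists, see the methods
#' vignette.
#' @param seed integer seed.
#' @return a `titration_scenario`.
#' @export
default_emsa_scenario <- function(seed = 1L) {
  titration_scenario("hill", kd_true = 85, hill_h_true = 3,
                     probe_conc = 15, seed = seed)
}

#' Default thermophoresis (MST) titration scenario
#'
#' Simple (h = 1) binding truth with KD 140 nM, 25 nM probe, protein from
#' 3.6 nM to 60 uM.
#' @param seed integer seed.
#' @return a `titration_scenario`.
#' @export
default_mst_scenario <- function(seed = 1L) {
  titration_scenario("hill", kd_true = 140, hill_h_true = 1,
                     probe_conc = 25,
                     protein_concs = 10^seq(log10(3.6), log10(60000),
                                            length.out = 16),
                     seed = seed)
}

#' Default ParB-stimulated (depletion regime) titration scenario
#'
#' KD truth 10 nM, close to the 15 nM probe concentration, so the
#' depletion model is required; protein 1-500 nM.
#' @param seed integer seed.
#' @return a `titration_scenario`.
#' @export
default_parb_scenario <- function(seed = 1L) {
  titration_scenario("depletion", kd_true = 10, probe_conc = 15,
                     protein_concs = 10^seq(0, log10(500), length.out = 12),
                     noise_sd = 0.02, seed = seed)
}

#' Simulate a titration isotherm
#'
#' Fraction bound per protein concentration from the scenario's forward
#' model plus Gaussian noise, clipped to `[0, 1]`.
#'
#' @param s a `titration_scenario`.
#' @return list of class `binding_isotherm`: `conc_nM`, `fraction_bound`,
#'   `probe_nM`, `model_kind`.
#' @export
simulate_isotherm <- function(s) {
  stopifnot(inherits(s, "titration_scenario"))
  theta <- switch(s$model_kind,
    hill = hill_model(s$protein_concs, s$kd_true, s$hill_h_true),
    depletion = depletion_model(s$protein_concs, s$probe_conc, s$kd_true),
    stop("unknown model_kind: ", s$model_kind)
  )
  noisy <- with_seed(derive_seed(s$seed, "isotherm"), {
    theta + stats::rnorm(length(theta), 0, s$noise_sd)
  })
  structure(list(conc_nM = s$protein_concs,
                 fraction_bound = pmin(1, pmax(0, noisy)),
                 probe_nM = s$probe_conc, model_kind = s$model_kind),
            class = "binding_isotherm")
}
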