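# End-to-end orchestration: generate synthetic inputs, run every analysis
# stage in dependency order, and emit a reproducible report. A single
# global seed feeds stage-name-keyed substreams so that enabling or
# disabling one stage never reshuffles the randomness of the others.

PIPELINE_STAGES <- c("motifs", "spr", "isotherms", "geometry",
                     "flexibility", "thermal")

#' Validate and normalise a pipeline configuration
#'
#' Accepts a JSON file path or a list. Unknown keys are an error (naming
#' the keys); missing keys are filled with defaults; concentration-like
#' character values such as `"85 nM"` are normalised to molar.
#'
#' @param config path to a JSON config or a list.
#' @return normalised list of class `pipeline_config` with fields `seed`,
#'   `stages`, `out_dir` (NULL for no file output), and per-stage
#'   parameter lists.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  known <- c("seed", "stages", "out_dir", "motifs", "spr", "isotherms",
             "geometry", "flexibility", "thermal")
  extra <- setdiff(names(config), known)
  if (length(extra)) {
    stop("unknown config key(s): ", paste(extra, collapse = ", "))
  }
  out <- list(
    seed = as.integer(config$seed %||% 1L),
    stages = config$stages %||% PIPELINE_STAGES,
    out_dir = config$out_dir %||% NULL,
    motifs = config$motifs %||% list(),
    spr = config$spr %||% list(),
    isotherms = config$isotherms %||% list(),
    geometry = config$geometry %||% list(),
    flexibility = config$flexibility %||% list(),
    thermal = config$thermal %||% list()
  )
  bad <- setdiff(out$stages, PIPELINE_STAGES)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  # unit normalisation for quantity-like strings
  for (st in c("spr", "isotherms")) {
    out[[st]] <- lapply(out[[st]], function(v) {
      if (is.character(v) && length(v) == 1L) parse_quantity(v) else v
    })
  }
  class(out) <- "pipeline_config"
  out
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order over synthetic
#' scenario inputs (or a user FASTA for the motif stage), collecting
#' per-stage results into a report. Identical config + seed gives an
#' identical report (excluding the timestamp). When `out_dir` is set,
#' intermediate files (FASTA, CSV, TSV, JSON report) are written there.
#'
#' @param config a `pipeline_config`, list, or JSON path (passed through
#'   [validate_config()]).
#' @return list of class `pipeline_report`: one element per executed
#'   stage plus `provenance` (config hash, seed, package version).
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "pipeline_config")) config else
    validate_config(config)
  seed <- cfg$seed
  out_dir <- cfg$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  report <- list()
  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  arch_report <- NULL
  if ("motifs" %in% cfg$stages) {
    report$motifs <- run_stage("motifs", function() {
      mp <- cfg$motifs
      if (!is.null(mp$fasta)) {
        seqs <- read_promoter_fasta(mp$fasta)
        seqstr <- seqs[[1]]
        truth <- NULL
      } else {
        prom <- build_promoter_sequence(f_promoter_architecture(),
                                        derive_seed(seed, "motifs"))
        seqstr <- prom$sequence
        truth <- prom$truth
        if (!is.null(out_dir)) {
          write_promoter_fasta(prom, file.path(out_dir, "promoter.fasta"))
        }
      }
      hits <- scan_motifs(seqstr, mp$consensus %||% "CTTTGC",
                          mp$max_mismatch %||% 2L)
      pairs <- find_inverted_repeats(hits,
                                     mp$spacer_min %||% 26L,
                                     mp$spacer_max %||% 29L)
      rep_ <- classify_architecture(hits, pairs, nchar(seqstr))
      if (!is.null(out_dir)) {
        write_motifs_bed(hits, file.path(out_dir, "motif_hits.tsv"))
        write_motifs_bed(pairs, file.path(out_dir, "ir_pairs.tsv"))
      }
      arch_report <<- rep_
      list(n_hits = nrow(hits),
           n_exact = sum(hits$mismatches == 0),
           hits = hits, pairs = pairs, report = rep_, truth = truth)
    })
  }

  if ("spr" %in% cfg$stages) {
    report$spr <- run_stage("spr", function() {
      sp <- cfg$spr
      scen <- spr_scenario(
        true_dimers_bound = sp$true_dimers_bound %||% 3,
        noise_sd = sp$noise_sd %||% 5,
        seed = derive_seed(seed, "spr")
      )
      sg <- simulate_sensorgrams(scen)
      if (!is.null(out_dir)) {
        write_sensorgram_csv(sg, file.path(out_dir, "sensorgrams.csv"))
      }
      fit <- fit_kinetics(sg, mode = sp$mode %||% "local")
      st <- stoichiometry(fit$rmax, scen$mw_analyte, scen$mw_ligand,
                          scen$rl_immobilized)
      list(fit = fit, stoichiometry = st, scenario_rmax = scen$rmax_true)
    })
  }

  if ("isotherms" %in% cfg$stages) {
    report$isotherms <- run_stage("isotherms", function() {
      iso_seed <- derive_seed(seed, "isotherms")
      emsa <- simulate_isotherm(default_emsa_scenario(iso_seed))
      mst <- simulate_isotherm(default_mst_scenario(iso_seed))
      parb <- simulate_isotherm(default_parb_scenario(iso_seed))
      if (!is.null(out_dir)) {
        write_isotherm_csv(emsa, file.path(out_dir, "isotherm_emsa.csv"))
        write_isotherm_csv(mst, file.path(out_dir, "isotherm_mst.csv"))
        write_isotherm_csv(parb, file.path(out_dir, "isotherm_parb.csv"))
      }
      f_emsa <- fit_hill(emsa)
      f_mst <- fit_hill(mst)
      f_parb <- fit_depletion(parb)
      list(emsa = f_emsa, mst = f_mst, parb = f_parb,
           fold_stimulation = fold_stimulation(f_emsa$kd_app,
                                               f_parb$kd_app))
    })
  }

  if ("geometry" %in% cfg$stages) {
    report$geometry <- run_stage("geometry", function() {
      gp <- cfg$geometry
      sep <- gp$center_sep_bp %||% {
        if (!is.null(arch_report) && nrow(arch_report$ir_pairs) &&
            any(arch_report$ir_pairs$irclass == "perfect")) {
          arch_report$ir_pairs$center_distance[
            arch_report$ir_pairs$irclass == "perfect"][1]
        } else 34
      }
      scan <- scan_bend_for_span(sep, gp$span_range %||% c(10, 11))
      list(center_sep_bp = sep,
           contour_nm = sep * 0.34,
           face = face_offset(sep),
           scan = scan)
    })
  }

  if ("flexibility" %in% cfg$stages) {
    report$flexibility <- run_stage("flexibility", function() {
      fp <- cfg$flexibility
      scen <- trajectory_scenario(
        n_frames = fp$n_frames %||% 400L,
        marker_residue = fp$marker_residue %||% 75L,
        marker_displacement = fp$marker_displacement %||% 30,
        seed = derive_seed(seed, "flexibility")
      )
      traj <- simulate_trajectory(scen)
      prof <- fluctuation_profile(traj)
      regions <- flexible_regions(prof)
      disp <- displacement(traj, 1L, scen$n_frames, scen$marker_residue,
                           core = setdiff(seq_len(scen$n_residues),
                                          scen$loop_interval[1]:
                                            scen$loop_interval[2]))
      if (!is.null(out_dir)) {
        write_profile_csv(prof, file.path(out_dir, "bfactor_profile.csv"))
      }
      list(profile = prof, regions = regions,
           marker_displacement_A = disp,
           rmsd_final_A = rmsd_series(traj)[scen$n_frames])
    })
  }

  if ("thermal" %in% cfg$stages) {
    report$thermal <- run_stage("thermal", function() {
      tp <- cfg$thermal
      scens <- default_melt_scenarios(noise_sd = tp$noise_sd %||% 0,
                                      seed = derive_seed(seed, "thermal"))
      tms <- lapply(scens, function(s) extract_tm(simulate_melt_curve(s)))
      tab <- data.frame(condition = names(tms),
                        tm_C = vapply(tms, function(x) x$tm, numeric(1)))
      list(tm_table = tab,
           delta_tm_adp = delta_tm(tms$apo, tms$adp))
    })
  }

  cfg_json <- jsonlite::toJSON(cfg[setdiff(names(cfg), "out_dir")],
                               auto_unbox = TRUE, digits = NA,
                               force = TRUE)
  report$provenance <- list(
    config_hash = hash_string(as.character(cfg_json)),
    seed = seed,
    package_version = as.character(utils::packageVersion("parpromoter"))
  )
  class(report) <- "pipeline_report"
  if (!is.null(out_dir)) {
    writable <- summarise_report(report)
    jsonlite::write_json(writable, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

# flatten a pipeline report into JSON-friendly scalars/tables
summarise_report <- function(report) {
  out <- list(provenance = report$provenance)
  if (!is.null(report$motifs)) {
    out$motifs <- list(n_hits = report$motifs$n_hits,
                       n_exact = report$motifs$n_exact,
                       n_ir_pairs = nrow(report$motifs$pairs),
                       n_singletons = nrow(report$motifs$report$singletons),
                       overlapping_pairs =
                         nrow(report$motifs$report$overlaps) / 2)
  }
  if (!is.null(report$spr)) {
    out$spr <- list(rmax_RU = report$spr$fit$rmax,
                    KD_M = report$spr$fit$KD,
                    monomers_per_dna = report$spr$stoichiometry$S_monomers,
                    dimers_per_dna = report$spr$stoichiometry$S_dimers)
  }
  if (!is.null(report$isotherms)) {
    out$isotherms <- list(emsa_kd_nM = report$isotherms$emsa$kd_app,
                          emsa_h = report$isotherms$emsa$hill_h,
                          mst_kd_nM = report$isotherms$mst$kd_app,
                          parb_kd_nM = report$isotherms$parb$kd_app,
                          fold_stimulation =
                            report$isotherms$fold_stimulation)
  }
  if (!is.null(report$geometry)) {
    out$geometry <- list(center_sep_bp = report$geometry$center_sep_bp,
                         contour_nm = report$geometry$contour_nm,
                         face_offset_deg = report$geometry$face$offset_deg,
                         same_face = report$geometry$face$same_face,
                         best_bend_deg = report$geometry$scan$best_bend,
                         best_chord_nm = report$geometry$scan$best_chord)
  }
  if (!is.null(report$flexibility)) {
    out$flexibility <- list(
      regions = report$flexibility$regions,
      marker_displacement_A = report$flexibility$marker_displacement_A)
  }
  if (!is.null(report$thermal)) {
    out$thermal <- list(tm_table = report$thermal$tm_table,
                        delta_tm_adp_C = report$thermal$delta_tm_adp)
  }
  out
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report (seed ", x$provenance$seed, ", config ",
      x$provenance$config_hash, ")\n", sep = "")
  for (st in setdiff(names(x), "provenance")) {
    cat(" stage:", st, "\n")
  }
  invisible(x)
}
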