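# End-to-end pipeline: build model -> synthetic data -> analysis -> fits.
#
# One nested config drives every stage; all randomness flows from seeds
# recorded in the config, so a rerun with the same config reproduces every
# output byte-for-byte (the log, which records timings, is the only
# exception).

#' Default pipeline configuration
#'
#' The defaults describe the reference system: an antiparallel octamer of
#' 8-residue rings at 4.85 Angstrom spacing (7 interfaces, up to 56
#' backbone hydrogen bonds: 16 cap, 40 core), a 100 ns jittered
#' trajectory, Markov bond kinetics in the regime of a weakly-protected
#' (short-linker) conjugate, micrograph-style length statistics, and a
#' core-shell cylinder SANS synthesis + refit.
#'
#' @param seed Base seed; stage seeds are derived from it deterministically.
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  seed <- as.integer(seed)
  list(
    geometry = list(n_residues = 8L, n_unimers = 8L, radius = 4.0,
                    spacing = 4.85, amide_offset = 0.5,
                    arrangement = "antiparallel"),
    trajectory = list(n_frames = 1000L, frame_dt = 0.1, sigma = 0.2,
                      seed = seed,
                      unbinding = list(enabled = FALSE, event_frame = 500L,
                                       displacement = 10, tilt = 15)),
    kinetics = list(n_cap_bonds = 16L, n_core_bonds = 40L,
                    k_break_cap = 0.12, k_break_core = 0.025,
                    k_reform = 5, frame_dt = 0.1, n_frames = 15000L,
                    seed = seed + 1L),
    criteria = list(d_max = 3.5, theta_min = 120),
    metrics = list(flicker_window = 0L, drop_threshold = 6,
                   persistence = 50L, median_window = 11L),
    lengths = list(n_tubes = 200L, mean_nm = 157, sd_nm = 60,
                   seed = seed + 2L),
    sans = list(R_core = 30, t_shell = 20, L = 800, sld_core = 1.8,
                sld_shell = 5.5, sld_solvent = 6.36, scale = 0.003,
                background = 0.05, rel_noise = 0.05, seed = seed + 3L,
                fixed = c("sld_core", "sld_shell", "sld_solvent")),
    write_trajectory_pdb = FALSE)
}

#' Validate a pipeline configuration
#'
#' @param config Nested configuration list (see [default_config()]).
#' @return `config`, invisibly; errors list every offending field.
#' @export
validate_config <- function(config) {
  problems <- character()
  need <- function(block, field, test, what) {
    v <- config[[block]][[field]]
    if (is.null(v) || !test(v))
      problems <<- c(problems, sprintf("%s$%s (%s)", block, field, what))
  }
  pos <- function(v) is.numeric(v) && length(v) == 1L && v > 0
  nneg <- function(v) is.numeric(v) && length(v) == 1L && v >= 0
  int1 <- function(v) is.numeric(v) && length(v) == 1L && v == round(v)

  need("geometry", "n_residues", function(v) int1(v) && v >= 4 &&
         v %% 2 == 0, "even integer >= 4")
  need("geometry", "n_unimers", function(v) int1(v) && v >= 1,
       "integer >= 1")
  need("geometry", "radius", pos, "positive")
  need("geometry", "spacing", pos, "positive")
  need("geometry", "amide_offset", pos, "positive")
  need("trajectory", "n_frames", function(v) int1(v) && v >= 1,
       "integer >= 1")
  need("trajectory", "frame_dt", pos, "positive ns")
  need("trajectory", "sigma", nneg, ">= 0 Angstrom")
  need("trajectory", "seed", int1, "integer seed")
  for (f in c("k_break_cap", "k_break_core", "k_reform"))
    need("kinetics", f, nneg, ">= 0 1/ns")
  need("kinetics", "seed", int1, "integer seed")
  need("criteria", "d_max", pos, "positive Angstrom")
  need("criteria", "theta_min", function(v) is.numeric(v) && v >= 0 &&
         v <= 180, "degrees in [0, 180]")
  need("metrics", "flicker_window", nneg, ">= 0 frames")
  need("lengths", "seed", int1, "integer seed")
  need("sans", "seed", int1, "integer seed")
  if (length(problems))
    stop("invalid config fields:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  invisible(config)
}

# Stable hash of the semantic config content.
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(config), f)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline
#'
#' Stages: build the ideal nanotube model; generate a jittered trajectory
#' (with an optional scripted cap-unbinding event); detect hydrogen bonds
#' per frame; compute the stability report; run the Markov bond-kinetics
#' simulation and compare estimated break rates against truth; summarize
#' synthetic tube lengths; synthesize and refit a SANS curve. Every output
#' JSON carries the config hash.
#'
#' @param config Configuration list, see [default_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with all in-memory results.
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  log_path <- file.path(out_dir, "log.txt")
  logf <- function(...) {
    msg <- sprintf(...)
    message(msg)
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
  }
  put_json <- function(x, name) {
    x$config_hash <- hash
    jsonlite::write_json(x, file.path(out_dir, name), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  t0 <- proc.time()[["elapsed"]]
  cat(sprintf("run started (R %s.%s, cpnano %s)\n",
              R.version$major, R.version$minor,
              as.character(utils::packageVersion("cpnano"))),
      file = log_path)
  writeLines(yaml::as.yaml(config), file.path(out_dir, "config.yaml"))

  g <- config$geometry
  ring <- build_ring(g$n_residues, g$radius, g$amide_offset)
  model <- stack_rings(ring, g$n_unimers, g$spacing, g$arrangement)
  write_structure(model, file.path(out_dir, "model.pdb"))
  put_json(model_metadata(model), "model_metadata.json")
  logf("model: %d rings, %d interfaces, up to %d H-bonds",
       model$n_unimers, n_interfaces(model),
       model$n_residues * n_interfaces(model))

  tr <- config$trajectory
  traj <- jitter_trajectory(model, tr$n_frames, tr$sigma, tr$frame_dt,
                            tr$seed)
  if (isTRUE(tr$unbinding$enabled))
    traj <- script_cap_unbinding(traj, tr$unbinding$event_frame,
                                 tr$unbinding$displacement,
                                 tr$unbinding$tilt)
  if (isTRUE(config$write_trajectory_pdb))
    write_trajectory(traj, file.path(out_dir, "trajectory.pdb"))

  crit <- hbond_criteria(config$criteria$d_max, config$criteria$theta_min)
  m <- config$metrics
  rep <- stability_report(traj, crit, m$flicker_window, m$drop_threshold,
                          m$persistence, m$median_window)
  utils::write.csv(rep$counts, file.path(out_dir, "hbond_counts.csv"),
                   row.names = FALSE)
  utils::write.csv(rep$dissociation_events,
                   file.path(out_dir, "dissociation_events.csv"),
                   row.names = FALSE)
  sr <- unclass(rep)
  sr$counts <- NULL
  sr$dissociation_events <- NULL
  put_json(sr, "stability_report.json")
  logf("trajectory: mean %.1f bonds/frame, BHB %.3g/ns, %d event(s)",
       rep$mean_count_total, rep$bhb_total, nrow(rep$dissociation_events))

  kc <- config$kinetics
  bs <- simulate_bond_states(kc$n_cap_bonds, kc$n_core_bonds,
                             kc$k_break_cap, kc$k_break_core, kc$k_reform,
                             kc$frame_dt, kc$n_frames, kc$seed)
  kr <- broken_bonds_per_ns(bs, m$flicker_window)
  expected <- function(n, kb) n * kb * kc$k_reform / (kb + kc$k_reform)
  kin <- list(estimated = unclass(kr)[c("bhb_total", "bhb_cap", "bhb_core")],
              expected = list(
                bhb_cap = expected(kc$n_cap_bonds, kc$k_break_cap),
                bhb_core = expected(kc$n_core_bonds, kc$k_break_core)),
              truth = bs$truth)
  put_json(kin, "kinetics_report.json")
  logf("kinetics: BHB %.3g/ns estimated vs %.3g/ns expected",
       kr$bhb_total, kin$expected$bhb_cap + kin$expected$bhb_core)

  lc <- config$lengths
  lens <- simulate_tem_lengths(lc$n_tubes, lc$mean_nm, lc$sd_nm, lc$seed)
  ls <- summarize_lengths(lens)
  lsum <- unclass(ls)
  lsum$bins <- NULL
  lsum$mean_unimers <- length_to_unimer_count(ls$mean_nm,
                                              g$spacing / 10)
  put_json(lsum, "length_summary.json")
  logf("lengths: %d tubes, mean %.1f nm (~%d unimers)",
       ls$n_tubes, ls$mean_nm, lsum$mean_unimers)

  sc <- config$sans
  true_p <- core_shell_cylinder(sc$R_core, sc$t_shell, sc$L, sc$sld_core,
                                sc$sld_shell, sc$sld_solvent, sc$scale,
                                sc$background)
  curve <- synthesize_sans_curve(true_p, rel_noise = sc$rel_noise,
                                 seed = sc$seed)
  write_sans_curve(curve, file.path(out_dir, "sans_curve.csv"))
  init <- true_p
  for (nm in setdiff(names(unclass(init)), sc$fixed))
    init[[nm]] <- init[[nm]] * 1.5
  class(init) <- "core_shell_cylinder"
  fit <- fit_sans_cylinder(curve, init, fixed = sc$fixed)
  put_json(list(fitted = unclass(fit$params), true = unclass(true_p),
                chisq_red = fit$chisq_red, converged = fit$converged),
           "sans_fit.json")
  logf("sans: R_core %.3g A (true %.3g), t_shell %.3g A (true %.3g), chi2_red %.3g",
       fit$params$R_core, sc$R_core, fit$params$t_shell, sc$t_shell,
       fit$chisq_red)

  summary_lines <- c(
    sprintf("config hash: %s", hash),
    sprintf("model: %d rings x %d residues, %d interfaces, max %d H-bonds (%d cap / %d core)",
            model$n_unimers, model$n_residues, n_interfaces(model),
            model$n_residues * n_interfaces(model),
            model$n_residues * sum(interface_classes(model$n_unimers) == "cap"),
            model$n_residues * sum(interface_classes(model$n_unimers) == "core")),
    sprintf("trajectory: %d frames x %.3g ns, sigma %.2g A", tr$n_frames,
            tr$frame_dt, tr$sigma),
    sprintf("mean H-bond count: %.2f (cap %.2f, core %.2f)",
            rep$mean_count_total, rep$mean_count_cap, rep$mean_count_core),
    sprintf("BHB/ns: total %.4g, cap %.4g, core %.4g (flicker window %d)",
            rep$bhb_total, rep$bhb_cap, rep$bhb_core, m$flicker_window),
    sprintf("mean inter-unimer spacing: %.3f A", rep$mean_spacing),
    sprintf("dissociation events: %d", nrow(rep$dissociation_events)),
    sprintf("kinetics check: estimated %.4g vs expected %.4g BHB/ns",
            kr$bhb_total, kin$expected$bhb_cap + kin$expected$bhb_core),
    sprintf("tube lengths: mean %.1f nm ~ %d unimers", ls$mean_nm,
            lsum$mean_unimers),
    sprintf("SANS refit: R_core %.4g A, t_shell %.4g A, L %.5g A, chi2_red %.3g",
            fit$params$R_core, fit$params$t_shell, fit$params$L,
            fit$chisq_red))
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))
  logf("run finished in %.1f s", proc.time()[["elapsed"]] - t0)

  invisible(list(model = model, trajectory = traj, stability = rep,
                 kinetics = kin, lengths = ls, sans_fit = fit,
                 config_hash = hash))
}
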