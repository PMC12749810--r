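#' End-to-end demonstration run on synthetic data
#'
#' Generates a small synthetic plate, a dose series of growth movies and a
#' FUCCI time-lapse, runs every pipeline (meniscus simulation, plate QC,
#' height-map extraction, confluency + IC50, cell-cycle scoring and
#' tracking) and writes CSV/JSON artifacts plus a summary.  All randomness
#' derives from `seed`; outputs are byte-identical across runs.
#'
#' @param seed master seed.
#' @param out_dir output directory (created if missing).
#' @param n_wells wells on the synthetic QC plate.
#' @param quiet suppress progress messages.
#' @return (invisibly) the summary list.
#' @export
run_demo <- function(seed = 1, out_dir = "gelplate-demo", n_wells = 24,
                     quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) gp_log("info", ...)
  seeds <- derive_seeds(seed, 4)
  pars <- default_params()

  say("meniscus model")
  men <- solve_wall_meniscus(ul_to_m3(50), pars$well, pars$fluid,
                             pars$wetting$theta_wall)
  prot <- dispense_protocol(data.frame(action = c("dispense", "aspirate"),
                                       volume = ul_to_m3(c(12, 12))))
  sim <- simulate_protocol(prot, pars$well, pars$fluid, pars$wetting)
  men_metrics <- list(
    meniscus_coverage = coverage_metric(men, pars$well),
    meniscus_flatness = flatness_metric(men, pars$well),
    film_coverage = sim$coverage, film_flatness = sim$flatness,
    flatness_fold = sim$flatness / flatness_metric(men, pars$well),
    wall_contact = sim$wall_contact_ever)
  utils::write.csv(sim$trajectory, file.path(out_dir, "trajectory.csv"),
                   row.names = FALSE)
  prof_df <- data.frame(r_mm = sim$final_profile$r * 1e3,
                        z_um = sim$final_profile$z * 1e6)
  utils::write.csv(prof_df, file.path(out_dir, "final_profile.csv"),
                   row.names = FALSE)

  say("plate QC (", n_wells, " wells)")
  plate <- generate_plate(n_wells, seed = seeds[1])
  rep <- qc_plate(plate, out_dir = file.path(out_dir, "qc"))
  truth_cls <- vapply(plate, function(w)
    c(planar = "planar", meniscus = "bad", concave = "concave",
      empty = "empty")[[w$truth$class]], "")
  qc_acc <- mean(rep$records$qc_class == truth_cls)

  say("height-map extraction")
  ph <- generate_well_phantom(phantom_spec(gel_height_um = 20, z_step_um = 2,
                                           n_slices = 16,
                                           bead_density = 1.5e-2,
                                           pixel_size_um = 5,
                                           seed = seeds[2]))
  hm <- extract_height_map(stack_channel(canonical_stack(ph$stack), "gel"),
                           z_step_um = 2)
  med_h <- median(hm$heights[hm$heights > 0])

  say("confluency dose series + IC50")
  exp <- run_ic50_experiment(seeds[3], n_replicates = 2, n_boot = 50)
  fit <- exp$fit
  utils::write.csv(exp$responses, file.path(out_dir, "dose_response.csv"),
                   row.names = FALSE)

  say("cell-cycle scoring + tracking")
  fu <- generate_fucci_timelapse(n_cells = 30, n_frames = 8,
                                 mitotic_fraction = 0.2, seed = seeds[4])
  arr <- fu$stack$pixels
  dets <- list()
  for (t in seq_len(dim(arr)[1])) {
    fr <- array(arr[t, , , ], dim(arr)[2:4])
    labs <- array(fu$labels[t, , ], dim(arr)[3:4])
    nuc <- classify_nuclei(fr, labs)
    mit <- detect_mitotic(fr, labs, substrate = "hydrogel")
    nuc$mitotic <- mit$mitotic[match(nuc$label_id, mit$label_id)]
    nuc$frame <- t
    dets[[t]] <- nuc
  }
  nuclei <- do.call(rbind, dets)
  utils::write.csv(nuclei, file.path(out_dir, "nuclei.csv"),
                   row.names = FALSE)
  tr <- link_tracks(nuclei, pixel_size_um = 1)
  utils::write.csv(tr$tracks, file.path(out_dir, "tracks.csv"),
                   row.names = FALSE)

  summary <- list(
    seed = seed,
    meniscus = men_metrics,
    qc = list(accuracy = qc_acc,
              class_fractions = as.list(rep$class_fractions)),
    height_map = list(median_height_um = med_h, true_height_um = 20),
    ic50 = list(fitted = fit$ic50, true = 18, hill = fit$hill),
    cell_cycle = list(
      n_nuclei = nrow(nuclei),
      class_counts = as.list(table(nuclei$cycle_class)),
      mitotic_fraction = mean(nuclei$mitotic, na.rm = TRUE),
      n_tracks = length(unique(tr$tracks$track_id))))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_resolved_config(list(seed = seed, out_dir = out_dir), out_dir)
  say("done: ", out_dir)
  invisible(summary)
}
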