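## End-to-end pipeline: fixtures -> grids -> docking -> clustering ->
## configuration classification -> H-bond tabulation -> report, driven by
## one flat key = value configuration with full defaults.

.pipeline_defaults <- list(
  seed = 1,
  ## BD protocol
  timestep = 1, start_radius = 185, stop_radius = 204, n_trajectories = 20000,
  encounter_c2c_max = 98, encounter_dyad_max = 40, dedup_rmsd = 1,
  capacity = 5000, n_clusters = 10, max_steps = 2.5e5,
  energy_mode = "one_sided", auto_scale = TRUE,
  ## electrostatics
  grid_spacing = 1.0, temperature = 298.15, ionic_strength = 0.100,
  eps_solvent = 78.54, eps_solute = 2, excluded_margin = 0.5,
  fit_charges = FALSE, grid_cutoff = Inf,
  ## analysis
  hbond_min = 3.2, hbond_max = 3.6, contact_cutoff = 5.0,
  helical_repeat = 10.4, theta_x = 30,
  ## fixtures
  core_bp = 147, l_dna_bp = 18, lh_size = 80, lh_net_charge = 11,
  ## panels: conformers "a1:a2;a1:a2;..." (opening angles, degrees),
  ## variants "V80K,S67ph,..."
  conformers = "0:0", variants = "")

.logical_keys <- c("auto_scale", "fit_charges")
.character_keys <- c("energy_mode", "conformers", "variants")

#' Validate and normalize a pipeline configuration
#'
#' Accepts a named list, a path to a flat `key = value` text file
#' (`#` comments allowed), or `NULL` (all defaults). Every protocol
#' default is filled in (1 ps time step; 185/204 A start/stop; 98/40 A
#' encounter criteria; 1 A deduplication RMSD; 5000-complex archive; 10
#' clusters; 20000 trajectories; 3.2-3.6 A H-bond window; 0.5 A excluded
#' volume margin; 298.15 K; dielectric constants 78.54/2; 100 mM ionic
#' strength). Unknown keys and contradictory values are errors.
#'
#' @param config named list, file path, or NULL.
#' @return normalized configuration list of class `pipeline_config`.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- .read_config_file(config)
  }
  if (is.null(config)) config <- list()
  unknown <- setdiff(names(config), names(.pipeline_defaults))
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(.pipeline_defaults, config)
  for (k in names(cfg)) {
    if (k %in% .logical_keys) {
      cfg[[k]] <- as.logical(cfg[[k]])
      if (is.na(cfg[[k]])) stop("key ", k, " must be TRUE or FALSE")
    } else if (!(k %in% .character_keys)) {
      v <- suppressWarnings(as.numeric(cfg[[k]]))
      if (is.na(v)) stop("key ", k, " must be numeric")
      cfg[[k]] <- v
    }
  }
  if (!cfg$energy_mode %in% c("one_sided", "symmetrized")) {
    stop("energy_mode must be 'one_sided' or 'symmetrized'")
  }
  problems <- character(0)
  if (cfg$stop_radius <= cfg$start_radius) {
    problems <- c(problems, "stop_radius must exceed start_radius")
  }
  if (cfg$start_radius <= cfg$encounter_c2c_max && !cfg$auto_scale) {
    problems <- c(problems, "start_radius must exceed encounter_c2c_max")
  }
  if (cfg$hbond_min > cfg$hbond_max) {
    problems <- c(problems, "hbond_min must not exceed hbond_max")
  }
  if (cfg$capacity <= 0) problems <- c(problems, "capacity must be positive")
  if (length(problems) > 0) stop(paste(problems, collapse = "; "))
  structure(cfg, class = "pipeline_config")
}

.read_config_file <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_0-9]+)\\s*[=:]\\s*(.*)$", ln))[[1]]
    if (length(m) == 0) stop("malformed config line: ", ln)
    out[[m[2]]] <- trimws(m[3])
  }
  out
}

.parse_conformers <- function(text) {
  parts <- strsplit(trimws(text), ";")[[1]]
  parts <- parts[nzchar(parts)]
  out <- lapply(parts, function(p) {
    ab <- as.numeric(strsplit(p, ":")[[1]])
    if (length(ab) != 2 || any(is.na(ab))) stop("malformed conformer spec: ", p)
    ab
  })
  names(out) <- sprintf("conf%d", seq_along(out))
  out
}

.parse_variants <- function(text) {
  v <- strsplit(trimws(text), ",")[[1]]
  trimws(v[nzchar(trimws(v))])
}

## derived seed for a (variant, conformer) docking run
.run_seed <- function(master, vi, ci) {
  as.integer((as.numeric(master) * 2654435 + vi * 97561 + ci * 1013) %%
               2147480017 + 1)
}

#' Run the full docking pipeline
#'
#' Builds the synthetic fixtures, computes grids, docks every requested
#' LH variant to every nucleosome conformer, clusters and classifies the
#' encounter complexes, tabulates hydrogen bonds of the top-two cluster
#' representatives, and writes all artifacts plus a reproducibility
#' manifest to `output_dir`.
#'
#' Artifacts: `records.csv` (recorded set of the reference run),
#' `clusters.json` (all runs), `configurations.csv` (variant x conformer
#' matrix with match categories), `hbonds.csv` (per-residue totals),
#' `manifest.json`, `pipeline.log`.
#'
#' @param config configuration (list, file path or NULL), see
#'   [validate_config()].
#' @param output_dir output directory (created if absent).
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the in-memory results (`matrix`,
#'   `hbonds`, `runs`, `config`, `manifest`).
#' @export
run_pipeline <- function(config = NULL, output_dir = tempfile("chromadock_"),
                         quiet = FALSE) {
  cfg <- validate_config(config)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(output_dir, "pipeline.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con), add = TRUE)
  say <- function(...) {
    msg <- sprintf(...)
    writeLines(msg, log_con)
    if (!quiet) message(msg)
  }
  stage <- function(name, expr) {
    say("[%s] start", name)
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    say("[%s] done in %.1f s", name, as.numeric(difftime(Sys.time(), t0, "secs")))
    res
  }

  conformers <- .parse_conformers(cfg$conformers)
  variants <- .parse_variants(cfg$variants)

  ## -- fixtures ---------------------------------------------------------
  fx <- stage("fixtures", {
    lh_wt <- build_toy_lh(fixture_spec(lh_size = cfg$lh_size,
                                       lh_net_charge = cfg$lh_net_charge,
                                       l_dna_bp = cfg$l_dna_bp,
                                       core_bp = cfg$core_bp,
                                       seed = cfg$seed))
    nucs <- lapply(conformers, function(ab) {
      build_ideal_nucleosome(fixture_spec(core_bp = cfg$core_bp,
                                          l_dna_bp = cfg$l_dna_bp,
                                          opening_angle_1 = ab[1],
                                          opening_angle_2 = ab[2],
                                          seed = cfg$seed))
    })
    lhs <- c(list(WT = lh_wt),
             stats::setNames(lapply(variants, function(v) {
               apply_variants(lh_wt, v)
             }), variants))
    say("fixtures: LH %+d e, %d variant(s), %d conformer(s)",
        net_formal_charge(lh_wt$solute), length(variants), length(nucs))
    list(lhs = lhs, nucs = nucs)
  })

  base_bd <- bd_config(timestep = cfg$timestep, start_radius = cfg$start_radius,
                       stop_radius = cfg$stop_radius,
                       n_trajectories = cfg$n_trajectories,
                       encounter_c2c_max = cfg$encounter_c2c_max,
                       encounter_dyad_max = cfg$encounter_dyad_max,
                       dedup_rmsd = cfg$dedup_rmsd, capacity = cfg$capacity,
                       n_clusters = cfg$n_clusters, rng_seed = cfg$seed,
                       max_steps = cfg$max_steps,
                       energy_mode = cfg$energy_mode,
                       auto_scale = cfg$auto_scale)

  ## -- grids (per conformer) -------------------------------------------
  grids <- stage("grids", {
    lapply(fx$nucs, function(nuc) {
      g <- prepare_docking(fx$lhs$WT, nuc, base_bd, spacing = cfg$grid_spacing,
                           fit_charges = cfg$fit_charges,
                           cutoff = cfg$grid_cutoff)
      say("grid %dx%dx%d @ %.1f A, nucleosome %+d e", g$nuc_grid$dims[1],
          g$nuc_grid$dims[2], g$nuc_grid$dims[3], cfg$grid_spacing,
          round(g$nuc_grid$tail_Q))
      g
    })
  })

  ## -- docking / clustering / classification ---------------------------
  runs <- stage("dock", {
    out <- list()
    for (vi in seq_along(fx$lhs)) {
      vname <- names(fx$lhs)[vi]
      lh_v <- fx$lhs[[vi]]
      out[[vname]] <- list()
      for (ci in seq_along(fx$nucs)) {
        cname <- names(fx$nucs)[ci]
        nuc <- fx$nucs[[ci]]
        bd <- base_bd
        if (cfg$auto_scale) bd <- scale_bd_config(bd, nuc)
        bd$rng_seed <- .run_seed(cfg$seed, vi, ci)
        ## variant charges: the LH charge set must match the docked variant
        gr <- grids[[ci]]
        gr$lh_charges <- if (cfg$fit_charges) {
          fit_effective_charges(lh_v$solute,
                                debye_huckel_grid(lh_v$solute,
                                                  spacing = cfg$grid_spacing))
        } else formal_effective_charges(lh_v$solute)
        rs <- run_docking(lh_v, nuc, gr, bd)
        cl <- cluster_recorded_set(rs, k = min(bd$n_clusters, max(rs$n, 1)))
        sites <- groove_site_coords(enumerate_groove_sites(
          nuc, helical_repeat = cfg$helical_repeat), nuc)
        cfgs <- lapply(top_clusters(cl, 2), function(c1) {
          classify(lh_v, c1$representative_pose, nuc, sites = sites,
                   cutoff = cfg$contact_cutoff, theta_x = cfg$theta_x)
        })
        if (length(cfgs) == 0) {
          ## no encounters recorded at this scale: an empty configuration
          empty <- structure(list(contacts = list(alpha3 = integer(0),
                                                  beta1 = integer(0),
                                                  l1 = integer(0)),
                                  alpha3_symbol = "X", dyad_mode = "none"),
                             class = "lh_configuration")
          empty$string <- format(empty)
          cfgs <- list(empty)
        }
        say("dock %s/%s: %.0f encounters, %d records, %d clusters, top %s [%s]",
            vname, cname, rs$seen, rs$n, length(cl),
            if (length(cfgs) > 0) cfgs[[1]]$string else "-",
            if (length(cfgs) > 0) cfgs[[1]]$dyad_mode else "-")
        out[[vname]][[cname]] <- list(recorded = rs, clusters = cl,
                                      configurations = cfgs, nuc = nuc,
                                      lh = lh_v)
      }
    }
    out
  })

  ## -- configuration matrix (largest cluster per run) -------------------
  mat <- stage("classify", {
    cfg_map <- lapply(runs, function(v) {
      lapply(v, function(r) r$configurations[[1]])
    })
    build_match_matrix(cfg_map, reference = "WT")
  })

  ## -- H-bonds of the top-two cluster representatives -------------------
  hb <- stage("hbonds", {
    per_variant <- lapply(names(runs), function(vname) {
      tabs <- list()
      for (cname in names(runs[[vname]])) {
        r <- runs[[vname]][[cname]]
        tops <- top_clusters(r$clusters, 2)
        for (ti in seq_along(tops)) {
          tabs[[sprintf("%s_c%d", cname, ti)]] <-
            find_hbonds(r$lh, tops[[ti]]$representative_pose, r$nuc,
                        d_min = cfg$hbond_min, d_max = cfg$hbond_max)
        }
      }
      agg <- aggregate_hbonds(tabs)
      say("hbonds %s: total %d", vname, agg$total)
      agg
    })
    names(per_variant) <- names(runs)
    per_variant
  })

  ## -- report -----------------------------------------------------------
  manifest <- stage("report", {
    ref <- runs$WT[[1]]
    utils::write.csv(as.data.frame(ref$recorded),
                     file.path(output_dir, "records.csv"), row.names = FALSE)
    cl_json <- lapply(runs, function(v) lapply(v, function(r) {
      clusters_to_list(r$clusters)
    }))
    jsonlite::write_json(cl_json, file.path(output_dir, "clusters.json"),
                         auto_unbox = TRUE, digits = NA)
    mat_out <- mat
    attr(mat_out, "shift_counts") <- NULL
    utils::write.csv(mat_out, file.path(output_dir, "configurations.csv"),
                     row.names = FALSE)
    hb_rows <- do.call(rbind, lapply(names(hb), function(v) {
      pr <- hb[[v]]$per_residue
      if (nrow(pr) == 0) return(NULL)
      cbind(variant = v, pr)
    }))
    if (is.null(hb_rows)) {
      hb_rows <- data.frame(variant = character(0), residue_index = integer(0),
                            residue_name = character(0), n_hbonds = numeric(0),
                            multiple = logical(0))
    }
    utils::write.csv(hb_rows, file.path(output_dir, "hbonds.csv"),
                     row.names = FALSE)
    arts <- c("records.csv", "clusters.json", "configurations.csv", "hbonds.csv")
    hashes <- tools::md5sum(file.path(output_dir, arts))
    names(hashes) <- arts
    man <- list(config = unclass(cfg), master_seed = cfg$seed,
                package_version = as.character(utils::packageVersion("chromadock")),
                r_version = R.version.string,
                timestamp = format(Sys.time(), tz = "UTC"),
                artifacts = as.list(hashes),
                shift_counts = as.list(attr(mat, "shift_counts")),
                counts = list(
                  trajectories = cfg$n_trajectories * length(runs) *
                    length(conformers),
                  encounters_seen = sum(vapply(runs, function(v) {
                    sum(vapply(v, function(r) r$recorded$seen, numeric(1)))
                  }, numeric(1))),
                  records_kept = sum(vapply(runs, function(v) {
                    sum(vapply(v, function(r) r$recorded$n, numeric(1)))
                  }, numeric(1)))))
    jsonlite::write_json(man, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    man
  })
  say("pipeline complete: %s", output_dir)
  invisible(list(matrix = mat, hbonds = hb, runs = runs, config = cfg,
                 manifest = manifest, output_dir = output_dir))
}

#' Rescale the start/stop spheres to the system size
#'
#' start = nucleosome bounding radius + 30 A, stop = start + 19 A, the
#' same offsets as the full-scale protocol relative to its system.
#'
#' @param config a [bd_config].
#' @param nuc a `nucleosome_model`.
#' @return the adjusted `bd_config`.
#' @export
scale_bd_config <- function(config, nuc) {
  xyz <- as.matrix(nuc$solute$atoms[, c("x", "y", "z")])
  ctr <- colMeans(xyz)
  b <- sqrt(max(rowSums(sweep(xyz, 2, ctr)^2)))
  config$start_radius <- b + 30
  config$stop_radius <- config$start_radius + 19
  validate_bd_config(config)
  config
}
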