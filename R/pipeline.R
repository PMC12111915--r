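# Configuration-driven orchestration: run any analysis stage, or the full
# multi-condition comparison workflow, from files. Outputs are flat
# CSV/JSON with a metadata sidecar per stage (config hash, seed, package
# version and every default that matters for auditability).

#' Read a run configuration
#'
#' YAML configuration for one condition. Recognised keys: `name`,
#' `structure` (PDB/PQR path), `trajectory` (DCD or multi-model PDB path),
#' `dt` (ns), `box`, `seed`, `output_dir`, `log_level`, `selections`
#' (named selection expressions: `ligand`, `ion`, `water`, `protein`, ...),
#' `domains` (named `[from, to]` residue ranges), `distance_pairs` (list of
#' `{label, selA, selB}`), `ligand_atom_map` (e.g. phosphate labels to atom
#' names), `criteria` (overrides for [contact_criteria()]), `analyses`
#' (enabled stage names), per-stage parameter blocks (`msd`, `rdf`,
#' `energy`, ...), and `simulate` (generator spec used instead of input
#' files).
#'
#' @param path YAML file, or a named list already in memory.
#' @return List of class `"run_config"`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  cfg$name <- cfg$name %||% "condition"
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$output_dir <- cfg$output_dir %||% file.path(tempdir(), cfg$name)
  cfg$log_level <- cfg$log_level %||% "info"
  cfg$selections <- cfg$selections %||% list()
  cfg$analyses <- cfg$analyses %||% character()
  if (is.null(cfg$simulate)) {
    for (f in c("structure", "trajectory")) {
      if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
        abort(paste0("config error: ", f, " file does not exist: ", cfg[[f]]))
      }
    }
    if (is.null(cfg$structure) && is.null(cfg$trajectory)) {
      abort("config error: need either input files or a simulate block")
    }
    if (is.null(cfg$dt)) abort("config error: dt (ns per frame) is required")
  }
  structure(cfg, class = c("run_config", "list"))
}

log_levels <- c(debug = 1L, info = 2L, warning = 3L, error = 4L)

pipe_log <- function(cfg, level, msg) {
  if (log_levels[[level]] >= log_levels[[cfg$log_level %||% "info"]]) {
    inform(paste0("[", cfg$name, "] ", msg))
  }
  logfile <- file.path(cfg$output_dir, "run.log")
  if (dir.exists(cfg$output_dir)) {
    cat(sprintf("%s %-7s %s\n", format(Sys.time(), "%H:%M:%S"), level, msg),
        file = logfile, append = TRUE)
  }
  invisible(NULL)
}

config_selection <- function(cfg, top, key, default = NULL, required = TRUE) {
  expr <- cfg$selections[[key]] %||% default
  if (is.null(expr)) {
    if (required) abort(paste0("config error: no selection named \"", key, "\""))
    return(NULL)
  }
  sel <- select_atoms(top, expr, label = key)
  if (required && length(sel) == 0L) {
    abort(paste0("config error: selection \"", key, "\" (", expr,
                 ") matches no atoms"))
  }
  sel
}

config_criteria <- function(cfg) {
  do.call(contact_criteria, cfg$criteria %||% list())
}

config_domains <- function(cfg) {
  if (is.null(cfg$domains)) return(domain_map())
  do.call(domain_map, lapply(cfg$domains, as.integer))
}

# build or load the condition's trajectory
pipeline_trajectory <- function(cfg) {
  if (!is.null(cfg$simulate)) {
    sim <- cfg$simulate
    kind <- sim$kind %||% abort("config error: simulate block needs a kind")
    seed <- as.integer(sim$seed %||% cfg$seed)
    switch(
      kind,
      brownian = gen_brownian(
        n_particles = sim$n_particles %||% 10L, D = sim$D %||% 0.1,
        dt = sim$dt %||% 0.1, n_frames = sim$n_frames %||% 500L,
        box = unlist(sim$box %||% c(50, 50, 50)), seed = seed
      ),
      ou_tethered = gen_ou_tethered(
        sigma = sim$sigma %||% 1, tau_relax = sim$tau_relax %||% 1,
        center = unlist(sim$center %||% c(0, 0, 0)), dt = sim$dt %||% 0.1,
        n_frames = sim$n_frames %||% 500L, seed = seed,
        n_particles = sim$n_particles %||% 1L
      ),
      ideal_gas = gen_ideal_gas(
        density = sim$density %||% 0.0334,
        box = unlist(sim$box %||% c(30, 30, 30)),
        n_frames = sim$n_frames %||% 10L, seed = seed
      ),
      hydration_shell = gen_hydration_shell(
        shells = lapply(sim$shells %||% list(c(2.4, 6)), unlist),
        jitter = sim$jitter %||% 0, n_frames = sim$n_frames %||% 10L,
        seed = seed, box = unlist(sim$box %||% c(30, 30, 30))
      ),
      rigid_body = gen_rigid_body_protein(
        n_residues = sim$n_residues %||% 50L,
        per_residue_noise = sim$per_residue_noise %||% 0.5,
        n_frames = sim$n_frames %||% 200L, seed = seed
      ),
      abort(paste0("config error: unknown simulate kind \"", kind, "\""))
    )
  } else {
    st <- load_structure(cfg$structure)
    if (is.null(cfg$trajectory)) {
      trajectory(st$topology, array(st$coords, c(1L, nrow(st$coords), 3L)),
                 dt = cfg$dt %||% 1, box = unlist(cfg$box) %||% st$box)
    } else {
      load_trajectory(cfg$trajectory, st$topology, dt = cfg$dt,
                      box = unlist(cfg$box) %||% st$box)
    }
  }
}

pipeline_stages <- c(
  "simulate", "msd", "diffusion", "rdf", "rmsd", "rg", "rmsf", "distances",
  "contacts", "intra-hbonds", "coordination", "energy", "compare"
)

write_stage_output <- function(cfg, stage, df, extra_meta = list()) {
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(cfg$output_dir, paste0(gsub("-", "_", stage), ".csv"))
  write.csv(as.data.frame(df), csv, row.names = FALSE)
  meta <- c(
    list(
      stage = stage, condition = cfg$name, seed = cfg$seed,
      config_hash = rlang::hash(unclass(cfg)),
      package_version = as.character(utils::packageVersion("tidytraj")),
      rows = nrow(df)
    ),
    extra_meta
  )
  sidecar <- file.path(cfg$output_dir, paste0(gsub("-", "_", stage), ".meta.json"))
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  pipe_log(cfg, "info", paste0(stage, " -> ", csv))
  c(csv = csv, meta = sidecar)
}

#' Run one pipeline stage
#'
#' Executes a single analysis stage for one condition and writes its
#' outputs (CSV plus a JSON metadata sidecar recording the config hash,
#' seed, package version, and the defaults in effect) under the config's
#' `output_dir`.
#'
#' @param config A [read_run_config()] result (or path to one).
#' @param stage One of `"simulate"`, `"msd"`, `"diffusion"`, `"rdf"`,
#'   `"rmsd"`, `"rg"`, `"rmsf"`, `"distances"`, `"contacts"`,
#'   `"intra-hbonds"`, `"coordination"`, `"energy"`, `"compare"`.
#' @return Invisibly, a list with `result` (the computed tibble) and
#'   `files` (paths written).
#' @export
run_stage <- function(config, stage) {
  if (is.character(config)) config <- read_run_config(config)
  if (!stage %in% pipeline_stages) {
    abort(paste0("usage error: unknown stage \"", stage, "\"; stages are: ",
                 paste(pipeline_stages, collapse = ", ")))
  }
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  if (stage == "compare") return(run_compare_stage(config))
  traj <- pipeline_trajectory(config)
  top <- traj$topology
  dm <- config_domains(config)
  crit <- config_criteria(config)

  result <- switch(
    stage,
    simulate = {
      out <- file.path(config$output_dir, "trajectory.pdb")
      write_models_pdb(traj, out)
      pipe_log(config, "info", paste0("simulate -> ", out))
      tibble(file = out, n_frames = n_frames(traj), n_atoms = n_atoms(traj))
    },
    msd = {
      sel <- config_selection(config, top, "ligand", default = "all")
      p <- config$msd %||% list()
      compute_msd(
        traj, sel,
        align_sel = if (!is.null(p$align)) select_atoms(top, p$align),
        max_lag = p$max_lag, origin_stride = p$origin_stride %||% 1L,
        track_mode = p$track_mode %||% "com"
      )
    },
    diffusion = {
      sel <- config_selection(config, top, "ligand", default = "all")
      p <- config$msd %||% list()
      prof <- compute_msd(traj, sel, max_lag = p$max_lag,
                          origin_stride = p$origin_stride %||% 1L,
                          track_mode = p$track_mode %||% "com")
      fr <- unlist(config$diffusion$fit_range %||% c(0.1, 0.5))
      tidy(fit_diffusion(prof, fit_range = fr,
                         d = config$diffusion$d %||% 3L))
    },
    rdf = {
      center <- config_selection(config, top, "ion", default = "ion")
      target <- config_selection(config, top, "water_oxygen",
                                 default = "water and element O")
      p <- config$rdf %||% list()
      compute_rdf(traj, center, target,
                  r_max = p$r_max %||% (min(traj$box) / 2),
                  dr = p$dr %||% 0.1)
    },
    rmsd = per_domain_series(traj, dm, compute_rmsd_series),
    rg = per_domain_series(traj, dm, compute_rg_series),
    rmsf = {
      sel <- config_selection(config, top, "protein", default = "protein")
      compute_rmsf(traj, sel)
    },
    distances = {
      pairs <- config$distance_pairs %||%
        abort("config error: distances stage needs distance_pairs")
      bind_rows(lapply(pairs, function(p) {
        ts <- distance_series(
          traj, select_atoms(top, resolve_atom_map(config, p$selA)),
          select_atoms(top, resolve_atom_map(config, p$selB)),
          mode = p$mode %||% "min"
        )
        tibble(label = p$label %||% paste(p$selA, "-", p$selB),
               time_ns = ts$time_ns, value = ts$value)
      }))
    },
    contacts = {
      s1 <- config_selection(config, top, "protein", default = "protein")
      s2 <- config_selection(config, top, "ligand")
      counts <- count_contacts(traj, s1, s2, crit,
                               hbond_mode = config$contacts$hbond_mode %||%
                                 "geometric")
      counts
    },
    `intra-hbonds` = {
      bind_rows(lapply(dm$domain, function(d) {
        row <- dm[dm$domain == d, ]
        sel <- select_atoms(top, sprintf("resid %d to %d", row$from, row$to))
        if (length(sel) == 0L) return(NULL)
        ts <- detect_hbonds_intra(traj, sel, crit)
        tibble(domain = d, time_ns = ts$time_ns, count = ts$value)
      }))
    },
    coordination = {
      ion <- config_selection(config, top, "ion", default = "ion")
      ion_coordination(traj, ion, radius = crit$coordination_radius)
    },
    energy = {
      rec <- config_selection(config, top, "protein", default = "protein")
      lig <- config_selection(config, top, "ligand")
      params <- config_energy_params(config, top)
      binding_energy_series(traj, rec, lig, params,
                            interval = config$energy$interval %||% 10)
    }
  )
  files <- write_stage_output(
    config, stage, result,
    extra_meta = list(defaults = list(
      msd_fit_window = unlist(config$diffusion$fit_range %||% c(0.1, 0.5)),
      msd_origin_stride = config$msd$origin_stride %||% 1L,
      hbond_angle_convention = paste0(
        "D-H...A at ", crit$angle_at, ", min ", crit$hbond_angle_min, " deg"
      ),
      coordination_radius = crit$coordination_radius
    ))
  )
  invisible(list(result = result, files = files))
}

per_domain_series <- function(traj, dm, fn) {
  bind_rows(lapply(dm$domain, function(d) {
    sel <- tryCatch(domain_selection(traj$topology, dm, d),
                    error = function(e) integer())
    if (length(sel) < 3L) return(NULL)
    ts <- fn(traj, sel)
    tibble(domain = d, time_ns = ts$time_ns, value = ts$value)
  }))
}

# replace ligand atom-map labels (e.g. "@4-OP4") with configured atom names
resolve_atom_map <- function(cfg, expr) {
  map <- cfg$ligand_atom_map %||% list()
  for (lab in names(map)) {
    expr <- gsub(paste0("@", lab), paste("name", paste(map[[lab]], collapse = " ")),
                 expr, fixed = TRUE)
  }
  expr
}

config_energy_params <- function(cfg, top) {
  p <- cfg$energy %||% list()
  if (!is.null(p$lj_table)) {
    tab <- as_tibble(read.csv(p$lj_table, strip.white = TRUE))
    m <- match(toupper(top$name), toupper(tab$name))
    if (anyNA(m)) {
      abort(paste0("missing LJ parameters for atom names: ",
                   paste(unique(top$name[is.na(m)]), collapse = ", ")))
    }
    energy_parameters(
      top, eps = tab$eps[m], sigma = tab$sigma[m],
      born_radius = tab$born_radius[m] %||% top$vdw_radius,
      eps_in = p$eps_in %||% 1, eps_out = p$eps_out %||% 78.5,
      gamma = p$gamma %||% 0.0072
    )
  } else {
    energy_parameters(top, eps_in = p$eps_in %||% 1,
                      eps_out = p$eps_out %||% 78.5,
                      gamma = p$gamma %||% 0.0072)
  }
}

run_compare_stage <- function(config) {
  cmp <- config$compare %||% abort("config error: compare stage needs a compare block")
  files <- cmp$metric_files %||% abort("config error: compare needs metric_files")
  groups <- lapply(files, function(f) {
    if (!file.exists(f)) abort(paste0("config error: missing metric file ", f))
    read.csv(f)$value
  })
  gc_ <- compare_groups(groups)
  out <- cbind(glance(gc_), metric = cmp$metric %||% "metric")
  files_out <- write_stage_output(config, "compare", out)
  json <- file.path(config$output_dir, "compare.json")
  jsonlite::write_json(
    list(glance = glance(gc_), per_group = tidy(gc_)), json,
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  invisible(list(result = gc_, files = c(files_out, json = json)))
}

#' Run the full multi-condition comparison pipeline
#'
#' Computes every requested per-frame metric for each condition and then
#' compares the conditions metric-by-metric with [compare_groups()],
#' mirroring a wild-type versus mutants study design. All conditions must
#' share the same frame spacing.
#'
#' @param configs List of [read_run_config()] results (or paths), one per
#'   condition; names default to each config's `name`.
#' @param metrics Per-frame metrics to compare: any of `"rmsd"`, `"rg"`,
#'   `"rmsf"`, `"contacts"`, `"coordination_residues"`,
#'   `"coordination_waters"`, `"intra_hbonds"`.
#' @param output_dir Where the comparison table is written; `NULL` for no
#'   files.
#' @return Tibble: one row per metric with the test used, statistic,
#'   p-value and stars, plus a `per_condition` list column of group
#'   summaries.
#' @export
run_full_pipeline <- function(configs,
                              metrics = c("rmsd", "rg"),
                              output_dir = NULL) {
  configs <- lapply(configs, function(x) {
    if (is.character(x)) read_run_config(x) else x
  })
  names(configs) <- vapply(configs, function(c_) c_$name, character(1))
  trajs <- lapply(configs, pipeline_trajectory)
  dts <- vapply(trajs, function(t_) t_$dt, numeric(1))
  if (length(unique(dts)) != 1L) {
    abort("consistency error: conditions have different frame spacings (dt)")
  }
  metric_values <- function(cfg, traj, metric) {
    top <- traj$topology
    switch(
      metric,
      rmsd = compute_rmsd_series(
        traj, config_selection(cfg, top, "protein", default = "protein")
      )$value,
      rg = compute_rg_series(
        traj, config_selection(cfg, top, "protein", default = "protein")
      )$value,
      rmsf = compute_rmsf(
        traj, config_selection(cfg, top, "protein", default = "protein")
      )$rmsf,
      contacts = count_contacts(
        traj, config_selection(cfg, top, "protein", default = "protein"),
        config_selection(cfg, top, "ligand"), config_criteria(cfg)
      )$total,
      coordination_residues = ion_coordination(
        traj, config_selection(cfg, top, "ion", default = "ion")
      )$n_residues,
      coordination_waters = ion_coordination(
        traj, config_selection(cfg, top, "ion", default = "ion")
      )$n_waters,
      intra_hbonds = {
        sel <- config_selection(cfg, top, "protein", default = "protein")
        detect_hbonds_intra(traj, sel, config_criteria(cfg))$value
      },
      abort(paste0("unknown metric \"", metric, "\""))
    )
  }
  rows <- lapply(metrics, function(m) {
    groups <- lapply(names(configs), function(nm) {
      metric_values(configs[[nm]], trajs[[nm]], m)
    })
    names(groups) <- names(configs)
    gc_ <- compare_groups(groups)
    g <- glance(gc_)
    tibble(
      metric = m, test_used = g$test_used, statistic = g$statistic,
      p_value = g$p_value, stars = g$stars,
      per_condition = list(tidy(gc_))
    )
  })
  out <- bind_rows(rows)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(out[, setdiff(names(out), "per_condition")],
              file.path(output_dir, "comparison.csv"), row.names = FALSE)
    jsonlite::write_json(
      lapply(seq_len(nrow(out)), function(i) {
        c(as.list(out[i, setdiff(names(out), "per_condition")]),
          list(per_condition = out$per_condition[[i]]))
      }),
      file.path(output_dir, "comparison.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows"
    )
  }
  out
}
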