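#' Rank-based comparison of two condition groups
#'
#' Kruskal-Wallis test between two measurement groups, with the
#' significance-star annotation convention (* p < 0.05, ** p < 0.01,
#' *** p < 0.001, ns otherwise).
#'
#' @param values Numeric measurements.
#' @param groups Group label per measurement.
#' @param group_a,group_b The two labels to compare.
#' @return List with `H` (Kruskal-Wallis statistic), `p_value`, `stars`,
#'   `n_a`, `n_b`.
#' @export
compare_conditions <- function(values, groups, group_a, group_b) {
  va <- values[groups == group_a]
  vb <- values[groups == group_b]
  if (length(va) < 2 || length(vb) < 2) {
    stop_input("need at least 2 observations per group")
  }
  kt <- kruskal.test(list(va, vb))
  p <- kt$p.value
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**" else
    if (p < 0.05) "*" else "ns"
  list(H = unname(kt$statistic), p_value = p, stars = stars,
       n_a = length(va), n_b = length(vb))
}

valid_conditions <- c("Ctrl", "T0", "T1", "Compressed")

#' Default study-condition parameters of the synthetic pipeline
#'
#' Per-condition generator settings emulating the experimental design:
#' cell shapes (sphere at Ctrl, volume-conserving oblate when compressed),
#' Flipper-TR lifetimes (4.7 ns baseline, +12% at T0, recovered at T1),
#' cortex ring radii (0.7 um thickness at Ctrl halving to 0.4 um at T0),
#' planted nanoparticle counts (12x delivery at T0, 6x at T1 for 200 nm),
#' and transport mixtures (diffusive share rising at T1).
#'
#' @return Nested list of per-stage, per-condition parameters.
#' @export
default_conditions <- function() {
  list(
    curvature = list(
      Ctrl = c(d2a = 16.66, d2c = 16.66),
      Compressed = c(d2a = 19.2, d2c = 12.4)
    ),
    flim = list(Ctrl = 4.7, T0 = 5.264, T1 = 4.7),
    tension = list(
      Ctrl = list(sector = NULL, n_points = 16),   # uniform angles
      T0 = list(sector = 40, n_points = 16)        # one 40-deg arc
    ),
    cortex = list(
      Ctrl = c(r_major = 8.0, r_minor = 6.6),
      T0 = c(r_major = 7.6, r_minor = 6.8),
      T1 = c(r_major = 8.0, r_minor = 6.65)
    ),
    np = list(Ctrl = 10, T0 = 120, T1 = 60),
    coloc = list(Ctrl = 0.60, T0 = 0.14),
    msd = list(Ctrl = list(n = 40, frac_directed = 0.7),
               T1 = list(n = 65, frac_directed = 0.5))
  )
}

#' Build a pipeline run manifest
#'
#' @param seed Integer master seed; per-stage seeds are derived from it.
#' @param outdir Output directory for CSV tables and the run log.
#' @param stages Stages to run, in dependency order; subset of
#'   `curvature`, `flim`, `tension`, `cortex`, `np`, `msd`, `poresim`.
#' @param conditions Condition labels; must be drawn from
#'   `Ctrl`, `T0`, `T1`, `Compressed`.
#' @param n_cells Cells per condition for the per-cell stages.
#' @param params Per-stage condition parameters; defaults from
#'   [default_conditions()].
#' @param inputs Named list of optional input files (e.g.
#'   `curvature_csv`, `tracks_csv`); every referenced file must exist.
#' @return A validated manifest (class `run_manifest`).
#' @export
run_manifest <- function(seed = 1, outdir = tempfile("mechanopore_run_"),
                         stages = c("curvature", "flim", "tension",
                                    "cortex", "np", "msd", "poresim"),
                         conditions = c("Ctrl", "T0", "T1", "Compressed"),
                         n_cells = 4, params = default_conditions(),
                         inputs = list()) {
  bad <- setdiff(conditions, valid_conditions)
  if (length(bad)) {
    stop_input("unknown condition label(s): ", paste(bad, collapse = ", "),
               " (allowed: ", paste(valid_conditions, collapse = ", "), ")")
  }
  known <- c("curvature", "flim", "tension", "cortex", "np", "msd", "poresim")
  bad <- setdiff(stages, known)
  if (length(bad)) stop_input("unknown stage(s): ", paste(bad, collapse = ", "))
  for (nm in names(inputs)) {
    if (!file.exists(inputs[[nm]])) {
      stop_input("input file for '", nm, "' does not exist: ", inputs[[nm]])
    }
  }
  structure(list(seed = as.integer(seed), outdir = outdir,
                 stages = intersect(known, stages), conditions = conditions,
                 n_cells = n_cells, params = params, inputs = inputs),
            class = "run_manifest")
}

#' Read a run manifest from a YAML file
#'
#' @param path YAML file with any of the [run_manifest()] fields.
#' @return A validated `run_manifest`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_input("manifest file not found: ", path)
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), c("seed", "outdir", "stages", "conditions",
                                  "n_cells", "inputs"))]
  do.call(run_manifest, args)
}

# internal: derived per-stage seed (kept below 2^31)
stage_seed <- function(manifest, offset) {
  (manifest$seed * 1000L + offset) %% 2147483647L
}

stage_curvature <- function(m) {
  p <- m$params$curvature
  conds <- intersect(m$conditions, names(p))
  if ("curvature_csv" %in% names(m$inputs)) {
    tab <- cell_curvature_table(m$inputs$curvature_csv)
    tab$condition <- "Ctrl"
  } else {
    with_seed(stage_seed(m, 1L), {
      rows <- lapply(conds, function(cond) {
        d <- p[[cond]]
        jit <- 1 + rnorm(m$n_cells, 0, 0.02)   # 2% measurement scatter
        d2a <- d[["d2a"]] * jit
        d2c <- pmin(d[["d2c"]] * (1 + rnorm(m$n_cells, 0, 0.02)), d2a)
        t <- cell_curvature_table(data.frame(
          cell_id = paste0(cond, "_", seq_len(m$n_cells)),
          d2a_um = d2a, d2c_um = d2c))
        t$condition <- cond
        t
      })
      tab <- do.call(rbind, rows)
    })
  }
  tab$stage <- "curvature"
  tab
}

stage_flim <- function(m) {
  p <- m$params$flim
  conds <- intersect(m$conditions, names(p))
  with_seed(stage_seed(m, 2L), {
    rows <- lapply(conds, function(cond) {
      tau <- p[[cond]] * (1 + rnorm(m$n_cells, 0, 0.02))
      est <- vapply(seq_len(m$n_cells), function(i) {
        d <- gen_decay(tau1 = tau[i], tau2 = 1.2, i1 = 9, i2 = 1,
                       n_photons = 1e5)
        fit_biexponential(d)$tau1
      }, numeric(1))
      data.frame(cell_id = paste0(cond, "_", seq_len(m$n_cells)),
                 condition = cond, tau1_ns = est)
    })
    tab <- do.call(rbind, rows)
  })
  tab$stage <- "flim"
  tab
}

stage_tension <- function(m) {
  p <- m$params$tension
  conds <- intersect(m$conditions, names(p))
  with_seed(stage_seed(m, 3L), {
    rows <- lapply(conds, function(cond) {
      pc <- p[[cond]]
      vals <- vapply(seq_len(m$n_cells), function(i) {
        angles <- if (is.null(pc$sector)) {
          runif(pc$n_points, 0, 360)
        } else {
          start <- runif(1, 0, 360)
          (start + runif(pc$n_points, 0, pc$sector)) %% 360
        }
        g <- gen_tension_image(cell_radius = 60, point_angles = angles)
        seg <- segment_cell_circle(g$image[, , 1] + g$image[, , 2])
        pts <- detect_high_tension_points(g$image)
        pmap <- polarize_points(pts, seg$centroid, seg$cell_radius)
        angular_concentration(pmap)$max_bin_fraction
      }, numeric(1))
      data.frame(cell_id = paste0(cond, "_", seq_len(m$n_cells)),
                 condition = cond, max_bin_fraction = vals,
                 baseline = 12.5)
    })
    tab <- do.call(rbind, rows)
  })
  tab$stage <- "tension"
  tab
}

stage_cortex <- function(m) {
  p <- m$params$cortex
  conds <- intersect(m$conditions, names(p))
  with_seed(stage_seed(m, 4L), {
    rows <- lapply(conds, function(cond) {
      r <- p[[cond]]
      res <- t(vapply(seq_len(m$n_cells), function(i) {
        g <- gen_ring_image(r_major = r[["r_major"]] * (1 + rnorm(1, 0, 0.01)),
                            r_minor = r[["r_minor"]] * (1 + rnorm(1, 0, 0.01)),
                            intensity = 100, dxy = 0.1, noise_sd = 2)
        ring <- estimate_cortex_ring(g$image, g$dxy)
        met <- cortex_metrics(ring)
        c(met$thickness_um, met$normalized_intensity)
      }, numeric(2)))
      data.frame(cell_id = paste0(cond, "_", seq_len(m$n_cells)),
                 condition = cond, thickness_um = res[, 1],
                 normalized_intensity = res[, 2])
    })
    tab <- do.call(rbind, rows)
  })
  tab$stage <- "cortex"
  tab
}

stage_np <- function(m, np_diameter = 200) {
  p <- m$params$np
  conds <- intersect(m$conditions, names(p))
  with_seed(stage_seed(m, 5L), {
    ref <- gen_np_reference(n_beads = 96, np_diameter = np_diameter)
    thr <- calibrate_np_threshold(ref$stack, ref$n_beads)
    rows <- lapply(conds, function(cond) {
      planted <- pmax(1, round(p[[cond]] * (1 + rnorm(m$n_cells, 0, 0.05))))
      res <- t(vapply(seq_len(m$n_cells), function(i) {
        g <- gen_zstack(planted[i], np_diameter = np_diameter)
        slab <- analysis_slab(g$stack, major_radius = g$cell_semi_axes[1])
        q <- count_particles(g$stack, slab, thr)
        c(planted[i], q$particle_count, q$voxel_count)
      }, numeric(3)))
      data.frame(cell_id = paste0(cond, "_", seq_len(m$n_cells)),
                 condition = cond, planted = res[, 1],
                 particle_count = res[, 2], voxel_count = res[, 3])
    })
    tab <- do.call(rbind, rows)
  })
  tab$stage <- "np"
  tab
}

stage_msd <- function(m) {
  p <- m$params$msd
  conds <- intersect(m$conditions, names(p))
  with_seed(stage_seed(m, 6L), {
    rows <- lapply(conds, function(cond) {
      pc <- p[[cond]]
      g <- gen_trajectories(n = pc$n, frac_directed = pc$frac_directed)
      res <- analyze_tracks(g$tracks)
      res$condition <- cond
      res$true_label <- g$labels$label[match(res$track_id,
                                             g$labels$track_id)]
      res$cell_id <- paste0(cond, "_t", res$track_id)
      res
    })
    tab <- do.call(rbind, rows)
  })
  tab$stage <- "msd"
  tab
}

stage_poresim <- function(m) {
  # scaled-down geometry so the pipeline smoke run stays fast
  run1 <- function(pore, t_end) {
    dom <- pore_domain(cell_radius = 3, pore_diameter = pore, h = 0.25,
                       box_radius = 6, box_height = 12)
    res <- solve_uptake(dom, t_end = t_end, dt = t_end / 60,
                        record_every = 10L)
    utils::tail(res$intracellular_amount, 1)
  }
  data.frame(cell_id = "sim", condition = "T0", stage = "poresim",
             pore_um = c(1.5, 0.5), t_end_s = c(300, 1200),
             uptake_fraction = c(run1(1.5, 300), run1(0.5, 1200)))
}

#' Run the full synthetic analysis pipeline
#'
#' Executes the requested stages in dependency order on synthetic data
#' generated under the manifest's per-condition parameters, writes one
#' per-cell CSV per stage plus a machine-readable summary and a run log
#' to the manifest's output directory, and returns all tables. Reruns
#' with the same manifest (including seed) reproduce the outputs
#' byte-for-byte.
#'
#' @param manifest A [run_manifest()].
#' @return Invisibly, a list with `tables` (per stage), `summary`
#'   (long data frame) and `outdir`.
#' @export
run_pipeline <- function(manifest) {
  stopifnot(inherits(manifest, "run_manifest"))
  dir.create(manifest$outdir, recursive = TRUE, showWarnings = FALSE)
  runners <- list(curvature = stage_curvature, flim = stage_flim,
                  tension = stage_tension, cortex = stage_cortex,
                  np = stage_np, msd = stage_msd, poresim = stage_poresim)
  tables <- list()
  log_lines <- c(sprintf("mechanopore pipeline run (seed %d)", manifest$seed),
                 sprintf("conditions: %s",
                         paste(manifest$conditions, collapse = ", ")))
  for (st in manifest$stages) {
    tab <- tryCatch(runners[[st]](manifest), error = function(e) {
      stop_input("stage '", st, "' failed: ", conditionMessage(e))
    })
    tables[[st]] <- tab
    f <- file.path(manifest$outdir, paste0(st, "_per_cell.csv"))
    write.csv(tab, f, row.names = FALSE)
    log_lines <- c(log_lines, sprintf("stage %-9s: %d rows -> %s",
                                      st, nrow(tab), basename(f)))
  }
  summary_rows <- list()
  add <- function(stage, condition, metric, value) {
    summary_rows[[length(summary_rows) + 1]] <<- data.frame(
      stage = stage, condition = condition, metric = metric, value = value)
  }
  for (st in names(tables)) {
    tab <- tables[[st]]
    num <- vapply(tab, is.numeric, logical(1))
    metrics <- setdiff(names(tab)[num], c("planted", "track_id"))
    for (cond in unique(tab$condition)) {
      for (mcol in metrics) {
        v <- tab[[mcol]][tab$condition == cond]
        v <- v[is.finite(v)]
        if (length(v)) add(st, cond, paste0("mean_", mcol), mean(v))
      }
    }
    if (st == "np") {
      ctrl <- mean(tab$particle_count[tab$condition == "Ctrl"])
      for (cond in setdiff(unique(tab$condition), "Ctrl")) {
        eff <- delivery_efficiency(
          mean(tab$particle_count[tab$condition == cond]), ctrl)
        add("np", cond, "delivery_efficiency", eff$ratio)
      }
    }
    if (st == "msd") {
      for (cond in unique(tab$condition)) {
        sub <- tab[tab$condition == cond, ]
        acc <- sub$label != "rejected"
        if (any(acc)) {
          add("msd", cond, "pct_diffusive",
              100 * mean(sub$label[acc] == "diffusive"))
        }
      }
    }
  }
  summary <- do.call(rbind, summary_rows)
  write.csv(summary, file.path(manifest$outdir, "summary.csv"),
            row.names = FALSE)
  writeLines(log_lines, file.path(manifest$outdir, "run_log.txt"))
  invisible(list(tables = tables, summary = summary,
                 outdir = manifest$outdir))
}
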