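#' Load and validate a pipeline configuration
#'
#' Configurations are JSON (or an equivalent R list). Fields:
#' \describe{
#'   \item{mode}{"run" (simulate + analyze + compare), "simulate",
#'     "iccs", "pla" or "stats".}
#'   \item{seed}{Integer master seed; per-cell seeds are derived from it.}
#'   \item{groups}{For run/simulate: list of group descriptors with
#'     `name`, `n_cells`, `f_true`, and optionally `n_foci`,
#'     `pla_mean`, `pla_sd`, `pla_n_spots`.}
#'   \item{inputs}{For iccs/pla: list of `{path, group, channels}`
#'     entries pointing at TIFF files.}
#'   \item{cells_csv, value_column}{For stats: a per-cell table and the
#'     measurement column to compare.}
#'   \item{iccs, pla}{Optional analysis settings forwarded to
#'     [iccs_config()] / [count_spots()].}
#'   \item{alpha_family}{Family-wise level for [compare_groups()].}
#'   \item{use_segmentation}{In run mode, segment the simulated DNA
#'     channel instead of using the ground-truth nucleus support.}
#'   \item{write_profiles}{Dump radial profiles as CSV.}
#' }
#'
#' @param config A list or a path to a JSON file.
#' @return Validated config list.
#' @export
load_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) abort_validation(sprintf("config file not found: %s", config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  if (!is.list(config)) abort_validation("config must be a list or a JSON file path")
  need <- function(key, where = config, path = key) {
    if (is.null(where[[key]]))
      abort_validation(sprintf("config key missing: %s", path))
    where[[key]]
  }
  mode <- need("mode")
  if (!mode %in% c("run", "simulate", "iccs", "pla", "stats"))
    abort_validation(sprintf("config key invalid: mode (got '%s')", mode))
  config$seed <- as.integer(if (is.null(config$seed)) 1L else config$seed)
  config$alpha_family <- if (is.null(config$alpha_family)) 0.05 else config$alpha_family
  if (mode %in% c("run", "simulate")) {
    groups <- need("groups")
    if (!length(groups)) abort_validation("config key invalid: groups (empty)")
    for (i in seq_along(groups)) {
      g <- groups[[i]]
      for (key in c("name", "n_cells", "f_true")) {
        if (is.null(g[[key]]))
          abort_validation(sprintf("config key missing: groups[%d].%s", i, key))
      }
      if (g$f_true < 0 || g$f_true > 1)
        abort_validation(sprintf("config key invalid: groups[%d].f_true", i))
    }
  }
  if (mode %in% c("iccs", "pla")) {
    inputs <- need("inputs")
    for (i in seq_along(inputs)) {
      if (is.null(inputs[[i]]$path))
        abort_validation(sprintf("config key missing: inputs[%d].path", i))
      if (!file.exists(inputs[[i]]$path))
        abort_validation(sprintf("config key invalid: inputs[%d].path (file not found: %s)",
                                 i, inputs[[i]]$path))
    }
  }
  if (mode == "stats") {
    csv <- need("cells_csv")
    if (!file.exists(csv))
      abort_validation(sprintf("config key invalid: cells_csv (file not found: %s)", csv))
    need("value_column")
  }
  config
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

derive_seed <- function(master, index) {
  as.integer((as.numeric(master) * 7919 + index * 104729) %% 2147483647)
}

write_result_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  path
}

pipeline_iccs_config <- function(config) {
  do.call(iccs_config, if (is.null(config$iccs)) list() else config$iccs)
}

#' Run the end-to-end pipeline
#'
#' Orchestrates simulation and/or analysis according to the config mode
#' and writes `cells.csv`, `comparisons.csv` (when >= 2 groups are
#' present) and `run.log` into `out_dir`. Output CSVs are
#' byte-reproducible given the same config and seed.
#'
#' @param config A config list or JSON path (see [load_config()]).
#' @param out_dir Output directory (created if needed); overrides the
#'   config's `out_dir`.
#' @param seed Optional override of the config seed.
#' @return Invisibly, a list with the output paths and in-memory result
#'   tables (`cells`, `comparisons`).
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  config <- load_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (is.null(out_dir)) out_dir <- if (is.null(config$out_dir)) "." else config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "run.log")
  log_line <- function(...) cat(sprintf(...), "\n", sep = "", file = logf, append = TRUE)
  cat("", file = logf)
  log_line("iccscoloc %s | R %s.%s", as.character(utils::packageVersion("iccscoloc")),
           R.version$major, R.version$minor)
  log_line("mode=%s seed=%d config_md5=%s", config$mode, config$seed,
           config_hash(config))

  cells <- switch(config$mode,
    run = pipeline_run_mode(config, out_dir, log_line),
    simulate = pipeline_simulate_mode(config, out_dir, log_line),
    iccs = pipeline_iccs_mode(config, out_dir, log_line),
    pla = pipeline_pla_mode(config, out_dir, log_line),
    stats = utils::read.csv(config$cells_csv, stringsAsFactors = FALSE))

  outputs <- list(cells = cells)
  cells_path <- file.path(out_dir, "cells.csv")
  write_result_csv(cells, cells_path)
  outputs$cells_csv <- cells_path

  value_cols <- if (config$mode == "stats") config$value_column else
    intersect(c("f", "pla_count"), names(cells))
  if (!is.null(cells$group) && length(unique(cells$group)) >= 2 &&
      length(value_cols)) {
    comp_rows <- lapply(value_cols, function(col) {
      vals <- cells[[col]]
      ok <- is.finite(vals)
      gs <- lapply(split(vals[ok], cells$group[ok]), function(v) v)
      gs <- gs[vapply(gs, length, integer(1)) >= 2]
      if (length(gs) < 2) return(NULL)
      rep_ <- tryCatch(
        compare_groups(lapply(names(gs), function(nm) group_sample(nm, gs[[nm]])),
                       alpha_family = config$alpha_family),
        iccscoloc_degenerate_error = function(e) {
          log_line("metric %s skipped: %s", col, conditionMessage(e))
          NULL
        })
      if (is.null(rep_)) return(NULL)
      cbind(metric = col, anova_F = rep_$anova_F, anova_p = rep_$anova_p,
            alpha_bonferroni = rep_$alpha_bonferroni, rep_$pairwise,
            stringsAsFactors = FALSE)
    })
    comp <- do.call(rbind, comp_rows[!vapply(comp_rows, is.null, logical(1))])
    if (!is.null(comp)) {
      comp_path <- file.path(out_dir, "comparisons.csv")
      write_result_csv(comp, comp_path)
      outputs$comparisons <- comp
      outputs$comparisons_csv <- comp_path
      log_line("comparisons: %d metric(s), alpha_bonferroni=%.6g",
               length(unique(comp$metric)), comp$alpha_bonferroni[1])
    }
  }
  log_line("cells: %d row(s)", nrow(cells))
  invisible(outputs)
}

# simulate + analyze each cell end to end
pipeline_run_mode <- function(config, out_dir, log_line) {
  icfg <- pipeline_iccs_config(config)
  pla_cfg <- config$pla
  rows <- list()
  for (gi in seq_along(config$groups)) {
    g <- config$groups[[gi]]
    n_foci <- if (is.null(g$n_foci)) 50L else as.integer(g$n_foci)
    set.seed(derive_seed(config$seed, gi * 100000))
    n_spots_vec <- if (!is.null(g$pla_mean)) {
      pmax(0, round(stats::rnorm(g$n_cells, g$pla_mean,
                                 if (is.null(g$pla_sd)) 0 else g$pla_sd)))
    } else if (!is.null(g$pla_n_spots)) {
      rep(as.integer(g$pla_n_spots), g$n_cells)
    } else NULL
    for (ci in seq_len(g$n_cells)) {
      cell_seed <- derive_seed(config$seed, gi * 10000 + ci)
      sim <- simulate_two_channel(foci_sim_params(
        n_foci_a = n_foci, n_foci_b = n_foci, f_true = g$f_true,
        include_dna_channel = isTRUE(config$use_segmentation),
        seed = cell_seed))
      mask <- if (isTRUE(config$use_segmentation)) {
        segment_nucleus(sim$image$channels[[3]])
      } else {
        nuclear_mask(sim$truth$nucleus_mask_true)
      }
      res <- run_iccs(sim$image, 1, 2, mask, icfg,
                      keep_profiles = isTRUE(config$write_profiles))
      row <- data.frame(group = g$name, cell_id = ci, f_true = g$f_true,
                        f_raw = res$f_raw, f = res$f,
                        g0_11 = res$fit11$g0, g0_22 = res$fit22$g0,
                        g0_12 = res$fit12$g0,
                        qc_flags = paste(res$qc_flags, collapse = ";"),
                        seed = cell_seed, stringsAsFactors = FALSE)
      if (!is.null(n_spots_vec)) {
        pstack <- simulate_pla_stack(n_spots = n_spots_vec[ci],
                                     seed = derive_seed(cell_seed, 7))
        sc <- count_spots(pstack$stack,
                          threshold = if (is.null(pla_cfg$threshold)) "otsu" else pla_cfg$threshold,
                          min_size_vox = if (is.null(pla_cfg$min_size_vox)) 4 else pla_cfg$min_size_vox,
                          connectivity = if (is.null(pla_cfg$connectivity)) 26 else pla_cfg$connectivity)
        row$pla_count <- sc$count
        row$pla_threshold <- sc$threshold_used
      }
      if (isTRUE(config$write_profiles)) {
        pdir <- file.path(out_dir, "radial_profiles")
        dir.create(pdir, showWarnings = FALSE)
        prof <- data.frame(r = res$profiles$m11$radii_px,
                           g11 = res$profiles$m11$g,
                           g22 = res$profiles$m22$g,
                           g12 = res$profiles$m12$g)
        write_result_csv(prof, file.path(pdir, sprintf("%s_cell%03d.csv", g$name, ci)))
      }
      rows[[length(rows) + 1L]] <- row
    }
    log_line("group %s: %d cell(s) simulated and analyzed", g$name, g$n_cells)
  }
  do.call(rbind, rows)
}

# simulation only: write TIFFs plus ground truth
pipeline_simulate_mode <- function(config, out_dir, log_line) {
  img_dir <- file.path(out_dir, "images")
  dir.create(img_dir, showWarnings = FALSE)
  rows <- list()
  for (gi in seq_along(config$groups)) {
    g <- config$groups[[gi]]
    n_foci <- if (is.null(g$n_foci)) 50L else as.integer(g$n_foci)
    for (ci in seq_len(g$n_cells)) {
      cell_seed <- derive_seed(config$seed, gi * 10000 + ci)
      sim <- simulate_two_channel(foci_sim_params(
        n_foci_a = n_foci, n_foci_b = n_foci, f_true = g$f_true,
        seed = cell_seed))
      base <- sprintf("%s_cell%03d", g$name, ci)
      img_path <- file.path(img_dir, paste0(base, ".tif"))
      img <- sim$image
      img$channels <- lapply(img$channels, round)
      write_image(img, img_path)
      truth_path <- file.path(img_dir, paste0(base, "_truth.json"))
      jsonlite::write_json(list(f_true = g$f_true, seed = cell_seed,
                                foci_a = sim$truth$foci_coords_a,
                                foci_b = sim$truth$foci_coords_b),
                           truth_path, auto_unbox = TRUE, digits = NA)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g$name, cell_id = ci, f_true = g$f_true,
        image = img_path, truth = truth_path, seed = cell_seed,
        stringsAsFactors = FALSE)
    }
    log_line("group %s: %d image(s) written", g$name, g$n_cells)
  }
  do.call(rbind, rows)
}

pipeline_iccs_mode <- function(config, out_dir, log_line) {
  icfg <- pipeline_iccs_config(config)
  rows <- list()
  for (i in seq_along(config$inputs)) {
    inp <- config$inputs[[i]]
    chans <- if (is.null(inp$channels)) c(1, 2) else unlist(inp$channels)
    img <- read_image(inp$path)
    mask <- if (!is.null(inp$dna_channel)) {
      segment_nucleus(img$channels[[inp$dna_channel]])
    } else if (!is.null(inp$mask_path)) {
      read_mask(inp$mask_path)
    } else {
      abort_validation(sprintf("config key missing: inputs[%d].dna_channel or mask_path", i))
    }
    res <- run_iccs(img, chans[1], chans[2], mask, icfg)
    rows[[i]] <- data.frame(
      group = if (is.null(inp$group)) "all" else inp$group,
      cell_id = i, path = inp$path,
      f_raw = res$f_raw, f = res$f,
      g0_11 = res$fit11$g0, g0_22 = res$fit22$g0, g0_12 = res$fit12$g0,
      qc_flags = paste(res$qc_flags, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  log_line("iccs: %d image(s) analyzed", length(config$inputs))
  do.call(rbind, rows)
}

pipeline_pla_mode <- function(config, out_dir, log_line) {
  pla_cfg <- config$pla
  results <- list(); labels <- character(0)
  for (i in seq_along(config$inputs)) {
    inp <- config$inputs[[i]]
    stack <- read_stack(inp$path)
    results[[i]] <- count_spots(
      stack,
      threshold = if (is.null(pla_cfg$threshold)) "otsu" else pla_cfg$threshold,
      min_size_vox = if (is.null(pla_cfg$min_size_vox)) 4 else pla_cfg$min_size_vox,
      connectivity = if (is.null(pla_cfg$connectivity)) 26 else pla_cfg$connectivity)
    labels[i] <- if (is.null(inp$group)) "all" else inp$group
  }
  log_line("pla: %d stack(s) counted", length(config$inputs))
  summarize_counts(results, labels)
}

#' Command-line entry point
#'
#' Drives the pipeline from the shell:
#' `iccs-coloc <simulate|iccs|pla|stats|run> --config cfg.json
#' [--seed N] [--out-dir DIR]`. The subcommand overrides the config's
#' `mode`. Returns (and, via the installed script, exits with) 0 on
#' success and 2 on validation errors.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status, invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: iccs-coloc <simulate|iccs|pla|stats|run> --config <file.json>",
    "                  [--seed <int>] [--out-dir <dir>]", sep = "\n")
  if (!length(args) || args[1] %in% c("-h", "--help")) {
    message(usage)
    return(invisible(0L))
  }
  opt <- list(mode = args[1], config = NULL, seed = NULL, out_dir = NULL)
  i <- 2
  while (i <= length(args)) {
    key <- args[i]
    if (!key %in% c("--config", "--seed", "--out-dir", "--log-level")) {
      message("unknown argument: ", key, "\n", usage)
      return(invisible(2L))
    }
    if (i == length(args)) {
      message("missing value for ", key)
      return(invisible(2L))
    }
    val <- args[i + 1]
    if (key == "--config") opt$config <- val
    if (key == "--seed") opt$seed <- as.integer(val)
    if (key == "--out-dir") opt$out_dir <- val
    i <- i + 2
  }
  status <- tryCatch({
    if (is.null(opt$config)) abort_validation("--config is required")
    config <- load_config(opt$config)
    config$mode <- opt$mode
    config <- load_config(config) # re-validate under the subcommand's mode
    run_pipeline(config, out_dir = opt$out_dir, seed = opt$seed)
    0L
  },
  iccscoloc_validation_error = function(e) {
    message("validation error: ", conditionMessage(e))
    2L
  },
  error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
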