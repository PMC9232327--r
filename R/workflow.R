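#' Analysis options
#'
#' Tunables of the analyze stage, with the package defaults.
#'
#' @param zero_speed_threshold speed (m/s) treated as "stopped" when
#'   locating the braking endpoint.
#' @param smooth_window moving-average window (frames, odd) for the speed
#'   series; 0 disables smoothing.
#' @param emg_filter apply the 20–450 Hz band-pass before EMG metrics
#'   (off by default: the synthetic carrier is already band-limited).
#' @param emg_band band edges (Hz) when filtering.
#' @param mvic_window_s MVIC sliding-window length (s).
#' @param t_variant `"student"` or `"welch"`.
#' @param grade_bands correlation grade band edges on `|r|`.
#' @return A named list of class `analysis_options`.
#' @export
analysis_options <- function(zero_speed_threshold = 1e-3, smooth_window = 0,
                             emg_filter = FALSE, emg_band = c(20, 450),
                             mvic_window_s = 1,
                             t_variant = c("student", "welch"),
                             grade_bands = c(0.1, 0.3, 0.7)) {
  structure(
    list(
      zero_speed_threshold = zero_speed_threshold,
      smooth_window = smooth_window, emg_filter = emg_filter,
      emg_band = emg_band, mvic_window_s = mvic_window_s,
      t_variant = match.arg(t_variant), grade_bands = grade_bands
    ),
    class = "analysis_options"
  )
}

trial_file <- function(dir, subject_id, combo, kind) {
  if (kind == "mvic") {
    file.path(dir, sprintf("%s_mvic.csv", subject_id))
  } else {
    file.path(dir, sprintf("%s_c%d_%s.csv", subject_id, combo, kind))
  }
}

#' Simulate a cohort to disk
#'
#' Generates a seeded synthetic cohort ([generate_cohort()]) and writes the
#' per-subject file set (trajectory, EMG and MVIC CSVs per combination)
#' plus a JSON manifest echoing the configuration. Deterministic: the same
#' config yields byte-identical files.
#'
#' @param config a [cohort_config()].
#' @param out_dir output directory (created if missing).
#' @param combos combinations to generate.
#' @param include_emg write EMG and MVIC files.
#' @return The manifest, invisibly.
#' @export
simulate_cohort <- function(config, out_dir, combos = c(1L, 2L),
                            include_emg = TRUE) {
  validate_cohort_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop_invalid("cannot create output dir ", out_dir)
  cohort <- generate_cohort(config, combos = combos, include_emg = include_emg)
  files <- character()
  for (key in names(cohort$motion)) {
    trial <- cohort$motion[[key]]
    f <- trial_file(out_dir, trial$subject$subject_id, trial$combo_id, "trajectory")
    write_trajectory_csv(trial, f)
    files <- c(files, basename(f))
    if (include_emg) {
      f <- trial_file(out_dir, trial$subject$subject_id, trial$combo_id, "emg")
      write_emg_csv(cohort$emg[[key]], f)
      files <- c(files, basename(f))
    }
  }
  for (id in names(cohort$mvic)) {
    f <- trial_file(out_dir, id, 0L, "mvic")
    write_mvic_csv(cohort$mvic[[id]], f)
    files <- c(files, basename(f))
  }
  manifest <- list(
    stage = "simulate",
    package_version = as.character(packageVersion("armbeat")),
    seed = config$seed,
    combos = as.integer(combos),
    include_emg = include_emg,
    config = config_to_list(config),
    profiles = cohort$profiles,
    n_files = length(files),
    files = sort(files)
  )
  write_manifest(manifest, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}

combo_n_beats <- function(combo) if (combo == 1) 8L else 4L

#' Analyze a simulated or recorded cohort
#'
#' Runs the kinematics and EMG stages for every subject and combination in
#' `in_dir` (as laid out by [simulate_cohort()]), then the group-level
#' statistics, and writes the stage CSVs (`kinematics.csv`, `braking.csv`,
#' `emg.csv`, `stats.csv`, `correlations.csv`), an analysis manifest and a
#' rendered `report.md`. A defective file affects only its subject/stage:
#' the subject is dropped from that stage's summaries and the problem is
#' recorded in the manifest warnings.
#'
#' @param in_dir input directory holding the cohort file set + manifest.
#' @param out_dir output directory for metrics and the report.
#' @param options an [analysis_options()].
#' @return The analysis manifest, invisibly.
#' @export
analyze_cohort <- function(in_dir, out_dir, options = analysis_options()) {
  manifest_path <- file.path(in_dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    stop_invalid("no manifest.json in ", in_dir, ": not a cohort directory")
  }
  sim <- read_manifest(manifest_path)
  config <- list_to_config(sim$config)
  profiles <- sim$profiles
  combos <- as.integer(sim$combos)
  include_emg <- isTRUE(sim$include_emg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  warnings_log <- character()
  note <- function(fmt, ...) {
    warnings_log <<- c(warnings_log, sprintf(fmt, ...))
  }

  kin_rows <- list()
  brake_rows <- list()
  emg_rows <- list()
  for (i in seq_len(nrow(profiles))) {
    id <- profiles$subject_id[i]
    height <- profiles$height[i]
    mvic <- NULL
    if (include_emg) {
      mvic <- tryCatch(read_mvic_csv(trial_file(in_dir, id, 0L, "mvic")),
                       error = function(e) {
                         note("subject %s: MVIC unreadable (%s)", id, conditionMessage(e))
                         NULL
                       })
    }
    for (combo in combos) {
      nb <- combo_n_beats(combo)
      hands <- tryCatch(
        read_trajectory_csv(trial_file(in_dir, id, combo, "trajectory"),
                            frame_rate = config$frame_rate),
        error = function(e) {
          note("subject %s combo %d: trajectory unreadable (%s)", id, combo,
               conditionMessage(e))
          NULL
        }
      )
      boundaries <- NULL
      if (!is.null(hands)) {
        res <- tryCatch({
          boundaries <- segment_beats(n_frames(hands$left) - 1L, config$tempo,
                                      config$frame_rate, nb)
          sums <- lapply(hands, track_length_summary, height = height,
                         subject_id = id)
          sums$left$hand <- "left"; sums$right$hand <- "right"
          avg <- hand_average(sums$left, sums$right)
          kin <- rbind(sums$left, sums$right, avg)
          kin$combo <- combo
          braking <- withCallingHandlers(
            lapply(hands, function(tr) {
              braking_metrics(linear_speed(tr, options$smooth_window),
                              boundaries, options$zero_speed_threshold)
            }),
            warning = function(w) {
              note("subject %s combo %d: %s", id, combo, conditionMessage(w))
              invokeRestart("muffleWarning")
            }
          )
          braking$left$hand <- "left"; braking$right$hand <- "right"
          bavg <- braking_average(braking$left, braking$right)
          bavg$hand <- "averaged"
          brk <- rbind(braking$left, braking$right, bavg)
          brk$combo <- combo
          list(kin = cbind(subject_id = id, group = profiles$group[i],
                           kin[setdiff(names(kin), "subject_id")]),
               brk = cbind(subject_id = id, group = profiles$group[i], brk))
        }, error = function(e) {
          note("subject %s combo %d: kinematics failed (%s)", id, combo,
               conditionMessage(e))
          NULL
        })
        if (!is.null(res)) {
          kin_rows[[length(kin_rows) + 1L]] <- res$kin
          brake_rows[[length(brake_rows) + 1L]] <- res$brk
        }
      }
      if (include_emg && !is.null(mvic) && !is.null(boundaries)) {
        erow <- tryCatch({
          trial <- read_emg_csv(trial_file(in_dir, id, combo, "emg"),
                                rate = config$emg_rate)
          if (options$emg_filter) {
            nm <- names(trial$channels)
            trial$channels <- lapply(nm, function(ch) {
              emg_preprocess(emg_series(trial$channels[[ch]], trial$rate, ch),
                             band = options$emg_band)$values
            })
            names(trial$channels) <- nm
          }
          m <- per_beat_emg(trial, boundaries / config$frame_rate, mvic)
          cbind(subject_id = id, group = profiles$group[i], combo = combo, m)
        }, error = function(e) {
          note("subject %s combo %d: EMG failed (%s)", id, combo,
               conditionMessage(e))
          NULL
        })
        if (!is.null(erow)) emg_rows[[length(emg_rows) + 1L]] <- erow
      }
    }
  }
  kin <- do.call(rbind, kin_rows)
  brk <- do.call(rbind, brake_rows)
  emg <- if (length(emg_rows)) do.call(rbind, emg_rows) else NULL
  if (is.null(kin)) stop_invalid("no analyzable subject in ", in_dir)

  stats_df <- compute_group_stats(kin, brk, emg, combos, options, note)
  cors <- compute_correlations(kin, emg, combos, options, note)

  write.csv(format_num(kin), file.path(out_dir, "kinematics.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(format_num(brk), file.path(out_dir, "braking.csv"),
            row.names = FALSE, quote = FALSE)
  if (!is.null(emg)) {
    write.csv(format_num(emg), file.path(out_dir, "emg.csv"),
              row.names = FALSE, quote = FALSE)
  }
  write.csv(format_num(stats_df), file.path(out_dir, "stats.csv"),
            row.names = FALSE, quote = FALSE)
  if (!is.null(cors)) {
    write.csv(format_num(cors), file.path(out_dir, "correlations.csv"),
              row.names = FALSE, quote = FALSE)
  }
  manifest <- list(
    stage = "analyze",
    package_version = as.character(packageVersion("armbeat")),
    seed = config$seed,
    options = unclass(options),
    rows = list(
      kinematics = nrow(kin), braking = nrow(brk),
      emg = if (is.null(emg)) 0L else nrow(emg), stats = nrow(stats_df)
    ),
    warnings = warnings_log
  )
  write_manifest(manifest, file.path(out_dir, "manifest_analysis.json"))
  render_report(out_dir)
  invisible(manifest)
}

# One comparison row: group summary + t-test, NA-padded when a group is
# missing or too small.
comparison_row <- function(values, groups, combo, family, key, variant) {
  a <- values[groups == "A"]
  b <- values[groups == "B"]
  row <- data.frame(
    combo = combo, family = family, key = key,
    mean_a = NA_real_, sd_a = NA_real_, n_a = length(a),
    mean_b = NA_real_, sd_b = NA_real_, n_b = length(b),
    diff = NA_real_, t = NA_real_, df = NA_real_, p = NA_real_,
    significant_05 = NA, significant_01 = NA, stringsAsFactors = FALSE
  )
  if (length(a)) { row$mean_a <- mean(a); row$sd_a <- if (length(a) > 1) sd(a) else NA_real_ }
  if (length(b)) { row$mean_b <- mean(b); row$sd_b <- if (length(b) > 1) sd(b) else NA_real_ }
  if (length(a) >= 2 && length(b) >= 2) {
    gs <- group_summary(list(A = a, B = b), metric = key)
    row$diff <- gs$difference
    tt <- suppressWarnings(independent_t_test(a, b, variant, metric = key))
    row$t <- tt$t; row$df <- tt$df; row$p <- tt$p
    row$significant_05 <- tt$significant_05
    row$significant_01 <- tt$significant_01
  }
  row
}

compute_group_stats <- function(kin, brk, emg, combos, options, note) {
  rows <- list()
  add <- function(r) rows[[length(rows) + 1L]] <<- r
  variant <- options$t_variant
  for (combo in combos) {
    k <- kin[kin$combo == combo & kin$hand == "averaged", ]
    for (plane in c("XY", "XZ", "YZ", "XYZ")) {
      kp <- k[k$plane == plane, ]
      add(comparison_row(kp$length_m, kp$group, combo, "track_length", plane, variant))
      add(comparison_row(kp$relative_length, kp$group, combo,
                         "relative_track_length", plane, variant))
    }
    b <- brk[brk$combo == combo & brk$hand == "averaged" & !brk$degenerate, ]
    for (beat in sort(unique(b$beat_index))) {
      bb <- b[b$beat_index == beat, ]
      add(comparison_row(bb$delta_v, bb$group, combo, "delta_v",
                         as.character(beat), variant))
      add(comparison_row(bb$a_bar, bb$group, combo, "a_bar",
                         as.character(beat), variant))
    }
    if (!is.null(emg)) {
      e <- emg[emg$combo == combo & emg$window == "trial", ]
      for (ch in emg_channels()) {
        ec <- e[e$channel == ch, ]
        if (!nrow(ec)) next
        add(comparison_row(ec$rms_pct, ec$group, combo, "rms_pct", ch, variant))
        add(comparison_row(ec$iemg_pct, ec$group, combo, "iemg_pct", ch, variant))
      }
    }
  }
  do.call(rbind, rows)
}

compute_correlations <- function(kin, emg, combos, options, note) {
  if (is.null(emg)) return(NULL)
  rows <- list()
  for (combo in combos) {
    k <- kin[kin$combo == combo & kin$hand == "averaged" & kin$plane == "XYZ", ]
    e <- emg[emg$combo == combo & emg$window == "trial", ]
    ids <- intersect(k$subject_id, unique(e$subject_id))
    if (length(ids) < 3L) next
    d <- do.call(rbind, lapply(ids, function(id) {
      es <- e[e$subject_id == id, ]
      data.frame(
        subject_id = id, group = k$group[k$subject_id == id][1],
        track_length = k$length_m[k$subject_id == id][1],
        rms_pct = mean(es$rms_pct), iemg_pct = mean(es$iemg_pct),
        stringsAsFactors = FALSE
      )
    }))
    panel <- withCallingHandlers(
      correlation_panel(d, bands = options$grade_bands),
      warning = function(w) {
        note("combo %d correlations: %s", combo, conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
    rows[[length(rows) + 1L]] <- cbind(combo = combo, panel)
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

sig_stars <- function(p) {
  p <- suppressWarnings(as.numeric(p))
  ifelse(is.na(p), "", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

fmt_ms <- function(m, s) {
  m <- suppressWarnings(as.numeric(m))
  s <- suppressWarnings(as.numeric(s))
  out <- rep("", length(m))
  ok <- !is.na(m) & !is.na(s)
  out[ok] <- sprintf("%.3f ± %.3f", m[ok], s[ok])
  out
}

fmt3 <- function(x) {
  x <- suppressWarnings(as.numeric(x))
  out <- rep("", length(x))
  out[!is.na(x)] <- sprintf("%.3f", x[!is.na(x)])
  out
}

#' Render the analysis report
#'
#' Deterministically renders `report.md` from the stage CSVs written by
#' [analyze_cohort()]: per combination the track-length and relative
#' track-length tables by plane, the per-beat braking tables, the
#' standardized-EMG table by channel, and the correlation panel. Values
#' are printed to 3 decimals; significance is marked `*` (p < 0.05) and
#' `**` (p < 0.01). No value is computed here — every number traces to a
#' stage CSV row.
#'
#' @param metrics_dir directory holding `stats.csv` (and optionally
#'   `correlations.csv`).
#' @return The report path, invisibly.
#' @export
render_report <- function(metrics_dir) {
  stats_path <- file.path(metrics_dir, "stats.csv")
  if (!file.exists(stats_path)) stop_invalid("no stats.csv in ", metrics_dir)
  s <- read.csv(stats_path, stringsAsFactors = FALSE)
  needed <- c("combo", "family", "key", "mean_a", "sd_a", "mean_b", "sd_b",
              "diff", "t", "p")
  missing <- setdiff(needed, names(s))
  if (length(missing)) {
    stop_invalid("stats.csv schema mismatch: missing column ",
                 paste(missing, collapse = ", "))
  }
  lines <- c("# Arm manipulation analysis report", "")
  has_b <- any(s$n_b >= 2, na.rm = TRUE)
  if (!has_b) {
    lines <- c(lines,
               "> Warning: group B absent or too small; difference and test columns are blank.",
               "")
  }
  table_block <- function(d, keyname, title) {
    if (!nrow(d)) return(character())
    header <- sprintf("| %s | Group A | Group B | A-B | t | p | sig |", keyname)
    sep <- "|---|---|---|---|---|---|---|"
    body <- sprintf(
      "| %s | %s | %s | %s | %s | %s | %s |",
      d$key, fmt_ms(d$mean_a, d$sd_a), fmt_ms(d$mean_b, d$sd_b),
      fmt3(d$diff), fmt3(d$t), fmt3(d$p), sig_stars(d$p)
    )
    c(paste0("## ", title), "", header, sep, body, "")
  }
  for (combo in sort(unique(s$combo))) {
    sc <- s[s$combo == combo, ]
    lines <- c(
      lines,
      table_block(sc[sc$family == "track_length" & sc$key != "XYZ", ], "Plane",
                  sprintf("Combination %d: track length (m)", combo)),
      table_block(sc[sc$family == "relative_track_length" & sc$key != "XYZ", ],
                  "Plane",
                  sprintf("Combination %d: relative track length (length/height)", combo)),
      table_block(sc[sc$family == "delta_v", ], "Beat",
                  sprintf("Combination %d: braking speed drop delta_v (m/s)", combo)),
      table_block(sc[sc$family == "a_bar", ], "Beat",
                  sprintf("Combination %d: mean braking acceleration a_bar (m/s^2)", combo)),
      table_block(sc[sc$family == "rms_pct", ], "Channel",
                  sprintf("Combination %d: standardized RMS (%% MVIC)", combo)),
      table_block(sc[sc$family == "iemg_pct", ], "Channel",
                  sprintf("Combination %d: standardized iEMG (%% MVIC)", combo))
    )
  }
  cor_path <- file.path(metrics_dir, "correlations.csv")
  if (file.exists(cor_path)) {
    cors <- read.csv(cor_path, stringsAsFactors = FALSE)
    lines <- c(lines, "## Correlation panel (track length, RMS%, iEMG%)", "",
               "| Combo | Group | Pair | r | p | grade |",
               "|---|---|---|---|---|---|",
               sprintf("| %d | %s | %s | %s | %s | %s |",
                       cors$combo, cors$group, cors$pair, fmt3(cors$r),
                       fmt3(cors$p), ifelse(is.na(cors$grade), "", cors$grade)),
               "")
  }
  path <- file.path(metrics_dir, "report.md")
  writeLines(lines, path)
  invisible(path)
}

#' Load a run configuration from YAML
#'
#' Reads a YAML file with optional top-level blocks `cohort` (arguments of
#' [cohort_config()]) and `options` (arguments of [analysis_options()]).
#'
#' @param path YAML file path.
#' @return List with elements `config` and `options`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg_args <- y$cohort %||% list()
  for (field in c("amplitude_scale", "braking_sharpness")) {
    if (!is.null(cfg_args[[field]])) cfg_args[[field]] <- unlist(cfg_args[[field]])
  }
  if (!is.null(cfg_args$muscle_weights)) {
    cfg_args$muscle_weights <- lapply(cfg_args$muscle_weights, unlist)
  }
  opt_args <- y$options %||% list()
  if (!is.null(opt_args$emg_band)) opt_args$emg_band <- unlist(opt_args$emg_band)
  if (!is.null(opt_args$grade_bands)) opt_args$grade_bands <- unlist(opt_args$grade_bands)
  list(config = do.call(cohort_config, cfg_args),
       options = do.call(analysis_options, opt_args))
}

#' Command-line entry point
#'
#' Thin dispatcher behind the `inst/cli/armbeat.R` script:
#' `simulate --config cfg.yaml --out DIR`,
#' `analyze --in DIR --out DIR [--config cfg.yaml]`,
#' `report --in DIR`.
#'
#' @param argv character vector of arguments (defaults to the command
#'   line).
#' @return Exit status 0 invisibly; stops with a message on usage errors.
#' @export
armbeat_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage:",
    "  armbeat simulate --config cfg.yaml --out DIR",
    "  armbeat analyze --in DIR --out DIR [--config cfg.yaml]",
    "  armbeat report --in DIR",
    sep = "\n"
  )
  if (!length(argv)) stop_invalid(usage)
  cmd <- argv[1]
  opts <- list()
  i <- 2L
  while (i <= length(argv)) {
    key <- sub("^--", "", argv[i])
    if (i + 1L > length(argv)) stop_invalid("missing value for --", key)
    opts[[key]] <- argv[i + 1L]
    i <- i + 2L
  }
  run <- if (!is.null(opts$config)) read_run_config(opts$config) else
    list(config = cohort_config(), options = analysis_options())
  switch(cmd,
    simulate = {
      if (is.null(opts$out)) stop_invalid("simulate needs --out DIR")
      simulate_cohort(run$config, opts$out)
      message("cohort written to ", opts$out)
    },
    analyze = {
      if (is.null(opts$`in`) || is.null(opts$out)) {
        stop_invalid("analyze needs --in DIR and --out DIR")
      }
      analyze_cohort(opts$`in`, opts$out, run$options)
      message("analysis written to ", opts$out)
    },
    report = {
      if (is.null(opts$`in`)) stop_invalid("report needs --in DIR")
      render_report(opts$`in`)
      message("report rendered in ", opts$`in`)
    },
    stop_invalid("unknown command '", cmd, "'\n", usage)
  )
  invisible(0L)
}
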