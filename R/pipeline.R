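#' Write a session's raw tables to delimited text files
#'
#' Long-format trace tables (`participant, video, condition, time_s, value`),
#' the trial-record table, and the ground-truth event table, written as
#' tab-separated text. See `inst/extdata/data_dictionary.tsv` for the column
#' dictionary.
#'
#' @param session output of [generate_session()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  # numerics are written with 17 significant digits so a written session
  # reads back bit-identically (exact reproduction of downstream MCMC)
  full_prec <- function(d) {
    d[] <- lapply(d, function(col)
      if (is.double(col)) sprintf("%.17g", col) else col)
    d
  }
  long_one <- function(tr) {
    data.frame(participant = tr$participant, video = tr$video,
               condition = tr$condition,
               time_s = (seq_along(tr$values) - 1) / tr$rate,
               value = tr$values, stringsAsFactors = FALSE)
  }
  for (sig in c("eda", "pupil", "joystick")) {
    rows <- lapply(session$traces, function(pv)
      lapply(pv, function(v) long_one(v[[sig]])))
    tab <- do.call(rbind, unlist(rows, recursive = FALSE))
    write.table(full_prec(tab), file.path(dir, paste0(sig, ".tsv")),
                sep = "\t", row.names = FALSE, quote = FALSE)
  }
  write.table(full_prec(session$trials), file.path(dir, "trials.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(session$ground_truth$events,
              file.path(dir, "ground_truth_events.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read session tables written by [write_session()]
#'
#' Reconstructs the nested trace structure (sampling rates are inferred from
#' the time grid). This is also the entry point for reproduction mode: any
#' dataset reshaped to this schema can be pushed through the pipeline.
#'
#' @param dir directory containing `eda.tsv`, `pupil.tsv`, `joystick.tsv`,
#'   `trials.tsv`.
#' @return list with `traces` and `trials` in the layout of
#'   [generate_session()].
#' @export
read_session <- function(dir) {
  read_sig <- function(sig) {
    f <- file.path(dir, paste0(sig, ".tsv"))
    stop_if_not(file.exists(f), paste("missing table:", f))
    read.delim(f, stringsAsFactors = FALSE)
  }
  tabs <- lapply(c(eda = "eda", pupil = "pupil", joystick = "joystick"),
                 read_sig)
  trials <- read.delim(file.path(dir, "trials.tsv"),
                       stringsAsFactors = FALSE)
  participants <- unique(trials$participant)
  traces <- lapply(participants, function(p) {
    vids <- unique(trials$video[trials$participant == p])
    out <- lapply(vids, function(v) {
      one <- lapply(names(tabs), function(sig) {
        d <- tabs[[sig]]
        d <- d[d$participant == p & d$video == v, ]
        d <- d[order(d$time_s), ]
        rate <- round(1 / median(diff(d$time_s)))
        tr <- new_trace(if (sig == "pupil") "pupil" else sig,
                        d$value, rate, participant = p, video = v,
                        condition = d$condition[1])
        if (sig == "pupil") tr$blink_mask <- is.na(d$value)
        tr
      })
      names(one) <- names(tabs)
      one
    })
    names(out) <- vids
    out
  })
  names(traces) <- participants
  list(traces = traces, trials = trials)
}

#' Validate session tables
#'
#' Schema, unit-range and completeness checks for the long-format tables:
#' required columns present, condition labels valid, joystick values in
#' `[0, 0.5]`, ratings in `[1, 7]`, time grids positive and increasing.
#'
#' @param tables named list with any of `eda`, `pupil`, `joystick` (long
#'   data.frames) and `trials`.
#' @return data.frame of violations (zero rows when everything passes), with
#'   columns `table`, `check`, `message`.
#' @export
validate_inputs <- function(tables) {
  v <- list()
  note <- function(tab, check, msg) {
    v[[length(v) + 1]] <<- data.frame(table = tab, check = check,
                                      message = msg,
                                      stringsAsFactors = FALSE)
  }
  trace_cols <- c("participant", "video", "condition", "time_s", "value")
  for (sig in intersect(names(tables), c("eda", "pupil", "joystick"))) {
    d <- tables[[sig]]
    missing_cols <- setdiff(trace_cols, names(d))
    if (length(missing_cols)) {
      note(sig, "schema", paste("missing columns:",
                                paste(missing_cols, collapse = ", ")))
      next
    }
    bad_cond <- setdiff(unique(d$condition),
                        c("neutral", "amusement", "awe"))
    if (length(bad_cond)) {
      note(sig, "labels", paste("unknown condition:",
                                paste(bad_cond, collapse = ", ")))
    }
    if (any(d$time_s < 0, na.rm = TRUE)) {
      note(sig, "range", "negative time_s")
    }
    if (sig == "joystick" &&
        any(d$value < 0 | d$value > 0.5, na.rm = TRUE)) {
      note(sig, "range", "joystick values outside [0, 0.5]")
    }
    if (sig != "pupil" && anyNA(d$value)) {
      note(sig, "completeness", "missing values outside pupil table")
    }
  }
  if ("trials" %in% names(tables)) {
    d <- tables$trials
    need <- c("participant", "video", "condition")
    missing_cols <- setdiff(need, names(d))
    if (length(missing_cols)) {
      note("trials", "schema", paste("missing columns:",
                                     paste(missing_cols, collapse = ", ")))
    } else {
      rating_cols <- intersect(rownames(synthetic_config()$rating_means),
                               names(d))
      for (rc in rating_cols) {
        if (any(d[[rc]] < 1 | d[[rc]] > 7, na.rm = TRUE)) {
          note("trials", "range", paste("rating outside [1, 7]:", rc))
        }
      }
      bad_cond <- setdiff(unique(d$condition),
                          c("neutral", "amusement", "awe"))
      if (length(bad_cond)) {
        note("trials", "labels", paste("unknown condition:",
                                       paste(bad_cond, collapse = ", ")))
      }
    }
  }
  if (!length(v)) {
    return(data.frame(table = character(), check = character(),
                      message = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, v)
}

fnv_hash <- function(x) {
  s <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 2166136261
  for (b in s) h <- bitwAnd(bitwXor(h, b) * 16777619, 4294967295) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Run the full analysis pipeline
#'
#' Orchestrates generate (or load) -> SCR feature extraction -> pupil
#' preprocessing -> 1-Hz series -> smoothed-trend fits and fluctuation
#' contrasts -> hierarchical condition contrasts, with one master seed and a
#' machine-readable run manifest.
#'
#' Participants whose pupil trace exceeds the missing-data threshold on any
#' video are excluded from all analyses.
#'
#' @param config list. `mode` is `"synthetic"` (default; field `synthetic`
#'   holds [synthetic_config()] overrides) or `"reproduction"` (field
#'   `input_dir` names a directory of tables in the [write_session()]
#'   schema). Optional blocks: `eda` (min_amplitude, highpass_hz),
#'   `pupil` (max_missing, window_ms, pad_ms), `sampler` (chains, iter,
#'   warmup, paper_scale), `outcomes` (trial outcomes to contrast),
#'   `out_dir` (write result tables), `seed`.
#' @return object of class `pipeline_result`: trial table with outcomes,
#'   contrast fits, per-signal fluctuation contrasts, trend fits,
#'   diagnostics, exclusions, and `manifest`.
#' @export
run_pipeline <- function(config = list()) {
  t0 <- Sys.time()
  mode <- config$mode %||% "synthetic"
  seed <- as.integer(config$seed %||% 1L)
  sampler <- modifyList(list(chains = 4, iter = 2000, warmup = 1000,
                             paper_scale = FALSE), config$sampler %||% list())
  eda_cfg <- modifyList(list(min_amplitude = 0.01, highpass_hz = 0.02),
                        config$eda %||% list())
  pupil_cfg <- modifyList(list(max_missing = 0.10, window_ms = 100,
                               pad_ms = 50, velocity_limit = 10),
                          config$pupil %||% list())

  stages <- character()
  stage <- function(nm) {
    stages <<- c(stages, sprintf("%s @ %.1fs", nm,
                                 as.numeric(Sys.time() - t0, units = "secs")))
    message("[awedyn] stage: ", nm)
  }

  if (mode == "synthetic") {
    stage("generate")
    syn <- do.call(synthetic_config,
                   modifyList(config$synthetic %||% list(),
                              list(seed = seed)))
    session <- generate_session(syn)
  } else if (mode == "reproduction") {
    stage("load")
    stop_if_not(!is.null(config$input_dir),
                "reproduction mode needs config$input_dir")
    session <- read_session(config$input_dir)
  } else stop("unknown mode: ", mode)

  trials <- session$trials
  participants <- names(session$traces)
  vids <- unique(trials$video)
  duration <- length(session$traces[[1]][[1]]$pupil$values) /
    session$traces[[1]][[1]]$pupil$rate
  scr_window <- c(min(10, duration / 3), duration)

  # ---- pupil preprocessing + participant exclusion ----
  stage("pupil")
  pupil_series <- list()
  excluded <- character()
  for (p in participants) {
    res <- lapply(session$traces[[p]], function(v)
      pupil_preprocess_pipeline(v$pupil, pupil_cfg$velocity_limit,
                                pupil_cfg$pad_ms, pupil_cfg$window_ms,
                                pupil_cfg$max_missing))
    if (any(vapply(res, `[[`, logical(1), "exclude"))) {
      excluded <- c(excluded, p)
    } else {
      pupil_series[[p]] <- lapply(res, `[[`, "series")
    }
  }
  keep <- setdiff(participants, excluded)
  stop_if_not(length(keep) >= 2, "fewer than 2 participants retained")

  # ---- SCR features ----
  stage("eda")
  eda_traces <- unlist(lapply(keep, function(p)
    lapply(session$traces[[p]], `[[`, "eda")), recursive = FALSE)
  eda_res <- eda_feature_pipeline(eda_traces,
                                  min_amplitude = eda_cfg$min_amplitude,
                                  highpass_hz = eda_cfg$highpass_hz,
                                  window = scr_window)

  # ---- joystick series ----
  stage("joystick")
  joy_series <- lapply(keep, function(p)
    lapply(session$traces[[p]], function(v) to_second_series(v$joystick)))
  names(joy_series) <- keep

  # ---- group-level 1-Hz series per video and signal ----
  stage("series")
  series <- list()
  for (v in vids) {
    cond <- trials$condition[match(v, trials$video)]
    cnt <- lapply(keep, function(p) {
      idx <- which(vapply(eda_traces, function(tr)
        tr$participant == p && tr$video == v, logical(1)))
      eda_res$counts[[idx]]
    })
    s_cnt <- group_average(cnt)
    s_cnt$video <- v; s_cnt$condition <- cond; s_cnt$source <- "scr_count"
    s_pup <- group_average(lapply(keep, function(p) pupil_series[[p]][[v]]))
    s_joy <- group_average(lapply(keep, function(p) joy_series[[p]][[v]]))
    series[[v]] <- list(scr_count = s_cnt, pupil = s_pup, joystick = s_joy)
  }

  # ---- smoothed-trend fits and fluctuation contrasts ----
  stage("trend fits")
  fits <- list()
  fluct <- list()
  for (sig in c("scr_count", "pupil", "joystick")) {
    fits[[sig]] <- lapply(vids, function(v) {
      fit_trend(series[[v]][[sig]]$values, chains = sampler$chains,
                iter = sampler$iter, warmup = sampler$warmup,
                keep_states = FALSE,
                seed = sub_seed(seed, match(v, vids) * 31 +
                                  match(sig, c("scr_count", "pupil",
                                               "joystick"))),
                series_id = paste(sig, v, sep = ":"),
                paper_scale = sampler$paper_scale)
    })
    names(fits[[sig]]) <- vids
    cond_of <- vapply(vids, function(v)
      trials$condition[match(v, trials$video)], character(1))
    cond_draws <- lapply(c(neutral = "neutral", amusement = "amusement",
                           awe = "awe"), function(cc) {
      average_condition_sigma(fits[[sig]][cond_of == cc])
    })
    fluct[[sig]] <- fluctuation_contrast(cond_draws)
  }

  # ---- per-trial outcomes + hierarchical contrasts ----
  stage("contrasts")
  trials <- trials[trials$participant %in% keep, ]
  feat <- eda_res$features
  trials <- merge(trials, feat, by = c("participant", "video", "condition"),
                  all.x = TRUE, sort = FALSE)
  trials$mean_pupil <- mapply(function(p, v)
    mean(pupil_series[[p]][[v]]$values), trials$participant, trials$video)
  trials$mean_joystick <- mapply(function(p, v)
    mean(joy_series[[p]][[v]]$values), trials$participant, trials$video)

  outcomes <- config$outcomes %||%
    c("n_scrs", "mean_log_amplitude", "mean_log_rise", "mean_log_recovery",
      "mean_pupil", "mean_joystick")
  outcomes <- intersect(outcomes, names(trials))
  contrast_fits <- list()
  for (oc in outcomes) {
    d <- trials[!is.na(trials[[oc]]), ]
    if (nrow(d) < 6 || length(unique(d$condition)) < 2) next
    des <- build_design(d, oc, variant = "simple")
    contrast_fits[[oc]] <- fit_hier(des, chains = sampler$chains,
                                    iter = sampler$iter,
                                    warmup = sampler$warmup,
                                    seed = sub_seed(seed, 997 +
                                                      match(oc, outcomes)),
                                    paper_scale = sampler$paper_scale)
  }

  stage("done")
  manifest <- list(mode = mode, seed = seed,
                   config_hash = fnv_hash(config),
                   sampler = sampler,
                   n_participants = length(participants),
                   excluded = excluded,
                   r_version = R.version.string,
                   package_version =
                     as.character(utils::packageVersion("awedyn")),
                   stages = stages)

  out <- structure(list(trials = trials, series = series,
                        trend_fits = fits, fluctuation = fluct,
                        contrasts = contrast_fits,
                        contrast_table = summarize_fits(contrast_fits,
                          terms = c("awe_contrast", "amusement_contrast")),
                        events = eda_res$events,
                        excluded = excluded, manifest = manifest,
                        ground_truth = session$ground_truth %||% NULL),
                   class = "pipeline_result")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(out$contrast_table,
                file.path(config$out_dir, "contrast_table.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    fl <- do.call(rbind, lapply(names(fluct), function(sig)
      cbind(signal = sig, fluct[[sig]]$table)))
    write.table(fl, file.path(config$out_dir, "fluctuation_contrasts.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    write.table(trials, file.path(config$out_dir, "trial_records.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    writeLines(yaml::as.yaml(manifest),
               file.path(config$out_dir, "manifest.yaml"))
  }
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("awedyn pipeline result\n")
  cat(sprintf("  participants: %d retained, %d excluded\n",
              length(unique(x$trials$participant)), length(x$excluded)))
  cat("  fluctuation contrasts (sigma_dif, 95% CI):\n")
  for (sig in names(x$fluctuation)) {
    t <- x$fluctuation[[sig]]$table
    r <- t[t$contrast == "awe_vs_others", ]
    cat(sprintf("    %-10s awe-others: %.4g [%.4g, %.4g]%s\n", sig,
                r$eap, r$lower, r$upper, if (r$significant) " *" else ""))
  }
  if (nrow(x$contrast_table)) {
    cat("  condition contrasts (awe):\n")
    t <- x$contrast_table[x$contrast_table$term == "awe_contrast", ]
    for (i in seq_len(nrow(t))) {
      cat(sprintf("    %-20s %.3f [%.3f, %.3f]%s\n", t$outcome[i],
                  t$eap[i], t$lower[i], t$upper[i],
                  if (t$significant[i]) " *" else ""))
    }
  }
  invisible(x)
}
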