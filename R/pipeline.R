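#' Pipeline configuration
#'
#' @param kin_cutoff_hz Marker low-pass cut-off (12).
#' @param emg_highpass_hz sEMG high-pass cut-off (40).
#' @param envelope_hz Continuous envelope cut-off (25).
#' @param peak_envelope_hz Peak-timing envelope cut-off (10).
#' @param amp_frac,time_frac Double-threshold detector fractions (0.05,
#'   0.05).
#' @param alpha Test level for discrete and waveform comparisons (0.05).
#' @param analysis_unit `"horse_mean"` (default, paired across horses) or
#'   `"stride"` for the waveform comparisons.
#' @param max_gap Longest marker gap filled, frames (10).
#' @param seed Seed for any randomized step (the default pipeline is fully
#'   deterministic; the seed feeds the optional permutation oracle).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(kin_cutoff_hz = 12, emg_highpass_hz = 40,
                            envelope_hz = 25, peak_envelope_hz = 10,
                            amp_frac = 0.05, time_frac = 0.05, alpha = 0.05,
                            analysis_unit = c("horse_mean", "stride"),
                            max_gap = 10, seed = 1L) {
  stopifnot(amp_frac > 0, amp_frac < 1, time_frac > 0, time_frac < 1,
            alpha > 0, alpha < 1)
  structure(list(kin_cutoff_hz = kin_cutoff_hz,
                 emg_highpass_hz = emg_highpass_hz,
                 envelope_hz = envelope_hz,
                 peak_envelope_hz = peak_envelope_hz,
                 amp_frac = amp_frac, time_frac = time_frac, alpha = alpha,
                 analysis_unit = match.arg(analysis_unit),
                 max_gap = max_gap, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Validate a cohort manifest
#'
#' Checks trial completeness (horse, lead, marker and static files), the
#' four-muscle channel map (triceps, splenius, gluteal, biceps), file
#' existence, and that declared sampling rates match the file contents.
#'
#' @param path Path to `manifest.yaml`.
#' @return Data frame of errors (`trial`, `problem`); zero rows when the
#'   manifest is valid.
#' @export
validate_manifest <- function(path) {
  errs <- list()
  note <- function(trial, problem)
    errs[[length(errs) + 1]] <<- data.frame(trial = trial, problem = problem)
  if (!file.exists(path)) {
    note("<manifest>", paste0("file not found: ", path))
    return(do.call(rbind, errs))
  }
  man <- tryCatch(read_manifest(path), error = function(e) NULL)
  if (is.null(man) || is.null(man$trials) || is.null(man$dataset)) {
    note("<manifest>", "not a manifest: needs 'dataset' and 'trials'")
    return(do.call(rbind, errs))
  }
  dir <- dirname(path)
  muscles <- c("triceps", "splenius", "gluteal", "biceps")
  for (tr in man$trials) {
    id <- paste0(tr$horse %||% "?", "_", tr$lead %||% "?")
    if (is.null(tr$horse)) note(id, "missing horse id")
    if (is.null(tr$lead) || !tr$lead %in% c("left", "right"))
      note(id, "lead must be 'left' or 'right'")
    for (f in c(tr$markers, tr$static))
      if (is.null(f) || !file.exists(file.path(dir, f)))
        note(id, paste0("missing marker file: ", f %||% "<unset>"))
    for (m in muscles) {
      f <- tr$emg[[m]]
      if (is.null(f)) { note(id, paste0("missing ", m, " channel")); next }
      if (!file.exists(file.path(dir, f))) {
        note(id, paste0("missing sEMG file: ", f)); next
      }
      head <- utils::read.csv(file.path(dir, f), nrows = 50)
      if (nrow(head) > 2) {
        rate <- 1 / stats::median(diff(head$time_s))
        decl <- man$dataset$emg_rate_hz
        if (!is.null(decl) && abs(rate - decl) / decl > 0.01)
          note(id, sprintf("%s rate mismatch: declared %g Hz, file ~%.0f Hz",
                           m, decl, rate))
      }
    }
  }
  if (!length(errs))
    return(data.frame(trial = character(), problem = character()))
  do.call(rbind, errs)
}

# kinematic + sEMG processing of one trial; returns stride table, per-stride
# discrete sEMG rows (un-normalized), per-stride curves and EMG envelopes
process_trial <- function(tr, dir, man, config, statics_cache) {
  rate <- man$dataset$kin_rate_hz
  reader <- if (identical(man$dataset$marker_format, "trc"))
    function(p) read_trc(p) else function(p) read_markers_csv(p, rate)
  markers <- reader(file.path(dir, tr$markers))
  markers <- interpolate_gaps(markers, config$max_gap)
  markers <- lowpass_kinematics(markers, config$kin_cutoff_hz)
  static <- statics_cache[[tr$static]]

  angles <- compute_joint_angles(markers, static = static)
  hind_ev <- detect_hoof_events(markers, "hind")
  fore_ev <- detect_hoof_events(markers, "fore")
  strides <- segment_strides(hind_ev, fore_ev, tr$lead, tr$horse)
  strides <- spatiotemporal(strides, markers)

  curves <- list()
  for (j in names(angles)) {
    av <- angular_velocity(angles[[j]])
    for (k in seq_len(nrow(strides))) {
      w <- c(strides$start_s[k], strides$end_s[k])
      curves[[length(curves) + 1]] <- list(
        variable = paste0("angle_", j), stride = k,
        values = time_normalize(angles[[j]]$values, markers$time, w))
      curves[[length(curves) + 1]] <- list(
        variable = paste0("angvel_", j), stride = k,
        values = time_normalize(av$values, markers$time, w))
    }
  }
  for (limb in c("fore", "hind")) {
    pr <- compute_proretraction(markers, limb)
    for (k in seq_len(nrow(strides))) {
      w <- c(strides$start_s[k], strides$end_s[k])
      curves[[length(curves) + 1]] <- list(
        variable = paste0("proretraction_", limb), stride = k,
        values = time_normalize(pr$values, markers$time, w))
    }
  }

  emg <- list()
  for (m in names(tr$emg)) {
    ch <- read_emg_csv(file.path(dir, tr$emg[[m]]), man$dataset$emg_rate_hz,
                       muscle = m, horse = tr$horse, lead = tr$lead)
    rect <- preprocess_emg(ch, config$emg_highpass_hz)
    env25 <- butter_zero_phase(rect$values, config$envelope_hz, rect$rate_hz,
                               "low")
    env10 <- butter_zero_phase(rect$values, config$peak_envelope_hz,
                               rect$rate_hz, "low")
    bursts <- detect_bursts(rect, strides, man$dataset$mean_stride_s,
                            config$amp_frac, config$time_frac,
                            envelope_cutoff_hz = config$envelope_hz)
    per_stride <- lapply(seq_len(nrow(strides)), function(k) {
      w <- c(strides$start_s[k], strides$end_s[k])
      main <- bursts[bursts$stride == k & bursts$is_main, ]
      data.frame(
        stride = k,
        arv_raw = stride_arv(rect$values, rect$time, w),
        peak_pct = peak_timing(env10, rect$time, w),
        onset_pct = if (nrow(main)) main$onset_pct else NA_real_,
        offset_pct = if (nrow(main)) main$offset_pct else NA_real_,
        duration_pct = if (nrow(main)) main$duration_pct else NA_real_,
        has_main = nrow(main) > 0)
    })
    emg[[m]] <- list(per_stride = do.call(rbind, per_stride),
                     envelope = env25, time = rect$time)
  }
  list(strides = strides, curves = curves, emg = emg,
       dropped = attr(strides, "dropped") %||% 0L)
}

#' Run the full canter analysis pipeline on a dataset
#'
#' Ingests a manifest, processes every trial (marker filtering, joint
#' angles referenced to the static trial, angular velocities,
#' pro-retraction, hoof events, stride segmentation, spatiotemporal
#' variables; sEMG preprocessing, ARV, double-threshold burst timing, peak
#' timing, envelopes), normalizes ARVs and envelopes per horse and muscle,
#' and compares leading vs trailing limbs with within-subject mixed models
#' (discrete variables) and paired 1D SPM (101-point waveforms). Writes a
#' results bundle when `out_dir` is given.
#'
#' @param dataset_dir Directory holding `manifest.yaml` and the trial
#'   files.
#' @param out_dir Optional output directory for the results bundle.
#' @param config A [pipeline_config()].
#' @return Invisibly, a list: `strides`, `discrete` (long table),
#'   `summaries`, `comparisons`, `spm` (named list of `spm_paired`),
#'   `phasic`, `log`.
#' @export
run_gait_pipeline <- function(dataset_dir, out_dir = NULL,
                              config = pipeline_config()) {
  mp <- file.path(dataset_dir, "manifest.yaml")
  errs <- validate_manifest(mp)
  if (nrow(errs) > 0)
    stop("invalid manifest:\n", paste(errs$trial, errs$problem,
                                      sep = ": ", collapse = "\n"))
  man <- read_manifest(mp)
  rate <- man$dataset$kin_rate_hz
  reader <- if (identical(man$dataset$marker_format, "trc"))
    function(p) read_trc(p) else function(p) read_markers_csv(p, rate)
  statics <- unique(vapply(man$trials, function(tr) tr$static, character(1)))
  statics_cache <- lapply(stats::setNames(statics, statics), function(f)
    lowpass_kinematics(reader(file.path(dataset_dir, f)), config$kin_cutoff_hz))

  trials <- list(); failures <- character()
  for (tr in man$trials) {
    id <- paste0(tr$horse, "_", tr$lead)
    res <- tryCatch(
      process_trial(tr, dataset_dir, man, config, statics_cache),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, paste0(id, ": ", conditionMessage(res)))
      next
    }
    res$horse <- tr$horse; res$lead <- tr$lead
    trials[[id]] <- res
  }
  if (!length(trials)) stop("no trial survived processing:\n",
                            paste(failures, collapse = "\n"))

  # ---- discrete kinematic rows -------------------------------------------
  disc <- list()
  add <- function(df) disc[[length(disc) + 1]] <<- df
  for (tr in trials) {
    s <- tr$strides
    role_lead <- if (s$lead[1] == "right") "Ld" else "Tr"
    add(data.frame(horse = s$horse, lead = s$lead, limb_role = role_lead,
                   stride = s$stride, muscle = NA_character_,
                   variable = "stride_duration_s", value = s$stride_duration_s))
    add(data.frame(horse = s$horse, lead = s$lead, limb_role = role_lead,
                   stride = s$stride, muscle = NA_character_,
                   variable = "stride_velocity_mps",
                   value = s$stride_velocity_mps))
    add(data.frame(horse = s$horse, lead = s$lead, limb_role = s$role_fore,
                   stride = s$stride, muscle = NA_character_,
                   variable = "fore_stance_s", value = s$fore_stance_s))
    add(data.frame(horse = s$horse, lead = s$lead, limb_role = s$role_hind,
                   stride = s$stride, muscle = NA_character_,
                   variable = "hind_stance_s", value = s$hind_stance_s))
  }

  # ---- per-horse/muscle ARV + RVC normalization --------------------------
  muscles <- unlist(man$dataset$muscles)
  horses <- unique(vapply(trials, function(t) t$horse, character(1)))
  n_arv_outliers <- 0L
  emg_rows <- list()
  rvc_curves <- list()
  for (h in horses) {
    ids <- names(trials)[vapply(trials, function(t) t$horse == h, logical(1))]
    for (m in muscles) {
      ps <- do.call(rbind, lapply(ids, function(id) {
        d <- trials[[id]]$emg[[m]]$per_stride
        d$trial <- id
        d$lead <- trials[[id]]$lead
        d$limb_role <- emg_limb_role(m, trials[[id]]$lead)
        d
      }))
      out_fl <- if (nrow(ps) >= 4) flag_arv_outliers(ps$arv_raw)
        else rep(FALSE, nrow(ps))
      n_arv_outliers <- n_arv_outliers + sum(out_fl)
      ps$arv_outlier <- out_fl
      ps$arv_norm <- normalize_arv(ps$arv_raw, out_fl)
      ps$horse <- h; ps$muscle <- m
      emg_rows[[paste(h, m)]] <- ps
      # RVC across all strides of this horse and muscle
      all_peaks <- numeric(); wins <- list()
      for (id in ids) {
        e <- trials[[id]]$emg[[m]]
        s <- trials[[id]]$strides
        pk <- vapply(seq_len(nrow(s)), function(k) {
          w <- e$time >= s$start_s[k] & e$time < s$end_s[k]
          max(e$envelope[w])
        }, numeric(1))
        all_peaks <- c(all_peaks, pk)
      }
      fl <- if (length(all_peaks) >= 4) flag_arv_outliers(all_peaks)
        else rep(FALSE, length(all_peaks))
      rvc <- max(all_peaks[!fl])
      for (id in ids) {
        e <- trials[[id]]$emg[[m]]
        s <- trials[[id]]$strides
        for (k in seq_len(nrow(s))) {
          w <- c(s$start_s[k], s$end_s[k])
          rvc_curves[[length(rvc_curves) + 1]] <- list(
            horse = h, lead = trials[[id]]$lead,
            limb_role = emg_limb_role(m, trials[[id]]$lead),
            variable = paste0("emg_", m), stride = k,
            values = time_normalize(e$envelope * 100 / rvc, e$time, w))
        }
      }
    }
  }
  emg_tab <- do.call(rbind, emg_rows)
  # wrap boundary-straddling onsets per muscle (all strides and limbs)
  for (m in muscles) {
    i <- emg_tab$muscle == m
    emg_tab$onset_pct[i] <- wrap_onsets(emg_tab$onset_pct[i])
  }
  emg_tab$duration_pct <- ifelse(is.na(emg_tab$duration_pct), NA,
                                 emg_tab$duration_pct)
  for (v in c("arv_norm", "duration_pct", "onset_pct", "offset_pct",
              "peak_pct")) {
    keep <- if (v == "arv_norm") !emg_tab$arv_outlier else rep(TRUE, nrow(emg_tab))
    add(data.frame(horse = emg_tab$horse[keep], lead = emg_tab$lead[keep],
                   limb_role = emg_tab$limb_role[keep],
                   stride = emg_tab$stride[keep],
                   muscle = emg_tab$muscle[keep],
                   variable = v, value = emg_tab[[v]][keep]))
  }
  discrete <- do.call(rbind, disc)

  # ---- summaries and mixed-model comparisons -----------------------------
  summaries <- summarize_discrete(discrete)
  comparisons <- list()
  for (v in c("stride_duration_s", "stride_velocity_mps", "fore_stance_s",
              "hind_stance_s")) {
    cmp <- tryCatch(compare_limbs(discrete, v), error = function(e) NULL)
    if (!is.null(cmp))
      comparisons[[v]] <- data.frame(muscle = NA_character_, variable = v,
                                     estimate = cmp$estimate,
                                     p_value = cmp$p_value)
  }
  for (m in muscles) for (v in c("arv_norm", "duration_pct", "onset_pct",
                                 "offset_pct", "peak_pct")) {
    cmp <- tryCatch(compare_limbs(discrete, v, muscle = m),
                    error = function(e) NULL)
    if (!is.null(cmp))
      comparisons[[paste(m, v)]] <- data.frame(muscle = m, variable = v,
                                               estimate = cmp$estimate,
                                               p_value = cmp$p_value)
  }
  comparisons <- do.call(rbind, comparisons)

  # ---- SPM on per-horse mean curves --------------------------------------
  all_curves <- c(unlist(lapply(names(trials), function(id) {
    lapply(trials[[id]]$curves, function(cv) {
      role <- if (trials[[id]]$lead == "right") "leading" else "trailing"
      c(list(horse = trials[[id]]$horse, lead = trials[[id]]$lead,
             limb_role = role), cv)
    })
  }), recursive = FALSE),
  lapply(rvc_curves, function(cv) {
    cv$limb_role <- if (cv$lead == "right") "leading" else "trailing"
    cv
  }))
  vars <- unique(vapply(all_curves, function(cv) cv$variable, character(1)))
  spm_results <- list()
  for (v in vars) {
    sel <- all_curves[vapply(all_curves, function(cv) cv$variable == v,
                             logical(1))]
    mat <- do.call(rbind, lapply(sel, function(cv) cv$values))
    horse <- vapply(sel, function(cv) cv$horse, character(1))
    cond <- vapply(sel, function(cv) cv$limb_role, character(1))
    if (length(unique(cond)) != 2) next
    sm <- suppressWarnings(subject_means(mat, horse, cond))
    if (config$analysis_unit == "horse_mean") {
      a <- sm$values[sm$condition == "leading", , drop = FALSE]
      b <- sm$values[sm$condition == "trailing", , drop = FALSE]
      ha <- sm$horse[sm$condition == "leading"]
      hb <- sm$horse[sm$condition == "trailing"]
      a <- a[order(ha), , drop = FALSE]; b <- b[order(hb), , drop = FALSE]
    } else {
      stop("per-stride pooling is not a paired design; use horse_mean")
    }
    if (nrow(a) < 2) next
    res <- tryCatch(spm_paired(a, b, alpha = config$alpha, variable = v),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, paste0("spm ", v, ": ", conditionMessage(res)))
      next
    }
    spm_results[[v]] <- res
  }

  # ---- phasic composite-stride diagram -----------------------------------
  stance_rows <- summaries[summaries$variable %in%
                             c("fore_stance_s", "hind_stance_s"), ]
  msd <- mean(discrete$value[discrete$variable == "stride_duration_s"],
              na.rm = TRUE)
  stances <- do.call(rbind, lapply(seq_len(nrow(stance_rows)), function(i) {
    r <- stance_rows[i, ]
    pct <- r$mean / msd * 100
    start <- if (grepl("F$", r$limb_role))
      mean(vapply(trials, function(t)
        mean((t$strides$fore_impact_s - t$strides$start_s) /
               t$strides$stride_duration_s * 100), numeric(1))[
                 vapply(trials, function(t)
                   (if (t$lead == "right") "Ld" else "Tr") ==
                     substr(r$limb_role, 1, 2), logical(1))]) else 0
    data.frame(limb_role = r$limb_role, start_pct = start,
               end_pct = start + pct)
  }))
  bsum <- stats::aggregate(
    cbind(onset_pct, offset_pct) ~ muscle + limb_role, data = emg_tab,
    FUN = function(x) mean(x, na.rm = TRUE))
  cons <- stats::aggregate(has_main ~ muscle + limb_role, data = emg_tab,
                           FUN = mean)
  bsum$consistent <- cons$has_main[match(paste(bsum$muscle, bsum$limb_role),
                                         paste(cons$muscle, cons$limb_role))]
  trh <- summaries[summaries$variable == "hind_stance_s" &
                     summaries$limb_role == "TrH", ]
  trh_pct <- if (nrow(trh)) trh$mean / msd * 100 else
    mean(discrete$value[discrete$variable == "hind_stance_s"],
         na.rm = TRUE) / msd * 100
  phasic <- build_phasic_diagram(bsum, stances, trh_pct)

  strides_all <- do.call(rbind, lapply(trials, function(t) t$strides))
  log <- list(n_trials = length(trials), failures = failures,
              n_strides = nrow(strides_all),
              n_dropped = sum(vapply(trials, function(t) t$dropped,
                                     integer(1))),
              n_arv_outliers = n_arv_outliers)

  result <- list(strides = strides_all, discrete = discrete,
                 summaries = summaries, comparisons = comparisons,
                 spm = spm_results, phasic = phasic, log = log)
  if (!is.null(out_dir)) write_bundle(result, out_dir)
  invisible(result)
}

emg_limb_role <- function(muscle, lead) {
  fore <- muscle %in% c("triceps", "splenius")
  paste0(if (lead == "right") "Ld" else "Tr", if (fore) "F" else "H")
}

# results bundle: tidy CSVs plus JSON for SPM and the phasic diagram
write_bundle <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, f) utils::write.csv(
    df, file.path(out_dir, f), row.names = FALSE, quote = FALSE, na = "")
  wcsv(result$strides, "strides.csv")
  wcsv(result$discrete, "discrete.csv")
  wcsv(result$summaries, "summaries.csv")
  wcsv(result$comparisons, "comparisons.csv")
  spm_json <- lapply(result$spm, function(s)
    list(variable = s$variable, df = s$df, fwhm = s$fwhm, resels = s$resels,
         t_star = s$t_star, alpha = s$alpha, t_field = s$t,
         clusters = s$clusters))
  jsonlite::write_json(spm_json, file.path(out_dir, "spm.json"),
                       auto_unbox = TRUE, digits = 10)
  clusters <- do.call(rbind, lapply(result$spm, function(s)
    if (nrow(s$clusters)) cbind(variable = s$variable, s$clusters)))
  wcsv(clusters %||% data.frame(), "clusters.csv")
  jsonlite::write_json(result$phasic, file.path(out_dir, "phasic.json"),
                       auto_unbox = TRUE, digits = 10)
  jsonlite::write_json(result$log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = 10)
  invisible(out_dir)
}
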