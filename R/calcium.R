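## dF/F0 computation, per-stimulus response amplitudes and KCl/ionomycin
## cell gating for 1-Hz calcium recordings.

#' Calcium trace
#'
#' A fluorescence time series on a uniform 1-Hz grid.
#'
#' @param t time in seconds (strictly increasing, uniform).
#' @param F fluorescence (AU, finite).
#' @param cell_id identifier.
#' @return object of class `calcium_trace`.
#' @export
calcium_trace <- function(t, F, cell_id = "cell") {
  if (length(t) != length(F)) stop("t and F lengths differ")
  if (any(!is.finite(F))) stop("F must be finite")
  dt <- diff(t)
  if (any(dt <= 0)) stop("t must be strictly increasing")
  if (length(dt) && max(abs(dt - dt[1])) > 1e-9) stop("t must be uniform")
  structure(list(t = as.numeric(t), F = as.numeric(F), cell_id = cell_id),
            class = "calcium_trace")
}

#' Stimulus schedule
#'
#' Non-overlapping, time-sorted stimulus applications.  The typical
#' protocol applies 2-s pulses of GABA, glutamate, KCl and ionomycin
#' separated by 2-min washouts; [default_schedule()] reproduces it.
#'
#' @param label stimulus labels (e.g. GABA, glutamate, KCl, ionomycin).
#' @param onset onsets in seconds.
#' @param duration durations in seconds.
#' @return object of class `stimulus_schedule`.
#' @export
stimulus_schedule <- function(label, onset, duration = 2) {
  duration <- rep(duration, length.out = length(label))
  o <- order(onset)
  label <- label[o]; onset <- onset[o]; duration <- duration[o]
  if (length(onset) > 1 &&
      any(onset[-1] < (onset + duration)[-length(onset)]))
    stop("events must not overlap")
  structure(list(events = data.frame(label = label, onset = onset,
                                     duration = duration)),
            class = "stimulus_schedule")
}

#' Default four-stimulus schedule
#'
#' 2-s applications of GABA, glutamate, KCl and ionomycin separated by
#' 120-s washouts, starting at `first_onset`.
#'
#' @param first_onset onset of the first stimulus in s.
#' @return a [stimulus_schedule()].
#' @export
default_schedule <- function(first_onset = 60) {
  stimulus_schedule(c("GABA", "glutamate", "KCl", "ionomycin"),
                    first_onset + 120 * (0:3), 2)
}

#' Compute dF/F0
#'
#' `dF/F0 = (F - F0) / F0` with `F0` the mean fluorescence over the
#' baseline window (resting conditions preceding the first stimulus; the
#' default window is the 30 s before `first_stim_onset`).
#'
#' @param trace a [calcium_trace()].
#' @param baseline_window `c(start, end)` in s, or `NULL` to derive it from
#'   `first_stim_onset`.
#' @param first_stim_onset onset of the first stimulus (s), used when
#'   `baseline_window` is `NULL`.
#' @return numeric dF/F0 series (same length as the trace) with attribute
#'   `F0`.
#' @export
compute_dff <- function(trace, baseline_window = NULL,
                        first_stim_onset = NULL) {
  stopifnot(inherits(trace, "calcium_trace"))
  if (is.null(baseline_window)) {
    if (is.null(first_stim_onset))
      stop("either baseline_window or first_stim_onset is required")
    baseline_window <- c(max(min(trace$t), first_stim_onset - 30),
                         first_stim_onset)
  }
  sel <- trace$t >= baseline_window[1] & trace$t < baseline_window[2]
  if (!any(sel)) stop("invalid baseline")
  F0 <- mean(trace$F[sel])
  if (F0 <= 0) stop("invalid baseline")
  structure((trace$F - F0) / F0, F0 = F0)
}

#' Per-stimulus peak dF/F0
#'
#' Peak of the dF/F0 series within `[onset, onset + response_window]` for
#' each scheduled event.
#'
#' @param dff numeric dF/F0 series.
#' @param t time vector matching `dff` (s).
#' @param schedule a [stimulus_schedule()].
#' @param response_window seconds after onset searched for the peak.
#' @return named numeric vector of peaks (one per event, in schedule
#'   order).
#' @export
stimulus_amplitudes <- function(dff, t, schedule, response_window = 30) {
  ev <- if (inherits(schedule, "stimulus_schedule")) schedule$events
        else schedule
  peaks <- numeric(nrow(ev))
  for (e in seq_len(nrow(ev))) {
    if (ev$onset[e] < min(t) || ev$onset[e] + response_window > max(t))
      stop(sprintf("response window for '%s' out of range", ev$label[e]))
    sel <- t >= ev$onset[e] & t <= ev$onset[e] + response_window
    peaks[e] <- max(dff[sel])
  }
  names(peaks) <- ev$label
  peaks
}

#' Classify a cell from its KCl and ionomycin responses
#'
#' Gate precedence: a cell is `non_viable` when its ionomycin peak is below
#' `viability_iono_min`; otherwise it is a `neuron` iff its KCl peak is at
#' least `neuron_kcl_min`, else `non_neuronal` (glia).  KCl depolarization
#' separates neurons from glia; ionomycin (a calcium ionophore) probes
#' viability.
#'
#' @param peaks named numeric vector of per-stimulus peak dF/F0 including
#'   `KCl` and `ionomycin`.
#' @param neuron_kcl_min minimum KCl peak dF/F0 for a neuron.
#' @param viability_iono_min minimum ionomycin peak dF/F0 for viability.
#' @return one of `"neuron"`, `"non_neuronal"`, `"non_viable"`.
#' @export
classify_cell <- function(peaks, neuron_kcl_min = 0.1,
                          viability_iono_min = 0.2) {
  if (!all(c("KCl", "ionomycin") %in% names(peaks)))
    stop("KCl and ionomycin peaks are required")
  if (peaks[["ionomycin"]] < viability_iono_min) return("non_viable")
  if (peaks[["KCl"]] >= neuron_kcl_min) "neuron" else "non_neuronal"
}

#' Analyze a set of traces against a schedule
#'
#' Convenience wrapper: computes dF/F0 (baseline = 30 s before the first
#' stimulus), per-stimulus peaks and the KCl/ionomycin classification for
#' every cell column of a wide trace table.
#'
#' @param traces data.frame with column `t` plus one column per cell.
#' @param schedule a [stimulus_schedule()].
#' @param response_window seconds after onset searched for the peak.
#' @param neuron_kcl_min,viability_iono_min gating thresholds.
#' @return data.frame: one row per cell with per-stimulus peak columns,
#'   `class`, `is_neuron`, `is_viable`.
#' @export
calcium_profiles <- function(traces, schedule, response_window = 30,
                             neuron_kcl_min = 0.1,
                             viability_iono_min = 0.2) {
  ev <- schedule$events
  cells <- setdiff(names(traces), "t")
  rows <- lapply(cells, function(cn) {
    tr <- calcium_trace(traces$t, traces[[cn]], cn)
    dff <- compute_dff(tr, first_stim_onset = min(ev$onset))
    pk <- stimulus_amplitudes(dff, tr$t, schedule, response_window)
    cls <- classify_cell(pk, neuron_kcl_min, viability_iono_min)
    cbind(data.frame(cell_id = cn), as.data.frame(as.list(pk)),
          data.frame(class = cls, is_neuron = cls == "neuron",
                     is_viable = cls != "non_viable"))
  })
  do.call(rbind, rows)
}

#' Per-group mean and SEM of stimulus responses
#'
#' Averages per-stimulus peak dF/F0 over classified neurons only
#' (non-viable and non-neuronal cells are excluded), per group.  Values are
#' reported as mean and standard error of the mean.
#'
#' @param profiles data.frame from [calcium_profiles()].
#' @param grouping named character vector or factor: `cell_id` -> group.
#' @param stimuli stimulus columns to summarize (default: all present).
#' @return data.frame with columns `group`, `stimulus`, `n`, `mean`, `sem`
#'   (`sem` is `NA` for singleton groups).
#' @export
group_summary <- function(profiles, grouping, stimuli = NULL) {
  profiles <- profiles[profiles$class == "neuron", , drop = FALSE]
  grp <- grouping[profiles$cell_id]
  if (is.null(stimuli))
    stimuli <- setdiff(names(profiles),
                       c("cell_id", "class", "is_neuron", "is_viable"))
  out <- list()
  for (g in unique(grouping)) {
    sub <- profiles[grp == g & !is.na(grp), , drop = FALSE]
    if (!nrow(sub)) { warning("empty group omitted: ", g); next }
    for (st in stimuli) {
      v <- sub[[st]]
      out[[length(out) + 1L]] <-
        data.frame(group = g, stimulus = st, n = length(v), mean = mean(v),
                   sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v))
                         else NA_real_)
    }
  }
  if (!length(out)) {
    warning("no viable neurons in any group")
    return(data.frame(group = character(), stimulus = character(),
                      n = integer(), mean = numeric(), sem = numeric()))
  }
  do.call(rbind, out)
}
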