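#' Run the full trace-analysis chain on a trace set
#'
#' End-to-end analysis in the order the data are acquired and reduced:
#' quality control (anticorrelation + single-step bleach), bleed-through
#' correction, FRET computation with truncation at the detected bleach,
#' HMM idealization with BIC state selection, width-based transition
#' filtering, assignment of dwells to the declared FRET levels,
#' mechanistic classification, replicate class fractions, and (for every
#' requested transition class) dwell extraction, exponential decay
#' fitting and photobleach/window rate correction. Rates are taken from
#' the quantization-aware maximum-likelihood estimate of [fit_dwell]
#' (the histogram fit is reported alongside), and when both directions
#' of a reversible two-state phase are requested the dead-time
#' missed-event correction ([correct_missed_events]) is applied before
#' the photobleach/window correction. One log line per stage reports
#' the number of traces in and out and the thresholds used.
#'
#' @param ts a `trace_set` (from [generate_dataset] or
#'   [read_trace_set]).
#' @param config an [analysis_config].
#' @param dwell_classes named list of `c(from, to)` level pairs to
#'   extract and fit, e.g. `list(dissociation = c("high", "dark"))`.
#' @param verbose emit per-stage log lines (default `TRUE`).
#' @return An `analysis_result`: list with `qc` (report), `ftraces`,
#'   `itraces` (level-assigned), `classes` (per-trace data frame),
#'   `fractions` (a `classification_result`), `dwells` (per class: the
#'   pooled fitted `dwell_distribution` plus per-replicate corrected
#'   rates with mean and s.d.), and `config`.
#' @export
analyze_traces <- function(ts, config = analysis_config(),
                           dwell_classes = list(), verbose = TRUE) {
  say <- function(...) if (verbose) message("[analyze] ", ...)
  trs <- ts$traces
  man <- ts$manifest
  say(length(trs), " traces in; qc: anticorr <= ",
      config$anticorr_threshold, ", bleach steps <= 1")
  qc <- qc_select(trs, anticorr_threshold = config$anticorr_threshold,
                  beta = config$beta)
  say(length(qc$traces), " traces pass qc")
  kept_ids <- vapply(qc$traces, function(tr) attr(tr, "molecule_id"),
                     character(1))
  replicate <- man$replicate[match(kept_ids, man$molecule_id)]

  ftraces <- lapply(qc$traces, function(tr)
    compute_fret(correct_bleedthrough(tr, config$beta)))
  ok <- !vapply(ftraces, function(f) isTRUE(attr(f, "all_invalid")),
                logical(1))
  ftraces <- ftraces[ok]; replicate <- replicate[ok]
  kept_ids <- kept_ids[ok]
  say(length(ftraces), " traces with valid FRET (beta = ", config$beta, ")")

  itraces <- lapply(ftraces, function(f)
    idealize(f, max_states = config$max_states))
  fitted <- !vapply(itraces, is.null, logical(1))
  itraces <- itraces[fitted]; replicate2 <- replicate[fitted]
  ids2 <- kept_ids[fitted]
  say(length(itraces), " traces idealized (max ", config$max_states,
      " states, BIC)")
  itraces <- lapply(itraces, filter_transitions)
  itraces <- lapply(itraces, assign_levels, levels = config$levels)

  classes <- vapply(itraces, classify_trace,
                    min_frames = config$min_frames, character(1))
  class_df <- data.frame(molecule_id = ids2, replicate = replicate2,
                         class = classes)
  fractions <- class_fractions(classes, replicate2)
  say("classes: ", paste(names(table(classes)), table(classes),
                         sep = "=", collapse = ", "))

  # raw dwell fits per class (pooled and per replicate)
  dwells <- list()
  for (nm in names(dwell_classes)) {
    pair <- dwell_classes[[nm]]
    pooled <- extract_dwells(itraces, pair[1], pair[2])
    pooled <- tryCatch(
      fit_dwell(pooled, bin_frames = config$bin_frames,
                min_dwells = config$min_dwells),
      warning = function(w) { say(nm, ": ", conditionMessage(w)); pooled })
    per_rep <- do.call(rbind, lapply(sort(unique(replicate2)), function(r) {
      dr <- extract_dwells(itraces[replicate2 == r], pair[1], pair[2])
      k_obs <- NA_real_
      if (dr$n >= config$min_dwells) {
        dr <- suppressWarnings(fit_dwell(dr, bin_frames = config$bin_frames,
                                         min_dwells = config$min_dwells))
        if (!is.null(dr$fit)) k_obs <- dr$fit$k_mle
      }
      data.frame(replicate = r, n = dr$n, k_observed = k_obs)
    }))
    dwells[[nm]] <- list(pooled = pooled, per_replicate = per_rep,
                         pair = pair, n_total = pooled$n)
  }

  # missed-event correction where both directions of a reversible
  # two-state phase were requested, then photobleach/window correction
  pairs_of <- vapply(dwells, function(d) paste(d$pair, collapse = ">"),
                     character(1))
  for (nm in names(dwells)) {
    d <- dwells[[nm]]
    rev_nm <- names(pairs_of)[pairs_of == paste(rev(d$pair),
                                                collapse = ">")]
    k_obs_pool <- if (!is.null(d$pooled$fit)) d$pooled$fit$k_mle
                  else NA_real_
    k_obs_rep <- d$per_replicate$k_observed
    if (length(rev_nm) == 1L) {
      dr <- dwells[[rev_nm]]
      k_rev_pool <- if (!is.null(dr$pooled$fit)) dr$pooled$fit$k_mle
                    else NA_real_
      if (!is.na(k_obs_pool) && !is.na(k_rev_pool))
        k_obs_pool <- unname(correct_missed_events(k_obs_pool,
                                                   k_rev_pool)["k_fwd"])
      k_obs_rep <- mapply(function(ka, kb) {
        if (is.na(ka) || is.na(kb)) return(ka)
        unname(correct_missed_events(ka, kb)["k_fwd"])
      }, k_obs_rep, dr$per_replicate$k_observed)
    }
    k_corr_rep <- ifelse(is.na(k_obs_rep), NA_real_,
                         suppressWarnings(as.numeric(correct_rate(
                           k_obs_rep, config$k_photobleach,
                           config$window))))
    est <- k_corr_rep[!is.na(k_corr_rep)]
    dwells[[nm]]$per_replicate$k_observed <- k_obs_rep
    dwells[[nm]]$per_replicate$k_corrected <- k_corr_rep
    dwells[[nm]]$k_corrected_pooled <- if (is.na(k_obs_pool)) NA_real_
      else as.numeric(suppressWarnings(correct_rate(
        k_obs_pool, config$k_photobleach, config$window)))
    dwells[[nm]]$k_corrected_mean <- if (length(est)) mean(est)
                                     else NA_real_
    dwells[[nm]]$k_corrected_sd <- if (length(est) > 1) stats::sd(est)
                                   else NA_real_
    say(nm, ": n = ", dwells[[nm]]$n_total,
        ", k_corrected (mean over replicates) = ",
        signif(dwells[[nm]]$k_corrected_mean, 4), " s^-1")
  }

  structure(list(qc = qc$report, ftraces = ftraces, itraces = itraces,
                 classes = class_df, fractions = fractions,
                 dwells = dwells, replicate = replicate2,
                 config = config),
            class = "analysis_result")
}

#' Pool FRET frames belonging to given levels
#'
#' Selects, per replicate, the per-frame FRET values of dwells assigned
#' to the requested levels — the phase selection behind state-histogram
#' fitting (e.g. the codon-reading phase, or the post-decoding
#' fluctuation phase).
#'
#' @param res an [analyze_traces] result.
#' @param levels_wanted character vector of level names.
#' @return A list (one numeric vector per replicate) suitable for
#'   [fit_fret_histogram].
#' @export
pool_phase_frames <- function(res, levels_wanted) {
  reps <- sort(unique(res$replicate))
  idx_by_id <- stats::setNames(seq_along(res$ftraces),
                               vapply(res$ftraces, attr, "", "molecule_id"))
  out <- lapply(reps, function(r) {
    sel <- which(res$replicate == r)
    unlist(lapply(sel, function(i) {
      it <- res$itraces[[i]]
      ft <- res$ftraces[[idx_by_id[[it$molecule_id]]]]
      segs <- it$segments[it$segments$level %in% levels_wanted, ,
                          drop = FALSE]
      unlist(lapply(seq_len(nrow(segs)), function(s) {
        fr <- segs$start_frame[s]:segs$end_frame[s]
        e <- ft$E[ft$frame %in% fr & ft$valid]
        e[is.finite(e)]
      }))
    }))
  })
  stats::setNames(out, paste0("rep", reps))
}

#' Simulate a dataset and write it to disk
#'
#' Convenience wrapper tying the generator to the on-disk format: trace
#' tables, manifest with seeds and ground truth.
#'
#' @param rates a [rate_set].
#' @param out_dir output directory.
#' @param ... passed to [generate_dataset].
#' @return The `trace_set`, invisibly.
#' @export
simulate_to_dir <- function(rates, out_dir, ...) {
  ts <- generate_dataset(rates, ...)
  write_trace_set(ts, out_dir)
  message("[simulate] wrote ", length(ts$traces), " traces to ", out_dir)
  invisible(ts)
}

#' Render a human-readable analysis report
#'
#' Side-by-side rate and class-fraction tables per condition, with
#' fold-changes when exactly two conditions are present. Deterministic
#' for a fixed input.
#'
#' @param results named list of [analyze_traces] results (one per
#'   condition).
#' @param file optional path; default prints to the console.
#' @return The report lines, invisibly.
#' @export
render_report <- function(results, file = "") {
  conds <- names(results)
  lines <- c("== Dwell-derived rate constants (s^-1) ==")
  classes <- unique(unlist(lapply(results, function(r) names(r$dwells))))
  for (cl in classes) {
    vals <- vapply(results, function(r) {
      d <- r$dwells[[cl]]
      if (is.null(d)) NA_real_ else d$k_corrected_mean
    }, numeric(1))
    ns <- vapply(results, function(r) {
      d <- r$dwells[[cl]]
      if (is.null(d)) NA_integer_ else d$n_total
    }, numeric(1))
    row <- paste0("  ", format(cl, width = 18),
                  paste(sprintf("%s: %.3g (n=%d)", conds, vals, ns),
                        collapse = "   "))
    if (length(conds) == 2L && all(is.finite(vals)))
      row <- paste0(row, sprintf("   fold = %.2f", vals[2] / vals[1]))
    lines <- c(lines, row)
  }
  lines <- c(lines, "", "== Trace class fractions (percent) ==")
  for (cond in conds) {
    s <- results[[cond]]$fractions$summary
    lines <- c(lines, paste0("  [", cond, "]"))
    lines <- c(lines, sprintf("    %-14s %5.1f +/- %4.1f", s$class, s$mean,
                              ifelse(is.na(s$sd), 0, s$sd)))
  }
  writeLines(lines, con = if (nzchar(file)) file else stdout())
  invisible(lines)
}
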