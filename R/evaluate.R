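#' Aggregate confusion matrices across sessions
#'
#' @param confusions list of `confusion_matrix` of identical dimension
#' @return elementwise-sum `confusion_matrix`
#' @export
aggregate_confusions <- function(confusions) {
  if (length(confusions) < 1) {
    dot_stop("dot_invalid_parameter", "empty confusion list")
  }
  dims <- vapply(confusions, nrow, integer(1))
  if (any(dims != dims[1])) {
    dot_stop("dot_shape_error", "confusion matrices differ in dimension")
  }
  confusion_matrix(Reduce(`+`, lapply(confusions, unclass)))
}

#' Decoding accuracy of a confusion matrix
#'
#' Fraction of trials decoded correctly: trace / total.
#'
#' @param conf a `confusion_matrix`
#' @return fraction in \[0, 1\]
#' @export
decoding_accuracy <- function(conf) {
  tot <- sum(conf)
  if (tot <= 0) dot_stop("dot_undefined", "confusion matrix has no trials")
  sum(diag(conf)) / tot
}

#' One-sided exact binomial test above chance
#'
#' Upper-tail probability P(X >= k) for X ~ Binomial(n, p0): the
#' probability of decoding at least k of n trials correctly if the
#' classifier guessed at the chance rate p0 = 1 / n_templates.
#'
#' @param k correct trials
#' @param n total trials
#' @param p0 chance probability
#' @return p-value in (0, 1]
#' @export
#' @examples
#' binomial_test_above_chance(49, 52, 0.25)
binomial_test_above_chance <- function(k, n, p0) {
  if (!is_count(n) || !(is_number(k) && k >= 0 && k <= n && k == round(k))) {
    dot_stop("dot_invalid_parameter", "need 0 <= k <= n, integers")
  }
  if (!is_number(p0) || p0 <= 0 || p0 >= 1) {
    dot_stop("dot_invalid_parameter", "p0 must be in (0, 1)")
  }
  if (k == 0) return(1)
  stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
}

#' Cohen's d of decoding accuracy above chance
#'
#' (mean session accuracy - chance) / sample SD of session accuracies
#' (n - 1 denominator).
#'
#' @param session_accuracies per-session accuracy fractions (>= 2)
#' @param chance chance accuracy fraction
#' @return effect size d
#' @export
cohens_d <- function(session_accuracies, chance) {
  if (length(session_accuracies) < 2) {
    dot_stop("dot_invalid_parameter", "need at least two sessions")
  }
  s <- stats::sd(session_accuracies)
  if (s == 0) {
    dot_stop("dot_undefined_effect_size",
             "all session accuracies identical; effect size undefined")
  }
  (mean(session_accuracies) - chance) / s
}

#' Standard error of the mean session accuracy
#'
#' @param session_accuracies per-session accuracy fractions (>= 2)
#' @return sample SD / sqrt(n sessions)
#' @export
sem_accuracy <- function(session_accuracies) {
  if (length(session_accuracies) < 2) {
    dot_stop("dot_invalid_parameter", "need at least two sessions")
  }
  stats::sd(session_accuracies) / sqrt(length(session_accuracies))
}

#' Summarize decoding across sessions
#'
#' Pools the per-session confusion matrices, reports the pooled accuracy
#' (total fraction of trials decoded correctly), the SEM and Cohen's d of
#' the per-session accuracies, and the exact binomial p-value against the
#' chance rate 1 / n_templates.
#'
#' @param decodings list of `session_decoding` (or of `confusion_matrix`)
#' @param n_templates decoding choices (taken from the decodings if NULL)
#' @param trial_duration seconds per trial (metadata echo)
#' @return list of class `decoding_report`
#' @export
decoding_report <- function(decodings, n_templates = NULL,
                            trial_duration = NA_real_) {
  confs <- lapply(decodings, function(d) {
    if (inherits(d, "session_decoding")) d$confusion else confusion_matrix(d)
  })
  if (is.null(n_templates)) n_templates <- nrow(confs[[1]])
  agg <- aggregate_confusions(confs)
  acc <- vapply(confs, decoding_accuracy, numeric(1))
  k <- sum(diag(agg)); n <- sum(agg)
  chance <- 1 / n_templates
  structure(list(
    session_accuracies = acc,
    aggregate_confusion = agg,
    mean_accuracy = k / n,
    sem = if (length(acc) >= 2) sem_accuracy(acc) else NA_real_,
    chance = chance,
    p_value = binomial_test_above_chance(k, n, chance),
    cohens_d = if (length(acc) >= 2 && stats::sd(acc) > 0)
      cohens_d(acc, chance) else NA_real_,
    n_correct = k, n_trials = n,
    n_templates = n_templates, trial_duration = trial_duration),
    class = "decoding_report")
}

#' @export
print.decoding_report <- function(x, ...) {
  cat(sprintf(
    "<decoding_report %d-way, %g s trials: %s%% (chance %s%%), p = %.3g, d = %.3g>\n",
    x$n_templates, x$trial_duration, format_pct(x$mean_accuracy),
    format_pct(x$chance), x$p_value, x$cohens_d))
  invisible(x)
}

#' Monte-Carlo chance accuracy of a uniform-random classifier
#'
#' Simulates a classifier that guesses uniformly among `n_templates`
#' options and returns its empirical accuracy; converges to 1 /
#' n_templates.
#'
#' @param n_templates number of choices
#' @param n_draws number of simulated trials
#' @param seed integer seed
#' @return empirical accuracy fraction
#' @export
chance_accuracy_mc <- function(n_templates, n_draws = 2e5, seed = NULL) {
  if (!is_count(n_templates) || n_templates < 2) {
    dot_stop("dot_invalid_parameter", "n_templates must be >= 2")
  }
  with_seed(seed, {
    truth <- sample.int(n_templates, n_draws, replace = TRUE)
    guess <- sample.int(n_templates, n_draws, replace = TRUE)
    mean(guess == truth)
  })
}

#' Sweep decoding parameters over sessions
#'
#' Decodes every session at each (n_templates, trial_duration) grid point
#' and tabulates one report per point.  Infeasible points (segments that
#' do not fit the runs) are reported as skipped with the timing error
#' message rather than dropped silently.
#'
#' @param sessions list of sessions; each session is a list of
#'   `voxel_timeseries` runs (each movie twice)
#' @param grid data frame with columns `n_templates` and `trial_duration`
#' @param mask logical voxel vector or NULL
#' @param crop_initial,inter_trial_gap extraction timing (seconds)
#' @param train_viewing which viewing supplies templates
#' @return data frame with one row per grid point: n_templates,
#'   trial_duration, chance, chance_pct, mean_accuracy, sem, p_value,
#'   cohens_d, n_correct, n_trials, skipped, reason; the per-point reports
#'   are attached as attribute `reports`
#' @export
sweep_decoding <- function(sessions, grid, mask = NULL, crop_initial = 15,
                           inter_trial_gap = 15, train_viewing = 1L) {
  if (!all(c("n_templates", "trial_duration") %in% names(grid))) {
    dot_stop("dot_invalid_parameter",
             "grid needs n_templates and trial_duration columns")
  }
  reports <- vector("list", nrow(grid))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    k <- grid$n_templates[i]; dur <- grid$trial_duration[i]
    sp <- trial_spec(dur, k, crop_initial, inter_trial_gap)
    res <- tryCatch({
      decs <- lapply(sessions, function(runs) {
        decode_session(split_session(runs, train_viewing), sp, mask)
      })
      decoding_report(decs, k, dur)
    }, dot_timing_error = function(e) e, dot_invalid_parameter = function(e) e)
    if (inherits(res, "error")) {
      data.frame(n_templates = k, trial_duration = dur,
                 chance = 1 / k, chance_pct = as.numeric(format_pct(1 / k)),
                 mean_accuracy = NA_real_, sem = NA_real_,
                 p_value = NA_real_, cohens_d = NA_real_,
                 n_correct = NA_integer_, n_trials = NA_integer_,
                 skipped = TRUE, reason = conditionMessage(res))
    } else {
      reports[[i]] <<- res
      data.frame(n_templates = k, trial_duration = dur,
                 chance = res$chance,
                 chance_pct = as.numeric(format_pct(res$chance)),
                 mean_accuracy = res$mean_accuracy, sem = res$sem,
                 p_value = res$p_value, cohens_d = res$cohens_d,
                 n_correct = res$n_correct, n_trials = res$n_trials,
                 skipped = FALSE, reason = "")
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "reports") <- reports
  out
}

#' Accuracy-vs-parameter sweep plot
#'
#' Base-graphics plot of mean accuracy (with SEM bars) against trial
#' duration or template count from a [sweep_decoding()] table.
#'
#' @param tab sweep table
#' @param x which column to use on the x axis
#' @param ... passed to [plot()]
#' @return invisibly, the plotted table
#' @export
plot_sweep <- function(tab, x = c("trial_duration", "n_templates"), ...) {
  x <- match.arg(x)
  t2 <- tab[!tab$skipped, ]
  graphics::plot(t2[[x]], 100 * t2$mean_accuracy, type = "b", pch = 16,
       xlab = if (x == "trial_duration") "Trial duration (s)"
       else "Number of templates",
       ylab = "Decoding accuracy (%)", ylim = c(0, 100), ...)
  graphics::arrows(t2[[x]], 100 * (t2$mean_accuracy - t2$sem),
         t2[[x]], 100 * (t2$mean_accuracy + t2$sem),
         angle = 90, code = 3, length = 0.03)
  graphics::lines(t2[[x]], 100 * t2$chance, lty = 2)
  invisible(t2)
}
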