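#' Trimmed mean of an MEP block
#'
#' Post-stimulation blocks of 12 TMS pulses are summarized by dropping
#' exactly one minimum and one maximum amplitude (first occurrence each on
#' ties) and averaging the remaining trials. Baseline blocks (10 pulses)
#' are averaged untrimmed; use \code{trim = FALSE}.
#'
#' @param amplitudes peak-to-peak MEP amplitudes, mV (>= 3 when trimming).
#' @param trim drop one min and one max before averaging.
#' @return mean amplitude, mV.
#' @export
trimmed_mep_mean <- function(amplitudes, trim = TRUE) {
  if (any(amplitudes < 0)) stop("MEP amplitudes must be >= 0")
  if (!trim) return(mean(amplitudes))
  if (length(amplitudes) < 3) stop("need at least 3 trials to trim")
  x <- amplitudes[-which.min(amplitudes)]   # first-occurrence min
  x <- x[-which.max(x)]                     # then first-occurrence max
  mean(x)
}

POST_INTERVALS <- c(0, 5, 10, 15, 20, 25, 30, 60, 90)

#' Normalize a session to its baseline
#'
#' Per-interval trimmed means divided by the untrimmed baseline mean, the
#' per-interval after-effect ratios; the overall session ratio is the mean
#' over the nine post-stimulation intervals, and early/late groupings
#' average intervals 0--30 min and 60--90 min.
#'
#' @param session list with \code{baseline} (vector of baseline trial
#'   amplitudes, mV) and \code{intervals} (named list of post-block trial
#'   vectors; names are minutes post-stimulation).
#' @return list: \code{baseline_mean}, \code{ratios} (named per interval),
#'   \code{overall} (mean of all intervals), \code{early} (0--30 min),
#'   \code{late} (60--90 min).
#' @export
normalize_to_baseline <- function(session) {
  b <- mean(session$baseline)
  if (b <= 0) stop("baseline mean must be > 0")
  ratios <- vapply(session$intervals, function(x) trimmed_mep_mean(x) / b,
                   numeric(1))
  mins <- as.numeric(names(ratios))
  list(baseline_mean = b,
       ratios = ratios,
       overall = mean(ratios),
       early = mean(ratios[mins <= 30]),
       late = mean(ratios[mins >= 60]))
}

#' Paired one-tailed t-test
#'
#' Classical paired t on the per-participant differences with df = n - 1;
#' the one-tailed p-value tests mean(condition) < mean(placebo) by default.
#' Zero-variance differences are flagged and given p = 0 or 1 by the sign
#' of the mean difference (0.5 when identically zero).
#'
#' @param condition,placebo equal-length paired vectors (session ratios).
#' @param alternative "less" (default) or "greater".
#' @return list: \code{t}, \code{df}, \code{p}, \code{mean_diff},
#'   \code{degenerate}.
#' @export
paired_one_tailed_t <- function(condition, placebo, alternative = "less") {
  if (length(condition) != length(placebo)) stop("paired vectors differ in length")
  n <- length(condition)
  if (n < 2) stop("need n >= 2 pairs")
  d <- condition - placebo
  if (stats::sd(d) == 0) {
    p <- if (mean(d) == 0) 0.5
         else if (alternative == "less") as.numeric(mean(d) > 0)
         else as.numeric(mean(d) < 0)
    return(list(t = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                df = n - 1, p = p, mean_diff = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(condition, placebo, paired = TRUE,
                      alternative = alternative)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = mean(d), degenerate = FALSE)
}

#' Exact binomial tail probability
#'
#' Upper-tail exact goodness-of-fit p-value P(X >= k) under
#' Binomial(n, p0), by explicit summation of the exact probability mass.
#' Used to compare an observed responder count against a published
#' response proportion.
#'
#' @param k observed count (0..n).
#' @param n trials.
#' @param p0 null proportion, in (0, 1).
#' @param tail "upper" (P(X >= k)) or "lower" (P(X <= k)).
#' @return exact p-value.
#' @export
exact_binomial_tail <- function(k, n, p0, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  if (k < 0 || k > n) stop("k must be in 0..n")
  if (p0 <= 0 || p0 >= 1) stop("p0 must be in (0, 1)")
  if (tail == "upper") sum(stats::dbinom(k:n, n, p0))
  else sum(stats::dbinom(0:k, n, p0))
}

#' Synthetic MEP cohort specification
#'
#' Statistical structure of a three-condition crossover excitability study:
#' per-condition mean/SD of the session after-effect ratio (cathodal
#' 0.79/0.21, anodal 0.93/0.08, placebo 1.10/0.36), baseline MEP
#' 0.97 mV (SD 0.35, truncated above 0.1 mV), and multiplicative lognormal
#' trial noise. Trial noise is kept modest (sigma-log 0.15) because the
#' condition-level SDs already absorb most between-session variability;
#' see the package vignette.
#'
#' @param n participants.
#' @param ratio_mean,ratio_sd named per-condition parameters.
#' @param baseline_mean,baseline_sd baseline amplitude distribution, mV.
#' @param trial_sdlog lognormal sigma of trial noise.
#' @return object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n = 12,
                        ratio_mean = c(cathodal = 0.79, anodal = 0.93,
                                       placebo = 1.10),
                        ratio_sd = c(cathodal = 0.21, anodal = 0.08,
                                     placebo = 0.36),
                        baseline_mean = 0.97, baseline_sd = 0.35,
                        trial_sdlog = 0.15) {
  if (n < 2) stop("need n >= 2 participants")
  if (any(ratio_sd <= 0) || baseline_sd <= 0 || trial_sdlog <= 0)
    stop("SDs must be > 0")
  structure(list(n = n, ratio_mean = ratio_mean, ratio_sd = ratio_sd,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 trial_sdlog = trial_sdlog),
            class = "cohort_spec")
}

#' Simulate a synthetic MEP cohort
#'
#' Per participant and condition: a truncated-normal baseline amplitude, a
#' normal true after-effect ratio, a 10-trial baseline block, and a
#' 12-trial block per post-stimulation interval with amplitudes
#' baseline x ratio x lognormal trial noise (unit mean). Deterministic for
#' a fixed seed.
#'
#' @param spec a [cohort_spec()].
#' @param seed RNG seed.
#' @return object of class \code{mep_cohort}: nested list
#'   \code{sessions[[participant]][[condition]]}, each with
#'   \code{baseline} and \code{intervals}; plus \code{true_ratios} matrix.
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  conds <- names(spec$ratio_mean)
  mlog <- -spec$trial_sdlog^2 / 2               # unit-mean trial noise
  sessions <- vector("list", spec$n)
  true_ratios <- matrix(NA_real_, spec$n, length(conds),
                        dimnames = list(NULL, conds))
  for (i in seq_len(spec$n)) {
    sessions[[i]] <- list()
    for (cn in conds) {
      repeat {
        b <- stats::rnorm(1, spec$baseline_mean, spec$baseline_sd)
        if (b > 0.1) break
      }
      r <- stats::rnorm(1, spec$ratio_mean[[cn]], spec$ratio_sd[[cn]])
      r <- max(r, 0.05)
      true_ratios[i, cn] <- r
      noise <- function(k) stats::rlnorm(k, mlog, spec$trial_sdlog)
      iv <- lapply(POST_INTERVALS, function(m) b * r * noise(12))
      names(iv) <- POST_INTERVALS
      sessions[[i]][[cn]] <- list(baseline = b * noise(10), intervals = iv)
    }
  }
  structure(list(sessions = sessions, true_ratios = true_ratios, spec = spec,
                 seed = seed),
            class = "mep_cohort")
}

#' Analyse a cohort: ratios and condition contrasts
#'
#' Runs the full after-effect pipeline on a (simulated or loaded) cohort:
#' trimmed interval means, baseline normalization, per-participant session
#' ratios, and one-tailed paired t-tests of each active condition against
#' placebo, overall and for the early (0--30 min) and late (60--90 min)
#' groupings. Exact binomial goodness-of-fit tests compare the number of
#' participants whose overall ratio falls below 1 against reference
#' response proportions.
#'
#' @param cohort an \code{mep_cohort} (or compatible nested list).
#' @param reference_props null responder proportions for the binomial
#'   tests, named by condition.
#' @param exclude participant indices to drop from the late-interval
#'   re-analysis (none by default).
#' @return list: \code{ratios} (participants x conditions, overall),
#'   \code{early}, \code{late}, \code{tests} (data.frame), \code{binomial}
#'   (data.frame).
#' @export
analyze_cohort <- function(cohort,
                           reference_props = c(cathodal = 22 / 53,
                                               anodal = 0.26),
                           exclude = integer(0)) {
  sessions <- cohort$sessions
  n <- length(sessions)
  conds <- names(sessions[[1]])
  get <- function(field) sapply(conds, function(cn)
    sapply(seq_len(n), function(i) normalize_to_baseline(sessions[[i]][[cn]])[[field]]))
  overall <- get("overall"); early <- get("early"); late <- get("late")
  active <- setdiff(conds, "placebo")
  run <- function(mat, keep = seq_len(n)) {
    do.call(rbind, lapply(active, function(cn) {
      tt <- paired_one_tailed_t(mat[keep, cn], mat[keep, "placebo"])
      data.frame(condition = cn, t = tt$t, df = tt$df, p = tt$p)
    }))
  }
  tests <- rbind(cbind(window = "overall", run(overall)),
                 cbind(window = "early", run(early)),
                 cbind(window = "late", run(late, setdiff(seq_len(n), exclude))))
  binom <- do.call(rbind, lapply(intersect(active, names(reference_props)),
    function(cn) {
      k <- sum(overall[, cn] < 1)
      data.frame(condition = cn, k = k, n = n, p0 = reference_props[[cn]],
                 p = exact_binomial_tail(k, n, reference_props[[cn]]))
    }))
  list(ratios = overall, early = early, late = late,
       tests = tests, binomial = binom)
}

#' Write / read cohort trial data as CSV
#'
#' Long format: participant, condition, interval ("baseline" or minutes),
#' trial, amplitude_mV.
#'
#' @param cohort an \code{mep_cohort}.
#' @param path CSV path.
#' @return \code{path} / an \code{mep_cohort}-compatible list.
#' @export
write_cohort_csv <- function(cohort, path) {
  rows <- list()
  for (i in seq_along(cohort$sessions)) for (cn in names(cohort$sessions[[i]])) {
    s <- cohort$sessions[[i]][[cn]]
    rows[[length(rows) + 1]] <- data.frame(
      participant = i, condition = cn, interval = "baseline",
      trial = seq_along(s$baseline), amplitude_mV = s$baseline)
    for (m in names(s$intervals))
      rows[[length(rows) + 1]] <- data.frame(
        participant = i, condition = cn, interval = m,
        trial = seq_along(s$intervals[[m]]), amplitude_mV = s$intervals[[m]])
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  sessions <- lapply(sort(unique(d$participant)), function(i) {
    di <- d[d$participant == i, ]
    out <- lapply(unique(di$condition), function(cn) {
      dc <- di[di$condition == cn, ]
      iv_names <- setdiff(unique(dc$interval), "baseline")
      iv <- lapply(iv_names, function(m) dc$amplitude_mV[dc$interval == m])
      names(iv) <- iv_names
      list(baseline = dc$amplitude_mV[dc$interval == "baseline"],
           intervals = iv)
    })
    names(out) <- unique(di$condition)
    out
  })
  structure(list(sessions = sessions), class = "mep_cohort")
}
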