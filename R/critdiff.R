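#' Score observation
#'
#' A proportion-correct speech score together with the effective number of
#' scored items it is based on. This is the atom of every significance
#' computation in the package: binomial measurement error at `n` items is the
#' noise model against which two scores are compared.
#'
#' `p` need not lie on the grid `{0, 1/n, ..., 1}`: a score averaged over
#' several sessions can fall between grid points and is handled directly.
#'
#' @param p Proportion correct in `[0, 1]`.
#' @param n Effective number of scored items (positive integer). For sentence
#'   keyword tests this is typically a conservative override (e.g. 40), not
#'   the raw keyword count; see [effective_n()].
#' @return An object of class `score_observation` with fields `p` and `n`.
#' @examples
#' score_observation(0.44, 50)
#' @export
score_observation <- function(p, n) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop("`p` must be a single proportion in [0, 1]", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1 || n != round(n))
    stop("`n` must be a single positive integer", call. = FALSE)
  structure(list(p = as.numeric(p), n = as.integer(n)),
            class = "score_observation")
}

#' @export
print.score_observation <- function(x, ...) {
  cat(sprintf("<score: %.1f%% correct on n = %d items>\n", 100 * x$p, x$n))
  invisible(x)
}

as_score_observation <- function(x) {
  if (inherits(x, "score_observation")) return(x)
  if (is.numeric(x) && length(x) == 2L) return(score_observation(x[[1L]], x[[2L]]))
  if (is.list(x) && all(c("p", "n") %in% names(x)))
    return(score_observation(x$p, x$n))
  stop("cannot interpret input as a score observation", call. = FALSE)
}

#' Configuration for critical-difference computations
#'
#' Bundles the Monte-Carlo repetition count, the significance cutoff on the
#' z statistic, and the random seed. Defaults follow the conventional
#' two-tailed 5% test: 40,000 iterations and a critical z of 1.96.
#'
#' @param iterations Number of Monte-Carlo repetitions (>= 2).
#' @param critical_z Positive cutoff; a pair is significant when z exceeds it.
#' @param seed Optional integer seed; when given, every simulation-based
#'   comparison is reproducible and the seed is recorded in results.
#' @param use_exact One of `"auto"`, `"always"`, `"never"`. Under `"auto"`
#'   (default) [compare_scores()] substitutes the deterministic
#'   exact-enumeration statistic whenever the outcome-pair count
#'   `(n1 + 1)(n2 + 1)` is at most `exact_guard`.
#' @param exact_guard Largest outcome-pair count for which exact enumeration
#'   is attempted.
#' @param statistic `"signed"` (default) decides significance from the
#'   magnitude of the signed statistic mean(d)/sd(d) over the simulated
#'   difference scores, the construction under which a two-tailed cutoff of
#'   +/-1.96 delivers close to the nominal 2.5% chance rate per direction;
#'   `"absolute"` uses mean(|d|)/sd(|d|), a more liberal variant (see the
#'   package vignette for the calibration comparison).
#' @return An object of class `crit_diff_config`.
#' @export
crit_diff_config <- function(iterations = 40000L, critical_z = 1.96,
                             seed = NULL, use_exact = c("auto", "always", "never"),
                             exact_guard = 1e6,
                             statistic = c("signed", "absolute")) {
  use_exact <- match.arg(use_exact)
  statistic <- match.arg(statistic)
  if (!is.numeric(iterations) || length(iterations) != 1L || iterations < 1)
    stop("`iterations` must be a positive integer", call. = FALSE)
  if (!is.numeric(critical_z) || length(critical_z) != 1L || critical_z <= 0)
    stop("`critical_z` must be positive", call. = FALSE)
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(iterations = as.integer(iterations),
                 critical_z = as.numeric(critical_z),
                 seed = seed, use_exact = use_exact,
                 exact_guard = exact_guard, statistic = statistic),
            class = "crit_diff_config")
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Possible proportion scores for a test of n items
#'
#' @param n Positive integer number of scored items.
#' @return Ascending numeric vector `c(0, 1/n, ..., 1)` of length `n + 1`.
#' @examples
#' possible_scores(25)[1:4] # 0.00 0.04 0.08 0.12
#' @export
possible_scores <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1 || n != round(n))
    stop("`n` must be a single positive integer", call. = FALSE)
  seq.int(0L, n) / n
}

# Shared degenerate-spread contract: identical certain scores are never
# significant (z = 0); maximally separated certain scores always are (z = Inf).
z_from_moments <- function(mean_d, sd_d) {
  if (sd_d == 0) {
    if (mean_d == 0) return(0)
    return(Inf)
  }
  mean_d / sd_d
}

#' Exact critical-difference z statistic by full enumeration
#'
#' Deterministic counterpart of [simulate_abs_diff_z()]: enumerates every
#' outcome pair `(k1, k2)` with exact binomial probabilities and returns the
#' exact mean of `|k1/n1 - k2/n2|` divided by its exact (population) standard
#' deviation. Used both as a fast deterministic path for small `n` and as the
#' verification oracle for the Monte-Carlo statistic.
#'
#' @param a,b Score observations (see [score_observation()]); numeric
#'   length-2 vectors `c(p, n)` are also accepted.
#' @param guard Maximum number of outcome pairs `(n1 + 1)(n2 + 1)` that will
#'   be enumerated; larger problems are refused.
#' @return Non-negative z value, possibly `Inf` (degenerate spread with a
#'   non-zero mean difference) or 0 (degenerate spread, zero mean).
#' @examples
#' exact_abs_diff_z(score_observation(0.5, 1), score_observation(0.5, 1)) # 1
#' @export
exact_abs_diff_z <- function(a, b, guard = 1e6) {
  a <- as_score_observation(a); b <- as_score_observation(b)
  n_pairs <- (a$n + 1) * (b$n + 1)
  if (n_pairs > guard)
    stop(sprintf("enumeration of %.0f outcome pairs exceeds guard of %.0f",
                 n_pairs, guard), call. = FALSE)
  w1 <- stats::dbinom(0:a$n, a$n, a$p)
  w2 <- stats::dbinom(0:b$n, b$n, b$p)
  d <- abs(outer((0:a$n) / a$n, (0:b$n) / b$n, "-"))
  w <- outer(w1, w2)
  m1 <- sum(w * d)
  m2 <- sum(w * d * d)
  z_from_moments(m1, sqrt(max(m2 - m1 * m1, 0)))
}

#' Monte-Carlo critical-difference z statistic
#'
#' On each iteration one binomial count is drawn at `(a$n, a$p)` and one at
#' `(b$n, b$p)`; both are converted to proportions and the absolute difference
#' recorded. The statistic is the mean of the absolute differences divided by
#' their sample standard deviation. Two certain, identical scores give z = 0;
#' certain, different scores give z = Inf.
#'
#' @inheritParams exact_abs_diff_z
#' @param cfg A [crit_diff_config()]; `cfg$iterations >= 2` is required so
#'   the standard deviation is defined, and `cfg$seed` (if set) makes the
#'   draw reproducible.
#' @return Non-negative z value, possibly `Inf`.
#' @export
simulate_abs_diff_z <- function(a, b, cfg = crit_diff_config()) {
  a <- as_score_observation(a); b <- as_score_observation(b)
  if (cfg$iterations < 2L)
    stop("at least 2 iterations are required (sd undefined otherwise)",
         call. = FALSE)
  with_seed(cfg$seed, {
    d <- abs(stats::rbinom(cfg$iterations, a$n, a$p) / a$n -
             stats::rbinom(cfg$iterations, b$n, b$p) / b$n)
    z_from_moments(mean(d), stats::sd(d))
  })
}

#' Exact signed critical-difference z statistic
#'
#' Signed counterpart of [exact_abs_diff_z()]: the exact mean of the signed
#' difference `k1/n1 - k2/n2` divided by its exact standard deviation. This
#' is the statistic whose two-tailed comparison against +/-1.96 gives close
#' to the nominal 2.5% chance rate in each direction; its magnitude is what
#' [compare_scores()] thresholds by default. Positive sign means the first
#' score exceeds the second.
#'
#' @inheritParams exact_abs_diff_z
#' @return Signed z value; 0 when both mean and spread vanish, +/-`Inf` when
#'   the spread vanishes with a non-zero mean.
#' @export
exact_diff_z <- function(a, b, guard = 1e6) {
  a <- as_score_observation(a); b <- as_score_observation(b)
  n_pairs <- (a$n + 1) * (b$n + 1)
  if (n_pairs > guard)
    stop(sprintf("enumeration of %.0f outcome pairs exceeds guard of %.0f",
                 n_pairs, guard), call. = FALSE)
  # difference of independent binomial proportions: moments in closed form
  m <- a$p - b$p
  v <- a$p * (1 - a$p) / a$n + b$p * (1 - b$p) / b$n
  if (v <= 0) {
    if (m == 0) return(0)
    return(sign(m) * Inf)
  }
  m / sqrt(v)
}

#' Monte-Carlo signed critical-difference z statistic
#'
#' As [simulate_abs_diff_z()], but the signed differences are kept: the
#' statistic is the mean of `k1/n1 - k2/n2` across iterations divided by
#' their sample standard deviation.
#'
#' @inheritParams simulate_abs_diff_z
#' @return Signed z value (see [exact_diff_z()] for the degenerate cases).
#' @export
simulate_diff_z <- function(a, b, cfg = crit_diff_config()) {
  a <- as_score_observation(a); b <- as_score_observation(b)
  if (cfg$iterations < 2L)
    stop("at least 2 iterations are required (sd undefined otherwise)",
         call. = FALSE)
  with_seed(cfg$seed, {
    d <- stats::rbinom(cfg$iterations, a$n, a$p) / a$n -
      stats::rbinom(cfg$iterations, b$n, b$p) / b$n
    m <- mean(d); s <- stats::sd(d)
    if (s == 0) {
      if (m == 0) 0 else sign(m) * Inf
    } else m / s
  })
}

# Dispatch on cfg$statistic (signed magnitude vs absolute variant) and on
# cfg$use_exact (enumeration vs simulation). Returns the non-negative z
# actually thresholded.
stat_z <- function(a, b, cfg) {
  a <- as_score_observation(a); b <- as_score_observation(b)
  feasible <- (a$n + 1) * (b$n + 1) <= cfg$exact_guard
  use_exact <- switch(cfg$use_exact,
                      always = TRUE,
                      never = FALSE,
                      auto = feasible)
  z <- if (cfg$statistic == "signed") {
    if (use_exact) abs(exact_diff_z(a, b, guard = cfg$exact_guard))
    else abs(simulate_diff_z(a, b, cfg))
  } else {
    if (use_exact) exact_abs_diff_z(a, b, guard = cfg$exact_guard)
    else simulate_abs_diff_z(a, b, cfg)
  }
  list(z = z, method = if (use_exact) "exact" else "simulation")
}

#' Compare two proportion-correct scores
#'
#' Decides whether a pre/post pair of scores differs significantly under
#' binomial measurement error at each score's effective item count. By
#' default the magnitude of the signed difference statistic
#' ([exact_diff_z()]) is thresholded, which keeps the per-direction chance
#' rate close to the nominal level; `cfg$statistic = "absolute"` selects
#' the more liberal absolute-difference variant. The exact value is used
#' when the outcome space is small enough (deterministic, default guard 1e6
#' outcome pairs), otherwise the Monte-Carlo estimate.
#'
#' @param pre,post Score observations (or `c(p, n)` vectors).
#' @param cfg A [crit_diff_config()].
#' @return An object of class `crit_diff_result`: a list with `z`,
#'   `significant` (`z > cfg$critical_z`), `direction` (`"lower"`, `"higher"`
#'   or `"none"`, comparing `post$p` to `pre$p`), `method` (`"exact"` or
#'   `"simulation"`), and the `critical_z` and `seed` used.
#' @examples
#' compare_scores(c(0.60, 25), c(0.20, 25))
#' @export
compare_scores <- function(pre, post, cfg = crit_diff_config()) {
  pre <- as_score_observation(pre); post <- as_score_observation(post)
  res <- stat_z(pre, post, cfg)
  direction <- if (post$p < pre$p) "lower" else if (post$p > pre$p) "higher" else "none"
  structure(list(z = res$z,
                 significant = res$z > cfg$critical_z,
                 direction = direction,
                 method = res$method,
                 critical_z = cfg$critical_z,
                 seed = cfg$seed),
            class = "crit_diff_result")
}

#' @export
print.crit_diff_result <- function(x, ...) {
  cat(sprintf("<critical difference: z = %.3f (%s), %s at |z| > %.2f, direction %s>\n",
              x$z, x$method,
              if (x$significant) "significant" else "not significant",
              x$critical_z, x$direction))
  invisible(x)
}

#' Matrix of critical-difference z values over two score grids
#'
#' Computes the z statistic for every pair of attainable proportions
#' `(p1, p2)` on the grids for `n1` and `n2` items. Rows index
#' `possible_scores(n1)`, columns `possible_scores(n2)`.
#'
#' @param n1,n2 Positive integer item counts.
#' @param cfg A [crit_diff_config()]. When simulation is used, a single
#'   seeded stream covers the whole grid.
#' @return Numeric matrix of dimension `(n1 + 1) x (n2 + 1)` with dimnames
#'   giving the grid proportions.
#' @export
crit_diff_z_grid <- function(n1, n2, cfg = crit_diff_config()) {
  g1 <- possible_scores(n1)
  g2 <- possible_scores(n2)
  compute <- function() {
    # cfg seed already applied to the whole grid; avoid re-seeding per cell
    cell_cfg <- cfg; cell_cfg$seed <- NULL
    vapply(g2, function(p2) {
      vapply(g1, function(p1) {
        stat_z(score_observation(p1, n1), score_observation(p2, n2),
               cell_cfg)$z
      }, numeric(1))
    }, numeric(length(g1)))
  }
  z <- with_seed(cfg$seed, compute())
  dimnames(z) <- list(p1 = format(g1, trim = TRUE),
                      p2 = format(g2, trim = TRUE))
  z
}

#' Critical range for one reference score
#'
#' The set of attainable second scores `p2` (on the grid for `n2` items) that
#' are *not* significantly different from a reference score `p1` obtained on
#' `n1` items.
#'
#' @param p1 Reference proportion (need not lie on the `n1` grid).
#' @param n1,n2 Positive integer item counts.
#' @param cfg A [crit_diff_config()].
#' @return Ascending numeric vector of non-significant `p2` grid values.
#' @export
critical_range <- function(p1, n1, n2, cfg = crit_diff_config()) {
  g2 <- possible_scores(n2)
  a <- score_observation(p1, n1)
  keep <- with_seed(cfg$seed, {
    cell_cfg <- cfg; cell_cfg$seed <- NULL
    vapply(g2, function(p2) {
      stat_z(a, score_observation(p2, n2), cell_cfg)$z <= cfg$critical_z
    }, logical(1))
  })
  g2[keep]
}

#' Build a full critical-difference table
#'
#' For every attainable first score `p1` on the `n1`-item grid, records the
#' set of second scores `p2` on the `n2`-item grid that are statistically
#' compatible with it (z not exceeding the critical value). This supports
#' comparisons with unequal item counts, e.g. one 50-word list against the
#' average of three 50-word lists (n2 = 150, a 151-point grid).
#'
#' The non-significant set is stored literally; whether each row is a
#' contiguous run of grid values is reported in the `contiguous` column
#' rather than assumed.
#'
#' @inheritParams crit_diff_z_grid
#' @return An object of class `crit_diff_table`: list with `n1`, `n2`,
#'   `critical_z`, `rows` (a data.frame with `p1`, `lower_ns_p2`,
#'   `upper_ns_p2`, `n_ns`, `contiguous`), `ns_sets` (list of non-significant
#'   `p2` vectors per `p1`), and the z matrix.
#' @export
build_table <- function(n1, n2, cfg = crit_diff_config()) {
  z <- crit_diff_z_grid(n1, n2, cfg)
  g1 <- possible_scores(n1)
  g2 <- possible_scores(n2)
  ns_sets <- apply(z <= cfg$critical_z, 1L, function(keep) g2[keep],
                   simplify = FALSE)
  contiguous <- vapply(ns_sets, function(s) {
    idx <- match(s, g2)
    length(idx) > 0L && all(diff(idx) == 1L)
  }, logical(1))
  rows <- data.frame(
    p1 = g1,
    lower_ns_p2 = vapply(ns_sets, function(s) if (length(s)) min(s) else NA_real_, numeric(1)),
    upper_ns_p2 = vapply(ns_sets, function(s) if (length(s)) max(s) else NA_real_, numeric(1)),
    n_ns = lengths(ns_sets),
    contiguous = contiguous,
    row.names = NULL
  )
  structure(list(n1 = as.integer(n1), n2 = as.integer(n2),
                 critical_z = cfg$critical_z, rows = rows,
                 ns_sets = ns_sets, z = z, seed = cfg$seed),
            class = "crit_diff_table")
}

#' @export
print.crit_diff_table <- function(x, ...) {
  cat(sprintf("<critical difference table: n1 = %d, n2 = %d, |z| > %.2f>\n",
              x$n1, x$n2, x$critical_z))
  print(utils::head(x$rows, 10L))
  if (nrow(x$rows) > 10L) cat(sprintf("... %d more rows\n", nrow(x$rows) - 10L))
  invisible(x)
}

#' Export a critical-difference table as a data frame
#'
#' @param x A `crit_diff_table`.
#' @param format `"ranges"` (one row per `p1`, with the lower/upper bounds of
#'   the non-significant range) or `"long"` (one row per non-significant
#'   `(p1, p2)` pair).
#' @return A data.frame suitable for writing as CSV.
#' @export
as_table_frame <- function(x, format = c("ranges", "long")) {
  stopifnot(inherits(x, "crit_diff_table"))
  format <- match.arg(format)
  if (format == "ranges") {
    return(x$rows[c("p1", "lower_ns_p2", "upper_ns_p2")])
  }
  do.call(rbind, lapply(seq_along(x$ns_sets), function(i) {
    s <- x$ns_sets[[i]]
    if (!length(s)) return(NULL)
    data.frame(p1 = possible_scores(x$n1)[i], p2 = s)
  }))
}
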