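#' Per-time-step repeated-measures ANOVA on the critical window
#'
#' For each step of the aligned critical window, runs a two-way
#' repeated-measures ANOVA on the normalised ASI values with within-subject
#' factors centrality (3 levels: primary, secondary, central) and frontality
#' (2 levels: posterior, anterior), with CAs as subjects, plus planned
#' one-df comparisons: each centrality level against the zero baseline and
#' the pairwise central-vs-secondary and secondary-vs-primary differences.
#' Main effects use their own subject-by-factor interaction as error term
#' (no sphericity correction); planned comparisons are tested on
#' per-subject contrast scores, i.e. with `n - 1` error df.
#'
#' @param window_data A `ca_window` tibble from [align_baseline()], or any
#'   tibble with columns `pattern`, `area`, `centrality`, `frontality`,
#'   `step`, `value` describing a balanced design (6 areas per subject).
#' @return An object of class `ca_anova`: a tibble with columns `step`,
#'   `term`, `df1`, `df2`, `statistic` (F) and `p.value`.
#' @export
rm_anova <- function(window_data) {
  d <- tibble::as_tibble(window_data)
  need <- c("pattern", "area", "centrality", "frontality", "step", "value")
  stopifnot(all(need %in% names(d)))
  subjects <- sort(unique(d$pattern))
  if (length(subjects) < 2) {
    stop("repeated-measures ANOVA needs at least 2 CAs (subjects); got ",
         length(subjects))
  }
  out <- purrr::map_dfr(sort(unique(d$step)), function(s) {
    ds <- d[d$step == s, ]
    res <- rm_anova_one(ds)
    res$step <- s
    res
  })
  out <- out[, c("step", "term", "df1", "df2", "statistic", "p.value")]
  structure(out, n_subjects = length(subjects),
            class = c("ca_anova", class(tibble::tibble())))
}

# Two-way within-subject ANOVA (one observation per subject x cell) plus
# planned contrasts, computed from textbook sums of squares.
rm_anova_one <- function(ds) {
  ds <- ds[order(ds$pattern, ds$area), ]
  subj <- factor(ds$pattern)
  C <- factor(ds$centrality, levels = c("primary", "secondary", "central"))
  Fr <- factor(ds$frontality, levels = c("posterior", "anterior"))
  y <- ds$value
  n <- nlevels(subj); a <- nlevels(C); b <- nlevels(Fr)
  stopifnot(length(y) == n * a * b)

  grand <- mean(y)
  m_s <- tapply(y, subj, mean)
  m_c <- tapply(y, C, mean)
  m_f <- tapply(y, Fr, mean)
  m_cf <- tapply(y, list(C, Fr), mean)
  m_sc <- tapply(y, list(subj, C), mean)
  m_sf <- tapply(y, list(subj, Fr), mean)

  ss_c <- n * b * sum((m_c - grand)^2)
  ss_f <- n * a * sum((m_f - grand)^2)
  ss_cf <- n * sum((sweep(sweep(m_cf, 1, m_c, "-"), 2, m_f, "-") + grand)^2)
  ss_sc <- b * sum((sweep(sweep(m_sc, 1, m_s, "-"), 2, m_c, "-") + grand)^2)
  ss_sf <- a * sum((sweep(sweep(m_sf, 1, m_s, "-"), 2, m_f, "-") + grand)^2)
  # residual (subject x C x F) by subtraction from total
  ss_tot <- sum((y - grand)^2)
  ss_s <- a * b * sum((m_s - grand)^2)
  ss_scf <- max(ss_tot - ss_s - ss_c - ss_f - ss_cf - ss_sc - ss_sf, 0)

  eff <- function(term, ss, df1, ss_err, df2) {
    f <- safe_f(ss / df1, ss_err / df2, df1, df2)
    tibble::tibble(term = term, df1 = df1, df2 = df2,
                   statistic = f$F, p.value = f$p)
  }
  main <- dplyr::bind_rows(
    eff("centrality", ss_c, a - 1, ss_sc, (n - 1) * (a - 1)),
    eff("frontality", ss_f, b - 1, ss_sf, (n - 1) * (b - 1)),
    eff("centrality:frontality", ss_cf, (a - 1) * (b - 1),
        ss_scf, (n - 1) * (a - 1) * (b - 1))
  )

  # planned comparisons on per-subject contrast scores (df = n - 1)
  lvl_mean <- function(level) rowMeans(m_sc[, level, drop = FALSE])
  contrasts <- list(
    central_vs_baseline = lvl_mean("central"),
    secondary_vs_baseline = lvl_mean("secondary"),
    primary_vs_baseline = lvl_mean("primary"),
    central_vs_secondary = lvl_mean("central") - lvl_mean("secondary"),
    secondary_vs_primary = lvl_mean("secondary") - lvl_mean("primary")
  )
  planned <- purrr::imap_dfr(contrasts, function(L, nm) {
    t2 <- contrast_f(L)
    tibble::tibble(term = nm, df1 = 1, df2 = length(L) - 1,
                   statistic = t2$F, p.value = t2$p)
  })
  dplyr::bind_rows(main, planned)
}

safe_f <- function(ms_eff, ms_err, df1, df2) {
  if (ms_err <= 0) {
    if (ms_eff <= 0) return(list(F = 0, p = 1))
    return(list(F = Inf, p = 0))
  }
  Fv <- ms_eff / ms_err
  list(F = Fv, p = stats::pf(Fv, df1, df2, lower.tail = FALSE))
}

contrast_f <- function(L) {
  n <- length(L)
  v <- stats::var(L)
  if (v == 0) {
    if (mean(L) == 0) return(list(F = 0, p = 1))
    return(list(F = Inf, p = 0))
  }
  tval <- mean(L) / sqrt(v / n)
  Fv <- tval^2
  list(F = Fv, p = stats::pf(Fv, 1, n - 1, lower.tail = FALSE))
}

#' First significant activation step per centrality level
#'
#' From a per-step [rm_anova()] table, reports for each centrality level the
#' earliest critical-window step at which the level-vs-baseline planned
#' comparison is significant (default `p < 0.05`, uncorrected).
#'
#' @param anova A `ca_anova` tibble.
#' @param alpha Significance level (default 0.05).
#' @return A tibble with columns `level` and `first_step` (`NA` if the level
#'   never reaches significance).
#' @export
activation_onset_summary <- function(anova, alpha = 0.05) {
  stopifnot(inherits(anova, "ca_anova") || is.data.frame(anova))
  lv <- c(central = "central_vs_baseline",
          secondary = "secondary_vs_baseline",
          primary = "primary_vs_baseline")
  purrr::imap_dfr(lv, function(term, level) {
    rows <- anova[anova$term == term & !is.na(anova$p.value) &
                    anova$p.value < alpha, ]
    tibble::tibble(level = level,
                   first_step = if (nrow(rows) == 0) NA_integer_
                                else as.integer(min(rows$step)))
  })
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy ca_anova
#' @export
tidy.ca_anova <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @method glance ca_anova
#' @export
glance.ca_anova <- function(x, ...) {
  on <- activation_onset_summary(x)
  tibble::tibble(
    n_subjects = attr(x, "n_subjects"),
    n_steps = length(unique(x$step)),
    first_step_central = on$first_step[on$level == "central"],
    first_step_secondary = on$first_step[on$level == "secondary"],
    first_step_primary = on$first_step[on$level == "primary"]
  )
}
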