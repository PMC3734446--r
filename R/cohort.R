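#' Eligibility filtering of birth records
#'
#' Restricts records to liveborn singletons of at least 33 completed weeks
#' gestation with a non-null POBW (the case-definition denominator).
#' Exclusion reasons are counted in that fixed order: a record failing
#' several rules is counted once, under the first.
#'
#' @param records data frame of birth records with columns `liveborn`,
#'   `singleton`, `gestation`, `pobw`.
#' @return list with `records` (the eligible subset) and `exclusions`
#'   (named integer vector: `not_liveborn`, `not_singleton`,
#'   `gestation_lt_33`, `null_pobw`).
#' @export
filter_eligible <- function(records) {
  if (nrow(records) == 0) {
    return(list(records = records,
                exclusions = c(not_liveborn = 0L, not_singleton = 0L,
                               gestation_lt_33 = 0L, null_pobw = 0L)))
  }
  reason <- rep(NA_character_, nrow(records))
  reason[is.na(records$pobw)] <- "null_pobw"
  reason[records$gestation < 33] <- "gestation_lt_33"
  reason[!records$singleton] <- "not_singleton"
  reason[!records$liveborn] <- "not_liveborn"
  keep <- is.na(reason)
  counts <- c(not_liveborn = sum(reason == "not_liveborn", na.rm = TRUE),
              not_singleton = sum(reason == "not_singleton", na.rm = TRUE),
              gestation_lt_33 = sum(reason == "gestation_lt_33", na.rm = TRUE),
              null_pobw = sum(reason == "null_pobw", na.rm = TRUE))
  list(records = records[keep, , drop = FALSE], exclusions = counts)
}

#' Classify poor fetal growth from POBW
#'
#' A birth is a case when its Proportion of Optimal Birth Weight is strictly
#' under 80% (`pobw < 0.80`); a POBW of exactly 0.80 is not a case.
#'
#' @param pobw numeric POBW ratio(s); must be non-null (filter first).
#' @return logical vector.
#' @export
classify_poor_fetal_growth <- function(pobw) {
  if (any(is.na(pobw))) stop("null POBW: records must be eligibility-filtered first")
  pobw < 0.80
}

#' Classify small-for-gestational-age (SGA)
#'
#' True when birthweight is strictly below the 10th-centile reference value
#' for the record's sex and gestation; a weight exactly at the centile is
#' not SGA.
#'
#' @param birthweight grams.
#' @param sex `"M"`/`"F"`.
#' @param gestation completed weeks.
#' @param reference data frame `sex`, `gestation`, `p10_weight_g`
#'   (default: packaged synthetic table, [sga_reference()]).
#' @return logical vector; errors if any (sex, gestation) pair is not
#'   covered by the reference.
#' @export
classify_sga <- function(birthweight, sex, gestation, reference = sga_reference()) {
  idx <- match(paste(sex, gestation), paste(reference$sex, reference$gestation))
  if (any(is.na(idx))) {
    miss <- unique(paste0(sex, "/", gestation)[is.na(idx)])
    stop("reference table does not cover: ", paste(miss, collapse = ", "))
  }
  birthweight < reference$p10_weight_g[idx]
}

#' Aggregate eligible birth records to a suburb table
#'
#' Counts eligible births `N_i` and poor-fetal-growth cases `R_i` per
#' suburb and attaches the raw and standardized SES index. Standardization
#' is to mean 0, SD 1 across the suburbs present in the SES table (the
#' study area).
#'
#' @param records eligible birth records (see [filter_eligible()]).
#' @param ses_by_suburb data frame `suburb_id`, `ses_raw` covering every
#'   suburb appearing in `records`.
#' @return suburb table `suburb_id`, `births`, `cases`, `ses_raw`,
#'   `ses_std` (one row per suburb of the SES table with at least one
#'   record).
#' @export
aggregate_to_suburbs <- function(records, ses_by_suburb) {
  ids <- as.character(ses_by_suburb$suburb_id)
  rec_ids <- as.character(records$suburb_id)
  unknown <- setdiff(unique(rec_ids), ids)
  if (length(unknown)) {
    stop("records reference suburbs absent from the SES table: ",
         paste(unknown, collapse = ", "))
  }
  case <- classify_poor_fetal_growth(records$pobw)
  births <- tapply(rec_ids, rec_ids, length)
  cases <- tapply(case, rec_ids, sum)
  present <- ids[ids %in% names(births)]
  ses_raw <- ses_by_suburb$ses_raw[match(present, ids)]
  std_all <- standardize_ses(ses_by_suburb$ses_raw)
  data.frame(suburb_id = present,
             births = as.integer(births[present]),
             cases = as.integer(cases[present]),
             ses_raw = ses_raw,
             ses_std = std_all[match(present, ids)],
             stringsAsFactors = FALSE)
}

#' Incidence as a percentage
#'
#' @param cases,births counts (scalars or vectors).
#' @param digits rounding for the printed percentage (default 1, the
#'   convention used for reporting study-period incidence).
#' @return percentage(s).
#' @export
incidence <- function(cases, births, digits = 1) {
  if (any(births <= 0)) stop("births must be positive")
  round(100 * cases / births, digits)
}

#' Standardize an SES index within the study area
#'
#' Centres to mean 0 and scales to SD 1 using the population SD (divisor
#' `n`).
#'
#' @param x numeric vector with at least two distinct values.
#' @return standardized vector.
#' @export
standardize_ses <- function(x) {
  if (length(x) < 2 || length(unique(x)) < 2) {
    stop("SES standardization needs at least two distinct values")
  }
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  (x - m) / s
}

#' Odds ratio of a 2x2 table with Woolf confidence interval
#'
#' `OR = ad / (bc)`; the 95% CI is
#' `exp(log(OR) +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`.
#'
#' @param a,b,c,d cell counts (a/b one row, c/d the other).
#' @param continuity add 0.5 to every cell (required when any cell is 0).
#' @return list `or`, `ci_low`, `ci_high`.
#' @export
odds_ratio_2x2 <- function(a, b, c, d, continuity = FALSE) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop("cell counts must be non-negative")
  if (any(cells == 0) && !continuity) {
    stop("zero cell: set continuity = TRUE for the 0.5 correction")
  }
  if (continuity) cells <- cells + 0.5
  a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
  or <- a * d / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(or = or,
       ci_low = exp(log(or) - 1.96 * se),
       ci_high = exp(log(or) + 1.96 * se))
}

#' Upper-tail chi-square probability
#'
#' `P(X > x)` for `X ~ chi-square(df)` (the regularized incomplete gamma
#' function, via [stats::pchisq()]).
#'
#' @param x non-negative statistic.
#' @param df degrees of freedom (>= 1).
#' @return p-value.
#' @export
chi_square_upper_tail <- function(x, df) {
  if (any(x < 0)) stop("statistic must be non-negative")
  if (any(df < 1) || any(df != round(df))) stop("df must be a positive integer")
  stats::pchisq(x, df, lower.tail = FALSE)
}

#' Breslow-Day test of homogeneity of odds ratios
#'
#' The classic Breslow-Day statistic against the Mantel-Haenszel common
#' odds ratio: for each stratum the fitted a-cell under the common OR is
#' found by solving the quadratic in the fixed margins, and
#' `chi2 = sum (a_k - fitted_k)^2 / Var_k` with `df = K - 1`.
#'
#' @param tables list of 2x2 matrices (rows: exposure; cols: outcome,
#'   case first) or a `K x 4` matrix/data frame of cells `a, b, c, d`.
#' @return list `statistic`, `df`, `p_value`, `or_mh`.
#' @export
breslow_day <- function(tables) {
  cells <- as_2x2_cells(tables)
  K <- nrow(cells)
  if (K < 2) stop("at least two strata are required")
  for (k in seq_len(K)) {
    a <- cells[k, 1]; b <- cells[k, 2]; c <- cells[k, 3]; d <- cells[k, 4]
    if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) {
      stop("degenerate stratum ", k, ": a zero margin")
    }
  }
  or_mh <- sum(cells[, 1] * cells[, 4] / rowSums(cells)) /
    sum(cells[, 2] * cells[, 3] / rowSums(cells))
  stat <- 0
  for (k in seq_len(K)) {
    a <- cells[k, 1]; b <- cells[k, 2]; c <- cells[k, 3]; d <- cells[k, 4]
    n <- a + b + c + d
    t1 <- a + b       # exposed margin
    s1 <- a + c       # case margin
    R <- or_mh
    if (abs(R - 1) < 1e-12) {
      A <- t1 * s1 / n
    } else {
      qa <- 1 - R
      qb <- n - t1 - s1 + R * (t1 + s1)
      qc <- -R * t1 * s1
      disc <- sqrt(qb^2 - 4 * qa * qc)
      roots <- c((-qb + disc) / (2 * qa), (-qb - disc) / (2 * qa))
      lo <- max(0, t1 + s1 - n); hi <- min(t1, s1)
      A <- roots[roots >= lo - 1e-9 & roots <= hi + 1e-9][1]
      if (is.na(A)) stop("no admissible fitted cell in stratum ", k)
    }
    v <- 1 / (1 / A + 1 / (t1 - A) + 1 / (s1 - A) + 1 / (n - t1 - s1 + A))
    stat <- stat + (a - A)^2 / v
  }
  df <- as.integer(K - 1)
  list(statistic = stat, df = df,
       p_value = chi_square_upper_tail(stat, df), or_mh = or_mh)
}

as_2x2_cells <- function(tables) {
  if (is.list(tables) && !is.data.frame(tables)) {
    cells <- t(vapply(tables, function(m) {
      m <- as.matrix(m)
      stopifnot(all(dim(m) == c(2, 2)))
      c(m[1, 1], m[1, 2], m[2, 1], m[2, 2])
    }, numeric(4)))
  } else {
    cells <- as.matrix(tables)
    stopifnot(ncol(cells) == 4)
  }
  cells
}

#' Goodness of fit of SGA cases among POBW-null records
#'
#' Compares the suburb distribution of SGA cases among records with null
#' POBW to the per-suburb case probabilities fitted by the random effects
#' model: observed `O_i` = SGA cases among null records in suburb `i`,
#' expected `E_i = n_i * p_i`, Pearson `chi2 = sum (O - E)^2 / E` over the
#' contributing suburbs, `df` = contributing suburbs - 1. Suburbs with zero
#' expected count are dropped with a warning.
#'
#' @param null_records data frame of POBW-null records with `suburb_id` and
#'   logical `sga`.
#' @param fitted_probs data frame `suburb_id`, `p` (fitted case
#'   probability); must cover every contributing suburb.
#' @return list `statistic`, `df`, `p_value`, `n_suburbs`.
#' @export
pobw_null_gof <- function(null_records, fitted_probs) {
  ids <- as.character(null_records$suburb_id)
  obs <- tapply(null_records$sga, ids, sum)
  n_i <- tapply(ids, ids, length)
  sub <- names(obs)
  idx <- match(sub, as.character(fitted_probs$suburb_id))
  if (any(is.na(idx))) {
    stop("fitted probabilities missing for suburb(s): ",
         paste(sub[is.na(idx)], collapse = ", "))
  }
  expd <- as.numeric(n_i) * fitted_probs$p[idx]
  drop <- expd <= 0
  if (any(drop)) {
    warning(sum(drop), " suburb(s) dropped for zero expected count")
    obs <- obs[!drop]; expd <- expd[!drop]
  }
  if (length(expd) < 2) stop("fewer than two contributing suburbs")
  stat <- sum((as.numeric(obs) - expd)^2 / expd)
  df <- length(expd) - 1L
  list(statistic = stat, df = df,
       p_value = chi_square_upper_tail(stat, df), n_suburbs = length(expd))
}

#' Missing-POBW sensitivity report
#'
#' Bundles the three checks on whether null-POBW records bias the analysis:
#' (i) the odds ratio of SGA for null versus non-null POBW, (ii) the
#' Breslow-Day homogeneity of that odds ratio across SES quintiles, and
#' (iii) the goodness of fit of SGA cases among null records to fitted
#' per-suburb probabilities.
#'
#' @param records birth records (after restricting to liveborn singletons
#'   of 33+ weeks) with `pobw`, `sga`, `ses_quintile`, `suburb_id`.
#' @param fitted_probs optional data frame `suburb_id`, `p` for the
#'   goodness-of-fit component (skipped when `NULL`).
#' @return a `sensitivity_report` list: `or_sga` (with CI), `breslow_day`,
#'   `gof` (or `NULL`).
#' @export
sensitivity_report <- function(records, fitted_probs = NULL) {
  nul <- is.na(records$pobw)
  a <- sum(nul & records$sga);  b <- sum(nul & !records$sga)
  c <- sum(!nul & records$sga); d <- sum(!nul & !records$sga)
  or <- odds_ratio_2x2(a, b, c, d, continuity = any(c(a, b, c, d) == 0))
  tabs <- lapply(sort(unique(records$ses_quintile)), function(q) {
    r <- records[records$ses_quintile == q, ]
    matrix(c(sum(is.na(r$pobw) & r$sga), sum(is.na(r$pobw) & !r$sga),
             sum(!is.na(r$pobw) & r$sga), sum(!is.na(r$pobw) & !r$sga)),
           2, 2, byrow = TRUE)
  })
  bd <- tryCatch(breslow_day(tabs), error = function(e) NULL)
  gof <- if (!is.null(fitted_probs) && any(nul)) {
    pobw_null_gof(records[nul, , drop = FALSE], fitted_probs)
  } else NULL
  structure(list(or_sga = or, breslow_day = bd, gof = gof),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("Missing-POBW sensitivity analysis\n")
  cat(sprintf("  SGA odds ratio (null vs non-null POBW): %.2f (%.2f to %.2f)\n",
              x$or_sga$or, x$or_sga$ci_low, x$or_sga$ci_high))
  if (!is.null(x$breslow_day)) {
    cat(sprintf("  Breslow-Day homogeneity across SES quintiles: chi2 = %.2f, df = %d, p = %.2f\n",
                x$breslow_day$statistic, x$breslow_day$df, x$breslow_day$p_value))
  }
  if (!is.null(x$gof)) {
    cat(sprintf("  GOF of SGA cases among null-POBW suburbs: chi2 = %.2f, df = %d, p = %.2f\n",
                x$gof$statistic, x$gof$df, x$gof$p_value))
  }
  invisible(x)
}
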