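#' Two-sample t-test on organic-acid measurements
#'
#' Tests a variety contrast for one acid at one stage, either from raw
#' replicate values or from printed summaries (mean, SD, n). Student mode
#' uses the pooled-variance statistic with `n_a + n_b - 2` degrees of
#' freedom; Welch mode uses the Satterthwaite approximation. Two-sided.
#'
#' @param a,b either numeric vectors of replicate values (mg/g FW) or lists
#'   `list(mean =, sd =, n =)`.
#' @param mode `"student"` (default) or `"welch"`.
#' @return list of class `acid_test` with `t`, `df`, `p`, `label`
#'   (`"ns"`, `"*"` for p < 0.05, `"**"` for p < 0.01), and the two group
#'   summaries.
#' @export
two_sample_ttest <- function(a, b, mode = c("student", "welch")) {
  mode <- match.arg(mode)
  summ <- function(x) {
    if (is.list(x)) {
      stopifnot(all(c("mean", "sd", "n") %in% names(x)))
      list(mean = x$mean, sd = x$sd, n = as.integer(x$n))
    } else {
      if (length(x) < 2) stop("need >= 2 replicates per group")
      list(mean = mean(x), sd = sd(x), n = length(x))
    }
  }
  sa <- summ(a); sb <- summ(b)
  if (sa$n < 2 || sb$n < 2) stop("need n >= 2 in both groups")
  if (sa$sd < 0 || sb$sd < 0) stop("sd must be >= 0")
  if (sa$sd == 0 && sb$sd == 0 && sa$mean == sb$mean) {
    t <- 0; df <- sa$n + sb$n - 2; p <- 1
  } else if (mode == "student") {
    df <- sa$n + sb$n - 2
    sp2 <- ((sa$n - 1) * sa$sd^2 + (sb$n - 1) * sb$sd^2) / df
    se <- sqrt(sp2 * (1 / sa$n + 1 / sb$n))
    t <- (sa$mean - sb$mean) / se
    p <- 2 * pt(-abs(t), df)
  } else {
    va <- sa$sd^2 / sa$n; vb <- sb$sd^2 / sb$n
    se <- sqrt(va + vb)
    t <- (sa$mean - sb$mean) / se
    df <- (va + vb)^2 / (va^2 / (sa$n - 1) + vb^2 / (sb$n - 1))
    p <- 2 * pt(-abs(t), df)
  }
  label <- if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
  structure(list(t = t, df = df, p = p, label = label,
                 group_a = sa, group_b = sb, mode = mode),
            class = "acid_test")
}

#' @export
print.acid_test <- function(x, ...) {
  cat(sprintf("%s t = %.3f, df = %.2f, p = %.3g [%s]\n",
              x$mode, x$t, x$df, x$p, x$label))
  invisible(x)
}

#' Summarise raw acid replicates to mean +/- SD per cell
#'
#' @param traits data.frame of per-sample OA/MA/CA values (rownames =
#'   sample ids).
#' @param meta `sample_meta` covering those samples.
#' @return data.frame with columns acid, variety, stage, mean, sd, n.
#' @export
summarize_acids <- function(traits, meta) {
  stopifnot(all(rownames(traits) %in% meta$sample_id))
  m <- meta[match(rownames(traits), meta$sample_id), ]
  out <- list()
  for (acid in c("OA", "MA", "CA")) {
    for (v in unique(m$variety)) for (st in unique(m$stage)) {
      vals <- traits[m$variety == v & m$stage == st, acid]
      if (!length(vals)) stop("empty cell: ", acid, " ", v, " ", st)
      if (length(vals) < 2) stop("need >= 2 replicates for ", acid, " ", v, " ", st)
      out[[length(out) + 1]] <- data.frame(
        acid = acid, variety = v, stage = st,
        mean = mean(vals), sd = sd(vals), n = length(vals),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Relative expression by the 2^-ddCt method
#'
#' ddCt = (Ct_target,sample - Ct_ref,sample) -
#'        (Ct_target,calibrator - Ct_ref,calibrator); returns 2^-ddCt.
#' All arguments are vectorised.
#'
#' @param ct_target_sample,ct_ref_sample,ct_target_calibrator,ct_ref_calibrator
#'   cycle-threshold values (reference gene = internal control).
#' @return relative expression values.
#' @export
ddct_relative_expression <- function(ct_target_sample, ct_ref_sample,
                                     ct_target_calibrator, ct_ref_calibrator) {
  vals <- c(ct_target_sample, ct_ref_sample, ct_target_calibrator,
            ct_ref_calibrator)
  if (!all(is.finite(vals))) stop("Ct values must be finite")
  ddct <- (ct_target_sample - ct_ref_sample) -
    (ct_target_calibrator - ct_ref_calibrator)
  2^(-ddct)
}

#' Pearson correlation between FPKM and qPCR series
#'
#' @param fpkm_series,qpcr_series equal-length numeric vectors (>= 3 points).
#' @return list with `r` and two-sided `p` (t transform); zero variance in
#'   either series gives `r = NA` with `flag = "zero_variance"`.
#' @export
validation_pcc <- function(fpkm_series, qpcr_series) {
  stopifnot(length(fpkm_series) == length(qpcr_series),
            length(fpkm_series) >= 3)
  if (sd(fpkm_series) == 0 || sd(qpcr_series) == 0)
    return(list(r = NA_real_, p = NA_real_, flag = "zero_variance"))
  n <- length(fpkm_series)
  r <- cor(fpkm_series, qpcr_series)
  if (abs(r) >= 1) return(list(r = r, p = 0, flag = NULL))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t), n - 2), flag = NULL)
}

#' Packaged transcription of the published acid-content table
#'
#' Mean +/- SD (n = 3) of oxalic, malic and citric acid (mg/g FW) for the
#' two varieties across the four stages.
#'
#' @return data.frame with columns acid, variety, stage, mean, sd, n.
#' @export
acid_table_fixture <- function() {
  path <- system.file("extdata", "table1.csv", package = "acidsweep",
                      mustWork = TRUE)
  out <- as.data.frame(data.table::fread(path))
  out$n <- as.integer(out$n)
  out
}

#' Per-stage variety tests for one acid from a summary table
#'
#' @param tab summary table as from [acid_table_fixture()] or
#'   [summarize_acids()].
#' @param acid `"OA"`, `"MA"` or `"CA"`.
#' @param mode passed to [two_sample_ttest()].
#' @return data.frame with stage, t, df, p, label (AMT vs DSHS).
#' @export
acid_stage_tests <- function(tab, acid, mode = "student") {
  tab <- tab[tab$acid == acid, ]
  out <- lapply(STAGES, function(st) {
    a <- tab[tab$variety == "AMT" & tab$stage == st, ]
    d <- tab[tab$variety == "DSHS" & tab$stage == st, ]
    tt <- two_sample_ttest(list(mean = a$mean, sd = a$sd, n = a$n),
                           list(mean = d$mean, sd = d$sd, n = d$n),
                           mode = mode)
    data.frame(stage = st, t = tt$t, df = tt$df, p = tt$p, label = tt$label,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
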