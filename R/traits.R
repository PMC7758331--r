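# Spike-fertility statistics: seed set, potential spikelet
# productivity, and multi-line trait comparison via one-way ANOVA with
# Fisher's protected LSD flags.

#' Seed set in florets 1 and 2
#'
#' Percentage of grains formed in the first two florets of developed
#' spikelets: `100 * grains / (2 * developed_spikelets)`, capped at
#' 100. Reduced (undeveloped) spikelets must already be excluded from
#' the denominator.
#'
#' @param grains_f1f2 grain count in florets 1+2 (vectorized).
#' @param developed_spikelets developed spikelet count (> 0).
#' @return percent in `[0, 100]`.
#' @examples
#' seed_set(20, 10)  # 100
#' @export
seed_set <- function(grains_f1f2, developed_spikelets) {
  if (any(developed_spikelets <= 0)) {
    stop("developed_spikelets must be > 0 (seed set is undefined otherwise)")
  }
  if (any(grains_f1f2 < 0)) stop("grain counts must be >= 0")
  pmin(100, 100 * grains_f1f2 / (2 * developed_spikelets))
}

#' Potential spikelet productivity
#'
#' Grains per spikelet at harvest maturity as a percentage of floret
#' primordia per spikelet (same spike position) at the terminal
#' spikelet stage.
#'
#' @param grains_at_hm mean grains per spikelet at harvest maturity.
#' @param primordia_at_ts mean floret primordia per spikelet at the
#'   terminal spikelet stage (> 0).
#' @return percent (may exceed 100 only if grains exceed primordia,
#'   which the data model forbids upstream).
#' @export
potential_productivity <- function(grains_at_hm, primordia_at_ts) {
  if (any(primordia_at_ts <= 0)) {
    stop("primordia_at_ts must be > 0 (productivity is undefined otherwise)")
  }
  if (any(grains_at_hm < 0)) stop("grain counts must be >= 0")
  100 * grains_at_hm / primordia_at_ts
}

.validate_obs <- function(obs) {
  need <- c("line", "replicate", "trait", "value")
  if (!all(need %in% names(obs))) {
    stop("trait observations need columns: ", paste(need, collapse = ", "))
  }
  if (any(!is.finite(obs$value))) stop("trait values must be finite")
  obs
}

#' One-way ANOVA with Fisher's protected LSD flags
#'
#' For every trait, fits a one-way ANOVA across lines and — only where
#' the omnibus F test rejects at a given alpha (the "protected" rule) —
#' compares each line against the control with the least significant
#' difference `LSD = t(1 - alpha/2, df_err) * sqrt(MSE * (1/n_i +
#' 1/n_c))`. A comparison exceeding the LSD at alpha 0.01 is flagged
#' `"**"`, at 0.05 `"*"`, else `""`. Lines with fewer than two
#' replicates for a trait are excluded with a warning. With exactly two
#' groups the procedure coincides with the pooled two-sample t test.
#'
#' @param obs long data frame: `line`, `replicate`, `trait`, `value`.
#' @param control name of the control line.
#' @param alphas significance levels for the flags (default 0.05, 0.01;
#'   `"*"` marks the largest, `"**"` the smallest).
#' @param all_pairs if `TRUE`, also returns every pairwise line-line
#'   comparison (the control-vs-line table is the primary output).
#' @param bonferroni if `TRUE`, divides each alpha by the number of
#'   comparisons per trait before flagging (off by default, matching
#'   the plain protected-LSD convention).
#' @return data frame: `trait`, `line`, `n`, `mean`, `diff` (line minus
#'   control), `p_omnibus`, `p_vs_control` (unprotected pairwise
#'   p-value), `flag`; plus attribute `all_pairs` when requested.
#' @export
anova_lsd <- function(obs, control, alphas = c(0.05, 0.01),
                      all_pairs = FALSE, bonferroni = FALSE) {
  obs <- .validate_obs(obs)
  if (!control %in% obs$line) stop("control line '", control,
                                   "' absent from the observations")
  alphas <- sort(alphas, decreasing = TRUE)  # "*" first, "**" last
  flags <- vapply(seq_along(alphas), function(i) {
    paste(rep("*", i), collapse = "")
  }, character(1))

  res <- list()
  pairs <- list()
  for (tr in unique(obs$trait)) {
    d <- obs[obs$trait == tr, ]
    n_by <- table(d$line)
    low <- names(n_by)[n_by < 2]
    if (length(low)) {
      warning("trait '", tr, "': excluding line(s) with < 2 replicates: ",
              paste(low, collapse = ", "))
      d <- d[!d$line %in% low, ]
    }
    if (!control %in% d$line) stop("trait '", tr,
                                   "': control has < 2 replicates")
    d$line <- factor(d$line)
    if (nlevels(d$line) < 2) {
      res[[length(res) + 1]] <- data.frame(
        trait = tr, line = control, n = sum(d$line == control),
        mean = mean(d$value[d$line == control]), diff = 0,
        p_omnibus = NA_real_, p_vs_control = NA_real_, flag = "",
        stringsAsFactors = FALSE)
      next
    }
    fit <- stats::aov(value ~ line, data = d)
    an <- stats::anova(fit)
    mse <- an["Residuals", "Mean Sq"]
    dfe <- an["Residuals", "Df"]
    p_omni <- an["line", "Pr(>F)"]
    if (is.nan(p_omni)) p_omni <- if (an["line", "Mean Sq"] > 0) 0 else 1
    means <- tapply(d$value, d$line, mean)
    ns <- table(d$line)
    others <- setdiff(levels(d$line), control)
    m <- if (bonferroni) length(others) else 1

    flag_of <- function(delta, se) {
      fl <- ""
      for (i in seq_along(alphas)) {
        a <- alphas[i] / m
        lsd <- stats::qt(1 - a / 2, dfe) * se
        if (!is.na(p_omni) && p_omni <= a && abs(delta) > lsd) fl <- flags[i]
      }
      fl
    }
    p_pair <- function(delta, se) {
      if (se == 0) return(if (abs(delta) > 0) 0 else 1)
      2 * stats::pt(-abs(delta) / se, dfe)
    }

    for (ln in others) {
      se <- sqrt(mse * (1 / ns[[ln]] + 1 / ns[[control]]))
      delta <- means[[ln]] - means[[control]]
      res[[length(res) + 1]] <- data.frame(
        trait = tr, line = ln, n = ns[[ln]], mean = means[[ln]],
        diff = delta, p_omnibus = p_omni, p_vs_control = p_pair(delta, se),
        flag = flag_of(delta, se), stringsAsFactors = FALSE)
    }
    res[[length(res) + 1]] <- data.frame(
      trait = tr, line = control, n = ns[[control]],
      mean = means[[control]], diff = 0, p_omnibus = p_omni,
      p_vs_control = NA_real_, flag = "", stringsAsFactors = FALSE)

    if (all_pairs) {
      lv <- levels(d$line)
      for (i in seq_along(lv)) for (j in seq_along(lv)) {
        if (i >= j) next
        se <- sqrt(mse * (1 / ns[[lv[i]]] + 1 / ns[[lv[j]]]))
        delta <- means[[lv[j]]] - means[[lv[i]]]
        pairs[[length(pairs) + 1]] <- data.frame(
          trait = tr, line_a = lv[i], line_b = lv[j], diff = delta,
          p = p_pair(delta, se), flag = flag_of(delta, se),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  if (all_pairs) attr(out, "all_pairs") <- do.call(rbind, pairs)
  out
}

#' Panel summary table of trait means with significance flags
#'
#' Per-line trait means with protected-LSD flags against the control
#' and, when supplied, the seed-viability phenotype — one row per line,
#' control first, then input order.
#'
#' @param obs long trait observations (see [anova_lsd()]).
#' @param control control line name.
#' @param phenotype optional named vector of `"viable"`/`"non_viable"`/
#'   `"unknown"` per line, shown as `+`/`-`/`NA`.
#' @param alphas passed to [anova_lsd()].
#' @return data frame of class `panel_report`: `line`, `viability`,
#'   then `<trait>` (mean) and `<trait>_flag` columns per trait.
#' @export
summarize_panel <- function(obs, control, phenotype = NULL,
                            alphas = c(0.05, 0.01)) {
  stats <- anova_lsd(obs, control, alphas = alphas)
  traits <- unique(stats$trait)
  lines <- unique(c(control, unique(obs$line)))
  lines <- lines[lines %in% stats$line]
  out <- data.frame(line = lines, stringsAsFactors = FALSE)
  out$viability <- if (is.null(phenotype)) NA_character_ else {
    unname(c(viable = "+", non_viable = "-", unknown = NA)[phenotype[lines]])
  }
  for (tr in traits) {
    s <- stats[stats$trait == tr, ]
    i <- match(lines, s$line)
    out[[tr]] <- s$mean[i]
    out[[paste0(tr, "_flag")]] <- s$flag[i]
  }
  class(out) <- c("panel_report", "data.frame")
  out
}

#' Write / read a panel report as TSV (round-trip stable)
#'
#' @param report a `panel_report` from [summarize_panel()].
#' @param path TSV path.
#' @return `write_panel_report`: `path` invisibly;
#'   `read_panel_report`: the report.
#' @export
write_panel_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_panel_report
#' @export
read_panel_report <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = NA, na.strings = "NA")
  flag_cols <- grep("_flag$", names(out))
  for (j in flag_cols) {
    out[[j]] <- ifelse(is.na(out[[j]]), "", as.character(out[[j]]))
  }
  out$line <- as.character(out$line)
  class(out) <- c("panel_report", "data.frame")
  out
}
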