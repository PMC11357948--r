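# Milestone-wise regression modelling: standardization by the cohort SD,
# univariable scans with Bonferroni-Holm adjustment, p-value-based stepwise
# selection, standardized effects with normal-theory CIs, R2 and partial R2.

#' Standardize numeric columns by their own cohort SD
#'
#' Centers each selected column and divides by its own SD so that
#' standardized beta coefficients are comparable between variables and
#' outcomes.
#'
#' @param table data.frame.
#' @param columns Columns to standardize (default: all numeric columns).
#' @return The table with the selected columns standardized.
#' @export
standardize <- function(table, columns = NULL) {
  if (is.null(columns))
    columns <- names(table)[vapply(table, is.numeric, logical(1))]
  for (cl in columns) {
    s <- stats::sd(table[[cl]], na.rm = TRUE)
    if (!is.finite(s) || s == 0)
      stop(sprintf("degenerate column '%s': zero or undefined SD", cl))
    table[[cl]] <- (table[[cl]] - mean(table[[cl]], na.rm = TRUE)) / s
  }
  table
}

#' Bonferroni-Holm step-down adjustment
#'
#' @param pvals Vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values in the input order, monotone over the sorted
#'   sequence and capped at 1.
#' @export
holm_adjust <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "holm")
}

#' Univariable regression scan
#'
#' Simple linear regression of the standardized outcome on each
#' standardized candidate variable separately (complete cases per pair),
#' with normal-theory 95% CIs, Holm adjustment across the scanned set, and
#' R2 equal to the squared Pearson correlation.
#'
#' @param table data.frame (cohort table).
#' @param outcome Outcome column name.
#' @param variables Character vector of candidate column names.
#' @param min_n Minimum complete pairs per variable (default 10); variables
#'   with fewer are skipped with a message.
#' @return data.frame: `variable`, `n`, `beta` (standardized), `ci_low`,
#'   `ci_high`, `p`, `p_holm`, `r2`.
#' @export
univariable_scan <- function(table, outcome, variables, min_n = 10) {
  rows <- lapply(variables, function(v) {
    ok <- stats::complete.cases(table[, c(outcome, v)])
    n <- sum(ok)
    if (n < min_n) {
      message(sprintf("skipping '%s': only %d complete pairs", v, n))
      return(NULL)
    }
    d <- standardize(table[ok, c(outcome, v)], c(outcome, v))
    fit <- stats::lm(stats::reformulate(v, outcome), data = d)
    sm <- summary(fit)$coefficients
    beta <- sm[v, "Estimate"]
    se <- sm[v, "Std. Error"]
    ci <- beta + c(-1, 1) * stats::qnorm(0.975) * se
    data.frame(variable = v, n = n, beta = beta, ci_low = ci[1],
               ci_high = ci[2], p = sm[v, "Pr(>|t|)"],
               r2 = summary(fit)$r.squared)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(variable = character(), n = integer(), beta = numeric(),
                      ci_low = numeric(), ci_high = numeric(), p = numeric(),
                      p_holm = numeric(), r2 = numeric()))
  out$p_holm <- holm_adjust(out$p)
  out[, c("variable", "n", "beta", "ci_low", "ci_high", "p", "p_holm", "r2")]
}

# p-value of each non-intercept term of a fitted lm (named vector)
term_stat <- function(fit, col) {
  sm <- summary(fit)$coefficients
  keep <- setdiff(rownames(sm), "(Intercept)")
  stats::setNames(sm[keep, col], keep)
}
term_pvals <- function(fit) term_stat(fit, "Pr(>|t|)")
term_tvals <- function(fit) term_stat(fit, "t value")

#' Stepwise forward and backward selection by p-value
#'
#' Forward steps add the candidate with the smallest partial p-value below
#' `alpha_enter`; backward steps remove any included variable whose p-value
#' exceeds `alpha_remove`; the two alternate until a fixpoint. Ties are
#' broken by the larger |t| statistic, then alphabetically. Perfectly
#' collinear candidates (aliased in the fit) are dropped with a warning.
#'
#' @param table data.frame; rows with missing outcome or candidates are
#'   dropped (listwise complete cases).
#' @param outcome Outcome column name.
#' @param candidates Character vector of candidate column names.
#' @param alpha_enter,alpha_remove Entry and removal thresholds (default
#'   0.05 both).
#' @param standardized Standardize outcome and candidates by their cohort SD
#'   before fitting (default TRUE).
#' @return List of class `stepwise_fit`: `selected` (character), `fit`
#'   (the final `lm` on standardized data, or `NULL` if empty), `r2`,
#'   `n`, `table` (per-selected-variable beta, CI, p, partial R2).
#' @export
stepwise_select <- function(table, outcome, candidates, alpha_enter = 0.05,
                            alpha_remove = 0.05, standardized = TRUE) {
  ok <- stats::complete.cases(table[, c(outcome, candidates), drop = FALSE])
  d <- table[ok, c(outcome, candidates), drop = FALSE]
  if (length(candidates) > 0 && standardized)
    d <- standardize(d, c(outcome, candidates))
  n <- nrow(d)

  selected <- character()
  pool <- candidates
  seen <- character()           # visited selected-sets, to guard cycles
  repeat {
    changed <- FALSE
    # forward
    if (length(pool) > 0) {
      cand_p <- sapply(pool, function(v) {
        fit <- stats::lm(stats::reformulate(c(selected, v), outcome), data = d)
        if (any(is.na(stats::coef(fit)))) return(c(NA_real_, NA_real_))
        c(term_pvals(fit)[[v]], abs(term_tvals(fit)[[v]]))
      })
      aliased <- is.na(cand_p[1, ])
      if (any(aliased)) {
        warning(sprintf("dropping collinear candidate(s): %s",
                        paste(sort(pool[aliased]), collapse = ", ")))
        pool <- pool[!aliased]
        cand_p <- cand_p[, !aliased, drop = FALSE]
      }
      if (length(pool) > 0) {
        best <- order(cand_p[1, ], -cand_p[2, ], pool)[1]
        if (is.finite(cand_p[1, best]) && cand_p[1, best] < alpha_enter) {
          selected <- c(selected, pool[best])
          pool <- pool[-best]
          changed <- TRUE
        }
      }
    }
    # backward
    if (length(selected) > 0) {
      fit <- stats::lm(stats::reformulate(selected, outcome), data = d)
      pv <- term_pvals(fit)
      if (max(pv) > alpha_remove) {
        worst <- names(pv)[order(-pv, abs(term_tvals(fit)), names(pv))[1]]
        selected <- setdiff(selected, worst)
        pool <- c(pool, worst)
        changed <- TRUE
      }
    }
    key <- paste(sort(selected), collapse = "|")
    if (!changed || key %in% seen) break
    seen <- c(seen, key)
  }

  if (length(selected) == 0)
    return(structure(list(selected = character(), fit = NULL, r2 = 0, n = n,
                          table = data.frame()), class = "stepwise_fit"))
  fit <- stats::lm(stats::reformulate(selected, outcome), data = d)
  sm <- summary(fit)$coefficients
  tab <- do.call(rbind, lapply(selected, function(v) {
    beta <- sm[v, "Estimate"]
    se <- sm[v, "Std. Error"]
    data.frame(variable = v, beta = beta,
               ci_low = beta - stats::qnorm(0.975) * se,
               ci_high = beta + stats::qnorm(0.975) * se,
               p = sm[v, "Pr(>|t|)"],
               partial_r2 = partial_r2(d, outcome, selected, v))
  }))
  structure(list(selected = selected, fit = fit,
                 r2 = summary(fit)$r.squared, n = n, table = tab),
            class = "stepwise_fit")
}

#' @export
print.stepwise_fit <- function(x, ...) {
  cat(sprintf("stepwise model: n = %d, R2 = %.3f\n", x$n, x$r2))
  if (nrow(x$table) > 0) print(x$table, row.names = FALSE, digits = 3)
  else cat("  (no variable selected)\n")
  invisible(x)
}

#' Partial R-squared of a variable in a multivariable model
#'
#' `(SSE_without - SSE_with) / SSE_without`, refitting the model with the
#' variable omitted.
#'
#' @param data data.frame (complete cases for the model).
#' @param outcome Outcome column name.
#' @param selected Character vector of model variables.
#' @param variable The variable whose contribution is measured (must be in
#'   `selected`).
#' @return Partial R2 in \[0, 1\].
#' @export
partial_r2 <- function(data, outcome, selected, variable) {
  stopifnot(variable %in% selected)
  full <- stats::lm(stats::reformulate(selected, outcome), data = data)
  rest <- setdiff(selected, variable)
  red <- if (length(rest) == 0) stats::lm(stats::reformulate("1", outcome), data = data)
         else stats::lm(stats::reformulate(rest, outcome), data = data)
  sse_w <- sum(stats::resid(full)^2)
  sse_wo <- sum(stats::resid(red)^2)
  (sse_wo - sse_w) / sse_wo
}

#' Milestone-wise regression models
#'
#' For the menarcheal-age outcome: a univariable scan and a stepwise
#' multivariable model at each clinical milestone, using the cumulative set
#' of variables available up to that milestone, reported in milestone order.
#' For the postmenarcheal-gain outcome: the univariable scan, with the
#' multivariable step run only when more than one variable shows a
#' Holm-significant association.
#'
#' @param table [derive_cohort()] output (or any data.frame with the
#'   grouped columns).
#' @param outcome Outcome column (default `"age_menarche"`).
#' @param groups Named list of milestone variable groups in milestone order
#'   (default [milestone_groups()]); candidate sets are cumulative.
#' @param alpha Entry/removal threshold for the stepwise selection
#'   (default 0.05).
#' @return List of class `milestone_models`, one element per milestone:
#'   `milestone`, `candidates`, `univariable` (scan table), `model`
#'   (`stepwise_fit` or `NULL` when skipped), `r2`.
#' @export
milestone_models <- function(table, outcome = "age_menarche",
                             groups = milestone_groups(), alpha = 0.05) {
  missing_groups <- setdiff(unlist(groups), names(table))
  if (length(missing_groups) > 0)
    stop(sprintf("configuration error: missing columns: %s",
                 paste(missing_groups, collapse = ", ")))
  out <- list()
  cumulative <- character()
  for (g in names(groups)) {
    cumulative <- c(cumulative, groups[[g]])
    uni <- univariable_scan(table, outcome, cumulative)
    n_sig <- sum(uni$p_holm < alpha)
    run_multi <- !(outcome == "postmenarcheal_gain" && n_sig <= 1)
    model <- if (run_multi)
      stepwise_select(table, outcome, cumulative, alpha, alpha) else NULL
    out[[g]] <- list(milestone = g, candidates = cumulative,
                     univariable = uni, model = model,
                     r2 = if (is.null(model)) NA_real_ else model$r2)
  }
  structure(out, class = "milestone_models", outcome = outcome)
}

#' @export
print.milestone_models <- function(x, ...) {
  cat(sprintf("milestone models for outcome '%s'\n", attr(x, "outcome")))
  for (g in names(x)) {
    r2 <- x[[g]]$r2
    sel <- if (is.null(x[[g]]$model)) "(multivariable step skipped)"
           else paste(x[[g]]$model$selected, collapse = ", ")
    cat(sprintf("  %-15s R2 = %s  selected: %s\n", g,
                if (is.na(r2)) "  NA " else sprintf("%.3f", r2), sel))
  }
  invisible(x)
}

#' Forest-style plot of milestone model effects
#'
#' Standardized betas with 95% CIs for the variables selected at each
#' milestone. Requires ggplot2.
#'
#' @param models [milestone_models()] output.
#' @return A ggplot object.
#' @export
plot_effects <- function(models) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_effects() requires the ggplot2 package")
  rows <- do.call(rbind, lapply(names(models), function(g) {
    m <- models[[g]]$model
    if (is.null(m) || nrow(m$table) == 0) return(NULL)
    cbind(milestone = g, m$table)
  }))
  if (is.null(rows)) stop("no selected variables to plot")
  rows$milestone <- factor(rows$milestone, levels = names(models))
  ggplot2::ggplot(rows, ggplot2::aes(x = .data$beta, y = .data$variable)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$milestone),
                        scales = "free_y", space = "free_y") +
    ggplot2::labs(x = "standardized beta (95% CI)", y = NULL)
}
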