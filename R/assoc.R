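#' Mixed-model association of SV occurrence with local genomic features
#'
#' Contrasts observed structural variants (response 1) with an equal number
#' of length-preserving shuffled control intervals (response 0) in a
#' binomial GLMM with chromosome as a random intercept. Predictors are the
#' distance to the nearest chromosome end, the distance to the closest
#' assembly gap, the SV length, and the proportion of bases annotated as
#' TEs, tandem repeats, LINE elements and genes within `flank_bp` windows
#' around the SV midpoint (clipped at chromosome ends, clipped length as
#' denominator). All predictors are standardized before fitting; the
#' standardization uses the control-group mean and SD, so coefficients are
#' log-odds per genomic-background SD and do not rescale with the strength
#' of the enrichment being measured. Odds ratios and 95% Wald confidence
#' intervals are obtained by exponentiating coefficients (`+- 1.96 SE`).
#'
#' @param svs Interval tibble of observed SVs (any type).
#' @param layout A [genome_layout()] (>= 2 chromosomes).
#' @param features Named list of interval tibbles; defaults expected:
#'   `te`, `tandem`, `line`, `genes`. Each becomes a flank-density
#'   predictor `frac_<name>`.
#' @param flank_bp Half-window around the SV midpoint (50,000 bp default).
#' @param seed Mandatory seed for the control draw.
#' @param method `"glmer"` (random chromosome intercept, Laplace
#'   approximation via lme4) or `"glm"` (fixed chromosome effects fallback;
#'   flagged in the output).
#' @param include_length Include SV length as predictor (controls inherit
#'   case lengths, so length is uninformative alone; kept by default and
#'   documented as a caveat).
#' @return An object of class `sv_assoc`; see [tidy.sv_assoc()] and
#'   [glance.sv_assoc()].
#' @export
sv_feature_association <- function(svs, layout, features, flank_bp = 50000,
                                   seed, method = c("glmer", "glm"),
                                   include_length = TRUE) {
  method <- match.arg(method)
  check_intervals(svs)
  if (nrow(layout$chromosomes) < 2) abort("need >= 2 chromosomes")
  controls <- shuffle_intervals(svs[, c("chrom", "start", "end")], layout,
                                seed = seed)
  cases <- svs[, c("chrom", "start", "end")]
  dat <- bind_rows(mutate(cases, y = 1L), mutate(controls, y = 0L))
  X <- assoc_predictors(dat, layout, features, flank_bp)
  if (!include_length) X$sv_length <- NULL
  has_gap <- nrow(layout$gaps) > 0
  if (!has_gap) X$dist_gap <- NULL
  terms <- names(X)
  # standardize on the control rows (genomic background)
  ctrl <- dat$y == 0L
  for (v in terms) {
    mu <- mean(X[[v]][ctrl]); s <- sd(X[[v]][ctrl])
    if (is.na(s) || s == 0) {
      abort(paste0("predictor '", v, "' is constant in the controls"))
    }
    X[[v]] <- (X[[v]] - mu) / s
  }
  fit_dat <- bind_cols(tibble(y = dat$y, chrom = dat$chrom), X)
  form_fixed <- paste("y ~", paste(terms, collapse = " + "))
  converged <- TRUE; singular <- FALSE; re_var <- NA_real_
  if (method == "glmer") {
    fit <- withCallingHandlers(
      lme4::glmer(stats::as.formula(paste(form_fixed, "+ (1 | chrom)")),
                  data = fit_dat, family = binomial()),
      warning = function(w) {
        if (grepl("converge", conditionMessage(w), ignore.case = TRUE)) {
          converged <<- FALSE
        }
        invokeRestart("muffleWarning")
      },
      message = function(m) invokeRestart("muffleMessage"))
    singular <- lme4::isSingular(fit)
    vc <- lme4::VarCorr(fit)
    re_var <- as.numeric(vc$chrom[1])
    sm <- summary(fit)$coefficients
  } else {
    fit <- stats::glm(stats::as.formula(paste(form_fixed, "+ chrom")),
                      data = fit_dat, family = binomial())
    converged <- fit$converged
    sm <- summary(fit)$coefficients
    sm <- sm[rownames(sm) %in% c("(Intercept)", terms), , drop = FALSE]
  }
  est <- sm[, 1]; se <- sm[, 2]
  sep <- names(est)[abs(est) > 15 & names(est) != "(Intercept)"]
  if (length(sep)) {
    abort(paste0("separation detected for predictor(s): ",
                 paste(sep, collapse = ", ")))
  }
  coefs <- tibble(
    term = rownames(sm),
    estimate = unname(est),
    std_error = unname(se),
    odds_ratio = exp(unname(est)),
    conf_low = exp(unname(est) - 1.96 * unname(se)),
    conf_high = exp(unname(est) + 1.96 * unname(se))
  )
  structure(list(coefficients = coefs, method = method,
                 converged = converged, singular = singular,
                 re_variance = re_var, n_cases = sum(dat$y == 1L),
                 n_controls = sum(dat$y == 0L), flank_bp = flank_bp,
                 dropped_gap_predictor = !has_gap, fit = fit),
            class = "sv_assoc")
}

# predictor matrix for a set of intervals
assoc_predictors <- function(x, layout, features, flank_bp) {
  mid <- floor((x$start + x$end) / 2)
  win <- tibble(chrom = x$chrom, start = mid - flank_bp, end = mid + flank_bp)
  len <- layout_length(layout, win$chrom)
  win$start <- pmax(0, win$start)
  win$end <- pmin(win$end, len)
  out <- tibble(
    dist_chrom_end = distance_to_chrom_end(x[, c("chrom", "start", "end")],
                                           layout),
    sv_length = x$end - x$start
  )
  if (nrow(layout$gaps) > 0) {
    dg <- distance_to_nearest(x, layout$gaps)
    # chromosomes without a gap: treat as maximally distant
    dg[is.na(dg)] <- max(dg, na.rm = TRUE)
    out$dist_gap <- dg
  }
  for (nm in names(features)) {
    out[[paste0("frac_", nm)]] <- feature_fraction(win, features[[nm]], layout)
  }
  out
}

#' @export
print.sv_assoc <- function(x, ...) {
  cat("<sv_assoc> ", x$n_cases, " SVs vs ", x$n_controls,
      " shuffled controls (", x$method,
      if (!x$converged) ", NOT converged" else "",
      if (x$singular) ", singular RE" else "", ")\n", sep = "")
  print(x$coefficients)
  invisible(x)
}

#' Tidy an SV/feature association fit
#'
#' @param x An `sv_assoc` object.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate` (standardized log-odds),
#'   `std_error`, `odds_ratio`, `conf_low`, `conf_high`.
#' @export
tidy.sv_assoc <- function(x, ...) x$coefficients

#' @rdname tidy.sv_assoc
#' @return For `glance`: one-row tibble with fit-level metadata.
#' @export
glance.sv_assoc <- function(x, ...) {
  tibble(n_cases = x$n_cases, n_controls = x$n_controls,
         method = x$method, converged = x$converged, singular = x$singular,
         re_variance = x$re_variance, flank_bp = x$flank_bp)
}

#' Forest plot of an SV/feature association fit
#'
#' Odds ratios with 95% confidence intervals per predictor, on a log scale.
#'
#' @param object An `sv_assoc` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sv_assoc <- function(object, ...) {
  d <- filter(object$coefficients, .data$term != "(Intercept)")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$odds_ratio, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf_low,
                                         xmax = .data$conf_high),
                            height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (95% CI)", y = NULL,
                  title = "SV occurrence vs genomic features") +
    ggplot2::theme_minimal()
}
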